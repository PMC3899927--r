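#' Simulate a two-condition expression dataset with known DE genes
#'
#' Generates a genes x samples matrix of log2 intensities with a planted set
#' of differentially expressed genes, in the style of two-condition
#' microarray simulators: each gene gets a baseline log2 level drawn
#' uniformly from `baseline_range`; a fraction `p_de` of genes receive a
#' signed log2 shift in the test group with magnitude uniform in
#' `lfc_range` (up-regulated with probability `up_fraction`); every observed
#' value is the gene-level mean plus independent Gaussian noise of standard
#' deviation `sigma_n`. The generator is fully reproducible from `seed`
#' (which is mandatory) and restores the caller's RNG state on exit.
#'
#' Defaults mirror a standard simulation study design: 10,000 genes, 7 + 7
#' samples, 2% DE genes (an expected 200), noise level 0.4 log2 units
#' (the middle of the commonly explored 0.2-0.6 range).
#'
#' @param n Number of genes.
#' @param m1,m2 Number of control and test samples.
#' @param p_de Proportion of DE genes in `[0, 1]`.
#' @param sigma_n Additive Gaussian noise standard deviation, log2 units.
#' @param lfc_range Length-2 range of planted `|log2 FC|`.
#' @param baseline_range Length-2 range of baseline log2 expression.
#' @param up_fraction Probability that a DE gene is up-regulated.
#' @param seed Integer seed (required).
#'
#' @return Object of class `"sim_dataset"`: list with `data` (an
#'   [expression_set()]), `de_indices` (sorted indices of planted DE genes),
#'   `true_lfc` (length-`n` signed log2 effect, 0 for non-DE genes) and
#'   `config` (the parameters used).
#'
#' @examples
#' sim <- simulate_dataset(n = 500, m1 = 3, m2 = 3, seed = 42)
#' sim$data
#' length(sim$de_indices)  # round(500 * 0.02) = 10
#' @export
simulate_dataset <- function(n = 10000, m1 = 7, m2 = 7, p_de = 0.02,
                             sigma_n = 0.4, lfc_range = c(0.6, 3),
                             baseline_range = c(4, 14), up_fraction = 0.5,
                             seed) {
  cfg <- check_sim_config(n, m1, m2, p_de, sigma_n, lfc_range,
                          baseline_range, up_fraction, seed)
  truth <- sim_truth(cfg)
  values <- sim_values(truth, cfg, seed = cfg$seed, shift = 0)
  new_sim_dataset(truth, values, cfg)
}

#' Simulate two batches sharing the same ground truth
#'
#' Draws one set of gene baselines and planted DE effects (from `seed`),
#' then generates two batches of samples with independent noise; the second
#' batch receives an additive global offset `batch_shift` (emulating an
#' uncorrected batch effect) and uses `seed2` for its noise. With
#' `batch_shift = 0` and `seed2 = seed` the second batch is a verbatim copy
#' of the first.
#'
#' @inheritParams simulate_dataset
#' @param batch_shift Additive log2 offset applied to every value of the
#'   second batch.
#' @param seed2 Integer seed for the second batch's noise.
#' @return List with elements `batch1` and `batch2`, each a `"sim_dataset"`
#'   sharing `de_indices` and `true_lfc`.
#' @export
simulate_two_batches <- function(n = 10000, m1 = 7, m2 = 7, p_de = 0.02,
                                 sigma_n = 0.4, lfc_range = c(0.6, 3),
                                 baseline_range = c(4, 14),
                                 up_fraction = 0.5, seed,
                                 batch_shift = 0, seed2) {
  cfg <- check_sim_config(n, m1, m2, p_de, sigma_n, lfc_range,
                          baseline_range, up_fraction, seed)
  if (missing(seed2)) stop("'seed2' is required", call. = FALSE)
  truth <- sim_truth(cfg)
  v1 <- sim_values(truth, cfg, seed = cfg$seed, shift = 0)
  v2 <- sim_values(truth, cfg, seed = as.integer(seed2),
                   shift = as.numeric(batch_shift))
  list(batch1 = new_sim_dataset(truth, v1, cfg),
       batch2 = new_sim_dataset(truth, v2, cfg))
}

check_sim_config <- function(n, m1, m2, p_de, sigma_n, lfc_range,
                             baseline_range, up_fraction, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (n < 2 || m1 < 1 || m2 < 1 || p_de < 0 || p_de > 1 || sigma_n < 0 ||
      length(lfc_range) != 2L || lfc_range[1L] > lfc_range[2L] ||
      length(baseline_range) != 2L ||
      baseline_range[1L] >= baseline_range[2L] ||
      up_fraction < 0 || up_fraction > 1)
    stop("invalid simulation configuration", call. = FALSE)
  n_de <- round(n * p_de)
  if (n_de == 0 && p_de > 0)
    warning("p_de > 0 but round(n * p_de) = 0: no DE genes planted")
  list(n = as.integer(n), m1 = as.integer(m1), m2 = as.integer(m2),
       p_de = p_de, sigma_n = sigma_n, lfc_range = lfc_range,
       baseline_range = baseline_range, up_fraction = up_fraction,
       seed = as.integer(seed), n_de = as.integer(n_de))
}

# run expr with a locally seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

sim_truth <- function(cfg) {
  with_seed(cfg$seed, {
    mu <- stats::runif(cfg$n, cfg$baseline_range[1L], cfg$baseline_range[2L])
    de <- if (cfg$n_de > 0L) sort(sample.int(cfg$n, cfg$n_de)) else integer(0)
    lfc <- numeric(cfg$n)
    if (cfg$n_de > 0L) {
      sign <- ifelse(stats::runif(cfg$n_de) < cfg$up_fraction, 1, -1)
      lfc[de] <- sign * stats::runif(cfg$n_de, cfg$lfc_range[1L],
                                     cfg$lfc_range[2L])
    }
    list(mu = mu, de_indices = de, true_lfc = lfc)
  })
}

sim_values <- function(truth, cfg, seed, shift) {
  m <- cfg$m1 + cfg$m2
  means <- cbind(matrix(truth$mu, cfg$n, cfg$m1),
                 matrix(truth$mu + truth$true_lfc, cfg$n, cfg$m2))
  noise <- with_seed(seed,
    matrix(stats::rnorm(cfg$n * m, sd = cfg$sigma_n), cfg$n, m))
  vals <- means + noise + shift
  dimnames(vals) <- list(sprintf("gene_%05d", seq_len(cfg$n)),
                         c(sprintf("ctrl_%02d", seq_len(cfg$m1)),
                           sprintf("test_%02d", seq_len(cfg$m2))))
  vals
}

new_sim_dataset <- function(truth, values, cfg) {
  es <- expression_set(values, control = seq_len(cfg$m1),
                       test = cfg$m1 + seq_len(cfg$m2),
                       scale = "log2-intensity")
  structure(list(data = es, de_indices = truth$de_indices,
                 true_lfc = truth$true_lfc, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated two-condition dataset: ", x$config$n, " genes, ",
      x$config$m1, " + ", x$config$m2, " samples, ",
      length(x$de_indices), " DE genes (sigma_n = ", x$config$sigma_n,
      ", seed = ", x$config$seed, ")\n", sep = "")
  invisible(x)
}
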