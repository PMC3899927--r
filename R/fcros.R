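#' Enumerate pairwise control/test sample comparisons
#'
#' Builds the ordered list of (control, test) sample pairs used for the
#' pairwise fold-change comparisons. The full grid of `m1 * m2` pairs is
#' enumerated in control-major order (all test samples against control 1,
#' then control 2, ...); when `k` is smaller than the full grid the first
#' `k` pairs of this canonical order are taken, so the pairing is
#' deterministic and reproducible.
#'
#' @param m1,m2 Number of control and test samples.
#' @param k Number of comparisons to use: `"all"` (default) for the full
#'   `m1 * m2` grid, or an integer in `[1, m1 * m2]`.
#'
#' @return Integer matrix with `k` rows and columns `control`, `test`
#'   holding within-group sample positions (1-based).
#'
#' @examples
#' build_pairing(2, 2)            # the full 4-pair grid
#' build_pairing(3, 2, k = 5)     # first 5 pairs of the 3 x 2 grid
#' @export
build_pairing <- function(m1, m2, k = "all") {
  m1 <- as.integer(m1); m2 <- as.integer(m2)
  if (m1 < 1L || m2 < 1L)
    stop("'m1' and 'm2' must be at least 1", call. = FALSE)
  kmax <- m1 * m2
  if (identical(k, "all")) k <- kmax
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > kmax)
    stop("'k' must be \"all\" or an integer in [1, ", kmax, "]",
         call. = FALSE)
  grid <- cbind(control = rep(seq_len(m1), each = m2),
                test = rep(seq_len(m2), times = m1))
  grid[seq_len(k), , drop = FALSE]
}

#' Pairwise log2 fold changes
#'
#' Computes the n x k matrix of per-comparison log2 fold changes
#' (test minus control, i.e. log2 of the test/control ratio since the data
#' are on the log2 scale).
#'
#' @param x An [expression_set()].
#' @param pairing Pair matrix from [build_pairing()]; positions index within
#'   the control and test groups of `x`.
#'
#' @return Numeric matrix, genes x comparisons.
#' @export
pairwise_log_fc <- function(x, pairing = build_pairing(length(x$control),
                                                       length(x$test))) {
  stopifnot(inherits(x, "expression_set"))
  if (any(pairing[, 1L] > length(x$control)) ||
      any(pairing[, 2L] > length(x$test)) || any(pairing < 1L))
    stop("pairing refers to samples outside the declared groups",
         call. = FALSE)
  fc <- x$values[, x$test[pairing[, 2L]], drop = FALSE] -
        x$values[, x$control[pairing[, 1L]], drop = FALSE]
  dimnames(fc) <- list(gene_ids(x), NULL)
  fc
}

#' Per-comparison ascending ranks with midrank ties
#'
#' Ranks each column of a fold-change matrix in increasing order. Tied
#' values receive midranks (the average of the integer ranks they span), so
#' every column sums to `n(n+1)/2` exactly, with or without ties.
#'
#' @param fc Numeric matrix of log2 fold changes, genes x comparisons, with
#'   at least 2 rows and all entries finite.
#' @return Numeric matrix of ranks in `[1, n]`, same shape as `fc`.
#' @export
rank_columns <- function(fc) {
  fc <- as.matrix(fc)
  if (nrow(fc) < 2L) stop("at least 2 genes are required", call. = FALSE)
  if (any(!is.finite(fc))) stop("non-finite fold change values", call. = FALSE)
  apply(fc, 2L, rank, ties.method = "average")
}

#' Standardized trimmed rank means
#'
#' For each gene, sorts its `k` per-comparison ranks, removes
#' `floor(k * trim)` ranks from each end, averages the remainder and divides
#' by `n`. The trimming makes the rank summary robust to outlier samples: a
#' `trim` of 0.1 means 80% of a gene's ranks enter its mean.
#'
#' @param ranks Rank matrix from [rank_columns()].
#' @param trim Fraction in `[0, 0.5)` of ranks removed from each end.
#' @return Numeric vector of standardized rank means, one per gene, in
#'   `(0, 1]`.
#' @export
trimmed_rank_means <- function(ranks, trim = 0.3) {
  ranks <- as.matrix(ranks)
  n <- nrow(ranks)
  k <- ncol(ranks)
  if (!is.numeric(trim) || length(trim) != 1L || trim < 0 || trim >= 0.5)
    stop("'trim' must be a single value in [0, 0.5)", call. = FALSE)
  if (k - 2L * floor(k * trim) < 1L)
    stop("'trim' leaves no ranks to average (k = ", k, ")", call. = FALSE)
  rbar <- apply(ranks, 1L, mean, trim = trim) / n
  names(rbar) <- rownames(ranks)
  rbar
}

#' Fit the rank-ordering model
#'
#' Summarises a vector of standardized trimmed rank means by the parameters
#' of the rank-ordering model: the extremes `a` and `b`, the mean gap
#' `delta_hat` between consecutive sorted rank means (which telescopes to
#' `(b - a)/(n - 1)`), and the sample mean `R_bar` and sample variance
#' `sigma2_hat` (divisor `n - 1`) used as the parameters of the normal
#' distribution from which f-values are read.
#'
#' @param rbar Standardized rank means in `(0, 1]`, length `n >= 2`.
#' @param trim Trim fraction used to produce `rbar` (stored for reporting).
#' @return Object of class `"rank_summary"`: list with `rbar`, `a`, `b`,
#'   `delta_hat`, `R_bar`, `sigma2_hat`, `trim` and `n`.
#' @seealso [theoretical_moments()] for the large-`k` theoretical values.
#' @export
fit_rank_model <- function(rbar, trim = NA_real_) {
  n <- length(rbar)
  if (n < 2L) stop("at least 2 rank means are required", call. = FALSE)
  if (any(!is.finite(rbar)) || any(rbar <= 0) || any(rbar > 1))
    stop("standardized rank means must lie in (0, 1]", call. = FALSE)
  a <- min(rbar)
  b <- max(rbar)
  sigma2 <- stats::var(rbar)
  if (sigma2 == 0)
    stop("all rank means are identical: rank model variance is degenerate ",
         "and f-values are undefined", call. = FALSE)
  structure(list(rbar = rbar, a = a, b = b,
                 delta_hat = (b - a) / (n - 1),
                 R_bar = mean(rbar), sigma2_hat = sigma2,
                 trim = trim, n = n),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat("Rank-ordering model (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  a = %.6g, b = %.6g\n", x$a, x$b))
  cat(sprintf("  delta_hat = %.6g (rank-scale n*delta_hat = %.4f)\n",
              x$delta_hat, x$n * x$delta_hat))
  cat(sprintf("  R_bar = %.6g, sigma2_hat = %.6g\n", x$R_bar, x$sigma2_hat))
  invisible(x)
}

#' f-values: probabilities from the rank-ordering model
#'
#' Converts standardized rank means into probabilities via the normal
#' distribution with the fitted sample mean and variance:
#' `f_i = pnorm((rbar_i - R_bar) / sigma_hat)`. An f-value near 0 flags a
#' down-regulated gene, near 0.5 an equally expressed gene, and near 1 an
#' up-regulated gene. Values are kept strictly inside (0, 1).
#'
#' @param rbar Standardized rank means.
#' @param model A `"rank_summary"` from [fit_rank_model()].
#' @return Numeric vector of f-values in (0, 1).
#' @export
f_values <- function(rbar, model) {
  stopifnot(inherits(model, "rank_summary"))
  if (model$sigma2_hat <= 0)
    stop("degenerate rank model variance", call. = FALSE)
  f <- stats::pnorm((rbar - model$R_bar) / sqrt(model$sigma2_hat))
  pmin(pmax(f, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Three-way DE classification from f-values
#'
#' Calls a gene down-regulated when `f <= alpha1`, up-regulated when
#' `f >= alpha2`, and equally expressed (EE) otherwise. The expected
#' selection error of the resulting DE list is
#' `100 * (alpha1 + 1 - alpha2)` percent (see [selection_error()]).
#'
#' @param f Vector of f-values in (0, 1).
#' @param alpha1,alpha2 Lower and upper thresholds, `0 < alpha1 < alpha2 < 1`.
#' @return List with `call` (factor with levels down/EE/up) and
#'   `error_percent`.
#' @export
classify_genes <- function(f, alpha1 = 0.025, alpha2 = 0.975) {
  check_alphas(alpha1, alpha2)
  call <- factor(ifelse(f <= alpha1, "down", ifelse(f >= alpha2, "up", "EE")),
                 levels = c("down", "EE", "up"))
  names(call) <- names(f)
  list(call = call, error_percent = selection_error(alpha1, alpha2))
}

check_alphas <- function(alpha1, alpha2) {
  if (!is.numeric(alpha1) || !is.numeric(alpha2) ||
      alpha1 <= 0 || alpha2 >= 1 || alpha1 >= alpha2)
    stop("thresholds must satisfy 0 < alpha1 < alpha2 < 1", call. = FALSE)
  invisible(TRUE)
}

#' Expected selection error of an f-value DE list
#'
#' `100 * (alpha1 + 1 - alpha2)`: the percentage of the f-value distribution
#' captured by the two selection tails, i.e. the expected false-call rate of
#' the combined down + up list.
#'
#' @param alpha1,alpha2 Selection thresholds, `0 < alpha1 < alpha2 < 1`.
#' @return Error in percent.
#' @examples
#' selection_error(0.025, 0.975)  # symmetric 2.5% tails -> 5%
#' @export
selection_error <- function(alpha1, alpha2) {
  check_alphas(alpha1, alpha2)
  100 * (alpha1 + 1 - alpha2)
}

#' Expected selection error of a p-value cutoff list
#'
#' For selection of `n_selected` genes out of `n` at a p-value threshold
#' `alpha`, the expected percentage of false calls is
#' `100 * alpha * n / n_selected`.
#'
#' @param alpha p-value threshold used for the selection.
#' @param n Total number of genes tested.
#' @param n_selected Number of genes selected.
#' @return Error in percent.
#' @export
ttest_selection_error <- function(alpha, n, n_selected) {
  if (alpha <= 0 || alpha >= 1 || n < 1 || n_selected < 1)
    stop("invalid arguments", call. = FALSE)
  100 * alpha * n / n_selected
}

#' Per-gene fold change
#'
#' For one-color (log2-intensity) data the fold change is the ratio of
#' arithmetic means of the unlogged values, `mean(2^x_test) / mean(2^x_ctrl)`
#' (`method = "arithmetic"`, the default). `method = "geometric"` returns
#' `2^(mean(x_test) - mean(x_ctrl))` instead; for two-color (log2-ratio)
#' data absolute intensities are unavailable, so the geometric form is
#' always used.
#'
#' @param x An [expression_set()].
#' @param method `"arithmetic"` or `"geometric"`.
#' @return Named numeric vector of positive fold changes, one per gene.
#' @examples
#' m <- matrix(c(3, 3, 4, 4), nrow = 1)
#' es <- expression_set(rbind(m, m + 1), control = 1:2, test = 3:4)
#' fold_changes(es)  # both genes doubled: FC = 2
#' @export
fold_changes <- function(x, method = c("arithmetic", "geometric")) {
  stopifnot(inherits(x, "expression_set"))
  method <- match.arg(method)
  if (x$scale == "log2-ratio") method <- "geometric"
  ctrl <- x$values[, x$control, drop = FALSE]
  test <- x$values[, x$test, drop = FALSE]
  fc <- if (method == "arithmetic") {
    rowMeans(2^test) / rowMeans(2^ctrl)
  } else {
    2^(rowMeans(test) - rowMeans(ctrl))
  }
  names(fc) <- gene_ids(x)
  fc
}

#' Theoretical moments of equally spaced ordered rank means
#'
#' For ordered averages of ranks lying on an exact grid
#' `a, a + delta, ..., a + (n-1) delta = b`, the limiting normal
#' distribution has mean `(a + b)/2` and variance `(n^2 - 1)/12 * delta^2`.
#' These are diagnostics: the fitted model uses the sample moments.
#'
#' @param a,b Minimum and maximum ordered rank means.
#' @param n Number of genes.
#' @param delta Gap between consecutive ordered rank means; defaults to
#'   `(b - a)/(n - 1)`.
#' @return Named vector `c(mean, variance)`.
#' @examples
#' theoretical_moments(1, 100, 100)  # ideal case: mean 50.5, var (n^2-1)/12
#' @export
theoretical_moments <- function(a, b, n, delta = (b - a) / (n - 1)) {
  if (n < 2 || b < a || delta < 0) stop("invalid arguments", call. = FALSE)
  c(mean = (a + b) / 2, variance = (n^2 - 1) / 12 * delta^2)
}

#' Fold change rank ordering statistics (FCROS)
#'
#' Fits the FCROS model to a two-condition expression matrix. Log2 fold
#' changes are computed for `k` pairwise control/test comparisons, ranked in
#' increasing order within each comparison (midranks for ties), and each
#' gene's ranks are summarised by a trimmed mean divided by `n`. A normal
#' distribution with the sample mean and variance of these standardized rank
#' means assigns each gene a probability, its f-value: close to 0 for
#' down-regulated genes, 0.5 for unchanged genes and 1 for up-regulated
#' genes. Because a single global model produces all probabilities, no
#' per-gene multiple-testing correction is involved. The procedure is fully
#' deterministic.
#'
#' @param x An [expression_set()], or a numeric matrix/data frame of log2
#'   values (rows = genes) in which case `control` and `test` select the
#'   sample columns.
#' @param control,test Column indices or names when `x` is a plain matrix;
#'   ignored when `x` is already an `expression_set`.
#' @param trim Trim fraction for the per-gene rank mean (default 0.3).
#' @param k Number of pairwise comparisons: `"all"` (default) or an integer
#'   up to `m1 * m2`; see [build_pairing()].
#' @param alpha1,alpha2 f-value thresholds for calling down- and
#'   up-regulated genes.
#' @param fc.method Fold-change report: `"arithmetic"` (ratio of unlogged
#'   means, default) or `"geometric"` (`2^` mean log difference).
#' @param scale Passed to [expression_set()] when `x` is a plain matrix.
#'
#' @return Object of class `"fcros"`: list with `results` (data frame with
#'   columns `gene_id`, `rbar`, `f_value`, `fold_change`, `call`), `model`
#'   (the fitted [fit_rank_model()] summary), `k`, `alpha1`, `alpha2`,
#'   `error_percent` and the matched call. Methods: `print`, `summary`,
#'   `coef` (named f-values), `plot`, `as.data.frame`.
#'
#' @examples
#' sim <- simulate_dataset(n = 300, m1 = 4, m2 = 4, p_de = 0.05,
#'                         sigma_n = 0.2, seed = 7)
#' fit <- fcros(sim$data)
#' fit
#' head(as.data.frame(fit))
#' @export
fcros <- function(x, control = NULL, test = NULL, trim = 0.3, k = "all",
                  alpha1 = 0.025, alpha2 = 0.975,
                  fc.method = c("arithmetic", "geometric"),
                  scale = c("log2-intensity", "log2-ratio")) {
  cl <- match.call()
  if (!inherits(x, "expression_set"))
    x <- expression_set(x, control = control, test = test,
                        scale = match.arg(scale))
  check_alphas(alpha1, alpha2)
  pairing <- build_pairing(length(x$control), length(x$test), k)
  fc <- pairwise_log_fc(x, pairing)
  fit <- fcros_from_fc(fc, trim = trim, alpha1 = alpha1, alpha2 = alpha2)
  fit$results$fold_change <- unname(fold_changes(x, match.arg(fc.method)))
  fit$results <- fit$results[, c("gene_id", "rbar", "f_value",
                                 "fold_change", "call")]
  fit$k <- nrow(pairing)
  fit$call <- cl
  fit
}

# shared tail of fcros()/fcros2(): rank, trim, fit, classify
fcros_from_fc <- function(fc, trim, alpha1, alpha2) {
  ranks <- rank_columns(fc)
  rbar <- trimmed_rank_means(ranks, trim)
  model <- fit_rank_model(rbar, trim = trim)
  f <- f_values(rbar, model)
  cls <- classify_genes(f, alpha1, alpha2)
  results <- data.frame(gene_id = rownames(fc), rbar = unname(rbar),
                        f_value = unname(f), call = unname(cls$call),
                        stringsAsFactors = FALSE)
  structure(list(results = results, model = model, k = ncol(fc),
                 alpha1 = alpha1, alpha2 = alpha2,
                 error_percent = cls$error_percent),
            class = "fcros")
}

#' Two-batch FCROS
#'
#' Applies FCROS to data from two experimental batches without any
#' inter-batch normalization: pairwise fold-change comparisons are formed
#' within each batch only (`k = k1 + k2` columns) and the pooled rank matrix
#' is then summarised exactly as in [fcros()]. Because ranks are invariant
#' to any batch-wide monotone shift, batch-level biases cancel without
#' explicit correction. Both batches must contain the same genes in the same
#' order.
#'
#' The reported fold change is the geometric mean of the two per-batch fold
#' changes, since a ratio of unlogged means pooled across unnormalized
#' batches would mix batch effects into the estimate.
#'
#' @param batch1,batch2 [expression_set()] objects over identical gene ids.
#' @param trim,alpha1,alpha2,fc.method As in [fcros()]; all `m1 * m2`
#'   within-batch pairs are used in each batch.
#' @return An object of class `"fcros"` (see [fcros()]); `k` is `k1 + k2`.
#' @export
fcros2 <- function(batch1, batch2, trim = 0.3, alpha1 = 0.025,
                   alpha2 = 0.975, fc.method = c("arithmetic", "geometric")) {
  cl <- match.call()
  stopifnot(inherits(batch1, "expression_set"),
            inherits(batch2, "expression_set"))
  g1 <- gene_ids(batch1); g2 <- gene_ids(batch2)
  if (length(g1) != length(g2) || any(g1 != g2)) {
    i <- if (length(g1) != length(g2)) NA_integer_ else which(g1 != g2)[1L]
    stop("batches must share the same gene ids in the same order",
         if (!is.na(i)) paste0(": first mismatch at row ", i, " ('", g1[i],
                               "' vs '", g2[i], "')"),
         call. = FALSE)
  }
  check_alphas(alpha1, alpha2)
  fc.method <- match.arg(fc.method)
  fc <- cbind(pairwise_log_fc(batch1), pairwise_log_fc(batch2))
  fit <- fcros_from_fc(fc, trim = trim, alpha1 = alpha1, alpha2 = alpha2)
  fit$results$fold_change <-
    unname(sqrt(fold_changes(batch1, fc.method) *
                fold_changes(batch2, fc.method)))
  fit$results <- fit$results[, c("gene_id", "rbar", "f_value",
                                 "fold_change", "call")]
  fit$call <- cl
  fit
}

#' @export
print.fcros <- function(x, ...) {
  cat("FCROS fit: ", nrow(x$results), " genes, k = ", x$k,
      " pairwise comparisons\n", sep = "")
  tab <- table(x$results$call)
  cat("  calls: ", tab[["down"]], " down, ", tab[["EE"]], " EE, ",
      tab[["up"]], " up  (alpha1 = ", x$alpha1, ", alpha2 = ", x$alpha2,
      ", expected error ", format(x$error_percent), "%)\n", sep = "")
  invisible(x)
}

#' @export
summary.fcros <- function(object, ...) {
  structure(list(fit = object), class = "summary.fcros")
}

#' @export
print.summary.fcros <- function(x, ...) {
  fit <- x$fit
  print(fit)
  print(fit$model)
  f <- fit$results$f_value
  cat("  f-value quartiles:",
      paste(format(stats::quantile(f), digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.fcros <- function(object, ...) {
  stats::setNames(object$results$f_value, object$results$gene_id)
}

#' @export
as.data.frame.fcros <- function(x, ...) x$results

#' Plot an FCROS fit
#'
#' Plots the sorted standardized rank means against their order index, the
#' near-linear pattern that underlies the normal approximation, with genes
#' coloured by their down/EE/up call.
#'
#' @param x An `"fcros"` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fcros <- function(x, ...) {
  ord <- order(x$results$rbar)
  col <- c(down = "blue", EE = "grey60", up = "red")[
    as.character(x$results$call[ord])]
  graphics::plot(seq_along(ord), x$results$rbar[ord], col = col, pch = 20,
                 xlab = "gene order", ylab = "standardized trimmed rank mean",
                 main = "Ordered averages of ranks", ...)
  invisible(x)
}
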