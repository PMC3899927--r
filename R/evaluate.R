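#' Confusion counts for a selected gene list
#'
#' Standard 2x2 counts of a selection against a ground-truth DE set over a
#' universe of `n` genes.
#'
#' @param selected Indices (or ids) of selected genes.
#' @param truth Indices (or ids) of true DE genes.
#' @param n Total number of genes in the universe.
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @examples
#' confusion_counts(c(1, 2, 5), c(1, 2, 3), n = 10)
#' @export
confusion_counts <- function(selected, truth, n) {
  selected <- unique(selected); truth <- unique(truth)
  tp <- length(intersect(selected, truth))
  fp <- length(selected) - tp
  fn <- length(truth) - tp
  c(TP = tp, FP = fp, FN = fn, TN = as.integer(n) - tp - fp - fn)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve for a per-gene score against a binary truth,
#' computed by the Mann-Whitney rank formulation: the probability that a
#' randomly chosen true DE gene receives a higher score than a randomly
#' chosen non-DE gene, with midranks handling ties. For f-values, pass the
#' two-sided DE ordering `abs(f - 0.5)` (see [de_score()]).
#'
#' @param statistic Numeric score per gene; larger means more DE.
#' @param truth Logical vector (or indices into `statistic`) marking the
#'   true DE genes; both classes must be non-empty.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(statistic, truth) {
  if (!is.logical(truth)) {
    pos <- logical(length(statistic)); pos[truth] <- TRUE; truth <- pos
  }
  if (length(truth) != length(statistic))
    stop("'truth' must match 'statistic' in length", call. = FALSE)
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0L || nneg == 0L)
    stop("need at least one DE and one non-DE gene", call. = FALSE)
  r <- rank(statistic, ties.method = "average")
  (sum(r[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Two-sided DE ordering of f-values
#'
#' Maps f-values to a single score suitable for top-N selection and AUC:
#' `abs(f - 0.5)`, large for both strongly down- (f near 0) and up-regulated
#' (f near 1) genes.
#'
#' @param f Vector of f-values.
#' @return Non-negative scores.
#' @export
de_score <- function(f) abs(f - 0.5)

#' Subsampling stability scores
#'
#' Assesses the stability of a method's top gene list under sample
#' subsampling. Each run (a) randomly selects `m1_sub` control and `m2_sub`
#' test samples — or, with `randomize_groups = TRUE`, draws
#' `m1_sub + m2_sub` samples from the pooled columns irrespective of their
#' biological group, the null protocol used to calibrate a score threshold —
#' (b) computes the method's statistic on the subsample and (c) assigns 1 to
#' the `top_n` most DE genes and 0 to the rest. Per-gene scores accumulate
#' over `runs` repetitions, so every score lies in `[0, runs]` and the
#' scores always sum to `runs * top_n`.
#'
#' @param x An [expression_set()].
#' @param method One of `"fcros"`, `"fc"`, `"wad"`, `"ttest"`. Top-N
#'   ordering: `abs(f - 0.5)` for fcros, `max(FC, 1/FC)` for fc, `|WAD|`
#'   for wad, `|t|` for ttest; ties broken by gene order.
#' @param m1_sub,m2_sub Subsample sizes for the two groups.
#' @param runs Number of repetitions.
#' @param top_n Number of genes scored 1 per run.
#' @param seed Integer seed (required; the procedure is otherwise
#'   deterministic).
#' @param randomize_groups If `TRUE`, ignore the biological groups when
#'   drawing samples (null calibration protocol).
#' @param trim Trim fraction for the fcros method.
#' @return Object of class `"score_table"`: list with `gene_ids`, `score`
#'   (integer per gene), `runs`, `top_n` and `protocol`
#'   (`"true-groups"` or `"randomized-groups"`).
#' @export
subsample_score <- function(x, method = c("fcros", "fc", "wad", "ttest"),
                            m1_sub, m2_sub, runs = 100, top_n = 100, seed,
                            randomize_groups = FALSE, trim = 0.3) {
  stopifnot(inherits(x, "expression_set"))
  method <- match.arg(method)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  m1 <- length(x$control); m2 <- length(x$test)
  m1_sub <- as.integer(m1_sub); m2_sub <- as.integer(m2_sub)
  if (runs < 1L || top_n < 1L || top_n > nrow(x$values))
    stop("invalid 'runs' or 'top_n'", call. = FALSE)
  if (randomize_groups) {
    if (m1_sub + m2_sub > m1 + m2)
      stop("subsample larger than the pooled sample set", call. = FALSE)
  } else if (m1_sub > m1 || m2_sub > m2) {
    stop("subsample larger than a sample group", call. = FALSE)
  }
  if (m1_sub < 1L || m2_sub < 1L)
    stop("subsample sizes must be at least 1", call. = FALSE)

  n <- nrow(x$values)
  score <- integer(n)
  with_seed(as.integer(seed), {
    for (r in seq_len(runs)) {
      if (randomize_groups) {
        pool <- sample(c(x$control, x$test), m1_sub + m2_sub)
        ctrl <- pool[seq_len(m1_sub)]
        test <- pool[m1_sub + seq_len(m2_sub)]
      } else {
        ctrl <- sample(x$control, m1_sub)
        test <- sample(x$test, m2_sub)
      }
      sub <- expression_set(x$values, control = ctrl, test = test,
                            scale = x$scale)
      s <- method_score(sub, method, trim)
      top <- order(-s, seq_along(s))[seq_len(top_n)]
      score[top] <- score[top] + 1L
    }
  })
  structure(list(gene_ids = gene_ids(x), score = score, runs = as.integer(runs),
                 top_n = as.integer(top_n),
                 protocol = if (randomize_groups) "randomized-groups"
                            else "true-groups"),
            class = "score_table")
}

# two-sided DE ordering score of each baseline method (larger = more DE)
method_score <- function(x, method, trim) {
  switch(method,
    fcros = {
      fc <- pairwise_log_fc(x)
      rbar <- trimmed_rank_means(rank_columns(fc), trim)
      de_score(f_values(rbar, fit_rank_model(rbar, trim)))
    },
    fc = {
      f <- fold_changes(x)
      pmax(f, 1 / f)
    },
    wad = abs(wad_statistic(x)$wad),
    ttest = abs(ttest_statistics(x)$t_statistic))
}

#' @export
print.score_table <- function(x, ...) {
  cat("Subsampling score table (", x$protocol, "): ", length(x$score),
      " genes, ", x$runs, " runs, top ", x$top_n, " per run\n", sep = "")
  cat("  genes with score > 0: ", sum(x$score > 0L), "; max score: ",
      max(x$score), "\n", sep = "")
  invisible(x)
}

#' Reproducibility counts from a score table
#'
#' Counts, for each threshold, the number of genes whose subsampling score
#' reaches the threshold — e.g. genes with a perfect score (`runs`) were in
#' the top list of every run.
#'
#' @param scores A `"score_table"` from [subsample_score()], or a numeric
#'   vector of scores.
#' @param thresholds Numeric thresholds.
#' @return Named integer vector of counts (one per threshold).
#' @examples
#' reproducibility_counts(c(100, 95, 40, 0), thresholds = c(100, 90))
#' @export
reproducibility_counts <- function(scores, thresholds) {
  s <- if (inherits(scores, "score_table")) scores$score else scores
  stats::setNames(vapply(thresholds, function(th) sum(s >= th), integer(1)),
                  thresholds)
}
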