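#' Pooled two-sample Student t-test
#'
#' Equal-variance two-sample t-test for a single gene:
#' `t = (mean(test) - mean(control)) / (sp * sqrt(1/m1 + 1/m2))` with the
#' pooled variance
#' `sp^2 = ((m1-1) s1^2 + (m2-1) s2^2) / (m1 + m2 - 2)` and a two-sided
#' p-value from the Student t distribution with `m1 + m2 - 2` degrees of
#' freedom. A small p-value need not mean a large fold change (small
#' fold change, small variance) and vice versa (large fold change, large
#' variance) — the contrast that motivates rank-based fold-change methods.
#'
#' @param control,test Numeric vectors of log2 values, each of length >= 2.
#' @return Object of class `"pooled_t"`: list with `t_statistic`,
#'   `pooled_variance`, `p_value`, `df` and the two group means.
#' @examples
#' pooled_t_test(rnorm(5), rnorm(5, 1))
#' @export
pooled_t_test <- function(control, test) {
  m1 <- length(control); m2 <- length(test)
  if (m1 < 2L || m2 < 2L)
    stop("both groups need at least 2 samples", call. = FALSE)
  if (any(!is.finite(control)) || any(!is.finite(test)))
    stop("non-finite values", call. = FALSE)
  df <- m1 + m2 - 2L
  sp2 <- ((m1 - 1) * stats::var(control) + (m2 - 1) * stats::var(test)) / df
  if (sp2 == 0)
    stop("pooled variance is zero: t statistic undefined", call. = FALSE)
  tt <- (mean(test) - mean(control)) / sqrt(sp2 * (1 / m1 + 1 / m2))
  structure(list(t_statistic = tt, pooled_variance = sp2,
                 p_value = 2 * stats::pt(-abs(tt), df), df = df,
                 mean_control = mean(control), mean_test = mean(test)),
            class = "pooled_t")
}

#' @export
print.pooled_t <- function(x, ...) {
  cat(sprintf("Pooled two-sample t-test: t = %.4g on %d df, p = %.4g (sp^2 = %.4g)\n",
              x$t_statistic, x$df, x$p_value, x$pooled_variance))
  invisible(x)
}

#' Per-gene pooled t statistics for an expression set
#'
#' Vectorised [pooled_t_test()] over all genes of an [expression_set()].
#'
#' @param x An [expression_set()] with at least 2 samples per group.
#' @return Data frame with columns `gene_id`, `t_statistic`,
#'   `pooled_variance`, `p_value`.
#' @export
ttest_statistics <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  ctrl <- x$values[, x$control, drop = FALSE]
  test <- x$values[, x$test, drop = FALSE]
  m1 <- ncol(ctrl); m2 <- ncol(test)
  if (m1 < 2L || m2 < 2L)
    stop("both groups need at least 2 samples", call. = FALSE)
  df <- m1 + m2 - 2L
  v1 <- apply(ctrl, 1L, stats::var)
  v2 <- apply(test, 1L, stats::var)
  sp2 <- ((m1 - 1) * v1 + (m2 - 1) * v2) / df
  tt <- (rowMeans(test) - rowMeans(ctrl)) / sqrt(sp2 * (1 / m1 + 1 / m2))
  data.frame(gene_id = gene_ids(x), t_statistic = unname(tt),
             pooled_variance = unname(sp2),
             p_value = unname(2 * stats::pt(-abs(tt), df)),
             stringsAsFactors = FALSE)
}

#' Weighted average difference (WAD) statistic
#'
#' For each gene the average difference on the log2 scale,
#' `AD_i = mean(test_i) - mean(control_i)`, is weighted by the gene's
#' relative overall expression,
#' `w_i = (xbar_i - min(xbar)) / (max(xbar) - min(xbar))` where `xbar_i` is
#' the mean over all samples: `WAD_i = AD_i * w_i`. The weight promotes
#' highly expressed genes — two genes with equal average difference rank by
#' their overall expression level.
#'
#' @param x An [expression_set()].
#' @return Data frame with columns `gene_id`, `ad`, `weight`, `wad`.
#' @export
wad_statistic <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  ctrl <- x$values[, x$control, drop = FALSE]
  test <- x$values[, x$test, drop = FALSE]
  ad <- rowMeans(test) - rowMeans(ctrl)
  xbar <- rowMeans(cbind(ctrl, test))
  rng <- range(xbar)
  if (rng[1L] == rng[2L])
    stop("all genes have the same overall mean: WAD weights are degenerate",
         call. = FALSE)
  w <- (xbar - rng[1L]) / (rng[2L] - rng[1L])
  data.frame(gene_id = gene_ids(x), ad = unname(ad), weight = unname(w),
             wad = unname(ad * w), stringsAsFactors = FALSE)
}

#' Simple fold-change ranking
#'
#' Ranks genes by fold change with a two-sided score `max(FC, 1/FC)` so that
#' down- and up-regulated genes compete on the same footing (an FC of 0.2 is
#' more extreme than an FC of 4 because 1/0.2 = 5 > 4). Rank 1 is the most
#' extreme gene; ties are broken by gene order for determinism.
#'
#' @param x An [expression_set()].
#' @param method Fold-change definition, see [fold_changes()].
#' @return Data frame with columns `gene_id`, `fold_change`, `score`
#'   (`max(FC, 1/FC)`) and `rank`.
#' @export
fc_ranking <- function(x, method = c("arithmetic", "geometric")) {
  fc <- fold_changes(x, match.arg(method))
  score <- pmax(fc, 1 / fc)
  rank <- integer(length(score))
  rank[order(-score, seq_along(score))] <- seq_along(score)
  data.frame(gene_id = names(fc), fold_change = unname(fc),
             score = unname(score), rank = rank, stringsAsFactors = FALSE)
}
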