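#' Two-condition expression set
#'
#' Container for a genes x samples matrix of log2 expression values together
#' with the assignment of columns to the control and test groups. For
#' one-color platforms the values are log2 intensities
#' (`scale = "log2-intensity"`); for two-color platforms they are log2 ratios
#' (`scale = "log2-ratio"`). All downstream rank computations only use
#' within-pair differences, so the two scales are treated identically except
#' for how the reported fold change is derived (see [fold_changes()]).
#'
#' @param values Numeric matrix (or data frame) with `n >= 2` rows (genes) and
#'   at least `m1 + m2` columns (samples); all entries must be finite.
#' @param control,test Column indices (integer) or column names (character)
#'   of the control and test samples. Must be disjoint and non-empty.
#' @param gene_ids Character vector of unique gene/probe identifiers, one per
#'   row. Defaults to the row names of `values`.
#' @param scale `"log2-intensity"` (one-color) or `"log2-ratio"` (two-color).
#'
#' @return An object of class `"expression_set"`: a list with elements
#'   `values` (numeric matrix with gene ids as row names), `control` and
#'   `test` (integer column indices) and `scale`.
#'
#' @examples
#' m <- matrix(rnorm(20, mean = 8), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' es <- expression_set(m, control = 1:2, test = 3:4)
#' es
#' @export
expression_set <- function(values, control, test, gene_ids = rownames(values),
                           scale = c("log2-intensity", "log2-ratio")) {
  scale <- match.arg(scale)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  n <- nrow(values)
  if (n < 2L) stop("at least 2 genes are required", call. = FALSE)

  control <- resolve_columns(control, values, "control")
  test <- resolve_columns(test, values, "test")
  if (length(intersect(control, test)) > 0L)
    stop("control and test sample sets must be disjoint", call. = FALSE)

  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(n))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != n)
    stop("'gene_ids' must have one entry per row of 'values'", call. = FALSE)
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    stop("duplicated gene id: '", dup, "'", call. = FALSE)
  }
  bad <- which(!is.finite(values[, c(control, test), drop = FALSE]))
  if (length(bad) > 0L) {
    sub <- values[, c(control, test), drop = FALSE]
    i <- ((bad[1L] - 1L) %% nrow(sub)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(sub)) + 1L
    stop("non-finite expression value for gene '", gene_ids[i],
         "', sample '", colnames(sub)[j], "'", call. = FALSE)
  }
  rownames(values) <- gene_ids
  structure(list(values = values, control = control, test = test,
                 scale = scale),
            class = "expression_set")
}

resolve_columns <- function(idx, values, what) {
  if (is.character(idx)) {
    miss <- setdiff(idx, colnames(values))
    if (length(miss) > 0L)
      stop("unknown ", what, " sample(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    idx <- match(idx, colnames(values))
  }
  idx <- as.integer(idx)
  if (length(idx) < 1L || anyNA(idx) || any(idx < 1L) || any(idx > ncol(values)))
    stop("invalid ", what, " column indices", call. = FALSE)
  if (anyDuplicated(idx))
    stop("duplicated ", what, " column indices", call. = FALSE)
  idx
}

#' @export
print.expression_set <- function(x, ...) {
  cat("Two-condition expression set (", x$scale, ")\n", sep = "")
  cat("  genes:   ", nrow(x$values), "\n", sep = "")
  cat("  samples: ", length(x$control), " control, ", length(x$test),
      " test\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_set <- function(x) {
  c(nrow(x$values), length(x$control) + length(x$test))
}

gene_ids <- function(x) rownames(x$values)
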