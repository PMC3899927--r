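#' Read an expression table from TSV/CSV
#'
#' Reads a delimited expression table whose first column holds gene ids and
#' remaining columns hold samples, validates it, and attaches the
#' control/test group assignment. Groups come either from `control`/`test`
#' (indices into the sample columns, or sample names) or from a two-column
#' design file/data frame with columns `sample_id` and `group` (values
#' `control` or `test`).
#'
#' @param path Path to the table. Tab-separated by default; files ending in
#'   `.csv` are read comma-separated.
#' @param design Optional design: a path to a TSV/CSV with columns
#'   `sample_id`, `group`, or an equivalent data frame.
#' @param control,test Used when `design` is `NULL`: sample column indices
#'   (1 = first sample column) or sample names.
#' @param scale Expression scale, see [expression_set()].
#' @param sep Field separator; inferred from the extension by default.
#' @return An [expression_set()].
#' @export
read_expression_table <- function(path, design = NULL, control = NULL,
                                  test = NULL,
                                  scale = c("log2-intensity", "log2-ratio"),
                                  sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA, comment.char = "")
  if (ncol(tab) < 3L)
    stop("expected a gene id column plus at least 2 sample columns",
         call. = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated gene id: '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  num <- tab[-1L]
  for (j in seq_along(num)) {
    if (!is.numeric(num[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(num[[j]]))))[1L]
      stop("non-numeric value in column '", names(num)[j], "', row ",
           bad, " (gene '", ids[bad], "')", call. = FALSE)
    }
  }
  values <- as.matrix(num)
  rownames(values) <- ids

  if (!is.null(design)) {
    d <- if (is.data.frame(design)) design else {
      dsep <- if (grepl("\\.csv$", design, TRUE)) "," else "\t"
      utils::read.table(design, header = TRUE, sep = dsep,
                        stringsAsFactors = FALSE)
    }
    if (!all(c("sample_id", "group") %in% names(d)))
      stop("design needs columns 'sample_id' and 'group'", call. = FALSE)
    if (!all(d$group %in% c("control", "test")))
      stop("design groups must be 'control' or 'test'", call. = FALSE)
    miss <- setdiff(d$sample_id, colnames(values))
    if (length(miss) > 0L)
      stop("design samples missing from the table: ",
           paste(miss, collapse = ", "), call. = FALSE)
    control <- d$sample_id[d$group == "control"]
    test <- d$sample_id[d$group == "test"]
  }
  if (is.null(control) || is.null(test))
    stop("provide either a design or both 'control' and 'test'",
         call. = FALSE)
  expression_set(values, control = control, test = test, gene_ids = ids,
                 scale = match.arg(scale))
}

#' Write an expression set (plus optional truth) to TSV
#'
#' Writes the matrix as a TSV (first column `gene_id`) and, for simulated
#' datasets, a companion truth table with columns `gene_id`, `is_de`,
#' `true_lfc`.
#'
#' @param x An [expression_set()] or `"sim_dataset"`.
#' @param path Output TSV path.
#' @param truth_path Optional path for the ground-truth table (only for
#'   `"sim_dataset"` input).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, truth_path = NULL) {
  sim <- NULL
  if (inherits(x, "sim_dataset")) { sim <- x; x <- x$data }
  stopifnot(inherits(x, "expression_set"))
  vals <- x$values[, c(x$control, x$test), drop = FALSE]
  write_tsv(data.frame(gene_id = gene_ids(x), vals, check.names = FALSE,
                       stringsAsFactors = FALSE), path)
  if (!is.null(truth_path)) {
    if (is.null(sim))
      stop("truth output requires a simulated dataset", call. = FALSE)
    is_de <- as.integer(seq_len(nrow(vals)) %in% sim$de_indices)
    write_tsv(data.frame(gene_id = gene_ids(x), is_de = is_de,
                         true_lfc = sim$true_lfc, stringsAsFactors = FALSE),
              truth_path)
  }
  invisible(path)
}

#' Write an FCROS result to TSV with a summary sidecar
#'
#' Writes the per-gene table (`gene_id`, `rbar`, `f_value`, `fold_change`,
#' `call`) in the input gene order at full numeric precision, plus a
#' key-value sidecar `<path>.summary` with the fitted model diagnostics
#' (`a`, `b`, `delta_hat`, `R_bar`, `sigma2_hat`, `trim`, `k`, `alpha1`,
#' `alpha2`, `error_percent`).
#'
#' @param fit An `"fcros"` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fcros_results <- function(fit, path) {
  stopifnot(inherits(fit, "fcros"))
  write_tsv(fit$results, path)
  m <- fit$model
  kv <- c(a = m$a, b = m$b, delta_hat = m$delta_hat, R_bar = m$R_bar,
          sigma2_hat = m$sigma2_hat, trim = m$trim, k = fit$k,
          alpha1 = fit$alpha1, alpha2 = fit$alpha2,
          error_percent = fit$error_percent)
  writeLines(paste(names(kv), fmt_num(kv), sep = "\t"),
             paste0(path, ".summary"))
  invisible(path)
}

#' Read back an FCROS result table
#'
#' @param path Path written by [write_fcros_results()].
#' @return Data frame with the per-gene result columns.
#' @export
read_fcros_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# full-precision TSV writer (numbers survive a round trip bit-exactly)
write_tsv <- function(df, path) {
  for (j in seq_along(df)) if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
    df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.numeric(v) && v == round(v) && abs(v) < 1e15)
      return(format(v, scientific = FALSE))
    sprintf("%.17g", as.numeric(v))
  }, character(1))
  out
}

#' Bundled two-gene Agilent example
#'
#' A small real-data example: log2 intensities of two genes (MACF1 and
#' TREM2) over 10 control and 10 test samples from a one-color Agilent
#' hybridisation. MACF1 is the classic "small fold change, small variance"
#' case (FC 0.88 with a t-test p-value of 2.5e-4) and TREM2 the "large fold
#' change, large variance" case (FC 6.26 with p = 0.013) — the pair of
#' observations that motivates fold-change rank statistics.
#'
#' @return An [expression_set()] with 2 genes and 20 samples.
#' @examples
#' es <- two_gene_example()
#' fold_changes(es)
#' @export
two_gene_example <- function() {
  read_expression_table(
    system.file("extdata", "agilent_two_gene.tsv", package = "fcrank",
                mustWork = TRUE),
    design = system.file("extdata", "agilent_two_gene_design.tsv",
                         package = "fcrank", mustWork = TRUE))
}
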