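#' Expression datasets
#'
#' An expression dataset is a genes x samples matrix of expression values
#' together with its time-series design: `n_times` time points measured on
#' `n_replicates` replicates. Columns are ordered replicate-major: all time
#' points of replicate 1 first, then replicate 2, and so on. Steady-state
#' (non-time-series) data use `n_times = 1` with one column per sample or
#' set `is_time_series = FALSE`.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene names),
#'   samples in columns.
#' @param n_times Number of time points `T` (>= 1).
#' @param n_replicates Number of replicates `R` (>= 1).
#' @param is_time_series Whether the columns follow the `T x R` time-series
#'   layout; when `TRUE`, `ncol(values)` must equal `n_times * n_replicates`.
#'
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, n_times, n_replicates,
                               is_time_series = n_times > 1L) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "bmanet_read_error")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%02d", seq_len(nrow(values)))
  }
  genes <- rownames(values)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    abort(paste0("Duplicate gene names: ", paste(dup, collapse = ", ")),
          class = "bmanet_read_error")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    abort(sprintf("Non-finite expression value at gene '%s', sample column %d.",
                  genes[bad[1L]], bad[2L]),
          class = "bmanet_read_error")
  }
  n_times <- as.integer(n_times)
  n_replicates <- as.integer(n_replicates)
  if (n_times < 1L || n_replicates < 1L) {
    abort("`n_times` and `n_replicates` must be >= 1.", class = "bmanet_read_error")
  }
  if (isTRUE(is_time_series) && ncol(values) != n_times * n_replicates) {
    abort(sprintf(
      "Declared design (%d time points x %d replicates = %d samples) does not match %d columns.",
      n_times, n_replicates, n_times * n_replicates, ncol(values)),
      class = "bmanet_dimension_error")
  }
  structure(
    list(values = values, gene_names = genes, n_times = n_times,
         n_replicates = n_replicates, is_time_series = isTRUE(is_time_series)),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples (%s: T = %d, R = %d)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_time_series) "time series" else "steady state",
              x$n_times, x$n_replicates))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' One row per gene: the first field is the gene name, remaining fields are
#' numeric expression values. Columns must be ordered replicate-major
#' (all time points of replicate 1, then replicate 2, ...); the declared
#' `n_times * n_replicates` must match the column count.
#'
#' @param path Path to a tab-separated file.
#' @inheritParams expression_dataset
#' @return An [expression_dataset].
#' @export
read_expression <- function(path, n_times, n_replicates,
                            is_time_series = n_times > 1L) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) {
    abort("Expression file needs a gene-name column plus at least one sample column.",
          class = "bmanet_read_error")
  }
  genes <- raw[[1L]]
  num <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(num), dim = dim(num)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    abort(sprintf("Non-numeric cell '%s' at row %d (gene '%s'), sample column %d.",
                  num[bad[1L], bad[2L]], bad[1L], genes[bad[1L]], bad[2L]),
          class = "bmanet_read_error")
  }
  rownames(vals) <- genes
  expression_dataset(vals, n_times, n_replicates, is_time_series)
}

#' Write an expression dataset to TSV
#'
#' Values are printed with 17 significant digits so a write/read round trip
#' reproduces them exactly.
#'
#' @param dataset An [expression_dataset].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  lines <- vapply(seq_len(nrow(dataset$values)), function(i) {
    paste(c(dataset$gene_names[i], sprintf("%.17g", dataset$values[i, ])),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
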