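#' Build the regression design for one target gene
#'
#' In time-series mode the design stacks, for every replicate, the lag-1
#' pairs: predictors are all genes' expression at time `t - 1` and the
#' response is the target's expression at time `t`, for `t = 2 ... T`, so
#' `n = R * (T - 1)` rows. In steady-state mode predictors and response are
#' taken over all `n = R * T` samples. The target gene's own (lagged) value
#' is excluded from the candidate columns unless `self_edges = TRUE`.
#'
#' Both response and predictor columns are centered and scaled to unit
#' sample variance; zero-variance candidate columns are dropped and
#' recorded in `$dropped`.
#'
#' @param dataset An [expression_dataset].
#' @param target Gene index or gene name of the response.
#' @param time_series Use the lag-1 time-series design (default: the
#'   dataset's own flag).
#' @param self_edges Keep the target's own lagged value as a candidate.
#' @return A list of class `bma_design` with fields `y` (length `n`), `X`
#'   (`n x p`), `candidate_indices` (gene index per column), `n`, `target`,
#'   `dropped` (gene indices of zero-variance candidates), `y_scale`.
#' @export
build_design <- function(dataset, target,
                         time_series = dataset$is_time_series,
                         self_edges = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.character(target)) {
    target <- match(target, dataset$gene_names)
    if (is.na(target)) abort("Unknown target gene name.")
  }
  target <- as.integer(target)
  stopifnot(target >= 1L, target <= nrow(dataset$values))
  vals <- dataset$values
  Tn <- dataset$n_times
  R <- dataset$n_replicates

  if (time_series) {
    if (Tn < 2L) {
      abort("Time-series design needs at least 2 time points.",
            class = "bmanet_design_error")
    }
    prev_cols <- integer(0)
    next_cols <- integer(0)
    for (r in seq_len(R)) {
      base <- (r - 1L) * Tn
      prev_cols <- c(prev_cols, base + seq_len(Tn - 1L))
      next_cols <- c(next_cols, base + 1L + seq_len(Tn - 1L))
    }
    X <- t(vals[, prev_cols, drop = FALSE])
    y <- vals[target, next_cols]
  } else {
    X <- t(vals)
    y <- vals[target, ]
  }
  n <- length(y)
  if (n < 3L) {
    abort("Fewer than 3 usable samples.", class = "bmanet_design_error")
  }

  candidates <- seq_len(nrow(vals))
  if (!self_edges) candidates <- candidates[candidates != target]
  X <- X[, candidates, drop = FALSE]

  sds <- apply(X, 2L, stats::sd)
  dropped <- candidates[sds == 0]
  keep <- sds > 0
  X <- X[, keep, drop = FALSE]
  candidates <- candidates[keep]
  sds <- sds[keep]

  y_sd <- stats::sd(y)
  if (y_sd == 0) {
    abort(sprintf("Target gene '%s' has constant expression.",
                  dataset$gene_names[target]),
          class = "bmanet_degenerate_target")
  }
  X <- scale(X, center = TRUE, scale = sds)
  y <- (y - mean(y)) / y_sd
  attributes(X)[c("scaled:center", "scaled:scale")] <- NULL

  structure(
    list(y = as.numeric(y), X = X, candidate_indices = candidates,
         n = n, target = target, dropped = dropped, y_scale = y_sd,
         gene_names = dataset$gene_names),
    class = "bma_design")
}
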