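#' Prior edge probabilities
#'
#' A prior matrix maps ordered (regulator, target) gene pairs to prior
#' inclusion probabilities; pairs not listed fall back to `default_prior`.
#' When `default_prior` is `NULL`, the sparse-network default `1 / p`
#' is used at scan time, where `p` is the number of candidate regulators
#' for the target under consideration.
#'
#' @param pairs A data frame with columns `regulator`, `target`,
#'   `probability` (gene names and a probability in `[0, 1]`), or `NULL`
#'   for no informative priors.
#' @param default_prior Fallback probability in `(0, 1)`, or `NULL` for the
#'   per-target `1/p` default.
#' @return An object of class `prior_matrix`.
#' @export
prior_matrix <- function(pairs = NULL, default_prior = NULL) {
  if (!is.null(default_prior)) {
    if (!is.numeric(default_prior) || length(default_prior) != 1L ||
        default_prior <= 0 || default_prior >= 1) {
      abort("`default_prior` must be a single probability in (0, 1).")
    }
  }
  if (is.null(pairs)) {
    pairs <- tibble(regulator = character(), target = character(),
                    probability = double())
  } else {
    pairs <- as_tibble(pairs)
    stopifnot(all(c("regulator", "target", "probability") %in% names(pairs)))
    if (any(pairs$probability < 0 | pairs$probability > 1)) {
      abort("Prior probabilities must lie in [0, 1].")
    }
  }
  structure(list(pairs = pairs, default_prior = default_prior,
                 informative = nrow(pairs) > 0L),
            class = "prior_matrix")
}

#' @export
print.prior_matrix <- function(x, ...) {
  cat(sprintf("<prior_matrix> %d informative pairs, default = %s\n",
              nrow(x$pairs),
              if (is.null(x$default_prior)) "1/p" else
                format(x$default_prior)))
  invisible(x)
}

#' Read prior edge probabilities from TSV
#'
#' Rows are `regulator<TAB>target<TAB>probability`. Rows naming genes absent
#' from `dataset` are skipped with a warning that reports how many were
#' dropped; probabilities outside `[0, 1]` are an error naming the line.
#'
#' @param path Path to a 3-column TSV (no header).
#' @param dataset The [expression_dataset] whose genes define valid names.
#' @inheritParams prior_matrix
#' @return A [prior_matrix] restricted to genes present in `dataset`.
#' @export
read_priors <- function(path, dataset, default_prior = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, colClasses = "character",
                      stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    return(prior_matrix(NULL, default_prior))
  }
  if (ncol(raw) < 3L) {
    abort("Prior file needs 3 columns: regulator, target, probability.",
          class = "bmanet_read_error")
  }
  prob <- suppressWarnings(as.numeric(raw[[3L]]))
  if (anyNA(prob)) {
    abort(sprintf("Non-numeric prior probability '%s' at line %d.",
                  raw[[3L]][which(is.na(prob))[1L]], which(is.na(prob))[1L]),
          class = "bmanet_read_error")
  }
  bad <- which(prob < 0 | prob > 1)
  if (length(bad)) {
    abort(sprintf("Prior probability %g outside [0, 1] at line %d.",
                  prob[bad[1L]], bad[1L]),
          class = "bmanet_read_error")
  }
  known <- raw[[1L]] %in% dataset$gene_names & raw[[2L]] %in% dataset$gene_names
  n_skipped <- sum(!known)
  if (n_skipped > 0L) {
    warn(sprintf("Skipped %d prior rows naming genes absent from the dataset.",
                 n_skipped))
  }
  pm <- prior_matrix(
    tibble(regulator = raw[[1L]][known], target = raw[[2L]][known],
           probability = prob[known]),
    default_prior)
  attr(pm, "n_skipped") <- n_skipped
  pm
}

# Prior inclusion probability for each candidate regulator of `target_name`,
# clamped away from exact 0/1 so no model is impossible or mandatory.
# The uninformative default 1/p gives every target an expected in-degree of
# one edge, the sparse-network regime of real regulatory networks.
prior_vector <- function(priors, target_name, candidate_names) {
  p <- length(candidate_names)
  default <- priors$default_prior
  if (is.null(default)) default <- 1 / max(p, 2L)
  pi <- rep(default, p)
  if (priors$informative) {
    rows <- priors$pairs[priors$pairs$target == target_name, ]
    idx <- match(rows$regulator, candidate_names)
    keep <- !is.na(idx)
    pi[idx[keep]] <- rows$probability[keep]
  }
  pmin(pmax(pi, 1e-6), 1 - 1e-6)
}
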