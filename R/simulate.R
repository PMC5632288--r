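#' Sample a sparse random ground-truth network
#'
#' Each ordered non-self gene pair receives a directed regulatory edge
#' independently with probability `density`; edge coefficients are drawn
#' uniformly from `±[lo, hi]`. If the resulting coefficient matrix has
#' spectral radius above 0.9 it is rescaled to radius 0.9 so the lag-1
#' dynamics are stable.
#'
#' @param n_genes Number of genes (>= 2).
#' @param density Expected edge fraction in `(0, 1)` (or 0 for an empty
#'   network).
#' @param coeff_range Length-2 vector `c(lo, hi)` of absolute coefficient
#'   bounds.
#' @param seed Integer seed; the network is a deterministic function of the
#'   arguments.
#' @return An object of class `grn_truth`: `adjacency` (matrix `A` with
#'   `A[i, j]` the coefficient of regulator `j` on target `i`), `edges`
#'   tibble (`regulator`, `target`, `coefficient`), `density`, `genes`.
#' @export
sample_network <- function(n_genes, density, coeff_range = c(0.5, 0.9),
                           seed = 1L) {
  stopifnot(n_genes >= 2L, density >= 0, density < 1)
  genes <- sprintf("G%02d", seq_len(n_genes))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  A <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
  off <- which(row(A) != col(A))
  present <- off[runif(length(off)) < density]
  coef <- runif(length(present), coeff_range[1L], coeff_range[2L]) *
    sample(c(-1, 1), length(present), replace = TRUE)
  A[present] <- coef
  rad <- if (length(present)) max(abs(eigen(A, only.values = TRUE)$values)) else 0
  if (rad > 0.9) A <- A * (0.9 / rad)
  idx <- which(A != 0, arr.ind = TRUE)
  edges <- tibble(regulator = genes[idx[, 2L]], target = genes[idx[, 1L]],
                  coefficient = A[idx])
  structure(list(adjacency = A, edges = edges, density = density,
                 genes = genes),
            class = "grn_truth")
}

#' @export
print.grn_truth <- function(x, ...) {
  cat(sprintf("<grn_truth> %d genes, %d edges (density %.3g)\n",
              length(x$genes), nrow(x$edges), x$density))
  invisible(x)
}

#' Simulate lag-1 linear Gaussian expression dynamics
#'
#' Per replicate, the initial state is standard normal per gene and each
#' subsequent time point is `x_t = A x_{t-1} + e`, with independent
#' Gaussian noise `e ~ N(0, noise_sd^2)` per gene — the first-order vector
#' autoregression that matches the inference model, so parameter recovery
#' is an attributable test of the estimator. Columns are laid out
#' replicate-major (all time points of replicate 1 first).
#'
#' @param truth A [sample_network()] object.
#' @param n_times Number of time points `T` (>= 2).
#' @param n_replicates Number of replicates.
#' @param noise_sd Innovation standard deviation.
#' @param seed Integer seed.
#' @return An [expression_dataset].
#' @export
simulate_expression <- function(truth, n_times, n_replicates,
                                noise_sd = 0.2, seed = 1L) {
  stopifnot(inherits(truth, "grn_truth"), n_times >= 2L, n_replicates >= 1L,
            noise_sd >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  A <- truth$adjacency
  ng <- nrow(A)
  vals <- matrix(NA_real_, ng, n_times * n_replicates,
                 dimnames = list(truth$genes, NULL))
  for (r in seq_len(n_replicates)) {
    x <- rnorm(ng)
    base <- (r - 1L) * n_times
    vals[, base + 1L] <- x
    for (t in 2L:n_times) {
      x <- drop(A %*% x) + rnorm(ng, sd = noise_sd)
      vals[, base + t] <- x
    }
  }
  expression_dataset(vals, n_times, n_replicates, is_time_series = TRUE)
}

#' @rdname sample_network
#' @param x A `grn_truth` object.
#' @param ... Unused.
#' @export
tidy.grn_truth <- function(x, ...) x$edges
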