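# Incremental-Cholesky regression engine.
#
# Every candidate model is an index set over the design's columns. The
# normal-equations matrix X'X restricted to the member columns is kept as
# an upper-triangular Cholesky factor R (R'R = X'X[members, members]).
# Adding a variable borders the factor with one new column (O(k^2));
# removing one deletes its column and restores triangularity with Givens
# rotations (O(k^2)), so a scan that perturbs a model by one variable never
# pays the O(k^3) cost of refactorizing. X'X, X'y and y'y are precomputed
# once per design.

# scalar-multiplication counters, used by tests to assert cost scaling
.chol_ops <- new.env(parent = emptyenv())
.chol_ops$count <- 0

chol_ops_reset <- function() .chol_ops$count <- 0
chol_ops_get <- function() .chol_ops$count
chol_ops_add <- function(n) .chol_ops$count <- .chol_ops$count + n

# Precomputed cross-products for a design (the regression cache).
reg_cache <- function(design) {
  list(XtX = crossprod(design$X), Xty = drop(crossprod(design$X, design$y)),
       yty = sum(design$y^2), p = ncol(design$X), n = design$n)
}

new_chol_state <- function(members, factor) {
  list(members = as.integer(members), factor = factor)
}

# Dense factorization of the member submatrix, with one ridge-jitter retry
# (1e-10 * trace / k on the diagonal) on numerical failure.
factor_from_scratch <- function(cache, members) {
  members <- as.integer(members)
  if (anyDuplicated(members)) abort("Duplicate members.", class = "bmanet_degenerate_model")
  k <- length(members)
  if (k == 0L) return(new_chol_state(integer(0), matrix(0, 0, 0)))
  S <- cache$XtX[members, members, drop = FALSE]
  chol_ops_add(k^3 / 3)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    jitter <- 1e-10 * sum(diag(S)) / k
    R <- tryCatch(chol(S + diag(jitter, k)), error = function(e) NULL)
    if (is.null(R)) {
      abort("Member columns are numerically singular even after ridge jitter.",
            class = "bmanet_degenerate_model")
    }
  }
  dimnames(R) <- NULL
  new_chol_state(members, R)
}

# Border the factor with column j: solve R' r = X'X[members, j], then the
# new diagonal entry is sqrt(XtX[j,j] - r'r). Collinearity surfaces as a
# non-positive pivot.
add_variable <- function(state, cache, j) {
  j <- as.integer(j)
  if (j %in% state$members) abort("Variable already in model.", class = "bmanet_degenerate_model")
  k <- length(state$members)
  d <- cache$XtX[j, j]
  if (k == 0L) {
    if (d <= 0) abort("Zero-norm column.", class = "bmanet_degenerate_model")
    return(new_chol_state(j, matrix(sqrt(d), 1L, 1L)))
  }
  c_vec <- cache$XtX[state$members, j]
  r <- forwardsolve(t(state$factor), c_vec)
  chol_ops_add(k * (k + 1) / 2)
  rho2 <- d - sum(r^2)
  if (rho2 <= 1e-10 * d) {
    abort("New column is collinear with current members.",
          class = "bmanet_degenerate_model")
  }
  Rn <- rbind(cbind(state$factor, r), c(rep(0, k), sqrt(rho2)))
  dimnames(Rn) <- NULL
  new_chol_state(c(state$members, j), Rn)
}

# Delete member j's column; the factor becomes upper-Hessenberg from j's
# position on, and Givens rotations on adjacent row pairs restore the
# triangle (qrupdate-style delete).
remove_variable <- function(state, j) {
  j <- as.integer(j)
  pos <- match(j, state$members)
  if (is.na(pos)) abort("Variable not in model.", class = "bmanet_degenerate_model")
  k <- length(state$members)
  if (k == 1L) return(new_chol_state(integer(0), matrix(0, 0, 0)))
  R <- state$factor[, -pos, drop = FALSE]   # k x (k-1)
  m <- k - 1L
  for (q in seq_len(m - pos + 1L) + pos - 1L) {  # empty when pos == k
    a <- R[q, q]; b <- R[q + 1L, q]
    chol_ops_add(4 * (m - q + 1) + 2)
    if (b != 0) {
      hyp <- sqrt(a^2 + b^2)
      cth <- a / hyp; sth <- b / hyp
      rows <- R[c(q, q + 1L), q:m, drop = FALSE]
      R[q, q:m] <- cth * rows[1L, ] + sth * rows[2L, ]
      R[q + 1L, q:m] <- -sth * rows[1L, ] + cth * rows[2L, ]
    }
  }
  Rn <- R[seq_len(m), , drop = FALSE]
  # keep the conventional positive diagonal
  neg <- diag(Rn) < 0
  if (any(neg)) Rn[neg, ] <- -Rn[neg, , drop = FALSE]
  new_chol_state(state$members[-pos], Rn)
}

# R^2 and coefficients by back substitution. With centered, unit-variance
# response, TSS = y'y and R^2 = |z|^2 / y'y where R' z = X'y[members].
fit_statistics <- function(state, cache) {
  k <- length(state$members)
  if (k == 0L) {
    return(list(r2 = 0, betas = numeric(0), z = numeric(0)))
  }
  if (cache$yty <= 0) abort("Constant response.", class = "bmanet_degenerate_target")
  z <- forwardsolve(t(state$factor), cache$Xty[state$members])
  chol_ops_add(k * (k + 1))
  betas <- backsolve(state$factor, z)
  r2 <- min(max(sum(z^2) / cache$yty, 0), 1)
  list(r2 = r2, betas = betas, z = z)
}
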