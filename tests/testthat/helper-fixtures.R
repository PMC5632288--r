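# Shared fixture builders. Everything is generated in code at test time.

# random steady-state dataset whose first gene is a response built from a
# sparse linear signal over the remaining genes
random_problem <- function(seed, p = NULL, nobs = NULL, noise_sd = 1) {
  set.seed(seed)
  if (is.null(p)) p <- sample(4:10, 1L)
  if (is.null(nobs)) nobs <- sample(c(20L, 40L, 60L), 1L)
  X <- matrix(rnorm(nobs * p), nobs, p)
  ktrue <- sample(1:3, 1L)
  beta <- numeric(p)
  beta[sample(p, ktrue)] <- runif(ktrue, 0.3, 1) * sample(c(-1, 1), ktrue, TRUE)
  y <- as.numeric(X %*% beta + rnorm(nobs, sd = noise_sd))
  vals <- t(cbind(y, X))
  rownames(vals) <- c("Y", paste0("V", seq_len(p)))
  expression_dataset(vals, n_times = 1L, n_replicates = nobs,
                     is_time_series = FALSE)
}

# random standardized design matrix (for the regression-engine tests)
random_design <- function(seed, p = 8L, nobs = 50L) {
  ds <- random_problem(seed, p = p, nobs = nobs)
  build_design(ds, 1L, time_series = FALSE)
}

# dense least-squares R^2 via base QR: the independent fit oracle
qr_r2 <- function(design, members) {
  if (length(members) == 0L) return(0)
  fit <- qr(design$X[, members, drop = FALSE])
  yhat <- qr.fitted(fit, design$y)
  sum(yhat^2) / sum(design$y^2)
}

# dense refactorization oracle for a Cholesky state
scratch_factor <- function(design, members) {
  cache <- bmanet:::reg_cache(design)
  bmanet:::factor_from_scratch(cache, members)
}

# Exhaustive windowed BMA: enumerate all subsets, score with a dense
# Cholesky (independent of the incremental update path), apply the Occam
# window at g0 = n, optimize g, rescore, re-window, and sum weights into
# per-candidate inclusion probabilities.
brute_force_bma <- function(design, pi, odds_ratio) {
  p <- ncol(design$X)
  n <- design$n
  X <- design$X
  yty <- sum(design$y^2)
  subsets <- lapply(0:(2^p - 1L), function(b)
    which(bitwAnd(b, 2^(0:(p - 1L))) > 0))
  r2s <- vapply(subsets, function(m) {
    if (!length(m)) return(0)
    R <- chol(crossprod(X[, m, drop = FALSE]))
    z <- forwardsolve(t(R), crossprod(X[, m, drop = FALSE], design$y))
    min(max(sum(z^2) / yty, 0), 1)
  }, numeric(1L))
  ks <- lengths(subsets)
  lps <- vapply(subsets, function(m) log_model_prior(m, pi), numeric(1L))
  lpost <- ifelse(ks <= n - 2L,
                  log_marginal_likelihood(r2s, n, ks, n) + lps, -Inf)
  win <- lpost >= max(lpost) - log(odds_ratio)
  opt <- optimize_g(r2s[win], ks[win], lps[win], n)
  lpost2 <- log_marginal_likelihood(r2s[win], n, ks[win], opt$g) + lps[win]
  win2 <- lpost2 >= max(lpost2) - log(odds_ratio)
  w <- posterior_weights(lpost2[win2])
  subs <- subsets[win][win2]
  inc <- numeric(p)
  for (i in seq_along(subs)) inc[subs[[i]]] <- inc[subs[[i]]] + w[i]
  list(inclusion = inc, g = opt$g, members = subs)
}

# inclusion vector of a scan in design-column order
scan_inclusion <- function(scan, design) {
  scan$inclusion$inclusion[match(design$candidate_indices,
                                 scan$inclusion$regulator_index)]
}

# all simple directed paths u -> v with >= 2 edges: DFS path enumeration,
# returning the minimum -log-weight path length (Inf when none exists)
brute_force_indirect <- function(edges, u, v) {
  nodes <- unique(c(edges$regulator, edges$target))
  best <- Inf
  dfs <- function(node, visited, dist, depth) {
    out <- edges[edges$regulator == node, ]
    for (i in seq_len(nrow(out))) {
      head <- out$target[i]
      d <- dist - log(out$weight[i])
      if (depth == 0L && node == u && head == v) next  # skip the direct edge
      if (head == v) {
        if (depth >= 1L) best <<- min(best, d)
        next
      }
      if (head %in% visited) next
      dfs(head, c(visited, head), d, depth + 1L)
    }
  }
  dfs(u, u, 0, 0L)
  best
}

random_digraph <- function(seed, n_nodes = 8L, density = 0.3) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- expand.grid(regulator = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  keep <- runif(nrow(pairs)) < density
  edges <- pairs[keep, ]
  edges$weight <- runif(nrow(edges), 0.05, 1)
  grn_network(tibble::as_tibble(edges))
}
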