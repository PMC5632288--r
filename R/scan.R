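#' Search configuration
#'
#' Parameters of the Occam's-window model scan.
#'
#' @param odds_ratio Occam's window width `OR` (> 1): models whose posterior
#'   odds against the current best model fall below `1/OR` are discarded.
#'   Wider windows are slower and more accurate; 100, 1000 and 10000 are
#'   typical settings and 10000 is the default.
#' @param max_candidates Optional cap on the number of ranked candidate
#'   regulators considered per target (e.g. 100 to triage a genome-scale
#'   candidate set by prior probability or correlation).
#' @param self_edges Allow a gene's own (lagged) expression as a candidate.
#' @param time_series `NULL` to follow the dataset's flag, otherwise force
#'   lagged (`TRUE`) or steady-state (`FALSE`) designs.
#' @param seed Integer seed for the bit-filter hash codes.
#' @param rescan Repeat the scan at the optimized `g` until the model set
#'   is stable (at most 5 rounds) instead of the single scan-then-optimize
#'   pass.
#' @param edge_cutoff Minimum posterior inclusion probability for an edge
#'   to be kept in the output network.
#' @param dedupe `"filter"` for the constant-space bit filter (default) or
#'   `"exact"` for an exact hash set (used by oracle tests).
#' @param g_tol Tolerance of the Brent search for `g`.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(odds_ratio = 1e4, max_candidates = NULL,
                        self_edges = FALSE, time_series = NULL,
                        seed = 1L, rescan = FALSE, edge_cutoff = 0.5,
                        dedupe = c("filter", "exact"), g_tol = 1e-8) {
  dedupe <- match.arg(dedupe)
  if (!is.numeric(odds_ratio) || odds_ratio <= 1) {
    abort("`odds_ratio` must exceed 1.")
  }
  if (!is.null(max_candidates) && max_candidates < 1) {
    abort("`max_candidates` must be >= 1 when set.")
  }
  if (edge_cutoff < 0 || edge_cutoff > 1) abort("`edge_cutoff` must be in [0, 1].")
  structure(list(odds_ratio = odds_ratio, max_candidates = max_candidates,
                 self_edges = isTRUE(self_edges), time_series = time_series,
                 seed = as.integer(seed), rescan = isTRUE(rescan),
                 edge_cutoff = edge_cutoff, dedupe = dedupe, g_tol = g_tol),
            class = "scan_config")
}

#' Rank candidate regulators for one target
#'
#' With informative priors, candidates are ordered by descending prior
#' inclusion probability, ties broken by absolute Pearson correlation with
#' the response; with uniform priors this reduces to pure correlation
#' order, remaining ties broken by column index. Truncated to
#' `max_candidates` when set.
#'
#' @param design A [build_design()] object.
#' @param pi Prior inclusion probability per design column.
#' @param max_candidates Optional cap on the returned ranking.
#' @return Integer vector of design column indices, best first.
#' @export
order_candidates <- function(design, pi, max_candidates = NULL) {
  abscor <- abs(as.numeric(suppressWarnings(cor(design$X, design$y))))
  abscor[is.na(abscor)] <- 0
  ord <- order(-pi, -abscor, seq_along(pi))
  if (!is.null(max_candidates)) ord <- head(ord, max_candidates)
  ord
}

# One full Occam's-window expansion at fixed g: starting from `models`
# (a list of records), propose every single-variable addition and removal
# from every model ever admitted to the window, skip proposals the dedupe
# structure has seen, score the rest incrementally, and keep those within
# log(OR) of the running best. Returns the surviving window.
scan_window <- function(models, cache, pi, filter, config, g) {
  log_or <- log(config$odds_ratio)
  p <- cache$p
  best <- max(vapply(models, `[[`, numeric(1L), "log_post"))
  queue_i <- 1L
  exact <- inherits(filter, "exact_filter")

  while (queue_i <= length(models)) {
    m <- models[[queue_i]]
    queue_i <- queue_i + 1L
    in_model <- logical(p)
    in_model[m$members] <- TRUE
    # additions in ranked-candidate (column) order, then removals
    proposals <- c(which(!in_model), m$members)
    for (j in proposals) {
      adding <- !in_model[j]
      new_k <- m$k + if (adding) 1L else -1L
      if (new_k > cache$n - 2L) next         # score requires n > k + 1
      h <- update_hash(m$hash, filter$var_hash[j])
      seen <- if (exact) {
        exact_test_and_set(filter, if (adding) c(m$members, j) else
          setdiff(m$members, j))
      } else {
        filter_test_and_set(filter, h, new_k)
      }
      if (seen) next
      state <- tryCatch(
        if (adding) add_variable(m$state, cache, j) else
          remove_variable(m$state, j),
        bmanet_degenerate_model = function(e) NULL)
      if (is.null(state)) next
      fit <- fit_statistics(state, cache)
      lp <- if (adding) m$log_prior + log(pi[j]) - log1p(-pi[j]) else
        m$log_prior - log(pi[j]) + log1p(-pi[j])
      log_post <- log_marginal_likelihood(fit$r2, cache$n, new_k, g) + lp
      if (log_post >= best - log_or) {
        models[[length(models) + 1L]] <- list(
          members = sort(state$members), k = new_k, r2 = fit$r2,
          log_prior = lp, log_post = log_post, hash = h, state = state)
        if (log_post > best) best <- log_post
      }
    }
  }
  keep <- vapply(models, function(m) m$log_post >= best - log_or, logical(1L))
  models[keep]
}

#' Scan for the regulators of one target gene
#'
#' Runs the Occam's-window scan: starting from the null model at
#' `g0 = n`, all single-variable additions and removals of every model in
#' the current window are proposed, de-duplicated through the bit filter,
#' scored by incremental Cholesky regression under the g-prior, and
#' retained while within `log(OR)` of the best model, until a pass adds no
#' new model. Brent optimization then picks the `g` in `[1, n]` maximizing
#' the window's total posterior mass, all models are rescored at that `g`
#' and the window re-applied. The posterior inclusion probability of
#' candidate `j` is the summed weight of retained models containing `j`.
#'
#' @param dataset An [expression_dataset].
#' @param target Target gene index or name.
#' @param priors A [prior_matrix] (or `NULL` for the uninformative default).
#' @param config A [scan_config].
#' @return An object of class `bma_scan`: a list with `target`,
#'   `inclusion` (tibble of regulator, inclusion probability), `models`
#'   (tibble of retained models with weights), `g`, `n`, `n_evaluated`,
#'   `dropped`. Degenerate (constant-expression) targets yield an empty
#'   scan with a warning.
#' @export
scan_target <- function(dataset, target, priors = NULL,
                        config = scan_config()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(priors)) priors <- prior_matrix()
  ts <- if (is.null(config$time_series)) dataset$is_time_series else
    config$time_series
  design <- tryCatch(
    build_design(dataset, target, time_series = ts,
                 self_edges = config$self_edges),
    bmanet_degenerate_target = function(e) NULL)
  target_name <- if (is.character(target)) target else
    dataset$gene_names[target]
  if (is.null(design)) {
    warn(sprintf("Target '%s' has constant expression; skipped.", target_name))
    return(empty_scan(target_name))
  }

  pi_full <- prior_vector(priors, target_name,
                          dataset$gene_names[design$candidate_indices])
  ord <- order_candidates(design, pi_full, config$max_candidates)
  # restrict + reorder the design so column order is ranked order
  design$X <- design$X[, ord, drop = FALSE]
  design$candidate_indices <- design$candidate_indices[ord]
  pi <- pi_full[ord]

  cache <- reg_cache(design)
  filter <- if (config$dedupe == "exact") {
    init_exact_filter(cache$p, config$seed)
  } else {
    init_filter(cache$p, config$seed)
  }
  if (inherits(filter, "exact_filter")) {
    exact_test_and_set(filter, integer(0))
  } else {
    filter_test_and_set(filter, 0, 0)
  }

  null_model <- list(members = integer(0), k = 0L, r2 = 0,
                     log_prior = log_model_prior(integer(0), pi),
                     log_post = log_model_prior(integer(0), pi),
                     hash = 0, state = new_chol_state(integer(0), matrix(0, 0, 0)))
  g <- cache$n
  models <- scan_window(list(null_model), cache, pi, filter, config, g)

  rescore <- function(models, g) {
    for (i in seq_along(models)) {
      m <- models[[i]]
      models[[i]]$log_post <-
        log_marginal_likelihood(m$r2, cache$n, m$k, g) + m$log_prior
    }
    best <- max(vapply(models, `[[`, numeric(1L), "log_post"))
    models[vapply(models, function(m) m$log_post >= best - log(config$odds_ratio),
                  logical(1L))]
  }

  opt <- optimize_g(vapply(models, `[[`, numeric(1L), "r2"),
                    vapply(models, `[[`, numeric(1L), "k"),
                    vapply(models, `[[`, numeric(1L), "log_prior"),
                    cache$n, tol = config$g_tol)
  g <- opt$g
  models <- rescore(models, g)

  if (config$rescan) {
    for (round in seq_len(5L)) {
      n_before <- length(models)
      models <- scan_window(models, cache, pi, filter, config, g)
      opt <- optimize_g(vapply(models, `[[`, numeric(1L), "r2"),
                        vapply(models, `[[`, numeric(1L), "k"),
                        vapply(models, `[[`, numeric(1L), "log_prior"),
                        cache$n, tol = config$g_tol)
      g <- opt$g
      models <- rescore(models, g)
      if (length(models) == n_before) break
    }
  }

  w <- posterior_weights(vapply(models, `[[`, numeric(1L), "log_post"))
  inc <- numeric(cache$p)
  for (i in seq_along(models)) {
    inc[models[[i]]$members] <- inc[models[[i]]$members] + w[i]
  }
  inc <- pmin(inc, 1)

  structure(list(
    target = target_name,
    inclusion = tibble(
      regulator = dataset$gene_names[design$candidate_indices],
      regulator_index = design$candidate_indices,
      inclusion = inc),
    models = tibble(
      members = purrr::map(models, function(m)
        design$candidate_indices[m$members]),
      k = vapply(models, `[[`, integer(1L), "k"),
      r2 = vapply(models, `[[`, numeric(1L), "r2"),
      log_post = vapply(models, `[[`, numeric(1L), "log_post"),
      weight = w),
    g = g, n = cache$n, n_models = length(models),
    dropped = design$dropped), class = "bma_scan")
}

empty_scan <- function(target_name) {
  structure(list(target = target_name,
                 inclusion = tibble(regulator = character(),
                                    regulator_index = integer(),
                                    inclusion = double()),
                 models = tibble(members = list(), k = integer(),
                                 r2 = double(), log_post = double(),
                                 weight = double()),
                 g = NA_real_, n = NA_integer_, n_models = 0L,
                 dropped = integer()), class = "bma_scan")
}

#' @export
print.bma_scan <- function(x, ...) {
  cat(sprintf("<bma_scan> target '%s': %d models in window, g* = %s\n",
              x$target, x$n_models, format(x$g, digits = 4)))
  top <- dplyr::arrange(x$inclusion, dplyr::desc(.data$inclusion))
  print(head(top, 5L))
  invisible(x)
}

#' @rdname scan_target
#' @param x A `bma_scan` object.
#' @param ... Unused.
#' @export
tidy.bma_scan <- function(x, ...) {
  dplyr::arrange(x$inclusion, dplyr::desc(.data$inclusion))
}

#' @rdname scan_target
#' @export
glance.bma_scan <- function(x, ...) {
  tibble(target = x$target, n_models = x$n_models, g = x$g, n = x$n,
         best_log_post = if (nrow(x$models)) max(x$models$log_post) else NA_real_)
}
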