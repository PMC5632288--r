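#' Confusion counts at a weight threshold
#'
#' An edge is predicted at threshold `tau` when its weight is `>= tau`.
#' True positives are predicted edges present in the gold standard; false
#' positives predicted edges absent from it; false negatives gold edges not
#' predicted; true negatives the remaining pairs of the universe.
#'
#' @param pred A [grn_network] (or edge tibble) of predictions.
#' @param gold Data frame of gold-standard edges (`regulator`, `target`).
#' @param universe Data frame of all scored ordered pairs (`regulator`,
#'   `target`); defaults to all ordered non-self pairs over the union of
#'   gene names seen in `pred` and `gold` (or the network's `genes`
#'   attribute when present).
#' @param tau Weight threshold.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at_threshold <- function(pred, gold, universe = NULL, tau) {
  z <- eval_pairs(pred, gold, universe)
  predicted <- z$weight >= tau
  tibble(tp = sum(predicted & z$is_gold),
         fp = sum(predicted & !z$is_gold),
         fn = sum(!predicted & z$is_gold),
         tn = sum(!predicted & !z$is_gold))
}

# shared scaffolding: one row per universe pair with its predicted weight
# (0 when unpredicted) and gold membership
eval_pairs <- function(pred, gold, universe = NULL) {
  pred <- as_tibble(pred)
  gold <- as_tibble(gold)
  names(gold)[1:2] <- c("regulator", "target")
  if (is.null(universe)) {
    genes <- attr(pred, "genes")
    if (is.null(genes)) {
      genes <- sort(unique(c(pred$regulator, pred$target,
                             gold$regulator, gold$target)))
    }
    universe <- tidyr::expand_grid(regulator = genes, target = genes)
    universe <- dplyr::filter(universe, .data$regulator != .data$target)
  } else {
    universe <- as_tibble(universe)
    names(universe)[1:2] <- c("regulator", "target")
  }
  ukey <- paste(universe$regulator, universe$target, sep = "\r")
  gkey <- paste(gold$regulator, gold$target, sep = "\r")
  pkey <- paste(pred$regulator, pred$target, sep = "\r")
  if (!all(gkey %in% ukey)) {
    abort("Gold-standard edges outside the scored universe.",
          class = "bmanet_universe_error")
  }
  if (!all(pkey %in% ukey)) {
    abort("Predicted edges outside the scored universe.",
          class = "bmanet_universe_error")
  }
  w <- numeric(nrow(universe))
  w[match(pkey, ukey)] <- pred$weight
  tibble(regulator = universe$regulator, target = universe$target,
         weight = w, is_gold = ukey %in% gkey)
}

#' Precision-recall and ROC curves against a gold standard
#'
#' Sweeps the threshold over every distinct predicted weight (equal-weight
#' edges enter together; unpredicted universe pairs enter at weight 0) and
#' accumulates TP/FP/FN/TN, precision, recall and false-positive rate at
#' each step. AUROC is the trapezoid area over (fpr, recall); AUPR uses
#' the step rule `sum((recall_i - recall_{i-1}) * precision_i)`, the
#' standard convention for sparse-network evaluation.
#'
#' @inheritParams confusion_at_threshold
#' @return An object of class `grn_eval` with `points` (tibble of
#'   threshold, tp, fp, fn, tn, precision, recall, fpr), `aupr`, `auroc`,
#'   `n_gold`, `n_universe`.
#' @export
evaluate_network <- function(pred, gold, universe = NULL) {
  z <- eval_pairs(pred, gold, universe)
  n_gold <- sum(z$is_gold)
  if (n_gold == 0L) {
    abort("Empty gold standard: recall is undefined.",
          class = "bmanet_eval_error")
  }
  n_universe <- nrow(z)
  # group ties: cumulative counts after admitting each threshold group
  ord <- order(-z$weight)
  wts <- z$weight[ord]
  goldv <- z$is_gold[ord]
  grp_last <- which(c(wts[-1L] != wts[-length(wts)], TRUE))
  thresholds <- wts[grp_last]
  cum_tp <- cumsum(goldv)[grp_last]
  cum_n <- grp_last
  tp <- cum_tp
  fp <- cum_n - cum_tp
  fn <- n_gold - tp
  tn <- n_universe - cum_n - fn
  precision <- tp / pmax(tp + fp, 1L)
  recall <- tp / n_gold
  fpr <- fp / max(n_universe - n_gold, 1L)
  points <- tibble(threshold = thresholds, tp = tp, fp = fp, fn = fn,
                   tn = tn, precision = precision, recall = recall,
                   fpr = fpr)
  aupr <- sum(diff(c(0, recall)) * precision)
  auroc <- sum(diff(c(0, fpr)) * (c(0, head(recall, -1L)) + recall) / 2)
  structure(list(points = points, aupr = aupr, auroc = auroc,
                 n_gold = n_gold, n_universe = n_universe),
            class = "grn_eval")
}

#' @export
print.grn_eval <- function(x, ...) {
  cat(sprintf("<grn_eval> %d gold edges over %d pairs: AUPR = %.4f, AUROC = %.4f\n",
              x$n_gold, x$n_universe, x$aupr, x$auroc))
  invisible(x)
}

#' @rdname evaluate_network
#' @param x A `grn_eval` object.
#' @param ... Unused.
#' @export
tidy.grn_eval <- function(x, ...) x$points

#' @rdname evaluate_network
#' @export
glance.grn_eval <- function(x, ...) {
  tibble(aupr = x$aupr, auroc = x$auroc, n_gold = x$n_gold,
         n_universe = x$n_universe)
}

#' @rdname evaluate_network
#' @param object A `grn_eval` object.
#' @param curve `"pr"` or `"roc"`.
#' @export
autoplot.grn_eval <- function(object, curve = c("pr", "roc"), ...) {
  curve <- match.arg(curve)
  pts <- object$points
  if (curve == "pr") {
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(title = sprintf("Precision-recall (AUPR = %.3f)", object$aupr),
                    x = "recall", y = "precision") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$recall)) +
      ggplot2::geom_line() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(title = sprintf("ROC (AUROC = %.3f)", object$auroc),
                    x = "false-positive rate", y = "recall") +
      ggplot2::theme_minimal()
  }
}
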