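#' Weighted directed networks
#'
#' Inferred networks are tibbles with columns `regulator`, `target` and
#' `weight` (posterior inclusion probability in `(0, 1]`), at most one edge
#' per ordered pair and no self-edges unless inference allowed them.
#'
#' @param edges A data frame with columns `regulator`, `target`, `weight`.
#' @param genes Optional character vector of all gene names in the
#'   underlying dataset (kept as an attribute for evaluation universes).
#' @return A `grn_network` tibble.
#' @export
grn_network <- function(edges, genes = NULL) {
  edges <- as_tibble(edges)
  stopifnot(all(c("regulator", "target", "weight") %in% names(edges)))
  if (any(edges$weight <= 0 | edges$weight > 1)) {
    abort("Edge weights must lie in (0, 1].", class = "bmanet_weight_error")
  }
  if (anyDuplicated(edges[, c("regulator", "target")])) {
    abort("At most one edge per ordered (regulator, target) pair.")
  }
  structure(edges, genes = genes,
            class = c("grn_network", class(tibble())))
}

#' Infer a gene regulatory network by Bayesian model averaging
#'
#' Runs [scan_target()] independently for every gene in the dataset (each
#' target's regulator scan is a separate task, so targets are distributed
#' over a worker pool) and assembles the edge list: an edge `j -> i`
#' carries the posterior inclusion probability of regulator `j` in target
#' `i`'s scan. Edges below `edge_cutoff` are dropped. The result is
#' identical for any worker count.
#'
#' @inheritParams scan_target
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @param prune Apply [reduce_network()] transitive reduction to the
#'   result.
#' @return A [grn_network] tibble, ordered by target then regulator. Scans
#'   that failed (constant targets) are recorded in the `skipped`
#'   attribute.
#' @export
infer_network <- function(dataset, priors = NULL, config = scan_config(),
                          workers = 1L, prune = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  targets <- seq_len(nrow(dataset$values))
  run_one <- function(i) {
    withCallingHandlers(
      scan_target(dataset, i, priors, config),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  scans <- if (workers > 1L) {
    parallel::mclapply(targets, run_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(targets, run_one)
  }
  skipped <- dataset$gene_names[vapply(scans, function(s) s$n_models == 0L,
                                       logical(1L))]
  edges <- purrr::map_dfr(scans, function(s) {
    if (s$n_models == 0L) return(NULL)
    dplyr::filter(
      tibble(regulator = s$inclusion$regulator, target = s$target,
             weight = s$inclusion$inclusion),
      .data$weight >= config$edge_cutoff, .data$weight > 0)
  })
  edges <- dplyr::arrange(edges,
                          match(.data$target, dataset$gene_names),
                          match(.data$regulator, dataset$gene_names))
  net <- grn_network(edges, genes = dataset$gene_names)
  attr(net, "skipped") <- skipped
  if (prune) net <- reduce_network(net)
  net
}

#' Read / write edge-list TSV
#'
#' Three tab-separated columns: regulator, target, weight. Weights are
#' written with 9 significant digits.
#'
#' @param path File path.
#' @param genes Optional gene universe attached to the network.
#' @return A [grn_network] (read) or `path` invisibly (write).
#' @export
read_network <- function(path, genes = NULL) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    return(grn_network(tibble(regulator = character(), target = character(),
                              weight = double()), genes))
  }
  if (ncol(raw) < 3L) abort("Edge list needs 3 columns.", class = "bmanet_read_error")
  w <- suppressWarnings(as.numeric(raw[[3L]]))
  if (anyNA(w)) {
    abort(sprintf("Non-numeric weight at line %d.", which(is.na(w))[1L]),
          class = "bmanet_read_error")
  }
  grn_network(tibble(regulator = as.character(raw[[1L]]),
                     target = as.character(raw[[2L]]), weight = w), genes)
}

#' @rdname read_network
#' @param network A [grn_network].
#' @export
write_network <- function(network, path) {
  lines <- sprintf("%s\t%s\t%.9g", network$regulator, network$target,
                   network$weight)
  writeLines(lines, path)
  invisible(path)
}

#' Plot an inferred network's weight distribution and top edges
#'
#' @param object A [grn_network].
#' @param top Number of strongest edges to label.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grn_network <- function(object, top = 15L, ...) {
  df <- as_tibble(object)
  df <- dplyr::arrange(df, dplyr::desc(.data$weight))
  df$edge <- factor(paste(df$regulator, "→", df$target),
                    levels = rev(paste(df$regulator, "→", df$target)))
  ggplot2::ggplot(head(df, top),
                  ggplot2::aes(x = .data$weight, y = .data$edge)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "posterior inclusion probability", y = NULL,
                  title = "Strongest inferred edges") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}
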