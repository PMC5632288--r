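#' Transitive reduction by bounded shortest paths
#'
#' Treats each edge weight `w` in `(0, 1]` as an independent probability and
#' each path's probability as the product of its edge weights. Mapping
#' weights to distances `d = -log(w)` turns the highest-probability path
#' into the shortest path, so a direct edge `u -> v` is removed when some
#' indirect path (two or more edges) from `u` to `v` in the *original*
#' graph is strictly shorter than `-log(w(u -> v))` — i.e. when the
#' indirect route explains the pair better than the direct edge. Dijkstra
#' is run from `u` with the direct edge deleted, and the frontier is pruned
#' as soon as its distance exceeds the direct distance, so most searches
#' terminate quickly on the sparse high-weight graphs the inference
#' produces. All removals are decided simultaneously against the unmodified
#' input; ties keep the direct edge; surviving edges keep their weights.
#'
#' @param network A [grn_network] (any edge list with weights in `(0, 1]`).
#' @param iterate Repeat the reduction until no edge is removed (the single
#'   pass is the default post-processing step; a second pass can remove
#'   more because removals are decided against the original graph).
#' @return The reduced [grn_network]; removed edges are recorded in the
#'   `removed` attribute.
#' @export
reduce_network <- function(network, iterate = FALSE) {
  net <- grn_network(as_tibble(network), genes = attr(network, "genes"))
  removed_all <- net[0, ]
  repeat {
    keep <- reduce_once(net)
    removed_all <- dplyr::bind_rows(removed_all, net[!keep, ])
    out <- net[keep, ]
    if (!iterate || all(keep)) {
      out <- grn_network(out, genes = attr(network, "genes"))
      attr(out, "removed") <- as_tibble(removed_all)
      return(out)
    }
    net <- out
  }
}

# logical keep-vector for one simultaneous pass
reduce_once <- function(net) {
  m <- nrow(net)
  if (m == 0L) return(logical(0))
  nodes <- unique(c(net$regulator, net$target))
  u <- match(net$regulator, nodes)
  v <- match(net$target, nodes)
  d <- -log(net$weight)
  nn <- length(nodes)
  # adjacency: per source node, outgoing (head, dist, edge id)
  adj_head <- split(v, u)
  adj_dist <- split(d, u)
  adj_id <- split(seq_len(m), u)
  keep <- logical(m)
  for (e in seq_len(m)) {
    keep[e] <- !(shortest_indirect(u[e], v[e], d[e], e, nn,
                                   adj_head, adj_dist, adj_id))
  }
  keep
}

# Bounded Dijkstra from `src` with edge `skip_id` removed: TRUE iff some
# path reaches `dst` with distance strictly below `bound`.
shortest_indirect <- function(src, dst, bound, skip_id, nn,
                              adj_head, adj_dist, adj_id) {
  dist <- rep(Inf, nn)
  done <- logical(nn)
  dist[src] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) return(FALSE)
    node <- cand[which.min(dist[cand])]
    dd <- dist[node]
    if (dd >= bound) return(FALSE)          # frontier already too long
    if (node == dst) return(TRUE)           # dd < bound established above
    done[node] <- TRUE
    key <- as.character(node)
    heads <- adj_head[[key]]
    if (is.null(heads)) next
    dists <- adj_dist[[key]]
    ids <- adj_id[[key]]
    for (i in seq_along(heads)) {
      if (ids[i] == skip_id) next
      w <- heads[i]
      nd <- dd + dists[i]
      if (nd < dist[w]) dist[w] <- nd
    }
  }
}
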