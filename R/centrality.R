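#' Node centrality indices for a weighted signed network
#'
#' Computes, per node: strength (sum of absolute incident edge weights),
#' one-step expected influence (signed sum of incident weights, so
#' negative edges subtract), closeness and betweenness, plus a
#' z-standardized version of each (population SD across nodes; a
#' zero-variance index standardizes to 0).
#'
#' Path-based indices use the edge length `1 / |w_ij|`, the standard
#' transform in the psychometric-network literature; edge signs are
#' ignored for paths.  Closeness is the inverse of the *sum* of a node's
#' shortest-path distances to all others and is set to 0 for a node with
#' any unreachable partner (including isolated nodes).  Betweenness
#' follows Brandes' accounting with fractional credit on tied shortest
#' paths; disconnected pairs contribute nothing.
#'
#' @param net a [symptom_network()] with at least two nodes.
#' @return A data.frame of class `centrality_table` with columns `node`,
#'   `strength`, `expected_influence`, `closeness`, `betweenness` and
#'   `z_`-prefixed standardized versions.
#' @export
centrality_table <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  w <- net$weights
  p <- nrow(w)
  if (p < 2)
    sn_stop("sn_usage_error",
            "centrality requires at least two nodes (z-scores undefined)")
  strength <- rowSums(abs(w))
  ei <- rowSums(w)
  aw <- abs(w)
  g <- igraph::graph_from_adjacency_matrix(aw, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  if (igraph::ecount(g) > 0) {
    d <- igraph::distances(g, weights = len)
    btw <- igraph::betweenness(g, weights = len, directed = FALSE)
  } else {
    d <- matrix(Inf, p, p); diag(d) <- 0
    btw <- rep(0, p)
  }
  closeness <- apply(d, 1, function(di) {
    tot <- sum(di[is.finite(di)])
    if (any(is.infinite(di)) || tot == 0) 0 else 1 / tot
  })
  zstd <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  out <- data.frame(node = net$nodes, strength = strength,
                    expected_influence = ei, closeness = closeness,
                    betweenness = btw,
                    z_strength = zstd(strength),
                    z_expected_influence = zstd(ei),
                    z_closeness = zstd(closeness),
                    z_betweenness = zstd(btw),
                    row.names = NULL)
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Top nodes by a centrality index
#'
#' Orders nodes by the raw index, descending, with ties broken by node
#' name in lexicographic order, and returns the first `k`.
#'
#' @param table a [centrality_table()].
#' @param index one of `"strength"`, `"expected_influence"`,
#'   `"closeness"`, `"betweenness"`.
#' @param k how many nodes (capped at the node count).
#' @return Character vector of node names.
#' @export
rank_nodes <- function(table, index = "expected_influence", k = 3L) {
  stopifnot(inherits(table, "centrality_table"))
  if (!index %in% c("strength", "expected_influence", "closeness",
                    "betweenness"))
    sn_stop("sn_usage_error", "unknown centrality index '%s'", index)
  ord <- order(-table[[index]], table$node)
  head(table$node[ord], min(k, nrow(table)))
}
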