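#' Edge distances of a weighted network
#'
#' Converts partial-correlation weights to shortest-path lengths with the
#' standard reciprocal transform `d_ij = 1 / |w_ij|`: stronger edges are
#' shorter.  Node pairs without a direct edge get `Inf`; the diagonal is 0.
#'
#' @param network A `network_model`.
#' @return A symmetric distance matrix.
#' @export
edge_distances <- function(network) {
  w <- abs(network$weights)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  d
}

check_node <- function(network, node) {
  i <- if (is.character(node)) match(node, network$nodes) else as.integer(node)
  if (is.na(i) || i < 1 || i > length(network$nodes))
    stop("unknown node: ", node)
  i
}

#' Node strength
#'
#' Sum of edge weights incident to a node, `k_i = sum_j w_ij`.  By default
#' absolute weights are summed (the field convention for partial-correlation
#' networks, where centrality should not cancel across positive and negative
#' edges); `signed = TRUE` gives the raw signed sum.
#'
#' @param network A `network_model`.
#' @param node Node name or index; `NULL` for all nodes.
#' @param signed Use signed weights instead of absolute values?
#' @return Named numeric vector (or scalar for a single node).
#' @export
node_strength <- function(network, node = NULL, signed = FALSE) {
  w <- if (signed) network$weights else abs(network$weights)
  k <- rowSums(w)
  if (is.null(node)) k else k[[check_node(network, node)]]
}

# single-source Dijkstra with geodesic counting; ties within a relative
# tolerance are all counted
dijkstra_count <- function(d, s, tol = 1e-10) {
  p <- nrow(d)
  dist <- rep(Inf, p); dist[s] <- 0
  sigma <- rep(0, p); sigma[s] <- 1
  done <- rep(FALSE, p)
  for (step in seq_len(p)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (v in which(!done & is.finite(d[u, ]))) {
      if (v == u) next
      alt <- dist[u] + d[u, v]
      eps <- tol * (1 + abs(alt))
      if (alt < dist[v] - eps) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
      } else if (abs(alt - dist[v]) <= eps) {
        sigma[v] <- sigma[v] + sigma[u]
      }
    }
  }
  list(dist = dist, sigma = sigma)
}

#' Geodesic lengths, path counts, and pass-through counts
#'
#' All-pairs shortest-path structure of a nonnegative distance matrix:
#' geodesic lengths `d_jk`, geodesic counts `p_jk` (all equal-length
#' geodesics counted), and the array of pass-through counts `p_jk(i)` --
#' geodesics from j to k whose interior passes through i, computed as
#' `p_ji * p_ik` when `d_ji + d_ik = d_jk`.
#'
#' @param distances Symmetric nonnegative matrix, zero diagonal, `Inf` for
#'   missing edges.
#' @return List with matrices `dist` and `counts` and the p x p x p array
#'   `through` (`through[j, k, i]` = `p_jk(i)`).
#' @export
shortest_paths_counts <- function(distances) {
  d <- as.matrix(distances)
  if (any(d[is.finite(d)] < 0)) stop("distances must be nonnegative")
  p <- nrow(d)
  dist <- matrix(Inf, p, p); counts <- matrix(0, p, p)
  for (s in seq_len(p)) {
    r <- dijkstra_count(d, s)
    dist[s, ] <- r$dist
    counts[s, ] <- r$sigma
  }
  diag(counts) <- 0
  through <- array(0, c(p, p, p))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j == i) next
      for (k in seq_len(p)) {
        if (k == i || k == j) next
        if (!is.finite(dist[j, k])) next
        s <- dist[j, i] + dist[i, k]
        if (is.finite(s) &&
            abs(s - dist[j, k]) <= 1e-9 * (1 + dist[j, k]))
          through[j, k, i] <- counts[j, i] * counts[i, k]
      }
    }
  }
  dimnames(dist) <- dimnames(counts) <- dimnames(distances)
  if (!is.null(dimnames(distances)))
    dimnames(through) <- c(dimnames(distances), dimnames(distances)[2])
  list(dist = dist, counts = counts, through = through)
}

#' Betweenness centrality
#'
#' `b_i = sum_{j < k} p_jk(i) / p_jk` over weighted geodesics: the
#' fraction-weighted number of shortest paths passing through node i
#' (endpoints excluded, unnormalized; unreachable pairs skipped).
#'
#' @inheritParams node_strength
#' @param paths Optional precomputed [shortest_paths_counts()] result.
#' @return Named numeric vector (or scalar for a single node).
#' @export
betweenness <- function(network, node = NULL, paths = NULL) {
  if (is.null(paths)) paths <- shortest_paths_counts(edge_distances(network))
  p <- length(network$nodes)
  b <- numeric(p)
  for (i in seq_len(p)) {
    tot <- 0
    for (j in seq_len(p - 1)) {
      for (k in (j + 1):p) {
        if (j == i || k == i) next
        if (paths$counts[j, k] > 0)
          tot <- tot + paths$through[j, k, i] / paths$counts[j, k]
      }
    }
    b[i] <- tot
  }
  names(b) <- network$nodes
  if (is.null(node)) b else b[[check_node(network, node)]]
}

#' Closeness centrality
#'
#' The reciprocal of the average geodesic distance from a node to the other
#' nodes: `(n - 1) / sum_j d_ij`, restricted to the node's connected
#' component (the count of reachable nodes replaces `n - 1` when the network
#' is disconnected).  Isolated nodes get 0.  `variant = "inverse_total"`
#' gives the unscaled `1 / sum_j d_ij` form instead.
#'
#' @inheritParams betweenness
#' @param variant `"average"` (default) or `"inverse_total"`.
#' @return Named numeric vector (or scalar for a single node).
#' @export
closeness <- function(network, node = NULL,
                      variant = c("average", "inverse_total"),
                      paths = NULL) {
  variant <- match.arg(variant)
  if (is.null(paths)) paths <- shortest_paths_counts(edge_distances(network))
  p <- length(network$nodes)
  cl <- numeric(p)
  for (i in seq_len(p)) {
    d <- paths$dist[i, -i]
    reach <- is.finite(d)
    if (!any(reach)) { cl[i] <- 0; next }
    cl[i] <- if (variant == "average") sum(reach) / sum(d[reach])
             else 1 / sum(d[reach])
  }
  names(cl) <- network$nodes
  if (is.null(node)) cl else cl[[check_node(network, node)]]
}

#' All three centrality indices of a network
#'
#' @param network A `network_model`.
#' @param signed Use signed weights for strength?
#' @param closeness_variant Passed to [closeness()].
#' @return A `centrality_profile`: list with `nodes`, `strength`,
#'   `betweenness`, `closeness` and the `distance_matrix` used.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- w[2, 3] <- w[3, 2] <- 0.5
#' centrality_profile(mixedggm:::network_model(w))
#' @export
centrality_profile <- function(network, signed = FALSE,
                               closeness_variant = "average") {
  d <- edge_distances(network)
  paths <- shortest_paths_counts(d)
  structure(list(nodes = network$nodes,
                 strength = node_strength(network, signed = signed),
                 betweenness = betweenness(network, paths = paths),
                 closeness = closeness(network, variant = closeness_variant,
                                       paths = paths),
                 distance_matrix = d),
            class = "centrality_profile")
}

#' @export
print.centrality_profile <- function(x, ...) {
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
as.data.frame.centrality_profile <- function(x, ...) {
  data.frame(node = x$nodes, strength = unname(x$strength),
             betweenness = unname(x$betweenness),
             closeness = unname(x$closeness))
}
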