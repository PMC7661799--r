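# Independent oracles used across the suite.  These deliberately avoid the
# package's own algorithms: centrality by exhaustive enumeration of all
# simple paths, modularity by exhaustive search over all set partitions.

# enumerate every simple path between a and b in an adjacency of distances
# (Inf = no edge); returns list of numeric path lengths and interior-node
# index lists
enumerate_paths <- function(d, a, b) {
  p <- nrow(d)
  lengths <- numeric(0)
  interiors <- list()
  dfs <- function(v, visited, len, interior) {
    if (v == b) {
      lengths[[length(lengths) + 1]] <<- len
      interiors[[length(interiors) + 1]] <<- interior
      return(invisible())
    }
    for (u in seq_len(p)) {
      if (!visited[u] && is.finite(d[v, u]) && u != v) {
        visited[u] <- TRUE
        dfs(u, visited, len + d[v, u],
            if (u == b) interior else c(interior, u))
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, p); visited[a] <- TRUE
  dfs(a, visited, 0, integer(0))
  list(lengths = lengths, interiors = interiors)
}

# brute-force strength/betweenness/closeness from a weight matrix, following
# the d = 1/|w| transform, fractional tie splitting, and the
# reachable-count/total-distance closeness
brute_force_centrality <- function(w, tol = 1e-9) {
  p <- nrow(w)
  d <- ifelse(w != 0, 1 / abs(w), Inf); diag(d) <- 0
  btw <- numeric(p)
  dist <- matrix(Inf, p, p); diag(dist) <- 0
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      paths <- enumerate_paths(d, a, b)
      if (!length(paths$lengths)) next
      dmin <- min(paths$lengths)
      dist[a, b] <- dist[b, a] <- dmin
      geo <- which(paths$lengths <= dmin + tol * (1 + dmin))
      for (g in geo)
        for (i in paths$interiors[[g]])
          btw[i] <- btw[i] + 1 / length(geo)
    }
  }
  clo <- numeric(p)
  for (i in seq_len(p)) {
    di <- dist[i, -i]
    reach <- is.finite(di)
    clo[i] <- if (any(reach)) sum(reach) / sum(di[reach]) else 0
  }
  list(strength = rowSums(abs(w)), betweenness = btw, closeness = clo,
       dist = dist)
}

# independent modularity (per-community form) on absolute weights
oracle_Q <- function(w, memb) {
  A <- abs(w); diag(A) <- 0
  two_m <- sum(A)
  s <- rowSums(A)
  q <- 0
  for (c in unique(memb)) {
    in_c <- memb == c
    q <- q + sum(A[in_c, in_c]) / two_m - (sum(s[in_c]) / two_m)^2
  }
  q
}

# exhaustive best partition via restricted growth strings
best_partition_Q <- function(w) {
  p <- nrow(w)
  best <- -Inf
  memb <- integer(p)
  rec <- function(i, kmax) {
    if (i > p) {
      q <- oracle_Q(w, memb)
      if (q > best) best <<- q
      return(invisible())
    }
    for (c in seq_len(kmax + 1)) {
      memb[i] <<- c
      rec(i + 1, max(kmax, c))
    }
  }
  rec(1, 0)
  best
}

# random signed weighted graph as a network_model
random_network <- function(p, edge_prob = 0.4) {
  w <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < edge_prob) {
        w[i, j] <- w[j, i] <- sample(c(-1, 1), 1) * runif(1, 0.1, 0.9)
      }
    }
  }
  mixedggm:::network_model(w)
}

# quick builder for measure tables used in io/dispatch tests
toy_table <- function(n = 40, seed = 1) {
  vars <- list(
    variable_spec("ord_a", "ordinal", levels = 4, range = c(0, 3)),
    variable_spec("ord_b", "ordinal", levels = 5, range = c(0, 4)),
    variable_spec("cont_a", "continuous", range = c(0, 10))
  )
  K <- diag(3); K[1, 2] <- K[2, 1] <- -0.4; K[1, 3] <- K[3, 1] <- -0.3
  spec <- group_spec("G", n, vars, K,
                     thresholds = list(ord_a = c(-1, 0, 1),
                                       ord_b = c(-1.2, -0.4, 0.4, 1.2)),
                     continuous_scale = list(cont_a = c(5, 1.5)))
  generate_group_sample(spec, seed = seed)
}
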