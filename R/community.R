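# modularity of a membership on a weighted adjacency with the aggregate
# self-loop convention (A_ii = twice the internal weight of a super-node)
modularity_adj <- function(A, memb) {
  two_m <- sum(A)
  s <- rowSums(A)
  same <- outer(memb, memb, "==")
  sum((A - tcrossprod(s) / two_m) * same) / two_m
}

#' Modularity of a network partition
#'
#' The weighted Newman-Girvan quality of a division into communities,
#' `Q = (1/2m) sum_ij (a_ij - s_i s_j / 2m) delta(c_i, c_j)`, computed on
#' absolute edge weights `a_ij = |w_ij|` (the partial-correlation networks
#' this package estimates contain negative edges; the classical modularity
#' is defined for nonnegative weights).
#'
#' @param network A `network_model` with at least one edge.
#' @param assignment Integer community labels, one per node (any coding).
#' @return Q, in `[-1, 1]`.
#' @examples
#' w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- w[3, 4] <- w[4, 3] <- 0.5
#' modularity(mixedggm:::network_model(w), c(1, 1, 2, 2))  # 0.5
#' @export
modularity <- function(network, assignment) {
  A <- abs(network$weights)
  if (sum(A) == 0) stop("network has no edges; modularity is undefined")
  if (length(assignment) != length(network$nodes))
    stop("assignment must label every node exactly once")
  modularity_adj(A, as.integer(factor(assignment)))
}

# one full Louvain run (local moves + aggregation) for a fixed sweep order
louvain_once <- function(A, order) {
  p0 <- nrow(A)
  memb <- seq_len(p0)       # membership of original nodes
  level_A <- A
  repeat {
    p <- nrow(level_A)
    two_m <- sum(level_A)
    s <- rowSums(level_A)
    comm <- seq_len(p)
    S <- s                  # total strength per community
    moved_any <- FALSE
    ord <- if (p == p0) order else seq_len(p)
    repeat {
      moved <- FALSE
      for (v in ord) {
        nb <- which(level_A[v, ] > 0 & seq_len(p) != v)
        if (!length(nb)) next
        old <- comm[v]
        S[old] <- S[old] - s[v]
        cand <- unique(c(comm[nb], old))
        kvc <- vapply(cand, function(cc)
          sum(level_A[v, nb[comm[nb] == cc]]), numeric(1))
        gain <- (kvc - s[v] * S[cand] / two_m) / (two_m / 2)
        best <- cand[order(-gain, cand)][1]
        if (gain[match(best, cand)] <= gain[match(old, cand)] + 1e-12)
          best <- old
        comm[v] <- best
        S[best] <- S[best] + s[v]
        if (best != old) { moved <- TRUE; moved_any <- TRUE }
      }
      if (!moved) break
    }
    if (!moved_any) break
    # aggregate communities into super-nodes
    lab <- as.integer(factor(comm))
    k <- max(lab)
    M <- matrix(0, p, k); M[cbind(seq_len(p), lab)] <- 1
    level_A <- t(M) %*% level_A %*% M
    memb <- lab[memb]
    if (k == p) break
  }
  as.integer(factor(memb))
}

#' Louvain community detection
#'
#' Greedy modularity optimization: starting from singleton communities,
#' each node is moved to the neighboring community giving the largest
#' positive modularity gain (ties to the lowest community index), sweeps
#' repeating until no move improves Q; communities are then aggregated into
#' super-nodes and the procedure repeats.  Because a single run depends on
#' the node sweep order, `restarts` shuffled orders are tried (seeded, so
#' results are reproducible) and the best-Q partition is returned.  Isolated
#' nodes end as singleton communities.  Absolute edge weights are used, as
#' in [modularity()].
#'
#' @param network A `network_model` with at least one edge.
#' @param seed Integer seed for the sweep-order shuffles.
#' @param restarts Number of shuffled restarts (default 20).
#' @return A `community_partition`: list with `assignment` (named integer
#'   vector, communities numbered contiguously from 1), `Q`,
#'   `n_communities`, `seed`, `restarts`.
#' @examples
#' w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- w[3, 4] <- w[4, 3] <- 0.5
#' louvain(mixedggm:::network_model(w), seed = 1)
#' @export
louvain <- function(network, seed = 1, restarts = 20) {
  A <- abs(network$weights)
  if (sum(A) == 0) stop("network has no edges; communities are undefined")
  p <- nrow(A)
  restore <- local_seed(seed)
  on.exit(restore())
  best <- NULL; best_q <- -Inf
  for (r in seq_len(restarts)) {
    ord <- sample.int(p)
    memb <- louvain_once(A, ord)
    q <- modularity_adj(A, memb)
    if (q > best_q + 1e-15) { best_q <- q; best <- memb }
  }
  # renumber communities by first appearance for a stable labelling
  best <- as.integer(factor(best, levels = unique(best)))
  structure(list(assignment = setNames(best, network$nodes), Q = best_q,
                 n_communities = length(unique(best)), seed = seed,
                 restarts = restarts),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition: ", x$n_communities, " communities, Q = ",
      signif(x$Q, 4), " (", interpret_modularity(x$Q), ")\n", sep = "")
  for (k in seq_len(x$n_communities))
    cat("  [", k, "] ", paste(names(x$assignment)[x$assignment == k],
                              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Interpret a modularity value
#'
#' Q near 0 means the division is no better than random; empirically,
#' networks with real community structure fall between 0.3 and 0.7, and
#' values above that are exceptionally strong.
#'
#' @param Q Modularity in `[-1, 1]`.
#' @return One of `"no-community-structure"`, `"community-structure"`,
#'   `"exceptionally-strong"`.
#' @export
interpret_modularity <- function(Q) {
  if (!is.numeric(Q) || length(Q) != 1 || is.na(Q) || Q < -1 || Q > 1)
    stop("Q must be a single value in [-1, 1]")
  if (Q < 0.3) "no-community-structure"
  else if (Q <= 0.7) "community-structure"
  else "exceptionally-strong"
}
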