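#' Graphical lasso precision estimate
#'
#' Maximizes `log det K - tr(SK) - lambda * sum_{i != j} |K_ij|` by block
#' coordinate descent (off-diagonal-only penalty, so marginal scales are
#' untouched).  The returned off-diagonal zeros are exact.
#'
#' @param S Symmetric positive-semidefinite correlation matrix (unit
#'   diagonal).
#' @param lambda Penalty, >= 0.
#' @param tol Convergence tolerance on the mean absolute off-diagonal scale
#'   of `S` (default 1e-5).
#' @param maxit Sweep cap (default 1000).
#' @param W0 Optional warm-start covariance estimate (used internally for
#'   penalty paths).
#' @return A `precision_estimate`: list with `K`, `W` (the implied
#'   covariance), `lambda`, `converged`.
#' @examples
#' S <- matrix(c(1, .5, .5, 1), 2)
#' graphical_lasso(S, 0)$K   # the exact inverse
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-5, maxit = 1000, W0 = NULL) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("S must be symmetric")
  if (lambda < 0) stop("lambda must be >= 0")
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8)
    stop("S is not positive semidefinite (min eigenvalue ", signif(ev_min, 3),
         "); repair it with nearest_psd() first")
  if (lambda == 0 && ev_min < 1e-10)
    stop("S is singular; lambda = 0 solution does not exist")
  fit <- .glasso_cd(S, lambda, tol, as.integer(maxit), W0)
  if (!fit$converged)
    stop("graphical lasso did not converge in ", maxit,
         " sweeps (residual ", signif(fit$residual, 3), ")")
  K <- fit$K
  dimnames(K) <- dimnames(fit$W) <- dimnames(S)
  structure(list(K = K, W = fit$W, lambda = lambda,
                 converged = fit$converged),
            class = "precision_estimate")
}

# KKT residual of a glasso solution: for zero entries |S - W|_ij <= lambda,
# for active entries S_ij - W_ij + lambda * sign(K_ij) = 0 (W = K^{-1})
glasso_kkt <- function(est, S) {
  K <- est$K
  G <- S - solve(K)
  off <- row(K) != col(K)
  zero <- off & K == 0
  act <- off & K != 0
  r_zero <- if (any(zero)) max(abs(G[zero])) - est$lambda else -Inf
  r_act <- if (any(act)) max(abs(G[act] + est$lambda * sign(K[act]))) else 0
  max(r_zero, r_act)
}

#' BIC of a precision estimate
#'
#' `-2 * l + E * log(n)` with Gaussian log-likelihood
#' `l = (n/2) (log det K - tr(SK))` and model size `E` = number of nonzero
#' upper-triangle off-diagonal entries of `K`.
#'
#' @param est A `precision_estimate` (or any list with element `K`).
#' @param S The correlation matrix the model was fit to.
#' @param n Sample size (>= 2).
#' @return The BIC (smaller is better).
#' @export
bic_score <- function(est, S, n) {
  K <- est$K
  if (!all(dim(K) == dim(S))) stop("dimension mismatch between K and S")
  if (n < 2) stop("n must be >= 2")
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus))
    stop("K is not positive definite")
  ll <- (n / 2) * (as.numeric(ld$modulus) - sum(S * K))
  E <- sum(K[upper.tri(K)] != 0)
  -2 * ll + E * log(n)
}

#' Select the graphical-lasso penalty by BIC
#'
#' Fits the graphical lasso over a log-spaced grid of `grid_size` penalties
#' from `lambda_max` (the largest off-diagonal `|S_ij|`, at which the
#' network is empty) down to `0.01 * lambda_max`, with warm starts, and
#' returns the penalty minimizing [bic_score()].  BIC ties resolve to the
#' larger (sparser) penalty.
#'
#' With `refit = TRUE` (default) each candidate edge set proposed along the
#' path is re-estimated by support-constrained unpenalized maximum
#' likelihood and the BIC is evaluated at that refit -- the classical BIC
#' recipe (likelihood at the model's ML fit), which selects supports
#' consistently; the winning refit is returned.  `refit = FALSE` scores the
#' shrunken penalized estimates directly, the convention of much network
#' psychometrics tooling; because heavy penalties bias the active edges,
#' that convention systematically favors denser models (see the methods
#' vignette).
#'
#' @inheritParams graphical_lasso
#' @param n Sample size used in the BIC.
#' @param grid_size Number of grid points (default 100).
#' @param refit Score candidate supports at their unpenalized restricted
#'   MLE (default `TRUE`)?
#' @return List with `lambda`, the winning `precision_estimate` (`fit`),
#'   and the search `path` (lambda, bic, edges per grid point).
#' @export
select_penalty <- function(S, n, grid_size = 100, tol = 1e-5, maxit = 1000,
                           refit = TRUE) {
  S <- as.matrix(S)
  if (grid_size < 1) stop("grid_size must be >= 1")
  off <- abs(S[row(S) != col(S)])
  lam_max <- if (length(off)) max(off) else 0
  lambdas <- if (lam_max == 0 || grid_size == 1) rep(lam_max, 1)
             else exp(seq(log(lam_max), log(0.01 * lam_max),
                          length.out = grid_size))
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8)
    stop("S is not positive semidefinite; repair it with nearest_psd() first")
  res <- .glasso_path(S, lambdas, n, tol, as.integer(maxit), refit)
  K <- res$K; W <- res$W
  dimnames(K) <- dimnames(W) <- dimnames(S)
  fit <- structure(list(K = K, W = W, lambda = res$lambda,
                        converged = res$converged),
                   class = "precision_estimate")
  list(lambda = res$lambda, fit = fit, bic = res$bic,
       path = data.frame(lambda = lambdas, bic = res$bic_path,
                         edges = res$edges_path))
}

#' Convert a precision matrix to a partial-correlation network
#'
#' Edge weights are `w_ij = -K_ij / sqrt(K_ii K_jj)`, the partial
#' correlation between i and j given all other nodes; the diagonal is zero.
#'
#' @param est A `precision_estimate`.
#' @param n Optional sample size carried into the network.
#' @param bic Optional fit score carried into the network.
#' @return A `network_model`: list with `nodes`, symmetric `weights` matrix
#'   (zero diagonal), `lambda`, `bic`, `n`.
#' @export
precision_to_partial <- function(est, n = NA_integer_, bic = NA_real_) {
  K <- est$K
  d <- diag(K)
  if (any(d <= 0)) stop("precision diagonal must be positive")
  w <- -K / tcrossprod(sqrt(d))
  diag(w) <- 0
  nodes <- rownames(K)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(K)))
  dimnames(w) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = w, lambda = est$lambda,
                 bic = bic, n = n),
            class = "network_model")
}

# light constructor used by tests and examples to build a network directly
# from a weight matrix
network_model <- function(weights, nodes = NULL, lambda = NA_real_,
                          bic = NA_real_, n = NA_integer_) {
  weights <- as.matrix(weights)
  if (max(abs(weights - t(weights))) > 1e-10)
    stop("weights must be symmetric")
  diag(weights) <- 0
  if (is.null(nodes))
    nodes <- if (!is.null(rownames(weights))) rownames(weights)
             else paste0("V", seq_len(nrow(weights)))
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights, lambda = lambda,
                 bic = bic, n = n),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  e <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("network_model: ", length(x$nodes), " nodes, ", e, " edges",
      if (!is.na(x$lambda)) paste0(", lambda = ", signif(x$lambda, 4)),
      if (!is.na(x$bic)) paste0(", BIC = ", signif(x$bic, 6)), "\n", sep = "")
  invisible(x)
}

#' Estimate a partial-correlation network from a measure table
#'
#' The full estimation chain for one group: mixed-type correlations
#' ([mixed_correlation_matrix()]), positive-semidefinite repair
#' ([nearest_psd()]), BIC-selected graphical lasso ([select_penalty()]),
#' conversion to partial correlations ([precision_to_partial()]), and
#' significance filtering -- edges whose underlying correlation is not
#' significant at `alpha` (unadjusted) are removed from the network.
#'
#' The filter acts on the estimated edges rather than on the correlation
#' matrix fed to the graphical lasso: zeroing scattered entries of a smooth
#' polychoric matrix before estimation leaves a matrix that is close to no
#' sparse-precision model at all, which destabilizes the likelihood that
#' BIC penalty selection relies on (see the methods vignette).
#'
#' @param table A `measure_table` for a single group.
#' @param alpha Significance level of the correlation filter (default 0.05,
#'   unadjusted).
#' @param grid_size Penalty-grid size (default 100).
#' @param verbose Print per-stage summaries (selected penalty, filtered and
#'   final edge counts)?
#' @return A `network_model` with attribute `stages` recording the stage
#'   summaries.
#' @examples
#' specs <- asd_td_specs()
#' net <- estimate_network(generate_group_sample(specs$td, seed = 7))
#' net
#' @export
estimate_network <- function(table, alpha = 0.05, grid_size = 100,
                             verbose = FALSE) {
  assoc <- mixed_correlation_matrix(table)
  net <- estimate_from_assoc(assoc, alpha, grid_size)
  st <- attr(net, "stages")
  if (verbose)
    message("estimate_network: lambda* = ", signif(st$lambda, 4),
            "; ", st$n_edges + st$n_zeroed, " edges, ", st$n_zeroed,
            " removed by the significance filter, ", st$n_edges, " kept")
  net
}

# shared tail of the estimation chain (also the bootstrap inner loop)
estimate_from_assoc <- function(assoc, alpha, grid_size) {
  S <- nearest_psd(assoc$r)
  sel <- select_penalty(S, assoc$n, grid_size = grid_size)
  net <- precision_to_partial(sel$fit, n = assoc$n, bic = sel$bic)
  drop <- net$weights != 0 & assoc$p_value > alpha
  net$weights[drop] <- 0
  attr(net, "stages") <- list(
    lambda = sel$lambda,
    n_zeroed = sum(drop[upper.tri(drop)]),
    n_edges = sum(net$weights[upper.tri(net$weights)] != 0))
  net
}
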