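#' Pearson product-moment correlation with a t-based p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return List with `r` and `p_value` (two-sided, from the t transform with
#'   n - 2 degrees of freedom).
#' @examples
#' pearson_corr(c(1, 2, 3, 4), c(1, 2, 4, 3))
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0) stop("x is constant; correlation undefined")
  if (sd(y) == 0) stop("y is constant; correlation undefined")
  r <- cor(x, y)
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p)
}

# shared two-step machinery: thresholds from marginal cumulative proportions
ordinal_thresholds <- function(x) {
  tab <- table(x)
  if (length(tab) < 2)
    stop("ordinal variable has a single observed category")
  qnorm(cumsum(as.numeric(tab))[-length(tab)] / length(x))
}

# tabulate-based crosstab of 1-based category codes (much faster than
# table() in the bootstrap inner loop)
crosstab <- function(xi, yi, nx, ny) {
  matrix(tabulate((xi - 1L) * ny + yi, nx * ny), nx, ny, byrow = TRUE)
}

# likelihood-ratio p against rho = 0 with thresholds held fixed; chosen over
# the Wald form because the Wald test on the profile likelihood measures
# anticonservative at these sample sizes (see the methods vignette)
lr_p <- function(nll0, nll) {
  stat <- max(2 * (nll0 - nll), 0)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Polychoric correlation (two-step maximum likelihood)
#'
#' Estimates the latent bivariate-normal correlation between two ordinal
#' variables.  Thresholds are fixed at standard-normal quantiles of the
#' marginal cumulative proportions; the correlation then maximizes the
#' likelihood of the observed contingency table, by Brent search over
#' \code{[-0.999, 0.999]}.  The p-value is a likelihood-ratio test against
#' independence with the thresholds held fixed; the Wald standard error from
#' the numerically differentiated observed information is also returned.
#'
#' @param x,y Integer-valued vectors, each with >= 2 observed categories.
#' @return List with `r`, `p_value`, `se`, and `clipped`.
#' @examples
#' set.seed(1)
#' z <- matrix(rnorm(400), 200) %*% chol(matrix(c(1, .5, .5, 1), 2))
#' polychoric_corr(z[, 1] > 0, z[, 2] > 0.3)
#' @export
polychoric_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0) stop("empty table")
  xi <- as.integer(factor(x)); yi <- as.integer(factor(y))
  polychoric_codes(xi, yi, max(xi), max(yi))
}

#' Polyserial correlation (two-step maximum likelihood)
#'
#' Estimates the latent correlation between a continuous variable and an
#' ordinal variable.  Thresholds are fixed from the ordinal marginals; the
#' correlation maximizes the conditional likelihood of the ordinal responses
#' given the standardized continuous scores.
#'
#' @param x Numeric (continuous) vector, nonconstant.
#' @param y Integer-valued vector with >= 2 observed categories.
#' @return List with `r`, `p_value`, `se`, and `clipped`.
#' @export
polyserial_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0) stop("empty table")
  if (sd(x) == 0) stop("x is constant; correlation undefined")
  z <- (x - mean(x)) / sd(x)
  polyserial_codes(z, as.integer(factor(y)))
}

# core two-step fits on precomputed 1-based category codes; with thresholds
# fixed at the marginal quantiles, the rho = 0 cell probabilities are
# exactly the products of the observed marginals, which gives the
# likelihood-ratio null term in closed form
polychoric_codes <- function(xi, yi, nx, ny) {
  n <- length(xi)
  if (nx < 2 || ny < 2)
    stop("ordinal variable has a single observed category")
  tab <- crosstab(xi, yi, nx, ny)
  rm_ <- rowSums(tab); cm_ <- colSums(tab)
  tx <- qnorm(cumsum(rm_)[-nx] / n)
  ty <- qnorm(cumsum(cm_)[-ny] / n)
  fit <- .polychoric_fit(tab, tx, ty, 0.999)
  nll0 <- -sum(tab * log(pmax(outer(rm_ / n, cm_ / n), 1e-14)))
  list(r = fit$rho, p_value = lr_p(nll0, fit$nll),
       se = fit$se, clipped = fit$clipped)
}

polyserial_codes <- function(z, yi) {
  ny <- max(yi)
  if (ny < 2) stop("ordinal variable has a single observed category")
  cnt <- tabulate(yi, ny)
  tau <- qnorm(cumsum(cnt)[-ny] / length(z))
  fit <- .polyserial_fit(yi - 1L, z, tau, 0.999)
  pk <- diff(c(0, pnorm(tau), 1))
  nll0 <- -sum(cnt * log(pmax(pk, 1e-14)))
  list(r = fit$rho, p_value = lr_p(nll0, fit$nll),
       se = fit$se, clipped = fit$clipped)
}

#' Mixed-type correlation matrix
#'
#' Computes the full symmetric correlation matrix of a measure table,
#' dispatching per pair on the declared variable kinds:
#' continuous-continuous pairs use Pearson, continuous-ordinal polyserial,
#' ordinal-ordinal polychoric.  Ordinal columns with more than
#' `max_ordinal_levels` distinct observed values are treated as continuous
#' (their polychoric contingency tables would be too sparse to be useful).
#'
#' @param table A `measure_table` (see [generate_group_sample()] /
#'   [read_measure_table()]).
#' @param max_ordinal_levels Observed-level cutoff above which an ordinal
#'   column is treated as continuous (default 10).
#' @return An `association_matrix`: list with correlation matrix `r`, method
#'   tag matrix `method`, p-value matrix `p_value`, and sample size `n`.
#' @export
mixed_correlation_matrix <- function(table, max_ordinal_levels = 10) {
  stopifnot(inherits(table, "measure_table"))
  vars <- attr(table, "variables")
  nms <- vapply(vars, `[[`, character(1), "name")
  p <- length(nms)
  n <- nrow(table)
  if (n < 3) stop("need at least 3 subjects")
  x <- as.matrix(table[, nms, drop = FALSE])
  for (j in seq_len(p)) if (sd(x[, j]) == 0)
    stop("column '", nms[j], "' is constant")
  kinds <- vapply(vars, `[[`, character(1), "kind")
  out <- mixed_corr_core(x, kinds, max_ordinal_levels)
  dimnames(out$r) <- dimnames(out$p_value) <- dimnames(out$method) <-
    list(nms, nms)
  structure(out, class = "association_matrix")
}

# matrix-level core shared with the bootstrap inner loop; x must be a
# numeric matrix with nonconstant columns
mixed_corr_core <- function(x, kinds, max_ordinal_levels = 10) {
  p <- ncol(x)
  eff <- kinds
  # per-column preprocessing shared by every pair involving the column
  codes <- vector("list", p); ncat <- integer(p); zstd <- vector("list", p)
  for (j in seq_len(p)) {
    if (kinds[j] == "ordinal") {
      cj <- as.integer(factor(x[, j]))
      if (max(cj) > max_ordinal_levels) eff[j] <- "continuous"
      else { codes[[j]] <- cj; ncat[j] <- max(cj) }
    }
    if (eff[j] == "continuous")
      zstd[[j]] <- (x[, j] - mean(x[, j])) / sd(x[, j])
  }
  r <- diag(p); pv <- matrix(0, p, p); meth <- matrix("", p, p)
  diag(meth) <- "none"
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (eff[i] == "continuous" && eff[j] == "continuous") {
        fit <- pearson_corr(x[, i], x[, j]); m <- "pearson"
      } else if (eff[i] == "ordinal" && eff[j] == "ordinal") {
        fit <- polychoric_codes(codes[[i]], codes[[j]], ncat[i], ncat[j])
        m <- "polychoric"
      } else if (eff[i] == "continuous") {
        fit <- polyserial_codes(zstd[[i]], codes[[j]]); m <- "polyserial"
      } else {
        fit <- polyserial_codes(zstd[[j]], codes[[i]]); m <- "polyserial"
      }
      r[i, j] <- r[j, i] <- fit$r
      pv[i, j] <- pv[j, i] <- fit$p_value
      meth[i, j] <- meth[j, i] <- m
    }
  }
  list(r = r, method = meth, p_value = pv, n = nrow(x))
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("association_matrix: ", nrow(x$r), " variables, n = ", x$n, "\n",
      sep = "")
  tab <- table(x$method[upper.tri(x$method)])
  cat("methods:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(attr(x, "n_zeroed")))
    cat("entries zeroed by significance filter:", attr(x, "n_zeroed"), "\n")
  invisible(x)
}

#' Zero out non-significant correlations
#'
#' Sets to zero every off-diagonal correlation whose p-value exceeds `alpha`
#' (unadjusted), mirroring the practice of retaining only significant
#' associations before regularized network estimation.
#'
#' @param assoc An `association_matrix`.
#' @param alpha Significance level in (0, 1).
#' @return A new `association_matrix` with attribute `n_zeroed` giving the
#'   number of zeroed (unordered) pairs.
#' @export
significance_filter <- function(assoc, alpha = 0.05) {
  stopifnot(inherits(assoc, "association_matrix"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  drop <- assoc$p_value > alpha & upper.tri(assoc$r)
  out <- assoc
  out$r[drop | t(drop)] <- 0
  attr(out, "n_zeroed") <- sum(drop)
  out
}

#' Nearest positive-semidefinite repair of a correlation matrix
#'
#' Significance filtering (and polychoric estimation itself) can leave a
#' correlation matrix indefinite, which the graphical lasso cannot accept.
#' Eigenvalues below `eps` are clipped to `eps`, the matrix is reconstructed
#' and its diagonal rescaled to 1.  PSD inputs pass through unchanged.
#'
#' @param r Symmetric matrix with unit diagonal.
#' @param eps Eigenvalue floor (default 1e-8).
#' @return Symmetric positive-semidefinite matrix with unit diagonal.
#' @export
nearest_psd <- function(r, eps = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-8)
    stop("input must be a symmetric matrix")
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= eps) return(r)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(r)
  out
}
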