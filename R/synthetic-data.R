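#' Declare a measured variable
#'
#' A variable spec records how a subscale score is typed for correlation
#' dispatch and simulation: `"continuous"` scores enter Pearson/polyserial
#' correlations, `"ordinal"` scores enter polyserial/polychoric correlations
#' and are simulated by thresholding a latent standard-normal variable.
#'
#' @param name Variable name (unique within a spec set).
#' @param kind `"continuous"` or `"ordinal"`.
#' @param levels Number of ordinal categories (ordinal only, >= 2).
#' @param range Numeric length-2 instrument range, `min < max`.
#' @return An object of class `variable_spec`.
#' @examples
#' variable_spec("E-CST", "ordinal", levels = 6, range = c(0, 5))
#' @export
variable_spec <- function(name, kind = c("continuous", "ordinal"),
                          levels = NULL, range) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(range) || length(range) != 2L || range[1] >= range[2])
    stop("`range` must be c(min, max) with min < max for variable '",
         name, "'")
  if (kind == "ordinal") {
    if (is.null(levels) || levels < 2)
      stop("ordinal variable '", name, "' needs `levels` >= 2")
    levels <- as.integer(levels)
  } else {
    levels <- NULL
  }
  structure(list(name = name, kind = kind, levels = levels,
                 range = as.numeric(range)),
            class = "variable_spec")
}

#' Declare a group's generating model
#'
#' A group spec bundles the ground truth for one simulated group: its sample
#' size, variable definitions, latent precision (inverse covariance) matrix,
#' per-ordinal-variable thresholds on the latent standard-normal scale, and
#' mean/SD mappings for continuous variables.  The latent scale is fixed to
#' correlation form (the precision is rescaled so the implied covariance has
#' unit diagonal), matching the polychoric model and making thresholds
#' standard-normal quantiles.
#'
#' @param label Group label.
#' @param n Number of subjects.
#' @param variables List of [variable_spec()] objects (defines column order).
#' @param precision p x p symmetric positive-definite matrix; its off-diagonal
#'   pattern encodes the ground-truth partial correlations
#'   `-K_ij / sqrt(K_ii K_jj)`.
#' @param thresholds Named list: for each ordinal variable, `levels - 1`
#'   strictly increasing latent cut-points.
#' @param continuous_scale Named list: for each continuous variable,
#'   `c(mean, sd)` mapping the latent standard normal to the instrument scale.
#' @return An object of class `group_spec`.
#' @seealso [generate_group_sample()], [asd_td_specs()]
#' @export
group_spec <- function(label, n, variables, precision, thresholds = list(),
                       continuous_scale = list()) {
  stopifnot(is.list(variables), length(variables) > 0)
  ok <- vapply(variables, inherits, logical(1), "variable_spec")
  if (!all(ok)) stop("`variables` must be a list of variable_spec objects")
  nms <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate variable names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  p <- length(variables)
  precision <- as.matrix(precision)
  if (nrow(precision) != p || ncol(precision) != p)
    stop("`precision` must be ", p, " x ", p)
  if (max(abs(precision - t(precision))) > 1e-8)
    stop("precision matrix for group '", label, "' is not symmetric")
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("precision matrix for group '", label,
         "' is not positive definite (min eigenvalue ", signif(min(ev), 3), ")")
  # rescale so the implied latent covariance is a correlation matrix
  sigma <- chol2inv(chol(precision))
  d <- sqrt(diag(sigma))
  sigma <- sigma / tcrossprod(d)
  precision <- chol2inv(chol(sigma))
  dimnames(precision) <- dimnames(sigma) <- list(nms, nms)

  for (v in variables) {
    if (v$kind == "ordinal") {
      th <- thresholds[[v$name]]
      if (is.null(th) || length(th) != v$levels - 1L)
        stop("variable '", v$name, "' needs ", v$levels - 1L,
             " thresholds, got ", length(th))
      if (any(diff(th) <= 0))
        stop("thresholds for '", v$name, "' must be strictly increasing")
    } else {
      sc <- continuous_scale[[v$name]]
      if (is.null(sc) || length(sc) != 2L || sc[2] <= 0)
        stop("continuous variable '", v$name,
             "' needs continuous_scale = c(mean, sd) with sd > 0")
    }
  }
  if (n < p + 1)
    warning("n = ", n, " < p + 1 = ", p + 1,
            "; downstream estimates will be unstable")
  structure(list(label = label, n = as.integer(n), variables = variables,
                 precision = precision, sigma = sigma,
                 thresholds = thresholds,
                 continuous_scale = continuous_scale),
            class = "group_spec")
}

#' Discretize latent values at fixed cut-points
#'
#' Returns, for each value, the count of thresholds strictly below it, i.e.
#' the 0-based ordinal category under the latent-threshold model that also
#' underlies the polychoric correlation.
#'
#' @param values Numeric vector of latent values.
#' @param thresholds Strictly increasing numeric cut-points.
#' @return Integer vector in `0:length(thresholds)`.
#' @examples
#' discretize_latent(c(-2, 0.5, 9), thresholds = c(-1, 0, 1))
#' @export
discretize_latent <- function(values, thresholds) {
  if (length(thresholds) == 0) return(rep(0L, length(values)))
  if (any(diff(thresholds) <= 0))
    stop("`thresholds` must be strictly increasing")
  findInterval(values, thresholds, left.open = TRUE)
}

#' Simulate one group's subjects-by-measures table
#'
#' Draws `n` latent vectors from the zero-mean Gaussian with covariance equal
#' to the inverse of the spec's precision matrix, then maps each column to
#' its instrument scale: ordinal columns by thresholding
#' ([discretize_latent()] shifted to the range minimum), continuous columns
#' by the spec's affine mean/SD map, rounded to 0.01 and clipped to the
#' instrument range.
#'
#' @param spec A [group_spec()].
#' @param seed Integer seed; the same seed reproduces the table bit for bit.
#' @return A `measure_table`: a data frame whose first column `group` holds
#'   the group label, followed by one numeric column per variable, with the
#'   variable specs attached as attribute `"variables"`.
#' @examples
#' specs <- asd_td_specs()
#' tab <- generate_group_sample(specs$td, seed = 1)
#' dim(tab)
#' @export
generate_group_sample <- function(spec, seed) {
  stopifnot(inherits(spec, "group_spec"))
  restore <- local_seed(seed)
  on.exit(restore())
  p <- length(spec$variables)
  z <- matrix(rnorm(spec$n * p), spec$n, p) %*% chol(spec$sigma)
  out <- data.frame(group = rep(spec$label, spec$n),
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    v <- spec$variables[[j]]
    if (v$kind == "ordinal") {
      val <- v$range[1] + discretize_latent(z[, j], spec$thresholds[[v$name]])
    } else {
      sc <- spec$continuous_scale[[v$name]]
      val <- round(pmin(pmax(sc[1] + sc[2] * z[, j], v$range[1]), v$range[2]), 2)
    }
    out[[v$name]] <- val
  }
  measure_table(out, spec$variables)
}

# internal constructor: validates values against the variable specs
measure_table <- function(df, variables) {
  nms <- vapply(variables, `[[`, character(1), "name")
  if (!identical(names(df), c("group", nms)))
    stop("measure table columns must be 'group' followed by: ",
         paste(nms, collapse = ", "))
  for (v in variables) {
    x <- df[[v$name]]
    if (!is.numeric(x)) stop("column '", v$name, "' is not numeric")
    if (anyNA(x)) stop("column '", v$name, "' contains missing values")
    bad <- which(x < v$range[1] | x > v$range[2])
    if (length(bad))
      stop("column '", v$name, "' has value ", x[bad[1]], " (row ", bad[1],
           ") outside its declared range [", v$range[1], ", ", v$range[2], "]")
    if (v$kind == "ordinal" && any(x != round(x)))
      stop("ordinal column '", v$name, "' contains non-integer values")
  }
  structure(df, variables = variables,
            class = c("measure_table", "data.frame"))
}

#' @export
print.measure_table <- function(x, ...) {
  vars <- attr(x, "variables")
  kinds <- vapply(vars, `[[`, character(1), "kind")
  cat("measure_table: ", nrow(x), " subjects x ", length(vars),
      " measures (", sum(kinds == "ordinal"), " ordinal, ",
      sum(kinds == "continuous"), " continuous); groups: ",
      paste(unique(x$group), collapse = ", "), "\n", sep = "")
  NextMethod()
  invisible(x)
}

# latent cut-points reproducing a discretized-normal marginal with the given
# instrument-scale mean/sd; zero-probability cells are floored so cut-points
# stay strictly increasing
marginal_thresholds <- function(mu, sigma, levels, min = 0) {
  scores <- min + seq_len(levels) - 1
  pr <- diff(c(0, pnorm((scores[-levels] + 0.5 - mu) / sigma), 1))
  pr <- pmax(pr, 1e-3)
  pr <- pr / sum(pr)
  qnorm(cumsum(pr)[-levels])
}

# assemble a unit-diagonal precision from a sparse list of target partial
# correlations; entries are K_ij = -w_ij
precision_from_partials <- function(names, edges) {
  p <- length(names)
  K <- diag(p)
  dimnames(K) <- list(names, names)
  for (e in edges) {
    K[e[[1]], e[[2]]] <- K[e[[2]], e[[1]]] <- -as.numeric(e[[3]])
  }
  K
}

#' Two-group reference specs for the 11 social-cognition measures
#'
#' Builds the pair of generating models the package uses as its study
#' emulation: 11 subscale scores (four Eyes Task accuracy composites, 0-14;
#' three Comic Strip Task theory-of-mind subscales, 0-5; four Social
#' Information Processing Interview steps) for a typically-developing-like
#' group (n = 81) and an ASD-like group (n = 76).
#'
#' The TD-like precision encodes one dense component: every pair of measures
#' has a positive partial correlation (0.08, just inside the positive-definite
#' bound 1/(p-1) for an equi-partial-correlation model).  The ASD-like
#' precision encodes three blocks -- (a) I-SIPI, PMS-ET, NMS-ET, PPE-ET,
#' NPE-ET, RE-SIPI; (b) E-CST, B-CST, I-CST, RC-SIPI; (c) E-SIPI isolated,
#' with every off-diagonal precision entry in its row zero.  Within-block
#' edges are partial correlations of 0.3 arranged as the densest 3-regular
#' structure each block admits (an equicorrelated block at 0.3 would not be
#' positive definite): a prism for block (a), the complete graph for block
#' (b).  Two weak bridges of 0.1 (PMS-ET to E-CST, RC-SIPI to RE-SIPI)
#' connect blocks (a) and (b).  Ordinal thresholds and continuous scalings are placed so the
#' simulated marginals approximate the skewed instrument distributions
#' reported for the two groups (e.g. emotion-subscale medians of 4-5).
#'
#' @return A list with elements `td` and `asd`, each a [group_spec()].
#' @examples
#' specs <- asd_td_specs()
#' specs$asd$precision["E-SIPI", ]
#' @export
asd_td_specs <- function() {
  vars <- list(
    variable_spec("B-CST",   "ordinal", levels = 6,  range = c(0, 5)),
    variable_spec("E-CST",   "ordinal", levels = 6,  range = c(0, 5)),
    variable_spec("I-CST",   "ordinal", levels = 6,  range = c(0, 5)),
    variable_spec("NPE-ET",  "ordinal", levels = 15, range = c(0, 14)),
    variable_spec("PPE-ET",  "ordinal", levels = 15, range = c(0, 14)),
    variable_spec("NMS-ET",  "ordinal", levels = 15, range = c(0, 14)),
    variable_spec("PMS-ET",  "ordinal", levels = 15, range = c(0, 14)),
    variable_spec("E-SIPI",  "ordinal", levels = 5,  range = c(0, 4)),
    variable_spec("I-SIPI",  "ordinal", levels = 5,  range = c(0, 4)),
    variable_spec("RC-SIPI", "ordinal", levels = 9,  range = c(0, 8)),
    variable_spec("RE-SIPI", "continuous", range = c(0, 36))
  )
  nms <- vapply(vars, `[[`, character(1), "name")

  # TD: single dense community, uniform positive partials
  pairs <- which(upper.tri(diag(11)), arr.ind = TRUE)
  td_edges <- lapply(seq_len(nrow(pairs)), function(i)
    list(nms[pairs[i, 1]], nms[pairs[i, 2]], 0.08))
  K_td <- precision_from_partials(nms, td_edges)

  # ASD: three blocks, E-SIPI isolated, weak (a)-(b) bridges.  Within-block
  # edges carry partial correlation 0.3; an equicorrelated block at 0.3
  # would not be positive definite, so each block is the densest 0.3-capable
  # structure: a 3-regular prism for the 6-node block (largest adjacency
  # eigenvalue 3 keeps the minimum precision eigenvalue at 1 - 0.9 = 0.1)
  # and the complete graph for the 4-node block (also 3-regular).
  w <- 0.3
  asd_edges <- list(
    # block (a) prism: triangles I-SIPI/PMS-ET/NMS-ET and
    # PPE-ET/NPE-ET/RE-SIPI joined by three rungs
    list("I-SIPI", "PMS-ET", w), list("PMS-ET", "NMS-ET", w),
    list("NMS-ET", "I-SIPI", w),
    list("PPE-ET", "NPE-ET", w), list("NPE-ET", "RE-SIPI", w),
    list("RE-SIPI", "PPE-ET", w),
    list("I-SIPI", "RE-SIPI", w), list("PMS-ET", "PPE-ET", w),
    list("NMS-ET", "NPE-ET", w),
    # block (b): complete graph on E-CST, B-CST, I-CST, RC-SIPI
    list("E-CST", "B-CST", w), list("E-CST", "I-CST", w),
    list("E-CST", "RC-SIPI", w), list("B-CST", "I-CST", w),
    list("B-CST", "RC-SIPI", w), list("I-CST", "RC-SIPI", w),
    # weak bridges between blocks (a) and (b)
    list("PMS-ET", "E-CST", 0.1), list("RC-SIPI", "RE-SIPI", 0.1)
  )
  K_asd <- precision_from_partials(nms, asd_edges)

  marg <- function(tab) {
    th <- list()
    for (v in vars) {
      if (v$kind != "ordinal") next
      m <- tab[[v$name]]
      th[[v$name]] <- marginal_thresholds(m[1], m[2], v$levels, v$range[1])
    }
    th
  }
  # instrument-scale target means/SDs per group (skewed ceiling-heavy
  # marginals for the emotion and encoding subscales)
  asd_m <- list(`B-CST` = c(1.5, 1.2), `E-CST` = c(4.0, 1.0),
                `I-CST` = c(4.0, 1.2), `NPE-ET` = c(12.1, 2.1),
                `PPE-ET` = c(11.5, 2.4), `NMS-ET` = c(10.6, 2.6),
                `PMS-ET` = c(10.3, 2.4), `E-SIPI` = c(3.4, 0.8),
                `I-SIPI` = c(2.6, 0.9), `RC-SIPI` = c(2.0, 1.4))
  td_m  <- list(`B-CST` = c(3.3, 1.3), `E-CST` = c(4.4, 0.8),
                `I-CST` = c(4.0, 1.2), `NPE-ET` = c(12.2, 1.3),
                `PPE-ET` = c(11.1, 1.7), `NMS-ET` = c(11.6, 1.7),
                `PMS-ET` = c(10.8, 1.7), `E-SIPI` = c(3.4, 0.8),
                `I-SIPI` = c(3.2, 0.8), `RC-SIPI` = c(4.0, 1.5))

  list(
    td = group_spec("TD", 81, vars, K_td, thresholds = marg(td_m),
                    continuous_scale = list(`RE-SIPI` = c(29.7, 1.1))),
    asd = group_spec("ASD", 76, vars, K_asd, thresholds = marg(asd_m),
                     continuous_scale = list(`RE-SIPI` = c(19.7, 2.2)))
  )
}
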