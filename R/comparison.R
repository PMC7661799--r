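#' Nonparametric bootstrap of one group's network centralities
#'
#' Resamples subjects with replacement `B` times; each replicate runs the
#' full estimation chain ([estimate_network()]) and computes the three
#' centrality indices.  Replicates in which a column becomes constant or
#' estimation fails are redrawn (up to `10 * B` total draws) and counted, so
#' the result always holds exactly `B` successful replicates.
#'
#' @param table A `measure_table` for a single group.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; results are reproducible.
#' @param alpha Correlation-filter level passed to [estimate_network()].
#' @param grid_size Penalty-grid size passed to [estimate_network()].
#' @param closeness_variant Passed to [centrality_profile()].
#' @return A `bootstrap_result`: list with `group`, `B`, `nodes`, `values`
#'   (per metric, a B x p matrix of replicate centralities), `mean` and `sd`
#'   (per metric, named vectors), and `failures` (count of redraws).
#' @export
bootstrap_networks <- function(table, B = 1000, seed = 1, alpha = 0.05,
                               grid_size = 100,
                               closeness_variant = "average") {
  stopifnot(inherits(table, "measure_table"), B >= 1)
  grp <- unique(table$group)
  if (length(grp) != 1)
    stop("bootstrap_networks expects a single-group table; got groups: ",
         paste(grp, collapse = ", "))
  vars <- attr(table, "variables")
  nms <- vapply(vars, `[[`, character(1), "name")
  kinds <- vapply(vars, `[[`, character(1), "kind")
  xmat <- as.matrix(as.data.frame(table)[, nms, drop = FALSE])
  n <- nrow(table)
  restore <- local_seed(seed)
  on.exit(restore())
  metrics <- c("strength", "betweenness", "closeness")
  vals <- lapply(metrics, function(m)
    matrix(NA_real_, B, length(nms), dimnames = list(NULL, nms)))
  names(vals) <- metrics
  failures <- 0L
  draws <- 0L
  b <- 1L
  while (b <= B) {
    if (draws >= 10L * B)
      stop("bootstrap redraw cap exceeded: ", failures, " failures in ",
           draws, " draws (", round(100 * failures / draws), "% failure rate)")
    draws <- draws + 1L
    idx <- sample.int(n, n, replace = TRUE)
    xr <- xmat[idx, , drop = FALSE]
    rng <- apply(xr, 2, range)
    if (any(rng[1, ] == rng[2, ])) {    # a constant column: redraw
      failures <- failures + 1L
      next
    }
    prof <- tryCatch({
      assoc <- mixed_corr_core(xr, kinds)
      dimnames(assoc$r) <- dimnames(assoc$p_value) <- list(nms, nms)
      net <- estimate_from_assoc(assoc, alpha, grid_size)
      centrality_profile(net, closeness_variant = closeness_variant)
    }, error = function(e) NULL)
    if (is.null(prof)) {
      failures <- failures + 1L
      next
    }
    for (m in metrics) vals[[m]][b, ] <- prof[[m]]
    b <- b + 1L
  }
  structure(list(group = grp, B = as.integer(B), nodes = nms,
                 values = vals,
                 mean = lapply(vals, colMeans),
                 sd = lapply(vals, function(v) apply(v, 2, sd)),
                 failures = failures),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("bootstrap_result: group '", x$group, "', B = ", x$B, ", ",
      x$failures, " redraws\n", sep = "")
  df <- data.frame(node = x$nodes)
  for (m in names(x$mean)) {
    df[[paste0(m, "_mean")]] <- round(unname(x$mean[[m]]), 3)
    df[[paste0(m, "_sd")]] <- round(unname(x$sd[[m]]), 3)
  }
  print(df)
  invisible(x)
}

#' Bonferroni significance flags
#'
#' Tests each of `m = length(p_values)` hypotheses at `alpha / m`.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error level (default 0.05).
#' @return Logical vector of flags (empty input gives an empty vector).
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p_values <= alpha / length(p_values)
}

#' Compare two groups' bootstrap centrality distributions
#'
#' For every node and metric, a two-sample z statistic is built from the two
#' groups' bootstrap means and SDs, with a two-sided normal p-value and a
#' Bonferroni flag at `alpha / m` (`m` = number of testable node-metric
#' cells; cells with a zero denominator are undefined, reported as `NA`, and
#' excluded from `m`).
#'
#' Two denominator conventions are provided.  The default `"sd"` combines
#' the bootstrap SDs in quadrature, `z = (mean_a - mean_b) /
#' sqrt(sd_a^2 + sd_b^2)`; since the bootstrap SD estimates the sampling SD
#' of each group's centrality, this is the calibrated two-sample
#' construction.  `"se"` divides instead by the bootstrap standard error of
#' the mean, `sqrt(sd_a^2/B_a + sd_b^2/B_b)` -- the arithmetic behind some
#' published bootstrap z tables.  Its denominator shrinks with the number of
#' replicates rather than with the information in the data, so it overstates
#' evidence by a factor of roughly `sqrt(B)` and rejects almost always under
#' the null; it is included for comparability, not inference (see the
#' methods vignette).
#'
#' @param a,b `bootstrap_result` objects with identical nodes.
#' @param alpha Family-wise error level (default 0.05).
#' @param metrics Metrics to compare (default all three).
#' @param denominator `"sd"` (calibrated, default) or `"se"`.
#' @return A `comparison_report` data frame with columns `node`, `metric`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `z`, `p`, `significant`, and
#'   attributes `m`, `alpha`, `denominator`.
#' @export
centrality_z_test <- function(a, b, alpha = 0.05,
                              metrics = c("strength", "betweenness",
                                          "closeness"),
                              denominator = c("sd", "se")) {
  stopifnot(inherits(a, "bootstrap_result"), inherits(b, "bootstrap_result"))
  denominator <- match.arg(denominator)
  if (!identical(a$nodes, b$nodes))
    stop("the two bootstrap results cover different nodes")
  rows <- list()
  for (m in metrics) {
    den <- if (denominator == "sd") sqrt(a$sd[[m]]^2 + b$sd[[m]]^2)
           else sqrt(a$sd[[m]]^2 / a$B + b$sd[[m]]^2 / b$B)
    z <- ifelse(den > 0, (a$mean[[m]] - b$mean[[m]]) / den, NA_real_)
    rows[[m]] <- data.frame(node = a$nodes, metric = m,
                            mean_a = unname(a$mean[[m]]),
                            sd_a = unname(a$sd[[m]]),
                            mean_b = unname(b$mean[[m]]),
                            sd_b = unname(b$sd[[m]]),
                            z = unname(z))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p <- 2 * pnorm(-abs(out$z))
  m_eff <- sum(!is.na(out$p))
  out$significant <- ifelse(is.na(out$p), NA, out$p <= alpha / m_eff)
  structure(out, m = m_eff, alpha = alpha, denominator = denominator,
            class = c("comparison_report", "data.frame"))
}

#' Descriptive two-group tests on the raw measures
#'
#' Continuous-typed measures are compared with the two-sample Student t test
#' (pooled variance; `welch = TRUE` switches to Welch), ordinal-typed
#' measures with the Mann-Whitney U test.  P-values receive Bonferroni flags
#' across all measures tested.  Measures that are constant in both groups
#' cannot be tested and are reported with `NA` statistics and a note.
#'
#' @param a,b `measure_table`s with identical variables.
#' @param alpha Family-wise error level (default 0.05).
#' @param welch Use the Welch t test instead of pooled variance?
#' @return Data frame with columns `measure`, `test`, `statistic`, `p`,
#'   `significant`, `note`.
#' @export
descriptive_tests <- function(a, b, alpha = 0.05, welch = FALSE) {
  va <- attr(a, "variables"); vb <- attr(b, "variables")
  na_ <- vapply(va, `[[`, character(1), "name")
  nb_ <- vapply(vb, `[[`, character(1), "name")
  if (!identical(na_, nb_))
    stop("the two tables measure different variables")
  out <- data.frame(measure = na_, test = NA_character_,
                    statistic = NA_real_, p = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_along(va)) {
    x <- a[[na_[i]]]; y <- b[[na_[i]]]
    if (va[[i]]$kind == "continuous") {
      out$test[i] <- "t"
      ft <- tryCatch(t.test(x, y, var.equal = !welch), error = function(e) e)
      if (inherits(ft, "error")) {
        out$note[i] <- "degenerate: zero variance in both groups"
      } else {
        out$statistic[i] <- unname(ft$statistic)
        out$p[i] <- ft$p.value
      }
    } else {
      out$test[i] <- "mann-whitney"
      ft <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
      out$statistic[i] <- unname(ft$statistic)
      out$p[i] <- ft$p.value
    }
  }
  ok <- !is.na(out$p)
  out$significant <- NA
  if (any(ok))
    out$significant[ok] <- out$p[ok] <= alpha / sum(ok)
  attr(out, "alpha") <- alpha
  attr(out, "m") <- sum(ok)
  out
}
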