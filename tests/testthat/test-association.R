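test_that("pearson_corr matches the sum-formula oracle and handles edge cases", {
  expect_equal(pearson_corr(1:5, 1:5)$r, 1)
  expect_equal(pearson_corr(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_equal(pearson_corr(c(1, 2, 3, 4), c(1, 2, 4, 3))$r, 0.8)
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    fit <- pearson_corr(x, y)
    expect_equal(fit$r, r_oracle, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(fit$p_value, ct$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_corr(1:3, 1:4), "length")
  expect_error(pearson_corr(1:2, 2:1), "3 observations")
})

test_that("polychoric correlation behaves exactly on canonical 2x2 tables", {
  # balanced independent table: 25 in every cell
  x <- rep(c(0, 0, 1, 1), each = 25)
  y <- rep(c(0, 1, 0, 1), each = 25)
  expect_lt(abs(polychoric_corr(x, y)$r), 1e-6)
  # perfectly diagonal table drives rho to the clipping boundary
  x2 <- rep(c(0, 1), each = 50)
  fit <- polychoric_corr(x2, x2)
  expect_equal(fit$r, 0.999, tolerance = 1e-4)
  expect_true(fit$clipped)
  expect_lt(fit$p_value, 1e-10)
  expect_error(polychoric_corr(rep(0, 10), rep(0:1, 5)), "single observed")
  expect_error(polychoric_corr(numeric(0), numeric(0)), "empty")
})

test_that("polychoric recovers a known latent correlation by simulation", {
  set.seed(7)
  n <- 10000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  x <- as.integer(z1 > 0); y <- as.integer(z2 > 0)   # median splits
  expect_equal(polychoric_corr(x, y)$r, 0.5, tolerance = 0.05)
})

test_that("polyserial recovers latent structure and rejects bad input", {
  set.seed(8)
  n <- 10000
  x <- rnorm(n)
  y <- as.integer(x > median(x))   # latent rho = 1 through a median split
  expect_gte(polyserial_corr(x, y)$r, 0.95)
  y2 <- as.integer(rnorm(n) > 0)
  fit <- polyserial_corr(x, y2)
  expect_lt(abs(fit$r), 0.05)
  expect_gt(fit$p_value, 0.001)
  expect_error(polyserial_corr(rep(1, 10), rep(0:1, 5)), "constant")
})

test_that("ordinal p-values are calibrated near the nominal level", {
  # matched to the study's sample size; LR filtering depends on this
  set.seed(41)
  n <- 76; B <- 400
  hits_pc <- 0; hits_ps <- 0
  for (b in 1:B) {
    x <- pmin(pmax(round(rnorm(n, 3.4, 0.8)), 0), 4)
    y <- pmin(pmax(round(rnorm(n, 4.0, 1.0)), 0), 5)
    z <- rnorm(n)
    if (sd(x) == 0 || sd(y) == 0) next
    hits_pc <- hits_pc + (polychoric_corr(x, y)$p_value < 0.05)
    hits_ps <- hits_ps + (polyserial_corr(z, y)$p_value < 0.05)
  }
  # binomial 99% envelope around 0.05 at B = 400 is ~ +/- 0.028
  expect_lt(hits_pc / B, 0.08)
  expect_lt(hits_ps / B, 0.08)
})

test_that("mixed_correlation_matrix dispatches on declared kinds", {
  specs <- asd_td_specs()
  tab <- generate_group_sample(specs$td, seed = 21)
  assoc <- mixed_correlation_matrix(tab)
  expect_s3_class(assoc, "association_matrix")
  # RE-SIPI is continuous: all its pairs with CST subscales are polyserial
  for (cst in c("B-CST", "E-CST", "I-CST"))
    expect_equal(assoc$method["RE-SIPI", cst], "polyserial")
  expect_equal(assoc$method["B-CST", "E-CST"], "polychoric")
  # exact symmetry and unit diagonal
  expect_identical(assoc$r, t(assoc$r))
  expect_equal(unname(diag(assoc$r)), rep(1, 11))
  expect_identical(assoc$method, t(assoc$method))
  expect_true(all(assoc$p_value >= 0 & assoc$p_value <= 1))
})

test_that("all-continuous tables use Pearson throughout", {
  vars <- lapply(1:3, function(i)
    variable_spec(paste0("v", i), "continuous", range = c(-50, 50)))
  spec <- group_spec("G", 30, vars, diag(3),
                     continuous_scale = setNames(rep(list(c(0, 1)), 3),
                                                 paste0("v", 1:3)))
  assoc <- mixed_correlation_matrix(generate_group_sample(spec, seed = 3))
  expect_true(all(assoc$method[upper.tri(assoc$method)] == "pearson"))
})

test_that("mixed_correlation_matrix is permutation-equivariant", {
  tab <- toy_table(n = 60, seed = 13)
  assoc <- mixed_correlation_matrix(tab)
  perm <- c(3, 1, 2)
  vars <- attr(tab, "variables")[perm]
  tab2 <- mixedggm:::measure_table(
    tab[, c("group", vapply(vars, `[[`, character(1), "name"))], vars)
  assoc2 <- mixed_correlation_matrix(tab2)
  expect_equal(assoc2$r, assoc$r[perm, perm])
  expect_equal(assoc2$p_value, assoc$p_value[perm, perm])
})

test_that("constant columns are reported by name", {
  tab <- toy_table(n = 30, seed = 2)
  tab$ord_a <- 2
  expect_error(mixed_correlation_matrix(tab), "ord_a")
})

test_that("significance_filter zeroes exactly the non-significant pairs", {
  # critical |r| at alpha = 0.05, n = 157 is about 0.157: r = 0.10 must go,
  # r = 0.30 must stay (two-sided t oracle computed here independently)
  n <- 157
  p_of_r <- function(r) 2 * pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2)
  r <- matrix(c(1, 0.1, 0.3,
                0.1, 1, 0.2,
                0.3, 0.2, 1), 3, byrow = TRUE)
  pv <- matrix(0, 3, 3)
  for (i in 1:2) for (j in (i + 1):3)
    pv[i, j] <- pv[j, i] <- p_of_r(r[i, j])
  assoc <- structure(list(r = r, method = matrix("pearson", 3, 3),
                          p_value = pv, n = n),
                     class = "association_matrix")
  out <- significance_filter(assoc, 0.05)
  expect_equal(out$r[1, 2], 0)         # r = 0.10 zeroed
  expect_equal(out$r[1, 3], 0.3)       # r = 0.30 retained
  expect_equal(out$r[2, 3], 0.2)       # above the 0.157 cutoff
  expect_equal(attr(out, "n_zeroed"), 1)
  expect_identical(out$r, t(out$r))
  expect_equal(unname(diag(out$r)), rep(1, 3))
  expect_error(significance_filter(assoc, 1), "alpha")
  expect_error(significance_filter(assoc, 0), "alpha")
})

test_that("nearest_psd repairs indefinite matrices and fixes PSD ones", {
  r_bad <- matrix(-0.9, 3, 3); diag(r_bad) <- 1
  expect_lt(min(eigen(r_bad, symmetric = TRUE)$values), 0)
  out <- nearest_psd(r_bad)
  expect_gte(min(eigen(out, symmetric = TRUE)$values), -1e-10)
  expect_equal(unname(diag(out)), rep(1, 3))
  # PSD inputs pass through unchanged; identity is a fixed point
  r_ok <- matrix(c(1, .5, .5, 1), 2)
  expect_equal(nearest_psd(r_ok), r_ok, tolerance = 1e-12)
  expect_equal(nearest_psd(diag(4)), diag(4))
  # idempotence up to the eigenvalue floor
  expect_equal(nearest_psd(out), out, tolerance = 1e-6)
  expect_error(nearest_psd(matrix(1:4, 2)), "symmetric")
})
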