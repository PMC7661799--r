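test_that("graphical lasso solves canonical cases exactly", {
  # identity input is already optimal at any penalty
  for (lam in c(0, 0.2, 1)) {
    fit <- graphical_lasso(diag(3), lam)
    expect_equal(fit$K, diag(3), tolerance = 1e-10)
  }
  # unpenalized solution is the matrix inverse
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  fit0 <- graphical_lasso(S, 0, tol = 1e-9)
  expect_equal(fit0$K, matrix(c(4, -2, -2, 4) / 3, 2), tolerance = 1e-6)
  # off-diagonal vanishes exactly once lambda reaches |s_12|
  for (lam in c(0.5, 0.7)) {
    fitL <- graphical_lasso(S, lam)
    expect_equal(fitL$K[1, 2], 0)
    expect_equal(diag(fitL$K), 1 / diag(S), tolerance = 1e-8)
  }
  expect_error(graphical_lasso(matrix(c(1, 2, 2, 1), 2) * -1, 0.1),
               "positive semidefinite")
  expect_error(graphical_lasso(S, -0.1), "lambda")
})

test_that("glasso satisfies its KKT conditions on random problems", {
  set.seed(17)
  for (rep in 1:5) {
    p <- sample(4:9, 1)
    A <- matrix(rnorm(p * p), p)
    S <- cov2cor(crossprod(A) / p + diag(p))
    lam <- runif(1, 0.05, 0.4)
    fit <- graphical_lasso(S, lam, tol = 1e-7)
    expect_lt(mixedggm:::glasso_kkt(fit, S), 1e-4)
  }
})

test_that("unpenalized fit equals the direct inverse on well-conditioned S", {
  set.seed(18)
  A <- matrix(rnorm(36), 6)
  S <- cov2cor(crossprod(A) / 6 + diag(6))
  fit <- graphical_lasso(S, 0, tol = 1e-9)
  expect_equal(fit$K, solve(S), tolerance = 1e-6)
})

test_that("edge count is monotone non-increasing in lambda", {
  set.seed(19)
  A <- matrix(rnorm(64), 8)
  S <- cov2cor(crossprod(A) / 8 + diag(8))
  sel <- select_penalty(S, n = 200, grid_size = 60)
  path <- sel$path   # lambdas descend, so edges must not decrease
  expect_true(all(diff(path$edges) >= 0))
})

test_that("bic_score implements -2l + E log n", {
  est <- list(K = diag(2))
  # log det I = 0, tr(I I) = 2 -> l = -n, E = 0
  expect_equal(bic_score(est, diag(2), 100), 200)
  # one active edge adds log(n)
  K <- matrix(c(4, -2, -2, 4) / 3, 2)
  S <- matrix(c(1, .5, .5, 1), 2)
  ll <- (100 / 2) * (determinant(K)$modulus[1] - sum(S * K))
  expect_equal(bic_score(list(K = K), S, 100), -2 * ll + log(100))
  expect_error(bic_score(list(K = matrix(0, 2, 2)), diag(2), 10),
               "positive definite")
})

test_that("BIC prefers the true sparsity on data from a sparse model", {
  # 4-node chain precision; BIC at the true structure must not exceed the
  # unpenalized (dense) fit for most replicates
  K_true <- diag(4)
  K_true[1, 2] <- K_true[2, 1] <- -0.4
  K_true[2, 3] <- K_true[3, 2] <- -0.4
  K_true[3, 4] <- K_true[4, 3] <- -0.4
  sigma <- cov2cor(solve(K_true))
  wins <- 0
  set.seed(23)
  for (rep in 1:20) {
    x <- matrix(rnorm(1000 * 4), 1000, 4) %*% chol(sigma)
    S <- cor(x)
    sel <- select_penalty(S, 1000)
    dense <- graphical_lasso(S, 0, tol = 1e-8)
    wins <- wins + (sel$bic <= bic_score(dense, S, 1000))
  }
  expect_gt(wins, 10)
})

test_that("select_penalty follows the grid and tie conventions", {
  # identity: every lambda gives the same fit; the tie rule keeps the
  # largest lambda, which for a zero off-diagonal matrix is 0
  sel <- select_penalty(diag(3), 50)
  expect_equal(sel$fit$K, diag(3), tolerance = 1e-10)
  expect_equal(sel$lambda, sel$path$lambda[1])
  # degenerate one-point grid returns the lambda_max fit (empty network)
  S <- matrix(c(1, .6, .6, 1), 2)
  sel1 <- select_penalty(S, 100, grid_size = 1)
  expect_equal(sel1$lambda, 0.6)
  expect_equal(sel1$fit$K[1, 2], 0)
  # the reported BIC agrees with bic_score recomputed in R
  set.seed(29)
  A <- matrix(rnorm(49), 7)
  S2 <- cov2cor(crossprod(A) / 7 + diag(7))
  sel2 <- select_penalty(S2, 150)
  expect_equal(sel2$bic, bic_score(sel2$fit, S2, 150), tolerance = 1e-8)
})

test_that("precision_to_partial applies the sign-flipped scaling", {
  K <- matrix(c(4, -2, -2, 4) / 3, 2)
  net <- precision_to_partial(list(K = K, lambda = 0.1))
  expect_equal(net$weights[1, 2], 0.5)
  expect_equal(diag(net$weights), c(V1 = 0, V2 = 0))
  # positive K_12 gives a negative edge
  K2 <- matrix(c(2, 0.5, 0.5, 2), 2)
  net2 <- precision_to_partial(list(K = K2, lambda = 0))
  expect_lt(net2$weights[1, 2], 0)
  # diagonal precision gives an empty network
  net3 <- precision_to_partial(list(K = diag(c(2, 3)), lambda = 0))
  expect_true(all(net3$weights == 0))
  expect_error(precision_to_partial(list(K = diag(c(-1, 1)), lambda = 0)),
               "positive")
})

test_that("partial correlations reproduce the textbook 3-variable formula", {
  # recursive formula: r_12.3 = (r12 - r13 r23) / sqrt((1-r13^2)(1-r23^2))
  r12 <- 0.5; r13 <- 0.4; r23 <- 0.6
  S <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
  net <- precision_to_partial(list(K = solve(S), lambda = 0))
  oracle <- function(rab, rac, rbc)
    (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  expect_equal(net$weights[1, 2], oracle(r12, r13, r23), tolerance = 1e-10)
  expect_equal(net$weights[1, 3], oracle(r13, r12, r23), tolerance = 1e-10)
  expect_equal(net$weights[2, 3], oracle(r23, r12, r13), tolerance = 1e-10)
})

test_that("estimate_network composes the stages and survives tiny samples", {
  specs <- asd_td_specs()
  tab <- generate_group_sample(specs$td, seed = 7)
  net <- estimate_network(tab, verbose = FALSE)
  expect_s3_class(net, "network_model")
  expect_equal(net$nodes, vapply(attr(tab, "variables"), `[[`,
                                 character(1), "name"))
  expect_identical(net$weights, t(net$weights))
  expect_true(all(abs(net$weights) < 1))
  expect_equal(net$n, 81)
  st <- attr(net, "stages")
  expect_true(all(c("lambda", "n_zeroed", "n_edges") %in% names(st)))
  # a 6-subject sample must run and return a (possibly empty) network
  tiny <- tab[1:6, ]
  attr(tiny, "variables") <- attr(tab, "variables")
  class(tiny) <- class(tab)
  net_tiny <- estimate_network(tiny)
  expect_s3_class(net_tiny, "network_model")
})
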