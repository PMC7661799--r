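test_that("bootstrap with B = 1 reproduces a single profile and seeds repeat", {
  tab <- toy_table(n = 50, seed = 3)
  bs1 <- bootstrap_networks(tab, B = 1, seed = 4)
  expect_equal(bs1$B, 1L)
  for (m in c("strength", "betweenness", "closeness")) {
    expect_equal(nrow(bs1$values[[m]]), 1)
    expect_equal(unname(bs1$mean[[m]]), unname(bs1$values[[m]][1, ]))
  }
  bs2 <- bootstrap_networks(tab, B = 5, seed = 8)
  bs3 <- bootstrap_networks(tab, B = 5, seed = 8)
  expect_identical(bs2, bs3)
  bs4 <- bootstrap_networks(tab, B = 5, seed = 9)
  expect_false(identical(bs2, bs4))
})

test_that("bootstrap summaries equal statistics of the stored replicates", {
  tab <- toy_table(n = 50, seed = 5)
  bs <- bootstrap_networks(tab, B = 12, seed = 2)
  for (m in c("strength", "betweenness", "closeness")) {
    expect_equal(bs$mean[[m]], colMeans(bs$values[[m]]), tolerance = 1e-12)
    expect_equal(bs$sd[[m]], apply(bs$values[[m]], 2, sd), tolerance = 1e-12)
    expect_true(all(bs$sd[[m]] >= 0))
  }
  tab2 <- toy_table(10, 6); tab2$group <- "H"
  comb <- mixedggm:::measure_table(rbind(as.data.frame(tab),
                                         as.data.frame(tab2)),
                                   attr(tab, "variables"))
  expect_error(bootstrap_networks(comb, B = 2, seed = 1), "single-group")
})

test_that("bootstrap means track the full-sample centralities", {
  specs <- asd_td_specs()
  tab <- generate_group_sample(specs$td, seed = 12)
  prof <- centrality_profile(estimate_network(tab))
  bs <- bootstrap_networks(tab, B = 60, seed = 13)
  within <- abs(bs$mean$strength - prof$strength) <= 2 * bs$sd$strength
  expect_gte(sum(within), 9)   # at least 9 of 11 nodes
  expect_equal(bs$failures >= 0, TRUE)
})

test_that("z statistics follow the quadrature formula in both conventions", {
  make_bs <- function(mean_s, sd_s, B = 100) {
    structure(list(group = "G", B = as.integer(B), nodes = c("n1", "n2"),
                   values = NULL,
                   mean = list(strength = c(n1 = mean_s, n2 = 1),
                               betweenness = c(n1 = 0, n2 = 0),
                               closeness = c(n1 = 0.5, n2 = 0.5)),
                   sd = list(strength = c(n1 = sd_s, n2 = 1),
                             betweenness = c(n1 = 0, n2 = 0),
                             closeness = c(n1 = 0.1, n2 = 0.1)),
                   failures = 0L),
              class = "bootstrap_result")
  }
  a <- make_bs(5, 1); b <- make_bs(3, 1)
  rep_sd <- centrality_z_test(a, b)
  z_n1 <- rep_sd$z[rep_sd$node == "n1" & rep_sd$metric == "strength"]
  expect_equal(z_n1, sqrt(2), tolerance = 1e-12)
  # identical distributions give z = 0 and no flags
  rep0 <- centrality_z_test(a, a)
  expect_true(all(rep0$z == 0, na.rm = TRUE))
  expect_false(any(rep0$significant, na.rm = TRUE))
  # zero-SD cells are excluded from the family size m
  expect_true(all(is.na(rep_sd$z[rep_sd$metric == "betweenness"])))
  expect_equal(attr(rep_sd, "m"), 4)
  # the se convention scales z by sqrt(B/2 * 2) relative to sd quadrature
  rep_se <- centrality_z_test(a, b, denominator = "se")
  z_se <- rep_se$z[rep_se$node == "n1" & rep_se$metric == "strength"]
  expect_equal(z_se, sqrt(2) * sqrt(100), tolerance = 1e-12)
})

test_that("bonferroni flags use alpha / m", {
  expect_identical(bonferroni(numeric(0)), logical(0))
  p <- c(0.001, rep(0.5, 32))
  flags <- bonferroni(p)            # m = 33, cutoff ~ 0.001515
  expect_true(flags[1])
  expect_false(any(flags[-1]))
  p2 <- c(0.01, rep(0.5, 32))
  expect_false(any(bonferroni(p2)))  # 0.01 > 0.05 / 33
  expect_true(bonferroni(0.05))      # m = 1 reduces to p <= alpha
  expect_false(bonferroni(0.051))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("descriptive tests dispatch on kind and handle degeneracy", {
  tab_a <- toy_table(n = 40, seed = 21)
  tab_b <- toy_table(n = 45, seed = 22)
  out <- descriptive_tests(tab_a, tab_b)
  expect_equal(out$test, c("mann-whitney", "mann-whitney", "t"))
  expect_true(all(out$p >= 0 & out$p <= 1, na.rm = TRUE))
  # identical samples: t = 0 and U = n_a n_b / 2, p ~ 1
  out_same <- descriptive_tests(tab_a, tab_a)
  expect_equal(out_same$statistic[out_same$test == "t"], 0, tolerance = 1e-12)
  expect_equal(out_same$statistic[1], 40 * 40 / 2)
  expect_true(all(out_same$p > 0.9))
  # full separation: U = 0
  sep_a <- tab_a; sep_a$ord_a <- rep(0:1, 20)
  sep_b <- tab_b; sep_b$ord_a <- rep(2:3, length.out = 45)
  out_sep <- descriptive_tests(sep_a, sep_b)
  expect_equal(out_sep$statistic[1], 0)
  expect_lt(out_sep$p[1], 1e-10)
  # zero variance in both groups must not crash the t test
  dg_a <- tab_a; dg_a$cont_a <- 0
  dg_b <- tab_b; dg_b$cont_a <- 1
  out_dg <- descriptive_tests(dg_a, dg_b)
  expect_true(is.na(out_dg$statistic[3]) || is.finite(out_dg$statistic[3]))
})

test_that("student t is the default with welch behind the flag", {
  tab_a <- toy_table(n = 30, seed = 31)
  tab_b <- toy_table(n = 35, seed = 32)
  t_pooled <- t.test(tab_a$cont_a, tab_b$cont_a, var.equal = TRUE)$statistic
  t_welch <- t.test(tab_a$cont_a, tab_b$cont_a)$statistic
  expect_equal(descriptive_tests(tab_a, tab_b)$statistic[3],
               unname(t_pooled))
  expect_equal(descriptive_tests(tab_a, tab_b, welch = TRUE)$statistic[3],
               unname(t_welch))
})

test_that("group difference points the measured way on the reference design", {
  # TD-like networks are denser and stronger than ASD-like ones by
  # construction; the strength difference for the encoding node must be
  # positive (TD minus ASD) with the z sign to match
  specs <- asd_td_specs()
  ta <- generate_group_sample(specs$td, seed = 41)
  tb <- generate_group_sample(specs$asd, seed = 42)
  ba <- bootstrap_networks(ta, B = 40, seed = 43)
  bb <- bootstrap_networks(tb, B = 40, seed = 44)
  rep <- centrality_z_test(ba, bb)
  z_es <- rep$z[rep$node == "E-SIPI" & rep$metric == "strength"]
  expect_gt(z_es, 0)
})
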