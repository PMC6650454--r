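test_that("degenerate permutation cases behave as required", {
  vals <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  # group = pool: observed equals the pool mean, p = 1
  r <- permutation_null(vals, names(vals), B = 200, seed = 1)
  expect_equal(r$observed_mean, mean(vals))
  expect_equal(r$expected_mean, mean(vals))
  expect_equal(r$p_two_tailed, 1)
  # constant statistic: zero-width interval, p = 1
  cvals <- setNames(rep(2.5, 40), sprintf("g%02d", 1:40))
  rc <- permutation_null(cvals, sprintf("g%02d", 1:10), B = 200, seed = 1)
  expect_equal(rc$expected_mean, 2.5)
  expect_equal(rc$ci_low, rc$ci_high)
  expect_equal(rc$p_two_tailed, 1)
  expect_error(permutation_null(vals, names(vals)[1:5], B = 50), "at least 100")
  expect_error(permutation_null(vals, "nope", B = 200), "absent")
})

test_that("permutation p floors at 1/B and results are seed-reproducible", {
  set.seed(61)
  vals <- setNames(c(rep(100, 10), rnorm(190)), sprintf("g%03d", 1:200))
  r <- permutation_null(vals, sprintf("g%03d", 1:10), B = 500, seed = 9)
  expect_equal(r$p_two_tailed, 1 / 500)
  r2 <- permutation_null(vals, sprintf("g%03d", 1:10), B = 500, seed = 9)
  expect_identical(r, r2)
})

test_that("null groups give calibrated uniform p-values", {
  set.seed(62)
  vals <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  ps <- replicate(200, {
    grp <- sample(names(vals), 30)
    permutation_null(vals, grp, B = 200)$p_two_tailed
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  expect_gte(mean(ps <= 0.05), 0.03 - 0.015)
  expect_lte(mean(ps <= 0.05), 0.07 + 0.015)
})

test_that("enrichment null equals the hypergeometric distribution", {
  set.seed(63)
  flags <- setNames(rep(c(TRUE, FALSE), c(15, 45)), sprintf("g%02d", 1:60))
  grp <- sprintf("g%02d", seq(1, 60, by = 3))   # 20 genes
  r <- categorical_enrichment(flags, grp, B = 10000, seed = 3)
  # compare the enrichment null CDF against Hypergeometric(60, 15, 20)
  ks <- seq(0, 15)
  emp <- vapply(ks, function(k) mean(r$null <= k), 0)
  theo <- stats::phyper(ks, 15, 45, 20)
  expect_lt(max(abs(emp - theo)), 0.02)
  expect_true(r$counts)
  expect_equal(r$N, 20L)
})

test_that("feature held by the whole pool or by nobody gives p = 1", {
  flags_all <- setNames(rep(TRUE, 30), sprintf("g%02d", 1:30))
  r <- categorical_enrichment(flags_all, sprintf("g%02d", 1:10), B = 200)
  expect_equal(r$observed_mean, 10)
  expect_equal(r$expected_mean, 10)
  expect_equal(r$p_two_tailed, 1)
  flags_none <- setNames(rep(FALSE, 30), sprintf("g%02d", 1:30))
  r0 <- categorical_enrichment(flags_none, sprintf("g%02d", 1:10), B = 200)
  expect_equal(r0$observed_mean, 0)
  expect_equal(r0$p_two_tailed, 1)
})

test_that("covariate adjustment is near-identity when covariates are inert", {
  set.seed(64)
  n <- 2000
  ids <- sprintf("g%04d", 1:n)
  vals <- setNames(rnorm(n), ids)
  len <- setNames(runif(n, 300, 3000), ids)
  ex <- setNames(rlnorm(n, 3), ids)
  adj <- covariate_adjust(vals, len, ex)
  expect_gt(cor(adj, vals[names(adj)]), 0.99)
  # bottom length quartile removed
  expect_equal(length(adj), sum(len >= quantile(len, 0.25)))
})

test_that("covariate adjustment absorbs an exact linear dependence", {
  set.seed(65)
  ids <- sprintf("g%03d", 1:200)
  len <- setNames(runif(200, 300, 3000), ids)
  ex <- setNames(rlnorm(200, 3), ids)
  vals <- setNames(0.002 * len, ids)
  adj <- covariate_adjust(vals, len, ex)
  expect_lt(stats::var(adj), 1e-12 * stats::var(vals))
  # constant covariates: identity after intercept (up to the length filter)
  cl <- setNames(rep(1000, 200), ids)
  ce <- setNames(rep(5, 200), ids)
  v2 <- setNames(rnorm(200), ids)
  adj2 <- suppressWarnings(covariate_adjust(v2, cl, ce,
                                            drop_length_quartile = FALSE))
  expect_equal(unname(adj2), unname(v2), tolerance = 1e-9)
})

test_that("BH step-up matches hand-evaluated q-values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.001, 0.5, 0.9, 1.0)), c(0.004, 1, 1, 1),
               tolerance = 1e-12)
  expect_error(bh_fdr(c(0, 0.5)), "p values")
})

test_that("ISE correlation test recovers self-correlation and refuses bad input", {
  set.seed(66)
  ids <- sprintf("g%03d", 1:100)
  ise <- setNames(runif(100), ids)
  r <- ise_correlation_test(ise, ise, B = 400, seed = 2)
  expect_equal(r$r, 1)
  expect_equal(r$p_value, 1 / 401)
  expect_error(ise_correlation_test(ise[1:5], ise[1:5], B = 400), "10 complete")
  expect_error(ise_correlation_test(ise, setNames(rep(1, 100), ids), B = 400),
               "constant")
  # sociality genes are excluded before correlating
  vals <- setNames(rnorm(100), ids)
  vals[1:40] <- 50
  r2 <- ise_correlation_test(ise, vals, sociality = ids[1:40], B = 400,
                             seed = 2)
  expect_equal(r2$n, 60)
})

test_that("independent values give calibrated correlation rejection rates", {
  set.seed(67)
  ids <- sprintf("g%03d", 1:80)
  ps <- replicate(200, {
    ise <- setNames(runif(80), ids)
    vals <- setNames(rnorm(80), ids)
    ise_correlation_test(ise, vals, B = 99)$p_value
  })
  rej <- mean(ps <= 0.05)
  expect_gte(rej, 0.015)
  expect_lte(rej, 0.085)
})
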