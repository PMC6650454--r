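test_that("mixture line interpolates the pool means", {
  expect_equal(mixture_line(0, 3, 7), 7)
  expect_equal(mixture_line(1, 3, 7), 3)
  expect_equal(mixture_line(0.5, 3, 7), 5)
  expect_error(mixture_line(1.2, 3, 7))
})

test_that("proportion-matched null collapses to single-pool sampling at k = 0 and k = N", {
  set.seed(71)
  ids <- sprintf("g%03d", 1:300)
  soc <- ids[1:100]
  vals <- setNames(c(rnorm(100, 5), rnorm(200, 0)), ids)
  pure_soc <- proportion_matched_null(vals, soc[1:40], soc, B = 2000, seed = 1)
  expect_equal(pure_soc$k, 40L)
  expect_equal(pure_soc$prop_sociality, 1)
  expect_lt(abs(pure_soc$expected_mean - mean(vals[soc])), 0.1)
  pure_non <- proportion_matched_null(vals, ids[101:140], soc, B = 2000,
                                      seed = 2)
  expect_equal(pure_non$prop_sociality, 0)
  expect_lt(abs(pure_non$expected_mean - mean(vals[ids[101:300]])), 0.1)
  expect_error(proportion_matched_null(vals, "nope", soc, B = 200),
               "no class gene")
})

test_that("proportion-matched null at k = N matches plain permutation over the sociality pool", {
  set.seed(72)
  ids <- sprintf("g%03d", 1:200)
  soc <- ids[1:120]
  vals <- setNames(rnorm(200), ids)
  grp <- soc[1:30]
  a <- proportion_matched_null(vals, grp, soc, B = 3000, seed = 5)
  b <- permutation_null(vals[soc], grp, B = 3000, seed = 6)
  expect_gt(suppressWarnings(stats::ks.test(a$null, b$null)$p.value), 0.01)
  expect_lt(abs(a$expected_mean - mean(vals[soc])), 0.05)
})

test_that("two-point and collinear fits are exact", {
  ids <- sprintf("g%03d", 1:400)
  soc <- ids[1:200]
  vals <- setNames(c(rep(10, 200), rep(2, 200)), ids)
  classes <- list(a = ids[201:260], b = soc[1:60],
                  c = c(soc[61:90], ids[261:290]))
  fit <- weighted_regression(vals, classes, soc, B = 200, seed = 1)
  # class means lie exactly on the mixture line: r^2 = 1, slope = difference
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 8, tolerance = 1e-9)
  expect_equal(fit$intercept, 2, tolerance = 1e-9)
  expect_equal(unname(coef(fit)), c(2, 8), tolerance = 1e-9)
  expect_error(weighted_regression(vals, list(a = soc[1:10], b = soc[11:30],
                                              c = soc[31:60]), soc, B = 200),
               "identical sociality proportion")
})

test_that("mixture line through the whole pool equals the whole-pool mean", {
  set.seed(73)
  ids <- sprintf("g%03d", 1:150)
  soc <- ids[1:60]
  vals <- setNames(rnorm(150), ids)
  prop <- length(soc) / length(ids)
  expect_equal(mixture_line(prop, mean(vals[soc]), mean(vals[setdiff(ids, soc)])),
               mean(vals), tolerance = 1e-12)
})

test_that("structured classes are detected and unstructured ones are not", {
  set.seed(74)
  cfg <- sim_config(n_genes = 500, n_strains = 20, codon_counts = c(50, 150),
                    frac_sociality = 0.3, frac_conditional_other = 0,
                    dilution = 2.5, seed = 11)
  ds <- generate_dataset(cfg)
  stats_df <- compute_gene_stats(ds$cds, ds$variants, ds$mapping)
  vals <- setNames(stats_df$pi_site_cds, stats_df$gene_id)
  soc <- ds$truth$gene_id[ds$truth$class == "sociality"]
  classes <- build_mixture_classes(ds$truth, c(0, 0.25, 0.5, 0.75, 1), 80,
                                   seed = 4)
  fit <- weighted_regression(vals, classes, soc, B = 500, seed = 6)
  expect_gt(fit$r_squared, 0.8)
  expect_lt(fit$p_perm, 0.05)
  # observed class means fall inside the proportion-matched 95% interval
  summaries <- lapply(names(classes), function(cn)
    proportion_matched_null(vals, classes[[cn]], soc, B = 1000,
                            seed = 7, class_name = cn))
  inside <- vapply(summaries, function(s)
    s$observed_mean >= s$ci_low && s$observed_mean <= s$ci_high, TRUE)
  expect_gte(mean(inside), 0.8)
  # no Red King structure: p_perm roughly uniform over replicates
  vals0 <- setNames(rnorm(length(vals)), names(vals))
  p0 <- replicate(30, {
    cls0 <- build_mixture_classes(ds$truth, c(0, 0.25, 0.5, 0.75, 1), 80)
    weighted_regression(vals0, cls0, soc, B = 99)$p_perm
  })
  expect_gt(mean(p0 > 0.05), 0.7)
})

test_that("plot method draws without error", {
  ids <- sprintf("g%03d", 1:200)
  soc <- ids[1:100]
  vals <- setNames(c(rnorm(100, 2), rnorm(100)), ids)
  classes <- build_mixture_classes(
    data.frame(gene_id = ids,
               class = rep(c("sociality", "non_sociality"), each = 100)),
    c(0, 0.5, 1), 40, seed = 1)
  fit <- weighted_regression(vals, classes, soc, B = 100, seed = 1)
  summaries <- lapply(classes, proportion_matched_null, values = vals,
                      sociality_genes = soc, B = 200, seed = 1)
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(fit, summaries = summaries))
})
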