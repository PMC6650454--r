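test_that("configuration validation enforces the domain invariants", {
  expect_error(sim_config(n_genes = 0), "at least one gene")
  expect_error(sim_config(10, n_strains = 3), "at least 4")
  expect_error(sim_config(10, dilution = 0.5), "dilution")
  expect_error(sim_config(10, theta_site = 0), "positive")
  expect_error(sim_config(10, frac_sociality = 0.8,
                          frac_conditional_other = 0.4), "exceed 1")
  expect_error(simulate_gene("g", 5, 10, 0.01, 0.01), "at least 10")
})

test_that("identical configuration gives an identical dataset", {
  cfg <- sim_config(n_genes = 20, n_strains = 8, codon_counts = c(30, 60),
                    seed = 99)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$variants, d2$variants)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(d1$mapping, d2$mapping)
})

test_that("frac_sociality = 0 yields no sociality gene and expressed vegetative stages", {
  cfg <- sim_config(n_genes = 30, n_strains = 6, codon_counts = c(20, 40),
                    frac_sociality = 0, frac_conditional_other = 0, seed = 2)
  ds <- generate_dataset(cfg)
  expect_false(any(ds$truth$class == "sociality"))
  veg_cols <- ds$expression$meta$compartment == "vegetative"
  expect_true(all(rowMeans(ds$expression$values[, veg_cols]) > 0))
})

test_that("zero mutation intensity gives an empty variant matrix", {
  set.seed(8)
  sim <- simulate_gene("g", 30, 8, theta_site = 1e-12, divergence = 1e-12)
  expect_equal(length(sim$vm$pos), 0L)
  expect_identical(outgroup_sequence(sim$cds, sim$vm), sim$cds$sequence)
})

test_that("simulated CDS starts with ATG and variants match their classes", {
  set.seed(9)
  sim <- simulate_gene("g", 80, 10, theta_site = 0.03, divergence = 0.05,
                       stop_gain_rate = 1)
  expect_equal(substr(sim$cds$sequence, 1, 3), "ATG")
  # recomputed effect classes agree with the stored ones
  reclass <- vapply(seq_along(sim$vm$pos), function(i)
    classify_variant(sim$cds, sim$vm$pos[i], sim$vm$ref[i], sim$vm$alt[i]), "")
  expect_identical(reclass, sim$vm$site_class)
  expect_true(annotate_stop_gain(sim$vm))
})

test_that("stop_gain_rate = 1 forces a detectable stop gain in every gene", {
  set.seed(10)
  carriers <- vapply(1:30, function(i) {
    sim <- simulate_gene(paste0("g", i), 40, 8, 0.02, 0.02,
                         stop_gain_rate = 1)
    annotate_stop_gain(sim$vm)
  }, TRUE)
  expect_true(all(carriers))
})

test_that("the neutral SFS matches the 1/i expectation at sfs_skew = 0", {
  set.seed(12)
  n <- 10
  counts <- integer(n - 1)
  for (i in 1:400) {
    sim <- simulate_gene(paste0("g", i), 30, n, theta_site = 0.05,
                         divergence = 1e-9, sfs_skew = 0)
    if (!length(sim$vm$pos)) next
    alt <- rowSums(sim$vm$geno == 1L, na.rm = TRUE)
    alt <- alt[alt >= 1 & alt <= n - 1]
    counts <- counts + tabulate(alt, nbins = n - 1)
  }
  expected <- (1 / (1:(n - 1))) / sum(1 / (1:(n - 1)))
  p <- stats::chisq.test(counts, p = expected)$p.value
  expect_gt(p, 0.01)
})

test_that("dilution raises sociality polymorphism above background", {
  set.seed(13)
  wins <- vapply(1:8, function(s) {
    cfg <- sim_config(n_genes = 150, n_strains = 12,
                      codon_counts = c(40, 100), frac_sociality = 0.3,
                      frac_conditional_other = 0, dilution = 2,
                      pav_rate = c(non_sociality = 0, sociality = 0,
                                   conditional_other = 0), seed = 100 + s)
    ds <- generate_dataset(cfg)
    st <- compute_gene_stats(ds$cds, ds$variants, ds$mapping)
    soc <- ds$truth$class == "sociality"
    mean(st$pi_site_cds[soc], na.rm = TRUE) >
      mean(st$pi_site_cds[!soc], na.rm = TRUE)
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("expression truths: sociality ISE = 1, conditional undefined, others mid-range", {
  cfg <- sim_config(n_genes = 300, n_strains = 6, codon_counts = c(20, 30),
                    frac_sociality = 0.2, frac_conditional_other = 0.1,
                    seed = 14)
  ds <- generate_dataset(cfg)
  cls <- classify_gene_sets(ds$expression)
  merged <- merge(cls, ds$truth, by = "gene_id")
  expect_true(all(merged$ise[merged$class.y == "sociality"] == 1))
  expect_true(all(is.na(merged$ise[merged$class.y == "conditional_other"])))
  ns <- merged$ise[merged$class.y == "non_sociality"]
  expect_equal(mean(ns), 0.5, tolerance = 0.05)
  # classification recovers the truth exactly in the noise-free setting
  expect_identical(merged$class.x, merged$class.y)
})

test_that("PAV rates and mapping fractions respect the regime labels", {
  cfg <- sim_config(n_genes = 200, n_strains = 8, codon_counts = c(20, 40),
                    pav_rate = c(non_sociality = 0.3, sociality = 0.3,
                                 conditional_other = 0.3), seed = 15)
  ds <- generate_dataset(cfg)
  pav <- classify_pav(ds$mapping)
  expect_identical(unname(pav$is_pav), ds$truth$is_pav)
  frac <- mean(ds$truth$is_pav)
  ci <- qbinom(c(0.005, 0.995), 200, 0.3) / 200
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})
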