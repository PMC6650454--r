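test_that("MK table assembles fixed and segregating sites correctly", {
  # 5 hand-constructed sites over 4 strains + outgroup:
  #  1: segregating nonsyn (outgroup ref)
  #  2: segregating syn, outgroup carries alt -> still segregating
  #  3: ingroup all ref, outgroup alt, nonsyn -> Dn
  #  4: ingroup all ref, outgroup alt, syn -> Ds
  #  5: outgroup missing -> skipped
  geno <- rbind(c(0L, 1L, 0L, 0L),
                c(1L, 1L, 0L, 0L),
                c(0L, 0L, 0L, 0L),
                c(0L, 0L, 0L, 0L),
                c(0L, 1L, 0L, 0L))
  vm <- vm_from_geno(geno,
                     site_class = c("nonsynonymous", "synonymous",
                                    "nonsynonymous", "synonymous",
                                    "nonsynonymous"),
                     outgroup = c(0L, 1L, 1L, 1L, NA))
  tab <- build_mk_table(vm)
  expect_equal(c(tab$Pn, tab$Ps, tab$Dn, tab$Ds), c(1L, 1L, 1L, 1L))
  expect_equal(tab$skipped, 1L)
})

test_that("ingroup fixed for the alternative allele counts as fixed only if outgroup differs", {
  geno <- matrix(1L, 1, 4)
  vm1 <- vm_from_geno(geno, outgroup = 0L)   # outgroup = ref, ingroup = alt
  expect_equal(build_mk_table(vm1)$Dn, 1L)
  vm2 <- vm_from_geno(geno, outgroup = 1L)   # both alt: no difference
  expect_equal(build_mk_table(vm2)$Dn, 0L)
})

test_that("monomorphic gene with 2 synonymous outgroup differences gives (0,0,0,2)", {
  geno <- matrix(0L, 2, 5)
  vm <- vm_from_geno(geno, site_class = c("synonymous", "synonymous"),
                     outgroup = c(1L, 1L))
  tab <- build_mk_table(vm)
  expect_equal(c(tab$Pn, tab$Ps, tab$Dn, tab$Ds), c(0L, 0L, 0L, 2L))
})

test_that("MK Fisher p equals exhaustive hypergeometric enumeration", {
  expect_equal(mk_test(mk_table(5, 5, 5, 5))$p_value, 1.0)
  expect_equal(mk_test(mk_table(5, 5, 5, 5))$classification, "not_significant")
  r <- mk_test(mk_table(2, 20, 20, 2))
  expect_equal(r$p_value, oracle_fisher_p(20, 2, 2, 20), tolerance = 1e-9)
  expect_equal(r$classification, "positive_selection")
  # zero margin: no information
  r0 <- mk_test(mk_table(0, 0, 3, 1))
  expect_equal(r0$p_value, 1)
  expect_equal(r0$classification, "not_significant")
  set.seed(31)
  for (rep in 1:25) {
    t <- as.integer(rmultinom(1, sample(5:30, 1), rep(0.25, 4)))
    got <- mk_test(mk_table(t[1], t[2], t[3], t[4]))$p_value
    expect_equal(got, oracle_fisher_p(t[3], t[4], t[1], t[2]),
                 tolerance = 1e-9)
  }
})

test_that("MK p is invariant under simultaneous row and column swap", {
  set.seed(32)
  for (rep in 1:10) {
    t <- as.integer(rmultinom(1, 30, rep(0.25, 4))) + 1L
    p1 <- mk_test(mk_table(t[1], t[2], t[3], t[4]))$p_value
    p2 <- mk_test(mk_table(t[2], t[1], t[4], t[3]))$p_value  # swap syn/nonsyn
    p3 <- mk_test(mk_table(t[3], t[4], t[1], t[2]))$p_value  # swap P/D
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_equal(p1, p3, tolerance = 1e-12)
  }
})

test_that("DoS arithmetic, bounds, antisymmetry and domain rules hold", {
  expect_equal(unname(dos(mk_table(2, 2, 2, 2))["dos"]), 0)
  expect_equal(unname(dos(mk_table(1, 4, 4, 1))["dos"]), 0.6)
  expect_true(is.na(dos(mk_table(0, 0, 3, 1))["dos"]))
  expect_true(is.na(dos(mk_table(3, 1, 0, 0))["dos"]))
  set.seed(33)
  for (rep in 1:200) {
    t <- as.integer(rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    d <- dos(mk_table(t[1], t[2], t[3], t[4]))[["dos"]]
    if (is.na(d)) next
    expect_gte(d, -1)
    expect_lte(d, 1)
    swapped <- dos(mk_table(t[3], t[4], t[1], t[2]))[["dos"]]
    expect_equal(d, -swapped, tolerance = 1e-12)
  }
})
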