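make_em <- function(values, hours = NULL) {
  # columns: 2 vegetative conditions x 2 reps, 2 developmental x 2 reps
  labs <- c("veg:c1:r1", "veg:c1:r2", "veg:c2:r1", "veg:c2:r2",
            "dev:h0:r1", "dev:h0:r2", "dev:h4:r1", "dev:h4:r2",
            "dev:h12:r1", "dev:h12:r2")
  meta <- data.frame(
    library = labs,
    compartment = c(rep("vegetative", 6), rep("social", 4)),
    condition = sub(":r[0-9]+$", "", labs),
    hour = c(NA, NA, NA, NA, 0, 0, 4, 4, 12, 12),
    stringsAsFactors = FALSE)
  colnames(values) <- labs
  expr_matrix(values, meta)
}

test_that("ISE is the social share of mean expression, replicates first", {
  v <- matrix(0, 3, 10, dimnames = list(c("soc", "even", "silent"), NULL))
  v["soc", 7:10] <- 7.3               # social only
  v["even", ] <- 5                    # equal everywhere
  em <- make_em(v)
  ise <- compute_ise(em)
  expect_equal(unname(ise["soc"]), 1.0)
  expect_equal(unname(ise["even"]), 0.5)
  expect_true(is.na(ise["silent"]))
  # zero social expression
  v2 <- matrix(0, 1, 10, dimnames = list("veg_only", NULL))
  v2[1, 1:6] <- 2
  expect_equal(unname(compute_ise(make_em(v2))), 0)
})

test_that("replicate averaging precedes condition averaging", {
  # unbalanced replicate values: averaging libraries directly would differ
  v <- matrix(0, 1, 10, dimnames = list("g", NULL))
  v[1, c(1, 2)] <- c(10, 0)   # veg:c1 mean 5
  v[1, c(3, 4)] <- c(1, 1)    # veg:c2 mean 1
  v[1, 5:6] <- 0              # dev:h0 (vegetative) mean 0
  v[1, 7:8] <- c(6, 0)        # dev:h4 mean 3
  v[1, 9:10] <- c(3, 3)       # dev:h12 mean 3
  ise <- compute_ise(make_em(v))
  expect_equal(unname(ise), 3 / (2 + 3))   # veg mean (5+1+0)/3, soc mean 3
})

test_that("sociality threshold is strict and conditional genes are separated", {
  v <- matrix(0, 4, 10,
              dimnames = list(c("hi", "boundary", "lo", "silent"), NULL))
  # veg condition means all equal, social all equal: ISE = b / (a + b)
  v["hi", ] <- c(rep(1, 6), rep(19, 4))              # ISE 19/20 = 0.95
  v["boundary", ] <- c(rep(1, 6), rep(9, 4))         # ISE 0.9 exactly
  v["lo", ] <- c(rep(1, 6), rep(1, 4))               # ISE 0.5
  em <- make_em(v)
  cls <- classify_gene_sets(em)
  got <- setNames(cls$class, cls$gene_id)
  expect_equal(unname(got["hi"]), "sociality")
  expect_equal(unname(got["boundary"]), "non_sociality")  # 0.9 excluded
  expect_equal(unname(got["lo"]), "non_sociality")
  expect_equal(unname(got["silent"]), "conditional_other")
  expect_true(is.na(cls$ise[cls$gene_id == "silent"]))
})

test_that("label tables attach membership and warn on unknown ids", {
  v <- matrix(1, 2, 10, dimnames = list(c("a", "b"), NULL))
  em <- make_em(v)
  labs <- list(cheater = data.frame(gene_id = c("a", "zz")))
  expect_warning(cls <- classify_gene_sets(em, labs), "unknown gene id")
  expect_equal(cls$cheater, c(TRUE, FALSE))
})

test_that("cell-type bias averages datasets and thresholds inclusively", {
  ds1 <- list(prestalk = matrix(c(10, 8.5, 5, 0), 4, 1,
                                dimnames = list(c("st", "mid", "eq", "none"))),
              prespore = matrix(c(0, 1.5, 5, 0), 4, 1,
                                dimnames = list(c("st", "mid", "eq", "none"))))
  ds2 <- list(prestalk = matrix(c(10, 7.5, 5, 0), 4, 1,
                                dimnames = list(c("st", "mid", "eq", "none"))),
              prespore = matrix(c(0, 2.5, 5, 0), 4, 1,
                                dimnames = list(c("st", "mid", "eq", "none"))))
  b <- cell_type_bias(list(ds1, ds2))
  expect_equal(b$prestalk_bias[b$gene_id == "st"], 1.0)
  # biases 0.85 and 0.75 average to 0.8: inside the 0.8 set, outside 0.9
  expect_equal(b$prestalk_bias[b$gene_id == "mid"], 0.8)
  expect_true(b$bias_set_0.8[b$gene_id == "mid"])
  expect_false(b$bias_set_0.9[b$gene_id == "mid"])
  expect_false(b$bias_set_0.8[b$gene_id == "eq"])   # bias 0.5
  expect_true(is.na(b$prestalk_bias[b$gene_id == "none"]))
  # complement identity and subset property
  ok <- !is.na(b$prestalk_bias)
  expect_equal(b$prestalk_bias[ok] + b$prespore_bias[ok], rep(1, sum(ok)))
  expect_true(all(!b$bias_set_0.9 | b$bias_set_0.8))
})

test_that("low-expression filter drops the bottom quartile by max expression", {
  set.seed(51)
  v <- matrix(rlnorm(100 * 10), 100, 10,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  em <- make_em(v)
  kept <- filter_low_expression(em, 0.25)
  expect_equal(length(kept), 75)
  summ <- apply(v, 1, max)
  expect_gte(min(summ[kept]), max(summ[setdiff(rownames(v), kept)]))
  expect_equal(length(filter_low_expression(em, 0)), 100)
})

test_that("expression matrix validates labels and hour-0 compartment", {
  v <- matrix(1, 1, 2, dimnames = list("g", c("x", "y")))
  meta_bad <- data.frame(library = c("x", "y"),
                         compartment = c("vegetative", "social"),
                         condition = c("a", "b"), hour = c(0, 0))
  expect_error(expr_matrix(v, meta_bad), "hour-0")
  meta_neg <- data.frame(library = c("x", "y"),
                         compartment = c("vegetative", "odd"),
                         condition = c("a", "b"))
  expect_error(expr_matrix(v, meta_neg), "compartment")
  expect_error(expr_matrix(-v, data.frame(library = c("x", "y"),
                                          compartment = c("vegetative", "social"),
                                          condition = c("a", "b"))),
               "non-negative")
})
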