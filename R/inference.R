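# Randomization framework: class-vs-background expected values, confidence
# intervals, two-tailed permutation p values, categorical enrichment,
# covariate adjustment, FDR, and the ISE-correlation permutation test.

.perm_result <- function(statistic, group, N, observed, means, B, seed,
                         counts = FALSE) {
  ci <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
  n_le <- sum(means <= observed)
  n_ge <- sum(means >= observed)
  p <- max(1 / B, min(1, 2 * min(n_le, n_ge) / B))
  structure(
    list(statistic = statistic, group = group, N = N,
         observed_mean = observed, expected_mean = mean(means),
         ci_low = ci[1], ci_high = ci[2], p_two_tailed = p,
         q_fdr = NA_real_, B = B, seed = seed, counts = counts,
         null = means),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$statistic, " | group ", x$group, " (N = ", x$N, ")\n",
      "  observed ", format(x$observed_mean, digits = 6),
      ", expected ", format(x$expected_mean, digits = 6),
      " [", format(x$ci_low, digits = 6), ", ",
      format(x$ci_high, digits = 6), "]\n",
      "  two-tailed p = ", format(x$p_two_tailed, digits = 4),
      if (!is.na(x$q_fdr)) paste0(", q = ", format(x$q_fdr, digits = 4)) else "",
      "  (B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' Permutation null for a gene-group mean against its background
#'
#' Draws `B` random gene sets of the group's size, without replacement,
#' from the pool formed by the group plus its background, and compares the
#' observed group mean of a per-gene statistic with the resulting null
#' distribution of sample means. Genes with undefined (`NA`) values are
#' excluded before drawing, so every sample mean averages the same number
#' of genes as the observed group.
#'
#' The two-tailed p value is twice the smaller tail count divided by `B`,
#' capped at 1 and floored at `1/B` (a permutation p of exactly zero is
#' never reported).
#'
#' @param values Named numeric vector of the per-gene statistic over the
#'   pool (group plus background); `NA` marks undefined genes.
#' @param group Character vector of gene ids forming the group; must be a
#'   subset of `names(values)`.
#' @param B Number of random draws (default 10000; at least 100).
#' @param seed Optional integer seed for reproducibility.
#' @param statistic Label recorded in the result.
#' @param group_name Label recorded in the result.
#' @return A `perm_test` object with observed and expected means, the
#'   2.5th-97.5th percentile interval, and the two-tailed p value.
#' @export
permutation_null <- function(values, group, B = 10000, seed = NULL,
                             statistic = "statistic", group_name = "group") {
  if (B < 100) stop("B must be at least 100")
  if (!all(group %in% names(values))) stop("group contains ids absent from the pool")
  pool_vals <- values[!is.na(values)]
  grp_vals <- pool_vals[names(pool_vals) %in% group]
  N <- length(grp_vals)
  if (N < 1) stop("no group gene has a defined value")
  if (N > length(pool_vals)) stop("group larger than the defined pool")
  if (!is.null(seed)) set.seed(seed)
  v <- unname(pool_vals)
  np <- length(v)
  means <- vapply(seq_len(B), function(i) mean(v[sample.int(np, N)]), 0)
  .perm_result(statistic, group_name, N, mean(grp_vals), means, B, seed)
}

#' Permutation enrichment of a binary gene feature in a group
#'
#' As [permutation_null()], but the statistic is the count of genes in the
#' drawn set that carry a binary feature (stop-gain SNPs, presence/absence
#' variation, Tajima's D above a threshold, a selection class, a GO-style
#' annotation, ...). The null distribution of counts is hypergeometric by
#' construction (sampling without replacement from a finite pool).
#'
#' @param flags Named logical vector over the pool; `NA` not allowed.
#' @param group Character vector of gene ids forming the group.
#' @inheritParams permutation_null
#' @return A `perm_test` object whose observed/expected values are counts.
#' @export
categorical_enrichment <- function(flags, group, B = 10000, seed = NULL,
                                   statistic = "feature", group_name = "group") {
  if (B < 100) stop("B must be at least 100")
  if (anyNA(flags)) stop("flags must not contain NA")
  if (!all(group %in% names(flags))) stop("group contains ids absent from the pool")
  N <- length(group)
  if (N > length(flags)) stop("group larger than the pool")
  if (!is.null(seed)) set.seed(seed)
  f <- unname(as.logical(flags))
  np <- length(f)
  observed <- sum(flags[group])
  counts <- vapply(seq_len(B), function(i) sum(f[sample.int(np, N)]), 0L)
  .perm_result(statistic, group_name, N, observed, as.numeric(counts), B,
               seed, counts = TRUE)
}

#' Covariate-adjust a per-gene statistic
#'
#' Removes the bottom quartile of mapped CDS lengths (short genes give
#' noisy, downwardly biased statistics), then regresses the statistic on
#' mapped length and maximum expression (linear and quadratic terms each)
#' by ordinary least squares over the whole pool. The adjusted value is
#' the residual plus the pool mean, so adjusted and raw values share their
#' scale. A rank-deficient design drops the offending quadratic term with
#' a warning.
#'
#' @param values Named numeric vector of the statistic (NA allowed).
#' @param length_cov Named numeric vector of mapped CDS lengths.
#' @param maxexpr_cov Named numeric vector of maximum expression levels.
#' @param drop_length_quartile Remove genes in the bottom length quartile
#'   first (default TRUE).
#' @return Named numeric vector of adjusted values over the retained genes
#'   with defined statistic and covariates.
#' @export
covariate_adjust <- function(values, length_cov, maxexpr_cov,
                             drop_length_quartile = TRUE) {
  ids <- names(values)
  if (is.null(ids) || !all(ids %in% names(length_cov)) ||
      !all(ids %in% names(maxexpr_cov)))
    stop("covariates must be available for all genes")
  len <- length_cov[ids]
  ex <- maxexpr_cov[ids]
  keep <- !is.na(values) & !is.na(len) & !is.na(ex)
  if (drop_length_quartile) {
    cut <- stats::quantile(len[keep], 0.25, names = FALSE)
    keep <- keep & len >= cut
  }
  v <- values[keep]; l <- len[keep]; e <- ex[keep]
  df <- data.frame(v = v, l = l, l2 = l^2, e = e, e2 = e^2)
  fit <- stats::lm(v ~ l + l2 + e + e2, data = df)
  if (anyNA(stats::coef(fit)))
    warning("rank-deficient design: dropped term(s) ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  adj <- stats::residuals(fit) + mean(v)
  names(adj) <- names(v)
  adj
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up false-discovery-rate adjustment.
#'
#' @param p Numeric vector of p values in (0, 1].
#' @return Vector of q values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("p values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Correlation between ISE and an evolutionary statistic, by permutation
#'
#' Tests whether, among the non-conditionally expressed genes, the bias of
#' expression towards the social stage predicts an evolutionary statistic.
#' Sociality genes are excluded (their ISE forms a separate categorical
#' class already tested by the group comparisons). ISE values are held
#' fixed and the statistic is randomly permuted; the p value is the
#' add-one-smoothed fraction of permutations with |r| at least the
#' observed |r|.
#'
#' @param ise Named numeric vector of ISE values.
#' @param values Named numeric vector of the statistic.
#' @param sociality Character vector of sociality gene ids to exclude.
#' @param B Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p_value`, `n`, `method`, `B`.
#' @export
ise_correlation_test <- function(ise, values, sociality = character(0),
                                 B = 10000, seed = NULL,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ids <- intersect(names(ise), names(values))
  ids <- setdiff(ids, sociality)
  x <- ise[ids]; y <- values[ids]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("fewer than 10 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant values")
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(x, y, method = method)
  r_perm <- vapply(seq_len(B), function(i)
    stats::cor(x, sample(y), method = method), 0)
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (B + 1)
  list(r = r_obs, p_value = p, n = length(x), method = method, B = B)
}
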