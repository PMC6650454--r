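# Within-species diversity: segregating sites, pi, Tajima's D.

# Per-site summaries on non-missing calls: alt count, call count.
.site_counts <- function(vm) {
  if (length(vm$pos) == 0)
    return(list(alt = integer(0), n = integer(0)))
  alt <- rowSums(vm$geno == 1L, na.rm = TRUE)
  n <- rowSums(!is.na(vm$geno))
  list(alt = alt, n = n)
}

# Unbiased per-site pairwise-difference contribution 2 p (1-p) n/(n-1),
# equal to (#pairs differing)/(#pairs) among non-missing calls.
.pi_contrib <- function(alt, n) {
  h <- ifelse(n >= 2, 2 * (alt / n) * (1 - alt / n) * n / (n - 1), NA_real_)
  h
}

#' Nucleotide diversity and SNP density of one gene
#'
#' Computes the segregating-site count and the average number of pairwise
#' differences over the strains, scaled to the mapped CDS length of the
#' requested site class. Sites with fewer than two non-missing calls are
#' dropped (and the mapped length reduced accordingly). Per-site values use
#' either the gene's exact NG86 synonymous/nonsynonymous site counts
#' (default) or a fixed global class split via `fixed_class_fractions`.
#'
#' @param vm A [variant_matrix()].
#' @param cds The matching [gene_cds()].
#' @param site_class `"cds"` (all sites), `"nonsyn"` (nonsynonymous,
#'   including stop gains) or `"syn"`.
#' @param fixed_class_fractions Optional named vector `c(nonsyn=, syn=)`
#'   replacing the per-gene site counts in the per-site denominator.
#' @return List with `S`, `pi_total`, `pi_per_site`, `snp_per_site`,
#'   `n_eff` (median non-missing call count over counted sites) and
#'   `mapped_class_length`. Per-site values are `NA` when the class has no
#'   mapped length.
#' @export
nucleotide_diversity <- function(vm, cds, site_class = c("cds", "nonsyn", "syn"),
                                 fixed_class_fractions = NULL) {
  site_class <- match.arg(site_class)
  stopifnot(inherits(vm, "variant_matrix"), inherits(cds, "gene_cds"))
  idx <- .class_sites(vm, site_class)
  sc <- .site_counts(vm)
  alt <- sc$alt[idx]; n <- sc$n[idx]
  dropped <- sum(n < 2)
  keep <- n >= 2
  alt <- alt[keep]; n <- n[keep]
  seg <- alt > 0 & alt < n
  S <- sum(seg)
  pi_total <- if (length(alt)) sum(.pi_contrib(alt, n)) else 0
  frac <- .class_fraction(site_class, cds, fixed_class_fractions)
  denom <- max(vm$mapped_cds_length - dropped, 0) * frac
  list(
    S = as.integer(S),
    pi_total = pi_total,
    pi_per_site = if (denom > 0) pi_total / denom else NA_real_,
    snp_per_site = if (denom > 0) S / denom else NA_real_,
    n_eff = if (any(seg)) as.integer(stats::median(n[seg])) else NA_integer_,
    mapped_class_length = denom
  )
}

# Harmonic-number helpers used by the frequency-spectrum statistics.
.a1 <- function(n) sum(1 / seq_len(n - 1))
.a2 <- function(n) sum(1 / seq_len(n - 1)^2)

#' Tajima's D of one gene
#'
#' The standardized difference between the pairwise-diversity and
#' segregating-sites estimators of the population mutation rate, with the
#' constants of the original 1989 estimator. The effective sample size used
#' for the constants is the median non-missing call count across the gene's
#' segregating sites; per-site frequencies always use the site's own
#' non-missing calls.
#'
#' @param vm A [variant_matrix()].
#' @return Tajima's D, or `NA` when undefined (no segregating site, or
#'   fewer than 4 effective strains).
#' @export
tajimas_d <- function(vm) {
  stopifnot(inherits(vm, "variant_matrix"))
  sc <- .site_counts(vm)
  keep <- sc$n >= 2
  alt <- sc$alt[keep]; nn <- sc$n[keep]
  seg <- alt > 0 & alt < nn
  S <- sum(seg)
  if (S < 1) return(NA_real_)
  n <- stats::median(nn[seg])
  if (n < 4) return(NA_real_)
  pi_total <- sum(.pi_contrib(alt[seg], nn[seg]))
  a1 <- .a1(n); a2 <- .a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
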