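# Auxiliary neutrality tests: Fu & Li's D* and F* (without outgroup) and
# Wall's B and Q (linkage-disequilibrium based, on haploid haplotypes).

# Constants for D* and F* with the Simonsen et al. (1995) corrections.
.fu_li_constants <- function(n) {
  a <- .a1(n); b <- .a2(n)
  an1 <- a + 1 / n
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * b - 6 + 8 / n)) / (a^2 + b)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           (2 * (n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / a - vF
  list(a = a, uD = uD, vD = vD, uF = uF, vF = vF)
}

#' Fu and Li's D* and F* of one gene
#'
#' Singleton-based neutrality tests that do not require an outgroup: a
#' singleton is a segregating site whose minor allele is carried by exactly
#' one strain (among its non-missing calls). The effective sample size is
#' the median non-missing call count across segregating sites, as for
#' [tajimas_d()].
#'
#' @param vm A [variant_matrix()].
#' @return Named vector `c(dstar =, fstar =)`; `NA` when undefined
#'   (`S == 0` or fewer than 4 effective strains).
#' @export
fu_li_stats <- function(vm) {
  stopifnot(inherits(vm, "variant_matrix"))
  sc <- .site_counts(vm)
  keep <- sc$n >= 2
  alt <- sc$alt[keep]; nn <- sc$n[keep]
  seg <- alt > 0 & alt < nn
  S <- sum(seg)
  if (S < 1) return(c(dstar = NA_real_, fstar = NA_real_))
  n <- stats::median(nn[seg])
  if (n < 4) return(c(dstar = NA_real_, fstar = NA_real_))
  minor <- pmin(alt[seg], nn[seg] - alt[seg])
  eta_s <- sum(minor == 1)
  pi_total <- sum(.pi_contrib(alt[seg], nn[seg]))
  k <- .fu_li_constants(n)
  dstar <- ((n / (n - 1)) * S - k$a * eta_s) / sqrt(k$uD * S + k$vD * S^2)
  fstar <- (pi_total - ((n - 1) / n) * eta_s) / sqrt(k$uF * S + k$vF * S^2)
  c(dstar = dstar, fstar = fstar)
}

# Canonical bipartition of strains induced by a pair of sites, restricted to
# strains called at both; NULL when fewer than 2 strains or monomorphic.
.pair_partition <- function(g, keep) {
  g <- g[keep]
  if (length(g) < 2 || length(unique(g)) < 2) return(NULL)
  if (g[1] == 1L) g <- 1L - g   # complement-invariant canonical form
  g
}

#' Wall's B and Q of one gene
#'
#' B is the proportion of adjacent segregating-site pairs that induce the
#' same bipartition of the strains (complete linkage between neighbours);
#' Q additionally credits the number of distinct congruent partition types:
#' Q = (B (S-1) + A) / S. Strains with a missing call at either site of a
#' pair are dropped from that pair's comparison.
#'
#' @param vm A [variant_matrix()].
#' @return Named vector `c(wall_b =, wall_q =)`; `NA` when `S < 2`.
#' @export
wall_stats <- function(vm) {
  stopifnot(inherits(vm, "variant_matrix"))
  sc <- .site_counts(vm)
  seg_idx <- which(sc$n >= 2 & sc$alt > 0 & sc$alt < sc$n)
  S <- length(seg_idx)
  if (S < 2) return(c(wall_b = NA_real_, wall_q = NA_real_))
  geno <- vm$geno[seg_idx, , drop = FALSE]
  congruent <- 0L
  types <- character(0)
  for (i in seq_len(S - 1)) {
    gi <- geno[i, ]; gj <- geno[i + 1, ]
    keep <- !is.na(gi) & !is.na(gj)
    pi_ <- .pair_partition(gi, keep)
    pj <- .pair_partition(gj, keep)
    if (is.null(pi_) || is.null(pj)) next
    if (identical(pi_, pj)) {
      congruent <- congruent + 1L
      # encode the partition on the full strain vector (NA where uncalled)
      full <- rep(NA_integer_, length(gi))
      full[keep] <- pi_
      types <- c(types, paste(full, collapse = ""))
    }
  }
  B <- congruent / (S - 1)
  A <- length(unique(types))
  c(wall_b = B, wall_q = (congruent + A) / S)
}

#' All auxiliary neutrality tests of one gene
#'
#' @param vm A [variant_matrix()].
#' @return Named vector with `tajima_d`, `fu_li_dstar`, `fu_li_fstar`,
#'   `wall_b`, `wall_q`; undefined values are `NA`, never zero-filled.
#' @export
neutrality_tests <- function(vm) {
  fl <- fu_li_stats(vm)
  wl <- wall_stats(vm)
  c(tajima_d = tajimas_d(vm),
    fu_li_dstar = unname(fl["dstar"]), fu_li_fstar = unname(fl["fstar"]),
    wall_b = unname(wl["wall_b"]), wall_q = unname(wl["wall_q"]))
}

#' Stop-gain carrier status of one gene
#'
#' `TRUE` when the gene has at least one stop-introducing SNP whose
#' alternative allele is carried by at least one strain.
#'
#' @param vm A [variant_matrix()].
#' @return Logical scalar.
#' @export
annotate_stop_gain <- function(vm) {
  stopifnot(inherits(vm, "variant_matrix"))
  idx <- which(vm$site_class == "stop_gained")
  if (!length(idx)) return(FALSE)
  any(rowSums(vm$geno[idx, , drop = FALSE] == 1L, na.rm = TRUE) > 0)
}

#' Presence/absence-variation flag from mapping fractions
#'
#' A gene whose mean per-strain mapping fraction is at or below the
#' threshold is flagged as carrying a presence/absence variant (partial or
#' complete deletion in part of the panel); the boundary is inclusive.
#' PAV genes are excluded from diversity and neutrality statistics and
#' analysed only through categorical enrichment.
#'
#' @param mapping Numeric matrix genes x strains of mapping fractions in
#'   \[0, 1\], with gene ids as row names.
#' @param threshold Mean-mapping cutoff (default 0.5).
#' @return Data frame with `gene_id`, `mean_mapping`, `is_pav`.
#' @export
classify_pav <- function(mapping, threshold = 0.5) {
  if (is.null(dim(mapping))) mapping <- matrix(mapping, nrow = 1)
  if (any(mapping < 0 | mapping > 1, na.rm = TRUE))
    stop("mapping fractions must lie in [0, 1]")
  mm <- rowMeans(mapping, na.rm = TRUE)
  data.frame(gene_id = rownames(mapping) %||% as.character(seq_along(mm)),
             mean_mapping = unname(mm),
             is_pav = unname(mm <= threshold),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
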