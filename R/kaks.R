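# Pairwise Ka/Ks by the Nei-Gojobori (NG86) counting method with
# Jukes-Cantor correction.

# Average synonymous/nonsynonymous difference counts between two codons,
# averaging equally over minimal mutational pathways. Pathways passing
# through a stop codon are excluded unless every pathway does.
.codon_pair_diffs <- function(c1, c2) {
  aa <- .codon_aa()
  n1 <- strsplit(c1, "")[[1]]; n2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(n1 != n2)
  k <- length(diff_pos)
  if (k == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (k == 1) list(diff_pos)
           else if (k == 2) list(diff_pos, rev(diff_pos))
           else list(diff_pos[c(1,2,3)], diff_pos[c(1,3,2)], diff_pos[c(2,1,3)],
                     diff_pos[c(2,3,1)], diff_pos[c(3,1,2)], diff_pos[c(3,2,1)])
  walk <- function(order, allow_stop) {
    cur <- n1
    sd <- 0; nd <- 0
    for (p in order) {
      prev <- paste(cur, collapse = "")
      cur[p] <- n2[p]
      nxt <- paste(cur, collapse = "")
      if (!allow_stop && nxt != c2 && aa[nxt] == "*") return(NULL)
      if (aa[prev] == aa[nxt] && aa[nxt] != "*") sd <- sd + 1 else nd <- nd + 1
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (!length(res)) res <- lapply(perms, walk, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

# Lazily cached lookup of pair differences for all 64 x 64 codon pairs.
.pair_diff_tables <- function() {
  if (!is.null(.redking_env$pair_syn)) {
    return(list(syn = .redking_env$pair_syn, nonsyn = .redking_env$pair_nonsyn))
  }
  codons <- .all_codons()
  syn <- matrix(0, 64, 64, dimnames = list(codons, codons))
  nonsyn <- syn
  for (i in seq_along(codons)) {
    for (j in seq_along(codons)) {
      if (i == j) next
      d <- .codon_pair_diffs(codons[i], codons[j])
      syn[i, j] <- d[["syn"]]
      nonsyn[i, j] <- d[["nonsyn"]]
    }
  }
  .redking_env$pair_syn <- syn
  .redking_env$pair_nonsyn <- nonsyn
  list(syn = syn, nonsyn = nonsyn)
}

.jc_correct <- function(p) {
  x <- 1 - 4 * p / 3
  if (x <= 0) return(NA_real_)
  -0.75 * log(x)
}

#' Pairwise Ka and Ks between two codon-aligned coding sequences
#'
#' NG86 counting: synonymous and nonsynonymous site totals are averaged over
#' the two sequences; differences within each codon pair are averaged
#' equally over minimal mutational pathways (pathways through stop codons
#' excluded when avoidable); per-class proportions are corrected for
#' multiple hits with the Jukes-Cantor formula d = -(3/4) ln(1 - (4/3) p).
#' The ratio is undefined when `Ks` is 0 or a correction diverges
#' (saturated sites).
#'
#' @param cds_ref A [gene_cds()] (the ingroup reference sequence).
#' @param outgroup_seq DNA string of the same length, codon-aligned
#'   (substitution-only alignment).
#' @param method Counting method; only `"ng86"` is implemented.
#' @return List with `Ka`, `Ks`, `ratio` (each `NA` when undefined) and the
#'   underlying counts `N_sites`, `S_sites`, `N_diff`, `S_diff`.
#' @export
kaks <- function(cds_ref, outgroup_seq, method = c("ng86")) {
  method <- match.arg(method)
  stopifnot(inherits(cds_ref, "gene_cds"))
  outgroup_seq <- toupper(as.character(outgroup_seq))
  if (nchar(outgroup_seq) != cds_ref$length)
    stop("sequences differ in length; codon alignment required")
  out <- tryCatch(gene_cds(cds_ref$gene_id, outgroup_seq),
                  error = function(e) stop("outgroup sequence invalid: ",
                                           conditionMessage(e)))
  L <- cds_ref$length
  starts <- seq(1, L, 3)
  cod1 <- substring(cds_ref$sequence, starts, starts + 2)
  cod2 <- substring(out$sequence, starts, starts + 2)
  S_sites <- (sum(cds_ref$site_weights) + sum(out$site_weights)) / 2
  N_sites <- L - S_sites
  tabs <- .pair_diff_tables()
  idx <- cbind(match(cod1, .all_codons()), match(cod2, .all_codons()))
  S_diff <- sum(tabs$syn[idx])
  N_diff <- sum(tabs$nonsyn[idx])
  pS <- if (S_sites > 0) S_diff / S_sites else NA_real_
  pN <- if (N_sites > 0) N_diff / N_sites else NA_real_
  Ks <- if (is.na(pS)) NA_real_ else .jc_correct(pS)
  Ka <- if (is.na(pN)) NA_real_ else .jc_correct(pN)
  ratio <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  list(Ka = Ka, Ks = Ks, ratio = ratio,
       N_sites = N_sites, S_sites = S_sites,
       N_diff = N_diff, S_diff = S_diff)
}

#' Reconstruct the outgroup coding sequence implied by a variant matrix
#'
#' Applies the outgroup's alternative alleles to the reference CDS at every
#' site where the outgroup carries the alternative.
#'
#' @param cds A [gene_cds()].
#' @param vm The matching [variant_matrix()].
#' @return DNA string of the outgroup CDS.
#' @export
outgroup_sequence <- function(cds, vm) {
  stopifnot(inherits(cds, "gene_cds"), inherits(vm, "variant_matrix"))
  s <- strsplit(cds$sequence, "")[[1]]
  idx <- which(!is.na(vm$outgroup) & vm$outgroup == 1L)
  s[vm$pos[idx]] <- vm$alt[idx]
  paste(s, collapse = "")
}
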