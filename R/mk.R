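# Outgroup-based contingency statistics: McDonald-Kreitman table and test,
# and the Direction of Selection statistic.

#' Build the McDonald-Kreitman table of one gene
#'
#' Counts segregating (P) and fixed (D) differences, split into
#' nonsynonymous and synonymous classes (stop gains count as
#' nonsynonymous). A site is *fixed* when all non-missing ingroup calls
#' share one allele and the outgroup carries the other; *segregating* when
#' both alleles are present in the ingroup (the outgroup state is then
#' irrelevant). Sites without an outgroup call are skipped and counted.
#'
#' @param vm A [variant_matrix()] with its `outgroup` slot populated.
#' @return List of class `mk_table` with `Pn`, `Ps`, `Dn`, `Ds` and
#'   `skipped` (sites lacking an outgroup call).
#' @export
build_mk_table <- function(vm) {
  stopifnot(inherits(vm, "variant_matrix"))
  tab <- c(Pn = 0L, Ps = 0L, Dn = 0L, Ds = 0L)
  skipped <- 0L
  if (length(vm$pos)) {
    sc <- .site_counts(vm)
    nonsyn <- vm$site_class %in% c("nonsynonymous", "stop_gained")
    for (i in seq_along(vm$pos)) {
      if (is.na(vm$outgroup[i])) { skipped <- skipped + 1L; next }
      if (sc$n[i] < 1) { skipped <- skipped + 1L; next }
      seg <- sc$alt[i] > 0 && sc$alt[i] < sc$n[i]
      if (seg) {
        cell <- if (nonsyn[i]) "Pn" else "Ps"
        tab[cell] <- tab[cell] + 1L
      } else {
        ingroup_allele <- if (sc$alt[i] == sc$n[i]) 1L else 0L
        if (ingroup_allele != vm$outgroup[i]) {
          cell <- if (nonsyn[i]) "Dn" else "Ds"
          tab[cell] <- tab[cell] + 1L
        }
      }
    }
  }
  structure(list(Pn = tab[["Pn"]], Ps = tab[["Ps"]],
                 Dn = tab[["Dn"]], Ds = tab[["Ds"]], skipped = skipped),
            class = "mk_table")
}

#' Construct a McDonald-Kreitman table directly from counts
#' @param Pn,Ps Segregating nonsynonymous/synonymous counts.
#' @param Dn,Ds Fixed nonsynonymous/synonymous counts vs the outgroup.
#' @return An `mk_table`.
#' @export
mk_table <- function(Pn, Ps, Dn, Ds) {
  stopifnot(Pn >= 0, Ps >= 0, Dn >= 0, Ds >= 0)
  structure(list(Pn = as.integer(Pn), Ps = as.integer(Ps),
                 Dn = as.integer(Dn), Ds = as.integer(Ds), skipped = 0L),
            class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  m <- matrix(c(x$Dn, x$Ds, x$Pn, x$Ps), 2, 2, byrow = TRUE,
              dimnames = list(c("fixed", "segregating"),
                              c("nonsyn", "syn")))
  print(m)
  invisible(x)
}

#' McDonald-Kreitman test
#'
#' Two-sided Fisher exact test on the 2x2 table \[\[Dn, Ds\], \[Pn, Ps\]\].
#' A table with a zero margin carries no information about the association
#' and is reported as `p = 1`, `not_significant`. The classification is
#' `positive_selection` when significant with an excess of fixed
#' nonsynonymous differences (Dn/Ds > Pn/Ps), `excess_polymorphism` when
#' significant in the other direction.
#'
#' @param tab An `mk_table`.
#' @param alpha Significance level applied to `p_value` (a pipeline-level
#'   FDR step normally precedes interpretation).
#' @return List with `table`, `p_value`, `classification`.
#' @export
mk_test <- function(tab, alpha = 0.05) {
  stopifnot(inherits(tab, "mk_table"))
  m <- matrix(c(tab$Dn, tab$Ds, tab$Pn, tab$Ps), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(table = tab, p_value = 1, classification = "not_significant"))
  }
  p <- stats::fisher.test(m)$p.value
  cls <- "not_significant"
  if (p < alpha) {
    if (tab$Dn * tab$Ps > tab$Pn * tab$Ds) cls <- "positive_selection"
    else if (tab$Dn * tab$Ps < tab$Pn * tab$Ds) cls <- "excess_polymorphism"
  }
  list(table = tab, p_value = p, classification = cls)
}

#' Direction of Selection statistic
#'
#' DoS = Dn/(Dn + Ds) - Pn/(Pn + Ps): zero under neutrality, positive with
#' an excess of adaptive substitution, negative with segregating slightly
#' deleterious variation or balancing selection. Undefined (and excluded
#' from group means) unless both the fixed and the segregating margin are
#' positive.
#'
#' @param tab An `mk_table`.
#' @return Named vector `c(dos =, d_component =, p_component =)`; all `NA`
#'   when undefined.
#' @export
dos <- function(tab) {
  stopifnot(inherits(tab, "mk_table"))
  Dtot <- tab$Dn + tab$Ds
  Ptot <- tab$Pn + tab$Ps
  if (Dtot == 0 || Ptot == 0)
    return(c(dos = NA_real_, d_component = NA_real_, p_component = NA_real_))
  dcomp <- tab$Dn / Dtot
  pcomp <- tab$Pn / Ptot
  c(dos = dcomp - pcomp, d_component = dcomp, p_component = pcomp)
}
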