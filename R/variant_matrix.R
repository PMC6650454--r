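# Per-gene biallelic SNP matrix over haploid strains, plus the outgroup allele.

#' Construct a per-gene variant matrix
#'
#' Holds the biallelic SNPs of one gene over a panel of haploid strains.
#' Genotypes are coded 0 (reference), 1 (alternative) or `NA` (missing call);
#' one call per strain per site. The outgroup is carried as a separate
#' per-site allele so that fixed differences can be counted alongside
#' polymorphism.
#'
#' @param gene_id Gene identifier.
#' @param pos Integer vector of strictly increasing 1-based CDS positions.
#' @param ref,alt Reference and alternative alleles (single bases).
#' @param geno Integer matrix, sites x strains, values in \{0, 1, NA\}.
#' @param site_class Character vector: `"synonymous"`, `"nonsynonymous"` or
#'   `"stop_gained"` per site (as from [classify_variant()]).
#' @param mapped_cds_length Number of CDS positions passing mapping filters;
#'   defaults to the CDS length implied by `cds_length`.
#' @param outgroup Integer vector per site: 0 (reference allele), 1
#'   (alternative) or `NA` (no outgroup call).
#' @param cds_length Total CDS length (used for validation and per-site
#'   scaling).
#' @return An object of class `variant_matrix`.
#' @export
variant_matrix <- function(gene_id, pos, ref, alt, geno, site_class,
                           cds_length, mapped_cds_length = cds_length,
                           outgroup = rep(NA_integer_, length(pos))) {
  pos <- as.integer(pos)
  n_sites <- length(pos)
  dn <- dimnames(geno)
  nc <- if (!is.null(dim(geno))) ncol(geno)
        else if (n_sites > 0) length(geno) %/% n_sites else 0L
  geno <- matrix(as.integer(geno), nrow = n_sites, ncol = nc)
  if (!is.null(dn)) dimnames(geno) <- list(NULL, dn[[2]])
  if (n_sites > 0) {
    if (is.unsorted(pos, strictly = TRUE)) stop("positions must be strictly increasing")
    if (any(pos < 1L) || any(pos > cds_length)) stop("site position outside the CDS")
    if (length(ref) != n_sites || length(alt) != n_sites ||
        length(site_class) != n_sites || length(outgroup) != n_sites)
      stop("per-site fields have inconsistent lengths")
    if (any(ref == alt)) stop("alt allele equal to reference")
    if (!all(geno %in% c(0L, 1L, NA_integer_))) stop("genotypes must be 0, 1 or NA")
    if (!all(site_class %in% c("synonymous", "nonsynonymous", "stop_gained")))
      stop("unknown site class")
  }
  if (mapped_cds_length > cds_length) stop("mapped length exceeds CDS length")
  structure(
    list(gene_id = gene_id, pos = pos, ref = as.character(ref),
         alt = as.character(alt), geno = geno,
         site_class = as.character(site_class),
         cds_length = as.integer(cds_length),
         mapped_cds_length = as.integer(mapped_cds_length),
         outgroup = as.integer(outgroup)),
    class = "variant_matrix"
  )
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat("<variant_matrix> ", x$gene_id, ": ", length(x$pos), " sites x ",
      ncol(x$geno), " strains (mapped ", x$mapped_cds_length, "/",
      x$cds_length, " nt)\n", sep = "")
  invisible(x)
}

# Indices of sites belonging to a site-class selection. Stop-gain variants
# change the protein, so they are counted with the nonsynonymous class.
.class_sites <- function(vm, site_class = c("cds", "nonsyn", "syn")) {
  site_class <- match.arg(site_class)
  switch(site_class,
    cds = seq_along(vm$pos),
    nonsyn = which(vm$site_class %in% c("nonsynonymous", "stop_gained")),
    syn = which(vm$site_class == "synonymous")
  )
}

# Fraction of the mapped length belonging to a site class: per-gene exact
# NG86 site counts by default, or a fixed global split (e.g. c(nonsyn = 0.78,
# syn = 0.22)) mirroring a genome-wide average.
.class_fraction <- function(site_class, cds, fixed = NULL) {
  if (site_class == "cds") return(1)
  if (!is.null(fixed)) {
    if (!all(c("nonsyn", "syn") %in% names(fixed)))
      stop("fixed class fractions need names 'nonsyn' and 'syn'")
    return(unname(fixed[site_class]))
  }
  sc <- site_counts(cds)
  unname(sc[site_class] / cds$length)
}
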