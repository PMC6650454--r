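# Codon-level site classification (NG86 convention, standard nuclear code).

.redking_env <- new.env(parent = emptyenv())

.bases <- c("A", "C", "G", "T")

#' @importFrom Biostrings GENETIC_CODE
.codon_aa <- function() {
  if (is.null(.redking_env$codon_aa)) {
    gc <- Biostrings::GENETIC_CODE
    .redking_env$codon_aa <- setNames(as.character(gc), names(gc))
  }
  .redking_env$codon_aa
}

.all_codons <- function() names(.codon_aa())

.stop_codons <- function() names(which(.codon_aa() == "*"))

#' Per-position synonymous-site fractions of every codon
#'
#' For each codon and each of its three positions, the fraction of the three
#' possible single-nucleotide changes that preserve the encoded amino acid.
#' Changes to or from a stop codon never preserve the amino acid, so they
#' count as nonsynonymous; the three fractions therefore partition each codon
#' into synonymous and nonsynonymous site counts that sum exactly to 3.
#'
#' @return A 64 x 3 numeric matrix with codons as row names.
#' @keywords internal
.codon_syn_fraction <- function() {
  if (!is.null(.redking_env$syn_frac)) return(.redking_env$syn_frac)
  aa <- .codon_aa()
  codons <- names(aa)
  m <- matrix(0, nrow = 64, ncol = 3, dimnames = list(codons, NULL))
  for (cdn in codons) {
    nt <- strsplit(cdn, "")[[1]]
    for (j in 1:3) {
      alts <- setdiff(.bases, nt[j])
      nsyn <- 0
      for (b in alts) {
        mut <- nt
        mut[j] <- b
        if (aa[paste(mut, collapse = "")] == aa[cdn]) nsyn <- nsyn + 1
      }
      m[cdn, j] <- nsyn / 3
    }
  }
  .redking_env$syn_frac <- m
  m
}

#' Construct a coding sequence with NG86 site weights
#'
#' A `gene_cds` bundles a gene identifier, its coding sequence and the
#' per-position synonymous-site weights used by every downstream per-gene
#' statistic. The sequence must be a multiple of three in length and contain
#' no in-frame stop codon.
#'
#' @param gene_id Gene identifier.
#' @param sequence DNA string (A/C/G/T), length divisible by 3.
#' @return An object of class `gene_cds` with elements `gene_id`, `sequence`,
#'   `site_weights` (per-position synonymous fraction) and `length`.
#' @examples
#' g <- gene_cds("g1", "ATGTTTAAA")
#' sum(g$site_weights) + sum(1 - g$site_weights) == g$length
#' @export
gene_cds <- function(gene_id, sequence) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (L == 0 || L %% 3 != 0)
    stop("CDS length of '", gene_id, "' is not a positive multiple of 3")
  nt <- strsplit(sequence, "")[[1]]
  if (!all(nt %in% .bases))
    stop("CDS of '", gene_id, "' contains non-ACGT characters")
  codons <- substring(sequence, seq(1, L, 3), seq(3, L, 3))
  if (any(codons %in% .stop_codons()))
    stop("CDS of '", gene_id, "' contains an in-frame stop codon")
  w <- as.vector(t(.codon_syn_fraction()[codons, , drop = FALSE]))
  structure(
    list(gene_id = gene_id, sequence = sequence, site_weights = w, length = L),
    class = "gene_cds"
  )
}

#' @export
print.gene_cds <- function(x, ...) {
  cat("<gene_cds> ", x$gene_id, ": ", x$length, " nt, ",
      format(sum(x$site_weights), digits = 5), " synonymous sites\n", sep = "")
  invisible(x)
}

#' Synonymous and nonsynonymous site counts of a CDS
#'
#' @param cds A [gene_cds()].
#' @return Named vector with `syn` and `nonsyn` site counts; they sum to the
#'   CDS length.
#' @export
site_counts <- function(cds) {
  stopifnot(inherits(cds, "gene_cds"))
  s <- sum(cds$site_weights)
  c(syn = s, nonsyn = cds$length - s)
}

.codon_at <- function(cds, pos) {
  ci <- (pos - 1L) %/% 3L
  substr(cds$sequence, ci * 3L + 1L, ci * 3L + 3L)
}

#' Classify a single-nucleotide variant against a coding sequence
#'
#' A variant is `synonymous` when the reference and alternative codons
#' translate to the same amino acid, `stop_gained` when the alternative codon
#' is a stop and the reference is not, and `nonsynonymous` otherwise.
#'
#' @param cds A [gene_cds()].
#' @param pos 1-based position within the CDS.
#' @param ref,alt Reference and alternative bases. `ref` must match the CDS.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stop_gained"`.
#' @export
classify_variant <- function(cds, pos, ref, alt) {
  stopifnot(inherits(cds, "gene_cds"))
  if (pos < 1 || pos > cds$length) stop("position outside CDS")
  if (substr(cds$sequence, pos, pos) != ref)
    stop("reference allele does not match the CDS at position ", pos)
  if (ref == alt) stop("alternative allele equals the reference")
  aa <- .codon_aa()
  ref_codon <- .codon_at(cds, pos)
  off <- (pos - 1L) %% 3L + 1L
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt
  if (aa[alt_codon] == "*") return("stop_gained")
  if (aa[alt_codon] == aa[ref_codon]) "synonymous" else "nonsynonymous"
}
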