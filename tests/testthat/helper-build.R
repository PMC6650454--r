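# Builders for small in-code fixtures.

dummy_cds <- function(n_codons = 40) {
  gene_cds("dummy", paste0("ATG", strrep("GCT", n_codons - 1)))
}

# Variant matrix straight from a genotype matrix (sites x strains); site
# classes default to nonsynonymous, positions to 1..S.
vm_from_geno <- function(geno, site_class = NULL, outgroup = NULL,
                         cds_length = NULL) {
  S <- nrow(geno)
  if (is.null(site_class)) site_class <- rep("nonsynonymous", S)
  if (is.null(outgroup)) outgroup <- rep(NA_integer_, S)
  if (is.null(cds_length)) cds_length <- max(3, 3 * ceiling(S / 3))
  variant_matrix("toy", seq_len(S), rep("A", S), rep("G", S), geno,
                 site_class, cds_length = cds_length, outgroup = outgroup)
}

# Random genotype matrix: each site gets an alt count in 1..(n-1), then
# missing calls are injected.
random_geno <- function(n_strains, n_sites, missing_rate = 0, rng = NULL) {
  g <- matrix(0L, n_sites, n_strains)
  for (i in seq_len(n_sites)) {
    k <- sample.int(n_strains - 1, 1)
    g[i, sample.int(n_strains, k)] <- 1L
  }
  if (missing_rate > 0) g[runif(length(g)) < missing_rate] <- NA_integer_
  g
}

random_cds <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  gene_cds("rnd", paste(c("ATG", sample(sense, n_codons - 1, TRUE)),
                        collapse = ""))
}
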