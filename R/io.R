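# Fixture I/O: FASTA (Biostrings), VCF 4.2 (one pseudo-contig per gene,
# haploid genotypes, the outgroup as a designated sample) and TSV tables.
# A write/read round trip reproduces the in-memory dataset exactly.

.vcf_outgroup_sample <- "OUTGROUP"

#' Write a synthetic dataset to standard-format fixture files
#'
#' Emits `genes.fasta` (one record per gene), `variants.vcf` (VCF 4.2, one
#' pseudo-contig per gene with 1-based CDS coordinates, haploid genotypes,
#' outgroup as the last sample), `expression.tsv` (genes x libraries, first
#' header token `gene_id`, library labels `veg:<cond>:r<rep>` /
#' `dev:h<hour>:r<rep>`), `mapping.tsv` and `truth.tsv`.
#'
#' @param dataset A `synth_dataset` from [generate_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixtures <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(fasta = file.path(out_dir, "genes.fasta"),
             vcf = file.path(out_dir, "variants.vcf"),
             expression = file.path(out_dir, "expression.tsv"),
             mapping = file.path(out_dir, "mapping.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  seqs <- Biostrings::DNAStringSet(vapply(dataset$cds, `[[`, "", "sequence"))
  names(seqs) <- names(dataset$cds)
  Biostrings::writeXStringSet(seqs, paths["fasta"])
  write_vcf(dataset$variants, paths["vcf"],
            cds_lengths = vapply(dataset$cds, `[[`, 0L, "length"))
  .write_tsv(dataset$expression$values, paths["expression"])
  .write_tsv(dataset$mapping, paths["mapping"])
  utils::write.table(dataset$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

.write_tsv <- function(mat, path) {
  # %.17g preserves doubles exactly across a write/read cycle
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), dimnames = dimnames(mat))
  df <- data.frame(gene_id = rownames(mat), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write per-gene variant matrices as a VCF file
#'
#' One pseudo-contig per gene; positions are 1-based CDS coordinates on the
#' coding strand. Genotypes are haploid: `0`, `1` or `.` (missing). The
#' outgroup is written as the final sample, named `OUTGROUP`.
#'
#' @param variants Named list of [variant_matrix()] objects.
#' @param path Output file.
#' @param cds_lengths Optional named integer vector for `##contig` headers.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(variants, path, cds_lengths = NULL) {
  strains <- colnames(variants[[1]]$geno)
  if (is.null(strains)) strains <- sprintf("S%03d", seq_len(ncol(variants[[1]]$geno)))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=redking",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">')
  if (!is.null(cds_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(cds_lengths), cds_lengths))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", strains,
                        .vcf_outgroup_sample), collapse = "\t"))
  body <- unlist(lapply(variants, function(vm) {
    if (!length(vm$pos)) return(character(0))
    gt <- apply(vm$geno, 1, function(g)
      paste(ifelse(is.na(g), ".", as.character(g)), collapse = "\t"))
    og <- ifelse(is.na(vm$outgroup), ".", as.character(vm$outgroup))
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s\t%s",
            vm$gene_id, vm$pos, vm$ref, vm$alt, gt, og)
  }), use.names = FALSE)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Load pipeline inputs from standard-format files
#'
#' Reads reference coding sequences (FASTA), variants (VCF; record contig =
#' gene id, positions 1-based on the CDS) and, when given, the expression,
#' mapping and truth/label tables. Variant records that are indels,
#' multiallelic, or on a contig without a CDS are skipped with a counted
#' reason; genes whose CDS length is not a multiple of 3 (or that contain
#' an in-frame stop) are dropped and reported. Site classes are recomputed
#' from the CDS, so a written dataset reloads identically.
#'
#' @param fasta Path to the CDS FASTA.
#' @param vcf Path to the VCF.
#' @param expression,mapping,truth Optional paths to the TSV tables.
#' @return List with `cds`, `variants`, `expression`, `mapping`, `truth`
#'   and `log` (skip/drop counts by reason).
#' @export
load_inputs <- function(fasta, vcf, expression = NULL, mapping = NULL,
                        truth = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  log <- list(genes_dropped = character(0), records_skipped = c(
    indel = 0L, multiallelic = 0L, no_cds = 0L, outside_cds = 0L))
  cds <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    g <- tryCatch(gene_cds(id, as.character(seqs[[i]])), error = function(e) NULL)
    if (is.null(g)) log$genes_dropped <- c(log$genes_dropped, id)
    else cds[[id]] <- g
  }

  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt
  samples <- colnames(gt_raw)[-1]
  ingroup <- setdiff(samples, .vcf_outgroup_sample)
  has_outgroup <- .vcf_outgroup_sample %in% samples

  keep <- rep(TRUE, nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    if (grepl(",", alt)) { log$records_skipped["multiallelic"] <-
      log$records_skipped["multiallelic"] + 1L; keep[i] <- FALSE; next }
    if (nchar(ref) != 1 || nchar(alt) != 1) { log$records_skipped["indel"] <-
      log$records_skipped["indel"] + 1L; keep[i] <- FALSE; next }
    if (!fix[i, "CHROM"] %in% names(cds)) { log$records_skipped["no_cds"] <-
      log$records_skipped["no_cds"] + 1L; keep[i] <- FALSE; next }
    if (as.integer(fix[i, "POS"]) > cds[[fix[i, "CHROM"]]]$length) {
      log$records_skipped["outside_cds"] <-
        log$records_skipped["outside_cds"] + 1L; keep[i] <- FALSE }
  }

  gt_chr <- sub(":.*", "", gt_raw[, -1, drop = FALSE])
  parse_call <- function(x) ifelse(x %in% c(".", "./.", ".|."), NA_integer_,
                                   suppressWarnings(as.integer(substr(x, 1, 1))))
  variants <- list()
  for (id in names(cds)) {
    rows <- which(keep & fix[, "CHROM"] == id)
    rows <- rows[order(as.integer(fix[rows, "POS"]))]
    if (length(rows)) {
      pos <- as.integer(fix[rows, "POS"])
      ref <- fix[rows, "REF"]; alt <- fix[rows, "ALT"]
      geno <- matrix(parse_call(gt_chr[rows, ingroup, drop = FALSE]),
                     nrow = length(rows),
                     dimnames = list(NULL, ingroup))
      og <- if (has_outgroup)
        parse_call(gt_chr[rows, .vcf_outgroup_sample]) else
          rep(NA_integer_, length(rows))
      sclass <- vapply(seq_along(pos), function(j)
        classify_variant(cds[[id]], pos[j], ref[j], alt[j]), "")
      variants[[id]] <- variant_matrix(id, pos, ref, alt, geno, sclass,
                                       cds_length = cds[[id]]$length,
                                       outgroup = og)
    } else {
      geno <- matrix(integer(0), nrow = 0, ncol = length(ingroup),
                     dimnames = list(NULL, ingroup))
      variants[[id]] <- variant_matrix(id, integer(0), character(0),
                                       character(0), geno, character(0),
                                       cds_length = cds[[id]]$length,
                                       outgroup = integer(0))
    }
  }

  expr <- NULL
  if (!is.null(expression)) {
    m <- .read_tsv_matrix(expression)
    expr <- expr_matrix(m, .meta_from_labels(colnames(m)))
  }
  mapping_m <- if (!is.null(mapping)) .read_tsv_matrix(mapping) else NULL
  if (!is.null(mapping_m)) {
    for (id in intersect(rownames(mapping_m), names(variants)))
      variants[[id]]$mapped_cds_length <-
        as.integer(round(cds[[id]]$length * mean(mapping_m[id, ])))
  }
  truth_df <- if (!is.null(truth))
    utils::read.delim(truth, stringsAsFactors = FALSE) else NULL
  list(cds = cds, variants = variants, expression = expr,
       mapping = mapping_m, truth = truth_df, log = log)
}

# Library metadata from labels "veg:<cond>:r<rep>" / "dev:h<hour>:r<rep>".
.meta_from_labels <- function(labels) {
  parts <- strsplit(labels, ":")
  cond <- vapply(parts, function(p) paste(p[1:2], collapse = ":"), "")
  hour <- ifelse(startsWith(labels, "dev:h"),
                 suppressWarnings(as.numeric(sub("^dev:h([0-9.]+):.*$", "\\1",
                                                 labels))), NA)
  data.frame(library = labels,
             compartment = ifelse(!is.na(hour) & hour >= 1, "social",
                                  "vegetative"),
             condition = cond, hour = hour, stringsAsFactors = FALSE)
}

#' Read back a fixture directory written by [write_fixtures()]
#'
#' @param dir Directory containing the fixture files.
#' @return As [load_inputs()].
#' @export
read_fixtures <- function(dir) {
  load_inputs(fasta = file.path(dir, "genes.fasta"),
              vcf = file.path(dir, "variants.vcf"),
              expression = file.path(dir, "expression.tsv"),
              mapping = file.path(dir, "mapping.tsv"),
              truth = file.path(dir, "truth.tsv"))
}
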