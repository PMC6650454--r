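# Orchestration: run configuration, the strain/site filters, the per-gene
# statistics table, and the end-to-end pipeline.

#' Pipeline run configuration
#'
#' Either a `simulate` block (a [sim_config()]) or input paths must be
#' given. Thresholds default to the published filtering rules: strains
#' with more than 30% missing calls are dropped, then sites called in
#' fewer than 90% of the remaining strains, then multiallelic/indel
#' records (the latter already at load time); genes with mean mapping at
#' or below 0.5 are routed to presence/absence analysis only.
#'
#' @param simulate Optional [sim_config()]; when given, inputs are
#'   generated in memory instead of read from files.
#' @param fasta,vcf,expression,mapping,truth Input paths (used when
#'   `simulate` is NULL).
#' @param strain_missing_max Maximum per-strain missing-call rate.
#' @param site_called_min Minimum fraction of remaining strains called at
#'   a site.
#' @param pav_threshold Mean-mapping cutoff for presence/absence flags.
#' @param ise_threshold Sociality cutoff on ISE (strict).
#' @param bias_thresholds Cell-type bias cutoffs.
#' @param fixed_class_fractions Optional `c(nonsyn=, syn=)` global split
#'   for per-site denominators (default: exact per-gene site counts).
#' @param permutations Number of randomization draws B.
#' @param seed Seed for the randomization stages.
#' @param out_dir Optional directory for the output TSVs.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(simulate = NULL, fasta = NULL, vcf = NULL,
                       expression = NULL, mapping = NULL, truth = NULL,
                       strain_missing_max = 0.3, site_called_min = 0.9,
                       pav_threshold = 0.5, ise_threshold = 0.9,
                       bias_thresholds = c(0.8, 0.9),
                       fixed_class_fractions = NULL,
                       permutations = 10000, seed = 1, out_dir = NULL) {
  if (is.null(simulate) && (is.null(fasta) || is.null(vcf)))
    stop("either a simulate block or fasta+vcf paths are required")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  thr <- c(strain_missing_max, site_called_min, pav_threshold, ise_threshold,
           bias_thresholds)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  if (permutations < 100) stop("permutations must be at least 100")
  structure(list(simulate = simulate, fasta = fasta, vcf = vcf,
                 expression = expression, mapping = mapping, truth = truth,
                 strain_missing_max = strain_missing_max,
                 site_called_min = site_called_min,
                 pav_threshold = pav_threshold,
                 ise_threshold = ise_threshold,
                 bias_thresholds = bias_thresholds,
                 fixed_class_fractions = fixed_class_fractions,
                 permutations = as.integer(permutations),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Apply the strain and site call-rate filters
#'
#' Order of operations: (1) drop strains whose missing-call rate across
#' all genes exceeds `strain_missing_max`; (2) drop sites called in fewer
#' than `site_called_min` of the remaining strains. Multiallelic and indel
#' records are already removed at load time. Counts are logged at each
#' step, and input sites equal retained plus dropped per gene.
#'
#' @param variants Named list of [variant_matrix()] objects.
#' @param strain_missing_max,site_called_min Thresholds in \[0, 1\].
#' @return List with `variants` (filtered), and `log` (`strains_dropped`,
#'   `sites_dropped` per gene, `strains_kept`).
#' @export
filter_variants <- function(variants, strain_missing_max = 0.3,
                            site_called_min = 0.9) {
  if (is.null(colnames(variants[[1]]$geno))) {
    nm <- sprintf("strain%03d", seq_len(ncol(variants[[1]]$geno)))
    for (id in seq_along(variants)) colnames(variants[[id]]$geno) <- nm
  }
  tot <- 0; miss <- NULL
  for (vm in variants) {
    if (!length(vm$pos)) next
    m <- colSums(is.na(vm$geno))
    miss <- if (is.null(miss)) m else miss + m
    tot <- tot + length(vm$pos)
  }
  strains <- colnames(variants[[1]]$geno)
  if (tot == 0) {
    return(list(variants = variants,
                log = list(strains_dropped = character(0),
                           strains_kept = strains,
                           sites_dropped = integer(length(variants)))))
  }
  rate <- miss / tot
  drop_strains <- strains[rate > strain_missing_max]
  keep_strains <- setdiff(strains, drop_strains)
  if (!length(keep_strains)) stop("all strains dropped by the missing-call filter")
  sites_dropped <- integer(length(variants))
  names(sites_dropped) <- names(variants)
  out <- variants
  for (id in names(variants)) {
    vm <- variants[[id]]
    geno <- vm$geno[, keep_strains, drop = FALSE]
    if (length(vm$pos)) {
      called <- rowSums(!is.na(geno)) / length(keep_strains)
      keep_sites <- called >= site_called_min
      sites_dropped[id] <- sum(!keep_sites)
      out[[id]] <- variant_matrix(vm$gene_id, vm$pos[keep_sites],
                                  vm$ref[keep_sites], vm$alt[keep_sites],
                                  geno[keep_sites, , drop = FALSE],
                                  vm$site_class[keep_sites],
                                  cds_length = vm$cds_length,
                                  mapped_cds_length = vm$mapped_cds_length,
                                  outgroup = vm$outgroup[keep_sites])
      colnames(out[[id]]$geno) <- keep_strains
    } else {
      out[[id]]$geno <- geno
    }
  }
  list(variants = out,
       log = list(strains_dropped = drop_strains,
                  strains_kept = keep_strains,
                  sites_dropped = sites_dropped))
}

#' Per-gene evolutionary statistics table
#'
#' One row per gene with polymorphism (S, pi/site and SNP/site for CDS,
#' nonsynonymous and synonymous sites, Tajima's D, Fu & Li's D*/F*,
#' Wall's B/Q, stop-gain carrier flag), presence/absence status, and —
#' when the outgroup is available — the McDonald-Kreitman counts and
#' test, Direction of Selection with its components, and NG86 Ka/Ks.
#' Genes flagged as PAV are excluded from the quantitative statistics
#' (reported as NA) and only analysed categorically. Undefined statistics
#' stay NA and are never zero-filled.
#'
#' @param cds Named list of [gene_cds()].
#' @param variants Named list of [variant_matrix()].
#' @param mapping Optional genes x strains mapping-fraction matrix.
#' @param pav_threshold Mean-mapping PAV cutoff (inclusive).
#' @param fixed_class_fractions Optional global `c(nonsyn=, syn=)` split.
#' @return Data frame, one row per gene.
#' @export
compute_gene_stats <- function(cds, variants, mapping = NULL,
                               pav_threshold = 0.5,
                               fixed_class_fractions = NULL) {
  ids <- names(cds)
  pav <- if (!is.null(mapping))
    classify_pav(mapping[ids, , drop = FALSE], pav_threshold) else
      data.frame(gene_id = ids, mean_mapping = 1, is_pav = FALSE)
  rows <- lapply(ids, function(id) {
    vm <- variants[[id]]
    g <- cds[[id]]
    is_pav <- pav$is_pav[pav$gene_id == id]
    base <- data.frame(gene_id = id, mapped_cds_length = vm$mapped_cds_length,
                       mean_mapping = pav$mean_mapping[pav$gene_id == id],
                       is_pav = is_pav, stringsAsFactors = FALSE)
    if (is_pav) {
      na <- NA_real_
      return(cbind(base, data.frame(
        S = NA_integer_, pi_site_cds = na, pi_site_nonsyn = na,
        pi_site_syn = na, snp_site_cds = na, snp_site_nonsyn = na,
        snp_site_syn = na, tajima_d = na, fu_li_dstar = na,
        fu_li_fstar = na, wall_b = na, wall_q = na, stop_gain = NA,
        Pn = NA_integer_, Ps = NA_integer_, Dn = NA_integer_,
        Ds = NA_integer_, mk_p = na, mk_class = NA_character_, DoS = na,
        dos_d_component = na, dos_p_component = na, Ka = na, Ks = na,
        KaKs = na)))
    }
    d_cds <- nucleotide_diversity(vm, g, "cds", fixed_class_fractions)
    d_non <- nucleotide_diversity(vm, g, "nonsyn", fixed_class_fractions)
    d_syn <- nucleotide_diversity(vm, g, "syn", fixed_class_fractions)
    nt <- neutrality_tests(vm)
    tab <- build_mk_table(vm)
    mk <- mk_test(tab)
    ds <- dos(tab)
    kk <- if (any(!is.na(vm$outgroup)))
      kaks(g, outgroup_sequence(g, vm)) else
        list(Ka = NA_real_, Ks = NA_real_, ratio = NA_real_)
    cbind(base, data.frame(
      S = d_cds$S, pi_site_cds = d_cds$pi_per_site,
      pi_site_nonsyn = d_non$pi_per_site, pi_site_syn = d_syn$pi_per_site,
      snp_site_cds = d_cds$snp_per_site,
      snp_site_nonsyn = d_non$snp_per_site,
      snp_site_syn = d_syn$snp_per_site,
      tajima_d = unname(nt["tajima_d"]),
      fu_li_dstar = unname(nt["fu_li_dstar"]),
      fu_li_fstar = unname(nt["fu_li_fstar"]),
      wall_b = unname(nt["wall_b"]), wall_q = unname(nt["wall_q"]),
      stop_gain = annotate_stop_gain(vm),
      Pn = tab$Pn, Ps = tab$Ps, Dn = tab$Dn, Ds = tab$Ds,
      mk_p = mk$p_value, mk_class = mk$classification,
      DoS = unname(ds["dos"]), dos_d_component = unname(ds["d_component"]),
      dos_p_component = unname(ds["p_component"]),
      Ka = kk$Ka, Ks = kk$Ks, KaKs = kk$ratio,
      stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

# One class-vs-background comparison block over several statistics.
.compare_block <- function(stats_df, statistics, group, group_name, B, seed) {
  res <- lapply(seq_along(statistics), function(i) {
    st <- statistics[i]
    vals <- stats::setNames(stats_df[[st]], stats_df$gene_id)
    permutation_null(vals, group, B = B, seed = seed + i,
                     statistic = st, group_name = group_name)
  })
  data.frame(statistic = statistics, group = group_name,
             N = vapply(res, `[[`, 0L, "N"),
             observed_mean = vapply(res, `[[`, 0, "observed_mean"),
             expected_mean = vapply(res, `[[`, 0, "expected_mean"),
             ci_low = vapply(res, `[[`, 0, "ci_low"),
             ci_high = vapply(res, `[[`, 0, "ci_high"),
             p_two_tailed = vapply(res, `[[`, 0, "p_two_tailed"),
             stringsAsFactors = FALSE)
}

#' Run the complete analysis pipeline
#'
#' Sequences load (or simulate) -> filter -> per-gene statistics ->
#' expression classification -> class-vs-background randomization tests
#' (continuous statistics and categorical enrichments, with BH-FDR within
#' each family) -> ISE correlation tests -> Red King proportion-matched
#' regression across mixture classes. All tables are written as TSV
#' (single header line, empty field for missing, 10 significant digits)
#' when `out_dir` is set. Exit reflects completion, not significance.
#'
#' @param cfg A [run_config()].
#' @return Object of class `run_report`: the config echo, dataset summary,
#'   per-gene statistics, gene classes, comparison tables, enrichments,
#'   correlation tests and the Red King fits.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$simulate)) {
    ds <- generate_dataset(cfg$simulate)
    data <- list(cds = ds$cds, variants = ds$variants,
                 expression = ds$expression, mapping = ds$mapping,
                 truth = ds$truth,
                 log = list(records_skipped = c(indel = 0L, multiallelic = 0L,
                                                no_cds = 0L, outside_cds = 0L),
                            genes_dropped = character(0)))
  } else {
    data <- load_inputs(cfg$fasta, cfg$vcf, cfg$expression, cfg$mapping,
                        cfg$truth)
  }
  flt <- filter_variants(data$variants, cfg$strain_missing_max,
                         cfg$site_called_min)
  stats_df <- compute_gene_stats(data$cds, flt$variants, data$mapping,
                                 cfg$pav_threshold,
                                 cfg$fixed_class_fractions)
  classes <- classify_gene_sets(data$expression,
                                ise_threshold = cfg$ise_threshold)
  soc <- classes$gene_id[classes$class == "sociality"]
  nonsoc <- classes$gene_id[classes$class == "non_sociality"]
  expressed <- classes$gene_id[classes$class != "conditional_other"]
  B <- cfg$permutations

  cont_stats <- c("pi_site_cds", "pi_site_nonsyn", "pi_site_syn",
                  "snp_site_cds", "tajima_d", "DoS", "Ka", "Ks", "KaKs")
  pool_df <- stats_df[stats_df$gene_id %in% expressed, ]
  comparisons <- .compare_block(pool_df, cont_stats, soc, "sociality",
                                B, cfg$seed)
  cond <- classes$gene_id[classes$class == "conditional_other"]
  if (length(cond)) {
    pool_cond <- stats_df[stats_df$gene_id %in% c(cond, nonsoc), ]
    comparisons <- rbind(comparisons,
                         .compare_block(pool_cond, cont_stats, cond,
                                        "conditional_other", B, cfg$seed + 100))
  }
  comparisons$q_fdr <- bh_fdr(comparisons$p_two_tailed)

  # categorical enrichments: stop-gain and PAV carriers, Tajima's D
  # exceeding balancing-selection thresholds, MK classifications
  enr_feats <- list(
    stop_gain = stats_df$stop_gain %in% TRUE,
    pav = stats_df$is_pav %in% TRUE,
    tajima_d_gt_2 = !is.na(stats_df$tajima_d) & stats_df$tajima_d > 2,
    tajima_d_gt_1.5 = !is.na(stats_df$tajima_d) & stats_df$tajima_d > 1.5,
    tajima_d_gt_1 = !is.na(stats_df$tajima_d) & stats_df$tajima_d > 1,
    mk_positive = stats_df$mk_class %in% "positive_selection",
    mk_excess_poly = stats_df$mk_class %in% "excess_polymorphism")
  enrichments <- do.call(rbind, lapply(seq_along(enr_feats), function(i) {
    flags <- stats::setNames(enr_feats[[i]], stats_df$gene_id)
    flags <- flags[names(flags) %in% expressed]
    r <- categorical_enrichment(flags, intersect(soc, names(flags)),
                                B = B, seed = cfg$seed + 200 + i,
                                statistic = names(enr_feats)[i],
                                group_name = "sociality")
    data.frame(feature = names(enr_feats)[i], group = "sociality",
               N = r$N, observed = r$observed_mean,
               expected = r$expected_mean, ci_low = r$ci_low,
               ci_high = r$ci_high, p_two_tailed = r$p_two_tailed,
               stringsAsFactors = FALSE)
  }))
  enrichments$q_fdr <- bh_fdr(enrichments$p_two_tailed)

  ise <- stats::setNames(classes$ise, classes$gene_id)
  cor_stats <- c("pi_site_cds", "tajima_d", "Ka", "Ks")
  correlations <- do.call(rbind, lapply(seq_along(cor_stats), function(i) {
    st <- cor_stats[i]
    vals <- stats::setNames(stats_df[[st]], stats_df$gene_id)
    r <- tryCatch(ise_correlation_test(ise, vals, sociality = soc, B = B,
                                       seed = cfg$seed + 300 + i),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(statistic = st, r = r$r, p = r$p_value, n = r$n,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(correlations) && nrow(correlations))
    correlations$q_fdr <- bh_fdr(correlations$p)

  # Red King stage: mixture classes spanning the proportion range
  rk <- NULL
  truth_like <- data.frame(gene_id = classes$gene_id, class = classes$class,
                           stringsAsFactors = FALSE)
  n_soc <- length(soc); n_non <- length(nonsoc)
  size <- min(200, n_soc, n_non)
  if (size >= 20) {
    mix <- build_mixture_classes(truth_like, c(0, 0.25, 0.5, 0.75, 1),
                                 size, seed = cfg$seed + 400)
    rk_stats <- c("pi_site_cds", "pi_site_nonsyn", "pi_site_syn", "Ka", "Ks")
    rk <- lapply(rk_stats, function(st) {
      vals <- stats::setNames(stats_df[[st]], stats_df$gene_id)
      vals <- vals[names(vals) %in% expressed]
      weighted_regression(vals, mix, soc, B = min(B, 2000),
                          seed = cfg$seed + 500, statistic = st)
    })
    names(rk) <- rk_stats
  }

  report <- structure(
    list(config = cfg,
         summary = list(
           n_genes = length(data$cds),
           n_strains = length(flt$log$strains_kept),
           strains_dropped = flt$log$strains_dropped,
           sites_dropped = sum(flt$log$sites_dropped),
           records_skipped = data$log$records_skipped,
           genes_dropped = data$log$genes_dropped,
           n_sociality = length(soc),
           n_conditional = sum(classes$class == "conditional_other")),
         gene_stats = stats_df, gene_classes = classes,
         comparisons = comparisons, enrichments = enrichments,
         correlations = correlations, redking = rk,
         seed = cfg$seed),
    class = "run_report")
  if (!is.null(cfg$out_dir)) .write_report(report, cfg$out_dir)
  report
}

.fmt_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), "",
                                                formatC(x, digits = 10,
                                                        format = "g")))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

.write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  .fmt_tsv(report$gene_stats, file.path(out_dir, "gene_stats.tsv"))
  .fmt_tsv(as.data.frame(report$gene_classes),
           file.path(out_dir, "gene_classes.tsv"))
  .fmt_tsv(report$comparisons, file.path(out_dir, "comparisons.tsv"))
  .fmt_tsv(report$enrichments, file.path(out_dir, "enrichments.tsv"))
  if (!is.null(report$correlations))
    .fmt_tsv(report$correlations, file.path(out_dir, "ise_correlations.tsv"))
  if (!is.null(report$redking)) {
    fits <- do.call(rbind, lapply(report$redking, function(f)
      data.frame(statistic = f$statistic, slope = f$slope,
                 intercept = f$intercept, r_squared = f$r_squared,
                 p_perm = f$p_perm, stringsAsFactors = FALSE)))
    .fmt_tsv(fits, file.path(out_dir, "redking_fits.tsv"))
  }
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat("<run_report> ", s$n_genes, " genes, ", s$n_strains, " strains; ",
      s$n_sociality, " sociality genes, ", s$n_conditional,
      " conditional\n", sep = "")
  cat("comparisons (sociality vs background):\n")
  print(x$comparisons[x$comparisons$group == "sociality",
                      c("statistic", "observed_mean", "expected_mean",
                        "p_two_tailed", "q_fdr")], row.names = FALSE)
  invisible(x)
}
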