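# Synthetic-data generator: fully labelled datasets (genotypes, outgroup,
# expression, mapping fractions, class truth) with the statistical
# structure the analysis assumes. Sites are drawn from a parametric site
# frequency spectrum rather than forward simulation, so the expectations
# used by the calibration tests are known in closed form.

#' Configuration for the synthetic-data generator
#'
#' The defaults emulate the study design the pipeline targets: 67 haploid
#' strains, a divergent outgroup, roughly 13% of genes conditionally
#' expressed in the social stage only, seven vegetative conditions and 18
#' developmental time points (hours 0-24, duplicated), a site frequency
#' spectrum tilted towards rare variants (negative Tajima's D), and a
#' two-fold dilution of selection at conditionally expressed genes that
#' elevates both polymorphism and outgroup divergence at all site classes.
#'
#' @param n_genes Number of genes (required).
#' @param n_strains Number of haploid ingroup strains (default 67; at
#'   least 4, below which Tajima's D is undefined).
#' @param codon_counts Length-2 bounds (codons) of the per-gene CDS length
#'   distribution (uniform on the integer range).
#' @param theta_site Expected pairwise diversity per site for
#'   non-conditional genes.
#' @param dilution Multiplier >= 1 applied to the mutation-accumulation
#'   intensity (theta and outgroup divergence, both site classes) of
#'   conditionally expressed genes.
#' @param sfs_skew Non-negative parameter tilting the site frequency
#'   spectrum: derived-allele counts are drawn with probability
#'   proportional to i^-(1 + sfs_skew); 0 gives the neutral 1/i spectrum,
#'   positive values give an excess of rare variants and negative expected
#'   Tajima's D.
#' @param outgroup_divergence Expected substitutions per site to the
#'   outgroup for non-conditional genes.
#' @param frac_sociality Fraction of genes expressed only in the social
#'   stage (hours 1-24).
#' @param frac_conditional_other Fraction of genes with zero expression in
#'   every library (conditional outside the sampled conditions).
#' @param stop_gain_rate,pav_rate Named per-regime probabilities
#'   (`non_sociality`, `sociality`, `conditional_other`) that a gene
#'   carries a stop-gain SNP / a presence-absence variant.
#' @param n_veg_libraries Number of vegetative conditions.
#' @param n_dev_timepoints Number of developmental time points over hours
#'   0-24 (hour 0 counts as vegetative).
#' @param n_replicates Replicates per condition.
#' @param missing_rate Per-call probability of a missing ingroup genotype.
#' @param seed Random seed (the generator is deterministic given the
#'   configuration).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes,
                       n_strains = 67,
                       codon_counts = c(100, 500),
                       theta_site = 0.01,
                       dilution = 2,
                       sfs_skew = 0.3,
                       outgroup_divergence = 0.08,
                       frac_sociality = 0.13,
                       frac_conditional_other = 0.05,
                       stop_gain_rate = c(non_sociality = 0.035,
                                          sociality = 0.05,
                                          conditional_other = 0.05),
                       pav_rate = c(non_sociality = 0.003,
                                    sociality = 0.007,
                                    conditional_other = 0.007),
                       n_veg_libraries = 7,
                       n_dev_timepoints = 18,
                       n_replicates = 2,
                       missing_rate = 0.02,
                       seed = 1) {
  if (n_genes < 1) stop("at least one gene is required")
  if (n_strains < 4) stop("n_strains must be at least 4 (Tajima's D undefined below)")
  if (length(codon_counts) != 2 || codon_counts[1] < 10 ||
      codon_counts[2] < codon_counts[1])
    stop("codon_counts must be bounds >= 10")
  if (theta_site <= 0 || outgroup_divergence <= 0)
    stop("theta_site and outgroup_divergence must be positive")
  if (dilution < 1) stop("dilution must be >= 1")
  if (n_dev_timepoints < 1) stop("n_dev_timepoints must be >= 1")
  regimes <- c("non_sociality", "sociality", "conditional_other")
  for (nm in c("stop_gain_rate", "pav_rate")) {
    v <- get(nm)
    if (!all(regimes %in% names(v))) stop(nm, " needs rates for: ",
                                          paste(regimes, collapse = ", "))
    if (any(v < 0 | v > 1)) stop(nm, " must lie in [0, 1]")
  }
  probs <- c(frac_sociality, frac_conditional_other, missing_rate)
  if (any(probs < 0 | probs > 1)) stop("fractions and rates must lie in [0, 1]")
  if (frac_sociality + frac_conditional_other > 1)
    stop("regime fractions exceed 1")
  structure(
    list(n_genes = as.integer(n_genes), n_strains = as.integer(n_strains),
         codon_counts = as.integer(codon_counts), theta_site = theta_site,
         dilution = dilution, sfs_skew = sfs_skew,
         outgroup_divergence = outgroup_divergence,
         frac_sociality = frac_sociality,
         frac_conditional_other = frac_conditional_other,
         stop_gain_rate = stop_gain_rate[regimes],
         pav_rate = pav_rate[regimes],
         n_veg_libraries = as.integer(n_veg_libraries),
         n_dev_timepoints = as.integer(n_dev_timepoints),
         n_replicates = as.integer(n_replicates),
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# For each codon, the single-base changes that create a stop codon:
# a list of (position offset, alternative base) matrices.
.stop_moves <- function() {
  if (!is.null(.redking_env$stop_moves)) return(.redking_env$stop_moves)
  aa <- .codon_aa()
  res <- lapply(names(aa), function(cdn) {
    if (aa[cdn] == "*") return(matrix(nrow = 0, ncol = 2))
    nt <- strsplit(cdn, "")[[1]]
    hits <- NULL
    for (j in 1:3) for (b in setdiff(.bases, nt[j])) {
      mut <- nt; mut[j] <- b
      if (aa[paste(mut, collapse = "")] == "*") hits <- rbind(hits, c(j, match(b, .bases)))
    }
    if (is.null(hits)) matrix(nrow = 0, ncol = 2) else hits
  })
  names(res) <- names(aa)
  .redking_env$stop_moves <- res
  res
}

# Alternative bases at a CDS position by effect class relative to the
# reference codon; stop-producing changes are reported separately.
.alt_candidates <- function(ref_codon, offset) {
  aa <- .codon_aa()
  nt <- strsplit(ref_codon, "")[[1]]
  syn <- character(0); nonsyn <- character(0); stopg <- character(0)
  for (b in setdiff(.bases, nt[offset])) {
    mut <- nt; mut[offset] <- b
    mc <- paste(mut, collapse = "")
    if (aa[mc] == "*") stopg <- c(stopg, b)
    else if (aa[mc] == aa[ref_codon]) syn <- c(syn, b)
    else nonsyn <- c(nonsyn, b)
  }
  list(syn = syn, nonsyn = nonsyn, stop = stopg)
}

# Draw derived-allele counts from the parametric SFS p(i) ~ i^-(1+skew).
.draw_sfs <- function(n_sites, n_strains, skew) {
  i <- seq_len(n_strains - 1)
  sample(i, n_sites, replace = TRUE, prob = i^(-1 - skew))
}

#' Simulate one gene under a mutation-intensity regime
#'
#' Builds a stop-free coding sequence beginning with ATG, draws
#' class-specific segregating-site counts as Poisson with mean
#' `theta * a1(n) * L_class` (Watterson's expectation inverted), assigns
#' derived-allele counts from the configured site frequency spectrum,
#' places fixed outgroup differences as Poisson with mean
#' `divergence * L_class`, and optionally injects a stop-gain variant.
#'
#' @param gene_id Gene identifier.
#' @param n_codons CDS length in codons (>= 10).
#' @param n_strains Number of ingroup strains.
#' @param theta_site,divergence Per-site intensities after any dilution
#'   multiplier.
#' @param sfs_skew Site-frequency-spectrum tilt (see [sim_config()]).
#' @param stop_gain_rate Probability that the gene carries a stop-gain SNP.
#' @param missing_rate Per-call missing probability (ingroup only).
#' @return List with `cds` ([gene_cds()]) and `vm` ([variant_matrix()]).
#' @export
simulate_gene <- function(gene_id, n_codons, n_strains, theta_site,
                          divergence, sfs_skew = 0.3, stop_gain_rate = 0,
                          missing_rate = 0) {
  if (n_codons < 10) stop("n_codons must be at least 10")
  sense <- setdiff(.all_codons(), .stop_codons())
  codons <- c("ATG", sample(sense, n_codons - 1, replace = TRUE))
  cds <- gene_cds(gene_id, paste(codons, collapse = ""))
  L <- cds$length
  w <- cds$site_weights
  a1 <- .a1(n_strains)
  used <- logical(L)

  pick_sites <- function(n_sites, weights, kind) {
    pos <- integer(0); alt <- character(0)
    avail <- which(weights > 0 & !used)
    if (!length(avail) || n_sites == 0) return(list(pos = pos, alt = alt))
    n_sites <- min(n_sites, length(avail))
    cand <- sample(avail, n_sites, prob = weights[avail])
    for (p in cand) {
      cc <- .alt_candidates(.codon_at(cds, p), (p - 1L) %% 3L + 1L)
      ch <- cc[[kind]]
      if (!length(ch)) next
      pos <- c(pos, p); alt <- c(alt, if (length(ch) == 1) ch else sample(ch, 1))
      used[p] <<- TRUE
    }
    list(pos = pos, alt = alt)
  }

  syn_w <- w; nonsyn_w <- 1 - w
  S_syn <- stats::rpois(1, theta_site * a1 * sum(syn_w))
  S_non <- stats::rpois(1, theta_site * a1 * sum(nonsyn_w))
  seg_s <- pick_sites(S_syn, syn_w, "syn")
  seg_n <- pick_sites(S_non, nonsyn_w, "nonsyn")

  stop_pos <- integer(0); stop_alt <- character(0)
  if (stats::runif(1) < stop_gain_rate) {
    sm <- .stop_moves()
    starts <- seq(1, L, 3)
    cods <- substring(cds$sequence, starts, starts + 2)
    cand <- NULL
    for (ci in seq_along(cods)) {
      mv <- sm[[cods[ci]]]
      if (nrow(mv)) cand <- rbind(cand, cbind((ci - 1L) * 3L + mv[, 1], mv[, 2]))
    }
    if (!is.null(cand)) {
      cand <- cand[!used[cand[, 1]], , drop = FALSE]
      if (nrow(cand)) {
        j <- if (nrow(cand) == 1) 1 else sample(nrow(cand), 1)
        stop_pos <- cand[j, 1]
        stop_alt <- .bases[cand[j, 2]]
        used[stop_pos] <- TRUE
      }
    }
  }

  D_syn <- stats::rpois(1, divergence * sum(syn_w))
  D_non <- stats::rpois(1, divergence * sum(nonsyn_w))
  out_s <- pick_sites(D_syn, syn_w, "syn")
  out_n <- pick_sites(D_non, nonsyn_w, "nonsyn")

  seg_pos <- c(seg_s$pos, seg_n$pos, stop_pos)
  seg_alt <- c(seg_s$alt, seg_n$alt, stop_alt)
  out_pos <- c(out_s$pos, out_n$pos)
  out_alt <- c(out_s$alt, out_n$alt)

  # combined outgroup substitutions must not create an in-frame stop
  if (length(out_pos)) {
    s <- strsplit(cds$sequence, "")[[1]]
    s[out_pos] <- out_alt
    starts <- seq(1, L, 3)
    ocods <- substring(paste(s, collapse = ""), starts, starts + 2)
    bad <- which(ocods %in% .stop_codons())
    if (length(bad)) {
      drop <- ((out_pos - 1L) %/% 3L + 1L) %in% bad
      used[out_pos[drop]] <- FALSE
      out_pos <- out_pos[!drop]; out_alt <- out_alt[!drop]
    }
  }

  pos <- c(seg_pos, out_pos)
  alt <- c(seg_alt, out_alt)
  n_seg <- length(seg_pos)
  geno <- matrix(0L, nrow = length(pos), ncol = n_strains)
  if (n_seg) {
    counts <- .draw_sfs(n_seg, n_strains, sfs_skew)
    for (i in seq_len(n_seg))
      geno[i, sample.int(n_strains, counts[i])] <- 1L
  }
  outgroup <- c(rep(0L, n_seg), rep(1L, length(out_pos)))
  if (missing_rate > 0 && length(pos)) {
    miss <- stats::runif(length(geno)) < missing_rate
    geno[miss] <- NA_integer_
  }
  ord <- order(pos)
  pos <- pos[ord]; alt <- alt[ord]
  geno <- geno[ord, , drop = FALSE]
  outgroup <- outgroup[ord]
  refs <- strsplit(cds$sequence, "")[[1]][pos]
  sclass <- vapply(seq_along(pos), function(i)
    classify_variant(cds, pos[i], refs[i], alt[i]), "")
  vm <- variant_matrix(gene_id, pos, refs, alt, geno, sclass,
                       cds_length = L, outgroup = outgroup)
  list(cds = cds, vm = vm)
}

#' Simulate the expression matrix implied by the truth labels
#'
#' Sociality genes are silent in every vegetative library and at hour 0
#' and log-normally expressed at hours >= 1 (so their recomputed ISE is
#' exactly 1); conditionally expressed non-social genes are silent in
#' every library (ISE undefined); non-sociality genes are expressed in
#' both compartments from a shared log-normal, giving ISE near 0.5.
#'
#' @param truth Data frame with `gene_id` and `class`.
#' @param config A [sim_config()].
#' @return An [expr_matrix()].
#' @export
simulate_expression <- function(truth, config) {
  hours <- unique(round(seq(0, 24, length.out = config$n_dev_timepoints)))
  conds <- c(paste0("veg:c", seq_len(config$n_veg_libraries)),
             paste0("dev:h", hours))
  meta <- do.call(rbind, lapply(conds, function(cn) {
    hr <- if (startsWith(cn, "dev:h")) as.numeric(sub("dev:h", "", cn)) else NA
    data.frame(
      library = paste0(cn, ":r", seq_len(config$n_replicates)),
      compartment = if (!is.na(hr) && hr >= 1) "social" else "vegetative",
      condition = cn, hour = hr, stringsAsFactors = FALSE)
  }))
  ng <- nrow(truth)
  vals <- matrix(0, nrow = ng, ncol = nrow(meta),
                 dimnames = list(truth$gene_id, meta$library))
  base <- stats::rnorm(ng, mean = 3, sd = 1)
  soc_cols <- meta$compartment == "social"
  for (g in seq_len(ng)) {
    cls <- truth$class[g]
    if (cls == "conditional_other") next
    cols <- if (cls == "sociality") which(soc_cols) else seq_len(nrow(meta))
    vals[g, cols] <- stats::rlnorm(length(cols), meanlog = base[g], sdlog = 0.3)
  }
  expr_matrix(vals, meta)
}

#' Generate a complete labelled synthetic dataset
#'
#' Assigns each gene to a regime (`sociality`, `conditional_other`,
#' `non_sociality`) per the configured fractions, applies the dilution
#' multiplier to the mutation-accumulation intensity (theta and outgroup
#' divergence) of both conditional regimes at both site classes, simulates
#' genotypes, outgroup, expression and per-strain mapping fractions, and
#' records the truth labels. Deterministic given the configuration
#' (including its seed).
#'
#' @param config A [sim_config()].
#' @return Object of class `synth_dataset`: list with `config`, `cds`
#'   (named list of [gene_cds()]), `variants` (named list of
#'   [variant_matrix()]), `expression` ([expr_matrix()]), `mapping`
#'   (genes x strains matrix) and `truth` (data frame with `gene_id`,
#'   `class`, `is_pav`, `theta`, `divergence`, `n_codons`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  ids <- sprintf("g%04d", seq_len(ng))
  strains <- sprintf("S%03d", seq_len(config$n_strains))
  n_soc <- round(config$frac_sociality * ng)
  n_cond <- round(config$frac_conditional_other * ng)
  cls <- rep("non_sociality", ng)
  pick <- sample.int(ng, n_soc + n_cond)
  cls[pick[seq_len(n_soc)]] <- "sociality"
  if (n_cond > 0) cls[pick[n_soc + seq_len(n_cond)]] <- "conditional_other"
  conditional <- cls != "non_sociality"
  mult <- ifelse(conditional, config$dilution, 1)
  n_codons <- sample(config$codon_counts[1]:config$codon_counts[2], ng,
                     replace = TRUE)
  is_pav <- stats::runif(ng) < unname(config$pav_rate[cls])
  truth <- data.frame(gene_id = ids, class = cls, is_pav = is_pav,
                      theta = config$theta_site * mult,
                      divergence = config$outgroup_divergence * mult,
                      n_codons = n_codons, stringsAsFactors = FALSE)
  cds <- vector("list", ng); vms <- vector("list", ng)
  mapping <- matrix(NA_real_, ng, config$n_strains,
                    dimnames = list(ids, strains))
  for (g in seq_len(ng)) {
    sim <- simulate_gene(ids[g], n_codons[g], config$n_strains,
                         theta_site = truth$theta[g],
                         divergence = truth$divergence[g],
                         sfs_skew = config$sfs_skew,
                         stop_gain_rate = unname(config$stop_gain_rate[cls[g]]),
                         missing_rate = config$missing_rate)
    mapping[g, ] <- if (is_pav[g]) stats::runif(config$n_strains, 0.1, 0.5)
                    else stats::runif(config$n_strains, 0.92, 1.0)
    sim$vm$mapped_cds_length <- as.integer(round(sim$cds$length * mean(mapping[g, ])))
    colnames(sim$vm$geno) <- strains
    cds[[g]] <- sim$cds; vms[[g]] <- sim$vm
  }
  names(cds) <- ids; names(vms) <- ids
  expression <- simulate_expression(truth, config)
  structure(list(config = config, cds = cds, variants = vms,
                 expression = expression, mapping = mapping, truth = truth),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("<synth_dataset> ", length(x$cds), " genes x ", x$config$n_strains,
      " strains (+outgroup); ",
      sum(x$truth$class == "sociality"), " sociality, ",
      sum(x$truth$class == "conditional_other"), " conditional, ",
      sum(x$truth$class == "non_sociality"), " non-sociality\n", sep = "")
  invisible(x)
}

#' Build gene classes with prescribed sociality proportions
#'
#' Samples gene classes that mix the sociality and non-sociality pools at
#' given proportions — the construction under which the proportion-matched
#' null is true, used to exercise the Red King regression.
#'
#' @param truth Truth data frame from [generate_dataset()] (or any data
#'   frame with `gene_id` and `class`).
#' @param props Numeric vector of sociality proportions in \[0, 1\].
#' @param size Class size (genes per class).
#' @param seed Optional integer seed.
#' @return Named list of gene-id vectors (`mix_<prop>`).
#' @export
build_mixture_classes <- function(truth, props, size, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  soc <- truth$gene_id[truth$class == "sociality"]
  non <- truth$gene_id[truth$class == "non_sociality"]
  out <- lapply(props, function(p) {
    k <- round(p * size)
    if (k > length(soc) || (size - k) > length(non))
      stop("requested class infeasible for the pools")
    c(if (k > 0) sample(soc, k) else character(0),
      if (size - k > 0) sample(non, size - k) else character(0))
  })
  names(out) <- paste0("mix_", props)
  out
}
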