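# Expression-based gene classification: the index of social expression
# (ISE), the three-way conditional/sociality partition, cell-type bias
# sets and the low-expression robustness filter.

#' Construct an expression matrix with library metadata
#'
#' @param values Non-negative numeric matrix, genes x libraries, with gene
#'   ids as row names and library ids as column names.
#' @param meta Data frame with one row per library: `library` (matching the
#'   column names), `compartment` (`"vegetative"` or `"social"`; hour-0
#'   developmental libraries are vegetative), `condition` (replicate
#'   grouping; replicates share a condition) and optionally `hour`.
#' @return Object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, meta) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("expression values must be non-negative")
  req <- c("library", "compartment", "condition")
  if (!all(req %in% names(meta))) stop("meta needs columns: ",
                                       paste(req, collapse = ", "))
  if (!setequal(meta$library, colnames(values)))
    stop("meta libraries do not match value columns")
  if (!all(meta$compartment %in% c("vegetative", "social")))
    stop("compartment must be 'vegetative' or 'social'")
  if ("hour" %in% names(meta) &&
      any(meta$compartment[!is.na(meta$hour) & meta$hour == 0] != "vegetative"))
    stop("hour-0 libraries must be labelled vegetative")
  meta <- meta[match(colnames(values), meta$library), , drop = FALSE]
  structure(list(values = values, meta = meta), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " libraries (", sum(x$meta$compartment == "vegetative"),
      " vegetative, ", sum(x$meta$compartment == "social"), " social)\n",
      sep = "")
  invisible(x)
}

# Mean expression per condition (replicates averaged), genes x conditions.
.condition_means <- function(em) {
  conds <- unique(em$meta$condition)
  m <- vapply(conds, function(cn) {
    cols <- em$meta$library[em$meta$condition == cn]
    rowMeans(em$values[, cols, drop = FALSE])
  }, numeric(nrow(em$values)))
  if (is.null(dim(m)))
    m <- matrix(m, nrow = 1, dimnames = list(rownames(em$values)[1], NULL))
  colnames(m) <- conds
  m
}

#' Index of social expression (ISE)
#'
#' The proportion of a gene's total expression that appears in the social
#' libraries: replicates are averaged within condition first, then
#' conditions are averaged within compartment (each condition weighted
#' equally), and ISE = social / (vegetative + social). Undefined (`NA`)
#' when both compartment means are zero.
#'
#' @param em An [expr_matrix()].
#' @return Named numeric vector of ISE values per gene, in \[0, 1\].
#' @export
compute_ise <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  cm <- .condition_means(em)
  comp_of <- em$meta$compartment[match(colnames(cm), em$meta$condition)]
  veg <- rowMeans(cm[, comp_of == "vegetative", drop = FALSE])
  soc <- rowMeans(cm[, comp_of == "social", drop = FALSE])
  tot <- veg + soc
  ise <- ifelse(tot > 0, soc / tot, NA_real_)
  names(ise) <- rownames(em$values)
  ise
}

#' Classify genes into sociality / conditional / non-sociality sets
#'
#' Sociality genes have ISE strictly above the threshold (expression
#' concentrated in the social stage); conditionally expressed non-social
#' genes have zero expression in every library (ISE undefined); all other
#' genes are non-sociality. Externally determined memberships (chimerism,
#' antagonism, cheater, ...) are attached from label tables; labels naming
#' unknown genes are skipped with a warning.
#'
#' @param em An [expr_matrix()].
#' @param label_tables Named list of data frames with a `gene_id` column
#'   (one table per external gene set).
#' @param ise_threshold Sociality cutoff on ISE (strict inequality).
#' @param detection_floor Expression at or below this value counts as
#'   undetected when testing for all-zero genes (default 0, exact zero).
#' @return Data frame (class `gene_class_set`) with `gene_id`, `ise`,
#'   `class` and one logical column per label table.
#' @export
classify_gene_sets <- function(em, label_tables = list(), ise_threshold = 0.9,
                               detection_floor = 0) {
  stopifnot(inherits(em, "expr_matrix"))
  ise <- compute_ise(em)
  all_zero <- apply(em$values, 1, function(v) all(v <= detection_floor))
  cls <- ifelse(all_zero, "conditional_other",
                ifelse(!is.na(ise) & ise > ise_threshold,
                       "sociality", "non_sociality"))
  out <- data.frame(gene_id = rownames(em$values), ise = unname(ise),
                    class = unname(cls), stringsAsFactors = FALSE)
  for (nm in names(label_tables)) {
    ids <- label_tables[[nm]]$gene_id
    unknown <- setdiff(ids, out$gene_id)
    if (length(unknown))
      warning("label table '", nm, "': ", length(unknown),
              " unknown gene id(s) skipped")
    out[[nm]] <- out$gene_id %in% ids
  }
  class(out) <- c("gene_class_set", "data.frame")
  out
}

#' Cell-type expression bias and thresholded bias sets
#'
#' Within each dataset, the prestalk bias of a gene is its prestalk
#' expression divided by its total (prestalk + prespore) expression, with
#' replicates averaged first; the prespore bias is the complement. Biases
#' from the datasets are averaged per gene (datasets with zero total
#' expression for the gene are excluded from the average), and a gene
#' enters a threshold set when its mean bias in *either* cell type reaches
#' the threshold (boundary inclusive).
#'
#' @param datasets List of datasets; each is a list with numeric matrices
#'   (or vectors) `prestalk` and `prespore`, genes x replicates, sharing
#'   row names across datasets.
#' @param thresholds Bias cutoffs defining the sets (default 0.8 and 0.9).
#' @return Data frame with `gene_id`, `prestalk_bias`, `prespore_bias` and
#'   one logical column `bias_set_<t>` per threshold.
#' @export
cell_type_bias <- function(datasets, thresholds = c(0.8, 0.9)) {
  stopifnot(length(datasets) >= 1)
  as_mat <- function(x) if (is.null(dim(x))) matrix(x, ncol = 1,
                                                    dimnames = list(names(x))) else x
  per_ds <- lapply(datasets, function(d) {
    pst <- rowMeans(as_mat(d$prestalk))
    psp <- rowMeans(as_mat(d$prespore))
    tot <- pst + psp
    ifelse(tot > 0, pst / tot, NA_real_)
  })
  genes <- names(per_ds[[1]])
  bias_mat <- vapply(per_ds, function(b) b[genes], numeric(length(genes)))
  if (is.null(dim(bias_mat)))
    bias_mat <- matrix(bias_mat, nrow = length(genes))
  prestalk <- rowMeans(bias_mat, na.rm = TRUE)
  prestalk[is.nan(prestalk)] <- NA_real_
  prespore <- 1 - prestalk
  out <- data.frame(gene_id = genes, prestalk_bias = unname(prestalk),
                    prespore_bias = unname(prespore), stringsAsFactors = FALSE)
  for (t in thresholds) {
    inset <- !is.na(prestalk) & (prestalk >= t | prespore >= t)
    out[[paste0("bias_set_", t)]] <- unname(inset)
  }
  out
}

#' Remove the lowest-expressed genes
#'
#' Summarizes each gene by its maximum expression over all libraries and
#' retains genes at or above the given quantile of that summary. Used to
#' build the robustness subset that discounts leaky low-level expression.
#'
#' @param em An [expr_matrix()].
#' @param quantile Fraction of genes to drop from the bottom (default 0.25,
#'   the bottom quartile).
#' @return Character vector of retained gene ids.
#' @export
filter_low_expression <- function(em, quantile = 0.25) {
  stopifnot(inherits(em, "expr_matrix"), quantile >= 0, quantile < 1)
  summ <- apply(em$values, 1, max)
  cut <- stats::quantile(summ, probs = quantile, names = FALSE)
  rownames(em$values)[summ >= cut]
}
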