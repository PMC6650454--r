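# The Red King null model: proportion-matched permutation nulls per gene
# class, the two-pool mixture expectation, and the sqrt(N)-weighted
# regression of class means on sociality proportion.

#' Proportion-matched permutation null for one gene class
#'
#' Under the Red King null hypothesis, a gene class is an arbitrary mixture
#' of conditionally expressed (sociality) and non-conditional genes, and
#' its mean statistic is predicted by its sociality proportion alone. Each
#' of the `B` draws therefore takes `k` genes from the sociality pool and
#' `N - k` from the non-sociality pool (both without replacement), where
#' `k/N` is the class's observed sociality proportion among genes with a
#' defined statistic.
#'
#' @param values Named numeric vector of the per-gene statistic over all
#'   genes (`NA` = undefined, excluded before drawing).
#' @param class_genes Character vector of gene ids forming the class.
#' @param sociality_genes Character vector of sociality gene ids; every
#'   other gene with a defined value is treated as non-sociality.
#' @param B Number of draws (default 10000; at least 100).
#' @param seed Optional integer seed.
#' @param statistic,class_name Labels recorded in the result.
#' @return A `class_summary` object: `N`, `k`, `prop_sociality`,
#'   `observed_mean`, `expected_mean`, `ci_low`, `ci_high`,
#'   `p_two_tailed`, `B`, `seed`.
#' @export
proportion_matched_null <- function(values, class_genes, sociality_genes,
                                    B = 10000, seed = NULL,
                                    statistic = "statistic",
                                    class_name = "class") {
  if (B < 100) stop("B must be at least 100")
  def <- names(values)[!is.na(values)]
  soc_pool <- values[intersect(def, sociality_genes)]
  non_pool <- values[setdiff(def, sociality_genes)]
  cls <- intersect(class_genes, def)
  k <- sum(cls %in% sociality_genes)
  N <- length(cls)
  if (N < 1) stop("no class gene has a defined value")
  if (k > length(soc_pool) || (N - k) > length(non_pool))
    stop("class composition infeasible for the pools")
  if (!is.null(seed)) set.seed(seed)
  vs <- unname(soc_pool); vn <- unname(non_pool)
  means <- vapply(seq_len(B), function(i) {
    s <- if (k > 0) vs[sample.int(length(vs), k)] else numeric(0)
    ns <- if (N - k > 0) vn[sample.int(length(vn), N - k)] else numeric(0)
    mean(c(s, ns))
  }, 0)
  res <- .perm_result(statistic, class_name, N, mean(values[cls]), means,
                      B, seed)
  res$k <- k
  res$prop_sociality <- k / N
  class(res) <- c("class_summary", class(res))
  res
}

#' Two-pool mixture expectation
#'
#' The expected value of a statistic for a class that mixes the sociality
#' and non-sociality pools at a given proportion:
#' `prop * mean_sociality + (1 - prop) * mean_non_sociality`.
#'
#' @param prop Sociality proportion(s) in \[0, 1\].
#' @param mean_sociality,mean_non_sociality Pool means of the statistic.
#' @return Expected value(s), linear in `prop`.
#' @export
mixture_line <- function(prop, mean_sociality, mean_non_sociality) {
  stopifnot(all(prop >= 0 & prop <= 1))
  prop * mean_sociality + (1 - prop) * mean_non_sociality
}

# Weighted least squares of class means on sociality proportion with the
# weighted coefficient of determination.
.wls_fit <- function(prop, means, w) {
  fit <- stats::lm(means ~ prop, weights = w)
  mbar <- sum(w * means) / sum(w)
  ss_tot <- sum(w * (means - mbar)^2)
  ss_res <- sum(w * stats::residuals(fit)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(coef = stats::coef(fit), r_squared = r2)
}

#' Weighted regression of class means on sociality proportion
#'
#' Fits the Red King relationship across gene classes: the class mean of an
#' evolutionary statistic regressed on the class's proportion of sociality
#' genes, weighting each class by the square root of its size. A
#' permutation p value for the fit reassigns genes to classes at random
#' (preserving class sizes, hence destroying the sociality proportions)
#' and recomputes the class means, proportions and the weighted R-squared;
#' p = (1 + #\{R2_perm >= R2_obs\}) / (B + 1).
#'
#' @param values Named numeric vector of the per-gene statistic (`NA` =
#'   undefined).
#' @param classes Named list of character vectors: the gene classes
#'   (classes may overlap).
#' @param sociality_genes Character vector of sociality gene ids.
#' @param B Number of permutations for the fit p value (default 2000).
#' @param seed Optional integer seed.
#' @param statistic Label recorded in the fit.
#' @return An object of class `redking_fit` with `slope`, `intercept`,
#'   `r_squared`, `p_perm`, per-class `summary` data frame, the mixture
#'   line endpoints `mean_sociality` and `mean_non_sociality`, `B`, `seed`.
#' @export
weighted_regression <- function(values, classes, sociality_genes, B = 2000,
                                seed = NULL, statistic = "statistic") {
  def <- names(values)[!is.na(values)]
  cls_def <- lapply(classes, intersect, def)
  N <- vapply(cls_def, length, 0L)
  if (sum(N >= 1) < 3) stop("need at least 3 classes with defined means")
  k <- vapply(cls_def, function(g) sum(g %in% sociality_genes), 0L)
  prop <- k / N
  if (stats::sd(prop) == 0) stop("all classes have identical sociality proportion")
  means <- vapply(cls_def, function(g) mean(values[g]), 0)
  w <- sqrt(N)
  obs <- .wls_fit(prop, means, w)
  soc_pool <- intersect(def, sociality_genes)
  non_pool <- setdiff(def, sociality_genes)
  is_soc <- stats::setNames(def %in% sociality_genes, def)
  vdef <- values[def]
  if (!is.null(seed)) set.seed(seed)
  nd <- length(def)
  r2_perm <- vapply(seq_len(B), function(i) {
    pm <- vapply(seq_along(N), function(j) {
      idx <- sample.int(nd, N[j])
      c(mean(vdef[idx]), sum(is_soc[idx]) / N[j])
    }, numeric(2))
    if (stats::sd(pm[2, ]) == 0) return(0)
    .wls_fit(pm[2, ], pm[1, ], w)$r_squared
  }, 0)
  p_perm <- (1 + sum(r2_perm >= obs$r_squared)) / (B + 1)
  structure(
    list(statistic = statistic,
         slope = unname(obs$coef[2]), intercept = unname(obs$coef[1]),
         r_squared = obs$r_squared, p_perm = p_perm,
         summary = data.frame(class = names(classes), N = unname(N),
                              k = unname(k), prop_sociality = unname(prop),
                              observed_mean = unname(means),
                              stringsAsFactors = FALSE),
         mean_sociality = mean(values[soc_pool]),
         mean_non_sociality = mean(values[non_pool]),
         B = B, seed = seed),
    class = "redking_fit"
  )
}

#' @export
print.redking_fit <- function(x, ...) {
  cat("<redking_fit> ", x$statistic, ": mean ~ proportion of sociality genes",
      " (weights sqrt(N))\n",
      "  slope ", format(x$slope, digits = 5),
      ", intercept ", format(x$intercept, digits = 5),
      ", R^2 = ", format(x$r_squared, digits = 4),
      ", permutation p = ", format(x$p_perm, digits = 4),
      " (B = ", x$B, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
coef.redking_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Plot a Red King fit
#'
#' Observed class means against sociality proportion (point size scaled by
#' `sqrt(N)`), the dashed two-pool mixture expectation, the solid weighted
#' regression line, and (when class summaries from
#' [proportion_matched_null()] are supplied) expected points with 95%
#' interval whiskers.
#'
#' @param x A `redking_fit`.
#' @param summaries Optional list of `class_summary` objects (one per
#'   class) providing expected means and intervals.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.redking_fit <- function(x, summaries = NULL, ...) {
  s <- x$summary
  ylim <- range(s$observed_mean,
                if (!is.null(summaries))
                  unlist(lapply(summaries, function(z) c(z$ci_low, z$ci_high))))
  graphics::plot(s$prop_sociality, s$observed_mean, xlim = c(0, 1),
                 ylim = ylim, pch = 19, col = "steelblue",
                 cex = 0.6 + 1.4 * sqrt(s$N) / max(sqrt(s$N)),
                 xlab = "proportion of sociality genes",
                 ylab = x$statistic, ...)
  graphics::abline(a = x$mean_non_sociality,
                   b = x$mean_sociality - x$mean_non_sociality,
                   lty = 2, col = "grey40")
  graphics::abline(a = x$intercept, b = x$slope, col = "black")
  if (!is.null(summaries)) {
    ep <- vapply(summaries, function(z)
      c(z$prop_sociality, z$expected_mean, z$ci_low, z$ci_high), numeric(4))
    graphics::segments(ep[1, ], ep[3, ], ep[1, ], ep[4, ], col = "firebrick")
    graphics::points(ep[1, ], ep[2, ], pch = 19, col = "firebrick", cex = 0.8)
  }
  invisible(x)
}
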