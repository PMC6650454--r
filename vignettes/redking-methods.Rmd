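---
title: "Detecting diluted selection at conditionally expressed genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diluted selection at conditionally expressed genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

In facultatively social microbes such as *Dictyostelium discoideum*, a
large set of genes is expressed only during the multicellular (social)
stage, which occurs once per many vegetative generations. Selection on
such conditionally expressed genes is *diluted* by the generations in
which they are silent: drift plays a proportionally larger role, so both
standing polymorphism and the rate of substitution are expected to rise —
at synonymous and nonsynonymous sites alike. We refer to this
dilution-of-selection scenario as the Red King process, in contrast to
conflict-driven Red Queen dynamics (selective sweeps or balancing
selection), which make site-class-specific predictions instead.

`redking` implements the full inferential machinery for distinguishing
these hypotheses from a strain panel and expression data:

1. **Per-gene statistics** — nucleotide diversity per site (π/site) and
   SNP density for CDS, nonsynonymous and synonymous sites; Tajima's D;
   Fu & Li's D* and F*; Wall's B and Q; stop-gain annotation;
   presence/absence (PAV) classification; and, against a divergent
   outgroup, the McDonald–Kreitman (MK) table and test, the Direction of
   Selection (DoS), and NG86 Ka/Ks.
2. **Expression classification** — the index of social expression
   (ISE = mean social expression / (mean vegetative + mean social)),
   the sociality / conditional / non-sociality partition, cell-type bias
   sets, and a low-expression robustness filter.
3. **Randomization inference** — class-vs-background expected values and
   95% intervals from random gene sets of matched size, two-tailed
   permutation p values, categorical enrichment, OLS covariate
   adjustment, BH-FDR, and an ISE-correlation permutation test.
4. **The Red King null model** — proportion-matched permutation nulls, a
   two-pool mixture expectation line, and a √N-weighted regression of
   class means on the class's proportion of sociality genes, with a
   permutation p value for the fit.
5. **A synthetic-data generator** whose regimes encode the Red King
   hypothesis, so every stage can be exercised and calibrated end to end.

## Statistical model and conventions

**Genotypes are haploid.** One call per strain per site (amoeba strains),
coded reference / alternative / missing. All per-site frequencies use the
non-missing calls at that site; a site with fewer than two calls is
dropped and the mapped length reduced accordingly.

**π and S.** The per-site pairwise-difference contribution is
`2 p (1 − p) n/(n − 1)` with `p` the alternative-allele frequency and `n`
the site's call count — identical to explicit enumeration of differing
strain pairs, which is how the test suite verifies it. Per-site scaling
divides by mapped length × site-class fraction. By default the class
fraction is the gene's exact NG86 site count (each codon position
contributes the fraction of its three possible changes that are
synonymous); a fixed global split (e.g. 78% nonsynonymous / 22%
synonymous) can be supplied instead to mirror genome-wide scaling
conventions.

**Effective sample size with missing data.** Tajima's D and Fu & Li's
D*/F* need a single `n` for their normalizing constants, but missing
calls make `n` site-specific. We use the median call count across the
gene's segregating sites. The upstream site filter (≥ 90% called)
bounds the spread of per-site `n`, so the choice has little leverage;
it is declared rather than inferred from any reference implementation.

**Wall's B and Q.** Computed on the haploid haplotypes as given. A pair
of adjacent segregating sites is congruent when the two sites induce the
same bipartition of the strains called at both; B is the congruent
fraction and Q = (B(S−1) + A)/S where A counts distinct congruent
partition types.

**MK, DoS, Ka/Ks.** A site is a fixed difference only when the ingroup
is monomorphic at it (missing calls ignored; no ancestral-state
inference) and the outgroup differs; segregating sites are never counted
as fixed. Stop-gain variants count with the nonsynonymous class. The MK
test is the two-sided Fisher exact test on [[Dn, Ds], [Pn, Ps]]; a table
with a zero margin carries no information and is reported as p = 1.
Ka/Ks uses NG86 counting: site totals averaged over the two sequences,
per-codon differences averaged equally over minimal mutational pathways
(pathways through stop codons excluded unless all are), and a
Jukes–Cantor correction per class; the ratio is undefined when Ks is 0
or a correction diverges (saturation). NG86 was chosen over Li-style
counting because it is fully specifiable and testable against an
independent enumeration oracle; the interface reserves a method switch.

**ISE and classification.** Replicates are averaged within condition
first; condition means are then averaged within compartment with equal
weight per condition (not per library) — the definition is ambiguous
between the two and this choice is declared. Hour-0 developmental
libraries count as vegetative. Sociality requires ISE strictly above 0.9;
genes with zero expression in every library form the separate
conditional class (ISE undefined); "zero" is an exact zero by default,
with a configurable detection floor for normalized real data. The
cell-type bias threshold is inclusive (mean bias ≥ 0.8 enters the 0.8
set), matching the stated rule; the 0.9 set is a subset of the 0.8 set
by construction. PAV status (mean mapping ≤ 0.5, boundary inclusive)
excludes a gene from all quantitative statistics; PAV genes are analysed
only through categorical enrichment.

**Randomization framework.** Groups are compared against the pool formed
by the group plus its background by drawing B = 10,000 (default) random
sets of the group's size *without replacement* — the finite gene universe
makes the without-replacement null the natural one, and it reproduces the
hypergeometric law for categorical counts (verified in the tests by total
variation distance). Undefined values are excluded before drawing, so
every null draw averages as many genes as the observed group. The
two-tailed p doubles the smaller tail count, capped at 1 and floored at
1/B: a permutation p of exactly zero is never reported. Covariate
adjustment regresses a statistic on mapped CDS length and maximum
expression (linear and quadratic each) by OLS after removing the bottom
quartile of lengths (short genes give noisy, downward-biased statistics);
the adjusted value is residual + pool mean so raw and adjusted results
share a scale. OLS residualization stands in for a mixed-model fit whose
exact specification is not recoverable; both raw and adjusted results are
reported so the adjustment is never load-bearing in silence.

**The Red King null.** For a class of N genes containing k sociality
genes, each null draw takes k genes from the sociality pool and N−k from
the non-sociality pool. If class membership is unrelated to selection
given conditionality, the class mean must match this proportion-matched
expectation, and class means across classes must fall on the mixture
line `E(prop) = prop × mean_soc + (1 − prop) × mean_non_soc`. The
weighted regression of class means on sociality proportion uses weights
√N and reports the weighted R². Its permutation p value reassigns genes
to classes preserving class sizes only (destroying the proportions) and
recomputes everything; this permutation unit is our construction — the
alternative units are not distinguishable from the published description
— and is therefore documented and isolated so another scheme can be
substituted. Classes may overlap; draws are independent per class.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions the package is calibrated to: 67 haploid strains, one
divergent outgroup, ~13% sociality genes, seven vegetative conditions
and 18 developmental time points (hours 0–24, two replicates each), 2%
missing calls, and a site frequency spectrum tilted toward rare variants.

* Segregating sites per class are Poisson with mean
  `theta × a1(n) × L_class` (inverting Watterson's estimator), so
  `theta` is the expected pairwise diversity per site. Default 0.01 —
  a realistic order for a diverse microbial eukaryote panel.
* Derived-allele counts follow `P(i) ∝ i^−(1+sfs_skew)`. `sfs_skew = 0`
  is the neutral 1/i spectrum (verified by a χ² goodness-of-fit test);
  the default 0.3 yields the negative average Tajima's D regime that
  motivates the threshold-enrichment analyses. The skew is chosen to
  reproduce the *sign* of the study system's D, not a particular
  magnitude, because the empirical spectrum is not published.
* The `dilution` multiplier (default 2) scales both `theta` and outgroup
  divergence of conditionally expressed genes at both site classes —
  the defining Red King signature. Setting it to 1 produces the global
  null used by the calibration tests.
* Outgroup divergence (default 0.08 substitutions/site) is Poisson per
  class; outgroup substitutions never create an in-frame stop.
* Stop-gain SNPs are injected per regime (default 5% of sociality /
  conditional genes, 3.5% of others) and PAV genes likewise (0.7% vs
  0.3%) — the same direction and order of enrichment the categorical
  machinery is meant to detect.
* Sociality genes are silent in vegetative libraries and at hour 0 and
  log-normal at hours ≥ 1 (recomputed ISE exactly 1); conditional genes
  are silent everywhere (ISE undefined); other genes share one
  log-normal across compartments (mean ISE ≈ 0.5).

What the generator does **not** emulate: linkage between genes,
recombination within genes, demography, alignment/calling error,
expression noise that blurs the ISE boundary, and indels (the loader
skips indel records; the generator never emits them). Passing tests
therefore demonstrate correctness and calibration of the *inference
machinery* under the stated model, not robustness to the full
complexity of real panels.

## Numerical choices and degenerate inputs

* Undefined statistics are `NA` throughout and excluded from group
  means; they are never zero-filled, and output TSVs keep them as empty
  fields.
* Tajima's D requires S ≥ 1 and n ≥ 4; Wall's statistics require S ≥ 2;
  DoS requires both margins positive; the correlation test refuses
  fewer than 10 complete pairs or a constant statistic; the weighted
  regression refuses classes with identical proportions.
* Filter order is fixed and logged: strains by missing rate (> 0.3
  dropped), then sites by call rate (< 0.9 of remaining strains), then
  record-type exclusions (indel/multiallelic, handled at load).
  Input site counts equal retained plus dropped at every step.
* Fixture TSVs print doubles with `%.17g`, making write/read round trips
  bit-exact; report TSVs round to 10 significant digits for diffability.

## Problem sizes used by the test suite

The acceptance tests run the full recovery analysis at 2,000 genes × 40
strains × 20 seeded replicates (with 2,000-draw nulls) for the dilution
signature, and 1,000 genes × 3 seeds for the mixture-line regression;
oracle-equivalence checks use 50 randomized instances at n ≤ 12 strains.
Gene lengths in these runs are drawn from 40–100 codons. These sizes were
chosen so the suite completes comfortably on a single CPU while leaving
the Monte-Carlo error of every asserted quantity an order of magnitude
below its acceptance margin.

## Worked example

```{r, eval = FALSE}
library(redking)

cfg <- run_config(
  simulate = sim_config(n_genes = 500, n_strains = 40,
                        codon_counts = c(40, 100), dilution = 2, seed = 1),
  permutations = 2000, seed = 1, out_dir = "redking-out")
report <- run_pipeline(cfg)
print(report)

# Red King regression for nucleotide diversity
plot(report$redking$pi_site_cds)
```

## Known limitations

* Fixed differences use no ancestral-state inference; back-mutations at
  high divergence bias Dn/Ds slightly downward (partially absorbed by
  the Jukes–Cantor correction in Ka/Ks, not in the MK counts).
* The MK test's significance feeds the pipeline-level FDR; no per-gene
  multiplicity scheme beyond that is applied.
* Covariate adjustment is OLS residualization, not a mixed model.
* The permutation unit for the regression p value is a package design
  choice (see above).
* Sliding-window/genomic-block statistics and haplotype-based selection
  scans are intentionally out of scope: all statistics are per-gene on
  the CDS.
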