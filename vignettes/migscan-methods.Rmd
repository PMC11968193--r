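---
title: "Methods: replicated resident-migrant selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicated resident-migrant selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design

`migscan` analyses a replicated contrast between resident and migrant
populations. The unit of inference is a *case comparison*: one resident
population set against one migrant population set within a clade. Because
any two populations differ at many loci for purely demographic reasons,
each case comparison is paired with *control comparisons* — contrasts
between two migrant populations of the same clade, and between two resident
populations of the same clade — whose outliers mark differentiation that
cannot be attributed to the migratory phenotype. Candidates that replicate
across case comparisons after control exclusion are then classified at two
resolutions: the same variant shared across comparisons (parallel evolution
at the SNP level) versus the same gene hit by different variants
(parallelism at the genic level), with the remainder read as convergence
through different genes.

## Statistics

**Hudson F_ST.** Per site, with alternate-allele frequencies `p1`, `p2`
and called-allele counts `n1`, `n2`:

    num = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)
    den = p1(1-p2) + p2(1-p1)

The finite-sample correction makes the numerator unbiased for the squared
frequency difference, so under the simulator's drift model the genome-wide
ratio of sums recovers the drift parameter analytically (see *Calibration*
below). Windows (50 kb span, 25 kb step, tiling from coordinate 0) take the
ratio of summed numerators to summed denominators over their defined sites
— never a mean of per-site ratios, which would overweight low-information
sites. Negative site values are retained; sites where both populations are
fixed for the same allele are undefined and excluded. The estimator choice
is this package's: robust to unequal sample sizes and with a closed-form
expectation under the simulator, which gives the acceptance suite an
analytic surface to test against.

**Outlier calling and exclusion.** Outliers are values strictly above the
empirical 99th percentile (linear-interpolation quantile; ties at the
threshold are not flagged — the only reading under which "the top
percentile" is non-empty and at most 1%). Case outliers are removed when
they overlap any control outlier. Site-level case sets are excluded against
both control sites (which degenerates to exact-position matching) and
control outlier *windows*: a control-visible divergence is a region, and a
case variant inside that region is explained by demography even if its
exact position was not itself a control outlier. Window-level case sets are
excluded against control windows and then merged (half-open semantics;
book-ended windows do not merge).

**PCA selection scan.** Dosages are standardized per site (missing calls
mean-imputed, centered by `2p`, scaled by `sqrt(2p(1-p))`). For component
`k` with unit sample-eigenvector `v` and eigenvalue `lambda`, the per-site
statistic measures `corr^2(z_j, v) / lambda`. The eigenvalue normalization
absorbs the optimism of estimating `v` from the same data (the leading
eigenvalue of a finite sample covariance exceeds 1 even without structure);
without it the genome-wide statistic is inflated by roughly `lambda` and
null p-values fail uniformity. The exact null law of the normalized squared
correlation at `n` samples is Beta(1/2, (n-2)/2); the statistic is mapped
to its chi-squared(1) equivalent deviate so that the conventional
chi-squared conversion applies and stays calibrated at the sample sizes
this design uses (tens of individuals), where the raw `(n-1) r^2`
approximation is visibly miscalibrated. The default component is PC1 of the
clade-restricted sample set — the resident/migrant axis under this design —
and `p < 0.05` flags a signal.

**XP-EHH.** EHH over an inclusive span of sites is the probability that two
haplotypes drawn from the set are identical over the span, computed by
partition refinement (`sum_g C(m_g,2) / C(m,2)`). For the cross-population
form, all of a population's haplotypes are pooled (no allele partition at
the core beyond the core site itself, so the curve starts at the core-site
homozygosity); iHH is the trapezoidal integral of the decay curve over
physical distance, extended in both directions and truncated at the first
point below EHH = 0.05 (that segment is not added; extension also stops at
the chromosome ends). The unstandardized score is `ln(iHH_A / iHH_B)`,
standardized genome-wide (unbinned) to mean 0, sd 1. Significance is
rank-based: `p = rank(|score|) / L` with ties sharing the mean rank, called
at `-log10(p) > 2` (strict), i.e. the top 1% of |scores| minus the boundary
rank. Distances are physical base pairs — the design has no genetic map —
and the 0.05 truncation and unbinned normalization follow the statistic's
conventional defaults. The core loop is compiled (Rcpp): each outward step
refines the haplotype partition in O(haplotypes), which is what makes
whole-scan XP-EHH feasible at the default 20,000 sites. The implementation
is verified exactly (to 1e-10) against an exhaustive pair-enumeration
oracle on small inputs.

**Gene proximity and classification.** All interval arithmetic is 0-based
half-open, converted once at the I/O boundary (VCF positions are 1-based;
BED is half-open; GFF is converted on read). A gene is associated with an
outlier item when the gap between the intervals is at most 25,000 bp,
boundary inclusive. Venn regions are exclusive; by construction their
counts sum to the union and `shared_all <= shared_multi <= union` is
asserted on every report. Directionality concordance takes, per shared item
and per sharing comparison, the sign of the standardized XP-EHH score at
the best (largest |score|) significant site overlapping the item; an item
with an undetermined sign in any sharing comparison is excluded from the
concordant fraction's denominator. The best-site rule and the inclusive
25 kb boundary are this package's choices where the procedure is otherwise
underdetermined. The simplified functional categorizer labels items genic
(overlapping a gene), proximal-regulatory (within 25 kb, not overlapping)
or intergenic; it deliberately replaces codon-level effect prediction,
which is out of scope.

## Population structure utilities

**Single-read sampling.** One allele is drawn uniformly from each sample's
two at every site — a genotype-level proxy for sampling a single sequencing
read, which removes depth-dependent bias when coverage varies. Draws are
coded 0/1, centered by the site's sampled-allele frequency, scaled by
`sqrt(p(1-p))`; a pair's covariance averages the product over sites where
both are called, excluding sites monomorphic in the draw. This
standardization is this package's definition (the read-level original
leaves it unstated); the resulting scale puts a duplicated sample near 0.5
and unrelated samples near 0, so the 0.3 relatedness threshold separates
the two regimes cleanly.

**Relatedness filtering** builds a graph over pairs with covariance at or
above the threshold and keeps, per connected component, the sample with the
highest call rate (ties break lexicographically) — the component-wise rule
generalizes keep-one-per-pair to related clusters; the call-rate tie-break
is this package's choice.

**Windowed nucleotide diversity** uses
`pi_site = 2 c_ref c_alt / (n (n-1))` on called alleles and divides each
10 kb window's sum by the window length in bp, so positions absent from the
variant set count as invariant; the caller supplies chromosome lengths and
the final partial window uses its true length. Input should be unfiltered
for MAF. The statistic is invariant to ref/alt relabelling.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
the biology that produced it:

- **Hierarchical Balding–Nichols frequencies.** Ancestral frequencies are
  uniform on [0.05, 0.5]; clade frequencies are Beta-distributed around
  them with variance `F_clade p(1-p)` (default 0.15, deep divergence), and
  population frequencies likewise around the clade value with `F_pop`
  (default 0.02, within-clade structure). Beta draws are clipped to
  [1e-6, 1-1e-6] so sites stay polymorphic at the expected-frequency level;
  sampling can still fix sites, and every downstream statistic handles
  that. The closed-form consequence `E[Hudson F_ST] = F_pop` is the
  acceptance surface for the whole frequency pipeline.
- **Founder-mosaic haplotypes.** Per population, 8 x n_diploids founder
  haplotypes are drawn site-wise Bernoulli at the population frequency;
  each output haplotype copies a founder and switches to a random founder
  with probability 0.05 between adjacent sites. This produces
  distance-decaying linkage disequilibrium sufficient for EHH statistics
  with trivial implementation — no coalescent, no genetic map, no gene
  conversion. The founder pool is 4 times the haplotype sample so that
  pool resampling adds only O(1/founders) (~0.005) to between-population
  differentiation, keeping the F_ST recovery band honest.
- **Planted hard sweeps.** A sweep replaces 90% of a population's
  haplotypes with copies of one donor haplotype over a 50 kb radius around
  a gene midpoint — the post-sweep signature (one long haplotype above the
  80% frequency regime) without forward simulation. Sweeps assigned to a
  resident *unit* (e.g. two pooled resident populations analysed together)
  share one donor allele vector across the unit's populations, modelling
  selection on shared standing variation; without a shared donor the
  resident–resident control would flag the gene and the exclusion step
  would delete exactly the parallel signal the design exists to find.
  Clade-wide background sweeps instead use an independent donor per
  population, producing control-visible divergence in every within-clade
  contrast.
- **Default geometry.** One 100 Mb chromosome, 20,000 SNPs (one per 5 kb),
  30 genes of 10 kb, 8 populations x 12 diploids, nine resident-unit
  sweeps and one clade-wide sweep. The sparse candidate-panel-style
  annotation is deliberate: with ~170 outlier sites per comparison at the
  99th percentile, the chance rate of a given gene acquiring an outlier
  within 25 kb must stay below a few percent for the null Venn triple
  region to be empty — a design assumption of the replicated-comparison
  logic itself. Density much above this (or a much shorter chromosome)
  breaks that assumption by geometry alone, not by any failure of the
  statistics. These defaults are chosen for signal visibility and internal
  consistency of the design, not biological realism; no split times or
  effective sizes are modelled.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: realistic allele-frequency spectra and mutation
processes, recombination-rate variation, soft or incomplete sweeps,
background selection, sequencing error and genotype uncertainty (inputs are
hard calls; the single-read sampler is a proxy, not a read model), and
reference bias. Missing data beyond an optional uniform masking rate is not
simulated.

## Determinism and numerical choices

Every stochastic step derives from one integer seed (simulation stages use
fixed offsets; the single-read draw uses `seed + 10`), restoring the
caller's RNG state afterwards; identical config and seed give byte-identical
outputs. Degenerate inputs have defined behaviour throughout: undefined
allele frequencies are flagged rather than coerced to 0, windows with no
defined F_ST site are omitted, sites with zero iHH on either side are
dropped from XP-EHH with a logged count, monomorphic sites are excluded from
standardized-dosage statistics, and the percentile caller warns and returns
nothing when given fewer values than the percentile can resolve. The
relatedness filter's output is independent of sample order up to its
documented tie-break.

## Problem sizes in the test and acceptance suites

Module tests run on hand-built toys and small cohorts (~3,000 sites, 8
diploids per population). The calibration suites use the default scenario:
F_ST recovery averages 10 seeds of 2 x 25 diploids at 20,000 sites; the
XP-EHH oracle comparison enumerates 100 random toys of at most 16
haplotypes x 20 sites; sweep recovery and null calibration each run the
full pipeline on 10 seeds of the default cohort (96 samples x 20,000
sites), the null runs skipping the haplotype scans they do not assess.

## Known limitations

- Control exclusion can also remove true case signal when a sweep is
  private to one resident population: that population's resident–resident
  contrast sees the sweep. This is inherent to the design, which trades
  sensitivity to private sweeps for robustness to shared demography;
  detection through XP-EHH is unaffected.
- Rank-based XP-EHH significance fixes the significant fraction at 1% by
  construction; it localizes the strongest signals rather than testing a
  null.
- The F_ST estimator's recovery of the drift parameter carries a small
  positive offset (~ +1/founders from the generator's founder pool), well
  inside the ±0.02 acceptance band.
- Genotype-likelihood input is not supported; the pipeline assumes called,
  optionally phased genotypes, with phasing done upstream.
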