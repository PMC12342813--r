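---
title: "Methods: models, simulations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episelect)
```

# The scientific setting

`episelect` analyses selection experiments on genetically uniform
*Arabidopsis thaliana* accessions in which replicate populations evolved
under different herbivory regimes and their offspring were later phenotyped
in a common environment. Because plants within an accession are
(near-)isogenic, any heritable phenotypic response to the selection
treatments points at epigenetic rather than genetic variation — provided the
accessions really are what their labels claim, which is why the package also
ships a genotype-based identity check. The package covers four stages:

1. a multi-stratum sequential ANOVA with planned orthogonal contrasts,
2. a Monte-Carlo power study over the experiment's full design,
3. sample-identity QC from allele-sharing distances, and
4. downstream methylome statistics (per-cytosine tests, epigenetic
   distances, multivariate dispersion).

Every stage is exercisable on synthetic data whose generators are themselves
first-class, tested code.

# The linear model and its error strata

The phenotypic design crosses five blocks (`BL`, with a one-degree-of-freedom
contrast `EX` separating blocks 1–3 from 4–5, which differed in growth
substrate) and 75 trays (`TR`) with three accessions (`ET`), 18 replicate
selection populations plus one shared ancestral pseudo-population (`LI`), and
261 maternal lines (`MO`). The selection treatment has four levels —
ancestral, control, and two aphid regimes (*B. brassicae*, BB; *L. erysimi*,
LE) — decomposed into three orthogonal one-degree-of-freedom contrasts:

* `AN = (3, -1, -1, -1)` — ancestral vs all selected material,
* `CO = (0, 2, -1, -1)` — control vs the two aphid treatments,
* `SE = (0, 0, 1, -1)` — the two aphid treatments against each other.

F tests are invariant to rescaling a contrast, so only orthogonality and the
zero sums are load-bearing; the integer coding is a convention. Two model
term orders are supported:

```
m1: EX + BL + TR + AN + CO + SE + LI + ET + (AN + CO + SE + LI):ET + MO
m2: EX + BL + TR + AN + CO + SE + LI + ET + EX:(AN + CO + SE + LI) + EX:ET + LI:ET + MO
```

Sums of squares are sequential (Type I): each term's SS is the reduction in
residual SS when it enters after everything to its left. On the unbalanced
realized design this attribution depends on the order, which is exactly the
formula order above; aliased columns are dropped in entry order with degrees
of freedom adjusted. Internally the model matrix is assembled block by block
and decomposed once by a pivoted QR; a response costs a single projection,
which is what makes the power study cheap (the layout is a constant of the
experiment, so the decomposition is shared across simulation replicates).
The implementation is checked in the test suite against two independent
routes: a brute-force successive-projection oracle on small designs, and
`anova(lm(...))` with `keep.order = TRUE` on the full design.

Hypothesis tests use the design's error strata rather than the residual for
everything: the treatment contrasts are tested against population identity
(`LI`); interactions of the contrasts with accession, or with the block
contrast, against `LI:ET`; accession against maternal lines (`MO`); the
remaining nuisance terms (blocks, trays, `LI`, `LI:ET`, `MO`) against the
residual stratum. A stratum whose realized degrees of freedom are zero marks
its dependent tests `p_defined = FALSE` instead of silently returning `NA`.

**The ancestral pseudo-population.** Ancestral plants did not stem from
replicate populations. They receive one shared `LI` level (`"A"`), giving
`LI` 18 + 1 levels. A per-accession ancestral label was considered and
rejected: those indicator columns are jointly absorbed by the `LI` and `ET`
main effects, which aliases the `AN:ET` interaction completely (zero df),
whereas the analysis is meant to test this interaction — the shared level is
the coding that keeps it estimable.

**A structural caveat for `AN`.** The ancestral group is a *single*
population-level unit of roughly 460 plants, facing eighteen units of
roughly 80 plants. The sequential F of `AN` against `LI` weights the
ancestral unit's effect by its plant count, so when ancestral material
carries population-level (seed-lot) variance comparable to the selection
populations, this test is anticonservative (measured null rejection ≈ 0.30
at α = 0.05 in the package's calibration runs); if ancestral material
carries none, the same test is conservative instead. No choice of variance
components centres it at the nominal level — this is a property of testing a
one-unit group against a stratum of many small units, and a reason to read
`AN` p-values from this design with caution. `CO` and `SE` compare balanced
sets of populations and hold their nominal level (measured 0.058 and 0.062
over 500 null replicates).

## Transformation choice and outlier handling

`choose_transformation()` refits the model under the admissible candidates
(identity always; square root for non-negative traits; natural log for
strictly positive traits) and keeps the one with the largest Shapiro–Wilk W
on the residuals, identity winning ties. The log requires positivity; an
optional shift by the smallest positive value is off by default.

`rout_outliers()` adapts the ROUT procedure (robust fit + FDR-controlled
outlier detection) to grouped univariate data, grouping by accession and
selection treatment: the group median is the "fit", the robust scale is the
68.27th percentile of absolute residuals times `n/(n-1)`, and points are
examined from the most extreme inwards, flagging the i-th most extreme when
its two-sided t probability falls below `Q (n - i + 1)/n`. ROUT was defined
for nonlinear regression; the intercept-only model per group is its natural
degenerate case. Flags are returned, the data never mutated.

# The phenotype generator and the power study

`simulate_phenotypes()` draws, for each plant,

```
trait = grand_mean + EX offset + block + tray + accession + population
        + mother + residual (+ treatment offset)
```

with independent normal effects per level — the same error model the ANOVA
assumes. On the log scale (used for trichome density) the effects are
log-normal multipliers and a fractional effect `f` scales a group by
`(1 + f)`. Five treatment-effect scenarios are supported: (i) all four
groups differ by cumulative steps of `f` (ordered ancestral < control < BB
< LE, so the largest gap is `3f`); (ii) only ancestrals differ; (iii) only
controls; (iv) both aphid treatments; (v) one aphid treatment (LE).
Effect sizes are fractions of the grand mean.

**Default variance components.** The magnitudes are calibrated so the
expected percent sums of squares roughly match the variance shares such
experiments report (blocks dominant for most traits, accession dominant for
bolting time) at field-realistic grand means and coefficients of variation;
the tray share, which such tables fold into the residual, is set to a small
2%. For example, the
bolting profile uses a 30-day grand mean with SDs (block 1.2, tray 0.7,
accession 2.4, population 1.5, mother 1.4, residual 3.6) days and a 0.7-day
block-contrast deficit; trichome density is log-normal with total log-SD
0.38 (CV ≈ 39% — trichome counts are notoriously variable), two accessions
(the third lacks trichomes) and the correspondingly reduced 174 maternal
lines. All values are plain constructor arguments and fully overridable;
they were fixed from those reported variance shares, not adjusted afterwards.

**What the generator does not emulate.** Real populations differ partly
through accession composition rather than true population divergence; traits
are generated independently rather than with their empirical correlations;
there is no spatial structure within trays; missingness is absent unless
injected. Passing tests therefore demonstrate that the *pipeline* behaves as
specified under the design's own error model, not that any particular
biological effect exists in real data.

`run_power()` simulates replicate datasets per scenario-by-effect cell,
analyses each with model `m1` and the strata above, and applies a
scenario-matched detection rule at α: scenario (ii) is detected by `AN`,
(iii) and (iv) by `CO`, (v) by `SE`, and (i) by any of the three (a
deliberately conservative reading of "significant outcome" for the
all-groups-differ setting). Replicate seeds derive deterministically from
the master seed; power comes with its exact Monte-Carlo standard error
`sqrt(p(1-p)/n)`. The conventional summary across settings is the pooled
fraction of significant outcomes over scenarios (i)–(v); with the default
profiles this exceeds 0.80 at a 10% effect for the non-trichome traits,
while trichome density first reaches 0.80 at 20% on the
{1, 5, 10, 15, 20}% grid — the quantities `scripts/acceptance.R` recomputes.
The default is 1000 replicates per cell; the script and tests use 200 per
scenario (1000 pooled per effect size), which resolves power to about one
percentage point.

# Genotype-based sample identity QC

RNA-seq or resequencing genotypes are reduced to biallelic dosages (0/1/2).
`filter_variants()` applies the two rules in fixed order: coverage between
10 and 1000 in at least four plants of *every* accession-by-treatment cell,
then removal of variants with minor allele frequency below 5% over all
samples. `allele_distance()` computes the fraction of alleles differing
between two plants, `mean(|dosage_a − dosage_b|)/2` over jointly typed
variants (missing sites excluded pairwise; pairs with fewer than 100 shared
sites are flagged unreliable — RNA-seq genotypes are sparse). Pairs are
classified within-line / within-accession / between-accession, with
within-line taking precedence; the mix-up flag line is the within-line mean
plus three sample standard deviations (n−1 denominator; the estimator is a
package choice). `assign_accessions()` maps every sample to its nearest
reference-panel accession (deterministic lexicographic tie-break), and
`confounding_report()` flags each labelled cell whose samples' modal
assignment disagrees with the label — the signature of a treatment-confounded
mix-up, as opposed to scattered individual errors.

The genotype simulator models accessions as fully inbred homozygous lines
whose per-variant allele frequency is chosen so the expected
between-accession distance equals the configured divergence
(`2q(1−q) = divergence`); plants deviate from their accession by rare
independent homozygous flips so the expected within-lineage distance equals
`within_error`. A mislabel plan swaps the generating accession of whole
cells while keeping labels, reproducing the confounding scenario end to end.

# Methylome statistics

Cytosine reports (chrom, 1-based position, strand, context, methylated and
total counts) are filtered per group: coverage between 5 and 100 in at least
two samples of every group for differential testing, or at least five per
treatment for the distance analysis — both are the same function with
different `min_samples`.

`test_dmc()` is a deliberately simple per-cytosine two-group test: a
chi-square on the pooled counts, with an overdispersion-robust option that
deflates the statistic by a quasi-likelihood dispersion estimated from
between-sample Pearson residuals. It stands in for shrinkage-based
bisulfite testers and makes no claim to reproduce their exact calls;
externally reported DMC counts are therefore not comparison targets. P-values are
converted to FDRs by Benjamini–Hochberg step-up pooled across all tested
cytosines (not per context), and cytosines untestable in a group (zero
coverage) are counted in a skip log rather than dropped silently.

`epigenetic_distance()` is the average *absolute* difference in percent
methylation over jointly covered cytosines — signed differences would
cancel. `dispersion_test()` compares group spreads via distances to group
centroids in a principal-coordinates embedding that retains
negative-eigenvalue axes, with permutation inference; it delegates to
`vegan::betadisper()`/`permutest()` (centroids, not spatial medians) and
excludes groups below four samples. The default 999 permutations is a
package choice (seedable); all-zero distance matrices return a flagged
degenerate result instead of a p-value.

`annotate_dmcs()` measures the distance of each DMC to the nearest gene (0
inside, otherwise base pairs to the nearest boundary, so "1500 bp upstream"
reads as 1500) and reports the fractions within a 2-kb window of genes, and
of genes or transposable elements, plus the CG/CHG/CHH shares. Coordinates
are 1-based inclusive throughout, the GFF3 and cytosine-report convention.

# Numerical and degenerate-input choices

* Rank decisions use the pivoted QR's default tolerance; indicator and
  small-integer contrast columns keep the matrix well scaled.
* `%SS` always includes the residual row, so the column sums to 100; a zero
  total SS is an error, not a division by zero.
* Ties in `assign_accessions()` break lexicographically; ties in the
  transformation choice go to identity.
* ROUT with a zero robust scale flags only points with nonzero residuals
  (they are infinitely many robust SDs out); groups under three values are
  skipped with a warning.
* Categorical levels are compared case-sensitively after whitespace
  trimming; `"NA"` and empty cells are missing.
* Generated datasets are bit-reproducible under a fixed seed.

# Problem sizes used in tests and the acceptance script

The packaged checks run the full 1800-plant design for power and
calibration (200 replicates per scenario-by-effect cell; 500 for null
calibration), 2000–10,000 variants for the identity QC, and 2000–10,000
cytosines for the methylome checks. These sizes resolve the tested
quantities well inside the tolerances asserted (Monte-Carlo SE ≈ 1
percentage point on pooled power) while keeping a full run in minutes on a
single core.

# Known limitations

* The `AN`-vs-`LI` test is structurally miscalibrated (see above); the
  package reports it exactly as the procedure defines it.
* The fixed-effects fits are the only implementation; the mixed-model
  variant was reported to give practically identical results and is not
  reimplemented here.
* The per-cytosine test is a stand-in; region-level (DMR) calling and GO
  enrichment are out of scope.
* No read-level processing: the package consumes variant tables and
  cytosine reports, not raw sequence.
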