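---
title: "Finding age-associated metabolite features in CSF: models and design choices"
author: "metaboDrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding age-associated metabolite features in CSF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboDrift)
```

## The problem

Untargeted LC-MS metabolomics of cerebrospinal fluid (CSF) produces a table
of *features* — (m/z, retention time) pairs with one intensity per
injection — that is contaminated by solvent background, run-order signal
drift, and technically unstable peaks.  Given such a table from a cohort
spanning adulthood (here: 41 subjects aged 20–74), the scientific question
is which features change systematically with chronological age, in which
direction, and what chemistry they represent.

`metaboDrift` implements the full chain: pooled-QC-based cleaning,
constrained ordination to quantify the global age effect, all-relevant
feature selection over random forests, clustering and a linearity check,
and putative annotation with class enrichment.  Because the real study
data cannot be bundled, the package ships a synthetic cohort generator
with planted ground truth; every stage is validated against it.

## The data model

A `MetaboSet` extends `SummarizedExperiment`: rows are features (`ion_mode`,
`mz` in Da, `rt` in seconds), columns are injections with `run_order`,
`sample_type` (`sample`, `qc`, `blank`, `dilution`), and, where applicable,
`injection_volume` (µL), `subject_age` (years) and `subject_gender`.
Missing intensities are `NA` and are never silently zero-filled; the
presence filter is the only stage that imputes (half-minimum, documented
below).

## Quality-control chain

Stages run in a fixed order; each returns the filtered object plus a
`FilterReport` with per-feature diagnostics.

1. **Presence** (default 0.75): keep a feature observed in ≥ 75% of the
   study samples; impute remaining missing sample cells with half the
   feature's minimum observed value.  This stage runs first because the
   later Pearson and LOESS stages need complete rows.
2. **Blank filter** (default 0.01): remove a feature whose median blank
   intensity exceeds 1% of its maximum sample intensity (strict `>`; the
   wording "higher than" motivates strict inequalities at every threshold
   in the chain).
3. **Dilution filter** (default α = 0.05): the pooled QC was injected at a
   twofold volume ladder (0.5–32 µL); a genuine analyte signal must rise
   with injected amount, so we keep features with a *positive* Pearson
   correlation between raw volume and raw intensity at two-sided p < α
   (t statistic with n − 2 df).  Constant rows have undefined r and fail
   the keep-rule.  A log–log variant is available via `log_scale`.
4. **LOESS drift correction** (default span 0.2): per feature, a local
   linear fit (`limma::loessFit`) of QC intensity against run order,
   evaluated at every injection (constant extrapolation beyond the first
   and last QC) and divided out after normalising the curve to its QC
   mean.  The corrected row is rescaled so the feature's mean QC intensity
   is preserved to machine precision, making the correction
   scale-equivariant.  The curve is anchored on QC injections only: with a
   pooled-QC design, the QCs are the only injections whose true signal is
   constant, so any structure in them is, by construction, technical.
   With fewer than 4 QCs no curve is identifiable; a constant factor is
   used and the report flagged.
5. **CV filter** (default 0.20): keep features whose QC coefficient of
   variation (sample standard deviation over mean, n − 1 denominator
   because QC counts are small) is strictly below 20%.

After the chain, QC, blank and dilution injections are dropped: the
analysis matrix holds study samples only.

## Ordination: dbRDA

The global age and gender effects are quantified by distance-based
redundancy analysis on Bray–Curtis dissimilarities
(d(u,v) = Σ|uᵢ−vᵢ| / Σ(uᵢ+vᵢ)).  We use the McArdle–Anderson formulation:
with G = −½·J·D²·J and H the hat matrix of the centred constraint design
(age z-scored, gender a centred indicator), the constrained inertia is
tr(HGH), axes come from the eigendecomposition of HGH, and residual
structure from (I−H)G(I−H).  This is exact — no principal-coordinate
truncation step — which is why the package's tests can demand equality
with classical RDA to 1e-8 on Euclidean distances.  Negative eigenvalues
(Bray–Curtis is non-Euclidean) stay in the total inertia but contribute no
axes; a Lingoes correction is available but off by default, matching
common practice.

Significance uses the add-one permutation estimator
p = (1 + #{F\* ≥ F}) / (1 + n\_perm), which can never return 0; per-constraint
tests permute only the tested column.  Post-hoc goodness of fit
(`envfitVariable`) projects a variable onto the first two constrained axes
(the published figures are 2-D; the axis count is an argument): r² of the
least-squares projection for numeric variables, 1 − SS\_within/SS\_total of
the axis scores for factors, with the same permutation estimator.

## Feature selection: shadow features over random forests

`borutaSelect` iterates: permuted "shadow" copies of the features join the
design; a `ranger` forest (regression on age, classification on gender) is
fitted; the importance statistic is out-of-bag permutation importance
divided by its standard error across trees (a Z-score — impurity
importance is not scale-free enough to compare against shadows); a feature
scores a *hit* when its Z strictly exceeds the best shadow Z (ties are
non-hits).  Hit counts are tested after every iteration against
Binomial(k, ½) with the standard pair of exact one-sided binomial tests at
level 0.01, Bonferroni-adjusted across the full feature family.  Features
left undecided at `boruta_max_runs` are reported *tentative*, never
silently confirmed.

Two design choices deserve emphasis, both driven by family-wise error
control under the per-iteration sequential testing:

* the Bonferroni family is the full feature set, not the shrinking set of
  still-undecided features — a shrinking family re-tests survivors at ever
  looser thresholds;
* the shadow background keeps the full feature width for the whole run.
  If shadows shrink with rejections, the best-shadow bar drops late in a
  run and chance-correlated noise features start "winning".  The price is
  conservatism: a relevant feature must beat the maximum of as many shadow
  Z-scores as there are features, so weak signals (sample r² below roughly
  0.3 at n = 41) are often left tentative rather than confirmed.

Confirmed features are validated two ways: a CART regression tree
(`rpart`, depth ≤ 5, minimum leaf 5) fitted on the confirmed set, reporting
R² = 1 − SS\_res/SS\_tot, and the out-of-bag R² of a forest restricted to
the confirmed set.  Direction and per-feature significance come from
ordinary least squares of intensity on age with a two-sided slope t-test.

For the recovery experiments in the test-suite we run 1000-tree forests
rather than the 500-tree default: the scaled importance Z of a truly
relevant feature grows roughly with the square root of the tree count
while shadow Z-scores do not, and at 41 samples 500 trees leaves
borderline features under-powered.  Even so, planted features whose
realised sample r² falls in the low tail (~0.3 at a nominal 0.4) sit below
the max-of-all-shadows detection bar and are reported tentative; on the
package's synthetic conditions measured sensitivity is about 0.85–0.87
with a false-discovery proportion near 0.03.

## Clustering and the linearity check

Samples are clustered on Bray–Curtis with **Ward.D** agglomeration — the
classic Lance–Williams Ward update applied to unsquared dissimilarities,
deliberately distinct from Ward.D2 — and cut into three groups for the
young/middle/old view.  Features are clustered on Euclidean distances of
z-scored profiles (zero-variance features get an all-zero profile and a
flag).  Display scaling is the caller's business; clustering inputs are as
stated.

The linearity of an age relationship is scored by dynamic time warping:
the age-ordered profile and its own least-squares line are both z-scored
and compared with the classic DP recursion (absolute-difference cost,
symmetric steps, no window), normalised by series length.  0 means
exactly linear; a constant profile is defined to score 0 and flagged
degenerate.  This is one declared interpretation of "applying DTW to the
data"; the original account does not pin the comparison down, and the
score makes no claim to reproduce it exactly.

## Annotation, enrichment, ontology

* `adductMz` computes theoretical [M+H]⁺ / [M−H]⁻ m/z from monoisotopic
  atomic masses (proton mass 1.00727646 Da).  `libraryMatch` accepts a hit
  within 10 ppm (inclusive at the boundary, with a 1e-9 ppm guard against
  floating-point round-off exactly at it), ranked by |ppm| then compound
  id.
* MSI identification levels follow the highest-evidence rule:
  in-house spectral match → 1, public spectral → 2, in-silico structure →
  3, class-only → 4, bare formula → `formula_only`, else `unknown`.
* `classEnrichment` runs one two-sided 2×2 Fisher exact test per class
  (a one-sided mode exists) and flags a class *enriched* only when
  p < 0.005 **and** the selected-set fraction exceeds the background
  fraction.  No multiple-testing correction is applied across classes —
  the single conservative α stands in for it, and this is stated rather
  than hidden.  Depleted classes are never flagged.
* `pruneOntology` normalises case and whitespace, collapses duplicate
  paths per compound, and drops every path equal to or descending from an
  entry of the shipped removal list (drug-classification schemes,
  disposition/exposure bookkeeping, entity-less superclasses).
  `aggregateTreemap` counts distinct compounds per term with parent counts
  the distinct union over descendants, so counts are monotone up the
  hierarchy.

## The synthetic cohort

`generateCohort` emulates the study design: 41 subjects spread over 20–74
years, 1169 positive- plus 672 negative-mode features, a pooled QC every
8 injections, 5 solvent blanks, and the twofold 0.5–32 µL dilution ladder.
Sample order is randomised blocked on age tertiles (interleaved), an
age-constrained randomisation without claiming to reproduce any particular
scheduler.  Intensities are lognormal baselines times effect factors:

* 69 age features (5 decreasing) add a term *linear in age on the raw
  scale*, with the slope solved so age explains `effect_r2` of the
  feature's variance at the configured noise (with `noise_cv = 0` the
  column is exactly linear in age, and a fixed 50% span across the age
  range is used since the variance ratio is then degenerate);
* 41 gender features, disjoint from the age set;
* 50 contaminants at a constant level across all injection types, so
  blanks carry them but dilution volumes do not scale them;
* a smooth multiplicative drift (slow sinusoid plus trend, peak amplitude
  20%) multiplying every injection — deliberately within reach of a
  span-0.2 LOESS;
* 5% lognormal technical noise and 5% completely-at-random missingness
  among sample cells (no missingness mechanism is claimed by the source
  design; MCAR is the neutral choice).

Noise at 5% and drift at 20% are realistic for pooled-QC Orbitrap runs;
they were fixed once as the package's study conditions.  What the
generator does **not** emulate: peak shapes or spectra, correlated
metabolome-wide age covariation beyond the planted features,
batch-to-batch structure, intensity-dependent missingness, or real
compound identities (classes are assigned, not predicted).  Passing the
recovery tests therefore demonstrates the statistical machinery, not
instrument-level realism; in particular the constrained-variance fractions
on synthetic data (about 12% for age at `effect_r2 = 0.3` on the planted
set) are smaller than the published 29.49% on real data, which reflects
broad age covariation the generator leaves out.

Chemical classes come from a 190-leaf catalogue over ten superclass
branches; enriched classes are planted by converting the configured odds
ratio into multinomial weights so the *realised* per-class odds ratio
matches the nominal one.

## Numerical and testing choices

* Problem sizes in the test-suite: QC-chain recovery uses 20 full-scale
  cohorts; selection experiments use 20 seeds at 200 features × 41
  samples with `max_runs = 100` (decisions at the planted effect sizes
  settle far earlier; the published default of 1000 exists for real data
  where stragglers matter); null ordination calibration uses 200 null
  draws at 99 permutations.
* Oracles: Euclidean dbRDA is checked against direct classical RDA;
  Fisher p against exhaustive conditional enumeration over the
  symmetry-reduced set of all 2×2 tables with margins ≤ 30; DTW against
  brute-force path enumeration over all short integer series.
* Degenerate inputs are decided, not left to chance: constant dilution
  rows are removed; zero-variance envfit variables score (0, 1); constant
  linearity profiles score 0 with a flag; ties with the best shadow are
  non-hits; the permutation estimator never returns 0.

## Reproducing the numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` regenerates
every quantity discussed here from scratch — fixture accounting, adduct
masses, oracle deviations, QC recovery rates, selection sensitivity and
FDR, validation R², ordination fractions and permutation p-values — using
only the installed package and the seed.
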