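---
title: "Models and methods behind glucovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glucovar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucovar)
```

glucovar interprets missense variants of human glucokinase (GCK) by
combining enzyme kinetics, variant-effect predictor scores and
evolutionary conservation. This vignette is the package's own account of
the models it implements, the parameters that matter, the numerical
choices made, and what its validation on synthetic data does and does not
establish.

## The beta-cell kinetic model

GCK is the glucose sensor of the pancreatic beta cell: a monomeric,
cooperative hexokinase whose half-saturating glucose concentration
(S~0.5~ ≈ 8.8 mM in the wild type) sits inside the physiological blood
glucose range. The package models the phosphorylation rate of one enzyme
form as a Hill law in glucose times a Michaelis factor in ATP:

$$A(G) = k_\mathrm{cat}\,
  \frac{G^{n_H}}{S_{0.5}^{\,n_H} + G^{n_H}}\cdot
  \frac{[\mathrm{ATP}]}{[\mathrm{ATP}] + K_{M,\mathrm{ATP}}}$$

The two derived quantities are:

* **RAI** (relative activity index): $A_\mathrm{var}/A_\mathrm{wt}$ at
  the reference condition. Wild type is 1.00 by construction; values
  below the floor are censored (reported `"<0.01"`).
* **GSIR-T** (threshold for glucose-stimulated insulin release): the
  smallest glucose concentration $G^\*$ at which the heterozygous cell,

  $$h\,\kappa\,A_\mathrm{wt}(G^\*) + h\,A_\mathrm{var}(G^\*)
    = A_\mathrm{wt}(G_\mathrm{ref}),$$

  recovers the wild-type setpoint rate, with allele dose $h = 0.5$ and
  compensation $\kappa = 1$ by default. Inactivating alleles raise
  $G^\*$ above 5 mM (hyperglycemia before insulin release — the
  GCK-MODY mechanism); activating alleles lower it (hypoglycemia —
  PHHI); a null allele leaves only half the wild-type dose, whose
  threshold lies above the 7.1 mM censoring cap.

The exact equations used historically to compute RAI and GSIR-T from
fitted constants are not uniquely fixed in the literature (published
variants differ in the ATP concentration assumed and in whether the
remaining wild-type allele is compensatorily upregulated). The package
therefore fixes one documented default — the Hill × Michaelis form above
at 5 mM glucose and 2.5 mM ATP, 50:50 allele dose, no compensation — and
exposes *every* constant in `beta_cell_config()`, so an alternative
published parameterization is a configuration change, not a code change.
Consequently the package treats reported per-variant RAI/GSIR-T values as
an *ordinal* reference: the test suite requires Spearman rank agreement
(≥ 0.9 for RAI, ≥ 0.8 for GSIR-T with censored values tied at the cap)
between derived and reported values over the bundled reference kinetics
(`gck_kinetic_table()`, 13 variants with complete constants), not
numerical equality.

Parameters of `beta_cell_config()`:

| parameter | default | units | role |
|---|---|---|---|
| `g_ref` | 5.0 | mM glucose | wild-type setpoint defining the threshold condition |
| `atp_conc` | 2.5 | mM ATP | condition at which activity is evaluated |
| `gsirt_cap` | 7.1 | mM glucose | censoring cap for GSIR-T |
| `rai_floor` | 0.01 | — | censoring floor for RAI |
| `het_fraction` | 0.5 | — | allele dose of each allele |
| `compensation` | 1.0 | — | upregulation of the wild-type allele |
| `tol` | 1e-6 | mM | bisection tolerance |

### Numerical choices

* **Root finding.** The threshold gap function is monotone increasing in
  glucose, so `gsir_threshold()` expands the bracket upward (upper bound
  doubling from 50 to at most 500 mM) and bisects to `tol`. Reported
  values are rounded to 0.1 mM, the working precision of the field's
  tables; the unrounded root is kept in `gsirt_raw`. A variant whose gap
  function vanishes at the setpoint (numerically indistinguishable from
  wild type) returns exactly `g_ref`, avoiding a spurious ±`tol` wobble.
  Failure to bracket by 500 mM is censored at the cap.
* **Fitting.** `fit_hill()`, `fit_michaelis()` and `fit_ic50()` use
  Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with box
  bounds. Hill starting values: S~0.5~ at the concentration nearest
  half-maximal observed rate, n~H~ = 1.5, v~max~ at the maximal rate;
  n~H~ is bounded to [0.5, 4], the physically meaningful range for this
  enzyme. The IC~50~ fit constrains the top plateau to the mean
  uninhibited (dose-0) rate and censors as a greater-than bound when the
  dose–response trend is non-decreasing.
* **Detection limit.** An assay whose maximal rate does not exceed twice
  the blank standard deviation (when one is supplied) is flagged
  `no_activity` rather than fitted; the derived RAI is then censored at
  the floor and GSIR-T at the cap.

## Evidence-based threshold calibration

Default thresholds of variant-effect predictors are tuned for
genome-wide sensitivity and misclassify most neutral GCK variants. The
calibration implemented here is purely neutral-distribution based: from
the scores of normoglycemic variants, the boundary is

$$t = \mathrm{center} \pm k\cdot\mathrm{spread}$$

shifted in the deleterious direction (below for predictors where lower
scores mean damage, above otherwise), with $k = 2$. Choices and their
rationale:

* **Center.** Median by default (robust to the outliers common in small
  neutral sets); the SNAP2 calibration uses the mean, following the
  convention established for that score. Per-predictor override in
  `predictor_specs()`.
* **Spread.** Sample standard deviation (n − 1 denominator). A robust
  alternative (1.4826·MAD) is available via `spread_stat = "mad"` but is
  not the default, because the reference large-sample thresholds the
  generator is parameterized from (−6.31 for EVmutation, 1.42 kcal/mol
  for PoPMuSiC, 6.5 for SNAP2) are center ± 2·SD quantities.
* **Strictness.** A score exactly at the boundary is *not* called
  deleterious — only scores strictly past it "pass" the threshold.
  Missing scores are never imputed and propagate as `not_called`.
* **Uncertainty.** `center_ci()` provides a seeded nonparametric
  percentile bootstrap (10^4^ resamples by default) of the center; the
  CI method is a package choice since none is canonical here.
* Binary predictors (PhD-SNP, SNPs&GO) admit no threshold and are
  excluded from calibration by construction.

## Multi-class evaluation

`class_metrics()` evaluates calls against three groupings: clinical
phenotype (MODY / PHHI / PNDM / normoglycemic), GSIR-T bins (< 4 mM
activating, 4–5.5 mM normal, > 5.5 mM deactivating) and Hill-coefficient
bins (< 1.2 cooperativity lost, 1.2–1.5 reduced, > 1.5 normal). Each
class carries an *expected call* — deleterious for disease and
abnormal-kinetics classes, neutral for normoglycemic and normal-range
classes — and sensitivity is the percentage of scored class members
matching it. The false-positive ratio is the percentage of
disease-expectation variants called neutral: with an order of magnitude
more disease-associated than neutral GCK variants on record, even a
modest neutral-call rate among disease variants swamps the true
neutrals, which is why this ratio is reported alongside per-class
sensitivity. Bin boundaries are inclusive in the middle (normal) bins;
the sources of such tables print open-looking labels ("4–5.5") without
stating inclusivity, so this is a documented package convention.
Variants without a score are excluded from all denominators and counted
in `n_missing` (structure-based predictors only cover crystal-resolved
residues, so this exclusion is routine, not exceptional).

Score combination follows two routes:

* **Ternary transformation** (`harmonize_ternary()`): the three
  informative continuous scores are min–max rescaled on their observed
  ranges to a common deleteriousness scale (EVmutation negated so higher
  always means more deleterious), and each triple is divided by its sum.
  The observed-range choice makes the coordinates dataset-relative; the
  ranges used are recorded in the result's `ranges` attribute for
  reproducibility. Degenerate cases: an all-zero triple (benign corner)
  maps to the barycenter (⅓, ⅓, ⅓); a degenerate score range aborts.
* **Region classification** (`region_classify()`): putatively highly
  pathogenic iff EVmutation < −7.5 and SNAP2 > 70; putatively benign iff
  EVmutation ∈ [−4, −2] and SNAP2 < −50; everything else `other`.
  Boundary values fall in `other` (strict inequalities), so the regions
  partition the plane.

## Conservation: GV and GD

The Grantham (1974) distance weighs squared differences in composition,
polarity and side-chain volume ($\alpha = 1.833$, $\beta = 0.1018$,
$\gamma = 0.000399$, $\rho = 50.723$; properties embedded in
`grantham_table()`). Per alignment column, **GV** applies the same form
to the componentwise property *ranges* over the observed residue set
(duplicates ignored — GV is a range, not a variance), and **GD** to a
mutant residue's deviation from those ranges. Useful anchors: a {T,S}
column scores 57.75, {V,I} scores 29.61, and GV < 61.3 is the
conservation call. The embedded published integer matrix
(`grantham_published()`) serves as a rounding cross-check; its Asp–Trp
entry is given as the formula-consistent 191 because printed copies of
the table vary for this one pair.

Column conventions: gaps carry no physicochemical properties and are
excluded from a column's residue multiset (counted in `n_gaps`); columns
with fewer than two non-gap sequences are flagged *unscorable* rather
than scored 0, since a single observation spans no range. Reference
numbering is 1-based on the ungapped reference sequence, with the
original alignment column retained in `alignment_column`. Whether GV at
gapped columns should instead use a penalized convention is genuinely
open; the gap-exclusion rule is this package's choice and is applied
uniformly.

`conservation_frequency_corr()` correlates per-position GV with
disease-family counts over *all* reference positions, zero-filling
positions with no recorded families — the alternative (only mutated
residues) conditions on the outcome and was rejected. Ties in the
Spearman ranks use midranks; constant vectors abort rather than return
`NA`.

## What the synthetic generator emulates — and what it does not

`gen_variant_table()`, `gen_assay()`, `gen_alignment()` and
`gen_family_counts()` produce inputs with known ground truth:

* Neutral-class score distributions are Normal with location/scale
  derived from reported summary statistics of neutral GCK variants
  (EVmutation median −2.39 with SD 1.96 derived as (center −
  threshold)/2 from the −6.31 threshold; SNAP2 mean −58, SD 32.25;
  PoPMuSiC median 0.58, SD 0.42 kcal/mol). Disease-class distributions
  are *plausible placeholders* (marked as such in `score_spec()`), not
  derived from published statistics.
* Class sizes default to the composition of the curated GCK sets
  (499 MODY, 16 PHHI, 53 normoglycemic).
* Assay noise is Gaussian with SD proportional to the curve maximum
  (2% default), truncated at zero — initial-rate noise, not raw
  spectrophotometer traces.
* Alignments have an exact invariant-column count
  (`round(L · invariant_fraction)`, default 301/465 — the conservation
  level typical of the 12-vertebrate GCK ortholog set) and draw variable
  columns from small physicochemically coherent residue pools.
* Family counts are negative-binomial with log-mean decreasing in GV
  (`coupling` = 0.02/Grantham-unit, base mean 3, size 0.6 — chosen once
  as a realistic overdispersed coupling producing a moderate negative
  rank correlation, and not revisited).

Passing round-trip tests on these inputs shows the *estimators* are
correct under the generating model; it does not show that real GCK data
follow Normal score distributions, homoscedastic assay noise or
negative-binomial family counts, nor that real class separations match
the placeholder disease distributions. Reproduction of the published
real-data statistics requires the study's supplementary table and
alignment, which the package does not distribute; the corresponding test
block documents exactly which numbers it would check and fails (rather
than silently skipping) in their absence.

## Problem sizes and determinism

The validation suite runs at deliberately modest sizes: 10^4^ neutral
scores for threshold recovery (the spread of a median ± 2·SD estimate at
that n is well inside the ±0.05 acceptance band for EVmutation), 100
random parameter draws for the bisection-vs-grid-scan cross-check
(grid step 10^−3^ mM), 1000 random toy sets for the confusion-matrix
oracle, and a few hundred bootstrap replications for CI coverage. All
stochastic steps take explicit seeds; generators are deterministic given
their arguments plus seed, and `run_pipeline()` writes a manifest (input
hashes, settings, seed, package version) so a re-run can be verified
byte-identical.

## Known limitations

* The beta-cell model stops at the phosphorylation-threshold condition:
  no glucose transport, downstream glycolytic flux or insulin secretion
  dynamics, and no liver (GKRP-mediated) compartment.
* RAI/GSIR-T values are model-dependent; only their ordering is
  validated against reported values (see above). Users comparing against
  a specific published parameterization should set `beta_cell_config()`
  accordingly.
* Align-GVGD's full classifier grades (C0–C65) are out of scope; only
  GV/GD values and the GV < 61.3 conservation rule are provided.
* The predictors themselves are never run; their scores are inputs.
* Ordination of predictor outcomes (detrended correspondence analysis
  and relatives) is left to dedicated ordination packages.
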