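# glucovar

Interpretation of nonsynonymous (missense) variants of human glucokinase
(GCK), the pancreatic beta-cell glucose sensor, from three complementary
lines of evidence:

1. **Enzyme kinetics.** Hill, Michaelis–Menten and dose–response fits to
   titration assays, and a heterozygous beta-cell model that turns fitted
   constants into the two quantities clinicians reason about: the relative
   activity index (RAI) and the threshold for glucose-stimulated insulin
   release (GSIR-T).
2. **Variant-effect predictor scores.** Evidence-based calibration of
   decision thresholds for continuous predictor scores (EVmutation,
   PoPMuSiC 2.1 ΔΔG, SNAP2, …) from the score distribution of
   *normoglycemic* (neutral) variants, plus per-class evaluation, score
   combination (ternary transformation, 2-D region classification) and
   saturating substitution enumeration.
3. **Evolutionary conservation.** Grantham variation (GV) and Grantham
   deviation (GD) profiling of a vertebrate ortholog alignment, and the
   correlation of per-residue conservation with disease-family frequency.

A synthetic-data module generates all three input kinds (variant tables,
assays, alignments, family counts) with known ground truth, so every
analysis stage can be validated by parameter recovery.

## The models

**Enzyme activity.** GCK is a cooperative monomeric enzyme; its glucose
dependence follows a Hill law with an ATP Michaelis factor:

```
A(G) = kcat · G^nH / (S0.5^nH + G^nH) · [ATP] / ([ATP] + KM,ATP)
```

with S0.5 ≈ 8.8 mM, nH ≈ 1.7, kcat ≈ 44 s⁻¹ for the wild type. The
**RAI** is `A_var / A_wt` evaluated at the reference condition (5 mM
glucose, 2.5 mM ATP; wild type = 1.00, censored below 0.01). The
**GSIR-T** is the glucose concentration at which a heterozygous beta cell
(50:50 allele dose) recovers the wild-type setpoint rate:

```
0.5 · A_wt(G*) + 0.5 · A_var(G*) = A_wt(5 mM)
```

solved by bracketing + bisection; 5.0 mM for wild type, reported in the
5.7–7.1 mM range for inactivating (MODY-type) alleles, censored at
≥ 7.1 mM for null alleles, and below 5 mM for activating (PHHI-type)
alleles. Every constant lives in `beta_cell_config()`.

**Evidence-based thresholds.** For a continuous predictor with neutral
score sample `x`, the decision boundary is `center(x) ± k·SD(x)` shifted
in the deleterious direction (k = 2; median center by default, mean for
SNAP2), with a percentile-bootstrap CI of the center. A score strictly
past the boundary is called deleterious.

**Conservation.** For an alignment column, GV is the Grantham-style
distance between the componentwise extremes of composition, polarity and
volume over the observed residues (0 for invariant columns); GD measures
how far a mutant residue falls outside those observed ranges. Positions
with GV < 61.3 are called conserved.

## Worked example

```r
library(glucovar)

## kinetics: an inactivating variant vs wild type
wt   <- kinetic_params(s05 = 8.82,  n_h = 1.72, kcat = 43.8, km_atp = 0.36)
v33a <- kinetic_params(s05 = 12.77, n_h = 1.56, kcat = 42.6, km_atp = 0.53)
dplyr::bind_cols(compute_rai(v33a, wt), gsir_threshold(v33a, wt))
#> # A tibble: 1 x 7
#>     rai rai_censored rai_label gsirt_raw gsirt gsirt_censored gsirt_label
#>   <dbl> <lgl>        <chr>         <dbl> <dbl> <lgl>          <chr>
#> 1 0.631 FALSE        0.63           5.92   5.9 FALSE          5.9
```

The variant retains 63% of wild-type activity and shifts the insulin
release threshold to 5.9 mM glucose — mild fasting hyperglycemia, the
classic GCK-MODY picture.

```r
## calibrate predictor thresholds on a simulated cohort
vt  <- gen_variant_table(c(MODY = 499, PHHI = 16, normoglycemic = 53), seed = 1)
thr <- calibrate_thresholds(vt, ci = TRUE, n_boot = 2000, seed = 1)
dplyr::select(thr, predictor, n, center, spread, threshold, direction)
#> # A tibble: 3 x 6
#>   predictor        n  center spread threshold direction
#>   <chr>        <int>   <dbl>  <dbl>     <dbl> <chr>
#> 1 popmusic_ddg    46   0.519  0.366      1.25 above
#> 2 snap2           50 -58.0   31.7        5.35 above
#> 3 evmutation      51  -1.96   1.89      -5.73 below

ev <- thr[thr$predictor == "evmutation", ]
pass_rate(apply_threshold(vt$evmutation, ev), vt$phenotype, "MODY")
#> [1] 62
```

With only ~50 neutral variants the calibrated boundaries scatter around
their large-sample values (−6.31, 1.42 and 6.5 for EVmutation, PoPMuSiC
and SNAP2 under the generator's neutral-class defaults); the `n`,
`spread` and CI columns make that uncertainty explicit.

```r
## conservation profiling of a simulated 12-species ortholog alignment
sim  <- gen_alignment(seed = 1)                  # L = 465, 65% invariant
prof <- conservation_profile(map_alignment(sim$alignment))
sum(prof$invariant)
#> [1] 301
fam <- gen_family_counts(prof, seed = 2)
conservation_frequency_corr(prof, fam)
#> # A tibble: 2 x 4
#>   method   estimate     p_value     n
#>   <chr>       <dbl>       <dbl> <int>
#> 1 pearson    -0.232 0.000000402   465
#> 2 spearman   -0.238 0.000000199   465
```

Strongly conserved (low-GV) positions carry more disease families — the
negative rank correlation the conservation analysis is built to expose.

Each fitted object plays well with the usual verbs: `tidy()` /
`glance()` on kinetic fits and class metrics, `autoplot()` on fits, and
`plot_score_distributions()`, `plot_ternary()`, `plot_conservation()`
for the result tables. `run_pipeline()` chains calibration, evaluation
and conservation over files and writes TSV outputs plus a manifest.

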