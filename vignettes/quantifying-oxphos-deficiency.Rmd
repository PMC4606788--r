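---
title: "Quantifying single-fibre OXPHOS deficiency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-fibre OXPHOS deficiency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadfibre)
```

## The problem

Mitochondrial myopathies typically produce *mosaic* OXPHOS deficiency: within
one muscle section, individual fibres range from biochemically normal to
completely deficient, depending on their burden of mutated mtDNA. Bulk
biochemistry averages over this mosaic and histochemistry (COX/SDH) is
semi-quantitative, covers only complexes II and IV, and is classified by eye.
`quadfibre` implements an objective alternative built on quadruple
immunofluorescence: each 10 µm transverse section is labelled for laminin
(fibre boundaries, 405 nm), COX-I (complex IV, 488 nm), porin/VDAC1
(mitochondrial mass, 546 nm) and NDUFB8 (complex I, 647 nm), and every fibre
is quantified and classified individually.

The pipeline has six stages, each exposed as ordinary R functions:

1. **Segmentation** — a laminin mask isolates fibre interiors; per-fibre mean
   channel signals are measured (`segment_section()`).
2. **Background correction** — non-specific signal measured on a matched
   no-primary-control (NPC) section is subtracted (`correct_fibres()`).
3. **Transformation** — corrected signals are log-transformed.
4. **Control model** — porin mean/SD and per-protein regressions are fitted
   on a pooled control sample (`build_control_model()`).
5. **Scoring and classification** — Z-scores against the control model map
   each fibre into mass and deficiency categories (`classify_section()`).
6. **Reporting** — expression-profile plots, category proportions and
   two-proportion reproducibility comparisons (`make_profile_plot()`,
   `compare_runs()`).

## The statistical model

### Signal scale

Densitometry exports often report optical density on an inverted 16-bit scale
(0 = brightest). Background subtraction and regression are only physically
coherent on a brightness-monotone scale, so the package works internally on
the *signal* scale `S = 65535 - OD` (import flag `od_convention` in
`read_fibre_table()`); images measured directly use raw mean pixel intensity.

### Background correction

The NPC section (laminin primary only, all secondaries) measures non-specific
binding. COX-I and porin are corrected by subtracting the NPC global channel
means. The NDUFB8 secondary, however, binds off-target preferentially in
fibres with high mitochondrial mass, so a global subtraction would
over-correct low-mass and under-correct high-mass fibres. Instead, sample
fibres are ranked into 100 porin-percentile groups
(`g = ceiling(100 * rank / n)`, average ranks on ties) and each fibre's
647 nm signal is corrected by the mean NPC 647 nm signal of the *matching*
percentile group.

Two details are left open by the source protocol and were decided here:

* NPC fibres are unstained for porin, so their "porin percentile" is not
  directly observable. We rank NPC fibres by their own 546 nm signal, which
  tracks mass through the same non-specific binding. This is the natural
  proxy because the NPC is a serial section of the same biopsy — its fibres
  are, to first order, the same fibres.
* Corrected values at or below zero are floored at `epsilon = 1` signal unit
  and flagged, rather than dropped. Dropping would silently change the fibre
  counts that category proportions are computed from; the flag supports
  sensitivity analyses. At default simulation conditions clipping affects
  < 1% of fibres.

### Transformation and the control model

Corrected signals are natural-log transformed; a Box-Cox profile-likelihood
diagnostic (`check_boxcox_lambda()`, grid `[-2, 2]`, step 0.05) warns if the
log is a poor choice, and Shapiro-Wilk plus a D'Agostino-Pearson omnibus test
(implemented in-package; Shapiro on a seeded 5000-fibre subsample beyond its
implementation range) report on normality. These are validations, not gates —
a failed test warns and proceeds.

The control pool draws an equal number of fibres from every control subject
(the smallest subject sets the count; sampling is without replacement and
seeded). On the pool, the model records:

* `porin_mu_T`, `porin_sd_T` — mean and SD of log porin;
* for each protein, an OLS regression of log protein on log porin with its
  standard error of estimate `see = sqrt(SSE / (n - 2))`.

Z-scores follow as

* `porin_Z = (porin_T - porin_mu_T) / porin_sd_T`,
* `protein_Z = (protein_T - (intercept + slope * porin_T)) / see`.

The SEE is a single constant over the porin range: homoscedasticity is
assumed (and checkable from the residuals stored with each fit). Both healthy
and disease controls may enter the pool; the subject list is configuration.
One pool is fixed per run, with its seed recorded in the model provenance.

### Classification

Porin bands (SD units): very_low `z < -3`; low `-3 <= z < -2`; normal
`-2 <= z <= 2`; high `2 < z <= 3`; very_high `z > 3`. Protein bands (SEE
units): normal `z > -3`; intermediate(+) `-4.5 < z <= -3`; intermediate(−)
`-6 < z <= -4.5`; deficient `z <= -6`. Band closure at the exact boundary is
not specified by the band names; we close each protein band on its deficient
side (ties are measure-zero but must be deterministic).

The `-6` deficient cut can alternatively be *calibrated* from red-appearing
fibres — fibres visibly expressing porin but neither protein — by setting the
cut to the highest protein Z among the flagged fibres
(`calibrate_deficiency_threshold()`). Both the default and the calibrated
thresholds are supported; calibration is global across a run by default, and
its source fibre ids are recorded.

### Reproducibility statistics

Category proportions between two runs (days, observers, or visual vs
objective classification) are compared with the two-proportion Z test. The
95% CI for the difference uses the unpooled Wald form
`diff ± 1.96 * sqrt(p1 q1 / n1 + p2 q2 / n2)`; the test statistic uses the
pooled proportion. This exact form was verified by recomputing the published
day-1/day-2 confidence intervals from their printed proportions and fibre
counts (`reproduce_published_cis()`); bounds reproduce at the printed precision
except for a handful of rows whose printed interval contradicts its own
printed estimate (typographical errors, flagged by the function's
internal-consistency check). No multiplicity adjustment is applied across
categories, matching the published analysis; interpret per-category CIs
accordingly.

## The synthetic data generator

No biopsy images are distributed, so every stage is validated against a
ground-truthed generator (`simulation_config()`,
`generate_control_section()`, `generate_patient_section()`,
`generate_npc_section()`, `render_section_image()`).

### Control fibres

Latent log-signal porin is Gaussian `N(porin_mu_T, porin_sd_T)`; latent log
COX-I and NDUFB8 are linear in log porin with Gaussian residuals of scale
equal to the configured SEE. Stored 16-bit signals are `exp(latent)` plus the
section's non-specific background plus `N(0, noise_sd)` measurement noise,
clamped to `[0, 65535]`. The latent scale is deliberately the log scale the
pipeline's transform recovers, so correction and transformation jointly
invert the generator up to noise.

Defaults (`porin_mu_T = 9.2`, `porin_sd_T = 0.35`, slopes 0.9, SEE 0.15,
`noise_sd = 100`) put mean signals in the mid-thousands of a 16-bit range
with coefficient-of-variation and regression scatter plausible for
fluorescence densitometry; the default section size (1000 fibres) sits inside
the 447–2400 fibres-per-section range of real acquisitions.

### Non-specific background

All NPC channels have a flat base (default 300 signal units). The 647 nm
channel adds `npc_slope_647 * rel_mass` where
`rel_mass = exp(porin_T - porin_mu_T)` is the fibre's relative mitochondrial
mass; the 546 nm channel adds an analogous `npc_mass_546 * rel_mass` term.
Both coefficients default to 600 — the off-target binding belongs to the
secondary antibody itself (a fluorophore swap moves it between channels), so
the two channels' mass-tracking magnitudes should match. Sample sections
carry the *same* additive background in every channel, which is what makes
NPC subtraction the correct correction.

Two modelling choices deserve note:

* The bias is linear in *relative mass*, not in the mass percentile. A
  percentile form saturates for ragged-red fibres (they all sit at
  percentile ≈ 1), which would erase the very trend the percentile-matched
  correction is meant to remove and make its validation vacuous.
* `generate_npc_section()` reuses the sample section's latent masses when
  given its ground truth: the NPC is a serial section of the same biopsy.
  Shared masses are also what makes percentile matching effective — if the
  NPC mass distribution differed from the sample's, group means would be
  estimated at the wrong masses.

A related caveat the generator makes visible: percentile matching is
rank-based, so noisy NPC ranking flattens the estimated group-mean curve
(classical regression dilution) and leaves a residual mass trend. With the
default 546 nm tracking coefficient the ranking is well resolved; users
simulating weaker tracking should expect partial correction.

A second method-level artifact: porin itself is corrected by *global*
subtraction, so its mass-dependent background component
(`npc_mass_546 * rel_mass`, exactly proportional to `exp(porin_T)`) is
removed only on average. The corrected porin scale is therefore slightly
stretched relative to the latent scale, and regression slopes fitted on
corrected data sit a few percent below the generating slope. This is a
property of the published correction scheme, not of the implementation; it
is self-consistent because patients and controls are corrected identically.

### Patient presets

Deficient subpopulations are parametrised mixtures, not mechanistic models:
each fibre draws a category per protein (fractions are configuration) and
deficient categories are displaced below the control regression by
`planted_shifts[category]` SEE units. Defaults put the shifts at the band
midpoints (−3.75, −5.25) and at −7.5 for the open-ended deficient band (one
band-width below its −6 cut, preserving the 1.5-SD band geometry). Planted
fibres scatter around their planted level with `shift_jitter_sd = 0.2` Z
units: the full control SEE would smear planted categories across band
boundaries (the bands are only 1.5 SD wide), which would make planted labels
meaningless as ground truth; a small jitter keeps labels and values
consistent while avoiding degenerate point masses.

The joint complex I / complex IV trajectory per preset mirrors the
genotype-specific patterns the assay resolves:

* `isolated_CIV`, `isolated_CI` — one protein affected, the other normal.
* `single_deletion` — simultaneous decline, NDUFB8 one band milder.
* `multiple_deletions` — one population with decreased NDUFB8 only plus a
  second (`md_both_fraction`) with both complexes equally down-regulated.
* `m3243AG` — the rotated-L: COX-I falls below normal only in fibres whose
  NDUFB8 is already deficient.
* `mt_tW_plateau` — COX-I of affected fibres at a common plateau just inside
  the deficient band, NDUFB8 spanning a wide severity range.

Ragged-red fibres (any preset, `rrf_fraction`) get porin Z drawn in
`rrf_porin_z_range = (3, 5)` and both proteins fixed at a basal latent
constant (default 7.5 SEE below the prediction at the control mean porin),
matching their phenotype of massive mitochondrial accumulation with basal
OXPHOS protein.

### Rendered images

`render_section_image()` draws fibres as a jittered Voronoi tessellation:
bright laminin boundaries (including the image frame, so that interior fibres
are not spuriously border-filtered), interiors filled with the fibre's
channel values plus optional pixel noise, and a ground-truth label map. The
generator emulates geometry and intensity, *not* optics: no point-spread
function, no uneven illumination, no fibre-type structure, no heteroplasmy
dynamics. Passing segmentation tests therefore demonstrate correctness of
the masking/labelling/measurement logic, not robustness to real microscopy
artefacts — on real images the Otsu threshold, closing radius and filter
settings are the tunable surface.

## Numerical and implementation choices

* **Segmentation**: Otsu threshold by default (manual override available),
  morphological closing with a disc of radius 1 to seal 1–2 px membrane
  gaps, connected components at 8-connectivity (4 available), filters
  defaulting to min area 300 px, min solidity 0.6, border-touching regions
  excluded. Solidity uses convex-hull pixel counts via Pick's theorem so it
  is a ratio of pixel counts. Region ids are assigned in row-major centroid
  order so joins are reproducible; coordinates are reported 0-based.
* **Correction**: 100 percentile groups, fixed; `ceiling(100 * rank / n)`
  with average-rank ties; empty NPC groups filled by linear interpolation
  between neighbours; clipping floor 1 signal unit.
* **Model**: natural log (the base cancels from every Z-score); see above
  for Shapiro subsampling and the Box-Cox grid.
* **Determinism**: every stochastic step takes a seed and restores the
  caller's RNG state; identical seed + configuration gives bit-identical
  tables, images and reports.

## Validation problem sizes

The test-suite and the acceptance script validate at sizes chosen to make
sampling error small relative to the tolerances while keeping runs fast: a
3 × 1000-fibre control pool, 2000-fibre test sections, 1000-fibre sections
with 30% ragged-red fibres for the correction validation, 10 × 10-fibre
rendered sections for segmentation, and 500 replicate pairs for CI coverage.
The vignette states no empirical result beyond what those computations
produce.

## Known limitations

* The control SEE is porin-independent; strongly heteroscedastic data would
  need a local scale the published scheme does not define.
* Percentile-matched correction assumes the NPC and sample sections share a
  mass distribution (serial sections); it degrades for non-serial NPCs.
* Wald intervals are used for proportion differences (as published); they
  are anti-conservative for very small counts — the degenerate
  absent-in-both case is reported with a warning.
* The genotype presets reproduce pattern *classes* for testing and
  illustration; they are not fitted disease models and carry no heteroplasmy
  interpretation.

## A minimal worked run

```{r example, eval = FALSE}
res <- run_pipeline(list(
  seed = 1, out_dir = "run1",
  simulate = list(
    n_controls = 3,
    control = list(n_fibres = 1000),
    patient = list(n_fibres = 1000, genotype_preset = "multiple_deletions",
                   class_fractions = list(
                     coxi   = c(normal = 0.8, int_plus = 0.05,
                                int_minus = 0.05, deficient = 0.1),
                     ndufb8 = c(normal = 0.6, int_plus = 0.1,
                                int_minus = 0.1, deficient = 0.2)))
  )
))
res$summary$ndufb8
```
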