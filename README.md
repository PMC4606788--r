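# quadfibre

Objective quantification of OXPHOS deficiency in single skeletal muscle
fibres from quadruple immunofluorescence.

Mitochondrial myopathies produce *mosaic* biochemical deficiency: within one
muscle section, fibres range from normal to completely deficient depending
on their mutant mtDNA load. Visual COX/SDH histochemistry classifies fibres
subjectively, covers only complex IV (and II), and varies between observers.
`quadfibre` implements, in R, an objective densitometry pipeline for
sections labelled with laminin (405 nm, fibre boundaries), COX-I (488 nm,
complex IV), porin/VDAC1 (546 nm, mitochondrial mass) and NDUFB8 (647 nm,
complex I). It is aimed at muscle and mitochondrial-disease labs that want
reproducible per-fibre deficiency calls and at methodologists validating
single-cell densitometry pipelines.

## What it computes

For every fibre *i* with background-corrected, log-transformed signals
(`ODporin_T`, `ODCOX-I_T`, `ODNDUFB8_T`):

* mass score: `porin_Z = (ODporin_T − μ_porin) / σ_porin`, with `μ, σ` from
  a pooled control sample (equal fibre counts per control subject, sampled
  without replacement);
* expression scores against the control regression of each protein on
  porin: `protein_Z = (ODprotein_T − (a + b·ODporin_T)) / SEE`, where
  `SEE = sqrt(SSE/(n−2))` is the regression standard error of estimate;
* categories: porin in very-low/low/normal/high/very-high at (−3, −2, +2,
  +3) SD, proteins in normal/intermediate(+)/intermediate(−)/deficient at
  (−3, −4.5, −6) SD — the −6 cut optionally calibrated from red-appearing
  (porin-positive, protein-negative) fibres.

Background correction uses a matched no-primary-control (NPC) section:
global mean subtraction for COX-I and porin, and a porin-percentile-matched
correction for NDUFB8, whose secondary antibody binds off-target in
proportion to mitochondrial mass. Category proportions between runs or
observers are compared with the two-proportion Z test and unpooled Wald 95%
intervals. A ground-truthed synthetic-data module (fibre tables, NPC tables
and rendered 16-bit multi-page TIFF sections) makes every stage testable
without biopsy material.

## Worked example

Simulate a study — three control subjects plus one patient with multiple
mtDNA deletions (a population of complex-I-deficient fibres, half of which
also lose complex IV) — then run the full pipeline:

```r
library(quadfibre)
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
  )))
res$summary$ndufb8
#>    category count percent
#> 1    normal   611    61.1
#> 2  int_plus   104    10.4
#> 3 int_minus    85     8.5
#> 4 deficient   200    20.0
```

The pipeline pooled 3 × 1000 corrected control fibres, fitted the control
model, corrected the patient section against its NPC and classified each
fibre: 20.0% of fibres are NDUFB8-deficient (Z ≤ −6) against planted 20%,
with the intermediate bands likewise recovered. `run1/` contains the
classified CSV, a summary JSON (thresholds, model provenance, seed,
clipping counts), the profile plot and a run log.

Comparing a published day-1/day-2 pair of category proportions (COX-I
deficient: 80.7% of 424 fibres vs 78.0% of 1258):

```r
compare_proportions(0.807, 424, 0.780, 1258)[, c("diff", "ci_low", "ci_high")]
#>   diff ci_low ci_high
#> 1  2.7 -1.699   7.099
```

a 2.7 percentage-point difference whose 95% CI (−1.7, 7.1) spans zero — the
two days agree.

## Command line

A thin CLI over the same functions ships at `inst/cli/quadfibre.R`
(subcommands `simulate`, `segment`, `correct`, `fit-controls`, `classify`,
`compare`, `plot`, `run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "quadfibre.R", package = "quadfibre"))')" \
    run --config config.yaml --out-dir out/
```
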