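# swimcoord

Quantitative analysis of **inter-limb coordination in swimming horses**.

Horses swimming in a pool all use the same propulsion sequence — left fore
(LF), left hind (LH), right fore (RF), right hind (RH) — but differ in how
the four limbs are timed against each other: lateral two-beat swimming
(ipsilateral fore–hind pairs move together), diagonal two-beat swimming
(diagonal pairs move together), and four-beat swimming (each limb on its
own beat). These patterns matter for equine rehabilitation and aquatic
training, where the choice of pattern shifts with direction, breaks and
fatigue. swimcoord is for biomechanics researchers and clinicians who have
per-limb propulsion/return event timings (tagged upstream from underwater
video or IMUs) and want a reproducible path from those timings to
classified, statistically compared swimming patterns.

## What it computes

Each swimming cycle is normalized to a circular percent-of-cycle axis with
the LF propulsion start at 0%. Per cycle and per lap the package computes:

- **duty factors** `DF = PP / Tcycle` per limb (propulsion share of the
  cycle), with fore/hind means `DFFront`, `DFHind`;
- **delays** between propulsion starts: lateral (LF→LH, RF→RH), diagonal
  (RH→LF, LH→RF) and contralateral; the four sequence delays always close
  the cycle (sum to 100%);
- **signed overlaps** of propulsion intervals — when two propulsions do not
  overlap, the sliding gap is returned as a negative overlap;
- the **composite ratios**

  α = MeanLatDL / DFFront,  β = MeanDiagDL / DFHind.

Laps are classified in the (α, β) plane by a **two-step k-means threshold
classifier**: k = 2 on α isolates the lateral two-beat category CatA
(α ≤ α1); k = 3 on β splits the rest into CatB (β < β1, diagonal two-beat),
CatC (β1 ≤ β < β2, four-beat medium overlap) and CatD (β ≥ β2, four-beat low
overlap). Categories map onto expert strategies as A→S1, B→S2, C/D→S3.
Published reference thresholds (0.58, 0.63, 0.91) are bundled for
fixed-threshold classification; evaluation against expert labels uses
confusion matrices, precision/recall/F1 and two-sample permutation tests
(10,000 permutations, significance at p < 0.001). A synthetic lap generator
with bundled per-category coordination profiles supports validation studies
end to end. See the vignette in `vignettes/coordination-analysis.Rmd` for
the full model description.

## Worked example

Simulate four horses (12 laps each, uniform category mixture), fit the
classifier, and evaluate it against the emitted expert labels:

```r
library(swimcoord)

cfg    <- synthetic_config(laps_per_horse = 12L, seed = 42)
laps   <- generate_cohort(equal_mixtures(sprintf("H%02d", 1:4)), cfg)
params <- lap_parameters(laps)

model <- fit_two_step(params, seed = 42)
model
#> <swim_classifier>  two-step k-means threshold classifier
#>   alpha1 = 0.6096   beta1 = 0.6182   beta2 = 0.8790
#>   fitted on 48 laps: CatA=17 CatB=7 CatC=8 CatD=16

params$category <- as.character(predict(model, params))
confusion_evaluate(params$expert_label, params$category)
#> <confusion_summary>  overall accuracy: 91.7%
#>
#>       predicted
#> expert  A  B C+D
#>     S1 14  0   0
#>     S2  0  7   1
#>     S3  3  0  23
#>
#>  group strategy precision recall   f1 support
#>      A       S1      0.82   1.00 0.90      14
#>      B       S2      1.00   0.88 0.93       8
#>    C+D       S3      0.96   0.88 0.92      26
```

The fitted thresholds (0.61, 0.62, 0.88) land next to the bundled reference
constants (0.58, 0.63, 0.91): on simulated cohorts the two-step procedure
recovers boundaries close to the published ones, with the residual
misclassification concentrated where the four-beat medium-overlap group
borders its neighbours. `summarize_cohort(params)` then prints the
per-category lap shares, the two-beat/four-beat split, hand shares and each
horse's dominant category; `plot_coordination(laps[[1]])` draws the
coordination diagram (propulsion bars on the 0–100% cycle axis).

A thin command-line wrapper covers the same pipeline
(`inst/cli/swimcoord simulate|metrics|classify|evaluate|report`; see
`?swim_cli`).

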