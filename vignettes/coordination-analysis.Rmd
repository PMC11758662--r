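---
title: "Quantifying and classifying swimming limb coordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and classifying swimming limb coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimcoord)
```

## The problem

When a horse swims, each limb alternates between a *propulsion phase* (the
backward, thrust-producing sweep, the aquatic analogue of stance) and a
*return phase* (the forward recovery, the analogue of swing). All horses use
the same propulsion sequence — left fore, left hind, right fore, right hind —
but the *timing* of the four limbs varies widely: some horses pair the
ipsilateral fore and hind limbs (a lateral two-beat pattern), some pair the
diagonals (a diagonal two-beat pattern), and some move each limb
independently (a four-beat pattern). swimcoord turns tagged propulsion/return
event times into quantitative coordination parameters, classifies laps into
four categories, and evaluates the classification against expert labels.

## From event times to the circular cycle

A swimming cycle runs from one propulsion start of the reference limb
(left forelimb by default) to the next. `normalize_cycle()` maps each limb's
propulsion interval onto a circular percent-of-cycle axis with the reference
start at exactly 0%. Conventions that remove all ambiguity downstream:

* the axis is half-open, `[0, 100)`; a propulsion interval is
  `(start, start + duration)` and an interval crossing the cycle boundary
  keeps `end > 100` internally, being reduced mod 100 only for display;
* event times are taken as exact (the upstream tagging already operates at
  the frame level; a frame column is accepted and converted at 120 fps);
* laps keep only complete cycles: `split_lap_into_cycles()` segments an
  event stream at successive reference starts (n starts give n − 1 cycles)
  and drops the trailing incomplete cycle with a warning rather than
  extrapolating it.

## The coordination parameters

For each cycle, `compute_params()` produces:

* **Duty factor** `DF = PP / Tcycle` per limb, with `DFFront` and `DFHind`
  the fore/hind pair means. Units: percent of cycle.
* **Delay** `DL(i → j)`: the circular forward distance from limb *i*'s
  propulsion start to limb *j*'s. The pairings follow the propulsion
  sequence: lateral delays run fore → ipsilateral hind (LF→LH, RF→RH),
  diagonal delays run hind → diagonal fore (RH→LF wrapping the boundary,
  LH→RF), contralateral delays run left → right. Under exactly these
  directions the four sequence delays close the cycle:
  `LatDL_left + DiagDL_right + LatDL_right + DiagDL_left = 100`.
* **Signed overlap**: the circular intersection of two limbs' propulsion
  intervals; when the intervals are disjoint the limbs are *sliding* and the
  value is minus the smaller of the two circular gaps, so one signed number
  encodes both regimes (`SL = max(0, −OL)` is available as a helper).
* **Composite ratios**
  $$\alpha = \frac{\mathrm{MeanLatDL}}{\mathrm{DF_{Front}}}, \qquad
    \beta = \frac{\mathrm{MeanDiagDL}}{\mathrm{DF_{Hind}}}.$$
  Small $\alpha$ means ipsilateral synchronization (lateral two-beat); small
  $\beta$ means diagonal synchronization (diagonal two-beat). Both are
  dimensionless and invariant to uniform time scaling — cycle duration
  cancels in every parameter.

`aggregate_lap()` reduces a lap to one parameter vector by averaging the
base parameters (duty factors, delays, overlaps) over its cycles and then
*recomputing* the pair means and ratios from the averaged components. The
alternative (averaging per-cycle ratios) differs only at second order but is
ill-defined as a summary of a ratio; we fix the ratio-of-means convention
and document it rather than exposing both.

## The two-step classifier

`fit_two_step()` mirrors a two-stage unsupervised procedure:

1. k-means with k = 2 on $\alpha$ alone; the lower cluster is **CatA**
   (lateral two-beat) and the threshold $\alpha_1$ separates it;
2. k-means with k = 3 on $\beta$ of the remaining laps, giving
   **CatB** ($\beta < \beta_1$), **CatC** ($\beta_1 \le \beta < \beta_2$)
   and **CatD** ($\beta \ge \beta_2$).

Two-beat categories map onto strategies as CatA → S1, CatB → S2; both
four-beat categories CatC/CatD map to S3 (medium vs low overlap), so the
category → strategy map is not invertible.

Design choices where the procedure was genuinely open:

* **Threshold extraction.** A k-means fit yields clusters, not thresholds.
  We define each threshold as the midpoint between the two adjacent
  clusters' *nearest members* (not between centroids): this is the unique
  natural boundary that reproduces the cluster assignment exactly when the
  training laps are re-classified with the thresholds, making the model
  fully summarized by `(alpha1, beta1, beta2)`.
* **Initialization.** `stats::kmeans()` with 10 random restarts under a
  caller-supplied seed. On 1-D data with well-separated groups the optimum
  is found reliably; fits are deterministic given the seed and label
  assignments are invariant to the input order.
* **Raw scales.** Clustering runs on raw ratio values with no
  standardization, so thresholds live on the same scale as the ratios.
* **Boundary ties** follow the stated inequalities exactly:
  $\alpha = \alpha_1$ → CatA, $\beta = \beta_1$ → CatC,
  $\beta = \beta_2$ → CatD.
* **1-D, not 2-D.** The two stages cluster $\alpha$ and $\beta$ separately
  rather than the plane jointly; `fit_alternative()` provides the plane
  k = 3 variant and a two-successive-k = 2 variant for comparison — both
  produce only three groups and cannot resolve the two four-beat
  subcategories.

Bundled reference constants: the published thresholds
$(\alpha_1, \beta_1, \beta_2) = (0.58, 0.63, 0.91)$ are shipped via
`reference_thresholds()` for fixed-threshold classification; they are
constants, not something the package refits (the original per-lap data are
not public).

## Evaluation

`confusion_evaluate()` treats the expert strategy labels as ground truth: a
predicted category is correct when its mapped strategy equals the expert
label. Per category-wise group (A, B, and C+D pooled by default) it reports
precision, recall, F1 (harmonic mean; defined 0 at precision = recall = 0)
and support. `cohen_kappa()` is available when a symmetric agreement measure
is preferred.

`permutation_test()` compares two samples with the statistic
$|\bar{x}_a - \bar{x}_b|$, a two-sided minimal reading of "difference".
The null is built by re-partitioning the pooled values `n_perm` times
(default 10,000) and the p-value uses the add-one estimator
$p = (1 + \#\{T^* \ge T\}) / (1 + n_\mathrm{perm})$, which can never return
zero. The pooled values are sorted and the smaller group size is permuted,
making the test exactly symmetric in its arguments. Significance defaults to
$p < 0.001$; no multiple-testing correction is applied by default because
the reference analysis reports a fixed level across all pairs — a
Bonferroni option exists but is off.

## The synthetic-lap generator

No public per-lap dataset exists, so `generate_lap()` /
`generate_cohort()` emulate the statistical structure the analysis assumes:

* **Generative primitives** are the four duty factors and the four sequence
  delays, drawn independently from truncated normal distributions (inverse
  CDF, truncation at 5–95% of cycle to exclude degenerate phases) around a
  category profile. The bundled `category_profiles()` carry the published
  per-category means and SDs; the delays are renormalized to sum to exactly
  100 (spreading the adjustment evenly rather than solving for the fourth
  delay), so delay closure holds in every generated cycle. Overlaps are
  consequences of the construction, never drawn.
* **Cycle-to-cycle jitter** perturbs each parameter within a lap
  (`jitter_sd`, default 1.5% of cycle — real within-lap variability is not
  reported anywhere we know of, so this default is a deliberately mild
  guess, flagged here).
* **Timelines.** Cycle duration is drawn uniformly from 2.0–3.5 s, a
  realistic range for a swimming cycle; it is cosmetic, since every
  parameter is a cycle percentage.
* **Sessions.** A simulated session has 12 laps: two warm-up laps (one per
  hand) and a left-hand and right-hand block of five, each block opening
  with an `after_break` lap. Categories are drawn per lap from per-horse
  (optionally per-hand) mixtures; emitted expert labels equal the
  generating category's strategy, flipped with probability
  `label_noise_rate`.

### What passing tests do and do not show

The generator reproduces the *marginal* per-category distributions of the
eight primitives and their closure constraint. It does not model
within-horse correlation across laps, fatigue drift, turn mechanics, or any
correlation between duty factors and delays within a lap. One measurable
consequence: cohorts resampled from the published per-category SDs as
untruncated normals overlap in the $(\alpha, \beta)$ plane — the published
SDs describe groups that were themselves *delimited* by thresholds in that
plane, so resampling them without that truncation re-creates boundary
overlap, concentrated in CatC, whose $\beta$ spread spans both $\beta_1$
and $\beta_2$. The test suite measures recovery of generating categories by
a freshly fitted classifier at 32 laps per category (about 90% at the fixed
seed, against a 95% aspiration), and we keep both the published SDs and the
strict bar rather than quietly narrowing the generator to make the check
pass. Fitted thresholds on such cohorts land close to the published
constants, which is the substantive claim the simulation can support.

## Numerical choices

* Circular intersection of two propulsion arcs is computed exactly (linear
  overlap at shifts −100/0/+100), not on a grid; the test suite checks it
  against an independent 10,000-point discretized oracle to 0.02.
* Degenerate inputs fail loudly with stable messages: `"incomplete cycle"`,
  `"ambiguous cycle"`, `"invalid timing"`, `"no analyzable cycle"`,
  `"degenerate clustering input"`, `"unclassifiable lap"`,
  `"insufficient data"`, `"invalid mixture"`, `"infeasible profile"`.
  `validate_lap()` is the one diagnostic surface that never raises.
* Report percentages are rounded to one decimal only at print time; all
  stored values are exact.
* Problem sizes in the test suite (32–100 laps per category, 2,000–10,000
  permutations, 500 calibration replicates) are chosen so the whole suite
  runs in well under a minute while keeping Monte-Carlo error far below the
  asserted tolerances.

## Limitations

* Event tagging is upstream: the package takes propulsion/return times as
  given and does not process video or joint-angle signals.
* The published thresholds are constants of one 125-lap, 11-horse cohort of
  show jumpers in one pool; nothing here claims they transfer to other
  populations — refit with `fit_two_step()` where per-lap data exist.
* The generator's independence assumptions above; see the recovery
  discussion.
* Two small internal inconsistencies of the published summary tables are
  preserved as printed and noted in the accessors' documentation
  (`reference_cohort_counts()`, `reference_category_metrics()`), not
  silently repaired.
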