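---
title: "Detecting condition-related facial-shape change from landmark time series"
author: "facegmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting condition-related facial-shape change from landmark time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facegmm)
```

## The problem

Automated facial-landmark detectors can turn ordinary video of an animal
into a time series of 2-D landmark configurations, one per analysed frame,
each with a detector confidence score. Given such series for a set of
subjects filmed under two conditions — here, dogs filmed at home during a
real firework event and again on a calm evening — we want to know whether
facial *shape* differs between conditions, where on the face the change
is localized, and how strongly the two conditions separate in shape space.

The raw series are noisy: frames where the head is tilted or turned, or the
detector is unsure, carry more pose artefact than expression signal, and
consecutive frames are nearly duplicates of one another. `facegmm`
implements the complete chain from raw series to condition statistics:

1. **Frame selection** — a cascade of quality filters (below).
2. **Generalised Procrustes Analysis (GPA)** — removes translation, scale
   and rotation, leaving only shape.
3. **Shape PCA** — decomposes the aligned coordinates into orthogonal
   modes of variation.
4. **Per-PC condition tests** — one-way two-group ANOVA on each retained
   component's scores, Shapiro–Wilk residual checks, and
   Benjamini–Hochberg FDR control across components.
5. **Subject-level effect size and power** — paired Cohen's *d* on
   per-subject mean scores and noncentral-*t* post-hoc power.
6. **Pose residualization** — pooled within-group regression of shape on
   the first three PCs (which predominantly encode residual head pose).
7. **Two-group CVA** — Fisher's discriminant with Wilks' Λ and its exact
   two-group *F* transform.

Because datasets of this kind are rarely public, the package ships a
synthetic-data generator that emulates the statistical structure the
pipeline assumes, with recorded ground truth, so every stage is testable
end to end.

## The landmark scheme

The detector scheme has 46 landmarks. Ear-pinna geometry varies enormously
between breeds (pricked, rose, floppy …) and moves partly by inertia, so
the five pinna landmarks per ear are discarded before analysis, leaving 36
landmarks that include the ear *bases* — ear carriage therefore still
enters the analysis, while breed-specific pinna shape does not. The roles
the statistics need are fixed by landmark number: inner eye corners 6 and
7, nose centre 22, upper-muzzle pair 25/28, lower-muzzle pair 31/32, lip
corners 33/34, ear bases 35/36. Coordinates are in the image frame
(x rightward, y downward), so "dorsal" is negative y and "medial" points
toward the facial midline.

```{r scheme}
scheme <- default_scheme()
scheme
reduce_scheme(scheme)
```

## The filter cascade

Filters run in this order, each shrinking the previous stage's output:

| stage | rule | default |
|---|---|---|
| confidence | keep sets with confidence ≥ threshold (inclusive) | 0.6 |
| pose outliers | drop sets whose head tilt **or** rotation asymmetry exceeds the percentile of the pooled post-confidence sample | 95th |
| interval | greedy earliest-first thinning to ≥ a minimum spacing | 1 s |
| subject inclusion | keep subjects with ≥ a minimum of sets in *both* conditions | 10 |
| top-k | keep the k highest-confidence sets per subject per condition | 10 |

Head tilt is the acute angle (degrees, folded to [0, 90] — no sign
convention is meaningful for outlier removal) between the inner-eye
segment and the x-axis; rotation asymmetry is the absolute difference of
the two eye-to-nose distances, which is zero for a frontal face and grows
as the head turns. The percentile uses linear interpolation between order
statistics (R's type 7), a single declared convention that makes survivor
counts exactly reproducible. Pooling the percentile across videos is the
default (a per-video switch exists): the quantile is then a property of
the study, not of each video's own pose distribution. Ties in the top-k
selection break by earlier timestamp, then input order, so selection is
deterministic.

With 11 subjects, two conditions and abundant qualifying frames, the
design forces 11 × 2 × 10 = 220 analysis sets.

## Superimposition and shape statistics

GPA centres every configuration, scales it to unit centroid size, and
iteratively rotates all configurations onto the running consensus (the
renormalized mean) until the consensus moves less than `tol` (default
1e-8) in Frobenius norm. Only proper rotations are allowed — a reflection
would silently swap left and right anatomy. The consensus is initialized
from the normalized mean of the normalized shapes: this is deterministic,
independent of input order, and makes the procedure a fixed point on its
own output (re-running GPA on aligned coordinates converges in one
iteration), which is the natural stability property to test. Tangent-space
projection before PCA is deliberately omitted: shape variation at this
scale is small enough that Procrustes coordinates and tangent coordinates
differ negligibly, and the PCA is defined directly on the Procrustes
coordinates.

PCA retains the smallest prefix of components whose cumulative explained
variance reaches `variance_target` (default 0.90) — the prefix is
data-driven rather than a hard-coded component count. The per-component
ANOVA is run on all retained landmark sets. This pseudo-replicates
subjects (each contributes 10 sets per condition); the package follows
the source design exactly here and addresses independence at the
subject level instead: the effect-size and power computation first
averages scores per subject per condition, then forms paired differences.
Since subjects appear in both conditions, subject effects cancel from the
between-condition contrast while inflating the within-group variance, so
the set-level ANOVA errs conservative rather than anticonservative — the
null-simulation test verifies that the any-significant-PC rate stays at
or below its binomial band around α.

Power is computed from the noncentral *t* distribution for a two-sided
paired test: noncentrality |d|·√n with n−1 degrees of freedom. With
d = 1.11 and n = 11 this gives 0.912, the printed three-figure value.

CVA runs by default on the tested-PC scores, not the raw 72 coordinates:
with n = 220 and q ≈ 8–20 the pooled within-group covariance is then
guaranteed nonsingular, and Wilks' Λ = det(W)/det(W+B) has the exact
two-group transform F = ((1−Λ)/Λ)(n−q−1)/q with df (q, n−q−1). The unit
CV1 direction is mapped back through the PC loadings to a landmark
displacement field for visualisation.

## The synthetic generator

`simulate_dataset()` draws, per subject, a base face = canonical template
plus a smoothed Gaussian deviation field (i.i.d. per-landmark draws
averaged with the two nearest template neighbours — crude spatial
coherence without a full deformation model); per frame it adds the
condition displacement field (fireworks only), i.i.d. landmark jitter, a
one-sided x-compression standing in for yaw, a roll rotation, and a
log-normal-scale/Gaussian-translation similarity map into pixel space.
Detector confidence is linear in normalized pose magnitude and jitter
norm, clipped to [0, 1] — only its monotonicity matters to the filter
tests, so no more elaborate model is warranted.

The ground-truth displacement field mirrors the direction structure the
analysis should recover: ear bases medial, nose and upper muzzle dorsal,
lower muzzle ventral, lip corners lateral.

Defaults follow the study design: 11 subjects × 2 conditions, 13 landmark
sets/second (within the 12–15 range), 264 s videos (the mean video
length), jitter SD 0.005 and subject SD 0.02 centroid-size units, roll SD
8°, yaw SD 0.15, ear displacement 0.03 and mouth displacement 0.015
centroid-size units. No quantitative effect magnitude is published for
the real faces, so the displacement defaults are chosen for testability —
large enough to be recoverable at the stated noise, small relative to
subject variation. Remaining nuisance defaults (image scale 120 px/unit
with log-SD 0.08, translation SD 20 px around a 320×240 centre,
confidence base 0.85 with pose slope 0.08, noise slope 0.5, jitter SD
0.02) were set once to plausible video-analytics magnitudes; they are not
calibrated to any reported quantity.

The template itself is an invented frontal configuration — bilaterally
symmetric, unit centroid size, horizontal inter-eye line — standing in
for a frontal dog face. Its one deliberately tuned feature is wide-set
eyes (normalized inter-eye distance ≈ 0.28): the head-tilt metric divides
frame jitter by the inter-eye distance, so a narrow-eyed template would
make measured tilt jitter-dominated and decouple it from the simulated
roll that it is supposed to proxy.

What the generator does *not* emulate: photorealistic or breed-specific
geometry, true 3-D perspective (yaw is a planar compression), detector
failure modes beyond confidence degradation, temporal autocorrelation of
expressions, or owner/environment covariates. Passing recovery tests on
this generator therefore shows the pipeline is statistically sound under
its stated assumptions — not that any particular real-world dataset
satisfies those assumptions.

## Numerical choices and degenerate inputs

* Percentile: linear interpolation (type 7); confidence boundary
  inclusive; outlier rule removes on *either* metric.
* GPA: tol 1e-8 on consensus movement, max 100 iterations;
  non-convergence is a warning with `converged = FALSE`, not an error.
* Rotation fitting: SVD with determinant correction; coincident-landmark
  configurations raise degenerate-shape errors.
* BH adjustment delegates to `stats::p.adjust`; ANOVA to `stats::aov`;
  Shapiro–Wilk to `stats::shapiro.test`; PCA to `stats::prcomp` — these
  are standard computations with canonical implementations, and the
  package's own contribution is the pipeline around them.
* The TPS heatmap solves the standard `r² log r` system; a singular
  system (duplicate landmarks) falls back to nearest-neighbour with a
  warning.
* Zero-variance paired differences make Cohen's d undefined and raise an
  error rather than returning infinity.

## Simulation sizes used in the test suite

The packaged tests run the full pipeline on synthetic studies with
shortened videos (25–40 s instead of 264 s). This is purely a
problem-size choice: the cascade still saturates the 220-set design
(interval thinning caps each video's contribution at about one set per
second, and top-10 selection needs only 10 per condition), so the
statistical structure under test is unchanged while simulation stays
cheap. The recovery and error-control suites use 100 effect replicates
and 200 null replicates at 30 s per video.

## Known limitations

* 2-D only; no sliding semilandmarks; no missing-landmark estimation
  (all landmarks must be present after filtering).
* The set-level ANOVA pseudo-replicates subjects by design (see above);
  a subject-averaged ANOVA is available by passing per-subject mean
  scores to `anova_per_pc()` directly.
* CVA p-values come from the exact two-group F transform, not
  permutation; with strong non-normality they are approximate.
* The generator's confidence model is monotone-linear; real detector
  confidence can be miscalibrated in ways no filter threshold fixes.

## A worked run

```{r run, eval = FALSE}
cfg <- run_config(
  synthetic = synthetic_config(seed = 1),
  out_dir = "facegmm_run"
)
summary <- run_pipeline(cfg)
str(summary)
```

The run directory contains the per-stage filter counts
(`filter_report.json`), the per-PC test table (`condition_tests.csv`),
per-set scores (`pc_scores.csv`), the paired effect (`effect.json`), the
CVA statistics (`cva.json`), displacement fields (CSV), the rendered
figures, and a machine-readable `summary.json`. Re-running the same
config reproduces every file byte for byte.
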