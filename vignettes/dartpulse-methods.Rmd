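---
title: "Methods: quantifying love-dart mucus effects on snail reproductive organs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying love-dart mucus effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartpulse)
```

# The experiment being modelled

In organ-bath cross-reactivity experiments on helicid snails, a dissected
preparation of the female reproductive tract of a focal species (diverticulum,
copulatory canal, bursa copulatrix tract and atrium, pinned in saline) is
exposed to dart-gland mucus extracts of several species. Three small black
markers are glued onto the diverticulum, the copulatory canal and the atrium,
and a webcam records the preparation. Each *trial* is one mucus application:
10 min of control activity, a 5-min exposure pause, then 10 min of response
activity. Marker positions are tracked per frame and analysed every 5 s.

Each experimental day uses one preparation. The focal species' own mucus is
tested once at the start and once at the end of the day (the two *positive
controls*); between them, up to five other species' extracts are applied in
random order, each extract used only once. A separate assay photographs the
diverticulum before mucus addition and 15 min later and measures its length
six times (three per side), yielding the *shortening* effect.

`dartpulse` implements the complete analysis: displacement traces, a
rule-based contraction detector and trial scorer, daily-control
normalization, the shortening metric, and the study-level inference (Steel
many-one rank test, split-plot mixed ANOVA with simple effects,
paired/nonparametric tests, log-link GLMs with AICc, Blomberg's K). A
synthetic-data module generates every input with known ground truth, so the
whole chain can be exercised and calibrated end to end. The exported
functions, the `simulate_study()` wrapper and this vignette are the
package's interface; no shell entry point is shipped because users drive the
pipeline from R.

# Contraction scoring

## Displacement series

For a marker track resampled to the 5-s grid, the displacement at step $k$
is the Euclidean distance between consecutive positions,
$d_k = \lVert p_{k+1} - p_k \rVert$. Samples are labelled by segment
(control: 0–600 s; response: 900–1500 s); intervals inside the exposure
pause are dropped. A 600-s segment therefore contributes 121 coordinate
samples and 120 displacement values. Displacements are translation
invariant by construction, and all event-counting criteria below are
relative, so the coordinate units (pixels or an abstract scale) cancel;
intensity scales linearly with the units.

## Detection rules

Three counting rules define a contraction:

1. **Relative threshold.** $T = d_{\min} + 0.25\,(d_{\max} - d_{\min})$,
   computed over the *whole trial* — control and response segments jointly.
   The joint range keeps the two segments of a trial comparable; a
   per-segment range would let a quiet control segment manufacture events
   out of noise. (Applying the rule to the displacement series rather than
   to raw coordinate excursions is the implemented reading; the
   `threshold_frac` argument makes the rule's strength configurable.)
2. **Duration.** Maximal runs of samples with $d > T$ are candidate events;
   a run that stays above threshold for more than 180 s is not counted.
   "Time above threshold" is the only operational definition of event
   duration available from the series.
3. **Separation.** Peaks (the run maximum; earliest sample on ties) closer
   than 15 s are merged, keeping the larger peak and the union of the run
   extents. Merging is closest-pair-first, which is order independent.

Degenerate traces (range below `range_epsilon`, default $10^{-8}$) yield
zero events with a warning rather than thresholding numerical noise. Runs
truncated by a segment edge are retained when their observed duration passes
the 180-s filter (`keep_boundary = FALSE` drops them).

The per-trial score is then: contraction counts per segment, the *induced*
count (response minus control), the *intensity* (maximum displacement
anywhere in the trial) and the responder flag (strictly more response- than
control-segment contractions).

## Daily-control normalization

Because preparations differ between days (and respond more strongly to the
second daily control than to the first), a trial's response is expressed
relative to its day: `induced_rel` subtracts the mean induced count of the
day's two positive controls, and `intensity_rel_pct` maps intensity onto a
0–100 scale anchored at a configured zero-response baseline (0 displacement
units for synthetic data; in real data, the coordinate level of
preparations that showed no response) and at the day's control mean
intensity (100 %). The atrium stream is excluded by default as
non-meaningful, and day–organ strata in which nothing responded can be
dropped (`drop_nonresponding_days`), mirroring the study's exclusions.

# The synthetic-data generator

The generator's defaults *are* the study conditions: 29 days; two focal
controls bracketing up to five of eight other species per day; 600 s
control / 300 s pause / 600 s response sampled every 5 s; and per-species
fractional shortening effects of 0.077 (focal control, the midpoint of the
two controls' range), 0.066, 0.054, 0.065, 0.155 and 0.196 for the species
with a real effect, 0 otherwise, around a 29.1-mm baseline length (the
value that makes the strongest effect equal 5.7 mm = 19.6 %). Contraction
rates default to 2 events per 10 min of spontaneous activity and, in the
response segment, 3.98 for the focal species (so the mean induced count is
1.98, the observed pooled control mean) and for the other reactive species,
with the three non-reactive species (*H. pomatia*, *H. lucorum*,
*F. fruticum*) left at the spontaneous rate. The webcam frame rate is not
fixed by the protocol, only the 5-s analysis grid; the native frame
interval is a parameter (default 1 s) and within-interval motion is linear.

Events are raised-cosine displacement pulses: smooth, single-peaked, with
controllable duration — realized as alternating-direction positional
increments so that the 5-s displacement series shows a bump whose peak
equals the event amplitude. Amplitudes are drawn from
$N(10, 2^2)$ truncated to $[0.45, 1.4]\times$ mean and widths to
$[20, 175]$ s, with at least 20 s between events: within this regime every
planted event clears the 25 % relative threshold of its trial in the
noise-free case, survives the 180-s filter, and cannot be merged with a
neighbour — which is what makes exact ground-truth recovery a meaningful
test. Baseline jitter is likewise planted in the displacement domain
(`noise_sd` sets the scale of the per-interval fluctuation): differencing
iid positional noise would instead produce a heavy-tailed displacement
floor whose spikes are indistinguishable from real events under a purely
rule-based detector. A slow linear-plus-sinusoidal drift (0.002 units/s and
0.2 units over a 300-s period) exercises the relative threshold without
approaching event amplitudes.

What the generator does **not** emulate: correlated multi-organ motion (a
contracting canal displacing the diverticulum's marker), secular changes in
preparation responsiveness within a day (available only as the optional
`control2_inflation`), non-stationary noise, or marker occlusion. Passing
tests on synthetic data therefore demonstrate the correctness and
calibration of the *procedure*, not the biological fidelity of any
particular recording.

Tracking is a stand-in for the original GUI auto-tracker: Otsu thresholding
on range-normalized inverted intensity (markers are high-contrast black
tape, and the relative threshold makes tracking invariant to global
intensity rescaling), connected components via `EBImage::bwlabel`,
intensity-weighted centroids, greedy one-to-one nearest-neighbour linking,
linear interpolation across gaps of up to 3 frames, and an unusable flag
beyond 10 % gap frames. Rendered frames use sub-pixel edge anti-aliasing so
the round trip render → track is accurate to well under half a pixel.

# Inference layer

## Steel many-one rank test

The centrepiece statistic compares each treatment sample with a shared
control. For treatment $i$ the pooled control-plus-treatment sample is
midranked; the statistic is the treatment rank sum $R_i$, standardized as
$Z_i = (R_i - E[R_i]) / \sqrt{\mathrm{Var}(R_i)}$ with
$E[R_i]=n_i(N+1)/2$ and the tie-corrected variance
$\mathrm{Var}(R_i) = \frac{n_0 n_i}{12}\left[(N+1) -
\frac{\sum_j (t_j^3-t_j)}{N(N-1)}\right]$. Negative $Z$ means the
treatment sits below the control. Family-wise adjusted p-values take the
$k$ comparisons' shared control into account:

* **normal mode** evaluates $P(\max_j |Z_j| \ge |z_i|)$ under an
  equicorrelated multivariate normal with
  $\rho_{ij} = \sqrt{\lambda_i\lambda_j}$, $\lambda_i = n_i/(n_i+n_0)$
  (averaged over pairs when sizes are unbalanced), by one-dimensional
  integration over the shared factor; a conservative Šidák adjustment is
  available as `adjust = "sidak"`;
* **permutation mode** jointly permutes the group labels and compares
  $|z_i|$ with the permutation distribution of $\max_j |Z_j|$, with the
  observed arrangement counted in numerator and denominator. This mode is
  also the small-sample oracle: the two modes agree on continuous data and
  the permutation p matches exhaustive enumeration on tiny samples.

`mode = "auto"` uses the normal approximation unless a sample has fewer
than 6 observations. The null calibration (8 treatments of $n = 19$ against
an $n = 19$ control) holds the family-wise size at or below the nominal
0.05 (~0.046 over 5000 simulations).

## Remaining tests

Textbook procedures delegate to their standard implementations —
`kruskal.test` (tie-corrected H; defined as $H=0$ when every observation is
identical), Pearson `chisq.test` without continuity correction on 2×2
responder tables, `lm`/`anova` for the one-way baseline-recovery check, and
`glm` for the order-effect models (Poisson log link for counts; Gaussian
log link for intensities, initialized at the log response clipped below at
$10^{-6}$ since intensities can approach zero). Model comparison uses
$AICc = AIC + 2k(k+1)/(n-k-1)$. The paired Wilcoxon statistic is computed
directly (zeros dropped, midranks, tie-corrected normal approximation, no
continuity correction) because the reported quantity is the standardized
$Z$, which `wilcox.test` does not expose.

The mixed (split-plot) ANOVA for the paired log lengths exploits the
two-level repeated factor: subject means carry the between-subject
information (Species: one-way ANOVA on means), subject differences the
within-subject information. With unbalanced species groups the Time main
effect is Type-III style — it tests the *unweighted* mean of the per-species
Time effects — and the interaction is the one-way ANOVA of the differences.
Both use the pooled within-subject error with $N - s$ degrees of freedom,
and Time has 1 numerator d.f. Simple effects of Time per species are
Fisher-LSD contrasts: deliberately unadjusted t-tests against the pooled
within-subject error, which is what LSD means; with a significant
interaction as gate, this matches the study's follow-up. Subjects missing a
time point are dropped with a warning.

## Blomberg's K

With trait vector $x$ on a tree with Brownian covariance $V$ (entries =
shared root-to-tip path length; from `ape::vcv`),
$\hat a = (1'V^{-1}1)^{-1} 1'V^{-1}x$,
$MSE_0 = (x-\hat a)'(x-\hat a)/(n-1)$,
$MSE = (x-\hat a)'V^{-1}(x-\hat a)/(n-1)$, and
$$K = \frac{MSE_0/MSE}{\left[\mathrm{tr}(V) - n/(1'V^{-1}1)\right]/(n-1)}.$$
$K = 1$ is the Brownian expectation; a star tree forces $K = 1$ exactly for
any non-constant trait. K is invariant to affine trait transforms and tip
order, and the implementation agrees with `phytools::phylosig` to machine
precision (the reference is used only as a cross-check in the tests).
Randomization p-values permute trait values across tips, count the observed
arrangement in numerator and denominator (so $p \ge 1/(n_{\text{rand}}+1)$),
and default to 1000 randomizations. Zero-length terminal branches are
nudged by $10^{-8}\times$ tree height to keep $V$ invertible (logged via a
message). The trait fed to K for the shortening effect is the per-species
mean shortening in mm; for the contraction responses, per-species means of
the relative response are the default (means of raw scores work equally via
`species_trait_means`).

The study tree shipped in `inst/extdata/` is a *synthetic* stand-in with
plausible topology and branch lengths — tree inference from sequences is
out of scope, and the tree is an input, not a result.

# Numerical choices and problem sizes

* Per-trial seeds derive deterministically from the master seed, day and
  order position (kept below $2^{31}$), so identical parameters give
  byte-identical simulations while trials stay independent.
* The detector treats ranges below $10^{-8}$ as degenerate; the Steel test
  reports $Z = 0$ with a warning when a pooled sample is entirely tied;
  constant traits make K undefined (error).
* Validation and calibration sizes were chosen to finish in minutes on one
  CPU while leaving Monte-Carlo error well inside the margins being tested:
  500 trials per detector-recovery regime, 5000 null simulations for the
  Steel family-wise size, 1000 Brownian replicates for the K calibration,
  150 × 199 randomizations for the null-p uniformity check, and the full
  29-day study (203 trials × 3 organs) for the end-to-end runs.

# Known limitations

* The rule-based detector counts any suprathreshold excursion; under heavy
  noise with only weak planted events, noise spikes can enter the count
  (exact-recovery remains ≥ 95 % at noise equal to 10 % of the mean event
  amplitude, but degrades beyond that). This is a property of the counting
  rules, not of the implementation.
* The equicorrelated-MVN family-wise adjustment is an approximation for
  unbalanced designs (exact correlation structure is only approximately
  equicorrelated); the permutation mode bounds the discrepancy.
* The tracker assumes high-contrast, non-overlapping markers; it does not
  handle occlusion or deformable templates.
* Whether the six length measurements should be averaged per side first is
  ambiguous in the assay description; the grand mean of six is implemented,
  and the two differ only with unequal per-side replication.
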