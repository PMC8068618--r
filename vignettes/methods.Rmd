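---
title: "Methods: sway ellipses, gait stability and path-integration scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sway ellipses, gait stability and path-integration scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturenav)
```

This package implements the measurement chain of a balance/gait/navigation
study in blind and visually-impaired (BVI) versus sighted children, plus
the statistics layer and a synthetic cohort generator that provides ground
truth for every stage. This vignette documents the models, the tunable
parameters, the numerical choices, and what the validation battery does
and does not establish.

## Postural sway: the 95% prediction ellipse

Center-of-pressure traces (medial–lateral and anterior–posterior, cm,
180 Hz, 30 s trials) are summarized by the area of the ellipse expected to
contain a *future* CoP observation with 95% probability under bivariate
normality. With sample covariance $S$ over $n$ samples the area is
$\pi \sqrt{\det S}\, k$ with the prediction-ellipse scale factor

$$k = \frac{2(n+1)(n-1)}{n(n-2)} F_{0.95;\,2,\,n-2},$$

which is the small-sample form appropriate for a prediction (not a
confidence) ellipse; at $n = 5400$ it is within 0.1% of
$\chi^2_{0.95,2} = 5.99$. Semi-axes are the square roots of the
eigenvalues of $kS$, so area $= \pi a b$ holds identically.

Choices worth knowing:

* **No filtering or detrending** is applied before the fit. A low-pass
  option could be layered on by the caller; none is built in.
* **Autocorrelation is ignored in the scale factor** (the standard PEA
  convention). CoP samples at 180 Hz are strongly dependent, so the
  *containment fraction* of a single trace fluctuates more than an iid
  calculation suggests; the tests therefore check nominal containment
  (93–97%) on iid Gaussian input and only the area on OU sway.
* Degenerate traces (constant, or $n < 3$) are errors, not NaNs.

## Gait dynamics

### Exclusion rules

The walking protocol is 6 min of out-and-back 25 m hallway passes. The
first and last full bout are discarded, and within each remaining bout
10% of samples (2.5 m / 25 m) are trimmed at both ends, mapping distance
linearly onto time within a bout — without position data a linear map is
the only defensible convention, and the trimming fractions, not the
absolute distances, are what matter. A per-sample exclusion mask removes
visually flagged non-stationary segments. Fewer than three bouts is an
error (nothing would remain).

### Stride segmentation and variability

Stride-start events are prominent sagittal-plane angular-velocity peaks
with a minimum separation of 0.4 s and a height threshold at 50% of the
signal range. Any detector that recovers ground-truth events on generated
gait satisfies the contract; on the generator's templates the recovered
stride times match the drawn ones to within one sample. Stride-time
variability is the $n-1$ sample standard deviation of the inter-event
intervals.

### Local dynamic stability

The three angular-velocity channels of 63 strides (the study minimum) are
linearly time-normalized to 100 samples per stride (6300 samples), so the
Lyapunov exponent is expressed per stride rather than per second and
faster walkers are not mechanically penalized. The series is
delay-embedded with $\tau = 11$ samples and five delayed copies per
channel — the study's total dimension 15 interpreted as $3 \times 5$, the
standard multichannel reading when only the total is printed — giving
$6300 - 4\cdot11 = 6256$ state vectors. Auto-selection is available:
$\tau$ from the first strict local minimum of a 16-equiprobable-bin
average mutual information, and the dimension from Kennel's
false-nearest-neighbour criterion (ratio threshold 15, attractor-size
threshold 2, 1% cutoff).

Rosenstein's estimator then tracks, for every state vector, its nearest
neighbour outside a Theiler window of one stride (100 samples), and
averages log distances after $k$ steps; the LLE is the least-squares
slope over steps 0–50 (half a stride), the short-term stability
convention in the gait literature. Numerical points:

* Pairs whose trajectories run off the end of the series drop out of the
  mean at that step (Rosenstein's convention).
* Exact recurrences (perfectly periodic input) receive a distance floor
  of $10^{-12}$ times the state spread so the divergence curve is defined
  and flat; a constant state matrix is an error.
* Neighbour search is blocked brute force (BLAS matrix products); at
  $n \approx 6\times10^3$ this is a desk-scale computation.

Two estimator facts surfaced by the validation battery are worth
recording. First, the histogram AMI of a *noise-free* periodic signal has
grid-resonance artifacts (the binned joint distribution of an exactly
commensurate sine is supported on few atoms), so the classical
quarter-period first minimum emerges only once realistic measurement
noise is present; the tests use a noisy sine for exactly this reason.
Second, on the Lorenz system the divergence curve shows a
neighbour-selection transient before settling into its scaling region, so
the Lorenz oracle fits steps 100–250 (1–2.5 time units), where the slope
agrees with the literature value of ≈ 0.9; the logistic map shows no such
transient and is fit from step 0.

## Triangle completion

Trials are scored at the turning vertex $C$: the angle error is the
wrapped difference between the produced turn (inbound heading
$B\!\to\!C$ to $C\!\to\!P$) and the correct turn (to $C\!\to\!A$); the
distance error is walked length $|CP|$ minus correct length $|CA|$
(negative = underestimated path). Absolute values of both are the
dependent variables, averaged over the four-trial protocol; the Euclidean
miss $|PA|$ is kept as an auxiliary metric. The two course triangles are
fixed at the top of the stated 150–300 cm segment range: an equilateral
triangle with 300 cm sides and a 30–60–90 triangle with a 300 cm
hypotenuse (the exact sizes are not printed anywhere, only the range and
the angle set; the choice is configurable via `scale`). Scoring is
invariant under rotation, translation, and mirror-with-direction-flip,
which the tests exercise directly.

## Statistics

The 2×2 mixed ANOVA (between: Group; within: Condition) is computed by
the exact split-plot collapse: per-participant condition *averages* carry
the Group effect, per-participant condition *differences* carry the
Condition and interaction effects. Both strata are linear models with
sum-to-zero contrasts, so the F tests are Type III (unweighted-means)
tests — this matters once missing-data removal unbalances the groups, and
it reproduces the classical `aov` split-plot table exactly in balanced
designs (tested against a hand sums-of-squares oracle).

* **Heteroscedasticity**: when Levene's test (classic mean-centred form;
  median centring available) rejects at 0.05 — or on request — the F
  statistics are recomputed as Wald tests with an HC3 sandwich
  covariance, the small-sample recommendation at n = 14 per group.
  The gate uses the between-stratum values, mirroring "corrected in case
  of variance heterogeneity between groups".
* **Effect sizes**: Cohen's *d* with pooled ($n-1$) sd between groups and
  difference-score sd within; 95% CIs by noncentral-$t$ inversion.
* **Contrasts**: estimated marginal means with Tukey adjustment via
  `emmeans`; for two-level factors the adjustment collapses to the raw
  test (asserted to $10^{-9}$).
* **Correlations**: per-group two-sided Pearson with $t_{n-2}$ p values
  and Fisher-z CIs, computed on participant means, as in the study's
  correlation design.

Degrees of freedom follow whatever rows are present — missing
participants (and their matched partners, removed pairwise by
`build_cohort`) shrink the df exactly as in the study's varying
$F(1, 21)$ / $F(1, 26)$ bookkeeping.

## The synthetic cohort generator

The generator is the package's ground-truth instrument, not a biomechanical
simulation. Per participant a latent weekly-exercise factor is drawn
lognormally (sdlog 0.6; median 240 min/week for BVI vs 400 for sighted,
mirroring the reported ≈160 min/week group difference) and mapped to each
outcome's mean via a loading per doubling of exercise — negative for sway
area, stride-time sd, LLE and both navigation errors, positive for
single-leg stance time — plus a per-group offset reproducing the reported
effect directions (BVI: more sway, shorter stance, slightly higher
gait/navigation means). Baselines are of the order of the study's
measures (sway ≈ 10 cm², stride time 1.1 s with 30 ms sd, errors of tens
of cm/degrees) but carry no claim of matching unprinted values. Raw
signals:

* **CoP**: a 2-D Ornstein–Uhlenbeck process with exact discretization;
  stationary per-axis sd $\sigma/\sqrt{2\theta}$, so the long-run PEA is
  $\pi \chi^2_{0.95,2} \sigma^2 / (2\theta)$ — a closed form the tests
  use directly.
* **Gait**: a 3-channel stride template, time-warped per stride with iid
  Gaussian stride times (truncated at 0.3 s) and additive white noise.
  The template's segmentation peak sits 5% into the stride so that
  peak-to-peak intervals track the drawn stride times (a peak mid-stride
  would average adjacent durations and attenuate the recovered sd by
  ~20%). Timing jitter is iid — sufficient for variability and stability
  contrasts; long-range-correlated jitter is a possible extension.
* **Triangles**: produced turn = correct + bias + noise; produced length
  = correct × gain × (1 + noise).

With all loadings at a fixed magnitude the implied population correlation
between raw exercise minutes and an outcome is capped at
$\sigma/\sqrt{e^{\sigma^2}-1} \approx 0.91$ (the outcome is linear in
*log* exercise); `implied_exercise_correlation()` gives the exact value
and is how the end-to-end tests plant a −0.8 correlation.

`gen_cohort` has two levels: `"dv"` draws outcomes directly from the
latent model (fast; used for the statistical calibrations), `"trace"`
generates raw signals and runs the measurement pipelines (slow; exercises
the whole chain on small cohorts). What passing tests show is that the
chain recovers known effects embedded in signals with these noise
structures — not that real pediatric force-plate or IMU data behave this
way; in particular the generator has no residual-vision heterogeneity, no
fatigue drift, and no non-stationary artifacts beyond the exclusion-mask
mechanism.

## Problem sizes in the validation battery

The battery uses 5400-sample sway traces (one 30 s trial), 5000-point
logistic-map and 15000-point Lorenz series, 63–200-stride gait traces, 20
seeds for recovery/ordering checks, 5000 simulated studies for the ANOVA
type-I calibration at n = 14 per group (500 each for Levene and the
Pearson CI coverage), and 200 null cohorts for the report-level false
positive fraction — sizes at which the Monte-Carlo bands in the tests are
comfortably wider than the binomial noise.

## Known limitations

* The stride detector is contract-equivalent to, not a reproduction of,
  the proprietary sensor-fusion segmentation used with the original IMU
  data; dead-reckoning quantities (gait velocity, stride length, foot
  clearance) are out of scope.
* Whether the study fixed $(\tau, d_E)$ globally or per participant is
  not stated; both are supported (`tau = 11` or `"auto"`).
* The LLE is reported per normalized-time unit (per stride). A real-time
  axis would scale it by the participant's stride rate.
* The ANOVA layer is specialized to the study's 2×2 mixed design;
  higher-order designs are not implemented (the contrast machinery via
  `emmeans` does generalize to more levels).
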