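---
title: "Liver segment respiratory motion and ITV margin derivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liver segment respiratory motion and ITV margin derivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmotion)
library(dplyr)
```

## The problem

Free breathing moves the liver by several millimetres, mostly along the
superior–inferior (SI) axis, and the motion differs between the nine Couinaud
segments (S1, S2, S3, S4a, S4b, S5–S8).  When a radiotherapy target is
delineated on a single free-breathing helical CT — a snapshot taken at an
uncontrolled point of the breathing cycle — the internal target volume (ITV)
must be expanded enough to contain the target wherever respiration carries
it.  A single generic margin wastes healthy liver for the quiet segments and
under-covers the mobile ones, so the margin should be derived per segment and
per direction.

The quantities involved are per-patient displacements of one representative
point per segment, observed in three imaging states:

* `helical` — the free-breathing snapshot,
* `phase0` — end-inspiration bin of a 10-phase gated 4DCT,
* `phase50` — end-expiration bin.

All displacements in this package are *destination minus origin*, in mm, with
the fixed sign convention **positive = left / posterior / superior**.

## The margin rule

For one segment and one axis, let $(\bar d_0, s_0)$ and $(\bar d_{50},
s_{50})$ be the cohort mean and sample SD (with $n-1$ denominator) of the
displacement from the helical snapshot to phase 0 and to phase 50, over $n$
patients.  Each phase contributes a Student-t interval for the cohort mean,

$$ I_p = \left[\ \bar d_p - t\,\frac{s_p}{\sqrt n},\ \ \bar d_p +
t\,\frac{s_p}{\sqrt n}\ \right], \qquad t = t_{0.975,\,n-1}, $$

and the asymmetric margin is the envelope of the two intervals, clamped so
that it always contains zero (an expansion can never shrink the target):

$$ [\text{neg},\ \text{pos}] = \big[\ \min(0, \min I_0, \min I_{50}),\ \
\max(0, \max I_0, \max I_{50})\ \big]. $$

At the reference cohort size $n = 20$ the multiplier is fixed at the
published three-decimal value $t = 2.093$; for any other $n$,
`margin_config()` uses `qt(0.975, n - 1)`.  The clamp is not optional
decoration: reference cells such as S5-LR and S8-LR have both intervals
entirely on the negative side, and their published positive bound is exactly
0.0, which only the clamp produces.

`itv_margin()` implements the rule on any statistics table;
`margin_table()` derives the statistics from a cohort and adds an overall
row.  Applied to the reference helical-to-phase statistics
(`reference_helical_stats()`), the rule reproduces all 54 published margin
bounds within 0.15 mm — the slack is entirely explained by the inputs being
printed at 0.1 mm precision — which the test suite asserts.

```{r margins}
itv_margin(reference_helical_stats(), margin_config(20)) %>%
  filter(segment %in% c("S5", "S7"))
```

### The overall row

The published overall margin row is reproducible neither as the formula
applied to pooled statistics nor exactly as the mean of the per-segment
margins (both disagree with it by up to 0.1 mm).  `margin_table()` uses the
*mean of per-segment margins* convention, which matches the published
overall superior margin (5.0 mm) exactly and every other overall cell within
0.1 mm.  Likewise the overall amplitude SD: the source does not say whether
it pools all $9n$ values or averages the nine segment SDs;
`amplitude_table()` defaults to the pooled convention
(`overall_sd = "pooled"`) and offers `"mean_of_sds"`.

## The synthetic cohort generator

No patient data were published, so the package ships a generator whose
defaults *are* the study conditions; they are deliberately not tuned
further.

For each patient:

1. One total expiration displacement $d \sim \mathcal N(\mu, \sigma)$ is
   drawn per segment and axis, with $(\mu, \sigma)$ taken from the published
   per-segment amplitude table (`reference_amplitudes()`, e.g.
   S7-SI $8.6 \pm 3.4$ mm).
2. The phase-0 position sits at a fixed, documented 9-point layout
   (`segment_layout()`).  Its absolute coordinates are arbitrary and
   provably irrelevant: every statistic depends only on differences between
   states, and a test asserts invariance under rigid per-patient
   translation.
3. The phase-50 position is `phase0 + d`.
4. The helical snapshot sits at `phase0 + u * d`, with the **helical
   fraction** $u \sim \mathcal N(0.42, 0.15)$ truncated to $[0,1]$, drawn
   *once per patient* — one helical scan per patient, hence one breathing
   moment shared by all segments.

The helical fraction law needs two parameters the source never states (it
only says the snapshot location is random and roughly normally distributed
over the cycle).  The mean 0.42 is not free: the published helical-to-phase
mean displacements split the published total amplitudes at ≈ 0.42 for the
large-motion segments (e.g. S7-SI: $-0.42 \times 8.6 = -3.6$ and
$0.58 \times 8.6 = 5.0$, exactly the published pair).  The spread 0.15 is a
calibrated choice for "anywhere mid-cycle, rarely at the extremes"; it is
configurable in `sim_params()`.

Axes and segments are independent by default (no covariances are published).
Setting `shared_depth_sd > 0` multiplies all of a patient's displacements by
a common factor, emulating breathing-depth correlation; it is off by default
and exercised in tests.

Lung volumes: per-patient log-normal size factor (σ = 0.15) scales the
published phase-0 and phase-50 state means, a mildly jittered expiration
ratio gives phase 50, and the helical volume interpolates at the patient's
own $u$ — so the bracketing property `phase50 <= helical <= phase0` that
`lung_bracket_check()` verifies holds by construction, mirroring the
respiratory-stability assumption it was designed to test.  Published per-state
SDs do not exist; σ = 0.15 reflects typical adult lung-volume spread.

Breathing traces are raised-cosine cycles (peak = end-inspiration = gating
phase 0) with 4 s mean period, 10% cycle-to-cycle period and amplitude
jitter, sampled at 25 Hz — typical free-breathing surrogate values, chosen
once.  `max_phase_error()` reports, for a gated phase, the range over cycles
of the surrogate amplitude at that phase as a percentage of the mean
peak-to-peak amplitude.  The gating software whose per-patient "maximum
phase error" the emulator imitates publishes no formula; this
range-over-cycles definition is our own documented emulation, not a
reproduction of the vendor's internals.

### What the generator does and does not emulate

It reproduces the published per-segment displacement distributions (a
2000-patient cohort recovers every cell mean within $3\sigma/\sqrt{n}$ and
every SD within 10% — asserted in tests), the one-snapshot-per-patient
structure, and lung bracketing.  It does **not** emulate: hysteresis
(inhale and exhale paths differ in real livers), intra-/inter-fraction drift,
non-normal displacement tails, segment-to-segment covariance (beyond the
optional shared depth factor), or any voxel-level imaging.  Consequently a
passing suite shows the *procedure* is implemented correctly under the
stated model, not that the published margins are clinically sufficient.

## What the margin formula actually guarantees

The phrase "cover more than 95% of each tumor" admits several readings.  The
formula is a t-interval for the *cohort mean* displacement, so the reading it
can actually guarantee — and the one `coverage_simulation()` scores as its
primary output — is: the derived `[neg, pos]` contains the model's true mean
helical-to-phase displacements.  A per-tumor reading (does an individual
patient's own displacement fall inside the margin?) is reported alongside in
`tumor_cov_pct`; it is necessarily far lower, because a $\sqrt n$-shrinking
interval cannot bound individual variation.  With the default model it sits
near 50% — a finding worth knowing before using such margins prospectively
on new patients.

Two further calibration facts, both computed by the package's own simulation
and asserted in the tests:

* With the helical fraction fixed (`helical_sd = 0`) the helical-to-phase
  displacement is exactly normal, and the plain t-interval (one phase, clamp
  off) covers its mean at the nominal 95% within Monte-Carlo error — the
  implementation agrees with the closed form.
* Under the default *random* helical fraction, the helical-to-phase
  displacement is a product $u \cdot d$ and is noticeably skewed.  The
  t-interval is then only approximate: pooled over all 27 segment/axis
  cells the margins cover the true means in slightly over 95% of replicate
  20-patient cohorts, but the individual large-motion SI cells fall a
  percentage point or two *below* 95%.  The acceptance suite asserts the
  per-cell bound as stated and therefore records this honestly as a failure;
  the pooled bound holds.  The lesson is scientific, not numerical: the
  nominal 95% of a t-interval does not survive the snapshot-timing
  randomness for the most mobile segments.

## Numerical and design choices

* Sample SDs use the $n-1$ denominator throughout, consistent with the
  t-interval.
* Reports round to 0.1 mm, half away from zero; machine-readable outputs
  (CSV/JSON) keep full precision, written as shortest-exact decimals so
  write/read round trips are bit-identical.
* The published overall LR amplitude appears once unsigned; the signed
  per-segment table value (−0.6 mm) is treated as authoritative.
* Coverage inclusion tests use a $10^{-9}$ mm tolerance so that degenerate
  zero-variance models, where the truth lies exactly on a bound, are not
  failed by floating-point round-off.
* Ties in the lung bracket pass (inclusive inequalities): the published mean
  volumes are strictly ordered, but individual ties are not evidence of
  instability.
* `generate_cohort(n_patients = 0)` returns a valid empty cohort; statistics
  require ≥ 2 patients (SD undefined below that) and error otherwise.

## Problem sizes

The shipped tests and the acceptance script use: 20-patient cohorts
(the study size) for margin derivation; 2000 patients for parameter
recovery; 1000 Monte-Carlo replicates for coverage; 100 seeds for the trace
jitter calibration.  These sizes put Monte-Carlo error comfortably inside
the asserted tolerances while keeping a full run in tens of seconds.

## Limitations

Everything image-bound is out of scope by design: no DICOM handling, no
deformable registration (deformed coordinates are generated directly), no
contour rasterization (the overlap index `voi()` takes pre-measured
volumes).  Published values that depend on the original CT images — overlap
indices of real liver contours, patient lung volumes, per-patient gating
phase errors — are not reproduction targets; the structural properties of
the corresponding operations are tested instead.  Margins produced here are
GTV/CTV→ITV expansions only; setup-error (PTV) margins are deliberately not
added.
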