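---
title: "Velocity-dependent gait signatures: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-dependent gait signatures: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsig)
```

## The analysis in one paragraph

Every spatiotemporal gait parameter of a walking mouse is a function of how
fast that particular stride was: stride length rises and saturates with
velocity, stance duration falls steeply, swing duration drifts down gently,
cadence rises. A group contrast that averages over strides therefore mixes
changes in *velocity* with changes in *gait quality*. `gaitsig` keeps the
stride-to-stride data unaveraged, models each parameter as a curve of stride
velocity over a restricted walking range, and asks whether a second dataset
(post-lesion, different sex, different cohort, ...) can share the baseline
curve. The decision statistic is the extra sum-of-squares F-test; rejecting
the shared curve is what we call a gait-signature shift.

## Stride derivation and its conventions

A stride is delimited by consecutive swing onsets of the same paw. Given
marked footfall events (swing onset, swing offset, touchdown position),
`strides_from_footfalls()` computes, for each consecutive event pair:

* swing duration = offset − onset of the leading event;
* stride duration = next onset − current onset;
* stance duration = next onset − current offset;
* stride length = distance between consecutive touchdown positions,

so that stride = swing + stance holds *exactly* by construction, and
velocity (cm/s), cadence (strides/s) and swing speed (mm/s) follow
arithmetically. Cadence is reported per second for internal consistency
(1/stride duration); multiply by 120 for human steps/min (two steps per
stride, as `human_trial_params()` does). When events come from video, times
are frame-quantised; the identity tolerance is then one frame period
(8.3 ms at 120 frames/s), which is also the accuracy bound the round-trip
tests enforce.

Trial-level filters mirror runway practice: trials with fewer than 3
strides are dropped, touch-cued strides are excluded (tactile prompting
produces erratic traversals), olfactory-cued strides are kept but counted,
and at most 4 trials per subject are analysed. Left/right hindlimb records
are pooled only by the caller, never silently.

## Model families and the walking range

Three candidate families, in increasing complexity:

| family | formula | parameters |
|---|---|---|
| linear | β₀ + β₁v | 2 |
| one-phase | Y0 + (Plateau − Y0)(1 − e^(−Kv)) | 3 |
| two-phase | Y0 + SpanFast(1 − e^(−KFast·v)) + SpanSlow(1 − e^(−KSlow·v)) | 5 |

These are the standard parameterizations of the saturating-exponential
families used by common curve-fitting software, stated here explicitly so
estimates are comparable across tools. Decreasing curves (stance duration)
simply have Plateau < Y0; rate constants are bounded in (10⁻⁶, 100) per
cm/s. Stance duration may also be fitted on the natural-log scale
(`transform = "log"`), which straightens its steep low-velocity rise.

The default walking range is the closed interval **[3, 16] cm/s**: the
slowest strides (accelerating, stopping, sniffing) and the fastest
(trotting) are omitted because models fitted there do not generalise across
baseline cohorts. The boundary values are included — an explicit choice, as
"omit 0–3 and >16" is ambiguous at the boundaries. `scan_velocity_ranges()`
re-runs model selection over a grid of lower (0, 1, 2, ...) and upper
(25, 24, ...) bounds and reports, rather than decides; range choice is a
scientific judgement, and the default encodes it.

## Fitting: initialization, convergence, tie-breaks

Linear fits are closed-form least squares. Exponential families are fitted
by bounded Levenberg–Marquardt from multiple starts. The rate constants are
started on a log-spaced grid of 10 values in [0.05, 2] per cm/s — the range
of curvature scales visible on a 3–16 cm/s window; for each rate-constant
start, the remaining parameters (Y0 and plateau/spans) enter the model
linearly and are started at their *exact conditional least-squares* values
(a variable-projection-style initialization). We chose this over the
simpler "Y0 = min response, Plateau = max response" start because min/max
points the wrong way for decreasing curves such as stance duration, while
the conditional solve is exact and costs one small QR factorisation per
start. Convergence tolerance is 10⁻¹⁰ on the relative SS change; equal-SS
starts break toward the lowest rate constant (the least curved, most
conservative solution). Two-phase solutions are re-ordered so KFast ≥ KSlow.
A fit that converges from no start is flagged and refused by every
downstream test.

Degrees of freedom are n − p with n counted after range restriction.
Standard errors come from the Gauss–Newton covariance s²(JᵀJ)⁻¹ with a
central-difference Jacobian; confidence bands on predictions are Wald bands
from the same covariance and are documented as approximate.

## Model selection (quasi-nested F chain)

`select_gait_model()` walks linear (2 df) → one-phase (3) → two-phase (5)
with the extra sum-of-squares statistic

F = ((SS₁ − SS₂)/(DF₁ − DF₂)) / (SS₂/DF₂),

preferring the more complex family only at p ≤ 0.05. The linear family is
not a strict submodel of the one-phase family; the chain treats them as
quasi-nested through their df difference, which is standard curve-fitting
practice and is flagged here because it means F can be negative — it is then
clipped to 0 and p reported as 1 (the simpler model wins). Preferring the
simplest adequate model guards against declaring "significant" differences
that have no physiological content.

## The shared-curve test

`compare_gait_curves()` fits the chosen family three times — dataset A,
dataset B, pooled — and computes

F = ((SS_combined − (SS_A + SS_B)) / (DF_combined − (DF_A + DF_B))) /
((SS_A + SS_B) / (DF_A + DF_B)),

with numerator df equal to the family's parameter count. `p < α` (default
0.05) means separate curves; the per-parameter A−B differences are then
summarised with approximate Wald 95% intervals, and for the linear family
`classify_shift()` labels the result intercept-shift / slope-shift / both.
Design points worth knowing:

* **The same family is imposed on A, B and pooled.** Choose it on baseline
  data with `select_gait_model()` and reuse it post-intervention. This
  matters: if the true relation is curved and both groups occupy different
  velocity ranges (exactly the situation the method exists for), comparing
  misspecified straight lines rejects spuriously. The package's own
  acceptance checks show this: a velocity-only split of one-phase data
  shares a curve in ~95% of replicates under the one-phase family but only
  ~50% under a linear family.
* Perfect separate fits (SS_A + SS_B numerically zero) make the statistic
  degenerate; the result is F = ∞, p = 0 with a `degenerate` flag rather
  than an error, because toy datasets hit this case.
* `compare_gait_groups()` runs all pairwise comparisons without family-wise
  adjustment by default — each shared-curve decision is reported on its own;
  α = 0.001 is available as a conservative option.
* Human walkway data are derived (`human_trial_params()`) and plotted, not
  formally compared; trial averages lack the stride-to-stride structure the
  F-test consumes.

## Residual diagnostics

The Wald–Wolfowitz runs test on residual signs ordered by velocity detects
systematic lack of fit (clustered runs). We use the two-sided exact
conditional test (exact run-count distribution up to n = 200, normal
approximation beyond). When one sign is entirely absent the conditional
distribution is degenerate, and a flagged unconditional fallback
p = 2^(1−n) is reported instead. Normality of residuals is screened with
the D'Agostino–Pearson omnibus K² (transformed skewness + transformed
kurtosis against χ²₂), implemented in-package and verified against an
independent implementation on frozen fixtures; it requires n ≥ 8 and is
refused (flagged, not silent) below that. Gait residuals often fail strict
normality because the velocity axis is unbalanced, not because of outliers;
the diagnostics are attached to every fit so users can judge.

## Conventional contrasts and power

The speed-independent analyses are provided for comparison with the
curve-based approach: a D'Agostino–Pearson screen at p < 0.05 routes each
two-group contrast to a t-test or a Mann–Whitney/Wilcoxon rank test, and
each ≥3-group contrast to ANOVA + Holm–Šidák or Kruskal–Wallis + Dunn
(Šidák-corrected rank-sum z), at a family-wise 0.05. Routing is always
reported. Note the composition effect: both samples must pass a 5%-level
screen, so even for perfectly Gaussian data the t-path is taken in only
about 0.95² ≈ 90% of samples, slightly less in practice because the omnibus
test is anticonservative at n ≈ 30.

`paired_t_sample_size()` computes exact noncentral-t power
(ncp = d·√n, df = n − 1) and iterates n upward. Published pre/post
summaries rarely state the effect-size convention, so it is a parameter:
`"pooled"` (mean change over the RMS of the two SDs, the default), `"pre"`,
or `"post"`. The choice moves the answer by ±1 subject in typical cases —
which is precisely why it is exposed rather than guessed.

## The synthetic generator: what it emulates, what it does not

`simulate_gait_cohort()` reproduces the statistical structure the analyses
assume: stride velocities from a normal with mean 9 cm/s and SD 6 cm/s —
typical walking speeds for laboratory mice — truncated to [3, 16] cm/s by
inverse-CDF sampling; stride length from a one-phase generating curve
(Y0 = 30 mm, Plateau = 80 mm, K = 0.15 per cm/s, Gaussian noise SD 3 mm);
swing duration from a shallow negative linear trend (140 ms − 2.5 ms per
cm/s, noise SD 8 ms); and stride duration, stance, cadence and swing speed
derived so every stride identity holds exactly — which automatically
produces the characteristic decreasing stance and increasing cadence
curves. These generating values are *plausible synthetic defaults shaped
like published mouse runway figures*, not estimates from any recorded
cohort. Noise is additive, Gaussian and homoscedastic because no better
noise model is established; swing draws are clamped to [1 ms, 0.9×stride]
so stance stays positive in the extreme tails (never triggered at zero
noise, <1% of records at default noise).

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: per-animal clustering (every stride is
independent given velocity; real mice contribute correlated strides),
heteroscedastic or velocity-dependent noise, cueing structure, interlimb
coordination, and pathological gait styles (circling, freezing). The
shared-curve test's type-I error verified here (≈5% over 500 synthetic
replicate pairs) is therefore a statement about independent strides; with
strong per-animal clustering the effective sample size shrinks and a
mixed-model extension would be required — deliberately out of scope.

Two constructions mirror the conceptual figures: `split_by_velocity()`
(random quarter fast, random quarter slow, ranked remainder — velocity
changes, quality does not) and `add_parameter_offset()` (+5 mm stride
length on half the data — quality changes). By default the offset holds
velocity fixed and re-derives the durations, because the construction
plots shifted lengths against the *original* velocities;
`hold_velocity = FALSE` instead keeps the temporal record and lets velocity
absorb the change. `apply_signature_shift()` generalises this to
record-wise affine shifts y → Δ + s·y with presets: `"mptp"` (stride-length
intercept −8 mm; cadence rises through the identities) and `"6ohda"`
(stride-length slope ×0.8 with the intercept preserved via an OLS intercept
estimate from the table being shifted). Shifts act on observed values
rather than re-simulating from the generating curve so they apply to any
stride table, including real data read from CSV.

## Numerical and degenerate-input policy

* Range restriction is a closed interval; empty results warn, never error.
* Fit preconditions (≥ p + 5 points in range, velocity span ≥ 5 cm/s) are
  rejected by name.
* One event per paw yields zero strides (not an error); unordered or
  overlapping swing phases are rejected with the offending event
  identified.
* Zero-variance paired differences refuse the test rather than fabricate
  p = 1 from a 0/0.
* CSV readers validate the stride identities on input and name offending
  rows; all columns carry units in their names (mm, s, cm/s) so unit
  confusion fails loudly.

## Problem sizes used in the verification suite

The packaged tests and the acceptance script use cohorts of 240 strides
(6 subjects × 4 trials × 10 strides) for the hypothetical-construction
rates (200 replicates), 200-stride groups for the 500-replicate type-I
study, n = 400 for parameter recovery, and 200 replicates for the
linear-preference rate — sizes chosen to estimate each rate to within a few
percentage points while keeping the whole suite runnable in about a minute
on a laptop core.

## Known limitations

* No mixed-effects layer: strides from one animal are treated as
  independent. Within-cohort, own-control designs limit the damage, but
  cross-cohort inference is explicitly not supported.
* Wald intervals on nonlinear parameter differences are approximate and can
  misbehave near the K bounds.
* The two-phase family is weakly identifiable on the default walking range
  (both phases must be visible in the data span for stable estimates); the
  selection chain's preference for simpler families usually protects users
  from it.
* "Leftward shift" narratives for stance curves are expressed through
  parameter differences; no bespoke horizontal-shift statistic is provided.
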