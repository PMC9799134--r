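---
title: "Workspace redundancy, movement variability, and single-trial adaptation: the reachprime model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Workspace redundancy, movement variability, and single-trial adaptation: the reachprime model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachprime)
```

## The scientific question

When a reach target is an arc centered on the hand's start position, *where
along the arc* the movement ends does not matter — movement direction is
task-redundant, while movement extent must be precise. A radially oriented
line target inverts this: extent is redundant, direction is constrained.
`reachprime` models a two-session paradigm that uses this geometry to ask
whether letting variability accumulate along one spatial dimension
("priming") speeds up subsequent error-based adaptation along that same
dimension.

Each session starts with a priming phase (7 blocks x 60 reaches to arc or
line targets at three locations: straight ahead and 30 degrees clockwise /
counterclockwise, 15 cm from home). A test phase follows with 90 mini-blocks
of 3-5 reaches to a small dot; endpoint feedback appears only on the
penultimate ("perturbed") trial of each mini-block and is either veridical or
perturbed — rotated by ±8.53 or ±5.71 degrees about home with radius intact,
or radially scaled by a gain of 1±0.15 or 1±0.10 with direction intact. These
magnitudes displace the cursor by 2.25 or 1.50 cm at the 15 cm target
distance, putting rotations and gains on a common cm scale (via `15 tan θ`
for rotations, which reproduces the printed 2.25/1.50 cm exactly, whereas an
arc-length conversion would not). The change in behavior from the perturbed
trial to the last ("test") trial, regressed on the signed perturbation,
measures the single-trial learning rate.

## The generative agent

Endpoints are decomposed into **direction** (degrees about home, relative to
the target bearing, clockwise positive) and **extent** (cm). Per dimension
`d` the agent holds an aim point `a_d` and produces, on trial `t`,

```
endpoint_d(t) = a_d(t) + plan_d(t) + exec_d(t)
a_d(t+1)      = (1 - lambda_d) * (a_d(t) + plan_d(t))
```

with planning noise `plan ~ N(0, sigma_plan_d)` and execution noise
`exec ~ N(0, sigma_exec_d)`. The aim *absorbs* planning noise — the next
movement is planned from where the previous plan landed — and is pulled back
toward the target by the gain `lambda_d`. A small `lambda` therefore turns
planning noise into a lag-1-autocorrelated random walk of endpoints, the
signature of exploration along a redundant dimension; `lambda = 1` resets the
aim every trial and endpoints become independent. During priming the
redundant dimension (direction under arc priming, extent under line priming)
gets `lambda_redundant` (default 0.2) and the constrained dimension
`lambda_constrained` (default 0.9).

On a perturbed trial with feedback error `e_d` (the rotation angle in
degrees, or the gain delta times the reach radius in cm) the next-trial aim
shifts by `-B_d * e_d`, with

```
B_d = b0_d + kappa * [d was redundant during this session's priming]
```

`kappa` is the hypothesized priming effect made explicit as a simulator knob:
`kappa = 0` switches it off, so recovery of the effect by the analysis chain
can be tested against ground truth in both directions.

### Default parameters and where they come from

The defaults of `agent_params()` were fixed once by inverting the stationary
variance of the aim recursion,
`Var(endpoint) = sigma_plan^2 / (1 - (1 - lambda)^2) + sigma_exec^2`,
against the condition means the paradigm reports (direction IQR 4.65 vs 3.08
degrees under arc vs line priming; extent IQR 1.98 vs 1.20 cm under line vs
arc priming, with IQR = 1.349 sigma for a Gaussian):

| parameter | default | units | role |
|---|---|---|---|
| `sigma_plan_dir` / `sigma_exec_dir` | 1.95 / 1.17 | deg | direction noise |
| `sigma_plan_ext` / `sigma_exec_ext` | 0.88 / 0.12 | cm | extent noise |
| `lambda_redundant` / `lambda_constrained` | 0.2 / 0.9 | — | aim correction |
| `b0_dir`, `b0_ext` | 0.15 | — | baseline learning rate |
| `kappa` | 0.15 | — | priming-dependent increment |
| `p_slow`, `p_curved`, `p_outlier` | 0.013, 0.001, 0.001 | — | artifact rates |
| `rt_mean_ms`, `rt_test_drop_ms`, `rt_sd_ms` | 484, 23, 60 | ms | response times |

`kappa = 0.15` doubles the redundant dimension's learning rate — a strong
but plausible rendering of the hypothesized effect; artifact rates sit at
the scale of the paradigm's reported exclusion percentages; the response-time
model centers on its reported perturbed/test means. Between-subject
heterogeneity enters as multiplicative lognormal jitter (CV 0.2 by default)
on the noise SDs and baseline learning rates.

Movement durations are generated by drawing a clean mean speed uniformly at
24-36 cm/s and deriving duration = extent/speed, so clean trials always clear
the 20 cm/s slow threshold; slow artifacts draw 10-15 cm/s instead. (A
duration-first model was rejected: with extent noise, long-duration draws on
short reaches would cross the threshold and blur the distinction between
artifact and clean trial that the exclusion tests rely on.)

### What the simulator does not emulate

No within-movement feedback control, biomechanics, or target-onset timing
structure; trajectories are minimum-jerk paths with small positional jitter
and a stationary tail, so path curvature in clean trials is essentially
zero rather than the mildly curved paths of real reaches; priming-phase
one-dimensional feedback influences the agent only through the `lambda`
gains, not through an explicit learning response. Passing tests therefore
certify the analysis chain and its statistical behavior under a controlled
generative model — not that real reach data satisfy the model.

## The analysis chain

**Kinematics.** Movement onset is the first sample beyond 0.5 cm of home;
offset is the first sample followed by at least 33.3 ms with no coordinate
change — at 200 Hz that is 7 consecutive inter-sample steps below 0.01 cm, a
tolerance chosen at the tablet's quantization scale since none is stated in
cm. Speed for the peak-velocity readout is the magnitude of an order-2,
31-sample (155 ms) Savitzky-Golay first derivative, evaluated only where the
full window fits; on quadratic signals this filter is exact, which the tests
use as its oracle. Direction at peak velocity uses the *position* bearing at
the peak sample (consistent with the endpoint definition); the velocity-vector
bearing is available as an option since the definition is ambiguous.

**Exclusion.** Three independent flags: mean speed below 20 cm/s (strict);
maximum deviation from the straight home-endpoint segment above 2 cm;
endpoints farther than 8 times the IQR of Euclidean distances from the
componentwise-median endpoint, per subject x session x phase x target cell
(cells under 4 trials skip the rule). Flags are computed on the full input,
not sequentially, and exclusion is equivalent to masking. Note that on
autocorrelated aim walks the 8 x IQR rule occasionally flags a legitimate
extreme even with artifact generation off — as it does on real data.

**Explored variability.** IQR (linear-interpolation quantiles) per target
location, averaged unweighted across the three locations to cancel
target-specific biases, then expressed as a percentage of the redundant
span: 30.56 degrees (the 8 cm arc's central angle, `deg(8/15)`; the printed
two-decimal value is used so percentages match the reported tables) for
direction, 8 cm for extent. Test-phase variability drops each mini-block's
final trial, which reflects the correction to the preceding feedback. The
priming x dimension interaction is tested in a 2x2 within-subject ANOVA
(partial eta squared from the effect vs effect-by-subject decomposition),
with Bonferroni-corrected paired follow-ups.

**Single-trial adaptation.** One observation per perturbed mini-block whose
perturbed and test trials both survive exclusion: the response is the
test-minus-perturbed change in the perturbed dimension only (direction for
rotations, extent for gains; the orthogonal dimension is ignored to avoid
interference). The combined per-subject model regresses the within-subject
z-scored response — pooled across both dimensions, as the design specifies —
on the signed perturbation (cm), priming (arc = 1), dimension (direction =
1), all two-way interactions, and the three-way interaction, whose
coefficient is tested against zero across subjects. Under this coding the
hypothesized priming effect makes the three-way coefficient *negative*
(learning shifts responses opposite in sign to the perturbation, and priming
deepens that slope along the redundant dimension). Dimension-wise follow-up
models keep native units (direction in deg/cm — with both rotation
magnitudes pooled, the exact noiseless slope is `-B * sum(theta x)/sum(x^2)`
with `x = 15 tan theta`, which the tests assert). Veridical mini-blocks are
excluded by default (their dimension is undefined) and can be included as
zero-perturbation observations in both dimensions.

**Gating.** Subjects are optionally filtered by combined-model `R^2`
(thresholds 0.05-0.2, yielding nested subsets) and by adaptation evidence: a
subject is a non-adapter when BIC *or* AIC favors an intercept-only model
over a perturbation-only model — the disjunctive reading of the paradigm's
"ΔBIC and/or ΔAIC" exclusion phrasing, implemented verbatim.

**Correlations and response times.** At the left target (-30 degrees, the
location with the largest initial variability in the paradigm), each
subject's priming-related gain in redundant-dimension learning rate is
correlated with the priming-related change in explored variability
(Bonferroni family 2). Response-time tests are a paired t on per-subject
mean RTs (perturbed vs test trial) and Fisher-z one-sample t tests of
within-subject correlations between the RT change and the correction
magnitude; an all-constant RT difference is reported as t = 0, p = 1 (its
defined limit) rather than an error.

## Numerical and design choices

- Coordinate frame: home at origin, straight ahead = +y, angles in degrees
  clockwise-positive, all angular differences wrapped to (-180, 180].
  Angular IQRs are computed on linear angles — spreads are far below 360
  degrees, so circular statistics would add nothing.
- Test schedule: 9 cycles of 10 mini-blocks, each cycle holding all eight
  perturbations once plus two veridical mini-blocks, shuffled within cycle;
  lengths and locations are assigned by exact marginal balance (each
  perturbation x length and perturbation x location combination exactly 3
  times, veridical 6). Construction is direct, so no rejection sampling is
  needed. Breaks fall after mini-blocks 30 and 60. A subject's two sessions
  share one test schedule.
- Priming feedback trials: exactly 15 per 60-trial block (25% per block,
  hence 25% overall); the per-block balance is a design choice where only
  the overall fraction is stated.
- Degenerate inputs: zero-variance paired differences raise an error from
  the generic tests (the t statistic is undefined); a zero effect
  sum-of-squares in the ANOVA reports F = 0, p = 1.

## Problem sizes used by the test suite

The suite simulates cohorts of 33 subjects (test phase only) for the
parameter-recovery study — 200 replicate cohorts with `kappa = 0.15` for
power in the hypothesized direction and 500 with `kappa = 0` for the type-I
rate — plus smaller full two-phase cohorts (4-12 subjects) for end-to-end
checks, ~10,000 trials for artifact-rate recovery, and 1,200-1,500
replicate walks for the random-walk variance law. A 50-cohort pilot during
development put the power of the recovery design at ~1 for n = 33 before the
suite was frozen.

## A worked example

```{r example, eval = FALSE}
library(reachprime)

cfg <- run_config(n_subjects = 33, seed = 1)
res <- run_full_analysis(cfg)
res$study_table
```

The condensed `study_table` holds one row per statistical readout (ANOVA
interactions, planned comparisons, three-way tests at every scope,
correlations, response-time tests) with statistic, dfs, raw and corrected
p values, and effect size, computed on the simulated cohort.

## Known limitations

- The combined model's pooled z-scoring mixes degrees and centimeters; it
  standardizes the pooled response but does not equate the two dimensions'
  scales. The dimension-wise models avoid the issue and the combined model's
  inference is invariant to affine response changes, but coefficient
  magnitudes across dimensions should not be over-interpreted.
- Group inference is a summary-statistics approach (per-subject OLS, then
  t tests); no mixed-effects alternative is provided.
- The aim-correction gains `lambda` are per-session constants: the agent
  keeps its priming-phase gains through the test phase, so simulated
  test-phase variability does not attenuate the way real dot-target data
  (where both dimensions become task-relevant) would. The priming x
  dimension interaction survives either way; only its test-phase magnitude
  is overstated relative to a paradigm with re-tightened control.
- The simulator's aim dynamics are linear-Gaussian; heavy-tailed or
  use-dependent effects are out of scope.
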