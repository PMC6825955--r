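---
title: "Modelling and analysing adaptation to acute monaural plugging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing adaptation to acute monaural plugging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plugadapt)
```

## The scientific problem

Azimuth localization normally rests on binaural difference cues; elevation
localization on the spectral filtering of the pinnae. Plugging one ear
corrupts the binaural cues, leaving a mixture of an ambiguous head-shadow
level cue at the free ear, residual distorted binaural differences, and the
monaural spectral cues. With visual feedback, listeners re-weight these cues
within a few hundred trials. `plugadapt` packages (i) a Bayesian generative
listener that produces realistic stimulus–response trial tables for this
paradigm, (ii) the regression machinery that quantifies cue weights and
localization performance, (iii) windowed analyses of learning dynamics, and
(iv) a deterministic simulate–fit–report pipeline.

Because no per-trial human data are publicly deposited for this paradigm,
the synthetic listener is a first-class component: every analysis in the
package is exercised and validated against data simulated from a known
generative process.

## Coordinates and trial tables

All directions are double-polar: azimuth is the angle from the midsagittal
plane (positive rightward — the plugged side in the canonical setup),
elevation the angle from the horizontal plane (positive upward), both in
degrees, with |α| + |ε| ≤ 90° for physical speaker directions (the diamond
boundary of the frontal hemifield). The boundary check rounds at 1e-9
before comparing so that directions on the 90° rim never fail from float
jitter. Targets are constrained to the diamond; head-pointing *responses*
are deliberately not, since nothing physically prevents a response outside
it. Missing reaction times are stored as empty fields, never as 0.

## The Bayesian listener

Each spatial channel combines a Gaussian sensory likelihood N(μ_S, σ_S²)
with a Gaussian spatial prior N(μ_P, σ_P²). Writing the shrinkage gain
k = σ_P²/(σ_P² + σ_S²), both decision rules respond on average at the
posterior mean k·μ_S + (1 − k)·μ_P. Under the MAP rule the only response
variability comes from the trial-to-trial jitter of the sensory estimate,
giving variance k²σ_S²; under posterior sampling the response is a draw
from the posterior itself, with variance kσ_S² — larger by exactly
1 + σ_S²/σ_P². An infinite prior SD encodes the uniform (flat-prior)
limit, under which the response follows the likelihood. A sensory SD of
exactly zero is accepted by the simulator as the noiseless veridical limit
(used by the ideal-localizer tests), while the closed-form
`posterior_response()` requires strictly positive likelihood widths.

### Azimuth channel

The sensory azimuth estimate is centred on the target under binaural
hearing. Under plugged hearing it is pulled toward the free ear by the
perceived interaural level difference:

μ_S = T_α + α₀ + λ·(I_prox − I_ref),

with α₀ = `perceived_ild_bias_deg` (default −10°), λ =
`ild_level_slope_deg_per_db` (default −1.5 °/dB) and I_ref = 60 dBA. The
level dependence is the mechanism behind the negative standardized level
weight *p*: louder sounds produce a larger perceived interaural imbalance
and hence more leftward responses. The functional form of α₀ as a function
of the plug-induced level imbalance is not constrained by available
measurements, so it is exposed as these two free parameters rather than
hard-coded.

Sensory widths are per stimulus type (`BB`, `LP`, `HP`). Under plugging the
defaults are 30° for BB/HP and 12° for LP, reflecting that low-frequency
timing cues pass the plug largely unobstructed, so low-pass sounds retain a
usable binaural azimuth cue (and consequently a higher response gain) while
broadband/high-pass sounds do not.

### Elevation channel

The spectral elevation cue is read out with a reliability that depends on
which ear dominates: under plugged hearing the sensory SD interpolates
logistically in target azimuth between
`elevation_sensory_sd_hearing_deg` (default 5°) far on the free side and
`elevation_sensory_sd_plugged_deg` (default 50°) far on the plugged side,
with midpoint 0° and slope `binaural_weight_slope` (default 0.05 per
degree, i.e. most of the transition happens within ±40°). The logistic is a
modelling choice: the binaural weighting of the two ears' spectral cues by
perceived azimuth is well supported qualitatively, but no parametric form
is established, and a logistic is the simplest smooth, bounded, monotone
interpolant. Under binaural hearing the width is constant at the free-side
value.

### Condition presets

| condition | azimuth prior | elevation prior | azimuth σ_S (HP) |
|---|---|---|---|
| `binaural` | (0°, 180°) ≈ uniform | (3°, 12°) | 4° |
| `plugged_pre` | (−40°, 15°) | (3°, 12°) | 30° |
| `plugged_training` | (−40°, 15°) → schedule | (3°, 12°) → schedule | 30° → schedule |
| `plugged_post` | (−10°, 60°) | (0°, 5°) | 15° |

The binaural azimuth prior is effectively uniform (estimation is
likelihood-dominated); the 12° elevation prior width sits inside the
plausible 10–15° band for normal listeners and, with a 5° sensory width,
yields the familiar binaural elevation gain of ~0.85 and a small upward
bias. The plugged-pre azimuth prior (−40°, 15°) produces the strong
leftward capture and low gain characteristic of acute plugging. The
post-training elevation prior (0°, 5°) encodes the trained belief that
targets sit on the horizon, which is what drags elevation gain down on
*both* sides after training. These presets are modelling choices calibrated
to the qualitative phenomenology, not fitted constants; every field is
overridable.

### Training schedule

Feedback training relaxes parameters exponentially,
θ(t) = θ_end + (θ_start − θ_end)·e^{−(t−1)/τ}: the azimuth prior recentres
and widens (−40°, 15°) → (−10°, 60°), the elevation prior narrows onto the
horizon (3°, 12°) → (0°, 5°), and the azimuth sensory SD shrinks 30° → 15°
as the head-shadow and remapped residual binaural cues become informative.
The default time constant is τ = 150 trials: learning is then ~95% complete
after ~450 of the 500 training trials, i.e. improvement spans the whole
session rather than saturating halfway through, matching the gradual
learning curves reported for this paradigm. Note that the response gain
saturates somewhat earlier than the parameters themselves, because the
shrinkage gain k is a saturating function of σ_P.

### Reaction times

Reaction time is simulated as (150 ms + 5 ms/deg · σ_S) multiplied by
lognormal noise (σ_log = 0.1): the listener is faster when the sensory
evidence is more reliable. We deliberately tie RT to the *sensory*
precision rather than the posterior precision: during training the prior
widens, so posterior precision falls even as the listener's
stimulus-driven confidence — and empirically, response speed — grows. The
RT channel exists so the dynamics analyses have a realistic RT series; it
is not a claim about mechanism.

### Randomness

Each session takes a single integer seed. The stimulus menu is drawn in a
seed-0 substream; each trial's noise is drawn in a substream derived
deterministically from (seed, trial index), so reordering or truncating a
design never silently reshuffles the noise of unrelated trials. The same
seed always reproduces a byte-identical trial table.

## Session designs

* `training` — 500 trials of HP at 60 dBA from ten fixed azimuths
  (±12°…±60°) on the horizon, 50 repeats each, pseudo-random order.
* `pre_test` / `post_test` — 180 trials of HP at 50/60/70 dBA (60 each),
  targets uniform over azimuth [−60, 60]° and elevation [−40, 50]° inside
  the diamond, excluding the ten trained locations.
* `control_binaural` / `control_plugged` — 300 trials: HP at six levels
  (45–70 dBA, 5-dB steps; 30 each) plus BB and LP at 50 and 65 dBA (30
  each), azimuth [−80, 80]°, elevation [−40, 50]°.

## The regression suite

z-scoring uses the sample SD (denominator n − 1), which makes `[1, 2, 3]`
standardize exactly to `[-1, 0, 1]`. The standardized regressions are fit
without an intercept: z-scored variables are centred, so an intercept is
identically zero and would only dilute the degrees of freedom. The r²
reported for cue fits is that of the multiple regression on standardized
variables. MAE is computed on raw response − target differences; residual
SD on the residuals around the fitted line — the two measure different
things (inaccuracy vs. imprecision) and are kept distinct.

Two policy decisions matter in practice:

* **Collinearity.** With a single sound level, I_prox is a deterministic
  monotone function of T_α and the weights p, q are unidentifiable; such
  designs are refused with an explicit error rather than silently fitted.
  Near-collinear designs (condition number of the standardized design
  > 10³) fit but carry a warning in the result.
* **Hemifield boundary.** For hemifield-split elevation fits, targets at
  azimuth exactly 0° belong to neither hemifield; they are excluded from
  both subsets.

## Dynamics analyses

The training-dynamics analysis slides a fully contained 50-trial window in
5-trial steps (500 trials → 91 windows; edge windows are never padded,
since partial windows would mix unequal variances into the series) and
refits the azimuth regression per window. The local elevation gain uses
20°-wide azimuth bins shifted in 5° steps with centers −80°…+60° (29
bins), half-open [c − 10, c + 10) so that each target falls in a
deterministic set of bins; membership uses *target* azimuth. Bins with
fewer than 5 trials, or without elevation variation, are reported missing
(`NA`) rather than fit on a handful of points. Across-listener averaging is
a plain mean ± SD per center, dropping sessions that are missing that
center.

## The pipeline

`run_experiment()` simulates a cohort (default 8 listeners, each with mild
idiosyncratic jitter: azimuth-prior mean ± 5° SD, sensory widths scattered
lognormally with σ_log = 0.15), runs pre-test, training and post-test,
fits everything, and writes deterministic artifacts. "Improvement" per
parameter follows the conventional directions — gain and r² up, |bias| and
MAE down — and is summarized by exact one-sided binomial sign tests, per
parameter (8 listeners × 3 levels = 24 pairs) and pooled (96 pairs). The
pooled test treats the four parameters of one fit as independent, which
they are not; the pooled count is reported mechanically and should be read
with that caveat.

## What the synthetic data do and do not show

The generator reproduces the statistical *structure* of the paradigm:
level-dependent leftward bias (negative p), partial azimuth information
(0 < q < 1), azimuth-dependent elevation reliability (s falling from the
free to the plugged side), prior-driven learning dynamics, and the
pre→post re-weighting pattern (q up, p more negative, s down on both
sides). It does not reproduce idiosyncratic HRTF-dependent cue quality,
front–back confusions, the non-monotonic dependence of bias on absolute
level, motor undershoot of large head movements, or any audiometric
variability — so passing tests validate the analysis machinery and the
qualitative phenomenology, not quantitative claims about human listeners.
Fitting the generative model to real subject data is likewise out of
scope.

## Numerical choices and problem sizes

Closed-form posterior moments are verified against Monte-Carlo sampling
(10⁵ draws per parameter set, 100 randomized sets, 3-SE tolerance); the
variance-ratio identity is checked to 1e-12; all regressions are checked
against brute-force normal equations to 1e-8 on 200 random designs;
parameter recovery uses n = 2000 trials × 20 seeds at 3-SE tolerance.
Learning-curve monotonicity is assessed on the across-listener mean of 8
simulated sessions — the same aggregate a cross-participant running-average
figure plots — via Spearman rank correlation; the local-gain profile uses a
3000-trial plugged control session. These sizes keep the full suite around
half a minute on one CPU while leaving comfortable statistical margins.

## Known limitations

* The double-polar diamond constraint is enforced for targets only.
* The logistic binaural-weighting form and the exponential training
  schedule are parsimonious stand-ins for mechanisms whose true functional
  forms are unknown.
* Cue weights from the no-intercept standardized regression can exceed 1
  in magnitude when predictors are correlated; they are partial weights,
  not correlations.
* The sign-test summary assumes exchangeable independent pairs; the pooled
  variant violates independence (see above).
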