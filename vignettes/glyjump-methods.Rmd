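---
title: "Forecasting CGM glucose with a jump neural network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting CGM glucose with a jump neural network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyjump)
```

## The forecasting problem

Continuous glucose monitoring (CGM) sensors report interstitial glucose every
few minutes. For a person with type 1 diabetes, a reliable 30-minute-ahead
forecast buys time to prevent excursions out of the euglycaemic band
(70–180 mg/dL) — in particular the rapid falls that accompany aerobic
exercise and the rises that accompany anaerobic exercise, which are among
the hardest regimes for any forecaster.

`glyjump` fits one model per patient on that patient's own data (a
precision-medicine design) and is deliberately univariate: the only input is
the CGM trace itself, so the patient is never asked to log meals, insulin,
or heart rate. Forecast skill is judged against the *persistence* baseline
$\hat y(t + PH) = y(t)$, the standard floor for CGM forecasting.

## The model

The forecaster is a *jump neural network*: a one-hidden-layer feed-forward
regressor whose $M$ inputs are connected both to $L$ hidden tanh neurons and
directly — jumping over the hidden layer — to the single linear output:

$$
\hat y(t + PH \mid t) \;=\; \mathrm{IOW}\cdot \mathbf I(t)^\top
  \;+\; \mathrm{HOW}\cdot f\!\left(\mathrm{IHW}\cdot \mathbf I(t)^\top\right),
$$

where $\mathbf I(t) = (y(t-M+1), \dots, y(t))$ is the most recent
$M$-minute window (oldest value first), $f = \tanh$ elementwise,
$\mathrm{IOW}$ ($M$ weights) is the direct input–output "jump" path,
$\mathrm{IHW}$ ($L \times M$) and $\mathrm{HOW}$ ($L$) form the hidden path.
The jump path carries the (dominant) linear relationship between recent
glucose and its near future; the hidden path models the nonlinear residual.
Bias terms exist in the implementation but default to zero and are excluded
from training (`train_bias = FALSE`), so the default model is exactly the
bias-free form above; frameworks that add biases by default can be mimicked
by enabling the flag.

Defaults are $M = 10$ (ten minutes of history), $L = 4$, $PH = 30$ minutes.

## From a device export to supervised pairs

* **Minute grid.** All bookkeeping ("10 min of CGM" = 10 samples, "every
  five timestamps" = every 5 minutes) presumes a 1-minute grid, so raw
  exports (typically 5-minute) are linearly interpolated onto it
  (`resample_to_minute_grid()`). Intervals between readings longer than
  `max_gap_minutes = 10` are treated as sensor disconnections and marked
  missing — one missed 5-minute reading is bridgeable, more is not.
  Readings are preserved exactly at their own minutes; duplicate timestamps
  are averaged (deterministic and order-independent).
* **Continuous days.** Only calendar days (midnight to midnight) whose 1440
  minutes are all present survive; maximal runs of consecutive complete
  days form stand-alone groups (`find_continuous_day_groups()`). No window,
  horizon, or training set ever spans a gap: each group is processed
  independently. Midnight-to-midnight is the simplest testable reading of
  a "continuous 24 h" day and is stated here as an assumption.
* **Pairs.** Within a group of $N$ minutes, anchors $t = M, \dots, N - PH$
  give $N - PH - M + 1$ pairs $(\mathbf I(t),\, y(t+PH))$. Anchors earlier
  than $M$ are dropped: a window must own its full history.
* **Split.** Offline training uses the pairs whose *target* falls in the
  first 24 h of the first group, split chronologically — earliest 80% train,
  latest 20% validation, no shuffling. Keying the split on the target time
  guarantees no training label lies beyond the first day, and chronology
  guarantees no leakage (every train anchor precedes every validation
  anchor).

## The three training protocols

All three start from the same offline phase: Glorot-uniform initialization
(seeded), then full-batch gradient descent on the training MSE with
learning rate 0.1 for at most 500 epochs, validation MSE checked every 4
epochs, early stopping after 10 consecutive checks without strict
improvement, and the returned weights are the best-validation snapshot
(ties favour the earlier check, so runs are deterministic).

1. **Offline** (`run_offline()`): the weights are then frozen and every
   eligible later timestamp — the rest of the first group and all later
   groups — is forecast with the fixed model.
2. **Online** (`run_online()`): warm-started from the offline weights. Every
   `update_cadence = 5` test timestamps, the network takes
   `online_epochs_per_update = 1` full-batch clipped gradient step
   (learning rate 0.01) on the pairs of the trailing 24 h of CGM. Only pairs
   whose window lies inside the trailing span *and* whose target has already
   realized are used, so updates are strictly causal; after a gap the
   trailing window must refill inside the new group before update steps
   resume, while predictions resume as soon as a window and target fit.
3. **Online with penalty**: identical, except each update weights the
   squared errors by the piecewise penalty below, evaluated at the
   current-model errors.

The first 24 h (the training day) is excluded from test metrics in every
configuration. Weights persist across group boundaries (one continuing
model per patient). With `update_cadence = Inf` or `lr_online = 0` the
online protocols reduce exactly to the offline one — a property the test
suite checks.

## Losses and the penalty

Errors are signed, truth minus prediction: $e(t) = y(t) - \hat y(t)$.
Offline training and the plain online updates minimise the MSE
$\frac1N \sum_t e(t)^2$; reporting uses its square root (RMSE, mg/dL).
The penalized loss multiplies each squared error by a weight that grows
with the miss:

$$
\mathrm{penalty}(e) =
\begin{cases}
0 & |e| \le 5 \\
1 & 5 < |e| \le 10 \\
2 & 10 < |e| \le 20 \\
0.5\,|e| & |e| > 20
\end{cases}
\qquad
\text{penalized loss} = \frac1N \sum_t e(t)^2\,\mathrm{penalty}(e(t)).
$$

Two choices deserve comment:

* **Magnitude vs sign.** Read literally, the piecewise rule applied to the
  signed error would give weight 0 to *any* large negative error, which
  contradicts its stated purpose of bearing down on large misses of either
  sign. The package therefore applies the thresholds to $|e|$ by default;
  the literal signed rule is available via `use_magnitude = FALSE` for
  exactness testing. Boundary values (5, 10, 20) take the lower branch, as
  the inclusive conditions dictate.
* **Stop-gradient weighting.** During training the penalty acts as a
  per-sample weight held constant within each step: no gradient flows
  through the weight's own dependence on $e$ in the $0.5|e|$ branch. This
  matches the "squared error times penalty" construction and the semantics
  of sample-weighted losses in common frameworks, and avoids optimizing a
  discontinuous objective. The finite-difference tests check the gradient
  of exactly this fixed-weight objective.

## Numerical choices

* **Glucose scaling.** The learning rates (0.1 offline, 0.01 online), the
  Glorot initialization bounds, and the 0.3 clip are all unit-scale
  quantities; applied to raw glucose (~40–400 mg/dL) full-batch descent at
  these settings is unstable — the largest Hessian eigenvalue of the linear
  path alone is of order $10^5$. The protocols therefore map the offline
  training split's glucose range affinely onto $[-1, 1]$ (midrange center,
  half-range scale), the classic feed-forward preprocessing, and map
  predictions back to mg/dL. The scaler is frozen after the offline phase
  and shared by all online updates and all three configurations, so it never
  peeks past the first day. Penalty weights are always computed on
  mg/dL-scale errors, where the 5/10/20 thresholds live. `jumpnet_forward()`
  itself is scale-agnostic: it computes the equation above on whatever units
  it is given.
* **Optimizer.** Plain full-batch gradient descent. No optimizer, batch
  size, or shuffle scheme is prescribed by the protocol definition, and a
  first day of CGM is only ~1400 pairs; full-batch keeps every run exactly
  reproducible from (seed, data, config) with no further choices.
* **Clipping.** By value (elementwise clamp to $\pm 0.3$), the common
  framework semantics; `clip_gradients()` also offers norm clipping. The
  clip is applied in both phases: at learning rate 0.1 the unclipped
  offline iteration sits at the edge of stability
  ($\mathrm{lr} \cdot \lambda_{\max} \approx 2$ even on scaled windows,
  which are highly collinear) and the clamp is what keeps early epochs
  bounded.
* **Degenerate inputs.** Non-finite training loss raises an error naming
  the epoch rather than returning silently; a constant training day yields
  a degenerate scaler (half-range 0), which falls back to scale 1.
* **Early stopping bookkeeping.** "Improvement" means any strict decrease
  of validation MSE (no minimum delta); if no validation check ever runs
  (fewer epochs than the check interval) the final weights are returned.

## The synthetic cohort generator

Real CGM traces from exercising patients are rarely shareable, so
`simulate_patient()` provides the test bed. It is phenomenological — an
additive decomposition, not a glucose–insulin ODE model — because what the
forecaster sees is statistical structure, not metabolism:

* baseline 120 mg/dL plus a 24-h sinusoid (amplitude 15 mg/dL);
* three daily meals (07:30, 12:30, 19:00, timing jitter SD 20 min) as
  bi-exponential excursions peaking at 60 ± 10 mg/dL (rise/decay constants
  20/60 min), normalized so the analytic peak equals the drawn amplitude;
* exercise: aerobic bouts ramp glucose down at 8 mg/dL per 10 min with a
  symmetric linear recovery; anaerobic bouts rise to +30 mg/dL by mid-bout
  and decay within 120 min of the end — the characteristic directions of
  the two activity types. An optional pre-exercise snack excursion is off
  by default so paired simulations isolate the exercise effect;
* AR(1) sensor noise (lag-1 coefficient 0.8, stationary SD 3 mg/dL), then
  clipping to the 40–400 mg/dL sensor range (clipped minutes are still
  readings);
* scheduled dropouts, which are what exercise the continuous-day filter.

Magnitudes are chosen to produce visibly physiologic traces (the default
patient spends well over 60% of minutes in 70–180 mg/dL — asserted in the
tests) with 2–8 activity bouts over a 6–81-day-scale recording; none of
them is a measured constant. One random stream per patient is consumed in
a fixed component order (meal timing, meal amplitudes, noise), so disabling
one component does not perturb the draws of the others.

What the generator does *not* emulate: insulin boluses and basal changes,
carbohydrate counting, sensor calibration artefacts, MARD-scale
device-specific error profiles, or inter-day habit drift. Passing the
end-to-end tests therefore demonstrates that the pipeline and protocols are
implemented correctly and can extract predictable structure, not that the
quoted accuracies transfer to any real patient.

## Problem sizes in the shipped tests

The unit and property tests run on single synthetic days or 2–4-day
patients; the end-to-end comparison uses one 10-day synthetic patient per
seed across five seeds, with all three protocols sharing each seed's
offline initialization. These sizes give stable RMSE estimates (roughly
13,000 test predictions per run) while a full suite run stays in the
minutes range.

## Known limitations

* The penalized online configuration is the most delicate of the three.
  Its weights reach $0.5|e|$ for large misses, which can inflate the update
  gradient until most components sit at the clip boundary; each update then
  degenerates into a fixed-size sign step, and the extra jitter can cost
  the penalized run a little accuracy relative to the plain online run on
  clean, easy-to-predict traces. The mechanism is visible in the
  comparison runs shipped in the tests; norm clipping
  (`clip_gradients(mode = "norm")`) softens but does not remove it.
* A chronological 80/20 split of a single day means validation covers only
  the late evening; early stopping can be mis-steered when that slice is
  unrepresentative of the rest of the recording.
* The continuous-day rule discards whole days for a single missing minute
  beyond the interpolation tolerance; that is the intended (conservative)
  inclusion rule, not a data-recovery strategy.
* Whether online updates should take one pass or retrain to convergence is
  genuinely open; the default single pass keeps the per-update cost bounded
  and is configurable via `online_epochs_per_update` (we observed no
  accuracy benefit from more passes on synthetic patients).
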