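---
title: "Response-locked classification images and the attention-gain accumulator model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-locked classification images and the attention-gain accumulator model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlci)
```

## The task and what the package computes

`rlci` simulates and analyzes a Posner-cued contrast-detection experiment.
An observer watches two fields of dynamic one-dimensional noise (16 vertical
bars each, contrasts redrawn at 30 Hz from a zero-mean Gaussian with SD 0.1,
4500 ms per trial). A target — a contrast increment whose log10 contrast
ramps up by 0.05 per frame from $10^{-3}$ — is added to the two central bars
of the left or the right field, starting at a random frame in the first
500 ms. On 94% of trials a 100-ms spatial cue flashes 500–2000 ms after
target onset, on the target side with probability 0.75 (valid) and on the
opposite side otherwise (invalid). The observer reports the target side as
fast as possible.

The package provides:

* a stimulus/trial-schedule generator (`stim_params()`, `make_trial_stimulus()`,
  `simulate_stimuli()`, `schedule_trials()`);
* a model observer (`model_params()`, `simulate_session()`, `run_observer()`)
  that converts each stimulus movie into a choice and a reaction time;
* reaction-time analyses (`assign_condition()`, `harmonic_mean_rt()`,
  `rt_by_cue_onset()`);
* response-locked classification images and impact curves
  (`response_locked_ci()`, `impact_curves()`, `epoch_cis()`, `peak_impact()`);
* model fitting by RMS error on impact curves and a parameter-recovery
  harness (`impact_rms()`, `predict_impact()`, `fit_impact()`,
  `recover_parameter()`);
* an orchestration layer (`run_pipeline()`) and the numbered drivers under
  `analysis/`.

## The model observer

The perceptual front end is a separable linear spatiotemporal filter
$F_{st}(x,t) = F_s(x)\,F_t(t)$, applied to each field's contrast movie
$I(x,t)$ with a (possibly time-varying) gain $A$:

$$R(x,t) = A \cdot (F_{st} * I)(x,t).$$

The spatial filter is a difference of Gaussians in pixel units
(0.018 deg/pixel),

$$F_s(x) = e^{-x^2/2\sigma_c^2} - \frac{\sigma_c^2}{\sigma_s^2}
           e^{-x^2/2\sigma_s^2},$$

and the temporal filter a biphasic gamma-difference on the frame grid
(33.3 ms/frame),

$$F_t(t) = \left(\frac{1}{n!} - B\frac{(t/\tau)^2}{(n+2)!}\right)
           (t/\tau)^n e^{-t/\tau},$$

with the number of stages fixed at $n = 5$. The momentary evidence compares
the spatial sums of absolute responses,
$\Delta R(t) = \sum_x |R_\mathrm{left}(x,t)| - \sum_x |R_\mathrm{right}(x,t)|$,
and the decision variable is the noisy leaky accumulation

$$S(T) = \sum_{t=1}^{T} \left(\gamma^{T-t}\,\Delta R(t) + \epsilon_t\right),
\qquad \epsilon_t \sim \mathcal{N}(0, \sigma_\epsilon^2),$$

with a response ("left"/"right") at the first $|S(T)| \ge b$ and a constant
250-ms motor delay added to the crossing time. A cue raises the cued field's
gain from 1 to $A$ starting exactly 50 ms after cue onset (quantized to the
next frame boundary) and sustained to the end of the trial. Two fitted
parameter profiles ship with the package:

```{r profiles}
model_params("valid")
model_params("invalid")
```

### Numerical conventions

* **Time.** Frames are 1-based; frame $f$ spans $[(f-1)\Delta, f\Delta)$ ms
  with $\Delta = 1000/30$. Event times are stored in ms and quantized to
  frames only where the simulation needs them; an epsilon of $10^{-9}$
  absorbs floating-point edge cases at exact frame boundaries.
* **Ramp origin.** The target-contrast formula counts $t$ from the onset of
  target addition (so the ramp starts at its minimum $10^{-3}$ at the random
  onset frame), not from noise onset; the alternative reading would make the
  starting contrast depend on the onset draw.
* **Kernels.** The temporal kernel is evaluated on the frame grid and
  truncated once $|F_t|$ stays below 0.1% of its peak (about 50 frames at
  the fitted parameters); the spatial filter is evaluated exactly over the
  256-pixel field with zero padding beyond the edges. Neither filter is
  normalized beyond its printed closed form, so the boundary $b$ and noise
  SD $\sigma_\epsilon$ are in the model units implied by those forms — with
  the consequence, visible in simulation, that the fitted boundary (356)
  sits slightly above the zero-noise asymptote of the leaked evidence for a
  saturated target (~321): crossings are driven over the line by stimulus
  and internal noise, which produces a broad RT distribution and a
  substantial fraction of deadline lapses (~25% at the valid profile).
  These lapsed trials are excluded from analysis, as are errors and
  responses past the 4500-ms deadline.
* **Internal noise.** The accumulation formula is implemented literally:
  the decay $\gamma^{T-t}$ applies to the evidence only, so the internal
  noise terms accumulate as an unleaked random walk. `leak_noise = TRUE`
  switches to the common alternative in which noise decays like the
  evidence. The literal reading is the default because it is what the
  printed formula says; the choice materially affects how much of the RT
  variance is internal (the walk grows as $\sqrt{T}$ and dominates late in
  the trial).
* **Geometry.** The pixel grid is derived from the bar grid (16 bars ×
  16 px = 256 px ≈ 4.6 deg at 0.018 deg/px); the nominal field size is
  checked to half a bar width. The cue rectangles lie outside the noise
  fields and are represented as event metadata only.

## Classification images

`response_locked_ci()` computes, for each bar and each backward lag from
the response frame (the frame containing the response time), the mean of
the *pre-clipping* Gaussian noise samples over contributing trials. With
zero-mean i.i.d. noise this mean-noise estimator differs from a per-cell
correlation coefficient only by scale; a `"pearson"` variant is available.
Left-target trials are mirrored (fields swapped, bar order reversed) into
the right-target orientation, so bars 8–9 are always the target bars and
7, 10 their flankers. Only correct, non-excluded trials contribute by
default: accuracy is near ceiling, so response-sorting and target-sorting
coincide, matching the target-field/non-target-field split. Cells that no
trial reaches (lags extending before stimulus onset) are missing, not zero.

Impact curves collapse the CI to the mean of the central two bars
("center") and of the two flankers ("surround") per lag; the peak impact is
the mean of a curve over the 300–400 ms window before the response
(inclusive). Epoch analysis splits cued trials by `rt - cue_onset` into
500-ms windows shifted by 250 ms over 0–1500 ms, a trial entering every
window containing its value (half-open edges).

## Fitting and parameter recovery

`fit_impact()` minimizes the RMS difference between observed and simulated
center+surround impact curves over backward lags 0–1000 ms (the window
covering the biphasic structure). Simulations reuse one fixed stimulus set
including its standardized accumulator-noise streams — common random
numbers — so the objective is a deterministic function of the parameters.
One free parameter is searched by a 17-point grid scan over its bounds
(the current value is always part of the start set) followed by
golden-section refinement; several free parameters by Nelder–Mead with
five starts, scale parameters in log space. Bounds:
$\sigma_c \in [0.5, 20]$ px, $\sigma_s \in [2, 60]$ px (with
$\sigma_c < \sigma_s$ enforced by penalty), $B \in [0, 1]$,
$\tau \in [0.5, 10]$ frames, $\gamma \in [0, 0.95]$, $b \in [50, 2000]$,
$\sigma_\epsilon \in [0, 50]$, $A \in [0.5, 3]$. $n$ and the delays are
structural constants and cannot be freed; invalid-condition fits fix
$A = 1$.

The recovery harness (`recover_parameter()`) simulates a session of
always-valid-cue trials at the fitted valid-condition parameters and
refits one parameter with everything else held at truth. Following the
original procedure, the candidate models are evaluated **on the stimuli
shown to the (synthetic) observer**. This matters quantitatively: with
independent stimulus or internal-noise streams, the objective acquires a
noise floor of roughly 0.002 contrast units — the same order as the model's
CI amplitude at a few thousand trials — and one-dimensional refits become
poorly conditioned. With full common random numbers the objective has an
exact zero at the generating value and recovery probes whether the RMS
objective identifies that value uniquely over the bounds. Recovery
sessions use 3200 trials, the per-observer session floor of the emulated
experiment; the acceptance-oriented tests use 2000.

## What the synthetic data does and does not emulate

The generator reproduces the display statistics (noise SD, frame rate,
durations), the trial schedule (target side/onset, cue probability,
validity, onset range), and — through the model observer — trial records
whose RT distributions and classification images are qualitatively like
the human ones (biphasic center curve peaking a few hundred ms before the
response, opposing surround, faster valid-cue responses). It does not
emulate: sequential effects between trials (each trial is independent),
eye movements or fixation breaks, motor-delay variability, observer
heterogeneity beyond seed differences, or luminance/display calibration
(contrast is the native unit; a luminance rendering would be
$L = L_\mathrm{mean}(1 + C)$). Passing tests on synthetic data therefore
validate the computational chain, not claims about any human dataset.

Two empirical notes from the simulations, fixed here so the tests are read
correctly. First, the windowed peak-impact statistic is noisy: its
sampling SD at 3000 trials (~0.001 contrast units) is as large as the
gain-induced trend across plausible gains, so no test asserts a monotone
peak-impact/gain relation; the gain's reliable signatures at desk scale
are the RT advantage and the RMS objective. Second, a "flat" CI over
16 bars × 41 lags has 656 cells, so a few 3-SE excursions are expected by
chance; the null-CI checks use a simultaneous 4.5-SE band plus a 1% cap on
3-SE exceedances.

## Problem sizes

The shipped analyses use sessions of 1500–6000 trials in the test suite,
3200-trial sessions (five observers per condition) in the `analysis/`
drivers, and 3200-trial sessions for acceptance recoveries — the same
order as the emulated experiment (each human completed 3200–4960 trials).
A 3200-trial session simulates in roughly ten seconds on one core.

## Known limitations

* The printed boundary/noise units are tied to the unnormalized filter
  forms; a different (unstated) normalization in the original code would
  rescale $b$ and $\sigma_\epsilon$ without changing the structure.
* The non-target-field CI is computed but flat, as in the emulated data;
  no bias correction for target-present CIs is implemented.
* Fits are per-condition and per-observer; no hierarchical pooling, and no
  likelihood-based alternative to the RMS objective.
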