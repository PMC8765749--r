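---
title: "Methods: models, preprocessing and inference in optomask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, preprocessing and inference in optomask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`optomask` analyzes experiments in which a monkey detects a small visual
target while orange light optogenetically drives a co-localized patch of
V1 expressing an excitatory opsin (C1V1), with the population response
read out by widefield GCaMP imaging. The scientific quantity of interest
is the *masking* interaction: how much the optostim-evoked pedestal
suppresses the visual-evoked response (`rho_physiology`) and raises the
behavioral detection threshold (`rho_behavior`). This vignette documents
the models, the numerical choices, what the synthetic generator does and
does not emulate, and the design decisions that were genuinely open.

## The task and timeline

Each trial: fixation, a temporal cue, then on half of the trials a small
Gaussian target of Weber contrast `c = (Lmax - Lbg)/Lbg` appearing 250 ms
after the cue, for at most 250 ms. In optostim blocks, light pulses
(5 ms every 22.5 ms, ~44 Hz, 22% duty cycle) are delivered on *every*
trial starting 290 ms after the cue — 40 ms after the target, matching
V1 response latency — for at most 210 ms. The camera runs at 20 Hz for
1.2 s (24 frames), triggered on a QRS upstroke of the EKG; with the cue
100 ms into acquisition, target onset falls at the start of frame F8 and
frames F5–F7 cover the 150 ms just before onset. `build_timeline()`
encodes and validates all of this.

## Preprocessing chain

The order is fixed: stabilize → (downsample) → dF/F → heartbeat removal
→ pre-stimulus anchoring and detrending → window summary → z-score.

**Motion-regression stabilization.** Pixel intensity is modelled as
`I[x,y,t] = I0[x,y,t] + alpha[x,y]·v[t]` with one global translation
`v[t]` per frame and a per-pixel coefficient 2-vector `alpha`. `v[t]` is
estimated from the central quarter of the image by FFT cross-correlation
with parabolic sub-pixel interpolation. Two implementation details
matter and are worth stating: (i) the raw trial-median frame is blurred
by the very motion being estimated, so estimation is two-pass —
consecutive-frame shifts are integrated into a provisional trace, frames
are de-shifted, and their average is the sharp reference for the final
estimates; (ii) clamped (non-periodic) image edges bias a single
correlation toward zero by roughly 8% of the shift, so estimates above
0.3 px are refined iteratively against a shifted reference. A Hann
window suppresses the edge discontinuity. As written, the model with a
free `I0[x,y,t]` is unidentifiable; `alpha` is therefore fitted only on
frames where the stimulus-driven component is constant — the
pre-stimulus frames of every trial plus all frames of blank trials —
pooled across the session (per-trial fitting is available but noisier).
The intercept is discarded; stabilization subtracts `alpha·v[t]`.

**Heartbeat removal.** Acquisition is EKG-triggered, so the heartbeat
artifact is locked to trial start but stretches with the trial's heart
rate; at a fixed (pixel, frame) the intensity varies predictably with
HR. The model `I[x,y,t,k] = S[x,y,t,s(k)] + f[x,y,t](HR_k)` with `f` a
quartic polynomial in HR with no constant term is solved jointly for
the condition responses `S` and the polynomial coefficients, as one
batched least squares over all pixels and frames. Raw `HR^1..HR^4`
columns are catastrophically collinear (condition numbers ~1e12), so HR
is standardized and each polynomial column mean-centered before
fitting; this is a reparameterization, not a model change — the
constant it introduces is absorbed by the condition indicators, and it
guarantees the subtracted artifact averages exactly to zero over
trials. Degenerate heart-rate variance yields a flagged no-op model.

**dF/F, ROI, detrending, z-score.** `dF/F = (F - F0)/F0` with `F0` the
mean of the three pre-stimulus frames. The ROI is the 1 × 1 mm² window
maximizing the visual-evoked mean response, found by exhaustive search
(integral image; ties broken at the smallest `(y0, x0)`). One detail is
deliberate: the *selection* map is computed over a late 200–400 ms
post-stimulus window, disjoint from the 50–200 ms response window.
Maximizing over the response frames themselves adds the selection
optimum's noise to the visual-only responses (winner's curse) — at
desk-scale SNR this biased the reduction statistic upward by ~+0.02 —
while the sustained GCaMP response makes the late window carry the same
spatial map. Slow drifts
are removed with the two-component model `R(t) = R_S(t) + m_S(t) +
m_k·t`: per-trial pre-stimulus anchoring, a per-condition affine
component estimated on pre-stimulus frames (the only reading consistent
with forcing every conditional mean to a *flat, zero* pre-stimulus
baseline — a slope alone cannot achieve both), and a per-trial residual
slope fitted on frames up to the saccade. The per-condition affine uses
*all* pre-stimulus frames (F1–F7 at the default timing), not only the
three F0 frames: it is extrapolated several frame-periods into the
response window, and a 3-point fit amplifies pre-stimulus noise roughly
four-fold (switching to F1–F7 halved the session-to-session SD of the
reduction estimate in simulation). The scalar response is the
mean over frames whose start times fall in [50, 200) ms post-onset
(exactly three frames at 20 Hz; the half-open convention is what makes
it three, and is configurable). Z-scores divide by the unbiased SD of
the blank trials (no visual, no optostim) of the same session and are
poolable across sessions.

## Neural statistics

Contrast-response functions use the Naka-Rushton form
`Z(c) = Zmax·c^n/(c^n + c50^n)`. `Zmax` enters linearly and is profiled
out in closed form; the remaining 2-D problem in `(log n, log c50)` is
solved by L-BFGS-B from a fixed 16-point multi-start grid, so the fit
is deterministic. The visual contribution under optostim is
`Z_optosub(c) = mean Z_optovis(c) - mean Z_optobase`, subtracting the
optostim-only baseline measured on target-absent trials of the same
power. The reduction statistic is the weighted least-squares scaling
`rho = 1 - sum(w·Zvis·Zoptosub)/sum(w·Zvis²)`, reported *unclipped*
with a quality flag outside [0, 1] (clipping would bias the bootstrap
distribution); weights default to matched trial counts, with an
equal-weight mode behind a flag. Bootstrap inference resamples trials
with replacement within each stimulus condition (contrast × optostim
level), 1000 times by default; the SD of replicate `rho` values is the
error bar and the one-sided p-value against `rho = 0` is the fraction
of replicates agreeing with the null, Bonferroni-adjusted across power
levels. Two resampling depths are offered: the default resamples the
final z-table; the fuller mode (pass the extracted session to
`bootstrap_neural()`) re-runs detrending, window summary and z-scoring
on every resample. The distinction matters because the detrend
parameters and `sigma_blank` are themselves estimated from the trials:
resampling only the final z-scores treats them as fixed and, in
simulation, understates the across-session SD of `rho` several-fold at
small trial counts, while the re-run mode is calibrated (bootstrap SD
within ~10% of the Monte-Carlo SD across sessions).

## Behavioral model

Detection behavior follows an equal-variance signal-detection model
with `d'(c) = (c/alpha)^beta`, hit and correct-rejection probabilities
`Phi(d'/2 ∓ delta)`; target-absent trials use the block's target
contrast, as the blocked design implies. `alpha` is the threshold
(d' = 1, ≈69% bias-corrected correct), `delta` the criterion (positive
= bias toward "absent"). Visual-only and optostim blocks are fitted
jointly with separate `(alpha, delta)` and a shared `beta`, by BFGS on
`(log alpha, log beta, delta)` from a fixed 8-start grid, tolerance
1e-9 on the negative log-likelihood.

Observed proportions are rescaled to `P̂ = 0.005 + 0.99·P` so cells
with P ∈ {0, 1} keep a finite likelihood. One design point deviates
from the obvious implementation, deliberately: the *model* probabilities
pass through the same affine map before entering the binomial
cross-entropy (equivalently, a fixed 0.5% guess and lapse rate). If
rescaled targets are compared against unrescaled model probabilities,
the capped high-contrast cells drag the shared `beta` down by ~12% even
at 10,000 trials per condition — a bias, not noise. With the symmetric
map the fit reduces to standard maximum likelihood up to the tiny fixed
lapse and recovers `alpha` and `beta` to within ~1–2% at that scale.

`rho_behavior = alpha_optovis/alpha_vis`. Bootstrap resampling is
stratified within (block × contrast × target-presence) cells —
preserving present/absent counts — with joint refits warm-started at
the point estimate; threshold SDs are also reported normalized by the
mean visual-only threshold, and p-values (no threshold increase, no
criterion change) are Bonferroni-adjusted across power levels.

## The synthetic generator: what it emulates

A rendered trial is
`T_v( B·(1 + G1·r1(t) + G2·r2(t) + d(t)) + B·M·h(t) ) + noise`:

- `B`: baseline fluorescence with two texture scales (broad expression
  unevenness plus fine vasculature-like structure — the latter is what
  registration latches onto);
- `G1, G2`: Gaussian expression sites. Site 1 (opsin + indicator)
  receives visual drive following a Naka-Rushton law in dF/F and
  optostim drive per power level; on combined trials the visual-evoked
  component is scaled by `1 - rho_true` — the sublinearity the pipeline
  must recover. Site 2 (indicator only) receives attenuated visual
  drive and no optostim.
- response kernels rise with a 60 ms time constant while the stimulus
  is on and decay slowly (800 ms) after offset, mimicking GCaMP6f;
- `h(t)`: a sinusoid locked to acquisition start whose amplitude is a
  no-constant-term polynomial of standardized heart rate — matched to
  the removal model's function class so recovery is a fair test. A
  model-mismatch mode (`hb_phase_mismatch`) makes the waveform
  frequency follow each trial's heart rate (the "accordion" stretching
  of the real artifact) for robustness studies.
- `d(t)`: linear drift with per-condition and per-trial slopes;
- `T_v`: whole-frame translation by a random-walk micro-motion trace,
  via separable Catmull–Rom cubic convolution (chosen over an exact
  spline for vectorizability; it is exact on affine images, which gives
  the stabilization stage an analytic oracle);
- i.i.d. Gaussian sensor noise.

Every stochastic component is returned in a per-trial sidecar, so tests
can reconstruct the noise-free stack exactly and verify each stage by
parameter recovery. One session seed expands into fixed-purpose child
seeds, so single trials re-render in isolation.

Choices where the literature, not the data, set the value: heart rate
150 ± 10 beats/min (awake macaque); saccadic reaction times log-normal
with 160 ms median, truncated to the task's 75–600 ms window; visual
dF/F ceiling 4%, optostim response 3% at 0.6 mW/mm²; heartbeat
amplitude 0.4% of baseline; micro-motion random-walk step 0.05 px;
drift ~0.2%/s; sensor noise 0.3% of mean baseline.

By default the rendered responses run to the stimuli's maximum
durations even on saccade trials. In the task the target and optostim
extinguish at the saccade; emulating that (`truncate_at_saccade = TRUE`)
makes the optostim pedestal smaller on combined (mostly hit) trials
than on optostim-only (mostly stay) trials, which biases the
baseline-subtracted reduction upward by ~0.15 — a real confound of the
subtraction method worth studying, but not part of the stated
generative world the recovery tests assume.

What the generator does **not** emulate: optics (point-spread,
hemodynamic absorption), eye-movement-locked image shifts, spiking
dynamics, non-rigid deformation, and trial-to-trial response-amplitude
correlations. A green recovery test therefore establishes correctness
of the estimators under the stated model, not robustness to everything
real data can do.

### Geometry

The desk-scale default is 64 × 64 px covering a 2 × 2 mm field
(31 µm/px), sites 1.4 mm apart, so the standard 1 × 1 mm² ROI is a
32 px window the search can actually place. A field of exactly
1 × 1 mm (the naive miniaturization of 8 mm/512 px) would make the ROI
the whole image and force both expression sites — separate cortical
locations in the real experiment, analyzed separately — into one ROI,
diluting the measured reduction by the indicator-only site's share.

## Numerical and degenerate-input conventions

Frame labels are 1-based ("F5–F7"); times are ms from acquisition
start, pixel coordinates (x right, y down). sigma_blank uses the n−1
estimator. Rank-deficient heartbeat designs fall back to minimum-norm
coefficients; collinear motion traces drop an axis with a diagnostic;
conditions with one trial are flagged (their mean is that trial);
trials with fewer than two valid frames get `m_k = 0` and a flag;
`sigma_blank = 0` and `F0 <= 0` are hard errors. Bootstrap p-values are
reported as replicate proportions (resolution 1/n_boot).

## Known limitations

- The z-table bootstrap (default mode) treats ROI placement, the
  heartbeat fit and the upstream stack-level corrections as fixed;
  their estimation noise is coherent within conditions and invisible to
  the resample. The timecourse-level mode recovers the detrend and
  z-scoring contributions; the stack-level ones remain conditional.
- At desk scale the reduction estimate retains a small positive bias
  (~+0.02 at 200-trial sessions) from the interaction of artifact
  removal and detrending with 12–25-trial conditions; it is absent in
  an artifact-free render with a fixed ROI and shrinks with trial
  count.
- The reduction statistic assumes the optostim pedestal is identical on
  combined and optostim-only trials; behaviorally coupled truncation
  violates this (see above).
- The first-order motion model is exact only for image structure that
  is smooth on the scale of the motion. For the default fine (1.2 px)
  vasculature texture and ~0.1 px micro-motion, stabilization leaves
  7–9% of the motion-correlated variance whether the trace is estimated
  or exact — a modelling limit, not an estimation one. Motion below
  ~0.05 px is additionally at the resolution limit of the correlation
  estimator.
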