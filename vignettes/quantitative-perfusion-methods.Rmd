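---
title: "Methods: quantitative myocardial perfusion mapping with qperf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative myocardial perfusion mapping with qperf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qperf)
```

## Scope and model

`qperf` implements the standard quantitative analysis chain for dynamic
first-pass saturation-recovery (SR) perfusion CMR: signal conversion,
preprocessing, arterial input function (AIF) handling, tracer-kinetic
estimation, map assembly and quality control, plus a digital phantom that
generates dual-sequence stress/rest studies with known ground truth.

The physics layer models the SR readout explicitly. After an (ideally
complete) saturation, the longitudinal magnetization recovers for the
delay TD, is tipped by each readout pulse, and recovers over each TR; the
signal of interest is the transverse magnitude at the k-space centre line.
For spoiled GRE this propagation has a closed form, which the test suite
verifies against a literal step-by-step Bloch recursion to 1e-9 relative;
for bSSFP an on-resonance stepwise recursion with a fixed assumed T2
(default 45 ms for myocardium) is used. Conversion from signal to
concentration inverts a tabulated signal dictionary (1-ms steps over
50–3000 ms by default; linear interpolation) and applies the fast-exchange
relaxivity relation `1/T1 = 1/T1_0 + r1·CA`. Signals outside the dictionary
range are clamped and flagged — never silently extrapolated — and negative
concentrations are flagged rather than clipped, so the QC report can
surface both.

Two conversion conventions deserve note:

* **M0 normalization.** The unsaturated PD-weighted lead-in frames are
  rendered/read with the same readout model at the PD flip angle, so
  dividing by them converts pixel signal to the dictionary's M0 scale and
  simultaneously cancels any multiplicative coil-sensitivity field. Both a
  per-pixel PD reference and a fitted polynomial PD surface are exposed
  (`pd_mode`), neither privileged.
* **Fixed baselines.** Population-level baseline T1 values are used
  (defaults 1600 ms blood, 1200 ms myocardium, 3T-like), configurable in
  `quant_config()`.

## Kinetic estimators

Tissue kinetics are linear and time-invariant,
`C_myo = F_p (R * C_aif)`, with `R(0) = 1` and R non-increasing, so MBF is
the impulse response at time zero. The AIF is converted to plasma
concentration by `1/(1 - Hct)` (default hematocrit 0.42); reported MBF
defaults to whole-blood flow per gram, `F_p / (1 - Hct) / 1.05`, with the
plasma convention available as a switch.

* **Fermi.** The impulse response is `A/(exp((t-mu)k)+1) + offset`. On
  short first-pass windows (often ~10 samples) the shape parameters are
  only weakly identified and a single local optimization is unreliable, so
  the fit is global-then-local: a coarse grid over (mu, k) with the two
  linear amplitudes profiled out, then Levenberg–Marquardt from the best
  grid point. MBF is read as the full I(0) including the offset: the
  offset models slow interstitial leakage, which at t = 0 is part of the
  tissue's impulse response. On two-compartment-generated tissue,
  excluding it biases MBF low by tens of percent, while including it keeps
  the cross-model error within a few percent at physiologic flows.
* **2CXM.** The bi-exponential impulse response is evaluated analytically
  from the 2x2 compartment matrix eigenstructure. Stage 1 evaluates an
  8-points-per-parameter grid over physiologic ranges (F_p 0.1–6 mL/min/mL,
  v_p 0.01–0.2, v_e 0.05–0.5, PS 0–2); exponential convolutions use an
  exact piecewise-linear-input integrator, vectorized across all 8192 grid
  rates, so the whole grid costs a few milliseconds. Stage 2 is a
  Nelder–Mead refinement in log-parameter space. A reduced impermeable
  model (PS = 0) is also refined and kept on an effective tie: when the
  tissue is purely intravascular the full model's PS and v_e are jointly
  unidentifiable, and parsimony resolves the degeneracy.
* **Patlak.** Linear regression of `C_t/C_a` on `∫C_a/C_a` over an early
  window, by default the bolus upslope up to the AIF peak — later samples
  bend the plot through backflux and bias K_trans low.
* **Tikhonov.** The causal convolution is discretized as a lower-triangular
  Toeplitz system (rectangle rule, nonsingular whenever the AIF is nonzero
  at the window start) and solved by SVD with a ridge penalty on the
  identity; the weight is chosen by generalized cross-validation unless
  given. The first recovered node is biased low because the AIF rises from
  zero across the first interval, so I(0) is read by a short linear
  extrapolation from the following nodes.

### Windows and arrival

`crop_first_pass()` windows both curves from one sample *before* the
detected AIF arrival (the bolus onset generally falls between samples;
starting at the detected arrival discards the leading rise and biases all
convolution fits by several percent) to the end of the first pass — the
first post-peak sample at or below 30% of peak, or the pre-recirculation
minimum, whichever comes first. Arrival detection offers the triangle
method (computed on the peak-normalized curve, hence amplitude-invariant)
and an upslope-line fit over the 10–50% band, which hugs the foot of a
convex bolus front. `arrival_search()` repeats any fit over candidate
myocardial arrival delays and keeps the minimum-residual fit, ties broken
toward the earliest delay.

## The phantom

`phantom_spec()`/`phantom_study()` generate dual-sequence studies: three
short-axis slices (myocardial annulus, LV blood pool, RV crescent, a
chest-wall band and a liver-like blob — the asymmetric static anatomy that
makes in-plane registration well-posed, as in real thoraxes), plus a
half-resolution short-TS AIF series. The bolus is a gamma-variate (onset
8 s, shape 3, scale 1.5 s, peak 4 mmol/L), deliberately reaching the
strongly nonlinear signal regime at the default sequence settings;
recirculation is an optional delayed scaled copy. Tissue curves come from
the chosen residue model via oversampled causal convolution (verified
against a 100x-oversampled Riemann oracle within 1%). Frames are rendered
through the same signal model used for conversion — PD lead-in frames
unsaturated at low flip angle — then multiplied by a second-order
polynomial coil field, moved (anatomy moves; the coil pattern is static in
space), and corrupted with Rician-like noise whose SD is a fraction of the
PD-weighted myocardial signal. Frame times follow the RR schedule, which
may include missed beats; identical seeds give byte-identical studies.

What the phantom does *not* emulate: through-plane and non-rigid motion,
dark-rim artifacts, k-space undersampling artifacts, water-exchange and
slice-profile effects, and any claim that its bolus amplitude matches a
particular clinical dose. Passing tests therefore demonstrate numerical
and algorithmic correctness under idealized 2D translational conditions,
not clinical performance.

## Preprocessing choices

Registration is translation-only and sequential: adjacent frames are in
nearly identical enhancement states, so pairwise high-passed FFT
cross-correlation (the high-pass removes the static coil pattern) with
parabolic subpixel refinement is well-posed even though direct correlation
across contrast states is not; pairwise displacements are accumulated and
referred to the reference frame, and estimates below 0.1 px are snapped to
zero. Accumulated drift stays well under a pixel for step-like breathing
patterns and around a pixel for a 60-frame random walk. Coil correction
offers the quadratic-surface fit and the pixel-wise PD division; because
the coil pattern is static while anatomy moves, the exact order for a
moving acquisition is coil-correct (from motion-free PD frames), then
register, then convert — the pipeline order is configurable, defaulting to
register-first, which is equivalent whenever residual motion is small
relative to the bias gradient (the residual error scales as
|∇bias|·|displacement|). Temporal filtering is deliberately not
implemented; spatial filtering refuses AIF series.

## Maps, burden and QC

`quantify_pixelwise()` fits every masked pixel (failed pixels flagged, not
filled), `compute_mpr()` guards against near-zero rest flow (default floor
0.1 mL/min/g), and `aha16_segment()` labels 6/6/4 sectors counterclockwise
from the anterior RV insertion. Ischemic burden is pixel-area-weighted,
with the segment-count percentage (affected/16) reported alongside for the
two-segment rule of thumb; apical pixels within one pixel of the mask
boundary can be excluded as a partial-volume guard. Abnormality thresholds
(stress MBF < 1.5 mL/min/g, MPR < 2) are explicitly configurable and
non-normative. The QC thresholds (missed beat at 1.75x the running-median
RR, 1% flat-top tolerance, minimum AIF SNR 10, 20% per-segment failure
fraction, 1.2x baseline LV/myocardium ratio, 1 px residual motion) are
package choices, recorded in every report.

## Numerical sizes used in the tests

The shipped test-suite and acceptance script run the phantom at 96x96
(three slices) for conversion and QC checks and 40x40 single-slice for
pixel-wise mapping, 50–60 frames at 1000-ms RR, 50 noise replicates per
flow level at curve SNR 20, and flow levels 0.5–4 mL/min/mL. These sizes
were chosen so that each property is measured with comfortable margin
while the whole suite stays quick to run; all are parameters, not limits.

## Known limitations

* Fermi deconvolution underestimates flow on two-compartment tissue
  increasingly with flow (about 14% at F_p = 4 mL/min/mL with resting
  blood volumes at 1-s sampling): the early vascular transit becomes
  shorter than the sampling interval. The matched-model 2CXM fit does not
  share this bias; reporting several models side by side is intentional.
* Model-independent deconvolution at 1-s sampling cannot resolve impulse
  responses whose initial decay is faster than the sampling interval; its
  I(0) read-out is accurate for smooth responses and degrades for sharp
  high-flow ones.
* The archive format stores DICOM-style tag addresses in JSON sidecars
  with NIfTI pixel data; it preserves the full required parameter set and
  round-trips losslessly, but it is not a DICOM implementation.
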