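# qperf — quantitative myocardial perfusion CMR

`qperf` turns dynamic first-pass saturation-recovery perfusion CMR series
into pixel-wise maps of myocardial blood flow (MBF, mL/min/g), myocardial
perfusion reserve (MPR = stress MBF / rest MBF) and tracer arrival time,
with AHA 16-segment summaries, ischemic-burden percentages, acquisition
protocol validation and a computable quality-control checklist. It is
written for imaging scientists and physicists building or validating
quantitative perfusion pipelines; a digital perfusion phantom with full
ground truth makes every stage testable without patient data.

## The model

Contrast concentration follows from the measured signal through the
saturation-recovery signal model and the relaxivity relation

    1/T1 = 1/T1_0 + r1 · CA

where the signal-to-T1 inversion uses a Bloch-simulated dictionary of the
SR-GRE (or bSSFP) readout, normalized per pixel by unsaturated
proton-density frames (which also cancels coil bias). Tissue kinetics are
linear and time-invariant:

    C_myo(t) = F_p · (R ∗ C_aif)(t),   R(0) = 1, R non-increasing

so MBF is the tissue impulse response at time zero, I(0) = F_p. Four
estimators of I(t) are provided behind one interface, `fit_perfusion()`:

* **Fermi-constrained deconvolution** — I(t) = A/(exp((t−μ)k)+1) + offset,
  fitted to the first pass by a global (μ, k) profile search plus
  Levenberg–Marquardt;
* **two-compartment exchange model (2CXM)** — analytic bi-exponential
  impulse response in (F_p, v_p, v_e, PS), fitted coarse-to-fine (8⁴ grid
  search, then Nelder–Mead);
* **Patlak plot** — early-window linearization giving K_trans and v_p;
* **Tikhonov model-independent deconvolution** — ridge-regularized
  discrete deconvolution with generalized cross-validation.

All fits return a classed `perfusion_fit` object with `print`, `summary`,
`coef`, `fitted`, `residuals`, `predict`, `plot` and `simulate` methods.

## Worked example

```r
library(qperf)

# a synthetic dual-sequence stress study with known ground truth
study <- phantom_study(phantom_spec(seed = 1))
gt <- study$ground_truth

# convert the AIF series to plasma concentration
aif_conv <- si_to_concentration(study$aif_series, config = gt$config)
ca <- apply(aif_conv$concentration, 3, function(fr) mean(fr[gt$aif_blood_mask]))
aif <- ca / (1 - gt$config$hematocrit)

# fit the myocardial mean curve with the Fermi model
conv <- si_to_concentration(study$myocardial[[1]], config = gt$config)
tissue <- apply(conv$concentration, 3, function(fr) mean(fr[gt$myo_masks[[1]]]))
cr <- crop_first_pass(aif, tissue, conv$times)
fit <- fit_fermi(cr$aif, cr$tissue, cr$times)
fit
#> <perfusion_fit> model fermi: MBF = 1.579 mL/min/g (F_p = 0.962 mL/min/mL)
#>   rss 6.836e-07 over 11 points; converged: TRUE
```

The phantom's ground-truth plasma flow is F_p = 1 mL/min/mL; under the
whole-blood convention (hematocrit 0.42, density 1.05 g/mL) that is
1/0.58/1.05 = 1.64 mL/min/g. The whole-myocardium mean curve recovers it
to within about 4% (the Fermi shape is an approximation to the phantom's
two-compartment response; per-pixel matched-model fits land well under
1%, see `tests/testthat/test-acceptance.R`). `quantify_pixelwise()` repeats this per masked pixel (with an
optional arrival-time search), `compute_mpr()` forms the reserve map,
`aha16_segment()` + `ischemic_burden()` summarize it, and `study_qc()`
produces the quality-control report. `run_pipeline()` chains the whole
workflow from a config list or YAML/JSON file; `inst/cli/qperf` exposes
`simulate`, `quantify`, `qc` and `validate-protocol` subcommands.

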