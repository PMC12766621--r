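# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# Small clean dual-sequence study used by many tests.
clean_study <- function() {
  if (is.null(fixture_env$clean))
    fixture_env$clean <- phantom_study(phantom_spec())
  fixture_env$clean
}

# Canonical curve pair: 1-s sampling, gamma-variate bolus, plasma units.
curve_pair <- function(model = "2cxm", params = kinetic_params(),
                       tmax = 90, dt = 1, recirc = 0) {
  t <- seq(0, tmax, dt)
  aifp <- generate_aif(t, recirc_fraction = recirc) / (1 - 0.42)
  tissue <- forward_tissue(aifp, params, model, t)
  list(t = t, aif = aifp, tissue = tissue, params = params)
}

# Independent step-by-step Bloch recursion oracle for the SR-GRE signal.
bloch_oracle <- function(T1, seq, M0 = 1) {
  mz <- (1 - seq$saturation_efficiency) * M0
  mz <- M0 - (M0 - mz) * exp(-seq$TD / T1)
  ca <- cos(seq$flip_angle * pi / 180)
  sa <- sin(seq$flip_angle * pi / 180)
  if (seq$lines_to_center > 1)
    for (i in seq_len(seq$lines_to_center - 1)) {
      mz <- mz * ca
      mz <- M0 - (M0 - mz) * exp(-seq$TR / T1)
    }
  sa * mz
}

# Fine-grid Riemann convolution oracle for the tissue forward model.
conv_oracle <- function(aif, params, model, times, dt_fine = 0.01) {
  fine <- seq(0, max(times) - times[1], dt_fine)
  ca <- approx(times - times[1], aif, fine, rule = 2, yleft = 0)$y
  r <- residue_function(fine, params, model)
  vapply(times - times[1], function(ti) {
    sel <- fine <= ti
    if (sum(sel) < 2) return(0)
    (params$F_p / 60) * sum(rev(r[sel]) * ca[sel]) * dt_fine
  }, numeric(1))
}

# Mean concentration over a mask for each frame of a converted array.
mask_curve <- function(conc, mask) apply(conc, 3, function(fr) mean(fr[mask]))

# Blood-pool plasma AIF of a study, from ground truth masks.
study_aif_plasma <- function(study) {
  gt <- study$ground_truth
  conv <- si_to_concentration(study$aif_series, config = gt$config)
  ca <- mask_curve(conv$concentration, gt$aif_blood_mask)
  list(times = conv$times, values = ca / (1 - gt$config$hematocrit),
       blood = ca)
}
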