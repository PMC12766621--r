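#' Saturation-recovery sequence parameters
#'
#' Container for the acquisition parameters needed to model the
#' saturation-recovery (SR) readout and convert signal intensity to T1 and
#' contrast-agent concentration: flip angle, TR, TE, saturation time TS
#' (saturation pulse to k-space centre), trigger delay TD (saturation pulse to
#' first readout RF pulse), and the number of phase-encode lines acquired
#' before the k-space centre.
#'
#' @param flip_angle readout flip angle in degrees.
#' @param TR repetition time in ms.
#' @param TE echo time in ms; may be a vector for multi-echo readouts.
#' @param TS saturation time in ms, measured from the saturation pulse to the
#'   acquisition of the centre line of k-space.
#' @param TD delay in ms from the saturation pulse to the first readout RF
#'   pulse. `TS >= TD` and the triple (TS, TD, lines_to_center) must be
#'   mutually consistent within one TR.
#' @param lines_to_center number of readout pulses up to and including the
#'   k-space centre line (>= 1).
#' @param readout `"GRE"` (spoiled gradient echo) or `"bSSFP"`.
#' @param acquisition_window total readout duration per image in ms.
#' @param dynamic_interval nominal frame interval in ms (scalar or per-frame).
#' @param role `"myocardial"` or `"AIF"`.
#' @param pd_flip_angle flip angle in degrees used for the unsaturated
#'   proton-density (PD) lead-in frames.
#' @param saturation_efficiency fraction of longitudinal magnetization
#'   destroyed by the saturation pulse (1 = ideal).
#' @param T2 assumed T2 in ms, used only for the bSSFP readout model.
#' @return an object of class `seq_params`.
#' @export
#' @examples
#' seq_params(flip_angle = 10, TR = 2.5, TE = 1.2, TS = 100, TD = 5,
#'            lines_to_center = 40, role = "myocardial")
seq_params <- function(flip_angle, TR, TE = 1.0, TS, TD = 0,
                       lines_to_center = 1L,
                       readout = c("GRE", "bSSFP"),
                       acquisition_window = NULL,
                       dynamic_interval = NULL,
                       role = c("myocardial", "AIF"),
                       pd_flip_angle = 5,
                       saturation_efficiency = 1,
                       T2 = 45) {
  readout <- match.arg(readout)
  role <- match.arg(role)
  if (TR <= 0) stop("TR must be positive")
  if (TS < 0 || TD < 0 || TS < TD) stop("require TS >= TD >= 0")
  lines_to_center <- as.integer(lines_to_center)
  if (lines_to_center < 1L) stop("lines_to_center must be >= 1")
  if (any(TE < 0)) stop("TE must be non-negative")
  if (saturation_efficiency < 0 || saturation_efficiency > 1)
    stop("saturation_efficiency must lie in [0, 1]")
  # TS, TD and the echo-train length must agree within rounding of one TR
  implied <- TD + (lines_to_center - 1L) * TR
  if (abs(TS - implied) > TR + 1e-9)
    stop(sprintf(
      "inconsistent timing: TS = %g ms but TD + (lines_to_center - 1) * TR = %g ms",
      TS, implied))
  if (is.null(acquisition_window)) acquisition_window <- lines_to_center * TR * 2
  structure(
    list(flip_angle = flip_angle, TR = TR, TE = TE, TS = TS, TD = TD,
         lines_to_center = lines_to_center, readout = readout,
         acquisition_window = acquisition_window,
         dynamic_interval = dynamic_interval, role = role,
         pd_flip_angle = pd_flip_angle,
         saturation_efficiency = saturation_efficiency, T2 = T2),
    class = "seq_params")
}

#' @export
print.seq_params <- function(x, ...) {
  cat(sprintf(
    "<seq_params> %s %s readout: flip %g deg, TR %g ms, TE %s ms,\n  TS %g ms, TD %g ms, %d lines to k-space centre, sat. efficiency %g\n",
    x$role, x$readout, x$flip_angle, paste(x$TE, collapse = "/"),
    x$TS, x$TD, x$lines_to_center, x$saturation_efficiency))
  invisible(x)
}

#' Gadolinium-based contrast agent properties
#'
#' @param name agent name, recorded in study metadata.
#' @param r1 longitudinal relaxivity in L mmol^-1 s^-1.
#' @param r2_star optional effective transverse relaxivity in L mmol^-1 s^-1.
#' @return an object of class `contrast_agent`.
#' @export
contrast_agent <- function(name = "gadobutrol", r1 = 4.5, r2_star = NULL) {
  if (r1 <= 0) stop("r1 must be positive")
  structure(list(name = name, r1 = r1, r2_star = r2_star),
            class = "contrast_agent")
}

#' Quantification configuration
#'
#' Fixed baseline T1 values, hematocrit, tissue density and contrast agent
#' used throughout signal conversion and kinetic modelling. Fixed
#' population-level baseline T1 values are used rather than per-patient
#' measurements; the defaults correspond to 3T-like settings and are
#' deliberately overridable.
#'
#' @param T1_0_blood baseline (native) blood T1 in ms.
#' @param T1_0_myo baseline myocardial T1 in ms.
#' @param hematocrit hematocrit fraction in (0, 1), used to convert blood to
#'   plasma concentration.
#' @param tissue_density myocardial density in g/mL, used to express flows
#'   per gram of tissue.
#' @param agent a [contrast_agent()].
#' @param flow_convention report myocardial blood flow as whole-blood flow
#'   (`"blood"`, i.e. Fp / (1 - Hct)) or as plasma flow (`"plasma"`).
#' @return an object of class `quant_config`.
#' @export
quant_config <- function(T1_0_blood = 1600, T1_0_myo = 1200,
                         hematocrit = 0.42, tissue_density = 1.05,
                         agent = contrast_agent(),
                         flow_convention = c("blood", "plasma")) {
  if (T1_0_blood <= 0 || T1_0_myo <= 0) stop("baseline T1 values must be positive")
  if (hematocrit <= 0 || hematocrit >= 1) stop("hematocrit must lie in (0, 1)")
  if (tissue_density <= 0) stop("tissue_density must be positive")
  stopifnot(inherits(agent, "contrast_agent"))
  structure(list(T1_0_blood = T1_0_blood, T1_0_myo = T1_0_myo,
                 hematocrit = hematocrit, tissue_density = tissue_density,
                 agent = agent,
                 flow_convention = match.arg(flow_convention)),
            class = "quant_config")
}

# Longitudinal magnetization just before the k-space-centre readout pulse of a
# spoiled GRE echo train, computed in closed form. After the saturation pulse
# Mz = (1 - eff) * M0; Mz then recovers over TD, and each of the first
# (lines_to_center - 1) readout pulses tips Mz by cos(alpha) followed by TR of
# recovery. The geometric series is summed in closed form; the testthat suite
# checks it against a literal step-by-step recursion.
mz_before_center <- function(T1, seq, M0) {
  eff <- seq$saturation_efficiency
  E_td <- exp(-seq$TD / T1)
  mz <- M0 - (M0 - (1 - eff) * M0) * E_td
  n <- seq$lines_to_center - 1L
  if (n > 0L) {
    ca <- cos(seq$flip_angle * pi / 180)
    E_tr <- exp(-seq$TR / T1)
    a <- ca * E_tr
    b <- M0 * (1 - E_tr)
    mz <- ifelse(abs(1 - a) < 1e-12, mz + n * b,
                 a^n * mz + b * (1 - a^n) / (1 - a))
  }
  mz
}

# On-resonance bSSFP propagation with alternating +/- alpha pulses and an
# alpha/2 catalyst; tracks (Mxy', Mz) with T2 decay of the transverse
# component over each TR. Returns |Mxy| at the centre line.
bssfp_center_signal <- function(T1, seq, M0) {
  eff <- seq$saturation_efficiency
  a <- seq$flip_angle * pi / 180
  E1 <- exp(-seq$TR / T1)
  E2 <- exp(-seq$TR / seq$T2)
  mz <- M0 - (M0 - (1 - eff) * M0) * exp(-seq$TD / T1)
  # alpha/2 preparation half a TR before the first full pulse
  mx <- mz * sin(a / 2)
  mz <- mz * cos(a / 2)
  mx <- mx * exp(-seq$TR / 2 / seq$T2)
  mz <- M0 - (M0 - mz) * exp(-seq$TR / 2 / T1)
  sgn <- 1
  for (i in seq_len(seq$lines_to_center)) {
    th <- sgn * a
    mx_new <- mx * cos(th) + mz * sin(th)
    mz_new <- -mx * sin(th) + mz * cos(th)
    if (i == seq$lines_to_center) return(abs(mx_new))
    mx <- mx_new * E2
    mz <- M0 - (M0 - mz_new) * E1
    sgn <- -sgn
  }
}

#' Saturation-recovery signal at the k-space centre
#'
#' Transverse signal magnitude at the acquisition of the k-space centre line
#' for a saturation-recovery readout, obtained by propagating the longitudinal
#' magnetization through saturation, TD recovery, and the readout pulse train
#' (Bloch simulation; closed-form for spoiled GRE, stepwise for bSSFP).
#'
#' @param T1 longitudinal relaxation time in ms (positive; vectorized).
#' @param seq a [seq_params()] object.
#' @param M0 equilibrium magnetization (arbitrary units).
#' @return signal in the same arbitrary units as `M0`.
#' @export
#' @examples
#' s <- seq_params(10, TR = 2.5, TS = 100, TD = 5, lines_to_center = 40)
#' sr_gre_signal(1000, s)
sr_gre_signal <- function(T1, seq, M0 = 1) {
  stopifnot(inherits(seq, "seq_params"))
  if (any(T1 <= 0)) stop("T1 must be positive")
  if (seq$readout == "bSSFP")
    return(vapply(T1, bssfp_center_signal, numeric(1), seq = seq, M0 = M0))
  sa <- sin(seq$flip_angle * pi / 180)
  sa * mz_before_center(T1, seq, M0)
}

# Signal of the unsaturated PD-weighted readout (saturation efficiency 0,
# low flip angle), used as the M0 reference in conversion.
pd_reference_signal <- function(T1, seq, M0 = 1) {
  pd_seq <- seq
  pd_seq$saturation_efficiency <- 0
  pd_seq$flip_angle <- seq$pd_flip_angle
  sr_gre_signal(T1, pd_seq, M0)
}

#' Build a Bloch-simulated signal dictionary
#'
#' Tabulates the saturation-recovery signal over a T1 grid so that measured
#' signal intensities can be inverted to T1 by interpolation (a look-up table
#' of pre-computed signal/T1 combinations).
#'
#' @param seq a [seq_params()] object.
#' @param T1_range T1 interval in ms, within (0, 5000].
#' @param step grid step in ms.
#' @param M0 reference magnetization for the tabulated signals.
#' @return an object of class `signal_dictionary` with fields `T1_grid`,
#'   `signal_grid`, `seq`, `M0_reference`.
#' @export
build_dictionary <- function(seq, T1_range = c(50, 3000), step = 1, M0 = 1) {
  stopifnot(inherits(seq, "seq_params"))
  if (step <= 0) stop("step must be positive")
  if (T1_range[1] <= 0 || T1_range[2] > 5000 || T1_range[1] >= T1_range[2])
    stop("T1_range must be an ascending interval within (0, 5000] ms")
  T1_grid <- seq.int(0L, ceiling((T1_range[2] - T1_range[1]) / step)) * step +
    T1_range[1]
  signal_grid <- sr_gre_signal(T1_grid, seq, M0)
  if (any(diff(signal_grid) >= 0))
    stop("dictionary signal is not strictly monotone decreasing in T1; ",
         "inversion would be ambiguous for these sequence settings")
  structure(list(T1_grid = T1_grid, signal_grid = signal_grid, seq = seq,
                 M0_reference = M0),
            class = "signal_dictionary")
}

#' Invert signal intensities through a dictionary
#'
#' Linear interpolation of the (signal, T1) table. Signals outside the
#' tabulated range are clamped to the nearest end and flagged rather than
#' extrapolated.
#'
#' @param dict a [build_dictionary()] result.
#' @param signal measured signal values on the dictionary's `M0_reference`
#'   scale (vectorized).
#' @return list with `T1` (ms) and logical `clamped` per input value.
#' @export
dict_invert <- function(dict, signal) {
  stopifnot(inherits(dict, "signal_dictionary"))
  lo <- min(dict$signal_grid)  # signal at the longest T1
  hi <- max(dict$signal_grid)
  clamped <- signal < lo | signal > hi
  s <- pmin(pmax(signal, lo), hi)
  T1 <- stats::approx(x = rev(dict$signal_grid), y = rev(dict$T1_grid),
                      xout = s, ties = "ordered")$y
  list(T1 = T1, clamped = clamped)
}

#' Convert a dynamic series to contrast-agent concentration
#'
#' Per pixel and frame the saturation-recovery signal is normalized by the
#' PD-derived M0, inverted to T1 through the dictionary, and converted to
#' concentration with the fast-exchange relaxivity relation
#' CA = (1/T1 - 1/T1_0) / r1 (T1 in seconds, CA in mmol/L). Because both the
#' SR and PD frames are scaled by the same coil sensitivity, the per-pixel PD
#' normalization also removes coil bias.
#'
#' @param series a `dynamic_series` (see [phantom_study()] / [read_study()]).
#' @param pd_reference PD reference image; default the mean of the series' PD
#'   frames (`pd_mode = "pixelwise"`), or a second-order polynomial surface
#'   fitted to it (`pd_mode = "surface"`). Both are exposed; neither is
#'   privileged.
#' @param config a [quant_config()].
#' @param dict optional [build_dictionary()] result; built from `series$seq`
#'   when omitted.
#' @param T1_0 baseline T1 in ms; defaults to the blood or myocardial value in
#'   `config` according to `series$seq$role`.
#' @param pd_mode `"pixelwise"` or `"surface"` M0 normalization.
#' @return list with `concentration` (x,y,frame array over the SR frames, in
#'   mmol/L), `times` (s, SR frames), `T1` (ms array), `clamped_fraction`
#'   (per-frame fraction of pixels clamped at the dictionary range, a QC
#'   quantity) and `negative_ca` (logical array flag; negative concentrations
#'   are flagged, never clipped).
#' @export
si_to_concentration <- function(series, pd_reference = NULL, config = quant_config(),
                                dict = NULL, T1_0 = NULL,
                                pd_mode = c("pixelwise", "surface")) {
  stopifnot(inherits(series, "dynamic_series"), inherits(config, "quant_config"))
  pd_mode <- match.arg(pd_mode)
  if (is.null(dict)) dict <- build_dictionary(series$seq)
  if (is.null(T1_0))
    T1_0 <- if (series$seq$role == "AIF") config$T1_0_blood else config$T1_0_myo
  pd_idx <- which(series$frame_roles == "PD")
  if (is.null(pd_reference)) {
    if (!length(pd_idx)) stop("no PD frames and no pd_reference supplied")
    pd_reference <- frame_mean(series$frames, pd_idx)
  }
  if (pd_mode == "surface") pd_reference <- fit_poly_surface(pd_reference)$surface
  if (all(pd_reference == 0)) stop("PD reference is identically zero")
  # M0 per pixel from the PD signal model at the dictionary's M0 reference
  pd_unit <- pd_reference_signal(T1_0, series$seq, dict$M0_reference)
  M0 <- pd_reference / pd_unit
  M0[M0 <= 0] <- NA_real_
  sr_idx <- which(series$frame_roles == "SR")
  si <- series$frames[, , sr_idx, drop = FALSE]
  norm <- sweep(si, c(1, 2), M0, "/")
  inv <- dict_invert(dict, as.vector(norm))
  T1 <- array(inv$T1, dim = dim(si))
  clamped <- array(inv$clamped, dim = dim(si))
  ca <- (1000 / T1 - 1000 / T1_0) / config$agent$r1
  list(concentration = ca,
       times = series$trigger_times[sr_idx] / 1000,
       T1 = T1,
       clamped_fraction = apply(clamped, 3, mean, na.rm = TRUE),
       negative_ca = ca < 0)
}

#' Concentration from a measured T1 (relaxivity relation)
#'
#' @param T1 measured T1 in ms.
#' @param T1_0 baseline T1 in ms.
#' @param r1 relaxivity in L mmol^-1 s^-1.
#' @return concentration in mmol/L.
#' @export
#' @examples
#' concentration_from_t1(400, 1600, 4.5)  # 0.4167 mmol/L
concentration_from_t1 <- function(T1, T1_0, r1) {
  (1000 / T1 - 1000 / T1_0) / r1
}

#' T2* correction from a multi-echo readout
#'
#' Log-linear least-squares fit of S(TE) = S0 exp(-TE/T2*). With two echoes
#' the fit is exact. If the signal does not decay with TE, T2* is reported as
#' infinite with `flat = TRUE` and S0 as the mean signal.
#'
#' @param signals positive signal magnitudes, one per echo.
#' @param TEs echo times in ms (distinct, same length as `signals`).
#' @return list with `S0`, `T2star` (ms, possibly `Inf`), `flat` flag, and
#'   `residual` (RSS of the log-linear fit).
#' @export
t2star_correct <- function(signals, TEs) {
  if (length(signals) < 2 || length(signals) != length(TEs))
    stop("need >= 2 echoes with matching TEs")
  if (anyDuplicated(TEs)) stop("TEs must be distinct")
  if (any(signals <= 0)) stop("signals must be positive")
  fit <- stats::lm.fit(cbind(1, -TEs), log(signals))
  slope <- fit$coefficients[2]
  if (slope <= 0) {
    return(list(S0 = mean(signals), T2star = Inf, flat = TRUE,
                residual = sum((signals - mean(signals))^2)))
  }
  list(S0 = unname(exp(fit$coefficients[1])), T2star = unname(1 / slope),
       flat = FALSE, residual = sum(fit$residuals^2))
}
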