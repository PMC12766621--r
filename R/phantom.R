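#' Digital perfusion phantom specification
#'
#' Geometry, kinetics, bolus shape, acquisition schedule and corruption
#' parameters for a synthetic dual-sequence first-pass perfusion study with
#' known ground truth. Defaults describe a stress study in the
#' signal-nonlinearity regime: a compact gamma-variate bolus peaking at
#' 4 mmol/L in blood, three short-axis slices, one frame per 1000-ms RR
#' interval, and two unsaturated PD lead-in frames.
#'
#' @param matrix image matrix size in pixels (square).
#' @param n_slices number of short-axis slices (base, mid, apex order).
#' @param center annulus centre in pixels `c(x, y)`; default image centre.
#' @param r_inner,r_outer endocardial / epicardial radii in pixels (scalar or
#'   per slice).
#' @param r_blood LV blood-pool disk radius in pixels.
#' @param region_kinetics list of sector definitions, each a list with
#'   `angles = c(from, to)` in degrees (counterclockwise from the RV-insertion
#'   direction) and `params = kinetic_params(...)`. Pixels not covered by any
#'   sector use `base_kinetics`.
#' @param base_kinetics default [kinetic_params()] for the myocardium.
#' @param tissue_model forward model generating the tissue response.
#' @param aif_peak,aif_onset,aif_alpha,aif_beta gamma-variate bolus: peak
#'   concentration (mmol/L), onset (s), shape alpha, scale beta (s).
#' @param recirc_fraction,recirc_delay recirculation bump: fraction of the
#'   first-pass amplitude and delay in seconds (0 disables it).
#' @param n_pd_frames number of PD-weighted lead-in frames, in 1..4.
#' @param n_frames total number of frames (PD + SR).
#' @param rr_schedule RR intervals in ms, one per frame gap; recycled.
#'   Irregular schedules (missed beats) are allowed.
#' @param noise_sd Rician noise level as a fraction of the PD signal (additive
#'   Gaussian on two complex channels before the magnitude).
#' @param coil_bias second-order polynomial coefficients
#'   `c(1, x, y, x^2, x*y, y^2)` on normalized coordinates in [-1, 1];
#'   `NULL` disables coil bias.
#' @param baseline_offset additive pre-contrast signal offset (a.u.).
#' @param residual_ca_blood remnant contrast concentration in the blood pool
#'   before the bolus (mmol/L), emulating an insufficient delay after a
#'   previous injection.
#' @param motion per-frame in-plane translation, an `n_frames x 2` matrix in
#'   pixels, or `NULL` for a motion-free study.
#' @param rv_angle image-plane angle (degrees) of the anterior RV insertion
#'   point used for AHA segmentation of the ground truth.
#' @param seed integer seed making the rendered study reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix = 96, n_slices = 3, center = NULL,
                         r_inner = NULL, r_outer = NULL, r_blood = NULL,
                         region_kinetics = list(),
                         base_kinetics = kinetic_params(),
                         tissue_model = c("2cxm", "one_compartment", "fermi",
                                          "kety_tofts"),
                         aif_peak = 4, aif_onset = 8, aif_alpha = 3,
                         aif_beta = 1.5,
                         recirc_fraction = 0, recirc_delay = 20,
                         n_pd_frames = 2, n_frames = 60,
                         rr_schedule = 1000,
                         noise_sd = 0, coil_bias = NULL, baseline_offset = 0,
                         residual_ca_blood = 0, motion = NULL,
                         rv_angle = 90, seed = 1L) {
  tissue_model <- match.arg(tissue_model)
  if (n_pd_frames < 1 || n_pd_frames > 4)
    stop("n_pd_frames must lie in 1..4")
  center <- center %||% rep((matrix + 1) / 2, 2)
  r_outer <- r_outer %||% round(matrix * c(0.24, 0.22, 0.18)[pmin(seq_len(n_slices), 3)])
  r_inner <- r_inner %||% round(r_outer * 0.62)
  r_blood <- r_blood %||% round(min(r_inner) * 0.72)
  if (length(r_outer) == 1) r_outer <- rep(r_outer, n_slices)
  if (length(r_inner) == 1) r_inner <- rep(r_inner, n_slices)
  if (any(r_inner >= r_outer)) stop("r_inner must be smaller than r_outer")
  if (max(r_outer) + max(abs(motion %||% 0)) > matrix / 2 - 1)
    stop("phantom geometry exceeds the image matrix")
  if (aif_alpha <= 0 || aif_beta <= 0) stop("gamma-variate parameters must be positive")
  structure(list(matrix = as.integer(matrix), n_slices = as.integer(n_slices),
                 center = center, r_inner = r_inner, r_outer = r_outer,
                 r_blood = r_blood, region_kinetics = region_kinetics,
                 base_kinetics = base_kinetics, tissue_model = tissue_model,
                 aif_peak = aif_peak, aif_onset = aif_onset,
                 aif_alpha = aif_alpha, aif_beta = aif_beta,
                 recirc_fraction = recirc_fraction, recirc_delay = recirc_delay,
                 n_pd_frames = as.integer(n_pd_frames),
                 n_frames = as.integer(n_frames),
                 rr_schedule = rr_schedule, noise_sd = noise_sd,
                 coil_bias = coil_bias, baseline_offset = baseline_offset,
                 residual_ca_blood = residual_ca_blood, motion = motion,
                 rv_angle = rv_angle, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Gamma-variate arterial input function
#'
#' A peaked first-pass bolus, zero before onset, with an optional delayed and
#' scaled recirculation copy. The curve is normalized so that its first-pass
#' peak equals `peak`, attained at `onset + alpha * beta`.
#'
#' @param times sample times in seconds (ascending; may be non-uniform).
#' @param peak peak concentration in mmol/L.
#' @param onset bolus arrival time in seconds.
#' @param alpha,beta gamma-variate shape and scale (both positive).
#' @param recirc_fraction,recirc_delay recirculation amplitude fraction and
#'   delay in seconds.
#' @return concentration values in mmol/L, one per time.
#' @export
generate_aif <- function(times, peak = 4, onset = 8, alpha = 3, beta = 1.5,
                         recirc_fraction = 0, recirc_delay = 20) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (is.unsorted(times)) stop("times must be ascending")
  gv <- function(t) {
    s <- pmax(t - onset, 0)
    ((s / (alpha * beta))^alpha) * exp(alpha - s / beta) * (t > onset)
  }
  ca <- peak * gv(times)
  if (recirc_fraction > 0)
    ca <- ca + recirc_fraction * peak * gv(times - recirc_delay)
  ca
}

#' Forward tissue response by causal convolution
#'
#' Evaluates C_myo(t) = F_p (R * C_aif)(t) on the sampling grid, oversampling
#' internally (linear interpolation of the AIF, exact residue evaluation) so
#' the quadrature error stays well below the model signal.
#'
#' @param aif arterial (plasma) concentration values at `times`, mmol/L.
#' @param params a [kinetic_params()] set.
#' @param model residue model, see [residue_function()].
#' @param times sample times in seconds (matching `aif`).
#' @param oversample internal grid refinement factor.
#' @return tissue concentration at `times` (mmol/L).
#' @export
forward_tissue <- function(aif, params, model = "2cxm", times,
                           oversample = 10) {
  if (length(aif) != length(times)) stop("aif and times must match")
  if (params$F_p < 0) stop("negative F_p")
  if (params$F_p == 0) return(numeric(length(times)))
  tt <- times - times[1]
  fine <- seq(0, tt[length(tt)], by = stats::median(diff(tt)) / oversample)
  ca <- interp_curve(tt, aif, fine)
  r <- residue_function(fine, params, model)
  conv <- conv_uniform(r, ca, fine[2] - fine[1])
  (params$F_p / 60) * interp_curve(fine, conv, tt)
}

# Pixel geometry helpers -----------------------------------------------------

pixel_grid <- function(n, center) {
  x <- matrix(seq_len(n), n, n) - center[1]
  y <- matrix(seq_len(n), n, n, byrow = TRUE) - center[2]
  list(x = x, y = y, r = sqrt(x^2 + y^2),
       theta = (atan2(y, x) * 180 / pi) %% 360)
}

coil_bias_field <- function(n, coefs) {
  if (is.null(coefs)) return(matrix(1, n, n))
  u <- matrix(seq(-1, 1, length.out = n), n, n)
  v <- t(u)
  coefs <- c(coefs, rep(0, 6 - length(coefs)))
  coefs[1] + coefs[2] * u + coefs[3] * v + coefs[4] * u^2 +
    coefs[5] * u * v + coefs[6] * v^2
}

phantom_masks <- function(spec, slice) {
  g <- pixel_grid(spec$matrix, spec$center)
  blood <- g$r <= spec$r_blood
  myo <- g$r >= spec$r_inner[slice] & g$r <= spec$r_outer[slice]
  # asymmetric anatomy: RV blood-pool crescent and a bright chest-wall band;
  # real short-axis frames are not rotationally symmetric, and in-plane
  # registration is only well-posed because of such static structure
  rv_c <- spec$center - c(1.45 * spec$r_outer[slice], 0)
  rv_r <- sqrt((g$x + 1.45 * spec$r_outer[slice])^2 + g$y^2)
  rv <- rv_r <= 0.75 * spec$r_outer[slice] & !myo & !blood
  band_rows <- seq(max(1, round(spec$matrix * 0.06)),
                   max(2, round(spec$matrix * 0.12)))
  band_cols <- seq(round(spec$matrix * 0.15), round(spec$matrix * 0.72))
  chest <- matrix(FALSE, spec$matrix, spec$matrix)
  chest[band_rows, band_cols] <- TRUE
  # liver-like blob in the lower-right quadrant
  lx <- spec$matrix * 0.80; ly <- spec$matrix * 0.76
  liver <- sqrt((g$x + spec$center[1] - lx)^2 +
                (g$y + spec$center[2] - ly)^2) <= spec$matrix * 0.14
  chest <- chest & !myo & !blood & !rv
  liver <- liver & !myo & !blood & !rv & !chest
  region <- matrix(0L, spec$matrix, spec$matrix)
  ang <- (g$theta - spec$rv_angle) %% 360
  if (length(spec$region_kinetics))
    for (i in seq_along(spec$region_kinetics)) {
      a <- spec$region_kinetics[[i]]$angles %% 360
      inside <- if (a[1] <= a[2]) ang >= a[1] & ang < a[2] else ang >= a[1] | ang < a[2]
      region[myo & inside] <- i
    }
  list(blood = blood, myo = myo, rv = rv, chest = chest, liver = liver,
       region = region, grid = g)
}

phantom_frame_times <- function(spec) {
  rr <- rep_len(spec$rr_schedule, spec$n_frames - 1L)
  c(0, cumsum(rr))
}

# Ground-truth concentration curves for every tissue class in a spec.
phantom_truth_curves <- function(spec, config) {
  times <- phantom_frame_times(spec) / 1000
  sr <- seq.int(spec$n_pd_frames + 1L, spec$n_frames)
  t_sr <- times[sr]
  aif <- generate_aif(t_sr, spec$aif_peak, spec$aif_onset, spec$aif_alpha,
                      spec$aif_beta, spec$recirc_fraction, spec$recirc_delay)
  aif_blood <- aif + spec$residual_ca_blood
  aif_plasma <- aif / (1 - config$hematocrit)
  params_list <- c(list(spec$base_kinetics),
                   lapply(spec$region_kinetics, `[[`, "params"))
  tissue <- lapply(params_list, function(p)
    forward_tissue(aif_plasma, p, spec$tissue_model, t_sr))
  list(times = times, t_sr = t_sr, sr_frames = sr, aif = aif,
       aif_blood = aif_blood, aif_plasma = aif_plasma,
       tissue = tissue, params_list = params_list)
}

scale_spec <- function(spec, n) {
  sub <- spec
  sub$matrix <- as.integer(n)
  sub$center <- spec$center * n / spec$matrix
  sub$r_inner <- spec$r_inner * n / spec$matrix
  sub$r_outer <- spec$r_outer * n / spec$matrix
  sub$r_blood <- spec$r_blood * n / spec$matrix
  sub
}

render_series <- function(spec, seq, config, truth, lowres = FALSE) {
  n <- spec$matrix
  if (lowres) n <- as.integer(n / 2)
  sub <- scale_spec(spec, n)
  bias <- coil_bias_field(n, spec$coil_bias)
  T1_0_b <- config$T1_0_blood
  T1_0_m <- config$T1_0_myo
  r1 <- config$agent$r1
  dict_T1 <- function(T1_0, ca) 1 / (1 / T1_0 + r1 * ca / 1000)
  n_frames <- spec$n_frames
  slices <- if (seq$role == "AIF") 1L else seq_len(spec$n_slices)
  out <- vector("list", length(slices))
  M0 <- 100
  for (s in seq_along(slices)) {
    masks <- phantom_masks(sub, slices[s])
    frames <- array(0, dim = c(n, n, n_frames))
    bg_T1 <- 900  # static background tissue
    for (f in seq_len(n_frames)) {
      img <- matrix(0, n, n)
      is_pd <- f <= spec$n_pd_frames
      k <- f - spec$n_pd_frames  # SR frame counter
      ca_b <- if (is_pd) spec$residual_ca_blood else truth$aif_blood[k]
      sig <- function(T1, m0 = M0)
        if (is_pd) pd_reference_signal(T1, seq, m0) else sr_gre_signal(T1, seq, m0)
      img[!masks$blood & !masks$myo] <- sig(bg_T1)
      img[masks$rv] <- sig(dict_T1(T1_0_b, ca_b))
      img[masks$chest] <- sig(300, 1.3 * M0)  # fat-like: short T1, high PD
      img[masks$liver] <- sig(600, 1.15 * M0)
      img[masks$blood] <- sig(dict_T1(T1_0_b, ca_b))
      for (ri in 0:length(spec$region_kinetics)) {
        m <- masks$myo & masks$region == ri
        if (!any(m)) next
        ca_t <- if (is_pd) 0 else truth$tissue[[ri + 1L]][k]
        img[m] <- sig(dict_T1(T1_0_m, ca_t))
      }
      # anatomy moves; the coil sensitivity pattern stays fixed in space
      if (!is.null(spec$motion)) {
        v <- spec$motion[f, ] * n / spec$matrix
        if (any(v != 0)) img <- shift_image(img, v)
      }
      img <- img * bias + spec$baseline_offset
      if (spec$noise_sd > 0) {
        # Rician-like: Gaussian on two complex channels, SD as a fraction of
        # the PD-weighted myocardial signal
        sd <- spec$noise_sd * pd_reference_signal(config$T1_0_myo, seq, M0)
        img <- sqrt((img + stats::rnorm(n * n, 0, sd))^2 +
                    stats::rnorm(n * n, 0, sd)^2)
      }
      frames[, , f] <- img
    }
    out[[s]] <- dynamic_series(
      frames = frames, trigger_times = phantom_frame_times(spec),
      frame_roles = c(rep("PD", spec$n_pd_frames),
                      rep("SR", n_frames - spec$n_pd_frames)),
      pixel_spacing = if (lowres) 5 else 2.5,
      slice_location = (slices[s] - 1) * 10, seq = seq)
  }
  out
}

#' Render a synthetic perfusion study
#'
#' Renders a dual-sequence stress or rest study from a [phantom_spec()]:
#' high-resolution myocardial slices plus a low-resolution short-TS AIF
#' series, with PD lead-in frames, coil bias, Rician noise, in-plane motion
#' and the full ground truth (concentration curves, kinetic maps, motion and
#' arrival times). The same seed produces an identical study.
#'
#' @param spec a [phantom_spec()].
#' @param seq_myo myocardial [seq_params()]; the phantom refuses
#'   protocol-violating parameters (TS > 130 ms; AIF TS >= 30 ms) unless
#'   `noncompliant = TRUE`.
#' @param seq_aif AIF-series [seq_params()].
#' @param config a [quant_config()].
#' @param condition `"stress"` or `"rest"` (metadata only; kinetics come from
#'   `spec`).
#' @param seed overrides `spec$seed`.
#' @param noncompliant allow protocol-violating sequence parameters, for
#'   exercising the protocol validator.
#' @return an object of class `study_bundle`: `myocardial` (list of
#'   `dynamic_series` per slice), `aif_series`, `ground_truth`, `condition`.
#' @export
phantom_study <- function(spec = phantom_spec(),
                          seq_myo = default_seq_myo(),
                          seq_aif = default_seq_aif(),
                          config = quant_config(),
                          condition = c("stress", "rest"),
                          seed = NULL, noncompliant = FALSE) {
  condition <- match.arg(condition)
  stopifnot(inherits(spec, "phantom_spec"))
  if (!noncompliant) {
    if (seq_myo$TS > 130)
      stop("myocardial TS exceeds 130 ms; use noncompliant = TRUE to force")
    if (seq_aif$TS >= 30)
      stop("AIF TS must be < 30 ms; use noncompliant = TRUE to force")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %||% spec$seed)
  truth <- phantom_truth_curves(spec, config)
  myo <- render_series(spec, seq_myo, config, truth, lowres = FALSE)
  aif <- render_series(spec, seq_aif, config, truth, lowres = TRUE)[[1]]
  masks <- lapply(seq_len(spec$n_slices), function(s) phantom_masks(spec, s))
  mbf_maps <- lapply(seq_len(spec$n_slices), function(s) {
    m <- matrix(NA_real_, spec$matrix, spec$matrix)
    for (ri in 0:length(spec$region_kinetics)) {
      sel <- masks[[s]]$myo & masks[[s]]$region == ri
      m[sel] <- truth$params_list[[ri + 1L]]$F_p
    }
    m
  })
  structure(list(
    myocardial = myo, aif_series = aif,
    ground_truth = list(
      times = truth$times, t_sr = truth$t_sr, sr_frames = truth$sr_frames,
      aif = truth$aif, aif_blood = truth$aif_blood,
      aif_plasma = truth$aif_plasma,
      tissue = truth$tissue, params = truth$params_list,
      fp_maps = mbf_maps,
      myo_masks = lapply(masks, `[[`, "myo"),
      blood_mask = masks[[1]]$blood,
      aif_blood_mask = phantom_masks(scale_spec(spec, spec$matrix / 2), 1)$blood,
      region_masks = lapply(masks, `[[`, "region"),
      arrival_time = spec$aif_onset,
      motion = spec$motion, spec = spec, config = config),
    condition = condition), class = "study_bundle")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default dual-sequence acquisition parameters
#'
#' A compliant high-resolution myocardial readout (TS 102.5 ms) and a
#' low-resolution short-TS AIF readout (TS 22.5 ms), both spoiled GRE with
#' linear ordering.
#' @return a [seq_params()] object.
#' @export
default_seq_myo <- function() {
  seq_params(flip_angle = 10, TR = 2.5, TE = 1.2, TS = 102.5, TD = 5,
             lines_to_center = 40, readout = "GRE", acquisition_window = 100,
             role = "myocardial")
}

#' @rdname default_seq_myo
#' @export
default_seq_aif <- function() {
  seq_params(flip_angle = 8, TR = 2.2, TE = 0.7, TS = 22.5, TD = 5,
             lines_to_center = 9, readout = "GRE", acquisition_window = 40,
             role = "AIF")
}

#' Dynamic image series
#'
#' @param frames numeric array `x * y * frame`, time-ordered.
#' @param trigger_times frame trigger times in ms, strictly increasing.
#' @param frame_roles character vector of `"PD"` / `"SR"` per frame.
#' @param pixel_spacing in-plane pixel spacing in mm.
#' @param slice_location slice position in mm.
#' @param seq the [seq_params()] the frames were acquired with.
#' @return an object of class `dynamic_series`.
#' @export
dynamic_series <- function(frames, trigger_times, frame_roles, pixel_spacing,
                           slice_location = 0, seq) {
  stopifnot(length(dim(frames)) == 3,
            dim(frames)[3] == length(trigger_times),
            length(frame_roles) == length(trigger_times))
  if (any(diff(trigger_times) <= 0)) stop("trigger_times must be strictly increasing")
  structure(list(frames = frames, trigger_times = trigger_times,
                 frame_roles = frame_roles, pixel_spacing = pixel_spacing,
                 slice_location = slice_location, seq = seq),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dynamic_series> %dx%d, %d frames (%d PD), %s role, %.1f mm spacing\n",
              d[1], d[2], d[3], sum(x$frame_roles == "PD"), x$seq$role,
              x$pixel_spacing))
  invisible(x)
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %s: %d myocardial slice(s) + AIF series (%s)\n",
              x$condition, length(x$myocardial),
              paste(dim(x$aif_series$frames), collapse = "x")))
  invisible(x)
}
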