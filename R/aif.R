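#' Detect the LV blood pool
#'
#' Computes the temporal standard-deviation map of the SR frames, thresholds
#' it (Otsu), ranks the connected enhancing regions by earliest arrival and
#' peak amplitude, and erodes the winning region by one pixel so that
#' papillary muscles and endocardial border pixels are excluded.
#'
#' @param series a motion-corrected `dynamic_series`.
#' @param min_area minimum candidate area in pixels.
#' @return logical blood-pool mask.
#' @export
detect_lv <- function(series, min_area = 9) {
  stop_if_not_series(series)
  sr <- which(series$frame_roles == "SR")
  stack <- series$frames[, , sr, drop = FALSE]
  sdmap <- apply(stack, c(1, 2), stats::sd)
  if (max(sdmap) <= 1e-9) stop("no LV candidate: series has no enhancing region")
  thr <- EBImage::otsu(sdmap / max(sdmap))
  bw <- sdmap / max(sdmap) > thr
  lab <- EBImage::bwlabel(bw)
  ids <- setdiff(unique(as.vector(lab)), 0)
  ids <- ids[vapply(ids, function(i) sum(lab == i), numeric(1)) >= min_area]
  if (!length(ids)) stop("no LV candidate: no enhancing region above threshold")
  t_sr <- series$trigger_times[sr] / 1000
  score <- vapply(ids, function(i) {
    m <- lab == i
    curve <- apply(stack, 3, function(fr) mean(fr[m]))
    curve <- curve - min(curve)
    peak <- max(curve)
    half <- which(curve >= peak / 2)[1]
    # earlier arrival and higher amplitude both favour the blood pool
    peak / max(t_sr[half], 1e-3)
  }, numeric(1))
  # among near-maximal candidates (LV and RV both enhance early and
  # strongly) prefer the one closest to the image centre, where the LV sits
  # in a short-axis perfusion acquisition
  near <- ids[score >= 0.6 * max(score)]
  ctr <- (dim(stack)[1:2] + 1) / 2
  d2 <- vapply(near, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    sum((colMeans(w) - ctr)^2)
  }, numeric(1))
  win <- near[which.min(d2)]
  mask <- lab == win
  kern <- EBImage::makeBrush(3, shape = "box")
  mask <- as.matrix(EBImage::erode(mask * 1, kern)) > 0.5
  if (!any(mask)) stop("no LV candidate: winning region vanished under erosion")
  mask
}

#' Extract the arterial input function over a mask
#'
#' Per-frame mean over the blood-pool mask (SR frames only; PD frames are
#' used upstream for normalization, not in the curve). A mixed-curve detector
#' flags probable contamination: if the per-pixel peak times inside the mask
#' are heterogeneous (late-peaking myocardial or border pixels mixed with
#' blood), a QC flag is raised.
#'
#' @param series a `dynamic_series`.
#' @param mask non-empty logical matrix.
#' @return list of class `concentration_curve`: `times` (s), `values` (a.u.
#'   or mmol/L), `role = "aif_blood"`, `flags`.
#' @export
extract_aif <- function(series, mask) {
  stop_if_not_series(series)
  if (!any(mask)) stop("empty AIF mask")
  sr <- which(series$frame_roles == "SR")
  stack <- series$frames[, , sr, drop = FALSE]
  values <- apply(stack, 3, function(fr) mean(fr[mask]))
  flags <- character()
  if (sum(mask) >= 4) {
    px <- matrix(stack, ncol = length(sr))[as.vector(mask), , drop = FALSE]
    pk <- apply(px, 1, which.max)
    if (mean(abs(pk - stats::median(pk)) > 3) > 0.1)
      flags <- "possible contamination: heterogeneous peak times inside AIF mask"
  }
  structure(list(times = series$trigger_times[sr] / 1000, values = values,
                 role = "aif_blood", arrival_index = NULL, flags = flags),
            class = "concentration_curve")
}

#' Detect tracer arrival in a curve
#'
#' Two detectors. `triangle`: on the peak-normalized curve, the foot is the
#' sample of maximal perpendicular distance from the chord joining the first
#' sample to the peak; the arrival is the first sample after the foot where
#' the curve rises above the foot value. `upslope_line`: a line is fitted to
#' the 20-80%-of-peak upslope samples and intersected with zero; the arrival
#' is the first sample at/after the intersection.
#'
#' The curve must be baseline-corrected; a flat curve (peak below 3 baseline
#' standard deviations) raises "no bolus detected".
#'
#' @param curve numeric values, or a `concentration_curve`.
#' @param times sample times in seconds (ignored when `curve` carries them).
#' @param method `"triangle"` or `"upslope_line"`.
#' @return list of class `arrival_estimate`: `index`, `time` (s), `method`,
#'   `confidence` (peak / baseline SD).
#' @export
detect_arrival <- function(curve, times = NULL,
                           method = c("triangle", "upslope_line")) {
  method <- match.arg(method)
  if (inherits(curve, "concentration_curve")) {
    times <- curve$times
    curve <- curve$values
  }
  if (is.null(times)) times <- seq_along(curve) - 1
  n <- length(curve)
  if (n < 5) stop("need at least 5 samples")
  pk <- which.max(curve)
  base_n <- max(3, floor(pk / 3))
  base_sd <- stats::sd(curve[seq_len(base_n)])
  peak <- curve[pk]
  if (!is.finite(peak) || peak <= 3 * max(base_sd, 1e-12) || pk == 1)
    stop("no bolus detected")
  if (method == "triangle") {
    # normalize both axes so the detection is amplitude- and scale-invariant
    x <- (times - times[1]) / (times[pk] - times[1])
    y <- curve / peak
    seg <- seq_len(pk)
    dx <- x[pk] - x[1]; dy <- y[pk] - y[1]
    dist <- abs(dx * (y[seg] - y[1]) - dy * (x[seg] - x[1])) / sqrt(dx^2 + dy^2)
    foot <- seg[which.max(dist)]
    idx <- foot
    while (idx < pk && curve[idx + 1] <= curve[foot] + 1e-12) idx <- idx + 1
    if (idx < pk) idx <- idx + 1
  } else {
    # hug the foot of the upslope: the low band keeps the linearized
    # intersection close to the true arrival on convex bolus fronts
    up <- which(curve >= 0.1 * peak & curve <= 0.5 * peak &
                seq_along(curve) <= pk & seq_along(curve) > 1)
    if (length(up) >= 2) {
      fit <- stats::lm(curve[up] ~ times[up])
      t0 <- -stats::coef(fit)[1] / stats::coef(fit)[2]
      idx <- which(times >= t0)[1]
      if (is.na(idx)) idx <- pk
    } else {
      idx <- which(curve >= 0.5 * peak)[1]
    }
  }
  structure(list(index = as.integer(idx), time = times[idx], method = method,
                 confidence = peak / max(base_sd, 1e-12)),
            class = "arrival_estimate")
}

#' Convert a blood AIF to plasma concentration
#'
#' Divides blood concentration by (1 - hematocrit). Refuses curves that are
#' not blood-role (in particular, curves already converted).
#'
#' @param curve a `concentration_curve` with role `"aif_blood"`.
#' @param config a [quant_config()] carrying the hematocrit.
#' @return the curve with role `"aif_plasma"`.
#' @export
to_plasma <- function(curve, config = quant_config()) {
  if (!inherits(curve, "concentration_curve") || curve$role != "aif_blood")
    stop("to_plasma expects a blood-role concentration curve")
  curve$values <- curve$values / (1 - config$hematocrit)
  curve$role <- "aif_plasma"
  curve
}

#' Assemble a dual-bolus AIF
#'
#' Scales the diluted pre-bolus AIF by 1/dilution and time-shifts it so its
#' arrival coincides with the main-bolus arrival observed in the myocardial
#' series' LV signal; the result serves as the AIF for quantifying the main
#' study.
#'
#' @param prebolus_aif a `concentration_curve` from the diluted pre-bolus.
#' @param main_lv_curve a `concentration_curve` (or numeric values) of the LV
#'   signal during the main bolus.
#' @param main_times times of the main study samples in seconds (when
#'   `main_lv_curve` is numeric).
#' @param dilution pre-bolus dilution fraction, strictly inside (0, 1);
#'   default 0.10 (a 10% dilute pre-bolus of the same volume).
#' @return a `concentration_curve` on the main-study time grid.
#' @export
assemble_dual_bolus <- function(prebolus_aif, main_lv_curve, main_times = NULL,
                                dilution = 0.10) {
  if (dilution <= 0 || dilution >= 1) stop("dilution must lie strictly in (0, 1)")
  stopifnot(inherits(prebolus_aif, "concentration_curve"))
  if (inherits(main_lv_curve, "concentration_curve")) {
    main_times <- main_lv_curve$times
    main_lv_curve <- main_lv_curve$values
  }
  pre_arr <- detect_arrival(prebolus_aif$values, prebolus_aif$times)
  main_arr <- detect_arrival(main_lv_curve, main_times)
  shift <- main_arr$time - pre_arr$time
  values <- interp_curve(prebolus_aif$times + shift,
                         prebolus_aif$values / dilution, main_times)
  structure(list(times = main_times, values = values, role = "aif_blood",
                 arrival_index = main_arr$index,
                 flags = prebolus_aif$flags),
            class = "concentration_curve")
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf("<concentration_curve> %s, %d samples, peak %.3g at %.1f s\n",
              x$role, length(x$values), max(x$values),
              x$times[which.max(x$values)]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Construct a concentration curve
#'
#' @param times sample times in seconds (ascending).
#' @param values concentrations (mmol/L) or signal (a.u.).
#' @param role `"aif_blood"`, `"aif_plasma"` or `"tissue"`.
#' @return a `concentration_curve`.
#' @export
concentration_curve <- function(times, values,
                                role = c("aif_blood", "aif_plasma", "tissue")) {
  if (is.unsorted(times)) stop("times must be ascending")
  if (any(!is.finite(values))) stop("values must be finite")
  structure(list(times = times, values = values, role = match.arg(role),
                 arrival_index = NULL, flags = character()),
            class = "concentration_curve")
}
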