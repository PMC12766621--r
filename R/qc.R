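#' RR-interval check
#'
#' Flags missed or irregular beats: any interval exceeding `factor` times the
#' running median is flagged, and a flag is critical if it falls inside the
#' AIF or myocardial upslope window where a missed beat corrupts
#' quantification.
#'
#' @param trigger_times frame trigger times in ms (>= 5).
#' @param upslope_window optional integer frame-index range `c(from, to)` of
#'   the bolus upslope; flags inside it are marked critical.
#' @param factor missed-beat threshold on the interval / running-median ratio.
#' @return data.frame with one row per flagged interval: `frame` (index of
#'   the late frame), `interval`, `expected`, `critical`; zero rows when the
#'   rhythm is regular.
#' @export
rr_check <- function(trigger_times, upslope_window = NULL, factor = 1.75) {
  if (length(trigger_times) < 5) stop("need at least 5 triggers")
  rr <- diff(trigger_times)
  med <- stats::runmed(rr, k = min(5, length(rr) - (1 - length(rr) %% 2)))
  bad <- which(rr > factor * med)
  out <- data.frame(frame = bad + 1L, interval = rr[bad], expected = med[bad],
                    critical = logical(length(bad)))
  if (!is.null(upslope_window) && nrow(out))
    out$critical <- out$frame >= upslope_window[1] & out$frame <= upslope_window[2]
  out
}

#' AIF curve quality metrics
#'
#' Smoothness (1 - total variation of the residual around a smoothing-spline
#' trend, relative to the curve's total variation), a flat-top saturation
#' flag (>= 3 consecutive near-peak samples within 1% of the peak), and a
#' low-SNR flag (peak / baseline SD below 10). Thresholds are configurable
#' and recorded in the output.
#'
#' @param curve baseline-corrected AIF values (or a `concentration_curve`).
#' @param flat_tol relative flat-top tolerance.
#' @param snr_min minimum acceptable peak/baseline-SD ratio.
#' @return list with `smoothness`, `snr`, `peak`, `saturation_flag`,
#'   `low_snr_flag`, `flags`, `thresholds`.
#' @export
aif_qc <- function(curve, flat_tol = 0.01, snr_min = 10) {
  if (inherits(curve, "concentration_curve")) curve <- curve$values
  n <- length(curve)
  trend <- tryCatch(
    stats::fitted(stats::smooth.spline(seq_len(n), curve)),
    error = function(e) curve)
  resid <- curve - trend
  tv <- function(x) sum(abs(diff(x)))
  smoothness <- 1 - tv(resid) / max(tv(curve), 1e-12)
  pk <- which.max(curve)
  peak <- curve[pk]
  near <- abs(curve - peak) <= flat_tol * peak
  r <- rle(near)
  saturation <- any(r$lengths[r$values] >= 3)
  base_n <- max(3, floor(pk / 3))
  snr <- peak / max(stats::sd(curve[seq_len(base_n)]), 1e-12)
  flags <- character()
  if (saturation) flags <- c(flags, "saturated AIF: flat top at peak")
  if (snr < snr_min) flags <- c(flags, sprintf("low-SNR AIF (%.1f < %g)", snr, snr_min))
  list(smoothness = smoothness, snr = snr, peak = peak,
       saturation_flag = saturation, low_snr_flag = snr < snr_min,
       flags = flags, thresholds = list(flat_tol = flat_tol, snr_min = snr_min))
}

#' Study-level quality control report
#'
#' Computable checks over a complete pipeline run: RR regularity, AIF curve
#' quality, baseline blood-pool enhancement (remnant contrast), residual
#' motion after registration, map-vs-raw wall-thickness agreement, and the
#' per-segment failed-pixel fraction with segment exclusions. Missing inputs
#' yield partial reports with "unverifiable" items, never silent passes.
#'
#' @param study a `study_bundle` (motion/coil corrected series expected).
#' @param map optional `parameter_map` from [quantify_pixelwise()].
#' @param aif_curve optional baseline-corrected AIF `concentration_curve`.
#' @param segments optional `segment_model` for segment-level exclusion.
#' @param lv_mask,myo_mask optional masks for the baseline-enhancement check
#'   (defaults from the phantom ground truth when present).
#' @param thresholds named list overriding the rule thresholds
#'   (`baseline_ratio`, `residual_motion_px`, `wall_ratio`,
#'   `segment_fail_fraction`, plus the [rr_check()] / [aif_qc()] settings).
#' @return list of class `qc_report` with per-rule results, `flags` (each
#'   flag carries a locus and rule id), and `overall`
#'   (`"pass"`, `"review"` or `"fail"`).
#' @export
study_qc <- function(study, map = NULL, aif_curve = NULL, segments = NULL,
                     lv_mask = NULL, myo_mask = NULL, thresholds = list()) {
  th <- utils::modifyList(list(baseline_ratio = 1.2, residual_motion_px = 1,
                               wall_ratio = c(0.7, 1.4),
                               segment_fail_fraction = 0.2,
                               rr_factor = 1.75, flat_tol = 0.01,
                               snr_min = 10), thresholds)
  flags <- list()
  add_flag <- function(rule, locus, msg, critical = FALSE)
    flags[[length(flags) + 1L]] <<- list(rule = rule, locus = locus,
                                         message = msg, critical = critical)
  unverifiable <- character()
  series <- study$myocardial[[1]]
  gt <- study$ground_truth

  # RR intervals
  up <- NULL
  if (!is.null(aif_curve)) {
    arr <- tryCatch(detect_arrival(aif_curve), error = function(e) NULL)
    if (!is.null(arr)) {
      sr <- which(series$frame_roles == "SR")
      pk <- sr[which.max(aif_curve$values)]
      up <- c(sr[arr$index], pk)
    }
  }
  rr <- rr_check(series$trigger_times, upslope_window = up, factor = th$rr_factor)
  if (nrow(rr))
    for (i in seq_len(nrow(rr)))
      add_flag("rr_missed_beat", sprintf("frame %d", rr$frame[i]),
               sprintf("interval %.0f ms vs expected %.0f ms", rr$interval[i],
                       rr$expected[i]), critical = rr$critical[i])

  # AIF metrics
  aif_metrics <- NULL
  if (!is.null(aif_curve)) {
    aif_metrics <- aif_qc(aif_curve, flat_tol = th$flat_tol, snr_min = th$snr_min)
    for (f in aif_metrics$flags) add_flag("aif_quality", "AIF curve", f)
  } else unverifiable <- c(unverifiable, "aif_metrics")

  # Baseline blood-pool enhancement (remnant contrast)
  lv_mask <- lv_mask %||% gt$blood_mask
  myo_mask <- myo_mask %||% gt$myo_masks[[1]]
  baseline_ratio <- NA_real_
  if (!is.null(lv_mask) && !is.null(myo_mask)) {
    sr <- which(series$frame_roles == "SR")
    pre <- tryCatch(pre_contrast_frames(series), error = function(e) sr[1:3])
    base <- frame_mean(series$frames, pre)
    baseline_ratio <- mean(base[lv_mask]) / max(mean(base[myo_mask]), 1e-12)
    if (baseline_ratio > th$baseline_ratio)
      add_flag("baseline_enhancement", "LV blood pool",
               sprintf("pre-contrast LV/myocardium signal ratio %.2f > %.2f: remnant contrast suspected",
                       baseline_ratio, th$baseline_ratio))
  } else unverifiable <- c(unverifiable, "baseline_enhancement")

  # Residual motion after correction
  reg <- register_translation(series)
  resid_motion <- max(sqrt(rowSums(reg$displacements^2)))
  if (resid_motion > th$residual_motion_px)
    add_flag("residual_motion",
             sprintf("frame %d", which.max(sqrt(rowSums(reg$displacements^2)))),
             sprintf("residual frame displacement %.2f px > %g px",
                     resid_motion, th$residual_motion_px))

  # Map vs raw wall thickness
  wall_ratio <- NA_real_
  if (!is.null(map) && !is.null(myo_mask)) {
    map_mask <- map$mask & !is.na(map$mbf)
    wall_ratio <- sum(map_mask) / max(sum(myo_mask), 1)
    if (wall_ratio < th$wall_ratio[1] || wall_ratio > th$wall_ratio[2])
      add_flag("map_shape", "MBF map",
               sprintf("map/raw myocardial area ratio %.2f outside [%.2f, %.2f]",
                       wall_ratio, th$wall_ratio[1], th$wall_ratio[2]))
  } else if (is.null(map)) unverifiable <- c(unverifiable, "map_shape")

  # Per-segment failed-pixel fraction
  segment_exclusions <- integer()
  if (!is.null(map) && !is.null(segments)) {
    sel <- map$mask & !is.na(segments$labels)
    fail <- tapply(map$qc_flags[sel] == 1, segments$labels[sel], mean)
    segment_exclusions <- as.integer(names(fail))[!is.na(fail) &
                                                  fail > th$segment_fail_fraction]
    for (s in segment_exclusions)
      add_flag("segment_exclusion", sprintf("segment %d", s),
               sprintf("failed-pixel fraction %.0f%% > %.0f%%",
                       100 * fail[as.character(s)],
                       100 * th$segment_fail_fraction))
  } else if (is.null(segments)) unverifiable <- c(unverifiable, "segment_exclusions")

  critical <- any(vapply(flags, `[[`, logical(1), "critical"))
  overall <- if (!length(flags)) "pass" else if (critical) "fail" else "review"
  structure(list(rr_flags = rr, aif_metrics = aif_metrics,
                 baseline_ratio = baseline_ratio,
                 residual_motion_px = resid_motion,
                 wall_ratio = wall_ratio,
                 segment_exclusions = segment_exclusions,
                 flags = flags, unverifiable = unverifiable,
                 thresholds = th, overall = overall),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> overall: %s (%d flag(s))\n", x$overall, length(x$flags)))
  for (f in x$flags)
    cat(sprintf("  [%s]%s %s: %s\n", f$rule, if (f$critical) " CRITICAL" else "",
                f$locus, f$message))
  if (length(x$unverifiable))
    cat("  unverifiable:", paste(x$unverifiable, collapse = ", "), "\n")
  invisible(x)
}
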