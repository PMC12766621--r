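#' Pixel-wise perfusion quantification
#'
#' Fits the chosen kinetic model to every masked myocardial pixel of a
#' converted slice, with an optional arrival-time search per pixel, and
#' returns MBF, tracer-arrival and residual maps. Failed pixels are flagged,
#' never silently filled.
#'
#' @param concentration `x * y * time` array of myocardial concentration
#'   (mmol/L), baseline-corrected.
#' @param times sample times in seconds.
#' @param aif_plasma plasma AIF values on the same grid.
#' @param mask logical myocardial mask (non-empty).
#' @param model kinetic model passed to [fit_perfusion()].
#' @param config a [quant_config()].
#' @param arrival_delays candidate myocardial arrival delays in seconds for
#'   the per-pixel [arrival_search()]; `NULL` disables the search.
#' @param crop crop curves to the AIF first pass before fitting (recommended
#'   for the Fermi model).
#' @param ... passed to the model fitter.
#' @return an object of class `parameter_map`: `mbf` (mL/min/g), `F_p`
#'   (mL/min/mL), `arrival` (s), `rss`, `mask`, `qc_flags` (matrix;
#'   `NA` outside mask, 0 ok, 1 failed fit), `times`, `model`.
#' @export
quantify_pixelwise <- function(concentration, times, aif_plasma, mask,
                               model = "fermi", config = quant_config(),
                               arrival_delays = NULL, crop = TRUE, ...) {
  if (!any(mask)) stop("empty myocardial mask")
  d <- dim(concentration)
  arr_est <- detect_arrival(aif_plasma, times)
  if (crop) {
    cr <- crop_first_pass(aif_plasma, aif_plasma, times, arrival = arr_est$index)
    idx <- seq.int(cr$start, cr$end)
  } else {
    idx <- seq.int(arr_est$index, length(times))
  }
  a <- aif_plasma[idx]
  tt <- times[idx]
  mbf <- fp <- arrival <- rss <- matrix(NA_real_, d[1], d[2])
  qc <- matrix(NA_real_, d[1], d[2])
  px <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(px))) {
    cur <- concentration[px[i, 1], px[i, 2], idx]
    fit <- tryCatch({
      if (is.null(arrival_delays))
        fit_perfusion(a, cur, tt, model = model, config = config, ...)
      else
        arrival_search(function(aa, cc, ttt, ...)
          fit_perfusion(aa, cc, ttt, model = model, config = config, ...),
          a, cur, tt, delays = arrival_delays, ...)
    }, error = function(e) NULL)
    r <- px[i, 1]; c <- px[i, 2]
    if (is.null(fit) || !isTRUE(fit$converged) || !is.finite(fit$mbf)) {
      qc[r, c] <- 1
      if (!is.null(fit)) {
        mbf[r, c] <- fit$mbf; fp[r, c] <- fit$F_p; rss[r, c] <- fit$rss
      }
    } else {
      qc[r, c] <- 0
      mbf[r, c] <- fit$mbf
      fp[r, c] <- fit$F_p
      arrival[r, c] <- tt[1] + fit$arrival_offset
      rss[r, c] <- fit$rss
    }
  }
  structure(list(mbf = mbf, F_p = fp, arrival = arrival, rss = rss,
                 mask = mask, qc_flags = qc, times = times, model = model,
                 aif_arrival = arr_est$time, config = config),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$mbf[x$mask]
  cat(sprintf("<parameter_map> %s model, %d myocardial pixels, median MBF %.2f mL/min/g, %d failed\n",
              x$model, sum(x$mask), stats::median(v, na.rm = TRUE),
              sum(x$qc_flags == 1, na.rm = TRUE)))
  invisible(x)
}

#' Myocardial perfusion reserve map
#'
#' Pixel-wise stress/rest MBF ratio on co-registered masks. Rest pixels below
#' `rest_floor` are left undefined and flagged rather than producing
#' unstable ratios.
#'
#' @param stress,rest `parameter_map` objects with identical masks.
#' @param rest_floor minimum rest MBF in mL/min/g.
#' @return a `parameter_map` whose `mbf` field holds the stress map and with
#'   an `mpr` field added.
#' @export
compute_mpr <- function(stress, rest, rest_floor = 0.1) {
  stopifnot(inherits(stress, "parameter_map"), inherits(rest, "parameter_map"))
  if (!identical(dim(stress$mbf), dim(rest$mbf)) ||
      !identical(stress$mask, rest$mask))
    stop("stress and rest masks do not match")
  mpr <- stress$mbf / rest$mbf
  low <- !is.na(rest$mbf) & rest$mbf < rest_floor
  mpr[low] <- NA_real_
  out <- stress
  out$mpr <- mpr
  out$qc_flags[low] <- pmax(out$qc_flags[low], 1)
  out$flags <- if (any(low)) sprintf("%d pixels below rest MBF floor %.2g", sum(low), rest_floor) else character()
  out
}

#' AHA 16-segment model
#'
#' Labels every masked myocardial pixel with its AHA segment: 6 sectors of
#' 60 degrees at base (segments 1-6) and mid (7-12), 4 sectors of 90 degrees
#' at apex (13-16), measured counterclockwise from the anterior RV insertion
#' point.
#'
#' @param mask logical myocardial mask for the slice.
#' @param center LV centre `c(x, y)` in pixels.
#' @param rv_point anterior RV insertion point `c(x, y)` in pixels (required).
#' @param level `"base"`, `"mid"` or `"apex"`.
#' @return list of class `segment_model`: `labels` (integer matrix, NA
#'   outside mask), `level`, `n_sectors`, `rv_angle`.
#' @export
aha16_segment <- function(mask, center, rv_point, level = c("base", "mid", "apex")) {
  level <- match.arg(level)
  if (missing(rv_point) || is.null(rv_point)) stop("missing RV insertion point")
  n_sectors <- if (level == "apex") 4L else 6L
  offset <- switch(level, base = 0L, mid = 6L, apex = 12L)
  rv_angle <- atan2(rv_point[2] - center[2], rv_point[1] - center[1]) * 180 / pi
  g <- pixel_grid(nrow(mask), center)
  ang <- (g$theta - rv_angle) %% 360
  sector <- pmin(floor(ang / (360 / n_sectors)) + 1L, n_sectors)
  labels <- matrix(NA_integer_, nrow(mask), ncol(mask))
  labels[mask] <- sector[mask] + offset
  structure(list(labels = labels, level = level, n_sectors = n_sectors,
                 rv_angle = rv_angle, center = center),
            class = "segment_model")
}

#' Ischemic burden report
#'
#' Percent of myocardium with abnormal perfusion, computed on pixels
#' (area-weighted) with a segment-level summary alongside. A segment whose
#' mean falls below the threshold counts as affected; the segment-count
#' percent (affected / 16) is reported for the two-segment rule of thumb.
#'
#' @param map a `parameter_map`.
#' @param segments a `segment_model` (or list of them, one per slice, with
#'   `map` then a list of maps of equal length).
#' @param threshold abnormality threshold; pixels with `metric` below it are
#'   abnormal. Defaults are deliberately configurable and non-normative:
#'   1.5 mL/min/g for stress MBF, 2 for MPR.
#' @param metric `"mbf"` or `"mpr"`.
#' @param apex_guard exclude apical pixels within 1 px of the mask boundary
#'   from the statistics (partial-volume guard).
#' @return list of class `burden_report`: `threshold`, `metric`,
#'   `percent_abnormal` (pixel-weighted), `percent_by_segments`
#'   (100 * affected / 16), `segment_means`, `affected_segments`,
#'   `n_pixels`, `n_abnormal`.
#' @export
ischemic_burden <- function(map, segments, threshold = NULL,
                            metric = c("mbf", "mpr"), apex_guard = TRUE) {
  metric <- match.arg(metric)
  if (is.null(threshold)) threshold <- if (metric == "mbf") 1.5 else 2
  maps <- if (inherits(map, "parameter_map")) list(map) else map
  segs <- if (inherits(segments, "segment_model")) list(segments) else segments
  stopifnot(length(maps) == length(segs))
  vals <- labs <- list()
  for (s in seq_along(maps)) {
    v <- maps[[s]][[metric]]
    if (is.null(v)) stop(sprintf("map has no '%s' field", metric))
    m <- maps[[s]]$mask
    if (apex_guard && segs[[s]]$level == "apex") {
      kern <- EBImage::makeBrush(3, shape = "box")
      m <- as.matrix(EBImage::erode(m * 1, kern)) > 0.5
    }
    sel <- m & !is.na(v) & !is.na(segs[[s]]$labels)
    vals[[s]] <- v[sel]
    labs[[s]] <- segs[[s]]$labels[sel]
  }
  vals <- unlist(vals); labs <- unlist(labs)
  if (!length(vals)) stop("empty myocardial mask")
  abnormal <- vals < threshold
  seg_means <- tapply(vals, labs, mean)
  affected <- as.integer(names(seg_means))[seg_means < threshold]
  structure(list(threshold = threshold, metric = metric,
                 percent_abnormal = 100 * mean(abnormal),
                 percent_by_segments = 100 * length(affected) / 16,
                 segment_means = seg_means,
                 affected_segments = affected,
                 n_pixels = length(vals), n_abnormal = sum(abnormal)),
            class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  cat(sprintf("<burden_report> %s < %.3g: %.1f%% of myocardium (%d/%d pixels); %d/16 segments affected (%.1f%%)\n",
              x$metric, x$threshold, x$percent_abnormal, x$n_abnormal,
              x$n_pixels, length(x$affected_segments), x$percent_by_segments))
  invisible(x)
}

#' Achievable in-plane resolution
#'
#' Lines acquired in the readout window = floor(window / TR); the full-matrix
#' line count recovers partial-Fourier and parallel-imaging factors
#' (acquired * acceleration / partial fraction); resolution = FOV / full
#' lines.
#'
#' @param window temporal acquisition window in ms.
#' @param TR repetition time in ms.
#' @param partial_fraction partial-Fourier fraction in (0, 1].
#' @param accel_factor parallel-imaging acceleration (>= 1).
#' @param FOV field of view in mm.
#' @return achievable in-plane resolution in mm.
#' @export
#' @examples
#' achievable_resolution(100, 2.5, 0.8, 2, 300)  # 3 mm
achievable_resolution <- function(window, TR, partial_fraction = 1,
                                  accel_factor = 1, FOV = 300) {
  if (window < TR) stop("acquisition window shorter than one TR")
  if (partial_fraction <= 0 || partial_fraction > 1)
    stop("partial_fraction must lie in (0, 1]")
  if (accel_factor < 1) stop("accel_factor must be >= 1")
  if (TR <= 0 || FOV <= 0) stop("TR and FOV must be positive")
  acquired <- floor(window / TR)
  full <- acquired * accel_factor / partial_fraction
  FOV / full
}

#' Validate a protocol against recommended acquisition thresholds
#'
#' Checks the recommended bounds: myocardial TS <= 130 ms, AIF TS < 30 ms,
#' acquisition window < 120 ms, in-plane spacing <= 2.5 mm, slice thickness
#' <= 10 mm, at least 3 slices, saturation efficiency > 95%, and 1-4 PD
#' frames. Missing parameters are reported as unverifiable, not as failures.
#'
#' @param seq_myo myocardial [seq_params()] (or `NULL`).
#' @param seq_aif AIF [seq_params()] (or `NULL`).
#' @param pixel_spacing in-plane spacing in mm.
#' @param slice_thickness slice thickness in mm.
#' @param n_slices number of myocardial slices.
#' @param n_pd_frames number of PD lead-in frames.
#' @return data.frame of class `protocol_report` with columns `rule`,
#'   `value`, `bound`, `status` (`"pass"`, `"violation"`, `"unverifiable"`).
#' @export
validate_protocol <- function(seq_myo = NULL, seq_aif = NULL,
                              pixel_spacing = NULL, slice_thickness = NULL,
                              n_slices = NULL, n_pd_frames = NULL) {
  rows <- list()
  add <- function(rule, value, bound, ok) {
    status <- if (is.null(value) || is.na(value)) "unverifiable"
              else if (ok) "pass" else "violation"
    rows[[length(rows) + 1L]] <<- data.frame(
      rule = rule, value = if (is.null(value)) NA_real_ else value,
      bound = bound, status = status, stringsAsFactors = FALSE)
  }
  ts_myo <- if (!is.null(seq_myo)) seq_myo$TS else NULL
  add("myocardial TS (ms)", ts_myo, "<= 130", isTRUE(ts_myo <= 130))
  ts_aif <- if (!is.null(seq_aif)) seq_aif$TS else NULL
  add("AIF TS (ms)", ts_aif, "< 30", isTRUE(ts_aif < 30))
  win <- if (!is.null(seq_myo)) seq_myo$acquisition_window else NULL
  add("acquisition window (ms)", win, "< 120", isTRUE(win < 120))
  add("in-plane spacing (mm)", pixel_spacing, "<= 2.5",
      isTRUE(pixel_spacing <= 2.5))
  add("slice thickness (mm)", slice_thickness, "<= 10",
      isTRUE(slice_thickness <= 10))
  add("spatial coverage (slices)", n_slices, ">= 3", isTRUE(n_slices >= 3))
  eff <- if (!is.null(seq_myo)) seq_myo$saturation_efficiency else NULL
  add("saturation efficiency", eff, "> 0.95", isTRUE(eff > 0.95))
  add("PD lead-in frames", n_pd_frames, "1..4",
      isTRUE(n_pd_frames >= 1 && n_pd_frames <= 4))
  out <- do.call(rbind, rows)
  class(out) <- c("protocol_report", "data.frame")
  out
}
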