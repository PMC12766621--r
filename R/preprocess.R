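# FFT cross-correlation shift estimate of image b relative to image a, with
# parabolic subpixel refinement. When max_shift is finite the peak search is
# restricted to |shift| <= max_shift (used in the refinement pass, where a
# global search could lock onto contrast-driven structure).
xcorr_shift <- function(a, b, max_shift = Inf, highpass = 6) {
  n <- dim(a)
  # remove smooth stationary structure (coil-sensitivity pattern) so the
  # correlation follows anatomy edges rather than the static bias field;
  # the kernel must fit inside the image
  sigma <- min(highpass, (min(n) - 3) / 7)
  if (sigma >= 0.5) {
    a <- a - as.matrix(EBImage::gblur(a, sigma = sigma))
    b <- b - as.matrix(EBImage::gblur(b, sigma = sigma))
  }
  cc <- Re(stats::fft(stats::fft(b - mean(b)) * Conj(stats::fft(a - mean(a))),
                      inverse = TRUE))
  if (is.finite(max_shift)) {
    sh1 <- ((seq_len(n[1]) - 1 + n[1] / 2) %% n[1]) - n[1] / 2
    sh2 <- ((seq_len(n[2]) - 1 + n[2] / 2) %% n[2]) - n[2] / 2
    allowed <- outer(abs(sh1) <= max_shift, abs(sh2) <= max_shift)
    cc[!allowed] <- -Inf
  }
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sub <- function(axis) {
    i <- pk[axis]
    nn <- n[axis]
    im <- ((i - 2) %% nn) + 1
    ip <- (i %% nn) + 1
    v <- if (axis == 1) c(cc[im, pk[2]], cc[i, pk[2]], cc[ip, pk[2]])
         else c(cc[pk[1], im], cc[pk[1], i], cc[pk[1], ip])
    if (!all(is.finite(v))) return(0)
    den <- v[1] - 2 * v[2] + v[3]
    if (abs(den) < 1e-12) 0 else clamp(0.5 * (v[1] - v[3]) / den, -1, 1)
  }
  sh <- pk - 1
  sh[1] <- if (sh[1] > n[1] / 2) sh[1] - n[1] else sh[1]
  sh[2] <- if (sh[2] > n[2] / 2) sh[2] - n[2] else sh[2]
  sh + c(sub(1), sub(2))
}

#' Translation-only frame registration
#'
#' Estimates a per-frame in-plane translation and resamples every frame (PD
#' frames included) onto the reference. Because the contrast dynamics defeat
#' direct correlation between frames in different enhancement states, the
#' estimate is sequential: adjacent frames (nearly identical contrast) are
#' registered by high-passed FFT cross-correlation with parabolic subpixel
#' refinement, and the pairwise displacements are accumulated along the
#' series and referred to the reference frame.
#'
#' @param series a `dynamic_series` with at least 2 frames.
#' @param reference reference frame index; default the frame of peak total
#'   signal.
#' @return list with `displacements` (`n x 2` matrix, pixels; the estimated
#'   content shift of each frame relative to the reference), `corrected`
#'   (the resampled `dynamic_series`) and `flags`.
#' @export
register_translation <- function(series, reference = NULL) {
  stop_if_not_series(series)
  d <- dim(series$frames)
  if (d[3] < 2) stop("need at least 2 frames")
  if (is.null(reference))
    reference <- which.max(apply(series$frames, 3, sum))
  flags <- character()
  ok <- apply(series$frames, 3, stats::sd) > 1e-12
  if (!all(ok))
    flags <- sprintf("frame %d constant; displacement set to 0", which(!ok))
  # chain adjacent-frame estimates: consecutive frames are in nearly the
  # same enhancement state, so pairwise correlation is well-posed even
  # though direct correlation across contrast states is not
  rel <- matrix(0, d[3], 2)
  for (f in 2:d[3])
    if (ok[f] && ok[f - 1])
      rel[f, ] <- xcorr_shift(series$frames[, , f - 1], series$frames[, , f])
  disp <- apply(rel, 2, cumsum)
  disp <- sweep(disp, 2, disp[reference, ])
  disp[!ok, ] <- 0
  disp[abs(disp) < 0.1] <- 0  # below the estimator noise floor
  corrected <- series$frames
  for (f in seq_len(d[3]))
    if (any(disp[f, ] != 0))
      corrected[, , f] <- shift_image(series$frames[, , f], -disp[f, ])
  out <- series
  out$frames <- corrected
  list(displacements = disp, corrected = out, flags = flags)
}

# Second-order 2D polynomial surface fit over a mask.
fit_poly_surface <- function(img, mask = NULL) {
  n1 <- nrow(img); n2 <- ncol(img)
  if (is.null(mask)) mask <- img > 0.1 * max(img)  # body mask at 10% of max
  u <- matrix(seq(-1, 1, length.out = n1), n1, n2)
  v <- matrix(seq(-1, 1, length.out = n2), n1, n2, byrow = TRUE)
  X <- cbind(1, u[mask], v[mask], u[mask]^2, u[mask] * v[mask], v[mask]^2)
  beta <- stats::lm.fit(X, img[mask])$coefficients
  beta[is.na(beta)] <- 0
  surface <- beta[1] + beta[2] * u + beta[3] * v + beta[4] * u^2 +
    beta[5] * u * v + beta[6] * v^2
  list(surface = surface, coefficients = beta, mask = mask)
}

#' Coil sensitivity correction
#'
#' Estimates the coil bias field from aligned PD-weighted frames and divides
#' it out of every frame. `surface_fit` fits a second-order 2D polynomial to
#' the PD image over a body mask (10% of the PD maximum) and normalizes the
#' surface to unit mean over the mask; `pixelwise` divides by a lightly
#' smoothed mean PD image directly.
#'
#' @param series a `dynamic_series`.
#' @param pd_frames indices of the PD frames; default from `frame_roles`.
#' @param method `"surface_fit"` or `"pixelwise"`.
#' @param smooth Gaussian sigma in pixels for the pixelwise PD smoothing.
#' @return list with `corrected` series and the estimated `bias` field
#'   (unit-mean over the body mask) for QC review.
#' @export
coil_correct <- function(series, pd_frames = NULL,
                         method = c("surface_fit", "pixelwise"), smooth = 1) {
  stop_if_not_series(series)
  method <- match.arg(method)
  pd_frames <- pd_frames %||% which(series$frame_roles == "PD")
  if (!length(pd_frames)) stop("need at least one aligned PD frame")
  pd <- frame_mean(series$frames, pd_frames)
  if (all(pd == 0)) stop("PD frames are identically zero")
  if (method == "surface_fit") {
    fit <- fit_poly_surface(pd)
    bias <- fit$surface / mean(fit$surface[fit$mask])
  } else {
    sm <- if (smooth > 0) as.matrix(EBImage::gblur(pd, sigma = smooth)) else pd
    bias <- sm / mean(sm[sm > 0.1 * max(sm)])
  }
  bias[bias <= 1e-6] <- 1  # avoid dividing background by ~0
  out <- series
  out$frames <- sweep(series$frames, c(1, 2), bias, "/")
  list(corrected = out, bias = bias)
}

#' Baseline (pre-contrast) correction
#'
#' Subtracts the mean over the identified pre-contrast frames/samples from
#' every time point, so that the pre-contrast signal (or concentration) is
#' nulled. Applies to a `dynamic_series` (per pixel, SR frames only; PD
#' frames are never part of the baseline) or to a plain numeric curve.
#'
#' @param x a `dynamic_series` or numeric vector/matrix of curves
#'   (time in the last dimension).
#' @param pre_contrast index set of pre-contrast SR frames (for a series,
#'   indices into the frame dimension; PD frames are dropped from the set).
#' @return the corrected object, same shape as the input.
#' @export
baseline_correct <- function(x, pre_contrast) {
  if (!length(pre_contrast)) stop("empty pre-contrast frame set")
  if (is_dynamic_series(x)) {
    pre <- setdiff(pre_contrast, which(x$frame_roles == "PD"))
    if (!length(pre)) stop("pre-contrast set contains no SR frames")
    base <- frame_mean(x$frames, pre)
    sr <- which(x$frame_roles == "SR")
    x$frames[, , sr] <- sweep(x$frames[, , sr, drop = FALSE], c(1, 2), base, "-")
    return(x)
  }
  if (is.matrix(x)) return(x - rowMeans(x[, pre_contrast, drop = FALSE]))
  x - mean(x[pre_contrast])
}

#' Spatial filtering of myocardial frames
#'
#' Optional 2D filtering of the high-resolution myocardial frames (PD frames
#' included). Refuses AIF series: filtering the AIF would bias its peak, and
#' temporal filtering is not provided at all.
#'
#' @param series a myocardial `dynamic_series`.
#' @param kernel `"none"`, `"gaussian"` or `"median"`.
#' @param width Gaussian sigma in pixels, or median window half-width.
#' @return the filtered series.
#' @export
spatial_filter <- function(series, kernel = c("none", "gaussian", "median"),
                           width = 1) {
  stop_if_not_series(series)
  kernel <- match.arg(kernel)
  if (series$seq$role == "AIF")
    stop("spatial filtering is limited to myocardial series; AIF series refused")
  if (kernel == "none") return(series)
  for (f in seq_len(dim(series$frames)[3])) {
    img <- series$frames[, , f]
    series$frames[, , f] <- switch(kernel,
      gaussian = as.matrix(EBImage::gblur(img, sigma = width)),
      median = {
        mx <- max(img)
        if (mx <= 0) img else
          as.matrix(EBImage::medianFilter(img / mx, size = width)) * mx
      })
  }
  series
}

#' Identify pre-contrast SR frames
#'
#' Frames strictly before the detected AIF arrival (minus one guard frame),
#' excluding PD frames. Used as the default baseline window.
#'
#' @param series a `dynamic_series`.
#' @param aif_curve optional blood-pool curve over the SR frames; by default
#'   the mean over the brightest decile of the peak-enhancement frame.
#' @return integer frame indices (into the series) of pre-contrast SR frames.
#' @export
pre_contrast_frames <- function(series, aif_curve = NULL) {
  stop_if_not_series(series)
  sr <- which(series$frame_roles == "SR")
  if (is.null(aif_curve)) {
    pk <- sr[which.max(apply(series$frames[, , sr, drop = FALSE], 3, sum))]
    thr <- stats::quantile(series$frames[, , pk], 0.9)
    m <- series$frames[, , pk] >= thr
    aif_curve <- apply(series$frames[, , sr, drop = FALSE], 3, function(fr) mean(fr[m]))
  }
  arr <- detect_arrival(aif_curve - min(aif_curve),
                        series$trigger_times[sr] / 1000)$index
  if (arr <= 2) stop("no pre-contrast SR frames before arrival")
  sr[seq_len(arr - 2)]
}
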