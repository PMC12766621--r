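#' Fermi impulse-response function
#'
#' I(t) = A / (exp((t - mu) k) + 1) + offset: an initial plateau of width mu
#' followed by a decay at rate k, used as the constrained shape of the tissue
#' impulse response in Fermi deconvolution. The fourth offset parameter
#' absorbs slow interstitial leakage.
#'
#' @param t times in seconds.
#' @param A amplitude.
#' @param mu plateau width / temporal delay in seconds.
#' @param k decay rate in s^-1 (non-negative).
#' @param offset additive offset.
#' @return impulse-response values, monotone non-increasing in `t`.
#' @export
#' @examples
#' fermi_irf(7, A = 1, mu = 5, k = 0.5)  # 1 / (e + 1)
fermi_irf <- function(t, A, mu, k, offset = 0) {
  if (any(k < 0)) stop("k must be non-negative")
  A / (exp((t - mu) * k) + 1) + offset
}

# Uniform internal grid shared by the convolution-based fitters, with a
# lower-triangular Toeplitz operator so that conv(irf, ca) = dt * T %*% irf
# (trapezoid quadrature).
fit_grid <- function(aif, tissue, times, oversample = 2) {
  if (length(aif) != length(tissue) || length(aif) != length(times))
    stop("aif, tissue and times must have equal length")
  if (length(times) < 5) stop("need at least 5 samples")
  tt <- times - times[1]
  tfine <- uniform_grid(tt, oversample)
  ca <- interp_curve(tt, aif, tfine)
  n <- length(tfine)
  T <- matrix(0, n, n)
  for (j in seq_len(n)) T[j:n, j] <- ca[seq_len(n - j + 1)]
  T[, 1] <- T[, 1] / 2
  T <- T - diag(ca[1] / 2, n)  # half-weight both quadrature ends
  T[1, 1] <- 0
  list(tt = tt, tfine = tfine, dt = tfine[2] - tfine[1],
       ca = ca, T = T, tissue_fine = interp_curve(tt, tissue, tfine))
}

conv_T <- function(g, irf) g$dt * (g$T %*% irf)

new_perfusion_fit <- function(model, params, F_p, mbf, rss, n_points,
                              converged, data, fitted, flags = character(),
                              arrival_offset = 0, extra = list()) {
  structure(c(list(model = model, params = params, F_p = F_p, mbf = mbf,
                   rss = rss, n_points = n_points, converged = converged,
                   data = data, fitted = fitted, flags = flags,
                   arrival_offset = arrival_offset), extra),
            class = "perfusion_fit")
}

flow_to_mbf <- function(F_p, config) {
  f <- if (config$flow_convention == "blood") F_p / (1 - config$hematocrit) else F_p
  f / config$tissue_density
}

#' Fit a perfusion model to an AIF/tissue curve pair
#'
#' The central estimator: fits the tissue concentration curve as the causal
#' convolution of the (plasma) arterial input function with a tissue impulse
#' response, and reads myocardial blood flow off the impulse response at time
#' zero. Four estimators are available: Fermi-constrained deconvolution
#' (Levenberg-Marquardt), the two-compartment exchange model (coarse grid
#' search then Nelder-Mead refinement), the Patlak plot, and Tikhonov
#' model-independent deconvolution.
#'
#' Curves are assumed baseline-corrected and on a common time grid; the Fermi
#' model additionally expects first-pass-cropped curves (see
#' [crop_first_pass()]), while the 2CXM can use the whole post-arrival curve.
#'
#' @param aif arterial plasma concentration (mmol/L) at `times`.
#' @param tissue myocardial concentration (mmol/L) at `times`.
#' @param times sample times in seconds (possibly non-uniform; fitting is
#'   performed on an oversampled uniform internal grid).
#' @param model `"fermi"`, `"2cxm"`, `"patlak"` or `"tikhonov"`.
#' @param config a [quant_config()]; sets the blood/plasma flow convention
#'   and tissue density used to express `mbf` in mL/min/g.
#' @param ... passed to the model-specific fitter ([fit_fermi()],
#'   [fit_2cxm()], [fit_patlak()], [deconvolve_tikhonov()]).
#' @return an object of class `perfusion_fit` with elements `params`
#'   (model parameters; flows in mL/min/mL), `F_p` (plasma flow in
#'   mL/min/mL), `mbf` (mL/min/g under the configured convention), `rss`,
#'   `n_points`, `converged`, `fitted`, `flags` and the input `data`.
#' @seealso [crop_first_pass()], [arrival_search()]
#' @export
fit_perfusion <- function(aif, tissue, times,
                          model = c("fermi", "2cxm", "patlak", "tikhonov"),
                          config = quant_config(), ...) {
  model <- match.arg(model)
  switch(model,
         fermi = fit_fermi(aif, tissue, times, config = config, ...),
         "2cxm" = fit_2cxm(aif, tissue, times, config = config, ...),
         patlak = fit_patlak(aif, tissue, times, config = config, ...),
         tikhonov = deconvolve_tikhonov(aif, tissue, times, config = config, ...))
}

#' Fermi-constrained deconvolution
#'
#' Least-squares fit of tissue = (I_fermi * aif) with I parameterized as
#' [fermi_irf()]. Because the Fermi shape parameters are only weakly
#' identified on short first-pass windows, the fit is global-then-local: a
#' coarse grid over (mu, k) with the two linear amplitudes (A, offset)
#' profiled out by non-negative least squares, followed by
#' Levenberg-Marquardt refinement from the best grid point. MBF is read as
#' the impulse response at time zero, I(0) = A / (exp(-mu k) + 1) + offset:
#' the leakage offset is part of the tissue impulse response at t = 0 and is
#' included in the flow read-out.
#'
#' @inheritParams fit_perfusion
#' @param start optional starting values `c(A, mu, k, offset)` (A in
#'   min^-1); skips the grid stage.
#' @param offset logical; include the fourth offset parameter.
#' @return a `perfusion_fit`.
#' @export
fit_fermi <- function(aif, tissue, times, config = quant_config(),
                      start = NULL, offset = TRUE) {
  g <- fit_grid(aif, tissue, times)
  pred_fun <- function(p) {
    irf <- fermi_irf(g$tfine, p[1], p[2], p[3], p[4]) / 60
    interp_curve(g$tfine, conv_T(g, irf), g$tt)
  }
  if (is.null(start)) {
    tmax <- max(g$tt)
    mus <- seq(0, min(10, tmax / 2), by = 0.5)
    ks <- exp(seq(log(0.05), log(5), length.out = 20))
    grid <- as.matrix(expand.grid(mu = mus, k = ks))
    irfs <- matrix(0, length(g$tfine), nrow(grid))
    for (i in seq_len(nrow(grid)))
      irfs[, i] <- fermi_irf(g$tfine, 1, grid[i, 1], grid[i, 2], 0) / 60
    basis <- g$dt * (g$T %*% irfs)
    b_off <- interp_curve(g$tfine,
                          g$dt * (g$T %*% rep(1 / 60, length(g$tfine))), g$tt)
    best <- list(rss = Inf)
    obs_idx <- vapply(g$tt, function(x) which.min(abs(g$tfine - x)), integer(1))
    for (i in seq_len(nrow(grid))) {
      X <- cbind(basis[obs_idx, i], b_off)
      cf <- tryCatch(pmax(qr.solve(X, tissue), 0), error = function(e) c(0, 0))
      if (!offset) cf[2] <- 0
      r <- sum((tissue - X %*% cf)^2)
      if (r < best$rss)
        best <- list(rss = r, par = c(A = unname(cf[1]), mu = unname(grid[i, 1]),
                                      k = unname(grid[i, 2]),
                                      offset = unname(cf[2])))
    }
    start <- best$par
  }
  lower <- c(0, 0, 1e-4, 0)
  upper <- c(Inf, max(g$tt), 10, Inf)
  if (!offset) { start <- start[1:3]; lower <- lower[1:3]; upper <- upper[1:3] }
  ctl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12, ptol = 1e-12)
  fit <- minpack.lm::nls.lm(
    par = pmax(start, lower + 1e-10), lower = lower, upper = upper,
    fn = function(p) tissue - pred_fun(c(p, 0)[1:4]), control = ctl)
  p <- c(fit$par, 0)[1:4]
  F_p <- p[1] / (exp(-p[2] * p[3]) + 1) + p[4]
  fitted <- pred_fun(p)
  new_perfusion_fit(
    "fermi",
    list(fermi_A = unname(p[1]), fermi_mu = unname(p[2]),
         fermi_k = unname(p[3]), fermi_offset = if (offset) unname(p[4]) else 0),
    F_p = F_p, mbf = flow_to_mbf(F_p, config),
    rss = sum((tissue - fitted)^2), n_points = length(times),
    converged = fit$info %in% 1:4,
    data = list(aif = aif, tissue = tissue, times = times),
    fitted = fitted,
    extra = list(config = config, start = start,
                 bounds = list(lower = lower, upper = upper)))
}

# Physiologic coarse-search ranges for the 2CXM (8 points per parameter).
cxm_grid_ranges <- function() {
  list(F_p = c(0.1, 6), v_p = c(0.01, 0.2), v_e = c(0.05, 0.5), PS = c(0, 2))
}

cxm_pred <- function(p, g) {
  # p = c(F_p, v_p, v_e, PS)
  bi <- biexp_2cxm(p[1], p[2], p[3], p[4])
  y <- conv_exp(g$ca, g$dt, c(bi$l1, bi$l2))
  fine <- bi$c1 * y[, 1] + bi$c2 * y[, 2]
  interp_curve(g$tfine, fine, g$tt)
}

#' Two-compartment exchange model fit
#'
#' Coarse-to-fine estimation of (F_p, v_p, v_e, PS): stage 1 evaluates the
#' analytic bi-exponential impulse response on an 8^4 grid over physiologic
#' ranges (F_p 0.1-6, v_p 0.01-0.2, v_e 0.05-0.5, PS 0-2, flows in
#' mL/min/mL); the best grid point initializes a Nelder-Mead simplex
#' refinement in log-parameter space. Parameters pinned at the search
#' boundaries are flagged.
#'
#' @inheritParams fit_perfusion
#' @param grid_n grid points per parameter in the coarse search.
#' @return a `perfusion_fit`.
#' @export
fit_2cxm <- function(aif, tissue, times, config = quant_config(), grid_n = 8) {
  g <- fit_grid(aif, tissue, times)
  rg <- cxm_grid_ranges()
  axes <- lapply(rg, function(r) {
    lo <- max(r[1], 1e-3)
    exp(seq(log(lo), log(max(r[2], lo * 2)), length.out = grid_n))
  })
  # keep PS = 0 itself in the grid alongside a log spread up to the range top
  axes$PS <- c(0, exp(seq(log(0.01), log(rg$PS[2]), length.out = grid_n - 1)))
  grid <- as.matrix(expand.grid(axes))
  ok <- grid[, "v_p"] + grid[, "v_e"] <= 1
  grid <- grid[ok, , drop = FALSE]
  bi <- biexp_2cxm(grid[, "F_p"], grid[, "v_p"], grid[, "v_e"], grid[, "PS"])
  y <- conv_exp(g$ca, g$dt, c(bi$l1, bi$l2))
  m <- nrow(grid)
  pred <- y[, seq_len(m), drop = FALSE] * rep(bi$c1, each = length(g$tfine)) +
    y[, m + seq_len(m), drop = FALSE] * rep(bi$c2, each = length(g$tfine))
  rss0 <- colSums((pred - g$tissue_fine)^2)
  p0 <- grid[which.min(rss0), ]
  obj <- function(lp) {
    p <- exp(lp)
    if (p[2] + p[3] > 1) return(1e9)
    sum((tissue - cxm_pred(p, g))^2)
  }
  opt <- stats::optim(log(pmax(p0, 1e-6)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- exp(opt$par)
  # also refine the reduced impermeable model (PS = 0, v_e inert) and keep
  # it on an effective tie: parsimony breaks the PS/v_e degeneracy that the
  # full model exhibits when the tissue is intravascular
  obj0 <- function(lp) sum((tissue - cxm_pred(c(exp(lp), 0), g))^2)
  opt0 <- stats::optim(log(pmax(p0[1:3], 1e-6)), obj0, method = "Nelder-Mead",
                       control = list(maxit = 1500, reltol = 1e-12))
  if (opt0$value <= opt$value * (1 + 1e-6) + 1e-7 * sum(tissue^2)) {
    p <- c(exp(opt0$par), 0)
    opt <- opt0
  }
  names(p) <- names(rg)
  fitted <- cxm_pred(p, g)
  flags <- character()
  for (nm in names(rg))
    if (p[nm] > 0.999 * rg[[nm]][2] * 2)  # far beyond the physiologic range
      flags <- c(flags, sprintf("%s pinned outside physiologic range", nm))
  params <- kinetic_params(F_p = unname(p["F_p"]), v_p = unname(min(p["v_p"], 1)),
                           v_e = unname(min(p["v_e"], 1 - min(p["v_p"], 1))),
                           PS = unname(p["PS"]))
  new_perfusion_fit(
    "2cxm", params, F_p = unname(p["F_p"]),
    mbf = flow_to_mbf(unname(p["F_p"]), config),
    rss = opt$value, n_points = length(times),
    converged = opt$convergence == 0 && !length(flags),
    data = list(aif = aif, tissue = tissue, times = times),
    fitted = fitted, flags = flags,
    extra = list(config = config, start = p0,
                 bounds = rg, grid_rss = min(rss0)))
}

#' Patlak-plot analysis
#'
#' Linear regression of tissue/C_aif against the normalized integral
#' int C_aif / C_aif over an early window: the slope estimates K_trans and
#' the intercept v_p. A negative fitted slope is reported as K_trans = 0 with
#' a flag.
#'
#' @inheritParams fit_perfusion
#' @param window integer index vector of samples to use; default all samples
#'   with C_aif above 2% of peak up to 10 s past the AIF peak.
#' @return a `perfusion_fit` (K_trans and v_p in `params`; `F_p` is `NA`
#'   because Patlak does not resolve plasma flow).
#' @export
fit_patlak <- function(aif, tissue, times, config = quant_config(),
                       window = NULL) {
  if (length(aif) != length(tissue) || length(aif) != length(times))
    stop("aif, tissue and times must have equal length")
  if (is.null(window)) {
    # early window: bolus upslope to the AIF peak, before backflux from the
    # extravascular space bends the Patlak plot
    pk <- which.max(aif)
    window <- which(aif > 0.02 * max(aif) & seq_along(aif) <= pk)
  }
  window <- window[aif[window] > 0]
  if (length(window) < 3) stop("fewer than 3 valid Patlak points")
  x <- cumtrapz(times, aif)[window] / aif[window]
  y <- tissue[window] / aif[window]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  v_p <- unname(stats::coef(fit)[1])
  flags <- character()
  K_trans <- 60 * slope
  if (K_trans < 0) { flags <- "negative Patlak slope; K_trans set to 0"; K_trans <- 0 }
  fitted <- (v_p + pmax(slope, 0) * cumtrapz(times, aif) / pmax(aif, 1e-12)) * aif
  new_perfusion_fit(
    "patlak", list(K_trans = K_trans, v_p = v_p),
    F_p = NA_real_, mbf = NA_real_,
    rss = sum(stats::residuals(fit)^2), n_points = length(window),
    converged = TRUE,
    data = list(aif = aif, tissue = tissue, times = times),
    fitted = fitted, flags = flags,
    extra = list(config = config, window = window))
}

#' Tikhonov model-independent deconvolution
#'
#' Discretizes the causal convolution tissue = A I (A lower-triangular, built
#' from the AIF) and solves the ridge-penalized least-squares problem
#' (A'A + lambda^2 Id) I = A' tissue. MBF is read as I(0) of the recovered
#' impulse response.
#'
#' @inheritParams fit_perfusion
#' @param lambda regularization weight, relative to the largest singular
#'   value of the convolution operator; `NULL` selects it from `lambdas` by
#'   generalized cross-validation.
#' @param lambdas candidate grid used when `lambda` is `NULL`.
#' @return a `perfusion_fit`; the recovered impulse response (per minute) is
#'   in `$irf` with its time grid in `$irf_times`.
#' @export
deconvolve_tikhonov <- function(aif, tissue, times, config = quant_config(),
                                lambda = NULL,
                                lambdas = 10^seq(-4, 0, length.out = 25)) {
  if (length(aif) != length(tissue) || length(aif) != length(times))
    stop("aif, tissue and times must have equal length")
  if (!is.null(lambda) && lambda < 0) stop("lambda must be >= 0")
  tt <- times - times[1]
  dt <- diff(tt)
  uniform <- max(dt) - min(dt) < 1e-9 * max(dt)
  if (!uniform) {
    tu <- uniform_grid(tt, oversample = 1)
    aif_u <- interp_curve(tt, aif, tu)
    tis_u <- interp_curve(tt, tissue, tu)
  } else {
    tu <- tt; aif_u <- aif; tis_u <- tissue
  }
  n <- length(tu)
  h <- if (n > 1) tu[2] - tu[1] else 1
  # lower-triangular Toeplitz convolution operator (rectangle rule); the
  # system is nonsingular whenever the AIF is nonzero at the window start
  A <- matrix(0, n, n)
  for (j in seq_len(n)) A[j:n, j] <- aif_u[seq_len(n - j + 1)] * h
  sv <- svd(A)
  smax <- sv$d[1]
  solve_l <- function(l) {
    la <- l * smax
    filt <- sv$d / (sv$d^2 + la^2)
    if (any(!is.finite(filt)))
      stop("singular deconvolution system; use lambda > 0", call. = FALSE)
    as.vector(sv$v %*% (filt * crossprod(sv$u, tis_u)))
  }
  if (lambda_given <- !is.null(lambda)) {
    if (lambda == 0 && min(sv$d) < 1e-12 * smax)
      stop("singular deconvolution system; use lambda > 0", call. = FALSE)
  } else {
    # generalized cross-validation over the candidate grid
    uc <- as.vector(crossprod(sv$u, tis_u))
    gcv <- vapply(lambdas, function(l) {
      la <- l * smax
      shrink <- sv$d^2 / (sv$d^2 + la^2)
      rss <- sum(((1 - shrink) * uc)^2) + sum(tis_u^2) - sum(uc^2)
      (rss / n) / (1 - sum(shrink) / n)^2
    }, numeric(1))
    lambda <- lambdas[which.min(gcv)]
  }
  I <- solve_l(lambda)
  fitted_u <- as.vector(A %*% I)
  fitted <- interp_curve(tu, fitted_u, tt)
  # The first node of the discrete impulse response is biased low because the
  # AIF rises from ~0 across the first interval; I(0) is therefore read by a
  # short linear extrapolation from the following nodes.
  I0 <- if (n >= 3) max(I[1], 2 * I[2] - I[3]) else I[1]
  F_p <- 60 * I0
  new_perfusion_fit(
    "tikhonov", list(lambda = lambda), F_p = F_p,
    mbf = flow_to_mbf(F_p, config),
    rss = sum((tissue - fitted)^2), n_points = length(times),
    converged = TRUE,
    data = list(aif = aif, tissue = tissue, times = times),
    fitted = fitted,
    extra = list(config = config, irf = 60 * I, irf_times = tu,
                 lambda_relative = lambda, sigma_max = smax))
}

#' Crop an AIF/tissue pair to the first pass
#'
#' The window runs from the AIF arrival to the end of the first pass: the
#' first post-peak sample at or below `end_fraction` of the peak, or the
#' pre-recirculation minimum, whichever comes first. Both curves are cropped
#' identically.
#'
#' @param aif,tissue,times curve pair on a common grid (times in seconds).
#' @param arrival AIF arrival index; detected with [detect_arrival()] when
#'   missing.
#' @param end_fraction post-peak decay fraction ending the window.
#' @return list with cropped `aif`, `tissue`, `times`, plus `start`/`end`
#'   indices into the input grid.
#' @export
crop_first_pass <- function(aif, tissue, times, arrival = NULL,
                            end_fraction = 0.3) {
  if (length(tissue) != length(aif) || length(times) != length(aif))
    stop("aif, tissue and times grids must match")
  if (is.null(arrival)) {
    # start one sample before the detected arrival so that the initial rise
    # of the AIF (onset usually falls between samples) stays in the window;
    # otherwise every downstream convolution misses its leading mass
    arrival <- max(detect_arrival(aif, times)$index - 1L, 1L)
  }
  pk <- which.max(aif)
  if (pk <= arrival || pk == length(aif))
    stop("no first-pass peak found after arrival")
  post <- seq.int(pk, length(aif))
  dec <- post[aif[post] <= end_fraction * aif[pk]]
  e1 <- if (length(dec)) dec[1] else length(aif)
  # pre-recirculation minimum: first local minimum after the peak followed by
  # a rise of more than 5% of peak
  v <- aif[post]
  e2 <- length(aif)
  if (length(v) > 2) {
    mins <- which(diff(sign(diff(v))) > 0) + 1
    for (m in mins) {
      if (max(v[m:length(v)]) - v[m] > 0.05 * aif[pk]) { e2 <- post[m]; break }
    }
  }
  end <- min(e1, e2)
  idx <- seq.int(arrival, end)
  list(aif = aif[idx], tissue = tissue[idx], times = times[idx],
       start = arrival, end = end)
}

#' Arrival-time search
#'
#' Repeats a fit over candidate myocardial tracer-arrival delays (the AIF is
#' shifted by each candidate delay before fitting) and returns the
#' minimum-residual fit; ties break toward the earliest arrival.
#'
#' @param fitter fitting function `(aif, tissue, times, ...) -> perfusion_fit`,
#'   e.g. [fit_fermi()].
#' @param aif,tissue,times curve pair on a common grid.
#' @param delays candidate myocardial arrival delays in seconds (relative to
#'   the AIF arrival), non-empty.
#' @param ... passed to `fitter`.
#' @return the best `perfusion_fit`, with `arrival_offset` set to the selected
#'   delay and the per-candidate residuals in `$search`.
#' @export
arrival_search <- function(fitter, aif, tissue, times, delays, ...) {
  if (!length(delays)) stop("empty candidate arrival range")
  tt <- times - times[1]
  fits <- lapply(delays, function(d) {
    ca <- interp_curve(tt + d, aif, tt)  # AIF delayed by d seconds
    ca[tt < d] <- 0
    tryCatch(fitter(ca, tissue, times, ...), error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all candidate arrivals failed to fit")
  rss <- vapply(fits[ok], `[[`, numeric(1), "rss")
  pick <- which(ok)[which(rss <= min(rss) * (1 + 1e-9))[1]]  # earliest on ties
  best <- fits[[pick]]
  best$arrival_offset <- delays[pick]
  best$search <- data.frame(delay = delays[ok], rss = rss)
  best
}

# S3 methods ------------------------------------------------------------------

#' @export
print.perfusion_fit <- function(x, ...) {
  cat(sprintf("<perfusion_fit> model %s: MBF = %s mL/min/g (F_p = %s mL/min/mL)\n",
              x$model,
              ifelse(is.na(x$mbf), "NA", sprintf("%.3f", x$mbf)),
              ifelse(is.na(x$F_p), "NA", sprintf("%.3f", x$F_p))))
  cat(sprintf("  rss %.4g over %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.perfusion_fit <- function(object, ...) {
  p <- object$params
  unlist(p[!vapply(p, is.null, logical(1)) &
           vapply(p, is.numeric, logical(1))])
}

#' @export
summary.perfusion_fit <- function(object, ...) {
  out <- list(model = object$model, coefficients = coef(object),
              F_p = object$F_p, mbf = object$mbf, rss = object$rss,
              sigma = sqrt(object$rss / max(object$n_points - length(coef(object)), 1)),
              n_points = object$n_points, converged = object$converged,
              arrival_offset = object$arrival_offset, flags = object$flags)
  class(out) <- "summary.perfusion_fit"
  out
}

#' @export
print.summary.perfusion_fit <- function(x, ...) {
  cat(sprintf("Perfusion fit (%s model)\n", x$model))
  print(round(x$coefficients, 5))
  cat(sprintf("F_p = %.4g mL/min/mL, MBF = %.4g mL/min/g\n", x$F_p, x$mbf))
  cat(sprintf("RSS %.4g (sigma %.4g) over %d points; arrival offset %.2f s\n",
              x$rss, x$sigma, x$n_points, x$arrival_offset))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
fitted.perfusion_fit <- function(object, ...) object$fitted

#' @export
residuals.perfusion_fit <- function(object, ...) object$data$tissue - object$fitted

#' Predict the model tissue curve
#'
#' @param object a `perfusion_fit`.
#' @param times optional new times in seconds (same AIF); default the fitted
#'   grid.
#' @param ... unused.
#' @return predicted tissue concentration.
#' @export
predict.perfusion_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  tt0 <- object$data$times
  interp_curve(tt0 - tt0[1], object$fitted, times - tt0[1])
}

#' @export
plot.perfusion_fit <- function(x, ...) {
  t <- x$data$times
  graphics::plot(t, x$data$tissue, pch = 16, cex = 0.7,
                 xlab = "time (s)", ylab = "concentration (mmol/L)",
                 main = sprintf("%s fit: MBF %.2f mL/min/g", x$model, x$mbf), ...)
  graphics::lines(t, x$fitted, col = "red3", lwd = 2)
  graphics::lines(t, x$data$aif * max(x$data$tissue) / max(x$data$aif),
                  col = "grey60", lty = 2)
  graphics::legend("topright", c("tissue", "fit", "AIF (scaled)"),
                   col = c("black", "red3", "grey60"),
                   lty = c(NA, 1, 2), pch = c(16, NA, NA), bty = "n")
  invisible(x)
}

#' Simulate noisy tissue curves from a fitted model
#'
#' Draws replicate tissue curves by adding Gaussian noise to the fitted model
#' curve, with standard deviation peak tissue concentration / `snr`.
#'
#' @param object a `perfusion_fit`.
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param snr peak signal-to-noise ratio of the replicates.
#' @param ... unused.
#' @return matrix `n_points x nsim` of simulated tissue curves.
#' @export
simulate.perfusion_fit <- function(object, nsim = 1, seed = NULL, snr = 20, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd <- max(object$fitted) / snr
  matrix(object$fitted, length(object$fitted), nsim) +
    matrix(stats::rnorm(length(object$fitted) * nsim, 0, sd),
           length(object$fitted), nsim)
}
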