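test_that("Fermi impulse response follows its closed form", {
  expect_equal(fermi_irf(5, A = 2, mu = 5, k = 0.5), 2 / 2 + 0)
  expect_equal(fermi_irf(7, 1, 5, 0.5), 1 / (exp(1) + 1), tolerance = 1e-9)
  expect_equal(fermi_irf(7, 1, 5, 0.5), 0.26894, tolerance = 1e-5)
  # large k approaches a step at mu
  t <- seq(0, 10, 0.5)
  hard <- fermi_irf(t, 1, 5, 1e4)
  expect_equal(hard[t < 5], rep(1, sum(t < 5)), tolerance = 1e-6)
  expect_equal(hard[t > 5], rep(0, sum(t > 5)), tolerance = 1e-6)
  expect_true(all(diff(fermi_irf(t, 1, 3, 0.4)) <= 0))
  expect_error(fermi_irf(1, 1, 1, -2), "non-negative")
})

test_that("first-pass cropping applies the decay and recirculation rules", {
  t <- seq(0, 90, 1)
  a0 <- generate_aif(t)
  cr <- crop_first_pass(a0, a0, t)
  pk <- which.max(a0)
  expect_lte(a0[cr$end] / max(a0), 0.3)           # ends at <=30% of peak
  expect_gt(a0[cr$end - 1] / max(a0), 0.3)        # first sample below
  expect_lte(cr$start, detect_arrival(a0, t)$index)
  # strong early recirculation: crop ends at the inter-pass minimum
  ar <- generate_aif(t, recirc_fraction = 0.6, recirc_delay = 10)
  crr <- crop_first_pass(ar, ar, t)
  post <- seq(which.max(ar), length(ar))
  expect_gt(ar[crr$end] / max(ar), 0.25)  # stopped before the 30% decay
  expect_lt(ar[crr$end + 1], max(ar[post]))  # at a local dip
  expect_error(crop_first_pass(a0, a0[1:50], t), "match")
})

test_that("matched-model fits recover the generating parameters", {
  cp <- curve_pair("fermi", kinetic_params(F_p = 2, fermi_A = 2.2,
                                           fermi_mu = 4, fermi_k = 0.25))
  cr <- crop_first_pass(cp$aif, cp$tissue, cp$t)
  ft <- fit_fermi(cr$aif, cr$tissue, cr$times)
  expect_true(ft$converged)
  expect_lt(abs(ft$F_p - 2) / 2, 0.01)
  # doubling the tissue doubles MBF and leaves the shape parameters alone
  f2 <- fit_fermi(cr$aif, 2 * cr$tissue, cr$times)
  expect_equal(f2$F_p, 2 * ft$F_p, tolerance = 0.01)
  expect_equal(f2$params$fermi_k, ft$params$fermi_k, tolerance = 0.05)
  # 2CXM recovery at the canonical parameter set
  c2 <- curve_pair("2cxm", kinetic_params(F_p = 1, v_p = 0.08, v_e = 0.2,
                                          PS = 0.5))
  arr <- max(detect_arrival(c2$aif, c2$t)$index - 1, 1)
  idx <- arr:length(c2$t)
  f2x <- fit_2cxm(c2$aif[idx], c2$tissue[idx], c2$t[idx])
  expect_lt(abs(f2x$F_p - 1), 0.02)
  expect_lt(abs(f2x$params$v_p - 0.08) / 0.08, 0.02)
  expect_lt(abs(f2x$params$v_e - 0.2) / 0.2, 0.02)
  expect_lt(abs(f2x$params$PS - 0.5) / 0.5, 0.02)
  # degenerate PS = 0 phantom
  c0 <- curve_pair("2cxm", kinetic_params(F_p = 1, v_p = 0.08, v_e = 0.2,
                                          PS = 0))
  f0 <- fit_2cxm(c0$aif[idx], c0$tissue[idx], c0$t[idx])
  expect_lt(f0$params$PS, 0.01)
  expect_lt(abs(f0$F_p - 1), 0.02)
})

test_that("Fermi fit on 2CXM tissue stays within the cross-model bound", {
  c2 <- curve_pair("2cxm", kinetic_params(F_p = 1, v_p = 0.08, v_e = 0.2,
                                          PS = 0.5))
  cr <- crop_first_pass(c2$aif, c2$tissue, c2$t)
  fx <- fit_fermi(cr$aif, cr$tissue, cr$times)
  expect_lt(abs(fx$F_p - 1), 0.10)
})

test_that("doubling the AIF halves fitted MBF", {
  cp <- curve_pair("fermi", kinetic_params(F_p = 2, fermi_A = 2.2,
                                           fermi_mu = 4, fermi_k = 0.25))
  cr <- crop_first_pass(cp$aif, cp$tissue, cp$t)
  f1 <- fit_fermi(cr$aif, cr$tissue, cr$times)
  f2 <- fit_fermi(2 * cr$aif, cr$tissue, cr$times)
  expect_equal(f2$F_p, f1$F_p / 2, tolerance = 0.01)
})

test_that("Tikhonov deconvolution matches direct inversion at lambda 0", {
  # 5-sample system with a discrete unit impulse AIF: identity kernel
  h <- 1
  tt <- seq(0, 4, h)
  aif <- c(1 / h, 0, 0, 0, 0)
  tis <- c(0.9, 0.7, 0.5, 0.35, 0.2)
  tk <- deconvolve_tikhonov(aif, tis, tt, lambda = 0)
  expect_equal(tk$irf / 60, tis, tolerance = 1e-8)
  # generic nonsingular 5-sample system equals solve(A, c)
  aif2 <- c(2, 1.5, 1, 0.6, 0.3)
  A <- matrix(0, 5, 5)
  for (j in 1:5) A[j:5, j] <- aif2[1:(5 - j + 1)] * h
  irf_true <- c(0.8, 0.5, 0.3, 0.2, 0.15)
  tis2 <- as.vector(A %*% irf_true)
  tk2 <- deconvolve_tikhonov(aif2, tis2, tt, lambda = 0)
  expect_equal(tk2$irf / 60, irf_true, tolerance = 1e-8)
  # singular at lambda 0 advises regularization
  expect_error(deconvolve_tikhonov(c(0, 1, 2, 1, 0.5), tis, tt, lambda = 0),
               "lambda > 0")
})

test_that("Tikhonov recovers phantom MBF across a lambda sweep", {
  cp <- curve_pair("fermi", kinetic_params(F_p = 2, fermi_A = 2.2,
                                           fermi_mu = 4, fermi_k = 0.25))
  cr <- crop_first_pass(cp$aif, cp$tissue, cp$t)
  tk <- deconvolve_tikhonov(cr$aif, cr$tissue, cr$times)  # L-curve lambda
  expect_lt(abs(tk$F_p - 2) / 2, 0.1)
  # recovered impulse response is causal and decays
  expect_gt(tk$irf[2], tk$irf[10])
})

test_that("Patlak analysis estimates K_trans and v_p", {
  t <- seq(0, 90, 1)
  aifp <- generate_aif(t) / 0.58
  # pure plasma signal: zero slope, intercept v_p
  f0 <- fit_patlak(aifp + 0.01, 0.07 * (aifp + 0.01), t)
  expect_lt(abs(f0$params$K_trans), 1e-6)
  expect_equal(f0$params$v_p, 0.07, tolerance = 1e-6)
  # extended Kety-Tofts forward data, early window
  kep <- 0.3 / 0.25 / 60
  conv <- qperf:::conv_uniform(exp(-kep * t), aifp, 1)
  tis <- 0.05 * aifp + (0.3 / 60) * conv
  fk <- fit_patlak(aifp, tis, t)
  expect_lt(abs(fk$params$K_trans - 0.3) / 0.3, 0.05)
  # decaying tissue: negative slope clamped to zero with a flag
  fn <- fit_patlak(aifp + 0.05, 0.1 * (aifp + 0.05) * exp(-t / 20), t)
  expect_equal(fn$params$K_trans, 0)
  expect_true(length(fn$flags) > 0)
  expect_error(fit_patlak(c(0, 0, 1), c(0, 0, 0.1), c(0, 1, 2)), "3 valid")
})

test_that("arrival search finds the delayed myocardial response", {
  c2 <- curve_pair("2cxm", kinetic_params(F_p = 1, v_p = 0.08, v_e = 0.2,
                                          PS = 0.5))
  tisd <- qperf:::interp_curve(c2$t + 3, c2$tissue, c2$t)
  cr <- crop_first_pass(c2$aif, c2$aif, c2$t)
  idx <- cr$start:min(cr$end + 15, length(c2$t))
  bs <- arrival_search(fit_fermi, c2$aif[idx], tisd[idx], c2$t[idx],
                       delays = 0:5)
  expect_equal(bs$arrival_offset, 3)
  # duplicate candidates tie toward the earliest listed
  bt <- arrival_search(fit_fermi, c2$aif[idx], tisd[idx], c2$t[idx],
                       delays = c(3, 3))
  expect_equal(bt$arrival_offset, 3)
  expect_error(arrival_search(fit_fermi, c2$aif[idx], tisd[idx], c2$t[idx],
                              delays = numeric(0)), "empty")
})

test_that("deconvolution tolerates non-uniform cardiac gating", {
  set.seed(4)
  rr <- sample(c(800, 1000, 1200), 70, replace = TRUE)
  tn <- cumsum(c(0, rr)) / 1000
  p <- kinetic_params(F_p = 1, v_p = 0.08, v_e = 0.2, PS = 0.5)
  aifn <- generate_aif(tn) / 0.58
  tisn <- forward_tissue(aifn, p, "2cxm", tn)
  arrn <- max(detect_arrival(aifn, tn)$index - 1, 1)
  f_nu <- fit_2cxm(aifn[arrn:length(tn)], tisn[arrn:length(tn)],
                   tn[arrn:length(tn)])
  tu <- seq(0, max(tn), 1)
  aifu <- qperf:::interp_curve(tn, aifn, tu)
  tisu <- qperf:::interp_curve(tn, tisn, tu)
  arru <- max(detect_arrival(aifu, tu)$index - 1, 1)
  f_u <- fit_2cxm(aifu[arru:length(tu)], tisu[arru:length(tu)],
                  tu[arru:length(tu)])
  expect_lt(abs(f_nu$F_p - f_u$F_p) / f_u$F_p, 0.03)
})

test_that("perfusion_fit methods behave like a fitted model object", {
  cp <- curve_pair("fermi", kinetic_params(F_p = 2, fermi_A = 2.2,
                                           fermi_mu = 4, fermi_k = 0.25))
  cr <- crop_first_pass(cp$aif, cp$tissue, cp$t)
  fit <- fit_fermi(cr$aif, cr$tissue, cr$times)
  expect_s3_class(fit, "perfusion_fit")
  expect_named(coef(fit), c("fermi_A", "fermi_mu", "fermi_k", "fermi_offset"))
  expect_equal(fitted(fit) + residuals(fit), cr$tissue)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, cr$times), fitted(fit), tolerance = 1e-9)
  s <- summary(fit)
  expect_s3_class(s, "summary.perfusion_fit")
  expect_output(print(fit), "MBF")
  expect_output(print(s), "Perfusion fit")
  sim <- simulate(fit, nsim = 3, seed = 9, snr = 20)
  expect_equal(dim(sim), c(length(cr$times), 3))
  expect_lt(abs(sd(sim[, 1] - fitted(fit)) - max(fitted(fit)) / 20), 0.02)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  # mbf under the blood-flow convention: F_p / (1 - Hct) / density
  expect_equal(fit$mbf, fit$F_p / 0.58 / 1.05, tolerance = 1e-9)
  cfgp <- quant_config(flow_convention = "plasma")
  fp <- fit_fermi(cr$aif, cr$tissue, cr$times, config = cfgp)
  expect_equal(fp$mbf, fp$F_p / 1.05, tolerance = 1e-9)
})
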