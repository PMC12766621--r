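#' Tissue residue functions
#'
#' Residue function R(t): the fraction of an instantaneous tracer bolus still
#' present in the tissue at time t after an impulse arterial input. All
#' residue functions satisfy R(0) = 1 and are monotone non-increasing. Flows
#' (`F_p`, `PS`, `K_trans`) are in mL/min per mL of tissue; volumes (`v_p`,
#' `v_e`) are fractions; times are in seconds.
#'
#' @param t times in seconds (vector).
#' @param params named list of kinetic parameters (see [kinetic_params()]).
#' @param model one of `"2cxm"`, `"one_compartment"`, `"fermi"`,
#'   `"kety_tofts"`.
#' @return R(t) values.
#' @export
residue_function <- function(t, params, model = c("2cxm", "one_compartment",
                                                  "fermi", "kety_tofts")) {
  model <- match.arg(model)
  switch(model,
    "2cxm" = {
      bi <- biexp_2cxm(params$F_p, params$v_p, params$v_e, params$PS)
      (bi$c1 * exp(bi$l1 * t) + bi$c2 * exp(bi$l2 * t)) / (params$F_p / 60)
    },
    one_compartment = exp(-(params$F_p / 60) * t / params$v_p),
    fermi = {
      i0 <- fermi_irf(0, params$fermi_A, params$fermi_mu, params$fermi_k, 0)
      fermi_irf(t, params$fermi_A, params$fermi_mu, params$fermi_k, 0) / i0
    },
    kety_tofts = exp(-(params$K_trans / 60) * t / params$v_e))
}

# Closed-form bi-exponential impulse response of the two-compartment exchange
# model: I(t) = c1 exp(l1 t) + c2 exp(l2 t), with I(0) = F_p (per second) and
# I'(0) = -(F_p/60)^2 / v_p. Vectorized over parameter vectors; rates are
# converted to per-second units internally.
biexp_2cxm <- function(F_p, v_p, v_e, PS) {
  fps <- F_p / 60
  pss <- PS / 60
  tr <- -((fps + pss) / v_p + pss / v_e)
  dt2 <- fps * pss / (v_p * v_e)
  disc <- sqrt(pmax(tr^2 - 4 * dt2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  sep <- l1 - l2
  i0 <- fps
  di0 <- -fps^2 / v_p
  c1 <- ifelse(sep > 1e-12, (di0 - l2 * i0) / sep, i0)
  c2 <- i0 - c1
  list(l1 = l1, l2 = l2, c1 = c1, c2 = c2)
}

#' Kinetic parameter set
#'
#' @param F_p plasma flow in mL/min/mL of tissue.
#' @param v_p plasma volume fraction.
#' @param v_e extravascular-extracellular volume fraction (`v_p + v_e <= 1`).
#' @param PS permeability-surface-area product in mL/min/mL.
#' @param K_trans transfer constant in mL/min/mL (Kety-Tofts / Patlak).
#' @param fermi_A,fermi_mu,fermi_k,fermi_offset Fermi impulse-response
#'   parameters: amplitude (min^-1), plateau width mu (s), decay rate k
#'   (s^-1), and additive offset.
#' @return a list of class `kinetic_params`; the total distribution volume
#'   `v = v_p + v_e` is filled in.
#' @export
kinetic_params <- function(F_p = 1, v_p = 0.08, v_e = 0.2, PS = 0.5,
                           K_trans = NULL, fermi_A = NULL, fermi_mu = NULL,
                           fermi_k = NULL, fermi_offset = 0) {
  vals <- c(F_p = F_p, v_p = v_p, v_e = v_e, PS = PS)
  if (any(vals < 0)) stop("kinetic parameters must be non-negative")
  if (v_p + v_e > 1) stop("v_p + v_e must not exceed 1")
  structure(list(F_p = F_p, v_p = v_p, v_e = v_e, PS = PS, v = v_p + v_e,
                 K_trans = K_trans %||% PS, fermi_A = fermi_A,
                 fermi_mu = fermi_mu, fermi_k = fermi_k,
                 fermi_offset = fermi_offset),
            class = "kinetic_params")
}
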