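#' Construct a binary spin bath parameter set
#'
#' Parameters of the two-pool (binary spin bath) model for one voxel or
#' tissue class: a free (liquid) proton pool with full Bloch dynamics and a
#' semisolid (bound) pool represented by its longitudinal magnetization and
#' an absorption lineshape. `f` is the bound-to-free pool-size ratio
#' (bound proton fraction), `kf` the pseudo-first-order exchange rate from
#' the free to the bound pool; detailed balance fixes the reverse rate at
#' `kb = kf / f`.
#'
#' @param m0 equilibrium free-pool magnetization (arbitrary signal units).
#' @param f bound proton fraction, in `[0, 1)`; `f = 0` requires `kf = 0`.
#' @param kf free-to-bound exchange rate, 1/s.
#' @param t1f,t2f free-pool relaxation times, seconds (`t2f < t1f`).
#' @param t1b,t2b bound-pool relaxation times, seconds; fixed by convention
#'   (defaults 1.0 s and 12 microseconds) since only `f`, `kf`, `t2f` are
#'   estimated from data.
#' @param lineshape bound-pool absorption lineshape, `"super_lorentzian"`
#'   (default, brain tissue) or `"gaussian"`.
#' @return A list of class `"two_pool_params"`.
#' @examples
#' two_pool_params(m0 = 1000, f = 0.12, kf = 3, t1f = 1.1, t2f = 0.07)
#' @export
two_pool_params <- function(m0 = 1, f = 0.1, kf = 2, t1f = 1, t2f = 0.08,
                            t1b = 1.0, t2b = 12e-6,
                            lineshape = c("super_lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  if (m0 < 0) stop("m0 must be non-negative")
  if (f < 0 || f >= 1) stop("f must be in [0, 1)")
  if (kf < 0) stop("kf must be non-negative")
  if (f == 0 && kf > 0) stop("f = 0 requires kf = 0 (no bound pool)")
  for (nm in c("t1f", "t2f", "t1b", "t2b")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0) stop(nm, " must be strictly positive")
  }
  if (t2f >= t1f) stop("t2f must be smaller than t1f")
  if (t2b >= t2f) stop("t2b must be much smaller than t2f")
  structure(list(m0 = m0, f = f, kf = kf, t1f = t1f, t1b = t1b,
                 t2f = t2f, t2b = t2b, lineshape = lineshape),
            class = "two_pool_params")
}

#' Spoiled gradient echo (SPGR) signal
#'
#' Ideal-spoiling SPGR steady-state signal
#' S = m0 sin(a) (1 - E1) / (1 - E1 cos(a)), E1 = exp(-TR/T1).
#'
#' @param m0 equilibrium magnetization (signal units).
#' @param t1f longitudinal relaxation time, seconds.
#' @param seq an [acquisition_spec()] with `kind = "spgr"`.
#' @return Signal in the units of `m0`.
#' @examples
#' spgr_signal(1, 1.0, acquisition_spec("spgr", 15, 30))
#' @export
spgr_signal <- function(m0, t1f, seq) {
  seq <- as_acquisition_spec(seq)
  if (seq$kind != "spgr") stop("spgr_signal requires an SPGR acquisition")
  if (any(t1f <= 0)) stop("t1f must be strictly positive")
  a <- seq$flip_deg * pi / 180
  e1 <- exp(-seq$tr_ms * 1e-3 / t1f)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Two-pool bSSFP steady-state signal (closed form)
#'
#' Steady-state on-resonance, alternating-phase balanced SSFP signal of the
#' binary spin bath model. The free pool follows balanced SSFP dynamics; the
#' bound pool is saturated during each RF pulse at the mean rate
#' W = pi * omega1_rms^2 * G(0) (see [mean_saturation_rate()]) and exchanges
#' with the free pool at rates `kf` and `kb = kf/f`. The RF pulse is treated
#' as an instantaneous rotation of the free pool combined with a bound-pool
#' saturation factor exp(-W trf); inter-pulse relaxation and exchange are
#' propagated exactly through the 2x2 longitudinal exchange-relaxation
#' matrix. The returned amplitude is referenced to TE = 0 (the echo train
#' extrapolated to the pulse center); for `f = 0` it reduces exactly to the
#' single-pool form m0 sin(a) (1-E1) / (1 - (E1-E2) cos(a) - E1 E2).
#'
#' @param p a [two_pool_params()] set; vectorized over parameter values if
#'   plain numeric vectors of equal length are supplied in a list.
#' @param seq an [acquisition_spec()] with `kind = "bssfp"`, or a protocol
#'   data frame of bSSFP rows (vectorized over rows).
#' @return Signal amplitude(s), strictly positive for valid parameters.
#' @examples
#' p <- two_pool_params(m0 = 1, f = 0.12, kf = 3, t1f = 1.1, t2f = 0.07)
#' seq <- acquisition_spec("bssfp", 35, 4.81, 1.38)
#' bssfp_two_pool_signal(p, seq)
#' @export
bssfp_two_pool_signal <- function(p, seq) {
  if (is.data.frame(seq)) {
    if (any(seq$kind != "bssfp"))
      stop("all protocol rows must be bSSFP acquisitions")
    rows <- seq
  } else {
    s <- as_acquisition_spec(seq)
    if (s$kind != "bssfp") stop("bssfp_two_pool_signal requires bSSFP")
    rows <- data.frame(flip_deg = s$flip_deg, tr_ms = s$tr_ms,
                       trf_ms = s$trf_ms, pulse_shape = s$pulse_shape)
  }
  if (!"pulse_shape" %in% names(rows)) rows$pulse_shape <- "rectangular"
  g0 <- lineshape_value(p$lineshape, p$t2b, 0)
  alpha <- rows$flip_deg * pi / 180
  trf <- rows$trf_ms * 1e-3
  if (any(!is.finite(trf)) || any(trf <= 0))
    stop("bSSFP rows require a positive RF pulse duration")
  rmsfac <- vapply(rows$pulse_shape, pulse_rms_factor, numeric(1))
  w <- pi * (alpha / trf * rmsfac)^2 * g0
  bssfp_signal_core(p$m0, p$f, p$kf, p$t1f, p$t1b, p$t2f,
                    alpha, rows$tr_ms * 1e-3, trf, w)
}

# Elementwise closed-form core; every argument may be a vector (recycled).
# alpha in radians, tr/trf in seconds, w in 1/s.
bssfp_signal_core <- function(m0, f, kf, t1f, t1b, t2f, alpha, tr, trf, w) {
  if (any(f < 0) || any(f >= 1)) stop("f must be in [0, 1)")
  if (any(kf < 0) || any(t1f <= 0) || any(t2f <= 0) || any(t1b <= 0))
    stop("rates and relaxation times must be non-negative/positive")
  if (any(f == 0 & kf > 0)) stop("f = 0 requires kf = 0")
  r1f <- 1 / t1f
  r1b <- 1 / t1b
  kb <- ifelse(f > 0, kf / f, 0)
  m0f <- m0
  m0b <- f * m0
  # 2x2 longitudinal generator L = [[-(r1f+kf), kb], [kf, -(r1b+kb)]]
  la <- -(r1f + kf); lb <- kb; lc <- kf; ld <- -(r1b + kb)
  mu <- (la + ld) / 2
  dd <- sqrt(((la - ld) / 2)^2 + lb * lc)
  # expm(L*tr) = e^{mu tr} [cosh(dd tr) I + sinh(dd tr)/dd (L - mu I)]
  ch <- cosh(dd * tr)
  sh_over <- ifelse(dd * tr > 1e-8, sinh(dd * tr) / dd, tr * (1 + (dd * tr)^2 / 6))
  em <- exp(mu * tr)
  e11 <- em * (ch + sh_over * (la - mu))
  e12 <- em * (sh_over * lb)
  e21 <- em * (sh_over * lc)
  e22 <- em * (ch + sh_over * (ld - mu))
  # affine part over TR: a = (I - E) (m0f, m0b)
  a1 <- (1 - e11) * m0f - e12 * m0b
  a2 <- -e21 * m0f + (1 - e22) * m0b
  e2 <- exp(-tr / t2f)
  fw <- exp(-w * trf)
  ca <- cos(alpha); sa <- sin(alpha)
  g <- e2 * sa / (1 + e2 * ca)
  h <- ca + sa * g
  det <- (1 - e11 * h) * (1 - e22 * fw) - e12 * fw * e21 * h
  zf <- (a1 * (1 - e22 * fw) + a2 * e12 * fw) / det
  abs(sa * zf / (1 + e2 * ca))
}

# Apparent (observed) longitudinal relaxation time of the coupled two-pool
# system: reciprocal of the slowest-decaying eigenmode of the exchange-
# relaxation matrix. Inverse of derive_t1f().
#' Observed T1 of a two-pool system
#'
#' The mono-exponential T1 an inversion/saturation recovery or VFA
#' experiment observes: the reciprocal of the slowest-decaying longitudinal
#' eigenmode of the 2x2 exchange-relaxation matrix.
#'
#' @param p a [two_pool_params()] set (or list with `f`, `kf`, `t1f`, `t1b`).
#' @return Observed T1 in seconds.
#' @export
observed_t1 <- function(p) {
  if (p$f == 0) return(p$t1f)
  kb <- p$kf / p$f
  la <- -(1 / p$t1f + p$kf); lb <- kb; lc <- p$kf; ld <- -(1 / p$t1b + kb)
  mu <- (la + ld) / 2
  dd <- sqrt(((la - ld) / 2)^2 + lb * lc)
  -1 / (mu + dd) # slow eigenvalue is the larger (closer to zero)
}
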