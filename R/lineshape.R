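#' Absorption lineshape of the semisolid (bound) proton pool
#'
#' Evaluates the absorption lineshape G(offset) of the macromolecular pool,
#' in seconds, at a given frequency offset from resonance. The Gaussian
#' lineshape has the closed form
#' G(d) = (t2b / sqrt(2*pi)) * exp(-(2*pi*d*t2b)^2 / 2).
#' The super-Lorentzian, the standard model for semisolid protons in tissue,
#' integrates a Lorentzian over fiber orientation,
#' G(d) = int_0^1 sqrt(2/pi) * t2b/|3u^2-1| * exp(-2*(2*pi*d*t2b/(3u^2-1))^2) du,
#' which diverges on resonance; following common practice the value for
#' offsets below `cutoff_hz` (default 1 kHz) is obtained by extrapolating a
#' quadratic fitted to the lineshape just above the cutoff.
#'
#' @param lineshape `"gaussian"` or `"super_lorentzian"`.
#' @param t2b bound-pool transverse relaxation time in seconds (order 1e-5).
#' @param offset_hz frequency offset in Hz (vectorized, non-negative).
#' @param cutoff_hz extrapolation cutoff for the super-Lorentzian singularity.
#' @return Lineshape value(s) in seconds.
#' @examples
#' lineshape_value("gaussian", 12e-6, 0)        # t2b/sqrt(2*pi)
#' lineshape_value("super_lorentzian", 12e-6, 0) # extrapolated on-resonance
#' @export
lineshape_value <- function(lineshape = c("super_lorentzian", "gaussian"),
                            t2b, offset_hz, cutoff_hz = 1000) {
  lineshape <- match.arg(lineshape)
  if (!is.finite(t2b) || t2b <= 0) stop("t2b must be positive")
  if (any(!is.finite(offset_hz)) || any(offset_hz < 0))
    stop("offset_hz must be finite and non-negative")
  if (lineshape == "gaussian") {
    return(t2b / sqrt(2 * pi) * exp(-(2 * pi * offset_hz * t2b)^2 / 2))
  }
  out <- numeric(length(offset_hz))
  hi <- offset_hz >= cutoff_hz
  if (any(hi)) out[hi] <- vapply(offset_hz[hi], super_lorentzian_raw,
                                 numeric(1), t2b = t2b)
  if (any(!hi)) {
    # quadratic in offset^2 through three points at and above the cutoff
    d <- cutoff_hz * c(1, 1.5, 2)
    g <- vapply(d, super_lorentzian_raw, numeric(1), t2b = t2b)
    co <- solve(outer(d^2, 0:2, `^`), g)
    x2 <- offset_hz[!hi]^2
    out[!hi] <- co[1] + co[2] * x2 + co[3] * x2^2
  }
  out
}

# Orientation integral of the super-Lorentzian, valid away from resonance.
super_lorentzian_raw <- function(offset_hz, t2b) {
  f <- function(u) {
    s <- abs(3 * u^2 - 1)
    sqrt(2 / pi) * t2b / s * exp(-2 * (2 * pi * offset_hz * t2b / s)^2)
  }
  # integrand is singular (but integrable) at u = 1/sqrt(3); split there
  u0 <- 1 / sqrt(3)
  i1 <- stats::integrate(f, 0, u0, rel.tol = 1e-9, abs.tol = 0,
                         subdivisions = 500L)
  i2 <- stats::integrate(f, u0, 1, rel.tol = 1e-9, abs.tol = 0,
                         subdivisions = 500L)
  i1$value + i2$value
}

#' Mean bound-pool saturation rate of an RF pulse
#'
#' Computes the root-mean-square on-resonance RF amplitude that delivers the
#' prescribed flip angle within the pulse duration, and the resulting mean
#' saturation rate of the bound pool, W = pi * omega1_rms^2 * G(0). For a
#' rectangular pulse omega1 is constant at alpha/trf; for the sinc shape a
#' Hann-windowed sinc envelope (two side lobes) is scaled to the same flip
#' angle and its RMS amplitude used.
#'
#' @param seq an [acquisition_spec()] (or coercible); must be bSSFP with a
#'   finite pulse duration.
#' @param lineshape,t2b passed to [lineshape_value()]; `t2b` in seconds.
#' @param offset_hz effective offset at which the lineshape is evaluated
#'   (0 for on-resonance bSSFP).
#' @return A list of class `"saturation_context"` with elements
#'   `omega1_rms` (rad/s), `g0` (s) and `w` (1/s).
#' @examples
#' seq <- acquisition_spec("bssfp", 35, 4.81, 1.0)
#' mean_saturation_rate(seq, "gaussian", 12e-6)
#' @export
mean_saturation_rate <- function(seq, lineshape = "super_lorentzian",
                                 t2b = 12e-6, offset_hz = 0) {
  seq <- as_acquisition_spec(seq)
  if (seq$kind != "bssfp")
    stop("mean_saturation_rate is defined for bSSFP acquisitions")
  if (!is.finite(seq$trf_ms))
    stop("RF pulse duration trf_ms is unset")
  alpha <- seq$flip_deg * pi / 180
  trf <- seq$trf_ms * 1e-3
  omega1_rms <- alpha / trf * pulse_rms_factor(seq$pulse_shape)
  g0 <- lineshape_value(lineshape, t2b, offset_hz)
  structure(list(omega1_rms = omega1_rms, g0 = g0,
                 w = pi * omega1_rms^2 * g0),
            class = "saturation_context")
}

# RMS amplitude of a unit-flip pulse relative to a rectangular pulse of the
# same duration: sqrt(mean(e^2)) / mean(e) for the envelope e(t).
pulse_rms_factor <- function(pulse_shape) {
  if (pulse_shape == "rectangular") return(1)
  t <- seq(-1, 1, length.out = 4096L)
  e <- sinc_fn(3 * t) * (0.5 + 0.5 * cos(pi * t)) # Hann-windowed, 2 side lobes
  sqrt(mean(e^2)) / mean(e)
}

sinc_fn <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
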