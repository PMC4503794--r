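#' Variable flip angle T1 fit for one voxel
#'
#' Estimates T1 and M0 from an SPGR series acquired at several flip angles
#' and a common TR, by the standard linearization of the SPGR equation:
#' regressing y = S/sin(a) on x = S/tan(a) gives slope E1 = exp(-TR/T1) and
#' intercept M0 (1 - E1). An optional Levenberg-Marquardt refinement of the
#' nonlinear model follows the linear solution.
#'
#' @param signals numeric vector of measured signals (>= 2, typically 3).
#' @param flips_deg flip angles in degrees, same length as `signals`.
#' @param tr_ms repetition time in milliseconds (common to the series).
#' @param refine if `TRUE`, polish the linearized solution by nonlinear
#'   least squares.
#' @return A list with `t1` (seconds), `m0` (signal units) and `valid`;
#'   degenerate inputs (slope outside (0, 1), non-positive signals) yield
#'   `valid = FALSE` with `NA` estimates rather than an error.
#' @examples
#' seqs <- lapply(c(5, 15, 25), function(a) acquisition_spec("spgr", a, 30))
#' s <- vapply(seqs, function(q) spgr_signal(1, 1.0, q), numeric(1))
#' fit_vfa_t1(s, c(5, 15, 25), 30)
#' @export
fit_vfa_t1 <- function(signals, flips_deg, tr_ms, refine = FALSE) {
  invalid <- list(t1 = NA_real_, m0 = NA_real_, valid = FALSE)
  if (length(signals) != length(flips_deg) || length(signals) < 2)
    stop("need >= 2 signals with matching flip angles")
  if (length(unique(flips_deg)) < 2)
    stop("need >= 2 distinct flip angles")
  if (any(!is.finite(signals)) || any(signals < 0)) return(invalid)
  if (all(signals == 0)) return(invalid)
  # equal signals at distinct flips cannot come from the SPGR model
  if (diff(range(signals)) <= 1e-12 * max(signals)) return(invalid)
  a <- flips_deg * pi / 180
  y <- signals / sin(a)
  x <- signals / tan(a)
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) return(invalid)
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  if (!is.finite(slope) || slope <= 0 || slope >= 1 || intercept <= 0)
    return(invalid)
  tr <- tr_ms * 1e-3
  t1 <- -tr / log(slope)
  m0 <- intercept / (1 - slope)
  if (refine) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(log_t1 = log(t1), log_m0 = log(m0)),
        fn = function(par) {
          e1 <- exp(-tr / exp(par[["log_t1"]]))
          exp(par[["log_m0"]]) * sin(a) * (1 - e1) / (1 - e1 * cos(a)) - signals
        },
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      t1 <- exp(fit$par[["log_t1"]])
      m0 <- exp(fit$par[["log_m0"]])
    }
  }
  list(t1 = t1, m0 = m0, valid = TRUE)
}

#' Voxel-wise variable flip angle T1 map
#'
#' Applies [fit_vfa_t1()] independently to every voxel inside the mask.
#'
#' @param vfa_data 4-D array (x, y, z, flip) of SPGR signals.
#' @param mask logical or 0/1 3-D array matching the spatial grid.
#' @param flips_deg,tr_ms acquisition parameters of the series.
#' @param refine passed to [fit_vfa_t1()].
#' @return A list of class `"t1_map"` with 3-D arrays `t1`, `m0`, `valid`
#'   (`NA` outside the mask / at degenerate voxels).
#' @export
fit_vfa_t1_map <- function(vfa_data, mask, flips_deg, tr_ms, refine = FALSE) {
  dims <- dim(vfa_data)
  if (length(dims) != 4 || dims[4] != length(flips_deg))
    stop("vfa_data must be 4-D with one volume per flip angle")
  if (!all(dim(mask) == dims[1:3])) stop("mask does not match the data grid")
  mask <- array(as.logical(mask), dim = dims[1:3])
  t1 <- m0 <- array(NA_real_, dims[1:3])
  valid <- array(FALSE, dims[1:3])
  sig <- matrix(vfa_data, ncol = dims[4])
  idx <- which(mask)
  for (i in idx) {
    fit <- fit_vfa_t1(sig[i, ], flips_deg, tr_ms, refine)
    t1[i] <- fit$t1
    m0[i] <- fit$m0
    valid[i] <- fit$valid
  }
  structure(list(t1 = t1, m0 = m0, valid = valid, mask = mask,
                 flips_deg = flips_deg, tr_ms = tr_ms),
            class = "t1_map")
}

#' Free-pool T1 from the observed T1 of the coupled system
#'
#' In the two-pool system the mono-exponential T1 observed by a VFA (or
#' recovery) experiment is the reciprocal of the slowest-decaying
#' longitudinal eigenmode of the exchange-relaxation matrix built from
#' 1/t1f, 1/t1b, kf and kb = kf/f. This function inverts that relation:
#' given the observed T1 and current (f, kf, t1b), it returns the free-pool
#' t1f for which the slow eigenmode rate equals 1/t1_observed. Substituting
#' lambda = -1/t1_observed into the characteristic polynomial yields the
#' closed form
#' R1f = R1obs - kf + kf kb / (R1b + kb - R1obs).
#'
#' @param t1_observed observed T1, seconds.
#' @param f bound proton fraction; `f = 0` returns `t1_observed` unchanged.
#' @param kf free-to-bound exchange rate, 1/s.
#' @param t1b bound-pool T1, seconds.
#' @return `t1f` in seconds, or `NA` if no positive solution exists (the
#'   voxel should be flagged invalid by the caller).
#' @examples
#' derive_t1f(1.0, f = 0.1, kf = 3, t1b = 1.0)
#' derive_t1f(1.0, f = 0, kf = 0, t1b = 1.0) # == 1.0
#' @export
derive_t1f <- function(t1_observed, f, kf, t1b = 1.0) {
  if (any(t1_observed <= 0) || any(t1b <= 0) || any(f < 0) || any(f >= 1) ||
      any(kf < 0))
    stop("invalid inputs to derive_t1f")
  r1obs <- 1 / t1_observed
  kb <- ifelse(f > 0, kf / f, 0)
  denom <- 1 / t1b + kb - r1obs
  r1f <- ifelse(f > 0 & kf > 0,
                r1obs - kf + kf * kb / denom,
                r1obs)
  bad <- !is.finite(r1f) | r1f <= 0 | (f > 0 & kf > 0 & denom <= 0)
  out <- 1 / r1f
  out[bad] <- NA_real_
  out
}
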