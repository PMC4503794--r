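#' Options for the voxel-wise qMT fit
#'
#' Starting values, box bounds and fixed constants for the
#' Levenberg-Marquardt fit of (m0, f, kf, t2f). Defaults are physiological
#' brain ranges; the starting point is a single deterministic init with m0
#' scale-matched to the data.
#'
#' @param init named numeric vector with starting `f`, `kf` (1/s) and `t2f`
#'   (s); `m0` is initialized from the data.
#' @param lower,upper named bounds for `f`, `kf`, `t2f`.
#' @param t1_mode how the free-pool T1 is obtained from the observed T1:
#'   `"eigen_corrected"` (slowest-eigenmode inversion, see [derive_t1f()])
#'   or `"observed_as_t1f"` (use the observed T1 directly).
#' @param t1b,t2b,lineshape fixed bound-pool constants of the model.
#' @param max_iterations,tolerance Levenberg-Marquardt controls (relative
#'   `ftol`/`ptol`).
#' @return A list of class `"qmt_fit_options"`.
#' @export
qmt_fit_options <- function(init = c(f = 0.1, kf = 2, t2f = 0.08),
                            lower = c(f = 0.001, kf = 0.1, t2f = 0.01),
                            upper = c(f = 0.5, kf = 20, t2f = 0.3),
                            t1_mode = c("eigen_corrected", "observed_as_t1f"),
                            t1b = 1.0, t2b = 12e-6,
                            lineshape = "super_lorentzian",
                            max_iterations = 100L, tolerance = 1e-10) {
  t1_mode <- match.arg(t1_mode)
  for (nm in c("f", "kf", "t2f")) {
    if (!(lower[[nm]] <= init[[nm]] && init[[nm]] <= upper[[nm]]))
      stop("bounds must bracket the starting value for ", nm)
  }
  if (tolerance <= 0) stop("tolerance must be positive")
  structure(list(init = init, lower = lower, upper = upper, t1_mode = t1_mode,
                 t1b = t1b, t2b = t2b, lineshape = lineshape,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "qmt_fit_options")
}

# Precompute per-row pulse constants for a bSSFP protocol.
qmt_row_constants <- function(protocol, opts) {
  stopifnot(all(protocol$kind == "bssfp"))
  alpha <- protocol$flip_deg * pi / 180
  trf <- protocol$trf_ms * 1e-3
  shape <- if ("pulse_shape" %in% names(protocol)) protocol$pulse_shape
           else rep("rectangular", nrow(protocol))
  rmsfac <- vapply(shape, pulse_rms_factor, numeric(1))
  g0 <- lineshape_value(opts$lineshape, opts$t2b, 0)
  list(alpha = alpha, tr = protocol$tr_ms * 1e-3, trf = trf,
       w = pi * (alpha / trf * rmsfac)^2 * g0)
}

#' Fit the two-pool model to one voxel's bSSFP series
#'
#' Levenberg-Marquardt least-squares estimation of (m0, f, kf, t2f) from the
#' measured bSSFP signals, with the free-pool T1 tied to the voxel's
#' observed T1 according to `opts$t1_mode`. Box bounds are enforced by the
#' optimizer; the fit is deterministic given the starting values.
#'
#' @param signals numeric vector of measured bSSFP signals.
#' @param protocol data frame of matching bSSFP protocol rows (one per
#'   signal, >= 4 distinct (flip, TR, trf) combinations).
#' @param t1_observed observed T1 of the voxel, seconds.
#' @param opts a [qmt_fit_options()] object.
#' @return A list with estimates `f`, `kf`, `t2f`, `m0`, `t1f`, and
#'   diagnostics `residual_norm`, `converged`, `niter`, `valid`. Degenerate
#'   input (all-zero or non-finite signals, invalid T1) gives
#'   `valid = FALSE` with `NA` estimates rather than an exception.
#' @examples
#' prot <- default_protocol()
#' bs <- prot[prot$kind == "bssfp", ]
#' truth <- two_pool_params(m0 = 1000, f = 0.12, kf = 3, t1f = 1.05,
#'                          t2f = 0.07)
#' s <- bssfp_two_pool_signal(truth, bs)
#' fit_qmt_voxel(s, bs, t1_observed = observed_t1(truth))
#' @export
fit_qmt_voxel <- function(signals, protocol, t1_observed,
                          opts = qmt_fit_options()) {
  combos <- unique(protocol[, c("flip_deg", "tr_ms", "trf_ms")])
  if (nrow(combos) < 4)
    stop("need >= 4 distinct (flip, TR, trf) combinations to fit 4 parameters")
  if (length(signals) != nrow(protocol))
    stop("signals and protocol rows must match")
  invalid <- list(f = NA_real_, kf = NA_real_, t2f = NA_real_, m0 = NA_real_,
                  t1f = NA_real_, residual_norm = NA_real_, converged = FALSE,
                  niter = 0L, valid = FALSE)
  if (any(!is.finite(signals)) || all(signals == 0) ||
      !is.finite(t1_observed) || t1_observed <= 0)
    return(invalid)
  const <- qmt_row_constants(protocol, opts)
  fit_qmt_voxel_impl(signals, const, t1_observed, opts)
}

fit_qmt_voxel_impl <- function(signals, const, t1_observed, opts) {
  t1f_of <- function(f, kf) {
    if (opts$t1_mode == "observed_as_t1f") t1_observed
    else derive_t1f(t1_observed, f, kf, opts$t1b)
  }
  model <- function(m0, f, kf, t2f) {
    t1f <- t1f_of(f, kf)
    if (!is.finite(t1f)) return(NULL)
    bssfp_signal_core(m0, f, kf, t1f, opts$t1b, t2f,
                      const$alpha, const$tr, const$trf, const$w)
  }
  s0 <- model(1, opts$init[["f"]], opts$init[["kf"]], opts$init[["t2f"]])
  if (is.null(s0)) return(list(f = NA_real_, kf = NA_real_, t2f = NA_real_,
                               m0 = NA_real_, t1f = NA_real_,
                               residual_norm = NA_real_, converged = FALSE,
                               niter = 0L, valid = FALSE))
  m0_init <- sum(signals * s0) / sum(s0^2) # least-squares optimal scale
  big <- sqrt(.Machine$double.xmax)
  resid_fn <- function(par) {
    s <- model(par[["m0"]], par[["f"]], par[["kf"]], par[["t2f"]])
    if (is.null(s) || any(!is.finite(s))) return(rep(big, length(signals)))
    s - signals
  }
  fit <- minpack.lm::nls.lm(
    par = c(m0 = m0_init, f = opts$init[["f"]], kf = opts$init[["kf"]],
            t2f = opts$init[["t2f"]]),
    lower = c(m0 = 0, opts$lower[c("f", "kf", "t2f")]),
    upper = c(m0 = Inf, opts$upper[c("f", "kf", "t2f")]),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = opts$max_iterations,
      ftol = opts$tolerance, ptol = opts$tolerance))
  par <- fit$par
  list(f = par[["f"]], kf = par[["kf"]], t2f = par[["t2f"]], m0 = par[["m0"]],
       t1f = t1f_of(par[["f"]], par[["kf"]]),
       residual_norm = sqrt(sum(fit$fvec^2)),
       converged = fit$info %in% 1:4, niter = fit$niter, valid = TRUE)
}

#' Fit the two-pool model voxel-wise over a volume
#'
#' Applies [fit_qmt_voxel()] independently to every masked voxel of a 4-D
#' bSSFP acquisition; voxel order does not affect results and the fitted
#' maps are left unsmoothed.
#'
#' @param data 4-D array (x, y, z, volume), one volume per bSSFP protocol
#'   row.
#' @param mask logical/0-1 3-D array on the same grid.
#' @param t1map 3-D array of observed T1 (seconds), or a `"t1_map"` object
#'   from [fit_vfa_t1_map()].
#' @param protocol bSSFP protocol rows matching the 4th dimension.
#' @param opts a [qmt_fit_options()] object.
#' @return A list of class `"qmt_maps"` with 3-D arrays `f`, `kf`, `t2f`,
#'   `m0`, `t1f`, `residual_norm`, `converged`, `valid`, the `mask`, and the
#'   scalar `convergence_fraction`.
#' @export
fit_qmt_volume <- function(data, mask, t1map, protocol,
                           opts = qmt_fit_options()) {
  dims <- dim(data)
  if (length(dims) != 4 || dims[4] != nrow(protocol))
    stop("data must be 4-D with one volume per protocol row")
  if (!all(dim(mask) == dims[1:3])) stop("mask does not match the data grid")
  if (inherits(t1map, "t1_map")) t1map <- t1map$t1
  if (!all(dim(t1map) == dims[1:3])) stop("t1map does not match the data grid")
  combos <- unique(protocol[, c("flip_deg", "tr_ms", "trf_ms")])
  if (nrow(combos) < 4)
    stop("need >= 4 distinct (flip, TR, trf) combinations to fit 4 parameters")
  mask <- array(as.logical(mask), dim = dims[1:3])
  idx <- which(mask)
  if (length(idx) == 0) warning("mask is empty; returning empty maps")
  shape <- dims[1:3]
  out <- list(f = array(NA_real_, shape), kf = array(NA_real_, shape),
              t2f = array(NA_real_, shape), m0 = array(NA_real_, shape),
              t1f = array(NA_real_, shape),
              residual_norm = array(NA_real_, shape),
              converged = array(FALSE, shape), valid = array(FALSE, shape))
  const <- qmt_row_constants(protocol, opts)
  sig <- matrix(data, ncol = dims[4])
  for (i in idx) {
    s <- sig[i, ]
    t1o <- t1map[i]
    if (any(!is.finite(s)) || all(s == 0) || !is.finite(t1o) || t1o <= 0)
      next
    fit <- fit_qmt_voxel_impl(s, const, t1o, opts)
    out$f[i] <- fit$f; out$kf[i] <- fit$kf; out$t2f[i] <- fit$t2f
    out$m0[i] <- fit$m0; out$t1f[i] <- fit$t1f
    out$residual_norm[i] <- fit$residual_norm
    out$converged[i] <- fit$converged
    out$valid[i] <- fit$valid
  }
  out$mask <- mask
  out$convergence_fraction <-
    if (length(idx) > 0) mean(out$converged[idx]) else NA_real_
  out$options <- opts
  class(out) <- "qmt_maps"
  out
}

#' @export
print.qmt_maps <- function(x, ...) {
  cat(sprintf("<qmt_maps> %s grid, %d masked voxels, %.1f%% converged\n",
              paste(dim(x$f), collapse = "x"), sum(x$mask),
              100 * x$convergence_fraction))
  invisible(x)
}
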