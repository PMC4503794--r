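#' Bloch-McConnell steady state by time stepping (numerical oracle)
#'
#' Brute-force reference for [bssfp_two_pool_signal()]: integrates the
#' coupled two-pool magnetization equations through repeated TRs with
#' alternating RF phase until a periodic steady state is reached. Each RF
#' event rotates the free pool instantaneously by +/- alpha (finite-RF
#' transverse dynamics are outside the model, matching the closed form's
#' excitation convention); the bound pool is then saturated at the rate
#' W = pi * omega1_rms^2 * G(0) throughout the pulse window `trf`, resolved
#' with classical fourth-order Runge-Kutta steps of size `dt` together with
#' relaxation and exchange, so the oracle tests the closed form's lumping of
#' the saturation window into a single exp(-W trf) factor as well as its
#' exact inter-pulse propagation. The remainder of the TR is propagated by
#' the matrix exponential of the free-evolution generator (via
#' [Matrix::expm()], independent of the closed form's hand-written 2x2
#' eigendecomposition). Returns the post-pulse (TE = 0) amplitude.
#'
#' @param p a [two_pool_params()] set.
#' @param seq an [acquisition_spec()] with `kind = "bssfp"` and a
#'   rectangular pulse.
#' @param dt time step in seconds; must satisfy `dt <= trf/20`.
#' @param init optional initial state `c(My, Mzf, Mzb)`; the steady state is
#'   invariant to it.
#' @param tol relative TR-to-TR convergence tolerance.
#' @param max_periods cap on the number of two-TR periods before a
#'   convergence error is raised.
#' @return Steady-state signal amplitude (signal units).
#' @examples
#' p <- two_pool_params(m0 = 1, f = 0.12, kf = 3, t1f = 1.1, t2f = 0.07)
#' seq <- acquisition_spec("bssfp", 35, 4.81, 1.38)
#' bloch_mcconnell_steady_state(p, seq, dt = 1e-5)
#' @export
bloch_mcconnell_steady_state <- function(p, seq, dt = NULL, init = NULL,
                                         tol = 1e-9, max_periods = 200000L) {
  seq <- as_acquisition_spec(seq)
  if (seq$kind != "bssfp") stop("requires a bSSFP acquisition")
  if (seq$pulse_shape != "rectangular")
    stop("the time-stepping oracle supports rectangular pulses only")
  alpha <- seq$flip_deg * pi / 180
  tr <- seq$tr_ms * 1e-3
  trf <- seq$trf_ms * 1e-3
  if (is.null(dt)) dt <- trf / 40
  if (dt > trf / 20 + 1e-15) stop("dt must satisfy dt <= trf/20")
  omega1 <- alpha / trf
  w <- pi * omega1^2 * lineshape_value(p$lineshape, p$t2b, 0)
  r1f <- 1 / p$t1f; r1b <- 1 / p$t1b; r2f <- 1 / p$t2f
  kf <- p$kf
  kb <- if (p$f > 0) kf / p$f else 0
  m0f <- p$m0; m0b <- p$f * p$m0

  # relaxation/exchange generator on (My, Mzf, Mzb, 1); RF rotation is a
  # separate instantaneous event, wsat acts only during the pulse window
  gen <- function(wsat) {
    matrix(c(-r2f,  0,                0,                 0,
              0,   -(r1f + kf),       kb,                r1f * m0f,
              0,    kf,              -(r1b + kb + wsat), r1b * m0b,
              0,    0,                0,                 0),
           nrow = 4, byrow = TRUE)
  }
  rot <- function(sgn) {
    ca <- cos(alpha); sa <- sin(alpha) * sgn
    matrix(c(ca, sa, 0, 0,
             -sa, ca, 0, 0,
             0, 0, 1, 0,
             0, 0, 0, 1), nrow = 4, byrow = TRUE)
  }
  rk4_step <- function(G, h) {
    A <- G * h
    A2 <- A %*% A
    diag(4) + A + A2 / 2 + (A2 %*% A) / 6 + (A2 %*% A2) / 24
  }
  n_steps <- max(20L, as.integer(ceiling(trf / dt)))
  h <- trf / n_steps
  S <- rk4_step(gen(w), h)
  Psat <- diag(4)
  for (i in seq_len(n_steps)) Psat <- S %*% Psat
  Ffree <- as.matrix(Matrix::expm(gen(0) * (tr - trf)))
  Aplus <- Ffree %*% Psat %*% rot(1)
  Aminus <- Ffree %*% Psat %*% rot(-1)
  A2 <- Aminus %*% Aplus # two-TR map (pulse +a then -a)

  x <- c(if (is.null(init)) c(0, m0f, m0b) else init, 1)
  converged <- FALSE
  for (i in seq_len(max_periods)) {
    x_new <- A2 %*% x
    if (sum(abs(x_new - x)) <= tol * (sum(abs(x_new)) + 1e-300)) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  if (!converged)
    stop("Bloch-McConnell iteration failed to reach a periodic steady state")
  x_post <- rot(1) %*% x # immediately after the +alpha rotation
  abs(x_post[1])
}

#' SPGR steady state by time stepping with perfect spoiling
#'
#' Reference simulation for [spgr_signal()]: instantaneous excitation each
#' TR, transverse magnetization discarded (ideal spoiling), longitudinal
#' recovery integrated with RK4 steps of size `dt`, iterated to steady
#' state. Returns the post-pulse transverse amplitude sin(a) * Mz.
#'
#' @param m0,t1f equilibrium magnetization and T1 (seconds).
#' @param seq an [acquisition_spec()] with `kind = "spgr"`.
#' @param dt time step in seconds.
#' @param tol relative TR-to-TR convergence tolerance.
#' @return Steady-state signal amplitude.
#' @export
spgr_bloch_steady_state <- function(m0, t1f, seq, dt = 1e-4, tol = 1e-12) {
  seq <- as_acquisition_spec(seq)
  if (seq$kind != "spgr") stop("requires an SPGR acquisition")
  a <- seq$flip_deg * pi / 180
  tr <- seq$tr_ms * 1e-3
  n <- max(2L, as.integer(ceiling(tr / dt)))
  h <- tr / n
  relax_tr <- function(mz) {
    for (i in seq_len(n)) {
      k1 <- (m0 - mz) / t1f
      k2 <- (m0 - (mz + h / 2 * k1)) / t1f
      k3 <- (m0 - (mz + h / 2 * k2)) / t1f
      k4 <- (m0 - (mz + h * k3)) / t1f
      mz <- mz + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    mz
  }
  mz <- m0
  for (i in seq_len(100000L)) {
    mz_new <- relax_tr(mz * cos(a))
    if (abs(mz_new - mz) <= tol * (abs(mz_new) + 1e-300)) {
      mz <- mz_new
      break
    }
    mz <- mz_new
  }
  sin(a) * mz
}
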