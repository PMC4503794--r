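test_that("lineshape closed forms and limits", {
  t2b <- 12e-6
  expect_equal(lineshape_value("gaussian", t2b, 0), t2b / sqrt(2 * pi),
               tolerance = 1e-12)
  # absorption vanishes far off-resonance
  expect_lt(lineshape_value("gaussian", t2b, 1e6), 1e-20)
  expect_lt(lineshape_value("super_lorentzian", t2b, 5e6),
            1e-6 * lineshape_value("super_lorentzian", t2b, 2000))
  expect_error(lineshape_value("gaussian", -1e-6, 0), "t2b")
})

test_that("super-Lorentzian matches an independent fine-grid quadrature", {
  t2b <- 12e-6
  for (offset in c(2e3, 1e4, 3e4)) {
    # trapezoid over a fine orientation grid, avoiding the magic-angle point
    u <- seq(0, 1, length.out = 2e6 + 1)
    s <- abs(3 * u^2 - 1)
    fu <- sqrt(2 / pi) * t2b / s * exp(-2 * (2 * pi * offset * t2b / s)^2)
    fu[!is.finite(fu)] <- 0
    oracle <- sum((fu[-1] + fu[-length(fu)]) / 2) * diff(u[1:2])
    got <- lineshape_value("super_lorentzian", t2b, offset)
    expect_lt(abs(got - oracle) / oracle, 1e-4)
  }
})

test_that("mean saturation rate follows the RF amplitude arithmetic", {
  seq1 <- acquisition_spec("bssfp", 35, 4.81, 1.0)
  ctx1 <- mean_saturation_rate(seq1, "gaussian", 12e-6)
  expect_equal(ctx1$omega1_rms, (35 * pi / 180) / 1e-3, tolerance = 1e-12)
  expect_equal(ctx1$omega1_rms, 610.9, tolerance = 1e-4)
  # doubling trf at fixed flip halves omega1 and quarters w
  ctx2 <- mean_saturation_rate(acquisition_spec("bssfp", 35, 4.81, 2.0),
                               "gaussian", 12e-6)
  expect_equal(ctx2$w, ctx1$w / 4, tolerance = 1e-12)
  # independent arithmetic recomputation
  seq3 <- acquisition_spec("bssfp", 40, 4.81, 0.5)
  ctx3 <- mean_saturation_rate(seq3, "gaussian", 12e-6)
  expect_equal(ctx3$w,
               pi * ((40 * pi / 180) / 5e-4)^2 * (12e-6 / sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_error(mean_saturation_rate(acquisition_spec("spgr", 15, 30)),
               "bSSFP")
})

test_that("SPGR signal obeys limits and the Ernst angle", {
  tr <- 30
  t1 <- 1.0
  s_small <- spgr_signal(1, t1, list(kind = "spgr", flip_deg = 1e-4,
                                     tr_ms = tr))
  expect_lt(s_small, 1e-5) # S -> 0 as flip -> 0
  # numeric maximization oracle for the Ernst angle
  obj <- function(a_deg) -spgr_signal(1, t1, list(kind = "spgr",
                                                  flip_deg = a_deg,
                                                  tr_ms = tr))
  a_star <- stats::optimize(obj, c(1, 89))$minimum
  ernst <- acos(exp(-tr * 1e-3 / t1)) * 180 / pi
  expect_equal(a_star, ernst, tolerance = 1e-4)
  # spoiled Bloch simulation oracle
  s_cf <- spgr_signal(1, t1, list(kind = "spgr", flip_deg = 15, tr_ms = tr))
  s_bl <- spgr_bloch_steady_state(1, t1, list(kind = "spgr", flip_deg = 15,
                                              tr_ms = tr))
  expect_lt(abs(s_cf - s_bl) / s_bl, 1e-3)
})

test_that("two-pool bSSFP reduces to the single-pool closed form at f = 0", {
  p0 <- two_pool_params(m0 = 2, f = 0, kf = 0, t1f = 1.0, t2f = 0.08)
  for (row in c(1, 7, 15, 22)) {
    seqr <- protocol_row(bssfp_rows(), row)
    a <- seqr$flip_deg * pi / 180
    e1 <- exp(-seqr$tr_ms * 1e-3 / 1.0)
    e2 <- exp(-seqr$tr_ms * 1e-3 / 0.08)
    ref <- 2 * sin(a) * (1 - e1) / (1 - (e1 - e2) * cos(a) - e1 * e2)
    expect_lt(abs(bssfp_two_pool_signal(p0, seqr) - ref) / ref, 1e-9)
  }
})

test_that("bSSFP signal is linear in m0 and decreasing in saturation", {
  prot <- bssfp_rows()
  p1 <- canonical_voxel()
  s1 <- bssfp_two_pool_signal(p1, prot)
  p3 <- two_pool_params(m0 = 3000, f = 0.12, kf = 3.0, t1f = 1.05,
                        t2f = 0.07)
  expect_equal(bssfp_two_pool_signal(p3, prot), 3 * s1, tolerance = 1e-12)
  # shrinking trf at fixed flip/TR strengthens saturation: signal drops
  trfs <- c(2.0, 1.0, 0.5, 0.25)
  sig <- vapply(trfs, function(trf)
    bssfp_two_pool_signal(p1, acquisition_spec("bssfp", 35, 4.81, trf)),
    numeric(1))
  expect_true(all(diff(sig) < 0))
})

test_that("Bloch-McConnell oracle converges, is init-invariant and consistent", {
  p <- canonical_voxel()
  seqr <- acquisition_spec("bssfp", 30, 4.81, 1.38)
  s1 <- bloch_mcconnell_steady_state(p, seqr, dt = 1.38e-3 / 20, tol = 1e-12)
  s2 <- bloch_mcconnell_steady_state(p, seqr, dt = 1.38e-3 / 40, tol = 1e-12)
  s3 <- bloch_mcconnell_steady_state(p, seqr, dt = 1.38e-3 / 80, tol = 1e-12)
  # step halving: error shrinks (Richardson consistency at RK4 order)
  expect_lt(abs(s3 - s2), abs(s2 - s1) + 1e-10)
  expect_lt(abs(s2 - s1) / s1, 1e-6)
  # steady state does not depend on the starting magnetization
  s_init <- bloch_mcconnell_steady_state(p, seqr, init = c(0.3, -0.2, 0.05),
                                         tol = 1e-12)
  expect_equal(s_init, bloch_mcconnell_steady_state(p, seqr, tol = 1e-12),
               tolerance = 1e-8)
  expect_error(bloch_mcconnell_steady_state(p, seqr, dt = 1e-3), "dt")
  # f = 0 limit against the analytic single-pool form
  p0 <- two_pool_params(m0 = 1, f = 0, kf = 0, t1f = 1.0, t2f = 0.08)
  a <- 30 * pi / 180
  e1 <- exp(-4.81e-3); e2 <- exp(-4.81e-3 / 0.08)
  ref <- sin(a) * (1 - e1) / (1 - (e1 - e2) * cos(a) - e1 * e2)
  expect_lt(abs(bloch_mcconnell_steady_state(p0, seqr) - ref) / ref, 1e-3)
})

test_that("closed form agrees with the simulator on a physiological spot grid", {
  rows <- bssfp_rows()[c(1, 6, 12, 13, 17, 22), ]
  grid <- expand.grid(f = c(0.05, 0.25), kf = c(1, 6), t2f = c(0.04, 0.12))
  for (i in seq_len(nrow(grid))) {
    p <- two_pool_params(m0 = 1, f = grid$f[i], kf = grid$kf[i], t1f = 1.0,
                         t2f = grid$t2f[i])
    s_cf <- bssfp_two_pool_signal(p, rows)
    s_bm <- vapply(seq_len(nrow(rows)), function(j)
      bloch_mcconnell_steady_state(p, protocol_row(rows, j)), numeric(1))
    expect_lt(max(abs(s_cf - s_bm) / s_bm), 0.01)
  }
})

test_that("parameter validation rejects unphysical two-pool settings", {
  expect_error(two_pool_params(f = 1.2), "f must be")
  expect_error(two_pool_params(f = 0, kf = 3), "kf = 0")
  expect_error(two_pool_params(t2f = 2, t1f = 1), "t2f")
  expect_error(spgr_signal(1, -1, list(kind = "spgr", flip_deg = 15,
                                       tr_ms = 30)), "t1f")
})
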