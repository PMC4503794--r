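test_that("noiseless VFA recovery is exact across the physiological range", {
  sp <- spgr_rows()
  for (t1 in c(0.5, 0.8, 1.0, 1.6, 2.2, 3.0)) {
    s <- vapply(seq_len(nrow(sp)), function(j)
      spgr_signal(2.5, t1, protocol_row(sp, j)), numeric(1))
    fit <- fit_vfa_t1(s, sp$flip_deg, sp$tr_ms[1])
    expect_true(fit$valid)
    expect_lt(abs(fit$t1 - t1) / t1, 1e-9)
    expect_lt(abs(fit$m0 - 2.5) / 2.5, 1e-9)
  }
})

test_that("degenerate VFA inputs are flagged, not thrown", {
  expect_false(fit_vfa_t1(c(5, 5, 5), c(5, 15, 25), 30)$valid)
  expect_false(fit_vfa_t1(c(0, 0, 0), c(5, 15, 25), 30)$valid)
  expect_error(fit_vfa_t1(c(1, 2), c(10, 10), 30), "distinct")
})

test_that("VFA T1 bias stays small under Rician noise at SNR 50", {
  sp <- spgr_rows()
  t1 <- 1.0
  s <- vapply(seq_len(nrow(sp)), function(j)
    spgr_signal(1, t1, protocol_row(sp, j)), numeric(1))
  sigma <- mean(s) / 50
  set.seed(101)
  t1_hat <- replicate(1000, fit_vfa_t1(add_rician(s, sigma), sp$flip_deg,
                                       sp$tr_ms[1])$t1)
  expect_lt(abs(stats::median(t1_hat, na.rm = TRUE) - t1) / t1, 0.02)
})

test_that("free-pool T1 solves the slow-eigenmode equation", {
  # no exchange: observed T1 is the free-pool T1
  expect_equal(derive_t1f(1.3, f = 0, kf = 0), 1.3)
  grid <- expand.grid(t1o = c(0.6, 1.0, 1.5), f = c(0.05, 0.15, 0.3),
                      kf = c(0.5, 2, 5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    t1f <- derive_t1f(g$t1o, g$f, g$kf, t1b = 1.0)
    expect_true(is.finite(t1f) && t1f > 0)
    # eigenvalue oracle: slowest mode of the assembled matrix
    kb <- g$kf / g$f
    L <- matrix(c(-(1 / t1f + g$kf), kb, g$kf, -(1 + kb)), 2, 2,
                byrow = TRUE)
    lam_slow <- max(eigen(L, only.values = TRUE)$values)
    expect_lt(abs(-lam_slow - 1 / g$t1o) * g$t1o, 1e-10)
    # self-consistency through the forward map
    p <- list(f = g$f, kf = g$kf, t1f = t1f, t1b = 1.0)
    expect_lt(abs(observed_t1(p) - g$t1o) / g$t1o, 1e-10)
  }
})

test_that("recovered free-pool T1 is monotone in the exchange rate", {
  kfs <- seq(0.5, 6, by = 0.5)
  t1f <- vapply(kfs, function(k) derive_t1f(1.0, 0.12, k), numeric(1))
  expect_true(all(diff(t1f) >= 0))
})

test_that("voxel-wise T1 mapping honors the mask and flags bad voxels", {
  sp <- spgr_rows()
  sh <- c(4, 4, 2)
  s_good <- vapply(seq_len(nrow(sp)), function(j)
    spgr_signal(1, 0.9, protocol_row(sp, j)), numeric(1))
  vfa <- array(0, c(sh, 3))
  for (j in 1:3) vfa[, , , j] <- s_good[j]
  vfa[2, 2, 1, ] <- 7 # equal signals: degenerate geometry
  mask <- array(TRUE, sh)
  mask[1, 1, 1] <- FALSE
  t1m <- fit_vfa_t1_map(vfa, mask, sp$flip_deg, sp$tr_ms[1])
  expect_true(is.na(t1m$t1[1, 1, 1]))
  expect_false(t1m$valid[2, 2, 1])
  expect_equal(t1m$t1[3, 3, 2], 0.9, tolerance = 1e-9)
})
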