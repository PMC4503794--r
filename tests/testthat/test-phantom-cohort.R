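test_that("phantom tissue classes partition the grid and ROIs sit in gray", {
  ph <- tiny_phantom()
  expect_true(all(ph$labels %in% 0:3))
  for (k in 0:3) expect_gt(sum(ph$labels == k), 0)
  for (nm in names(ph$rois)) {
    roi <- ph$rois[[nm]]
    expect_gt(sum(roi), 0)
    expect_true(all(ph$labels[roi] == 1L))
  }
  ph2 <- tiny_phantom()
  expect_identical(ph$labels, ph2$labels)
  expect_identical(ph$truth$kf, ph2$truth$kf)
})

test_that("condition effect changes only kf inside the ROI", {
  ph <- tiny_phantom()
  roi <- ph$rois$insula_left
  same <- apply_condition_effect(ph$truth, roi, 0)
  expect_identical(same$kf, ph$truth$kf)
  shifted <- apply_condition_effect(ph$truth, roi, 0.4)
  expect_equal(mean(shifted$kf[roi] - ph$truth$kf[roi]), 0.4,
               tolerance = 1e-12)
  expect_identical(shifted$kf[!roi], ph$truth$kf[!roi])
  expect_identical(shifted$f, ph$truth$f)
  expect_error(apply_condition_effect(ph$truth, roi & !roi, 0.4), "empty")
})

test_that("session simulation matches the forward model and noise contract", {
  ph <- tiny_phantom()
  prot <- default_protocol()
  clean <- simulate_subject_session(ph, prot, snr = Inf)
  # a gray-matter voxel equals the closed-form forward signal exactly
  gi <- which(ph$labels == 1L & !ph$rois$insula_left)[1]
  idx3 <- arrayInd(gi, dim(ph$labels))
  gray <- ph$spec$tissues$gray
  bs <- prot[prot$kind == "bssfp", ]
  expect_equal(clean[idx3[1], idx3[2], idx3[3], bs$volume_index],
               unname(bssfp_two_pool_signal(gray, bs)), tolerance = 1e-12)
  expect_true(all(clean >= 0))
  # Rician magnitude noise: all intensities non-negative, empirical SD near
  # sigma in the high-SNR (Gaussian) regime of a homogeneous region
  noisy <- simulate_subject_session(ph, prot, snr = 100, seed = 2)
  expect_true(all(noisy >= 0))
  white <- ph$labels == 2L
  s_b <- bssfp_two_pool_signal(gray, bs)
  sigma <- mean(s_b) / 100
  # strongest-signal volume: local SNR is high, Rician ~ Gaussian
  s_white <- bssfp_two_pool_signal(ph$spec$tissues$white, bs)
  jmax <- bs$volume_index[which.max(s_white)]
  resid <- (noisy - clean)[, , , jmax][white]
  expect_lt(abs(stats::sd(resid) - sigma) / sigma, 0.05)
})

test_that("behavioral generator honors its trivial and calibrated regimes", {
  co1 <- cohort_spec(n_subjects = 12, fatigue_r2 = 1)
  delta <- rnorm(12, 0.5, 0.2)
  beh <- simulate_behavioral(co1, delta, seed = 4)
  expect_equal(nrow(beh), 12 * 4)
  v <- beh[beh$condition == "vaccine", ]
  dfat <- v$fatigue[v$timepoint == "4h"] - v$fatigue[v$timepoint == "baseline"]
  # zero residual noise: fatigue change is an exact line in delta-kf
  expect_equal(stats::cor(dfat, delta)^2, 1, tolerance = 1e-12)
  expect_true(all(is.finite(beh$il6)) && all(beh$il6 > 0))
  expect_error(simulate_behavioral(cohort_spec(n_subjects = 5), delta),
               "per subject")
})

test_that("expected sample R2 matches brute-force simulation", {
  set.seed(31)
  n <- 10
  rho2 <- 0.24
  r2 <- replicate(4000, {
    x <- rnorm(n)
    y <- sqrt(rho2) * x + sqrt(1 - rho2) * rnorm(n)
    stats::cor(x, y)^2
  })
  expect_equal(mean(r2), expected_sample_r2(rho2, n), tolerance = 0.015)
  expect_equal(expected_sample_r2(1, 20), 1)
})

test_that("a tiny cohort dataset honors the shape and determinism contracts", {
  ph_spec <- phantom_spec(shape = c(16, 16, 8), snr = Inf)
  co <- cohort_spec(n_subjects = 3, seed = 9)
  prot <- default_protocol()
  ds1 <- simulate_cohort(ph_spec, co, prot)
  expect_length(ds1$subjects, 3)
  expect_equal(nrow(ds1$behavioral), 12)
  expect_equal(dim(ds1$subjects[[1]]$raw$vaccine), c(16, 16, 8, nrow(prot)))
  expect_true(all(c("vaccine", "placebo") %in%
                    ds1$subjects[[2]]$session_order))
  ds2 <- simulate_cohort(ph_spec, co, prot)
  expect_identical(ds1$subjects[[3]]$raw$placebo,
                   ds2$subjects[[3]]$raw$placebo)
  expect_identical(ds1$behavioral, ds2$behavioral)
  # vaccine-session truth carries the subject effect inside the ROI only
  roi <- ds1$phantom$rois$insula_left
  d <- ds1$subjects[[1]]$truth_kf$vaccine - ds1$subjects[[1]]$truth_kf$placebo
  expect_equal(mean(d[roi]), ds1$subjects[[1]]$delta_kf, tolerance = 1e-12)
  expect_true(all(d[!roi] == 0))
})

test_that("map-level cohort generator reproduces the injected effect", {
  ph <- tiny_phantom()
  co <- cohort_spec(n_subjects = 8, effect_mean = 0.5, effect_sd = 0.1)
  dat <- simulate_kf_map_cohort(ph, co, sigma_vox = 0.05, seed = 12)
  expect_length(dat$vaccine, 8)
  d_roi <- vapply(seq_len(8), function(s)
    mean(dat$vaccine[[s]][dat$roi] - dat$placebo[[s]][dat$roi]), numeric(1))
  expect_equal(d_roi, dat$subject_delta,
               tolerance = 0.05) # voxel noise shrinks as 1/sqrt(|roi|)
})
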