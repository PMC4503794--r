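test_that("Gaussian smoothing: identity, mass preservation, kernel width", {
  set.seed(8)
  x <- array(rnorm(20 * 20 * 8), c(20, 20, 8))
  mask <- array(TRUE, dim(x))
  expect_identical(smooth_volume(x, 0, 3), x)
  cst <- array(4.2, dim(x))
  expect_equal(smooth_volume(cst, 8, 3, mask), {
    out <- cst
    out
  }, tolerance = 1e-12)
  # delta spike: fitted FWHM of the impulse response matches the request
  sh <- c(41, 41, 41)
  spike <- array(0, sh)
  spike[21, 21, 21] <- 1
  fwhm <- 6
  sm <- smooth_volume(spike, fwhm, 1)
  prof <- sm[, 21, 21]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation at the half-maximum crossings
  lo <- min(above); hi <- max(above)
  x_lo <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  x_hi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  expect_lt(abs((x_hi - x_lo) - fwhm) / fwhm, 0.05)
  expect_error(smooth_volume(x, -1, 3), "non-negative")
})

test_that("paired t map equals the scalar oracle and flags degeneracy", {
  sh <- c(6, 5, 4)
  n <- 9
  set.seed(21)
  a <- lapply(1:n, function(i) array(rnorm(prod(sh)), sh))
  b <- lapply(1:n, function(i) array(rnorm(prod(sh)), sh))
  mask <- array(TRUE, sh)
  st <- paired_t_map(a, b, mask)
  expect_equal(st$df, n - 1)
  # brute-force scalar loop
  for (vox in sample(prod(sh), 12)) {
    d <- vapply(1:n, function(s) a[[s]][vox] - b[[s]][vox], numeric(1))
    expect_lt(abs(st$t[vox] - mean(d) / (sd(d) / sqrt(n))), 1e-12)
  }
  expect_true(all(abs(st$t[mask]) < Inf))
  st0 <- paired_t_map(a, a, mask)
  expect_true(all(st0$t[mask] == 0))
  # constant nonzero difference: sd = 0 -> invalid, not infinite
  a_c <- lapply(a, function(m) m + 1)
  a_c <- lapply(1:n, function(s) b[[s]] + 2)
  stc <- paired_t_map(a_c, b, mask)
  expect_true(all(is.na(stc$t)))
  expect_error(paired_t_map(a[1:3], b, mask), "pair up")
})

test_that("cluster extraction follows connectivity semantics", {
  sh <- c(8, 8, 4)
  t_arr <- array(0, sh)
  mask <- array(TRUE, sh)
  t_arr[2, 2, 2] <- 10
  st <- structure(list(t = t_arr, df = 15L, n_pairs = 16L, mask = mask),
                  class = "stat_map")
  cl <- extract_clusters(st, 0.001)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$extent, 1L)
  expect_equal(c(cl$peak_x, cl$peak_y, cl$peak_z), c(2, 2, 2))
  # two voxels touching only at a corner
  t_arr[3, 3, 3] <- 8
  st$t <- t_arr
  expect_equal(nrow(extract_clusters(st, 0.001, connectivity = 26)), 1)
  expect_equal(nrow(extract_clusters(st, 0.001, connectivity = 6)), 2)
  expect_error(extract_clusters(st, 0.001, connectivity = 10),
               "connectivity")
})

test_that("component labels match an independent flood-fill oracle", {
  flood_oracle <- function(mask, connectivity) {
    sh <- dim(mask)
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    nz <- rowSums(abs(off))
    off <- off[switch(as.character(connectivity), "6" = nz == 1,
                      "18" = nz >= 1 & nz <= 2, nz >= 1), , drop = FALSE]
    lab <- array(0L, sh)
    cur <- 0L
    fill <- function(start) {
      stack <- list(start)
      while (length(stack) > 0) {
        c0 <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (o in seq_len(nrow(off))) {
          nb <- c0 + off[o, ]
          if (any(nb < 1) || any(nb > sh)) next
          if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
            lab[nb[1], nb[2], nb[3]] <<- cur
            stack[[length(stack) + 1]] <- nb
          }
        }
      }
    }
    for (i in which(mask)) {
      if (lab[i] == 0L) {
        cur <- cur + 1L
        lab[i] <- cur
        fill(arrayInd(i, sh)[1, ])
      }
    }
    lab
  }
  set.seed(14)
  for (conn in c(6L, 18L, 26L)) {
    m <- array(runif(10 * 9 * 5) < 0.25, c(10, 9, 5))
    got <- label_components(m, conn)
    want <- flood_oracle(m, conn)
    # same partition up to label permutation
    expect_equal(got > 0, want > 0)
    tab <- table(got[m], want[m])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("Monte Carlo extent threshold is deterministic and analytic at fwhm 0", {
  mask <- array(TRUE, c(10, 10, 10))
  # unsmoothed noise at a draconian threshold: expected count << 1, k* = 1
  mc <- monte_carlo_cluster_threshold(mask, fwhm_mm = 0, voxel_mm = 3,
                                      p_voxel = 1e-6, n_iter = 200, seed = 3)
  expect_equal(mc$k_star, 1L)
  mask2 <- tiny_phantom()$brain_mask
  mc1 <- monte_carlo_cluster_threshold(mask2, 8, 3, n_iter = 150, seed = 5)
  mc2 <- monte_carlo_cluster_threshold(mask2, 8, 3, n_iter = 150, seed = 5)
  expect_identical(mc1$k_star, mc2$k_star)
  expect_identical(mc1$max_extents, mc2$max_extents)
  expect_error(monte_carlo_cluster_threshold(array(FALSE, c(4, 4, 4)), 8, 3,
                                             n_iter = 150), "empty")
})

test_that("ROI sign-flip FWE: enumeration granularity, type I error, power", {
  sh <- c(8, 8, 4)
  roi <- array(FALSE, sh)
  roi[3:6, 3:6, 2:3] <- TRUE
  n <- 5
  set.seed(33)
  a <- lapply(1:n, function(i) array(rnorm(prod(sh)), sh))
  b <- lapply(1:n, function(i) array(rnorm(prod(sh)), sh))
  res <- roi_fwe_smallvolume(a, b, roi, n_perm = 64)
  expect_true(res$exact)
  expect_equal(res$n_perm_used, 32)
  expect_equal(res$p_fwe * 32, round(res$p_fwe * 32)) # multiple of 1/32
  # type-I calibration on null cohorts
  set.seed(44)
  n2 <- 10
  hits <- replicate(400, {
    a2 <- lapply(1:n2, function(i) array(rnorm(prod(sh)), sh))
    b2 <- lapply(1:n2, function(i) array(rnorm(prod(sh)), sh))
    roi_fwe_smallvolume(a2, b2, roi, n_perm = 300)$p_fwe <= 0.05
  })
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
  # power at a 3-sigma injected effect
  set.seed(55)
  power_hits <- replicate(60, {
    a3 <- lapply(1:n2, function(i) array(rnorm(prod(sh)), sh) + 3 * roi)
    b3 <- lapply(1:n2, function(i) array(rnorm(prod(sh)), sh))
    roi_fwe_smallvolume(a3, b3, roi, n_perm = 300)$p_fwe <= 0.05
  })
  expect_gt(mean(power_hits), 0.9)
  expect_error(roi_fwe_smallvolume(a, b, array(FALSE, sh)), "empty")
})

test_that("ROI mean change equals the scalar oracle", {
  sh <- c(5, 4, 3)
  roi <- array(FALSE, sh)
  roi[2:3, 2, 1:2] <- TRUE
  cst <- array(0.7, sh)
  expect_equal(roi_mean_change(list(cst), roi), 0.7)
  one <- array(FALSE, sh)
  one[4, 3, 2] <- TRUE
  m <- array(rnorm(prod(sh)), sh)
  expect_equal(roi_mean_change(list(m), one), m[4, 3, 2])
  vals <- roi_mean_change(list(m), roi)
  expect_lt(abs(vals - mean(m[which(roi)])), 1e-12)
})

test_that("regression on covariate change behaves at the extremes", {
  x <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  fit <- suppressWarnings(regress_change_on_covariate(x, 3 + 2 * x))
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  y <- c(1, -1, 1, -1, 0) # orthogonal to x by construction
  y <- y - mean(y)
  y <- y - sum(y * (x - mean(x))) / sum((x - mean(x))^2) * (x - mean(x))
  fit2 <- regress_change_on_covariate(x, y)
  expect_lt(fit2$r2, 1e-20)
  expect_error(regress_change_on_covariate(rep(1, 5), rnorm(5)),
               "zero variance")
})

test_that("2x2 interaction equals a brute-force repeated-measures ANOVA", {
  toy <- expand.grid(subject = 1:3, condition = c("vaccine", "placebo"),
                     timepoint = c("baseline", "4h"),
                     stringsAsFactors = FALSE)
  toy$fatigue <- c(10, 12, 9, 11, 14, 10, 30, 25, 28, 13, 16, 12)
  got <- repeated_measures_interaction(toy, "fatigue")
  av <- stats::aov(fatigue ~ condition * timepoint +
                     Error(factor(subject) / (condition * timepoint)),
                   data = toy)
  sm <- summary(av)
  tab <- sm[["Error: factor(subject):condition:timepoint"]][[1]]
  F_oracle <- tab["condition:timepoint", "F value"]
  expect_lt(abs(got$F - F_oracle), 1e-10)
  expect_equal(got$df1, 1L)
  expect_equal(got$df2, 2L)
  # null case
  toy0 <- toy
  toy0$fatigue <- rep(c(5, 6, 7), 4) + rep(c(0, 0, 2, 2), each = 3)
  expect_equal(repeated_measures_interaction(toy0, "fatigue")$F, 0)
  expect_error(repeated_measures_interaction(toy[-1, ], "fatigue"),
               "incomplete")
})

test_that("grand-mean scaling is exact, idempotent and scale invariant", {
  set.seed(77)
  m <- array(runif(6 * 6 * 3, 10, 90), c(6, 6, 3))
  mask <- array(runif(prod(dim(m))) < 0.7, dim(m))
  g <- grand_mean_scale(m, mask, 50)
  expect_equal(mean(g[mask]), 50, tolerance = 1e-14)
  expect_equal(grand_mean_scale(g, mask, 50), g, tolerance = 1e-12)
  expect_equal(grand_mean_scale(3 * m, mask, 50), g, tolerance = 1e-12)
  expect_error(grand_mean_scale(m * 0, mask, 50), "zero")
})

test_that("exclusive masking matches the per-voxel logical oracle", {
  sh <- c(7, 6, 4)
  mask <- array(TRUE, sh)
  set.seed(66)
  mk <- function(scale) {
    structure(list(t = array(rnorm(prod(sh), sd = scale), sh), df = 19L,
                   n_pairs = 20L, mask = mask), class = "stat_map")
  }
  stat <- mk(2)
  ctrl <- mk(2)
  out <- exclusive_mask(stat, ctrl, p_mask = 0.005)
  thr <- qt(1 - 0.005, 19)
  oracle_keep <- ctrl$t <= thr
  expect_equal(is.na(out$t), !oracle_keep)
  expect_identical(out$t[oracle_keep], stat$t[oracle_keep])
  # all-subthreshold control leaves the map untouched
  ctrl0 <- mk(1e-3)
  expect_identical(exclusive_mask(stat, ctrl0)$t, stat$t)
  # all-suprathreshold control empties the map with a warning
  ctrl_hi <- ctrl0
  ctrl_hi$t <- array(10, sh)
  expect_warning(out2 <- exclusive_mask(stat, ctrl_hi), "every voxel")
  expect_true(all(is.na(out2$t)))
})
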