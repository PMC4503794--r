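#' Specification of the synthetic crossover cohort
#'
#' Parameters of the two-session (vaccine/placebo) crossover study the
#' generator emulates: the localized exchange-rate effect, its
#' between-subject variability, and the behavioral (fatigue, IL-6) effect
#' structure. The distributional anchors default to the printed group
#' statistics of the inflammation study the pipeline models: a fatigue
#' visual-analog-scale rise of 16.18 +/- 12.57 to 42.40 +/- 22.52 under
#' vaccine (22.08 +/- 17.72 to 29.60 +/- 17.94 under placebo), IL-6 rising
#' roughly threefold (1.29 to 3.74 pmol/L, placebo flat), and a fatigue
#' change for which the insular exchange-rate change explains ~24% of the
#' variance. Change-score SDs are recovered from the printed paired t
#' statistics (sd = mean * sqrt(n) / t at n = 20); IL-6 SDs from the
#' printed standard errors (SE * sqrt(20)).
#'
#' @param n_subjects number of subjects (>= 3; default 20).
#' @param effect_mean mean exchange-rate increase (1/s) in the affected
#'   region under vaccine.
#' @param effect_sd between-subject SD of that increase (1/s).
#' @param fatigue_r2 target fraction of vaccine fatigue-change variance
#'   explained by the subject's regional exchange-rate change, as the
#'   expected sample R^2 at `n_subjects` (in (0, 1]).
#' @param effect_roi name of the phantom ROI carrying the effect.
#' @param seed integer seed for all cohort-level randomness.
#' @return A list of class `"cohort_spec"` including the derived behavioral
#'   constants.
#' @export
cohort_spec <- function(n_subjects = 20L, effect_mean = 0.5, effect_sd = 0.2,
                        fatigue_r2 = 0.24, effect_roi = "insula_left",
                        seed = 1L) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (fatigue_r2 <= 0 || fatigue_r2 > 1)
    stop("fatigue_r2 must be in (0, 1]")
  sdn <- sqrt(20) # printed group statistics are for n = 20
  structure(list(
    n_subjects = as.integer(n_subjects),
    effect_mean = effect_mean, effect_sd = effect_sd,
    fatigue_r2 = fatigue_r2, effect_roi = effect_roi, seed = as.integer(seed),
    fatigue_baseline_mean = c(vaccine = 16.18, placebo = 22.08),
    fatigue_baseline_sd = c(vaccine = 12.57, placebo = 17.72),
    fatigue_delta_mean = c(vaccine = 42.40 - 16.18, placebo = 29.60 - 22.08),
    fatigue_delta_sd = c(vaccine = (42.40 - 16.18) * sdn / 6.05,
                         placebo = (29.60 - 22.08) * sdn / 1.93),
    il6_mean = c(vaccine_baseline = 1.29, vaccine_4h = 3.74,
                 placebo_baseline = 0.97, placebo_4h = 0.90),
    il6_sd = c(vaccine_baseline = 0.38, vaccine_4h = 0.27,
               placebo_baseline = 0.23, placebo_4h = 0.18) * sdn),
    class = "cohort_spec")
}

#' Expected sample R-squared of a bivariate-normal regression
#'
#' For jointly normal (x, y) with population squared correlation `rho2`,
#' the expectation of the ordinary sample R^2 on `n` observations is
#' 1 - ((n-2)/(n-1)) (1-rho2) 2F1(1, 1; (n+1)/2; rho2). Used to calibrate
#' the fatigue generator so that the *sample* R^2 matches the target on
#' average (sample R^2 is biased upward at small n).
#'
#' @param rho2 population squared correlation, in `[0, 1]`.
#' @param n sample size (>= 4).
#' @return Expected sample R^2.
#' @export
expected_sample_r2 <- function(rho2, n) {
  if (rho2 >= 1) return(1)
  # 2F1(1, 1; c; x) = sum_k k! / (c)_k x^k
  cc <- (n + 1) / 2
  term <- 1
  s <- 1
  for (k in 1:500) {
    term <- term * k / (cc + k - 1) * rho2
    s <- s + term
    if (term < 1e-14 * s) break
  }
  1 - (n - 2) / (n - 1) * (1 - rho2) * s
}

# Invert expected_sample_r2 in rho2 for a given target sample R^2. At very
# small n the expected sample R^2 under independence already exceeds
# moderate targets, so the small-sample bias correction is meaningless
# there; the population R^2 is used directly instead.
calibrate_rho2 <- function(target_r2, n) {
  if (target_r2 >= 1) return(1)
  if (target_r2 <= expected_sample_r2(0, n)) return(target_r2)
  stats::uniroot(function(r) expected_sample_r2(r, n) - target_r2,
                 c(0, 1 - 1e-12), tol = 1e-12)$root
}

#' Simulate the behavioral table of one cohort
#'
#' Draws the 2 (condition) x 2 (timepoint) behavioral measurements per
#' subject. Fatigue baselines and the placebo fatigue change are normal
#' draws at the printed means/SDs; the vaccine fatigue change is linear in
#' the subject's regional exchange-rate change with residual noise
#' calibrated so the expected sample R^2 across subjects equals
#' `cohort$fatigue_r2` while the total change SD matches the printed value.
#' IL-6 is drawn log-normally per condition and timepoint, moment-matched
#' to the printed means and SDs.
#'
#' @param cohort a [cohort_spec()].
#' @param subject_delta_kf numeric vector (length `n_subjects`) of
#'   per-subject regional exchange-rate changes, 1/s.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A data frame with columns `subject`, `condition`, `timepoint`,
#'   `il6`, `fatigue` (n_subjects x 2 x 2 rows).
#' @export
simulate_behavioral <- function(cohort, subject_delta_kf, seed = NULL) {
  n <- cohort$n_subjects
  if (length(subject_delta_kf) != n)
    stop("subject_delta_kf must have one entry per subject")
  set_seed_scoped(seed)
  rho2 <- calibrate_rho2(cohort$fatigue_r2, n)
  sd_tot <- cohort$fatigue_delta_sd[["vaccine"]]
  beta1 <- sqrt(rho2) * sd_tot / cohort$effect_sd
  sigma_eps <- sd_tot * sqrt(1 - rho2)
  beta0 <- cohort$fatigue_delta_mean[["vaccine"]] - beta1 * cohort$effect_mean

  base_v <- stats::rnorm(n, cohort$fatigue_baseline_mean[["vaccine"]],
                         cohort$fatigue_baseline_sd[["vaccine"]])
  base_p <- stats::rnorm(n, cohort$fatigue_baseline_mean[["placebo"]],
                         cohort$fatigue_baseline_sd[["placebo"]])
  delta_v <- beta0 + beta1 * subject_delta_kf + stats::rnorm(n, 0, sigma_eps)
  delta_p <- stats::rnorm(n, cohort$fatigue_delta_mean[["placebo"]],
                          cohort$fatigue_delta_sd[["placebo"]])

  rlog <- function(n, m, s) {
    s2 <- log(1 + (s / m)^2)
    stats::rlnorm(n, log(m) - s2 / 2, sqrt(s2))
  }
  il6 <- list(
    vaccine_baseline = rlog(n, cohort$il6_mean[["vaccine_baseline"]],
                            cohort$il6_sd[["vaccine_baseline"]]),
    vaccine_4h = rlog(n, cohort$il6_mean[["vaccine_4h"]],
                      cohort$il6_sd[["vaccine_4h"]]),
    placebo_baseline = rlog(n, cohort$il6_mean[["placebo_baseline"]],
                            cohort$il6_sd[["placebo_baseline"]]),
    placebo_4h = rlog(n, cohort$il6_mean[["placebo_4h"]],
                      cohort$il6_sd[["placebo_4h"]]))

  grid <- expand.grid(subject = seq_len(n),
                      condition = c("vaccine", "placebo"),
                      timepoint = c("baseline", "4h"),
                      stringsAsFactors = FALSE)
  fatigue <- numeric(nrow(grid))
  il6_col <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- grid$subject[i]
    v <- grid$condition[i] == "vaccine"
    b <- grid$timepoint[i] == "baseline"
    fatigue[i] <- if (v) base_v[s] + if (b) 0 else delta_v[s]
                  else base_p[s] + if (b) 0 else delta_p[s]
    il6_col[i] <- il6[[paste0(grid$condition[i], "_",
                              ifelse(b, "baseline", "4h"))]][s]
  }
  grid$il6 <- il6_col
  grid$fatigue <- fatigue
  grid
}

#' Simulate the raw image volumes of one scanning session
#'
#' Forward-models every brain voxel of the ground-truth maps through the
#' two-pool bSSFP closed form (and the SPGR equation with the voxel's
#' observed T1 for the VFA rows), then adds Rician noise: the magnitude of
#' the complex signal with independent Gaussian noise of SD
#' sigma = (gray-matter mean bSSFP signal) / snr in both channels.
#' `snr = Inf` returns the exact noiseless forward signals.
#'
#' @param phantom a [build_phantom()] result.
#' @param protocol protocol data frame (bSSFP and/or SPGR rows).
#' @param snr reference signal-to-noise ratio (default from the phantom
#'   spec).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param truth optional replacement truth maps (e.g. after
#'   [apply_condition_effect()]).
#' @return 4-D array (x, y, z, volume) of magnitude signals (all >= 0).
#' @export
simulate_subject_session <- function(phantom, protocol,
                                     snr = phantom$spec$snr, seed = NULL,
                                     truth = phantom$truth) {
  if (nrow(protocol) == 0) stop("protocol is empty")
  sh <- dim(phantom$labels)
  if (!all(dim(truth$kf) == sh)) stop("truth maps do not match the grid")
  set_seed_scoped(seed)
  idx <- which(phantom$labels > 0L)
  nvol <- nrow(protocol)
  out <- array(0, c(sh, nvol))
  g0 <- lineshape_value(phantom$lineshape, phantom$t2b, 0)
  m0v <- truth$m0[idx]; fv <- truth$f[idx]; kfv <- truth$kf[idx]
  t1fv <- truth$t1f[idx]; t2fv <- truth$t2f[idx]; t1ov <- truth$t1_obs[idx]
  vol_stride <- prod(sh)
  gray_sum <- 0; gray_n <- 0
  gray_sel <- phantom$gray_mask[idx]
  for (j in seq_len(nvol)) {
    row <- protocol[j, ]
    if (row$kind == "bssfp") {
      alpha <- row$flip_deg * pi / 180
      trf <- row$trf_ms * 1e-3
      w <- pi * (alpha / trf)^2 * g0
      s <- bssfp_signal_core(m0v, fv, kfv, t1fv, phantom$t1b, t2fv,
                             alpha, row$tr_ms * 1e-3, trf, w)
      gray_sum <- gray_sum + sum(s[gray_sel]); gray_n <- gray_n + sum(gray_sel)
    } else {
      s <- spgr_signal(m0v, t1ov, protocol_row(protocol, j))
    }
    out[(j - 1) * vol_stride + idx] <- s
  }
  if (is.finite(snr)) {
    sigma <- (gray_sum / gray_n) / snr
    n_tot <- length(out)
    out <- sqrt((out + stats::rnorm(n_tot, 0, sigma))^2 +
                stats::rnorm(n_tot, 0, sigma)^2)
  }
  out
}

#' Simulate a full synthetic crossover cohort
#'
#' Orchestrates the generator end to end: builds the phantom, draws the
#' per-subject regional exchange-rate effects, injects them into the
#' vaccine-session truth maps, forward-simulates the raw volumes of both
#' sessions with Rician noise, randomizes the crossover order, and draws
#' the behavioral table. Fully deterministic given `cohort$seed`.
#'
#' @param phantom_spec a [phantom_spec()].
#' @param cohort a [cohort_spec()].
#' @param protocol protocol data frame (default [default_protocol()]).
#' @param simulate_raw if `FALSE`, skip the (memory-heavy) raw volumes and
#'   return ground-truth maps only.
#' @return A list of class `"cohort_dataset"` with elements `phantom`,
#'   `protocol`, `subjects` (per subject: `delta_kf`, `session_order`, and
#'   per condition `raw` 4-D array plus `truth_kf` map), `behavioral`, and
#'   `provenance`.
#' @export
simulate_cohort <- function(phantom_spec = phantom_spec(),
                            cohort = cohort_spec(),
                            protocol = default_protocol(),
                            simulate_raw = TRUE) {
  set_seed_scoped(cohort$seed)
  ph <- build_phantom(phantom_spec, seed = cohort$seed)
  roi <- ph$rois[[cohort$effect_roi]]
  if (is.null(roi)) stop("unknown effect ROI: ", cohort$effect_roi)
  n <- cohort$n_subjects
  delta <- stats::rnorm(n, cohort$effect_mean, cohort$effect_sd)
  order_first <- sample(rep(c("vaccine", "placebo"), length.out = n))
  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    truth_v <- apply_condition_effect(ph$truth, roi, delta[s], t1b = ph$t1b)
    subj <- list(delta_kf = delta[s],
                 session_order = c(order_first[s],
                                   setdiff(c("vaccine", "placebo"),
                                           order_first[s])),
                 truth_kf = list(placebo = ph$truth$kf, vaccine = truth_v$kf))
    if (simulate_raw) {
      subj$raw <- list(
        placebo = simulate_subject_session(ph, protocol, truth = ph$truth),
        vaccine = simulate_subject_session(ph, protocol, truth = truth_v))
    }
    subjects[[s]] <- subj
  }
  behavioral <- simulate_behavioral(cohort, delta)
  structure(list(phantom = ph, protocol = protocol, subjects = subjects,
                 behavioral = behavioral,
                 provenance = list(phantom_spec = phantom_spec,
                                   cohort_spec = cohort,
                                   seed = cohort$seed,
                                   package_version =
                                     as.character(utils::packageVersion("qmtbssfp")))),
            class = "cohort_dataset")
}

#' Simulate fitted exchange-rate maps for a cohort (map level)
#'
#' Generates per-subject, per-session exchange-rate maps directly at the
#' parameter-map level: ground truth (with the subject's vaccine effect)
#' plus independent Gaussian voxel noise of SD `sigma_vox`, emulating the
#' voxel-wise fit error of the full image pipeline. This is the problem
#' size used for replication studies of the group-inference stage, where
#' refitting raw volumes for every replicate would add nothing: the fit
#' noise scale is instead calibrated once with [estimate_kf_sigma()].
#'
#' @param phantom a [build_phantom()] result.
#' @param cohort a [cohort_spec()].
#' @param sigma_vox voxel-level SD of the exchange-rate estimate, 1/s.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A list with `vaccine` and `placebo` (lists of n 3-D maps),
#'   `subject_delta` and the effect `roi` mask.
#' @export
simulate_kf_map_cohort <- function(phantom, cohort, sigma_vox, seed = NULL) {
  set_seed_scoped(seed)
  roi <- phantom$rois[[cohort$effect_roi]]
  n <- cohort$n_subjects
  sh <- dim(phantom$labels)
  base_kf <- phantom$truth$kf
  base_kf[!phantom$brain_mask] <- NA_real_
  delta <- stats::rnorm(n, cohort$effect_mean, cohort$effect_sd)
  noise_map <- function() array(stats::rnorm(prod(sh), 0, sigma_vox), sh)
  vaccine <- placebo <- vector("list", n)
  for (s in seq_len(n)) {
    kf_v <- base_kf
    kf_v[roi] <- kf_v[roi] + delta[s]
    vaccine[[s]] <- kf_v + noise_map()
    placebo[[s]] <- base_kf + noise_map()
  }
  list(vaccine = vaccine, placebo = placebo, subject_delta = delta, roi = roi)
}

#' Calibrate the voxel-level exchange-rate fit noise
#'
#' Monte Carlo estimate of the SD of the fitted exchange rate for a
#' gray-matter voxel at the given SNR: replicates of the full per-voxel
#' pipeline (Rician noise on the bSSFP and VFA series, VFA T1 fit, qMT
#' fit).
#'
#' @param phantom a [build_phantom()] result.
#' @param protocol protocol data frame with bSSFP and SPGR rows.
#' @param snr reference SNR (default from the phantom spec).
#' @param n_rep number of Monte Carlo replicates.
#' @param seed integer seed.
#' @param opts [qmt_fit_options()] used for the fits.
#' @return A list with `sigma_kf` (SD of fitted kf, 1/s), `bias_kf`, and
#'   the vector of estimates `kf_hat`.
#' @export
estimate_kf_sigma <- function(phantom, protocol, snr = phantom$spec$snr,
                              n_rep = 200L, seed = 1L,
                              opts = qmt_fit_options()) {
  set_seed_scoped(seed)
  p <- phantom$spec$tissues$gray
  bs <- protocol[protocol$kind == "bssfp", ]
  sp <- protocol[protocol$kind == "spgr", ]
  s_bssfp <- bssfp_two_pool_signal(p, bs)
  t1o <- observed_t1(p)
  s_spgr <- vapply(seq_len(nrow(sp)), function(j)
    spgr_signal(p$m0, t1o, protocol_row(sp, j)), numeric(1))
  sigma <- mean(s_bssfp) / snr
  kf_hat <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    nb <- length(s_bssfp); ns <- length(s_spgr)
    y_b <- sqrt((s_bssfp + stats::rnorm(nb, 0, sigma))^2 +
                stats::rnorm(nb, 0, sigma)^2)
    y_s <- sqrt((s_spgr + stats::rnorm(ns, 0, sigma))^2 +
                stats::rnorm(ns, 0, sigma)^2)
    t1fit <- fit_vfa_t1(y_s, sp$flip_deg, sp$tr_ms[1])
    if (!t1fit$valid) next
    fit <- fit_qmt_voxel(y_b, bs, t1fit$t1, opts)
    if (fit$valid) kf_hat[r] <- fit$kf
  }
  ok <- is.finite(kf_hat)
  list(sigma_kf = stats::sd(kf_hat[ok]),
       bias_kf = mean(kf_hat[ok]) - p$kf,
       kf_hat = kf_hat)
}
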