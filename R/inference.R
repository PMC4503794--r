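#' Gaussian smoothing of a 3-D map
#'
#' Separable Gaussian convolution with kernel SD
#' sigma = fwhm / (2 sqrt(2 log 2)) per axis, specified in millimetres.
#' With a mask, values outside it are excluded and the kernel renormalized
#' over in-mask voxels, so a constant map stays constant; voxels outside
#' the mask are `NA` in the output. `fwhm_mm = 0` returns the input
#' unchanged.
#'
#' @param map 3-D numeric array.
#' @param fwhm_mm full width at half maximum in mm (scalar or per-axis).
#' @param voxel_mm voxel size in mm (scalar or per-axis).
#' @param mask optional logical 3-D array.
#' @return Smoothed 3-D array.
#' @export
smooth_volume <- function(map, fwhm_mm, voxel_mm, mask = NULL) {
  if (any(fwhm_mm < 0)) stop("fwhm_mm must be non-negative")
  if (all(fwhm_mm == 0)) {
    if (!is.null(mask)) map[!mask] <- NA_real_
    return(map)
  }
  sh <- dim(map)
  kernels <- gaussian_kernels(fwhm_mm, voxel_mm, sh)
  if (is.null(mask)) {
    num <- conv_separable(map, kernels)
    den <- conv_separable(array(1, sh), kernels)
    return(num / den)
  }
  mask <- array(as.logical(mask), sh)
  x <- map
  x[!mask] <- 0
  num <- conv_separable(x, kernels)
  den <- conv_separable(array(as.numeric(mask), sh), kernels)
  out <- num / den
  out[!mask] <- NA_real_
  out
}

gaussian_kernels <- function(fwhm_mm, voxel_mm, sh) {
  fwhm_mm <- rep(fwhm_mm, length.out = 3)
  voxel_mm <- rep(voxel_mm, length.out = 3)
  lapply(1:3, function(d) {
    sigma <- fwhm_mm[d] / (2 * sqrt(2 * log(2))) / voxel_mm[d]
    if (sigma == 0) return(1)
    r <- max(1L, ceiling(4 * sigma))
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    k / sum(k)
  })
}

# Separable convolution with zero padding, via banded matrices per axis.
conv_separable <- function(x, kernels) {
  sh <- dim(x)
  for (d in 1:3) {
    k <- kernels[[d]]
    if (length(k) == 1) next
    n <- sh[d]
    r <- (length(k) - 1) / 2
    K <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[off + r + 1]
    }
    perm <- c(d, setdiff(1:3, d))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xm <- K %*% matrix(xp, nrow = n)
    x <- aperm(array(xm, dp), order(perm))
  }
  x
}

#' Voxel-wise paired t map
#'
#' Per voxel inside the mask, the one-sample t statistic of the paired
#' differences d = a - b across subjects: t = mean(d) / (sd(d)/sqrt(n)).
#' Voxels with zero difference variance are flagged invalid (`NA`) rather
#' than returning infinities.
#'
#' @param maps_a,maps_b lists of per-subject 3-D maps, same subjects in the
#'   same order (n >= 3).
#' @param mask logical 3-D array.
#' @return A list of class `"stat_map"` with the `t` array (`NA` outside
#'   the mask and at invalid voxels), `df = n - 1`, `n_pairs` and `mask`.
#' @export
paired_t_map <- function(maps_a, maps_b, mask) {
  n <- length(maps_a)
  if (length(maps_b) != n) stop("maps_a and maps_b must pair up per subject")
  if (n < 3) stop("need at least 3 subject pairs")
  sh <- dim(maps_a[[1]])
  mask <- array(as.logical(mask), sh)
  idx <- which(mask)
  d <- vapply(seq_len(n),
              function(s) maps_a[[s]][idx] - maps_b[[s]][idx],
              numeric(length(idx)))
  m <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - m)^2) / (n - 1))
  # (near-)zero sd with zero mean (a == b) is t = 0; a constant nonzero
  # difference has no finite t and is flagged invalid
  degenerate <- sd_d <= 1e-12 * pmax(abs(m), .Machine$double.xmin)
  tval <- ifelse(!degenerate, m / (sd_d / sqrt(n)),
                 ifelse(m == 0, 0, NA_real_))
  t_arr <- array(NA_real_, sh)
  t_arr[idx] <- tval
  structure(list(t = t_arr, df = n - 1L, n_pairs = n, mask = mask),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> df=%d, %d masked voxels, max |t| = %.3f\n",
              x$df, sum(x$mask), max(abs(x$t), na.rm = TRUE)))
  invisible(x)
}

# Neighbor offsets for a given 3-D connectivity.
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Label connected components of a binary 3-D mask
#'
#' Breadth-first labeling at 6, 18 or 26 connectivity.
#'
#' @param mask logical 3-D array.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (all neighbors).
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  sh <- dim(mask)
  off <- connectivity_offsets(as.integer(connectivity))
  idx <- which(mask)
  labels <- array(0L, sh)
  if (length(idx) == 0) return(labels)
  coords <- arrayInd(idx, sh)
  pos <- array(0L, sh)
  pos[idx] <- seq_along(idx)
  lab_v <- integer(length(idx))
  current <- 0L
  for (seed in seq_along(idx)) {
    if (lab_v[seed] != 0L) next
    current <- current + 1L
    queue <- seed
    lab_v[seed] <- current
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      cc <- coords[v, ]
      for (o in seq_len(nrow(off))) {
        nb <- cc + off[o, ]
        if (any(nb < 1) || any(nb > sh)) next
        pid <- pos[nb[1], nb[2], nb[3]]
        if (pid != 0L && lab_v[pid] == 0L) {
          lab_v[pid] <- current
          queue <- c(queue, pid)
        }
      }
    }
  }
  labels[idx] <- lab_v
  labels
}

#' Extract suprathreshold clusters from a t map
#'
#' Thresholds the statistic map at the one-sided (default) or two-sided
#' t quantile for `p_voxel`, labels connected components, and tabulates
#' them sorted by extent.
#'
#' @param stat a `"stat_map"` from [paired_t_map()].
#' @param p_voxel cluster-forming voxel-level p threshold, in (0, 1).
#' @param connectivity 6, 18 or 26 (default).
#' @param alternative `"greater"` (default; positive effects, matching a
#'   vaccine > placebo contrast) or `"two.sided"`.
#' @param voxel_mm voxel size for peak coordinates in mm.
#' @return A data frame with one row per cluster: `label`, `extent`,
#'   `peak_t`, `peak_x`, `peak_y`, `peak_z` (grid indices), `peak_x_mm`,
#'   `peak_y_mm`, `peak_z_mm`, plus attribute `"threshold"`.
#' @export
extract_clusters <- function(stat, p_voxel = 0.001, connectivity = 26L,
                             alternative = c("greater", "two.sided"),
                             voxel_mm = 1) {
  alternative <- match.arg(alternative)
  if (p_voxel <= 0 || p_voxel >= 1) stop("p_voxel must be in (0, 1)")
  thr <- stats::qt(1 - if (alternative == "greater") p_voxel else p_voxel / 2,
                   stat$df)
  tv <- stat$t
  supra <- !is.na(tv) & (if (alternative == "greater") tv > thr
                         else abs(tv) > thr)
  labels <- label_components(supra, connectivity)
  n_cl <- max(labels)
  voxel_mm <- rep(voxel_mm, length.out = 3)
  if (n_cl == 0) {
    out <- data.frame(label = integer(0), extent = integer(0),
                      peak_t = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0),
                      peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                      peak_z_mm = numeric(0))
    attr(out, "threshold") <- thr
    attr(out, "labels") <- labels
    return(out)
  }
  rows <- lapply(seq_len(n_cl), function(l) {
    vox <- which(labels == l)
    tt <- tv[vox]
    peak <- vox[which.max(abs(tt))]
    pc <- arrayInd(peak, dim(tv))[1, ]
    data.frame(label = l, extent = length(vox), peak_t = tt[which.max(abs(tt))],
               peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
               peak_x_mm = pc[1] * voxel_mm[1], peak_y_mm = pc[2] * voxel_mm[2],
               peak_z_mm = pc[3] * voxel_mm[3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$extent), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "labels") <- labels
  out
}

#' Monte Carlo critical cluster extent
#'
#' Simulates the null distribution of the largest suprathreshold cluster in
#' smoothed Gaussian noise restricted to the mask, and returns the critical
#' extent k*: the smallest integer k such that the estimated probability of
#' observing any null cluster of extent >= k is at most `alpha`. A cluster
#' is then declared significant when its extent is at least k*. Per
#' iteration the mask is filled with unit white noise, smoothed with the
#' renormalized masked kernel, re-standardized within the mask and
#' thresholded at the one-sided normal quantile for `p_voxel`.
#' Re-standardization is per voxel by default: the smoothing variance
#' Var_i = sum_j K_ij^2 / (sum_j K_ij)^2 of the renormalized kernel is
#' computed analytically (the squared Gaussian kernel is a Gaussian with
#' sigma/sqrt(2)), so mask-boundary voxels are standardized exactly like
#' interior ones — matching the per-voxel self-normalization of the t map
#' the threshold is applied to.
#'
#' @param mask logical 3-D array.
#' @param fwhm_mm,voxel_mm smoothing kernel geometry, mm.
#' @param p_voxel cluster-forming threshold.
#' @param n_iter number of Monte Carlo iterations (>= 100; default 1000).
#' @param alpha corrected significance level (default 0.05).
#' @param seed integer seed (simulation is deterministic given it).
#' @param connectivity cluster connectivity (default 26).
#' @param standardize `"voxel"` (default) or `"global"`.
#' @param df if supplied, simulate a degrees-of-freedom-matched null: each
#'   iteration draws `df + 1` smoothed noise maps and thresholds the
#'   one-sample t field of their per-voxel mean at the t quantile, exactly
#'   mirroring the statistic the threshold is applied to. The default
#'   (`NULL`) thresholds a single standardized Gaussian field at the normal
#'   quantile, which is slightly conservative for small samples because a
#'   t field is rougher than its underlying Gaussian.
#' @return A list of class `"mc_extent"` with `k_star`, the sorted
#'   `max_extents`, and the call parameters.
#' @export
monte_carlo_cluster_threshold <- function(mask, fwhm_mm, voxel_mm,
                                          p_voxel = 0.001, n_iter = 1000L,
                                          alpha = 0.05, seed = 1L,
                                          connectivity = 26L,
                                          standardize = c("voxel", "global"),
                                          df = NULL) {
  standardize <- match.arg(standardize)
  if (n_iter < 100) stop("n_iter must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  sh <- dim(mask)
  mask <- array(as.logical(mask), sh)
  if (!any(mask)) stop("mask is empty")
  idx <- which(mask)
  zthr <- stats::qnorm(1 - p_voxel)
  kernels <- gaussian_kernels(fwhm_mm, voxel_mm, sh)
  smoothing <- !all(fwhm_mm == 0)
  if (smoothing) {
    m_num <- array(as.numeric(mask), sh)
    den <- conv_separable(m_num, kernels) # sum of kernel weights in mask
    k2 <- lapply(kernels, function(k) if (length(k) == 1) 1 else k^2)
    u <- conv_separable(m_num, k2)        # sum of squared kernel weights
    sd_map <- sqrt(u) / den
  }
  if (!is.null(df)) {
    if (df < 2) stop("df must be >= 2 for the t-matched null")
    tthr <- stats::qt(1 - p_voxel, df)
    n_sub <- df + 1L
  }
  smooth_field <- function() {
    e <- array(0, sh)
    e[idx] <- stats::rnorm(length(idx))
    if (!smoothing) return(e)
    z <- conv_separable(e, kernels) / den
    if (standardize == "voxel") z / sd_map else z / stats::sd(z[idx])
  }
  set_seed_scoped(seed)
  max_extents <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    supra <- array(FALSE, sh)
    if (is.null(df)) {
      z <- smooth_field()
      supra[idx] <- z[idx] > zthr
    } else {
      d <- vapply(seq_len(n_sub), function(s) smooth_field()[idx],
                  numeric(length(idx)))
      m <- rowMeans(d)
      sd_d <- sqrt(rowSums((d - m)^2) / df)
      supra[idx] <- sd_d > 0 & m / (sd_d / sqrt(n_sub)) > tthr
    }
    if (!any(supra)) next
    labels <- label_components(supra, connectivity)
    max_extents[it] <- max(tabulate(labels[labels > 0L]))
  }
  k <- 1L
  while (mean(max_extents >= k) > alpha) k <- k + 1L
  structure(list(k_star = k, max_extents = sort(max_extents),
                 p_voxel = p_voxel, alpha = alpha, n_iter = n_iter,
                 fwhm_mm = fwhm_mm, voxel_mm = voxel_mm,
                 connectivity = connectivity, seed = seed, df = df),
            class = "mc_extent")
}

#' @export
print.mc_extent <- function(x, ...) {
  cat(sprintf(
    "<mc_extent> k* = %d voxels (p_voxel = %g, alpha = %g, %d iterations)\n",
    x$k_star, x$p_voxel, x$alpha, x$n_iter))
  invisible(x)
}

#' Small-volume family-wise error by sign-flip permutation
#'
#' Voxel-level FWE-corrected inference within a region of interest: the
#' null distribution of the maximum t statistic over ROI voxels is built by
#' flipping the signs of the paired differences per subject (exact
#' enumeration of all 2^n sign patterns when feasible, otherwise random
#' flips), and the corrected p of the observed peak is its rank in that
#' distribution.
#'
#' @param maps_a,maps_b per-subject 3-D map lists (n >= 5 recommended).
#' @param roi_mask logical 3-D array, subset of the acquisition mask.
#' @param n_perm permutation budget; all `2^n` sign patterns are enumerated
#'   when `2^n <= n_perm`.
#' @param seed integer seed for random flips.
#' @param alternative `"greater"` (max t, default) or `"two.sided"`
#'   (max |t|).
#' @return A list with `p_fwe`, `peak_t`, `peak_index` (grid indices),
#'   `n_perm_used` and `exact` (logical, full enumeration).
#' @export
roi_fwe_smallvolume <- function(maps_a, maps_b, roi_mask, n_perm = 2000L,
                                seed = NULL,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!any(roi_mask)) stop("roi is empty")
  n <- length(maps_a)
  if (length(maps_b) != n) stop("maps_a and maps_b must pair up per subject")
  idx <- which(roi_mask)
  d <- vapply(seq_len(n),
              function(s) maps_a[[s]][idx] - maps_b[[s]][idx],
              numeric(length(idx)))
  d <- t(d) # subjects x voxels
  ss <- colSums(d^2) # invariant under sign flips
  stat_of <- function(signs_matrix) {
    m <- (signs_matrix %*% d) / n
    se <- sqrt(pmax(sweep(-n * m^2, 2, ss, `+`), 0) / (n - 1) / n)
    tmat <- m / se
    tmat[!is.finite(tmat)] <- 0
    if (alternative == "greater") apply(tmat, 1, max)
    else apply(abs(tmat), 1, max)
  }
  obs <- stat_of(matrix(1, 1, n))
  exact <- 2^n <= n_perm
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_max <- stat_of(signs)
    p <- mean(null_max >= obs)
    n_used <- nrow(signs)
  } else {
    set_seed_scoped(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    null_max <- stat_of(signs)
    p <- (1 + sum(null_max >= obs)) / (n_perm + 1)
    n_used <- n_perm
  }
  peak_local <- {
    t_obs <- (colSums(d) / n) /
      sqrt(pmax(ss - n * (colSums(d) / n)^2, 0) / (n - 1) / n)
    if (alternative == "greater") which.max(t_obs) else which.max(abs(t_obs))
  }
  list(p_fwe = p, peak_t = obs,
       peak_index = arrayInd(idx[peak_local], dim(roi_mask))[1, ],
       n_perm_used = n_used, exact = exact)
}

#' Mean change within a region of interest, per subject
#'
#' Unweighted mean over ROI voxels of each subject's difference map.
#'
#' @param diff_maps list of per-subject 3-D difference maps.
#' @param roi_mask logical 3-D array.
#' @return Numeric vector, one value per subject.
#' @export
roi_mean_change <- function(diff_maps, roi_mask) {
  if (!any(roi_mask)) stop("roi is empty")
  sh <- dim(roi_mask)
  vapply(diff_maps, function(m) {
    if (!all(dim(m) == sh)) stop("map grid does not match the ROI grid")
    mean(m[roi_mask])
  }, numeric(1))
}

#' Regress a behavioral change on a regional imaging change
#'
#' Ordinary least squares of the covariate change (e.g. fatigue) on the
#' per-subject regional imaging change (e.g. mean insular exchange-rate
#' change), with the two-sided p value of the slope from the t distribution
#' with n - 2 degrees of freedom.
#'
#' @param delta_roi per-subject regional change (predictor).
#' @param delta_covariate per-subject behavioral change (response).
#' @return A list with `slope`, `intercept`, `r2` and `p`.
#' @export
regress_change_on_covariate <- function(delta_roi, delta_covariate) {
  n <- length(delta_roi)
  if (length(delta_covariate) != n) stop("inputs must have equal length")
  if (n < 3) stop("need at least 3 subjects")
  if (any(!is.finite(delta_roi)) || any(!is.finite(delta_covariate)))
    stop("inputs must be finite")
  if (stats::var(delta_roi) == 0)
    stop("zero variance in the predictor")
  fit <- stats::lm(delta_covariate ~ delta_roi)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients[2, 4]))
}

#' Within-subject 2x2 treatment-by-time interaction
#'
#' The repeated-measures interaction F for a complete 2 (condition) x
#' 2 (timepoint) within-subject design, computed through the exact identity
#' F = t^2 where t is the one-sample t of the per-subject
#' difference-of-differences (change under vaccine minus change under
#' placebo); df1 = 1, df2 = n - 1.
#'
#' @param table behavioral data frame with columns `subject`, `condition`
#'   (`vaccine`/`placebo`), `timepoint` (`baseline`/`4h`) and the outcome.
#' @param outcome name of the outcome column (e.g. `"fatigue"`, `"il6"`).
#' @return A list with `F`, `df1`, `df2`, `p` and the per-subject
#'   difference-of-differences `dod`.
#' @export
repeated_measures_interaction <- function(table, outcome = "fatigue") {
  if (!outcome %in% names(table)) stop("no column named ", outcome)
  subs <- sort(unique(table$subject))
  cell <- function(s, cond, tp) {
    v <- table[table$subject == s & table$condition == cond &
                 table$timepoint == tp, outcome]
    if (length(v) != 1 || !is.finite(v))
      stop("incomplete or non-finite 2x2 design for subject ", s)
    v
  }
  dod <- vapply(subs, function(s) {
    (cell(s, "vaccine", "4h") - cell(s, "vaccine", "baseline")) -
      (cell(s, "placebo", "4h") - cell(s, "placebo", "baseline"))
  }, numeric(1))
  n <- length(dod)
  if (n < 2) stop("need at least 2 subjects")
  sd_dod <- stats::sd(dod)
  tval <- if (sd_dod == 0) 0 else mean(dod) / (sd_dod / sqrt(n))
  Fval <- tval^2
  list(F = Fval, df1 = 1L, df2 = n - 1L,
       p = stats::pf(Fval, 1, n - 1, lower.tail = FALSE), dod = dod)
}

#' Scale a volume to a grand mean
#'
#' Multiplies the volume so that its mean over the mask equals `target`
#' exactly (the normalization used for uptake-like maps, conventionally to
#' 50 mL/100 g/min).
#'
#' @param map 3-D array.
#' @param mask logical 3-D array.
#' @param target target within-mask mean (default 50).
#' @return The rescaled map.
#' @export
grand_mean_scale <- function(map, mask, target = 50) {
  m <- mean(map[mask])
  if (!is.finite(m) || m == 0) stop("within-mask mean is zero or undefined")
  map * (target / m)
}

#' Exclusive masking of a statistic map
#'
#' Invalidates (sets to `NA`) every voxel of `stat` at which the control
#' statistic map exceeds its one-sided threshold at `p_mask`, the device
#' used to discount nonspecific (e.g. time-of-day) effects: voxels
#' "active" in the control contrast are excluded from the contrast of
#' interest. All other voxels pass through unchanged.
#'
#' @param stat,control_stat `"stat_map"` objects on the same grid.
#' @param p_mask masking threshold (default 0.005).
#' @return A `"stat_map"` like `stat` with masked voxels invalidated; its
#'   `mask` is updated accordingly. Warns when nothing survives.
#' @export
exclusive_mask <- function(stat, control_stat, p_mask = 0.005) {
  if (!all(dim(stat$t) == dim(control_stat$t)))
    stop("statistic maps are on different grids")
  thr <- stats::qt(1 - p_mask, control_stat$df)
  exclude <- !is.na(control_stat$t) & control_stat$t > thr
  out <- stat
  out$t[exclude] <- NA_real_
  out$mask <- out$mask & !exclude
  if (!any(!is.na(out$t) & out$mask))
    warning("exclusive mask removed every voxel")
  out
}
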