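#' Specification of the digital brain phantom
#'
#' Describes the geometry and tissue composition of the synthetic phantom:
#' an ellipsoidal brain with a gray-matter mantle, a white-matter core, a
#' small central CSF compartment, deep gray-matter blobs standing in for the
#' basal ganglia, and insula-like ellipsoidal regions of interest in the
#' lateral gray matter of each hemisphere. Geometry is procedural, not
#' anatomical; regions of interest are defined as the intersection of an
#' ellipsoid with the gray-matter label, so the containment invariant holds
#' by construction.
#'
#' @param shape integer vector of grid dimensions (default 32 x 32 x 8).
#' @param voxel_mm isotropic voxel size in millimetres (default 3).
#' @param tissues named list of [two_pool_params()] for `gray`, `white`,
#'   `csf`. Defaults are literature-style 1.5 T brain values.
#' @param snr reference signal-to-noise ratio: gray-matter mean signal
#'   divided by the Gaussian channel noise sigma of the Rician model.
#' @param jitter_sd relative SD of an optional smooth multiplicative jitter
#'   applied to the `f` and `kf` truth maps (0 disables it).
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 8L), voxel_mm = 3,
                         tissues = default_tissues(), snr = 100,
                         jitter_sd = 0) {
  if (length(shape) != 3 || any(shape < 8))
    stop("shape must be a 3-vector with all dimensions >= 8")
  if (voxel_mm <= 0) stop("voxel_mm must be positive")
  stopifnot(all(c("gray", "white", "csf") %in% names(tissues)))
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 tissues = tissues, snr = snr, jitter_sd = jitter_sd),
            class = "phantom_spec")
}

#' Default tissue parameters of the phantom
#'
#' Two-pool parameters for the phantom's tissue classes, typical of brain
#' at 1.5 T: white matter with a larger bound pool and faster exchange than
#' gray matter, and CSF modeled as an (almost) free single pool.
#'
#' @return Named list of [two_pool_params()].
#' @export
default_tissues <- function() {
  list(
    gray = two_pool_params(m0 = 1000, f = 0.08, kf = 2.6, t1f = 1.15,
                           t2f = 0.085),
    white = two_pool_params(m0 = 900, f = 0.14, kf = 4.2, t1f = 0.65,
                            t2f = 0.055),
    csf = two_pool_params(m0 = 1100, f = 0.001, kf = 0.3, t1f = 3.5,
                          t2f = 0.25)
  )
}

# Ellipsoid membership on the voxel grid; center/semi in voxel units.
ellipsoid_mask <- function(shape, center, semi) {
  x <- seq_len(shape[1]); y <- seq_len(shape[2]); z <- seq_len(shape[3])
  dx2 <- ((x - center[1]) / semi[1])^2
  dy2 <- ((y - center[2]) / semi[2])^2
  dz2 <- ((z - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Build the digital phantom
#'
#' Assembles the label volume, region-of-interest masks and per-voxel
#' ground-truth parameter maps from a [phantom_spec()]. Deterministic given
#' `seed` (randomness enters only through the optional smooth jitter).
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the jitter field.
#' @return A list of class `"phantom"` with `labels` (3-D array coded
#'   0 = background, 1 = gray, 2 = white, 3 = csf), `rois` (named list of
#'   logical masks: `insula_left`, `insula_right`, `bg_left`, `bg_right`),
#'   `brain_mask` (gray + white), `truth` (list of 3-D arrays `m0`, `f`,
#'   `kf`, `t1f`, `t2f`, `t1_obs`), the bound-pool constants, and the spec.
#' @examples
#' ph <- build_phantom(phantom_spec(shape = c(16, 16, 4)))
#' table(ph$labels)
#' @export
build_phantom <- function(spec = phantom_spec(), seed = 1L) {
  sh <- spec$shape
  c0 <- (sh + 1) / 2
  rel <- function(cx, cy, cz) c0 + c(cx, cy, cz) * sh / c(32, 32, 8)
  sc <- function(sx, sy, sz) c(sx, sy, sz) * sh / c(32, 32, 8)

  brain <- ellipsoid_mask(sh, c0, sc(13, 14, 3.6))
  white <- ellipsoid_mask(sh, c0, sc(8, 9, 2.2))
  csf <- ellipsoid_mask(sh, c0, sc(2.5, 2.5, 1.0))
  # deep gray blobs (basal-ganglia-like) carved out of the white core
  bg_l <- ellipsoid_mask(sh, rel(-4.5, 1, 0), sc(2.2, 2.8, 1.3))
  bg_r <- ellipsoid_mask(sh, rel(4.5, 1, 0), sc(2.2, 2.8, 1.3))
  labels <- array(0L, sh)
  labels[brain] <- 1L            # gray mantle
  labels[white] <- 2L
  labels[csf] <- 3L
  labels[(bg_l | bg_r) & labels == 2L] <- 1L # deep gray islands
  gray <- labels == 1L

  ins_l <- ellipsoid_mask(sh, rel(-9.5, 0, 0), sc(3.2, 5.5, 2.4)) & gray
  ins_r <- ellipsoid_mask(sh, rel(9.5, 0, 0), sc(3.2, 5.5, 2.4)) & gray
  rois <- list(insula_left = ins_l, insula_right = ins_r,
               bg_left = bg_l & gray, bg_right = bg_r & gray)
  for (nm in names(rois)) {
    if (!any(rois[[nm]])) stop("ROI ", nm, " is empty on this grid")
    if (any(rois[[nm]] & !gray)) stop("ROI ", nm, " escapes the gray matter")
  }

  tis <- spec$tissues
  truth <- list(m0 = array(0, sh), f = array(0, sh), kf = array(0, sh),
                t1f = array(NA_real_, sh), t2f = array(NA_real_, sh))
  for (k in 1:3) {
    p <- tis[[c("gray", "white", "csf")[k]]]
    sel <- labels == k
    truth$m0[sel] <- p$m0; truth$f[sel] <- p$f; truth$kf[sel] <- p$kf
    truth$t1f[sel] <- p$t1f; truth$t2f[sel] <- p$t2f
  }
  if (spec$jitter_sd > 0) {
    set_seed_scoped(seed)
    jit <- array(stats::rnorm(prod(sh)), sh)
    jit <- smooth_volume(jit, fwhm_mm = 3 * spec$voxel_mm,
                         voxel_mm = spec$voxel_mm)
    jit <- 1 + spec$jitter_sd * jit / stats::sd(jit[labels > 0])
    jit[jit < 0.5] <- 0.5
    inb <- labels > 0
    truth$f[inb] <- pmin(truth$f[inb] * jit[inb], 0.45)
    truth$kf[inb] <- truth$kf[inb] * jit[inb]
  }
  truth$t1_obs <- array(NA_real_, sh)
  inb <- which(labels > 0)
  truth$t1_obs[inb] <- vapply(inb, function(i) {
    observed_t1(list(f = truth$f[i], kf = truth$kf[i], t1f = truth$t1f[i],
                     t1b = tis$gray$t1b))
  }, numeric(1))

  structure(list(labels = labels, rois = rois,
                 brain_mask = labels == 1L | labels == 2L,
                 gray_mask = gray, truth = truth,
                 t1b = tis$gray$t1b, t2b = tis$gray$t2b,
                 lineshape = tis$gray$lineshape, spec = spec),
            class = "phantom")
}

#' Inject a condition effect into ground-truth maps
#'
#' Adds `delta_kf` to the exchange-rate truth map inside the region of
#' interest, leaving every other voxel and parameter untouched. This is the
#' generative model of the inflammation effect: a localized increase in the
#' free-to-bound exchange rate.
#'
#' @param truth the `truth` list of a [build_phantom()] result (or any list
#'   of parameter arrays containing `kf`).
#' @param roi logical mask of the affected region.
#' @param delta_kf exchange-rate increase in 1/s (finite; may be negative).
#' @param t1b bound-pool T1 used to refresh the observed-T1 map.
#' @return The modified truth list; `delta_kf = 0` returns it unchanged.
#' @export
apply_condition_effect <- function(truth, roi, delta_kf, t1b = 1.0) {
  if (!is.finite(delta_kf)) stop("delta_kf must be finite")
  if (!any(roi)) stop("roi is empty")
  if (!all(dim(roi) == dim(truth$kf))) stop("roi does not match the grid")
  truth$kf[roi] <- truth$kf[roi] + delta_kf
  if (!is.null(truth$t1_obs)) {
    idx <- which(roi & is.finite(truth$t1_obs))
    truth$t1_obs[idx] <- vapply(idx, function(i) {
      observed_t1(list(f = truth$f[i], kf = truth$kf[i], t1f = truth$t1f[i],
                       t1b = t1b))
    }, numeric(1))
  }
  truth
}
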