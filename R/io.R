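#' Read a NIfTI volume
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return A list with `data` (numeric array) and `voxel_mm` (per-axis
#'   voxel size).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  list(data = array(as.numeric(img), dim(img)),
       voxel_mm = RNifti::pixdim(img)[seq_len(min(3, nd))])
}

#' Write a NIfTI volume
#'
#' @param volume numeric array (3-D or 4-D).
#' @param path destination path (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel size in mm (scalar or per-axis).
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, voxel_mm = 1) {
  img <- RNifti::asNifti(volume)
  nd <- length(dim(volume))
  pd <- c(rep(voxel_mm, length.out = min(3, nd)), rep(1, max(0, nd - 3)))
  RNifti::pixdim(img) <- pd
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an acquisition protocol table
#'
#' Accepts tab- or comma-separated text (by extension `.tsv`/`.csv`) or
#' JSON (an array of row objects). Columns `volume_index`, `kind`,
#' `flip_deg`, `tr_ms`, `trf_ms` are required; every row is validated and
#' errors name the offending row.
#'
#' @param path protocol file path.
#' @return Validated protocol data frame in file order.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  protocol <- switch(ext,
    tsv = utils::read.delim(path, stringsAsFactors = FALSE),
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path)),
    stop("unsupported protocol format: .", ext))
  validate_protocol(protocol)
}

#' Write an acquisition protocol table
#'
#' @param protocol protocol data frame.
#' @param path destination (`.tsv`, `.csv` or `.json`).
#' @return The path, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  ext <- tolower(tools::file_ext(path))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path))
  switch(ext,
    tsv = utils::write.table(protocol, tmp, sep = "\t", row.names = FALSE,
                             quote = FALSE),
    csv = utils::write.csv(protocol, tmp, row.names = FALSE, quote = FALSE),
    json = jsonlite::write_json(protocol, tmp, digits = NA),
    stop("unsupported protocol format: .", ext))
  file.rename(tmp, path)
  invisible(path)
}

write_json_atomic <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path))
  utils::write.table(df, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a simulated cohort to a BIDS-like directory
#'
#' Lays out `sub-XX/ses-{placebo,vaccine}/` NIfTI volumes (raw 4-D series
#' and ground-truth exchange-rate map), the protocol TSV, the behavioral
#' table as `participants.tsv`, mask/ROI volumes under `masks/`, and a
#' provenance JSON carrying the generating specifications and seed.
#'
#' @param dataset a [simulate_cohort()] result (with raw volumes).
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- dataset$phantom$spec$voxel_mm
  write_protocol(dataset$protocol, file.path(dir, "protocol.tsv"))
  write_tsv_atomic(dataset$behavioral, file.path(dir, "participants.tsv"))
  write_volume(dataset$phantom$labels + 0, file.path(dir, "masks",
                                                     "labels.nii.gz"), vox)
  write_volume(dataset$phantom$brain_mask + 0,
               file.path(dir, "masks", "brain_mask.nii.gz"), vox)
  for (nm in names(dataset$phantom$rois))
    write_volume(dataset$phantom$rois[[nm]] + 0,
                 file.path(dir, "masks", paste0("roi-", nm, ".nii.gz")), vox)
  for (s in seq_along(dataset$subjects)) {
    sub <- dataset$subjects[[s]]
    sid <- sprintf("sub-%02d", s)
    for (ses in c("placebo", "vaccine")) {
      sesdir <- file.path(dir, sid, paste0("ses-", ses))
      if (!is.null(sub$raw))
        write_volume(sub$raw[[ses]],
                     file.path(sesdir, paste0(sid, "_ses-", ses,
                                              "_qmt.nii.gz")), vox)
      write_volume(sub$truth_kf[[ses]],
                   file.path(sesdir, paste0(sid, "_ses-", ses,
                                            "_truth-kf.nii.gz")), vox)
    }
  }
  prov <- dataset$provenance
  prov$subject_delta_kf <- vapply(dataset$subjects, `[[`, numeric(1),
                                  "delta_kf")
  prov$session_order <- lapply(dataset$subjects, `[[`, "session_order")
  write_json_atomic(prov, file.path(dir, "provenance.json"))
  invisible(dir)
}

#' Default run configuration
#'
#' The single source of truth for pipeline settings: phantom and cohort
#' blocks, fit options, and inference options (8 mm FWHM smoothing, voxel
#' threshold p = .001, corrected alpha = .05, 1000 Monte Carlo iterations).
#'
#' @return Nested list of settings.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    phantom = list(shape = c(32L, 32L, 8L), voxel_mm = 3, snr = 100,
                   jitter_sd = 0),
    cohort = list(n_subjects = 20L, effect_mean = 0.5, effect_sd = 0.2,
                  fatigue_r2 = 0.24, effect_roi = "insula_left"),
    fit = list(t1_mode = "eigen_corrected", t1b = 1.0, t2b = 12e-6,
               lineshape = "super_lorentzian"),
    inference = list(fwhm_mm = 8, p_voxel = 0.001, alpha = 0.05,
                     n_iter = 1000L, connectivity = 26L,
                     p_mask = 0.005, grand_mean_target = 50)
  )
}

#' Read a run configuration file
#'
#' YAML (or JSON) configuration merged over [default_run_config()];
#' unknown top-level blocks are rejected.
#'
#' @param path YAML/JSON file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  for (blk in names(user)) {
    if (is.list(cfg[[blk]])) {
      bad <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
      if (length(bad) > 0)
        stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
      cfg[[blk]][names(user[[blk]])] <- user[[blk]]
    } else {
      cfg[[blk]] <- user[[blk]]
    }
  }
  cfg
}

log_msg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), ...)
}
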