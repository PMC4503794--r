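#' Simulate a cohort dataset to disk
#'
#' @param config configuration list (see [read_run_config()]).
#' @param out output directory.
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config = default_run_config(), out) {
  ph_spec <- phantom_spec(shape = config$phantom$shape,
                          voxel_mm = config$phantom$voxel_mm,
                          snr = config$phantom$snr,
                          jitter_sd = config$phantom$jitter_sd)
  co <- cohort_spec(n_subjects = config$cohort$n_subjects,
                    effect_mean = config$cohort$effect_mean,
                    effect_sd = config$cohort$effect_sd,
                    fatigue_r2 = config$cohort$fatigue_r2,
                    effect_roi = config$cohort$effect_roi,
                    seed = config$seed)
  log_msg("simulating cohort: n=", co$n_subjects, ", seed=", co$seed)
  ds <- simulate_cohort(ph_spec, co)
  write_cohort(ds, out)
  log_msg("cohort written to ", out)
  invisible(out)
}

session_dirs <- function(data_dir) {
  subs <- list.dirs(data_dir, recursive = FALSE)
  subs <- subs[grepl("sub-[0-9]+$", subs)]
  out <- list()
  for (sd in subs) for (ses in c("placebo", "vaccine")) {
    d <- file.path(sd, paste0("ses-", ses))
    if (dir.exists(d))
      out[[length(out) + 1]] <- list(subject = basename(sd), session = ses,
                                     dir = d)
  }
  out
}

#' Fit T1 maps for every session of a dataset directory
#'
#' @param data_dir a [write_cohort()] layout.
#' @param config configuration list.
#' @return Invisibly, the list of written T1 map paths.
#' @export
run_fit_t1 <- function(data_dir, config = default_run_config()) {
  protocol <- read_protocol(file.path(data_dir, "protocol.tsv"))
  mask <- read_volume(file.path(data_dir, "masks", "brain_mask.nii.gz"))
  sp <- protocol[protocol$kind == "spgr", ]
  if (nrow(sp) < 2) stop("protocol has no SPGR series to fit T1 from")
  written <- character(0)
  for (s in session_dirs(data_dir)) {
    raw_path <- file.path(s$dir, paste0(s$subject, "_ses-", s$session,
                                        "_qmt.nii.gz"))
    raw <- read_volume(raw_path)
    vfa <- raw$data[, , , sp$volume_index, drop = FALSE]
    t1m <- fit_vfa_t1_map(vfa, mask$data > 0, sp$flip_deg, sp$tr_ms[1])
    out <- file.path(s$dir, paste0(s$subject, "_ses-", s$session,
                                   "_t1.nii.gz"))
    write_volume(t1m$t1, out, mask$voxel_mm)
    write_json_atomic(list(flips_deg = sp$flip_deg, tr_ms = sp$tr_ms[1],
                           n_valid = sum(t1m$valid)),
                      sub("\\.nii\\.gz$", ".json", out))
    written <- c(written, out)
    log_msg("T1 map: ", out)
  }
  invisible(written)
}

#' Fit qMT parameter maps for every session of a dataset directory
#'
#' Requires [run_fit_t1()] outputs to be present.
#'
#' @param data_dir a [write_cohort()] layout.
#' @param config configuration list.
#' @return Invisibly, the list of session directories processed.
#' @export
run_fit_qmt <- function(data_dir, config = default_run_config()) {
  protocol <- read_protocol(file.path(data_dir, "protocol.tsv"))
  mask <- read_volume(file.path(data_dir, "masks", "brain_mask.nii.gz"))
  bs <- protocol[protocol$kind == "bssfp", ]
  opts <- qmt_fit_options(t1_mode = config$fit$t1_mode, t1b = config$fit$t1b,
                          t2b = config$fit$t2b,
                          lineshape = config$fit$lineshape)
  done <- character(0)
  for (s in session_dirs(data_dir)) {
    base <- file.path(s$dir, paste0(s$subject, "_ses-", s$session))
    raw <- read_volume(paste0(base, "_qmt.nii.gz"))
    t1 <- read_volume(paste0(base, "_t1.nii.gz"))
    maps <- fit_qmt_volume(raw$data[, , , bs$volume_index, drop = FALSE],
                           mask$data > 0, t1$data, bs, opts)
    for (par in c("f", "kf", "t2f", "m0", "residual_norm"))
      write_volume(maps[[par]], paste0(base, "_", gsub("_", "-", par),
                                       ".nii.gz"), mask$voxel_mm)
    write_volume(maps$converged + 0, paste0(base, "_converged.nii.gz"),
                 mask$voxel_mm)
    write_json_atomic(list(convergence_fraction = maps$convergence_fraction,
                           t1_mode = opts$t1_mode,
                           deterministic = "fit has no random component"),
                      paste0(base, "_qmtfit.json"))
    done <- c(done, s$dir)
    log_msg("qMT maps: ", base, " (", round(100 * maps$convergence_fraction),
            "% converged)")
  }
  invisible(done)
}

#' Group-level inference over a fitted dataset directory
#'
#' Smooths the per-session exchange-rate maps, computes the paired
#' vaccine-vs-placebo t map, calibrates the Monte Carlo cluster extent
#' threshold, tabulates surviving clusters, runs the small-volume sign-flip
#' FWE test in each ROI, and regresses the fatigue change on the mean
#' exchange-rate change of the effect ROI (computed from unsmoothed maps).
#'
#' @param data_dir a dataset directory with fitted maps.
#' @param config configuration list.
#' @param out output directory (default `<data_dir>/group`).
#' @param map which fitted parameter to analyze (default `"kf"`).
#' @return Invisibly, the stats report list (also written as JSON).
#' @export
run_group <- function(data_dir, config = default_run_config(),
                      out = file.path(data_dir, "group"), map = "kf") {
  inf <- config$inference
  mask_v <- read_volume(file.path(data_dir, "masks", "brain_mask.nii.gz"))
  mask <- mask_v$data > 0
  vox <- mask_v$voxel_mm
  rois <- list()
  for (p in list.files(file.path(data_dir, "masks"), "^roi-.*\\.nii\\.gz$",
                       full.names = TRUE))
    rois[[sub("^roi-(.*)\\.nii\\.gz$", "\\1", basename(p))]] <-
      read_volume(p)$data > 0
  sess <- session_dirs(data_dir)
  subjects <- sort(unique(vapply(sess, `[[`, character(1), "subject")))
  read_map <- function(sub, ses) {
    read_volume(file.path(data_dir, sub, paste0("ses-", ses),
                          paste0(sub, "_ses-", ses, "_", map,
                                 ".nii.gz")))$data
  }
  vac <- lapply(subjects, read_map, ses = "vaccine")
  pla <- lapply(subjects, read_map, ses = "placebo")
  sm <- function(m) smooth_volume(m, inf$fwhm_mm, vox, mask)
  stat <- paired_t_map(lapply(vac, sm), lapply(pla, sm), mask)
  mc <- monte_carlo_cluster_threshold(mask, inf$fwhm_mm, vox,
                                      p_voxel = inf$p_voxel,
                                      n_iter = inf$n_iter, alpha = inf$alpha,
                                      seed = config$seed,
                                      connectivity = inf$connectivity,
                                      df = length(subjects) - 1L)
  clusters <- extract_clusters(stat, inf$p_voxel, inf$connectivity,
                               voxel_mm = vox)
  clusters$significant <- clusters$extent >= mc$k_star

  roi_stats <- lapply(names(rois), function(nm) {
    fwe <- roi_fwe_smallvolume(vac, pla, rois[[nm]], seed = config$seed)
    list(roi = nm, peak_t = fwe$peak_t, p_fwe = fwe$p_fwe,
         n_perm = fwe$n_perm_used)
  })
  names(roi_stats) <- names(rois)

  report <- list(map = map, n_subjects = length(subjects),
                 k_star = mc$k_star, p_voxel = inf$p_voxel,
                 alpha = inf$alpha, fwhm_mm = inf$fwhm_mm,
                 n_clusters = nrow(clusters),
                 n_significant = sum(clusters$significant),
                 roi_fwe = roi_stats, seed = config$seed)

  beh_path <- file.path(data_dir, "participants.tsv")
  if (file.exists(beh_path) && config$cohort$effect_roi %in% names(rois)) {
    beh <- utils::read.delim(beh_path, stringsAsFactors = FALSE)
    diff_maps <- Map(function(a, b) a - b, vac, pla)
    droi <- roi_mean_change(diff_maps, rois[[config$cohort$effect_roi]])
    dfat <- vapply(seq_along(subjects), function(s) {
      v <- beh[beh$subject == s & beh$condition == "vaccine", ]
      v$fatigue[v$timepoint == "4h"] - v$fatigue[v$timepoint == "baseline"]
    }, numeric(1))
    report$fatigue_regression <- regress_change_on_covariate(droi, dfat)
    report$roi_mean_delta_kf <- mean(droi)
  }

  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_volume(stat$t, file.path(out, paste0("tmap_", map, ".nii.gz")), vox)
  write_tsv_atomic(clusters, file.path(out, "clusters.tsv"))
  write_json_atomic(report, file.path(out, "group_stats.json"))
  log_msg("group inference: ", sum(clusters$significant),
          " significant cluster(s), k* = ", mc$k_star)
  invisible(report)
}

#' Behavioral statistics of a dataset directory
#'
#' Repeated-measures 2x2 interaction and paired t tests for fatigue and
#' IL-6.
#'
#' @param data_dir dataset directory containing `participants.tsv`.
#' @param out output JSON path (default inside `data_dir`).
#' @return Invisibly, the report list.
#' @export
run_behave <- function(data_dir,
                       out = file.path(data_dir, "behavioral_stats.json")) {
  beh <- utils::read.delim(file.path(data_dir, "participants.tsv"),
                           stringsAsFactors = FALSE)
  paired_t <- function(cond, outcome) {
    w <- beh[beh$condition == cond, ]
    w4 <- w[w$timepoint == "4h", ]
    wb <- w[w$timepoint == "baseline", ]
    w4 <- w4[order(w4$subject), ]
    wb <- wb[order(wb$subject), ]
    ht <- stats::t.test(w4[[outcome]], wb[[outcome]], paired = TRUE)
    list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
         mean_baseline = mean(wb[[outcome]]), mean_4h = mean(w4[[outcome]]))
  }
  report <- list()
  for (outc in c("fatigue", "il6")) {
    ia <- repeated_measures_interaction(beh, outc)
    report[[outc]] <- list(
      interaction = list(F = ia$F, df1 = ia$df1, df2 = ia$df2, p = ia$p),
      vaccine = paired_t("vaccine", outc),
      placebo = paired_t("placebo", outc))
  }
  write_json_atomic(report, out)
  invisible(report)
}

#' Merge stage reports into one summary
#'
#' @param data_dir dataset directory.
#' @param out output JSON path.
#' @return Invisibly, the merged report.
#' @export
run_report <- function(data_dir, out = file.path(data_dir, "report.json")) {
  pick <- function(p) if (file.exists(p)) jsonlite::fromJSON(p) else NULL
  report <- list(
    provenance = pick(file.path(data_dir, "provenance.json")),
    group = pick(file.path(data_dir, "group", "group_stats.json")),
    behavioral = pick(file.path(data_dir, "behavioral_stats.json")))
  write_json_atomic(report, out)
  invisible(report)
}

#' Command-line entry point
#'
#' Thin dispatcher over the pipeline stages; used by the packaged
#' `qmtbssfp` Rscript (see `system.file("cli", "qmtbssfp.R", package =
#' "qmtbssfp")`). Subcommands: `simulate`, `fit-t1`, `fit-qmt`, `group`,
#' `behave`, `report`.
#'
#' @param argv character vector of arguments (excluding the program name).
#' @return Exit status, 0 on success (invisibly).
#' @export
qmt_cli <- function(argv) {
  usage <- paste(
    "usage: qmtbssfp <subcommand> [--config FILE] [--seed N]",
    "                [--data DIR] [--out DIR]",
    "subcommands: simulate fit-t1 fit-qmt group behave report", sep = "\n")
  if (length(argv) < 1) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- argv[1]
  args <- argv[-1]
  opt <- list(config = NULL, seed = NULL, data = NULL, out = NULL)
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!args[i] %in% c("--config", "--seed", "--data", "--out") ||
        i == length(args)) {
      message("unknown or incomplete flag: ", args[i], "\n", usage)
      return(invisible(2L))
    }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  status <- tryCatch({
    config <- read_run_config(opt$config)
    if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
    switch(cmd,
      "simulate" = {
        if (is.null(opt$out)) stop("simulate requires --out")
        run_simulate(config, opt$out)
      },
      "fit-t1" = {
        if (is.null(opt$data)) stop("fit-t1 requires --data")
        run_fit_t1(opt$data, config)
      },
      "fit-qmt" = {
        if (is.null(opt$data)) stop("fit-qmt requires --data")
        run_fit_qmt(opt$data, config)
      },
      "group" = {
        if (is.null(opt$data)) stop("group requires --data")
        run_group(opt$data, config)
      },
      "behave" = {
        if (is.null(opt$data)) stop("behave requires --data")
        run_behave(opt$data)
      },
      "report" = {
        if (is.null(opt$data)) stop("report requires --data")
        run_report(opt$data)
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
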