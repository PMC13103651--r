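# End-to-end orchestration of the three analyses: normative targeting,
# individual targeting, and surrogate-stimulation validation. All modes run
# synthetic-first: with no cohort directory they generate cohorts from the
# config's truth parameters, so the full pipeline is exercised with known
# ground truth. Every random draw descends from the config's master seed
# through named substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an analysis configuration
#'
#' Central parameter record for the pipeline. The denoising and targeting
#' defaults are the reference protocol's values: FD threshold 0.5 mm,
#' band-pass 0.01-0.1 Hz, 6 mm smoothing, 6 mm sphere radius, top-30%
#' stimulation mask. Cohort sizes default to the study design (100
#' patients / 100 controls, 35 longitudinal); the normative population
#' size is a desk-scale choice.
#'
#' @param mode `"normative"`, `"individual"` or `"simulate-validate"`.
#' @param seed Master RNG seed.
#' @param n_per_group,n_normative,n_longitudinal Cohort sizes.
#' @param n_frames Frames acquired per run (240).
#' @param tr_seconds Repetition time (2 s).
#' @param drop_frames Initial frames dropped for study runs (10).
#' @param drop_frames_normative Initial frames dropped for normative runs
#'   (4, the normative dataset's own convention).
#' @param fd_threshold_mm Censoring threshold (0.5).
#' @param band_hz Band-pass edges (0.01, 0.1).
#' @param fwhm_mm Smoothing kernel FWHM (6).
#' @param sphere_radius_mm Geodesic sphere radius (6).
#' @param mask_fraction Stimulation-mask fraction (0.30).
#' @param surrogate_sigma_mm Field-surrogate decay scale (20).
#' @param head_radius_mm FD rotation conversion radius (50).
#' @param seed_labels Volume seed labels (231:246).
#' @param recipe Denoising recipe for study runs: `"36p"` (default) or
#'   `"gsr"`.
#' @param normative_recipe Recipe for normative runs (default `"gsr"`,
#'   the normative dataset's own denoising; the mismatch with the study
#'   recipe is deliberate and logged).
#' @param mesh_subdivisions,mesh_radius_mm Synthetic cortex resolution.
#' @param scalp_radius_mm Synthetic scalp radius.
#' @param coupling_r,jitter_sd,delta_coupling_r,contamination Generator
#'   truth parameters (see [cohort_truth()]).
#' @param cohort_dir Optional directory of on-disk subject FC maps (see
#'   [write_cohort_maps()]); when given, generation is skipped.
#' @param out_dir Optional report directory.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("normative", "individual",
                                     "simulate-validate"),
                            seed = 1,
                            n_per_group = 100, n_normative = 100,
                            n_longitudinal = 35,
                            n_frames = 240, tr_seconds = 2,
                            drop_frames = 10, drop_frames_normative = 4,
                            fd_threshold_mm = 0.5,
                            band_hz = c(0.01, 0.1),
                            fwhm_mm = 6, sphere_radius_mm = 6,
                            mask_fraction = 0.30, surrogate_sigma_mm = 20,
                            head_radius_mm = 50,
                            seed_labels = 231:246,
                            recipe = c("36p", "gsr"),
                            normative_recipe = c("gsr", "36p"),
                            mesh_subdivisions = 3, mesh_radius_mm = 80,
                            scalp_radius_mm = 95,
                            coupling_r = -0.3, jitter_sd = 0.18,
                            delta_coupling_r = -0.4, contamination = 0.5,
                            cohort_dir = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  recipe <- match.arg(recipe)
  normative_recipe <- match.arg(normative_recipe)
  for (nm in c("n_per_group", "n_normative", "n_longitudinal", "n_frames",
               "tr_seconds", "fd_threshold_mm", "fwhm_mm",
               "sphere_radius_mm", "mask_fraction", "surrogate_sigma_mm",
               "head_radius_mm", "mesh_radius_mm", "scalp_radius_mm"))
    check_scalar_number(get(nm), nm, positive = TRUE)
  if (length(band_hz) != 2L || band_hz[1] <= 0 || band_hz[2] <= band_hz[1])
    stop_arg("`band_hz` must be increasing positive edges")
  if (mask_fraction > 1) stop_arg("`mask_fraction` must be in (0, 1]")
  # canonical storage types, so a config serialized to JSON and rebuilt
  # hashes identically to the original
  for (nm in c("seed", "n_per_group", "n_normative", "n_longitudinal",
               "n_frames", "drop_frames", "drop_frames_normative",
               "mesh_subdivisions"))
    assign(nm, as.integer(get(nm)))
  for (nm in c("tr_seconds", "fd_threshold_mm", "fwhm_mm",
               "sphere_radius_mm", "mask_fraction", "surrogate_sigma_mm",
               "head_radius_mm", "mesh_radius_mm", "scalp_radius_mm",
               "coupling_r", "jitter_sd", "delta_coupling_r",
               "contamination"))
    assign(nm, as.numeric(get(nm)))
  band_hz <- as.numeric(band_hz)
  seed_labels <- as.integer(seed_labels)
  rm(nm)
  structure(as.list(environment()), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("<analysis_config> mode %s, seed %d\n", x$mode, x$seed))
  cat(sprintf("  denoise: drop %d, FD > %.2g mm censored, %s, band %.3g-%.3g Hz, FWHM %g mm\n",
              x$drop_frames, x$fd_threshold_mm, x$recipe, x$band_hz[1],
              x$band_hz[2], x$fwhm_mm))
  cat(sprintf("  target: sphere %g mm, mask top %.0f%%, surrogate sigma %g mm\n",
              x$sphere_radius_mm, 100 * x$mask_fraction, x$surrogate_sigma_mm))
  invisible(x)
}

config_truth <- function(config) {
  mesh <- make_mesh(config$mesh_subdivisions, config$mesh_radius_mm)
  field <- connectivity_field(mesh)
  cohort_truth(field, coupling_r = config$coupling_r,
               jitter_sd = config$jitter_sd,
               delta_coupling_r = config$delta_coupling_r,
               contamination = config$contamination, seed = config$seed)
}

# "gsr" recipe regressors: global signal, its derivative, their squares.
build_confounds_gsr <- function(tissue) {
  gs <- as.matrix(tissue)[, 1]
  d <- c(0, diff(gs))
  out <- cbind(global_signal = gs, global_signal_derivative1 = d,
               global_signal_power2 = gs^2,
               global_signal_derivative1_power2 = d^2)
  out
}

#' Run the denoising chain on one BOLD run
#'
#' Initial frame dropping, FD censoring, nuisance regression (36P or
#' global-signal recipe), zero-phase band-pass and spatial smoothing, in
#' that order. A `denoise_log` attribute records frames dropped, frames
#' censored and the filter parameters.
#'
#' @param run A `bold_run` carrying motion parameters.
#' @param tissue Frames x 3 tissue-mean matrix (global, WM, CSF) aligned
#'   with the run before dropping.
#' @param config An `analysis_config` supplying the parameters.
#' @param recipe Denoising recipe override.
#' @param drop_frames Frame-drop override.
#' @return The denoised `bold_run`.
#' @export
preprocess_run <- function(run, tissue, config = analysis_config(),
                           recipe = config$recipe,
                           drop_frames = config$drop_frames) {
  if (!inherits(run, "bold_run")) stop_arg("`run` must be a bold_run")
  if (is.null(run$motion)) stop_arg("run must carry motion parameters")
  tissue <- as.matrix(tissue)
  if (nrow(tissue) != nrow(run$data))
    stop_arg("tissue series must match the run's frame count")
  n0 <- nrow(run$data)
  run <- drop_initial_frames(run, drop_frames)
  if (drop_frames > 0) tissue <- tissue[-seq_len(drop_frames), , drop = FALSE]
  fd <- framewise_displacement(run$motion, config$head_radius_mm)
  run <- censor(run, fd, config$fd_threshold_mm)
  conf <- if (recipe == "36p") build_confounds_36p(run$motion, tissue)
          else build_confounds_gsr(tissue)
  run <- regress_out(run, conf)
  run <- bandpass(run, config$band_hz[1], config$band_hz[2])
  run <- smooth_map(run, config$fwhm_mm)
  attr(run, "denoise_log") <- list(frames_in = n0, dropped = drop_frames,
                                   censored = sum(!run$mask),
                                   recipe = recipe,
                                   band_hz = config$band_hz,
                                   fd_threshold_mm = config$fd_threshold_mm,
                                   fwhm_mm = config$fwhm_mm)
  run
}

# Denoise one generated subject and return their Fisher-z seed FC map.
# Subjects without signals (fast-path cohorts) contribute their true
# field's Fisher-z map: the noise-free limit of the measured pipeline.
subject_zmap <- function(subject, config, recipe = config$recipe,
                         drop_frames = config$drop_frames) {
  if (is.null(subject$run))
    return(fc_map(atanh(subject$field$rho), subject$field$space, scale = "z",
                  provenance = subject$subject_id))
  run <- preprocess_run(subject$run, subject$tissue, config,
                        recipe = recipe, drop_frames = drop_frames)
  seed_ts <- run$seed_ts %||% seed_mean_timeseries(run, config$seed_labels)
  fisher_z(correlation_map(run, seed_ts, provenance = subject$subject_id))
}

site_values <- function(map, sites, spheres) {
  c(pos_vertex = map$values[sites$positive$vertex],
    neg_vertex = map$values[sites$negative$vertex],
    pos_sphere = sphere_mean(map, spheres$positive),
    neg_sphere = sphere_mean(map, spheres$negative))
}

# Group-comparison + symptom-correlation battery over the four site/level
# value columns. Returns tidy rows; the number of tests performed is
# reported alongside (no multiplicity correction is applied anywhere).
# Degenerate inputs (e.g. constant FC values) yield NA statistics with an
# explanatory note instead of aborting the whole analysis.
site_statistics <- function(values) {
  pat <- values[values$group == "patient", , drop = FALSE]
  ctl <- values[values$group == "control", , drop = FALSE]
  rows <- list()
  add_row <- function(level, polarity, test, expr) {
    row <- tryCatch(expr, fctarget_data_error = function(e)
      list(estimate = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_),
           n = NA_integer_, note = conditionMessage(e)))
    rows[[length(rows) + 1L]] <<-
      data.frame(level = level, polarity = polarity, test = test,
                 estimate = row$estimate, p = row$p,
                 ci_low = row$ci[1], ci_high = row$ci[2], n = row$n,
                 note = row$note %||% "")
  }
  for (col in c("pos_vertex", "neg_vertex", "pos_sphere", "neg_sphere")) {
    polarity <- if (startsWith(col, "pos")) "positive" else "negative"
    level <- if (endsWith(col, "vertex")) "vertex" else "sphere"
    if (nrow(ctl) >= 2) {
      add_row(level, polarity, "group_t", {
        tt <- two_sample_t(pat[[col]], ctl[[col]])
        list(estimate = tt$t, p = tt$p, ci = c(NA_real_, NA_real_),
             n = sum(tt$n))
      })
    }
    add_row(level, polarity, "fs14_correlation", {
      ct <- pearson_test(pat[[col]], pat$fs14)
      list(estimate = ct$r, p = ct$p, ci = ct$ci, n = ct$n)
    })
  }
  do.call(rbind, rows)
}

new_cohort_result <- function(mode, config, sites, spheres, values, stats,
                              extra = list()) {
  structure(c(list(mode = mode, config = config, sites = sites,
                   spheres = spheres, values = values, stats = stats,
                   n_tests = nrow(stats),
                   input_hash = content_hash(list(config[setdiff(names(config),
                                                                 "out_dir")],
                                                  mode))),
              extra),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> mode %s\n", x$mode))
  if (!is.null(x$sites)) {
    for (p in c("negative", "positive")) {
      s <- x$sites[[p]]
      if (!is.null(s))
        cat(sprintf("  %s site: vertex %d (%.1f, %.1f, %.1f) mm\n", p,
                    s$vertex, s$xyz[1], s$xyz[2], s$xyz[3]))
    }
  }
  if (!is.null(x$overlap)) {
    for (nm in names(x$overlap))
      cat(sprintf("  overlap rate (%s): %.3f\n", nm, x$overlap[[nm]]))
  }
  if (!is.null(x$stats) && nrow(x$stats)) {
    cat(sprintf("  %d statistical tests (no multiplicity correction):\n",
                x$n_tests))
    print(x$stats, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Run the normative targeting analysis
#'
#' Averages the normative population's Fisher-z seed FC maps, identifies
#' the positive and negative surface peaks, grows geodesic sphere ROIs,
#' extracts every study subject's FC at those fixed sites (vertex and
#' sphere level), and computes group comparisons and FS14 correlations.
#'
#' @param config An `analysis_config`.
#' @param cohort Optional pre-built study `synthetic_cohort` (generated
#'   from the config when omitted).
#' @param normative_cohort Optional pre-built normative cohort.
#' @return A `cohort_result` with sites, per-subject values, statistics
#'   and the normative map.
#' @export
run_normative <- function(config = analysis_config("normative"),
                          cohort = NULL, normative_cohort = NULL) {
  if (!is.null(config$cohort_dir)) return(run_from_maps(config))
  truth <- config_truth(config)
  normative_cohort <- normative_cohort %||%
    simulate_cohort(truth, config$n_normative, config$n_frames,
                    config$tr_seconds,
                    seed = substream_seed(config$seed, "normative"),
                    groups = "control")
  cohort <- cohort %||%
    simulate_cohort(truth, config$n_per_group, config$n_frames,
                    config$tr_seconds,
                    seed = substream_seed(config$seed, "study"))
  norm_maps <- lapply(normative_cohort$subjects, subject_zmap, config = config,
                      recipe = config$normative_recipe,
                      drop_frames = config$drop_frames_normative)
  normative_map <- average_maps(norm_maps)
  sites <- find_peaks(normative_map)
  mesh <- normative_map$space
  spheres <- list(positive = geodesic_sphere(mesh, sites$positive,
                                             config$sphere_radius_mm),
                  negative = geodesic_sphere(mesh, sites$negative,
                                             config$sphere_radius_mm))
  maps <- lapply(cohort$subjects, subject_zmap, config = config)
  vals <- as.data.frame(t(vapply(maps, site_values, numeric(4),
                                 sites = sites, spheres = spheres)))
  values <- cbind(cohort$phenotypes, vals)
  stats <- site_statistics(values)
  new_cohort_result("normative", config, sites, spheres, values, stats,
                    extra = list(normative_map = normative_map,
                                 truth = truth,
                                 subject_maps = maps))
}

#' Run the individual targeting analysis
#'
#' Identifies each subject's own FC extrema (whole-mesh argmax/argmin, no
#' restriction), extracts subject-specific vertex and sphere values, and
#' quantifies the cross-subject spatial overlap of the sphere ROIs per
#' group and polarity, alongside the same statistical battery as the
#' normative mode.
#'
#' @param config An `analysis_config`.
#' @param cohort Optional pre-built study cohort.
#' @return A `cohort_result`; its `overlap` element holds the per-group,
#'   per-polarity overlap rates and `peak_vertices` the per-subject peaks.
#' @export
run_individual <- function(config = analysis_config("individual"),
                           cohort = NULL) {
  truth <- config_truth(config)
  cohort <- cohort %||%
    simulate_cohort(truth, config$n_per_group, config$n_frames,
                    config$tr_seconds,
                    seed = substream_seed(config$seed, "study"))
  maps <- lapply(cohort$subjects, subject_zmap, config = config)
  mesh <- maps[[1]]$space
  per <- lapply(maps, function(m) {
    sites <- find_peaks(m)
    spheres <- list(positive = geodesic_sphere(mesh, sites$positive,
                                               config$sphere_radius_mm),
                    negative = geodesic_sphere(mesh, sites$negative,
                                               config$sphere_radius_mm))
    list(sites = sites, spheres = spheres,
         values = site_values(m, sites, spheres))
  })
  vals <- as.data.frame(t(vapply(per, `[[`, numeric(4), "values")))
  values <- cbind(cohort$phenotypes, vals)
  stats <- site_statistics(values)
  overlap <- list()
  for (grp in unique(values$group)) {
    idx <- which(values$group == grp)
    if (length(idx) < 2) next
    for (pol in c("positive", "negative")) {
      rois <- lapply(per[idx], function(s) s$spheres[[pol]])
      overlap[[paste(grp, pol, sep = "_")]] <- overlap_rate(rois, mesh)
    }
  }
  peaks <- data.frame(subject_id = values$subject_id,
                      positive = vapply(per, function(s) s$sites$positive$vertex,
                                        integer(1)),
                      negative = vapply(per, function(s) s$sites$negative$vertex,
                                        integer(1)))
  new_cohort_result("individual", config, sites = NULL, spheres = NULL,
                    values = values, stats = stats,
                    extra = list(overlap = overlap, peak_vertices = peaks,
                                 truth = truth))
}

#' Run the surrogate-stimulation validation analysis
#'
#' For each target site: project it to the scalp (nearest neighbour),
#' compute the surrogate field over the cortex from that coil position,
#' mask the top fraction of vertices, extract each longitudinal subject's
#' masked mean FC before and after treatment, and correlate the FC change
#' with the FS14 change.
#'
#' @param config An `analysis_config`.
#' @param sites Optional list with `positive` / `negative` `target_site`
#'   objects (computed by a normative run on the same config when
#'   omitted).
#' @param cohort Optional pre-built `longitudinal_cohort`.
#' @return A `cohort_result`; `delta` holds per-site
#'   `correlation_result`s and per-subject pre/post masked means.
#' @export
run_simulation_validation <- function(config = analysis_config("simulate-validate"),
                                      sites = NULL, cohort = NULL) {
  truth <- config_truth(config)
  if (is.null(sites)) {
    norm <- run_normative(config)
    sites <- norm$sites
  }
  cohort <- cohort %||%
    simulate_longitudinal(truth, config$n_longitudinal, config$n_frames,
                          config$tr_seconds,
                          seed = substream_seed(config$seed, "longitudinal"))
  for (s in cohort$subjects) {
    if (!is.null(s$pre$run) && is.null(s$post$run))
      stop_data("subject %s lacks a post-treatment run", s$pre$subject_id)
  }
  mesh <- truth$field$space
  scalp <- make_mesh(2, config$scalp_radius_mm)
  signals <- !is.null(cohort$subjects[[1]]$pre$run)
  pre_maps <- post_maps <- NULL
  if (signals) {
    pre_maps <- lapply(cohort$subjects, function(s)
      subject_zmap(s$pre, config))
    post_maps <- lapply(cohort$subjects, function(s)
      subject_zmap(s$post, config))
  } else {
    pre_maps <- lapply(cohort$subjects, function(s)
      fc_map(atanh(s$pre$field$rho), mesh, scale = "z",
             provenance = s$pre$subject_id))
    post_maps <- lapply(cohort$subjects, function(s)
      fc_map(atanh(s$post$field$rho), mesh, scale = "z",
             provenance = s$pre$subject_id))
  }
  delta <- list()
  rows <- list()
  per_subject <- list()
  for (pol in c("negative", "positive")) {
    site <- sites[[pol]]
    if (is.null(site)) next
    proj <- project_to_scalp(site, scalp)
    fld <- surrogate_field(mesh, proj$xyz, config$surrogate_sigma_mm)
    mask <- top_fraction_mask(fld, config$mask_fraction)
    pre_fc <- vapply(pre_maps, masked_mean_fc, numeric(1), mask = mask)
    post_fc <- vapply(post_maps, masked_mean_fc, numeric(1), mask = mask)
    res <- delta_correlation(pre_fc, post_fc, cohort$phenotypes$fs14,
                             cohort$phenotypes$fs14_post)
    delta[[pol]] <- res
    per_subject[[pol]] <- data.frame(
      subject_id = cohort$phenotypes$subject_id, polarity = pol,
      pre_fc = pre_fc, post_fc = post_fc, delta_fc = post_fc - pre_fc,
      delta_fs14 = cohort$phenotypes$fs14_post - cohort$phenotypes$fs14)
    rows[[pol]] <- data.frame(level = "mask", polarity = pol,
                              test = "delta_correlation", estimate = res$r,
                              p = res$p, ci_low = res$ci[1],
                              ci_high = res$ci[2], n = res$n)
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  new_cohort_result("simulate-validate", config, sites,
                    spheres = NULL, values = do.call(rbind, per_subject),
                    stats = stats,
                    extra = list(delta = delta, truth = truth,
                                 scalp_sites = lapply(sites, function(s)
                                   project_to_scalp(s, scalp))))
}
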