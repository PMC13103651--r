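# Result serialization: a human-readable report, tidy TSV tables and a
# JSON config/provenance sidecar. Reports carry no timestamps, so a rerun
# with the same config and seed is byte-identical.

#' Write a cohort result to a report directory
#'
#' Produces `report.txt` (human-readable summary), `results.tsv` (one row
#' per statistical test), `sites.tsv` (target sites, when present),
#' `values.tsv` (per-subject extracted values) and `config.json`
#' (parameters plus input hash). Output is deterministic: rerunning the
#' same config and seed reproduces the files byte for byte.
#'
#' @param result A `cohort_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  if (!inherits(result, "cohort_result"))
    stop_arg("`result` must be a cohort_result")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_io("cannot create report directory %s", dir)
  write_tsv(result$stats, file.path(dir, "results.tsv"))
  if (!is.null(result$values))
    write_tsv(result$values, file.path(dir, "values.tsv"))
  if (!is.null(result$sites)) {
    rows <- lapply(names(result$sites), function(p) {
      s <- result$sites[[p]]
      data.frame(polarity = p, vertex = s$vertex,
                 x = s$xyz[1], y = s$xyz[2], z = s$xyz[3],
                 sphere_size = if (!is.null(result$spheres))
                   length(result$spheres[[p]]$members) else NA_integer_)
    })
    write_tsv(do.call(rbind, rows), file.path(dir, "sites.tsv"))
  }
  cfg <- result$config
  cfg_json <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(c(cfg_json, list(input_hash = result$input_hash,
                                        n_tests = result$n_tests)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(dir, "report.txt"), "w")
  on.exit(close(con))
  out <- utils::capture.output(print(result))
  writeLines(c(sprintf("fctarget %s analysis (master seed %d)",
                       result$mode, cfg$seed),
               sprintf("input hash: %s", result$input_hash), "", out), con)
  invisible(dir)
}

#' Write a cohort of subject FC maps to a directory
#'
#' On-disk exchange format for the map-level pipeline: the mesh
#' (TSV pair), `phenotypes.tsv`, and one `<subject_id>_zmap.tsv` per
#' subject.
#'
#' @param maps List of per-subject Fisher-z `fc_map`s (surface space).
#' @param phenotypes Matching phenotype data frame.
#' @param dir Output directory.
#' @return `dir` invisibly.
#' @export
write_cohort_maps <- function(maps, phenotypes, dir) {
  if (length(maps) != nrow(phenotypes))
    stop_arg("one map per phenotype row required")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_io("cannot create cohort directory %s", dir)
  write_mesh_tsv(maps[[1]]$space, file.path(dir, "mesh"))
  write_phenotypes_tsv(phenotypes, file.path(dir, "phenotypes.tsv"))
  for (i in seq_along(maps))
    write_fc_map_tsv(maps[[i]],
                     file.path(dir, paste0(phenotypes$subject_id[i],
                                           "_zmap.tsv")))
  invisible(dir)
}

#' @rdname write_cohort_maps
#' @export
read_cohort_maps <- function(dir) {
  if (!dir.exists(dir)) stop_io("cohort directory not found: %s", dir)
  mesh <- read_mesh_tsv(file.path(dir, "mesh"))
  phen <- read_phenotypes_tsv(file.path(dir, "phenotypes.tsv"))
  maps <- lapply(phen$subject_id, function(id) {
    p <- file.path(dir, paste0(id, "_zmap.tsv"))
    if (!file.exists(p)) stop_io("missing FC map for subject %s: %s", id, p)
    read_fc_map_tsv(p, mesh)
  })
  list(maps = maps, phenotypes = phen, mesh = mesh)
}

# Map-level analysis over an on-disk cohort: the normative map is the
# average over control subjects' maps, targeting and statistics as in the
# generated-cohort path.
run_from_maps <- function(config) {
  ch <- read_cohort_maps(config$cohort_dir)
  ctl <- which(ch$phenotypes$group == "control")
  if (length(ctl) == 0L)
    stop_data("cohort directory has no control subjects for a normative map")
  normative_map <- average_maps(ch$maps[ctl])
  sites <- find_peaks(normative_map)
  spheres <- list(positive = geodesic_sphere(ch$mesh, sites$positive,
                                             config$sphere_radius_mm),
                  negative = geodesic_sphere(ch$mesh, sites$negative,
                                             config$sphere_radius_mm))
  vals <- as.data.frame(t(vapply(ch$maps, site_values, numeric(4),
                                 sites = sites, spheres = spheres)))
  values <- cbind(ch$phenotypes, vals)
  stats <- site_statistics(values)
  new_cohort_result("normative", config, sites, spheres, values, stats,
                    extra = list(normative_map = normative_map))
}
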