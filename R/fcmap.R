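# Seed-based functional connectivity maps. An fc_map holds one value per
# location of its space (surface vertices or volume voxels), flagged as raw
# Pearson r or Fisher z. Fisher z is the scale on which maps are averaged
# and statistics computed.

#' Construct an FC map
#'
#' @param values Numeric vector, one value per location of `space`.
#' @param space A `surface_mesh` or `volume_grid`.
#' @param scale `"r"` (raw Pearson correlations) or `"z"` (Fisher z).
#' @param provenance Free-text origin tag (subject id or `"normative"`).
#' @return An object of class `fc_map`.
#' @export
fc_map <- function(values, space, scale = c("r", "z"), provenance = "unknown") {
  scale <- match.arg(scale)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop_data("FC map values must be finite")
  n <- space_size(space)
  if (length(values) != n)
    stop_arg("map has %d values but its space has %d locations", length(values), n)
  structure(list(values = values, space = space, scale = scale,
                 provenance = provenance),
            class = "fc_map")
}

space_size <- function(space) {
  if (inherits(space, "surface_mesh")) return(n_vertices(space))
  if (inherits(space, "volume_grid")) return(n_voxels(space))
  stop_arg("space must be a surface_mesh or volume_grid")
}

same_space <- function(a, b) {
  identical(class(a), class(b)) && space_size(a) == space_size(b) &&
    (if (inherits(a, "surface_mesh")) isTRUE(all.equal(a$vertices, b$vertices))
     else isTRUE(all.equal(a$affine, b$affine)) && all(a$shape == b$shape))
}

#' @export
print.fc_map <- function(x, ...) {
  cat(sprintf("<fc_map> %d locations (%s space), scale %s, provenance %s\n",
              length(x$values),
              if (inherits(x$space, "surface_mesh")) "surface" else "volume",
              x$scale, x$provenance))
  cat(sprintf("  range [%.4f, %.4f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Mean time series over a labelled seed region
#'
#' Unweighted average of the run's signal over all locations whose label is
#' in `seed_labels`, restricted to retained frames. The default label set is
#' the bilateral thalamus of the Brainnetome atlas (231-246).
#'
#' @param run A `bold_run` in volume space (its grid supplies the labels).
#' @param seed_labels Integer label set defining the seed.
#' @return Numeric vector, one value per retained frame.
#' @export
seed_mean_timeseries <- function(run, seed_labels = 231:246) {
  if (!inherits(run, "bold_run")) stop_arg("`run` must be a bold_run")
  if (!inherits(run$space, "volume_grid"))
    stop_arg("seed extraction by label requires a volume-space run")
  sel <- as.vector(run$space$labels) %in% seed_labels
  if (!any(sel)) stop_arg("no location carries a seed label")
  sub <- run$data[run$mask, sel, drop = FALSE]
  rowMeans(sub)
}

#' Seed correlation map
#'
#' Pearson correlation between every location's time series and the seed
#' series, over retained frames only. Locations with constant signal get
#' r = 0 with a warning.
#'
#' @param run A `bold_run`.
#' @param seed_ts Seed time series: either over all frames (length = frame
#'   count; it is masked alongside the data) or already restricted to
#'   retained frames.
#' @param provenance Provenance tag for the resulting map.
#' @return An `fc_map` on the raw `"r"` scale.
#' @export
correlation_map <- function(run, seed_ts, provenance = "unknown") {
  if (!inherits(run, "bold_run")) stop_arg("`run` must be a bold_run")
  n_frames <- nrow(run$data)
  n_kept <- sum(run$mask)
  seed_ts <- as.numeric(seed_ts)
  if (length(seed_ts) == n_frames) seed_ts <- seed_ts[run$mask]
  if (length(seed_ts) != n_kept)
    stop_arg("seed series length matches neither the frame count nor the retained count")
  if (n_kept < 3L) stop_data("fewer than 3 retained frames")
  if (stats::sd(seed_ts) == 0) stop_data("seed time series is constant")
  y <- run$data[run$mask, , drop = FALSE]
  s0 <- seed_ts - mean(seed_ts)
  yc <- sweep(y, 2, colMeans(y))
  ynorm <- sqrt(colSums(yc^2))
  const <- ynorm == 0
  r <- numeric(ncol(y))
  r[!const] <- as.vector(crossprod(yc[, !const, drop = FALSE], s0)) /
    (ynorm[!const] * sqrt(sum(s0^2)))
  if (any(const))
    warning(sprintf("%d constant location(s); their r set to 0", sum(const)))
  fc_map(r, space = run$space, scale = "r", provenance = provenance)
}

#' Fisher r-to-z transform of an FC map
#'
#' `z = atanh(r)`, with r clipped to +/- (1 - 1e-7) first so that perfectly
#' correlated locations map to a large finite value rather than infinity.
#'
#' @param map An `fc_map` on the `"r"` scale.
#' @return The map on the `"z"` scale.
#' @export
fisher_z <- function(map) {
  if (!inherits(map, "fc_map")) stop_arg("`map` must be an fc_map")
  if (map$scale != "r") stop_arg("map is already Fisher-z transformed")
  r <- pmin(pmax(map$values, -(1 - 1e-7)), 1 - 1e-7)
  fc_map(atanh(r), space = map$space, scale = "z", provenance = map$provenance)
}

#' Combine multiple runs of one subject
#'
#' Subjects with several runs can be combined either by averaging their
#' per-run Fisher-z maps (`combine_run_maps`, the default convention) or
#' by concatenating the retained frames of the runs before computing one
#' FC map (`concatenate_runs`). Both conventions are exposed because
#' normative datasets differ in which they use.
#'
#' @param maps List of Fisher-z `fc_map`s from one subject's runs.
#' @param provenance Provenance tag of the combined result.
#' @return `combine_run_maps`: one `fc_map`; `concatenate_runs`: one
#'   `bold_run` whose frames are the runs' frames stacked in order.
#' @export
combine_run_maps <- function(maps, provenance = "combined") {
  average_maps(maps, provenance = provenance)
}

#' @rdname combine_run_maps
#' @param runs List of `bold_run`s sharing one space and TR.
#' @export
concatenate_runs <- function(runs) {
  if (!is.list(runs) || length(runs) == 0L ||
      !all(vapply(runs, inherits, logical(1), "bold_run")))
    stop_arg("`runs` must be a non-empty list of bold_run objects")
  ref <- runs[[1]]
  for (r in runs[-1]) {
    if (!same_space(ref$space, r$space)) stop_arg("runs live in different spaces")
    if (r$tr_seconds != ref$tr_seconds) stop_arg("runs have different TRs")
  }
  has_seed <- !vapply(runs, function(r) is.null(r$seed_ts), logical(1))
  bold_run(do.call(rbind, lapply(runs, `[[`, "data")),
           ref$tr_seconds, ref$space,
           mask = unlist(lapply(runs, `[[`, "mask")),
           seed_ts = if (all(has_seed))
             unlist(lapply(runs, `[[`, "seed_ts")) else NULL)
}

#' Average FC maps element-wise
#'
#' The normative-map operation: the arithmetic mean of Fisher-z maps
#' sharing one space.
#'
#' @param maps List of `fc_map` objects, all surface or all volume on the
#'   same space, all on the `"z"` scale.
#' @param provenance Provenance of the result (default `"normative"`).
#' @return An `fc_map`.
#' @export
average_maps <- function(maps, provenance = "normative") {
  if (!is.list(maps) || length(maps) == 0L)
    stop_arg("`maps` must be a non-empty list of fc_map objects")
  if (!all(vapply(maps, inherits, logical(1), "fc_map")))
    stop_arg("`maps` must contain only fc_map objects")
  if (any(vapply(maps, function(m) m$scale, character(1)) != "z"))
    stop_arg("all maps must be Fisher-z before averaging")
  ref <- maps[[1]]$space
  for (m in maps[-1]) if (!same_space(ref, m$space))
    stop_arg("maps live in different spaces")
  vals <- vapply(maps, function(m) m$values, numeric(length(maps[[1]]$values)))
  vals <- if (is.matrix(vals)) rowMeans(vals) else mean(vals)
  fc_map(vals, space = ref, scale = "z", provenance = provenance)
}
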