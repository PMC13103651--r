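# Stimulation-field surrogate. The finite-element E-field solver of a real
# TMS simulation (tissue conductivities, coil windings) is deliberately not
# reimplemented: the package substitutes an isotropic Gaussian distance
# decay from the coil position, which preserves the downstream pipeline
# logic -- scalp projection of the cortical target, a per-vertex field
# magnitude map, the top-30% cortical mask, and the masked mean FC
# comparison. The surrogate is clearly labelled as such in all outputs.

#' Project a cortical point to the scalp
#'
#' Nearest-neighbour resampling of a target coordinate onto a scalp mesh:
#' the stimulation-coil position for that target. Ties go to the lowest
#' vertex index.
#'
#' @param point xyz mm coordinate (e.g. a `target_site`'s `xyz`).
#' @param scalp A `surface_mesh` of the scalp.
#' @return A list with `vertex` (scalp vertex index) and `xyz` (its mm
#'   coordinate).
#' @export
project_to_scalp <- function(point, scalp) {
  if (inherits(point, "target_site")) point <- point$xyz
  point <- as.numeric(point)
  if (length(point) != 3L || !all(is.finite(point)))
    stop_arg("`point` must be a finite xyz coordinate")
  if (!inherits(scalp, "surface_mesh") || n_vertices(scalp) == 0L)
    stop_arg("`scalp` must be a non-empty surface_mesh")
  v <- nearest_vertex(scalp, point)
  list(vertex = v, xyz = as.numeric(scalp$vertices[v, ]))
}

#' Surrogate stimulation-field magnitude map
#'
#' Field magnitude at cortical vertex v is `exp(-d_v^2 / (2 sigma^2))`
#' with `d_v` the Euclidean distance from v to the coil position:
#' maximal at the vertex nearest the coil and strictly decreasing with
#' distance. Units are arbitrary (the mask construction only uses ranks).
#'
#' @param cortex Cortical `surface_mesh`.
#' @param coil_position xyz mm coordinate of the coil (typically a scalp
#'   projection from [project_to_scalp()]).
#' @param sigma_mm Decay scale in mm (default 20, chosen so the top-30%
#'   mask on a brain-scale mesh is one contiguous patch).
#' @return An object of class `field_map` with per-vertex `values`.
#' @export
surrogate_field <- function(cortex, coil_position, sigma_mm = 20) {
  if (!inherits(cortex, "surface_mesh")) stop_arg("`cortex` must be a surface_mesh")
  if (is.list(coil_position) && !is.null(coil_position$xyz))
    coil_position <- coil_position$xyz
  coil_position <- as.numeric(coil_position)
  if (length(coil_position) != 3L || !all(is.finite(coil_position)))
    stop_arg("`coil_position` must be a finite xyz coordinate")
  check_scalar_number(sigma_mm, "sigma_mm", positive = TRUE)
  d2 <- rowSums(sweep(cortex$vertices, 2, coil_position)^2)
  structure(list(values = exp(-d2 / (2 * sigma_mm^2)), space = cortex,
                 coil_position = coil_position, sigma_mm = sigma_mm),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> surrogate, %d vertices, coil at (%.1f, %.1f, %.1f), sigma %.0f mm\n",
              length(x$values), x$coil_position[1], x$coil_position[2],
              x$coil_position[3], x$sigma_mm))
  invisible(x)
}

#' Mask of the vertices receiving the top fraction of the field
#'
#' The stimulation mask: the `ceiling(fraction * N)` vertices with the
#' highest field magnitude. Ties at the cut are admitted in order of
#' lowest vertex index until the cardinality is met.
#'
#' @param field A `field_map` (or plain numeric vector of magnitudes).
#' @param fraction Fraction of vertices to keep, in (0, 1\] (default 0.30).
#' @return A logical vertex mask with exactly `ceiling(fraction * N)`
#'   `TRUE` entries.
#' @export
top_fraction_mask <- function(field, fraction = 0.30) {
  vals <- if (inherits(field, "field_map")) field$values else as.numeric(field)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop_arg("`fraction` must lie in (0, 1]")
  n <- length(vals)
  k <- ceiling(fraction * n)
  ord <- order(vals, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
  mask <- logical(n)
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Mean FC within a stimulation mask
#'
#' @param map An `fc_map` in surface space.
#' @param mask Logical vertex mask (e.g. from [top_fraction_mask()]).
#' @return The unweighted mean of the map over masked vertices.
#' @export
masked_mean_fc <- function(map, mask) {
  if (!inherits(map, "fc_map")) stop_arg("`map` must be an fc_map")
  mask <- as.logical(mask)
  if (length(mask) != length(map$values))
    stop_arg("mask length must equal the map's location count")
  if (!any(mask)) stop_arg("mask is empty")
  mean(map$values[mask])
}
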