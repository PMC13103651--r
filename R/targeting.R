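# Surface targeting: find the positive and negative extrema of a surface
# FC map, expand each peak to a geodesic sphere ROI, extract vertex- and
# sphere-level values, and quantify cross-subject spatial overlap.

#' Construct a target site
#'
#' @param vertex 1-based vertex index of the peak.
#' @param polarity `"positive"` or `"negative"`.
#' @param mesh The `surface_mesh` the vertex lives on.
#' @param scalp_xyz Optional mm coordinate of the site's scalp projection.
#' @return An object of class `target_site` with the cortical mm
#'   coordinate filled in from the mesh.
#' @export
target_site <- function(vertex, polarity = c("positive", "negative"), mesh,
                        scalp_xyz = NULL) {
  polarity <- match.arg(polarity)
  vertex <- as.integer(vertex)
  if (vertex < 1L || vertex > n_vertices(mesh))
    stop_arg("vertex index out of range")
  structure(list(vertex = vertex, polarity = polarity,
                 xyz = as.numeric(mesh$vertices[vertex, ]),
                 scalp_xyz = scalp_xyz),
            class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("<target_site> %s peak at vertex %d (%.1f, %.1f, %.1f) mm\n",
              x$polarity, x$vertex, x$xyz[1], x$xyz[2], x$xyz[3]))
  invisible(x)
}

#' Find the positive and negative peaks of a surface FC map
#'
#' The positive peak is the argmax and the negative peak the argmin over
#' non-excluded vertices; ties are broken by the lowest vertex index. No
#' other restriction is applied (whole-mesh search).
#'
#' @param map An `fc_map` in surface space.
#' @param exclude Optional logical vertex flags to skip (defaults to the
#'   mesh's own exclusion flags, e.g. a medial wall).
#' @return A list with elements `positive` and `negative`, both
#'   `target_site` objects.
#' @export
find_peaks <- function(map, exclude = NULL) {
  if (!inherits(map, "fc_map")) stop_arg("`map` must be an fc_map")
  if (!inherits(map$space, "surface_mesh"))
    stop_arg("peak finding operates on surface maps")
  mesh <- map$space
  if (is.null(exclude)) exclude <- mesh$exclude
  if (length(exclude) != n_vertices(mesh))
    stop_arg("`exclude` must have one flag per vertex")
  ok <- which(!exclude)
  if (length(ok) == 0L) stop_arg("all vertices are excluded")
  vals <- map$values[ok]
  if (max(vals) == min(vals)) stop_data("map is constant: no peaks")
  pos <- ok[which.max(vals)]   # which.max returns the first (lowest) index
  neg <- ok[which.min(vals)]
  list(positive = target_site(pos, "positive", mesh),
       negative = target_site(neg, "negative", mesh))
}

#' Grow a geodesic sphere ROI around a vertex
#'
#' The "surface-based sphere": all vertices whose shortest-path distance
#' along mesh edges (Euclidean edge lengths) from the centre is at most
#' `radius_mm`. The centre is always a member (distance 0).
#'
#' @param mesh A `surface_mesh`.
#' @param center Centre vertex index, or a `target_site`.
#' @param radius_mm Geodesic radius in mm (default 6).
#' @return An object of class `sphere_roi` with `members` (vertex indices)
#'   and `distances` (their geodesic distances from the centre).
#' @export
geodesic_sphere <- function(mesh, center, radius_mm = 6) {
  if (inherits(center, "target_site")) center <- center$vertex
  center <- as.integer(center)
  if (center < 1L || center > n_vertices(mesh))
    stop_arg("`center` must be a valid vertex index")
  if (!is.numeric(radius_mm) || radius_mm < 0)
    stop_arg("`radius_mm` must be >= 0")
  d <- geodesic_distances(mesh, center)
  members <- which(d <= radius_mm)
  structure(list(center = center, radius_mm = radius_mm,
                 members = members, distances = d[members]),
            class = "sphere_roi")
}

#' @export
print.sphere_roi <- function(x, ...) {
  cat(sprintf("<sphere_roi> centre vertex %d, radius %.1f mm, %d member(s)\n",
              x$center, x$radius_mm, length(x$members)))
  invisible(x)
}

#' Mean FC over a sphere ROI
#'
#' The sphere-level value: the unweighted mean of the map over the ROI's
#' member vertices.
#'
#' @param map An `fc_map` in surface space.
#' @param roi A `sphere_roi` (or any list with a `members` vector).
#' @return A scalar.
#' @export
sphere_mean <- function(map, roi) {
  if (!inherits(map, "fc_map")) stop_arg("`map` must be an fc_map")
  members <- if (is.list(roi)) roi$members else as.integer(roi)
  if (length(members) == 0L) stop_arg("ROI has no members")
  if (any(members < 1L | members > length(map$values)))
    stop_arg("ROI members outside the map's space")
  mean(map$values[members])
}

#' Cross-subject overlap rate of sphere ROIs
#'
#' The maximum, over vertices, of the fraction of subjects whose ROI
#' contains that vertex ("max-coverage" reading). With `statistic =
#' "mean_pairwise"` the mean Jaccard index over subject pairs is returned
#' instead; the quantity is not standardized in the field, so the choice
#' is explicit and logged with results.
#'
#' @param rois List of per-subject `sphere_roi` objects (>= 2).
#' @param mesh The common `surface_mesh`.
#' @param statistic `"max_coverage"` (default) or `"mean_pairwise"`.
#' @return A fraction in \[0, 1\].
#' @export
overlap_rate <- function(rois, mesh, statistic = c("max_coverage",
                                                   "mean_pairwise")) {
  statistic <- match.arg(statistic)
  if (!is.list(rois) || length(rois) < 2L)
    stop_arg("`rois` must list at least 2 subjects")
  n <- length(rois)
  if (statistic == "max_coverage") {
    counts <- integer(n_vertices(mesh))
    for (r in rois) counts[r$members] <- counts[r$members] + 1L
    return(max(counts) / n)
  }
  jac <- numeric(0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- rois[[i]]$members; b <- rois[[j]]$members
    jac <- c(jac, length(intersect(a, b)) / length(union(a, b)))
  }
  mean(jac)
}
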