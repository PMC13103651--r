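# Volume grids: a voxel lattice with an affine into mm space (RAS+) and an
# integer seed-label image. Synthetic grids stand in for the standard
# 2 mm template space; the default seed labels mirror the bilateral
# thalamic labels 231-246 of the Brainnetome atlas.

#' Construct a volume grid
#'
#' @param shape Integer vector of length 3 (voxels per axis).
#' @param affine 4 x 4 matrix mapping homogeneous 0-based voxel indices to
#'   mm coordinates; must be invertible.
#' @param labels Optional integer array of `shape` with per-voxel region
#'   labels (0 = background). Seed regions are sets of labels.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, affine, labels = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_arg("`shape` must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop_arg("`affine` must be a finite 4 x 4 matrix")
  if (abs(det(affine)) < 1e-12) stop_arg("`affine` must be invertible")
  if (is.null(labels)) labels <- array(0L, dim = shape)
  labels <- array(as.integer(labels), dim = shape)
  if (any(labels < 0L)) stop_arg("voxel labels must be >= 0")
  structure(list(shape = shape, affine = affine, labels = labels),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, %d labelled\n",
              paste(x$shape, collapse = " x "), sum(x$labels > 0)))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

# 0-based voxel index matrix (n x 3) -> mm coordinates (n x 3).
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  xyz <- cbind(ijk, 1) %*% t(grid$affine)
  xyz[, 1:3, drop = FALSE]
}

# mm coordinates (n x 3) -> continuous 0-based voxel coordinates (n x 3).
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  ijk <- cbind(xyz, 1) %*% t(solve(grid$affine))
  ijk[, 1:3, drop = FALSE]
}

# All voxel indices in array (column-major) order, 0-based, as n x 3.
grid_index_table <- function(grid) {
  s <- grid$shape
  cbind(rep.int(seq_len(s[1]) - 1L, s[2] * s[3]),
        rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3]),
        rep(seq_len(s[3]) - 1L, each = s[1] * s[2]))
}

#' Build a small synthetic standard-space grid with a central seed region
#'
#' Convenience constructor for desk-scale volume work: an isotropic grid
#' centred on the origin with a block of central voxels carrying the
#' thalamic seed labels 231-246.
#'
#' @param shape Voxels per axis (default `c(16, 16, 16)`).
#' @param voxel_mm Isotropic voxel size in mm (default 8; keeps the grid
#'   brain-sized at low resolution).
#' @return A `volume_grid`.
#' @export
make_grid <- function(shape = c(16, 16, 16), voxel_mm = 8) {
  shape <- as.integer(shape)
  check_scalar_number(voxel_mm, "voxel_mm", positive = TRUE)
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- -(shape - 1) / 2 * voxel_mm
  labels <- array(0L, dim = shape)
  centre <- round(shape / 2)
  seed_labels <- 231:246
  # a 4 x 2 x 2 block of central voxels, one label each
  offs <- as.matrix(expand.grid(0:3, 0:1, 0:1))
  for (k in seq_len(nrow(offs))) {
    idx <- centre + offs[k, ] - c(2, 1, 1)
    labels[idx[1], idx[2], idx[3]] <- seed_labels[k]
  }
  volume_grid(shape, affine, labels)
}

#' Sample a volume FC map onto a surface mesh
#'
#' Trilinear interpolation of the volume at each vertex coordinate, the
#' standard volume-to-surface projection. Vertices falling outside the
#' voxel lattice receive the value of the nearest in-grid voxel and are
#' flagged in the result's `clamped` attribute.
#'
#' @param map An `fc_map` in volume space.
#' @param mesh Target `surface_mesh`.
#' @param grid The map's `volume_grid` (defaults to the map's own space).
#' @return An `fc_map` in surface space; attribute `clamped` flags
#'   vertices that fell outside the grid.
#' @export
volume_to_surface <- function(map, mesh, grid = map$space) {
  if (!inherits(map, "fc_map")) stop_arg("`map` must be an fc_map")
  if (!inherits(grid, "volume_grid")) stop_arg("`grid` must be a volume_grid")
  if (!inherits(mesh, "surface_mesh")) stop_arg("`mesh` must be a surface_mesh")
  vol <- array(map$values, dim = grid$shape)
  ijk <- world_to_voxel(grid, mesh$vertices)
  s <- grid$shape
  clamped <- ijk[, 1] < 0 | ijk[, 1] > s[1] - 1 |
             ijk[, 2] < 0 | ijk[, 2] > s[2] - 1 |
             ijk[, 3] < 0 | ijk[, 3] > s[3] - 1
  # clamp to the lattice, then interpolate
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 0), s[a] - 1)
  lo <- floor(ijk)
  frac <- ijk - lo
  lo1 <- lo + 1  # 1-based corner
  hi1 <- pmin(lo1 + 1, matrix(s, nrow(lo1), 3, byrow = TRUE))
  val <- numeric(nrow(ijk))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ci <- if (dx == 0) lo1[, 1] else hi1[, 1]
    cj <- if (dy == 0) lo1[, 2] else hi1[, 2]
    ck <- if (dz == 0) lo1[, 3] else hi1[, 3]
    w <- (if (dx == 0) 1 - frac[, 1] else frac[, 1]) *
         (if (dy == 0) 1 - frac[, 2] else frac[, 2]) *
         (if (dz == 0) 1 - frac[, 3] else frac[, 3])
    val <- val + w * vol[cbind(ci, cj, ck)]
  }
  out <- fc_map(val, space = mesh, scale = map$scale, provenance = map$provenance)
  attr(out, "clamped") <- clamped
  out
}
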