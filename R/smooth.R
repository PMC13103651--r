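# Spatial smoothing with a Gaussian kernel of given FWHM
# (sigma = FWHM / (2 sqrt(2 ln 2))). Volume data are smoothed with a
# separable discrete Gaussian; surface data with a sparse distance-weighted
# kernel over the local vertex neighbourhood (the surface extension of the
# volume-only smoothing in the original denoising chain). Both operators
# are row-normalized, so constant input is returned unchanged.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.3548

# Banded 1-D convolution matrix with a truncated discrete Gaussian,
# renormalized per row (reflecting nothing: weights that fall off the
# lattice are redistributed, which keeps constants exact at the edges and
# conserves mass for interior impulses).
gaussian_band_matrix <- function(n, sigma) {
  if (sigma <= 0) return(Matrix::Diagonal(n))
  radius <- max(1L, ceiling(4 * sigma))
  offsets <- -radius:radius
  w <- exp(-offsets^2 / (2 * sigma^2))
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (k in seq_along(offsets)) {
    i <- seq_len(n)
    j <- i + offsets[k]
    ok <- j >= 1L & j <= n
    rows <- c(rows, i[ok]); cols <- c(cols, j[ok])
    vals <- c(vals, rep(w[k], sum(ok)))
  }
  m <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  rs <- Matrix::rowSums(m)
  Matrix::Diagonal(x = 1 / rs) %*% m
}

# Smooth a 3-D array with voxel sizes `vox` (mm per axis).
smooth_volume_array <- function(arr, fwhm_mm, vox) {
  s <- dim(arr)
  sig <- (fwhm_mm * FWHM_TO_SIGMA) / vox
  for (axis in 1:3) {
    b <- gaussian_band_matrix(s[axis], sig[axis])
    perm <- c(axis, setdiff(1:3, axis))
    x <- aperm(arr, perm)
    x <- as.matrix(b %*% matrix(x, nrow = s[axis]))
    arr <- aperm(array(x, dim = s[perm]), order(perm))
  }
  arr
}

# Sparse surface smoothing operator: Gaussian weights over each vertex's
# one- and two-ring neighbourhood by Euclidean distance (a good local
# approximation to the geodesic at sub-edge-length sigma), row-normalized.
# Cached per mesh and FWHM.
surface_smoother <- function(mesh, fwhm_mm) {
  key <- sprintf("smoother_%.6g", fwhm_mm)
  if (!is.null(mesh$cache) && !is.null(mesh$cache[[key]]))
    return(mesh$cache[[key]])
  sigma <- fwhm_mm * FWHM_TO_SIGMA
  n <- n_vertices(mesh)
  edges <- mesh_edges(mesh)
  a <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(n, n))
  nb2 <- a %*% a + a + Matrix::Diagonal(n)  # two-ring pattern
  idx <- Matrix::which(nb2 != 0, arr.ind = TRUE)
  d <- sqrt(rowSums((mesh$vertices[idx[, 1], , drop = FALSE] -
                     mesh$vertices[idx[, 2], , drop = FALSE])^2))
  w <- exp(-d^2 / (2 * sigma^2))
  m <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = w, dims = c(n, n))
  m <- Matrix::Diagonal(x = 1 / Matrix::rowSums(m)) %*% m
  if (!is.null(mesh$cache)) mesh$cache[[key]] <- m
  m
}

#' Smooth an FC map or BOLD run spatially
#'
#' Gaussian smoothing at the given FWHM. For volume objects this is a
#' separable discrete Gaussian over the voxel lattice; for surface objects
#' a distance-weighted kernel over the local vertex neighbourhood.
#' Constant input is returned unchanged.
#'
#' @param x An `fc_map` or `bold_run`.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm
#'   (default 6).
#' @return An object of the same class as `x`.
#' @export
smooth_map <- function(x, fwhm_mm = 6) {
  check_scalar_number(fwhm_mm, "fwhm_mm", positive = TRUE)
  UseMethod("smooth_map")
}

#' @export
smooth_map.fc_map <- function(x, fwhm_mm = 6) {
  if (inherits(x$space, "volume_grid")) {
    vox <- sqrt(colSums(x$space$affine[1:3, 1:3]^2))
    arr <- array(x$values, dim = x$space$shape)
    x$values <- as.vector(smooth_volume_array(arr, fwhm_mm, vox))
  } else {
    w <- surface_smoother(x$space, fwhm_mm)
    x$values <- as.vector(w %*% x$values)
  }
  x
}

#' @export
smooth_map.bold_run <- function(x, fwhm_mm = 6) {
  if (inherits(x$space, "volume_grid")) {
    vox <- sqrt(colSums(x$space$affine[1:3, 1:3]^2))
    for (t in seq_len(nrow(x$data))) {
      arr <- array(x$data[t, ], dim = x$space$shape)
      x$data[t, ] <- as.vector(smooth_volume_array(arr, fwhm_mm, vox))
    }
  } else {
    w <- surface_smoother(x$space, fwhm_mm)
    x$data <- as.matrix(Matrix::tcrossprod(x$data, w))
  }
  x
}
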