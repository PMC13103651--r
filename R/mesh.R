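# Triangulated surface meshes: the carrier for surface FC maps, geodesic
# sphere ROIs and field maps. Synthetic cortices are icospheres; real meshes
# can be supplied as vertex/triangle tables.

#' Construct a surface mesh
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates in mm (RAS+).
#' @param triangles Integer m x 3 matrix of 1-based vertex indices.
#' @param exclude Optional logical vector flagging non-cortical vertices
#'   (e.g. a medial wall) that peak search must skip.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, exclude = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3L) stop_arg("`vertices` must be an n x 3 matrix")
  if (!all(is.finite(vertices))) stop_data("mesh vertices must be finite")
  n <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > n))
    stop_arg("triangle indices must reference valid vertices (1..%d)", n)
  if (is.null(exclude)) exclude <- rep(FALSE, n)
  if (length(exclude) != n) stop_arg("`exclude` must have one flag per vertex")
  for (k in 1:3) {
    a <- triangles[, k]; b <- triangles[, k %% 3 + 1]
    if (any(rowSums((vertices[a, , drop = FALSE] -
                     vertices[b, , drop = FALSE])^2) == 0))
      stop_data("mesh contains a zero-length edge")
  }
  structure(list(vertices = vertices, triangles = triangles,
                 exclude = as.logical(exclude),
                 cache = new.env(parent = emptyenv())),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, %d excluded\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$exclude)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

# Unique undirected edges of the triangulation, as a 2-column index matrix.
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

mesh_edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  d <- mesh$vertices[edges[, 1], , drop = FALSE] -
       mesh$vertices[edges[, 2], , drop = FALSE]
  sqrt(rowSums(d * d))
}

# igraph view of the edge graph, with Euclidean edge lengths as weights.
# Cached in the mesh's environment: meshes are immutable after construction.
mesh_graph <- function(mesh) {
  if (!is.null(mesh$cache) && !is.null(mesh$cache$graph)) return(mesh$cache$graph)
  edges <- mesh_edges(mesh)
  w <- mesh_edge_lengths(mesh, edges)
  if (any(w <= 0)) stop_data("mesh contains a zero-length edge")
  g <- igraph::make_graph(t(edges), n = n_vertices(mesh), directed = FALSE)
  igraph::E(g)$weight <- w
  if (!is.null(mesh$cache)) mesh$cache$graph <- g
  g
}

#' Geodesic (edge-graph) distances from one vertex to all vertices
#'
#' Shortest-path distance along mesh edges with Euclidean edge lengths --
#' the metric used for geodesic sphere ROIs and peak-distance checks.
#'
#' @param mesh A `surface_mesh`.
#' @param from 1-based vertex index.
#' @return Numeric vector of distances in mm (Inf for unreachable vertices).
#' @export
geodesic_distances <- function(mesh, from) {
  from <- as.integer(from)
  if (is.na(from) || from < 1L || from > n_vertices(mesh))
    stop_arg("`from` must be a valid vertex index")
  g <- mesh_graph(mesh)
  as.vector(igraph::distances(g, v = from, weights = igraph::E(g)$weight))
}

#' Build an icosphere mesh
#'
#' Recursively subdivided icosahedron projected onto a sphere -- the
#' package's synthetic stand-in for a template cortical surface. Each
#' subdivision splits every triangle in four (V' = V + E, F' = 4F).
#'
#' @param subdivisions Non-negative integer (0 = icosahedron); at most 6.
#' @param radius_mm Sphere radius in mm.
#' @return A `surface_mesh` with all vertices at `radius_mm` from the origin.
#' @export
#' @examples
#' m <- make_mesh(1, 80)           # 42 vertices, 80 triangles
#' range(sqrt(rowSums(m$vertices^2)))
make_mesh <- function(subdivisions = 3, radius_mm = 80) {
  if (!is.numeric(subdivisions) || length(subdivisions) != 1L ||
      subdivisions < 0 || subdivisions != round(subdivisions))
    stop_arg("`subdivisions` must be a non-negative integer")
  if (subdivisions > 6) stop_arg("`subdivisions` must be <= 6")
  check_scalar_number(radius_mm, "radius_mm", positive = TRUE)

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  tri <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))

  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- midpoint_cache[[key]]
      if (is.null(idx)) {
        verts <<- rbind(verts, (verts[i, ] + verts[j, ]) / 2)
        idx <- nrow(verts)
        midpoint_cache[[key]] <- idx
      }
      idx
    }
    new_tri <- matrix(0L, nrow = 4 * nrow(tri), ncol = 3)
    for (t in seq_len(nrow(tri))) {
      a <- tri[t, 1]; b <- tri[t, 2]; c <- tri[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      new_tri[4 * t - 3, ] <- c(a, ab, ca)
      new_tri[4 * t - 2, ] <- c(b, bc, ab)
      new_tri[4 * t - 1, ] <- c(c, ca, bc)
      new_tri[4 * t, ]     <- c(ab, bc, ca)
    }
    v <- verts
    tri <- new_tri
  }

  v <- v / sqrt(rowSums(v * v)) * radius_mm
  surface_mesh(v, tri)
}

# Vertex nearest a given mm coordinate (used to anchor planted peaks).
nearest_vertex <- function(mesh, point) {
  point <- as.numeric(point)
  if (length(point) != 3L || !all(is.finite(point)))
    stop_arg("`point` must be a finite xyz coordinate")
  d2 <- rowSums(sweep(mesh$vertices, 2, point)^2)
  which.min(d2)  # which.min takes the lowest index on ties
}
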