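# Plain-text and NIfTI I/O. Volume data travel as NIfTI (RNifti); surface
# meshes, surface maps, ROIs, sites and tabular data as TSV with documented
# columns; run-level provenance as JSON sidecars. (The environment has no
# GIFTI reader, so surface objects use TSV rather than GIFTI containers.)

write_tsv <- function(df, path) {
  ok <- try(utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stop_io("cannot write %s", path)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a surface mesh as TSV
#'
#' Two files are produced from `prefix`: `<prefix>_vertices.tsv`
#' (columns x, y, z, exclude) and `<prefix>_triangles.tsv` (v1, v2, v3,
#' 1-based).
#'
#' @param mesh A `surface_mesh`.
#' @param prefix Path prefix for the two files.
#' @return `prefix`, invisibly; `read_mesh_tsv` returns the mesh.
#' @export
write_mesh_tsv <- function(mesh, prefix) {
  v <- as.data.frame(mesh$vertices)
  names(v) <- c("x", "y", "z")
  v$exclude <- as.integer(mesh$exclude)
  write_tsv(v, paste0(prefix, "_vertices.tsv"))
  tr <- as.data.frame(mesh$triangles)
  names(tr) <- c("v1", "v2", "v3")
  write_tsv(tr, paste0(prefix, "_triangles.tsv"))
  invisible(prefix)
}

#' @rdname write_mesh_tsv
#' @export
read_mesh_tsv <- function(prefix) {
  v <- read_tsv(paste0(prefix, "_vertices.tsv"))
  tr <- read_tsv(paste0(prefix, "_triangles.tsv"))
  surface_mesh(as.matrix(v[, c("x", "y", "z")]),
               as.matrix(tr[, c("v1", "v2", "v3")]),
               exclude = as.logical(v$exclude))
}

#' Write / read a surface FC map as TSV
#'
#' One row per vertex (columns vertex, value); scale and provenance go to
#' a JSON sidecar `<path>.json`.
#'
#' @param map An `fc_map` in surface space.
#' @param path Output TSV path.
#' @param mesh Mesh to attach on reading.
#' @return `path` invisibly; `read_fc_map_tsv` returns the map.
#' @export
write_fc_map_tsv <- function(map, path) {
  if (!inherits(map$space, "surface_mesh"))
    stop_arg("use write_fc_map_nifti for volume maps")
  write_tsv(data.frame(vertex = seq_along(map$values), value = map$values),
            path)
  jsonlite::write_json(list(scale = map$scale, provenance = map$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fc_map_tsv
#' @export
read_fc_map_tsv <- function(path, mesh) {
  df <- read_tsv(path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  fc_map(df$value[order(df$vertex)], space = mesh, scale = side$scale,
         provenance = side$provenance)
}

#' Write / read a volume FC map as NIfTI
#'
#' @param map An `fc_map` in volume space.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param grid The `volume_grid` to attach on reading.
#' @return `path` invisibly; the reader returns the map.
#' @export
write_fc_map_nifti <- function(map, path) {
  if (!inherits(map$space, "volume_grid"))
    stop_arg("use write_fc_map_tsv for surface maps")
  img <- RNifti::asNifti(array(map$values, dim = map$space$shape))
  RNifti::qform(img) <- structure(map$space$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_fc_map_nifti
#' @export
read_fc_map_nifti <- function(path, grid, scale = "z",
                              provenance = "unknown") {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  img <- RNifti::readNifti(path)
  fc_map(as.vector(img), space = grid, scale = scale, provenance = provenance)
}

#' Write / read a volume BOLD run as 4D NIfTI
#'
#' Frames become the 4th dimension; the retained-frame mask and TR go to a
#' JSON sidecar.
#'
#' @param run A `bold_run` in volume space.
#' @param path Output path.
#' @param grid The `volume_grid` to attach on reading.
#' @return `path` invisibly; the reader returns the run.
#' @export
write_bold_nifti <- function(run, path) {
  if (!inherits(run$space, "volume_grid"))
    stop_arg("NIfTI export requires a volume-space run")
  arr <- array(t(run$data), dim = c(run$space$shape, nrow(run$data)))
  img <- RNifti::asNifti(arr)
  RNifti::qform(img) <- structure(run$space$affine, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(tr_seconds = run$tr_seconds,
                            retained = as.integer(run$mask)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path, grid) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop_data("expected a 4D NIfTI, got %dD", length(d))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- t(matrix(img, nrow = prod(d[1:3]), ncol = d[4]))
  bold_run(data, tr_seconds = side$tr_seconds, space = grid,
           mask = as.logical(side$retained))
}

#' Write / read BIDS-style confounds TSV
#'
#' Named columns `trans_x..rot_z`, `global_signal`, `white_matter`, `csf`
#' (motion and tissue inputs of the 36P expansion).
#'
#' @param motion Frames x 6 motion matrix.
#' @param tissue Frames x 3 tissue-mean matrix.
#' @param path Output path.
#' @return `path` invisibly; the reader returns
#'   `list(motion=, tissue=)`.
#' @export
write_confounds_tsv <- function(motion, tissue, path) {
  m <- as.matrix(motion); ti <- as.matrix(tissue)
  df <- data.frame(m, ti)
  names(df) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
                 "global_signal", "white_matter", "csf")
  write_tsv(df, path)
}

#' @rdname write_confounds_tsv
#' @export
read_confounds_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
            "global_signal", "white_matter", "csf")
  if (!all(need %in% names(df)))
    stop_data("confound TSV %s lacks required columns", path)
  list(motion = as.matrix(df[, need[1:6]]),
       tissue = as.matrix(df[, need[7:9]]))
}

#' Write / read a phenotype table as TSV
#'
#' Columns subject_id, group, fs14, and optionally hamd / fs14_post.
#'
#' @param phenotypes Data frame.
#' @param path Output path.
#' @return `path` invisibly; the reader returns the data frame.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  if (!all(c("subject_id", "group", "fs14") %in% names(phenotypes)))
    stop_arg("phenotypes need subject_id, group, fs14 columns")
  write_tsv(phenotypes, path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  df <- read_tsv(path)
  if (!all(c("subject_id", "group", "fs14") %in% names(df)))
    stop_data("phenotype TSV %s lacks required columns", path)
  df
}
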