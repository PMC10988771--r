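#' Surface meshes and parcellation labels
#'
#' Meshes are stored as a vertex matrix (n x 3, unit-sphere or world mm) and
#' a face matrix (m x 3 of 1-based vertex indices). On disk they use the CSV
#' fallback format: a vertex table (`x,y,z`), a face table (`v1,v2,v3`,
#' 0-based on file), and a one-column label table (integer per vertex,
#' 0 = unassigned / medial wall).
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return A `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  if (!all(is.finite(vertices))) abort("vertex coordinates must be finite",
                                       class = "glio_format_error")
  if (any(faces < 1) || any(faces > nrow(vertices)))
    abort("face index out of range", class = "glio_format_error")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read or write a mesh plus per-vertex labels
#'
#' @param mesh_path CSV of vertex coordinates with columns `x,y,z` and a
#'   paired `<stem>_faces.csv` with 0-based columns `v1,v2,v3`.
#' @param labels_path Optional CSV with a `label` column, one integer row per
#'   vertex.
#' @return A list with `mesh` (a [surface_mesh()]) and `labels` (integer
#'   vector, or NULL).
#' @export
read_surface <- function(mesh_path, labels_path = NULL) {
  v <- utils::read.csv(mesh_path)
  f <- utils::read.csv(faces_path_for(mesh_path))
  mesh <- surface_mesh(as.matrix(v[, c("x", "y", "z")]),
                       as.matrix(f[, c("v1", "v2", "v3")]) + 1L)
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- utils::read.csv(labels_path)$label
    if (length(labels) != nrow(mesh$vertices))
      abort(sprintf("labels length %d != vertex count %d",
                    length(labels), nrow(mesh$vertices)),
            class = "glio_length_error")
    labels <- as.integer(labels)
  }
  list(mesh = mesh, labels = labels)
}

#' @rdname read_surface
#' @param mesh A [surface_mesh()].
#' @param labels Optional integer labels, one per vertex.
#' @export
write_surface <- function(mesh, mesh_path, labels = NULL, labels_path = NULL) {
  utils::write.csv(setNames(as.data.frame(mesh$vertices), c("x", "y", "z")),
                   mesh_path, row.names = FALSE)
  utils::write.csv(setNames(as.data.frame(mesh$faces - 1L), c("v1", "v2", "v3")),
                   faces_path_for(mesh_path), row.names = FALSE)
  if (!is.null(labels))
    utils::write.csv(data.frame(label = as.integer(labels)), labels_path,
                     row.names = FALSE)
  invisible(mesh_path)
}

faces_path_for <- function(mesh_path) sub("(\\.csv)?$", "_faces.csv",
                                          mesh_path, perl = TRUE)

#' Per-vertex surface map
#'
#' @param values Numeric vector, one value per mesh vertex.
#' @param valid Logical vector marking vertices with a defined value.
#' @return A `surface_map`.
#' @export
surface_map <- function(values, valid = is.finite(values)) {
  stopifnot(length(values) == length(valid))
  structure(list(values = as.numeric(values), valid = as.logical(valid)),
            class = "surface_map")
}

#' @rdname surface_map
#' @param path CSV with columns `value`, `valid`.
#' @export
read_surface_map <- function(path) {
  d <- utils::read.csv(path)
  surface_map(d$value, as.logical(d$valid))
}

#' @rdname surface_map
#' @param map A `surface_map`.
#' @export
write_surface_map <- function(map, path) {
  utils::write.csv(data.frame(value = map$values, valid = map$valid), path,
                   row.names = FALSE)
  invisible(path)
}
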