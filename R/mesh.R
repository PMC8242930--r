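# Triangle mesh container and validation.
#
# A mesh is a list with a numeric n x 3 `vertices` matrix (meters) and an
# integer m x 3 `faces` matrix of vertex indices, 1-based, counter-clockwise
# when viewed from outside (outward normals). The anatomical frame is
# x craniocaudal, y mediolateral, z vertical.

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in meters.
#' @param faces integer matrix (m x 3) of 1-based vertex indices, ordered
#'   counter-clockwise seen from outside the solid.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns", call. = FALSE)
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns", call. = FALSE)
  if (nrow(faces) == 0L) stop("empty mesh: no faces", call. = FALSE)
  if (any(is.na(vertices))) stop("NA vertex coordinates", call. = FALSE)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, signed volume %.6g m^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

# Signed enclosed volume (divergence theorem over origin tetrahedra).
#' Signed enclosed volume of a triangle mesh
#' @param mesh a `triangle_mesh`.
#' @return signed volume in m^3 (positive for outward-oriented meshes).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  det3 <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
          a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
          a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  sum(det3) / 6
}

# doubled face areas (norm of cross product)
.face_areas2 <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  sqrt(cx^2 + cy^2 + cz^2)
}

.directed_edges <- function(faces) {
  rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
}

#' Validate a triangle mesh
#'
#' Report-only checks of the structural invariants a mesh must satisfy
#' before mass properties can be computed: every edge shared by exactly two
#' faces (watertight), globally consistent orientation (each shared edge
#' traversed in opposite directions by its two faces), positive signed
#' volume, and absence of degenerate (zero-area) faces.
#'
#' @param mesh a `triangle_mesh`.
#' @return a list of class `mesh_validation` with logical flags
#'   `watertight`, `consistently_oriented`, `positive_volume`, an integer
#'   vector `degenerate_faces`, and `ok` (all checks passed).
#' @export
validate_mesh <- function(mesh) {
  de <- .directed_edges(mesh$faces)
  key <- paste(pmin(de[, 1L], de[, 2L]), pmax(de[, 1L], de[, 2L]))
  cnt <- table(key)
  watertight <- all(cnt == 2L)
  # orientation: each undirected edge traversed once per direction
  dkey <- paste(de[, 1L], de[, 2L])
  consistently_oriented <- watertight && !anyDuplicated(dkey)
  vol <- mesh_volume(mesh)
  scale <- max(abs(range(mesh$vertices)), 1e-30)
  degenerate <- which(.face_areas2(mesh) <= 1e-14 * scale^2)
  structure(list(
    watertight = watertight,
    consistently_oriented = consistently_oriented,
    positive_volume = vol > 0,
    degenerate_faces = degenerate,
    signed_volume = vol,
    ok = watertight && consistently_oriented && vol > 0 &&
      length(degenerate) == 0L
  ), class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat(sprintf(
    "mesh validation: watertight=%s oriented=%s positive_volume=%s degenerate=%d [%s]\n",
    x$watertight, x$consistently_oriented, x$positive_volume,
    length(x$degenerate_faces), if (x$ok) "OK" else "FAIL"))
  invisible(x)
}

# Stop unless the mesh is a valid closed, outward-oriented solid.
.require_solid <- function(mesh, what = "mesh") {
  rep_ <- validate_mesh(mesh)
  if (!rep_$watertight)
    stop(what, " is not watertight", call. = FALSE)
  if (!rep_$consistently_oriented)
    stop(what, " has inconsistent face orientation", call. = FALSE)
  if (length(rep_$degenerate_faces))
    stop(what, " has degenerate (zero-area) faces", call. = FALSE)
  if (!rep_$positive_volume)
    stop(what, " has non-positive enclosed volume (inward orientation?)",
         call. = FALSE)
  mesh
}

# Repair applied only at the read boundary: a globally inverted but
# otherwise consistently oriented mesh is flipped; mixed orientation is an
# error, never silently repaired.
.repair_orientation <- function(mesh) {
  rep_ <- validate_mesh(mesh)
  if (rep_$watertight && rep_$consistently_oriented && !rep_$positive_volume) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh
}

#' Translate a mesh
#' @param mesh a `triangle_mesh`.
#' @param offset numeric length-3 translation vector (m).
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2L, as.numeric(offset), "+")
  mesh
}

#' Rotate a mesh about the origin
#' @param mesh a `triangle_mesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @export
rotate_mesh <- function(mesh, rotation) {
  mesh$vertices <- mesh$vertices %*% t(rotation)
  mesh
}
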