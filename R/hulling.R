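# Convex hulls of 3D point sets.
#
# No convex-hull library ships with the target environment, so the hull is
# computed natively with an incremental beneath--beyond algorithm (the
# Quickhull family): starting from an extreme tetrahedron, each remaining
# point outside the current hull deletes its visible faces and is joined to
# the horizon edges. Interior and on-face points (within tolerance) are
# discarded and never affect the result.

#' Convex hull of a 3D point set
#'
#' @param x an n x 3 numeric matrix of points, or a `triangle_mesh` whose
#'   vertices are taken.
#' @return an object of class `hull_result`: a list with `hull` (a
#'   watertight, outward-oriented `triangle_mesh`), `input_vertex_count` and
#'   `hull_vertex_count`. Degenerate input (fewer than 4 points, or all
#'   points coplanar/collinear) raises an error rather than returning a
#'   flat pseudo-hull.
#' @export
convex_hull <- function(x) {
  pts <- if (inherits(x, "triangle_mesh")) x$vertices else as.matrix(x)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("points must have 3 columns", call. = FALSE)
  pts <- pts[!duplicated(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n < 4L) stop("degenerate input: need at least 4 distinct points",
                   call. = FALSE)
  scale <- max(abs(range(pts)), .Machine$double.xmin)
  eps <- 1e-10 * scale

  # --- initial extreme tetrahedron -----------------------------------------
  i1 <- which.min(pts[, 1L] + 1e-9 * (pts[, 2L] + pts[, 3L]))
  d1 <- rowSums(sweep(pts, 2L, pts[i1, ])^2)
  i2 <- which.max(d1)
  e <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2L, pts[i1, ])
  crx <- cbind(rel[, 2L] * e[3L] - rel[, 3L] * e[2L],
               rel[, 3L] * e[1L] - rel[, 1L] * e[3L],
               rel[, 1L] * e[2L] - rel[, 2L] * e[1L])
  a2 <- rowSums(crx^2)
  i3 <- which.max(a2)
  if (sqrt(a2[i3]) <= eps * sqrt(sum(e^2)))
    stop("degenerate input: points are collinear", call. = FALSE)
  nrm <- crx[i3, ] / sqrt(a2[i3])
  h <- abs(rel %*% nrm)
  i4 <- which.max(h)
  if (h[i4] <= eps)
    stop("degenerate input: points are coplanar", call. = FALSE)

  # outward faces for a NEGATIVELY oriented quadruple; flip otherwise
  faces <- rbind(c(i1, i2, i3), c(i1, i3, i4), c(i1, i4, i2), c(i2, i4, i3))
  if (.signed_vol6(pts[i1, ], pts[i2, ], pts[i3, ], pts[i4, ]) > 0)
    faces <- faces[, c(1L, 3L, 2L), drop = FALSE]
  pl <- .hull_planes(pts, faces)

  used <- c(i1, i2, i3, i4)
  for (p in setdiff(seq_len(n), used)) {
    dist <- pl$normals %*% pts[p, ] - pl$offsets
    vis <- which(dist > eps)
    if (length(vis) == 0L) next
    visf <- faces[vis, , drop = FALSE]
    de <- .directed_edges(visf)
    dkey <- paste(de[, 1L], de[, 2L])
    rkey <- paste(de[, 2L], de[, 1L])
    horizon <- de[!(rkey %in% dkey), , drop = FALSE]
    if (nrow(horizon) == 0L) next  # numerically inside-out; skip
    newf <- cbind(horizon, p)
    faces <- rbind(faces[-vis, , drop = FALSE], newf)
    newpl <- .hull_planes(pts, newf)
    pl$normals <- rbind(pl$normals[-vis, , drop = FALSE], newpl$normals)
    pl$offsets <- c(pl$offsets[-vis], newpl$offsets)
  }

  keep <- sort(unique(as.vector(faces)))
  remap <- match(faces, keep)
  hull <- triangle_mesh(pts[keep, , drop = FALSE],
                        matrix(remap, ncol = 3L))
  hull <- .require_solid(hull, "hull")
  structure(list(hull = hull,
                 input_vertex_count = n,
                 hull_vertex_count = length(keep)),
            class = "hull_result")
}

#' @export
print.hull_result <- function(x, ...) {
  cat(sprintf("hull_result: %d -> %d vertices, volume %.6g m^3\n",
              x$input_vertex_count, x$hull_vertex_count,
              mesh_volume(x$hull)))
  invisible(x)
}

.signed_vol6 <- function(a, b, c_, d) {
  u <- b - a; v <- c_ - a; w <- d - a
  u[1] * (v[2] * w[3] - v[3] * w[2]) -
    u[2] * (v[1] * w[3] - v[3] * w[1]) +
    u[3] * (v[1] * w[2] - v[2] * w[1])
}

# unit outward normals and plane offsets for hull faces
.hull_planes <- function(pts, faces) {
  A <- pts[faces[, 1L], , drop = FALSE]
  B <- pts[faces[, 2L], , drop = FALSE]
  C <- pts[faces[, 3L], , drop = FALSE]
  e1 <- B - A; e2 <- C - A
  nx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  ny <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  nz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  len <- pmax(sqrt(nx^2 + ny^2 + nz^2), .Machine$double.xmin)
  normals <- cbind(nx / len, ny / len, nz / len)
  list(normals = normals, offsets = rowSums(normals * A))
}

#' BSP of the convex hull of a skeletal segment
#'
#' The naive hull BSP: mass properties of the convex hull of the skeleton
#' mesh's vertices, the raw quantity the calibration equations convert to a
#' soft-tissue prediction.
#'
#' @param skeleton_mesh a `triangle_mesh` (need not be watertight; only its
#'   vertices are used).
#' @param density density in kg m^-3 (default 1000).
#' @return a `bsp`.
#' @export
hull_bsp <- function(skeleton_mesh, density = 1000) {
  hr <- convex_hull(skeleton_mesh)
  mass_properties(hr$hull, density)
}
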