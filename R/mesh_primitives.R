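# Programmatic mesh fixtures with closed-form mass properties.

#' Axis-aligned box mesh
#'
#' @param extents numeric length-3 `(a, b, c)` edge lengths in meters.
#' @param center numeric length-3 box center (default origin).
#' @return a watertight, outward-oriented `triangle_mesh` with 8 vertices
#'   and 12 faces; enclosed volume is exactly `a * b * c`.
#' @export
make_box <- function(extents, center = c(0, 0, 0)) {
  extents <- as.numeric(extents)
  if (length(extents) != 3L || any(!is.finite(extents)) || any(extents <= 0))
    stop("box extents must be three positive numbers", call. = FALSE)
  h <- extents / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- sweep(as.matrix(s) * rep(h, each = 8L), 2L, as.numeric(center), "+")
  # vertex order: (-,-,-),(+,-,-),(-,+,-),(+,+,-),(-,-,+),(+,-,+),(-,+,+),(+,+,+)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z- (viewed from below: outward -z)
    c(5, 6, 8), c(5, 8, 7),   # z+
    c(1, 2, 6), c(1, 6, 5),   # y-
    c(3, 7, 8), c(3, 8, 4),   # y+
    c(1, 5, 7), c(1, 7, 3),   # x-
    c(2, 4, 8), c(2, 8, 6))   # x+
  triangle_mesh(v, f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere; volume converges to
#' `(4/3) * pi * r^3` as `subdivisions` grows (within 0.3% at 4 levels).
#'
#' @param radius sphere radius in meters.
#' @param subdivisions non-negative integer subdivision level.
#' @param center numeric length-3 center.
#' @return a watertight `triangle_mesh`.
#' @export
make_icosphere <- function(radius, subdivisions = 3L, center = c(0, 0, 0)) {
  if (!is.finite(radius) || radius <= 0)
    stop("radius must be positive", call. = FALSE)
  if (subdivisions < 0) stop("subdivisions must be >= 0", call. = FALSE)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(1 + phi^2)
  for (lvl in seq_len(subdivisions)) {
    midcache <- new.env(parent = emptyenv())
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(midcache[[key]])) return(midcache[[key]])
      m <- (vlist[[i]] + vlist[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1L]] <<- m
      midcache[[key]] <- length(vlist)
      length(vlist)
    }
    nf <- vector("list", nrow(f) * 4L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; c_ <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[[4L * k - 3L]] <- c(a, ab, ca)
      nf[[4L * k - 2L]] <- c(b, bc, ab)
      nf[[4L * k - 1L]] <- c(c_, ca, bc)
      nf[[4L * k]]      <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- do.call(rbind, nf)
  }
  v <- sweep(v * radius, 2L, as.numeric(center), "+")
  triangle_mesh(v, f)
}

#' Prism mesh from a convex cross-section polygon
#'
#' Extrudes a convex planar polygon along a coordinate axis, centered on the
#' origin along that axis. For axis `"x"` the polygon coordinates map to
#' (y, z); for `"y"` to (z, x); for `"z"` to (x, y). The polygon must be in
#' counter-clockwise order as seen from the positive end of the axis.
#'
#' @param length extrusion length in meters.
#' @param polygon k x 2 matrix of convex cross-section vertices (meters),
#'   counter-clockwise.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return a watertight `triangle_mesh` of `4k - 4` faces.
#' @export
make_prism <- function(length, polygon, axis = "x") {
  if (!is.finite(length) || length <= 0)
    stop("prism length must be positive", call. = FALSE)
  polygon <- as.matrix(polygon)
  k <- nrow(polygon)
  if (k < 3L) stop("cross-section needs at least 3 vertices", call. = FALSE)
  # signed polygon area must be positive (ccw)
  j <- c(2:k, 1L)
  area2 <- sum(polygon[, 1L] * polygon[j, 2L] - polygon[j, 1L] * polygon[, 2L])
  if (area2 <= 0) stop("cross-section polygon must be counter-clockwise with positive area",
                       call. = FALSE)
  lo <- -length / 2; hi <- length / 2
  # build in the z-axis frame: polygon is (x, y), caps at z = lo / hi
  vbot <- cbind(polygon, lo)
  vtop <- cbind(polygon, hi)
  v <- rbind(vbot, vtop)
  faces <- list()
  # bottom cap (normal -z): fan, clockwise seen from +z
  for (i in 2:(k - 1L)) faces[[length(faces) + 1L]] <- c(1L, i + 1L, i)
  # top cap (normal +z): ccw
  for (i in 2:(k - 1L)) faces[[length(faces) + 1L]] <- c(k + 1L, k + i, k + i + 1L)
  # sides
  for (i in seq_len(k)) {
    i2 <- if (i == k) 1L else i + 1L
    faces[[length(faces) + 1L]] <- c(i, i2, k + i2)
    faces[[length(faces) + 1L]] <- c(i, k + i2, k + i)
  }
  f <- do.call(rbind, faces)
  # cyclic column permutation puts the extrusion axis where requested while
  # keeping the frame right-handed (orientation preserved)
  perm <- switch(axis,
    z = c(1L, 2L, 3L),   # world (x,y,z) = local (x,y,z)
    x = c(3L, 1L, 2L),   # world x = local z (extrusion), y = local x, z = local y
    y = c(2L, 3L, 1L),   # world y = local z (extrusion), z = local x, x = local y
    stop("axis must be one of 'x', 'y', 'z'", call. = FALSE))
  v <- v[, perm, drop = FALSE]
  triangle_mesh(v, f)
}
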