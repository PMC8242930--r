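# Exact mass properties of watertight triangle meshes.
#
# All ten volume integrals (volume, first, second and mixed moments) are
# evaluated exactly by signed-tetrahedron decomposition: each surface
# triangle (A, B, C) forms a tetrahedron with the origin, over which
# monomial integrals have closed forms; signed contributions sum to the
# integral over the enclosed solid (divergence theorem). Accumulation uses
# R's sum(), which accumulates in extended precision where available.

#' Exact polyhedral volume integrals
#'
#' Computes the ten volume integrals over the solid enclosed by a
#' watertight, outward-oriented mesh: `V = int dV`, first moments
#' `int x, int y, int z`, second moments `int x^2, int y^2, int z^2` and
#' mixed moments `int xy, int yz, int zx`. Exact up to floating point for
#' polyhedral input.
#'
#' @param mesh a watertight, outward-oriented `triangle_mesh` with positive
#'   enclosed volume.
#' @return named numeric vector with elements `volume`, `x`, `y`, `z`,
#'   `xx`, `yy`, `zz`, `xy`, `yz`, `zx`.
#' @export
polyhedron_integrals <- function(mesh) {
  mesh <- .require_solid(mesh)
  v <- mesh$vertices; f <- mesh$faces
  A <- v[f[, 1L], , drop = FALSE]
  B <- v[f[, 2L], , drop = FALSE]
  C <- v[f[, 3L], , drop = FALSE]
  # 6 * signed volume of tetra (0, A, B, C)
  d6 <- A[, 1L] * (B[, 2L] * C[, 3L] - B[, 3L] * C[, 2L]) -
        A[, 2L] * (B[, 1L] * C[, 3L] - B[, 3L] * C[, 1L]) +
        A[, 3L] * (B[, 1L] * C[, 2L] - B[, 2L] * C[, 1L])
  vol <- sum(d6) / 6
  # over a tetra with vertices {0, A, B, C} and signed volume V = d6/6:
  #   int x_i dV       = V/4 * (A_i + B_i + C_i)
  #   int x_i x_j dV   = V/20 * (A_iA_j + B_iB_j + C_iC_j + S_i S_j),
  #                      S_i = A_i + B_i + C_i (4th vertex at origin)
  first <- vapply(1:3, function(i)
    sum(d6 * (A[, i] + B[, i] + C[, i])) / 24, 0)
  second_ <- function(i, j) {
    Si <- A[, i] + B[, i] + C[, i]
    Sj <- A[, j] + B[, j] + C[, j]
    sum(d6 * (A[, i] * A[, j] + B[, i] * B[, j] + C[, i] * C[, j] + Si * Sj)) / 120
  }
  c(volume = vol,
    x = first[1], y = first[2], z = first[3],
    xx = second_(1, 1), yy = second_(2, 2), zz = second_(3, 3),
    xy = second_(1, 2), yz = second_(2, 3), zx = second_(3, 1))
}

#' Construct a body segment parameter vector
#'
#' The ten BSPs of a rigid segment plus the density used: mass (kg), centre
#' of mass (m, in the mesh frame), moments of inertia Ixx/Iyy/Izz and
#' products of inertia Ixy/Ixz/Iyz (kg m^2), all about axes through the
#' centre of mass parallel to the frame axes. Products are stored with the
#' positive-integral convention `Ixy = rho * int xy dV`; the assembled
#' inertia tensor negates them off-diagonal.
#'
#' @param mass segment mass in kg.
#' @param com numeric length-3 centre of mass (m).
#' @param moments numeric length-3 `(Ixx, Iyy, Izz)` in kg m^2.
#' @param products numeric length-3 `(Ixy, Ixz, Iyz)` in kg m^2,
#'   positive-integral convention.
#' @param density density used, kg m^-3.
#' @return an object of class `bsp`.
#' @export
bsp <- function(mass, com, moments, products, density = 1000) {
  structure(list(mass = as.numeric(mass),
                 com = setNames(as.numeric(com), c("x", "y", "z")),
                 moments = setNames(as.numeric(moments), c("ixx", "iyy", "izz")),
                 products = setNames(as.numeric(products), c("ixy", "ixz", "iyz")),
                 density = as.numeric(density)),
            class = "bsp")
}

#' @export
print.bsp <- function(x, ...) {
  cat(sprintf("bsp: mass %.6g kg at density %g kg/m^3\n", x$mass, x$density))
  cat(sprintf("  com      (%.6g, %.6g, %.6g) m\n", x$com[1], x$com[2], x$com[3]))
  cat(sprintf("  moments  Ixx %.6g  Iyy %.6g  Izz %.6g kg m^2\n",
              x$moments[1], x$moments[2], x$moments[3]))
  cat(sprintf("  products Ixy %.6g  Ixz %.6g  Iyz %.6g kg m^2\n",
              x$products[1], x$products[2], x$products[3]))
  invisible(x)
}

#' Inertia tensor of a BSP
#'
#' Assembles the 3x3 inertia tensor about the centre of mass. Off-diagonal
#' entries are the negated stored products (positive-integral convention).
#'
#' @param x a `bsp`.
#' @return 3x3 symmetric matrix (kg m^2).
#' @export
inertia_tensor <- function(x) {
  with(x, matrix(c(moments[1], -products[1], -products[2],
                   -products[1], moments[2], -products[3],
                   -products[2], -products[3], moments[3]), 3, 3))
}

#' Mass properties of a watertight mesh
#'
#' Computes the full BSP vector of a uniform-density solid: mass, centre of
#' mass, and the six inertial components about axes through the centre of
#' mass (parallel-axis-corrected from the origin-frame integrals).
#'
#' @param mesh a watertight, outward-oriented `triangle_mesh`.
#' @param density uniform density in kg m^-3 (default 1000, the nominal
#'   density of water used throughout the calibration).
#' @return a `bsp`.
#' @export
mass_properties <- function(mesh, density = 1000) {
  if (!is.finite(density) || density <= 0)
    stop("density must be positive", call. = FALSE)
  I <- polyhedron_integrals(mesh)
  V <- I[["volume"]]
  if (V <= 0) stop("mesh encloses non-positive volume", call. = FALSE)
  m <- density * V
  com <- c(I[["x"]], I[["y"]], I[["z"]]) / V
  # origin-frame second moments -> CoM frame (parallel axis)
  ixx <- density * (I[["yy"]] + I[["zz"]]) - m * (com[2]^2 + com[3]^2)
  iyy <- density * (I[["xx"]] + I[["zz"]]) - m * (com[1]^2 + com[3]^2)
  izz <- density * (I[["xx"]] + I[["yy"]]) - m * (com[1]^2 + com[2]^2)
  ixy <- density * I[["xy"]] - m * com[1] * com[2]
  ixz <- density * I[["zx"]] - m * com[1] * com[3]
  iyz <- density * I[["yz"]] - m * com[2] * com[3]
  bsp(m, com, c(ixx, iyy, izz), c(ixy, ixz, iyz), density)
}

#' Rescale a BSP to a new density
#'
#' Mass and all six inertial components scale linearly with density; the
#' centre of mass is unchanged (uniform density within the segment).
#'
#' @param x a `bsp`.
#' @param new_density target density in kg m^-3.
#' @return the rescaled `bsp` with its `density` field updated.
#' @export
rescale_density <- function(x, new_density) {
  if (!is.finite(new_density) || new_density <= 0)
    stop("density must be positive", call. = FALSE)
  if (!is.finite(x$density) || x$density <= 0)
    stop("input bsp has non-positive density", call. = FALSE)
  k <- new_density / x$density
  bsp(x$mass * k, x$com, x$moments * k, x$products * k, new_density)
}

#' Inertial components about an arbitrary point
#'
#' Parallel-axis transfer of the six inertial components from the centre of
#' mass to axes through `point` (parallel to the frame axes). Products keep
#' the positive-integral convention.
#'
#' @param x a `bsp`.
#' @param point numeric length-3 reference point (m).
#' @return named numeric vector `(ixx, iyy, izz, ixy, ixz, iyz)` in kg m^2.
#' @export
inertia_about_point <- function(x, point) {
  d <- unname(as.numeric(point) - x$com)
  m <- x$mass
  c(ixx = x$moments[["ixx"]] + m * (d[2]^2 + d[3]^2),
    iyy = x$moments[["iyy"]] + m * (d[1]^2 + d[3]^2),
    izz = x$moments[["izz"]] + m * (d[1]^2 + d[2]^2),
    ixy = x$products[["ixy"]] + m * d[1] * d[2],
    ixz = x$products[["ixz"]] + m * d[1] * d[3],
    iyz = x$products[["iyz"]] + m * d[2] * d[3])
}

# ---- serialization ---------------------------------------------------------

#' BSP as a one-row data frame with the output schema
#'
#' Columns: `mass_kg`, `cm_x_m`, `cm_y_m`, `cm_z_m`, `ixx_kgm2`, `iyy_kgm2`,
#' `izz_kgm2`, `ixy_kgm2`, `ixz_kgm2`, `iyz_kgm2`, `density_kgm3`,
#' `products_sign_convention` (fixed to `"positive_integral"`).
#'
#' @param x a `bsp`.
#' @param row.names,optional,... ignored (S3 method signature).
#' @export
as.data.frame.bsp <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(mass_kg = x$mass,
             cm_x_m = x$com[["x"]], cm_y_m = x$com[["y"]], cm_z_m = x$com[["z"]],
             ixx_kgm2 = x$moments[["ixx"]], iyy_kgm2 = x$moments[["iyy"]],
             izz_kgm2 = x$moments[["izz"]],
             ixy_kgm2 = x$products[["ixy"]], ixz_kgm2 = x$products[["ixz"]],
             iyz_kgm2 = x$products[["iyz"]],
             density_kgm3 = x$density,
             products_sign_convention = "positive_integral")
}

#' Serialize a BSP to JSON
#' @param x a `bsp`.
#' @return a JSON string using the schema of [as.data.frame.bsp()].
#' @export
bsp_to_json <- function(x) {
  jsonlite::toJSON(as.list(as.data.frame(x)), auto_unbox = TRUE, digits = NA)
}
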