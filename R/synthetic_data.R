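# Synthetic test-world generators: pure-birth trees, Brownian tip values,
# paired calibration datasets with known coefficients, primitive paired
# skeleton/skin specimens, and a Monte-Carlo mass-properties oracle.
#
# All generators are deterministic under their seed. The specimen world
# deliberately uses geometric primitives, not anatomy: every quantity has a
# closed form or an exact reference, which is what makes the end-to-end
# pipeline testable.

#' Simulate a pure-birth phylogeny
#'
#' Yule (pure-birth) tree with exponential waiting times between
#' speciations; tips are labelled `sp1 ... spN`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed; identical seeds give identical trees.
#' @return an `ape::phylo`.
#' @export
simulate_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 2L) stop("need at least 2 tips", call. = FALSE)
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$tip.label <- paste0("sp", seq_len(n_tips))
  tr
}

#' Simulate Brownian motion on a tree
#'
#' Tip values are jointly Gaussian with mean 0 (the root value) and
#' covariance `sigma^2 * bm_covariance(tree)`.
#'
#' @param tree an `ape::phylo`.
#' @param sigma per-unit-branch-length standard deviation.
#' @param seed integer seed.
#' @return named numeric vector of tip values (tree tip order).
#' @export
simulate_bm <- function(tree, sigma, seed = 1L) {
  tips <- tree$tip.label
  if (sigma == 0) return(setNames(rep(0, length(tips)), tips))
  V <- bm_covariance(tree, tips)
  set.seed(seed)
  z <- rnorm(length(tips))
  setNames(as.numeric(sigma * t(chol(V)) %*% z), tips)
}

#' Simulation configuration for paired datasets
#'
#' Defaults describe the emulated calibration world: species spanning a
#' body-mass range of roughly 0.02 to 400 kg (about four orders of
#' magnitude), per-cell conversion equations defaulting to the bundled
#' calibration coefficients, and residual scatter of 0.05 on the transform
#' scale (iid by default, or Brownian on a supplied tree).
#'
#' @param n_species number of species.
#' @param seed integer seed.
#' @param segments,parameters cells to generate (defaults: all 13 x 10).
#' @param true_intercepts,true_slopes named vectors keyed
#'   `"segment|parameter"`; cells absent from them fall back to the bundled
#'   table's coefficients.
#' @param noise_sd residual standard deviation on the transform scale.
#' @param noise_mode `"iid"` or `"brownian"`.
#' @param size_range length-2 body-mass range (kg) spanned log-uniformly.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 32L, seed = 1L,
                              segments = segment_names(),
                              parameters = parameter_names(),
                              true_intercepts = NULL, true_slopes = NULL,
                              noise_sd = 0.05,
                              noise_mode = c("iid", "brownian"),
                              size_range = c(0.02, 400)) {
  noise_mode <- match.arg(noise_mode)
  if (length(size_range) != 2L || any(size_range <= 0) ||
      size_range[1] >= size_range[2])
    stop("size_range must be an increasing positive pair", call. = FALSE)
  structure(list(n_species = as.integer(n_species), seed = as.integer(seed),
                 segments = segments, parameters = parameters,
                 true_intercepts = true_intercepts, true_slopes = true_slopes,
                 noise_sd = noise_sd, noise_mode = noise_mode,
                 size_range = size_range),
            class = "simulation_config")
}

# hull-value scale for a parameter given a body mass (kg): lengths go as
# M^(1/3), inertial terms as M^(5/3); constants are arbitrary but fixed
.hull_scale <- function(parameter, mass_kg) {
  switch(parameter,
         mass = 0.4 * mass_kg,
         cm_x = 0.12 * mass_kg^(1 / 3),
         cm_y = 0.02 * mass_kg^(1 / 3),
         cm_z = 0.05 * mass_kg^(1 / 3),
         ixx = , iyy = , izz = 0.05 * mass_kg^(5 / 3),
         ixy = , ixz = , iyz = 0.002 * mass_kg^(5 / 3))
}

#' Generate a paired hull/soft dataset with known coefficients
#'
#' Hull values are spread log-uniformly (via body mass) over the configured
#' size range; soft values are the inverse-transformed linear model
#' `a + b * transform(hull) + eps` with iid Gaussian or Brownian
#' tree-structured residuals. The generating truth is attached as
#' `attr(x, "truth")`.
#'
#' @param config a `simulation_config`.
#' @param tree an `ape::phylo`; required for `noise_mode = "brownian"`,
#'   and, when given, its tip labels name the species.
#' @return a `paired_dataset` with attribute `truth`.
#' @export
generate_paired_dataset <- function(config, tree = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$noise_mode == "brownian" && is.null(tree))
    stop("brownian noise requires a tree", call. = FALSE)
  species <- if (!is.null(tree)) tree$tip.label
             else paste0("sp", seq_len(config$n_species))
  ns <- length(species)
  set.seed(config$seed)
  lmass <- runif(ns, log10(config$size_range[1]), log10(config$size_range[2]))
  body_mass <- 10^lmass
  bundled <- load_bundled_table()
  truth <- list(); rows <- list()
  cell_id <- 0L
  for (seg in config$segments) {
    side <- if (seg %in% .SEGMENTS_APPENDICULAR) "left" else "none"
    for (par in config$parameters) {
      cell_id <- cell_id + 1L
      key <- .model_key(seg, par)
      a <- if (!is.null(config$true_intercepts) &&
               key %in% names(config$true_intercepts))
        config$true_intercepts[[key]] else bundled$models[[key]]$intercept
      b <- if (!is.null(config$true_slopes) &&
               key %in% names(config$true_slopes))
        config$true_slopes[[key]] else bundled$models[[key]]$slope
      hull <- .hull_scale(par, body_mass)
      ht <- transform_values(hull, par)
      eps <- if (config$noise_sd == 0) {
        rep(0, ns)
      } else if (config$noise_mode == "iid") {
        rnorm(ns, 0, config$noise_sd)
      } else {
        # per-cell derived seed keeps cells independent yet reproducible
        simulate_bm(tree, config$noise_sd,
                    seed = (config$seed + 7919L * cell_id) %% 2147483647L)
      }
      st <- a + b * ht + eps
      soft <- if (parameter_transform(par) == "log10") 10^st else st
      rows[[cell_id]] <- data.frame(
        species = species, segment = seg, side = side, parameter = par,
        hull_value = hull, soft_value = soft)
      truth[[cell_id]] <- data.frame(segment = seg, parameter = par,
                                     intercept = a, slope = b)
    }
  }
  out <- paired_dataset(do.call(rbind, rows))
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

# per-segment primitive shapes (unscaled, body_scale = 1); dimensions in
# meters, roughly proportioned like a mid-sized quadruped
.SEGMENT_SHAPES <- list(
  arm     = list(kind = "box",    dims = c(0.30, 0.12, 0.12), at = c(0.55,  0.25, 0.55)),
  forearm = list(kind = "box",    dims = c(0.26, 0.10, 0.10), at = c(0.55,  0.25, 0.30)),
  hand    = list(kind = "box",    dims = c(0.14, 0.08, 0.05), at = c(0.55,  0.25, 0.05)),
  thigh   = list(kind = "box",    dims = c(0.36, 0.18, 0.18), at = c(-0.45, 0.25, 0.60)),
  shank   = list(kind = "box",    dims = c(0.30, 0.12, 0.12), at = c(-0.45, 0.25, 0.30)),
  foot    = list(kind = "box",    dims = c(0.20, 0.10, 0.06), at = c(-0.45, 0.25, 0.05)),
  head    = list(kind = "sphere", dims = 0.14,                at = c(0.95,  0.00, 0.85)),
  neck    = list(kind = "prism",  dims = c(0.25, 0.10),       at = c(0.70,  0.00, 0.85)),
  torso   = list(kind = "box",    dims = c(0.85, 0.40, 0.45), at = c(0.00,  0.00, 0.80)),
  tail1   = list(kind = "prism",  dims = c(0.18, 0.060),      at = c(-0.75, 0.00, 0.80)),
  tail2   = list(kind = "prism",  dims = c(0.18, 0.048),      at = c(-0.95, 0.00, 0.80)),
  tail3   = list(kind = "prism",  dims = c(0.18, 0.036),      at = c(-1.15, 0.00, 0.80)),
  tail4   = list(kind = "prism",  dims = c(0.18, 0.026),      at = c(-1.35, 0.00, 0.80)))

.hexagon <- function(r) {
  ang <- seq(0, 2 * pi, length.out = 7L)[-7L]
  cbind(r * cos(ang), r * sin(ang))
}

#' Generate a synthetic paired skeleton/skin specimen
#'
#' Builds, for each of the 13 fit-table segments, an outer primitive mesh
#' (the "skin": box, icosphere or hexagonal prism, proportioned like a
#' generic quadruped and scaled by `body_scale`) and an inner "skeleton"
#' obtained by isotropically shrinking the skin toward its centroid by a
#' factor drawn in [0.3, 0.7] -- so skeleton vertices always lie strictly
#' inside the skin. The true BSP of each segment is the exact mass
#' properties of the skin at 1000 kg m^-3.
#'
#' @param species species name recorded in the specimen.
#' @param body_scale linear scale multiplier (> 0); masses scale as its
#'   cube.
#' @param seed integer seed.
#' @param shrink_range range the per-segment shrink factor is drawn from.
#'   The shrink spread is the pipeline's noise source: because it perturbs
#'   the hull (x) side of the hull/soft relation, a wide spread attenuates
#'   fitted slopes (regression dilution); parameter-recovery checks should
#'   use a narrow spread.
#' @return a list of class `synthetic_specimen` with `species`,
#'   `body_scale` and a per-segment list of `skin`, `skeleton` (both
#'   `triangle_mesh`) and `true_bsp`.
#' @export
generate_specimen <- function(species, body_scale = 1, seed = 1L,
                              shrink_range = c(0.3, 0.7)) {
  if (!is.finite(body_scale) || body_scale <= 0)
    stop("body_scale must be positive", call. = FALSE)
  if (length(shrink_range) != 2L || shrink_range[1] <= 0 ||
      shrink_range[2] >= 1 || shrink_range[1] > shrink_range[2])
    stop("shrink_range must lie inside (0, 1)", call. = FALSE)
  set.seed(seed)
  segments <- lapply(names(.SEGMENT_SHAPES), function(seg) {
    sh <- .SEGMENT_SHAPES[[seg]]
    at <- sh$at * body_scale
    skin <- switch(sh$kind,
      box = make_box(sh$dims * body_scale, at),
      sphere = make_icosphere(sh$dims * body_scale, 2L, at),
      prism = translate_mesh(
        make_prism(sh$dims[1] * body_scale,
                   .hexagon(sh$dims[2] * body_scale), axis = "x"), at))
    shrink <- runif(1, shrink_range[1], shrink_range[2])
    centroid <- colMeans(skin$vertices)
    skeleton <- skin
    skeleton$vertices <- sweep(sweep(skin$vertices, 2L, centroid) * shrink,
                               2L, centroid, "+")
    list(skin = skin, skeleton = skeleton,
         true_bsp = mass_properties(skin, 1000))
  })
  names(segments) <- names(.SEGMENT_SHAPES)
  structure(list(species = species, body_scale = body_scale,
                 segments = segments),
            class = "synthetic_specimen")
}

#' Monte-Carlo mass-properties oracle
#'
#' Brute-force estimator of the ten polyhedral volume integrals (and the
#' derived BSP) by uniform rejection sampling in the axis-aligned bounding
#' box with ray-crossing inside tests. Entirely independent of the exact
#' integral code path; used to validate it.
#'
#' @param mesh a watertight `triangle_mesh`.
#' @param n_samples number of points thrown into the bounding box.
#' @param seed integer seed.
#' @param density density for the derived BSP estimate (kg m^-3).
#' @return list of class `mc_bsp` with `integrals` and `se` (named as in
#'   [polyhedron_integrals()]), `bsp` (a `bsp` built from the estimated
#'   integrals), `n_samples` and `n_accepted`.
#' @export
mc_mass_properties <- function(mesh, n_samples = 1e5, seed = 1L,
                               density = 1000) {
  mesh <- .require_solid(mesh)
  lo <- apply(mesh$vertices, 2L, min)
  hi <- apply(mesh$vertices, 2L, max)
  B <- prod(hi - lo)
  set.seed(seed)
  n <- as.integer(n_samples)
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  inside <- .points_in_mesh_cpp(pts, mesh$vertices, mesh$faces)
  if (!any(inside)) stop("no samples fell inside the mesh", call. = FALSE)
  x <- pts[, 1L]; y <- pts[, 2L]; z <- pts[, 3L]
  fs <- list(volume = rep(1, n), x = x, y = y, z = z,
             xx = x^2, yy = y^2, zz = z^2,
             xy = x * y, yz = y * z, zx = z * x)
  est <- vapply(fs, function(f) B * mean(f * inside), 0)
  se <- vapply(fs, function(f) B * sd(f * inside) / sqrt(n), 0)
  V <- est[["volume"]]
  m <- density * V
  com <- c(est[["x"]], est[["y"]], est[["z"]]) / V
  ixx <- density * (est[["yy"]] + est[["zz"]]) - m * (com[2]^2 + com[3]^2)
  iyy <- density * (est[["xx"]] + est[["zz"]]) - m * (com[1]^2 + com[3]^2)
  izz <- density * (est[["xx"]] + est[["yy"]]) - m * (com[1]^2 + com[2]^2)
  ixy <- density * est[["xy"]] - m * com[1] * com[2]
  ixz <- density * est[["zx"]] - m * com[1] * com[3]
  iyz <- density * est[["yz"]] - m * com[2] * com[3]
  structure(list(
    integrals = est, se = se,
    bsp = bsp(m, com, c(ixx, iyy, izz), c(ixy, ixz, iyz), density),
    n_samples = n, n_accepted = sum(inside)),
    class = "mc_bsp")
}
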