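# Segment taxonomy, calibration models, the bundled mammalian calibration
# table, and prediction of soft-tissue BSPs from naive hull BSPs.
#
# The fit table is keyed by 13 segments (the six left limb segments plus
# head, neck, torso and four tail quarters) x 10 parameters. Mass and the
# three moments of inertia are modelled on the log10 scale; the centre of
# mass coordinates and the products of inertia on the linear (signed)
# scale. Right-sided limb segments reuse the left-side equations with the
# signs of the laterally antisymmetric quantities -- CM(y), Ixy, Iyz --
# reversed.

.SEGMENTS_APPENDICULAR <- c("arm", "forearm", "hand", "thigh", "shank", "foot")
.SEGMENTS_AXIAL <- c("head", "neck", "torso", "tail1", "tail2", "tail3", "tail4")
.SEGMENTS <- c(.SEGMENTS_APPENDICULAR, .SEGMENTS_AXIAL)
.PARAMETERS <- c("mass", "cm_x", "cm_y", "cm_z",
                 "ixx", "iyy", "izz", "ixy", "ixz", "iyz")
.LOG10_PARAMETERS <- c("mass", "ixx", "iyy", "izz")
.MIRROR_PARAMETERS <- c("cm_y", "ixy", "iyz")

#' Segment and parameter vocabularies
#'
#' `segment_names()` returns the 13 fit-table segment keys;
#' `parameter_names()` the 10 body segment parameters;
#' `parameter_transform()` the modelling scale of a parameter (`"log10"`
#' for mass and the moments of inertia, `"linear"` otherwise).
#'
#' @return character vectors.
#' @export
segment_names <- function() .SEGMENTS

#' @rdname segment_names
#' @export
parameter_names <- function() .PARAMETERS

#' @rdname segment_names
#' @param parameter a parameter name.
#' @export
parameter_transform <- function(parameter) {
  parameter <- match.arg(parameter, .PARAMETERS)
  if (parameter %in% .LOG10_PARAMETERS) "log10" else "linear"
}

#' Construct a segment label
#'
#' @param name one of the 13 segment names (see [segment_names()]).
#' @param side `"left"`, `"right"` or `"none"`. Appendicular (limb)
#'   segments require a side; axial segments must have side `"none"`.
#' @return a list of class `segment_label` with fields `name`, `side` and
#'   `class` (`"appendicular"` or `"axial"`).
#' @export
segment_label <- function(name, side = c("none", "left", "right")) {
  name <- match.arg(name, .SEGMENTS)
  side <- match.arg(side)
  cls <- if (name %in% .SEGMENTS_APPENDICULAR) "appendicular" else "axial"
  if (cls == "axial" && side != "none")
    stop("axial segment '", name, "' cannot have a side", call. = FALSE)
  if (cls == "appendicular" && side == "none")
    stop("appendicular segment '", name, "' needs side 'left' or 'right'",
         call. = FALSE)
  structure(list(name = name, side = side, class = cls),
            class = "segment_label")
}

#' Construct a calibration model
#'
#' A per-(segment, parameter) linear equation on the stated transform
#' scale: `soft_t = intercept + slope * hull_t`, with `_t` the transformed
#' value (log10 for mass and moments of inertia, identity otherwise).
#'
#' @param segment a `segment_label` (side `"left"` or `"none"`), or a
#'   segment name.
#' @param parameter one of the 10 parameter names.
#' @param intercept,slope equation coefficients (intercept in transformed
#'   parameter units, slope dimensionless).
#' @param intercept_ci,slope_ci optional length-2 95% confidence intervals.
#' @param method `"OLS"` or `"PGLS-BM"`.
#' @param n,r2,rmse optional fit diagnostics.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(segment, parameter, intercept, slope,
                              intercept_ci = NULL, slope_ci = NULL,
                              method = c("OLS", "PGLS-BM"),
                              n = NA_integer_, r2 = NA_real_,
                              rmse = NA_real_) {
  if (is.character(segment)) {
    nm <- match.arg(segment, .SEGMENTS)
    segment <- segment_label(nm, if (nm %in% .SEGMENTS_APPENDICULAR) "left"
                                 else "none")
  }
  if (!inherits(segment, "segment_label")) stop("bad segment", call. = FALSE)
  if (segment$side == "right")
    stop("calibration models are stored for the left side; use mirror_model()",
         call. = FALSE)
  parameter <- match.arg(parameter, .PARAMETERS)
  method <- match.arg(method)
  chk_ci <- function(ci, est, what) {
    if (is.null(ci) || any(is.na(ci))) return(NULL)
    if (length(ci) != 2L || ci[1] > ci[2])
      stop("malformed ", what, " CI", call. = FALSE)
    if (est < ci[1] - 1e-9 || est > ci[2] + 1e-9)
      warning(what, " point estimate outside its CI", call. = FALSE)
    as.numeric(ci)
  }
  structure(list(segment = segment, parameter = parameter,
                 transform = parameter_transform(parameter),
                 intercept = as.numeric(intercept), slope = as.numeric(slope),
                 intercept_ci = chk_ci(intercept_ci, intercept, "intercept"),
                 slope_ci = chk_ci(slope_ci, slope, "slope"),
                 method = method, n = n, r2 = r2, rmse = rmse),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model [%s %s, %s, %s]: %.4g + %.4g x\n",
              x$segment$side, x$segment$name, x$parameter, x$transform,
              x$intercept, x$slope))
  invisible(x)
}

.model_key <- function(segment_name, parameter) paste(segment_name, parameter,
                                                      sep = "|")

#' Construct a calibration table
#'
#' @param models list of `calibration_model`s (left side / axial only).
#' @param provenance free-text description of the table's origin.
#' @param mass_range optional length-2 hull-mass range (kg) over which the
#'   table was calibrated; predictions outside it raise an extrapolation
#'   warning.
#' @return an object of class `calibration_table`.
#' @export
calibration_table <- function(models, provenance = "",
                              mass_range = NULL) {
  keys <- vapply(models, function(m) .model_key(m$segment$name, m$parameter),
                 "")
  if (anyDuplicated(keys))
    stop("duplicate (segment, parameter) models", call. = FALSE)
  names(models) <- keys
  structure(list(models = models, provenance = provenance,
                 mass_range = mass_range),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("calibration_table: %d models (%s)\n", length(x$models),
              x$provenance))
  invisible(x)
}

#' Load the bundled mammalian calibration table
#'
#' The packaged table of 130 linear conversion equations (13 segments x 10
#' parameters) calibrated on paired skeleton/skin CT reconstructions of 32
#' extant mammal species spanning roughly 0.02--400 kg body mass, together
#' with 95% confidence intervals of each intercept and slope. Coefficients
#' are stored exactly as printed in the source tables (3-significant-figure
#' intercepts, 2-decimal slopes).
#'
#' @return a `calibration_table` with 130 entries.
#' @export
load_bundled_table <- function() {
  path <- system.file("extdata", "calibration_mammal.csv", package = "hullbsp",
                      mustWork = TRUE)
  tab <- read_calibration_csv(path)
  tab$provenance <- "bundled mammalian calibration (32 extant species, CT)"
  tab$mass_range <- c(0.02, 400)
  tab
}

#' Read / write a calibration table as CSV
#'
#' Schema: `segment, side, parameter, transform, intercept, slope,
#' intercept_lo, intercept_hi, slope_lo, slope_hi, method, n, r2, rmse`.
#'
#' @param path CSV file path.
#' @return `read_calibration_csv()` returns a `calibration_table`.
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "side", "parameter", "transform", "intercept", "slope")
  if (!all(need %in% names(df)))
    stop("calibration CSV lacks required columns", call. = FALSE)
  models <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    expected <- parameter_transform(r$parameter)
    if (!identical(r$transform, expected))
      stop("row ", i, ": transform '", r$transform, "' must be '", expected,
           "' for parameter ", r$parameter, call. = FALSE)
    calibration_model(
      segment_label(r$segment, r$side),
      r$parameter, r$intercept, r$slope,
      intercept_ci = c(r$intercept_lo, r$intercept_hi),
      slope_ci = c(r$slope_lo, r$slope_hi),
      method = r$method,
      n = if ("n" %in% names(df)) r$n else NA_integer_,
      r2 = if ("r2" %in% names(df)) r$r2 else NA_real_,
      rmse = if ("rmse" %in% names(df)) r$rmse else NA_real_)
  })
  calibration_table(models, provenance = path)
}

#' @rdname read_calibration_csv
#' @param table a `calibration_table`.
#' @export
write_calibration_csv <- function(table, path) {
  rows <- lapply(table$models, function(m) {
    data.frame(segment = m$segment$name, side = m$segment$side,
               parameter = m$parameter, transform = m$transform,
               intercept = m$intercept, slope = m$slope,
               intercept_lo = if (is.null(m$intercept_ci)) NA else m$intercept_ci[1],
               intercept_hi = if (is.null(m$intercept_ci)) NA else m$intercept_ci[2],
               slope_lo = if (is.null(m$slope_ci)) NA else m$slope_ci[1],
               slope_hi = if (is.null(m$slope_ci)) NA else m$slope_ci[2],
               method = m$method, n = m$n, r2 = m$r2, rmse = m$rmse)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Convert one hull value with a calibration model
#'
#' log10 models return `10^(a + b * log10(hull_value))`; linear models
#' return `a + b * hull_value`. Inputs and outputs are in SI units.
#'
#' @param hull_value naive convex-hull value (SI units).
#' @param model a `calibration_model`.
#' @return predicted soft-tissue value (SI units).
#' @export
predict_parameter <- function(hull_value, model) {
  if (model$transform == "log10") {
    if (any(hull_value <= 0))
      stop("log10-transformed parameter '", model$parameter,
           "' requires a positive hull value", call. = FALSE)
    10^(model$intercept + model$slope * log10(hull_value))
  } else {
    model$intercept + model$slope * hull_value
  }
}

#' Mirror a left-side calibration model to the right side
#'
#' For the laterally antisymmetric parameters CM(y), Ixy and Iyz the
#' intercept's sign is reversed (the slope, acting on sign-flipped inputs,
#' is unchanged); all other parameters are unchanged. Applying the result
#' to a right-sided hull BSP is equivalent to mirroring the BSP, applying
#' the left model, and mirroring back.
#'
#' @param model a left-side appendicular `calibration_model`.
#' @return the right-side model.
#' @export
mirror_model <- function(model) {
  if (model$segment$class == "axial")
    stop("cannot mirror an axial segment model", call. = FALSE)
  out <- model
  if (model$segment$side == "right") {
    out$segment$side <- "left"
  } else {
    out$segment$side <- "right"
  }
  if (model$parameter %in% .MIRROR_PARAMETERS) {
    out$intercept <- -model$intercept
    if (!is.null(model$intercept_ci))
      out$intercept_ci <- sort(-model$intercept_ci)
  }
  out
}

#' Mirror a BSP across the sagittal (xz) plane
#'
#' Negates CM(y), Ixy and Iyz; everything else is unchanged. An involution.
#'
#' @param x a `bsp`.
#' @return the mirrored `bsp`.
#' @export
mirror_bsp <- function(x) {
  x$com[["y"]] <- -x$com[["y"]]
  x$products[["ixy"]] <- -x$products[["ixy"]]
  x$products[["iyz"]] <- -x$products[["iyz"]]
  x
}

.bsp_value <- function(x, parameter) {
  switch(parameter,
         mass = x$mass,
         cm_x = x$com[["x"]], cm_y = x$com[["y"]], cm_z = x$com[["z"]],
         ixx = x$moments[["ixx"]], iyy = x$moments[["iyy"]],
         izz = x$moments[["izz"]],
         ixy = x$products[["ixy"]], ixz = x$products[["ixz"]],
         iyz = x$products[["iyz"]])
}

#' Predict soft-tissue BSPs from a naive hull BSP
#'
#' Applies the 10 per-parameter calibration equations for the segment.
#' Right-sided limb segments use the mirrored left-side models. With
#' `zero_axial = TRUE`, the laterally antisymmetric parameters (CM(y),
#' Ixy, Iyz) of axial segments are forced to exactly zero after prediction,
#' as multibody models assume lateral symmetry. A warning is raised when
#' the hull mass lies outside the table's calibrated mass range
#' (extrapolation), and when the hull BSP was computed at a density other
#' than the calibration's nominal 1000 kg m^-3 (rescale the *prediction*
#' with [rescale_density()] instead).
#'
#' @param hull_bsp a `bsp` computed from a segment's convex hull.
#' @param segment a `segment_label` or segment name (axial).
#' @param table a `calibration_table` (default: the bundled table).
#' @param zero_axial force CM(y), Ixy, Iyz of axial segments to zero.
#' @return the predicted soft-tissue `bsp`.
#' @export
predict_segment <- function(hull_bsp, segment, table = load_bundled_table(),
                            zero_axial = FALSE) {
  if (is.character(segment)) {
    nm <- match.arg(segment, .SEGMENTS)
    segment <- segment_label(nm, if (nm %in% .SEGMENTS_APPENDICULAR) "left"
                                 else "none")
  }
  models <- lapply(.PARAMETERS, function(p) {
    m <- table$models[[.model_key(segment$name, p)]]
    if (is.null(m))
      stop("no calibration model for (", segment$name, ", ", p, ")",
           call. = FALSE)
    if (segment$side == "right") m <- mirror_model(m)
    m
  })
  names(models) <- .PARAMETERS
  if (!is.null(table$mass_range) &&
      (hull_bsp$mass < table$mass_range[1] ||
       hull_bsp$mass > table$mass_range[2]))
    warning(sprintf(
      "hull mass %.3g kg is outside the calibrated range [%.3g, %.3g] kg; %s",
      hull_bsp$mass, table$mass_range[1], table$mass_range[2],
      "prediction is an extrapolation"), call. = FALSE)
  if (hull_bsp$density != 1000)
    warning("calibration assumes hull BSPs at 1000 kg m^-3; rescale the ",
            "prediction, not the input", call. = FALSE)
  pred <- vapply(.PARAMETERS, function(p)
    predict_parameter(.bsp_value(hull_bsp, p), models[[p]]), 0)
  out <- bsp(pred[["mass"]],
             c(pred[["cm_x"]], pred[["cm_y"]], pred[["cm_z"]]),
             c(pred[["ixx"]], pred[["iyy"]], pred[["izz"]]),
             c(pred[["ixy"]], pred[["ixz"]], pred[["iyz"]]),
             hull_bsp$density)
  if (zero_axial && segment$class == "axial") {
    out$com[["y"]] <- 0
    out$products[["ixy"]] <- 0
    out$products[["iyz"]] <- 0
  }
  out
}
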