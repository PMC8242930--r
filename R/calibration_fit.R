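# Fitting calibration tables from paired hull/soft-tissue observations.
#
# Each (segment, parameter) cell is a simple linear regression of the
# transformed soft value on the transformed hull value, fit by OLS and --
# when a phylogeny is supplied -- by generalized least squares with the
# Brownian-motion covariance (Pagel's lambda fixed at 1; OLS is lambda =
# 0). Both are maximum-likelihood fits with k = 3 parameters (intercept,
# slope, residual variance), so their AICs are directly comparable and any
# AIC difference reflects only the residual covariance structure. OLS fits
# additionally report R^2 and a leave-one-out cross-validated RMSE.

#' Transform values to the modelling scale of a parameter
#'
#' Mass and the three moments of inertia are modelled on the log10 scale;
#' centre-of-mass coordinates and products of inertia on the linear
#' (signed) scale.
#'
#' @param values numeric vector in SI units.
#' @param parameter one of the 10 parameter names.
#' @return transformed numeric vector.
#' @export
transform_values <- function(values, parameter) {
  if (parameter_transform(parameter) == "log10") {
    bad <- which(!(values > 0))
    if (length(bad))
      stop("parameter '", parameter, "' is log10-transformed but row",
           if (length(bad) > 1) "s" else "", " ",
           paste(bad, collapse = ", "), " ",
           if (length(bad) > 1) "are" else "is", " not positive",
           call. = FALSE)
    log10(values)
  } else {
    values
  }
}

.regression_fit <- function(method, a, b, sigma2, loglik, aic, a_ci, b_ci,
                            n, r2 = NA_real_, loocv_rmse = NA_real_) {
  structure(list(method = method, intercept = a, slope = b, sigma2 = sigma2,
                 loglik = loglik, aic = aic,
                 intercept_ci = a_ci, slope_ci = b_ci,
                 r2 = r2, loocv_rmse = loocv_rmse, n = n),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("%s fit (n=%d): a=%.5g b=%.5g  AIC=%.3f", x$method, x$n,
              x$intercept, x$slope, x$aic))
  if (!is.na(x$r2)) cat(sprintf("  R2=%.4f", x$r2))
  cat("\n")
  invisible(x)
}

#' Ordinary least squares fit
#'
#' Gaussian maximum-likelihood simple linear regression. The log-likelihood
#' is evaluated at the ML variance `RSS/n` and `AIC = 2k - 2 loglik` with
#' `k = 3`; 95% confidence intervals use the t distribution with `n - 2`
#' degrees of freedom. When `n >= 4` the leave-one-out cross-validated
#' RMSE of prediction is included (hat-matrix closed form).
#'
#' @param x,y numeric vectors (already transformed).
#' @return a `regression_fit`.
#' @export
fit_ols <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("singular fit: x is constant", call. = FALSE)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  resid <- y - a - b * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  s2ml <- rss / n
  loglik <- if (s2ml > 0) -0.5 * (n * log(2 * pi * s2ml) + n) else Inf
  aic <- 2 * 3 - 2 * loglik
  s2 <- rss / (n - 2L)
  se_b <- sqrt(s2 / sxx)
  se_a <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  tq <- qt(0.975, n - 2L)
  loo <- if (n >= 4L) loocv_rmse(x, y) else NA_real_
  .regression_fit("OLS", a, b, s2ml, loglik, aic,
                  c(a - tq * se_a, a + tq * se_a),
                  c(b - tq * se_b, b + tq * se_b),
                  n, r2 = r2, loocv_rmse = loo)
}

#' Brownian-motion covariance matrix of a phylogeny
#'
#' Under Brownian motion with unit rate, the covariance of two tips is the
#' shared root-to-tip path length; the variance of a tip is its depth. The
#' tree need not be ultrametric.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param species_order character vector of tip labels giving the row/column
#'   order of the result.
#' @return a symmetric positive-definite matrix.
#' @export
bm_covariance <- function(tree, species_order) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo'",
                                     call. = FALSE)
  missing_ <- setdiff(species_order, tree$tip.label)
  if (length(missing_))
    stop("species not in tree: ", paste(missing_, collapse = ", "),
         call. = FALSE)
  V <- ape::vcv(tree)
  V[species_order, species_order, drop = FALSE]
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' GLS with residual covariance proportional to [bm_covariance()] (Pagel's
#' lambda fixed at 1). Maximum-likelihood variance and log-likelihood, AIC
#' with `k = 3`; confidence intervals use the t distribution with `n - 2`
#' degrees of freedom on the GLS standard errors. No R^2 or LOOCV is
#' reported for PGLS fits.
#'
#' @param x,y numeric vectors (already transformed), ordered as `species`.
#' @param tree an `ape::phylo` covering all `species`.
#' @param species character vector of species names matching `x` and `y`.
#' @return a `regression_fit` with method `"PGLS-BM"`.
#' @export
fit_pgls_bm <- function(x, y, tree, species) {
  n <- length(x)
  if (length(y) != n || length(species) != n)
    stop("x, y and species lengths differ", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  V <- bm_covariance(tree, species)
  L <- tryCatch(chol(V), error = function(e)
    stop("Brownian covariance is not positive definite: ",
         conditionMessage(e), call. = FALSE))
  X <- cbind(1, x)
  # whiten: L' z = v  =>  z = L'^-1 v ; then OLS on whitened data
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  if (rcond(XtX) < 1e-14)
    stop("singular fit: x is constant (after whitening)", call. = FALSE)
  beta <- solve(XtX, crossprod(Xw, yw))
  rw <- yw - Xw %*% beta
  rssg <- sum(rw^2)
  s2ml <- rssg / n
  logdetV <- 2 * sum(log(diag(L)))
  loglik <- -0.5 * (n * log(2 * pi * s2ml) + logdetV + n)
  aic <- 2 * 3 - 2 * loglik
  s2 <- rssg / (n - 2L)
  covb <- s2 * solve(XtX)
  tq <- qt(0.975, n - 2L)
  a <- beta[1L]; b <- beta[2L]
  .regression_fit("PGLS-BM", a, b, s2ml, loglik, aic,
                  c(a - tq * sqrt(covb[1, 1]), a + tq * sqrt(covb[1, 1])),
                  c(b - tq * sqrt(covb[2, 2]), b + tq * sqrt(covb[2, 2])),
                  n)
}

#' Select between OLS and PGLS fits by AIC
#'
#' Returns the fit with the lower AIC; ties (|dAIC| < 1e-9) go to OLS, the
#' simpler covariance structure.
#'
#' @param ols,pgls `regression_fit`s on identical data.
#' @return the selected `regression_fit`.
#' @export
select_model <- function(ols, pgls) {
  if (ols$n != pgls$n)
    stop("fits were not computed on the same data (n differs)", call. = FALSE)
  if (pgls$aic < ols$aic - 1e-9) pgls else ols
}

#' Leave-one-out cross-validated RMSE of an OLS fit
#'
#' Root mean square error of prediction over leave-one-out refits, computed
#' with the exact hat-matrix identity `e_i / (1 - h_ii)` (identical to
#' explicit refitting).
#'
#' @param x,y numeric vectors, `n >= 4`.
#' @return non-negative scalar.
#' @export
loocv_rmse <- function(x, y) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations for LOOCV", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("singular fit: x is constant", call. = FALSE)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  e <- y - a - b * x
  h <- 1 / n + (x - mean(x))^2 / sxx
  sqrt(mean((e / (1 - h))^2))
}

#' Read a paired hull/soft dataset from CSV
#'
#' Columns: `species, segment, side, parameter, hull_value, soft_value`.
#'
#' @param path CSV file path.
#' @return a data frame of class `paired_dataset`.
#' @export
read_paired_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  paired_dataset(df)
}

#' Construct / validate a paired dataset
#'
#' @param df data frame with columns `species, segment, side, parameter,
#'   hull_value, soft_value`; one row per (species, segment, side,
#'   parameter).
#' @return the validated data frame, classed `paired_dataset`.
#' @export
paired_dataset <- function(df) {
  need <- c("species", "segment", "side", "parameter", "hull_value",
            "soft_value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("paired dataset lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("empty paired dataset", call. = FALSE)
  bad_seg <- setdiff(unique(df$segment), .SEGMENTS)
  if (length(bad_seg))
    stop("unknown segments: ", paste(bad_seg, collapse = ", "), call. = FALSE)
  bad_par <- setdiff(unique(df$parameter), .PARAMETERS)
  if (length(bad_par))
    stop("unknown parameters: ", paste(bad_par, collapse = ", "),
         call. = FALSE)
  key <- paste(df$species, df$segment, df$side, df$parameter)
  if (anyDuplicated(key))
    stop("duplicate (species, segment, side, parameter) rows", call. = FALSE)
  class(df) <- c("paired_dataset", "data.frame")
  df
}

# fold right-sided appendicular rows onto the left side by mirroring the
# antisymmetric parameters
.fold_right <- function(df) {
  r <- df$side == "right"
  flip <- r & df$parameter %in% .MIRROR_PARAMETERS
  df$hull_value[flip] <- -df$hull_value[flip]
  df$soft_value[flip] <- -df$soft_value[flip]
  df$side[r] <- "left"
  # a specimen contributing both sides would now collide; keep the original
  # left observation and drop the folded duplicate
  df <- df[order(r), , drop = FALSE]
  key <- paste(df$species, df$segment, df$side, df$parameter)
  df[!duplicated(key), , drop = FALSE]
}

#' Fit a calibration table from a paired dataset
#'
#' For every (segment, parameter) cell with at least `min_n` species the
#' transformed soft values are regressed on the transformed hull values by
#' OLS and, when a tree is supplied, by PGLS under Brownian motion (with
#' the tree pruned to the species present in the cell); the model with the
#' lower AIC is retained. Right-sided appendicular rows are folded onto the
#' left side by sign reversal of CM(y), Ixy and Iyz before fitting. Cells
#' with insufficient data are omitted, never silently filled.
#'
#' @param dataset a `paired_dataset` (or data frame with its columns).
#' @param tree optional `ape::phylo` covering the dataset's species.
#' @param min_n minimum species per cell (default 3).
#' @return list with `table` (a `calibration_table`) and `report` (a data
#'   frame with one row per fitted cell: coefficients, CIs, R2, LOOCV RMSE,
#'   `aic_ols`, `aic_pgls`, `chosen`).
#' @export
build_calibration <- function(dataset, tree = NULL, min_n = 3L) {
  df <- .fold_right(paired_dataset(as.data.frame(dataset)))
  cells <- unique(df[, c("segment", "parameter")])
  models <- list()
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    seg <- cells$segment[i]; par <- cells$parameter[i]
    cell <- df[df$segment == seg & df$parameter == par, , drop = FALSE]
    if (nrow(cell) < min_n) next
    xt <- transform_values(cell$hull_value, par)
    yt <- transform_values(cell$soft_value, par)
    ols <- fit_ols(xt, yt)
    pgls <- NULL
    if (!is.null(tree)) {
      sub <- ape::keep.tip(tree, intersect(tree$tip.label, cell$species))
      if (!all(cell$species %in% sub$tip.label))
        stop("species missing from tree: ",
             paste(setdiff(cell$species, sub$tip.label), collapse = ", "),
             call. = FALSE)
      pgls <- fit_pgls_bm(xt, yt, sub, cell$species)
    }
    chosen <- if (is.null(pgls)) ols else select_model(ols, pgls)
    side <- if (seg %in% .SEGMENTS_APPENDICULAR) "left" else "none"
    models[[length(models) + 1L]] <- calibration_model(
      segment_label(seg, side), par, chosen$intercept, chosen$slope,
      intercept_ci = chosen$intercept_ci, slope_ci = chosen$slope_ci,
      method = chosen$method, n = chosen$n,
      r2 = ols$r2, rmse = ols$loocv_rmse)
    rows[[length(rows) + 1L]] <- data.frame(
      segment = seg, side = side, parameter = par,
      transform = parameter_transform(par),
      intercept = chosen$intercept, slope = chosen$slope,
      intercept_lo = chosen$intercept_ci[1],
      intercept_hi = chosen$intercept_ci[2],
      slope_lo = chosen$slope_ci[1], slope_hi = chosen$slope_ci[2],
      n = chosen$n, r2 = ols$r2, loocv_rmse = ols$loocv_rmse,
      aic_ols = ols$aic,
      aic_pgls = if (is.null(pgls)) NA_real_ else pgls$aic,
      chosen = chosen$method)
  }
  if (length(models) == 0L)
    stop("no (segment, parameter) cell had at least ", min_n, " observations",
         call. = FALSE)
  list(table = calibration_table(models,
                                 provenance = "fitted by build_calibration"),
       report = do.call(rbind, rows))
}
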