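# regression engine: OLS, PGLS under Brownian motion, AIC, LOOCV

test_that("transform_values follows the log10 rule and names bad rows", {
  expect_equal(transform_values(c(1, 10, 100), "mass"), c(0, 1, 2))
  expect_equal(transform_values(c(-0.2, 0.3), "cm_x"), c(-0.2, 0.3))
  expect_equal(transform_values(c(-1e-4, 2e-3), "ixy"), c(-1e-4, 2e-3))
  expect_error(transform_values(c(1, 0, 2), "mass"), "row.* 2")
  expect_error(transform_values(c(1, -1, 0), "izz"), "2, 3")
})

test_that("fit_ols matches exact fits and the normal-equations oracle", {
  f <- fit_ols(c(0, 1, 2), c(2, 3, 4))
  expect_equal(f$intercept, 2, tolerance = 1e-12)
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1)

  fc <- fit_ols(c(1, 2, 3, 4), c(5, 5, 5, 5))
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  expect_equal(fc$r2, 0)

  set.seed(30)
  x <- rnorm(30); y <- 0.3 + 0.9 * x + rnorm(30, 0, 0.2)
  f2 <- fit_ols(x, y)
  ab <- oracle_ols(x, y)
  expect_equal(c(f2$intercept, f2$slope), ab, tolerance = 1e-10)
  expect_equal(f2$aic, 6 - 2 * f2$loglik)
  expect_true(f2$intercept_ci[1] <= f2$intercept &&
              f2$intercept <= f2$intercept_ci[2])
  # loglik equals the closed-form Gaussian ML value
  rss <- sum((y - ab[1] - ab[2] * x)^2)
  expect_equal(f2$loglik, -0.5 * (30 * log(2 * pi * rss / 30) + 30),
               tolerance = 1e-10)

  expect_error(fit_ols(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(fit_ols(1:2, 1:2), "at least 3")
})

test_that("bm_covariance reproduces shared path lengths", {
  # star tree: no shared history off the diagonal
  star <- ape::read.tree(text = "(a:2,b:2,c:2,d:2);")
  V <- bm_covariance(star, c("a", "b", "c", "d"))
  expect_equal(unname(V), diag(2, 4), tolerance = 1e-12)

  # two-tip cherry with zero stem
  two <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(unname(bm_covariance(two, c("a", "b"))), diag(1, 2))

  # balanced 4-tip, all branches 1: sisters share 1
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  V4 <- bm_covariance(bal, c("a", "b", "c", "d"))
  expect_equal(unname(V4),
               matrix(c(2, 1, 0, 0, 1, 2, 0, 0,
                        0, 0, 2, 1, 0, 0, 1, 2), 4), tolerance = 1e-12)

  # ordering respected; random trees match the edge-walking oracle
  expect_equal(unname(bm_covariance(bal, c("c", "a", "d", "b"))),
               unname(oracle_bm_vcv(bal, c("c", "a", "d", "b"))))
  tr <- simulate_tree(12, seed = 5)
  sp <- sample(tr$tip.label)
  expect_equal(bm_covariance(tr, sp), oracle_bm_vcv(tr, sp),
               tolerance = 1e-12)

  expect_error(bm_covariance(bal, c("a", "zz")), "zz")
})

test_that("PGLS on a star tree degenerates to OLS", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1,f:1,g:1,h:1);")
  set.seed(8)
  x <- rnorm(8); y <- 0.5 + 1.2 * x + rnorm(8, 0, 0.3)
  ols <- fit_ols(x, y)
  pgls <- fit_pgls_bm(x, y, star, letters[1:8])
  expect_equal(pgls$intercept, ols$intercept, tolerance = 1e-10)
  expect_equal(pgls$slope, ols$slope, tolerance = 1e-10)
  expect_equal(pgls$loglik, ols$loglik, tolerance = 1e-10)
  expect_equal(pgls$aic, ols$aic, tolerance = 1e-10)
  expect_equal(pgls$intercept_ci, ols$intercept_ci, tolerance = 1e-10)
  # star tree with depth T: V = T I; loglik must still match OLS? No --
  # scaling V changes the ML sigma2 but not the maximized likelihood
  star2 <- ape::read.tree(text = "(a:5,b:5,c:5,d:5,e:5,f:5,g:5,h:5);")
  pgls2 <- fit_pgls_bm(x, y, star2, letters[1:8])
  expect_equal(pgls2$loglik, ols$loglik, tolerance = 1e-10)
  expect_equal(pgls2$slope, ols$slope, tolerance = 1e-10)
})

test_that("PGLS slope recovery on a known Brownian world", {
  tr <- simulate_tree(32, seed = 42)
  set.seed(99)
  x <- runif(32, -1, 2)
  hit <- 0L
  for (r in 1:50) {
    y <- 0.3 + 0.9 * x + simulate_bm(tr, 0.5, seed = 1000L + r)
    f <- fit_pgls_bm(x, y, tr, tr$tip.label)
    if (f$slope_ci[1] <= 0.9 && 0.9 <= f$slope_ci[2]) hit <- hit + 1L
  }
  expect_gte(hit, 43L)  # nominal 95% coverage; 43/50 is ~3 sd below
})

test_that("select_model picks the lower AIC and breaks ties to OLS", {
  mk <- function(aic, method) structure(
    list(method = method, aic = aic, n = 10L), class = "regression_fit")
  expect_equal(select_model(mk(10, "OLS"), mk(12, "PGLS-BM"))$method, "OLS")
  expect_equal(select_model(mk(12, "OLS"), mk(10, "PGLS-BM"))$method,
               "PGLS-BM")
  expect_equal(select_model(mk(10, "OLS"), mk(10, "PGLS-BM"))$method, "OLS")
  bad <- mk(10, "PGLS-BM"); bad$n <- 9L
  expect_error(select_model(mk(10, "OLS"), bad), "same data")
})

test_that("LOOCV hat-matrix shortcut equals explicit refits", {
  set.seed(12)
  x <- rnorm(20); y <- 1 + 2 * x + rnorm(20, 0, 0.5)
  expect_equal(loocv_rmse(x, y), oracle_loocv(x, y), tolerance = 1e-10)

  # perfectly collinear data predict perfectly
  expect_equal(loocv_rmse(1:5, 2 + 3 * (1:5)), 0, tolerance = 1e-10)
  expect_gte(loocv_rmse(x, y), 0)
  expect_error(loocv_rmse(1:3, 1:3), "at least 4")
})

test_that("build_calibration recovers known coefficients and handles sides", {
  cfg <- simulation_config(n_species = 30, seed = 2, segments = "thigh",
                           parameters = c("mass", "cm_y"), noise_sd = 0)
  ds <- generate_paired_dataset(cfg)
  fit <- build_calibration(ds)
  truth <- attr(ds, "truth")
  m <- fit$table$models[["thigh|mass"]]
  expect_equal(m$intercept,
               truth$intercept[truth$parameter == "mass"], tolerance = 1e-10)
  expect_equal(m$slope, truth$slope[truth$parameter == "mass"],
               tolerance = 1e-10)
  expect_equal(m$method, "OLS")
  expect_equal(fit$report$chosen, rep("OLS", 2))

  # noisy recovery within 2 SE
  cfg2 <- simulation_config(n_species = 30, seed = 3, segments = "arm",
                            parameters = "mass", noise_sd = 0.05)
  ds2 <- generate_paired_dataset(cfg2)
  fit2 <- build_calibration(ds2)
  m2 <- fit2$table$models[["arm|mass"]]
  se <- diff(m2$slope_ci) / (2 * qt(0.975, m2$n - 2))
  truth2 <- attr(ds2, "truth")
  expect_lt(abs(m2$slope - truth2$slope), 2 * se)

  # right-side rows are folded by mirroring before the fit
  ds_r <- ds[ds$parameter == "cm_y", ]
  ds_r$side <- "right"
  ds_r$hull_value <- -ds_r$hull_value
  ds_r$soft_value <- -ds_r$soft_value
  fit_r <- build_calibration(ds_r)
  expect_equal(fit_r$table$models[["thigh|cm_y"]]$slope,
               fit$table$models[["thigh|cm_y"]]$slope, tolerance = 1e-10)
  expect_equal(fit_r$table$models[["thigh|cm_y"]]$intercept,
               fit$table$models[["thigh|cm_y"]]$intercept, tolerance = 1e-10)
})

test_that("a fully populated dataset yields 130 models, OLS without a tree", {
  cfg <- simulation_config(n_species = 8, seed = 4, noise_sd = 0.01)
  ds <- generate_paired_dataset(cfg)
  fit <- build_calibration(ds)
  expect_length(fit$table$models, 130L)
  expect_true(all(fit$report$chosen == "OLS"))
  expect_true(all(is.na(fit$report$aic_pgls)))
})

test_that("build_calibration with a tree selects by AIC per cell", {
  tr <- simulate_tree(24, seed = 9)
  cfg <- simulation_config(seed = 10, segments = "head",
                           parameters = "mass", noise_sd = 0.3,
                           noise_mode = "brownian")
  ds <- generate_paired_dataset(cfg, tr)
  fit <- build_calibration(ds, tr)
  expect_false(is.na(fit$report$aic_pgls))
  expect_equal(fit$report$chosen,
               ifelse(fit$report$aic_pgls < fit$report$aic_ols - 1e-9,
                      "PGLS-BM", "OLS"))

  # pruning: drop some species from the dataset but not the tree
  ds_sub <- paired_dataset(ds[1:15, ])
  fit_sub <- build_calibration(ds_sub, tr)
  expect_equal(fit_sub$table$models[["head|mass"]]$n, 15L)
})

test_that("paired dataset validation catches structural problems", {
  ds <- data.frame(species = "sp1", segment = "thigh", side = "left",
                   parameter = "mass", hull_value = 1, soft_value = 2)
  expect_s3_class(paired_dataset(ds), "paired_dataset")
  expect_error(paired_dataset(ds[, -1]), "lacks columns")
  expect_error(paired_dataset(rbind(ds, ds)), "duplicate")
  bad <- ds; bad$segment <- "wing"
  expect_error(paired_dataset(bad), "unknown segments")
  expect_error(build_calibration(ds), "at least 3")
})
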