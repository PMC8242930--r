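# segment taxonomy, bundled table, prediction and mirroring

test_that("segment and parameter vocabularies are complete", {
  expect_length(segment_names(), 13L)
  expect_length(parameter_names(), 10L)
  expect_equal(parameter_transform("mass"), "log10")
  expect_equal(parameter_transform("ixx"), "log10")
  expect_equal(parameter_transform("cm_y"), "linear")
  expect_equal(parameter_transform("ixy"), "linear")

  expect_error(segment_label("torso", "left"), "cannot have a side")
  expect_error(segment_label("thigh", "none"), "needs side")
  expect_equal(segment_label("thigh", "left")$class, "appendicular")
  expect_equal(segment_label("tail2")$class, "axial")
})

test_that("bundled table has 130 models with the printed coefficients", {
  tab <- load_bundled_table()
  expect_length(tab$models, 130L)
  keys <- names(tab$models)
  for (seg in segment_names())
    for (par in parameter_names())
      expect_true(paste(seg, par, sep = "|") %in% keys)

  thigh_mass <- tab$models[["thigh|mass"]]
  expect_equal(thigh_mass$intercept, 0.549)
  expect_equal(thigh_mass$slope, 0.94)
  expect_equal(thigh_mass$transform, "log10")

  head_mass <- tab$models[["head|mass"]]
  expect_equal(head_mass$intercept, 0.106)
  expect_equal(head_mass$slope, 0.93)

  arm_mass <- tab$models[["arm|mass"]]
  expect_equal(arm_mass$slope, 0.88)
  expect_equal(arm_mass$intercept_ci, c(0.1833, 0.4264))
  expect_equal(arm_mass$slope_ci, c(0.82, 0.94))

  # transform rule holds for every entry; CIs bracket the estimates
  for (m in tab$models) {
    expect_equal(m$transform, parameter_transform(m$parameter))
    expect_true(m$slope_ci[1] <= m$slope + 1e-9 &&
                m$slope + 1e-9 >= m$slope_ci[1])
    expect_true(m$intercept >= m$intercept_ci[1] - 1e-9 &&
                m$intercept <= m$intercept_ci[2] + 1e-9)
  }
})

test_that("predict_parameter applies the stated transform", {
  thigh_mass <- load_bundled_table()$models[["thigh|mass"]]
  expect_equal(predict_parameter(1, thigh_mass), 10^0.549, tolerance = 1e-12)

  arm_mass <- load_bundled_table()$models[["arm|mass"]]
  # frozen from independent arithmetic: 10^(0.305 + 0.88*log10(2))
  expect_equal(predict_parameter(2, arm_mass), 3.714552, tolerance = 1e-6)

  ident <- calibration_model("torso", "cm_x", 0, 1)
  expect_equal(predict_parameter(c(-0.5, 0, 2), ident), c(-0.5, 0, 2))

  expect_error(predict_parameter(-1, thigh_mass), "positive")
  # monotonicity of log10 models with b > 0
  xs <- c(0.01, 0.1, 1, 10, 100)
  expect_true(all(diff(predict_parameter(xs, thigh_mass)) > 0))
})

test_that("mirror_model reverses only the antisymmetric intercepts", {
  m <- calibration_model(segment_label("thigh", "left"), "cm_y", 1.55e-3, 0.97)
  r <- mirror_model(m)
  expect_equal(r$intercept, -1.55e-3)
  expect_equal(r$slope, 0.97)
  expect_equal(r$segment$side, "right")
  expect_equal(mirror_model(r)$intercept, m$intercept)

  mm <- calibration_model(segment_label("arm", "left"), "mass", 0.305, 0.88)
  rm_ <- mirror_model(mm)
  expect_equal(rm_$intercept, 0.305)
  expect_equal(rm_$segment$side, "right")

  ax <- calibration_model("neck", "cm_y", 1e-3, 1)
  expect_error(mirror_model(ax), "axial")
})

test_that("mirror_bsp is an involution that flips cm_y, ixy, iyz", {
  b <- bsp(10, c(0.1, 0.2, 0.3), c(1, 2, 3), c(0.1, 0.2, 0.3))
  mb <- mirror_bsp(b)
  expect_equal(mb$com[["y"]], -0.2)
  expect_equal(mb$products[["ixy"]], -0.1)
  expect_equal(mb$products[["ixz"]], 0.2)
  expect_equal(mb$products[["iyz"]], -0.3)
  expect_equal(mirror_bsp(mb), b)

  sym <- bsp(10, c(0.1, 0, 0.3), c(1, 2, 3), c(0, 0.2, 0))
  expect_equal(mirror_bsp(sym), sym)
})

test_that("predict_segment converts all ten parameters and mirrors sides", {
  tab <- load_bundled_table()
  hull <- bsp(2, c(0.05, 0.01, -0.03), c(0.004, 0.005, 0.006),
              c(2e-4, -1e-4, 5e-5))
  left <- predict_segment(hull, segment_label("thigh", "left"), tab)
  expect_equal(left$mass, predict_parameter(2, tab$models[["thigh|mass"]]))
  expect_equal(left$com[["x"]],
               predict_parameter(0.05, tab$models[["thigh|cm_x"]]))
  expect_equal(left$products[["ixz"]],
               predict_parameter(-1e-4, tab$models[["thigh|ixz"]]))

  # mirror consistency: right prediction == mirror(left(mirror(hull)))
  right <- predict_segment(hull, segment_label("thigh", "right"), tab)
  via_mirror <- mirror_bsp(predict_segment(mirror_bsp(hull),
                                           segment_label("thigh", "left"),
                                           tab))
  expect_equal(right, via_mirror, tolerance = 1e-12)
})

test_that("identity table passes values through unchanged", {
  models <- lapply(parameter_names(), function(p)
    calibration_model("torso", p, 0, 1))
  tab <- calibration_table(models)
  hull <- bsp(5, c(0.2, 0.04, -0.1), c(0.5, 0.6, 0.7), c(0.01, -0.02, 0.03))
  out <- predict_segment(hull, "torso", tab)
  expect_equal(out, hull, tolerance = 1e-12)
})

test_that("zero_axial forces cm_y, ixy, iyz to exactly zero (axial only)", {
  tab <- load_bundled_table()
  hull <- bsp(5, c(0.2, 0.04, -0.1), c(0.5, 0.6, 0.7), c(0.01, -0.02, 0.03))
  out <- predict_segment(hull, "torso", tab, zero_axial = TRUE)
  expect_identical(out$com[["y"]], 0)
  expect_identical(out$products[["ixy"]], 0)
  expect_identical(out$products[["iyz"]], 0)
  expect_false(out$products[["ixz"]] == 0)

  limb <- predict_segment(hull, segment_label("thigh", "left"), tab,
                          zero_axial = TRUE)
  expect_false(limb$com[["y"]] == 0)
})

test_that("extrapolation and density mismatches warn", {
  tab <- load_bundled_table()
  big <- bsp(5000, c(1, 0.1, 0.5), c(100, 120, 130), c(1, -2, 0.5))
  expect_warning(predict_segment(big, "torso", tab), "extrapolation")
  odd <- bsp(5, c(0.2, 0.04, -0.1), c(0.5, 0.6, 0.7), c(0.01, -0.02, 0.03),
             density = 900)
  expect_warning(predict_segment(odd, "torso", tab), "1000")
})

test_that("calibration CSV round-trips through write/read", {
  tab <- load_bundled_table()
  p <- file.path(tempdir(), "cal.csv")
  write_calibration_csv(tab, p)
  back <- read_calibration_csv(p)
  expect_length(back$models, 130L)
  for (key in c("thigh|mass", "neck|ixy", "tail4|cm_x")) {
    expect_equal(back$models[[key]]$intercept, tab$models[[key]]$intercept)
    expect_equal(back$models[[key]]$slope_ci, tab$models[[key]]$slope_ci)
  }
})

test_that("missing models are reported, not silently filled", {
  tab <- calibration_table(list(calibration_model("torso", "mass", 0.1, 0.9)))
  hull <- bsp(5, c(0.2, 0.04, -0.1), c(0.5, 0.6, 0.7), c(0.01, -0.02, 0.03))
  expect_error(predict_segment(hull, "torso", tab), "no calibration model")
})
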