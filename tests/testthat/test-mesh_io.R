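# mesh construction, validation, format round trips

test_that("generator fixtures are valid and have closed-form volumes", {
  cube <- make_box(c(1, 1, 1), c(0.5, 0.5, 0.5))
  expect_equal(mesh_volume(cube), 1)
  expect_equal(nrow(cube$vertices), 8L)
  expect_equal(nrow(cube$faces), 12L)

  box <- make_box(c(2, 1, 1))
  expect_equal(mesh_volume(box), 2)

  for (m in list(cube, box, make_icosphere(0.5, 2), make_prism(1, cbind(
    c(0.2, -0.2, -0.2, 0.2), c(0.2, 0.2, -0.2, -0.2)), "y"))) {
    v <- validate_mesh(m)
    expect_true(v$ok)
  }

  expect_error(make_box(c(1, 0, 1)), "positive")
  expect_error(make_icosphere(-1), "positive")
  expect_error(make_prism(0, cbind(c(0, 1, 0), c(0, 0, 1))), "positive")
})

test_that("icosphere volume converges to the analytic sphere", {
  # error shrinks roughly 4x per level; level 4 is within 0.3%
  errs <- vapply(2:4, function(s)
    abs(mesh_volume(make_icosphere(1, s)) - 4 / 3 * pi) / (4 / 3 * pi), 0)
  expect_lt(errs[3], 0.003)
  expect_true(all(diff(errs) < 0))
})

test_that("prism volume equals cross-section area times length on all axes", {
  ang <- seq(0, 2 * pi, length.out = 7L)[-7L]
  hexa <- cbind(0.3 * cos(ang), 0.3 * sin(ang))
  area <- 6 * (0.3^2 * sqrt(3) / 4)
  for (ax in c("x", "y", "z")) {
    p <- make_prism(2, hexa, ax)
    expect_equal(mesh_volume(p), 2 * area, tolerance = 1e-12)
    expect_true(validate_mesh(p)$ok)
    # extrusion axis has the 2 m extent
    ext <- apply(p$vertices, 2, function(v) diff(range(v)))
    expect_equal(which.max(ext), match(ax, c("x", "y", "z")),
                 ignore_attr = TRUE)
  }
})

test_that("validate_mesh flags broken meshes independently", {
  cube <- make_box(c(1, 1, 1))
  expect_true(validate_mesh(cube)$ok)

  open_ <- triangle_mesh(cube$vertices, cube$faces[-1L, ])
  vo <- validate_mesh(open_)
  expect_false(vo$watertight)

  inverted <- triangle_mesh(cube$vertices, cube$faces[, c(1, 3, 2)])
  vi <- validate_mesh(inverted)
  expect_true(vi$watertight)
  expect_false(vi$positive_volume)
  expect_equal(vi$signed_volume, -1)

  mixed <- cube
  mixed$faces[1L, ] <- mixed$faces[1L, c(1, 3, 2)]
  expect_false(validate_mesh(mixed)$consistently_oriented)

  degen <- triangle_mesh(rbind(cube$vertices, cube$vertices[1, ]),
                         rbind(cube$faces, c(1L, 1L, 9L)))
  expect_true(length(validate_mesh(degen)$degenerate_faces) > 0)
})

test_that("round trips preserve geometry across formats", {
  mesh <- make_icosphere(0.37, 2, center = c(0.1, -0.2, 0.05))
  v0 <- mesh_volume(mesh)
  for (fmt in c("obj", "ply")) {
    path <- file.path(tempdir(), paste0("rt.", fmt))
    write_mesh(mesh, path)
    back <- read_mesh(path)
    expect_identical(back$vertices, mesh$vertices)  # 17 digits: bit-exact
    expect_equal(nrow(back$faces), nrow(mesh$faces))
    expect_equal(mesh_volume(back), v0)
  }
  # binary STL stores float32: use float-exact coordinates for exactness
  q <- make_box(c(0.5, 0.25, 1), c(0.25, -0.5, 0.125))
  path <- file.path(tempdir(), "rt.stl")
  write_mesh(q, path)
  back <- read_mesh(path)
  expect_equal(nrow(back$vertices), 8L)  # welded from 36 records
  expect_equal(mesh_volume(back), mesh_volume(q), tolerance = 1e-12)
  # a general mesh round-trips within float32 precision
  write_mesh(mesh, path)
  expect_equal(mesh_volume(read_mesh(path)), v0, tolerance = 1e-6)
})

test_that("OBJ quads are fan-triangulated with exact volume", {
  path <- file.path(tempdir(), "quad.obj")
  writeLines(c(
    "v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
    "v 0 0 1", "v 1 0 1", "v 1 1 1", "v 0 1 1",
    "f 4 3 2 1", "f 5 6 7 8", "f 1 2 6 5",
    "f 2 3 7 6", "f 3 4 8 7", "f 4 1 5 8"), path)
  mesh <- read_mesh(path)
  expect_equal(nrow(mesh$faces), 12L)
  expect_equal(mesh_volume(mesh), 1)
  expect_true(validate_mesh(mesh)$ok)
})

test_that("malformed inputs give informative format errors", {
  p <- file.path(tempdir(), "bad.obj")
  writeLines(c("v 0 0 0", "v 1 0", "f 1 2 3"), p)
  expect_error(read_mesh(p), "line 2")

  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0"), p)
  expect_error(read_mesh(p), "no faces")

  # truncated binary STL: header claims more facets than the file holds
  cube <- make_box(c(1, 1, 1))
  ps <- file.path(tempdir(), "trunc.stl")
  write_mesh(cube, ps)
  sz <- file.size(ps)
  raw_ <- readBin(ps, "raw", sz)
  writeBin(raw_[1:(sz - 50L)], ps)
  con <- file(ps, "r+b"); seek(con, 80L)
  writeBin(12L, con, size = 4L, endian = "little"); close(con)
  expect_error(read_mesh(ps), "STL parse error")

  pp <- file.path(tempdir(), "bad.ply")
  writeLines(c("ply", "format ascii 1.0", "end_header"), pp)
  expect_error(read_mesh(pp), "PLY parse error")

  expect_error(read_mesh(file.path(tempdir(), "nope.obj")), "not found")
})

test_that("write_mesh refuses invalid meshes", {
  cube <- make_box(c(1, 1, 1))
  open_ <- triangle_mesh(cube$vertices, cube$faces[-1L, ])
  expect_error(write_mesh(open_, file.path(tempdir(), "x.obj")), "invalid")
})

test_that("globally inverted meshes are flipped at the read boundary", {
  cube <- make_box(c(1, 1, 1))
  p <- file.path(tempdir(), "inv.obj")
  writeLines(c(sprintf("v %g %g %g", cube$vertices[, 1], cube$vertices[, 2],
                       cube$vertices[, 3]),
               sprintf("f %d %d %d", cube$faces[, 1], cube$faces[, 3],
                       cube$faces[, 2])), p)
  back <- read_mesh(p)
  expect_gt(mesh_volume(back), 0)
})

test_that("ascii STL reads and welds", {
  cube <- make_box(c(1, 2, 3))
  p <- file.path(tempdir(), "a.stl")
  v <- cube$vertices; f <- cube$faces
  lines <- c("solid fixture")
  for (k in seq_len(nrow(f))) {
    lines <- c(lines, "facet normal 0 0 0", "outer loop",
               sprintf("vertex %.17g %.17g %.17g",
                       v[f[k, ], 1], v[f[k, ], 2], v[f[k, ], 3]),
               "endloop", "endfacet")
  }
  writeLines(c(lines, "endsolid fixture"), p)
  back <- read_mesh(p)
  expect_equal(nrow(back$vertices), 8L)
  expect_equal(mesh_volume(back), 6)
})
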