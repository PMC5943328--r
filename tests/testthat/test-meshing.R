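test_that("a linear ramp yields a planar isosurface of the expected area", {
  for (n in c(32, 64)) {
    vol <- sample_grid(ramp_field(0.5), unit_domain(n))
    mesh <- extract_isosurface(vol, 0)
    # the open surface spans the voxel-center cross-section
    expect_equal(mesh_area(mesh), ((n - 1) / n)^2, tolerance = 1e-9)
    expect_equal(range(mesh$vertices[, 1]), c(0.5, 0.5), tolerance = 1e-12)
  }
})

test_that("sphere mesh area converges to 4 pi R^2", {
  R <- 0.3
  errs <- vapply(c(32, 64), function(n) {
    mesh <- extract_isosurface(sample_grid(sphere_field(R), unit_domain(n)), 0)
    abs(mesh_area(mesh) - 4 * pi * R^2) / (4 * pi * R^2)
  }, numeric(1))
  expect_lt(errs[2], 0.02)      # within 2 percent at 64^3
  expect_lt(errs[2], errs[1])   # refinement reduces the error
})

test_that("degenerate volumes give empty meshes", {
  const <- voxel_volume(array(1, c(4, 4, 4)), spacing = 0.1)
  expect_warning(m <- extract_isosurface(const, 1), "constant")
  expect_equal(nrow(m$faces), 0L)
  vol <- sample_grid(sphere_field(0.3), unit_domain(16))
  expect_equal(nrow(extract_isosurface(vol, 10)$faces), 0L)
  expect_equal(nrow(cap_boundary(vol, -10)$faces), 0L)
})

test_that("mesh vertices lie on the implicit surface up to interpolation error", {
  g <- tpms_preset("G")
  n <- 32
  vol <- sample_grid(g, unit_domain(n))
  mesh <- extract_isosurface(vol, 0)
  # |grad| of the gyroid field is at most 2*pi*sqrt(3)/cell_size; linear
  # interpolation keeps vertices within a voxel diagonal of the surface
  lip <- 2 * pi * sqrt(3)
  expect_lt(max(abs(eval_field(g, mesh$vertices))),
            lip * sqrt(3) / n / 2)
})

test_that("capped half-space and full solid recover their volumes", {
  vol <- sample_grid(ramp_field(0.5), unit_domain(32))
  half <- cap_boundary(vol, 0)
  expect_true(is_watertight(half))
  expect_equal(mesh_volume(half), 0.5, tolerance = 0.01)
  # a fully solid volume closes to the domain box; box edges are
  # chamfered at the half-voxel scale by the interpolating extraction,
  # so volume and area converge at O(h)
  solid <- voxel_volume(array(-1, c(16, 16, 16)), spacing = 1 / 16)
  box <- cap_boundary(solid, 0)
  expect_true(is_watertight(box))
  expect_equal(mesh_volume(box), 1, tolerance = 0.01)
  expect_equal(mesh_area(box), 6, tolerance = 0.03)
})

test_that("capped preset meshes are watertight and volume-consistent", {
  for (name in all_presets) {
    vol <- sample_grid(tpms_preset(name), unit_domain(32))
    mesh <- cap_boundary(vol, 0)
    expect_true(is_watertight(mesh), label = paste(name, "watertight"))
    vox <- mean(vol$values <= 0)
    expect_lt(abs(mesh_volume(mesh) - vox), 0.02,
              label = paste(name, "volume vs voxel count"))
  }
})

test_that("the P surface over one period has Euler characteristic -4", {
  for (n in c(32, 64)) {
    mesh <- extract_isosurface(sample_grid(tpms_preset("P"),
                                           unit_domain(n)), 0)
    expect_equal(euler_characteristic(mesh), -4L)
  }
})

test_that("capped meshes carry outward normals (positive enclosed volume)", {
  vol <- sample_grid(sphere_field(0.25), unit_domain(24))
  mesh <- cap_boundary(vol, 0)
  expect_gt(mesh_volume(mesh), 0)
  expect_equal(mesh_volume(mesh), 4 / 3 * pi * 0.25^3, tolerance = 0.02)
})

test_that("cap classification separates box faces from interior surface", {
  vol <- sample_grid(ramp_field(0.4), unit_domain(24))
  mesh <- cap_boundary(vol, 0)
  # the wide band also absorbs the chamfered box-edge strips
  caps <- cap_faces(mesh, vol, tol = 0.55)
  inner <- subset_mesh(mesh, !caps)
  # interior surface of the half-space is the plane x = 0.4 (a few cap
  # junction slivers may survive within half a voxel of it)
  expect_lt(max(abs(inner$vertices[, 1] - 0.4)), 0.55 / 24)
  expect_gt(mean(abs(inner$vertices[, 1] - 0.4) < 1e-9), 0.9)
  # full cross-section minus the excluded boundary band
  expect_equal(mesh_area(inner), 1, tolerance = 0.1)
})

test_that("STL binary and ASCII round trips preserve the mesh", {
  tri <- triangle_mesh(matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3,
                              byrow = TRUE), matrix(1:3, 1))
  for (mode in c("binary", "ascii")) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(tri, path, mode)
    back <- read_stl(path)
    expect_equal(nrow(back$faces), 1L)
    expect_equal(back$vertices[back$faces[1, ], ], tri$vertices,
                 ignore_attr = TRUE)
  }

  vol <- sample_grid(tpms_preset("G"), unit_domain(32))
  mesh <- cap_boundary(vol, 0)
  soup <- function(m) cbind(m$vertices[m$faces[, 1], ],
                            m$vertices[m$faces[, 2], ],
                            m$vertices[m$faces[, 3], ])
  for (mode in c("binary", "ascii")) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(mesh, path, mode)
    back <- read_stl(path)
    expect_equal(nrow(back$faces), nrow(mesh$faces))
    # single-precision storage: absolute error below 1e-6 on unit-box coords
    expect_lt(max(abs(soup(back) - soup(mesh))), 1e-6)
    expect_true(is_watertight(back))
  }
})

test_that("STL writer rejects empty meshes and reader flags bad files", {
  empty <- triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(write_stl(empty, tempfile()), "0 facets")
  # truncated binary file
  vol <- sample_grid(sphere_field(0.3), unit_domain(16))
  mesh <- cap_boundary(vol, 0)
  good <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, good)
  bad <- withr::local_tempfile(fileext = ".stl")
  bytes <- readBin(good, "raw", 500)
  writeBin(bytes, bad)
  expect_error(read_stl(bad), "mismatch|truncated")
})
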