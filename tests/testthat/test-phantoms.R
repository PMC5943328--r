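test_that("phantom voxelization matches analytic porosity", {
  for (n in c(32, 64)) {
    sl <- make_phantom("slab", res = n, thickness = 0.2)
    expect_equal(porosity(sl$volume), sl$truth$porosity, tolerance = 2 / n)
    cy <- make_phantom("cylinder", res = n, radius = 0.15)
    expect_equal(porosity(cy$volume), cy$truth$porosity, tolerance = 2 / n)
    sp <- make_phantom("sphere", res = n, radius = 0.3)
    expect_equal(porosity(sp$volume), sp$truth$porosity, tolerance = 2 / n)
  }
})

test_that("phantom truth records carry the ideal-shape morphometry", {
  sl <- make_phantom("slab", res = 16, thickness = 0.2)
  expect_equal(sl$truth$smi, 0)
  expect_equal(sl$truth$sad, 10)
  expect_equal(sl$truth$tt, 0.2)
  cy <- make_phantom("cylinder", res = 16, radius = 0.1)
  expect_equal(cy$truth$smi, 3)
  expect_equal(cy$truth$tt, 0.2)
  sp <- make_phantom("sphere", res = 16, radius = 0.25)
  expect_equal(sp$truth$smi, 4)
  expect_equal(sp$truth$sad, 12)
})

test_that("voxelization is by center inclusion", {
  # 4-voxel box, slab of thickness 0.5 centered: exactly the middle two
  # voxel centers (0.375, 0.625) are inside
  sl <- make_phantom("slab", res = 4, thickness = 0.5)
  expect_identical(sl$volume$mask[, 1, 1], c(FALSE, TRUE, TRUE, FALSE))
  # sphere of radius 0.3: the 8 centers nearest the middle are inside
  sp <- make_phantom("sphere", res = 4, radius = 0.3)
  expect_equal(sum(sp$volume$mask), 8)
})

test_that("phantom geometry must fit the domain", {
  expect_error(make_phantom("sphere", res = 16, radius = 0.6), "fit")
  expect_error(make_phantom("cylinder", res = 16, radius = 0.7), "fit")
  expect_error(make_phantom("slab", res = 16, thickness = 2), "thickness")
})

test_that("grayscale rendering is exact without blur and noise", {
  ph <- make_phantom("cylinder", res = 24, radius = 0.2)
  gray <- render_grayscale(ph$volume, fg = 80, bg = 20)
  rec <- segment(gray, threshold = 50)
  expect_identical(rec$mask, ph$volume$mask)
})

test_that("rendering is deterministic in the seed and preserves RNG state", {
  ph <- make_phantom("slab", res = 24, thickness = 0.3)
  set.seed(99)
  before <- .Random.seed
  g1 <- render_grayscale(ph$volume, fg = 1, bg = 0, blur_sigma = 1,
                         noise_sd = 0.05, seed = 5)
  expect_identical(.Random.seed, before)
  g2 <- render_grayscale(ph$volume, fg = 1, bg = 0, blur_sigma = 1,
                         noise_sd = 0.05, seed = 5)
  expect_identical(g1$values, g2$values)
  g3 <- render_grayscale(ph$volume, fg = 1, bg = 0, blur_sigma = 1,
                         noise_sd = 0.05, seed = 6)
  expect_false(identical(g1$values, g3$values))
})

test_that("noisy rendering still supports midpoint-threshold recovery", {
  ph <- make_phantom("slab", res = 48, thickness = 0.4)
  gray <- render_grayscale(ph$volume, fg = 1, bg = 0, blur_sigma = 1,
                           noise_sd = 0.05, seed = 3)
  rec <- segment(gray, 0.5)
  expect_equal(solid_fraction(rec), solid_fraction(ph$volume),
               tolerance = 0.02)
})

test_that("the gradient demo produces a printable graded scaffold", {
  demo <- make_gradient_demo(res = 16, report = TRUE)
  expect_true(is_watertight(demo$mesh))
  expect_gt(nrow(demo$mesh$faces), 1000)
  # porosity profile along the gradient axis: symmetric and non-constant
  cells <- colMeans(matrix(demo$profile$porosity, nrow = 16))
  expect_equal(cells[1], cells[3], tolerance = 1e-12)
  expect_gt(abs(cells[2] - cells[1]), 0.02)
  # the morphometry report is complete and finite
  expect_true(all(is.finite(unlist(demo$report))))
  # STL export round-trips
  stl <- withr::local_tempfile(fileext = ".stl")
  demo2 <- make_gradient_demo(res = 12, stl_path = stl)
  expect_equal(nrow(read_stl(stl)$faces), nrow(demo2$mesh$faces))
})

test_that("a demo built from identical units is periodic, not graded", {
  u <- tpms_preset("TGab")
  demo <- make_gradient_demo(res = 16, units = list(u, u, u))
  cells <- colMeans(matrix(demo$profile$porosity, nrow = 16))
  expect_lt(max(cells) - min(cells), 0.02)
  # slice-wise, the profile repeats with the unit-cell period
  prof <- demo$profile$porosity
  expect_equal(prof[1:16], prof[17:32], tolerance = 0.05)
})
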