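test_that("segmentation thresholds gray volumes as specified", {
  vals <- array(0, c(6, 6, 6))
  vals[2:4, , ] <- 100
  gray <- voxel_volume(vals, spacing = 0.1)
  bin <- segment(gray, 50)
  expect_identical(bin$mask, vals == 100)
  expect_warning(all_solid <- segment(gray, -5), "degenerate")
  expect_equal(porosity(all_solid), 0)
})

test_that("largest-component filtering drops disconnected islands", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:8, 2:8, 2:8] <- TRUE   # big block
  m[10, 10, 10] <- TRUE      # lone voxel
  gray <- voxel_volume(array(as.numeric(m), dim(m)), spacing = 0.1)
  bin <- segment(gray, 0.5, largest_component = TRUE)
  expect_equal(sum(bin$mask), 7^3)
  expect_false(bin$mask[10, 10, 10])
})

test_that("porosity is the pore fraction and complements solid fraction", {
  empty <- binary_volume(array(FALSE, c(4, 4, 4)), spacing = 1)
  expect_equal(porosity(empty), 1)
  slab <- make_phantom("slab", res = 32, thickness = 0.5)$volume
  expect_equal(porosity(slab), 0.5, tolerance = 1 / 32)
  expect_equal(porosity(slab) + solid_fraction(slab), 1)
})

test_that("segmenting a rendered phantom recovers the true solid fraction", {
  ph <- make_phantom("slab", res = 48, thickness = 0.3)
  gray <- render_grayscale(ph$volume, fg = 100, bg = 10, blur_sigma = 1,
                           noise_sd = 4.5, seed = 7)
  rec <- segment(gray, threshold = 55)
  expect_equal(solid_fraction(rec), solid_fraction(ph$volume),
               tolerance = 0.02)
})

test_that("local thickness recovers plate and gap widths within a voxel", {
  n <- 64
  h <- 1 / n
  slab <- make_phantom("slab", res = n, thickness = 0.2)
  tt <- local_thickness(slab$volume, "solid")
  expect_equal(tt$mean, slab$truth$tt, tolerance = h / slab$truth$tt)
  arr <- make_phantom("slab_array", res = n, thickness = 0.25, gap = 0.25)
  expect_equal(local_thickness(arr$volume, "solid")$mean, 0.25,
               tolerance = h / 0.25)
  expect_equal(local_thickness(arr$volume, "pore")$mean, 0.25,
               tolerance = h / 0.25)
})

test_that("local thickness of a spanning rod approaches its diameter", {
  n <- 96
  cyl <- make_phantom("cylinder", res = n, radius = 0.1)
  tt <- local_thickness(cyl$volume, "solid")
  # curved digitized surfaces carry a shell deficit of up to ~2 voxels
  expect_equal(tt$mean, 0.2, tolerance = 2.5 / (n * 0.2))
  expect_equal(max(tt$map$values), 0.2, tolerance = 2 / (n * 0.2))
})

test_that("pore thickness equals solid thickness of the inverted mask", {
  arr <- make_phantom("slab_array", res = 32, thickness = 0.25,
                      gap = 0.25)$volume
  inv <- binary_volume(!arr$mask, spacing = arr$spacing,
                       origin = arr$origin)
  a <- local_thickness(arr, "pore")
  b <- local_thickness(inv, "solid")
  expect_identical(a$map$values, b$map$values)
})

test_that("thickness metrics require a non-empty phase and isotropic voxels", {
  full <- binary_volume(array(TRUE, c(6, 6, 6)), spacing = 0.1)
  expect_error(local_thickness(full, "pore"), "empty")
  aniso <- binary_volume(array(TRUE, c(6, 6, 6)), spacing = c(0.1, 0.1, 0.2))
  expect_error(local_thickness(aniso), "isotropic")
})

test_that("surface area density matches analytic phantoms", {
  n <- 96
  slab <- make_phantom("slab", res = n, thickness = 0.2)
  # discrete slab thickness is a whole number of voxels
  t_vox <- mean(slab$volume$mask) * 1
  expect_equal(surface_area_density(slab$volume)$sad, 2 / t_vox,
               tolerance = 0.03)
  sph <- make_phantom("sphere", res = n, radius = 0.3)
  expect_equal(surface_area_density(sph$volume)$sad, 3 / 0.3,
               tolerance = 0.05)
  cyl <- make_phantom("cylinder", res = n, radius = 0.1)
  expect_equal(surface_area_density(cyl$volume)$sad, 2 / 0.1,
               tolerance = 0.05)
})

test_that("a volume-filling solid has zero SAD (all surface is cap)", {
  full <- binary_volume(array(TRUE, c(12, 12, 12)), spacing = 0.1)
  expect_equal(surface_area_density(full)$sad, 0)
  none <- binary_volume(array(FALSE, c(12, 12, 12)), spacing = 0.1)
  expect_error(surface_area_density(none), "no solid")
  expect_error(smi(full), "caps only")
})

test_that("SMI separates plates, rods and spheres", {
  n <- 96
  slab <- make_phantom("slab", res = n, thickness = 0.2)
  expect_equal(smi(slab$volume)$smi, 0, tolerance = 0.05)
  sph <- make_phantom("sphere", res = n, radius = 0.3)
  expect_equal(smi(sph$volume)$smi, 4, tolerance = 0.15)
  cyl <- make_phantom("cylinder", res = n, radius = 0.1)
  expect_equal(smi(cyl$volume)$smi, 3, tolerance = 0.25)
})

test_that("morphometry metrics scale correctly under uniform rescaling", {
  a <- make_phantom("cylinder", res = 64, box = 1, radius = 0.1)$volume
  b <- make_phantom("cylinder", res = 64, box = 2, radius = 0.2)$volume
  expect_equal(smi(b)$smi, smi(a)$smi, tolerance = 1e-9)
  expect_equal(surface_area_density(b)$sad,
               surface_area_density(a)$sad / 2, tolerance = 1e-9)
  expect_equal(local_thickness(b, "solid")$mean,
               2 * local_thickness(a, "solid")$mean, tolerance = 1e-9)
})

test_that("the full morphometry report is consistent and serializable", {
  gyr <- make_phantom("gyroid_block", res = 40)$volume
  rep <- morphometry_report(gyr)
  expect_equal(rep$porosity + rep$solid_fraction, 1)
  expect_true(all(is.finite(unlist(rep))))
  expect_gte(rep$tt_mean, 0)
  expect_gte(rep$sad, 0)
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rep, js)
  back <- jsonlite::read_json(js)
  expect_equal(back$porosity, rep$porosity)
  cs <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, cs)
  df <- read.csv(cs)
  expect_setequal(df$metric, names(rep))
})
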