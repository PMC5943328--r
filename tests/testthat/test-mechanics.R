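test_that("gray-to-density calibration is the affine map through both anchors", {
  gray <- voxel_volume(array(c(0, 127.5, 255, 51), c(2, 2, 1)),
                       spacing = 0.1)
  rho <- density_from_gray(gray, list(c(0, 0), c(255, 2)))
  expect_equal(rho$values[1, 1, 1], 0)
  expect_equal(rho$values[2, 1, 1], 1)      # midpoint gray -> 1 g/cm^3
  expect_equal(rho$values[1, 2, 1], 2)      # calibration point itself
  expect_equal(rho$values[2, 2, 1], 0.4)
  expect_error(density_from_gray(gray, list(c(10, 0), c(10, 2))), "differ")
  # negative extrapolation clamps with a warning
  gray2 <- voxel_volume(array(-50, c(2, 2, 2)), spacing = 0.1)
  expect_warning(rho2 <- density_from_gray(gray2, list(c(0, 0), c(255, 2))),
                 "clamped")
  expect_true(all(rho2$values == 0))
})

test_that("the density power law reproduces its printed constants", {
  expect_identical(modulus_from_density(1), 6850)
  expect_equal(modulus_from_density(2), 22219.03, tolerance = 1e-6)
  # the branch boundary takes the low-density branch
  expect_equal(modulus_from_density(1.68), 14838.89, tolerance = 1e-6)
  expect_gt(modulus_from_density(1.68), modulus_from_density(1.681))
  expect_identical(modulus_from_density(0), 0)
  expect_error(modulus_from_density(-0.1), "non-negative")
})

test_that("the air floor maps weak elements to exactly 0.01 MPa", {
  E <- c(0, 4.9, 5, 5.0001, 6, 6850)
  out <- apply_floor(E)
  expect_identical(out, c(0.01, 0.01, 0.01, 5.0001, 6, 6850))
  # conservation: exactly the weak voxels end up at the floor value
  set.seed(31)
  E2 <- runif(5000, 0, 100)
  E2 <- E2[abs(E2 - 0.01) > 1e-6]
  expect_identical(sum(apply_floor(E2) == 0.01), sum(E2 <= 5))
})

test_that("von Mises stress has its closed-form values", {
  expect_equal(von_mises_stress(c(7, 7, 7, 0, 0, 0)), 0)
  expect_equal(von_mises_stress(c(-13, 0, 0, 0, 0, 0)), 13)
  expect_equal(von_mises_stress(c(0, 0, 0, 3, 0, 0)), sqrt(3) * 3)
  expect_equal(von_mises_stress(c(0, 0, 0, 0, 0, 2)), sqrt(3) * 2)
  m <- cbind(c(1, 1, 1, 0, 0, 0), c(5, 0, 0, 0, 0, 0))
  expect_equal(von_mises_stress(m), c(0, 5))
})

test_that("a uniform block at zero Poisson ratio returns its own modulus", {
  E0 <- 1234
  mat <- material_field(array(E0, c(12, 12, 12)), nu = 0, spacing = 0.05)
  res <- homogenize(mat, load_case(2, strain = 0.01))
  expect_equal(res$E_app_MPa, E0, tolerance = 1e-3)
  expect_equal(res$mean_von_mises_MPa, 0.01 * E0, tolerance = 1e-3)
})

test_that("a two-layer series laminate returns the harmonic mean", {
  E <- array(1000, c(16, 16, 16))
  E[9:16, , ] <- 250
  mat <- material_field(E, nu = 0, spacing = 0.05)
  res <- homogenize(mat, load_case(1, strain = 0.01))
  expect_equal(res$E_app_MPa, 2 * 1000 * 250 / 1250, tolerance = 0.01)
})

test_that("strain-controlled response is linear in the moduli", {
  set.seed(32)
  E <- array(exp(runif(10^3, log(10), log(1000))), c(10, 10, 10))
  m1 <- material_field(E, nu = 0.3, spacing = 0.05)
  m2 <- material_field(3 * E, nu = 0.3, spacing = 0.05)
  r1 <- homogenize(m1, load_case(1))
  r2 <- homogenize(m2, load_case(1))
  expect_equal(r2$E_app_MPa / r1$E_app_MPa, 3, tolerance = 1e-5)
  expect_equal(r2$mean_von_mises_MPa / r1$mean_von_mises_MPa, 3,
               tolerance = 1e-5)
})

test_that("a cubically symmetric phantom is equally stiff in all directions", {
  ph <- make_phantom("sphere", res = 12, radius = 0.35)
  mat <- material_from_mask(ph$volume, E_solid = 1000, E_void = 1, nu = 0.3)
  e <- vapply(1:3, function(d) {
    homogenize(mat, load_case(d))$E_app_MPa
  }, numeric(1))
  expect_equal(e[2], e[1], tolerance = 1e-5)
  expect_equal(e[3], e[1], tolerance = 1e-5)
})

test_that("removing solid material never stiffens the scaffold", {
  g <- tpms_preset("G")
  vol <- sample_grid(g, unit_domain(16))
  e_app <- vapply(c(0.4, 0, -0.4), function(lev) {
    bin <- solidify(vol, lev)
    mat <- material_from_mask(bin, E_solid = 1000, E_void = 0.01, nu = 0.3)
    homogenize(mat, load_case(1))$E_app_MPa
  }, numeric(1))
  # level 0.4 mask is a superset of level 0, which is a superset of -0.4
  expect_true(all(diff(e_app) < 0))
})

test_that("homogenization rejects invalid inputs", {
  expect_error(load_case(4), "direction")
  expect_error(load_case(1, strain = 0.5), "strain")
  expect_error(material_field(array(0, c(8, 8, 8)), spacing = 0.1),
               "positive")
  small <- material_field(array(1, c(4, 4, 4)), spacing = 0.1)
  expect_error(homogenize(small), "8 voxels")
})
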