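test_that("sigmoid weight has the logistic contract", {
  expect_equal(sigmoid_weight(0, 1), 0.5)
  expect_equal(sigmoid_weight(0, 250), 0.5)
  # saturation: 20 decades of k g brings the weight within 2.1e-9 of 1
  for (k in c(0.5, 2, 30)) {
    expect_equal(sigmoid_weight(20 / k, k), 1 - 2.061154e-9,
                 tolerance = 1e-6)
  }
  # antisymmetry
  g <- seq(-4, 4, by = 0.37)
  expect_equal(sigmoid_weight(-g, 3), 1 - sigmoid_weight(g, 3))
  # strictly increasing
  expect_true(all(diff(sigmoid_weight(g, 1.2)) > 0))
  expect_error(sigmoid_weight(1, 0), "positive")
  expect_error(sigmoid_weight(1, -2), "positive")
})

test_that("blending identical fields reproduces the field exactly", {
  p <- tpms_preset("P")
  set.seed(21)
  pts <- matrix(runif(90, -1, 2), ncol = 3)
  for (trans in list(
    transition_spec("plane", k = 3, normal = c(1, 2, -1), offset = 0.2),
    transition_spec("sphere", k = 40, center = c(0.5, 0, 0), c2 = 0.3)
  )) {
    bl <- blend_spec(p, p, trans)
    expect_lt(max(abs(blend_eval(bl, pts) - eval_field(p, pts))), 1e-12)
  }
})

test_that("on the transition boundary the blend is the arithmetic mean", {
  p <- tpms_preset("P")
  g <- tpms_preset("G")
  bl <- blend_spec(p, g, transition_spec("plane", k = 7, normal = c(1, 0, 0),
                                         offset = 0.31))
  pts <- cbind(0.31, runif(20), runif(20))
  expect_equal(blend_eval(bl, pts),
               (eval_field(p, pts) + eval_field(g, pts)) / 2,
               tolerance = 1e-12)
})

test_that("level constants are removed before blending", {
  p_hi <- set_level(tpms_preset("P"), 1.2)
  g <- tpms_preset("G")
  bl <- blend_spec(p_hi, g, transition_spec("plane", k = 8, offset = 0.5))
  # deep inside region 1 the blend approaches phi_1 - level_1, not phi_1
  far <- matrix(c(20, 0.1, 0.1), 1)
  expect_equal(blend_eval(bl, far), eval_field(p_hi, far) - 1.2,
               tolerance = 1e-6)
  expect_equal(field_level(bl), 0)
})

test_that("sigmoid tail bound holds away from the boundary", {
  p <- tpms_preset("P")
  g <- tpms_preset("G")
  k <- 10
  bl <- blend_spec(p, g, transition_spec("plane", k = k, offset = 0.5))
  pts <- cbind(seq(0.7, 2.5, by = 0.06), 0.37, 0.21)
  gap <- abs(blend_eval(bl, pts) - eval_field(p, pts))
  bound <- abs(eval_field(p, pts) - eval_field(g, pts)) *
    exp(-k * (pts[, 1] - 0.5))
  expect_true(all(gap <= bound + 1e-12))
})

test_that("as steepness grows the blend converges to the sign-selected field", {
  p <- tpms_preset("P")
  g <- tpms_preset("G")
  set.seed(22)
  pts <- matrix(runif(120), ncol = 3)
  off <- abs(pts[, 1] - 0.5) > 0.05 # stay off the boundary
  pts <- pts[off, , drop = FALSE]
  target <- ifelse(pts[, 1] > 0.5, eval_field(p, pts), eval_field(g, pts))
  errs <- vapply(c(10, 40, 160), function(k) {
    bl <- blend_spec(p, g, transition_spec("plane", k = k, offset = 0.5))
    max(abs(blend_eval(bl, pts) - target))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("the weight is monotone along a line crossing the boundary", {
  tr <- transition_spec("sphere", k = 6, center = c(0.5, 0.5, 0.5), c2 = 0.09)
  line <- cbind(seq(0.5, 1.5, by = 0.01), 0.5, 0.5)
  a <- sigmoid_weight(boundary_value(tr, line), tr$k)
  expect_true(all(diff(a) > 0))
  expect_equal(a[which.min(abs(line[, 1] - 0.8))], 0.5, tolerance = 0.01)
})

test_that("multi_blend cascades pairwise and degenerates correctly", {
  p <- tpms_preset("P")
  set.seed(23)
  pts <- matrix(runif(60), ncol = 3)
  expect_identical(multi_blend(list(list(field = p))), p)
  tr <- transition_spec("plane", k = 5, offset = 0.5)
  three <- multi_blend(list(
    list(field = p), list(field = p, transition = tr),
    list(field = p, transition = tr)
  ))
  expect_lt(max(abs(field_values(three, pts) - eval_field(p, pts))), 1e-12)
  expect_error(multi_blend(list()), "non-empty")
  expect_error(multi_blend(list(list(field = p), list(field = p))),
               "transition")
})

test_that("a TGab|TGc|TGab stack has a symmetric, non-constant porosity gradient", {
  demo <- make_gradient_demo(res = 16)
  prof <- demo$profile$porosity
  # cell-averaged porosity along the gradient axis
  cells <- colMeans(matrix(prof, nrow = 16))
  expect_equal(cells[1], cells[3], tolerance = 1e-12) # outer cells symmetric
  expect_gt(abs(cells[2] - cells[1]), 0.02)           # middle cell differs
})

test_that("blend specs survive a JSON round trip", {
  bl <- blend_spec(
    tpms_preset("TGab"),
    blend_spec(tpms_preset("TGc"), tpms_preset("G"),
               transition_spec("sphere", k = 9, center = c(1, 0, 0), c2 = 2)),
    transition_spec("quadric", k = 4, quad = c(1, 1, 0, 0, 0, 0),
                    lin = c(0, 0, -1), const = 0.2)
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_blend_json(bl, path)
  back <- read_blend_json(path)
  set.seed(24)
  pts <- matrix(runif(60, -1, 2), ncol = 3)
  expect_equal(blend_eval(back, pts), blend_eval(bl, pts))
})
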