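#' Fit the level constant to a target porosity
#'
#' The level constant is the natural wall-thickness dial of a nodal
#' TPMS: raising it grows the solid phase `{phi <= level}`. This routine
#' drives the voxel-measured porosity to a target by scalar bisection on
#' the level, after verifying that porosity is monotone over the
#' bracket (it is for all built-in presets). The field is sampled once
#' and re-thresholded per iterate, so the fit is deterministic and
#' cheap.
#'
#' @param spec a [field_spec()] (or any field-like object).
#' @param target target porosity in (0, 1).
#' @param dom a [domain()] to measure porosity on.
#' @param tolerance accepted |porosity - target|.
#' @param bounds level search interval; defaults to the sampled value
#'   range. Must bracket the target.
#' @param max_iter bisection cap.
#' @return list with `level`, `achieved` porosity and `iterations`.
#' @export
fit_level_to_porosity <- function(spec, target, dom,
                                  tolerance = 0.005, bounds = NULL,
                                  max_iter = 100L) {
  if (target <= 0 || target >= 1) stop("target porosity must be in (0, 1)")
  vol <- sample_grid(spec, dom)
  vals <- as.numeric(vol$values)
  por_at <- function(level) mean(vals > level)
  if (is.null(bounds)) {
    rng <- range(vals)
    pad <- 1e-9 * max(1, abs(rng))
    bounds <- c(rng[1] - pad, rng[2] + pad)
  }
  lo <- bounds[1]; hi <- bounds[2]
  p_lo <- por_at(lo); p_hi <- por_at(hi)
  # porosity decreases in the level constant (more solid as level rises)
  if (!((p_lo >= target && p_hi <= target))) {
    stop(sprintf(
      "bounds [%.4g, %.4g] give porosity [%.4g, %.4g]: target %.4g not bracketed; widen the bounds",
      lo, hi, p_hi, p_lo, target))
  }
  # monotonicity check on a coarse scan before bisecting
  scan <- seq(lo, hi, length.out = 9)
  pscan <- vapply(scan, por_at, numeric(1))
  if (any(diff(pscan) > 1e-12)) {
    warning("porosity not monotone over the bracket; bisection may land on one of several roots")
  }
  achieved <- NA_real_
  level <- NA_real_
  for (it in seq_len(max_iter)) {
    level <- (lo + hi) / 2
    achieved <- por_at(level)
    if (abs(achieved - target) <= tolerance) break
    if (achieved > target) lo <- level else hi <- level
  }
  list(level = level, achieved = achieved, iterations = it)
}

#' Re-level or re-scale a field spec
#'
#' `set_level` returns the spec with a new level constant.
#' `scale_amplitudes` multiplies the amplitudes of all non-constant
#' terms by `s` (constant offset terms are left alone, so the scaling
#' thickens or thins the walls without moving the mean level).
#'
#' @param spec a [field_spec()].
#' @param level new level constant.
#' @return A [field_spec()].
#' @export
set_level <- function(spec, level) {
  stopifnot(inherits(spec, "field_spec"))
  spec$level <- as.numeric(level)
  spec
}

#' @rdname set_level
#' @param s amplitude scale factor, > 0.
#' @export
scale_amplitudes <- function(spec, s) {
  stopifnot(inherits(spec, "field_spec"))
  if (s <= 0) stop("amplitude scale must be positive")
  spec$terms <- lapply(spec$terms, function(t) {
    if (!all(t$kinds == "unity")) t$amplitude <- t$amplitude * s
    t
  })
  spec
}

#' Fit a structural parameter to a target apparent modulus
#'
#' Automates the manual matching loop in which the scaffold's structural
#' parameters are adjusted until its simulated apparent modulus matches
#' that of natural bone. One free parameter (the level constant or a
#' global amplitude scale) is searched by bisection; each candidate is
#' voxelized on `dom`, converted to a two-phase material (solid modulus
#' / air floor) and homogenized along `direction`. A coarse pre-scan
#' checks that the response is monotone over the bracket; if not, the
#' bracketing sub-interval is bisected with a warning.
#'
#' @param spec a [field_spec()].
#' @param target_E target apparent modulus (MPa).
#' @param bounds parameter search interval (must bracket the target
#'   response).
#' @param direction loading direction 1, 2 or 3.
#' @param parameter `"level"` or `"amplitude_scale"`.
#' @param dom fitting [domain()]; keep it modest (e.g. 32^3), the solver
#'   runs once per iterate.
#' @param E_solid,E_void,nu material model passed to
#'   [material_from_mask()].
#' @param strain applied compressive strain.
#' @param tol_rel accepted |E_app - target| / target.
#' @param max_iter bisection cap.
#' @param scan_points pre-scan size for the monotonicity check.
#' @param verbose print each iterate.
#' @return list with `parameter`, `value`, the adjusted `spec`,
#'   `E_app`, and the iteration `trace` (data.frame).
#' @export
fit_to_modulus <- function(spec, target_E, bounds, direction = 1,
                           parameter = c("level", "amplitude_scale"),
                           dom = NULL, E_solid = 6850, E_void = 0.01,
                           nu = 0.3, strain = 0.01, tol_rel = 0.02,
                           max_iter = 40L, scan_points = 5L,
                           verbose = FALSE) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(spec, "field_spec"))
  if (is.null(dom)) {
    a <- spec$cell_size
    dom <- domain(c(0, 0, 0), c(a, a, a), 32L)
  }
  apply_par <- function(value) {
    if (parameter == "level") set_level(spec, value) else
      scale_amplitudes(spec, value)
  }
  trace <- data.frame(value = numeric(0), E_app = numeric(0))
  measure <- function(value) {
    s2 <- apply_par(value)
    vol <- sample_grid(s2, dom)
    bin <- solidify(vol, level = s2$level)
    if (!any(bin$mask) || all(bin$mask)) {
      e <- if (all(bin$mask)) E_solid else E_void
    } else {
      mat <- material_from_mask(bin, E_solid, E_void, nu)
      e <- homogenize(mat, load_case(direction, strain))$E_app_MPa
    }
    trace[nrow(trace) + 1L, ] <<- c(value, e)
    if (verbose) message(sprintf("  %s = %.6g -> E_app = %.6g MPa",
                                 parameter, value, e))
    e
  }
  lo <- bounds[1]; hi <- bounds[2]
  scan <- seq(lo, hi, length.out = max(2L, scan_points))
  escan <- vapply(scan, measure, numeric(1))
  resid <- escan - target_E
  if (all(resid > 0) || all(resid < 0)) {
    stop(sprintf(
      "bounds [%.4g, %.4g] give E_app [%.5g, %.5g] MPa: target %.5g not bracketed",
      lo, hi, min(escan), max(escan), target_E))
  }
  if (any(diff(escan) * sign(escan[length(escan)] - escan[1]) < 0)) {
    warning("E_app response not monotone over the bracket; using the first bracketing sub-interval")
  }
  ib <- which(resid[-length(resid)] * resid[-1] <= 0)[1]
  lo <- scan[ib]; hi <- scan[ib + 1L]
  e_lo <- escan[ib]
  best <- list(value = lo, E_app = e_lo)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    e_mid <- measure(mid)
    if (abs(e_mid - target_E) < abs(best$E_app - target_E)) {
      best <- list(value = mid, E_app = e_mid)
    }
    if (abs(e_mid - target_E) <= tol_rel * target_E) break
    if ((e_mid - target_E) * (e_lo - target_E) <= 0) {
      hi <- mid
    } else {
      lo <- mid
      e_lo <- e_mid
    }
  }
  list(parameter = parameter, value = best$value,
       spec = apply_par(best$value), E_app = best$E_app, trace = trace)
}
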