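#' Map micro-CT gray values to apparent density
#'
#' Gray value and sample density are linearly related; the affine map is
#' anchored by two calibration references (e.g. a hydroxyapatite phantom
#' of known density and background). Densities extrapolating below zero
#' are clamped to 0 with a warning.
#'
#' @param gray a [voxel_volume()] of gray values.
#' @param calibration two `(gray, density)` reference pairs as a 2 x 2
#'   matrix or list of two length-2 vectors; densities in g/cm^3.
#' @return A [voxel_volume()] of densities (g/cm^3).
#' @export
density_from_gray <- function(gray, calibration) {
  stopifnot(inherits(gray, "voxel_volume"))
  cal <- if (is.list(calibration)) do.call(rbind, calibration) else
    as.matrix(calibration)
  if (!all(dim(cal) == c(2L, 2L))) {
    stop("`calibration` must supply two (gray, density) pairs")
  }
  g1 <- cal[1, 1]; d1 <- cal[1, 2]
  g2 <- cal[2, 1]; d2 <- cal[2, 2]
  if (g1 == g2) stop("calibration gray values must differ")
  slope <- (d2 - d1) / (g2 - g1)
  rho <- d1 + slope * (gray$values - g1)
  if (any(rho < 0)) {
    warning(sprintf("%d voxel(s) extrapolated below zero density: clamped",
                    sum(rho < 0)))
    rho[rho < 0] <- 0
  }
  voxel_volume(rho, spacing = gray$spacing, origin = gray$origin)
}

#' Cancellous-bone modulus from apparent density
#'
#' Piecewise power law relating elastic modulus (MPa) to apparent
#' density \eqn{\rho} (g/cm^3):
#' \deqn{E = 6850\,\rho^{1.49} \; (\rho \le 1.68), \qquad
#'       E = 4239\,\rho^{2.39} \; (\rho > 1.68).}
#' The branch boundary \eqn{\rho = 1.68} takes the first branch; the two
#' branches do not meet exactly there (14839 vs 14647 MPa), which is a
#' property of the published law and is implemented as printed.
#'
#' @param rho density in g/cm^3 (vector or array); must be >= 0.
#' @return modulus in MPa, same shape as `rho`.
#' @examples
#' modulus_from_density(1)   # 6850
#' @export
modulus_from_density <- function(rho) {
  if (any(rho < 0, na.rm = TRUE)) stop("density must be non-negative")
  E <- ifelse(rho <= 1.68, 6850 * rho^1.49, 4239 * rho^2.39)
  if (is.array(rho)) dim(E) <- dim(rho)
  E
}

#' Soft-tissue/air modulus floor
#'
#' Every element with modulus of 5 MPa or less is assigned 0.01 MPa
#' (close to air), which removes near-zero stiffnesses from the system
#' while keeping the mesh intact; all other values are unchanged.
#'
#' @param E modulus values (MPa), vector or array.
#' @param threshold inclusive cutoff (MPa).
#' @param floor value assigned below the cutoff (MPa).
#' @return modified modulus values.
#' @export
apply_floor <- function(E, threshold = 5, floor = 0.01) {
  E[E <= threshold] <- floor
  E
}

#' Per-voxel material field for homogenization
#'
#' @param E a [voxel_volume()] (or 3D array with `spacing`) of elastic
#'   moduli in MPa, strictly positive (apply [apply_floor()] first).
#' @param nu Poisson ratio shared by all voxels (default 0.3).
#' @param spacing voxel spacing in mm if `E` is a bare array.
#' @param rho optional density volume carried for reference.
#' @return An object of class `material_field`.
#' @export
material_field <- function(E, nu = 0.3, spacing = NULL, rho = NULL) {
  if (inherits(E, "voxel_volume")) {
    vol <- E
  } else {
    if (is.null(spacing)) stop("`spacing` required for a bare modulus array")
    vol <- voxel_volume(E, spacing = spacing)
  }
  if (any(vol$values <= 0)) stop("all moduli must be positive (apply the floor rule first)")
  if (nu < 0 || nu >= 0.5) stop("Poisson ratio must be in [0, 0.5)")
  structure(list(E = vol, nu = nu, rho = rho), class = "material_field")
}

#' Material field from a binary scaffold volume
#'
#' Solid voxels get the solid modulus, pore voxels the air-like floor
#' modulus — the standard way a segmented scaffold enters the voxel
#' solver.
#'
#' @param bin a [binary_volume()].
#' @param E_solid solid modulus in MPa.
#' @param E_void pore modulus in MPa (default the 0.01 MPa floor).
#' @param nu Poisson ratio.
#' @return A [material_field()].
#' @export
material_from_mask <- function(bin, E_solid, E_void = 0.01, nu = 0.3) {
  stopifnot(inherits(bin, "binary_volume"))
  E <- array(ifelse(bin$mask, E_solid, E_void), dim(bin$mask))
  material_field(voxel_volume(E, spacing = bin$spacing,
                              origin = bin$origin), nu = nu)
}

# 24 x 24 stiffness of a trilinear hexahedron, unit modulus, unit edge,
# 2x2x2 Gauss quadrature. Physical stiffness = E * h * ke.
hex_reference_ke <- function(nu) {
  C <- elastic_matrix(1, nu)
  gp <- (1 + c(-1, 1) / sqrt(3)) / 2 # Gauss points mapped to [0, 1]
  ke <- matrix(0, 24, 24)
  for (gx in gp) for (gy in gp) for (gz in gp) {
    B <- hex_B(gx, gy, gz)
    ke <- ke + t(B) %*% C %*% B / 8 # weight (1/2)^3 on [0,1]^3 * 8 pts
  }
  (ke + t(ke)) / 2
}

# local node order must match the C++ solver
hex_node_offsets <- function() {
  matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
           0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1),
         ncol = 3, byrow = TRUE)
}

# strain-displacement matrix (engineering shear) at reference point
# (x, y, z) in [0,1]^3, unit edge
hex_B <- function(x, y, z) {
  off <- hex_node_offsets()
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    sx <- if (off[a, 1] == 1) x else 1 - x
    sy <- if (off[a, 2] == 1) y else 1 - y
    sz <- if (off[a, 3] == 1) z else 1 - z
    dx <- (if (off[a, 1] == 1) 1 else -1) * sy * sz
    dy <- (if (off[a, 2] == 1) 1 else -1) * sx * sz
    dz <- (if (off[a, 3] == 1) 1 else -1) * sx * sy
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dx
    B[2, c0 + 2] <- dy
    B[3, c0 + 3] <- dz
    B[4, c0 + 1] <- dy; B[4, c0 + 2] <- dx
    B[5, c0 + 2] <- dz; B[5, c0 + 3] <- dy
    B[6, c0 + 1] <- dz; B[6, c0 + 3] <- dx
  }
  B
}

elastic_matrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

#' Von Mises equivalent stress
#'
#' Scalar equivalent stress from the second invariant of the stress
#' deviator. Stress components are ordered (xx, yy, zz, xy, yz, xz).
#'
#' @param sigma length-6 stress vector or 6 x n matrix (MPa).
#' @return von Mises stress (MPa), one value per column.
#' @examples
#' von_mises_stress(c(100, 100, 100, 0, 0, 0)) # hydrostatic: 0
#' @export
von_mises_stress <- function(sigma) {
  s <- if (is.matrix(sigma)) sigma else matrix(sigma, ncol = 1)
  if (nrow(s) != 6L) stop("stress must have 6 components")
  sqrt(0.5 * ((s[1, ] - s[2, ])^2 + (s[2, ] - s[3, ])^2 +
                (s[3, ] - s[1, ])^2) +
         3 * (s[4, ]^2 + s[5, ]^2 + s[6, ]^2))
}

#' Compressive load case for voxel homogenization
#'
#' @param direction loading axis 1, 2 or 3.
#' @param strain applied compressive strain (fraction, default 0.01 =
#'   1 percent).
#' @param loaded_face `"normal"` (default): the loaded face gets a
#'   uniform prescribed normal displacement, tangentially free;
#'   `"clamped"`: all three components prescribed on the loaded face.
#'   The opposite face is fully fixed in both styles; lateral faces are
#'   traction-free.
#' @return An object of class `load_case`.
#' @export
load_case <- function(direction = 1, strain = 0.01,
                      loaded_face = c("normal", "clamped")) {
  if (!(direction %in% 1:3)) stop("direction must be 1, 2 or 3")
  if (!is.numeric(strain) || strain <= 0 || strain >= 0.1) {
    stop("strain must be in (0, 0.1)")
  }
  structure(list(direction = as.integer(direction), strain = strain,
                 loaded_face = match.arg(loaded_face)),
            class = "load_case")
}

#' Apparent modulus and stress summary by voxel FEA
#'
#' Solves static linear elasticity on the voxel grid (one trilinear
#' hexahedral element per voxel, per-voxel modulus, shared Poisson
#' ratio) under displacement-controlled uniaxial compression: the loaded
#' face is pushed in by `strain` times the span along the loading
#' direction, the opposite face is fully fixed, lateral faces are free.
#' The system is solved matrix-free with Jacobi-preconditioned conjugate
#' gradients. The apparent elastic modulus is the loaded-face reaction
#' force divided by the loaded area and the applied strain; the von
#' Mises summary averages over load-bearing voxels (modulus above the
#' air floor).
#'
#' @param material a [material_field()] with isotropic spacing.
#' @param load a [load_case()] (or direction number).
#' @param tol relative residual tolerance of the solver.
#' @param maxit iteration cap; default `2000 * nvox^(1/3)`.
#' @param solid_threshold voxels with modulus above this value (MPa)
#'   count as load-bearing solid for the von Mises mean.
#' @param keep_fields also return the per-voxel von Mises volume.
#' @return An object of class `homogenization_result`: a list with
#'   `direction`, `E_app_MPa`, `mean_von_mises_MPa`, `reaction_N`,
#'   solver diagnostics, and optionally `von_mises` (a
#'   [voxel_volume()]).
#' @export
homogenize <- function(material, load = load_case(), tol = 1e-8,
                       maxit = NULL, solid_threshold = 0.01,
                       keep_fields = FALSE) {
  stopifnot(inherits(material, "material_field"))
  if (is.numeric(load)) load <- load_case(direction = load)
  stopifnot(inherits(load, "load_case"))
  h <- require_isotropic(material$E, "voxel homogenization")
  d <- dim(material$E$values)
  if (any(d < 8L)) stop("homogenization needs at least 8 voxels per axis")
  dir <- load$direction
  ke <- hex_reference_ke(material$nu)
  nn <- d + 1L
  nnode <- prod(nn)

  # node index grids along the loading axis
  idx <- arrayInd(seq_len(nnode), nn)
  on_fixed <- idx[, dir] == 1L
  on_loaded <- idx[, dir] == nn[dir]

  fixed <- matrix(FALSE, 3, nnode)
  u0 <- matrix(0, 3, nnode)
  fixed[, on_fixed] <- TRUE
  span <- d[dir] * h
  if (load$loaded_face == "clamped") {
    fixed[, on_loaded] <- TRUE
  } else {
    fixed[dir, on_loaded] <- TRUE
  }
  u0[dir, on_loaded] <- -load$strain * span

  nvox <- prod(d)
  if (is.null(maxit)) maxit <- ceiling(2000 * nvox^(1 / 3))
  sol <- .cpp_hex_solve(d, as.numeric(material$E$values), ke, h,
                        as.logical(fixed), as.numeric(u0), tol,
                        as.integer(maxit))
  if (!sol$converged) {
    stop(sprintf(
      "voxel solver did not converge: relative residual %.3g after %d iterations",
      sol$relres, sol$iterations))
  }

  f <- .cpp_hex_forces(d, as.numeric(material$E$values), ke, h, sol$u)
  fm <- matrix(f, 3, nnode)
  reaction <- sum(fm[dir, on_loaded])
  area <- prod((d * h)[-dir])
  E_app <- abs(reaction) / (area * load$strain)

  Bc <- hex_B(0.5, 0.5, 0.5) / h
  eps <- .cpp_hex_strains(d, Bc, sol$u)
  Cunit <- elastic_matrix(1, material$nu)
  sig <- (Cunit %*% eps) * rep(as.numeric(material$E$values),
                               each = 6)
  vm <- von_mises_stress(sig)
  solid <- as.numeric(material$E$values) > solid_threshold
  mean_vm <- if (any(solid)) mean(vm[solid]) else mean(vm)

  out <- list(
    direction = dir, strain = load$strain, E_app_MPa = E_app,
    mean_von_mises_MPa = mean_vm, reaction_N = reaction,
    iterations = sol$iterations, relres = sol$relres
  )
  if (keep_fields) {
    out$von_mises <- voxel_volume(array(vm, d),
                                  spacing = material$E$spacing,
                                  origin = material$E$origin)
    out$displacement <- sol$u
  }
  structure(out, class = "homogenization_result")
}

#' @export
print.homogenization_result <- function(x, ...) {
  cat(sprintf(
    "<homogenization_result> direction %d, strain %.3g\n  E_app = %.6g MPa, mean von Mises (solid) = %.6g MPa\n  solver: %d iterations, relres %.3g\n",
    x$direction, x$strain, x$E_app_MPa, x$mean_von_mises_MPa,
    x$iterations, x$relres))
  invisible(x)
}
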