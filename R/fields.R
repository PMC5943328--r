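#' Trigonometric product term of a nodal TPMS field
#'
#' Nodal (approximate) triply periodic minimal surfaces are level sets of
#' short sums of trigonometric products,
#' \deqn{\phi(r) = \sum_k A_k \prod_{i \in \{x,y,z\}} f_{k,i}(n_{k,i}\,
#'   \theta_i + p_{k,i}), \qquad \theta_i = 2\pi r_i / a,}
#' where each axis factor \eqn{f} is `cos`, `sin` or the constant 1
#' (`"unity"`), \eqn{n} is an integer frequency multiplier, \eqn{p} a
#' phase offset, and \eqn{a} the physical unit-cell edge. Integer
#' frequencies keep the field exactly periodic with period `a` on every
#' axis.
#'
#' @param amplitude term amplitude \eqn{A_k} (dimensionless).
#' @param kinds character length-3, the per-axis factor type, each one of
#'   `"cos"`, `"sin"`, `"unity"`.
#' @param freqs integer length-3 frequency multipliers (>= 0).
#' @param phases numeric length-3 phase offsets in radians.
#' @return An object of class `trig_term`.
#' @seealso [field_spec()], [tpms_preset()]
#' @export
trig_term <- function(amplitude, kinds = c("unity", "unity", "unity"),
                      freqs = c(0L, 0L, 0L), phases = c(0, 0, 0)) {
  kinds <- match.arg(rep_len(kinds, 3L), c("cos", "sin", "unity"),
                     several.ok = TRUE)
  if (length(kinds) != 3L) kinds <- rep_len(kinds, 3L)
  freqs <- rep_len(as.numeric(freqs), 3L)
  phases <- rep_len(as.numeric(phases), 3L)
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      !is.finite(amplitude)) {
    stop("`amplitude` must be a single finite number")
  }
  if (any(freqs < 0) || any(freqs != round(freqs))) {
    stop("frequency multipliers must be integers >= 0")
  }
  structure(
    list(amplitude = amplitude, kinds = kinds, freqs = as.integer(freqs),
         phases = phases),
    class = "trig_term"
  )
}

#' Nodal TPMS implicit field specification
#'
#' Bundles a list of [trig_term()]s with a level constant \eqn{C} and a
#' physical unit-cell edge length. The surface is the level set
#' \eqn{\{\phi(r) = C\}} and the solid phase is taken as
#' \eqn{\{\phi(r) \le C\}} throughout the package, so raising the level
#' grows the solid phase for P-like fields.
#'
#' @param terms list of [trig_term()] objects.
#' @param level level constant \eqn{C} (iso-value of the surface).
#' @param cell_size physical edge length of one period, in mm.
#' @param name optional label.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(terms, level = 0, cell_size = 1, name = "custom") {
  if (!length(terms) || !all(vapply(terms, inherits, TRUE, "trig_term"))) {
    stop("`terms` must be a non-empty list of trig_term objects")
  }
  if (!is.numeric(cell_size) || cell_size <= 0 || !is.finite(cell_size)) {
    stop("`cell_size` must be a positive length in mm")
  }
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level)) {
    stop("`level` must be a single finite number")
  }
  structure(
    list(terms = terms, level = level, cell_size = as.numeric(cell_size),
         name = as.character(name)),
    class = "field_spec"
  )
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> '%s': %d term(s), level %.4g, cell %.4g mm\n",
              x$name, length(x$terms), x$level, x$cell_size))
  invisible(x)
}

# product of axis factors, vectorized over an n x 3 matrix of angular
# coordinates theta (radians)
term_values <- function(term, theta) {
  out <- rep(term$amplitude, nrow(theta))
  for (i in 1:3) {
    out <- out * switch(term$kinds[i],
      cos = cos(term$freqs[i] * theta[, i] + term$phases[i]),
      sin = sin(term$freqs[i] * theta[, i] + term$phases[i]),
      unity = 1
    )
  }
  out
}

as_point_matrix <- function(point) {
  if (is.matrix(point)) {
    if (ncol(point) != 3L) stop("points must have 3 columns")
    point
  } else {
    if (length(point) != 3L) stop("a point must have 3 coordinates")
    matrix(point, 1L, 3L)
  }
}

#' Evaluate a TPMS field at physical points
#'
#' Coordinates are physical mm; internally each axis is mapped to the
#' angular coordinate \eqn{\theta = 2\pi\, r / a} (one unit cell per
#' `cell_size` on every axis) before the trigonometric factors are
#' evaluated. The level constant is *not* subtracted: the surface is the
#' point set where the returned value equals `spec$level`.
#'
#' @param spec a [field_spec()], [blend_spec()] or composite field.
#' @param point numeric length-3 position in mm, or an n x 3 matrix.
#' @return Numeric vector of field values.
#' @examples
#' p <- tpms_preset("P")
#' eval_field(p, c(0, 0, 0)) # 3: cos 0 + cos 0 + cos 0
#' @export
eval_field <- function(spec, point) {
  pts <- as_point_matrix(point)
  if (any(!is.finite(pts))) stop("points must be finite")
  field_values(spec, pts)
}

#' Field evaluation generic (vectorized, internal workhorse)
#'
#' @param spec field-like object.
#' @param pts n x 3 matrix of physical positions (mm).
#' @return numeric vector of length n.
#' @keywords internal
#' @export
field_values <- function(spec, pts) UseMethod("field_values")

#' @export
field_values.field_spec <- function(spec, pts) {
  theta <- 2 * pi * pts / spec$cell_size
  out <- numeric(nrow(pts))
  for (term in spec$terms) out <- out + term_values(term, theta)
  out
}

#' @export
field_values.function <- function(spec, pts) spec(pts)

#' Level constant of a field-like object
#' @param spec field-like object.
#' @keywords internal
#' @export
field_level <- function(spec) UseMethod("field_level")

#' @export
field_level.field_spec <- function(spec) spec$level

#' @export
field_level.default <- function(spec) 0

#' Built-in TPMS unit presets
#'
#' The classical nodal forms (level 0, angular coordinates
#' \eqn{X = 2\pi x / a} etc.):
#' \describe{
#'   \item{P}{\eqn{\cos X + \cos Y + \cos Z}}
#'   \item{D}{\eqn{\cos X \cos Y \cos Z - \sin X \sin Y \sin Z}}
#'   \item{G}{\eqn{\sin X \cos Y + \sin Z \cos X + \sin Y \cos Z}}
#' }
#' plus the two tubular-gyroid bone-scaffold units, which add
#' second-harmonic product terms and a constant offset to the gyroid
#' skeleton:
#' \describe{
#'   \item{TGab}{\eqn{20(\cos X \sin Y + \cos Y \sin Z + \cos Z \sin X)
#'     - 0.5(\cos 2X \cos 2Y + \cos 2Y \cos 2Z + \cos 2Z \cos 2X) - 4}}
#'   \item{TGc}{\eqn{10(\cos X \sin Y + \cos Y \sin Z + \cos Z \sin X)
#'     - 2(\cos 2X \cos 2Y + \cos 2Y \cos 2Z + \cos 2Z \cos 2X) - 12}}
#' }
#' The TG offsets (-4, -12) are carried as constant terms so that every
#' preset's surface sits at level 0 and the solid phase is
#' \eqn{\{\phi \le 0\}}. TGab reproduces the coarser plate-like cortical
#' regions, TGc the finer, more uniform medial region.
#'
#' @param name one of `"P"`, `"D"`, `"G"`, `"TGab"`, `"TGc"`.
#' @param cell_size physical unit-cell edge (mm).
#' @return A [field_spec()].
#' @examples
#' g <- tpms_preset("G", cell_size = 2)
#' eval_field(g, c(0, 0, 0)) # 0: the origin lies on the gyroid surface
#' @export
tpms_preset <- function(name = c("P", "D", "G", "TGab", "TGc"),
                        cell_size = 1) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% c("P", "D", "G", "TGab", "TGc"))) {
    stop("unknown preset; valid presets are: P, D, G, TGab, TGc")
  }
  axis_term <- function(amp, kx, ky, kz, f = 1L) {
    trig_term(amp, kinds = c(kx, ky, kz),
              freqs = ifelse(c(kx, ky, kz) == "unity", 0L, f))
  }
  terms <- switch(name,
    P = list(
      axis_term(1, "cos", "unity", "unity"),
      axis_term(1, "unity", "cos", "unity"),
      axis_term(1, "unity", "unity", "cos")
    ),
    D = list(
      axis_term(1, "cos", "cos", "cos"),
      axis_term(-1, "sin", "sin", "sin")
    ),
    G = list(
      axis_term(1, "sin", "cos", "unity"),   # sin X cos Y
      axis_term(1, "cos", "unity", "sin"),   # sin Z cos X
      axis_term(1, "unity", "sin", "cos")    # sin Y cos Z
    ),
    TGab = tubular_g_terms(20, -0.5, -4),
    TGc = tubular_g_terms(10, -2, -12)
  )
  field_spec(terms, level = 0, cell_size = cell_size, name = name)
}

tubular_g_terms <- function(a1, a2, offset) {
  gyroid <- list(
    trig_term(a1, c("cos", "sin", "unity"), c(1, 1, 0)),  # cos X sin Y
    trig_term(a1, c("unity", "cos", "sin"), c(0, 1, 1)),  # cos Y sin Z
    trig_term(a1, c("sin", "unity", "cos"), c(1, 0, 1))   # cos Z sin X
  )
  second <- list(
    trig_term(a2, c("cos", "cos", "unity"), c(2, 2, 0)),  # cos 2X cos 2Y
    trig_term(a2, c("unity", "cos", "cos"), c(0, 2, 2)),  # cos 2Y cos 2Z
    trig_term(a2, c("cos", "unity", "cos"), c(2, 0, 2))   # cos 2Z cos 2X
  )
  c(gyroid, second, list(trig_term(offset)))
}

#' Rectangular sampling domain
#'
#' @param lower,upper numeric length-3 physical box corners in mm
#'   (`upper > lower` per axis).
#' @param res voxels per axis (scalar or length 3, each >= 2).
#' @return An object of class `domain`.
#' @export
domain <- function(lower, upper, res) {
  lower <- rep_len(as.numeric(lower), 3L)
  upper <- rep_len(as.numeric(upper), 3L)
  res <- rep_len(as.integer(res), 3L)
  if (any(upper <= lower)) stop("`upper` must exceed `lower` on each axis")
  if (any(res < 2L)) stop("resolution must be >= 2 voxels per axis")
  structure(list(lower = lower, upper = upper, res = res), class = "domain")
}

#' Sample a field on a voxel grid
#'
#' Values are taken at voxel centers (half a voxel inside the domain
#' corners), so domain boundaries are treated symmetrically. Downstream,
#' the solid phase is the voxel set with value <= the field's level.
#'
#' @param spec field-like object ([field_spec()], [blend_spec()],
#'   composite, or a function of an n x 3 matrix).
#' @param dom a [domain()].
#' @param max_voxels guard against runaway grids.
#' @return A [voxel_volume()].
#' @export
sample_grid <- function(spec, dom, max_voxels = 2^27) {
  stopifnot(inherits(dom, "domain"))
  n <- prod(as.numeric(dom$res))
  if (n > max_voxels) {
    stop(sprintf("grid of %.3g voxels exceeds max_voxels = %.3g", n,
                 max_voxels))
  }
  spacing <- (dom$upper - dom$lower) / dom$res
  origin <- dom$lower + spacing / 2
  ax <- lapply(1:3, function(i) origin[i] + (seq_len(dom$res[i]) - 1) *
                 spacing[i])
  pts <- cbind(
    rep(ax[[1]], times = dom$res[2] * dom$res[3]),
    rep(rep(ax[[2]], each = dom$res[1]), times = dom$res[3]),
    rep(ax[[3]], each = dom$res[1] * dom$res[2])
  )
  vals <- field_values(spec, pts)
  voxel_volume(array(vals, dom$res), spacing = spacing, origin = origin)
}

#' Binarize a sampled field into solid and pore
#'
#' Solid phase is `{value <= level}`; by default `level` is the field's
#' own level constant.
#'
#' @param vol a [voxel_volume()] of field values.
#' @param level iso-level; solid is value <= level.
#' @return A [binary_volume()].
#' @export
solidify <- function(vol, level = 0) {
  stopifnot(inherits(vol, "voxel_volume"))
  binary_volume(vol$values <= level, spacing = vol$spacing,
                origin = vol$origin)
}

#' Serialize field specifications to and from JSON
#'
#' The schema mirrors the object: `name`, `cell_size`, `level`, and a
#' `terms` array with `amplitude`, `kinds`, `freqs`, `phases` each.
#'
#' @param spec a [field_spec()].
#' @param path file path.
#' @return `read_field_json` returns a [field_spec()].
#' @export
write_field_json <- function(spec, path) {
  stopifnot(inherits(spec, "field_spec"))
  obj <- list(
    name = spec$name, cell_size = spec$cell_size, level = spec$level,
    terms = lapply(spec$terms, function(t) {
      list(amplitude = t$amplitude, kinds = t$kinds, freqs = t$freqs,
           phases = t$phases)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field_json
#' @export
read_field_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  terms <- lapply(obj$terms, function(t) {
    trig_term(t$amplitude, kinds = t$kinds, freqs = t$freqs,
              phases = t$phases)
  })
  field_spec(terms, level = obj$level, cell_size = obj$cell_size,
             name = obj$name)
}
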