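#' Transition boundary for sigmoid blending
#'
#' A graded scaffold fuses two implicit units across the zero set of a
#' continuous boundary function \eqn{G(x,y,z)}. Supported analytic
#' forms:
#' \describe{
#'   \item{plane}{\eqn{G = n \cdot r - d} (unit-normalized `normal`).}
#'   \item{sphere}{\eqn{G = |r - center|^2 - c}, i.e. the paper-style
#'     spherical boundary \eqn{x^2+y^2+z^2 - C} (with `c` the squared
#'     radius); positive outside the sphere.}
#'   \item{quadric}{a general second-order polynomial with coefficients
#'     `quad` (xx, yy, zz, xy, yz, xz), `lin` (x, y, z) and `const`.}
#' }
#' The steepness `k` (1/mm for a unit-gradient boundary) sets how fast
#' the sigmoid weight moves from one unit to the other; larger `k`
#' gives a sharper transition.
#'
#' @param type `"plane"`, `"sphere"` or `"quadric"`.
#' @param k sigmoid steepness, > 0. Default `2 * pi` puts most of the
#'   transition within roughly one millimetre-scale unit cell of a
#'   unit-gradient boundary.
#' @param normal,offset plane parameters (`G = normal . r - offset`).
#' @param center,c2 sphere parameters (`G = |r - center|^2 - c2`).
#' @param quad,lin,const quadric coefficients.
#' @return An object of class `transition_spec`.
#' @export
transition_spec <- function(type = c("plane", "sphere", "quadric"),
                            k = 2 * pi,
                            normal = c(1, 0, 0), offset = 0,
                            center = c(0, 0, 0), c2 = 1,
                            quad = c(0, 0, 0, 0, 0, 0),
                            lin = c(0, 0, 0), const = 0) {
  type <- match.arg(type)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("steepness `k` must be a single positive number")
  }
  spec <- switch(type,
    plane = {
      normal <- rep_len(as.numeric(normal), 3L)
      nn <- sqrt(sum(normal^2))
      if (nn == 0) stop("plane normal must be nonzero")
      list(normal = normal / nn, offset = as.numeric(offset))
    },
    sphere = list(center = rep_len(as.numeric(center), 3L),
                  c2 = as.numeric(c2)),
    quadric = list(quad = rep_len(as.numeric(quad), 6L),
                   lin = rep_len(as.numeric(lin), 3L),
                   const = as.numeric(const))
  )
  structure(c(list(type = type, k = k), spec), class = "transition_spec")
}

#' Boundary function values of a transition
#'
#' @param trans a [transition_spec()].
#' @param pts n x 3 matrix of physical positions (mm).
#' @return numeric vector of \eqn{G(x,y,z)} values.
#' @export
boundary_value <- function(trans, pts) {
  stopifnot(inherits(trans, "transition_spec"))
  pts <- as_point_matrix(pts)
  switch(trans$type,
    plane = drop(pts %*% trans$normal) - trans$offset,
    sphere = rowSums(sweep(pts, 2, trans$center)^2) - trans$c2,
    quadric = {
      q <- trans$quad
      q[1] * pts[, 1]^2 + q[2] * pts[, 2]^2 + q[3] * pts[, 3]^2 +
        q[4] * pts[, 1] * pts[, 2] + q[5] * pts[, 2] * pts[, 3] +
        q[6] * pts[, 1] * pts[, 3] +
        drop(pts %*% trans$lin) + trans$const
    }
  )
}

#' Sigmoid transition weight
#'
#' The logistic weight \eqn{\alpha = 1 / (1 + e^{-k G})}: strictly
#' increasing in \eqn{G}, exactly 1/2 on the transition boundary
#' (\eqn{G = 0}), saturating to 1 deep inside the \eqn{G > 0} region and
#' to 0 deep inside \eqn{G < 0}.
#'
#' @param g_value boundary function value(s).
#' @param k steepness, > 0.
#' @return weights in (0, 1).
#' @examples
#' sigmoid_weight(0, 5)   # 0.5 on the boundary
#' @export
sigmoid_weight <- function(g_value, k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("steepness `k` must be a single positive number")
  }
  1 / (1 + exp(-k * g_value))
}

#' Sigmoid-blended pair of implicit fields
#'
#' The fused structure is the convex combination
#' \deqn{\phi_{sf} = \alpha\,\phi_1 + (1 - \alpha)\,\phi_2,}
#' with \eqn{\alpha} the [sigmoid_weight()] of the transition boundary:
#' unit 1 dominates where \eqn{G > 0}, unit 2 where \eqn{G < 0}, and the
#' two mix smoothly across the boundary. Because the two units may carry
#' different level constants, each field enters as \eqn{\phi_i -
#' C_i}, so the fused surface is always the zero level set of the blend.
#'
#' @param field_1,field_2 field-like objects sharing one physical frame.
#' @param transition a [transition_spec()].
#' @param name optional label.
#' @return An object of class `blend_spec` (itself field-like: it can be
#'   sampled, blended again, and meshed).
#' @export
blend_spec <- function(field_1, field_2, transition, name = "blend") {
  stopifnot(inherits(transition, "transition_spec"))
  structure(
    list(field_1 = field_1, field_2 = field_2, transition = transition,
         name = name),
    class = "blend_spec"
  )
}

#' @export
print.blend_spec <- function(x, ...) {
  cat(sprintf("<blend_spec> '%s': %s transition, k = %.4g\n",
              x$name, x$transition$type, x$transition$k))
  invisible(x)
}

#' Evaluate a blended field at physical points
#'
#' @param blend a [blend_spec()].
#' @param point length-3 position (mm) or n x 3 matrix.
#' @return numeric vector; the fused surface is `{value = 0}` and the
#'   solid phase `{value <= 0}`.
#' @export
blend_eval <- function(blend, point) {
  stopifnot(inherits(blend, "blend_spec"))
  pts <- as_point_matrix(point)
  if (any(!is.finite(pts))) stop("points must be finite")
  field_values(blend, pts)
}

#' @export
field_values.blend_spec <- function(spec, pts) {
  a <- sigmoid_weight(boundary_value(spec$transition, pts),
                      spec$transition$k)
  f1 <- field_values(spec$field_1, pts) - field_level(spec$field_1)
  f2 <- field_values(spec$field_2, pts) - field_level(spec$field_2)
  a * f1 + (1 - a) * f2
}

#' @export
field_level.blend_spec <- function(spec) 0

#' Fuse an ordered sequence of units into one graded field
#'
#' Pairwise cascade of sigmoid blends: the running result plays the role
#' of unit 1 in each step, and unit *i* takes over where its own
#' transition boundary is negative. A single unit is returned unchanged.
#' Near triple junctions the result depends on the unit order (the
#' cascade is documented as order-dependent there).
#'
#' @param units list; each element a list with components `field` (a
#'   field-like object) and `transition` (a [transition_spec()]; unused
#'   and optional for the first unit).
#' @return the single unit's field, or a nested [blend_spec()].
#' @export
multi_blend <- function(units) {
  if (!is.list(units) || length(units) < 1L) {
    stop("`units` must be a non-empty list of (field, transition) pairs")
  }
  res <- units[[1]]$field
  if (is.null(res)) stop("each unit needs a `field` component")
  if (length(units) > 1L) {
    for (i in 2:length(units)) {
      u <- units[[i]]
      if (is.null(u$field) || is.null(u$transition)) {
        stop("units after the first need `field` and `transition`")
      }
      res <- blend_spec(res, u$field, u$transition,
                        name = sprintf("cascade_%d", i))
    }
  }
  res
}

#' Serialize a blend specification to and from JSON
#'
#' Nested blends are written recursively; leaf fields use the
#' [write_field_json()] schema inline.
#'
#' @param blend a [blend_spec()] or [field_spec()].
#' @param path file path.
#' @export
write_blend_json <- function(blend, path) {
  jsonlite::write_json(blend_to_list(blend), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

blend_to_list <- function(x) {
  if (inherits(x, "field_spec")) {
    list(kind = "field", name = x$name, cell_size = x$cell_size,
         level = x$level,
         terms = lapply(x$terms, function(t) {
           list(amplitude = t$amplitude, kinds = t$kinds, freqs = t$freqs,
                phases = t$phases)
         }))
  } else if (inherits(x, "blend_spec")) {
    tr <- unclass(x$transition)
    list(kind = "blend", name = x$name,
         field_1 = blend_to_list(x$field_1),
         field_2 = blend_to_list(x$field_2),
         transition = tr)
  } else {
    stop("cannot serialize fields of class ", paste(class(x), collapse = "/"))
  }
}

#' @rdname write_blend_json
#' @export
read_blend_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  blend_from_list(obj)
}

blend_from_list <- function(obj) {
  if (identical(obj$kind, "field")) {
    terms <- lapply(obj$terms, function(t) {
      trig_term(t$amplitude, kinds = t$kinds, freqs = t$freqs,
                phases = t$phases)
    })
    field_spec(terms, level = obj$level, cell_size = obj$cell_size,
               name = obj$name)
  } else if (identical(obj$kind, "blend")) {
    tr <- obj$transition
    trans <- switch(tr$type,
      plane = transition_spec("plane", k = tr$k, normal = unlist(tr$normal),
                              offset = tr$offset),
      sphere = transition_spec("sphere", k = tr$k,
                               center = unlist(tr$center), c2 = tr$c2),
      quadric = transition_spec("quadric", k = tr$k, quad = unlist(tr$quad),
                                lin = unlist(tr$lin), const = tr$const)
    )
    blend_spec(blend_from_list(obj$field_1), blend_from_list(obj$field_2),
               trans, name = obj$name)
  } else {
    stop("unrecognized blend JSON node")
  }
}
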