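#' Analytic test phantoms with known morphometry
#'
#' Generates binarized stand-ins for micro-CT volumes from exact
#' analytic shapes, voxelized by center inclusion (a voxel is solid iff
#' its center lies inside the shape), so the recorded ground truth is
#' exact geometry at any resolution. Available kinds:
#' \describe{
#'   \item{slab}{a plate of `thickness` spanning the box perpendicular
#'     to `axis`, centered. Ideal plate: SMI 0, SAD 2/t, TT = t.}
#'   \item{slab_array}{parallel plates of `thickness` separated by
#'     `gap`, repeating along `axis`, with half-gap margins at both box
#'     faces (the pattern is mirror-symmetric about the faces, so
#'     sphere-fitting thickness metrics see effectively infinite
#'     repetition). TT = t, TS = g.}
#'   \item{cylinder}{a rod of `radius` spanning the box along `axis`,
#'     centered. Ideal rod: SMI 3, SAD 2/R, TT = 2R.}
#'   \item{sphere}{a ball of `radius` centered in the box (fully
#'     interior). SMI 4, SAD 3/R, TT = 2R.}
#'   \item{gyroid_block}{one period of the gyroid preset thresholded at
#'     `level` (porosity 0.5 at level 0 by the point-inversion symmetry
#'     of the two labyrinths).}
#' }
#'
#' @param kind phantom kind (see above).
#' @param res voxels per axis (scalar or length 3).
#' @param box physical edge length(s) of the domain in mm (scalar or
#'   length 3); the box corner sits at the origin.
#' @param thickness slab thickness (mm).
#' @param gap slab-array gap (mm).
#' @param radius cylinder/sphere radius (mm).
#' @param axis slab normal / cylinder axis (1, 2 or 3).
#' @param level gyroid level constant.
#' @return list with `volume` (a [binary_volume()]), `truth` (named
#'   list of analytic metric values, `NA` where undefined) and `spec`
#'   (the arguments).
#' @export
make_phantom <- function(kind = c("slab", "slab_array", "cylinder",
                                  "sphere", "gyroid_block"),
                         res = 64L, box = 1, thickness = 0.2,
                         gap = 0.2, radius = 0.1, axis = NULL,
                         level = 0) {
  kind <- match.arg(kind)
  box <- rep_len(as.numeric(box), 3L)
  dom <- domain(c(0, 0, 0), box, res)
  spacing <- (dom$upper - dom$lower) / dom$res
  ax <- lapply(1:3, function(i) (seq_len(dom$res[i]) - 0.5) * spacing[i])
  ctr <- box / 2

  truth <- list(porosity = NA_real_, tt = NA_real_, ts = NA_real_,
                sad = NA_real_, smi = NA_real_)
  if (kind == "slab") {
    if (is.null(axis)) axis <- 1L
    if (thickness <= 0 || thickness > box[axis]) {
      stop("slab thickness must lie in (0, box]")
    }
    inside1 <- abs(ax[[axis]] - ctr[axis]) <= thickness / 2
    mask <- project_axis(inside1, dom$res, axis)
    truth$porosity <- 1 - thickness / box[axis]
    truth$tt <- thickness
    truth$sad <- 2 / thickness
    truth$smi <- 0
  } else if (kind == "slab_array") {
    if (is.null(axis)) axis <- 1L
    if (thickness <= 0 || gap <= 0) stop("thickness and gap must be positive")
    period <- thickness + gap
    # half-gap margin: pore | slab | gap | slab | ... | pore
    inside1 <- ((ax[[axis]] - gap / 2) %% period) < thickness
    mask <- project_axis(inside1, dom$res, axis)
    truth$porosity <- gap / period
    truth$tt <- thickness
    truth$ts <- gap
    truth$sad <- 2 / thickness
    truth$smi <- 0
  } else if (kind == "cylinder") {
    if (is.null(axis)) axis <- 3L
    tr <- setdiff(1:3, axis)
    if (radius <= 0 || any(radius > box[tr] / 2)) {
      stop("cylinder radius must fit inside the box cross-section")
    }
    r2 <- outer((ax[[tr[1]]] - ctr[tr[1]])^2,
                (ax[[tr[2]]] - ctr[tr[2]])^2, `+`)
    inside2 <- r2 <= radius^2
    mask <- project_plane(inside2, dom$res, tr, axis)
    truth$porosity <- 1 - pi * radius^2 / (box[tr[1]] * box[tr[2]])
    truth$tt <- 2 * radius
    truth$sad <- 2 / radius
    truth$smi <- 3
  } else if (kind == "sphere") {
    if (radius <= 0 || any(radius > box / 2)) {
      stop("sphere radius must fit inside the box")
    }
    dx2 <- (ax[[1]] - ctr[1])^2
    dy2 <- (ax[[2]] - ctr[2])^2
    dz2 <- (ax[[3]] - ctr[3])^2
    r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    mask <- r2 <= radius^2
    truth$porosity <- 1 - (4 / 3) * pi * radius^3 / prod(box)
    truth$tt <- 2 * radius
    truth$sad <- 3 / radius
    truth$smi <- 4
  } else { # gyroid_block
    g <- tpms_preset("G", cell_size = box[1])
    vol <- sample_grid(g, dom)
    mask <- vol$values <= level
    if (level == 0) truth$porosity <- 0.5
  }
  dim(mask) <- dom$res
  list(
    volume = binary_volume(mask, spacing = spacing,
                           origin = dom$lower + spacing / 2),
    truth = truth,
    spec = list(kind = kind, res = dom$res, box = box,
                thickness = thickness, gap = gap, radius = radius,
                axis = axis, level = level)
  )
}

# broadcast a 1D inclusion along the other two axes
project_axis <- function(inside1, res, axis) {
  arr <- array(FALSE, res)
  idx <- slice.index(arr, axis)
  array(inside1[idx], res)
}

# broadcast a 2D inclusion (over axes tr) along the remaining axis
project_plane <- function(inside2, res, tr, axis) {
  arr <- array(FALSE, res)
  i1 <- slice.index(arr, tr[1])
  i2 <- slice.index(arr, tr[2])
  array(inside2[cbind(as.vector(i1), as.vector(i2))], res)
}

#' Render a binary phantom as a synthetic grayscale volume
#'
#' Emulates a micro-CT grayscale stack from a binary phantom:
#' foreground/background gray assignment, optional Gaussian blur
#' (partial-volume effect) and additive Gaussian noise. All randomness
#' flows through `seed`; identical arguments give bit-identical volumes
#' and the caller's RNG state is left untouched.
#'
#' @param bin a [binary_volume()].
#' @param fg,bg foreground (solid) and background gray values.
#' @param blur_sigma Gaussian blur in voxels (>= 0).
#' @param noise_sd additive Gaussian noise standard deviation (gray
#'   units, >= 0).
#' @param seed integer RNG seed used when `noise_sd > 0`.
#' @return A [voxel_volume()].
#' @export
render_grayscale <- function(bin, fg = 1, bg = 0, blur_sigma = 0,
                             noise_sd = 0, seed = 1L) {
  stopifnot(inherits(bin, "binary_volume"))
  if (blur_sigma < 0 || noise_sd < 0) {
    stop("blur_sigma and noise_sd must be >= 0")
  }
  d <- dim(bin$mask)
  gray <- array(ifelse(bin$mask, fg, bg), d)
  if (blur_sigma > 0) gray <- .cpp_gaussian_blur(gray, d, blur_sigma)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    gray <- gray + array(rnorm(length(gray), sd = noise_sd), d)
  }
  voxel_volume(gray, spacing = bin$spacing, origin = bin$origin)
}

#' End-to-end functionally graded scaffold demo
#'
#' Builds the package's reference gradient scaffold: tubular-gyroid
#' units stacked along x (coarse TGab outside, fine TGc in the middle by
#' default) fused by two plane transitions, then sampled, binarized,
#' capped-meshed and summarized. Exercises the whole
#' fields - blending - meshing - morphometry pipeline in one call.
#'
#' @param res voxels per unit cell (the sampled grid is
#'   `n_cells * res` voxels per axis).
#' @param cell_size unit-cell edge (mm).
#' @param n_cells cells along x (the gradient axis); y and z get one
#'   cell each.
#' @param units list of field-like units stacked along x (length >= 1);
#'   default `TGab | TGc | TGab`.
#' @param k sigmoid steepness; default `2 * pi / cell_size` (the
#'   transition band spans about one unit cell).
#' @param stl_path optional path; when given the capped mesh is written
#'   as binary STL.
#' @param report compute the full morphometry report (slower).
#' @return list with `blend`, `volume` ([voxel_volume()]), `mask`
#'   ([binary_volume()]), `mesh` (watertight [triangle_mesh()]),
#'   `profile` (porosity along x) and optionally `report`.
#' @export
make_gradient_demo <- function(res = 32L, cell_size = 1, n_cells = 3L,
                               units = NULL, k = NULL, stl_path = NULL,
                               report = FALSE) {
  if (is.null(k)) k <- 2 * pi / cell_size
  L <- n_cells * cell_size
  if (is.null(units)) {
    units <- c(list(tpms_preset("TGab", cell_size)),
               rep(list(tpms_preset("TGc", cell_size)), n_cells > 1),
               rep(list(tpms_preset("TGab", cell_size)), n_cells > 2))
  }
  n_units <- length(units)
  pieces <- list(list(field = units[[1]]))
  if (n_units > 1) {
    cuts <- seq(0, L, length.out = n_units + 1)[2:n_units]
    for (i in 2:n_units) {
      # unit i takes over where x > cuts[i-1] (its G < 0 region)
      pieces[[i]] <- list(
        field = units[[i]],
        transition = transition_spec("plane", k = k,
                                     normal = c(-1, 0, 0),
                                     offset = -cuts[i - 1])
      )
    }
  }
  blend <- multi_blend(pieces)
  dom <- domain(c(0, 0, 0), c(L, cell_size, cell_size),
                c(n_cells * res, res, res))
  vol <- sample_grid(blend, dom)
  mask <- solidify(vol, level = 0)
  mesh <- cap_boundary(vol, level = 0, solid = "below")
  if (!is.null(stl_path)) write_stl(mesh, stl_path, mode = "binary")
  out <- list(blend = blend, volume = vol, mask = mask, mesh = mesh,
              profile = porosity_profile(mask, axis = 1))
  if (report) out$report <- morphometry_report(mask)
  out
}
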