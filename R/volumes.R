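#' Scalar voxel volume with physical spacing
#'
#' A `voxel_volume` is a 3D numeric array of samples taken at voxel
#' centers, together with the voxel spacing (mm) and the physical
#' position of the first voxel center (mm). It is the container for
#' sampled implicit fields and for micro-CT-like grayscale stacks.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3 voxel spacing in mm (scalar recycled).
#' @param origin numeric length-3 position (mm) of the center of voxel
#'   `[1, 1, 1]`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be positive and finite")
  }
  structure(
    list(values = values, spacing = spacing, origin = origin),
    class = "voxel_volume"
  )
}

#' Binary (solid/pore) voxel volume
#'
#' Container for segmented volumes: `TRUE` voxels are solid (bone),
#' `FALSE` voxels are pore. Same spatial conventions as
#' [voxel_volume()].
#'
#' @param mask 3D logical array, `TRUE` = solid.
#' @inheritParams voxel_volume
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, spacing, origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  storage.mode(mask) <- "logical"
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be positive and finite")
  }
  structure(
    list(mask = mask, spacing = spacing, origin = origin),
    class = "binary_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<binary_volume> %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  solid fraction %.4f\n", mean(x$mask)))
  invisible(x)
}

vol_dims <- function(vol) {
  dim(if (inherits(vol, "binary_volume")) vol$mask else vol$values)
}

#' Physical bounding box of a volume
#'
#' The box spanned by the voxel faces (half a voxel beyond the outermost
#' voxel centers on every side).
#'
#' @param vol a [voxel_volume()] or [binary_volume()].
#' @return list with `lower` and `upper` (mm).
#' @export
volume_box <- function(vol) {
  d <- vol_dims(vol)
  list(
    lower = vol$origin - vol$spacing / 2,
    upper = vol$origin + (d - 0.5) * vol$spacing
  )
}

require_isotropic <- function(vol, what = "this operation") {
  s <- vol$spacing
  if (diff(range(s)) > 1e-9 * max(s)) {
    stop(sprintf("%s requires isotropic voxel spacing", what))
  }
  s[1]
}

#' Read / write volumes with spacing metadata
#'
#' NIfTI files (`.nii`, `.nii.gz`) carry the voxel spacing natively and
#' are the preferred on-disk format; multi-page TIFF stacks (`.tif`,
#' `.tiff`) are also supported (spacing supplied by the caller on read).
#'
#' @param vol a [voxel_volume()] or [binary_volume()] (masks are written
#'   as 0/1).
#' @param path output file; format chosen by extension.
#' @return `write_volume` returns `path` invisibly; `read_volume`
#'   returns a [voxel_volume()].
#' @export
write_volume <- function(vol, path) {
  values <- if (inherits(vol, "binary_volume")) {
    array(as.numeric(vol$mask), dim(vol$mask))
  } else {
    vol$values
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(values)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to write TIFF stacks")
    }
    slices <- lapply(seq_len(dim(values)[3]), function(k) values[, , k])
    tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' @rdname write_volume
#' @param spacing spacing override (mm); required for TIFF input.
#' @param origin origin override (mm).
#' @export
read_volume <- function(path, spacing = NULL, origin = c(0, 0, 0)) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    values <- array(as.numeric(img), dim(img)[1:3])
    if (is.null(spacing)) spacing <- RNifti::pixdim(img)[1:3]
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to read TIFF stacks")
    }
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    values <- array(unlist(slices), c(dim(slices[[1]])[1:2], length(slices)))
    if (is.null(spacing)) stop("`spacing` must be given for TIFF input")
  } else {
    stop("unsupported volume format: ", path)
  }
  voxel_volume(values, spacing = spacing, origin = origin)
}
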