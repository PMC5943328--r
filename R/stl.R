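#' Write a triangle mesh as STL
#'
#' Binary STL follows the canonical layout: 80-byte header, uint32
#' triangle count, then one 50-byte record per facet (float32 normal,
#' three float32 vertices, uint16 attribute). Facet normals are
#' recomputed from the vertex winding on write. ASCII STL uses the
#' `solid`/`facet normal`/`vertex` dialect. Writing an empty mesh is
#' rejected (an STL with zero facets is almost always an upstream
#' error).
#'
#' @param mesh a non-empty [triangle_mesh()].
#' @param path output file.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @param name solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii"),
                      name = "tpmscaffold") {
  stopifnot(inherits(mesh, "triangle_mesh"))
  mode <- match.arg(mode)
  nt <- nrow(mesh$faces)
  if (nt == 0L) stop("refusing to write an STL with 0 facets")

  v <- mesh$vertices
  f <- mesh$faces
  cr <- mesh_cross(mesh)
  len <- sqrt(rowSums(cr^2))
  nrm <- cr
  nz <- len > 0
  nrm[nz, ] <- nrm[nz, , drop = FALSE] / len[nz]

  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("binary STL:", name)))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nt), con, size = 4L, endian = "little")
    # 12 floats per facet, contiguous, then interleave the 2-byte
    # attribute by building the 50-byte records as a raw matrix
    rec <- cbind(nrm,
                 v[f[, 1], , drop = FALSE],
                 v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE])
    fl <- writeBin(as.vector(t(rec)), raw(), size = 4L, endian = "little")
    m <- matrix(fl, nrow = 48L)
    out <- rbind(m, matrix(as.raw(0), 2L, nt))
    writeBin(as.vector(out), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", name), con)
    body <- sprintf(
      paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
             "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
             "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
      nrm[, 1], nrm[, 2], nrm[, 3],
      v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
      v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
      v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3]
    )
    writeLines(body, con)
    writeLines(sprintf("endsolid %s", name), con)
  }
  invisible(path)
}

#' Read an STL file
#'
#' Auto-detects binary vs ASCII (by checking the declared facet count
#' against the file size). Identical vertex coordinates are merged so
#' the triangle soup becomes an indexed mesh and watertightness can be
#' checked after a round trip. Truncated binary files raise an error
#' naming the byte offset where data ran out.
#'
#' @param path STL file.
#' @param merge_vertices merge exactly coincident vertices (default
#'   TRUE).
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path, merge_vertices = TRUE) {
  size <- file.info(path)$size
  if (is.na(size) || size < 15) {
    stop(sprintf("'%s' is not a readable STL file", path))
  }
  con <- file(path, "rb")
  head84 <- readBin(con, "raw", n = 84L)
  close(con)
  is_binary <- FALSE
  if (length(head84) == 84L) {
    nt <- readBin(head84[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(nt) && nt >= 0 && size == 84 + 50 * as.numeric(nt)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    read_stl_binary(path, size, merge_vertices)
  } else if (grepl("^\\s*solid", rawToChar(head84[1:15]))) {
    read_stl_ascii(path, merge_vertices)
  } else {
    stop(sprintf(
      "'%s': not ASCII STL and binary record size mismatch (file size %d, expected 84 + 50 * count)",
      path, size
    ))
  }
}

read_stl_binary <- function(path, size, merge_vertices) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  nt <- readBin(con, "integer", size = 4L, endian = "little")
  body <- readBin(con, "raw", n = 50L * nt)
  if (length(body) < 50L * nt) {
    stop(sprintf("truncated binary STL: expected %d bytes of facets, got %d (offset %d)",
                 50L * nt, length(body), 84L + length(body)))
  }
  m <- matrix(body, nrow = 50L)
  fl <- readBin(as.vector(m[1:48, , drop = FALSE]), "numeric", size = 4L,
                n = 12L * nt, endian = "little")
  rec <- matrix(fl, ncol = 12L, byrow = TRUE)
  soup_to_mesh(rec[, 4:12, drop = FALSE], merge_vertices)
}

read_stl_ascii <- function(path, merge_vertices) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) %% 3L != 0L) {
    stop(sprintf("malformed ASCII STL '%s': %d vertex lines (not a multiple of 3)",
                 path, length(vlines)))
  }
  coords <- vapply(strsplit(trimws(vlines), "\\s+"), function(tok) {
    as.numeric(tok[2:4])
  }, numeric(3))
  # coords is 3 x (3 * nfacet), vertex-major: reshape to one facet per row
  soup <- matrix(as.vector(coords), ncol = 9L, byrow = TRUE)
  soup_to_mesh(soup, merge_vertices)
}

# rows: v1x v1y v1z v2x ... v3z
soup_to_mesh <- function(soup, merge_vertices) {
  nt <- nrow(soup)
  verts <- rbind(soup[, 1:3, drop = FALSE], soup[, 4:6, drop = FALSE],
                 soup[, 7:9, drop = FALSE])
  faces <- cbind(seq_len(nt), seq_len(nt) + nt, seq_len(nt) + 2L * nt)
  if (merge_vertices && nt > 0) {
    key <- paste(verts[, 1], verts[, 2], verts[, 3], sep = "|")
    idx <- match(key, key)
    used <- sort(unique(idx))
    remap <- integer(nrow(verts))
    remap[used] <- seq_along(used)
    verts <- verts[used, , drop = FALSE]
    faces <- matrix(remap[idx[faces]], ncol = 3L)
  }
  triangle_mesh(verts, faces)
}
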