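#' Construct a surface mesh
#'
#' Triangulated surface in physical mm coordinates.
#'
#' @param vertices n x 3 numeric matrix of points (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param label source-mask label.
#' @return a \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, faces, label = "surface") {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (max(faces) > nrow(vertices) || min(faces) < 1L))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> '%s': %d vertices, %d faces\n", x$label,
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Extract an isosurface from a binary mask
#'
#' Marching-cubes-family surface extraction on the mask's 0/1 field at
#' \code{iso_level}, using the hole-free tetrahedral-decomposition variant
#' (each lattice cell is split into six Kuhn tetrahedra, which tile space
#' consistently, so closed objects always yield watertight surfaces).
#' Vertex coordinates are mapped to physical mm through the mask geometry,
#' with consistent outward orientation.
#'
#' By default the binary field is band-limited with a small Gaussian
#' (\code{smooth_sigma} = 0.7 voxel) before extraction. Raw 0/1 fields
#' force every surface vertex onto an edge midpoint, which inflates the
#' surface area of smooth objects by roughly 9\%; sub-voxel smoothing
#' restores both area and enclosed volume to within a few percent of the
#' underlying object. Set \code{smooth_sigma = 0} for the raw staircase
#' surface.
#'
#' The grid is zero-padded by one voxel so structures touching the volume
#' boundary still close.
#'
#' @param mask a non-empty \code{\link{binary_mask}}.
#' @param iso_level isovalue on the 0/1 field (default 0.5).
#' @param smooth_sigma Gaussian band-limiting sigma in voxels (0 disables).
#' @return a \code{\link{surface_mesh}}.
#' @export
extract_surface <- function(mask, iso_level = 0.5, smooth_sigma = 0.7) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask_voxel_count(mask) == 0L)
    stop("empty-mesh error: mask has no foreground voxels", call. = FALSE)
  d <- mask$geometry$dim
  field <- array(0, dim = d + 2L)
  field[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <-
    as.numeric(mask$bits)
  if (smooth_sigma > 0)
    field <- cpp_gauss3d(field, dim(field), smooth_sigma)
  res <- cpp_marching_tets(field, dim(field), iso_level)
  if (nrow(res$vertices) == 0L)
    stop("empty-mesh error: no isosurface at the requested level",
         call. = FALSE)
  # padded-grid index -> original 0-based index -> physical mm
  idx <- res$vertices - 1
  g <- mask$geometry
  verts <- t(g$origin + g$direction %*% (t(idx) * g$spacing))
  surface_mesh(verts, res$faces + 1L, label = mask$label)
}

#' Enclosed volume and surface area of a mesh
#'
#' Area is the sum of triangle areas; enclosed volume is the absolute sum
#' of signed tetrahedron volumes over faces (valid for watertight meshes;
#' the result also checks edge-manifoldness and flags the volume as
#' unreliable otherwise).
#'
#' @param mesh a \code{\link{surface_mesh}}.
#' @return list with \code{volume_mm3}, \code{area_mm2},
#'   \code{watertight} (every edge shared by exactly two faces),
#'   \code{volume_reliable}.
#' @export
mesh_measures <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0L)
    return(list(volume_mm3 = 0, area_mm2 = 0, watertight = FALSE,
                volume_reliable = FALSE))
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  vol <- abs(sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
                 a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
                 a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))) / 6
  wt <- is_watertight(mesh)
  list(volume_mm3 = vol, area_mm2 = area, watertight = wt,
       volume_reliable = wt)
}

#' Check that every mesh edge is shared by exactly two faces
#'
#' @param mesh a \code{\link{surface_mesh}}.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]),
               pmax(edges[, 1], edges[, 2]))
  all(table(key) == 2L)
}

#' Write a mesh as STL
#'
#' Binary dialect (default): 80-byte header, little-endian uint32 triangle
#' count, then 50 bytes per facet (normal + 3 vertices as float32 plus a
#' 2-byte attribute count). Facet normals are recomputed from the vertex
#' winding. The ASCII dialect writes the standard \code{solid} text form.
#'
#' @param mesh a \code{\link{surface_mesh}}.
#' @param file_path output path.
#' @param dialect \code{"binary"} or \code{"ascii"}.
#' @return the path, invisibly.
#' @export
write_stl <- function(mesh, file_path, dialect = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "surface_mesh"))
  dialect <- match.arg(dialect)
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(f)
  normals <- if (n > 0) {
    a <- v[f[, 1], , drop = FALSE]
    e1 <- v[f[, 2], , drop = FALSE] - a
    e2 <- v[f[, 3], , drop = FALSE] - a
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    len <- sqrt(rowSums(cr^2))
    cr / ifelse(len > 0, len, 1)
  } else matrix(0, 0, 3)
  con <- tryCatch(file(file_path, "wb"),
                  error = function(e) stop(sprintf(
                    "I/O error: cannot open %s for writing", file_path),
                    call. = FALSE))
  on.exit(close(con), add = TRUE)
  if (dialect == "binary") {
    header <- charToRaw(sprintf("%-80s", paste("renalseg", mesh$label)))
    writeBin(header[1:80], con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    if (n > 0) {
      # interleave: normal, v1, v2, v3 (12 floats) + attribute uint16
      dat <- t(cbind(normals, v[f[, 1], , drop = FALSE],
                     v[f[, 2], , drop = FALSE], v[f[, 3], , drop = FALSE]))
      for (i in seq_len(n)) {
        writeBin(as.numeric(dat[, i]), con, size = 4L, endian = "little")
        writeBin(as.integer(0), con, size = 2L, endian = "little")
      }
    }
  } else {
    writeLines(sprintf("solid %s", mesh$label), con)
    for (i in seq_len(n)) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", normals[i, 1],
                normals[i, 2], normals[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e", v[f[i, ], 1], v[f[i, ], 2],
                v[f[i, ], 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$label), con)
  }
  invisible(file_path)
}

#' Read a binary STL file
#'
#' Returns the triangle soup as a \code{\link{surface_mesh}} (vertices are
#' not merged).
#'
#' @param file_path path to a binary STL.
#' @return a \code{surface_mesh}.
#' @export
read_stl <- function(file_path) {
  if (!file.exists(file_path))
    stop(sprintf("I/O error: file not found: %s", file_path), call. = FALSE)
  bytes <- readBin(file_path, "raw", n = file.size(file_path))
  if (length(bytes) < 84L)
    stop("format error: truncated STL", call. = FALSE)
  n <- readBin(bytes[81:84], "integer", size = 4L, endian = "little")
  if (length(bytes) != 84L + 50L * n)
    stop("format error: STL byte length does not match triangle count",
         call. = FALSE)
  if (n == 0L)
    return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  verts <- matrix(0, 3L * n, 3L)
  faces <- matrix(0L, n, 3L)
  for (i in seq_len(n)) {
    off <- 84L + 50L * (i - 1L)
    vals <- readBin(bytes[(off + 1L):(off + 48L)], "double", n = 12L,
                    size = 4L, endian = "little")
    verts[3L * i - 2L, ] <- vals[4:6]
    verts[3L * i - 1L, ] <- vals[7:9]
    verts[3L * i, ] <- vals[10:12]
    faces[i, ] <- c(3L * i - 2L, 3L * i - 1L, 3L * i)
  }
  surface_mesh(verts, faces)
}
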