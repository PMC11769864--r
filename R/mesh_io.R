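# STL mesh input/output and declarative region selection.
#
# STL files carry no units; this package fixes millimetres as the canonical
# unit throughout. Note that binary STL stores float32 coordinates, which at
# ~50 mm coordinates quantizes at the micrometre scale; the ASCII dialect is
# written with full double precision and is the one to use when exactness at
# sub-micrometre level matters.

#' Triangle mesh container
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (!is.numeric(vertices) || ncol(vertices) != 3L) {
    stop("vertices must be an n x 3 numeric matrix", call. = FALSE)
  }
  if (nrow(faces) < 1L) stop("empty mesh: no faces", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# merge vertices that coincide within tol and drop zero-area faces
.clean_mesh <- function(vertices, faces, tol = 1e-9) {
  key <- apply(round(vertices / tol) * tol, 1L, paste, collapse = "|")
  first <- !duplicated(key)
  # new index of every old vertex = its position in the compacted table
  vmap <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(vmap[faces], ncol = 3L)
  # degenerate faces: repeated vertices or (near-)zero area
  keep <- vapply(seq_len(nrow(faces)), function(i) {
    f <- faces[i, ]
    if (anyDuplicated(f) > 0L) return(FALSE)
    a <- vertices[f[2L], ] - vertices[f[1L], ]
    b <- vertices[f[3L], ] - vertices[f[1L], ]
    .norm3(.cross3(a, b)) > 1e-12
  }, logical(1L))
  list(vertices = vertices, faces = faces[keep, , drop = FALSE])
}

#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL (auto-detected). Duplicate vertices closer than
#' 1e-9 mm are merged and zero-area facets dropped.
#'
#' @param path path to an STL file.
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path, call. = FALSE)
  size <- file.info(path)$size
  if (is.na(size) || size < 15L) {
    stop("STL format error in ", path, ": file too short (", size,
         " bytes, header incomplete at byte offset 0)", call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80L)
  looks_ascii <- identical(rawToChar(header[1:5]), "solid")
  is_binary <- FALSE
  ntri <- NA_integer_
  if (size >= 84L) {
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri)) {
      is_binary <- TRUE
    }
  }
  if (!is_binary && !looks_ascii) {
    stop("STL format error in ", path, ": binary facet section truncated (",
         size, " bytes, expected ",
         if (is.na(ntri)) "at least 84" else 84 + 50 * as.numeric(ntri),
         ") at byte offset ", size, call. = FALSE)
  }
  if (is_binary) {
    tris <- .read_stl_binary(con, ntri, path)
  } else {
    # ASCII: re-read as text
    close(con)
    on.exit()
    tris <- .read_stl_ascii(path)
  }
  if (nrow(tris) == 0L) stop("empty mesh: ", path, " has no facets", call. = FALSE)
  verts <- matrix(t(tris), ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  cleaned <- .clean_mesh(verts, faces)
  if (nrow(cleaned$faces) == 0L) {
    stop("empty mesh: ", path, " contains only degenerate facets", call. = FALSE)
  }
  triangle_mesh(cleaned$vertices, cleaned$faces)
}

# each row: x1 y1 z1 x2 y2 z2 x3 y3 z3
.read_stl_binary <- function(con, ntri, path) {
  out <- matrix(0, nrow = ntri, ncol = 9L)
  for (i in seq_len(ntri)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    if (length(rec) < 12L) {
      stop("STL format error in ", path, ": truncated facet record at byte offset ",
           84 + 50 * (i - 1), call. = FALSE)
    }
    attr_bytes <- readBin(con, "raw", n = 2L)
    if (length(attr_bytes) < 2L) {
      stop("STL format error in ", path, ": truncated attribute bytes at byte offset ",
           84 + 50 * (i - 1) + 48, call. = FALSE)
    }
    out[i, ] <- rec[4:12]
  }
  out
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vt <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vt) == 0L) stop("empty mesh: ", path, " has no facets", call. = FALSE)
  if (length(vt) %% 3L != 0L) {
    stop("STL format error in ", path, ": vertex count ", length(vt),
         " not a multiple of 3 (truncated facet near line ",
         utils::tail(grep("^\\s*vertex\\s", lines), 1L), ")", call. = FALSE)
  }
  nums <- vapply(strsplit(trimws(vt), "\\s+"), function(tok) {
    as.double(tok[2:4])
  }, double(3L))
  if (any(!is.finite(nums))) {
    stop("STL format error in ", path, ": non-numeric vertex coordinates",
         call. = FALSE)
  }
  matrix(as.vector(nums), ncol = 9L, byrow = TRUE)
}

#' Write a mesh as STL
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param dialect `"binary"` (float32 coordinates) or `"ascii"` (full double
#'   precision).
#' @return The path, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  dialect <- match.arg(dialect)
  v <- mesh$vertices
  f <- mesh$faces
  normals <- t(vapply(seq_len(nrow(f)), function(i) {
    a <- v[f[i, 2L], ] - v[f[i, 1L], ]
    b <- v[f[i, 3L], ] - v[f[i, 1L], ]
    n <- .cross3(a, b)
    nn <- .norm3(n)
    if (nn < 1e-12) c(0, 0, 0) else n / nn
  }, double(3L)))
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      rec <- c(normals[i, ], t(v[f[i, ], , drop = FALSE]))
      writeBin(as.numeric(rec), con, size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid archbar", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.12e %.12e %.12e",
                         normals[i, 1L], normals[i, 2L], normals[i, 3L]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        p <- v[f[i, k], ]
        writeLines(sprintf("      vertex %.12e %.12e %.12e", p[1L], p[2L], p[3L]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid archbar", con)
  }
  invisible(path)
}

#' Declarative mesh region selector
#'
#' Replaces interactive surface picking with a reproducible geometric
#' selector stored in the configuration: either an oriented box (center,
#' half-extents, rotation) or a seed point plus radius.
#'
#' @param name region name; the six bar-face regions are AP1, PP1, VP1,
#'   AP2, PP2, VP2.
#' @param type `"box"` or `"sphere"`.
#' @param center box center (mm), for `type = "box"`.
#' @param half_extents positive length-3 box half-extents (mm).
#' @param rotation 3 x 3 rotation whose columns are the box axes in the model
#'   frame.
#' @param seed_point sphere center (mm), for `type = "sphere"`.
#' @param radius positive sphere radius (mm).
#' @param outward_hint length-3 direction used to orient the fitted plane
#'   normal outward from the bar.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, type = c("box", "sphere"), center = NULL,
                        half_extents = NULL, rotation = diag(3),
                        seed_point = NULL, radius = NULL,
                        outward_hint = c(0, 0, 1)) {
  type <- match.arg(type)
  if (type == "box") {
    center <- .check_point3(center, "box center")
    half_extents <- .check_point3(half_extents, "box half-extents")
    if (any(half_extents <= 0)) stop("half-extents must be positive", call. = FALSE)
    rotation <- as.matrix(rotation)
    dimnames(rotation) <- NULL
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
      stop("box rotation must be orthonormal", call. = FALSE)
    }
  } else {
    seed_point <- .check_point3(seed_point, "seed point")
    if (!is.numeric(radius) || radius <= 0) stop("radius must be positive", call. = FALSE)
  }
  structure(list(name = name, type = type, center = center,
                 half_extents = half_extents, rotation = rotation,
                 seed_point = seed_point, radius = radius,
                 outward_hint = .check_point3(outward_hint, "outward hint")),
            class = "region_spec")
}

#' Select mesh vertices inside a region
#'
#' Deterministic and order-stable: vertices are returned in mesh order.
#'
#' @param mesh a [triangle_mesh()].
#' @param spec a [region_spec()].
#' @param min_points minimum number of vertices required (default 3, the
#'   plane-fitting minimum).
#' @return Matrix of selected vertex coordinates, with attribute `indices`.
#' @export
select_region <- function(mesh, spec, min_points = 3L) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(spec, "region_spec"))
  v <- mesh$vertices
  if (spec$type == "box") {
    local <- sweep(v, 2L, spec$center) %*% spec$rotation
    inside <- abs(local[, 1L]) <= spec$half_extents[1L] &
      abs(local[, 2L]) <= spec$half_extents[2L] &
      abs(local[, 3L]) <= spec$half_extents[3L]
  } else {
    d2 <- rowSums(sweep(v, 2L, spec$seed_point)^2)
    inside <- d2 <= spec$radius^2
  }
  idx <- unname(which(inside))
  if (length(idx) < min_points) {
    stop("insufficient region '", spec$name, "': selector matched ",
         length(idx), " vertices (need >= ", min_points, ")", call. = FALSE)
  }
  out <- v[idx, , drop = FALSE]
  attr(out, "indices") <- idx
  out
}
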