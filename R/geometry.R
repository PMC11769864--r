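# 3D primitives used by the bar constructions: oriented planes, lines,
# orthogonal least-squares plane fitting and the two intersection operations.
# All coordinates are in mm in the model frame; angles in degrees.

# parallelism cutoff on normalized cross/dot products
.PARALLEL_TOL <- 1e-6
# geometric identity assertions (mm)
.GEOM_TOL <- 1e-9

.norm3 <- function(v) sqrt(sum(v^2))

.unit3 <- function(v, what = "vector") {
  n <- .norm3(v)
  if (!is.finite(n) || n < .GEOM_TOL) {
    stop("degenerate geometry: cannot normalize near-zero ", what, call. = FALSE)
  }
  v / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.check_point3 <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 3L || !all(is.finite(p))) {
    stop(what, " must be a finite numeric vector of length 3", call. = FALSE)
  }
  as.double(p)
}

#' Oriented infinite plane
#'
#' A plane is stored as any point on it plus a unit normal. The representation
#' is invariant under the choice of the anchor point; two planes with the same
#' normal and zero point-to-plane offset are the same plane.
#'
#' @param point numeric length-3, any point on the plane (mm).
#' @param normal numeric length-3 normal direction; normalized internally.
#' @return An object of class `bar_plane` with elements `point` and `normal`.
#' @export
plane <- function(point, normal) {
  structure(list(point = .check_point3(point, "plane point"),
                 normal = .unit3(.check_point3(normal, "plane normal"), "plane normal")),
            class = "bar_plane")
}

#' Oriented 3D line
#'
#' @param point numeric length-3, any point on the line (mm).
#' @param direction numeric length-3 direction; normalized internally.
#' @return An object of class `bar_line` with elements `point` and `direction`.
#' @export
line3 <- function(point, direction) {
  structure(list(point = .check_point3(point, "line point"),
                 direction = .unit3(.check_point3(direction, "line direction"),
                                    "line direction")),
            class = "bar_line")
}

#' Signed distance from a point to a plane
#'
#' @param p numeric length-3 point (mm).
#' @param pl a [plane()].
#' @return Signed distance in mm (positive on the normal side).
#' @export
plane_distance <- function(p, pl) {
  sum((.check_point3(p) - pl$point) * pl$normal)
}

#' Fit a plane to a point cloud by orthogonal least squares
#'
#' Minimizes the sum of squared perpendicular distances: the fitted plane
#' passes through the centroid and its normal is the eigenvector of the
#' smallest eigenvalue of the centered second-moment matrix. This is the
#' standard analogue of a contact-feature plane construction in inspection
#' software.
#'
#' @param points an n x 3 numeric matrix (or coercible) of points, n >= 3,
#'   not all collinear.
#' @param outward_hint optional length-3 vector; the returned normal is
#'   flipped, if needed, to have positive dot product with the hint. Without a
#'   hint the eigenvector sign is arbitrary.
#' @return A [plane()] anchored at the centroid, with attribute `rms_residual`
#'   (mm, root-mean-square orthogonal residual).
#' @export
fit_plane <- function(points, outward_hint = NULL) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 3L) {
    stop("points must be an n x 3 numeric matrix", call. = FALSE)
  }
  if (nrow(pts) < 3L) {
    stop("degenerate geometry: plane fitting needs at least 3 points, got ",
         nrow(pts), call. = FALSE)
  }
  if (!all(is.finite(pts))) stop("points contain non-finite values", call. = FALSE)
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2L, ctr)
  mom <- crossprod(centered) / nrow(pts)
  eig <- eigen(mom, symmetric = TRUE)
  # eigenvalues descending; collinear clouds have a vanishing second eigenvalue
  scale2 <- max(eig$values[1L], .GEOM_TOL^2)
  if (eig$values[2L] / scale2 < 1e-12) {
    stop("degenerate geometry: points are collinear (rank-deficient cloud)",
         call. = FALSE)
  }
  normal <- eig$vectors[, 3L]
  if (!is.null(outward_hint)) {
    hint <- .check_point3(outward_hint, "outward hint")
    if (sum(normal * hint) < 0) normal <- -normal
  }
  out <- plane(ctr, normal)
  # residual from the projections themselves: the smallest eigenvalue only
  # carries eigen()'s absolute error (~1e-12 at cm-scale moments)
  attr(out, "rms_residual") <- sqrt(mean((centered %*% normal)^2))
  out
}

#' Intersect two planes
#'
#' @param a,b [plane()] objects; must not be (near-)parallel.
#' @return A [line3()] lying in both planes. Direction sign is arbitrary; use
#'   [orient_direction()] for the reporting convention.
#' @export
intersect_planes <- function(a, b) {
  stopifnot(inherits(a, "bar_plane"), inherits(b, "bar_plane"))
  d <- .cross3(a$normal, b$normal)
  nd <- .norm3(d)
  if (nd < .PARALLEL_TOL) {
    stop("degenerate geometry: planes are (near-)parallel, cannot intersect",
         call. = FALSE)
  }
  d <- d / nd
  # point on both planes: solve for the combination p = s*na + t*nb with
  # na.p = ca, nb.p = cb (unit normals)
  ca <- sum(a$normal * a$point)
  cb <- sum(b$normal * b$point)
  dot <- sum(a$normal * b$normal)
  den <- 1 - dot^2
  s <- (ca - cb * dot) / den
  t <- (cb - ca * dot) / den
  p <- s * a$normal + t * b$normal
  line3(p, d)
}

#' Intersect a line with a plane
#'
#' @param l a [line3()].
#' @param p a [plane()]; the line must not be (near-)parallel to it.
#' @return The intersection point, numeric length-3 (mm).
#' @export
intersect_line_plane <- function(l, p) {
  stopifnot(inherits(l, "bar_line"), inherits(p, "bar_plane"))
  denom <- sum(l$direction * p$normal)
  if (abs(denom) < .PARALLEL_TOL) {
    stop("degenerate geometry: line is (near-)parallel to the plane",
         call. = FALSE)
  }
  t <- sum((p$point - l$point) * p$normal) / denom
  l$point + t * l$direction
}

#' Parallel-shift a plane along a direction
#'
#' Every point of the plane moves by `distance * direction`; the normal is
#' unchanged. Used to construct the reference-length-shifted vestibular plane.
#'
#' @param p a [plane()].
#' @param direction length-3 shift direction; normalized internally.
#' @param distance shift distance in mm (finite; may be 0 or negative).
#' @return The shifted [plane()].
#' @export
translate_plane <- function(p, direction, distance) {
  stopifnot(inherits(p, "bar_plane"))
  if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance)) {
    stop("distance must be a finite scalar", call. = FALSE)
  }
  dir <- .unit3(.check_point3(direction, "shift direction"), "shift direction")
  plane(p$point + distance * dir, p$normal)
}

#' Resolve the sign of a line direction for reporting
#'
#' Directions feeding the arccos-based angle formulas must share a sign
#' convention, otherwise flipped lines report ~180 deg instead of ~0 deg.
#' The convention: positive X component; if the X component is (near-)zero,
#' fall back to positive Y, then positive Z.
#'
#' @param v length-3 direction vector.
#' @return The same direction, possibly negated.
#' @export
orient_direction <- function(v) {
  v <- .check_point3(v, "direction")
  for (i in 1:3) {
    if (abs(v[i]) >= .GEOM_TOL) {
      if (v[i] < 0) v <- -v
      return(v)
    }
  }
  v
}

#' Orthonormal right-handed reference frame
#'
#' The model frame of the analysis: X transversal (left-right, along the bar,
#' positive toward the first quadrant), Y anterior-posterior, Z vertical. The
#' XZ, XY and YZ coordinate planes play the roles of the coronal, transversal
#' and sagittal anatomical planes.
#'
#' @param origin frame origin in world coordinates (mm).
#' @param axes 3 x 3 matrix whose columns are the X, Y, Z unit axes in world
#'   coordinates; must be orthonormal and right-handed.
#' @return An object of class `bar_frame`.
#' @export
reference_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  origin <- .check_point3(origin, "frame origin")
  axes <- as.matrix(axes)
  if (!is.numeric(axes) || any(dim(axes) != c(3L, 3L))) {
    stop("axes must be a 3 x 3 numeric matrix", call. = FALSE)
  }
  if (max(abs(crossprod(axes) - diag(3))) > 1e-8) {
    stop("frame axes must be orthonormal", call. = FALSE)
  }
  if (det(axes) < 0) {
    stop("frame axes must be right-handed (det = +1)", call. = FALSE)
  }
  structure(list(origin = origin, axes = axes), class = "bar_frame")
}

#' Express world points in a reference frame
#'
#' @param points n x 3 matrix (or length-3 vector) of world coordinates (mm).
#' @param frame a [reference_frame()].
#' @return Coordinates in the frame, same shape as the input.
#' @export
to_frame <- function(points, frame) {
  stopifnot(inherits(frame, "bar_frame"))
  if (is.null(dim(points))) {
    return(drop(crossprod(frame$axes, .check_point3(points) - frame$origin)))
  }
  pts <- as.matrix(points)
  sweep(pts, 2L, frame$origin) %*% frame$axes
}

#' @export
print.bar_plane <- function(x, ...) {
  cat(sprintf("<plane> point (%.4f, %.4f, %.4f) normal (%.6f, %.6f, %.6f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' @export
print.bar_line <- function(x, ...) {
  cat(sprintf("<line> point (%.4f, %.4f, %.4f) direction (%.6f, %.6f, %.6f)\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}
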