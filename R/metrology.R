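# Per-scan bar metrology: from six fitted bar-end planes to the vectorial
# error V_E, the length deviation dL and the three angular deviations.
#
# Constructions: the anterior and posterior surfaces of each bar end (AP, PP)
# intersect in the horizontal edge vector of that end (V1, V2); each edge
# meets the vestibular end surface (VP) in the reference point (P1, P2). VP2
# is parallel-shifted by the certified bar length toward the first quadrant
# to give VP2'; its intersection with V2 is the constructed point P2'. V_E is
# the componentwise difference P1 - P2' (reported in micrometres), dL the
# difference between the measured P1-P2 distance and the certified length,
# and the angles compare the edge directions V1 vs V2: alpha_overall in 3D,
# alpha_coronal on the X,Y components, alpha_axial on the X,Z components.

RAD2DEG <- 180 / pi

#' Certified reference bar
#'
#' @param length_mm certified (coordinate-measuring-machine) bar length, mm.
#'   The default is the pipeline's reference bar, 55.066 mm.
#' @return An object of class `reference_bar`.
#' @export
reference_bar <- function(length_mm = 55.066) {
  if (!is.numeric(length_mm) || length(length_mm) != 1L ||
      !is.finite(length_mm) || length_mm <= 0) {
    stop("bar length must be a positive finite scalar (mm)", call. = FALSE)
  }
  structure(list(length_mm = as.double(length_mm)), class = "reference_bar")
}

#' Edge vector and reference point of one bar end
#'
#' Intersects the anterior and posterior planes into the bar-edge line
#' (orientation convention applied, see [orient_direction()]), then intersects
#' that line with the vestibular end plane to obtain the reference point.
#'
#' @param ap,pp,vp fitted [plane()]s of one bar end (anterior, posterior,
#'   vestibular).
#' @param quadrant 1 or 2, used only to annotate degenerate-geometry errors.
#' @return List with `line` (a [line3()]) and `point` (length-3, mm).
#' @export
construct_end_geometry <- function(ap, pp, vp, quadrant = NA) {
  edge <- tryCatch(intersect_planes(ap, pp), error = function(e) {
    stop("quadrant ", quadrant, ": ", conditionMessage(e), call. = FALSE)
  })
  edge <- line3(edge$point, orient_direction(edge$direction))
  pt <- tryCatch(intersect_line_plane(edge, vp), error = function(e) {
    stop("quadrant ", quadrant, ": ", conditionMessage(e), call. = FALSE)
  })
  list(line = edge, point = pt)
}

#' Construct the shifted reference point P2'
#'
#' Parallel-shifts the second-quadrant vestibular plane by the certified bar
#' length toward the first quadrant and intersects the shifted plane with the
#' second edge vector.
#'
#' @param v2 the second-quadrant edge [line3()].
#' @param vp2 the second-quadrant vestibular [plane()].
#' @param bar a [reference_bar()].
#' @param shift_direction unit direction from quadrant 2 toward quadrant 1
#'   (the model-frame +X axis under the standard frame).
#' @return The constructed point P2' (length-3, mm).
#' @export
construct_p2prime <- function(v2, vp2, bar, shift_direction) {
  stopifnot(inherits(bar, "reference_bar"))
  vp2p <- translate_plane(vp2, shift_direction, bar$length_mm)
  intersect_line_plane(v2, vp2p)
}

#' Vectorial error between P1 and P2'
#'
#' @param p1 reference point of the first quadrant (mm).
#' @param p2prime constructed point P2' (mm).
#' @return Named list: `VE` (length-3, micrometres, componentwise P1 - P2')
#'   and `VE_norm` (Euclidean norm, micrometres).
#' @export
vector_error <- function(p1, p2prime) {
  ve <- (.check_point3(p1) - .check_point3(p2prime)) * 1000
  list(VE = ve, VE_norm = .norm3(ve))
}

#' Length deviation of the measured bar
#'
#' Distance between the two measured reference points minus the certified
#' length, in micrometres.
#'
#' @param p1,p2 measured reference points (mm).
#' @param bar a [reference_bar()].
#' @return Scalar deviation in micrometres (negative = measured short).
#' @export
length_deviation <- function(p1, p2, bar) {
  stopifnot(inherits(bar, "reference_bar"))
  (.norm3(.check_point3(p2) - .check_point3(p1)) - bar$length_mm) * 1000
}

.angle_from_components <- function(u, v, what) {
  nu <- .norm3(u)
  nv <- .norm3(v)
  if (nu < .GEOM_TOL || nv < .GEOM_TOL) {
    stop("undefined projection: zero-length ", what, " component vector",
         call. = FALSE)
  }
  arg <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, arg))) * RAD2DEG
}

.as_direction <- function(v) {
  if (inherits(v, "bar_line")) v$direction else .check_point3(v, "direction")
}

#' Overall angular deviation between the two bar edges
#'
#' The full 3D angle between the edge directions,
#' `acos(<V1, V2> / (|V1| |V2|)) * 180 / pi`.
#'
#' @param v1,v2 edge directions ([line3()] or length-3 vectors) with the
#'   reporting orientation convention applied.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angle_overall <- function(v1, v2) {
  .angle_from_components(.as_direction(v1), .as_direction(v2), "3D")
}

#' Angular deviation projected on the X,Y components
#'
#' `acos` of the normalized dot product of the (X, Y) components only; the
#' torsion seen in the transversal view.
#'
#' @inheritParams angle_overall
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angle_coronal <- function(v1, v2) {
  .angle_from_components(.as_direction(v1)[1:2], .as_direction(v2)[1:2], "X,Y")
}

#' Angular deviation projected on the X,Z components
#'
#' `acos` of the normalized dot product of the (X, Z) components only; the
#' torsion seen in the coronal view.
#'
#' @inheritParams angle_overall
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angle_axial <- function(v1, v2) {
  .angle_from_components(.as_direction(v1)[c(1L, 3L)],
                         .as_direction(v2)[c(1L, 3L)], "X,Z")
}

#' Scan analysis configuration
#'
#' @param regions named list of six [region_spec()]s: AP1, PP1, VP1, AP2,
#'   PP2, VP2.
#' @param bar a [reference_bar()] (or its certified length in mm).
#' @param frame the model [reference_frame()] the scan is re-expressed in.
#' @param scan_id identifier recorded in the measurement.
#' @param strategy scanning-strategy label recorded in the measurement.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(regions, bar = reference_bar(),
                        frame = reference_frame(), scan_id = NA_character_,
                        strategy = NA_character_) {
  if (is.numeric(bar)) bar <- reference_bar(bar)
  stopifnot(inherits(bar, "reference_bar"), inherits(frame, "bar_frame"))
  needed <- c("AP1", "PP1", "VP1", "AP2", "PP2", "VP2")
  if (!all(needed %in% names(regions))) {
    stop("regions must name all of: ", paste(needed, collapse = ", "),
         "; missing: ", paste(setdiff(needed, names(regions)), collapse = ", "),
         call. = FALSE)
  }
  structure(list(regions = regions, bar = bar, frame = frame,
                 scan_id = scan_id, strategy = strategy),
            class = "scan_config")
}

#' Analyze one scan mesh into a bar measurement
#'
#' Re-expresses the mesh in the configured model frame, selects the six bar
#' face regions, fits the six planes by orthogonal least squares, runs the
#' edge/point constructions and returns the complete per-scan record.
#'
#' @param mesh a [triangle_mesh()].
#' @param config a [scan_config()]; region selectors and outward hints are
#'   interpreted in frame coordinates.
#' @return An object of class `bar_measurement`: list with `V1`, `V2`
#'   ([line3()]), `P1`, `P2`, `P2prime` (mm), `VE` (length-3, um), `VE_norm`
#'   (um), `deltaL` (um), `alpha_overall`, `alpha_coronal`, `alpha_axial`
#'   (degrees), `strategy`, `scan_id`.
#' @export
analyze_scan <- function(mesh, config) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(config, "scan_config"))
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop("scan '", config$scan_id, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  verts <- to_frame(mesh$vertices, config$frame)
  fmesh <- triangle_mesh(verts, mesh$faces)
  fit_region <- function(name) {
    spec <- config$regions[[name]]
    pts <- wrap(select_region(fmesh, spec))
    wrap(fit_plane(pts, outward_hint = spec$outward_hint))
  }
  planes <- lapply(stats::setNames(nm = c("AP1", "PP1", "VP1", "AP2", "PP2", "VP2")),
                   fit_region)
  end1 <- wrap(construct_end_geometry(planes$AP1, planes$PP1, planes$VP1, quadrant = 1))
  end2 <- wrap(construct_end_geometry(planes$AP2, planes$PP2, planes$VP2, quadrant = 2))
  # shift toward the first quadrant: sign of (P1 - P2) along the frame X axis
  sgn <- sign(end1$point[1L] - end2$point[1L])
  if (sgn == 0) sgn <- 1
  shift_dir <- c(sgn, 0, 0)
  p2prime <- wrap(construct_p2prime(end2$line, planes$VP2, config$bar, shift_dir))
  ve <- vector_error(end1$point, p2prime)
  measurement <- list(
    V1 = end1$line, V2 = end2$line,
    P1 = end1$point, P2 = end2$point, P2prime = p2prime,
    VE = ve$VE, VE_norm = ve$VE_norm,
    deltaL = length_deviation(end1$point, end2$point, config$bar),
    alpha_overall = wrap(angle_overall(end1$line, end2$line)),
    alpha_coronal = wrap(angle_coronal(end1$line, end2$line)),
    alpha_axial = wrap(angle_axial(end1$line, end2$line)),
    strategy = config$strategy, scan_id = config$scan_id
  )
  structure(measurement, class = "bar_measurement")
}

#' One-row data frame of a bar measurement
#'
#' Column layout of the per-scan CSV: scan_id, strategy, deltaL_um, VE_um,
#' VE_x_um, VE_y_um, VE_z_um, alpha_overall_deg, alpha_coronal_deg,
#' alpha_axial_deg.
#'
#' @param x a `bar_measurement`.
#' @param ... unused.
#' @export
as.data.frame.bar_measurement <- function(x, ...) {
  data.frame(
    scan_id = x$scan_id, strategy = x$strategy,
    deltaL_um = x$deltaL, VE_um = x$VE_norm,
    VE_x_um = x$VE[1L], VE_y_um = x$VE[2L], VE_z_um = x$VE[3L],
    alpha_overall_deg = x$alpha_overall,
    alpha_coronal_deg = x$alpha_coronal,
    alpha_axial_deg = x$alpha_axial,
    stringsAsFactors = FALSE
  )
}

#' @export
print.bar_measurement <- function(x, ...) {
  cat(sprintf("<bar_measurement> scan %s (strategy %s)\n", x$scan_id, x$strategy))
  cat(sprintf("  dL = %.2f um, |V_E| = %.2f um, V_E = (%.2f, %.2f, %.2f) um\n",
              x$deltaL, x$VE_norm, x$VE[1L], x$VE[2L], x$VE[3L]))
  cat(sprintf("  alpha overall/coronal/axial = %.4f / %.4f / %.4f deg\n",
              x$alpha_overall, x$alpha_coronal, x$alpha_axial))
  invisible(x)
}

.measurement_columns <- c("scan_id", "strategy", "deltaL_um", "VE_um",
                          "VE_x_um", "VE_y_um", "VE_z_um",
                          "alpha_overall_deg", "alpha_coronal_deg",
                          "alpha_axial_deg")
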