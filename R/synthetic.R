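# Synthetic scan generator: a parametric arch ribbon plus two bar-end prisms
# whose outer end faces are exactly the certified bar length apart, with a
# known injected per-scan distortion (rigid transform of the second bar end
# plus isotropic vertex noise). The physical bar is a precision square whose
# anterior and posterior surfaces meet in the upper edge; the generator uses
# a rhombic prism cross-section so that the AP and PP faces intersect in
# that edge, which is what the downstream constructions measure.
#
# The generator is the ground-truth side of the pipeline: every distortion it
# injects can be propagated in closed form to the expected measurement, so
# recovery of V_E and the angular deviations is testable without any
# physical scan.

#' Synthetic model specification
#'
#' Defaults reproduce the study geometry: a 55.066 mm reference bar of which
#' at most 20 mm of each end is captured, spanning a full-arch surface.
#'
#' @param bar_length_mm distance between the two outer (vestibular) end
#'   faces; the certified reference length.
#' @param bar_width_mm,bar_height_mm full width (Y) and height (Z) of the
#'   rhombic bar cross-section.
#' @param captured_end_length_mm length of each bar end present in the mesh
#'   (<= 20, the study's capture rule).
#' @param arch_radius_mm,arch_width_mm radius and radial width of the arch
#'   ribbon connecting the bar ends.
#' @param resolution_mm target mesh edge length.
#' @param seed recorded for bookkeeping; the construction itself is
#'   deterministic.
#' @return An object of class `synthetic_model_spec`.
#' @export
synthetic_model_spec <- function(bar_length_mm = 55.066,
                                 bar_width_mm = 6, bar_height_mm = 6,
                                 captured_end_length_mm = 18,
                                 arch_radius_mm = bar_length_mm / 2,
                                 arch_width_mm = 8,
                                 resolution_mm = 0.4,
                                 seed = NULL) {
  if (captured_end_length_mm > 20) {
    stop("captured_end_length_mm must be <= 20 (study capture rule)", call. = FALSE)
  }
  if (captured_end_length_mm <= 0 || resolution_mm <= 0 ||
      bar_width_mm <= 0 || bar_height_mm <= 0 || bar_length_mm <= 0) {
    stop("all dimensions must be positive", call. = FALSE)
  }
  if (2 * captured_end_length_mm >= bar_length_mm) {
    stop("captured ends overlap: 2 * captured_end_length_mm must be < bar_length_mm",
         call. = FALSE)
  }
  structure(list(bar_length_mm = bar_length_mm,
                 bar_width_mm = bar_width_mm, bar_height_mm = bar_height_mm,
                 captured_end_length_mm = captured_end_length_mm,
                 arch_radius_mm = arch_radius_mm, arch_width_mm = arch_width_mm,
                 resolution_mm = resolution_mm, seed = seed),
            class = "synthetic_model_spec")
}

# grid mesh of a planar quad patch: origin + u*su + v*sv, s in [0,1]
.mesh_patch <- function(origin, u, v, nu, nv) {
  su <- seq(0, 1, length.out = nu)
  sv <- seq(0, 1, length.out = nv)
  verts <- matrix(0, nrow = nu * nv, ncol = 3L)
  k <- 1L
  for (j in seq_len(nv)) {
    for (i in seq_len(nu)) {
      verts[k, ] <- origin + su[i] * u + sv[j] * v
      k <- k + 1L
    }
  }
  faces <- matrix(0L, nrow = 2L * (nu - 1L) * (nv - 1L), ncol = 3L)
  k <- 1L
  for (j in seq_len(nv - 1L)) {
    for (i in seq_len(nu - 1L)) {
      a <- (j - 1L) * nu + i
      b <- a + 1L
      cc <- a + nu
      d <- cc + 1L
      faces[k, ] <- c(a, b, d); k <- k + 1L
      faces[k, ] <- c(a, d, cc); k <- k + 1L
    }
  }
  list(vertices = verts, faces = faces)
}

# fan-triangulated rhombus cap at fixed x, ring subdivided to match the side
# face grids (nt points per edge)
.mesh_cap <- function(x, a, b, nt, flip = FALSE) {
  corners <- list(c(0, a, 0), c(0, 0, b), c(0, -a, 0), c(0, 0, -b))
  ring <- list()
  for (e in 1:4) {
    p0 <- corners[[e]]
    p1 <- corners[[if (e == 4L) 1L else e + 1L]]
    tt <- seq(0, 1, length.out = nt)[-nt]  # drop endpoint, next edge supplies it
    for (t in tt) ring[[length(ring) + 1L]] <- (1 - t) * p0 + t * p1
  }
  ring <- do.call(rbind, ring)
  ring[, 1L] <- x
  center <- c(x, 0, 0)
  verts <- rbind(center, ring)
  nring <- nrow(ring)
  faces <- matrix(0L, nrow = nring, ncol = 3L)
  for (i in seq_len(nring)) {
    j <- if (i == nring) 1L else i + 1L
    faces[i, ] <- if (flip) c(1L, 1L + j, 1L + i) else c(1L, 1L + i, 1L + j)
  }
  list(vertices = verts, faces = faces)
}

.combine_patches <- function(patches) {
  verts <- do.call(rbind, lapply(patches, `[[`, "vertices"))
  offs <- cumsum(c(0L, vapply(patches, function(p) nrow(p$vertices), integer(1L))))
  faces <- do.call(rbind, lapply(seq_along(patches), function(i) {
    patches[[i]]$faces + offs[i]
  }))
  list(vertices = verts, faces = faces)
}

#' Generate the synthetic reference model
#'
#' Builds the undistorted mesh (arch ribbon plus two rhombic bar-end prisms
#' whose outer end faces are exactly `bar_length_mm` apart), the six face
#' [region_spec()]s, an end-2 selector for distortion injection, and the
#' ground-truth record (true edge points, edge direction and end-2 centroid)
#' used by [propagate_distortion()].
#'
#' Model frame: X along the bar (positive toward the first quadrant), Y
#' anterior, Z vertical; the bar top edge runs along `{y = 0, z = height/2}`.
#'
#' @param spec a [synthetic_model_spec()].
#' @return List with `mesh`, `regions` (named list AP1...VP2), `end2_region`,
#'   and `truth` (list: `P1`, `P2`, `V_dir`, `bar_length_mm`,
#'   `end2_centroid`, `vertex_count`, `spec`).
#' @export
generate_reference_model <- function(spec = synthetic_model_spec()) {
  stopifnot(inherits(spec, "synthetic_model_spec"))
  L <- spec$bar_length_mm
  a <- spec$bar_width_mm / 2
  b <- spec$bar_height_mm / 2
  cap <- spec$captured_end_length_mm
  res <- spec$resolution_mm
  s <- sqrt(a^2 + b^2)           # cross-sectional face width
  nu <- max(2L, ceiling(cap / res) + 1L)
  nt <- max(2L, ceiling(s / res) + 1L)

  # cross-section corners (y, z): front (anterior), top, back, bottom
  # side faces as (start corner, end corner, name stem); AP: front->top,
  # PP: top->back (outward normals (0,b,a)/s and (0,-b,a)/s)
  edges <- list(AP = list(c(a, 0), c(0, b)),
                PP = list(c(0, b), c(-a, 0)),
                PL = list(c(-a, 0), c(0, -b)),
                AL = list(c(0, -b), c(a, 0)))
  prism <- function(x0) {
    patches <- lapply(edges, function(e) {
      p0 <- c(x0, e[[1L]][1L], e[[1L]][2L])
      v <- c(0, e[[2L]][1L] - e[[1L]][1L], e[[2L]][2L] - e[[1L]][2L])
      .mesh_patch(p0, c(cap, 0, 0), v, nu, nt)
    })
    patches
  }
  end1 <- prism(L / 2 - cap)
  end2 <- prism(-L / 2)
  cap1o <- .mesh_cap(L / 2, a, b, nt)                 # VP1, outward +X
  cap1i <- .mesh_cap(L / 2 - cap, a, b, nt, flip = TRUE)
  cap2o <- .mesh_cap(-L / 2, a, b, nt, flip = TRUE)   # VP2, outward -X
  cap2i <- .mesh_cap(-L / 2 + cap, a, b, nt)

  # arch ribbon: semicircle bulging anteriorly (+Y), below the bar
  z0 <- -(b + 6)
  r <- spec$arch_radius_mm
  w <- spec$arch_width_mm
  narc <- max(8L, ceiling(pi * r / res) + 1L)
  nrad <- max(2L, ceiling(w / res) + 1L)
  theta <- seq(0, pi, length.out = narc)
  rad <- seq(r - w / 2, r + w / 2, length.out = nrad)
  averts <- matrix(0, nrow = narc * nrad, ncol = 3L)
  k <- 1L
  for (j in seq_len(nrad)) {
    for (i in seq_len(narc)) {
      averts[k, ] <- c(rad[j] * cos(theta[i]), rad[j] * sin(theta[i]), z0)
      k <- k + 1L
    }
  }
  afaces <- .mesh_patch(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), narc, nrad)$faces
  arch <- list(vertices = averts, faces = afaces)

  raw <- .combine_patches(c(end1, list(cap1o, cap1i), end2,
                            list(cap2o, cap2i), list(arch)))
  cleaned <- .clean_mesh(raw$vertices, raw$faces)
  mesh <- triangle_mesh(cleaned$vertices, cleaned$faces)

  # region selectors: shrink side-face boxes in-plane so distorted meshes do
  # not leak neighbouring-face vertices into a fit; side-face thickness
  # tolerates distortions up to ~0.4 mm. The end-cap (VP) selector thickness
  # is half the axial grid step: it must exclude the first side-face grid
  # line, which also bounds the tolerated end translation along X to
  # ~resolution/2.
  thick <- 0.6
  thick_vp <- cap / (nu - 1L) / 2
  shrink <- 0.8
  if (cap / 2 - shrink <= res / 2 || s / 2 - shrink <= res / 4) {
    stop("resolution too coarse for the face selectors: fewer than 3 ",
         "interior vertices per face; refine resolution_mm or enlarge the bar",
         call. = FALSE)
  }
  side_box <- function(name, x_center, edge) {
    p0 <- edge[[1L]]; p1 <- edge[[2L]]
    mid <- (p0 + p1) / 2
    u2 <- c(0, p1 - p0) / s                  # in-plane cross direction
    n <- .cross3(u2, c(1, 0, 0))             # outward normal of the face
    region_spec(name, "box",
                center = c(x_center, mid[1L], mid[2L]),
                half_extents = c(cap / 2 - shrink, s / 2 - shrink, thick),
                rotation = cbind(c(1, 0, 0), u2, n),
                outward_hint = n)
  }
  x1 <- L / 2 - cap / 2
  x2 <- -L / 2 + cap / 2
  regions <- list(
    AP1 = side_box("AP1", x1, edges$AP),
    PP1 = side_box("PP1", x1, edges$PP),
    VP1 = region_spec("VP1", "box", center = c(L / 2, 0, 0),
                      half_extents = c(thick_vp, a + 0.1, b + 0.1),
                      outward_hint = c(1, 0, 0)),
    AP2 = side_box("AP2", x2, edges$AP),
    PP2 = side_box("PP2", x2, edges$PP),
    VP2 = region_spec("VP2", "box", center = c(-L / 2, 0, 0),
                      half_extents = c(thick_vp, a + 0.1, b + 0.1),
                      outward_hint = c(-1, 0, 0))
  )
  # sanity: every face selector must resolve on the undistorted mesh
  for (rg in regions) select_region(mesh, rg)

  end2_region <- region_spec("END2", "box",
                             center = c(x2, 0, 0),
                             half_extents = c(cap / 2 + 2, a + 2, b + 2),
                             outward_hint = c(-1, 0, 0))
  end2_pts <- select_region(mesh, end2_region)
  truth <- list(P1 = c(L / 2, 0, b), P2 = c(-L / 2, 0, b),
                V_dir = c(1, 0, 0),
                bar_length_mm = L,
                end2_centroid = colMeans(end2_pts),
                vertex_count = nrow(mesh$vertices),
                spec = spec)
  list(mesh = mesh, regions = regions, end2_region = end2_region, truth = truth)
}

#' Per-scan distortion parameters
#'
#' The distortion model: the second bar end is rigidly moved (rotation about
#' the end-2 centroid, then translation), emulating the cumulative stitching
#' error across the arch, and isotropic Gaussian noise is added to every
#' vertex, emulating surface measurement noise.
#'
#' @param translation_um length-3 end-2 translation, micrometres.
#' @param rotation_deg length-3 rotations about the X, Y, Z axes through the
#'   end-2 centroid, degrees (applied as Rz Ry Rx).
#' @param noise_sigma_um isotropic per-coordinate vertex noise SD,
#'   micrometres (>= 0).
#' @param seed optional seed making the noise reproducible in isolation; when
#'   `NULL` the current RNG stream is used.
#' @param center optional explicit rotation center (mm); default is the
#'   centroid of the selected end-2 vertices.
#' @return An object of class `distortion_params`.
#' @export
distortion_params <- function(translation_um = c(0, 0, 0),
                              rotation_deg = c(0, 0, 0),
                              noise_sigma_um = 0, seed = NULL, center = NULL) {
  translation_um <- .check_point3(translation_um, "translation")
  rotation_deg <- .check_point3(rotation_deg, "rotation")
  if (!is.numeric(noise_sigma_um) || noise_sigma_um < 0) {
    stop("noise_sigma_um must be >= 0", call. = FALSE)
  }
  if (!is.null(center)) center <- .check_point3(center, "rotation center")
  structure(list(translation_um = translation_um, rotation_deg = rotation_deg,
                 noise_sigma_um = noise_sigma_um, seed = seed, center = center),
            class = "distortion_params")
}

.rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  cx <- cos(r[1L]); sx <- sin(r[1L])
  cy <- cos(r[2L]); sy <- sin(r[2L])
  cz <- cos(r[3L]); sz <- sin(r[3L])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a scan distortion to the reference mesh
#'
#' @param mesh the undistorted [triangle_mesh()].
#' @param end2_region [region_spec()] selecting the end-2 vertex set.
#' @param params a [distortion_params()].
#' @return The distorted [triangle_mesh()].
#' @export
apply_distortion <- function(mesh, end2_region, params) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(params, "distortion_params"))
  v <- mesh$vertices
  pts <- select_region(mesh, end2_region)
  idx <- attr(pts, "indices")
  ctr <- if (is.null(params$center)) colMeans(pts) else params$center
  R <- .rotation_matrix(params$rotation_deg)
  t_mm <- params$translation_um / 1000
  moved <- sweep(sweep(v[idx, , drop = FALSE], 2L, ctr) %*% t(R), 2L,
                 ctr + t_mm, FUN = "+")
  v[idx, ] <- moved
  if (params$noise_sigma_um > 0) {
    add_noise <- function() {
      v + matrix(stats::rnorm(length(v), 0, params$noise_sigma_um / 1000),
                 ncol = 3L)
    }
    v <- if (is.null(params$seed)) add_noise() else {
      withr::with_seed(params$seed, add_noise())
    }
  }
  triangle_mesh(v, mesh$faces)
}

#' Closed-form propagation of a distortion to the expected measurement
#'
#' Propagates the injected rigid end-2 transform through the exact geometry
#' (no meshing, no noise) using the same plane/line constructions the
#' analysis applies to fitted planes: the expected V_E is the negated
#' translation plus the rotation-induced offset of the edge point, and the
#' expected angles compare the rotated edge direction with the X axis.
#'
#' @param truth ground-truth record from [generate_reference_model()] (or
#'   [reference_truth()] for the meshless fast path).
#' @param params a [distortion_params()] (noise is ignored: this is the
#'   noise-free expectation).
#' @return One-row data frame in the per-scan measurement layout.
#' @export
propagate_distortion <- function(truth, params) {
  stopifnot(inherits(params, "distortion_params"))
  L <- truth$bar_length_mm
  bar <- reference_bar(L)
  ctr <- if (is.null(params$center)) truth$end2_centroid else params$center
  R <- .rotation_matrix(params$rotation_deg)
  t_mm <- params$translation_um / 1000
  xform <- function(p) drop(R %*% (p - ctr)) + ctr + t_mm
  v1 <- line3(truth$P1, orient_direction(truth$V_dir))
  v2 <- line3(xform(truth$P2), orient_direction(drop(R %*% truth$V_dir)))
  vp2 <- plane(xform(c(-L / 2, 0, 0)), drop(R %*% c(-1, 0, 0)))
  p2 <- intersect_line_plane(v2, vp2)
  sgn <- sign(truth$P1[1L] - p2[1L]); if (sgn == 0) sgn <- 1
  p2prime <- construct_p2prime(v2, vp2, bar, c(sgn, 0, 0))
  ve <- vector_error(truth$P1, p2prime)
  data.frame(
    deltaL_um = length_deviation(truth$P1, p2, bar),
    VE_um = ve$VE_norm,
    VE_x_um = ve$VE[1L], VE_y_um = ve$VE[2L], VE_z_um = ve$VE[3L],
    alpha_overall_deg = angle_overall(v1, v2),
    alpha_coronal_deg = angle_coronal(v1, v2),
    alpha_axial_deg = angle_axial(v1, v2)
  )
}

#' Meshless ground truth for the fast simulation path
#'
#' The analytic truth record of [synthetic_model_spec()] geometry, with the
#' end-2 centroid at the captured-prism center (its value by symmetry).
#'
#' @param spec a [synthetic_model_spec()].
#' @return Truth record as in [generate_reference_model()].
#' @export
reference_truth <- function(spec = synthetic_model_spec()) {
  stopifnot(inherits(spec, "synthetic_model_spec"))
  L <- spec$bar_length_mm
  list(P1 = c(L / 2, 0, spec$bar_height_mm / 2),
       P2 = c(-L / 2, 0, spec$bar_height_mm / 2),
       V_dir = c(1, 0, 0), bar_length_mm = L,
       end2_centroid = c(-(L / 2 - spec$captured_end_length_mm / 2), 0, 0),
       vertex_count = NA_integer_, spec = spec)
}

#' Scanning-strategy error profile
#'
#' Distribution of per-scan distortions for one strategy: each component of
#' the end-2 translation and rotation is drawn independently from a normal
#' with the given location and scale.
#'
#' @param strategy_id label, e.g. `"FL"` (segmentation F/H/S x movement
#'   L/Z/C).
#' @param t_loc_um,t_scale_um length-3 location/scale of the translation
#'   components, micrometres.
#' @param r_loc_deg,r_scale_deg length-3 location/scale of the rotation
#'   components (about X, Y, Z), degrees.
#' @param noise_sigma_um vertex noise SD, micrometres (mesh path only).
#' @return An object of class `strategy_profile`.
#' @export
strategy_profile <- function(strategy_id, t_loc_um = c(0, 0, 0),
                             t_scale_um = c(0, 0, 0),
                             r_loc_deg = c(0, 0, 0),
                             r_scale_deg = c(0, 0, 0),
                             noise_sigma_um = 5) {
  if (any(t_scale_um < 0) || any(r_scale_deg < 0) || noise_sigma_um < 0) {
    stop("scales must be >= 0", call. = FALSE)
  }
  structure(list(strategy_id = strategy_id,
                 t_loc_um = .check_point3(t_loc_um),
                 t_scale_um = .check_point3(t_scale_um),
                 r_loc_deg = .check_point3(r_loc_deg),
                 r_scale_deg = .check_point3(r_scale_deg),
                 noise_sigma_um = noise_sigma_um),
            class = "strategy_profile")
}

#' Default nine-strategy profiles
#'
#' The 3 x 3 grid of scan-area segmentation (F = full jaw, H = half jaw,
#' S = sextant) and movement pattern (L = linear, Z = zig-zag, C = combined).
#' Translation and rotation magnitudes are configuration values shaped on the
#' order of magnitude typical for full-arch intraoral scans (tens to a few
#' hundred micrometres, tenths of a degree), with the zig-zag and sextant
#' strategies given larger scales.
#'
#' @return Named list of nine [strategy_profile()]s.
#' @export
default_strategy_profiles <- function() {
  # strategy_id, t_loc (x,y,z) um, t_scale um, rot loc/scale about (X,Y,Z) deg
  tbl <- list(
    FL = list(t = c(68, 34, -121), ts = c(59, 61, 75),
              r = c(0.05, 0.09, 0.17), rs = c(0.04, 0.06, 0.13)),
    FZ = list(t = c(50, -42, -148), ts = c(96, 257, 185),
              r = c(0.08, 0.32, 0.33), rs = c(0.06, 0.38, 0.35)),
    FC = list(t = c(61, 53, -26), ts = c(80, 133, 91),
              r = c(0.05, 0.14, 0.15), rs = c(0.04, 0.15, 0.10)),
    HL = list(t = c(50, -69, -13), ts = c(46, 164, 108),
              r = c(0.06, 0.22, 0.15), rs = c(0.05, 0.18, 0.12)),
    HZ = list(t = c(81, -148, -154), ts = c(99, 241, 74),
              r = c(0.07, 0.22, 0.18), rs = c(0.05, 0.21, 0.14)),
    HC = list(t = c(84, -41, -46), ts = c(68, 142, 166),
              r = c(0.06, 0.17, 0.20), rs = c(0.05, 0.13, 0.16)),
    SL = list(t = c(75, -19, -128), ts = c(73, 149, 118),
              r = c(0.06, 0.19, 0.21), rs = c(0.05, 0.32, 0.15)),
    SZ = list(t = c(89, -116, -78), ts = c(133, 284, 282),
              r = c(0.09, 0.30, 0.30), rs = c(0.07, 0.35, 0.19)),
    SC = list(t = c(78, -11, -43), ts = c(88, 208, 142),
              r = c(0.08, 0.31, 0.26), rs = c(0.06, 0.49, 0.33))
  )
  lapply(stats::setNames(nm = names(tbl)), function(id) {
    e <- tbl[[id]]
    strategy_profile(id, t_loc_um = e$t, t_scale_um = e$ts,
                     r_loc_deg = e$r, r_scale_deg = e$rs)
  })
}

.draw_distortion <- function(profile) {
  distortion_params(
    translation_um = stats::rnorm(3L, profile$t_loc_um, profile$t_scale_um),
    rotation_deg = stats::rnorm(3L, profile$r_loc_deg, profile$r_scale_deg),
    noise_sigma_um = profile$noise_sigma_um
  )
}

#' Simulate a multi-strategy scan study
#'
#' Draws `n_per_group` per-scan distortions per strategy profile and returns
#' the per-scan measurement records. The fast path (default) propagates each
#' drawn distortion in closed form without meshing; the mesh path generates
#' the reference mesh once, applies each distortion (including vertex noise)
#' and runs the full plane-fitting analysis.
#'
#' @param profiles list of [strategy_profile()]s with distinct ids (default:
#'   the nine-strategy grid).
#' @param n_per_group scans per strategy (study design: 25).
#' @param seed integer seed; the whole study is reproducible from it.
#' @param fast logical; `TRUE` for the closed-form path.
#' @param spec a [synthetic_model_spec()].
#' @return Data frame with one row per scan in the per-scan measurement
#'   layout (`scan_id`, `strategy`, deviations in micrometres and degrees).
#' @export
simulate_strategy_study <- function(profiles = default_strategy_profiles(),
                                    n_per_group = 25, seed = 1,
                                    fast = TRUE,
                                    spec = synthetic_model_spec()) {
  ids <- vapply(profiles, `[[`, character(1L), "strategy_id")
  if (anyDuplicated(ids) > 0L) {
    stop("duplicate strategy ids: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  }
  if (n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    model <- if (fast) NULL else generate_reference_model(spec)
    truth <- if (fast) reference_truth(spec) else model$truth
    rows <- vector("list", length(profiles) * n_per_group)
    k <- 1L
    for (profile in profiles) {
      for (i in seq_len(n_per_group)) {
        d <- .draw_distortion(profile)
        rec <- if (fast) {
          propagate_distortion(truth, d)
        } else {
          mesh <- apply_distortion(model$mesh, model$end2_region, d)
          cfg <- scan_config(model$regions, reference_bar(spec$bar_length_mm),
                             scan_id = sprintf("%s_%02d", profile$strategy_id, i),
                             strategy = profile$strategy_id)
          as.data.frame(analyze_scan(mesh, cfg))[, -(1:2)]
        }
        rows[[k]] <- cbind(
          data.frame(scan_id = sprintf("%s_%02d", profile$strategy_id, i),
                     strategy = profile$strategy_id,
                     stringsAsFactors = FALSE),
          rec)
        k <- k + 1L
      }
    }
    do.call(rbind, rows)
  })
}
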