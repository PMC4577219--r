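# Scene construction: voxelized tissue label maps, needle electrodes, and
# the closed-form geometry helpers used for margin/hot-zone bookkeeping.
#
# Voxel membership is decided by a center-point test: a voxel belongs to a
# shape iff its center does. This is unbiased as spacing -> 0 and keeps
# rasterized volumes convergent to the closed forms.

#' Create a needle electrode
#'
#' Electrodes are straight needles with an exposed (active) conducting tip
#' segment and an insulated shaft behind it. The active segment runs from
#' the tip backwards along `-axis` for `exposure_length` mm and is modeled
#' as a flat-capped cylinder; the real conical tip is sub-voxel at the
#' default spacing and is ignored.
#'
#' @param tip deepest point of the needle, mm.
#' @param axis unit insertion direction (pointing from entry towards tip).
#' @param index integer identifier (1-based, matching protocol pair labels).
#' @param radius needle radius, mm (default 0.5; needle gauge is rarely
#'   reported, so this is configurable).
#' @param exposure_length active exposure, mm (default 20, the clinical
#'   setting for liver ablation).
#' @param insulated_length insulated shaft length behind the exposure, mm.
#' @export
electrode <- function(tip, axis, index, radius = 0.5, exposure_length = 20,
                      insulated_length = 60) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm) < 1e-12) stop("electrode axis must be a nonzero vector")
  if (abs(nrm - 1) > 1e-9) axis <- axis / nrm
  if (radius <= 0 || exposure_length <= 0 || insulated_length < 0)
    stop("electrode radius and exposure_length must be positive")
  structure(list(tip = as.numeric(tip), axis = axis, radius = radius,
                 exposure_length = exposure_length,
                 insulated_length = insulated_length,
                 index = as.integer(index)),
            class = "ire_electrode")
}

#' Create an empty scene on a voxel grid
#'
#' A scene bundles the voxel grid, the per-voxel tissue label array, the
#' electrode array and (optionally) a pulse protocol.
#'
#' @param grid a [build_grid()] voxel grid.
#' @param fill tissue filling the whole domain initially
#'   (`"background"` or `"liver"`).
#' @export
new_scene <- function(grid, fill = c("background", "liver")) {
  fill <- match.arg(fill)
  structure(list(grid = grid,
                 labels = array(label_code(fill), dim = grid$shape),
                 electrodes = list(),
                 protocol = NULL),
            class = "ire_scene")
}

#' @export
print.ire_scene <- function(x, ...) {
  cat(sprintf("<ire_scene> %d x %d x %d voxels @ %s mm, %d electrode(s)\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              paste(signif(x$grid$spacing, 3), collapse = "x"),
              length(x$electrodes)))
  vols <- label_volumes(x)
  for (nm in names(vols))
    if (vols[[nm]] > 0) cat(sprintf("  %-22s %8.3f cm^3\n", nm, vols[[nm]]))
  if (!is.null(x$protocol))
    cat(sprintf("  protocol: %d train(s), %d pulses\n",
                nrow(x$protocol), total_pulses(x$protocol)))
  invisible(x)
}

#' Volume of one label in cm^3
#' @param scene an `ire_scene`.
#' @param label label name (`"liver"`, `"tumor"`, `"vessel"`,
#'   `"background"`), or `"electrode_active"`/`"electrode_insulated"` with
#'   `index`.
#' @param index electrode index for electrode labels.
#' @export
label_volume <- function(scene, label, index = NULL) {
  code <- label_code(label, index)
  sum(scene$labels == code) * voxel_volume(scene$grid) / 1000
}

# All label volumes (cm^3), named.
label_volumes <- function(scene) {
  tab <- table(scene$labels)
  codes <- as.integer(names(tab))
  setNames(as.numeric(tab) * voxel_volume(scene$grid) / 1000, label_name(codes))
}

#' Rasterize an ellipsoid into a scene's label map
#'
#' Voxels whose centers satisfy the axis-aligned ellipsoid inequality
#' receive the label, overriding previous tissue labels (electrode voxels
#' are never overwritten).
#'
#' @param scene an `ire_scene`.
#' @param center ellipsoid center, mm.
#' @param semi_axes length-3 semi-axes, mm.
#' @param label tissue label name.
#' @return The updated scene. Warns (and changes nothing) if the ellipsoid
#'   misses the grid entirely.
#' @export
rasterize_ellipsoid <- function(scene, center, semi_axes, label = "tumor") {
  semi_axes <- rep_len(as.numeric(semi_axes), 3L)
  if (any(semi_axes <= 0)) stop("semi_axes must be positive")
  g <- scene$grid
  q <- lapply(1:3, function(a)
    ((axis_centers(g, a) - center[a]) / semi_axes[a])^2)
  inside <- outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+") <= 1
  if (!any(inside)) {
    warning("ellipsoid does not intersect the grid; no voxels labeled")
    return(scene)
  }
  scene$labels[inside & !is_electrode_voxel(scene$labels)] <-
    label_code(label)
  scene
}

is_electrode_voxel <- function(codes)
  is_active_code(codes) | is_insulated_code(codes)

# Mask of voxels within `radius` of segment p0--p1. caps = "round" gives a
# capsule (spherical caps), "flat" a finite cylinder. Voxels traversed by
# the axis itself are always included (thin-structure guarantee: needles
# thinner than the spacing still rasterize to a connected line of voxels).
segment_mask <- function(grid, p0, p1, radius, caps = c("round", "flat")) {
  caps <- match.arg(caps)
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 < 1e-18) stop("degenerate segment: p0 == p1")
  if (radius <= 0) stop("radius must be positive")
  co <- coordinate_arrays(grid)
  rx <- co$x - p0[1]; ry <- co$y - p0[2]; rz <- co$z - p0[3]
  t <- (rx * d[1] + ry * d[2] + rz * d[3]) / len2
  tc <- pmin(pmax(t, 0), 1)
  dist2 <- (rx - tc * d[1])^2 + (ry - tc * d[2])^2 + (rz - tc * d[3])^2
  mask <- if (caps == "round") dist2 <= radius^2
          else dist2 <= radius^2 & t >= 0 & t <= 1
  # thin-structure guarantee: walk the axis at half-voxel steps
  len <- sqrt(len2)
  ts <- seq(0, 1, by = min(grid$spacing) / (2 * len))
  pts <- cbind(p0[1] + ts * d[1], p0[2] + ts * d[2], p0[3] + ts * d[3])
  ijk <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")
  ijk <- floor(ijk) + 1
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= grid$shape[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= grid$shape[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= grid$shape[3]
  if (any(ok)) {
    lin <- ijk[ok, 1] + grid$shape[1] * (ijk[ok, 2] - 1) +
      grid$shape[1] * grid$shape[2] * (ijk[ok, 3] - 1)
    mask[lin] <- TRUE
  }
  mask
}

#' Rasterize a finite cylinder (capsule)
#'
#' Used for vessels. Voxels within `radius` of the segment `p0`--`p1` get
#' the label; voxels containing the axis are always labeled even when the
#' radius is below half the voxel spacing. Caps are flat by default (the
#' labeled volume converges to `pi r^2 h`); `caps = "round"` gives a true
#' capsule with hemispherical ends.
#'
#' @inheritParams rasterize_ellipsoid
#' @param p0,p1 segment end points, mm.
#' @param radius capsule radius, mm.
#' @param caps `"flat"` or `"round"`.
#' @export
rasterize_capsule <- function(scene, p0, p1, radius, label = "vessel",
                              caps = c("flat", "round")) {
  mask <- segment_mask(scene$grid, p0, p1, radius, caps = match.arg(caps))
  scene$labels[mask & !is_electrode_voxel(scene$labels)] <- label_code(label)
  scene
}

#' Place an electrode into a scene
#'
#' The active segment (tip backwards along the axis for `exposure_length`)
#' is labeled `electrode_active`, the following `insulated_length` labeled
#' `electrode_insulated`, both as flat-capped cylinders clipped to the
#' grid. Electrode voxels override tissue labels.
#'
#' @param scene an `ire_scene`.
#' @param e an [electrode()].
#' @export
place_electrode <- function(scene, e) {
  stopifnot(inherits(e, "ire_electrode"))
  if (any(vapply(scene$electrodes, function(x) x$index, 1L) == e$index))
    stop("electrode index ", e$index, " already present in scene")
  g <- scene$grid
  p_back <- e$tip - e$axis * e$exposure_length
  if (!point_in_grid(g, e$tip) || !point_in_grid(g, p_back))
    stop("active segment of electrode ", e$index, " lies outside the grid")
  act <- segment_mask(g, e$tip, p_back, e$radius, caps = "flat")
  scene$labels[act] <- label_code("electrode_active", e$index)
  if (e$insulated_length > 0) {
    p_end <- p_back - e$axis * e$insulated_length
    ins <- segment_mask(g, p_back, p_end, e$radius, caps = "flat")
    ins <- ins & !act
    scene$labels[ins] <- label_code("electrode_insulated", e$index)
  }
  scene$electrodes[[length(scene$electrodes) + 1L]] <- e
  scene
}

#' Pairwise electrode geometry
#'
#' Tip-to-tip Euclidean distances and inter-axis angles for every
#' unordered electrode pair, matching the layout of reconstructed-geometry
#' tables used in clinical IRE reports.
#'
#' @param scene an `ire_scene` (or a list of [electrode()]s).
#' @return data.frame with columns `pair`, `a`, `b`, `distance_mm`,
#'   `angle_deg`.
#' @export
pairwise_geometry <- function(scene) {
  el <- if (inherits(scene, "ire_scene")) scene$electrodes else scene
  if (length(el) < 2) stop("need at least two electrodes")
  el <- el[order(vapply(el, function(e) e$index, 1L))]
  rows <- list()
  for (i in seq_len(length(el) - 1))
    for (j in (i + 1):length(el)) {
      a <- el[[i]]; b <- el[[j]]
      dist <- sqrt(sum((a$tip - b$tip)^2))
      cosang <- min(1, abs(sum(a$axis * b$axis)))
      rows[[length(rows) + 1L]] <- data.frame(
        pair = sprintf("%d-%d", a$index, b$index),
        a = a$index, b = b$index,
        distance_mm = dist, angle_deg = acos(cosang) * 180 / pi)
    }
  do.call(rbind, rows)
}

#' Closed-form ellipsoid volume
#'
#' @param semi_axes length-3 semi-axes, mm.
#' @return Volume `4/3 * pi * a * b * c` in cm^3.
#' @examples
#' ellipsoid_volume(c(7, 4.5, 7.5))    # the 14 x 9 x 15 mm tumor: 0.990
#' @export
ellipsoid_volume <- function(semi_axes) {
  semi_axes <- rep_len(as.numeric(semi_axes), 3L)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("semi-axes must be positive")
  4 / 3 * pi * prod(semi_axes) / 1000
}

#' Safety-margin ellipsoid volume
#'
#' Volume of the tumor ellipsoid grown by a uniform surgical-type margin:
#' each semi-axis is increased by `margin` mm. With the conventional 1 cm
#' margin this is the minimum lesion volume a planner should target.
#'
#' @param tumor_diameters length-3 tumor diameters, mm.
#' @param margin margin added to each semi-axis, mm (>= 0).
#' @export
safety_margin_volume <- function(tumor_diameters, margin = 10) {
  if (margin < 0) stop("margin must be >= 0")
  ellipsoid_volume(rep_len(as.numeric(tumor_diameters), 3L) / 2 + margin)
}

#' Cylindrical hot-zone volume
#'
#' Closed-form estimate of the thermally affected volume as `n` cylinders
#' around the electrodes (radius = lateral extent of the hot zone, height =
#' active exposure plus the hot zone on either side).
#'
#' @param n number of electrodes.
#' @param radius cylinder radius, mm.
#' @param height cylinder height, mm.
#' @return total volume in cm^3.
#' @examples
#' cylinder_hot_zone_volume(4, 4, 28)   # 5.63 cm^3
#' @export
cylinder_hot_zone_volume <- function(n, radius = 4, height = 28) {
  if (n < 0 || radius <= 0 || height <= 0)
    stop("n must be >= 0 and radius/height positive")
  n * pi * radius^2 * height / 1000
}

# Embed four needle tips in 3D from the six pairwise distances
# (trilateration): tip 1 at the origin, tip 2 on +x, tip 3 in the xy
# plane, tip 4 resolved with z >= 0. Exact by construction.
embed_tips <- function(d) {
  # d: named distances "12","13","14","23","24","34" in mm
  p1 <- c(0, 0, 0)
  p2 <- c(d[["12"]], 0, 0)
  x3 <- (d[["13"]]^2 + d[["12"]]^2 - d[["23"]]^2) / (2 * d[["12"]])
  y3 <- sqrt(max(0, d[["13"]]^2 - x3^2))
  p3 <- c(x3, y3, 0)
  x4 <- (d[["14"]]^2 + d[["12"]]^2 - d[["24"]]^2) / (2 * d[["12"]])
  y4 <- (d[["14"]]^2 - d[["34"]]^2 + x3^2 + y3^2 - 2 * x4 * x3) / (2 * y3)
  z4 <- sqrt(max(0, d[["14"]]^2 - x4^2 - y4^2))
  p4 <- c(x4, y4, z4)
  list(p1, p2, p3, p4)
}

#' Synthetic four-electrode liver case
#'
#' Builds a deterministic voxel scene emulating a percutaneous IRE
#' treatment of a small liver metastasis adjacent to a hepatic vein:
#' a liver-filled cubic domain, an ellipsoidal tumor of 14 x 9 x 15 mm,
#' an 8 mm vessel running parallel to the needles and touching the tumor,
#' and four parallel needle electrodes (20 mm exposure) whose tip
#' distances reproduce the reconstructed clinical geometry
#' (pairs 1-2: 18, 1-3: 14, 1-4: 12, 2-3: 15, 2-4: 12, 3-4: 17 mm).
#' The reference pulse protocol ships with the package and is attached to
#' the returned scene.
#'
#' @param spacing voxel spacing, mm (1 for tests, 0.5 for production runs).
#' @param seed integer seed; controls the optional tip jitter only.
#' @param extent domain edge length, mm.
#' @param tumor_diameters tumor diameters, mm.
#' @param vessel_radius vessel radius, mm.
#' @param tip_jitter_mm s.d. of an isotropic Gaussian jitter applied to the
#'   needle tips (default 0: the stated geometry, bit-reproducible).
#' @return An `ire_scene` with attached protocol.
#' @export
synthetic_case <- function(spacing = 1, seed = 1L, extent = 80,
                           tumor_diameters = c(14, 9, 15),
                           vessel_radius = 4, tip_jitter_mm = 0) {
  grid <- build_grid(rep(extent, 3), spacing)
  center <- grid$origin + grid$shape * grid$spacing / 2
  semi <- tumor_diameters / 2

  # Needle tips from the reconstructed pairwise distances; needles run
  # along +z with the exposure mid-plane through the tumor center.
  tips <- embed_tips(c("12" = 18, "13" = 14, "14" = 12,
                       "23" = 15, "24" = 12, "34" = 17))
  xy <- do.call(rbind, tips)
  centroid <- colMeans(xy)
  exposure <- 20
  tips <- lapply(tips, function(p)
    c(p[1] - centroid[1] + center[1],
      p[2] - centroid[2] + center[2],
      p[3] - centroid[3] + center[3] + exposure / 2))
  if (tip_jitter_mm > 0) {
    set.seed(as.integer(seed))
    tips <- lapply(tips, function(p) p + stats::rnorm(3, 0, tip_jitter_mm))
  }

  scene <- new_scene(grid, fill = "liver")

  # Vessel: axis parallel to the needles, placed in the widest angular gap
  # between them so needles clear the lumen, at a distance that makes the
  # lumen touch the tumor surface (ellipse radius along the gap direction
  # plus the vessel radius).
  u <- c(0.755, 0.656); u <- u / sqrt(sum(u^2))
  r_ell <- 1 / sqrt((u[1] / semi[1])^2 + (u[2] / semi[2])^2)
  vx <- center[1] + u[1] * (r_ell + vessel_radius)
  vy <- center[2] + u[2] * (r_ell + vessel_radius)
  scene <- rasterize_capsule(scene,
                             c(vx, vy, grid$origin[3]),
                             c(vx, vy, grid$origin[3] + extent),
                             vessel_radius, "vessel")
  scene <- rasterize_ellipsoid(scene, center, semi, "tumor")

  for (k in 1:4)
    scene <- place_electrode(scene, electrode(
      tip = tips[[k]], axis = c(0, 0, 1), index = k,
      exposure_length = exposure,
      insulated_length = tips[[k]][3] - exposure - grid$origin[3]))

  scene$protocol <- table3_protocol()
  scene
}
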