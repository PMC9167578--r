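# 3D reconstruction of tendon geometry from tracked, segmented sweeps:
# pixel -> world rigid transforms, two-point length, cross-sectional areas,
# length-weighted mean CSA and trapezoidal volume integration.

#' Ultrasound spatial calibration
#'
#' The rigid transform taking image-plane coordinates into the probe frame,
#' together with the pixel spacing. Calibration is treated as a validated
#' input (as obtained from e.g. a single-wall phantom procedure).
#'
#' Pixel `(row, col)` maps to the in-plane point
#' `(col * spacing_col, row * spacing_row, 0)` mm, which is then rotated and
#' translated into the probe frame.
#'
#' @param pixel_spacing_mm Length-2 positive numeric: mm per pixel along
#'   (row, col).
#' @param rotation 3x3 orthonormal matrix or unit quaternion `(w,x,y,z)`.
#' @param translation Length-3 numeric, mm.
#' @return An object of class `us_calibration`.
#' @export
us_calibration <- function(pixel_spacing_mm = c(0.05, 0.05),
                           rotation = diag(3),
                           translation = c(0, 0, 0)) {
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 2 ||
      any(pixel_spacing_mm <= 0)) {
    stop("pixel_spacing_mm must be two positive values (row, col)")
  }
  R <- as_rotmat(rotation)
  stopifnot(is.numeric(translation), length(translation) == 3)
  structure(list(pixel_spacing_mm = pixel_spacing_mm,
                 rotation = R, translation = as.numeric(translation)),
            class = "us_calibration")
}

#' Probe pose
#'
#' Position and orientation of the tracked transducer in the world frame.
#'
#' @param rotation 3x3 orthonormal matrix or unit quaternion `(w,x,y,z)`.
#' @param translation Length-3 numeric, mm.
#' @return An object of class `probe_pose`.
#' @export
probe_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  R <- as_rotmat(rotation)
  stopifnot(is.numeric(translation), length(translation) == 3)
  structure(list(rotation = R, translation = as.numeric(translation)),
            class = "probe_pose")
}

#' Transform image pixels to world coordinates
#'
#' Composes calibration (image plane -> probe frame) with the probe pose
#' (probe frame -> world). The composition is rigid for fixed pixel spacing,
#' so pairwise distances are preserved up to the pixel-spacing scaling.
#'
#' @param pixel_rc Length-2 numeric `(row, col)` or an n x 2 matrix of pixels.
#'   Sub-pixel (non-integer) coordinates are allowed.
#' @param calibration A [us_calibration()].
#' @param pose A [probe_pose()].
#' @return Length-3 numeric (or n x 3 matrix) of world coordinates in mm.
#' @export
pixel_to_world <- function(pixel_rc, calibration, pose) {
  stopifnot(inherits(calibration, "us_calibration"),
            inherits(pose, "probe_pose"))
  px <- if (is.matrix(pixel_rc)) pixel_rc else matrix(pixel_rc, ncol = 2)
  if (ncol(px) != 2) stop("pixel_rc must have two columns (row, col)")
  sp <- calibration$pixel_spacing_mm
  # image-plane mm coordinates: x along columns, y along rows, z = 0
  plane <- cbind(px[, 2] * sp[2], px[, 1] * sp[1], 0)
  probe <- plane %*% t(calibration$rotation)
  probe <- sweep(probe, 2, calibration$translation, "+")
  world <- probe %*% t(pose$rotation)
  world <- sweep(world, 2, pose$translation, "+")
  if (is.matrix(pixel_rc)) world else drop(world)
}

#' Free-tendon length by the two-point method
#'
#' Euclidean distance between the two anatomical landmark points (calcaneal
#' notch and soleus muscle-tendon junction) in world coordinates. The
#' straight chord is used, consistent with a landmark-to-landmark length
#' tool on a short, near-straight tendon.
#'
#' @param landmark_a,landmark_b Length-3 numeric world points (mm), or `NULL`
#'   if the site was not marked.
#' @param names_ab Character length-2 used in error messages when a landmark
#'   is missing.
#' @return Length in mm.
#' @export
tendon_length <- function(landmark_a, landmark_b,
                          names_ab = c("calcaneal_notch", "soleus_mtj")) {
  if (is.null(landmark_a) || anyNA(landmark_a)) {
    stop("missing landmark: ", names_ab[1])
  }
  if (is.null(landmark_b) || anyNA(landmark_b)) {
    stop("missing landmark: ", names_ab[2])
  }
  stopifnot(length(landmark_a) == 3, length(landmark_b) == 3)
  sqrt(sum((as.numeric(landmark_a) - as.numeric(landmark_b))^2))
}

#' Area of a segmented cross-section contour
#'
#' Shoelace area of a simple polygon. 2D vertices are used as-is; 3D
#' vertices are checked for planarity (maximum out-of-plane deviation
#' 0.5 mm, matching the axial/lateral imaging resolution) and projected
#' onto their best-fit plane. The result is orientation-independent.
#'
#' @param polygon n x 2 or n x 3 numeric matrix of ordered vertices, n >= 3.
#' @param planarity_tol_mm Maximum allowed out-of-plane deviation for 3D
#'   contours (default 0.5 mm).
#' @return Area in mm^2 (same squared units as the vertices).
#' @export
contour_area <- function(polygon, planarity_tol_mm = 0.5) {
  p <- as.matrix(polygon)
  if (nrow(p) < 3) stop("a contour needs at least 3 vertices")
  if (!ncol(p) %in% c(2, 3)) stop("polygon must be n x 2 or n x 3")
  if (ncol(p) == 3) p <- project_to_plane(p, planarity_tol_mm)
  if (polygon_self_intersects(p)) {
    stop("contour polygon is self-intersecting")
  }
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Best-fit plane projection for a near-planar 3D polygon; errors when the
# out-of-plane spread exceeds tol.
project_to_plane <- function(p, tol) {
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  sv <- svd(q, nu = 0, nv = 3)
  dev <- abs(q %*% sv$v[, 3])
  if (max(dev) > tol) {
    stop(sprintf("contour is not planar: max out-of-plane deviation %.3f mm exceeds %.3f mm",
                 max(dev), tol))
  }
  q %*% sv$v[, 1:2]
}

# O(n^2) segment-intersection test; adjacent segments share endpoints and
# are skipped. Contours have tens of vertices, so this is cheap.
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg_a <- p
  seg_b <- p[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      d1 <- cross2(seg_a[j, 1], seg_a[j, 2], seg_b[j, 1], seg_b[j, 2], seg_a[i, 1], seg_a[i, 2])
      d2 <- cross2(seg_a[j, 1], seg_a[j, 2], seg_b[j, 1], seg_b[j, 2], seg_b[i, 1], seg_b[i, 2])
      d3 <- cross2(seg_a[i, 1], seg_a[i, 2], seg_b[i, 1], seg_b[i, 2], seg_a[j, 1], seg_a[j, 2])
      d4 <- cross2(seg_a[i, 1], seg_a[i, 2], seg_b[i, 1], seg_b[i, 2], seg_b[j, 1], seg_b[j, 2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

as_slice_table <- function(slices) {
  if (is.data.frame(slices)) {
    stopifnot(all(c("station_mm", "area_mm2") %in% names(slices)))
    df <- slices[, c("station_mm", "area_mm2")]
  } else if (is.list(slices)) {
    df <- data.frame(
      station_mm = vapply(slices, function(s) s$station_mm, numeric(1)),
      area_mm2   = vapply(slices, function(s) s$area_mm2, numeric(1))
    )
  } else {
    stop("slices must be a data.frame or a list of contour slices")
  }
  df
}

#' Reconstruct tendon volume from segmented cross-sections
#'
#' Linearly interpolates the cross-sectional area between consecutive slice
#' stations at resolution `step_mm` and integrates by the trapezoidal rule
#' over the full slice span. Exact for linear area profiles.
#'
#' @param slices Data frame with columns `station_mm` (arclength station
#'   along the tendon, strictly increasing) and `area_mm2`, or a list of
#'   slices with those fields.
#' @param step_mm Integration resolution, mm (default 0.1).
#' @return Volume in ml (1 ml = 1000 mm^3).
#' @export
reconstruct_volume <- function(slices, step_mm = 0.1) {
  df <- as_slice_table(slices)
  if (nrow(df) < 2) stop("need at least 2 slices to reconstruct a volume")
  if (is.unsorted(df$station_mm, strictly = TRUE)) {
    stop("slice stations must be strictly increasing (sort slices and ",
         "remove duplicate stations first)")
  }
  stopifnot(step_mm > 0, all(df$area_mm2 > 0))
  integrate_area(df) / 1000
}

# Trapezoid integral of the piecewise-linear area profile; refining the grid
# below the knot spacing leaves the result unchanged, so integrate on the
# knots directly.
integrate_area <- function(df) {
  s <- df$station_mm; a <- df$area_mm2
  sum(diff(s) * (head(a, -1) + tail(a, -1)) / 2)
}

#' Length-weighted mean cross-sectional area
#'
#' Integral of the linearly interpolated area profile divided by the slice
#' span, so that `mean_csa(slices) * span / 1000` equals
#' [reconstruct_volume()] exactly. With a single slice the slice area is
#' returned.
#'
#' @inheritParams reconstruct_volume
#' @return Mean CSA in mm^2.
#' @export
mean_csa <- function(slices) {
  df <- as_slice_table(slices)
  if (nrow(df) == 0) stop("no slices supplied")
  if (nrow(df) == 1) return(df$area_mm2)
  if (is.unsorted(df$station_mm, strictly = TRUE)) {
    stop("slice stations must be strictly increasing")
  }
  integrate_area(df) / (max(df$station_mm) - min(df$station_mm))
}

#' Reconstruct tendon geometry from a tracked sweep
#'
#' Transforms the landmark pixels and (a subset of) the segmented contours
#' into world coordinates, computes the two-point free-tendon length, the
#' per-slice areas with their stations (projection of the slice centroid
#' onto the landmark chord), the length-weighted mean CSA and the volume.
#'
#' Contours are used at approximately `slice_interval_mm` spacing (the
#' first and last frames are always kept), mirroring manual contouring at
#' regular intervals; set `slice_interval_mm = NULL` to use every frame.
#'
#' @param sweep A [simulate_sweep()] result or an object read by
#'   [read_sweep_json()].
#' @param slice_interval_mm Approximate spacing between used contours (mm),
#'   default 5. `NULL` uses all frames.
#' @param step_mm Integration resolution passed to [reconstruct_volume()].
#' @return An object of class `tendon_geometry`: `length_mm`, `slices`
#'   (data frame `station_mm`, `area_mm2`), `mean_csa_mm2`, `volume_ml`,
#'   and the landmark world coordinates.
#' @export
reconstruct_geometry <- function(sweep, slice_interval_mm = 5, step_mm = 0.1) {
  stopifnot(inherits(sweep, "tracked_sweep"))
  cal <- sweep$calibration
  lm_pts <- list()
  for (fr in sweep$frames) {
    if (!is.null(fr$landmark)) {
      lm_pts[[fr$landmark$name]] <-
        pixel_to_world(fr$landmark$pixel_rc, cal, fr$pose)
    }
  }
  len <- tendon_length(lm_pts[["calcaneal_notch"]], lm_pts[["soleus_mtj"]])
  axis <- (lm_pts[["soleus_mtj"]] - lm_pts[["calcaneal_notch"]]) / len

  idx <- seq_along(sweep$frames)
  if (!is.null(slice_interval_mm)) {
    stride <- max(1L, round(slice_interval_mm / sweep$frame_spacing_mm))
    idx <- unique(c(seq(1L, length(idx), by = stride), length(idx)))
  }
  st <- ar <- numeric(length(idx))
  for (k in seq_along(idx)) {
    fr <- sweep$frames[[idx[k]]]
    world <- pixel_to_world(fr$contour_px, cal, fr$pose)
    ctr <- colMeans(world)
    st[k] <- sum((ctr - lm_pts[["calcaneal_notch"]]) * axis)
    ar[k] <- contour_area(world)
  }
  o <- order(st)
  df <- data.frame(station_mm = st[o], area_mm2 = ar[o])
  if (anyDuplicated(df$station_mm)) {
    stop("duplicate slice stations after ordering; reduce pose noise or ",
         "increase slice_interval_mm")
  }
  structure(list(
    length_mm    = len,
    slices       = df,
    mean_csa_mm2 = mean_csa(df),
    volume_ml    = reconstruct_volume(df, step_mm),
    landmarks    = lm_pts
  ), class = "tendon_geometry")
}

#' @export
print.tendon_geometry <- function(x, ...) {
  cat("Tendon geometry\n")
  cat(sprintf("  length:   %.2f mm\n", x$length_mm))
  cat(sprintf("  mean CSA: %.2f mm^2 (%d slices)\n",
              x$mean_csa_mm2, nrow(x$slices)))
  cat(sprintf("  volume:   %.4f ml\n", x$volume_ml))
  invisible(x)
}
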