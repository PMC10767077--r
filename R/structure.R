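#' Estimate the tree location from the basal slice
#'
#' Fits a circle to the lowest `slice_height` (default 0.30 m) slice of the
#' cleaned cloud; the fitted centre gives the planimetric tree location and
#' the minimum z of the cloud gives the tree base elevation.
#'
#' @param cloud Cleaned point-cloud data frame.
#' @param slice_height Height of the basal slice in metres (default 0.30).
#' @param min_points Minimum slice points required (default 10).
#' @return List with `x`, `y`, `z` (base z) and `fit` (the [fit_circle()]
#'   result).
#' @export
estimate_location <- function(cloud, slice_height = cm_defaults()$location_slice,
                              min_points = cm_defaults()$min_circle_points) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) == 0) {
    cm_abort("cannot locate a tree in an empty cloud", "cm_error_insufficient")
  }
  z0 <- min(cloud$z)
  slice <- horizontal_slice(cloud, z0, z0 + slice_height)
  if (nrow(slice) < min_points || is_collinear_xy(as_xy(slice))) {
    cm_abort(sprintf(
      "location slice [%.2f, %.2f) m has %d usable points; need >= %d non-collinear",
      z0, z0 + slice_height, nrow(slice), min_points),
      "cm_error_insufficient")
  }
  fit <- fit_circle(slice)
  list(x = fit$center_x, y = fit$center_y, z = z0, fit = fit)
}

#' Estimate DBH from the breast-height slice
#'
#' Fits a circle to the slice 1.27--1.33 m above the tree base; DBH is twice
#' the fitted radius.
#'
#' @param cloud Cleaned point-cloud data frame.
#' @param base_z Tree base elevation (minimum z of the cleaned cloud), m.
#' @param slice_lo,slice_hi Slice bounds above the base, m (1.27, 1.33).
#' @param min_points Minimum slice points required (default 10).
#' @return List with `dbh` (m) and `fit` (the [fit_circle()] result).
#' @export
estimate_dbh <- function(cloud, base_z,
                         slice_lo = cm_defaults()$dbh_slice_lo,
                         slice_hi = cm_defaults()$dbh_slice_hi,
                         min_points = cm_defaults()$min_circle_points) {
  cloud <- as_point_cloud(cloud)
  stopifnot(is_scalar_num(base_z))
  slice <- horizontal_slice(cloud, base_z + slice_lo, base_z + slice_hi)
  if (nrow(slice) < min_points || is_collinear_xy(as_xy(slice))) {
    cm_abort(sprintf(
      "DBH slice [%.2f, %.2f) m above base has %d usable points; need >= %d non-collinear",
      slice_lo, slice_hi, nrow(slice), min_points),
      "cm_error_insufficient")
  }
  fit <- fit_circle(slice)
  list(dbh = 2 * fit$radius, fit = fit)
}

#' Detect the crown start height by the slice-radius jump
#'
#' Scans contiguous `slice_height` (0.10 m) slices upward from the top of the
#' DBH slice, fitting a circle to each slice with at least `min_points`
#' points.  Slices with fewer points (or collinear points, or a failed fit)
#' are skipped and do not update the reference radius.  The crown starts at
#' the bottom of the first slice whose fitted radius is at least `jump`
#' (default 1.2, i.e. a 20% increase) times the previous successfully fitted
#' radius; the reference is initialized to the DBH-slice radius.  The scan is
#' capped at `max_frac` (60%) of the tree height: if no slice qualifies below
#' the cap the crown start is reported as missing (`NA`), not 0.
#'
#' @param cloud Cleaned point-cloud data frame.
#' @param base_z Tree base elevation, m.
#' @param dbh_radius Radius of the DBH-slice circle fit, m.
#' @param tree_height Tree height (for the scan cap), m.
#' @param jump Relative radius jump marking the crown (default 1.2).
#' @param slice_height Scan slice height, m (default 0.10).
#' @param scan_start Height above base where the scan begins (default 1.33,
#'   the top of the DBH slice).
#' @param max_frac Scan cap as a fraction of tree height (default 0.60).
#' @param min_points Minimum points per slice fit (default 10).
#' @return List with `crown_start` (m above base, or `NA_real_` when not
#'   found) and `trace`, a tibble with one row per scanned slice
#'   (`height`, `n_points`, `radius`, `fitted`, `triggered`).
#' @export
estimate_crown_start <- function(cloud, base_z, dbh_radius, tree_height,
                                 jump = cm_defaults()$crown_jump,
                                 slice_height = cm_defaults()$slice_height,
                                 scan_start = cm_defaults()$dbh_slice_hi,
                                 max_frac = cm_defaults()$crown_scan_max_frac,
                                 min_points = cm_defaults()$min_circle_points) {
  cloud <- as_point_cloud(cloud)
  stopifnot(is_scalar_num(base_z), is_scalar_num(dbh_radius), dbh_radius > 0,
            is_scalar_num(tree_height), tree_height > 0,
            is_scalar_num(jump), jump > 1)
  cap <- max_frac * tree_height
  bottoms <- seq(scan_start, cap, by = slice_height)
  bottoms <- bottoms[bottoms < cap]
  prev <- dbh_radius
  trace <- vector("list", length(bottoms))
  crown_start <- NA_real_
  for (i in seq_along(bottoms)) {
    lo <- base_z + bottoms[i]
    slice <- horizontal_slice(cloud, lo, lo + slice_height)
    row <- tibble(height = bottoms[i], n_points = nrow(slice),
                  radius = NA_real_, fitted = FALSE, triggered = FALSE)
    if (nrow(slice) >= min_points && !is_collinear_xy(as_xy(slice))) {
      fit <- tryCatch(fit_circle(slice), error = function(e) NULL)
      if (!is.null(fit)) {
        row$radius <- fit$radius
        row$fitted <- TRUE
        if (fit$radius >= jump * prev) {
          row$triggered <- TRUE
          trace[[i]] <- row
          crown_start <- bottoms[i]
          trace <- trace[seq_len(i)]
          break
        }
        prev <- fit$radius
      }
    }
    trace[[i]] <- row
  }
  list(crown_start = crown_start, trace = dplyr::bind_rows(trace))
}

#' Tree height as the vertical point-cloud extent
#'
#' Height is the difference between the highest and the lowest point of the
#' cleaned cloud.
#'
#' @param cloud Cleaned point-cloud data frame with at least 2 points.
#' @return Tree height in metres.
#' @export
estimate_tree_height <- function(cloud) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) < 2) {
    cm_abort("tree height needs at least 2 points", "cm_error_insufficient")
  }
  max(cloud$z) - min(cloud$z)
}

# Shared slab scan: maximum horizontal distance from `center` to the points
# of `cloud`, per azimuthal direction.  A point belongs to direction theta
# when it lies within the vertical slab of total width `slab_width` centred
# on the vertical plane through `center` along u(theta), on the positive
# side.  Directions with no points yield radius 0.
slab_radii <- function(cloud, center, angles_deg, slab_width) {
  dx <- cloud$x - center[1]
  dy <- cloud$y - center[2]
  rho <- sqrt(dx^2 + dy^2)
  half <- slab_width / 2
  vapply(angles_deg, function(theta) {
    t_rad <- theta * pi / 180
    along <- dx * cos(t_rad) + dy * sin(t_rad)
    perp <- abs(dy * cos(t_rad) - dx * sin(t_rad))
    sel <- perp <= half & along > 0
    if (any(sel)) max(rho[sel]) else 0
  }, double(1))
}

#' Crown radii in 72 azimuthal directions
#'
#' For each direction theta in 0, 5, ..., 355 degrees (counterclockwise from
#' +x), the crown radius is the longest horizontal distance from the tree
#' location to the crown points lying in the vertical slab of total width
#' `slab_width` (0.10 m) centred on the vertical plane through the location
#' along theta, restricted to the positive half-plane.  Crown points are the
#' points at or above `crown_start` above the base; when `crown_start` is
#' missing (`NA`) the whole cloud is used as a fallback.  Empty directions
#' yield radius 0.
#'
#' @param cloud Cleaned point-cloud data frame.
#' @param location Tree location: list or vector with `x`, `y`, `z` (base z).
#' @param crown_start Crown start height above base, m, or `NA`.
#' @param slab_width Total slab width, m (default 0.10).
#' @param angle_step Azimuthal step in degrees (default 5).
#' @return Tibble with columns `direction_deg` and `radius` (m), 360 /
#'   `angle_step` rows.
#' @export
crown_radii_72 <- function(cloud, location, crown_start,
                           slab_width = cm_defaults()$slab_width,
                           angle_step = cm_defaults()$angle_step) {
  cloud <- as_point_cloud(cloud)
  loc <- as_location(location)
  angles <- seq(0, 360 - angle_step, by = angle_step)
  crown <- if (is.na(crown_start)) cloud else
    cloud[cloud$z >= loc[3] + crown_start, , drop = FALSE]
  tibble(direction_deg = angles,
         radius = slab_radii(crown, loc, angles, slab_width))
}

#' Crown radii per 2 m height band
#'
#' Applies the directional slab scan of [crown_radii_72()] separately to each
#' height band `[2k, 2k + 2)` metres above the tree base, for bands up to
#' `max_height` (30 m, i.e. 15 bands).  The whole cloud is used, not only the
#' crown: bands below the crown start legitimately measure the trunk.  Empty
#' bands (or empty directions) yield radius 0.
#'
#' @inheritParams crown_radii_72
#' @param band_height Band height in metres (default 2).
#' @param max_height Upper end of the banded scan above the base (default 30).
#' @return Tibble with columns `band`, `band_lo`, `band_hi`, `direction_deg`,
#'   `radius`; `(max_height / band_height) * (360 / angle_step)` rows.
#' @export
crown_radii_by_height <- function(cloud, location,
                                  band_height = cm_defaults()$band_height,
                                  max_height = cm_defaults()$band_max_height,
                                  slab_width = cm_defaults()$slab_width,
                                  angle_step = cm_defaults()$angle_step) {
  cloud <- as_point_cloud(cloud)
  loc <- as_location(location)
  angles <- seq(0, 360 - angle_step, by = angle_step)
  n_bands <- as.integer(round(max_height / band_height))
  purrr::map_dfr(seq_len(n_bands) - 1L, function(k) {
    lo <- loc[3] + k * band_height
    band_cloud <- horizontal_slice(cloud, lo, lo + band_height)
    radii <- slab_radii(band_cloud, loc, angles, slab_width)
    tibble(band = k + 1L,
           band_lo = k * band_height,
           band_hi = (k + 1L) * band_height,
           direction_deg = angles,
           radius = radii)
  })
}

#' Maximum horizontal crown diameter
#'
#' The maximum over all direction pairs of the sum of opposite crown radii:
#' `max_i radii[i] + radii[(i + 36) mod 72]`.
#'
#' @param radii The 72 crown radii: a numeric vector ordered by direction or
#'   the tibble returned by [crown_radii_72()].
#' @return Maximum crown diameter in metres.
#' @export
max_crown_diameter <- function(radii) {
  if (is.data.frame(radii)) {
    radii <- radii$radius[order(radii$direction_deg)]
  }
  n <- length(radii)
  stopifnot(is.numeric(radii), n >= 2, n %% 2 == 0)
  half <- n / 2
  max(radii + radii[(seq_len(n) - 1 + half) %% n + 1])
}

#' Crown projection area
#'
#' Area of the 2D convex hull of the XY projection of the crown points
#' (points at or above the crown start; whole cloud when the crown start is
#' missing).
#'
#' @inheritParams crown_radii_72
#' @return Area in square metres.
#' @export
crown_projection_area <- function(cloud, location, crown_start) {
  cloud <- as_point_cloud(cloud)
  base_z <- as_location(location)[3]
  crown <- if (is.na(crown_start)) cloud else
    cloud[cloud$z >= base_z + crown_start, , drop = FALSE]
  if (nrow(crown) < 3) {
    cm_abort("crown projection area needs at least 3 crown points",
             "cm_error_degenerate")
  }
  convex_hull_area(crown)
}
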