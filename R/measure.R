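#' Measure a single tree end to end
#'
#' Runs the full whole-tree measurement pipeline on one raw single-tree
#' point cloud: outlier removal, tree location, DBH, crown start, tree
#' height, 72-direction crown radii, maximum crown diameter, crown projection
#' area, and crown radii per 2 m height band.  When an [affine_transform()]
#' is supplied the project-frame location is additionally mapped to global
#' coordinates.  Total woody volume is taken from a QSM cylinder table when
#' one is supplied (see [total_volume()]); it is never derived from the point
#' cloud itself.
#'
#' Stage failures are not fatal: a failed estimate is reported as `NA` and
#' recorded in the machine-readable stage `log`, and downstream stages run
#' with what is available (crown metrics fall back to the whole cloud when
#' the crown start is undetected).  Only an empty input cloud aborts.
#'
#' @param cloud Raw point-cloud data frame (non-empty).
#' @param tree_id,project_id,date,botanical_name Identifier strings carried
#'   into the output record.
#' @param transform Optional [affine_transform()] mapping project to global
#'   coordinates.
#' @param cylinders Optional QSM cylinder table (see [read_cylinders()]) used
#'   only for the total volume.
#' @param knn,outlier_threshold Outlier-removal parameters
#'   (see [remove_outliers()]).
#' @param crown_jump,slice_height Crown-start scan parameters
#'   (see [estimate_crown_start()]).
#' @param slab_width,angle_step Directional-slab parameters
#'   (see [crown_radii_72()]).
#' @param band_height,band_max_height Height-band parameters
#'   (see [crown_radii_by_height()]).
#' @param min_circle_points Minimum points per slice circle fit.
#' @return An object of class `tree_metrics`:
#' \describe{
#'   \item{summary}{one-row tibble of the scalar metrics (ids, location,
#'     global location, dbh, tree_height, crown_start_height,
#'     crown_diameter_max, crown_projection_area, total_volume)}
#'   \item{crown_radii}{tibble of the 72 directional radii}
#'   \item{crown_radii_by_height}{tibble of the banded radii (15 x 72 rows)}
#'   \item{log}{tibble of per-stage outcomes (`stage`, `status`, `message`)}
#'   \item{fits}{the underlying circle fits and crown-scan trace}
#'   \item{params}{the parameter set used}
#' }
#' Use [tidy()] for the wide one-row export record and [write_metrics()] for
#' the CSV.
#' @examples
#' tree <- generate_tree(synthetic_tree_spec(seed = 1, point_spacing = 0.05))
#' m <- measure_tree(tree$cloud, tree_id = "demo")
#' glance(m)
#' @export
measure_tree <- function(cloud,
                         tree_id = "tree",
                         project_id = NA_character_,
                         date = NA_character_,
                         botanical_name = NA_character_,
                         transform = NULL,
                         cylinders = NULL,
                         knn = cm_defaults()$knn,
                         outlier_threshold = cm_defaults()$outlier_threshold,
                         crown_jump = cm_defaults()$crown_jump,
                         slice_height = cm_defaults()$slice_height,
                         slab_width = cm_defaults()$slab_width,
                         angle_step = cm_defaults()$angle_step,
                         band_height = cm_defaults()$band_height,
                         band_max_height = cm_defaults()$band_max_height,
                         min_circle_points = cm_defaults()$min_circle_points) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) == 0) {
    cm_abort("cannot measure an empty point cloud", "cm_error_insufficient")
  }
  if (!is.null(transform)) stopifnot(inherits(transform, "affine_transform"))

  log_rows <- list()
  note <- function(stage, status, message = "") {
    log_rows[[length(log_rows) + 1]] <<-
      tibble(stage = stage, status = status, message = message)
  }
  run <- function(stage, expr) {
    tryCatch({
      out <- force(expr)
      note(stage, "ok")
      out
    }, error = function(e) {
      note(stage, "failed", conditionMessage(e))
      NULL
    })
  }

  clean <- run("remove_outliers",
               remove_outliers(cloud, k = knn, threshold = outlier_threshold))
  if (is.null(clean)) {
    kept <- cloud
  } else {
    kept <- clean$kept
    note("remove_outliers_detail", "info",
         sprintf("%d of %d points removed", length(clean$removed_indices),
                 nrow(cloud)))
  }

  location <- run("estimate_location", estimate_location(
    cloud = kept, min_points = min_circle_points))
  base_z <- if (!is.null(location)) location$z else min(kept$z)

  height <- run("estimate_tree_height", estimate_tree_height(kept))

  dbh_est <- run("estimate_dbh", estimate_dbh(
    kept, base_z, min_points = min_circle_points))

  crown_scan <- NULL
  if (!is.null(dbh_est) && !is.null(height)) {
    crown_scan <- run("estimate_crown_start", estimate_crown_start(
      kept, base_z, dbh_radius = dbh_est$fit$radius, tree_height = height,
      jump = crown_jump, slice_height = slice_height,
      min_points = min_circle_points))
  } else {
    note("estimate_crown_start", "skipped", "needs DBH fit and tree height")
  }
  crown_start <- if (!is.null(crown_scan)) crown_scan$crown_start else NA_real_
  if (is.na(crown_start)) {
    note("crown_fallback", "info",
         "crown start undetected; crown metrics use the whole cloud")
  }

  loc_vec <- if (!is.null(location)) c(location$x, location$y, location$z) else
    c(NA_real_, NA_real_, NA_real_)

  radii <- NULL
  diameter_max <- NA_real_
  area <- NA_real_
  bands <- NULL
  if (!is.null(location)) {
    radii <- run("crown_radii_72", crown_radii_72(
      kept, location, crown_start, slab_width = slab_width,
      angle_step = angle_step))
    if (!is.null(radii)) diameter_max <- max_crown_diameter(radii)
    area <- run("crown_projection_area",
                crown_projection_area(kept, location, crown_start))
    area <- area %||% NA_real_
    bands <- run("crown_radii_by_height", crown_radii_by_height(
      kept, location, band_height = band_height, max_height = band_max_height,
      slab_width = slab_width, angle_step = angle_step))
  } else {
    note("crown_radii_72", "skipped", "needs tree location")
    note("crown_projection_area", "skipped", "needs tree location")
    note("crown_radii_by_height", "skipped", "needs tree location")
  }

  global <- c(NA_real_, NA_real_, NA_real_)
  if (!is.null(transform) && !anyNA(loc_vec)) {
    global <- unname(apply_transform(loc_vec, transform))
    note("apply_transform", "ok")
  }

  volume <- NA_real_
  if (!is.null(cylinders)) {
    vol <- run("total_volume", total_volume(cylinders))
    volume <- vol %||% NA_real_
  }

  angles <- seq(0, 360 - angle_step, by = angle_step)
  if (is.null(radii)) radii <- tibble(direction_deg = angles, radius = NA_real_)
  if (is.null(bands)) {
    n_bands <- as.integer(round(band_max_height / band_height))
    bands <- tidyr::expand_grid(band = seq_len(n_bands),
                                direction_deg = angles)
    bands$band_lo <- (bands$band - 1) * band_height
    bands$band_hi <- bands$band * band_height
    bands$radius <- NA_real_
    bands <- bands[, c("band", "band_lo", "band_hi", "direction_deg", "radius")]
  }

  summary <- tibble(
    date = as.character(date),
    project_id = as.character(project_id),
    tree_id = as.character(tree_id),
    botanical_name = as.character(botanical_name),
    location_x = loc_vec[1], location_y = loc_vec[2], location_z = loc_vec[3],
    location_lat = global[1], location_long = global[2],
    location_alt = global[3],
    dbh = if (!is.null(dbh_est)) dbh_est$dbh else NA_real_,
    tree_height = height %||% NA_real_,
    crown_start_height = crown_start,
    crown_diameter_max = diameter_max,
    crown_projection_area = area,
    total_volume = volume
  )

  structure(
    list(
      summary = summary,
      crown_radii = radii,
      crown_radii_by_height = bands,
      log = dplyr::bind_rows(log_rows),
      fits = list(
        location = if (!is.null(location)) location$fit else NULL,
        dbh = if (!is.null(dbh_est)) dbh_est$fit else NULL,
        crown_scan = if (!is.null(crown_scan)) crown_scan$trace else NULL,
        outliers = clean
      ),
      params = list(
        knn = knn, outlier_threshold = outlier_threshold,
        crown_jump = crown_jump, slice_height = slice_height,
        slab_width = slab_width, angle_step = angle_step,
        band_height = band_height, band_max_height = band_max_height,
        min_circle_points = min_circle_points,
        crown_points = if (is.na(crown_start)) "whole_cloud" else "crown_only"
      )
    ),
    class = "tree_metrics"
  )
}

#' @export
print.tree_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<tree_metrics> tree %s\n", s$tree_id))
  cat(sprintf("  DBH %.3f m | height %.2f m | crown start %s m\n",
              s$dbh, s$tree_height,
              ifelse(is.na(s$crown_start_height), "NA",
                     sprintf("%.2f", s$crown_start_height))))
  cat(sprintf("  max crown diameter %.2f m | projection area %.2f m^2\n",
              s$crown_diameter_max, s$crown_projection_area))
  n_fail <- sum(x$log$status == "failed")
  if (n_fail > 0) cat(sprintf("  %d stage(s) failed; see $log\n", n_fail))
  invisible(x)
}

# Column names of the wide export record follow the published dataset table:
# crown radii as crownX_XXd_m_ (direction in hundredths of degrees x 100,
# e.g. 355 degrees -> crown3_55d_m_) and banded radii as cr_XXmX_XXd_m_
# (band lower edge in metres, then the direction in the same encoding).
crown_col_name <- function(deg) {
  sprintf("crown%d_%02dd_m_", deg %/% 100, deg %% 100)
}
band_col_name <- function(band_lo, deg) {
  sprintf("cr_%02dm%d_%02dd_m_", band_lo, deg %/% 100, deg %% 100)
}

#' @describeIn measure_tree Wide one-row record with the dataset's column
#'   names (`DBH.m.`-style scalars plus the 72 `crownX_XXd_m_` and 15 x 72
#'   `cr_XXmX_XXd_m_` radius columns).
#' @param x A `tree_metrics` object.
#' @param ... Unused.
#' @export
tidy.tree_metrics <- function(x, ...) {
  s <- x$summary
  wide <- tibble(
    date = s$date, projectID = s$project_id, treeID = s$tree_id,
    botanical.name = s$botanical_name,
    location.x = s$location_x, location.y = s$location_y,
    location.z = s$location_z,
    location.lat = s$location_lat, location.long = s$location_long,
    location.alt = s$location_alt,
    `DBH(m)` = s$dbh,
    `treeHeight(m)` = s$tree_height,
    `crownStartHeight(m)` = s$crown_start_height,
    `crownDiameterMax(m)` = s$crown_diameter_max,
    `crownProjectionArea(m2)` = s$crown_projection_area,
    `totalVolume(L)` = s$total_volume
  )
  r <- x$crown_radii[order(x$crown_radii$direction_deg), ]
  radii_row <- as_tibble(setNames(as.list(r$radius),
                                  crown_col_name(r$direction_deg)))
  b <- x$crown_radii_by_height[order(x$crown_radii_by_height$band_lo,
                                     x$crown_radii_by_height$direction_deg), ]
  band_row <- as_tibble(setNames(as.list(b$radius),
                                 band_col_name(b$band_lo, b$direction_deg)))
  dplyr::bind_cols(wide, radii_row, band_row)
}

#' @describeIn measure_tree One-row tibble of the scalar metrics only.
#' @export
glance.tree_metrics <- function(x, ...) {
  x$summary
}

#' Write tree metrics to CSV
#'
#' Writes one row per tree in the wide dataset layout produced by
#' [tidy.tree_metrics()].
#'
#' @param metrics A `tree_metrics` object or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (inherits(metrics, "tree_metrics")) metrics <- list(metrics)
  rows <- dplyr::bind_rows(lapply(metrics, tidy))
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

#' @describeIn measure_tree Polar plot of the 72 crown radii (optionally the
#'   banded radii, faceted by height band).
#' @param object A `tree_metrics` object.
#' @param bands If `TRUE`, plot the per-band radii faceted by height band
#'   instead of the flat crown radii.
#' @export
autoplot.tree_metrics <- function(object, bands = FALSE, ...) {
  if (bands) {
    dat <- object$crown_radii_by_height
    dat <- dat[!is.na(dat$radius) & dat$radius > 0, ]
    dat$band_label <- sprintf("%g-%g m", dat$band_lo, dat$band_hi)
    dat$band_label <- factor(dat$band_label,
                             levels = unique(dat$band_label[order(dat$band_lo)]))
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$direction_deg,
                                           y = .data$radius)) +
      ggplot2::geom_col(width = 4, fill = "forestgreen") +
      ggplot2::facet_wrap(~band_label)
  } else {
    p <- ggplot2::ggplot(object$crown_radii,
                         ggplot2::aes(x = .data$direction_deg,
                                      y = .data$radius)) +
      ggplot2::geom_col(width = 4, fill = "forestgreen")
  }
  p +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(breaks = seq(0, 315, by = 45), limits = c(-2.5, 357.5)) +
    ggplot2::labs(x = "azimuth (degrees from +x, counterclockwise)",
                  y = "crown radius (m)",
                  title = sprintf("Crown radii: %s", object$summary$tree_id)) +
    ggplot2::theme_minimal()
}
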