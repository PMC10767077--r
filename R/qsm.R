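# Canonical QSM cylinder-table schema: dataset CSV header -> internal name.
qsm_schema <- c(
  date = "date", projectID = "project_id", treeID = "tree_id",
  branchID = "branch_id", branchOrder = "branch_order",
  cylinderID = "cylinder_id", posInBranch = "pos_in_branch",
  parentCylID = "parent_cyl_id", childCyID = "child_cyl_id",
  start_x = "start_x", start_y = "start_y", start_z = "start_z",
  axis_x = "axis_x", axis_y = "axis_y", axis_z = "axis_z",
  length = "length", radius = "radius", addedVirtual = "added_virtual"
)

#' Validate a QSM cylinder table
#'
#' Coerces a data frame of QSM cylinders to the canonical internal layout
#' and validates it.  Accepts either the dataset CSV header names
#' (`cylinderID`, `parentCylID`, `childCyID`, `start_x`, ..., `addedVirtual`)
#' or the internal snake_case names.  Validation enforces unique cylinder
#' ids, `parent_cyl_id != cylinder_id`, positive length and radius, and unit
#' axis vectors: every axis is renormalized, and a deviation from unit norm
#' beyond 1e-2 additionally raises a validation warning and sets the
#' `axis_renormalized` flag on the row.
#'
#' @param cylinders Data frame of cylinder records.
#' @return A validated tibble in internal naming, row order preserved, with
#'   an `axis_renormalized` logical column.
#' @seealso [read_cylinders()], [build_graph()], [total_volume()]
#' @export
as_cylinders <- function(cylinders) {
  if (!is.data.frame(cylinders)) {
    cm_abort("`cylinders` must be a data frame", "cm_error_type")
  }
  df <- as_tibble(cylinders)
  dataset_named <- intersect(names(qsm_schema), names(df))
  internal <- unname(qsm_schema)
  if (length(dataset_named) > 0) {
    names(df)[match(dataset_named, names(df))] <- qsm_schema[dataset_named]
  }
  missing_cols <- setdiff(internal, names(df))
  if (length(missing_cols) > 0) {
    # report in the dataset's own header vocabulary
    as_header <- names(qsm_schema)[match(missing_cols, internal)]
    cm_abort(sprintf("cylinder table is missing column(s): %s",
                     paste(as_header, collapse = ", ")),
             "cm_error_schema")
  }
  df <- df[, internal, drop = FALSE]
  int_cols <- c("branch_id", "branch_order", "cylinder_id", "pos_in_branch",
                "parent_cyl_id", "child_cyl_id", "added_virtual")
  for (col in int_cols) df[[col]] <- as.integer(df[[col]])
  num_cols <- c("start_x", "start_y", "start_z", "axis_x", "axis_y", "axis_z",
                "length", "radius")
  for (col in num_cols) df[[col]] <- as.double(df[[col]])
  if (nrow(df) == 0) {
    df$axis_renormalized <- logical()
    return(df)
  }

  if (anyDuplicated(df$cylinder_id)) {
    dup <- df$cylinder_id[duplicated(df$cylinder_id)][1]
    cm_abort(sprintf("duplicate cylinderID: %d", dup), "cm_error_validation")
  }
  if (any(df$parent_cyl_id == df$cylinder_id)) {
    bad <- df$cylinder_id[df$parent_cyl_id == df$cylinder_id][1]
    cm_abort(sprintf("cylinder %d lists itself as parent", bad),
             "cm_error_validation")
  }
  if (any(!is.finite(df$length) | df$length <= 0)) {
    cm_abort("cylinder lengths must be positive", "cm_error_validation")
  }
  if (any(!is.finite(df$radius) | df$radius <= 0)) {
    cm_abort("cylinder radii must be positive", "cm_error_validation")
  }
  nrm <- sqrt(df$axis_x^2 + df$axis_y^2 + df$axis_z^2)
  if (any(nrm < 1e-12)) {
    cm_abort("cylinder axis vectors must be non-zero", "cm_error_validation")
  }
  off <- abs(nrm - 1) > 1e-2
  if (any(off)) {
    warn(sprintf(
      "%d cylinder axis vector(s) deviate from unit norm by more than 1e-2; renormalized",
      sum(off)), class = "cm_warning_validation")
  }
  df$axis_x <- df$axis_x / nrm
  df$axis_y <- df$axis_y / nrm
  df$axis_z <- df$axis_z / nrm
  df$axis_renormalized <- off
  df
}

#' Read a QSM cylinder table from CSV
#'
#' Reads the per-cylinder CSV produced alongside quantitative structure
#' models (one row per fitted cylinder: ids, branch topology pointers, start
#' point, unit axis, length, radius, and the `addedVirtual` flag marking
#' cylinders added after the normal fitting pass) and validates it with
#' [as_cylinders()].
#'
#' @param path Path to the CSV file.
#' @return A validated cylinder tibble, row order preserved.
#' @export
read_cylinders <- function(path) {
  if (!file.exists(path)) {
    cm_abort(sprintf("cylinder file not found: %s", path), "cm_error_io")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_cylinders(df)
}

#' Write a QSM cylinder table to CSV
#'
#' Writes with the dataset's header names so the file round-trips through
#' [read_cylinders()].
#'
#' @param cylinders Cylinder table (validated or coercible).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cylinders <- function(cylinders, path) {
  df <- as_cylinders(cylinders)
  df$axis_renormalized <- NULL
  names(df) <- names(qsm_schema)[match(names(df), qsm_schema)]
  readr::write_csv(df, path)
  invisible(path)
}

#' Total woody volume of a cylinder model
#'
#' Sum of the cylinder volumes, converted to litres:
#' `1000 * sum(pi * radius^2 * length)`.
#'
#' @param cylinders Cylinder table (validated or coercible; an empty table
#'   gives 0).
#' @return Total volume in litres.
#' @examples
#' total_volume(data.frame(
#'   date = "d", projectID = "p", treeID = "t", branchID = 1, branchOrder = 0,
#'   cylinderID = 1, posInBranch = 1, parentCylID = 0, childCyID = 0,
#'   start_x = 0, start_y = 0, start_z = 0, axis_x = 0, axis_y = 0, axis_z = 1,
#'   length = 1, radius = 0.1, addedVirtual = 0))  # 31.4159 L
#' @export
total_volume <- function(cylinders) {
  df <- as_cylinders(cylinders)
  1000 * sum(pi * df$radius^2 * df$length)
}

#' Audit a QSM against its source point cloud
#'
#' Computes, for every point, the minimum distance to any cylinder of the
#' model (cylinders treated as solids, see
#' [point_to_cylinder_distance()]) and labels the point `not_fitted` when
#' that distance strictly exceeds `threshold`.  In a sound model the
#' not-fitted points are mostly thin twigs below the cylinder-fitting scale;
#' a large not-fitted fraction signals a reconstruction problem.
#'
#' @param cloud Point-cloud data frame.
#' @param cylinders Cylinder table (at least one cylinder).
#' @param threshold Distance above which a point is not fitted, m
#'   (default 0.05).
#' @return An object of class `qsm_fit_check`:
#' \describe{
#'   \item{points}{the cloud with `distance` (m) and `fitted` columns}
#'   \item{n_fitted, n_not_fitted}{summary counts}
#'   \item{threshold}{the threshold used}
#' }
#' @export
flag_unfitted_points <- function(cloud, cylinders,
                                 threshold = cm_defaults()$unfitted_threshold) {
  cloud <- as_point_cloud(cloud)
  stopifnot(is_scalar_num(threshold), threshold >= 0)
  if (is.data.frame(cylinders)) cylinders <- as_cylinders(cylinders)
  d <- min_cylinder_distance(cloud, cylinders)
  pts <- cloud
  pts$distance <- d
  pts$fitted <- d <= threshold
  structure(
    list(points = pts,
         n_fitted = sum(pts$fitted),
         n_not_fitted = sum(!pts$fitted),
         threshold = threshold),
    class = "qsm_fit_check"
  )
}

#' @export
print.qsm_fit_check <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf(
    "<qsm_fit_check> %d points: %d fitted, %d not fitted (%.2f%%) at %g m\n",
    n, x$n_fitted, x$n_not_fitted, 100 * x$n_not_fitted / max(n, 1),
    x$threshold))
  invisible(x)
}

#' @describeIn flag_unfitted_points Per-point table with distances and flags.
#' @param x A `qsm_fit_check`.
#' @param ... Unused.
#' @export
tidy.qsm_fit_check <- function(x, ...) {
  x$points
}

#' @describeIn flag_unfitted_points One-row summary of the audit.
#' @export
glance.qsm_fit_check <- function(x, ...) {
  n <- nrow(x$points)
  tibble(n_points = n, n_fitted = x$n_fitted, n_not_fitted = x$n_not_fitted,
         not_fitted_fraction = x$n_not_fitted / max(n, 1),
         threshold = x$threshold)
}

#' @describeIn flag_unfitted_points Side view of the audit, not-fitted points
#'   highlighted.
#' @param object A `qsm_fit_check`.
#' @export
autoplot.qsm_fit_check <- function(object, ...) {
  dat <- object$points
  dat$status <- ifelse(dat$fitted, "fitted", "not fitted")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$z,
                                    colour = .data$status)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = c("fitted" = "darkgreen",
                                            "not fitted" = "red")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "z (m)", colour = NULL,
                  title = "QSM cylinder-fit audit") +
    ggplot2::theme_minimal()
}
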