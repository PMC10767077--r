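# Internal helpers shared across modules.

cm_abort <- function(message, class, ...) {
  abort(message, class = c(class, "cm_error"), ...)
}

# Validate a point-cloud data frame: numeric finite x, y, z and an optional
# intensity column of the same length.  Returns a tibble.
as_point_cloud <- function(cloud, arg = "cloud") {
  if (!is.data.frame(cloud)) {
    cm_abort(sprintf("`%s` must be a data frame with columns x, y, z", arg),
             "cm_error_type")
  }
  missing_cols <- setdiff(c("x", "y", "z"), names(cloud))
  if (length(missing_cols) > 0) {
    cm_abort(sprintf("`%s` is missing column(s): %s", arg,
                     paste(missing_cols, collapse = ", ")),
             "cm_error_type")
  }
  for (col in intersect(c("x", "y", "z", "intensity"), names(cloud))) {
    if (!is.numeric(cloud[[col]])) {
      cm_abort(sprintf("column `%s` of `%s` must be numeric", col, arg),
               "cm_error_type")
    }
  }
  if (nrow(cloud) > 0 &&
      !all(is.finite(cloud$x) & is.finite(cloud$y) & is.finite(cloud$z))) {
    cm_abort(sprintf("`%s` contains non-finite coordinates", arg),
             "cm_error_type")
  }
  as_tibble(cloud)
}

pc_xyz <- function(cloud) {
  cbind(cloud$x, cloud$y, cloud$z)
}

# 2D point input for planar geometry: data frame with x/y or a 2-column matrix.
as_xy <- function(points, arg = "points") {
  if (is.matrix(points) && ncol(points) >= 2) {
    xy <- points[, 1:2, drop = FALSE]
  } else if (is.data.frame(points) && all(c("x", "y") %in% names(points))) {
    xy <- cbind(points$x, points$y)
  } else {
    cm_abort(sprintf(
      "`%s` must be a data frame with columns x, y or a 2-column matrix", arg),
      "cm_error_type")
  }
  storage.mode(xy) <- "double"
  if (nrow(xy) > 0 && !all(is.finite(xy))) {
    cm_abort(sprintf("`%s` contains non-finite coordinates", arg),
             "cm_error_type")
  }
  xy
}

# Rank-deficiency test used by the circle fit and hull code: TRUE when the
# points lie on one line (or point) within a relative tolerance.
is_collinear_xy <- function(xy, tol = 1e-9) {
  if (nrow(xy) < 3) return(TRUE)
  centered <- sweep(xy, 2, colMeans(xy))
  sv <- svd(centered, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)
}

is_scalar_num <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}

# Coerce a tree location (list from estimate_location, named vector, or plain
# length-3 numeric) to c(x, y, z).
as_location <- function(location) {
  if (is.list(location)) {
    loc <- c(location$x, location$y, location$z)
  } else if (is.numeric(location) && length(location) == 3) {
    loc <- if (!is.null(names(location)) &&
               all(c("x", "y", "z") %in% names(location))) {
      unname(location[c("x", "y", "z")])
    } else {
      unname(location)
    }
  } else {
    cm_abort("`location` must be a list or length-3 numeric with x, y, z",
             "cm_error_type")
  }
  if (length(loc) != 3 || !all(is.finite(loc))) {
    cm_abort("`location` must supply finite x, y, z", "cm_error_type")
  }
  as.double(loc)
}
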