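#' Least-squares circle fit
#'
#' Fits the circle minimizing the sum of squared *radial* residuals
#' \eqn{\sum_i (\lVert p_i - c \rVert - r)^2} over centre \eqn{c = (c_x,
#' c_y)} and radius \eqn{r}.  The algebraic Kasa linear least-squares
#' solution is computed first and then refined by Gauss--Newton iterations on
#' the geometric objective; on noise-free circular data the algebraic step is
#' already exact and the refinement is a no-op.
#'
#' This fit underlies the tree location (lowest 30 cm slice), the DBH
#' (1.27--1.33 m slice) and the crown-start slice scan.
#'
#' @param points 2D points: a data frame with columns `x`, `y` or a 2-column
#'   matrix.  At least 3 points, not collinear.
#' @return An object of class `circle_fit` with fields `center_x`,
#'   `center_y`, `radius`, `rms_residual` (root-mean-square radial residual),
#'   `n_points`, `objective` (sum of squared residuals) and `iterations`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' fit_circle(data.frame(x = cos(th), y = sin(th)))
#' @export
fit_circle <- function(points) {
  xy <- as_xy(points)
  n <- nrow(xy)
  if (n < 3) {
    cm_abort("circle fitting needs at least 3 points", "cm_error_degenerate")
  }
  if (is_collinear_xy(xy)) {
    cm_abort("circle fitting needs non-collinear points", "cm_error_degenerate")
  }
  x <- xy[, 1]; y <- xy[, 2]
  # Kasa algebraic fit: minimize ||A b - d||^2 with b = (cx, cy, cx^2+cy^2-r^2)
  a <- cbind(2 * x, 2 * y, 1)
  d <- x^2 + y^2
  b <- qr.solve(a, d)
  cx <- b[1]; cy <- b[2]
  r <- sqrt(max(b[3] + cx^2 + cy^2, .Machine$double.eps))

  # Gauss-Newton refinement of the geometric objective
  obj <- function(cx, cy, r) {
    rho <- sqrt((x - cx)^2 + (y - cy)^2)
    sum((rho - r)^2)
  }
  cur <- obj(cx, cy, r)
  iterations <- 0L
  for (it in seq_len(50)) {
    dx <- x - cx; dy <- y - cy
    rho <- sqrt(dx^2 + dy^2)
    rho[rho < 1e-12] <- 1e-12
    res <- rho - r
    jac <- cbind(-dx / rho, -dy / rho, -1)
    step <- tryCatch(qr.solve(jac, -res), error = function(e) NULL)
    if (is.null(step)) break
    new <- c(cx, cy, r) + step
    if (new[3] <= 0) break
    cand <- obj(new[1], new[2], new[3])
    if (!is.finite(cand) || cand > cur + 1e-15) break
    improved <- cur - cand
    cx <- new[1]; cy <- new[2]; r <- new[3]
    cur <- cand
    iterations <- it
    if (improved < 1e-15 * max(cur, 1e-12) || max(abs(step)) < 1e-14) break
  }
  rho <- sqrt((x - cx)^2 + (y - cy)^2)
  structure(
    list(center_x = cx, center_y = cy, radius = r,
         rms_residual = sqrt(mean((rho - r)^2)),
         objective = cur, n_points = n, iterations = iterations),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf(
    "<circle_fit> center (%.4f, %.4f), radius %.4f m, rms %.2g m (n = %d)\n",
    x$center_x, x$center_y, x$radius, x$rms_residual, x$n_points))
  invisible(x)
}

#' @describeIn fit_circle One-row tibble of the fitted parameters.
#' @param x A `circle_fit`.
#' @param ... Unused.
#' @export
tidy.circle_fit <- function(x, ...) {
  tibble(center_x = x$center_x, center_y = x$center_y, radius = x$radius)
}

#' @describeIn fit_circle One-row fit summary (rms, objective, n, iterations).
#' @export
glance.circle_fit <- function(x, ...) {
  tibble(rms_residual = x$rms_residual, objective = x$objective,
         n_points = x$n_points, iterations = x$iterations)
}

#' Horizontal slice of a point cloud
#'
#' Returns the points with `z_lo <= z < z_hi` (half-open, so adjacent slices
#' partition the cloud), order preserved.  Bounds are absolute z values; the
#' caller is responsible for referencing them to the tree base.
#'
#' @param cloud Point-cloud data frame.
#' @param z_lo,z_hi Slice bounds in metres, `z_lo < z_hi`.
#' @return Tibble of the points inside the slice (possibly 0 rows).
#' @export
horizontal_slice <- function(cloud, z_lo, z_hi) {
  cloud <- as_point_cloud(cloud)
  stopifnot(is_scalar_num(z_lo), is_scalar_num(z_hi))
  if (z_lo >= z_hi) {
    cm_abort("horizontal_slice needs z_lo < z_hi", "cm_error_type")
  }
  cloud[cloud$z >= z_lo & cloud$z < z_hi, , drop = FALSE]
}

#' Convex-hull area of 2D points
#'
#' Area of the convex hull of the XY projection, by the shoelace formula on
#' the hull vertices.  Used for the crown projection area.
#'
#' @param points 2D points (data frame with `x`, `y` or 2-column matrix); at
#'   least 3 points, not all collinear.
#' @return Hull area in square metres.
#' @examples
#' convex_hull_area(data.frame(x = c(0, 1, 1, 0, 0.5), y = c(0, 0, 1, 1, 0.5)))
#' @export
convex_hull_area <- function(points) {
  xy <- as_xy(points)
  if (nrow(xy) < 3 || is_collinear_xy(xy)) {
    cm_abort("convex hull area needs at least 3 non-collinear points",
             "cm_error_degenerate")
  }
  h <- chull(xy[, 1], xy[, 2])
  hx <- xy[h, 1]; hy <- xy[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Construct a cylinder
#'
#' A finite closed cylinder given by its start point, unit axis direction,
#' length and radius — the geometric element of a quantitative structure
#' model (QSM).
#'
#' @param start Length-3 numeric, the axis start point (m).
#' @param axis Length-3 numeric direction; must be within 1e-6 of unit norm.
#' @param length Cylinder length (m), > 0.
#' @param radius Cylinder radius (m), > 0.
#' @return A `cylinder` object (named list).
#' @export
cylinder <- function(start, axis, length, radius) {
  stopifnot(is.numeric(start), length(start) == 3, all(is.finite(start)),
            is.numeric(axis), length(axis) == 3, all(is.finite(axis)),
            is_scalar_num(length), length > 0,
            is_scalar_num(radius), radius > 0)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-6) {
    cm_abort("cylinder axis must be a unit vector (|axis| within 1e-6 of 1)",
             "cm_error_type")
  }
  structure(list(start = as.double(start), axis = as.double(axis) / nrm,
                 length = as.double(length), radius = as.double(radius)),
            class = "cylinder")
}

#' Distance from points to a solid cylinder
#'
#' Euclidean distance from each point to a finite closed cylinder treated as
#' a *solid*: points on or inside the surface envelope return 0.  For a point
#' whose axial projection falls within `[0, length]` the distance is
#' `max(0, radial_distance - radius)`; beyond the caps it is the distance to
#' the nearest cap disk (face or rim).  This is the residual used by the QSM
#' fit-quality audit, which flags only points far *outside* the cylinder
#' model.
#'
#' @param points Point-cloud data frame (or length-3 numeric for one point).
#' @param cyl A [cylinder()], or anything coercible via its fields
#'   (`start`, `axis`, `length`, `radius`).
#' @return Numeric vector of distances (m), one per point.
#' @examples
#' cyl <- cylinder(c(0, 0, 0), c(0, 0, 1), length = 2, radius = 0.1)
#' point_to_cylinder_distance(c(0.3, 0, 1), cyl)
#' @export
point_to_cylinder_distance <- function(points, cyl) {
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 3) {
    points <- tibble(x = points[1], y = points[2], z = points[3])
  }
  cloud <- as_point_cloud(points, arg = "points")
  if (!inherits(cyl, "cylinder")) {
    cyl <- cylinder(cyl$start, cyl$axis, cyl$length, cyl$radius)
  }
  if (nrow(cloud) == 0) return(double())
  vx <- cloud$x - cyl$start[1]
  vy <- cloud$y - cyl$start[2]
  vz <- cloud$z - cyl$start[3]
  t_ax <- vx * cyl$axis[1] + vy * cyl$axis[2] + vz * cyl$axis[3]
  rad2 <- pmax(vx^2 + vy^2 + vz^2 - t_ax^2, 0)
  rad <- sqrt(rad2)
  dr <- pmax(rad - cyl$radius, 0)                     # radial excess
  dz <- pmax(pmax(-t_ax, t_ax - cyl$length), 0)       # axial excess past caps
  sqrt(dr^2 + dz^2)
}

# Minimum distance from each point to any cylinder in a list/table.
min_cylinder_distance <- function(cloud, cylinders) {
  cloud <- as_point_cloud(cloud)
  cyls <- cylinder_list(cylinders)
  if (length(cyls) == 0) {
    cm_abort("at least one cylinder is required", "cm_error_insufficient")
  }
  d <- rep(Inf, nrow(cloud))
  for (cyl in cyls) {
    d <- pmin(d, point_to_cylinder_distance(cloud, cyl))
  }
  d
}

# Coerce a cylinder table (Table-3-style tibble) or list of cylinder objects
# to a list of `cylinder`s.
cylinder_list <- function(cylinders) {
  if (inherits(cylinders, "cylinder")) return(list(cylinders))
  if (is.data.frame(cylinders)) {
    req <- c("start_x", "start_y", "start_z", "axis_x", "axis_y", "axis_z",
             "length", "radius")
    missing_cols <- setdiff(req, names(cylinders))
    if (length(missing_cols) > 0) {
      cm_abort(sprintf("cylinder table is missing column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "cm_error_schema")
    }
    return(purrr::pmap(
      list(cylinders$start_x, cylinders$start_y, cylinders$start_z,
           cylinders$axis_x, cylinders$axis_y, cylinders$axis_z,
           cylinders$length, cylinders$radius),
      function(sx, sy, sz, ax, ay, az, len, rad) {
        cylinder(c(sx, sy, sz), c(ax, ay, az), len, rad)
      }))
  }
  if (is.list(cylinders)) {
    return(lapply(cylinders, function(cyl) {
      if (inherits(cyl, "cylinder")) cyl
      else cylinder(cyl$start, cyl$axis, cyl$length, cyl$radius)
    }))
  }
  cm_abort("`cylinders` must be a cylinder, a list of cylinders, or a table",
           "cm_error_type")
}
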