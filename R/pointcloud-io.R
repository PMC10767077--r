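#' Read a point cloud from xyz(i) text
#'
#' Reads the plain-text single-tree point-cloud format used by leaf-off TLS
#' tree datasets: one point per line, three or four whitespace-separated
#' numbers.  The first three numbers are the x, y, z coordinates (metres,
#' z-up, local project frame); the optional fourth is the scanner return
#' intensity, which is carried through unchanged and uninterpreted.
#'
#' The `intensity` column is present in the result only when *every* line
#' carries a fourth field.  Blank lines are ignored; an empty file yields an
#' empty (0-point) cloud.
#'
#' @param path Path to the text file.
#' @return A tibble with columns `x`, `y`, `z` and optionally `intensity`,
#'   one row per point, input order preserved.
#' @seealso [write_xyzi()], [apply_transform()]
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("1.0 2.0 3.0 45.0", "1.5 2.5 3.5 47.0"), f)
#' read_xyzi(f)
#' @export
read_xyzi <- function(path) {
  if (!file.exists(path)) {
    cm_abort(sprintf("point-cloud file not found: %s", path), "cm_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(tibble(x = double(), y = double(), z = double()))
  }
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf != 3L & nf != 4L)
  if (length(bad) > 0) {
    cm_abort(sprintf(
      "malformed point-cloud line %d: expected 3 or 4 fields, found %d",
      keep[bad[1]], nf[bad[1]]), "cm_error_parse")
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad) > 0) {
    cm_abort(sprintf("malformed point-cloud line %d: non-numeric field",
                     keep[bad[1]]), "cm_error_parse")
  }
  m <- matrix(unlist(lapply(vals, `[`, 1:3)), ncol = 3, byrow = TRUE)
  cloud <- tibble(x = m[, 1], y = m[, 2], z = m[, 3])
  if (all(nf == 4L)) {
    cloud$intensity <- vapply(vals, `[`, double(1), 4L)
  }
  cloud
}

#' Write a point cloud to xyz(i) text
#'
#' Inverse of [read_xyzi()]: one line per point, `x y z` plus `intensity`
#' when the cloud has it.  Coordinates are written with 12 significant
#' digits, so a read/write round trip preserves them to well below 1e-9 m
#' at project-frame magnitudes.
#'
#' @param cloud Point-cloud data frame (columns `x`, `y`, `z`, optional
#'   `intensity`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyzi <- function(cloud, path) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) == 0) {
    lines <- character()
  } else if ("intensity" %in% names(cloud)) {
    lines <- sprintf("%.12g %.12g %.12g %.12g",
                     cloud$x, cloud$y, cloud$z, cloud$intensity)
  } else {
    lines <- sprintf("%.12g %.12g %.12g", cloud$x, cloud$y, cloud$z)
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) cm_abort(sprintf("cannot write point cloud to %s", path),
                    "cm_error_io")
  invisible(path)
}

#' Construct an affine project-to-global transform
#'
#' A scanning project's local frame is mapped to geocentric coordinates by a
#' single 4x4 homogeneous matrix: the upper-left 3x3 block holds the rotation
#' and scale terms, the fourth column the translation, and the last row is
#' `(0, 0, 0, 1)`.
#'
#' @param matrix A numeric 4x4 matrix with last row `(0,0,0,1)` (within 1e-9)
#'   and a non-singular upper-left 3x3 block.
#' @return An object of class `affine_transform` (the validated matrix).
#' @seealso [read_transform()], [apply_transform()], [inverse_transform()]
#' @examples
#' affine_transform(diag(4))
#' @export
affine_transform <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix) ||
      !identical(dim(matrix), c(4L, 4L)) || !all(is.finite(matrix))) {
    cm_abort("an affine transform must be a finite numeric 4x4 matrix",
             "cm_error_format")
  }
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-9) {
    cm_abort("last row of an affine transform must be (0, 0, 0, 1)",
             "cm_error_format")
  }
  if (abs(det(matrix[1:3, 1:3])) < 1e-12) {
    cm_abort("upper-left 3x3 block of an affine transform is singular",
             "cm_error_format")
  }
  structure(matrix, class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Read a 4x4 transformation matrix from text
#'
#' Parses a whitespace-delimited, row-major 4x4 matrix (16 numbers, any line
#' layout).  Lines starting with `#` are treated as comments and skipped.
#'
#' @param path Path to the matrix file.
#' @return An [affine_transform()] object.
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) {
    cm_abort(sprintf("transform file not found: %s", path), "cm_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  tokens <- unlist(strsplit(trimws(lines[nzchar(trimws(lines))]), "[ \t,]+"))
  vals <- suppressWarnings(as.numeric(tokens))
  if (anyNA(vals)) {
    cm_abort(sprintf("transform file %s contains a non-numeric field", path),
             "cm_error_format")
  }
  if (length(vals) != 16) {
    cm_abort(sprintf("transform file %s holds %d numbers; expected 16",
                     path, length(vals)), "cm_error_format")
  }
  affine_transform(matrix(vals, nrow = 4, byrow = TRUE))
}

#' Write a transformation matrix to text
#'
#' @param transform An [affine_transform()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "affine_transform"))
  m <- unclass(transform)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             path)
  invisible(path)
}

#' Apply an affine transform to points
#'
#' Maps coordinates through the homogeneous 4x4 matrix (project frame to
#' global frame).  Accepts either a point-cloud data frame, whose `x`, `y`,
#' `z` columns are replaced (all other columns, e.g. `intensity`, carried
#' through unchanged), or a single point as a length-3 numeric vector.
#'
#' @param x Point-cloud data frame or length-3 numeric `c(x, y, z)`.
#' @param transform An [affine_transform()].
#' @return Same shape as `x`, with transformed coordinates.
#' @examples
#' t90 <- affine_transform(rbind(c(0, -1, 0, 0), c(1, 0, 0, 0),
#'                               c(0, 0, 1, 0), c(0, 0, 0, 1)))
#' apply_transform(c(1, 0, 0), t90)
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "affine_transform"))
  m <- unclass(transform)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3) {
    out <- m %*% c(x, 1)
    return(setNames(as.vector(out)[1:3], c("x", "y", "z")))
  }
  cloud <- as_point_cloud(x, arg = "x")
  if (nrow(cloud) == 0) return(cloud)
  h <- m %*% rbind(cloud$x, cloud$y, cloud$z, 1)
  cloud$x <- h[1, ]
  cloud$y <- h[2, ]
  cloud$z <- h[3, ]
  cloud
}

#' Invert an affine transform
#'
#' Utility for mapping global coordinates back into the project frame (and
#' for round-trip checks); the published pipeline itself only maps project to
#' global.
#'
#' @param transform An [affine_transform()].
#' @return The inverse [affine_transform()].
#' @export
inverse_transform <- function(transform) {
  stopifnot(inherits(transform, "affine_transform"))
  inv <- solve(unclass(transform))
  inv[4, ] <- c(0, 0, 0, 1)  # clamp rounding in the homogeneous row
  affine_transform(inv)
}
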