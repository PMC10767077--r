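#' Statistical outlier removal by mean k-nearest-neighbour distance
#'
#' First stage of the measurement pipeline.  For every point the mean
#' Euclidean distance to its `k` nearest neighbours (excluding itself) is
#' computed on the *original* cloud, and a point is removed iff that mean
#' strictly exceeds `threshold`.  The filter is a single pass, not iterated:
#' neighbourhoods are never recomputed on the partially cleaned cloud.
#'
#' With the default `k = 20` and `threshold = 0.30` m this reproduces the
#' standard TLS single-tree denoising rule (points whose average distance to
#' their 20 closest neighbours exceeds 30 cm are discarded).  When the cloud
#' has `n <= k` points, `k` is reduced to `n - 1`.  Neighbour ties at the
#' k-th distance are broken arbitrarily (exactly `k` neighbours are used),
#' which can matter only on degenerate, perfectly symmetric inputs.
#'
#' @param cloud Point-cloud data frame with at least 2 points.
#' @param k Number of neighbours (default 20).
#' @param threshold Mean-distance cut-off in metres (default 0.30).
#' @return An object of class `outlier_report`:
#' \describe{
#'   \item{kept}{tibble of retained points, input order preserved}
#'   \item{removed}{tibble of removed points}
#'   \item{removed_indices}{integer indices of removed points in the input}
#'   \item{mean_knn_distance}{numeric vector, one mean distance per input point}
#'   \item{k, threshold}{the parameters used (`k` after any reduction)}
#' }
#' @examples
#' pts <- expand.grid(x = 0:5 * 0.02, y = 0:5 * 0.02, z = 0)
#' rep <- remove_outliers(rbind(pts, c(50, 50, 50)))
#' rep$removed_indices
#' @export
remove_outliers <- function(cloud, k = cm_defaults()$knn,
                            threshold = cm_defaults()$outlier_threshold) {
  cloud <- as_point_cloud(cloud)
  n <- nrow(cloud)
  if (n < 2) {
    cm_abort("outlier removal needs at least 2 points", "cm_error_insufficient")
  }
  stopifnot(is_count(k), k >= 1, is_scalar_num(threshold), threshold >= 0)
  k_eff <- as.integer(min(k, n - 1))
  xyz <- pc_xyz(cloud)
  # exact kd-tree search; column 1 is the query point itself (distance 0)
  nn <- RANN::nn2(xyz, xyz, k = k_eff + 1L)
  mean_d <- rowMeans(nn$nn.dists[, -1, drop = FALSE])
  removed <- which(mean_d > threshold)
  structure(
    list(
      kept = cloud[setdiff(seq_len(n), removed), , drop = FALSE],
      removed = cloud[removed, , drop = FALSE],
      removed_indices = as.integer(removed),
      mean_knn_distance = mean_d,
      k = k_eff,
      threshold = threshold
    ),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "<outlier_report> %d points: %d kept, %d removed (k = %d, threshold = %g m)\n",
    length(x$mean_knn_distance), nrow(x$kept), length(x$removed_indices),
    x$k, x$threshold))
  invisible(x)
}

#' @describeIn remove_outliers Per-point table: coordinates, mean k-NN
#'   distance and an `outlier` flag.
#' @param x An `outlier_report`.
#' @param ... Unused.
#' @export
tidy.outlier_report <- function(x, ...) {
  n <- length(x$mean_knn_distance)
  tibble(index = seq_len(n),
         mean_knn_distance = x$mean_knn_distance,
         outlier = seq_len(n) %in% x$removed_indices)
}

#' @describeIn remove_outliers One-row summary (counts and parameters).
#' @export
glance.outlier_report <- function(x, ...) {
  tibble(
    n_points = length(x$mean_knn_distance),
    n_kept = nrow(x$kept),
    n_removed = length(x$removed_indices),
    k = x$k,
    threshold = x$threshold
  )
}
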