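# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (O(n^2) searches, dense surface sampling, grid+polish
# optimisation) so they share no code path with the package implementation.

# Mean distance to the k nearest neighbours, by full distance matrix.
bf_mean_knn <- function(cloud, k) {
  xyz <- cbind(cloud$x, cloud$y, cloud$z)
  n <- nrow(xyz)
  k_eff <- min(k, n - 1)
  d <- as.matrix(dist(xyz))
  diag(d) <- Inf
  apply(d, 1, function(row) mean(sort(row)[seq_len(k_eff)]))
}

bf_outlier_partition <- function(cloud, k = 20, threshold = 0.30) {
  which(bf_mean_knn(cloud, k) > threshold)
}

# Sum of squared radial residuals of a candidate circle.
bf_circle_objective <- function(par, xy) {
  sum((sqrt((xy[, 1] - par[1])^2 + (xy[, 2] - par[2])^2) - par[3])^2)
}

# Grid search over (cx, cy, r) followed by a Nelder-Mead polish; returns the
# minimised objective value.
bf_circle_grid_polish <- function(xy) {
  cx0 <- mean(xy[, 1]); cy0 <- mean(xy[, 2])
  r0 <- mean(sqrt((xy[, 1] - cx0)^2 + (xy[, 2] - cy0)^2))
  grid <- expand.grid(cx = cx0 + seq(-0.05, 0.05, by = 0.005),
                      cy = cy0 + seq(-0.05, 0.05, by = 0.005),
                      r = r0 + seq(-0.05, 0.05, by = 0.005))
  vals <- apply(grid, 1, bf_circle_objective, xy = xy)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- optim(best, bf_circle_objective, xy = xy, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Dense deterministic sampling of a finite closed cylinder surface
# (lateral sheet + two cap disks, sunflower layout on the caps).
bf_cylinder_surface_samples <- function(cyl, n = 1e5) {
  stopifnot(inherits(cyl, "cylinder"))
  r <- cyl$radius; len <- cyl$length
  a_lat <- 2 * pi * r * len
  a_cap <- pi * r^2
  n_cap <- max(1L, round(n * a_cap / (a_lat + 2 * a_cap)))
  n_lat <- n - 2 * n_cap
  n_z <- max(2L, round(sqrt(n_lat * len / (2 * pi * r))))
  n_phi <- max(3L, ceiling(n_lat / n_z))
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  zs <- len * (seq_len(n_z) - 0.5) / n_z
  lat <- cbind(r * cos(rep(phi, times = n_z)),
               r * sin(rep(phi, times = n_z)),
               rep(zs, each = n_phi))
  i <- seq_len(n_cap)
  cr <- r * sqrt((i - 0.5) / n_cap)
  ca <- i * 2.39996322972865332
  cap <- cbind(cr * cos(ca), cr * sin(ca))
  pts <- rbind(lat,
               cbind(cap[, 1], cap[, 2], 0),
               cbind(cap[, 1], cap[, 2], len))
  # rotate local frame (axis = +z) onto the cylinder axis, then translate
  ax <- cyl$axis
  helper <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- helper - sum(helper * ax) * ax
  u <- u / sqrt(sum(u^2))
  v <- c(ax[2] * u[3] - ax[3] * u[2],
         ax[3] * u[1] - ax[1] * u[3],
         ax[1] * u[2] - ax[2] * u[1])
  world <- pts[, 1] %o% u + pts[, 2] %o% v + pts[, 3] %o% ax
  sweep(world, 2, cyl$start, "+")
}

# Minimum distance from each query point to any sample point (chunked).
bf_min_dist_to_samples <- function(points, samples) {
  q <- as.matrix(points)
  s2 <- rowSums(samples^2)
  out <- numeric(nrow(q))
  idx <- split(seq_len(nrow(q)), ceiling(seq_len(nrow(q)) / 100))
  for (ii in idx) {
    qq <- q[ii, , drop = FALSE]
    d2 <- outer(rowSums(qq^2), s2, "+") - 2 * qq %*% t(samples)
    out[ii] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# Exact containment test for the solid cylinder (independent of the
# distance code path).
bf_inside_cylinder <- function(points, cyl) {
  q <- as.matrix(points)
  v <- sweep(q, 2, cyl$start)
  t_ax <- v %*% cyl$axis
  rad2 <- rowSums(v^2) - t_ax^2
  t_ax >= 0 & t_ax <= cyl$length & rad2 <= cyl$radius^2 + 1e-12
}

# Deterministic stack of circular rings: a hand-built "trunk" cloud with an
# explicit radius profile, used where the full generator would be overkill.
ring_stack_cloud <- function(z_values, radius_at, spacing = 0.02,
                             center = c(0, 0)) {
  rows <- lapply(z_values, function(z) {
    r <- radius_at(z)
    n <- max(3L, ceiling(2 * pi * r / spacing))
    t <- 2 * pi * (seq_len(n) - 1) / n
    data.frame(x = center[1] + r * cos(t), y = center[2] + r * sin(t), z = z)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# Random well-conditioned affine transform (rotation + scale + translation).
random_transform <- function() {
  ang <- runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  rz <- rbind(c(cos(ang[2]), -sin(ang[2]), 0),
              c(sin(ang[2]), cos(ang[2]), 0), c(0, 0, 1))
  s <- runif(1, 0.5, 2)
  m <- diag(4)
  m[1:3, 1:3] <- s * rz %*% rx
  m[1:3, 4] <- runif(3, -100, 100)
  affine_transform(m)
}

random_cloud <- function(n, scale = 1) {
  tibble::tibble(x = runif(n, -scale, scale),
                 y = runif(n, -scale, scale),
                 z = runif(n, -scale, scale))
}
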