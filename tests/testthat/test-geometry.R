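test_that("fit_circle is exact on noise-free circles", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]  # 8 points at 45 degrees
  fit <- fit_circle(data.frame(x = cos(th), y = sin(th)))
  expect_lt(abs(fit$center_x), 1e-9)
  expect_lt(abs(fit$center_y), 1e-9)
  expect_lt(abs(fit$radius - 1), 1e-9)
  expect_lt(fit$rms_residual, 1e-9)

  th12 <- seq(0, 2 * pi, length.out = 13)[-13]
  fit12 <- fit_circle(data.frame(x = 2.5 + 0.15 * cos(th12),
                                 y = -1.0 + 0.15 * sin(th12)))
  expect_lt(abs(fit12$center_x - 2.5), 1e-9)
  expect_lt(abs(fit12$center_y + 1.0), 1e-9)
  expect_lt(abs(fit12$radius - 0.15), 1e-9)
})

test_that("fit_circle reaches the grid+polish optimum on noisy circles", {
  for (seed in 1:5) {
    withr::local_seed(seed)
    th <- runif(50, 0, 2 * pi)
    r_noisy <- 0.2 + rnorm(50, sd = 0.005)
    xy <- cbind(r_noisy * cos(th), r_noisy * sin(th))
    fit <- fit_circle(xy)
    oracle <- bf_circle_grid_polish(xy)
    expect_lt(abs(fit$objective - oracle), 1e-6)
    expect_lte(fit$objective, oracle + 1e-6)  # never worse than the oracle
  }
})

test_that("fit_circle rejects degenerate input", {
  expect_error(fit_circle(data.frame(x = c(0, 1), y = c(0, 1))),
               class = "cm_error_degenerate")
  expect_error(fit_circle(data.frame(x = c(0, 1, 2), y = c(0, 1, 2))),
               class = "cm_error_degenerate")
})

test_that("fit_circle is invariant to rigid motion", {
  withr::local_seed(31)
  th <- runif(40, 0, 2 * pi)
  xy <- cbind(0.3 * cos(th) + rnorm(40, sd = 0.004),
              0.3 * sin(th) + rnorm(40, sd = 0.004))
  base <- fit_circle(xy)
  ang <- 0.7; shift <- c(12, -3)
  rot <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  moved <- sweep(xy %*% t(rot), 2, shift, "+")
  fit <- fit_circle(moved)
  ctr <- rot %*% c(base$center_x, base$center_y) + shift
  expect_lt(abs(fit$center_x - ctr[1]), 1e-9)
  expect_lt(abs(fit$center_y - ctr[2]), 1e-9)
  expect_lt(abs(fit$radius - base$radius), 1e-9)
  expect_lt(abs(fit$rms_residual - base$rms_residual), 1e-9)
})

test_that("horizontal_slice is half-open and order-preserving", {
  cloud <- tibble::tibble(x = 1:3, y = 1:3, z = c(0.0, 1.30, 2.0))
  expect_equal(nrow(horizontal_slice(cloud, 1.27, 1.33)), 1)
  expect_equal(horizontal_slice(cloud, 1.27, 1.33)$x, 2)
  expect_equal(nrow(horizontal_slice(cloud, 5, 6)), 0)
  boundary <- tibble::tibble(x = 0, y = 0, z = 1.33)
  expect_equal(nrow(horizontal_slice(boundary, 1.27, 1.33)), 0)
  expect_error(horizontal_slice(cloud, 2, 1), class = "cm_error_type")
})

test_that("convex_hull_area matches closed forms and ignores interior points", {
  square <- data.frame(x = c(0, 1, 1, 0, 0.5, 0.25),
                       y = c(0, 0, 1, 1, 0.5, 0.75))
  expect_equal(convex_hull_area(square), 1.0)

  n <- 3600
  t <- 2 * pi * (seq_len(n) - 1) / n
  ngon <- data.frame(x = 2 * cos(t), y = 2 * sin(t))
  exact <- (n / 2) * 4 * sin(2 * pi / n)  # inscribed regular n-gon
  expect_equal(convex_hull_area(ngon), exact, tolerance = 1e-12)
  expect_lt(abs(convex_hull_area(ngon) - pi * 4) / (pi * 4), 0.005)

  # duplication and interior insertion leave the hull unchanged
  expect_equal(convex_hull_area(rbind(square, square)), 1.0)

  expect_error(convex_hull_area(data.frame(x = c(0, 1, 2), y = c(0, 1, 2))),
               class = "cm_error_degenerate")
})

test_that("point_to_cylinder_distance handles surface, interior and caps", {
  cyl <- cylinder(c(0, 0, 0), c(0, 0, 1), length = 2, radius = 0.1)
  expect_equal(point_to_cylinder_distance(c(0.1, 0, 1), cyl), 0)
  expect_equal(point_to_cylinder_distance(c(0, 0, 1), cyl), 0)  # inside solid
  expect_equal(point_to_cylinder_distance(c(0.3, 0, 1), cyl), 0.2)
  expect_equal(point_to_cylinder_distance(c(0, 0, -0.5), cyl), 0.5)  # below cap face
  expect_equal(point_to_cylinder_distance(c(0.4, 0, 2.4), cyl),
               sqrt(0.3^2 + 0.4^2))  # past the cap rim
})

test_that("point_to_cylinder_distance agrees with a dense surface oracle", {
  withr::local_seed(5)
  cyl <- cylinder(c(0.2, -0.1, 0.3), c(1, 2, 2) / 3, length = 0.8,
                  radius = 0.1)
  pts <- tibble::tibble(x = runif(200, -0.4, 1.0),
                        y = runif(200, -0.6, 0.8),
                        z = runif(200, -0.3, 1.3))
  d <- point_to_cylinder_distance(pts, cyl)
  samples <- bf_cylinder_surface_samples(cyl, n = 1e5)
  d_oracle <- bf_min_dist_to_samples(cbind(pts$x, pts$y, pts$z), samples)
  inside <- bf_inside_cylinder(cbind(pts$x, pts$y, pts$z), cyl)
  expect_true(all(d[inside] == 0))
  expect_lt(max(abs(d[!inside] - d_oracle[!inside])), 0.002)
})

test_that("point_to_cylinder_distance is 1-Lipschitz", {
  withr::local_seed(9)
  cyl <- cylinder(c(0, 0, 0), c(0, 1, 0), length = 1.5, radius = 0.25)
  p <- random_cloud(300, scale = 2)
  q <- random_cloud(300, scale = 2)
  dp <- point_to_cylinder_distance(p, cyl)
  dq <- point_to_cylinder_distance(q, cyl)
  step <- sqrt((p$x - q$x)^2 + (p$y - q$y)^2 + (p$z - q$z)^2)
  expect_true(all(abs(dp - dq) <= step + 1e-12))
})
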