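# A tiny hand-written cylinder table in the dataset's CSV vocabulary.
demo_cyl_table <- function() {
  tibble::tibble(
    date = "2026-01-01", projectID = "p1", treeID = "t1",
    branchID = 1L, branchOrder = 0L,
    cylinderID = 1:3, posInBranch = 1:3,
    parentCylID = c(0L, 1L, 2L), childCyID = c(2L, 3L, 0L),
    start_x = 0, start_y = 0, start_z = c(0, 1, 2),
    axis_x = 0, axis_y = 0, axis_z = 1,
    length = 1, radius = c(0.2, 0.15, 0.1), addedVirtual = 0L)
}

test_that("cylinder CSVs round trip and keep row order", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_cylinders(demo_cyl_table(), f)
  cyl <- read_cylinders(f)
  expect_equal(nrow(cyl), 3)
  expect_equal(cyl$cylinder_id, 1:3)
  expect_equal(cyl$radius, c(0.2, 0.15, 0.1))
  expect_equal(cyl$parent_cyl_id, c(0L, 1L, 2L))
})

test_that("schema violations fail loudly, naming the offender", {
  f <- withr::local_tempfile(fileext = ".csv")
  broken <- demo_cyl_table()
  broken$radius <- NULL
  readr::write_csv(broken, f)
  expect_error(read_cylinders(f), "radius", class = "cm_error_schema")

  dup <- demo_cyl_table()
  dup$cylinderID <- c(1L, 1L, 3L)
  expect_error(as_cylinders(dup), "1", class = "cm_error_validation")

  selfp <- demo_cyl_table()
  selfp$parentCylID <- c(0L, 2L, 3L)
  expect_error(as_cylinders(selfp), class = "cm_error_validation")
})

test_that("off-unit axes are renormalized with a warning and flagged", {
  odd <- demo_cyl_table()
  odd$axis_z <- c(1, 2, 1)  # row 2 has |axis| = 2
  expect_warning(cyl <- as_cylinders(odd), class = "cm_warning_validation")
  expect_equal(cyl$axis_z, c(1, 1, 1))
  expect_equal(cyl$axis_renormalized, c(FALSE, TRUE, FALSE))
  # within-tolerance deviations renormalize silently
  ok <- demo_cyl_table()
  ok$axis_z <- 1 + 5e-3
  expect_no_warning(as_cylinders(ok))
})

test_that("build_graph wires parent edges, finds roots, rejects cycles", {
  g <- build_graph(demo_cyl_table())
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$roots, 1L)
  expect_equal(g$edges$from, c(1L, 2L))
  expect_equal(g$edges$to, c(2L, 3L))

  mutual <- demo_cyl_table()[1:2, ]
  mutual$parentCylID <- c(2L, 1L)
  expect_error(build_graph(mutual), "cycle", class = "cm_error_topology")
})

test_that("generated QSMs build single-root acyclic graphs at any size", {
  tree <- generate_tree(synthetic_tree_spec(
    seed = 12, dbh = 0.4, tree_height = 20, crown_start = 5,
    crown_shape = "ellipsoid", crown_radius_x = 3, branch_count = 160L,
    point_spacing = 0.2, noise_sigma = 0))
  expect_equal(nrow(tree$cylinders), 200)
  g <- build_graph(tree$cylinders)
  expect_equal(nrow(g$nodes), 200)
  expect_equal(nrow(g$edges), 199)
  expect_length(g$roots, 1)
  expect_true(igraph::is_dag(g$graph))
  expect_equal(glance(g)$max_branch_order, 1L)
})

test_that("total volume is the closed-form cylinder sum in litres", {
  one <- demo_cyl_table()[1, ]
  one$radius <- 0.1; one$length <- 1
  expect_equal(total_volume(one), 1000 * pi * 0.1^2 * 1, tolerance = 1e-9)

  empty <- demo_cyl_table()[0, ]
  expect_equal(total_volume(empty), 0)

  withr::local_seed(13)
  many <- demo_cyl_table()[rep(1, 100), ]
  many$cylinderID <- 1:100
  many$parentCylID <- 0:99
  many$radius <- runif(100, 0.01, 0.3)
  many$length <- runif(100, 0.1, 2)
  expect_equal(total_volume(many),
               sum(vapply(1:100, function(i) {
                 1000 * pi * many$radius[i]^2 * many$length[i]
               }, double(1))),
               tolerance = 1e-9)
  # additive over any split
  expect_equal(total_volume(many),
               total_volume(many[1:40, ]) + total_volume(many[41:100, ]))
})

test_that("the fit audit flags exactly the far points", {
  pole <- generate_tree(synthetic_tree_spec(
    seed = 14, dbh = 0.4, tree_height = 4, crown_shape = "none", taper = 0,
    point_spacing = 0.03, noise_sigma = 0))
  check <- flag_unfitted_points(pole$cloud, pole$cylinders)
  expect_equal(check$n_not_fitted, 0)

  with_far <- dplyr::bind_rows(pole$cloud,
                               tibble::tibble(x = 5, y = 5, z = 2,
                                              intensity = 0.5))
  check2 <- flag_unfitted_points(with_far, pole$cylinders)
  expect_equal(check2$n_not_fitted, 1)
  expect_false(tail(tidy(check2)$fitted, 1))

  expect_error(flag_unfitted_points(pole$cloud, pole$cylinders[0, ]),
               class = "cm_error_insufficient")
})

test_that("noisy on-model points stay almost entirely within 5 cm", {
  pole <- generate_tree(synthetic_tree_spec(
    seed = 15, dbh = 0.4, tree_height = 6, crown_shape = "none",
    point_spacing = 0.02, noise_sigma = 0.005))
  check <- flag_unfitted_points(pole$cloud, pole$cylinders, threshold = 0.05)
  expect_lt(glance(check)$not_fitted_fraction, 0.01)

  # monotone in the threshold
  loose <- flag_unfitted_points(pole$cloud, pole$cylinders, threshold = 0.10)
  strict <- flag_unfitted_points(pole$cloud, pole$cylinders, threshold = 0.02)
  expect_lte(loose$n_not_fitted, check$n_not_fitted)
  expect_lte(check$n_not_fitted, strict$n_not_fitted)
})

test_that("graph serialization round trips losslessly", {
  f <- withr::local_tempfile(fileext = ".json")

  empty <- build_graph(demo_cyl_table()[0, ])
  write_graph(empty, f)
  expect_equal(nrow(read_graph(f)$nodes), 0)

  chain <- build_graph(demo_cyl_table())
  write_graph(chain, f)
  back <- read_graph(f)
  expect_equal(back$nodes, chain$nodes)
  expect_equal(back$edges, chain$edges)
  expect_equal(back$roots, chain$roots)

  big <- build_graph(generate_tree(synthetic_tree_spec(
    seed = 16, dbh = 0.4, tree_height = 20, crown_start = 5,
    crown_shape = "cylinder", crown_radius_x = 2.5, branch_count = 160L,
    point_spacing = 0.2))$cylinders)
  write_graph(big, f)
  big_back <- read_graph(f)
  expect_equal(big_back$nodes, big$nodes, tolerance = 1e-12)
  expect_equal(big_back$edges, big$edges)

  writeLines("{\"format\": \"something-else\"}", f)
  expect_error(read_graph(f), class = "cm_error_parse")
})
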