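test_that("build_grid shapes, voxel volumes, and argument checking", {
  g <- build_grid(c(80, 80, 80), 1)
  expect_identical(g$shape, c(80L, 80L, 80L))
  expect_equal(voxel_volume(g), 1)
  expect_equal(n_voxels(build_grid(c(10, 10, 10), 0.5)), 8000)
  expect_error(build_grid(c(10, 10, 10), c(0, 1, 1)), "positive")
  expect_error(build_grid(c(-1, 10, 10), 1), "positive")
})

test_that("rasterized ellipsoids converge to the analytic volume", {
  # 14 x 9 x 15 mm tumor at 0.5 mm spacing: 4/3 pi abc = 0.990 cm^3
  g <- build_grid(c(20, 20, 20), 0.5)
  sc <- rasterize_ellipsoid(new_scene(g), c(10, 10, 10), c(7, 4.5, 7.5))
  expect_lt(abs(label_volume(sc, "tumor") - 0.990) / 0.990, 0.05)

  # unit sphere at 0.1 mm spacing: 4.19 mm^3 within 2%
  g2 <- build_grid(c(4, 4, 4), 0.1)
  sc2 <- rasterize_ellipsoid(new_scene(g2), c(2, 2, 2), c(1, 1, 1))
  expect_lt(abs(label_volume(sc2, "tumor") * 1000 - 4.18879) / 4.18879, 0.02)

  # error strictly decreases with spacing
  err <- vapply(c(2, 1, 0.5), function(sp) {
    sc <- rasterize_ellipsoid(new_scene(build_grid(c(20, 20, 20), sp)),
                              c(10, 10, 10), c(7, 4.5, 7.5))
    abs(label_volume(sc, "tumor") - 0.990)
  }, 1.0)
  expect_true(all(diff(err) < 0))

  # fully outside the grid: warning, no change
  sc3 <- new_scene(build_grid(c(10, 10, 10), 1))
  expect_warning(sc4 <- rasterize_ellipsoid(sc3, c(1000, 0, 0), c(1, 1, 1)),
                 "does not intersect")
  expect_identical(sc4$labels, sc3$labels)
  expect_error(rasterize_ellipsoid(sc3, c(5, 5, 5), c(-1, 1, 1)), "positive")
})

test_that("rasterized cylinders converge to pi r^2 h and keep thin axes", {
  g <- build_grid(c(20, 20, 36), 0.5)
  sc <- rasterize_capsule(new_scene(g), c(10, 10, 4), c(10, 10, 32), 4)
  expect_lt(abs(label_volume(sc, "vessel") - 1.40743) / 1.40743, 0.05)

  # 8 mm diameter, 60 mm long vessel: 3.016 cm^3
  g2 <- build_grid(c(20, 20, 70), 0.5)
  sc2 <- rasterize_capsule(new_scene(g2), c(10, 10, 5), c(10, 10, 65), 4)
  expect_lt(abs(label_volume(sc2, "vessel") - 3.01593) / 3.01593, 0.05)

  # radius below half the spacing: axis voxels still labeled
  g3 <- build_grid(c(10, 10, 10), 1)
  sc3 <- rasterize_capsule(new_scene(g3), c(5.2, 5.2, 1), c(5.2, 5.2, 9), 0.1)
  expect_gte(sum(sc3$labels == 3L), 8)
  expect_error(rasterize_capsule(sc3, c(1, 1, 1), c(1, 1, 1), 1), "degenerate")
})

test_that("label maps are partition-complete", {
  sc <- synthetic_case(spacing = 2)
  tab <- table(sc$labels)
  expect_equal(sum(tab), n_voxels(sc$grid))
})

test_that("place_electrode labels the stated exposure and stays disjoint", {
  g <- build_grid(c(40, 40, 40), 1)
  sc <- new_scene(g, fill = "liver")
  e1 <- electrode(c(11, 20, 35), c(0, 0, 1), 1, exposure_length = 20,
                  insulated_length = 10)
  sc <- place_electrode(sc, e1)
  act <- which(sc$labels == ireplan:::label_code("electrode_active", 1),
               arr.ind = TRUE)
  zs <- (act[, 3] - 0.5) * 1
  expect_lt(abs(diff(range(zs)) - 20), 1 + 1e-9)  # 20 mm +/- one voxel
  expect_gt(sum(sc$labels == ireplan:::label_code("electrode_insulated", 1)), 0)

  sc <- place_electrode(sc, electrode(c(29, 20, 35), c(0, 0, 1), 2,
                                      insulated_length = 0))
  a1 <- sc$labels == ireplan:::label_code("electrode_active", 1)
  a2 <- sc$labels == ireplan:::label_code("electrode_active", 2)
  expect_equal(sum(a1 & a2), 0)
  expect_equal(sum(sc$labels == ireplan:::label_code("electrode_insulated", 2)),
               0)
  expect_error(place_electrode(sc, electrode(c(200, 20, 20), c(0, 0, 1), 3)),
               "outside")
})

test_that("pairwise_geometry reports distances/angles and is order-invariant", {
  e1 <- electrode(c(0, 0, 30), c(0, 0, 1), 1)
  e2 <- electrode(c(18, 0, 30), c(0, 0, 1), 2)
  th <- 4.1 * pi / 180
  e3 <- electrode(c(0, 10, 30), c(sin(th), 0, cos(th)), 3)
  pg <- pairwise_geometry(list(e1, e2, e3))
  expect_equal(pg$distance_mm[pg$pair == "1-2"], 18)
  expect_equal(pg$angle_deg[pg$pair == "1-2"], 0)
  expect_equal(pg$angle_deg[pg$pair == "1-3"], 4.1, tolerance = 1e-6)

  sc <- synthetic_case(spacing = 2)
  pg4 <- pairwise_geometry(sc)
  expect_equal(nrow(pg4), 6)
  pg4r <- pairwise_geometry(rev(sc$electrodes))
  expect_equal(pg4, pg4r)
  expect_error(pairwise_geometry(list(e1)), "at least two")
})

test_that("synthetic_case reproduces the reconstructed geometry", {
  sc <- synthetic_case(spacing = 1)
  pg <- pairwise_geometry(sc)
  ref <- c("1-2" = 18, "1-3" = 14, "1-4" = 12,
           "2-3" = 15, "2-4" = 12, "3-4" = 17)
  expect_true(all(abs(pg$distance_mm - ref[pg$pair]) < 1))
  expect_true(all(pg$angle_deg < 6))
  expect_equal(nrow(sc$protocol), 18)

  sc5 <- synthetic_case(spacing = 0.5)
  expect_lt(abs(label_volume(sc5, "tumor") - 0.990) / 0.990, 0.10)

  expect_identical(synthetic_case(spacing = 2, seed = 7)$labels,
                   synthetic_case(spacing = 2, seed = 7)$labels)
})

test_that("closed-form volumes match their formulas", {
  expect_equal(ellipsoid_volume(c(17, 14.5, 17.5)), 18.068, tolerance = 1e-4)
  expect_lt(abs(ellipsoid_volume(c(17, 14.5, 17.5)) - 18.05) / 18.05, 0.002)
  expect_equal(ellipsoid_volume(c(10, 10, 10)), 4.18879, tolerance = 1e-5)
  expect_equal(ellipsoid_volume(c(7, 4.5, 7.5)), 0.98960, tolerance = 1e-4)
  expect_error(ellipsoid_volume(c(0, 1, 1)), "positive")

  expect_equal(safety_margin_volume(c(14, 9, 15), 10), 18.068,
               tolerance = 1e-4)
  expect_equal(safety_margin_volume(c(14, 9, 15), 0),
               ellipsoid_volume(c(7, 4.5, 7.5)))
  # semi-axes (12, 9.5, 12.5): 4/3 pi * 1425 mm^3
  expect_equal(safety_margin_volume(c(14, 9, 15), 5), 5.96903,
               tolerance = 1e-4)

  expect_equal(cylinder_hot_zone_volume(4, 4, 28), 5.62973, tolerance = 1e-4)
  expect_equal(cylinder_hot_zone_volume(1, 4, 28), 1.40743, tolerance = 1e-4)
  expect_equal(cylinder_hot_zone_volume(0, 4, 28), 0)
})
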