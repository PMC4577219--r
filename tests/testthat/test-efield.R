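test_that("parallel-plate slab reproduces V/d and Ohm's law", {
  # 10 mm tissue gap, 100 V: E = 100 V/cm; sigma U A / d = 0.4 A
  sc <- plate_scene(n_gap = 10, spacing = 1, ny = 20, nz = 20)
  m <- frozen_materials(0.1)
  sol <- solve_pair(sc, m, boundary_assignment(c(1, 2), 100),
                    sigma_e = FALSE, n_iter = 1)
  interior <- array(FALSE, dim = sc$grid$shape)
  interior[3:10, , ] <- TRUE  # away from the smeared metal interface
  expect_lt(max(abs(sol$E_mag[interior] - 100)) / 100, 0.01)
  expect_equal(sol$current, 0.1 * 100 * (0.02 * 0.02) / 0.01,
               tolerance = 0.02)
  cc <- compute_current(sol)
  expect_lt(cc$relative_difference, 0.02)
})

test_that("field and current scale linearly when sigma(E) is off", {
  sc <- two_needle_scene(spacing = 2)
  m <- frozen_materials(0.2)
  s1 <- solve_pair(sc, m, boundary_assignment(c(1, 2), 500),
                   sigma_e = FALSE, n_iter = 1)
  s3 <- solve_pair(sc, m, boundary_assignment(c(1, 2), 1500),
                   sigma_e = FALSE, n_iter = 1)
  expect_equal(s3$current / s1$current, 3, tolerance = 1e-6)
  expect_equal(max(abs(s3$E_mag - 3 * s1$E_mag)) / max(s3$E_mag), 0,
               tolerance = 1e-6)

  # doubling sigma doubles the current and leaves the field unchanged
  s2 <- solve_pair(sc, frozen_materials(0.4),
                   boundary_assignment(c(1, 2), 500),
                   sigma_e = FALSE, n_iter = 1)
  expect_equal(s2$current / s1$current, 2, tolerance = 1e-6)
  expect_lt(max(abs(s2$E_mag - s1$E_mag)) / max(s1$E_mag), 1e-6)

  # zero voltage: zero field, zero current
  s0 <- solve_pair(sc, m, boundary_assignment(c(1, 2), 0),
                   sigma_e = FALSE, n_iter = 1)
  expect_equal(s0$current, 0)
  expect_lt(max(s0$E_mag), 1e-9)
})

test_that("conductivity rise increases current monotonically", {
  sc <- two_needle_scene(spacing = 2)
  m <- default_material_table()
  ba <- boundary_assignment(c(1, 2), 2400)
  s_on <- solve_pair(sc, m, ba)
  s_off <- solve_pair(sc, m, ba, sigma_e = FALSE)
  expect_gt(s_on$current, s_off$current)

  # energy bookkeeping: the Joule density integrates exactly to U * I
  expect_equal(sum(s_on$joule) * voxel_volume(sc$grid) * 1e-9,
               2400 * s_on$current, tolerance = 1e-9)

  tr <- field_iteration_trace(s_on)
  expect_equal(nrow(tr), 6)
  expect_true(all(diff(tr$current_A) >= -1e-9))
  expect_true(all(diff(tr$electroporated_cm3) >= -1e-12))
  expect_true(all(s_on$E_peak >= s_on$E_mag - 1e-9))

  tr_off <- field_iteration_trace(s_off)
  expect_lt(diff(range(tr_off$current_A)), 1e-9 * tr_off$current_A[1])

  # voltage too low to electroporate anything: no conductivity change
  s_low <- solve_pair(sc, m, boundary_assignment(c(1, 2), 5))
  expect_equal(field_iteration_trace(s_low)$electroporated_cm3,
               rep(0, 6))
})

test_that("field inside a conductive sphere matches the analytic inclusion law", {
  # sphere (sigma_in) in uniform field E0: E_in = 3 s_out/(2 s_out + s_in) E0
  sc <- plate_scene(n_gap = 38, spacing = 1, ny = 40, nz = 40)
  sc <- rasterize_ellipsoid(sc, c(20, 20, 20), c(5, 5, 5), "tumor")
  m <- default_material_table()
  m$tissues$liver$sigma_f <- m$tissues$liver$sigma0
  m$tissues$tumor$sigma_f <- m$tissues$tumor$sigma0
  sol <- solve_pair(sc, m, boundary_assignment(c(1, 2), 100),
                    sigma_e = FALSE, n_iter = 1)
  E0 <- 100 / 3.8  # V/cm across the 38 mm tissue gap
  co <- ireplan:::coordinate_arrays(sc$grid)
  core <- sc$labels == 2L &
    (co$x - 20)^2 + (co$y - 20)^2 + (co$z - 20)^2 <= 9  # away from poles
  pred <- 3 * 0.091 / (2 * 0.091 + 0.4) * E0
  expect_lt(abs(mean(sol$E_mag[core]) - pred) / pred, 0.08)
})

test_that("a conductive vessel shields its lumen and raises the current", {
  sc0 <- two_needle_scene(spacing = 2)
  # vessel column midway between the needles, parallel to them
  sc1 <- rasterize_capsule(sc0, c(30, 30, 0), c(30, 30, 20), 4)
  sc1$electrodes <- sc0$electrodes
  m <- default_material_table()
  m$tissues$liver$sigma_f <- m$tissues$liver$sigma0
  m$tissues$vessel$sigma_f <- m$tissues$vessel$sigma0
  ba <- boundary_assignment(c(1, 2), 1000)
  s0 <- solve_pair(sc0, m, ba, sigma_e = FALSE, n_iter = 1)
  s1 <- solve_pair(sc1, m, ba, sigma_e = FALSE, n_iter = 1)
  lumen <- sc1$labels == 3L
  expect_lt(mean(s1$E_mag[lumen]), mean(s0$E_mag[lumen]))
  expect_gt(s1$current, s0$current)
})

test_that("current is consistent under grid refinement for resolved needles", {
  m <- frozen_materials(0.2)
  Is <- vapply(c(1, 0.5), function(sp)
    solve_pair(two_needle_scene(sp, radius = 2), m,
               boundary_assignment(c(1, 2), 1000),
               sigma_e = FALSE, n_iter = 1)$current, 1.0)
  expect_lt(abs(Is[1] - Is[2]) / Is[2], 0.05)
})

test_that("degenerate assignments are rejected", {
  expect_error(boundary_assignment(c(1, 1), 100), "distinct")
  expect_error(boundary_assignment(c(1, 2), -5), ">= 0")
  sc <- two_needle_scene(spacing = 2)
  expect_error(solve_pair(sc, frozen_materials(),
                          boundary_assignment(c(1, 3), 100)), "active voxels")
})
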