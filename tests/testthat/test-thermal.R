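test_that("equilibrium is preserved without sources", {
  g <- build_grid(c(20, 20, 20), 2)
  sc <- new_scene(g, fill = "liver")
  m <- default_material_table()
  m$tissues$liver$metabolic_q <- 0
  sys <- pennes_system(sc, m)
  st <- new_thermal_state(sc)
  st2 <- step_pennes(st, 0, sys)
  expect_lt(max(abs(st2$T - 310)), 1e-9)
  expect_equal(st2$t, 1)
})

test_that("perfusion balances a uniform source at the closed-form offset", {
  # conduction suppressed, adiabatic: steady dT = Q / (w_b rho_b c_b)
  g <- build_grid(c(10, 10, 10), 2)
  sc <- new_scene(g, fill = "liver")
  m <- default_material_table()
  m$tissues$liver$metabolic_q <- 0
  m$tissues$liver$k <- 1e-12
  params <- thermal_params(dt = 50, boundary = "adiabatic")
  sys <- pennes_system(sc, m, params)
  st <- new_thermal_state(sc, params)
  Q <- 10740
  for (i in 1:40) st <- step_pennes(st, Q, sys)
  dT_ref <- Q / (0.018 * 1060 * 3840)  # 0.1466 K
  expect_equal(max(st$T) - 310, dT_ref, tolerance = 0.01)
  expect_equal(min(st$T) - 310, dT_ref, tolerance = 0.01)
})

test_that("point source matches the perfused Green's function", {
  # steady state of conduction + perfusion sink around a point source:
  # dT(r) = P exp(-r/lambda) / (4 pi k r), lambda = sqrt(k/(w rho_b c_b))
  g <- build_grid(c(30, 30, 30), 0.5)
  sc <- new_scene(g, fill = "liver")
  m <- default_material_table()
  m$tissues$liver$metabolic_q <- 0
  sys <- pennes_system(sc, m)
  st <- new_thermal_state(sc)
  P <- 0.2  # W
  src <- array(0, dim = g$shape)
  src[30, 30, 30] <- P / (voxel_volume(g) * 1e-9)
  # one huge implicit step lands on the steady state directly
  st <- step_pennes(st, src, sys, dt = 1e9, maxit = 5000)
  k <- 0.52
  lambda <- sqrt(k / (0.018 * 1060 * 3840)) * 1000  # mm
  co <- ireplan:::coordinate_arrays(g)
  ctr <- 29.5 * 0.5
  r <- sqrt((co$x - ctr)^2 + (co$y - ctr)^2 + (co$z - ctr)^2)
  sel <- r >= 3 & r <= 8
  pred <- P * exp(-r[sel] / lambda) / (4 * pi * k * (r[sel] / 1000))
  obs <- st$T[sel] - 310
  expect_lt(max(abs(obs - pred) / pred), 0.05)
})

test_that("Arrhenius accumulation matches closed form and quadrature", {
  ap <- default_material_table()$arrhenius
  # constant temperature: time to omega = 1 is exp(Ea/(R T)) / zeta
  T0 <- 316.15
  t_star <- exp(ap$Ea / (ap$R * T0)) / ap$zeta
  expect_gt(t_star, 1e3); expect_lt(t_star, 2e3)   # ~1.3e3 s at 43 C
  omega <- 0
  n <- 1000
  for (i in seq_len(n)) omega <- arrhenius_update(omega, T0, t_star / n, ap)
  expect_equal(omega, 1, tolerance = 1e-3)

  # time-varying profile: independent oracle = adaptive quadrature
  Tfun <- function(t) 310 + 45 * exp(-t / 120)  # cooling from 82 C
  oracle <- stats::integrate(function(t) ap$zeta * exp(-ap$Ea / (ap$R * Tfun(t))),
                             0, 300, rel.tol = 1e-10)$value
  dt <- 0.05
  ts <- seq(dt / 2, 300 - dt / 2, by = dt)  # midpoint rule
  omega2 <- 0
  for (t in ts) omega2 <- arrhenius_update(omega2, Tfun(t), dt, ap)
  expect_equal(omega2, oracle, tolerance = 1e-3)

  # linearity in dt and the cold limit
  expect_equal(arrhenius_update(0, 350, 2, ap),
               2 * arrhenius_update(0, 350, 1, ap))
  expect_equal(arrhenius_update(0, 1e-3, 1, ap), 0)
  expect_error(arrhenius_update(0, 310, -1, ap), "positive")
})

test_that("damage probability follows first-order kinetics", {
  expect_equal(damage_probability(1), 1 - exp(-1))
  expect_equal(round(damage_probability(1), 2), 0.63)
  expect_equal(damage_probability(0), 0)
  expect_equal(damage_probability(1e9), 1)
  expect_error(damage_probability(-1), ">= 0")
})

test_that("exceedance volumes count mask voxels above the level", {
  sc <- synthetic_case(spacing = 2)
  Tarr <- array(310, dim = sc$grid$shape)
  expect_equal(exceedance_volume(Tarr, 323.15, sc), 0)
  expect_equal(exceedance_volume(Tarr, 300, sc),
               label_volume(sc, "liver") + label_volume(sc, "tumor") +
                 label_volume(sc, "vessel"))
  expect_equal(exceedance_volume(Tarr, 300, sc, mask = "tumor"),
               label_volume(sc, "tumor"))
})

test_that("enthalpy bookkeeping closes without perfusion and boundary losses", {
  g <- build_grid(c(20, 20, 20), 2)
  sc <- new_scene(g, fill = "liver")
  m <- default_material_table()
  m$tissues$liver$metabolic_q <- 0
  m$tissues$liver$perfusion <- 0
  params <- thermal_params(dt = 1, boundary = "adiabatic")
  sys <- pennes_system(sc, m, params)
  st <- new_thermal_state(sc, params)
  src <- array(0, dim = g$shape)
  src[4:6, 4:6, 4:6] <- 5e5
  Vm3 <- voxel_volume(g) * 1e-9
  rhoc <- 1079 * 3540
  for (i in 1:10) {
    T_old <- st$T
    st <- step_pennes(st, src, sys)
    gain <- sum((st$T - T_old) * rhoc * Vm3)
    expect_equal(gain, sum(src) * Vm3 * 1, tolerance = 0.005)
  }
  # temperature bounded below by the initial/boundary temperature
  expect_gte(min(st$T), 310 - 1e-9)
})

test_that("a full coarse protocol run heats electrodes most and damages monotonically", {
  run <- coarse_run()
  sc <- run$scene
  m <- default_material_table()
  th <- suppressWarnings(run_thermal(sc, m, run))
  s <- th$series
  expect_equal(nrow(s), 661)
  expect_true(all(diff(s$vol_omega_ge_1_cm3) >= -1e-12))
  expect_true(all(diff(s$max_T_K)[1:20] > 0))
  # hottest tissue voxel adjoins an electrode active segment
  Tt <- th$state$T
  Tt[!ireplan:::is_tissue_code(sc$labels)] <- 0
  am <- which(Tt == max(Tt), arr.ind = TRUE)[1, ]
  act <- which(ireplan:::is_active_code(sc$labels), arr.ind = TRUE)
  dmin <- sqrt(min(colSums((t(act) - as.numeric(am))^2))) *
    sc$grid$spacing[1]
  expect_lte(dmin, 2 * sc$grid$spacing[1])
  # omega >= 1 implies high damage probability
  expect_true(all(damage_probability(th$state$omega[th$state$omega >= 1]) >=
                    0.63))
})

test_that("halving the time step barely changes the damage volume", {
  run <- coarse_run()
  m <- default_material_table()
  p8 <- run$protocol[1:8, ]
  th1 <- suppressWarnings(run_thermal(run$scene, m, run$solutions[1:8], p8,
                                      thermal_params(dt = 1)))
  th2 <- suppressWarnings(run_thermal(run$scene, m, run$solutions[1:8], p8,
                                      thermal_params(dt = 0.5)))
  v1 <- utils::tail(th1$series$vol_omega_ge_1_cm3, 1)
  v2 <- utils::tail(th2$series$vol_omega_ge_1_cm3, 1)
  expect_gt(v1, 0)
  expect_lt(abs(v1 - v2) / v2, 0.03)
})
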