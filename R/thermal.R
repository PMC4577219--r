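# Transient Pennes bioheat model with duty-cycle Joule heating and
# Arrhenius thermal-damage accumulation.
#
#   rho c dT/dt = div(k grad T) - w_b rho_b c_b (T - T_b) + q''' + Q
#
# with Q = duty * sigma |E|^2 from the electric solve. The very fast
# in-pulse transient (90 us on, ~1 s off) is not resolved: the
# time-averaged (duty-scaled) source gives the same bulk heating and is
# unconditionally stable with implicit (backward-Euler) stepping on the
# same 7-point conduction stencil. Temperatures above 100 C are reported
# with a warning rather than capped: the model deliberately contains no
# boiling/electrolysis term.

#' Thermal solver parameters
#'
#' @param dt time step, s (default 1 s, one pulse period at 1 Hz).
#' @param T_init initial tissue temperature, K.
#' @param boundary_T fixed temperature on the outer domain faces, K
#'   (far-field body temperature; keep the domain at least 2 cm larger
#'   than the electrode array so the choice is immaterial).
#' @param boundary `"dirichlet"` (fixed outer faces) or `"adiabatic"`
#'   (no heat flux; used for energy-conservation checks).
#' @param couple_sigma_T rescale the Joule source by the conductivity
#'   thermal coefficient `(1 + alpha_T (T - T_init))` while stepping.
#' @param gap_s source-off gap between pulse trains, s (default 0:
#'   trains are contiguous at the pulse rate).
#' @export
thermal_params <- function(dt = 1, T_init = 310, boundary_T = 310,
                           boundary = c("dirichlet", "adiabatic"),
                           couple_sigma_T = FALSE, gap_s = 0) {
  if (dt <= 0) stop("dt must be positive")
  structure(list(dt = dt, T_init = T_init, boundary_T = boundary_T,
                 boundary = match.arg(boundary),
                 couple_sigma_T = couple_sigma_T, gap_s = gap_s),
            class = "thermal_params")
}

#' Precompute the discrete Pennes system for a scene
#'
#' Face conductances from the per-tissue thermal conductivity, volumetric
#' heat capacity, perfusion sink and metabolic source arrays, and the
#' fixed-boundary mask. Build once, reuse for every step.
#'
#' @param scene an `ire_scene`.
#' @param materials an `ire_materials` table.
#' @param params a [thermal_params()].
#' @export
pennes_system <- function(scene, materials, params = thermal_params()) {
  grid <- scene$grid
  sh <- grid$shape
  Vm3 <- voxel_volume(grid) * 1e-9
  k_map <- material_array(scene, materials, "k")
  rhoc <- material_array(scene, materials, "rho") *
    material_array(scene, materials, "c")
  perf <- material_array(scene, materials, "perfusion") *
    materials$blood$rho_b * materials$blood$c_b
  qmet <- material_array(scene, materials, "metabolic_q")
  alphaT <- material_array(scene, materials, "alphaT")

  fixed <- array(0L, dim = sh)
  if (params$boundary == "dirichlet") {
    fixed[c(1, sh[1]), , ] <- 1L
    fixed[, c(1, sh[2]), ] <- 1L
    fixed[, , c(1, sh[3])] <- 1L
  }
  gvals <- array(params$boundary_T, dim = sh)

  structure(list(grid = grid, w = face_weights(k_map, grid), Vm3 = Vm3,
                 rhoc = rhoc, perf = perf, qmet = qmet, alphaT = alphaT,
                 fixed = fixed, gvals = gvals,
                 T_b = materials$blood$T_b, params = params,
                 tissue = is_tissue_code(scene$labels)),
            class = "pennes_system")
}

#' Initial thermal state
#' @param scene an `ire_scene`.
#' @param params a [thermal_params()].
#' @return A `thermal_state` with uniform `T` (K), zero Arrhenius
#'   integral `omega`, and elapsed time `t = 0`.
#' @export
new_thermal_state <- function(scene, params = thermal_params()) {
  structure(list(T = array(params$T_init, dim = scene$grid$shape),
                 omega = array(0, dim = scene$grid$shape), t = 0),
            class = "thermal_state")
}

#' Duty-cycle-scaled volumetric heat source
#'
#' @param sol a `field_solution`.
#' @param duty duty cycle (pulse width x rate).
#' @param system optional [pennes_system()]; required with coupling.
#' @param state optional `thermal_state`; when given and the system's
#'   parameters request `couple_sigma_T`, the source is rescaled by
#'   `(1 + alpha_T (T - T_init))`.
#' @return per-voxel source, W/m^3.
#' @export
heat_source <- function(sol, duty, system = NULL, state = NULL) {
  if (duty < 0 || duty >= 1) stop("duty must be in [0, 1)")
  Q <- duty * sol$joule
  if (!is.null(system) && !is.null(state) && system$params$couple_sigma_T)
    Q <- Q * pmax(1 + system$alphaT * (state$T - system$params$T_init), 0)
  Q
}

#' Advance the bioheat equation by one implicit step
#'
#' Backward-Euler step of the Pennes equation; unconditionally stable.
#' Errors on non-finite temperatures.
#'
#' @param state a `thermal_state`.
#' @param source per-voxel source, W/m^3 (scalar 0 allowed).
#' @param system a [pennes_system()].
#' @param dt step length, s (default: the system's `dt`).
#' @param tol,maxit conjugate-gradient controls.
#' @return the advanced `thermal_state` (Arrhenius integral untouched;
#'   see [arrhenius_update()]).
#' @export
step_pennes <- function(state, source, system, dt = system$params$dt,
                        tol = 1e-9, maxit = 2000) {
  sh <- system$grid$shape
  dex <- system$Vm3 * (system$rhoc / dt + system$perf)
  rhs <- system$Vm3 * (system$rhoc / dt * state$T + system$perf * system$T_b +
                         system$qmet + source)
  sol <- .cg_stencil_solve(sh, system$w$wx, system$w$wy, system$w$wz,
                           dex, system$fixed, system$gvals, rhs, state$T,
                           tol, maxit)
  if (!sol$converged)
    stop("thermal CG did not converge; residual ",
         utils::tail(sol$residuals, 1))
  Tn <- array(sol$x, dim = sh)
  if (any(!is.finite(Tn))) stop("non-finite temperatures in thermal step")
  state$T <- Tn
  state$t <- state$t + dt
  state
}

#' Arrhenius damage-integral update
#'
#' First-order thermal damage kinetics: `omega` grows at the rate
#' `zeta * exp(-Ea / (R T))`, so `d omega = rate * dt` per voxel.
#'
#' @param omega current damage integral (array or scalar).
#' @param T_K temperature, K.
#' @param dt step length, s (> 0).
#' @param ap Arrhenius parameters (`Ea`, `zeta`, `R`), e.g.
#'   `default_material_table()$arrhenius`.
#' @export
arrhenius_update <- function(omega, T_K, dt, ap) {
  if (dt <= 0) stop("dt must be positive")
  omega + dt * ap$zeta * exp(-ap$Ea / (ap$R * T_K))
}

#' Thermal damage probability
#'
#' First-order kinetics map the damage integral to a probability
#' `1 - exp(-omega)`; `omega = 1` corresponds to 63% damage probability.
#'
#' @param omega Arrhenius damage integral (>= 0).
#' @export
damage_probability <- function(omega) {
  if (any(omega < 0)) stop("omega must be >= 0")
  1 - exp(-omega)
}

#' Volume above a level within a mask
#'
#' @param x per-voxel field (temperature, damage integral, ...).
#' @param level threshold; voxels strictly above it are counted.
#' @param scene the `ire_scene` providing grid and labels.
#' @param mask `"tissue"` (liver + tumor + vessel), a tissue name, or a
#'   logical array.
#' @return volume in cm^3.
#' @export
exceedance_volume <- function(x, level, scene, mask = "tissue") {
  m <- if (is.array(mask)) mask
       else if (identical(mask, "tissue")) is_tissue_code(scene$labels)
       else scene$labels == label_code(mask)
  sum(x[m] > level) * voxel_volume(scene$grid) / 1000
}

#' Run the thermal model over a full protocol
#'
#' Trains are simulated in protocol order; during train `i` the source is
#' the duty-scaled Joule map of that train's field solution for
#' `n_pulses / rate` seconds (plus an optional source-off gap between
#' trains). The Arrhenius integral is updated every step and the time
#' series of maximum tissue temperature and exceedance volumes recorded.
#'
#' @param scene an `ire_scene`.
#' @param materials an `ire_materials` table.
#' @param run a `protocol_run` (or a list of one `field_solution` per
#'   train).
#' @param p the protocol (default: taken from `run`).
#' @param params a [thermal_params()].
#' @param progress print one line per train.
#' @return A `thermal_run`: final `state` (`T`, `omega`, `t`), per-step
#'   `series` (time, max tissue temperature, volumes above 50/70/100 C
#'   and with omega >= 1), and per-train `snapshots` of the same summary.
#' @export
run_thermal <- function(scene, materials, run, p = NULL,
                        params = thermal_params(), progress = FALSE) {
  if (inherits(run, "protocol_run")) {
    if (is.null(p)) p <- run$protocol
    solutions <- run$solutions
  } else solutions <- run
  if (is.null(p)) stop("no protocol given")
  if (length(solutions) != nrow(p))
    stop("need one field solution per protocol train")

  sys <- pennes_system(scene, materials, params)
  state <- new_thermal_state(scene, params)
  ap <- materials$arrhenius
  tissue <- sys$tissue
  voxvol <- voxel_volume(scene$grid) / 1000
  series <- list()
  snapshots <- list()

  record <- function(state) {
    Tt <- state$T[tissue]
    data.frame(t_s = state$t, max_T_K = max(Tt),
               vol_gt_50C_cm3 = sum(Tt > 323.15) * voxvol,
               vol_gt_70C_cm3 = sum(Tt > 343.15) * voxvol,
               vol_gt_100C_cm3 = sum(Tt > 373.15) * voxvol,
               vol_omega_ge_1_cm3 = sum(state$omega[tissue] >= 1) * voxvol)
  }
  series[[1]] <- record(state)

  advance <- function(state, source, duration) {
    remaining <- duration
    while (remaining > 1e-12) {
      dt <- min(params$dt, remaining)
      src <- if (params$couple_sigma_T && is.array(source))
        source * pmax(1 + sys$alphaT * (state$T - params$T_init), 0)
      else source
      state <- step_pennes(state, src, sys, dt = dt)
      state$omega <- arrhenius_update(state$omega, state$T, dt, ap)
      series[[length(series) + 1L]] <<- record(state)
      remaining <- remaining - dt
    }
    state
  }

  for (i in seq_len(nrow(p))) {
    duty <- duty_cycle(p$width_us[i] * 1e-6, p$rate_Hz[i])
    source <- duty * solutions[[i]]$joule
    state <- advance(state, source, p$n_pulses[i] / p$rate_Hz[i])
    snapshots[[i]] <- cbind(train = p$train[i], record(state))
    if (params$gap_s > 0 && i < nrow(p))
      state <- advance(state, 0, params$gap_s)
    if (progress) {
      s <- snapshots[[i]]
      cat(sprintf("train %2d done at t=%5.0f s: max T %.1f C, V(>50C) %.2f cm^3, V(omega>=1) %.2f cm^3\n",
                  p$train[i], s$t_s, s$max_T_K - 273.15,
                  s$vol_gt_50C_cm3, s$vol_omega_ge_1_cm3))
    }
  }

  if (max(state$T) > 373.15)
    warning(sprintf(
      "maximum temperature %.1f C exceeds 100 C; the model has no boiling term",
      max(state$T) - 273.15))

  structure(list(state = state, series = do.call(rbind, series),
                 snapshots = do.call(rbind, snapshots),
                 params = params, scene = scene),
            class = "thermal_run")
}

#' @export
print.thermal_run <- function(x, ...) {
  s <- x$series[nrow(x$series), ]
  cat(sprintf(
    "<thermal_run> t = %.0f s: max T %.1f C, V(>50C) %.2f cm^3, V(omega>=1) %.2f cm^3\n",
    s$t_s, s$max_T_K - 273.15, s$vol_gt_50C_cm3, s$vol_omega_ge_1_cm3))
  invisible(x)
}
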