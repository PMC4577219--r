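# Stationary electric solve for one energized electrode pair.
#
# The potential solves div(sigma grad phi) = 0 with Dirichlet values on
# the active electrode voxels (U on the anode, 0 on the cathode), zero
# normal current on the outer domain boundary, floating (unconstrained,
# highly conductive) metal for inactive electrodes, and perfectly
# insulating shaft voxels (excluded from the system). Discretization is
# cell-centered finite volumes with harmonic face averaging of sigma and a
# 7-point stencil; the linear systems are solved with Jacobi-preconditioned
# conjugate gradients. Field-dependent conductivity is handled by the
# standard sequential scheme: a fixed number of stationary solves
# (default 6) with a monotone conductivity update
# sigma <- max(sigma, sigma(|E|)) between solves, which guarantees a
# non-decreasing current trace.

#' Boundary assignment for one energized pair
#'
#' @param pair integer pair `(anode, cathode)`: the anode is held at
#'   `voltage`, the cathode at 0. Fields and currents are
#'   polarity-symmetric, so the order is cosmetic.
#' @param voltage applied potential difference, V (> 0 unless both
#'   electrodes are grounded for a null test).
#' @export
boundary_assignment <- function(pair, voltage) {
  pair <- as.integer(pair)
  if (length(pair) != 2 || pair[1] == pair[2])
    stop("pair must be two distinct electrode indices")
  if (voltage < 0) stop("voltage must be >= 0")
  structure(list(pair = pair, voltage = as.numeric(voltage)),
            class = "boundary_assignment")
}

# Face conductance arrays (S) from a per-voxel sigma array (S/m) on a grid
# with mm spacing. Harmonic averaging handles discontinuous coefficients;
# a zero sigma on either side disconnects the face.
face_weights <- function(sigma, grid) {
  sp <- grid$spacing * 1e-3  # m
  harm <- function(a, b) {
    s <- a + b
    w <- 2 * a * b
    w[s > 0] <- w[s > 0] / s[s > 0]
    w[s <= 0] <- 0
    w
  }
  sh <- grid$shape
  list(
    wx = harm(sigma[-sh[1], , , drop = FALSE], sigma[-1, , , drop = FALSE]) *
      (sp[2] * sp[3] / sp[1]),
    wy = harm(sigma[, -sh[2], , drop = FALSE], sigma[, -1, , drop = FALSE]) *
      (sp[1] * sp[3] / sp[2]),
    wz = harm(sigma[, , -sh[3], drop = FALSE], sigma[, , -1, drop = FALSE]) *
      (sp[1] * sp[2] / sp[3]))
}

# |grad phi| in V/cm by central differences at voxel centers, one-sided
# at the domain boundary and next to excluded (`!valid`) voxels such as
# insulated shafts, whose stored potential is meaningless. phi in V,
# spacing in mm: 1 V/mm = 10 V/cm.
gradient_magnitude <- function(phi, grid, valid = NULL) {
  sh <- grid$shape
  if (is.null(valid)) valid <- array(TRUE, dim = sh)
  g2 <- array(0, dim = sh)
  shift <- function(x, axis, by, fill) {
    # x shifted so that out[i] = x[i + by] along `axis`
    n <- sh[axis]
    src <- if (by > 0) (1 + by):n else 1:(n + by)
    dst <- if (by > 0) 1:(n - by) else (1 - by):n
    out <- array(fill, dim = sh)
    if (axis == 1) out[dst, , ] <- x[src, , ]
    else if (axis == 2) out[, dst, ] <- x[, src, ]
    else out[, , dst] <- x[, , src]
    out
  }
  for (axis in 1:3) {
    h <- grid$spacing[axis]
    phi_f <- shift(phi, axis, 1L, 0)
    phi_b <- shift(phi, axis, -1L, 0)
    okf <- valid & shift(valid, axis, 1L, FALSE)
    okb <- valid & shift(valid, axis, -1L, FALSE)
    df <- (phi_f - phi) / h
    db <- (phi - phi_b) / h
    d <- array(0, dim = sh)
    both <- okf & okb
    d[both] <- (df[both] + db[both]) / 2
    fo <- okf & !okb
    d[fo] <- df[fo]
    bo <- okb & !okf
    d[bo] <- db[bo]
    g2 <- g2 + d^2
  }
  sqrt(g2) * 10
}

# Dissipated power (W) from the discrete face energy sum w * dphi^2.
face_energy <- function(phi, w, sh) {
  sum(w$wx * (phi[-1, , ] - phi[-sh[1], , ])^2) +
    sum(w$wy * (phi[, -1, ] - phi[, -sh[2], ])^2) +
    sum(w$wz * (phi[, , -1] - phi[, , -sh[3]])^2)
}

# Energy-consistent Joule density (W/m^3): each face's dissipated power
# w (dphi)^2 is split evenly between its two cells, except that faces
# touching metal give their whole power to the tissue side (the interior
# of a conductor is field-free, and the half-link resistance sits in the
# tissue). Discretely exact: sum(joule * voxel volume) = U * I. This
# matters most in the first tissue shell around a needle, where a
# center-point sigma |E|^2 badly underestimates the logarithmically
# concentrated dissipation at practical voxel sizes.
joule_density <- function(phi, w, grid, metal) {
  sh <- grid$shape
  J <- array(0, dim = sh)
  scatter <- function(J, p, mlo, mhi, axis) {
    # p: per-face power; mlo/mhi: metal flags of the lower/upper cell
    f_lo <- ifelse(mlo & !mhi, 0, ifelse(!mlo & mhi, 1, 0.5))
    n <- sh[axis]
    if (axis == 1) {
      J[-n, , ] <- J[-n, , ] + p * f_lo
      J[-1, , ] <- J[-1, , ] + p * (1 - f_lo)
    } else if (axis == 2) {
      J[, -n, ] <- J[, -n, ] + p * f_lo
      J[, -1, ] <- J[, -1, ] + p * (1 - f_lo)
    } else {
      J[, , -n] <- J[, , -n] + p * f_lo
      J[, , -1] <- J[, , -1] + p * (1 - f_lo)
    }
    J
  }
  J <- scatter(J, w$wx * (phi[-1, , ] - phi[-sh[1], , ])^2,
               metal[-sh[1], , ], metal[-1, , ], 1)
  J <- scatter(J, w$wy * (phi[, -1, ] - phi[, -sh[2], ])^2,
               metal[, -sh[2], ], metal[, -1, ], 2)
  J <- scatter(J, w$wz * (phi[, , -1] - phi[, , -sh[3]])^2,
               metal[, , -sh[3]], metal[, , -1], 3)
  J / (voxel_volume(grid) * 1e-9)
}

# Net current (A) through the grid face layer between the two electrodes:
# the mid-plane is taken perpendicular to the axis with the largest
# separation of the active-voxel centroids.
midplane_current <- function(phi, w, grid, labels, pair) {
  cen <- lapply(pair, function(k) {
    m <- which(labels == label_code("electrode_active", k), arr.ind = TRUE)
    if (nrow(m) == 0) stop("electrode ", k, " has no active voxels")
    grid$origin + (colMeans(m) - 0.5) * grid$spacing
  })
  d <- cen[[2]] - cen[[1]]
  axis <- which.max(abs(d))
  mid <- (cen[[1]][axis] + cen[[2]][axis]) / 2
  # face layer l sits between voxel layers l and l+1
  l <- round((mid - grid$origin[axis]) / grid$spacing[axis])
  l <- min(max(l, 1L), grid$shape[axis] - 1L)
  flux <- switch(axis,
                 sum(w$wx[l, , ] * (phi[l, , ] - phi[l + 1, , ])),
                 sum(w$wy[, l, ] * (phi[, l, ] - phi[, l + 1, ])),
                 sum(w$wz[, , l] * (phi[, , l] - phi[, , l + 1])))
  abs(flux)
}

#' Solve the stationary electric problem for one electrode pair
#'
#' @param scene an `ire_scene` containing the pair's electrodes.
#' @param materials an `ire_materials` table.
#' @param assignment a [boundary_assignment()].
#' @param n_iter number of stationary solves with conductivity updates in
#'   between (default 6).
#' @param sigma_e apply the field-dependent conductivity rise
#'   (`FALSE` solves the linear problem once per iteration with no update).
#' @param tol relative residual tolerance of the conjugate-gradient solver.
#' @param maxit maximum CG iterations per solve.
#' @param keep_potential retain the potential array in the result.
#' @return A `field_solution`: `E_mag` (V/cm, field of the final
#'   stationary solve), `E_peak` (V/cm, voxelwise maximum over the
#'   conductivity iterations — the highest field a location experiences
#'   while the tissue conductivity evolves during the pulse, which is the
#'   relevant magnitude for electroporation coverage since poration is
#'   effectively instantaneous and irreversible), `sigma_map` (S/m),
#'   `joule` (W/m^3, instantaneous during the pulse; energy-consistent
#'   face-based density whose volume integral equals U x I exactly),
#'   `current` (A,
#'   dissipated power / U), `current_flux` (A, mid-plane estimator),
#'   `iterations`, `residuals`, and the per-iteration `trace`.
#' @export
solve_pair <- function(scene, materials, assignment, n_iter = 6,
                       sigma_e = TRUE, tol = 1e-8, maxit = 10000,
                       keep_potential = FALSE) {
  stopifnot(inherits(scene, "ire_scene"),
            inherits(assignment, "boundary_assignment"))
  grid <- scene$grid
  labels <- scene$labels
  sh <- grid$shape
  U <- assignment$voltage

  code_a <- label_code("electrode_active", assignment$pair[1])
  code_c <- label_code("electrode_active", assignment$pair[2])
  if (!any(labels == code_a) || !any(labels == code_c))
    stop("both pair electrodes must have active voxels in the scene")

  sigma <- material_array(scene, materials, "sigma0")
  insul <- is_insulated_code(labels)
  sigma[insul] <- 0  # perfect insulator: shaft voxels leave the system

  fixed <- array(0L, dim = sh)
  gvals <- array(0, dim = sh)
  fixed[labels == code_a | labels == code_c] <- 1L
  fixed[insul] <- 1L
  gvals[labels == code_a] <- U

  tissue <- is_tissue_code(labels)
  metal <- is_electrode_voxel(labels)
  valid <- !insul
  sigma0_map <- sigma
  phi <- array(0, dim = sh)
  E_peak <- array(0, dim = sh)
  zero <- array(0, dim = sh)
  voxvol_cm3 <- voxel_volume(grid) / 1000
  trace <- data.frame(iteration = integer(), current_A = numeric(),
                      electroporated_cm3 = numeric(),
                      cg_iterations = integer())
  residuals <- numeric()
  w <- NULL

  for (it in seq_len(n_iter)) {
    w <- face_weights(sigma, grid)
    sol <- .cg_stencil_solve(sh, w$wx, w$wy, w$wz, zero,
                             fixed, gvals, zero, phi, tol, maxit)
    if (!sol$converged)
      stop(sprintf(
        "CG did not converge (iteration %d, %d iterations, residual %.3e)",
        it, sol$iterations, utils::tail(sol$residuals, 1)))
    phi <- array(sol$x, dim = sh)
    residuals <- c(residuals, utils::tail(sol$residuals, 1))
    E <- gradient_magnitude(phi, grid, valid)
    E[metal] <- 0  # the interior of a conductor is field-free
    E_peak <- pmax(E_peak, E)
    cur <- if (U > 0) face_energy(phi, w, sh) / U else 0
    ep_vol <- sum(tissue & sigma > sigma0_map * (1 + 1e-12)) * voxvol_cm3
    trace[it, ] <- list(it, cur, ep_vol, sol$iterations)
    if (sigma_e && it < n_iter) {
      s_new <- sigma
      for (nm in c("liver", "tumor", "vessel")) {
        sel <- labels == .LBL[[nm]]
        if (any(sel))
          s_new[sel] <- sigma_of_field(E[sel], materials$tissues[[nm]],
                                       shape = materials$sigma_shape)
      }
      sigma <- pmax(sigma, s_new)
    }
  }

  E <- gradient_magnitude(phi, grid, valid)
  E[metal] <- 0
  joule <- joule_density(phi, w, grid, metal)
  current <- trace$current_A[n_iter]
  current_flux <- midplane_current(phi, w, grid, labels, assignment$pair)
  ref <- max(current, current_flux)
  if (ref > 0 && abs(current - current_flux) / ref > 0.10)
    stop(sprintf(
      "current estimators disagree by %.1f%% (energy %.3f A, mid-plane %.3f A): refine the grid",
      100 * abs(current - current_flux) / ref, current, current_flux))

  structure(list(potential = if (keep_potential) phi else NULL,
                 E_mag = E, E_peak = E_peak, sigma_map = sigma,
                 joule = joule,
                 current = current, current_flux = current_flux,
                 iterations = n_iter, residuals = residuals,
                 trace = trace, assignment = assignment,
                 grid = grid),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf(
    "<field_solution> pair %d-%d at %.0f V: current %.2f A (mid-plane %.2f A), max |E| %.0f V/cm\n",
    x$assignment$pair[1], x$assignment$pair[2], x$assignment$voltage,
    x$current, x$current_flux, max(x$E_mag)))
  invisible(x)
}

#' Predicted current of a solved pair
#'
#' Two independent discrete estimators: the primary one divides the total
#' dissipated power by the applied voltage; the secondary one sums the
#' current flux through a mid-plane between the electrodes. In an exactly
#' solved discrete system the two agree by charge conservation; their
#' difference measures the residual discretization/solver error.
#'
#' @param sol a `field_solution`.
#' @return list with `current_A` (primary), `current_flux_A` (secondary)
#'   and `relative_difference`.
#' @export
compute_current <- function(sol) {
  stopifnot(inherits(sol, "field_solution"))
  ref <- max(sol$current, sol$current_flux)
  list(current_A = sol$current, current_flux_A = sol$current_flux,
       relative_difference = if (ref > 0)
         abs(sol$current - sol$current_flux) / ref else 0)
}

#' Per-iteration current and electroporated volume
#'
#' The monotone conductivity update makes both sequences non-decreasing;
#' with the field-dependent rise disabled all iterations are identical.
#'
#' @param sol a `field_solution`.
#' @return data.frame with one row per stationary solve.
#' @export
field_iteration_trace <- function(sol) {
  stopifnot(inherits(sol, "field_solution"))
  sol$trace
}
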