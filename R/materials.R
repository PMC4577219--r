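# Electrical and thermal tissue parameters and the conductivity laws.
#
# All internal computation is SI (m, S/m, K, W). Electric-field thresholds
# are exposed in V/cm at the interfaces (1 V/cm = 100 V/m).

#' Construct a tissue material
#'
#' @param name tissue name.
#' @param sigma0 initial (pre-electroporation) conductivity, S/m.
#' @param sigma_f final (fully electroporated) conductivity, S/m.
#' @param E_rev field at which the conductivity rise begins, V/cm.
#' @param E_irr irreversible-electroporation threshold where the rise
#'   saturates, V/cm.
#' @param alphaT thermal coefficient of conductivity, fraction per K.
#' @param k thermal conductivity, W/(m K).
#' @param rho density, kg/m^3.
#' @param c heat capacity, J/(kg K).
#' @param perfusion blood perfusion as volumetric fraction per second, 1/s.
#' @param metabolic_q metabolic heat generation, W/m^3.
#' @export
tissue_material <- function(name, sigma0, sigma_f, E_rev, E_irr,
                            alphaT = 0, k, rho, c, perfusion = 0,
                            metabolic_q = 0) {
  if (!(sigma0 > 0) || sigma_f < sigma0)
    stop(name, ": need sigma_f >= sigma0 > 0")
  if (!(E_rev > 0) || E_irr < E_rev)
    stop(name, ": need 0 < E_rev <= E_irr")
  if (k <= 0 || rho <= 0 || c <= 0 || perfusion < 0)
    stop(name, ": thermal parameters must be positive, perfusion >= 0")
  structure(list(name = name, sigma0 = sigma0, sigma_f = sigma_f,
                 E_rev = E_rev, E_irr = E_irr, alphaT = alphaT,
                 k = k, rho = rho, c = c, perfusion = perfusion,
                 metabolic_q = metabolic_q),
            class = "tissue_material")
}

#' Default material table
#'
#' Literature defaults for the hepatic IRE model: initial/final
#' conductivities for liver (0.091 -> 0.45 S/m), tumor (0.4 -> 1.6 S/m)
#' and vessel (0.7 -> 1.05 S/m); IRE thresholds of 700 V/cm (liver,
#' vessel) and 800 V/cm (tumor); a thermal conductivity coefficient of
#' 1.5 %/K; tissue k = 0.52 W/(m K), rho = 1079 kg/m^3, c = 3540 J/(kg K);
#' perfusion 1.8 mL/s/100 mL = 0.018 1/s; metabolic heat 10740 W/m^3;
#' blood rho = 1060 kg/m^3, c = 3840 J/(kg K), arterial temperature 310 K;
#' Arrhenius activation energy 5.06e5 J/mol with frequency factor
#' 2.984e80 1/s; stainless-steel electrodes with sigma = 1e6 S/m, k = 15,
#' rho = 6000, c = 500.
#'
#' The onset field `E_rev` of the conductivity ramp is not tabulated in
#' the source literature consistently; the default is `E_irr / 2`
#' (liver/vessel 350, tumor 400 V/cm) and should be adjusted when better
#' tissue data are available. Tumor perfusion is set to half the liver
#' value (tumor perfusion is reported as lower but unquantified). The
#' vessel is one homogeneous tissue (wall + blood lumped) with liver-like
#' thermal properties; the `background` filler is a near-insulator used
#' only outside the body.
#'
#' @return An `ire_materials` object: `$tissues` (named list of
#'   [tissue_material()]), `$blood` (rho_b, c_b, T_b), `$arrhenius`
#'   (Ea, zeta, R), `$sigma_shape` (conductivity ramp shape).
#' @export
default_material_table <- function() {
  tissues <- list(
    liver = tissue_material("liver", sigma0 = 0.091, sigma_f = 0.45,
                            E_rev = 350, E_irr = 700, alphaT = 0.015,
                            k = 0.52, rho = 1079, c = 3540,
                            perfusion = 0.018, metabolic_q = 10740),
    tumor = tissue_material("tumor", sigma0 = 0.4, sigma_f = 1.6,
                            E_rev = 400, E_irr = 800, alphaT = 0.015,
                            k = 0.52, rho = 1079, c = 3540,
                            perfusion = 0.009, metabolic_q = 10740),
    vessel = tissue_material("vessel", sigma0 = 0.7, sigma_f = 1.05,
                             E_rev = 350, E_irr = 700, alphaT = 0.015,
                             k = 0.52, rho = 1079, c = 3540,
                             perfusion = 0.018, metabolic_q = 0),
    electrode = structure(list(name = "electrode", sigma0 = 1e6,
                               sigma_f = 1e6, E_rev = Inf, E_irr = Inf,
                               alphaT = 0, k = 15, rho = 6000, c = 500,
                               perfusion = 0, metabolic_q = 0),
                          class = "tissue_material"),
    background = structure(list(name = "background", sigma0 = 1e-5,
                                sigma_f = 1e-5, E_rev = Inf, E_irr = Inf,
                                alphaT = 0, k = 0.52, rho = 1079, c = 3540,
                                perfusion = 0, metabolic_q = 0),
                           class = "tissue_material"))
  structure(list(tissues = tissues,
                 blood = list(rho_b = 1060, c_b = 3840, T_b = 310),
                 arrhenius = list(Ea = 5.06e5, zeta = 2.984e80, R = 8.314),
                 sigma_shape = "linear"),
            class = "ire_materials")
}

#' Field-dependent conductivity
#'
#' Conductivity as a function of the local field magnitude: `sigma0` below
#' `E_rev`, `sigma_f` above `E_irr`, and a continuous monotone transition
#' in between. The default `"linear"` ramp interpolates linearly; the
#' `"sigmoid"` variant uses a smooth logistic transition centered between
#' the thresholds (both shapes are consistent with published
#' electroporation conductivity models, which differ among themselves).
#'
#' @param E field magnitude(s), V/cm (>= 0).
#' @param m a [tissue_material()].
#' @param shape `"linear"` or `"sigmoid"`.
#' @return conductivity, S/m (vectorized over `E`).
#' @export
sigma_of_field <- function(E, m, shape = c("linear", "sigmoid")) {
  shape <- match.arg(shape)
  if (any(E < 0)) stop("field magnitude must be >= 0")
  if (!is.finite(m$E_rev)) return(rep(m$sigma0, length(E)))
  if (shape == "linear") {
    f <- (E - m$E_rev) / max(m$E_irr - m$E_rev, .Machine$double.eps)
  } else {
    mid <- (m$E_rev + m$E_irr) / 2
    width <- max(m$E_irr - m$E_rev, .Machine$double.eps)
    f <- 1 / (1 + exp(-10 * (E - mid) / width))
  }
  f <- pmin(pmax(f, 0), 1)
  f[E <= m$E_rev] <- 0
  f[E >= m$E_irr] <- 1
  m$sigma0 + f * (m$sigma_f - m$sigma0)
}

#' Temperature-dependent conductivity rescaling
#'
#' @param sigma conductivity, S/m.
#' @param T_K temperature, K (> 0).
#' @param alphaT thermal coefficient, 1/K.
#' @param T_ref reference temperature, K.
#' @return `sigma * (1 + alphaT * (T_K - T_ref))`, clamped at 0.
#' @export
sigma_of_temperature <- function(sigma, T_K, alphaT, T_ref = 310) {
  if (any(T_K <= 0)) stop("temperature must be positive (kelvin)")
  pmax(sigma * (1 + alphaT * (T_K - T_ref)), 0)
}

#' Write a material table to JSON
#' @param materials an `ire_materials` object.
#' @param path output file.
#' @export
write_materials_json <- function(materials, path) {
  obj <- list(format = "ireplan-materials", version = 1L,
              sigma_shape = materials$sigma_shape,
              blood = materials$blood, arrhenius = materials$arrhenius,
              tissues = lapply(materials$tissues, unclass))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a material table from JSON
#' @param path file written by [write_materials_json()].
#' @export
read_materials_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ireplan-materials"))
    stop("not an ireplan materials file: ", path)
  tissues <- lapply(obj$tissues, function(t) {
    t <- as.list(t)
    t$E_rev <- as.numeric(t$E_rev); t$E_irr <- as.numeric(t$E_irr)
    structure(t, class = "tissue_material")
  })
  structure(list(tissues = tissues, blood = as.list(obj$blood),
                 arrhenius = as.list(obj$arrhenius),
                 sigma_shape = obj$sigma_shape),
            class = "ire_materials")
}

# Per-voxel parameter array from a label map. field: one of the
# tissue_material fields. Electrode voxels use the "electrode" material;
# insulated shafts get sigma 0 in the electric solve (handled in efield).
material_array <- function(scene, materials, field) {
  codes <- scene$labels
  out <- array(materials$tissues$background[[field]], dim = dim(codes))
  out[codes == 1L] <- materials$tissues$liver[[field]]
  out[codes == 2L] <- materials$tissues$tumor[[field]]
  out[codes == 3L] <- materials$tissues$vessel[[field]]
  el <- is_electrode_voxel(codes)
  out[el] <- materials$tissues$electrode[[field]]
  out
}
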