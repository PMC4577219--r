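# Pulse protocols: the delivery ledger (pair, voltage, pulse count, width,
# rate, optional measured current), per-pair field solves, combination of
# per-pair fields as voxelwise maxima, coverage curves, lesion volumes and
# the power/duty-cycle bookkeeping.

.protocol_cols <- c("train", "pair_a", "pair_b", "voltage_V", "n_pulses",
                    "width_us", "rate_Hz", "measured_current_A", "phase")

#' Load a pulse protocol from CSV
#'
#' Expected header:
#' `train,pair_a,pair_b,voltage_V,n_pulses,width_us,rate_Hz,measured_current_A,phase`.
#' `measured_current_A` may be empty; `phase` is one of
#' `test`/`treatment`/`additional`.
#'
#' @param file CSV path.
#' @return An `ire_protocol` data.frame.
#' @export
load_protocol <- function(file) {
  if (!file.exists(file)) stop("protocol file not found: ", file)
  df <- read.csv(file, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("protocol file is empty: ", file)
  missing <- setdiff(setdiff(.protocol_cols, "measured_current_A"), names(df))
  if (length(missing))
    stop("protocol file missing column(s): ", paste(missing, collapse = ", "))
  if (!"measured_current_A" %in% names(df)) df$measured_current_A <- NA_real_
  for (col in c("train", "pair_a", "pair_b", "voltage_V", "n_pulses",
                "width_us", "rate_Hz", "measured_current_A")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "" &
                   col != "measured_current_A")
    if (length(bad))
      stop("non-numeric value in column '", col, "' at row ", bad[1])
    df[[col]] <- v
  }
  as_protocol(df)
}

# Validate and class a protocol data.frame.
as_protocol <- function(df) {
  if (any(df$voltage_V <= 0)) stop("voltages must be positive")
  if (any(df$n_pulses <= 0)) stop("pulse counts must be positive")
  if (any(df$width_us * 1e-6 * df$rate_Hz >= 1))
    stop("pulse width x rate must be < 1 (duty cycle below unity)")
  if (any(diff(df$train) <= 0)) stop("train indices must be strictly increasing")
  if (any(df$pair_a == df$pair_b)) stop("pairs must name two distinct electrodes")
  class(df) <- c("ire_protocol", "data.frame")
  df
}

#' Reference clinical protocol (18 pulse trains)
#'
#' The delivery ledger of the reference hepatic case: 6 test trains of 20
#' pulses, 6 treatment trains of 70 pulses, 6 additional trains of 20
#' pulses (660 pulses in total), 90 us pulses at 1 Hz, voltages
#' 1540-3000 V across 6 electrode pairs, with the generator-measured
#' current per train.
#'
#' @return An `ire_protocol`.
#' @export
table3_protocol <- function() {
  load_protocol(system.file("extdata", "protocol_table3.csv",
                            package = "ireplan", mustWork = TRUE))
}

#' Total number of pulses in a protocol
#' @param p an `ire_protocol`.
#' @export
total_pulses <- function(p) sum(p$n_pulses)

#' Duty cycle of a pulse schedule
#' @param width pulse width, s.
#' @param rate repetition rate, Hz.
#' @return fraction of time the pulse is on (`width * rate`).
#' @examples
#' duty_cycle(90e-6, 1)          # 9e-05
#' duty_cycle(90e-6, 100 / 60)   # 1.5e-04 at 100 pulses/min
#' @export
duty_cycle <- function(width, rate) {
  if (width < 0 || rate < 0) stop("width and rate must be >= 0")
  if (width * rate >= 1) stop("width x rate must be < 1")
  width * rate
}

#' Peak electrical power during a pulse
#' @param voltage applied voltage, V.
#' @param current delivered current, A.
#' @export
peak_power <- function(voltage, current) {
  if (voltage < 0 || current < 0) stop("voltage and current must be >= 0")
  voltage * current
}

#' Time-averaged power of a pulsed delivery
#' @param peak peak power, W.
#' @param duty duty cycle in `[0, 1]`.
#' @export
average_power <- function(peak, duty) {
  if (duty < 0 || duty > 1) stop("duty must be in [0, 1]")
  peak * duty
}

#' Manufacturer-style voltage recommendation
#'
#' Applied voltage from the voltage-to-distance dosing rule. Warns when
#' the electrode spacing exceeds the recommended maximum of 2.2 cm.
#'
#' @param distance inter-electrode distance, cm.
#' @param ratio voltage-to-distance ratio, V/cm (1500-1700 recommended).
#' @export
recommended_voltage <- function(distance, ratio = 1500) {
  if (distance <= 0) stop("distance must be positive")
  if (distance > 2.2)
    warning("electrode distance ", distance,
            " cm exceeds the recommended maximum of 2.2 cm")
  distance * ratio
}

#' Run a full pulse protocol
#'
#' Solves the stationary field once per train at the train's voltage
#' (caching identical pair/voltage combinations) and folds the per-train
#' fields into a combined field by voxelwise maximum — the standard way
#' multiple sequentially energized pairs accumulate coverage. The
#' combination uses each train's `E_peak` (the peak field over the
#' conductivity iterations): electroporation is cumulative, so a location
#' exposed above threshold at any point of the delivery stays porated
#' even though the field there drops once the tissue conductivity rises.
#'
#' @param scene an `ire_scene`.
#' @param materials an `ire_materials` table.
#' @param p an `ire_protocol` (default: the protocol attached to the scene).
#' @param thresholds named per-tissue IRE thresholds (V/cm) used for the
#'   per-train coverage bookkeeping.
#' @param progress print one line per train.
#' @param ... passed to [solve_pair()].
#' @return A `protocol_run`: `solutions` (per train), `E_max` (combined
#'   field, V/cm), `trains` (per-train data.frame with predicted and
#'   measured currents and cumulative coverage fractions), `scene`.
#' @export
run_protocol <- function(scene, materials, p = scene$protocol,
                         thresholds = c(liver = 700, tumor = 800),
                         progress = FALSE, ...) {
  if (is.null(p)) stop("no protocol given and none attached to the scene")
  idx <- vapply(scene$electrodes, function(e) e$index, 1L)
  if (!all(c(p$pair_a, p$pair_b) %in% idx))
    stop("protocol references electrodes not present in the scene")
  tumor_mask <- scene$labels == label_code("tumor")
  liver_mask <- scene$labels == label_code("liver")
  voxvol <- voxel_volume(scene$grid) / 1000
  cache <- new.env(parent = emptyenv())
  solutions <- vector("list", nrow(p))
  E_max <- array(0, dim = scene$grid$shape)
  rows <- vector("list", nrow(p))

  for (i in seq_len(nrow(p))) {
    key <- sprintf("%d_%d_%g", min(p$pair_a[i], p$pair_b[i]),
                   max(p$pair_a[i], p$pair_b[i]), p$voltage_V[i])
    if (is.null(cache[[key]])) {
      sol <- tryCatch(
        solve_pair(scene, materials,
                   boundary_assignment(c(p$pair_a[i], p$pair_b[i]),
                                       p$voltage_V[i]), ...),
        error = function(e)
          stop("train ", p$train[i], ": ", conditionMessage(e)))
      cache[[key]] <- sol
    }
    sol <- cache[[key]]
    solutions[[i]] <- sol
    E_max <- pmax(E_max, sol$E_peak)
    rows[[i]] <- data.frame(
      train = p$train[i], pair = sprintf("%d-%d", p$pair_a[i], p$pair_b[i]),
      voltage_V = p$voltage_V[i], n_pulses = p$n_pulses[i],
      phase = p$phase[i],
      measured_current_A = p$measured_current_A[i],
      computed_current_A = sol$current,
      tumor_frac_800 = mean(E_max[tumor_mask] >= 800),
      tumor_frac_900 = mean(E_max[tumor_mask] >= 900),
      tumor_frac_thr = mean(E_max[tumor_mask] >= thresholds[["tumor"]]),
      liver_cm3_thr = sum(E_max[liver_mask] >= thresholds[["liver"]]) * voxvol)
    if (progress)
      cat(sprintf("train %2d pair %s %4.0f V: %5.2f A, tumor>=800: %5.1f%%\n",
                  p$train[i], rows[[i]]$pair, p$voltage_V[i], sol$current,
                  100 * rows[[i]]$tumor_frac_800))
  }

  structure(list(solutions = solutions, E_max = E_max,
                 trains = do.call(rbind, rows), protocol = p,
                 thresholds = thresholds, scene = scene),
            class = "protocol_run")
}

#' @export
print.protocol_run <- function(x, ...) {
  n <- nrow(x$trains)
  cat(sprintf("<protocol_run> %d train(s); final tumor coverage >=800 V/cm: %.1f%%\n",
              n, 100 * x$trains$tumor_frac_800[n]))
  invisible(x)
}

#' Coverage curve: volume above field threshold
#'
#' Volume (cm^3) of a tissue mask exposed to a combined field at or above
#' each threshold — the threshold-sweep view used to judge coverage of the
#' tumor and the surrounding liver separately.
#'
#' @param E_max combined field array, V/cm (e.g. `run$E_max`), or a
#'   `protocol_run`.
#' @param scene the `ire_scene` the field was computed on (ignored when
#'   `E_max` is a `protocol_run`).
#' @param tissue tissue mask name (`"tumor"`, `"liver"`, `"vessel"`).
#' @param thresholds threshold grid, V/cm.
#' @return data.frame with `threshold_Vcm` and `volume_cm3`
#'   (non-increasing in threshold).
#' @export
coverage_curve <- function(E_max, scene = NULL, tissue = "tumor",
                           thresholds = seq(0, 1500, by = 25)) {
  if (inherits(E_max, "protocol_run")) {
    scene <- E_max$scene
    E_max <- E_max$E_max
  }
  mask <- scene$labels == label_code(tissue)
  if (!any(mask)) stop("tissue mask '", tissue, "' is empty")
  vals <- E_max[mask]
  voxvol <- voxel_volume(scene$grid) / 1000
  data.frame(threshold_Vcm = thresholds,
             volume_cm3 = vapply(thresholds,
                                 function(t) sum(vals >= t) * voxvol, 1.0))
}

#' Lesion volume at per-tissue IRE thresholds
#'
#' Tissue at or above its irreversible-electroporation threshold is
#' counted as ablated: liver at 700 V/cm and tumor at 800 V/cm by
#' default. Vessel and electrode voxels are excluded (ablation volumes
#' are tissue volumes).
#'
#' @param E_max combined field array (V/cm) or a `protocol_run`.
#' @param scene the scene (ignored for a `protocol_run`).
#' @param thresholds named per-tissue thresholds, V/cm.
#' @return list with per-tissue volumes and `total_cm3`.
#' @export
lesion_volume <- function(E_max, scene = NULL,
                          thresholds = c(liver = 700, tumor = 800)) {
  if (inherits(E_max, "protocol_run")) {
    scene <- E_max$scene
    E_max <- E_max$E_max
  }
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  voxvol <- voxel_volume(scene$grid) / 1000
  out <- list()
  for (nm in names(thresholds)) {
    mask <- scene$labels == label_code(nm)
    out[[paste0(nm, "_cm3")]] <- sum(E_max[mask] >= thresholds[[nm]]) * voxvol
  }
  out$total_cm3 <- sum(unlist(out))
  out
}

#' Write a coverage curve (or several) to CSV
#' @param curves named list of [coverage_curve()] results (or one curve).
#' @param path output CSV.
#' @export
write_coverage_csv <- function(curves, path) {
  if (is.data.frame(curves)) curves <- list(volume_cm3 = curves)
  out <- curves[[1]]["threshold_Vcm"]
  for (nm in names(curves)) out[[nm]] <- curves[[nm]]$volume_cm3
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
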