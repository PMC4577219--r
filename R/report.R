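# Run report: current comparison against generator measurements, summary
# statistics, and serialized JSON/text output.

#' Percent error of a computed current
#'
#' `100 * (computed - measured) / measured`. Note the convention: the
#' measured value is the denominator, so swapping the arguments does not
#' simply flip the sign.
#'
#' @param measured measured current, A (> 0).
#' @param computed model-predicted current, A.
#' @export
percent_error <- function(measured, computed) {
  if (any(measured <= 0)) stop("measured current must be positive")
  100 * (computed - measured) / measured
}

#' Root-mean-square error of computed vs measured currents
#'
#' @param comparison data.frame with columns `measured_current_A` and
#'   `computed_current_A` (rows with either missing are dropped), or two
#'   numeric vectors via `computed`.
#' @param computed optional vector of computed currents when
#'   `comparison` is the measured vector.
#' @return RMSE in A: `sqrt(mean((computed - measured)^2))`.
#' @export
current_rmse <- function(comparison, computed = NULL) {
  if (is.data.frame(comparison)) {
    m <- comparison$measured_current_A
    c_ <- comparison$computed_current_A
  } else {
    m <- comparison; c_ <- computed
  }
  ok <- is.finite(m) & is.finite(c_)
  if (!any(ok)) stop("no rows with both measured and computed currents")
  sqrt(mean((c_[ok] - m[ok])^2))
}

#' Per-train current comparison table
#'
#' @param trains per-train data.frame with `measured_current_A` and
#'   `computed_current_A` (e.g. `run$trains` from [run_protocol()]).
#' @return A `current_comparison`: the table plus integer-rounded percent
#'   errors and the RMSE attribute.
#' @export
current_comparison <- function(trains) {
  cc <- trains[, intersect(c("train", "pair", "voltage_V",
                             "measured_current_A", "computed_current_A"),
                           names(trains))]
  cc$error_pct <- round(percent_error(cc$measured_current_A,
                                      cc$computed_current_A))
  attr(cc, "rmse_A") <- current_rmse(cc)
  class(cc) <- c("current_comparison", "data.frame")
  cc
}

#' Assemble the run report
#'
#' Collects protocol bookkeeping (pulse count, duty cycle, power budget),
#' lesion volumes and tumor coverage (evaluated at both 800 and
#' 900 V/cm), thermal exceedance and damage volumes, the current
#' comparison, and the safety-margin ellipsoid, into one deterministic
#' document. Upstream results may be omitted: a protocol-only report is
#' valid.
#'
#' @param protocol an `ire_protocol`.
#' @param run optional `protocol_run`.
#' @param thermal optional `thermal_run`.
#' @param scene optional `ire_scene` (defaults to the run's scene).
#' @param tumor_diameters tumor diameters for the safety-margin
#'   bookkeeping, mm.
#' @param margin_mm safety margin, mm.
#' @param seed optional seed recorded as provenance.
#' @return A `run_report` list.
#' @export
build_report <- function(protocol, run = NULL, thermal = NULL, scene = NULL,
                         tumor_diameters = c(14, 9, 15), margin_mm = 10,
                         seed = NULL) {
  if (is.null(scene) && !is.null(run)) scene <- run$scene
  if (!is.null(run) && !is.null(thermal) &&
      !identical(dim(run$E_max), dim(thermal$state$T)))
    stop("field and thermal results live on different grids")

  duty <- duty_cycle(protocol$width_us[1] * 1e-6, protocol$rate_Hz[1])
  vmax <- max(protocol$voltage_V)
  imax <- if (any(is.finite(protocol$measured_current_A)))
    max(protocol$measured_current_A, na.rm = TRUE) else NA_real_
  rep_ <- list(
    schema = "ireplan-report", schema_version = 1L,
    protocol = list(
      n_trains = nrow(protocol),
      total_pulses = total_pulses(protocol),
      duty_cycle = duty,
      max_voltage_V = vmax,
      max_measured_current_A = imax,
      peak_power_W = if (is.finite(imax)) peak_power(vmax, imax) else NA_real_,
      average_power_W = if (is.finite(imax))
        average_power(peak_power(vmax, imax), duty) else NA_real_),
    safety_margin = list(
      tumor_diameters_mm = tumor_diameters, margin_mm = margin_mm,
      target_lesion_cm3 = safety_margin_volume(tumor_diameters, margin_mm)))

  if (!is.null(run)) {
    lv <- lesion_volume(run)
    n <- nrow(run$trains)
    rep_$lesion <- c(lv, list(
      tumor_coverage_800 = run$trains$tumor_frac_800[n],
      tumor_coverage_900 = run$trains$tumor_frac_900[n]))
    cc <- if (any(is.finite(run$trains$measured_current_A)))
      current_comparison(run$trains) else NULL
    if (!is.null(cc)) {
      rep_$currents <- as.data.frame(cc)
      rep_$current_rmse_A <- attr(cc, "rmse_A")
    }
  }
  if (!is.null(thermal)) {
    s <- thermal$series[nrow(thermal$series), ]
    rep_$thermal <- list(
      t_end_s = s$t_s, max_T_C = s$max_T_K - 273.15,
      vol_gt_50C_cm3 = s$vol_gt_50C_cm3,
      vol_gt_70C_cm3 = s$vol_gt_70C_cm3,
      vol_gt_100C_cm3 = s$vol_gt_100C_cm3,
      vol_omega_ge_1_cm3 = s$vol_omega_ge_1_cm3)
  }
  rep_$provenance <- list(package_version = as.character(packageVersion("ireplan")),
                          seed = seed)
  class(rep_) <- "run_report"
  rep_
}

#' Write a run report to disk
#'
#' Produces `report.json` (machine-readable, full precision),
#' `report.txt` (human summary: currents to 0.1 A, errors to whole
#' percent, volumes to 0.01 cm^3) and, when a current comparison exists,
#' `currents.csv`.
#'
#' @param report a [build_report()] result.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  txt <- c("ireplan run report",
           sprintf("trains: %d, pulses: %d, duty cycle: %.4f%%",
                   report$protocol$n_trains, report$protocol$total_pulses,
                   100 * report$protocol$duty_cycle))
  if (is.finite(report$protocol$peak_power_W %||% NA))
    txt <- c(txt, sprintf("peak power: %.1f kW, average power: %.1f W",
                          report$protocol$peak_power_W / 1000,
                          report$protocol$average_power_W))
  txt <- c(txt, sprintf("safety-margin target lesion: %.2f cm^3",
                        report$safety_margin$target_lesion_cm3))
  if (!is.null(report$lesion))
    txt <- c(txt, sprintf(
      "lesion: %.2f cm^3 total; tumor coverage %.1f%% (>=800 V/cm), %.1f%% (>=900 V/cm)",
      report$lesion$total_cm3, 100 * report$lesion$tumor_coverage_800,
      100 * report$lesion$tumor_coverage_900))
  if (!is.null(report$current_rmse_A))
    txt <- c(txt, sprintf("current RMSE: %.1f A", report$current_rmse_A))
  if (!is.null(report$thermal))
    txt <- c(txt, sprintf(
      "thermal: max %.1f C, V(>50C) %.2f cm^3, V(omega>=1) %.2f cm^3",
      report$thermal$max_T_C, report$thermal$vol_gt_50C_cm3,
      report$thermal$vol_omega_ge_1_cm3))
  writeLines(txt, file.path(dir, "report.txt"))
  if (!is.null(report$currents)) {
    cc <- report$currents
    cc$measured_current_A <- round(cc$measured_current_A, 1)
    cc$computed_current_A <- round(cc$computed_current_A, 1)
    write.csv(cc, file.path(dir, "currents.csv"), row.names = FALSE)
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$protocol$n_trains, "train(s),",
      x$protocol$total_pulses, "pulses\n")
  if (!is.null(x$lesion))
    cat(sprintf("  lesion %.2f cm^3, tumor coverage %.1f%% at 800 V/cm\n",
                x$lesion$total_cm3, 100 * x$lesion$tumor_coverage_800))
  if (!is.null(x$current_rmse_A))
    cat(sprintf("  current RMSE %.2f A\n", x$current_rmse_A))
  invisible(x)
}
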