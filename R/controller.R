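#' Protocol builder and closed-loop simulated runs
#'
#' The standard maintenance protocol for adherent culture in this system is a
#' periodic partial media refresh: every `period_h` hours, drain a fixed
#' volume of spent media from each well to waste (past the pH sensor), draw
#' the same volume of fresh media, and refill the well. These functions
#' generate that protocol as a script in the control language, execute it
#' against the simulated device bus and culture twin, and bundle the
#' resulting event trace, pH log and summaries into a run report.
#'
#' @name controller
NULL

#' Define a periodic media-refresh protocol
#'
#' @param wells Channel ids of the wells to service (serviced in the given
#'   order each cycle).
#' @param volume_ml Volume drained and replaced per well per cycle.
#' @param period_h Hours between cycles.
#' @param cycles Number of refresh cycles (>= 1).
#' @return A `refresh_protocol` object.
#' @export
refresh_protocol <- function(wells = paste0("W", 1:6), volume_ml = 2,
                             period_h = 6, cycles = 8) {
  stopifnot(length(wells) >= 1, volume_ml > 0, period_h > 0)
  if (cycles < 1) stop("cycles must be >= 1")
  structure(list(wells = wells, volume_ml = volume_ml, period_h = period_h,
                 cycles = as.integer(cycles)),
            class = "refresh_protocol")
}

#' Generate the refresh protocol as a control script
#'
#' Emits, for each well in each cycle, the four-transfer sequence: drain
#' (`Ch well / Dir B / Vol v / Start`), dispose to waste through the sensor
#' line (`Ch WASTE / Dir F / Start`), draw fresh media (`Ch FRESH / Dir B /
#' Start`), refill (`Ch well / Dir F / Start`); then a `Wait` of one period.
#' The whole cycle body is wrapped in `Loop cycles` / `Goto`, so the script
#' stays short no matter how many cycles run. The generated script passes
#' [validate_script()] under the same config.
#'
#' @param protocol A [refresh_protocol()].
#' @param config A [br_config()]; supplies the fresh/waste channel ids and
#'   the syringe capacity check.
#' @return A `br_script`.
#' @export
build_refresh_script <- function(protocol, config = br_config()) {
  stopifnot(inherits(protocol, "refresh_protocol"))
  if (protocol$volume_ml > config$pump$capacity_ml)
    stop(sprintf("exchange volume %.3g mL exceeds syringe capacity %.3g mL",
                 protocol$volume_ml, config$pump$capacity_ml))
  missing <- setdiff(protocol$wells,
                     config$channels$channel[config$channels$role == "well"])
  if (length(missing))
    stop("protocol wells not in channel table: ", paste(missing, collapse = ", "))

  v <- format(protocol$volume_ml, scientific = FALSE, trim = TRUE)
  lines <- c(sprintf("Loop %d", protocol$cycles))
  for (w in protocol$wells) {
    lines <- c(lines,
               sprintf("Ch %s", w), "Dir B", sprintf("Vol %s", v), "Start",
               sprintf("Ch %s", config$waste_channel), "Dir F", "Start",
               sprintf("Ch %s", config$fresh_channel), "Dir B", "Start",
               sprintf("Ch %s", w), "Dir F", "Start")
  }
  lines <- c(lines, sprintf("Wait %s", format_hms(protocol$period_h * 3600)),
             "Goto 2")
  parse_script(lines)
}

#' Execute a refresh protocol against the simulated bioreactor
#'
#' Builds the protocol script, validates it, seeds the wells with the
#' standard initial conditions (7e4 cells in 5 mL, unless `wells` overrides
#' them), and runs the interpreter against a [simulated_bus()]. The culture
#' twin advances during `Wait`s and pump transfers; every dispose-to-waste
#' transfer pushes spent media past the pH sensor and logs one reading.
#' Fully reproducible: all randomness (sensor noise) derives from `seed`.
#'
#' @param protocol A [refresh_protocol()].
#' @param config A [br_config()].
#' @param seed Integer seed for the run's random stream.
#' @param wells Optional named list of starting `well_state`s.
#' @return A `run_report`: list with `events` (event trace), `ph_log`
#'   (sensor readings), `wells` (final `well_state`s), `clock_s`, `seed`, and
#'   `summary` (mean/min/max logged pH, fraction of readings inside the
#'   `ph_optimum +/- ph_tolerance` band, final cell counts, media ledger).
#' @export
run_protocol <- function(protocol = refresh_protocol(), config = br_config(),
                         seed = 1L, wells = NULL) {
  script <- build_refresh_script(protocol, config)
  diags <- validate_script(script, config)
  if (any(diags$severity == "error"))
    stop("generated script failed validation: ",
         paste(diags$message[diags$severity == "error"], collapse = "; "))

  set.seed(seed)
  bus <- simulated_bus(config, wells = wells)
  reservoir_start <- bus$reservoir_ml
  events <- run_script(script, bus, config)
  ph_log <- bus_sensor_log(bus)

  report <- list(events = events, ph_log = ph_log, wells = bus$wells,
                 clock_s = attr(events, "final_clock_s"), seed = seed,
                 summary = summarize_run(ph_log, bus, config,
                                         reservoir_start = reservoir_start))
  class(report) <- "run_report"
  report
}

summarize_run <- function(ph_log, bus, config, reservoir_start) {
  band <- config$twin$ph_optimum + c(-1, 1) * config$twin$ph_tolerance
  ph <- ph_log$ph_estimate
  list(
    n_readings = nrow(ph_log),
    mean_ph = if (length(ph)) mean(ph) else NA_real_,
    min_ph = if (length(ph)) min(ph) else NA_real_,
    max_ph = if (length(ph)) max(ph) else NA_real_,
    ph_band = band,
    frac_in_band = if (length(ph)) mean(ph >= band[1] & ph <= band[2]) else NA_real_,
    final_cells = vapply(bus$wells, function(w) w$cells, numeric(1)),
    media_used_ml = reservoir_start - bus$reservoir_ml,
    waste_ml = bus$waste_ml)
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("bioreactor run: %.1f h simulated, %d pump events, %d pH readings\n",
              x$clock_s / 3600, sum(x$events$event_type == "pump"), s$n_readings))
  if (s$n_readings) {
    cat(sprintf("  logged pH: mean %.3f, range [%.3f, %.3f], %.0f%% inside [%.1f, %.1f]\n",
                s$mean_ph, s$min_ph, s$max_ph, 100 * s$frac_in_band,
                s$ph_band[1], s$ph_band[2]))
  }
  cat(sprintf("  media used %.3g mL, waste %.3g mL, final cells/well %.3g (mean)\n",
              s$media_used_ml, s$waste_ml, mean(s$final_cells)))
  invisible(x)
}

#' Write a run report to a directory
#'
#' Writes `events.csv`, `ph_log.csv` and `report.json` (summary statistics)
#' under `dir`.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_event_trace(report$events, file.path(dir, "events.csv"))
  write_ph_log(report$ph_log, file.path(dir, "ph_log.csv"))
  s <- report$summary
  s$final_cells <- as.list(s$final_cells)
  jsonlite::write_json(
    list(seed = report$seed, clock_s = report$clock_s, summary = s),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
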