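#' Run configuration
#'
#' One object bundles everything a simulated run needs: the pump geometry,
#' the selector's channel table, the culture-twin parameters, the sensor
#' model, the fresh-media reservoir size and the interpreter's termination
#' guard. Build it in code with [br_config()] or load it from a YAML file
#' with [read_br_config()].
#'
#' @param pump A [pump_config()].
#' @param channels A [channel_table()].
#' @param twin A [culture_params()].
#' @param sensor List with `curve` (a [ph_calibration()]), `noise_sd`
#'   (counts) and `quantize` (logical, 10-bit ADC rounding).
#' @param reservoir_ml Initial fresh-media reservoir volume.
#' @param max_steps Interpreter instruction budget (infinite-loop guard).
#' @return A `br_config` object with derived fields `fresh_channel` and
#'   `waste_channel`.
#' @export
br_config <- function(pump = pump_config(),
                      channels = channel_table(),
                      twin = culture_params(),
                      sensor = list(curve = default_ph_calibration(),
                                    noise_sd = 2, quantize = FALSE),
                      reservoir_ml = 250,
                      max_steps = 1e5) {
  stopifnot(inherits(pump, "pump_config"), is.data.frame(channels),
            inherits(twin, "culture_params"),
            inherits(sensor$curve, "ph_calibration"),
            sensor$noise_sd >= 0, reservoir_ml >= 0, max_steps >= 1)
  if (sum(channels$role == "fresh_media") != 1L ||
      sum(channels$role == "waste") != 1L)
    stop("channel table needs exactly one fresh_media and one waste channel")
  structure(list(pump = pump, channels = channels, twin = twin,
                 sensor = sensor, reservoir_ml = reservoir_ml,
                 max_steps = as.integer(max_steps),
                 fresh_channel = channels$channel[channels$role == "fresh_media"],
                 waste_channel = channels$channel[channels$role == "waste"]),
            class = "br_config")
}

#' @export
print.br_config <- function(x, ...) {
  cat("bioreactor configuration\n")
  cat(sprintf("  pump: %.3g mL syringe, %g steps/mL, default %.3g mL/min\n",
              x$pump$capacity_ml, x$pump$steps_per_ml,
              x$pump$default_rate_ml_min))
  cat(sprintf("  channels: %d wells, fresh=%s, waste=%s\n",
              sum(x$channels$role == "well"), x$fresh_channel, x$waste_channel))
  cat(sprintf("  twin: r=%.3g/h, K=%.3g, q=%.3g, fresh pH %.2f\n",
              x$twin$r_per_h, x$twin$K_cells, x$twin$q, x$twin$fresh_ph))
  invisible(x)
}

# keys recognised in each YAML section; unknown keys are rejected outright so
# a typo never silently falls back to a default
config_known_keys <- list(
  pump = c("capacity_ml", "steps_per_ml", "max_rate_ml_min", "default_rate_ml_min"),
  twin = c("r_per_h", "K_cells", "q", "beta", "fresh_ph", "ph_optimum", "ph_tolerance"),
  sensor = c("slope", "intercept", "valid_ph_low", "valid_ph_high",
             "noise_sd", "quantize"),
  sim = c("reservoir_ml", "max_steps", "seed"))

#' Read a run configuration from YAML
#'
#' Recognised sections: `pump`, `channels` (map channel id -> role), `twin`,
#' `sensor`, `sim`. Every key is optional and falls back to the package
#' default; unknown sections or keys are an error.
#'
#' @param path YAML file path.
#' @return A `br_config`.
#' @export
read_br_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c(names(config_known_keys), "channels"))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config_known_keys)) {
    bad <- setdiff(names(raw[[sec]]), config_known_keys[[sec]])
    if (length(bad))
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
  }
  take <- function(sec, key, default) {
    v <- raw[[sec]][[key]]
    if (is.null(v)) default else v
  }
  pump <- pump_config(
    capacity_ml = take("pump", "capacity_ml", 10),
    steps_per_ml = take("pump", "steps_per_ml", 800),
    max_rate_ml_min = take("pump", "max_rate_ml_min", 5),
    default_rate_ml_min = take("pump", "default_rate_ml_min", 2))
  twin <- culture_params(
    r_per_h = take("twin", "r_per_h", 0.035),
    K_cells = take("twin", "K_cells", 1.2e6),
    q = take("twin", "q", 6e-7),
    beta = take("twin", "beta", 3.0),
    fresh_ph = take("twin", "fresh_ph", 7.5),
    ph_optimum = take("twin", "ph_optimum", 7.4),
    ph_tolerance = take("twin", "ph_tolerance", 0.2))
  curve <- ph_calibration(
    slope = take("sensor", "slope", -57.7),
    intercept = take("sensor", "intercept", 1032),
    valid_ph_range = c(take("sensor", "valid_ph_low", 6.90),
                       take("sensor", "valid_ph_high", 7.83)))
  sensor <- list(curve = curve,
                 noise_sd = take("sensor", "noise_sd", 2),
                 quantize = isTRUE(take("sensor", "quantize", FALSE)))
  channels <- if (is.null(raw$channels)) channel_table() else {
    roles <- unlist(raw$channels)
    ok <- c("well", "fresh_media", "waste")
    if (!all(roles %in% ok))
      stop("channel roles must be one of: ", paste(ok, collapse = ", "))
    channel_table(wells = names(roles)[roles == "well"],
                  fresh = names(roles)[roles == "fresh_media"],
                  waste = names(roles)[roles == "waste"])
  }
  cfg <- br_config(pump = pump, channels = channels, twin = twin,
                   sensor = sensor,
                   reservoir_ml = take("sim", "reservoir_ml", 250),
                   max_steps = take("sim", "max_steps", 1e5))
  cfg$seed <- take("sim", "seed", NULL)
  cfg
}
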