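#' Device models: syringe pump, selector, stirrers
#'
#' Contracts and simulated implementations for the bioreactor's wetted
#' hardware: a stepper-motor syringe pump holding a disposable 10-mL syringe,
#' a servo-driven selector that routes flow between the pump, the culture
#' wells, a fresh-media reservoir and the waste line, and one magnetic
#' micro-stirrer per well. Only simulated backends ship; a serial backend
#' would implement the same device-bus contract.
#'
#' @name hardware
NULL

#' Syringe pump configuration
#'
#' @param capacity_ml Syringe capacity; the standard disposable syringe is
#'   10 mL.
#' @param steps_per_ml Stepper-motor steps per mL of plunger travel (drive
#'   geometry dependent; 800 is typical for a NEMA17 + leadscrew drive).
#' @param max_rate_ml_min Maximum deliverable flow rate.
#' @param default_rate_ml_min Flow rate used when a transfer does not specify
#'   one.
#' @return A `pump_config` object.
#' @export
pump_config <- function(capacity_ml = 10, steps_per_ml = 800,
                        max_rate_ml_min = 5, default_rate_ml_min = 2) {
  stopifnot(capacity_ml > 0, steps_per_ml > 0, max_rate_ml_min > 0,
            default_rate_ml_min > 0, default_rate_ml_min <= max_rate_ml_min)
  structure(list(capacity_ml = capacity_ml, steps_per_ml = steps_per_ml,
                 max_rate_ml_min = max_rate_ml_min,
                 default_rate_ml_min = default_rate_ml_min),
            class = "pump_config")
}

#' Calibrate the syringe pump from gravimetric measurements
#'
#' The pump is calibrated by running it at several set flow rates for a fixed
#' collection time (one minute) and weighing the dispensed water on an
#' analytical balance. This fits the ordinary least-squares line of measured
#' mass on set rate across all replicates; with water at 1.000 g/mL and a
#' 1-min collection, an accurate pump gives slope ~1 g per (mL/min) and
#' intercept ~0.
#'
#' @param points Data frame with columns `set_rate_ml_min` and `mass_g`
#'   (optionally `replicate`).
#' @return A `pump_calibration`: slope (g per mL/min), intercept (g),
#'   r_squared, and the points used.
#' @export
calibrate_pump <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("set_rate_ml_min", "mass_g") %in% names(points)))
  if (length(unique(points$set_rate_ml_min)) < 2L)
    stop("degenerate design: need at least 2 distinct set-rate levels")
  fit <- stats::lm(mass_g ~ set_rate_ml_min, data = points)
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf["set_rate_ml_min"]),
                 intercept = unname(cf["(Intercept)"]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 points = points),
            class = "pump_calibration")
}

#' @export
print.pump_calibration <- function(x, ...) {
  cat(sprintf("pump calibration: mass = %.4g * rate + %.4g g (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Convert a dispense volume to motor steps and back
#'
#' @param volume_ml Volume in `(0, capacity]`.
#' @param config A `pump_config`.
#' @return `volume_to_steps`: integer motor steps (rounded);
#'   `steps_to_volume`: mL. The round trip is exact to half a step.
#' @export
volume_to_steps <- function(volume_ml, config = pump_config()) {
  stopifnot(inherits(config, "pump_config"))
  if (any(volume_ml <= 0)) stop("volume must be positive")
  if (any(volume_ml > config$capacity_ml))
    stop(sprintf("volume %.3g mL exceeds syringe capacity %.3g mL",
                 max(volume_ml), config$capacity_ml))
  as.integer(round(volume_ml * config$steps_per_ml))
}

#' @rdname volume_to_steps
#' @param steps Motor steps.
#' @export
steps_to_volume <- function(steps, config = pump_config()) {
  stopifnot(inherits(config, "pump_config"))
  steps / config$steps_per_ml
}

#' Channel table for the selector
#'
#' Maps channel identifiers to their role in the flow path. Exactly one
#' channel is the fresh-media reservoir and exactly one the waste line; the
#' non-contact pH sensor sits on the waste line, immediately upstream of the
#' waste container, so it reads whatever media was last pushed towards waste.
#' Servo index/angle placeholders record where each channel sits on the
#' 3-servo selector head.
#'
#' @param wells Character vector of well channel ids.
#' @param fresh Fresh-media channel id.
#' @param waste Waste (sensor-line) channel id.
#' @return Data frame with columns `channel`, `role`, `servo`, `angle_deg`.
#' @export
channel_table <- function(wells = paste0("W", 1:6), fresh = "FRESH",
                          waste = "WASTE") {
  ids <- c(wells, fresh, waste)
  if (anyDuplicated(ids)) stop("channel ids must be unique")
  n <- length(ids)
  data.frame(channel = ids,
             role = c(rep("well", length(wells)), "fresh_media", "waste"),
             servo = ((seq_len(n) - 1L) %/% 3L) + 1L,
             angle_deg = ((seq_len(n) - 1L) %% 3L) * 60,
             stringsAsFactors = FALSE)
}

#' Simulated device bus
#'
#' Builds a backend satisfying the device-bus contract against the digital
#' twin: `run_pump(volume, direction, channel, rate)` moves media between the
#' syringe and the selected channel and returns the transfer duration in
#' seconds (volume / rate); `set_channel` and `set_stirrer` drive the selector
#' and stirrers; `read_green_intensity` applies the forward sensor model to
#' the media currently in the sensor line (the line to waste);
#' `elapse(dt_s)` advances the twin's wells, standing in for wall-clock time.
#'
#' Direction convention: `"B"`(ackward) withdraws from the selected channel
#' into the syringe, `"F"`(orward) dispenses from the syringe to it. The
#' selector is exclusive -- one open channel at a time. Every dispense towards
#' the waste line updates the sensor line with the pH of the dispensed
#' aliquot and appends a time-stamped reading to the bus's sensor log.
#'
#' @param config Full device configuration, see [br_config()].
#' @param wells Named list of `well_state`s, one per well channel. Defaults to
#'   the config's seeding conditions.
#' @return An environment of class `sim_bus` with the contract functions and
#'   inspectable state (`syringe_ml`, `syringe_acid`, `wells`, `waste_ml`,
#'   `reservoir_ml`, `stirrers`, `clock_s`, `sensor_log`).
#' @export
simulated_bus <- function(config = br_config(), wells = NULL) {
  chan <- config$channels
  params <- config$twin
  if (is.null(wells)) {
    ids <- chan$channel[chan$role == "well"]
    wells <- setNames(lapply(ids, function(i) well_state()), ids)
  }
  stopifnot(all(names(wells) %in% chan$channel[chan$role == "well"]))

  bus <- new.env(parent = emptyenv())
  bus$config <- config
  bus$wells <- wells
  bus$syringe_ml <- 0
  bus$syringe_acid <- 0
  bus$active_channel <- NA_character_
  bus$stirrers <- setNames(rep(FALSE, length(wells)), names(wells))
  bus$reservoir_ml <- config$reservoir_ml
  bus$waste_ml <- 0
  bus$waste_acid <- 0
  bus$sensor_line_ph <- NA_real_
  bus$clock_s <- 0
  bus$sensor_log <- list()

  role_of <- function(channel) {
    r <- chan$role[chan$channel == channel]
    if (!length(r)) stop("unknown channel '", channel, "'")
    r
  }

  bus$set_channel <- function(channel) {
    role_of(channel)  # validates
    bus$active_channel <- channel
    invisible(channel)
  }

  bus$set_stirrer <- function(channel, on) {
    if (!channel %in% names(bus$stirrers))
      stop("unknown stirrer channel '", channel, "'")
    bus$stirrers[[channel]] <- isTRUE(on)
    invisible(on)
  }

  bus$elapse <- function(dt_s) {
    if (dt_s <= 0) return(invisible(NULL))
    bus$wells <- lapply(bus$wells, advance_well, dt_h = dt_s / 3600,
                        params = params)
    bus$clock_s <- bus$clock_s + dt_s
    invisible(NULL)
  }

  record_reading <- function(ph) {
    g <- ph_to_intensity(ph, config$sensor$curve,
                         noise_sd = config$sensor$noise_sd,
                         quantize = config$sensor$quantize)
    est <- intensity_to_ph(g, config$sensor$curve)
    bus$sensor_log[[length(bus$sensor_log) + 1L]] <- data.frame(
      elapsed_s = bus$clock_s, channel = config$waste_channel,
      green_intensity = as.numeric(g), ph_estimate = as.numeric(est),
      in_range = attr(est, "in_range"))
  }

  bus$run_pump <- function(volume_ml, direction, channel = bus$active_channel,
                           rate_ml_min = config$pump$default_rate_ml_min) {
    if (is.na(channel)) stop("no channel selected")
    role <- role_of(channel)
    stopifnot(volume_ml > 0, direction %in% c("F", "B"),
              rate_ml_min > 0, rate_ml_min <= config$pump$max_rate_ml_min)
    duration_s <- volume_ml / rate_ml_min * 60

    if (direction == "B") {  # withdraw into syringe
      if (bus$syringe_ml + volume_ml > config$pump$capacity_ml + 1e-9)
        stop(sprintf("syringe overfill: %.3g + %.3g mL exceeds capacity %.3g mL",
                     bus$syringe_ml, volume_ml, config$pump$capacity_ml))
      if (role == "well") {
        w <- bus$wells[[channel]]
        if (volume_ml > w$volume_ml + 1e-9)
          stop(sprintf("overdraw: %.3g mL requested from %.3g mL in %s",
                       volume_ml, w$volume_ml, channel))
        acid_out <- w$acid * volume_ml / w$volume_ml
        bus$wells[[channel]] <- well_state(w$cells, w$volume_ml - volume_ml,
                                           w$acid - acid_out)
        bus$syringe_acid <- bus$syringe_acid + acid_out
      } else if (role == "fresh_media") {
        if (volume_ml > bus$reservoir_ml + 1e-9)
          stop("fresh media reservoir exhausted")
        bus$reservoir_ml <- bus$reservoir_ml - volume_ml
      } else stop("cannot withdraw from the waste line")
      bus$syringe_ml <- bus$syringe_ml + volume_ml
    } else {  # dispense from syringe
      if (volume_ml > bus$syringe_ml + 1e-9)
        stop(sprintf("syringe underflow: dispensing %.3g mL but syringe holds %.3g mL",
                     volume_ml, bus$syringe_ml))
      conc <- if (bus$syringe_ml > 0) bus$syringe_acid / bus$syringe_ml else 0
      acid_out <- conc * volume_ml
      if (role == "well") {
        w <- bus$wells[[channel]]
        bus$wells[[channel]] <- well_state(w$cells, w$volume_ml + volume_ml,
                                           w$acid + acid_out)
      } else if (role == "waste") {
        bus$waste_ml <- bus$waste_ml + volume_ml
        bus$waste_acid <- bus$waste_acid + acid_out
        bus$sensor_line_ph <- params$fresh_ph - conc / params$beta
        record_reading(bus$sensor_line_ph)
      } else stop("cannot dispense into the fresh media reservoir")
      bus$syringe_ml <- bus$syringe_ml - volume_ml
      bus$syringe_acid <- bus$syringe_acid - acid_out
    }
    bus$elapse(duration_s)
    duration_s
  }

  bus$read_green_intensity <- function() {
    if (is.na(bus$sensor_line_ph))
      stop("sensor line is empty: no media has passed towards waste yet")
    ph_to_intensity(bus$sensor_line_ph, config$sensor$curve,
                    noise_sd = config$sensor$noise_sd,
                    quantize = config$sensor$quantize)
  }

  class(bus) <- c("sim_bus", class(bus))
  bus
}

#' Total liquid volume tracked by a simulated bus
#'
#' Sum of all well volumes, syringe contents, waste and reservoir; constant
#' across any sequence of pump operations (conservation check).
#' @param bus A `sim_bus`.
#' @return Total volume in mL.
#' @export
bus_total_volume <- function(bus) {
  sum(vapply(bus$wells, function(w) w$volume_ml, numeric(1))) +
    bus$syringe_ml + bus$waste_ml + bus$reservoir_ml
}

#' Sensor log accumulated by a simulated bus
#'
#' @param bus A `sim_bus`.
#' @return Data frame in pH-log format (see [write_ph_log()]), zero rows if no
#'   media has been disposed yet.
#' @export
bus_sensor_log <- function(bus) {
  if (!length(bus$sensor_log))
    return(data.frame(elapsed_s = numeric(0), channel = character(0),
                      green_intensity = numeric(0), ph_estimate = numeric(0),
                      in_range = logical(0)))
  do.call(rbind, bus$sensor_log)
}

#' Read a pump-calibration point CSV
#'
#' Expected columns: `set_rate_ml_min,replicate,mass_g`.
#' @param path CSV path.
#' @return Data frame of calibration points.
#' @export
read_pump_points <- function(path) {
  out <- utils::read.csv(path)
  need <- c("set_rate_ml_min", "mass_g")
  if (!all(need %in% names(out)))
    stop("pump calibration CSV must have columns set_rate_ml_min,mass_g")
  out
}
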