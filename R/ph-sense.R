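#' Colorimetric pH sensing via phenol red
#'
#' Standard culture media contain phenol red, which shifts from yellow to pink
#' over pH ~6.8-8.2. Rising pH deepens the red colour, which absorbs more
#' green light, so the green intensity transmitted through a tube of media
#' falls linearly with pH over the indicator's working window. These functions
#' fit and apply that straight-line calibration and read/write the CSV
#' monitoring log produced during a culture run.
#'
#' @name ph-sense
NULL

#' Phenol red indicator window (pH units)
#'
#' Outside ~6.8-8.2 the dye is saturated at one of its two colour forms and
#' green intensity no longer encodes pH.
#' @export
PHENOL_RED_WINDOW <- c(6.8, 8.2)

#' Construct a green-intensity vs pH calibration curve
#'
#' @param slope Intensity counts per pH unit (negative for phenol red: greener
#'   light is absorbed as pH rises).
#' @param intercept Intensity counts at pH 0 (extrapolated).
#' @param valid_ph_range Length-2 numeric, the pH span covered by the
#'   calibration points; estimates outside it are flagged. Must lie within the
#'   phenol red window.
#' @param n_replicates Number of replicate readings per level used in the fit.
#' @return An object of class `ph_calibration`.
#' @export
ph_calibration <- function(slope, intercept, valid_ph_range, n_replicates = 1L) {
  stopifnot(is.numeric(slope), length(slope) == 1L, slope != 0,
            is.numeric(intercept), length(intercept) == 1L,
            is.numeric(valid_ph_range), length(valid_ph_range) == 2L)
  valid_ph_range <- sort(valid_ph_range)
  if (valid_ph_range[1] < PHENOL_RED_WINDOW[1] - 1e-9 ||
      valid_ph_range[2] > PHENOL_RED_WINDOW[2] + 1e-9) {
    stop("valid_ph_range must lie within the phenol red window [",
         PHENOL_RED_WINDOW[1], ", ", PHENOL_RED_WINDOW[2], "]")
  }
  if (valid_ph_range[1] >= valid_ph_range[2])
    stop("valid_ph_range must span a non-empty interval")
  structure(
    list(slope = slope, intercept = intercept,
         valid_ph_range = valid_ph_range,
         n_replicates = as.integer(n_replicates)),
    class = "ph_calibration")
}

#' Default pH calibration for phenol-red DMEM
#'
#' The reference line relating transmitted green intensity G to pH for DMEM,
#' G = -57.7 pH + 1032, established over pH 6.90-7.83 with n = 3 replicates
#' per level.
#' @return A `ph_calibration` object.
#' @export
default_ph_calibration <- function() {
  ph_calibration(slope = -57.7, intercept = 1032,
                 valid_ph_range = c(6.90, 7.83), n_replicates = 3L)
}

#' @export
print.ph_calibration <- function(x, ...) {
  cat(sprintf("pH calibration: intensity = %.4g * pH + %.5g\n", x$slope, x$intercept))
  cat(sprintf("  valid over pH [%.2f, %.2f], n = %d replicates/level\n",
              x$valid_ph_range[1], x$valid_ph_range[2], x$n_replicates))
  invisible(x)
}

#' Fit a pH calibration line by least squares
#'
#' Ordinary least squares of green intensity on pH over all replicate points.
#' The validity range of the returned curve is the span of the calibration pH
#' levels used.
#'
#' @param points Data frame with columns `ph` and `green_intensity` (a
#'   `replicate` column, if present, is ignored by the fit).
#' @return A `ph_calibration` with the fitted slope/intercept and an
#'   `r_squared` element.
#' @export
fit_ph_calibration <- function(points) {
  stopifnot(is.data.frame(points), all(c("ph", "green_intensity") %in% names(points)))
  ph <- points$ph
  if (any(ph < PHENOL_RED_WINDOW[1] | ph > PHENOL_RED_WINDOW[2]))
    stop("calibration pH level outside the phenol red window [",
         PHENOL_RED_WINDOW[1], ", ", PHENOL_RED_WINDOW[2],
         "]: phenol red is not informative there")
  if (length(unique(ph)) < 2L)
    stop("degenerate design: need at least 2 distinct pH levels")
  fit <- stats::lm(green_intensity ~ ph, data = points)
  cf <- stats::coef(fit)
  n_rep <- if ("replicate" %in% names(points))
    max(table(ph)) else as.integer(max(table(ph)))
  curve <- ph_calibration(slope = unname(cf["ph"]),
                          intercept = unname(cf["(Intercept)"]),
                          valid_ph_range = range(ph),
                          n_replicates = n_rep)
  curve$r_squared <- suppressWarnings(summary(fit)$r.squared)
  curve
}

#' Convert a green-intensity reading to pH
#'
#' Inverts the linear calibration: pH = (G - intercept) / slope. A reading
#' whose implied pH falls more than 0.1 outside the curve's validity range is
#' flagged, not rejected -- monitoring is passive and must never halt a run.
#'
#' @param intensity Green intensity counts (vectorised).
#' @param curve A `ph_calibration`.
#' @return Numeric pH vector with attribute `in_range` (logical vector).
#' @export
intensity_to_ph <- function(intensity, curve = default_ph_calibration()) {
  stopifnot(inherits(curve, "ph_calibration"))
  ph <- (intensity - curve$intercept) / curve$slope
  lo <- curve$valid_ph_range[1] - 0.1
  hi <- curve$valid_ph_range[2] + 0.1
  structure(ph, in_range = ph >= lo & ph <= hi)
}

#' Forward sensor model: pH to green intensity
#'
#' Simulates the optical sensor (LED source + ambient-light detector reading
#' media through translucent tubing): intensity = slope * pH + intercept plus
#' additive Gaussian noise on the counts. Draws from the current R random
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param ph pH values (vectorised).
#' @param curve A `ph_calibration`.
#' @param noise_sd Standard deviation of the additive count noise (>= 0).
#' @param quantize If `TRUE`, round to integer counts and clamp to a 10-bit
#'   ADC range `[0, 1023]`.
#' @return Green intensity counts.
#' @export
ph_to_intensity <- function(ph, curve = default_ph_calibration(),
                            noise_sd = 0, quantize = FALSE) {
  stopifnot(inherits(curve, "ph_calibration"), noise_sd >= 0)
  g <- curve$slope * ph + curve$intercept
  if (noise_sd > 0) g <- g + stats::rnorm(length(g), 0, noise_sd)
  if (quantize) g <- pmin(pmax(round(g), 0), 1023)
  g
}

#' Generate a synthetic calibration point set
#'
#' Convenience generator for calibration experiments: replicate intensity
#' readings from the forward sensor model at the given pH levels.
#'
#' @param ph_levels pH levels to read at.
#' @param n_replicates Replicates per level.
#' @param curve True underlying `ph_calibration`.
#' @param noise_sd Count noise standard deviation.
#' @return Data frame with columns `ph`, `replicate`, `green_intensity`.
#' @export
synth_calibration_points <- function(ph_levels, n_replicates = 3L,
                                     curve = default_ph_calibration(),
                                     noise_sd = 2) {
  ph <- rep(ph_levels, each = n_replicates)
  data.frame(
    ph = ph,
    replicate = rep(seq_len(n_replicates), times = length(ph_levels)),
    green_intensity = ph_to_intensity(ph, curve, noise_sd = noise_sd))
}

ph_log_columns <- c("elapsed_s", "channel", "green_intensity", "ph_estimate", "in_range")

#' Write / read the pH monitoring log
#'
#' The monitoring log is a plain CSV, one row per sensor reading, with columns
#' `elapsed_s, channel, green_intensity, ph_estimate, in_range`. The round
#' trip `read_ph_log(write_ph_log(x, f))` is lossless.
#'
#' @param readings Data frame of readings (see columns above), time-ordered.
#' @param path File path of the CSV.
#' @return `write_ph_log` returns `path` invisibly; `read_ph_log` returns the
#'   readings data frame.
#' @export
write_ph_log <- function(readings, path) {
  stopifnot(is.data.frame(readings))
  if (nrow(readings) == 0L) {
    readings <- as.data.frame(setNames(rep(list(numeric(0)), 5), ph_log_columns))
    readings$channel <- character(0)
    readings$in_range <- logical(0)
  }
  stopifnot(all(ph_log_columns %in% names(readings)))
  if (is.unsorted(readings$elapsed_s)) stop("readings must be time-ordered")
  utils::write.csv(readings[ph_log_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ph_log
#' @export
read_ph_log <- function(path) {
  out <- tryCatch(
    utils::read.csv(path, colClasses = c(elapsed_s = "numeric",
                                         channel = "character",
                                         green_intensity = "numeric",
                                         ph_estimate = "numeric",
                                         in_range = "logical")),
    error = function(e) stop("malformed pH log '", path, "': ", conditionMessage(e)))
  if (!identical(names(out), ph_log_columns))
    stop("malformed pH log '", path, "': expected columns ",
         paste(ph_log_columns, collapse = ","))
  bad <- which(is.na(out$elapsed_s) | is.na(out$green_intensity))
  if (length(bad))
    stop("malformed pH log '", path, "': bad row at data line ", bad[1])
  out
}
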