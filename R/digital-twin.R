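#' Digital twin of the culture wells
#'
#' A deterministic compartment model of one adherent-culture well that stands
#' in for the physical plate so control software can be exercised without
#' hardware. Cells grow logistically with a pH-dependent rate factor,
#' metabolism adds acid equivalents to the media, and pH follows a linear
#' buffer approximation:
#'
#'   dN/dt = r f(pH) N (1 - N/K),   dA/dt = q N,
#'   pH    = fresh_ph - A / (beta * V)
#'
#' where f(pH) = 1 inside `ph_optimum +/- ph_tolerance` and declines linearly
#' to 0 at a deviation of 1.0 pH unit. Media exchange removes well-mixed media
#' (scaling A) and refills with fresh, acid-free media; adherent cells are
#' never removed. Integration is explicit Euler with sub-steps of at most
#' 0.1 h.
#'
#' @name digital-twin
NULL

#' Culture kinetics parameters
#'
#' Defaults describe an L929-like fibroblast monolayer in a 6-well plate and
#' are calibrated so that 2 mL/6 h media refresh holds pH near 7.4 +/- 0.2
#' over 48 h while an unrefreshed well drifts below 7.2 within 72 h. They are
#' qualitative: chosen to reproduce emergent behaviour, not fitted to
#' measured kinetics.
#'
#' @param r_per_h Intrinsic specific growth rate (1/h).
#' @param K_cells Carrying capacity (cells/well).
#' @param q Acid production rate (acid equivalents per cell per hour).
#' @param beta Buffer capacity (acid equivalents per mL per pH unit).
#' @param fresh_ph pH of fresh media (must sit in the phenol red window).
#' @param ph_optimum pH at which growth is unimpaired.
#' @param ph_tolerance Half-width of the no-penalty pH band.
#' @return A `culture_params` object.
#' @export
culture_params <- function(r_per_h = 0.035, K_cells = 1.2e6, q = 6e-7,
                           beta = 3.0, fresh_ph = 7.5,
                           ph_optimum = 7.4, ph_tolerance = 0.2) {
  vals <- c(r_per_h, K_cells, q, beta, fresh_ph, ph_optimum, ph_tolerance)
  stopifnot(is.numeric(vals), all(vals > 0))
  if (fresh_ph < PHENOL_RED_WINDOW[1] || fresh_ph > PHENOL_RED_WINDOW[2])
    stop("fresh_ph must lie within the phenol red window")
  structure(list(r_per_h = r_per_h, K_cells = K_cells, q = q, beta = beta,
                 fresh_ph = fresh_ph, ph_optimum = ph_optimum,
                 ph_tolerance = ph_tolerance),
            class = "culture_params")
}

#' State of one culture well
#'
#' @param cells Cell count (>= 0). Default is the standard 6-well seeding
#'   density of 7e4 cells per well.
#' @param volume_ml Media volume (> 0); 5 mL is the standard working volume.
#' @param acid Accumulated acid load (acid equivalents, >= 0).
#' @return A `well_state` object.
#' @export
well_state <- function(cells = 7e4, volume_ml = 5, acid = 0) {
  stopifnot(cells >= 0, volume_ml >= 0, acid >= 0)
  structure(list(cells = cells, volume_ml = volume_ml, acid = acid),
            class = "well_state")
}

#' @export
print.well_state <- function(x, ...) {
  cat(sprintf("well: %.4g cells, %.3g mL, acid %.4g\n", x$cells, x$volume_ml, x$acid))
  invisible(x)
}

#' Derived pH of a well under the linear buffer approximation
#'
#' @param state A `well_state`.
#' @param params A `culture_params`.
#' @return pH of the well media.
#' @export
well_ph <- function(state, params) {
  if (state$volume_ml == 0) return(params$fresh_ph)  # drained well, no media
  params$fresh_ph - state$acid / (params$beta * state$volume_ml)
}

# growth-rate multiplier: 1 in the tolerance band, linear to 0 at |dpH| = 1
ph_growth_factor <- function(ph, params) {
  d <- abs(ph - params$ph_optimum)
  pmax(0, pmin(1, (1 - d) / (1 - params$ph_tolerance)))
}

#' Advance a well by dt hours
#'
#' Explicit Euler integration of the growth/acidification system, sub-stepped
#' at `max_substep_h` (default 0.1 h) or finer so that `dt` divides evenly.
#'
#' @param state A `well_state`.
#' @param dt_h Time step in hours (> 0).
#' @param params A `culture_params`.
#' @param max_substep_h Upper bound on the Euler sub-step (h).
#' @return Updated `well_state`.
#' @export
advance_well <- function(state, dt_h, params, max_substep_h = 0.1) {
  stopifnot(inherits(state, "well_state"), inherits(params, "culture_params"))
  if (!is.numeric(dt_h) || dt_h <= 0) stop("dt_h must be positive")
  n_sub <- max(1L, ceiling(dt_h / max_substep_h))
  h <- dt_h / n_sub
  N <- state$cells; A <- state$acid; V <- state$volume_ml
  if (V == 0) return(state)  # drained well: no media to grow in or acidify
  for (i in seq_len(n_sub)) {
    ph <- params$fresh_ph - A / (params$beta * V)
    f <- ph_growth_factor(ph, params)
    dN <- params$r_per_h * f * N * (1 - N / params$K_cells)
    dA <- params$q * N
    N <- max(0, N + h * dN)
    A <- A + h * dA
  }
  well_state(cells = N, volume_ml = V, acid = A)
}

#' Partial media exchange on a well
#'
#' Removes `v_out` mL of well-mixed media (acid load scales by the fraction of
#' volume left) and adds `v_in` mL of fresh, acid-free media. Adherent cells
#' stay on the plate and are unaffected.
#'
#' @param state A `well_state`.
#' @param v_out mL removed, in `[0, volume]`.
#' @param v_in mL of fresh media added (>= 0).
#' @param params A `culture_params` (unused by the arithmetic but kept so the
#'   pH invariant is checkable at the call site).
#' @return Updated `well_state`.
#' @export
exchange_media <- function(state, v_out, v_in, params) {
  stopifnot(inherits(state, "well_state"), v_out >= 0, v_in >= 0)
  if (v_out > state$volume_ml + 1e-12)
    stop(sprintf("overdraw: cannot remove %.3g mL from a %.3g mL well",
                 v_out, state$volume_ml))
  V <- state$volume_ml
  A <- state$acid * (V - v_out) / V
  well_state(cells = state$cells, volume_ml = V - v_out + v_in, acid = A)
}

#' Simulate a well under a timed exchange schedule
#'
#' Alternates `advance_well` with `exchange_media` at the scheduled times and
#' samples the state at a resolution of at most 0.1 h, plus exactly at every
#' exchange boundary (state recorded after the exchange).
#'
#' @param exchanges Data frame with columns `time_h`, `v_out_ml`, `v_in_ml`,
#'   sorted by time, all within the horizon. May have zero rows.
#' @param horizon_h Total simulated time (h).
#' @param params A `culture_params`.
#' @param initial Starting `well_state`.
#' @param sample_h Sampling resolution (h), <= 0.1.
#' @return Data frame `elapsed_h, cells, volume_ml, acid_load, ph`.
#' @export
simulate_culture <- function(exchanges = NULL, horizon_h, params = culture_params(),
                             initial = well_state(), sample_h = 0.1) {
  stopifnot(horizon_h > 0, sample_h > 0, sample_h <= 0.1 + 1e-12)
  if (is.null(exchanges) || nrow(exchanges) == 0L) {
    exchanges <- data.frame(time_h = numeric(0), v_out_ml = numeric(0),
                            v_in_ml = numeric(0))
  }
  stopifnot(all(c("time_h", "v_out_ml", "v_in_ml") %in% names(exchanges)))
  if (is.unsorted(exchanges$time_h, strictly = FALSE))
    stop("exchange events must be time-sorted")
  if (any(exchanges$time_h < 0 | exchanges$time_h > horizon_h))
    stop("exchange events must lie within the horizon")

  # round the grid so sampling times collide exactly with event times
  times <- sort(unique(round(c(seq(0, horizon_h, by = sample_h), horizon_h,
                               exchanges$time_h), 9)))
  state <- initial
  rows <- vector("list", length(times))
  ev <- 1L
  for (i in seq_along(times)) {
    t <- times[i]
    if (i > 1L && t > times[i - 1L])
      state <- advance_well(state, t - times[i - 1L], params,
                            max_substep_h = sample_h)
    while (ev <= nrow(exchanges) && abs(exchanges$time_h[ev] - t) < 1e-9) {
      state <- exchange_media(state, exchanges$v_out_ml[ev],
                              exchanges$v_in_ml[ev], params)
      ev <- ev + 1L
    }
    rows[[i]] <- data.frame(elapsed_h = t, cells = state$cells,
                            volume_ml = state$volume_ml, acid_load = state$acid,
                            ph = well_ph(state, params))
  }
  do.call(rbind, rows)
}

#' Build a periodic exchange schedule
#'
#' @param period_h Hours between exchanges; first exchange at `period_h`.
#' @param horizon_h Schedule horizon (exchanges strictly before or at horizon).
#' @param v_ml Volume removed and replaced at each exchange.
#' @return Exchange data frame for [simulate_culture()].
#' @export
periodic_exchanges <- function(period_h, horizon_h, v_ml) {
  t <- seq(period_h, horizon_h, by = period_h)
  data.frame(time_h = t, v_out_ml = rep(v_ml, length(t)),
             v_in_ml = rep(v_ml, length(t)))
}

#' Refit growth and acidification rates from a trajectory
#'
#' Least-squares recovery of (r, q) from a simulated (or logged) trajectory of
#' cell counts and pH, holding the remaining parameters fixed. Residuals are
#' taken on log cell count and on pH so both observables carry comparable
#' weight. Used as a self-consistency check of the twin: a noise-free
#' trajectory must give back its generating values.
#'
#' @param trajectory Data frame from [simulate_culture()] (columns `elapsed_h`,
#'   `cells`, `ph` used).
#' @param params `culture_params` supplying the fixed parameters and the
#'   optimiser's starting point for (r, q).
#' @param initial The known initial `well_state`.
#' @param exchanges The exchange schedule the trajectory was produced under.
#' @return List with elements `r_per_h`, `q`, and `convergence` (0 = success).
#' @export
fit_culture_kinetics <- function(trajectory, params = culture_params(),
                                 initial = well_state(), exchanges = NULL) {
  stopifnot(all(c("elapsed_h", "cells", "ph") %in% names(trajectory)))
  horizon <- max(trajectory$elapsed_h)
  obj <- function(theta) {
    p <- params
    p$r_per_h <- exp(theta[1]); p$q <- exp(theta[2])
    sim <- simulate_culture(exchanges, horizon, p, initial)
    sim <- sim[match(round(trajectory$elapsed_h, 6), round(sim$elapsed_h, 6)), ]
    sum((log(pmax(sim$cells, 1)) - log(pmax(trajectory$cells, 1)))^2) +
      sum((sim$ph - trajectory$ph)^2)
  }
  start <- log(c(params$r_per_h, params$q) * c(1.35, 0.7))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  list(r_per_h = exp(fit$par[1]), q = exp(fit$par[2]),
       convergence = fit$convergence)
}

#' Export / import a twin trajectory as CSV
#'
#' Columns: `elapsed_h, well, cells, volume_ml, acid_load, ph`.
#' @param trajectories Named list of trajectory data frames (one per well) or
#'   a single data frame (well id "W1").
#' @param path CSV path.
#' @export
write_twin_trajectory <- function(trajectories, path) {
  if (is.data.frame(trajectories)) trajectories <- list(W1 = trajectories)
  rows <- lapply(names(trajectories), function(w) {
    df <- trajectories[[w]]
    data.frame(elapsed_h = df$elapsed_h, well = w, cells = df$cells,
               volume_ml = df$volume_ml, acid_load = df$acid_load, ph = df$ph)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
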