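#' Parameters of the synthetic geomagnetic field generator
#'
#' The synthetic field is a planar monotone "pseudo-dipole": every cue
#' interpolates radially from a pole point (F = `F_pole`, I = `I_pole`)
#' down to the grid location farthest from it (`F_equator`, `I_equator`),
#' with H = F cos I. It is not a physical dipole, but preserves exactly the
#' properties the navigation strategies consume: smooth monotone gradients,
#' consistent F/I/H relations, and daily dynamics. Defaults span the
#' field-strength range between magnetic pole (60,000-65,000 nT, dip 90
#' degrees) and low latitudes (23,000-25,000 nT, dip near 0).
#'
#' Daily dynamics: day k (0-based) adds `daily_drift * k` plus zero-mean
#' storm noise with sd `storm_amplitude` (truncated at 3 sd) to F;
#' inclination receives the proportionally scaled perturbation and H is
#' re-derived, so every stack satisfies H = F cos I exactly.
#'
#' @param geometry a [grid_geometry()].
#' @param pole_xy planar coordinates (m) of the simulated pole (defaults to
#'   the centre of the grid's top-right cell).
#' @param F_pole,F_equator intensity extremes, nT (63000, 24000).
#' @param I_pole,I_equator inclination extremes, degrees (90, 10).
#' @param daily_drift secular + daily model change, nT/day (default 10,
#'   the order of the global mean change of F per km of travel).
#' @param storm_amplitude sd of the daily disturbance field, nT (default
#'   30, typical quiet-to-moderate mid-latitude daily variation).
#' @param seed RNG seed for the storm noise.
#' @return an object of class `synth_field_params`.
#' @export
synth_field_params <- function(geometry, pole_xy = NULL, F_pole = 63000,
                               F_equator = 24000, I_pole = 90,
                               I_equator = 10, daily_drift = 10,
                               storm_amplitude = 30, seed = 1) {
  stopifnot(F_pole > F_equator, F_equator > 0,
            I_pole > I_equator, I_pole <= 90, I_equator >= 0)
  if (is.null(pole_xy))
    pole_xy <- c(geometry$origin_x + (geometry$n_cols - 1) *
                   geometry$cell_size,
                 geometry$origin_y)
  structure(list(geometry = geometry, pole_xy = as.numeric(pole_xy),
                 F_pole = F_pole, F_equator = F_equator,
                 I_pole = I_pole, I_equator = I_equator,
                 daily_drift = daily_drift,
                 storm_amplitude = storm_amplitude,
                 seed = as.integer(seed)),
            class = "synth_field_params")
}

#' Generate synthetic daily field stacks
#'
#' @param p a [synth_field_params()].
#' @param dates vector of `Date`s (or ISO strings); day 0 of the drift law
#'   is the first date.
#' @return list of `field_stack`s, one per date, in date order.
#' @export
synth_field_stack <- function(p, dates) {
  dates <- as.Date(dates)
  g <- p$geometry
  xs <- matrix(col_x(g), g$n_rows, g$n_cols, byrow = TRUE)
  ys <- matrix(row_y(g), g$n_rows, g$n_cols)
  d <- sqrt((xs - p$pole_xy[1])^2 + (ys - p$pole_xy[2])^2)
  frac <- d / max(d)
  F0 <- p$F_pole - (p$F_pole - p$F_equator) * frac
  I0 <- p$I_pole - (p$I_pole - p$I_equator) * frac
  rI <- (p$I_pole - p$I_equator) / (p$F_pole - p$F_equator)  # deg per nT
  lapply(seq_along(dates), function(k) {
    day <- as.numeric(dates[k] - dates[1])
    noise <- 0
    if (p$storm_amplitude > 0) {
      set.seed((p$seed + hash31(c("storm", format(dates[k])))) %%
                 2147483647L)
      noise <- matrix(stats::rnorm(length(F0), 0, p$storm_amplitude),
                      nrow(F0), ncol(F0))
      noise <- pmin(pmax(noise, -3 * p$storm_amplitude),
                    3 * p$storm_amplitude)
    }
    Fv <- pmax(F0 + p$daily_drift * day + noise, 0)
    Iv <- pmin(pmax(I0 + (p$daily_drift * day + noise) * rI, 0), 90)
    field_stack(field_grid("F", dates[k], g, Fv),
                field_grid("I", dates[k], g, Iv))
  })
}

#' Parameters of the synthetic migration-track generator
#'
#' Emulates autumn goose migrations: each animal flies a corridor from near
#' the synthetic pole towards low field values, at hourly fixes, completing
#' well over the 1500 km length-filter threshold within at most 3 days.
#'
#' @param n_animals number of migrations (default 14).
#' @param duration flight hours (<= 72; default 72).
#' @param mean_speed km/h (default 30; combined with `duration` must give
#'   more than 1500 km for a usable fixture).
#' @param corridor_heading radians, mathematical convention; `NULL`
#'   (default) means "from the pole towards the farthest grid corner",
#'   i.e. down the field gradient.
#' @param heading_noise_sd sd (rad) of the per-fix heading noise (default
#'   0.25).
#' @param speed_cv coefficient of variation of the per-step speed
#'   (default 0.15).
#' @param generating_strategy `NULL` for corridor mode, or a
#'   `strategy_spec`: tracks are then produced by [simulate_crw()] under
#'   that strategy at bias weight `bias_beta` with a corridor-estimated
#'   reference kernel.
#' @param bias_beta bias exponent for strategy mode (default 5).
#' @param start_date first fix date (default "2016-09-19").
#' @param seed RNG seed.
#' @return an object of class `synth_track_params`.
#' @export
synth_track_params <- function(n_animals = 14, duration = 72,
                               mean_speed = 30, corridor_heading = NULL,
                               heading_noise_sd = 0.25, speed_cv = 0.15,
                               generating_strategy = NULL, bias_beta = 5,
                               start_date = "2016-09-19", seed = 1) {
  stopifnot(duration <= 72, duration >= 2, n_animals >= 1, mean_speed > 0)
  if (duration * mean_speed <= 1500)
    warning("duration x mean_speed <= 1500 km: tracks will fail the ",
            "length filter")
  structure(list(n_animals = as.integer(n_animals),
                 duration = as.integer(duration), mean_speed = mean_speed,
                 corridor_heading = corridor_heading,
                 heading_noise_sd = heading_noise_sd, speed_cv = speed_cv,
                 generating_strategy = generating_strategy,
                 bias_beta = bias_beta,
                 start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "synth_track_params")
}

# deterministic start positions: staggered around the point 15% of the way
# from the pole towards the farthest corner, jittered by up to one cell
#' @keywords internal
synth_starts <- function(p, fields) {
  g <- fields[[1]]$geometry
  pole <- attr(fields, "pole_xy")
  b <- grid_bounds(g)
  corners <- rbind(c(b$xmin + g$cell_size / 2, b$ymin + g$cell_size / 2),
                   c(b$xmin + g$cell_size / 2, b$ymax - g$cell_size / 2),
                   c(b$xmax - g$cell_size / 2, b$ymin + g$cell_size / 2),
                   c(b$xmax - g$cell_size / 2, b$ymax - g$cell_size / 2))
  far <- corners[which.max(edist(pole[1], pole[2], corners[, 1],
                                 corners[, 2])), ]
  u <- (far - pole) / sqrt(sum((far - pole)^2))
  base <- pole + 0.15 * (far - pole)
  head <- p$corridor_heading %||% atan2(u[2], u[1])
  list(base = base, heading = head, unit = u)
}

#' Generate synthetic migration trajectories
#'
#' Corridor mode (default): hourly fixes along the corridor heading at the
#' mean speed, with seeded per-fix heading noise and speed variation.
#' Strategy mode: delegates to [simulate_crw()] under
#' `p$generating_strategy` at bias weight `p$bias_beta`, using a reference
#' movement kernel estimated from corridor tracks of the same parameters,
#' then adds small positional jitter. Generated tracks are verified to pass
#' the migratory length filter (regenerated on a fresh substream if not,
#' bounded retries).
#'
#' @param p a [synth_track_params()].
#' @param fields list of `field_stack`s (as from [synth_field_stack()]);
#'   must carry attribute `pole_xy` or default to the top-right origin
#'   corner convention of [synth_field_params()].
#' @return named list of hourly `trajectory` objects.
#' @export
synth_tracks <- function(p, fields) {
  if (is.null(attr(fields, "pole_xy")))
    attr(fields, "pole_xy") <- c(
      fields[[1]]$geometry$origin_x +
        (fields[[1]]$geometry$n_cols - 1) * fields[[1]]$geometry$cell_size,
      fields[[1]]$geometry$origin_y)
  if (is.null(p$generating_strategy)) return(corridor_tracks(p, fields))
  strategy_tracks(p, fields)
}

#' @keywords internal
corridor_tracks <- function(p, fields) {
  st <- synth_starts(p, fields)
  g <- fields[[1]]$geometry
  t0 <- as.POSIXct(paste(format(p$start_date), "00:00:00"), tz = "UTC")
  ids <- sprintf("animal_%02d", seq_len(p$n_animals))
  out <- list()
  for (a in seq_len(p$n_animals)) {
    for (try in 1:10) {
      set.seed((p$seed + hash31(c("corridor", ids[a], try))) %% 2147483647L)
      start <- st$base + stats::runif(2, -g$cell_size, g$cell_size) +
        (a - 1) %% 4 * 0.2 * g$cell_size * c(-st$unit[2], st$unit[1])
      L <- p$mean_speed * 1000 *
        pmax(stats::rnorm(p$duration, 1, p$speed_cv), 0.2)
      h <- st$heading + stats::rnorm(p$duration, 0, p$heading_noise_sd)
      x <- cumsum(c(start[1], L * cos(h)))
      y <- cumsum(c(start[2], L * sin(h)))
      b <- grid_bounds(g)
      x <- pmin(pmax(x, b$xmin), b$xmax)   # clip to grid bounds
      y <- pmin(pmax(y, b$ymin), b$ymax)
      tr <- trajectory(ids[a], t0 + 3600 * (0:p$duration), x, y)
      if (length_filter(tr)) break
    }
    if (!length_filter(tr))
      stop("failed to generate a track longer than 1500 km for ", ids[a])
    out[[ids[a]]] <- tr
  }
  out
}

#' @keywords internal
strategy_tracks <- function(p, fields) {
  # reference kernel from corridor tracks of the same parameters
  pc <- p; pc$generating_strategy <- NULL
  ref <- corridor_tracks(pc, fields)
  kernel <- estimate_kernel(lapply(ref, to_steps))
  g <- fields[[1]]$geometry
  t0 <- as.POSIXct(paste(format(p$start_date), "00:00:00"), tz = "UTC")
  out <- list()
  for (a in seq_along(ref)) {
    id <- names(ref)[a]
    base <- ref[[a]]
    start <- c(base$x[1], base$y[1])
    target <- c(base$x[n_fixes(base)], base$y[n_fixes(base)])
    ti <- list(animal_id = id, target_xy = target,
               target_values = target_cue_values(fields, target))
    cfg <- simulation_config("CRW", n_steps = p$duration, start_xy = start,
                             target_xy = target, beta = p$bias_beta,
                             n_replicates = 1, seed = p$seed)
    for (try in 1:10) {
      set.seed((p$seed + hash31(c("strategy", id, try))) %% 2147483647L)
      sim <- simulate_crw(kernel, p$generating_strategy, fields, cfg, ti)
      x <- sim$x + stats::rnorm(length(sim$x), 0, g$cell_size / 10)
      y <- sim$y + stats::rnorm(length(sim$y), 0, g$cell_size / 10)
      b <- grid_bounds(g)
      x <- pmin(pmax(x, b$xmin), b$xmax)
      y <- pmin(pmax(y, b$ymin), b$ymax)
      tr <- trajectory(id, t0 + 3600 * (0:p$duration), x, y)
      if (length_filter(tr)) break
    }
    out[[id]] <- tr
  }
  out
}

#' Cue values at a target point on the final day
#'
#' @param fields list of `field_stack`s.
#' @param target_xy planar coordinates (m).
#' @return named numeric vector with entries `F`, `I`, `H`.
#' @export
target_cue_values <- function(fields, target_xy) {
  last <- fields[[length(fields)]]
  c(F = value_at(last$F, target_xy[1], target_xy[2]),
    I = value_at(last$I, target_xy[1], target_xy[2]),
    H = value_at(last$H, target_xy[1], target_xy[2]))
}

#' Assemble animals for a simulation batch
#'
#' @param tracks named list of hourly `trajectory` objects.
#' @param fields list of `field_stack`s.
#' @return list of entries `list(trajectory, target_info)` as consumed by
#'   [run_batch()].
#' @export
make_animals <- function(tracks, fields) {
  lapply(tracks, function(tr) {
    n <- n_fixes(tr)
    target <- c(tr$x[n], tr$y[n])
    list(trajectory = tr,
         target_info = list(animal_id = tr$animal_id, target_xy = target,
                            target_values = target_cue_values(fields,
                                                              target)))
  })
}

#' Named, seeded, reproducible fixture bundles
#'
#' Three standard scenarios used throughout the test-suite and examples:
#'
#' * `"smoke"`: 3 animals, 24 hourly steps, 60 x 60 grid of 30 km cells -
#'   the smallest end-to-end configuration.
#' * `"paper-scale"`: 14 animals, 72 hourly steps, 100 x 100 grid of 25 km
#'   cells - the full experiment's animal count and flight duration.
#' * `"recovery-taxis"`: 6 animals, 48 hourly steps, 70 x 70 grid of 30 km
#'   cells, with tracks generated under taxis-on-F at bias weight 5 - used
#'   for parameter-recovery checks.
#'
#' @param name scenario name.
#' @param seed integer seed (default 1).
#' @return list with `fields` (field stacks per day), `tracks` (hourly
#'   trajectories), `animals` (input for [run_batch()]), `kernel`
#'   (movement kernel estimated from the bundled tracks), `geometry`.
#' @export
fixture_scenario <- function(name = c("smoke", "paper-scale",
                                      "recovery-taxis"), seed = 1) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  conf <- switch(name,
    "smoke" = list(nr = 60, cell = 30000, n_animals = 3, duration = 24,
                   speed = 65, strategy = NULL),
    "paper-scale" = list(nr = 100, cell = 25000, n_animals = 14,
                         duration = 72, speed = 30, strategy = NULL),
    "recovery-taxis" = list(nr = 70, cell = 30000, n_animals = 6,
                            duration = 48, speed = 40,
                            strategy = strategy_spec("TAXIS", "F")))
  g <- grid_geometry(origin_x = 0, origin_y = (conf$nr - 1) * conf$cell,
                     cell_size = conf$cell, n_rows = conf$nr,
                     n_cols = conf$nr, crs_label = "synthetic planar")
  fp <- synth_field_params(g, seed = seed)
  n_days <- ceiling(conf$duration / 24) + 1
  dates <- as.Date("2016-09-19") + 0:(n_days - 1)
  fields <- synth_field_stack(fp, dates)
  attr(fields, "pole_xy") <- fp$pole_xy
  tp <- synth_track_params(n_animals = conf$n_animals,
                           duration = conf$duration,
                           mean_speed = conf$speed,
                           generating_strategy = conf$strategy,
                           seed = seed)
  tracks <- synth_tracks(tp, fields)
  kernel <- estimate_kernel(lapply(tracks, to_steps))
  list(fields = fields, tracks = tracks,
       animals = make_animals(tracks, fields), kernel = kernel,
       geometry = g, field_params = fp, track_params = tp)
}

#' Steepest-descent reference path down a cue gradient
#'
#' Deterministic reference trajectory for calibration experiments: from the
#' start, each step moves `step_m` metres in the direction of steepest
#' descent of the cue (estimated by central differences at a tenth of the
#' cell size), clamped to the grid bounds. A strongly taxis-weighted walk
#' should concentrate around this path.
#'
#' @param grid a `field_grid`.
#' @param start_xy planar coordinates (m).
#' @param n_steps number of steps.
#' @param step_m step length (m), e.g. the kernel's mean step.
#' @return `(n_steps + 1) x 2` matrix of positions.
#' @export
gradient_descent_path <- function(grid, start_xy, n_steps, step_m) {
  g <- grid$geometry
  b <- grid_bounds(g)
  h <- g$cell_size / 10
  cx <- function(x) pmin(pmax(x, b$xmin), b$xmax)
  cy <- function(y) pmin(pmax(y, b$ymin), b$ymax)
  out <- matrix(NA_real_, n_steps + 1, 2)
  out[1, ] <- start_xy
  for (s in seq_len(n_steps)) {
    x <- out[s, 1]; y <- out[s, 2]
    gx <- (value_at(grid, cx(x + h), y) - value_at(grid, cx(x - h), y)) /
      (cx(x + h) - cx(x - h))
    gy <- (value_at(grid, x, cy(y + h)) - value_at(grid, x, cy(y - h))) /
      (cy(y + h) - cy(y - h))
    nv <- sqrt(gx^2 + gy^2)
    dir <- if (nv > 0) -c(gx, gy) / nv else c(0, 0)
    out[s + 1, 1] <- cx(x + step_m * dir[1])
    out[s + 1, 2] <- cy(y + step_m * dir[2])
  }
  out
}
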