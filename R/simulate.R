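#' Configure a simulation run
#'
#' @param mode `"CRW"` (free endpoint) or `"CRB"` (bridge: start and end
#'   fixed in space).
#' @param n_steps number of hourly steps; matched to the paired empirical
#'   trajectory's step count by [run_batch()].
#' @param start_xy,target_xy planar coordinates (m), `c(x, y)`.
#' @param alpha exponent on the movement probability surface (default 0.5:
#'   the square root of the movement raster is multiplied by the bias
#'   raster, putting the higher weight on the navigational bias).
#' @param beta exponent on the strategy bias surface (default 1).
#' @param heading_error half-width (rad) of the uniform error on the initial
#'   optimum heading (default pi/12).
#' @param steps_per_day steps per simulated calendar day (default 24;
#'   constant-heading calibration is refreshed at the first step of each
#'   day).
#' @param n_replicates replicates per model per animal (default 100).
#' @param seed base RNG seed for the batch.
#' @param jitter `"uniform"` (position drawn uniformly within the sampled
#'   cell) or `"centre"` (cell centre, for exact reproducibility checks).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(mode = c("CRW", "CRB"), n_steps, start_xy,
                              target_xy, alpha = 0.5, beta = 1,
                              heading_error = pi / 12, steps_per_day = 24,
                              n_replicates = 100, seed = 1,
                              jitter = c("uniform", "centre")) {
  mode <- match.arg(mode)
  jitter <- match.arg(jitter)
  stopifnot(n_steps >= 2, alpha >= 0, beta >= 0,
            heading_error >= 0, heading_error <= pi,
            steps_per_day >= 1, n_replicates >= 1)
  structure(list(mode = mode, n_steps = as.integer(n_steps),
                 start_xy = as.numeric(start_xy),
                 target_xy = as.numeric(target_xy),
                 alpha = alpha, beta = beta,
                 heading_error = heading_error,
                 steps_per_day = as.integer(steps_per_day),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), jitter = jitter),
            class = "simulation_config")
}

#' Movement probability surface around the current position
#'
#' Full-raster view of the movement kernel at one step: each cell within
#' `L_max` of the current position gets a value proportional to the kernel
#' density of the (step length, turning angle) reaching its centre, rescaled
#' to a maximum of 1; all other cells are 0.
#'
#' @param kernel a `movement_kernel`.
#' @param current_xy planar coordinates (m).
#' @param prev_heading previous heading (rad, mathematical convention).
#' @param prev_L,prev_phi previous step length (m) and turning angle (rad).
#' @param geometry a `grid_geometry`.
#' @return a `prob_surface` (zero outside the reachable window).
#' @export
movement_surface <- function(kernel, current_xy, prev_heading, prev_L,
                             prev_phi, geometry) {
  w <- reach_window(geometry, current_xy, kernel$L_max)
  if (length(w$r) == 0)
    stop("current position is outside the grid: no reachable cells")
  dens <- window_movement_density(kernel, w, current_xy, prev_heading,
                                  prev_L, prev_phi)
  m <- matrix(0, geometry$n_rows, geometry$n_cols)
  if (max(dens) > 0) dens <- dens / max(dens)
  m[cbind(w$r, w$c)] <- dens
  if (max(m) <= 0)
    m[cbind(w$r, w$c)] <- 1 / length(w$r)   # degenerate kernel support
  new_prob_surface(geometry, m)
}

# cells whose centres lie within `radius` of (x, y), clipped to the grid
#' @keywords internal
reach_window <- function(g, xy, radius) {
  rc <- round((g$origin_y - xy[2]) / g$cell_size) + 1
  cc <- round((xy[1] - g$origin_x) / g$cell_size) + 1
  R <- ceiling(radius / g$cell_size)
  rows <- max(1, rc - R):min(g$n_rows, rc + R)
  cols <- max(1, cc - R):min(g$n_cols, cc + R)
  if (rc + R < 1 || rc - R > g$n_rows || cc + R < 1 || cc - R > g$n_cols)
    return(list(r = integer(0), c = integer(0),
                x = numeric(0), y = numeric(0), d = numeric(0)))
  r <- rep(rows, times = length(cols))
  c_ <- rep(cols, each = length(rows))
  x <- g$origin_x + (c_ - 1) * g$cell_size
  y <- g$origin_y - (r - 1) * g$cell_size
  d <- sqrt((x - xy[1])^2 + (y - xy[2])^2)
  keep <- d <= radius & d > 1e-9
  list(r = r[keep], c = c_[keep], x = x[keep], y = y[keep], d = d[keep])
}

#' @keywords internal
window_movement_density <- function(kernel, w, xy, prev_heading, prev_L,
                                    prev_phi) {
  phi <- wrap_angle(atan2(w$y - xy[2], w$x - xy[1]) - prev_heading)
  step_density(kernel, w$d, phi, prev_L, prev_phi)
}

#' Combine movement and bias surfaces into a sampling distribution
#'
#' `movement^alpha * bias^beta` cellwise, normalised to sum 1 over the
#' movement window. The defaults (0.5, 1) take the square root of the
#' movement raster times the bias raster, weighting the navigational signal
#' above the movement persistence. If the combined surface is zero
#' everywhere, the normalised movement surface alone is returned with
#' attribute `fallback = TRUE`.
#'
#' @param movement,bias `prob_surface`s on the same geometry.
#' @param alpha,beta non-negative exponents.
#' @return a `prob_surface` whose values sum to 1.
#' @export
combine_surfaces <- function(movement, bias, alpha = 0.5, beta = 1) {
  if (!same_geometry(movement$geometry, bias$geometry))
    stop("movement and bias surfaces have mismatched geometry")
  m <- movement$values^alpha * bias$values^beta
  m[movement$values == 0] <- 0   # bias is cropped to the movement window
  fallback <- FALSE
  if (sum(m) == 0) {
    m <- movement$values
    fallback <- TRUE
    if (sum(m) == 0) stop("movement surface is zero everywhere")
  }
  out <- new_prob_surface(movement$geometry, m / sum(m))
  attr(out, "fallback") <- fallback
  out
}

#' Draw the initial heading for a replicate
#'
#' The navigation-specific optimum heading is the bearing from the start to
#' the highest-valued bias cell within `L_ref` of the start (ties broken by
#' nearest, then row-major order). When the bias carries no directional
#' information in range (all reachable cells equal, as for the no-bias
#' control), the optimum falls back to the bearing to the target. The
#' returned heading adds a uniform error on
#' `[-heading_error, +heading_error]`.
#'
#' Uses the R session RNG.
#'
#' @param bias a `prob_surface`.
#' @param start_xy planar coordinates (m).
#' @param L_ref search radius (m), typically the kernel's `L_max`.
#' @param heading_error half-width of the uniform heading error (rad).
#' @param target_xy fallback bearing target.
#' @return heading in radians, `(-pi, pi]`.
#' @export
initial_heading <- function(bias, start_xy, L_ref, heading_error,
                            target_xy) {
  w <- reach_window(bias$geometry, start_xy, L_ref)
  optimum <- NULL
  if (length(w$r)) {
    b <- bias$values[cbind(w$r, w$c)]
    if (max(b) > min(b) && max(b) > 0) {
      best <- which(b == max(b))
      best <- best[order(w$d[best], w$r[best], w$c[best])][1]
      optimum <- atan2(w$y[best] - start_xy[2], w$x[best] - start_xy[1])
    }
  }
  if (is.null(optimum))
    optimum <- atan2(target_xy[2] - start_xy[2], target_xy[1] - start_xy[1])
  err <- if (heading_error > 0)
    stats::runif(1, -heading_error, heading_error) else 0
  wrap_angle(optimum + err)
}

#' Target-pull surface for the correlated random bridge
#'
#' Weights each cell by the feasibility of reaching the target from it in
#' the remaining steps: with `k = steps_remaining > 1` the weight is the
#' normal density of the required per-step displacement
#' `d(cell, target) / (k - 1)` under the kernel's step-length mean and a
#' standard error shrinking as `1 / sqrt(k - 1)`; cells farther than
#' `(k - 1) * L_max` from the target get 0. At `k = 1` all mass sits on the
#' target cell.
#'
#' @param kernel a `movement_kernel`.
#' @param target_xy planar coordinates (m).
#' @param steps_remaining steps left including the current one (>= 1).
#' @param geometry a `grid_geometry`.
#' @return a `prob_surface` rescaled to a maximum of 1.
#' @export
crb_pull_surface <- function(kernel, target_xy, steps_remaining, geometry) {
  stopifnot(steps_remaining >= 1)
  g <- geometry
  xs <- matrix(col_x(g), g$n_rows, g$n_cols, byrow = TRUE)
  ys <- matrix(row_y(g), g$n_rows, g$n_cols)
  d <- sqrt((xs - target_xy[1])^2 + (ys - target_xy[2])^2)
  if (steps_remaining == 1) {
    m <- matrix(0, g$n_rows, g$n_cols)
    rc <- round((g$origin_y - target_xy[2]) / g$cell_size) + 1
    cc <- round((target_xy[1] - g$origin_x) / g$cell_size) + 1
    if (rc < 1 || rc > g$n_rows || cc < 1 || cc > g$n_cols)
      stop("target lies outside the grid")
    m[rc, cc] <- 1
    return(new_prob_surface(g, m))
  }
  w <- crb_pull_weights(kernel, d, steps_remaining, g$cell_size)
  if (max(w) == 0)
    stop("no feasible cell: n_steps too small for the start-target distance")
  new_prob_surface(g, w / max(w))
}

# Sustainable bridge pace: a correlated walk cannot convert every future
# step into net displacement (turning inertia), and within-cell jitter can
# cost up to half a cell of progress per step, so the prism shrinks at
# min(L_max - cell/2, mu + 0.5 sd) per remaining step rather than at L_max.
#' @keywords internal
crb_pace <- function(kernel, cell_size) {
  max(min(kernel$L_max - cell_size / 2,
          kernel$mu_L + 0.5 * kernel$sd_L), 1e-3)
}

# Normal pace penalty on the required per-step displacement, with the cut
# at the sustainable pace (inside the hard (k - 1) L_max feasibility
# bound): it keeps the endpoint reachable under turning inertia and
# within-cell jitter, and keeps the walkers' time profiles comparable
# across strategies.
#' @keywords internal
crb_pull_weights <- function(kernel, d, k, cell_size = 0) {
  sd_k <- max(kernel$sd_L, 1e-6) / sqrt(k - 1)
  w <- stats::dnorm(d / (k - 1), mean = kernel$mu_L, sd = sd_k)
  w[d > (k - 1) * crb_pace(kernel, cell_size)] <- 0
  w
}

# ---- per-day bias caches ---------------------------------------------------

# Everything about a (strategy, animal, day) that does not depend on the
# walker's position is computed once per day: full bias matrices for the
# position-independent strategies, the gradient-map component and the
# heading-cue extreme for the position-dependent ones.
#' @keywords internal
build_day_cache <- function(spec, stack, target_info) {
  out <- list(mat = NULL, grad = NULL, ext_xy = NULL)
  if (spec$strategy %in% c("NO_BIAS", "TAXIS", "BIGRADIENT")) {
    out$mat <- strategy_surface(spec, stack, current_xy = NULL,
                                target_xy = NULL,
                                target_info = target_info)$values
  } else if (spec$strategy == "CONSTANT_HEADING") {
    ext <- extremum_location(stack[[spec$cues[1]]], spec$extreme)
    out$ext_xy <- c(ext$x, ext$y)
  } else {   # COMBINATION: gradient map on cue 1, heading on cue 2
    out$grad <- gradient_surface_values(stack[[spec$cues[1]]],
                                        target_info$target_values)
    ext <- extremum_location(stack[[spec$cues[2]]], "min")
    out$ext_xy <- c(ext$x, ext$y)
  }
  out
}

# theta* from a cached extreme (engine-internal version of
# constant_heading_calibration)
#' @keywords internal
theta_star_at <- function(current_xy, target_xy, ext_xy, cell_size) {
  d <- sqrt(sum((target_xy - current_xy)^2))
  if (d == 0) return(0)
  n_samp <- max(2, ceiling(d / cell_size))
  frac <- seq_len(n_samp) / n_samp
  px <- current_xy[1] + frac * (target_xy[1] - current_xy[1])
  py <- current_xy[2] + frac * (target_xy[2] - current_xy[2])
  mean(vertex_angle_deg(current_xy, ext_xy, px, py))
}

# bias values at window cells
#' @keywords internal
window_bias <- function(spec, cache, w, current_xy, theta_star) {
  if (!is.null(cache$mat)) return(cache$mat[cbind(w$r, w$c)])
  ang <- vertex_angle_deg(current_xy, cache$ext_xy, w$x, w$y)
  ch <- constant_heading_prob(ang, theta_star)
  ch[ch < 0] <- 0
  if (!is.null(cache$grad)) ch * cache$grad[cbind(w$r, w$c)] else ch
}

# ---- single-replicate engine ----------------------------------------------

#' @keywords internal
sim_one <- function(kernel, spec, fields, cfg, target_info, day_caches,
                    replicate_id = 1L) {
  g <- fields[[1]]$geometry
  cs <- g$cell_size
  n <- cfg$n_steps
  n_days <- length(fields)
  crb <- cfg$mode == "CRB"
  if (crb) {
    d0 <- sqrt(sum((cfg$target_xy - cfg$start_xy)^2))
    if (n * kernel$L_max < d0)
      stop("infeasible bridge: ", n, " steps of at most ", kernel$L_max,
           " m cannot cover ", round(d0), " m")
  }

  xs <- numeric(n + 1); ys <- numeric(n + 1)
  Ls <- numeric(n); phis <- numeric(n)
  xs[1] <- cfg$start_xy[1]; ys[1] <- cfg$start_xy[2]
  n_fallback <- 0L

  # initial heading from the day-1 bias field around the start
  w0 <- reach_window(g, cfg$start_xy, kernel$L_max)
  theta0 <- if (is.null(day_caches[[1]]$ext_xy)) 0 else
    theta_star_at(cfg$start_xy, cfg$target_xy, day_caches[[1]]$ext_xy, cs)
  optimum <- NULL
  if (length(w0$r)) {
    b0 <- window_bias(spec, day_caches[[1]], w0, cfg$start_xy, theta0)
    if (length(b0) && max(b0) > min(b0) && max(b0) > 0) {
      best <- which(b0 == max(b0))
      best <- best[order(w0$d[best], w0$r[best], w0$c[best])][1]
      optimum <- atan2(w0$y[best] - cfg$start_xy[2],
                       w0$x[best] - cfg$start_xy[1])
    }
  }
  if (is.null(optimum))
    optimum <- atan2(cfg$target_xy[2] - cfg$start_xy[2],
                     cfg$target_xy[1] - cfg$start_xy[1])
  err <- if (cfg$heading_error > 0)
    stats::runif(1, -cfg$heading_error, cfg$heading_error) else 0
  prev_heading <- wrap_angle(optimum + err)
  prev_L <- kernel$mu_L
  prev_phi <- 0
  theta_day <- NA_real_
  cur_day <- 0L

  for (s in seq_len(n)) {
    day <- min((s - 1L) %/% cfg$steps_per_day + 1L, n_days)
    cache <- day_caches[[day]]
    pos <- c(xs[s], ys[s])
    k <- n - s + 1L   # steps remaining including this one

    if (crb && k == 1L) {
      # bridge endpoint: final position is the target, exactly
      xs[s + 1] <- cfg$target_xy[1]; ys[s + 1] <- cfg$target_xy[2]
      dx <- xs[s + 1] - xs[s]; dy <- ys[s + 1] - ys[s]
      Ls[s] <- sqrt(dx^2 + dy^2)
      if (Ls[s] > kernel$L_max)
        stop(structure(class = c("magnav_bridge_miss", "error",
                                 "condition"),
                       list(message = sprintf(
                         "bridge missed: final hop %.0f m exceeds L_max %.0f m",
                         Ls[s], kernel$L_max), call = NULL)))
      h <- if (Ls[s] > 0) atan2(dy, dx) else prev_heading
      phis[s] <- wrap_angle(h - prev_heading)
      break
    }

    # daily recalibration of the constant-heading reference angle
    if (!is.null(cache$ext_xy) && (day != cur_day || s == 1L)) {
      theta_day <- theta_star_at(pos, cfg$target_xy, cache$ext_xy, cs)
      cur_day <- day
    }

    w <- reach_window(g, pos, kernel$L_max)
    if (length(w$r) == 0)
      stop("walker has no reachable cells (outside grid?) at step ", s)

    mov <- window_movement_density(kernel, w, pos, prev_heading, prev_L,
                                   prev_phi)
    bias <- window_bias(spec, cache, w, pos, theta_day)
    wt <- mov^cfg$alpha * bias^cfg$beta
    if (sum(wt) == 0) {           # disjoint supports: movement alone,
      wt <- mov                   # then bias alone, then uniform
      n_fallback <- n_fallback + 1L
      if (sum(wt) == 0) wt <- bias^cfg$beta
      if (sum(wt) == 0) wt <- rep(1, length(w$r))
    }
    if (crb) {
      dt <- edist(cfg$target_xy[1], cfg$target_xy[2], w$x, w$y)
      pull <- crb_pull_weights(kernel, dt, k, cs)
      # small floor on the movement-and-bias weight: the endpoint is a hard
      # constraint, so when every kernel-supported cell is badly off pace
      # the pull may override the kernel preference
      wtp <- (wt + 1e-6 * max(wt)) * pull
      d_now <- edist(cfg$target_xy[1], cfg$target_xy[2], pos[1], pos[2])
      if (d_now > (k - 1) * kernel$mu_L)   # lagging: never lose ground
        wtp[dt >= d_now] <- 0
      if (sum(wtp) == 0) {
        # no feasible cell in reach: greedy step towards the target
        wtp <- as.numeric(seq_along(dt) == which.min(dt))
        n_fallback <- n_fallback + 1L
      }
      wt <- wtp
    }
    pick <- if (length(wt) == 1L) 1L else
      sample.int(length(wt), 1L, prob = wt)
    nx <- w$x[pick]; ny <- w$y[pick]
    if (cfg$jitter == "uniform") {
      nx <- nx + stats::runif(1, -cs / 2, cs / 2)
      ny <- ny + stats::runif(1, -cs / 2, cs / 2)
    }
    if (crb &&
        edist(cfg$target_xy[1], cfg$target_xy[2], nx, ny) >
          (k - 1) * crb_pace(kernel, cs)) {
      # jitter must not push the position out of the shrinking prism
      nx <- w$x[pick]; ny <- w$y[pick]
    }
    dx <- nx - pos[1]; dy <- ny - pos[2]
    L <- sqrt(dx^2 + dy^2)
    if (L > kernel$L_max) {       # radial clamp: jitter may not extend reach
      f <- kernel$L_max / L
      nx <- pos[1] + dx * f; ny <- pos[2] + dy * f
      dx <- nx - pos[1]; dy <- ny - pos[2]
      L <- kernel$L_max
    }
    xs[s + 1] <- nx; ys[s + 1] <- ny
    h <- if (L > 0) atan2(dy, dx) else prev_heading
    Ls[s] <- L
    phis[s] <- wrap_angle(h - prev_heading)
    prev_phi <- phis[s]
    prev_L <- L
    prev_heading <- h
  }

  structure(list(animal_id = target_info$animal_id %||% "sim",
                 label = spec$label, replicate = as.integer(replicate_id),
                 x = xs, y = ys, step_lengths = Ls, turning_angles = phis,
                 mode = cfg$mode, n_fallback = n_fallback),
            class = "sim_track")
}

#' @export
print.sim_track <- function(x, ...) {
  cat(sprintf("<sim_track %s %s #%d: %d steps (%s)>\n", x$animal_id,
              x$label, x$replicate, length(x$step_lengths), x$mode))
}

#' Simulate one correlated random walk replicate
#'
#' Runs a biased correlated random walk: at each hourly step the strategy
#' bias surface is rebuilt from the current day's geomagnetic grids and the
#' current position, combined with the movement surface as
#' `movement^alpha * bias^beta`, and the next cell is sampled from the
#' result (position jittered uniformly within the cell). There is no
#' endpoint constraint; the target enters only through the bias (and the
#' initial-heading fallback).
#'
#' Uses the R session RNG; call `set.seed()` for reproducibility.
#'
#' @param kernel a `movement_kernel`.
#' @param spec a `strategy_spec`.
#' @param fields list of `field_stack`s, one per simulated day from
#'   departure (recycled by clamping if the walk outlasts them).
#' @param cfg a `simulation_config` with `mode = "CRW"`.
#' @param target_info list with `target_xy`, `target_values` and optionally
#'   `animal_id`.
#' @param replicate_id integer tag carried into the output.
#' @return a `sim_track`.
#' @export
simulate_crw <- function(kernel, spec, fields, cfg, target_info,
                         replicate_id = 1L) {
  stopifnot(cfg$mode == "CRW")
  caches <- lapply(fields, function(st) build_day_cache(spec, st,
                                                        target_info))
  sim_one(kernel, spec, fields, cfg, target_info, caches, replicate_id)
}

#' Simulate one correlated random bridge replicate
#'
#' As [simulate_crw()], but the per-step sampling distribution is further
#' multiplied by the target-pull feasibility weights of
#' [crb_pull_surface()], and the final position is set to the target
#' exactly: the bridge fixes both endpoints in space.
#'
#' @inheritParams simulate_crw
#' @param cfg a `simulation_config` with `mode = "CRB"`.
#' @return a `sim_track` whose last position equals `cfg$target_xy`.
#' @export
simulate_crb <- function(kernel, spec, fields, cfg, target_info,
                         replicate_id = 1L) {
  stopifnot(cfg$mode == "CRB")
  caches <- lapply(fields, function(st) build_day_cache(spec, st,
                                                        target_info))
  sim_one(kernel, spec, fields, cfg, target_info, caches, replicate_id)
}

#' Run a full simulation batch
#'
#' Simulates `n_replicates` tracks for every (strategy, animal) pair. Each
#' animal's configuration uses its own hourly step count, start and target
#' (the first and last fix of its empirical trajectory). Replicate `r` of
#' animal `a` under model `label` runs on its own RNG substream seeded by
#' `seed + hash(a, label, r)`, so batches are reproducible and
#' order-independent.
#'
#' @param kernel a `movement_kernel`.
#' @param specs list of `strategy_spec`s.
#' @param animals list of entries, each a list with `trajectory` (cleaned,
#'   hourly `trajectory`) and `target_info` (list with `target_xy`,
#'   `target_values`).
#' @param fields list of `field_stack`s, one per day from departure.
#' @param cfg a `simulation_config`; its `n_steps`, `start_xy` and
#'   `target_xy` are overridden per animal.
#' @return an object of class `sim_batch`: list of `sim_track`s with the
#'   run seed in attribute `seed`.
#' @export
run_batch <- function(kernel, specs, animals, fields, cfg) {
  out <- vector("list", length(specs) * length(animals) * cfg$n_replicates)
  i <- 0L
  for (spec in specs) {
    for (an in animals) {
      tr <- an$trajectory
      ti <- an$target_info
      ti$animal_id <- ti$animal_id %||% tr$animal_id
      acfg <- cfg
      acfg$n_steps <- n_fixes(tr) - 1L
      acfg$start_xy <- c(tr$x[1], tr$y[1])
      acfg$target_xy <- c(tr$x[n_fixes(tr)], tr$y[n_fixes(tr)])
      caches <- lapply(fields, function(st)
        build_day_cache(spec, st, ti))
      for (r in seq_len(cfg$n_replicates)) {
        i <- i + 1L
        # bounded retries on fresh substreams: a bridge replicate whose
        # final hop would exceed L_max aborts and is redrawn
        for (try in seq_len(50L)) {
          sub <- (cfg$seed +
                    hash31(c(ti$animal_id, spec$label, r, try))) %%
            2147483647L
          set.seed(sub)
          res <- tryCatch(
            sim_one(kernel, spec, fields, acfg, ti, caches, r),
            magnav_bridge_miss = function(e) e)
          if (!inherits(res, "condition")) break
        }
        if (inherits(res, "condition"))
          stop("replicate ", r, " of ", spec$label, " for animal ",
               ti$animal_id, " failed after 50 attempts: ",
               conditionMessage(res))
        attr(res, "attempts") <- try
        out[[i]] <- res
      }
    }
  }
  structure(out, class = "sim_batch", seed = cfg$seed)
}

#' @export
print.sim_batch <- function(x, ...) {
  cat(sprintf("<sim_batch of %d tracks (seed %d)>\n", length(x),
              attr(x, "seed")))
}

#' Flatten a simulation batch to a long-format data frame
#'
#' One row per position: `animal_id`, `label`, `replicate`, `step`
#' (0-based; 0 is the start), `x`, `y`.
#'
#' @param x a `sim_batch`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a `data.frame`.
#' @export
as.data.frame.sim_batch <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  do.call(rbind, lapply(unclass(x), function(tr) {
    n <- length(tr$x)
    data.frame(animal_id = tr$animal_id, label = tr$label,
               replicate = tr$replicate, step = 0:(n - 1),
               x = tr$x, y = tr$y, stringsAsFactors = FALSE)
  }))
}
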