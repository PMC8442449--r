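#' Specify a navigational strategy configuration
#'
#' The experiment compares five strategy families: a no-bias control, taxis
#' along one cue gradient, constant heading calibrated against one cue's
#' global extreme, bi-gradient map navigation on two cues, and a combination
#' of a single-cue gradient map with constant heading.
#'
#' @param strategy one of `"NO_BIAS"`, `"TAXIS"`, `"CONSTANT_HEADING"`,
#'   `"BIGRADIENT"`, `"COMBINATION"`.
#' @param cues character vector of cue ids (`"F"`, `"I"`, `"H"`); arity must
#'   match the strategy (0, 1, 1, 2, 2). BIGRADIENT pairs are unordered
#'   (stored sorted); COMBINATION pairs are ordered: first cue feeds the
#'   gradient-to-target raster, second the constant-heading raster.
#' @param extreme `"min"` or `"max"`; CONSTANT_HEADING only (which global
#'   extreme serves as the calibration reference).
#' @return an object of class `strategy_spec` with a canonical `label`.
#' @export
strategy_spec <- function(strategy, cues = character(0), extreme = NULL) {
  strategy <- match.arg(strategy, c("NO_BIAS", "TAXIS", "CONSTANT_HEADING",
                                    "BIGRADIENT", "COMBINATION"))
  cues <- as.character(cues)
  if (length(cues)) stopifnot(all(cues %in% c("F", "I", "H")))
  arity <- c(NO_BIAS = 0, TAXIS = 1, CONSTANT_HEADING = 1,
             BIGRADIENT = 2, COMBINATION = 2)[[strategy]]
  if (length(cues) != arity)
    stop(strategy, " requires ", arity, " cue(s), got ", length(cues))
  if (strategy == "BIGRADIENT") {
    if (cues[1] == cues[2]) stop("BIGRADIENT cues must differ")
    cues <- sort(cues)
  }
  if (strategy == "COMBINATION" && cues[1] == cues[2])
    stop("COMBINATION cues must differ")
  if (strategy == "CONSTANT_HEADING") {
    if (is.null(extreme)) stop("CONSTANT_HEADING requires extreme")
    extreme <- match.arg(extreme, c("min", "max"))
  } else {
    extreme <- NULL
  }
  label <- switch(strategy,
                  NO_BIAS = "no_bias",
                  TAXIS = paste0("taxis_", cues),
                  CONSTANT_HEADING = paste0("ch_", extreme, cues),
                  BIGRADIENT = paste0("bigrad_", paste(cues, collapse = "")),
                  COMBINATION = paste0("comb_", paste(cues, collapse = "")))
  structure(list(strategy = strategy, cues = cues, extreme = extreme,
                 label = label),
            class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("<strategy_spec %s>\n", x$label))
}

#' Enumerate the complete experiment design
#'
#' The full set of model configurations: 1 no-bias control; taxis for each
#' of F, H, I; constant heading towards the global max and the global min of
#' each cue (6); bi-gradient maps on the 3 unordered cue pairs; and the 6
#' ordered cue pairs for the combination strategy. 19 configurations in
#' total, each with a unique canonical label.
#'
#' @return list of 19 `strategy_spec` objects.
#' @export
enumerate_model_configs <- function() {
  cues <- c("F", "H", "I")
  specs <- list(strategy_spec("NO_BIAS"))
  for (cu in cues) specs <- c(specs, list(strategy_spec("TAXIS", cu)))
  for (ex in c("max", "min"))
    for (cu in cues)
      specs <- c(specs, list(strategy_spec("CONSTANT_HEADING", cu,
                                           extreme = ex)))
  for (pair in list(c("F", "H"), c("F", "I"), c("I", "H")))
    specs <- c(specs, list(strategy_spec("BIGRADIENT", pair)))
  for (pair in list(c("F", "H"), c("F", "I"), c("H", "F"),
                    c("H", "I"), c("I", "F"), c("I", "H")))
    specs <- c(specs, list(strategy_spec("COMBINATION", pair)))
  specs
}

#' @keywords internal
new_prob_surface <- function(geometry, values) {
  values <- as.matrix(values)
  if (min(values) < -1e-12 || max(values) > 1 + 1e-12)
    stop("probability surface values outside [0, 1]")
  values[values < 0] <- 0
  values[values > 1] <- 1
  if (max(values) <= 0)
    stop("probability surface has no strictly positive cell")
  structure(list(geometry = geometry, values = values),
            class = "prob_surface")
}

#' @export
print.prob_surface <- function(x, ...) {
  cat(sprintf("<prob_surface %s, range [%.3g, %.3g]>\n",
              format(x$geometry), min(x$values), max(x$values)))
}

# ---- vectorised per-value probability cores --------------------------------
# These cores are shared between the full-raster surface builders below and
# the windowed evaluation inside the simulation engines.

#' @keywords internal
taxis_prob <- function(v, v_min, v_max) (v_max - v) / (v_max - v_min)

#' @keywords internal
gradient_target_prob <- function(v, v_target, v_min, v_max) {
  p <- 1 - abs(v - v_target) / (v_max - v_min)
  pmin(pmax(p, 0), 1)
}

# unsigned angle (degrees, [0, 180]) at vertex `current` between the rays
# current -> extreme and current -> (x, y); 0 where the point coincides with
# the vertex
#' @keywords internal
vertex_angle_deg <- function(current_xy, extreme_xy, x, y) {
  a_ref <- atan2(extreme_xy[2] - current_xy[2], extreme_xy[1] - current_xy[1])
  a_pt <- atan2(y - current_xy[2], x - current_xy[1])
  d <- abs(wrap_angle(a_pt - a_ref))
  d[(x == current_xy[1]) & (y == current_xy[2])] <- 0
  rad2deg(d)
}

#' @keywords internal
constant_heading_prob <- function(angle_deg, theta_star) {
  1 - abs(angle_deg - theta_star) / 180
}

#' Calibrate the constant-heading optimum angle
#'
#' The compass reference is the grid's global extreme E of the chosen cue.
#' Points P are sampled at cell-size spacing along the straight segment from
#' the current position to the target; for each, the unsigned angle at the
#' current position between the rays towards E and towards P is computed.
#' The optimum angle theta* is the mean of these angles, in degrees
#' [0, 180]. Recalibrated once per simulated day.
#'
#' @param grid a `field_grid` (cue used for the extreme).
#' @param current_xy,target_xy planar coordinates (m), `c(x, y)`.
#' @param extreme `"min"` or `"max"`.
#' @return list with `theta_star` (degrees) and `extreme_xy`.
#' @export
constant_heading_calibration <- function(grid, current_xy, target_xy,
                                         extreme = c("min", "max")) {
  extreme <- match.arg(extreme)
  if (all(current_xy == target_xy))
    stop("current position coincides with the target")
  ext <- extremum_location(grid, extreme)
  ext_xy <- c(ext$x, ext$y)
  if (all(ext_xy == current_xy))
    stop("current position coincides with the cue extreme")
  d <- sqrt(sum((target_xy - current_xy)^2))
  n_samp <- max(2, ceiling(d / grid$geometry$cell_size))
  frac <- seq_len(n_samp) / n_samp    # exclude the vertex itself
  px <- current_xy[1] + frac * (target_xy[1] - current_xy[1])
  py <- current_xy[2] + frac * (target_xy[2] - current_xy[2])
  theta <- mean(vertex_angle_deg(current_xy, ext_xy, px, py))
  list(theta_star = theta, extreme_xy = ext_xy)
}

# ---- full-raster surface builders ------------------------------------------

#' Taxis bias surface
#'
#' Movement towards the cue's global minimum along the gradient (autumn
#' migration runs from high to low geomagnetic values): the day's minimum
#' value gets probability 1, the maximum 0, linear in between. Set
#' `towards = "max"` for the spring-equivalent gradient ascent.
#'
#' @param grid a `field_grid`.
#' @param towards `"min"` (default, autumn) or `"max"`.
#' @return a `prob_surface` on the grid's geometry.
#' @export
taxis_surface <- function(grid, towards = c("min", "max")) {
  towards <- match.arg(towards)
  v <- grid$values
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("taxis surface undefined on a constant grid")
  p <- taxis_prob(v, rng[1], rng[2])
  if (towards == "max") p <- 1 - p
  new_prob_surface(grid$geometry, p)
}

#' Constant-heading bias surface
#'
#' Each cell's probability is 1 minus the deviation (scaled by 180 degrees)
#' of its vertex angle from the optimum angle theta*, where the vertex angle
#' of a cell is measured at the current position between the rays towards
#' the cue's global extreme and towards the cell.
#'
#' @param grid a `field_grid`.
#' @param current_xy,target_xy planar coordinates (m).
#' @param extreme `"min"` or `"max"`.
#' @param calibration optional precomputed result of
#'   [constant_heading_calibration()] (the daily calibration); computed from
#'   the current position if omitted.
#' @return a `prob_surface`.
#' @export
constant_heading_surface <- function(grid, current_xy, target_xy,
                                     extreme = c("min", "max"),
                                     calibration = NULL) {
  extreme <- match.arg(extreme)
  if (is.null(calibration))
    calibration <- constant_heading_calibration(grid, current_xy, target_xy,
                                                extreme)
  g <- grid$geometry
  xs <- col_x(g); ys <- row_y(g)
  ang <- vertex_angle_deg(current_xy, calibration$extreme_xy,
                          matrix(xs, g$n_rows, g$n_cols, byrow = TRUE),
                          matrix(ys, g$n_rows, g$n_cols))
  new_prob_surface(g, constant_heading_prob(ang, calibration$theta_star))
}

#' Bi-gradient map bias surface
#'
#' Map navigation towards the target's known values of two cues: per cue,
#' the cell value equal to the target's value gets probability 1, falling
#' off linearly with the deviation scaled by the raster's full daily range
#' (clipped to [0, 1]); the two single-cue surfaces are multiplied.
#'
#' @param grid1,grid2 `field_grid`s of the two cues (same geometry).
#' @param target_values named numeric vector of cue values at the target,
#'   containing entries for both grids' cues.
#' @return a `prob_surface`.
#' @export
bigradient_surface <- function(grid1, grid2, target_values) {
  if (!same_geometry(grid1$geometry, grid2$geometry))
    stop("bigradient grids have mismatched geometry")
  p1 <- gradient_surface_values(grid1, target_values)
  p2 <- gradient_surface_values(grid2, target_values)
  new_prob_surface(grid1$geometry, p1 * p2)
}

# single-cue gradient-to-target raster values
#' @keywords internal
gradient_surface_values <- function(grid, target_values) {
  vt <- target_values[[grid$cue]]
  if (is.null(vt)) stop("target value for cue ", grid$cue, " missing")
  rng <- range(grid$values)
  if (rng[1] == rng[2])
    stop("gradient surface undefined on a constant ", grid$cue, " grid")
  gradient_target_prob(grid$values, vt, rng[1], rng[2])
}

#' Combination bias surface (gradient map x constant heading)
#'
#' Product of the single-cue gradient-to-target raster (first cue, the
#' per-cue bi-gradient formula) and the constant-heading raster (second
#' cue).
#'
#' @param map_cue_grid `field_grid` for the gradient-to-target component.
#' @param heading_cue_grid `field_grid` for the constant-heading component.
#' @param current_xy,target_xy planar coordinates (m).
#' @param target_values named numeric vector with the map cue's target value.
#' @param extreme `"min"` or `"max"` for the constant-heading reference.
#' @param calibration optional precomputed daily calibration for the
#'   heading component.
#' @return a `prob_surface`.
#' @export
combination_surface <- function(map_cue_grid, heading_cue_grid,
                                current_xy, target_xy, target_values,
                                extreme = c("min", "max"),
                                calibration = NULL) {
  extreme <- match.arg(extreme)
  if (!same_geometry(map_cue_grid$geometry, heading_cue_grid$geometry))
    stop("combination grids have mismatched geometry")
  pm <- gradient_surface_values(map_cue_grid, target_values)
  ph <- constant_heading_surface(heading_cue_grid, current_xy, target_xy,
                                 extreme, calibration)$values
  new_prob_surface(map_cue_grid$geometry, pm * ph)
}

#' No-bias control surface
#'
#' All cells 1: multiplied into the movement surface it leaves the pure
#' correlated random walk unchanged.
#'
#' @param geometry a `grid_geometry`.
#' @return a `prob_surface` of ones.
#' @export
no_bias_surface <- function(geometry) {
  new_prob_surface(geometry, matrix(1, geometry$n_rows, geometry$n_cols))
}

#' Build the bias surface for a strategy at one simulation step
#'
#' Dispatches on the `strategy_spec`, reading the needed cue grids from the
#' day's `field_stack`. For constant-heading and combination strategies the
#' daily calibration (theta*) must be supplied via `calibration` (computed
#' at the first step of each simulated day); the raster itself is rebuilt
#' from the current position at every step.
#'
#' @param spec a `strategy_spec`.
#' @param stack the current day's `field_stack`.
#' @param current_xy,target_xy planar coordinates (m).
#' @param target_info list with `target_values` (named cue values at the
#'   target); required for BIGRADIENT and COMBINATION.
#' @param calibration daily constant-heading calibration, if applicable.
#' @return a `prob_surface`.
#' @export
strategy_surface <- function(spec, stack, current_xy, target_xy,
                             target_info = NULL, calibration = NULL) {
  switch(spec$strategy,
    NO_BIAS = no_bias_surface(stack$geometry),
    TAXIS = taxis_surface(stack[[spec$cues[1]]]),
    CONSTANT_HEADING = constant_heading_surface(
      stack[[spec$cues[1]]], current_xy, target_xy, spec$extreme,
      calibration),
    BIGRADIENT = bigradient_surface(stack[[spec$cues[1]]],
                                    stack[[spec$cues[2]]],
                                    target_info$target_values),
    COMBINATION = combination_surface(
      stack[[spec$cues[1]]], stack[[spec$cues[2]]], current_xy, target_xy,
      target_info$target_values,
      extreme = "min", calibration = calibration))
}

#' Export a probability surface as a float TIFF + world file
#'
#' @param surface a `prob_surface`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  g <- surface$geometry
  write_float_tiff(surface$values, path)
  writeLines(c(format(g$cell_size, digits = 15), "0", "0",
               format(-g$cell_size, digits = 15),
               format(g$origin_x, digits = 15),
               format(g$origin_y, digits = 15)),
             world_file_path(path))
  invisible(path)
}
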