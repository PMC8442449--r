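# Small deterministic builders shared across the test files.

# grid with origin at (0, (nr-1)*cs): x grows east, y grows north,
# row 1 is the northern edge
toy_geometry <- function(nr = 5, nc = 5, cs = 1000) {
  grid_geometry(origin_x = 0, origin_y = (nr - 1) * cs, cell_size = cs,
                n_rows = nr, n_cols = nc)
}

toy_grid <- function(values, cue = "F", cs = 1000,
                     date = as.Date("2016-09-19")) {
  values <- as.matrix(values)
  field_grid(cue, date, toy_geometry(nrow(values), ncol(values), cs),
             values)
}

# trajectory along +x with constant speed, hourly fixes
straight_traj <- function(step_m = 5000, n_steps = 6, id = "a1",
                          start = c(0, 0)) {
  t0 <- as.POSIXct("2016-09-19 00:00:00", tz = "UTC")
  trajectory(id, t0 + 3600 * (0:n_steps),
             start[1] + step_m * (0:n_steps), rep(start[2], n_steps + 1))
}

# degenerate kernel: every step 5000 m straight ahead
straight_kernel <- function(step_m = 5000) {
  estimate_kernel(to_steps(straight_traj(step_m, 8)))
}

# hand-built two-bin toy kernel with known masses; uniform difference
# masses make step_density proportional to the joint alone
toy_kernel2 <- function(joint = matrix(c(0.3, 0.2, 0.1, 0.4), 2, 2),
                        L_max = 2000, uniform_diffs = TRUE) {
  stopifnot(all(dim(joint) == c(2, 2)), abs(sum(joint) - 1) < 1e-12)
  k <- list(joint = joint,
            dL = if (uniform_diffs) c(0.5, 0.5) else c(0, 1),
            dPhi = if (uniform_diffs) c(0.5, 0.5) else c(0, 1),
            len_edges = c(0, L_max / 2, L_max),
            ang_edges = c(-pi, 0, pi),
            dL_edges = c(-L_max, 0, L_max),
            dPhi_edges = c(-pi, 0, pi),
            L_max = L_max, mu_L = L_max / 2, sd_L = L_max / 4,
            n_len_bins = 2L, n_ang_bins = 2L)
  class(k) <- "movement_kernel"
  k
}

# independent DTW oracle: exhaustive enumeration of all monotone warping
# paths (no dynamic programming), minimum total cost
brute_dtw <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    c0 <- cost(i, j)
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    c0 + best
  }
  rec(n, m)
}

# random synthetic field stack on a small grid
random_stack <- function(seed, nr = 12, cs = 30000) {
  g <- grid_geometry(0, (nr - 1) * cs, cs, nr, nr)
  p <- synth_field_params(g, storm_amplitude = 200, daily_drift = 25,
                          seed = seed)
  synth_field_stack(p, as.Date("2016-09-19"))[[1]]
}
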