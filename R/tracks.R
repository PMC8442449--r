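#' Construct a trajectory
#'
#' A time-ordered sequence of projected GPS fixes for one animal. Timestamps
#' must be strictly increasing; coordinates are planar metres.
#'
#' @param animal_id animal identifier (character scalar).
#' @param t `POSIXct` timestamps (UTC).
#' @param x,y planar coordinates in metres.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(animal_id, t, x, y) {
  stopifnot(length(t) == length(x), length(x) == length(y))
  if (!inherits(t, "POSIXct")) stop("t must be POSIXct")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite coordinates in trajectory for animal ", animal_id)
  if (length(t) > 1 && any(diff(as.numeric(t)) <= 0))
    stop("timestamps not strictly increasing for animal ", animal_id)
  structure(list(animal_id = as.character(animal_id),
                 t = t, x = as.numeric(x), y = as.numeric(y)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s: %d fixes, %s to %s>\n", x$animal_id,
              length(x$t), format(min(x$t)), format(max(x$t))))
}

#' Number of fixes in a trajectory
#' @param traj a `trajectory`.
#' @return integer count.
#' @export
n_fixes <- function(traj) length(traj$t)

#' Preprocessing parameters for raw migration tracks
#'
#' Defaults follow the standard cleaning of autumn goose migrations: fixes
#' slower than 6 km/h are treated as stopover/foraging, a 500 km exclusion
#' zone around the northernmost fix removes the breeding area, 700 km zones
#' around the southernmost and westernmost fixes remove the wintering area,
#' tracks shorter than 1500 km path length are discarded, and survivors are
#' linearly interpolated to hourly fixes.
#'
#' @param speed_threshold km/h; fixes with both adjacent segment speeds below
#'   this are removed.
#' @param north_radius km; exclusion radius around the northernmost fix.
#' @param southwest_radius km; exclusion radius around the southernmost and
#'   westernmost fixes.
#' @param min_track_length km; minimum total path length to keep a track.
#' @param interp_interval hours; interpolation interval.
#' @return an object of class `preprocess_params`.
#' @export
preprocess_params <- function(speed_threshold = 6, north_radius = 500,
                              southwest_radius = 700,
                              min_track_length = 1500,
                              interp_interval = 1) {
  p <- list(speed_threshold = speed_threshold, north_radius = north_radius,
            southwest_radius = southwest_radius,
            min_track_length = min_track_length,
            interp_interval = interp_interval)
  if (any(unlist(p) <= 0)) stop("all preprocessing parameters must be > 0")
  structure(p, class = "preprocess_params")
}

#' Read trajectories from CSV
#'
#' Expects a header `animal_id,timestamp,x,y` with ISO-8601 UTC timestamps
#' and planar coordinates in metres. Rows are sorted by time within animal;
#' duplicate timestamps within an animal are an error.
#'
#' @param path CSV file path.
#' @return named list of `trajectory` objects, one per animal.
#' @export
read_tracks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "x", "y")
  if (!all(need %in% names(d)))
    stop("CSV must have columns ", paste(need, collapse = ", "))
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  tt <- as.POSIXct(rep(NA_real_, nrow(d)), origin = "1970-01-01",
                   tz = "UTC")
  for (f in fmts) {
    idx <- is.na(tt)
    if (!any(idx)) break
    tt[idx] <- as.POSIXct(strptime(d$timestamp[idx], f, tz = "UTC"))
  }
  if (any(is.na(tt)))
    stop("malformed timestamp: ", d$timestamp[which(is.na(tt))[1]])
  out <- lapply(split(seq_len(nrow(d)), d$animal_id), function(idx) {
    o <- idx[order(tt[idx])]
    dup <- duplicated(tt[o])
    if (any(dup))
      stop("duplicate timestamp ", format(tt[o][dup][1]),
           " for animal ", d$animal_id[o[1]])
    trajectory(d$animal_id[o[1]], tt[o], d$x[o], d$y[o])
  })
  out[order(names(out))]
}

#' Write trajectories to CSV
#'
#' @param trajs list of `trajectory` objects.
#' @param path output CSV path (same dialect as [read_tracks()]).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trajs, path) {
  rows <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(animal_id = tr$animal_id,
               timestamp = format(tr$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               x = tr$x, y = tr$y, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# segment speeds in km/h between consecutive fixes
#' @keywords internal
segment_speeds <- function(traj) {
  n <- n_fixes(traj)
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) / 1000          # km
  dt <- diff(as.numeric(traj$t)) / 3600                      # h
  d / dt
}

#' @keywords internal
subset_traj <- function(traj, keep) {
  structure(list(animal_id = traj$animal_id, t = traj$t[keep],
                 x = traj$x[keep], y = traj$y[keep]),
            class = "trajectory")
}

#' Remove stationary fixes by ground speed
#'
#' A fix is retained iff at least one of its adjacent segments is at or
#' above the threshold speed; the first and last fixes are judged by their
#' single adjacent segment. This removes stopover clusters without clipping
#' the onset or end of flight.
#'
#' @param traj a `trajectory` with >= 2 fixes.
#' @param threshold km/h (default 6).
#' @return filtered `trajectory` (may have fewer than 2 fixes; check
#'   [n_fixes()] before further use).
#' @export
speed_filter <- function(traj, threshold = 6) {
  n <- n_fixes(traj)
  stopifnot(n >= 2)
  sp <- segment_speeds(traj)
  incoming <- c(-Inf, sp)    # speed of segment arriving at each fix
  outgoing <- c(sp, -Inf)    # speed of segment leaving each fix
  keep <- pmax(incoming, outgoing) >= threshold
  subset_traj(traj, keep)
}

#' Remove breeding- and wintering-area fixes by exclusion zones
#'
#' Fixes within `north_radius` of the northernmost fix (breeding area), or
#' within `southwest_radius` of the southernmost or of the westernmost fix
#' (wintering area), are removed. Distances are planar Euclidean. Call once
#' per animal per migration.
#'
#' @param traj a `trajectory` with >= 2 fixes.
#' @param p a [preprocess_params()].
#' @return filtered `trajectory`.
#' @export
exclusion_zones <- function(traj, p = preprocess_params()) {
  stopifnot(n_fixes(traj) >= 2)
  i_n <- which.max(traj$y)
  i_s <- which.min(traj$y)
  i_w <- which.min(traj$x)
  d_n <- edist(traj$x[i_n], traj$y[i_n], traj$x, traj$y) / 1000
  d_s <- edist(traj$x[i_s], traj$y[i_s], traj$x, traj$y) / 1000
  d_w <- edist(traj$x[i_w], traj$y[i_w], traj$x, traj$y) / 1000
  keep <- d_n >= p$north_radius &
    d_s >= p$southwest_radius & d_w >= p$southwest_radius
  subset_traj(traj, keep)
}

#' Total path length of a trajectory in km
#' @param traj a `trajectory`.
#' @return numeric, km.
#' @export
track_length_km <- function(traj) {
  if (n_fixes(traj) < 2) return(0)
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2)) / 1000
}

#' Keep/discard flag by migratory path length
#'
#' Uses cumulative path length (not net displacement): a zigzag track whose
#' chord is short but whose flown distance exceeds the threshold is kept.
#'
#' @param traj a `trajectory`.
#' @param min_km minimum path length in km (default 1500).
#' @return logical: `TRUE` to keep.
#' @export
length_filter <- function(traj, min_km = 1500) {
  track_length_km(traj) > min_km
}

#' Linearly interpolate a trajectory to a regular interval
#'
#' Produces fixes at `t0, t0 + interval, ...` up to the last original
#' timestamp, with coordinates linear in time between bracketing originals.
#' Idempotent on already-regular tracks.
#'
#' @param traj a `trajectory` with >= 2 fixes.
#' @param interval hours between output fixes (default 1).
#' @return interpolated `trajectory`.
#' @export
interpolate_hourly <- function(traj, interval = 1) {
  stopifnot(n_fixes(traj) >= 2)
  tn <- as.numeric(traj$t)
  out_t <- seq(tn[1], tn[length(tn)], by = interval * 3600)
  x <- stats::approx(tn, traj$x, xout = out_t)$y
  y <- stats::approx(tn, traj$y, xout = out_t)$y
  trajectory(traj$animal_id,
             as.POSIXct(out_t, origin = "1970-01-01", tz = "UTC"), x, y)
}

#' Decompose a trajectory into steps
#'
#' @param traj a `trajectory` with >= 2 fixes.
#' @return an object of class `step_series`: list with `step_lengths` (m),
#'   `headings` (radians, mathematical convention, in (-pi, pi]) and
#'   `turning_angles` (wrapped heading differences, one fewer than steps),
#'   plus the originating `animal_id`.
#' @export
to_steps <- function(traj) {
  stopifnot(n_fixes(traj) >= 2)
  dx <- diff(traj$x); dy <- diff(traj$y)
  L <- sqrt(dx^2 + dy^2)
  h <- wrap_angle(atan2(dy, dx))
  phi <- if (length(h) > 1) wrap_angle(diff(h)) else numeric(0)
  structure(list(step_lengths = L, headings = h, turning_angles = phi,
                 animal_id = traj$animal_id),
            class = "step_series")
}

#' Run the full preprocessing pipeline on raw trajectories
#'
#' Fixed stage order: exclusion zones, then speed filter, then length
#' filter, then interpolation to the regular interval. Tracks reduced below
#' 2 fixes or failing the length filter are dropped.
#'
#' @param trajs list of raw `trajectory` objects.
#' @param p a [preprocess_params()].
#' @return named list of cleaned, hourly `trajectory` objects.
#' @export
preprocess_tracks <- function(trajs, p = preprocess_params()) {
  out <- list()
  for (tr in trajs) {
    if (n_fixes(tr) < 2) next
    tr <- exclusion_zones(tr, p)
    if (n_fixes(tr) < 2) next
    tr <- speed_filter(tr, p$speed_threshold)
    if (n_fixes(tr) < 2) next
    if (!length_filter(tr, p$min_track_length)) next
    out[[tr$animal_id]] <- interpolate_hourly(tr, p$interp_interval)
  }
  out
}

#' Export a trajectory as a GeoJSON LineString
#'
#' @param traj a `trajectory`.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(traj, path) {
  gj <- list(
    type = "Feature",
    properties = list(animal_id = traj$animal_id,
                      start = format(traj$t[1], "%Y-%m-%dT%H:%M:%SZ"),
                      end = format(traj$t[n_fixes(traj)],
                                   "%Y-%m-%dT%H:%M:%SZ")),
    geometry = list(type = "LineString",
                    coordinates = mapply(c, traj$x, traj$y, SIMPLIFY = FALSE))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
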