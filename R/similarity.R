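#' @useDynLib magnav, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' @keywords internal
as_xy <- function(p) {
  if (inherits(p, "trajectory") || inherits(p, "sim_track"))
    return(cbind(p$x, p$y))
  p <- as.matrix(p)
  stopifnot(ncol(p) == 2)
  p
}

#' Mean pointwise distance between two matched trajectories
#'
#' The mean Euclidean distance between every point of the simulated
#' trajectory and the corresponding (same-index) point of the matched
#' empirical trajectory. Lower values indicate more similar movement.
#'
#' @param sim,obs two-column coordinate matrices (or `trajectory` /
#'   `sim_track` objects) with equal point counts.
#' @return metres.
#' @export
mean_distance <- function(sim, obs) {
  a <- as_xy(sim); b <- as_xy(obs)
  if (nrow(a) != nrow(b))
    stop("mean_distance needs equal point counts (", nrow(a), " vs ",
         nrow(b), ")")
  mean(sqrt(rowSums((a - b)^2)))
}

#' Dynamic time warping distance between two trajectories
#'
#' Classic dynamic-programming DTW with Euclidean local cost and symmetric
#' unit-slope moves (match, insert, delete), no window constraint. Returns
#' the unnormalised total accumulated cost: warping shifts and stretches
#' one trajectory onto the other, so the measure is robust to local timing
#' differences. Lower is more similar.
#'
#' @param sim,obs two-column coordinate matrices (or `trajectory` /
#'   `sim_track` objects); lengths may differ.
#' @return metres (accumulated cost).
#' @export
dtw_distance <- function(sim, obs) {
  a <- as_xy(sim); b <- as_xy(obs)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty trajectory")
  .dtw_cost(a[, 1], a[, 2], b[, 1], b[, 2])
}

#' Dynamic interaction index between two matched trajectories
#'
#' A per-step measure of similarity in the direction and displacement
#' components of movement: for step t,
#' `di_t = cos(theta_sim - theta_obs) *
#'        (1 - (|d_sim - d_obs| / (d_sim + d_obs))^delta)`,
#' averaged over steps. The displacement factor is 1 when both
#' displacements are zero and 0 when exactly one is zero. Values lie in
#' [-1, 1]; values near 1 indicate highly similar movement, near 0 no
#' similarity.
#'
#' @param sim,obs two-column coordinate matrices (or `trajectory` /
#'   `sim_track` objects) with equal point counts (>= 2).
#' @param delta exponent on the displacement ratio (default 1).
#' @return unitless value in [-1, 1].
#' @export
di_index <- function(sim, obs, delta = 1) {
  a <- as_xy(sim); b <- as_xy(obs)
  if (nrow(a) != nrow(b))
    stop("di_index needs equal point counts (", nrow(a), " vs ", nrow(b),
         ")")
  if (nrow(a) < 2) stop("di_index needs at least 2 points")
  da <- diff(a); db <- diff(b)
  la <- sqrt(rowSums(da^2)); lb <- sqrt(rowSums(db^2))
  ha <- atan2(da[, 2], da[, 1]); hb <- atan2(db[, 2], db[, 1])
  ang <- cos(ha - hb)
  ang[la == 0 | lb == 0] <- 1   # heading undefined: neutral azimuth factor
  disp <- ifelse(la + lb == 0, 1, 1 - (abs(la - lb) / (la + lb))^delta)
  both0 <- la == 0 & lb == 0
  one0 <- xor(la == 0, lb == 0)
  disp[both0] <- 1
  disp[one0] <- 0
  mean(ang * disp)
}

#' Score a simulation batch against the empirical trajectories
#'
#' Computes all three similarity measures for every simulated track against
#' its animal's cleaned hourly trajectory.
#'
#' @param batch a `sim_batch` (or plain list of `sim_track`s).
#' @param trajectories named list of `trajectory` objects keyed by
#'   `animal_id` (point counts must match the simulated tracks).
#' @return a `data.frame` with columns `animal_id`, `label`, `replicate`,
#'   `mean_distance`, `dtw`, `di`.
#' @export
score_batch <- function(batch, trajectories) {
  rows <- lapply(unclass(batch), function(tr) {
    obs <- trajectories[[tr$animal_id]]
    if (is.null(obs))
      stop("no reference trajectory for animal ", tr$animal_id)
    data.frame(animal_id = tr$animal_id, label = tr$label,
               replicate = tr$replicate,
               mean_distance = mean_distance(tr, obs),
               dtw = dtw_distance(tr, obs),
               di = di_index(tr, obs), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
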