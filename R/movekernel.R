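#' Estimate the pooled empirical movement kernel
#'
#' Builds the movement model used by the random-walk engines: a joint
#' histogram of (step length, turning angle) pooled over all animals, plus
#' unidimensional histograms of the lag-1 differences of step lengths and of
#' turning angles. The lag-1 difference structure maintains the empirical
#' autocorrelation of consecutive steps. Differences are computed within
#' each animal only, never across animals.
#'
#' @param steps a `step_series` or a list of them (one per animal).
#' @param n_len_bins number of step-length bins over `[0, L_max]`.
#' @param n_ang_bins number of turning-angle bins over `(-pi, pi]`.
#' @return an object of class `movement_kernel` with elements `joint`
#'   (`n_len_bins x n_ang_bins` probability mass matrix), `dL`, `dPhi`
#'   (difference mass vectors), the corresponding bin edges, `L_max`, and
#'   the pooled step-length mean `mu_L` and sd `sd_L`.
#' @export
estimate_kernel <- function(steps, n_len_bins = 30, n_ang_bins = 24) {
  if (inherits(steps, "step_series")) steps <- list(steps)
  L_all <- unlist(lapply(steps, `[[`, "step_lengths"))
  phi_all <- unlist(lapply(steps, `[[`, "turning_angles"))
  if (length(L_all) < 2 || length(phi_all) < 2)
    stop("need at least 2 pooled steps and 2 pooled turning angles")
  L_max <- max(L_all)
  if (L_max <= 0) stop("all pooled step lengths are zero")

  len_edges <- seq(0, L_max, length.out = n_len_bins + 1)
  ang_edges <- seq(-pi, pi, length.out = n_ang_bins + 1)
  dL_edges <- seq(-L_max, L_max, length.out = n_len_bins + 1)
  dPhi_edges <- seq(-pi, pi, length.out = n_ang_bins + 1)

  # joint over (L, phi) pairs: phi_t pairs with the step it turns INTO,
  # i.e. (L_{t+1}, phi_t); pools across animals
  iL <- iA <- integer(0)
  dL <- dphi <- numeric(0)
  for (s in steps) {
    L <- s$step_lengths; phi <- s$turning_angles
    if (length(phi) >= 1) {
      iL <- c(iL, bin_index(L[-1], len_edges))
      iA <- c(iA, bin_index(phi, ang_edges))
    }
    if (length(L) >= 2) dL <- c(dL, diff(L))
    if (length(phi) >= 2) dphi <- c(dphi, wrap_angle(diff(phi)))
  }
  if (length(iL) == 0) stop("empty pooled (step length, turning angle) set")
  joint <- matrix(0, n_len_bins, n_ang_bins)
  ok <- iL > 0 & iA > 0
  for (k in which(ok)) joint[iL[k], iA[k]] <- joint[iL[k], iA[k]] + 1
  joint <- joint / sum(joint)

  hist1 <- function(v, edges) {
    h <- tabulate(bin_index(v, edges), nbins = length(edges) - 1)
    if (sum(h) == 0) h[ceiling(length(h) / 2)] <- 1   # degenerate: centre mass
    h / sum(h)
  }
  structure(list(joint = joint,
                 dL = hist1(dL, dL_edges),
                 dPhi = hist1(dphi, dPhi_edges),
                 len_edges = len_edges, ang_edges = ang_edges,
                 dL_edges = dL_edges, dPhi_edges = dPhi_edges,
                 L_max = L_max,
                 mu_L = mean(L_all), sd_L = stats::sd(L_all),
                 n_len_bins = n_len_bins, n_ang_bins = n_ang_bins),
            class = "movement_kernel")
}

#' @export
print.movement_kernel <- function(x, ...) {
  cat(sprintf(
    "<movement_kernel %d x %d bins, L_max %.0f m, mean step %.0f m>\n",
    x$n_len_bins, x$n_ang_bins, x$L_max, x$mu_L))
}

# Uniform-bin index: 0 for values outside [edges[1], edges[n+1]]; the top
# edge is included in the last bin (right-closed convention, so a turning
# angle of exactly pi lands in the final bin).
#' @keywords internal
bin_index <- function(v, edges) {
  n <- length(edges) - 1
  w <- (edges[n + 1] - edges[1]) / n
  tol <- 1e-9 * w
  idx <- floor((v - edges[1]) / w) + 1
  idx <- pmin(pmax(idx, 1), n)    # clamp top-edge / FP-boundary values
  idx[v < edges[1] - tol | v > edges[n + 1] + tol] <- 0
  as.integer(idx)
}

#' Evaluate the movement kernel density for a candidate step
#'
#' The (unnormalised) probability mass for taking a step of length `L` and
#' turning angle `phi` after a previous step `(prev_L, prev_phi)`:
#' the product of the pooled joint mass at `(L, phi)`, the lag-1
#' step-length-difference mass at `L - prev_L`, and the lag-1
#' turning-angle-difference mass at `phi - prev_phi` (wrapped). Zero outside
#' the kernel support. Invariant to adding multiples of 2 pi to `phi`.
#'
#' @param kernel a `movement_kernel`.
#' @param L,phi candidate step length (m) and turning angle (rad); vectors
#'   of equal length.
#' @param prev_L,prev_phi previous step's length and turning angle
#'   (scalars).
#' @return numeric vector of unnormalised densities.
#' @export
step_density <- function(kernel, L, phi, prev_L, prev_phi) {
  phi <- wrap_angle(phi)
  iL <- bin_index(L, kernel$len_edges)
  iA <- bin_index(phi, kernel$ang_edges)
  iDL <- bin_index(L - prev_L, kernel$dL_edges)
  iDP <- bin_index(wrap_angle(phi - prev_phi), kernel$dPhi_edges)
  d <- numeric(length(L))
  ok <- iL > 0 & iA > 0 & iDL > 0 & iDP > 0
  if (any(ok))
    d[ok] <- kernel$joint[cbind(iL[ok], iA[ok])] *
      kernel$dL[iDL[ok]] * kernel$dPhi[iDP[ok]]
  d
}

#' @keywords internal
bin_centres <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Sample one step from the movement kernel
#'
#' Draws a (step length, turning angle) bin proportionally to
#' [step_density()] over the full bin grid, then jitters uniformly within
#' the chosen bin. If the conditional density is zero everywhere (disjoint
#' lag-1 supports), falls back to the joint histogram alone; the fallback is
#' recorded in the `fallback` attribute of the result.
#'
#' Uses the R session RNG; call `set.seed()` for reproducibility.
#'
#' @param kernel a `movement_kernel`.
#' @param prev_L,prev_phi previous step's length (m) and turning angle (rad).
#' @return numeric vector `c(L, phi)`.
#' @export
sample_step <- function(kernel, prev_L, prev_phi) {
  nL <- kernel$n_len_bins; nA <- kernel$n_ang_bins
  Lc <- bin_centres(kernel$len_edges)
  Ac <- bin_centres(kernel$ang_edges)
  grid_L <- rep(Lc, times = nA)
  grid_A <- rep(Ac, each = nL)
  dens <- step_density(kernel, grid_L, grid_A, prev_L, prev_phi)
  fallback <- FALSE
  if (sum(dens) == 0) {
    dens <- as.vector(kernel$joint)
    fallback <- TRUE
  }
  k <- sample.int(length(dens), 1, prob = dens)
  iL <- (k - 1) %% nL + 1
  iA <- (k - 1) %/% nL + 1
  wL <- diff(kernel$len_edges[c(iL, iL + 1)])
  wA <- diff(kernel$ang_edges[c(iA, iA + 1)])
  L <- kernel$len_edges[iL] + stats::runif(1) * wL
  phi <- wrap_angle(kernel$ang_edges[iA] + stats::runif(1) * wA)
  structure(c(L = unname(L), phi = unname(phi)), fallback = fallback)
}

#' Serialise a movement kernel to a YAML + CSV bundle
#'
#' Writes `kernel.yaml` (bin edges, scalars) plus `joint.csv`, `dL.csv`,
#' `dPhi.csv` into `dir` for reuse across runs.
#'
#' @param kernel a `movement_kernel`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_kernel <- function(kernel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(
    n_len_bins = kernel$n_len_bins, n_ang_bins = kernel$n_ang_bins,
    L_max = kernel$L_max, mu_L = kernel$mu_L, sd_L = kernel$sd_L,
    len_edges = kernel$len_edges, ang_edges = kernel$ang_edges,
    dL_edges = kernel$dL_edges, dPhi_edges = kernel$dPhi_edges),
    file.path(dir, "kernel.yaml"))
  utils::write.csv(as.data.frame(kernel$joint),
                   file.path(dir, "joint.csv"), row.names = FALSE)
  utils::write.csv(data.frame(mass = kernel$dL),
                   file.path(dir, "dL.csv"), row.names = FALSE)
  utils::write.csv(data.frame(mass = kernel$dPhi),
                   file.path(dir, "dPhi.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a movement kernel written by [write_kernel()]
#'
#' @param dir bundle directory.
#' @return a `movement_kernel`.
#' @export
read_kernel <- function(dir) {
  y <- yaml::read_yaml(file.path(dir, "kernel.yaml"))
  joint <- as.matrix(utils::read.csv(file.path(dir, "joint.csv")))
  dimnames(joint) <- NULL
  structure(list(joint = joint,
                 dL = utils::read.csv(file.path(dir, "dL.csv"))$mass,
                 dPhi = utils::read.csv(file.path(dir, "dPhi.csv"))$mass,
                 len_edges = y$len_edges, ang_edges = y$ang_edges,
                 dL_edges = y$dL_edges, dPhi_edges = y$dPhi_edges,
                 L_max = y$L_max, mu_L = y$mu_L, sd_L = y$sd_L,
                 n_len_bins = y$n_len_bins, n_ang_bins = y$n_ang_bins),
            class = "movement_kernel")
}
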