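#' Probability of vascular recruitment into a voxel
#'
#' Angiogenesis requires a crowded focal voxel (combined live + dead density
#' at least a quarter of carrying capacity, `H(0) = 1` at the gate) and a
#' mixture of live and dead cells in the neighborhood:
#' `p = p0 * H(N + N_d - sigma/4) * sum_j N_j N_dj / (N_j + N_dj)^2`,
#' summed over the supplied neighbors, with empty neighbors contributing 0.
#' Each neighbor term is at most 1/4 (attained at a 50:50 live/dead mix), so
#' on a von Neumann 4-neighborhood the sum is at most 1 and `p0` is the
#' literal maximum probability. The result is clamped to `[0, 1]` to cover
#' larger user-configured neighborhoods.
#'
#' @param N,N_d Live and dead cells in the focal voxel.
#' @param neighbors List of length-2 numeric vectors `c(N_j, N_dj)` (or a
#'   2-column matrix), one entry per neighbor voxel.
#' @param p0 Maximum angiogenesis probability.
#' @param sigma Carrying capacity (cells/voxel).
#' @return Recruitment probability in `[0, 1]`.
#' @export
#' @examples
#' p <- sim_params()
#' recruitment_probability(p$sigma / 4, p$sigma / 4,
#'                         neighbors = replicate(4, c(100, 100), simplify = FALSE),
#'                         p0 = p$p0, sigma = p$sigma)
recruitment_probability <- function(N, N_d, neighbors, p0, sigma) {
  check_nonneg(N, "N"); check_nonneg(N_d, "N_d")
  if (is.matrix(neighbors)) neighbors <- asplit(neighbors, 1)
  terms <- vapply(neighbors, function(nb) {
    check_nonneg(nb, "neighbor counts")
    s <- nb[[1]] + nb[[2]]
    if (s <= 0) 0 else nb[[1]] * nb[[2]] / s^2
  }, numeric(1))
  p <- p0 * heaviside(N + N_d - sigma / 4) * sum(terms)
  min(max(p, 0), 1)
}

# Vectorized recruitment probability map over the whole grid (von Neumann
# 4-neighborhood, neighbors outside the grid contribute 0).
recruitment_probability_map <- function(state, params) {
  Ntot <- Reduce(`+`, state$n)
  Nd <- state$Nd
  s <- Ntot + Nd
  Tm <- zero_like(Ntot)
  pos <- s > 0
  Tm[pos] <- Ntot[pos] * Nd[pos] / s[pos]^2
  nr <- nrow(Tm); nc <- ncol(Tm)
  nb <- zero_like(Tm)
  if (nr > 1) {
    nb[-nr, ] <- nb[-nr, ] + Tm[-1, ]
    nb[-1, ] <- nb[-1, ] + Tm[-nr, ]
  }
  if (nc > 1) {
    nb[, -nc] <- nb[, -nc] + Tm[, -1]
    nb[, -1] <- nb[, -1] + Tm[, -nc]
  }
  p <- params$p0 * heaviside(s - params$sigma / 4) * nb
  pmin(pmax(p, 0), 1)
}

#' Stochastic daily vessel recruitment
#'
#' Draws one Bernoulli trial per voxel at the probability returned by
#' [recruitment_probability()] evaluated on the 4-neighborhood; each success
#' adds one vessel unit to the voxel. The vessel count map never decreases
#' (no vessel regression is modeled). Uses the current R random number stream:
#' seed it (e.g. via [run_simulation()]'s seed) for reproducible trajectories.
#'
#' @param state A [grid_state()].
#' @param params A [sim_params()].
#' @param log_events If `TRUE`, attach a data frame of the day's candidate
#'   voxels (positive probability) with columns `day, x, y, p, outcome`.
#' @return The state with an updated `V` map (and `events` attribute if
#'   requested).
#' @export
recruit <- function(state, params, log_events = FALSE) {
  p <- recruitment_probability_map(state, params)
  u <- matrix(stats::runif(length(p)), nrow(p), ncol(p))
  hit <- (u < p) * 1
  state$V <- state$V + hit
  if (log_events) {
    idx <- which(p > 0, arr.ind = TRUE)
    attr(state, "events") <- data.frame(
      day = state$day, x = idx[, 1], y = idx[, 2],
      p = p[idx], outcome = hit[idx]
    )
  }
  state
}
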