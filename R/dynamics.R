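#' Metabolic state of a voxel
#'
#' Cells run oxidative phosphorylation while local oxygen is at or above the
#' switch threshold `O_th` and fall back to glycolysis below it. The tie at
#' exactly `O_th` resolves to oxphos ([heaviside()] convention `H(0) = 1`).
#'
#' @param N_o Oxygen concentration(s), mg/L; scalar, vector or matrix.
#' @param O_th Switch threshold, mg/L.
#' @return Character object of the same shape, `"oxphos"` or `"glycolysis"`.
#' @export
#' @examples
#' metabolic_state(c(0.06, 0.04, 0.051), O_th = 0.051)
metabolic_state <- function(N_o, O_th) {
  stop_if(any(N_o < 0), "oxygen concentration must be non-negative")
  stop_if(O_th < 0, "'O_th' must be non-negative")
  out <- ifelse(N_o >= O_th, "oxphos", "glycolysis")
  dim(out) <- dim(N_o)
  out
}

#' Nutrient- and density-limited proliferation rate
#'
#' Logistic crowding (live plus dead cells count against the carrying
#' capacity) times a Michaelis-Menten nutrient factor whose substrate depends
#' on the metabolic state: oxygen (half-max `alpha_g`) under oxphos, glucose
#' (clone-specific half-max `beta_g_i`) under glycolysis.
#'
#' @param clone A [clone_params()].
#' @param N_o,N_g Oxygen (mg/L) and glucose (mM); scalars or maps.
#' @param N_total Total live cells per voxel (all clones).
#' @param N_d Dead cells per voxel.
#' @param params A [sim_params()].
#' @return Proliferation rate (1/day) in `[0, gamma_i]`, same shape as input.
#' @export
proliferation_rate <- function(clone, N_o, N_g, N_total, N_d, params) {
  check_nonneg(N_o, "N_o"); check_nonneg(N_g, "N_g")
  check_nonneg(N_total, "N_total"); check_nonneg(N_d, "N_d")
  gam <- clone$gamma_i %||% params$gamma
  ox <- heaviside(N_o - params$O_th)
  Gamma <- mm_sat(N_o, params$alpha_g) * ox + mm_sat(N_g, clone$beta_g_i) * (1 - ox)
  gam * pmax(1 - (N_total + N_d) / params$sigma, 0) * Gamma
}

#' Starvation death rate
#'
#' The shrinkage rate `delta_R` scaled by one minus a saturating survival
#' factor: oxygen-dependent (half-max `alpha_d`) under oxphos,
#' glucose-dependent (clone half-max `beta_d_i`) under glycolysis. Fully
#' starved cells die at `delta_R` per day; saturating resources drive the rate
#' to zero.
#'
#' @param clone A [clone_params()].
#' @param N_o,N_g Oxygen (mg/L) and glucose (mM).
#' @param state Metabolic state as returned by [metabolic_state()]
#'   (`"oxphos"`/`"glycolysis"`, recycled over the inputs).
#' @param params A [sim_params()].
#' @return Death rate (1/day) in `[0, delta_R]`.
#' @export
starvation_death_rate <- function(clone, N_o, N_g, state, params) {
  check_nonneg(N_o, "N_o"); check_nonneg(N_g, "N_g")
  ox <- as.numeric(state == "oxphos")
  Sv <- mm_sat(N_o, params$alpha_d) * ox + mm_sat(N_g, clone$beta_d_i) * (1 - ox)
  params$delta_R * (1 - Sv)
}

# Peak value of the biphasic migration curve phi(g) = exp(-a g) - exp(-b g),
# attained at g* = log(b/a) / (b - a). For a = 0 the curve saturates at 1.
phi_peak <- function(a_mig, b_mig) {
  stop_if(b_mig <= a_mig, "'b_mig' must exceed 'a_mig'")
  if (a_mig == 0) return(1)
  gstar <- log(b_mig / a_mig) / (b_mig - a_mig)
  exp(-a_mig * gstar) - exp(-b_mig * gstar)
}

#' Peak normalization constant over a set of clones
#'
#' The largest biphasic-curve peak across the active clones. Dividing each
#' clone's curve by this shared constant makes the fastest clone top out at
#' `v_max` while preserving relative migration differences between clones.
#'
#' @param clones List of [clone_params()].
#' @return Scalar peak value.
#' @export
migration_norm <- function(clones) {
  stop_if(length(clones) == 0, "need at least one clone")
  max(vapply(clones, function(cl) phi_peak(cl$a_mig, cl$b_mig), numeric(1)))
}

# Stiffness modifier: concave parabola c2 S^2 + c3 S clamped to [0, f_opt] and
# normalized by its maximum f_opt = -c3^2 / (4 c2).
stiffness_modifier <- function(S, params) {
  f_opt <- -params$c3^2 / (4 * params$c2)
  f <- params$c2 * S^2 + params$c3 * S
  pmin(pmax(f, 0), f_opt) / f_opt
}

#' Glucose- and stiffness-dependent migration coefficient
#'
#' `K = v_max * phi(N_g) / norm * f(S)` where `phi` is the clone's biphasic
#' glucose response and `f` the stiffness parabola normalized to its optimum.
#' With `norm` equal to the peak over all active clones (see
#' [migration_norm()]) the fastest clone at its optimal glucose and stiffness
#' migrates at exactly `v_max`.
#'
#' @param clone A [clone_params()].
#' @param N_g Glucose (mM); scalar or map.
#' @param S Tissue stiffness (Pa); scalar or map.
#' @param params A [sim_params()].
#' @param norm Peak scale; defaults to this clone's own peak so a lone clone
#'   tops out at `v_max`.
#' @return Migration coefficient (voxel^2/day) in `[0, v_max]`.
#' @export
migration_coefficient <- function(clone, N_g, S, params, norm = NULL) {
  check_nonneg(S, "S")
  check_nonneg(N_g, "N_g")
  norm <- norm %||% phi_peak(clone$a_mig, clone$b_mig)
  phi <- exp(-clone$a_mig * N_g) - exp(-clone$b_mig * N_g)
  params$v_max * (phi / norm) * stiffness_modifier(S, params)
}

#' Forward-Euler resource update
#'
#' Oxygen is consumed proportionally to live-cell density and supplied by
#' recruited vasculature; glucose likewise, with the consumption rate switching
#' from `iota_g` (oxphos) to `iota_g2` (glycolysis) below the oxygen threshold.
#' There is no spatial resource diffusion. Results are clamped at zero.
#'
#' @param state A [grid_state()].
#' @param params A [sim_params()].
#' @param dt Step size (day).
#' @return The state with updated `N_o` and `N_g` maps.
#' @export
update_resources <- function(state, params, dt) {
  stop_if(dt <= 0, "'dt' must be positive")
  Ntot <- Reduce(`+`, state$n)
  ox <- heaviside(state$No - params$O_th)
  iog <- params$iota_g * ox + params$iota_g2 * (1 - ox)
  state$No <- pmax(state$No + dt * (-params$iota_o * state$No * Ntot +
                                      params$omega_o * state$V), 0)
  state$Ng <- pmax(state$Ng + dt * (-iog * state$Ng * Ntot +
                                      params$omega_g * state$V), 0)
  state
}

#' Dead-cell clearance
#'
#' Discrete Euler update `N_d (1 - c_d dt)`; requires `c_d * dt <= 1` so the
#' update cannot overshoot into negative counts.
#'
#' @param N_d Dead cells (scalar or map).
#' @param c_d Clearance rate (1/day).
#' @param dt Step size (day).
#' @return Updated dead-cell counts.
#' @export
clear_dead <- function(N_d, c_d, dt) {
  check_nonneg(N_d, "N_d")
  stop_if(c_d * dt > 1,
          sprintf("c_d * dt = %.3g exceeds 1; reduce dt below %.3g", c_d * dt, 1 / c_d))
  N_d * (1 - c_d * dt)
}

#' Tissue stiffness field
#'
#' Baseline stiffness decays by a factor `c0` per delivered radiation fraction
#' (radiation-induced edema) and rises with tumor cell crowding once the
#' combined live + dead density exceeds 5% of carrying capacity:
#' `S = stiff_ic * c0^tr_star * (1 + c1 * dens/sigma * H(dens - 0.05 sigma))`.
#'
#' @param state A [grid_state()].
#' @param params A [sim_params()].
#' @return Stiffness map (Pa).
#' @export
stiffness_field <- function(state, params) {
  stop_if(state$tr_star < 0, "'tr_star' must be non-negative")
  dens <- Reduce(`+`, state$n) + state$Nd
  state$stiff_ic * params$c0^state$tr_star *
    (1 + params$c1 * (dens / params$sigma) * heaviside(dens - 0.05 * params$sigma))
}

# One conservative diffusion step of field n with spatially varying coefficient
# K: 5-point stencil, face coefficients are arithmetic means of the adjacent
# voxel coefficients, zero-flux boundaries. Exactly mass conserving because
# every face flux is added to one voxel and subtracted from its neighbor.
diffuse_step <- function(n, K, dt) {
  nr <- nrow(n); nc <- ncol(n)
  div <- matrix(0, nr, nc)
  if (nc > 1) {
    Ke <- 0.5 * (K[, -nc, drop = FALSE] + K[, -1, drop = FALSE])
    Fe <- Ke * (n[, -1, drop = FALSE] - n[, -nc, drop = FALSE])
    div[, -nc] <- div[, -nc] + Fe
    div[, -1] <- div[, -1] - Fe
  }
  if (nr > 1) {
    Ks <- 0.5 * (K[-nr, , drop = FALSE] + K[-1, , drop = FALSE])
    Fs <- Ks * (n[-1, , drop = FALSE] - n[-nr, , drop = FALSE])
    div[-nr, ] <- div[-nr, ] + Fs
    div[-1, ] <- div[-1, ] - Fs
  }
  n + dt * div
}

#' Conservative cell migration
#'
#' Moves each clone's density down its own gradient with the per-voxel
#' coefficient maps, as a conservative finite-difference diffusion
#' `div(K grad n)` with zero-flux boundaries: total cell mass is preserved to
#' numerical tolerance. The explicit scheme requires
#' `max(K) * dt <= 1/4` (voxel spacing 1); violations raise an error with a
#' suggested step size.
#'
#' @param state A [grid_state()].
#' @param K_maps List of per-clone coefficient maps (voxel^2/day), same order
#'   as `state$n`.
#' @param dt Step size (day).
#' @return The state with migrated `n` maps.
#' @export
migrate <- function(state, K_maps, dt) {
  stop_if(length(K_maps) != length(state$n),
          "need one coefficient map per clone")
  kmax <- max(0, vapply(K_maps, max, numeric(1)))
  stop_if(kmax * dt > 0.25 + 1e-12,
          sprintf("diffusion stability bound violated (max(K)*dt = %.3g > 0.25); use dt <= %.3g",
                  kmax * dt, 0.25 / kmax))
  for (i in seq_along(state$n)) {
    stop_if(!same_dim(K_maps[[i]], state$n[[i]]), "coefficient map shape mismatch")
    state$n[[i]] <- diffuse_step(state$n[[i]], K_maps[[i]], dt)
  }
  state
}
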