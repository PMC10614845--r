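#' Simulation parameters with literature defaults
#'
#' Constructs the full scalar parameter set of the lattice model. Defaults are
#' the literature-informed values used for glioblastoma simulations; all of
#' them can be overridden. Units are given per field.
#'
#' The per-cell consumption rates `iota_o`, `iota_g` and `iota_g2` are not part
#' of the published parameter table; their defaults are documented placeholders
#' bracketed by two requirements: a voxel crowded to carrying capacity should
#' exhaust its oxygen pool within about a week (tumor cores become hypoxic),
#' while a small premalignant focus growing at `gamma` must still be able to
#' reach the angiogenic switch density (a quarter of carrying capacity) before
#' exhausting local oxygen — otherwise stochastic vessel recruitment could
#' never activate. Glycolysis consumes glucose twice as fast as oxidative
#' phosphorylation. They are exposed here and in config files like every other
#' parameter.
#'
#' @param gamma Baseline proliferation rate (1/day).
#' @param alpha_d Oxygen concentration at which cell survival is half-maximal
#'   (mg/L).
#' @param beta_d Glucose concentration at which cell survival is half-maximal
#'   (mM); clone-specific values live in [clone_params()].
#' @param alpha_g Oxygen concentration at which proliferation is half-maximal
#'   (mg/L).
#' @param beta_g Glucose concentration at which proliferation is half-maximal
#'   (mM).
#' @param v_max Top migration speed (voxels/day).
#' @param sigma Carrying capacity (cells/voxel).
#' @param stiff0 Maximum tissue stiffness (Pa).
#' @param c0 Per-fraction radiation-induced stiffness decay base
#'   (dimensionless, in (0, 1]).
#' @param c1 Crowding-induced stiffness gain (dimensionless).
#' @param c2 Quadratic coefficient of the stiffness-migration parabola
#'   (1/Pa^2); must be negative so the parabola has a finite optimum.
#' @param c3 Linear coefficient of the stiffness-migration parabola (1/Pa).
#' @param c_d Clearance rate of dead cells (fraction/day).
#' @param delta_R Starvation shrinkage rate (fraction/day).
#' @param p0 Maximum per-day angiogenesis probability (dimensionless).
#' @param omega_g Additional glucose generated per vessel unit (mM/day).
#' @param omega_o Additional oxygen generated per vessel unit (mg/L/day).
#' @param alpha_rt Linear-quadratic radiosensitivity alpha (1/Gy).
#' @param beta_rt Linear-quadratic radiosensitivity beta (1/Gy^2).
#' @param r_star Oxygen enhancement ratio (dimensionless, >= 1).
#' @param a_Tchemo Oxygen at which the temozolomide kill rate is half-maximal
#'   (mg/L).
#' @param delta_Tc Maximum temozolomide-induced shrinkage rate (fraction/day).
#' @param O_th Oxygen threshold below which metabolism switches from oxidative
#'   phosphorylation to glycolysis (mg/L).
#' @param iota_o Per-cell oxygen consumption rate (1/(cell day)).
#' @param iota_g Per-cell glucose consumption rate under oxidative
#'   phosphorylation (1/(cell day)).
#' @param iota_g2 Per-cell glucose consumption rate under glycolysis
#'   (1/(cell day)).
#' @param dt Default Euler step size (day).
#' @param voxel_area Voxel area (mm^2).
#' @return An object of class `sim_params` (a named list of doubles).
#' @export
#' @examples
#' p <- sim_params()
#' p$gamma
#' p$sigma
sim_params <- function(gamma = 0.063,
                       alpha_d = 0.0025,
                       beta_d = 1.00,
                       alpha_g = 0.003,
                       beta_g = 2.949,
                       v_max = 0.36,
                       sigma = 15448,
                       stiff0 = 2930,
                       c0 = 0.987,
                       c1 = 6.6792,
                       c2 = -1.38e-8,
                       c3 = 2.35e-3,
                       c_d = 0.63,
                       delta_R = 0.171,
                       p0 = 0.2,
                       omega_g = 0.18204,
                       omega_o = 0.00257,
                       alpha_rt = 0.102,
                       beta_rt = 0.008,
                       r_star = 3.00,
                       a_Tchemo = 1.15,
                       delta_Tc = 0.0196,
                       O_th = 0.0510,
                       iota_o = 1.2e-5,
                       iota_g = 1.2e-5,
                       iota_g2 = 2.4e-5,
                       dt = 0.1,
                       voxel_area = 4) {
  p <- lapply(
    list(gamma = gamma, alpha_d = alpha_d, beta_d = beta_d, alpha_g = alpha_g,
         beta_g = beta_g, v_max = v_max, sigma = sigma, stiff0 = stiff0,
         c0 = c0, c1 = c1, c2 = c2, c3 = c3, c_d = c_d, delta_R = delta_R,
         p0 = p0, omega_g = omega_g, omega_o = omega_o, alpha_rt = alpha_rt,
         beta_rt = beta_rt, r_star = r_star, a_Tchemo = a_Tchemo,
         delta_Tc = delta_Tc, O_th = O_th, iota_o = iota_o, iota_g = iota_g,
         iota_g2 = iota_g2, dt = dt, voxel_area = voxel_area),
    function(x) {
      stop_if(length(x) != 1 || !is.numeric(x), "all parameters must be scalar numerics")
      as.numeric(x)
    }
  )
  nonneg <- setdiff(names(p), "c2")
  for (nm in nonneg) check_nonneg(p[[nm]], nm)
  stop_if(p$p0 > 1, "'p0' must lie in [0, 1]")
  stop_if(p$c0 <= 0 || p$c0 > 1, "'c0' must lie in (0, 1]")
  stop_if(p$c2 >= 0, "'c2' must be negative (concave stiffness-migration parabola)")
  stop_if(p$r_star < 1, "'r_star' must be >= 1")
  stop_if(p$dt <= 0, "'dt' must be positive")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (", length(unclass(x)), " scalars)\n", sep = "")
  df <- data.frame(value = unlist(unclass(x)))
  print(df, ...)
  invisible(x)
}

#' Per-clone parameters
#'
#' A clone is characterised by its ploidy (DNA content), its glucose
#' half-maximum constants for survival (`beta_d_i`) and proliferation
#' (`beta_g_i`), and the two rate constants of its biphasic
#' glucose-dependent migration curve
#' \eqn{\phi(g) = e^{-a_{mig} g} - e^{-b_{mig} g}}, which is non-negative for
#' `b_mig > a_mig`, zero at zero glucose, and peaks at
#' \eqn{g^* = \log(b/a)/(b-a)}.
#'
#' @param label Clone name.
#' @param ploidy DNA content relative to haploid (2 = diploid, 4 = tetraploid).
#' @param beta_d_i Glucose at which survival is half-maximal (mM).
#' @param beta_g_i Glucose at which proliferation is half-maximal (mM).
#' @param a_mig,b_mig Biphasic migration rate constants (1/mM), `b_mig > a_mig`.
#' @param gamma_i Optional clone-specific proliferation rate (1/day); when
#'   `NULL` the shared [sim_params()] `gamma` is used.
#' @return An object of class `clone_params`.
#' @export
#' @examples
#' clone_params("2N", ploidy = 2, beta_d_i = 1.0, beta_g_i = 2.9,
#'              a_mig = 0.53, b_mig = 0.57)
clone_params <- function(label, ploidy, beta_d_i, beta_g_i, a_mig, b_mig,
                         gamma_i = NULL) {
  stop_if(!is.character(label) || length(label) != 1, "'label' must be a string")
  stop_if(ploidy <= 0, "'ploidy' must be positive")
  check_nonneg(beta_d_i, "beta_d_i")
  check_nonneg(beta_g_i, "beta_g_i")
  check_nonneg(a_mig, "a_mig")
  check_nonneg(b_mig, "b_mig")
  stop_if(b_mig <= a_mig,
          "'b_mig' must exceed 'a_mig' (non-negative biphasic migration curve)")
  if (!is.null(gamma_i)) check_nonneg(gamma_i, "gamma_i")
  structure(list(label = label, ploidy = as.numeric(ploidy),
                 beta_d_i = as.numeric(beta_d_i), beta_g_i = as.numeric(beta_g_i),
                 a_mig = as.numeric(a_mig), b_mig = as.numeric(b_mig),
                 gamma_i = if (is.null(gamma_i)) NULL else as.numeric(gamma_i)),
            class = "clone_params")
}

#' @export
print.clone_params <- function(x, ...) {
  cat(sprintf("Clone '%s': ploidy %.3g, beta_d %.4g mM, beta_g %.4g mM, migration (%.3g, %.3g) 1/mM\n",
              x$label, x$ploidy, x$beta_d_i, x$beta_g_i, x$a_mig, x$b_mig))
  invisible(x)
}

#' In-vitro 2N/4N biphasic migration constants
#'
#' The rate constants of the glucose-dependent biphasic migration curve
#' measured for isogenic near-diploid and near-tetraploid cells:
#' (0.53, 0.57) 1/mM for 2N and (0.34, 0.95) 1/mM for 4N. The 4N curve lies
#' above the 2N curve at every positive glucose concentration.
#'
#' @param ploidy_class `"2N"` or `"4N"`.
#' @return Named numeric vector `c(a_mig, b_mig)`.
#' @export
migration_constants <- function(ploidy_class = c("2N", "4N")) {
  ploidy_class <- match.arg(ploidy_class)
  switch(ploidy_class,
         "2N" = c(a_mig = 0.53, b_mig = 0.57),
         "4N" = c(a_mig = 0.34, b_mig = 0.95))
}

#' The two aneuploid clones fitted to the patient data
#'
#' Glucose-response constants of the low-ploidy (1.98) and high-ploidy (2.29)
#' clones inferred from longitudinal patient imaging: survival half-max 1.17
#' vs 2.13 mM and proliferation half-max 1.66 vs 1.72 mM. The low-ploidy clone
#' carries the in-vitro 2N migration curve and the high-ploidy clone the 4N
#' curve, preserving the measured relative migration differences.
#'
#' @return List with elements `low` and `high`, both [clone_params()].
#' @export
#' @examples
#' fitted_patient_clones()$high$beta_d_i
fitted_patient_clones <- function() {
  m2 <- migration_constants("2N")
  m4 <- migration_constants("4N")
  list(
    low = clone_params("clone1", ploidy = 1.98, beta_d_i = 1.17,
                       beta_g_i = 1.66, a_mig = m2[["a_mig"]], b_mig = m2[["b_mig"]]),
    high = clone_params("clone2", ploidy = 2.29, beta_d_i = 2.13,
                        beta_g_i = 1.72, a_mig = m4[["a_mig"]], b_mig = m4[["b_mig"]])
  )
}

#' Extrapolate clone glucose-response constants along ploidy
#'
#' Higher-ploidy cells need more resources to replicate their larger genome, so
#' their glucose half-maximum constants shift upward. Given two fitted clones,
#' this extrapolates `beta_d_i` and `beta_g_i` to a target ploidy, either
#' linearly in ploidy or log-linearly (a power law in the ploidy ratio).
#' Extrapolated constants are clamped to stay positive. Migration constants are
#' not extrapolated: the target clone inherits the measured 2N or 4N curve by
#' nearest canonical ploidy. If the target ploidy coincides with one of the
#' fitted knots, that clone is returned unchanged.
#'
#' @param fitted_low,fitted_high Two [clone_params()] with distinct ploidies.
#' @param target_ploidy Ploidy to extrapolate to (> 0).
#' @param mode `"linear"` (default, straight line through the two fitted
#'   points) or `"loglinear"` (linear in log-constants vs log-ploidy).
#' @param label Optional label for the new clone.
#' @return A [clone_params()] at the target ploidy.
#' @export
#' @examples
#' cl <- fitted_patient_clones()
#' extrapolate_clone_params(cl$low, cl$high, target_ploidy = 4)
extrapolate_clone_params <- function(fitted_low, fitted_high, target_ploidy,
                                     mode = c("linear", "loglinear"),
                                     label = NULL) {
  mode <- match.arg(mode)
  stop_if(!inherits(fitted_low, "clone_params") || !inherits(fitted_high, "clone_params"),
          "fitted clones must be 'clone_params' objects")
  stop_if(target_ploidy <= 0, "'target_ploidy' must be positive")
  p1 <- fitted_low$ploidy
  p2 <- fitted_high$ploidy
  stop_if(p1 == p2, "fitted clones have identical ploidies: extrapolation is degenerate")
  if (target_ploidy == p1) return(fitted_low)
  if (target_ploidy == p2) return(fitted_high)

  interp <- function(y1, y2) {
    if (mode == "linear") {
      y1 + (y2 - y1) / (p2 - p1) * (target_ploidy - p1)
    } else {
      # power law beta ~ ploidy^k through the two knots
      exp(log(y1) + (log(y2) - log(y1)) / (log(p2) - log(p1)) *
            (log(target_ploidy) - log(p1)))
    }
  }
  eps <- 1e-6
  bd <- max(eps, interp(fitted_low$beta_d_i, fitted_high$beta_d_i))
  bg <- max(eps, interp(fitted_low$beta_g_i, fitted_high$beta_g_i))
  mig <- migration_constants(if (abs(target_ploidy - 2) <= abs(target_ploidy - 4)) "2N" else "4N")
  g1 <- fitted_low$gamma_i
  g2 <- fitted_high$gamma_i
  gam <- if (!is.null(g1) && !is.null(g2) && g1 == g2) g1 else NULL
  clone_params(label %||% sprintf("ploidy%.3g", target_ploidy),
               ploidy = target_ploidy, beta_d_i = bd, beta_g_i = bg,
               a_mig = mig[["a_mig"]], b_mig = mig[["b_mig"]], gamma_i = gam)
}

# ---- structured config (YAML) -----------------------------------------------

clone_to_list <- function(cl) {
  out <- list(label = cl$label, ploidy = cl$ploidy, beta_d_i = cl$beta_d_i,
              beta_g_i = cl$beta_g_i, a_mig = cl$a_mig, b_mig = cl$b_mig)
  if (!is.null(cl$gamma_i)) out$gamma_i <- cl$gamma_i
  out
}

#' Write model parameters (and clones) to a YAML config file
#'
#' Every parameter is stored under its own named key with 17 significant
#' digits, so a write/read round trip reproduces the doubles bit-exactly.
#'
#' @param path Output file path.
#' @param params A [sim_params()] object.
#' @param clones Optional list of [clone_params()].
#' @return `path`, invisibly.
#' @export
write_model_config <- function(path, params, clones = list()) {
  stop_if(!inherits(params, "sim_params"), "'params' must be a 'sim_params' object")
  cfg <- list(params = unclass(params))
  if (length(clones)) cfg$clones <- lapply(clones, clone_to_list)
  writeLines(yaml::as.yaml(cfg, precision = 17L), path)
  invisible(path)
}

#' Read model parameters (and clones) from a YAML config file
#'
#' Unknown keys are rejected so typos in parameter names fail loudly rather
#' than silently falling back to defaults.
#'
#' @param path Config file written by [write_model_config()] or by hand.
#' @return List with elements `params` ([sim_params()]) and `clones` (list of
#'   [clone_params()], possibly empty).
#' @export
read_model_config <- function(path) {
  stop_if(!file.exists(path), sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  extra <- setdiff(names(cfg), c("params", "clones"))
  stop_if(length(extra) > 0,
          "unknown top-level config keys: ", paste(extra, collapse = ", "))
  pl <- cfg$params %||% list()
  known <- names(formals(sim_params))
  extra <- setdiff(names(pl), known)
  stop_if(length(extra) > 0,
          "unknown parameter keys: ", paste(extra, collapse = ", "))
  params <- do.call(sim_params, lapply(pl, as.numeric))
  clones <- lapply(cfg$clones %||% list(), function(cl) {
    known_cl <- c("label", "ploidy", "beta_d_i", "beta_g_i", "a_mig", "b_mig", "gamma_i")
    extra <- setdiff(names(cl), known_cl)
    stop_if(length(extra) > 0,
            "unknown clone keys: ", paste(extra, collapse = ", "))
    do.call(clone_params, cl)
  })
  list(params = params, clones = clones)
}
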