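#' Full per-voxel state of the lattice
#'
#' Holds one live-cell density map per clone, the dead-cell map, oxygen,
#' glucose, recruited-vessel counts, baseline stiffness, the cumulative
#' resection mask, the count of delivered radiation fractions and the
#' simulation day. All maps share one shape and all counts are non-negative.
#'
#' @param atlases An [atlas_set()] supplying initial glucose, oxygen and
#'   baseline stiffness.
#' @param initial Named list of per-clone live-cell density matrices matching
#'   the atlas shape.
#' @return An object of class `grid_state`.
#' @export
grid_state <- function(atlases, initial) {
  stop_if(!inherits(atlases, "atlas_set"), "'atlases' must be an 'atlas_set'")
  stop_if(length(initial) == 0, "need at least one clone density map")
  for (m in initial) {
    stop_if(!same_dim(m, atlases$glucose), "initial map shape does not match the atlas")
    check_nonneg(m, "initial cell densities")
  }
  z <- zero_like(atlases$glucose)
  structure(list(n = initial, Nd = z, No = atlases$oxygen, Ng = atlases$glucose,
                 V = z, stiff_ic = atlases$stiffness, cavity = z,
                 tr_star = 0, day = 0),
            class = "grid_state")
}

#' @export
print.grid_state <- function(x, ...) {
  tot <- vapply(x$n, sum, numeric(1))
  cat(sprintf("Grid state %dx%d, day %g\n", nrow(x$Nd), ncol(x$Nd), x$day))
  cat("  live cells:", paste(sprintf("%s=%.4g", names(x$n) %||% seq_along(x$n), tot),
                             collapse = ", "), "\n")
  cat(sprintf("  dead %.4g, vessels %g, fractions delivered %g\n",
              sum(x$Nd), sum(x$V), x$tr_star))
  invisible(x)
}

#' Simulation run configuration
#'
#' Bundles everything a run needs: scalar parameters, clones, atlases, initial
#' per-clone density maps, an optional treatment schedule, duration, step
#' size, seed and output cadence. The sub-day step size must divide one day
#' evenly (vascular recruitment is drawn once per simulated day).
#'
#' @param params A [sim_params()].
#' @param clones List of [clone_params()], one per initial map.
#' @param atlases An [atlas_set()].
#' @param initial Named list of per-clone initial density matrices.
#' @param schedule Optional [treatment_schedule()].
#' @param duration Simulated days (> 0, integer).
#' @param dt Euler step (day); defaults to `params$dt`.
#' @param seed Integer seed controlling the stochastic vasculature draws.
#' @param cadence Snapshot interval in days.
#' @param record_maps If `TRUE`, store the total live-density map at every
#'   snapshot (needed by [fit_simulation_params()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(params, clones, atlases, initial, schedule = NULL,
                       duration, dt = params$dt, seed = 1, cadence = 1,
                       record_maps = FALSE) {
  stop_if(!inherits(params, "sim_params"), "'params' must be 'sim_params'")
  stop_if(length(clones) != length(initial),
          "need exactly one clone per initial density map")
  stop_if(duration < 0, "'duration' must be non-negative")
  spd <- round(1 / dt)
  stop_if(spd < 1 || abs(spd * dt - 1) > 1e-9,
          "'dt' must divide one day evenly (e.g. 0.5, 0.25, 0.1, 0.05)")
  if (is.null(names(initial))) {
    names(initial) <- vapply(clones, `[[`, character(1), "label")
  }
  if (!is.null(schedule)) {
    stop_if(!inherits(schedule, "treatment_schedule"),
            "'schedule' must be a 'treatment_schedule'")
  }
  structure(list(params = params, clones = clones, atlases = atlases,
                 initial = initial, schedule = schedule,
                 duration = as.integer(duration), steps_per_day = spd,
                 seed = as.integer(seed), cadence = as.integer(cadence),
                 record_maps = isTRUE(record_maps),
                 mig_norm = migration_norm(clones)),
            class = "run_config")
}

# One Euler substep of the continuous dynamics, in the model's update order:
# death (starvation + TMZ) -> clearance -> proliferation -> migration ->
# resources. The metabolic mask is evaluated once at substep entry.
substep <- function(state, p, clones, dt, tmz_on, norm) {
  ox <- heaviside(state$No - p$O_th)
  gly <- 1 - ox
  Sv_ox <- mm_sat(state$No, p$alpha_d)
  tmz <- if (tmz_on) p$delta_Tc * mm_sat(state$No, p$a_Tchemo) else 0

  active <- vapply(state$n, function(m) sum(m) > 1e-9, logical(1))

  # death: killed cells transfer to the dead compartment
  died <- zero_like(state$Nd)
  for (i in seq_along(state$n)) {
    if (!active[i]) next
    cl <- clones[[i]]
    Sv <- Sv_ox * ox + mm_sat(state$Ng, cl$beta_d_i) * gly
    frac <- pmin((p$delta_R * (1 - Sv) + tmz) * dt, 1)
    k <- state$n[[i]] * frac
    state$n[[i]] <- state$n[[i]] - k
    died <- died + k
  }
  state$Nd <- state$Nd + died
  state$Nd <- state$Nd * (1 - p$c_d * dt)

  # proliferation (crowding uses post-death totals)
  Ntot <- Reduce(`+`, state$n)
  cap <- pmax(1 - (Ntot + state$Nd) / p$sigma, 0)
  G_ox <- mm_sat(state$No, p$alpha_g)
  for (i in seq_along(state$n)) {
    if (!active[i]) next
    cl <- clones[[i]]
    G <- G_ox * ox + mm_sat(state$Ng, cl$beta_g_i) * gly
    gam <- cl$gamma_i %||% p$gamma
    state$n[[i]] <- state$n[[i]] + dt * gam * state$n[[i]] * cap * G
  }

  # migration
  S <- stiffness_field(state, p)
  fh <- stiffness_modifier(S, p)
  K_maps <- vector("list", length(state$n))
  for (i in seq_along(state$n)) {
    cl <- clones[[i]]
    K_maps[[i]] <- if (active[i]) {
      p$v_max * ((exp(-cl$a_mig * state$Ng) - exp(-cl$b_mig * state$Ng)) / norm) * fh
    } else zero_like(state$Nd)
  }
  state <- migrate(state, K_maps, dt)

  # resources (forward Euler, clamped at zero)
  update_resources(state, p, dt)
}

#' Advance the simulation by one day
#'
#' Applies, in order: scheduled surgery; the radiation pulse of any fraction
#' due today (killed cells move to the dead compartment and the delivered
#' fraction count increments); then the sub-day Euler substeps of death
#' (starvation plus TMZ on active days), dead-cell clearance, proliferation,
#' conservative migration and resource consumption/supply; and finally one
#' stochastic vasculature recruitment draw (recruitment probabilities are
#' per day). Non-negativity is preserved by construction.
#'
#' @param state A [grid_state()].
#' @param cfg A [run_config()].
#' @return The state advanced by one day.
#' @export
sim_step <- function(state, cfg) {
  p <- cfg$params
  today <- state$day
  dt <- 1 / cfg$steps_per_day
  sch <- cfg$schedule

  if (!is.null(sch)) {
    for (s in sch$surgeries) {
      if (s$day == today) state <- apply_surgery(state, s$cavity)
    }
    due <- sch$rt_fractions$day == today
    if (any(due)) {
      for (dose in sch$rt_fractions$dose[due]) {
        sf <- radiation_survival(dose, state$No, p)
        for (i in seq_along(state$n)) {
          killed <- state$n[[i]] * (1 - sf)
          state$n[[i]] <- state$n[[i]] - killed
          state$Nd <- state$Nd + killed
        }
        state$tr_star <- state$tr_star + 1
      }
    }
  }
  tmz_on <- !is.null(sch) && (today %in% sch$tmz_days)

  for (s in seq_len(cfg$steps_per_day)) {
    state <- substep(state, p, cfg$clones, dt, tmz_on, cfg$mig_norm)
  }
  state <- recruit(state, p)
  state$day <- today + 1
  state
}

snapshot_row <- function(state) {
  tot <- vapply(state$n, sum, numeric(1))
  mx <- vapply(state$n, max, numeric(1))
  labels <- names(state$n) %||% as.character(seq_along(state$n))
  row <- c(day = state$day, live_total = sum(tot), dead = sum(state$Nd),
           mean_o2 = mean(state$No), mean_glc = mean(state$Ng),
           total_v = sum(state$V))
  names(tot) <- paste0("live_", labels)
  names(mx) <- paste0("maxvox_", labels)
  c(row, tot, mx)
}

#' Run a full simulation
#'
#' Iterates [sim_step()] over the configured duration with a seeded RNG,
#' recording summary snapshots (and optionally total-density maps) at the
#' configured cadence. The initial state (day 0) is always included. Each
#' snapshot is audited: any non-finite or negative field aborts the run with
#' a diagnostic.
#'
#' @param cfg A [run_config()].
#' @return An object of class `trajectory` with elements `summary` (data
#'   frame, one row per snapshot), `maps` (list of total-density matrices or
#'   `NULL`), `final_state` and `config`.
#' @export
run_simulation <- function(cfg) {
  state <- grid_state(cfg$atlases, cfg$initial)
  days <- seq_len(cfg$duration)
  snap_days <- c(0, days[days %% cfg$cadence == 0 | days == cfg$duration])
  rows <- vector("list", length(snap_days))
  maps <- if (cfg$record_maps) vector("list", length(snap_days)) else NULL
  k <- 1
  audit <- function(st) {
    for (nm in c("Nd", "No", "Ng", "V")) {
      stop_if(any(!is.finite(st[[nm]])),
              sprintf("non-finite values in '%s' at day %g: unstable step size?", nm, st$day))
      stop_if(any(st[[nm]] < 0), sprintf("negative values in '%s' at day %g", nm, st$day))
    }
    for (m in st$n) {
      stop_if(any(!is.finite(m)), sprintf("non-finite cell densities at day %g", st$day))
      stop_if(any(m < -1e-9), sprintf("negative cell densities at day %g", st$day))
    }
  }
  record <- function(st) {
    rows[[k]] <<- snapshot_row(st)
    if (cfg$record_maps) maps[[k]] <<- Reduce(`+`, st$n)
    k <<- k + 1
  }
  withr::with_seed(cfg$seed, {
    audit(state)
    record(state)
    for (d in days) {
      state <- sim_step(state, cfg)
      if (d %% cfg$cadence == 0 || d == cfg$duration) {
        audit(state)
        record(state)
      }
    }
  })
  summary <- as.data.frame(do.call(rbind, rows))
  if (cfg$record_maps) names(maps) <- summary$day
  structure(list(summary = summary, maps = maps, final_state = state,
                 config = cfg),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Trajectory: %d snapshots over %g days\n", nrow(s), max(s$day)))
  cat(sprintf("  final live %.4g, dead %.4g, vessels %g\n",
              s$live_total[nrow(s)], s$dead[nrow(s)], s$total_v[nrow(s)]))
  invisible(x)
}

first_day_below <- function(summary, col, threshold = 1) {
  hit <- summary$day[summary[[col]] < threshold]
  if (length(hit)) min(hit) else NA_real_
}

#' Premalignant diploid/tetraploid competition experiment
#'
#' Seeds a 1,000-cell premalignant population, half diploid and half
#' tetraploid (glucose-response constants extrapolated from the two fitted
#' patient clones to ploidy 2 and 4), into a single central voxel of a
#' synthetic brain region and lets the clones compete. A clone is extinct on
#' the first day its maximum per-voxel cell representation falls below 1 cell.
#'
#' @param preset `"low_glucose"` (mean 1.22 mM) or `"high_glucose"`
#'   (mean 2.36 mM) region.
#' @param seed Integer seed (controls both the atlas and the stochastic
#'   angiogenesis draws).
#' @param shape Grid dimensions.
#' @param duration Simulated days (default three years).
#' @param n_cells Total seeded cells (split 50:50).
#' @param params A [sim_params()].
#' @param dt Euler step (day).
#' @param clones Optional list of exactly two clones to compete (defaults to
#'   the extrapolated 2N and 4N clones).
#' @return List with `trajectory`, `clones`, per-clone `extinction_day`
#'   (`NA` if never extinct) and `alive_at_end`.
#' @export
experiment_premalignant <- function(preset = c("low_glucose", "high_glucose"),
                                    seed = 1, shape = c(64, 64),
                                    duration = 1095, n_cells = 1000,
                                    params = sim_params(), dt = params$dt,
                                    clones = NULL) {
  preset <- match.arg(preset)
  if (is.null(clones)) {
    fitted <- fitted_patient_clones()
    clones <- list(
      extrapolate_clone_params(fitted$low, fitted$high, 2, label = "2N"),
      extrapolate_clone_params(fitted$low, fitted$high, 4, label = "4N")
    )
  }
  stop_if(length(clones) != 2, "the competition experiment takes exactly two clones")
  atl <- synthetic_atlases(shape, seed = seed, preset = preset)
  center <- pmax(1, round(shape / 2))
  mk <- function() {
    m <- zero_like(atl$glucose)
    m[center[1], center[2]] <- n_cells / 2
    m
  }
  initial <- list(mk(), mk())
  names(initial) <- vapply(clones, `[[`, character(1), "label")
  cfg <- run_config(params, clones, atl, initial, duration = duration,
                    dt = dt, seed = seed, cadence = 1)
  traj <- run_simulation(cfg)
  labels <- names(initial)
  ext <- vapply(labels, function(lb)
    first_day_below(traj$summary, paste0("maxvox_", lb)), numeric(1))
  alive <- vapply(labels, function(lb)
    traj$summary[[paste0("maxvox_", lb)]][nrow(traj$summary)] >= 1, logical(1))
  list(trajectory = traj, clones = clones, extinction_day = ext,
       alive_at_end = alive)
}

# Synthetic post-surgery tumor bed: an isotropic Gaussian bolus of total_cells
# centered on the grid, truncated at the carrying capacity.
synthetic_tumor_map <- function(shape, total_cells, width = shape[1] / 10,
                                sigma_cap = Inf) {
  r <- outer((seq_len(shape[1]) - (shape[1] + 1) / 2)^2,
             (seq_len(shape[2]) - (shape[2] + 1) / 2)^2, `+`)
  m <- exp(-r / (2 * width^2))
  m <- m / sum(m) * total_cells
  pmin(m, sigma_cap)
}

log_burden_slope <- function(summary, window = 90) {
  s <- summary[summary$day >= max(summary$day) - window, ]
  stats::coef(stats::lm(log(pmax(s$live_total, 1e-9)) ~ s$day))[[2]]
}

#' Recurrence experiment: purely diploid vs purely tetraploid tumors
#'
#' Initializes the same synthetic post-surgery tumor bed (a Gaussian cell
#' bolus, 2.1 million cells by default) with either a purely diploid or a
#' purely tetraploid population, runs both with identical seeds (with or
#' without adjuvant chemoradiation), and summarizes progression as the slope
#' of log total burden over the final 90 days.
#'
#' @param therapy If `TRUE`, apply the standard chemoradiation preset
#'   ([schedule_stupp()]) starting on day 7.
#' @param seed Integer seed shared by both runs.
#' @param shape Grid dimensions.
#' @param duration Simulated days.
#' @param total_cells Initial tumor burden (cells).
#' @param preset Atlas preset for the tumor bed.
#' @param params A [sim_params()].
#' @param dt Euler step (day).
#' @param slope_window Days at the end of the run over which the log-burden
#'   slope is measured.
#' @return List with `trajectories` (named `2N`, `4N`), `progression_rate`
#'   (log-burden slopes, 1/day) and `rate_ratio` (4N over 2N).
#' @export
experiment_recurrence <- function(therapy = TRUE, seed = 1, shape = c(64, 64),
                                  duration = 240, total_cells = 2.1e6,
                                  preset = "high_glucose",
                                  params = sim_params(), dt = params$dt,
                                  slope_window = 90) {
  fitted <- fitted_patient_clones()
  clones <- list(
    "2N" = extrapolate_clone_params(fitted$low, fitted$high, 2, label = "2N"),
    "4N" = extrapolate_clone_params(fitted$low, fitted$high, 4, label = "4N")
  )
  atl <- synthetic_atlases(shape, seed = seed, preset = preset)
  init_map <- synthetic_tumor_map(shape, total_cells, sigma_cap = params$sigma)
  sch <- if (therapy) schedule_stupp(start_day = 7) else NULL
  runs <- lapply(clones, function(cl) {
    cfg <- run_config(params, list(cl), atl,
                      stats::setNames(list(init_map), cl$label),
                      schedule = sch, duration = duration, dt = dt,
                      seed = seed, cadence = 1)
    run_simulation(cfg)
  })
  rates <- vapply(runs, function(tr) log_burden_slope(tr$summary, slope_window),
                  numeric(1))
  list(trajectories = runs, progression_rate = rates,
       rate_ratio = rates[["4N"]] / rates[["2N"]])
}

# Replace free parameters (global sim_params fields or per-clone constants
# named like "beta_d_i.<label>") in a run_config.
apply_free_params <- function(cfg, theta) {
  for (nm in names(theta)) {
    if (grepl("\\.", nm)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      field <- parts[1]; label <- parts[2]
      hit <- which(vapply(cfg$clones, `[[`, character(1), "label") == label)
      stop_if(length(hit) != 1, sprintf("unknown clone '%s' in free parameter '%s'", label, nm))
      cfg$clones[[hit]][[field]] <- theta[[nm]]
    } else {
      stop_if(!nm %in% names(cfg$params), sprintf("unknown parameter '%s'", nm))
      cfg$params[[nm]] <- theta[[nm]]
    }
  }
  cfg$mig_norm <- migration_norm(cfg$clones)
  cfg
}

# Collapse a multi-clone config to a single aggregate clone (summed initial
# densities, averaged glucose constants) for stage-1 fitting.
aggregate_config <- function(cfg) {
  if (length(cfg$clones) == 1) return(cfg)
  cl1 <- cfg$clones[[1]]
  agg <- clone_params("aggregate",
                      ploidy = mean(vapply(cfg$clones, `[[`, numeric(1), "ploidy")),
                      beta_d_i = mean(vapply(cfg$clones, `[[`, numeric(1), "beta_d_i")),
                      beta_g_i = mean(vapply(cfg$clones, `[[`, numeric(1), "beta_g_i")),
                      a_mig = cl1$a_mig, b_mig = cl1$b_mig)
  cfg$clones <- list(agg)
  cfg$initial <- stats::setNames(list(Reduce(`+`, cfg$initial)), "aggregate")
  cfg$mig_norm <- migration_norm(cfg$clones)
  cfg
}

#' Fit model parameters to observed density maps
#'
#' Minimizes the voxelwise squared error between simulated and observed total
#' cell-density maps over a chosen subset of free parameters
#' (`v_max`, `delta_R`, or per-clone `beta_d_i.<label>` / `beta_g_i.<label>`).
#' The objective freezes the simulation RNG per evaluation (the config seed),
#' so it is deterministic given the parameters. Fitting runs in two stages:
#' stage 1 fits with a single aggregate clone; stage 2 restarts from the
#' stage-1 solution with the full clone set. Single-parameter problems use
#' golden-section search on the bound interval; multi-parameter problems use
#' a derivative-free Nelder-Mead simplex with multiple deterministic starts.
#'
#' @param observed List with elements `days` (vector of observation days) and
#'   `maps` (list of observed total-density matrices, same order).
#' @param free Character vector of free parameter names.
#' @param bounds Named list of `c(lower, upper)` per free parameter; the
#'   search is confined to the box.
#' @param cfg A [run_config()] describing the fixed setting (duration must
#'   cover the observation days).
#' @param n_starts Nelder-Mead starts for multi-parameter problems.
#' @param tol Relative convergence tolerance.
#' @return List with `par` (named fitted values), `objective`, `trace`
#'   (data frame of evaluated points) and `stage1` (stage-1 solution).
#' @export
fit_simulation_params <- function(observed, free, bounds, cfg, n_starts = 5,
                                  tol = 1e-3) {
  stop_if(length(observed$days) < 1, "need at least one observation time")
  stop_if(length(observed$days) != length(observed$maps),
          "'days' and 'maps' must align")
  stop_if(!setequal(names(bounds), free), "'bounds' must name every free parameter")
  for (b in bounds) stop_if(length(b) != 2 || b[1] >= b[2], "each bound must be c(lower, upper)")
  stop_if(max(observed$days) > cfg$duration,
          "config duration does not cover the observation days")

  cfg$record_maps <- TRUE
  cfg$cadence <- 1L
  trace_env <- new.env()
  trace_env$rows <- list()

  make_obj <- function(base_cfg) {
    function(theta) {
      theta <- stats::setNames(pmin(pmax(theta, vapply(bounds[free], `[`, numeric(1), 1)),
                                    vapply(bounds[free], `[`, numeric(1), 2)), free)
      cfg2 <- apply_free_params(base_cfg, as.list(theta))
      traj <- run_simulation(cfg2)
      obj <- 0
      for (i in seq_along(observed$days)) {
        sim <- traj$maps[[as.character(observed$days[i])]]
        obj <- obj + sum((sim - observed$maps[[i]])^2)
      }
      stop_if(!is.finite(obj), "non-finite fitting objective")
      trace_env$rows[[length(trace_env$rows) + 1]] <- c(theta, objective = obj)
      obj
    }
  }

  lower <- vapply(bounds[free], `[`, numeric(1), 1)
  upper <- vapply(bounds[free], `[`, numeric(1), 2)

  optimize_stage <- function(base_cfg, start) {
    obj <- make_obj(base_cfg)
    if (length(free) == 1) {
      span <- upper - lower
      int <- c(max(lower, start - 0.35 * span), min(upper, start + 0.35 * span))
      if (int[1] >= int[2]) int <- c(lower, upper)
      opt <- stats::optimize(obj, interval = int, tol = tol * span)
      list(par = stats::setNames(opt$minimum, free), value = opt$objective)
    } else {
      span <- upper - lower
      starts <- lapply(seq_len(n_starts), function(s) {
        if (s == 1) start
        else lower + span * ((seq_along(free) * s * 0.381966) %% 1)
      })
      best <- NULL
      for (st in starts) {
        opt <- stats::optim(st, obj, method = "Nelder-Mead",
                            control = list(reltol = tol, maxit = 200))
        if (is.null(best) || opt$value < best$value) best <- opt
      }
      list(par = stats::setNames(pmin(pmax(best$par, lower), upper), free),
           value = best$value)
    }
  }

  mid <- (lower + upper) / 2
  stage1 <- optimize_stage(aggregate_config(cfg), mid)
  stage2 <- optimize_stage(cfg, stage1$par)

  trace <- as.data.frame(do.call(rbind, trace_env$rows))
  list(par = stage2$par, objective = stage2$value, trace = trace,
       stage1 = stage1)
}

#' Rank correlation between tissue resource levels and cancer ploidy
#'
#' Spearman rank correlation (two-sided, average ranks for ties) between a
#' per-organ resource level (e.g. median glucose uptake or oxygen partial
#' pressure) and the median ploidy of cancers arising in that organ.
#'
#' @param table Data frame with at least the columns named by `resource_col`
#'   and `ploidy_col`; 4 or more rows required.
#' @param resource_col,ploidy_col Column names.
#' @return List with `rho`, `p_value`, `n`.
#' @export
#' @examples
#' tab <- data.frame(organ = letters[1:5],
#'                   resource = c(5, 3, 9, 1, 7),
#'                   ploidy = c(2.1, 2.0, 3.4, 1.9, 2.9))
#' resource_ploidy_correlation(tab)
resource_ploidy_correlation <- function(table, resource_col = "resource",
                                        ploidy_col = "ploidy") {
  stop_if(nrow(table) < 4, "need at least 4 organs/rows")
  x <- table[[resource_col]]
  y <- table[[ploidy_col]]
  stop_if(is.null(x) || is.null(y), "resource or ploidy column not found")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(table))
}
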