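#' Radiation surviving fraction with oxygen enhancement
#'
#' Linear-quadratic survival with an oxygen-dependent dose-modifying factor.
#' The oxygen enhancement ratio follows an Alper-Howard-Flanders-style curve
#' `OER(N_o) = (r_star N_o + K_m) / (N_o + K_m)` with half-effect constant
#' `K_m = alpha_d` (the model's oxygen survival scale), rising from 1 at
#' anoxia to `r_star` at full oxygenation. The effective dose is
#' `dose * OER / r_star`, so a fully oxygenated voxel receives the nominal
#' dose and an anoxic voxel an `r_star`-fold smaller one; survival is
#' `exp(-(alpha_rt d_eff + beta_rt d_eff^2))`.
#'
#' @param dose Physical dose (Gy), non-negative.
#' @param N_o Oxygen concentration (mg/L); scalar or map.
#' @param params A [sim_params()].
#' @return Surviving fraction in (0, 1], same shape as `N_o`.
#' @export
#' @examples
#' radiation_survival(2, N_o = 10, params = sim_params())
radiation_survival <- function(dose, N_o, params) {
  stop_if(any(dose < 0), "'dose' must be non-negative")
  check_nonneg(N_o, "N_o")
  Km <- params$alpha_d
  oer <- (params$r_star * N_o + Km) / (N_o + Km)
  d_eff <- dose * oer / params$r_star
  exp(-(params$alpha_rt * d_eff + params$beta_rt * d_eff^2))
}

#' Temozolomide-induced death rate
#'
#' TMZ kills proportionally to oxygenation (the drug needs oxygen to be
#' effective): `delta_Tc * N_o / (N_o + a_Tchemo)` on active days, 0 otherwise.
#'
#' @param N_o Oxygen concentration (mg/L); scalar or map.
#' @param params A [sim_params()].
#' @param active Whether TMZ is being administered.
#' @return Death rate (1/day) in `[0, delta_Tc]`.
#' @export
tmz_death_rate <- function(N_o, params, active = TRUE) {
  check_nonneg(N_o, "N_o")
  if (!active) return(0 * N_o)
  params$delta_Tc * mm_sat(N_o, params$a_Tchemo)
}

#' Apply a surgical resection
#'
#' Inside the cavity all live and dead cells are removed, baseline stiffness
#' drops by a tenth (loss of tissue integrity), and glucose and oxygen halve
#' (loss of the local perfusion pattern); voxels outside are untouched. The
#' cavity is accumulated into the state's resection mask. Applying the same
#' cavity twice applies the resource/stiffness reductions twice: surgery is
#' deliberately not idempotent.
#'
#' @param state A [grid_state()].
#' @param cavity 0/1 matrix matching the grid shape.
#' @return The modified state.
#' @export
apply_surgery <- function(state, cavity) {
  stop_if(!same_dim(cavity, state$Nd), "cavity mask shape does not match the grid")
  stop_if(!all(cavity %in% c(0, 1)), "cavity mask must be 0/1")
  state$stiff_ic <- state$stiff_ic - state$stiff_ic / 10 * cavity
  state$Ng <- state$Ng - state$Ng / 2 * cavity
  state$No <- state$No - state$No / 2 * cavity
  inside <- cavity == 1
  for (i in seq_along(state$n)) state$n[[i]][inside] <- 0
  state$Nd[inside] <- 0
  state$cavity <- pmax(state$cavity, cavity)
  state
}

#' Treatment schedule
#'
#' @param rt_fractions Data frame with columns `day` and `dose` (Gy), one row
#'   per radiation fraction; days non-negative and sorted, doses positive.
#' @param tmz_days Integer vector of days on which temozolomide is active.
#' @param surgeries List of `list(day =, cavity =)` resection events.
#' @return An object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(rt_fractions = NULL, tmz_days = integer(0),
                               surgeries = list()) {
  if (is.null(rt_fractions)) {
    rt_fractions <- data.frame(day = numeric(0), dose = numeric(0))
  }
  stop_if(!all(c("day", "dose") %in% names(rt_fractions)),
          "'rt_fractions' needs columns 'day' and 'dose'")
  stop_if(any(rt_fractions$day < 0), "fraction days must be non-negative")
  stop_if(is.unsorted(rt_fractions$day), "fraction days must be sorted")
  stop_if(any(rt_fractions$dose <= 0), "doses must be positive")
  stop_if(any(tmz_days < 0), "TMZ days must be non-negative")
  for (s in surgeries) {
    stop_if(is.null(s$day) || is.null(s$cavity), "each surgery needs 'day' and 'cavity'")
    stop_if(s$day < 0, "surgery days must be non-negative")
  }
  structure(list(rt_fractions = rt_fractions,
                 tmz_days = sort(unique(as.integer(tmz_days))),
                 surgeries = surgeries),
            class = "treatment_schedule")
}

#' Standard-of-care chemoradiation preset
#'
#' The conventional regimen for newly diagnosed glioblastoma: 30 radiation
#' fractions of 2 Gy on weekdays over 6 weeks with concurrent daily
#' temozolomide, followed (after a 4-week break) by 6 adjuvant temozolomide
#' cycles of 5 days on / 23 days off. All values are arguments so the preset
#' can be edited.
#'
#' @param start_day First day of radiotherapy.
#' @param n_fractions Number of fractions.
#' @param dose_per_fraction Dose per fraction (Gy).
#' @param adjuvant_cycles Number of adjuvant TMZ cycles.
#' @param surgeries Optional surgeries to include.
#' @return A [treatment_schedule()].
#' @export
schedule_stupp <- function(start_day = 0, n_fractions = 30,
                           dose_per_fraction = 2, adjuvant_cycles = 6,
                           surgeries = list()) {
  offs <- seq(0, length.out = ceiling(n_fractions / 5) * 7)
  weekdays <- offs[offs %% 7 < 5][seq_len(n_fractions)]
  rt_days <- start_day + weekdays
  concurrent <- seq(start_day, max(rt_days))
  adj_start <- max(rt_days) + 28
  adjuvant <- unlist(lapply(seq_len(adjuvant_cycles) - 1, function(c) {
    adj_start + c * 28 + 0:4
  }))
  treatment_schedule(
    rt_fractions = data.frame(day = rt_days, dose = dose_per_fraction),
    tmz_days = c(concurrent, adjuvant),
    surgeries = surgeries
  )
}
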