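test_that("an empty grid without a schedule is a fixed point", {
  p <- sim_params()
  atl <- uniform_atlas(6, 6)
  cfg <- run_config(p, list(single_clone()), atl, list(c = matrix(0, 6, 6)),
                    duration = 3, seed = 1)
  st0 <- grid_state(atl, cfg$initial)
  st <- withr::with_seed(1, sim_step(st0, cfg))
  expect_equal(st$n$c, st0$n$c)
  expect_identical(st$No, st0$No)
  expect_identical(st$Ng, st0$Ng)
  expect_identical(st$V, st0$V)
  expect_equal(st$day, 1)
})

test_that("death and clearance keep an exact cell balance sheet", {
  # no proliferation, no clearance, no vessels: live + dead is conserved
  p <- sim_params(gamma = 0, c_d = 0, p0 = 0)
  atl <- uniform_atlas(8, 8, glucose = 0.5, oxygen = 0.01)  # starving, hypoxic
  withr::with_seed(2, init <- matrix(runif(64, 0, 2000), 8))
  cfg <- run_config(p, list(single_clone()), atl, list(c = init),
                    duration = 5, seed = 1)
  tr <- run_simulation(cfg)
  tot <- tr$summary$live_total + tr$summary$dead
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  expect_lt(tr$summary$live_total[6], tr$summary$live_total[1])
})

test_that("identical seeds give bit-identical trajectories", {
  clones <- premalignant_clone_pair()
  atl <- synthetic_atlases(c(16, 16), seed = 2, preset = "high_glucose")
  init <- list(`2N` = center_seed_map(16, 16, 4000),
               `4N` = center_seed_map(16, 16, 4000))
  cfg <- run_config(sim_params(), clones, atl, init, duration = 30, seed = 9)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$summary, t2$summary)
  # with active angiogenesis, different seeds diverge
  p <- sim_params()
  st <- grid_state(atl, list(c = matrix(p$sigma / 3, 16, 16)))
  st$Nd <- matrix(p$sigma / 3, 16, 16)
  cfg1 <- run_config(p, list(single_clone()), atl,
                     list(c = matrix(0, 16, 16)), duration = 1, seed = 1)
  a <- withr::with_seed(9, sim_step(st, cfg1))
  b <- withr::with_seed(10, sim_step(st, cfg1))
  expect_false(identical(a$V, b$V))
})

test_that("a zero-duration run emits only the initial snapshot", {
  cfg <- logistic_cfg(duration = 0)
  tr <- run_simulation(cfg)
  expect_equal(nrow(tr$summary), 1)
  expect_equal(tr$summary$day, 0)
  expect_equal(tr$summary$live_total, 100)
})

test_that("single-voxel unlimited-resource growth follows the logistic closed form", {
  cfg <- logistic_cfg(n0 = 100, duration = 100, dt = 0.05)
  tr <- run_simulation(cfg)
  p <- cfg$params
  t <- tr$summary$day
  exact <- p$sigma * 100 * exp(p$gamma * t) / (p$sigma + 100 * (exp(p$gamma * t) - 1))
  expect_lt(max(abs(tr$summary$live_total - exact) / exact), 0.01)
})

test_that("halving the step size leaves the logistic benchmark within 5%", {
  a <- run_simulation(logistic_cfg(duration = 60, dt = 0.1))
  b <- run_simulation(logistic_cfg(duration = 60, dt = 0.05))
  expect_lt(max(abs(a$summary$live_total - b$summary$live_total) /
                  b$summary$live_total), 0.05)
})

test_that("clone labels do not influence the dynamics", {
  atl <- synthetic_atlases(c(12, 12), seed = 3, preset = "high_glucose")
  mk <- function(label) {
    cl <- clone_params(label, 2, 1.2, 1.7, 0.53, 0.57)
    cfg <- run_config(sim_params(), list(cl), atl,
                      stats::setNames(list(center_seed_map(12, 12, 2000)), label),
                      duration = 20, seed = 4)
    run_simulation(cfg)$summary
  }
  a <- mk("2N"); b <- mk("4N")
  expect_equal(a$live_total, b$live_total)
  expect_equal(a$mean_o2, b$mean_o2)
})

test_that("symmetric clones keep 50:50 frequencies under competition", {
  atl <- synthetic_atlases(c(12, 12), seed = 5, preset = "high_glucose")
  cl1 <- clone_params("a", 2, 1.2, 1.7, 0.53, 0.57)
  cl2 <- clone_params("b", 2, 1.2, 1.7, 0.53, 0.57)
  init <- list(a = center_seed_map(12, 12, 500), b = center_seed_map(12, 12, 500))
  cfg <- run_config(sim_params(), list(cl1, cl2), atl, init,
                    duration = 40, seed = 6)
  s <- run_simulation(cfg)$summary
  expect_equal(s$live_a, s$live_b, tolerance = 1e-9)
})

test_that("radiation fraction days pulse the burden downward", {
  res <- experiment_recurrence(therapy = TRUE, seed = 2, shape = c(24, 24),
                               duration = 30, total_cells = 2e5)
  s <- res$trajectories[["2N"]]$summary
  fr_days <- schedule_stupp(7)$rt_fractions$day
  fr_days <- fr_days[fr_days < 30]
  before <- s$live_total[match(fr_days, s$day)]
  after <- s$live_total[match(fr_days + 1, s$day)]
  expect_true(all(after < before))
})

test_that("delta_R is recovered from self-generated density maps", {
  clones <- premalignant_clone_pair()
  atl <- synthetic_atlases(c(32, 32), seed = 7, preset = "low_glucose")
  init <- list(`2N` = center_seed_map(32, 32, 3000),
               `4N` = center_seed_map(32, 32, 3000))
  cfg <- run_config(sim_params(), clones, atl, init, duration = 24,
                    dt = 0.25, seed = 7, record_maps = TRUE)
  truth <- run_simulation(cfg)
  obs <- list(days = c(12, 24), maps = truth$maps[c("12", "24")])
  fit <- fit_simulation_params(obs, free = "delta_R",
                               bounds = list(delta_R = c(0.053, 0.209)), cfg)
  expect_lt(abs(fit$par[["delta_R"]] - 0.171) / 0.171, 0.1)
  # the objective trace reaches (near) zero at the recovered parameter
  expect_lt(fit$objective, min(fit$trace$objective) + 1e-9)
})

test_that("fit validation rejects inconsistent problems", {
  cfg <- logistic_cfg(duration = 10)
  obs <- list(days = 5, maps = list(matrix(1, 1, 1)))
  expect_error(fit_simulation_params(obs, free = "delta_R",
                                     bounds = list(v_max = c(0, 1)), cfg),
               "bounds")
  expect_error(fit_simulation_params(list(days = 20, maps = list(matrix(1))),
                                     free = "delta_R",
                                     bounds = list(delta_R = c(0.05, 0.2)), cfg),
               "duration")
})

test_that("rank correlation matches a brute-force rank computation with ties", {
  tab <- data.frame(resource = c(5, 3, 9, 1, 7, 7, 2, 8, 4, 6),
                    ploidy = c(2.1, 2.0, 3.4, 1.9, 2.9, 2.9, 2.2, 3.0, 2.4, 2.6))
  out <- resource_ploidy_correlation(tab)
  # oracle: average ranks computed explicitly, then Pearson on the ranks
  avg_rank <- function(x) {
    r <- numeric(length(x))
    for (i in seq_along(x)) r[i] <- mean(which(sort(x) == x[i]))
    r
  }
  oracle <- cor(avg_rank(tab$resource), avg_rank(tab$ploidy))
  expect_equal(out$rho, oracle, tolerance = 1e-12)
  # perfect concordance / discordance
  mono <- data.frame(resource = 1:6, ploidy = (1:6)^2)
  expect_equal(resource_ploidy_correlation(mono)$rho, 1)
  mono$ploidy <- rev(mono$ploidy)
  expect_equal(resource_ploidy_correlation(mono)$rho, -1)
  expect_error(resource_ploidy_correlation(tab[1:3, ]), "4")
})
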