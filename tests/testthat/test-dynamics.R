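test_that("metabolic switch threshold uses the H(0)=1 convention", {
  expect_equal(metabolic_state(0.06, 0.0510), "oxphos")
  expect_equal(metabolic_state(0.04, 0.0510), "glycolysis")
  expect_equal(metabolic_state(0.0510, 0.0510), "oxphos")
  expect_error(metabolic_state(-0.1, 0.05), "non-negative")
  m <- metabolic_state(matrix(c(0.1, 0.01), 1), 0.051)
  expect_equal(dim(m), c(1L, 2L))
})

test_that("proliferation vanishes at capacity and saturates at gamma", {
  p <- sim_params()
  cl <- single_clone()
  expect_equal(proliferation_rate(cl, 10, 2, p$sigma, 0, p), 0)
  expect_equal(proliferation_rate(cl, 10, 2, p$sigma / 2, p$sigma / 2, p), 0)
  # empty voxel, oxygen far above half-max
  expect_equal(proliferation_rate(cl, 1e6, 2, 0, 0, p), p$gamma,
               tolerance = 1e-6)
  # glycolysis at the glucose half-max gives gamma/2
  expect_equal(proliferation_rate(cl, 0, cl$beta_g_i, 0, 0, p), p$gamma / 2)
})

test_that("starvation death spans [0, delta_R] with half-max at beta_d", {
  p <- sim_params()
  cl <- single_clone()
  expect_equal(starvation_death_rate(cl, 0, cl$beta_d_i, "glycolysis", p),
               p$delta_R / 2)
  expect_equal(starvation_death_rate(cl, 0, 0, "glycolysis", p), 0.171)
  expect_lt(starvation_death_rate(cl, 0, 1e9, "glycolysis", p), 1e-9)
})

test_that("rate operations stay in their declared intervals on random draws", {
  p <- sim_params()
  cl <- single_clone()
  withr::with_seed(42, {
    No <- runif(1e4, 0, 0.5)
    Ng <- runif(1e4, 0, 3)
    Ntot <- runif(1e4, 0, p$sigma)
    Nd <- runif(1e4, 0, p$sigma - Ntot)
    S <- runif(1e4, 0, 3000)
  })
  pr <- proliferation_rate(cl, No, Ng, Ntot, Nd, p)
  expect_true(all(pr >= 0 & pr <= p$gamma))
  dr <- starvation_death_rate(cl, No, Ng, metabolic_state(No, p$O_th), p)
  expect_true(all(dr >= 0 & dr <= p$delta_R))
  K <- migration_coefficient(cl, Ng, S, p)
  expect_true(all(K >= 0 & K <= p$v_max))
  sf <- radiation_survival(2, No, p)
  expect_true(all(sf > 0 & sf <= 1))
})

test_that("biphasic migration peaks where the curve's calculus says", {
  p <- sim_params()
  cl2 <- single_clone()
  # numeric maximization oracle over glucose
  opt <- optimize(function(g) exp(-0.53 * g) - exp(-0.57 * g),
                  c(0, 25), maximum = TRUE)
  expect_equal(opt$maximum, log(0.57 / 0.53) / (0.57 - 0.53), tolerance = 1e-4)
  expect_equal(opt$maximum, 1.82, tolerance = 0.01)
  # K is zero without glucose and tops out at v_max at the optimum
  expect_equal(migration_coefficient(cl2, 0, 85000, p), 0)
  kpk <- migration_coefficient(cl2, opt$maximum, -p$c3 / (2 * p$c2), p)
  expect_equal(kpk, p$v_max, tolerance = 1e-6)
})

test_that("the 4N migration curve dominates the 2N curve at all glucose levels", {
  g <- seq(0.01, 25, by = 0.05)
  phi2 <- exp(-0.53 * g) - exp(-0.57 * g)
  phi4 <- exp(-0.34 * g) - exp(-0.95 * g)
  expect_true(all(phi4 > phi2))
})

test_that("shared-peak normalization preserves relative clone speeds", {
  p <- sim_params()
  clones <- premalignant_clone_pair()
  norm <- migration_norm(clones)
  k2 <- migration_coefficient(clones[[1]], 1.8, 2000, p, norm = norm)
  k4 <- migration_coefficient(clones[[2]], 1.8, 2000, p, norm = norm)
  expect_gt(k4, k2)
  expect_lte(k4, p$v_max)
})

test_that("resource update follows the Euler scheme with the metabolic switch", {
  p <- sim_params()
  atl <- uniform_atlas(2, 2, glucose = 2, oxygen = 0.2)
  st <- grid_state(atl, list(c = matrix(0, 2, 2)))
  # no cells, no vessels: nothing changes
  st2 <- update_resources(st, p, 1)
  expect_identical(st2$Ng, st$Ng)
  expect_identical(st2$No, st$No)
  # one vessel, no cells, dt 1: glucose rises by omega_g exactly
  st$V[1, 1] <- 1
  st3 <- update_resources(st, p, 1)
  expect_equal(st3$Ng[1, 1] - st$Ng[1, 1], 0.18204)
  expect_equal(st3$No[1, 1] - st$No[1, 1], p$omega_o)
  # glycolysis consumes glucose faster than oxphos
  st_ox <- st; st_ox$V[] <- 0; st_ox$n$c[] <- 1000
  st_gly <- st_ox; st_gly$No[] <- p$O_th / 2
  expect_lt(update_resources(st_gly, p, 0.1)$Ng[2, 2],
            update_resources(st_ox, p, 0.1)$Ng[2, 2])
})

test_that("dead-cell clearance is the discrete Euler decay", {
  expect_equal(clear_dead(100, 0.63, 1), 37)
  expect_equal(clear_dead(50, 0, 1), 50)
  expect_error(clear_dead(10, 0.63, 2), "dt")
  withr::with_seed(1, nd <- matrix(runif(16, 0, 100), 4))
  expect_true(all(clear_dead(nd, 0.63, 0.1) >= 0))
})

test_that("stiffness combines radiation decay and crowding with a 5% gate", {
  p <- sim_params()
  atl <- uniform_atlas(2, 2, stiffness = 2930)
  st <- grid_state(atl, list(c = matrix(0, 2, 2)))
  expect_equal(stiffness_field(st, p), st$stiff_ic)
  st$tr_star <- 30
  expect_equal(stiffness_field(st, p), st$stiff_ic * 0.987^30)
  # below the 5% density gate the crowding term stays off
  st$n$c[] <- 0.04 * p$sigma
  expect_equal(stiffness_field(st, p), st$stiff_ic * 0.987^30)
  # above the gate it switches on
  st$n$c[] <- 0.06 * p$sigma
  expect_equal(stiffness_field(st, p),
               st$stiff_ic * 0.987^30 * (1 + p$c1 * 0.06))
})

test_that("migration conserves mass, flattens gradients, spreads as diffusion", {
  p <- sim_params()
  atl <- uniform_atlas(9, 9)
  # uniform density is a fixed point
  st <- grid_state(atl, list(c = matrix(50, 9, 9)))
  K <- matrix(0.2, 9, 9)
  expect_equal(migrate(st, list(K), 0.5)$n$c, st$n$c)
  # point mass: variance grows as 2 K dt per axis after one step
  st$n$c <- center_seed_map(9, 9, 1)
  out <- migrate(st, list(K), 0.5)$n$c
  xs <- row(out) - 5
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_equal(sum(out * xs^2), 2 * 0.2 * 0.5, tolerance = 1e-12)
  # stability guard
  expect_error(migrate(st, list(matrix(1, 9, 9)), 0.5), "stability")
})

test_that("migration conserves total cells on random fields and coefficients", {
  p <- sim_params()
  atl <- uniform_atlas(12, 12)
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- matrix(runif(144, 0, 1000), 12)
      K <- matrix(runif(144, 0, p$v_max), 12)
      st <- grid_state(atl, list(c = n))
      out <- migrate(st, list(K), 0.25)$n$c
      expect_equal(sum(out), sum(n), tolerance = 1e-12)
      expect_true(all(out >= -1e-9))
    }
  })
})
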