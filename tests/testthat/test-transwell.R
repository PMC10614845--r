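test_that("the closed form matches an adaptive numeric integrator", {
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, parms) {
    with(as.list(parms), {
      list(c((lambda_T - mu - delta) * y[1], mu * y[1], delta * y[1]))
    })
  }
  times <- seq(0, 48, by = 2)
  withr::with_seed(4, {
    for (i in 1:5) {
      r <- transwell_rates(runif(1, 0, 0.02), runif(1, 0, 0.05), runif(1, 0, 0.05))
      init <- c(1000, 50, 10)
      exact <- transwell_solve(r, init, times)
      num <- deSolve::lsoda(init, times, rhs, unlist(r),
                            rtol = 1e-12, atol = 1e-10)
      expect_equal(exact$ta, unname(num[, 2]), tolerance = 1e-8)
      expect_equal(exact$ba, unname(num[, 3]), tolerance = 1e-8)
      expect_equal(exact$td, unname(num[, 4]), tolerance = 1e-8)
    }
  })
})

test_that("degenerate rate limits behave analytically", {
  times <- 0:48
  const <- transwell_solve(transwell_rates(0, 0, 0), c(100, 5, 1), times)
  expect_true(all(const$ta == 100 & const$ba == 5 & const$td == 1))
  # pure migration conserves top + bottom and decays the top exponentially
  mig <- transwell_solve(transwell_rates(0, 0.03, 0), c(1000, 0, 0), times)
  expect_equal(mig$ta, 1000 * exp(-0.03 * times))
  expect_equal(mig$ta + mig$ba, rep(1000, length(times)), tolerance = 1e-9)
  # k -> 0 limit: lambda exactly balances losses
  bal <- transwell_solve(transwell_rates(0.05, 0.03, 0.02), c(1000, 0, 0), times)
  expect_equal(bal$ta, rep(1000, length(times)))
  expect_equal(bal$ba, 1000 * 0.03 * times)
})

test_that("noise-free fits recover the generating rates almost exactly", {
  truth <- transwell_rates(0.005, 0.02, 0.01)
  d <- synthetic_transwell(list("5" = truth), init = c(1000, 0, 0),
                           noise = "none", seed = 1)[[1]]
  f <- transwell_fit(d, n_boot = 0)
  expect_equal(f$rates$lambda_T, truth$lambda_T, tolerance = 1e-4)
  expect_equal(f$rates$mu, truth$mu, tolerance = 1e-4)
  expect_equal(f$rates$delta, truth$delta, tolerance = 1e-4)
  expect_lt(f$residual_norm, 1e-4)
})

test_that("noise-free recovery bias stays under 2% across random rate draws", {
  withr::with_seed(8, {
    rel_err <- replicate(50, {
      truth <- transwell_rates(runif(1, 0.001, 0.01), runif(1, 0.005, 0.05),
                               runif(1, 0.005, 0.05))
      d <- synthetic_transwell(list(x = truth), init = c(1000, 0, 0),
                               noise = "none", seed = sample.int(1e6, 1))[[1]]
      f <- transwell_fit(d, n_boot = 0)
      max(abs(unlist(f$rates) - unlist(truth)) / pmax(unlist(truth), 1e-6))
    })
  })
  expect_lt(mean(rel_err), 0.02)
})

test_that("a zero migration rate is recovered as statistically negligible", {
  truth <- transwell_rates(0.004, 0, 0.02)
  d <- synthetic_transwell(list(x = truth), init = c(2000, 0, 0),
                           noise = "gaussian", seed = 3, cv = 0.03)[[1]]
  f <- transwell_fit(d, n_boot = 100, seed = 2)
  delta_ci_width <- diff(f$ci[, "delta"])
  expect_lt(f$rates$mu, delta_ci_width)
})

test_that("degenerate transwell data are rejected", {
  expect_error(transwell_fit(transwell_dataset(0:10, rep(0, 11), rep(0, 11),
                                               rep(0, 11))), "degenerate")
  expect_error(transwell_fit(transwell_dataset(c(0, 2, 4), c(1, 1, 1),
                                               c(0, 0, 0), c(0, 0, 0))),
               "4 time points")
})

test_that("rate-glucose trends recover exact and flagged correlations", {
  mk <- function(glc, delta) {
    structure(list(rates = transwell_rates(0.001, 0.01, delta),
                   glucose_mM = glc), class = "transwell_fit")
  }
  # death rate linearly decreasing in glucose: r = -1
  glc <- c(0.1, 0.5, 1, 5, 25)
  fits <- Map(mk, glc, 0.05 - 0.001 * glc)
  tr <- rate_glucose_trend(fits)
  expect_equal(tr$r[tr$rate == "delta"], -1, tolerance = 1e-12)
  # constant rates are flagged, not correlated
  expect_true(tr$constant[tr$rate == "lambda_T"])
  expect_true(is.na(tr$r[tr$rate == "lambda_T"]))
  expect_error(rate_glucose_trend(fits[1:2]), "3")
})

test_that("synthetic assay data are reproducible and noise scales correctly", {
  r <- list("1" = transwell_rates(0.002, 0.015, 0.02))
  a <- synthetic_transwell(r, init = c(1000, 0, 0), noise = "poisson", seed = 5)
  b <- synthetic_transwell(r, init = c(1000, 0, 0), noise = "poisson", seed = 5)
  expect_identical(a, b)
  exact <- synthetic_transwell(r, init = c(1000, 0, 0), noise = "none", seed = 5)[[1]]
  expect_equal(exact$ta, transwell_solve(r[[1]], c(1000, 0, 0),
                                         seq(0, 48, 2))$ta)
  # Poisson relative spread shrinks roughly as 1/sqrt(count)
  big <- synthetic_transwell(list("1" = transwell_rates(0, 0, 0)),
                             init = c(1e6, 0, 0), noise = "poisson", seed = 6)[[1]]
  small <- synthetic_transwell(list("1" = transwell_rates(0, 0, 0)),
                               init = c(100, 0, 0), noise = "poisson", seed = 6)[[1]]
  expect_lt(sd(big$ta) / mean(big$ta), sd(small$ta) / mean(small$ta))
})

test_that("assay CSV files round-trip through the condition reader", {
  r <- transwell_rates(0.002, 0.02, 0.01)
  d <- transwell_solve(r, c(1000, 0, 0), seq(0, 48, 2))
  df <- data.frame(condition_glucose_mM = rep(c(0.5, 5), each = nrow(d)),
                   condition_fbs_pct = 1,
                   time_h = d$time, ta = d$ta, ba = d$ba, td = d$td)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  sets <- read_transwell_csv(path)
  expect_length(sets, 2)
  expect_equal(attr(sets[["0.5_1"]], "glucose_mM"), 0.5)
  expect_equal(sets[["5_1"]]$ta, d$ta)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, -1], bad, row.names = FALSE)
  expect_error(read_transwell_csv(bad), "condition_glucose_mM")
})
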