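# deterministic counts traced exactly along the logistic increments
noiseless_counts <- function(params, start, end) {
  mu <- nhrp_annual_means(params, seq(start, end))
  new_annual_counts(round(mu), start)
}

test_that("the logistic cumulative curve has the stated algebra", {
  p <- nhrp_params(1000, 0.1, 2000)
  expect_equal(logistic_cumulative(p, 2000), 500) # inflection = N/2
  expect_equal(logistic_cumulative(p, 2000 + 1e6), 1000)
  expect_equal(logistic_cumulative(p, 2000 - 1e6), 0)
  # direct evaluation: 2000 / (1 + e^-1)
  p2 <- nhrp_params(2000, 0.05, 2000)
  expect_equal(logistic_cumulative(p2, 2020), 2000 / (1 + exp(-1)),
    tolerance = 1e-12
  )
  # strictly increasing
  tt <- seq(1800, 2200, by = 0.5)
  expect_true(all(diff(logistic_cumulative(p, tt)) > 0))
})

test_that("the intensity is the curve's derivative, peaked and symmetric", {
  p <- nhrp_params(3000, 0.07, 1990)
  expect_equal(logistic_intensity(p, 1990), 3000 * 0.07 / 4)
  d <- c(3, 11, 40)
  expect_equal(logistic_intensity(p, 1990 + d), logistic_intensity(p, 1990 - d))
  # central finite-difference oracle at 10 seeded random times
  tt <- withr::with_seed(9, runif(10, 1900, 2100))
  h <- 1e-4
  num <- (logistic_cumulative(p, tt + h) - logistic_cumulative(p, tt - h)) /
    (2 * h)
  expect_equal(logistic_intensity(p, tt), num, tolerance = 1e-6)
})

test_that("the intensity integrates to the cumulative increment", {
  p <- nhrp_params(2500, 0.04, 2010)
  for (win in list(c(1950, 2000), c(2005, 2015), c(1800, 2300))) {
    num <- stats::integrate(function(t) logistic_intensity(p, t),
      win[1], win[2],
      rel.tol = 1e-10
    )$value
    expect_equal(
      num,
      logistic_cumulative(p, win[2]) - logistic_cumulative(p, win[1]),
      tolerance = 1e-6
    )
  }
})

test_that("the Poisson log-likelihood matches closed forms and brute force", {
  p <- nhrp_params(500, 0.05, 1990)
  # single year, count k: k log mu - mu - log k!
  d1 <- new_annual_counts(7L, 1985)
  mu1 <- logistic_cumulative(p, 1986) - logistic_cumulative(p, 1985)
  expect_equal(nhrp_loglik(p, d1), 7 * log(mu1) - mu1 - lfactorial(7))
  # all-zero counts: sum of -mu
  d0 <- new_annual_counts(rep(0L, 12), 1980)
  mu0 <- nhrp_annual_means(p, 1980:1991)
  expect_equal(nhrp_loglik(p, d0), -sum(mu0))
  # 5-year fixture vs direct pmf summation
  d5 <- new_annual_counts(c(2L, 5L, 1L, 0L, 8L), 1988)
  mu5 <- nhrp_annual_means(p, 1988:1992)
  brute <- sum(d5$counts * log(mu5) - mu5 - lfactorial(d5$counts))
  expect_equal(nhrp_loglik(p, d5), brute)
})

test_that("the negative binomial log-likelihood matches direct pmf evaluation", {
  p <- nhrp_params(500, 0.05, 1990)
  d <- new_annual_counts(c(2L, 5L, 1L, 0L, 8L), 1988)
  mu <- nhrp_annual_means(p, 1988:1992)
  phi <- 2.5
  size <- mu / (phi - 1)
  brute <- sum(lgamma(d$counts + size) - lgamma(size) - lfactorial(d$counts) +
    size * log(size / (size + mu)) + d$counts * log(mu / (size + mu)))
  expect_equal(nhrp_loglik(p, d, phi = phi), brute, tolerance = 1e-10)
})

test_that("the fit recovers parameters from noiseless logistic data", {
  truth <- nhrp_params(10000, 0.05, 1990)
  d <- noiseless_counts(truth, 1900, 2080)
  fit <- fit_nhrp(d)
  expect_true(fit$converged)
  expect_equal(fit$params$N, truth$N, tolerance = 0.01)
  expect_equal(fit$params$v1, truth$v1, tolerance = 0.01)
  expect_lt(abs(fit$params$v2 - truth$v2), 0.5)
  expect_true(fit$params$N >= sum(d$counts))
})

test_that("the optimizer is at least as good as a coarse grid search", {
  truth <- nhrp_params(800, 0.08, 2005)
  d <- simulate_descriptions(truth, 1, 1989, 2018, seed = 11)
  fit <- fit_nhrp(d)
  expect_true(fit$converged)
  total <- sum(d$counts)
  grid <- expand.grid(
    N = total * c(1, 1.5, 2, 3, 5, 8, 12),
    v1 = c(0.01, 0.03, 0.05, 0.08, 0.12, 0.2, 0.4),
    v2 = seq(1985, 2040, by = 5)
  )
  grid_ll <- max(apply(grid, 1, function(g) {
    nhrp_loglik(nhrp_params(g[1], g[2], g[3]), d)
  }))
  expect_gte(fit$loglik, grid_ll - 1e-8)
})

test_that("shifting the data by +100 years shifts v2 by exactly +100", {
  truth <- nhrp_params(900, 0.06, 2000)
  d <- simulate_descriptions(truth, 1, 1950, 2018, seed = 3)
  d2 <- new_annual_counts(d$counts, d$start_year + 100L)
  f1 <- fit_nhrp(d)
  f2 <- fit_nhrp(d2)
  expect_true(f1$converged && f2$converged)
  expect_equal(f2$params$v2, f1$params$v2 + 100, tolerance = 1e-6)
  expect_equal(f2$params$N, f1$params$N, tolerance = 1e-6)
  expect_equal(f2$params$v1, f1$params$v1, tolerance = 1e-6)
})

test_that("degenerate inputs are refused or flagged, never silent", {
  flat <- new_annual_counts(rep(5L, 30), 1989)
  fit <- fit_nhrp(flat)
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "flat")
  expect_error(predict_new_species(fit, 2018, 2050, 10, 1), "non-converged")
  expect_error(fit_nhrp(new_annual_counts(c(1L, 2L), 2000)), "10 years")
  expect_error(fit_nhrp(new_annual_counts(rep(0L, 20), 2000)), "nonzero")
})

test_that("simulation is seed-reproducible and leaves the RNG untouched", {
  p <- nhrp_params(1000, 0.05, 2000)
  a <- simulate_descriptions(p, 1, 1980, 2018, seed = 5)
  b <- simulate_descriptions(p, 1, 1980, 2018, seed = 5)
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_descriptions(p, 1, 1980, 2018, seed = 6)
  ))
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_descriptions(p, 1, 1980, 2018, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("simulated totals match the analytic mean within Monte-Carlo error", {
  p <- nhrp_params(600, 0.09, 2000)
  totals <- vapply(
    1:400,
    function(r) sum(simulate_descriptions(p, 1, 1980, 2020, seed = r)$counts),
    numeric(1)
  )
  expected <- sum(nhrp_annual_means(p, 1980:2020))
  se <- stats::sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("dispersion phi = 2 doubles the across-replicate count variance", {
  p <- nhrp_params(4000, 0.05, 2000)
  yrs_keep <- 15:25 # mid-curve years with sizeable means
  v <- function(phi, off) {
    m <- t(vapply(
      1:300,
      function(r) {
        simulate_descriptions(p, phi, 1990, 2020, seed = off + r)$counts
      },
      numeric(31)
    ))
    mean(apply(m[, yrs_keep], 2, stats::var) /
      colMeans(m[, yrs_keep]))
  }
  ratio <- v(2, 10000) / v(1, 20000)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
})

test_that("predictions are ordered, monotone in horizon, and zero at horizon 0", {
  truth <- nhrp_params(2000, 0.05, 2010)
  d <- simulate_descriptions(truth, 1, 1900, 2018, seed = 21)
  fit <- fit_nhrp(d)
  pred <- predict_new_species(fit, 2018, c(2018, 2035, 2050, 2100),
    n_reps = 200, seed = 4, keep_reps = TRUE
  )
  expect_equal(pred$median_new[pred$horizon_year == 2018], 0)
  expect_equal(pred$lower95[pred$horizon_year == 2018], 0)
  expect_true(all(pred$lower95 <= pred$median_new))
  expect_true(all(pred$median_new <= pred$upper95))
  expect_true(all(pred$median_new >= 0))
  reps <- attr(pred, "reps")
  # on shared replicate streams every later horizon dominates replicate-wise
  expect_true(all(diff(t(reps)) >= 0))
})

test_that("noiseless-fit predictions match the analytic logistic increment", {
  truth <- nhrp_params(10000, 0.05, 2005)
  d <- noiseless_counts(truth, 1900, 2018)
  fit <- fit_nhrp(d)
  pred <- predict_new_species(fit, 2018, 2050, n_reps = 1000, seed = 8)
  analytic <- logistic_cumulative(fit$params, 2051) -
    logistic_cumulative(fit$params, 2019)
  expect_equal(pred$mean_new, analytic, tolerance = 0.005)
})

test_that("goodness of fit is calm under the model and flags a step change", {
  truth <- nhrp_params(3000, 0.05, 2000)
  d <- simulate_descriptions(truth, 1, 1900, 2018, seed = 31)
  fit <- fit_nhrp(d)
  g <- goodness_of_fit(fit, d)
  expect_gt(nrow(g$residuals), 0)
  expect_lt(abs(g$dispersion - 1), 0.35)
  expect_equal(g$curves$observed_cum, cumsum(d$counts))

  # double the late-period rate: a systematic residual run appears
  broken <- d
  late <- seq(from = length(d$counts) - 19, to = length(d$counts))
  broken$counts[late] <- broken$counts[late] * 2L
  fit2 <- fit_nhrp(broken)
  g2 <- goodness_of_fit(fit2, broken)
  expect_gt(g2$dispersion, g$dispersion)
  expect_gte(g2$max_sign_run, 8)
})

test_that("parameter-uncertainty propagation widens prediction intervals", {
  truth <- nhrp_params(4000, 0.04, 2020)
  d <- simulate_descriptions(truth, 1, 1850, 2018, seed = 77)
  fit <- fit_nhrp(d)
  p1 <- predict_new_species(fit, 2018, 2050, n_reps = 300, seed = 5)
  p2 <- predict_new_species(fit, 2018, 2050,
    n_reps = 300, seed = 5,
    propagate_param_uncertainty = TRUE
  )
  expect_gt(p2$upper95 - p2$lower95, p1$upper95 - p1$lower95)
})
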