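intercept_spec <- function(n_guilds = 1, n_sites = 1, n_visits = 1, ...) {
  sm_model_spec(sm_design(n_guilds = n_guilds, n_sites = n_sites,
                          n_visits = n_visits, ...))
}

test_that("log-linear predictors exponentiate correctly", {
  spec <- intercept_spec()
  th <- sm_params(spec, c(nu_A0 = 5, rho_A0 = -4, psi_A0 = -7))
  expect_equal(expected_abundance(th, spec, "A", 1), exp(5))
  expect_equal(capture_rate(th, spec, "A", 1), exp(-4))
  expect_equal(vocal_rate(th, spec, "A", 1), exp(-7))

  th0 <- sm_params(spec) # all zero
  expect_equal(expected_abundance(th0, spec, "A", 1), 1)
  expect_equal(capture_rate(th0, spec, "A", 1), 1)
  expect_equal(vocal_rate(th0, spec, "A", 1), 1)
})

test_that("covariates enter the abundance predictor linearly on log scale", {
  d <- sm_design(n_guilds = 1, n_sites = 1, n_visits = 1, guilds = "A")
  cov <- tibble::tibble(site = 1, visit = 1, x = 100)
  spec <- sm_model_spec(d, cov, abundance = c(x = "shared"))
  th <- sm_params(spec, c(nu_A0 = 5, nu_1 = 0.01))
  expect_equal(expected_abundance(th, spec, "A", 1), exp(6))
})

test_that("guild-specific coefficients resolve per guild", {
  spec <- intercept_spec(n_guilds = 3)
  th <- sm_params(spec, c(rho_A0 = -4, rho_B0 = -3.5, rho_C0 = -4.8))
  expect_equal(capture_rate(th, spec, "C", 1), exp(-4.8))
  expect_equal(capture_rate(th, spec, "B", 1), exp(-3.5))
})

test_that("p_capture follows the exponential first-capture time", {
  expect_equal(p_capture(0, 6), 0)
  expect_equal(p_capture(exp(-4), 6), 1 - exp(-6 * exp(-4)))
  expect_lt(abs(p_capture(exp(-4), 6) - 0.1040708), 1e-6)
  expect_equal(p_capture(1e6, 6), 1) # saturation
  # monotone in both arguments
  r <- seq(0, 2, by = 0.1)
  expect_true(all(diff(p_capture(r, 6)) >= 0))
  expect_true(all(diff(p_capture(0.3, seq(0, 10, 0.5))) >= 0))
  expect_true(all(p_capture(r, 6) >= 0 & p_capture(r, 6) < 1))
})

test_that("p_acoustic is the chance of hearing any of N individuals", {
  expect_equal(p_acoustic(exp(-7), 0, 0.03), 0)
  expect_equal(p_acoustic(exp(-7), 148, 0.03),
               1 - exp(-148 * 0.03 * exp(-7)))
  expect_lt(abs(p_acoustic(exp(-7), 148, 0.03) - 0.004043), 1e-5)
  expect_equal(p_acoustic(exp(-7), 148, 0), 0)
  N <- 0:500
  p <- p_acoustic(exp(-5), N, 0.03)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p < 1))
})

test_that("first-capture and acoustic counts are binomial", {
  expect_equal(loglik_first_captures(0, 0, 0.3), 0)
  expect_equal(loglik_first_captures(10, 10, 1), 0)
  p <- 0.10415
  expect_equal(loglik_first_captures(3, 10, p),
               lchoose(10, 3) + 3 * log(p) + 7 * log(1 - p))
  expect_identical(loglik_first_captures(11, 10, 0.5), -Inf)

  expect_equal(loglik_acoustic(0, 20, 0), 0)
  expect_equal(loglik_acoustic(20, 20, 1), 0)
  pa <- 0.004043
  expect_equal(loglik_acoustic(2, 20, pa),
               lchoose(20, 2) + 2 * log(pa) + 18 * log(1 - pa))
})

test_that("capture-history likelihood uses the truncated exponential", {
  r <- exp(-4); T_ <- 6
  expect_equal(loglik_capture_history(2, 1, r, T_),
               oracle_hist_loglik(2, 1, r, T_))
  # zero exposure limit: Poisson term vanishes as c -> T
  near_T <- T_ - 1e-9
  expect_equal(loglik_capture_history(near_T, 0, r, T_),
               log(r * exp(-r * near_T) / (1 - exp(-r * T_))),
               tolerance = 1e-6)
  # functional identity when doubling r
  v1 <- loglik_capture_history(2, 1, r, T_)
  v2 <- loglik_capture_history(2, 1, 2 * r, T_)
  expect_equal(v2 - v1, oracle_hist_loglik(2, 1, 2 * r, T_) -
                 oracle_hist_loglik(2, 1, r, T_))
  expect_error(loglik_capture_history(6, 0, r, T_), "\\[0, T\\)")
})

test_that("truncated first-capture density integrates to 1 over [0, T)", {
  for (r in c(0.02, 0.3, 1.5)) {
    T_ <- 6
    dens <- function(cc) r * exp(-r * cc) / (1 - exp(-r * T_))
    expect_equal(stats::integrate(dens, 0, T_)$value, 1, tolerance = 1e-8)
    # summing the joint (c, y) likelihood over y recovers the density
    cc <- 1.7
    tot <- sum(exp(loglik_capture_history(cc, 0:100, r, T_)))
    expect_equal(tot, dens(cc), tolerance = 1e-10)
  }
})

test_that("history density matches the simulated generative process", {
  set.seed(11)
  r <- 0.4; T_ <- 6
  cc <- rexp(2e5, r)
  cc <- cc[cc < T_]
  # empirical cdf at a grid vs integral of the truncated density
  dens <- function(x) r * exp(-r * x) / (1 - exp(-r * T_))
  for (x in c(1, 3, 5)) {
    emp <- mean(cc < x)
    thr <- stats::integrate(dens, 0, x)$value
    expect_equal(emp, thr, tolerance = 0.01)
  }
})

test_that("marginal cell likelihood matches brute-force N summation", {
  set.seed(42)
  for (k in 1:20) {
    inst <- random_cell_instance()
    got <- marginal_cell_loglik(inst$n, inst$histories, inst$a, inst$D,
                                inst$r, inst$lam, inst$T_, inst$L, inst$M)
    want <- oracle_cell_marginal(inst$n, inst$a, inst$D, inst$r, inst$lam,
                                 inst$L, inst$T_, inst$M) +
      if (inst$n > 0) sum(oracle_hist_loglik(inst$histories$first_capture_time,
                                             inst$histories$n_recaptures,
                                             inst$r, inst$T_)) else 0
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("dropping acoustics recovers the Poisson-thinning closed form", {
  for (D in c(0.5, 3, 40, 200)) {
    for (p_target in c(0.05, 0.3, 0.8)) {
      r <- -log(1 - p_target) / 6
      for (n in c(0L, 1L, 5L)) {
        hh <- tibble::tibble(first_capture_time = rep(1, n),
                             n_recaptures = rep(0L, n))
        via_marginal <- marginal_cell_loglik(n, hh, 0L, D, r, 0, 6, 0L, 0.03)
        if (n > 0)
          via_marginal <- via_marginal -
            sum(loglik_capture_history(hh$first_capture_time,
                                       hh$n_recaptures, r, 6))
        expect_equal(via_marginal, dpois(n, D * p_target, log = TRUE),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("lambda = 0 with acoustics equals the no-acoustics marginal", {
  empty <- tibble::tibble(first_capture_time = numeric(),
                          n_recaptures = integer())
  v1 <- marginal_cell_loglik(0L, empty, 0L, 10, 0.1, 0, 6, 20L, 0.03)
  v2 <- marginal_cell_loglik(0L, empty, 0L, 10, 0.1, 0, 6, 0L, 0.03)
  expect_equal(v1, v2, tolerance = 1e-10) # a = 0 binomial term is exactly 0
})

test_that("marginal is insensitive to widening the summation window", {
  set.seed(9)
  inst <- random_cell_instance()
  want1 <- oracle_cell_marginal(inst$n, inst$a, inst$D, inst$r, inst$lam,
                                inst$L, inst$T_, inst$M, N_max = 2000)
  want2 <- oracle_cell_marginal(inst$n, inst$a, inst$D, inst$r, inst$lam,
                                inst$L, inst$T_, inst$M, N_max = 20000)
  expect_equal(want1, want2, tolerance = 1e-10)
  got <- marginal_cell_loglik(inst$n, inst$histories, inst$a, inst$D,
                              inst$r, inst$lam, inst$T_, inst$L, inst$M) -
    sum(oracle_hist_loglik(inst$histories$first_capture_time,
                           inst$histories$n_recaptures, inst$r, inst$T_))
  expect_equal(got, want2, tolerance = 1e-8)
})

test_that("marginal rejects inconsistent history counts", {
  empty <- tibble::tibble(first_capture_time = numeric(),
                          n_recaptures = integer())
  expect_error(marginal_cell_loglik(2L, empty, 0L, 10, 0.1, 0.01, 6, 20L,
                                    0.03),
               "must equal n")
})
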