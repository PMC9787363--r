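test_that("the log prior is a sum of normal log-densities", {
  spec <- sm_model_spec(sm_design(n_guilds = 1, n_sites = 1, n_visits = 1,
                                  guilds = "A"))
  pr <- sm_priors(spec)
  th <- sm_params(spec, c(nu_A0 = 6, rho_A0 = 0, psi_A0 = -5))
  at_mean <- sm_log_prior(th, pr)
  expect_equal(at_mean, dnorm(6, 6, 0.82, log = TRUE) +
                 dnorm(0, 0, 3.16, log = TRUE) + dnorm(-5, -5, 2, log = TRUE))
  # shifting one parameter by +1 sd costs exactly 0.5
  th2 <- th; th2["nu_A0"] <- 6 + 0.82
  expect_equal(at_mean - sm_log_prior(th2, pr), 0.5)
  # prior means maximize the prior
  th3 <- th; th3["rho_A0"] <- 1
  expect_lt(sm_log_prior(th3, pr), at_mean)
})

test_that("default priors match the reference simulation scenario", {
  sim <- sm_simulate(seed = 1)
  pr <- sm_priors(sim$data$spec)
  expect_equal(pr$mean[pr$term == "nu_A0"], 6)
  expect_equal(pr$sd[pr$term == "nu_A0"], 0.82)
  expect_equal(pr$sd[pr$term == "nu_1"], 1)
  expect_equal(pr$sd[pr$term == "nu_2"], 0.2)
  expect_equal(pr$sd[pr$term == "rho_B0"], 3.16)
  expect_equal(pr$mean[pr$term == "psi_C0"], -5)
  expect_equal(pr$sd[pr$term == "psi_C0"], 2)
  pr2 <- sm_priors(sim$data$spec, overrides = list(nu_1 = c(0, 5)))
  expect_equal(pr2$sd[pr2$term == "nu_1"], 5)
  expect_error(sm_priors(sim$data$spec, overrides = list(zz = c(0, 1))),
               "unknown term")
})

test_that("the joint log posterior matches a brute-force oracle", {
  set.seed(21)
  cfg <- tiny_config()
  sim <- sm_simulate(cfg, seed = 77)
  pr <- sm_priors(sim$data$spec)
  th <- sm_params(sim$data$spec, cfg$truths)
  for (model in c("integrated", "mr")) {
    got <- sm_log_posterior(
      if (model == "mr") th[!grepl("^psi", names(th))] else th,
      sim$data, model = model, priors = pr)
    want <- oracle_log_posterior(th, sim$data, model = model, priors = pr)
    expect_equal(got, want, tolerance = 1e-8)
  }
  # and at a perturbed parameter point
  th2 <- th + 0.15
  got <- sm_log_posterior(th2, sim$data, model = "integrated", priors = pr)
  want <- oracle_log_posterior(th2, sim$data, priors = pr)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("without listening periods the integrated model equals mr", {
  cfg <- tiny_config()
  cfg$design <- sm_design(n_guilds = 2, n_sites = 6, n_visits = 2,
                          n_listening = 0, guilds = c("A", "B"))
  sim <- sm_simulate(cfg, seed = 5)
  expect_null(sim$data$a)
  pr <- sm_priors(sim$data$spec)
  th <- sm_params(sim$data$spec, cfg$truths)
  th_mr <- th[!grepl("^psi", names(th))]
  suppressMessages(
    lp_int <- sm_log_posterior(th, sim$data, "integrated", priors = pr))
  lp_mr <- sm_log_posterior(th_mr, sim$data, "mr", priors = pr)
  psi_prior <- sum(dnorm(th[grepl("^psi", names(th))], -5, 2, log = TRUE))
  expect_equal(lp_int - psi_prior, lp_mr, tolerance = 1e-10)
})

test_that("an empty model reduces to the prior", {
  spec <- sm_model_spec(sm_design(n_guilds = 2, n_sites = 2, n_visits = 1,
                                  guilds = c("A", "B")))
  pr <- sm_priors(spec)
  th <- sm_params(spec, c(nu_A0 = 5, rho_B0 = -2))
  expect_equal(sm_log_posterior(th, NULL, "integrated", pr, spec = spec),
               sm_log_prior(th, pr))
})

test_that("split-chain R-hat behaves as a convergence diagnostic", {
  expect_equal(rhat(cbind(rep(1, 100), rep(1, 100))), 1)
  set.seed(31)
  mixed <- cbind(rnorm(2000), rnorm(2000), rnorm(2000))
  expect_lt(rhat(mixed), 1.02)
  disjoint <- cbind(rnorm(500), rnorm(500) + 50)
  expect_gt(rhat(disjoint), 5)
  # textbook formula, computed independently (floored at 1)
  x <- matrix(rnorm(1200, sd = 2), 300, 4)
  n <- 150
  seqs <- cbind(x[1:150, ], x[151:300, ])
  W <- mean(apply(seqs, 2, var))
  B <- n * var(colMeans(seqs))
  expect_equal(rhat(x), max(1, sqrt(((n - 1) / n * W + B / n) / W)))
  expect_gte(rhat(x), 1)
  # identical non-degenerate chains sit exactly at the floor
  expect_identical(rhat(cbind(x[, 1], x[, 1])), 1)
})

test_that("R-hat agrees with coda on well-mixed chains", {
  skip_if_not_installed("coda")
  set.seed(41)
  x <- matrix(rnorm(3000), 1000, 3)
  cl <- coda::mcmc.list(lapply(1:3, function(j) coda::mcmc(x[, j])))
  psrf <- coda::gelman.diag(cl, autoburnin = FALSE)$psrf[1, 1]
  expect_lt(abs(rhat(x) - psrf), 0.05)
})

test_that("HPD intervals are the shortest intervals of given mass", {
  set.seed(51)
  z <- rnorm(2e5)
  h <- hpd_interval(z)
  expect_lt(abs(h[["lower"]] + 1.96), 0.04)
  expect_lt(abs(h[["upper"]] - 1.96), 0.04)
  expect_equal(unname(hpd_interval(rep(3.3, 50))), c(3.3, 3.3))
  # exponential: anchored near zero, shorter than the quantile interval
  e <- rexp(2e5)
  he <- hpd_interval(e)
  expect_lt(he[["lower"]], 0.01)
  q <- unname(quantile(e, c(0.025, 0.975)))
  expect_lt(he[["upper"]] - he[["lower"]], q[2] - q[1])
})

test_that("HPD matches coda's implementation", {
  skip_if_not_installed("coda")
  set.seed(61)
  x <- rgamma(5000, 2, 1)
  ours <- hpd_interval(x)
  theirs <- coda::HPDinterval(coda::mcmc(x))
  expect_equal(unname(ours), as.numeric(theirs), tolerance = 0.01)
})

test_that("fits are reproducible and flag convergence honestly", {
  cfg <- tiny_config()
  sim <- sm_simulate(cfg, seed = 13)
  f1 <- sm_fit(sim$data, chains = 2, iter = 600, burnin = 200, seed = 4)
  f2 <- sm_fit(sim$data, chains = 2, iter = 600, burnin = 200, seed = 4)
  expect_identical(f1$draws, f2$draws)
  f3 <- sm_fit(sim$data, chains = 2, iter = 600, burnin = 200, seed = 5)
  expect_false(identical(f1$draws, f3$draws))
  expect_identical(f1$converged, all(f1$rhat < 1.1))
  expect_true(all(tidy(f1)$conf.low <= tidy(f1)$conf.high))
  g <- glance(f1)
  expect_equal(g$n_params, 9)
  expect_s3_class(autoplot(f1, truth = cfg$truths), "ggplot")
})

test_that("a data-free fit recovers its prior", {
  spec <- sm_model_spec(sm_design(n_guilds = 1, n_sites = 1, n_visits = 1,
                                  guilds = "A"))
  pr <- sm_priors(spec)
  fit <- sm_fit(NULL, spec = spec, chains = 3, iter = 6000, burnin = 1000,
                seed = 2)
  td <- tidy(fit)
  for (i in seq_len(nrow(td))) {
    m <- pr$mean[pr$term == td$term[i]]
    s <- pr$sd[pr$term == td$term[i]]
    # batch-means Monte Carlo standard error
    pooled <- as.vector(fit$draws[, td$term[i], ])
    nb <- 50
    bm <- tapply(pooled, rep(seq_len(nb), each = length(pooled) / nb), mean)
    mcse <- sd(bm) / sqrt(nb)
    expect_lt(abs(td$estimate[i] - m), 3 * mcse + 1e-9)
    expect_lt(abs(td$std.error[i] - s) / s, 0.1)
  }
})

test_that("posterior abundance reduces to known conditionals", {
  d <- sm_design(n_guilds = 1, n_sites = 1, n_visits = 1, guilds = "A")
  spec <- sm_model_spec(d)
  # certain capture (huge r): N must equal n
  expect_equal(songmark:::cpp_draw_N(0.5, 7L, 0L, 10, 10, 0, 0L, 6, 0.03,
                                     TRUE), 7)
  # no data at all: N ~ Poisson(D) exactly
  set.seed(71)
  D <- 4.2
  draws <- vapply(runif(30000), function(u)
    songmark:::cpp_draw_N(u, 0L, 0L, D, 0, 0, 0L, 6, 0.03, TRUE), 1L)
  expect_lt(abs(mean(draws) - D), 3 * sqrt(D / 30000))
  expect_lt(abs(var(draws) - D) / D, 0.05)
  # small instance: conditional pmf matches brute-force enumeration
  n <- 1L; a <- 1L; Dv <- 3; r <- 0.2; lam <- 0.5; L <- 2L
  N <- n:200
  w <- dpois(N, Dv) * dbinom(n, N, p_capture(r, 6)) *
    dbinom(a, L, p_acoustic(lam, N, 0.03))
  pmf <- w / sum(w)
  u <- (seq_len(20000) - 0.5) / 20000
  got <- vapply(u, function(ui)
    songmark:::cpp_draw_N(ui, n, a, Dv, r, lam, L, 6, 0.03, TRUE), 1L)
  emp <- tabulate(got, nbins = 30) / length(got)
  expect_lt(max(abs(emp[1:10] - pmf[1:10])), 0.002)
})

test_that("mr fits warn about guilds never captured", {
  cfg <- tiny_config()
  cfg$truths["rho_B0"] <- -20 # guild B essentially uncatchable
  sim <- sm_simulate(cfg, seed = 3)
  expect_true(all(sim$data$n[2, ] == 0))
  expect_warning(
    sm_fit(sim$data, model = "mr", chains = 2, iter = 400, burnin = 100,
           seed = 1),
    "never captured")
})
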