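# Independent brute-force oracles: direct summation over the latent N in
# linear space (no log-sum-exp, no adaptive windows), deliberately written
# against the generative model rather than the package internals.

oracle_cell_marginal <- function(n, a, D, r, lambda, L, T_, M,
                                 N_max = 5000, acoustic = TRUE) {
  N <- n:N_max
  p <- 1 - exp(-r * T_)
  terms <- dpois(N, D) * dbinom(n, N, p)
  if (acoustic && L > 0)
    terms <- terms * dbinom(a, L, 1 - exp(-lambda * N * M))
  log(sum(terms))
}

oracle_hist_loglik <- function(cc, y, r, T_) {
  log(r * exp(-r * cc) / (1 - exp(-r * T_))) +
    dpois(y, r * (T_ - cc), log = TRUE)
}

# full log posterior by brute force, matching sm_log_posterior's contract
oracle_log_posterior <- function(params, data, model = "integrated",
                                 priors, N_max = 5000) {
  spec <- data$spec
  lay <- spec$layout
  if (model == "mr") lay <- lay[lay$block != "psi", ]
  theta <- params[lay$term]
  i <- match(names(theta), priors$term)
  lp <- sum(dnorm(theta, priors$mean[i], priors$sd[i], log = TRUE))
  d <- spec$design
  acoustic <- model == "integrated" && !is.null(data$a) && d$n_listening > 0
  for (g in seq_len(d$n_guilds)) {
    gl <- d$guilds[g]
    for (z in seq_len(d$n_events)) {
      D <- expected_abundance(params, spec, gl, z)
      r <- capture_rate(params, spec, gl, z)
      lam <- if (model == "integrated") vocal_rate(params, spec, gl, z) else 0
      av <- if (acoustic) data$a[g, z] else 0L
      lp <- lp + oracle_cell_marginal(
        data$n[g, z], av, D, r, lam,
        if (acoustic) d$n_listening else 0L, d$capture_duration,
        d$period_length, N_max = N_max, acoustic = acoustic)
      h <- data$histories[data$histories$guild == gl &
                            data$histories$event == z, ]
      if (nrow(h))
        lp <- lp + sum(oracle_hist_loglik(h$first_capture_time,
                                          h$n_recaptures, r,
                                          d$capture_duration))
    }
  }
  lp
}

# small, fast simulation scenario used by unit tests: 2 guilds, 6 sites,
# modest abundances so fits take seconds
tiny_config <- function() {
  d <- sm_design(n_guilds = 2, n_sites = 6, n_visits = 2,
                 capture_duration = 6, n_listening = 20,
                 period_length = 0.03, guilds = c("A", "B"))
  sm_sim_config(
    design = d,
    truths = c(nu_A0 = 3.0, nu_B0 = 2.5, nu_1 = 0.01, nu_2 = 0.15,
               rho_A0 = -3.0, rho_B0 = -3.3, rho_1 = -0.01,
               psi_A0 = -4.5, psi_B0 = -4.0))
}

# random tiny cell instances for oracle-equivalence checks
random_cell_instance <- function() {
  D <- runif(1, 0.5, 30)
  r <- exp(runif(1, -4, -0.5))
  lam <- exp(runif(1, -5, -1))
  T_ <- runif(1, 2, 8)
  L <- sample(0:25, 1)
  M <- runif(1, 0.01, 0.1)
  N <- rpois(1, D)
  p <- 1 - exp(-r * T_)
  n <- rbinom(1, N, p)
  a <- if (L > 0) rbinom(1, L, 1 - exp(-lam * N * M)) else 0L
  cc <- runif(n, 0, T_)
  y <- rpois(n, r * (T_ - cc))
  list(n = n, a = a, D = D, r = r, lam = lam, T_ = T_, L = L, M = M,
       histories = tibble::tibble(first_capture_time = cc,
                                  n_recaptures = as.integer(y)))
}
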