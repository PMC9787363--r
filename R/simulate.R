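#' Default true parameters of the three-guild simulation scenario
#'
#' Intercepts and covariate effects used to generate data in the default
#' simulation study: abundance intercepts 5.00, 3.00 and 4.50 for guilds A,
#' B and C, a shared site-covariate effect on abundance (0.01) and on
#' capture rate (-0.01), a shared visit effect on abundance (0.15), capture
#' intercepts -4.00, -3.50 and -4.80, and vocalization intercepts -7.00,
#' -5.00 and -6.00.
#'
#' @return A named numeric vector matching the default simulation spec.
#' @export
sm_default_truths <- function() {
  c(nu_A0 = 5.00, nu_B0 = 3.00, nu_C0 = 4.50, nu_1 = 0.01, nu_2 = 0.15,
    rho_A0 = -4.00, rho_B0 = -3.50, rho_C0 = -4.80, rho_1 = -0.01,
    psi_A0 = -7.00, psi_B0 = -5.00, psi_C0 = -6.00)
}

#' Configure the synthetic-data generator
#'
#' The default configuration reproduces the reference simulation scenario:
#' 20 sites, 3 guilds, 2 visits per site (40 sampling events), a 6-hour
#' capture period, 20 listening periods of 0.03 h each; a site-level
#' covariate drawn Uniform(0, 100) entering both the abundance and the
#' capture predictors with shared coefficients, and a binary visit covariate
#' (0 on the first visit, 1 on the second) entering the abundance predictor;
#' true parameter values from [sm_default_truths()].
#'
#' @param design An [sm_design()]; defaults to the scenario above.
#' @param truths Named numeric vector of true parameter values.
#' @param site_cov_fn Function of the number of sites returning the
#'   site-level covariate values.
#' @param visit_cov_fn Function of the visit index vector returning the
#'   visit-level covariate values.
#' @return A list of class `sm_sim_config`.
#' @export
sm_sim_config <- function(design = sm_design(),
                          truths = sm_default_truths(),
                          site_cov_fn = function(n) runif(n, 0, 100),
                          visit_cov_fn = function(visit)
                            as.numeric(visit > 1)) {
  structure(list(design = design, truths = truths,
                 site_cov_fn = site_cov_fn, visit_cov_fn = visit_cov_fn),
            class = "sm_sim_config")
}

#' Draw the covariate tables of the simulation scenario
#'
#' @param config An [sm_sim_config()].
#' @return A tibble with one row per event: `site`, `visit`, `site_cov`,
#'   `visit_cov`.
#' @export
simulate_covariates <- function(config) {
  d <- config$design
  site_vals <- config$site_cov_fn(d$n_sites)
  tibble::tibble(site = d$events$site, visit = d$events$visit,
                 site_cov = site_vals[d$events$site],
                 visit_cov = config$visit_cov_fn(d$events$visit))
}

#' Elementary generative draws
#'
#' `simulate_abundance()` draws latent population sizes `N ~ Poisson(D)`.
#' `simulate_captures()` pushes `N` individuals through the continuous-time
#' capture process: each individual's first-capture time is
#' `Exponential(rate = r)`, individuals with `c < T` are caught and their
#' recaptures are `Poisson(r (T - c))`. `simulate_acoustics()` draws the
#' number of listening periods with at least one detection,
#' `Binomial(L, 1 - exp(-lambda N M))`.
#'
#' @param D Expected abundance (vectorized).
#' @param N Population size (scalar).
#' @param r Capture rate per hour.
#' @param T_ Capture period in hours.
#' @param lambda Per-capita vocalization detection rate per hour.
#' @param L Number of listening periods.
#' @param M Listening-period length in hours.
#' @param seed Optional integer seed (set locally when supplied).
#' @return `simulate_abundance()`: integer vector. `simulate_captures()`:
#'   list with `n` and a tibble `histories` (`first_capture_time`,
#'   `n_recaptures`). `simulate_acoustics()`: integer scalar.
#' @export
simulate_abundance <- function(D, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(D >= 0))
  rpois(length(D), D)
}

#' @rdname simulate_abundance
#' @export
simulate_captures <- function(N, r, T_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(N >= 0, r >= 0, T_ > 0)
  if (N == 0 || r == 0) {
    return(list(n = 0L, histories = tibble::tibble(
      first_capture_time = numeric(), n_recaptures = integer())))
  }
  cc <- rexp(N, rate = r)
  cc <- cc[cc < T_]
  y <- if (length(cc)) rpois(length(cc), r * (T_ - cc)) else integer()
  list(n = length(cc),
       histories = tibble::tibble(first_capture_time = cc,
                                  n_recaptures = as.integer(y)))
}

#' @rdname simulate_abundance
#' @export
simulate_acoustics <- function(N, lambda, L, M, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(N >= 0, lambda >= 0, L >= 0, M >= 0)
  if (L == 0) return(0L)
  rbinom(1, L, p_acoustic(lambda, N, M))
}

#' Simulate a complete dataset from the generative model
#'
#' Runs the full pipeline: draw covariates, evaluate the log-linear
#' predictors at the true parameters, draw the latent population size of
#' every guild-by-event cell (populations are redrawn independently per
#' event — the model does not assume they stay constant between visits),
#' then the capture histories and acoustic counts.
#'
#' @param config An [sm_sim_config()].
#' @param seed Integer seed; fully determines the output.
#' @return A list with `data` (an [sm_data] object) and `truth` (list with
#'   `params`, the realized `N` matrix, the covariates and the cell-level
#'   rates).
#' @examples
#' sim <- sm_simulate(seed = 1)
#' sim$data
#' @export
sm_simulate <- function(config = sm_sim_config(), seed = 1) {
  stopifnot(inherits(config, "sm_sim_config"))
  set.seed(seed)
  d <- config$design
  covs <- simulate_covariates(config)
  has_site <- "site_cov" %in% names(covs)
  spec <- sm_model_spec(
    d, covs,
    abundance = c(if (has_site) c(site_cov = "shared"),
                  if ("visit_cov" %in% names(covs)) c(visit_cov = "shared")),
    capture = if (has_site) c(site_cov = "shared"))
  theta <- sm_params(spec, config$truths)
  rates <- sm_rates(theta, spec)

  N <- matrix(0L, d$n_guilds, d$n_events,
              dimnames = list(d$guilds, NULL))
  n <- N
  a <- if (d$n_listening > 0) N else NULL
  hist_list <- list()
  for (i in seq_len(nrow(rates))) {
    gi <- match(rates$guild[i], d$guilds)
    z <- rates$event[i]
    Ni <- simulate_abundance(rates$D[i])
    N[gi, z] <- Ni
    cap <- simulate_captures(Ni, rates$r[i], d$capture_duration)
    n[gi, z] <- cap$n
    if (cap$n > 0)
      hist_list[[length(hist_list) + 1L]] <-
        dplyr::mutate(cap$histories, guild = rates$guild[i], event = z,
                      .before = 1)
    if (!is.null(a))
      a[gi, z] <- simulate_acoustics(Ni, rates$lambda[i], d$n_listening,
                                     d$period_length)
  }
  histories <- if (length(hist_list)) dplyr::bind_rows(hist_list)
               else tibble::tibble(guild = character(), event = integer(),
                                   first_capture_time = numeric(),
                                   n_recaptures = integer())
  data <- new_sm_data(spec, n, a,
                      histories[, c("guild", "event", "first_capture_time",
                                    "n_recaptures")])
  list(data = data,
       truth = list(params = sm_params(spec, config$truths), N = N,
                    covariates = covs, rates = rates, seed = seed))
}
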