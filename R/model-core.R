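#' Per-cell rates implied by a parameter vector
#'
#' Evaluates the three log-linear predictors for every guild-by-event cell:
#' expected abundance `D = exp(X nu)`, capture rate `r = exp(W rho)`
#' (captures per hour per individual) and per-capita vocalization detection
#' rate `lambda = exp(G psi)` (detections per hour per individual).
#'
#' @param params Named parameter vector from [sm_params()].
#' @param spec An [sm_model_spec()].
#' @return A tibble with one row per cell: `guild`, `event`, `site`,
#'   `visit`, `D`, `r`, `lambda`.
#' @export
sm_rates <- function(params, spec) {
  stopifnot(inherits(spec, "sm_spec"))
  d <- spec$design
  lay <- spec$layout
  out <- vector("list", d$n_guilds)
  for (g in seq_len(d$n_guilds)) {
    gl <- d$guilds[g]
    eta_D <- drop(spec$X %*% params[coef_index(lay, "nu", gl)])
    eta_r <- drop(spec$W %*% params[coef_index(lay, "rho", gl)])
    eta_l <- drop(spec$G %*% params[coef_index(lay, "psi", gl)])
    if (!all(is.finite(eta_D), is.finite(eta_r), is.finite(eta_l)))
      abort("non-finite linear predictor; check covariates and coefficients")
    out[[g]] <- tibble::tibble(guild = gl, event = d$events$event,
                               site = d$events$site, visit = d$events$visit,
                               D = exp(eta_D), r = exp(eta_r),
                               lambda = exp(eta_l))
  }
  dplyr::bind_rows(out)
}

rate_scalar <- function(params, spec, guild, event, block, mat) {
  stopifnot(inherits(spec, "sm_spec"))
  gl <- if (is.numeric(guild)) spec$design$guilds[guild] else guild
  eta <- drop(mat[event, , drop = FALSE] %*%
                params[coef_index(spec$layout, block, gl)])
  if (!is.finite(eta)) {
    bad <- colnames(mat)[!is.finite(mat[event, ] *
                           params[coef_index(spec$layout, block, gl)])]
    abort(paste0("non-finite linear predictor",
                 if (length(bad)) paste0(" (covariate ",
                                         paste(bad, collapse = ", "), ")")))
  }
  exp(eta)
}

#' Expected abundance, capture rate and vocalization rate for one cell
#'
#' Scalar versions of the log-linear predictors, mainly useful for
#' inspection and testing; [sm_rates()] evaluates all cells at once.
#'
#' @param params Named parameter vector.
#' @param spec An [sm_model_spec()].
#' @param guild Guild label or index.
#' @param event Sampling-event index.
#' @return A positive scalar.
#' @export
expected_abundance <- function(params, spec, guild, event)
  rate_scalar(params, spec, guild, event, "nu", spec$X)

#' @rdname expected_abundance
#' @export
capture_rate <- function(params, spec, guild, event)
  rate_scalar(params, spec, guild, event, "rho", spec$W)

#' @rdname expected_abundance
#' @export
vocal_rate <- function(params, spec, guild, event)
  rate_scalar(params, spec, guild, event, "psi", spec$G)

#' Detection probabilities
#'
#' `p_capture()` is the probability that an individual with capture rate `r`
#' (captures/hour) is caught at least once during a capture period of `T`
#' hours: `1 - exp(-rT)`, the probability that an exponential first-capture
#' time falls below `T`. `p_acoustic()` is the probability that at least one
#' vocalization from a population of `N` individuals, each detected at
#' per-capita rate `lambda` (detections/hour), is recorded during one
#' listening period of `M` hours: `1 - exp(-lambda N M)`.
#'
#' @param r Capture rate per hour (non-negative).
#' @param T_ Capture period in hours (non-negative).
#' @param lambda Per-capita vocalization detection rate per hour.
#' @param N Population size (non-negative integer).
#' @param M Listening-period length in hours.
#' @return A probability in `[0, 1)`, vectorized over the inputs.
#' @examples
#' p_capture(exp(-4), 6)
#' p_acoustic(exp(-7), 148, 0.03)
#' @export
p_capture <- function(r, T_) {
  stopifnot(all(r >= 0), all(T_ >= 0))
  -expm1(-r * T_)
}

#' @rdname p_capture
#' @export
p_acoustic <- function(lambda, N, M) {
  stopifnot(all(lambda >= 0), all(N >= 0), all(M >= 0))
  -expm1(-lambda * N * M)
}

#' Component log-likelihoods
#'
#' `loglik_first_captures()` is the binomial log-likelihood of catching `n`
#' distinct individuals out of a population of size `N` when each is caught
#' with probability `p`. `loglik_acoustic()` is the binomial log-likelihood
#' of `a` listening periods with a detection out of `L` when each period
#' detects with probability `p`. `loglik_capture_history()` is the
#' log-likelihood of one marked individual's history — first capture at time
#' `c` (exponential density truncated to the capture period, since the
#' binomial first-capture term already accounts for detection) plus `y`
#' recaptures (Poisson with exposure `r (T - c)`).
#'
#' @param n,N,p,a,L Binomial counts, population size and probabilities.
#' @param first_capture_time Time of first capture in hours, in `[0, T)`.
#' @param n_recaptures Number of recaptures after the first capture.
#' @param r Capture rate per hour.
#' @param T_ Capture period in hours.
#' @return Log-likelihood value(s); `-Inf` for impossible data.
#' @export
loglik_first_captures <- function(n, N, p) {
  out <- dbinom(n, N, p, log = TRUE)
  out[n > N] <- -Inf
  out
}

#' @rdname loglik_first_captures
#' @export
loglik_acoustic <- function(a, L, p) dbinom(a, L, p, log = TRUE)

#' @rdname loglik_first_captures
#' @export
loglik_capture_history <- function(first_capture_time, n_recaptures, r, T_) {
  k <- max(length(first_capture_time), length(n_recaptures),
           length(r), length(T_))
  cc <- rep_len(first_capture_time, k)
  if (any(cc < 0) || any(cc >= rep_len(T_, k)))
    abort("first_capture_time must lie in [0, T): record contradicts detection")
  cpp_hist_ll_records(cc, as.integer(rep_len(n_recaptures, k)),
                      rep_len(r, k), rep_len(T_, k))
}

#' Marginal log-likelihood of one guild-by-event cell
#'
#' The latent population size `N ~ Poisson(D)` is marginalized by finite
#' summation (log-sum-exp over an adaptive window around the integrand
#' mode): the cell likelihood is the sum over `N >= n` of
#' `Poisson(N; D) * Binomial(n; N, p_capture) * Binomial(a; L, p_acoustic(N))`,
#' multiplied by the capture-history terms, which do not depend on `N`.
#' With `L = 0` (or `acoustic = FALSE`) this reduces, by Poisson thinning,
#' to the closed-form mark-recapture marginal
#' `Poisson(n; D * p_capture)` times the history terms.
#'
#' @param n First-capture count for the cell.
#' @param histories Tibble (or data frame) of the cell's capture histories
#'   with columns `first_capture_time` and `n_recaptures`; may be empty.
#' @param a Number of listening periods with a detection (ignored when
#'   `acoustic = FALSE`).
#' @param D Expected abundance.
#' @param r Capture rate per hour.
#' @param lambda Per-capita vocalization detection rate per hour.
#' @param T_ Capture period (hours).
#' @param L Number of listening periods.
#' @param M Listening-period length (hours).
#' @param acoustic If `FALSE`, the acoustic factor is dropped (the
#'   mark-recapture-only model).
#' @return The cell log-likelihood (a scalar).
#' @export
marginal_cell_loglik <- function(n, histories, a, D, r, lambda, T_, L, M,
                                 acoustic = TRUE) {
  stopifnot(n >= 0, a >= 0, a <= max(L, a), D >= 0, r >= 0, lambda >= 0)
  if (nrow(histories) != n)
    abort("number of capture-history records must equal n")
  ll <- cpp_cell_marginal(as.integer(n), as.integer(a), D, r, lambda,
                          as.integer(L), T_, M, isTRUE(acoustic))
  if (n > 0)
    ll <- ll + sum(loglik_capture_history(histories$first_capture_time,
                                          histories$n_recaptures, r, T_))
  ll
}
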