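#' Normal priors for the model coefficients
#'
#' Every coefficient carries an independent normal prior. Defaults follow
#' the reference simulation scenario: abundance intercepts N(6, 0.82),
#' capture-rate intercepts N(0, 3.16), vocalization-rate intercepts
#' N(-5, 2), covariate effects N(0, 1) — except a covariate named
#' `visit_cov`, the binary visit effect of the default scenario, which
#' carries the tighter N(0, 0.2).
#'
#' @param spec An [sm_model_spec()].
#' @param overrides Named list of `c(mean, sd)` pairs keyed by parameter
#'   term, replacing the defaults.
#' @return A tibble with columns `term`, `mean`, `sd`.
#' @export
sm_priors <- function(spec, overrides = NULL) {
  lay <- spec$layout
  mean <- ifelse(lay$q == 0,
                 c(nu = 6, rho = 0, psi = -5)[lay$block], 0)
  sd <- ifelse(lay$q == 0,
               c(nu = 0.82, rho = 3.16, psi = 2)[lay$block],
               ifelse(lay$covariate == "visit_cov", 0.2, 1))
  pr <- tibble::tibble(term = lay$term, mean = unname(mean),
                       sd = unname(sd))
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), pr$term)
    if (length(bad))
      abort(paste0("priors for unknown term(s): ", paste(bad, collapse = ", ")))
    for (nm in names(overrides)) {
      pr$mean[pr$term == nm] <- overrides[[nm]][1]
      pr$sd[pr$term == nm] <- overrides[[nm]][2]
    }
  }
  if (any(pr$sd <= 0)) abort("prior standard deviations must be positive")
  pr
}

#' Log prior density
#'
#' @param params Named parameter vector.
#' @param priors Prior tibble from [sm_priors()].
#' @return Sum of normal log-densities.
#' @export
sm_log_prior <- function(params, priors) {
  i <- match(names(params), priors$term)
  if (anyNA(i)) abort("parameters and priors do not match")
  sum(dnorm(params, priors$mean[i], priors$sd[i], log = TRUE))
}

# --- likelihood engine -----------------------------------------------------

# Precomputes everything the sampler touches repeatedly: coefficient index
# maps per guild, per-guild observation arrays and capture-history arrays.
sm_engine <- function(data, model = c("integrated", "mr"), spec = NULL) {
  model <- match.arg(model)
  if (is.null(data)) {
    if (is.null(spec)) abort("a model spec is required when data is NULL")
    lay <- spec$layout
    if (model == "mr") lay <- lay[lay$block != "psi", ]
    return(list(model = model, spec = spec, layout = lay, n_guilds = 0L,
                prior_only = TRUE))
  }
  stopifnot(inherits(data, "sm_data"))
  spec <- data$spec
  d <- spec$design
  lay <- spec$layout
  integrated <- model == "integrated" && !is.null(data$a) &&
    d$n_listening > 0
  if (model == "integrated" && (is.null(data$a) || d$n_listening == 0))
    inform("no acoustic data present; integrated model reduces to the mark-recapture likelihood")
  if (model == "mr") lay <- lay[lay$block != "psi", ]
  E <- d$n_events
  idx <- list()
  for (b in intersect(c("nu", "rho", "psi"), unique(lay$block)))
    idx[[b]] <- lapply(d$guilds, function(g) coef_index(lay, b, g))
  hist_by_guild <- lapply(d$guilds, function(g) {
    h <- data$histories[data$histories$guild == g, ]
    list(event0 = as.integer(h$event - 1L), cc = h$first_capture_time,
         y = as.integer(h$n_recaptures))
  })
  a <- data$a
  if (is.null(a)) a <- matrix(0L, d$n_guilds, E)
  Lv <- rep(if (integrated) d$n_listening else 0L, E)
  list(model = model, spec = spec, layout = lay, prior_only = FALSE,
       col_scale = layout_col_scale(lay, spec),
       integrated = integrated, n_guilds = d$n_guilds, n_events = E,
       guilds = d$guilds, X = spec$X, W = spec$W, G = spec$G, idx = idx,
       n = data$n, a = a, L = as.integer(Lv),
       T_ = rep(d$capture_duration, E), M = d$period_length,
       hist = hist_by_guild)
}

# typical magnitude of each design column, used to put proposal step sizes
# and start jitter on the scale of the corresponding coefficient
layout_col_scale <- function(lay, spec) {
  mats <- list(nu = spec$X, rho = spec$W, psi = spec$G)
  vapply(seq_len(nrow(lay)), function(i) {
    col <- lay$covariate[i]
    if (col == "(Intercept)") return(1)
    s <- sd(mats[[lay$block[i]]][, col])
    max(s, 1e-8)
  }, numeric(1))
}

guild_loglik <- function(eng, theta, g) {
  D <- exp(drop(eng$X %*% theta[eng$idx$nu[[g]]]))
  r <- exp(drop(eng$W %*% theta[eng$idx$rho[[g]]]))
  lam <- if (eng$integrated) exp(drop(eng$G %*% theta[eng$idx$psi[[g]]]))
         else rep(0, eng$n_events)
  marg <- cpp_cell_marginal(eng$n[g, ], eng$a[g, ], D, r, lam, eng$L,
                            eng$T_, eng$M, eng$integrated)
  h <- eng$hist[[g]]
  hl <- if (length(h$cc))
    cpp_hist_loglik(h$event0, h$cc, h$y, r, eng$T_, eng$n_events)
  else 0
  sum(marg) + sum(hl)
}

#' Log posterior of the integrated or mark-recapture-only model
#'
#' Sum of the normal log prior and, per guild-by-event cell, the
#' latent-N-marginalized likelihood (see [marginal_cell_loglik()]). The
#' `"mr"` model ignores acoustic counts entirely and drops the vocalization
#' block from the parameter vector.
#'
#' @param params Named parameter vector (must match the model's layout;
#'   the `"mr"` model has no `psi` coefficients).
#' @param data An [sm_data] object, or `NULL` for the prior alone.
#' @param model `"integrated"` or `"mr"`.
#' @param priors Prior tibble; defaults to [sm_priors()] of the data's spec.
#' @param spec Model spec, required when `data` is `NULL`.
#' @return The unnormalized log posterior (a scalar).
#' @export
sm_log_posterior <- function(params, data, model = c("integrated", "mr"),
                             priors = NULL, spec = NULL) {
  model <- match.arg(model)
  eng <- sm_engine(data, model, spec)
  if (is.null(priors)) priors <- sm_priors(eng$spec)
  priors <- priors[priors$term %in% eng$layout$term, ]
  if (!identical(sort(names(params)), sort(eng$layout$term)))
    abort("parameter names do not match the model layout")
  theta <- params[eng$layout$term]
  lp <- sm_log_prior(theta, priors)
  if (!eng$prior_only)
    lp <- lp + sum(vapply(seq_len(eng$n_guilds),
                          function(g) guild_loglik(eng, theta, g),
                          numeric(1)))
  lp
}

# --- adaptive Metropolis-within-Gibbs sampler ------------------------------

# Blocks: one per guild (all guild-specific coefficients of that guild) plus
# one block of shared coefficients. Guild blocks need only that guild's
# likelihood; the shared block touches all guilds.
make_blocks <- function(eng) {
  lay <- eng$layout
  blocks <- list()
  if (eng$n_guilds > 0 || eng$prior_only) {
    guilds <- unique(lay$guild[!is.na(lay$guild)])
    for (g in guilds) {
      gi <- if (eng$prior_only) integer() else match(g, eng$guilds)
      blocks[[length(blocks) + 1L]] <-
        list(idx = which(lay$guild == g & !is.na(lay$guild)), guilds = gi)
    }
  }
  shared <- which(is.na(lay$guild))
  if (length(shared))
    blocks[[length(blocks) + 1L]] <-
      list(idx = shared,
           guilds = if (eng$prior_only) integer() else seq_len(eng$n_guilds))
  blocks
}

run_chain <- function(eng, priors, n_iter, burnin, thin, chain_seed,
                      target_accept = 0.3) {
  set.seed(chain_seed)
  lay <- eng$layout
  npar <- nrow(lay)
  pm <- priors$mean[match(lay$term, priors$term)]
  ps <- priors$sd[match(lay$term, priors$term)]
  cs <- if (is.null(eng$col_scale)) rep(1, npar) else eng$col_scale
  base <- pmin(ps, 1 / cs, 1) # per-parameter step scale
  theta <- setNames(pm + 0.3 * base * rnorm(npar), lay$term)
  blocks <- make_blocks(eng)
  # adaptation state per block
  st <- lapply(blocks, function(b) {
    d <- length(b$idx)
    s0 <- 0.2 * base[b$idx]
    list(ls = log(1 / sqrt(d)), m = theta[b$idx], S = diag(s0^2, d),
         R = diag(s0, d), acc = 0, tries = 0)
  })
  llg <- if (eng$prior_only) numeric(0)
         else vapply(seq_len(eng$n_guilds),
                     function(g) guild_loglik(eng, theta, g), numeric(1))
  lprior <- dnorm(theta, pm, ps, log = TRUE)

  n_keep <- floor((n_iter - burnin) / thin)
  draws <- matrix(NA_real_, n_keep, npar, dimnames = list(NULL, lay$term))
  lp_trace <- numeric(n_keep)
  k <- 0L
  for (it in seq_len(n_iter)) {
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]; s <- st[[bi]]
      d <- length(b$idx)
      step <- exp(s$ls) * drop(rnorm(d) %*% s$R)
      prop <- theta
      prop[b$idx] <- theta[b$idx] + step
      lpr_new <- dnorm(prop[b$idx], pm[b$idx], ps[b$idx], log = TRUE)
      dlp <- sum(lpr_new) - sum(lprior[b$idx])
      ll_new <- numeric(0)
      if (length(b$guilds)) {
        ll_new <- vapply(b$guilds, function(g) guild_loglik(eng, prop, g),
                         numeric(1))
        dlp <- dlp + sum(ll_new) - sum(llg[b$guilds])
      }
      alpha <- if (is.finite(dlp)) min(1, exp(dlp)) else 0
      if (runif(1) < alpha) {
        theta <- prop
        lprior[b$idx] <- lpr_new
        if (length(b$guilds)) llg[b$guilds] <- ll_new
        s$acc <- s$acc + 1
      }
      s$tries <- s$tries + 1
      if (it <= burnin) {
        gam <- min(0.25, 2 / it^0.6)
        s$ls <- s$ls + gam * (alpha - target_accept)
        dx <- theta[b$idx] - s$m
        s$m <- s$m + gam * dx
        s$S <- s$S + gam * (tcrossprod(dx) - s$S)
        if (it >= 200 && it %% 25 == 0) {
          ch <- tryCatch(chol(s$S + diag(1e-10, d)), error = function(e) NULL)
          if (!is.null(ch)) s$R <- ch
        }
      }
      st[[bi]] <- s
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      k <- k + 1L
      draws[k, ] <- theta
      lp_trace[k] <- sum(lprior) + sum(llg)
    }
  }
  list(draws = draws, lp = lp_trace,
       accept = vapply(st, function(s) s$acc / s$tries, numeric(1)))
}

#' Fit the integrated or mark-recapture-only model by MCMC
#'
#' Samples the posterior with an adaptive random-walk
#' Metropolis-within-Gibbs sampler: parameters are updated in blocks (all
#' guild-specific coefficients of one guild per block, plus one block of
#' shared coefficients) with multivariate normal proposals whose scale and
#' covariance adapt during burn-in and are frozen afterwards. The latent
#' population sizes are marginalized out of the likelihood and can be
#' re-materialized with [posterior_abundance()]. Convergence is assessed
#' with the split-chain Gelman-Rubin diagnostic ([rhat()]); the fit is
#' flagged `converged` when every parameter's R-hat is below 1.1 — a fit
#' that fails the threshold is returned flagged, not raised.
#'
#' @param data An [sm_data] object, or `NULL` to sample the prior (a
#'   data-free fit; `spec` must then be supplied).
#' @param model `"integrated"` (mark-recapture + acoustics) or `"mr"`
#'   (mark-recapture only; acoustic counts ignored, no vocalization
#'   parameters).
#' @param priors Prior tibble from [sm_priors()]; defaults to the spec's
#'   default priors.
#' @param chains Number of chains (at least 2 for R-hat).
#' @param iter Iterations per chain, including burn-in.
#' @param burnin Burn-in iterations discarded per chain (adaptation window).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Master seed; per-chain seeds are derived from it and fully
#'   determine the fit.
#' @param spec Model spec, required when `data` is `NULL`.
#' @param target_accept Proposal acceptance rate targeted during adaptation.
#' @return An object of class `sm_fit`; see [tidy.sm_fit()],
#'   [glance.sm_fit()], [autoplot.sm_fit()] and [posterior_abundance()].
#' @examples
#' \donttest{
#' sim <- sm_simulate(sm_sim_config(sm_design(n_sites = 4)), seed = 1)
#' fit <- sm_fit(sim$data, chains = 2, iter = 2000, burnin = 500, seed = 1)
#' tidy(fit)
#' }
#' @export
sm_fit <- function(data, model = c("integrated", "mr"), priors = NULL,
                   chains = 3, iter = 100000, burnin = 5000, thin = 1,
                   seed = 1, spec = NULL, target_accept = 0.3) {
  model <- match.arg(model)
  stopifnot(chains >= 2, burnin < iter, thin >= 1)
  t0 <- proc.time()[["elapsed"]]
  eng <- sm_engine(data, model, spec)
  if (model == "mr" && !is.null(data)) {
    silent <- rowSums(data$n) == 0
    if (any(silent))
      warn(paste0("guild(s) never captured anywhere: ",
                  paste(eng$guilds[silent], collapse = ", "),
                  "; under the mark-recapture-only model their abundance ",
                  "is informed by the prior alone"))
  }
  if (is.null(priors)) priors <- sm_priors(eng$spec)
  priors_used <- priors[match(eng$layout$term, priors$term), ]
  if (anyNA(priors_used$term)) abort("priors must cover every parameter")

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  res <- lapply(chain_seeds, function(cs)
    run_chain(eng, priors_used, iter, burnin, thin, cs, target_accept))

  draws <- array(NA_real_, c(nrow(res[[1]]$draws), nrow(eng$layout), chains),
                 dimnames = list(NULL, eng$layout$term, NULL))
  for (ch in seq_len(chains)) draws[, , ch] <- res[[ch]]$draws
  rh <- apply(draws, 2, function(m) rhat(m))
  pooled <- apply(draws, 2, identity)
  hpd <- t(apply(pooled, 2, hpd_interval))
  summary <- tibble::tibble(
    term = eng$layout$term,
    estimate = colMeans(pooled), std.error = apply(pooled, 2, sd),
    conf.low = hpd[, 1], conf.high = hpd[, 2], rhat = unname(rh))
  structure(
    list(draws = draws, layout = eng$layout, priors = priors_used,
         model = model, summary = summary, rhat = rh,
         converged = all(rh < 1.1),
         lp = vapply(res, function(x) mean(x$lp), numeric(1)),
         accept = t(vapply(res, function(x) x$accept,
                           numeric(length(res[[1]]$accept)))),
         config = list(chains = chains, iter = iter, burnin = burnin,
                       thin = thin, seed = seed,
                       target_accept = target_accept),
         data = data, spec = eng$spec,
         elapsed = proc.time()[["elapsed"]] - t0),
    class = "sm_fit")
}

#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Each chain is split in half and the classic potential scale reduction
#' factor is computed over the resulting sequences:
#' `sqrt(((n-1)/n W + B/n) / W)` with `W` the mean within-sequence variance
#' and `B/n` the between-sequence variance of the means. Values near 1
#' indicate the chains agree; below 1.1 is the conventional convergence
#' threshold.
#'
#' @param x Matrix of draws, iterations by chains.
#' @return The R-hat statistic, floored at 1 (identical chains give exactly
#'   1).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  n <- floor(nrow(x) / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(n), j], x[n + seq_len(n), j])))
  W <- mean(apply(halves, 2, var))
  B <- n * var(colMeans(halves))
  if (W == 0) return(if (B == 0) 1 else Inf)
  # clamped at 1, the statistic's asymptotic floor (identical chains give
  # B = 0 and a raw value of sqrt((n-1)/n))
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

#' Highest-posterior-density interval of a sample
#'
#' The shortest contiguous interval containing `prob` of the empirical
#' draws — for skewed posteriors this differs from the symmetric quantile
#' interval (e.g. for an exponential sample the HPD is anchored near 0).
#'
#' @param x Numeric vector of draws.
#' @param prob Probability mass of the interval.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  i <- which.min(x[k:n] - x[seq_len(n - k + 1)])
  c(lower = x[i], upper = x[i + k - 1])
}

#' Posterior of the latent population sizes
#'
#' The latent `N` of every guild-by-event cell is marginalized out during
#' fitting; this re-materializes it by the law of total probability: for a
#' subsample of posterior draws the conditional pmf of `N` given the
#' parameters and the cell's data is computed over its support and one `N`
#' is drawn per cell per draw, giving a sample from the joint posterior.
#'
#' @param fit An [sm_fit()] result fitted to data.
#' @param n_draws Number of posterior draws to re-materialize.
#' @param seed Seed for the subsampling and conditional draws.
#' @return A tibble per cell: `guild`, `event`, `site`, `visit`, `n`,
#'   posterior `mean`, `sd` and 95% HPD bounds of `N`.
#' @export
posterior_abundance <- function(fit, n_draws = 400, seed = 1) {
  stopifnot(inherits(fit, "sm_fit"))
  if (is.null(fit$data)) abort("fit has no data; N has no posterior")
  eng <- sm_engine(fit$data, fit$model)
  set.seed(seed)
  pooled <- apply(fit$draws, 2, identity)
  take <- sample.int(nrow(pooled), min(n_draws, nrow(pooled)))
  E <- eng$n_events
  out <- vector("list", eng$n_guilds)
  for (g in seq_len(eng$n_guilds)) {
    Ns <- matrix(0L, length(take), E)
    for (j in seq_along(take)) {
      th <- pooled[take[j], ]
      D <- exp(drop(eng$X %*% th[eng$idx$nu[[g]]]))
      r <- exp(drop(eng$W %*% th[eng$idx$rho[[g]]]))
      lam <- if (eng$integrated) exp(drop(eng$G %*% th[eng$idx$psi[[g]]]))
             else rep(0, E)
      for (z in seq_len(E))
        Ns[j, z] <- cpp_draw_N(runif(1), eng$n[g, z], eng$a[g, z], D[z],
                               r[z], lam[z], eng$L[z], eng$T_[z], eng$M,
                               eng$integrated)
    }
    hpd <- t(apply(Ns, 2, hpd_interval))
    out[[g]] <- tibble::tibble(
      guild = eng$guilds[g], event = seq_len(E),
      site = eng$spec$design$events$site,
      visit = eng$spec$design$events$visit, n = eng$n[g, ],
      mean = colMeans(Ns), sd = apply(Ns, 2, sd),
      conf.low = hpd[, 1], conf.high = hpd[, 2])
  }
  dplyr::bind_rows(out)
}
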