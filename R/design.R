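#' Define a closed-population survey design
#'
#' A design describes the dimensions of the study — guilds, sites and repeat
#' visits — together with the per-event survey effort: the mist-netting
#' duration `capture_duration` (hours), the number of acoustic listening
#' periods `n_listening` and the length of one listening period
#' `period_length` (hours). Every site-by-visit combination is one *sampling
#' event*, the closed-population unit over which captures and listening
#' periods accrue.
#'
#' @param n_guilds Number of guilds (species, families or functional groups
#'   sharing model parameters). At least 1.
#' @param n_sites Number of sites. At least 1.
#' @param n_visits Number of visits per site. At least 1.
#' @param capture_duration Mist-netting duration per event, in hours
#'   (the capture period `T`). Must be positive.
#' @param n_listening Number of listening periods per event (`L`); `0` means
#'   no acoustic survey (mark-recapture-only data).
#' @param period_length Length of one listening period, in hours (`M`).
#' @param guilds Character labels for the guilds; defaults to `A`, `B`, ...
#'
#' @return An object of class `sm_design`: a list with the effort constants
#'   and an `events` tibble (one row per sampling event with columns
#'   `event`, `site`, `visit`).
#' @examples
#' d <- sm_design(n_guilds = 3, n_sites = 20, n_visits = 2)
#' d$events
#' @export
sm_design <- function(n_guilds = 3, n_sites = 20, n_visits = 2,
                      capture_duration = 6, n_listening = 20,
                      period_length = 0.03,
                      guilds = LETTERS[seq_len(n_guilds)]) {
  stopifnot(n_guilds >= 1, n_sites >= 1, n_visits >= 1,
            capture_duration > 0, n_listening >= 0, period_length > 0,
            length(guilds) == n_guilds, !anyDuplicated(guilds))
  events <- tidyr::expand_grid(site = seq_len(n_sites),
                               visit = seq_len(n_visits))
  events <- tibble::tibble(event = seq_len(nrow(events)),
                           site = events$site, visit = events$visit)
  structure(
    list(n_guilds = as.integer(n_guilds), n_sites = as.integer(n_sites),
         n_visits = as.integer(n_visits), n_events = nrow(events),
         capture_duration = capture_duration,
         n_listening = as.integer(n_listening),
         period_length = period_length,
         guilds = as.character(guilds), events = events),
    class = "sm_design")
}

#' @export
print.sm_design <- function(x, ...) {
  cat("<sm_design> ", x$n_guilds, " guilds x ", x$n_sites, " sites x ",
      x$n_visits, " visits (", x$n_events, " events)\n",
      "  capture period T = ", x$capture_duration, " h; L = ",
      x$n_listening, " listening periods of M = ", x$period_length,
      " h\n", sep = "")
  invisible(x)
}

term_spec <- function(terms, covariates, what) {
  if (is.null(terms)) terms <- character()
  if (length(terms) && is.null(names(terms)))
    abort(paste0("`", what, "` terms must be a named vector, e.g. ",
                 "c(canopy = \"shared\")"))
  bad <- setdiff(terms, c("shared", "guild"))
  if (length(bad))
    abort(paste0("coefficient sharing must be \"shared\" or \"guild\", got ",
                 paste(bad, collapse = ", ")))
  miss <- setdiff(names(terms), names(covariates))
  if (length(miss))
    abort(paste0("covariate(s) ", paste(miss, collapse = ", "),
                 " in `", what, "` not found in the covariate table"))
  tibble::tibble(q = seq_along(terms),
                 covariate = if (length(terms)) names(terms) else character(),
                 guild_specific = unname(terms == "guild"))
}

design_matrix <- function(terms, covariates, n_events) {
  X <- cbind(`(Intercept)` = rep(1, n_events))
  for (v in terms$covariate) X <- cbind(X, covariates[[v]])
  colnames(X) <- c("(Intercept)", terms$covariate)
  if (!all(is.finite(X))) abort("design matrices must contain finite values only")
  X
}

#' Specify the log-linear predictors of the model
#'
#' Three log-linear predictors drive the model: expected abundance
#' `log D = X nu`, capture rate `log r = W rho` (captures per hour) and
#' per-capita vocalization detection rate `log lambda = G psi` (detections
#' per hour). Each predictor has a guild-specific intercept; every further
#' covariate enters with a coefficient that is either shared across guilds
#' or guild-specific.
#'
#' @param design An [sm_design()].
#' @param covariates A tibble of event-level covariates with one row per
#'   sampling event, keyed by `site` and `visit` columns; remaining columns
#'   are covariate values. `NULL` for intercept-only models.
#' @param abundance,capture,vocal Named character vectors choosing the
#'   covariate columns entering each predictor and their coefficient
#'   sharing: `c(canopy = "guild", season = "shared")`. Intercepts are
#'   implicit and always guild-specific.
#'
#' @return An object of class `sm_spec` holding the design matrices, the
#'   sharing maps and the parameter layout (see [sm_param_layout()]).
#' @examples
#' d <- sm_design(n_sites = 4)
#' cov <- dplyr::mutate(d$events, elev = rnorm(dplyr::n()))
#' sm_model_spec(d, cov, abundance = c(elev = "shared"))
#' @export
sm_model_spec <- function(design, covariates = NULL, abundance = NULL,
                          capture = NULL, vocal = NULL) {
  stopifnot(inherits(design, "sm_design"))
  if (is.null(covariates)) {
    covariates <- design$events
  } else {
    stopifnot(all(c("site", "visit") %in% names(covariates)))
    covariates <- dplyr::left_join(design$events, covariates,
                                   by = c("site", "visit"))
    if (anyNA(covariates))
      abort("covariate table does not cover every sampling event")
  }
  terms <- list(nu = term_spec(abundance, covariates, "abundance"),
                rho = term_spec(capture, covariates, "capture"),
                psi = term_spec(vocal, covariates, "vocal"))
  mats <- list(X = design_matrix(terms$nu, covariates, design$n_events),
               W = design_matrix(terms$rho, covariates, design$n_events),
               G = design_matrix(terms$psi, covariates, design$n_events))
  spec <- structure(list(design = design, covariates = covariates,
                         terms = terms, X = mats$X, W = mats$W, G = mats$G),
                    class = "sm_spec")
  spec$layout <- sm_param_layout(spec)
  spec
}

#' Parameter layout of a model specification
#'
#' Enumerates the flat parameter vector implied by a model spec: abundance
#' coefficients (`nu`), then capture coefficients (`rho`), then vocalization
#' coefficients (`psi`); within a block, covariates in order with
#' guild-specific coefficients expanded per guild. Names follow
#' `nu_A0` (guild-specific, guild A, covariate 0 = intercept) and `nu_1`
#' (shared, covariate 1).
#'
#' @param spec An [sm_model_spec()].
#' @return A tibble with columns `term`, `block`, `q`, `guild` (`NA` for
#'   shared coefficients) and `covariate`.
#' @export
sm_param_layout <- function(spec) {
  guilds <- spec$design$guilds
  one_block <- function(block) {
    tm <- spec$terms[[block]]
    rows <- list(tibble::tibble(term = paste0(block, "_", guilds, 0),
                                block = block, q = 0L, guild = guilds,
                                covariate = "(Intercept)"))
    for (k in seq_len(nrow(tm))) {
      rows[[k + 1L]] <- if (tm$guild_specific[k]) {
        tibble::tibble(term = paste0(block, "_", guilds, tm$q[k]),
                       block = block, q = tm$q[k], guild = guilds,
                       covariate = tm$covariate[k])
      } else {
        tibble::tibble(term = paste0(block, "_", tm$q[k]), block = block,
                       q = tm$q[k], guild = NA_character_,
                       covariate = tm$covariate[k])
      }
    }
    dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(lapply(c("nu", "rho", "psi"), one_block))
}

# positions in the flat parameter vector of the coefficients for `block`
# seen by guild `g`: length Q+1, ordered by covariate index q.
coef_index <- function(layout, block, g) {
  lb <- layout[layout$block == block, ]
  qs <- sort(unique(lb$q))
  vapply(qs, function(q) {
    i <- which(lb$q == q & (is.na(lb$guild) | lb$guild == g))
    which(layout$term == lb$term[i])
  }, integer(1))
}

#' Construct a named parameter vector for a model spec
#'
#' @param spec An [sm_model_spec()].
#' @param values Named numeric values; names must match the spec's
#'   parameter layout (`sm_param_layout(spec)$term`). Unnamed defaults
#'   to zero.
#' @return A named numeric vector in layout order.
#' @export
sm_params <- function(spec, values = NULL) {
  terms <- spec$layout$term
  theta <- setNames(numeric(length(terms)), terms)
  if (!is.null(values)) {
    bad <- setdiff(names(values), terms)
    if (length(bad))
      abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    theta[names(values)] <- values
  }
  if (!all(is.finite(theta))) abort("parameters must be finite")
  theta
}

#' Assemble a dataset of capture histories and acoustic counts
#'
#' @param spec An [sm_model_spec()].
#' @param captures Tibble of individual capture histories with columns
#'   `guild`, `site`, `visit`, `first_capture_time` (hours since the event
#'   start, in `[0, T)`) and `n_recaptures`.
#' @param acoustics Tibble with columns `guild`, `site`, `visit`,
#'   `n_detected` (listening periods with at least one detection); `NULL`
#'   loads as mark-recapture-only data (no listening periods).
#' @return An object of class `sm_data`.
#' @export
sm_data <- function(spec, captures = NULL, acoustics = NULL) {
  design <- spec$design
  G <- design$n_guilds; E <- design$n_events
  n <- matrix(0L, G, E, dimnames = list(design$guilds, NULL))
  histories <- tibble::tibble(guild = character(), event = integer(),
                              first_capture_time = numeric(),
                              n_recaptures = integer())
  if (!is.null(captures) && nrow(captures)) {
    captures <- dplyr::left_join(
      captures, design$events, by = c("site", "visit"))
    if (anyNA(captures$event))
      abort("captures reference site/visit combinations not in the design")
    histories <- tibble::tibble(
      guild = as.character(captures$guild), event = captures$event,
      first_capture_time = captures$first_capture_time,
      n_recaptures = as.integer(captures$n_recaptures))
    tab <- table(factor(histories$guild, levels = design$guilds),
                 factor(histories$event, levels = seq_len(E)))
    n <- matrix(as.integer(tab), G, E, dimnames = list(design$guilds, NULL))
  }
  a <- NULL
  if (!is.null(acoustics)) {
    acoustics <- dplyr::left_join(acoustics, design$events,
                                  by = c("site", "visit"))
    if (anyNA(acoustics$event))
      abort("acoustics reference site/visit combinations not in the design")
    a <- matrix(0L, G, E, dimnames = list(design$guilds, NULL))
    gi <- match(as.character(acoustics$guild), design$guilds)
    a[cbind(gi, acoustics$event)] <- as.integer(acoustics$n_detected)
  }
  new_sm_data(spec, n, a, histories)
}

# internal constructor on the matrix representation used by the simulator
new_sm_data <- function(spec, n, a, histories) {
  x <- structure(list(spec = spec, design = spec$design, n = n, a = a,
                      histories = histories), class = "sm_data")
  validate_sm_data(x)
}

validate_sm_data <- function(x) {
  design <- x$design
  stopifnot(is.matrix(x$n), nrow(x$n) == design$n_guilds,
            ncol(x$n) == design$n_events, all(x$n >= 0))
  if (!is.null(x$a)) {
    stopifnot(is.matrix(x$a), nrow(x$a) == design$n_guilds,
              ncol(x$a) == design$n_events)
    if (any(x$a < 0) || any(x$a > design$n_listening))
      abort("acoustic counts must satisfy 0 <= a <= L")
  }
  h <- x$histories
  if (nrow(h)) {
    if (any(h$first_capture_time < 0) ||
        any(h$first_capture_time >= design$capture_duration))
      abort(paste0("first capture times must lie in [0, T); T = ",
                   design$capture_duration, " h"))
    if (any(h$n_recaptures < 0)) abort("recapture counts must be >= 0")
    if (!all(h$guild %in% design$guilds))
      abort("capture histories reference unknown guilds")
    tab <- table(factor(h$guild, levels = design$guilds),
                 factor(h$event, levels = seq_len(design$n_events)))
    if (!all(as.integer(tab) == as.integer(x$n)))
      abort("first-capture counts do not match the capture-history records")
  } else if (any(x$n > 0)) {
    abort("first-capture counts are positive but no histories are present")
  }
  x
}

#' @export
print.sm_data <- function(x, ...) {
  d <- x$design
  cat("<sm_data> ", d$n_guilds, " guilds x ", d$n_events, " events; ",
      sum(x$n), " first captures, ", nrow(x$histories), " histories; ",
      if (is.null(x$a)) "no acoustic data"
      else paste0(sum(x$a), " acoustic detections (L = ", d$n_listening, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Observed counts of a dataset as a tibble
#'
#' One row per guild-by-event cell with the first-capture count `n`, the
#' number of listening periods with a detection `a` (`NA` when no acoustic
#' survey ran) and the event keys.
#'
#' @param data An [sm_data] object.
#' @return A tibble with columns `guild`, `event`, `site`, `visit`, `n`, `a`.
#' @export
sm_counts <- function(data) {
  stopifnot(inherits(data, "sm_data"))
  d <- data$design
  out <- tidyr::expand_grid(guild = d$guilds, event = seq_len(d$n_events))
  out$n <- data$n[cbind(match(out$guild, d$guilds), out$event)]
  out$a <- if (is.null(data$a)) NA_integer_
           else data$a[cbind(match(out$guild, d$guilds), out$event)]
  dplyr::left_join(out, d$events, by = "event") |>
    dplyr::select("guild", "event", "site", "visit", "n", "a")
}
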