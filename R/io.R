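#' Write a dataset to delimited text tables
#'
#' Writes the four-table on-disk representation (UTF-8 CSV with header
#' rows, times in hours, 1-based public identifiers, rows sorted by guild,
#' site, visit):
#' `captures.csv` (guild_id, site_id, visit_id, individual_id,
#' first_capture_time_h, n_recaptures), `acoustics.csv` (guild_id, site_id,
#' visit_id, n_listening_periods, n_periods_with_detection,
#' period_length_h), `covariates.csv` (site_id, visit_id, covariate_name,
#' value), `events.csv` (site_id, visit_id, capture_duration_h), plus
#' `spec.json` recording guild labels and the coefficient-sharing maps.
#'
#' @param data An [sm_data] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
sm_write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "sm_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- data$design
  ev <- d$events
  h <- data$histories
  caps <- tibble::tibble(
    guild_id = match(h$guild, d$guilds),
    site_id = ev$site[h$event], visit_id = ev$visit[h$event],
    first_capture_time_h = h$first_capture_time,
    n_recaptures = h$n_recaptures) |>
    dplyr::arrange(.data$guild_id, .data$site_id, .data$visit_id,
                   .data$first_capture_time_h) |>
    dplyr::group_by(.data$guild_id, .data$site_id, .data$visit_id) |>
    dplyr::mutate(individual_id = dplyr::row_number(), .before = 4) |>
    dplyr::ungroup()
  readr::write_csv(caps, file.path(dir, "captures.csv"))

  if (!is.null(data$a)) {
    ac <- tidyr::expand_grid(guild_id = seq_len(d$n_guilds),
                             event = seq_len(d$n_events))
    ac <- tibble::tibble(
      guild_id = ac$guild_id, site_id = ev$site[ac$event],
      visit_id = ev$visit[ac$event],
      n_listening_periods = d$n_listening,
      n_periods_with_detection = data$a[cbind(ac$guild_id, ac$event)],
      period_length_h = d$period_length) |>
      dplyr::arrange(.data$guild_id, .data$site_id, .data$visit_id)
    readr::write_csv(ac, file.path(dir, "acoustics.csv"))
  }

  cov_cols <- setdiff(names(data$spec$covariates), c("event", "site", "visit"))
  if (length(cov_cols)) {
    cv <- data$spec$covariates |>
      dplyr::select("site", "visit", dplyr::all_of(cov_cols)) |>
      tidyr::pivot_longer(dplyr::all_of(cov_cols),
                          names_to = "covariate_name", values_to = "value") |>
      dplyr::rename(site_id = "site", visit_id = "visit") |>
      dplyr::arrange(.data$covariate_name, .data$site_id, .data$visit_id)
    readr::write_csv(cv, file.path(dir, "covariates.csv"))
  }

  readr::write_csv(
    tibble::tibble(site_id = ev$site, visit_id = ev$visit,
                   capture_duration_h = d$capture_duration),
    file.path(dir, "events.csv"))

  terms_json <- lapply(data$spec$terms, function(tm)
    lapply(seq_len(nrow(tm)), function(k)
      list(covariate = tm$covariate[k],
           sharing = if (tm$guild_specific[k]) "guild" else "shared")))
  jsonlite::write_json(
    list(guilds = d$guilds, n_sites = d$n_sites, n_visits = d$n_visits,
         terms = terms_json),
    file.path(dir, "spec.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

io_abort <- function(file, row, rule) {
  abort(paste0(file, if (!is.na(row)) paste0(", row ", row), ": ", rule))
}

#' Read a dataset from delimited text tables
#'
#' Loads and validates the tables written by [sm_write_dataset()]; every
#' invariant of the model's data types is enforced at load and violations
#' raise errors naming the file, row and rule. A missing `acoustics.csv`
#' loads as a mark-recapture-only dataset (no listening periods) with a
#' warning.
#'
#' @param dir Directory holding the tables.
#' @return An [sm_data] object.
#' @export
sm_read_dataset <- function(dir) {
  pth <- function(f) file.path(dir, f)
  for (f in c("events.csv", "captures.csv"))
    if (!file.exists(pth(f))) abort(paste0("missing required table: ", pth(f)))
  events <- readr::read_csv(pth("events.csv"), show_col_types = FALSE)
  caps <- readr::read_csv(pth("captures.csv"), show_col_types = FALSE)
  covs <- if (file.exists(pth("covariates.csv")))
    readr::read_csv(pth("covariates.csv"), show_col_types = FALSE) else NULL
  has_ac <- file.exists(pth("acoustics.csv"))
  ac <- if (has_ac) readr::read_csv(pth("acoustics.csv"),
                                    show_col_types = FALSE) else NULL
  if (!has_ac)
    warn("acoustics.csv not found; loading as mark-recapture-only data (L = 0)")

  meta <- if (file.exists(pth("spec.json")))
    jsonlite::read_json(pth("spec.json"), simplifyVector = FALSE) else NULL
  n_sites <- max(events$site_id)
  n_visits <- max(events$visit_id)
  guilds <- if (!is.null(meta)) unlist(meta$guilds)
            else LETTERS[seq_len(max(caps$guild_id, ac$guild_id, 1))]
  T_ <- unique(events$capture_duration_h)
  if (length(T_) != 1)
    io_abort("events.csv", NA, "a single capture duration per design is required")
  if (T_ <= 0) io_abort("events.csv", NA, "capture_duration_h must be positive")
  L <- 0L; M <- 0.03
  if (has_ac) {
    L <- unique(ac$n_listening_periods)
    M <- unique(ac$period_length_h)
    if (length(L) != 1 || length(M) != 1)
      io_abort("acoustics.csv", NA,
               "n_listening_periods and period_length_h must be constant")
    bad <- which(ac$n_periods_with_detection > ac$n_listening_periods |
                   ac$n_periods_with_detection < 0)
    if (length(bad))
      io_abort("acoustics.csv", bad[1],
               "0 <= n_periods_with_detection <= n_listening_periods")
  }
  design <- sm_design(n_guilds = length(guilds), n_sites = n_sites,
                      n_visits = n_visits, capture_duration = T_,
                      n_listening = if (has_ac) L else 0,
                      period_length = M, guilds = guilds)

  bad <- which(caps$first_capture_time_h < 0 |
                 caps$first_capture_time_h >= T_)
  if (length(bad))
    io_abort("captures.csv", bad[1],
             "first_capture_time_h must lie in [0, capture_duration_h)")
  bad <- which(!caps$guild_id %in% seq_along(guilds))
  if (length(bad))
    io_abort("captures.csv", bad[1], "unknown guild_id")
  bad <- which(!paste(caps$site_id, caps$visit_id) %in%
                 paste(events$site_id, events$visit_id))
  if (length(bad))
    io_abort("captures.csv", bad[1], "site/visit not present in events.csv")

  cov_tab <- NULL
  terms <- list(abundance = NULL, capture = NULL, vocal = NULL)
  if (!is.null(covs) && nrow(covs)) {
    cov_tab <- covs |>
      tidyr::pivot_wider(names_from = "covariate_name",
                         values_from = "value") |>
      dplyr::rename(site = "site_id", visit = "visit_id")
    if (!is.null(meta)) {
      pick <- function(block) {
        v <- vapply(meta$terms[[block]], function(t) t$sharing, character(1))
        names(v) <- vapply(meta$terms[[block]], function(t) t$covariate,
                           character(1))
        if (length(v)) v else NULL
      }
      terms <- list(abundance = pick("nu"), capture = pick("rho"),
                    vocal = pick("psi"))
    }
  }
  spec <- sm_model_spec(design, cov_tab, abundance = terms$abundance,
                        capture = terms$capture, vocal = terms$vocal)

  captures <- tibble::tibble(
    guild = guilds[caps$guild_id], site = caps$site_id,
    visit = caps$visit_id,
    first_capture_time = caps$first_capture_time_h,
    n_recaptures = caps$n_recaptures)
  acoustics <- if (has_ac)
    tibble::tibble(guild = guilds[ac$guild_id], site = ac$site_id,
                   visit = ac$visit_id,
                   n_detected = ac$n_periods_with_detection) else NULL
  sm_data(spec, captures, acoustics)
}
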