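#' @export
print.sm_fit <- function(x, ...) {
  cat("<sm_fit> ", x$model, " model; ", x$config$chains, " chains x ",
      x$config$iter, " iterations (burn-in ", x$config$burnin, ")\n",
      "  max R-hat = ", format(max(x$rhat), digits = 4),
      if (x$converged) " (converged)" else " (NOT converged)", "\n",
      sep = "")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Tidy a fitted model
#'
#' One row per parameter with the posterior mean, posterior standard
#' deviation, 95% highest-posterior-density bounds and the split-chain
#' R-hat.
#'
#' @param x An [sm_fit()] result.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @export
tidy.sm_fit <- function(x, ...) x$summary

#' One-row summary of a fitted model
#'
#' @param x An [sm_fit()] result.
#' @param ... Unused.
#' @return A tibble with the model label, dimensions, worst R-hat,
#'   convergence flag, mean log posterior and wall time in seconds.
#' @export
glance.sm_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_params = nrow(x$layout),
                 chains = x$config$chains,
                 draws = dim(x$draws)[1] * x$config$chains,
                 max_rhat = max(x$rhat), converged = x$converged,
                 mean_lp = mean(x$lp), elapsed = x$elapsed)
}

#' Posterior interval plot of a fitted model
#'
#' Posterior means with 95% HPD intervals per parameter, optionally with
#' the true values overlaid (triangles) when the fit comes from simulated
#' data.
#'
#' @param object An [sm_fit()] result.
#' @param truth Optional named numeric vector of true parameter values.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sm_fit <- function(object, truth = NULL, ...) {
  df <- tidy(object)
  df$term <- factor(df$term, levels = rev(df$term))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "posterior mean (95% HPD)", y = NULL,
                  title = paste(object$model, "model")) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    td <- tibble::tibble(term = factor(names(truth), levels = levels(df$term)),
                         value = unname(truth))
    td <- td[!is.na(td$term), ]
    p <- p + ggplot2::geom_point(data = td,
                                 ggplot2::aes(x = .data$value, y = .data$term),
                                 shape = 17, colour = "red", size = 2)
  }
  p
}

#' Plot estimated abundance against a covariate
#'
#' Displays the posterior of the latent population sizes (from
#' [posterior_abundance()]) against an event-level covariate, by guild.
#'
#' @param abundance Tibble from [posterior_abundance()].
#' @param covariates Event-level covariate tibble with `site` and `visit`.
#' @param covariate Name of the covariate column to place on the x axis.
#' @return A ggplot object.
#' @export
plot_abundance <- function(abundance, covariates, covariate) {
  df <- dplyr::left_join(abundance, covariates, by = c("site", "visit"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[covariate]], y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             alpha = 0.6) +
    ggplot2::facet_wrap(~guild, scales = "free_y") +
    ggplot2::labs(x = covariate, y = "population size (posterior mean, 95% HPD)") +
    ggplot2::theme_minimal()
}
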