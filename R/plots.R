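#' Forest plot comparing risk-difference estimates
#'
#' Draws the crude, within-population adjusted and transported risk
#' differences side by side as point estimates with confidence intervals
#' — the standard way to display how an effect estimated in the study
#' population compares with the effect in the target population. Accepts
#' any tibble in the shape produced by [crude_rd()],
#' [adjusted_rd_gcomp()] and `tidy(transport_tmle)` rows bound together
#' (columns `method`, `estimate`, `conf.low`, `conf.high`, optionally
#' `population`).
#'
#' @param estimates A tibble of estimates.
#' @param percent Display the x axis in percent.
#' @return A ggplot object.
#' @export
plot_rd_comparison <- function(estimates, percent = TRUE) {
  req <- c("method", "estimate", "conf.low", "conf.high")
  missing_cols <- setdiff(req, names(estimates))
  if (length(missing_cols)) {
    abort(sprintf("estimates lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  est <- as_tibble(estimates)
  if (is.null(est[["population"]])) est$population <- ""
  est$label <- factor(
    trimws(paste(est$method, est$population)),
    levels = rev(unique(trimws(paste(est$method, est$population))))
  )
  k <- if (percent) 100 else 1
  ggplot2::ggplot(est, ggplot2::aes(x = k * .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = k * .data$conf.low,
                                          xmax = k * .data$conf.high)) +
    ggplot2::labs(x = if (percent) "Risk difference (%)" else
      "Risk difference", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_rd_comparison Forest display of a single TMLE fit.
#' @param object A `transport_tmle` object.
#' @param ... Unused.
#' @export
autoplot.transport_tmle <- function(object, ...) {
  plot_rd_comparison(tidy(object), ...)
}

#' Overlap plot of the fitted selection probabilities
#'
#' Plots the distribution of the fitted study-membership probability
#' \eqn{P(S=1 \mid Z)} separately for study and target rows of a
#' [transport_tmle()] fit. Good overlap (both histograms sharing support
#' away from 0 and 1) is the visual counterpart of the positivity of
#' selection assumption.
#'
#' @param fit A `transport_tmle` object.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_selection_overlap <- function(fit, bins = 40) {
  if (!inherits(fit, "transport_tmle")) {
    abort("fit must be a transport_tmle object")
  }
  df <- dplyr::bind_rows(
    tibble(pS = fit$study$pS, population = "study"),
    tibble(pS = fit$target$pS, population = "target")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pS, fill = .data$population)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "Fitted P(S = 1 | Z)", y = "Subjects") +
    ggplot2::theme_minimal()
}
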