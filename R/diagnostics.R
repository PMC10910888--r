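#' Table-1-style covariate balance between study and target
#'
#' Summarises each covariate in both populations — median and quartiles
#' for age, counts and percentages for parity and education — together
#' with standardized differences. For age the standardized difference is
#' \eqn{(\bar{x}_1 - \bar{x}_0)/\sqrt{(s_1^2 + s_0^2)/2}}; for a category
#' with proportions \eqn{p_1, p_0} it is
#' \eqn{(p_1 - p_0)/\sqrt{\{p_1(1-p_1) + p_0(1-p_0)\}/2}}. The sign
#' convention is study minus target, so swapping the populations flips
#' every sign.
#'
#' @param study,target Population tables with covariates.
#' @return A tibble with columns `variable`, `level`, `study`, `target`
#'   (percent for categorical levels, years for age summaries) and
#'   `std_diff`.
#' @export
covariate_balance <- function(study, target) {
  study <- check_covariates(study, "study")
  target <- check_covariates(target, "target")
  age_sd <- (mean(study$age) - mean(target$age)) /
    sqrt((var(study$age) + var(target$age)) / 2)
  age_rows <- tibble(
    variable = "age",
    level = c("median", "q1", "q3", "mean"),
    study = c(quantile(study$age, c(0.5, 0.25, 0.75), names = FALSE),
              mean(study$age)),
    target = c(quantile(target$age, c(0.5, 0.25, 0.75), names = FALSE),
               mean(target$age)),
    std_diff = c(NA_real_, NA_real_, NA_real_, age_sd)
  )
  cat_rows <- function(var, levels) {
    p1 <- prop.table(table(factor(study[[var]], levels = levels)))
    p0 <- prop.table(table(factor(target[[var]], levels = levels)))
    tibble(
      variable = var, level = levels,
      study = 100 * as.numeric(p1), target = 100 * as.numeric(p0),
      std_diff = (as.numeric(p1) - as.numeric(p0)) /
        sqrt((as.numeric(p1) * (1 - as.numeric(p1)) +
                as.numeric(p0) * (1 - as.numeric(p0))) / 2)
    )
  }
  dplyr::bind_rows(age_rows,
                   cat_rows("parity", .parity_levels),
                   cat_rows("education", .education_levels))
}

#' Positivity diagnostics for transport estimation
#'
#' Operationalizes the two verifiable assumptions of the transport
#' analysis. *Positivity of selection* requires every covariate pattern
#' with positive density in the target population to have a positive
#' probability of study membership, checked via the fitted
#' \eqn{P(S=1 \mid Z)} on target rows and via categorical strata present
#' in the target but empty in the study. *Positivity of treatment*
#' requires every study covariate pattern to have both exposure levels
#' possible, checked via the fitted \eqn{P(A=1 \mid S=1, Z)} and via
#' per-stratum exposure variability. The remaining identification
#' assumptions (conditional exchangeability for treatment and for
#' selection, no interference, consistency of treatment versions) are
#' untestable from data and are listed in the report header as a
#' checklist, never as pass/fail.
#'
#' @param study,target Population tables (`study` must contain `a`).
#' @param selection_model,treatment_model Optional fitted binary-response
#'   models; fitted by logistic regression on the default formulas when
#'   `NULL`.
#' @param threshold Flagging threshold for estimated probabilities
#'   (descriptive alarm, distinct from the estimation truncation bounds).
#' @return An object of class `positivity_report`: quantile summaries of
#'   the two fitted probabilities, truncation-style counts, a per-stratum
#'   exposure table, flags, and the untestable-assumption checklist.
#' @export
positivity_report <- function(study, target,
                              selection_model = NULL, treatment_model = NULL,
                              threshold = 0.01) {
  study <- check_estimation_rows(study, need = "a", context = "study")
  target <- check_covariates(target, "target")
  stacked <- dplyr::bind_rows(
    mutate(select(study, all_of(c("age", "parity", "education"))), s = 1L),
    mutate(select(target, all_of(c("age", "parity", "education"))), s = 0L)
  )
  selection_model <- selection_model %||%
    fit_logistic(s ~ age + parity + education, stacked, "selection")
  treatment_model <- treatment_model %||%
    fit_logistic(a ~ age + parity + education, study, "treatment")

  pS_target <- predict(selection_model, newdata = target, type = "response")
  pA_study <- predict(treatment_model, newdata = study, type = "response")
  qs <- c(0, 0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99, 1)
  summarise_p <- function(p, label) {
    tibble(quantity = label,
           quantile = qs,
           value = quantile(p, qs, names = FALSE))
  }
  prob_summary <- dplyr::bind_rows(
    summarise_p(pS_target, "P(S=1|Z) on target rows"),
    summarise_p(pA_study, "P(A=1|S=1,Z) on study rows")
  )

  strata <- dplyr::full_join(
    study |> count(.data$parity, .data$education, name = "n_study") |>
      left_join(
        study |> group_by(.data$parity, .data$education) |>
          summarise(exposed_frac = mean(.data$a), .groups = "drop"),
        by = c("parity", "education")),
    target |> count(.data$parity, .data$education, name = "n_target"),
    by = c("parity", "education")
  ) |>
    mutate(n_study = dplyr::coalesce(.data$n_study, 0L),
           n_target = dplyr::coalesce(.data$n_target, 0L))

  flags <- character()
  structural <- dplyr::filter(strata, .data$n_target > 0, .data$n_study == 0)
  if (nrow(structural)) {
    flags <- c(flags, sprintf(
      "selection_positivity_structural: %d target stratum(a) unrepresented in the study",
      nrow(structural)))
  }
  if (any(pS_target < threshold)) {
    flags <- c(flags, sprintf(
      "selection_positivity: %d target rows with P(S=1|Z) < %g",
      sum(pS_target < threshold), threshold))
  }
  if (any(pA_study < threshold | pA_study > 1 - threshold)) {
    flags <- c(flags, sprintf(
      "treatment_positivity: %d study rows with P(A=1|S=1,Z) outside (%g, %g)",
      sum(pA_study < threshold | pA_study > 1 - threshold),
      threshold, 1 - threshold))
  }
  degenerate <- dplyr::filter(strata, .data$n_study > 0,
                              .data$exposed_frac %in% c(0, 1))
  if (nrow(degenerate)) {
    flags <- c(flags, sprintf(
      "treatment_positivity_empirical: %d study stratum(a) with a single observed exposure level",
      nrow(degenerate)))
  }

  structure(
    list(
      untestable_assumptions = c(
        "conditional treatment exchangeability (no unmeasured confounding in the study)",
        "conditional exchangeability for study selection given Z",
        "no interference between subjects (within or across populations)",
        "treatment definition and version consistency across populations"
      ),
      threshold = threshold,
      prob_summary = prob_summary,
      counts = c(
        n_study = nrow(study), n_target = nrow(target),
        pS_below_threshold = sum(pS_target < threshold),
        pA_outside_threshold = sum(pA_study < threshold |
                                     pA_study > 1 - threshold)
      ),
      strata = strata,
      flags = flags
    ),
    class = "positivity_report"
  )
}

#' @export
print.positivity_report <- function(x, ...) {
  cat("Positivity diagnostics\n")
  cat("  untestable assumptions (review, not pass/fail):\n")
  for (a in x$untestable_assumptions) cat("    -", a, "\n")
  cat(sprintf("  n: %d study, %d target; flag threshold %g\n",
              x$counts[["n_study"]], x$counts[["n_target"]], x$threshold))
  wide <- tidyr::pivot_wider(x$prob_summary, names_from = "quantile",
                             values_from = "value")
  print(as.data.frame(wide), digits = 3, row.names = FALSE)
  if (length(x$flags)) {
    cat("  FLAGS:\n")
    for (f in x$flags) cat("    !", f, "\n")
  } else {
    cat("  no positivity flags\n")
  }
  invisible(x)
}
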