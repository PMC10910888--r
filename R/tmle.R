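#' Fit the nuisance models for the transport TMLE
#'
#' Three logistic regressions supply the initial ingredients of the
#' targeted estimator: the outcome regression
#' \eqn{E^0(Y \mid S=1, Z, A)} and the treatment mechanism
#' \eqn{P(A=1 \mid S=1, Z)}, both fitted on study rows, and the selection
#' mechanism \eqn{P(S=1 \mid Z)} fitted on the stacked study + target
#' sample. The study/target size ratio is absorbed by the empirical
#' selection fit and cancels in the final standardization.
#'
#' @param study Study-population table (covariates, `a`, `y`).
#' @param stacked Stacked table with `s` (1 = study, 0 = target) and
#'   covariates for both populations.
#' @param outcome_formula,treatment_formula,selection_formula Model
#'   formulas for the three regressions.
#' @return A list with components `outcome`, `treatment`, `selection`
#'   (fitted `glm` objects).
#' @export
fit_nuisance_models <- function(study, stacked,
                                outcome_formula = y ~ a + age + parity +
                                  education + a:education,
                                treatment_formula = a ~ age + parity + education,
                                selection_formula = s ~ age + parity + education) {
  fits <- list(
    outcome = fit_logistic(outcome_formula, study, "outcome"),
    treatment = fit_logistic(treatment_formula, study, "treatment"),
    selection = fit_logistic(selection_formula, stacked, "selection")
  )
  fits
}

fit_logistic <- function(formula, data, label) {
  fit <- tryCatch(
    glm(formula, family = binomial(), data = data),
    error = function(e) abort(sprintf("%s model failed to fit: %s",
                                      label, conditionMessage(e)))
  )
  if (!isTRUE(fit$converged)) {
    abort(sprintf("%s model did not converge", label))
  }
  fit
}

#' Clever covariates of the transport TMLE
#'
#' The targeting step regresses the study outcomes on two covariates
#' constructed from the nuisance probabilities,
#' \deqn{H_0 = \frac{(1-A)\,[1-P(S=1\mid Z)]}{P(S=1\mid Z)\,[1-P(A=1\mid S=1,Z)]},
#'   \qquad
#'   H_1 = \frac{A\,[1-P(S=1\mid Z)]}{P(S=1\mid Z)\,P(A=1\mid S=1,Z)}.}
#' Each study row contributes to exactly one of the two (its observed
#' arm); rows resembling the target population (small \eqn{P(S=1|Z)})
#' receive large weight. Probabilities are truncated to `bounds` before
#' use to keep the ratios finite.
#'
#' @param a Binary exposure vector.
#' @param pS Estimated selection probabilities \eqn{P(S=1\mid Z)}.
#' @param pA Estimated treatment probabilities \eqn{P(A=1\mid S=1,Z)}.
#' @param bounds Truncation interval for `pS` and `pA`; set `NULL` to
#'   forbid truncation (probabilities at 0/1 then raise an error).
#' @return A tibble with columns `H0` and `H1` (non-negative; exactly one
#'   nonzero per row).
#' @export
clever_covariates <- function(a, pS, pA, bounds = c(0.001, 0.999)) {
  if (!all(a %in% c(0, 1))) abort("exposure values must be 0/1")
  if (is.null(bounds)) {
    if (any(pS <= 0 | pS >= 1) || any(pA <= 0 | pA >= 1)) {
      abort("nuisance probabilities at 0/1; set `bounds` to truncate them")
    }
  } else {
    pS <- bound_probs(pS, bounds)
    pA <- bound_probs(pA, bounds)
  }
  w <- (1 - pS) / pS
  tibble(H0 = (1 - a) * w / (1 - pA),
         H1 = a * w / pA)
}

bound_probs <- function(p, bounds) pmin(pmax(p, bounds[1]), bounds[2])

#' Fluctuate the initial outcome regression
#'
#' The targeting update fits the fluctuation parameters
#' \eqn{\varepsilon = (\varepsilon_0, \varepsilon_1)} of the clever
#' covariates and returns the updated outcome predictions. On the default
#' `"logit"` scale the update is a no-intercept logistic regression of the
#' study outcomes on \eqn{(H_0, H_1)} with offset
#' \eqn{\mathrm{logit}\,E^0}, giving
#' \eqn{E^* = \mathrm{plogis}(\mathrm{logit}\,E^0 + \varepsilon_0 H_0 +
#' \varepsilon_1 H_1)}, which respects the \[0, 1\] outcome scale. The
#' `"linear"` scale performs the additive update
#' \eqn{E^* = E^0 + \varepsilon_0 H_0 + \varepsilon_1 H_1} (no-intercept
#' least squares on the residual), with predictions truncated to \[0, 1\].
#' Either way \eqn{\varepsilon} solves the score equations
#' \eqn{\sum_i H_{a,i}(Y_i - E^*_i) = 0}; when the initial outcome model
#' is correctly specified and fitted by maximum likelihood the residual
#' variation is already exhausted and \eqn{\varepsilon \approx 0}.
#'
#' @param y Binary study outcomes.
#' @param e0_pred Initial outcome predictions \eqn{E^0} on study rows.
#' @param H0,H1 Clever covariates on study rows.
#' @param scale `"logit"` (default) or `"linear"`.
#' @return A list with `epsilon` (named length-2 vector), `scale`, and
#'   `update(e0, H0, H1)`, a function applying the fitted fluctuation to
#'   new (possibly counterfactual) predictions.
#' @export
fluctuate <- function(y, e0_pred, H0, H1, scale = c("logit", "linear")) {
  scale <- match.arg(scale)
  if (any(e0_pred < 0 | e0_pred > 1)) abort("e0_pred must lie in [0, 1]")
  e0 <- bound_probs(e0_pred, c(1e-8, 1 - 1e-8))
  if (scale == "logit") {
    dat <- data.frame(y = y, H0 = H0, H1 = H1, off = qlogis(e0))
    fit <- tryCatch(
      glm(y ~ 0 + H0 + H1 + offset(off), family = binomial(), data = dat),
      error = function(e) abort(sprintf("fluctuation fit failed: %s",
                                        conditionMessage(e)))
    )
    eps <- coef(fit)
    eps[is.na(eps)] <- 0
    update <- function(e0, H0, H1) {
      e0 <- bound_probs(e0, c(1e-8, 1 - 1e-8))
      plogis(qlogis(e0) + eps[["H0"]] * H0 + eps[["H1"]] * H1)
    }
  } else {
    dat <- data.frame(r = y - e0, H0 = H0, H1 = H1)
    fit <- lm(r ~ 0 + H0 + H1, data = dat)
    eps <- coef(fit)
    eps[is.na(eps)] <- 0
    update <- function(e0, H0, H1) {
      bound_probs(e0 + eps[["H0"]] * H0 + eps[["H1"]] * H1, c(0, 1))
    }
  }
  list(epsilon = c(epsilon0 = unname(eps[["H0"]]),
                   epsilon1 = unname(eps[["H1"]])),
       scale = scale, update = update)
}

#' Standardize updated counterfactual predictions over the target rows
#'
#' The transported average treatment effect is
#' \eqn{\psi = \frac{1}{n_0}\sum_{i: S_i=0} \{E^*(Y\mid S=1,A=1,Z_i) -
#' E^*(Y\mid S=1,A=0,Z_i)\}}: the empirical target covariate distribution
#' realizes \eqn{P(Z = z \mid S = 0)} in the transport formula.
#'
#' @param pred1,pred0 Updated predictions on target rows with exposure
#'   forced to 1 resp. 0.
#' @return The transported risk difference.
#' @export
transported_ate <- function(pred1, pred0) {
  if (!length(pred1) || length(pred1) != length(pred0)) {
    abort("pred1 and pred0 must be non-empty vectors of equal length")
  }
  mean(pred1 - pred0)
}

#' Transport TMLE of the target-population risk difference
#'
#' Estimates the average treatment effect in the target population,
#' \eqn{E(Y^1 - Y^0 \mid S = 0)} on the risk-difference scale, using
#' individual-level exposure, outcome and covariates from the study
#' population but only covariates from the target population. The
#' procedure is the targeted maximum likelihood estimator for this
#' transport parameter:
#' \enumerate{
#'   \item fit the outcome, treatment and selection nuisance models
#'     ([fit_nuisance_models()]);
#'   \item form the clever covariates on the study rows
#'     ([clever_covariates()]);
#'   \item fluctuate the initial outcome predictions ([fluctuate()]) —
#'     a single update suffices for this parameter;
#'   \item standardize the updated counterfactual predictions over the
#'     target rows ([transported_ate()]);
#'   \item estimate the standard error from the sample variance of the
#'     efficient influence curve.
#' }
#' The estimator is doubly robust: it is consistent when either the
#' outcome model, or both the treatment and selection models, are
#' correctly specified. Rows with missing required fields are dropped
#' (complete-case analysis) and counted in the result.
#'
#' The per-unit efficient influence curve is
#' \deqn{D_i = \frac{S_i}{P(S=0)} (H_{1,i} - H_{0,i}) (Y_i - E^*_i)
#'   + \frac{1 - S_i}{P(S=0)} \{E^*(1, Z_i) - E^*(0, Z_i) - \psi\},}
#' with \eqn{P(S=0)} the empirical target fraction; its sample mean is
#' (numerically) zero at the TMLE solution and its sample variance over
#' all \eqn{N} units gives \eqn{se = \sqrt{\widehat{var}(D)/N}}.
#'
#' @param study Study-population table (covariates, `a`, `y`).
#' @param target Target-population table (covariates; any `a`/`y`
#'   columns are ignored).
#' @inheritParams fit_nuisance_models
#' @param fluctuation Fluctuation scale, `"logit"` (default) or
#'   `"linear"`; see [fluctuate()].
#' @param bounds Truncation interval for the selection and treatment
#'   probabilities.
#' @param conf_level Confidence level for the Wald interval
#'   \eqn{\psi \pm z \cdot se}.
#' @return An object of class `transport_tmle`; see [tidy.transport_tmle()].
#' @export
#' @examples
#' study <- simulate_population(margins_ninfea(), 1500, seed = 1, s = 1)
#' target <- simulate_population(margins_pbr(), 4000, seed = 2, s = 0)
#' fit <- transport_tmle(study, target)
#' tidy(fit)
transport_tmle <- function(study, target,
                           outcome_formula = y ~ a + age + parity +
                             education + a:education,
                           treatment_formula = a ~ age + parity + education,
                           selection_formula = s ~ age + parity + education,
                           fluctuation = c("logit", "linear"),
                           bounds = c(0.001, 0.999),
                           conf_level = 0.95) {
  fluctuation <- match.arg(fluctuation)
  study <- check_estimation_rows(study, need = c("a", "y"), context = "study")
  n_dropped_study <- attr(study, "n_dropped")
  target <- check_covariates(target, "target")
  keep <- complete.cases(target[, c("age", "parity", "education")])
  n_dropped_target <- sum(!keep)
  target <- target[keep, c("age", "parity", "education"), drop = FALSE]
  if (nrow(target) == 0L) abort("target has no complete rows")

  study$s <- 1L
  stacked <- dplyr::bind_rows(
    select(study, all_of(c("s", "age", "parity", "education"))),
    mutate(target, s = 0L)
  )
  models <- fit_nuisance_models(study, stacked,
                                outcome_formula = outcome_formula,
                                treatment_formula = treatment_formula,
                                selection_formula = selection_formula)

  pS_s <- predict(models$selection, newdata = study, type = "response")
  pA_s <- predict(models$treatment, newdata = study, type = "response")
  truncation_counts <- c(
    selection = sum(pS_s < bounds[1] | pS_s > bounds[2]),
    treatment = sum(pA_s < bounds[1] | pA_s > bounds[2])
  )
  H_s <- clever_covariates(study$a, pS_s, pA_s, bounds)
  e0_s <- predict(models$outcome, newdata = study, type = "response")

  fl <- fluctuate(study$y, e0_s, H_s$H0, H_s$H1, scale = fluctuation)
  estar_s <- fl$update(e0_s, H_s$H0, H_s$H1)

  # counterfactual clever covariates and predictions on the target rows
  pS_t <- bound_probs(predict(models$selection, newdata = target,
                              type = "response"), bounds)
  pA_t <- bound_probs(predict(models$treatment, newdata = target,
                              type = "response"), bounds)
  w_t <- (1 - pS_t) / pS_t
  H1_t <- w_t / pA_t
  H0_t <- w_t / (1 - pA_t)
  e0_t1 <- predict(models$outcome, newdata = mutate(target, a = 1),
                   type = "response")
  e0_t0 <- predict(models$outcome, newdata = mutate(target, a = 0),
                   type = "response")
  estar_t1 <- fl$update(e0_t1, 0, H1_t)
  estar_t0 <- fl$update(e0_t0, H0_t, 0)

  psi <- transported_ate(estar_t1, estar_t0)

  n1 <- nrow(study); n0 <- nrow(target); n <- n1 + n0
  p_s0 <- n0 / n
  eic_study <- (H_s$H1 - H_s$H0) * (study$y - estar_s) / p_s0
  eic_target <- (estar_t1 - estar_t0 - psi) / p_s0
  eic <- c(eic_study, eic_target)
  inf <- eic_inference(psi, eic, conf_level)
  se <- inf$se
  ci <- inf$ci95

  structure(
    list(
      psi = psi, se = se, ci95 = ci, conf_level = conf_level,
      epsilon = fl$epsilon, fluctuation = fluctuation, bounds = bounds,
      n_study = n1, n_target = n0,
      n_dropped = c(study = n_dropped_study, target = n_dropped_target),
      truncation_counts = truncation_counts,
      epsilon_scale = fluctuation,
      study = mutate(study,
                     pS = pS_s, pA = pA_s,
                     H0 = H_s$H0, H1 = H_s$H1,
                     e0 = e0_s, e_star = estar_s, eic = eic_study),
      target = mutate(target,
                      pS = pS_t, pA = pA_t,
                      e_star1 = estar_t1, e_star0 = estar_t0,
                      eic = eic_target),
      eic = eic, models = models,
      formulas = list(outcome = outcome_formula,
                      treatment = treatment_formula,
                      selection = selection_formula),
      call = match.call()
    ),
    class = "transport_tmle"
  )
}

#' Wald inference from the efficient influence curve
#'
#' Computes the TMLE standard error as the square root of the sample
#' variance of the per-unit efficient influence values divided by the
#' total sample size, and the corresponding normal-approximation
#' confidence interval \eqn{\psi \pm z \cdot se}.
#'
#' @param psi Point estimate (transported risk difference).
#' @param eic Per-unit efficient influence values over all study and
#'   target units.
#' @param conf_level Confidence level.
#' @return A list with `se` and `ci95` (length-2 vector).
#' @export
eic_inference <- function(psi, eic, conf_level = 0.95) {
  n <- length(eic)
  if (n < 2L) abort("eic must contain at least two units")
  v <- var(eic)
  if (v == 0 && n > 1L) {
    warn("efficient influence curve has zero variance; the interval is degenerate")
  }
  se <- sqrt(v / n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(se = se, ci95 = c(psi - z * se, psi + z * se))
}

#' Tidiers and printers for transport TMLE fits
#'
#' `tidy()` returns the one-row estimate table (risk difference, standard
#' error, Wald interval); `glance()` returns a one-row model summary with
#' the fluctuation parameters, efficient-influence-curve mean (a
#' numerical-zero check), sample sizes, complete-case exclusions and
#' truncation counts.
#'
#' @param x A `transport_tmle` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.transport_tmle <- function(x, ...) {
  tibble(method = "tmle_transport",
         estimate = x$psi, std.error = x$se,
         conf.low = x$ci95[1], conf.high = x$ci95[2],
         n = x$n_study + x$n_target, n_boot = NA_integer_)
}

#' @rdname tidy.transport_tmle
#' @export
glance.transport_tmle <- function(x, ...) {
  tibble(estimate = x$psi, std.error = x$se,
         epsilon0 = x$epsilon[["epsilon0"]],
         epsilon1 = x$epsilon[["epsilon1"]],
         fluctuation = x$fluctuation,
         mean_eic = mean(x$eic),
         n_study = x$n_study, n_target = x$n_target,
         n_dropped_study = x$n_dropped[["study"]],
         n_dropped_target = x$n_dropped[["target"]],
         truncated_selection = x$truncation_counts[["selection"]],
         truncated_treatment = x$truncation_counts[["treatment"]])
}

#' @export
print.transport_tmle <- function(x, ...) {
  cat("Transported risk difference (TMLE)\n")
  cat(sprintf("  psi = %.4f  (se %.4f, %g%% CI %.4f to %.4f)\n",
              x$psi, x$se, 100 * x$conf_level, x$ci95[1], x$ci95[2]))
  cat(sprintf("  fluctuation (%s scale): epsilon0 = %.4g, epsilon1 = %.4g\n",
              x$fluctuation, x$epsilon[["epsilon0"]], x$epsilon[["epsilon1"]]))
  cat(sprintf("  n: %d study, %d target (dropped %d / %d incomplete rows)\n",
              x$n_study, x$n_target,
              x$n_dropped[["study"]], x$n_dropped[["target"]]))
  if (any(x$truncation_counts > 0)) {
    cat(sprintf("  truncated probabilities: %d selection, %d treatment\n",
                x$truncation_counts[["selection"]],
                x$truncation_counts[["treatment"]]))
  }
  invisible(x)
}
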