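#' Coefficients of the exposure and outcome generating models
#'
#' The synthetic cohorts receive a binary exposure \eqn{A} and binary
#' outcome \eqn{Y} from two logistic models. The exposure probability is
#' \deqn{\pi_i = \mathrm{plogis}\{b_{age}(age_i - \overline{age})
#'   - 0.3\,I(parity_i = 1) - 0.5\,I(parity_i = 2+)\}}
#' and the outcome probability is the logistic transform of
#' \deqn{g_a A_i + g_{age}(age_i - \overline{age}) + g_{par1} I(parity_i=1)
#'   + g_{par2} I(parity_i=2+) + g_{eduM} I(edu_i=med) + g_{eduL} I(edu_i=low)
#'   + g_{a:eduM} A_i I(edu_i=med) + g_{a:eduL} A_i I(edu_i=low).}
#' Maternal age and parity therefore act as confounders (they affect both
#' exposure and outcome) and maternal education as an effect modifier
#' (exposure-by-education interactions). The defaults are the coefficients
#' of the motivating simulation.
#'
#' Age is centered before entering either linear predictor. With
#' `age_centering = "per_population_mean"` (default) each population is
#' centered at its own realized mean age, so each simulated table is
#' self-contained; `"fixed_value"` centers at `age_center_value`, which is
#' useful for sensitivity checks where study and target must share one
#' centering constant.
#'
#' @param b_age,b_par1,b_par2 Exposure-model coefficients (per year of
#'   centered age; parity 1 and 2+ indicators).
#' @param g_a,g_age,g_par1,g_par2,g_eduM,g_eduL,g_a_eduM,g_a_eduL
#'   Outcome-model coefficients: exposure main effect, centered age,
#'   parity indicators, education indicators, exposure-by-education
#'   interactions.
#' @param age_centering How to center age, see Details.
#' @param age_center_value Centering constant when
#'   `age_centering = "fixed_value"` (years).
#'
#' @return An object of class `dgm_params`.
#' @seealso [assign_exposure()], [assign_outcome()], [true_target_ate()]
#' @export
dgm_params <- function(b_age = 0.1, b_par1 = -0.3, b_par2 = -0.5,
                       g_a = 0.6, g_age = 0.2, g_par1 = -0.1, g_par2 = -0.3,
                       g_eduM = 0.4, g_eduL = 0.6,
                       g_a_eduM = 0.3, g_a_eduL = 0.5,
                       age_centering = c("per_population_mean", "fixed_value"),
                       age_center_value = NULL) {
  age_centering <- match.arg(age_centering)
  co <- c(b_age = b_age, b_par1 = b_par1, b_par2 = b_par2,
          g_a = g_a, g_age = g_age, g_par1 = g_par1, g_par2 = g_par2,
          g_eduM = g_eduM, g_eduL = g_eduL,
          g_a_eduM = g_a_eduM, g_a_eduL = g_a_eduL)
  if (any(!is.finite(co))) abort("all dgm_params coefficients must be finite")
  if (age_centering == "fixed_value" &&
      (is.null(age_center_value) || !is.finite(age_center_value))) {
    abort("age_center_value must be a finite number when age_centering = 'fixed_value'")
  }
  structure(c(as.list(co),
              list(age_centering = age_centering,
                   age_center_value = age_center_value)),
            class = "dgm_params")
}

#' @export
print.dgm_params <- function(x, ...) {
  cat("<dgm_params>\n")
  cat(sprintf("  exposure: %.3g*age_c %+.3g*I(par=1) %+.3g*I(par=2+)\n",
              x$b_age, x$b_par1, x$b_par2))
  cat(sprintf(
    "  outcome:  %.3g*A %+.3g*age_c %+.3g*I(par=1) %+.3g*I(par=2+) %+.3g*I(eduM) %+.3g*I(eduL) %+.3g*A:eduM %+.3g*A:eduL\n",
    x$g_a, x$g_age, x$g_par1, x$g_par2, x$g_eduM, x$g_eduL,
    x$g_a_eduM, x$g_a_eduL))
  cat("  age centering:", x$age_centering,
      if (x$age_centering == "fixed_value") sprintf("(%g years)", x$age_center_value),
      "\n")
  invisible(x)
}

# centering constant used by the generating models for one population table
resolve_age_center <- function(pop, params) {
  if (params$age_centering == "fixed_value") params$age_center_value
  else mean(pop$age)
}

#' Model-implied exposure and outcome probabilities
#'
#' Evaluate the generating models of [dgm_params()] on a covariate table,
#' returning the per-subject Bernoulli probabilities \eqn{\pi_i} (exposure)
#' and \eqn{\rho_i} (outcome). These closed-form probabilities are what the
#' oracle [true_target_ate()] averages; the `assign_*` functions draw from
#' them.
#'
#' @param pop A population table with `age`, `parity`, `education` (and
#'   `a` for `outcome_probability()` unless `a` is forced).
#' @param params A [dgm_params()] object.
#' @param a Optional forced exposure level (0 or 1, recycled) realizing
#'   the counterfactual \eqn{Y^a}; when `NULL` the observed `a` column is
#'   used.
#' @param age_center Optional centering constant override (years).
#' @return A numeric vector of probabilities in (0, 1).
#' @export
exposure_probability <- function(pop, params = dgm_params(), age_center = NULL) {
  pop <- check_covariates(pop)
  ac <- age_center %||% resolve_age_center(pop, params)
  lp <- params$b_age * (pop$age - ac) +
    params$b_par1 * (pop$parity == "1") +
    params$b_par2 * (pop$parity == "2+")
  plogis(lp)
}

#' @rdname exposure_probability
#' @export
outcome_probability <- function(pop, params = dgm_params(), a = NULL,
                                age_center = NULL) {
  pop <- check_covariates(pop)
  if (is.null(a)) {
    if (is.null(pop[["a"]]) || anyNA(pop$a)) {
      abort("outcome_probability() needs an `a` column (or a forced `a`)")
    }
    a <- pop$a
  }
  if (!all(a %in% c(0, 1))) abort("exposure values must be 0/1")
  ac <- age_center %||% resolve_age_center(pop, params)
  edu_m <- pop$education == "medium"
  edu_l <- pop$education == "low"
  lp <- params$g_a * a +
    params$g_age * (pop$age - ac) +
    params$g_par1 * (pop$parity == "1") +
    params$g_par2 * (pop$parity == "2+") +
    params$g_eduM * edu_m + params$g_eduL * edu_l +
    params$g_a_eduM * a * edu_m + params$g_a_eduL * a * edu_l
  plogis(lp)
}
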