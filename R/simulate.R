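#' Draw a synthetic covariate table from marginal summaries
#'
#' Samples `n` subjects whose maternal age, parity and education follow
#' the marginal distributions of a [population_margins()] object. Age is
#' drawn from a truncated normal (or two-piece normal) whose location is
#' the printed median and whose scale reproduces the printed IQR; parity
#' and education are drawn independently from their probability vectors.
#' Only margins are emulated: the joint covariate dependence of any real
#' population is not reproduced.
#'
#' @param margins A [population_margins()] object.
#' @param n Number of subjects (>= 0).
#' @param seed Integer seed; the draw is deterministic given `seed` and
#'   does not disturb the caller's random-number state.
#' @return A tibble with columns `age` (numeric years), `parity` (factor
#'   `0`/`1`/`2+`) and `education` (factor `high`/`medium`/`low`).
#' @export
#' @examples
#' sample_covariates(margins_ninfea(), n = 5, seed = 1)
sample_covariates <- function(margins, n, seed = 1L) {
  if (!inherits(margins, "population_margins")) {
    abort("margins must be a population_margins object")
  }
  if (length(n) != 1L || is.na(n) || n < 0) abort("n must be a single count >= 0")
  n <- as.integer(n)
  if (n == 0L) {
    return(tibble(age = numeric(),
                  parity = factor(character(), levels = .parity_levels),
                  education = factor(character(), levels = .education_levels)))
  }
  withr::with_seed(as.integer(seed), {
    age <- sample_age(margins, n)
    parity <- sample(.parity_levels, n, replace = TRUE,
                     prob = margins$parity_probs)
    education <- sample(.education_levels, n, replace = TRUE,
                        prob = margins$education_probs)
    tibble(age = age,
           parity = factor(parity, levels = .parity_levels),
           education = factor(education, levels = .education_levels))
  })
}

# Truncated (split) normal draw by CDF inversion. The two-piece form puts
# mass 1/2 on each side of the median with side-specific scales
# (median - q1)/z75 and (q3 - median)/z75, so median and IQR are matched
# exactly; the symmetric form uses the single scale IQR/(2 * z75) = IQR/1.349.
sample_age <- function(margins, n) {
  z75 <- qnorm(0.75)
  m <- margins$age_median
  lo <- margins$age_bounds[1]; hi <- margins$age_bounds[2]
  if (margins$age_shape == "normal") {
    s <- (margins$age_q3 - margins$age_q1) / (2 * z75)
    u <- runif(n, pnorm(lo, m, s), pnorm(hi, m, s))
    qnorm(u, m, s)
  } else {
    s_lo <- (m - margins$age_q1) / z75
    s_hi <- (margins$age_q3 - m) / z75
    side <- runif(n) < 0.5
    u <- runif(n)
    # half-normal inversion, truncated at the support bound on each side
    t_lo <- s_lo * qnorm((1 + u * (2 * pnorm((m - lo) / s_lo) - 1)) / 2)
    t_hi <- s_hi * qnorm((1 + u * (2 * pnorm((hi - m) / s_hi) - 1)) / 2)
    ifelse(side, m - t_lo, m + t_hi)
  }
}

check_covariates <- function(pop, context = "population table") {
  if (!is.data.frame(pop)) abort(sprintf("%s must be a data frame", context))
  missing_cols <- setdiff(c("age", "parity", "education"), names(pop))
  if (length(missing_cols)) {
    abort(sprintf("%s lacks column(s): %s", context,
                  paste(missing_cols, collapse = ", ")))
  }
  pop <- as_tibble(pop)
  pop$parity <- as_category(pop$parity, .parity_levels, "parity")
  pop$education <- as_category(pop$education, .education_levels, "education")
  if (any(!is.na(pop$age) & !is.finite(pop$age))) abort("age must be finite")
  pop
}

as_category <- function(x, levels, name) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x) && name == "parity") {
    x <- as.character(x)
    x[x == "2"] <- "2+"
  }
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    abort(sprintf("invalid %s value(s): %s", name,
                  paste(unique(x[bad]), collapse = ", ")))
  }
  factor(x, levels = levels)
}

#' Assign exposure and outcome from the generating models
#'
#' `assign_exposure()` fills the binary exposure column `a` with Bernoulli
#' draws from the per-subject probability \eqn{\pi_i} of
#' [exposure_probability()]; `assign_outcome()` fills the outcome `y` from
#' \eqn{\rho_i} of [outcome_probability()]. Supplying `force_a` to
#' `assign_outcome()` evaluates the outcome model with exposure set to a
#' fixed level for every subject, i.e. it realizes the potential outcome
#' \eqn{Y^a}; the observed `a` column is left untouched.
#'
#' @inheritParams exposure_probability
#' @param seed Integer seed; deterministic draws that do not disturb the
#'   caller's random-number state.
#' @param force_a Optional counterfactual exposure level (0 or 1).
#' @return The input tibble with column `a` (resp. `y`) filled.
#' @export
assign_exposure <- function(pop, params = dgm_params(), seed = 1L,
                            age_center = NULL) {
  pop <- check_covariates(pop)
  p <- exposure_probability(pop, params, age_center = age_center)
  pop$a <- withr::with_seed(as.integer(seed), rbinom(nrow(pop), 1L, p))
  pop
}

#' @rdname assign_exposure
#' @export
assign_outcome <- function(pop, params = dgm_params(), seed = 1L,
                           force_a = NULL, age_center = NULL) {
  pop <- check_covariates(pop)
  p <- outcome_probability(pop, params, a = force_a, age_center = age_center)
  pop$y <- withr::with_seed(as.integer(seed), rbinom(nrow(pop), 1L, p))
  pop
}

#' Simulate a complete study or target population
#'
#' One-call wrapper: draws covariates from `margins`, then exposure, then
#' outcome, and stamps the population indicator `s` (1 = study,
#' 0 = target). Covariates, exposure and outcome use independent seed
#' substreams (`seed`, `seed + 1`, `seed + 2`) so that e.g. regenerating
#' outcomes does not reshuffle covariates.
#'
#' @inheritParams sample_covariates
#' @param params A [dgm_params()] object.
#' @param s Population indicator stamped on every row.
#' @return A tibble with columns `s`, `age`, `parity`, `education`, `a`, `y`.
#' @export
#' @examples
#' simulate_population(margins_ninfea(), n = 10, seed = 7, s = 1)
simulate_population <- function(margins, n, seed = 1L, params = dgm_params(),
                                s = 1L) {
  seed <- as.integer(seed)
  pop <- sample_covariates(margins, n, seed = seed)
  pop <- assign_exposure(pop, params, seed = seed + 1L)
  pop <- assign_outcome(pop, params, seed = seed + 2L)
  dplyr::bind_cols(tibble(s = rep(as.integer(s), nrow(pop))), pop)
}

#' Closed-form oracle for the target-population average treatment effect
#'
#' The estimand of the transport analysis is the average treatment effect
#' in the target population, \eqn{ATE = E(Y^1 - Y^0 \mid S = 0)}, on the
#' risk-difference scale. Because the generating outcome model is known in
#' a simulation, the ATE conditional on the realized target covariates has
#' the closed form
#' \deqn{\frac{1}{n}\sum_i \{\rho_i(a{=}1) - \rho_i(a{=}0)\},}
#' the average over target rows of the difference in model-implied outcome
#' probabilities under forced exposure. No Monte-Carlo draw is involved,
#' so the value is exact given the covariate table and independent of any
#' seed; it is the reference against which the transport estimators are
#' validated.
#'
#' @param params A [dgm_params()] object.
#' @param target Target-population covariate table.
#' @param age_center Optional centering constant override (years).
#' @return The true risk difference (a single number).
#' @export
true_target_ate <- function(params = dgm_params(), target, age_center = NULL) {
  target <- check_covariates(target, "target")
  if (nrow(target) == 0L) abort("target table is empty")
  ac <- age_center %||% resolve_age_center(target, params)
  p1 <- outcome_probability(target, params, a = 1, age_center = ac)
  p0 <- outcome_probability(target, params, a = 0, age_center = ac)
  mean(p1 - p0)
}
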