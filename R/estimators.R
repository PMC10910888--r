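#' Crude risk difference
#'
#' The unadjusted contrast `mean(y | a = 1) - mean(y | a = 0)` in one
#' population, with a percentile bootstrap confidence interval obtained by
#' resampling subjects. In the presence of confounding this estimate is
#' biased for the causal risk difference; it is reported as the naive
#' benchmark.
#'
#' @param pop Population table with binary columns `a` and `y`.
#' @param n_boot Number of bootstrap resamples (0 skips the interval).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return A one-row tibble with columns `method`, `estimate`,
#'   `conf.low`, `conf.high`, `n`, `n_boot`.
#' @export
crude_rd <- function(pop, n_boot = 1000, seed = 1L, conf_level = 0.95) {
  pop <- check_estimation_rows(pop, need = c("a", "y"))
  if (!any(pop$a == 1) || !any(pop$a == 0)) {
    abort("both exposure arms must be non-empty")
  }
  est <- rd_from_arms(pop$a, pop$y)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot <- withr::with_seed(as.integer(seed), {
      replicate(n_boot, {
        idx <- sample.int(nrow(pop), replace = TRUE)
        rd_from_arms(pop$a[idx], pop$y[idx])
      })
    })
    ci <- quantile(boot, probs = c((1 - conf_level) / 2,
                                   1 - (1 - conf_level) / 2),
                   na.rm = TRUE, names = FALSE)
  }
  tibble(method = "crude", estimate = est,
         conf.low = ci[1], conf.high = ci[2],
         n = nrow(pop), n_boot = as.integer(n_boot))
}

rd_from_arms <- function(a, y) {
  if (!any(a == 1) || !any(a == 0)) return(NA_real_)
  mean(y[a == 1]) - mean(y[a == 0])
}

#' Covariate-adjusted marginal risk difference by g-computation
#'
#' Fits a logistic outcome model on `pop` and standardizes: the returned
#' estimate is the mean, over `standardization_pop`, of the difference in
#' predicted outcome risk with exposure forced to 1 versus 0. With the
#' default formula the model includes exposure, maternal age, parity,
#' education and exposure-by-education interactions, so education is
#' allowed to modify the effect. The confidence interval is a percentile
#' bootstrap resampling `pop` (and `standardization_pop` jointly when it
#' is a distinct table).
#'
#' @param pop Population table used to fit the outcome model (`a`, `y`
#'   and covariates present).
#' @param formula Outcome model formula.
#' @param standardization_pop Covariate table over which predictions are
#'   averaged; defaults to `pop` itself (within-population adjusted
#'   estimate).
#' @inheritParams crude_rd
#' @return A one-row tibble with columns `method`, `estimate`,
#'   `conf.low`, `conf.high`, `n`, `n_boot`.
#' @export
adjusted_rd_gcomp <- function(pop,
                              formula = y ~ a + age + parity + education +
                                a:education,
                              standardization_pop = NULL,
                              n_boot = 1000, seed = 1L, conf_level = 0.95) {
  pop <- check_estimation_rows(pop, need = c("a", "y"))
  self_standardized <- is.null(standardization_pop)
  std <- if (self_standardized) pop else
    check_covariates(standardization_pop, "standardization_pop")
  warn_if_disjoint_support(pop, std)
  est <- gcomp_once(pop, std, formula)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot <- withr::with_seed(as.integer(seed), {
      replicate(n_boot, {
        fit_idx <- sample.int(nrow(pop), replace = TRUE)
        std_b <- if (self_standardized) pop[fit_idx, ] else
          std[sample.int(nrow(std), replace = TRUE), ]
        tryCatch(gcomp_once(pop[fit_idx, ], std_b, formula),
                 error = function(e) NA_real_)
      })
    })
    ci <- quantile(boot, probs = c((1 - conf_level) / 2,
                                   1 - (1 - conf_level) / 2),
                   na.rm = TRUE, names = FALSE)
  }
  tibble(method = "gcomp", estimate = est,
         conf.low = ci[1], conf.high = ci[2],
         n = nrow(pop), n_boot = as.integer(n_boot))
}

gcomp_once <- function(pop, std, formula) {
  fit <- glm(formula, family = binomial(), data = pop)
  # rows of the standardization population whose factor levels never occur
  # in the fitting data cannot be predicted; drop them with a warning
  keep <- rep(TRUE, nrow(std))
  for (v in names(fit$xlevels)) {
    if (v %in% names(std)) {
      keep <- keep & (as.character(std[[v]]) %in% fit$xlevels[[v]])
    }
  }
  if (!all(keep)) {
    warn(sprintf(
      "%d standardization rows dropped: covariate level unseen in the fitting data (positivity concern)",
      sum(!keep)))
    std <- std[keep, , drop = FALSE]
  }
  p1 <- predict(fit, newdata = mutate(std, a = 1), type = "response")
  p0 <- predict(fit, newdata = mutate(std, a = 0), type = "response")
  mean(p1 - p0)
}

# complete-case filter for estimation inputs; errors if nothing usable
check_estimation_rows <- function(pop, need = c("a", "y"),
                                  context = "population table") {
  pop <- check_covariates(pop, context)
  missing_cols <- setdiff(need, names(pop))
  if (length(missing_cols)) {
    abort(sprintf("%s lacks column(s): %s", context,
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in need) {
    if (!all(pop[[col]] %in% c(0, 1) | is.na(pop[[col]]))) {
      abort(sprintf("column '%s' must be binary 0/1", col))
    }
  }
  keep <- complete.cases(pop[, c("age", "parity", "education", need)])
  pop <- pop[keep, , drop = FALSE]
  if (nrow(pop) == 0L) abort(sprintf("%s has no complete rows", context))
  attr(pop, "n_dropped") <- sum(!keep)
  pop
}

warn_if_disjoint_support <- function(pop, std) {
  for (col in c("parity", "education")) {
    extra <- setdiff(unique(as.character(std[[col]])),
                     unique(as.character(pop[[col]])))
    extra <- extra[!is.na(extra)]
    if (length(extra)) {
      warn(sprintf(
        "standardization population has %s level(s) absent from the fitting population: %s (positivity concern)",
        col, paste(extra, collapse = ", ")))
    }
  }
  invisible(NULL)
}
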