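test_that("clever covariates match direct substitution", {
  h <- clever_covariates(a = c(1, 0), pS = c(0.5, 0.5), pA = c(0.5, 0.5))
  expect_equal(h$H1, c(2, 0))
  expect_equal(h$H0, c(0, 2))
  # no comparable target units: weights vanish
  h2 <- clever_covariates(a = c(1, 0), pS = c(0.999, 0.999),
                          pA = c(0.5, 0.5), bounds = NULL)
  expect_lt(max(h2$H0, h2$H1), 0.005)
  # exactly one of the pair nonzero per subject
  pop <- make_study(300, seed = 61)
  h3 <- clever_covariates(pop$a, runif(300, 0.1, 0.9), runif(300, 0.1, 0.9))
  expect_true(all((h3$H0 == 0) != (h3$H1 == 0)))
  expect_true(all(h3$H0 >= 0 & h3$H1 >= 0))
  expect_error(clever_covariates(1, pS = 1, pA = 0.5, bounds = NULL),
               "bounds")
})

test_that("fluctuation solves its score equations on both scales", {
  withr::local_seed(62)
  n <- 2000
  e0 <- runif(n, 0.2, 0.8)
  a <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(qlogis(e0) + 0.3 * a))  # e0 deliberately off
  h <- clever_covariates(a, runif(n, 0.2, 0.8), runif(n, 0.3, 0.7))
  for (scale in c("logit", "linear")) {
    fl <- fluctuate(y, e0, h$H0, h$H1, scale = scale)
    estar <- fl$update(e0, h$H0, h$H1)
    expect_lt(abs(mean(h$H0 * (y - estar))), 1e-6)
    expect_lt(abs(mean(h$H1 * (y - estar))), 1e-6)
  }
})

test_that("epsilon is near zero when the initial outcome model is correct", {
  study <- make_study(20000, seed = 63)
  target <- target_covariates(make_target(20000, seed = 64))
  fit <- transport_tmle(study, target)
  expect_lt(max(abs(fit$epsilon)), 0.05)
})

test_that("nuisance fits behave as expected", {
  # identical margins: no covariate predicts membership
  a <- simulate_population(margins_ninfea(), 4000, seed = 65, s = 1)
  b <- simulate_population(margins_ninfea(), 8000, seed = 66, s = 0)
  stacked <- dplyr::bind_rows(a, b)
  fits <- fit_nuisance_models(a, stacked)
  pS <- predict(fits$selection, newdata = stacked, type = "response")
  expect_equal(mean(pS), 4000 / 12000, tolerance = 0.01)
  expect_lt(sd(pS), 0.03)
  # treatment model recovers the generating coefficients
  big <- simulate_population(margins_ninfea(), 60000, seed = 67, s = 1)
  big$age_c <- big$age - mean(big$age)
  tf <- glm(a ~ age_c + parity, family = binomial(), data = big)
  expect_equal(unname(coef(tf)[["age_c"]]), 0.1, tolerance = 0.015)
  expect_equal(unname(coef(tf)[["parity1"]]), -0.3, tolerance = 0.1)
  expect_equal(unname(coef(tf)[["parity2+"]]), -0.5, tolerance = 0.15)
  # outcome predictions are the logistic transform of the linear predictor
  lp <- predict(fits$outcome, newdata = a[1:5, ])
  expect_equal(predict(fits$outcome, newdata = a[1:5, ], type = "response"),
               plogis(lp))
})

test_that("the TMLE solves the EIC estimating equation and its CI is coherent", {
  study <- make_study(4000, seed = 68)
  target <- target_covariates(make_target(8000, seed = 69))
  fit <- transport_tmle(study, target)
  expect_lt(abs(mean(fit$eic)), 1e-6)
  expect_lt(abs(mean(fit$study$H0 * (fit$study$y - fit$study$e_star))), 1e-6)
  expect_lt(abs(mean(fit$study$H1 * (fit$study$y - fit$study$e_star))), 1e-6)
  expect_lte(fit$ci95[1], fit$psi)
  expect_gte(fit$ci95[2], fit$psi)
  expect_gt(fit$se, 0)
  td <- tidy(fit)
  expect_equal(td$estimate, fit$psi)
  gl <- glance(fit)
  expect_equal(gl$n_study, 4000L)
  expect_equal(gl$n_target, 8000L)
})

test_that("psi is invariant to row order and untouched by inactive bounds", {
  study <- make_study(3000, seed = 70)
  target <- target_covariates(make_target(5000, seed = 71))
  fit <- transport_tmle(study, target)
  perm <- withr::with_seed(1, sample(nrow(study)))
  permt <- withr::with_seed(2, sample(nrow(target)))
  fit_perm <- transport_tmle(study[perm, ], target[permt, ])
  expect_equal(fit_perm$psi, fit$psi, tolerance = 1e-12)
  # loosening bounds below the observed probability range changes nothing
  rng <- range(fit$study$pS, fit$study$pA, fit$target$pS, fit$target$pA)
  expect_gt(rng[1], 0.001)
  fit_loose <- transport_tmle(study, target, bounds = c(1e-5, 1 - 1e-5))
  expect_equal(fit_loose$psi, fit$psi, tolerance = 1e-12)
  expect_equal(fit$truncation_counts, c(selection = 0L, treatment = 0L))
})

test_that("transported estimate tracks the closed-form oracle", {
  study <- make_study(30000, seed = 72)
  target <- target_covariates(make_target(30000, seed = 73))
  truth <- true_target_ate(dgm_params(), target)
  fit <- transport_tmle(study, target)
  expect_lt(abs(fit$psi - truth), 3 * fit$se)
  # linear (additive) fluctuation gives essentially the same answer here
  fit_lin <- transport_tmle(study, target, fluctuation = "linear")
  expect_lt(abs(fit_lin$psi - fit$psi), 0.005)
})

test_that("double robustness holds under single-model misspecification", {
  # bias is assessed as the seed-averaged deviation from the closed-form
  # oracle, since a single draw carries Monte-Carlo noise of the same order
  dev_a <- dev_b <- numeric(3)
  for (i in 1:3) {
    study <- make_study(30000, seed = 740 + i)
    target <- target_covariates(make_target(30000, seed = 750 + i))
    truth <- true_target_ate(dgm_params(), target)
    # (a) outcome model stripped of interactions; treatment/selection
    # correct. The two age distributions differ in variance, so the true
    # selection log-odds are quadratic in age: age^2 belongs in the model.
    fit_a <- transport_tmle(study, target,
                            outcome_formula = y ~ a + age + parity + education,
                            selection_formula = s ~ age + I(age^2) + parity +
                              education)
    # (b) correct outcome model; intercept-only treatment and selection
    fit_b <- transport_tmle(study, target,
                            treatment_formula = a ~ 1,
                            selection_formula = s ~ 1)
    dev_a[i] <- fit_a$psi - truth
    dev_b[i] <- fit_b$psi - truth
  }
  expect_lt(abs(mean(dev_a)), 0.02)
  expect_lt(abs(mean(dev_b)), 0.02)
})

test_that("degenerate outcomes push the update to the boundary and a null effect", {
  withr::local_seed(76)
  n <- 800
  y <- rep(1L, n)
  e0 <- runif(n, 0.5, 0.9)
  a <- rbinom(n, 1, 0.5)
  h <- clever_covariates(a, runif(n, 0.2, 0.8), runif(n, 0.3, 0.7))
  fl <- suppressWarnings(fluctuate(y, e0, h$H0, h$H1))
  pred1 <- fl$update(runif(n, 0.5, 0.9), 0, h$H1 + h$H0)
  pred0 <- fl$update(runif(n, 0.5, 0.9), h$H1 + h$H0, 0)
  expect_gt(min(pred1), 0.95)
  expect_lt(abs(transported_ate(pred1, pred0)), 0.05)
  # a fully degenerate outcome makes the outcome regression inestimable,
  # which the orchestrator reports by name
  study <- make_study(500, seed = 77)
  study$y <- 1L
  target <- target_covariates(make_target(500, seed = 78))
  expect_error(suppressWarnings(transport_tmle(study, target)), "outcome model")
})

test_that("complete-case filtering is applied and counted", {
  study <- make_study(1000, seed = 78)
  study$y[1:30] <- NA
  target <- target_covariates(make_target(1000, seed = 79))
  target$age[1:10] <- NA
  fit <- transport_tmle(study, target)
  expect_equal(fit$n_dropped, c(study = 30L, target = 10L))
  expect_equal(fit$n_study, 970L)
  expect_equal(fit$n_target, 990L)
})
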