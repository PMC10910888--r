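# frozen expected values computed by direct arithmetic: exp(v)/(1+exp(v))
test_that("generating-model probabilities match direct logistic arithmetic", {
  pop <- tibble::tibble(age = c(30, 30, 30),
                        parity = c("0", "2+", "0"),
                        education = c("high", "high", "low"))
  params <- dgm_params()
  # age at its mean: the age term vanishes for every subject
  pi <- exposure_probability(pop, params, age_center = 30)
  expect_equal(pi[1], 0.5)                        # empty linear predictor
  expect_equal(pi[2], 0.37754067, tolerance = 1e-7)  # exp(-.5)/(1+exp(-.5))
  # logistic symmetry: plogis(v) + plogis(-v) = 1
  expect_equal(stats::plogis(0.6), 0.64565631, tolerance = 1e-7)
  expect_equal(stats::plogis(0.6) + stats::plogis(-0.6), 1)

  rho0 <- outcome_probability(pop, params, a = 0, age_center = 30)
  rho1 <- outcome_probability(pop, params, a = 1, age_center = 30)
  expect_equal(rho0[1], 0.5)                        # unexposed, baseline levels
  expect_equal(rho1[3], 0.84553473, tolerance = 1e-7)  # plogis(0.6+0.6+0.5)

  zero <- dgm_params(g_a = 0, g_age = 0, g_par1 = 0, g_par2 = 0,
                     g_eduM = 0, g_eduL = 0, g_a_eduM = 0, g_a_eduL = 0)
  expect_equal(outcome_probability(pop, zero, a = 1), rep(0.5, 3))
})

test_that("sampled covariates reproduce the configured margins", {
  m <- margins_ninfea()
  pop <- sample_covariates(m, 60000, seed = 5)
  expect_equal(as.numeric(prop.table(table(pop$education))),
               unname(m$education_probs), tolerance = 0.02)
  expect_equal(as.numeric(prop.table(table(pop$parity))),
               unname(m$parity_probs), tolerance = 0.02)
  expect_lt(abs(median(pop$age) - 33), 0.2)
  expect_lt(abs(quantile(pop$age, 0.25) - 30), 0.3)
  expect_lt(abs(quantile(pop$age, 0.75) - 36), 0.3)
  expect_true(all(pop$age >= 15 & pop$age <= 50))
})

test_that("split-normal age matches median and quartiles of skewed margins", {
  m <- margins_pbr(age_shape = "split_normal")  # IQR 28-36 around median 32
  pop <- sample_covariates(m, 60000, seed = 9)
  expect_lt(abs(median(pop$age) - 32), 0.2)
  expect_lt(abs(quantile(pop$age, 0.25) - 28), 0.3)
  expect_lt(abs(quantile(pop$age, 0.75) - 36), 0.3)
})

test_that("generation is deterministic given a seed and leaves RNG state alone", {
  a <- sample_covariates(margins_pbr(), 500, seed = 3)
  before <- runif(1)
  b <- sample_covariates(margins_pbr(), 500, seed = 3)
  expect_identical(a, b)
  p1 <- simulate_population(margins_ninfea(), 200, seed = 4)
  p2 <- simulate_population(margins_ninfea(), 200, seed = 4)
  expect_identical(p1, p2)
  p3 <- simulate_population(margins_ninfea(), 200, seed = 5)
  expect_false(identical(p1$a, p3$a))
})

test_that("degenerate and invalid generator inputs are handled", {
  empty <- sample_covariates(margins_ninfea(), 0, seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("age", "parity", "education"))
  expect_error(population_margins(33, 30, 36, c(0.5, 0.5, 0.5),
                                  c(0.3, 0.3, 0.4)), "summing to 1")
  expect_error(population_margins(33, 36, 30, c(0.5, 0.3, 0.2),
                                  c(0.3, 0.3, 0.4)), "q1 < age_median")
  expect_error(sample_covariates(list(), 5), "population_margins")
  pop <- sample_covariates(margins_ninfea(), 10, seed = 1)
  expect_error(outcome_probability(pop, dgm_params()), "`a`")
})

test_that("exposure prevalence converges to the analytic mean of pi_i", {
  params <- dgm_params()
  for (n in c(2000, 50000)) {
    pop <- sample_covariates(margins_ninfea(), n, seed = 21)
    pop <- assign_exposure(pop, params, seed = 22)
    analytic <- mean(exposure_probability(pop, params))
    expect_lt(abs(mean(pop$a) - analytic), 4 / sqrt(n))
  }
})

test_that("the closed-form oracle behaves as an oracle should", {
  params <- dgm_params()
  tg <- sample_covariates(margins_pbr(), 4000, seed = 31)
  # no dependence on any seed: pure function of covariates
  expect_identical(true_target_ate(params, tg), true_target_ate(params, tg))
  # exposure absent from the outcome model -> exactly zero effect
  null_params <- dgm_params(g_a = 0, g_a_eduM = 0, g_a_eduL = 0)
  expect_equal(true_target_ate(null_params, tg), 0)
  # single subject at baseline levels: plogis(0.6) - plogis(0)
  one <- tibble::tibble(age = 30, parity = "0", education = "high")
  expect_equal(true_target_ate(params, one), 0.14565631, tolerance = 1e-7)
  expect_error(true_target_ate(params, one[0, ]), "empty")
})

test_that("equal margins make study- and target-standardized true effects agree", {
  params <- dgm_params()
  a <- sample_covariates(margins_ninfea(), 30000, seed = 41)
  b <- sample_covariates(margins_ninfea(), 30000, seed = 42)
  expect_lt(abs(true_target_ate(params, a) - true_target_ate(params, b)),
            0.01)
})

test_that("fixed-value age centering overrides the realized mean", {
  pop <- tibble::tibble(age = c(20, 40), parity = c("0", "0"),
                        education = c("high", "high"))
  params_fixed <- dgm_params(age_centering = "fixed_value",
                             age_center_value = 20)
  expect_equal(exposure_probability(pop, params_fixed),
               stats::plogis(c(0, 2)))
  expect_error(dgm_params(age_centering = "fixed_value"), "age_center_value")
})
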