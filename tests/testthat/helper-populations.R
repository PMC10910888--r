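# small simulated populations used across tests
make_study <- function(n = 3000, seed = 11) {
  simulate_population(margins_ninfea(), n, seed = seed, s = 1L)
}

make_target <- function(n = 6000, seed = 12) {
  simulate_population(margins_pbr(), n, seed = seed, s = 0L)
}

target_covariates <- function(pop) pop[, c("age", "parity", "education")]

# hand-built table with exact arm counts: n1/k1 events among exposed,
# n0/k0 among unexposed
arm_table <- function(k1, n1, k0, n0) {
  tibble::tibble(
    s = 1L,
    age = 30,
    parity = factor("0", levels = c("0", "1", "2+")),
    education = factor("high", levels = c("high", "medium", "low")),
    a = rep(c(1L, 0L), c(n1, n0)),
    y = c(rep(c(1L, 0L), c(k1, n1 - k1)), rep(c(1L, 0L), c(k0, n0 - k0)))
  )
}
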