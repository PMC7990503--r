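## Shared fixtures. Expensive objects (MCMC fits, the default synthetic
## study) are memoised so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## A small but non-trivial synthetic study (8 subjects, full 144-trial
## design each).
small_study <- function() {
  memo("small_study",
       generate_choice_study(population_spec(n_subjects = 8), seed = 11))
}

## Reduced-MCMC fit of the winning model to the small study.
small_fit <- function() {
  memo("small_fit", {
    fit_model(small_study()$trials, 5,
              mcmc_control("test", warmup = 250, iter = 250), seed = 21)
  })
}

## The full 39-subject default study (the study conditions).
default_study <- function() {
  memo("default_study", generate_choice_study(population_spec(), seed = 11))
}

## Reduced-MCMC fit of the winning model to the default study (4 chains,
## as in the full protocol, at reduced length); shared by the acceptance
## checks on convergence, recovery and the predictive checks.
default_fit <- function() {
  memo("default_fit", {
    fit_model(default_study()$trials, 5,
              mcmc_control("test", chains = 4, warmup = 500, iter = 500),
              seed = 31)
  })
}

## Reference parameter set at the group posterior means.
group_mean_params <- function() {
  c(beta_p = -0.88, beta_ph = 16.02, theta = 5.94, omega = 0.97,
    gamma = -2.35)
}

## One-subject parameter tibble for simulation helpers.
params_tbl <- function(..., subject_id = 1, tau = 0.01) {
  tibble::tibble(subject_id = subject_id, ..., tau = tau)
}
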