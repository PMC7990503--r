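test_that("population draws follow the group distribution and bounds", {
  spec <- population_spec(n_subjects = 39)
  pop <- draw_population(spec, seed = 1)
  expect_equal(nrow(pop), 39)
  expect_setequal(names(pop),
                  c("subject_id", "beta_p", "beta_ph", "theta", "omega",
                    "gamma", "tau"))
  ## all values inside the model bounds, tau fixed at the calibrated value
  for (p in c("beta_p", "beta_ph", "theta", "omega", "gamma")) {
    expect_true(all(pop[[p]] >= -20 & pop[[p]] <= 20))
  }
  expect_equal(pop$tau, rep(0.01, 39))
  ## normal-theory check on the sample mean of theta (printed 5.94 +/- 4.28)
  expect_lt(abs(mean(pop$theta) - 5.94), 3 * 4.28 / sqrt(39))
  ## zero-SD population collapses onto the group means
  degen <- population_spec(n_subjects = 5,
                           sds = c(beta_p = 0, beta_ph = 0, theta = 0,
                                   omega = 0, gamma = 0))
  pop0 <- draw_population(degen, seed = 2)
  expect_equal(unique(pop0$theta), 5.94)
  expect_equal(unique(pop0$beta_ph), 16.02)
  ## determinism
  expect_identical(pop, draw_population(spec, seed = 1))
  expect_warning(draw_population(population_spec(n_subjects = 1), seed = 1),
                 "2 subjects")
})

test_that("a default study has the full design and plausible acceptance", {
  study <- default_study()
  expect_equal(nrow(study$trials), 39 * 144)
  acc <- acceptance_by_condition(study$trials)
  ## grand-mean per-condition acceptance in the observed 60-85% band
  expect_true(all(acc$acceptance > 0.60 & acc$acceptance < 0.85))
  ## conniving cost: Control above Bribe within each scenario
  rates <- setNames(acc$acceptance, acc$condition)
  expect_gt(rates["SC"], rates["SB"])
  expect_gt(rates["DC"], rates["DB"])
})

test_that("a strong harm cost pushes Dyad-Bribe acceptance below Solo-Bribe", {
  spec <- population_spec(n_subjects = 30,
                          means = c(omega = 19), sds = c(omega = 0.5))
  study <- generate_choice_study(spec, seed = 3)
  rates <- setNames(acceptance_by_condition(study$trials)$acceptance,
                    acceptance_by_condition(study$trials)$condition)
  expect_lt(rates["DB"], rates["SB"])
})

test_that("pattern generation plants the advertised structure", {
  params <- draw_population(population_spec(n_subjects = 20), seed = 4)
  spec <- pattern_spec(n_subjects = 20, n_voxels = 60,
                       condition_effect = 0.5, shared_signal = 2,
                       behavior_coupling = 0, noise_sd = 0.5)
  pats <- generate_patterns(spec, params, seed = 5)
  expect_s3_class(pats$bribe, "mc_patterns")
  expect_equal(dim(pats$bribe), c(20, 60))
  ## strong shared signal: positive cross-condition correlation per subject
  sim <- pattern_similarity(pats$bribe, pats$control, n_perm = 200,
                            seed = 1)
  expect_gt(sim$mean_r, 0.5)
  ## a condition effect well above the noise makes the maps decodable
  spec_dec <- pattern_spec(n_subjects = 20, n_voxels = 60,
                           condition_effect = 4, shared_signal = 2,
                           behavior_coupling = 0, noise_sd = 0.5)
  pats_dec <- generate_patterns(spec_dec, params, seed = 5)
  dec <- loso_decode(pats_dec$bribe, pats_dec$control, n_perm = 20,
                     seed = 1)
  expect_equal(dec$accuracy, 1.0)
  ## determinism
  pats2 <- generate_patterns(spec, params, seed = 5)
  expect_equal(unclass(pats$bribe), unclass(pats2$bribe))
  expect_error(generate_patterns(pattern_spec(n_subjects = 3), params, 1),
               "one row per subject")
})

test_that("behaviour-brain coupling in the generator reaches the IS-RSA", {
  params <- draw_population(population_spec(n_subjects = 25), seed = 6)
  rho_at <- function(coupling, seed) {
    spec <- pattern_spec(n_subjects = 25, n_voxels = 60,
                         behavior_coupling = coupling, noise_sd = 0.7)
    pats <- generate_patterns(spec, params, seed = seed)
    contrast <- as_pattern_matrix(unclass(pats$bribe) -
                                    unclass(pats$control))
    suppressWarnings(isrsa(parameter_rdm(params$theta, params$omega),
                           neural_rdm(contrast), n_perm = 50,
                           seed = seed))$rho
  }
  ## averaged over seeds, planted coupling raises the IS-RSA correlation
  rho0 <- mean(vapply(1:8, function(s) rho_at(0, s), numeric(1)))
  rho1 <- mean(vapply(1:8, function(s) rho_at(1, s), numeric(1)))
  expect_gt(rho1, rho0 + 0.1)
})
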