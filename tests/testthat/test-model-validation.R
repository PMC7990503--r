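test_that("parameter recovery runs the simulate-refit loop and reports r", {
  fit <- small_fit()
  rec <- parameter_recovery(fit, seed = 3,
                            mcmc = mcmc_control("test", chains = 2,
                                                warmup = 150, iter = 150))
  expect_s3_class(rec, "mc_recovery")
  expect_setequal(rec$correlations$parameter, fit$model$parameter_names)
  expect_true(all(rec$correlations$r >= -1 & rec$correlations$r <= 1,
                  na.rm = TRUE))
  expect_equal(nrow(rec$scatter), 5 * length(fit$subjects))
  ## the strongly identified conniving cost recovers well even at small n
  expect_gt(rec$correlations$r[rec$correlations$parameter == "theta"], 0.5)
})

test_that("degenerate generating values are flagged as unrecoverable", {
  gen <- tibble::tibble(subject_id = 1:4, beta_p = 1, beta_ph = 10,
                        theta = 2, omega = 1, gamma = 0)
  recov <- tibble::tibble(subject_id = 1:4, beta_p = rnorm(4),
                          beta_ph = rnorm(4), theta = rnorm(4),
                          omega = rnorm(4), gamma = rnorm(4))
  expect_warning(
    rep <- moralcost:::recovery_report(gen, recov, model_spec(5)),
    "zero variance")
  expect_true(all(is.na(rep$correlations$r)))
})

test_that("within-sample PPC matches direct softmax averaging", {
  fit <- small_fit()
  ppc <- ppc_within(fit, n_reps = 100, seed = 2)
  expect_s3_class(ppc, "mc_ppc")
  expect_equal(ppc$mode, "within")
  expect_true(all(ppc$proportions$predicted >= 0 &
                    ppc$proportions$predicted <= 1))
  expect_equal(sort(unique(ppc$proportions$condition)),
               sort(c("SC", "SB", "DC", "DB")))
  expect_equal(nrow(ppc$proportions), 4 * length(fit$subjects))
  ## analytic path equals averaging accept probabilities over draws:
  ## with all draws it must match a manual computation on one subject
  probs <- moralcost:::posterior_accept_prob(fit, fit$data, n_reps = 100,
                                             seed = 2)
  manual <- dplyr::tibble(subject_id = fit$data$subject_id,
                          condition = fit$data$condition,
                          p = probs) |>
    dplyr::summarise(predicted = mean(p),
                     .by = c("subject_id", "condition"))
  joined <- dplyr::inner_join(ppc$proportions, manual,
                              by = c("subject_id", "condition"))
  expect_equal(joined$predicted.x, joined$predicted.y, tolerance = 1e-12)
  ## simulate path agrees with the analytic one up to Monte Carlo error
  ppc_sim <- ppc_within(fit, n_reps = 150, seed = 4, method = "simulate")
  agree <- dplyr::inner_join(ppc$proportions, ppc_sim$proportions,
                             by = c("subject_id", "condition"))
  expect_lt(max(abs(agree$predicted.x - agree$predicted.y)), 0.15)
  ## clipping warning when requesting more draws than available
  expect_warning(ppc_within(fit, n_reps = 10000, seed = 1), "clipped")
})

test_that("self-consistent predictions give near-perfect PPC correlations", {
  ## predictions computed from the generating parameters themselves
  study <- small_study()
  probs <- plogis(study$params$tau[match(study$trials$subject_id,
                                         study$params$subject_id)] *
                    moralcost:::sv_difference(model_spec(5), study$params,
                                              study$trials))
  rep <- moralcost:::ppc_report(study$trials, probs, mode = "within")
  expect_gt(min(rep$correlations$r), 0.9)
})

test_that("permuting subjects destroys the PPC correlation", {
  study <- default_study()
  probs <- plogis(study$params$tau[match(study$trials$subject_id,
                                         study$params$subject_id)] *
                    moralcost:::sv_difference(model_spec(5), study$params,
                                              study$trials))
  tab <- dplyr::tibble(subject_id = study$trials$subject_id,
                       condition = study$trials$condition,
                       actual = study$trials$choice, p = probs) |>
    dplyr::summarise(predicted = mean(p), actual = mean(actual),
                     .by = c("subject_id", "condition"))
  set.seed(55)
  rs <- replicate(50, {
    shuffled <- tab |>
      dplyr::mutate(predicted = predicted[sample(dplyr::n())],
                    .by = "condition")
    shuffled |>
      dplyr::summarise(r = cor(predicted, actual), .by = "condition") |>
      dplyr::pull(r) |> mean()
  })
  expect_lt(abs(mean(rs)), 0.12)
})

test_that("out-of-sample PPC fits run 1 and predicts run 2", {
  study <- small_study()
  ppc <- ppc_out_of_sample(study$trials, 5,
                           mcmc_control("test", chains = 2, warmup = 150,
                                        iter = 150), seed = 6)
  expect_equal(ppc$mode, "out_of_sample")
  ## the underlying fit saw only run-1 trials
  expect_equal(ppc$fit$n_trials, sum(study$trials$run == 1))
  expect_equal(nrow(ppc$proportions), 4 * length(unique(
    study$trials$subject_id)))
  ## exchangeable runs: decent generalisation even at n = 8
  expect_gt(min(ppc$correlations$r), 0.3)
  expect_error(ppc_out_of_sample(dplyr::select(study$trials, -run), 5),
               "run")
})
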