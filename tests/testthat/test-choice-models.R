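db_trial <- function() {
  tibble::tibble(scenario = "Dyad", conduct = "Bribe",
                 reported_payoff = 96L, offer_amount = 38L)
}

test_that("the winning model reproduces the worked subjective values", {
  pars <- group_mean_params()
  ## hand computation: -0.88*58 + 0.97*4 + (16.02-5.94)*38 - 2.35*20
  expect_equal(subjective_value(model_spec(5), pars, db_trial(), "accept"),
               288.88, tolerance = 1e-10)
  ## rejecting leaves only the omega term on the indicated option (96)
  expect_equal(subjective_value(model_spec(5), pars, db_trial(), "reject"),
               0.97 * 96, tolerance = 1e-10)
})

test_that("models 1-4 assign zero value to rejection", {
  trials <- expand_design(build_offer_set(), 1, seed = 4)
  for (m in 1:4) {
    spec <- model_spec(m)
    pars <- setNames(runif(length(spec$parameter_names), -3, 3),
                     spec$parameter_names)
    expect_equal(subjective_value(spec, pars, trials, "reject"),
                 rep(0, nrow(trials)))
  }
})

test_that("nested models collapse onto each other at boundary parameters", {
  trials <- expand_design(build_offer_set(), 1, seed = 5)
  base <- c(beta_p = -0.5, beta_ph = 2, theta = 1.5)
  for (ch in c("accept", "reject")) {
    ## gamma = 0: Model 2 equals Model 1
    expect_equal(
      subjective_value(model_spec(2), c(base, gamma = 0), trials, ch),
      subjective_value(model_spec(1), base, trials, ch))
    ## delta = 0: Model 4 equals Model 2
    expect_equal(
      subjective_value(model_spec(4), c(base, delta = 0, gamma = 0.7),
                       trials, ch),
      subjective_value(model_spec(2), c(base, gamma = 0.7), trials, ch))
    ## omega = 0: Model 5 equals Model 2
    expect_equal(
      subjective_value(model_spec(5), c(base, omega = 0, gamma = 0.7),
                       trials, ch),
      subjective_value(model_spec(2), c(base, gamma = 0.7), trials, ch))
  }
})

test_that("bribe-specific parameters are inert on Control trials", {
  trials <- expand_design(build_offer_set(), 1, seed = 6)
  control <- trials[trials$conduct == "Control", ]
  base <- c(beta_p = 1, beta_ph = 2, theta = 3, omega = 1.2, gamma = -0.4)
  alt <- base
  alt[c("theta", "omega")] <- c(-5, 7)
  for (ch in c("accept", "reject")) {
    expect_equal(subjective_value(model_spec(5), base, control, ch),
                 subjective_value(model_spec(5), alt, control, ch))
  }
})

test_that("Fehr-Schmidt forms follow the printed condition/agent structure", {
  trials <- expand_design(build_offer_set(), 1, seed = 8)
  spec6 <- model_spec(6)
  pars6 <- setNames(seq(0.1, 0.8, 0.1), spec6$parameter_names)
  sv6 <- subjective_value(spec6, pars6, trials, "accept")
  pay <- payoffs_for_choice(trials, "accept")
  cond <- tolower(trials$condition)
  manual <- pay$p_ph -
    unname(pars6[paste0("alpha_", cond)]) * pmax(pay$p_p - pay$p_ph, 0) -
    unname(pars6[paste0("beta_", cond)]) * pmax(pay$p_ph - pay$p_p, 0)
  expect_equal(sv6, manual)
  ## model 6 rejection: all payoffs zero so SV is 0
  expect_equal(subjective_value(spec6, pars6, trials, "reject"),
               rep(0, nrow(trials)))
  ## model 7 Dyad averages proposer and third-party inequity with 0.5
  spec7 <- model_spec(7)
  pars7 <- setNames(c(0.2, 0.3, 0.1, 0.15, 0.5, 0.25, 0.6, 0.35),
                    spec7$parameter_names)
  db <- trials[trials$condition == "DB", ][1, ]
  p <- payoffs_for_choice(db, "accept")
  expected <- p$p_ph -
    0.5 * (0.5 * max(p$p_p - p$p_ph, 0) + 0.6 * max(p$p_t - p$p_ph, 0)) -
    0.5 * (0.25 * max(p$p_ph - p$p_p, 0) + 0.35 * max(p$p_ph - p$p_t, 0))
  expect_equal(subjective_value(spec7, pars7, db, "accept"), expected)
  ## model 7 Dyad rejection values the third party's indicated payoff
  pr <- payoffs_for_choice(db, "reject")
  expect_equal(subjective_value(spec7, pars7, db, "reject"),
               -0.5 * 0.6 * pr$p_t)
})

test_that("softmax choice rule is stable, complementary and monotone", {
  expect_equal(accept_probability(0, 123, -456), 0.5)
  expect_equal(accept_probability(3, 7.7, 7.7), 0.5)
  expect_equal(accept_probability(0.01, 288.88, 93.12),
               1 / (1 + exp(-1.9576)), tolerance = 1e-12)
  ## no overflow at extreme products; probabilities stay inside (0, 1)
  expect_equal(accept_probability(10, 1e4, -1e4), 1)
  expect_gt(accept_probability(10, -1e4, 1e4), 0)
  ## complementarity
  a <- runif(50, -100, 100); r <- runif(50, -100, 100)
  expect_equal(accept_probability(2, a, r) + accept_probability(2, r, a),
               rep(1, 50))
  ## strictly increasing in the value difference
  d <- seq(-50, 50, length.out = 21)
  expect_true(all(diff(accept_probability(0.1, d, 0)) > 0))
  expect_error(accept_probability(-1, 0, 0), "tau")
  expect_error(accept_probability(11, 0, 0), "tau")
})

test_that("log-likelihood matches the softmax rule per trial", {
  trials <- expand_design(build_offer_set(), 1, seed = 9)
  trials$choice <- rep(c(1L, 0L), length.out = nrow(trials))
  pars <- c(group_mean_params(), tau = 0)
  ## tau = 0 makes every choice a coin flip
  expect_equal(log_likelihood(trials, 5, as.list(pars)),
               rep(log(0.5), nrow(trials)))
  pars["tau"] <- 0.01
  ll <- log_likelihood(trials, 5, as.list(pars))
  one <- db_trial()
  one$choice <- 1L
  expect_equal(log_likelihood(one, 5, as.list(pars)),
               log(accept_probability(0.01, 288.88, 93.12)),
               tolerance = 1e-6)
  ## flipping one choice only changes that element
  trials2 <- trials
  trials2$choice[5] <- 1L - trials2$choice[5]
  ll2 <- log_likelihood(trials2, 5, as.list(pars))
  expect_equal(ll[-5], ll2[-5])
  expect_false(ll[5] == ll2[5])
})

test_that("the vectorised value difference agrees with explicit SVs", {
  ## dual route: model_design_matrix vs subjective_value, all models
  trials <- expand_design(build_offer_set(), 2, seed = 10)
  for (m in 1:7) {
    spec <- model_spec(m)
    set.seed(m)
    ptab <- tibble::tibble(subject_id = 1:2)
    for (p in spec$parameter_names) ptab[[p]] <- runif(2, -2, 2)
    ptab$tau <- c(0.01, 0.05)
    dsv <- moralcost:::sv_difference(spec, ptab, trials)
    direct <- vapply(seq_len(nrow(trials)), function(i) {
      pars <- as.list(ptab[ptab$subject_id == trials$subject_id[i], ])
      subjective_value(spec, pars, trials[i, ], "accept") -
        subjective_value(spec, pars, trials[i, ], "reject")
    }, numeric(1))
    expect_equal(dsv, direct, tolerance = 1e-10)
  }
})

test_that("choice simulation is seeded and saturates correctly", {
  design <- expand_design(build_offer_set(), 1, seed = 12)
  ## parameters that make accepting hugely better everywhere
  strong <- params_tbl(beta_p = 0, beta_ph = 20, theta = 0, omega = 0,
                       gamma = 0, tau = 10)
  sim <- simulate_choices(design, 5, strong, seed = 1)
  expect_equal(mean(sim$choice), 1)
  ## tau = 0: random choices near one half
  coin <- params_tbl(beta_p = 0, beta_ph = 20, theta = 0, omega = 0,
                     gamma = 0, tau = 0)
  sim0 <- simulate_choices(design, 5, coin, seed = 2)
  expect_equal(sim0$p_accept, rep(0.5, 144))
  expect_gt(mean(sim0$choice), 0.35)
  expect_lt(mean(sim0$choice), 0.65)
  ## determinism
  expect_identical(simulate_choices(design, 5, strong, seed = 9),
                   simulate_choices(design, 5, strong, seed = 9))
  expect_error(simulate_choices(design, 5,
                                dplyr::mutate(strong, subject_id = 99),
                                seed = 1),
               "cover every subject")
})
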