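#' Parameter recovery for a fitted model
#'
#' Simulates one full choice dataset from the fitted individual-level
#' posterior means (each subject keeps their own parameters and trial
#' sequences), refits the same model with the same MCMC settings, and
#' correlates generating against recovered individual posterior means for
#' every parameter. High correlations indicate the model is identifiable
#' on this design.
#'
#' @param fit An `mc_fit`.
#' @param seed Integer seed for the simulation and refit.
#' @param mcmc Optional [mcmc_control()] overriding the original settings
#'   for the refit.
#' @return An `mc_recovery` list: `correlations` tibble (parameter, r),
#'   `scatter` tibble (per subject generating/recovered values), `refit`.
#' @export
parameter_recovery <- function(fit, seed = 1, mcmc = NULL) {
  stopifnot(inherits(fit, "mc_fit"))
  generating <- fit$estimates
  sim <- simulate_choices(fit$data, fit$model, generating, seed = seed)
  refit <- fit_model(sim, fit$model, mcmc %||% fit$mcmc, seed = seed + 1L,
                     prior = fit$prior)
  recovery_report(generating, refit$estimates, fit$model, refit)
}

recovery_report <- function(generating, recovered, model, refit = NULL) {
  params <- model$parameter_names
  idx <- match(generating$subject_id, recovered$subject_id)
  cors <- purrr::map_dfr(params, function(p) {
    gen_vals <- generating[[p]]
    rec_vals <- recovered[[p]][idx]
    degen <- sd(gen_vals) == 0 || sd(rec_vals) == 0
    tibble(parameter = p,
           r = if (degen) NA_real_ else cor(gen_vals, rec_vals),
           degenerate = degen)
  })
  if (any(cors$degenerate)) {
    warn("zero variance in generating or recovered values for some parameter(s); r undefined")
  }
  scatter <- purrr::map_dfr(params, function(p) {
    tibble(parameter = p, subject_id = generating$subject_id,
           generating = generating[[p]], recovered = recovered[[p]][idx])
  })
  structure(list(correlations = cors, scatter = scatter, refit = refit),
            class = "mc_recovery")
}

#' @export
print.mc_recovery <- function(x, ...) {
  cat("Parameter recovery (Pearson r, generating vs recovered):\n")
  for (i in seq_len(nrow(x$correlations))) {
    cat(sprintf("  %-10s r = %s\n", x$correlations$parameter[i],
                formatC(x$correlations$r[i], digits = 3, format = "f")))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mc_recovery <- function(x, ...) x$correlations

#' Within-sample posterior predictive check
#'
#' For each retained posterior draw, the model's acceptance probability is
#' evaluated on every actual trial; per subject and condition these are
#' averaged into a predicted acceptance proportion and correlated with the
#' observed proportion across subjects. `method = "analytic"` averages the
#' softmax probabilities directly (the infinite-replication limit);
#' `method = "simulate"` draws Bernoulli choices per draw, as in a full
#' generative replication.
#'
#' @param fit An `mc_fit` for `dataset`.
#' @param n_reps Number of posterior draws used (clipped to the available
#'   draws with a warning).
#' @param seed Integer seed (used by `method = "simulate"` and draw
#'   subsampling).
#' @param method `"analytic"` (default) or `"simulate"`.
#' @return An `mc_ppc` with `proportions` (subject x condition predicted
#'   and actual) and `correlations` (per-condition Pearson r), mode
#'   `"within"`.
#' @export
ppc_within <- function(fit, n_reps = 200, seed = 1,
                       method = c("analytic", "simulate")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "mc_fit"))
  pred <- posterior_accept_prob(fit, fit$data, n_reps = n_reps, seed = seed,
                                simulate = method == "simulate")
  ppc_report(fit$data, pred, mode = "within")
}

#' Out-of-sample posterior predictive check across runs
#'
#' Fits the model to run-1 trials only, then simulates run-2 choices from
#' the individual-level posterior means on the run-2 stimuli and
#' correlates predicted against actual run-2 acceptance proportions per
#' condition across subjects.
#'
#' @param data Full trial tibble with `run` and `choice` columns.
#' @param model_id Model id or `mc_model`.
#' @param mcmc [mcmc_control()] for the run-1 fit.
#' @param seed Integer seed.
#' @param prior Optional prior overrides (see [fit_model()]).
#' @return An `mc_ppc` (mode `"out_of_sample"`) with the run-1 `fit`
#'   attached.
#' @export
ppc_out_of_sample <- function(data, model_id, mcmc = mcmc_control("full"),
                              seed = 1, prior = NULL) {
  if (!"run" %in% names(data)) abort("`data` needs a `run` column")
  runs <- sort(unique(data$run))
  if (!identical(as.integer(runs), c(1L, 2L))) {
    abort("`data` must contain runs 1 and 2 for every subject")
  }
  fit1 <- fit_model(filter(data, .data$run == 1), model_id, mcmc,
                    seed = seed, prior = prior)
  run2 <- filter(data, .data$run == 2)
  sim <- simulate_choices(run2, fit1$model, fit1$estimates,
                          seed = seed + 1L)
  out <- ppc_report(run2, sim$choice, mode = "out_of_sample")
  out$fit <- fit1
  out
}

ppc_report <- function(trials, predicted, mode) {
  tab <- trials |>
    mutate(condition = trial_condition(trials),
           actual = choice_to_binary(.data$choice),
           predicted = predicted) |>
    summarise(predicted = mean(.data$predicted),
              actual = mean(.data$actual),
              n_trials = dplyr::n(),
              .by = c("subject_id", "condition"))
  cors <- tab |>
    summarise(r = cor(.data$predicted, .data$actual), .by = "condition") |>
    arrange(factor(.data$condition, levels = condition_levels))
  structure(list(proportions = tab, correlations = cors, mode = mode),
            class = "mc_ppc")
}

#' @export
print.mc_ppc <- function(x, ...) {
  cat("Posterior predictive check (", x$mode, "):\n", sep = "")
  for (i in seq_len(nrow(x$correlations))) {
    cat(sprintf("  %s: predicted-vs-actual r = %.3f\n",
                x$correlations$condition[i], x$correlations$r[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mc_ppc <- function(x, ...) x$proportions

#' @exportS3Method generics::glance
glance.mc_ppc <- function(x, ...) {
  tibble(mode = x$mode, min_r = min(x$correlations$r),
         max_r = max(x$correlations$r))
}

## Posterior-mean acceptance probability (or one simulated choice set per
## draw, averaged) for each row of `trials`, using up to n_reps draws.
posterior_accept_prob <- function(fit, trials, n_reps, seed,
                                  simulate = FALSE) {
  draws <- do.call(rbind, fit$draws)
  n_avail <- nrow(draws)
  if (n_reps > n_avail) {
    warn(paste0("n_reps clipped to the ", n_avail, " available draws"))
    n_reps <- n_avail
  }
  idx <- round(seq(1, n_avail, length.out = n_reps))
  model <- fit$model
  K <- length(model$parameter_names)
  P <- K + 1
  S <- length(fit$subjects)
  dm <- model_design_matrix(model, trials)
  si <- match(trials$subject_id, fit$subjects)
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  acc <- numeric(nrow(trials))
  for (d in idx) {
    theta <- vapply(seq_len(K), function(k) {
      lo <- unname(model$lower[k])
      range <- unname(model$upper[k] - model$lower[k])
      lo + range * pnorm(draws[d, k] + exp(draws[d, P + k]) *
                           draws[d, 2 * P + (k - 1) * S + seq_len(S)])
    }, numeric(S))
    tau <- model$tau_upper *
      pnorm(draws[d, P] + exp(draws[d, 2 * P]) *
              draws[d, 2 * P + (P - 1) * S + seq_len(S)])
    p <- plogis(tau[si] * (dm$offset + rowSums(dm$X * theta[si, ,
                                                            drop = FALSE])))
    acc <- acc + if (simulate) rbinom(length(p), 1L, p) else p
  }
  acc / length(idx)
}
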