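#' MCMC settings for hierarchical fits
#'
#' Two presets are shipped. `"full"` is the complete estimation
#' protocol: 4 chains, 2000 warmup and 1000 sampling iterations per chain
#' (4000 posterior draws). `"test"` is a reduced desk-scale preset
#' (2 chains, 400 + 400) used throughout the test-suite.
#'
#' @param preset `"full"` or `"test"`, or `NULL` when giving explicit
#'   values.
#' @param chains,warmup,iter Chain count and per-chain warmup/sampling
#'   iterations (override the preset).
#' @param adapt_delta Dual-averaging target acceptance rate.
#' @param max_depth Maximum binary tree depth of the sampler.
#' @return An `mc_mcmc` list.
#' @export
mcmc_control <- function(preset = "full", chains = NULL, warmup = NULL,
                         iter = NULL, adapt_delta = 0.8, max_depth = 10) {
  base <- switch(preset %||% "custom",
    full = list(chains = 4L, warmup = 2000L, iter = 1000L),
    test = list(chains = 2L, warmup = 400L, iter = 400L),
    custom = list(chains = 4L, warmup = 1000L, iter = 1000L),
    abort('`preset` must be "full", "test" or NULL')
  )
  out <- list(
    preset = preset %||% "custom",
    chains = as.integer(chains %||% base$chains),
    warmup = as.integer(warmup %||% base$warmup),
    iter = as.integer(iter %||% base$iter),
    adapt_delta = adapt_delta,
    max_depth = as.integer(max_depth)
  )
  stopifnot(out$chains >= 1, out$warmup >= 20, out$iter >= 10)
  structure(out, class = "mc_mcmc")
}

#' Fit a choice model hierarchically by MCMC
#'
#' Estimates one of the seven utility models with a hierarchical Bayesian
#' structure: each subject's parameters are normal draws from group-level
#' distributions on an unconstrained scale and are mapped to their bounded
#' support (\[-20, 20\] for utility weights, \[0, 10\] for the inverse
#' temperature) through a probit-type squashing
#' `lower + (upper - lower) * Phi(mu + sigma * z)`. Priors on the
#' unconstrained scale are `mu ~ Normal(0, 1)` and
#' `sigma ~ half-Normal(1)` (overridable via `prior`). Sampling uses the
#' package's No-U-Turn sampler with dual-averaging step-size adaptation
#' and a diagonal metric; convergence is summarised by split R-hat and
#' model fit by PSIS-LOO.
#'
#' @param data Trial tibble with `subject_id` and a recorded `choice`
#'   (0/1 or "accept"/"reject") on every row.
#' @param model_id Model id 1-7 or name.
#' @param mcmc An [mcmc_control()] object.
#' @param seed Integer seed (chain seeds are derived from it).
#' @param prior Optional list overriding `mu_sd` and/or `sigma_sd`.
#' @return An `mc_fit` object: posterior `draws` (per chain, unconstrained
#'   scale), `estimates` (individual posterior means on the natural
#'   scale), `group` (group-level posterior summary), `rhat`, `loo`,
#'   `diagnostics`, and metadata. Use [tidy()], [glance()],
#'   [check_convergence()], [compare_models()] downstream.
#' @examples
#' \donttest{
#' study <- generate_choice_study(population_spec(n_subjects = 8), seed = 1)
#' fit <- fit_model(study$trials, 5,
#'                  mcmc_control("test", warmup = 100, iter = 100), seed = 2)
#' glance(fit)
#' }
#' @export
fit_model <- function(data, model_id, mcmc = mcmc_control("full"),
                      seed = 1, prior = NULL) {
  model <- if (inherits(model_id, "mc_model")) model_id else
    model_spec(model_id)
  stopifnot(inherits(mcmc, "mc_mcmc"))
  y_all <- choice_to_binary(data$choice)
  if (is.null(y_all) || anyNA(y_all)) {
    abort("every trial needs a recorded choice")
  }
  data <- mutate(data, .y = y_all) |> arrange(.data$subject_id)
  subjects <- unique(data$subject_id)
  S <- length(subjects)
  if (S < 2) abort("hierarchical fitting needs at least 2 subjects")
  invariant <- data |>
    summarise(v = var(.data$.y), .by = "subject_id") |>
    filter(.data$v == 0)
  if (nrow(invariant) > 0) {
    warn(paste0(nrow(invariant),
                " subject(s) with zero choice variance; the hierarchy will shrink them"))
  }
  prior_mu_sd <- prior$mu_sd %||% 1
  prior_sigma_sd <- prior$sigma_sd %||% 1

  dm <- model_design_matrix(model, data)
  K <- length(model$parameter_names)
  P <- K + 1
  subj0 <- match(data$subject_id, subjects) - 1L
  lb <- unname(model$lower)
  ub <- unname(model$upper)

  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max / 2, mcmc$chains)
  t0 <- Sys.time()
  chains <- purrr::map(seq_len(mcmc$chains), function(ch) {
    q0 <- c(rnorm(K, 0, 0.3), -2 + rnorm(1, 0, 0.2),     # mu_raw (tau last)
            log(0.3) + rnorm(P, 0, 0.2),                 # log sigma
            rnorm(S * P, 0, 0.2))                        # z
    nuts_chain(dm$X, dm$offset, as.numeric(data$.y), subj0, S, lb, ub,
               model$tau_upper, q0, mcmc$warmup, mcmc$iter,
               chain_seeds[ch], mcmc$adapt_delta, mcmc$max_depth,
               prior_mu_sd, prior_sigma_sd)
  })
  runtime <- as.numeric(Sys.time() - t0, units = "secs")

  natural <- purrr::map(chains, ~ natural_draws(.x$draws, model, S))
  rhat_tbl <- fit_rhat(natural, chains)
  est <- individual_estimates(natural, model, subjects)
  group <- group_summary(natural, model)
  all_draws <- do.call(rbind, purrr::map(chains, "draws"))
  log_lik <- pointwise_loglik(all_draws, dm$X, dm$offset,
                              as.numeric(data$.y), subj0, S, lb, ub,
                              model$tau_upper)
  loo <- psis_loo(log_lik)

  structure(list(
    model = model,
    mcmc = mcmc,
    seed = seed,
    chain_seeds = chain_seeds,
    prior = list(mu_sd = prior_mu_sd, sigma_sd = prior_sigma_sd),
    subjects = subjects,
    data = select(data, -".y"),
    n_trials = nrow(data),
    draws = purrr::map(chains, "draws"),
    natural = natural,
    estimates = est,
    group = group,
    rhat = rhat_tbl,
    loo = loo,
    diagnostics = tibble(
      chain = seq_len(mcmc$chains),
      n_divergent = purrr::map_int(chains, ~ as.integer(.x$n_divergent)),
      step_size = purrr::map_dbl(chains, "step_size"),
      mean_treedepth = purrr::map_dbl(chains, ~ mean(.x$treedepth)),
      mean_accept = purrr::map_dbl(chains, ~ mean(.x$accept_stat))
    ),
    lp = purrr::map(chains, "lp"),
    runtime_s = runtime
  ), class = "mc_fit")
}

## Map unconstrained draws to natural-scale quantities. Returns a named
## list of draw matrices: individual parameters (iter x S per parameter,
## incl. tau) plus group location / scale summaries.
natural_draws <- function(draws, model, S) {
  K <- length(model$parameter_names)
  P <- K + 1
  nm <- c(model$parameter_names, "tau")
  out <- list()
  for (k in seq_len(P)) {
    lo <- if (k <= K) unname(model$lower[k]) else 0
    range <- if (k <= K) unname(model$upper[k] - model$lower[k]) else
      model$tau_upper
    a <- draws[, k] + exp(draws[, P + k]) *
      draws[, 2 * P + (k - 1) * S + seq_len(S), drop = FALSE]
    out[[nm[k]]] <- lo + range * pnorm(a)
    out[[paste0("mu_", nm[k])]] <- lo + range * pnorm(draws[, k])
    out[[paste0("sigma_", nm[k])]] <- exp(draws[, P + k])
  }
  out
}

fit_rhat <- function(natural, chains) {
  nm <- names(natural[[1]])
  rows <- purrr::map_dfr(nm, function(q) {
    mats <- purrr::map(natural, ~ as.matrix(.x[[q]]))
    nc <- ncol(mats[[1]])
    tibble(
      parameter = if (nc == 1) q else paste0(q, "[", seq_len(nc), "]"),
      rhat = vapply(seq_len(nc), function(j) {
        split_rhat(sapply(mats, function(m) m[, j]))
      }, numeric(1))
    )
  })
  lp <- tibble(parameter = "lp__",
               rhat = split_rhat(sapply(chains, `[[`, "lp")))
  bind_rows(rows, lp)
}

individual_estimates <- function(natural, model, subjects) {
  nm <- c(model$parameter_names, "tau")
  est <- purrr::map(nm, function(q) {
    colMeans(do.call(rbind, purrr::map(natural, ~ as.matrix(.x[[q]]))))
  })
  tibble(subject_id = subjects, !!!setNames(est, nm))
}

group_summary <- function(natural, model) {
  nm <- c(model$parameter_names, "tau")
  purrr::map_dfr(nm, function(q) {
    mu <- unlist(purrr::map(natural, ~ .x[[paste0("mu_", q)]]))
    sg <- unlist(purrr::map(natural, ~ .x[[paste0("sigma_", q)]]))
    tibble(
      parameter = q,
      mu_mean = mean(mu), mu_sd = sd(mu),
      mu_q025 = quantile(mu, 0.025), mu_q975 = quantile(mu, 0.975),
      sigma_raw_mean = mean(sg)
    )
  })
}

#' Pointwise log-likelihood matrix of a fit
#'
#' Recomputes the draws-by-trials log-likelihood array from the stored
#' posterior draws (it is not kept inside the fit object because of its
#' size).
#'
#' @param fit An `mc_fit`.
#' @return Matrix with one row per posterior draw and one column per
#'   trial (trial order: `fit$data`).
#' @export
pointwise_log_lik <- function(fit) {
  stopifnot(inherits(fit, "mc_fit"))
  dm <- model_design_matrix(fit$model, fit$data)
  subj0 <- match(fit$data$subject_id, fit$subjects) - 1L
  pointwise_loglik(do.call(rbind, fit$draws), dm$X, dm$offset,
                   choice_to_binary(fit$data$choice), subj0,
                   length(fit$subjects), unname(fit$model$lower),
                   unname(fit$model$upper), fit$model$tau_upper)
}

#' @export
print.mc_fit <- function(x, ...) {
  cat("<mc_fit: model ", x$model$model_id, " (", x$model$name, "), ",
      length(x$subjects), " subjects, ", x$n_trials, " trials>\n", sep = "")
  cat(sprintf("  %d chains x (%d warmup + %d sampling); %.0f s\n",
              x$mcmc$chains, x$mcmc$warmup, x$mcmc$iter, x$runtime_s))
  cat(sprintf("  max split R-hat %.3f; %d divergent transition(s)\n",
              max(x$rhat$rhat), sum(x$diagnostics$n_divergent)))
  cat(sprintf("  LOOIC %.1f (se %.1f)\n", x$loo$looic, x$loo$se_looic))
  invisible(x)
}

#' Tidy posterior summaries of a hierarchical fit
#'
#' @param x An `mc_fit`.
#' @param level `"group"` (default) for group-level posterior locations,
#'   or `"individual"` for per-subject posterior means.
#' @param ... Unused.
#' @return A tibble. At group level: one row per parameter with the
#'   posterior mean / sd / 95% interval of the group location (natural
#'   scale) plus the across-subject mean and SD of the individual
#'   posterior means. At individual level: `fit$estimates` in long form.
#' @exportS3Method generics::tidy
tidy.mc_fit <- function(x, level = c("group", "individual"), ...) {
  level <- match.arg(level)
  if (level == "individual") {
    return(tidyr::pivot_longer(x$estimates, -"subject_id",
                               names_to = "term", values_to = "estimate"))
  }
  ind <- x$estimates
  x$group |>
    transmute(
      term = .data$parameter,
      estimate = .data$mu_mean,
      std.error = .data$mu_sd,
      conf.low = .data$mu_q025,
      conf.high = .data$mu_q975,
      subject_mean = purrr::map_dbl(.data$parameter, ~ mean(ind[[.x]])),
      subject_sd = purrr::map_dbl(.data$parameter, ~ sd(ind[[.x]]))
    )
}

#' @exportS3Method generics::glance
glance.mc_fit <- function(x, ...) {
  tibble(
    model_id = x$model$model_id,
    name = x$model$name,
    n_subjects = length(x$subjects),
    n_trials = x$n_trials,
    chains = x$mcmc$chains,
    draws = x$mcmc$chains * x$mcmc$iter,
    max_rhat = max(x$rhat$rhat),
    n_divergent = sum(x$diagnostics$n_divergent),
    looic = x$loo$looic,
    elpd = x$loo$elpd,
    p_loo = x$loo$p_loo
  )
}

#' Write / read a fit archive
#'
#' Serialises a fit as plain files: unconstrained posterior draws per
#' chain (CSV), individual posterior means (CSV), and a JSON metadata file
#' (model, MCMC settings, seeds, R-hat table, LOOIC).
#'
#' @param fit An `mc_fit`.
#' @param dir Directory to create/fill.
#' @return `write_fit()` returns `dir` invisibly; `read_fit()` returns a
#'   list with the archive contents (not a full `mc_fit`).
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in seq_along(fit$draws)) {
    write.csv(as.data.frame(fit$draws[[ch]]),
              file.path(dir, sprintf("draws_chain%d.csv", ch)),
              row.names = FALSE)
  }
  write.csv(fit$estimates, file.path(dir, "individual_estimates.csv"),
            row.names = FALSE)
  meta <- list(
    model_id = fit$model$model_id, model_name = fit$model$name,
    parameters = fit$model$parameter_names,
    mcmc = unclass(fit$mcmc), seed = fit$seed,
    chain_seeds = fit$chain_seeds, prior = fit$prior,
    n_subjects = length(fit$subjects), n_trials = fit$n_trials,
    looic = fit$loo$looic, elpd = fit$loo$elpd,
    max_rhat = max(fit$rhat$rhat),
    rhat = fit$rhat, diagnostics = fit$diagnostics,
    runtime_s = fit$runtime_s
  )
  jsonlite::write_json(meta, file.path(dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_fit
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "fit.json"),
                              simplifyVector = TRUE)
  chains <- sort(list.files(dir, pattern = "^draws_chain\\d+\\.csv$"))
  list(
    meta = meta,
    draws = purrr::map(chains, ~ as.matrix(read.csv(file.path(dir, .x)))),
    estimates = as_tibble(read.csv(file.path(dir,
                                             "individual_estimates.csv")))
  )
}
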