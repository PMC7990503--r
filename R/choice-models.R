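#' The social-utility model family
#'
#' Seven candidate utility functions describe how a power-holder values
#' accepting versus rejecting an offer. Writing `p_p`, `p_ph`, `p_t` for
#' the payoffs of proposer, power-holder and third party under the chosen
#' option, and `q = 1` on Bribe trials:
#'
#' * **Model 1** `SV = beta_p * p_p + (beta_ph - theta * q) * p_ph`:
#'   the moral cost of conniving (`theta`) devalues the power-holder's own
#'   bribe-tainted gain.
#' * **Model 2** adds unsigned inequity between proposer and power-holder,
#'   `gamma * |p_p - p_ph|`.
#' * **Model 3** adds an extra conniving cost `delta` in the Dyad scenario
#'   (`theta + delta` replaces `theta` there).
#' * **Model 4** combines Models 2 and 3.
#' * **Model 5** (the winning model) replaces `delta` with an explicit
#'   weight `omega` on the third party's payoff under bribery:
#'   `SV = beta_p * p_p + omega * q * p_t + (beta_ph - theta * q) * p_ph +
#'   gamma * |p_p - p_ph|` in Dyad, without the `omega` term in Solo.
#' * **Model 6** is a condition-specific Fehr-Schmidt form,
#'   `SV = p_ph - alpha_c * max(p_p - p_ph, 0) - beta_c * max(p_ph - p_p, 0)`
#'   with `alpha`/`beta` varying over the four conditions.
#' * **Model 7** is the three-agent Fehr-Schmidt form: in Dyad the
#'   proposer- and third-party-inequity terms are averaged with weight 0.5,
#'   with agent-specific `alpha`/`beta`.
#'
#' Utility parameters are bounded in \[-20, 20\]; the inverse softmax
#' temperature `tau` in \[0, 10\].
#'
#' @param model_id Integer 1-7, or a model name such as `"moral_harm"`.
#' @return A `mc_model` list with fields `model_id`, `name`,
#'   `parameter_names`, `lower`, `upper`, `tau_upper`.
#' @examples
#' model_spec(5)$parameter_names
#' @export
model_spec <- function(model_id) {
  reg <- model_registry()
  if (is.character(model_id)) {
    hit <- purrr::detect(reg, ~ .x$name == model_id)
    if (is.null(hit)) abort(paste0("unknown model name: ", model_id))
    return(hit)
  }
  if (!is.numeric(model_id) || length(model_id) != 1 ||
      !(model_id %in% 1:7)) {
    abort("`model_id` must be an integer in 1..7 or a model name")
  }
  reg[[as.integer(model_id)]]
}

model_registry <- function() {
  mk <- function(id, name, pars) {
    structure(list(
      model_id = id, name = name, parameter_names = pars,
      lower = setNames(rep(-20, length(pars)), pars),
      upper = setNames(rep(20, length(pars)), pars),
      tau_upper = 10
    ), class = "mc_model")
  }
  list(
    mk(1L, "moral_basic", c("beta_p", "beta_ph", "theta")),
    mk(2L, "moral_inequity", c("beta_p", "beta_ph", "theta", "gamma")),
    mk(3L, "moral_dyad_cost", c("beta_p", "beta_ph", "theta", "delta")),
    mk(4L, "moral_dyad_inequity",
       c("beta_p", "beta_ph", "theta", "delta", "gamma")),
    mk(5L, "moral_harm",
       c("beta_p", "beta_ph", "theta", "omega", "gamma")),
    mk(6L, "fehr_schmidt_condition",
       c("alpha_sc", "alpha_sb", "alpha_dc", "alpha_db",
         "beta_sc", "beta_sb", "beta_dc", "beta_db")),
    mk(7L, "fehr_schmidt_agents",
       c("alpha_sc", "alpha_sb", "beta_sc", "beta_sb",
         "alpha_p", "beta_p_fs", "alpha_t", "beta_t"))
  )
}

#' List the available choice models
#'
#' @return A tibble with one row per model: id, name and parameter names.
#' @export
list_models <- function() {
  purrr::map_dfr(model_registry(), function(m) {
    tibble(model_id = m$model_id, name = m$name,
           n_parameters = length(m$parameter_names),
           parameters = paste(m$parameter_names, collapse = ", "))
  })
}

#' @export
print.mc_model <- function(x, ...) {
  cat("<mc_model ", x$model_id, ": ", x$name, ">\n", sep = "")
  cat("  parameters:", paste(x$parameter_names, collapse = ", "), "\n")
  cat("  bounds: [-20, 20]; tau in [0,", x$tau_upper, "]\n")
  invisible(x)
}

check_params <- function(model, params) {
  missing <- setdiff(model$parameter_names, names(params))
  if (length(missing)) {
    abort(paste0("missing parameter(s) for model ", model$model_id, ": ",
                 paste(missing, collapse = ", ")))
  }
  vals <- unlist(params[model$parameter_names])
  out_of_bounds <- vals < model$lower - 1e-9 | vals > model$upper + 1e-9
  if (any(out_of_bounds)) {
    abort(paste0("parameter(s) out of bounds: ",
                 paste(model$parameter_names[out_of_bounds], collapse = ", ")))
  }
  vals
}

#' Subjective value of a choice under a model
#'
#' Evaluates the utility a power-holder with parameters `params` assigns to
#' accepting or rejecting each trial, from the payoffs implied by the
#' choice (see [payoffs_for_choice()]). Rejection zeroes the proposer's and
#' power-holder's payoffs; in the Dyad scenario the third party is then
#' paid according to the computer-indicated option, which Models 5 and 7
#' still value.
#'
#' @param model A `mc_model` from [model_spec()] (or an id passed to it).
#' @param params Named list or vector with one value per model parameter.
#' @param trials A trial tibble.
#' @param choice `"accept"` or `"reject"` (scalar or per-row).
#' @return Numeric vector of subjective values, one per trial.
#' @examples
#' trial <- tibble::tibble(scenario = "Dyad", conduct = "Bribe",
#'                         reported_payoff = 96L, offer_amount = 38L)
#' pars <- c(beta_p = -0.88, beta_ph = 16.02, theta = 5.94,
#'           omega = 0.97, gamma = -2.35)
#' subjective_value(model_spec(5), pars, trial, "accept") # 288.88
#' @export
subjective_value <- function(model, params, trials, choice) {
  if (!inherits(model, "mc_model")) model <- model_spec(model)
  v <- check_params(model, params)
  pay <- payoffs_for_choice(trials, choice)
  q <- as.numeric(trials$conduct == "Bribe")
  dyad <- trials$scenario == "Dyad"
  p_p <- pay$p_p
  p_ph <- pay$p_ph
  p_t <- ifelse(dyad, pay$p_t, 0)
  ineq <- abs(p_p - p_ph)
  id <- model$model_id
  if (id <= 5) {
    sv <- v["beta_p"] * p_p + (v["beta_ph"] - v["theta"] * q) * p_ph
    if (id %in% c(2, 4, 5)) sv <- sv + v["gamma"] * ineq
    if (id %in% c(3, 4)) sv <- sv - v["delta"] * q * dyad * p_ph
    if (id == 5) sv <- sv + v["omega"] * q * dyad * p_t
    return(unname(sv))
  }
  dis <- pmax(p_p - p_ph, 0) # disadvantageous inequity vs proposer
  adv <- pmax(p_ph - p_p, 0)
  if (id == 6) {
    cond <- tolower(trial_condition(trials))
    a <- v[paste0("alpha_", cond)]
    b <- v[paste0("beta_", cond)]
    return(unname(p_ph - a * dis - b * adv))
  }
  ## Model 7: Solo as Model 6; Dyad averages proposer and third-party terms
  cond <- tolower(trial_condition(trials))
  dis_t <- pmax(p_t - p_ph, 0)
  adv_t <- pmax(p_ph - p_t, 0)
  a_solo <- ifelse(cond == "sb", v["alpha_sb"], v["alpha_sc"])
  b_solo <- ifelse(cond == "sb", v["beta_sb"], v["beta_sc"])
  sv_solo <- p_ph - a_solo * dis - b_solo * adv
  sv_dyad <- p_ph -
    0.5 * (v["alpha_p"] * dis + v["alpha_t"] * dis_t) -
    0.5 * (v["beta_p_fs"] * adv + v["beta_t"] * adv_t)
  unname(ifelse(dyad, sv_dyad, sv_solo))
}

trial_condition <- function(trials) {
  if ("condition" %in% names(trials)) return(trials$condition)
  paste0(ifelse(trials$scenario == "Dyad", "D", "S"),
         ifelse(trials$conduct == "Bribe", "B", "C"))
}

#' Softmax probability of accepting an offer
#'
#' `P(accept) = exp(tau * sv_accept) / (exp(tau * sv_accept) +
#' exp(tau * sv_reject))`, evaluated in the numerically stable logistic
#' form so that large `tau * SV` products cannot overflow.
#'
#' @param tau Inverse softmax temperature in \[0, 10\].
#' @param sv_accept,sv_reject Subjective values of the two options.
#' @return Probability of acceptance, strictly within (0, 1) for finite
#'   inputs.
#' @examples
#' accept_probability(0.01, 288.88, 93.12) # ~0.876
#' @export
accept_probability <- function(tau, sv_accept, sv_reject) {
  if (any(tau < 0 | tau > 10)) abort("`tau` must lie in [0, 10]")
  p <- plogis(tau * (sv_accept - sv_reject))
  ## keep strictly inside (0, 1) so downstream logs stay finite
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.neg.eps)
}

#' Per-trial log-likelihood of recorded choices
#'
#' @param data Trial tibble with a 0/1 (or "accept"/"reject") `choice`
#'   column.
#' @param model A `mc_model` or model id.
#' @param params Named parameter list including `tau`.
#' @return Numeric vector of per-trial log-probabilities.
#' @export
log_likelihood <- function(data, model, params) {
  if (!inherits(model, "mc_model")) model <- model_spec(model)
  y <- choice_to_binary(data$choice)
  if (anyNA(y)) abort("every trial needs a recorded choice")
  tau <- params[["tau"]] %||% abort("`params` must include `tau`")
  sv_a <- subjective_value(model, params, data, "accept")
  sv_r <- subjective_value(model, params, data, "reject")
  p <- accept_probability(tau, sv_a, sv_r)
  ifelse(y == 1, log(p), log1p(-p))
}

choice_to_binary <- function(choice) {
  if (is.null(choice)) return(NULL)
  if (is.character(choice) || is.factor(choice)) {
    as.integer(as.character(choice) == "accept")
  } else {
    as.integer(choice)
  }
}

#' Simulate choices for a design under a model
#'
#' Draws each choice from a Bernoulli distribution with the softmax
#' acceptance probability implied by that subject's parameters.
#'
#' @param design Trial tibble covering one or more subjects.
#' @param model A `mc_model` or model id.
#' @param params_by_subject Tibble with one row per subject: `subject_id`,
#'   one column per model parameter, and `tau`.
#' @param seed Integer seed.
#' @return The design with a 0/1 `choice` column (1 = accept) and the
#'   latent `p_accept` column appended.
#' @export
simulate_choices <- function(design, model, params_by_subject, seed) {
  if (!inherits(model, "mc_model")) model <- model_spec(model)
  subs <- unique(design$subject_id)
  if (!all(subs %in% params_by_subject$subject_id)) {
    abort("`params_by_subject` must cover every subject in the design")
  }
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  dsv <- sv_difference(model, params_by_subject, design)
  tau <- params_by_subject$tau[match(design$subject_id,
                                     params_by_subject$subject_id)]
  if (any(tau < 0 | tau > 10)) abort("`tau` must lie in [0, 10]")
  p <- plogis(tau * dsv)
  design |>
    mutate(p_accept = p, choice = rbinom(length(p), 1L, p))
}

## Vectorised SV(accept) - SV(reject) for a whole multi-subject table.
## Every model reduces to offset + X %*% theta with subject-specific theta;
## this same decomposition feeds the compiled sampler.
sv_difference <- function(model, params_by_subject, trials) {
  dm <- model_design_matrix(model, trials)
  idx <- match(trials$subject_id, params_by_subject$subject_id)
  theta <- as.matrix(params_by_subject[model$parameter_names])[idx, ,
                                                               drop = FALSE]
  unname(dm$offset + rowSums(dm$X * theta))
}

## Design matrix of the accept-minus-reject value difference.
model_design_matrix <- function(model, trials) {
  if (!inherits(model, "mc_model")) model <- model_spec(model)
  acc <- payoffs_for_choice(trials, "accept")
  rej <- payoffs_for_choice(trials, "reject")
  q <- as.numeric(trials$conduct == "Bribe")
  dyad <- as.numeric(trials$scenario == "Dyad")
  p_p <- acc$p_p
  p_ph <- acc$p_ph
  p_ta <- ifelse(dyad == 1, acc$p_t, 0)
  p_tr <- ifelse(dyad == 1, rej$p_t, 0)
  ineq <- abs(p_p - p_ph)
  id <- model$model_id
  n <- nrow(trials)
  if (id <= 5) {
    cols <- list(beta_p = p_p, beta_ph = p_ph, theta = -q * p_ph)
    if (id %in% c(3, 4)) cols$delta <- -q * dyad * p_ph
    if (id == 5) cols$omega <- q * dyad * (p_ta - p_tr)
    if (id %in% c(2, 4, 5)) cols$gamma <- ineq
    X <- do.call(cbind, cols[model$parameter_names])
    return(list(X = X, offset = rep(0, n)))
  }
  dis <- pmax(p_p - p_ph, 0)
  adv <- pmax(p_ph - p_p, 0)
  cond <- tolower(trial_condition(trials))
  if (id == 6) {
    X <- sapply(model$parameter_names, function(nm) {
      parts <- strsplit(nm, "_")[[1]]
      base <- if (parts[1] == "alpha") dis else adv
      -base * (cond == parts[2])
    })
    return(list(X = X, offset = p_ph))
  }
  ## Model 7: reject leaves the third party with the indicated payoff, so
  ## the accept-reject difference gains +0.5 * alpha_t * p_t(reject).
  dis_t <- pmax(p_ta - p_ph, 0)
  adv_t <- pmax(p_ph - p_ta, 0)
  X <- cbind(
    alpha_sc = -dis * (cond == "sc"),
    alpha_sb = -dis * (cond == "sb"),
    beta_sc = -adv * (cond == "sc"),
    beta_sb = -adv * (cond == "sb"),
    alpha_p = -0.5 * dis * dyad,
    beta_p_fs = -0.5 * adv * dyad,
    alpha_t = -0.5 * (dis_t - p_tr) * dyad,
    beta_t = -0.5 * adv_t * dyad
  )[, model$parameter_names, drop = FALSE]
  list(X = X, offset = p_ph)
}
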