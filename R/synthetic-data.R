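#' Specify a synthetic subject population
#'
#' Defines the group-level distribution from which individual utility
#' parameters are drawn. The defaults reproduce the study conditions of
#' the bribery experiment: 39 subjects and, for the winning moral-harm
#' model, group means and SDs `beta_ph 16.02 +/- 2.47`,
#' `beta_p -0.88 +/- 2.48`, `theta 5.94 +/- 4.28`, `omega 0.97 +/- 0.82`,
#' `gamma -2.35 +/- 2.23`. The inverse temperature defaults to a fixed
#' `tau = 0.01`, which with these utilities yields per-condition acceptance
#' rates in the observed 60-85% range.
#'
#' @param model_id Model the parameters belong to (default 5).
#' @param n_subjects Number of subjects (default 39).
#' @param means,sds Named numeric vectors overriding the per-parameter
#'   group means and SDs.
#' @param tau Either a single fixed value applied to all subjects or a
#'   `c(mean, sd)` pair for normal draws (truncated to \[0, 10\]).
#' @return A `mc_population` list.
#' @export
population_spec <- function(model_id = 5, n_subjects = 39, means = NULL,
                            sds = NULL, tau = 0.01) {
  model <- model_spec(model_id)
  def <- default_population(model)
  m <- def$means
  s <- def$sds
  if (!is.null(means)) m[names(means)] <- means
  if (!is.null(sds)) s[names(sds)] <- sds
  if (any(s < 0)) abort("group SDs must be non-negative")
  if (!length(tau) %in% 1:2 || any(tau[1] < 0 | tau[1] > 10)) {
    abort("`tau` must be a fixed value in [0, 10] or a (mean, sd) pair")
  }
  structure(list(model_id = model$model_id, n_subjects = n_subjects,
                 means = m, sds = s, tau = tau),
            class = "mc_population")
}

default_population <- function(model) {
  printed <- c(beta_p = -0.88, beta_ph = 16.02, theta = 5.94,
               omega = 0.97, gamma = -2.35, delta = 0)
  printed_sd <- c(beta_p = 2.48, beta_ph = 2.47, theta = 4.28,
                  omega = 0.82, gamma = 2.23, delta = 1)
  nm <- model$parameter_names
  means <- setNames(ifelse(nm %in% names(printed), printed[nm], 0.5), nm)
  sds <- setNames(ifelse(nm %in% names(printed_sd), printed_sd[nm], 0.5), nm)
  list(means = means, sds = sds)
}

#' Draw a population of subject parameters
#'
#' Independent normal draws per parameter per subject, truncated to the
#' model bounds (truncation rather than rejection keeps the draw count,
#' and hence reproducibility, independent of the bounds).
#'
#' @param spec A `mc_population` from [population_spec()].
#' @param seed Integer seed.
#' @return Tibble with `subject_id`, one column per utility parameter,
#'   and `tau`.
#' @export
draw_population <- function(spec, seed) {
  stopifnot(inherits(spec, "mc_population"))
  if (spec$n_subjects < 2) {
    warn("fewer than 2 subjects: downstream between-subject analyses will fail")
  }
  model <- model_spec(spec$model_id)
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- spec$n_subjects
  draws <- purrr::imap(spec$means, function(m, nm) {
    pmin(model$upper[nm], pmax(model$lower[nm], rnorm(n, m, spec$sds[nm])))
  })
  tau <- if (length(spec$tau) == 1) rep(spec$tau, n) else {
    pmin(10, pmax(0, rnorm(n, spec$tau[1], spec$tau[2])))
  }
  tibble(subject_id = seq_len(n), !!!draws, tau = tau)
}

#' Generate a complete synthetic choice study
#'
#' Composes [build_offer_set()], [expand_design()], [draw_population()]
#' and [simulate_choices()]: 36 offers x 4 conditions x `n_subjects`
#' subjects, with choices generated from the requested model.
#'
#' @param pop_spec A `mc_population`; default `population_spec()` (the
#'   39-subject winning-model population).
#' @param seed Integer seed driving design randomisation, parameter draws
#'   and choice simulation.
#' @return A list with `trials` (trial tibble incl. `choice`), `params`
#'   (the generating per-subject parameters) and `pop_spec`.
#' @examples
#' study <- generate_choice_study(population_spec(n_subjects = 4), seed = 1)
#' nrow(study$trials) # 4 * 144
#' @export
generate_choice_study <- function(pop_spec = population_spec(), seed) {
  stopifnot(inherits(pop_spec, "mc_population"))
  design <- expand_design(build_offer_set(), pop_spec$n_subjects,
                          seed = seed)
  params <- draw_population(pop_spec, seed = seed + 1L)
  trials <- simulate_choices(design, model_spec(pop_spec$model_id), params,
                             seed = seed + 2L)
  list(trials = trials, params = params, pop_spec = pop_spec)
}

#' Specify synthetic neural pattern matrices
#'
#' Controls the generative structure of synthetic subject-by-voxel
#' contrast maps for the Bribe and Control conditions. These are
#' statistical stand-ins for ROI-extracted GLM contrast values: no
#' haemodynamics or spatial smoothness are modelled, only the components
#' the similarity and decoding analyses are sensitive to.
#'
#' Each subject's maps are built from (i) a subject-specific signal shared
#' by both conditions (`shared_signal`, driving cross-condition pattern
#' similarity), (ii) a common condition-effect direction separating Bribe
#' from Control maps (`condition_effect`, driving decodability), (iii) a
#' moral-preference component in the Bribe-minus-Control contrast whose
#' amplitude follows the subject's standardised `(theta, omega)`
#' (`behavior_coupling`, driving the inter-subject behaviour-brain
#' association), and (iv) i.i.d. Gaussian noise (`noise_sd`).
#'
#' @param n_subjects,n_voxels Dimensions of each pattern matrix.
#' @param condition_effect Amplitude of the Bribe-vs-Control mean pattern
#'   separation (same units as the noise SD).
#' @param shared_signal Amplitude of the per-subject component common to
#'   both condition maps.
#' @param behavior_coupling In \[0, 1\]: 0 makes patterns independent of
#'   the behavioural parameters.
#' @param noise_sd Standard deviation of the additive noise.
#' @return A `mc_pattern_spec` list.
#' @export
pattern_spec <- function(n_subjects = 39, n_voxels = 100,
                         condition_effect = 0.5, shared_signal = 0.5,
                         behavior_coupling = 0.5, noise_sd = 1) {
  if (n_voxels < 2) abort("`n_voxels` must be at least 2")
  if (behavior_coupling < 0 || behavior_coupling > 1) {
    abort("`behavior_coupling` must lie in [0, 1]")
  }
  structure(list(n_subjects = n_subjects, n_voxels = n_voxels,
                 condition_effect = condition_effect,
                 shared_signal = shared_signal,
                 behavior_coupling = behavior_coupling,
                 noise_sd = noise_sd),
            class = "mc_pattern_spec")
}

#' Generate synthetic condition pattern matrices
#'
#' @param spec A `mc_pattern_spec`.
#' @param params Per-subject parameter tibble with `theta` and `omega`
#'   columns (e.g. from [draw_population()]); row count must equal
#'   `spec$n_subjects`.
#' @param seed Integer seed.
#' @return A list with `bribe` and `control` pattern matrices (class
#'   `mc_patterns`, see [as_pattern_matrix()]) and `truth`, a record of
#'   the planted components.
#' @export
generate_patterns <- function(spec, params, seed) {
  stopifnot(inherits(spec, "mc_pattern_spec"))
  if (nrow(params) != spec$n_subjects) {
    abort("`params` must have one row per subject in the pattern spec")
  }
  if (!all(c("theta", "omega") %in% names(params))) {
    abort("`params` must contain `theta` and `omega` columns")
  }
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  S <- spec$n_subjects
  V <- spec$n_voxels
  zscore <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  th <- zscore(params$theta)
  om <- zscore(params$omega)
  u <- rnorm(V)                 # condition-effect direction
  e1 <- rnorm(V)                # preference embedding directions
  e2 <- rnorm(V)
  shared <- matrix(rnorm(S * V), S, V) * spec$shared_signal
  coupling <- spec$behavior_coupling * (outer(th, e1) + outer(om, e2))
  bribe <- shared +
    matrix(u * spec$condition_effect / 2, S, V, byrow = TRUE) +
    coupling +
    matrix(rnorm(S * V, 0, spec$noise_sd), S, V)
  control <- shared -
    matrix(u * spec$condition_effect / 2, S, V, byrow = TRUE) +
    matrix(rnorm(S * V, 0, spec$noise_sd), S, V)
  ids <- params$subject_id %||% seq_len(S)
  list(
    bribe = as_pattern_matrix(bribe, subject_ids = ids,
                              roi_label = "synthetic",
                              contrast_label = "bribe"),
    control = as_pattern_matrix(control, subject_ids = ids,
                                roi_label = "synthetic",
                                contrast_label = "control"),
    truth = list(condition_direction = u, embedding = cbind(e1, e2),
                 theta_z = th, omega_z = om, spec = spec)
  )
}
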