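#' Read / write choice-trial tables
#'
#' Trial tables are plain delimited text with a header row; the canonical
#' columns are `subject_id`, `run`, `trial_index`, `scenario`, `conduct`,
#' `reported_payoff`, `offer_proportion`, `offer_amount` and (optionally)
#' `choice` and `rt_ms`. A `column_map` (old = new) renames non-standard
#' headers on read.
#'
#' @param path File path (comma- or tab-delimited, inferred from the
#'   extension: `.tsv`/`.txt` are read as tab).
#' @param column_map Optional named character vector mapping file columns
#'   to canonical names, e.g. `c(subj = "subject_id")`.
#' @return A trial tibble.
#' @examples
#' path <- system.file("extdata", "synthetic_choices.csv",
#'                     package = "moralcost")
#' head(read_choice_table(path))
#' @export
read_choice_table <- function(path, column_map = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE)
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(df))
    if (anyNA(idx)) abort("column_map refers to columns absent from the file")
    names(df)[idx] <- unname(column_map)
  }
  as_tibble(df)
}

#' @rdname read_choice_table
#' @param trials A trial tibble.
#' @export
write_choice_table <- function(trials, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(trials, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Validate a choice table against the task's invariants
#'
#' Schema and invariant checks for a trial table (a path or an in-memory
#' data frame): required columns, valid scenario/conduct levels, payoffs
#' within the task's constraints (reported payoff in (50, 100\]; offer
#' amount below `2 * reported_payoff - 100` so the proposer stays better
#' off), and per-subject per-condition trial counts. Subjects missing one
#' choice type (all-accept or all-reject) in some condition are flagged
#' but not dropped.
#'
#' @param x File path or trial data frame.
#' @param column_map Passed to [read_choice_table()] when `x` is a path.
#' @return A list with `data` (validated tibble), `violations` (tibble of
#'   row-level problems), `subject_summary` (per subject x condition trial
#'   and acceptance counts) and `flags` (subject-level warnings).
#' @export
validate_choice_table <- function(x, column_map = NULL) {
  data <- if (is.character(x)) read_choice_table(x, column_map) else
    as_tibble(x)
  required <- c("subject_id", "scenario", "conduct", "reported_payoff",
                "offer_amount")
  missing <- setdiff(required, names(data))
  if (length(missing) || nrow(data) == 0) {
    abort(paste0("malformed choice table: ",
                 if (nrow(data) == 0) "no rows" else
                   paste("missing column(s)", paste(missing, collapse = ", "))))
  }
  row_id <- seq_len(nrow(data))
  problems <- list(
    bad_scenario = !data$scenario %in% c("Solo", "Dyad"),
    bad_conduct = !data$conduct %in% c("Control", "Bribe"),
    payoff_out_of_range = data$reported_payoff <= 50 |
      data$reported_payoff > 100,
    offer_not_profitable = data$reported_payoff - data$offer_amount <=
      100 - data$reported_payoff,
    offer_out_of_range = data$offer_amount < 0 |
      data$offer_amount > data$reported_payoff
  )
  violations <- purrr::imap_dfr(problems, function(bad, nm) {
    bad <- bad & !is.na(bad)
    tibble(row = row_id[bad], problem = nm)
  })
  has_choice <- "choice" %in% names(data)
  subject_summary <- data |>
    mutate(condition = trial_condition(data)) |>
    summarise(
      n_trials = dplyr::n(),
      n_accept = if (has_choice) sum(choice_to_binary(.data$choice),
                                     na.rm = TRUE) else NA_integer_,
      .by = c("subject_id", "condition")
    )
  flags <- character()
  if (has_choice) {
    one_sided <- subject_summary |>
      filter(.data$n_accept == 0 | .data$n_accept == .data$n_trials)
    if (nrow(one_sided)) {
      flags <- paste0("subject ", one_sided$subject_id, " has a missing choice type in ",
                      one_sided$condition)
    }
  }
  list(data = data, violations = violations,
       subject_summary = subject_summary, flags = flags)
}

#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: which models to fit,
#' the MCMC preset, the population and pattern generators, permutation
#' counts and the master seed. The `"full"` preset pins the complete
#' protocol (4 chains, 2000 + 1000 iterations, 5000 permutations, 4000
#' PPC replications); `"test"` pins the reduced desk-scale settings.
#'
#' @param preset `"full"` or `"test"`.
#' @param models Integer vector of model ids to fit and compare.
#' @param seed Master seed.
#' @param out_dir Optional output directory for [run_pipeline()] archives.
#' @param pop_spec,pattern_spec Generator specifications.
#' @param n_perm,ppc_reps,mcmc Overrides of the preset values.
#' @return An `mc_config` list.
#' @export
pipeline_config <- function(preset = c("test", "full"), models = 1:5,
                            seed = 1, out_dir = NULL,
                            pop_spec = population_spec(),
                            pattern_spec = moralcost::pattern_spec(),
                            n_perm = NULL, ppc_reps = NULL, mcmc = NULL) {
  preset <- match.arg(preset)
  if (!all(models %in% 1:7)) abort("`models` must be ids in 1..7")
  base <- if (preset == "full") {
    list(mcmc = mcmc_control("full"), n_perm = 5000L, ppc_reps = 4000L)
  } else {
    list(mcmc = mcmc_control("test"), n_perm = 500L, ppc_reps = 200L)
  }
  structure(list(
    preset = preset, models = as.integer(models), seed = as.integer(seed),
    out_dir = out_dir, pop_spec = pop_spec, pattern_spec = pattern_spec,
    mcmc = mcmc %||% base$mcmc,
    n_perm = as.integer(n_perm %||% base$n_perm),
    ppc_reps = as.integer(ppc_reps %||% base$ppc_reps)
  ), class = "mc_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage in order: design + simulation, model fitting for
#' all requested models, LOOIC comparison, convergence checks, parameter
#' recovery, within- and out-of-sample posterior predictive checks, and
#' the neural-similarity stage (pattern generation, IS-RSA, cross-
#' condition similarity, LOSO decoding). All stage seeds derive from the
#' config's master seed, so identical configs give identical results. If
#' `config$out_dir` is set, JSON/CSV reports are written as the stages
#' complete.
#'
#' @param config An `mc_config` from [pipeline_config()].
#' @return A named list of stage outputs (invisible).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  out <- list(config = config)
  emit <- function(name, obj) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(config$out_dir, paste0(name, ".json"))
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    }
  }
  seed <- config$seed

  study <- generate_choice_study(config$pop_spec, seed = seed)
  out$study <- study
  emit("acceptance_rates", acceptance_by_condition(study$trials))

  out$fits <- purrr::map(config$models, function(m) {
    fit_model(study$trials, m, config$mcmc, seed = seed + 10L + m)
  })
  names(out$fits) <- paste0("model_", config$models)
  out$comparison <- compare_models(out$fits)
  emit("model_comparison", out$comparison)
  out$convergence <- purrr::map(out$fits, check_convergence)

  win_id <- out$comparison$model_id[1]
  win <- out$fits[[paste0("model_", win_id)]]
  out$recovery <- parameter_recovery(win, seed = seed + 20L)
  emit("parameter_recovery", out$recovery$correlations)
  out$ppc_within <- ppc_within(win, n_reps = config$ppc_reps,
                               seed = seed + 30L)
  emit("ppc_within", out$ppc_within$correlations)
  out$ppc_oos <- ppc_out_of_sample(study$trials, win_id, config$mcmc,
                                   seed = seed + 40L)
  emit("ppc_out_of_sample", out$ppc_oos$correlations)

  pats <- generate_patterns(config$pattern_spec, study$params,
                            seed = seed + 50L)
  out$patterns <- pats
  est <- win$estimates
  if (all(c("theta", "omega") %in% names(est))) {
    contrast <- as_pattern_matrix(unclass(pats$bribe) - unclass(pats$control),
                                  subject_ids = attr(pats$bribe, "subject_ids"),
                                  contrast_label = "bribe - control")
    out$isrsa <- isrsa(parameter_rdm(est$theta, est$omega,
                                     subject_ids = est$subject_id),
                       neural_rdm(contrast),
                       n_perm = config$n_perm, seed = seed + 60L)
    emit("isrsa", glance(out$isrsa))
  }
  out$similarity <- pattern_similarity(pats$bribe, pats$control,
                                       n_perm = config$n_perm,
                                       seed = seed + 70L)
  emit("pattern_similarity", glance(out$similarity))
  out$decoding <- loso_decode(pats$bribe, pats$control,
                              n_perm = min(config$n_perm, 1000L),
                              seed = seed + 80L)
  emit("loso_decoding", glance(out$decoding))
  invisible(out)
}

#' Per-condition acceptance rates
#'
#' @param trials Trial tibble with choices.
#' @return Tibble with condition, acceptance rate (subject-mean) and the
#'   across-subject SD.
#' @export
acceptance_by_condition <- function(trials) {
  trials |>
    mutate(condition = trial_condition(trials),
           y = choice_to_binary(.data$choice)) |>
    summarise(rate = mean(.data$y), .by = c("subject_id", "condition")) |>
    summarise(acceptance = mean(.data$rate), sd = sd(.data$rate),
              .by = "condition") |>
    arrange(factor(.data$condition, levels = condition_levels))
}
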