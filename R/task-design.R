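#' Build the offer set of the bribery game
#'
#' Enumerates the stimulus grid of the task: proposer reported payoffs from
#' CNY 56 to 96 in steps of 8, crossed with offer proportions from 10% to
#' 90% in steps of 10%. The offer amount is the nearest integer to
#' `proportion * reported_payoff` (ties to even, so amounts stay integral
#' CNY). Only offers that keep the proposer strictly better off after
#' sharing are retained: `reported_payoff - offer_amount` must exceed the
#' alternative payoff `100 - reported_payoff`, since the two options always
#' sum to CNY 100 and a rational proposer only lies (or bribes) for a net
#' gain. Under the default grid exactly 36 offers survive.
#'
#' @param reported_payoffs Integer vector of reported (higher) proposer
#'   payoffs in CNY. Default `seq(56, 96, by = 8)`.
#' @param proportions Numeric vector of offer proportions in (0, 1).
#'   Default `seq(0.1, 0.9, by = 0.1)`.
#' @return A tibble with one row per offer, columns `offer_id`,
#'   `reported_payoff`, `offer_proportion`, `offer_amount`, ordered by
#'   payoff then proportion.
#' @examples
#' offers <- build_offer_set()
#' nrow(offers) # 36
#' @export
build_offer_set <- function(reported_payoffs = seq(56L, 96L, by = 8L),
                            proportions = seq(0.1, 0.9, by = 0.1)) {
  if (any(reported_payoffs <= 50 | reported_payoffs > 100)) {
    abort("reported payoffs must lie in (50, 100]: the reported option is the higher of two options summing to 100")
  }
  if (any(proportions <= 0 | proportions >= 1)) {
    abort("offer proportions must lie strictly in (0, 1)")
  }
  offers <- tidyr::expand_grid(
    reported_payoff = as.integer(sort(unique(reported_payoffs))),
    offer_proportion = sort(unique(proportions))
  ) |>
    mutate(offer_amount = as.integer(round(.data$offer_proportion *
                                             .data$reported_payoff))) |>
    filter(.data$reported_payoff - .data$offer_amount >
             100L - .data$reported_payoff) |>
    arrange(.data$reported_payoff, .data$offer_proportion) |>
    mutate(offer_id = row_number(), .before = 1)
  offers
}

#' Expand an offer set into a full within-subject trial design
#'
#' Crosses each offer with the four experimental conditions (scenario
#' Solo/Dyad by proposer conduct Control/Bribe) so each offer appears once
#' per condition per subject, and splits the 4 x n_offers trials into two
#' runs such that each offer appears exactly twice per run. The split
#' follows the task's randomisation: per subject, offers are divided into
#' two equal subsets; one random pair of conditions is presented with
#' subset 1 in run 1 (and with subset 2 in run 2), the other pair vice
#' versa. Trial order within a run is shuffled.
#'
#' @param offers Offer tibble from [build_offer_set()] (or a compatible
#'   table with unique `reported_payoff` x `offer_proportion` rows and an
#'   `offer_amount` column).
#' @param n_subjects Number of subjects to generate designs for.
#' @param seed Integer seed driving the run split and trial order.
#' @return A trial tibble with columns `subject_id`, `run`, `trial_index`,
#'   `scenario` ("Solo"/"Dyad"), `conduct` ("Control"/"Bribe"), `condition`
#'   (SC/SB/DC/DB), `q` (1 in Bribe trials), `reported_payoff`,
#'   `offer_proportion`, `offer_amount`.
#' @examples
#' design <- expand_design(build_offer_set(), n_subjects = 2, seed = 1)
#' dplyr::count(design, subject_id, run)
#' @export
expand_design <- function(offers, n_subjects, seed) {
  stopifnot(nrow(offers) >= 2, n_subjects >= 1)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer")
  }
  key <- paste(offers$reported_payoff, offers$offer_proportion)
  if (anyDuplicated(key)) {
    abort("offers contain duplicated (reported_payoff, offer_proportion) pairs")
  }
  if (nrow(offers) %% 2 != 0) {
    abort("the number of offers must be even to split runs evenly")
  }
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))

  conds <- condition_levels
  half <- nrow(offers) / 2
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    subset_id <- sample(rep(1:2, each = half))
    cond_order <- sample(conds)
    base <- tidyr::expand_grid(offer_id = offers$offer_id, condition = conds) |>
      left_join(offers, by = "offer_id") |>
      mutate(
        subset = subset_id[match(.data$offer_id, offers$offer_id)],
        run = ifelse(
          (.data$subset == 1 & .data$condition %in% cond_order[1:2]) |
            (.data$subset == 2 & .data$condition %in% cond_order[3:4]),
          1L, 2L
        )
      ) |>
      select(-"subset")
    base <- base[order(base$run, sample(nrow(base))), ]
    base |>
      mutate(
        subject_id = s,
        trial_index = row_number(),
        scenario = ifelse(.data$condition %in% c("DC", "DB"), "Dyad", "Solo"),
        conduct = ifelse(.data$condition %in% c("SB", "DB"), "Bribe", "Control"),
        q = as.integer(.data$conduct == "Bribe")
      ) |>
      select("subject_id", "run", "trial_index", "scenario", "conduct",
             "condition", "q", "reported_payoff", "offer_proportion",
             "offer_amount")
  })
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Payoffs implied by accepting or rejecting a trial's offer
#'
#' Encodes the monetary consequences of the power-holder's decision for the
#' proposer (`p_p`), the power-holder (`p_ph`), and -- in the Dyad scenario
#' -- the innocent third party (`p_t`). Accepting pays the power-holder the
#' offer amount and the proposer the remainder of the reported payoff; the
#' third party receives the complement of the reported payoff (CNY 100
#' minus it). Rejecting earns both the proposer and the power-holder
#' nothing, while the third party is paid according to the option the
#' computer indicated: in Control the reported option is the indicated one
#' (so the third party again gets the complement); in Bribe the reported
#' option is the fraudulent, non-indicated one, so the indicated option
#' gives the third party the reported payoff itself.
#'
#' @param trials A trial tibble (as from [expand_design()]).
#' @param choice `"accept"` or `"reject"`; either a single value applied to
#'   all rows or one value per row.
#' @return A tibble with columns `p_p`, `p_ph`, `p_t` (`p_t` is `NA` for
#'   Solo trials, where no third party exists).
#' @examples
#' trial <- tibble::tibble(scenario = "Dyad", conduct = "Bribe",
#'                         reported_payoff = 96L, offer_amount = 38L)
#' payoffs_for_choice(trial, "accept") # 58 / 38 / 4
#' payoffs_for_choice(trial, "reject") # 0 / 0 / 96
#' @export
payoffs_for_choice <- function(trials, choice) {
  choice <- match_choice(choice, nrow(trials))
  dyad <- trials$scenario == "Dyad"
  bribe <- trials$conduct == "Bribe"
  accept <- choice == "accept"
  p_p <- ifelse(accept, trials$reported_payoff - trials$offer_amount, 0)
  p_ph <- ifelse(accept, trials$offer_amount, 0)
  third_indicated <- ifelse(bribe, trials$reported_payoff,
                            100 - trials$reported_payoff)
  p_t <- ifelse(dyad,
                ifelse(accept, 100 - trials$reported_payoff, third_indicated),
                NA_real_)
  out <- tibble(p_p = as.numeric(p_p), p_ph = as.numeric(p_ph), p_t = p_t)
  bad <- !is.na(out$p_p) & (out$p_p < 0 | out$p_ph < 0 | out$p_p > 100 |
                              out$p_ph > 100)
  if (any(bad)) abort("payoffs fall outside [0, 100]; check the trial table")
  out
}

match_choice <- function(choice, n) {
  choice <- as.character(choice)
  if (!all(choice %in% c("accept", "reject"))) {
    abort('`choice` must be "accept" or "reject"')
  }
  if (length(choice) == 1) rep(choice, n) else {
    stopifnot(length(choice) == n)
    choice
  }
}

#' Trial-level expected gains and third-party loss
#'
#' Computes the decision covariates used as parametric modulators of neural
#' activity: the power-holder's expected gain if the offer is accepted
#' (`expected_gain_ph`, the offer amount), the proposer's expected gain
#' (`expected_gain_p`, reported payoff minus offer amount), and the
#' expected loss to the third party (`expected_loss_t`). The third party
#' only stands to lose in the Dyad Bribe condition, where acceptance moves
#' their payoff from the indicated `reported_payoff` down to
#' `100 - reported_payoff`, a loss of `2 * reported_payoff - 100`; in every
#' other condition their payoff does not depend on the decision and the
#' loss is zero.
#'
#' @param trials A trial tibble.
#' @return The input with columns `expected_gain_ph`, `expected_gain_p`,
#'   `expected_loss_t` appended.
#' @export
trial_covariates <- function(trials) {
  db <- trials$scenario == "Dyad" & trials$conduct == "Bribe"
  trials |>
    mutate(
      expected_gain_ph = as.numeric(.data$offer_amount),
      expected_gain_p = as.numeric(.data$reported_payoff - .data$offer_amount),
      expected_loss_t = ifelse(db, 2 * .data$reported_payoff - 100, 0)
    )
}
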