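#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Computes the expected log pointwise predictive density (elpd) by
#' leave-one-out importance sampling on a pointwise log-likelihood matrix,
#' stabilising each observation's importance ratios by fitting a
#' generalized Pareto distribution to their right tail (empirical-Bayes
#' fit of Zhang & Stephens 2009) and replacing the tail with its order
#' statistics. `looic = -2 * elpd` on the deviance scale; lower is better.
#'
#' @param log_lik Matrix of pointwise log-likelihood values, posterior
#'   draws in rows, observations in columns.
#' @return An `mc_loo` list with `looic`, `elpd`, `se_looic`, `p_loo`,
#'   `pointwise` (tibble with per-observation `elpd_i` and Pareto `k`).
#' @references Vehtari, Gelman & Gabry (2017) Statistics and Computing;
#'   Vehtari et al. (2024) JMLR 25(72).
#' @export
psis_loo <- function(log_lik) {
  stopifnot(is.matrix(log_lik), all(is.finite(log_lik)))
  S <- nrow(log_lik)
  N <- ncol(log_lik)
  if (S < 25) warn("very few posterior draws; PSIS tail fits are unstable")
  lpd_i <- apply(log_lik, 2, logsumexp) - log(S)
  elpd_i <- numeric(N)
  k_i <- numeric(N)
  for (j in seq_len(N)) {
    sm <- psis_smooth(-log_lik[, j])
    ## normalized smoothed log weights combined with the log likelihood
    elpd_i[j] <- logsumexp(sm$log_weights + log_lik[, j]) -
      logsumexp(sm$log_weights)
    k_i[j] <- sm$k
  }
  elpd <- sum(elpd_i)
  se_elpd <- sqrt(N * var(elpd_i))
  structure(list(
    looic = -2 * elpd, elpd = elpd, se_looic = 2 * se_elpd,
    se_elpd = se_elpd, p_loo = sum(lpd_i) - elpd,
    pointwise = tibble(elpd_i = elpd_i, k = k_i),
    n_draws = S, n_obs = N
  ), class = "mc_loo")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Smooth one observation's raw log importance weights. Tail length
## follows min(S/5, 3*sqrt(S)); smoothed weights are truncated at the
## largest raw weight.
psis_smooth <- function(log_ratios) {
  s <- length(log_ratios)
  x <- log_ratios - max(log_ratios)
  tail_len <- as.integer(ceiling(min(s / 5, 3 * sqrt(s))))
  ord <- order(x)
  xcutoff <- max(x[ord[s - tail_len]], log(.Machine$double.xmin))
  tail_ids <- which(x > xcutoff)
  k <- Inf
  if (length(tail_ids) > 4) {
    exp_cutoff <- exp(xcutoff)
    x_tail <- exp(x[tail_ids]) - exp_cutoff
    tail_ord <- order(x_tail)
    fit <- gpd_fit(x_tail[tail_ord])
    k <- fit$k
    if (is.finite(k)) {
      n_t <- length(x_tail)
      probs <- (seq_len(n_t) - 0.5) / n_t
      smoothed <- log(gpd_quantile(probs, fit$k, fit$sigma) + exp_cutoff)
      x[tail_ids[tail_ord]] <- smoothed
      x[x > 0] <- 0
    }
  }
  list(log_weights = x, k = k)
}

## Empirical-Bayes generalized-Pareto fit (Zhang & Stephens 2009) to a
## sorted sample of exceedances.
gpd_fit <- function(x) {
  n <- length(x)
  prior_bs <- 3
  prior_k <- 10
  m <- 30 + floor(sqrt(n))
  b <- 1 / x[n] +
    (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_bs * x[floor(n / 4 + 0.5)])
  k_b <- vapply(b, function(bj) mean(log1p(-bj * x)), numeric(1))
  log_lik_b <- n * (log(-b / k_b) - k_b - 1)
  w <- 1 / vapply(log_lik_b, function(l) sum(exp(log_lik_b - l)), numeric(1))
  keep <- w >= 10 * .Machine$double.eps
  w <- w[keep] / sum(w[keep])
  b_post <- sum(b[keep] * w)
  k_post <- mean(log1p(-b_post * x))
  sigma <- -k_post / b_post
  list(k = (n * k_post + prior_k * 0.5) / (n + prior_k), sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (sigma <= 0) return(rep(NaN, length(p)))
  if (abs(k) < .Machine$double.eps) sigma * (-log1p(-p))
  else sigma * expm1(-k * log1p(-p)) / k
}

#' @export
print.mc_loo <- function(x, ...) {
  cat("PSIS-LOO:", x$n_obs, "observations,", x$n_draws, "draws\n")
  cat(sprintf("  elpd  = %.1f (se %.1f)\n", x$elpd, x$se_elpd))
  cat(sprintf("  looic = %.1f (se %.1f), p_loo = %.1f\n",
              x$looic, x$se_looic, x$p_loo))
  bad <- sum(x$pointwise$k > 0.7)
  if (bad) cat("  ", bad, "observation(s) with Pareto k > 0.7\n")
  invisible(x)
}

#' Compare fitted models by LOOIC
#'
#' Ranks fits of competing utility models on the same dataset by their
#' leave-one-out information criterion. The model with the lowest LOOIC
#' wins; a LOOIC difference of at least 10 is conventionally regarded as
#' decisive.
#'
#' @param ... Fitted models (`mc_fit` objects), or a single list of them.
#' @return A tibble sorted by LOOIC with columns `model_id`, `name`,
#'   `looic`, `se_looic`, `elpd`, `p_loo`, `delta_looic` (relative to the
#'   winner) and `decisive`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "mc_fit")) fits <- fits[[1]]
  if (!all(purrr::map_lgl(fits, inherits, "mc_fit"))) {
    abort("compare_models() expects mc_fit objects")
  }
  n_obs <- purrr::map_int(fits, ~ .x$loo$n_obs)
  if (length(unique(n_obs)) != 1) {
    abort("fits were not computed on the same number of trials")
  }
  out <- purrr::map_dfr(fits, function(f) {
    tibble(model_id = f$model$model_id, name = f$model$name,
           looic = f$loo$looic, se_looic = f$loo$se_looic,
           elpd = f$loo$elpd, p_loo = f$loo$p_loo)
  }) |>
    arrange(.data$looic) |>
    mutate(delta_looic = .data$looic - .data$looic[1],
           decisive = .data$delta_looic >= 10)
  class(out) <- c("mc_comparison", class(out))
  out
}
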