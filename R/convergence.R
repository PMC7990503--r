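#' Split-chain Gelman-Rubin diagnostic
#'
#' The potential scale reduction factor computed after splitting each
#' chain in half, so that within-chain trends register as apparent
#' between-chain variance. Values near 1 indicate converged, well-mixed
#' chains; a common threshold is 1.1.
#'
#' @param x Iterations-by-chains matrix of draws for one quantity.
#' @return The split R-hat value.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  half <- floor(nrow(x) / 2)
  if (half < 2) return(NA_real_)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(half + 1):(2 * half), , drop = FALSE])
  m <- ncol(sp)
  n <- nrow(sp)
  w <- mean(apply(sp, 2, var))
  b <- n * var(colMeans(sp))
  if (w == 0) return(if (b == 0) 1 else Inf)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Check MCMC convergence of a fit
#'
#' Applies [split_rhat()] to every monitored quantity of a hierarchical
#' fit (group-level means and SDs, individual parameters, and the log
#' posterior) and compares the maximum against a threshold.
#'
#' @param fit An `mc_fit`.
#' @param threshold Pass iff max R-hat is at or below this (default 1.1).
#' @return An `mc_convergence` list with `passed`, `max_rhat`, `threshold`
#'   and the per-parameter `rhat` tibble.
#' @export
check_convergence <- function(fit, threshold = 1.1) {
  stopifnot(inherits(fit, "mc_fit"))
  if (fit$mcmc$chains < 2) {
    abort("convergence checking needs at least 2 chains")
  }
  rh <- fit$rhat
  structure(list(passed = max(rh$rhat) <= threshold,
                 max_rhat = max(rh$rhat), threshold = threshold,
                 rhat = rh),
            class = "mc_convergence")
}

#' @export
print.mc_convergence <- function(x, ...) {
  cat(sprintf("Convergence %s: max split R-hat = %.4f (threshold %.2f, %d quantities)\n",
              if (x$passed) "PASSED" else "FAILED", x$max_rhat, x$threshold,
              nrow(x$rhat)))
  invisible(x)
}
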