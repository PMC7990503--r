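#' Representational dissimilarity matrices
#'
#' An RDM is a symmetric subject-by-subject distance matrix with zero
#' diagonal: Euclidean distance in moral-preference parameter space for
#' the behavioural RDM, correlation distance (1 - Pearson r between voxel
#' vectors) for the neural RDM.
#'
#' @name rdm
NULL

new_rdm <- function(m, subject_ids, metric_label) {
  stopifnot(isSymmetric(unname(m)), all(abs(diag(m)) < 1e-12))
  diag(m) <- 0
  structure(m, subject_ids = subject_ids, metric_label = metric_label,
            class = c("mc_rdm", "matrix", "array"))
}

#' @export
print.mc_rdm <- function(x, ...) {
  cat("<mc_rdm: ", nrow(x), " subjects; metric ", attr(x, "metric_label"),
      ">\n", sep = "")
  print(round(unclass(x)[seq_len(min(5, nrow(x))),
                         seq_len(min(5, ncol(x)))], 3))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mc_rdm <- function(x, ...) {
  ids <- attr(x, "subject_ids")
  n <- nrow(x)
  idx <- which(lower.tri(x), arr.ind = TRUE)
  tibble(subject_a = ids[idx[, 2]], subject_b = ids[idx[, 1]],
         distance = x[idx])
}

#' Behavioural RDM from the moral-cost parameters
#'
#' Pairwise Euclidean distance between subjects in the `(theta, omega)`
#' plane -- the two parameters that characterise bribery-specific moral
#' costs. By default each parameter is z-scored first, because their
#' spreads differ several-fold and raw distances would be dominated by
#' `theta`; set `standardize = FALSE` for raw-scale distances.
#'
#' @param theta,omega Per-subject parameter values (equal length >= 3).
#' @param standardize Z-score each parameter before computing distances.
#' @param subject_ids Optional identifiers.
#' @return An `mc_rdm` matrix.
#' @export
parameter_rdm <- function(theta, omega, standardize = TRUE,
                          subject_ids = NULL) {
  stopifnot(length(theta) == length(omega))
  if (length(theta) < 3) abort("RDM analyses need at least 3 subjects")
  if (standardize) {
    if (sd(theta) == 0 || sd(omega) == 0) {
      abort("cannot standardize a parameter with zero variance")
    }
    theta <- as.numeric(scale(theta))
    omega <- as.numeric(scale(omega))
  }
  m <- as.matrix(stats::dist(cbind(theta, omega)))
  dimnames(m) <- NULL
  new_rdm(m, subject_ids %||% seq_along(theta),
          if (standardize) "euclidean (z-scored)" else "euclidean")
}

#' Neural RDM from a pattern matrix
#'
#' Correlation distance `1 - Pearson r` between each pair of subjects'
#' voxel vectors.
#'
#' @param patterns An `mc_patterns` matrix (>= 2 voxels).
#' @return An `mc_rdm` matrix with entries in \[0, 2\].
#' @export
neural_rdm <- function(patterns) {
  x <- unclass(patterns)
  if (nrow(x) < 3) abort("RDM analyses need at least 3 subjects")
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("constant voxel vector (undefined correlation) for subject(s): ",
                 paste(attr(patterns, "subject_ids")[sds == 0], collapse = ", ")))
  }
  m <- 1 - cor(t(x))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- NULL
  new_rdm(m, attr(patterns, "subject_ids") %||% seq_len(nrow(x)),
          "1 - Pearson r")
}

rdm_lower <- function(rdm) rdm[lower.tri(rdm)]

#' Inter-subject representational similarity analysis
#'
#' Spearman rank correlation between the lower triangles of two RDMs
#' (typically a behavioural parameter RDM and a neural RDM), with
#' Mantel-style permutation inference: the rows and columns of the second
#' RDM are jointly permuted `n_perm` times and the permutation p-value is
#' `(b + 1) / (n_perm + 1)`, where `b` counts permuted statistics at least
#' as favourable as the observed one. One-tailed (positive association) by
#' default, matching the directional hypothesis that similar preferences
#' go with similar neural patterns.
#'
#' @param rdm_a,rdm_b `mc_rdm` matrices over the same subjects in the
#'   same order.
#' @param n_perm Number of permutations (5000 in the full analysis).
#' @param seed Integer seed.
#' @param alternative `"greater"` (default), `"two.sided"` or `"less"`.
#' @return An `mc_isrsa` list with `rho`, `p`, `n_perm`, `perm_rho`.
#' @export
isrsa <- function(rdm_a, rdm_b, n_perm = 5000, seed = 1,
                  alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  if (nrow(rdm_a) != nrow(rdm_b)) abort("RDMs must cover the same subjects")
  ids_a <- attr(rdm_a, "subject_ids")
  ids_b <- attr(rdm_b, "subject_ids")
  if (!is.null(ids_a) && !is.null(ids_b) && !identical(ids_a, ids_b)) {
    abort("RDM subject orderings differ; align them before calling isrsa()")
  }
  if (n_perm < 100) warn("fewer than 100 permutations gives a coarse p-value")
  va <- rdm_lower(rdm_a)
  rho <- cor(va, rdm_lower(rdm_b), method = "spearman")
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- nrow(rdm_b)
  b <- unclass(rdm_b)
  perm_rho <- vapply(seq_len(n_perm), function(i) {
    pp <- sample.int(n)
    cor(va, rdm_lower(b[pp, pp]), method = "spearman")
  }, numeric(1))
  p <- perm_pvalue(rho, perm_rho, alternative)
  structure(list(rho = rho, p = p, n_perm = n_perm, perm_rho = perm_rho,
                 alternative = alternative),
            class = "mc_isrsa")
}

perm_pvalue <- function(observed, permuted, alternative) {
  switch(alternative,
    greater = (sum(permuted >= observed) + 1) / (length(permuted) + 1),
    less = (sum(permuted <= observed) + 1) / (length(permuted) + 1),
    two.sided = (sum(abs(permuted) >= abs(observed)) + 1) /
      (length(permuted) + 1)
  )
}

#' @export
print.mc_isrsa <- function(x, ...) {
  cat("Inter-subject RSA: Spearman rho =", round(x$rho, 3),
      "; permutation p =", signif(x$p, 3),
      paste0("(", x$n_perm, " permutations, ", x$alternative, ")\n"))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mc_isrsa <- function(x, ...) {
  tibble(rho = x$rho, p.value = x$p, n_perm = x$n_perm,
         alternative = x$alternative)
}

#' Cross-condition pattern similarity
#'
#' For each subject, the Pearson correlation between their voxel patterns
#' in two conditions, Fisher z-transformed. The group-level test is a
#' sign-flip permutation of the mean z against zero (each subject's z has
#' its sign flipped independently), two-sided by default.
#'
#' @param patterns_a,patterns_b `mc_patterns` over the same subjects with
#'   the same voxel count.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return An `mc_patsim` list with per-subject `r` and `z`, `mean_z`,
#'   `mean_r`, and the permutation `p`.
#' @export
pattern_similarity <- function(patterns_a, patterns_b, n_perm = 5000,
                               seed = 1,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  if (!all(dim(patterns_a) == dim(patterns_b))) {
    abort("pattern matrices must share subjects and voxel count")
  }
  if (ncol(patterns_a) < 3) {
    warn("fewer than 3 voxels: per-subject correlations are near-degenerate")
  }
  a <- unclass(patterns_a)
  b <- unclass(patterns_b)
  r <- vapply(seq_len(nrow(a)), function(s) cor(a[s, ], b[s, ]), numeric(1))
  clipped <- abs(r) >= 1 - 1e-12
  if (any(clipped)) {
    warn("per-subject |r| = 1 clipped before the Fisher transform")
    r[clipped] <- sign(r[clipped]) * (1 - 1e-12)
  }
  z <- atanh(r)
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  perm_mean <- vapply(seq_len(n_perm), function(i) {
    mean(z * sample(c(-1, 1), length(z), replace = TRUE))
  }, numeric(1))
  p <- perm_pvalue(mean(z), perm_mean, alternative)
  structure(list(subject_ids = attr(patterns_a, "subject_ids"),
                 r = r, z = z, mean_r = mean(r), mean_z = mean(z),
                 p = p, n_perm = n_perm, alternative = alternative),
            class = "mc_patsim")
}

#' @export
print.mc_patsim <- function(x, ...) {
  cat("Cross-condition pattern similarity: mean r =", round(x$mean_r, 3),
      "(mean z =", round(x$mean_z, 3),
      "); sign-flip p =", signif(x$p, 3), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mc_patsim <- function(x, ...) {
  tibble(subject_id = x$subject_ids, r = x$r, z = x$z)
}

#' @exportS3Method generics::glance
glance.mc_patsim <- function(x, ...) {
  tibble(mean_r = x$mean_r, mean_z = x$mean_z, p.value = x$p,
         n_perm = x$n_perm, alternative = x$alternative)
}

#' Leave-one-subject-out forced-choice decoding
#'
#' Trains a linear support-vector classifier (slack parameter `C`,
#' default 1) to separate two condition maps, leaving one subject out at a
#' time. The held-out subject is scored by the two-alternative forced
#' choice: correct if the decision value of their condition-a map exceeds
#' that of their condition-b map. The ROC curve and AUC pool the
#' cross-validated decision values of all maps against the true labels.
#' Significance is assessed by re-running the full cross-validation
#' `n_perm` times with the two condition labels randomly swapped within
#' subjects.
#'
#' @param patterns_a,patterns_b `mc_patterns` for the two conditions,
#'   same subjects (condition a is coded +1, condition b -1).
#' @param c_value SVM slack parameter C.
#' @param n_perm Number of within-subject label-swap permutations.
#' @param seed Integer seed.
#' @return An `mc_loso` list with `accuracy`, per-subject `correct`,
#'   `decision_values`, `roc` (tibble of points), `auc`, `p`, `perm_acc`.
#' @export
loso_decode <- function(patterns_a, patterns_b, c_value = 1, n_perm = 1000,
                        seed = 1) {
  if (!all(dim(patterns_a) == dim(patterns_b))) {
    abort("pattern matrices must share subjects and voxel count")
  }
  if (nrow(patterns_a) < 3) abort("LOSO decoding needs at least 3 subjects")
  if (c_value <= 0) abort("`c_value` must be positive")
  a <- unclass(patterns_a)
  b <- unclass(patterns_b)
  res <- loso_pass(a, b, c_value)
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  S <- nrow(a)
  perm_acc <- vapply(seq_len(n_perm), function(i) {
    flip <- sample(c(TRUE, FALSE), S, replace = TRUE)
    aa <- a; bb <- b
    aa[flip, ] <- b[flip, ]
    bb[flip, ] <- a[flip, ]
    loso_pass(aa, bb, c_value)$accuracy
  }, numeric(1))
  p <- perm_pvalue(res$accuracy, perm_acc, "greater")
  dv <- res$decision_values
  lab <- rep(c(1, -1), each = S)
  structure(list(accuracy = res$accuracy, correct = res$correct,
                 decision_values = dv, labels = lab,
                 roc = roc_points(dv, lab), auc = auc_trapezoid(dv, lab),
                 p = p, perm_acc = perm_acc, n_perm = n_perm,
                 c_value = c_value,
                 subject_ids = attr(patterns_a, "subject_ids")),
            class = "mc_loso")
}

## One full leave-one-subject-out pass; returns forced-choice accuracy and
## cross-validated decision values (first all condition-a maps, then all b).
loso_pass <- function(a, b, c_value) {
  S <- nrow(a)
  dv_a <- numeric(S)
  dv_b <- numeric(S)
  for (s in seq_len(S)) {
    x_train <- rbind(a[-s, , drop = FALSE], b[-s, , drop = FALSE])
    y_train <- factor(rep(c(1, -1), each = S - 1), levels = c(1, -1))
    fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = c_value,
                      scale = FALSE)
    pred <- predict(fit, rbind(a[s, ], b[s, ]), decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    ## orient decision values so positive favours condition a (label +1)
    if (colnames(attr(pred, "decision.values"))[1] == "-1/1") dv <- -dv
    dv_a[s] <- dv[1]
    dv_b[s] <- dv[2]
  }
  correct <- dv_a > dv_b
  list(accuracy = mean(correct), correct = correct,
       decision_values = c(dv_a, dv_b))
}

roc_points <- function(dv, labels) {
  thr <- c(Inf, sort(unique(dv), decreasing = TRUE), -Inf)
  pos <- labels == 1
  tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(dv[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(dv[!pos] >= t), numeric(1))
  )
}

auc_trapezoid <- function(dv, labels) {
  rp <- roc_points(dv, labels)
  sum(diff(rp$fpr) * (head(rp$tpr, -1) + rp$tpr[-1]) / 2)
}

#' @export
print.mc_loso <- function(x, ...) {
  cat("LOSO forced-choice decoding: accuracy =",
      sprintf("%.1f%%", 100 * x$accuracy),
      "; AUC =", round(x$auc, 3),
      "; permutation p =", signif(x$p, 3), "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mc_loso <- function(x, ...) {
  tibble(accuracy = x$accuracy, auc = x$auc, p.value = x$p,
         n_perm = x$n_perm, c_value = x$c_value)
}
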