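test_that("parameter RDM is a Euclidean distance in the moral-cost plane", {
  ## hand-checked distances without standardisation
  rdm <- parameter_rdm(c(5, 8, 5), c(1, 1, 5), standardize = FALSE)
  expect_equal(rdm[1, 2], 3)
  expect_equal(rdm[1, 3], 4)
  expect_equal(rdm[2, 3], sqrt(9 + 16))
  expect_true(isSymmetric(unclass(rdm)))
  expect_equal(diag(rdm), rep(0, 3))
  ## identical subjects sit at distance zero
  rdm2 <- parameter_rdm(c(2, 2, 7), c(3, 3, 1), standardize = FALSE)
  expect_equal(rdm2[1, 2], 0)
  ## standardisation equalises the two parameters' leverage
  th <- c(0, 10, 20); om <- c(0, 0.5, 1)
  raw <- parameter_rdm(th, om, standardize = FALSE)
  std <- parameter_rdm(th, om, standardize = TRUE)
  expect_gt(raw[1, 3] / raw[1, 2], 1.9)   # theta dominates raw distances
  expect_equal(std[1, 3], 2 * std[1, 2], tolerance = 1e-10)
  expect_error(parameter_rdm(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(parameter_rdm(1:2, 1:2), "3 subjects")
})

test_that("neural RDM is the pairwise correlation distance", {
  x <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(-1, -2, -3, -4),
             c(4, 3, 2, 1))
  rdm <- neural_rdm(as_pattern_matrix(x))
  expect_equal(rdm[1, 2], 0)            # identical up to scale
  expect_equal(rdm[1, 3], 2)            # sign-flipped
  expect_equal(rdm[1, 4], 2)            # exactly anti-ordered
  expect_true(all(rdm >= 0 & rdm <= 2))
  ## near-orthogonal random vectors sit near distance 1
  set.seed(13)
  big <- matrix(rnorm(6 * 4000), 6, 4000)
  rdm_big <- neural_rdm(as_pattern_matrix(big))
  off <- rdm_big[lower.tri(rdm_big)]
  expect_true(all(abs(off - 1) < 0.12))
  expect_error(neural_rdm(as_pattern_matrix(rbind(c(1, 1, 1), c(1, 2, 3),
                                                  c(2, 1, 0)))),
               "constant voxel")
})

test_that("IS-RSA is rank-based with valid Mantel permutation inference", {
  set.seed(19)
  th <- rnorm(15); om <- rnorm(15)
  a <- parameter_rdm(th, om)
  expect_equal(isrsa(a, a, n_perm = 100, seed = 1)$rho, 1)
  ## invariance to monotone transforms of either RDM's entries
  b <- unclass(a)^3
  diag(b) <- 0
  res1 <- isrsa(a, moralcost:::new_rdm(b, attr(a, "subject_ids"), "m"),
                n_perm = 200, seed = 2)
  expect_equal(res1$rho, 1)
  ## permutation p-values live in [1/(B+1), 1]
  noise <- parameter_rdm(rnorm(15), rnorm(15))
  res2 <- suppressWarnings(isrsa(a, noise, n_perm = 99, seed = 3))
  expect_gte(res2$p, 1 / 100)
  expect_lte(res2$p, 1)
  ## the observed statistic is reproducible and order mismatch is caught
  expect_equal(suppressWarnings(isrsa(a, noise, n_perm = 50, seed = 4))$rho,
               res2$rho)
  bad <- parameter_rdm(rnorm(15), rnorm(15), subject_ids = 15:1)
  expect_error(isrsa(a, bad, n_perm = 500), "ordering")
  expect_warning(isrsa(a, noise, n_perm = 20, seed = 1), "100 permutations")
})

test_that("IS-RSA p-values are calibrated under independence", {
  ## with no behaviour-brain coupling the permutation p is uniform;
  ## check via the empirical CDF over many replicates
  set.seed(23)
  ps <- vapply(1:200, function(i) {
    a <- parameter_rdm(rnorm(10), rnorm(10))
    b <- parameter_rdm(rnorm(10), rnorm(10))
    suppressWarnings(isrsa(a, b, n_perm = 39, seed = i))$p
  }, numeric(1))
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lt(mean(ps <= 0.05), 0.12)
  expect_gt(mean(ps <= 0.5), 0.38)
})

test_that("pattern similarity detects shared signal and stays null without", {
  set.seed(29)
  S <- 20; V <- 80
  base <- matrix(rnorm(S * V), S, V)
  with_shared <- as_pattern_matrix(base + matrix(rnorm(S * V, 0, 1), S, V))
  copy <- as_pattern_matrix(base + matrix(rnorm(S * V, 0, 1), S, V))
  res <- pattern_similarity(with_shared, copy, n_perm = 500, seed = 1)
  expect_gt(res$mean_z, 0.2)
  expect_lt(res$p, 0.05)
  expect_equal(res$z, atanh(res$r))
  ## independent patterns: mean z near zero, p typically large
  indep <- as_pattern_matrix(matrix(rnorm(S * V), S, V))
  res0 <- pattern_similarity(as_pattern_matrix(base), indep,
                             n_perm = 500, seed = 2)
  expect_lt(abs(res0$mean_z), 0.1)
  ## two-voxel boundary runs but warns
  expect_warning(
    pattern_similarity(as_pattern_matrix(matrix(rnorm(12), 6, 2)),
                       as_pattern_matrix(matrix(rnorm(12), 6, 2)),
                       n_perm = 50, seed = 3),
    "3 voxels")
})

test_that("LOSO decoding separates planted conditions and respects symmetry", {
  set.seed(31)
  S <- 14; V <- 40
  u <- rnorm(V)
  a <- as_pattern_matrix(matrix(rnorm(S * V, 0, 0.5), S, V) +
                           matrix(u, S, V, byrow = TRUE))
  b <- as_pattern_matrix(matrix(rnorm(S * V, 0, 0.5), S, V) -
                           matrix(u, S, V, byrow = TRUE))
  res <- loso_decode(a, b, n_perm = 99, seed = 1)
  expect_equal(res$accuracy, 1)
  expect_gt(res$auc, 0.95)
  expect_lte(res$p, 0.05)
  ## label symmetry: swapping the matrices leaves forced-choice accuracy
  swapped <- loso_decode(b, a, n_perm = 10, seed = 1)
  expect_equal(swapped$accuracy, res$accuracy)
  ## scale invariance of the forced choice
  res_scaled <- loso_decode(as_pattern_matrix(unclass(a) * 7),
                            as_pattern_matrix(unclass(b) * 7),
                            n_perm = 10, seed = 1)
  expect_equal(res_scaled$accuracy, res$accuracy)
  expect_error(loso_decode(a, b, c_value = 0), "positive")
})

test_that("LOSO decoding is at chance without a condition effect", {
  set.seed(37)
  accs <- vapply(1:12, function(i) {
    a <- as_pattern_matrix(matrix(rnorm(10 * 25), 10, 25))
    b <- as_pattern_matrix(matrix(rnorm(10 * 25), 10, 25))
    loso_decode(a, b, n_perm = 10, seed = i)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("Mantel statistic agrees with an independent implementation", {
  set.seed(43)
  a <- parameter_rdm(rnorm(12), rnorm(12))
  b <- parameter_rdm(rnorm(12) + 0.5 * scale(attr(a, "subject_ids")),
                     rnorm(12))
  ours <- isrsa(a, b, n_perm = 500, seed = 9)
  ref <- vegan::mantel(stats::as.dist(unclass(a)),
                       stats::as.dist(unclass(b)),
                       method = "spearman", permutations = 500)
  expect_equal(ours$rho, unname(ref$statistic), tolerance = 1e-10)
})
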