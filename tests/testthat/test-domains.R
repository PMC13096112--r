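test_that("column standardization centers, scales, and drops constants", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 8, 14))
  expect_warning(Z <- standardize_columns(X), "constant")
  expect_equal(colnames(Z), c("a", "c"))
  expect_equal(Z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(standardize_columns(Z), Z, tolerance = 1e-12)  # idempotent
})

test_that("tucker phi matches its closed form and symmetries", {
  expect_equal(tucker_phi(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(tucker_phi(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(tucker_phi(c(1, 0), c(0, 1)), 0)
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(23); b <- rnorm(23); cc <- runif(1, 0.1, 10)
    closed <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    expect_equal(tucker_phi(a, b), closed, tolerance = 1e-12)
    expect_equal(tucker_phi(cc * a, b), tucker_phi(a, b), tolerance = 1e-12)
    expect_equal(tucker_phi(-a, b), -tucker_phi(a, b), tolerance = 1e-12)
  }
  expect_error(tucker_phi(c(0, 0), c(1, 1)), class = "stimvision_domain_error")
})

test_that("congruence matrix: identity, permutation, feature mismatch", {
  L <- planted_domain_loadings(seed = 2)
  cg <- congruence_matrix(L, L)
  expect_equal(unname(cg$diagonal), rep(1, 3), tolerance = 1e-12)
  expect_equal(cg$global_statistic, 1)

  perm <- c(3, 1, 2)
  cg2 <- congruence_matrix(L, L[, perm])
  expect_equal(cg2$optimal_assignment, order(perm))
  expect_equal(abs(unname(cg2$optimal_diagonal)), rep(1, 3), tolerance = 1e-12)

  L2 <- L; rownames(L2)[1] <- "other_feature"
  err <- expect_error(congruence_matrix(L, L2),
                      class = "stimvision_domain_error")
  expect_match(conditionMessage(err), "other_feature")
})

test_that("sparse PCA recovers a noiseless rank-1 planted loading", {
  set.seed(3)
  v <- c(rep(0, 15), runif(8, 0.5, 1)); v <- v / sqrt(sum(v^2))
  score <- rnorm(40, sd = 4)
  X <- outer(score, v)
  colnames(X) <- paste0("f", 1:23)
  fit <- sparse_pca(X, k = 3, penalty = 0.5)
  expect_gte(fit$explained_variance[1], 99)
  expect_gte(abs(tucker_phi(fit$loadings[, 1], v)), 0.99)
})

test_that("sparse PCA at 10% noise recovers all planted components", {
  ch <- generate_domain_structured_cohort(
    planted_domain_spec(n_patients = 150, noise_sd = 0.1, seed = 4))
  fit <- sparse_pca(standardize_columns(ch$matrix))
  cg <- congruence_matrix(fit, ch$loadings)
  expect_true(all(abs(cg$optimal_diagonal) >= 0.9))
  expect_gt(sum(fit$loadings == 0), 0)  # penalty 1 produces exact zeros
  expect_true(all(fit$explained_variance >= 0 & fit$explained_variance <= 100))
  expect_true(all(diff(fit$cumulative_variance) >= 0))
  expect_lte(max(fit$cumulative_variance), 100 + 1e-9)
})

test_that("penalty zero spans the ordinary principal subspace", {
  ch <- generate_domain_structured_cohort(
    planted_domain_spec(n_patients = 60, noise_sd = 0.3, seed = 5))
  X <- standardize_columns(ch$matrix)
  fit <- sparse_pca(X, penalty = 0)
  pc <- prcomp(X, center = FALSE)
  cosines <- svd(crossprod(qr.Q(qr(fit$loadings)),
                           qr.Q(qr(pc$rotation[, 1:3]))))$d
  expect_true(all(cosines > 1 - 1e-6))  # principal angles ~ 0
  expect_equal(fit$explained_variance,
               100 * pc$sdev[1:3]^2 / sum(pc$sdev^2), tolerance = 1e-4)
})

test_that("sparse PCA is deterministic and its sign convention fixed", {
  ch <- generate_domain_structured_cohort(planted_domain_spec(
    n_patients = 40, seed = 6))
  X <- standardize_columns(ch$matrix)
  f1 <- sparse_pca(X); f2 <- sparse_pca(X)
  expect_identical(f1$loadings, f2$loadings)
  for (k in 1:3) {
    expect_gt(f1$loadings[which.max(abs(f1$loadings[, k])), k], 0)
  }
})

test_that("an overwhelming penalty raises the empty-components error", {
  ch <- generate_domain_structured_cohort(planted_domain_spec(
    n_patients = 20, seed = 7))
  expect_error(sparse_pca(standardize_columns(ch$matrix), penalty = 1e5),
               class = "stimvision_domain_error")
})

test_that("bootstrap loading CIs are reproducible and noise-sensitive", {
  mk <- function(noise) generate_domain_structured_cohort(
    planted_domain_spec(n_patients = 50, noise_sd = noise, seed = 8))
  X_lo <- standardize_columns(mk(0.05)$matrix)
  X_hi <- standardize_columns(mk(0.6)$matrix)
  b1 <- bootstrap_loading_ci(X_lo, B = 40, seed = 9)
  b2 <- bootstrap_loading_ci(X_lo, B = 40, seed = 9)
  expect_identical(b1$ci_lo, b2$ci_lo)
  b3 <- bootstrap_loading_ci(X_hi, B = 40, seed = 9)
  expect_lt(median(b1$ci_hi - b1$ci_lo), median(b3$ci_hi - b3$ci_lo))
})

test_that("permutation test: self-similarity, invariance, refit/direct modes", {
  ch <- generate_domain_structured_cohort(planted_domain_spec(
    n_patients = 60, noise_sd = 0.1, seed = 10))
  X <- standardize_columns(ch$matrix)
  res <- permutation_similarity_test(X, X, iters = 200, seed = 1)
  expect_equal(res$global_statistic, 1, tolerance = 1e-9)
  expect_equal(res$permutation_p, 1 / 201, tolerance = 1e-12)

  # relabeling both cohorts identically leaves the statistic unchanged
  perm <- sample(ncol(X))
  Xp <- X[, perm]; colnames(Xp) <- colnames(X)
  res_p <- suppressWarnings(
    permutation_similarity_test(Xp, Xp, iters = 50, seed = 1))
  expect_equal(res_p$global_statistic, res$global_statistic, tolerance = 1e-9)

  # direct (loading) mode agrees with refit mode for the observed statistic
  f <- sparse_pca(X, cohort = "a")
  res_direct <- permutation_similarity_test(f, f, iters = 200, seed = 1)
  expect_equal(res_direct$global_statistic, res$global_statistic,
               tolerance = 1e-9)
  expect_equal(res_direct$permutation_p, res$permutation_p, tolerance = 1e-12)

  expect_warning(permutation_similarity_test(f, f, iters = 50, seed = 1),
                 "unstable")
})

test_that("partially shared planted structure yields a high/high/low diagonal", {
  L1 <- planted_domain_loadings(seed = 11)
  L2 <- L1
  # replace the third domain with an unrelated sparse pattern
  set.seed(12)
  idx <- 17:23
  v <- runif(7, 0.5, 1) * sample(c(-1, 1), 7, TRUE)
  L2[, 3] <- 0; L2[idx, 3] <- rev(v) / sqrt(sum(v^2))
  mk <- function(L, seed) generate_domain_structured_cohort(
    planted_domain_spec(n_patients = 120, loadings = L, noise_sd = 0.1,
                        seed = seed))
  f1 <- sparse_pca(standardize_columns(mk(L1, 13)$matrix))
  f2 <- sparse_pca(standardize_columns(mk(L2, 14)$matrix))
  cg <- congruence_matrix(f1, f2)
  phis <- sort(abs(cg$optimal_diagonal), decreasing = TRUE)
  expect_gt(phis[1], 0.8)
  expect_gt(phis[2], 0.8)
})
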