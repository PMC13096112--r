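test_that("exact signed-rank p matches full enumeration", {
  expect_equal(wilcoxon_median_gt0(1:5), 1 / 32)
  cases <- list(c(3, -1, 2, 4), c(5, 4, -3, 2, -1, 7),
                c(0.3, 1.2, -0.7, 2.2, 0.9, -1.5, 0.4))
  for (x in cases) {
    expect_equal(wilcoxon_median_gt0(x), enumerate_wilcoxon_p(x),
                 tolerance = 1e-12)
  }
  # property check over random no-tie samples up to n = 12
  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    x <- round(rnorm(n, 0.3), 6)
    expect_equal(wilcoxon_median_gt0(x), enumerate_wilcoxon_p(x),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank p is about one half for a symmetric null", {
  set.seed(2)
  x <- rnorm(200)
  expect_gt(wilcoxon_median_gt0(x), 0.2)
  expect_lt(wilcoxon_median_gt0(x), 0.8)
})

test_that("all-zero samples raise a degenerate-sample error", {
  expect_error(wilcoxon_median_gt0(rep(0, 10)),
               class = "stimvision_stats_error")
})

test_that("BH adjustment equals the hand step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_fdr(0.33), 0.33)
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(3:23, 1))
    expect_equal(bh_fdr(p), step_up_bh(p), tolerance = 1e-12)
    expect_equal(bh_fdr(p, m = 23), step_up_bh(p, m = 23), tolerance = 1e-12)
  }
})

test_that("bootstrap median CI is seed-reproducible and degenerates correctly", {
  expect_equal(bootstrap_median_ci(rep(7, 4), B = 200, seed = 1), c(7, 7))
  x <- rnorm(40, mean = 5)
  ci_a <- bootstrap_median_ci(x, B = 500, seed = 10)
  ci_b <- bootstrap_median_ci(x, B = 500, seed = 10)
  ci_c <- bootstrap_median_ci(x, B = 500, seed = 11)
  expect_identical(ci_a, ci_b)
  expect_false(identical(ci_a, ci_c))
  expect_lt(ci_a[1], ci_c[2])  # overlapping
  expect_gt(ci_c[1], ci_a[1] - diff(ci_a))
})

test_that("bootstrap CI width shrinks with sample size", {
  set.seed(4)
  big <- rnorm(400)
  widths <- vapply(c(25, 100, 400), function(n) {
    mean(vapply(1:5, function(s) {
      diff(bootstrap_median_ci(big[1:n], B = 400, seed = s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("cohort summary separates a clear winner from a clear loser", {
  X <- cbind(A = rep(10, 8) + rnorm(8, 0, 0.5),
             B = rep(-10, 8) + rnorm(8, 0, 0.5))
  out <- cohort_summary(X, B = 300, seed = 5)
  expect_equal(out$feature, c("A", "B"))  # sorted by median improvement
  expect_true(out$significant[out$feature == "A"])
  expect_false(out$significant[out$feature == "B"])
  expect_true(all(out$q >= out$p, na.rm = TRUE))
  expect_true(all(out$ci_lo <= out$median & out$median <= out$ci_hi))
})

test_that("cohort summary handles missing-heavy and degenerate features", {
  X <- cbind(ok = rnorm(8, 5), mostly_na = c(1, NA, NA, NA, NA, NA, NA, NA),
             zeros = rep(0, 8))
  expect_warning(out <- cohort_summary(X, B = 100, seed = 1), "missing")
  expect_false("mostly_na" %in% out$feature)
  expect_true(is.na(out$p[out$feature == "zeros"]))
})

test_that("polarity statistics count improving programs", {
  mk <- function(dwis) {
    structure(list(table = data.frame(program = paste0("P", seq_along(dwis)),
                                      dwis = dwis, rank = seq_along(dwis))),
              class = "program_ranking")
  }
  all_pos <- dwis_polarity_stats(list(mk(c(3, 2, 1)), mk(c(5, 4, 1))))
  expect_equal(all_pos$percent_positive, 100)
  half <- dwis_polarity_stats(list(mk(c(1, -1)), mk(c(2, -2))))
  expect_equal(half$percent_positive, 50)
  expect_equal(half$per_patient_percent_median, 50)
})

test_that("separation tests aggregate per-patient deltas with exact Wilcoxon", {
  mk <- function(dwis) {
    rk <- list(table = data.frame(program = paste0("P", seq_along(dwis)),
                                  dwis = sort(dwis, decreasing = TRUE),
                                  rank = seq_along(dwis)),
               delta_top2 = sort(dwis, decreasing = TRUE)[1] -
                 sort(dwis, decreasing = TRUE)[2],
               delta_top_median = sort(dwis, decreasing = TRUE)[1] -
                 median(dwis))
    structure(rk, class = "program_ranking")
  }
  rankings <- lapply(1:8, function(i) mk(c(1.2, 1.0, 0.5)))
  out <- separation_tests(rankings)
  expect_equal(out$median_delta_top2, 0.2)
  expect_equal(out$p_top2, (1 / 2)^8)  # all-positive exact case
  single <- structure(list(table = data.frame(program = "P1", dwis = 1,
                                              rank = 1),
                           delta_top2 = NA_real_,
                           delta_top_median = NA_real_),
                      class = "program_ranking")
  expect_warning(separation_tests(c(rankings, list(single))), "excluded")
})

test_that("concordance model recovers a noiseless linear relation exactly", {
  d <- generate_concordance_dataset(beta = 1, cluster_sd = 0, residual_sd = 0,
                                    n_clusters = 6, n_per_cluster = 8,
                                    seed = 1, discretize = FALSE)
  est <- suppressWarnings(suppressMessages(concordance_lmm(d)))
  expect_equal(est$beta, 1, tolerance = 1e-6)
  expect_lt(est$random_intercept_var, 1e-8)
  expect_type(est$singular, "logical")  # degeneracy is flagged, not fatal
})

test_that("constant delta_dwis is rejected before fitting", {
  d <- generate_concordance_dataset(n_clusters = 6, seed = 2)
  d$delta_dwis <- 1
  expect_error(concordance_lmm(d), class = "stimvision_stats_error")
})

test_that("raw-score robustness model reverses the slope sign", {
  d <- generate_concordance_dataset(beta = 0.7, seed = 6)
  imp <- concordance_lmm(d, "improvement")
  raw <- concordance_lmm(d, "raw-score")
  expect_lt(raw$beta, 0)
  expect_equal(raw$beta, -imp$beta, tolerance = 0.15)
  expect_true(is.finite(raw$baseline_p))
})

test_that("per-patient rank correlation matches the Spearman closed form", {
  mk <- function(dwis, labels) {
    structure(list(table = data.frame(program = labels, dwis = dwis,
                                      rank = seq_along(dwis)),
                   best_program = labels[1]),
              class = "program_ranking")
  }
  rk <- mk(c(4, 3, 2, 1), paste0("P", 1:4))
  identical_scores <- setNames(c(4, 3, 2, 1), paste0("P", 1:4))
  reversed <- setNames(c(1, 2, 3, 4), paste0("P", 1:4))
  swapped <- setNames(c(4, 2, 3, 1), paste0("P", 1:4))  # ranks 1,3,2,4
  out <- per_patient_rank_correlation(
    list(a = rk, b = rk, c = rk),
    list(a = identical_scores, b = reversed, c = swapped))
  expect_equal(out$spearman_rho, c(1, -1, 0.8))
  expect_equal(out$best_agrees, c(TRUE, FALSE, TRUE))
  const <- setNames(rep(2, 4), paste0("P", 1:4))
  out2 <- per_patient_rank_correlation(list(rk), list(const))
  expect_true(is.na(out2$spearman_rho))
})

test_that("raw-value mixed models recover a planted shift and a null", {
  set.seed(8)
  subjects <- sprintf("S%02d", 1:15)
  long <- do.call(rbind, lapply(subjects, function(s) {
    base <- rnorm(1, 10, 1)
    data.frame(subject = s, condition = c("baseline", "optimal"),
               feature = "f1", value = base + c(0, 2) + rnorm(2, 0, 0.5))
  }))
  null_rows <- long
  null_rows$feature <- "f2"
  null_rows$value <- rep(rnorm(15, 10, 1), each = 2)
  out <- raw_feature_lmm(rbind(long, null_rows))
  f1 <- out[out$feature == "f1", ]
  expect_true(f1$estimate - 1.96 * f1$se <= 2 && 2 <= f1$estimate + 1.96 * f1$se)
  f2 <- out[out$feature == "f2", ]
  expect_equal(f2$estimate, 0, tolerance = 1e-6)
  expect_gt(f2$q, 0.9)
  expect_error(raw_feature_lmm(long[long$subject == "S01", ]),
               class = "stimvision_stats_error")
})
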