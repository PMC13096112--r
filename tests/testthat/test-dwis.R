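test_that("improvement matrix orients percent change toward improvement", {
  m <- build_improvement_matrix(tiny_feature_table(), "OFF", tiny_catalog())
  expect_equal(m$values["PrA", "f_up"], 30)    # 10 -> 13, higher better
  expect_equal(m$values["PrA", "f_down"], 25)  # 2.0 -> 1.5, lower better
  expect_equal(m$values["PrB", "f_up"], 10)
  expect_equal(m$values["PrB", "f_down"], -10)
})

test_that("zero baselines are masked, not infinite", {
  tab <- tiny_feature_table()
  tab$f_up[tab$condition == "OFF"] <- 0
  expect_warning(m <- build_improvement_matrix(tab, "OFF", tiny_catalog()),
                 "masked")
  expect_true(all(is.na(m$values[, "f_up"])))
  expect_true("f_up" %in% m$excluded_features)
  expect_false(any(is.infinite(m$values)))
})

test_that("a missing baseline row is an error", {
  tab <- tiny_feature_table()[-1, ]
  expect_error(build_improvement_matrix(tab, "OFF", tiny_catalog()),
               class = "stimvision_dwis_error")
})

test_that("responsiveness is the sample SD across programs", {
  m <- structure(list(values = cbind(a = c(10, 20, 30), b = c(5, 5, 5),
                                     c = c(10, NA, 30)),
                      program_labels = c("P1", "P2", "P3"),
                      feature_names = c("a", "b", "c"),
                      baseline_condition = "OFF",
                      excluded_features = character(0)),
                 class = "improvement_matrix")
  r <- responsiveness(m)
  expect_equal(r[["a"]], 10)
  expect_equal(r[["b"]], 0)
  expect_equal(r[["c"]], sd(c(10, 30)))
  expect_equal(unname(r), vapply(c("a", "b", "c"),
                                 function(j) brute_force_sd(m$values[, j]),
                                 numeric(1)), ignore_attr = TRUE)
  one_row <- m; one_row$values <- m$values[1, , drop = FALSE]
  expect_error(responsiveness(one_row), class = "stimvision_dwis_error")
})

test_that("dynamic weights normalize, shrink, and fall back as specified", {
  w0 <- dynamic_weights(c(a = 10, b = 30), lambda = 0)
  expect_equal(unname(w0$weights), c(0.25, 0.75))
  w1 <- dynamic_weights(c(a = 10, b = 30), lambda = 0.1)
  expect_equal(unname(w1$weights), c(0.275, 0.725))
  wu <- dynamic_weights(c(a = 10, b = 30), lambda = 1)
  expect_equal(unname(wu$weights), c(0.5, 0.5))
  # non-responsive features get weight zero, sum stays 1
  wz <- dynamic_weights(c(a = 10, b = 0, c = 30), lambda = 0.2)
  expect_equal(wz$weights[["b"]], 0)
  expect_equal(sum(wz$weights), 1, tolerance = 1e-12)
  expect_warning(wf <- dynamic_weights(c(a = 0, b = 0)), "uniform")
  expect_equal(unname(wf$weights), c(0.5, 0.5))
  expect_error(dynamic_weights(c(1, 2), lambda = 1.5),
               class = "stimvision_dwis_error")
})

test_that("weights sum to one across the whole lambda range", {
  set.seed(42)
  for (i in 1:20) {
    r <- abs(rnorm(23)) * rbinom(23, 1, 0.8)
    if (all(r == 0)) r[1] <- 1
    for (lam in runif(5)) {
      expect_equal(sum(dynamic_weights(r, lam)$weights), 1, tolerance = 1e-12)
    }
  }
})

test_that("DWIS is the weighted oriented improvement; baseline anchors at 0", {
  m <- structure(list(values = cbind(a = c(40), b = c(-20)),
                      program_labels = "P1", feature_names = c("a", "b"),
                      baseline_condition = "OFF",
                      excluded_features = character(0)),
                 class = "improvement_matrix")
  rk <- compute_dwis(m, c(a = 0.25, b = 0.75))
  expect_equal(rk$table$dwis, -5)

  # the baseline itself scores exactly zero
  tab <- tiny_feature_table()
  tab <- rbind(tab, within(tab[1, ], condition <- "OFF2"))
  tab$f_up[4] <- tab$f_up[1]; tab$f_down[4] <- tab$f_down[1]
  m2 <- build_improvement_matrix(tab, "OFF", tiny_catalog())
  r <- responsiveness(m2)
  rk2 <- compute_dwis(m2, dynamic_weights(r, 0.1))
  expect_equal(rk2$table$dwis[rk2$table$program == "OFF2"], 0)
})

test_that("ranking reports separations and breaks ties chronologically", {
  m <- structure(list(values = cbind(f = c(20, 15, 3)),
                      program_labels = c("P1", "P2", "P3"),
                      feature_names = "f", baseline_condition = "OFF",
                      excluded_features = character(0)),
                 class = "improvement_matrix")
  rk <- compute_dwis(m, c(f = 1))
  expect_equal(rk$table$rank, 1:3)
  expect_equal(rk$delta_top2, 5)
  expect_equal(rk$delta_top_median, 5)
  expect_equal(rk$best_program, "P1")

  tie <- m; tie$values <- cbind(f = c(10, 10, 1))
  rk_tie <- compute_dwis(tie, c(f = 1))
  expect_equal(rk_tie$best_program, "P1")
  expect_setequal(rk_tie$ties, c("P1", "P2"))
})

test_that("DWIS and ranking match the brute-force oracle on random instances", {
  set.seed(123)
  for (i in 1:50) {
    vals <- matrix(rnorm(5 * 5, sd = 30), 5, 5,
                   dimnames = list(paste0("P", 1:5), paste0("f", 1:5)))
    vals[sample(25, 2)] <- NA  # masked cells
    m <- structure(list(values = vals, program_labels = rownames(vals),
                        feature_names = colnames(vals),
                        baseline_condition = "OFF",
                        excluded_features = character(0)),
                   class = "improvement_matrix")
    r <- responsiveness(m)
    lam <- runif(1)
    rk <- compute_dwis(m, suppressWarnings(dynamic_weights(r, lam)))
    oracle <- brute_force_dwis(vals, r, lam)
    got <- setNames(rk$table$dwis, rk$table$program)[rownames(vals)]
    expect_equal(unname(got), oracle, tolerance = 1e-10)
    expect_equal(rk$best_program, rownames(vals)[which.max(oracle)])
  }
})

test_that("percent change absorbs raw feature rescaling end to end", {
  tab <- tiny_feature_table()
  tab2 <- tab
  tab2$f_up <- tab2$f_up * 7.3
  m1 <- build_improvement_matrix(tab, "OFF", tiny_catalog())
  m2 <- build_improvement_matrix(tab2, "OFF", tiny_catalog())
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
})

test_that("lambda sensitivity flags dominance-stable and crossing cases", {
  # one dominant program: stable for any weights
  m <- structure(list(values = cbind(a = c(50, 10), b = c(40, 5)),
                      program_labels = c("P1", "P2"),
                      feature_names = c("a", "b"),
                      baseline_condition = "OFF",
                      excluded_features = character(0)),
                 class = "improvement_matrix")
  sens <- lambda_sensitivity(m)
  expect_true(sens$stable)
  expect_equal(nrow(sens$per_lambda), 10)
  expect_equal(sens$per_lambda$kendall_tau_vs_first, rep(1, 10),
               tolerance = 1e-9)

  # degenerate single-value grid
  sens1 <- lambda_sensitivity(m, lambda_grid = 0.1)
  expect_equal(nrow(sens1$per_lambda), 1)
  expect_true(sens1$stable)

  # constructed rank-1/2 crossing at lambda* = 0.3:
  # DWIS(p; lambda) = (1-lambda) * DWIS_resp(p) + lambda * DWIS_unif(p),
  # so choose scores with a0 > b0, au < bu crossing at 0.3.
  r <- c(a = 30, b = 10)  # w0 = (0.75, 0.25); uniform = (0.5, 0.5)
  # program rows (improvements) solving the crossing:
  #   A: (20, 0)   -> resp 15, unif 10
  #   B: (12, 21)  -> resp 14.25, unif 16.5
  # crossing where (1-l)*15 + l*10 = (1-l)*14.25 + l*16.5 -> l = 0.103...
  vals <- rbind(A = c(a = 20, b = 0), B = c(a = 12, b = 21))
  lam_star <- (15 - 14.25) / ((15 - 14.25) + (16.5 - 10))
  m3 <- structure(list(values = vals, program_labels = c("A", "B"),
                       feature_names = c("a", "b"),
                       baseline_condition = "OFF",
                       excluded_features = character(0)),
                  class = "improvement_matrix")
  # override responsiveness-driven weights by scoring at fixed lambdas
  below <- compute_dwis(m3, dynamic_weights(r, lam_star - 0.05))
  above <- compute_dwis(m3, dynamic_weights(r, lam_star + 0.05))
  expect_equal(below$best_program, "A")
  expect_equal(above$best_program, "B")
})

test_that("clinical view is a pure reordering by responsiveness and DWIS", {
  sess <- generate_patient_session(session_spec(n_programs = 4, seed = 9))
  feats <- batch_extract(sess$traces)$features
  sc <- score_session(feats)
  cv_ <- clinical_view_reorder(sc$matrix, sc$ranking, sc$weights)
  expect_setequal(as.numeric(cv_$values), as.numeric(sc$matrix$values))
  expect_equal(cv_$row_order, sc$ranking$table$program)
  r <- sc$weights$responsiveness[sc$matrix$feature_names]
  expect_equal(cv_$col_order,
               sc$matrix$feature_names[order(-r, seq_along(r))])
})
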