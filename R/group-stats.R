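#' One-sample Wilcoxon signed-rank test for a positive median
#'
#' One-sided test of whether the median of `values` exceeds zero. Zeros are
#' discarded (classical signed-rank convention). With no ties among the
#' absolute values and at most `exact_n_max` usable observations the p-value
#' comes from the exact null distribution of the signed-rank statistic
#' (tied samples are enumerated exactly over midranks up to n = 15);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param values Numeric vector.
#' @param exact_n_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return One-sided p-value for median > 0.
#' @export
#' @examples
#' wilcoxon_median_gt0(c(1, 2, 3, 4, 5))  # 1/32
wilcoxon_median_gt0 <- function(values, exact_n_max = 25L) {
  x <- values[is.finite(values)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) {
    stop_stimvision("degenerate sample: all values are zero or missing",
                    class = "stimvision_stats_error")
  }
  a <- abs(x)
  rk <- rank(a)
  w_plus <- sum(rk[x > 0])
  ties <- anyDuplicated(a) > 0L
  if (!ties && n <= exact_n_max) {
    # P(W+ >= w) under the exact null; psignrank is the CDF of W+.
    p <- psignrank(w_plus - 1, n, lower.tail = FALSE)
  } else if (ties && n <= 15L) {
    # Midranks break psignrank's lattice; enumerate the 2^n sign patterns.
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    p <- mean(as.numeric(signs %*% rk) >= w_plus)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(a)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    p <- pnorm((w_plus - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  unname(p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param m Number of tests the correction spans (default
#'   `length(pvalues)`; the feature battery uses 23).
#' @return Adjusted q-values, monotone in p.
#' @export
bh_fdr <- function(pvalues, m = length(pvalues)) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE), m >= length(pvalues[!is.na(pvalues)]))
  p.adjust(pvalues, method = "BH", n = m)
}

#' Percentile bootstrap confidence interval for the median
#'
#' @param values Numeric sample (n >= 3).
#' @param B Number of bootstrap resamples (default 10000).
#' @param seed RNG seed; required for reproducibility (default 0).
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_median_ci <- function(values, B = 10000L, seed = 0L, conf = 0.95) {
  x <- values[is.finite(values)]
  if (length(x) < 3L) {
    stop_stimvision("bootstrap CI needs at least 3 values",
                    class = "stimvision_stats_error")
  }
  meds <- with_seed(seed, {
    idx <- matrix(sample.int(length(x), length(x) * B, replace = TRUE), nrow = B)
    apply(idx, 1, function(i) median(x[i]))
  })
  alpha <- (1 - conf) / 2
  unname(quantile(meds, c(alpha, 1 - alpha), type = 7))
}

#' Cohort summary of optimal-program improvements
#'
#' Aggregates within-patient optimal-vs-baseline oriented percent changes
#' across the cohort. Per feature: median percent change, IQR, percentile
#' bootstrap 95% CI of the median, one-sided Wilcoxon p (median > 0), and
#' BH-FDR q across the feature battery. The output is sorted by descending
#' median improvement. Features missing in more than half the patients are
#' excluded with a warning.
#'
#' @param optimal_improvements Patients x features numeric matrix (oriented
#'   percent change at each patient's optimal program).
#' @param B,seed Bootstrap settings, see [bootstrap_median_ci()].
#' @param fdr_alpha Significance threshold on q (default 0.05).
#' @return Data frame: `feature`, `n`, `median`, `iqr_lo`, `iqr_hi`,
#'   `ci_lo`, `ci_hi`, `p`, `q`, `significant`.
#' @export
cohort_summary <- function(optimal_improvements, B = 10000L, seed = 0L,
                           fdr_alpha = 0.05) {
  X <- as.matrix(optimal_improvements)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (nrow(X) < 5L) {
    stop_stimvision("cohort summary needs at least 5 patients",
                    class = "stimvision_stats_error")
  }
  frac_missing <- colMeans(is.na(X))
  drop <- frac_missing > 0.5
  if (any(drop)) {
    warning("excluding feature(s) with >50% missing: ",
            paste(colnames(X)[drop], collapse = ", "), call. = FALSE)
    X <- X[, !drop, drop = FALSE]
  }
  rows <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]; x <- x[is.finite(x)]
    qs <- quantile(x, c(0.25, 0.75), names = FALSE)
    ci <- bootstrap_median_ci(x, B = B, seed = seed + j)
    p <- tryCatch(wilcoxon_median_gt0(x),
                  stimvision_stats_error = function(e) NA_real_)
    data.frame(feature = colnames(X)[j], n = length(x), median = median(x),
               iqr_lo = qs[1], iqr_hi = qs[2], ci_lo = ci[1], ci_hi = ci[2],
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p, m = nrow(out))
  out$significant <- !is.na(out$q) & out$q < fdr_alpha
  out <- out[order(-out$median), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Polarity of DWIS values across all tested programs
#'
#' Counts, over every patient-program combination in the supplied rankings,
#' how many programs scored above the stimulation-off baseline (DWIS > 0),
#' and summarizes the per-patient percentage of beneficial programs.
#'
#' @param rankings List of `program_ranking` objects, one per patient-hand.
#' @return List: `n_positive`, `n_total`, `percent_positive`,
#'   `per_patient_percent_median`, `per_patient_percent_iqr` (`c(lo, hi)`).
#' @export
dwis_polarity_stats <- function(rankings) {
  stopifnot(length(rankings) >= 1L)
  per_patient <- vapply(rankings, function(rk) {
    mean(rk$table$dwis > 0) * 100
  }, numeric(1))
  all_dwis <- unlist(lapply(rankings, function(rk) rk$table$dwis))
  list(n_positive = sum(all_dwis > 0),
       n_total = length(all_dwis),
       percent_positive = 100 * mean(all_dwis > 0),
       per_patient_percent_median = median(per_patient),
       per_patient_percent_iqr = unname(quantile(per_patient, c(0.25, 0.75))))
}

#' Separation between top-ranked and competitor programs
#'
#' Aggregates per-patient `delta_top2` (best minus second-best DWIS) and
#' `delta_top_median` (best minus median program DWIS) across the cohort and
#' tests each against zero with the one-sample Wilcoxon signed-rank test.
#' Patients with a single program contribute no separation and are excluded
#' with a warning.
#'
#' @param rankings List of `program_ranking` objects.
#' @return List: `median_delta_top2`, `p_top2`, `median_delta_top_median`,
#'   `p_top_median`, `n`.
#' @export
separation_tests <- function(rankings) {
  usable <- vapply(rankings, function(rk) nrow(rk$table) >= 2L, logical(1))
  if (any(!usable)) {
    warning(sum(!usable), " patient(s) with a single program excluded",
            call. = FALSE)
  }
  rankings <- rankings[usable]
  if (length(rankings) < 5L) {
    stop_stimvision("separation tests need at least 5 patients with >= 2 ",
                    "programs", class = "stimvision_stats_error")
  }
  d2 <- vapply(rankings, function(rk) rk$delta_top2, numeric(1))
  dm <- vapply(rankings, function(rk) rk$delta_top_median, numeric(1))
  list(median_delta_top2 = median(d2),
       p_top2 = wilcoxon_median_gt0(d2),
       median_delta_top_median = median(dm),
       p_top_median = wilcoxon_median_gt0(dm),
       n = length(rankings))
}

#' Mixed-effects concordance between DWIS and clinician ratings
#'
#' Fits, by REML, either the improvement model
#' `updrs_improvement ~ delta_dwis + (1 | patient_hand)` or the raw-score
#' robustness model
#' `program_score ~ delta_dwis + baseline_score + (1 | patient_hand)`.
#' Inference on the fixed effect uses the Wald z statistic.
#'
#' @param records Data frame with columns `patient_hand`, `program`,
#'   `delta_dwis`, `updrs_baseline`, `updrs_program` (item scores 0-4).
#' @param model `"improvement"` or `"raw-score"`.
#' @return Object of class `lmm_estimate`: list with `beta`, `se`, `z`, `p`,
#'   `ci95`, `random_intercept_var`, `singular`, `model`, `n`, `n_clusters`,
#'   and for the raw-score model also `baseline_beta`, `baseline_p`.
#' @export
concordance_lmm <- function(records, model = c("improvement", "raw-score")) {
  model <- match.arg(model)
  need <- c("patient_hand", "program", "delta_dwis",
            "updrs_baseline", "updrs_program")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop_stimvision("concordance records lack column(s): ",
                    paste(missing, collapse = ", "),
                    class = "stimvision_stats_error")
  }
  if (length(unique(records$patient_hand)) < 5L) {
    stop_stimvision("concordance model needs at least 5 patient-hand clusters",
                    class = "stimvision_stats_error")
  }
  if (sd(records$delta_dwis) == 0) {
    stop_stimvision("no fixed-effect variance: delta_dwis is constant",
                    class = "stimvision_stats_error")
  }
  records$updrs_improvement <- records$updrs_baseline - records$updrs_program
  fit <- if (model == "improvement") {
    lme4::lmer(updrs_improvement ~ delta_dwis + (1 | patient_hand),
               data = records, REML = TRUE)
  } else {
    lme4::lmer(updrs_program ~ delta_dwis + updrs_baseline + (1 | patient_hand),
               data = records, REML = TRUE)
  }
  fe <- lme4::fixef(fit)
  se_all <- sqrt(diag(as.matrix(vcov(fit))))
  beta <- unname(fe["delta_dwis"])
  se <- unname(se_all["delta_dwis"])
  z <- beta / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(beta = beta, se = se, z = z,
              p = 2 * pnorm(-abs(z)),
              ci95 = c(beta - 1.96 * se, beta + 1.96 * se),
              random_intercept_var = vc$vcov[vc$grp == "patient_hand"][1],
              singular = lme4::isSingular(fit),
              model = model, n = nrow(records),
              n_clusters = length(unique(records$patient_hand)))
  if (model == "raw-score") {
    zb <- unname(fe["updrs_baseline"] / se_all["updrs_baseline"])
    out$baseline_beta <- unname(fe["updrs_baseline"])
    out$baseline_p <- 2 * pnorm(-abs(zb))
  }
  structure(out, class = "lmm_estimate")
}

#' @export
print.lmm_estimate <- function(x, ...) {
  cat(sprintf(
    "<lmm_estimate> %s model: beta = %.3f, SE = %.3f, z = %.2f, p = %.3g\n",
    x$model, x$beta, x$se, x$z, x$p))
  cat(sprintf("  95%% CI [%.3f, %.3f]; random-intercept var = %.4f%s\n",
              x$ci95[1], x$ci95[2], x$random_intercept_var,
              if (x$singular) " (singular fit)" else ""))
  invisible(x)
}

#' Per-patient agreement between kinematic and clinical rankings
#'
#' @param rankings List of `program_ranking` objects (one per patient-hand).
#' @param clinical_scores List (same order/names) of named numeric vectors:
#'   clinician improvement per program (higher = better), names matching the
#'   ranking's program labels.
#' @return Data frame: `patient`, `n_programs`, `spearman_rho` (`NA` when
#'   the clinical scores are constant), `best_agrees` (DWIS-optimal program
#'   is in the set of clinically optimal programs).
#' @export
per_patient_rank_correlation <- function(rankings, clinical_scores) {
  stopifnot(length(rankings) == length(clinical_scores))
  ids <- names(rankings)
  if (is.null(ids)) ids <- paste0("patient_", seq_along(rankings))
  rows <- lapply(seq_along(rankings), function(i) {
    rk <- rankings[[i]]
    cs <- clinical_scores[[i]]
    progs <- rk$table$program
    if (length(progs) < 3L) {
      stop_stimvision("rank correlation needs >= 3 programs per patient",
                      class = "stimvision_stats_error")
    }
    if (!all(progs %in% names(cs))) {
      stop_stimvision("clinical scores missing program(s): ",
                      paste(setdiff(progs, names(cs)), collapse = ", "),
                      class = "stimvision_stats_error")
    }
    cs <- cs[progs]
    rho <- if (sd(cs) == 0) NA_real_ else
      cor(rk$table$dwis, cs, method = "spearman")
    best_clin <- names(cs)[cs == max(cs)]
    data.frame(patient = ids[i], n_programs = length(progs),
               spearman_rho = rho,
               best_agrees = rk$best_program %in% best_clin,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-feature condition effect on raw values (robustness check)
#'
#' For every feature, fits `value ~ condition + (1 | subject)` by REML on
#' raw (un-normalized) values across the baseline and optimal conditions,
#' then applies BH-FDR across features. This guards the percent-change
#' analysis against normalization artifacts.
#'
#' @param feature_table_long Data frame: `subject`, `condition` (two
#'   levels; the reference level is taken as baseline), `feature`, `value`.
#' @return Data frame: `feature`, `estimate`, `se`, `z`, `p`, `q`.
#' @export
raw_feature_lmm <- function(feature_table_long) {
  need <- c("subject", "condition", "feature", "value")
  stopifnot(all(need %in% names(feature_table_long)))
  if (length(unique(feature_table_long$subject)) < 2L) {
    stop_stimvision("raw-value mixed model needs >= 2 subjects",
                    class = "stimvision_stats_error")
  }
  feats <- unique(feature_table_long$feature)
  rows <- lapply(feats, function(f) {
    d <- feature_table_long[feature_table_long$feature == f, , drop = FALSE]
    d$condition <- factor(d$condition)
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(value ~ condition + (1 | subject), data = d, REML = TRUE)))
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))[2]
    z <- unname(fe[2] / se)
    data.frame(feature = f, estimate = unname(fe[2]), se = unname(se), z = z,
               p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p, m = nrow(out))
  out
}
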