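#' Run configuration
#'
#' Bundles the knobs of a full analysis run. Defaults follow the main
#' analysis: shrinkage `lambda = 0.1` with the sensitivity grid 0-0.45 in
#' steps of 0.05, 10000 bootstrap resamples, 10000 permutation iterations,
#' FDR threshold 0.05.
#'
#' @param baseline_label Condition label of the stimulation-off baseline.
#' @param lambda Shrinkage for the main analysis, in `[0, 1]`.
#' @param lambda_grid Sensitivity grid.
#' @param bootstrap_B,permutation_iters Resampling sizes (>= 1).
#' @param seed Seed for every randomized stage.
#' @param catalog_path Optional path to a catalog JSON (`NULL` = default
#'   catalog).
#' @param fdr_alpha Significance threshold on BH-FDR q, in (0, 1).
#' @return A list of class `run_config`.
#' @export
run_config <- function(baseline_label = "OFF", lambda = 0.1,
                       lambda_grid = seq(0, 0.45, by = 0.05),
                       bootstrap_B = 10000L, permutation_iters = 10000L,
                       seed = 0L, catalog_path = NULL, fdr_alpha = 0.05) {
  stopifnot(lambda >= 0, lambda <= 1, bootstrap_B >= 1,
            permutation_iters >= 1, fdr_alpha > 0, fdr_alpha < 1)
  structure(list(baseline_label = baseline_label, lambda = lambda,
                 lambda_grid = lambda_grid, bootstrap_B = bootstrap_B,
                 permutation_iters = permutation_iters, seed = seed,
                 catalog_path = catalog_path, fdr_alpha = fdr_alpha),
            class = "run_config")
}

#' Read / write a feature table
#'
#' The on-disk format is UTF-8 comma-separated CSV with a header; key
#' columns `patient_id`, `hand`, `condition` are required, every other
#' column is a numeric feature. Missing cells round-trip as empty fields.
#'
#' @param path File path.
#' @param table Feature table data frame.
#' @return `read_feature_table` returns the data frame.
#' @export
read_feature_table <- function(path) {
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) {
                   stop_stimvision("cannot read feature table ", path, ": ",
                                   conditionMessage(e),
                                   class = "stimvision_io_error")
                 })
  if (!ncol(df)) {
    stop_stimvision("feature table ", path, " has no header",
                    class = "stimvision_io_error")
  }
  for (key in c("patient_id", "hand", "condition")) {
    if (!key %in% names(df)) {
      stop_stimvision("feature table ", path, " is missing key column '",
                      key, "'", class = "stimvision_io_error")
    }
  }
  feat_cols <- setdiff(names(df), c("patient_id", "hand", "condition"))
  for (col in feat_cols) {
    if (!is.numeric(df[[col]])) {
      bad <- which(!is.na(df[[col]]) &
                     is.na(suppressWarnings(as.numeric(df[[col]]))))
      stop_stimvision("non-numeric value in feature column '", col,
                      "', row(s) ", paste(head(bad, 5), collapse = ", "),
                      class = "stimvision_io_error")
    }
  }
  df
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Score one patient-hand session end to end
#'
#' Convenience wrapper chaining [build_improvement_matrix()],
#' [responsiveness()], [dynamic_weights()], [compute_dwis()] and
#' [lambda_sensitivity()] for a single patient-hand's feature table.
#'
#' @param feature_table Rows of one patient-hand (baseline + programs).
#' @param config A [run_config()].
#' @param catalog Feature catalog.
#' @return List: `matrix`, `weights`, `ranking`, `sensitivity`.
#' @export
score_session <- function(feature_table, config = run_config(),
                          catalog = default_catalog()) {
  m <- build_improvement_matrix(feature_table, config$baseline_label, catalog)
  r <- responsiveness(m)
  w <- suppressWarnings(dynamic_weights(r, config$lambda))
  rk <- compute_dwis(m, w)
  sens <- lambda_sensitivity(m, config$lambda_grid)
  list(matrix = m, weights = w, ranking = rk, sensitivity = sens)
}

#' Assemble the per-patient decision report
#'
#' Packages the engineering view (chronological program rows), the clinical
#' view (rows by descending DWIS, columns by descending responsiveness),
#' and the DWIS waterfall (programs sorted best to worst, anchored at 0 by
#' the baseline) into one plain-data object; no value is mutated, only
#' reordered.
#'
#' @param matrix An `improvement_matrix`.
#' @param ranking A `program_ranking`.
#' @param weights A `weight_vector`.
#' @param stability Optional result of [lambda_sensitivity()].
#' @param therapy_comparison Optional named numeric of DWIS per therapy
#'   state (e.g. MedOff/DBSOff ... MedOn/DBSOn) for the comparison table.
#' @return A list of class `patient_report` with `engineering_view`,
#'   `clinical_view`, `waterfall`, `best_program`, `stable_across_lambda`,
#'   `therapy_comparison`.
#' @export
build_patient_report <- function(matrix, ranking, weights, stability = NULL,
                                 therapy_comparison = NULL) {
  cv_ <- clinical_view_reorder(matrix, ranking, weights)
  waterfall <- rbind(
    data.frame(program = ranking$table$program,
               delta_dwis = ranking$table$dwis,
               rank = ranking$table$rank, stringsAsFactors = FALSE),
    data.frame(program = matrix$baseline_condition, delta_dwis = 0,
               rank = NA_integer_, stringsAsFactors = FALSE))
  structure(list(
    engineering_view = matrix$values,
    clinical_view = cv_$values,
    clinical_row_order = cv_$row_order,
    clinical_col_order = cv_$col_order,
    waterfall = waterfall,
    best_program = ranking$best_program,
    stable_across_lambda = if (is.null(stability)) NA else stability$stable,
    therapy_comparison = if (is.null(therapy_comparison)) NULL else
      data.frame(condition = names(therapy_comparison),
                 dwis = as.numeric(therapy_comparison),
                 stringsAsFactors = FALSE)),
    class = "patient_report")
}

#' Write a ranking (and report) to JSON / CSV artifacts
#'
#' @param session Result of [score_session()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_session_outputs <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rk <- session$ranking
  ranking_json <- file.path(dir, "ranking.json")
  jsonlite::write_json(
    list(best_program = rk$best_program,
         delta_top2 = rk$delta_top2,
         delta_top_median = rk$delta_top_median,
         stable_across_lambda = session$sensitivity$stable,
         lambda = session$weights$lambda,
         ranking = rk$table),
    ranking_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  eng_csv <- file.path(dir, "improvement_engineering.csv")
  write.csv(session$matrix$values, eng_csv, na = "")
  report <- build_patient_report(session$matrix, rk, session$weights,
                                 session$sensitivity)
  clin_csv <- file.path(dir, "improvement_clinical.csv")
  write.csv(report$clinical_view, clin_csv, na = "")
  wf_csv <- file.path(dir, "waterfall.csv")
  write.csv(report$waterfall, wf_csv, row.names = FALSE, na = "")
  invisible(c(ranking_json, eng_csv, clin_csv, wf_csv))
}

#' Recompute the cohort-level report from deposited matrices
#'
#' Given externally supplied per-patient feature tables or the cohort's
#' optimal-improvement matrix (plus, optionally, a comparison cohort's
#' improvement or loading matrix), recomputes every headline cohort
#' quantity: positive-DWIS fraction, per-patient positive percentage,
#' median separation of the top two programs, shrinkage-stability count,
#' per-feature medians with Wilcoxon/BH-FDR inference, the sparse-domain
#' loadings with explained variance, and the cross-cohort congruence
#' diagonal with its permutation p-value.
#'
#' @param feature_tables List of per-patient-hand feature tables
#'   (baseline + programs each).
#' @param comparison Optional comparison cohort: a patients x features
#'   improvement matrix or a features x 3 loading matrix.
#' @param config A [run_config()].
#' @param catalog Feature catalog.
#' @return List with `polarity`, `separation`, `stability_count`, `n`,
#'   `group_stats`, `domains`, `congruence` (when a comparison is given).
#' @export
reproduce_cohort_report <- function(feature_tables, comparison = NULL,
                                    config = run_config(),
                                    catalog = default_catalog()) {
  sessions <- lapply(feature_tables, score_session, config = config,
                     catalog = catalog)
  rankings <- lapply(sessions, function(s) s$ranking)
  stability <- vapply(sessions, function(s) s$sensitivity$stable, logical(1))
  optimal <- t(vapply(sessions, function(s) {
    s$matrix$values[s$ranking$best_program, ]
  }, numeric(ncol(sessions[[1]]$matrix$values))))
  optimal_complete <- impute_column_median(optimal)
  out <- list(
    n = length(sessions),
    polarity = dwis_polarity_stats(rankings),
    separation = separation_tests(rankings),
    stability_count = sum(stability),
    group_stats = cohort_summary(optimal, B = config$bootstrap_B,
                                 seed = config$seed,
                                 fdr_alpha = config$fdr_alpha),
    domains = sparse_pca(standardize_columns(optimal_complete),
                         cohort = "DBS"))
  if (!is.null(comparison)) {
    out$congruence <- permutation_similarity_test(
      optimal_complete, comparison,
      iters = config$permutation_iters, seed = config$seed)
  }
  out
}

# Masked cells are rare at the cohort level; the sparse decomposition needs
# a complete matrix, so they are filled with the feature's median.
impute_column_median <- function(X) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- median(X[, j], na.rm = TRUE)
  }
  X
}
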