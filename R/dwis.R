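#' Build an oriented improvement matrix against the stimulation-off baseline
#'
#' For every DBS-on program row in the feature table, each feature's percent
#' change relative to the patient's stimulation-off baseline is computed and
#' oriented so that positive always means clinical improvement:
#' \deqn{I_{pj} = s_j \cdot 100 \cdot \frac{x_j(p) - x_j(\mathrm{off})}{|x_j(\mathrm{off})|}}
#' where \eqn{s_j} is +1 for higher-is-better and -1 for lower-is-better
#' features. Cells whose baseline magnitude is below `1e-9` times the
#' feature's column scale, or whose value is missing, are masked (set `NA`)
#' rather than allowed to blow up; a feature whose cells are all masked is
#' flagged excluded.
#'
#' @param feature_table Data frame with a `condition` column and one numeric
#'   column per catalog feature (one patient-hand's worth of rows).
#' @param baseline_condition Label of the stimulation-off baseline row.
#' @param catalog Feature catalog supplying orientations.
#' @return Object of class `improvement_matrix`: a list with `values`
#'   (programs x features numeric matrix, `NA` = masked), `program_labels`,
#'   `feature_names`, `baseline_condition`, `excluded_features`.
#' @export
build_improvement_matrix <- function(feature_table,
                                     baseline_condition = "OFF",
                                     catalog = default_catalog()) {
  validate_catalog(catalog, NA)
  stopifnot(is.data.frame(feature_table), "condition" %in% names(feature_table))
  feats <- catalog$name
  missing_cols <- setdiff(feats, names(feature_table))
  if (length(missing_cols)) {
    stop_stimvision("feature table lacks catalog column(s): ",
                    paste(missing_cols, collapse = ", "),
                    class = "stimvision_dwis_error")
  }
  is_base <- feature_table$condition == baseline_condition
  if (sum(is_base) != 1L) {
    stop_stimvision("expected exactly one baseline row with condition '",
                    baseline_condition, "', found ", sum(is_base),
                    class = "stimvision_dwis_error")
  }
  progs <- feature_table[!is_base, , drop = FALSE]
  if (!nrow(progs)) {
    stop_stimvision("no program rows besides the baseline",
                    class = "stimvision_dwis_error")
  }
  base <- as.numeric(feature_table[is_base, feats])
  X <- as.matrix(progs[, feats, drop = FALSE])
  signs <- orientation_signs(catalog)[feats]

  vals <- matrix(NA_real_, nrow(X), length(feats),
                 dimnames = list(progs$condition, feats))
  n_masked_baseline <- 0L
  for (j in seq_along(feats)) {
    col_scale <- max(abs(c(base[j], X[, j])), na.rm = TRUE)
    if (!is.finite(col_scale)) col_scale <- 0
    if (!is.finite(base[j]) || abs(base[j]) < 1e-9 * max(col_scale, 1e-300)) {
      n_masked_baseline <- n_masked_baseline + 1L
      next  # whole column masked: no usable denominator
    }
    vals[, j] <- signs[j] * 100 * (X[, j] - base[j]) / abs(base[j])
  }
  if (n_masked_baseline > 0L) {
    warning(n_masked_baseline, " feature(s) masked: baseline at or near zero",
            call. = FALSE)
  }
  excluded <- feats[colSums(!is.na(vals)) == 0L]
  structure(list(values = vals,
                 program_labels = rownames(vals),
                 feature_names = feats,
                 baseline_condition = baseline_condition,
                 excluded_features = excluded),
            class = "improvement_matrix")
}

#' @export
print.improvement_matrix <- function(x, ...) {
  cat(sprintf("<improvement_matrix> %d programs x %d features (baseline %s)\n",
              nrow(x$values), ncol(x$values), x$baseline_condition))
  if (length(x$excluded_features))
    cat("excluded:", paste(x$excluded_features, collapse = ", "), "\n")
  invisible(x)
}

as_improvement_matrix <- function(values, baseline_condition = "OFF") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  structure(list(values = values, program_labels = rownames(values),
                 feature_names = colnames(values),
                 baseline_condition = baseline_condition,
                 excluded_features = colnames(values)[colSums(!is.na(values)) == 0]),
            class = "improvement_matrix")
}

#' Per-feature responsiveness
#'
#' Responsiveness of a feature is the sample standard deviation (n-1
#' denominator) of its oriented improvement values across all DBS-on
#' programs: features that do not discriminate between candidate programs
#' within this session get low responsiveness and, downstream, low weight.
#' Masked cells are excluded; a feature with fewer than two usable cells
#' gets responsiveness 0 (it cannot discriminate).
#'
#' @param matrix An `improvement_matrix`.
#' @return Named numeric vector `r` (percent units), one entry per feature.
#' @export
responsiveness <- function(matrix) {
  stopifnot(inherits(matrix, "improvement_matrix"))
  if (nrow(matrix$values) < 2L) {
    stop_stimvision("responsiveness undefined: need at least 2 programs",
                    class = "stimvision_dwis_error")
  }
  apply(matrix$values, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2L) 0 else sd(col)
  })
}

#' Responsiveness-derived dynamic weights with shrinkage
#'
#' Base weights normalize responsiveness to sum to one,
#' \eqn{w_j^0 = r_j / \sum_k r_k}. The shrinkage form blends them with
#' uniform weights over the responsive set \eqn{R = \{j : r_j > 0\}}:
#' \deqn{w_j(\lambda) = (1-\lambda)\, w_j^0 + \lambda / |R| \quad (j \in R),
#'   \qquad w_j(\lambda) = 0 \ (j \notin R).}
#' If every feature has zero responsiveness the weights fall back to uniform
#' over all features, with a warning.
#'
#' @param r Responsiveness vector (named, non-negative).
#' @param lambda Shrinkage in `[0, 1]`; 0 = pure responsiveness weighting,
#'   1 = uniform over responsive features. Default 0.1.
#' @return Object of class `weight_vector`: list with `weights` (named, sums
#'   to 1), `responsiveness`, `lambda`, `responsive_set`, `uniform_fallback`.
#' @export
dynamic_weights <- function(r, lambda = 0.1) {
  stopifnot(is.numeric(r), all(is.finite(r)))
  if (any(r < 0)) {
    stop_stimvision("responsiveness must be non-negative",
                    class = "stimvision_dwis_error")
  }
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0 || lambda > 1) {
    stop_stimvision("lambda must be a single value in [0, 1]",
                    class = "stimvision_dwis_error")
  }
  if (is.null(names(r))) names(r) <- paste0("f", seq_along(r))
  responsive <- names(r)[r > 0]
  fallback <- length(responsive) == 0L
  if (fallback) {
    warning("all features have zero responsiveness; ",
            "falling back to uniform weights", call. = FALSE)
    w <- setNames(rep(1 / length(r), length(r)), names(r))
    responsive <- names(r)
  } else {
    w0 <- r / sum(r)
    w <- setNames(numeric(length(r)), names(r))
    w[responsive] <- (1 - lambda) * w0[responsive] +
      lambda / length(responsive)
  }
  structure(list(weights = w, responsiveness = r, lambda = lambda,
                 responsive_set = responsive, uniform_fallback = fallback),
            class = "weight_vector")
}

#' Dynamically Weighted Improvement Score and program ranking
#'
#' The DWIS of a program is the weighted sum of its oriented percent
#' improvements, \eqn{\mathrm{DWIS}(p) = \sum_j w_j I_{pj}} over unmasked
#' cells, with the weights renormalized over that program's unmasked
#' features (so masked cells never silently deflate a score). The baseline
#' condition has DWIS 0 by construction, so DWIS and \eqn{\Delta}DWIS
#' coincide. Programs are ranked by descending DWIS; ties break toward the
#' earlier (chronologically first) program and are reported.
#'
#' @param matrix An `improvement_matrix`.
#' @param weights A `weight_vector` (or bare named numeric weights).
#' @return Object of class `program_ranking`: list with `table` (data frame:
#'   `program`, `dwis`, `rank` in ranked order), `best_program`,
#'   `delta_top2`, `delta_top_median`, `ties`, `baseline_condition`.
#' @export
compute_dwis <- function(matrix, weights) {
  stopifnot(inherits(matrix, "improvement_matrix"))
  if (inherits(weights, "weight_vector")) w <- weights$weights else w <- weights
  stopifnot(is.numeric(w))
  if (!nrow(matrix$values)) {
    stop_stimvision("empty improvement matrix",
                    class = "stimvision_dwis_error")
  }
  if (!setequal(names(w), matrix$feature_names)) {
    stop_stimvision("weights do not match the matrix's features",
                    class = "stimvision_dwis_error")
  }
  w <- w[matrix$feature_names]
  dwis <- apply(matrix$values, 1, function(row) {
    ok <- !is.na(row) & w > 0
    if (!any(ok)) return(0)
    sum(w[ok] * row[ok]) / sum(w[ok])
  })

  ord <- order(-dwis, seq_along(dwis))  # ties -> earlier program
  ranked <- data.frame(program = matrix$program_labels[ord],
                       dwis = dwis[ord],
                       rank = seq_along(ord),
                       stringsAsFactors = FALSE)
  dup <- duplicated(signif(ranked$dwis, 12)) |
    duplicated(signif(ranked$dwis, 12), fromLast = TRUE)
  n <- nrow(ranked)
  structure(list(
    table = ranked,
    best_program = ranked$program[1],
    delta_top2 = if (n >= 2) ranked$dwis[1] - ranked$dwis[2] else NA_real_,
    delta_top_median = if (n >= 2) ranked$dwis[1] - median(ranked$dwis) else NA_real_,
    ties = ranked$program[dup],
    baseline_condition = matrix$baseline_condition),
    class = "program_ranking")
}

#' @export
print.program_ranking <- function(x, ...) {
  cat(sprintf("<program_ranking> best: %s (delta_top2 = %.4g)\n",
              x$best_program, x$delta_top2))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Ranking stability across the shrinkage grid
#'
#' Re-scores all programs at each shrinkage value and reports whether the
#' top-ranked program is identical across the whole grid, plus the Kendall
#' tau between the full ranking at `lambda = grid[1]` and every other grid
#' point. Because DWIS is affine in lambda, rank changes can only occur at
#' crossing points of two score lines; the grid scan surfaces them.
#'
#' @param matrix An `improvement_matrix`.
#' @param lambda_grid Shrinkage values (default `seq(0, 0.45, by = 0.05)`).
#' @return List with `per_lambda` (data frame: `lambda`, `best_program`,
#'   `kendall_tau_vs_first`), `stable` (logical), `best_programs` (unique
#'   labels seen), `rankings` (list of `program_ranking`).
#' @export
lambda_sensitivity <- function(matrix, lambda_grid = seq(0, 0.45, by = 0.05)) {
  stopifnot(length(lambda_grid) >= 1L)
  r <- responsiveness(matrix)
  rankings <- lapply(lambda_grid, function(l) {
    compute_dwis(matrix, suppressWarnings(dynamic_weights(r, l)))
  })
  rank_vec <- function(rk) {
    setNames(rk$table$rank, rk$table$program)[matrix$program_labels]
  }
  ref <- rank_vec(rankings[[1]])
  per_lambda <- data.frame(
    lambda = lambda_grid,
    best_program = vapply(rankings, function(rk) rk$best_program, character(1)),
    kendall_tau_vs_first = vapply(rankings, function(rk) {
      cor(ref, rank_vec(rk), method = "kendall")
    }, numeric(1)))
  list(per_lambda = per_lambda,
       stable = length(unique(per_lambda$best_program)) == 1L,
       best_programs = unique(per_lambda$best_program),
       rankings = rankings)
}

#' Reorder an improvement matrix for bedside reading
#'
#' The "clinical view" sorts columns by descending responsiveness and rows
#' by descending DWIS, lifting the most effective programs and the patient's
#' most discriminative features to the top-left. Values are permuted only,
#' never changed.
#'
#' @param matrix An `improvement_matrix`.
#' @param ranking A `program_ranking` for the same matrix.
#' @param weights A `weight_vector` (supplies the responsiveness order).
#' @return List with `values` (reordered matrix), `row_order`, `col_order`
#'   (permutations of the original labels).
#' @export
clinical_view_reorder <- function(matrix, ranking, weights) {
  stopifnot(inherits(matrix, "improvement_matrix"),
            inherits(ranking, "program_ranking"))
  r <- if (inherits(weights, "weight_vector")) weights$responsiveness else weights
  r <- r[matrix$feature_names]
  col_order <- order(-r, seq_along(r))
  row_order <- match(ranking$table$program, matrix$program_labels)
  list(values = matrix$values[row_order, col_order, drop = FALSE],
       row_order = matrix$program_labels[row_order],
       col_order = matrix$feature_names[col_order])
}
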