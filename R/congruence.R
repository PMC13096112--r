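#' Tucker's congruence coefficient
#'
#' \deqn{\Phi(a, b) = \frac{\sum_i a_i b_i}{\sqrt{\sum_i a_i^2 \sum_i b_i^2}}}
#' A cosine-style similarity between two loading vectors, in `[-1, 1]`;
#' invariant to positive rescaling of either argument and antisymmetric
#' under sign flips.
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return Phi in `[-1, 1]`.
#' @export
#' @examples
#' tucker_phi(c(1, 0), c(0, 1))  # 0
tucker_phi <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sum(a^2); nb <- sum(b^2)
  if (na == 0 || nb == 0) {
    stop_stimvision("tucker_phi is undefined for a zero vector",
                    class = "stimvision_domain_error")
  }
  sum(a * b) / sqrt(na * nb)
}

tucker_phi_safe <- function(a, b) {
  if (sum(a^2) == 0 || sum(b^2) == 0) return(NA_real_)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

phi_matrix_of <- function(L1, L2) {
  k1 <- ncol(L1); k2 <- ncol(L2)
  out <- matrix(NA_real_, k1, k2,
                dimnames = list(colnames(L1), colnames(L2)))
  for (i in seq_len(k1)) for (j in seq_len(k2)) {
    out[i, j] <- tucker_phi_safe(L1[, i], L2[, j])
  }
  out
}

#' Cross-cohort congruence matrix
#'
#' Computes the full k x k matrix of Tucker congruence coefficients between
#' two cohorts' loading matrices over a shared, identically ordered feature
#' set. The diagonal pairs components by index after each cohort's own
#' explained-variance ordering — the reading in which PC1 is matched with
#' PC1, and so on. An optimal-assignment pairing (maximizing the summed
#' |Phi| over all component permutations) is also reported; it is the
#' pairing used when aligning bootstrap replicates.
#'
#' @param L1,L2 `loading_matrix` objects (or bare features x k matrices with
#'   rownames) for the two cohorts.
#' @return Object of class `congruence_result`: list with `phi_matrix`,
#'   `diagonal` (signed Phi of index-matched pairs), `global_statistic`
#'   (mean |Phi| over the matched diagonal), `optimal_assignment`
#'   (permutation of L2 components), `optimal_diagonal`.
#' @export
congruence_matrix <- function(L1, L2) {
  M1 <- if (inherits(L1, "loading_matrix")) L1$loadings else as.matrix(L1)
  M2 <- if (inherits(L2, "loading_matrix")) L2$loadings else as.matrix(L2)
  if (!is.null(rownames(M1)) && !is.null(rownames(M2)) &&
      !identical(rownames(M1), rownames(M2))) {
    if (setequal(rownames(M1), rownames(M2))) {
      M2 <- M2[rownames(M1), , drop = FALSE]
    } else {
      diffs <- union(setdiff(rownames(M1), rownames(M2)),
                     setdiff(rownames(M2), rownames(M1)))
      stop_stimvision("feature sets differ between cohorts: ",
                      paste(diffs, collapse = ", "),
                      class = "stimvision_domain_error")
    }
  }
  stopifnot(nrow(M1) == nrow(M2), ncol(M1) == ncol(M2))
  k <- ncol(M1)
  phi <- phi_matrix_of(M1, M2)
  diagonal <- diag(phi)
  perms <- all_permutations(k)
  scores <- vapply(perms, function(pm) sum(abs(phi[cbind(seq_len(k), pm)])),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  structure(list(phi_matrix = phi,
                 diagonal = diagonal,
                 global_statistic = mean(abs(diagonal)),
                 optimal_assignment = best,
                 optimal_diagonal = phi[cbind(seq_len(k), best)]),
            class = "congruence_result")
}

#' @export
print.congruence_result <- function(x, ...) {
  cat("<congruence_result>\n")
  print(round(x$phi_matrix, 3))
  cat(sprintf("matched diagonal: %s | mean |phi| = %.3f\n",
              paste(sprintf("%.3f", x$diagonal), collapse = " / "),
              x$global_statistic))
  if (!is.null(x$permutation_p))
    cat(sprintf("permutation p = %.4g (%d iterations)\n",
                x$permutation_p, x$n_permutations))
  invisible(x)
}

#' Permutation test for global cross-cohort structural similarity
#'
#' Observed statistic: mean |Phi| over the index-matched diagonal of the
#' congruence matrix. The null relabels the features of the second cohort
#' at random: when improvement matrices are supplied, the feature columns of
#' cohort 2 are permuted and the sparse decomposition refit; when loading
#' matrices are supplied directly, the rows of cohort 2's loadings are
#' permuted (equivalent for a permutation-equivariant fit). The p-value is
#' `(1 + #(null >= observed)) / (1 + iters)`.
#'
#' @param cohort1,cohort2 Either patients x features improvement matrices
#'   (refit mode) or `loading_matrix` objects / features x k loading
#'   matrices (direct mode). Mixed input is allowed.
#' @param iters Number of permutations (default 10000).
#' @param seed RNG seed (default 0).
#' @param k,penalty,standardize Sparse-PCA settings used in refit mode.
#' @return `congruence_result` with `permutation_p`, `n_permutations` and
#'   `null_statistics` added.
#' @export
permutation_similarity_test <- function(cohort1, cohort2, iters = 10000L,
                                        seed = 0L, k = 3L, penalty = 1.0,
                                        standardize = TRUE) {
  if (iters < 100L) {
    warning("fewer than 100 permutations gives an unstable p-value",
            call. = FALSE)
  }
  is_data <- function(x) {
    !inherits(x, "loading_matrix") && is.matrix(x) && ncol(x) > k
  }
  fit_one <- function(X, label) {
    Xs <- if (standardize) standardize_columns(X) else as.matrix(X)
    sparse_pca(Xs, k = k, penalty = penalty, cohort = label)
  }
  L1 <- if (is_data(cohort1)) fit_one(cohort1, "cohort1") else cohort1
  refit2 <- is_data(cohort2)
  L2 <- if (refit2) fit_one(cohort2, "cohort2") else cohort2
  obs <- congruence_matrix(L1, L2)

  M1 <- if (inherits(L1, "loading_matrix")) L1$loadings else as.matrix(L1)
  M2 <- if (inherits(L2, "loading_matrix")) L2$loadings else as.matrix(L2)
  p_feat <- nrow(M1)

  null_stats <- with_seed(seed, vapply(seq_len(iters), function(i) {
    perm <- sample.int(p_feat)
    if (refit2) {
      X2p <- as.matrix(cohort2)[, perm, drop = FALSE]
      colnames(X2p) <- colnames(as.matrix(cohort2))
      fit <- tryCatch(fit_one(X2p, "perm"),
                      stimvision_domain_error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      M2p <- fit$loadings
      rownames(M2p) <- rownames(M2)
    } else {
      M2p <- M2[perm, , drop = FALSE]
      rownames(M2p) <- rownames(M2)
    }
    mean(abs(diag(phi_matrix_of(M1, M2p))))
  }, numeric(1)))
  null_stats <- null_stats[!is.na(null_stats)]
  obs$permutation_p <- (1 + sum(null_stats >= obs$global_statistic)) /
    (1 + length(null_stats))
  obs$n_permutations <- length(null_stats)
  obs$null_statistics <- null_stats
  obs
}
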