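#' Column standardization for improvement matrices
#'
#' Centers each feature column to mean 0 and scales to sample SD 1 before
#' sparse decomposition, since oriented percent changes live on wildly
#' different scales across features. Constant columns carry no structure and
#' are dropped with a warning.
#'
#' @param matrix Numeric matrix (patients x features).
#' @return Standardized matrix, possibly with fewer columns.
#' @export
standardize_columns <- function(matrix) {
  X <- as.matrix(matrix)
  stopifnot(nrow(X) >= 2L)
  sds <- apply(X, 2, sd)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant column(s): ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
}

#' Sparse principal component analysis of an improvement matrix
#'
#' Fits the l1-penalized dictionary-learning formulation
#' \deqn{\min_{U, V} \tfrac12 \|X - U V^\top\|_F^2 + \alpha \|V\|_1
#'   \quad \text{s.t.} \quad \|u_k\|_2 \le 1}
#' by alternating minimization: a coordinate-descent lasso step for the
#' loadings \eqn{V} (features x components, the sparse object) and a
#' norm-constrained least-squares step for the scores \eqn{U}. The solver is
#' initialized from the singular value decomposition of `X`, which makes the
#' fit deterministic; at `penalty = 0` the solution spans the ordinary
#' top-`k` principal subspace.
#'
#' Explained variance is computed on sequentially orthogonalized projections
#' (QR of \eqn{XV}): sparse components are generally correlated, and naive
#' per-component variances would double-count. Components are ordered by
#' this adjusted explained variance; each loading column's sign is fixed so
#' its largest-magnitude entry is positive.
#'
#' @param matrix Patients x features numeric matrix (standardize first via
#'   [standardize_columns()] if features are on different scales).
#' @param k Number of components (default 3, fixed a priori).
#' @param penalty l1 penalty strength alpha (default 1).
#' @param seed RNG seed recorded for provenance; the deterministic solver
#'   does not consume randomness (default 0).
#' @param max_iter,tol Alternation control.
#' @param cohort Label stored with the result (e.g. `"DBS"`).
#' @return Object of class `loading_matrix`: list with `loadings` (features
#'   x k), `explained_variance` (%), `cumulative_variance` (%), `scores`,
#'   `penalty`, `cohort`, `converged`.
#' @export
sparse_pca <- function(matrix, k = 3L, penalty = 1.0, seed = 0L,
                       max_iter = 200L, tol = 1e-7, cohort = "cohort") {
  X <- as.matrix(matrix)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  if (n < k + 2L) {
    stop_stimvision("sparse PCA needs at least k + 2 = ", k + 2L, " rows, got ",
                    n, class = "stimvision_domain_error")
  }
  sv <- svd(X, nu = k, nv = k)
  U <- sv$u                               # n x k, orthonormal columns
  V <- sv$v %*% diag(sv$d[seq_len(k)], k) # p x k

  soft <- function(z, a) sign(z) * pmax(abs(z) - a, 0)
  obj_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # V-step: per-feature lasso on the current scores, by coordinate descent.
    G <- crossprod(U)            # k x k
    C <- crossprod(U, X)         # k x p
    for (pass in 1:3) {
      for (kk in seq_len(k)) {
        if (G[kk, kk] <= 0) next
        r <- C[kk, ] - drop(G[kk, ] %*% t(V)) + G[kk, kk] * V[, kk]
        V[, kk] <- soft(r, penalty) / G[kk, kk]
      }
    }
    # U-step: block update with unit-ball projection per column.
    for (kk in seq_len(k)) {
      vk <- V[, kk]
      nv <- sum(vk^2)
      if (nv == 0) next
      u <- (X %*% vk - U %*% crossprod(V, vk) + U[, kk] * nv) / nv
      nu_ <- sqrt(sum(u^2))
      if (nu_ > 1) u <- u / nu_
      U[, kk] <- u
    }
    obj <- 0.5 * sum((X - U %*% t(V))^2) + penalty * sum(abs(V))
    if (is.finite(obj_prev) && abs(obj_prev - obj) < tol * max(1, obj)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }

  if (all(V == 0)) {
    stop_stimvision("empty components: penalty ", penalty,
                    " drove every loading to zero",
                    class = "stimvision_domain_error")
  }

  # Order by adjusted explained variance, fix signs, name everything.
  ev <- adjusted_explained_variance(X, V)
  ord <- order(-ev)
  V <- V[, ord, drop = FALSE]
  U <- U[, ord, drop = FALSE]
  ev <- adjusted_explained_variance(X, V)  # recompute in final order
  for (kk in seq_len(k)) {
    if (all(V[, kk] == 0)) next
    top <- which.max(abs(V[, kk]))
    if (V[top, kk] < 0) {
      V[, kk] <- -V[, kk]
      U[, kk] <- -U[, kk]
    }
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(k)))
  structure(list(loadings = V,
                 explained_variance = ev,
                 cumulative_variance = cumsum(ev),
                 scores = X %*% V,
                 penalty = penalty, seed = seed, cohort = cohort,
                 converged = converged),
            class = "loading_matrix")
}

# Percent of total variance captured by each component after sequential
# Gram-Schmidt orthogonalization of the projected scores T = X V, with the
# loading columns normalized to unit length first (only the direction of a
# component should matter for the variance it explains).
adjusted_explained_variance <- function(X, V) {
  n <- nrow(X)
  totvar <- sum(apply(X, 2, var))
  nrm <- sqrt(colSums(V^2))
  V <- sweep(V, 2, ifelse(nrm > 0, nrm, 1), "/")
  Tm <- X %*% V
  k <- ncol(V)
  ev <- numeric(k)
  Q <- matrix(0, n, 0)
  for (kk in seq_len(k)) {
    t_k <- Tm[, kk]
    if (ncol(Q)) t_k <- t_k - Q %*% crossprod(Q, t_k)
    nrm <- sqrt(sum(t_k^2))
    if (nrm > 1e-12) {
      ev[kk] <- nrm^2 / (n - 1) / totvar * 100
      Q <- cbind(Q, t_k / nrm)
    }
  }
  ev
}

#' @export
print.loading_matrix <- function(x, ...) {
  cat(sprintf("<loading_matrix> %s: %d features x %d components\n",
              x$cohort, nrow(x$loadings), ncol(x$loadings)))
  cat("explained variance (%):",
      paste(sprintf("%.1f", x$explained_variance), collapse = " / "),
      sprintf(" (cumulative %.1f)\n", max(x$cumulative_variance)))
  invisible(x)
}

#' Patient-level bootstrap confidence intervals for sparse loadings
#'
#' Resamples patients with replacement, refits [sparse_pca()], aligns each
#' replicate to the point estimate (optimal component assignment by maximal
#' summed |Tucker congruence|, with sign correction), and returns percentile
#' CIs per loading. Replicates whose resample contains fewer than `k + 2`
#' distinct patients are skipped and counted.
#'
#' @param matrix Patients x features matrix (same input as [sparse_pca()]).
#' @param B Number of bootstrap resamples (default 10000).
#' @param seed RNG seed (default 0).
#' @param k,penalty Passed to [sparse_pca()].
#' @param conf Confidence level.
#' @return List: `point` (the full-data `loading_matrix`), `ci_lo`, `ci_hi`
#'   (features x k matrices), `n_used`, `n_skipped`.
#' @export
bootstrap_loading_ci <- function(matrix, B = 10000L, seed = 0L, k = 3L,
                                 penalty = 1.0, conf = 0.95) {
  X <- as.matrix(matrix)
  point <- sparse_pca(X, k = k, penalty = penalty)
  n <- nrow(X)
  reps <- with_seed(seed, {
    out <- vector("list", B)
    skipped <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) < k + 2L) {
        skipped <- skipped + 1L
        next
      }
      fit <- tryCatch(sparse_pca(X[idx, , drop = FALSE], k = k,
                                 penalty = penalty),
                      stimvision_domain_error = function(e) NULL)
      if (is.null(fit)) {
        skipped <- skipped + 1L
        next
      }
      out[[b]] <- align_loadings(fit$loadings, point$loadings)
    }
    list(loadings = out[!vapply(out, is.null, logical(1))], skipped = skipped)
  })
  arr <- simplify2array(reps$loadings)  # p x k x B_used
  alpha <- (1 - conf) / 2
  ci_lo <- apply(arr, c(1, 2), quantile, probs = alpha)
  ci_hi <- apply(arr, c(1, 2), quantile, probs = 1 - alpha)
  dimnames(ci_lo) <- dimnames(ci_hi) <- dimnames(point$loadings)
  list(point = point, ci_lo = ci_lo, ci_hi = ci_hi,
       n_used = length(reps$loadings), n_skipped = reps$skipped)
}

# Permute/flip the columns of `L` to best match `ref` (max total |phi|).
align_loadings <- function(L, ref) {
  k <- ncol(ref)
  phi <- abs(phi_matrix_of(L, ref))
  perms <- all_permutations(k)
  best <- perms[[which.max(vapply(perms, function(pm) {
    sum(phi[cbind(pm, seq_len(k))])
  }, numeric(1)))]]
  out <- L[, best, drop = FALSE]
  for (kk in seq_len(k)) {
    s <- tucker_phi_safe(out[, kk], ref[, kk])
    if (!is.na(s) && s < 0) out[, kk] <- -out[, kk]
  }
  dimnames(out) <- dimnames(ref)
  out
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (pm in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(pm, k, after = pos - 1L)
    }
  }
  out
}
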