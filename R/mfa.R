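# Multiple Factor Analysis over per-condition time-course tables: joint
# row standardization, per-table weighting by the inverse first squared
# singular value, global SVD of the concatenated reweighted tables
# (compromise and partial factor scores), and permutation-based selection of
# significant dimensions.

#' Standardize tables by CRE
#'
#' Centers and scales each CRE row over the concatenation of all tables'
#' columns (joint standardization; set `joint = FALSE` to standardize per
#' table). The sample standard deviation (divide by n - 1, the `scale()`
#' convention) is used, so each retained concatenated row has mean 0 and
#' sd 1 exactly. Constant rows are dropped with a warning and reported.
#'
#' @param x a `multi_table_set` (counts may be raw or normalized), or a named
#'   list of numeric matrices sharing identical rownames and row order.
#' @param joint logical; standardize over the joint concatenation (default)
#'   or within each table.
#' @return An object of class `standardized_set`: `tables` (list of z-score
#'   matrices), `row_mean`, `row_sd` (per retained CRE; per table when
#'   `joint = FALSE` these are matrices), `dropped` (constant CRE ids),
#'   `conditions`, `vehicle` (if known) and `time_points`.
#' @export
standardize_tables <- function(x, joint = TRUE) {
  if (inherits(x, "multi_table_set")) {
    tables <- x$counts
    vehicle <- x$vehicle
    time_points <- x$time_points
  } else if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) {
    tables <- x
    vehicle <- NULL
    time_points <- NULL
  } else {
    stopf("`x` must be a multi_table_set or a named list of matrices")
  }
  if (length(tables) < 2L) stopf("need at least 2 tables")
  rn <- rownames(tables[[1]])
  if (is.null(rn)) stopf("tables must have rownames")
  for (m in tables) {
    if (!identical(rownames(m), rn)) stopf("all tables must share identical row order")
  }
  concat <- do.call(cbind, unname(tables))
  if (joint) {
    rm_ <- rowMeans(concat)
    rsd <- sqrt(rowSums((concat - rm_)^2) / (ncol(concat) - 1))  # sample sd
    drop <- rsd <= 1e-12
    if (any(drop)) {
      warnf("dropping %d constant CRE row(s): %s", sum(drop),
            paste(utils::head(rn[drop], 5), collapse = ", "))
    }
    keep <- !drop
    ztab <- lapply(tables, function(m) {
      (m[keep, , drop = FALSE] - rm_[keep]) / rsd[keep]
    })
    row_mean <- rm_[keep]; row_sd <- rsd[keep]
  } else {
    drop <- rep(FALSE, length(rn))
    for (m in tables) {
      rsd_k <- sqrt(rowSums((m - rowMeans(m))^2) / (ncol(m) - 1))
      drop <- drop | rsd_k <= 1e-12
    }
    if (any(drop)) {
      warnf("dropping %d constant CRE row(s)", sum(drop))
    }
    keep <- !drop
    row_mean <- sapply(tables, function(m) rowMeans(m[keep, , drop = FALSE]))
    row_sd <- sapply(tables, function(m) {
      mm <- m[keep, , drop = FALSE]
      sqrt(rowSums((mm - rowMeans(mm))^2) / (ncol(mm) - 1))
    })
    ztab <- lapply(seq_along(tables), function(k) {
      (tables[[k]][keep, , drop = FALSE] - row_mean[, k]) / row_sd[, k]
    })
    names(ztab) <- names(tables)
  }
  structure(list(tables = ztab, row_mean = row_mean, row_sd = row_sd,
                 dropped = rn[drop], conditions = names(tables),
                 vehicle = vehicle, time_points = time_points, joint = joint),
            class = "standardized_set")
}

#' @export
print.standardized_set <- function(x, ...) {
  cat(sprintf("standardized_set: %d tables x %d CREs (%d dropped), %s standardization\n",
              length(x$tables), nrow(x$tables[[1]]), length(x$dropped),
              if (x$joint) "joint" else "per-table"))
  invisible(x)
}

#' First eigenvalue of a data table
#'
#' The first eigenvalue of the (uncentered) PCA of a row-standardized table,
#' i.e. the square of its first singular value.
#'
#' @param x numeric matrix.
#' @return Positive scalar.
#' @export
first_eigenvalue <- function(x) {
  svd(x, nu = 0, nv = 0)$d[1]^2
}

#' MFA table weight
#'
#' The weight applied to each table before the global analysis: the inverse
#' of the first squared singular value, so the table divided by its first
#' singular value has first eigenvalue exactly 1 and all tables enter the
#' joint analysis on an equal footing.
#'
#' @param x numeric matrix (a standardized table).
#' @return Positive scalar weight `1 / sigma1^2`.
#' @examples
#' x <- matrix(rnorm(100), 20, 5)
#' w <- table_weight(x)
#' first_eigenvalue(x * sqrt(w))  # 1
#' @export
table_weight <- function(x) {
  s1 <- svd(x, nu = 0, nv = 0)$d[1]
  if (!is.finite(s1) || s1 <= 1e-12) stopf("zero or degenerate table")
  1 / s1^2
}

#' Fit the MFA compromise
#'
#' Divides each standardized table by its first singular value, concatenates,
#' and takes the global SVD (no further centering: rows are already
#' standardized). Compromise factor scores are `U %*% diag(d)`; partial
#' factor scores of table k are `K * Z_k V_k` (K tables), so their average
#' over tables equals the compromise scores exactly (the barycenter
#' identity). Dimension signs are fixed so the largest-magnitude loading of
#' each dimension is positive.
#'
#' @param std a `standardized_set`.
#' @param n_dims number of dimensions to retain (default: full rank).
#' @return An object of class `mfa_result`: `sigma1` (per-table first
#'   singular values), `eigenvalues` (squared singular values of the
#'   concatenated reweighted matrix), `var_explained`, `compromise_scores`
#'   (CRE x dimension), `partial_scores` (per table), `loadings` (column
#'   coordinates with a `table` index), `selected_dims`, `perm_pvalues`
#'   (filled by [select_dims()] / [mfa()]), `vehicle`, `conditions`.
#' @export
mfa_fit <- function(std, n_dims = NULL) {
  stopifnot(inherits(std, "standardized_set"))
  tables <- std$tables
  K <- length(tables)
  sigma1 <- vapply(tables, function(m) svd(m, nu = 0, nv = 0)$d[1], numeric(1))
  if (any(sigma1 <= 1e-12)) stopf("zero table in standardized set")
  Zk <- lapply(seq_len(K), function(k) tables[[k]] / sigma1[k])
  Z <- do.call(cbind, Zk)
  col_table <- rep(names(tables), vapply(tables, ncol, integer(1)))
  sv <- svd(Z)
  rank_ <- sum(sv$d > max(sv$d) * 1e-12)
  ndim <- min(n_dims %||% rank_, rank_)
  if (!is.null(n_dims) && n_dims > rank_) {
    warnf("requested %d dimensions but rank is %d; truncating", n_dims, rank_)
  }
  U <- sv$u[, seq_len(ndim), drop = FALSE]
  V <- sv$v[, seq_len(ndim), drop = FALSE]
  d <- sv$d[seq_len(ndim)]
  # deterministic sign: largest-magnitude loading positive per dimension
  for (j in seq_len(ndim)) {
    i_star <- which.max(abs(V[, j]))
    if (V[i_star, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  dim_names <- paste0("Dim", seq_len(ndim))
  compromise <- U * rep(d, each = nrow(U))
  dimnames(compromise) <- list(rownames(tables[[1]]), dim_names)
  rownames(V) <- colnames(Z) %||% paste0(col_table, "_c", unlist(lapply(tables, function(m) seq_len(ncol(m)))))
  colnames(V) <- dim_names
  partial <- vector("list", K)
  names(partial) <- names(tables)
  idx_start <- cumsum(c(1L, vapply(tables, ncol, integer(1))))
  for (k in seq_len(K)) {
    rows <- seq.int(idx_start[k], idx_start[k + 1L] - 1L)
    P <- K * (Zk[[k]] %*% V[rows, , drop = FALSE])
    dimnames(P) <- dimnames(compromise)
    partial[[k]] <- P
  }
  structure(list(sigma1 = sigma1,
                 eigenvalues = sv$d[seq_len(rank_)]^2,
                 var_explained = sv$d[seq_len(rank_)]^2 / sum(sv$d^2),
                 compromise_scores = compromise,
                 partial_scores = partial,
                 loadings = V, col_table = col_table,
                 selected_dims = NULL, perm_pvalues = NULL,
                 vehicle = std$vehicle, conditions = std$conditions,
                 n_tables = K),
            class = "mfa_result")
}

#' @export
print.mfa_result <- function(x, ...) {
  cat(sprintf("mfa_result: %d tables, %d CREs, %d dimensions (top var %.1f%%)\n",
              x$n_tables, nrow(x$compromise_scores),
              ncol(x$compromise_scores), 100 * x$var_explained[1]))
  if (!is.null(x$selected_dims)) {
    cat(sprintf("  selected dimensions: %s\n",
                paste(x$selected_dims, collapse = ", ")))
  }
  invisible(x)
}

# Eigenvalues only, for permutation refits
mfa_eigenvalues <- function(tables) {
  sigma1 <- vapply(tables, function(m) svd(m, nu = 0, nv = 0)$d[1], numeric(1))
  Z <- do.call(cbind, lapply(seq_along(tables), function(k) tables[[k]] / sigma1[k]))
  svd(Z, nu = 0, nv = 0)$d^2
}

# Joint row re-standardization of a table list (used by the permutation
# refit so null matrices satisfy the same row constraints as the observed
# one; without it the selection is anticonservative)
restandardize <- function(tables) {
  concat <- do.call(cbind, unname(tables))
  rm_ <- rowMeans(concat)
  rsd <- sqrt(rowSums((concat - rm_)^2) / (ncol(concat) - 1))
  rsd[rsd <= 1e-12] <- 1
  lapply(tables, function(m) (m - rm_) / rsd)
}

#' Permutation selection of significant MFA dimensions
#'
#' For each permutation, values are shuffled independently within every
#' column of every standardized table (preserving column marginals while
#' destroying CRE-wise kinetic structure), then the full analysis is refit:
#' rows re-standardized, table weights recomputed and the global eigenvalues
#' re-extracted. The per-dimension p-value is
#' `(1 + #(permuted eigenvalue >= observed)) / (1 + n_perm)`; dimensions with
#' p < `alpha` are selected.
#'
#' @param std a `standardized_set`.
#' @param n_perm number of permutations (>= 100).
#' @param alpha selection level (default 0.01).
#' @param seed integer RNG seed.
#' @return List with `selected_dims`, `perm_pvalues`, `obs_eigenvalues`,
#'   `n_perm`, `alpha`.
#' @export
select_dims <- function(std, n_perm = 500, alpha = 0.01, seed = 1) {
  stopifnot(inherits(std, "standardized_set"))
  assert_count(n_perm, "n_perm", min = 100L)
  assert_prob(alpha, "alpha")
  obs <- mfa_eigenvalues(std$tables)
  ndim <- length(obs)
  with_seed(seed, {
    exceed <- integer(ndim)
    for (b in seq_len(n_perm)) {
      perm_tables <- restandardize(lapply(std$tables, function(m) {
        apply(m, 2, sample)
      }))
      pe <- mfa_eigenvalues(perm_tables)
      L <- min(length(pe), ndim)
      exceed[seq_len(L)] <- exceed[seq_len(L)] + (pe[seq_len(L)] >= obs[seq_len(L)])
    }
    pvals <- (1 + exceed) / (1 + n_perm)
    # dimensions beyond the numerical rank carry no variance; comparing
    # their ~0 eigenvalues against the null is meaningless
    real <- obs > max(obs) * 1e-9
    list(selected_dims = which(pvals < alpha & real),
         perm_pvalues = pvals, obs_eigenvalues = obs,
         n_perm = n_perm, alpha = alpha)
  })
}

#' Fit MFA with permutation-selected dimensions
#'
#' Convenience wrapper: [mfa_fit()] followed by [select_dims()], with the
#' selection stored in the result.
#'
#' @inheritParams mfa_fit
#' @inheritParams select_dims
#' @return An `mfa_result` with `selected_dims` and `perm_pvalues` filled.
#' @export
mfa <- function(std, n_perm = 500, alpha = 0.01, seed = 1, n_dims = NULL) {
  fit <- mfa_fit(std, n_dims = n_dims)
  sel <- select_dims(std, n_perm = n_perm, alpha = alpha, seed = seed)
  fit$selected_dims <- sel$selected_dims[sel$selected_dims <= ncol(fit$compromise_scores)]
  fit$perm_pvalues <- sel$perm_pvalues
  fit
}
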