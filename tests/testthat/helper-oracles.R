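# Independent oracles. These deliberately avoid the package's own code paths:
# brute-force scans, exact enumeration and closed forms only.

# Exact mean/sd of the hypergeometric overlap count: draw m from a universe
# of N with K marked.
hyper_moments <- function(N, K, m) {
  mu <- m * K / N
  v <- m * (K / N) * (1 - K / N) * (N - m) / (N - 1)
  list(mean = mu, sd = sqrt(v))
}

# Exact expected Jaccard of two fixed-size uniform draws (sizes a, b) from a
# universe of N, by enumeration over the hypergeometric overlap.
exact_jaccard_mean <- function(N, a, b) {
  ks <- max(0, a + b - N):min(a, b)
  p <- dhyper(ks, a, N - a, b)
  sum(p * ks / (a + b - ks))
}

# Brute-force O(n*m) interval overlap count on 0-based half-open intervals
# given as data frames with chrom/start/end.
brute_overlap_count <- function(cres, peaks) {
  hits <- 0L
  for (i in seq_len(nrow(cres))) {
    any_hit <- FALSE
    for (j in seq_len(nrow(peaks))) {
      if (cres$chrom[i] == peaks$chrom[j] &&
          cres$start[i] < peaks$end[j] && peaks$start[j] < cres$end[i]) {
        any_hit <- TRUE
        break
      }
    }
    hits <- hits + any_hit
  }
  hits
}

# Exact Shapley values of `f` (a function of a feature matrix returning one
# number per row) for a single observation `x_row`, against a background
# matrix, by enumeration over all 2^p coalitions with marginal expectations.
exact_shapley <- function(f, x_row, background) {
  p <- length(x_row)
  stopifnot(p <= 10)
  v <- function(S) {
    X <- background
    if (length(S) > 0) X[, S] <- matrix(x_row[S], nrow(X), length(S), byrow = TRUE)
    mean(f(X))
  }
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1), function(mask) which(bitwAnd(mask, 2^(0:(p - 1))) > 0))
  vals <- vapply(subsets, v, numeric(1))
  key <- vapply(subsets, function(S) paste(S, collapse = ","), character(1))
  lookup <- function(S) vals[match(paste(sort(S), collapse = ","), key)]
  for (j in seq_len(p)) {
    for (i in seq_along(subsets)) {
      S <- subsets[[i]]
      if (j %in% S) next
      wgt <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[j] <- phi[j] + wgt * (lookup(c(S, j)) - lookup(S))
    }
  }
  names(phi) <- names(x_row)
  phi
}

# Direct SVD factor scores of a concatenated weighted matrix, assembled
# without the package's mfa code (crossprod + eigen).
direct_svd_scores <- function(tables) {
  Zk <- lapply(tables, function(m) {
    s1 <- sqrt(eigen(crossprod(m), symmetric = TRUE, only.values = TRUE)$values[1])
    m / s1
  })
  Z <- do.call(cbind, Zk)
  e <- eigen(tcrossprod(Z), symmetric = TRUE)
  k <- sum(e$values > max(e$values) * 1e-10)
  scores <- e$vectors[, seq_len(k), drop = FALSE] *
    rep(sqrt(pmax(e$values[seq_len(k)], 0)), each = nrow(Z))
  list(scores = scores, eigenvalues = e$values[seq_len(k)])
}

# Rank-based AUROC (Mann-Whitney), independent of pROC.
rank_auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
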