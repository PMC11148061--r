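# Between-sample normalization by invariant-feature selection: model the
# distribution of per-feature log2 count differences from a pseudo-reference
# with a skew-normal, call features within 1 sigma of the fitted mean
# invariant, and rescale each sample on its invariant set.

# Skew-normal log-density, direct parameterization (location xi, scale omega,
# shape alpha). alpha = 0 reduces to the normal.
dsn_log <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  log(2) - log(omega) + dnorm(z, log = TRUE) + pnorm(alpha * z, log.p = TRUE)
}

sn_delta <- function(alpha) alpha / sqrt(1 + alpha^2)

# Mean and sd of the skew-normal in terms of (xi, omega, alpha)
sn_moments <- function(xi, omega, alpha) {
  d <- sn_delta(alpha)
  list(mean = xi + omega * d * sqrt(2 / pi),
       sd = omega * sqrt(1 - 2 * d^2 / pi))
}

# Method-of-moments starting values from sample skewness
sn_mom_init <- function(x) {
  m <- mean(x); s <- sd(x)
  g1 <- mean((x - m)^3) / s^3
  a23 <- abs(g1)^(2 / 3)
  d2 <- (pi / 2) * a23 / (a23 + ((4 - pi) / 2)^(2 / 3))
  d <- sqrt(min(d2, 0.995^2)) * sign(g1)
  alpha <- d / sqrt(1 - d^2)
  omega <- s / sqrt(max(1 - 2 * d^2 / pi, 1e-6))
  xi <- m - omega * d * sqrt(2 / pi)
  c(xi = xi, log_omega = log(omega), alpha = alpha)
}

#' Maximum-likelihood skew-normal fit
#'
#' Fits a skew-normal distribution (location, scale, shape) by numerical
#' maximum likelihood with method-of-moments initialization. If optimization
#' fails to improve on a plain normal fit, the normal fit (shape = 0) is
#' returned instead.
#'
#' @param x numeric vector.
#' @return List with `location`, `scale`, `shape`, the implied distribution
#'   `mean` and `sd`, the attained `loglik` and the fit `method`
#'   ("skew-normal-mle" or "normal-fallback").
#' @export
fit_skew_normal <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stopf("need at least 4 finite values to fit")
  if (sd(x) < 1e-10) {
    return(list(location = mean(x), scale = 0, shape = 0,
                mean = mean(x), sd = 0, loglik = Inf, method = "degenerate"))
  }
  nll <- function(par) {
    om <- exp(par[2])
    -sum(dsn_log(x, par[1], om, par[3]))
  }
  init <- sn_mom_init(x)
  fit <- tryCatch(
    optim(init, nll, method = "BFGS", control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {
    fit <- tryCatch(optim(init, nll, control = list(maxit = 1000)),
                    error = function(e) NULL)
  }
  norm_ll <- sum(dnorm(x, mean(x), sd(x) * sqrt((length(x) - 1) / length(x)),
                       log = TRUE))
  if (is.null(fit) || !is.finite(fit$value) || -fit$value < norm_ll - 1e-6) {
    mom <- list(mean = mean(x), sd = sd(x))
    return(list(location = mom$mean, scale = mom$sd, shape = 0,
                mean = mom$mean, sd = mom$sd, loglik = norm_ll,
                method = "normal-fallback"))
  }
  xi <- fit$par[1]; omega <- exp(fit$par[2]); alpha <- fit$par[3]
  mo <- sn_moments(xi, omega, alpha)
  list(location = unname(xi), scale = unname(omega), shape = unname(alpha),
       mean = mo$mean, sd = mo$sd, loglik = -fit$value,
       method = "skew-normal-mle")
}

#' Fit the invariant-feature normalization model
#'
#' Builds a per-feature pseudo-reference (median log2 count across samples),
#' models each sample's vector of log2 differences from the reference with a
#' skew-normal, and calls features whose difference lies within
#' `sigma` standard deviations of the fitted mean invariant. Each sample's
#' scale factor makes the median ratio of that sample to the reference, over
#' its invariant features, equal to 1.
#'
#' @param counts numeric matrix, samples in rows, features in columns, with
#'   dimnames. Features with zero counts in every sample are dropped.
#' @param pseudocount added before log2.
#' @param sigma half-width of the invariant window in fitted standard
#'   deviations (default 1).
#' @return An object of class `invariant_fit` with the pseudo-`reference`,
#'   per-sample `diffs`, `skew_params` (location/scale/shape/mean/sd/method per
#'   sample), `invariant_features` (named list of feature id vectors),
#'   `scale_factors` (named positive numeric) and `dropped_features`.
#' @seealso [apply_normalization()]
#' @examples
#' a <- matrix(rpois(400, 50), 2, 200, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), paste0("f", 1:200)))
#' f <- fit_invariant_model(a)
#' f$scale_factors
#' @export
fit_invariant_model <- function(counts, pseudocount = 1, sigma = 1) {
  if (!is.matrix(counts) || nrow(counts) < 2L) {
    stopf("`counts` must be a matrix with >= 2 sample rows")
  }
  if (is.null(rownames(counts))) rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("F", seq_len(ncol(counts)))
  if (pseudocount <= 0) stopf("`pseudocount` must be > 0")
  keep <- colSums(counts) > 0
  dropped <- colnames(counts)[!keep]
  counts <- counts[, keep, drop = FALSE]

  logc <- log2(counts + pseudocount)
  reference <- apply(logc, 2, median)
  diffs <- sweep(logc, 2, reference)

  samples <- rownames(counts)
  skew_params <- vector("list", length(samples))
  invariant <- vector("list", length(samples))
  scale_factors <- numeric(length(samples))
  names(skew_params) <- names(invariant) <- names(scale_factors) <- samples
  for (s in samples) {
    d <- diffs[s, ]
    if (sd(d) < 1e-10) {
      # constant differences: the whole sample is a pure rescaling of the
      # reference; every feature is invariant
      fit <- list(location = median(d), scale = 0, shape = 0,
                  mean = median(d), sd = 0, method = "degenerate")
      inv <- colnames(counts)
    } else {
      fit <- fit_skew_normal(d)
      inv <- colnames(counts)[abs(d - fit$mean) <= sigma * fit$sd]
      if (length(inv) == 0L) inv <- colnames(counts)[which.min(abs(d - fit$mean))]
    }
    skew_params[[s]] <- fit
    invariant[[s]] <- inv
    scale_factors[s] <- 2^(-median(d[inv]))
  }
  structure(list(reference = reference, diffs = diffs,
                 skew_params = skew_params,
                 invariant_features = invariant,
                 scale_factors = scale_factors,
                 sigma = sigma, pseudocount = pseudocount,
                 dropped_features = dropped),
            class = "invariant_fit")
}

#' @export
print.invariant_fit <- function(x, ...) {
  cat(sprintf("invariant_fit: %d samples, %d features; scale factors in [%.3f, %.3f]\n",
              nrow(x$diffs), ncol(x$diffs),
              min(x$scale_factors), max(x$scale_factors)))
  invisible(x)
}

#' Apply invariant-feature scale factors
#'
#' Multiplies each sample by its fitted scale factor so the median ratio to
#' the pseudo-reference over its invariant feature set is 1.
#'
#' @param counts sample x feature matrix on the same feature universe the fit
#'   was computed on (features dropped during fitting are tolerated and
#'   dropped here too).
#' @param fit an `invariant_fit`.
#' @return The normalized matrix (same orientation as input).
#' @export
apply_normalization <- function(counts, fit) {
  stopifnot(inherits(fit, "invariant_fit"))
  feats <- colnames(fit$diffs)
  if (!all(feats %in% colnames(counts))) {
    stopf("`counts` is missing features the fit was computed on")
  }
  counts <- counts[, feats, drop = FALSE]
  samples <- rownames(fit$diffs)
  if (!all(samples %in% rownames(counts))) {
    stopf("`counts` is missing samples the fit was computed on")
  }
  if (any(lengths(fit$invariant_features) == 0L)) {
    stopf("empty invariant set for some sample: refit with a wider `sigma` window")
  }
  counts[samples, ] * fit$scale_factors[samples]
}

#' Normalize a multi-table count set
#'
#' Runs [fit_invariant_model()] and [apply_normalization()] over the
#' condition x time-point samples of a `multi_table_set`. By default the
#' pseudo-reference is built within each time point (samples sharing a time
#' point are directly comparable, so only the minority of perturbed CREs
#' differ between them); `group_by_time = FALSE` pools all samples against a
#' single cross-time reference, appropriate when the feature universe is
#' dominated by features that do not respond to the stimulus.
#'
#' @param mts a `multi_table_set`.
#' @param group_by_time build one pseudo-reference per time point (default)
#'   or a single pooled one.
#' @param ... passed to [fit_invariant_model()].
#' @return List with `tables` (the normalized `multi_table_set`, numeric
#'   matrices), `fits` (named list of `invariant_fit`, one per group) and
#'   `scale_factors` (per condition x time-point sample).
#' @export
normalize_tables <- function(mts, group_by_time = TRUE, ...) {
  stopifnot(inherits(mts, "multi_table_set"))
  out <- mts
  tps <- format_time(mts$time_points)
  # drop CREs with no counts anywhere so every group sees the same rows
  tot <- Reduce(`+`, lapply(mts$counts, rowSums))
  kept <- names(tot)[tot > 0]
  out$counts <- lapply(out$counts, function(m) m[kept, , drop = FALSE])
  fits <- list()
  scale_factors <- c()
  if (group_by_time) {
    for (tp in tps) {
      m <- vapply(mts$conditions, function(cd) out$counts[[cd]][, tp],
                  numeric(length(kept)))
      rownames(m) <- kept
      fit <- fit_invariant_model(t(m), ...)
      norm <- apply_normalization(t(m), fit)
      for (cd in mts$conditions) {
        out$counts[[cd]][colnames(fit$diffs), tp] <- norm[cd, ]
      }
      fits[[tp]] <- fit
      sf <- fit$scale_factors
      names(sf) <- paste0(names(sf), "_", tp)
      scale_factors <- c(scale_factors, sf)
    }
  } else {
    wide <- do.call(cbind, lapply(mts$conditions, function(cond) {
      m <- out$counts[[cond]]
      colnames(m) <- paste0(cond, "_", colnames(m))
      m
    }))
    fit <- fit_invariant_model(t(wide), ...)
    norm <- t(apply_normalization(t(wide), fit))
    for (cond in mts$conditions) {
      cols <- paste0(cond, "_", tps)
      m <- norm[, cols, drop = FALSE]
      colnames(m) <- tps
      out$counts[[cond]] <- m
    }
    fits <- list(pooled = fit)
    scale_factors <- fit$scale_factors
  }
  if (!is.null(out$cre_intervals)) {
    out$cre_intervals <- out$cre_intervals[names(out$cre_intervals) %in% kept]
  }
  list(tables = out, fits = fits, scale_factors = scale_factors)
}
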