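# Permutation association between inhibitor-affected CRE sets and TF peak
# interval sets, with Benjamini-Hochberg correction across all tests of a
# run. Interval arithmetic goes through GenomicRanges/IRanges.

#' Overlap indicator between CREs and a peak set
#'
#' A CRE counts as overlapped when any peak shares at least one base pair
#' with it (intervals are treated as 0-based half-open on disk; `GRanges`
#' objects in memory follow the usual 1-based closed convention, see
#' [read_bed()]).
#'
#' @param cres named `GRanges` of CRE intervals.
#' @param peaks `GRanges` of peaks.
#' @return List with `indicator` (named logical per CRE) and `count`.
#' @export
interval_overlap <- function(cres, peaks) {
  stopifnot(methods::is(cres, "GRanges"), methods::is(peaks, "GRanges"))
  if (is.null(names(cres))) stopf("`cres` must be named")
  # disjoint seqlevels are a legitimate zero-overlap query, not a warning
  ind <- suppressWarnings(IRanges::overlapsAny(cres, peaks, ignore.strand = TRUE))
  names(ind) <- names(cres)
  list(indicator = ind, count = sum(ind))
}

#' Permutation association of an affected CRE set with a peak indicator
#'
#' Compares the number of peak-bearing CREs in the affected set with a null
#' of `n_perm` uniform same-size resamples from the CRE universe. Reports the
#' standardized overlap `z = (obs - null_mean) / null_sd` and a two-sided
#' empirical p-value with +1 smoothing (deviations from the null mean at
#' least as large as the observed one).
#'
#' @param affected character vector of affected CRE ids (subset of
#'   `universe`).
#' @param universe character vector of all CRE ids.
#' @param peak_indicator named logical over the universe (from
#'   [interval_overlap()]).
#' @param n_perm number of resamples (default 5000).
#' @param seed integer RNG seed.
#' @return List with `observed_overlap`, `null_mean`, `null_sd`, `z`,
#'   `p_empirical` and a `degenerate` flag (`z = 0`, `p = 1` when the null
#'   has no spread, e.g. affected = universe).
#' @export
permutation_association <- function(affected, universe, peak_indicator,
                                    n_perm = 5000, seed = 1) {
  if (!all(affected %in% universe)) stopf("`affected` must be a subset of `universe`")
  if (!all(universe %in% names(peak_indicator))) {
    stopf("`peak_indicator` must cover the universe")
  }
  m <- length(affected)
  if (m == 0L) stopf("`affected` is empty")
  ind <- peak_indicator[universe]
  observed <- sum(ind[affected])
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) sum(ind[sample.int(length(ind), m)]),
           numeric(1))
  })
  nm <- mean(null); ns <- sd(null)
  degenerate <- !is.finite(ns) || ns <= 0
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- (observed - nm) / ns
    p <- (1 + sum(abs(null - nm) >= abs(observed - nm))) / (1 + n_perm)
  }
  list(observed_overlap = observed, null_mean = nm, null_sd = ns,
       z = z, p_empirical = p, n_affected = m, n_perm = n_perm,
       degenerate = degenerate)
}

#' Associate inhibitor effects with TF peak sets
#'
#' Runs [permutation_association()] for every TF x inhibitor x direction
#' combination with a non-empty affected set and applies Benjamini-Hochberg
#' correction across all tests of the invocation.
#'
#' @param calls a `perturbation_calls`.
#' @param tf_peaks named list of `GRanges` peak sets (one per TF).
#' @param cre_intervals named `GRanges` of CRE intervals covering the call
#'   universe.
#' @param n_perm,seed permutation parameters.
#' @param directions which call directions to test.
#' @return A data frame (class `association_result`) with one row per test:
#'   tf, inhibitor, direction, observed_overlap, null_mean, null_sd, z,
#'   p_empirical, p_adjusted, degenerate.
#' @export
associate_tf_effects <- function(calls, tf_peaks, cre_intervals,
                                 n_perm = 5000, seed = 1,
                                 directions = c("down", "up")) {
  stopifnot(inherits(calls, "perturbation_calls"))
  universe <- intersect(rownames(calls$calls), names(cre_intervals))
  if (length(universe) == 0L) stopf("no CRE shared between calls and intervals")
  cres <- cre_intervals[universe]
  indicators <- lapply(tf_peaks, function(p) interval_overlap(cres, p)$indicator)
  rows <- list()
  i <- 0L
  for (tf in names(tf_peaks)) {
    for (inh in colnames(calls$calls)) {
      for (dir in directions) {
        affected <- intersect(
          rownames(calls$calls)[calls$calls[, inh] == dir], universe)
        if (length(affected) == 0L) next
        i <- i + 1L
        res <- permutation_association(affected, universe, indicators[[tf]],
                                       n_perm = n_perm, seed = seed + i)
        rows[[i]] <- data.frame(tf = tf, inhibitor = inh, direction = dir,
                                observed_overlap = res$observed_overlap,
                                null_mean = res$null_mean,
                                null_sd = res$null_sd, z = res$z,
                                p_empirical = res$p_empirical,
                                degenerate = res$degenerate,
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) stopf("no non-empty affected set to test")
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_empirical, method = "BH")
  class(out) <- c("association_result", "data.frame")
  out
}
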