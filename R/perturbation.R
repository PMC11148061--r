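# Signed perturbation-likelihood scoring: per-CRE Euclidean distances between
# each inhibitor's and the vehicle's partial factor scores, a pooled
# log-normal null on the distances, the summed z-score difference across the
# time course (delta z), and the signed -log10 tail probability.

#' Per-CRE distances from the vehicle table
#'
#' Euclidean distance, over the selected MFA dimensions, between each
#' inhibitor table's partial factor score and the vehicle table's partial
#' factor score, for every CRE.
#'
#' @param mfa an `mfa_result` with non-empty `selected_dims`.
#' @param vehicle vehicle condition id (default: the one recorded in `mfa`).
#' @return Numeric matrix CRE x inhibitor of distances (vehicle column
#'   excluded).
#' @export
cre_distances <- function(mfa, vehicle = mfa$vehicle) {
  stopifnot(inherits(mfa, "mfa_result"))
  if (is.null(vehicle) || !vehicle %in% names(mfa$partial_scores)) {
    stopf("vehicle condition `%s` not found in the MFA result", vehicle %||% "<NULL>")
  }
  dims <- mfa$selected_dims
  if (is.null(dims) || length(dims) == 0L) {
    stopf("no selected dimensions: run select_dims()/mfa() first")
  }
  Pv <- mfa$partial_scores[[vehicle]][, dims, drop = FALSE]
  inhibitors <- setdiff(names(mfa$partial_scores), vehicle)
  out <- vapply(inhibitors, function(inh) {
    Pk <- mfa$partial_scores[[inh]][, dims, drop = FALSE]
    sqrt(rowSums((Pk - Pv)^2))
  }, numeric(nrow(Pv)))
  rownames(out) <- rownames(Pv)
  out
}

#' Signed perturbation-likelihood scores
#'
#' Pools the natural log of all CRE x inhibitor distances for the stimulus,
#' fits a normal distribution by maximum likelihood, and converts each
#' distance to its upper-tail probability (complementary CDF). The direction
#' of the change is taken from delta z — the sum over all time points of the
#' inhibitor table's standardized values minus the vehicle's — and the final
#' score is `-log10(ccdf) * sign(delta_z)`, 0 when delta z is 0.
#'
#' @param dist CRE x inhibitor distance matrix from [cre_distances()].
#' @param std the `standardized_set` the MFA was fitted on (provides the
#'   per-time-point z-scores for delta z).
#' @param vehicle vehicle condition id.
#' @param clamp floor for the tail probability, in decades (`ccdf` is clamped
#'   below at `10^-clamp` so scores stay finite).
#' @return An object of class `perturbation_scores`: `distance`, `log_null`
#'   (mean, sd of the fitted normal on ln distances), `ccdf`, `delta_z`,
#'   `score` and the `vehicle` id.
#' @export
score_perturbations <- function(dist, std, vehicle = std$vehicle, clamp = 300) {
  stopifnot(inherits(std, "standardized_set"), is.matrix(dist))
  if (is.null(vehicle) || !vehicle %in% names(std$tables)) {
    stopf("vehicle condition `%s` not found in the standardized set",
          vehicle %||% "<NULL>")
  }
  if (clamp <= 0) stopf("`clamp` must be > 0")
  inhibitors <- colnames(dist)
  cres <- rownames(dist)
  if (!all(inhibitors %in% names(std$tables))) {
    stopf("distance columns must be conditions of the standardized set")
  }
  # zero-distance guard before the log
  if (all(dist == 0)) stopf("all distances are zero: degenerate input")
  if (any(dist == 0)) {
    dist[dist == 0] <- min(dist[dist > 0]) * 1e-3
  }
  ln_d <- log(dist)
  # optim's exploration of sd < 0 inside the MLE raises harmless NaN warnings
  null_fit <- suppressWarnings(fitdistrplus::fitdist(as.numeric(ln_d), "norm"))
  m <- unname(null_fit$estimate["mean"])
  s <- unname(null_fit$estimate["sd"])
  if (!is.finite(s) || s <= 1e-12) stopf("degenerate ln-distance distribution (sd = 0)")
  z <- (ln_d - m) / s
  ccdf <- pmax(pnorm(z, lower.tail = FALSE), 10^(-clamp))

  zsum_vehicle <- rowSums(std$tables[[vehicle]][cres, , drop = FALSE])
  delta_z <- vapply(inhibitors, function(inh) {
    rowSums(std$tables[[inh]][cres, , drop = FALSE]) - zsum_vehicle
  }, numeric(length(cres)))
  rownames(delta_z) <- cres

  score <- -log10(ccdf) * sign(delta_z)
  score[delta_z == 0] <- 0
  structure(list(distance = dist, log_null = c(mean = m, sd = s),
                 ccdf = ccdf, delta_z = delta_z, score = score,
                 vehicle = vehicle, clamp = clamp),
            class = "perturbation_scores")
}

#' @export
print.perturbation_scores <- function(x, ...) {
  cat(sprintf("perturbation_scores: %d CREs x %d inhibitors; ln-distance null N(%.2f, %.2f)\n",
              nrow(x$score), ncol(x$score), x$log_null["mean"], x$log_null["sd"]))
  invisible(x)
}

#' Call discrete perturbation events
#'
#' Thresholds the signed likelihood score into up / down / none calls and
#' tabulates per-inhibitor event counts by direction.
#'
#' @param scores a `perturbation_scores`.
#' @param threshold positive likelihood threshold (default 1, i.e. a tail
#'   probability below 0.1 in the called direction).
#' @return An object of class `perturbation_calls`: `calls` (character matrix
#'   CRE x inhibitor with values "down"/"none"/"up"), `summary` (data frame
#'   inhibitor, up, down) and the `threshold`.
#' @export
call_events <- function(scores, threshold = 1) {
  stopifnot(inherits(scores, "perturbation_scores"))
  if (threshold <= 0) stopf("`threshold` must be > 0")
  s <- scores$score
  calls <- matrix("none", nrow(s), ncol(s), dimnames = dimnames(s))
  calls[s > threshold] <- "up"
  calls[s < -threshold] <- "down"
  summary <- data.frame(
    inhibitor = colnames(s),
    up = colSums(calls == "up"),
    down = colSums(calls == "down"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(calls = calls, summary = summary, threshold = threshold),
            class = "perturbation_calls")
}

#' @export
print.perturbation_calls <- function(x, ...) {
  cat(sprintf("perturbation_calls (|score| > %g): %d up, %d down over %d inhibitors\n",
              x$threshold, sum(x$summary$up), sum(x$summary$down),
              nrow(x$summary)))
  invisible(x)
}

#' Affected CRE sets per inhibitor and direction
#'
#' @param calls a `perturbation_calls`.
#' @return Named list (`<inhibitor>.<direction>`) of CRE id vectors; empty
#'   sets are kept.
#' @export
affected_sets <- function(calls) {
  stopifnot(inherits(calls, "perturbation_calls"))
  out <- list()
  for (inh in colnames(calls$calls)) {
    for (dir in c("down", "up")) {
      out[[paste(inh, dir, sep = ".")]] <-
        rownames(calls$calls)[calls$calls[, inh] == dir]
    }
  }
  out
}
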