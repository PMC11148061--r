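# Synthetic fixture generator: stimulus-induced acetylation kinetics at CREs,
# latent kinase -> TF-program -> CRE wiring, polypharmacological inhibitor
# effects, negative-binomial count noise, and TF peak annotations, together
# with machine-readable ground truth.

#' Kinetic templates for stimulus-induced acetylation
#'
#' Builds the per-cluster expected log-signal profiles over the time course.
#' Each template has a single maximum at its peak time; signal rises from a
#' common baseline, peaks, and decays, emulating the main kinetic classes of
#' stimulus-induced enhancer acetylation (early, intermediate, late and
#' sustained responders).
#'
#' @param time_points numeric vector of time points in hours.
#' @param peak_times numeric vector, one entry per kinetic cluster, giving the
#'   time (hours) at which that cluster's induction peaks. Must be a subset of
#'   `time_points` greater than 0.
#' @param base_log baseline natural-log signal shared by all clusters at rest.
#' @param induction natural-log fold induction at the peak time point.
#' @param width kinetic bandwidth (log-time units) controlling how sharply
#'   induction rises and decays around the peak.
#' @return A list of kinetic templates; each is a list with `cluster_id`,
#'   `profile` (expected log-signal per time point), `peak_time`,
#'   `induction_weight` (induction relative to the peak: 1 at the peak time,
#'   ~0 at rest) and `induced` (the at-least-half-maximally induced time
#'   points, where perturbation effects apply).
#' @examples
#' tpl <- kinetic_templates()
#' sapply(tpl, function(t) t$peak_time)
#' @export
kinetic_templates <- function(time_points = c(0, 0.5, 1, 2, 4),
                              peak_times = c(0.5, 1, 2, 4),
                              base_log = log(50),
                              induction = 1.5,
                              width = 0.6) {
  if (any(!peak_times %in% time_points) || any(peak_times <= 0)) {
    stopf("`peak_times` must be positive entries of `time_points`")
  }
  lapply(seq_along(peak_times), function(j) {
    pk <- peak_times[j]
    # log-time Gaussian bump; the +0.25 h offset keeps t = 0 finite and near
    # baseline for every cluster
    w <- exp(-0.5 * (log((time_points + 0.25) / (pk + 0.25)) / width)^2)
    profile <- base_log + induction * w
    names(profile) <- format_time(time_points)
    stopifnot(sum(profile == max(profile)) == 1L,
              which.max(profile) == match(pk, time_points))
    # a time point counts as induced when the cluster is at least
    # half-maximally induced there; perturbation effects apply at these
    # time points
    list(cluster_id = paste0("C", j),
         profile = profile,
         time_points = time_points,
         peak_time = pk,
         induction_weight = w,
         induced = w >= 0.5)
  })
}

format_time <- function(t) {
  vapply(t, function(x) paste0(format(x, trim = TRUE), "h"), character(1))
}

#' Generate latent kinase/program/inhibitor wiring
#'
#' Draws the latent causal structure the analysis is meant to recover: a set
#' of kinases, TF programs each driven by one kinase and owning a subset of
#' the CRE universe, and inhibitors carrying one intended target plus a
#' binomial number of off-targets with lower potency. Inhibitors are assigned
#' intended targets round-robin over the wired kinases, so inhibitors sharing
#' an intended target form a target family.
#'
#' @param n_cres,n_inhibitors,n_kinases,n_programs positive integer counts.
#'   `n_programs` must not exceed `n_kinases`.
#' @param offtarget_rate per-kinase probability that a non-intended kinase is
#'   an off-target of a given inhibitor.
#' @param up_frac fraction of programs whose perturbation is up-regulatory
#'   (the minority; stimulus-induced acetylation is mostly lost, not gained,
#'   under kinase inhibition).
#' @param program_coverage fraction of the CRE universe assigned to programs
#'   (split evenly and disjointly among programs); remaining CREs respond to
#'   the stimulus but to no inhibitor.
#' @param seed integer RNG seed; identical seeds give identical wiring.
#' @return An object of class `cki_wiring`: CRE/kinase/inhibitor identifiers,
#'   a `programs` data frame (program, kinase, tf, direction), `program_cres`
#'   (named list of CRE id subsets), `inhibitor_targets` (named list of data
#'   frames with kinase, potency, intended), `family` (named character vector,
#'   inhibitor to intended-target family), `cre_intervals` (a `GRanges` of
#'   1-kb CRE intervals) and the potency distribution used.
#' @examples
#' w <- generate_wiring(200, 6, 5, 3, offtarget_rate = 0, seed = 1)
#' sapply(w$inhibitor_targets, nrow)  # exactly one target each
#' @export
generate_wiring <- function(n_cres, n_inhibitors, n_kinases, n_programs,
                            offtarget_rate = 0.1, up_frac = 0.2,
                            program_coverage = 0.6, seed = 1) {
  assert_count(n_cres, "n_cres"); assert_count(n_inhibitors, "n_inhibitors")
  assert_count(n_kinases, "n_kinases"); assert_count(n_programs, "n_programs")
  assert_prob(offtarget_rate, "offtarget_rate")
  assert_prob(up_frac, "up_frac")
  if (n_programs > n_kinases) {
    stopf("n_programs (%d) may not exceed n_kinases (%d)", n_programs, n_kinases)
  }
  with_seed(seed, {
    cres <- sprintf("CRE%05d", seq_len(n_cres))
    kinases <- sprintf("K%02d", seq_len(n_kinases))
    program_ids <- sprintf("P%d", seq_len(n_programs))
    program_kinase <- sample(kinases, n_programs)

    n_up <- round(up_frac * n_programs)
    direction <- rep(-1L, n_programs)
    if (n_up > 0) direction[sample(n_programs, n_up)] <- 1L
    programs <- data.frame(program = program_ids,
                           kinase = program_kinase,
                           tf = paste0("TF_", program_ids),
                           direction = direction,
                           stringsAsFactors = FALSE)

    n_wired <- floor(program_coverage * n_cres)
    wired <- sample(cres, n_wired)
    program_cres <- split(wired, rep_len(seq_len(n_programs), n_wired))
    names(program_cres) <- program_ids

    inhibitors <- sprintf("INH%02d", seq_len(n_inhibitors))
    inhibitor_targets <- vector("list", n_inhibitors)
    names(inhibitor_targets) <- inhibitors
    for (i in seq_len(n_inhibitors)) {
      intended <- program_kinase[(i - 1L) %% n_programs + 1L]
      others <- setdiff(kinases, intended)
      n_off <- rbinom(1L, n_kinases - 1L, offtarget_rate)
      off <- if (n_off > 0) sample(others, n_off) else character(0)
      inhibitor_targets[[i]] <- data.frame(
        kinase = c(intended, off),
        potency = c(runif(1, 0.7, 1), runif(n_off, 0.2, 0.8)),
        intended = c(TRUE, rep(FALSE, n_off)),
        stringsAsFactors = FALSE)
    }
    family <- vapply(inhibitor_targets,
                     function(tg) tg$kinase[tg$intended][1L], character(1))

    cre_intervals <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(start = (seq_len(n_cres) - 1L) * 2000L + 1L,
                                width = 1000L),
      seqinfo = NULL)
    names(cre_intervals) <- cres

    structure(list(cres = cres, kinases = kinases, programs = programs,
                   program_cres = program_cres,
                   inhibitor_targets = inhibitor_targets,
                   family = family, cre_intervals = cre_intervals,
                   potency_dist = paste(
                     "intended ~ Uniform(0.7, 1);",
                     "off-target ~ Uniform(0.2, 0.8);",
                     "n_offtargets ~ Binomial(n_kinases - 1, offtarget_rate)"),
                   params = list(n_cres = n_cres, n_inhibitors = n_inhibitors,
                                 n_kinases = n_kinases, n_programs = n_programs,
                                 offtarget_rate = offtarget_rate,
                                 up_frac = up_frac,
                                 program_coverage = program_coverage,
                                 seed = seed)),
              class = "cki_wiring")
  })
}

#' @export
print.cki_wiring <- function(x, ...) {
  cat(sprintf("cki_wiring: %d CREs, %d inhibitors, %d kinases, %d programs\n",
              length(x$cres), length(x$inhibitor_targets),
              length(x$kinases), nrow(x$programs)))
  invisible(x)
}

#' Simulate per-condition count tables with ground truth
#'
#' Draws negative-binomial counts around each CRE's kinetic template for the
#' vehicle table, and shifts the log-mean of program member CREs — at the
#' cluster's induced time points (at least half-maximal induction) — for
#' every inhibitor hitting the program's kinase. The signed shift is
#' `direction * effect_scale * potency`, summed over the inhibitor's targets
#' wired to that program; per-sample sequencing-depth multipliers are
#' log-normal so the normalization step has real work to do.
#'
#' @param wiring a `cki_wiring` from [generate_wiring()].
#' @param templates kinetic templates from [kinetic_templates()].
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param depth global mean-depth multiplier.
#' @param effect_scale scale of the injected log-mean perturbation per unit
#'   potency; 0 gives a null dataset identical in distribution to vehicle.
#' @param depth_sd standard deviation of the log-normal per-sample depth
#'   multipliers (log scale).
#' @param vehicle,stimulus condition labels.
#' @param seed integer RNG seed.
#' @return A list with `tables` (a `multi_table_set`: stimulus, conditions,
#'   vehicle, time points, one CRE x time count matrix per condition, CRE
#'   intervals) and `truth` (a `synthetic_truth`: data frame of nonzero
#'   (CRE, inhibitor) effects with direction, CRE cluster assignment, and the
#'   per-sample depth multipliers actually used).
#' @examples
#' w <- generate_wiring(100, 4, 4, 2, seed = 1)
#' sim <- generate_counts(w, seed = 2)
#' dim(sim$tables$counts$DMSO)
#' @export
generate_counts <- function(wiring, templates = kinetic_templates(),
                            dispersion = 50, depth = 4, effect_scale = 1,
                            depth_sd = 0.15, vehicle = "DMSO",
                            stimulus = "LPS", seed = 1) {
  stopifnot(inherits(wiring, "cki_wiring"))
  if (dispersion <= 0) stopf("`dispersion` must be > 0")
  if (depth <= 0) stopf("`depth` must be > 0")
  time_points <- templates[[1]]$time_points
  n_t <- length(time_points)
  cres <- wiring$cres
  n_cres <- length(cres)
  inhibitors <- names(wiring$inhibitor_targets)
  conditions <- c(vehicle, inhibitors)

  with_seed(seed, {
    cluster_of <- sample(seq_along(templates), n_cres, replace = TRUE)
    names(cluster_of) <- cres

    # signed effect per (CRE, inhibitor): direction * effect_scale * total
    # potency of the inhibitor against the kinase driving the CRE's program
    effect <- matrix(0, n_cres, length(inhibitors),
                     dimnames = list(cres, inhibitors))
    for (p in seq_len(nrow(wiring$programs))) {
      kin <- wiring$programs$kinase[p]
      dir_p <- wiring$programs$direction[p]
      members <- wiring$program_cres[[wiring$programs$program[p]]]
      for (inh in inhibitors) {
        tg <- wiring$inhibitor_targets[[inh]]
        pot <- sum(tg$potency[tg$kinase == kin])
        if (pot > 0) {
          effect[members, inh] <- effect[members, inh] +
            dir_p * effect_scale * pot
        }
      }
    }

    depth_mult <- matrix(rlnorm(length(conditions) * n_t, 0, depth_sd),
                         length(conditions), n_t,
                         dimnames = list(conditions, format_time(time_points)))

    prof <- t(vapply(templates, function(tp) tp$profile, numeric(n_t)))
    indu <- t(vapply(templates, function(tp) as.numeric(tp$induced), numeric(n_t)))

    counts <- vector("list", length(conditions))
    names(counts) <- conditions
    base_logmean <- prof[cluster_of, , drop = FALSE] + log(depth)
    for (cond in conditions) {
      lm <- base_logmean
      if (cond != vehicle) {
        # effect scales with the CRE's own induction weight per time point
        lm <- lm + effect[, cond] * indu[cluster_of, , drop = FALSE]
      }
      mu <- exp(lm) * rep(depth_mult[cond, ], each = n_cres)
      if (any(!is.finite(mu))) {
        stopf("non-finite count mean for condition %s: check templates/effects",
              cond)
      }
      m <- matrix(rnbinom(n_cres * n_t, mu = mu, size = dispersion),
                  n_cres, n_t,
                  dimnames = list(cres, format_time(time_points)))
      counts[[cond]] <- m
    }

    nz <- which(effect != 0, arr.ind = TRUE)
    truth_effect <- data.frame(
      cre = cres[nz[, 1]],
      inhibitor = inhibitors[nz[, 2]],
      effect = effect[nz],
      direction = c("down", "none", "up")[sign(effect[nz]) + 2L],
      stringsAsFactors = FALSE)

    tables <- structure(list(stimulus = stimulus, conditions = conditions,
                             vehicle = vehicle, time_points = time_points,
                             counts = counts,
                             cre_intervals = wiring$cre_intervals),
                        class = "multi_table_set")
    truth <- structure(list(effect = truth_effect,
                            effect_matrix = effect,
                            cluster_of = cluster_of,
                            depth_mult = depth_mult,
                            params = list(dispersion = dispersion,
                                          depth = depth,
                                          effect_scale = effect_scale,
                                          depth_sd = depth_sd, seed = seed)),
                       class = "synthetic_truth")
    list(tables = tables, truth = truth)
  })
}

#' @export
print.multi_table_set <- function(x, ...) {
  cat(sprintf("multi_table_set [%s]: %d conditions (vehicle %s), %d CREs x %d time points\n",
              x$stimulus, length(x$conditions), x$vehicle,
              nrow(x$counts[[1]]), length(x$time_points)))
  invisible(x)
}

#' Simulate TF peak annotations aligned to the latent programs
#'
#' Each program's TF receives a peak (the central 200 bp of the CRE interval)
#' on its member CREs with probability `1 - fnr`, and spuriously on
#' non-members with probability `fpr`.
#'
#' @param wiring a `cki_wiring`.
#' @param fpr,fnr false-positive and false-negative peak probabilities.
#' @param seed integer RNG seed.
#' @return Named list (one element per program TF) of `GRanges` peak sets.
#' @export
generate_tf_peaks <- function(wiring, fpr = 0.05, fnr = 0.1, seed = 1) {
  stopifnot(inherits(wiring, "cki_wiring"))
  assert_prob(fpr, "fpr"); assert_prob(fnr, "fnr")
  with_seed(seed, {
    out <- vector("list", nrow(wiring$programs))
    names(out) <- wiring$programs$tf
    for (p in seq_len(nrow(wiring$programs))) {
      members <- wiring$cres %in% wiring$program_cres[[wiring$programs$program[p]]]
      prob <- ifelse(members, 1 - fnr, fpr)
      has_peak <- runif(length(wiring$cres)) < prob
      cre_gr <- wiring$cre_intervals[has_peak]
      if (length(cre_gr) > 0) {
        peaks <- GenomicRanges::resize(cre_gr, width = 200L, fix = "center")
        names(peaks) <- NULL
      } else {
        peaks <- GenomicRanges::GRanges()
      }
      out[[p]] <- peaks
    }
    out
  })
}
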