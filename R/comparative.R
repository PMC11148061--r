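# Inhibitor-level comparative statistics: PCA proximity + 3-NN network +
# Ward dendrogram, family-distance permutation tests, kinetic angle
# histograms, standardized Jaccard overlap, and cross-readout comparison.

#' Inhibitor proximity model
#'
#' PCA of the inhibitor x CRE signed-score matrix, permutation selection of
#' components (the same within-column shuffling scheme used for the MFA
#' compromise), Euclidean distances in the selected component space, a
#' k-nearest-neighbor edge list (ties broken by lexicographic inhibitor id)
#' and a Ward (`ward.D2`) dendrogram on the same distances.
#'
#' @param scores a `perturbation_scores` (or a plain inhibitor x CRE numeric
#'   matrix of signed scores).
#' @param k number of nearest neighbors per inhibitor (default 3).
#' @param n_perm,alpha,seed component-selection permutation parameters.
#' @return An object of class `proximity_model`: `pc_scores`, `eigenvalues`,
#'   `perm_pvalues`, `selected_comps`, `dist` (full symmetric matrix),
#'   `knn_edges` (data frame from, to, distance, rank), `dendrogram`
#'   (an `hclust`), `k`.
#' @export
proximity_fit <- function(scores, k = 3, n_perm = 200, alpha = 0.05, seed = 1) {
  M <- if (inherits(scores, "perturbation_scores")) t(scores$score) else scores
  stopifnot(is.matrix(M))
  n <- nrow(M)
  if (n < 4L) stopf("need at least 4 inhibitors")
  if (n < k + 1L) stopf("need at least k + 1 = %d inhibitors for a %d-NN graph", k + 1L, k)
  ids <- rownames(M) %||% paste0("I", seq_len(n))
  rownames(M) <- ids

  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  ndim <- length(eig)

  pvals <- with_seed(seed, {
    exceed <- integer(ndim)
    for (b in seq_len(n_perm)) {
      Mp <- apply(M, 2, sample)
      pe <- prcomp(Mp, center = TRUE, scale. = FALSE)$sdev^2
      L <- min(length(pe), ndim)
      exceed[seq_len(L)] <- exceed[seq_len(L)] + (pe[seq_len(L)] >= eig[seq_len(L)])
    }
    (1 + exceed) / (1 + n_perm)
  })
  selected <- which(pvals < alpha)
  if (length(selected) == 0L) {
    warnf("no component passed the permutation test at alpha = %g; using the first 2", alpha)
    selected <- seq_len(min(2L, ndim))
  }

  X <- pc$x[, selected, drop = FALSE]
  D <- as.matrix(dist(X))
  edges <- do.call(rbind, lapply(ids, function(i) {
    d <- D[i, setdiff(ids, i)]
    ord <- order(d, names(d))  # lexicographic tie-break
    nn <- names(d)[ord][seq_len(k)]
    data.frame(from = i, to = nn, distance = d[nn], rank = seq_len(k),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  dend <- hclust(as.dist(D), method = "ward.D2")
  structure(list(pc_scores = pc$x, eigenvalues = eig, perm_pvalues = pvals,
                 selected_comps = selected, dist = D, knn_edges = edges,
                 dendrogram = dend, k = k),
            class = "proximity_model")
}

#' @export
print.proximity_model <- function(x, ...) {
  cat(sprintf("proximity_model: %d inhibitors, %d selected component(s), %d-NN graph\n",
              nrow(x$pc_scores), length(x$selected_comps), x$k))
  invisible(x)
}

#' Proximity network as an igraph object
#'
#' @param model a `proximity_model`.
#' @return An undirected `igraph` graph with `distance` edge attributes
#'   (duplicate mutual edges collapsed).
#' @export
proximity_graph <- function(model) {
  stopifnot(inherits(model, "proximity_model"))
  g <- igraph::graph_from_data_frame(model$knn_edges, directed = FALSE,
                                     vertices = rownames(model$pc_scores))
  igraph::simplify(g, edge.attr.comb = list(distance = "first", rank = "min"))
}

#' Family-distance permutation test
#'
#' Tests whether inhibitors annotated with the same target family sit closer
#' together in the proximity space than expected under random label
#' assignment. The empirical p-value is
#' `(1 + #(shuffled mean <= observed mean)) / (1 + n_shuffle)`; a
#' Kruskal-Wallis rank test comparing within- vs between-family distances is
#' reported alongside.
#'
#' @param model a `proximity_model`.
#' @param family named character vector, inhibitor id to family label.
#' @param n_shuffle number of label shuffles.
#' @param seed integer RNG seed.
#' @return List with `observed` (mean within-family distance), `null`
#'   (shuffled means), `p_value`, `kruskal_p`, `n_within_pairs`.
#' @export
family_distance_test <- function(model, family, n_shuffle = 1000, seed = 1) {
  stopifnot(inherits(model, "proximity_model"))
  ids <- rownames(model$pc_scores)
  if (!all(ids %in% names(family))) stopf("`family` must label every inhibitor")
  fam <- family[ids]
  if (max(table(fam)) < 2L) stopf("all families are singletons: no within-family pairs")
  D <- model$dist
  pair_idx <- which(upper.tri(D), arr.ind = TRUE)
  dvals <- D[pair_idx]
  same <- fam[pair_idx[, 1]] == fam[pair_idx[, 2]]
  observed <- mean(dvals[same])
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffle), function(b) {
      fs <- sample(fam)
      mean(dvals[fs[pair_idx[, 1]] == fs[pair_idx[, 2]]])
    }, numeric(1))
  })
  p <- (1 + sum(null <= observed, na.rm = TRUE)) / (1 + n_shuffle)
  kw <- if (any(same) && any(!same)) {
    kruskal.test(list(dvals[same], dvals[!same]))$p.value
  } else {
    NA_real_
  }
  list(observed = observed, null = null, p_value = p, kruskal_p = kw,
       n_within_pairs = sum(same), n_shuffle = n_shuffle)
}

#' Kinetic-angle frequency histograms
#'
#' Maps each CRE to the angle of its (dim 1, dim 2) compromise coordinates —
#' the plane encoding response kinetics — and bins the CREs affected by one
#' inhibitor (up and down events separately) into 5-degree bins over
#' [0, 360), min-max scaling the per-bin counts to [0, 1].
#'
#' @param mfa an `mfa_result` with at least 2 dimensions.
#' @param calls a `perturbation_calls`.
#' @param inhibitor inhibitor id (a column of the calls).
#' @param dims the two compromise dimensions spanning the angle (default 1:2).
#' @param bin_width bin width in degrees (default 5).
#' @return Named list `up` / `down` of `angle_histogram` objects: `inhibitor`,
#'   `direction`, `bin_edges`, `counts`, `frequency` (min-max scaled) and an
#'   `empty` flag when the inhibitor has no event in that direction.
#' @export
angle_frequency <- function(mfa, calls, inhibitor, dims = c(1, 2), bin_width = 5) {
  stopifnot(inherits(mfa, "mfa_result"), inherits(calls, "perturbation_calls"))
  if (ncol(mfa$compromise_scores) < max(dims)) {
    stopf("compromise has fewer than %d dimensions", max(dims))
  }
  if (!inhibitor %in% colnames(calls$calls)) {
    stopf("unknown inhibitor `%s`", inhibitor)
  }
  xy <- mfa$compromise_scores[, dims, drop = FALSE]
  deg <- (atan2(xy[, 2], xy[, 1]) * 180 / pi) %% 360
  n_bins <- as.integer(360 / bin_width)
  edges <- seq(0, 360, by = bin_width)
  one <- function(direction) {
    ids <- rownames(calls$calls)[calls$calls[, inhibitor] == direction]
    ids <- intersect(ids, names(deg) %||% rownames(xy))
    bin <- pmin(floor(deg[ids] / bin_width) + 1L, n_bins)
    counts <- tabulate(bin, nbins = n_bins)
    empty <- length(ids) == 0L
    rng <- range(counts)
    frequency <- if (rng[2] > rng[1]) {
      (counts - rng[1]) / (rng[2] - rng[1])
    } else {
      rep(0, n_bins)
    }
    structure(list(inhibitor = inhibitor, direction = direction,
                   bin_edges = edges, counts = counts, frequency = frequency,
                   empty = empty),
              class = "angle_histogram")
  }
  list(up = one("up"), down = one("down"))
}

#' Standardized Jaccard overlap between two CRE sets
#'
#' Jaccard index of two affected-CRE sets, standardized against a resampling
#' null: `n_perm` pairs of same-size sets drawn uniformly (without
#' replacement) from the universe. The standardized effect size is
#' `(J - null_mean) / null_sd`, accounting for the two set sizes.
#'
#' @param setA,setB character vectors of CRE ids, subsets of `universe`.
#' @param universe character vector of all CRE ids.
#' @param n_perm number of resampling iterations (default 1000).
#' @param seed integer RNG seed.
#' @return An object of class `overlap_stat`: `jaccard`, `null_mean`,
#'   `null_sd`, `ses`, set sizes and a `degenerate` flag when the null has
#'   zero spread.
#' @export
ses_jaccard <- function(setA, setB, universe, n_perm = 1000, seed = 1) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe)) {
    stopf("sets must be subsets of the universe")
  }
  if (length(union(setA, setB)) == 0L) {
    stopf("both sets empty: Jaccard undefined")
  }
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  observed <- jac(setA, setB)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      jac(sample(universe, length(setA)), sample(universe, length(setB)))
    }, numeric(1))
  })
  nm <- mean(null); ns <- sd(null)
  degenerate <- !is.finite(ns) || ns <= 0
  ses <- if (degenerate) 0 else (observed - nm) / ns
  structure(list(jaccard = observed, null_mean = nm, null_sd = ns, ses = ses,
                 size_a = length(setA), size_b = length(setB),
                 n_universe = length(universe), n_perm = n_perm,
                 degenerate = degenerate),
            class = "overlap_stat")
}

#' @export
print.overlap_stat <- function(x, ...) {
  cat(sprintf("overlap_stat: J = %.3f, null %.3f +/- %.3f, SES = %.2f%s\n",
              x$jaccard, x$null_mean, x$null_sd, x$ses,
              if (x$degenerate) " (degenerate null)" else ""))
  invisible(x)
}

#' Compare two pairwise-distance readouts
#'
#' Rank correlation between two pairwise inhibitor distance tables from
#' different readouts, plus the distribution of the second readout's
#' distances within quintiles of the first (ties broken by pair id; quintile
#' sizes differ by at most one).
#'
#' @param distA,distB named numeric vectors over the same pair universe
#'   (names are pair ids), or `dist` objects over the same labels.
#' @param n_quantiles number of groups (default 5).
#' @return List with `spearman`, `quantile` (named integer group per pair)
#'   and `summary` (per group n, mean, median of `distB`).
#' @export
readout_compare <- function(distA, distB, n_quantiles = 5) {
  to_named <- function(d) {
    if (inherits(d, "dist")) {
      labs <- attr(d, "Labels")
      idx <- which(upper.tri(matrix(0, attr(d, "Size"), attr(d, "Size"))),
                   arr.ind = TRUE)
      v <- as.matrix(d)[idx]
      names(v) <- paste(labs[idx[, 1]], labs[idx[, 2]], sep = "|")
      v
    } else {
      d
    }
  }
  a <- to_named(distA); b <- to_named(distB)
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b)) || length(a) != length(b)) {
    stopf("the two distance tables must cover the same pair universe")
  }
  b <- b[names(a)]
  rho <- cor(a, b, method = "spearman")
  n <- length(a)
  ord <- order(a, names(a))
  grp <- integer(n)
  grp[ord] <- floor((seq_len(n) - 1) * n_quantiles / n) + 1L
  names(grp) <- names(a)
  summary <- do.call(rbind, lapply(seq_len(n_quantiles), function(q) {
    v <- b[grp == q]
    data.frame(quantile = q, n = length(v), mean = mean(v), median = median(v))
  }))
  list(spearman = rho, quantile = grp, summary = summary)
}
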