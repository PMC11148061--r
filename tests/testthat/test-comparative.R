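# Inhibitor-level comparisons: proximity model, family tests, angle
# histograms, SES Jaccard, readout comparison.

test_that("proximity model: geometry, knn contract and guards", {
  set.seed(51)
  base <- rnorm(50)
  M <- rbind(A1 = base + rnorm(50, sd = 0.01),
             A2 = base + rnorm(50, sd = 0.01),
             B1 = -base + rnorm(50, sd = 0.01),
             B2 = -base + rnorm(50, sd = 0.01),
             C1 = rnorm(50))
  pm <- proximity_fit(M, k = 3, n_perm = 100, seed = 52)
  # near-identical score vectors are mutual nearest neighbors
  expect_equal(pm$knn_edges$to[pm$knn_edges$from == "A1" & pm$knn_edges$rank == 1], "A2")
  expect_equal(pm$knn_edges$to[pm$knn_edges$from == "A2" & pm$knn_edges$rank == 1], "A1")
  # k edges per vertex, symmetric non-negative distances, triangle inequality
  expect_true(all(table(pm$knn_edges$from) == 3))
  expect_equal(pm$dist, t(pm$dist))
  expect_true(all(pm$dist >= 0))
  ids <- rownames(M)
  for (i in ids) for (j in ids) for (l in ids) {
    expect_lte(pm$dist[i, j], pm$dist[i, l] + pm$dist[l, j] + 1e-9)
  }
  expect_s3_class(pm$dendrogram, "hclust")
  expect_identical(pm$dendrogram$method, "ward.D2")
  g <- proximity_graph(pm)
  expect_setequal(igraph::V(g)$name, ids)
  expect_error(proximity_fit(M[1:3, ]), "at least 4")
  # identical score vectors at distance ~0
  expect_lt(pm$dist["A1", "A2"], pm$dist["A1", "B1"] / 10)
})

test_that("family distance test detects planted structure and is reproducible", {
  fx <- small_fixture(53, n_cres = 500, n_inhibitors = 8, n_kinases = 4,
                      n_programs = 4, offtarget_rate = 0)
  std <- standardize_tables(normalize_tables(fx$tables)$tables)
  fit <- mfa_fit(std); fit$selected_dims <- 1:2
  sc <- score_perturbations(cre_distances(fit), std)
  pm <- proximity_fit(sc, n_perm = 100, seed = 54)
  fam <- fx$wiring$family
  ft <- family_distance_test(pm, fam, n_shuffle = 500, seed = 55)
  expect_lt(ft$p_value, 0.05)
  expect_lt(ft$observed, mean(ft$null))
  ft2 <- family_distance_test(pm, fam, n_shuffle = 500, seed = 55)
  expect_identical(ft$null, ft2$null)
  # all labels identical: observed equals the all-pairs mean
  fam1 <- setNames(rep("x", nrow(pm$pc_scores)), rownames(pm$pc_scores))
  ft1 <- family_distance_test(pm, fam1, n_shuffle = 100, seed = 56)
  expect_equal(ft1$observed, mean(pm$dist[upper.tri(pm$dist)]))
  # all singletons error
  famS <- setNames(rownames(pm$pc_scores), rownames(pm$pc_scores))
  expect_error(family_distance_test(pm, famS), "singleton")
})

test_that("angle histograms bin the compromise plane in 72 bins", {
  cres <- c("east", "north", "x1")
  comp <- matrix(c(1, 0, -1, 0, 1, -1), 3, 2,
                 dimnames = list(cres, c("Dim1", "Dim2")))
  mfa <- fake_mfa(list(DMSO = comp, A = comp))
  calls <- call_events(fake_scores(matrix(c(2, 2, -2), 3, 1,
                                          dimnames = list(cres, "A"))))
  h <- angle_frequency(mfa, calls, "A")
  expect_length(h$up$frequency, 72)
  expect_length(h$down$frequency, 72)
  # (1,0) is 0 degrees -> bin 1; (0,1) is 90 degrees -> bin 19
  expect_equal(h$up$counts[1], 1)
  expect_equal(h$up$counts[19], 1)
  expect_equal(sum(h$up$counts), 2)
  # min-max scaling lands in [0, 1] with max exactly 1
  expect_equal(max(h$up$frequency), 1)
  expect_true(all(h$up$frequency >= 0 & h$up$frequency <= 1))
  expect_false(h$up$empty)
  # down event at 225 degrees -> bin 46
  expect_equal(h$down$counts[46], 1)
  # no affected CREs -> flagged empty all-zero histogram
  calls0 <- call_events(fake_scores(matrix(0, 3, 1, dimnames = list(cres, "A"))))
  h0 <- angle_frequency(mfa, calls0, "A")
  expect_true(h0$up$empty)
  expect_true(all(h0$up$frequency == 0))
})

test_that("kinetic clusters occupy coherent angular sectors", {
  fx <- small_fixture(57, n_cres = 600, n_inhibitors = 4, n_programs = 2)
  std <- standardize_tables(normalize_tables(fx$tables)$tables)
  fit <- mfa_fit(std)
  xy <- fit$compromise_scores[, 1:2]
  deg <- (atan2(xy[, 2], xy[, 1]) * 180 / pi) %% 360
  cl <- fx$truth$cluster_of[rownames(xy)]
  # circular spread within a kinetic cluster is far below the uniform spread
  circ_sd <- function(a) {
    r <- sqrt(mean(cos(a * pi / 180))^2 + mean(sin(a * pi / 180))^2)
    sqrt(-2 * log(r)) * 180 / pi
  }
  within <- vapply(1:4, function(k) circ_sd(deg[cl == k]), numeric(1))
  expect_true(all(within < circ_sd(deg)))
  # and cluster mean angles are distinct (kinetics order around the plane)
  means <- vapply(1:4, function(k) {
    atan2(mean(sin(deg[cl == k] * pi / 180)),
          mean(cos(deg[cl == k] * pi / 180))) * 180 / pi
  }, numeric(1))
  expect_equal(length(unique(round(means %% 360, -1))), 4)
})

test_that("SES Jaccard matches the exact hypergeometric oracle", {
  universe <- sprintf("u%02d", 1:20)
  A <- universe[1:5]
  expect_equal(ses_jaccard(A, A, universe, n_perm = 200, seed = 58)$jaccard, 1)
  expect_equal(ses_jaccard(A, universe[6:10], universe, n_perm = 200,
                           seed = 58)$jaccard, 0)
  st <- ses_jaccard(A, A, universe, n_perm = 2000, seed = 59)
  oracle <- exact_jaccard_mean(20, 5, 5)
  expect_lt(abs(st$null_mean - oracle), 4 * st$null_sd / sqrt(2000) * 3)
  expect_gt(st$ses, 3)
  # symmetry and label invariance (same seed, bijected ids)
  stAB <- ses_jaccard(A, universe[4:8], universe, n_perm = 500, seed = 60)
  stBA <- ses_jaccard(universe[4:8], A, universe, n_perm = 500, seed = 60)
  expect_equal(stAB$jaccard, stBA$jaccard)
  relab <- setNames(sprintf("v%02d", 1:20), universe)
  stR <- ses_jaccard(relab[A], relab[universe[4:8]], unname(relab),
                     n_perm = 500, seed = 60)
  expect_equal(stR$jaccard, stAB$jaccard)
  expect_equal(stR$ses, stAB$ses)
  expect_error(ses_jaccard(character(0), character(0), universe), "empty")
  expect_error(ses_jaccard("zz", A, universe), "subsets")
})

test_that("readout comparison: correlation, quintiles and guards", {
  set.seed(61)
  n <- 594  # all pairs of 34 + 33 extra: matches a screen-scale pair count
  a <- setNames(runif(n), sprintf("p%03d", seq_len(n)))
  cmp <- readout_compare(a, a)
  expect_equal(cmp$spearman, 1)
  expect_true(all(diff(cmp$summary$median) > 0))
  expect_true(all(abs(table(cmp$quantile) - n / 5) <= 1))
  # shuffled second readout decorrelates
  rhos <- vapply(1:50, function(i) {
    b <- setNames(sample(a), names(a))
    readout_compare(a, b)$spearman
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
  expect_error(readout_compare(a, a[-1]), "pair universe")
  # dist-object input
  m <- matrix(runif(25), 5, 5); m <- m + t(m); diag(m) <- 0
  dimnames(m) <- list(letters[1:5], letters[1:5])
  d1 <- as.dist(m)
  cmp2 <- readout_compare(d1, d1)
  expect_equal(cmp2$spearman, 1)
  expect_length(cmp2$quantile, 10)
})
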