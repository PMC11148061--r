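# Perturbation scoring: distances from the vehicle, signCCDF identities,
# event calling and truth recovery on the generator.

test_that("distances follow Euclidean geometry over selected dimensions", {
  cres <- c("c1", "c2")
  partial <- list(
    DMSO = matrix(0, 2, 2, dimnames = list(cres, c("Dim1", "Dim2"))),
    X = matrix(c(3, 1, 4, 0), 2, 2, dimnames = list(cres, c("Dim1", "Dim2"))))
  mfa <- fake_mfa(partial)
  d <- cre_distances(mfa)
  expect_equal(d["c1", "X"], 5)  # 3-4-5 triangle
  expect_equal(d["c2", "X"], 1)
  # a table identical to the vehicle has all-zero distances
  mfa2 <- fake_mfa(list(DMSO = partial$DMSO, Y = partial$DMSO, X = partial$X))
  expect_true(all(cre_distances(mfa2)[, "Y"] == 0))
  # distances invariant to rotation of the selected subspace
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  rot <- lapply(partial, function(m) m %*% R)
  rot <- lapply(rot, function(m) { dimnames(m) <- dimnames(partial[[1]]); m })
  expect_equal(cre_distances(fake_mfa(rot)), d, tolerance = 1e-12)
  # guards
  mfa$selected_dims <- integer(0)
  expect_error(cre_distances(mfa), "selected")
  expect_error(cre_distances(fake_mfa(partial), vehicle = "nope"), "vehicle")
})

test_that("signCCDF combines tail probability and delta-z sign", {
  fx <- small_fixture(41, n_cres = 200, n_inhibitors = 4)
  std <- standardize_tables(fx$tables)
  fit <- mfa_fit(std)
  fit$selected_dims <- 1:2
  d <- cre_distances(fit)
  sc <- score_perturbations(d, std)
  # identity: score = -log10(ccdf) * sign(delta_z), zero when delta_z = 0
  expected <- -log10(sc$ccdf) * sign(sc$delta_z)
  expected[sc$delta_z == 0] <- 0
  expect_equal(sc$score, expected, tolerance = 1e-12)
  expect_true(all(sc$ccdf > 0 & sc$ccdf <= 1))
  expect_true(all(sc$distance >= 0))
  # a cell at the 0.1 upper-tail with negative delta_z scores exactly -1:
  # check through the identity at the fitted null
  i <- which(sc$delta_z < 0)[1]
  q10 <- exp(unname(sc$log_null["mean"] + qnorm(0.9) * sc$log_null["sd"]))
  z <- (log(q10) - unname(sc$log_null["mean"])) / unname(sc$log_null["sd"])
  expect_equal(-log10(pnorm(z, lower.tail = FALSE)) * -1, -1, tolerance = 1e-12)
  expect_lt(sc$score[i], 0)
})

test_that("zero distances are guarded and degenerate input errors", {
  fx <- small_fixture(42, n_cres = 100, n_inhibitors = 4)
  std <- standardize_tables(fx$tables)
  fit <- mfa_fit(std)
  fit$selected_dims <- 1:2
  d <- cre_distances(fit)
  d[1, 1] <- 0
  expect_silent(sc <- score_perturbations(d, std))
  expect_true(is.finite(sc$score[1, 1]))
  expect_error(score_perturbations(d * 0, std), "degenerate|zero")
})

test_that("event calling thresholds scores and counts per inhibitor", {
  s <- matrix(c(0.99, -1.01, 1.5, 0, -0.5, 2.2), 3, 2,
              dimnames = list(c("c1", "c2", "c3"), c("A", "B")))
  calls <- call_events(fake_scores(s), threshold = 1)
  expect_equal(calls$calls["c1", "A"], "none")   # 0.99 below threshold
  expect_equal(calls$calls["c2", "A"], "down")   # -1.01
  expect_equal(calls$calls["c3", "A"], "up")
  expect_equal(calls$summary$up, c(1, 1))
  expect_equal(calls$summary$down, c(1, 0))
  expect_error(call_events(fake_scores(s), threshold = 0), "threshold")
  sets <- affected_sets(calls)
  expect_equal(sets[["A.down"]], "c2")
  expect_equal(sets[["B.up"]], "c3")
})

test_that("scores recover injected effects on the wired fixture", {
  fx <- small_fixture(43, n_cres = 800, n_inhibitors = 6, n_kinases = 6,
                      n_programs = 3, offtarget_rate = 0.1)
  norm <- normalize_tables(fx$tables)
  std <- standardize_tables(norm$tables)
  fit <- mfa(std, n_perm = 100, alpha = 0.01, seed = 44)
  sc <- score_perturbations(cre_distances(fit), std)
  E <- fx$truth$effect_matrix[rownames(sc$score), ]
  s <- abs(sc$score)
  idx <- E != 0
  # perturbed cells rank above unperturbed ones
  expect_gt(rank_auroc(as.numeric(s), as.logical(idx)), 0.85)
  # group-level monotonicity: mean |score| per (program, inhibitor) group
  # increases with the group's injected |effect|
  prog <- rep(NA_character_, nrow(E))
  names(prog) <- rownames(E)
  for (p in names(fx$wiring$program_cres)) {
    prog[intersect(fx$wiring$program_cres[[p]], rownames(E))] <- p
  }
  grp <- paste(prog[row(E)], colnames(E)[col(E)])
  gs <- tapply(s[idx], grp[idx], mean)
  ge <- tapply(abs(E[idx]), grp[idx], mean)
  expect_gt(cor(gs, ge, method = "spearman"), 0.7)
  # direction calls match the injected sign for strong effects
  calls <- call_events(sc)
  strong <- abs(E) >= 0.7
  called <- calls$calls[strong]
  truth_dir <- ifelse(E[strong] > 0, "up", "down")
  agree <- mean(called[called != "none"] == truth_dir[called != "none"])
  expect_gt(agree, 0.95)
})

test_that("flipping all injected effects flips call directions", {
  w <- generate_wiring(500, 4, 4, 2, offtarget_rate = 0, up_frac = 0, seed = 45)
  run <- function(wir) {
    # no depth variation, no normalization: isolates scoring symmetry from
    # the (documented) absorption behavior of invariant normalization
    sim <- generate_counts(wir, depth_sd = 0, seed = 46)
    std <- standardize_tables(sim$tables)
    fit <- mfa_fit(std)
    fit$selected_dims <- 1:2
    call_events(score_perturbations(cre_distances(fit), std))
  }
  c_dn <- run(w)
  w_up <- w
  w_up$programs$direction <- -w_up$programs$direction  # all programs now up
  c_up <- run(w_up)
  sim <- generate_counts(w, depth_sd = 0, seed = 46)
  E <- sim$truth$effect_matrix[rownames(c_dn$calls), ]
  # calls at injected cells follow the injected sign, and flip with it
  called_dn <- c_dn$calls[E != 0]
  called_up <- c_up$calls[E != 0]
  expect_gt(mean(called_dn[called_dn != "none"] == "down"), 0.95)
  expect_gt(mean(called_up[called_up != "none"] == "up"), 0.95)
  # event budgets at injected cells are on the same order in mirrored runs
  expect_lt(abs(log(sum(called_dn != "none") / sum(called_up != "none"))),
            log(3))
})
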