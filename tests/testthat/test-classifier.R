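# Feature extraction, class weights, training/evaluation and directional
# importance.

test_that("feature space keeps components by variance share", {
  set.seed(81)
  n <- 100
  c1 <- rnorm(n); c1 <- (c1 - mean(c1)) / sd(c1) * 2
  c2 <- residuals(lm(rnorm(n) ~ c1)); c2 <- c2 / sd(c2)
  X <- cbind(a = c1, b = c2)
  rownames(X) <- sprintf("r%03d", seq_len(n))
  fs <- build_feature_space(list(tab = X), standardize = "none")
  expect_equal(unname(fs$variance_explained), c(0.8, 0.2), tolerance = 1e-8)
  expect_equal(ncol(fs$features), 2)
  # duplicating the table leaves variance shares unchanged (equal footing)
  fs2 <- build_feature_space(list(tab = X, tab2 = X), standardize = "none")
  expect_equal(unname(fs2$variance_explained[1:2]),
               unname(fs$variance_explained), tolerance = 1e-8)
  # descriptors: correlations in [-1, 1], strongest column tracks its dim
  expect_true(all(abs(fs$descriptors$correlations) <= 1 + 1e-12))
  expect_gt(abs(fs$descriptors$correlations["tab.a", 1]), 0.99)
  expect_error(build_feature_space(list(tab = X), min_var = 1.0,
                                   standardize = "none"), "min_var")
})

test_that("v-test flags components separating a categorical grouping", {
  set.seed(82)
  g <- factor(rep(c("peak", "no"), each = 50))
  x <- rnorm(100) + 2 * (g == "peak")
  v <- v_test(x, g)
  expect_gt(v["peak"], 5)
  expect_lt(v["no"], -5)
  # null grouping is near zero
  v0 <- v_test(rnorm(100), g)
  expect_lt(max(abs(v0)), 4)
})

test_that("class weights reproduce the printed formulas and identities", {
  w <- class_weights(80, 15, 5)
  expect_equal(c(w$w0s, w$wds, w$wus), c(0.2, 0.6, 0.2), tolerance = 1e-12)
  expect_equal(class_weights(50, 25, 25)$w0s, 0.5, tolerance = 1e-12)
  expect_equal(class_weights(50, 25, 25)$wds, 0.25, tolerance = 1e-12)
  # sum to 1 for random admissible triples; swap and ordering identities
  set.seed(83)
  for (i in 1:20) {
    n0 <- sample(5:200, 1); nd <- sample(0:50, 1); nu <- sample(0:50, 1)
    if (nd + nu == 0) nu <- 1
    w <- class_weights(n0, nd, nu)
    expect_lt(abs(w$w0s + w$wds + w$wus - 1), 1e-12)
    ws <- class_weights(n0, nu, nd)
    expect_equal(ws$w0s, w$w0s, tolerance = 1e-12)
    if (nd != nu) expect_equal(w$wds > w$wus, nd > nu)
    if (nd > 0 && nu > 0) expect_equal(w$wds / w$wus, nd / nu, tolerance = 1e-9)
  }
  expect_error(class_weights(0, 5, 5), "n0")
  expect_error(class_weights(10, 0, 0), "affected")
})

test_that("stratified split preserves class proportions and errors on tiny classes", {
  labels <- factor(rep(c("down", "none", "up"), times = c(30, 200, 20)))
  ev_idx <- epiperturb:::stratified_split(labels, split = 0.7, seed = 84)
  expect_equal(sum(labels[ev_idx] == "down"), round(0.7 * 30))
  expect_equal(sum(labels[ev_idx] == "none"), round(0.7 * 200))
  expect_equal(sum(labels[ev_idx] == "up"), round(0.7 * 20))
  expect_identical(ev_idx, epiperturb:::stratified_split(labels, 0.7, seed = 84))
  tiny <- factor(c("down", rep("none", 10), rep("up", 5)),
                 levels = c("down", "none", "up"))
  expect_error(epiperturb:::stratified_split(tiny, 0.7, 1), "absent")
})

test_that("separable labels are learned; shuffled labels are not", {
  set.seed(85)
  n <- 400
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  labels <- ifelse(x[, 1] > 1, "up", ifelse(x[, 1] < -1, "down", "none"))
  grid1 <- expand.grid(max_depth = 3, eta = 0.3, nrounds = 60)
  ev <- train_eval(x, labels, seed = 86, grid = grid1)
  expect_true(all(ev$metrics$roc_auc > 0.97))
  expect_equal(ev$metrics$class, c("down", "none", "up"))
  # shuffled labels hover at chance
  rocs <- unlist(lapply(1:10, function(i) {
    set.seed(86 + i)
    train_eval(x, sample(labels), seed = 86 + i, grid = grid1)$metrics$roc_auc
  }))
  expect_lt(abs(mean(rocs) - 0.5), 0.06)
  # custom weights flow through: heavier down weight than up when nd > nu
  expect_gt(ev$weights$wds, ev$weights$wus)
  # custom backend closure is honored
  ev2 <- train_eval(x, labels, seed = 87,
                    backend = function(xtr, ytr, wtr) {
                      mu <- tapply(xtr[, 1], ytr, mean)
                      function(xn) {
                        d <- -abs(outer(xn[, 1], mu, "-"))
                        p <- exp(d); p / rowSums(p)
                      }
                    })
  expect_true(all(ev2$metrics$roc_auc > 0.9))
})

test_that("directional importance follows scaling/sign rules and the Shapley oracle", {
  set.seed(88)
  n <- 60
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  # synthetic additive attributions: A = a_j * x_j column-wise
  A_up <- cbind(2 * x[, 1], -0.5 * x[, 2], 0 * x[, 3])
  di <- directional_importance(list(up = A_up), x)
  expect_equal(di["f1", "up"], 1)    # largest mean |attr|, positive corr
  expect_equal(di["f3", "up"], 0)    # all-zero attribution
  expect_lt(di["f2", "up"], 0)       # negative value-attribution corr
  expect_true(all(abs(di) <= 1))
  expect_error(directional_importance(list(up = A_up[, 1:2]), x), "match")
  # invariant to observation order
  ord <- sample(n)
  di2 <- directional_importance(list(up = A_up[ord, ]), x[ord, ])
  expect_equal(di2, di, tolerance = 1e-12)

  # tree-model attributions agree with exact Shapley on a 3-feature model
  labels <- ifelse(2 * x[, 1] - x[, 2] + rnorm(n, sd = 0.1) > 0.5, "up",
                   ifelse(2 * x[, 1] - x[, 2] < -0.5, "down", "none"))
  if (min(table(labels)) >= 5) {
    ev <- train_eval(x, labels, seed = 89,
                     grid = expand.grid(max_depth = 3, eta = 0.3, nrounds = 50))
    at <- shap_attributions(ev, x)
    up_col <- which(ev$levels == "up")
    margin_fun <- function(X) {
      colnames(X) <- colnames(x)
      pr <- predict(ev$model, xgboost::xgb.DMatrix(X), outputmargin = TRUE)
      pr[, up_col]
    }
    idx <- sample(n, 15)
    phi <- t(vapply(idx, function(i) exact_shapley(margin_fun, x[i, ], x),
                    numeric(3)))
    mean_pkg <- colMeans(abs(at$up[idx, ]))
    mean_oracle <- colMeans(abs(phi))
    expect_equal(order(mean_pkg), order(mean_oracle))
    for (j in 1:2) {
      # f3 is unused by the model, so only the informative features carry a
      # well-defined attribution sign
      expect_equal(sign(suppressWarnings(cor(x[idx, j], at$up[idx, j]))),
                   sign(suppressWarnings(cor(x[idx, j], phi[, j]))))
    }
  }
})
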