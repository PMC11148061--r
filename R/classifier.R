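# Multi-class prediction of per-CRE perturbation direction from kinetic and
# TF-binding features: MFA-based feature extraction, the custom imbalance
# weights, stratified training/evaluation with gradient-boosted trees, and
# directional (signed) feature importance from additive attributions.

#' Build an MFA feature space from grouped source tables
#'
#' Runs MFA over the grouped source tables (one table per assay/group,
#' sharing the CRE universe), keeps the dimensions explaining at least
#' `min_var` of the variance and describes each kept component by its
#' correlation with every source column; columns of tables listed in
#' `categorical` are additionally described by the group-mean standardized
#' statistic (v-test) contrasting CREs in each category against all CREs.
#'
#' @param tables named list of numeric matrices with identical rownames.
#' @param min_var minimum variance share for a component to be kept
#'   (default 0.01).
#' @param categorical character vector of table names whose columns are
#'   0/1 or categorical (e.g. peak presence), described by v-tests instead
#'   of correlations.
#' @param standardize `"joint"` (default) or `"per_table"` row
#'   standardization via [standardize_tables()], or `"none"` to take the
#'   tables as-is (for engineered features already on comparable scales; also
#'   accepts a single table).
#' @return An object of class `feature_space`: `features` (CRE x kept
#'   component), `variance_explained` (shares of kept components),
#'   `eigenvalues`, `descriptors` (`correlations` matrix source column x
#'   component and `vtests` list), and the underlying `mfa` result.
#' @export
build_feature_space <- function(tables, min_var = 0.01, categorical = NULL,
                                standardize = c("joint", "per_table", "none")) {
  standardize <- match.arg(standardize)
  std <- if (standardize == "none") {
    rn <- rownames(tables[[1]])
    if (is.null(rn)) stopf("tables must have rownames")
    for (m in tables) {
      if (!identical(rownames(m), rn)) stopf("all tables must share identical row order")
    }
    structure(list(tables = tables, row_mean = NULL, row_sd = NULL,
                   dropped = character(0), conditions = names(tables),
                   vehicle = NULL, time_points = NULL, joint = FALSE),
              class = "standardized_set")
  } else {
    standardize_tables(tables, joint = standardize == "joint")
  }
  fit <- mfa_fit(std)
  shares <- fit$var_explained
  keep <- which(shares >= min_var)
  if (length(keep) == 0L) {
    stopf("no MFA dimension reaches a variance share of %g: lower `min_var`", min_var)
  }
  keep <- keep[keep <= ncol(fit$compromise_scores)]
  features <- fit$compromise_scores[, keep, drop = FALSE]

  src <- do.call(cbind, lapply(names(std$tables), function(nm) {
    m <- std$tables[[nm]]
    colnames(m) <- paste(nm, colnames(m) %||% seq_len(ncol(m)), sep = ".")
    m
  }))
  correlations <- cor(src, features)

  vtests <- NULL
  if (!is.null(categorical)) {
    vtests <- list()
    for (nm in intersect(categorical, names(tables))) {
      m <- tables[[nm]][rownames(features), , drop = FALSE]
      for (j in seq_len(ncol(m))) {
        groups <- factor(m[, j])
        key <- paste(nm, colnames(m)[j] %||% j, sep = ".")
        vtests[[key]] <- apply(features, 2, function(sc) v_test(sc, groups))
      }
    }
  }
  structure(list(features = features, variance_explained = shares[keep],
                 eigenvalues = fit$eigenvalues,
                 descriptors = list(correlations = correlations,
                                    vtests = vtests),
                 mfa = fit, min_var = min_var),
            class = "feature_space")
}

#' Group-mean standardized statistic (v-test)
#'
#' For each level g of a categorical variable over observations, the
#' standardized deviation of the group mean from the overall mean:
#' `v = (mean_g - mean) / sqrt(((N - n_g) / (N - 1)) * var / n_g)`,
#' approximately standard normal under random assignment.
#'
#' @param x numeric vector (e.g. component scores per CRE).
#' @param groups factor of the same length.
#' @return Named numeric vector, one v statistic per level.
#' @export
v_test <- function(x, groups) {
  groups <- as.factor(groups)
  N <- length(x)
  xbar <- mean(x)
  v <- var(x) * (N - 1) / N  # population variance
  vapply(levels(groups), function(g) {
    ng <- sum(groups == g)
    if (ng == 0L || ng == N) return(NA_real_)
    (mean(x[groups == g]) - xbar) / sqrt(((N - ng) / (N - 1)) * v / ng)
  }, numeric(1))
}

#' Custom class weights for imbalanced perturbation classes
#'
#' The weighting used for the three perturbation classes (unaffected, down,
#' up): `w0 = n / (2 n0)` for unaffected, `w_eff = n / (2 (n - n0))` for
#' affected, split between up and down in proportion to their counts
#' (`w_u = n_u / (n_d + n_u) * w_eff`, `w_d = n_d / (n_d + n_u) * w_eff`),
#' then scaled so the three weights sum to 1. Within changing observations
#' the larger class therefore gets the larger weight.
#'
#' @param n0,nd,nu counts of unaffected, down-regulated and up-regulated
#'   observations.
#' @return An object of class `class_weights`: counts, raw weights (`w0`,
#'   `w_eff`, `w_u`, `w_d`) and scaled weights (`w0s`, `wds`, `wus`, summing
#'   to 1).
#' @examples
#' w <- class_weights(80, 15, 5)
#' c(w$w0s, w$wds, w$wus)  # 0.2 0.6 0.2
#' @export
class_weights <- function(n0, nd, nu) {
  for (v in list(n0 = n0, nd = nd, nu = nu)) {
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != floor(v)) {
      stopf("class counts must be non-negative integers")
    }
  }
  n <- n0 + nd + nu
  if (n < 3L) stopf("need at least 3 observations")
  if (n0 == 0L) stopf("no unaffected observations (n0 = 0)")
  if (nd + nu == 0L) stopf("no affected observations (nd + nu = 0)")
  w0 <- n / (2 * n0)
  w_eff <- n / (2 * (n - n0))
  w_u <- nu / (nd + nu) * w_eff
  w_d <- nd / (nd + nu) * w_eff
  s <- w0 + w_u + w_d
  structure(list(n_samples = n, n0 = n0, nd = nd, nu = nu,
                 w0 = w0, w_eff = w_eff, w_u = w_u, w_d = w_d,
                 w0s = w0 / s, wds = w_d / s, wus = w_u / s),
            class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf("class_weights (n = %d): none %.3f, down %.3f, up %.3f (sum 1)\n",
              x$n_samples, x$w0s, x$wds, x$wus))
  invisible(x)
}

# Stratified index split: per class, round(split * n_class) observations go
# to training; both splits must contain every class.
stratified_split <- function(labels, split = 0.7, seed = 1) {
  labels <- as.factor(labels)
  with_seed(seed, {
    train <- unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      n_tr <- round(split * length(idx))
      if (n_tr == 0L || n_tr == length(idx)) {
        stopf(paste("class `%s` would be absent from one split;",
                    "collect more observations or change `split`"), cl)
      }
      sample(idx, n_tr)
    }), use.names = FALSE)
    sort(train)
  })
}

# Area under the precision-recall curve (average-precision estimator)
pr_auc <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  y <- positive[ord]
  n_pos <- sum(y)
  if (n_pos == 0L || n_pos == length(y)) return(NA_real_)
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision[y == 1]) / n_pos
}

#' Train and evaluate a perturbation-direction classifier
#'
#' Stratified 70/30 split, per-observation weights from the custom class
#' weights, a gradient-boosted-tree multi-class model tuned on a small grid
#' by 3-fold stratified cross-validation (selection criterion: balanced
#' accuracy, the mean of per-class recalls), and one-vs-rest ROC-AUC and
#' PR-AUC per class on the held-out set.
#'
#' @param features numeric matrix (observations x features) or a
#'   `feature_space`.
#' @param labels factor/character with values in down / none / up.
#' @param weights a `class_weights` object, or `NULL` to derive it from the
#'   label counts.
#' @param split training fraction (default 0.7).
#' @param seed integer RNG seed (split, CV folds and model fitting).
#' @param backend `"xgboost"` (default) or a function
#'   `f(x_train, y_train, w_train)` returning a prediction function
#'   `g(x_new)` that yields an observation x class probability matrix.
#' @param grid data frame of hyperparameter candidates with columns
#'   `max_depth`, `eta`, `nrounds`; default
#'   `expand.grid(max_depth = c(3, 6), eta = c(0.05, 0.1), nrounds = c(100, 300))`.
#' @param nthread threads for the tree backend (default 1, reproducible).
#' @return An object of class `cki_classifier_eval`: `metrics` (data frame
#'   class, roc_auc, pr_auc), `best_params`, `model` (the fitted booster or
#'   backend closure), `predict` (function mapping a feature matrix to class
#'   probabilities), `train_idx`, `levels`, `weights`.
#' @export
train_eval <- function(features, labels, weights = NULL, split = 0.7,
                       seed = 1, backend = "xgboost", grid = NULL,
                       nthread = 1) {
  x <- if (inherits(features, "feature_space")) features$features else features
  stopifnot(is.matrix(x))
  lv <- c("down", "none", "up")
  labels <- factor(as.character(labels), levels = lv)
  if (anyNA(labels)) stopf("labels must be down / none / up")
  if (nrow(x) != length(labels)) stopf("features and labels disagree in length")
  if (is.null(weights)) {
    weights <- class_weights(sum(labels == "none"), sum(labels == "down"),
                             sum(labels == "up"))
  }
  stopifnot(inherits(weights, "class_weights"))
  w_by_class <- c(down = weights$wds, none = weights$w0s, up = weights$wus)
  obs_w <- w_by_class[as.character(labels)]
  # relative class weights are what matter for the loss; rescale to mean 1 so
  # absolute-scale knobs (min_child_weight) keep their usual meaning
  obs_w <- obs_w / mean(obs_w)

  train_idx <- stratified_split(labels, split = split, seed = seed)
  test_idx <- setdiff(seq_len(nrow(x)), train_idx)
  if (nlevels(droplevels(labels[test_idx])) < nlevels(droplevels(labels))) {
    stopf("a class is absent from the test split; change `split` or `seed`")
  }

  fit_predict <- NULL
  best_params <- NULL
  model <- NULL
  if (is.function(backend)) {
    model <- backend(x[train_idx, , drop = FALSE], labels[train_idx],
                     obs_w[train_idx])
    fit_predict <- model
  } else if (identical(backend, "xgboost")) {
    if (is.null(grid)) {
      grid <- expand.grid(max_depth = c(3, 6), eta = c(0.05, 0.1),
                          nrounds = c(100, 300))
    }
    fit_xgb <- function(idx, params, nrounds) {
      dtr <- xgboost::xgb.DMatrix(x[idx, , drop = FALSE],
                                  label = as.integer(labels[idx]) - 1L,
                                  weight = obs_w[idx])
      xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds,
                         verbose = 0)
    }
    base_params <- list(objective = "multi:softprob", num_class = 3L,
                        subsample = 0.8, colsample_bytree = 0.8,
                        min_child_weight = 4, nthread = nthread,
                        seed = seed)
    if (nrow(grid) > 1L) {
      folds <- with_seed(seed + 1L, {
        f <- integer(length(train_idx))
        for (cl in lv) {
          pos <- which(labels[train_idx] == cl)
          f[pos] <- sample(rep_len(1:3, length(pos)))
        }
        f
      })
      cv_score <- vapply(seq_len(nrow(grid)), function(g) {
        params <- utils::modifyList(base_params,
                                    list(max_depth = grid$max_depth[g],
                                         eta = grid$eta[g]))
        accs <- vapply(1:3, function(k) {
          tr <- train_idx[folds != k]
          ho <- train_idx[folds == k]
          bst <- fit_xgb(tr, params, grid$nrounds[g])
          pr <- predict(bst, xgboost::xgb.DMatrix(x[ho, , drop = FALSE]))
          pred <- lv[max.col(pr)]
          mean(vapply(lv[table(labels[ho]) > 0], function(cl) {
            mean(pred[labels[ho] == cl] == cl)
          }, numeric(1)))
        }, numeric(1))
        mean(accs)
      }, numeric(1))
      best <- which.max(cv_score)
    } else {
      best <- 1L
    }
    best_params <- grid[best, , drop = FALSE]
    params <- utils::modifyList(base_params,
                                list(max_depth = best_params$max_depth,
                                     eta = best_params$eta))
    model <- fit_xgb(train_idx, params, best_params$nrounds)
    fit_predict <- function(x_new) {
      pr <- predict(model, xgboost::xgb.DMatrix(x_new))
      colnames(pr) <- lv
      pr
    }
  } else {
    stopf("unknown backend")
  }

  probs <- fit_predict(x[test_idx, , drop = FALSE])
  if (is.null(colnames(probs))) colnames(probs) <- lv
  metrics <- do.call(rbind, lapply(lv, function(cl) {
    truth <- as.integer(labels[test_idx] == cl)
    roc <- as.numeric(pROC::auc(pROC::roc(truth, probs[, cl], quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    data.frame(class = cl, roc_auc = roc,
               pr_auc = pr_auc(probs[, cl], truth),
               n_test = sum(truth), stringsAsFactors = FALSE)
  }))
  structure(list(metrics = metrics, best_params = best_params, model = model,
                 predict = fit_predict, train_idx = train_idx,
                 test_idx = test_idx, levels = lv, weights = weights),
            class = "cki_classifier_eval")
}

#' @export
print.cki_classifier_eval <- function(x, ...) {
  cat("cki_classifier_eval:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Per-class additive attributions from a tree model
#'
#' Tree-path (SHAP) contributions of every feature to every test observation
#' and class, from the fitted gradient-boosted model.
#'
#' @param eval a `cki_classifier_eval` fitted with the xgboost backend.
#' @param features observation x feature matrix to explain.
#' @return Named list (one per class) of observation x feature attribution
#'   matrices (bias column removed).
#' @export
shap_attributions <- function(eval, features) {
  stopifnot(inherits(eval, "cki_classifier_eval"))
  if (!inherits(eval$model, "xgb.Booster")) {
    stopf("attributions require the xgboost backend")
  }
  contrib <- predict(eval$model, xgboost::xgb.DMatrix(features),
                     predcontrib = TRUE)
  feat_names <- colnames(features)
  if (is.array(contrib) && length(dim(contrib)) == 3L) {
    # observations x class x (feature, intercept)
    out <- lapply(seq_len(dim(contrib)[2]), function(cl) {
      m <- contrib[, cl, seq_along(feat_names), drop = FALSE]
      dim(m) <- c(dim(contrib)[1], length(feat_names))
      colnames(m) <- feat_names
      m
    })
  } else {
    if (!is.list(contrib)) contrib <- list(contrib)
    out <- lapply(contrib, function(m) {
      m[, intersect(colnames(m), feat_names), drop = FALSE]
    })
  }
  names(out) <- eval$levels[seq_along(out)]
  out
}

#' Directional feature importance
#'
#' For each class, the mean absolute attribution of every feature, min-max
#' scaled across features to [0, 1] and multiplied by the sign of the
#' correlation between feature value and attribution — positive importance
#' means high feature values push predictions toward the class.
#'
#' @param attributions list (one per class) of observation x feature
#'   attribution matrices, e.g. from [shap_attributions()] or any additive
#'   explanation backend.
#' @param features observation x feature matrix the attributions were
#'   computed on.
#' @return Numeric matrix feature x class in [-1, 1].
#' @export
directional_importance <- function(attributions, features) {
  stopifnot(is.list(attributions), is.matrix(features))
  p <- ncol(features)
  out <- matrix(NA_real_, p, length(attributions),
                dimnames = list(colnames(features), names(attributions)))
  for (cl in seq_along(attributions)) {
    A <- attributions[[cl]]
    if (!is.matrix(A) || nrow(A) != nrow(features) || ncol(A) != p) {
      stopf("attribution matrix %d does not match the feature matrix", cl)
    }
    mi <- colMeans(abs(A))
    rng <- range(mi)
    scaled <- if (rng[2] > rng[1]) (mi - rng[1]) / (rng[2] - rng[1]) else rep(0, p)
    sgn <- vapply(seq_len(p), function(j) {
      if (sd(features[, j]) <= 0 || sd(A[, j]) <= 0) return(0)
      sign(cor(features[, j], A[, j]))
    }, numeric(1))
    out[, cl] <- scaled * sgn
  }
  out
}
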