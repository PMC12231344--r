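#' Specify one of the four tree-ensemble classifiers
#'
#' The bank covers four families: `random_forest`, `extra_trees`
#' (extremely randomized trees), `hist_gradient_boosting` (histogram-based
#' gradient boosting, LightGBM-style leaf-wise growth), and
#' `regularized_gradient_boosting` (XGBoost-style depth-wise boosting with
#' column/row subsampling). Default hyperparameters are the published
#' settings for each family; see [default_hyperparameters()]. Keys are
#' given in the conventional names of those tools and mapped to the R
#' backend (ranger for the two forests, xgboost for the two boosters)
#' through a translation table — unsupported keys raise an error rather
#' than being silently dropped.
#'
#' @param family One of the four family names.
#' @param hyperparameters Named list; defaults to
#'   `default_hyperparameters(family)`.
#' @param cv_folds Folds for cross-validated grid selection (>= 2).
#' @param oversample Randomly duplicate minority-class instances in
#'   training folds (and the final training set); evaluation data are
#'   never resampled.
#' @param seed Integer seed controlling every stochastic element of
#'   training.
#' @param grid Optional named list of hyperparameter value vectors to tune
#'   over by `cv_folds`-fold cross-validation, selecting by F1.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("random_forest", "extra_trees",
                                  "hist_gradient_boosting",
                                  "regularized_gradient_boosting"),
                       hyperparameters = NULL, cv_folds = 5L,
                       oversample = TRUE, seed = 1L, grid = NULL) {
  family <- match.arg(family)
  stopifnot(cv_folds >= 2L)
  hp <- default_hyperparameters(family)
  if (!is.null(hyperparameters)) {
    unknown <- setdiff(names(hyperparameters), names(hp))
    hp[names(hyperparameters)] <- hyperparameters
    if (length(unknown))
      hp <- c(hp, hyperparameters[unknown])
  }
  translate_hyperparameters(family, hp) # validate early
  if (!is.null(grid)) {
    stopifnot(is.list(grid), !is.null(names(grid)))
  }
  structure(list(family = family, hyperparameters = hp,
                 cv_folds = as.integer(cv_folds),
                 oversample = isTRUE(oversample),
                 seed = as.integer(seed), grid = grid),
            class = "model_spec")
}

#' Published default hyperparameters per model family
#'
#' @param family Model family name.
#' @return Named list of hyperparameters in the family's conventional
#'   key names.
#' @export
default_hyperparameters <- function(family) {
  switch(family,
    random_forest = list(criterion = "gini", max_features = "sqrt",
                         n_estimators = 500L, class_weight = "balanced"),
    extra_trees = list(n_estimators = 500L, class_weight = "balanced"),
    hist_gradient_boosting = list(objective = "binary", is_unbalance = TRUE,
                                  metric = "f1", max_depth = 5L,
                                  num_leaves = 31L, learning_rate = 0.01,
                                  reg_alpha = 0.9, reg_lambda = 1,
                                  num_iterations = 5000L),
    regularized_gradient_boosting = list(objective = "binary:logistic",
                                         max_depth = 6L,
                                         learning_rate = 0.01,
                                         n_estimators = 5000L,
                                         colsample_bytree = 0.4,
                                         subsample = 0.8),
    stop("unknown family: ", family, call. = FALSE))
}

# Map conventional hyperparameter keys onto backend arguments. Returns
# list(ranger = <args>) or list(xgb_params = <params>, nrounds = <n>,
# selection_metric = <chr>). Unknown keys are an error: never silently
# dropped.
translate_hyperparameters <- function(family, hp) {
  forest <- family %in% c("random_forest", "extra_trees")
  known <- if (forest) {
    c("criterion", "max_features", "max_feature", "n_estimators",
      "class_weight")
  } else {
    c("objective", "is_unbalance", "metric", "max_depth", "num_leaves",
      "learning_rate", "reg_alpha", "reg_lambda", "num_iterations",
      "n_estimators", "colsample_bytree", "subsample", "scale_pos_weight")
  }
  unknown <- setdiff(names(hp), known)
  if (length(unknown))
    stop("hyperparameter key(s) not supported for family '", family, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (forest) {
    crit <- hp$criterion %||% "gini"
    if (!identical(crit, "gini"))
      stop("only criterion='gini' is supported for forest families",
           call. = FALSE)
    args <- list(num.trees = as.integer(hp$n_estimators %||% 500L),
                 balanced = identical(hp$class_weight, "balanced"),
                 mtry_rule = hp$max_features %||% hp$max_feature %||% "sqrt")
    if (family == "extra_trees") {
      args$splitrule <- "extratrees"
      args$num.random.splits <- 1L
      args$replace <- FALSE
      args$sample.fraction <- 1
    } else {
      args$splitrule <- "gini"
      args$replace <- TRUE
      args$sample.fraction <- 1
    }
    return(list(ranger = args))
  }
  obj <- hp$objective %||% "binary:logistic"
  if (!obj %in% c("binary", "binary:logistic"))
    stop("only binary objectives are supported", call. = FALSE)
  params <- list(objective = "binary:logistic",
                 eta = hp$learning_rate %||% 0.3,
                 nthread = 1L)
  if (!is.null(hp$max_depth)) params$max_depth <- as.integer(hp$max_depth)
  if (!is.null(hp$reg_alpha)) params$alpha <- hp$reg_alpha
  if (!is.null(hp$reg_lambda)) params$lambda <- hp$reg_lambda
  if (!is.null(hp$colsample_bytree)) params$colsample_bytree <- hp$colsample_bytree
  if (!is.null(hp$subsample)) params$subsample <- hp$subsample
  if (!is.null(hp$scale_pos_weight)) params$scale_pos_weight <- hp$scale_pos_weight
  if (family == "hist_gradient_boosting") {
    params$tree_method <- "hist"
    params$grow_policy <- "lossguide"
    if (!is.null(hp$num_leaves)) params$max_leaves <- as.integer(hp$num_leaves)
  }
  nrounds <- as.integer(hp$num_iterations %||% hp$n_estimators %||% 100L)
  list(xgb_params = params, nrounds = nrounds,
       selection_metric = hp$metric %||% "f1",
       is_unbalance = isTRUE(hp$is_unbalance))
}

# Indices that balance the classes by duplicating minority instances.
oversample_indices <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0L)) return(seq_along(y))
  minority <- as.integer(names(tab)[which.min(tab)])
  deficit <- abs(diff(as.integer(tab)))
  if (deficit == 0L) return(seq_along(y))
  extra <- sample(which(y == minority), deficit, replace = TRUE)
  c(seq_along(y), extra)
}

fit_backend <- function(spec, x, y) {
  tr <- translate_hyperparameters(spec$family, spec$hyperparameters)
  if (!is.null(tr$ranger)) {
    a <- tr$ranger
    mtry <- if (identical(a$mtry_rule, "sqrt")) max(1L, floor(sqrt(ncol(x))))
            else as.integer(a$mtry_rule)
    cw <- if (a$balanced) {
      tab <- table(factor(y, levels = c(0, 1)))
      as.numeric(length(y) / (2 * tab))
    } else c(1, 1)
    fit <- ranger::ranger(
      x = as.data.frame(x, check.names = FALSE),
      y = factor(y, levels = c(0, 1)),
      num.trees = a$num.trees, mtry = mtry, splitrule = a$splitrule,
      num.random.splits = a$num.random.splits %||% 1L,
      replace = a$replace, sample.fraction = a$sample.fraction,
      class.weights = cw, importance = "impurity",
      probability = TRUE, seed = spec$seed, num.threads = 1L)
    return(list(backend = "ranger", fit = fit))
  }
  params <- tr$xgb_params
  if (tr$is_unbalance && is.null(params$scale_pos_weight)) {
    npos <- sum(y == 1); nneg <- sum(y == 0)
    params$scale_pos_weight <- if (npos > 0) nneg / npos else 1
  }
  params$seed <- spec$seed
  set.seed(spec$seed)
  fit <- xgboost::xgb.train(params = params,
                            data = xgboost::xgb.DMatrix(x, label = y),
                            nrounds = tr$nrounds, verbose = 0)
  list(backend = "xgboost", fit = fit)
}

score_backend <- function(model, x) {
  if (model$backend == "ranger") {
    p <- stats::predict(model$fit, as.data.frame(x, check.names = FALSE),
                        num.threads = 1L)$predictions
    unname(p[, "1"])
  } else {
    as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(x)))
  }
}

#' Train one classifier of the bank
#'
#' If the spec declares a tuning `grid`, each candidate is evaluated by
#' `cv_folds`-fold cross-validation on the training instances (minority
#' oversampling, when enabled, is applied inside each training fold only —
#' validation folds are never resampled) and the candidate with the best
#' mean F1 is selected. The final model is then refit on the full training
#' set (oversampled when enabled) with the selected hyperparameters.
#' Training is deterministic for a fixed spec and seed.
#'
#' @param spec A [model_spec()].
#' @param split A `dataset_split` from [split_instances()].
#' @return An object of class `comorisk_model` carrying the fitted backend,
#'   the feature column order, and the selected hyperparameters.
#' @export
train_model <- function(spec, split) {
  stopifnot(inherits(spec, "model_spec"), inherits(split, "dataset_split"))
  tv <- vectorize(split$train, split$vocabulary)
  if (length(unique(tv$y)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  sel_hp <- spec$hyperparameters
  cv <- NULL
  if (!is.null(spec$grid)) {
    cand <- expand.grid(spec$grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    folds <- sample(rep_len(seq_len(spec$cv_folds), length(tv$y)))
    f1s <- numeric(nrow(cand))
    for (ci in seq_len(nrow(cand))) {
      hp_ci <- sel_hp
      hp_ci[names(cand)] <- lapply(cand[ci, , drop = FALSE], identity)
      spec_ci <- spec; spec_ci$hyperparameters <- hp_ci
      fold_f1 <- vapply(seq_len(spec$cv_folds), function(f) {
        tr_i <- which(folds != f); va_i <- which(folds == f)
        if (spec$oversample) tr_i <- tr_i[oversample_indices(tv$y[tr_i])]
        m <- fit_backend(spec_ci, tv$x[tr_i, , drop = FALSE], tv$y[tr_i])
        s <- score_backend(m, tv$x[va_i, , drop = FALSE])
        mt <- compute_metrics(confusion_counts(as.integer(s >= 0.5),
                                               tv$y[va_i]))
        if (is.na(mt$f1)) 0 else mt$f1
      }, numeric(1))
      f1s[ci] <- mean(fold_f1)
    }
    best <- which.max(f1s)
    sel_hp[names(cand)] <- lapply(cand[best, , drop = FALSE], identity)
    cv <- list(candidates = cand, mean_f1 = f1s, selected = best)
  }
  spec_fit <- spec; spec_fit$hyperparameters <- sel_hp
  idx <- seq_along(tv$y)
  if (spec$oversample) idx <- idx[oversample_indices(tv$y)]
  fitted <- fit_backend(spec_fit, tv$x[idx, , drop = FALSE], tv$y[idx])
  structure(list(family = spec$family, spec = spec_fit,
                 backend = fitted$backend, fit = fitted$fit,
                 feature_names = colnames(tv$x),
                 vocabulary = split$vocabulary, cv = cv),
            class = "comorisk_model")
}

#' @export
print.comorisk_model <- function(x, ...) {
  cat("<comorisk_model>", x$family, "(", x$backend, "backend ),",
      length(x$feature_names), "features\n")
  invisible(x)
}

#' Predicted probability of the positive class
#'
#' @param object A `comorisk_model`.
#' @param instances Instance data.frame (vectorized against the model's
#'   vocabulary) or a pre-built numeric matrix with the model's columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.comorisk_model <- function(object, instances, ...) {
  x <- if (is.matrix(instances)) instances
       else vectorize(instances, object$vocabulary)$x
  stopifnot(identical(colnames(x), object$feature_names))
  score_backend(object, x)
}

#' Confusion counts and threshold metrics
#'
#' `confusion_counts()` tallies TP/FP/FN/TN from predicted and true 0/1
#' labels. `compute_metrics()` turns counts into accuracy
#' `(TP+TN)/(TP+FN+TN+FP)`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`
#' and the F1 harmonic mean `2PR/(P+R)`. A ratio with a zero denominator
#' is reported as `NA` ("undefined"), never coerced to 0.
#'
#' @param predicted,truth Integer 0/1 vectors of equal length.
#' @return `confusion_counts()`: object with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth),
            all(predicted %in% c(0, 1)), all(truth %in% c(0, 1)))
  structure(list(tp = sum(predicted == 1 & truth == 1),
                 fp = sum(predicted == 1 & truth == 0),
                 fn = sum(predicted == 0 & truth == 1),
                 tn = sum(predicted == 0 & truth == 0)),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param counts A `confusion_counts` object, or TP when giving the four
#'   counts positionally.
#' @param fp,fn,tn Remaining counts when `counts` is the TP count.
#' @return `compute_metrics()`: list with `accuracy`, `precision`,
#'   `recall`, `f1` (`NA` where undefined).
#' @examples
#' compute_metrics(3, 1, 2, 4)
#' @export
compute_metrics <- function(counts, fp = NULL, fn = NULL, tn = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- structure(list(tp = counts, fp = fp, fn = fn, tn = tn),
                        class = "confusion_counts")
  }
  with(counts, {
    if (any(c(tp, fp, fn, tn) < 0)) stop("negative counts", call. = FALSE)
    total <- tp + fp + fn + tn
    if (total == 0) stop("all-zero confusion counts", call. = FALSE)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    list(accuracy = (tp + tn) / total, precision = precision,
         recall = recall, f1 = f1)
  })
}

#' AUC, ROC curve and Youden-optimal threshold
#'
#' The AUC is computed by the rank (Mann-Whitney) formulation — the
#' probability that a random positive scores above a random negative, with
#' ties counting one half. ROC points are evaluated at every distinct
#' score; the optimal threshold maximizes Youden's J
#' (sensitivity + specificity - 1), ties broken toward higher specificity.
#'
#' @param scores Numeric predicted probabilities (or any monotone scores).
#' @param labels Integer 0/1 true labels; both classes must be present.
#' @return List with `auc`, `roc` (data.frame `threshold`, `tpr`, `fpr`),
#'   `optimal_threshold` and `youden_j`.
#' @examples
#' compute_auc(c(.9, .8, .7, .4, .3, .2), c(1, 1, 0, 1, 0, 0))$auc # 8/9
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  roc <- data.frame(threshold = thr, tpr = tpr, fpr = fpr)
  j <- tpr - fpr
  best_j <- max(j)
  cand <- which(j == best_j)
  cand <- cand[fpr[cand] == min(fpr[cand])] # higher specificity wins ties
  best <- cand[1L]
  list(auc = auc, roc = roc, optimal_threshold = thr[best],
       youden_j = best_j)
}

#' Evaluate a fitted model on held-out instances
#'
#' Scores the requested side of the split, thresholds at 0.5 for the
#' confusion-based metrics, and adds rank-based AUC with the
#' Youden-optimal threshold. `on = "cv"` reports metrics aggregated over
#' `cv_folds` cross-validation folds of the training set (training-fold
#' oversampling as in [train_model()]), for comparison with the held-out
#' numbers.
#'
#' @param model A `comorisk_model`.
#' @param split The `dataset_split` it was trained on.
#' @param on `"test"`, `"train"`, or `"cv"`.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `optimal_threshold`, plus the score vector and labels.
#' @export
evaluate_model <- function(model, split, on = c("test", "train", "cv")) {
  on <- match.arg(on)
  if (on == "cv") {
    tv <- vectorize(split$train, split$vocabulary)
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(model$spec$seed)
    folds <- sample(rep_len(seq_len(model$spec$cv_folds), length(tv$y)))
    scores <- numeric(length(tv$y))
    for (f in seq_len(model$spec$cv_folds)) {
      tr_i <- which(folds != f); va_i <- which(folds == f)
      if (model$spec$oversample) tr_i <- tr_i[oversample_indices(tv$y[tr_i])]
      m <- fit_backend(model$spec, tv$x[tr_i, , drop = FALSE], tv$y[tr_i])
      scores[va_i] <- score_backend(m, tv$x[va_i, , drop = FALSE])
    }
    y <- tv$y
  } else {
    inst <- if (on == "test") split$test else split$train
    y <- as.integer(inst$label)
    scores <- predict(model, inst)
  }
  mt <- compute_metrics(confusion_counts(as.integer(scores >= 0.5), y))
  au <- compute_auc(scores, y)
  c(mt, list(auc = au$auc, optimal_threshold = au$optimal_threshold,
             scores = scores, labels = y))
}

#' Feature-importance ranking of a fitted model
#'
#' Uses each family's native importance: mean impurity decrease for the
#' two forest families, total gain for the regularized booster, and the
#' integer split count per feature for the histogram booster. Features
#' never used by the model score 0. Ties are broken by lexicographic
#' feature name so rankings are deterministic.
#'
#' @param model A `comorisk_model`.
#' @param k Optional: return only the top `k` rows (clamped to the number
#'   of features).
#' @return data.frame `feature`, `importance`, non-increasing, with
#'   attribute `family`.
#' @export
rank_importances <- function(model, k = NULL) {
  stopifnot(inherits(model, "comorisk_model"))
  feats <- model$feature_names
  imp <- stats::setNames(numeric(length(feats)), feats)
  if (model$backend == "ranger") {
    vi <- model$fit$variable.importance
    imp[names(vi)] <- vi
  } else if (model$family == "hist_gradient_boosting") {
    tree <- xgboost::xgb.model.dt.tree(model = model$fit)
    splits <- tree[tree$Feature != "Leaf", ]
    cnt <- table(splits$Feature)
    imp[names(cnt)] <- as.numeric(cnt)
  } else {
    it <- xgboost::xgb.importance(model = model$fit)
    imp[it$Feature] <- it$Gain
  }
  ord <- order(-imp, names(imp))
  out <- data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(k)) out <- utils::head(out, k)
  rownames(out) <- NULL
  attr(out, "family") <- model$family
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Cross-model top-k importance consensus
#'
#' Given one importance ranking per model family, the *core* set is the
#' intersection of the four top-`k` feature-code sets and the *extended*
#' set their union. Both are mapped to disease categories through the
#' catalog (codes without a catalog category — e.g. demographics — carry
#' no category). The core nominates the risk diseases: codes that every
#' family ranks among its most informative predictors of the target.
#'
#' @param rankings List of at least four rankings (data.frames with a
#'   `feature` column ordered by importance, as from [rank_importances()]).
#' @param k Top-k cutoff (default 10).
#' @param catalog A `disease_catalog`.
#' @return An object of class `risk_consensus`: list with `core_codes`,
#'   `extended_codes`, `core_categories`, `extended_categories`,
#'   `top_codes` (per ranking).
#' @examples
#' cons <- consensus(example_rankings(), k = 10, catalog = default_catalog())
#' length(cons$extended_codes) # 12
#' @export
consensus <- function(rankings, k = 10L, catalog = default_catalog()) {
  if (length(rankings) < 4L)
    stop("consensus requires the rankings of all four model families",
         call. = FALSE)
  tops <- lapply(rankings, function(r) {
    stopifnot(is.data.frame(r), "feature" %in% names(r))
    utils::head(r$feature, k)
  })
  consensus_sets(tops, catalog)
}

# core/extended sets over any number of top-k lists (consensus() enforces
# the four-family contract; the pipeline reuses this for partial banks)
consensus_sets <- function(tops, catalog) {
  core <- sort(Reduce(intersect, tops))
  extended <- sort(Reduce(union, tops))
  cat_of <- function(codes) {
    cc <- categorize(codes, catalog)
    sort(unique(cc[!is.na(cc)]))
  }
  structure(list(core_codes = core, extended_codes = extended,
                 core_categories = cat_of(core),
                 extended_categories = cat_of(extended),
                 top_codes = tops),
            class = "risk_consensus")
}

#' @export
print.risk_consensus <- function(x, ...) {
  cat("<risk_consensus>\n")
  cat(sprintf("  extended: %d codes in %d categories\n",
              length(x$extended_codes), length(x$extended_categories)))
  cat(sprintf("  core:     %d codes in %d categories\n",
              length(x$core_codes), length(x$core_categories)))
  cat("  core codes:", paste(x$core_codes, collapse = ", "), "\n")
  invisible(x)
}

#' Worked-example top-10 importance rankings
#'
#' Four top-10 ICD-code rankings over chronic physical illness codes, one
#' per model family, bundled as a worked example for [consensus()] (their
#' union spans 12 codes in 10 categories; their intersection 8 codes in 7
#' categories). Scores are impurity importances for the forests, gain for
#' the regularized booster, and integer split counts for the histogram
#' booster.
#'
#' @return Named list of four `data.frame(feature, importance)` rankings.
#' @export
example_rankings <- function() {
  mk <- function(feature, importance)
    data.frame(feature = feature, importance = importance,
               stringsAsFactors = FALSE)
  list(
    random_forest = mk(
      c("I50.9", "I25.1", "I10", "N40", "K29.5", "E11.9", "I67.2", "I69.3",
        "E78.5", "I63.9"),
      c(0.048467, 0.044654, 0.033319, 0.027458, 0.025265, 0.020739,
        0.020462, 0.020399, 0.017025, 0.016396)),
    extra_trees = mk(
      c("I50.9", "I25.1", "I10", "N40", "K29.5", "E11.9", "I69.3", "I67.2",
        "E78.5", "I63.9"),
      c(0.048778, 0.043862, 0.033509, 0.027809, 0.024969, 0.020313,
        0.019940, 0.019592, 0.016730, 0.016353)),
    regularized_gradient_boosting = mk(
      c("I10", "K29.5", "I25.1", "I50.9", "I67.2", "I69.3", "E11.9", "N40",
        "D64.9", "E77.8"),
      c(0.010559, 0.007317, 0.006866, 0.006414, 0.006269, 0.006174,
        0.006115, 0.005924, 0.005724, 0.005624)),
    hist_gradient_boosting = mk(
      c("I50.9", "I10", "I67.2", "I25.1", "I69.3", "K29.5", "N40", "E77.8",
        "D64.9", "E11.9"),
      c(3069, 2833, 2470, 2104, 1984, 1954, 1821, 1581, 1575, 1368)))
}
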