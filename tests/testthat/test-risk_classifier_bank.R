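families <- c("random_forest", "extra_trees", "hist_gradient_boosting",
              "regularized_gradient_boosting")

# a linearly separable toy split: one code fully determines the label
make_separable_split <- function(n = 120, seed = 3) {
  set.seed(seed)
  signal <- rep(c(0L, 1L), length.out = n)
  noise <- sample(c("", "E78.5", "K29.5"), n, replace = TRUE)
  codes <- ifelse(signal == 1, paste0("I50.9", ifelse(nzchar(noise), ";", ""),
                                      noise), ifelse(nzchar(noise), noise,
                                                     "I10"))
  inst <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                     age = sample(30:80, n, replace = TRUE),
                     sex = sample(c("M", "F"), n, replace = TRUE),
                     label = signal, codes = codes,
                     stringsAsFactors = FALSE)
  split_instances(list(instances = inst,
                       vocabulary = c("E78.5", "I10", "I50.9", "K29.5")),
                  train_fraction = 0.7, seed = seed)
}

test_that("metric formulas match hand arithmetic and handle zero denominators", {
  m <- compute_metrics(confusion_counts(
    c(rep(1, 8), rep(1, 2), rep(0, 2), rep(0, 8)),
    c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)

  m2 <- compute_metrics(3, 1, 2, 4)
  expect_equal(m2$accuracy, 0.7)
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$recall, 0.6)
  expect_equal(m2$f1, 2 * 0.75 * 0.6 / 1.35)

  m3 <- compute_metrics(0, 0, 5, 5)
  expect_true(is.na(m3$precision)) # undefined, not zero
  expect_equal(m3$recall, 0)
  expect_error(compute_metrics(0, 0, 0, 0), "all-zero")
})

test_that("metrics agree with a brute-force confusion oracle", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    truth <- rbinom(n, 1, 0.5)
    pred <- rbinom(n, 1, 0.5)
    cc <- confusion_counts(pred, truth)
    # oracle: enumerate every instance
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (i in seq_len(n)) {
      if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
      else if (pred[i] == 1) fp <- fp + 1
      else if (truth[i] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(unclass(cc), list(tp = tp, fp = fp, fn = fn, tn = tn))
    m <- compute_metrics(cc)
    expect_equal(m$accuracy, mean(pred == truth))
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
  }
})

test_that("rank AUC equals exhaustive pair counting (and pROC) on fixtures", {
  pair_auc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
    tot / (length(pos) * length(neg))
  }
  s <- c(.9, .8, .7, .4, .3, .2); l <- c(1, 1, 0, 1, 0, 0)
  expect_equal(compute_auc(s, l)$auc, 8 / 9)
  expect_equal(pair_auc(s, l), 8 / 9)

  expect_equal(compute_auc(c(.9, .8, .1), c(1, 1, 0))$auc, 1.0)
  expect_equal(compute_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)

  set.seed(7)
  for (rep in 1:40) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2) # coarse grid forces ties
    got <- compute_auc(scores, labels)$auc
    expect_equal(got, pair_auc(scores, labels))
    expect_equal(got, as.numeric(suppressMessages(
      pROC::auc(labels, scores, direction = "<"))))
  }
})

test_that("optimal threshold maximizes Youden's J with specificity tiebreak", {
  s <- c(.9, .8, .7, .4, .3, .2); l <- c(1, 1, 0, 1, 0, 0)
  au <- compute_auc(s, l)
  J <- au$roc$tpr - au$roc$fpr
  expect_equal(au$youden_j, max(J))
  best_rows <- which(J == max(J))
  expect_equal(au$optimal_threshold,
               au$roc$threshold[best_rows[
                 which.min(au$roc$fpr[best_rows])]])
})

test_that("every family separates a deterministic single-code signal", {
  sp <- make_separable_split()
  for (fam in families) {
    m <- train_model(model_spec(fam, seed = 2), sp)
    ev <- evaluate_model(m, sp, on = "test")
    expect_equal(ev$f1, 1.0, info = fam)
    expect_equal(ev$auc, 1.0, info = fam)
    # the deterministic code tops the importance ranking
    expect_identical(rank_importances(m)$feature[1], "I50.9", info = fam)
  }
})

test_that("training is deterministic and oversampling never touches the test set", {
  sp <- make_separable_split(n = 80, seed = 9)
  for (fam in c("random_forest", "regularized_gradient_boosting")) {
    m1 <- train_model(model_spec(fam, seed = 5), sp)
    m2 <- train_model(model_spec(fam, seed = 5), sp)
    expect_identical(predict(m1, sp$test), predict(m2, sp$test), info = fam)
  }
  test_hash_before <- digest_df(sp$test)
  m_over <- train_model(model_spec("random_forest", oversample = TRUE,
                                   seed = 5), sp)
  m_no <- train_model(model_spec("random_forest", oversample = FALSE,
                                 seed = 5), sp)
  expect_identical(digest_df(sp$test), test_hash_before)
  expect_s3_class(m_over, "comorisk_model")
  expect_s3_class(m_no, "comorisk_model")
})

test_that("oversampling balances classes by duplicating the minority", {
  y <- c(rep(0L, 90), rep(1L, 10))
  set.seed(1)
  idx <- comorisk:::oversample_indices(y)
  expect_identical(sum(y[idx] == 0), sum(y[idx] == 1))
  expect_true(all(seq_along(y) %in% idx)) # originals all retained
  expect_identical(comorisk:::oversample_indices(rep(0L, 5)), 1:5)
})

test_that("grid search selects by cross-validated F1", {
  sp <- make_separable_split(n = 150, seed = 13)
  spec <- model_spec("random_forest", cv_folds = 3, seed = 8,
                     grid = list(n_estimators = c(10L, 50L)))
  m <- train_model(spec, sp)
  expect_identical(nrow(m$cv$candidates), 2L)
  expect_true(m$cv$selected %in% 1:2)
  expect_identical(m$spec$hyperparameters$n_estimators,
                   m$cv$candidates$n_estimators[m$cv$selected])
})

test_that("unsupported hyperparameter keys are rejected, not dropped", {
  expect_error(model_spec("random_forest",
                          hyperparameters = list(bogus_knob = 1)),
               "bogus_knob")
  expect_error(model_spec("hist_gradient_boosting",
                          hyperparameters = list(criterion = "gini")),
               "criterion")
})

test_that("importance rankings are complete, sorted and tie-stable", {
  sp <- make_separable_split()
  m <- train_model(model_spec("hist_gradient_boosting", seed = 2), sp)
  r <- rank_importances(m)
  expect_setequal(r$feature, c(sp$vocabulary, "age", "sex"))
  expect_true(all(diff(r$importance) <= 0))
  expect_true(all(r$importance == floor(r$importance))) # split counts
  expect_identical(nrow(rank_importances(m, k = 10)),
                   min(10L, nrow(r))) # top-k clamps to feature count
  # a constant feature carries zero importance
  zero_feats <- r$feature[r$importance == 0]
  expect_true(length(zero_feats) == 0 ||
              all(zero_feats %in% c("age", "sex", sp$vocabulary)))
})

test_that("consensus intersects and unions the four top-10 sets", {
  cat10 <- default_catalog()
  same <- example_rankings()[c(1, 1, 1, 1)]
  cons_same <- consensus(same, k = 10, catalog = cat10)
  expect_identical(cons_same$core_codes, cons_same$extended_codes)
  expect_length(cons_same$core_codes, 10L)

  disjoint <- list(
    data.frame(feature = "I10"), data.frame(feature = "N40"),
    data.frame(feature = "E11.9"), data.frame(feature = "I50.9"))
  cons_dis <- consensus(disjoint, k = 10, catalog = cat10)
  expect_length(cons_dis$core_codes, 0L)
  expect_length(cons_dis$extended_codes, 4L)

  expect_error(consensus(example_rankings()[1:3]), "four")
})

test_that("planted-effect strength moves planted codes up the rankings", {
  strengths <- c(0.25, 0.45, 0.65)
  ranks <- sapply(seq_along(strengths), function(si) {
    spec <- cohort_spec(
      1500,
      physical_prevalence = c("Prostate diseases" = 0.25,
                              "Dyslipidemia" = 0.25,
                              "Hypertension" = 0.25,
                              "Diabetes" = 0.25),
      mental_baseline = c("Organic mental disorders" = 0.25),
      planted_effects = list(list(physical = "Prostate diseases",
                                  mental = "Organic mental disorders",
                                  p_given = strengths[si],
                                  p_not_given = 0.15)),
      seed = 100 + si)
    rec <- generate_cohort(spec)
    inst <- build_instances(rec, default_catalog(),
                            target = "Organic mental disorders")
    sp <- split_instances(prune_rare(inst), seed = 1)
    m <- train_model(model_spec("random_forest", seed = 1), sp)
    which(rank_importances(m)$feature == "N40")
  })
  expect_true(ranks[3] <= ranks[1]) # stronger effect, same or better rank
  expect_identical(ranks[3], 1L) # strongest effect dominates the ranking
})
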