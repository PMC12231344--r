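cat10 <- default_catalog()
all_mental <- catalog_categories(cat10, "mental")

test_that("hand-traced labeling of consecutive record pairs", {
  # physical then mental: one instance, features {I10}, label 1
  rec <- make_records(list(codes = list("I10", "F05")))
  inst <- build_instances(rec, cat10, target = all_mental)
  expect_identical(nrow(inst), 1L)
  expect_identical(inst$codes, "I10")
  expect_identical(inst$label, 1L)

  # no target anywhere: chain of label-0 instances
  rec <- make_records(list(codes = list("I10", "E11.9", "K29.5")))
  inst <- build_instances(rec, cat10, target = all_mental)
  expect_identical(inst$label, c(0L, 0L))
  expect_identical(inst$codes, c("I10", "E11.9"))

  # first record already carries the target: no instances
  rec <- make_records(list(codes = list("F20", "I10")))
  expect_message(
    inst <- build_instances(rec, cat10, target = all_mental),
    "first record")
  expect_identical(nrow(inst), 0L)

  # chain stops at the first positive even when more records follow
  rec <- make_records(list(codes = list("I10", "E11.9", "F20", "K29.5")))
  inst <- build_instances(rec, cat10, target = all_mental)
  expect_identical(inst$label, c(0L, 1L))
})

test_that("cumulative mode accumulates the non-target history", {
  rec <- make_records(list(codes = list("I10", "E11.9;I10", "F20")))
  single <- build_instances(rec, cat10, target = all_mental,
                            feature_mode = "single")
  cumul <- build_instances(rec, cat10, target = all_mental,
                           feature_mode = "cumulative")
  expect_identical(single$codes, c("I10", "E11.9;I10"))
  expect_identical(cumul$codes, c("I10", "I10;E11.9"))
  expect_identical(single$label, cumul$label)
})

test_that("feature sets never contain target-category codes", {
  co <- shared_cohort()
  inst <- build_instances(co$records, co$catalog,
                          target = co$included_mental)
  feats <- unique(unlist(strsplit(inst$codes, ";", fixed = TRUE)))
  feats <- feats[nzchar(feats)]
  feat_cat <- categorize(feats, co$catalog)
  expect_false(any(feat_cat %in% co$included_mental))
  # mental categories outside the target remain legitimate features
  expect_true(all(inst$label %in% c(0L, 1L)))
  # at most one positive instance per patient
  pos_per_pat <- tapply(inst$label, inst$patient_id, sum)
  expect_true(all(pos_per_pat <= 1L))
})

test_that("positives are enriched for planted physical codes", {
  spec <- cohort_spec(
    3000,
    physical_prevalence = c("Prostate diseases" = 0.3,
                            "Dyslipidemia" = 0.3),
    mental_baseline = c("Organic mental disorders" = 0.3),
    planted_effects = list(list(physical = "Prostate diseases",
                                mental = "Organic mental disorders",
                                p_given = 0.6, p_not_given = 0.15)),
    seed = 5)
  rec <- generate_cohort(spec)
  inst <- build_instances(rec, cat10,
                          target = "Organic mental disorders")
  has_code <- function(codes, code)
    vapply(strsplit(codes, ";", fixed = TRUE), function(cc) code %in% cc,
           logical(1))
  planted_rate <- tapply(has_code(inst$codes, "N40"), inst$label, mean)
  neutral_rate <- tapply(has_code(inst$codes, "E78.5"), inst$label, mean)
  expect_gt(planted_rate[["1"]], planted_rate[["0"]])
  # the unplanted code shows no comparable enrichment
  expect_lt(neutral_rate[["1"]] - neutral_rate[["0"]],
            planted_rate[["1"]] - planted_rate[["0"]])
})

test_that("rare-code pruning removes codes and emptied instances", {
  inst <- data.frame(
    patient_id = sprintf("P%02d", 1:10),
    age = 50L, sex = "M",
    label = c(1L, rep(0L, 9)),
    codes = c(rep("I10;K29.5", 4), rep("I10", 4), "Q99.9", "Q99.9"),
    stringsAsFactors = FALSE)
  pr <- prune_rare(inst, min_occurrences = 5)
  expect_identical(pr$vocabulary, "I10") # K29.5 seen 4x, Q99.9 2x
  expect_identical(nrow(pr$instances), 8L)
  pr1 <- prune_rare(inst, min_occurrences = 1)
  expect_setequal(pr1$vocabulary, c("I10", "K29.5", "Q99.9"))
  expect_identical(nrow(pr1$instances), 10L)
  expect_error(prune_rare(inst, min_occurrences = 100), "every instance")
})

test_that("the split is patient-level, stratified and seeded", {
  co <- shared_cohort()
  pr <- prune_rare(build_instances(co$records, co$catalog,
                                   target = co$included_mental))
  sp1 <- split_instances(pr, train_fraction = 0.7, seed = 42)
  sp2 <- split_instances(pr, train_fraction = 0.7, seed = 42)
  expect_identical(sp1$train, sp2$train)
  expect_identical(sp1$test, sp2$test)
  expect_length(intersect(sp1$train$patient_id, sp1$test$patient_id), 0L)
  n_pat <- length(unique(pr$instances$patient_id))
  n_train <- length(unique(sp1$train$patient_id))
  expect_lt(abs(n_train / n_pat - 0.7), 0.01)
  # both classes on both sides
  expect_setequal(unique(sp1$train$label), c(0L, 1L))
  expect_setequal(unique(sp1$test$label), c(0L, 1L))

  all0 <- pr
  all0$instances$label <- 0L
  expect_error(split_instances(all0), "single class")
})

test_that("vectorization is a stable multi-hot encoding plus demographics", {
  inst <- data.frame(patient_id = c("a", "b", "c"),
                     age = c(30L, 60L, 70L), sex = c("M", "F", "M"),
                     label = c(0L, 1L, 0L),
                     codes = c("I10", "", "I10;E11.9;K29.5"),
                     stringsAsFactors = FALSE)
  vocab <- c("E11.9", "I10", "K29.5")
  v <- vectorize(inst, vocab)
  expect_identical(colnames(v$x), c(vocab, "age", "sex"))
  expect_equal(unname(rowSums(v$x[, vocab])), c(1, 0, 3))
  expect_equal(unname(v$x[, "sex"]), c(1, 0, 1))
  expect_equal(unname(v$x[1, ]), c(0, 1, 0, 30, 1))
  expect_identical(v$y, c(0L, 1L, 0L))
  expect_identical(vectorize(inst, vocab)$x, v$x)
})
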