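test_that("pair counts enumerate a toy cohort exactly", {
  # patients: {i}, {j}, {i,j}, {}
  has_i <- c(TRUE, FALSE, TRUE, FALSE)
  has_j <- c(FALSE, TRUE, TRUE, FALSE)
  cc <- pair_counts(has_i, has_j)
  expect_identical(unclass(cc), list(C = 1L, P_i = 2L, P_j = 2L, N = 4L))
  # self-pair: C equals the margin
  self <- pair_counts(has_i, has_i)
  expect_identical(self$C, self$P_i)
  expect_error(pair_counts(logical(0), logical(0)), "empty")
  expect_error(pair_counts(has_i, has_j[1:2]), "same cohort")
})

test_that("intensity reproduces the worked RR and phi values", {
  r <- intensity(pair_counts_raw(C = 40, P_i = 100, P_j = 200, N = 1000))
  expect_equal(r$rr, 2.0)
  expect_equal(r$phi, 20000 / 120000)
  # independence: C exactly P_i*P_j/N gives RR 1, phi 0
  ind <- intensity(pair_counts_raw(C = 20, P_i = 100, P_j = 200, N = 1000))
  expect_equal(ind$rr, 1.0)
  expect_equal(ind$phi, 0.0)
  # symmetry in i and j
  a <- intensity(pair_counts_raw(35, 80, 300, 1000))
  b <- intensity(pair_counts_raw(35, 300, 80, 1000))
  expect_equal(a$rr, b$rr)
  expect_equal(a$phi, b$phi)
})

test_that("degenerate margins yield a reasoned NA, never NaN", {
  r0 <- intensity(pair_counts_raw(0, 0, 100, 1000))
  expect_true(is.na(r0$rr) && is.na(r0$phi))
  expect_identical(r0$reason, "degenerate margin")
  rN <- intensity(pair_counts_raw(100, 1000, 100, 1000))
  expect_identical(rN$reason, "degenerate margin")
})

test_that("phi equals the Pearson correlation of the binary indicators", {
  set.seed(123)
  worst <- 0
  for (rep in 1:1000) {
    n <- sample(10:60, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8)) == 1
    y <- rbinom(n, 1, runif(1, 0.2, 0.8)) == 1
    if (all(x) || !any(x) || all(y) || !any(y)) next
    r <- intensity(pair_counts(x, y))
    worst <- max(worst, abs(r$phi - stats::cor(as.numeric(x),
                                               as.numeric(y))))
  }
  expect_lt(worst, 1e-12)
})

test_that("rr equals the incidence-ratio form exactly", {
  set.seed(5)
  for (rep in 1:200) {
    N <- sample(20:500, 1)
    P_i <- sample(1:(N - 1), 1); P_j <- sample(1:(N - 1), 1)
    C <- sample(0:min(P_i, P_j), 1)
    r <- intensity(pair_counts_raw(C, P_i, P_j, N))
    expect_identical(r$rr, (C / P_i) / (P_j / N))
  }
})

test_that("rr and phi increase strictly in the joint count", {
  rr <- phi <- numeric(0)
  for (C in 10:60) {
    r <- intensity(pair_counts_raw(C, 100, 200, 1000))
    rr <- c(rr, r$rr); phi <- c(phi, r$phi)
  }
  expect_true(all(diff(rr) > 0))
  expect_true(all(diff(phi) > 0))
})

test_that("screening applies strict thresholds and ranks by RR then phi", {
  pairs <- data.frame(
    category_i = letters[1:6], category_j = "m",
    C = 1, P_i = 1, P_j = 1, N = 10,
    rr = c(1.0, 1.3, 2.5, 1.9, 1.9, 0.8),
    phi = c(0.5, 0.05, 0.2, 0.3, 0.2, 0.4),
    reason = NA_character_, stringsAsFactors = FALSE)
  sc <- screen_pairs(pairs, top_k = 3)
  # rr exactly 1 excluded; negative-intensity pair excluded
  expect_false("a" %in% sc$included$category_i)
  expect_false("f" %in% sc$included$category_i)
  # rr>1 & phi>0 included but not high when below the high cutoffs
  expect_true("b" %in% sc$included$category_i)
  expect_false("b" %in% sc$high$category_i)
  # ranking by rr, phi tiebreak
  expect_identical(sc$top$category_i, c("c", "d", "e"))
  expect_setequal(sc$high$category_i, c("c", "d", "e"))
})

test_that("planted pair RR is recovered within Monte-Carlo tolerance", {
  co <- shared_cohort()
  pc <- patient_categories(co$records, co$catalog)
  for (pe in default_planted_effects()) {
    p_i <- default_physical_prevalence()[[pe$physical]]
    target <- expected_rr(p_i, pe$p_given, pe$p_not_given)
    emp <- intensity(count_pair(pc, pe$physical, pe$mental))
    # sanity band at n = 4000: ~2.5 SE for the smallest planted cell
    # (C ~ 100); the tight 5% recovery check runs at n = 50,000
    expect_lt(abs(emp$rr - target) / target, 0.25)
  }
})

test_that("stratified analysis localizes a stratum-conditional effect", {
  # plant a strong pair, then erase the mental category everywhere except
  # one stratum so the association exists only there
  spec <- cohort_spec(
    6000,
    physical_prevalence = c("Prostate diseases" = 0.3,
                            "Hypertension" = 0.3),
    mental_baseline = c("Organic mental disorders" = 0.25,
                        "Depression and mood diseases" = 0.3),
    planted_effects = list(list(physical = "Prostate diseases",
                                mental = "Organic mental disorders",
                                p_given = 0.6, p_not_given = 0.15)),
    seed = 31)
  rec <- generate_cohort(spec)
  cat10 <- default_catalog()
  # strip the planted mental code (F00) outside the M/45-60 stratum
  first <- rec[!duplicated(rec$patient_id), ]
  strat <- assign_stratum(first$age, first$sex)
  keep_pid <- first$patient_id[strat == "M/45-60"]
  strip <- !(rec$patient_id %in% keep_pid)
  rec$codes[strip] <- vapply(strsplit(rec$codes[strip], ";", fixed = TRUE),
                             function(cc) {
                               cc <- cc[cc != "F00"]
                               if (!length(cc)) "Z00" else
                                 paste(cc, collapse = ";")
                             }, character(1))
  res <- suppressMessages(stratified_analysis(
    rec, cat10, "Prostate diseases",
    c("Organic mental disorders", "Depression and mood diseases"),
    min_n = 50))
  planted <- res[res$category_i == "Prostate diseases" &
                 res$category_j == "Organic mental disorders" &
                 res$level == "sex_age", ]
  expect_true(planted$high[planted$stratum == "M/45-60"])
  expect_false(any(planted$high[planted$stratum != "M/45-60"], na.rm = TRUE))
})

test_that("full-cohort counts equal the sum over the 10 strata", {
  co <- shared_cohort()
  res <- suppressMessages(stratified_analysis(
    co$records, co$catalog, names(default_physical_prevalence()),
    co$included_mental, min_n = 1))
  for (pair_j in unique(res$category_j)[1:3]) {
    sub <- res[res$category_i == "Hypertension" & res$category_j == pair_j, ]
    expect_identical(sum(sub$C[sub$level == "sex_age"]),
                     sub$C[sub$level == "all"])
    expect_identical(sum(sub$N[sub$level == "sex_age"]),
                     sub$N[sub$level == "all"])
  }
})
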