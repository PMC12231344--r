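#' Specify a synthetic admission cohort
#'
#' Defines a seeded generative model for longitudinal hospital admission
#' records of patients seen for mental-health disorders, with enough
#' structure to exercise every downstream stage: a known sex-by-age-band
#' mix, per-category disease prevalences, planted pairwise comorbidity
#' between chosen physical and mental categories, a minimum of two
#' admissions per patient, and a temporal layout in which chronic physical
#' diagnoses precede the onset of mental-disorder codes.
#'
#' Planted effects are parameterized as conditional probabilities
#' `p(mental j | physical i)` and `p(mental j | not i)` rather than as a
#' relative risk, so the implied population RR is available in closed form
#' from [expected_rr()] and parameter recovery can be checked exactly in
#' expectation.
#'
#' Defaults emulate the scale of a regional mental-health inpatient cohort:
#' the sex-by-age-band weights follow the published cell counts of such a
#' cohort (N = 46,649), mental baselines follow its per-category
#' prevalences, and admissions per patient are `2 + Geometric(0.4)`,
#' capped at 12.
#'
#' @param n_patients Number of patients to simulate.
#' @param age_sex_weights Named numeric vector over the 10 cells
#'   `"<sex>/<band>"` (sex `M`/`F`; bands `0-18`, `18-45`, `45-60`,
#'   `60-80`, `>80`); must sum to 1.
#' @param physical_prevalence Named probabilities, one per physical
#'   category (names must exist in the catalog with member codes).
#' @param mental_baseline Named baseline probabilities per mental category.
#' @param planted_effects List of lists with fields `physical`, `mental`,
#'   `p_given` (= p(j|i)) and `p_not_given` (= p(j|not i)); at most one
#'   planted parent per mental category.
#' @param admissions Function `n -> integer vector` drawing admissions per
#'   patient (each value must be >= 2); default `2 + Geom(0.4)` capped at 12.
#' @param catalog `disease_catalog` supplying one representative code per
#'   category.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [expected_rr()]
#' @export
cohort_spec <- function(n_patients,
                        age_sex_weights = default_age_sex_weights(),
                        physical_prevalence = default_physical_prevalence(),
                        mental_baseline = default_mental_baseline(),
                        planted_effects = default_planted_effects(),
                        admissions = default_admissions_dist(),
                        catalog = default_catalog(),
                        seed = 1L) {
  stopifnot(is.numeric(n_patients), length(n_patients) == 1L, n_patients >= 0)
  if (abs(sum(age_sex_weights) - 1) > 1e-9)
    stop("age_sex_weights must sum to 1", call. = FALSE)
  if (any(age_sex_weights < 0)) stop("negative age_sex_weights", call. = FALSE)
  expected_cells <- as.vector(outer(c("M", "F"), age_band_labels(),
                                    paste, sep = "/"))
  if (!setequal(names(age_sex_weights), expected_cells))
    stop("age_sex_weights must be named over the 10 sex/age-band cells",
         call. = FALSE)
  chk_prob <- function(p, nm) {
    if (any(p < 0 | p > 1)) stop(nm, " must lie in [0,1]", call. = FALSE)
  }
  chk_prob(physical_prevalence, "physical_prevalence")
  chk_prob(mental_baseline, "mental_baseline")
  planted_mental <- vapply(planted_effects, `[[`, "", "mental")
  if (anyDuplicated(planted_mental))
    stop("at most one planted physical parent per mental category",
         call. = FALSE)
  for (pe in planted_effects) {
    chk_prob(c(pe$p_given, pe$p_not_given), "planted effect probabilities")
    if (!pe$physical %in% names(physical_prevalence))
      stop("planted effect references unknown physical category: ",
           pe$physical, call. = FALSE)
  }
  # every named category must have a representative code in the catalog
  representative_codes(catalog, c(names(physical_prevalence),
                                  names(mental_baseline)))
  structure(list(n_patients = as.integer(n_patients),
                 age_sex_weights = age_sex_weights[expected_cells],
                 physical_prevalence = physical_prevalence,
                 mental_baseline = mental_baseline,
                 planted_effects = planted_effects,
                 admissions = admissions,
                 catalog = catalog,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_age_sex_weights <- function() {
  # published sex-by-age-band cell counts of a 46,649-patient cohort
  m <- c("0-18" = 1967, "18-45" = 7896, "45-60" = 4362,
         "60-80" = 6281, ">80" = 3830)
  f <- c("0-18" = 868, "18-45" = 4836, "45-60" = 5270,
         "60-80" = 7483, ">80" = 3856)
  w <- c(stats::setNames(m, paste0("M/", names(m))),
         stats::setNames(f, paste0("F/", names(f))))
  w / sum(w)
}

#' @rdname cohort_spec
#' @export
default_physical_prevalence <- function() {
  # plausible chronic-disease scales for an inpatient mental-health cohort;
  # the physical side is not pinned by published counts
  c("Hypertension" = 0.25,
    "Cerebrovascular disease" = 0.20,
    "Ischemic heart disease" = 0.12,
    "Diabetes" = 0.12,
    "Esophagus, stomach, and duodenum diseases" = 0.10,
    "Heart failure" = 0.08,
    "Dyslipidemia" = 0.08,
    "Anemia" = 0.06,
    "Prostate diseases" = 0.05,
    "Other metabolic diseases" = 0.05)
}

#' @rdname cohort_spec
#' @export
default_mental_baseline <- function() {
  # per-category prevalences of the 8 mental groups retained at the >=1%
  # inclusion threshold in a 46,649-patient cohort
  c("Neurotic stress-related and somatoform diseases" = 0.3404,
    "Schizophrenia and delusional diseases" = 0.3137,
    "Organic mental disorders" = 0.2631,
    "Depression and mood diseases" = 0.0772,
    "Mental retardation" = 0.0735,
    "Mental and behavioral disorders due to psychoactive substance use" = 0.0235,
    "Pervasive developmental disorders" = 0.0133,
    "Sleep disorders_F" = 0.0131)
}

#' @rdname cohort_spec
#' @export
default_planted_effects <- function() {
  # three pairs at the intensity scale of the strongest reported
  # physical-mental combinations (closed-form RR about 2.0, 1.6 and 1.5)
  list(
    list(physical = "Prostate diseases",
         mental = "Organic mental disorders",
         p_given = 0.52, p_not_given = 0.245),
    list(physical = "Esophagus, stomach, and duodenum diseases",
         mental = "Neurotic stress-related and somatoform diseases",
         p_given = 0.55, p_not_given = 0.315),
    list(physical = "Hypertension",
         mental = "Depression and mood diseases",
         p_given = 0.115, p_not_given = 0.0645)
  )
}

#' @rdname cohort_spec
#' @export
default_admissions_dist <- function(min_admissions = 2L, geom_prob = 0.4,
                                    cap = 12L) {
  force(min_admissions); force(geom_prob); force(cap)
  function(n) pmin(min_admissions + stats::rgeom(n, geom_prob), cap)
}

#' Closed-form relative risk implied by planted conditional probabilities
#'
#' For a planted pair with physical prevalence `p_i`, conditional
#' probability `p_j_given_i` of the mental category given the physical one,
#' and `p_j_given_not_i` otherwise, the marginal mental prevalence is
#' `p_i * p_j_given_i + (1 - p_i) * p_j_given_not_i` and the population
#' relative risk is `p_j_given_i` divided by that marginal. This is the
#' analytic target against which empirical RR recovered from generated
#' cohorts is checked.
#'
#' @param p_i Physical-category prevalence, strictly inside (0, 1).
#' @param p_j_given_i,p_j_given_not_i Conditional probabilities of the
#'   mental category.
#' @return Positive scalar relative risk.
#' @examples
#' expected_rr(0.2, 0.5, 0.25) # 5/3
#' @export
expected_rr <- function(p_i, p_j_given_i, p_j_given_not_i) {
  stopifnot(p_i > 0, p_i < 1,
            p_j_given_i >= 0, p_j_given_i <= 1,
            p_j_given_not_i >= 0, p_j_given_not_i <= 1)
  marginal <- p_i * p_j_given_i + (1 - p_i) * p_j_given_not_i
  if (marginal == 0) stop("degenerate planted pair: marginal prevalence 0",
                          call. = FALSE)
  p_j_given_i / marginal
}

age_band_labels <- function() c("0-18", "18-45", "45-60", "60-80", ">80")

# uniform integer age inside a band; ">80" spans 80..95
sample_age_in_band <- function(band) {
  lo <- c("0-18" = 0L, "18-45" = 18L, "45-60" = 45L,
          "60-80" = 60L, ">80" = 80L)[band]
  hi <- c("0-18" = 17L, "18-45" = 44L, "45-60" = 59L,
          "60-80" = 79L, ">80" = 95L)[band]
  lo + floor(stats::runif(length(band)) * (hi - lo + 1L))
}

#' Generate a synthetic admission cohort
#'
#' Draws, per patient: a sex/age-band cell, independent physical-category
#' indicators, and mental-category indicators whose probability is either
#' the baseline or the planted conditional given the planted physical
#' parent. Each present category contributes one representative ICD-10 code
#' from the catalog. Codes are laid out over the patient's admissions so
#' that physical codes occupy admissions strictly before a sampled
#' mental-onset admission, and mental codes appear from the onset admission
#' onward — physical diagnoses precede mental-disorder onset by
#' construction. Admission dates are strictly increasing within a patient.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame of admission records: `patient_id`, `sex` (`M`/`F`),
#'   `age` (years at first admission), `admit_date`, `discharge_date`
#'   (`Date`), `codes` (semicolon-separated normalized ICD-10 codes,
#'   1–16 per admission), ordered by patient and admit date.
#' @examples
#' rec <- generate_cohort(cohort_spec(50, seed = 7))
#' head(rec)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  empty <- data.frame(patient_id = character(0), sex = character(0),
                      age = integer(0),
                      admit_date = as.Date(character(0)),
                      discharge_date = as.Date(character(0)),
                      codes = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  cells <- names(spec$age_sex_weights)
  cell <- cells[sample.int(length(cells), n, replace = TRUE,
                           prob = spec$age_sex_weights)]
  sex <- substr(cell, 1L, 1L)
  band <- substring(cell, 3L)
  age <- sample_age_in_band(band)

  phys_cats <- names(spec$physical_prevalence)
  ment_cats <- names(spec$mental_baseline)
  rep_code <- representative_codes(spec$catalog, c(phys_cats, ment_cats))

  phys <- matrix(stats::runif(n * length(phys_cats)), n) <
    matrix(spec$physical_prevalence, n, length(phys_cats), byrow = TRUE)
  colnames(phys) <- phys_cats

  planted_parent <- stats::setNames(rep(NA_character_, length(ment_cats)),
                                    ment_cats)
  p_given <- p_not_given <- stats::setNames(numeric(length(ment_cats)),
                                            ment_cats)
  for (pe in spec$planted_effects) {
    if (!pe$mental %in% ment_cats) next
    planted_parent[pe$mental] <- pe$physical
    p_given[pe$mental] <- pe$p_given
    p_not_given[pe$mental] <- pe$p_not_given
  }
  ment <- matrix(FALSE, n, length(ment_cats), dimnames = list(NULL, ment_cats))
  for (j in ment_cats) {
    pj <- if (is.na(planted_parent[j])) rep(spec$mental_baseline[j], n)
          else ifelse(phys[, planted_parent[j]], p_given[j], p_not_given[j])
    ment[, j] <- stats::runif(n) < pj
  }

  n_adm <- spec$admissions(n)
  if (any(n_adm < 2L))
    stop("admissions distribution produced a value below the minimum of 2",
         call. = FALSE)
  has_mental <- rowSums(ment) > 0L
  # onset admission index, uniform on 2..n_adm for patients with a mental
  # category; physical codes are confined to admissions before onset
  onset <- rep(NA_integer_, n)
  onset[has_mental] <- 2L + floor(stats::runif(sum(has_mental)) *
                                  (n_adm[has_mental] - 1L))

  pid <- sprintf("P%07d", seq_len(n))
  adm <- data.table::data.table(
    patient_id = rep(pid, n_adm),
    k = sequence(n_adm),
    row = rep(seq_len(n), n_adm))

  code_rows <- list()
  # physical codes: one admission slot each, uniform over the allowed range
  pw <- which(phys, arr.ind = TRUE)
  if (nrow(pw)) {
    upper <- ifelse(has_mental[pw[, 1L]], onset[pw[, 1L]] - 1L,
                    n_adm[pw[, 1L]])
    slot <- 1L + floor(stats::runif(nrow(pw)) * upper)
    code_rows$phys <- data.table::data.table(
      row = pw[, 1L], k = slot, code = rep_code[phys_cats[pw[, 2L]]])
  }
  # mental codes: onset admission and every later one
  mw <- which(ment, arr.ind = TRUE)
  if (nrow(mw)) {
    reps <- n_adm[mw[, 1L]] - onset[mw[, 1L]] + 1L
    code_rows$ment <- data.table::data.table(
      row = rep(mw[, 1L], reps),
      k = sequence(reps) + rep(onset[mw[, 1L]], reps) - 1L,
      code = rep(rep_code[length(phys_cats) + mw[, 2L]], reps))
  }
  codes_dt <- data.table::rbindlist(code_rows)
  k <- code <- codes <- patient_id <- NULL # data.table NSE
  if (nrow(codes_dt)) {
    data.table::setorder(codes_dt, row, k, code)
    codes_dt <- codes_dt[, .(codes = paste(utils::head(unique(code), 16L),
                                           collapse = ";")),
                         by = .(row, k)]
    adm <- merge(adm, codes_dt, by = c("row", "k"), all.x = TRUE)
  } else {
    adm[, codes := NA_character_]
  }
  # admissions that drew no category code get a neutral, uncatalogued code
  adm[is.na(codes), codes := "Z00"]

  # dates: first admission uniform over 2016-2021, then stay + gap forward
  data.table::setorder(adm, row, k)
  start <- as.Date("2016-01-01") + floor(stats::runif(n) * 2000)
  stay <- step <- off <- admit_date <- discharge_date <- NULL
  adm[, stay := 3L + floor(stats::runif(.N) * 28)]
  adm[, step := stay + 10L + floor(stats::runif(.N) * 170)]
  adm[, off := cumsum(step) - step, by = row]
  adm[, admit_date := start[row] + off]
  adm[, discharge_date := admit_date + stay]
  out <- data.frame(patient_id = adm$patient_id,
                    sex = sex[adm$row],
                    age = as.integer(age[adm$row]),
                    admit_date = adm$admit_date,
                    discharge_date = adm$discharge_date,
                    codes = adm$codes,
                    stringsAsFactors = FALSE)
  out[order(out$patient_id, out$admit_date), , drop = FALSE]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
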