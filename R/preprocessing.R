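#' @import data.table
NULL

#' Percentage helpers used throughout the cohort tables
#'
#' `prevalence_pct()` converts a distinct-patient count into a prevalence
#' percentage of the cohort; `retention_pct()` converts kept/raw record
#' counts into the record-level screening rate of the cleaning funnel.
#' Both are reported rounded to two decimals in printed tables while full
#' precision is retained internally for threshold comparisons.
#'
#' @param n,kept_records Numerator counts.
#' @param total,raw_records Denominator counts (> 0).
#' @param digits Decimal places for the rounded value; `NA` for full
#'   precision.
#' @return Numeric percentage in `[0, 100]`.
#' @examples
#' prevalence_pct(12273, 46649) # 26.31
#' retention_pct(268588, 348563) # 77.05
#' @export
prevalence_pct <- function(n, total, digits = 2) {
  stopifnot(all(total > 0), all(n >= 0), all(n <= total))
  pct <- n / total * 100
  if (is.na(digits)) pct else round(pct, digits)
}

#' @rdname prevalence_pct
#' @export
retention_pct <- function(kept_records, raw_records, digits = 2) {
  prevalence_pct(kept_records, raw_records, digits)
}

#' Clean raw admission records into the analysis cohort
#'
#' Applies the cohort filters in order: rows with missing age or sex are
#' deleted (no imputation); codes are normalized (rows whose code field is
#' empty or unparseable are counted and dropped); patients left with fewer
#' than two admissions are removed entirely. Within-patient duplicate
#' diagnoses (the same category across multiple hospitalizations) are NOT
#' removed here — every admission is needed downstream for trajectory
#' order — but all patient-level statistics ([prevalence()],
#' [patient_categories()]) count each patient once per category.
#'
#' @param records data.frame of admission records (`patient_id`, `sex`,
#'   `age`, `admit_date`, `discharge_date`, `codes`).
#' @param warn_drop_fraction Emit a warning when more than this fraction of
#'   rows is dropped for missingness (default 5%).
#' @return List with `records` (cleaned, ordered by patient and admit
#'   date, codes normalized) and `report` (a `cleaning_report`).
#' @export
clean_records <- function(records, warn_drop_fraction = 0.05) {
  stopifnot(is.data.frame(records))
  need <- c("patient_id", "sex", "age", "admit_date", "discharge_date",
            "codes")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  raw_records <- nrow(records)
  raw_patients <- length(unique(records$patient_id))

  sex_chr <- toupper(trimws(as.character(records$sex)))
  sex_chr[!sex_chr %in% c("M", "F")] <- NA_character_
  cod <- as.character(records$codes)
  missing_row <- is.na(records$age) | is.na(sex_chr) |
    is.na(records$patient_id) | is.na(cod) | !nzchar(trimws(cod))
  dropped_missing <- sum(missing_row)
  kept <- records[!missing_row, , drop = FALSE]
  kept$sex <- sex_chr[!missing_row]

  bad_code_rows <- 0L
  if (nrow(kept)) {
    norm <- vapply(strsplit(kept$codes, ";", fixed = TRUE), function(cc) {
      cc <- trimws(cc)
      cc <- cc[nzchar(cc)]
      out <- tryCatch(normalize_code(cc), error = function(e) NULL)
      if (is.null(out) || length(out) == 0L) NA_character_
      else paste(out, collapse = ";")
    }, character(1))
    bad_code_rows <- sum(is.na(norm))
    if (bad_code_rows)
      message(bad_code_rows, " record(s) dropped: unparseable diagnosis codes")
    kept <- kept[!is.na(norm), , drop = FALSE]
    kept$codes <- norm[!is.na(norm)]
  }
  dropped_missing <- dropped_missing + bad_code_rows

  # exact duplicate rows (same patient, dates, codes) are re-entries
  dup <- duplicated(kept[, need])
  dropped_duplicates <- sum(dup)
  kept <- kept[!dup, , drop = FALSE]

  adm_per_patient <- table(kept$patient_id)
  multi <- names(adm_per_patient)[adm_per_patient >= 2L]
  dropped_single <- nrow(kept) - sum(kept$patient_id %in% multi)
  kept <- kept[kept$patient_id %in% multi, , drop = FALSE]
  kept <- kept[order(kept$patient_id, kept$admit_date), , drop = FALSE]
  rownames(kept) <- NULL

  if (raw_records > 0 && dropped_missing / raw_records > warn_drop_fraction)
    warning(sprintf("%.1f%% of rows dropped for missing/invalid fields",
                    100 * dropped_missing / raw_records), call. = FALSE)

  report <- structure(list(
    raw_records = raw_records,
    raw_patients = raw_patients,
    kept_records = nrow(kept),
    kept_patients = length(unique(kept$patient_id)),
    retention_pct = if (raw_records > 0)
      retention_pct(nrow(kept), raw_records, digits = NA) else 0,
    dropped_missing = dropped_missing,
    dropped_single_admission = dropped_single,
    dropped_duplicates = dropped_duplicates), class = "cleaning_report")
  list(records = kept, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat(sprintf("  records: %d -> %d (screening rate %.2f%%)\n",
              x$raw_records, x$kept_records, x$retention_pct))
  cat(sprintf("  patients: %d -> %d\n", x$raw_patients, x$kept_patients))
  cat(sprintf("  dropped: %d missing/invalid, %d duplicates, %d in patients with <2 admissions\n",
              x$dropped_missing, x$dropped_duplicates,
              x$dropped_single_admission))
  invisible(x)
}

#' Patient-level disease category indicators
#'
#' Collapses cleaned admissions to one row per (patient, category): a
#' patient carries a category if any admission anywhere in the trajectory
#' contains a member code, counted once regardless of how many
#' hospitalizations repeat the diagnosis. Also returns one demographic row
#' per patient (sex, age at first admission, age band, stratum).
#'
#' @param records Cleaned admission records.
#' @param catalog A `disease_catalog`.
#' @return List with `flags` (data.table `patient_id`, `category`, `klass`)
#'   and `patients` (data.table `patient_id`, `sex`, `age`, `band`,
#'   `stratum`).
#' @export
patient_categories <- function(records, catalog) {
  stopifnot(is.data.frame(records))
  dt <- data.table::as.data.table(records)
  patient_id <- admit_date <- age <- category <- klass <- NULL
  band <- stratum <- NULL
  pat <- dt[, .(sex = sex[1L], age = age[which.min(admit_date)]),
            by = patient_id]
  pat[, band := age_band(age)]
  pat[, stratum := paste(sex, band, sep = "/")]
  code_list <- strsplit(dt$codes, ";", fixed = TRUE)
  long <- data.table::data.table(
    patient_id = rep(dt$patient_id, lengths(code_list)),
    code = unlist(code_list, use.names = FALSE))
  ucode <- unique(long$code)
  map <- data.table::data.table(code = ucode,
                                category = categorize(ucode, catalog),
                                klass = categorize(ucode, catalog, "klass"))
  long <- merge(long, map, by = "code", allow.cartesian = TRUE)
  flags <- unique(long[!is.na(category),
                       c("patient_id", "category", "klass")])
  data.table::setorder(flags, patient_id, category)
  list(flags = flags, patients = pat)
}

#' Category prevalence table
#'
#' Counts, for every catalog category of the requested class, the number of
#' distinct patients carrying at least one member code anywhere in their
#' trajectory, and expresses it as a percentage of the cohort.
#'
#' @param records Cleaned admission records (non-empty).
#' @param catalog A `disease_catalog`.
#' @param klass `"mental"`, `"physical"`, or `"both"`.
#' @return A `prevalence_table`: data.frame `category`, `klass`, `n`
#'   (distinct patients), `prevalence_pct` (2 decimals; the unrounded value
#'   is kept in column `prevalence_exact`), with attribute `N` = cohort
#'   size.
#' @export
prevalence <- function(records, catalog,
                       klass = c("both", "mental", "physical")) {
  klass <- match.arg(klass)
  if (nrow(records) == 0L) stop("empty cohort", call. = FALSE)
  pc <- patient_categories(records, catalog)
  N <- nrow(pc$patients)
  category <- patient_id <- NULL
  counts <- pc$flags[, .(n = length(unique(patient_id))), by = category]
  cats <- catalog$categories
  if (klass != "both") cats <- cats[cats$klass == klass, , drop = FALSE]
  out <- data.frame(category = cats$category, klass = cats$klass,
                    stringsAsFactors = FALSE)
  out$n <- counts$n[match(out$category, counts$category)]
  out$n[is.na(out$n)] <- 0L
  prevalence_table(out$category, out$n, N, klass = out$klass)
}

#' Construct a prevalence table from counts
#'
#' Used by [prevalence()] and directly when the distinct-patient counts are
#' already known (for example, counts printed in a published cohort table).
#'
#' @param category Category names.
#' @param n Distinct-patient counts.
#' @param N Cohort size.
#' @param klass Optional class labels.
#' @return A `prevalence_table` data.frame.
#' @export
prevalence_table <- function(category, n, N, klass = NA_character_) {
  stopifnot(length(category) == length(n), N > 0, all(n >= 0), all(n <= N))
  out <- data.frame(category = category, klass = klass, n = as.integer(n),
                    prevalence_pct = prevalence_pct(n, N),
                    prevalence_exact = prevalence_pct(n, N, digits = NA),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N") <- as.integer(N)
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Apply the prevalence inclusion filter
#'
#' Retains categories whose prevalence is greater than or equal to the
#' threshold (default 1% of the cohort). The comparison uses the unrounded
#' prevalence, so a category at exactly the threshold is included.
#'
#' @param table A `prevalence_table`.
#' @param threshold_pct Inclusion threshold in percent.
#' @return Character vector of included category names.
#' @export
apply_inclusion_filter <- function(table, threshold_pct = 1.0) {
  stopifnot(inherits(table, "prevalence_table"))
  table$category[table$prevalence_exact >= threshold_pct]
}

#' Age bands and cohort strata
#'
#' The cohort is partitioned into five age bands — half-open,
#' lower-inclusive: `[0,18)`, `[18,45)`, `[45,60)`, `[60,80)`, `[80,Inf)` —
#' labelled `0-18`, `18-45`, `45-60`, `60-80`, `>80`, and crossed with sex
#' into 10 strata labelled `"<sex>/<band>"`.
#'
#' @param age Integer ages in years (>= 0).
#' @param sex `"M"`/`"F"` vector (recycled against `age`).
#' @return `age_band()`: factor of band labels. `assign_stratum()`:
#'   character vector of stratum labels.
#' @examples
#' assign_stratum(c(17, 18, 81), c("M", "M", "F"))
#' @export
age_band <- function(age) {
  if (any(is.na(age)) || any(age < 0))
    stop("age must be non-negative and non-missing", call. = FALSE)
  cut(age, breaks = c(0, 18, 45, 60, 80, Inf), right = FALSE,
      labels = age_band_labels())
}

#' @rdname age_band
#' @export
assign_stratum <- function(age, sex) {
  sex <- toupper(as.character(sex))
  if (!all(sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'", call. = FALSE)
  paste(sex, age_band(age), sep = "/")
}
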