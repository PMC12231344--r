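# Shared fixtures built in code: tiny admission tables and a cached
# mid-sized synthetic cohort reused across test files.

make_records <- function(...) {
  # each argument: one patient as list(sex=, age=, codes = list of
  # per-admission semicolon strings)
  pats <- list(...)
  rows <- list()
  for (p in seq_along(pats)) {
    pat <- pats[[p]]
    n <- length(pat$codes)
    rows[[p]] <- data.frame(
      patient_id = sprintf("T%03d", p),
      sex = pat$sex %||% "M",
      age = pat$age %||% 50L,
      admit_date = as.Date("2018-01-01") + seq_len(n) * 30L,
      discharge_date = as.Date("2018-01-05") + seq_len(n) * 30L,
      codes = unlist(pat$codes),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digest_df <- function(df) {
  tmp <- tempfile(); on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

# one generated cohort shared by the heavier tests (built once per run)
shared_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      rec <- generate_cohort(cohort_spec(4000, seed = 20260925))
      cl <- clean_records(rec)
      cat10 <- default_catalog()
      inc <- apply_inclusion_filter(prevalence(cl$records, cat10, "mental"))
      memo <<- list(records = cl$records, report = cl$report,
                    catalog = cat10, included_mental = inc)
    }
    memo
  }
})
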