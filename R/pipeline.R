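#' Read and write canonical admission-record CSV
#'
#' The canonical long format has one row per admission: `patient_id`,
#' `sex` (`M`/`F`), `age`, `admit_date` and `discharge_date` (ISO-8601),
#' and `codes` (semicolon-separated ICD-10 codes, up to 16). A wide
#' dialect carrying the diagnosis codes in columns `diag1`..`diag16` is
#' accepted on read and collapsed into `codes`.
#'
#' @param path CSV file path.
#' @return `read_admissions()`: data.frame of admission records.
#' @export
read_admissions <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path,
                               call. = FALSE)
  df <- data.table::fread(path, colClasses = list(character = "patient_id"),
                          data.table = FALSE)
  diag_cols <- grep("^diag[0-9]+$", names(df), value = TRUE)
  if (!"codes" %in% names(df) && length(diag_cols)) {
    diag_cols <- diag_cols[order(as.integer(sub("diag", "", diag_cols)))]
    df$codes <- apply(df[diag_cols], 1L, function(r) {
      r <- trimws(as.character(r))
      paste(r[!is.na(r) & nzchar(r) & r != "NA"], collapse = ";")
    })
    df <- df[setdiff(names(df), diag_cols)]
  }
  need <- c("patient_id", "sex", "age", "admit_date", "discharge_date",
            "codes")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("records file lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$admit_date <- as.Date(df$admit_date)
  df$discharge_date <- as.Date(df$discharge_date)
  df[need]
}

#' @rdname read_admissions
#' @param records data.frame of admission records.
#' @export
write_admissions <- function(records, path) {
  data.table::fwrite(records, path)
  invisible(path)
}

#' Write a cohort spec's synthetic records to the canonical CSV
#'
#' @param spec A [cohort_spec()] (or a YAML file path understood by
#'   [read_cohort_spec()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
simulate_admissions <- function(spec, path) {
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  write_admissions(generate_cohort(spec), path)
}

#' Read a cohort spec from YAML
#'
#' Recognized fields: `n_patients`, `seed`, and optionally
#' `age_sex_weights`, `physical_prevalence`, `mental_baseline` (named
#' maps) and `planted_effects` (list of `physical`, `mental`, `p_given`,
#' `p_not_given`). Omitted fields use the package defaults.
#'
#' @param path YAML file path.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("n_patients", "seed", "age_sex_weights", "physical_prevalence",
             "mental_baseline", "planted_effects")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown cohort spec field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(y$n_patients)) stop("cohort spec lacks n_patients",
                                  call. = FALSE)
  args <- list(n_patients = y$n_patients, seed = y$seed %||% 1L)
  for (f in c("age_sex_weights", "physical_prevalence", "mental_baseline"))
    if (!is.null(y[[f]])) args[[f]] <- unlist(y[[f]])
  if (!is.null(y$planted_effects)) args$planted_effects <- y$planted_effects
  do.call(cohort_spec, args)
}

#' Configure the end-to-end pipeline
#'
#' Validates every knob before any stage runs; unknown arguments are
#' rejected. Stage toggles let a run stop after cleaning/prevalence, skip
#' the model bank (supplying `risk_categories` directly to the comorbidity
#' stage), or skip the comorbidity stage.
#'
#' @param records_path Input admission CSV (alternatively pass a records
#'   data.frame to [run_pipeline()] directly).
#' @param out_dir Output directory (created if needed).
#' @param catalog_path Catalog CSV, `NULL` for the bundled default.
#' @param inclusion_threshold_pct Prevalence inclusion threshold.
#' @param min_occurrences Rare-code pruning threshold.
#' @param feature_mode `"single"` or `"cumulative"` trajectory features.
#' @param train_fraction Train share of the patient-level split.
#' @param families Model families to train.
#' @param oversample Oversample minority instances during training.
#' @param run_models,run_comorbidity Stage toggles.
#' @param risk_categories Physical categories for the comorbidity stage
#'   when the model stage is disabled (ignored otherwise).
#' @param top_k Top-k cutoff for importance consensus.
#' @param min_stratum_n Minimum stratum size for stratified tables.
#' @param seed Global seed; all stage seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(records_path = NULL, out_dir = "comorisk_out",
                            catalog_path = NULL,
                            inclusion_threshold_pct = 1.0,
                            min_occurrences = 5L,
                            feature_mode = "single",
                            train_fraction = 0.7,
                            families = c("random_forest", "extra_trees",
                                         "hist_gradient_boosting",
                                         "regularized_gradient_boosting"),
                            oversample = TRUE,
                            run_models = TRUE, run_comorbidity = TRUE,
                            risk_categories = NULL,
                            top_k = 10L, min_stratum_n = 50L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(feature_mode %in% c("single", "cumulative"),
            train_fraction > 0, train_fraction < 1,
            all(families %in% c("random_forest", "extra_trees",
                                "hist_gradient_boosting",
                                "regularized_gradient_boosting")))
  if (!cfg$run_models && cfg$run_comorbidity &&
      is.null(cfg$risk_categories))
    stop("risk_categories must be supplied when the model stage is disabled",
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Run the full comorbidity-risk pipeline
#'
#' Executes, honoring the config's toggles: clean -> prevalence and
#' inclusion filter -> trajectory instances (prune, split) -> the
#' four-model bank with importance consensus -> comorbidity-intensity
#' tables, full-cohort and stratified. All outputs are written under
#' `out_dir` as plain CSV/JSON and a run manifest with file digests is
#' written last; identical config, input, and seed give identical digests.
#'
#' @param config A [pipeline_config()].
#' @param records Optional in-memory records data.frame (overrides
#'   `config$records_path`).
#' @return The manifest, invisibly (list: config hash, seed, stage log,
#'   output digests, package version).
#' @export
run_pipeline <- function(config, records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- load_catalog(config$catalog_path)
  stages <- list()
  outputs <- character(0)
  tick <- function(name, start) {
    stages[[name]] <<- round(as.numeric(Sys.time()) - as.numeric(start), 3)
  }
  emit <- function(obj, file, writer = data.table::fwrite) {
    path <- file.path(config$out_dir, file)
    writer(obj, path)
    outputs <<- c(outputs, path)
  }
  write_json_file <- function(obj, path)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)

  if (is.null(records)) {
    if (is.null(config$records_path))
      stop("no input records: set records_path or pass records",
           call. = FALSE)
    records <- read_admissions(config$records_path)
  }

  s <- Sys.time()
  cleaned <- clean_records(records)
  emit(unclass(cleaned$report), "cleaning_report.json", write_json_file)
  tick("clean", s)

  s <- Sys.time()
  prev <- prevalence(cleaned$records, catalog)
  emit(as.data.frame(prev), "prevalence.csv")
  prev_mental <- prev[prev$klass == "mental", , drop = FALSE]
  class(prev_mental) <- class(prev)
  included_mental <- apply_inclusion_filter(prev_mental,
                                            config$inclusion_threshold_pct)
  tick("prevalence", s)

  s <- Sys.time()
  instances <- build_instances(cleaned$records, catalog,
                               target = included_mental,
                               feature_mode = config$feature_mode)
  pruned <- prune_rare(instances, config$min_occurrences)
  split <- split_instances(pruned, config$train_fraction,
                           seed = config$seed)
  emit(pruned$instances, "instances.csv")
  writeLines(pruned$vocabulary, file.path(config$out_dir, "vocabulary.txt"))
  outputs <- c(outputs, file.path(config$out_dir, "vocabulary.txt"))
  tick("dataset", s)

  risk_categories <- config$risk_categories
  if (config$run_models) {
    s <- Sys.time()
    metrics <- list(); rankings <- list()
    for (fam in config$families) {
      spec <- model_spec(fam, oversample = config$oversample,
                         seed = config$seed)
      model <- train_model(spec, split)
      ev <- evaluate_model(model, split, on = "test")
      metrics[[fam]] <- data.frame(model = fam, accuracy = ev$accuracy,
                                   precision = ev$precision,
                                   recall = ev$recall, f1 = ev$f1,
                                   auc = ev$auc,
                                   optimal_threshold = ev$optimal_threshold)
      rankings[[fam]] <- rank_importances(model)
      emit(as.data.frame(rankings[[fam]]),
           paste0("importance_", fam, ".csv"))
      roc <- compute_auc(ev$scores, ev$labels)$roc
      emit(roc, paste0("roc_", fam, ".csv"))
    }
    emit(do.call(rbind, metrics), "metrics.csv")
    cons <- if (length(rankings) >= 4L) {
      consensus(rankings, k = config$top_k, catalog = catalog)
    } else {
      consensus_sets(lapply(rankings,
                            function(r) utils::head(r$feature,
                                                    config$top_k)),
                     catalog)
    }
    emit(unclass(cons)[c("core_codes", "extended_codes", "core_categories",
                         "extended_categories")],
         "consensus.json", write_json_file)
    risk_categories <- cons$core_categories
    tick("models", s)
  }

  if (config$run_comorbidity) {
    s <- Sys.time()
    pc <- patient_categories(cleaned$records, catalog)
    full <- screen_pairs(compute_pairs(pc, risk_categories,
                                       included_mental))
    emit(full$all, "pairs_full.csv")
    emit(full$all[!is.na(full$all$rr), c("category_i", "category_j",
                                         "rr", "phi")],
         "rr_phi_scatter.csv")
    strat <- stratified_analysis(cleaned$records, catalog, risk_categories,
                                 included_mental,
                                 min_n = config$min_stratum_n)
    emit(strat, "pairs_stratified.csv")
    tick("comorbidity", s)
  }

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("comorisk")),
    seed = config$seed,
    config_hash = hash_object(cfg_for_hash),
    stages = stages,
    included_mental = included_mental,
    risk_categories = risk_categories,
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)),
    elapsed_s = round(as.numeric(Sys.time()) - as.numeric(t0), 3))
  write_json_file(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}

# md5 of a canonical serialization; used for the config hash
hash_object <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
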