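#' Convert ordered admissions into labeled classification instances
#'
#' Each patient's chronologically ordered admissions are scanned in
#' consecutive pairs. While the current record carries no target-category
#' code, an instance is emitted whose features are that record's non-target
#' codes (`feature_mode = "single"`) or the union of non-target codes seen
#' so far (`"cumulative"`); its label is 1 if the *next* record contains a
#' target code and 0 otherwise. Emission stops at the first label-1
#' instance (each patient contributes at most one positive) or when the
#' records run out. Patients whose first record already carries the target
#' yield no instances; their count is reported via a message.
#'
#' The target defaults to "any mental disorder": every mental category in
#' the catalog. Codes mapping to a target category are excluded from
#' feature sets — asserted on every build as a leakage guard.
#'
#' @param records Cleaned admission records, sorted by patient and admit
#'   date (unsorted input is rejected).
#' @param catalog A `disease_catalog`.
#' @param target Character vector of target (mental) category names.
#' @param feature_mode `"single"` or `"cumulative"`.
#' @return data.frame of instances: `patient_id`, `age`, `sex`, `label`
#'   (0/1), `codes` (semicolon-separated non-target feature codes, possibly
#'   empty).
#' @export
build_instances <- function(records, catalog,
                            target = catalog_categories(catalog, "mental"),
                            feature_mode = c("single", "cumulative")) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(is.data.frame(records), length(target) >= 1L)
  dt <- data.table::as.data.table(records)
  patient_id <- admit_date <- NULL
  if (anyDuplicated(rle(as.character(dt$patient_id))$values))
    stop("records of each patient must be contiguous", call. = FALSE)
  ord <- dt[, is.unsorted(as.numeric(admit_date)), by = patient_id]
  if (any(ord$V1))
    stop("admissions must be sorted chronologically within patient",
         call. = FALSE)

  code_list <- strsplit(dt$codes, ";", fixed = TRUE)
  ucode <- unique(unlist(code_list, use.names = FALSE))
  is_target_code <- stats::setNames(categorize(ucode, catalog) %in% target,
                                    ucode)
  feat_list <- lapply(code_list, function(cc) cc[!is_target_code[cc]])
  has_target <- vapply(code_list, function(cc) any(is_target_code[cc]),
                       logical(1))

  dt[, `:=`(row_i = .I)]
  row_i <- NULL
  per <- dt[, {
    n <- .N
    ht <- has_target[row_i]
    t_idx <- if (any(ht)) which(ht)[1L] else NA_integer_
    K <- if (!is.na(t_idx)) t_idx - 1L else n - 1L
    K <- min(K, n - 1L)
    list(n = n, t_idx = t_idx, K = K, first_row = row_i[1L])
  }, by = patient_id]
  excluded_at_start <- sum(!is.na(per$t_idx) & per$t_idx == 1L)
  if (excluded_at_start > 0L)
    message(excluded_at_start,
            " patient(s) excluded: first record already carries the target")

  keep <- per$K >= 1L
  per <- per[keep]
  if (nrow(per) == 0L)
    return(data.frame(patient_id = character(0), age = integer(0),
                      sex = character(0), label = integer(0),
                      codes = character(0), stringsAsFactors = FALSE))

  inst_pid <- rep(per$patient_id, per$K)
  ks <- sequence(per$K)
  rows <- rep(per$first_row, per$K) + ks - 1L
  t_rep <- rep(per$t_idx, per$K)
  label <- as.integer(!is.na(t_rep) & ks + 1L == t_rep)

  feats <- if (feature_mode == "single") {
    feat_list[rows]
  } else {
    # running union of non-target codes r_1..r_k within each patient
    out <- vector("list", length(rows))
    pos <- 1L
    for (p in seq_len(nrow(per))) {
      acc <- character(0)
      base <- per$first_row[p]
      for (k in seq_len(per$K[p])) {
        acc <- unique(c(acc, feat_list[[base + k - 1L]]))
        out[[pos]] <- acc
        pos <- pos + 1L
      }
    }
    out
  }
  # leakage guard: no feature code may map to a target category
  fu <- unique(unlist(feats, use.names = FALSE))
  if (length(fu) && any(is_target_code[fu]))
    stop("internal error: target-category code leaked into features",
         call. = FALSE)
  data.frame(patient_id = inst_pid,
             age = dt$age[rows],
             sex = dt$sex[rows],
             label = label,
             codes = vapply(feats, paste, character(1), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Remove rare feature codes and emptied instances
#'
#' Drops from the feature vocabulary every code present in fewer than
#' `min_occurrences` instances (presence, not multiplicity), then removes
#' instances whose feature set becomes empty. Deterministic.
#'
#' @param instances Instance data.frame from [build_instances()].
#' @param min_occurrences Minimum number of instances a code must appear in.
#' @return List with `instances` (filtered) and `vocabulary`
#'   (lexicographically sorted retained codes).
#' @export
prune_rare <- function(instances, min_occurrences = 5L) {
  stopifnot(is.data.frame(instances), min_occurrences >= 1L)
  code_list <- lapply(strsplit(instances$codes, ";", fixed = TRUE),
                      function(cc) unique(cc[nzchar(cc)]))
  freq <- table(unlist(code_list, use.names = FALSE))
  vocab <- sort(names(freq)[freq >= min_occurrences])
  kept_codes <- lapply(code_list, function(cc) cc[cc %in% vocab])
  nonempty <- lengths(kept_codes) > 0L
  if (!any(nonempty))
    stop("pruning at min_occurrences = ", min_occurrences,
         " removed every instance", call. = FALSE)
  out <- instances[nonempty, , drop = FALSE]
  out$codes <- vapply(kept_codes[nonempty], paste, character(1),
                      collapse = ";")
  rownames(out) <- NULL
  list(instances = out, vocabulary = vocab)
}

#' Patient-level train/test split
#'
#' Splits *patients* (never instances) into train and test at the given
#' fraction, stratified on the patient-level label (whether the patient
#' contributes a positive instance) so both sides keep both classes.
#' Within-patient leakage across the split is impossible by construction.
#'
#' @param pruned List from [prune_rare()] (or a list with `instances` and
#'   `vocabulary`).
#' @param train_fraction Fraction of patients assigned to training.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return An object of class `dataset_split`: list with `train`, `test`
#'   (instance data.frames), `vocabulary`, `seed`.
#' @export
split_instances <- function(pruned, train_fraction = 0.7, seed = 1L) {
  instances <- pruned$instances
  vocabulary <- pruned$vocabulary
  stopifnot(is.data.frame(instances), train_fraction > 0, train_fraction < 1)
  agg <- tapply(instances$label, instances$patient_id, max)
  if (length(unique(agg)) < 2L)
    stop("degenerate label distribution: patients of a single class",
         call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train_pid <- character(0)
  for (lab in c(0, 1)) {
    pids <- sort(names(agg)[agg == lab])
    n_tr <- round(length(pids) * train_fraction)
    train_pid <- c(train_pid, sample(pids, n_tr))
  }
  in_train <- instances$patient_id %in% train_pid
  train <- instances[in_train, , drop = FALSE]
  test <- instances[!in_train, , drop = FALSE]
  if (length(unique(train$patient_id)) < 2L ||
      length(unique(test$patient_id)) < 2L)
    stop("too few patients on one side of the split", call. = FALSE)
  rownames(train) <- rownames(test) <- NULL
  structure(list(train = train, test = test, vocabulary = vocabulary,
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>\n")
  cat(sprintf("  train: %d instances (%d patients, %.1f%% positive)\n",
              nrow(x$train), length(unique(x$train$patient_id)),
              100 * mean(x$train$label)))
  cat(sprintf("  test:  %d instances (%d patients, %.1f%% positive)\n",
              nrow(x$test), length(unique(x$test$patient_id)),
              100 * mean(x$test$label)))
  cat("  vocabulary:", length(x$vocabulary), "codes\n")
  invisible(x)
}

#' Encode instances as a numeric feature matrix
#'
#' Multi-hot encoding of the feature codes over a fixed vocabulary,
#' followed by the demographic columns `age` (years) and `sex`
#' (male = 1, female = 0). Column order is the vocabulary order then the
#' demographics, stable across calls.
#'
#' @param instances Instance data.frame.
#' @param vocabulary Ordered character vector of feature codes.
#' @param demographics Include age and sex columns (default `TRUE`).
#' @return List with `x` (numeric matrix) and `y` (integer 0/1 labels).
#' @export
vectorize <- function(instances, vocabulary, demographics = TRUE) {
  stopifnot(is.data.frame(instances))
  n <- nrow(instances)
  p <- length(vocabulary)
  x <- matrix(0, nrow = n, ncol = p,
              dimnames = list(NULL, vocabulary))
  if (n > 0L && p > 0L) {
    code_list <- lapply(strsplit(instances$codes, ";", fixed = TRUE), unique)
    j <- lapply(code_list, function(cc) match(cc[cc %in% vocabulary],
                                              vocabulary))
    i <- rep(seq_len(n), lengths(j))
    x[cbind(i, unlist(j, use.names = FALSE))] <- 1
  }
  if (demographics)
    x <- cbind(x, age = as.numeric(instances$age),
               sex = as.numeric(instances$sex == "M"))
  list(x = x, y = as.integer(instances$label))
}
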