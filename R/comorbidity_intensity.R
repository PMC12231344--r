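#' Pairwise 2x2 counts for a disease pair
#'
#' Counts, at patient level, the 2x2 margins behind the comorbidity
#' statistics: `C` patients with both categories, `P_i` and `P_j` patients
#' with each, and the cohort size `N`. A patient is counted once per
#' category regardless of how many admissions repeat the diagnosis.
#'
#' @param has_i,has_j Logical patient-level indicator vectors over the same
#'   cohort (equal length).
#' @return An object of class `pair_counts` with `C`, `P_i`, `P_j`, `N`.
#' @export
pair_counts <- function(has_i, has_j) {
  if (length(has_i) != length(has_j))
    stop("indicator vectors must cover the same cohort", call. = FALSE)
  if (length(has_i) == 0L) stop("empty cohort", call. = FALSE)
  stopifnot(is.logical(has_i), is.logical(has_j))
  structure(list(C = sum(has_i & has_j), P_i = sum(has_i),
                 P_j = sum(has_j), N = length(has_i)),
            class = "pair_counts")
}

#' @rdname pair_counts
#' @param pc Result of [patient_categories()].
#' @param i,j Category names.
#' @export
count_pair <- function(pc, i, j) {
  pids <- pc$patients$patient_id
  with_cat <- function(cat) pids %in%
    pc$flags$patient_id[pc$flags$category == cat]
  pair_counts(with_cat(i), with_cat(j))
}

#' Comorbidity intensity of a disease pair: relative risk and phi
#'
#' From patient-level 2x2 counts, the relative risk is
#' `RR = C * N / (P_i * P_j)` — observed co-occurrence over that expected
#' under independence — and the phi coefficient is
#' `phi = (C*N - P_i*P_j) / sqrt(P_i * P_j * (N - P_i) * (N - P_j))`,
#' identical to the Pearson correlation of the two binary indicators.
#' Pairs with a degenerate margin (`P` of 0 or `N`) have undefined
#' intensity: both statistics are returned `NA` with a `reason`, never a
#' silent NaN.
#'
#' @param counts A `pair_counts` object.
#' @return List with the counts plus `rr`, `phi`, and `reason`
#'   (`NA` when defined).
#' @examples
#' intensity(pair_counts_raw(C = 40, P_i = 100, P_j = 200, N = 1000))
#' @export
intensity <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  with(counts, {
    if (C > min(P_i, P_j) || P_i > N || P_j > N)
      stop("inconsistent pair counts", call. = FALSE)
    if (P_i %in% c(0L, N) || P_j %in% c(0L, N)) {
      return(c(counts, list(rr = NA_real_, phi = NA_real_,
                            reason = "degenerate margin")))
    }
    rr <- (C / P_i) / (P_j / N) # == C*N/(P_i*P_j), overflow-safe form
    phi <- (C * as.numeric(N) - as.numeric(P_i) * P_j) /
      sqrt(as.numeric(P_i) * P_j * (N - P_i) * (N - P_j))
    c(counts, list(rr = rr, phi = phi, reason = NA_character_))
  })
}

#' @rdname pair_counts
#' @param C,P_i,P_j,N Counts given directly.
#' @export
pair_counts_raw <- function(C, P_i, P_j, N) {
  stopifnot(C >= 0, P_i >= 0, P_j >= 0, N > 0, C <= min(P_i, P_j),
            P_i <= N, P_j <= N)
  structure(list(C = C, P_i = P_i, P_j = P_j, N = N), class = "pair_counts")
}

#' Comorbidity-intensity table for a set of disease pairs
#'
#' Computes [intensity()] for every (physical, mental) category pair over
#' the patient-level indicators of a cohort (or stratum).
#'
#' @param pc Result of [patient_categories()] (optionally restricted to a
#'   stratum).
#' @param categories_i,categories_j Character vectors of category names
#'   (conventionally: risk physical categories and target mental
#'   categories).
#' @return data.frame with `category_i`, `category_j`, `C`, `P_i`, `P_j`,
#'   `N`, `rr`, `phi`, `reason`.
#' @export
compute_pairs <- function(pc, categories_i, categories_j) {
  pids <- pc$patients$patient_id
  ind <- function(cat) pids %in%
    pc$flags$patient_id[pc$flags$category == cat]
  ind_i <- lapply(categories_i, ind)
  ind_j <- lapply(categories_j, ind)
  grid <- expand.grid(i = seq_along(categories_i),
                      j = seq_along(categories_j))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    ii <- grid$i[g]; jj <- grid$j[g]
    r <- intensity(pair_counts(ind_i[[ii]], ind_j[[jj]]))
    data.frame(category_i = categories_i[ii], category_j = categories_j[jj],
               C = r$C, P_i = r$P_i, P_j = r$P_j, N = r$N,
               rr = r$rr, phi = r$phi, reason = r$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen pairs by comorbidity-intensity thresholds
#'
#' Mutually exclusive or independent combinations (`RR <= 1` or
#' `phi <= 0`) are excluded; among the included pairs, the high-intensity
#' subset satisfies `RR > 1.2` and `phi > 0.1`. The top-k table ranks the
#' included pairs by RR with phi as the tiebreaker.
#'
#' @param pairs data.frame from [compute_pairs()].
#' @param rr_include,phi_include Strict lower bounds for inclusion.
#' @param rr_high,phi_high Strict lower bounds for the high-intensity
#'   subset.
#' @param top_k Rows of the ranked table to return.
#' @return List with `included`, `high`, and `top` data.frames (each
#'   carries logical columns `included`, `high` as well).
#' @export
screen_pairs <- function(pairs, rr_include = 1, phi_include = 0,
                         rr_high = 1.2, phi_high = 0.1, top_k = 10L) {
  stopifnot(is.data.frame(pairs))
  ok <- !is.na(pairs$rr) & !is.na(pairs$phi)
  pairs$included <- ok & pairs$rr > rr_include & pairs$phi > phi_include
  pairs$high <- pairs$included & pairs$rr > rr_high & pairs$phi > phi_high
  inc <- pairs[pairs$included, , drop = FALSE]
  ord <- order(-inc$rr, -inc$phi, inc$category_i, inc$category_j)
  inc <- inc[ord, , drop = FALSE]
  rownames(inc) <- NULL
  high <- inc[inc$high, , drop = FALSE]
  rownames(high) <- NULL
  list(all = pairs, included = inc, high = high,
       top = utils::head(inc, top_k))
}

#' Sex- and age-stratified comorbidity analysis
#'
#' Runs [compute_pairs()] and [screen_pairs()] independently within the
#' full cohort, the two sex groups, and the 10 sex-by-age-band strata.
#' Every stratum uses its own `N`, so an association confined to one
#' subgroup surfaces only there. Strata smaller than `min_n` patients are
#' skipped with a message.
#'
#' @param records Cleaned admission records.
#' @param catalog A `disease_catalog`.
#' @param categories_i Risk (physical) category names.
#' @param categories_j Target (mental) category names.
#' @param min_n Minimum stratum size (default 50).
#' @param ... Threshold arguments passed to [screen_pairs()].
#' @return data.frame of per-stratum pair statistics with columns
#'   `stratum`, `level` (`all`/`sex`/`sex_age`) and the [compute_pairs()]
#'   columns plus `included`/`high` flags.
#' @export
stratified_analysis <- function(records, catalog, categories_i, categories_j,
                                min_n = 50L, ...) {
  pc <- patient_categories(records, catalog)
  strata <- c(list(all = rep(TRUE, nrow(pc$patients))),
              stats::setNames(lapply(c("M", "F"),
                                     function(s) pc$patients$sex == s),
                              c("M", "F")))
  for (s in sort(unique(pc$patients$stratum)))
    strata[[s]] <- pc$patients$stratum == s
  out <- list()
  for (nm in names(strata)) {
    keep <- strata[[nm]]
    n_str <- sum(keep)
    if (n_str < min_n) {
      message("stratum '", nm, "' skipped: ", n_str, " patients < min_n = ",
              min_n)
      next
    }
    pids <- pc$patients$patient_id[keep]
    sub <- list(flags = pc$flags[pc$flags$patient_id %in% pids, ,
                                 drop = FALSE],
                patients = pc$patients[keep, , drop = FALSE])
    tab <- compute_pairs(sub, categories_i, categories_j)
    tab <- screen_pairs(tab, ...)$all
    tab$stratum <- nm
    tab$level <- if (nm == "all") "all"
                 else if (nm %in% c("M", "F")) "sex" else "sex_age"
    out[[nm]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
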