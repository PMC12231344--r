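#' Normalize raw ICD-10 codes to 4-character form
#'
#' Diagnosis codes exported from hospital systems come in many dialects:
#' lower case, without the decimal point (`"E785"`), with extra specificity
#' (`"E78.51"`), or with a trailing wildcard (`"I10.x"`). All analyses in
#' this package run on a canonical 4-character form: an upper-case letter,
#' two digits, and optionally a decimal point plus one digit
#' (`"I50.9"`, `"I10"`). Longer codes are truncated to that resolution and
#' `"x"` wildcards collapse to the 3-character prefix.
#'
#' Normalization is idempotent: `normalize_code(normalize_code(x))` equals
#' `normalize_code(x)`.
#'
#' @param raw Character vector of raw ICD-10 code strings.
#' @return Character vector of normalized codes matching
#'   `^[A-Z][0-9]{2}(\.[0-9])?$`.
#' @examples
#' normalize_code(c("I50.9", "i10.x", "E78.51", "n40"))
#' @export
normalize_code <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- toupper(trimws(as.character(raw)))
  compact <- gsub(".", "", x, fixed = TRUE)
  ok <- !is.na(compact) & grepl("^[A-Z][0-9]{2}[0-9X]*$", compact)
  if (any(!ok)) {
    bad <- unique(raw[!ok])
    stop("malformed ICD-10 code(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "",
         call. = FALSE)
  }
  fourth <- substr(compact, 4L, 4L)
  ifelse(fourth == "" | fourth == "X",
         substr(compact, 1L, 3L),
         paste0(substr(compact, 1L, 3L), ".", fourth))
}

# Member token kinds: exact 4-char code ("I50.9"), 3-char prefix ("N40"),
# 3-char range ("F00-F09") or 4-char range ("F51.0-F51.3").
parse_member_token <- function(token, category) {
  token <- toupper(trimws(token))
  if (grepl("^[A-Z][0-9]{2}\\.[0-9]$", token)) {
    return(list(kind = "exact", codes = token))
  }
  if (grepl("^[A-Z][0-9]{2}$", token)) {
    return(list(kind = "prefix", codes = token))
  }
  if (grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", token)) {
    lo <- sub("-.*", "", token); hi <- sub(".*-", "", token)
    if (substr(lo, 1L, 1L) != substr(hi, 1L, 1L))
      stop("range endpoints must share a letter: ", token, " (", category, ")",
           call. = FALSE)
    nums <- seq(as.integer(substr(lo, 2L, 3L)), as.integer(substr(hi, 2L, 3L)))
    return(list(kind = "prefix",
                codes = sprintf("%s%02d", substr(lo, 1L, 1L), nums)))
  }
  if (grepl("^[A-Z][0-9]{2}\\.[0-9]-[A-Z][0-9]{2}\\.[0-9]$", token)) {
    lo <- sub("-.*", "", token); hi <- sub(".*-", "", token)
    if (substr(lo, 1L, 3L) != substr(hi, 1L, 3L))
      stop("4-character range endpoints must share a 3-character stem: ",
           token, " (", category, ")", call. = FALSE)
    digs <- seq(as.integer(substr(lo, 5L, 5L)), as.integer(substr(hi, 5L, 5L)))
    return(list(kind = "exact",
                codes = sprintf("%s.%d", substr(lo, 1L, 3L), digs)))
  }
  stop("unparseable catalog member token: '", token, "' in category '",
       category, "'", call. = FALSE)
}

#' Build a disease catalog from category definitions
#'
#' A catalog maps normalized ICD-10 codes to named disease categories, each
#' flagged as chronic `physical` or `mental`. Members of a category are
#' given as tokens: exact 4-character codes (`"I50.9"`), 3-character
#' prefixes (`"N40"`, matching the bare code and all its decimal children),
#' or inclusive ranges (`"F00-F09"`, `"F51.0-F51.3"`).
#'
#' Validation enforces the structural constraints the downstream statistics
#' rely on: mental members all lie in the ICD-10 F chapter, physical members
#' never do, and no code can resolve to two categories of the same class.
#'
#' @param categories data.frame with columns `category`, `klass`
#'   (`"physical"` or `"mental"`), and `members` (semicolon-separated
#'   tokens; may be empty for categories whose code lists are supplied
#'   later).
#' @param version Character version tag stored on the catalog.
#' @return An object of class `disease_catalog`.
#' @seealso [load_catalog()], [default_catalog()], [categorize()]
#' @export
disease_catalog <- function(categories, version = "custom") {
  stopifnot(is.data.frame(categories),
            all(c("category", "klass", "members") %in% names(categories)))
  categories$klass <- match.arg2(categories$klass, c("physical", "mental"))
  if (anyDuplicated(categories$category))
    stop("duplicated category names in catalog", call. = FALSE)

  # Expand every token to its covered cells at the two match resolutions.
  exact_rows <- list(); prefix_rows <- list()
  for (r in seq_len(nrow(categories))) {
    members <- categories$members[[r]]
    toks <- if (is.na(members) || !nzchar(trimws(members))) character(0)
            else strsplit(members, ";", fixed = TRUE)[[1]]
    for (tok in toks) {
      p <- parse_member_token(tok, categories$category[[r]])
      row <- data.frame(code = p$codes,
                        category = categories$category[[r]],
                        klass = categories$klass[[r]],
                        stringsAsFactors = FALSE)
      if (p$kind == "exact") exact_rows[[length(exact_rows) + 1L]] <- row
      else prefix_rows[[length(prefix_rows) + 1L]] <- row
    }
  }
  exact <- if (length(exact_rows)) do.call(rbind, exact_rows) else
    data.frame(code = character(0), category = character(0), klass = character(0))
  prefix <- if (length(prefix_rows)) do.call(rbind, prefix_rows) else
    data.frame(code = character(0), category = character(0), klass = character(0))

  # F-chapter discipline.
  is_f <- function(codes) substr(codes, 1L, 1L) == "F"
  for (tab in list(exact, prefix)) {
    if (nrow(tab) == 0L) next
    bad_m <- tab$klass == "mental" & !is_f(tab$code)
    bad_p <- tab$klass == "physical" & is_f(tab$code)
    if (any(bad_m)) stop("mental category members must start with F: ",
                         paste(unique(tab$code[bad_m]), collapse = ", "),
                         call. = FALSE)
    if (any(bad_p)) stop("physical category members must not start with F: ",
                         paste(unique(tab$code[bad_p]), collapse = ", "),
                         call. = FALSE)
  }

  # Uniqueness within a klass: a cell claimed by two categories is a
  # collision. Check at matched resolution (exact vs exact, prefix vs
  # prefix, and exact falling inside a foreign prefix).
  collisions <- character(0)
  for (kl in c("physical", "mental")) {
    e <- exact[exact$klass == kl, , drop = FALSE]
    p <- prefix[prefix$klass == kl, , drop = FALSE]
    dup_e <- e[duplicated(e$code) | duplicated(e$code, fromLast = TRUE), ]
    dup_p <- p[duplicated(p$code) | duplicated(p$code, fromLast = TRUE), ]
    if (nrow(dup_e)) collisions <- c(collisions, unique(dup_e$code))
    if (nrow(dup_p)) collisions <- c(collisions, unique(dup_p$code))
    if (nrow(e) && nrow(p)) {
      stem <- substr(e$code, 1L, 3L)
      hit <- match(stem, p$code)
      cross <- !is.na(hit) & p$category[hit] != e$category
      if (any(cross)) collisions <- c(collisions, unique(e$code[cross]))
    }
  }
  collisions <- unique(collisions)
  if (length(collisions))
    stop("catalog member collisions (code claimed by two categories of the ",
         "same class): ", paste(collisions, collapse = ", "), call. = FALSE)

  structure(list(categories = categories,
                 exact = exact,
                 prefix = prefix,
                 version = version),
            class = "disease_catalog")
}

match.arg2 <- function(x, choices) {
  x <- tolower(trimws(x))
  if (!all(x %in% choices))
    stop("klass must be one of: ", paste(choices, collapse = ", "),
         call. = FALSE)
  x
}

#' @export
print.disease_catalog <- function(x, ...) {
  cat("<disease_catalog> version:", x$version, "\n")
  cat("  categories:", nrow(x$categories),
      sprintf("(%d physical, %d mental)\n",
              sum(x$categories$klass == "physical"),
              sum(x$categories$klass == "mental")))
  invisible(x)
}

#' Map normalized ICD-10 codes to disease categories
#'
#' Resolution order: an exact 4-character member wins over a 3-character
#' prefix member, which wins over membership derived from a range. Codes
#' matching no catalog entry return `NA` — an unmatched diagnosis is a
#' valid outcome (the record is kept, the code simply carries no category).
#'
#' @param code Character vector of normalized codes (see [normalize_code()]).
#' @param catalog A `disease_catalog`.
#' @param what `"category"` (default) or `"klass"`.
#' @return Character vector: category name (or klass) per code, `NA` when
#'   unmatched.
#' @examples
#' cat10 <- default_catalog()
#' categorize(c("F05.1", "N40", "Z99.9"), cat10)
#' @export
categorize <- function(code, catalog, what = c("category", "klass")) {
  stopifnot(inherits(catalog, "disease_catalog"))
  what <- match.arg(what)
  col <- what
  out <- rep(NA_character_, length(code))
  if (length(code) == 0L) return(out)
  stem <- substr(code, 1L, 3L)
  hit <- match(code, catalog$exact$code)
  out[!is.na(hit)] <- catalog$exact[[col]][hit[!is.na(hit)]]
  need <- is.na(out)
  hit <- match(stem[need], catalog$prefix$code)
  out[need][!is.na(hit)] <- catalog$prefix[[col]][hit[!is.na(hit)]]
  out
}

#' Load a disease catalog from a CSV file
#'
#' The file has columns `category`, `klass` (`physical`/`mental`), and
#' `members` (semicolon-separated code tokens; see [disease_catalog()] for
#' token syntax). With `path = NULL` the catalog bundled with the package is
#' loaded: all 11 mental-disorder groups plus the chronic physical illness
#' categories, with code memberships for the physical categories attested
#' by the risk-disease rankings (the remaining physical categories are
#' present by name so users can supply fuller code maps).
#'
#' @param path Path to a catalog CSV, or `NULL` for the bundled default.
#' @return A `disease_catalog`.
#' @export
load_catalog <- function(path = NULL) {
  version <- if (is.null(path)) "default" else basename(path)
  if (is.null(path))
    path <- system.file("extdata", "default_catalog.csv", package = "comorisk",
                        mustWork = TRUE)
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0))
  disease_catalog(df, version = version)
}

#' @rdname load_catalog
#' @export
default_catalog <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- load_catalog(NULL)
    memo
  }
})

#' List catalog categories of one class
#'
#' @param catalog A `disease_catalog`.
#' @param klass `"physical"` or `"mental"`.
#' @param with_members If `TRUE`, keep only categories that define at least
#'   one member code (those usable for matching and simulation).
#' @return Character vector of category names.
#' @export
catalog_categories <- function(catalog, klass = c("physical", "mental"),
                               with_members = FALSE) {
  klass <- match.arg(klass)
  cc <- catalog$categories
  keep <- cc$klass == klass
  if (with_members)
    keep <- keep & cc$category %in% c(catalog$exact$category,
                                      catalog$prefix$category)
  cc$category[keep]
}

# One deterministic representative code per category, used by the cohort
# generator: the lowest exact member, else the lowest prefix member.
representative_codes <- function(catalog, categories) {
  vapply(categories, function(cat) {
    e <- sort(catalog$exact$code[catalog$exact$category == cat])
    if (length(e)) return(e[[1L]])
    p <- sort(catalog$prefix$code[catalog$prefix$category == cat])
    if (length(p)) return(p[[1L]])
    stop("catalog provides no member code for category '", cat, "'",
         call. = FALSE)
  }, character(1))
}
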