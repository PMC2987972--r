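#' Normalize an ICD-9 code to its canonical dotless form
#'
#' Claims tables and code lists write ICD-9 codes with or without the decimal
#' point ("714.0" vs "7140"). The canonical form used throughout this package
#' is dotless, upper-case, whitespace-stripped: 3-5 characters, a leading
#' digit, "V" or "E", digits thereafter.
#'
#' @param raw character vector of raw code strings.
#' @return character vector of normalized codes.
#' @examples
#' normalize_icd9(c("714.0", "7140", " v58.69 "))
#' @export
normalize_icd9 <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (!is.character(raw)) raw <- as.character(raw)
  if (anyNA(raw) || any(!nzchar(trimws(raw)))) {
    stop("normalize_icd9: empty or missing code", call. = FALSE)
  }
  code <- toupper(gsub("[[:space:]]", "", raw))
  code <- sub(".", "", code, fixed = TRUE)
  bad <- !grepl("^[0-9VE][0-9]{2,4}$", code)
  if (any(bad)) {
    stop(sprintf(
      "normalize_icd9: malformed ICD-9 code(s): %s",
      paste(sQuote(unique(raw[bad])), collapse = ", ")
    ), call. = FALSE)
  }
  code
}

#' Match normalized ICD-9 codes against a code pattern
#'
#' Patterns are written as in cohort definitions: an exact code ("496") or a
#' prefix wildcard ("714.0*", "690.*"). The pattern is normalized (dot and
#' trailing "*" stripped) before comparison; a wildcard matches any code whose
#' normalized form starts with the pattern's prefix.
#'
#' @param code character vector of normalized codes (see [normalize_icd9()]).
#' @param pattern a single pattern string.
#' @return logical vector.
#' @examples
#' icd9_matches(c("7140", "71400", "7149"), "714.0*")
#' @export
icd9_matches <- function(code, pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  wild <- endsWith(pattern, "*")
  prefix <- sub("\\*$", "", pattern)
  prefix <- toupper(gsub("[[:space:]]", "", sub(".", "", prefix, fixed = TRUE)))
  if (nchar(prefix) < 3L || nchar(prefix) > 5L) {
    stop(sprintf("icd9_matches: pattern prefix %s must be 3-5 characters",
                 sQuote(prefix)), call. = FALSE)
  }
  if (wild) startsWith(code, prefix) else code == prefix
}

#' @rdname icd9_matches
#' @param patterns character vector of patterns; `icd9_matches_any()` returns
#'   TRUE where a code matches at least one of them.
#' @export
icd9_matches_any <- function(code, patterns) {
  out <- rep(FALSE, length(code))
  for (p in patterns) out <- out | icd9_matches(code, p)
  out
}

#' Is a code in the excluded (target-disease-related) ICD-9 ranges?
#'
#' The screen drops codes that are plausibly part of the case-defining disease
#' itself: arthropathies and related disorders (710-719), dorsopathies
#' (720-724), rheumatism excluding the back (725-729), and mechanical
#' complication of internal orthopedic device/implant/graft (996.4).
#' The decision depends only on the 3-digit stem, except for the 996.4 rule
#' which is a 4-character prefix.
#'
#' @param code character vector of normalized codes.
#' @return logical vector.
#' @examples
#' is_excluded_code(c("7140", "7200", "9964", "6960"))
#' @export
is_excluded_code <- function(code) {
  stem <- suppressWarnings(as.integer(substr(code, 1L, 3L)))
  in_range <- !is.na(stem) & stem >= 710L & stem <= 729L
  in_range | startsWith(code, "9964")
}
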