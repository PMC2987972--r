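## Readers and writers for the three claims-shaped input tables.
## Schema (comma-delimited, UTF-8, header mandatory):
##   persons.csv:    person_id, birth_year, sex (F/M), plan (medicare/commercial)
##   claims.csv:     person_id, service_date (ISO-8601), icd9, claim_kind
##   enrollment.csv: person_id, start, end (ISO-8601)

CLAIM_KINDS <- c("encounter", "lab", "radiology", "pharmacy")

read_table_checked <- function(path, what, required) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", what, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df
}

parse_date_col <- function(x, what, col) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) | format(d, "%Y-%m-%d") != x)
  if (length(bad)) {
    stop(sprintf("%s: unparseable %s at row %d (got %s)", what, col, bad[1L],
                 sQuote(x[bad[1L]])), call. = FALSE)
  }
  d
}

#' Read a persons table
#'
#' @param path path to a CSV with columns person_id, birth_year, sex, plan.
#' @return data.frame with typed columns; person_id guaranteed unique,
#'   sex in {F, M}, plan in {medicare, commercial}.
#' @export
read_persons <- function(path) {
  df <- read_table_checked(path, "persons", c("person_id", "birth_year", "sex", "plan"))
  if (nrow(df) == 0L) return(empty_persons())
  dup <- which(duplicated(df$person_id))
  if (length(dup)) {
    stop(sprintf("persons: duplicate person_id %s at row %d",
                 sQuote(df$person_id[dup[1L]]), dup[1L]), call. = FALSE)
  }
  by <- suppressWarnings(as.integer(df$birth_year))
  if (anyNA(by)) {
    stop(sprintf("persons: unparseable birth_year at row %d",
                 which(is.na(by))[1L]), call. = FALSE)
  }
  bad_sex <- which(!df$sex %in% c("F", "M"))
  if (length(bad_sex)) {
    stop(sprintf("persons: sex must be 'F' or 'M' at row %d (got %s)",
                 bad_sex[1L], sQuote(df$sex[bad_sex[1L]])), call. = FALSE)
  }
  bad_plan <- which(!df$plan %in% c("medicare", "commercial"))
  if (length(bad_plan)) {
    stop(sprintf("persons: plan must be 'medicare' or 'commercial' at row %d (got %s)",
                 bad_plan[1L], sQuote(df$plan[bad_plan[1L]])), call. = FALSE)
  }
  data.frame(person_id = df$person_id, birth_year = by, sex = df$sex,
             plan = df$plan, stringsAsFactors = FALSE)
}

#' Read a claims table
#'
#' ICD-9 codes are normalized on read (see [normalize_icd9()]).
#'
#' @param path path to a CSV with columns person_id, service_date, icd9,
#'   claim_kind.
#' @return data.frame of claim records.
#' @export
read_claims <- function(path) {
  df <- read_table_checked(path, "claims", c("person_id", "service_date", "icd9", "claim_kind"))
  if (nrow(df) == 0L) return(empty_claims())
  bad_kind <- which(!df$claim_kind %in% CLAIM_KINDS)
  if (length(bad_kind)) {
    stop(sprintf("claims: claim_kind must be one of %s at row %d (got %s)",
                 paste(CLAIM_KINDS, collapse = "/"), bad_kind[1L],
                 sQuote(df$claim_kind[bad_kind[1L]])), call. = FALSE)
  }
  data.frame(
    person_id = df$person_id,
    service_date = parse_date_col(df$service_date, "claims", "service_date"),
    icd9 = normalize_icd9(df$icd9),
    claim_kind = df$claim_kind,
    stringsAsFactors = FALSE
  )
}

#' Read an enrollment-spell table
#'
#' Spells must satisfy start <= end and may not overlap within a person.
#'
#' @param path path to a CSV with columns person_id, start, end.
#' @return data.frame of enrollment spells.
#' @export
read_enrollment <- function(path) {
  df <- read_table_checked(path, "enrollment", c("person_id", "start", "end"))
  if (nrow(df) == 0L) return(empty_enrollment())
  out <- data.frame(
    person_id = df$person_id,
    start = parse_date_col(df$start, "enrollment", "start"),
    end = parse_date_col(df$end, "enrollment", "end"),
    stringsAsFactors = FALSE
  )
  bad <- which(out$start > out$end)
  if (length(bad)) {
    stop(sprintf("enrollment: start > end at row %d", bad[1L]), call. = FALSE)
  }
  # overlap check within person
  o <- order(out$person_id, out$start)
  s <- out[o, ]
  same <- s$person_id[-1L] == s$person_id[-nrow(s)]
  overlap <- which(same & s$start[-1L] <= s$end[-nrow(s)])
  if (length(overlap)) {
    stop(sprintf("enrollment: overlapping spells for person %s",
                 sQuote(s$person_id[overlap[1L] + 1L])), call. = FALSE)
  }
  out
}

empty_persons <- function() {
  data.frame(person_id = character(0), birth_year = integer(0),
             sex = character(0), plan = character(0), stringsAsFactors = FALSE)
}
empty_claims <- function() {
  data.frame(person_id = character(0), service_date = as.Date(character(0)),
             icd9 = character(0), claim_kind = character(0), stringsAsFactors = FALSE)
}
empty_enrollment <- function() {
  data.frame(person_id = character(0), start = as.Date(character(0)),
             end = as.Date(character(0)), stringsAsFactors = FALSE)
}

#' Write the three claims-shaped tables
#'
#' Inverse of the readers: `read_*(write_*(x))` parses to equal records.
#'
#' @param x typed data.frame as returned by the corresponding reader.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_persons <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_persons
#' @export
write_claims <- function(x, path) {
  x$service_date <- format(x$service_date, "%Y-%m-%d")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_persons
#' @export
write_enrollment <- function(x, path) {
  x$start <- format(x$start, "%Y-%m-%d")
  x$end <- format(x$end, "%Y-%m-%d")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
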