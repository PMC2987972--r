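#' Cohort eligibility specification
#'
#' Encodes the cohort-defining rules: at least `min_claims` claims of eligible
#' kinds matching the condition patterns, an enrollment spell covering
#' `active_on`, at least one matching claim strictly before `pre_cutoff`, and
#' age at the index date of at least `min_age`. The index date is the earliest
#' matching eligible claim.
#'
#' @param patterns character vector of ICD-9 patterns (e.g. "714.0*").
#' @param min_claims minimum matching claims (default 2).
#' @param eligible_claim_kinds claim kinds that may define the cohort;
#'   default "encounter" (lab/radiology claims are non-diagnostic).
#' @param active_on enrollment reference date (default 2007-06-30).
#' @param pre_cutoff first matching claim must be strictly before this date
#'   (default 2006-07-01).
#' @param min_age minimum age in years at index (default 16).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(patterns, min_claims = 2L,
                        eligible_claim_kinds = "encounter",
                        active_on = as.Date("2007-06-30"),
                        pre_cutoff = as.Date("2006-07-01"),
                        min_age = 16L) {
  active_on <- as.Date(active_on); pre_cutoff <- as.Date(pre_cutoff)
  stopifnot(length(patterns) >= 1L, min_claims >= 1L, pre_cutoff <= active_on)
  structure(list(patterns = patterns, min_claims = as.integer(min_claims),
                 eligible_claim_kinds = eligible_claim_kinds,
                 active_on = active_on, pre_cutoff = pre_cutoff,
                 min_age = as.integer(min_age)),
            class = "cohort_spec")
}

#' Age in completed calendar years
#'
#' Birth dates are modeled at year resolution, as claims extracts rarely carry
#' finer detail; age is the calendar-year difference, deterministic for every
#' date in the year.
#'
#' @param birth_year integer vector of birth years.
#' @param on the date (or dates) at which to compute age.
#' @return integer vector of ages.
#' @export
age_at <- function(birth_year, on) {
  on_year <- as.integer(format(as.Date(on), "%Y"))
  age <- on_year - as.integer(birth_year)
  if (any(age < 0)) {
    stop(sprintf("age_at: negative age for birth_year %d",
                 birth_year[which(age < 0)[1L]]), call. = FALSE)
  }
  age
}

#' Select a cohort arm from claims, enrollment and persons tables
#'
#' Applies the four eligibility rules of the `spec` (claim count, active
#' enrollment, pre-cutoff claim, minimum age at index) and assigns the index
#' date as the earliest matching eligible claim.
#'
#' @param claims claims data.frame (normalized, as from [read_claims()]).
#' @param enrollment enrollment-spell data.frame.
#' @param persons persons data.frame.
#' @param spec a [cohort_spec()].
#' @param arm label for the selected members ("case" or "control").
#' @return data.frame of cohort members: person_id, arm, index_date,
#'   age_at_index, sex, plan. Empty cohorts are valid results.
#' @export
select_cohort <- function(claims, enrollment, persons, spec, arm = "case") {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- claims[claims$claim_kind %in% spec$eligible_claim_kinds &
                icd9_matches_any(claims$icd9, spec$patterns), , drop = FALSE]
  if (nrow(m) == 0L) return(empty_cohort())

  n_match <- tapply(m$person_id, m$person_id, length)
  first_claim <- tapply(as.integer(m$service_date), m$person_id, min)
  earliest <- as.Date(first_claim, origin = "1970-01-01")
  ids <- names(n_match)

  ok_count <- n_match >= spec$min_claims
  ok_precut <- earliest < spec$pre_cutoff

  active_ids <- unique(enrollment$person_id[
    enrollment$start <= spec$active_on & spec$active_on <= enrollment$end])
  ok_active <- ids %in% active_ids

  pi <- match(ids, persons$person_id)
  if (anyNA(pi)) {
    stop(sprintf("select_cohort: claims reference unknown person %s",
                 sQuote(ids[which(is.na(pi))[1L]])), call. = FALSE)
  }
  age_idx <- as.integer(format(earliest, "%Y")) - persons$birth_year[pi]
  ok_age <- age_idx >= spec$min_age

  keep <- ok_count & ok_precut & ok_active & ok_age
  out <- data.frame(
    person_id = ids[keep],
    arm = arm,
    index_date = earliest[keep],
    age_at_index = age_idx[keep],
    sex = persons$sex[pi][keep],
    plan = persons$plan[pi][keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$person_id), , drop = FALSE]
}

empty_cohort <- function() {
  data.frame(person_id = character(0), arm = character(0),
             index_date = as.Date(character(0)), age_at_index = integer(0),
             sex = character(0), plan = character(0), stringsAsFactors = FALSE)
}

#' Select both arms, keeping them disjoint
#'
#' A person qualifying for both conditions is assigned to the case arm and
#' barred from the control pool, so the matched arms never share persons.
#'
#' @inheritParams select_cohort
#' @param case_spec,control_spec [cohort_spec()]s for the two conditions.
#' @return combined cohort data.frame with `arm` in {case, control}.
#' @export
select_case_control <- function(claims, enrollment, persons,
                                case_spec, control_spec) {
  cases <- select_cohort(claims, enrollment, persons, case_spec, arm = "case")
  controls <- select_cohort(claims, enrollment, persons, control_spec, arm = "control")
  controls <- controls[!controls$person_id %in% cases$person_id, , drop = FALSE]
  out <- rbind(cases, controls)
  rownames(out) <- NULL
  out
}

#' Demographic summary of a cohort
#'
#' Mean age, percent female, percent Medicare, and a 5-year age-band by sex
#' histogram (the usual cohort-description figure for claims studies).
#'
#' @param members cohort data.frame from [select_cohort()].
#' @return object of class `demographic_summary`.
#' @export
demographic_summary <- function(members) {
  if (nrow(members) == 0L) stop("demographic_summary: empty cohort", call. = FALSE)
  bins <- cut(members$age_at_index,
              breaks = seq(0, 105, by = 5), right = FALSE,
              labels = paste(seq(0, 100, 5), seq(4, 104, 5), sep = "-"))
  structure(list(
    n = nrow(members),
    mean_age = mean(members$age_at_index),
    pct_female = 100 * mean(members$sex == "F"),
    pct_medicare = 100 * mean(members$plan == "medicare"),
    age_sex_hist = table(age_band = bins, sex = members$sex)
  ), class = "demographic_summary")
}

#' @export
print.demographic_summary <- function(x, ...) {
  cat(sprintf("cohort of %d persons: mean age %.1f, %.1f%% female, %.1f%% medicare\n",
              x$n, x$mean_age, x$pct_female, x$pct_medicare))
  h <- x$age_sex_hist
  h <- h[rowSums(h) > 0, , drop = FALSE]
  print(h)
  invisible(x)
}
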