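# In-code fixture builders shared across test files.

make_persons <- function(ids, birth_year = 1950, sex = "F", plan = "commercial") {
  data.frame(person_id = ids,
             birth_year = as.integer(rep_len(birth_year, length(ids))),
             sex = rep_len(sex, length(ids)),
             plan = rep_len(plan, length(ids)),
             stringsAsFactors = FALSE)
}

make_claims <- function(person_id, service_date, icd9, claim_kind = "encounter") {
  n <- max(length(person_id), length(service_date), length(icd9))
  data.frame(person_id = rep_len(person_id, n),
             service_date = as.Date(rep_len(service_date, n)),
             icd9 = rep_len(icd9, n),
             claim_kind = rep_len(claim_kind, n),
             stringsAsFactors = FALSE)
}

make_enrollment <- function(ids, start = "2004-01-01", end = "2007-12-31") {
  data.frame(person_id = ids,
             start = as.Date(rep_len(start, length(ids))),
             end = as.Date(rep_len(end, length(ids))),
             stringsAsFactors = FALSE)
}

# prevalence-shaped rows for screen-stage tests
make_prev <- function(icd9, n_case, n_control, N_case = 1000L, N_control = 1000L) {
  data.frame(icd9 = icd9, n_case = n_case, N_case = N_case,
             n_control = n_control, N_control = N_control,
             p_case = n_case / N_case, p_control = n_control / N_control,
             stringsAsFactors = FALSE)
}

tiny_truth <- function(seed = 42, n = 300, ...) {
  simulation_truth(
    code_book(c("4019", "5163"), p0 = c(0.2, 0.02), rr = c(1, 3)),
    n_cases = n, n_controls = n, seed = seed, ...)
}
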