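## Synthetic administrative-claims generator with planted per-code relative
## risks, emulating the statistical structure a claims comorbidity screen
## assumes: chronic-disease coding (>=2 claims) for a case condition and a
## control condition, enrollment spells covering the reference date, and
## person-level Bernoulli comorbidity events.

DEFAULT_CASE_PATTERNS <- c("714.0*", "714.1*", "714.2*", "714.3*")
DEFAULT_CONTROL_PATTERNS <- c("690.*", "691.*", "692.*")

# concrete codes emitted for the defining conditions (all match the patterns)
CASE_CODES <- c("7140", "71400", "7141", "7142", "7143")
CONTROL_CODES <- c("6908", "6918", "6920", "6929", "69210")

TRUTH_SCHEMA_VERSION <- 1L

#' Build a comorbidity code book with planted effects
#'
#' Each entry is one screenable ICD-9 code occurring as a per-person Bernoulli
#' event: baseline one-year probability `p0` in controls, `p1 = min(rr * p0, 1)`
#' in cases, optionally confounded by age through `confounder_slope`
#' (additive log-odds per decade of age, centred at the population mean age).
#'
#' @param icd9 character vector of codes (normalized on input).
#' @param p0 baseline control-arm probabilities, each in (0, 1).
#' @param rr planted relative risks, each >= 0.
#' @param description optional code descriptions.
#' @param confounder_slope log-odds change per decade of age (default 0).
#' @return data.frame of class `code_book`.
#' @export
code_book <- function(icd9, p0, rr, description = NULL, confounder_slope = 0) {
  icd9 <- normalize_icd9(icd9)
  if (length(icd9) == 0L) stop("code_book: empty code book", call. = FALSE)
  if (anyDuplicated(icd9)) stop("code_book: duplicate codes", call. = FALSE)
  stopifnot(all(p0 > 0 & p0 < 1), all(rr >= 0))
  if (is.null(description)) description <- paste("synthetic condition", icd9)
  cb <- data.frame(
    icd9 = icd9,
    description = as.character(description),
    p0 = as.numeric(p0),
    rr = as.numeric(rr),
    confounder_slope = as.numeric(rep_len(confounder_slope, length(icd9))),
    stringsAsFactors = FALSE
  )
  class(cb) <- c("code_book", "data.frame")
  cb
}

#' Ground-truth specification for a simulated claims database
#'
#' Bundles the code book, arm sizes, demographic spec and seed that fully
#' determine one synthetic database. Serializable via
#' [write_truth_manifest()] / [read_truth_manifest()].
#'
#' @param codebook a [code_book()].
#' @param n_cases,n_controls arm sizes (designated at generation time).
#' @param seed integer RNG seed.
#' @param mean_age,sd_age age distribution: truncated normal on [16, 100]
#'   (defaults 59.0 and 15 years, matching a chronic-disease claims cohort).
#' @param female_frac,medicare_frac Bernoulli fractions (defaults 0.738, 0.35).
#' @param case_age_shift additive shift (years) of the case arm's mean age;
#'   non-zero values create age confounding to exercise the matcher.
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(codebook, n_cases, n_controls, seed,
                             mean_age = 59, sd_age = 15,
                             female_frac = 0.738, medicare_frac = 0.35,
                             case_age_shift = 0) {
  stopifnot(inherits(codebook, "code_book"),
            n_cases >= 1, n_controls >= 1, is.numeric(seed))
  if (female_frac < 0 || female_frac > 1 || medicare_frac < 0 || medicare_frac > 1) {
    stop("simulation_truth: fractions must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    codebook = codebook,
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    seed = as.integer(seed),
    mean_age = mean_age, sd_age = sd_age,
    female_frac = female_frac, medicare_frac = medicare_frac,
    case_age_shift = case_age_shift
  ), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation_truth: %d cases / %d controls, %d codes, seed %d\n",
              x$n_cases, x$n_controls, nrow(x$codebook), x$seed))
  cat(sprintf("  demographics: mean age %.1f (sd %.1f, case shift %+.1f), %.1f%% female, %.1f%% medicare\n",
              x$mean_age, x$sd_age, x$case_age_shift,
              100 * x$female_frac, 100 * x$medicare_frac))
  invisible(x)
}

rtruncnorm_ages <- function(n, mean, sd, lo = 16, hi = 100) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic person table
#'
#' Ages are drawn from a normal truncated to [16, 100]; sex and plan are
#' Bernoulli at the specified fractions. Birth years are set so that calendar
#' age at `ref_year` equals the drawn (floored) age. Deterministic given `seed`.
#'
#' @param n number of persons.
#' @param seed integer seed.
#' @param mean_age,sd_age,female_frac,medicare_frac demographic spec.
#' @param ref_year calendar year anchoring ages (default 2007).
#' @param id_prefix prefix for generated person_ids.
#' @return persons data.frame (schema of [read_persons()]).
#' @export
generate_population <- function(n, seed, mean_age = 59, sd_age = 15,
                                female_frac = 0.738, medicare_frac = 0.35,
                                ref_year = 2007, id_prefix = "P") {
  stopifnot(n >= 1)
  if (female_frac < 0 || female_frac > 1 || medicare_frac < 0 || medicare_frac > 1) {
    stop("generate_population: fractions must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  age <- floor(rtruncnorm_ages(n, mean_age, sd_age))
  data.frame(
    person_id = sprintf("%s%07d", id_prefix, seq_len(n)),
    birth_year = as.integer(ref_year - age),
    sex = ifelse(stats::runif(n) < female_frac, "F", "M"),
    plan = ifelse(stats::runif(n) < medicare_frac, "medicare", "commercial"),
    stringsAsFactors = FALSE
  )
}

# dates drawn uniformly (by day) in [from, to]
runif_dates <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

#' Generate claims and enrollment spells for designated cases and controls
#'
#' Every person receives the chronic-disease coding pattern of their arm:
#' >= 2 encounter claims drawn from concrete codes matching the arm's
#' condition patterns, the earliest strictly before `pre_cutoff` (it becomes
#' the index date), the rest up to `window_end`. Each code-book comorbidity is
#' then emitted at most once per person as a Bernoulli event with
#' arm-specific probability (`p0` or `min(rr * p0, 1)`, shifted on the
#' log-odds scale by `confounder_slope` per decade of age), dated uniformly
#' inside the one-year window. One enrollment spell per person covers the
#' reference date.
#'
#' @param persons persons data.frame.
#' @param arm character vector ("case"/"control") aligned with `persons`.
#' @param truth a [simulation_truth()] (its code book and demographics drive
#'   the event probabilities).
#' @param seed integer seed.
#' @param window_start,window_end the one-year comorbidity window.
#' @param pre_cutoff date the first defining claim must precede.
#' @param ref_year calendar year used to compute ages.
#' @return list with `claims` and `enrollment` data.frames.
#' @export
generate_cohort_claims <- function(persons, arm, truth, seed,
                                   window_start = as.Date("2006-07-01"),
                                   window_end = as.Date("2007-06-30"),
                                   pre_cutoff = as.Date("2006-07-01"),
                                   ref_year = 2007) {
  stopifnot(nrow(persons) == length(arm), all(arm %in% c("case", "control")))
  cb <- truth$codebook
  if (is.null(cb) || nrow(cb) == 0L) stop("generate_cohort_claims: empty code book", call. = FALSE)
  set.seed(seed)
  n <- nrow(persons)
  is_case <- arm == "case"
  age <- ref_year - persons$birth_year

  # defining-condition claims: 2 per person, first strictly before pre_cutoff
  first_date <- runif_dates(n, pre_cutoff - 365L, pre_cutoff - 1L)
  second_date <- runif_dates(n, window_start, window_end)
  def_code <- ifelse(is_case,
                     sample(CASE_CODES, n, replace = TRUE),
                     sample(CONTROL_CODES, n, replace = TRUE))
  def_code2 <- ifelse(is_case,
                      sample(CASE_CODES, n, replace = TRUE),
                      sample(CONTROL_CODES, n, replace = TRUE))
  claims <- list(data.frame(
    person_id = rep(persons$person_id, 2L),
    service_date = c(first_date, second_date),
    icd9 = c(def_code, def_code2),
    claim_kind = "encounter",
    stringsAsFactors = FALSE
  ))

  # person-level Bernoulli comorbidity events, one claim max per person-code
  for (k in seq_len(nrow(cb))) {
    p_arm <- ifelse(is_case, min(cb$rr[k] * cb$p0[k], 1), cb$p0[k])
    slope <- cb$confounder_slope[k]
    p <- if (slope != 0) {
      ifelse(p_arm >= 1, 1,
             stats::plogis(stats::qlogis(p_arm) + slope * (age - truth$mean_age) / 10))
    } else p_arm
    hit <- stats::runif(n) < p
    if (any(hit)) {
      claims[[length(claims) + 1L]] <- data.frame(
        person_id = persons$person_id[hit],
        service_date = runif_dates(sum(hit), window_start, window_end),
        icd9 = cb$icd9[k],
        claim_kind = "encounter",
        stringsAsFactors = FALSE
      )
    }
  }
  claims <- do.call(rbind, claims)

  enrollment <- data.frame(
    person_id = persons$person_id,
    start = as.Date(sprintf("%d-01-01", ref_year - 3L)),
    end = as.Date(sprintf("%d-12-31", ref_year)),
    stringsAsFactors = FALSE
  )
  list(claims = claims, enrollment = enrollment)
}

#' Generate a full synthetic claims database from a truth specification
#'
#' Convenience wrapper: draws the case and control populations (applying any
#' `case_age_shift`), generates claims and enrollment, and returns everything
#' with the designated arm assignment for recovery testing.
#'
#' @param truth a [simulation_truth()].
#' @param seed optional seed overriding `truth$seed`.
#' @return list with `persons`, `claims`, `enrollment`, `arms` (person_id,
#'   arm) and `truth`.
#' @export
simulate_claims_db <- function(truth, seed = truth$seed) {
  cases <- generate_population(
    truth$n_cases, seed = seed,
    mean_age = truth$mean_age + truth$case_age_shift, sd_age = truth$sd_age,
    female_frac = truth$female_frac, medicare_frac = truth$medicare_frac,
    id_prefix = "A")
  controls <- generate_population(
    truth$n_controls, seed = seed + 1L,
    mean_age = truth$mean_age, sd_age = truth$sd_age,
    female_frac = truth$female_frac, medicare_frac = truth$medicare_frac,
    id_prefix = "B")
  persons <- rbind(cases, controls)
  arm <- rep(c("case", "control"), c(truth$n_cases, truth$n_controls))
  gen <- generate_cohort_claims(persons, arm, truth, seed = seed + 2L)
  list(persons = persons, claims = gen$claims, enrollment = gen$enrollment,
       arms = data.frame(person_id = persons$person_id, arm = arm,
                         stringsAsFactors = FALSE),
       truth = truth)
}

#' Write / read the ground-truth manifest
#'
#' YAML manifest with a schema version; the round-trip is lossless, so a
#' reloaded truth regenerates the identical database.
#'
#' @param truth a [simulation_truth()].
#' @param path manifest file path.
#' @return `path` invisibly; `read_truth_manifest()` returns the truth object.
#' @export
write_truth_manifest <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  yaml::write_yaml(list(
    schema_version = TRUTH_SCHEMA_VERSION,
    seed = truth$seed,
    n_cases = truth$n_cases,
    n_controls = truth$n_controls,
    demographics = list(mean_age = truth$mean_age, sd_age = truth$sd_age,
                        female_frac = truth$female_frac,
                        medicare_frac = truth$medicare_frac,
                        case_age_shift = truth$case_age_shift),
    codebook = lapply(seq_len(nrow(truth$codebook)), function(i) {
      as.list(truth$codebook[i, , drop = FALSE])
    })
  ), path)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$schema_version) || m$schema_version != TRUTH_SCHEMA_VERSION) {
    stop(sprintf("truth manifest: schema version mismatch (expected %d, got %s)",
                 TRUTH_SCHEMA_VERSION,
                 if (is.null(m$schema_version)) "none" else m$schema_version),
         call. = FALSE)
  }
  if (is.null(m$seed)) stop("truth manifest: missing seed field", call. = FALSE)
  cb <- do.call(rbind, lapply(m$codebook, function(e) {
    data.frame(icd9 = e$icd9, description = e$description, p0 = e$p0,
               rr = e$rr, confounder_slope = e$confounder_slope,
               stringsAsFactors = FALSE)
  }))
  d <- m$demographics
  simulation_truth(
    code_book(cb$icd9, cb$p0, cb$rr, cb$description, cb$confounder_slope),
    n_cases = m$n_cases, n_controls = m$n_controls, seed = m$seed,
    mean_age = d$mean_age, sd_age = d$sd_age,
    female_frac = d$female_frac, medicare_frac = d$medicare_frac,
    case_age_shift = d$case_age_shift
  )
}
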