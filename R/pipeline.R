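## End-to-end pipeline driven by a YAML run configuration, with structured
## stage logging and a run manifest. Every output is a pure function of
## config + seed: a single global seed fans out to per-stage seeds by a fixed
## derivation so stages are individually reproducible.

derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, match = 23L, screen = 37L)
  (as.integer(seed) + 1000003L * offsets[[stage]]) %% .Machine$integer.max
}

log_stage <- function(con, stage, event, ...) {
  extra <- c(...)
  line <- paste(c(sprintf("stage=%s event=%s", stage, event),
                  sprintf("%s=%s", names(extra), extra)), collapse = " ")
  if (!is.null(con)) writeLines(line, con)
  message(line)
}

#' Read a pipeline run configuration
#'
#' YAML with blocks: `inputs` (persons/claims/enrollment paths) or `simulate`
#' (n_cases, n_controls, codebook entries, demographics), `cohort`
#' (case_patterns, control_patterns, min_claims, active_on, pre_cutoff,
#' min_age), `matching` (max_digits), `screen` (window_start, window_end,
#' min_control_count, top_k, alpha), `seed`, `outdir`.
#'
#' @param path YAML file path.
#' @return named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run config: missing seed", call. = FALSE)
  if (is.null(cfg$inputs) && is.null(cfg$simulate)) {
    stop("run config: need either an inputs or a simulate block", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

config_truth <- function(cfg) {
  s <- cfg$simulate
  cb <- do.call(rbind, lapply(s$codebook, function(e) {
    data.frame(icd9 = e$icd9, p0 = e$p0, rr = e$rr,
               description = if (is.null(e$description)) NA_character_ else e$description,
               confounder_slope = if (is.null(e$confounder_slope)) 0 else e$confounder_slope,
               stringsAsFactors = FALSE)
  }))
  desc <- if (all(is.na(cb$description))) NULL else cb$description
  args <- list(code_book(cb$icd9, cb$p0, cb$rr, desc, cb$confounder_slope),
               n_cases = s$n_cases, n_controls = s$n_controls,
               seed = derive_seed(cfg$seed, "simulate"))
  for (f in c("mean_age", "sd_age", "female_frac", "medicare_frac", "case_age_shift")) {
    if (!is.null(s[[f]])) args[[f]] <- s[[f]]
  }
  do.call(simulation_truth, args)
}

config_cohort_specs <- function(cfg) {
  co <- if (is.null(cfg$cohort)) list() else cfg$cohort
  mk <- function(patterns) {
    args <- list(patterns = patterns)
    for (f in c("min_claims", "active_on", "pre_cutoff", "min_age")) {
      if (!is.null(co[[f]])) args[[f]] <- co[[f]]
    }
    do.call(cohort_spec, args)
  }
  list(case = mk(if (is.null(co$case_patterns)) DEFAULT_CASE_PATTERNS else co$case_patterns),
       control = mk(if (is.null(co$control_patterns)) DEFAULT_CONTROL_PATTERNS else co$control_patterns))
}

config_screen <- function(cfg) {
  s <- if (is.null(cfg$screen)) list() else cfg$screen
  args <- list()
  for (f in c("window_start", "window_end", "min_control_count", "top_k", "alpha")) {
    if (!is.null(s[[f]])) args[[f]] <- s[[f]]
  }
  do.call(screen_config, args)
}

#' Simulate a claims database to disk
#'
#' Writes persons.csv, claims.csv, enrollment.csv and truth.yaml under
#' `outdir`. Deterministic: the same config and seed give byte-identical
#' outputs.
#'
#' @param cfg a `run_config` (from [read_run_config()]) with a `simulate`
#'   block, or a path to one.
#' @param outdir output directory (default from the config).
#' @return invisible named vector of written paths.
#' @export
run_simulate <- function(cfg, outdir = cfg$outdir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(cfg$simulate)) stop("run_simulate: config has no simulate block", call. = FALSE)
  if (is.null(outdir)) stop("run_simulate: no output directory", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- config_truth(cfg)
  db <- simulate_claims_db(truth)
  paths <- c(persons = file.path(outdir, "persons.csv"),
             claims = file.path(outdir, "claims.csv"),
             enrollment = file.path(outdir, "enrollment.csv"),
             truth = file.path(outdir, "truth.yaml"))
  write_persons(db$persons, paths[["persons"]])
  write_claims(db$claims, paths[["claims"]])
  write_enrollment(db$enrollment, paths[["enrollment"]])
  write_truth_manifest(truth, paths[["truth"]])
  message(sprintf("stage=simulate event=done persons=%d claims=%d",
                  nrow(db$persons), nrow(db$claims)))
  invisible(paths)
}

#' Run the screening pipeline from a config
#'
#' Reads (or simulates) the three tables, runs [comorbidity_screen()], and
#' writes the stage artifacts under `outdir`: cohort.csv, match.csv,
#' ranked.csv (full ranked output), top_k.txt, balance.csv, demographics.txt
#' and run.log (the cohort funnel, structured and timestamp-free).
#'
#' @param cfg a `run_config` or a path to one.
#' @param outdir output directory (default from the config).
#' @return the `comorbidity_screen` object, invisibly.
#' @export
run_screen <- function(cfg, outdir = cfg$outdir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(outdir)) stop("run_screen: no output directory", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(outdir, "run.log"), "w")
  on.exit(close(logf))

  if (!is.null(cfg$inputs)) {
    persons <- read_persons(cfg$inputs$persons)
    claims <- read_claims(cfg$inputs$claims)
    enrollment <- read_enrollment(cfg$inputs$enrollment)
  } else {
    db <- simulate_claims_db(config_truth(cfg))
    persons <- db$persons; claims <- db$claims; enrollment <- db$enrollment
  }
  log_stage(logf, "load", "done", persons = nrow(persons), claims = nrow(claims))

  specs <- config_cohort_specs(cfg)
  scfg <- config_screen(cfg)
  scr <- comorbidity_screen(claims, enrollment, persons,
                            case_spec = specs$case, control_spec = specs$control,
                            config = scfg, seed = derive_seed(cfg$seed, "match"))
  f <- scr$funnel
  log_stage(logf, "cohort", "selected", cases = f[["cases_selected"]],
            controls = f[["controls_selected"]])
  log_stage(logf, "match", "done", pairs = f[["pairs_matched"]],
            unmatched = length(scr$match$unmatched_cases))
  log_stage(logf, "screen", "done", codes_screened = f[["codes_screened"]],
            excluded_range = scr$drops[["excluded_range"]],
            rare_in_controls = scr$drops[["rare_in_controls"]],
            codes_ranked = f[["codes_ranked"]])
  if (f[["codes_ranked"]] == 0L) log_stage(logf, "screen", "empty_ranked_output")

  utils::write.csv(scr$cohort, file.path(outdir, "cohort.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(scr$match$pairs, file.path(outdir, "match.csv"), row.names = FALSE, quote = FALSE)
  write_ranked_csv(scr$results, file.path(outdir, "ranked.csv"))
  utils::write.csv(scr$balance, file.path(outdir, "balance.csv"), row.names = FALSE, quote = FALSE)
  writeLines(utils::capture.output(print(top_k_report(scr$results, scfg$top_k),
                                         row.names = FALSE)),
             file.path(outdir, "top_k.txt"))
  writeLines(utils::capture.output(print(demographic_summary(
    scr$matched_cohort[scr$matched_cohort$arm == "case", , drop = FALSE]))),
    file.path(outdir, "demographics.txt"))
  invisible(scr)
}

RANKED_COLS <- c("icd9", "description", "n_case", "pct_case", "rr", "ci_low",
                 "ci_high", "odds_ratio", "or_ci_low", "or_ci_high",
                 "n_control", "rank")

write_ranked_csv <- function(results, path) {
  out <- data.frame(
    icd9 = results$icd9,
    description = if ("description" %in% names(results)) results$description
                  else rep("", nrow(results)),
    n_case = results$n_case,
    pct_case = 100 * results$p_case,
    rr = results$rr,
    ci_low = results$ci_low, ci_high = results$ci_high,
    odds_ratio = results$odds_ratio,
    or_ci_low = results$or_ci_low, or_ci_high = results$or_ci_high,
    n_control = results$n_control,
    rank = results$rank,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Format a top-k report from a ranked CSV
#'
#' Reruns of the report never mutate upstream artifacts; it only reads the
#' ranked CSV written by [run_screen()].
#'
#' @param ranked_csv path to ranked.csv.
#' @param k number of rows (default 30).
#' @return character-column data.frame (printed layout of the headline table).
#' @export
run_report <- function(ranked_csv, k = 30L) {
  df <- utils::read.csv(ranked_csv, colClasses = "character")
  missing <- setdiff(c("icd9", "n_case", "pct_case", "rr", "ci_low", "ci_high"),
                     names(df))
  if (length(missing)) {
    stop(sprintf("run_report: ranked CSV missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rows <- data.frame(
    icd9 = df$icd9,
    description = if ("description" %in% names(df)) df$description else "",
    n_case = as.integer(df$n_case),
    p_case = as.numeric(df$pct_case) / 100,
    rr = as.numeric(df$rr),
    ci_low = as.numeric(df$ci_low), ci_high = as.numeric(df$ci_high),
    stringsAsFactors = FALSE
  )
  top_k_report(rows, k)
}
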