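#' Screen configuration
#'
#' @param window_start,window_end closed one-year comorbidity window
#'   (defaults 2006-07-01 through 2007-06-30).
#' @param min_control_count stability filter: codes kept only when at least
#'   this many control-arm persons carry them (default 20).
#' @param top_k rows in the headline report (default 30).
#' @param alpha two-sided CI level complement (default 0.05).
#' @return object of class `screen_config`.
#' @export
screen_config <- function(window_start = as.Date("2006-07-01"),
                          window_end = as.Date("2007-06-30"),
                          min_control_count = 20L, top_k = 30L, alpha = 0.05) {
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  stopifnot(window_start <= window_end, min_control_count >= 0, alpha > 0, alpha < 1)
  structure(list(window_start = window_start, window_end = window_end,
                 min_control_count = as.integer(min_control_count),
                 top_k = as.integer(top_k), alpha = alpha),
            class = "screen_config")
}

#' One-year period prevalence per ICD-9 code
#'
#' Counts, for each distinct code recorded in either arm inside the closed
#' window, the number of persons with at least one claim of that code; claim
#' multiplicity is irrelevant (each person contributes at most once per code).
#' All diagnosis-bearing claim kinds count here; the non-diagnostic
#' restriction applies only to cohort-defining claims.
#'
#' @param claims normalized claims data.frame.
#' @param cohort data.frame with person_id and arm ("case"/"control").
#' @param config a [screen_config()].
#' @return data.frame: icd9, n_case, N_case, n_control, N_control, p_case,
#'   p_control.
#' @export
period_prevalence <- function(claims, cohort, config = screen_config()) {
  N_case <- sum(cohort$arm == "case")
  N_control <- sum(cohort$arm == "control")
  if (N_case == 0L || N_control == 0L) {
    stop("period_prevalence: both arms must be non-empty", call. = FALSE)
  }
  w <- claims$service_date >= config$window_start &
    claims$service_date <= config$window_end &
    claims$person_id %in% cohort$person_id
  cl <- claims[w, c("person_id", "icd9")]
  cl <- cl[!duplicated(paste(cl$person_id, cl$icd9, sep = "\r")), , drop = FALSE]
  arm <- cohort$arm[match(cl$person_id, cohort$person_id)]
  codes <- sort(unique(cl$icd9))
  fc <- factor(cl$icd9, levels = codes)
  n_case <- as.integer(table(fc[arm == "case"]))
  n_control <- as.integer(table(fc[arm == "control"]))
  data.frame(
    icd9 = codes,
    n_case = n_case, N_case = N_case,
    n_control = n_control, N_control = N_control,
    p_case = n_case / N_case, p_control = n_control / N_control,
    stringsAsFactors = FALSE
  )
}

#' Relative risk as a ratio of period prevalences
#'
#' `rr = p_case / p_control`; with equal-size matched arms this reduces
#' exactly to `n_case / n_control`. Undefined (NaN/Inf) when the control
#' count is zero — such rows are dropped by the stability filter anyway.
#'
#' @param rec prevalence data.frame (rows from [period_prevalence()]).
#' @return numeric vector of relative risks.
#' @export
relative_risk <- function(rec) rec$p_case / rec$p_control

#' Confidence interval for a prevalence ratio (Katz log method)
#'
#' `exp(log rr +/- z * sqrt(1/n_case - 1/N_case + 1/n_control - 1/N_control))`.
#' Requires both numerators positive; rows with a zero cell get NA bounds.
#'
#' @param rec prevalence data.frame.
#' @param alpha two-sided level complement (default 0.05, z = 1.959964).
#' @return data.frame with columns low, high.
#' @export
rr_confidence_interval <- function(rec, alpha = 0.05) {
  rr <- relative_risk(rec)
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(1 / rec$n_case - 1 / rec$N_case + 1 / rec$n_control - 1 / rec$N_control)
  ok <- rec$n_case > 0 & rec$n_control > 0
  low <- ifelse(ok, exp(log(rr) - z * se), NA_real_)
  high <- ifelse(ok, exp(log(rr) + z * se), NA_real_)
  data.frame(low = low, high = high)
}

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product ratio of the person-count 2x2 table, with the Woolf log CI
#' `exp(log or +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. No continuity
#' correction: rows with a zero cell are flagged with NA.
#'
#' @inheritParams rr_confidence_interval
#' @return data.frame with columns or, low, high.
#' @export
odds_ratio <- function(rec, alpha = 0.05) {
  a <- rec$n_case; b <- rec$N_case - rec$n_case
  c_ <- rec$n_control; d <- rec$N_control - rec$n_control
  or <- (a * d) / (c_ * b)
  z <- stats::qnorm(1 - alpha / 2)
  ok <- a > 0 & b > 0 & c_ > 0 & d > 0
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  data.frame(or = or,
             low = ifelse(ok, exp(log(or) - z * se), NA_real_),
             high = ifelse(ok, exp(log(or) + z * se), NA_real_))
}

#' Exclusion and stability filters
#'
#' Drops codes in the excluded (target-disease) ICD-9 ranges and codes carried
#' by fewer than `min_control_count` control-arm persons. Drop counts per
#' reason are attached as the "drops" attribute and logged.
#'
#' @param records prevalence data.frame.
#' @param config a [screen_config()].
#' @param quiet suppress the log message.
#' @return filtered data.frame.
#' @export
apply_filters <- function(records, config = screen_config(), quiet = FALSE) {
  excl <- is_excluded_code(records$icd9)
  rare <- records$n_control < config$min_control_count
  out <- records[!excl & !rare, , drop = FALSE]
  drops <- c(excluded_range = sum(excl), rare_in_controls = sum(rare & !excl))
  attr(out, "drops") <- drops
  if (!quiet) {
    message(sprintf("apply_filters: dropped %d excluded-range and %d rare codes; %d remain",
                    drops[["excluded_range"]], drops[["rare_in_controls"]], nrow(out)))
  }
  rownames(out) <- NULL
  out
}

#' Rank codes by descending relative risk
#'
#' Ties broken by larger case count, then lexicographic code. Adds rr, CI, OR
#' columns if absent, and a 1-based `rank`.
#'
#' @param records filtered prevalence data.frame.
#' @param alpha CI level complement.
#' @return data.frame of ranked screen rows.
#' @export
rank_order <- function(records, alpha = 0.05) {
  if (!"rr" %in% names(records)) records$rr <- relative_risk(records)
  if (!"ci_low" %in% names(records)) {
    ci <- rr_confidence_interval(records, alpha)
    records$ci_low <- ci$low; records$ci_high <- ci$high
    orr <- odds_ratio(records, alpha)
    records$odds_ratio <- orr$or
    records$or_ci_low <- orr$low; records$or_ci_high <- orr$high
  }
  o <- order(-records$rr, -records$n_case, records$icd9)
  out <- records[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# round half away from zero at `digits` decimals (display convention;
# base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt1 <- function(x) formatC(round_half_up(x, 1), format = "f", digits = 1)

#' Format the top-k screen report
#'
#' Headline table in the layout of a published "top relative risks" table:
#' code, description, case count (thousands-separated), percent of the case
#' arm (1 decimal), RR (1 decimal) and its CI as "low-high". Percent and RR
#' are rounded half-up for display; internal values are never rounded.
#'
#' @param rows ranked screen rows from [rank_order()].
#' @param k number of rows (default 30; fewer if fewer are available).
#' @param descriptions optional named character vector (names = codes).
#' @return character-column data.frame.
#' @export
top_k_report <- function(rows, k = 30L, descriptions = NULL) {
  k <- min(k, nrow(rows))
  if (k == 0L) {
    return(data.frame(icd9 = character(0), description = character(0),
                      n_case = character(0), pct_case = character(0),
                      rr = character(0), ci95 = character(0),
                      stringsAsFactors = FALSE))
  }
  r <- rows[seq_len(k), , drop = FALSE]
  desc <- if (!is.null(descriptions)) {
    ifelse(is.na(descriptions[r$icd9]), "", descriptions[r$icd9])
  } else if ("description" %in% names(r)) r$description else rep("", nrow(r))
  out <- data.frame(
    icd9 = r$icd9,
    description = unname(desc),
    n_case = formatC(r$n_case, format = "d", big.mark = ","),
    pct_case = paste0(fmt1(100 * r$p_case), "%"),
    rr = fmt1(r$rr),
    ci95 = paste0(fmt1(r$ci_low), "-", fmt1(r$ci_high)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Run the full matched comorbidity screen
#'
#' The package's central estimator. From the three claims-shaped tables it
#' (1) selects case and control arms by the cohort rules, (2) fits the
#' logistic propensity model on age, sex and plan, (3) pairs each case with
#' one control by greedy digit-truncation matching, (4) computes one-year
#' period prevalences per ICD-9 code over the matched arms, (5) derives
#' relative risks with 95% CIs and odds ratios, and (6) applies the exclusion
#' and stability filters and rank-orders by RR.
#'
#' @param claims,enrollment,persons input tables (schemas of the `read_*`
#'   readers).
#' @param case_spec,control_spec [cohort_spec()]s defining the two arms.
#' @param config a [screen_config()].
#' @param max_digits finest digit-agreement level for matching (default 8).
#' @param seed integer seed (drives match tie-breaking).
#' @param descriptions optional named character vector of code descriptions.
#' @return object of class `comorbidity_screen` with components `results`
#'   (ranked rows), `prevalence` (unfiltered), `cohort`, `propensity`,
#'   `match`, `balance`, `funnel` (stage counts), `config`, `seed`.
#' @examples
#' truth <- simulation_truth(
#'   code_book(c("4019", "5163"), p0 = c(0.15, 0.01), rr = c(1.2, 4)),
#'   n_cases = 300, n_controls = 300, seed = 7)
#' db <- simulate_claims_db(truth)
#' scr <- comorbidity_screen(db$claims, db$enrollment, db$persons)
#' print(scr)
#' @export
comorbidity_screen <- function(claims, enrollment, persons,
                               case_spec = cohort_spec(DEFAULT_CASE_PATTERNS),
                               control_spec = cohort_spec(DEFAULT_CONTROL_PATTERNS),
                               config = screen_config(),
                               max_digits = 8L, seed = 1L,
                               descriptions = NULL) {
  cohort <- select_case_control(claims, enrollment, persons, case_spec, control_spec)
  n_case_sel <- sum(cohort$arm == "case")
  n_ctrl_sel <- sum(cohort$arm == "control")
  if (n_case_sel == 0L || n_ctrl_sel == 0L) {
    stop("comorbidity_screen: empty case or control arm after selection", call. = FALSE)
  }
  prop <- fit_propensity(cohort)
  score <- predict(prop)
  names(score) <- cohort$person_id
  match_res <- greedy_digit_match(score[cohort$arm == "case"],
                                  score[cohort$arm == "control"],
                                  max_digits = max_digits, seed = seed)
  matched_ids <- c(match_res$pairs$case_id, match_res$pairs$control_id)
  matched <- cohort[cohort$person_id %in% matched_ids, , drop = FALSE]
  bal <- balance_report(cohort, match_res)

  prev <- period_prevalence(claims, matched, config)
  filtered <- apply_filters(prev, config, quiet = TRUE)
  results <- rank_order(filtered, alpha = config$alpha)
  if (!is.null(descriptions)) {
    results$description <- unname(ifelse(is.na(descriptions[results$icd9]),
                                         "", descriptions[results$icd9]))
  }
  structure(list(
    results = results,
    prevalence = prev,
    cohort = cohort,
    matched_cohort = matched,
    propensity = prop,
    match = match_res,
    balance = bal,
    funnel = c(cases_selected = n_case_sel,
               controls_selected = n_ctrl_sel,
               pairs_matched = nrow(match_res$pairs),
               codes_screened = nrow(prev),
               codes_ranked = nrow(results)),
    drops = attr(filtered, "drops"),
    config = config,
    seed = seed
  ), class = "comorbidity_screen")
}

#' @export
print.comorbidity_screen <- function(x, ...) {
  f <- x$funnel
  cat("matched comorbidity screen\n")
  cat(sprintf("  cohort: %d cases, %d controls selected; %d pairs matched\n",
              f[["cases_selected"]], f[["controls_selected"]], f[["pairs_matched"]]))
  cat(sprintf("  codes:  %d screened, %d ranked after filters (%d excluded-range, %d rare)\n",
              f[["codes_screened"]], f[["codes_ranked"]],
              x$drops[["excluded_range"]], x$drops[["rare_in_controls"]]))
  k <- min(5L, nrow(x$results))
  if (k > 0L) {
    cat(sprintf("  top %d by RR:\n", k))
    print(top_k_report(x$results, k), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.comorbidity_screen <- function(object, k = object$config$top_k, ...) {
  structure(list(
    demographics = demographic_summary(object$matched_cohort[
      object$matched_cohort$arm == "case", , drop = FALSE]),
    balance = object$balance,
    funnel = object$funnel,
    top = top_k_report(object$results, k)
  ), class = "summary.comorbidity_screen")
}

#' @export
print.summary.comorbidity_screen <- function(x, ...) {
  cat("matched case arm demographics:\n")
  print(x$demographics)
  cat("\ncovariate balance (standardized mean differences):\n")
  print(x$balance, row.names = FALSE)
  cat("\nstage funnel:\n")
  print(x$funnel)
  cat("\ntop-ranked comorbidities:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.comorbidity_screen <- function(x, ...) x$results

#' Forest-style plot of the top-ranked relative risks
#'
#' @param x a `comorbidity_screen`.
#' @param k number of top rows to draw (default 30).
#' @param ... passed to [graphics::plot()].
#' @export
plot.comorbidity_screen <- function(x, k = 30L, ...) {
  r <- x$results[seq_len(min(k, nrow(x$results))), , drop = FALSE]
  if (nrow(r) == 0L) stop("plot: no ranked rows", call. = FALSE)
  r <- r[rev(seq_len(nrow(r))), ]
  old <- graphics::par(mar = c(4, 7, 2, 1)); on.exit(graphics::par(old))
  graphics::plot(r$rr, seq_len(nrow(r)), log = "x", pch = 16, yaxt = "n",
                 xlab = "relative risk (log scale)", ylab = "",
                 xlim = range(c(r$ci_low, r$ci_high, 1), na.rm = TRUE),
                 main = "top comorbidity relative risks", ...)
  graphics::segments(r$ci_low, seq_len(nrow(r)), r$ci_high, seq_len(nrow(r)))
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(nrow(r)), labels = r$icd9, las = 1, cex.axis = 0.7)
  invisible(x)
}
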