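#' Fit the case-membership propensity model
#'
#' Logistic regression of case-arm membership on age (years, linear), sex and
#' plan, fit by maximum likelihood (IRLS, convergence tolerance 1e-10, at most
#' 100 iterations). The propensity score is the fitted probability of being a
#' case. Complete separation and rank deficiency are detected up front and
#' raised as errors naming the offending covariate.
#'
#' @param members cohort data.frame with columns arm, age_at_index, sex, plan.
#' @return object of class `propensity_model`.
#' @export
fit_propensity <- function(members) {
  stopifnot(all(c("arm", "age_at_index", "sex", "plan") %in% names(members)))
  y <- as.integer(members$arm == "case")
  if (length(unique(y)) < 2L) {
    stop("fit_propensity: both arms must be present", call. = FALSE)
  }
  covs <- list(age = members$age_at_index,
               sexM = as.integer(members$sex == "M"),
               planMedicare = as.integer(members$plan == "medicare"))
  const <- vapply(covs, function(v) length(unique(v)) == 1L, logical(1))
  if (all(const)) {
    # intercept-only model: score is the case proportion exactly
    covs <- covs[0]
  } else {
    covs <- covs[!const]
    for (nm in names(covs)) {
      v <- covs[[nm]]
      if (max(v[y == 1L]) < min(v[y == 0L]) || max(v[y == 0L]) < min(v[y == 1L])) {
        stop(sprintf("fit_propensity: complete separation on covariate %s",
                     sQuote(nm)), call. = FALSE)
      }
    }
  }
  df <- if (length(covs)) data.frame(y = y, covs) else data.frame(y = y)
  X <- stats::model.matrix(y ~ ., data = df)
  if (qr(X)$rank < ncol(X)) {
    stop("fit_propensity: rank-deficient design matrix", call. = FALSE)
  }
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) stop("fit_propensity: IRLS did not converge", call. = FALSE)
  structure(list(
    coefficients = stats::coef(fit),
    fitted = TRUE,
    iterations = fit$iter,
    dropped_constant = names(const)[const],
    glm = fit
  ), class = "propensity_model")
}

#' @export
coef.propensity_model <- function(object, ...) object$coefficients

#' Predict propensity scores
#'
#' @param object a `propensity_model`.
#' @param newdata optional data.frame with age_at_index, sex, plan columns;
#'   defaults to the training data.
#' @param ... unused.
#' @return numeric vector of scores in (0, 1).
#' @export
predict.propensity_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(as.numeric(stats::fitted(object$glm)))
  nd <- data.frame(age = newdata$age_at_index,
                   sexM = as.integer(newdata$sex == "M"),
                   planMedicare = as.integer(newdata$plan == "medicare"))
  as.numeric(stats::predict(object$glm, newdata = nd, type = "response"))
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("propensity_model (logistic, %d IRLS iterations)\n", x$iterations))
  print(round(x$coefficients, 6))
  if (length(x$dropped_constant)) {
    cat("constant covariates dropped:", paste(x$dropped_constant, collapse = ", "), "\n")
  }
  invisible(x)
}

# floor-truncate a score to d decimal digits, as an integer key
truncate_digits <- function(score, d) floor(score * 10^d)

#' Greedy digit-truncation 1:1 matching
#'
#' Pairs each case with one control by agreement of the propensity score's
#' first d decimal digits, relaxing d from `max_digits` down to 0: scores are
#' floor-truncated (not rounded) to d digits; within each pass, still-unmatched
#' cases, in seeded random order, are paired with an arbitrary (seeded)
#' still-unmatched control sharing the truncated value. The d = 0 pass pairs
#' every remaining case with a remaining control, so with enough controls no
#' case is left unmatched. Each control is used at most once.
#'
#' @param case_scores named numeric vector (names = case ids), scores in (0, 1).
#' @param control_scores named numeric vector (names = control ids).
#' @param max_digits first (finest) truncation level, default 8.
#' @param seed integer seed driving within-pass order.
#' @return object of class `match_result`: data.frame `pairs` (case_id,
#'   control_id, case_score, control_score, digits_used) and character vector
#'   `unmatched_cases`.
#' @export
greedy_digit_match <- function(case_scores, control_scores, max_digits = 8L, seed = 1L) {
  stopifnot(!is.null(names(case_scores)) || length(case_scores) == 0L,
            !is.null(names(control_scores)) || length(control_scores) == 0L)
  if (length(case_scores) && (any(case_scores <= 0) || any(case_scores >= 1))) {
    stop("greedy_digit_match: case scores must lie in (0, 1)", call. = FALSE)
  }
  if (length(control_scores) && (any(control_scores <= 0) || any(control_scores >= 1))) {
    stop("greedy_digit_match: control scores must lie in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  ca_id <- names(case_scores); co_id <- names(control_scores)
  ca_free <- rep(TRUE, length(case_scores))
  co_free <- rep(TRUE, length(control_scores))
  pairs <- vector("list", max_digits + 1L)

  for (d in seq(max_digits, 0L)) {
    if (!any(ca_free) || !any(co_free)) break
    ci <- which(ca_free)[sample.int(sum(ca_free))]
    ki <- which(co_free)[sample.int(sum(co_free))]
    ca_key <- as.character(truncate_digits(case_scores[ci], d))
    co_key <- as.character(truncate_digits(control_scores[ki], d))
    # pair, within each shared key, cases and controls in shuffled order
    co_by_key <- split(ki, co_key)
    ca_by_key <- split(ci, ca_key)
    for (key in intersect(names(ca_by_key), names(co_by_key))) {
      a <- ca_by_key[[key]]; b <- co_by_key[[key]]
      m <- min(length(a), length(b))
      a <- a[seq_len(m)]; b <- b[seq_len(m)]
      pairs[[d + 1L]] <- rbind(pairs[[d + 1L]], data.frame(
        case_id = ca_id[a], control_id = co_id[b],
        case_score = unname(case_scores[a]),
        control_score = unname(control_scores[b]),
        digits_used = d, stringsAsFactors = FALSE))
      ca_free[a] <- FALSE
      co_free[b] <- FALSE
    }
  }
  pairs <- do.call(rbind, rev(pairs[!vapply(pairs, is.null, logical(1))]))
  if (is.null(pairs)) {
    pairs <- data.frame(case_id = character(0), control_id = character(0),
                        case_score = numeric(0), control_score = numeric(0),
                        digits_used = integer(0), stringsAsFactors = FALSE)
  }
  unmatched <- ca_id[ca_free]
  if (length(unmatched)) {
    warning(sprintf("greedy_digit_match: %d case(s) unmatched (control pool exhausted)",
                    length(unmatched)), call. = FALSE)
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, unmatched_cases = unmatched),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d pairs, %d unmatched cases\n",
              nrow(x$pairs), length(x$unmatched_cases)))
  if (nrow(x$pairs)) {
    cat("pairs by digits of score agreement:\n")
    print(table(digits_used = x$pairs$digits_used))
  }
  invisible(x)
}

smd_one <- function(v_case, v_control) {
  md <- mean(v_case) - mean(v_control)
  psd <- sqrt((stats::var(v_case) + stats::var(v_control)) / 2)
  if (psd == 0 || is.na(psd)) {
    if (isTRUE(all.equal(md, 0))) 0 else NA_real_
  } else md / psd
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences (case mean minus control mean over the pooled
#' SD) per covariate, computed on the full arms and on the matched pairs. A
#' zero pooled SD yields SMD 0 when the means agree and NA (flagged) when they
#' do not.
#'
#' @param members cohort data.frame (both arms).
#' @param match a `match_result` from [greedy_digit_match()].
#' @return data.frame: covariate, smd_before, smd_after.
#' @export
balance_report <- function(members, match) {
  if (nrow(match$pairs) == 0L) stop("balance_report: no matched pairs", call. = FALSE)
  covs <- function(df) data.frame(age = df$age_at_index,
                                  sexM = as.integer(df$sex == "M"),
                                  planMedicare = as.integer(df$plan == "medicare"))
  all_case <- covs(members[members$arm == "case", , drop = FALSE])
  all_ctrl <- covs(members[members$arm == "control", , drop = FALSE])
  mi <- match(match$pairs$case_id, members$person_id)
  mj <- match(match$pairs$control_id, members$person_id)
  m_case <- covs(members[mi, , drop = FALSE])
  m_ctrl <- covs(members[mj, , drop = FALSE])
  data.frame(
    covariate = names(all_case),
    smd_before = vapply(names(all_case), function(v) smd_one(all_case[[v]], all_ctrl[[v]]), numeric(1)),
    smd_after = vapply(names(all_case), function(v) smd_one(m_case[[v]], m_ctrl[[v]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
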