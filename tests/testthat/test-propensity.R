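make_members <- function(arm, age, sex = "F", plan = "commercial") {
  n <- length(arm)
  data.frame(person_id = sprintf("m%03d", seq_len(n)), arm = arm,
             index_date = as.Date("2006-01-01"),
             age_at_index = as.integer(rep_len(age, n)),
             sex = rep_len(sex, n), plan = rep_len(plan, n),
             stringsAsFactors = FALSE)
}

test_that("intercept-only data gives the case proportion as the score", {
  m <- make_members(rep(c("case", "control"), c(3, 7)), age = 50)
  fit <- fit_propensity(m)
  expect_equal(unname(predict(fit)), rep(0.3, 10), tolerance = 1e-8)
})

test_that("exchangeable arms give near-zero covariate coefficients", {
  set.seed(31)
  age <- sample(20:80, 400, replace = TRUE)
  sex <- sample(c("F", "M"), 400, replace = TRUE)
  plan <- sample(c("medicare", "commercial"), 400, replace = TRUE)
  m <- make_members(rep(c("case", "control"), each = 200), age, sex, plan)
  fit <- fit_propensity(m)
  se <- summary(fit$glm)$coefficients[-1, "Std. Error"]
  expect_true(all(abs(coef(fit)[-1]) < 3 * se))
  expect_lt(abs(mean(predict(fit)) - 0.5), 1e-6)
})

test_that("the fit maximizes the Bernoulli likelihood (grid-search oracle)", {
  # 20-row fixture, age as the only varying covariate
  set.seed(32)
  m <- make_members(rep(c("case", "control"), each = 10),
                    age = c(55, 62, 70, 48, 66, 59, 71, 63, 52, 68,
                            41, 53, 47, 60, 38, 50, 45, 57, 44, 49))
  fit <- fit_propensity(m)

  loglik <- function(b0, b1) {
    eta <- b0 + b1 * m$age_at_index
    y <- as.integer(m$arm == "case")
    sum(y * eta - log1p(exp(eta)))
  }
  # independent maximizer: iteratively refined 2-D grid search
  b0r <- c(-30, 10); b1r <- c(-1, 1)
  for (step in 1:7) {
    g0 <- seq(b0r[1], b0r[2], length.out = 81)
    g1 <- seq(b1r[1], b1r[2], length.out = 81)
    ll <- outer(g0, g1, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    w0 <- diff(b0r) / 20; w1 <- diff(b1r) / 20
    b0r <- g0[best[1]] + c(-w0, w0); b1r <- g1[best[2]] + c(-w1, w1)
  }
  expect_equal(unname(coef(fit)), c(mean(b0r), mean(b1r)), tolerance = 1e-4)
})

test_that("refitting identical data reproduces coefficients and scores lie in (0,1)", {
  set.seed(33)
  m <- make_members(sample(rep(c("case", "control"), each = 100)),
                    age = sample(20:90, 200, replace = TRUE),
                    sex = sample(c("F", "M"), 200, replace = TRUE))
  f1 <- fit_propensity(m); f2 <- fit_propensity(m)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  s <- predict(f1)
  expect_true(all(s > 0 & s < 1))
})

test_that("complete separation and single-arm input are errors", {
  m <- make_members(rep(c("case", "control"), each = 10),
                    age = c(60:69, 20:29))
  expect_error(fit_propensity(m), "separation.*age")
  expect_error(fit_propensity(make_members(rep("case", 5), 50)), "both arms")
})

test_that("digit matching reproduces hand-traced fixtures exactly", {
  # fixture A: one exact 8-digit agreement
  res <- greedy_digit_match(c(ca = 0.51234567), c(co = 0.51234567), seed = 1)
  expect_identical(res$pairs$case_id, "ca")
  expect_identical(res$pairs$control_id, "co")
  expect_identical(res$pairs$digits_used, 8L)

  # fixture B: 6 cases / 6 controls, every pairing forced by unique truncated
  # keys; hand trace: (c1,k1,8) (c3,k3,8) (c2,k2,3) (c4,k4,1) (c5,k5,1) (c6,k6,0)
  cases <- c(c1 = 0.12345678, c2 = 0.123456, c3 = 0.5,
             c4 = 0.51, c5 = 0.9, c6 = 0.25)
  controls <- c(k1 = 0.12345678, k2 = 0.12399999, k3 = 0.5,
                k4 = 0.52, k5 = 0.91, k6 = 0.35)
  for (seed in c(1, 99)) {  # forced pairings: seed must not matter
    res <- greedy_digit_match(cases, controls, seed = seed)
    got <- res$pairs[order(res$pairs$case_id), ]
    expect_identical(got$case_id, paste0("c", 1:6))
    expect_identical(got$control_id, paste0("k", 1:6))
    expect_identical(got$digits_used[order(-got$digits_used)], c(8L, 8L, 3L, 1L, 1L, 0L))
    expect_identical(got$digits_used[got$case_id == "c2"], 3L)
    expect_identical(got$digits_used[got$case_id == "c6"], 0L)
  }

  # fixture C: control pool exhaustion
  expect_warning(res <- greedy_digit_match(c(a = 0.5, b = 0.4), stats::setNames(numeric(0), character(0)), seed = 1),
                 "unmatched")
  expect_equal(nrow(res$pairs), 0L)
  expect_setequal(res$unmatched_cases, c("a", "b"))

  expect_warning(res <- greedy_digit_match(c(a = 0.31, b = 0.45, d = 0.77),
                                           c(k = 0.316), seed = 4), "unmatched")
  expect_identical(res$pairs$case_id, "a")
  expect_identical(res$pairs$digits_used, 2L)
  expect_setequal(res$unmatched_cases, c("b", "d"))
})

test_that("no control is reused and equal arms always match fully", {
  set.seed(34)
  for (i in 1:200) {
    nc <- sample(1:8, 1); nk <- sample(1:8, 1)
    cases <- stats::setNames(runif(nc), paste0("c", seq_len(nc)))
    controls <- stats::setNames(runif(nk), paste0("k", seq_len(nk)))
    res <- suppressWarnings(greedy_digit_match(cases, controls, seed = i))
    expect_equal(anyDuplicated(res$pairs$control_id), 0L)
    expect_equal(anyDuplicated(res$pairs$case_id), 0L)
    expect_equal(nrow(res$pairs), min(nc, nk))  # d = 0 pass pairs all leftovers
    expect_equal(nrow(res$pairs) + length(res$unmatched_cases), nc)
    expect_true(all(diff(res$pairs$digits_used) <= 0))
  }
})

test_that("matching is seed-deterministic and permutation leaves digits_used invariant", {
  set.seed(35)
  cases <- stats::setNames(round(runif(40, 0.01, 0.99), 3), paste0("c", 1:40))
  controls <- stats::setNames(round(runif(40, 0.01, 0.99), 3), paste0("k", 1:40))
  r1 <- greedy_digit_match(cases, controls, seed = 7)
  r2 <- greedy_digit_match(cases, controls, seed = 7)
  expect_identical(r1, r2)
  perm <- sample(40)
  r3 <- greedy_digit_match(cases[perm], controls[rev(perm)], seed = 7)
  expect_identical(sort(r3$pairs$digits_used), sort(r1$pairs$digits_used))
})

test_that("balance reporting: zero SMD on exact matches, shrinkage under confounding", {
  m <- make_members(rep(c("case", "control"), each = 4),
                    age = c(40, 50, 60, 70, 40, 50, 60, 70),
                    sex = c("F", "M", "F", "M", "F", "M", "F", "M"))
  scores <- stats::setNames(stats::plogis(-3 + 0.05 * m$age_at_index), m$person_id)
  res <- greedy_digit_match(scores[1:4], scores[5:8], seed = 1)
  bal <- balance_report(m, res)
  expect_equal(bal$smd_after, rep(0, 3))

  # age-shifted arms: positive SMD before, reduced after matching on a big pool
  set.seed(36)
  shifted <- rbind(make_members(rep("case", 150), age = round(rnorm(150, 62, 8))),
                   make_members(rep("control", 450), age = round(rnorm(450, 52, 8))))
  shifted$person_id <- sprintf("s%03d", seq_len(nrow(shifted)))
  fit <- fit_propensity(shifted)
  sc <- stats::setNames(predict(fit), shifted$person_id)
  res2 <- greedy_digit_match(sc[shifted$arm == "case"], sc[shifted$arm == "control"], seed = 2)
  bal2 <- balance_report(shifted, res2)
  age_row <- bal2[bal2$covariate == "age", ]
  expect_gt(age_row$smd_before, 0.5)
  expect_lt(abs(age_row$smd_after), abs(age_row$smd_before))
})
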