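test_that("period prevalence counts each person once, inside the closed window", {
  cohort <- data.frame(person_id = c("a", "b", "c", "d"),
                       arm = c("case", "case", "control", "control"),
                       stringsAsFactors = FALSE)
  claims <- rbind(
    make_claims(rep("a", 3), c("2006-08-01", "2006-09-01", "2007-01-01"), "4019"),
    make_claims("b", "2006-06-30", "4019"),     # day before the window opens
    make_claims("c", "2007-06-30", "4019"),     # last window day counts
    make_claims("d", "2007-07-01", "4019"),     # day after the window closes
    make_claims("c", "2006-12-01", "2859")
  )
  prev <- period_prevalence(claims, cohort)
  r <- prev[prev$icd9 == "4019", ]
  expect_equal(r$n_case, 1L)      # a's 3 claims count once; b outside window
  expect_equal(r$n_control, 1L)   # c inside; d outside
  expect_equal(r$N_case, 2L)
  expect_equal(r$p_case, 0.5)
  # duplicating every claim changes nothing
  expect_equal(period_prevalence(rbind(claims, claims), cohort), prev)
})

test_that("prevalence percent reproduces printed worked examples", {
  # printed count/denominator pairs from the shipped reference table
  t1 <- utils::read.csv(system.file("extdata", "ra_table1_prevalence.csv",
                                    package = "comorbscreen"))
  rows <- make_prev(t1$icd9[1:5], t1$n_case[1:5], 0, N_case = t1$N_case[1:5])
  rendered <- comorbscreen:::fmt1(100 * rows$p_case)
  expect_identical(as.numeric(rendered), t1$printed_pct[1:5])
  # 12,773 / 62,681 -> 20.4%
  expect_identical(rendered[1], "20.4")
})

test_that("relative risk is the prevalence ratio and cancels equal denominators", {
  rec <- make_prev("4019", 20, 10, 100, 100)
  expect_equal(relative_risk(rec), 2)
  expect_equal(relative_risk(make_prev("1", 7, 7)), 1)
  rec2 <- make_prev("2", 40, 10, 61591, 61591)
  expect_identical(relative_risk(rec2), 40 / 10)
})

test_that("Katz interval matches a parametric-bootstrap oracle and is symmetric at RR=1", {
  rec <- make_prev("x", 30, 15, 1000, 1000)
  ci <- rr_confidence_interval(rec)
  expect_lt(ci$low, 2); expect_gt(ci$high, 2)

  # oracle: Monte-Carlo binomial sampling distribution of the ratio
  set.seed(41)
  n1 <- stats::rbinom(1e5, 1000, 30 / 1000)
  n0 <- stats::rbinom(1e5, 1000, 15 / 1000)
  keep <- n0 > 0 & n1 > 0
  boot <- stats::quantile((n1 / 1000)[keep] / ((n0 / 1000)[keep]), c(0.025, 0.975))
  width_katz <- log(ci$high) - log(ci$low)
  width_boot <- log(boot[[2]]) - log(boot[[1]])
  expect_lt(abs(width_katz - width_boot) / width_boot, 0.10)

  sym <- rr_confidence_interval(make_prev("y", 25, 25, 500, 500))
  expect_lt(sym$low, 1); expect_gt(sym$high, 1)

  flagged <- rr_confidence_interval(make_prev("z", 0, 5))
  expect_true(is.na(flagged$low) && is.na(flagged$high))
})

test_that("odds ratio is the cross-product with Woolf CI, farther from 1 than RR", {
  expect_equal(odds_ratio(make_prev("s", 30, 30, 100, 100))$or, 1)
  expect_equal(odds_ratio(make_prev("t", 20, 10, 100, 100))$or, 2.25)

  # property over random tables: |ln OR| > |ln RR| whenever both prevalences
  # are strictly inside (0,1) and RR != 1
  set.seed(42)
  for (i in 1:100) {
    N <- sample(50:500, 2)
    rec <- make_prev("r", sample(N[1] - 1, 1), sample(N[2] - 1, 1), N[1], N[2])
    rr <- relative_risk(rec)
    if (isTRUE(all.equal(rr, 1))) next
    expect_gt(abs(log(odds_ratio(rec)$or)), abs(log(rr)))
  }
})

test_that("filters drop excluded ranges and rare codes, in either order", {
  rows <- make_prev(
    c("7100", "7200", "9964", "4019", "2859", "5163", "4660", "7905", "2449", "496"),
    n_case = c(50, 50, 50, 60, 55, 45, 30, 25, 80, 90),
    n_control = c(50, 50, 50, 40, 30, 19, 5, 20, 25, 90))
  cfg <- screen_config()
  kept <- suppressMessages(apply_filters(rows, cfg))
  # hand count: 3 excluded-range codes, 2 rare (n_control 19 and 5) -> 5 left
  expect_identical(kept$icd9, c("4019", "2859", "7905", "2449", "496"))
  expect_equal(attr(kept, "drops"),
               c(excluded_range = 3L, rare_in_controls = 2L))
  # boundary: exactly 20 controls is kept
  expect_true("7905" %in% kept$icd9)

  # order invariance: exclusion-then-rarity equals rarity-then-exclusion
  excl_first <- rows[!is_excluded_code(rows$icd9), ]
  excl_first <- excl_first[excl_first$n_control >= cfg$min_control_count, ]
  rare_first <- rows[rows$n_control >= cfg$min_control_count, ]
  rare_first <- rare_first[!is_excluded_code(rare_first$icd9), ]
  rownames(excl_first) <- rownames(rare_first) <- NULL
  expect_identical(excl_first, rare_first)
  expect_identical(kept$icd9, excl_first$icd9)
})

test_that("ranking is by descending RR with case-count then code tie-breaks", {
  rows <- make_prev(c("b500", "a500"), c(40, 50), c(20, 25))
  ranked <- rank_order(rows)
  expect_identical(ranked$icd9, c("a500", "b500"))  # equal rr=2: larger n_case first
  expect_identical(ranked$rank, 1:2)

  tie <- make_prev(c("b123", "a123"), c(30, 30), c(10, 10))
  expect_identical(rank_order(tie)$icd9, c("a123", "b123"))  # lexicographic last

  # 100 random rows vs an independently-coded selection sort
  set.seed(43)
  rnd <- make_prev(sprintf("%05d", sample(10000:99999, 100)),
                   sample(1:99, 100, replace = TRUE),
                   sample(1:99, 100, replace = TRUE))
  ranked <- rank_order(rnd)
  oracle <- rnd
  oracle$rr <- oracle$p_case / oracle$p_control
  out <- character(0)
  while (nrow(oracle) > 0) {
    best <- 1
    for (j in seq_len(nrow(oracle))) {
      if (oracle$rr[j] > oracle$rr[best] ||
          (oracle$rr[j] == oracle$rr[best] && oracle$n_case[j] > oracle$n_case[best]) ||
          (oracle$rr[j] == oracle$rr[best] && oracle$n_case[j] == oracle$n_case[best] &&
           oracle$icd9[j] < oracle$icd9[best])) best <- j
    }
    out <- c(out, oracle$icd9[best])
    oracle <- oracle[-best, , drop = FALSE]
  }
  expect_identical(ranked$icd9, out)
})

test_that("top-k report renders printed-table formatting", {
  t2 <- utils::read.csv(system.file("extdata", "ra_table2_top30.csv",
                                    package = "comorbscreen"))
  rows <- make_prev(t2$icd9, t2$n_case, 1, N_case = t2$N_case)
  rows$rr <- t2$printed_rr; rows$ci_low <- t2$printed_ci_low
  rows$ci_high <- t2$printed_ci_high
  rows$odds_ratio <- rows$or_ci_low <- rows$or_ci_high <- NA_real_
  rows$rank <- seq_len(nrow(rows))
  rep30 <- top_k_report(rows, k = 30)
  expect_equal(nrow(rep30), 30L)
  expect_identical(rep30$n_case[1], "1,540")
  expect_identical(rep30$pct_case[1], "2.5%")     # 1540/61591
  expect_identical(rep30$ci95[1], "10.5-15.1")
  expect_identical(rep30$pct_case[2], "0.6%")     # 360/61591

  expect_identical(comorbscreen:::fmt1(12.2951), "12.3")
  expect_identical(comorbscreen:::fmt1(2.25), "2.3")  # half-up, not banker's

  expect_equal(nrow(top_k_report(rows, k = 50)), 30L)  # k beyond rows: all rows
  empty <- top_k_report(rows[0, ], k = 30)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("icd9", "pct_case", "rr", "ci95") %in% names(empty)))
})
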