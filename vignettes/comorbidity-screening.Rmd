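---
title: "Matched comorbidity screening: model, matching algorithm, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched comorbidity screening: model, matching algorithm, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbscreen)
```

`comorbscreen` turns claims-shaped data — persons, diagnosis claims,
enrollment spells — into a rank-ordered table of comorbidity relative risks
for a case condition against a matched comparator condition. This vignette
is the package's account of the statistical model, the algorithmic choices,
what the synthetic generator does and does not emulate, and the limits of
what the validation shows.

## The estimand and its model

The unit of inference is an ICD-9 diagnosis code at its most detailed
recorded level (each distinct normalized code string is its own stratum; no
rollup to 3-digit stems). For code $k$, with $n_{1k}$ of $N_1$ matched cases
and $n_{0k}$ of $N_0$ matched controls carrying at least one claim of $k$
inside a fixed one-year window, the target is the period-prevalence ratio

$$\mathrm{RR}_k = \frac{n_{1k}/N_1}{n_{0k}/N_0}.$$

This is a *prevalence* ratio, not an incidence ratio: a person with thirty
claims of a code counts exactly once, and no attempt is made to distinguish
new from ongoing disease. With 1:1 matching, $N_1 = N_0$ and the ratio
reduces to $n_{1k}/n_{0k}$ exactly — a useful invariant the tests assert.

The 95% interval uses the Katz log method,
$\exp(\ln \mathrm{RR} \pm z\sqrt{1/n_1 - 1/N_1 + 1/n_0 - 1/N_0})$, the
standard Wald interval for a ratio of independent binomial proportions. No
source we re-derive the procedure from states its interval method, so this
is a design choice; the interval's empirical coverage is therefore one of
the package's central acceptance checks rather than an assumption. The odds
ratio is reported alongside with the Woolf interval
($\exp(\ln \mathrm{OR} \pm z\sqrt{1/a + 1/b + 1/c + 1/d})$, no continuity
correction; zero cells are flagged as NA rather than patched). For
prevalences strictly inside $(0,1)$ the OR is always farther from 1 than the
RR — a monotonicity the tests check on random tables.

Two filters precede ranking:

* **Exclusion filter.** Codes with 3-digit stems 710–729 (arthropathies,
  dorsopathies, rheumatism) and the 996.4 prefix (mechanical complication of
  orthopedic device) are removed as part-and-parcel of the case disease
  rather than comorbidity. The rule is stem-based, so e.g. psoriatic
  arthropathy (696.0, a skin-chapter code) stays in.
* **Stability filter.** Codes in fewer than `min_control_count = 20` control
  persons are removed; below that the denominator of the RR is too unstable
  to rank. The two filters commute, which the tests assert.

No multiple-testing adjustment is applied to the primary output: the screen
is a ranking and hypothesis-generation tool, and its intervals are
per-code. (Interpreting the full table of thousands of codes as a set of
significance tests would require adjustment; that is deliberately out of
scope for the primary output.)

## Cohort rules and their conventions

A person enters an arm iff (a) they have at least `min_claims = 2` claims of
eligible kinds matching the arm's code patterns, (b) an enrollment spell
covers the reference date (closed interval: a spell ending exactly on
2007-06-30 still counts), (c) at least one matching claim is dated *strictly
before* the pre-cutoff (2006-07-01), and (d) they are at least 16 at the
index date, defined as the earliest matching eligible claim. Only
`encounter` claims are cohort-defining — lab and radiology claims carry
codes for *rule-out* testing, not established diagnosis. The comorbidity
count stage, by contrast, accepts all claim kinds: there the question is
what was recorded, not what defines membership.

Birth dates are kept at year resolution, as claims extracts rarely carry
finer, and age is the calendar-year difference
(`age = year(date) − birth_year`). A mid-year birthday convention was
considered and rejected: it makes a person born in 1991 fifteen on
2007-06-30, which contradicts the convention used everywhere else in the
package that the 1991 cohort is the youngest eligible one at the mid-2007
reference date. Calendar-year age is deterministic, monotone and
documented; at these cohort sizes the ±half-year discretization is
immaterial to the propensity fit.

A person qualifying for both conditions is assigned to the case arm and
barred from the control pool — the arms must be disjoint for the matching
contract (each control used once) to be meaningful.

## Propensity fit and digit-truncation matching

The propensity score is the fitted probability from a logistic regression of
case membership on age (linear, in years), sex and plan — no interactions or
spline terms, because the matching covariates are few and coarse. The fit is
delegated to `stats::glm` (IRLS, `epsilon = 1e-10`, `maxit = 100`);
complete separation and rank deficiency are detected before fitting and
raised as errors naming the covariate, since `glm` itself only warns.

Matching is greedy 1:1 on truncated score digits: for $d = 8, 7, \ldots, 0$,
still-unmatched cases are paired with still-unmatched controls whose score
agrees after floor-truncation to $d$ decimal digits. Three conventions are
deliberate:

* **Truncation, not rounding** — "agreement of the first $d$ digits" is a
  digit-prefix criterion, and truncation is the convention of the classic
  greedy-matching macro family this algorithm descends from.
* **Seeded random order within a pass** — the order in which tied
  cases/controls pair is arbitrary; randomizing it (reproducibly, from the
  seed) avoids silent dependence on input row order. Permuting the input
  with the same seed can only permute pairings within equal-score ties; the
  multiset of `digits_used` is invariant.
* **The $d = 0$ pass is a complete fallback** — every score in $(0,1)$
  agrees on zero digits, so no case is left unmatched while any control
  remains. Matching quality degrades gracefully instead of failing.

Balance is reported as standardized mean differences (difference in means
over the pooled SD) per covariate, before and after matching; a zero pooled
SD with equal means reports 0, with unequal means NA (flagged).

## The synthetic generator

The generator exists so that every downstream stage is testable with known
ground truth. It emulates:

* demographics — age from a normal truncated to [16, 100] (default mean
  59.0, SD 15 — the SD is our choice, typical of adult chronic-disease
  claims cohorts; the mean, 73.8% female and 35% Medicare defaults mirror a
  published rheumatoid-arthritis claims cohort so that default runs resemble
  real screen output);
* chronic-disease coding — each designated case (control) receives two
  encounter claims with concrete codes matching the arm's patterns, the
  first strictly before the pre-cutoff, so designated persons satisfy the
  cohort rules by construction;
* comorbidity occurrence — each code-book code is a **person-level Bernoulli
  event**, probability $p_0$ in controls and $p_1 = \min(\mathrm{rr}\cdot
  p_0, 1)$ in cases, emitted at most once per person and dated uniformly in
  the window. The analysis counts persons, not claims, so within-person
  claim repetition would add realism but no information;
* confounding — an optional `confounder_slope` adds log-odds per decade of
  age (log-odds scale, so it composes with the logistic propensity model
  being tested), and `case_age_shift` moves the case arm's age
  distribution, creating genuine age confounding for the matcher to remove.

It does **not** emulate: longitudinal disease progression, enrollment churn
(one spell covers everyone), claim costs, code miscoding or upcoding,
between-code correlation, or care-seeking intensity differences. Passing
tests therefore demonstrate that the *procedure* is correct and calibrated
under its own sampling assumptions — not that real claims data meet those
assumptions.

## Validation design and problem sizes

The validation runs at desk scale, chosen to give tight Monte-Carlo bands at
interactive runtimes:

* **Worked-example checks (exact).** Prevalence percent rendering is checked
  against printed count/denominator pairs from a published screen's tables
  (shipped as reference CSVs), e.g. 12,773 / 62,681 → 20.4%.
* **Coverage (stochastic).** 500 replicate screens, 5,000 per arm, one code
  planted at $p_0 = 0.005$, RR = 3; empirical 95%-interval coverage must be
  in [0.93, 0.97].
* **Null calibration (stochastic).** One screen of 200 codes planted at
  RR = 1 with $p_0 \sim U(0.02, 0.10)$ ($p_0$ is our choice: large enough
  that the Wald approximation is in its comfort zone, small enough to be
  prevalence-like); the fraction of intervals excluding 1 must be in
  [0.03, 0.07]. At 200 codes this fraction has binomial SD ≈ 0.015, so the
  band is a ±1.3 SD check, deliberately at the spec'd size.
* **Confounding removal (stochastic).** 1,000 cases vs a 3,000-control pool
  (a surplus pool is needed for age-similar matches to exist),
  `confounder_slope = 0.8`/decade, case arm shifted +8 years, RR = 2 at
  $p_0 = 0.05$, 100 replicates: the matched estimate's mean absolute log-RR
  error must be strictly below the crude estimate's.
* **Matcher correctness (exact).** Hand-traced fixtures whose pass structure
  forces every pairing, plus a 1,000-instance property sweep (no control
  reused; equal arms always fully matched).
* **Determinism (exact).** Byte-identical ranked CSVs from repeated runs of
  one config + seed.

Display rounding is half-away-from-zero at one decimal (base R's `round`
is round-half-even, which would render 2.25 as "2.2"); internal values are
never rounded. Window and enrollment comparisons are closed-interval on
calendar dates. Seeds fan out from one global seed by a fixed affine
derivation, so each stage is individually reproducible.

## Known limitations

* The RR of a code reflects *recorded diagnosis*, confounded by care-seeking
  and testing intensity; the comparator condition is chosen to equalize
  health-care contact, but the design cannot remove diagnostic-workup bias.
* Greedy digit matching is not optimal matching: it guarantees completeness
  (given enough controls), not minimal total score distance.
* The Katz interval is asymptotic; rows near the stability threshold (20
  controls) have the least reliable intervals, which is precisely why the
  threshold exists.
* With equal-size selected arms the $d=0$ fallback matches everyone, so the
  matched-arm contrast equals the crude contrast; confounding removal
  requires a control surplus.
* Codes absent from both arms are (necessarily) invisible; codes absent only
  from the control arm yield undefined RRs and are removed by the stability
  filter, so the screen cannot rank case-exclusive rarities.
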