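# comorbscreen

Hypothesis-free comorbidity screening in administrative-claims-shaped data.

## The problem

When a drug is developed for a chronic disease, its safety profile has to be
read against the *full* spectrum of conditions that patients with that disease
already carry — including rare but severe ones that no targeted study would
have looked for. Large health-plan claims databases make this possible: select
a case cohort by diagnosis codes, select a comparator cohort with a different
chronic condition (so both groups have comparable contact with health care),
match them on demographics, and then rank *every* recorded diagnosis code by
how much more common it is among the cases. The top of that ranking is a
data-driven shortlist of disease-associated comorbidities.

`comorbscreen` implements that pipeline for claims-shaped inputs (three CSV
tables: persons, claims, enrollment spells), together with a synthetic claims
generator with *planted* per-code effects, so the whole procedure can be
validated end to end without access to any proprietary claims database.

## The method

For each ICD-9 diagnosis code *k* recorded in either matched arm during a
one-year window, the screen computes the one-year **period prevalence** in
each arm — each person counted at most once per code:

```
p̂_case(k) = n_case(k) / N_case        p̂_ctrl(k) = n_ctrl(k) / N_ctrl
```

and ranks codes by the prevalence ratio **RR(k) = p̂_case(k) / p̂_ctrl(k)**
(with 1:1-matched equal-size arms this is just `n_case / n_ctrl`), with the
Katz log-scale 95% interval

```
exp( ln RR ± z · √( 1/n_case − 1/N_case + 1/n_ctrl − 1/N_ctrl ) ),  z = 1.959964
```

plus the odds ratio with its Woolf interval. Before ranking, codes in the
case-disease-related ICD-9 ranges (710–729, 996.4) are excluded, and a
stability filter keeps only codes found in ≥ 20 control-arm persons.

Arms are built by the cohort rules (≥ 2 diagnostic claims matching the
condition's code patterns, an enrollment spell active on the reference date,
at least one claim strictly before the pre-cutoff date, age ≥ 16 at the index
date — the earliest matching claim), and paired 1:1 by **greedy
digit-truncation matching** on a logistic propensity score
P(case | age, sex, plan): controls must agree with a case on the first 8
decimal digits of the score, then 7, and so on down to 0, each control used
at most once.

## Worked example

Plant four comorbidity codes with known relative risks, simulate a claims
database, and run the screen:

```r
library(comorbscreen)

truth <- simulation_truth(
  code_book(c("4019", "5163", "2859", "5990"),
            p0 = c(0.20, 0.02, 0.06, 0.08),     # control-arm prevalences
            rr = c(1.2, 4, 2, 1),               # planted relative risks
            description = c("Hypertension NOS", "Idiopathic fibrosing alveolitis",
                            "Anemia NOS", "Urinary tract infection NOS")),
  n_cases = 5000, n_controls = 5000, seed = 42)

db  <- simulate_claims_db(truth)
scr <- comorbidity_screen(db$claims, db$enrollment, db$persons, seed = 42,
                          descriptions = setNames(truth$codebook$description,
                                                  truth$codebook$icd9))
print(scr)
```

```
matched comorbidity screen
  cohort: 4996 cases, 4995 controls selected; 4995 pairs matched
  codes:  14 screened, 9 ranked after filters (5 excluded-range, 0 rare)
  top 5 by RR:
 icd9                     description n_case pct_case  rr    ci95
 5163 Idiopathic fibrosing alveolitis    393     7.9% 4.1 3.3-5.0
 2859                      Anemia NOS    595    11.9% 1.9 1.7-2.2
 4019                Hypertension NOS  1,197    24.0% 1.2 1.1-1.3
 5990     Urinary tract infection NOS    423     8.5% 1.0 0.9-1.2
 6908                                      0     0.0% 0.0   NA-NA
```

The planted RRs (4, 2, 1.2, 1) are recovered inside their 95% intervals, the
case-defining codes (714.x, excluded range) are dropped, and the control-
defining skin codes surface with RR ≈ 0 — exactly the pattern a real screen
shows for conditions associated with the comparator group. `summary(scr)`
adds cohort demographics and the covariate-balance (standardized mean
difference) table; `plot(scr)` draws a forest plot of the top RRs;
`as.data.frame(scr)` returns the full ranked table.

A YAML-driven pipeline (`run_simulate()` / `run_screen()` / `run_report()`,
or `inst/cli/comorbscreen.R` for shell use) writes the stage artifacts —
cohort, match pairs, full ranked CSV, top-k table, balance report and an
auditable stage-count log — deterministically from config + seed.

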