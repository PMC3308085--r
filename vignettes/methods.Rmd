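---
title: "Methods: a claims-based effectiveness algorithm for RA medications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a claims-based effectiveness algorithm for RA medications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raclaims)
```

## The problem

Disease activity in rheumatoid arthritis is measured at the bedside —
joint counts, acute-phase reactants, global assessments — none of which
appear in administrative claims. Yet claims databases are where large-scale
comparative-effectiveness questions must be answered. The idea implemented
here is that *treatment behaviour* visible in claims is an informative
proxy for clinical response: a patient whose RA drug is working does not
switch biologics, add DMARDs, escalate doses, or start or escalate
glucocorticoids, and keeps filling the prescription. An episode that shows
none of those signals, with high adherence, is called effective.

The package provides three coupled pieces: the rule set itself
(`classify_episodes()`), the registry-based clinical gold standard used to
validate it (`evaluate_gold_standard()`), and the machinery to quantify
agreement and the consequences of disagreement (`performance_metrics()`,
`bias_analysis()`, `discordance_report()`).

## Episode construction

A new-user design anchors everything. An initiation is a fill or infusion
with no same-drug event in the preceding 183 days; the index date starts a
one-year observation window whose endpoint is a registry outcome visit 10
to 14 calendar months after the index date (nearest to 12 months when
several qualify). Episodes additionally require an oral fill of any drug 6
to 12 months pre-index — evidence the patient routinely fills through the
observed pharmacy system — and, for the primary analysis, a baseline
registry visit within ±31 days of the index date. Day-count windows are
fixed day equivalents (1/3/6 months = 31/90/183 days) for reproducibility;
only the outcome-visit window is defined in calendar months because that
is how a "1 year ± 2 months" visit is scheduled in practice. The
direction-agnostic ±31-day baseline window and the earliest-episode rule
in `one_episode_per_patient()` are deliberate choices where the design was
open; both are configurable.

DMARD episodes (leflunomide, sulfasalazine, hydroxychloroquine) require
any methotrexate exposure on or before the index date, and methotrexate
itself never forms an episode: it is the anchor therapy that is typically
continued regardless of response, so "new MTX user" is not a meaningful
response-evaluable population.

## The rule set and its tunable constants

All constants live in `ra_config()` so any one of them can be varied in a
sensitivity analysis. The ones that matter:

* **MPR threshold 0.80** over `[index, outcome)`: the conventional
  high-adherence cut. The default numerator counts full days supplied
  (supply overrunning the window still counts; the cap at 1 bounds the
  ratio); a `mpr_truncate` variant clips supply at the window end, since
  the literature uses both conventions.
* **Infusion schedules**: infliximab weeks 0/2/6/14 then every 8 weeks
  (adherence); the escalation rule's 120% limit is computed against a
  0/2/6-week load plus every-8-weeks. The two day grids coincide
  (6 + 8 = 14 weeks), so the distinction is kept in the interface but is
  numerically inert. Abatacept months are 30 days, with one missed
  infusion allowed.
* **Weekly-dose ceilings 75 / 30 mg** for etanercept / adalimumab over a
  60-day sliding window. Claims carry strength × quantity / days-supply,
  not prescribed frequency, so the prohibited regimens ("50 mg twice
  weekly", "40 mg weekly") are operationalised as mean weekly dispensed
  dose: 75 sits midway between 50 (allowed) and 100 (prohibited) mg/week,
  and 30 between 20 and 40. The 60-day window smooths fill-boundary
  artefacts.
* **Infliximab round-up rule**: doses are rounded *up* to the nearest
  100 mg before differencing, so 290 → 300 and a 290-to-300 change is not
  an escalation while 300-to-500 is.
* **Glucocorticoids**: the naive/prevalent branch is decided by any oral
  glucocorticoid fill in the 183 days before the index date. Prevalent
  comparisons use cumulative prednisone-equivalent milligrams and pass at
  exactly 120% (strictly greater fails). A prevalent user with zero
  recorded milligrams has a degenerate denominator and is treated as
  naive. Counting starts at index + 90 days because early bridging
  glucocorticoids while a biologic takes effect are expected clinical
  practice, not a failure signal.

Flags are not mutually exclusive; `classify_episodes()` records every
violated component, which is what makes the discordance tallies
interpretable.

## The gold standard

DAS28-ESR (4-variable):
`0.56·√TJC28 + 0.28·√SJC28 + 0.70·ln(ESR) + 0.014·GH`, with ESR floored at
1 mm/h to keep the logarithm defined — a conventional guard that only
affects a degenerate input. The ESR form is used because the registry
records ESR and a 0–100 patient global; the CRP variant is out of scope.
Primary effectiveness is LDA (DAS28 ≤ 3.2) *or* improvement strictly
greater than 1.2 units, *plus* high adherence; the strict inequality
follows the definition used when the criterion is stated formally, and is
configurable for readers who prefer ≥. CDAI divides the recorded 0–100
globals by 10 and uses the strict < 11 LDA cut. The adherence requirement
exists to attribute the observed disease activity to the indexed drug
rather than to whatever replaced it.

## Validation and bias

`performance_metrics()` computes PPV, NPV, Se, Sp on their own
denominators with exact Clopper–Pearson intervals by default. Two Wald
variants are provided, including `wald_pooled_n` (normal approximation on
the *total* episode count), which reproduces the interval widths of
reports that compute all four CIs on the overall n. Statistical
correctness is the default; report compatibility is opt-in.

`bias_analysis()` inverts the predictive values: an observed response rate
`obs` measured by an imperfect algorithm implies a true rate
`obs·PPV + (1 − obs)·(1 − NPV)`. The map is linear with endpoints `1 −
NPV` (at obs = 0) and `PPV` (at obs = 1), so with PPV = 0.76 and NPV =
0.90 the relative bias grows from under 1% at an observed 30% to 21% at
60% — small near the rate at which the algorithm was tuned, material far
from it. Percentages in printed reports are rounded half-up, matching
clinical-journal presentation.

## The synthetic cohort

`generate_cohort()` emulates the linked registry + claims structure the
algorithm was developed on. Its defaults are the study conditions: the
combined-cohort drug mix (adalimumab 24%, hydroxychloroquine 21%,
etanercept 20%, infliximab 11%, sulfasalazine 8%, rituximab 7%,
leflunomide 7%, abatacept 3%), a 27% gold-standard response rate, baseline
DAS28 4.9 ± 1.6, and an outcome visit at 365 ± 21 days. The prevalent
oral-glucocorticoid share (0.35) and the per-component failure
probabilities are the package's own choices, set once to what is realistic
for a comorbid veteran RA population: non-responder failures concentrate
on non-adherence/switching (0.60/0.20), then glucocorticoid increase
(0.40), new DMARDs (0.30), dose escalation (0.10) and injections (0.08),
with responder counterparts an order of magnitude smaller (0.08/0.01,
0.15, 0.08, 0.03, 0.05). Under these defaults `implied_performance()`
puts sensitivity in the low 70s and specificity in the high 80s — the
performance band that characterises this class of algorithm.

Two structural points deserve emphasis:

* **Adherence couples the two classifiers.** A switch truncates index-drug
  supply, so it breaks both the algorithm's adherence component and the
  gold standard's adherence requirement. Because of this, `prevalence`
  parameterises the *gold-standard-positive* rate: the latent
  clinical-responder rate is back-computed so that, after responders lost
  to non-adherence, the net gold-standard rate equals the configured
  value. `implied_performance()` carries the same coupling through the
  closed-form Se/Sp/PPV/NPV, integrating over the drug mix and the rules
  that do not apply to some drugs (no adherence or escalation rule for
  rituximab; no escalation rule for oral DMARD episodes).
* **Failures manifest deterministically.** Bernoulli draws decide *which*
  components fail; the claims are then constructed so the algorithm
  detects exactly those failures. Responder outcome visits are built to
  hit an exact DAS28 in the low-disease-activity region (joint counts and
  globals sampled plausibly, the ESR term solved analytically);
  non-responder visits land strictly outside both the LDA and the
  improvement regions with a 0.1-unit margin so floating-point noise
  cannot flip a classification.

What the generator does *not* emulate: coverage gaps and censoring,
comorbidity-driven coding, correlated component failures beyond the
switch–adherence coupling, dose titration trajectories, or visit
non-attendance. Tests passing on synthetic cohorts therefore demonstrate
that the implementation computes the rule set and its validation
correctly, not that the algorithm would attain the same Se/Sp in any
particular real population.

`boundary_cohort()` complements the stochastic generator with 30
deterministic episodes pinned to the decision boundaries (MPR exactly
0.80, glucocorticoid dose at exactly 120%, the 290/300 mg round-up edge,
one vs two injection days, the abatacept single-miss allowance), each with
a hand-audited expected classification.

`calibrate_misclassification()` rescales the responder failure
probabilities (bisection against the closed-form sensitivity) and the
non-responder probabilities (against specificity) to hit target Se/Sp —
the two problems separate exactly because responder non-adherence shifts
episodes out of the gold-positive denominator rather than misclassifying
them — then verifies the result on a seeded simulated cohort.

## Problem sizes and numerical choices

The test suite exercises a 5,000-patient cohort for the
parameter-recovery and law-of-large-numbers properties (empirical Se/Sp
within ±3 points of the implied values; gold-standard prevalence within
±2 points of the configured 27%) and a 3,000-patient verification cohort
for calibration, sizes at which binomial noise on the recovered metrics is
about one point. Dates are calendar `Date`s throughout (no times);
calendar-month arithmetic clamps to month ends (Jan 31 + 1 month =
Feb 28). Ties for "nearest visit" break toward the earlier date. All
randomness flows through a single integer seed, and the generator
restores the caller's RNG state.

## Known limitations

The comorbidity exclusion consumes pre-computed boolean flags; mapping
diagnosis codes to those flags is intentionally out of scope, as are
enrollment-gap handling, death censoring, glucocorticoid
dose-equivalence conversion, and the full EULAR good/moderate/none
response taxonomy (only the LDA-or-improvement criterion is implemented).
The escalation thresholds for the subcutaneous biologics are
operationalisations of qualitative regimen statements; they are exposed in
`ra_config()` precisely because other reasonable operationalisations
exist.
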