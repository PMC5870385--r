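---
title: "Methods: the triage engine, its evaluation statistics, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the triage engine, its evaluation statistics, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivrtriage)
```

## The problem and the model

In regions where the nearest clinic may be hours away, guardians of sick
children must decide — without medical training — whether a child needs
emergency care, a clinic visit, or can be nursed at home. `ivrtriage`
implements a phone-hotline triage algorithm for this decision: a
decision tree of dichotomous, *ask-only* questions derived from the
WHO/UNICEF Integrated Management of Childhood Illness (IMCI) guidelines,
stripped of every item that requires examination or measurement (breath
counting, thermometer readings, chest inspection), because a lay caller
cannot perform those reliably.

A call session walks the tree: two danger-sign questions first (inability
to drink or breastfeed; convulsions or unconsciousness), then four symptom
screens — fever, cough, diarrhoea, vomiting. A confirmed symptom opens a
block of severity follow-ups; a denied one skips to the next screen.
Specific answers emit *disease assessments* from a fixed catalogue of
eleven, each tied to exactly one triage level:

| Level | Meaning | Assessments |
|---|---|---|
| A | emergency care now | inability to drink/breastfeed, neurological emergency, severe febrile disease, severe RTI, GI infection with severe dehydration |
| B | causal treatment within 24 h | febrile disease, moderate RTI, GI infection with some dehydration, dysentery |
| C | home care | mild RTI, GI infection with no dehydration |

A call may register many assessments, but ends with a **single**
recommendation: the maximum-severity level over everything emitted — the
most life-threatening condition wins. This is the deliberate design bias
of the whole tool: when a lay report is ambiguous, err toward sending the
child to care, never away from it.

Two modelling decisions deserve emphasis:

* **A completed call with no assessment is not "home care".** It returns
  the sentinel `NONE_APPLICABLE` with a "symptoms not covered, seek care
  if worried" message. Mapping it silently to level C would claim a
  clinical judgement the algorithm never made.
* **Age is an eligibility precondition, not a routing variable.** The
  engine accepts children from 1 month up to (not including) 15 years and
  rejects others at session start; no question branches on age. An
  age-capture step therefore lives in the front-ends, not in the tree.

## The shipped default tree

The default definition (`default_algorithm()`) is a reconstruction: the
deployed questionnaire's exact wording is not published, so the severity
blocks are rebuilt from the IMCI "ask" items. Every reconstruction choice
lives in the shipped file `inst/extdata/imci_default.json`, not in code,
so a corrected transcription can replace it without touching the engine.
The choices:

* **Respiratory severity.** Severe RTI = cough plus breathing so
  difficult the child cannot drink, talk or feed normally, *or* harsh
  noisy breathing at rest; moderate RTI = cough plus fast or difficult
  breathing; mild RTI = cough alone. A severe finding short-circuits the
  block (IMCI classifies top-down), so each cough path emits exactly one
  respiratory grade.
* **Dehydration.** Severe = unusual sleepiness or inability to drink;
  some = sunken eyes or drinking eagerly as if very thirsty; none =
  neither. Asked whenever diarrhoea *or* vomiting is confirmed: vomiting
  is a screened symptom with no standalone assessment, so it feeds the
  gastrointestinal dehydration grading.
* **Two vomiting nodes, one prompt.** Routing is memoryless (the next
  node depends only on the current node and answer), so the tree carries
  `vomiting_gi` (reached after confirmed diarrhoea; always proceeds to
  the dehydration questions) and `vomiting_screen` (reached without
  diarrhoea; "no" ends the call). Both share the `q_vomiting` prompt.
* **Stiff neck** is asked only after confirmed fever; "yes" adds severe
  febrile disease *alongside* febrile disease rather than replacing it,
  because a session's emitted set is defined as the union of per-answer
  emissions (this keeps records replayable); the recommendation is
  unaffected since severity is maximised anyway.
* **Question cap 15.** A longer automated interrogation protracts the
  call and loses the caller; the shipped tree's longest path asks 13
  questions. The cap is a validated property of any definition file.

The tree has 14 nodes and 960 complete answer paths — small enough that
the test suite *enumerates all of them* and checks the engine against an
independently coded maximum-severity lookup driven straight off the raw
definition file.

## Evaluation statistics

The evaluation module reproduces a hospital validation design: each call
yields a tool label, the examining physician provides the gold-standard
label, and the comparison runs at three levels (symptom detection,
disease assessment, triage recommendation).

**Agreement and kappa.** For a square tool-by-physician table,
`percent_agreement()` is the diagonal share and `cohens_kappa()` computes
$\kappa = (p_o - p_e)/(1 - p_e)$ with $p_e$ from the marginal products.
The standard error under the null $\kappa = 0$ uses the Fleiss marginal
formula
$$\mathrm{SE}_0 = \sqrt{\frac{p_e + p_e^2 - \sum_i p_{i+} p_{+i}(p_{i+} + p_{+i})}{n\,(1-p_e)^2}},$$
and the reported p-value is one-sided for $\kappa > 0$ — the convention
of standard statistical packages. Verbal interpretation follows the
Landis–Koch bands (`landis_koch_band()`). Degenerate marginals
($p_e = 1$) yield `NA`, never a crash or a fake zero.

**Diagnostic accuracy.** `binary_metrics()` returns sensitivity,
specificity, PPV, NPV, prevalence and agreement as proportions, with `NA`
whenever a denominator is zero — a condition the gold standard never
identified has no defined sensitivity, and printing 0 there would be a
lie.

**Triage concordance.** `dichotomize_triage()` collapses the 3×3 A/B/C
table to the clinically decisive 2×2 — hospital (A or B) versus home (C);
`undertriage_rate()` counts the dangerous error direction (tool says
home, physician required care) over all cases; `capture_rate()` reports
the share of physician-level-A cases the tool also flagged A.

**Reconstructing 2×2 tables from printed summaries.** Published
comparisons usually print rounded percentages, not cell counts.
`reconstruct_confusion()` inverts this: it searches *all* integer 2×2
tables with the stated total whose implied prevalence, sensitivity and
specificity round (half-up) back onto the printed values, using optional
agreement/PPV/NPV for disambiguation. Exact matches are preferred, but
candidates within one unit of the printed last digit are admitted as a
fallback, because printed tables are occasionally internally inconsistent
at exactly that magnitude — `reconstruct_study_tables()` shows several
shipped rows where the unique admissible table implies a value one ulp
away from the printed one (e.g. a sensitivity printing as 86.1 where the
only consistent integer table gives 86.0). When several tables survive
every filter, the function raises an inconsistency error rather than
guessing: auditability beats convenience.

**Rounding.** All comparisons against printed values use half-up rounding
(`round_half_up()`), i.e. ties away from zero, at the printed precision —
1 decimal for percentages, 2 for kappas. Base R's banker's rounding would
silently disagree with how published tables are rounded.

## The synthetic cohort generator

`sample_cohort()` + `simulate_study()` emulate the validation study so
that engine and evaluation can be exercised end-to-end without any real
data, and so that parameter-recovery tests are possible.

What it models, and the defaults:

* **Recruitment and dropout.** 294 recruited calls; each call abandons
  mid-questionnaire with probability 27/294 ≈ 9.2%, hanging up at a
  uniformly chosen question. Abandoned calls stay in the log with no
  recommendation.
* **True child states.** Independent Bernoulli draws per symptom at the
  study's physician prevalences (fever 70.5%, cough 54.9%, diarrhoea
  18.1%, vomiting 24.5%); severity grades conditional on the parent
  symptom, proportional to the published assessment prevalences;
  danger signs at their (near-zero) study rates; age roughly exponential
  with median 3 years, clamped to the eligible window.
* **The physician standard.** Derived deterministically from the true
  flags through the same assessment-to-level catalogue the tool uses.
  This is intentional: every tool-versus-standard discrepancy in a
  simulation is then attributable to guardian misreporting alone, the
  error source under study.
* **Guardian misreporting.** One uniform draw per (child, question): a
  truly present state is reported with the per-question report
  sensitivity, an absent one denied with the report specificity
  (`reporting_model()`). The calibrated model
  (`study_reporting_model()`) uses the exact cell fractions of the
  reconstructed study tables (fever 151/167 and 47/70, cough 119/130 and
  76/107, …). Two items are unidentifiable from the study (the
  physicians never recorded them): their report specificity is set once
  to 0.90 — a modest false-alarm rate consistent with the other
  danger-sign question — and their sensitivity to 0.5, which nothing
  downstream depends on at zero true prevalence.

What it deliberately does **not** model: physician error (the standard is
noiseless), symptom co-occurrence beyond independence (only marginals are
published; a joint distribution would be invented), age-dependent
prevalence, audio comprehension or telephony failures other than the flat
dropout rate. Consequently, passing recovery tests demonstrates that the
engine and the statistics are correct and that *marginal* symptom
statistics are recoverable — it says nothing about joint structure in
real calls.

**Problem sizes.** Recovery tests run at n = 10\,000 with three seeds and
accept deviations within three Monte-Carlo standard errors of the kappa
estimate; truth-frequency checks use the binomial 3-SE band. The engine
oracle enumerates all 960 paths exhaustively. These sizes make every
stochastic check tight enough to catch real defects while keeping the
whole suite comfortably fast.

## Degenerate inputs and tie-breaks

* `triage(character(), def)` returns `NONE_APPLICABLE`; unknown
  assessment ids are catalogue errors.
* Out-of-order answers and answers after completion are path errors;
  unknown keypad codes are input errors (the interactive front-end
  re-prompts twice, then abandons).
* An answer vector that runs out mid-walk is a hang-up: the session is
  abandoned, carries no recommendation, and is retained in the log.
* `cohens_kappa()` on a table with $p_e = 1$ gives `NA`; empty tables are
  errors; non-square tables are rejected.
* `reconstruct_confusion()` ties are broken by number of exactly-matched
  inputs, then total absolute deviation, then printed agreement; a
  residual tie is an error.
* All simulation randomness flows through a single seed; identical
  (seed, configuration, model) triples give bitwise-identical output.

## Known limitations

* The default tree is a faithful-but-configurable reconstruction, not a
  verbatim transcription of the deployed questionnaire; wording-level
  differences (e.g. whether a fever-duration question existed) cannot be
  recovered from the published material and were not invented.
* The kappa p-value convention (Fleiss null SE, one-sided) reproduces the
  published non-significant p-values to within one printed unit, but the
  original analysis software was not specified, so p-values should be
  read qualitatively.
* Percentages reconstructed from printed tables inherit those tables'
  own one-ulp inconsistencies; the reconstruction reports per-statistic
  deviations rather than hiding them.
* The synthetic cohort is a marginal model; do not use it to estimate
  joint-symptom quantities.
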