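---
title: "De-labelling penicillin allergy from structured history: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-labelling penicillin allergy from structured history: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delabelr)
```

## The clinical problem

Up to a tenth of the population carries a penicillin-allergy label, but in
the large majority of tested patients hypersensitivity is excluded by
challenge testing. The label pushes prescribers toward broad-spectrum
alternatives, which is bad stewardship. Because formal allergy work-up
capacity is limited, history-based screens have been proposed that either
remove the label outright ("de-labelling") or flag the patient for an
alternative antibiotic. This package implements two such screens as
deterministic classifiers over structured history records, plus the
statistics needed to evaluate them against allergist-adjudicated ground
truth, and a synthetic cohort generator that reproduces the complete
outcome structure of an 800-patient allergy-clinic case series.

## The five-question algorithm

Each record answers five questions in a fixed order from coded fields; the
answers are tri-state (`yes` / `no` / `uncertain`):

1. **Q1 — not an allergy at all?** Complaints incompatible with allergic
   hypersensitivity (isolated abdominal pain, palpitation, headache), or an
   onset clearly too late: urticaria starting more than 2 days, or
   exanthema more than 1 week, after last intake. `yes` → de-label.
2. **Q2 — childhood rash without systemic symptoms?** Such rashes are
   almost always infection-related. `yes` → de-label.
3. **Q3 — prolonged urticaria without systemic signs?** Including episodes
   recurring days after stopping treatment. `yes` → de-label.
4. **Q4 — maculopapular exanthema in adulthood, in timely relation to
   intake?** The most common true delayed reaction; bothersome though not
   severe, so the recommendation is cautious: `yes` → alternative
   antibiotic.
5. **Q5 — any indicator of a severe reaction?** Onset within minutes,
   cardiovascular or respiratory signs, an incident during general
   anesthesia, mucosal erosions, cutaneous blisters, hepatitis, nephritis,
   or a sudden drop of blood cell numbers. `yes` → alternative antibiotic,
   otherwise de-label.

Questions 1–4 route any `no` **or `uncertain`** answer onward, so missing
information can never produce a definitive `yes`; only a positively
documented driver can. The outcome is binary and every decision carries its
answer trace, so each case is attributable to exactly one deciding question.

Two semantics were genuinely open and are resolved as follows:

* **Uncertain at Q5 de-labels.** The published per-question counts admit no
  third outcome at Q5, and the question's role is to *find* severe-reaction
  evidence: when none is documented, the case is treated as low risk. This
  is the algorithm's residual-risk locus — in this package an empty
  indicator set answers `no` outright, and `validate_histories()` ensures
  the set is well-formed rather than silently absent.
* **Adulthood threshold.** Q2 requires the rash to have occurred in
  childhood or adolescence; no numeric cutoff is published. We use
  age at reaction ≥ 18 years as adulthood, the conventional bound, and
  expose it as `adult_threshold` in `evaluate_question()` and
  `apply_algorithm()`. An adult age overrides a `yes` on the childhood-rash
  field; an unknown age does not (the field itself asserts the timing).

`onset_within_minutes` appears both as a severe-indicator flag (driving Q5)
and implicitly in the latency code `minutes`; only the flag drives Q5 and
only the latency enum drives Q1's late-onset arm, so the two cannot
interfere.

## PEN-FAST

PEN-FAST is scored from four items: **F** five years or less since the
reaction (2 points), **A** anaphylaxis or angioedema (2 points), **S**
severe cutaneous adverse reaction (2 points), **T** treatment required
(1 point); a total below 3 is low risk. The implementation follows this
item list as published in the case-series report, which implies a maximum
of 7 points; the original PEN-FAST derivation combines the A and S items
differently (maximum 5). The discrepancy is documented here rather than
resolved — the package models the rule as the comparison study describes
it. An undocumented item scores 0: the score is a bedside screen and an
absent feature cannot add risk; `known_items` in the output lets callers
audit how much of a score rests on documented answers.

## Accuracy statistics

"Positive" means the rule flags possible allergy (alternative antibiotic /
not low risk), so sensitivity is the proportion of proven-allergic cases
referred, and specificity the proportion of non-allergic cases de-labelled.
`metrics()` reports sensitivity, specificity, PPV, NPV and prevalence with
two-sided binomial confidence intervals. The source study reports no
interval estimates; the intervals are this package's addition, and the
Wilson score method is the default because several strata are small (n = 3)
and Wald intervals degenerate there. The method and level are
configurable. A metric with a zero denominator is reported as `NA`, never
an error. Display rounding is half-up to one decimal on the percent scale,
matching the convention of the printed tables (base `round()` would turn
94.05 into 94.0 rather than 94.1).

`prevalence_adjusted()` projects predictive values onto another
population's prevalence via Bayes' theorem,

$$PPV = \frac{se\,p}{se\,p + (1-sp)(1-p)}, \qquad
  NPV = \frac{sp\,(1-p)}{sp\,(1-p) + (1-se)\,p},$$

and coincides exactly with the count-based PPV/NPV at a cohort's own
prevalence — a numerical identity the test suite checks to 1e-12. The
study is descriptive and single-threshold, so no multiple-testing
correction and no ROC machinery are provided.

## The synthetic cohort generator

The published outcome structure is complete: the 2×2 table, the
per-question routing counts for allergic and non-allergic cases, the
per-stratum referral splits (anaphylaxis mild/moderate/severe 26/27/17;
delayed MPE/SDRIFE/FDE/DRESS 117/12/3/3), and the cohort descriptor
marginals (reported reaction type 334/421/45 with culprit class, route and
recall interval conditional on type). `generate_fixture()` therefore
constructs an 800-record cohort cell by cell so that classification
reproduces every printed count exactly, and verifies itself by re-routing
each record and failing loudly on any mismatch. What the published tables
do **not** pin down, the generator fixes by documented convention:

* **Question assignment of the 21 incorrect de-labellings within strata.**
  The totals per question (3/2/6 at Q1–Q3, 10 at Q5) and per stratum
  (mild 7, moderate 1, MPE 11, SDRIFE 2) are published, their joint is
  not; one consistent split is hard-coded (see `fixture_cells()`).
* **Descriptor × outcome joint.** Only marginals are published; descriptors
  are laid over the outcome cells by a deterministic low-discrepancy
  interleave, i.e. modelled independent of routing.
* **Severe-indicator flags.** Anaphylaxis records cycle immediate-onset and
  systemic-sign flags; FDE records carry cutaneous blistering (one
  hepatitis), DRESS records hepatitis/nephritis, matching the triggers the
  study names; the 70 non-allergic records referred at Q5 cycle the full
  indicator list, emulating "complaints incorrectly interpreted as severe".
* **Ages.** Not reported; childhood-rash records cycle ages 3–16, all
  others 20–79. Non-inferential scaffolding only.
* **PEN-FAST items.** The study never scores its own cohort, so item fields
  are derived from the latent stratum: recall ≤ 5 years ⇒ F; an
  immediate-type diagnosis or systemic-sign flags ⇒ A; FDE/DRESS or
  blistering/erosions ⇒ S; moderate-to-severe anaphylaxis or DRESS ⇒ T.
  A modelling choice, clearly not study data.

`generate_stochastic()` draws outcome cells multinomially from
`cohort_spec()` weights (defaults: the fixture counts normalized by 800)
and descriptors from the conditional marginals, all from a single seed set
once at entry, so a fixed seed reproduces a cohort exactly and the caller's
RNG state is restored afterwards. Attribute bundles within a cell come from
the same deterministic constructor as the fixture, so generated records
always route to their drawn cell.

**What passing tests show, and what they do not.** The generator emulates
the published joint distribution of ground truth and routing — by
construction. Reproducing the printed accuracy figures from the fixture
validates the classifiers, the counting, and the statistics, not the
clinical performance of the questions on free-text real-world histories:
the hard step of mapping a narrative to the coded fields is upstream of
this package and is exactly where inter-rater disagreement would live.

## Problem sizes and numerical choices

The fixture pipeline (800 records) runs in well under a second. The
law-of-large-numbers check on the stochastic generator uses n = 80,000
records against a 3-standard-error band on the non-allergic fraction, and
the confidence-interval coverage check uses 800 simulated binomial draws at
the sensitivity operating point (n = 205) with a 4-standard-error
Monte-Carlo band; both sizes keep the default test run in seconds while
leaving negligible flake probability at fixed seeds. Wilson intervals are
computed via `prop.test(correct = FALSE)`, whose interval is exactly the
score interval; the suite cross-checks it against the closed-form formula.
Tri-state file encoding uses literal `yes`/`no`/`uncertain` strings, with
blank meaning "no information" — mapped to `uncertain` for question inputs
and `unknown`/`unclear`/`NA` for factual fields — so that hand-edited CSVs
fail safe rather than de-label.

## Known limitations

* Free-text histories, EHR/FHIR ingestion and the downstream supervised
  re-administration pathway are out of scope; inputs are coded fields.
* The fixture's within-stratum question assignment and all descriptor
  joints are conventions (above), so analyses of *joints* the study did
  not publish reflect the generator, not the study.
* PEN-FAST results on generated cohorts inherit the item-derivation
  convention and should not be read as a validation of PEN-FAST.
* Severe bullous reactions of the SJS/TEN spectrum do not occur in the
  cohort the generator emulates.

## A worked run

```{r}
rep <- reproduce_paper(quiet = TRUE)
rep$ok
cat(rep$table, sep = "\n")
rep$headline
```
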