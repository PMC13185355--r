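---
title: "A medication-based algorithm for Parkinson's disease in EHR data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A medication-based algorithm for Parkinson's disease in EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmedalg)
library(dplyr)
```

## The problem and the model

Medication-purchase records are a robust signal for Parkinson's disease (PD)
in insurance registries: pharmacologic treatment is near-universal in PD,
purchases are recorded for administrative (billing) purposes, and — in
systems with universal drug coverage — patients rarely buy antiparkinsonian
medication (APM) outside their insurer. The algorithm in this package turns
that signal into a case definition with three layers:

1. **Inclusion.** At least two APM purchase *occasions* (distinct calendar
   dates — same-day multi-drug dispensing is one clinical event), insurance
   coverage at the first purchase date (FPD), FPD after 2004-12-31, and age
   25–100 at the FPD. Two occasions, not one, because prescriptions are
   dispensed for at most three months, so two purchases witness roughly six
   months of use; a higher floor would drop patients near the start of
   treatment, who are instead caught by the certainty tier below.
2. **Exclusion.** Fourteen criteria remove the alternative indications of
   APM: dopamine agonists for hyperprolactinemia, pituitary adenoma, and
   postpartum lactation suppression; dopaminergics after hydrocephalus,
   anoxic brain injury, or traumatic brain injury with coma; atypical
   parkinsonism (PSP/MSA/CBD) or restless-legs syndrome never followed by a
   PD diagnosis; drug-induced parkinsonism (antipsychotic purchase in the
   year before the FPD, unless the patient both purchased levodopa and
   carries a PD diagnosis — that combination marks a psychiatric patient who
   truly has PD); prolonged *exclusive* MAO-inhibitor or amantadine use
   without a PD diagnosis; long-term APM with recorded recurrent falls,
   lethargy or general deterioration; and purchase streams too short and too
   abandoned to be consistent with a progressive disease.
3. **Certainty.** Included, non-excluded patients are *possible* PD if any
   of four weakness flags fire (never PD-diagnosed; under two years between
   the FPD and the end of observation; over three years of APM but more than
   two years since the last purchase; antipsychotic use in the year before
   the FPD together with levodopa and a PD diagnosis), and *probable*
   otherwise.

The **index date** — the analysis-ready onset surrogate — is the earlier of
the FPD and the first PD diagnosis. Two exceptions: patients with a
hyperprolactinemia/pituitary diagnosis before the FPD take the *later* of
FPD and PD-diagnosis date (their early agonist purchases reflect the
endocrine indication), and patients with an anticholinergic purchase in the
year before the FPD take the earliest of the first anticholinergic purchase
and the PD diagnosis date (anticholinergics can precede other APM as early
symptomatic treatment).

## Temporal conventions

The source rules name windows in words; the engine needs days. All
conversions live in one place (the codebook) and are configurable:
one month = 30 d, six months = 183 d, N years = round-half-up(N × 365.25)
(so 1 y = 365 d, 2 y = 731 d, 3 y = 1096 d, 5 y = 1826 d). "The year prior
to the FPD" is `[FPD − 365, FPD)`; "up to one month after" is
`(FPD, FPD + 30]`; the functional-decline window is the closed interval
`[FPD − 365, FPD + 1826]`. Elapsed-time clauses ("more than one year since
the last purchase") are measured to the patient's *observation end* — the
earliest of death, HMO exit (last insurance end) and the data-extraction
date — not to the extraction date itself, so early leavers are not
penalised. Age is completed years (floor).

Several printed rules needed a reading decision, recorded here as the
package's own choices:

* **Exclusive-monotherapy thresholds.** The two printed bullets ("more than
  20 purchases or duration over 5 years"; "more than 8 purchases or duration
  over 2 years") are treated as alternative sufficient conditions (logical
  OR), which makes the 8-purchase/2-year bullet binding. Both thresholds are
  config-exposed.
* **The psychiatric-rescue flag.** The possible-PD criterion pairing
  antipsychotic and levodopa purchases is worded as if both fell in the year
  before the FPD; levodopa is itself an APM, so a levodopa purchase cannot
  precede the FPD. Implemented as: PD diagnosis present, antipsychotic
  purchase in `[FPD − 365, FPD)`, and at least one levodopa purchase at any
  time — the exact complement of the drug-induced-parkinsonism exclusion's
  rescue clause.
* **Atypical-parkinsonism rescue.** "A subsequent PD diagnosis following the
  last such diagnosis" means strictly later; a same-day tie does not rescue
  (strictness favours specificity).
* **Index-date exception precedence.** When both exceptions apply the
  pituitary rule wins (it is the more specific indication correction);
  switchable in the codebook.
* **"Exclusively purchased X"** is evaluated over APM purchases only;
  non-APM drugs never break exclusivity.
* The short-span/three-year-gap exclusion carries no "never diagnosed with
  PD" clause (unlike its two-year sibling), and none is imposed.
* Whether anticholinergics count toward inclusion is not fixed by the rules;
  the default codebook excludes them from the inclusion classes (they enter
  only through the index-date exception) and includes COMT inhibitors.
  `inclusion_classes` switches either choice.

## The codebook

The exact ATC-5 list behind the original algorithm is not public. The
default codebook reconstructs it from the ATC N04 group — levodopa
(N04BA01–03), dopamine agonists (N04BC), MAO-B inhibitors (N04BD),
amantadine (N04BB01), COMT inhibitors (N04BX), anticholinergics (N04AA) —
plus a standard N05A antipsychotic set with the quetiapine dose carve-out
(≤ 50 mg not counted; missing strength counts as above threshold by default,
conservative toward exclusion). Diagnosis sets are dot-insensitive ICD-10
prefixes (K59 matches K59.0 and K590), because registries mix 3- and
4-character codes. Every set and threshold can be replaced via a YAML config
(`read_codebook()`). One oddity is kept deliberately: the "tremor NOS" label
maps to R52.1 as printed in the source coding list, although R25.1 is the
usual tremor-NOS code; users with conventional coding should override it.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws patients from archetypes: textbook PD
(quarterly refills with ±20-day jitter, escalation from MAO-B/agonist
monotherapy to levodopa, a PD diagnosis near treatment start with a
configurable neurologist share), one variant per possible-PD flag, one
confounder archetype per exclusion criterion (e.g. a young woman with a
birth record and exclusive agonist use for the postpartum rule), and
never/barely-treated mimics. Defaults: a 2005–2025 horizon, onset ages
N(72, 8.5) truncated to 40–95, 55% male, 90-day refill cadence (the
three-month prescription ceiling), escalation probability 0.9, and an
embedded incidence decline of −4.47%/year in the population module. Each
patient is generated on an RNG substream derived from `(seed, patient
index)`, so adding patients or editing one archetype never reshuffles the
others, and a fixed seed reproduces the CSVs byte for byte.

The archetypes are generated *cleanly*: each satisfies its target criterion
and, by construction, no other. That is what makes the routing and
oracle-equivalence tests sharp — and it is also the generator's main
departure from real data, where patients fire several criteria at once,
codes are missing or wrong, and treatment gaps have benign causes. Passing
tests therefore demonstrate that the engine implements the stated rules
exactly and that the statistics recover planted truths; they do not
demonstrate field performance on a real registry, which requires local
validation. The mixed-scenario sensitivity/specificity check is a
qualitative mirror of that logic (thresholds 0.90/0.85), not a reproduction
of any registry estimate.

The prodromal module plants diagnosis codes year by year around the index
date: controls at a per-code annual baseline, cases at baseline × a
rate-ratio schedule that ramps linearly from 1 at the divergence-onset
offset to its maximum in the final pre-index year (smoking-related codes use
a constant protective ratio < 1). The default effect sizes are illustrative,
not calibrated claims.

## Statistical components

* **Proportion CIs.** Wilson score intervals are the default for all
  reported proportions; exact Clopper–Pearson intervals (beta-quantile
  inversion of the binomial CDF) are available everywhere. For the
  129-patient-scale validation cohorts the two disagree in the second
  decimal of the bounds, so reports can print both. Percentages are
  displayed half-up to one decimal.
* **Incidence.** A case enters the year and decadal age group
  ([20–40), [40–50), …, [90–100)) of its index date; denominators are annual
  insured-population counts treated as person-time. Cell CIs are exact
  Poisson (Garwood) intervals from chi-square quantiles. Direct
  standardization uses the WHO world standard population (5-year bands,
  embedded as a versioned constant, renormalized to sum exactly to 1), with
  an age ≥ 20 variant truncated and renormalized; the AAIR variance is the
  weighted sum of independent Poisson band variances.
* **Trends.** Incidence: log-linear Poisson regression of yearly counts on
  continuous calendar year with a log-population offset; when the residual
  deviance/df ratio exceeds 1 (configurable) the model is refitted as
  quasi-Poisson, scaling the standard errors. Prevalence: binomial
  regression weighted by population through the binomial denominator, log
  link by default so the year coefficient transforms directly to an annual
  percent change, APC = 100·(e^β − 1), with Wald limits on β. Prevalent
  cases persist until death or exit (no remission); a patient dying mid-year
  counts in that year.
* **Matching.** Exact on sex and age ± 1 completed year at the case's index
  date, controls alive at that date with at least the case's follow-up,
  selected without replacement in seeded random case order. Coarse exact
  matching on ethnicity/sector columns is available through `balance_keys`;
  a propensity model is deliberately not the default because its
  specification would be arbitrary and exact matching is reproducible.
* **Year-offset prevalence.** Offset k covers days `[k·365, (k+1)·365)`
  before the index date (offset 0 = the final pre-index year, down to −17).
  Denominators count subjects whose data start precedes the window's end, so
  they shrink with depth. Group comparisons are uncorrected Pearson
  chi-squared tests with Wald CIs on the proportion difference;
  Benjamini–Hochberg FDR correction is applied within each diagnosis code's
  family of offsets (per code × stratum in stratified runs). The family
  choice matters and is configurable by running codes separately; a global
  family would be more conservative at the deep offsets.

One testing note on FDR localization: BH controls the expected false
discovery *rate*, not the family-wise error, so with a strong planted
divergence at offsets ≥ −10 a small fraction of pre-divergence offsets is
expected to reach adjusted significance. The calibration test therefore
requires all planted offsets detected and the pre-divergence discovery share
near the nominal rate, rather than exactly zero early hits.

## Problem sizes and numerical choices

The bundled test suite runs the engine-vs-transcription equivalence on 1,000
mixed-archetype patients, archetype routing at 50 patients per criterion,
the mixed scenario at 5,000 patients, APC recovery over 500 simulated
20-year series at ~4-million-person denominators, Wilson coverage over
10,000 binomial replicates, and the pre-diagnostic pipeline at 600 matched
cases — sizes chosen to keep Monte-Carlo error well inside the asserted
bounds on a single CPU. Degenerate inputs are defined, not errors: zero
patients classify to an empty table, zero counts give a Poisson lower bound
of 0 and a Wilson lower bound of 0, empty matching pools warn and return no
matches, and zero denominators flag comparisons as skipped.

## Known limitations

The engine assumes one insurer's complete purchase stream; multi-payer
reconciliation, ICD-9 history, and probabilistic/ML phenotyping are out of
scope. The default codebook is a reconstruction, not the original list. The
synthetic generator does not attempt realistic demographic composition,
comorbidity correlation, or coding noise beyond what the archetypes need.
Early-stage patients not yet treated are invisible to a medication-based
definition by construction; estimates derived from it are conservative in
that respect.
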