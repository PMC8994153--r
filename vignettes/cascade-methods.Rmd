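---
title: "Methods: an inpatient-adapted cascade of diabetes care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an inpatient-adapted cascade of diabetes care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The cascade of care is a population-level staging of chronic-disease
management: of everyone *diagnosed*, how many are *linked to care*, and how
many of those reach *disease control*. The classical diabetes cascade is an
outpatient construct (primary-care follow-up, composite quality targets).
`dmcascade` implements an inpatient-only adaptation driven entirely by
hospital EHR events, because inpatient records reliably capture only a
subset of the outpatient definition:

* **Diagnosed** — a type 2 diabetes code (ICD-10 `E11.xx`) on the problem
  list of an admission, with the patient's *first* such problem-list entry
  falling within one day of an admission interval (the index admission).
  Gestational diabetes (`O24.xx`) and type 1 (`E10.xx`) carriers are
  excluded first.
* **Linked to care** — any prescription of an anti-diabetes medication
  (insulin, a noninsulin injectable, or an oral agent) within 90 days of
  the index discharge.
* **Controlled** — the follow-up HbA1c (latest value in the 180 days after
  discharge) at or below an individualized target:

  | age band | no complications/CVD | complications or CVD |
  |----------|----------------------|----------------------|
  | < 65     | 7.0 %                | 8.0 %                |
  | ≥ 65     | 7.5 %                | 8.5 %                |

  Patients with no follow-up value form an explicit third *missing* state —
  in inpatient-only data this is the largest control-arm category, and the
  package treats it as a first-class outcome rather than dropping it.

Alongside the cascade, three inpatient glycemic-care markers are computed
per index admission: HbA1c measured within 24 hours of admission, insulin
lispro *administered* within 24 hours, and a diabetes/endocrinology consult
at any point during the stay.

## Decisions on under-specified rules

Several rules in the source description admit more than one reading. The
package fixes each one explicitly, in one place, so a different reading is
a one-argument or one-function change:

* **Window conventions.** "3 months" is 90 days, closed on both ends: a
  prescription dated at the discharge instant counts (discharge
  prescriptions are the mechanism the cascade is about). "6 months" is 180
  days, *half-open*, excluding the discharge instant: an inpatient HbA1c
  drawn during the stay is not follow-up. Marker windows are closed and
  24 hours means exactly 86,400 s. "Within a day of diagnosis" for index
  anchoring is a ±1 calendar-day widening of the admission interval.
* **Control definition.** The source text first summarizes control as an
  HbA1c "between 7% and 8.5%" and then gives the individualized ≤ targets.
  The individualized inclusive thresholds are implemented as the operative
  definition (they match the outpatient cascade this one adapts); no lower
  bound is applied. Comparisons happen on tenths of a percent as integers,
  after round-half-up to one decimal, so 7.0 against a 7.0 target is
  controlled regardless of floating-point representation.
* **Follow-up selection.** Whether the study used the latest, the closest
  to 180 days, or any in-window value is unstated; the package uses
  *latest in window*, isolated in `select_followup_a1c()`. Ties at the
  single latest timestamp average with a warning.
* **Exclusion precedence.** Gestational before type 1, each patient
  excluded exactly once by the first matching rule. The published counts
  look disjoint but state no precedence; the tally conserves under any
  overlap either way.
* **Complication lookback.** Complication (`E11.2`–`E11.8`) and CVD
  (`I20`/`I21`/`I22`/`I50`) codes qualify if recorded on or before the
  index discharge; later diagnoses never retroactively change a target.
* **Insurance mapping.** Medicare > Medicaid > private > uninsured/self-pay.
  A label is "uninsured" only when it carries no other payer signal, so a
  mixed "Commercial + Self-pay" label is private; a genuinely absent label
  is `missing` (the descriptive tables report a handful of such patients,
  so missing cannot be folded into uninsured).
* **Age.** Completed years at the index admission; birthdays during the
  stay never move a stratum. Patients with unknown birth dates get the
  `missing` age group and are routed around target assignment with
  `control_status = "missing"`.

## The test statistic

Stage comparisons use the pooled two-sample z test of equal proportions:
\(z = (\hat p_1 - \hat p_2)/\sqrt{\bar p(1-\bar p)(1/n_1 + 1/n_2)}\) with
\(\bar p\) the pooled proportion; \(z^2\) is exactly the 1-df Pearson
chi-square of the corresponding 2×2 table, which the suite verifies against
`chisq.test()` on random tables. The continuity correction is off by
default — that choice, not the corrected variant, reproduces the published
p-values — and no multiplicity adjustment is applied by default, mirroring
the source analysis; both are flags. One caveat is inherited deliberately:
the diagnosed-vs-linked comparison treats the two stages as independent
samples although the linked cohort is nested in the diagnosed one. The
package replicates that choice because its purpose is to reproduce the
published inference; the nesting makes the printed p-values conservative
in a direction that is easy to reason about but not what a de-novo
analysis would do.

## The synthetic generator

`simulate_ehr()` emits the six event tables of a cohort whose *stated
world* is the published study's margins, as generator defaults: exclusion
fractions 3,875/93,433 (gestational) and 7,925/93,433 (type 1); sex, race,
age-group and insurance marginals at the published diagnosed-cohort
proportions; Promise Zone residence 17.5%; linkage 0.352; marker rates
0.274 / 0.725 / 0.061; follow-up missingness 0.609 (linked) and 0.756
(unlinked), which jointly reproduce the 70.4% overall missingness.
Quantities the study does not print are fixed once at realistic values for
an older inpatient type 2 diabetes population and not tuned: complication
prevalence 0.40, CVD prevalence 0.25, HbA1c lognormal with median 7.5% and
log-sd 0.2 (values rounded to one decimal at generation, matching the
classifier's comparison precision), admission length uniform on 2–10 days,
admissions uniform over 2010–2019.

Strata and outcomes are independent by default because only marginals are
published; `p_linkage_promise_zone` exists to inject a stratum-conditional
linkage effect for property tests. What a green test on synthetic data
establishes is therefore *mechanical correctness* — windows, precedence,
denominators, conservation, parameter recovery within binomial error — not
that the generator reproduces the study's joint distributions or its
disparities. Real EHR features the generator deliberately omits: multiple
admissions per patient, ICD-9-era coding, order-vs-fill ambiguity in
prescriptions, informative missingness, and any correlation between
markers and linkage.

The deterministic `generate_exclusion_fixture()` is separate from the
stochastic generator: exactly 93,433 patients with exactly 3,875 `O24.xx`
and 7,925 `E10.xx` carriers, so the exclusion funnel's published endpoint
(81,633) is an exact, seed-free check.

## The published-count fixture and its inconsistencies

`inst/extdata/published_counts.json` transcribes the published aggregate
counts (funnel, flow, stratified table, significance marks). At load time
every cell's printed percent is recomputed from its count and stage
denominator. 98 of 114 cells reproduce bit-exactly; 16 do not, and the
loader flags rather than hides them:

* five zero cells printed as "0" where the package convention prints
  "<1.0";
* the uncontrolled-arm insurance block, whose printed counts sum to 2,969
  against the stated arm total of 4,148 but whose percents are internally
  consistent with 2,969 — a denominator slip in the source;
* the Promise Zone control-arm percents and the race controlled column
  (which sums to 7,121, not 7,076), consistent with no stage denominator;
* four isolated one-tenth rounding slips.

One count is amended in the fixture (with the printed value preserved in a
note): the age 18–44 unlinked cell prints 2,924 where 3,924 restores both
the column sum (52,917) and the printed 7.4%. The descriptive table's
age/insurance "missing n=4" rows are not encoded because the non-missing
categories already sum exactly to 81,633. The abstract's "n=6789"
uninsured count is transcribed as 6,798, the value consistent with the
table column sums.

## Numerical conventions

Percent strings round half up at one decimal, with "<1.0" after rounding;
p-values format as two decimals without a leading zero, "<.001" below
.001. Degenerate pooled proportions (0 or 1) return z = 0, p = 1, flagged.
HbA1c values outside (3, 20)% are treated as recording artifacts: counted
and warned about, excluded from follow-up selection, never silently
deleted from the tables. Index-admission ties resolve by earliest
admission start, then lexicographically smallest admission identifier.
Empty stages (e.g. a cohort with nobody controlled) render `NA` percents
rather than dividing by zero. All timestamps are timezone-naive UTC.

## Known limitations

Inpatient-only linkage underestimates true linkage (outpatient
prescriptions are invisible), and missing follow-up HbA1c dominates the
control arms, so control-stage conclusions are fragile — this is a finding
of the adaptation, not a defect the package can fix. The generator's
independence assumptions mean synthetic joint cells should never be read
as estimates of the study's joint cells. The medication map is a shipped
default, not the study's (unpublished) formulary appendix; both the map
and every code set are user-overridable through `code_config()`.
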