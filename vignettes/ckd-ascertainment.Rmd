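---
title: "Ascertaining chronic kidney disease from administrative registries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ascertaining chronic kidney disease from administrative registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdprev)
```

## The problem and the approach

Chronic kidney disease is mostly silent until late stages, so
population prevalence measured from laboratory surveys (eGFR,
albuminuria) is expensive and limited to sampled areas. Administrative
health data — hospital discharges, exemptions, outpatient services,
drug dispensings — cover an entire resident population and can be
linked person by person through a pseudonymous identifier. `ckdprev`
implements a rule-based classifier over four such registries: a person
is a prevalent case at the prevalence date if at least one source shows
CKD-specific care during a multi-year selection window, subject to
exclusions that remove acute renal failure, the deceased and
out-migrants.

The trade-off is intrinsic: claims capture *care seeking*, not
glomerular filtration, so milder CKD that never reaches a nephrologist
is invisible, and the resulting prevalence is a lower bound
concentrated on clinically manifest disease. The package's severity
split (below) exists precisely to separate the unambiguous end of the
spectrum (dialysis, transplant, stage ≥ IV, late-stage drugs) from the
rest.

## Data model and conventions

One CSV per registry, linked by `person_id`. Choices a user should
know, all testable at the boundaries:

- **Dates** are ISO 8601 throughout.
- **Residence intervals** are half-open `[start, end)`: a person is
  resident on the start date, not on the end date. An exemption with
  `end_date` equal to the prevalence date is likewise *not* active.
- **Window membership** is inclusive on both ends and anchored on
  discharge date (HDR), service date (OSSIS) and dispensing date
  (PHARM); TER is judged by activity at the prevalence date, not by
  window overlap, so an exemption registered before the window still
  counts if still active.
- **"Died during the period"** means `death_date <= prevalence_date`.
- Invalid rows (discharge before admission, malformed ATC, overlapping
  residence intervals, …) abort the read with row numbers; a `lenient`
  flag downgrades this to skip-with-warning.

## Code matching

Codes are normalized (dots and whitespace removed, uppercased), so
"585.4" and "5854" are the same code. A catalogue pattern may end in a
run of `X` ("585.XX", "55.6X"): the trailing run matches any —
including empty — extension of the stem. The bare stem matches because
ICD-9-CM has 3-digit codes without a fourth digit; prefix semantics is
the standard claims-research reading. An `X` *inside* a code (ATC
"B03XA01") is literal. Wildcard-free patterns require exact equality.
Nephrology visits additionally require specialty branch 29; records
without a branch value do not qualify as visits.

The shipped catalogue is frozen by an exhaustive content test; it can
be exported/extended as YAML (`write_catalog()` / `read_catalog()`).

## The ascertainment rules and their ambiguities

Two readings of the outpatient/drug confirmation rule are defensible.
The implemented default (`ossis_rule = "with_standalone_pharm"`) is:

- OSSIS: ≥ 2 nephrology visits on distinct dates, or 1 visit +
  urine-albumin measurement, or 1 visit + listed drug;
- PHARM: ≥ 1 listed dispensing qualifies *on its own*.

The standalone drug pathway is required for drug-only cases to exist
at all, and exclusive drug-source cases are in fact observed in
contribution accounting; the stricter visit-confirmation-only parse
remains selectable (`"confirmation_only"`). Similarly, dialysis-related
outpatient services qualify directly without visit confirmation
(`ossis_dialysis_standalone = TRUE`): dialysis is unambiguous CKD care.
Same-day duplicate visits count once — they are billing artifacts, not
clinical encounters.

The acute-renal-failure exclusion is applied *per record*: a
hospitalization is eliminated when its only qualifying evidence is
procedure 39.95/38.95 and a 584.XX diagnosis is present. A person
survives if any other record, in any source, qualifies — the literal
reading of a rule about records, not persons. An eliminated record also
contributes no dialysis evidence to severity or validation:
consistency with the rule's purpose of dropping acute dialysis.

## Severity

Higher severity requires, within the window: dialysis evidence
(HDR procedures 39.95, 54.98, 39.27, 54.93, 39.42, 39.43, 38.95 on a
surviving record, or an OSSIS dialysis-related service), transplant
evidence (55.6X, V42.0, exemption 025.V42.0, packages P585B/PV420), a
stage ≥ IV diagnosis (585.4X/585.5X/585.6X), or any listed drug. Kidney
biopsy (55.23) qualifies a hospitalization but is deliberately *not*
severity evidence — it is a diagnostic act, not renal replacement or
late-stage care. A consequence worth noting: every drug-exclusive case
is higher severity by construction. Classification is idempotent and
monotone — adding records without severity evidence can never demote a
case.

## Rates, intervals, standardization

Rates are per 100 population; the denominator is residents alive at
the prevalence date. The published interval for the headline rate is
reproduced by the Wald interval on the proportion, which at
denominators in the millions is indistinguishable from exact methods;
`ci_method = "clopper-pearson"` exists for small strata. Direct
standardization weights stratum rates by a user-supplied reference
population (the appropriate national reference is distributed by the
statistics office and is not bundled); its default CI uses the
weighted sum of per-stratum binomial variances, with a Fay–Feuer-style
gamma interval for sparse strata. With weights proportional to the
study population itself, standardization reproduces the crude rate to
machine precision — a useful invariant and a test.

Printed-style rounding is half-away-from-zero (`round_half_up()`):
rates to 2 decimals, shares and validation metrics to 1, ratios to 2.
Male:female ratios are computed from unrounded rates. A metric with a
zero denominator (PPV of an empty detected set) is reported as
not-applicable rather than 0.

Validation uses the region-wide resident-alive population as the
true-negative denominator — the convention under which specificity of
a rare-condition classifier is quoted — with a cohort-only scope
available (`population_scope = "cohort"`).

## The synthetic generator

`generate_registries()` emulates the six registries with planted
ground truth. Defaults are fixed to the study conditions: the age/sex
structure and per-stratum case probabilities default to the published
regional stratum margins, the higher-severity fraction to 21.3%, and a
quarter of higher-severity cases are placed on dialysis — the dialysis
share within severe CKD is not published, and 25% is a realistic
resident ESRD share; it is configurable. The source-emission profile
(HDR 0.55, TER 0.25, OSSIS 0.65; PHARM 0.45 among higher-severity
cases) was chosen once to produce a mixture of single-source,
multi-source and all-source cases; no claim of calibration to the
published contribution surface is made.

Design points:

- Per-person substreams are keyed on `(seed, person index)`, so output
  is deterministic and growing `n_persons` never reshuffles existing
  persons.
- Every planted surviving case emits records that satisfy the rules in
  its selected sources; lower-severity cases never receive listed
  drugs, severity diagnoses or dialysis records, so planted labels are
  recoverable exactly on noise-free data.
- Noise channels inject exactly the patterns the algorithm must
  handle: acute-renal-failure admissions (absorbed by the exclusion),
  single unconfirmed visits, deaths/emigrations (legitimate
  exclusions, tracked in ground truth), background records with
  non-listed codes, and dialysis false positives/negatives for
  degrading the validation study in controlled amounts.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: realistic national demography
and drug-utilization patterns, miscoding and inter-provider coding
heterogeneity, linkage errors in the person identifier, registry lag,
or the care-seeking process that drives under-ascertainment of mild
CKD. Recovery of planted truth verifies the *algorithmic* correctness
of the rules, not the clinical accuracy of claims-based ascertainment.

## Verification strategy and problem sizes

Three independent lines of evidence, sized to run comfortably on one
CPU (the whole suite takes about three minutes):

1. **Arithmetic reproduction**: the published stratum grid (12 strata,
   99,457 cases over 5,636,510 residents), contribution shares and
   severity shares are re-derived from the printed counts cell by
   cell, including confidence bounds and ratios.
2. **Oracle equivalence**: 500 randomized 200-person instances, with
   all exclusion-noise channels active, are evaluated both by the
   pipeline and by a deliberately naive per-person, per-record,
   regex-based re-implementation kept in the test helpers; cohort,
   source sets, severity and dialysis sets must agree exactly.
3. **Planted recovery**: noise-free runs (1,000–1,500 persons at
   elevated stratum probabilities, so a few hundred cases) must
   recover the planted case set, severity labels and dialysis set
   exactly, with all four validation metrics at 100.0%; degraded runs
   must shift sensitivity/PPV by exactly the planted false-negative/
   false-positive counts.

## Known limitations

- Exact person identifiers are assumed; there is no probabilistic
  linkage.
- One prevalence date per run; no incidence, no trend series.
- The severity split is a pragmatic two-level proxy, not KDIGO
  staging, which requires laboratory values absent from claims.
- Real-data accuracy (the published validation of dialysis
  ascertainment, and standardized rates against the national
  reference) cannot be reproduced without the withheld person-level
  registries; the synthetic study substitutes property-based evidence.
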