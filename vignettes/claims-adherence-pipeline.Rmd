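---
title: "Adherence, persistence and costs from pharmacy claims: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adherence, persistence and costs from pharmacy claims: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Risdiplam is a daily oral disease-modifying therapy (DMT) for spinal
muscular atrophy (SMA). Because the drug is dispensed through pharmacies
with a recorded *days of supply*, administrative claims allow three
questions to be answered without any clinical instrument: how completely
patients keep drug on hand (**adherence**), how long they stay on therapy
before a terminal refill gap or a switch to another DMT
(**persistence**), and how all-cause health-care costs differ between
adherent and nonadherent patients (**cost burden**). `smaclaims`
implements that analysis as a tested pipeline over a minimal, documented
claims schema, together with a synthetic-claims generator so that every
stage can be validated against known ground truth — the real data source
for such analyses is a licensed commercial database that cannot be
redistributed.

```{r, eval = FALSE}
library(smaclaims)
res <- run_pipeline(simulate = sim_config(n_patients = 86, seed = 1),
                    out_dir = "report")
```

# Cohort selection

Patients enter the cohort if they have (1) at least one qualifying SMA
diagnosis code (ICD-10-CM G12.0, G12.1, G12.9) on a medical claim inside
the data window (2020-01-01 to 2022-06-30 by default); (2) an assignable
**index date** — the first risdiplam fill on or after the US approval
date, 2020-08-07; (3) at least 6 months of continuous enrollment after
index; and (4), for patients classified as SMA types 2–4, at least 3
months of continuous enrollment before index (infantile-onset type 1 is
exempt; so are patients matching no typing rule, by the same logic).
`select_cohort()` returns an auditable funnel: a log of counts after each
criterion, in order.

Numerical conventions, all configurable:

* months are fixed day counts — 3 months = 92 days, 6 months = 183 days —
  because a deterministic check cannot depend on an undefined "month";
* "continuous" enrollment tolerates a configurable gap (default 0 days;
  day-adjacent spans always merge);
* the study window runs from index to the earliest of enrollment end,
  data end, and index + 365 days, inclusive of the index day, so a
  window's length in days is `end - index + 1`. Ties are attributed in
  the order one-year cap, data end, enrollment end.

# SMA type classification

Claims-based SMA typing uses age at first SMA diagnosis, age at the end
of observed clinical activity, and severity markers (mechanical
ventilation, nutritional support, durable medical equipment, scoliosis
diagnoses). The published algorithms rest on proprietary code lists, so
the engine is the contract here, not the constants:
`classify_sma_type()` walks an ordered rule table
(`default_typing_rules()`, explicitly non-authoritative) and fires the
first rule whose age interval, age-at-end floor and marker logic are all
satisfied. Ages are exact day differences divided by 365.25. Users with
validated rule sets load them with `read_typing_rules()`. Patients
matching no rule are reported as unclassified rather than being forced
into a type.

# Adherence: proportion of days covered

The proportion of days covered (PDC) is the number of days in the study
window with drug on hand divided by the window length. Two conventions
matter and both are explicit in `build_coverage()`:

* **Stacking** (default `carry_forward = TRUE`): an early refill is
  banked — its effective supply starts the day after the previous supply
  is exhausted. This is the standard PDC convention; the alternative
  (each fill covers only its own calendar span, overlapping days counted
  once) is available via `carry_forward = FALSE` for sensitivity
  analysis.
* **Truncation**: supply extending past the window end never counts,
  applied after stacking.

The adherence threshold is PDC ≥ 0.80, and PDC bands are < 0.80,
0.80–< 0.90 and 0.90–1.00 (the top band closed at 1). Age groups use
completed years at index with two shipped presets ("methods": 0–2, 3–5,
6–17, ≥ 18; "results": 0–2, 3–5, 6–12, 13–17, ≥ 18).

The engine is validated two ways: worked interval fixtures, and exact
equivalence on a thousand random fill patterns against a brute-force
daily "pill stock" simulation written independently in the test suite.

# Persistence and the product-limit estimator

Discontinuation is the earlier of a refill gap — no fill within 30 days
after the stacked supply runs out, the event dated at the exhaustion day
(a gap of exactly 30 days is still allowable; 31 days is an event) — and
a switch, the first nusinersen or onasemnogene-abeparvovec claim after
index, which triggers the event even if risdiplam supply remains on
hand. Patients with neither event are censored at the window end. First
discontinuation is terminal: later resumptions do not re-enter.

`km_estimate()` is a from-scratch product-limit estimator:
\(S(t_i) = \prod_{j \le i} (1 - d_j / n_j)\) over distinct observed
times, censorings tied with events staying in the risk set at that time.
It is checked against hand-computed fixtures and against
`survival::survfit()` to 1e-12 on random datasets. The reported median is
the smallest observed time with \(S(t) \le 0.5\), "not reached"
otherwise. Confidence bands and hypothesis tests are out of scope: the
source analysis reports none.

# Costs

Per patient, claims inside the study window are bucketed: medical claims
by setting (inpatient, outpatient, emergency, other), with mechanical
ventilation and nutritional support accumulated as overlay subcategories
inside those buckets (they are deliberately excluded from the
setting-sum identity); non-risdiplam pharmacy fills as pharmacy costs.
DMT treatment costs — nusinersen/onasemnogene claims in medical data and
risdiplam fills in pharmacy data — contribute to no category at all.
Amounts are inflated to reference-year (2023) dollars by the ratio of a
health price index (the packaged `default_pce_index()` is an approximate
synthetic snapshot standing in for the official PCE Health Index series,
which the source does not print; supply the real series via
`inflation_index()`), then annualized to per-patient per-year (PPPY) by
dividing by `window_days / 365.25`. Patients whose raw study-period
total exceeds $4,000,000 are excluded as outliers before summarization.
Summaries use the sample SD (n−1; reported empty for a single patient)
and linearly interpolated quartiles (R quantile type 7) — the source
does not state a quantile method, so one is fixed and documented.

# The synthetic generator: what it does and does not establish

`generate_claims()` emits a bundle plus ground truth. Its *fixed* world
comes from the published cohort composition for this population: type
mix 1/18/47/20 of 86 patients, prior-nusinersen share 42/86 with 9 of 42
switching back, a single gene-therapy exposure, and per-type comorbidity
prevalences. Its *chosen-once* parameters are the refill process — 30-day
supplies, a per-type probability (0.05–0.20) of a late refill with
exponentially distributed extra gap days (mean 8–14), and a per-refill
stopping probability of 0.015, which together reproduce the published
marginals to first order (mean PDC ≈ 0.89, ≈ 80% adherent, ≈ 25%
discontinued within a year) — and log-normal cost amounts per service
category, with ventilation/nutrition costs attached only to severe types
so type-4 strata show zero medians. Decoy patients (10% per criterion by
default) each violate exactly one inclusion criterion, which is what
makes the selection funnel exactly auditable.

Determinism: every patient's draws come from a substream seeded by an
integer hash of (root seed, patient index), so insertion order can never
change a patient's data, and two runs with the same seed are
byte-identical through the entire report bundle.

What a green test establishes: the *mechanics* — interval stacking,
funnel ordering, risk-set bookkeeping, cost conservation, DMT exclusion
— are correct on data whose truth is known. What it does not establish:
agreement with the published cohort's printed numbers, which derive from
a proprietary database; realism of ICD code co-occurrence beyond what
the typing engine needs; billing noise, duplicate-claim pathologies or
coding error, which real claims have and this generator does not.

# Degenerate inputs and tie-breaks

* Empty bundles flow through every stage, producing header-only outputs
  and a full-length selection log of zeros.
* A one-day study window (index on the enrollment end date) is legal;
  PDC then is 0 or 1.
* A patient with no qualifying fill has no index date and exits at the
  funnel's second step, never later.
* Gap and switch candidates on the same day resolve to the gap.
* Exact duplicate claims are dropped at construction by default (the
  deduplication rule real multi-source extracts need); a flag disables
  it.

# Known limitations

The typing rule table and the comorbidity/inflation defaults are
documented stand-ins, not validated instruments. The pipeline performs
no inferential statistics by design. US Census region derivation from
state, vendor claim layouts, and dose-level (mg) adherence are out of
scope.
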