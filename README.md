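# smaclaims

Adherence, persistence and all-cause cost analysis for spinal muscular
atrophy (SMA) pharmacy-claims cohorts — a tested, reusable
implementation of the retrospective claims pipeline used to study
risdiplam, a daily oral disease-modifying therapy (DMT), with a
synthetic-claims generator standing in for the licensed databases such
analyses normally require.

## What it computes

For each patient in an administrative-claims bundle (enrollment spans,
medical claims with ICD-10-CM codes and allowed costs, pharmacy claims
with days of supply, demographics):

* **Cohort selection** — ≥1 SMA diagnosis (G12.0/G12.1/G12.9), index
  date = first risdiplam fill on/after 2020-08-07, ≥6 months post-index
  enrollment, ≥3 months pre-index enrollment for SMA types 2–4; study
  window = index to min(enrollment end, data end, index + 365 d), with
  an auditable exclusion funnel.
* **SMA type (1–4)** — a configurable rule engine over age at first
  diagnosis, age at end of clinical activity, and severity markers
  (ventilation, nutritional support, DME, scoliosis).
* **Adherence** — proportion of days covered (PDC): days with drug on
  hand (days-of-supply stacking with carry-forward banking, truncated at
  the window end) over window days; adherent iff PDC ≥ 0.80; bands
  <0.80, 0.80–<0.90, 0.90–1.00.
* **Persistence** — discontinuation at the earlier of a refill gap >30
  days after supply exhaustion (dated at exhaustion) or a switch to
  nusinersen / onasemnogene abeparvovec; Kaplan–Meier product-limit
  estimate S(t) = Π (1 − dᵢ/nᵢ) implemented from scratch, censoring at
  window end.
* **Costs** — per-category allowed costs (inpatient, outpatient, ED,
  other; ventilation/nutrition overlays; pharmacy) with DMT treatment
  costs excluded, inflated to 2023 USD, annualized to per-patient
  per-year (PPPY = raw / (window days / 365.25)), a >$4M outlier
  exclusion, and mean ± SD [median, IQR] summaries by adherence × type
  and by PDC band.

## Worked example

```r
library(smaclaims)
res <- run_pipeline(simulate = sim_config(n_patients = 86, seed = 1),
                    out_dir = "report")
s <- summarize_persistence(res$persistence)
sprintf("cohort %d | mean PDC %.3f | adherent %.1f%% | discontinued %.1f%%",
        nrow(res$cohort$windows), mean(res$adherence$pdc),
        100 * mean(res$adherence$adherent), s$pct_discontinued)
#> "cohort 86 | mean PDC 0.895 | adherent 81.4% | discontinued 24.4%"
read.csv("report/selection_log.csv")
#>               criterion n_remaining
#> 1          all_patients         113
#> 2         sma_diagnosis         104
#> 3 index_date_assignable          95
#> 4 post_index_enrollment          86
#> 5  pre_index_enrollment          86
read.csv("report/regimens.csv")
#>                       regimen  n       pct
#> 1            prior_nusinersen 35 40.697674
#> 2       risdiplam_monotherapy 43 50.000000
#> 3 prior_nusinersen_switchback  8  9.302326
```

The funnel shows the 113 generated patients (86 intended-includable plus
9 decoys per violated criterion) reduced to exactly the intended 86:
each decoy exits at the criterion it was constructed to violate. Mean
PDC 0.895 and 81.4% adherent are the pipeline's estimates on this seeded
synthetic cohort; the generator's defaults emulate the cohort structure
reported for this population (mean PDC 0.89, 83.7% adherent, ~21%
discontinuing within a year, 50% monotherapy). `report/` also contains
`table1.csv` (demographics/comorbidities by type), `table2.csv` (PDC by
type and age group), `table3.csv` (PPPY costs by adherence × type),
`km_curve.csv`, `pdc_band_costs.csv`, `patients.csv` and a
`manifest.json`.

A command-line wrapper is available:

```sh
Rscript -e 'smaclaims::claims_cli()' simulate --out bundle_dir --seed 7 --n 86
Rscript -e 'smaclaims::claims_cli()' run --bundle bundle_dir --out report
```

## Vignette

`vignettes/claims-adherence-pipeline.Rmd` documents the model,
conventions (stacking, truncation, tie-breaks), the synthetic world and
its limits, and every numerical default.
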