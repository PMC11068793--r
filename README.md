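# periodx

Deterministic, testable diagnosis of periodontal and peri-implant
conditions from full-mouth periodontal charts, under the 2017 AAP/EFP
classification — together with the statistical toolkit used to evaluate
clinical decision-support tools in paired control/test study designs.

The package is aimed at dental educators, clinical-decision-support
developers and biostatisticians who need (a) a reference implementation of
the classification logic that can be audited rule by rule, (b) labeled
synthetic charting data, and (c) reproducible diagnostic-accuracy and
power arithmetic.

## What is inside

* **Chart model and I/O** — per-tooth, per-site probing depth (PD) and
  signed recession in integer mm, bleeding on probing (BOP), suppuration,
  radiographic bone loss, furcation/mobility and finding flags; strict
  JSON and CSV dialects (`load_chart()`, `write_chart()`; the JSON schema
  ships in `inst/extdata/chart-schema.json`). Clinical attachment loss is
  CAL = PD + recession.
* **Classification engine** (`diagnose()`) — periodontitis case definition
  (interproximal CAL in ≥ 2 non-adjacent teeth, or buccal/lingual CAL
  ≥ 3 mm in ≥ 2 teeth), staging (severity from interdental CAL: 1–2 mm
  → I, 3–4 mm → II, ≥ 5 mm → III/IV; complexity shift-up at PD ≥ 6 mm,
  furcation ≥ II or vertical defects; stage IV by tooth loss, short
  dentition or masticatory dysfunction), grading (bone-loss%/age ratio
  bands 0.25 and 1.0 with upgrade-only smoking/diabetes modifiers),
  extent (30% cut-off, molar-incisor pattern), gingival status (BOP 10% /
  30%), peri-implant status, and six secondary-condition rules. Every
  fired rule is recorded in the report's rationale.
* **Question tree** (`build_default_tree()`, `traverse()`,
  `auto_answer()`) — a serializable Q&A graph over the same configured
  constants, provably equivalent to the engine on generated cohorts.
* **Synthetic cohorts** (`chart_for_diagnosis()`, `sample_cohort()`) —
  seeded rule-inversion generators reproducing the label and
  secondary-condition frequency structure of a 150-patient chairside
  cohort.
* **Study statistics** (`pool_row()`, `score_accuracy()`,
  `wilcoxon_signed_rank()`, `compare_conditions()`) — "n/n (%)" accuracy
  tables with pooled margins, incident-based secondary scoring, and an
  exact Wilcoxon matched-pairs signed-rank test (convolution null for
  n ≤ 25 without ties; tie-corrected normal approximation otherwise).
* **Power simulation** (`simulate_power()`, `power_curve()`,
  `min_n_for_power()`) — Monte-Carlo power of the exact two-sided paired
  test at α = 0.01 with paired differences ~ Normal(10, 10).

## Worked example

```r
library(periodx)

# a synthetic chart known to carry severe generalized disease, with a
# defective restoration on #19 and mobility on #30
ch <- chart_for_diagnosis("generalized periodontitis stage IV grade C",
                          seed = 42)
ch$teeth[["19"]]$flags <- "defective_restoration"
ch$teeth[["30"]]$mobility_class <- 2L

diagnose(ch)
#> <diagnosis_report> synth-42
#>   primary:   generalized periodontitis stage IV grade C
#>   secondary: occlusal_trauma (teeth 30)
#>   secondary: tooth_prosthesis_related_factors (teeth 19)
#>   treatment options:
#>    - Oral hygiene instruction and risk-factor control
#>    - Scaling and root planing (non-surgical periodontal therapy)
#>    - Periodontal re-evaluation in 4-6 weeks
#>    - Consider surgical therapy for residual pockets >= 5 mm
#>    - Supportive periodontal therapy at risk-based intervals
#>    - Occlusal analysis and selective adjustment; consider splinting mobile teeth
#>    - Correct or replace defective restorations; re-establish cleansable margins
```

The primary line reads: ≥ 30% of teeth show interdental attachment loss
(generalized), the worst interdental CAL is ≥ 5 mm with five teeth lost to
periodontitis (stage IV), and bone loss exceeds the patient's age in
percent per year (grade C). The two secondary findings come from the
mobility and restoration inputs; `report_to_json()` serializes the full
report including the fired-rule rationale.

Power of the study design behind such evaluations:

```r
cfg <- power_sim_config(reps = 10000, seed = 1)
simulate_power(16, cfg)
#> power at n=16: 0.8038 (SE 0.0040)
```

A command-line front end (`inst/cli/periodx`) wraps the same functions:
`diagnose`, `simulate`, `power`, `stats`, `validate`, `define` and an
interactive `interact` Q&A session.

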