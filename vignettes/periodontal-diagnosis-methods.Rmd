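---
title: "Methods: rule-based periodontal diagnosis, synthetic cohorts, and paired power simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based periodontal diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periodx)
```

## What the package models

periodx implements the 2017 AAP/EFP classification of periodontal and
peri-implant diseases as a deterministic rule engine over full-mouth
periodontal charts, plus the statistical machinery used in paired
control/test diagnostic-accuracy studies of clinical decision-support
tools: accuracy tables, the exact Wilcoxon matched-pairs signed-rank test,
and Monte-Carlo power simulation for that test.

A chart records, per tooth (Universal numbering 1–32) and per site (MB, B,
DB, ML, L, DL), the probing depth (PD, integer mm), signed recession
(positive when the gingival margin lies apical to the CEJ), bleeding on
probing and suppuration, together with tooth-level radiographic bone loss
(% of root length), furcation and mobility classes, and categorical finding
flags. Clinical attachment loss is derived as

$$\mathrm{CAL} = \mathrm{PD} + \mathrm{recession},$$

the standard clinical convention: a margin coronal to the CEJ (negative
recession) subtracts, so a shallow sulcus on an intact periodontium has
CAL at or below zero. Probing values are kept as integer millimetres
because periodontal probes read in 1 mm increments; this also makes every
threshold in the rule set exact rather than tolerance-dependent.

## The classification rules

All thresholds live in one versioned configuration object
(`clinical_config()`), shared by the engine and the question tree, so the
two surfaces cannot drift apart.

**Case definition.** A chart is a periodontitis case when interproximal
CAL (≥ 1 mm) is present on ≥ 2 non-adjacent teeth, or buccal/lingual CAL
≥ 3 mm on ≥ 2 teeth. Adjacency is consecutive Universal numbers within the
same arch; teeth 16 and 17 sit in different arches and are not adjacent.
The interdental rule takes precedence, and the evidence object records
which branch fired.

**Stage.** Severity comes from the worst interproximal CAL over affected
teeth: 1–2 mm → I, 3–4 mm → II, ≥ 5 mm → the III/IV band. Complexity
factors — any probing depth ≥ 6 mm, furcation involvement class II/III, or
a vertical bony defect — raise the stage to at least III regardless of CAL
severity: without this shift-up the deep-but-shallow-CAL presentations the
classification describes would be unreachable. Within the III/IV band,
stage IV requires dentition-level damage: ≥ 5 teeth lost to periodontitis,
< 20 remaining teeth, or masticatory dysfunction. A buccal/lingual-rule
case without interdental breakdown is staged from its worst buccal/lingual
CAL (a design choice; the severity bands are defined on interdental CAL
and the engine records the substitution in the rationale).

**Grade.** The indirect-evidence ratio is worst bone loss (%) divided by
age (years): < 0.25 → A, 0.25–1.0 (closed interval) → B, > 1.0 → C. Risk
modifiers only ever upgrade: smoking ≥ 10 cigarettes/day or HbA1c ≥ 7.0%
forces C; smoking 1–9/day or diagnosed diabetes below that HbA1c forces at
least B. Grading without any radiographic bone-loss reading is an error
rather than a default, since every case needs a grade and inventing one
would be clinically wrong.

**Extent.** Localized below 30% of scorable (present natural) teeth
affected, generalized at or above it. The molar-incisor pattern — affected
teeth confined to first/second molars and incisors, with at least one of
each — takes precedence over the percentage labels.

**Non-cases** split on the bleeding-site fraction: below 10% is clinical
gingival health, on an intact periodontium when there is no attachment
loss, bone loss, periodontal tooth loss or treatment history, otherwise on
a reduced one; at or above 10% is gingivitis (annotated localized to 30%,
generalized above it — the annotation travels in the rationale because
extent as a diagnosis component is reserved for periodontitis).

**Implants** are classified independently (health / mucositis /
peri-implantitis, keyed on bleeding/suppuration and the
progressive-bone-loss flag). For an implant-only dentition the worst
implant status becomes the chart's primary diagnosis; in a mixed dentition
the tooth-level diagnosis is primary and implant statuses are reported per
implant. The published material shows the implant route as a separate
branch without fixing this routing, so the package fixes it explicitly.

**Secondary findings** are pure lookups and thresholds over explicit chart
inputs: restorative/anatomical flags → tooth- and prosthesis-related
factors; fremitus, widened PDL or mobility ≥ 2 → occlusal trauma; site
recession ≥ 2 mm or a keratinized-tissue deficiency flag → mucogingival
deformity; configured systemic-disease codes → periodontitis as a systemic
manifestation (patient-level); an endodontically involved tooth probing
≥ 6 mm → endodontic-periodontal lesion; an abscess flag or suppuration at
≥ 4 mm → periodontal abscess. Because the criteria are flag-driven, the
rules are deterministic and additive over disjoint tooth sets. The flag
vocabulary includes `vertical_defect` and `keratinized_tissue_deficiency`
so the staging and mucogingival rules have explicit inputs.

## The question tree

`build_default_tree()` generates the full question/answer graph (~110
nodes) from the same configuration: case definition → extent → severity →
complexity → stage IV discriminators → grade band → risk modifiers, plus
the gingival and peri-implant branches. Each question carries expandable
info text and a machine-readable predicate id; `auto_answer()` evaluates
predicates against a chart and walks to a leaf. Every leaf pairs its
diagnosis with static treatment-option text. The central consistency
property — tested over generated cohorts and all reachable labels — is
that the auto-answered leaf diagnosis always equals `diagnose()`'s primary
diagnosis. The grade questions are two-step (ratio band, then a modifier
band of none/moderate/severe) with the upgrade logic encoded in the
topology, which keeps the tree at ~110 nodes instead of enumerating every
modifier combination. The tree is built in code rather than shipped as a
static file because it is a generated artifact of the configuration;
`save_tree()`/`load_tree()` provide the serialized form, and
`validate_tree()` checks dangling references, unreachable nodes, cycles,
under-specified questions and leaves missing treatment text.

## The synthetic cohort generator

`chart_for_diagnosis(label, seed)` inverts the rules: it constructs site
measurements, bone loss/age pairs, tooth counts and flags that satisfy
exactly the target label, with randomness confined to
non-label-determining choices (which teeth are affected, bleeding pattern,
small age jitter within a band). Rule inversion, not rejection sampling,
guarantees coverage of labels that occur rarely (the molar-incisor pattern
occurred once in 150 study patients). Fixed anchors keep the inversion
exact: stage I/II charts use severity sites of PD 4/CAL 2 and PD 5/CAL 4
so no complexity factor can fire; stage III/IV charts use PD 6/CAL 6;
grade targets use bone/age pairs of 10%/~60 y (A), 30%/~50 y (B) and
55%/~40 y (C), each with ±2 y jitter that cannot cross a band boundary;
stage IV charts drop five premolars/canines and record five teeth lost to
periodontitis. Healthy positions probe 2 mm with 2 mm of coronal margin
(CAL 0), so unaffected teeth can never join the affected set.

`sample_cohort()` draws labels i.i.d. from the study's label frequencies
(the chairside cohort's totals column, renormalized — its printed rows sum
to 151 over 150 cases, which renormalization absorbs) and injects
secondary conditions per category at the study's per-patient rates
(129/150, 118/150, 52/150, 49/150, 18/150, 13/150). Injections are
designed to be label-neutral: mucogingival deformity is injected through
the keratinized-tissue flag rather than recession (recession would add
CAL and could change the stage), and endodontic-periodontal lesions
require an existing ≥ 6 mm pocket, so they simply cannot be placed on
stage I/II or health charts. As a belt-and-braces guarantee the generator
re-diagnoses each chart after injection and rolls the injections back if
the primary label moved; with the current rules this path is never taken.

What the generator does *not* emulate: spatially correlated breakdown
(real periodontitis clusters within quadrants), non-integer probing
variation, partially erupted or supernumerary dentitions, and longitudinal
change. Passing round-trip tests therefore demonstrates that the engine
and generator agree on the rule set — they say nothing about performance
on charts from real patients, whose measurement noise and borderline
presentations the study's gold-standard faculty adjudicated by hand.

## Accuracy scoring and the exact Wilcoxon test

Primary correctness is the exact match of the (category, extent, stage,
grade) tuple against the gold label; secondary conditions are scored as
diagnosis incidents — one gold condition on one patient — so a patient can
contribute several, which is what makes the study's 379-incident
denominator over 150 patients coherent. `pool_row()` sums (correct, total)
cells and computes the pooled percent, rounding half-up at the printed
precision (base R rounds half to even, which would mis-render boundary
cells); empty denominators render as "(–)" as the tables print them.

`wilcoxon_signed_rank()` drops zero differences (the standard convention;
an all-zero input is degenerate with p = 1), ranks |d|, and for ≤ 25
untied differences computes the exact two-sided p from the null
distribution of the positive-rank sum W⁺ built by the shift/convolution
algorithm — the doubled smaller tail, capped at 1. Ties or larger n fall
back to mid-ranks with the tie-corrected normal approximation and
continuity correction. The exact path is property-tested against
brute-force enumeration of all 2ⁿ sign assignments and cross-checked
against the reference implementation in base R's `stats`.

## Power simulation

The study sized its sample with a simulation of the paired two-sided
Wilcoxon test at α = 0.01, modelling the proportion of correct diagnoses
as Normal(20%, 10%) with a true control/test difference of 10%. The
reproducible reading of that design — validated against all four of its
reported power values (0.47, 0.81, 0.92, 0.95 at n = 10, 16, 20, 22) — is
that paired differences are drawn as Normal(10, 10) and tested against
zero; the control mean itself cancels out of a paired shift model.
`simulate_power()` runs 10,000 replicates by default (Monte-Carlo SE ≤
0.005) using the exact test throughout the relevant n range and rejects at
p < α. Two numerical notes: the exact test is discrete, so its attainable
size at α = 0.01 is ~0.009 for n between 10 and 25 (the null rejection
rate matches α only up to that granularity), and for n ≤ 7 the smallest
attainable two-sided p (2/2ⁿ) is not below 0.01, so power is exactly zero
there — the function warns rather than returning a silent 0.
`min_n_for_power()` smooths the estimated curve by isotonic regression
before thresholding, since the true curve is nondecreasing in n and raw
Monte-Carlo noise would otherwise flip the reported minimum between
adjacent sample sizes.

```{r, eval = FALSE}
cfg <- power_sim_config(reps = 10000, seed = 1)
simulate_power(16, cfg)$power   # ~0.81
min_n_for_power(0.8, cfg)$n     # 16
```

## Problem sizes used in the tests

The shipped test-suite sizes are the package's own choices for a
deterministic, exhaustive check of the rule set: every one of the 24
reachable labels is generated and re-diagnosed at several seeds, the
cohort round trip runs at n = 1000 and tree/engine equivalence at n = 400
plus all labels, the exact-test property check runs 500 random cases at
n ≤ 10 against brute-force enumeration, and the power checks use the
study's own 10,000 replicates.

## Known limitations

* The exclusion of non-periodontitis causes of CAL ("attributable to
  inflammatory breakdown") is represented only through chart semantics
  (recession-only defects on a single tooth, flags), not by a differential
  module; published criteria for that exclusion are not explicit.
* Direct-evidence grading from serial radiographs is not computed; the
  input hook (bone loss per tooth) exists but only the indirect ratio is
  used.
* Gingivitis on a reduced periodontium is reported as gingivitis with the
  reduced-periodontium rationale, not as a distinct category.
* The question wording is this package's own; the tree reproduces the
  classification logic, not any particular product's verbatim text.
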