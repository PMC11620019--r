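---
title: "Screening CYP450-mediated drug interactions from prescription data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening CYP450-mediated drug interactions from prescription data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypddi)
library(dplyr)
```

## The problem

The hepatic cytochrome P450 (CYP450) enzyme family metabolizes a large share
of prescribed drugs. When a *substrate* of an isoform (say CYP3A4) is
co-prescribed with a strong *inhibitor* of the same isoform, the substrate's
blood concentration rises (risk of overdose, e.g. tacrolimus + azole
antifungals); with a strong *inducer* it falls (risk of underdosing, e.g.
paracetamol + carbamazepine). For prodrugs the logic extends to the
patient's genotype: clopidogrel is activated by CYP2C19, so a loss-of-function
variant — detectable by a genotyping act — silently removes the drug's
effect. In routine care neither the co-prescriptions nor the corresponding
therapeutic drug monitoring (TDM) are systematically surveyed.

`cypddi` screens hospital prescription streams for these situations
population-wide. It consumes:

1. an interaction **knowledge base**: one row per
   (cytochrome, substrate, relation, perpetrator) combination, with each
   substance's 13-digit dispensing codes (UCD, *unité commune de
   dispensation*) packed into `" or "`-separated cells;
2. an institutional **formulary** (the UCD codes actually dispensed on site);
3. flat **EHR event tables** — prescriptions, laboratory events (dosage and
   genotyping acts), patients;
4. an **analyte map** linking substances to lab analyte codes.

and produces per-rule surveillance tables and dashboard panels.

## The detection model

A *rule* pairs a substrate with a perpetrator under one of three relations:
`p_inhib` (strong inhibition), `p_induc` (strong induction), `mutation`
(substrate paired with a pharmacogenetic genotyping act rather than a drug).

For a drug-drug rule with substrate codes $S = \{s_1,\dots,s_m\}$ and
perpetrator codes $P = \{p_1,\dots,p_n\}$, the screening condition on one
patient-day with prescribed code set $C$ is the two-clause boolean query

$$(s_1 \lor \dots \lor s_m) \land (p_1 \lor \dots \lor p_n)
  \iff S \cap C \neq \emptyset \ \land\ P \cap C \neq \emptyset,$$

rendered textually as `"(s1 or s2 ...) and (p1 or p2 ...)"`. One rule yields
$|S| \times |P|$ possible code-level combinations, which is why a
moderate substance-level knowledge base explodes into millions of code pairs
before formulary filtering (`count_code_combinations()`).

A **hit** is a (rule, patient, day) triple where the condition holds; for
mutation rules the perpetrator clause is satisfied by a same-day genotyping
lab event whose analyte is mapped to the rule's genotype-test label. Per
rule, the summary reports

* `n_patients` — distinct patients with at least one hit;
* `n_days` — distinct (patient, day) pairs ("hospitalization days");
* `n_prescriptions` — distinct matched *substrate* prescription events.

These satisfy `n_patients <= n_days` and `n_patients <= n_prescriptions` by
construction.

### Design choices in the detection semantics

* **Temporal join**: co-occurrence means *same calendar day for the same
  patient*, for both rule kinds. Day-level joining is what makes "number of
  hospitalization days" a meaningful headline metric. A stricter
  `join_on = "stay_day"` additionally requires the same stay.
* **`n_prescriptions` counts substrate events only.** Upstream reports never
  pin down whether "prescriptions" covers both drugs; counting distinct
  matched substrate lines reproduces the common pattern
  `days = prescriptions` (one substrate line per hit day) while still
  allowing `prescriptions > days` when a substrate is dispensed several
  times per day (immunosuppressant regimens). This is an interpretive
  choice, stated here once.
* **Two analysis windows are first-class.** Drug-drug screening typically
  uses a short recent window; drug-genotype screening a multi-year window,
  because genotyping is rare enough that a short window under-samples it.
  Both are mandatory configuration — there is no silent default period.
* **Determinism.** All outputs are sorted (hits by rule/patient/day,
  rankings with a lexicographic (cytochrome, substrate, perpetrator)
  tie-break), so identical inputs give checksum-identical outputs.

## Knowledge-base hygiene

Two filters run before any query is built:

* `remove_self_interactions()` drops rows whose substrate and perpetrator
  are the same molecule. Comparison is on *canonical labels* (trimmed,
  upper-cased): knowledge-base exports mix cases freely for one molecule, so
  a byte-wise comparison would under-remove. Label matching, not
  terminology-server molecule identity, is the implemented semantics.
* `filter_to_formulary()` intersects each code list with the institutional
  formulary and drops rules whose substrate side empties (or whose
  perpetrator side empties, for non-mutation rules). The filter is
  idempotent and monotone in the formulary.

The loader itself is deliberately 1:1 with file rows — duplicate rows are
preserved and *reported*, not silently merged, so row counts across pipeline
stages remain auditable. Codes are validated as 13 decimal digits; GTIN-style
check digits are not verified.

## Dashboard panels

For one rule and period, `build_dashboard()` computes five panels:
distinct affected patients per time bin (zero bins included; per-bin
deduplication only, so a patient active in two months counts in both); sex
and age distributions (each patient once, age in completed years at first
hit, half-open decade bands `[0,10) ... [90,120)` by default); distinct
patients per medical unit (a patient in several units counts in each, so
unit totals may exceed `n_patients`); TDM coverage; and dosage results by
status.

**Coverage** is the fraction of affected patients with at least one
`dosage` lab event for a mapped analyte within the matching window. The
default window is *same stay as a hit*: monitoring typically happens during
and shortly after the co-prescription, not necessarily on the hit day
itself. `same_day` and `period` windows are available; with zero affected
patients coverage is undefined and reported as missing (`NA`/`"n/a"`),
never as 0. The **status** panel counts matched dosage *events* by
`below` / `in_range` / `above` / `unknown` — a patient measured repeatedly
contributes repeatedly. That duplication mirrors how repeated tests appear
in practice and is kept deliberately; `dedupe_patients = TRUE` retains only
each patient's first dosage. The four-value status set is itself an
interpretation: source systems report non-standardized local codes, and the
analyte map accepts free-form strings for the same reason (lab catalogues
are often not LOINC-coded).

Bundles export to schema-stable JSON (shipped schema:
`system.file("extdata", "bundle-schema.json", package = "cypddi")`) with an
exact re-import (`read_bundle()`), or to a dependency-free self-contained
HTML report. `ggplot2::autoplot()` renders each panel.

## The synthetic EHR generator

No hospital extract can ship with a package, so `simulate_ehr()` generates
one — and because its ground truth is *planted*, every pipeline stage can be
tested exactly rather than statistically.

```{r sim-example}
cfg <- sim_config(
  seed = 42, n_patients = 40, period = c("2021-06-01", "2021-07-31"),
  rules_spec = bind_rows(
    sim_rule("CYP3A4", "Paracetamol", "p_induc", "Carbamazepine",
             n_patients = 6, n_days = 8, n_prescriptions = 9,
             coverage = 0.5),
    sim_rule("CYP3A5", "Tacrolimus", "mutation", "Genotype CYP3A5",
             n_patients = 4, coverage = 0.75)),
  n_self_pairs = 2, n_off_formulary_rules = 1)
sim <- simulate_ehr(cfg)
kb_path <- tempfile(fileext = ".tsv")
readr::write_tsv(sim$kb, kb_path)
rules <- filter_to_formulary(
  remove_self_interactions(read_interaction_kb(kb_path))$kept,
  sim$formulary)
hits <- detect_interactions(rules, sim$prescriptions, sim$labs,
                            period = cfg$period,
                            analyte_map = sim$analyte_map)
summarize_interactions(hits, rules)
```

Key properties, each load-bearing for the tests:

* **Exactness by construction.** Background (non-interacting) events draw
  codes and analytes from pools *disjoint* from every rule's codes and
  mapped analytes, so an accidental co-occurrence is impossible; a
  post-generation audit independently rescans all events and aborts if the
  observed co-occurrence set differs from the planted one. This replaces a
  resample-on-collision loop with a guarantee.
* **Disjoint codes per rule.** A substance appearing in several rules
  receives disjoint code subsets per rule (read: different dispensing
  presentations). This keeps each rule's planted counts independent even
  when patients overlap across rules.
* **Deterministic planting.** `n_days` hit days are spread round-robin over
  the `n_patients` chosen patients; extra prescriptions are duplicated on
  existing hit days; exactly `round(coverage * n_patients)` patients receive
  a dosage event on their first hit day (same stay), with statuses cycling
  below/in\_range/above. Coverage is therefore recovered *exactly* whenever
  `coverage * n_patients` is integral.
* **Stays** are a deterministic function of (patient, 14-day block), so
  same-stay matching is well-defined across prescriptions and labs. Lab
  events carry a `stay_id` column for this reason; with lab files lacking
  it, the same-stay window errors and points to `same_day`/`period`.
* Ages are drawn from a normal (mean 62, sd 18, truncated to 0–100) — a
  plausible hospitalized-cohort profile; no empirical demographic is claimed.

What the generator does **not** emulate: realistic co-prescription
prevalence, dose values, free-text records, coding errors, transfers between
units within a day, or patients whose events straddle the period boundary.
A green planted-truth test therefore establishes that the pipeline's joins,
filters, counts and panels are correct — not that any clinical prevalence
estimate is.

### The demonstration profile

`demo_profile()` is a fixed configuration whose planted counts echo the
magnitudes of a real hospital surveillance run: eight drug-drug rules with
50/25/21/20/13/12/12/12 affected patients over June–September 2021, and two
drug-genotype rules — tacrolimus with CYP3A5 genotyping (675 patients, 1411
days, 3336 prescriptions) and clopidogrel with CYP2C19 genotyping
(804/823/828) — over January 2019–September 2021. Planted TDM coverage is
0.9 for tacrolimus (immunosuppressant monitoring is routine), 0.1 for
clopidogrel (no routine concentration assay) and 0.25 for the drug-drug
rules; these fractions are package choices, not reported values. Running the
pipeline on this profile reproduces the planted tables exactly — which
verifies the pipeline, and only the pipeline.

## Numerical and degenerate-input conventions

* UCD codes are validated as `^[0-9]{13}$`; all synthetic codes live in the
  `3400…` prefix space real codes occupy.
* Query parsing reports the character offset of the first violation;
  rendering then parsing is the identity (property-tested on random
  clause lists).
* `evaluate_query()` is monotone in the present-code set and false on the
  empty set for every drug-drug query.
* Empty inputs degrade cleanly: header-only knowledge bases load as zero
  rules, empty hit sets yield all-zero time series, empty demographic and
  unit tables, `NA` coverage and empty status counts.
* An empty formulary is a configuration error, not an empty result:
  "no formulary supplied" must not masquerade as "no overlap".
* Week bins start on ISO Mondays; month bins on the first of the month; age
  is completed years (no fractional ages at band edges).

## Limitations

* Self-interaction removal matches labels, not molecule identities; distinct
  spellings of one molecule across rows (beyond case/whitespace) are not
  unified.
* Severity grading beyond the three relation values, dose-level
  pharmacokinetics, and prescriber-facing alerting are out of scope.
* `n_prescriptions` is one defensible reading of an under-specified metric;
  comparisons with systems counting both drugs' lines will differ.
* The same-stay dosage window depends on stay identifiers being consistent
  between prescription and lab files.
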