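# cypddi

Population-wide screening of cytochrome P450 (CYP450)-mediated drug–drug and
drug–genotype interactions from hospital prescription data.

The CYP450 enzyme family metabolizes much of the pharmacopoeia. When a
substrate of an isoform is co-prescribed with a strong inhibitor or inducer
of the same isoform, the substrate's blood concentration drifts — overdose
under inhibition (tacrolimus + azoles), underdose under induction
(paracetamol + carbamazepine). For prodrugs the risk is genetic: clopidogrel
is activated by CYP2C19, so loss-of-function carriers need a genotyping act
to be identified. `cypddi` is for hospital pharmacologists and pharmacy
informaticians who want a surveillance view of these situations across an
institution: which interactions occur, in how many patients, on how many
hospitalization days, and how often the affected patients actually received
therapeutic drug monitoring (TDM) or genotyping.

## Method

Inputs are flat files: an interaction knowledge base (one row per
cytochrome / substrate / relation / perpetrator with each substance's
13-digit UCD dispensing codes), the institutional formulary, and EHR event
tables (prescriptions, lab events, patients) plus a substance → lab-analyte
map.

For a rule with substrate codes $S$ and perpetrator codes $P$, the
co-prescription condition on a patient-day with prescribed codes $C$ is the
two-clause boolean query

```
(s1 or s2 or ...) and (p1 or p2 or ...)   i.e.   S∩C ≠ ∅  and  P∩C ≠ ∅
```

After removing self-pairs (same molecule on both sides) and intersecting
with the formulary, the detector finds every (rule, patient, day) hit —
same-day genotyping lab events play the perpetrator role for `mutation`
rules — and summarises per rule: distinct patients, distinct
(patient, day) hospitalization days, and distinct matched substrate
prescriptions. Five dashboard panels per rule (temporal trend, sex/age,
medical units, TDM coverage, dosage status) export as JSON or
self-contained HTML, with `ggplot2::autoplot()` renderings.

A seeded synthetic-EHR generator (`simulate_ehr()`) plants exact ground
truth — hits, coverage fractions, decoy knowledge-base rows — so the whole
pipeline is testable without hospital data. See the vignette
(`vignettes/cyp-interaction-screening.Rmd`) for the full model and design
rationale.

## Worked example

Generate the shipped demonstration cohort (2000 synthetic patients, eight
planted drug–drug rules, two drug–genotype rules, decoy KB rows, background
noise) and run the pipeline:

```r
library(cypddi)
sim <- simulate_ehr(demo_profile(seed = 1), dir = "sim")
p <- demo_periods()
report <- run_pipeline(run_config(
  kb = sim$paths$kb, formulary = sim$paths$formulary,
  prescriptions = sim$paths$prescriptions, labs = sim$paths$labs,
  patients = sim$paths$patients, analyte_map = sim$paths$analyte_map,
  period_dd = p$dd, period_dg = p$dg, out_dir = "out", top_n = 5))
report
#> <interaction screening run>
#>   KB: 15 rows, 3 self-pairs removed, 10 rules after formulary filter
#>   code combinations: 90 before, 72 after formulary filter
#>   hits: 172 drug-drug, 2234 drug-genotype; 5 dashboard(s)
```

The 15 knowledge-base rows shrink to 10 active rules: 3 self-pairs are
removed and 2 decoy rules lose their perpetrator codes to the formulary
filter. The ranked drug–drug summary (`out/summary_drug_drug.tsv`)
recovers the planted counts exactly:

```
Cytochrome  Substrate     Type     Inhibitor or inducer  Number of patients  Number of hospitalization days  Number of prescriptions
CYP3A4      PARACETAMOL   p_induc  CARBAMAZEPINE         50                  55                              55
CYP3A4      ATORVASTINE   p_inhib  TICAGRELOR            25                  26                              26
CYP3A4      PARACETAMOL   p_inhib  VERAPAMIL             21                  21                              21
CYP2B6      TRAMADOL      p_inhib  CLOPIDOGREL           20                  20                              20
CYP3A4      PANTOPRAZOLE  p_inhib  TICAGRELOR            13                  14                              14
...
```

and the drug–genotype table reports tacrolimus + CYP3A5 genotyping with
675 patients / 1411 days / 3336 prescriptions and clopidogrel + CYP2C19
genotyping with 804 / 823 / 828 — the planted ground truth, so any
discrepancy would be a pipeline defect, not a data surprise. Patient counts
≤ days ≤ prescriptions because one patient accumulates several hit days and
an immunosuppressant is dispensed several times per day.

A single-rule worked example ships as a fixture: loading
`inst/extdata/example_kb.tsv` (flecainide, a CYP1A2 substrate, against the
inhibitor norfloxacin; 13 × 12 codes) and calling `build_query()` renders
the 156-combination boolean query string exactly.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it simulates the demonstration cohort with the given seed, executes the
full pipeline (knowledge-base validation → filters → query export →
detection over both analysis windows → ranked summaries → dashboard
bundles), prints the run report, and writes the (empty) target report to
`--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command line

A thin CLI over the same functions lives at `inst/cli/cypddi.R`
(subcommands `validate-kb`, `filter`, `queries`, `detect`, `dashboard`,
`simulate`, `run`; exit codes 0/2/3 for success / validation failure /
runtime failure).
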