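#' Shipped demonstration simulation profile
#'
#' A ready-made [sim_config()] whose planted world mirrors the magnitudes a
#' hospital-scale surveillance run produces: eight drug-drug rules with
#' 50, 25, 21, 20, 13, 12, 12, 12 affected patients over a four-month window
#' (2021-06-01 to 2021-09-30), and two drug-genotype rules — tacrolimus with
#' CYP3A5 genotyping (675 patients, 1411 hospitalization days, 3336
#' prescriptions) and clopidogrel with CYP2C19 genotyping (804 / 823 / 828)
#' — over an extended window (2019-01-01 to 2021-09-30) so the genotype
#' panels have enough patients. Planted dosage coverage is 0.9 for
#' tacrolimus (therapeutic drug monitoring of immunosuppressants is
#' routine), 0.1 for clopidogrel (no routine concentration assay) and 0.25
#' for the drug-drug rules. Three self-pair and two off-formulary decoy
#' rows exercise the knowledge-base filters.
#'
#' These counts are planted by construction: a demo run verifies the
#' pipeline end-to-end against exact ground truth, it does not re-derive any
#' hospital result.
#'
#' @param seed RNG seed (default 1).
#' @param n_patients cohort size (default 2000).
#' @return a `cypddi_sim_config`.
#' @export
#' @examples
#' cfg <- demo_profile(seed = 1)
#' cfg$rules_spec$n_patients
demo_profile <- function(seed = 1L, n_patients = 2000L) {
  dd_start <- "2021-06-01"
  dd_end <- "2021-09-30"
  dd <- function(cyto, sub, rel, perp, np, nd, nrx) {
    sim_rule(cyto, sub, rel, perp, n_patients = np, n_days = nd,
             n_prescriptions = nrx, coverage = 0.25,
             period_start = dd_start, period_end = dd_end)
  }
  rules_spec <- bind_rows(
    dd("CYP3A4", "Paracetamol", "p_induc", "Carbamazepine", 50, 55, 55),
    dd("CYP3A4", "Atorvastine", "p_inhib", "Ticagrelor", 25, 26, 26),
    dd("CYP3A4", "Paracetamol", "p_inhib", "Verapamil", 21, 21, 21),
    dd("CYP2B6", "Tramadol", "p_inhib", "Clopidogrel", 20, 20, 20),
    dd("CYP3A4", "Pantoprazole", "p_inhib", "Ticagrelor", 13, 14, 14),
    dd("CYP2D6", "Oxycodone", "p_inhib", "Paroxetine", 12, 12, 12),
    dd("CYP2D6", "Ondansetron", "p_inhib", "Paroxetine", 12, 12, 12),
    dd("CYP3A4", "Paracetamol", "p_inhib", "Ticagrelor", 12, 12, 12),
    sim_rule("CYP3A5", "Tacrolimus", "mutation", "Genotype CYP3A5",
             n_patients = 675, n_days = 1411, n_prescriptions = 3336,
             coverage = 0.9),
    sim_rule("CYP2C19", "Clopidogrel", "mutation", "Genotype CYP2C19",
             n_patients = 804, n_days = 823, n_prescriptions = 828,
             coverage = 0.1))
  sim_config(
    seed = seed, n_patients = n_patients,
    period = c("2019-01-01", "2021-09-30"),
    rules_spec = rules_spec,
    n_background_prescriptions = 4000L,
    n_background_labs = 1500L,
    n_self_pairs = 3L, n_off_formulary_rules = 2L)
}

#' Default analysis periods of the demonstration profile
#'
#' The drug-drug analysis window (four months) and the drug-genotype window
#' (almost three years, so genotyping panels accumulate enough patients).
#'
#' @return list with `dd` and `dg`, each a length-2 `Date` vector.
#' @export
demo_periods <- function() {
  list(dd = as_period(c("2021-06-01", "2021-09-30")),
       dg = as_period(c("2019-01-01", "2021-09-30")))
}
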