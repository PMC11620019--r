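#' Detect rule co-occurrences in EHR event streams
#'
#' Scans prescription (and lab) events for same-day co-occurrences of each
#' interaction rule, per patient. For a drug-drug rule, a hit is a
#' (patient, day) on which at least one prescription bears a substrate code
#' and at least one bears a perpetrator code. For a mutation rule, a hit is a
#' (patient, day) pairing a substrate prescription with a genotyping lab
#' event whose analyte is mapped to the rule's genotype-test label in
#' `analyte_map`. Co-occurrence is joined at calendar-day granularity by
#' default; `join_on = "stay_day"` additionally requires the same stay.
#'
#' @param rules a rules tibble (after self-interaction removal and formulary
#'   filtering).
#' @param prescriptions prescription events ([read_prescriptions()]).
#' @param labs lab events ([read_lab_events()]); required when `rules`
#'   contains mutation rules.
#' @param period study period, coerced with [as_period()]; events outside it
#'   are ignored.
#' @param analyte_map analyte mapping ([read_analyte_map()]); required for
#'   mutation rules.
#' @param join_on `"day"` (default) or `"stay_day"`.
#' @return a tibble of hits, sorted by (`rule_id`, `patient_id`, `day`), one
#'   row per rule x patient x day (x stay under `"stay_day"`), with
#'   list-columns `substrate_event_ids`, `substrate_units`, `stay_ids`
#'   (stays of the matched substrate events) and `perpetrator_event_ids`
#'   (prescription ids for drug-drug rules, lab event ids for mutation
#'   rules). The `period` and `join_on` are carried as attributes.
#' @export
detect_interactions <- function(rules, prescriptions, labs = NULL, period,
                                analyte_map = NULL,
                                join_on = c("day", "stay_day")) {
  join_on <- rlang::arg_match(join_on)
  period <- as_period(period)

  rx <- prescriptions |>
    filter(.data$day >= period[1], .data$day <= period[2])

  key <- c("rule_id", "patient_id", "day",
           if (join_on == "stay_day") "stay_id")

  empty_hits <- tibble(
    rule_id = integer(), patient_id = character(),
    day = as.Date(character()),
    substrate_event_ids = list(), substrate_units = list(),
    stay_ids = list(), perpetrator_event_ids = list())

  mut <- rules |> filter(.data$relation == "mutation")
  if (nrow(mut) > 0L) {
    if (is.null(analyte_map)) {
      abort(sprintf(
        "mutation rule(s) present (e.g. rule %d: %s / %s) but no analyte map supplied.",
        mut$rule_id[1], mut$substrate[1], mut$perpetrator[1]),
        class = "cypddi_config_error")
    }
    unmapped <- mut |>
      filter(purrr::map_int(.data$perpetrator,
        ~ length(mapped_analytes(analyte_map, .x, "genotyping"))) == 0L)
    if (nrow(unmapped) > 0L) {
      abort(sprintf(
        "no genotyping analyte mapped for mutation rule %d (%s / %s); add a kind=genotyping row to the analyte map.",
        unmapped$rule_id[1], unmapped$substrate[1], unmapped$perpetrator[1]),
        class = "cypddi_config_error")
    }
    if (is.null(labs)) {
      abort("mutation rules present but no lab events supplied.",
            class = "cypddi_config_error")
    }
  }

  # substrate side: prescription events matching each rule's substrate codes
  sub_long <- rules |>
    select("rule_id", code = "substrate_codes") |>
    tidyr::unnest("code")
  sub_matches <- inner_join(sub_long, rx, by = "code",
                            relationship = "many-to-many")

  sub_side <- sub_matches |>
    summarise(
      substrate_event_ids = list(.data$event_id),
      substrate_units = list(.data$unit),
      stay_ids = list(.data$stay_id),
      .by = dplyr::all_of(key))

  # perpetrator side, drug-drug: prescription events with perpetrator codes
  perp_long <- rules |>
    filter(.data$relation != "mutation") |>
    select("rule_id", code = "perpetrator_codes") |>
    tidyr::unnest("code")
  perp_dd <- inner_join(perp_long, rx, by = "code",
                        relationship = "many-to-many") |>
    summarise(perpetrator_event_ids = list(.data$event_id),
              .by = dplyr::all_of(key))

  # perpetrator side, mutation: genotyping lab events with mapped analytes
  perp_mut <- NULL
  if (nrow(mut) > 0L) {
    lab_key <- setdiff(key, "stay_id")
    geno <- labs |>
      filter(.data$kind == "genotyping",
             .data$day >= period[1], .data$day <= period[2])
    ana_long <- mut |>
      mutate(analyte = purrr::map(.data$perpetrator,
        ~ mapped_analytes(analyte_map, .x, "genotyping"))) |>
      select("rule_id", "analyte") |>
      tidyr::unnest("analyte")
    perp_mut <- inner_join(ana_long, geno, by = "analyte",
                           relationship = "many-to-many") |>
      summarise(perpetrator_event_ids = list(.data$event_id),
                .by = dplyr::all_of(lab_key))
    if (join_on == "stay_day" && nrow(perp_mut) > 0L) {
      # genotyping joined at day level even under stay_day (lab acts are not
      # reliably tied to a stay); attach every stay present that day
      perp_mut <- sub_side |>
        filter(.data$rule_id %in% mut$rule_id) |>
        select(dplyr::all_of(key)) |>
        inner_join(perp_mut, by = lab_key)
    }
  }

  hits_dd <- inner_join(sub_side, perp_dd, by = key)
  hits <- if (!is.null(perp_mut)) {
    bind_rows(hits_dd, inner_join(sub_side, perp_mut, by = key))
  } else {
    hits_dd
  }
  if (nrow(hits) == 0L) hits <- empty_hits

  hits <- hits |>
    select("rule_id", "patient_id", "day", "substrate_event_ids",
           "substrate_units", "stay_ids", "perpetrator_event_ids") |>
    arrange(.data$rule_id, .data$patient_id, .data$day)

  attr(hits, "period") <- period
  attr(hits, "join_on") <- join_on
  hits
}

#' Summarise detected interactions per rule
#'
#' Produces, for each rule, the three headline metrics of an interaction
#' surveillance table: the number of affected patients (distinct patients
#' with at least one hit), the number of hospitalization days (distinct
#' (patient, day) pairs), and the number of prescriptions (distinct matched
#' substrate prescription events). By construction
#' `n_patients <= n_days` and `n_patients <= n_prescriptions`.
#'
#' @param hits a hits tibble from [detect_interactions()].
#' @param rules the rules tibble the hits were detected with; every rule
#'   appears in the output, with zero counts when it produced no hit.
#' @return tibble with columns `rule_id`, `cytochrome`, `substrate`,
#'   `relation`, `perpetrator`, `n_patients`, `n_days`, `n_prescriptions`;
#'   the detection `period` attribute is carried over.
#' @export
summarize_interactions <- function(hits, rules) {
  counts <- hits |>
    summarise(
      n_patients = dplyr::n_distinct(.data$patient_id),
      n_days = dplyr::n_distinct(.data$patient_id, .data$day),
      n_prescriptions = dplyr::n_distinct(
        unlist(.data$substrate_event_ids, use.names = FALSE)),
      .by = "rule_id")
  out <- rules |>
    select("rule_id", "cytochrome", "substrate", "relation", "perpetrator") |>
    left_join(counts, by = "rule_id") |>
    mutate(across(c("n_patients", "n_days", "n_prescriptions"),
                  ~ dplyr::coalesce(.x, 0L)))
  attr(out, "period") <- attr(hits, "period")
  out
}

#' Rank interaction rules by a summary metric
#'
#' Orders a summary table descending by one metric, with deterministic
#' lexicographic tie-breaking on (cytochrome, substrate, perpetrator) so
#' repeated runs produce identical tables.
#'
#' @param summaries output of [summarize_interactions()].
#' @param by one of `"patients"`, `"days"`, `"prescriptions"`.
#' @return the reordered summary tibble (a permutation of the input rows).
#' @export
rank_rules <- function(summaries, by = c("patients", "days", "prescriptions")) {
  by <- rlang::arg_match(by)
  metric <- paste0("n_", by)
  summaries |>
    arrange(dplyr::desc(.data[[metric]]), .data$cytochrome,
            .data$substrate, .data$perpetrator)
}

#' Write a summary table in the surveillance-report column layout
#'
#' @param summaries output of [summarize_interactions()] / [rank_rules()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  out <- summaries |>
    transmute(
      Cytochrome = .data$cytochrome,
      Substrate = .data$substrate,
      Type = .data$relation,
      `Inhibitor or inducer` = .data$perpetrator,
      `Number of patients` = .data$n_patients,
      `Number of hospitalization days` = .data$n_days,
      `Number of prescriptions` = .data$n_prescriptions)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write detected hits as TSV
#'
#' List-columns are collapsed with `;`.
#'
#' @param hits a hits tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  flat <- hits |>
    mutate(across(c("substrate_event_ids", "substrate_units", "stay_ids",
                    "perpetrator_event_ids"),
                  ~ purrr::map_chr(.x, paste, collapse = ";")))
  readr::write_tsv(flat, path)
  invisible(path)
}
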