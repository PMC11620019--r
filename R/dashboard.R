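#' Temporal view of affected patients
#'
#' Counts distinct patients with at least one hit per time bin, over the full
#' detection period (bins with zero patients are included). A patient
#' hit in several bins is counted in each: deduplication is per-bin only.
#' Optionally restricts to hits whose matched substrate prescriptions
#' occurred in one medical unit.
#'
#' @param hits a hits tibble for one rule (from [detect_interactions()],
#'   filtered to a single `rule_id`).
#' @param bin `"month"` (default), `"week"` or `"day"`.
#' @param period study period; defaults to the hits' `period` attribute.
#' @param unit_filter optional medical-unit label; unknown labels error,
#'   listing the units present.
#' @return tibble with columns `bin_start` (Date) and `n_patients`.
#' @export
hit_time_series <- function(hits, bin = c("month", "week", "day"),
                            period = NULL, unit_filter = NULL) {
  bin <- rlang::arg_match(bin)
  period <- as_period(period %||% attr(hits, "period"))
  if (!is.null(unit_filter)) {
    known <- sort(unique(unlist(hits$substrate_units, use.names = FALSE)))
    if (!unit_filter %in% known) {
      abort(sprintf("unknown medical unit '%s'; units present: %s",
                    unit_filter, paste(known, collapse = ", ")),
            class = "cypddi_config_error")
    }
    hits <- hits |>
      filter(purrr::map_lgl(.data$substrate_units, ~ unit_filter %in% .x))
  }
  bins <- tibble(bin_start = seq(floor_bin(period[1], bin),
                                 floor_bin(period[2], bin),
                                 by = bin))
  counts <- hits |>
    mutate(bin_start = floor_bin(.data$day, bin)) |>
    summarise(n_patients = dplyr::n_distinct(.data$patient_id),
              .by = "bin_start")
  bins |>
    left_join(counts, by = "bin_start") |>
    mutate(n_patients = dplyr::coalesce(.data$n_patients, 0L))
}

#' Sex and age distribution of affected patients
#'
#' Each affected patient is counted exactly once; age is computed in
#' completed years at the patient's first hit date and assigned to half-open
#' bands `[lo, hi)`.
#'
#' @param hits a hits tibble for one rule.
#' @param patients patient table ([read_patients()]); every hit's patient
#'   must be present.
#' @param age_bands increasing numeric break points; defaults to decades
#'   0-10, ..., 90-120.
#' @return list with tibbles `sex` (`sex`, `n`) and `age` (`band`, `n`);
#'   both `n` columns sum to the number of affected patients.
#' @export
hit_demographics <- function(hits, patients,
                             age_bands = c(seq(0, 90, by = 10), 120)) {
  if (nrow(hits) == 0L) {
    return(list(sex = tibble(sex = character(), n = integer()),
                age = tibble(band = character(), n = integer())))
  }
  affected <- hits |>
    summarise(first_hit = min(.data$day), .by = "patient_id")
  missing_pat <- setdiff(affected$patient_id, patients$patient_id)
  if (length(missing_pat)) {
    abort(sprintf("patient(s) missing from the patient table: %s",
                  paste(utils::head(missing_pat, 5), collapse = ", ")),
          class = "cypddi_validation_error")
  }
  demo <- affected |>
    inner_join(patients, by = "patient_id") |>
    mutate(age = age_years(.data$birth_date, .data$first_hit),
           band = cut(.data$age, breaks = age_bands, right = FALSE,
                      include.lowest = FALSE))
  list(
    sex = demo |> count(.data$sex, name = "n") |> arrange(.data$sex),
    age = demo |>
      count(band = as.character(.data$band), name = "n") |>
      arrange(.data$band)
  )
}

#' Affected patients by medical unit
#'
#' Distinct patients per medical unit, where a patient belongs to every unit
#' in which one of their matched substrate prescriptions occurred; unit
#' totals can therefore exceed the number of affected patients.
#'
#' @param hits a hits tibble for one rule.
#' @return tibble with columns `unit`, `n_patients`.
#' @export
hit_unit_breakdown <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble(unit = character(), n_patients = integer()))
  }
  hits |>
    select("patient_id", "substrate_units") |>
    tidyr::unnest("substrate_units") |>
    distinct(.data$patient_id, unit = .data$substrate_units) |>
    count(.data$unit, name = "n_patients") |>
    arrange(.data$unit)
}

# dosage lab events matched to affected patients under the window config
match_dosage_events <- function(hits, labs, analytes,
                                window = c("same_stay", "same_day", "period"),
                                period = NULL, dedupe_patients = FALSE) {
  window <- rlang::arg_match(window)
  if (length(analytes) == 0L) {
    abort("no dosage analyte codes configured for this rule's substrate; add kind=dosage rows to the analyte map.",
          class = "cypddi_config_error")
  }
  dosages <- labs |>
    filter(.data$kind == "dosage", .data$analyte %in% analytes,
           .data$patient_id %in% hits$patient_id)
  matched <- switch(window,
    same_day = {
      hit_days <- hits |> distinct(.data$patient_id, .data$day)
      dosages |> semi_join(hit_days, by = c("patient_id", "day"))
    },
    same_stay = {
      if (!"stay_id" %in% names(labs)) {
        abort("lab events carry no stay_id column: the same-stay dosage window is not computable; use window = \"same_day\" or \"period\".",
              class = "cypddi_config_error")
      }
      hit_stays <- hits |>
        select("patient_id", "stay_ids") |>
        tidyr::unnest("stay_ids") |>
        distinct(.data$patient_id, stay_id = .data$stay_ids)
      dosages |> semi_join(hit_stays, by = c("patient_id", "stay_id"))
    },
    period = {
      p <- as_period(period %||% attr(hits, "period"))
      dosages |> filter(.data$day >= p[1], .data$day <= p[2])
    })
  matched <- matched |> arrange(.data$patient_id, .data$day, .data$event_id)
  if (dedupe_patients) {
    matched <- matched |> slice_head(n = 1L, by = "patient_id")
  }
  matched
}

#' Therapeutic drug monitoring coverage of affected patients
#'
#' Fraction of interaction-affected patients who had at least one blood
#' concentration measurement (kind `dosage`) of the substrate within the
#' matching window: same stay as a hit (default), same day as a hit, or
#' anywhere in the study period. With no affected patient the coverage is
#' undefined and `NA` is returned (not 0).
#'
#' @param hits a hits tibble for one rule.
#' @param labs lab events.
#' @param analytes character vector of dosage analyte codes mapped to the
#'   rule's substrate (see [read_analyte_map()]).
#' @param window `"same_stay"` (default), `"same_day"` or `"period"`.
#' @param period required for `window = "period"` when the hits carry no
#'   period attribute.
#' @return a proportion in `[0, 1]`, or `NA_real_` when undefined.
#' @export
dosage_coverage <- function(hits, labs, analytes,
                            window = c("same_stay", "same_day", "period"),
                            period = NULL) {
  n_affected <- dplyr::n_distinct(hits$patient_id)
  if (n_affected == 0L) return(NA_real_)
  matched <- match_dosage_events(hits, labs, analytes, window, period)
  dplyr::n_distinct(matched$patient_id) / n_affected
}

#' Dosage results by patient status
#'
#' Among the dosage events matched to affected patients (same window
#' semantics as [dosage_coverage()]), counts events by interpretation status
#' (`below`, `in_range`, `above`, `unknown`). Every matched event is counted:
#' a patient measured several times contributes several events, mirroring how
#' repeated tests appear in monitoring dashboards; set
#' `dedupe_patients = TRUE` to keep only each patient's first dosage.
#'
#' @inheritParams dosage_coverage
#' @param dedupe_patients count only the first matched dosage per patient.
#' @return tibble with columns `status`, `n` (statuses with zero events
#'   omitted; zero rows when nothing matched).
#' @export
dosage_by_status <- function(hits, labs, analytes,
                             window = c("same_stay", "same_day", "period"),
                             period = NULL, dedupe_patients = FALSE) {
  matched <- match_dosage_events(hits, labs, analytes, window, period,
                                 dedupe_patients = dedupe_patients)
  matched |>
    count(.data$status, name = "n") |>
    arrange(factor(.data$status, levels = STATUS_LEVELS))
}
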