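#' Read EHR event tables
#'
#' Flat-file stand-ins for a hospital data warehouse. All files are TSV with
#' a header and ISO-8601 dates.
#'
#' * prescriptions: `event_id`, `patient_id`, `stay_id`, `day`, `code`
#'   (13-digit UCD), `unit` (medical-unit label).
#' * lab events: `event_id`, `patient_id`, `day`, `analyte`, `kind`
#'   (`dosage` or `genotyping`), `value` (numeric, may be empty), `status`
#'   (`below` / `in_range` / `above` / `unknown`; empty treated as
#'   `unknown`), plus an optional `stay_id` used by the same-stay dosage
#'   window.
#' * patients: `patient_id`, `sex`, `birth_date`.
#'
#' @param path path to the TSV file.
#' @return a tibble with typed columns.
#' @name ehr_io
NULL

#' @rdname ehr_io
#' @export
read_prescriptions <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    event_id = "c", patient_id = "c", stay_id = "c",
    day = readr::col_date(), code = "c", unit = "c"), progress = FALSE)
  bad <- which(!is_ucd_code(x$code))
  if (length(bad)) {
    abort(sprintf("prescriptions: %d malformed UCD code(s), first at row %d ('%s')",
                  length(bad), bad[1], x$code[bad[1]]),
          class = "cypddi_validation_error")
  }
  if (anyNA(x$day)) {
    abort("prescriptions: unparseable dates in `day` (expected ISO-8601)",
          class = "cypddi_validation_error")
  }
  x
}

#' @rdname ehr_io
#' @export
read_lab_events <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    .default = "c", day = readr::col_date(), value = readr::col_double()),
    progress = FALSE)
  required <- c("event_id", "patient_id", "day", "analyte", "kind")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(sprintf("lab events missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "cypddi_schema_error")
  }
  if (!"value" %in% names(x)) x$value <- NA_real_
  if (!"status" %in% names(x)) x$status <- NA_character_
  x$status <- ifelse(is.na(x$status) | !nzchar(x$status), "unknown", x$status)
  bad_kind <- setdiff(unique(x$kind), c("dosage", "genotyping"))
  if (length(bad_kind)) {
    abort(sprintf("lab events: unknown kind value(s): %s",
                  paste(bad_kind, collapse = ", ")),
          class = "cypddi_validation_error")
  }
  bad_status <- setdiff(unique(x$status), STATUS_LEVELS)
  if (length(bad_status)) {
    abort(sprintf("lab events: unknown status value(s): %s",
                  paste(bad_status, collapse = ", ")),
          class = "cypddi_validation_error")
  }
  x
}

#' @rdname ehr_io
#' @export
read_patients <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    patient_id = "c", sex = "c", birth_date = readr::col_date()),
    progress = FALSE)
}

#' Read an analyte mapping configuration
#'
#' Maps substances to laboratory analyte codes: rows with `kind = "dosage"`
#' give, for a substrate substance, the analyte codes of its blood
#' concentration assays (used for monitoring-coverage panels); rows with
#' `kind = "genotyping"` give, for a genotype-test label (the perpetrator of
#' a mutation rule, e.g. `GENOTYPE CYP3A5`), the analyte codes of the
#' genotyping act. Analyte codes are free-form strings (the source lab
#' catalogue is not LOINC-coded); substances are canonicalized.
#'
#' @param path TSV with columns `kind`, `substance`, `analyte`.
#' @return tibble with columns `kind`, `substance` (canonical), `analyte`.
#' @export
read_analyte_map <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  required <- c("kind", "substance", "analyte")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(sprintf("analyte map missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "cypddi_schema_error")
  }
  bad <- setdiff(unique(x$kind), c("dosage", "genotyping"))
  if (length(bad)) {
    abort(sprintf("analyte map: unknown kind value(s): %s",
                  paste(bad, collapse = ", ")),
          class = "cypddi_validation_error")
  }
  x |> mutate(substance = canonical_label(.data$substance))
}

# analyte codes mapped to one substance for one kind
mapped_analytes <- function(analyte_map, substance, kind) {
  analyte_map$analyte[analyte_map$kind == kind &
                        analyte_map$substance == canonical_label(substance)]
}
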