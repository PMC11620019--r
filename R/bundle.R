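#' Assemble the five dashboard panels for one rule
#'
#' Computes, for a single interaction rule over one period, the complete set
#' of dashboard panels: temporal trend of affected patients, sex and age
#' distribution, medical-unit breakdown, therapeutic drug monitoring
#' coverage, and dosage results by status.
#'
#' @param hits hits tibble (may span several rules; filtered to `rule`).
#' @param rule one row of the rules tibble.
#' @param patients patient table.
#' @param labs lab events.
#' @param analyte_map analyte mapping ([read_analyte_map()]).
#' @param period study period; defaults to the hits' attribute.
#' @param bin time-series bin, `"month"` default.
#' @param window dosage matching window, `"same_stay"` default.
#' @param age_bands age band break points (decades by default).
#' @param dedupe_patients forwarded to [dosage_by_status()].
#' @return a `cypddi_bundle` object: a list with the rule identity, the
#'   period, `n_patients`, and elements `time_series`, `sex`, `age`,
#'   `units`, `dosage_coverage`, `dosage_status`.
#' @export
build_dashboard <- function(hits, rule, patients, labs, analyte_map,
                            period = NULL, bin = "month",
                            window = "same_stay",
                            age_bands = c(seq(0, 90, by = 10), 120),
                            dedupe_patients = FALSE) {
  stopifnot(nrow(rule) == 1L)
  period <- as_period(period %||% attr(hits, "period"))
  h <- hits |> filter(.data$rule_id == rule$rule_id)
  attr(h, "period") <- period
  analytes <- mapped_analytes(analyte_map, rule$substrate, "dosage")
  demo <- hit_demographics(h, patients, age_bands)
  structure(list(
    rule_id = rule$rule_id,
    cytochrome = rule$cytochrome,
    substrate = rule$substrate,
    relation = rule$relation,
    perpetrator = rule$perpetrator,
    period = period,
    bin = bin,
    n_patients = dplyr::n_distinct(h$patient_id),
    time_series = hit_time_series(h, bin = bin, period = period),
    sex = demo$sex,
    age = demo$age,
    units = hit_unit_breakdown(h),
    dosage_coverage = dosage_coverage(h, labs, analytes, window = window,
                                      period = period),
    dosage_status = dosage_by_status(h, labs, analytes, window = window,
                                     period = period,
                                     dedupe_patients = dedupe_patients)
  ), class = "cypddi_bundle")
}

#' @export
print.cypddi_bundle <- function(x, ...) {
  cat(sprintf("<interaction dashboard> %s: %s %s %s\n", x$cytochrome,
              x$substrate, x$relation, x$perpetrator))
  cat(sprintf("  period %s .. %s | %d affected patient(s)\n",
              x$period[1], x$period[2], x$n_patients))
  cov <- if (is.na(x$dosage_coverage)) "n/a" else
    sprintf("%.1f%%", 100 * x$dosage_coverage)
  cat(sprintf("  dosage coverage: %s | %d matched dosage event(s)\n",
              cov, sum(x$dosage_status$n)))
  invisible(x)
}

#' Tidy a dashboard bundle into one long tibble
#'
#' @param x a `cypddi_bundle`.
#' @param ... unused.
#' @return tibble with columns `panel`, `key`, `value` covering all five
#'   panels (coverage reported as a proportion under key `"coverage"`).
#' @export
tidy.cypddi_bundle <- function(x, ...) {
  bind_rows(
    x$time_series |>
      transmute(panel = "time_series", key = as.character(.data$bin_start),
                value = as.numeric(.data$n_patients)),
    x$sex |>
      transmute(panel = "sex", key = .data$sex, value = as.numeric(.data$n)),
    x$age |>
      transmute(panel = "age", key = .data$band, value = as.numeric(.data$n)),
    x$units |>
      transmute(panel = "unit", key = .data$unit,
                value = as.numeric(.data$n_patients)),
    tibble(panel = "coverage", key = "coverage",
           value = as.numeric(x$dosage_coverage)),
    x$dosage_status |>
      transmute(panel = "status", key = .data$status,
                value = as.numeric(.data$n))
  )
}

#' One-row overview of a dashboard bundle
#'
#' @param x a `cypddi_bundle`.
#' @param ... unused.
#' @return one-row tibble: rule identity, period bounds, `n_patients`,
#'   `dosage_coverage`, `n_dosage_events`.
#' @export
glance.cypddi_bundle <- function(x, ...) {
  tibble(
    rule_id = x$rule_id, cytochrome = x$cytochrome,
    substrate = x$substrate, relation = x$relation,
    perpetrator = x$perpetrator,
    period_start = x$period[1], period_end = x$period[2],
    n_patients = x$n_patients,
    dosage_coverage = x$dosage_coverage,
    n_dosage_events = sum(x$dosage_status$n))
}

#' Export a dashboard bundle
#'
#' `format = "json"` writes a schema-stable JSON document (the schema ships
#' at `system.file("extdata", "bundle-schema.json", package = "cypddi")`)
#' that [read_bundle()] round-trips exactly; `format = "html"` writes a
#' self-contained HTML report rendering the five panels with inline CSS (no
#' external assets).
#'
#' @param bundle a `cypddi_bundle`.
#' @param path output file.
#' @param format `"json"` or `"html"`.
#' @return `path`, invisibly.
#' @export
export_bundle <- function(bundle, path, format = c("json", "html")) {
  format <- rlang::arg_match(format)
  if (format == "json") {
    doc <- list(
      schema = "cypddi-bundle/1",
      rule_id = bundle$rule_id,
      cytochrome = bundle$cytochrome,
      substrate = bundle$substrate,
      relation = bundle$relation,
      perpetrator = bundle$perpetrator,
      period = as.character(bundle$period),
      bin = bundle$bin,
      n_patients = bundle$n_patients,
      time_series = bundle$time_series |>
        mutate(bin_start = as.character(.data$bin_start)),
      sex = bundle$sex,
      age = bundle$age,
      units = bundle$units,
      dosage_coverage = if (is.na(bundle$dosage_coverage)) NULL else
        bundle$dosage_coverage,
      dosage_status = bundle$dosage_status)
    ok <- tryCatch({
      jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                           null = "null", dataframe = "rows")
      TRUE
    }, error = function(e) {
      abort(sprintf("failed to write bundle to '%s': %s", path,
                    conditionMessage(e)), class = "cypddi_io_error")
    })
  } else {
    writeLines(render_bundle_html(bundle), path)
  }
  invisible(path)
}

#' Re-import an exported dashboard bundle
#'
#' @param path a JSON file written by [export_bundle()].
#' @return a `cypddi_bundle` equal to the exported one.
#' @export
read_bundle <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tbl <- function(x, template) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L)
      return(template)
    as_tibble(x)
  }
  structure(list(
    rule_id = as.integer(doc$rule_id),
    cytochrome = doc$cytochrome,
    substrate = doc$substrate,
    relation = doc$relation,
    perpetrator = doc$perpetrator,
    period = as.Date(doc$period),
    bin = doc$bin,
    n_patients = as.integer(doc$n_patients),
    time_series = as_tbl(doc$time_series,
                         tibble(bin_start = as.Date(character()),
                                n_patients = integer())) |>
      mutate(bin_start = as.Date(.data$bin_start),
             n_patients = as.integer(.data$n_patients)),
    sex = as_tbl(doc$sex, tibble(sex = character(), n = integer())) |>
      mutate(n = as.integer(.data$n)),
    age = as_tbl(doc$age, tibble(band = character(), n = integer())) |>
      mutate(n = as.integer(.data$n)),
    units = as_tbl(doc$units,
                   tibble(unit = character(), n_patients = integer())) |>
      mutate(n_patients = as.integer(.data$n_patients)),
    dosage_coverage = if (is.null(doc$dosage_coverage)) NA_real_ else
      as.numeric(doc$dosage_coverage),
    dosage_status = as_tbl(doc$dosage_status,
                           tibble(status = character(), n = integer())) |>
      mutate(n = as.integer(.data$n))
  ), class = "cypddi_bundle")
}

#' Validate an exported bundle JSON file against the shipped schema
#'
#' Structural check: required properties present, types as declared in
#' `inst/extdata/bundle-schema.json` (objects, arrays of row objects, number
#' ranges for the coverage proportion).
#'
#' @param path path to a bundle JSON file.
#' @return `TRUE` invisibly on success; aborts with the first violation
#'   otherwise.
#' @export
validate_bundle_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  schema <- jsonlite::read_json(
    system.file("extdata", "bundle-schema.json", package = "cypddi"),
    simplifyVector = FALSE)
  fail <- function(msg) abort(sprintf("bundle schema violation: %s", msg),
                              class = "cypddi_schema_error")
  props <- schema$properties
  for (req in unlist(schema$required)) {
    if (!req %in% names(doc)) fail(sprintf("missing required field '%s'", req))
  }
  check_type <- function(value, spec, where) {
    type <- spec$type
    ok <- switch(type,
      string = is.character(value) && length(value) == 1L,
      integer = is.numeric(value) && length(value) == 1L &&
        value == as.integer(value),
      number = is.numeric(value) && length(value) == 1L,
      array = is.list(value) || is.null(value),
      TRUE)
    if (!ok) fail(sprintf("field '%s' is not of type %s", where, type))
    if (type == "number" && !is.null(spec$minimum) && value < spec$minimum)
      fail(sprintf("field '%s' below minimum %s", where, spec$minimum))
    if (type == "number" && !is.null(spec$maximum) && value > spec$maximum)
      fail(sprintf("field '%s' above maximum %s", where, spec$maximum))
    if (type == "array" && !is.null(spec$items$required)) {
      for (row in value) {
        for (col in unlist(spec$items$required)) {
          if (!col %in% names(row))
            fail(sprintf("row of '%s' missing column '%s'", where, col))
        }
      }
    }
  }
  for (name in names(props)) {
    if (name %in% names(doc) && !is.null(doc[[name]])) {
      check_type(doc[[name]], props[[name]], name)
    }
  }
  invisible(TRUE)
}

# self-contained HTML report: tables + pure-CSS bars, no external assets
render_bundle_html <- function(b) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  bar_table <- function(df, key, val, title) {
    if (nrow(df) == 0L) {
      return(sprintf("<h2>%s</h2><p class='empty'>no data</p>", esc(title)))
    }
    mx <- max(df[[val]], 1)
    rows <- paste0(sprintf(
      "<tr><td>%s</td><td>%s</td><td><div class='bar' style='width:%.0fpx'></div></td></tr>",
      esc(as.character(df[[key]])), df[[val]], 220 * df[[val]] / mx),
      collapse = "\n")
    sprintf("<h2>%s</h2><table>%s</table>", esc(title), rows)
  }
  cov <- if (is.na(b$dosage_coverage)) "n/a" else
    sprintf("%.1f%%", 100 * b$dosage_coverage)
  paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>", esc(b$substrate), " / ", esc(b$perpetrator), "</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td{padding:2px 8px;border-bottom:1px solid #ddd}",
    ".bar{background:#4878a8;height:12px}.empty{color:#888}",
    ".gauge{font-size:2em;color:#2a6f4e}</style></head><body>",
    sprintf("<h1>%s &mdash; %s %s %s</h1>", esc(b$cytochrome),
            esc(b$substrate), esc(b$relation), esc(b$perpetrator)),
    sprintf("<p>Period %s to %s &middot; %d affected patient(s)</p>",
            b$period[1], b$period[2], b$n_patients),
    bar_table(b$time_series, "bin_start", "n_patients",
              "Affected patients over time"),
    bar_table(b$sex, "sex", "n", "Distribution by sex"),
    bar_table(b$age, "band", "n", "Distribution by age band"),
    bar_table(b$units, "unit", "n_patients", "Distribution by medical unit"),
    "<h2>Pharmacology dosage coverage</h2><p class='gauge'>", cov, "</p>",
    bar_table(b$dosage_status, "status", "n", "Dosage results by status"),
    "</body></html>")
}
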