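#' Configure a full detection run
#'
#' Bundles the file paths and analysis options of one end-to-end run. The
#' two analysis windows are mandatory: drug-drug co-prescriptions are
#' screened over `period_dd`, drug-genotype pairings over `period_dg`
#' (typically a longer window, so genotyping panels accumulate patients).
#' Referenced files are checked for existence at validation time.
#'
#' @param kb,formulary,prescriptions,labs,patients,analyte_map input paths.
#' @param period_dd,period_dg analysis windows (length-2 dates).
#' @param out_dir output directory (created if needed).
#' @param join_on co-occurrence granularity, `"day"` or `"stay_day"`.
#' @param top_n number of top-ranked rules (by patients, across both
#'   analyses) given dashboard bundles.
#' @param bin time-series bin for dashboards.
#' @param dosage_window dosage matching window for dashboards.
#' @param format dashboard export format, `"json"` or `"html"`.
#' @return a validated `cypddi_run_config` list.
#' @export
run_config <- function(kb, formulary, prescriptions, labs, patients,
                       analyte_map, period_dd, period_dg, out_dir,
                       join_on = "day", top_n = 10L, bin = "month",
                       dosage_window = "same_stay", format = "json") {
  paths <- list(kb = kb, formulary = formulary, prescriptions = prescriptions,
                labs = labs, patients = patients, analyte_map = analyte_map)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      abort(sprintf("input file for '%s' not found: %s", nm, paths[[nm]]),
            class = "cypddi_config_error")
    }
  }
  structure(c(paths, list(
    period_dd = as_period(period_dd), period_dg = as_period(period_dg),
    out_dir = out_dir, join_on = join_on, top_n = as.integer(top_n),
    bin = bin, dosage_window = dosage_window, format = format)),
    class = "cypddi_run_config")
}

#' Run the full interaction-screening pipeline
#'
#' Executes every stage in order: load and validate the knowledge base,
#' remove self-interactions, filter to the institutional formulary, export
#' the co-prescription queries, detect drug-drug hits over `period_dd` and
#' drug-genotype hits over `period_dg`, write ranked summary tables
#' (kept separate so drug interactions and pharmacogenetic/drug
#' combinations are clearly distinguished), build dashboard bundles for the
#' `top_n` rules by affected patients, and write a machine-readable run
#' report. The analysis path is fully deterministic: identical inputs give
#' checksum-identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a `cypddi_run_report` list with stage counts, output
#'   paths, the configuration hash and the package version. Any stage
#'   failure aborts with the stage name and cause.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cypddi_run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "cypddi_pipeline_error", parent = e)
    })
  }

  # 1. knowledge base validation
  rules_raw <- stage("validate-kb",
                     read_interaction_kb(config$kb, strict = FALSE))
  write_validation_report(kb_issues(rules_raw),
                          file.path(out_dir, "kb_validation_report.jsonl"))

  # 2-3. self-interaction and formulary filters
  parts <- stage("filter", remove_self_interactions(rules_raw))
  formulary <- stage("filter", read_formulary(config$formulary))
  rules <- stage("filter", filter_to_formulary(parts$kept, formulary))
  combos_before <- count_code_combinations(parts$kept)
  combos_after <- count_code_combinations(rules)

  # 4. query export
  stage("queries", write_query_export(
    rules, file.path(out_dir, "queries.txt"),
    file.path(out_dir, "query_manifest.tsv")))

  # 5. detection, drug-drug and drug-genotype windows separately
  rx <- stage("detect", read_prescriptions(config$prescriptions))
  labs <- stage("detect", read_lab_events(config$labs))
  patients <- stage("detect", read_patients(config$patients))
  analyte_map <- stage("detect", read_analyte_map(config$analyte_map))

  rules_dd <- rules |> filter(.data$relation != "mutation")
  rules_dg <- rules |> filter(.data$relation == "mutation")
  hits_dd <- stage("detect", detect_interactions(
    rules_dd, rx, labs, period = config$period_dd,
    analyte_map = analyte_map, join_on = config$join_on))
  hits_dg <- stage("detect", detect_interactions(
    rules_dg, rx, labs, period = config$period_dg,
    analyte_map = analyte_map, join_on = config$join_on))
  write_hits(hits_dd, file.path(out_dir, "hits_drug_drug.tsv"))
  write_hits(hits_dg, file.path(out_dir, "hits_drug_genotype.tsv"))

  summary_dd <- rank_rules(summarize_interactions(hits_dd, rules_dd))
  summary_dg <- rank_rules(summarize_interactions(hits_dg, rules_dg))
  write_summary_table(summary_dd,
                      file.path(out_dir, "summary_drug_drug.tsv"))
  write_summary_table(summary_dg,
                      file.path(out_dir, "summary_drug_genotype.tsv"))

  # 6. dashboards for the top-N rules by affected patients
  dash_dir <- file.path(out_dir, "dashboards")
  if (!dir.exists(dash_dir)) dir.create(dash_dir)
  top <- bind_rows(
    summary_dd |> mutate(analysis = "dd"),
    summary_dg |> mutate(analysis = "dg")) |>
    filter(.data$n_patients > 0L) |>
    rank_rules() |>
    slice_head(n = config$top_n)
  bundle_paths <- character(0)
  for (i in seq_len(nrow(top))) {
    row <- top[i, ]
    is_dd <- row$analysis == "dd"
    bundle <- stage("dashboard", build_dashboard(
      if (is_dd) hits_dd else hits_dg,
      rules |> filter(.data$rule_id == row$rule_id),
      patients, labs, analyte_map,
      period = if (is_dd) config$period_dd else config$period_dg,
      bin = config$bin, window = config$dosage_window))
    ext <- if (config$format == "html") "html" else "json"
    path <- file.path(dash_dir, sprintf("rule_%04d.%s", row$rule_id, ext))
    export_bundle(bundle, path, format = ext)
    bundle_paths <- c(bundle_paths, path)
  }

  # 7. run report
  report <- list(
    package_version = as.character(utils::packageVersion("cypddi")),
    config_hash = config_hash(unclass(config)),
    periods = list(dd = as.character(config$period_dd),
                   dg = as.character(config$period_dg)),
    counts = list(
      kb_rows = nrow(rules_raw),
      kb_issues = nrow(kb_issues(rules_raw)),
      self_pairs_removed = nrow(parts$removed),
      rules_after_self_filter = nrow(parts$kept),
      formulary_codes = length(formulary),
      rules_after_formulary = nrow(rules),
      combinations_before_formulary = combos_before,
      combinations_after_formulary = combos_after,
      hits_drug_drug = nrow(hits_dd),
      hits_drug_genotype = nrow(hits_dg),
      dashboards = length(bundle_paths)),
    outputs = list(
      validation_report = file.path(out_dir, "kb_validation_report.jsonl"),
      queries = file.path(out_dir, "queries.txt"),
      query_manifest = file.path(out_dir, "query_manifest.tsv"),
      hits_drug_drug = file.path(out_dir, "hits_drug_drug.tsv"),
      hits_drug_genotype = file.path(out_dir, "hits_drug_genotype.tsv"),
      summary_drug_drug = file.path(out_dir, "summary_drug_drug.tsv"),
      summary_drug_genotype = file.path(out_dir, "summary_drug_genotype.tsv"),
      dashboards = bundle_paths))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(report, class = "cypddi_run_report")
}

#' @export
print.cypddi_run_report <- function(x, ...) {
  cat("<interaction screening run>\n")
  cat(sprintf("  KB: %d rows, %d self-pairs removed, %d rules after formulary filter\n",
              x$counts$kb_rows, x$counts$self_pairs_removed,
              x$counts$rules_after_formulary))
  cat(sprintf("  code combinations: %s before, %s after formulary filter\n",
              format(x$counts$combinations_before_formulary, big.mark = ","),
              format(x$counts$combinations_after_formulary, big.mark = ",")))
  cat(sprintf("  hits: %d drug-drug, %d drug-genotype; %d dashboard(s)\n",
              x$counts$hits_drug_drug, x$counts$hits_drug_genotype,
              x$counts$dashboards))
  invisible(x)
}

#' One-row overview of a run report
#'
#' @param x a `cypddi_run_report`.
#' @param ... unused.
#' @return one-row tibble of the stage counts.
#' @export
glance.cypddi_run_report <- function(x, ...) {
  as_tibble(x$counts)
}
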