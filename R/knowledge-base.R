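#' Read a CYP450 interaction knowledge base
#'
#' Loads the interaction table exported from a terminology source: one row per
#' (cytochrome, substrate, relation, perpetrator) combination, with the
#' dispensing codes of both substances packed into delimiter-separated cells.
#'
#' The file must have a header with six required columns:
#' `cytochrome`, `substrate`, `relation`, `perpetrator`, `substrate_ucd`,
#' `perpetrator_ucd`. The two `*_ucd` cells hold UCD codes joined by the
#' literal separator `" or "` (the dialect of the source export); an
#' alternative separator can be configured. `relation` must be one of
#' `p_inhib` (enzyme inhibition), `p_induc` (enzyme induction) or `mutation`
#' (pairing of a substrate prescription with a pharmacogenetic genotyping
#' act); for `mutation` rows the `perpetrator_ucd` cell may be empty, since
#' the perpetrator is a laboratory act, not a drug.
#'
#' Substance labels are canonicalized with [canonical_label()]. The loader is
#' strictly 1:1 with file rows: duplicated rows are kept (deduplication, if
#' wanted, is an explicit downstream step) but surfaced in the validation
#' report, as are malformed codes and duplicate codes within one cell
#' (the latter are dropped from the list, first occurrence kept).
#'
#' @param path path to a TSV or CSV file. The delimiter is taken from the
#'   extension (`.csv` = comma, otherwise tab) unless `delim` is given.
#' @param delim field delimiter override.
#' @param code_sep separator between codes inside a cell (default `" or "`).
#' @param strict if `TRUE` (default) malformed codes or unknown relation
#'   values abort with a validation error naming row and value; if `FALSE`
#'   the offending codes are dropped, offending relation rows removed, and all
#'   issues returned in the `"issues"` attribute (see [kb_issues()]).
#' @return a tibble of interaction rules with columns `rule_id` (integer row
#'   number in the source file), `cytochrome`, `substrate`, `relation`,
#'   `perpetrator`, and list-columns `substrate_codes`, `perpetrator_codes`.
#' @seealso [remove_self_interactions()], [filter_to_formulary()],
#'   [count_code_combinations()]
#' @export
#' @examples
#' kb <- read_interaction_kb(system.file("extdata", "example_kb.tsv",
#'                                       package = "cypddi"))
#' lengths(kb$substrate_codes)
read_interaction_kb <- function(path, delim = NULL, code_sep = " or ",
                                strict = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("knowledge-base file not found: %s", path),
          class = "cypddi_io_error")
  }
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), trim_ws = TRUE, progress = FALSE)
  required <- c("cytochrome", "substrate", "relation", "perpetrator",
                "substrate_ucd", "perpetrator_ucd")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("knowledge base is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "cypddi_schema_error")
  }

  n <- nrow(raw)
  issues <- list()
  note <- function(row, column, value, issue) {
    issues[[length(issues) + 1L]] <<- tibble(
      row = row, column = column, value = value, issue = issue)
  }

  split_codes <- function(cell, row, column) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
    codes <- trimws(strsplit(cell, code_sep, fixed = TRUE)[[1]])
    codes <- codes[nzchar(codes)]
    bad <- codes[!is_ucd_code(codes)]
    for (b in bad) note(row, column, b, "malformed_code")
    codes <- codes[is_ucd_code(codes)]
    if (anyDuplicated(codes)) {
      for (d in unique(codes[duplicated(codes)])) {
        note(row, column, d, "duplicate_code_in_list")
      }
      codes <- codes[!duplicated(codes)]
    }
    codes
  }

  relation <- tolower(trimws(raw$relation))
  rules <- tibble(
    rule_id = seq_len(n),
    cytochrome = trimws(raw$cytochrome),
    substrate = canonical_label(raw$substrate),
    relation = relation,
    perpetrator = canonical_label(raw$perpetrator),
    substrate_codes = purrr::map(seq_len(n), function(i)
      split_codes(raw$substrate_ucd[i], i, "substrate_ucd")),
    perpetrator_codes = purrr::map(seq_len(n), function(i)
      split_codes(raw$perpetrator_ucd[i], i, "perpetrator_ucd"))
  )

  bad_rel <- which(!relation %in% RELATION_LEVELS)
  for (i in bad_rel) note(i, "relation", raw$relation[i], "unknown_relation")
  empty_perp <- which(relation != "mutation" &
                        lengths(rules$perpetrator_codes) == 0L &
                        !seq_len(n) %in% bad_rel)
  for (i in empty_perp) note(i, "perpetrator_ucd", "", "empty_perpetrator_codes")

  dup_rows <- which(duplicated(raw))
  for (i in dup_rows) note(i, "(row)", "", "duplicate_row")

  issues <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble(row = integer(), column = character(),
           value = character(), issue = character())

  hard <- issues$issue %in% c("malformed_code", "unknown_relation")
  if (strict && any(hard)) {
    first <- issues[hard, ][1, ]
    abort(sprintf(
      "invalid knowledge base: %d issue(s); first: row %d, column %s, value '%s' (%s). Use strict = FALSE to load anyway.",
      sum(hard), first$row, first$column, first$value, first$issue),
      class = "cypddi_validation_error")
  }
  if (length(bad_rel)) rules <- rules[-bad_rel, ]

  attr(rules, "issues") <- issues
  rules
}

#' Validation issues collected while loading a knowledge base
#'
#' @param rules a rules tibble from [read_interaction_kb()].
#' @return tibble with columns `row`, `column`, `value`, `issue`.
#' @export
kb_issues <- function(rules) {
  attr(rules, "issues") %||%
    tibble(row = integer(), column = character(),
           value = character(), issue = character())
}

#' Write a validation report as JSON lines
#'
#' One JSON object per issue, `{"row": .., "column": .., "value": ..,
#' "issue": ..}`, so reports stream into log pipelines.
#'
#' @param issues tibble as returned by [kb_issues()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(issues, path) {
  lines <- purrr::map_chr(seq_len(nrow(issues)), function(i)
    jsonlite::toJSON(as.list(issues[i, ]), auto_unbox = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read an institutional formulary
#'
#' A formulary is the flat list of dispensing (UCD) codes in use at one
#' institution: one code per line; blank lines and lines starting with `#`
#' are ignored.
#'
#' @param path path to the formulary file.
#' @return character vector of unique, validated 13-digit codes.
#' @export
read_formulary <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("formulary file not found: %s", path),
          class = "cypddi_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  codes <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bad <- codes[!is_ucd_code(codes)]
  if (length(bad)) {
    abort(sprintf("formulary contains %d malformed code(s), e.g. '%s'",
                  length(bad), bad[1]),
          class = "cypddi_validation_error")
  }
  unique(codes)
}

#' Remove rules whose substrate and perpetrator are the same molecule
#'
#' A knowledge-base export can pair a molecule with itself (the same substance
#' listed as both substrate and inhibitor/inducer); such rows carry no
#' co-prescription signal and are removed before querying. Comparison is on
#' canonical labels.
#'
#' @param rules a rules tibble.
#' @return list with elements `kept` and `removed`, each a rules tibble;
#'   together they partition the input, original order preserved.
#' @export
#' @examples
#' kb <- tibble::tibble(
#'   rule_id = 1:2, cytochrome = "CYP3A4",
#'   substrate = c("X", "X"), relation = "p_inhib",
#'   perpetrator = c("X", "Y"),
#'   substrate_codes = list("3400000000001", "3400000000001"),
#'   perpetrator_codes = list("3400000000002", "3400000000003"))
#' remove_self_interactions(kb)$removed$rule_id
remove_self_interactions <- function(rules) {
  self <- canonical_label(rules$substrate) == canonical_label(rules$perpetrator)
  list(kept = rules[!self, , drop = FALSE],
       removed = rules[self, , drop = FALSE])
}

#' Restrict a knowledge base to an institutional formulary
#'
#' Intersects each rule's substrate and perpetrator code lists with the
#' formulary, preserving the original code order. Rules whose substrate side
#' becomes empty are dropped; rules whose perpetrator side becomes empty are
#' dropped unless the relation is `mutation` (where the perpetrator is a
#' genotyping act, not a drug).
#'
#' @param rules a rules tibble.
#' @param formulary character vector of UCD codes (see [read_formulary()]).
#' @return the filtered rules tibble. Idempotent; enlarging the formulary
#'   never shrinks the result.
#' @export
filter_to_formulary <- function(rules, formulary) {
  if (length(formulary) == 0L) {
    abort("empty formulary: supply the institutional code list (an empty intersection would silently drop every rule).",
          class = "cypddi_config_error")
  }
  out <- rules |>
    mutate(
      substrate_codes = purrr::map(.data$substrate_codes,
                                   ~ .x[.x %in% formulary]),
      perpetrator_codes = purrr::map(.data$perpetrator_codes,
                                     ~ .x[.x %in% formulary])
    ) |>
    filter(lengths(.data$substrate_codes) > 0L,
           lengths(.data$perpetrator_codes) > 0L | .data$relation == "mutation")
  attr(out, "issues") <- attr(rules, "issues")
  out
}

#' Count possible code-level interaction combinations
#'
#' Every (substrate code, perpetrator code) pair of every rule is one
#' possible interaction combination; a single substance can have many
#' dispensing codes, so this count greatly exceeds the number of substance
#' pairs. Mutation rules (empty perpetrator code list) contribute zero.
#'
#' @param rules a rules tibble.
#' @return a single non-negative number: sum over rules of
#'   `|substrate_codes| * |perpetrator_codes|`.
#' @export
count_code_combinations <- function(rules) {
  sum(as.numeric(lengths(rules$substrate_codes)) *
        as.numeric(lengths(rules$perpetrator_codes)))
}
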