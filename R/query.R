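#' Build the boolean co-prescription query for a drug-drug rule
#'
#' Renders a rule as the two-clause boolean query used to interrogate a data
#' warehouse for co-prescriptions:
#' `"(UCD1 or UCD2 or ...) and (UCD3 or UCD4 or ...)"` — the first clause
#' holds the substrate's dispensing codes, the second the inhibitor/inducer's,
#' in knowledge-base order. The dialect is frozen: lowercase `" or "` /
#' `" and "`, one pair of parentheses per clause, no nesting.
#'
#' @param rule a single interaction rule: one row of a rules tibble (or any
#'   list with non-empty `substrate_codes` and `perpetrator_codes`).
#' @return a `cypddi_query`: list with `substrate`, `perpetrator` (character
#'   vectors of codes) and `text` (the rendered string).
#' @seealso [parse_query()], [evaluate_query()]
#' @export
#' @examples
#' q <- build_query(list(substrate_codes = list(c("1111111111111")),
#'                       perpetrator_codes = list(c("2222222222222"))))
#' q$text
build_query <- function(rule) {
  sub <- unlist(rule$substrate_codes, use.names = FALSE)
  perp <- unlist(rule$perpetrator_codes, use.names = FALSE)
  if (length(sub) == 0L || length(perp) == 0L) {
    abort(
      "cannot render a two-drug query: one side has no codes (mutation rules pair a prescription with a genotyping act and are handled by detect_interactions(), not rendered).",
      class = "cypddi_unsupported_rule")
  }
  new_query(sub, perp)
}

new_query <- function(substrate, perpetrator) {
  structure(
    list(substrate = substrate, perpetrator = perpetrator,
         text = render_clauses(substrate, perpetrator)),
    class = "cypddi_query")
}

render_clauses <- function(substrate, perpetrator) {
  paste0("(", paste(substrate, collapse = " or "), ") and (",
         paste(perpetrator, collapse = " or "), ")")
}

#' @export
print.cypddi_query <- function(x, ...) {
  cat("<co-prescription query> ", length(x$substrate), " substrate code(s) x ",
      length(x$perpetrator), " perpetrator code(s)\n", sep = "")
  cat(x$text, "\n")
  invisible(x)
}

#' @export
format.cypddi_query <- function(x, ...) x$text

#' Parse a rendered co-prescription query
#'
#' Inverse of [build_query()]: recovers the two ordered code lists from the
#' fixed-dialect string. Parsing then rendering is the identity, and so is
#' rendering then parsing.
#'
#' @param text a query string `"(c1 or c2) and (c3 or c4)"` whose atoms are
#'   13-digit codes.
#' @return a `cypddi_query`.
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pos <- 1L
  fail <- function(msg, at) {
    abort(sprintf("query parse error at character %d: %s", at, msg),
          class = "cypddi_parse_error")
  }
  expect_lit <- function(lit) {
    end <- pos + nchar(lit) - 1L
    if (end > nchar(text) || substr(text, pos, end) != lit) {
      fail(sprintf("expected '%s'", lit), pos)
    }
    pos <<- end + 1L
  }
  parse_clause <- function() {
    expect_lit("(")
    close <- regexpr(")", substr(text, pos, nchar(text)), fixed = TRUE)
    if (close == -1L) fail("unbalanced parentheses: missing ')'", nchar(text) + 1L)
    inner <- substr(text, pos, pos + close - 2L)
    codes <- strsplit(inner, " or ", fixed = TRUE)[[1]]
    offset <- pos
    for (code in codes) {
      if (!is_ucd_code(code)) {
        fail(sprintf("'%s' is not a 13-digit code", code), offset)
      }
      offset <- offset + nchar(code) + nchar(" or ")
    }
    if (length(codes) == 0L) fail("empty clause", pos)
    pos <<- pos + close
    codes
  }
  substrate <- parse_clause()
  expect_lit(" and ")
  perpetrator <- parse_clause()
  if (pos <= nchar(text)) fail("stray trailing characters", pos)
  new_query(substrate, perpetrator)
}

#' Evaluate a co-prescription query against a set of codes
#'
#' In-process equivalent of submitting the query to a warehouse service:
#' returns `TRUE` iff at least one substrate code and at least one
#' perpetrator code are both present. Monotone in `present_codes`.
#'
#' @param query a `cypddi_query`.
#' @param present_codes character vector of codes present (e.g. all codes
#'   prescribed to one patient on one day).
#' @return logical scalar.
#' @export
evaluate_query <- function(query, present_codes) {
  stopifnot(inherits(query, "cypddi_query"))
  any(query$substrate %in% present_codes) &&
    any(query$perpetrator %in% present_codes)
}

#' Export rendered queries with a rule manifest
#'
#' Writes one rendered query per line for every drug-drug rule, plus a TSV
#' manifest (`rule_id`, `cytochrome`, `substrate`, `relation`, `perpetrator`)
#' aligned line-for-line with the query file. Mutation rules are skipped.
#'
#' @param rules a rules tibble.
#' @param queries_path,manifest_path output paths.
#' @return invisibly, the tibble of exported rules with a `query` column.
#' @export
write_query_export <- function(rules, queries_path, manifest_path) {
  dd <- rules |> filter(.data$relation != "mutation")
  out <- dd |>
    mutate(query = purrr::map_chr(seq_len(nrow(dd)), function(i)
      build_query(dd[i, ])$text))
  writeLines(out$query, queries_path)
  readr::write_tsv(
    out |> select("rule_id", "cytochrome", "substrate", "relation", "perpetrator"),
    manifest_path)
  invisible(out)
}
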