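example_kb_path <- system.file("extdata", "example_kb.tsv", package = "cypddi")

test_that("the worked-example KB row loads with 13 substrate and 12 perpetrator codes", {
  kb <- read_interaction_kb(example_kb_path)
  expect_equal(nrow(kb), 1L)
  expect_equal(lengths(kb$substrate_codes), 13L)
  expect_equal(lengths(kb$perpetrator_codes), 12L)
  expect_equal(kb$substrate, "FLECAINID")
  expect_equal(kb$perpetrator, "NORFLOXACIN")
  expect_equal(kb$relation, "p_inhib")
  expect_true(all(is_ucd_code(unlist(kb$substrate_codes))))
  expect_equal(nrow(kb_issues(kb)), 0L)
})

test_that("loader is 1:1 with rows: header-only file is empty, duplicates kept", {
  header <- "cytochrome\tsubstrate\trelation\tperpetrator\tsubstrate_ucd\tperpetrator_ucd"
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(header, path)
  expect_equal(nrow(read_interaction_kb(path)), 0L)

  row <- "CYP3A4\tParacetamol\tp_induc\tCarbamazepine\t3400000000001\t3400000000002"
  writeLines(c(header, row, row,
               "CYP2D6\tOxycodone\tp_inhib\tParoxetine\t3400000000003\t3400000000004"),
             path)
  kb <- read_interaction_kb(path)
  expect_equal(nrow(kb), 3L)  # no deduplication at load time
  expect_true("duplicate_row" %in% kb_issues(kb)$issue)
  # labels are case-folded to one canonical case
  expect_equal(kb$substrate[1], "PARACETAMOL")
})

test_that("schema and validation errors name the column, row and value", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cytochrome\tsubstrate\trelation\tperpetrator\tsubstrate_ucd",
               "CYP3A4\tA\tp_inhib\tB\t3400000000001"), path)
  expect_error(read_interaction_kb(path), "perpetrator_ucd",
               class = "cypddi_schema_error")

  writeLines(c("cytochrome\tsubstrate\trelation\tperpetrator\tsubstrate_ucd\tperpetrator_ucd",
               "CYP3A4\tA\tp_inhib\tB\tBADCODE\t3400000000002"), path)
  expect_error(read_interaction_kb(path), "row 1.*BADCODE",
               class = "cypddi_validation_error")

  kb <- read_interaction_kb(path, strict = FALSE)
  issues <- kb_issues(kb)
  expect_true("malformed_code" %in% issues$issue)
  expect_true(all(c("row", "column", "value", "issue") %in% names(issues)))
  expect_equal(issues$value[issues$issue == "malformed_code"], "BADCODE")

  report <- withr::local_tempfile(fileext = ".jsonl")
  write_validation_report(issues, report)
  parsed <- lapply(readLines(report), jsonlite::fromJSON)
  expect_equal(length(parsed), nrow(issues))
  expect_equal(parsed[[1]]$issue, "malformed_code")
})

test_that("mutation rows may have an empty perpetrator code cell", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cytochrome\tsubstrate\trelation\tperpetrator\tsubstrate_ucd\tperpetrator_ucd",
               "CYP3A5\tTacrolimus\tMutation\tGenotype CYP3A5\t3400000000001\t"),
             path)
  kb <- read_interaction_kb(path)
  expect_equal(kb$relation, "mutation")
  expect_equal(lengths(kb$perpetrator_codes), 0L)
  expect_equal(nrow(kb_issues(kb)), 0L)
})

test_that("formulary reader skips comments and rejects malformed codes", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# institutional codes", "3400000000001", "",
               "3400000000002", "3400000000001"), path)
  expect_equal(read_formulary(path), c("3400000000001", "3400000000002"))
  writeLines(c("3400000000001", "oops"), path)
  expect_error(read_formulary(path), "oops", class = "cypddi_validation_error")
})

test_that("self-interaction removal partitions the rules by label identity", {
  rules <- make_rules(c("X", "X"), c("X", "Y"),
                      list("3400000000001", "3400000000001"),
                      list("3400000000002", "3400000000003"))
  parts <- remove_self_interactions(rules)
  expect_equal(parts$removed$rule_id, 1L)
  expect_equal(parts$kept$rule_id, 2L)

  empty <- rules[0, ]
  parts0 <- remove_self_interactions(empty)
  expect_equal(nrow(parts0$kept), 0L)
  expect_equal(nrow(parts0$removed), 0L)

  # 100 generated rules with 7 planted self-pairs: brute-force label oracle
  withr::with_seed(42, {
    kb <- random_kb(100, n_self = 7)
    parts <- remove_self_interactions(kb)
    oracle <- mapply(function(s, p) toupper(s) == toupper(p),
                     kb$substrate, kb$perpetrator)
    expect_equal(nrow(parts$removed), 7L)
    expect_equal(parts$removed$rule_id, kb$rule_id[oracle])
    # partition: kept + removed == input, order preserved and disjoint
    expect_equal(sort(c(parts$kept$rule_id, parts$removed$rule_id)),
                 kb$rule_id)
    expect_equal(dplyr::bind_rows(parts$kept, parts$removed) |>
                   dplyr::arrange(rule_id),
                 kb)
  })
})

test_that("formulary filter intersects codes and drops emptied rules", {
  a <- "3400000000001"; b <- "3400000000002"; c_ <- "3400000000003"
  rules <- make_rules("S", "P", list(c(a, b)), list(c_))
  out <- filter_to_formulary(rules, c(a, c_))
  expect_equal(out$substrate_codes[[1]], a)
  expect_equal(out$perpetrator_codes[[1]], c_)

  # perpetrator side emptied on a p_inhib rule: dropped
  expect_equal(nrow(filter_to_formulary(rules, a)), 0L)
  # same situation on a mutation rule: kept
  mut <- make_rules("S", "GENOTYPE X", list(c(a, b)), list(c_),
                    relation = "mutation")
  expect_equal(nrow(filter_to_formulary(mut, a)), 1L)

  expect_error(filter_to_formulary(rules, character(0)),
               class = "cypddi_config_error")
})

test_that("formulary filter is idempotent, monotone, and matches the set oracle", {
  withr::with_seed(7, {
    for (trial in 1:20) {
      kb <- random_kb(50)
      all_codes <- unique(unlist(c(kb$substrate_codes, kb$perpetrator_codes)))
      formulary <- sample(all_codes, ceiling(length(all_codes) / 2))
      got <- filter_to_formulary(kb, formulary)

      # naive per-code membership oracle
      keep <- logical(nrow(kb))
      for (i in seq_len(nrow(kb))) {
        s <- kb$substrate_codes[[i]][kb$substrate_codes[[i]] %in% formulary]
        p <- kb$perpetrator_codes[[i]][kb$perpetrator_codes[[i]] %in% formulary]
        keep[i] <- length(s) > 0 && (length(p) > 0 || kb$relation[i] == "mutation")
        if (keep[i]) {
          expect_equal(got$substrate_codes[[which(got$rule_id == kb$rule_id[i])]], s)
        }
      }
      expect_equal(got$rule_id, kb$rule_id[keep])
      # idempotence
      expect_equal(filter_to_formulary(got, formulary) |> as.data.frame(),
                   got |> as.data.frame())
      # monotonicity: enlarging the formulary never loses rules or codes
      bigger <- filter_to_formulary(kb, union(formulary,
                                              sample(all_codes, 5)))
      expect_true(all(got$rule_id %in% bigger$rule_id))
      expect_true(sum(lengths(bigger$substrate_codes)) >=
                    sum(lengths(got$substrate_codes)))
    }
  })
})

test_that("code-combination count multiplies list lengths and matches enumeration", {
  kb <- read_interaction_kb(example_kb_path)
  expect_equal(count_code_combinations(kb), 13 * 12)  # 156
  expect_equal(count_code_combinations(kb[0, ]), 0)
  mut <- make_rules("S", "G", list(ucd_codes(5)), list(character(0)),
                    relation = "mutation")
  expect_equal(count_code_combinations(mut), 0)

  withr::with_seed(11, {
    rnd <- random_kb(60)
    brute <- 0
    for (i in seq_len(nrow(rnd))) {
      for (s in rnd$substrate_codes[[i]]) {
        brute <- brute + length(rnd$perpetrator_codes[[i]])
      }
    }
    expect_equal(count_code_combinations(rnd), brute)
  })
})
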