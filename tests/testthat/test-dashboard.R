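period <- c("2021-06-01", "2021-09-30")

dash_fixture <- function() {
  rules <- make_rules("PARACETAMOL", "CARBAMAZEPINE",
                      list(ucd_codes(2)), list(ucd_codes(2, 10)))
  rx <- dplyr::bind_rows(
    rx_event("s1", "P1", "2021-06-05", ucd_codes(1), unit = "ICU"),
    rx_event("p1", "P1", "2021-06-05", ucd_codes(1, 10), unit = "ICU"),
    rx_event("s2", "P1", "2021-08-02", ucd_codes(1), unit = "CARDIOLOGY",
             stay_id = "P1-S2"),
    rx_event("p2", "P1", "2021-08-02", ucd_codes(1, 10), stay_id = "P1-S2"),
    rx_event("s3", "P2", "2021-06-10", ucd_codes(1), unit = "NEUROLOGY"),
    rx_event("p3", "P2", "2021-06-10", ucd_codes(1, 10)))
  patients <- tibble::tibble(
    patient_id = c("P1", "P2"), sex = c("F", "M"),
    birth_date = as.Date(c("1960-01-01", "1990-06-15")))
  labs <- dplyr::bind_rows(
    lab_event("l1", "P1", "2021-06-05", "DOS-PARACETAMOL", status = "above"),
    lab_event("l2", "P3", "2021-06-05", "DOS-PARACETAMOL"))
  amap <- tibble::tibble(kind = "dosage", substance = "PARACETAMOL",
                         analyte = "DOS-PARACETAMOL")
  hits <- detect_interactions(rules, rx, period = period)
  list(rules = rules, rx = rx, patients = patients, labs = labs,
       amap = amap, hits = hits)
}

test_that("the time series counts distinct patients per bin over the whole period", {
  f <- dash_fixture()
  ts <- hit_time_series(f$hits, bin = "month")
  expect_equal(ts$bin_start,
               as.Date(c("2021-06-01", "2021-07-01", "2021-08-01", "2021-09-01")))
  expect_equal(ts$n_patients, c(2L, 0L, 1L, 0L))
  # P1 hits in two months: counted once per bin, so the series total (3)
  # exceeds the number of distinct patients (2)
  expect_equal(sum(ts$n_patients), 3L)

  empty <- f$hits[0, ]
  attr(empty, "period") <- as_period(period)
  ts0 <- hit_time_series(empty, bin = "month")
  expect_equal(ts0$n_patients, rep(0L, 4))
})

test_that("per-day binning equals a brute-force per-day recount", {
  withr::with_seed(21, {
    sim <- simulate_ehr(random_sim_config(80))
    rules <- read_kb_from_sim(sim)
    hits <- detect_interactions(rules, sim$prescriptions, sim$labs,
                                period = c("2021-06-01", "2021-07-31"),
                                analyte_map = sim$analyte_map)
    expect_gt(nrow(hits), 0L)  # seed chosen so the recount is non-vacuous
    for (rid in unique(hits$rule_id)) {
      h <- hits[hits$rule_id == rid, ]
      attr(h, "period") <- attr(hits, "period")
      ts <- hit_time_series(h, bin = "day")
      for (k in which(ts$n_patients > 0)) {
        expect_equal(ts$n_patients[k],
                     length(unique(h$patient_id[h$day == ts$bin_start[k]])))
      }
    }
  })
})

test_that("unit filtering restricts to the substrate events' units", {
  f <- dash_fixture()
  ts_icu <- hit_time_series(f$hits, bin = "month", unit_filter = "ICU")
  expect_equal(ts_icu$n_patients, c(1L, 0L, 0L, 0L))
  full <- hit_time_series(f$hits, bin = "month")
  expect_true(all(ts_icu$n_patients <= full$n_patients))
  expect_error(hit_time_series(f$hits, unit_filter = "NO_SUCH_UNIT"),
               "CARDIOLOGY", class = "cypddi_config_error")
})

test_that("demographics count each affected patient once, age at first hit", {
  f <- dash_fixture()
  demo <- hit_demographics(f$hits, f$patients,
                           age_bands = c(0, 60, 120))
  expect_equal(demo$sex$n[demo$sex$sex == "F"], 1L)
  expect_equal(demo$sex$n[demo$sex$sex == "M"], 1L)
  # born 1960-01-01, first hit 2021-06-05: age 61, band [60,120)
  expect_equal(demo$age$n[demo$age$band == "[60,120)"], 1L)
  expect_equal(sum(demo$age$n), 2L)
  expect_equal(sum(demo$sex$n), 2L)

  orphan <- f$hits |> dplyr::mutate(patient_id = "P9")
  expect_error(hit_demographics(orphan, f$patients), "P9",
               class = "cypddi_validation_error")
})

test_that("unit breakdown counts distinct patients per unit of their substrate events", {
  f <- dash_fixture()
  ub <- hit_unit_breakdown(f$hits)
  expect_equal(ub$n_patients[ub$unit == "ICU"], 1L)
  expect_equal(ub$n_patients[ub$unit == "CARDIOLOGY"], 1L)  # P1 again
  expect_equal(ub$n_patients[ub$unit == "NEUROLOGY"], 1L)
  # a multi-unit patient counts in each unit: totals >= n_patients
  expect_gte(sum(ub$n_patients), 2L)
  expect_equal(nrow(hit_unit_breakdown(f$hits[0, ])), 0L)
})

test_that("dosage coverage is covered / affected, NA for an empty denominator", {
  f <- dash_fixture()
  cov <- dosage_coverage(f$hits, f$labs, "DOS-PARACETAMOL",
                         window = "same_day")
  expect_equal(cov, 0.5)  # P1 covered on a hit day, P2 not; P3 unaffected
  expect_equal(dosage_coverage(f$hits, f$labs, "DOS-PARACETAMOL",
                               window = "same_stay"), 0.5)
  empty <- f$hits[0, ]
  expect_true(is.na(dosage_coverage(empty, f$labs, "DOS-PARACETAMOL",
                                    window = "same_day")))
  expect_error(dosage_coverage(f$hits, f$labs, character(0),
                               window = "same_day"),
               class = "cypddi_config_error")
})

test_that("the period window admits dosages away from hit days; same_day does not", {
  f <- dash_fixture()
  labs <- lab_event("l9", "P2", "2021-09-20", "DOS-PARACETAMOL")
  expect_equal(dosage_coverage(f$hits, labs, "DOS-PARACETAMOL",
                               window = "same_day"), 0)
  expect_equal(dosage_coverage(f$hits, labs, "DOS-PARACETAMOL",
                               window = "period", period = period), 0.5)
  # same_stay without stay information in the lab file is a config error
  labs$stay_id <- NULL
  expect_error(dosage_coverage(f$hits, labs, "DOS-PARACETAMOL",
                               window = "same_stay"),
               "stay_id", class = "cypddi_config_error")
})

test_that("status counts cover every matched dosage event, optionally deduplicated", {
  f <- dash_fixture()
  labs <- dplyr::bind_rows(
    lab_event("l1", "P1", "2021-06-05", "DOS-PARACETAMOL", status = "below"),
    lab_event("l2", "P1", "2021-08-02", "DOS-PARACETAMOL", status = "in_range",
              stay_id = "P1-S2"),
    lab_event("l3", "P2", "2021-06-10", "DOS-PARACETAMOL", status = "in_range"))
  st <- dosage_by_status(f$hits, labs, "DOS-PARACETAMOL", window = "same_day")
  expect_equal(st$n[st$status == "below"], 1L)
  expect_equal(st$n[st$status == "in_range"], 2L)
  expect_equal(sum(st$n), 3L)  # P1 contributes twice (known duplication)

  dedup <- dosage_by_status(f$hits, labs, "DOS-PARACETAMOL",
                            window = "same_day", dedupe_patients = TRUE)
  expect_equal(sum(dedup$n), 2L)

  none <- dosage_by_status(f$hits[0, ], labs, "DOS-PARACETAMOL",
                           window = "same_day")
  expect_equal(nrow(none), 0L)
})

test_that("a bundle assembles all five panels with conserved totals", {
  f <- dash_fixture()
  b <- build_dashboard(f$hits, f$rules[1, ], f$patients, f$labs, f$amap,
                       period = period, window = "same_day")
  expect_s3_class(b, "cypddi_bundle")
  expect_equal(b$n_patients, 2L)
  expect_equal(sum(b$sex$n), b$n_patients)
  expect_equal(sum(b$age$n), b$n_patients)
  expect_equal(b$dosage_coverage, 0.5)
  expect_equal(sum(b$dosage_status$n), 1L)

  td <- tidy(b)
  expect_true(all(c("time_series", "sex", "age", "unit", "coverage",
                    "status") %in% td$panel))
  g <- glance(b)
  expect_equal(g$n_patients, 2L)
  expect_s3_class(autoplot(b), "ggplot")
  expect_s3_class(autoplot(b, panel = "coverage"), "ggplot")
})

test_that("bundle JSON export round-trips and validates against the schema", {
  f <- dash_fixture()
  b <- build_dashboard(f$hits, f$rules[1, ], f$patients, f$labs, f$amap,
                       period = period, window = "same_day")
  path <- withr::local_tempfile(fileext = ".json")
  export_bundle(b, path, format = "json")
  expect_true(validate_bundle_json(path))
  expect_equal(read_bundle(path), b, ignore_attr = TRUE)

  # empty-hits bundle: valid file with zeroed panels, coverage rendered null
  b0 <- build_dashboard(f$hits[0, ], f$rules[1, ], f$patients, f$labs,
                        f$amap, period = period, window = "same_day")
  export_bundle(b0, path, format = "json")
  expect_true(validate_bundle_json(path))
  back <- read_bundle(path)
  expect_equal(back$n_patients, 0L)
  expect_true(is.na(back$dosage_coverage))

  html <- withr::local_tempfile(fileext = ".html")
  export_bundle(b, html, format = "html")
  txt <- readLines(html)
  expect_true(any(grepl("PARACETAMOL", txt)))
  expect_true(any(grepl("50.0%", txt, fixed = TRUE)))
})

test_that("random bundles respect conservation and schema validity", {
  withr::with_seed(31, {
    path <- tempfile(fileext = ".json")
    for (trial in 1:25) {
      sim <- simulate_ehr(random_sim_config(1000 + trial))
      rules <- read_kb_from_sim(sim)
      hits <- detect_interactions(rules, sim$prescriptions, sim$labs,
                                  period = c("2021-06-01", "2021-07-31"),
                                  analyte_map = sim$analyte_map)
      for (i in seq_len(nrow(rules))) {
        b <- build_dashboard(hits, rules[i, ], sim$patients, sim$labs,
                             sim$analyte_map,
                             period = c("2021-06-01", "2021-07-31"))
        expect_equal(sum(b$sex$n), b$n_patients)
        expect_equal(sum(b$age$n), b$n_patients)
        if (!is.na(b$dosage_coverage)) {
          expect_gte(b$dosage_coverage, 0)
          expect_lte(b$dosage_coverage, 1)
        }
        export_bundle(b, path, format = "json")
        expect_true(validate_bundle_json(path))
      }
    }
  })
})
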