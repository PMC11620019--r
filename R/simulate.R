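#' Specify one rule to plant in a synthetic cohort
#'
#' Helper building one row of a simulation's `rules_spec`: the rule identity
#' plus the exact ground truth to plant — how many affected patients, how
#' many (patient, day) co-occurrence days (spread round-robin, at least one
#' per patient), how many substrate prescriptions (extra ones duplicated on
#' existing hit days), and the fraction of affected patients given a dosage
#' lab event (planted on the first hit day, same stay).
#'
#' @param cytochrome,substrate,relation,perpetrator rule identity; `relation`
#'   one of `p_inhib`, `p_induc`, `mutation`.
#' @param n_patients planted affected patients.
#' @param n_days planted distinct (patient, day) hit days (`>= n_patients`).
#' @param n_prescriptions planted substrate prescriptions (`>= n_days`).
#' @param coverage planted dosage-coverage fraction in `[0, 1]`.
#' @param n_substrate_codes,n_perpetrator_codes synthetic dispensing codes
#'   drawn for each side (perpetrator side forced to 0 for mutation rules).
#' @param period_start,period_end optional per-rule planting period
#'   (defaults to the simulation period).
#' @return a one-row tibble.
#' @export
sim_rule <- function(cytochrome, substrate, relation, perpetrator,
                     n_patients, n_days = n_patients,
                     n_prescriptions = n_days, coverage = 0,
                     n_substrate_codes = 3L, n_perpetrator_codes = 3L,
                     period_start = NA, period_end = NA) {
  tibble(
    cytochrome = cytochrome, substrate = canonical_label(substrate),
    relation = relation, perpetrator = canonical_label(perpetrator),
    n_patients = as.integer(n_patients), n_days = as.integer(n_days),
    n_prescriptions = as.integer(n_prescriptions),
    coverage = as.numeric(coverage),
    n_substrate_codes = as.integer(n_substrate_codes),
    n_perpetrator_codes = if (relation == "mutation") 0L else
      as.integer(n_perpetrator_codes),
    period_start = as.Date(period_start), period_end = as.Date(period_end))
}

#' Configure a synthetic EHR simulation
#'
#' Defines the stated world of a synthetic hospital extract: cohort size,
#' study period, the interaction rules to plant with their exact ground
#' truth, background (non-interacting) event volumes, decoy knowledge-base
#' rows, and cohort demographics. Everything downstream is deterministic
#' given `seed`.
#'
#' Background prescriptions and lab events draw their codes/analytes from
#' pools disjoint from every rule's codes and mapped analytes, so they can
#' never create an accidental co-occurrence; a post-generation audit
#' verifies this. Planted counts are therefore exact, which is what makes
#' planted-truth tests sharp.
#'
#' @param seed integer RNG seed.
#' @param n_patients cohort size.
#' @param period length-2 study period (dates).
#' @param rules_spec tibble of [sim_rule()] rows.
#' @param n_background_prescriptions,n_background_labs background event
#'   volumes.
#' @param n_self_pairs decoy KB rows pairing a molecule with itself
#'   (removed by [remove_self_interactions()]).
#' @param n_off_formulary_rules decoy KB rows whose perpetrator codes are
#'   absent from the formulary (dropped by [filter_to_formulary()]).
#' @param units medical-unit labels.
#' @param sex_ratio proportion of female patients.
#' @param age_mean,age_sd cohort age distribution (normal, truncated to
#'   0-100 years) at period start.
#' @return a `cypddi_sim_config` list; infeasible specifications (more hit
#'   days than patient-days available, coverage outside `[0, 1]`, ...) error
#'   here, before anything is generated.
#' @export
sim_config <- function(seed, n_patients, period, rules_spec,
                       n_background_prescriptions = 500L,
                       n_background_labs = 200L,
                       n_self_pairs = 0L, n_off_formulary_rules = 0L,
                       units = c("CARDIOLOGY", "NEPHROLOGY", "NEUROLOGY",
                                 "ONCOLOGY", "INTERNAL_MEDICINE", "ICU"),
                       sex_ratio = 0.5, age_mean = 62, age_sd = 18) {
  period <- as_period(period)
  if (nrow(rules_spec) == 0L) {
    abort("rules_spec must contain at least one rule.",
          class = "cypddi_sim_error")
  }
  spec <- rules_spec |>
    mutate(period_start = dplyr::coalesce(.data$period_start, period[1]),
           period_end = dplyr::coalesce(.data$period_end, period[2]))
  for (i in seq_len(nrow(spec))) {
    r <- spec[i, ]
    span <- as.integer(r$period_end - r$period_start) + 1L
    label <- sprintf("%s/%s", r$substrate, r$perpetrator)
    if (r$period_start < period[1] || r$period_end > period[2]) {
      abort(sprintf("rule %s: planting period outside the simulation period.",
                    label), class = "cypddi_sim_error")
    }
    if (r$n_patients > n_patients) {
      abort(sprintf("rule %s: %d planted patients exceed cohort size %d.",
                    label, r$n_patients, n_patients),
            class = "cypddi_sim_error")
    }
    if (r$n_days < r$n_patients || r$n_prescriptions < r$n_days) {
      abort(sprintf("rule %s: need n_patients <= n_days <= n_prescriptions.",
                    label), class = "cypddi_sim_error")
    }
    if (r$n_days > r$n_patients * span) {
      abort(sprintf(
        "rule %s: %d hit days infeasible for %d patients over %d days.",
        label, r$n_days, r$n_patients, span), class = "cypddi_sim_error")
    }
    if (r$coverage < 0 || r$coverage > 1) {
      abort(sprintf("rule %s: coverage must be in [0, 1].", label),
            class = "cypddi_sim_error")
    }
    if (!r$relation %in% RELATION_LEVELS) {
      abort(sprintf("rule %s: unknown relation '%s'.", label, r$relation),
            class = "cypddi_sim_error")
    }
  }
  structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    period = period, rules_spec = spec,
    n_background_prescriptions = as.integer(n_background_prescriptions),
    n_background_labs = as.integer(n_background_labs),
    n_self_pairs = as.integer(n_self_pairs),
    n_off_formulary_rules = as.integer(n_off_formulary_rules),
    units = units, sex_ratio = sex_ratio,
    age_mean = age_mean, age_sd = age_sd), class = "cypddi_sim_config")
}

# round-robin allocation of `extra` items over n slots
alloc_round_robin <- function(extra, n) {
  if (n == 0L) return(integer(0))
  counts <- integer(n)
  if (extra > 0L) {
    idx <- ((seq_len(extra) - 1L) %% n) + 1L
    counts <- tabulate(idx, nbins = n)
  }
  counts
}

#' Generate a synthetic hospital extract with planted interactions
#'
#' Emits the full file set a detection run needs — knowledge base,
#' formulary, patients, prescriptions, lab events, analyte map — plus the
#' machine-readable ground truth of everything planted. Deterministic for a
#' given seed: the same configuration produces byte-identical files.
#'
#' Each rule receives dispensing codes disjoint from every other rule's (as
#' if each rule involved distinct presentations), so planted counts are
#' exact even when substances recur across rules. Self-pair and
#' off-formulary decoy rows exercise the knowledge-base filters. After
#' generation an independent audit rescans all events and aborts if any
#' non-planted co-occurrence exists.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, writes `kb.tsv`,
#'   `formulary.txt`, `patients.tsv`, `prescriptions.tsv`, `labs.tsv`,
#'   `analyte_map.tsv` and `ground_truth.json` there.
#' @return invisibly, a list with the tibbles (`kb`, `formulary`,
#'   `patients`, `prescriptions`, `labs`, `analyte_map`), `ground_truth`,
#'   and `paths` (when `dir` given).
#' @export
simulate_ehr <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cypddi_sim_config"))
  withr::with_seed(config$seed, simulate_ehr_impl(config, dir))
}

simulate_ehr_impl <- function(config, dir) {
  spec <- config$rules_spec
  n_rules <- nrow(spec)
  period <- config$period

  # -- dispensing codes: unique 13-digit "3400" codes, disjoint per rule ----
  n_bg_codes <- 60L
  n_needed <- sum(spec$n_substrate_codes) + sum(spec$n_perpetrator_codes) +
    3L * config$n_self_pairs + 6L * config$n_off_formulary_rules + n_bg_codes
  suffixes <- sample.int(999999999L, n_needed)
  all_codes <- sprintf("3400%09d", suffixes)
  take <- local({
    i <- 0L
    function(n) {
      out <- all_codes[(i + 1L):(i + n)]
      i <<- i + n
      out
    }
  })
  sub_codes <- purrr::map(spec$n_substrate_codes, take)
  perp_codes <- purrr::map(spec$n_perpetrator_codes,
                           ~ if (.x == 0L) character(0) else take(.x))

  # -- knowledge base (active rules + decoys) -------------------------------
  pack <- function(codes) paste(codes, collapse = " or ")
  kb_active <- tibble(
    cytochrome = spec$cytochrome, substrate = spec$substrate,
    relation = spec$relation, perpetrator = spec$perpetrator,
    substrate_ucd = purrr::map_chr(sub_codes, pack),
    perpetrator_ucd = purrr::map_chr(perp_codes, pack))
  kb_self <- purrr::map_dfr(seq_len(config$n_self_pairs), function(i) {
    codes <- take(3L)
    tibble(cytochrome = "CYP3A4",
           substrate = sprintf("SELFDRUG%02d", i), relation = "p_inhib",
           perpetrator = sprintf("SELFDRUG%02d", i),
           substrate_ucd = pack(codes), perpetrator_ucd = pack(codes))
  })
  off_perp_codes <- list()
  kb_off <- purrr::map_dfr(seq_len(config$n_off_formulary_rules), function(i) {
    scod <- take(3L)
    pcod <- take(3L)
    off_perp_codes[[i]] <<- pcod
    tibble(cytochrome = "CYP2C9",
           substrate = sprintf("OFFDRUG%02dA", i), relation = "p_induc",
           perpetrator = sprintf("OFFDRUG%02dB", i),
           substrate_ucd = pack(scod), perpetrator_ucd = pack(pcod))
  })
  kb <- bind_rows(kb_active, kb_self, kb_off)

  bg_codes <- take(n_bg_codes)
  # formulary: everything except the off-formulary perpetrator codes
  formulary <- sort(setdiff(
    c(unlist(sub_codes), unlist(perp_codes),
      if (nrow(kb_self)) unlist(strsplit(kb_self$substrate_ucd, " or ",
                                         fixed = TRUE)),
      if (nrow(kb_off)) unlist(strsplit(kb_off$substrate_ucd, " or ",
                                        fixed = TRUE)),
      bg_codes),
    unlist(off_perp_codes)))

  # -- cohort ---------------------------------------------------------------
  patient_ids <- sprintf("P%05d", seq_len(config$n_patients))
  ages <- pmin(pmax(stats::rnorm(config$n_patients, config$age_mean,
                                 config$age_sd), 0), 100)
  patients <- tibble(
    patient_id = patient_ids,
    sex = ifelse(stats::runif(config$n_patients) < config$sex_ratio,
                 "F", "M"),
    birth_date = period[1] - round(ages * 365.25) -
      sample.int(365L, config$n_patients, replace = TRUE) + 1L)

  stay_of <- function(patient_id, day) {
    sprintf("%s-S%03d", patient_id,
            (as.integer(day - period[1]) %/% 14L) + 1L)
  }

  # -- analyte map ----------------------------------------------------------
  analyte_map <- bind_rows(
    spec |> distinct(.data$substrate) |>
      transmute(kind = "dosage", substance = .data$substrate,
                analyte = paste0("DOS-", gsub("[^A-Z0-9]", "", .data$substrate))),
    spec |> filter(.data$relation == "mutation") |>
      distinct(.data$perpetrator) |>
      transmute(kind = "genotyping", substance = .data$perpetrator,
                analyte = paste0("GENO-", gsub("[^A-Z0-9]", "", .data$perpetrator))))

  # -- planted events -------------------------------------------------------
  rx_rows <- list()
  lab_rows <- list()
  truth_rules <- vector("list", n_rules)

  for (i in seq_len(n_rules)) {
    r <- spec[i, ]
    if (r$n_patients == 0L) {
      truth_rules[[i]] <- list(
        cytochrome = r$cytochrome, substrate = r$substrate,
        relation = r$relation, perpetrator = r$perpetrator,
        n_patients = 0L, n_days = 0L, n_prescriptions = 0L,
        coverage = r$coverage,
        hits = tibble(patient_id = character(), day = as.Date(character())),
        covered_patients = character(),
        statuses = tibble(patient_id = character(), status = character()))
      next
    }
    rule_days <- seq(r$period_start, r$period_end, by = "day")
    chosen <- sample(patient_ids, r$n_patients)
    extra_days <- alloc_round_robin(r$n_days - r$n_patients, r$n_patients)
    hit_tbl <- purrr::map_dfr(seq_len(r$n_patients), function(j) {
      k <- 1L + extra_days[j]
      tibble(patient_id = chosen[j],
             day = sort(sample(rule_days, k)))
    })
    extra_rx <- alloc_round_robin(r$n_prescriptions - nrow(hit_tbl),
                                  nrow(hit_tbl))
    unit_of_day <- sample(config$units, nrow(hit_tbl), replace = TRUE)

    sub_n <- 1L + extra_rx
    sub_events <- tibble(
      patient_id = rep(hit_tbl$patient_id, sub_n),
      day = rep(hit_tbl$day, sub_n),
      code = sample(sub_codes[[i]], sum(sub_n), replace = TRUE),
      unit = rep(unit_of_day, sub_n))
    rx_rows[[length(rx_rows) + 1L]] <- sub_events

    if (r$relation != "mutation") {
      rx_rows[[length(rx_rows) + 1L]] <- tibble(
        patient_id = hit_tbl$patient_id, day = hit_tbl$day,
        code = sample(perp_codes[[i]], nrow(hit_tbl), replace = TRUE),
        unit = unit_of_day)
    } else {
      geno <- mapped_analytes(analyte_map, r$perpetrator, "genotyping")
      lab_rows[[length(lab_rows) + 1L]] <- tibble(
        patient_id = hit_tbl$patient_id, day = hit_tbl$day,
        analyte = geno[1], kind = "genotyping",
        value = NA_real_, status = "unknown")
    }

    n_cov <- as.integer(round(r$coverage * r$n_patients))
    covered <- chosen[seq_len(n_cov)]
    statuses <- tibble(patient_id = character(), status = character())
    if (n_cov > 0L) {
      first_day <- hit_tbl |>
        filter(.data$patient_id %in% covered) |>
        summarise(day = min(.data$day), .by = "patient_id")
      dos <- mapped_analytes(analyte_map, r$substrate, "dosage")
      status_cycle <- rep_len(c("below", "in_range", "above"), n_cov)
      ord <- match(covered, first_day$patient_id)
      lab_rows[[length(lab_rows) + 1L]] <- tibble(
        patient_id = first_day$patient_id[ord],
        day = first_day$day[ord],
        analyte = dos[1], kind = "dosage",
        value = round(stats::runif(n_cov, 2, 20), 1),
        status = status_cycle)
      statuses <- tibble(patient_id = covered, status = status_cycle)
    }

    truth_rules[[i]] <- list(
      cytochrome = r$cytochrome, substrate = r$substrate,
      relation = r$relation, perpetrator = r$perpetrator,
      n_patients = r$n_patients, n_days = r$n_days,
      n_prescriptions = r$n_prescriptions, coverage = r$coverage,
      hits = hit_tbl |> arrange(.data$patient_id, .data$day),
      covered_patients = sort(covered),
      statuses = statuses)
  }

  # -- background events (codes/analytes disjoint from every rule) ----------
  n_bg <- config$n_background_prescriptions
  if (n_bg > 0L) {
    rx_rows[[length(rx_rows) + 1L]] <- tibble(
      patient_id = sample(patient_ids, n_bg, replace = TRUE),
      day = sample(seq(period[1], period[2], by = "day"), n_bg,
                   replace = TRUE),
      code = sample(bg_codes, n_bg, replace = TRUE),
      unit = sample(config$units, n_bg, replace = TRUE))
  }
  n_bl <- config$n_background_labs
  if (n_bl > 0L) {
    lab_rows[[length(lab_rows) + 1L]] <- tibble(
      patient_id = sample(patient_ids, n_bl, replace = TRUE),
      day = sample(seq(period[1], period[2], by = "day"), n_bl,
                   replace = TRUE),
      analyte = sprintf("BIO-%03d", sample.int(40L, n_bl, replace = TRUE)),
      kind = sample(c("dosage", "genotyping"), n_bl, replace = TRUE,
                    prob = c(0.8, 0.2)),
      value = round(stats::runif(n_bl, 1, 300), 1),
      status = sample(STATUS_LEVELS, n_bl, replace = TRUE))
  }

  prescriptions <- bind_rows(rx_rows) |>
    mutate(stay_id = stay_of(.data$patient_id, .data$day),
           event_id = sprintf("RX%07d", dplyr::row_number())) |>
    select("event_id", "patient_id", "stay_id", "day", "code", "unit")
  labs <- bind_rows(lab_rows) |>
    mutate(stay_id = stay_of(.data$patient_id, .data$day),
           event_id = sprintf("LAB%07d", dplyr::row_number())) |>
    select("event_id", "patient_id", "stay_id", "day", "analyte", "kind",
           "value", "status")

  audit_no_accidental_hits(spec, sub_codes, perp_codes, prescriptions, labs,
                           analyte_map, truth_rules)

  ground_truth <- list(
    seed = config$seed,
    n_self_pairs = config$n_self_pairs,
    n_off_formulary_rules = config$n_off_formulary_rules,
    rules = truth_rules)

  out <- list(kb = kb, formulary = formulary, patients = patients,
              prescriptions = prescriptions, labs = labs,
              analyte_map = analyte_map, ground_truth = ground_truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      kb = file.path(dir, "kb.tsv"),
      formulary = file.path(dir, "formulary.txt"),
      patients = file.path(dir, "patients.tsv"),
      prescriptions = file.path(dir, "prescriptions.tsv"),
      labs = file.path(dir, "labs.tsv"),
      analyte_map = file.path(dir, "analyte_map.tsv"),
      ground_truth = file.path(dir, "ground_truth.json"))
    readr::write_tsv(kb, paths$kb)
    writeLines(c("# synthetic institutional formulary", formulary),
               paths$formulary)
    readr::write_tsv(patients, paths$patients)
    readr::write_tsv(prescriptions, paths$prescriptions)
    readr::write_tsv(labs, paths$labs)
    readr::write_tsv(analyte_map, paths$analyte_map)
    gt_json <- ground_truth
    gt_json$rules <- purrr::map(gt_json$rules, function(r) {
      r$hits <- r$hits |> mutate(day = as.character(.data$day))
      r
    })
    jsonlite::write_json(gt_json, paths$ground_truth, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    out$paths <- paths
  }
  invisible(out)
}

# independent rescan: every (rule, patient, day) with both sides present
# must be a planted hit, and every matched substrate event a planted one
audit_no_accidental_hits <- function(spec, sub_codes, perp_codes,
                                     prescriptions, labs, analyte_map,
                                     truth_rules) {
  for (i in seq_len(nrow(spec))) {
    r <- spec[i, ]
    sub_pd <- prescriptions |>
      filter(.data$code %in% sub_codes[[i]]) |>
      distinct(.data$patient_id, .data$day)
    perp_pd <- if (r$relation == "mutation") {
      geno <- mapped_analytes(analyte_map, r$perpetrator, "genotyping")
      labs |>
        filter(.data$kind == "genotyping", .data$analyte %in% geno) |>
        distinct(.data$patient_id, .data$day)
    } else {
      prescriptions |>
        filter(.data$code %in% perp_codes[[i]]) |>
        distinct(.data$patient_id, .data$day)
    }
    observed <- inner_join(sub_pd, perp_pd, by = c("patient_id", "day")) |>
      arrange(.data$patient_id, .data$day)
    planted <- truth_rules[[i]]$hits
    if (!identical(as.data.frame(observed), as.data.frame(planted))) {
      abort(sprintf(
        "simulation audit failed for rule %s/%s: observed co-occurrences differ from planted ground truth.",
        r$substrate, r$perpetrator), class = "cypddi_sim_error")
    }
  }
  invisible(TRUE)
}
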