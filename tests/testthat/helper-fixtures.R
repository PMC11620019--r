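# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# quick rules tibble from parallel vectors; codes given as list-columns
make_rules <- function(substrate, perpetrator,
                       substrate_codes, perpetrator_codes,
                       cytochrome = "CYP3A4", relation = "p_inhib") {
  tibble::tibble(
    rule_id = seq_along(substrate),
    cytochrome = rep_len(cytochrome, length(substrate)),
    substrate = toupper(substrate),
    relation = rep_len(relation, length(substrate)),
    perpetrator = toupper(perpetrator),
    substrate_codes = substrate_codes,
    perpetrator_codes = perpetrator_codes)
}

# n unique synthetic UCD codes
ucd_codes <- function(n, offset = 0L) {
  sprintf("3400%09d", seq_len(n) + offset)
}

rx_event <- function(event_id, patient_id, day, code,
                     stay_id = paste0(patient_id, "-S1"), unit = "ICU") {
  tibble::tibble(event_id = event_id, patient_id = patient_id,
                 stay_id = stay_id, day = as.Date(day), code = code,
                 unit = unit)
}

lab_event <- function(event_id, patient_id, day, analyte, kind = "dosage",
                      value = NA_real_, status = "unknown",
                      stay_id = paste0(patient_id, "-S1")) {
  tibble::tibble(event_id = event_id, patient_id = patient_id,
                 stay_id = stay_id, day = as.Date(day), analyte = analyte,
                 kind = kind, value = value, status = status)
}

# random KB for filter-oracle tests: plain tibble, labels DRUG001...,
# n_self rows made self-interacting
random_kb <- function(n, n_self = 0L) {
  labels <- sprintf("DRUG%03d", seq_len(2L * n))
  sub <- sample(labels, n, replace = TRUE)
  perp <- sample(labels, n, replace = TRUE)
  perp[perp == sub] <- paste0(perp[perp == sub], "X")  # start collision-free
  if (n_self > 0L) {
    idx <- sample.int(n, n_self)
    perp[idx] <- sub[idx]
  }
  pool <- sprintf("3400%09d", sample.int(999999L, 6L * n))
  make_rules(sub, perp,
             substrate_codes = lapply(seq_len(n), function(i)
               sample(pool, sample(1:4, 1))),
             perpetrator_codes = lapply(seq_len(n), function(i)
               sample(pool, sample(1:4, 1))))
}

# small random simulation configuration; coverage chosen so that
# coverage * n_patients is integral (exact recovery is then expected)
random_sim_config <- function(seed, max_rules = 3L) {
  withr::with_seed(seed, {
    n_pat <- sample(20:40, 1)
    n_rules <- sample(seq_len(max_rules), 1)
    specs <- lapply(seq_len(n_rules), function(i) {
      relation <- sample(c("p_inhib", "p_induc", "mutation"), 1)
      k <- sample(0:6, 1)
      nd <- if (k == 0L) 0L else k + sample(0:4, 1)
      nrx <- if (nd == 0L) 0L else nd + sample(0:5, 1)
      ncov <- if (k == 0L) 0L else sample(0:k, 1)
      sim_rule(sprintf("CYP%d", i), sprintf("SUB%02d", i), relation,
               if (relation == "mutation") sprintf("GENOTYPE CYP%d", i)
               else sprintf("PERP%02d", i),
               n_patients = k, n_days = nd, n_prescriptions = nrx,
               coverage = if (k == 0L) 0 else ncov / k)
    })
    sim_config(seed = seed, n_patients = n_pat,
               period = c("2021-06-01", "2021-07-31"),
               rules_spec = dplyr::bind_rows(specs),
               n_background_prescriptions = 40L,
               n_background_labs = 15L)
  })
}

# brute-force oracle: drug-drug co-occurrence by per-patient-day query
# evaluation, independent of the join-based detector
oracle_hit_keys <- function(rules, prescriptions, period) {
  period <- as.Date(period)
  rx <- prescriptions[prescriptions$day >= period[1] &
                        prescriptions$day <= period[2], ]
  pd <- unique(rx[, c("patient_id", "day")])
  out <- list()
  for (i in seq_len(nrow(rules))) {
    if (rules$relation[i] == "mutation") next
    q <- build_query(rules[i, ])
    for (j in seq_len(nrow(pd))) {
      codes <- rx$code[rx$patient_id == pd$patient_id[j] &
                         rx$day == pd$day[j]]
      if (evaluate_query(q, codes)) {
        out[[length(out) + 1L]] <- data.frame(
          rule_id = rules$rule_id[i], patient_id = pd$patient_id[j],
          day = pd$day[j])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(rule_id = integer(), patient_id = character(),
                      day = as.Date(character())))
  }
  res <- do.call(rbind, out)
  res[order(res$rule_id, res$patient_id, res$day), , drop = FALSE]
}

# reload a simulated KB through the loader + filters, as the pipeline would
read_kb_from_sim <- function(sim) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(sim$kb, path)
  kb <- read_interaction_kb(path)
  kept <- remove_self_interactions(kb)$kept
  filter_to_formulary(kept, sim$formulary)
}
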