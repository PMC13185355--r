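#' Criterion identifiers used by the rule engine
#'
#' Four inclusion checks (INC1-INC4), fourteen exclusion criteria
#' (EXC1-EXC14), four possible-PD criteria (POS1-POS4) and three index-date
#' rules.
#' @export
criterion_ids <- function() {
  c(paste0("INC", 1:4), paste0("EXC", 1:14), paste0("POS", 1:4))
}

first_dx_date <- function(diagnoses, prefixes) {
  hit <- diagnoses[icd10_match(diagnoses$icd10_code, prefixes), , drop = FALSE]
  hit %>% group_by(patient_id) %>%
    summarise(first = suppressWarnings(min(dx_date)),
              last = suppressWarnings(max(dx_date)), .groups = "drop")
}

#' Per-patient feature table backing the rule engine
#'
#' Collapses the event streams into one row per patient with every quantity
#' the criteria need: FPD (first purchase date of an inclusion-class APM),
#' last APM date, occasion count and span, exclusivity flags, windowed
#' purchase and diagnosis flags, first/last dates of the semantic diagnosis
#' sets, observation end and age at FPD. Exposed mainly for audit and
#' testing; [classify_cohort()] is the user-facing entry point.
#'
#' @param dataset an `ehr_dataset`.
#' @return tibble, one row per patient.
#' @export
patient_features <- function(dataset) {
  cb <- dataset$codebook
  pat <- dataset$patients
  pur <- dataset$purchases
  dx <- dataset$diagnoses

  apm <- pur %>% filter(apm_class %in% cb$inclusion_classes)
  apm_sum <- apm %>%
    group_by(patient_id) %>%
    summarise(
      fpd = suppressWarnings(min(purchase_date)),
      last_apm = suppressWarnings(max(purchase_date)),
      apm_occasions = dplyr::n_distinct(purchase_date),
      excl_mao = all(apm_class == "mao_inhibitor"),
      excl_amantadine = all(apm_class == "amantadine"),
      excl_agonist = all(apm_class == "dopamine_agonist"),
      excl_bromo_perg = all(atc_code %in% cb$bromocriptine_pergolide),
      excl_caber = all(atc_code %in% cb$cabergoline),
      any_levodopa = any(apm_class == "levodopa"),
      .groups = "drop") %>%
    mutate(apm_span = as.integer(last_apm - fpd))

  feats <- pat %>%
    left_join(apm_sum, by = "patient_id") %>%
    mutate(apm_occasions = coalesce(apm_occasions, 0L),
           apm_span = coalesce(apm_span, 0L),
           excl_mao = coalesce(excl_mao, FALSE),
           excl_amantadine = coalesce(excl_amantadine, FALSE),
           excl_agonist = coalesce(excl_agonist, FALSE),
           excl_bromo_perg = coalesce(excl_bromo_perg, FALSE),
           excl_caber = coalesce(excl_caber, FALSE),
           any_levodopa = coalesce(any_levodopa, FALSE))

  # purchases relative to the FPD
  pur_f <- pur %>%
    left_join(feats %>% select(patient_id, fpd), by = "patient_id")
  win <- pur_f %>%
    group_by(patient_id) %>%
    summarise(
      ach_first = suppressWarnings(min(purchase_date[apm_class == "anticholinergic"])),
      ach_prior = any(apm_class == "anticholinergic" & !is.na(fpd) &
                        purchase_date >= fpd - 365L & purchase_date < fpd),
      ap_prior = any(apm_class == "antipsychotic" & !is.na(fpd) &
                       purchase_date >= fpd - 365L & purchase_date < fpd),
      .groups = "drop") %>%
    mutate(ach_first = as.Date(ifelse(is.infinite(as.numeric(ach_first)),
                                      NA, ach_first), origin = "1970-01-01"))
  feats <- feats %>% left_join(win, by = "patient_id") %>%
    mutate(ach_prior = coalesce(ach_prior, FALSE),
           ap_prior = coalesce(ap_prior, FALSE))

  # first/last dates of the semantic diagnosis sets
  join_dx <- function(feats, set_names, out) {
    prefixes <- unlist(cb$dx_sets[set_names], use.names = FALSE)
    d <- first_dx_date(dx, prefixes)
    names(d) <- c("patient_id", paste0(out, "_first"), paste0(out, "_last"))
    left_join(feats, d, by = "patient_id")
  }
  feats <- feats %>%
    join_dx("pd", "pd") %>%
    join_dx(c("hyperprolactinemia", "pituitary_adenoma"), "hyperpit") %>%
    join_dx("pituitary_adenoma", "pituitary") %>%
    join_dx(c("hydrocephalus", "anoxic_brain_injury"), "hydro_anoxic") %>%
    join_dx(c("psp", "msa", "cbd"), "atyp") %>%
    join_dx("rls", "rls")

  # windowed diagnosis flags relative to the FPD
  dx_f <- dx %>% left_join(feats %>% select(patient_id, fpd), by = "patient_id") %>%
    filter(!is.na(fpd))
  wflag <- function(prefixes, lo, hi, closed_hi = FALSE) {
    hit <- icd10_match(dx_f$icd10_code, prefixes)
    rel <- as.integer(dx_f$dx_date - dx_f$fpd)
    ok <- hit & rel >= lo & (if (closed_hi) rel <= hi else rel < hi)
    dx_f$patient_id[ok]
  }
  two_years <- years_to_days(2)
  five_years <- years_to_days(5)
  preg_ids <- wflag(cb$dx_sets$pregnancy_or_birth, -two_years, 0L)
  tbi_ids <- wflag(cb$dx_sets$tbi, -cb$half_year_days, 0L)
  coma_ids <- wflag(cb$dx_sets$coma, -cb$half_year_days, 0L)
  decline_ids <- wflag(unlist(cb$dx_sets[c("recurrent_falls", "lethargy",
                                           "general_deterioration")]),
                       -365L, five_years, closed_hi = TRUE)
  feats <- feats %>%
    mutate(preg_prior2y = patient_id %in% preg_ids,
           tbi_6m = patient_id %in% tbi_ids,
           coma_6m = patient_id %in% coma_ids,
           decline_window = patient_id %in% decline_ids)

  # insurance coverage at the FPD, and observation end
  ins_sum <- dataset$insurance %>%
    left_join(feats %>% select(patient_id, fpd), by = "patient_id") %>%
    group_by(patient_id) %>%
    summarise(insured_at_fpd = any(!is.na(fpd) & start <= fpd & fpd <= end),
              ins_last_end = suppressWarnings(max(end)), .groups = "drop")
  feats <- feats %>% left_join(ins_sum, by = "patient_id") %>%
    mutate(insured_at_fpd = coalesce(insured_at_fpd, FALSE),
           obs_end = pmin(coalesce(death_date, dataset$extraction_date),
                          coalesce(ins_last_end, dataset$extraction_date),
                          dataset$extraction_date),
           age_fpd = age_at(birth_date, fpd))
  feats
}

# vectorized criterion evaluation over a feature table; returns a logical
# matrix-like tibble with one column per criterion id
evaluate_criteria <- function(feats, cb) {
  two_years <- years_to_days(2)
  three_years <- years_to_days(3)
  five_years <- years_to_days(5)
  has_pd <- !is.na(feats$pd_first)
  has_fpd <- !is.na(feats$fpd)
  gap <- as.integer(feats$obs_end - feats$last_apm)
  fu <- as.integer(feats$obs_end - feats$fpd)
  f <- function(x) coalesce(x, FALSE)

  heavy_use <- feats$apm_occasions > 20 | feats$apm_span > five_years |
    feats$apm_occasions > 8 | feats$apm_span > two_years

  tibble(
    patient_id = feats$patient_id,
    INC1 = feats$apm_occasions >= 2,
    INC2 = has_fpd & feats$insured_at_fpd,
    INC3 = f(feats$fpd >= cb$fpd_floor),
    INC4 = f(feats$age_fpd >= cb$age_min & feats$age_fpd <= cb$age_max),
    EXC1 = !is.na(feats$hyperpit_first) & !has_pd,
    EXC2 = !is.na(feats$pituitary_first) & has_pd & feats$excl_bromo_perg,
    EXC3 = !is.na(feats$pituitary_first) & has_pd &
      f(feats$fpd >= cb$cabergoline_cutoff) & feats$excl_caber,
    EXC4 = feats$sex == "female" & feats$excl_agonist & !has_pd &
      feats$preg_prior2y,
    EXC5 = f(feats$hydro_anoxic_first <= feats$fpd + cb$month_days),
    EXC6 = feats$tbi_6m & feats$coma_6m,
    EXC7 = !is.na(feats$atyp_last) &
      !f(feats$pd_last > feats$atyp_last),
    EXC8 = !is.na(feats$rls_last) & !f(feats$pd_last > feats$rls_last),
    EXC9 = feats$ap_prior & !(feats$any_levodopa & has_pd),
    EXC10 = feats$excl_mao & heavy_use & !has_pd,
    EXC11 = feats$excl_amantadine & heavy_use & !has_pd,
    EXC12 = !has_pd & feats$apm_span > two_years & feats$decline_window,
    EXC13 = !has_pd & feats$apm_span < two_years & f(gap > 365L),
    EXC14 = feats$apm_span < cb$half_year_days & f(gap > three_years),
    POS1 = !has_pd,
    POS2 = f(fu < two_years),
    POS3 = feats$apm_span > three_years & f(gap > two_years),
    POS4 = has_pd & feats$ap_prior & feats$any_levodopa
  )
}

# index date + rule used, vectorized over the feature table
compute_index <- function(feats, cb) {
  pmin_na <- function(a, b) {
    out <- pmin(a, b, na.rm = TRUE)
    as.Date(out, origin = "1970-01-01")
  }
  pmax_na <- function(a, b) as.Date(pmax(a, b, na.rm = TRUE), origin = "1970-01-01")

  default_idx <- pmin_na(feats$fpd, feats$pd_first)
  pit_applies <- !is.na(feats$hyperpit_first) & !is.na(feats$fpd) &
    feats$hyperpit_first < feats$fpd
  ach_applies <- feats$ach_prior
  pit_idx <- pmax_na(feats$fpd, feats$pd_first)
  ach_idx <- pmin_na(feats$ach_first, feats$pd_first)

  if (isTRUE(cb$pituitary_exception_wins)) {
    rule <- case_when(pit_applies ~ "IDX_PITUITARY",
                      ach_applies ~ "IDX_ANTICHOLINERGIC",
                      TRUE ~ "IDX_DEFAULT")
  } else {
    rule <- case_when(ach_applies ~ "IDX_ANTICHOLINERGIC",
                      pit_applies ~ "IDX_PITUITARY",
                      TRUE ~ "IDX_DEFAULT")
  }
  idx <- case_when(rule == "IDX_PITUITARY" ~ pit_idx,
                   rule == "IDX_ANTICHOLINERGIC" ~ ach_idx,
                   TRUE ~ default_idx)
  tibble(index_date = idx, index_rule = rule)
}

#' First APM purchase date (FPD)
#'
#' Earliest purchase date among inclusion-class APM purchases, or `NA` when
#' the patient never purchased an APM.
#'
#' @param purchases one patient's purchases with an `apm_class` column (as
#'   annotated by [new_ehr_dataset()]).
#' @param codebook `pd_codebook`.
#' @return Date scalar or NA.
#' @export
first_purchase_date <- function(purchases, codebook = default_codebook()) {
  d <- purchases$purchase_date[purchases$apm_class %in% codebook$inclusion_classes]
  if (length(d) == 0) return(as.Date(NA))
  min(d)
}

#' Classify every patient in a dataset
#'
#' Runs the full pipeline — inclusion screening, the fourteen exclusion
#' criteria, the possible/probable certainty tier, and the index-date rules —
#' over all patients at once. Pipeline order: a patient failing any inclusion
#' check is `not_eligible`; an included patient firing any exclusion is
#' `excluded`; otherwise the patient is `possible_pd` if at least one
#' possible-PD criterion fires and `probable_pd` if none does.
#'
#' @param dataset an `ehr_dataset`.
#' @return A tibble of class `pd_cohort`, one row per patient with columns
#'   `patient_id`, `status`, `fpd`, `index_date`, `index_rule`,
#'   `age_at_index` and `fired` (semicolon-joined criterion ids: failed INC
#'   checks for not-eligible patients, fired EXC ids for excluded patients,
#'   fired POS ids for possible-PD patients). Attributes: `funnel`
#'   (selection-funnel tibble, see [cohort_funnel()]) and `audit` (long
#'   per-patient per-criterion tibble, see [cohort_audit()]).
#' @export
#' @examples
#' ds <- simulate_cohort(scenario_config(n_patients = 50, seed = 1))$dataset
#' cohort <- classify_cohort(ds)
#' dplyr::count(cohort, status)
classify_cohort <- function(dataset) {
  cb <- dataset$codebook
  feats <- patient_features(dataset)
  if (nrow(feats) == 0) {
    out <- tibble(patient_id = character(), status = character(),
                  fpd = as.Date(character()), index_date = as.Date(character()),
                  index_rule = character(), age_at_index = integer(),
                  fired = character())
    attr(out, "funnel") <- tibble(step = character(), n = integer())
    attr(out, "audit") <- tibble(patient_id = character(),
                                 criterion = character(), fired = logical())
    class(out) <- c("pd_cohort", class(out))
    return(out)
  }
  crit <- evaluate_criteria(feats, cb)

  inc_cols <- paste0("INC", 1:4)
  exc_cols <- paste0("EXC", 1:14)
  pos_cols <- paste0("POS", 1:4)
  inc_m <- as.matrix(crit[inc_cols])
  exc_m <- as.matrix(crit[exc_cols])
  pos_m <- as.matrix(crit[pos_cols])
  eligible <- rowSums(inc_m) == 4L
  excluded <- eligible & rowSums(exc_m, na.rm = TRUE) > 0
  possible <- eligible & !excluded & rowSums(pos_m, na.rm = TRUE) > 0
  status <- case_when(!eligible ~ "not_eligible",
                      excluded ~ "excluded",
                      possible ~ "possible_pd",
                      TRUE ~ "probable_pd")

  join_ids <- function(m, cols, rows, invert = FALSE) {
    vapply(seq_along(rows), function(i) {
      if (!rows[i]) return(NA_character_)
      v <- m[i, ]
      if (invert) v <- !v
      paste(cols[which(v)], collapse = ";")
    }, character(1))
  }
  fired <- case_when(
    status == "not_eligible" ~ join_ids(inc_m, inc_cols, !eligible, invert = TRUE),
    status == "excluded" ~ join_ids(exc_m, exc_cols, excluded),
    status == "possible_pd" ~ join_ids(pos_m, pos_cols, possible),
    TRUE ~ "")

  idx <- compute_index(feats, cb)
  is_pd <- status %in% c("probable_pd", "possible_pd")
  out <- tibble(
    patient_id = feats$patient_id,
    status = status,
    fpd = as.Date(ifelse(is_pd, feats$fpd, NA), origin = "1970-01-01"),
    index_date = as.Date(ifelse(is_pd, idx$index_date, NA), origin = "1970-01-01"),
    index_rule = ifelse(is_pd, idx$index_rule, NA_character_),
    age_at_index = ifelse(is_pd, age_at(feats$birth_date,
                                        as.Date(idx$index_date, origin = "1970-01-01")),
                          NA_integer_),
    fired = fired)

  # selection funnel: patients surviving each successive criterion
  n0 <- nrow(feats)
  surv_inc <- n0
  funnel <- list(tibble(step = "all_patients", n = n0))
  ok <- rep(TRUE, n0)
  for (cc in inc_cols) {
    ok <- ok & inc_m[, cc]
    funnel[[length(funnel) + 1]] <- tibble(step = paste0("pass_", cc), n = sum(ok))
  }
  for (cc in exc_cols) {
    ok <- ok & !exc_m[, cc]
    funnel[[length(funnel) + 1]] <- tibble(step = paste0("survive_", cc), n = sum(ok))
  }
  funnel[[length(funnel) + 1]] <- tibble(step = "probable_pd",
                                         n = sum(status == "probable_pd"))
  funnel[[length(funnel) + 1]] <- tibble(step = "possible_pd",
                                         n = sum(status == "possible_pd"))
  funnel <- bind_rows(funnel)

  audit <- crit %>%
    tidyr::pivot_longer(-patient_id, names_to = "criterion",
                        values_to = "fired") %>%
    arrange(patient_id, criterion)

  attr(out, "funnel") <- funnel
  attr(out, "audit") <- audit
  class(out) <- c("pd_cohort", class(out))
  out
}

#' Selection funnel of a classified cohort
#' @param cohort result of [classify_cohort()].
#' @return tibble with `step` and `n` (patients surviving each criterion).
#' @export
cohort_funnel <- function(cohort) attr(cohort, "funnel")

#' Per-patient per-criterion audit trail
#' @param cohort result of [classify_cohort()].
#' @return long tibble `patient_id`, `criterion`, `fired`.
#' @export
cohort_audit <- function(cohort) attr(cohort, "audit")

#' Classify a single patient with evidence
#'
#' Single-patient view of [classify_cohort()] that additionally collects the
#' supporting events (purchase dates, diagnosis rows) for each fired
#' criterion.
#'
#' @param dataset an `ehr_dataset`.
#' @param patient_id the patient to classify.
#' @return list with `patient_id`, `status`, `fpd`, `index_date`,
#'   `index_rule`, `age_at_index`, and `criteria` (tibble: `criterion`,
#'   `fired`, `evidence` list-column of event descriptors, non-empty whenever
#'   `fired`).
#' @export
classify_patient <- function(dataset, patient_id) {
  sub <- subset_dataset(dataset, patient_id)
  cohort <- classify_cohort(sub)
  audit <- cohort_audit(cohort)
  feats <- patient_features(sub)
  crit <- audit %>%
    mutate(evidence = purrr::map2(criterion, fired, function(cid, f) {
      if (!isTRUE(f)) return(character())
      criterion_evidence(cid, sub, feats)
    }))
  row <- cohort[1, ]
  list(patient_id = patient_id, status = row$status, fpd = row$fpd,
       index_date = row$index_date, index_rule = row$index_rule,
       age_at_index = row$age_at_index, criteria = crit)
}

#' Check the inclusion criteria for one patient
#'
#' @param dataset an `ehr_dataset`.
#' @param patient_id patient to check.
#' @return list `eligible` (logical) and `checks` (tibble of the four
#'   inclusion criteria with pass flags).
#' @export
check_inclusion <- function(dataset, patient_id) {
  sub <- subset_dataset(dataset, patient_id)
  feats <- patient_features(sub)
  crit <- evaluate_criteria(feats, sub$codebook)
  checks <- tibble(criterion = paste0("INC", 1:4),
                   passed = c(crit$INC1, crit$INC2, crit$INC3, crit$INC4))
  list(eligible = all(checks$passed), checks = checks)
}

#' Assign the diagnostic-certainty tier for one patient
#'
#' Evaluates the four possible-PD criteria for an included, non-excluded
#' patient: possible if at least one fires, probable otherwise.
#'
#' @param dataset an `ehr_dataset`.
#' @param patient_id patient.
#' @return list `certainty` ("probable" / "possible") and `fired` (character
#'   vector of fired possible-PD criterion ids).
#' @export
assign_certainty <- function(dataset, patient_id) {
  sub <- subset_dataset(dataset, patient_id)
  crit <- evaluate_criteria(patient_features(sub), sub$codebook)
  pos <- paste0("POS", 1:4)
  fired <- pos[vapply(pos, function(p) isTRUE(crit[[p]][1]), logical(1))]
  list(certainty = if (length(fired)) "possible" else "probable",
       fired = fired)
}

#' Compute the index date for one patient
#'
#' Default rule: the earlier of the FPD and the first PD diagnosis date.
#' Exceptions: a hyperprolactinemia/pituitary-adenoma diagnosis before the
#' FPD switches to the later of the two; an anticholinergic purchase in the
#' year before the FPD switches to the earliest of the first anticholinergic
#' purchase date and the PD diagnosis date. When both exceptions apply the
#' pituitary rule wins by default (codebook-switchable).
#'
#' @param dataset an `ehr_dataset`.
#' @param patient_id patient.
#' @return one-row tibble `index_date`, `index_rule`.
#' @export
compute_index_date <- function(dataset, patient_id) {
  sub <- subset_dataset(dataset, patient_id)
  compute_index(patient_features(sub), sub$codebook)
}

#' Evaluate one named criterion for one patient
#'
#' @param dataset an `ehr_dataset`.
#' @param patient_id patient.
#' @param criterion_id one of [criterion_ids()].
#' @return tibble row: `criterion`, `fired`, `evidence` (list-column).
#' @export
evaluate_criterion <- function(dataset, patient_id, criterion_id) {
  if (!criterion_id %in% criterion_ids()) {
    abort(paste("unknown criterion id:", criterion_id))
  }
  sub <- subset_dataset(dataset, patient_id)
  feats <- patient_features(sub)
  crit <- evaluate_criteria(feats, sub$codebook)
  fired <- isTRUE(crit[[criterion_id]][1])
  tibble(criterion = criterion_id, fired = fired,
         evidence = list(if (fired) criterion_evidence(criterion_id, sub, feats)
                         else character()))
}

subset_dataset <- function(dataset, pid) {
  keep <- function(df) df[df$patient_id %in% pid, , drop = FALSE]
  structure(list(patients = keep(dataset$patients),
                 purchases = keep(dataset$purchases),
                 diagnoses = keep(dataset$diagnoses),
                 insurance = keep(dataset$insurance),
                 population = dataset$population,
                 extraction_date = dataset$extraction_date,
                 codebook = dataset$codebook),
            class = "ehr_dataset")
}

# human-readable event references backing a fired criterion
criterion_evidence <- function(cid, ds, feats) {
  cb <- ds$codebook
  pur <- ds$purchases
  dx <- ds$diagnoses
  fpd <- feats$fpd[1]
  dx_ev <- function(sets, lo = NULL, hi = NULL, closed_hi = FALSE) {
    hit <- dx[icd10_match(dx$icd10_code, unlist(cb$dx_sets[sets])), , drop = FALSE]
    if (!is.null(lo) && !is.na(fpd)) {
      rel <- as.integer(hit$dx_date - fpd)
      hit <- hit[rel >= lo & (if (closed_hi) rel <= hi else rel < hi), , drop = FALSE]
    }
    paste0("dx ", hit$icd10_code, " on ", format(hit$dx_date))
  }
  apm_ev <- function() {
    rows <- pur[pur$apm_class %in% cb$inclusion_classes, , drop = FALSE]
    paste0("purchase ", rows$atc_code, " on ", format(rows$purchase_date))
  }
  ap_ev <- function() {
    rows <- pur[pur$apm_class == "antipsychotic", , drop = FALSE]
    paste0("purchase ", rows$atc_code, " on ", format(rows$purchase_date))
  }
  two_years <- years_to_days(2)
  switch(cid,
    INC1 = apm_ev(),
    INC2 = paste0("FPD ", format(fpd), " within insurance period"),
    INC3 = paste0("FPD ", format(fpd)),
    INC4 = paste0("age at FPD ", feats$age_fpd[1]),
    EXC1 = dx_ev(c("hyperprolactinemia", "pituitary_adenoma")),
    EXC2 = c(dx_ev("pituitary_adenoma"), apm_ev()),
    EXC3 = c(dx_ev("pituitary_adenoma"), apm_ev()),
    EXC4 = c(dx_ev("pregnancy_or_birth", -two_years, 0L), apm_ev()),
    EXC5 = dx_ev(c("hydrocephalus", "anoxic_brain_injury")),
    EXC6 = c(dx_ev("tbi", -cb$half_year_days, 0L),
             dx_ev("coma", -cb$half_year_days, 0L)),
    EXC7 = dx_ev(c("psp", "msa", "cbd")),
    EXC8 = dx_ev("rls"),
    EXC9 = ap_ev(),
    EXC10 = apm_ev(),
    EXC11 = apm_ev(),
    EXC12 = dx_ev(c("recurrent_falls", "lethargy", "general_deterioration"),
                  -365L, years_to_days(5), closed_hi = TRUE),
    EXC13 = apm_ev(),
    EXC14 = apm_ev(),
    POS1 = "no PD diagnosis on record",
    POS2 = paste0("observation end ", format(feats$obs_end[1]),
                  " < 2 years after FPD ", format(fpd)),
    POS3 = apm_ev(),
    POS4 = c(ap_ev(), dx_ev("pd")),
    character())
}
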