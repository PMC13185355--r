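#' Matching specification for control selection
#'
#' Exact matching on sex and age (within `age_tolerance` completed years at
#' the case's index date), optional exact balance keys (e.g. ethnic group),
#' controls required to be alive at the case's index date and to have at
#' least the case's follow-up, selected without replacement in seeded random
#' case order.
#'
#' @param ratio controls per case (default 4).
#' @param age_tolerance years (default 1).
#' @param balance_keys further columns matched exactly (default none).
#' @param seed RNG seed for case order and tie-breaks.
#' @return list of class `pd_match_spec`.
#' @export
match_spec <- function(ratio = 4, age_tolerance = 1, balance_keys = character(),
                       seed = 1L) {
  stopifnot(ratio >= 1, age_tolerance >= 0)
  structure(list(ratio = as.integer(ratio), age_tolerance = age_tolerance,
                 balance_keys = balance_keys, seed = as.integer(seed)),
            class = c("pd_match_spec", "list"))
}

#' Select matched controls for each case
#'
#' The pool must be pre-filtered to valid controls (never purchased an APM,
#' never diagnosed with PD). Each control is used at most once; cases with
#' fewer than `ratio` eligible controls are matched as far as possible and
#' reported in the diagnostics. An empty pool yields zero matches with a
#' warning, not an error.
#'
#' @param cases tibble: `patient_id`, `sex`, `birth_date`, `index_date`,
#'   `obs_end` (end of follow-up), plus any `balance_keys`.
#' @param pool tibble: `patient_id`, `sex`, `birth_date`, `death_date`,
#'   `obs_end`, plus any `balance_keys`.
#' @param spec a [match_spec()].
#' @return list of class `pd_matched_cohort`: `matches` (tibble `case_id`,
#'   `control_id`, `index_date` — the artificial index date assigned to the
#'   control), `diagnostics` (per-case `n_controls`, `fully_matched`),
#'   `balance` (age standardized difference).
#' @export
select_controls <- function(cases, pool, spec = match_spec()) {
  set.seed(spec$seed)
  order_idx <- sample(nrow(cases))
  available <- rep(TRUE, nrow(pool))
  matches <- vector("list", nrow(cases))
  n_matched <- integer(nrow(cases))
  if (nrow(pool) == 0) warn("empty control pool: no case can be matched")

  pool_death <- pool$death_date
  for (ci in order_idx) {
    cs <- cases[ci, ]
    case_age <- age_at(cs$birth_date, cs$index_date)
    elig <- available &
      pool$sex == cs$sex &
      abs(age_at(pool$birth_date, cs$index_date) - case_age) <= spec$age_tolerance &
      (is.na(pool_death) | pool_death >= cs$index_date) &
      pool$obs_end >= cs$obs_end
    for (k in spec$balance_keys) elig <- elig & pool[[k]] == cs[[k]]
    idx <- which(elig)
    take <- min(spec$ratio, length(idx))
    if (take > 0) {
      sel <- if (length(idx) == 1) idx else sample(idx, take)
      available[sel] <- FALSE
      matches[[ci]] <- tibble(case_id = cs$patient_id,
                              control_id = pool$patient_id[sel],
                              index_date = cs$index_date)
    }
    n_matched[ci] <- take
  }
  matches <- purrr::list_rbind(purrr::compact(matches))
  diagnostics <- tibble(case_id = cases$patient_id, n_controls = n_matched,
                        fully_matched = n_matched == spec$ratio)

  balance <- NULL
  if (nrow(matches)) {
    case_ages <- age_at(cases$birth_date, cases$index_date)
    ctrl <- matches %>%
      left_join(pool %>% select(patient_id, birth_date),
                by = c(control_id = "patient_id"))
    ctrl_ages <- age_at(ctrl$birth_date, ctrl$index_date)
    sd_pool <- sqrt((sd(case_ages)^2 + sd(ctrl_ages)^2) / 2)
    balance <- tibble(variable = "age",
                      mean_case = mean(case_ages),
                      mean_control = mean(ctrl_ages),
                      std_diff = (mean(case_ages) - mean(ctrl_ages)) / sd_pool)
  }
  structure(list(matches = matches, diagnostics = diagnostics,
                 balance = balance, spec = spec),
            class = c("pd_matched_cohort", "list"))
}

#' Index table of a matched cohort
#'
#' One row per subject (cases and their matched controls), with the control
#' rows carrying their case's artificial index date, ready for
#' [plant_prodromal_codes()] and [annual_dx_prevalence()].
#'
#' @param matched a `pd_matched_cohort`.
#' @param cases,pool the tibbles passed to [select_controls()] (must carry
#'   `data_start`; `sex`/`birth_date` are propagated when present).
#' @return tibble `patient_id`, `group`, `index_date`, `data_start`, `sex`,
#'   `age_at_index`, `case_id`.
#' @export
matched_index_table <- function(matched, cases, pool) {
  m <- matched$matches
  kept_cases <- cases %>% filter(patient_id %in% m$case_id)
  case_rows <- kept_cases %>%
    transmute(patient_id, group = "case", index_date,
              data_start = .data$data_start, sex,
              age_at_index = age_at(birth_date, index_date),
              case_id = patient_id)
  ctrl_rows <- m %>%
    left_join(pool %>% select(patient_id, sex, birth_date,
                              data_start = "data_start"),
              by = c(control_id = "patient_id")) %>%
    transmute(patient_id = control_id, group = "control", index_date,
              data_start, sex,
              age_at_index = age_at(birth_date, index_date), case_id)
  bind_rows(case_rows, ctrl_rows)
}

#' Year-offset diagnosis prevalence before the index date
#'
#' For offsets 0 (the 365 days immediately preceding the index date) back to
#' `-max_offset_back`, the proportion of subjects with at least one matching
#' diagnosis inside the offset-year window `[index - (k+1)*365, index -
#' k*365)`, relative to the subjects with available data for that window
#' (window end after the subject's data start).
#'
#' @param index_table tibble with `patient_id`, `group`, `index_date`,
#'   `data_start`.
#' @param diagnoses diagnosis tibble (`patient_id`, `dx_date`, `icd10_code`).
#' @param code ICD-10 prefix (dot-insensitive).
#' @param max_offset_back deepest offset (default 17).
#' @return tibble `code`, `year_offset` (0, -1, ..), `group`, `numerator`,
#'   `denominator`, `proportion`.
#' @export
annual_dx_prevalence <- function(index_table, diagnoses, code,
                                 max_offset_back = 17) {
  if (!nrow(index_table)) abort("empty index table")
  hits <- diagnoses[icd10_match(diagnoses$icd10_code, code), , drop = FALSE] %>%
    inner_join(index_table %>% select(patient_id, index_date),
               by = "patient_id") %>%
    mutate(days_before = as.numeric(index_date - dx_date)) %>%
    filter(days_before > 0)
  out <- purrr::map(0:max_offset_back, function(k) {
    avail <- index_table$index_date - k * 365L > index_table$data_start
    hit_ids <- unique(hits$patient_id[hits$days_before > k * 365 &
                                        hits$days_before <= (k + 1) * 365])
    index_table %>%
      filter(avail) %>%
      group_by(group) %>%
      summarise(numerator = sum(patient_id %in% hit_ids),
                denominator = dplyr::n(), .groups = "drop") %>%
      mutate(code = code, year_offset = -k)
  }) %>% purrr::list_rbind()
  out %>%
    mutate(proportion = ifelse(denominator > 0, numerator / denominator,
                               NA_real_)) %>%
    select(code, year_offset, group, numerator, denominator, proportion)
}

#' Case-control comparison of year-offset prevalences
#'
#' Pearson chi-squared test for independence (uncorrected) on the 2x2
#' diagnosed-by-group table at each (code, offset), with a Wald CI on the
#' difference in proportions. Offsets where either group has a zero
#' denominator are flagged `skipped` and carry NA statistics.
#'
#' @param points output of [annual_dx_prevalence()] (both groups present).
#' @param level confidence level for the difference CI.
#' @return tibble, one row per (code, year_offset): proportions, `diff`,
#'   `diff_lower`, `diff_upper`, `chisq`, `p_value`, `skipped`.
#' @export
compare_groups <- function(points, level = 0.95) {
  wide <- points %>%
    tidyr::pivot_wider(id_cols = c(code, year_offset),
                       names_from = group,
                       values_from = c(numerator, denominator))
  z <- qnorm(1 - (1 - level) / 2)
  wide %>%
    rowwise() %>%
    mutate(
      skipped = is.na(.data$denominator_case) || is.na(.data$denominator_control) ||
        .data$denominator_case == 0 || .data$denominator_control == 0,
      p_case = if (skipped) NA_real_ else .data$numerator_case / .data$denominator_case,
      p_control = if (skipped) NA_real_ else
        .data$numerator_control / .data$denominator_control,
      diff = p_case - p_control,
      se_diff = if (skipped) NA_real_ else
        sqrt(p_case * (1 - p_case) / .data$denominator_case +
               p_control * (1 - p_control) / .data$denominator_control),
      diff_lower = diff - z * se_diff,
      diff_upper = diff + z * se_diff,
      chisq = if (skipped) NA_real_ else {
        m <- matrix(c(.data$numerator_case,
                      .data$denominator_case - .data$numerator_case,
                      .data$numerator_control,
                      .data$denominator_control - .data$numerator_control),
                    nrow = 2, byrow = TRUE)
        if (any(colSums(m) == 0)) NA_real_ else
          suppressWarnings(unname(chisq.test(m, correct = FALSE)$statistic))
      },
      p_value = if (is.na(chisq)) NA_real_ else
        stats::pchisq(chisq, df = 1, lower.tail = FALSE)) %>%
    ungroup() %>%
    select(code, year_offset, p_case, p_control, diff, diff_lower,
           diff_upper, chisq, p_value, skipped)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; the default family is all offsets within one
#' diagnosis code (applied by [prediagnostic_compare()]).
#'
#' @param p numeric vector of p-values in [0,1] (NA passed through).
#' @return adjusted p-values, monotone in rank order and at most 1.
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Full pre-diagnostic comparison for a set of codes
#'
#' Runs [annual_dx_prevalence()] and [compare_groups()] per code and applies
#' [fdr_adjust()] within each code's family of offsets.
#'
#' @param index_table matched index table ([matched_index_table()]).
#' @param diagnoses diagnosis tibble.
#' @param codes character vector of ICD-10 prefixes.
#' @param max_offset_back deepest offset.
#' @param level confidence level.
#' @return tibble with per-(code, offset) proportions, difference CI,
#'   chi-squared `p_value` and `p_adjusted`.
#' @export
prediagnostic_compare <- function(index_table, diagnoses, codes,
                                  max_offset_back = 17, level = 0.95) {
  purrr::list_rbind(purrr::map(codes, function(cd) {
    pts <- annual_dx_prevalence(index_table, diagnoses, cd, max_offset_back)
    compare_groups(pts, level) %>%
      mutate(p_adjusted = fdr_adjust(p_value))
  }))
}

#' Stratified pre-diagnostic analysis
#'
#' Repeats [prediagnostic_compare()] overall and within sex and
#' age-at-index (<= 75 / > 75) strata. Strata are defined by the *case's*
#' properties; matched controls inherit their case's stratum so sets stay
#' intact. Empty strata are skipped with a warning.
#'
#' @inheritParams prediagnostic_compare
#' @param age_cut stratum boundary for age at index (default 75).
#' @return tibble with a leading `stratum` column.
#' @export
stratified_run <- function(index_table, diagnoses, codes,
                           max_offset_back = 17, age_cut = 75, level = 0.95) {
  case_props <- index_table %>% filter(group == "case") %>%
    transmute(case_id, case_sex = sex,
              case_age_band = ifelse(age_at_index <= age_cut,
                                     paste0("age<=", age_cut),
                                     paste0("age>", age_cut)))
  it <- index_table %>% left_join(case_props, by = "case_id")
  strata <- list(
    overall = rep(TRUE, nrow(it)),
    male = it$case_sex == "male",
    female = it$case_sex == "female")
  strata[[paste0("age<=", age_cut)]] <- grepl("<=", it$case_age_band)
  strata[[paste0("age>", age_cut)]] <- grepl(">", it$case_age_band) &
    !grepl("<=", it$case_age_band)
  purrr::list_rbind(purrr::imap(strata, function(keep, nm) {
    sub <- it[keep, ]
    if (!nrow(sub) || !any(sub$group == "case")) {
      warn(paste0("stratum '", nm, "' empty: skipped"))
      return(NULL)
    }
    prediagnostic_compare(sub, diagnoses, codes, max_offset_back, level) %>%
      mutate(stratum = nm, .before = 1)
  }))
}
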