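#' Confusion counts against a reference standard
#'
#' Compares algorithm statuses with reference labels. Following the combined
#' case definition used for performance estimation, both certainty tiers
#' (`probable_pd`, `possible_pd`) count as algorithm-positive by default.
#'
#' @param predictions tibble with `patient_id` and `status` (a `pd_cohort`
#'   works as-is).
#' @param truth tibble with `patient_id` and `truth` (`"pd"` / `"non_pd"`).
#' @param positive_statuses statuses counted as algorithm-positive.
#' @return one-row tibble: `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`, `false_positive_rate` (proportions in [0,1]; NA when the
#'   denominator is empty).
#' @export
#' @examples
#' pred <- tibble::tibble(patient_id = as.character(1:4),
#'                        status = c("probable_pd", "excluded",
#'                                   "possible_pd", "not_eligible"))
#' truth <- tibble::tibble(patient_id = as.character(1:4),
#'                         truth = c("pd", "pd", "non_pd", "non_pd"))
#' confusion(pred, truth)
confusion <- function(predictions, truth,
                      positive_statuses = c("probable_pd", "possible_pd")) {
  if (anyDuplicated(predictions$patient_id) || anyDuplicated(truth$patient_id)) {
    abort("duplicated patient_id in predictions or truth")
  }
  unlabeled <- setdiff(truth$patient_id, predictions$patient_id)
  if (length(unlabeled)) {
    abort(paste0(length(unlabeled), " labeled patient(s) without a prediction"))
  }
  j <- inner_join(tibble(patient_id = truth$patient_id, truth = truth$truth),
                  predictions[, c("patient_id", "status")], by = "patient_id")
  pos <- j$status %in% positive_statuses
  is_pd <- j$truth == "pd"
  tp <- sum(pos & is_pd); fn <- sum(!pos & is_pd)
  fp <- sum(pos & !is_pd); tn <- sum(!pos & !is_pd)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble(tp = tp, fn = fn, tn = tn, fp = fp,
         sensitivity = div(tp, tp + fn),
         specificity = div(tn, tn + fp),
         false_positive_rate = div(fp, tn + fp))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form score interval (the default method for all reported
#' proportions).
#'
#' @param successes,n counts, `0 <= successes <= n`, `n >= 1`.
#' @param level confidence level.
#' @return one-row tibble: `estimate`, `lower`, `upper`, `level`, `method`.
#' @export
#' @examples
#' wilson_ci(19, 128)  # lower ~0.0971, upper ~0.2202
wilson_ci <- function(successes, n, level = 0.95) {
  if (n < 1) abort("n must be >= 1")
  if (successes < 0 || successes > n) abort("successes must be in [0, n]")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  tibble(estimate = p,
         lower = max(0, (centre - half) / den),
         upper = min(1, (centre + half) / den),
         level = level, method = "wilson")
}

#' Exact (Clopper-Pearson) confidence interval for a binomial proportion
#'
#' Computed by inversion of the binomial CDF via beta quantiles.
#'
#' @inheritParams wilson_ci
#' @return one-row tibble like [wilson_ci()], `method = "exact_binomial"`.
#' @export
exact_binomial_ci <- function(successes, n, level = 0.95) {
  if (n < 1) abort("n must be >= 1")
  if (successes < 0 || successes > n) abort("successes must be in [0, n]")
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else qbeta(a, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - a, successes + 1, n - successes)
  tibble(estimate = successes / n, lower = lower, upper = upper,
         level = level, method = "exact_binomial")
}

#' Validation report in the style of a diagnostic-performance table
#'
#' Combines [confusion()] with proportion CIs for sensitivity, specificity
#' and the false positive rate. Proportions are also given as percentages
#' rounded half-up to one decimal, the display convention used throughout.
#'
#' @inheritParams confusion
#' @param ci_method `"wilson"` (default) or `"exact_binomial"`.
#' @param level confidence level.
#' @return tibble, one row per metric: `metric`, `successes`, `n`,
#'   `estimate`, `lower`, `upper`, `percent` (1 d.p.), `method`.
#' @export
validation_report <- function(predictions, truth,
                              positive_statuses = c("probable_pd", "possible_pd"),
                              ci_method = c("wilson", "exact_binomial"),
                              level = 0.95) {
  ci_method <- match.arg(ci_method)
  cm <- confusion(predictions, truth, positive_statuses)
  ci_fun <- if (ci_method == "wilson") wilson_ci else exact_binomial_ci
  mk <- function(metric, x, n) {
    if (n == 0) {
      return(tibble(metric = metric, successes = x, n = n,
                    estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                    percent = NA_real_, method = ci_method))
    }
    ci <- ci_fun(x, n, level)
    tibble(metric = metric, successes = x, n = n, estimate = ci$estimate,
           lower = ci$lower, upper = ci$upper,
           percent = round_half_up(100 * ci$estimate, 1), method = ci_method)
  }
  bind_rows(
    mk("sensitivity", cm$tp, cm$tp + cm$fn),
    mk("specificity", cm$tn, cm$tn + cm$fp),
    mk("false_positive_rate", cm$fp, cm$tn + cm$fp))
}

# half-up rounding to match displayed percentages
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Diagnosis-based ascertainment audit
#'
#' The complement of the medication-based algorithm: take everyone with a
#' recorded PD diagnosis and audit (a) specialist involvement — the share
#' with no neurologist-assigned PD diagnosis and, further, neither a
#' neurologist diagnosis nor any movement-disorder-clinic (MDC) visit;
#' (b) APM purchasing — the share who never purchased an APM, overall and
#' within the specialist / no-specialist subgroups; and (c) the per-calendar-
#' year proportion of patients whose first PD diagnosis year included a
#' neurologist-assigned PD diagnosis within one year of their first PD
#' diagnosis.
#'
#' @param dataset an `ehr_dataset`.
#' @return list with `summary` (one-row tibble of shares with denominators;
#'   proportions NA with `empty_denominator = TRUE` flags when no PD
#'   diagnoses exist) and `by_year` (tibble `year`, `n`,
#'   `neurologist_within_1y`).
#' @export
ascertainment_audit <- function(dataset) {
  cb <- dataset$codebook
  dx <- dataset$diagnoses
  pd_dx <- dx[icd10_match(dx$icd10_code, cb$dx_sets$pd), , drop = FALSE]
  if (nrow(pd_dx) == 0) {
    return(list(
      summary = tibble(n_pd_diagnosed = 0L, prop_no_neurologist = NA_real_,
                       prop_no_specialist = NA_real_, prop_never_apm = NA_real_,
                       prop_never_apm_specialist = NA_real_,
                       prop_never_apm_no_specialist = NA_real_,
                       empty_denominator = TRUE),
      by_year = tibble(year = integer(), n = integer(),
                       neurologist_within_1y = numeric())))
  }
  per <- pd_dx %>%
    group_by(patient_id) %>%
    summarise(first_pd = min(dx_date),
              any_neuro = any(provider_type == "neurologist"),
              neuro_1y = any(provider_type == "neurologist" &
                               dx_date <= min(dx_date) + 365L),
              .groups = "drop")
  mdc_ids <- unique(dx$patient_id[dx$provider_type == "mdc"])
  apm_ids <- unique(dataset$purchases$patient_id[
    dataset$purchases$apm_class %in% cb$inclusion_classes])
  per <- per %>%
    mutate(mdc = patient_id %in% mdc_ids,
           specialist = any_neuro | mdc,
           never_apm = !(patient_id %in% apm_ids))
  prop_in <- function(flag, subset = rep(TRUE, nrow(per))) {
    d <- sum(subset)
    if (d == 0) NA_real_ else sum(flag & subset) / d
  }
  summary <- tibble(
    n_pd_diagnosed = nrow(per),
    prop_no_neurologist = prop_in(!per$any_neuro),
    prop_no_specialist = prop_in(!per$specialist),
    prop_never_apm = prop_in(per$never_apm),
    prop_never_apm_specialist = prop_in(per$never_apm, per$specialist),
    prop_never_apm_no_specialist = prop_in(per$never_apm, !per$specialist),
    empty_denominator = FALSE)
  by_year <- per %>%
    mutate(year = as.integer(format(first_pd, "%Y"))) %>%
    group_by(year) %>%
    summarise(n = dplyr::n(), neurologist_within_1y = mean(neuro_1y),
              .groups = "drop")
  list(summary = summary, by_year = by_year)
}
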