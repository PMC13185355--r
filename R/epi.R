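#' WHO world standard population weights
#'
#' The 5-year-band weights of the WHO world standard population (Ahmad et
#' al., GPE Discussion Paper 31, WHO 2001), embedded as a versioned constant
#' and renormalized to sum exactly to 1. Replaceable by any tibble with
#' `band_start` and `weight` columns.
#'
#' @param truncate_at optional lower age bound; bands below it are dropped
#'   and the remaining weights renormalized to 1 (the population at risk).
#' @return tibble `band_start`, `weight` (weights sum to 1).
#' @export
#' @examples
#' sum(who_standard_population()$weight)  # 1
#' who_standard_population(truncate_at = 20)
who_standard_population <- function(truncate_at = NULL) {
  w <- c(8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59, 6.04,
         5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.44, 0.15, 0.04)
  std <- tibble(band_start = seq(0, 95, by = 5), weight = w / sum(w))
  if (!is.null(truncate_at)) {
    std <- std %>% filter(band_start >= truncate_at) %>%
      mutate(weight = weight / sum(weight))
  }
  attr(std, "provenance") <- "WHO world standard population (2001), 5-year bands"
  std
}

#' Exact Poisson (Garwood) confidence interval for a rate
#'
#' Chi-square inversion of the Poisson count distribution, scaled to a rate
#' per `scale` person-years. Lower bound is 0 at zero counts.
#'
#' @param count observed case count (vectorized).
#' @param denominator person-time (approximated by annual population counts).
#' @param level confidence level.
#' @param scale rate multiplier (default 100,000).
#' @return tibble `rate`, `lower`, `upper` (per `scale`).
#' @export
#' @examples
#' poisson_exact_ci(0, 1e5)$upper  # 3.6889 per 100,000
poisson_exact_ci <- function(count, denominator, level = 0.95, scale = 1e5) {
  stopifnot(all(count >= 0), all(denominator > 0))
  a <- (1 - level) / 2
  lower <- ifelse(count == 0, 0, qchisq(a, 2 * count) / 2)
  upper <- qchisq(1 - a, 2 * count + 2) / 2
  tibble(rate = scale * count / denominator,
         lower = scale * lower / denominator,
         upper = scale * upper / denominator)
}

default_age_breaks <- function() c(20, 40, 50, 60, 70, 80, 90, 100)

age_group_label <- function(age, breaks = default_age_breaks()) {
  labs <- paste0("[", breaks[-length(breaks)], "-", breaks[-1], ")")
  cut(age, breaks = breaks, right = FALSE, labels = labs)
}

aggregate_population <- function(population, breaks = default_age_breaks(),
                                 by_sex = FALSE) {
  labs <- paste0("[", breaks[-length(breaks)], "-", breaks[-1], ")")
  pop <- population %>%
    mutate(age_group = cut(band_start, breaks = breaks, right = FALSE,
                           labels = labs)) %>%
    filter(!is.na(age_group))
  keys <- c("year", "age_group", if (by_sex) "sex")
  pop %>% group_by(across(all_of(keys))) %>%
    summarise(population = sum(population), .groups = "drop")
}

#' Annual crude incidence rates by age group
#'
#' New algorithm-identified PD cases per 100,000 insured population, by
#' calendar year and age group of the index date, with exact Poisson CIs.
#' A case contributes to the year and age group of its index date.
#'
#' @param cohort a `pd_cohort` from [classify_cohort()] (or any tibble with
#'   `status`, `index_date`, `age_at_index`, and `sex` when `by_sex`).
#' @param population denominator tibble `year`, `band_start`, `sex`,
#'   `population` (5-year bands).
#' @param breaks age-group boundaries; default the decadal study groups
#'   `[20-40), [40-50), ..., [90-100)`.
#' @param by_sex stratify by sex.
#' @param level confidence level.
#' @return tibble of class `pd_rate_table`: `year`, `age_group` (and `sex`),
#'   `count`, `population`, `rate`, `ci_lower`, `ci_upper` (per 100,000).
#' @export
crude_incidence <- function(cohort, population, breaks = default_age_breaks(),
                            by_sex = FALSE, level = 0.95) {
  cases <- as_tibble(cohort) %>%
    filter(status %in% c("probable_pd", "possible_pd"), !is.na(index_date)) %>%
    mutate(year = as.integer(format(index_date, "%Y")),
           age_group = age_group_label(age_at_index, breaks)) %>%
    filter(!is.na(age_group))
  keys <- c("year", "age_group", if (by_sex) "sex")
  counts <- cases %>% group_by(across(all_of(keys))) %>%
    summarise(count = dplyr::n(), .groups = "drop")
  pop <- aggregate_population(population, breaks, by_sex)
  missing <- anti_join(counts, pop, by = keys)
  if (nrow(missing)) {
    abort(paste0("missing population denominator for cell(s): ",
                 paste(utils::head(paste(missing$year, missing$age_group),
                                   3), collapse = "; ")))
  }
  out <- pop %>%
    left_join(counts, by = keys) %>%
    mutate(count = coalesce(count, 0L))
  ci <- poisson_exact_ci(out$count, out$population, level)
  out <- out %>% mutate(rate = ci$rate, ci_lower = ci$lower,
                        ci_upper = ci$upper) %>%
    arrange(across(all_of(keys)))
  class(out) <- c("pd_rate_table", class(out))
  out
}

#' Age-adjusted incidence rate by direct standardization
#'
#' Weighted sum of 5-year-band rates with external standard weights. The CI
#' uses the variance of the weighted sum of independent Poisson band counts.
#'
#' @param cells tibble with `band_start`, `count`, `population` (one row per
#'   5-year band, already aggregated over sex/strata).
#' @param standard tibble `band_start`, `weight` summing to 1
#'   ([who_standard_population()]); pass `truncate_at` there for the
#'   at-risk-population variant.
#' @param level confidence level.
#' @return one-row tibble `aair`, `ci_lower`, `ci_upper` per 100,000.
#' @export
aair <- function(cells, standard = who_standard_population(), level = 0.95) {
  cells <- cells %>% group_by(band_start) %>%
    summarise(count = sum(count), population = sum(population),
              .groups = "drop")
  if (!setequal(cells$band_start, standard$band_start)) {
    abort("age bands of data and standard population do not match")
  }
  j <- inner_join(cells, standard, by = "band_start")
  rate <- 1e5 * sum(j$weight * j$count / j$population)
  var_rate <- 1e10 * sum(j$weight^2 * j$count / j$population^2)
  z <- qnorm(1 - (1 - level) / 2)
  tibble(aair = rate,
         ci_lower = max(0, rate - z * sqrt(var_rate)),
         ci_upper = rate + z * sqrt(var_rate))
}

#' Annual point prevalence of algorithm-identified PD
#'
#' Numerator: patients classified PD (either tier) whose index date falls on
#' or before December 31 of the year and who are alive and insured at some
#' point during the year (cases remain prevalent until death or exit; a
#' patient dying mid-year still counts in that year). Denominator: the
#' year's insured population.
#'
#' @param cohort `pd_cohort`.
#' @param dataset the `ehr_dataset` behind it (for death and insurance).
#' @param years calendar years (default: the population table's years).
#' @param by_sex stratify by sex.
#' @return tibble `year` (and `sex`), `cases`, `population`,
#'   `prevalence_per_1e5`, `proportion`.
#' @export
point_prevalence <- function(cohort, dataset, years = NULL, by_sex = FALSE) {
  population <- dataset$population
  if (is.null(years)) years <- sort(unique(population$year))
  pd <- as_tibble(cohort) %>%
    filter(status %in% c("probable_pd", "possible_pd"), !is.na(index_date)) %>%
    left_join(dataset$patients %>% select(patient_id, sex, death_date),
              by = "patient_id")
  ins <- dataset$insurance %>% group_by(patient_id) %>%
    summarise(ins_start = min(start), ins_end = max(end), .groups = "drop")
  pd <- pd %>% left_join(ins, by = "patient_id")
  out <- purrr::map(years, function(y) {
    ystart <- as.Date(sprintf("%d-01-01", y))
    yend <- as.Date(sprintf("%d-12-31", y))
    alive <- is.na(pd$death_date) | pd$death_date >= ystart
    insured <- pd$ins_start <= yend & pd$ins_end >= ystart
    prevalent <- pd$index_date <= yend & alive & insured
    if (by_sex) {
      purrr::list_rbind(purrr::map(c("male", "female"), function(s) {
        n <- sum(prevalent & pd$sex == s)
        den <- sum(population$population[population$year == y &
                                           population$sex == s])
        tibble(year = y, sex = s, cases = n, population = den)
      }))
    } else {
      tibble(year = y, cases = sum(prevalent),
             population = sum(population$population[population$year == y]))
    }
  }) %>% purrr::list_rbind()
  out %>% mutate(prevalence_per_1e5 = 1e5 * cases / population,
                 proportion = cases / population)
}

new_pd_trend <- function(fit, family, beta, se, dispersion, level) {
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(
    fit = fit, family = family,
    beta = beta, se = se, dispersion = dispersion,
    deviance = fit$deviance, df_residual = fit$df.residual,
    apc = 100 * (exp(beta) - 1),
    apc_lower = 100 * (exp(beta - z * se) - 1),
    apc_upper = 100 * (exp(beta + z * se) - 1),
    level = level), class = "pd_trend")
}

#' Incidence trend with annual percent change
#'
#' Log-linear Poisson regression of yearly case counts on continuous
#' calendar year with a log-population offset. Overdispersion is assessed by
#' the residual deviance / degrees-of-freedom ratio; above
#' `dispersion_threshold` the model is refitted as quasi-Poisson (scaled
#' standard errors). APC = 100 (exp(beta) - 1) with Wald CI on beta.
#'
#' @param data tibble with `year`, `count`, `population`; multiple rows per
#'   year (e.g. age bands) are summed.
#' @param dispersion_threshold deviance/df ratio above which quasi-Poisson
#'   scaling is applied.
#' @param level confidence level.
#' @return object of class `pd_trend` (see [tidy.pd_trend()],
#'   [glance.pd_trend()]).
#' @export
#' @examples
#' d <- tibble::tibble(year = 2005:2024,
#'                     count = rpois(20, 500 * 0.96^(0:19)),
#'                     population = 1e6)
#' fit_incidence_trend(d)
fit_incidence_trend <- function(data, dispersion_threshold = 1, level = 0.95) {
  d <- data %>% group_by(year) %>%
    summarise(count = sum(count), population = sum(population),
              .groups = "drop")
  if (nrow(d) < 3) abort("at least 3 years of data required")
  fit <- suppressWarnings(
    glm(count ~ year + offset(log(population)), data = d, family = poisson()))
  dispersion <- fit$deviance / fit$df.residual
  family_used <- "poisson"
  if (dispersion > dispersion_threshold) {
    fit <- suppressWarnings(
      glm(count ~ year + offset(log(population)), data = d,
          family = quasipoisson()))
    family_used <- "quasi_poisson"
  }
  sm <- summary(fit)$coefficients
  new_pd_trend(fit, family_used, beta = sm["year", 1], se = sm["year", 2],
               dispersion = dispersion, level = level)
}

#' Prevalence trend with annual percent change
#'
#' Binomial regression of prevalent-case counts on continuous calendar year,
#' weighted by annual population size through the binomial denominator.
#' Default log link so the year coefficient transforms to an APC; logit
#' available.
#'
#' @param data tibble with `year`, `cases`, `population`.
#' @param link `"log"` (default) or `"logit"`.
#' @param level confidence level.
#' @return `pd_trend` object.
#' @export
fit_prevalence_trend <- function(data, link = c("log", "logit"), level = 0.95) {
  link <- match.arg(link)
  d <- data %>% group_by(year) %>%
    summarise(cases = sum(cases), population = sum(population),
              .groups = "drop")
  if (nrow(d) < 3) abort("at least 3 years of data required")
  if (any(d$cases >= d$population)) abort("prevalence >= 1 in some cell")
  fit <- suppressWarnings(
    glm(cbind(cases, population - cases) ~ year, data = d,
        family = binomial(link = link)))
  sm <- summary(fit)$coefficients
  new_pd_trend(fit, paste0("binomial_", link), beta = sm["year", 1],
               se = sm["year", 2],
               dispersion = fit$deviance / fit$df.residual, level = level)
}

#' Per-stratum incidence trends
#'
#' Fits [fit_incidence_trend()] within each level of a grouping column
#' (e.g. `age_group`) plus overall.
#'
#' @param rate_table output of [crude_incidence()].
#' @param by grouping column name (default `"age_group"`).
#' @inheritParams fit_incidence_trend
#' @return tibble: stratum, `beta`, `se`, `dispersion`, `family`, `apc`,
#'   `apc_lower`, `apc_upper`.
#' @export
incidence_trends <- function(rate_table, by = "age_group",
                             dispersion_threshold = 1, level = 0.95) {
  strata <- c("overall", as.character(unique(rate_table[[by]])))
  purrr::list_rbind(purrr::map(strata, function(s) {
    d <- if (s == "overall") rate_table else
      rate_table[as.character(rate_table[[by]]) == s, ]
    tr <- fit_incidence_trend(d, dispersion_threshold, level)
    tibble(stratum = s, beta = tr$beta, se = tr$se,
           dispersion = tr$dispersion, family = tr$family, apc = tr$apc,
           apc_lower = tr$apc_lower, apc_upper = tr$apc_upper)
  }))
}

#' @export
print.pd_trend <- function(x, ...) {
  cat("<pd_trend> family:", x$family, "\n",
      sprintf("beta(year) = %.5f (SE %.5f), dispersion = %.2f\n",
              x$beta, x$se, x$dispersion),
      sprintf("APC = %.2f%% (%g%% CI %.2f to %.2f)\n", x$apc, 100 * x$level,
              x$apc_lower, x$apc_upper))
  invisible(x)
}
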