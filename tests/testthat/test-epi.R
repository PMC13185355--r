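mk_cohort <- function(rows) {
  co <- tibble::tibble(patient_id = sprintf("P%03d", seq_len(nrow(rows))),
                       status = "probable_pd",
                       fpd = rows$index, index_date = rows$index,
                       index_rule = "IDX_DEFAULT",
                       age_at_index = rows$age, fired = "",
                       sex = rows[["sex"]] %||% "male")
  co
}

flat_pop <- function(years = 2010, size = 1000) {
  tidyr::expand_grid(year = years, band_start = seq(0, 95, 5),
                     sex = c("male", "female")) %>%
    dplyr::mutate(population = size)
}

test_that("crude incidence bins cases by index year and age group", {
  co <- mk_cohort(tibble::tibble(index = d("2010-07-01"), age = 85))
  rt <- crude_incidence(co, flat_pop())
  cell <- dplyr::filter(rt, age_group == "[80-90)")
  expect_equal(cell$count, 1)
  # a case appears in exactly one cell
  expect_equal(sum(rt$count), 1)
  # denominator: 2 bands x 2 sexes x 1000
  expect_equal(cell$population, 4000)
  expect_equal(cell$rate, 1e5 * 1 / 4000)
  # zero-case cells have rate 0 and CI lower 0
  zero <- dplyr::filter(rt, age_group == "[40-50)")
  expect_equal(zero$rate, 0)
  expect_equal(zero$ci_lower, 0)
  expect_gt(zero$ci_upper, 0)
  # 50 cases per 100,000 denominator
  co50 <- mk_cohort(tibble::tibble(index = rep(d("2010-07-01"), 50),
                                   age = rep(65, 50)))
  rt50 <- crude_incidence(co50, flat_pop(size = 25000))
  expect_equal(dplyr::filter(rt50, age_group == "[60-70)")$rate, 50)
  # missing denominator cell errors with the cell named
  expect_error(crude_incidence(co, flat_pop(years = 2011)), "2010")
})

test_that("exact Poisson intervals follow the chi-square closed forms", {
  ci0 <- poisson_exact_ci(0, 1e5)
  expect_equal(ci0$lower, 0)
  expect_equal(ci0$upper, -log(0.025), tolerance = 1e-9)  # 3.6889 per 1e5
  ci100 <- poisson_exact_ci(100, 1e5)
  expect_equal(ci100$lower, qchisq(0.025, 200) / 2, tolerance = 1e-9)
  expect_equal(ci100$upper, qchisq(0.975, 202) / 2, tolerance = 1e-9)
  # interval contains the rate; width shrinks with the count at fixed rate
  w <- vapply(c(10, 100, 1000), function(k) {
    ci <- poisson_exact_ci(k, k * 1000)
    expect_lte(ci$lower, ci$rate); expect_gte(ci$upper, ci$rate)
    ci$upper - ci$lower
  }, 1.0)
  expect_true(all(diff(w) < 0))
})

test_that("direct standardization identities hold", {
  cells <- tibble::tibble(band_start = seq(0, 95, 5),
                          count = rpois(20, 50),
                          population = round(runif(20, 1e4, 1e5)))
  # degenerate standard: all weight on one band equals that band's crude rate
  one <- tibble::tibble(band_start = seq(0, 95, 5), weight = c(1, rep(0, 19)))
  expect_equal(aair(cells, one)$aair, 1e5 * cells$count[1] / cells$population[1])
  # uniform weights give the arithmetic mean of band rates
  unif <- tibble::tibble(band_start = seq(0, 95, 5), weight = rep(1 / 20, 20))
  expect_equal(aair(cells, unif)$aair, mean(1e5 * cells$count / cells$population))
  # equal band rates are invariant to any weighting
  eq <- cells %>% dplyr::mutate(count = population * 30 / 1e5)
  expect_equal(aair(eq, who_standard_population())$aair, 30, tolerance = 1e-9)
  # own population shares as weights reproduce the crude all-ages rate
  own <- tibble::tibble(band_start = cells$band_start,
                        weight = cells$population / sum(cells$population))
  expect_equal(aair(cells, own)$aair,
               1e5 * sum(cells$count) / sum(cells$population),
               tolerance = 1e-9)
  # truncated standard weights renormalize to 1
  expect_equal(sum(who_standard_population(truncate_at = 20)$weight), 1,
               tolerance = 1e-12)
  expect_error(aair(cells[-1, ], who_standard_population()), "bands")
})

test_that("point prevalence counts survivors, not the dead of prior years", {
  pop <- flat_pop(years = 2014:2016)
  pat <- tibble::tibble(patient_id = c("P001", "P002"), sex = "male",
                        birth_date = d("1940-01-01"),
                        death_date = d(c("2015-06-15", NA)),
                        ethnic_group = "unknown", ses_stratum = "unknown")
  ins <- tibble::tibble(patient_id = c("P001", "P002"),
                        start = d("2000-01-01"), end = d("2025-01-01"))
  ds <- new_ehr_dataset(pat, tibble::tibble(
    patient_id = character(), purchase_date = d(character()),
    atc_code = character(), strength_mg = numeric()),
    tibble::tibble(patient_id = character(), dx_date = d(character()),
                   icd10_code = character(), provider_type = character()),
    ins, population = pop, extraction_date = d("2025-01-01"))
  co <- mk_cohort(tibble::tibble(index = d(c("2014-03-01", "2014-05-01")),
                                 age = c(74, 74)))
  co$patient_id <- c("P001", "P002")
  prev <- point_prevalence(co, ds)
  expect_equal(prev$cases, c(2, 2, 1))  # death mid-2015 counts in 2015, not 2016
  expect_equal(prev$prevalence_per_1e5[1], 1e5 * 2 / (40 * 1000))
  # no PD patients: zero everywhere
  prev0 <- point_prevalence(co[0, ], ds)
  expect_true(all(prev0$cases == 0))
})

test_that("trend fits recover exact log-linear structures", {
  years <- 2005:2024
  # counts exactly proportional to 0.96^t on constant population: APC = -4
  dat <- tibble::tibble(year = years, count = 1e4 * 0.96^(years - 2005),
                        population = 1e6)
  tr <- fit_incidence_trend(dat)
  expect_equal(tr$apc, -4, tolerance = 1e-8)
  # constant counts: APC 0
  tr0 <- fit_incidence_trend(tibble::tibble(year = years, count = 500,
                                            population = 1e6))
  expect_equal(tr0$apc, 0, tolerance = 1e-8)
  # APC transform consistency
  expect_equal(tr$apc, 100 * (exp(tr$beta) - 1))
  expect_equal(tr$apc_lower, 100 * (exp(tr$beta - qnorm(0.975) * tr$se) - 1))
  expect_error(fit_incidence_trend(dat[1:2, ]), "3 years")
  # prevalence proportional to 1.03^t under the log link: APC = +3
  prev <- tibble::tibble(year = years,
                         cases = 1e4 * 1.03^(years - 2005), population = 1e7)
  trp <- fit_prevalence_trend(prev)
  expect_equal(trp$apc, 3, tolerance = 1e-8)
  expect_error(fit_prevalence_trend(tibble::tibble(
    year = years, cases = 10, population = 10)), "prevalence")
})

test_that("overdispersed counts switch the fit to quasi-Poisson with wider CIs", {
  set.seed(7)
  years <- 2005:2024
  mu <- 400 * exp(rnorm(20, 0, 0.3))
  dat <- tibble::tibble(year = years, count = rpois(20, mu), population = 1e6)
  tr <- fit_incidence_trend(dat)
  expect_equal(tr$family, "quasi_poisson")
  expect_gt(tr$dispersion, 1)
  poisson_se <- summary(suppressWarnings(glm(
    count ~ year + offset(log(population)), data = dat,
    family = poisson())))$coefficients["year", 2]
  expect_gt(tr$se, poisson_se)
})

test_that("stratified trends recover opposite planted signs", {
  set.seed(11)
  years <- 2005:2024
  up <- tibble::tibble(year = years, age_group = "[50-60)",
                       count = rpois(20, 300 * 1.04^(years - 2005)),
                       population = 1e6)
  down <- tibble::tibble(year = years, age_group = "[80-90)",
                         count = rpois(20, 300 * 0.95^(years - 2005)),
                         population = 1e6)
  res <- incidence_trends(dplyr::bind_rows(up, down))
  expect_gt(res$apc[res$stratum == "[50-60)"], 0)
  expect_lt(res$apc[res$stratum == "[80-90)"], 0)
  # tidy/glance expose the same numbers
  tr <- fit_incidence_trend(up)
  td <- tidy(tr)
  expect_equal(td$apc[td$term == "year"], tr$apc)
  gl <- glance(tr)
  expect_equal(gl$apc, tr$apc)
  expect_equal(gl$beta, tr$beta)
})
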