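test_that("first purchase date ignores non-APM drugs and missing purchases", {
  ds <- mk_ds(purchases = tibble::tibble(
    date = c("2010-03-01", "2009-06-01", "2008-01-01"),
    atc = c("N04BA02", "N04BD02", "N05AD01")))
  expect_equal(first_purchase_date(ds$purchases), d("2009-06-01"))
  ds2 <- mk_ds(purchases = tibble::tibble(date = "2010-01-01", atc = "A10BA02"))
  expect_true(is.na(first_purchase_date(ds2$purchases)))
  expect_true(is.na(first_purchase_date(mk_ds()$purchases)))
})

test_that("inclusion requires two occasions, coverage, post-2004 FPD and age 25-100", {
  ok <- mk_ds(purchases = q_purchases("2010-01-01", 3))
  expect_true(check_inclusion(ok, "X1")$eligible)
  # single occasion (two same-day rows are one occasion)
  single <- mk_ds(purchases = tibble::tibble(
    date = c("2010-01-01", "2010-01-01"), atc = c("N04BA02", "N04BC05")))
  res <- check_inclusion(single, "X1")
  expect_false(res$eligible)
  expect_false(res$checks$passed[res$checks$criterion == "INC1"])
  # FPD before 2005
  early <- mk_ds(purchases = q_purchases("2004-11-15", 3))
  expect_false(check_inclusion(early, "X1")$eligible)
  expect_equal(status_of(early), "not_eligible")
  boundary <- mk_ds(purchases = q_purchases("2005-01-01", 3))
  expect_true(check_inclusion(boundary, "X1")$eligible)
  # age 24 at FPD
  young <- mk_ds(purchases = q_purchases("2010-06-01", 3), birth = "1986-01-01")
  expect_false(check_inclusion(young, "X1")$eligible)
  # age 100 inclusive
  century <- mk_ds(purchases = q_purchases("2010-06-01", 3), birth = "1910-01-01")
  expect_true(check_inclusion(century, "X1")$eligible)
  # FPD outside insurance coverage
  uninsured <- mk_ds(purchases = q_purchases("2010-01-01", 3),
                     ins_start = "2012-01-01")
  expect_false(check_inclusion(uninsured, "X1")$eligible)
})

test_that("dopamine-agonist use around childbirth is excluded (postpartum rule)", {
  ds <- mk_ds(sex = "female", birth = "1980-01-01",
              purchases = q_purchases("2012-01-01", 10, atc = "N04BC05"),
              diagnoses = tibble::tibble(date = "2010-11-01", code = "O80"))
  expect_equal(status_of(ds), "excluded")
  expect_equal(fired_of(ds), "EXC4")
  # same stream with a PD diagnosis is rescued
  ds2 <- mk_ds(sex = "female", birth = "1980-01-01",
               purchases = q_purchases("2012-01-01", 10, atc = "N04BC05"),
               diagnoses = tibble::tibble(date = c("2010-11-01", "2012-02-01"),
                                          code = c("O80", "G20")))
  expect_false(grepl("EXC4", fired_of(ds2)))
  # birth more than two years before FPD does not fire
  ds3 <- mk_ds(sex = "female", birth = "1980-01-01",
               purchases = q_purchases("2012-01-01", 10, atc = "N04BC05"),
               diagnoses = tibble::tibble(date = "2009-06-01", code = "O80"))
  expect_false(grepl("EXC4", fired_of(ds3)))
})

test_that("atypical parkinsonism and RLS exclusions are rescued by a subsequent PD diagnosis", {
  base_pur <- q_purchases("2011-01-01", 12)
  msa_only <- mk_ds(purchases = base_pur,
                    diagnoses = tibble::tibble(date = "2012-05-01", code = "G23.2"))
  expect_equal(fired_of(msa_only), "EXC7")
  rescued <- mk_ds(purchases = base_pur,
                   diagnoses = tibble::tibble(date = c("2012-05-01", "2014-01-01"),
                                              code = c("G23.2", "G20")))
  expect_false(grepl("EXC7", fired_of(rescued)))
  expect_equal(status_of(rescued), "probable_pd")
  # same-day PD diagnosis does not rescue (strictly later required)
  tie <- mk_ds(purchases = base_pur,
               diagnoses = tibble::tibble(date = c("2012-05-01", "2012-05-01"),
                                          code = c("G23.2", "G20")))
  expect_true(grepl("EXC7", fired_of(tie)))
  rls <- mk_ds(purchases = q_purchases("2011-01-01", 12, atc = "N04BC05"),
               diagnoses = tibble::tibble(date = "2010-01-01", code = "G25.8"))
  expect_equal(fired_of(rls), "EXC8")
})

test_that("exclusive MAO-inhibitor or amantadine use beyond thresholds is excluded", {
  # 9 occasions over ~2.5 years, never PD-diagnosed
  mao <- mk_ds(purchases = tibble::tibble(
    date = as.character(d("2011-01-01") + round(seq(0, 911, length.out = 9))),
    atc = "N04BD02"))
  expect_equal(fired_of(mao), "EXC10")
  ama <- mk_ds(purchases = tibble::tibble(
    date = as.character(d("2011-01-01") + round(seq(0, 911, length.out = 9))),
    atc = "N04BB01"))
  expect_equal(fired_of(ama), "EXC11")
  # a PD diagnosis turns the same stream into possible PD (POS3-free case)
  mao_pd <- mk_ds(purchases = tibble::tibble(
    date = as.character(d("2020-01-01") + round(seq(0, 911, length.out = 9))),
    atc = "N04BD02"),
    diagnoses = tibble::tibble(date = "2020-02-01", code = "G20"))
  expect_equal(status_of(mao_pd), "probable_pd")
  # short exclusive MAO use is not excluded by this rule
  mao_short <- mk_ds(purchases = q_purchases("2020-01-01", 4, atc = "N04BD02"),
                     diagnoses = tibble::tibble(date = "2020-02-01", code = "G20"))
  expect_false(grepl("EXC10", paste(fired_of(mao_short), collapse = "")))
})

test_that("antipsychotic use in the year before FPD excludes unless levodopa plus PD diagnosis", {
  pur <- dplyr::bind_rows(
    tibble::tibble(date = "2011-08-01", atc = "N05AD01"),
    q_purchases("2012-01-01", 12))
  no_pd <- mk_ds(purchases = pur)
  expect_equal(fired_of(no_pd), "EXC9")
  # levodopa purchased and PD diagnosed: not excluded, flagged possible via POS4
  with_pd <- mk_ds(purchases = pur,
                   diagnoses = tibble::tibble(date = "2012-03-01", code = "G20"))
  expect_equal(status_of(with_pd), "possible_pd")
  expect_equal(fired_of(with_pd), "POS4")
  # low-dose quetiapine does not trigger the exclusion
  quet <- mk_ds(purchases = dplyr::bind_rows(
    tibble::tibble(date = "2011-08-01", atc = "N05AH04", strength = 25),
    q_purchases("2012-01-01", 12)),
    diagnoses = tibble::tibble(date = "2012-03-01", code = "G20"))
  expect_equal(status_of(quet), "probable_pd")
  # antipsychotic purchased outside the year-prior window does not fire
  far <- mk_ds(purchases = dplyr::bind_rows(
    tibble::tibble(date = "2009-08-01", atc = "N05AD01"),
    q_purchases("2012-01-01", 12)))
  expect_false(grepl("EXC9", fired_of(far)))
})

test_that("non-continuous APM use without PD diagnosis is excluded (EXC13/EXC14)", {
  # ~1 year of purchases, then >1 year silence, never PD-diagnosed
  e13 <- mk_ds(purchases = q_purchases("2015-01-01", 5),
               extraction = "2019-01-01")
  expect_equal(fired_of(e13), "EXC13")
  # under six months of purchases, >3 years silence, even with a PD diagnosis
  e14 <- mk_ds(purchases = tibble::tibble(date = c("2015-01-01", "2015-04-01"),
                                          atc = "N04BA02"),
               diagnoses = tibble::tibble(date = "2015-02-01", code = "G20"),
               extraction = "2020-01-01")
  expect_equal(fired_of(e14), "EXC14")
  # elapsed time is measured to observation end, not extraction
  e13_exit <- mk_ds(purchases = q_purchases("2015-01-01", 5),
                    ins_end = "2016-06-01", extraction = "2025-03-31")
  expect_false(grepl("EXC13", fired_of(e13_exit)))
})

test_that("hydrocephalus/anoxic injury and TBI-with-coma windows are honoured", {
  hydro <- mk_ds(purchases = q_purchases("2012-01-01", 12),
                 diagnoses = tibble::tibble(date = c("2012-01-20", "2012-03-01"),
                                            code = c("G91.1", "G20")))
  expect_equal(fired_of(hydro), "EXC5")  # within one month after FPD
  hydro_late <- mk_ds(purchases = q_purchases("2012-01-01", 12),
                      diagnoses = tibble::tibble(date = c("2012-03-15", "2012-03-01"),
                                                 code = c("G91.1", "G20")))
  expect_false(grepl("EXC5", fired_of(hydro_late)))
  tbi <- mk_ds(purchases = q_purchases("2012-01-01", 12),
               diagnoses = tibble::tibble(
                 date = c("2011-09-01", "2011-09-03", "2012-02-01"),
                 code = c("S06.0", "R40.2", "G20")))
  expect_equal(fired_of(tbi), "EXC6")
  # TBI without coma does not fire
  tbi_only <- mk_ds(purchases = q_purchases("2012-01-01", 12),
                    diagnoses = tibble::tibble(date = c("2011-09-01", "2012-02-01"),
                                               code = c("S06.0", "G20")))
  expect_false(grepl("EXC6", fired_of(tbi_only)))
})

test_that("certainty tiers follow the possible-PD criteria", {
  # textbook: PD dx, long follow-up, continuous APM
  probable <- mk_ds(purchases = q_purchases("2012-01-01", 54),
                    diagnoses = tibble::tibble(date = "2012-02-01", code = "G20"))
  expect_equal(status_of(probable), "probable_pd")
  # POS1: never diagnosed
  pos1 <- mk_ds(purchases = q_purchases("2012-01-01", 54))
  expect_equal(fired_of(pos1), "POS1")
  # POS2: FPD 18 months before extraction
  pos2 <- mk_ds(purchases = q_purchases("2023-10-01", 5),
                diagnoses = tibble::tibble(date = "2023-11-01", code = "G20"),
                extraction = "2025-03-31")
  expect_equal(fired_of(pos2), "POS2")
  # POS3: >3y of APM, >2y since last purchase
  pos3 <- mk_ds(purchases = q_purchases("2015-01-01", 14),
                diagnoses = tibble::tibble(date = "2015-02-01", code = "G20"),
                extraction = "2021-06-01")
  expect_equal(fired_of(pos3), "POS3")
})

test_that("certainty and index date are exposed per patient", {
  ds <- mk_ds(purchases = q_purchases("2023-10-01", 5),
              diagnoses = tibble::tibble(date = "2023-11-01", code = "G20"),
              extraction = "2025-03-31")
  ac <- assign_certainty(ds, "X1")
  expect_equal(ac$certainty, "possible")
  expect_equal(ac$fired, "POS2")
  idx <- compute_index_date(ds, "X1")
  expect_equal(idx$index_date, d("2023-10-01"))
  expect_equal(idx$index_rule, "IDX_DEFAULT")
})

test_that("index date follows the default and exception rules", {
  # default: earlier of FPD and PD diagnosis
  co <- classify_cohort(mk_ds(
    purchases = q_purchases("2012-05-01", 20),
    diagnoses = tibble::tibble(date = "2011-09-01", code = "G20")))
  expect_equal(co$index_date, d("2011-09-01"))
  expect_equal(co$index_rule, "IDX_DEFAULT")
  # pituitary exception: later of FPD and PD diagnosis
  co2 <- classify_cohort(mk_ds(
    purchases = q_purchases("2010-01-01", 60),
    diagnoses = tibble::tibble(date = c("2008-03-01", "2012-01-01"),
                               code = c("D35.2", "G20"))))
  expect_equal(co2$status, "probable_pd")
  expect_equal(co2$index_date, d("2012-01-01"))
  expect_equal(co2$index_rule, "IDX_PITUITARY")
  # anticholinergic exception: earliest of first anticholinergic and PD dx
  co3 <- classify_cohort(mk_ds(
    purchases = dplyr::bind_rows(
      tibble::tibble(date = "2010-06-01", atc = "N04AA01"),
      q_purchases("2011-02-01", 20)),
    diagnoses = tibble::tibble(date = "2011-03-01", code = "G20")))
  expect_equal(co3$index_date, d("2010-06-01"))
  expect_equal(co3$index_rule, "IDX_ANTICHOLINERGIC")
  # index equals FPD when no exception applies and no earlier PD dx
  co4 <- classify_cohort(mk_ds(
    purchases = q_purchases("2012-05-01", 20),
    diagnoses = tibble::tibble(date = "2013-01-01", code = "G20")))
  expect_equal(co4$index_date, co4$fpd)
})

test_that("cohort classification partitions statuses and is deterministic", {
  sim <- simulate_cohort(scenario_config(n_patients = 300, seed = 42))
  co <- classify_cohort(sim$dataset)
  expect_equal(nrow(co), 300)
  expect_true(all(co$status %in% c("probable_pd", "possible_pd", "excluded",
                                   "not_eligible")))
  # PD statuses carry FPD and index date; excluded carry fired EXC ids
  is_pd <- co$status %in% c("probable_pd", "possible_pd")
  expect_true(all(!is.na(co$fpd[is_pd])))
  expect_true(all(!is.na(co$index_date[is_pd])))
  expect_true(all(grepl("^EXC", co$fired[co$status == "excluded"])))
  expect_true(all(grepl("POS", co$fired[co$status == "possible_pd"])))
  # byte-identical rerun
  co2 <- classify_cohort(simulate_cohort(scenario_config(n_patients = 300,
                                                         seed = 42))$dataset)
  expect_identical(co, co2)
  # empty cohort
  co0 <- classify_cohort(simulate_cohort(scenario_config(n_patients = 0))$dataset)
  expect_equal(nrow(co0), 0)
  expect_equal(nrow(cohort_funnel(co0)), 0)
})

test_that("a cohort of postpartum archetypes is excluded entirely via EXC4", {
  sim <- simulate_cohort(scenario_config(
    n_patients = 40, seed = 5, weights = c(exc4 = 1)))
  co <- classify_cohort(sim$dataset)
  expect_true(all(co$status == "excluded"))
  expect_true(all(co$fired == "EXC4"))
})

test_that("adding a PD diagnosis never newly fires a PD-gated criterion", {
  gated <- c("EXC1", "EXC7", "EXC8", "EXC9", "EXC10", "EXC11", "EXC12",
             "EXC13", "EXC14", "POS1")
  sim <- simulate_cohort(scenario_config(n_patients = 60, seed = 9))
  before <- cohort_audit(classify_cohort(sim$dataset))
  ds2 <- sim$dataset
  extra <- ds2$patients %>%
    dplyr::transmute(patient_id, dx_date = ds2$extraction_date - 30L,
                     icd10_code = "G20", provider_type = "neurologist")
  ds2$diagnoses <- dplyr::bind_rows(ds2$diagnoses, extra)
  after <- cohort_audit(classify_cohort(ds2))
  j <- dplyr::inner_join(before, after, by = c("patient_id", "criterion"),
                         suffix = c("_before", "_after"))
  jg <- dplyr::filter(j, criterion %in% gated)
  expect_false(any(jg$fired_after & !jg$fired_before, na.rm = TRUE))
})

test_that("single-patient classification carries evidence for fired criteria", {
  ds <- mk_ds(sex = "female", birth = "1980-01-01",
              purchases = q_purchases("2012-01-01", 10, atc = "N04BC05"),
              diagnoses = tibble::tibble(date = "2010-11-01", code = "O80"))
  res <- classify_patient(ds, "X1")
  expect_equal(res$status, "excluded")
  fired <- dplyr::filter(res$criteria, fired)
  expect_true(all(purrr::map_int(fired$evidence, length) > 0))
  expect_true("EXC4" %in% fired$criterion)
  ev <- evaluate_criterion(ds, "X1", "EXC4")
  expect_true(ev$fired)
  expect_true(any(grepl("O80", ev$evidence[[1]])))
  expect_error(evaluate_criterion(ds, "X1", "EXC99"), "unknown criterion")
})
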