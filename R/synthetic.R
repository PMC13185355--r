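#' Archetype registry of the synthetic-EHR generator
#'
#' Every rule of the classification algorithm has a matching generator
#' archetype: true-PD trajectories (textbook escalation plus one variant per
#' possible-PD criterion), one confounder archetype per exclusion criterion
#' (lactation suppression, drug-induced parkinsonism, atypical parkinsonism,
#' ...), and never-treated mimics that fail inclusion.
#'
#' @return tibble with `archetype_id`, `truth` (pd / non_pd),
#'   `intended_status` and `intended_criterion` (the single criterion the
#'   archetype is built to fire, NA for probable PD).
#' @export
archetype_table <- function() {
  tribble(
    ~archetype_id,      ~truth,   ~intended_status, ~intended_criterion,
    "pd_textbook",      "pd",     "probable_pd",    NA_character_,
    "pos1",             "pd",     "possible_pd",    "POS1",
    "pos2",             "pd",     "possible_pd",    "POS2",
    "pos3",             "pd",     "possible_pd",    "POS3",
    "pos4",             "pd",     "possible_pd",    "POS4",
    "exc1",             "non_pd", "excluded",       "EXC1",
    "exc2",             "non_pd", "excluded",       "EXC2",
    "exc3",             "non_pd", "excluded",       "EXC3",
    "exc4",             "non_pd", "excluded",       "EXC4",
    "exc5",             "non_pd", "excluded",       "EXC5",
    "exc6",             "non_pd", "excluded",       "EXC6",
    "exc7",             "non_pd", "excluded",       "EXC7",
    "exc8",             "non_pd", "excluded",       "EXC8",
    "exc9",             "non_pd", "excluded",       "EXC9",
    "exc10",            "non_pd", "excluded",       "EXC10",
    "exc11",            "non_pd", "excluded",       "EXC11",
    "exc12",            "non_pd", "excluded",       "EXC12",
    "exc13",            "non_pd", "excluded",       "EXC13",
    "exc14",            "non_pd", "excluded",       "EXC14",
    "mimic_no_apm",     "non_pd", "not_eligible",   "INC1",
    "mimic_single_apm", "non_pd", "not_eligible",   "INC1"
  )
}

#' Default archetype mix of the synthetic scenario
#'
#' 40% true PD (mostly textbook trajectories), 39% never/barely-treated
#' mimics, and 21% confounders spread evenly over the fourteen exclusion
#' archetypes — a deliberately confounder-rich mix so that specificity is
#' actually exercised.
#' @return named numeric vector of weights summing to 1.
#' @export
default_archetype_weights <- function() {
  w <- c(pd_textbook = 0.30, pos1 = 0.03, pos2 = 0.03, pos3 = 0.02,
         pos4 = 0.02,
         mimic_no_apm = 0.33, mimic_single_apm = 0.06)
  exc <- setNames(rep(0.015, 14), paste0("exc", 1:14))
  c(w, exc)
}

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe the study conditions the package is tested under:
#' a 2005--2025 observation horizon, quarterly prescription refills
#' (prescriptions are issued for at most three months, so refills arrive
#' roughly every 90 days with +/-20 day jitter), treatment escalation from
#' monotherapy to levodopa, specialist (neurologist) involvement in about
#' half of diagnoses, onset ages centred in the mid 70s, and an embedded
#' incidence decline of -4.47% per year.
#'
#' @param n_patients total patients to simulate.
#' @param weights named archetype weights (see [default_archetype_weights()]).
#' @param study_start,extraction_date observation horizon.
#' @param seed master RNG seed; per-patient substreams are derived from
#'   `(seed, patient index)` so editing one archetype never reshuffles others.
#' @param purchase_interval,purchase_jitter refill cadence in days.
#' @param escalation_prob probability a monotherapy starter escalates to
#'   levodopa.
#' @param dx_delay_days range (days, relative to first APM purchase) of the
#'   PD diagnosis date for true-PD trajectories.
#' @param neurologist_frac fraction of PD diagnoses assigned by a
#'   neurologist within the first year of index.
#' @param male_frac,onset_age_mean,onset_age_sd demographics.
#' @param incidence_apc annual percent change embedded in the population
#'   incidence schedule.
#' @param insurance_start earliest insurance start date.
#' @return list of class `pd_scenario`.
#' @export
scenario_config <- function(n_patients = 1000,
                            weights = default_archetype_weights(),
                            study_start = as.Date("2005-01-01"),
                            extraction_date = as.Date("2025-03-31"),
                            seed = 1L,
                            purchase_interval = 90,
                            purchase_jitter = 20,
                            escalation_prob = 0.9,
                            dx_delay_days = c(-60, 180),
                            neurologist_frac = 0.5,
                            male_frac = 0.55,
                            onset_age_mean = 72,
                            onset_age_sd = 8.5,
                            incidence_apc = -4.47,
                            insurance_start = as.Date("2000-01-01")) {
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-8)
  stopifnot(all(names(weights) %in% archetype_table()$archetype_id))
  structure(list(n_patients = n_patients, weights = weights,
                 study_start = as.Date(study_start),
                 extraction_date = as.Date(extraction_date),
                 seed = as.integer(seed),
                 purchase_interval = purchase_interval,
                 purchase_jitter = purchase_jitter,
                 escalation_prob = escalation_prob,
                 dx_delay_days = dx_delay_days,
                 neurologist_frac = neurologist_frac,
                 male_frac = male_frac,
                 onset_age_mean = onset_age_mean,
                 onset_age_sd = onset_age_sd,
                 incidence_apc = incidence_apc,
                 insurance_start = as.Date(insurance_start)),
            class = c("pd_scenario", "list"))
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483629L) + 1L
}

# quarterly refill dates in [from, to] with jitter; always includes `from`
refill_dates <- function(from, to, interval = 90, jitter = 20) {
  if (to < from) return(from)
  dates <- from
  cur <- from
  repeat {
    cur <- cur + round(interval + runif(1, -jitter, jitter))
    if (cur > to) break
    dates <- c(dates, cur)
  }
  as.Date(dates, origin = "1970-01-01")
}

purchase_rows <- function(pid, dates, atc, strength = NA_real_) {
  tibble(patient_id = pid, purchase_date = as.Date(dates, origin = "1970-01-01"),
         atc_code = atc, strength_mg = strength)
}

dx_rows <- function(pid, dates, code, provider = "primary_care") {
  tibble(patient_id = pid, dx_date = as.Date(dates, origin = "1970-01-01"),
         icd10_code = code, provider_type = provider)
}

#' Simulate a textbook PD treatment trajectory
#'
#' APM refills roughly every 90 days from treatment start until the end of
#' observation, with escalation from monotherapy (MAO-B inhibitor or
#' dopamine agonist) to levodopa, and a PD diagnosis placed near the first
#' purchase with a configurable provider mix. Uses the current RNG state;
#' callers seed their own substream.
#'
#' @param pid patient id.
#' @param onset_date first APM purchase date.
#' @param end_date last date events may occur (death/exit/extraction).
#' @param config a `pd_scenario`.
#' @return list of `purchases` and `diagnoses` tibbles.
#' @export
simulate_pd_trajectory <- function(pid, onset_date, end_date, config) {
  last_rx <- end_date - round(runif(1, 10, 100))
  if (last_rx < onset_date) last_rx <- onset_date
  dates <- refill_dates(onset_date, last_rx, config$purchase_interval,
                        config$purchase_jitter)
  starter <- sample(c("N04BA02", "N04BC05", "N04BD02"), 1,
                    prob = c(0.5, 0.3, 0.2))
  atc <- rep(starter, length(dates))
  if (starter != "N04BA02" && runif(1) < config$escalation_prob) {
    switch_after <- round(runif(1, 180, 720))
    atc[dates >= onset_date + switch_after] <- "N04BA02"
  }
  purchases <- purchase_rows(pid, dates, atc)

  delay <- round(runif(1, config$dx_delay_days[1], config$dx_delay_days[2]))
  dx_date <- onset_date + delay
  if (dx_date > end_date) dx_date <- end_date
  provider <- if (runif(1) < config$neurologist_frac) "neurologist" else
    sample(c("primary_care", "hospital", "mdc"), 1)
  diagnoses <- dx_rows(pid, dx_date, "G20", provider)
  # repeat diagnosis at a later visit for most patients
  if (runif(1) < 0.8 && dx_date + 400 <= end_date) {
    diagnoses <- bind_rows(diagnoses,
                           dx_rows(pid, dx_date + round(runif(1, 200, 400)),
                                   "G20", "primary_care"))
  }
  list(purchases = purchases, diagnoses = diagnoses)
}

#' Simulate a single archetype patient's event stream
#'
#' Generates purchases and diagnoses that deterministically satisfy the
#' archetype's target criterion and, by construction, no other exclusion or
#' possible-PD criterion. Uses the current RNG state.
#'
#' @param pid patient id.
#' @param archetype_id one of [archetype_table()]'s ids.
#' @param fpd first APM purchase date.
#' @param obs_end end of the patient's observation window.
#' @param config `pd_scenario`.
#' @return list of `purchases` and `diagnoses` tibbles.
#' @export
simulate_archetype <- function(pid, archetype_id, fpd, obs_end, config) {
  iv <- config$purchase_interval; jt <- config$purchase_jitter
  continuous <- function(atc, span) {
    to <- min(fpd + span, obs_end - round(runif(1, 10, 90)))
    if (to < fpd) to <- fpd
    dates <- refill_dates(fpd, to, iv, jt)
    # guarantee a second occasion and a span comfortably over two years
    if (length(dates) < 2) dates <- c(dates, min(fpd + 90, obs_end))
    purchase_rows(pid, dates, atc)
  }
  long_span <- round(runif(1, 850, 1300))
  pd_dx <- function(offset = round(runif(1, 0, 60))) {
    dx_rows(pid, min(fpd + offset, obs_end), "G20",
            if (runif(1) < config$neurologist_frac) "neurologist" else "primary_care")
  }
  emptydx <- dx_rows(pid, as.Date(character()), character(), character())

  res <- switch(archetype_id,
    pd_textbook = return(simulate_pd_trajectory(pid, fpd, obs_end, config)),
    pos1 = list(continuous("N04BA02", 1e6), emptydx),
    pos2 = {
      p <- continuous("N04BA02", 1e6)
      list(p, pd_dx(30))
    },
    pos3 = {
      # span must exceed 3 years and the tail gap must exceed 2 years
      total <- as.numeric(obs_end - fpd)
      gap <- round(runif(1, 760, max(761, total - 1150)))
      dates <- unique(c(refill_dates(fpd, obs_end - gap, iv, jt),
                        obs_end - gap))
      list(purchase_rows(pid, dates, "N04BA02"), pd_dx(30))
    },
    pos4 = {
      ap <- purchase_rows(pid, fpd - round(runif(1, 30, 330)), "N05AD01")
      list(bind_rows(ap, continuous("N04BA02", 1e6)), pd_dx(30))
    },
    exc1 = list(continuous("N04BC05", long_span),
                dx_rows(pid, max(fpd - round(runif(1, 100, 900)),
                                 config$insurance_start), "E22.1")),
    exc2 = list(continuous("N04BC01", long_span),
                bind_rows(dx_rows(pid, fpd - round(runif(1, 50, 400)), "D35.2"),
                          pd_dx())),
    exc3 = list(continuous("N04BC06", long_span),
                bind_rows(dx_rows(pid, fpd - round(runif(1, 50, 400)), "D35.2"),
                          pd_dx())),
    exc4 = list(continuous("N04BC05", long_span),
                dx_rows(pid, fpd - round(runif(1, 90, 600)), "O80", "hospital")),
    exc5 = list(continuous("N04BA02", long_span),
                bind_rows(dx_rows(pid, fpd + round(runif(1, -120, 25)), "G91.0",
                                  "hospital"),
                          pd_dx(90))),
    exc6 = list(continuous("N04BA02", long_span),
                bind_rows(dx_rows(pid, fpd - round(runif(1, 10, 170)), "S06.0",
                                  "hospital"),
                          dx_rows(pid, fpd - round(runif(1, 10, 170)), "R40.2",
                                  "hospital"),
                          pd_dx(90))),
    exc7 = list(continuous("N04BA02", long_span),
                dx_rows(pid, fpd + round(runif(1, 100, 600)), "G23.2",
                        "neurologist")),
    exc8 = list(continuous("N04BC05", long_span),
                dx_rows(pid, max(fpd - round(runif(1, 30, 400)),
                                 config$insurance_start), "G25.8")),
    exc9 = list(bind_rows(purchase_rows(pid, fpd - round(runif(1, 30, 330)),
                                        "N05AD01"),
                          continuous("N04BC05", long_span)),
                emptydx),
    exc10 = list(continuous("N04BD02", long_span), emptydx),
    exc11 = list(continuous("N04BB01", long_span), emptydx),
    exc12 = list(continuous("N04BA02", long_span),
                 dx_rows(pid, fpd + round(runif(1, 200,
                                                min(1500, as.numeric(obs_end - fpd) - 10))),
                         "R29.6")),
    exc13 = {
      # span between six months and two years, tail gap over one year
      total <- as.numeric(obs_end - fpd)
      span <- round(runif(1, 200, min(350, total - 380)))
      dates <- unique(c(refill_dates(fpd, fpd + span, iv, jt), fpd + span))
      list(purchase_rows(pid, dates, "N04BA02"), emptydx)
    },
    exc14 = {
      # span under six months, tail gap over three years; the PD diagnosis
      # keeps the (PD-gated) short-span/one-year-gap criterion out of play
      dates <- c(fpd, fpd + round(runif(1, 60, 120)))
      list(purchase_rows(pid, dates, "N04BA02"), pd_dx(30))
    },
    mimic_no_apm = list(purchase_rows(pid, as.Date(character()), character()),
                        dx_rows(pid, fpd + round(runif(1, -500, 500)), "G25.0",
                                "neurologist")),
    mimic_single_apm = list(purchase_rows(pid, fpd, "N04BA02"), emptydx),
    abort(paste("unknown archetype:", archetype_id))
  )
  list(purchases = res[[1]], diagnoses = res[[2]])
}

# minimum days of observation needed after the FPD for each archetype
archetype_horizon <- function(archetype_id) {
  switch(archetype_id,
    pd_textbook = round(runif(1, 950, 5500)),
    pos1 = round(runif(1, 1300, 4500)),
    pos2 = round(runif(1, 200, 700)),
    pos3 = round(runif(1, 1950, 2600)),
    pos4 = round(runif(1, 950, 4500)),
    exc13 = round(runif(1, 600, 1250)),
    exc14 = round(runif(1, 1250, 1850)),
    round(runif(1, 950, 2500)))
}

gen_patient <- function(i, archetype_id, config) {
  set.seed(derive_seed(config$seed, i))
  pid <- sprintf("P%06d", i)
  sex <- if (archetype_id == "exc4") "female" else
    if (archetype_id == "exc9") "male" else
      if (runif(1) < config$male_frac) "male" else "female"
  age <- if (archetype_id == "exc4") runif(1, 26, 40) else
    min(max(rnorm(1, config$onset_age_mean, config$onset_age_sd), 40), 95)

  horizon <- archetype_horizon(archetype_id)
  ext <- config$extraction_date
  latest_fpd <- ext - horizon
  earliest_fpd <- as.Date("2005-07-01")
  if (latest_fpd < earliest_fpd) latest_fpd <- earliest_fpd
  if (archetype_id == "exc3") {
    earliest_fpd <- max(earliest_fpd, as.Date("2014-06-01"))
    if (latest_fpd < earliest_fpd) latest_fpd <- earliest_fpd
  }
  fpd <- earliest_fpd +
    round(runif(1, 0, as.numeric(latest_fpd - earliest_fpd)))

  birth <- fpd - round(age * 365.25) - sample(0:364, 1)
  # pos2 patients are censored early (death or HMO exit shortly after FPD)
  death <- as.Date(NA)
  ins_end <- ext
  obs_end <- ext
  if (archetype_id == "pos2") {
    fu <- min(round(runif(1, 200, 700)), as.numeric(ext - fpd))
    if (runif(1) < 0.5) death <- fpd + fu else ins_end <- fpd + fu
    obs_end <- fpd + fu
  } else if (archetype_id == "pd_textbook" && runif(1) < 0.3) {
    death <- fpd + round(runif(1, 950, 6000))
    if (death >= ext) death <- as.Date(NA) else obs_end <- death
  }

  ins_start <- max(config$insurance_start, birth)
  ev <- simulate_archetype(pid, archetype_id, fpd, obs_end, config)
  # events must respect the observation window
  ev$purchases <- ev$purchases %>%
    filter(purchase_date >= ins_start, purchase_date <= obs_end)
  ev$diagnoses <- ev$diagnoses %>%
    mutate(dx_date = pmax(dx_date, ins_start)) %>%
    filter(dx_date <= obs_end)

  list(
    patient = tibble(patient_id = pid, sex = sex, birth_date = birth,
                     death_date = death,
                     ethnic_group = sample(c("ashkenazi", "yemenite",
                                             "iranian_iraqi", "north_african",
                                             "israeli_born", "other"), 1),
                     ses_stratum = sample(c("very_low", "low", "medium",
                                            "high", "very_high"), 1,
                                          prob = c(.08, .13, .38, .28, .13))),
    insurance = tibble(patient_id = pid, start = ins_start, end = ins_end),
    purchases = ev$purchases,
    diagnoses = ev$diagnoses,
    label = tibble(patient_id = pid,
                   truth = archetype_table()$truth[
                     archetype_table()$archetype_id == archetype_id],
                   archetype_id = archetype_id,
                   intended_status = archetype_table()$intended_status[
                     archetype_table()$archetype_id == archetype_id],
                   intended_criterion = archetype_table()$intended_criterion[
                     archetype_table()$archetype_id == archetype_id],
                   fpd_true = fpd,
                   followup_days = as.integer(obs_end - fpd))
  )
}

#' Simulate a synthetic EHR cohort with known ground truth
#'
#' Draws archetypes by the configured weights, generates each patient on an
#' independent RNG substream, and returns the dataset in exactly the schema
#' [load_dataset()] consumes together with a ground-truth label table.
#'
#' @param config a `pd_scenario` from [scenario_config()].
#' @return list with `dataset` (an `ehr_dataset`, including a synthetic
#'   population-denominator table) and `truth` (tibble: `patient_id`,
#'   `truth`, `archetype_id`, `intended_status`, `intended_criterion`,
#'   `fpd_true`, `followup_days`).
#' @export
#' @examples
#' sim <- simulate_cohort(scenario_config(n_patients = 20, seed = 7))
#' sim$truth
simulate_cohort <- function(config = scenario_config()) {
  n <- config$n_patients
  if (n == 0) {
    empty <- new_ehr_dataset(
      tibble(patient_id = character(), sex = character(),
             birth_date = as.Date(character()), death_date = as.Date(character()),
             ethnic_group = character(), ses_stratum = character()),
      tibble(patient_id = character(), purchase_date = as.Date(character()),
             atc_code = character(), strength_mg = numeric()),
      tibble(patient_id = character(), dx_date = as.Date(character()),
             icd10_code = character(), provider_type = character()),
      tibble(patient_id = character(), start = as.Date(character()),
             end = as.Date(character())),
      simulate_population(seed = config$seed),
      extraction_date = config$extraction_date)
    return(list(dataset = empty, truth = tibble(
      patient_id = character(), truth = character(), archetype_id = character(),
      intended_status = character(), intended_criterion = character(),
      fpd_true = as.Date(character()), followup_days = integer())))
  }
  set.seed(config$seed)
  arch <- sample(names(config$weights), n, replace = TRUE,
                 prob = config$weights)
  parts <- purrr::map(seq_len(n), function(i) gen_patient(i, arch[i], config))
  dataset <- new_ehr_dataset(
    patients = purrr::list_rbind(purrr::map(parts, "patient")),
    purchases = purrr::list_rbind(purrr::map(parts, "purchases")),
    diagnoses = purrr::list_rbind(purrr::map(parts, "diagnoses")),
    insurance = purrr::list_rbind(purrr::map(parts, "insurance")),
    population = simulate_population(seed = config$seed),
    extraction_date = config$extraction_date)
  truth <- purrr::list_rbind(purrr::map(parts, "label"))
  list(dataset = dataset, truth = truth)
}

#' Synthetic insured-population denominators
#'
#' Year x 5-year age band x sex counts emulating a large HMO's age pyramid,
#' with mild annual growth. Serves as the denominator table for incidence
#' and prevalence estimation so no external census is needed.
#'
#' @param years calendar years.
#' @param total_size insured members in the first year.
#' @param growth annual growth factor.
#' @param seed RNG seed (band-level jitter only).
#' @return tibble `year`, `band_start`, `sex`, `population`.
#' @export
simulate_population <- function(years = 2005:2024, total_size = 4e6,
                                growth = 1.015, seed = 1L) {
  set.seed(derive_seed(seed, 999983L))
  bands <- seq(0, 95, by = 5)
  w <- exp(-0.028 * bands); w[bands >= 80] <- w[bands >= 80] * 0.55
  w <- w / sum(w)
  grid <- tidyr::expand_grid(year = years, band_start = bands,
                             sex = c("male", "female"))
  jitter <- runif(nrow(grid), 0.97, 1.03)
  grid %>%
    mutate(population = round(total_size / 2 * w[match(band_start, bands)] *
                                growth^(year - min(years)) * jitter))
}

#' Simulate annual incidence counts with an embedded trend
#'
#' For each year/age-band/sex cell, draws a Poisson count with mean
#' `population x rate(band) x (1 + apc/100)^(year - year0)`. The baseline
#' rates follow the strong age gradient of PD incidence.
#'
#' @param population denominator tibble from [simulate_population()].
#' @param apc true annual percent change (e.g. -4.47).
#' @param base_rates named vector of per-100,000 rates at `year0`, indexed by
#'   `band_start`; defaults ramp from ~1/100k under 40 to ~550/100k at 80-89.
#' @param year0 reference year for the trend.
#' @param seed RNG seed.
#' @return tibble `year`, `band_start`, `sex`, `population`, `count`.
#' @export
simulate_incidence_counts <- function(population, apc = -4.47,
                                      base_rates = NULL, year0 = NULL,
                                      seed = 1L) {
  set.seed(derive_seed(seed, 424243L))
  if (is.null(year0)) year0 <- min(population$year)
  if (is.null(base_rates)) {
    bands <- sort(unique(population$band_start))
    base_rates <- setNames(vapply(bands, function(b) {
      if (b < 40) 1.5 else if (b < 50) 9 else if (b < 60) 30 else
        if (b < 70) 120 else if (b < 80) 400 else if (b < 90) 550 else 450
    }, 1.0), bands)
  }
  population %>%
    mutate(rate0 = base_rates[as.character(band_start)],
           mu = population * rate0 / 1e5 * (1 + apc / 100)^(year - year0),
           count = rpois(dplyr::n(), mu)) %>%
    select(year, band_start, sex, population, count)
}

#' Default pre-diagnostic (prodromal) code model
#'
#' Per-code annual probability of receiving the diagnosis in controls
#' (`baseline`), the case/control rate ratio in the final year before index
#' (`ratio0`), the year-offset at which divergence begins (`onset_back`,
#' years before index; the ratio ramps linearly from 1 at `onset_back` to
#' `ratio0` at offset 0), and `constant` for codes whose ratio does not vary
#' with offset (smoking-related codes, ratio < 1 throughout). Effect sizes
#' are illustrative defaults, not calibrated claims.
#'
#' @param null if TRUE, all rate ratios are 1 (calibration runs).
#' @return tibble `code`, `baseline`, `ratio0`, `onset_back`, `constant`.
#' @export
prodromal_model <- function(null = FALSE) {
  m <- tribble(
    ~code,    ~baseline, ~ratio0, ~onset_back, ~constant,
    "K59",    0.040,     2.0,     10,          FALSE,
    "G25.0",  0.005,     5.0,     16,          FALSE,
    "R52.1",  0.010,     3.0,     17,          FALSE,
    "F32",    0.050,     2.8,     9,           FALSE,
    "F17",    0.060,     0.65,    17,          TRUE,
    "Z72.0",  0.050,     0.70,    17,          TRUE
  )
  if (null) m$ratio0 <- 1
  m
}

prodromal_ratio <- function(model_row, offset_back) {
  if (model_row$constant || model_row$onset_back == 0) {
    ifelse(offset_back <= model_row$onset_back, model_row$ratio0, 1)
  } else {
    ramp <- pmax(0, 1 - offset_back / model_row$onset_back)
    ifelse(offset_back <= model_row$onset_back,
           1 + (model_row$ratio0 - 1) * ramp, 1)
  }
}

#' Plant pre-diagnostic diagnosis codes around index dates
#'
#' For each subject, code and year-offset (0 back to -17), draws a Bernoulli
#' indicator with probability `baseline x ratio(offset)` for cases and
#' `baseline` for controls, and places a diagnosis at a uniform day inside
#' the offset-year window. Windows entirely before the subject's data start
#' are skipped (no data, no code).
#'
#' @param index_table tibble with `patient_id`, `group` ("case"/"control"),
#'   `index_date`, and optionally `data_start` (defaults 2000-01-01).
#' @param model tibble from [prodromal_model()].
#' @param max_offset_back deepest year offset (default 17, i.e. year -17).
#' @param seed RNG seed.
#' @return diagnoses tibble (`patient_id`, `dx_date`, `icd10_code`,
#'   `provider_type`).
#' @export
plant_prodromal_codes <- function(index_table, model = prodromal_model(),
                                  max_offset_back = 17, seed = 1L) {
  set.seed(derive_seed(seed, 77003L))
  if (!"data_start" %in% names(index_table)) {
    index_table$data_start <- as.Date("2000-01-01")
  }
  out <- list()
  for (k in seq_len(nrow(model))) {
    row <- model[k, ]
    for (ob in 0:max_offset_back) {
      win_end <- index_table$index_date - ob * 365L        # exclusive
      win_start <- index_table$index_date - (ob + 1L) * 365L
      avail <- win_end > index_table$data_start
      p <- ifelse(index_table$group == "case",
                  pmin(row$baseline * prodromal_ratio(row, ob), 0.99),
                  row$baseline)
      hit <- avail & (runif(nrow(index_table)) < p)
      if (!any(hit)) next
      lo <- pmax(win_start[hit], index_table$data_start[hit])
      span <- as.numeric(win_end[hit] - lo)
      d <- lo + floor(runif(sum(hit)) * span)
      out[[length(out) + 1]] <- tibble(
        patient_id = index_table$patient_id[hit],
        dx_date = as.Date(d, origin = "1970-01-01"),
        icd10_code = row$code, provider_type = "primary_care")
    }
  }
  if (!length(out)) {
    return(tibble(patient_id = character(), dx_date = as.Date(character()),
                  icd10_code = character(), provider_type = character()))
  }
  purrr::list_rbind(out) %>% arrange(patient_id, dx_date)
}

#' Simulate a case pool and control pool for pre-diagnostic analysis
#'
#' Builds `n_cases` index patients (sex, birth date, index date, follow-up)
#' and a candidate-control pool `pool_factor` times larger with the same
#' demographic mix, never-APM and never-PD by construction. Intended input
#' for [select_controls()] followed by [plant_prodromal_codes()].
#'
#' @param n_cases number of cases.
#' @param pool_factor candidate controls per case.
#' @param seed RNG seed.
#' @param index_years calendar-year range for index dates.
#' @param extraction_date censoring date.
#' @return list `cases`, `pool` (tibbles with `patient_id`, `sex`,
#'   `birth_date`, `death_date`, `data_start`, `obs_end`, and for cases
#'   `index_date`, `age_at_index`).
#' @export
simulate_prediagnostic_panel <- function(n_cases = 400, pool_factor = 8,
                                         seed = 1L,
                                         index_years = c(2015, 2022),
                                         extraction_date = as.Date("2024-12-31")) {
  set.seed(derive_seed(seed, 550001L))
  mk <- function(n, prefix) {
    sex <- sample(c("male", "female"), n, TRUE, prob = c(0.55, 0.45))
    age <- pmin(pmax(rnorm(n, 72, 8), 45), 92)
    tibble(patient_id = sprintf("%s%06d", prefix, seq_len(n)), sex = sex,
           age = age)
  }
  cases <- mk(n_cases, "C")
  idx0 <- as.Date(sprintf("%d-01-01", index_years[1]))
  idx_span <- as.numeric(as.Date(sprintf("%d-12-31", index_years[2])) - idx0)
  cases <- cases %>%
    mutate(index_date = idx0 + floor(runif(n_cases) * idx_span),
           birth_date = index_date - round(age * 365.25) -
             sample(0:364, n_cases, TRUE),
           data_start = as.Date("2000-01-01"),
           death_date = as.Date(NA),
           obs_end = extraction_date,
           age_at_index = age_at(birth_date, index_date)) %>%
    select(-age)
  pool <- mk(n_cases * pool_factor, "K") %>%
    mutate(birth_date = as.Date("2020-01-01") - round(age * 365.25) -
             sample(0:364, dplyr::n(), TRUE),
           data_start = as.Date("2000-01-01"),
           death_date = as.Date(ifelse(runif(dplyr::n()) < 0.1,
                                       as.Date("2010-01-01") +
                                         floor(runif(dplyr::n()) * 5000), NA),
                                origin = "1970-01-01"),
           obs_end = pmin(coalesce(death_date, extraction_date),
                          extraction_date)) %>%
    select(-age)
  list(cases = cases, pool = pool)
}
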