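# hand-built single- and multi-patient datasets for rule tests

d <- function(x) as.Date(x)

# purchases: tibble(date, atc, strength); diagnoses: tibble(date, code, provider)
mk_ds <- function(purchases = NULL, diagnoses = NULL, pid = "X1",
                  sex = "male", birth = "1950-01-01", death = NA,
                  ins_start = "2000-01-01", ins_end = NULL,
                  extraction = "2025-03-31", codebook = default_codebook()) {
  extraction <- d(extraction)
  if (is.null(ins_end)) ins_end <- extraction
  pat <- tibble::tibble(patient_id = pid, sex = sex, birth_date = d(birth),
                        death_date = d(death),
                        ethnic_group = "unknown", ses_stratum = "unknown")
  pur <- if (is.null(purchases)) {
    tibble::tibble(patient_id = character(), purchase_date = d(character()),
                   atc_code = character(), strength_mg = numeric())
  } else {
    tibble::tibble(patient_id = pid, purchase_date = d(purchases$date),
                   atc_code = purchases$atc,
                   strength_mg = purchases[["strength"]] %||% NA_real_)
  }
  dx <- if (is.null(diagnoses)) {
    tibble::tibble(patient_id = character(), dx_date = d(character()),
                   icd10_code = character(), provider_type = character())
  } else {
    tibble::tibble(patient_id = pid, dx_date = d(diagnoses$date),
                   icd10_code = diagnoses$code,
                   provider_type = diagnoses[["provider"]] %||% "primary_care")
  }
  ins <- tibble::tibble(patient_id = pid, start = d(ins_start), end = d(ins_end))
  new_ehr_dataset(pat, pur, dx, ins, population = NULL,
                  extraction_date = extraction, codebook = codebook)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shorthand: n quarterly purchases of one drug starting at `from`
q_purchases <- function(from, n, atc = "N04BA02") {
  tibble::tibble(date = as.character(d(from) + 90 * (seq_len(n) - 1)), atc = atc)
}

status_of <- function(ds, pid = "X1") {
  co <- classify_cohort(ds)
  co$status[co$patient_id == pid]
}

fired_of <- function(ds, pid = "X1") {
  co <- classify_cohort(ds)
  co$fired[co$patient_id == pid]
}
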