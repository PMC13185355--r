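#' Construct and validate an EHR dataset
#'
#' Bundles the longitudinal tables the algorithm consumes. Purchases are
#' annotated with their semantic drug class (`apm_class`) from the codebook.
#' Invariants enforced: every event's `patient_id` exists in `patients`;
#' events are dated on or before `extraction_date`; insurance periods are
#' non-overlapping within patient; `birth_date < death_date` when both
#' present.
#'
#' @param patients tibble: `patient_id`, `sex` ("male"/"female"),
#'   `birth_date`, `death_date` (NA allowed), `ethnic_group`, `ses_stratum`.
#' @param purchases tibble: `patient_id`, `purchase_date`, `atc_code`,
#'   `strength_mg` (NA allowed).
#' @param diagnoses tibble: `patient_id`, `dx_date`, `icd10_code`,
#'   `provider_type` (neurologist/primary_care/hospital/mdc/other).
#' @param insurance tibble: `patient_id`, `start`, `end`.
#' @param population tibble: `year`, `band_start` (lower bound of 5-year age
#'   band), `sex`, `population`. May be `NULL` when only classification is
#'   needed.
#' @param extraction_date Date of data extraction (right-censoring bound).
#' @param codebook a `pd_codebook`; default [default_codebook()].
#' @return list of class `ehr_dataset`.
#' @export
new_ehr_dataset <- function(patients, purchases, diagnoses, insurance,
                            population = NULL,
                            extraction_date,
                            codebook = default_codebook()) {
  patients <- as_tibble(patients)
  purchases <- as_tibble(purchases)
  diagnoses <- as_tibble(diagnoses)
  insurance <- as_tibble(insurance)
  extraction_date <- as.Date(extraction_date)

  if (anyDuplicated(patients$patient_id)) {
    abort("duplicated patient_id in patients table")
  }
  bad_sex <- setdiff(unique(patients$sex), c("male", "female"))
  if (length(bad_sex)) abort(paste("invalid sex values:", paste(bad_sex, collapse = ", ")))
  both <- !is.na(patients$death_date)
  if (any(both & patients$death_date <= patients$birth_date)) {
    abort("death_date must be after birth_date")
  }
  for (tb in list(purchases = purchases, diagnoses = diagnoses,
                  insurance = insurance)) {
    unknown <- setdiff(unique(tb$patient_id), patients$patient_id)
    if (length(unknown)) {
      abort(paste0("event rows reference unknown patient_id: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
  }
  if (nrow(purchases) && any(purchases$purchase_date > extraction_date, na.rm = TRUE)) {
    abort("purchases dated after extraction_date")
  }
  if (nrow(diagnoses) && any(diagnoses$dx_date > extraction_date, na.rm = TRUE)) {
    abort("diagnoses dated after extraction_date")
  }
  ins_sorted <- insurance %>%
    arrange(patient_id, start) %>%
    group_by(patient_id) %>%
    mutate(overlap = start <= dplyr::lag(end, default = as.Date("0001-01-01"))
           & dplyr::row_number() > 1) %>%
    ungroup()
  if (any(ins_sorted$overlap)) abort("overlapping insurance periods within patient")
  insurance <- ins_sorted %>% select(-"overlap")

  if (!"strength_mg" %in% names(purchases)) purchases$strength_mg <- NA_real_
  purchases$apm_class <- classify_purchase(purchases$atc_code,
                                           purchases$strength_mg, codebook)

  structure(list(patients = patients, purchases = purchases,
                 diagnoses = diagnoses, insurance = insurance,
                 population = if (is.null(population)) NULL else as_tibble(population),
                 extraction_date = extraction_date,
                 codebook = codebook),
            class = "ehr_dataset")
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("<ehr_dataset> ", nrow(x$patients), " patients, ",
      nrow(x$purchases), " purchases, ", nrow(x$diagnoses),
      " diagnoses; extraction ", format(x$extraction_date), "\n", sep = "")
  invisible(x)
}

read_csv_quiet <- function(path, col_types) {
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}

check_columns <- function(df, required, file) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("schema error in ", file, ": missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
}

parse_date_col <- function(df, col, file) {
  raw <- df[[col]]
  parsed <- as.Date(suppressWarnings(readr::parse_date(as.character(raw),
                                                       format = "%Y-%m-%d")))
  bad <- !is.na(raw) & raw != "" & is.na(parsed)
  if (any(bad)) {
    warn(paste0(file, ": ", sum(bad), " row(s) with unparseable ", col,
                " (e.g. row ", which(bad)[1], " value '", raw[which(bad)[1]],
                "') excluded"))
  }
  df[[col]] <- parsed
  df[!bad, , drop = FALSE]
}

#' Load an EHR dataset from CSV files
#'
#' Reads `patients.csv`, `purchases.csv`, `diagnoses.csv`, `insurance.csv`
#' and optionally `population.csv` from a directory (or explicit paths).
#' Dates are ISO-8601; rows with unparseable dates are dropped with a warning
#' naming the first offending row; missing required columns raise an error;
#' events referencing unknown patients raise an error.
#'
#' @param dir directory containing the CSV files; alternatively pass named
#'   `paths` overriding individual files.
#' @param codebook `pd_codebook` used to annotate purchases.
#' @param extraction_date Date; defaults to the value stored in
#'   `manifest.json` in `dir` if present, else the maximum event date.
#' @param paths optional named list/character of explicit file paths
#'   (`patients`, `purchases`, `diagnoses`, `insurance`, `population`).
#' @return an `ehr_dataset`.
#' @export
load_dataset <- function(dir = NULL, codebook = default_codebook(),
                         extraction_date = NULL, paths = list()) {
  f <- function(name) {
    paths[[name]] %||% file.path(dir, paste0(name, ".csv"))
  }
  pat <- read_csv_quiet(f("patients"), readr::cols(.default = readr::col_character()))
  check_columns(pat, c("patient_id", "sex", "birth_date"), "patients.csv")
  if (!"death_date" %in% names(pat)) pat$death_date <- NA_character_
  if (!"ethnic_group" %in% names(pat)) pat$ethnic_group <- "unknown"
  if (!"ses_stratum" %in% names(pat)) pat$ses_stratum <- "unknown"
  pat <- parse_date_col(pat, "birth_date", "patients.csv")
  pat$death_date <- as.Date(suppressWarnings(
    readr::parse_date(as.character(pat$death_date), format = "%Y-%m-%d")))

  pur <- read_csv_quiet(f("purchases"), readr::cols(
    patient_id = readr::col_character(), purchase_date = readr::col_character(),
    atc_code = readr::col_character(), .default = readr::col_double()))
  check_columns(pur, c("patient_id", "purchase_date", "atc_code"), "purchases.csv")
  if (!"strength_mg" %in% names(pur)) pur$strength_mg <- NA_real_
  pur <- parse_date_col(pur, "purchase_date", "purchases.csv")

  dx <- read_csv_quiet(f("diagnoses"), readr::cols(.default = readr::col_character()))
  check_columns(dx, c("patient_id", "dx_date", "icd10_code"), "diagnoses.csv")
  if (!"provider_type" %in% names(dx)) dx$provider_type <- "other"
  dx <- parse_date_col(dx, "dx_date", "diagnoses.csv")
  bad_icd <- !grepl("^[A-Z][0-9]", dx$icd10_code)
  if (any(bad_icd)) {
    warn(paste0("diagnoses.csv: ", sum(bad_icd),
                " row(s) with malformed ICD-10 code excluded"))
    dx <- dx[!bad_icd, , drop = FALSE]
  }

  ins <- read_csv_quiet(f("insurance"), readr::cols(.default = readr::col_character()))
  check_columns(ins, c("patient_id", "start", "end"), "insurance.csv")
  ins <- parse_date_col(ins, "start", "insurance.csv")
  ins <- parse_date_col(ins, "end", "insurance.csv")

  pop <- NULL
  pop_path <- f("population")
  if (file.exists(pop_path)) {
    pop <- read_csv_quiet(pop_path, readr::cols(
      sex = readr::col_character(), .default = readr::col_double()))
    check_columns(pop, c("year", "band_start", "sex", "population"),
                  "population.csv")
  }

  if (is.null(extraction_date)) {
    mf <- if (!is.null(dir)) file.path(dir, "manifest.json") else ""
    if (nzchar(mf) && file.exists(mf)) {
      extraction_date <- as.Date(jsonlite::read_json(mf)$extraction_date)
    } else {
      extraction_date <- suppressWarnings(max(c(pur$purchase_date, dx$dx_date,
                                                ins$end), na.rm = TRUE))
    }
  }

  new_ehr_dataset(pat, pur, dx, ins, pop,
                  extraction_date = as.Date(extraction_date),
                  codebook = codebook)
}

#' Write an EHR dataset to CSV files
#'
#' Inverse of [load_dataset()]: writes the five CSV tables plus a
#' `manifest.json` carrying the extraction date. Output is byte-stable for a
#' fixed dataset (deterministic ordering, ISO dates).
#'
#' @param dataset `ehr_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    readr::write_csv(df, file.path(dir, paste0(name, ".csv")), progress = FALSE)
  }
  wr(dataset$patients %>% arrange(patient_id), "patients")
  wr(dataset$purchases %>% select(-any_of("apm_class")) %>%
       arrange(patient_id, purchase_date, atc_code), "purchases")
  wr(dataset$diagnoses %>% arrange(patient_id, dx_date, icd10_code), "diagnoses")
  wr(dataset$insurance %>% arrange(patient_id, start), "insurance")
  if (!is.null(dataset$population)) {
    wr(dataset$population %>% arrange(year, band_start, sex), "population")
  }
  jsonlite::write_json(list(extraction_date = format(dataset$extraction_date)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write a JSON run manifest
#'
#' Records the seed, a hash of the effective configuration and package
#' version for reproducibility audits.
#'
#' @param path output file.
#' @param seed integer seed used for the run (NA if none).
#' @param config list echoed (hashed) into the manifest.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, seed = NA_integer_, config = list()) {
  m <- list(
    package = "pdmedalg",
    version = as.character(utils::packageVersion("pdmedalg")),
    seed = seed,
    config_hash = rlang::hash(config),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(m)
}
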