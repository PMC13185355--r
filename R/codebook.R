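#' Default drug and diagnosis codebook
#'
#' The algorithm is driven by a codebook mapping ATC-5 drug codes and ICD-10
#' diagnosis prefixes to the semantic classes its rules use. The published
#' ATC list behind the algorithm is not public, so this default is a
#' best-effort reconstruction from the ATC N04 (anti-parkinson drugs) and
#' N05A (antipsychotics) groups and standard ICD-10 coding practice. Every
#' set is user-overridable, either by editing the returned list or via a YAML
#' config ([read_codebook()]).
#'
#' @details
#' The six APM (antiparkinsonian medication) subclasses are pairwise
#' disjoint. By default the anticholinergic class does **not** count toward
#' the inclusion rule or first-purchase-date (FPD): anticholinergics only
#' enter through the index-date exception. Set
#' `inclusion_classes` to change this.
#'
#' Quetiapine at low dose is commonly prescribed for non-psychotic
#' indications; purchases of `quetiapine_code` with strength less than or
#' equal to `quetiapine_max_mg` (default 50 mg) are not counted as
#' antipsychotic. A missing strength on a quetiapine row is treated as above
#' the threshold (counts as antipsychotic) unless
#' `quetiapine_missing_strength_counts` is set to `FALSE`.
#'
#' Duration words are mapped to days once, here: `month_days` (30),
#' `half_year_days` (183), and N years via round-half-up of N * 365.25
#' (see [years_to_days()]).
#'
#' @param overrides named list merged over the defaults (shallow for scalar
#'   settings, replacing whole code sets).
#' @return A list of class `pd_codebook` with elements `apm_classes`,
#'   `inclusion_classes`, `antipsychotics`, `quetiapine_code`,
#'   `quetiapine_max_mg`, `quetiapine_missing_strength_counts`, `dx_sets`,
#'   and the window constants.
#' @export
#' @examples
#' cb <- default_codebook()
#' names(cb$apm_classes)
default_codebook <- function(overrides = list()) {
  cb <- list(
    apm_classes = list(
      levodopa        = c("N04BA01", "N04BA02", "N04BA03"),
      dopamine_agonist = c("N04BC01", "N04BC02", "N04BC04", "N04BC05",
                           "N04BC06", "N04BC07", "N04BC08", "N04BC09"),
      mao_inhibitor   = c("N04BD01", "N04BD02", "N04BD03"),
      amantadine      = c("N04BB01"),
      comt_inhibitor  = c("N04BX01", "N04BX02", "N04BX04"),
      anticholinergic = c("N04AA01", "N04AA02", "N04AA04")
    ),
    # classes whose purchases define the FPD, occasions, spans and
    # "exclusively purchased" clauses
    inclusion_classes = c("levodopa", "dopamine_agonist", "mao_inhibitor",
                          "amantadine", "comt_inhibitor"),
    # dopamine agonists restricted to specific drugs in some exclusions
    bromocriptine_pergolide = c("N04BC01", "N04BC02"),
    cabergoline             = c("N04BC06"),
    antipsychotics = c(
      "N05AA01", "N05AA02", "N05AB02", "N05AB03", "N05AC02", "N05AD01",
      "N05AE03", "N05AE04", "N05AF01", "N05AF05", "N05AG02", "N05AH02",
      "N05AH03", "N05AH04", "N05AL01", "N05AX08", "N05AX12", "N05AX13"
    ),
    quetiapine_code = "N05AH04",
    quetiapine_max_mg = 50,
    quetiapine_missing_strength_counts = TRUE,
    dx_sets = list(
      pd                   = c("G20"),
      hyperprolactinemia   = c("E22.1"),
      pituitary_adenoma    = c("D35.2"),
      pregnancy_or_birth   = c("O80", "O81", "O82", "O83", "O84", "Z37", "Z33"),
      hydrocephalus        = c("G91"),
      anoxic_brain_injury  = c("G93.1"),
      tbi                  = c("S06"),
      coma                 = c("R40.2"),
      psp                  = c("G23.1"),
      msa                  = c("G23.2", "G23.3", "G90.3"),
      cbd                  = c("G23.8", "G31.8"),
      rls                  = c("G25.8"),
      recurrent_falls      = c("R29.6"),
      lethargy             = c("R53"),
      general_deterioration = c("R54"),
      constipation         = c("K59"),
      tremor               = c("G25.0"),
      tremor_nos           = c("R52.1"),
      depressive_episode   = c("F32"),
      tobacco_disorder     = c("F17"),
      heavy_smoker         = c("Z72.0")
    ),
    # temporal constants (days)
    month_days = 30L,
    half_year_days = 183L,
    # index-date exception precedence when both apply
    pituitary_exception_wins = TRUE,
    # first calendar date an FPD may take (inclusion 3: FPD after Dec 31 2004)
    fpd_floor = as.Date("2005-01-01"),
    # cabergoline-restriction cutoff (exclusion 3: FPD in the past ten years)
    cabergoline_cutoff = as.Date("2014-01-01"),
    age_min = 25L,
    age_max = 100L
  )
  cb <- utils::modifyList(cb, overrides)
  validate_codebook(cb)
}

#' Validate a codebook
#'
#' Checks the structural invariants: APM classes pairwise disjoint, all
#' semantic diagnosis sets used by the rules present and non-empty, scalar
#' settings well-formed.
#'
#' @param cb list as produced by [default_codebook()] or [read_codebook()].
#' @return the codebook, classed `pd_codebook`, invisibly usable downstream.
#' @export
validate_codebook <- function(cb) {
  stopifnot(is.list(cb$apm_classes), is.list(cb$dx_sets))
  all_codes <- unlist(cb$apm_classes, use.names = FALSE)
  if (anyDuplicated(all_codes)) {
    abort("APM classes must be pairwise disjoint ATC code sets")
  }
  required_dx <- c("pd", "hyperprolactinemia", "pituitary_adenoma",
                   "pregnancy_or_birth", "hydrocephalus", "anoxic_brain_injury",
                   "tbi", "coma", "psp", "msa", "cbd", "rls",
                   "recurrent_falls", "lethargy", "general_deterioration")
  missing <- setdiff(required_dx, names(cb$dx_sets))
  if (length(missing)) {
    abort(paste0("codebook dx_sets missing required conditions: ",
                 paste(missing, collapse = ", ")))
  }
  empty <- names(cb$dx_sets)[vapply(cb$dx_sets, length, 1L) == 0]
  if (length(empty)) {
    abort(paste0("codebook dx_sets empty for: ", paste(empty, collapse = ", ")))
  }
  if (!all(cb$inclusion_classes %in% names(cb$apm_classes))) {
    abort("inclusion_classes must name APM classes")
  }
  stopifnot(cb$quetiapine_max_mg >= 0, cb$month_days > 0,
            cb$half_year_days > 0)
  class(cb) <- c("pd_codebook", "list")
  cb
}

#' Read a codebook from a YAML config file
#'
#' The YAML schema mirrors the list returned by [default_codebook()]; any key
#' present in the file replaces the default. Dates may be given as
#' `YYYY-MM-DD` strings.
#'
#' @param path YAML file.
#' @return validated `pd_codebook`.
#' @export
read_codebook <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("fpd_floor", "cabergoline_cutoff")) {
    if (!is.null(y[[k]])) y[[k]] <- as.Date(y[[k]])
  }
  default_codebook(overrides = y)
}

#' Convert years to whole days
#'
#' Uses round-half-up of `n * 365.25`, so 1 year = 365 d, 2 years = 731 d,
#' 3 years = 1096 d, 5 years = 1826 d. All elapsed-time rules in the engine
#' are expressed through this one function.
#'
#' @param n years (possibly fractional).
#' @return integer days.
#' @export
years_to_days <- function(n) as.integer(floor(n * 365.25 + 0.5))

#' Classify one purchase row into a semantic drug class
#'
#' Total function: returns one of the six APM subclass names,
#' `"antipsychotic"`, or `"none"`. Quetiapine rows with strength at or below
#' the codebook threshold are not antipsychotic triggers (low-dose quetiapine
#' is used for non-psychotic indications); missing strength is treated per
#' the codebook's `quetiapine_missing_strength_counts` switch.
#'
#' @param atc_code character vector of ATC-5 codes.
#' @param strength_mg numeric vector (NA allowed) of per-unit strengths.
#' @param codebook a `pd_codebook`.
#' @return character vector of class labels.
#' @export
#' @examples
#' cb <- default_codebook()
#' classify_purchase("N04BA02", NA, cb)        # "levodopa"
#' classify_purchase("N05AH04", 25, cb)        # "none": low-dose quetiapine
#' classify_purchase("N05AH04", 100, cb)       # "antipsychotic"
classify_purchase <- function(atc_code, strength_mg = NA_real_, codebook) {
  strength_mg <- rep_len(as.numeric(strength_mg), length(atc_code))
  out <- rep("none", length(atc_code))
  for (cls in names(codebook$apm_classes)) {
    out[atc_code %in% codebook$apm_classes[[cls]]] <- cls
  }
  is_ap <- atc_code %in% codebook$antipsychotics & out == "none"
  quet <- atc_code %in% codebook$quetiapine_code
  low_quet <- quet & !is.na(strength_mg) &
    strength_mg <= codebook$quetiapine_max_mg
  missing_quet <- quet & is.na(strength_mg)
  drop <- low_quet | (missing_quet & !codebook$quetiapine_missing_strength_counts)
  out[is_ap & !drop] <- "antipsychotic"
  out
}

#' Dot-insensitive ICD-10 prefix match
#'
#' Registries mix 3- and 4-character codes; matching strips dots from both
#' sides and tests prefixes, so a prefix `K59` matches `K59.0` and `K590`.
#'
#' @param codes character vector of observed ICD-10 codes.
#' @param prefixes character vector of codebook prefixes.
#' @return logical vector, `TRUE` where any prefix matches.
#' @export
icd10_match <- function(codes, prefixes) {
  cc <- gsub(".", "", codes, fixed = TRUE)
  pp <- gsub(".", "", prefixes, fixed = TRUE)
  out <- rep(FALSE, length(cc))
  for (p in pp) out <- out | startsWith(cc, p)
  out
}
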