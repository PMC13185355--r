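# Independent naive re-implementation of the classification rules, used only
# as a cross-check. Each criterion is transcribed directly, base R, per
# patient, sharing no code with the engine (the codebook's code lists are the
# common input by design).

oracle_classify <- function(dataset) {
  cb <- dataset$codebook
  ext <- dataset$extraction_date
  strip <- function(x) gsub(".", "", x, fixed = TRUE)
  prefix_hit <- function(codes, prefixes) {
    if (length(codes) == 0) return(logical(0))
    out <- rep(FALSE, length(codes))
    for (p in strip(prefixes)) out <- out | startsWith(strip(codes), p)
    out
  }
  yd <- function(n) floor(n * 365.25 + 0.5)
  incl_codes <- unlist(cb$apm_classes[cb$inclusion_classes], use.names = FALSE)

  res <- vector("list", nrow(dataset$patients))
  for (i in seq_len(nrow(dataset$patients))) {
    p <- dataset$patients[i, ]
    pur <- dataset$purchases[dataset$purchases$patient_id == p$patient_id, ]
    dx <- dataset$diagnoses[dataset$diagnoses$patient_id == p$patient_id, ]
    ins <- dataset$insurance[dataset$insurance$patient_id == p$patient_id, ]

    apm <- pur[pur$atc_code %in% incl_codes, ]
    apm_dates <- sort(unique(apm$purchase_date))
    fpd <- if (length(apm_dates)) apm_dates[1] else as.Date(NA)
    last <- if (length(apm_dates)) apm_dates[length(apm_dates)] else as.Date(NA)
    span <- if (length(apm_dates)) as.numeric(last - fpd) else 0
    occ <- length(apm_dates)

    obs_end <- min(c(if (!is.na(p$death_date)) p$death_date, max(ins$end), ext))
    obs_end <- as.Date(obs_end, origin = "1970-01-01")

    # completed-years age (naive month/day comparison)
    age_fpd <- NA_integer_
    if (!is.na(fpd)) {
      by <- as.integer(format(p$birth_date, "%Y"))
      fy <- as.integer(format(fpd, "%Y"))
      had_bday <- format(fpd, "%m-%d") >= format(p$birth_date, "%m-%d")
      age_fpd <- fy - by - as.integer(!had_bday)
    }

    dx_in <- function(set) dx$dx_date[prefix_hit(dx$icd10_code, cb$dx_sets[[set]])]
    has <- function(set) length(dx_in(set)) > 0
    pd_dates <- dx_in("pd")
    has_pd <- length(pd_dates) > 0

    # antipsychotic purchases, honouring the low-dose quetiapine carve-out
    is_ap <- pur$atc_code %in% cb$antipsychotics
    quet <- pur$atc_code %in% cb$quetiapine_code
    low <- quet & !is.na(pur$strength_mg) & pur$strength_mg <= cb$quetiapine_max_mg
    if (!cb$quetiapine_missing_strength_counts) low <- low | (quet & is.na(pur$strength_mg))
    ap_dates <- pur$purchase_date[is_ap & !low]
    ap_prior <- !is.na(fpd) &&
      any(ap_dates >= fpd - 365 & ap_dates < fpd)
    levo <- any(pur$atc_code %in% cb$apm_classes$levodopa)
    ach_dates <- pur$purchase_date[pur$atc_code %in% cb$apm_classes$anticholinergic]

    only <- function(codes) occ > 0 && all(apm$atc_code %in% codes)

    inc <- c(
      INC1 = occ >= 2,
      INC2 = !is.na(fpd) && any(ins$start <= fpd & fpd <= ins$end),
      INC3 = !is.na(fpd) && fpd > as.Date("2004-12-31"),
      INC4 = !is.na(fpd) && age_fpd >= 25 && age_fpd <= 100)

    if (!all(inc)) {
      res[[i]] <- data.frame(patient_id = p$patient_id, status = "not_eligible",
                             fired = paste(names(inc)[!inc], collapse = ";"))
      next
    }

    in_win <- function(dates, lo, hi, closed_hi = FALSE) {
      rel <- as.numeric(dates - fpd)
      any(rel >= lo & (if (closed_hi) rel <= hi else rel < hi))
    }
    heavy <- (occ > 20 || span > yd(5)) || (occ > 8 || span > yd(2))
    gap <- as.numeric(obs_end - last)

    exc <- c(
      EXC1 = (has("hyperprolactinemia") || has("pituitary_adenoma")) && !has_pd,
      EXC2 = has("pituitary_adenoma") && has_pd &&
        only(cb$bromocriptine_pergolide),
      EXC3 = has("pituitary_adenoma") && has_pd && fpd >= as.Date("2014-01-01") &&
        only(cb$cabergoline),
      EXC4 = p$sex == "female" && only(cb$apm_classes$dopamine_agonist) &&
        !has_pd && in_win(dx_in("pregnancy_or_birth"), -yd(2), 0),
      EXC5 = any(c(dx_in("hydrocephalus"), dx_in("anoxic_brain_injury")) <= fpd + 30),
      EXC6 = in_win(dx_in("tbi"), -183, 0) && in_win(dx_in("coma"), -183, 0),
      EXC7 = {
        atyp <- c(dx_in("psp"), dx_in("msa"), dx_in("cbd"))
        length(atyp) > 0 && !any(pd_dates > max(atyp))
      },
      EXC8 = has("rls") && !any(pd_dates > max(dx_in("rls"))),
      EXC9 = ap_prior && (!levo || (levo && !has_pd)),
      EXC10 = only(cb$apm_classes$mao_inhibitor) && heavy && !has_pd,
      EXC11 = only(cb$apm_classes$amantadine) && heavy && !has_pd,
      EXC12 = !has_pd && span > yd(2) &&
        in_win(c(dx_in("recurrent_falls"), dx_in("lethargy"),
                 dx_in("general_deterioration")), -365, yd(5), closed_hi = TRUE),
      EXC13 = !has_pd && span < yd(2) && gap > 365,
      EXC14 = span < 183 && gap > yd(3))

    if (any(exc)) {
      res[[i]] <- data.frame(patient_id = p$patient_id, status = "excluded",
                             fired = paste(names(exc)[exc], collapse = ";"))
      next
    }

    pos <- c(
      POS1 = !has_pd,
      POS2 = as.numeric(obs_end - fpd) < yd(2),
      POS3 = span > yd(3) && gap > yd(2),
      POS4 = has_pd && ap_prior && levo)

    if (any(pos)) {
      res[[i]] <- data.frame(patient_id = p$patient_id, status = "possible_pd",
                             fired = paste(names(pos)[pos], collapse = ";"))
    } else {
      res[[i]] <- data.frame(patient_id = p$patient_id, status = "probable_pd",
                             fired = "")
    }
  }
  do.call(rbind, res)
}
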