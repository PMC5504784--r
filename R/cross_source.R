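# Steps 9-16: coherence of dates and demographics across data sources.

# share conditions of the DOB comparison: same (month, year), (month, day)
# or (day, year), or under `gap_days` days apart
.dob_close <- function(a, b, gap_days = 140L) {
  am <- format(a, "%m"); ay <- format(a, "%Y"); ad <- format(a, "%d")
  bm <- format(b, "%m"); by <- format(b, "%Y"); bd <- format(b, "%d")
  (am == bm & ay == by) | (am == bm & ad == bd) | (ad == bd & ay == by) |
    abs(as.integer(a - b)) < gap_days
}

# would replacing this delivery date create a step-6 or step-8
# person-level inconsistency for the mother?
.dob_safe_for_mother <- function(first_recs, replace_id, new_dob) {
  recs <- copy(first_recs)
  recs[record_id == replace_id, baby_dob := new_dob]
  recs <- recs[order(baby_dob)]
  if (nrow(recs) >= 2L) {
    iv <- pregnancy_interval(shift(recs$baby_dob)[-1], recs$baby_dob[-1],
                             recs$gestational_age[-1])
    if (any(!is.na(iv) & iv < 0L)) return(FALSE)
    p <- recs$parity
    nm <- p[!is.na(p)]
    if (classify_parity_sequence(p) == "illogical" && length(nm)) {
      expected <- max(nm) - min(nm) + 1L
      count <- nrow(recs)
      if ((expected == 1L && count >= 4L) ||
          (expected >= 2L && count - expected >= 2L)) return(FALSE)
    }
  }
  TRUE
}

#' Reconcile the baby's date of birth across sources
#'
#' The perinatal DOB is authoritative when it matches any patient DOB in
#' the baby's hospital/ED records. When it matches none, a patient DOB is
#' accepted as alternative only if it falls inside a maternal delivery
#' admission (admission <= DOB <= separation), is not the DOB of another
#' (non-twin) child of the same mother, and creates no new pregnancy
#' interval or parity inconsistency; the perinatal DOB is then corrected.
#' Finally the updated DOB is merged back: encounter records whose patient
#' DOB still disagrees get an age correction when the two dates share
#' month+year, month+day or day+year or lie under 20 weeks apart, and a
#' `deletion` flag otherwise.
#'
#' @param perinatal,encounters current views.
#' @param ledger a [ledger_new()] object.
#' @param baby_yob_range valid patient year-of-birth window; records
#'   outside it are ignored as evidence.
#' @param gap_days the 20-week bound in days (140; a gap of exactly 140 is
#'   not "less than" 20 weeks, so such records are flagged for deletion).
#' @return data.table, one row per baby examined, with the accepted
#'   alternative (if any) and per-record dispositions summarised.
#' @export
reconcile_baby_dob <- function(perinatal, encounters, ledger,
                               baby_yob_range = c(1920L, 2014L),
                               gap_days = 140L) {
  enc_b <- encounters[role == "baby" & !is.na(patient_dob)]
  enc_b <- enc_b[is.na(patient_yob) |
                   (patient_yob >= baby_yob_range[1] & patient_yob <= baby_yob_range[2])]
  cand <- merge(perinatal[, .(baby_ppn, mum_ppn, record_id, baby_dob)],
                enc_b[, .(baby_ppn = ppn, patient_dob)], by = "baby_ppn")
  if (!nrow(cand)) {
    return(data.table(baby_ppn = character(), accepted_alternative = as.Date(character())))
  }
  st <- cand[, .(match = any(baby_dob == patient_dob),
                 cands = list(unique(patient_dob))),
             by = .(baby_ppn, mum_ppn, record_id, baby_dob)]
  windows <- encounters[role == "mother" & is_delivery == TRUE]
  updated <- setNames(perinatal$baby_dob, perinatal$baby_ppn)
  out <- list()
  for (i in which(!st$match)) {
    b <- st$baby_ppn[i]; m <- st$mum_ppn[i]
    sibs <- perinatal[mum_ppn == m & baby_ppn != b]
    twin_dobs <- sibs[abs(as.integer(baby_dob - st$baby_dob[i])) <= 7L, baby_dob]
    other_dobs <- setdiff(sibs$baby_dob, twin_dobs)
    w <- windows[ppn == m]
    first_recs <- perinatal[mum_ppn == m & birth_order == 1L,
                            .(record_id, baby_dob, gestational_age, parity)]
    alts <- as.Date(character())
    for (d in st$cands[[i]]) {
      d <- as.Date(d, origin = "1970-01-01")
      if (!nrow(w[admission_date <= d & separation_date >= d])) next
      if (as.integer(d) %in% other_dobs) next
      if (st$record_id[i] %in% first_recs$record_id &&
          !.dob_safe_for_mother(first_recs, st$record_id[i], d)) next
      alts <- c(alts, d)
    }
    if (length(alts) == 1L) {
      ledger_correct(ledger, st$record_id[i], "baby_dob",
                     as.character(st$baby_dob[i]), as.character(alts), "S9.3")
      updated[b] <- alts
      out[[b]] <- data.table(baby_ppn = b, accepted_alternative = alts)
    } else if (length(alts) > 1L) {
      ledger_review(ledger, "S9.3", b,
                    sprintf("multiple candidate DOBs in delivery windows: %s",
                            paste(alts, collapse = "/")))
      out[[b]] <- data.table(baby_ppn = b, accepted_alternative = as.Date(NA))
    }
  }
  # 9.4: merge the updated DOB into hospital/ED records
  chk <- enc_b[ppn %in% names(updated)]
  chk[, updated_dob := updated[ppn]]
  chk <- chk[patient_dob != updated_dob]
  if (nrow(chk)) {
    close <- .dob_close(chk$updated_dob, chk$patient_dob, gap_days)
    if (any(close)) {
      cc <- chk[close]
      new_age <- pmax(0L, as.integer(floor(
        as.numeric(cc$admission_date - cc$updated_dob) / 365.25)))
      # the record's age is corrected; its patient DOB is left recorded so
      # step 14 can still compare the two dates
      ledger_correct(ledger, cc$record_id, "patient_age",
                     as.character(cc$patient_age),
                     as.character(new_age), "S9.4")
    }
    if (any(!close)) {
      ledger_flag(ledger, "record", chk[!close, record_id], "deletion", "S9.4",
                  reason_code = "irreconcilable_patient_dob")
    }
  }
  if (length(out)) rbindlist(out) else
    data.table(baby_ppn = character(), accepted_alternative = as.Date(character()))
}

#' Consistency between perinatal and congenital-condition records
#'
#' Acts only when both the DOB and the birthweight disagree. If the
#' congenital DOB equals the DOB of a different (non-twin) child of the
#' same mother the link is judged an error among the children and the
#' mother is flagged for exclusion; otherwise the case is queued for
#' review.
#'
#' @param perinatal,congenital current views.
#' @param ledger a [ledger_new()] object.
#' @return data.table of examined babies and dispositions.
#' @export
check_congenital_consistency <- function(perinatal, congenital, ledger) {
  if (is.null(congenital) || !nrow(congenital)) {
    return(data.table(baby_ppn = character(), disposition = character()))
  }
  j <- merge(congenital, perinatal[, .(baby_ppn, mum_ppn, p_dob = baby_dob,
                                       p_bw = birthweight)], by = "baby_ppn")
  j <- j[!is.na(baby_dob) & !is.na(birthweight) &
           baby_dob != p_dob & birthweight != p_bw]
  out <- list()
  for (i in seq_len(nrow(j))) {
    m <- j$mum_ppn[i]
    sib <- perinatal[mum_ppn == m & baby_ppn != j$baby_ppn[i] &
                       abs(as.integer(baby_dob - j$p_dob[i])) > 7L]
    if (j$baby_dob[i] %in% sib$baby_dob) {
      ledger_flag(ledger, "person", m, "exclusion", "S10.3",
                  reason_code = "congenital_sibling_dob", detail = j$baby_ppn[i])
      out[[i]] <- data.table(baby_ppn = j$baby_ppn[i], disposition = "mother_excluded")
    } else {
      ledger_review(ledger, "S10.3", m,
                    sprintf("congenital DOB/birthweight disagree for %s", j$baby_ppn[i]))
      out[[i]] <- data.table(baby_ppn = j$baby_ppn[i], disposition = "review")
    }
  }
  if (length(out)) rbindlist(out) else
    data.table(baby_ppn = character(), disposition = character())
}

# pooled mother year-of-birth observations: perinatal plus mother-role
# encounters (the death schema carries no YOB)
.mother_yob_obs <- function(perinatal, encounters, valid = c(1900L, 2014L)) {
  obs <- rbind(
    perinatal[!is.na(mother_yob), .(mum_ppn, yob = mother_yob)],
    encounters[role == "mother" & !is.na(patient_yob),
               .(mum_ppn = ppn, yob = patient_yob)]
  )
  obs[yob >= valid[1] & yob <= valid[2]]
}

#' Mother year-of-birth consistency
#'
#' The plausible YOB range is taken from the perinatal data; encounter
#' records outside the hard validity window are dropped from assessment. A
#' mother with two or more records outside the perinatal-derived range, or
#' more than three distinct YOBs, is flagged for exclusion.
#'
#' @param perinatal,encounters current views.
#' @param ledger a [ledger_new()] object.
#' @param valid_yob hard validity window (records outside are ignored).
#' @return assessment table per mother with any YOB anomaly.
#' @export
check_mother_yob <- function(perinatal, encounters, ledger,
                             valid_yob = c(1900L, 2014L)) {
  rng <- range(perinatal$mother_yob, na.rm = TRUE)
  obs <- .mother_yob_obs(perinatal, encounters, valid_yob)
  a <- obs[, .(n_out = sum(yob < rng[1] | yob > rng[2]),
               n_distinct = uniqueN(yob)), by = mum_ppn]
  bad <- a[n_out >= 2L | n_distinct > 3L]
  if (nrow(bad)) {
    ledger_flag(ledger, "person", bad$mum_ppn, "exclusion", "S11.4",
                reason_code = "inconsistent_mother_yob")
  }
  a[n_out > 0L | n_distinct > 1L]
}

#' Mother sex recorded as male
#'
#' Male-coded records alone are treated as clerical noise; a mother is
#' flagged only when two or more of her records are male-coded and her
#' records additionally disagree on year and/or month of birth.
#'
#' @param perinatal,encounters current views.
#' @param ledger a [ledger_new()] object.
#' @param valid_yob hard validity window applied before counting.
#' @return assessment table per mother with any male-coded record.
#' @export
check_mother_sex <- function(perinatal, encounters, ledger,
                             valid_yob = c(1900L, 2014L)) {
  enc_m <- encounters[role == "mother" &
                        (is.na(patient_yob) |
                           (patient_yob >= valid_yob[1] & patient_yob <= valid_yob[2]))]
  yobs <- .mother_yob_obs(perinatal, encounters, valid_yob)
  a <- enc_m[, .(n_male = sum(patient_sex == "male", na.rm = TRUE),
                 n_mob = uniqueN(month_of_birth, na.rm = TRUE)), by = .(mum_ppn = ppn)]
  a <- merge(a, yobs[, .(n_yob = uniqueN(yob)), by = mum_ppn], by = "mum_ppn", all.x = TRUE)
  bad <- a[n_male >= 2L & (n_yob > 1L | n_mob > 1L)]
  if (nrow(bad)) {
    ledger_flag(ledger, "person", bad$mum_ppn, "exclusion", "S12.2",
                reason_code = "male_sex_with_dob_conflict")
  }
  a[n_male > 0L]
}

#' Births after a total hysterectomy
#'
#' A delivery strictly later than the separation date of an admission with
#' a total-hysterectomy procedure is biologically impossible and flags the
#' mother for exclusion. With an empty code list the check is skipped.
#'
#' @param perinatal,encounters current views.
#' @param hysterectomy_codes character vector of procedure codes.
#' @param ledger a [ledger_new()] object.
#' @return data.table of mothers assessed (hysterectomy date vs last
#'   delivery).
#' @export
check_birth_after_hysterectomy <- function(perinatal, encounters,
                                           hysterectomy_codes, ledger) {
  if (!length(hysterectomy_codes)) {
    message("no hysterectomy procedure codes configured; step 13 skipped")
    return(data.table(mum_ppn = character(), flagged = logical()))
  }
  hosp <- encounters[role == "mother" & source == "hospital" &
                       !is.na(procedure_codes) & procedure_codes != ""]
  if (!nrow(hosp)) return(data.table(mum_ppn = character(), flagged = logical()))
  has_code <- vapply(strsplit(hosp$procedure_codes, ";", fixed = TRUE),
                     function(x) any(x %in% hysterectomy_codes), logical(1))
  hy <- hosp[has_code, .(hyst_sep = min(separation_date)), by = .(mum_ppn = ppn)]
  if (!nrow(hy)) return(data.table(mum_ppn = character(), flagged = logical()))
  last <- perinatal[, .(last_delivery = max(baby_dob)), by = mum_ppn]
  a <- merge(hy, last, by = "mum_ppn")
  a[, flagged := hyst_sep < last_delivery]
  if (any(a$flagged)) {
    ledger_flag(ledger, "person", a[flagged == TRUE, mum_ppn], "exclusion",
                "S13.3", reason_code = "birth_after_hysterectomy")
  }
  a
}

#' Baby DOB later than the date of discharge
#'
#' Uses the updated (post step 9) DOB. Records where the DOB exceeds the
#' separation date are errors: if the updated and patient DOBs are more
#' than 20 weeks apart the baby (and mother) are flagged for exclusion;
#' otherwise the record is flagged for deletion.
#'
#' @param perinatal,encounters current views (step-9 corrections applied).
#' @param ledger a [ledger_new()] object.
#' @param gap_days the 20-week bound in days; "more than" is strict, so a
#'   gap of exactly 140 days stays at record level.
#' @return data.table of offending records.
#' @export
check_dob_after_discharge <- function(perinatal, encounters, ledger,
                                      gap_days = 140L) {
  enc_b <- merge(encounters[role == "baby"],
                 perinatal[, .(ppn = baby_ppn, mum_ppn, updated_dob = baby_dob)],
                 by = "ppn")
  bad <- enc_b[updated_dob > separation_date]
  if (!nrow(bad)) return(data.table(record_id = character(), action = character()))
  bad[, gap := abs(as.integer(updated_dob - patient_dob))]
  excl <- bad[!is.na(gap) & gap > gap_days]
  del <- bad[is.na(gap) | gap <= gap_days]
  if (nrow(excl)) {
    ledger_flag(ledger, "person", unique(excl$ppn), "exclusion", "S14.3",
                reason_code = "dob_after_discharge")
  }
  if (nrow(del)) {
    ledger_flag(ledger, "record", del$record_id, "deletion", "S14.3",
                reason_code = "dob_after_discharge")
  }
  rbind(excl[, .(record_id, action = "exclusion")],
        del[, .(record_id, action = "deletion")])
}

#' Health service use after the date of death
#'
#' Any hospital/ED discharge or delivery more than the administrative
#' allowance (3 days) after the person's registered death flags the person
#' for exclusion; a flagged child propagates to the mother.
#'
#' @param perinatal,encounters,deaths current views.
#' @param ledger a [ledger_new()] object.
#' @param allowance_days administrative registration delay allowed.
#' @return character vector of flagged persons.
#' @export
check_service_after_death <- function(perinatal, encounters, deaths, ledger,
                                      allowance_days = 3L) {
  dd <- .death_dates(deaths)
  if (!nrow(dd)) return(character())
  svc <- rbind(
    encounters[, .(ppn, event_date = separation_date)],
    perinatal[, .(ppn = mum_ppn, event_date = baby_dob)]
  )
  j <- merge(svc, dd, by = "ppn")
  bad <- j[event_date > date_of_death + allowance_days, unique(ppn)]
  if (length(bad)) {
    ledger_flag(ledger, "person", bad, "exclusion", "S15.4",
                reason_code = "service_after_death")
  }
  bad
}

#' Admission or ED arrival after the separation date
#'
#' @param encounters current encounters view.
#' @param ledger a [ledger_new()] object.
#' @return record ids flagged for deletion.
#' @export
check_admission_after_discharge <- function(encounters, ledger) {
  bad <- encounters[admission_date > separation_date, record_id]
  if (length(bad)) {
    ledger_flag(ledger, "record", bad, "deletion", "S16.1",
                reason_code = "admission_after_separation")
  }
  bad
}
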