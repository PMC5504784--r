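library(data.table)

# ---- independent day-count oracle -----------------------------------------
# days since 1970-01-01 from a civil date, via the era/day-of-era algorithm;
# shares no code path with base-R Date arithmetic
days_from_civil <- function(y, m, d) {
  y <- ifelse(m <= 2L, y - 1L, y)
  era <- ifelse(y >= 0L, y, y - 399L) %/% 400L
  yoe <- y - era * 400L
  doy <- (153L * (m + ifelse(m > 2L, -3L, 9L)) + 2L) %/% 5L + d - 1L
  doe <- yoe * 365L + yoe %/% 4L - yoe %/% 100L + doy
  era * 146097L + doe - 719468L
}

oracle_days <- function(date_string) {
  p <- as.integer(strsplit(date_string, "-", fixed = TRUE)[[1]])
  days_from_civil(p[1], p[2], p[3])
}

oracle_conception_days <- function(dob_string, ga) oracle_days(dob_string) - 7L * ga + 14L

oracle_interval <- function(prior_string, dob_string, ga) {
  oracle_conception_days(dob_string, ga) - oracle_days(prior_string) - 7L
}

# ---- brute-force oracles ---------------------------------------------------
# O(n^2) pairwise identical-duplicate groups
brute_force_duplicate_flags <- function(dt) {
  other <- setdiff(names(dt), "record_id")
  n <- nrow(dt)
  flagged <- character()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      same <- all(vapply(other, function(cc) {
        a <- dt[[cc]][i]; b <- dt[[cc]][j]
        (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
      }, logical(1)))
      if (same && dt$record_id[j] < dt$record_id[i]) {
        flagged <- c(flagged, dt$record_id[i])
        break
      }
    }
  }
  sort(unique(flagged))
}

# transitive closure over a bipartite edge list (patid, mum_ppn): repeatedly
# merge component labels until stable
brute_force_components <- function(links) {
  nodes <- unique(c(paste0("P:", links$patid), paste0("M:", links$mum_ppn)))
  lab <- setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(links))) {
      a <- paste0("P:", links$patid[k]); b <- paste0("M:", links$mum_ppn[k])
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) {
        lab[lab == lab[a] | lab == lab[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(lab), lab)
}

# direct transcription of the two exclusion clauses for illogical parity
rule_831 <- function(expected, count) {
  (expected == 1L && count >= 4L) || (expected >= 2L && count - expected >= 2L)
}

# ---- fixture builders ------------------------------------------------------
per_row <- function(record_id, mum, baby, dob, ga = 39L, bw = 3400L,
                    parity = 0L, plurality = 1L, order = 1L, jur = "A",
                    yob = 1980L, apgar = 9L, postcode = "2000",
                    country = "AUS", hospital = "AH01", status = "home") {
  data.table(record_id = record_id, jurisdiction = jur, mum_ppn = mum,
             baby_ppn = baby, baby_dob = as.Date(dob),
             gestational_age = as.integer(ga), birthweight = as.integer(bw),
             parity = as.integer(parity), plurality = as.integer(plurality),
             birth_order = as.integer(order), mother_yob = as.integer(yob),
             mother_age = as.integer(as.integer(format(as.Date(dob), "%Y")) - yob),
             apgar5 = as.integer(apgar), discharge_status = status,
             postcode = postcode, country_of_birth = country,
             hospital = hospital)
}

enc_row <- function(record_id, ppn, adm, sep, role = "baby",
                    source = "hospital", pdob = NA, pyob = NA_integer_,
                    age = NA_integer_, sex = "female", mob = NA_integer_,
                    proc = "", deliv = FALSE, status = "home", jur = "A") {
  data.table(record_id = record_id, jurisdiction = jur, ppn = ppn,
             role = role, source = source, admission_date = as.Date(adm),
             separation_date = as.Date(sep), patient_dob = as.Date(pdob),
             patient_yob = as.integer(pyob), patient_age = as.integer(age),
             patient_sex = sex, month_of_birth = as.integer(mob),
             procedure_codes = proc, is_delivery = deliv,
             discharge_status = status)
}

death_row <- function(record_id, ppn, date, stream = "registration", jur = "A") {
  data.table(record_id = record_id, jurisdiction = jur, ppn = ppn,
             date_of_death = as.Date(date), stream = stream)
}

# ---- ground-truth recovery checking ---------------------------------------
# recovered: TRUE when the pipeline produced the flag/correction/review or
# cluster the truth row expects
truth_recovered <- function(tr, res) {
  lg <- ledger_entries(res$ledger)
  rv <- ledger_review_queue(res$ledger)
  cr <- ledger_corrections(res$ledger)
  vapply(seq_len(nrow(tr)), function(i) {
    t <- tr[i]
    switch(t$expected_flag,
      exclusion = ,
      duplicate = ,
      deletion = ,
      disregard_link = nrow(lg[target_id == t$target_id & flag == t$expected_flag &
                                 step_id == t$expected_step]) > 0L,
      review = nrow(rv[step_id == t$expected_step &
                         (grepl(t$target_id, target_ids, fixed = TRUE) |
                            grepl(t$mum_ppn, target_ids, fixed = TRUE))]) > 0L,
      correction = nrow(cr[record_id == t$target_id & step_id == t$expected_step]) > 0L,
      cluster = {
        ms <- strsplit(t$target_id, ";")[[1]]
        r <- res$resolution[mum_ppn %in% ms]
        nrow(r) == length(ms) && uniqueN(r$final_ppn) == 1L &&
          startsWith(r$final_ppn[1], "CL")
      },
      FALSE)
  }, logical(1))
}

# unexplained ledger entries: every flag must either match a truth row
# exactly or be an exclusion/record flag inside a family named by the truth
# table (mother <-> child propagation at the same protocol step)
unexplained_flags <- function(inj, res) {
  lg <- ledger_entries(res$ledger)
  if (!nrow(lg)) return(lg)
  tr <- inj$truth
  fam <- unique(unlist(lapply(seq_len(nrow(tr)), function(i) {
    m <- tr$mum_ppn[i]
    c(m, tr$target_id[i], inj$perinatal[mum_ppn == m, baby_ppn])
  })))
  ok_exact <- lg[, paste(target_id, flag, step_id, sep = "|")] %in%
    tr[, paste(target_id, expected_flag, expected_step, sep = "|")]
  ok_prop <- lg$scope == "person" & lg$flag == "exclusion" &
    lg$target_id %in% fam & lg$step_id %in% tr$expected_step
  lg[!(ok_exact | ok_prop)]
}

# one perinatal record per pregnancy for a mother with given parities
make_mother <- function(m, parities, start = "2004-01-01", gap = 500L) {
  rbindlist(lapply(seq_along(parities), function(i)
    per_row(sprintf("%s-P%d", m, i), m, sprintf("%s-B%d", m, i),
            as.Date(start) + (i - 1L) * gap, parity = parities[i])))
}

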