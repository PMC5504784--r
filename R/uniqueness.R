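# Steps 1-3: uniqueness of records.

#' Identical duplicates within one source table
#'
#' Rows equal on every column except the record identifier are grouped; the
#' first record of each group (lowest `record_id`) is kept and the rest are
#' flagged `duplicate`.
#'
#' @param dt any source table with a `record_id` column.
#' @param ledger a [ledger_new()] object (flags appended); `NULL` to only
#'   report.
#' @param step_id ledger step annotation.
#' @return a duplicate report: one row per group with the kept and flagged
#'   record ids.
#' @export
find_identical_duplicates <- function(dt, ledger = NULL, step_id = "S1.1") {
  stopifnot("record_id" %in% names(dt))
  other <- setdiff(names(dt), "record_id")
  sig <- do.call(paste, c(lapply(other, function(c) as.character(dt[[c]])), sep = "\r"))
  g <- data.table(record_id = dt$record_id, sig = sig)
  g <- g[, .(ids = list(sort(record_id)), n = .N), by = "sig"][n >= 2L]
  report <- data.table(
    keep_id = vapply(g$ids, `[`, character(1), 1L),
    flagged = vapply(g$ids, function(x) paste(x[-1], collapse = ";"), character(1)),
    kind = rep("identical", nrow(g))
  )
  if (!is.null(ledger) && nrow(g)) {
    ledger_flag(ledger, "record", unlist(lapply(g$ids, `[`, -1L)), "duplicate",
                step_id, reason_code = "identical_duplicate")
  }
  report
}

#' Partial duplicates of the same death
#'
#' After identical duplicates are removed, a person present in two or more
#' death records is a partial duplicate of one death. Equal dates: all but
#' the first record are flagged `duplicate`. Different dates: hospital/ED
#' evidence adjudicates - a discharge with deceased status on one of the
#' candidate dates supports that date and the others are flagged; without
#' evidence the case goes to the review queue unflagged.
#'
#' @param deaths current deaths view (identical duplicates removed).
#' @param encounters current encounters view (adjudication evidence).
#' @param ledger a [ledger_new()] object.
#' @return data.table of the multi-record persons and their disposition.
#' @export
find_partial_death_duplicates <- function(deaths, encounters, ledger) {
  multi <- deaths[, .N, by = ppn][N >= 2L, ppn]
  out <- list()
  for (p in multi) {
    recs <- deaths[ppn == p][order(date_of_death, record_id)]
    dates <- unique(recs$date_of_death)
    if (length(dates) == 1L) {
      ledger_flag(ledger, "record", recs$record_id[-1], "duplicate", "S1.2",
                  reason_code = "partial_death_duplicate")
      out[[p]] <- data.table(ppn = p, disposition = "flagged_same_date")
      next
    }
    supported <- encounters[ppn == p & discharge_status == "deceased" &
                              separation_date %in% dates,
                            unique(separation_date)]
    if (length(supported) == 1L) {
      keep <- recs[date_of_death == supported, record_id][1]
      ledger_flag(ledger, "record", setdiff(recs$record_id, keep), "duplicate",
                  "S1.2", reason_code = "partial_death_duplicate",
                  detail = sprintf("discharge evidence supports %s", supported))
      out[[p]] <- data.table(ppn = p, disposition = "flagged_by_evidence")
    } else {
      ledger_review(ledger, "S1.2", p,
                    sprintf("death dates %s; no decisive discharge evidence",
                            paste(dates, collapse = "/")))
      out[[p]] <- data.table(ppn = p, disposition = "review")
    }
  }
  if (length(out)) rbindlist(out) else
    data.table(ppn = character(), disposition = character())
}

#' Death-registration completeness (jurisdiction A only)
#'
#' Persons present in the causes-of-death stream must also appear in the
#' death-registration stream; both streams are deterministically linked at
#' source, so any orphan indicates a data-delivery problem. Jurisdiction B
#' delivers a single combined stream and is skipped.
#'
#' @param deaths current deaths view.
#' @param ledger optional ledger; offenders are queued for review.
#' @return character vector of offending PPNs.
#' @export
check_death_registration_completeness <- function(deaths, ledger = NULL) {
  da <- deaths[jurisdiction == "A"]
  if (!nrow(da[stream == "causes_of_death"])) return(character())
  offenders <- setdiff(da[stream == "causes_of_death", ppn],
                       da[stream == "registration", ppn])
  if (length(offenders) && !is.null(ledger)) {
    ledger_review(ledger, "S2.1", offenders,
                  "causes-of-death record without death registration")
  }
  offenders
}

# fields used to adjudicate suspected multiple entries of the same birth
.adjudication_fields <- c(
  "baby_dob", "plurality", "birth_order", "birthweight", "gestational_age",
  "apgar5", "discharge_status", "mother_age", "postcode", "country_of_birth",
  "hospital"
)

# agreement = every field with >=2 non-missing values has them all equal,
# and at least 3 such fields are comparable
.records_agree <- function(rows) {
  comparable <- 0L
  for (f in .adjudication_fields) {
    v <- rows[[f]]
    v <- v[!is.na(v)]
    if (length(v) < 2L) next
    comparable <- comparable + 1L
    if (length(unique(v)) > 1L) return(FALSE)
  }
  comparable >= 3L
}

#' Uniqueness of the baby person number
#'
#' A babyPPN on two or more (non-duplicate) perinatal records signals either
#' a linkage error or a double data entry. Different mothers sharing the
#' babyPPN are all flagged for exclusion. For a single mother, the records
#' are adjudicated over the review fields: agreement keeps one record and
#' flags the rest `duplicate`; disagreement flags the mother for exclusion.
#'
#' @param perinatal current perinatal view (step-1 duplicates removed).
#' @param ledger a [ledger_new()] object.
#' @return data.table of the affected babyPPNs and dispositions.
#' @export
check_baby_ppn_uniqueness <- function(perinatal, ledger) {
  multi <- perinatal[, .N, by = baby_ppn][N >= 2L, baby_ppn]
  out <- list()
  for (b in multi) {
    rows <- perinatal[baby_ppn == b][order(record_id)]
    mums <- unique(rows$mum_ppn)
    if (length(mums) > 1L) {
      ledger_flag(ledger, "person", mums, "exclusion", "S3.3",
                  reason_code = "shared_baby_ppn", detail = b)
      out[[b]] <- data.table(baby_ppn = b, disposition = "mothers_excluded")
    } else if (.records_agree(rows)) {
      ledger_flag(ledger, "record", rows$record_id[-1], "duplicate", "S3.4",
                  reason_code = "baby_double_entry", detail = b)
      out[[b]] <- data.table(baby_ppn = b, disposition = "duplicate_flagged")
    } else {
      ledger_flag(ledger, "person", mums, "exclusion", "S3.4",
                  reason_code = "inconsistent_baby_records", detail = b)
      out[[b]] <- data.table(baby_ppn = b, disposition = "mother_excluded")
    }
  }
  if (length(out)) rbindlist(out) else
    data.table(baby_ppn = character(), disposition = character())
}
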