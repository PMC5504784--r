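# Derived views: the only way ledger decisions reach the data.
#
# Steps are applied before the next step begins, so each step works on a
# view with prior corrections merged in, duplicate/deletion records removed
# and excluded families dropped. The underlying tables are never changed.

#' Merge ledger corrections into a copy of a table
#'
#' The latest correction per (record, field) wins. Values are coerced to the
#' column's class; empty strings become `NA`.
#'
#' @param dt a source table carrying a `record_id` column.
#' @param corrections the ledger's corrections table
#'   ([ledger_corrections()]).
#' @return a corrected copy of `dt`.
#' @export
apply_corrections <- function(dt, corrections) {
  dt <- copy(dt)
  if (!nrow(corrections) || !"record_id" %in% names(dt)) return(dt)
  cor <- corrections[record_id %in% dt$record_id & field %in% names(dt)]
  if (!nrow(cor)) return(dt)
  cor <- cor[, .SD[.N], by = .(record_id, field)]  # latest wins
  for (f in unique(cor$field)) {
    cf <- cor[field == f]
    val <- cf$new_value
    val[val == ""] <- NA
    idx <- match(cf$record_id, dt$record_id)
    cls <- class(dt[[f]])[1]
    newv <- switch(cls,
      Date = as.Date(val), IDate = as.Date(val), integer = as.integer(val),
      numeric = as.numeric(val), logical = as.logical(val), val)
    set(dt, i = idx, j = f, value = newv)
  }
  dt
}

#' Current working view of the cohort under a ledger
#'
#' Applies all corrections, drops records flagged `duplicate` or `deletion`,
#' and drops the records of excluded persons (an excluded mother removes her
#' perinatal records and, through propagation, her children's person
#' records). Mapping tables are returned unfiltered; link status is handled
#' separately by the cross-jurisdiction steps.
#'
#' @param tables named list of source tables.
#' @param ledger a [ledger_new()] object.
#' @return a named list of filtered, corrected copies.
#' @export
active_view <- function(tables, ledger) {
  cors <- ledger$corrections
  excl <- excluded_persons(ledger)
  dropped <- flagged_records(ledger)
  out <- list()
  for (what in names(tables)) {
    dt <- tables[[what]]
    if (what %in% c("mapping", "truth")) { out[[what]] <- copy(dt); next }
    dt <- apply_corrections(dt, cors)
    if ("record_id" %in% names(dt)) dt <- dt[!record_id %in% dropped]
    dt <- switch(what,
      perinatal = dt[!mum_ppn %in% excl & !baby_ppn %in% excl],
      encounters = dt[!ppn %in% excl],
      deaths = dt[!ppn %in% excl],
      congenital = dt[!baby_ppn %in% excl],
      dt)
    out[[what]] <- dt
  }
  out
}

# Date of death per person from the current deaths view. With unresolved
# multiple dates (review-queue cases) the earliest is used.
.death_dates <- function(deaths) {
  if (is.null(deaths) || !nrow(deaths)) {
    return(data.table(ppn = character(), date_of_death = as.Date(character())))
  }
  deaths[, .(date_of_death = min(date_of_death)), by = ppn]
}
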