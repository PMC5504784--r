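# Source-table schemas and delimited-text IO.
#
# One CSV per source, header row, ISO-8601 dates, empty field = missing.
# Missingness is always an explicit NA in memory, never zero: parity 0 is a
# meaningful value (no previous pregnancy of >= 20 weeks).

.table_schemas <- list(
  perinatal = c(
    record_id = "character", jurisdiction = "character",
    mum_ppn = "character", baby_ppn = "character", baby_dob = "Date",
    gestational_age = "integer", birthweight = "integer", parity = "integer",
    plurality = "integer", birth_order = "integer", mother_yob = "integer",
    mother_age = "integer", apgar5 = "integer", discharge_status = "character",
    postcode = "character", country_of_birth = "character",
    hospital = "character"
  ),
  encounters = c(
    record_id = "character", jurisdiction = "character", ppn = "character",
    role = "character", source = "character", admission_date = "Date",
    separation_date = "Date", patient_dob = "Date", patient_yob = "integer",
    patient_age = "integer", patient_sex = "character",
    month_of_birth = "integer", procedure_codes = "character",
    is_delivery = "logical", discharge_status = "character"
  ),
  deaths = c(
    record_id = "character", jurisdiction = "character", ppn = "character",
    date_of_death = "Date", stream = "character"
  ),
  congenital = c(
    record_id = "character", baby_ppn = "character", baby_dob = "Date",
    birthweight = "integer"
  ),
  claims = c(
    claim_id = "character", patid = "character", date_of_supply = "Date",
    item_code = "character", month_of_birth = "integer",
    year_of_birth = "integer"
  ),
  mapping = c(
    patid = "character", mum_ppn = "character", jurisdiction = "character",
    weight = "numeric"
  )
)

.coerce_col <- function(x, type) {
  switch(type,
    Date = as.Date(x),
    integer = as.integer(x),
    numeric = as.numeric(x),
    logical = as.logical(x),
    character = as.character(x)
  )
}

#' Build and validate a source table
#'
#' Coerces a data frame to the canonical schema for one of the six source
#' tables and checks the structural invariants (required columns, unique
#' record ids, value ranges such as `plurality >= 1`).
#'
#' @param df a data frame with at least the schema's columns.
#' @param what one of `"perinatal"`, `"encounters"`, `"deaths"`,
#'   `"congenital"`, `"claims"`, `"mapping"`.
#' @return a `data.table` with columns in schema order and types coerced.
#' @export
as_source_table <- function(df, what) {
  what <- match.arg(what, names(.table_schemas))
  schema <- .table_schemas[[what]]
  dt <- as.data.table(df)
  missing_cols <- setdiff(names(schema), names(dt))
  if (length(missing_cols)) {
    stop(sprintf("%s table is missing columns: %s", what,
                 paste(missing_cols, collapse = ", ")))
  }
  dt <- dt[, names(schema), with = FALSE]
  for (nm in names(schema)) set(dt, j = nm, value = .coerce_col(dt[[nm]], schema[[nm]]))
  validate_source_table(dt, what)
  dt[]
}

#' @rdname as_source_table
#' @param dt a table already in schema order.
#' @export
validate_source_table <- function(dt, what) {
  what <- match.arg(what, names(.table_schemas))
  idcol <- if (what == "claims") "claim_id" else if (what == "mapping") NULL else "record_id"
  if (!is.null(idcol)) {
    if (anyNA(dt[[idcol]])) stop(sprintf("%s: missing %s", what, idcol))
    if (anyDuplicated(dt[[idcol]])) stop(sprintf("%s: duplicated %s", what, idcol))
  }
  if (what == "perinatal" && nrow(dt)) {
    if (any(dt$plurality < 1L, na.rm = TRUE)) stop("perinatal: plurality must be >= 1")
    if (any(dt$birth_order < 1L, na.rm = TRUE)) stop("perinatal: birth_order must be >= 1")
    if (any(dt$parity < 0L, na.rm = TRUE)) stop("perinatal: parity must be >= 0")
    if (!all(dt$jurisdiction %in% c("A", "B"))) stop("perinatal: jurisdiction must be A or B")
  }
  if (what == "encounters" && nrow(dt)) {
    if (!all(dt$role %in% c("mother", "baby"))) stop("encounters: bad role")
    if (!all(dt$source %in% c("hospital", "ed"))) stop("encounters: bad source")
    bad <- !is.na(dt$patient_dob) & !is.na(dt$patient_yob) &
      dt$patient_yob != as.integer(format(dt$patient_dob, "%Y"))
    if (any(bad)) stop("encounters: patient_yob must equal year of patient_dob")
  }
  if (what == "deaths" && nrow(dt) && anyNA(dt$date_of_death)) {
    stop("deaths: date_of_death must be present")
  }
  if (what == "mapping" && nrow(dt)) {
    if (any(!is.finite(dt$weight))) stop("mapping: weight must be finite")
    if (anyDuplicated(dt[, .(patid, mum_ppn)])) stop("mapping: duplicated (patid, mum_ppn)")
    if (!all(dt$jurisdiction %in% c("A", "B"))) stop("mapping: jurisdiction must be A or B")
  }
  invisible(dt)
}

#' Read or write a full cohort of source tables
#'
#' A cohort on disk is a directory of CSV files named `perinatal.csv`,
#' `encounters.csv`, `deaths.csv`, `congenital.csv`, `claims.csv` and
#' `mapping.csv` (any may be absent except perinatal); dates are ISO-8601
#' and missing values are empty fields.
#'
#' @param dir directory path.
#' @return `read_cohort()`: a named list of validated `data.table`s.
#' @export
read_cohort <- function(dir) {
  out <- list()
  for (what in names(.table_schemas)) {
    path <- file.path(dir, paste0(what, ".csv"))
    if (!file.exists(path)) next
    dt <- fread(path, colClasses = "character", na.strings = "")
    out[[what]] <- as_source_table(dt, what)
  }
  if (is.null(out$perinatal)) stop("cohort has no perinatal.csv")
  path <- file.path(dir, "truth.csv")
  if (file.exists(path)) out$truth <- fread(path, na.strings = "")
  out
}

#' @rdname read_cohort
#' @param tables named list of source tables (e.g. from
#'   [generate_clean_cohort()]).
#' @return `write_cohort()`: the directory, invisibly.
#' @export
write_cohort <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (what in intersect(names(tables), c(names(.table_schemas), "truth"))) {
    fwrite(tables[[what]], file.path(dir, paste0(what, ".csv")), dateTimeAs = "ISO")
  }
  invisible(dir)
}
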