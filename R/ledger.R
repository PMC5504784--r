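# Append-only flag ledger.
#
# The protocol never deletes records or overwrites values: every decision is
# an appended flag, correction or review-queue entry carrying the step that
# produced it. The ledger is an environment so the step functions can append
# by reference while the source tables stay untouched; consumers derive
# filtered views with active_view().

.valid_flags <- list(
  person = "exclusion",
  record = c("duplicate", "deletion"),
  link   = "disregard_link"
)

#' Create an empty flag ledger
#'
#' The ledger accumulates person-level `exclusion` flags, record-level
#' `duplicate`/`deletion` flags, link-level `disregard_link` flags, field
#' corrections and manual-review queue entries. It is append-only: entries
#' are never edited or removed, and identical entries are appended once.
#'
#' @return An object of class `perilink_ledger`.
#' @seealso [ledger_flag()], [ledger_correct()], [ledger_review()],
#'   [active_view()]
#' @export
ledger_new <- function() {
  lg <- new.env(parent = emptyenv())
  lg$entries <- data.table(
    scope = character(), target_id = character(), flag = character(),
    step_id = character(), reason_code = character(), detail = character()
  )
  lg$corrections <- data.table(
    record_id = character(), field = character(), old_value = character(),
    new_value = character(), step_id = character()
  )
  lg$review <- data.table(
    queue_id = character(), step_id = character(), target_ids = character(),
    evidence = character()
  )
  class(lg) <- c("perilink_ledger", "environment")
  lg
}

#' Append a flag to the ledger
#'
#' @param ledger a [ledger_new()] object, modified by reference.
#' @param scope `"person"`, `"record"` or `"link"`.
#' @param target_id the flagged person/record identifier (for links,
#'   `"patid|mum_ppn"`).
#' @param flag flag kind; must be valid for the scope (`exclusion` only at
#'   person scope, `duplicate`/`deletion` only at record scope,
#'   `disregard_link` only at link scope).
#' @param step_id protocol step that produced the flag, e.g. `"S6.4"`.
#' @param reason_code,detail short machine/human readable context.
#' @return the ledger, invisibly. Appending an entry identical to an
#'   existing one (same scope, target, flag and step) is a no-op.
#' @export
ledger_flag <- function(ledger, scope, target_id, flag, step_id,
                        reason_code = "", detail = "") {
  stopifnot(inherits(ledger, "perilink_ledger"))
  scope <- match.arg(scope, names(.valid_flags))
  if (!flag %in% .valid_flags[[scope]]) {
    stop(sprintf("flag '%s' is not valid at %s scope", flag, scope))
  }
  n <- length(target_id)
  new <- data.table(
    scope = rep(scope, n), target_id = as.character(target_id),
    flag = rep(flag, n), step_id = rep(step_id, n),
    reason_code = rep_len(as.character(reason_code), n),
    detail = rep_len(as.character(detail), n)
  )
  key <- c("scope", "target_id", "flag", "step_id")
  new <- unique(new, by = key)
  if (nrow(ledger$entries)) {
    existing <- ledger$entries[, paste(scope, target_id, flag, step_id, sep = "\r")]
    new <- new[!paste(scope, target_id, flag, step_id, sep = "\r") %in% existing]
  }
  if (nrow(new)) ledger$entries <- rbind(ledger$entries, new)
  invisible(ledger)
}

#' Record a field correction
#'
#' Corrections do not overwrite source tables; [apply_corrections()] merges
#' them into derived views. Re-recording an identical correction is a no-op,
#' so replaying a step over corrected views leaves the ledger unchanged.
#'
#' @param ledger a [ledger_new()] object.
#' @param record_id record the correction applies to.
#' @param field column name.
#' @param old_value,new_value values as character (coerced on application).
#' @param step_id protocol step that produced the correction.
#' @return the ledger, invisibly.
#' @export
ledger_correct <- function(ledger, record_id, field, old_value, new_value,
                           step_id) {
  stopifnot(inherits(ledger, "perilink_ledger"))
  n <- length(record_id)
  new <- data.table(
    record_id = as.character(record_id), field = rep_len(field, n),
    old_value = rep_len(ifelse(is.na(old_value), "", as.character(old_value)), n),
    new_value = rep_len(ifelse(is.na(new_value), "", as.character(new_value)), n),
    step_id = rep_len(step_id, n)
  )
  new <- unique(new)
  if (nrow(ledger$corrections)) {
    existing <- do.call(paste, c(ledger$corrections, sep = "\r"))
    new <- new[!do.call(paste, c(new, sep = "\r")) %in% existing]
  }
  if (nrow(new)) ledger$corrections <- rbind(ledger$corrections, new)
  invisible(ledger)
}

#' Add an entry to the manual review queue
#'
#' Used where the protocol called for on-screen scrutiny and the automated
#' adjudication rules decline to decide; queued cases receive no flag.
#'
#' @param ledger a [ledger_new()] object.
#' @param step_id protocol step raising the case.
#' @param target_ids identifiers involved, `";"`-separated.
#' @param evidence short free-text summary for the reviewer.
#' @return the ledger, invisibly.
#' @export
ledger_review <- function(ledger, step_id, target_ids, evidence = "") {
  stopifnot(inherits(ledger, "perilink_ledger"))
  new <- data.table(
    queue_id = "", step_id = step_id, target_ids = as.character(target_ids),
    evidence = rep_len(as.character(evidence), length(target_ids))
  )
  if (nrow(ledger$review)) {
    existing <- ledger$review[, paste(step_id, target_ids, sep = "\r")]
    new <- new[!paste(step_id, target_ids, sep = "\r") %in% existing]
  }
  if (nrow(new)) {
    new$queue_id <- sprintf("Q%05d", nrow(ledger$review) + seq_len(nrow(new)))
    ledger$review <- rbind(ledger$review, new)
  }
  invisible(ledger)
}

#' @rdname ledger_accessors
#' @export
ledger_entries <- function(ledger) copy(ledger$entries)

#' Read the ledger contents
#'
#' @param ledger a [ledger_new()] object.
#' @return Copies of the flag entries, corrections and review queue as
#'   `data.table`s (the ledger itself cannot be edited through them).
#' @name ledger_accessors
#' @export
ledger_corrections <- function(ledger) copy(ledger$corrections)

#' @rdname ledger_accessors
#' @export
ledger_review_queue <- function(ledger) copy(ledger$review)

#' Person identifiers currently flagged for exclusion
#' @param ledger a [ledger_new()] object.
#' @return character vector of PPNs.
#' @export
excluded_persons <- function(ledger) {
  unique(ledger$entries[scope == "person" & flag == "exclusion", target_id])
}

#' Record identifiers currently flagged duplicate or deletion
#' @param ledger a [ledger_new()] object.
#' @return character vector of record ids.
#' @export
flagged_records <- function(ledger) {
  unique(ledger$entries[scope == "record", target_id])
}

#' Export ledger, corrections and review queue as CSV
#'
#' @param ledger a [ledger_new()] object.
#' @param dir output directory (created if needed). Writes `ledger.csv`,
#'   `corrections.csv` and `review_queue.csv`.
#' @return the paths written, invisibly.
#' @export
ledger_export <- function(ledger, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("ledger.csv", "corrections.csv", "review_queue.csv"))
  fwrite(ledger$entries, paths[1])
  fwrite(ledger$corrections, paths[2])
  fwrite(ledger$review, paths[3])
  invisible(paths)
}

#' Propagate exclusion flags between mothers and their children
#'
#' A person-level inconsistency found for a child implicates the link for the
#' whole family: the mother, and records for all of her children, are flagged
#' for exclusion. Run after every person-level step; idempotent.
#'
#' @param ledger a [ledger_new()] object.
#' @param perinatal the perinatal table (defines the mother-child map).
#' @return the ledger, invisibly.
#' @export
propagate_exclusions <- function(ledger, perinatal) {
  repeat {
    excl <- excluded_persons(ledger)
    if (!length(excl)) return(invisible(ledger))
    src <- ledger$entries[scope == "person" & flag == "exclusion"]
    step_of <- src[, setNames(step_id, target_id)]
    # children excluded -> mother
    kid <- perinatal[baby_ppn %in% excl & !mum_ppn %in% excl,
                     .(mum_ppn, via = baby_ppn)]
    # mother excluded -> all her children
    mum <- perinatal[mum_ppn %in% excl & !baby_ppn %in% excl,
                     .(baby_ppn, via = mum_ppn)]
    if (!nrow(kid) && !nrow(mum)) return(invisible(ledger))
    if (nrow(kid)) {
      kid <- unique(kid, by = "mum_ppn")
      ledger_flag(ledger, "person", kid$mum_ppn, "exclusion",
                  step_id = unname(step_of[kid$via]),
                  reason_code = "propagated_from_child", detail = kid$via)
    }
    if (nrow(mum)) {
      mum <- unique(mum, by = "baby_ppn")
      ledger_flag(ledger, "person", mum$baby_ppn, "exclusion",
                  step_id = unname(step_of[mum$via]),
                  reason_code = "propagated_from_mother", detail = mum$via)
    }
  }
}
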