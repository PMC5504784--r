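# Pipeline: steps 1-22 in protocol order, each step applied before the next.

#' Pipeline configuration
#'
#' All protocol constants in one place, defaulting to the recommended
#' values: acceptance weight thresholds 29 (jurisdiction A) and 28 (B),
#' valid patient year-of-birth window 1920-2014 for babies and 1900-2014
#' for mothers, the 20-week (140-day) DOB gap bound, the 40-week (280-day)
#' pregnancy-interval bound used by parity imputation, and a 3-day
#' allowance for death-registration delay.
#'
#' @param weight_thresholds named per-jurisdiction link acceptance
#'   thresholds.
#' @param baby_yob_valid,mother_yob_valid hard validity windows for
#'   recorded years of birth.
#' @param gap_days,interval_days,death_allowance_days day-granular
#'   constants (20 weeks, 40 weeks, administrative delay).
#' @param hysterectomy_codes procedure codes identifying a total
#'   hysterectomy (empty vector skips step 13).
#' @param steps integer vector of enabled steps (1-22). Dependencies
#'   between steps are enforced at run time.
#' @return a `perilink_config` list.
#' @export
pipeline_config <- function(weight_thresholds = c(A = 29, B = 28),
                            baby_yob_valid = c(1920L, 2014L),
                            mother_yob_valid = c(1900L, 2014L),
                            gap_days = 140L,
                            interval_days = 280L,
                            death_allowance_days = 3L,
                            hysterectomy_codes = c("3565300", "3565301", "3565800"),
                            steps = 1:22) {
  structure(list(
    weight_thresholds = weight_thresholds,
    baby_yob_valid = as.integer(baby_yob_valid),
    mother_yob_valid = as.integer(mother_yob_valid),
    gap_days = as.integer(gap_days),
    interval_days = as.integer(interval_days),
    death_allowance_days = as.integer(death_allowance_days),
    hysterectomy_codes = hysterectomy_codes,
    steps = as.integer(steps)
  ), class = "perilink_config")
}

#' Read a hysterectomy procedure-code list
#'
#' Plain text, one code per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return character vector of codes.
#' @export
read_procedure_codes <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[x != "" & !startsWith(x, "#")]
}

.step_deps <- list(
  `3` = 1L, `7` = c(5L, 6L), `8` = 7L, `14` = 9L,
  `19` = 17L, `20` = c(17L, 19L), `21` = c(19L, 20L), `22` = 21L
)

#' Run the full 22-step cleaning pipeline
#'
#' Executes the enabled steps in protocol order. Every step works on a
#' view with all earlier decisions applied (corrections merged, flagged
#' records and excluded families removed); exclusion flags are propagated
#' between mothers and children after each person-level step. Data
#' inconsistencies are findings, never failures: the pipeline always
#' completes on schema-valid input.
#'
#' @param tables named list of source tables (see [read_cohort()] /
#'   [generate_clean_cohort()]). `perinatal` is required; steps whose
#'   tables are absent are skipped with a warning.
#' @param config a [pipeline_config()].
#' @return object of class `perilink_result`: the ledger, per-step
#'   reports, the identity `resolution` (finalPPNmum per mumPPN), the link
#'   table with statuses, cluster and cross-state decisions, the parity
#'   assessment, and the final claims extract.
#' @export
run_pipeline <- function(tables, config = pipeline_config()) {
  stopifnot(!is.null(tables$perinatal))
  for (what in intersect(names(tables), c("perinatal", "encounters", "deaths",
                                          "congenital", "claims", "mapping"))) {
    validate_source_table(tables[[what]], what)
  }
  steps <- config$steps
  for (s in steps) {
    need <- .step_deps[[as.character(s)]]
    miss <- setdiff(need, steps)
    if (length(miss)) {
      stop(sprintf("step %d requires step(s) %s to be enabled", s,
                   paste(miss, collapse = ", ")))
    }
  }
  lg <- ledger_new()
  reports <- list()
  extras <- list()
  has <- function(what) !is.null(tables[[what]]) && nrow(tables[[what]]) >= 0L
  t_total <- proc.time()[["elapsed"]]

  run_step <- function(id, fun, required = character()) {
    if (!id %in% steps) return(invisible(NULL))
    absent <- required[!vapply(required, has, logical(1))]
    if (length(absent)) {
      warning(sprintf("step %d skipped: missing table(s) %s", id,
                      paste(absent, collapse = ", ")), call. = FALSE)
      return(invisible(NULL))
    }
    n0 <- nrow(lg$entries); c0 <- nrow(lg$corrections); r0 <- nrow(lg$review)
    t0 <- proc.time()[["elapsed"]]
    v <- active_view(tables, lg)
    fun(v)
    propagate_exclusions(lg, tables$perinatal)
    added <- lg$entries[seq_len(nrow(lg$entries)) > n0]
    reports[[length(reports) + 1L]] <<- data.table(
      step = id,
      n_exclusion = sum(added$flag == "exclusion"),
      n_duplicate = sum(added$flag == "duplicate"),
      n_deletion = sum(added$flag == "deletion"),
      n_disregard = sum(added$flag == "disregard_link"),
      n_corrections = nrow(lg$corrections) - c0,
      n_review = nrow(lg$review) - r0,
      runtime = round(proc.time()[["elapsed"]] - t0, 3)
    )
  }

  run_step(1L, function(v) {
    find_identical_duplicates(v$perinatal, lg, "S1.1")
    if (has("encounters")) find_identical_duplicates(v$encounters, lg, "S1.1")
    if (has("deaths") && nrow(v$deaths)) {
      find_identical_duplicates(v$deaths, lg, "S1.1")
      v2 <- active_view(tables, lg)
      find_partial_death_duplicates(v2$deaths, v2$encounters, lg)
    }
  })
  run_step(2L, function(v) {
    extras$completeness <<- check_death_registration_completeness(v$deaths, lg)
  }, "deaths")
  run_step(3L, function(v) check_baby_ppn_uniqueness(v$perinatal, lg))
  run_step(4L, function(v) {
    extras$birthweight_gestation <<- tabulate_birthweight_gestation(v$perinatal)
  })
  run_step(5L, function(v) validate_birth_order(v$perinatal, v$encounters, lg),
           "encounters")
  run_step(6L, function(v) check_pregnancy_intervals(v$perinatal, lg))
  run_step(7L, function(v) impute_missing_parity(v$perinatal, lg, config$interval_days))
  run_step(8L, function(v) {
    extras$parity_assessment <<- assess_parity_consistency(v$perinatal, lg)
  })
  run_step(9L, function(v) {
    extras$dob_reconciliation <<- reconcile_baby_dob(
      v$perinatal, v$encounters, lg, config$baby_yob_valid, config$gap_days)
  }, "encounters")
  run_step(10L, function(v) {
    if (!is.null(v$congenital) && nrow(v$congenital)) {
      check_congenital_consistency(v$perinatal, v$congenital, lg)
    }
  }, "congenital")
  run_step(11L, function(v) check_mother_yob(v$perinatal, v$encounters, lg,
                                             config$mother_yob_valid), "encounters")
  run_step(12L, function(v) check_mother_sex(v$perinatal, v$encounters, lg,
                                             config$mother_yob_valid), "encounters")
  run_step(13L, function(v) check_birth_after_hysterectomy(
    v$perinatal, v$encounters, config$hysterectomy_codes, lg), "encounters")
  run_step(14L, function(v) check_dob_after_discharge(v$perinatal, v$encounters,
                                                      lg, config$gap_days),
           "encounters")
  run_step(15L, function(v) check_service_after_death(
    v$perinatal, v$encounters, v$deaths, lg, config$death_allowance_days), "deaths")
  run_step(16L, function(v) check_admission_after_discharge(v$encounters, lg),
           "encounters")

  # cross-jurisdiction integration
  links <- NULL; clusters <- NULL
  cluster_decisions <- NULL; cross <- NULL
  if (has("mapping") && nrow(tables$mapping) && any(17:22 %in% steps)) {
    links <- extract_recommended_links(tables$mapping, config$weight_thresholds)
    run_step(17L, function(v) {
      r <- detect_patid_clusters(links, v, lg)
      links <<- r$links; clusters <<- r$clusters
    })
    run_step(18L, function(v) {
      links <<- check_supply_after_death(links, tables$claims, v$deaths, lg)
    }, c("claims", "deaths"))
    run_step(19L, function(v) {
      r <- validate_clusters(clusters, links, v, lg)
      links <<- r$links; cluster_decisions <<- r$decisions
    })
    run_step(20L, function(v) {
      r <- resolve_cross_state(links, v, lg)
      links <<- r$links; cross <<- r
    })
  }
  resolution <- NULL
  if (21L %in% steps) {
    all_ppns <- unique(c(tables$perinatal$mum_ppn,
                         if (!is.null(links)) links$mum_ppn))
    acc_clusters <- if (!is.null(clusters) && nrow(clusters) &&
                        !is.null(cluster_decisions)) {
      clusters[cluster_id %in% cluster_decisions[status == "accepted", cluster_id]]
    } else data.table(cluster_id = character(), patid = character(),
                      jurisdiction = character(), mum_ppn = character())
    xassign <- if (!is.null(cross)) cross$assignments else
      data.table(mum_ppn = character(), cross_id = character())
    resolution <- integrate_final_ppn(all_ppns, acc_clusters, xassign)
    resolution[, excluded := mum_ppn %in% excluded_persons(lg)]
  }
  claims_extract <- NULL; multi_patid <- NULL
  if (22L %in% steps && !is.null(links) && !is.null(resolution) && has("claims")) {
    run_step(22L, function(v) {
      r <- check_multi_patid(links, resolution, tables$claims, v, lg)
      links <<- r$links; multi_patid <<- r$multi_patid
      claims_extract <<- r$claims_extract
    })
    # refresh the exclusion column after step 22 flags
    resolution[, excluded := mum_ppn %in% excluded_persons(lg)]
  }

  structure(list(
    ledger = lg,
    reports = if (length(reports)) rbindlist(reports) else data.table(),
    resolution = resolution,
    links = links,
    cluster_decisions = cluster_decisions,
    cross_decisions = if (!is.null(cross)) cross$decisions else NULL,
    parity_assessment = extras$parity_assessment,
    dob_reconciliation = extras$dob_reconciliation,
    birthweight_gestation = extras$birthweight_gestation,
    multi_patid = multi_patid,
    claims_extract = claims_extract,
    config = config,
    runtime = round(proc.time()[["elapsed"]] - t_total, 3)
  ), class = "perilink_result")
}

#' Per-step summary of a pipeline run
#'
#' Tallies ledger entries by the fine-grained step that produced them,
#' reconciling with the ledger exactly (the report is a group-by of the
#' ledger, not a separate count).
#'
#' @param result a [run_pipeline()] result.
#' @return `data.table` with one row per (step_id, flag) plus correction
#'   and review counts.
#' @export
summarize_pipeline <- function(result) {
  lg <- result$ledger
  count_by <- function(dt, kind) {
    if (!nrow(dt)) return(data.table(step_id = character(), kind = character(),
                                     n = integer()))
    out <- dt[, .(n = .N), by = "step_id"]
    out[, kind := kind]
    out[, .(step_id, kind, n)]
  }
  parts <- list(
    if (nrow(lg$entries)) lg$entries[, .(n = .N), by = .(step_id, kind = flag)],
    count_by(lg$corrections, "correction"),
    count_by(lg$review, "review")
  )
  s <- rbindlist(parts, use.names = TRUE)
  if (!nrow(s)) return(data.table(step_id = character(), kind = character(),
                                  n = integer()))
  setorder(s, step_id, kind)
  s[]
}

#' @export
print.perilink_result <- function(x, ...) {
  cat("perilink pipeline result\n")
  cat(sprintf("  flags: %d (%d exclusion, %d duplicate, %d deletion, %d link)\n",
              nrow(x$ledger$entries),
              sum(x$ledger$entries$flag == "exclusion"),
              sum(x$ledger$entries$flag == "duplicate"),
              sum(x$ledger$entries$flag == "deletion"),
              sum(x$ledger$entries$flag == "disregard_link")))
  cat(sprintf("  corrections: %d, review queue: %d\n",
              nrow(x$ledger$corrections), nrow(x$ledger$review)))
  if (!is.null(x$resolution)) {
    cat(sprintf("  mothers: %d mumPPNs -> %d finalPPNmums (%d excluded)\n",
                nrow(x$resolution), uniqueN(x$resolution$final_ppn),
                sum(x$resolution$excluded)))
  }
  invisible(x)
}

#' Post-integration tables for downstream analysis
#'
#' Applies every ledger decision: corrections merged, flagged records and
#' excluded families dropped, mother identifiers replaced by finalPPNmum,
#' and only accepted links kept (collapsed per (patid, finalPPNmum),
#' keeping the highest weight). Re-running the pipeline on these tables is
#' a fixed point: no new flags and an identity resolution map.
#'
#' @param tables the original source tables.
#' @param result a [run_pipeline()] result.
#' @return named list of integrated tables.
#' @export
finalize_tables <- function(tables, result) {
  v <- active_view(tables, result$ledger)
  res <- result$resolution
  if (!is.null(res)) {
    fmap <- setNames(res$final_ppn, res$mum_ppn)
    sub <- function(x) fifelse(x %in% names(fmap), fmap[x], x)
    v$perinatal[, mum_ppn := sub(mum_ppn)]
    v$encounters[role == "mother", ppn := sub(ppn)]
    v$deaths[, ppn := sub(ppn)]
    if (!is.null(result$links)) {
      lk <- result$links[status == "accepted"]
      lk[, mum_ppn := sub(mum_ppn)]
      setorder(lk, patid, mum_ppn, -weight)
      lk <- unique(lk, by = c("patid", "mum_ppn"))
      v$mapping <- lk[, .(patid, mum_ppn, jurisdiction, weight)]
    }
  }
  v$truth <- NULL
  v
}
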