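# Labelled error injection.
#
# Each error class mirrors one finding category of the protocol. Every
# injected instance touches one (or two, for linkage-error classes) family
# that no other injection touches, and is recorded in a ground-truth table
# with the flag and step the pipeline is expected to produce. Deterministic
# classes are constructed so that recovery is exact; review-adjudicated
# classes are constructed so the case lands either in a flag or in the
# review queue.

.error_classes <- c(
  "identical_duplicate", "partial_death_duplicate",
  "shared_baby_ppn_across_mothers", "baby_ppn_double_entry",
  "implausible_birth_order", "negative_interval_false_link",
  "missing_parity", "parity_typo", "parity_illogical_false_link",
  "dob_typo_in_perinatal", "dob_typo_in_encounter", "congenital_mismatch",
  "yob_out_of_range", "sex_male_with_yob_conflict",
  "birth_after_hysterectomy", "dob_after_separation", "service_after_death",
  "admission_after_separation", "patid_split_across_ppns",
  "patid_merging_two_women", "supply_after_death",
  "multi_patid_per_mother_inconsistent"
)

#' Error-injection plan
#'
#' Per-class instance counts for [inject_errors()]. Classes not named get
#' zero instances.
#'
#' @param ... named integer counts; names must be error classes (see
#'   `perilink:::.error_classes`).
#' @param seed seed for the injection stream, independent of the cohort
#'   seed so the clean data is reproducible under varying plans.
#' @param hysterectomy_code procedure code written by the
#'   `birth_after_hysterectomy` class; must be present in the pipeline's
#'   configured code list.
#' @return a `perilink_error_plan` list of counts.
#' @export
error_plan <- function(..., seed = 100L, hysterectomy_code = "3565300") {
  counts <- list(...)
  if (length(counts) && (is.null(names(counts)) || any(names(counts) == ""))) {
    stop("all counts must be named")
  }
  bad <- setdiff(names(counts), .error_classes)
  if (length(bad)) stop("unknown error classes: ", paste(bad, collapse = ", "))
  plan <- setNames(rep(0L, length(.error_classes)), .error_classes)
  for (nm in names(counts)) plan[nm] <- as.integer(counts[[nm]])
  if (any(plan < 0L)) stop("counts must be non-negative")
  structure(list(counts = plan, seed = as.integer(seed),
                 hysterectomy_code = hysterectomy_code),
            class = "perilink_error_plan")
}

#' @rdname error_plan
#' @param n_per_class count applied to every error class.
#' @export
default_error_plan <- function(n_per_class = 5L, seed = 100L) {
  do.call(error_plan, c(as.list(setNames(rep(n_per_class, length(.error_classes)),
                                         .error_classes)),
                        list(seed = seed)))
}

.add_months <- function(d, k) {
  # day-preserving month shift; callers guarantee mday <= 28
  y <- as.integer(format(d, "%Y")); m <- as.integer(format(d, "%m"))
  dd <- as.integer(format(d, "%d"))
  m2 <- m + k; y2 <- y + (m2 - 1L) %/% 12L; m2 <- (m2 - 1L) %% 12L + 1L
  as.Date(sprintf("%d-%02d-%02d", y2, m2, dd))
}

#' Inject labelled errors into a clean cohort
#'
#' Returns corrupted copies of the tables plus a ground-truth table mapping
#' each injected instance to the flag and step the pipeline is expected to
#' produce. Inputs are not modified. An infeasible plan (more instances
#' than eligible untouched families) is rejected.
#'
#' @param tables a cohort from [generate_clean_cohort()] (the `meta`
#'   element is required).
#' @param plan an [error_plan()].
#' @return named list of corrupted tables with a populated `truth` table.
#' @export
inject_errors <- function(tables, plan = default_error_plan()) {
  stopifnot(inherits(plan, "perilink_error_plan"))
  if (is.null(tables$meta)) stop("tables must carry the generator's meta element")
  .with_seed(plan$seed, .inject_impl(tables, plan))
}

.inject_impl <- function(tables, plan) {
  tb <- new.env(parent = emptyenv())
  tb$per <- copy(tables$perinatal)
  tb$enc <- copy(tables$encounters)
  tb$dea <- copy(tables$deaths)
  tb$con <- copy(tables$congenital)
  tb$clm <- copy(tables$claims)
  tb$map <- copy(tables$mapping)
  truth <- list()
  serial <- new.env(parent = emptyenv()); serial$n <- 0L
  zid <- function(prefix) {
    serial$n <- serial$n + 1L
    sprintf("%s-Z%05d", prefix, serial$n)
  }
  note <- function(class, type, id, mum, flag, step) {
    truth[[length(truth) + 1L]] <<- data.table(
      error_class = class, target_type = type, target_id = id,
      mum_ppn = mum, expected_flag = flag, expected_step = step)
  }

  meta <- copy(tables$meta)
  # per-mother summary of the clean cohort, one row per mumPPN
  moms <- tb$per[birth_order == 1L,
                 .(n_preg = .N, first_dob = min(baby_dob), last_dob = max(baby_dob),
                   max_parity = max(parity)),
                 by = .(mum_ppn, jurisdiction)]
  moms <- merge(moms, tb$per[, .(mother_yob = mother_yob[1]), by = mum_ppn],
                by = "mum_ppn")
  sing_mums <- unique(tb$per[plurality == 1L, mum_ppn])
  moms[, has_singleton := mum_ppn %in% sing_mums]
  cross_ppns <- unlist(strsplit(meta[cross == TRUE, ppns], ";"))
  dead_mums <- tb$dea[ppn %in% moms$mum_ppn, ppn]
  moms[, eligible := !mum_ppn %in% cross_ppns & !mum_ppn %in% dead_mums]
  wmap <- meta[, .(woman_id, patid, yob, mob, home)]
  moms[, woman_id := as.integer(sub(".*-M", "", mum_ppn))]
  moms <- merge(moms, wmap, by = "woman_id")

  take <- function(n, filter = rep(TRUE, nrow(moms))) {
    cand <- moms[eligible & filter]
    if (nrow(cand) < n) {
      stop(sprintf("infeasible plan: %d eligible mothers available, %d required", nrow(cand), n))
    }
    picked <- cand[sample(.N, n)]
    moms[mum_ppn %in% picked$mum_ppn, eligible := FALSE]
    picked
  }
  cnt <- plan$counts

  # -- S1.1: identical duplicates (alternating perinatal / encounter rows) --
  if (cnt["identical_duplicate"] > 0L) {
    n <- cnt["identical_duplicate"]
    picked <- take(n)
    for (i in seq_len(n)) {
      m <- picked$mum_ppn[i]
      if (i %% 2L == 1L) {
        row <- tb$per[mum_ppn == m][1]
        row[, record_id := paste0(record_id, "-Z1")]
        tb$per <- rbind(tb$per, row)
      } else {
        row <- tb$enc[ppn == m][1]
        row[, record_id := paste0(record_id, "-Z1")]
        tb$enc <- rbind(tb$enc, row)
      }
      note("identical_duplicate", "record", row$record_id, m, "duplicate", "S1.1")
    }
  }

  # -- S1.2: partial duplicates of a death ---------------------------------
  if (cnt["partial_death_duplicate"] > 0L) {
    n <- cnt["partial_death_duplicate"]
    dead_babies <- tb$dea[ppn %like% "-B"]$ppn
    bk <- tb$per[baby_ppn %in% dead_babies, .(baby_ppn, mum_ppn)]
    bk <- bk[mum_ppn %in% moms[eligible == TRUE, mum_ppn]]
    n_res <- min(n, nrow(bk))
    if (n_res) {
      bk <- bk[sample(.N, n_res)]
      moms[mum_ppn %in% bk$mum_ppn, eligible := FALSE]
      for (i in seq_len(n_res)) {
        b <- bk$baby_ppn[i]
        true_dod <- tb$dea[ppn == b, date_of_death][1]
        jur <- tb$dea[ppn == b, jurisdiction][1]
        rid <- zid("D")
        tb$dea <- rbind(tb$dea, data.table(
          record_id = rid, jurisdiction = jur, ppn = b,
          date_of_death = true_dod + sample(5:30, 1L), stream = "registration"))
        note("partial_death_duplicate", "record", rid, bk$mum_ppn[i],
             "duplicate", "S1.2")
      }
    }
    # remainder: no discharge evidence -> unresolvable, review queue only
    n_rev <- n - n_res
    if (n_rev > 0L) {
      picked <- take(n_rev)
      for (i in seq_len(n_rev)) {
        m <- picked$mum_ppn[i]
        kid <- tb$per[mum_ppn == m & !baby_ppn %in% tb$dea$ppn][1]
        last_sep <- max(tb$enc[ppn == kid$baby_ppn, separation_date], kid$baby_dob)
        for (off in c(10L, 40L)) {
          tb$dea <- rbind(tb$dea, data.table(
            record_id = zid("D"), jurisdiction = kid$jurisdiction,
            ppn = kid$baby_ppn, date_of_death = last_sep + off,
            stream = "registration"))
        }
        note("partial_death_duplicate", "person", kid$baby_ppn, m, "review", "S1.2")
      }
    }
  }

  # -- S3.3: one babyPPN shared by two different mothers -------------------
  if (cnt["shared_baby_ppn_across_mothers"] > 0L) {
    n <- cnt["shared_baby_ppn_across_mothers"]
    picked <- take(2L * n)
    for (i in seq_len(n)) {
      m1 <- picked$mum_ppn[2L * i - 1L]; m2 <- picked$mum_ppn[2L * i]
      donor <- tb$per[mum_ppn == m1][1, baby_ppn]
      victim <- tb$per[mum_ppn == m2][1, record_id]
      tb$per[record_id == victim, baby_ppn := donor]
      note("shared_baby_ppn_across_mothers", "person", m1, m1, "exclusion", "S3.3")
      note("shared_baby_ppn_across_mothers", "person", m2, m2, "exclusion", "S3.3")
    }
  }

  # -- S3.4: double entry of the same baby under one mother ----------------
  if (cnt["baby_ppn_double_entry"] > 0L) {
    n <- cnt["baby_ppn_double_entry"]
    picked <- take(n)
    for (i in seq_len(n)) {
      m <- picked$mum_ppn[i]
      row <- tb$per[mum_ppn == m][1]
      row[, record_id := paste0(record_id, "-Z2")]
      row[, parity := NA_integer_]  # differs somewhere, so not an S1 duplicate
      if (i %% 2L == 1L) {
        tb$per <- rbind(tb$per, row)
        note("baby_ppn_double_entry", "record", row$record_id, m, "duplicate", "S3.4")
      } else {
        row[, baby_dob := baby_dob + 100L]
        row[, birthweight := birthweight + 400L]
        tb$per <- rbind(tb$per, row)
        note("baby_ppn_double_entry", "person", m, m, "exclusion", "S3.4")
      }
    }
  }

  # -- S5.1: singleton recorded with birth order 2 -------------------------
  if (cnt["implausible_birth_order"] > 0L) {
    n <- cnt["implausible_birth_order"]
    picked <- take(n, moms$has_singleton)
    for (i in seq_len(n)) {
      rid <- tb$per[mum_ppn == picked$mum_ppn[i] & plurality == 1L][1, record_id]
      tb$per[record_id == rid, birth_order := 2L]
      note("implausible_birth_order", "record", rid, picked$mum_ppn[i], "review", "S5.1")
    }
  }

  # -- S6.4: overlapping pregnancies (conception before prior delivery) ----
  if (cnt["negative_interval_false_link"] > 0L) {
    n <- cnt["negative_interval_false_link"]
    picked <- take(n)
    for (i in seq_len(n)) {
      m <- picked$mum_ppn[i]
      tmpl <- tb$per[mum_ppn == m][order(baby_dob)][.N]
      new <- copy(tmpl)
      new[, `:=`(record_id = zid("P"), baby_ppn = paste0("ZB-", zid("N")),
                 baby_dob = tmpl$baby_dob + 30L, gestational_age = 39L,
                 plurality = 1L, birth_order = 1L,
                 parity = picked$max_parity[i] + 1L,
                 birthweight = 3300L, apgar5 = 9L)]
      tb$per <- rbind(tb$per, new)
      note("negative_interval_false_link", "person", m, m, "exclusion", "S6.4")
    }
  }

  # -- S7.5: recoverable missing parity ------------------------------------
  if (cnt["missing_parity"] > 0L) {
    n <- cnt["missing_parity"]
    n_mid <- n %/% 2L
    if (n_mid > 0L) {  # blank a middle pregnancy: adjacent parity gap of 2
      picked <- take(n_mid, moms$n_preg >= 3L)
      for (i in seq_len(n_mid)) {
        first <- tb$per[mum_ppn == picked$mum_ppn[i] & birth_order == 1L][order(baby_dob)]
        mid <- first[2]
        if (mid$plurality > 1L) {  # blank the whole plural delivery
          tb$per[mum_ppn == picked$mum_ppn[i] & baby_dob == mid$baby_dob,
                 parity := NA_integer_]
        } else {
          tb$per[record_id == mid$record_id, parity := NA_integer_]
        }
        note("missing_parity", "record", mid$record_id, picked$mum_ppn[i],
             "correction", "S7.5.3")
      }
    }
    n_first <- n - n_mid  # blank the first pregnancy: next parity is 1
    if (n_first > 0L) {
      picked <- take(n_first, moms$n_preg >= 2L)
      for (i in seq_len(n_first)) {
        first <- tb$per[mum_ppn == picked$mum_ppn[i] & birth_order == 1L][order(baby_dob)][1]
        tb$per[mum_ppn == picked$mum_ppn[i] & baby_dob == first$baby_dob,
               parity := NA_integer_]
        note("missing_parity", "record", first$record_id, picked$mum_ppn[i],
             "correction", "S7.5.1")
      }
    }
  }

  # -- S8.2.4: parity typo (digit slip producing a >=10 outlier) -----------
  if (cnt["parity_typo"] > 0L) {
    n <- cnt["parity_typo"]
    picked <- take(n, moms$n_preg >= 2L)
    for (i in seq_len(n)) {
      m <- picked$mum_ppn[i]
      last <- tb$per[mum_ppn == m & birth_order == 1L][order(baby_dob)][.N]
      tb$per[mum_ppn == m & baby_dob == last$baby_dob, parity := parity + 10L]
      note("parity_typo", "record", last$record_id, m, "correction", "S8.2.4")
    }
  }

  # -- S8.3.1: false link producing an interleaved parity sequence ---------
  if (cnt["parity_illogical_false_link"] > 0L) {
    n <- cnt["parity_illogical_false_link"]
    picked <- take(n, moms$n_preg == 2L)
    for (i in seq_len(n)) {
      m <- picked$mum_ppn[i]
      tmpl <- tb$per[mum_ppn == m][order(baby_dob)][.N]
      for (k in 1:2) {
        new <- copy(tmpl)
        new[, `:=`(record_id = zid("P"), baby_ppn = paste0("ZB-", zid("N")),
                   baby_dob = tmpl$baby_dob + 400L * k, gestational_age = 39L,
                   plurality = 1L, birth_order = 1L, parity = k - 1L,
                   birthweight = 3200L, apgar5 = 9L)]
        tb$per <- rbind(tb$per, new)
      }
      note("parity_illogical_false_link", "person", m, m, "exclusion", "S8.3.1")
    }
  }

  # -- S9.3: typo in the perinatal baby DOB --------------------------------
  if (cnt["dob_typo_in_perinatal"] > 0L) {
    n <- cnt["dob_typo_in_perinatal"]
    picked <- take(n, moms$n_preg == 1L & moms$has_singleton)
    for (i in seq_len(n)) {
      m <- picked$mum_ppn[i]
      row <- tb$per[mum_ppn == m & plurality == 1L][1]
      tb$per[record_id == row$record_id, baby_dob := baby_dob + 40L]
      note("dob_typo_in_perinatal", "record", row$record_id, m, "correction", "S9.3")
    }
  }

  # -- S9.4: typo in an encounter patient DOB ------------------------------
  if (cnt["dob_typo_in_encounter"] > 0L) {
    n <- cnt["dob_typo_in_encounter"]
    has_extra <- tb$enc[role == "baby", .N, by = ppn][N >= 2L, ppn]
    elig <- tb$per[baby_ppn %in% has_extra & mum_ppn %in% moms[eligible == TRUE, mum_ppn]]
    picked_b <- unique(elig, by = "mum_ppn")
    if (nrow(picked_b) < n) stop("infeasible plan: too few babies with repeat encounters")
    picked_b <- picked_b[sample(.N, n)]
    moms[mum_ppn %in% picked_b$mum_ppn, eligible := FALSE]
    for (i in seq_len(n)) {
      b <- picked_b$baby_ppn[i]
      recs <- tb$enc[ppn == b][order(admission_date)]
      rid <- recs[.N, record_id]
      shift <- if (i %% 2L == 1L) 3L else 400L
      newdob <- picked_b$baby_dob[i] + shift
      tb$enc[record_id == rid,
             `:=`(patient_dob = newdob,
                  patient_yob = as.integer(format(newdob, "%Y")))]
      note("dob_typo_in_encounter", "record", rid, picked_b$mum_ppn[i],
           if (shift == 3L) "correction" else "deletion", "S9.4")
    }
  }

  # -- S10.3: congenital notification disagreeing with perinatal -----------
  if (cnt["congenital_mismatch"] > 0L) {
    n <- cnt["congenital_mismatch"]
    n_excl <- n %/% 2L
    if (n_excl > 0L) {  # congenital DOB equals a sibling's DOB -> linkage error
      picked <- take(n_excl, moms$jurisdiction == "A" & moms$n_preg >= 2L)
      for (i in seq_len(n_excl)) {
        m <- picked$mum_ppn[i]
        kids <- tb$per[mum_ppn == m & birth_order == 1L][order(baby_dob)]
        rid <- zid("C")
        tb$con <- rbind(tb$con, data.table(
          record_id = rid, baby_ppn = kids$baby_ppn[1],
          baby_dob = kids$baby_dob[2], birthweight = kids$birthweight[1] + 500L))
        note("congenital_mismatch", "person", m, m, "exclusion", "S10.3")
      }
    }
    n_rev <- n - n_excl
    if (n_rev > 0L) {  # both fields differ, no sibling match -> review
      picked <- take(n_rev, moms$jurisdiction == "A" & moms$n_preg == 1L)
      for (i in seq_len(n_rev)) {
        m <- picked$mum_ppn[i]
        kid <- tb$per[mum_ppn == m][1]
        rid <- zid("C")
        tb$con <- rbind(tb$con, data.table(
          record_id = rid, baby_ppn = kid$baby_ppn,
          baby_dob = kid$baby_dob + 15L, birthweight = kid$birthweight + 500L))
        note("congenital_mismatch", "person", m, m, "review", "S10.3")
      }
    }
  }

  # -- S11.4: two records with an out-of-range mother YOB ------------------
  if (cnt["yob_out_of_range"] > 0L) {
    n <- cnt["yob_out_of_range"]
    picked <- take(n)
    for (i in seq_len(n)) {
      m <- picked$mum_ppn[i]
      adm <- picked$first_dob[i] + c(30L, 60L)
      tb$enc <- rbind(tb$enc, data.table(
        record_id = c(zid("E"), zid("E")), jurisdiction = picked$jurisdiction[i],
        ppn = m, role = "mother", source = "ed", admission_date = adm,
        separation_date = adm, patient_dob = as.Date(NA),
        patient_yob = 1925L, patient_age = NA_integer_,
        patient_sex = "female", month_of_birth = picked$mob[i],
        procedure_codes = "", is_delivery = FALSE, discharge_status = "home"))
      note("yob_out_of_range", "person", m, m, "exclusion", "S11.4")
    }
  }

  # -- S12.2: sex recorded male with conflicting month of birth ------------
  if (cnt["sex_male_with_yob_conflict"] > 0L) {
    n <- cnt["sex_male_with_yob_conflict"]
    picked <- take(n)
    for (i in seq_len(n)) {
      m <- picked$mum_ppn[i]
      adm <- picked$first_dob[i] + c(90L, 120L)
      tb$enc <- rbind(tb$enc, data.table(
        record_id = c(zid("E"), zid("E")), jurisdiction = picked$jurisdiction[i],
        ppn = m, role = "mother", source = "ed", admission_date = adm,
        separation_date = adm, patient_dob = as.Date(NA),
        patient_yob = picked$yob[i], patient_age = NA_integer_,
        patient_sex = "male",
        month_of_birth = c(picked$mob[i], picked$mob[i] %% 12L + 1L),
        procedure_codes = "", is_delivery = FALSE, discharge_status = "home"))
      note("sex_male_with_yob_conflict", "person", m, m, "exclusion", "S12.2")
    }
  }

  # -- S13.3: delivery after a total hysterectomy --------------------------
  if (cnt["birth_after_hysterectomy"] > 0L) {
    n <- cnt["birth_after_hysterectomy"]
    picked <- take(n)
    for (i in seq_len(n)) {
      m <- picked$mum_ppn[i]
      sep <- picked$last_dob[i] - 100L
      tb$enc <- rbind(tb$enc, data.table(
        record_id = zid("H"), jurisdiction = picked$jurisdiction[i],
        ppn = m, role = "mother", source = "hospital",
        admission_date = sep - 3L, separation_date = sep,
        patient_dob = as.Date(NA), patient_yob = picked$yob[i],
        patient_age = NA_integer_, patient_sex = "female",
        month_of_birth = picked$mob[i],
        procedure_codes = plan$hysterectomy_code, is_delivery = FALSE,
        discharge_status = "home"))
      note("birth_after_hysterectomy", "person", m, m, "exclusion", "S13.3")
    }
  }

  # -- S14.3: baby DOB later than discharge --------------------------------
  if (cnt["dob_after_separation"] > 0L) {
    n <- cnt["dob_after_separation"]
    n_excl <- n %/% 4L
    elig_ppn <- moms[eligible == TRUE, mum_ppn]
    pool <- tb$per[mum_ppn %in% elig_ppn &
                     as.integer(format(baby_dob, "%m")) <= 7L &
                     as.integer(format(baby_dob, "%d")) <= 28L]
    pool <- unique(pool, by = "mum_ppn")
    if (nrow(pool) < n) stop("infeasible plan: too few eligible babies for dob_after_separation")
    pool <- pool[sample(.N, n)]
    moms[mum_ppn %in% pool$mum_ppn, eligible := FALSE]
    for (i in seq_len(n)) {
      b <- pool$baby_ppn[i]; dob <- pool$baby_dob[i]
      rid <- tb$enc[ppn == b][order(admission_date)][1, record_id]
      if (i <= n_excl) {
        # patient DOB 5 months on (shares day and year, >140 days) -> exclusion
        pd <- .add_months(dob, 5L)
        tb$enc[record_id == rid,
               `:=`(admission_date = dob - 40L, separation_date = dob - 30L,
                    patient_dob = pd, patient_yob = as.integer(format(pd, "%Y")))]
        note("dob_after_separation", "person", b, pool$mum_ppn[i], "exclusion", "S14.3")
      } else {
        tb$enc[record_id == rid,
               `:=`(admission_date = dob - 40L, separation_date = dob - 30L)]
        note("dob_after_separation", "record", rid, pool$mum_ppn[i], "deletion", "S14.3")
      }
    }
  }

  # -- S15.4: health service use after the date of death -------------------
  if (cnt["service_after_death"] > 0L) {
    n <- cnt["service_after_death"]
    elig_ppn <- moms[eligible == TRUE, mum_ppn]
    late <- tb$enc[role == "baby" & is_delivery == FALSE]
    late <- merge(late, tb$per[, .(ppn = baby_ppn, mum_ppn, baby_dob)], by = "ppn")
    late <- late[admission_date >= baby_dob + 20L & mum_ppn %in% elig_ppn &
                   !ppn %in% tb$dea$ppn]
    late <- unique(late[order(ppn, -admission_date)], by = "mum_ppn")
    if (nrow(late) < n) stop("infeasible plan: too few late baby encounters")
    late <- late[sample(.N, n)]
    moms[mum_ppn %in% late$mum_ppn, eligible := FALSE]
    for (i in seq_len(n)) {
      tb$dea <- rbind(tb$dea, data.table(
        record_id = zid("D"), jurisdiction = late$jurisdiction[i],
        ppn = late$ppn[i], date_of_death = late$separation_date[i] - 10L,
        stream = "registration"))
      note("service_after_death", "person", late$ppn[i], late$mum_ppn[i],
           "exclusion", "S15.4")
    }
  }

  # -- S16.1: admission later than separation ------------------------------
  if (cnt["admission_after_separation"] > 0L) {
    n <- cnt["admission_after_separation"]
    elig_ppn <- moms[eligible == TRUE, mum_ppn]
    pool <- tb$enc[role == "baby" & is_delivery == FALSE]
    pool <- merge(pool, tb$per[, .(ppn = baby_ppn, mum_ppn, baby_dob)], by = "ppn")
    pool <- pool[mum_ppn %in% elig_ppn & admission_date > baby_dob]
    pool <- unique(pool, by = "mum_ppn")
    if (nrow(pool) < n) stop("infeasible plan: too few baby encounters")
    pool <- pool[sample(.N, n)]
    moms[mum_ppn %in% pool$mum_ppn, eligible := FALSE]
    for (i in seq_len(n)) {
      tb$enc[record_id == pool$record_id[i],
             admission_date := separation_date + 5L]
      note("admission_after_separation", "record", pool$record_id[i],
           pool$mum_ppn[i], "deletion", "S16.1")
    }
  }

  # -- S17/S19: one woman's records split across two mumPPNs (missed link) -
  if (cnt["patid_split_across_ppns"] > 0L) {
    n <- cnt["patid_split_across_ppns"]
    picked <- take(n, moms$n_preg >= 2L)
    thr <- c(A = 29, B = 28)
    for (i in seq_len(n)) {
      m <- picked$mum_ppn[i]; jur <- picked$jurisdiction[i]
      m2 <- paste0(m, "X")
      last <- tb$per[mum_ppn == m & birth_order == 1L][order(baby_dob)][.N]
      tb$per[mum_ppn == m & baby_dob == last$baby_dob, mum_ppn := m2]
      tb$enc[ppn == m & is_delivery == TRUE &
               admission_date <= last$baby_dob & separation_date >= last$baby_dob,
             ppn := m2]
      tb$map <- rbind(tb$map, data.table(
        patid = picked$patid[i], mum_ppn = m2, jurisdiction = jur,
        weight = thr[jur] + 5))
      note("patid_split_across_ppns", "person", paste(m, m2, sep = ";"), m,
           "cluster", "S17.2")
    }
  }

  # -- S20.12: one PATID falsely linking two women across states -----------
  if (cnt["patid_merging_two_women"] > 0L) {
    n <- cnt["patid_merging_two_women"]
    for (i in seq_len(n)) {
      wa <- take(1L, moms$jurisdiction == "A")
      wb <- take(1L, moms$jurisdiction == "B" & moms$mother_yob != wa$mother_yob)
      tb$map <- rbind(tb$map, data.table(
        patid = wa$patid, mum_ppn = wb$mum_ppn, jurisdiction = "B",
        weight = 28.0))
      note("patid_merging_two_women", "link",
           paste(wa$patid, wb$mum_ppn, sep = "|"), wb$mum_ppn,
           "disregard_link", "S20.12")
    }
  }

  # -- S18.2: pharmaceutical supply after death ----------------------------
  if (cnt["supply_after_death"] > 0L) {
    n <- cnt["supply_after_death"]
    picked <- take(n)
    for (i in seq_len(n)) {
      m <- picked$mum_ppn[i]
      last <- max(c(tb$enc[ppn == m, as.numeric(separation_date)],
                    as.numeric(picked$last_dob[i]),
                    tb$clm[patid == picked$patid[i], as.numeric(date_of_supply)]))
      dod <- as.Date(last, origin = "1970-01-01") + 10L
      tb$dea <- rbind(tb$dea, data.table(
        record_id = zid("D"), jurisdiction = picked$jurisdiction[i], ppn = m,
        date_of_death = dod, stream = "registration"))
      tb$clm <- rbind(tb$clm, data.table(
        claim_id = zid("S"), patid = picked$patid[i],
        date_of_supply = dod + 30L, item_code = "ITM001",
        month_of_birth = picked$mob[i], year_of_birth = picked$yob[i]))
      note("supply_after_death", "link", paste(picked$patid[i], m, sep = "|"),
           m, "disregard_link", "S18.2")
    }
  }

  # -- S22.2: one woman under two PATIDs with inconsistent claim YOB -------
  if (cnt["multi_patid_per_mother_inconsistent"] > 0L) {
    n <- cnt["multi_patid_per_mother_inconsistent"]
    picked <- take(n)
    thr <- c(A = 29, B = 28)
    for (i in seq_len(n)) {
      m <- picked$mum_ppn[i]
      newpat <- sprintf("ZPAT%05d", i)
      tb$map <- rbind(tb$map, data.table(
        patid = newpat, mum_ppn = m, jurisdiction = picked$jurisdiction[i],
        weight = thr[picked$jurisdiction[i]] + 3))
      tb$clm <- rbind(tb$clm, data.table(
        claim_id = c(zid("S"), zid("S")), patid = newpat,
        date_of_supply = picked$first_dob[i] + c(10L, 50L),
        item_code = "ITM002", month_of_birth = picked$mob[i],
        year_of_birth = picked$yob[i] + 1L))
      note("multi_patid_per_mother_inconsistent", "person", m, m,
           "exclusion", "S22.2")
    }
  }

  out <- list(perinatal = tb$per, encounters = tb$enc, deaths = tb$dea,
              congenital = tb$con, claims = tb$clm, mapping = tb$map,
              truth = if (length(truth)) rbindlist(truth) else .empty_truth(),
              meta = meta)
  for (what in c("perinatal", "encounters", "deaths", "congenital", "claims", "mapping")) {
    validate_source_table(out[[what]], what)
  }
  out
}
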