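# Steps 4-8: consistency of perinatal information within and across a
# mother's pregnancies.

#' Cross-tabulate birthweight and gestational age
#'
#' Descriptive screen only: the protocol quantifies outliers but makes no
#' changes, since extreme values can have medical explanations.
#'
#' @param perinatal current perinatal view.
#' @return list with the 6x6 `table` (birthweight category x gestation
#'   category) and the four outlier `counts`.
#' @export
tabulate_birthweight_gestation <- function(perinatal) {
  bw_cat <- cut(perinatal$birthweight, c(-Inf, 399, 999, 1999, 4999, Inf),
                labels = c("<400", "400-999", "1000-1999", "2000-4999", ">=5000"))
  ga_cat <- cut(perinatal$gestational_age, c(-Inf, 19, 26, 36, 44, Inf),
                labels = c("<20", "20-26", "27-36", "37-44", ">=45"))
  bw_cat <- factor(ifelse(is.na(bw_cat), "missing", as.character(bw_cat)),
                   levels = c("missing", "<400", "400-999", "1000-1999",
                              "2000-4999", ">=5000"))
  ga_cat <- factor(ifelse(is.na(ga_cat), "missing", as.character(ga_cat)),
                   levels = c("missing", "<20", "20-26", "27-36", "37-44", ">=45"))
  tab <- table(birthweight = bw_cat, gestation = ga_cat)
  bw <- perinatal$birthweight; ga <- perinatal$gestational_age
  counts <- c(
    gest_lt20_bw_lt400 = sum(ga < 20L & bw < 400L, na.rm = TRUE),
    gest_ge45 = sum(ga >= 45L, na.rm = TRUE),
    bw_lt1000_gest_ge45 = sum(bw < 1000L & ga >= 45L, na.rm = TRUE),
    bw_ge2000_gest_le26 = sum(bw >= 2000L & ga <= 26L, na.rm = TRUE)
  )
  list(table = tab, counts = counts)
}

# group a mother's plural-birth records into deliveries: consecutive records
# (by DOB) belong to one delivery when the DOB gap does not exceed the
# gestational-age difference in days (twins can be born days apart)
.delivery_groups <- function(rows) {
  rows <- rows[order(baby_dob, birth_order, record_id)]
  grp <- integer(nrow(rows))
  grp[1] <- 1L
  if (nrow(rows) > 1L) {
    for (i in 2:nrow(rows)) {
      gap <- as.integer(rows$baby_dob[i] - rows$baby_dob[i - 1L])
      ga_gap <- abs(rows$gestational_age[i] - rows$gestational_age[i - 1L]) * 7L
      if (is.na(ga_gap)) ga_gap <- 0L
      grp[i] <- if (gap <= ga_gap) grp[i - 1L] else grp[i - 1L] + 1L
    }
  }
  rows[, grp := grp]
  rows
}

#' Validate birth order against plurality
#'
#' Reports records whose birth order exceeds the plurality (review queue),
#' and within each plural delivery compares the recorded birth orders with
#' the expected sequence 1..k; mismatches are corrected. A twin record whose
#' date of birth disagrees with its co-twins is corrected when the maternal
#' delivery admission identifies the right date, otherwise queued. A
#' supernumerary record agreeing with a co-record on the review fields is
#' flagged `duplicate`.
#'
#' @param perinatal current perinatal view.
#' @param encounters current encounters view (maternal delivery windows).
#' @param ledger a [ledger_new()] object.
#' @return data.table report of actions taken.
#' @export
validate_birth_order <- function(perinatal, encounters, ledger) {
  actions <- list()
  implausible <- perinatal[birth_order > plurality]
  if (nrow(implausible)) {
    ledger_review(ledger, "S5.1", implausible$record_id,
                  sprintf("birth order %d with plurality %d",
                          implausible$birth_order, implausible$plurality))
    actions[["implausible"]] <- data.table(
      record_id = implausible$record_id, action = "implausible_birth_order")
  }
  plural_mums <- unique(perinatal[plurality >= 2L, mum_ppn])
  windows <- encounters[role == "mother" & is_delivery == TRUE]
  for (m in plural_mums) {
    rows <- .delivery_groups(perinatal[mum_ppn == m & plurality >= 2L])
    # try to reunite split deliveries (one twin's DOB mistyped)
    sizes <- rows[, .(N = .N, plurality = plurality[1]), by = grp]
    short <- sizes[N < plurality, grp]
    if (length(short) >= 2L) {
      for (i in seq_along(short)) {
        for (j in seq_along(short)) {
          if (i >= j) next
          g1 <- rows[grp == short[i]]; g2 <- rows[grp == short[j]]
          if (!nrow(g1) || !nrow(g2)) next
          p <- g1$plurality[1]
          if (g2$plurality[1] != p || nrow(g1) + nrow(g2) != p) next
          if (!setequal(c(g1$birth_order, g2$birth_order), seq_len(p))) next
          w <- windows[ppn == m]
          in_win <- function(d) nrow(w[admission_date <= d & separation_date >= d]) > 0L
          ok1 <- in_win(g1$baby_dob[1]); ok2 <- in_win(g2$baby_dob[1])
          if (xor(ok1, ok2)) {
            good <- if (ok1) g1$baby_dob[1] else g2$baby_dob[1]
            bad <- if (ok1) g2 else g1
            ledger_correct(ledger, bad$record_id, "baby_dob",
                           as.character(bad$baby_dob), as.character(good), "S5.3")
            rows[record_id %in% bad$record_id, baby_dob := good]
            rows[grp == short[j], grp := short[i]]
            actions[[paste0(m, "-dob")]] <- data.table(
              record_id = bad$record_id, action = "baby_dob_corrected")
          } else {
            ledger_review(ledger, "S5.3", m, "split plural delivery, ambiguous DOB")
            actions[[paste0(m, "-rev")]] <- data.table(
              record_id = g1$record_id[1], action = "review")
          }
        }
      }
    }
    for (g in unique(rows$grp)) {
      gr <- rows[grp == g][order(baby_dob, birth_order, record_id)]
      p <- gr$plurality[1]
      if (nrow(gr) > p) {
        # supernumerary entries: identical-looking extras are duplicates
        dup <- duplicated(gr[, .(baby_dob, birthweight, gestational_age, apgar5)])
        if (any(dup)) {
          ledger_flag(ledger, "record", gr$record_id[dup], "duplicate", "S5.3",
                      reason_code = "supernumerary_plural_record")
          actions[[paste0(m, "-", g, "-dup")]] <- data.table(
            record_id = gr$record_id[dup], action = "duplicate")
          gr <- gr[!dup]
        } else {
          ledger_review(ledger, "S5.3", m, "more records than plurality")
          next
        }
      }
      expected <- seq_len(nrow(gr))
      fix <- which(gr$birth_order != expected)
      if (length(fix)) {
        ledger_correct(ledger, gr$record_id[fix], "birth_order",
                       as.character(gr$birth_order[fix]),
                       as.character(expected[fix]), "S5.3")
        actions[[paste0(m, "-", g, "-ord")]] <- data.table(
          record_id = gr$record_id[fix], action = "birth_order_corrected")
      }
    }
  }
  if (length(actions)) rbindlist(actions) else
    data.table(record_id = character(), action = character())
}

#' Flag mothers with a negative pregnancy interval
#'
#' One record per delivery (birth order 1) sorted by baby DOB; for each
#' consecutive pair the interval from prior delivery to next conception is
#' computed with [pregnancy_interval()]. A negative interval means the next
#' child was conceived before the prior was delivered: the mother is flagged
#' for exclusion. Pairs with missing gestation are not assessable.
#'
#' @param perinatal current perinatal view.
#' @param ledger a [ledger_new()] object.
#' @return data.table of assessed intervals (mum_ppn, interval, flagged).
#' @export
check_pregnancy_intervals <- function(perinatal, ledger) {
  d <- perinatal[birth_order == 1L][order(mum_ppn, baby_dob)]
  d <- d[, .(mum_ppn, baby_dob, gestational_age)]
  d[, prior := shift(baby_dob), by = mum_ppn]
  d <- d[!is.na(prior)]
  if (!nrow(d)) return(data.table(mum_ppn = character(), interval = integer()))
  d[, interval := pregnancy_interval(prior, baby_dob, gestational_age)]
  bad <- d[!is.na(interval) & interval < 0L, unique(mum_ppn)]
  if (length(bad)) {
    ledger_flag(ledger, "person", bad, "exclusion", "S6.4",
                reason_code = "negative_pregnancy_interval")
  }
  d[, .(mum_ppn, interval, flagged = mum_ppn %in% bad)]
}

#' Classify a parity sequence
#'
#' A sequence of non-missing parity values ordered by baby DOB is `logical`
#' when strictly increasing, otherwise `illogical`. Fewer than two values
#' cannot be assessed.
#'
#' @param parities integer vector of non-missing parity values in delivery
#'   order.
#' @return `"logical"`, `"illogical"` or `"not_assessable"`.
#' @export
classify_parity_sequence <- function(parities) {
  parities <- parities[!is.na(parities)]
  if (length(parities) < 2L) return("not_assessable")
  if (all(diff(parities) > 0L)) "logical" else "illogical"
}

#' Impute recoverable missing parity values
#'
#' Within a plural delivery a missing parity is replaced from a co-twin.
#' Then, per mother (one record per delivery), a single missing value is
#' imputed from its neighbours: first record as next parity minus one (next
#' parity 1, or greater with a pregnancy interval under 40 weeks), last
#' record as prior parity plus one when the interval is under 40 weeks, and
#' a middle record as prior plus one when the adjacent gap is exactly two
#' (or larger with interval under 40 weeks). Mothers with a single
#' pregnancy, two or more missing values, a zero parity in the second
#' record, or an illogical sequence are left unchanged for step 8.
#'
#' @param perinatal current perinatal view.
#' @param ledger a [ledger_new()] object.
#' @param interval_days the 40-week threshold in days (default 280).
#' @return data.table of imputations performed.
#' @export
impute_missing_parity <- function(perinatal, ledger, interval_days = 280L) {
  per <- copy(perinatal)
  done <- list()
  # 7.2: plural deliveries share maternal fields
  plur <- per[plurality >= 2L & mum_ppn %in% per[is.na(parity), unique(mum_ppn)]]
  if (nrow(plur)) {
    fills <- plur[, {
      v <- unique(parity[!is.na(parity)])
      if (length(v) == 1L && anyNA(parity)) .(record_id = record_id[is.na(parity)], value = v)
      else .(record_id = character(), value = integer())
    }, by = .(mum_ppn, baby_dob)]
    if (nrow(fills)) {
      ledger_correct(ledger, fills$record_id, "parity", NA, as.character(fills$value), "S7.2")
      per[record_id %in% fills$record_id,
          parity := fills$value[match(record_id, fills$record_id)]]
      done[["plural"]] <- data.table(record_id = fills$record_id, rule = "S7.2")
    }
  }
  first <- per[birth_order == 1L][order(mum_ppn, baby_dob)]
  target_mums <- first[, .(n = .N, nmiss = sum(is.na(parity))), by = mum_ppn][
    n >= 2L & nmiss == 1L, mum_ppn]
  for (m in target_mums) {
    recs <- first[mum_ppn == m]
    p <- recs$parity
    if (!is.na(p[2]) && p[2] == 0L) next            # error marker, not imputable
    if (classify_parity_sequence(p) == "illogical") next
    pos <- which(is.na(p))
    iv <- function(i, j) pregnancy_interval(recs$baby_dob[i], recs$baby_dob[j],
                                            recs$gestational_age[j])
    value <- NULL; rule <- NULL
    if (pos == 1L) {
      nxt <- p[2]
      if (!is.na(nxt) && (nxt == 1L ||
                          (nxt > 1L && !is.na(iv(1L, 2L)) && iv(1L, 2L) < interval_days))) {
        value <- nxt - 1L; rule <- "S7.5.1"
      }
    } else if (pos == length(p)) {
      ivl <- iv(pos - 1L, pos)
      if (!is.na(ivl) && ivl < interval_days) {
        value <- p[pos - 1L] + 1L; rule <- "S7.5.2"
      }
    } else {
      gap <- p[pos + 1L] - p[pos - 1L]
      ivl <- iv(pos - 1L, pos)
      if (!is.na(gap) && (gap == 2L || (gap > 2L && !is.na(ivl) && ivl < interval_days))) {
        value <- p[pos - 1L] + 1L; rule <- "S7.5.3"
      }
    }
    if (!is.null(value)) {
      # correct the whole delivery (plural siblings share the parity)
      ids <- per[mum_ppn == m & baby_dob == recs$baby_dob[pos] & is.na(parity), record_id]
      ledger_correct(ledger, ids, "parity", NA, as.character(value), rule)
      done[[m]] <- data.table(record_id = ids, rule = rule)
    }
  }
  if (length(done)) rbindlist(done) else
    data.table(record_id = character(), rule = character())
}

# single-value repairs considered plausible typo fixes: one decimal digit
# changed (same number of digits), or a >=10 value among single-digit
# neighbours replaced by any single digit
.typo_candidates <- function(recorded, neighbours) {
  s <- strsplit(as.character(recorded), "")[[1]]
  cand <- integer()
  for (i in seq_along(s)) {
    for (d in setdiff(as.character(0:9), s[i])) {
      s2 <- s; s2[i] <- d
      cand <- c(cand, as.integer(paste(s2, collapse = "")))
    }
  }
  if (recorded >= 10L && length(neighbours) && all(neighbours < 10L)) {
    cand <- c(cand, 0:9)
  }
  setdiff(unique(cand), recorded)
}

.repair_parity <- function(vals) {
  hits <- list()
  for (i in seq_along(vals)) {
    for (v in .typo_candidates(vals[i], vals[-i])) {
      new <- vals; new[i] <- v
      if (all(diff(new) > 0L) && (max(new) - min(new) + 1L) == length(new)) {
        hits[[length(hits) + 1L]] <- c(pos = i, value = v)
      }
    }
  }
  hits <- unique(hits)
  if (length(hits) == 1L) hits[[1]] else NULL
}

#' Assess the consistency of parity across a mother's pregnancies
#'
#' Per mother (one record per delivery, sorted by baby DOB): the number of
#' recorded pregnancies is compared with the expected number implied by the
#' parity range (highest minus lowest plus one) and the sequence class from
#' [classify_parity_sequence()]. Logical sequences: equal counts are
#' consistent; expected below count reflects unreplaced missing parity;
#' expected above count by 1-3 suggests intervening births elsewhere; a
#' substantially larger expected number (gap of four or more, or expected of
#' ten or more) triggers a plausible-typo repair. Illogical sequences
#' meeting the exclusion thresholds (expected 1 with count of four or more,
#' or expected at least 2 with count exceeding expected by two or more)
#' flag the mother for exclusion; other illogical patterns are documented
#' grey inconsistencies.
#'
#' @param perinatal current perinatal view (step-7 imputations applied).
#' @param ledger a [ledger_new()] object.
#' @return one assessment row per mother with at least one delivery record:
#'   `mum_ppn`, `count`, `expected`, `sequence_class`, `outcome`.
#' @export
assess_parity_consistency <- function(perinatal, ledger) {
  first <- perinatal[birth_order == 1L][order(mum_ppn, baby_dob)]
  res <- first[, {
    p <- parity
    nm <- p[!is.na(p)]
    count <- .N
    expected <- if (length(nm)) max(nm) - min(nm) + 1L else NA_integer_
    cls <- classify_parity_sequence(p)
    outcome <- "grey_no_change"; fix <- NULL
    if (is.na(expected) || count == 1L || cls == "not_assessable") {
      outcome <- if (!is.na(expected) && expected == count) "consistent" else "not_assessable"
    } else if (cls == "logical") {
      gap <- expected - count
      if (gap == 0L) outcome <- "consistent"
      else if (gap < 0L) outcome <- "missing_unreplaced"
      else if (gap <= 3L && expected < 10L) outcome <- "intervening_births"
      else {
        fix <- if (length(nm) == count) .repair_parity(nm) else NULL
        outcome <- if (!is.null(fix)) "typo_corrected" else "grey_no_change"
      }
    } else {  # illogical
      if ((expected == 1L && count >= 4L) ||
          (expected >= 2L && count - expected >= 2L)) {
        outcome <- "exclusion"
      } else if (expected - count >= 4L || expected >= 10L) {
        fix <- if (length(nm) == count) .repair_parity(nm) else NULL
        outcome <- if (!is.null(fix)) "typo_corrected" else "grey_no_change"
      }
    }
    .(count = count, expected = expected, sequence_class = cls,
      outcome = outcome,
      fix_pos = if (is.null(fix)) NA_integer_ else as.integer(fix["pos"]),
      fix_value = if (is.null(fix)) NA_integer_ else as.integer(fix["value"]))
  }, by = mum_ppn]
  excl <- res[outcome == "exclusion", mum_ppn]
  if (length(excl)) {
    ledger_flag(ledger, "person", excl, "exclusion", "S8.3.1",
                reason_code = "inconsistent_parity")
  }
  fixes <- res[outcome == "typo_corrected"]
  for (i in seq_len(nrow(fixes))) {
    m <- fixes$mum_ppn[i]
    recs <- first[mum_ppn == m]
    dob_fix <- recs$baby_dob[fixes$fix_pos[i]]
    step <- if (fixes$sequence_class[i] == "logical") "S8.2.4" else "S8.3.2"
    ids <- perinatal[mum_ppn == m & baby_dob == dob_fix, record_id]
    ledger_correct(ledger, ids, "parity",
                   as.character(recs$parity[fixes$fix_pos[i]]),
                   as.character(fixes$fix_value[i]), step)
  }
  res[, .(mum_ppn, count, expected, sequence_class, outcome)]
}
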