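test_that("birthweight/gestation tabulation matches a direct tally", {
  per <- rbind(per_row("P1", "M1", "B1", "2010-01-01", ga = 19, bw = 350),
               per_row("P2", "M2", "B2", "2010-01-01", ga = 39, bw = 3400))
  tab <- tabulate_birthweight_gestation(per)
  expect_identical(unname(tab$counts["gest_lt20_bw_lt400"]), 1L)
  expect_identical(tab$table["<400", "<20"], 1L)
  expect_identical(tab$table["2000-4999", "37-44"], 1L)

  set.seed(31)
  n <- 100L
  per2 <- rbindlist(lapply(seq_len(n), function(i)
    per_row(sprintf("P%03d", i), sprintf("M%03d", i), sprintf("B%03d", i),
            "2010-06-01",
            ga = sample(c(NA, 15:48), 1), bw = sample(c(NA, 300, 700, 1500, 3000, 5600), 1))))
  tab2 <- tabulate_birthweight_gestation(per2)
  expect_identical(sum(tab2$table), n)
  # margins equal independent tallies
  bw <- per2$birthweight
  expect_identical(as.integer(rowSums(tab2$table)),
                   c(sum(is.na(bw)), sum(bw < 400, na.rm = TRUE),
                     sum(bw >= 400 & bw < 1000, na.rm = TRUE),
                     sum(bw >= 1000 & bw < 2000, na.rm = TRUE),
                     sum(bw >= 2000 & bw < 5000, na.rm = TRUE),
                     sum(bw >= 5000, na.rm = TRUE)))
  expect_identical(unname(tab2$counts["gest_ge45"]),
                   sum(per2$gestational_age >= 45, na.rm = TRUE))
})

test_that("birth order is validated against plurality", {
  # twins both recorded first: second (by record id) corrected to 2
  twins <- rbind(per_row("P1", "M1", "B1", "2010-01-01", plurality = 2, order = 1),
                 per_row("P2", "M1", "B2", "2010-01-01", plurality = 2, order = 1))
  lg <- ledger_new()
  validate_birth_order(twins, enc_row("H1", "M1", "2009-12-31", "2010-01-04",
                                      role = "mother", deliv = TRUE), lg)
  cr <- ledger_corrections(lg)
  expect_identical(cr[record_id == "P2", new_value], "2")
  expect_identical(nrow(cr), 1L)

  # singleton with birth order 2: implausible, reported for review
  s <- per_row("P3", "M2", "B3", "2010-05-01", order = 2)
  lg2 <- ledger_new()
  validate_birth_order(s, enc_row("H1", "M2", "2010-04-30", "2010-05-03",
                                  role = "mother", deliv = TRUE), lg2)
  expect_identical(ledger_review_queue(lg2)$step_id, "S5.1")
  expect_identical(nrow(ledger_corrections(lg2)), 0L)

  # triplets 1,2,3: nothing to do
  tri <- rbindlist(lapply(1:3, function(k)
    per_row(sprintf("P%d", k), "M3", sprintf("B%d", k), "2010-02-01",
            plurality = 3, order = k, ga = 33)))
  lg3 <- ledger_new()
  validate_birth_order(tri, enc_row("H1", "M3", "2010-01-31", "2010-02-05",
                                    role = "mother", deliv = TRUE), lg3)
  expect_identical(nrow(ledger_entries(lg3)), 0L)
  expect_identical(nrow(ledger_corrections(lg3)), 0L)
})

test_that("a mistyped twin DOB is corrected from the delivery admission", {
  twins <- rbind(per_row("P1", "M1", "B1", "2010-01-01", plurality = 2, order = 1),
                 per_row("P2", "M1", "B2", "2010-02-15", plurality = 2, order = 2))
  win <- enc_row("H1", "M1", "2009-12-31", "2010-01-04", role = "mother",
                 deliv = TRUE)
  lg <- ledger_new()
  validate_birth_order(twins, win, lg)
  cr <- ledger_corrections(lg)
  expect_identical(cr[record_id == "P2" & field == "baby_dob", new_value],
                   "2010-01-01")
})

test_that("negative pregnancy intervals flag the mother for exclusion", {
  per <- rbind(per_row("P1", "M1", "B1", "2008-01-10"),
               per_row("P2", "M1", "B2", "2009-01-05", ga = 38, parity = 1))
  lg <- ledger_new()
  out <- check_pregnancy_intervals(per, lg)
  expect_identical(out$interval, 102L)
  expect_identical(excluded_persons(lg), character())

  per2 <- rbind(per_row("P1", "M2", "B1", "2009-06-01"),
                per_row("P2", "M2", "B2", "2009-12-01", ga = 30, parity = 1))
  lg2 <- ledger_new()
  out2 <- check_pregnancy_intervals(per2, lg2)
  expect_identical(out2$interval, -20L)
  expect_identical(excluded_persons(lg2), "M2")
  expect_identical(ledger_entries(lg2)$step_id, "S6.4")

  # single delivery: nothing to assess
  lg3 <- ledger_new()
  expect_identical(nrow(check_pregnancy_intervals(per_row("P1", "M3", "B1",
                                                          "2010-01-01"), lg3)), 0L)
})

test_that("parity sequences are classified as the brute-force definition", {
  expect_identical(classify_parity_sequence(c(0, 1, 2, 4)), "logical")
  expect_identical(classify_parity_sequence(c(0, 2, 1)), "illogical")
  expect_identical(classify_parity_sequence(c(1, 2, 2)), "illogical")
  expect_identical(classify_parity_sequence(2), "not_assessable")
  # exhaustive: all sequences of length <= 5 over 0..6
  for (len in 2:5) {
    grid <- as.matrix(do.call(expand.grid, rep(list(0:6), len)))
    got <- apply(grid, 1, classify_parity_sequence)
    want <- apply(grid, 1, function(x) {
      ok <- TRUE
      for (i in seq_len(length(x) - 1L)) if (x[i + 1L] <= x[i]) ok <- FALSE
      if (ok) "logical" else "illogical"
    })
    expect_identical(got, want)
  }
})

test_that("missing parity is imputed from neighbours under the printed rules", {
  lg <- ledger_new()
  per <- rbind(
    make_mother("M1", c(NA, 1, 2)),              # first record: next parity 1 -> 0
    make_mother("M2", c(0, NA, 2)),              # middle: adjacent gap 2 -> 1
    make_mother("M4", c(NA, 0)),                 # zero in second record: error marker
    make_mother("M5", c(2, 1, NA)),              # illogical: left for step 8
    make_mother("M6", c(NA, NA, 2))              # two missing: no imputation
  )
  # last record with interval 30 weeks (< 40): prior + 1
  m3 <- rbind(per_row("M3-P1", "M3", "M3-B1", "2004-01-01", parity = 0),
              per_row("M3-P2", "M3", "M3-B2", "2005-06-01", parity = 1),
              per_row("M3-P3", "M3", "M3-B3",
                      as.Date("2005-06-01") + 210L + 39L * 7L - 7L,
                      parity = NA))
  per <- rbind(per, m3)
  out <- impute_missing_parity(per, lg)
  cr <- ledger_corrections(lg)
  expect_identical(cr[record_id == "M1-P1", .(new_value, step_id)],
                   data.table(new_value = "0", step_id = "S7.5.1"))
  expect_identical(cr[record_id == "M2-P2", .(new_value, step_id)],
                   data.table(new_value = "1", step_id = "S7.5.3"))
  expect_identical(cr[record_id == "M3-P3", .(new_value, step_id)],
                   data.table(new_value = "2", step_id = "S7.5.2"))
  expect_false(any(grepl("^M[456]", cr$record_id)))
  # a last record separated by more than 40 weeks stays missing
  lg2 <- ledger_new()
  impute_missing_parity(make_mother("M7", c(0, NA), gap = 700L), lg2)
  expect_identical(nrow(ledger_corrections(lg2)), 0L)
  # plural-birth gap: missing filled from the co-twin
  tw <- rbind(per_row("P1", "M8", "B1", "2010-01-01", plurality = 2, order = 1,
                      parity = 1),
              per_row("P2", "M8", "B2", "2010-01-01", plurality = 2, order = 2,
                      parity = NA))
  lg3 <- ledger_new()
  impute_missing_parity(tw, lg3)
  expect_identical(ledger_corrections(lg3)[, .(record_id, new_value, step_id)],
                   data.table(record_id = "P2", new_value = "1", step_id = "S7.2"))
})

test_that("imputation never creates an illogical sequence", {
  set.seed(41)
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    pars <- as.integer(seq_len(k) - 1L + sample(0:2, 1))
    pars[sample(k, 1)] <- NA_integer_
    per <- make_mother(sprintf("M%02d", rep), pars,
                       gap = sample(c(300L, 700L), 1))
    lg <- ledger_new()
    impute_missing_parity(per, lg)
    v <- apply_corrections(per, ledger_corrections(lg))
    cls <- classify_parity_sequence(v[order(baby_dob), parity])
    expect_true(cls != "illogical")
  }
})

test_that("parity consistency reproduces the worked assessments", {
  lg <- ledger_new()
  per <- rbind(
    make_mother("M1", c(1, 2, 4, 5)),     # intervening births (expected 5, count 4)
    make_mother("M2", c(0, 1, 2, 0, 1)),  # linkage error: exclusion
    make_mother("M3", c(0, 1, 2, 13)),    # typo: corrected to 3
    make_mother("M4", c(1, 2, 2)),        # grey, no change
    make_mother("M5", c(0, 1, 2, 6, 4)),  # grey, no change
    make_mother("M6", c(0, 1, 2))         # consistent
  )
  a <- assess_parity_consistency(per, lg)
  expect_identical(a[mum_ppn == "M1", .(count, expected, outcome)],
                   data.table(count = 4L, expected = 5L, outcome = "intervening_births"))
  expect_identical(a[mum_ppn == "M2", .(count, expected, outcome)],
                   data.table(count = 5L, expected = 3L, outcome = "exclusion"))
  expect_identical(a[mum_ppn == "M3", outcome], "typo_corrected")
  expect_identical(a[mum_ppn == "M4", outcome], "grey_no_change")
  expect_identical(a[mum_ppn == "M5", outcome], "grey_no_change")
  expect_identical(a[mum_ppn == "M6", outcome], "consistent")
  expect_identical(excluded_persons(lg), "M2")
  cr <- ledger_corrections(lg)
  expect_identical(cr[record_id == "M3-P4", .(old_value, new_value, step_id)],
                   data.table(old_value = "13", new_value = "3", step_id = "S8.2.4"))
})

test_that("the exclusion rule matches its printed clauses over enumerated sequences", {
  set.seed(51)
  seqs <- list()
  for (len in 2:6) {
    grid <- do.call(expand.grid, rep(list(0:4), len))
    pick <- grid[sample(nrow(grid), min(60L, nrow(grid))), , drop = FALSE]
    seqs <- c(seqs, split(as.matrix(pick), seq_len(nrow(pick))))
  }
  per <- rbindlist(lapply(seq_along(seqs), function(i)
    make_mother(sprintf("M%04d", i), as.integer(seqs[[i]]))))
  lg <- ledger_new()
  a <- assess_parity_consistency(per, lg)
  for (i in seq_along(seqs)) {
    p <- as.integer(seqs[[i]])
    expected <- max(p) - min(p) + 1L
    want <- classify_parity_sequence(p) == "illogical" && rule_831(expected, length(p))
    got <- a[mum_ppn == sprintf("M%04d", i), outcome] == "exclusion"
    expect_identical(got, want)
  }
})
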