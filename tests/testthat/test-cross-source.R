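# step 9 -----------------------------------------------------------------

test_that("an alternative baby DOB inside the delivery admission is accepted", {
  per <- per_row("P1", "M1", "B1", "2010-05-03")
  enc <- rbind(
    enc_row("H1", "B1", "2010-03-05", "2010-03-09", pdob = "2010-03-05",
            pyob = 2010),
    enc_row("H0", "M1", "2010-03-04", "2010-03-08", role = "mother",
            deliv = TRUE, pdob = "1980-06-01", pyob = 1980)
  )
  lg <- ledger_new()
  out <- reconcile_baby_dob(per, enc, lg)
  expect_identical(out$accepted_alternative, as.Date("2010-03-05"))
  cr <- ledger_corrections(lg)
  expect_identical(cr[record_id == "P1" & field == "baby_dob", new_value],
                   "2010-03-05")
  expect_identical(nrow(ledger_entries(lg)), 0L)
})

test_that("merging the updated DOB corrects ages or flags deletion", {
  per <- rbind(per_row("P1", "M1", "B1", "2010-05-03"),
               per_row("P2", "M2", "B2", "2010-01-01"))
  enc <- rbind(
    enc_row("H1", "B1", "2010-05-03", "2010-05-08", pdob = "2010-05-03", pyob = 2010),
    # same month and day, different year: age corrected
    enc_row("H2", "B1", "2011-06-01", "2011-06-03", pdob = "2011-05-03", pyob = 2011),
    enc_row("H3", "B2", "2010-01-01", "2010-01-05", pdob = "2010-01-01", pyob = 2010),
    # 241 days apart, no shared component: deletion
    enc_row("H4", "B2", "2010-09-01", "2010-09-02", pdob = "2010-08-30", pyob = 2010)
  )
  lg <- ledger_new()
  reconcile_baby_dob(per, enc, lg)
  cr <- ledger_corrections(lg)
  expect_identical(cr[record_id == "H2", field], "patient_age")
  expect_identical(ledger_entries(lg)[flag == "deletion", target_id], "H4")
})

test_that("the 20-week DOB gap boundary is honoured at step 9.4", {
  per <- per_row("P1", "M1", "B1", "2010-01-01")
  enc <- rbind(
    enc_row("H0", "B1", "2010-01-01", "2010-01-04", pdob = "2010-01-01", pyob = 2010),
    enc_row("H139", "B1", "2010-06-01", "2010-06-02", pdob = "2010-05-20", pyob = 2010),
    enc_row("H140", "B1", "2010-06-01", "2010-06-02", pdob = "2010-05-21", pyob = 2010)
  )
  lg <- ledger_new()
  reconcile_baby_dob(per, enc, lg)
  # 139 days: under 20 weeks, age corrected; exactly 140: not "less than", deleted
  expect_identical(ledger_corrections(lg)$record_id, "H139")
  expect_identical(ledger_entries(lg)[flag == "deletion", target_id], "H140")
})

# step 10 ----------------------------------------------------------------

test_that("congenital records act only when both DOB and birthweight differ", {
  per <- rbind(per_row("P1", "M1", "B1", "2010-01-01", bw = 3400),
               per_row("P2", "M1", "B2", "2012-01-01", bw = 3000, parity = 1))
  lg <- ledger_new()
  # DOB differs, birthweight equal: no action
  cong <- data.table(record_id = "C1", baby_ppn = "B1",
                     baby_dob = as.Date("2010-02-01"), birthweight = 3400L)
  check_congenital_consistency(per, cong, lg)
  expect_identical(nrow(ledger_entries(lg)), 0L)
  expect_identical(nrow(ledger_review_queue(lg)), 0L)
  # both differ and the congenital DOB is a sibling's: linkage error, exclusion
  cong2 <- data.table(record_id = "C2", baby_ppn = "B1",
                      baby_dob = as.Date("2012-01-01"), birthweight = 3900L)
  check_congenital_consistency(per, cong2, lg)
  expect_identical(excluded_persons(lg), "M1")
  # both differ, no sibling match: review only
  lg2 <- ledger_new()
  cong3 <- data.table(record_id = "C3", baby_ppn = "B1",
                      baby_dob = as.Date("2010-03-01"), birthweight = 3900L)
  check_congenital_consistency(per, cong3, lg2)
  expect_identical(nrow(ledger_entries(lg2)), 0L)
  expect_identical(ledger_review_queue(lg2)$step_id, "S10.3")
})

# steps 11 and 12 --------------------------------------------------------

yob_fixture <- function() {
  rbind(per_row("PR1", "RngA", "BR1", "2003-06-01", yob = 1941),
        per_row("PR2", "RngB", "BR2", "2012-06-01", yob = 1999),
        per_row("PM1", "M1", "BM1", "2008-01-01", yob = 1975),
        per_row("PM2", "M2", "BM2", "2008-01-01", yob = 1975),
        per_row("PM3", "M3", "BM3", "2008-01-01", yob = 1975))
}

test_that("mother YOB anomalies follow the two printed clauses", {
  per <- yob_fixture()
  enc <- rbind(
    # M1: one out-of-range record, three distinct at most: no flag
    enc_row("E1", "M1", "2009-01-01", "2009-01-01", role = "mother", pyob = 1975),
    enc_row("E2", "M1", "2009-02-01", "2009-02-01", role = "mother", pyob = 1930),
    # M2: two out-of-range records: exclusion
    enc_row("E3", "M2", "2009-01-01", "2009-01-01", role = "mother", pyob = 1930),
    enc_row("E4", "M2", "2009-02-01", "2009-02-01", role = "mother", pyob = 1930),
    # M3: four distinct YOBs: exclusion
    enc_row("E5", "M3", "2009-01-01", "2009-01-01", role = "mother", pyob = 1976),
    enc_row("E6", "M3", "2009-02-01", "2009-02-01", role = "mother", pyob = 1977),
    enc_row("E7", "M3", "2009-03-01", "2009-03-01", role = "mother", pyob = 1978)
  )
  lg <- ledger_new()
  check_mother_yob(per, enc, lg)
  expect_setequal(excluded_persons(lg), c("M2", "M3"))
  expect_true(all(ledger_entries(lg)$step_id == "S11.4"))
  # a hard-invalid YOB (outside 1900-2014) is dropped from assessment
  enc2 <- rbind(enc_row("E8", "M1", "2009-01-01", "2009-01-01", role = "mother",
                        pyob = 1880),
                enc_row("E9", "M1", "2009-02-01", "2009-02-01", role = "mother",
                        pyob = 1881))
  lg2 <- ledger_new()
  check_mother_yob(per, enc2, lg2)
  expect_identical(excluded_persons(lg2), character())
})

test_that("male-coded records flag only with a second DOB conflict", {
  per <- yob_fixture()
  mk <- function(id, m, pyob, mob, sex = "male") {
    enc_row(id, m, "2009-01-01", "2009-01-01", role = "mother", source = "ed",
            pyob = pyob, mob = mob, sex = sex)
  }
  enc <- rbind(
    mk("E1", "M1", 1980, 3), mk("E2", "M1", 1982, 3),   # 2 male + 2 YOBs
    mk("E3", "M2", 1975, 4),                            # single male record
    mk("E4", "M3", 1975, 5), mk("E5", "M3", 1975, 5), mk("E6", "M3", 1975, 5)
  )
  lg <- ledger_new()
  check_mother_sex(per, enc, lg)
  expect_identical(excluded_persons(lg), "M1")
  expect_identical(ledger_entries(lg)$step_id, "S12.2")
})

# step 13 ----------------------------------------------------------------

test_that("a delivery after a hysterectomy separation excludes the mother", {
  per <- rbind(per_row("P1", "M1", "B1", "2008-03-01"),
               per_row("P2", "M2", "B2", "2008-03-01"),
               per_row("P3", "M3", "B3", "2008-03-01"))
  hy <- function(id, m, sep) {
    enc_row(id, m, as.Date(sep) - 2L, sep, role = "mother", proc = "3565300")
  }
  enc <- rbind(hy("H1", "M1", "2007-02-01"),   # before delivery: exclusion
               hy("H2", "M2", "2009-02-01"),   # after: fine
               hy("H3", "M3", "2008-03-01"))   # same day: strictly earlier required
  lg <- ledger_new()
  check_birth_after_hysterectomy(per, enc, "3565300", lg)
  expect_identical(excluded_persons(lg), "M1")
  # empty code list skips the check with a notice
  lg2 <- ledger_new()
  expect_message(check_birth_after_hysterectomy(per, enc, character(), lg2),
                 "skipped")
  expect_identical(nrow(ledger_entries(lg2)), 0L)
})

# step 14 ----------------------------------------------------------------

test_that("baby DOB after discharge splits on the 20-week patient-DOB gap", {
  per <- rbind(per_row("P1", "M1", "B1", "2010-06-01"),
               per_row("P2", "M2", "B2", "2010-03-01"),
               per_row("P3", "M3", "B3", "2010-01-01"))
  enc <- rbind(
    # gap 142 days: baby excluded
    enc_row("H1", "B1", "2010-01-10", "2010-01-15", pdob = "2010-01-10", pyob = 2010),
    # gap 50 days: record deleted
    enc_row("H2", "B2", "2010-01-10", "2010-01-15", pdob = "2010-01-10", pyob = 2010),
    # DOB not after separation: untouched
    enc_row("H3", "B3", "2010-01-01", "2010-01-05", pdob = "2010-01-01", pyob = 2010)
  )
  lg <- ledger_new()
  check_dob_after_discharge(per, enc, lg)
  expect_identical(excluded_persons(lg), "B1")
  expect_identical(ledger_entries(lg)[flag == "deletion", target_id], "H2")
  expect_identical(ledger_entries(lg)[target_id == "H3", .N], 0L)
})

# step 15 ----------------------------------------------------------------

test_that("service use after death respects the 3-day registration allowance", {
  per <- per_row("P1", "M9", "B9", "2009-01-01")
  de <- rbind(death_row("D1", "B1", "2010-01-01"),
              death_row("D2", "B2", "2010-01-01"),
              death_row("D3", "B3", "2010-01-01"))
  enc <- rbind(
    enc_row("H1", "B1", "2010-01-02", "2010-01-03"),  # within allowance
    enc_row("H2", "B2", "2010-01-02", "2010-01-04"),  # boundary: death + 3
    enc_row("H3", "B3", "2010-01-02", "2010-01-10")   # beyond: exclusion
  )
  lg <- ledger_new()
  check_service_after_death(per, enc, de, lg)
  expect_identical(excluded_persons(lg), "B3")
  # a mother delivering after her recorded death is caught via perinatal
  de2 <- death_row("D4", "M9", "2008-06-01")
  lg2 <- ledger_new()
  check_service_after_death(per, per[0][, .(record_id, jurisdiction, ppn = mum_ppn,
                                            role = "mother", source = "hospital",
                                            admission_date = baby_dob,
                                            separation_date = baby_dob,
                                            patient_dob = baby_dob,
                                            patient_yob = 1L, patient_age = 1L,
                                            patient_sex = "female",
                                            month_of_birth = 1L,
                                            procedure_codes = "",
                                            is_delivery = FALSE,
                                            discharge_status = "")],
                            de2, lg2)
  expect_identical(excluded_persons(lg2), "M9")
})

# step 16 ----------------------------------------------------------------

test_that("admission after separation flags the record for deletion", {
  enc <- rbind(enc_row("H1", "B1", "2010-05-10", "2010-05-08"),
               enc_row("H2", "B2", "2010-05-10", "2010-05-10"),
               enc_row("H3", "B3", "2010-05-10", "2010-05-12"))
  lg <- ledger_new()
  expect_identical(check_admission_after_discharge(enc, lg), "H1")
  expect_identical(flagged_records(lg), "H1")
  lg2 <- ledger_new()
  expect_identical(length(check_admission_after_discharge(enc[0], lg2)), 0L)
})
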