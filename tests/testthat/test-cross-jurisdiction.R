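mk_links <- function(...) {
  x <- rbindlist(list(...))
  setnames(x, c("patid", "mum_ppn", "jurisdiction", "weight"))
  x
}
lnk <- function(patid, ppn, jur, w) data.table(patid, ppn, jur, w)

empty_view <- function(per) {
  list(perinatal = per,
       encounters = enc_row("X", "X", "2000-01-01", "2000-01-01")[0],
       deaths = death_row("X", "X", "2000-01-01")[0])
}

test_that("link extraction applies the per-jurisdiction thresholds inclusively", {
  m <- mk_links(lnk("T1", "A-M1", "A", 28.5), lnk("T2", "B-M1", "B", 28.0),
                lnk("T3", "A-M2", "A", 29.0), lnk("T4", "B-M2", "B", 17.0))
  links <- extract_recommended_links(m)
  expect_identical(links[patid == "T1", status], "sub_threshold")  # < 29 in A
  expect_identical(links[patid == "T2", status], "accepted")       # >= 28 in B
  expect_identical(links[patid == "T3", status], "accepted")
  expect_identical(links[patid == "T4", status], "sub_threshold")  # kept for sensitivity
  expect_identical(nrow(links), nrow(m))
  expect_error(extract_recommended_links(mk_links(lnk("T", "M", "C", 30))),
               "jurisdiction")
})

test_that("component assignment equals the transitive-closure oracle", {
  set.seed(61)
  for (rep in 1:50) {
    n_pat <- sample(3:20, 1); n_ppn <- sample(3:25, 1)
    n_edge <- sample(2:40, 1)
    links <- unique(data.table(
      patid = sprintf("T%02d", sample(n_pat, n_edge, replace = TRUE)),
      mum_ppn = sprintf("M%02d", sample(n_ppn, n_edge, replace = TRUE))))
    got <- perilink:::.link_components(links)
    want <- brute_force_components(links)
    # same partition: two nodes share a component iff the oracle says so
    got_sets <- split(got$node, got$comp)
    norm <- function(sets) sort(vapply(sets, function(s)
      paste(sort(s), collapse = "+"), character(1)), method = "radix")
    expect_identical(unname(norm(got_sets)), unname(norm(want)))
  }
})

test_that("the consistency battery applies the person-level checks to pooled records", {
  lg <- ledger_new()
  # one woman split across two PPNs: interleaved logical parity, same YOB
  per_ok <- rbind(per_row("P1", "M1", "B1", "2004-01-01", parity = 0),
                  per_row("P2", "M2", "B2", "2006-01-01", parity = 1),
                  per_row("P3", "M1", "B3", "2008-01-01", parity = 2),
                  per_row("P4", "M2", "B4", "2010-01-01", parity = 3))
  expect_true(consistency_battery(c("M1", "M2"), empty_view(per_ok), lg)$ok)
  # overlapping pregnancies across members: negative pooled interval
  per_neg <- rbind(per_row("P1", "M3", "B5", "2009-06-01"),
                   per_row("P2", "M4", "B6", "2009-12-01", ga = 30))
  b <- consistency_battery(c("M3", "M4"), empty_view(per_neg), lg)
  expect_identical(b$reason, "negative_interval")
  # different years of birth
  per_yob <- rbind(per_row("P1", "M5", "B7", "2006-01-01", yob = 1975),
                   per_row("P2", "M6", "B8", "2009-01-01", yob = 1988, parity = 1))
  expect_identical(consistency_battery(c("M5", "M6"), empty_view(per_yob), lg)$reason,
                   "different_yob")
  # pooled parity 0,1,0 cannot be one woman
  per_par <- rbind(per_row("P1", "M7", "B9", "2004-01-01", parity = 0),
                   per_row("P2", "M7", "B10", "2006-01-01", parity = 1),
                   per_row("P3", "M8", "B11", "2008-01-01", parity = 0))
  expect_identical(consistency_battery(c("M7", "M8"), empty_view(per_par), lg)$reason,
                   "inconsistent_parity")
  # an inherited exclusion flag fails the battery outright
  lg2 <- ledger_new()
  ledger_flag(lg2, "person", "M1", "exclusion", "S6.4")
  expect_identical(consistency_battery(c("M1", "M2"), empty_view(per_ok), lg2)$reason,
                   "exclusion_flag")
})

test_that("multi-match PATIDs become clusters or keep their best link", {
  per <- rbind(per_row("P1", "M1", "B1", "2004-01-01", parity = 0),
               per_row("P2", "M2", "B2", "2007-01-01", parity = 1),
               per_row("P3", "M3", "B3", "2004-06-01", yob = 1970),
               per_row("P4", "M4", "B4", "2007-06-01", yob = 1985))
  lg <- ledger_new()
  links <- extract_recommended_links(mk_links(
    lnk("T1", "M1", "A", 33), lnk("T1", "M2", "A", 31),     # consistent pair
    lnk("T2", "M3", "A", 35), lnk("T2", "M4", "A", 29.2)))  # conflicting YOBs
  r <- detect_patid_clusters(links, empty_view(per), lg)
  expect_identical(sort(r$clusters$mum_ppn), c("M1", "M2"))
  expect_identical(uniqueN(r$clusters$cluster_id), 1L)
  # the weaker of the two conflicting links is disregarded and queued
  expect_identical(r$links[patid == "T2" & mum_ppn == "M4", status],
                   "disregarded_S17")
  expect_identical(r$links[patid == "T2" & mum_ppn == "M3", status], "accepted")
  expect_identical(ledger_entries(lg)[flag == "disregard_link", target_id],
                   "T2|M4")
  expect_identical(nrow(ledger_review_queue(lg)), 1L)
})

test_that("claims supplied after death disregard the link, strictly", {
  links <- extract_recommended_links(mk_links(
    lnk("T1", "M1", "A", 30), lnk("T2", "M2", "A", 30), lnk("T3", "M3", "A", 30)))
  claims <- data.table(
    claim_id = c("S1", "S2", "S3"), patid = c("T1", "T2", "T3"),
    date_of_supply = as.Date(c("2011-05-01", "2011-04-01", "2011-04-01")),
    item_code = "ITM001", month_of_birth = 1L, year_of_birth = 1980L)
  de <- rbind(death_row("D1", "M1", "2011-04-01"),
              death_row("D2", "M2", "2011-04-01"))
  lg <- ledger_new()
  out <- check_supply_after_death(links, claims, de, lg)
  expect_identical(out[mum_ppn == "M1", status], "disregarded_S18")  # after death
  expect_identical(out[mum_ppn == "M2", status], "accepted")         # same day kept
  expect_identical(out[mum_ppn == "M3", status], "accepted")         # no death
})

test_that("cluster validation rejects on the battery and excludes members", {
  per <- rbind(per_row("P1", "M1", "B1", "2009-06-01"),
               per_row("P2", "M2", "B2", "2009-12-01", ga = 30))
  clusters <- data.table(cluster_id = "CL0001", patid = "T1",
                         jurisdiction = "A", mum_ppn = c("M1", "M2"))
  links <- extract_recommended_links(mk_links(lnk("T1", "M1", "A", 30),
                                              lnk("T1", "M2", "A", 29)))
  lg <- ledger_new()
  r <- validate_clusters(clusters, links, empty_view(per), lg)
  expect_identical(r$decisions$status, "rejected")
  expect_identical(r$decisions$rejection_reason, "negative_interval")
  expect_setequal(excluded_persons(lg), c("M1", "M2"))
  expect_true(all(r$links$status == "disregarded_S19"))
})

test_that("a cross-state network forms one CrossID spanning all its PPNs", {
  # 1 A-PPN and 3 B-PPNs connected through 2 PATIDs: one woman, one CrossID
  per <- rbind(per_row("P1", "A-M1", "B1", "2003-01-01", parity = 0),
               per_row("P2", "B-M1", "B2", "2005-01-01", parity = 1, jur = "B"),
               per_row("P3", "B-M2", "B3", "2007-01-01", parity = 2, jur = "B"),
               per_row("P4", "B-M3", "B4", "2009-01-01", parity = 3, jur = "B"))
  links <- extract_recommended_links(mk_links(
    lnk("T1", "A-M1", "A", 33), lnk("T1", "B-M1", "B", 30),
    lnk("T2", "A-M1", "A", 31), lnk("T2", "B-M2", "B", 30),
    lnk("T2", "B-M3", "B", 29)))
  lg <- ledger_new()
  r <- resolve_cross_state(links, empty_view(per), lg)
  expect_identical(r$decisions$status, "accepted")
  expect_identical(nrow(r$decisions), 1L)
  expect_setequal(r$assignments$mum_ppn, c("A-M1", "B-M1", "B-M2", "B-M3"))
  expect_identical(uniqueN(r$assignments$cross_id), 1L)
})

test_that("a rejected cross-state pair loses its lower-weight link only", {
  per <- rbind(per_row("P1", "A-M1", "B1", "2006-01-01", yob = 1975),
               per_row("P2", "B-M9", "B2", "2008-01-01", yob = 1988),
               per_row("P3", "B-M9", "B3", "2010-01-01", yob = 1988, parity = 1))
  links <- extract_recommended_links(mk_links(
    lnk("T1", "A-M1", "A", 33), lnk("T1", "B-M9", "B", 28.4),
    lnk("T9", "B-M9", "B", 31)))
  lg <- ledger_new()
  r <- resolve_cross_state(links, empty_view(per), lg)
  expect_identical(r$decisions$status, "rejected")
  expect_identical(r$links[patid == "T1" & mum_ppn == "B-M9", status],
                   "disregarded_S20")
  expect_identical(r$links[patid == "T1" & mum_ppn == "A-M1", status], "accepted")
  # the same-state-only PATID keeps its link
  expect_identical(r$links[patid == "T9", status], "accepted")
  expect_identical(nrow(r$assignments), 0L)
})

test_that("finalPPNmum follows the CrossID > ClusterID > mumPPN hierarchy", {
  clusters <- data.table(
    cluster_id = c("CL0001", "CL0001", "CL0001", "CL0002", "CL0002", "CL0002"),
    mum_ppn = c("M1", "M2", "M3", "M4", "M5", "M6"))
  cross <- data.table(mum_ppn = c("M1", "M2", "M3"), cross_id = "X0001")
  res <- integrate_final_ppn(sprintf("M%d", 1:10), clusters, cross)
  expect_identical(res[mum_ppn == "M1", final_ppn], "X0001")   # cross wins
  expect_identical(res[mum_ppn == "M4", final_ppn], "CL0002")
  expect_identical(res[mum_ppn == "M8", final_ppn], "M8")      # itself
  # 2 clusters of 3 plus 4 singletons collapse 10 mumPPNs to 6 women
  res2 <- integrate_final_ppn(sprintf("M%d", 1:10), clusters,
                              cross[0])
  expect_identical(uniqueN(res2$final_ppn), 6L)
  # a cluster straddling two CrossIDs is a pipeline error
  bad_cross <- data.table(mum_ppn = c("M1", "M2"), cross_id = c("X0001", "X0002"))
  expect_error(integrate_final_ppn(sprintf("M%d", 1:6), clusters, bad_cross),
               "not nested")
})

test_that("women under multiple PATIDs are screened on claim month/year of birth", {
  per <- rbind(per_row("P1", "M1", "B1", "2006-01-01"),
               per_row("P2", "M2", "B2", "2006-01-01"),
               per_row("P3", "M3", "B3", "2006-01-01"))
  links <- extract_recommended_links(mk_links(
    lnk("T1", "M1", "A", 30), lnk("T2", "M1", "A", 30),   # conflicting YOBs
    lnk("T3", "M2", "A", 30), lnk("T4", "M2", "A", 30),   # consistent
    lnk("T5", "M3", "A", 30)))                            # single PATID
  claims <- data.table(
    claim_id = sprintf("S%d", 1:5),
    patid = c("T1", "T2", "T3", "T4", "T5"),
    date_of_supply = as.Date("2007-01-01"),
    item_code = "ITM001",
    month_of_birth = 6L,
    year_of_birth = c(1980L, 1981L, 1975L, 1975L, 1970L))
  resolution <- integrate_final_ppn(c("M1", "M2", "M3"),
                                    data.table(cluster_id = character(),
                                               mum_ppn = character()),
                                    data.table(mum_ppn = character(),
                                               cross_id = character()))
  lg <- ledger_new()
  r <- check_multi_patid(links, resolution, claims,
                         empty_view(per), lg)
  expect_identical(excluded_persons(lg), "M1")
  expect_identical(ledger_entries(lg)$step_id, "S22.2")
  expect_identical(r$multi_patid[final_ppn == "M2", disposition], "retained")
  expect_false("M3" %in% r$multi_patid$final_ppn)  # single PATID not assessed
  expect_true(all(r$links[mum_ppn == "M1", status] == "removed_S22"))
  expect_false("T1" %in% r$claims_extract$patid)
  expect_true("T3" %in% r$claims_extract$patid)
})
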