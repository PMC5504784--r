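# Steps 17-22: resolving mother identifiers across the claims (PATID) and
# state (mumPPN) identifier spaces.

#' Extract links at or above the recommended acceptance threshold
#'
#' Links with a match weight at or above the jurisdiction's recommended
#' threshold are accepted; the rest (released down to weight 17 to support
#' sensitivity analyses) are retained with status `sub_threshold`.
#'
#' @param mapping mapping table (`patid`, `mum_ppn`, `jurisdiction`,
#'   `weight`).
#' @param thresholds named numeric thresholds per jurisdiction (defaults
#'   `c(A = 29, B = 28)`).
#' @return copy of the mapping with a `status` column (`accepted` /
#'   `sub_threshold`).
#' @export
extract_recommended_links <- function(mapping, thresholds = c(A = 29, B = 28)) {
  unknown <- setdiff(unique(mapping$jurisdiction), names(thresholds))
  if (length(unknown)) {
    stop("no threshold configured for jurisdiction: ", paste(unknown, collapse = ", "))
  }
  links <- copy(mapping)
  links[, status := ifelse(weight >= thresholds[jurisdiction], "accepted", "sub_threshold")]
  links[]
}

# union-find connected components over the bipartite PATID/PPN graph
.link_components <- function(links) {
  nodes <- unique(c(paste0("P:", links$patid), paste0("M:", links$mum_ppn)))
  parent <- seq_along(nodes)
  idx <- setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(links))) {
    a <- find(idx[paste0("P:", links$patid[k])])
    b <- find(idx[paste0("M:", links$mum_ppn[k])])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_along(nodes), find, integer(1))
  data.table(node = nodes, comp = match(comp, unique(comp)))
}

#' Person-level consistency battery for a candidate identifier group
#'
#' Pools the perinatal, encounter and death records of a set of mumPPNs as
#' if they were one woman and applies the person-level checks: inherited
#' exclusion flag, negative pregnancy interval, disagreeing perinatal
#' mother year of birth, illogical pooled parity sequence, and service use
#' after the pooled date of death.
#'
#' @param ppns mumPPNs in the candidate cluster/cross-state group.
#' @param view current [active_view()] of the cohort.
#' @param ledger the ledger (consulted for inherited exclusion flags; not
#'   written to).
#' @param allowance_days death-registration delay allowance.
#' @return list with `ok` (logical) and `reason` (`NA` when consistent; one
#'   of `exclusion_flag`, `negative_interval`, `different_yob`,
#'   `inconsistent_parity`, `service_after_death`).
#' @export
consistency_battery <- function(ppns, view, ledger, allowance_days = 3L) {
  fail <- function(reason) list(ok = FALSE, reason = reason)
  if (any(ppns %in% excluded_persons(ledger))) return(fail("exclusion_flag"))
  per <- view$perinatal[mum_ppn %in% ppns]
  first <- per[birth_order == 1L][order(baby_dob)]
  if (nrow(first) >= 2L) {
    iv <- pregnancy_interval(shift(first$baby_dob)[-1], first$baby_dob[-1],
                             first$gestational_age[-1])
    if (any(!is.na(iv) & iv < 0L)) return(fail("negative_interval"))
  }
  yobs <- unique(per$mother_yob[!is.na(per$mother_yob)])
  if (length(yobs) > 1L) return(fail("different_yob"))
  if (classify_parity_sequence(first$parity) == "illogical") {
    return(fail("inconsistent_parity"))
  }
  dd <- .death_dates(view$deaths[ppn %in% ppns])
  if (nrow(dd)) {
    dod <- min(dd$date_of_death)
    svc <- c(view$encounters[ppn %in% ppns, separation_date], first$baby_dob)
    if (any(svc > dod + allowance_days)) return(fail("service_after_death"))
  }
  list(ok = TRUE, reason = NA_character_)
}

#' Detect and adjudicate PATIDs matching multiple mumPPNs within a state
#'
#' A PATID with accepted links to two or more mumPPNs of one jurisdiction
#' indicates either a missed state link (one woman under several PPNs) or a
#' false claims link. Each case is pre-screened with the step-19
#' consistency battery: a consistent group becomes a mumPPN cluster; an
#' inconsistent one keeps only its most reliable link (highest weight, ties
#' by number of perinatal records then lexicographic PPN) and the remainder
#' are disregarded and queued for review.
#'
#' @param links link table from [extract_recommended_links()].
#' @param view current [active_view()].
#' @param ledger a [ledger_new()] object.
#' @return list with `clusters` (cluster_id, patid, member ppns) and the
#'   updated `links` (statuses `disregarded_S17` added).
#' @export
detect_patid_clusters <- function(links, view, ledger) {
  links <- copy(links)
  acc <- links[status == "accepted"]
  multi <- acc[, .(n_ppn = uniqueN(mum_ppn)), by = .(jurisdiction, patid)][n_ppn >= 2L]
  clusters <- list()
  for (k in seq_len(nrow(multi))) {
    pid <- multi$patid[k]; jur <- multi$jurisdiction[k]
    cand <- acc[patid == pid & jurisdiction == jur]
    bat <- consistency_battery(cand$mum_ppn, view, ledger)
    if (bat$ok) {
      clusters[[length(clusters) + 1L]] <- data.table(
        patid = pid, jurisdiction = jur,
        mum_ppn = sort(unique(cand$mum_ppn)))
    } else {
      n_per <- view$perinatal[mum_ppn %in% cand$mum_ppn, .N, by = mum_ppn]
      cand <- merge(cand, n_per, by = "mum_ppn", all.x = TRUE)
      cand[is.na(N), N := 0L]
      setorder(cand, -weight, -N, mum_ppn)
      drop <- cand[-1L]
      ledger_flag(ledger, "link", paste(drop$patid, drop$mum_ppn, sep = "|"),
                  "disregard_link", "S17.3", reason_code = bat$reason)
      links[paste(patid, mum_ppn) %in% paste(drop$patid, drop$mum_ppn),
            status := "disregarded_S17"]
      ledger_review(ledger, "S17.3", pid,
                    sprintf("PATID matched %d mumPPNs; kept %s (%s)",
                            nrow(cand), cand$mum_ppn[1], bat$reason))
    }
  }
  clusters <- if (length(clusters)) rbindlist(clusters) else
    data.table(patid = character(), jurisdiction = character(), mum_ppn = character())
  if (nrow(clusters)) {
    key <- clusters[, .(members = paste(sort(unique(mum_ppn)), collapse = ";")), by = patid]
    key <- unique(key[, .(members)])
    key[, cluster_id := sprintf("CL%04d", .I)]
    clusters <- merge(clusters,
                      clusters[, .(members = paste(sort(unique(mum_ppn)), collapse = ";")),
                               by = patid],
                      by = "patid")
    clusters <- merge(clusters, key, by = "members")[, .(cluster_id, patid, jurisdiction, mum_ppn)]
    setorder(clusters, cluster_id, mum_ppn)
  } else {
    clusters[, cluster_id := character()]
  }
  list(clusters = clusters, links = links)
}

#' Disregard links whose claims postdate the woman's death
#'
#' @param links current link table.
#' @param claims claims table.
#' @param deaths current deaths view.
#' @param ledger a [ledger_new()] object.
#' @return updated link table (statuses `disregarded_S18` added).
#' @export
check_supply_after_death <- function(links, claims, deaths, ledger) {
  links <- copy(links)
  dd <- .death_dates(deaths)
  if (!nrow(dd)) return(links)
  acc <- links[status == "accepted"]
  j <- merge(acc, dd, by.x = "mum_ppn", by.y = "ppn")
  if (!nrow(j)) return(links)
  last_supply <- claims[patid %in% j$patid,
                        .(last_supply = max(date_of_supply)), by = patid]
  j <- merge(j, last_supply, by = "patid")
  bad <- j[last_supply > date_of_death]
  if (nrow(bad)) {
    ledger_flag(ledger, "link", paste(bad$patid, bad$mum_ppn, sep = "|"),
                "disregard_link", "S18.2", reason_code = "supply_after_death")
    links[paste(patid, mum_ppn) %in% paste(bad$patid, bad$mum_ppn),
          status := "disregarded_S18"]
  }
  links
}

#' Validate mumPPN clusters
#'
#' Each cluster inherits any member's death date and exclusion flag, and
#' the pooled records are re-assessed with the consistency battery. A
#' failing cluster is rejected: all member mumPPNs are flagged for
#' exclusion and the cluster's links disregarded.
#'
#' @param clusters cluster table from [detect_patid_clusters()].
#' @param links current link table.
#' @param view current [active_view()].
#' @param ledger a [ledger_new()] object.
#' @return list with `decisions` (one row per cluster) and updated `links`.
#' @export
validate_clusters <- function(clusters, links, view, ledger) {
  links <- copy(links)
  decisions <- list()
  for (cid in unique(clusters$cluster_id)) {
    members <- clusters[cluster_id == cid, unique(mum_ppn)]
    bat <- consistency_battery(members, view, ledger)
    if (!bat$ok) {
      ledger_flag(ledger, "person", members, "exclusion", "S19.4",
                  reason_code = bat$reason, detail = cid)
      pats <- clusters[cluster_id == cid, unique(patid)]
      drop <- links[status == "accepted" & patid %in% pats & mum_ppn %in% members]
      if (nrow(drop)) {
        ledger_flag(ledger, "link", paste(drop$patid, drop$mum_ppn, sep = "|"),
                    "disregard_link", "S19.4", reason_code = bat$reason)
        links[paste(patid, mum_ppn) %in% paste(drop$patid, drop$mum_ppn),
              status := "disregarded_S19"]
      }
    }
    decisions[[cid]] <- data.table(
      cluster_id = cid, n_members = length(members),
      members = paste(members, collapse = ";"),
      status = if (bat$ok) "accepted" else "rejected",
      rejection_reason = bat$reason)
  }
  decisions <- if (length(decisions)) rbindlist(decisions) else
    data.table(cluster_id = character(), n_members = integer(),
               members = character(), status = character(),
               rejection_reason = character())
  list(decisions = decisions, links = links)
}

#' Identify and validate women with records in both jurisdictions
#'
#' PATIDs whose remaining accepted links span both jurisdictions connect
#' mumPPNs into cross-state components (a network: one PPN may reach
#' further PPNs through shared PATIDs). Each component receives a CrossID
#' and is assessed with the consistency battery. Accepted CrossIDs
#' represent one woman delivering in both states. For a rejected CrossID
#' the links of each state-spanning PATID on one side are disregarded: the
#' side carrying the exclusion flag if any, otherwise the side with the
#' lower match weight.
#'
#' @param links current link table.
#' @param view current [active_view()].
#' @param ledger a [ledger_new()] object.
#' @return list with `decisions` (one row per CrossID), `assignments`
#'   (mum_ppn to accepted cross_id) and updated `links`.
#' @export
resolve_cross_state <- function(links, view, ledger) {
  links <- copy(links)
  acc <- links[status == "accepted"]
  span <- acc[, .(n_jur = uniqueN(jurisdiction)), by = patid][n_jur == 2L, patid]
  empty <- list(
    decisions = data.table(cross_id = character(), members = character(),
                           status = character(), rejection_reason = character()),
    assignments = data.table(mum_ppn = character(), cross_id = character()),
    links = links)
  if (!length(span)) return(empty)
  comp <- .link_components(acc)
  acc[, comp := comp$comp[match(paste0("P:", patid), comp$node)]]
  cross_comps <- unique(acc[patid %in% span, comp])
  decisions <- list(); assignments <- list()
  xi <- 0L
  for (cp in sort(cross_comps)) {
    xi <- xi + 1L
    xid <- sprintf("X%04d", xi)
    sub <- acc[comp == cp]
    members <- sort(unique(sub$mum_ppn))
    bat <- consistency_battery(members, view, ledger)
    if (bat$ok) {
      assignments[[xid]] <- data.table(mum_ppn = members, cross_id = xid)
    } else {
      excl_jur <- unique(view$perinatal[
        mum_ppn %in% intersect(members, excluded_persons(ledger)), jurisdiction])
      for (pid in intersect(span, sub$patid)) {
        pl <- sub[patid == pid]
        side <- if (length(excl_jur) == 1L && excl_jur %in% pl$jurisdiction) {
          excl_jur
        } else {
          by_jur <- pl[, .(w = max(weight), n = .N), by = jurisdiction]
          setorder(by_jur, w, n, -jurisdiction)  # lowest weight loses
          by_jur$jurisdiction[1]
        }
        drop <- pl[jurisdiction == side]
        ledger_flag(ledger, "link", paste(drop$patid, drop$mum_ppn, sep = "|"),
                    "disregard_link", "S20.12", reason_code = bat$reason)
        links[paste(patid, mum_ppn) %in% paste(drop$patid, drop$mum_ppn),
              status := "disregarded_S20"]
      }
    }
    decisions[[xid]] <- data.table(
      cross_id = xid, members = paste(members, collapse = ";"),
      status = if (bat$ok) "accepted" else "rejected",
      rejection_reason = bat$reason)
  }
  list(decisions = rbindlist(decisions),
       assignments = if (length(assignments)) rbindlist(assignments) else
         empty$assignments,
       links = links)
}

#' Integrate mother identifiers into finalPPNmum
#'
#' Collapses identifiers by the hierarchy accepted CrossID, then accepted
#' ClusterID, then the mumPPN itself. A mumPPN belonging to an accepted
#' cluster that straddles two different accepted CrossIDs would make the
#' hierarchy ambiguous and raises an error.
#'
#' @param mum_ppns all mumPPNs in scope.
#' @param clusters accepted cluster table (`cluster_id`, `mum_ppn`).
#' @param cross_assignments accepted cross-state assignments (`mum_ppn`,
#'   `cross_id`).
#' @return `data.table` (mum_ppn, cluster_id, cross_id, final_ppn).
#' @export
integrate_final_ppn <- function(mum_ppns, clusters, cross_assignments) {
  res <- data.table(mum_ppn = sort(unique(mum_ppns)))
  cl <- unique(clusters[, .(mum_ppn, cluster_id)])
  res <- merge(res, cl, by = "mum_ppn", all.x = TRUE)
  res <- merge(res, unique(cross_assignments), by = "mum_ppn", all.x = TRUE)
  chk <- res[!is.na(cluster_id) & !is.na(cross_id),
             .(n_cross = uniqueN(cross_id)), by = cluster_id]
  if (any(chk$n_cross > 1L)) {
    stop("accepted cluster spans two accepted CrossIDs; steps 19/20 are not nested")
  }
  res[, final_ppn := fifelse(!is.na(cross_id), cross_id,
                             fifelse(!is.na(cluster_id), cluster_id, mum_ppn))]
  res[]
}

#' Consistency of women matched to multiple PATIDs, and final cohort
#'
#' Links of excluded women are removed. Among the remainder, a finalPPNmum
#' matched to two or more PATIDs is checked for consistency of the month
#' and year of birth recorded in the claims and of the perinatal parity
#' sequence; failures are flagged for exclusion and their links removed.
#' The claims of the surviving links form the final cohort extract.
#'
#' @param links current link table.
#' @param resolution output of [integrate_final_ppn()].
#' @param claims claims table.
#' @param view current [active_view()].
#' @param ledger a [ledger_new()] object.
#' @return list: updated `links` (statuses `removed_S22` added),
#'   `multi_patid` assessment table, and `claims_extract`.
#' @export
check_multi_patid <- function(links, resolution, claims, view, ledger) {
  links <- copy(links)
  excl <- excluded_persons(ledger)
  links[status == "accepted" & mum_ppn %in% excl, status := "removed_S22"]
  acc <- merge(links[status == "accepted"], resolution[, .(mum_ppn, final_ppn)],
               by = "mum_ppn")
  multi <- acc[, .(n_patid = uniqueN(patid)), by = final_ppn][n_patid >= 2L, final_ppn]
  out <- list()
  for (f in multi) {
    sub <- acc[final_ppn == f]
    cb <- claims[patid %in% sub$patid]
    ok_dob <- cb[, uniqueN(year_of_birth, na.rm = TRUE) <= 1L &
                   uniqueN(month_of_birth, na.rm = TRUE) <= 1L]
    par <- view$perinatal[mum_ppn %in% sub$mum_ppn & birth_order == 1L][
      order(baby_dob), parity]
    ok_par <- classify_parity_sequence(par) != "illogical"
    if (!ok_dob || !ok_par) {
      ledger_flag(ledger, "person", unique(sub$mum_ppn), "exclusion", "S22.2",
                  reason_code = if (!ok_dob) "inconsistent_claim_dob" else
                    "illogical_parity")
      links[status == "accepted" & mum_ppn %in% sub$mum_ppn, status := "removed_S22"]
      out[[f]] <- data.table(final_ppn = f, n_patid = uniqueN(sub$patid),
                             disposition = "excluded")
    } else {
      out[[f]] <- data.table(final_ppn = f, n_patid = uniqueN(sub$patid),
                             disposition = "retained")
    }
  }
  keep_pat <- links[status == "accepted", unique(patid)]
  list(
    links = links,
    multi_patid = if (length(out)) rbindlist(out) else
      data.table(final_ppn = character(), n_patid = integer(),
                 disposition = character()),
    claims_extract = claims[patid %in% keep_pat]
  )
}
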