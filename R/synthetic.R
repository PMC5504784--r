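# Synthetic two-jurisdiction linked cohort.
#
# The generator emulates the structure the protocol expects: a
# mother -> pregnancy -> baby hierarchy in two jurisdictions (A and B), one
# perinatal record per baby, a maternal delivery admission spanning each
# birth, a newborn admission per baby, extra hospital/ED contacts, death
# registrations, pharmaceutical claims keyed by a national PATID, and
# per-jurisdiction PATID<->mumPPN mapping tables with probabilistic match
# weights (accepted links at/above the jurisdiction threshold plus
# sub-threshold decoys down to weight 17). Clean draws satisfy every
# protocol rule by construction; errors enter only through inject_errors().

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a plausible perinatal population: parity distribution
#' over 1-6 pregnancies per mother, ~3% plural pregnancies, gestation
#' centred on 39 completed weeks (plural pregnancies earlier),
#' gestation-dependent birthweight within 400-5000 g, strictly positive
#' inter-pregnancy intervals, and match weights at or above the recommended
#' acceptance thresholds (29 in jurisdiction A, 28 in B) with sub-threshold
#' decoy links drawn in [17, threshold).
#'
#' @param n_mothers_per_jurisdiction women initially generated per
#'   jurisdiction.
#' @param pregnancy_dist probabilities for 1..6 pregnancies per mother.
#' @param plurality_dist probabilities for 1..3 babies per pregnancy.
#' @param cross_state_mother_rate probability a woman delivers in both
#'   jurisdictions (she then carries one person number per jurisdiction and
#'   a single national PATID).
#' @param mother_extra_rate,baby_extra_rate Poisson means for additional
#'   hospital/ED contacts per person.
#' @param baby_death_rate,mother_death_rate probabilities of a registered
#'   death inside the observation window.
#' @param claims_mean Poisson mean for claims beyond the first per woman.
#' @param decoy_link_rate probability of one sub-threshold decoy link per
#'   woman.
#' @param congenital_rate probability a jurisdiction-A baby has a
#'   congenital-condition notification.
#' @param weight_thresholds named acceptance thresholds per jurisdiction.
#' @param seed integer seed; the full cohort is a pure function of the
#'   configuration.
#' @return a `perilink_cohort_config` list.
#' @export
cohort_config <- function(n_mothers_per_jurisdiction = 500,
                          pregnancy_dist = c(0.30, 0.35, 0.20, 0.10, 0.04, 0.01),
                          plurality_dist = c(0.97, 0.028, 0.002),
                          cross_state_mother_rate = 0.01,
                          mother_extra_rate = 0.8,
                          baby_extra_rate = 0.6,
                          baby_death_rate = 0.004,
                          mother_death_rate = 0.002,
                          claims_mean = 3,
                          decoy_link_rate = 0.05,
                          congenital_rate = 0.01,
                          weight_thresholds = c(A = 29, B = 28),
                          seed = 1L) {
  cfg <- list(
    n_mothers_per_jurisdiction = as.integer(n_mothers_per_jurisdiction),
    pregnancy_dist = pregnancy_dist / sum(pregnancy_dist),
    plurality_dist = plurality_dist / sum(plurality_dist),
    cross_state_mother_rate = cross_state_mother_rate,
    mother_extra_rate = mother_extra_rate,
    baby_extra_rate = baby_extra_rate,
    baby_death_rate = baby_death_rate,
    mother_death_rate = mother_death_rate,
    claims_mean = claims_mean,
    decoy_link_rate = decoy_link_rate,
    congenital_rate = congenital_rate,
    weight_thresholds = weight_thresholds,
    seed = as.integer(seed)
  )
  if (cfg$n_mothers_per_jurisdiction < 1L) stop("need at least one mother per jurisdiction")
  if (length(cfg$pregnancy_dist) != 6L || any(cfg$pregnancy_dist < 0)) {
    stop("pregnancy_dist must be 6 non-negative probabilities")
  }
  rates <- unlist(cfg[c("cross_state_mother_rate", "baby_death_rate",
                        "mother_death_rate", "decoy_link_rate", "congenital_rate")])
  if (any(rates < 0 | rates > 1)) stop("rates must be probabilities")
  if (!all(c("A", "B") %in% names(cfg$weight_thresholds))) {
    stop("weight_thresholds must name jurisdictions A and B")
  }
  structure(cfg, class = "perilink_cohort_config")
}

#' Generate a clean two-jurisdiction linked cohort
#'
#' Produces the full set of source tables. A clean cohort raises no
#' exclusion, duplicate or deletion flag in the pipeline: parity increases
#' by exactly one per pregnancy from zero, inter-pregnancy intervals are
#' positive, every date ordering the protocol checks holds, each woman maps
#' to exactly one PATID at or above the acceptance threshold, and
#' cross-jurisdiction women carry consistent records in both states.
#'
#' @param config a [cohort_config()].
#' @return named list with the six source tables, an empty `truth` table,
#'   and a `meta` element (per-woman summary including intended cross-state
#'   groupings, used by tests and by [inject_errors()]).
#' @export
generate_clean_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "perilink_cohort_config"))
  .with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n_per <- cfg$n_mothers_per_jurisdiction
  n_women <- 2L * n_per
  women <- data.table(
    woman_id = seq_len(n_women),
    home = rep(c("A", "B"), each = n_per)
  )
  women[, cross := runif(.N) < cfg$cross_state_mother_rate]
  women[, n_preg := sample(1:6, .N, replace = TRUE, prob = cfg$pregnancy_dist)]
  women[cross == TRUE, n_preg := pmax(n_preg, 2L)]
  # age 18-42 at first delivery; month/day of the mother's own birth
  women[, mob := sample(1:12, .N, replace = TRUE)]
  women[, mday := sample(1:28, .N, replace = TRUE)]

  # pregnancies -------------------------------------------------------------
  preg <- women[rep(seq_len(.N), n_preg),
                .(woman_id, home, cross, n_preg)]
  preg[, preg_index := seq_len(.N), by = woman_id]
  preg[, plurality := sample(1:3, .N, replace = TRUE, prob = cfg$plurality_dist)]
  preg[, ga := ifelse(plurality == 1L,
                      round(rnorm(.N, 39, 1.8)), round(rnorm(.N, 36.5, 2.2)))]
  preg[, ga := as.integer(.clip(ga, 25L, 43L))]
  first_dob <- as.Date("2003-01-01") + sample(0:3100, n_women, replace = TRUE)
  preg[, dob := first_dob[woman_id]]
  # sequential deliveries with strictly positive pregnancy intervals:
  # next_dob = prior_dob + interval + ga*7 - 7, interval drawn positive
  preg[, interval := sample(90:1000, .N, replace = TRUE)]
  preg[, offset := ifelse(preg_index == 1L, 0L, interval + ga * 7L - 7L)]
  preg[, dob := dob + cumsum(as.numeric(offset)), by = woman_id]
  preg[, parity := preg_index - 1L]
  # cross-state women deliver their first `cut` pregnancies at home
  preg[, cut := n_preg]
  cross_ids <- women[cross == TRUE, woman_id]
  if (length(cross_ids)) {
    cuts <- vapply(women[cross == TRUE, n_preg],
                   function(k) sample(seq_len(k - 1L), 1L), integer(1))
    preg[woman_id %in% cross_ids,
         cut := rep(cuts, times = women[cross == TRUE, n_preg])]
  }
  preg[, jurisdiction := ifelse(preg_index <= cut, home,
                                ifelse(home == "A", "B", "A"))]
  preg[, mum_ppn := sprintf("%s-M%05d", jurisdiction, woman_id)]
  preg[, pregnancy_id := .I]
  # mother year of birth from age at first delivery
  women[, age1 := sample(18:42, .N, replace = TRUE)]
  women[, yob := as.integer(format(first_dob[woman_id], "%Y")) - age1]
  women[, mother_dob := as.Date(sprintf("%d-%02d-%02d", yob, mob, mday))]
  preg[, yob := women$yob[woman_id]]

  # babies ------------------------------------------------------------------
  babies <- preg[rep(seq_len(.N), plurality),
                 .(pregnancy_id, woman_id, jurisdiction, mum_ppn, dob, ga,
                   plurality, parity, preg_index, yob)]
  babies[, birth_order := seq_len(.N), by = pregnancy_id]
  babies[, baby_ppn := sprintf("%s-B%06d", jurisdiction, .I)]
  babies[, bw := as.integer(.clip(round(rnorm(.N, 3450 - 160 * (40 - ga), 330)),
                                  400L, 5000L))]
  babies[, apgar5 := sample(7:10, .N, replace = TRUE, prob = c(.05, .15, .35, .45))]
  babies[, sex := sample(c("female", "male"), .N, replace = TRUE)]

  perinatal <- babies[, .(
    jurisdiction, mum_ppn, baby_ppn, baby_dob = dob, gestational_age = ga,
    birthweight = bw, parity, plurality, birth_order,
    mother_yob = yob,
    mother_age = as.integer(format(dob, "%Y")) - yob,
    apgar5, discharge_status = "home",
    postcode = sprintf("%s%03d", ifelse(jurisdiction == "A", "2", "6"),
                       sample(0:999, nrow(babies), replace = TRUE)),
    country_of_birth = sample(c("AUS", "NZL", "GBR", "CHN", "IND"),
                              nrow(babies), replace = TRUE,
                              prob = c(.7, .08, .08, .07, .07)),
    hospital = sprintf("%sH%02d", jurisdiction, sample(1:20, nrow(babies), replace = TRUE))
  )]
  setorder(perinatal, jurisdiction, mum_ppn, baby_dob, birth_order, baby_ppn)
  perinatal[, record_id := sprintf("P-%06d", .I)]

  # encounters --------------------------------------------------------------
  mk_enc <- function(jur, ppn, role, source, adm, sep, pdob, pyob, page, sex,
                     mob, proc = "", deliv = FALSE, status = "home") {
    data.table(jurisdiction = jur, ppn = ppn, role = role, source = source,
               admission_date = adm, separation_date = sep, patient_dob = pdob,
               patient_yob = as.integer(pyob), patient_age = as.integer(page),
               patient_sex = sex, month_of_birth = as.integer(mob),
               procedure_codes = proc, is_delivery = deliv,
               discharge_status = status)
  }
  # one maternal delivery admission per pregnancy, spanning the delivery
  mat_del <- preg[, {
    adm <- dob - sample(0:2, .N, replace = TRUE)
    sep <- dob + sample(1:5, .N, replace = TRUE)
    mk_enc(jurisdiction, mum_ppn, "mother", "hospital", adm, sep,
           women$mother_dob[woman_id], yob,
           as.integer(format(adm, "%Y")) - yob, "female",
           women$mob[woman_id], deliv = TRUE)
  }]
  # one newborn admission per baby
  baby_birth <- babies[, {
    sep <- dob + sample(1:7, .N, replace = TRUE)
    mk_enc(jurisdiction, baby_ppn, "baby", "hospital", dob, sep, dob,
           as.integer(format(dob, "%Y")), 0L, sex,
           as.integer(format(dob, "%m")))
  }]
  # additional mother contacts (home jurisdiction)
  n_extra_m <- rpois(n_women, cfg$mother_extra_rate)
  em <- women[rep(seq_len(.N), n_extra_m)]
  extra_m <- if (nrow(em)) {
    adm <- as.Date("2003-01-01") + sample(0:3800, nrow(em), replace = TRUE)
    em[, mk_enc(home, sprintf("%s-M%05d", home, woman_id),
                "mother", sample(c("hospital", "ed"), .N, replace = TRUE),
                adm, adm + sample(0:3, .N, replace = TRUE), mother_dob, yob,
                as.integer(format(adm, "%Y")) - yob, "female", mob)]
  } else NULL
  # additional baby contacts
  n_extra_b <- rpois(nrow(babies), cfg$baby_extra_rate)
  eb <- babies[rep(seq_len(.N), n_extra_b)]
  extra_b <- if (nrow(eb)) {
    adm <- eb$dob + sample(10:800, nrow(eb), replace = TRUE)
    eb[, mk_enc(jurisdiction, baby_ppn, "baby",
                sample(c("hospital", "ed"), .N, replace = TRUE),
                adm, adm + sample(0:2, .N, replace = TRUE), dob,
                as.integer(format(dob, "%Y")),
                as.integer(format(adm, "%Y")) - as.integer(format(dob, "%Y")),
                sex, as.integer(format(dob, "%m")))]
  } else NULL

  # deaths ------------------------------------------------------------------
  babies[, dead := runif(.N) < cfg$baby_death_rate]
  # dead newborns die in hospital: death = separation of the birth admission,
  # discharge status deceased, and no later contacts
  dead_idx <- which(babies$dead)
  if (length(dead_idx)) {
    baby_birth[dead_idx, discharge_status := "deceased"]
    if (!is.null(extra_b)) extra_b <- extra_b[!ppn %in% babies$baby_ppn[dead_idx]]
  }
  baby_deaths <- if (length(dead_idx)) {
    data.table(jurisdiction = babies$jurisdiction[dead_idx],
               ppn = babies$baby_ppn[dead_idx],
               date_of_death = baby_birth$separation_date[dead_idx],
               stream = "registration")
  } else NULL

  # claims ------------------------------------------------------------------
  women[, patid := sprintf("PAT%06d", woman_id)]
  n_claims <- 1L + rpois(n_women, cfg$claims_mean)
  cl <- women[rep(seq_len(.N), n_claims)]
  claims <- cl[, .(
    patid,
    date_of_supply = as.Date("2003-01-01") + sample(0:3800, nrow(cl), replace = TRUE),
    item_code = sprintf("ITM%03d", sample(1:50, nrow(cl), replace = TRUE)),
    month_of_birth = mob, year_of_birth = yob
  )]

  # mother deaths: non-cross women only, registered after every recorded
  # contact, delivery and claim
  women[, dead := runif(.N) < cfg$mother_death_rate & !cross]
  mother_deaths <- NULL
  mdead <- women[dead == TRUE]
  if (nrow(mdead)) {
    last_event <- vapply(mdead$woman_id, function(w) {
      pp <- sprintf("%s-M%05d", women$home[w], w)
      ev <- c(mat_del[ppn == pp, as.numeric(separation_date)],
              if (!is.null(extra_m)) extra_m[ppn == pp, as.numeric(separation_date)],
              preg[woman_id == w, as.numeric(dob)],
              claims[patid == women$patid[w], as.numeric(date_of_supply)])
      max(ev)
    }, numeric(1))
    mother_deaths <- data.table(
      jurisdiction = mdead$home,
      ppn = sprintf("%s-M%05d", mdead$home, mdead$woman_id),
      date_of_death = as.Date(last_event, origin = "1970-01-01") +
        sample(10:200, nrow(mdead), replace = TRUE),
      stream = "registration")
  }
  deaths <- rbindlist(list(baby_deaths, mother_deaths))
  if (!nrow(deaths)) {
    deaths <- data.table(jurisdiction = character(), ppn = character(),
                         date_of_death = as.Date(character()), stream = character())
  }
  setorder(deaths, jurisdiction, ppn, date_of_death)
  deaths[, record_id := sprintf("D-%05d", .I)]

  encounters <- rbindlist(list(mat_del, baby_birth, extra_m, extra_b))
  # two independently drawn contacts can coincide on every field; collapse
  # them so clean data carries no identical duplicates
  encounters <- unique(encounters)
  setorder(encounters, jurisdiction, ppn, admission_date, separation_date, source)
  encounters[, record_id := sprintf("%s-%06d", ifelse(source == "hospital", "H", "E"), .I)]

  # congenital notifications (jurisdiction A babies), matching perinatal
  cong_idx <- which(babies$jurisdiction == "A" & runif(nrow(babies)) < cfg$congenital_rate)
  congenital <- data.table(
    record_id = character(), baby_ppn = character(),
    baby_dob = as.Date(character()), birthweight = integer())
  if (length(cong_idx)) {
    congenital <- data.table(baby_ppn = babies$baby_ppn[cong_idx],
                             baby_dob = babies$dob[cong_idx],
                             birthweight = babies$bw[cong_idx])
    setorder(congenital, baby_ppn)
    congenital[, record_id := sprintf("C-%05d", .I)]
  }

  setorder(claims, patid, date_of_supply, item_code)
  claims[, claim_id := sprintf("S-%07d", .I)]

  # mapping tables: one accepted link per woman per jurisdiction of use,
  # plus sub-threshold decoys exercising the extraction filter
  jur_ppn <- unique(preg[, .(woman_id, jurisdiction, mum_ppn)])
  thr <- cfg$weight_thresholds
  mapping <- jur_ppn[, .(
    patid = women$patid[woman_id], mum_ppn, jurisdiction,
    weight = round(thr[jurisdiction] + runif(nrow(jur_ppn), 0, 12), 1)
  )]
  decoy <- jur_ppn[runif(nrow(jur_ppn)) < cfg$decoy_link_rate]
  if (nrow(decoy)) {
    pool <- split(jur_ppn$woman_id, jur_ppn$jurisdiction)
    other <- vapply(seq_len(nrow(decoy)), function(i) {
      cand <- setdiff(pool[[decoy$jurisdiction[i]]], decoy$woman_id[i])
      if (length(cand)) sample(cand, 1L) else NA_integer_
    }, integer(1))
    decoy <- decoy[!is.na(other)]
    other <- other[!is.na(other)]
    if (nrow(decoy)) {
      dec <- data.table(patid = women$patid[other], mum_ppn = decoy$mum_ppn,
                        jurisdiction = decoy$jurisdiction,
                        weight = round(runif(nrow(decoy), 17, thr[decoy$jurisdiction] - 0.1), 1))
      mapping <- rbind(mapping, dec)
      mapping <- unique(mapping, by = c("patid", "mum_ppn"))
    }
  }
  setorder(mapping, jurisdiction, patid, mum_ppn)

  meta <- women[, .(woman_id, home, cross, n_preg, yob, mob, patid,
                    mother_dead = dead)]
  meta <- merge(meta,
                preg[, .(ppns = paste(sort(unique(mum_ppn)), collapse = ";")),
                     by = woman_id],
                by = "woman_id")

  truth <- .empty_truth()
  cols <- function(dt, what) as_source_table(dt, what)
  list(
    perinatal = cols(perinatal, "perinatal"),
    encounters = cols(encounters, "encounters"),
    deaths = cols(deaths, "deaths"),
    congenital = cols(congenital, "congenital"),
    claims = cols(claims, "claims"),
    mapping = cols(mapping, "mapping"),
    truth = truth,
    meta = meta
  )
}

.empty_truth <- function() {
  data.table(error_class = character(), target_type = character(),
             target_id = character(), mum_ppn = character(),
             expected_flag = character(), expected_step = character())
}
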