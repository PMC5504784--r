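#' Estimated date of conception
#'
#' Estimates the date of conception from the baby's date of birth and the
#' gestational age in completed weeks, as `baby_dob - 7 * weeks + 14` days.
#' The two-week offset reflects gestational age being counted from the last
#' menstrual period rather than from conception.
#'
#' @param baby_dob `Date` vector, the baby's date of birth (date of delivery).
#' @param gestational_age integer vector, completed weeks of gestation.
#'   Missing values yield `NA` (the downstream interval check treats the
#'   pair as not assessable).
#' @return `Date` vector of estimated conception dates.
#' @examples
#' conception_date(as.Date("2010-03-15"), 40) # 2009-06-22
#' @export
conception_date <- function(baby_dob, gestational_age) {
  baby_dob <- as.Date(baby_dob)
  ga <- as.integer(gestational_age)
  if (any(!is.na(ga) & ga < 0L)) {
    stop("gestational_age must be >= 0 completed weeks")
  }
  baby_dob - ga * 7L + 14L
}

#' Interval between two consecutive pregnancies
#'
#' Days between the estimated conception of the later pregnancy and the
#' delivery date of the earlier one, minus a 7-day allowance for gestation
#' being recorded in completed (i.e. truncated) weeks:
#' `conception_date(next_baby_dob, next_gestation) - prior_delivery - 7`.
#' A negative interval means the later child was conceived before the
#' earlier child was delivered, which is biologically impossible for one
#' woman and indicates a false positive link.
#'
#' @param prior_delivery `Date`, delivery date of the earlier pregnancy.
#' @param next_baby_dob `Date`, delivery date of the later pregnancy.
#' @param next_gestation integer, completed weeks of gestation of the later
#'   pregnancy; `NA` makes the interval not assessable (`NA` returned).
#' @return integer vector of days; may be negative.
#' @examples
#' pregnancy_interval(as.Date("2008-01-10"), as.Date("2009-01-05"), 38) # 102
#' @export
pregnancy_interval <- function(prior_delivery, next_baby_dob, next_gestation) {
  conc <- conception_date(next_baby_dob, next_gestation)
  as.integer(conc - as.Date(prior_delivery)) - 7L
}
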