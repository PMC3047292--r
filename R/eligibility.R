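#' Demographic strata used throughout the package
#'
#' The five sex-by-age strata of the study's net sample: women enter at 60,
#' men at 70, and each sex is banded at 80 (women additionally at 70).
#'
#' @format A character vector of stratum labels.
#' @export
cta_strata <- c("F60-69", "F70-79", "F80+", "M70-79", "M80+")

#' Completed age in whole years
#'
#' Whole years elapsed between `birth_date` and `reference_date`, i.e. the
#' usual "age at last birthday". A birthday on Feb 29 counts as completed on
#' Mar 1 in non-leap years.
#'
#' @param birth_date,reference_date `Date` vectors (recycled to a common
#'   length). `reference_date` must not precede `birth_date`.
#' @return Integer vector of completed ages.
#' @export
completed_age <- function(birth_date, reference_date) {
  birth_date <- as.Date(birth_date)
  reference_date <- as.Date(reference_date)
  n <- max(length(birth_date), length(reference_date))
  birth_date <- rep_len(birth_date, n)
  reference_date <- rep_len(reference_date, n)
  if (any(reference_date < birth_date, na.rm = TRUE)) {
    rlang::abort("`reference_date` precedes `birth_date`", class = "cta_invalid_input")
  }
  yr <- function(d) as.integer(format(d, "%Y"))
  md <- function(d) as.integer(format(d, "%m")) * 100L + as.integer(format(d, "%d"))
  yr(reference_date) - yr(birth_date) - as.integer(md(reference_date) < md(birth_date))
}

#' Net-sample inclusion rule
#'
#' A patient belongs to the population at risk (net sample) if she is a woman
#' with completed age >= 60, or a man with completed age >= 70, at the
#' reference date. Age is evaluated at each EPR-opening, so patients crossing
#' a threshold mid-study enter the net sample at their next visit.
#'
#' @param sex Character vector, `"F"` or `"M"`.
#' @param birth_date,reference_date `Date` vectors.
#' @return Logical vector.
#' @examples
#' in_net_sample("F", as.Date("1947-05-01"), as.Date("2007-05-01")) # exactly 60
#' @export
in_net_sample <- function(sex, birth_date, reference_date) {
  sex <- check_sex(sex)
  age <- completed_age(birth_date, reference_date)
  (sex == "F" & age >= 60L) | (sex == "M" & age >= 70L)
}

#' Age band of a net-sample patient
#'
#' Maps sex and completed age to one of the five study strata
#' (see [cta_strata]). Patients below the inclusion threshold map to `NA`.
#'
#' @inheritParams in_net_sample
#' @return Character vector of stratum labels, `NA` outside the net sample.
#' @export
age_band <- function(sex, birth_date, reference_date) {
  sex <- check_sex(sex)
  age <- completed_age(birth_date, reference_date)
  dplyr::case_when(
    sex == "F" & age >= 80L ~ "F80+",
    sex == "F" & age >= 70L ~ "F70-79",
    sex == "F" & age >= 60L ~ "F60-69",
    sex == "M" & age >= 80L ~ "M80+",
    sex == "M" & age >= 70L ~ "M70-79",
    .default = NA_character_
  )
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !is.na(sex) & !sex %in% c("F", "M")
  if (any(bad)) {
    rlang::abort(
      paste0("`sex` must be \"F\" or \"M\"; got ", paste(unique(sex[bad]), collapse = ", ")),
      class = "cta_invalid_input"
    )
  }
  sex
}
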