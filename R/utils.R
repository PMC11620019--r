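#' @noRd
UCD_REGEX <- "^[0-9]{13}$"

RELATION_LEVELS <- c("p_inhib", "p_induc", "mutation")
STATUS_LEVELS <- c("below", "in_range", "above", "unknown")

#' Canonicalize a substance label
#'
#' Trims surrounding whitespace and upper-cases, so that mixed-case spellings
#' of the same molecule ("Flecainid", "FLECAINID") compare equal. All label
#' comparisons in the package (self-interaction removal, analyte mapping)
#' operate on canonical labels.
#'
#' @param x character vector of labels.
#' @return character vector of canonical labels.
#' @export
#' @examples
#' canonical_label(c("  Flecainid ", "FLECAINID"))
canonical_label <- function(x) {
  toupper(stringr::str_squish(x))
}

#' Test for valid 13-digit dispensing (UCD) codes
#'
#' A UCD (unite commune de dispensation) code is a string of exactly 13
#' decimal digits. Check digits are not verified.
#'
#' @param x character vector.
#' @return logical vector.
#' @export
is_ucd_code <- function(x) {
  !is.na(x) & grepl(UCD_REGEX, x)
}

#' Coerce a study period to a two-date interval
#'
#' @param period length-2 vector coercible to `Date` (start, end), start <= end.
#' @return a `Date` vector of length 2.
#' @export
as_period <- function(period) {
  p <- tryCatch(as.Date(period), error = function(e) NA)
  if (length(p) != 2L || anyNA(p)) {
    abort("`period` must be two parseable dates c(start, end).",
          class = "cypddi_config_error")
  }
  if (p[1] > p[2]) {
    abort(sprintf("period start (%s) is after period end (%s).", p[1], p[2]),
          class = "cypddi_config_error")
  }
  p
}

# first day of the bin containing each date
floor_bin <- function(day, bin) {
  switch(bin,
    day = day,
    week = day - (as.integer(format(day, "%u")) - 1L),  # ISO week, Monday
    month = as.Date(format(day, "%Y-%m-01"))
  )
}

# completed years between birth and a reference date
age_years <- function(birth, at) {
  b <- as.POSIXlt(birth)
  a <- as.POSIXlt(at)
  age <- a$year - b$year
  not_yet <- a$mon < b$mon | (a$mon == b$mon & a$mday < b$mday)
  age - as.integer(not_yet)
}

# stable, portable content hash used in run reports
config_hash <- function(x) {
  rlang::hash(x)
}
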