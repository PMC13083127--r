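# Shared small helpers: name normalization, FAERS date handling, banding.

#' Normalize a drug-name string for matching
#'
#' Lower-cases, trims, collapses internal whitespace and strips leading /
#' trailing punctuation, so that e.g. `"  Mk-3475 "` matches `"mk-3475"`.
#'
#' @param x character vector of raw names.
#' @return character vector of normalized names (`NA` stays `NA`).
#' @export
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("^[[:punct:][:space:]]+", "", x)
  x <- gsub("[[:punct:][:space:]]+$", "", x)
  x[!nzchar(x)] <- NA_character_
  x
}

#' Precision of a FAERS 8-digit date field
#'
#' FAERS dates are written `YYYYMMDD`; partial dates (`YYYYMM`, `YYYY`) are
#' legal and flagged rather than dropped. Anything else (empty, malformed,
#' impossible calendar date) is `"missing"`.
#'
#' @param x character vector of raw date fields.
#' @return character vector in `c("day", "month", "year", "missing")`.
#' @export
faers_date_precision <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  out <- rep("missing", length(x))
  digits <- grepl("^[0-9]+$", x)
  out[digits & nchar(x) == 4] <- "year"
  out[digits & nchar(x) == 6] <- "month"
  is_day <- digits & nchar(x) == 8
  if (any(is_day)) {
    ok <- !is.na(as.Date(x[is_day], format = "%Y%m%d"))
    out[is_day][ok] <- "day"
  }
  out
}

#' Convert day-precision FAERS dates to `Date`
#'
#' Partial or missing dates become `NA`: downstream day-resolution analyses
#' (time to onset) must not silently use month- or year-precision values.
#'
#' @param x character vector of raw date fields.
#' @return `Date` vector.
#' @export
faers_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  day <- faers_date_precision(x) == "day"
  out[day] <- as.Date(trimws(as.character(x[day])), format = "%Y%m%d")
  out
}

# age_cod units -> years. Unknown codes are treated as missing, never guessed.
age_to_years <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(as.character(age_cod)))
  cod[is.na(cod) | !nzchar(cod)] <- "YR"
  factor_map <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
                  DY = 1 / 365.25, HR = 1 / (365.25 * 24))
  mult <- unname(factor_map[cod])
  years <- age * mult
  years[is.na(mult)] <- NA_real_
  years[!is.na(years) & (years < 0 | years > 130)] <- NA_real_
  years
}

# wt_cod units -> kilograms; KG assumed when the code is absent.
weight_to_kg <- function(wt, wt_cod) {
  wt <- suppressWarnings(as.numeric(wt))
  cod <- toupper(trimws(as.character(wt_cod)))
  cod[is.na(cod) | !nzchar(cod)] <- "KG"
  mult <- c(KG = 1, KGS = 1, LBS = 0.453592, LB = 0.453592, GMS = 0.001)[cod]
  kg <- wt * unname(mult)
  kg[is.na(mult)] <- NA_real_
  kg[!is.na(kg) & (kg <= 0 | kg > 500)] <- NA_real_
  kg
}

normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("M", "MALE")] <- "M"
  out[x %in% c("F", "FEMALE")] <- "F"
  out
}

#' Age bands used by the analyses
#'
#' `age_band2()` gives the two-level split used for stratified signal
#' detection and onset subgroups (>= 65 vs < 65). `age_band3()` gives the
#' mortality-model bands 18-44 (reference), 44-64, >= 65; the overlapping
#' boundary is resolved by assigning age 44 to "18-44". Ages outside the
#' bands (or missing) return `NA`.
#'
#' @param age_years numeric vector of ages in years.
#' @return character vector of band labels.
#' @export
age_band2 <- function(age_years) {
  ifelse(is.na(age_years), NA_character_,
         ifelse(age_years >= 65, ">=65", "<65"))
}

#' @rdname age_band2
#' @export
age_band3 <- function(age_years) {
  out <- rep(NA_character_, length(age_years))
  out[!is.na(age_years) & age_years >= 18 & age_years <= 44] <- "18-44"
  out[!is.na(age_years) & age_years > 44 & age_years < 65] <- "44-64"
  out[!is.na(age_years) & age_years >= 65] <- ">=65"
  out
}

#' Weight bands (< 50, 50-100 reference, > 100 kg)
#'
#' @param weight_kg numeric vector of body weights in kilograms.
#' @return character vector of band labels (`NA` when weight is missing).
#' @export
weight_band <- function(weight_kg) {
  out <- rep(NA_character_, length(weight_kg))
  out[!is.na(weight_kg) & weight_kg < 50] <- "<50"
  out[!is.na(weight_kg) & weight_kg >= 50 & weight_kg <= 100] <- "50-100"
  out[!is.na(weight_kg) & weight_kg > 100] <- ">100"
  out
}

yyyymmdd <- function(date) as.integer(format(date, "%Y%m%d"))
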