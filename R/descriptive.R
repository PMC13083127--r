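# Descriptive demographics of a report cohort.

tally_var <- function(values, variable, n_total) {
  values[is.na(values) | !nzchar(as.character(values))] <- "unknown"
  tab <- sort(table(values), decreasing = TRUE)
  tibble(variable = variable, level = names(tab),
         n = as.integer(tab),
         pct = round(100 * as.integer(tab) / n_total, 1))
}

#' Descriptive summary of a cohort
#'
#' Counts and percentages by reporting country, receipt year, sex, reporter
#' occupation, age band, weight band, and outcome. Missing values form an
#' explicit `"unknown"` level so every single-choice variable sums to the
#' cohort size (outcome rows count reports carrying the code, so a report
#' with several outcomes appears in several rows).
#'
#' @param cohort a `faers_cohort`.
#' @return tibble `variable`, `level`, `n`, `pct`.
#' @export
describe_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  cases <- cohort$cases
  n <- nrow(cases)
  if (n == 0) {
    return(tibble(variable = character(0), level = character(0),
                  n = integer(0), pct = numeric(0)))
  }
  year <- substr(cases$fda_dt, 1, 4)
  year[faers_date_precision(cases$fda_dt) == "missing"] <- NA
  out <- dplyr::bind_rows(
    tally_var(cases$country, "country", n),
    tally_var(year, "year", n),
    tally_var(ifelse(cases$sex == "unknown", NA, cases$sex), "sex", n),
    tally_var(cases$reporter, "reporter", n),
    tally_var(age_band3(cases$age_years), "age_band", n),
    tally_var(weight_band(cases$weight_kg), "weight_band", n))
  outc <- cohort$outcomes %>%
    dplyr::distinct(.data$primaryid, .data$outc_cod) %>%
    dplyr::count(.data$outc_cod)
  if (nrow(outc)) {
    outc_pct <- round(100 * outc$n / n, 1)
    out <- dplyr::bind_rows(out, tibble(
      variable = "outcome", level = outc$outc_cod,
      n = as.integer(outc$n), pct = outc_pct))
  }
  out
}
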