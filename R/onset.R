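# Time-to-onset: Kaplan-Meier medians with log-log CIs and log-rank tests.
#
# Spontaneous reports are events by construction, so all records enter as
# events (no censoring); the product-limit estimate then coincides with the
# empirical survivor function, and the 95% CI of the median comes from the
# Brookmeyer-Crowley inversion on the log(-log) scale (survival::survfit,
# conf.type = "log-log").

#' Compute per-case time to onset
#'
#' Time to onset is the whole-day difference between the earliest
#' day-precision therapy start date of the target drug and the report's
#' event date (date of the first reported adverse event). Records missing
#' either date, carrying only partial (month/year) precision, or yielding a
#' negative difference are excluded with a counted reason.
#'
#' @param cohort a `faers_cohort`.
#' @return tibble of onset records (`primaryid`, `caseid`, `tto_days`,
#'   `event` = 1, `sex`, `age_band`, `weight_band`) with the exclusion
#'   ledger in attribute `exclusions` (tibble `reason`, `n`).
#' @export
compute_tto <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  starts <- cohort$therapy %>%
    mutate(start_date = faers_date(.data$start_dt)) %>%
    filter(!is.na(.data$start_date))
  starts <- if (nrow(starts)) {
    starts %>%
      group_by(.data$primaryid) %>%
      summarise(start_date = min(.data$start_date), .groups = "drop")
  } else {
    tibble(primaryid = character(0), start_date = as.Date(character(0)))
  }
  cases <- cohort$cases %>%
    left_join(starts, by = "primaryid") %>%
    mutate(event_date = faers_date(.data$event_dt))

  reason <- dplyr::case_when(
    is.na(cases$start_date) ~ "missing_or_partial_start",
    cases$event_dt_precision == "missing" ~ "missing_event_date",
    cases$event_dt_precision != "day" ~ "partial_event_date",
    cases$event_date < cases$start_date ~ "negative_tto",
    TRUE ~ "kept")
  exclusions <- tibble(reason = c("missing_or_partial_start",
                                  "missing_event_date", "partial_event_date",
                                  "negative_tto")) %>%
    mutate(n = vapply(.data$reason, function(r) sum(reason == r), integer(1)))

  kept <- cases[reason == "kept", ]
  out <- tibble(
    primaryid = kept$primaryid,
    caseid = kept$caseid,
    tto_days = as.integer(kept$event_date - kept$start_date),
    event = 1L,
    sex = ifelse(kept$sex %in% c("M", "F"), kept$sex, NA_character_),
    age_band = age_band2(kept$age_years),
    weight_band = weight_band(kept$weight_kg))
  attr(out, "exclusions") <- exclusions
  out
}

#' Kaplan-Meier curve of onset times
#'
#' @param tto_days nonnegative onset times in days.
#' @param event event indicators (default all 1: no censoring).
#' @return tibble step function: `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_curve <- function(tto_days, event = rep(1L, length(tto_days))) {
  if (length(tto_days) == 0) stop("no onset records", call. = FALSE)
  fit <- survival::survfit(survival::Surv(tto_days, event) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         survival = fit$surv)
}

#' Kaplan-Meier median onset with 95% CI
#'
#' Median = smallest time with S(t) <= 0.5; the 95% CI is the
#' Brookmeyer-Crowley inversion using Greenwood variance on the log(-log)
#' scale. Unreachable bounds are `NA`.
#'
#' @inheritParams km_curve
#' @return one-row tibble `n`, `median_days`, `ci_low`, `ci_high`.
#' @export
km_median <- function(tto_days, event = rep(1L, length(tto_days))) {
  if (length(tto_days) == 0) stop("no onset records", call. = FALSE)
  fit <- survival::survfit(survival::Surv(tto_days, event) ~ 1,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  tibble(n = length(tto_days),
         median_days = unname(tab["median"]),
         ci_low = unname(tab["0.95LCL"]),
         ci_high = unname(tab["0.95UCL"]))
}

#' Log-rank test across subgroup levels
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance at each distinct event time, referred to chi-square with
#' (levels - 1) degrees of freedom.
#'
#' @param tto_days onset times in days.
#' @param group group labels (>= 2 non-empty levels; `NA` rows dropped).
#' @param event event indicators.
#' @return list `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(tto_days, group,
                         event = rep(1L, length(tto_days))) {
  keep <- !is.na(group)
  tto_days <- tto_days[keep]; group <- as.character(group[keep])
  event <- event[keep]
  levels <- unique(group)
  if (length(levels) < 2) {
    stop("log-rank needs >= 2 non-empty groups; got ",
         paste(levels, collapse = ", "), call. = FALSE)
  }
  sd_fit <- survival::survdiff(survival::Surv(tto_days, event) ~ group)
  df <- length(sd_fit$n) - 1
  list(statistic = unname(sd_fit$chisq), df = df,
       p_value = unname(pchisq(sd_fit$chisq, df, lower.tail = FALSE)))
}

#' Subgroup onset summary (median + CI per level, log-rank p per variable)
#'
#' For each grouping variable, records missing that variable are excluded
#' from that variable's rows only (per-variable deletion). Variables whose
#' observed data collapse to a single level get their rows with `p_value`
#' marked not applicable (`NA`).
#'
#' @param onset onset-record tibble from [compute_tto()].
#' @param variables grouping columns present in `onset`.
#' @return tibble `variable`, `level`, `n`, `median_days`, `ci_low`,
#'   `ci_high`, `p_value` (repeated within variable).
#' @export
onset_report <- function(onset, variables = c("age_band", "sex",
                                              "weight_band")) {
  stopifnot(all(variables %in% names(onset)))
  rows <- list()
  for (v in variables) {
    sub <- onset[!is.na(onset[[v]]), ]
    if (nrow(sub) == 0) next
    levs <- sort(unique(sub[[v]]))
    p <- if (length(levs) >= 2) {
      logrank_test(sub$tto_days, sub[[v]], sub$event)$p_value
    } else NA_real_
    for (lev in levs) {
      m <- km_median(sub$tto_days[sub[[v]] == lev],
                     sub$event[sub[[v]] == lev])
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(variable = v, level = lev), m, tibble(p_value = p))
    }
  }
  dplyr::bind_rows(rows)
}
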