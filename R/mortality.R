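# Univariable logistic modelling of the fatal outcome.
#
# One fit per covariate (no multivariable model): death (outcome code DE on
# the deduplicated report) against age band, sex, weight band, cumulative
# distinct-PT count, and time to the first adverse event. Categorical
# covariates are dummy-coded against fixed reference levels; odds ratios
# carry Wald 95% CIs (exp(beta +/- 1.96 se)) and Wald p-values.

MORTALITY_COVARIATES <- list(
  age_band = list(ref = "18-44", levels = c("18-44", "44-64", ">=65")),
  sex = list(ref = "male", levels = c("male", "female")),
  weight_band = list(ref = "50-100", levels = c("50-100", "<50", ">100")),
  cumulative_aes = NULL,
  tto_first_days = NULL)

#' Build the per-case mortality analysis table
#'
#' `death` is 1 iff the report's outcome codes include `DE`. Age is banded
#' 18-44 (reference) / 44-64 / >= 65 with age 44 assigned to "18-44";
#' weight is banded < 50 / 50-100 (reference) / > 100 kg; `cumulative_aes`
#' counts distinct PTs on the report; `tto_first_days` is the time to onset
#' from [compute_tto()] (missing where that record was excluded). Missing
#' covariates are kept `NA` here and dropped per-variable at fit time.
#'
#' @param cohort a `faers_cohort`.
#' @param onset optional onset tibble from [compute_tto()]; computed from
#'   the cohort when omitted.
#' @return tibble of mortality records.
#' @export
build_mortality_table <- function(cohort, onset = NULL) {
  stopifnot(inherits(cohort, "faers_cohort"))
  if (is.null(onset)) onset <- compute_tto(cohort)
  deaths <- unique(cohort$outcomes$primaryid[cohort$outcomes$outc_cod == "DE"])
  n_pts <- cohort$events %>%
    dplyr::distinct(.data$primaryid, .data$pt) %>%
    dplyr::count(.data$primaryid, name = "cumulative_aes")
  cohort$cases %>%
    left_join(n_pts, by = "primaryid") %>%
    left_join(onset[, c("primaryid", "tto_days")], by = "primaryid") %>%
    transmute(
      primaryid = .data$primaryid,
      caseid = .data$caseid,
      death = as.integer(.data$primaryid %in% deaths),
      age_band = age_band3(.data$age_years),
      sex = dplyr::case_when(.data$sex == "M" ~ "male",
                             .data$sex == "F" ~ "female",
                             TRUE ~ NA_character_),
      weight_band = weight_band(.data$weight_kg),
      cumulative_aes = dplyr::coalesce(.data$cumulative_aes, 0L),
      tto_first_days = .data$tto_days)
}

# crude separation screen: a Wald CI is meaningless when the MLE diverges
is_separated <- function(beta, se) {
  !is.finite(beta) | !is.finite(se) | abs(beta) > 15 | se > 100
}

#' Fit one univariable logistic regression on death
#'
#' Records missing the covariate are excluded from this fit only.
#' Categorical covariates are dummy-coded against their fixed reference
#' level; continuous covariates (`cumulative_aes`, `tto_first_days`) enter
#' untransformed, per unit. Complete separation is flagged (`note`
#' `"separation"`, CI `NA`), not raised as an error; an all-one-class
#' outcome is an error.
#'
#' @param records tibble from [build_mortality_table()].
#' @param covariate one of `"age_band"`, `"sex"`, `"weight_band"`,
#'   `"cumulative_aes"`, `"tto_first_days"`.
#' @return tibble, one row per non-reference level (or one row for a
#'   continuous covariate): `covariate`, `level`, `n`, `n_deaths`, `beta`,
#'   `se`, `or`, `ci_low`, `ci_high`, `p_value`, `note`.
#' @export
fit_univariable <- function(records, covariate) {
  if (!covariate %in% names(MORTALITY_COVARIATES)) {
    stop("unknown covariate: ", covariate, call. = FALSE)
  }
  spec <- MORTALITY_COVARIATES[[covariate]]
  dat <- records[!is.na(records[[covariate]]), c("death", covariate)]
  if (nrow(dat) == 0) stop("no usable records for ", covariate, call. = FALSE)
  if (length(unique(dat$death)) < 2) {
    stop("outcome has a single class after per-variable deletion", call. = FALSE)
  }
  if (!is.null(spec)) {
    dat[[covariate]] <- factor(dat[[covariate]],
                               levels = intersect(spec$levels,
                                                  unique(dat[[covariate]])))
    if (nlevels(dat[[covariate]]) < 2) {
      return(tibble(covariate = covariate,
                    level = levels(dat[[covariate]]),
                    n = nrow(dat), n_deaths = sum(dat$death),
                    beta = NA_real_, se = NA_real_, or = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    p_value = NA_real_, note = "single_level"))
    }
  }
  fml <- stats::as.formula(paste("death ~", covariate))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = dat,
                              control = stats::glm.control(epsilon = 1e-12,
                                                           maxit = 100)))
  cf <- summary(fit)$coefficients
  idx <- setdiff(rownames(cf), "(Intercept)")
  beta <- cf[idx, "Estimate"]
  se <- cf[idx, "Std. Error"]
  p <- cf[idx, "Pr(>|z|)"]
  sep <- is_separated(beta, se) | !fit$converged
  level <- if (is.null(spec)) "per unit" else sub(covariate, "", idx, fixed = TRUE)
  n_lev <- if (is.null(spec)) rep(nrow(dat), length(idx)) else
    vapply(level, function(l) sum(dat[[covariate]] == l), integer(1))
  d_lev <- if (is.null(spec)) rep(sum(dat$death), length(idx)) else
    vapply(level, function(l) sum(dat$death[dat[[covariate]] == l]), integer(1))
  tibble(covariate = covariate, level = level,
         n = as.integer(n_lev), n_deaths = as.integer(d_lev),
         beta = unname(beta), se = unname(se),
         or = exp(unname(beta)),
         ci_low = ifelse(sep, NA_real_, exp(unname(beta) - 1.96 * unname(se))),
         ci_high = ifelse(sep, NA_real_, exp(unname(beta) + 1.96 * unname(se))),
         p_value = ifelse(sep, NA_real_, unname(p)),
         note = ifelse(sep, "separation", ""))
}

#' Full univariable mortality report
#'
#' Runs [fit_univariable()] for every covariate and assembles the
#' conventional risk-factor table: reference rows marked with OR = 1 and no
#' CI, one row per non-reference level or continuous covariate, and a
#' significance star at p < 0.05.
#'
#' @param records tibble from [build_mortality_table()].
#' @return tibble `covariate`, `level`, `n`, `n_deaths`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `significant`, `note` (`"reference"` rows carry
#'   `or` = 1 and `NA` elsewhere).
#' @export
mortality_report <- function(records) {
  rows <- list()
  for (cov in names(MORTALITY_COVARIATES)) {
    spec <- MORTALITY_COVARIATES[[cov]]
    fit <- tryCatch(fit_univariable(records, cov), error = function(e) {
      tibble(covariate = cov, level = NA_character_, n = NA_integer_,
             n_deaths = NA_integer_, beta = NA_real_, se = NA_real_,
             or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             p_value = NA_real_, note = conditionMessage(e))
    })
    if (!is.null(spec)) {
      sub <- records[!is.na(records[[cov]]), ]
      ref <- tibble(covariate = cov, level = spec$ref,
                    n = sum(sub[[cov]] == spec$ref),
                    n_deaths = sum(sub$death[sub[[cov]] == spec$ref]),
                    beta = NA_real_, se = NA_real_, or = 1,
                    ci_low = NA_real_, ci_high = NA_real_,
                    p_value = NA_real_, note = "reference")
      fit <- dplyr::bind_rows(ref, fit)
    }
    rows[[cov]] <- fit
  }
  dplyr::bind_rows(rows) %>%
    mutate(significant = !is.na(.data$p_value) & .data$p_value < 0.05) %>%
    select("covariate", "level", "n", "n_deaths", "or", "ci_low", "ci_high",
           "p_value", "significant", "note")
}
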