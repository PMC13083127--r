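# Disproportionality statistics and signal screening.
#
# Counting unit: unique deduplicated reports, one PT counted once per
# report. For a (target drug, PT) pair:
#   a = cohort reports listing the PT         b = cohort reports without it
#   c = background reports listing the PT     d = background reports without it
# with the background = all deduplicated reports outside the cohort.

#' BCPNN prior hyperparameters
#'
#' The standard information-component priors: marginal Dirichlet/Beta
#' parameters `alpha_i = beta_j = 1`, `alpha = beta = 2`, joint `gamma_ij = 1`,
#' with the joint prior weight rescaled per table as
#' `gamma = gamma_ij * (N + alpha)(N + beta) / ((a+b+alpha_i)(a+c+beta_j))`,
#' which centres the prior on independence.
#'
#' @param alpha_i,beta_j,alpha,beta,gamma_ij strictly positive reals.
#' @return object of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(alpha_i = 1, beta_j = 1, alpha = 2, beta = 2,
                         gamma_ij = 1) {
  p <- list(alpha_i = alpha_i, beta_j = beta_j, alpha = alpha, beta = beta,
            gamma_ij = gamma_ij)
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "bcpnn_priors")
}

#' Positivity criteria for the three algorithms
#'
#' Defaults are the conventional thresholds: at least 3 co-reports for any
#' algorithm; ROR positive when the lower 95% CI bound exceeds 1; PRR
#' positive when PRR >= 2 and chi-square >= 4; BCPNN positive when
#' IC025 > 0. `consensus` controls the headline "positive PT" definition.
#'
#' @param min_a minimum `a` count gate shared by all three algorithms.
#' @param ror_low_gt ROR lower-CI threshold.
#' @param prr_ge,chi2_ge PRR and chi-square thresholds.
#' @param ic025_gt IC025 threshold.
#' @param consensus `"all"` (all three algorithms, default) or `"any"`.
#' @return object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_a = 3, ror_low_gt = 1, prr_ge = 2,
                            chi2_ge = 4, ic025_gt = 0,
                            consensus = c("all", "any")) {
  structure(list(min_a = min_a, ror_low_gt = ror_low_gt, prr_ge = prr_ge,
                 chi2_ge = chi2_ge, ic025_gt = ic025_gt,
                 consensus = match.arg(consensus)),
            class = "signal_criteria")
}

#' Disproportionality statistics for 2x2 contingency counts
#'
#' Vectorized over tables. Computes, per table:
#' * `ror = (a d) / (b c)` with 95% CI
#'   `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`;
#' * `prr = (a / (a + b)) / (c / (c + d))` with its analogous 95% CI and the
#'   Pearson chi-square
#'   `(ad - bc)^2 N / ((a+b)(a+c)(c+d)(b+d))` (no continuity correction);
#' * the information component `ic = log2(a N / ((a+b)(a+c)))` and the
#'   closed-form BCPNN posterior moments `e_ic`, `v_ic` under `priors`, with
#'   `ic025 = e_ic - 2 sqrt(v_ic)`.
#'
#' Zero cells: by default statistics whose formula divides by (or takes the
#' log of) a zero are returned `NA` with the matching `*_defined` flag set
#' `FALSE`; `zero_cell = "haldane"` instead adds 0.5 to every cell for the
#' frequentist statistics (the Bayesian moments are already regularized by
#' the priors and never need it).
#'
#' @param a,b,c,d nonnegative integer vectors of equal length.
#' @param priors a [bcpnn_priors()].
#' @param zero_cell `"flag"` (default) or `"haldane"`.
#' @return tibble with the counts, all statistics, and definedness flags.
#' @export
signal_metrics <- function(a, b, c, d, priors = bcpnn_priors(),
                           zero_cell = c("flag", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  stopifnot(length(a) == length(b), length(a) == length(c),
            length(a) == length(d))
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) stop("negative cell count")
  n <- a + b + c + d
  if (any(n <= 0)) stop("empty 2x2 table (N = 0)")

  if (zero_cell == "haldane") {
    ah <- a + 0.5; bh <- b + 0.5; ch <- c + 0.5; dh <- d + 0.5
  } else {
    ah <- a; bh <- b; ch <- c; dh <- d
  }
  nh <- ah + bh + ch + dh

  ror_defined <- ah > 0 & bh > 0 & ch > 0 & dh > 0
  ror <- ror_low <- ror_high <- rep(NA_real_, length(a))
  i <- ror_defined
  ror[i] <- (ah[i] * dh[i]) / (bh[i] * ch[i])
  se <- sqrt(1 / ah[i] + 1 / bh[i] + 1 / ch[i] + 1 / dh[i])
  ror_low[i] <- exp(log(ror[i]) - 1.96 * se)
  ror_high[i] <- exp(log(ror[i]) + 1.96 * se)

  prr_defined <- (ah + bh) > 0 & ch > 0 & (ch + dh) > 0
  prr <- prr_low <- prr_high <- rep(NA_real_, length(a))
  i <- prr_defined
  prr[i] <- (ah[i] / (ah[i] + bh[i])) / (ch[i] / (ch[i] + dh[i]))
  i <- prr_defined & ah > 0
  se <- sqrt(1 / ah[i] - 1 / (ah[i] + bh[i]) + 1 / ch[i] - 1 / (ch[i] + dh[i]))
  prr_low[i] <- exp(log(prr[i]) - 1.96 * se)
  prr_high[i] <- exp(log(prr[i]) + 1.96 * se)

  chi2_defined <- (ah + bh) > 0 & (ah + ch) > 0 & (ch + dh) > 0 & (bh + dh) > 0
  chi2 <- rep(NA_real_, length(a))
  i <- chi2_defined
  chi2[i] <- (ah[i] * dh[i] - bh[i] * ch[i])^2 * nh[i] /
    ((ah[i] + bh[i]) * (ah[i] + ch[i]) * (ch[i] + dh[i]) * (bh[i] + dh[i]))

  # point IC on the raw counts; posterior moments under the priors
  ic_defined <- a > 0 & (a + b) > 0 & (a + c) > 0
  ic <- rep(NA_real_, length(a))
  i <- ic_defined
  ic[i] <- log2(a[i] * n[i] / ((a[i] + b[i]) * (a[i] + c[i])))

  p <- priors
  gamma <- p$gamma_ij * (n + p$alpha) * (n + p$beta) /
    ((a + b + p$alpha_i) * (a + c + p$beta_j))
  e_ic <- log2((a + p$gamma_ij) * (n + p$alpha) * (n + p$beta) /
                 ((n + gamma) * (a + b + p$alpha_i) * (a + c + p$beta_j)))
  v_ic <- (1 / log(2))^2 * (
    (n - a + gamma - p$gamma_ij) / ((a + p$gamma_ij) * (1 + n + gamma)) +
    (n - a - b + p$alpha - p$alpha_i) /
      ((a + b + p$alpha_i) * (1 + n + p$alpha)) +
    (n - a - c + p$beta - p$beta_j) /
      ((a + c + p$beta_j) * (1 + n + p$beta)))
  ic025 <- e_ic - 2 * sqrt(v_ic)

  tibble(a = a, b = b, c = c, d = d,
         ror = ror, ror_low = ror_low, ror_high = ror_high,
         prr = prr, prr_low = prr_low, prr_high = prr_high, chi2 = chi2,
         ic = ic, e_ic = e_ic, v_ic = v_ic, ic025 = ic025,
         ror_defined = ror_defined, prr_defined = prr_defined,
         chi2_defined = chi2_defined, ic_defined = ic_defined)
}

apply_criteria <- function(metrics, criteria) {
  cr <- criteria
  metrics %>%
    mutate(
      ror_positive = .data$a >= cr$min_a & .data$ror_defined &
        .data$ror_low > cr$ror_low_gt,
      prr_positive = .data$a >= cr$min_a & .data$prr_defined &
        .data$chi2_defined & .data$prr >= cr$prr_ge & .data$chi2 >= cr$chi2_ge,
      bcpnn_positive = .data$a >= cr$min_a & .data$ic025 > cr$ic025_gt,
      all_three = .data$ror_positive & .data$prr_positive & .data$bcpnn_positive,
      positive = if (cr$consensus == "all") .data$all_three else
        (.data$ror_positive | .data$prr_positive | .data$bcpnn_positive))
}

#' Build the 2x2 table for one preferred term
#'
#' @param cohort a `faers_cohort`.
#' @param pt preferred term (exact string as it appears in REAC).
#' @return one-row tibble `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(cohort, pt) {
  stopifnot(inherits(cohort, "faers_cohort"))
  n_cohort <- nrow(cohort$cases)
  n_bg <- cohort$background$n_reports
  a <- sum(cohort$events$pt == pt)
  c_ <- sum(cohort$background$events$pt == pt)
  tibble(a = a, b = n_cohort - a, c = c_, d = n_bg - c_,
         n = n_cohort + n_bg)
}

#' Screen every cohort PT with the three algorithms
#'
#' One row per distinct PT occurring in the cohort, with counts, all three
#' statistics, per-algorithm positivity flags and the consensus flag.
#' Rows are ordered by frequency (`a`) and then by the strength key (the
#' ROR lower CI bound by default). The number of PTs tested is attached as
#' attribute `n_tested` for post-hoc multiplicity assessment (none is
#' applied here).
#'
#' @param cohort a `faers_cohort`.
#' @param criteria a [signal_criteria()].
#' @param priors a [bcpnn_priors()].
#' @param zero_cell passed to [signal_metrics()].
#' @param rank_by strength ranking key, a column name (default `"ror_low"`).
#' @return tibble of per-PT signal metrics and flags.
#' @export
detect_signals <- function(cohort, criteria = signal_criteria(),
                           priors = bcpnn_priors(),
                           zero_cell = c("flag", "haldane"),
                           rank_by = "ror_low") {
  stopifnot(inherits(cohort, "faers_cohort"))
  n_cohort <- nrow(cohort$cases)
  n_bg <- cohort$background$n_reports
  a_tab <- dplyr::count(cohort$events, .data$pt, name = "a")
  c_tab <- dplyr::count(cohort$background$events, .data$pt, name = "c_bg")
  counts <- a_tab %>%
    left_join(c_tab, by = "pt") %>%
    mutate(c_bg = dplyr::coalesce(.data$c_bg, 0L))
  out <- dplyr::bind_cols(
    counts["pt"],
    signal_metrics(counts$a, n_cohort - counts$a,
                   counts$c_bg, n_bg - counts$c_bg,
                   priors = priors, zero_cell = zero_cell)) %>%
    apply_criteria(criteria) %>%
    arrange(desc(.data$a), desc(.data[[rank_by]])) %>%
    mutate(freq_rank = dplyr::row_number())
  strength_ord <- order(-out[[rank_by]], out$pt)
  out$strength_rank <- match(seq_len(nrow(out)), strength_ord)
  attr(out, "n_tested") <- nrow(out)
  out
}

#' Roll signals up to System Organ Class level
#'
#' Pools PT counts to SOC using a user-supplied PT -> SOC map (MedDRA is
#' licensed and never bundled): `a_SOC` counts cohort reports with at least
#' one PT in the SOC (a report with two PTs of one SOC counts once), the
#' background analogously, and all three algorithms are recomputed on the
#' SOC-level tables. PTs absent from the map are excluded from SOC rows and
#' listed in the `unmapped_pts` attribute.
#'
#' @param cohort a `faers_cohort`.
#' @param pt_soc_map tibble/data.frame with columns `pt`, `soc`.
#' @param criteria,priors,zero_cell as in [detect_signals()].
#' @return tibble of per-SOC metrics and flags.
#' @export
aggregate_soc <- function(cohort, pt_soc_map, criteria = signal_criteria(),
                          priors = bcpnn_priors(),
                          zero_cell = c("flag", "haldane")) {
  stopifnot(inherits(cohort, "faers_cohort"))
  pt_soc_map <- as_tibble(pt_soc_map)
  if (!all(c("pt", "soc") %in% names(pt_soc_map)) || nrow(pt_soc_map) == 0) {
    stop("pt_soc_map must be a non-empty table with columns pt, soc",
         call. = FALSE)
  }
  map <- dplyr::distinct(pt_soc_map[, c("pt", "soc")])
  unmapped <- setdiff(unique(cohort$events$pt), map$pt)
  soc_count <- function(events) {
    events %>%
      inner_join(map, by = "pt") %>%
      dplyr::distinct(.data$primaryid, .data$soc) %>%
      dplyr::count(.data$soc)
  }
  a_tab <- soc_count(cohort$events) %>% rename(a = "n")
  c_tab <- soc_count(cohort$background$events) %>% rename(c_bg = "n")
  counts <- a_tab %>%
    left_join(c_tab, by = "soc") %>%
    mutate(c_bg = dplyr::coalesce(.data$c_bg, 0L))
  n_cohort <- nrow(cohort$cases)
  n_bg <- cohort$background$n_reports
  out <- dplyr::bind_cols(
    counts["soc"],
    signal_metrics(counts$a, n_cohort - counts$a,
                   counts$c_bg, n_bg - counts$c_bg,
                   priors = priors, zero_cell = zero_cell)) %>%
    apply_criteria(criteria) %>%
    arrange(desc(.data$a))
  attr(out, "unmapped_pts") <- unmapped
  out
}

# stratum labels for a minimal case table (cohort or background)
stratum_values <- function(cases, variable) {
  switch(variable,
    sex = ifelse(cases$sex %in% c("M", "F"), cases$sex, NA_character_),
    age_band = age_band2(cases$age_years),
    weight_band = weight_band(cases$weight_kg),
    stop("unknown stratum variable: ", variable, call. = FALSE))
}

#' Per-stratum signal detection
#'
#' Splits the cohort by a demographic variable (sex, two-level age band, or
#' weight band) and re-runs [detect_signals()] per level. By default the
#' background is restratified to the same level (cases missing the variable
#' are excluded from both sides and counted); `background = "global"` keeps
#' the full background as comparator in every level. The positive-PT sets
#' unique to each level and shared between levels are attached as the
#' `"comparison"` attribute.
#'
#' @param cohort a `faers_cohort`.
#' @param variable `"sex"`, `"age_band"`, or `"weight_band"`.
#' @param criteria,priors as in [detect_signals()].
#' @param background `"restratified"` (default) or `"global"`.
#' @return named list of per-level signal tibbles, with attributes
#'   `excluded` (cases missing the variable) and `comparison`.
#' @export
stratified_signals <- function(cohort, variable = c("sex", "age_band",
                                                    "weight_band"),
                               criteria = signal_criteria(),
                               priors = bcpnn_priors(),
                               background = c("restratified", "global")) {
  variable <- match.arg(variable)
  background <- match.arg(background)
  stopifnot(inherits(cohort, "faers_cohort"))
  co_lab <- stratum_values(cohort$cases, variable)
  bg_lab <- stratum_values(cohort$background$cases, variable)
  levels <- sort(unique(co_lab[!is.na(co_lab)]))
  out <- list()
  for (lev in levels) {
    co_ids <- cohort$cases$primaryid[!is.na(co_lab) & co_lab == lev]
    if (background == "restratified") {
      bg_ids <- cohort$background$cases$primaryid[!is.na(bg_lab) & bg_lab == lev]
    } else {
      bg_ids <- cohort$background$cases$primaryid
    }
    sub <- cohort
    sub$cases <- cohort$cases[cohort$cases$primaryid %in% co_ids, ]
    sub$events <- cohort$events[cohort$events$primaryid %in% co_ids, ]
    sub$background <- list(
      n_reports = length(bg_ids),
      cases = cohort$background$cases[
        cohort$background$cases$primaryid %in% bg_ids, ],
      events = cohort$background$events[
        cohort$background$events$primaryid %in% bg_ids, ])
    if (nrow(sub$cases) == 0) {
      warning("stratum level '", lev, "' has no cohort cases", call. = FALSE)
      out[[lev]] <- tibble()
      next
    }
    out[[lev]] <- detect_signals(sub, criteria = criteria, priors = priors)
  }
  pos <- lapply(out, function(t) if (nrow(t)) t$pt[t$positive] else character(0))
  comparison <- list(shared = Reduce(intersect, pos),
                     unique = lapply(seq_along(pos), function(i) {
                       setdiff(pos[[i]], unlist(pos[-i]))
                     }))
  names(comparison$unique) <- names(out)
  attr(out, "excluded") <- sum(is.na(co_lab))
  attr(out, "comparison") <- comparison
  out
}
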