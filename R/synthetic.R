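# Seeded synthetic-FAERS generator with planted, recoverable structure.
#
# The generator emits the seven-table quarterly structure the reader
# consumes, with known ground truth recorded in a ledger: planted
# (drug, PT) disproportionality with an exact odds-ratio target, a
# configurable onset-time distribution, a logistic death model, duplicate
# report versions, and field-level missingness.

#' Default synthetic PT vocabulary
#'
#' A synthetic MedDRA-like vocabulary: a core of checkpoint-inhibitor-style
#' adverse-event preferred terms mapped to organ-class labels, padded with
#' clearly synthetic filler terms so null-signal behaviour can be studied
#' over a few hundred PTs. This is generator-owned content, not a MedDRA
#' excerpt.
#'
#' @param n_pt total vocabulary size (>= 24).
#' @return tibble with columns `pt`, `soc`.
#' @export
sim_pt_vocabulary <- function(n_pt = 205) {
  core <- tibble(
    pt = c("Hypothyroidism", "Hyperthyroidism", "Adrenal insufficiency",
           "Hypopituitarism", "Immune-mediated hepatitis", "Cholangitis",
           "Hepatic encephalopathy", "Renal impairment",
           "Immune-mediated renal disorder", "Immune-mediated enterocolitis",
           "Diarrhoea", "Immune-mediated lung disease", "Pneumonia aspiration",
           "Immune-mediated myocarditis", "Atrioventricular block complete",
           "Immune-mediated dermatitis", "Rash", "Myelosuppression",
           "Neutrophil count decreased", "White blood cell count decreased",
           "Malignant neoplasm progression", "Cerebral infarction",
           "Myasthenia gravis", "Dermatomyositis"),
    soc = c("Endocrine disorders", "Endocrine disorders", "Endocrine disorders",
            "Endocrine disorders", "Hepatobiliary disorders",
            "Hepatobiliary disorders", "Hepatobiliary disorders",
            "Renal and urinary disorders", "Renal and urinary disorders",
            "Gastrointestinal disorders", "Gastrointestinal disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "Cardiac disorders", "Cardiac disorders",
            "Skin and subcutaneous tissue disorders",
            "Skin and subcutaneous tissue disorders",
            "Blood and lymphatic system disorders",
            "Investigations", "Investigations",
            "Neoplasms benign, malignant and unspecified",
            "Nervous system disorders", "Musculoskeletal disorders",
            "Musculoskeletal disorders"))
  stopifnot(n_pt >= nrow(core))
  n_fill <- n_pt - nrow(core)
  if (n_fill > 0) {
    socs <- unique(core$soc)
    fill <- tibble(
      pt = sprintf("Synthetic PT %03d", seq_len(n_fill)),
      soc = socs[(seq_len(n_fill) - 1L) %% length(socs) + 1L])
    core <- dplyr::bind_rows(core, fill)
  }
  core
}

#' Configuration for the synthetic-FAERS generator
#'
#' Defaults emulate the reported real-world conditions for a PD-1 inhibitor
#' in oesophageal-cancer immunotherapy: a male-dominated (about 80%
#' of known sex), elderly (about 70% of known ages >= 65) cohort, exponential
#' first-event onset with median 35 days, about 14% fatal and 22%
#' hospitalized outcomes, and heavy weight missingness typical of
#' spontaneous reports. Every probability is per-case/per-field.
#'
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param n_cases number of distinct cases (before duplicate versions).
#' @param target_drug canonical target drug label.
#' @param target_synonyms trade/generic/code names emitted (with random case
#'   and whitespace noise) in `drugname` for target entries.
#' @param indication_pt indication preferred term attached to every target
#'   case's primary-suspect entry.
#' @param p_exposed probability a case is a target-drug case.
#' @param n_background_drugs number of distinct comparator drugs.
#' @param pt_vocabulary tibble `pt`, `soc`; see [sim_pt_vocabulary()].
#' @param planted_signals tibble `pt`, `target_ror`: pairs whose
#'   report-level reporting odds ratio against the background is exactly
#'   `target_ror` in expectation.
#' @param baseline_pt_prob per-report probability of each PT in the
#'   background (and of non-planted PTs in the cohort).
#' @param duplicate_rate probability a case emits 2-3 report versions
#'   sharing `caseid` with strictly increasing `fda_dt`/`primaryid`.
#' @param onset_model list: `family` in `c("exponential","weibull","lognormal")`
#'   plus parameters (`median_days` for exponential; `shape`,`scale` for
#'   weibull; `meanlog`,`sdlog` for lognormal). Distribution of the case's
#'   first-event onset time, in days.
#' @param mortality_model named list of logistic coefficients on the death
#'   outcome: `intercept`, `age65`, `female`, `weight_low` (< 50 kg),
#'   `weight_high` (> 100 kg), `cumulative_aes` (per distinct PT),
#'   `tto_first_days` (per day).
#' @param missingness named list of per-field missingness probabilities:
#'   `age`, `sex`, `weight`, `event_dt`, `start_dt`, plus
#'   `event_dt_partial` (probability an observed event date is month-precision).
#' @param p_hospital probability of a hospitalization outcome row.
#' @param p_male probability of male sex among reports with known sex.
#' @param p_bg_indicated probability a background case carries the target
#'   indication (other-drug, same-disease reports).
#' @return validated `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       n_cases = 2000L,
                       target_drug = "pembrolizumab",
                       target_synonyms = c("pembrolizumab", "keytruda", "mk-3475"),
                       indication_pt = "Oesophageal cancer",
                       p_exposed = 0.10,
                       n_background_drugs = 25L,
                       pt_vocabulary = sim_pt_vocabulary(),
                       planted_signals = tibble(
                         pt = c("Immune-mediated hepatitis", "Renal impairment",
                                "Hypothyroidism", "Immune-mediated myocarditis",
                                "Immune-mediated enterocolitis"),
                         target_ror = rep(5, 5)),
                       baseline_pt_prob = 0.01,
                       duplicate_rate = 0.10,
                       onset_model = list(family = "exponential", median_days = 35),
                       mortality_model = list(
                         intercept = qlogis(0.10), age65 = log(1.5),
                         female = log(1.1), weight_low = log(1.3),
                         weight_high = log(1.8), cumulative_aes = log(1.03),
                         tto_first_days = log(0.995)),
                       missingness = list(age = 0.137, sex = 0.055,
                                          weight = 0.80, event_dt = 0.08,
                                          start_dt = 0.05,
                                          event_dt_partial = 0.04),
                       p_hospital = 0.216,
                       p_male = 0.849,
                       p_bg_indicated = 0.05) {
  cfg <- list(seed = as.integer(seed), n_cases = as.integer(n_cases),
              target_drug = target_drug, target_synonyms = target_synonyms,
              indication_pt = indication_pt, p_exposed = p_exposed,
              n_background_drugs = as.integer(n_background_drugs),
              pt_vocabulary = as_tibble(pt_vocabulary),
              planted_signals = as_tibble(planted_signals),
              baseline_pt_prob = baseline_pt_prob,
              duplicate_rate = duplicate_rate, onset_model = onset_model,
              mortality_model = mortality_model,
              missingness = modifyList(
                list(age = 0.137, sex = 0.055, weight = 0.80, event_dt = 0.08,
                     start_dt = 0.05, event_dt_partial = 0.04), missingness),
              p_hospital = p_hospital, p_male = p_male,
              p_bg_indicated = p_bg_indicated)
  stopifnot(cfg$n_cases >= 1, cfg$n_background_drugs >= 1,
            cfg$baseline_pt_prob > 0, cfg$baseline_pt_prob < 1,
            cfg$p_exposed > 0, cfg$p_exposed < 1,
            cfg$duplicate_rate >= 0, cfg$duplicate_rate <= 1)
  probs <- unlist(cfg$missingness)
  stopifnot(all(probs >= 0), all(probs <= 1))
  if (nrow(cfg$planted_signals)) {
    stopifnot(all(cfg$planted_signals$target_ror > 0))
    missing_pt <- setdiff(cfg$planted_signals$pt, cfg$pt_vocabulary$pt)
    if (length(missing_pt)) {
      stop("planted PT(s) not in vocabulary: ",
           paste(missing_pt, collapse = ", "), call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

# Exposed-arm PT probability solving odds(p1) = ror * odds(p0), which makes
# `ror` the exact expectation of the report-level reporting odds ratio.
planted_prob <- function(p0, ror) {
  p1 <- ror * p0 / (1 - p0 + ror * p0)
  if (any(!is.finite(p1)) || any(p1 >= 1) || any(p1 <= 0)) {
    stop("infeasible planted target: implied event probability outside (0, 1)",
         call. = FALSE)
  }
  p1
}

sample_onset <- function(n, model) {
  fam <- model$family %||% "exponential"
  switch(fam,
    exponential = rexp(n, rate = log(2) / model$median_days),
    weibull = rweibull(n, shape = model$shape, scale = model$scale),
    lognormal = rlnorm(n, meanlog = model$meanlog, sdlog = model$sdlog),
    stop("unknown onset family: ", fam, call. = FALSE))
}

case_noise <- function(x, u) {
  # deterministic-given-u case/whitespace perturbation of drug names
  out <- x
  out[u < 1 / 3] <- toupper(x[u < 1 / 3])
  out[u > 2 / 3] <- paste0(" ", x[u > 2 / 3], " ")
  out
}

#' Generate a synthetic FAERS-shaped dataset
#'
#' Deterministic given `config$seed`. Every target case carries a
#' primary-suspect entry for the target drug linked to the configured
#' indication; planted (drug, PT) pairs are emitted with per-report
#' probability solved from the odds-ratio identity so the target ROR is the
#' exact expectation; a small fraction of background cases carry the target
#' drug as a concomitant (role C) entry and must not enter the cohort.
#' Internal dates satisfy start_dt <= event_dt <= fda_dt before missingness
#' is applied.
#'
#' @param config a [sim_config()].
#' @return list with elements `tables` (a `faers_tables` object) and
#'   `ledger` (ground truth: per-planted-pair realized a/b/c/d and ROR,
#'   per-case true onset/death/covariates before missingness, and the
#'   duplicate map).
#' @export
sim_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases
  vocab <- config$pt_vocabulary
  n_pt <- nrow(vocab)

  exposed <- runif(n) < config$p_exposed
  bg_names <- sprintf("BACKGROUND DRUG %02d", seq_len(config$n_background_drugs))
  drug_of <- ifelse(exposed, config$target_drug,
                    sample(bg_names, n, replace = TRUE))

  ## --- PT incidence -------------------------------------------------------
  p0 <- config$baseline_pt_prob
  prob <- matrix(p0, nrow = n, ncol = n_pt)
  planted_idx <- match(config$planted_signals$pt, vocab$pt)
  for (k in seq_along(planted_idx)) {
    prob[exposed, planted_idx[k]] <-
      planted_prob(p0, config$planted_signals$target_ror[k])
  }
  present <- matrix(runif(n * n_pt), nrow = n) < prob
  # every report must list at least one event; fill from non-planted PTs so
  # planted-pair probabilities stay exact
  empty <- which(rowSums(present) == 0L)
  if (length(empty)) {
    filler_pool <- setdiff(seq_len(n_pt), planted_idx)
    fill_j <- sample(filler_pool, length(empty), replace = TRUE)
    present[cbind(empty, fill_j)] <- TRUE
  }
  cumulative_aes <- rowSums(present)

  ## --- demographics -------------------------------------------------------
  sex <- ifelse(runif(n) < config$p_male, "M", "F")
  band <- sample(c("18-44", "44-64", ">=65"), n, replace = TRUE,
                 prob = c(0.019, 0.283, 0.698))
  age <- numeric(n)
  age[band == "18-44"] <- round(runif(sum(band == "18-44"), 18, 44))
  age[band == "44-64"] <- round(runif(sum(band == "44-64"), 45, 64))
  age[band == ">=65"] <- round(runif(sum(band == ">=65"), 65, 90))
  weight <- round(rlnorm(n, meanlog = log(64), sdlog = 0.24), 1)
  country <- sample(c("JP", "US", "CN", "DE", "FR", "GB"), n, replace = TRUE,
                    prob = c(0.617, 0.183, 0.094, 0.04, 0.036, 0.03))
  reporter <- sample(c("MD", "HP", "CN", "PH", "OT"), n, replace = TRUE,
                     prob = c(0.70, 0.12, 0.099, 0.05, 0.031))

  ## --- dates and onset ----------------------------------------------------
  start_date <- as.Date("2015-01-01") +
    sample.int(as.integer(as.Date("2024-06-30") - as.Date("2015-01-01")),
               n, replace = TRUE)
  tto_days <- pmax(0L, as.integer(round(sample_onset(n, config$onset_model))))
  event_date <- start_date + tto_days
  fda_date <- event_date + sample(3:60, n, replace = TRUE)

  ## --- outcomes -----------------------------------------------------------
  mm <- config$mortality_model
  lp <- mm$intercept +
    mm$age65 * (age >= 65) +
    mm$female * (sex == "F") +
    mm$weight_low * (weight < 50) +
    mm$weight_high * (weight > 100) +
    mm$cumulative_aes * cumulative_aes +
    mm$tto_first_days * tto_days
  death <- rbinom(n, 1L, plogis(lp))
  hosp <- rbinom(n, 1L, config$p_hospital)

  ## --- report versions (duplicates) ---------------------------------------
  n_versions <- rep(1L, n)
  dup <- runif(n) < config$duplicate_rate
  n_versions[dup] <- sample(2:3, sum(dup), replace = TRUE)
  caseid <- 10000000L + seq_len(n)
  case_idx <- rep(seq_len(n), n_versions)           # case of each version
  version <- sequence(n_versions)
  primaryid <- caseid[case_idx] * 100 + version
  is_last <- version == n_versions[case_idx]
  # earlier versions were received earlier but never before the event
  back_off <- (n_versions[case_idx] - version) * sample(15:90, length(version),
                                                        replace = TRUE)
  fda_v <- fda_date[case_idx] - back_off
  fda_v <- pmax(fda_v, event_date[case_idx])

  pid_chr <- format(primaryid, scientific = FALSE, trim = TRUE)
  cid_chr <- format(caseid[case_idx], scientific = FALSE, trim = TRUE)

  ## --- missingness --------------------------------------------------------
  ms <- config$missingness
  miss_age <- runif(n) < ms$age
  miss_sex <- runif(n) < ms$sex
  miss_wt <- runif(n) < ms$weight
  miss_event <- runif(n) < ms$event_dt
  partial_event <- !miss_event & runif(n) < ms$event_dt_partial
  miss_start <- runif(n) < ms$start_dt

  event_chr <- as.character(yyyymmdd(event_date))
  event_chr[partial_event] <- substr(event_chr[partial_event], 1, 6)
  event_chr[miss_event] <- NA_character_
  start_chr <- as.character(yyyymmdd(start_date))
  start_chr[miss_start] <- NA_character_

  demo <- tibble(
    primaryid = pid_chr,
    caseid = cid_chr,
    fda_dt = as.character(yyyymmdd(fda_v)),
    event_dt = event_chr[case_idx],
    age = ifelse(miss_age, NA_character_, as.character(age))[case_idx],
    age_cod = ifelse(miss_age, NA_character_, "YR")[case_idx],
    sex = ifelse(miss_sex, NA_character_, sex)[case_idx],
    wt = ifelse(miss_wt, NA_character_, format(weight, trim = TRUE))[case_idx],
    wt_cod = ifelse(miss_wt, NA_character_, "KG")[case_idx],
    occr_country = country[case_idx],
    occp_cod = reporter[case_idx])

  ## --- drug / ther / indi -------------------------------------------------
  # primary-suspect entry (seq 1) per case; noisy synonym for target cases
  syn <- sample(config$target_synonyms, n, replace = TRUE)
  syn <- case_noise(syn, runif(n))
  drugname <- ifelse(exposed, syn, drug_of)
  prod_ai <- ifelse(exposed, toupper(config$target_drug), drug_of)
  # a few background cases carry the target as concomitant (role C): these
  # must never qualify for a PS-role cohort
  conc_target <- !exposed & runif(n) < 0.02

  drug_case <- dplyr::bind_rows(
    tibble(case = seq_len(n), drug_seq = "1", role_cod = "PS",
           drugname = drugname, prod_ai = prod_ai),
    tibble(case = which(conc_target), drug_seq = "2", role_cod = "C",
           drugname = toupper(config$target_drug),
           prod_ai = toupper(config$target_drug)))
  ther_case <- tibble(case = seq_len(n), dsg_drug_seq = "1",
                      start_dt = start_chr, end_dt = NA_character_)
  bg_ind <- sample(c("Gastric cancer", "Lung neoplasm malignant",
                     "Colorectal cancer", "Breast cancer"), n, replace = TRUE)
  indi_pt <- ifelse(exposed | runif(n) < config$p_bg_indicated,
                    config$indication_pt, bg_ind)
  indi_case <- tibble(case = seq_len(n), indi_drug_seq = "1", indi_pt = indi_pt)

  ev_idx <- which(present, arr.ind = TRUE)
  ev_idx <- ev_idx[order(ev_idx[, 1], ev_idx[, 2]), , drop = FALSE]
  reac_case <- tibble(case = ev_idx[, 1], pt = vocab$pt[ev_idx[, 2]])
  outc_case <- dplyr::bind_rows(
    tibble(case = which(death == 1L), outc_cod = "DE"),
    tibble(case = which(hosp == 1L), outc_cod = "HO"))
  outc_case <- outc_case[order(outc_case$case), ]
  rpsr_case <- tibble(case = seq_len(n),
                      rpsr_cod = sample(c("FGN", "HP", "CSM"), n, replace = TRUE))

  # replicate per-case child rows across that case's report versions
  expand <- function(tab) {
    reps <- n_versions[tab$case]
    out <- tab[rep(seq_len(nrow(tab)), reps), , drop = FALSE]
    ver <- sequence(reps)
    out$primaryid <- format(caseid[out$case] * 100 + ver,
                            scientific = FALSE, trim = TRUE)
    out$case <- NULL
    dplyr::relocate(out, primaryid)
  }

  tables <- structure(list(
    demo = demo,
    drug = expand(drug_case),
    reac = expand(reac_case),
    outc = expand(outc_case),
    ther = expand(ther_case),
    indi = expand(indi_case),
    rpsr = expand(rpsr_case),
    meta = list(malformed = integer(0), orphans = integer(0))
  ), class = "faers_tables")

  ## --- truth ledger -------------------------------------------------------
  sig <- config$planted_signals
  if (nrow(sig)) {
    a <- colSums(present[exposed, planted_idx, drop = FALSE])
    c_ <- colSums(present[!exposed, planted_idx, drop = FALSE])
    b <- sum(exposed) - a
    d <- sum(!exposed) - c_
    signals <- tibble(drug = config$target_drug, pt = sig$pt,
                      target_ror = sig$target_ror,
                      a = as.integer(a), b = as.integer(b),
                      c = as.integer(c_), d = as.integer(d),
                      realized_ror = a * d / (b * c_))
  } else {
    signals <- tibble(drug = character(0), pt = character(0),
                      target_ror = numeric(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), realized_ror = numeric(0))
  }
  canonical_pid <- format(caseid * 100 + n_versions, scientific = FALSE,
                          trim = TRUE)
  ledger <- list(
    signals = signals,
    cases = tibble(
      caseid = format(caseid, scientific = FALSE, trim = TRUE),
      primaryid = canonical_pid,
      exposed = exposed, indicated = exposed | indi_pt == config$indication_pt,
      tto_days = tto_days, death = death, hospitalized = hosp,
      age_years = age, sex = sex, weight_kg = weight,
      cumulative_aes = as.integer(cumulative_aes),
      start_missing = miss_start,
      event_dt_usable = !miss_event & !partial_event),
    duplicates = tibble(caseid = cid_chr, primaryid = pid_chr,
                        version = version, kept = is_last),
    n_reports = length(primaryid))
  list(tables = tables, ledger = ledger)
}

#' Write a synthetic quarter in the FAERS ASCII dialect
#'
#' Emits `DEMO<q>.txt`, `DRUG<q>.txt`, ... as `$`-delimited, unquoted text
#' readable by [read_faers_quarter()]; missing fields are written empty.
#'
#' @param tables a `faers_tables` object.
#' @param path output directory (created if needed).
#' @param quarter quarter tag used in file names, e.g. `"25Q2"`.
#' @return invisibly, the vector of files written.
#' @export
write_faers_quarter <- function(tables, path, quarter = "25Q2") {
  stopifnot(inherits(tables, "faers_tables"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (tab in FAERS_TABLES) {
    df <- tables[[tab]]
    if (is.null(df)) next
    df <- as.data.frame(lapply(df, function(x) {
      x <- as.character(x)
      x[is.na(x)] <- ""
      x
    }), stringsAsFactors = FALSE, check.names = FALSE)
    lines <- c(paste(names(df), collapse = "$"),
               if (nrow(df)) do.call(paste, c(df, sep = "$")))
    file <- file.path(path, paste0(toupper(tab), quarter, ".txt"))
    readr::write_lines(lines, file)
    written <- c(written, file)
  }
  invisible(written)
}
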