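# Shared fixture builders (all data built in code at test time).

`%or%` <- function(a, b) if (is.null(a)) b else a

make_cases <- function(primaryid, age_years = NA_real_, sex = "M",
                       weight_kg = NA_real_, event_dt = NA_character_,
                       fda_dt = "20240101") {
  n <- length(primaryid)
  tibble::tibble(
    primaryid = as.character(primaryid),
    caseid = as.character(primaryid),
    fda_dt = rep_len(fda_dt, n),
    event_dt = rep_len(event_dt, n),
    event_dt_precision = faers_date_precision(rep_len(event_dt, n)),
    age_years = rep_len(age_years, n),
    sex = rep_len(sex, n),
    weight_kg = rep_len(weight_kg, n),
    country = "US", reporter = "MD")
}

# hand-assembled cohort object for unit tests of the analysis modules
fake_cohort <- function(cases, events, bg_cases = NULL, bg_events = NULL,
                        outcomes = NULL, therapy = NULL) {
  bg_cases <- bg_cases %or% make_cases(character(0))
  structure(list(
    target = "drugx", spec = NULL,
    cases = cases,
    events = events,
    outcomes = outcomes %or%
      tibble::tibble(primaryid = character(0), outc_cod = character(0)),
    therapy = therapy %or%
      tibble::tibble(primaryid = character(0), drug_seq = character(0),
                     start_dt = character(0)),
    background = list(
      n_reports = nrow(bg_cases),
      cases = bg_cases[, c("primaryid", "age_years", "sex", "weight_kg")],
      events = bg_events %or%
        tibble::tibble(primaryid = character(0), pt = character(0)))),
    class = "faers_cohort")
}

pembro_spec <- function(...) {
  cohort_spec(
    drug_synonym_map("pembrolizumab",
                     c("pembrolizumab", "keytruda", "mk-3475")),
    indication_terms = "Oesophageal cancer", ...)
}

# small fast generator config for end-to-end tests
small_sim <- function(seed = 7, n_cases = 1500, ...) {
  sim_config(seed = seed, n_cases = n_cases,
             pt_vocabulary = sim_pt_vocabulary(60), ...)
}
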