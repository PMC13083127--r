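# FAERS quarterly ASCII ingestion, FDA-rule deduplication, cohort assembly.

FAERS_TABLES <- c("demo", "drug", "reac", "outc", "ther", "indi", "rpsr")

# $-delimited, unquoted, optionally wrapped in leading/trailing delimiters.
# Malformed rows (wrong field count) are counted and reported, never guessed.
read_faers_table <- function(file, encoding = "latin1") {
  lines <- readr::read_lines(file, locale = readr::locale(encoding = encoding))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty FAERS table file: ", file, call. = FALSE)
  lines <- sub("^\\$", "", sub("\\$$", "", lines))
  parts <- strsplit(lines, "$", fixed = TRUE)
  header <- tolower(trimws(parts[[1]]))
  body <- parts[-1]
  # strsplit drops trailing empty fields; pad rows short by only that much
  n_col <- length(header)
  len <- lengths(body)
  ok <- len == n_col | (len < n_col & len >= 1)
  # rows with MORE fields than the header are malformed outright
  malformed <- sum(len > n_col)
  body <- body[len <= n_col]
  if (length(body)) {
    mat <- matrix(NA_character_, nrow = length(body), ncol = n_col)
    for (i in seq_along(body)) {
      row <- body[[i]]
      mat[i, seq_along(row)] <- row
    }
    mat[mat == ""] <- NA_character_
    tab <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                     .name_repair = "minimal")
    names(tab) <- header
  } else {
    tab <- as_tibble(setNames(
      as.data.frame(matrix(character(0), ncol = n_col)), header))
  }
  attr(tab, "n_malformed") <- malformed
  if (malformed > 0) {
    warning(sprintf("%s: %d malformed row(s) excluded (field count > header)",
                    basename(file), malformed), call. = FALSE)
  }
  tab
}

#' Read one FAERS-dialect quarter
#'
#' Locates the seven quarterly tables (DEMO, DRUG, REAC, OUTC, THER, INDI,
#' RPSR) in a directory by file-name prefix (case-insensitive, e.g.
#' `DEMO25Q1.txt`), parses the `$`-delimited layout with or without stray
#' leading/trailing delimiters, lower-cases all column names, and counts
#' malformed rows and orphaned records (non-DEMO rows whose `primaryid` is
#' absent from DEMO).
#'
#' @param path directory containing the quarter's files.
#' @param encoding file encoding (FAERS quarters are latin-1).
#' @param required tables whose absence is a hard error; RPSR is optional by
#'   default because no downstream analysis consumes it.
#' @return an object of class `faers_tables`: a named list of tibbles
#'   (`demo`, `drug`, `reac`, `outc`, `ther`, `indi`, `rpsr`) with a `meta`
#'   element recording per-table row, malformed-row and orphan counts.
#' @export
read_faers_quarter <- function(path, encoding = "latin1",
                               required = c("demo", "drug", "reac",
                                            "outc", "ther", "indi")) {
  stopifnot(dir.exists(path))
  files <- list.files(path, full.names = TRUE)
  out <- list()
  meta <- list(malformed = integer(0), orphans = integer(0))
  for (tab in FAERS_TABLES) {
    hit <- files[grepl(paste0("^", tab), tolower(basename(files))) &
                   grepl("\\.(txt|asc)$", tolower(basename(files)))]
    if (length(hit) == 0) {
      if (tab %in% required) {
        stop("missing mandatory FAERS table: ", toupper(tab), call. = FALSE)
      }
      out[[tab]] <- tibble(primaryid = character(0))
      next
    }
    parsed <- read_faers_table(hit[[1]], encoding = encoding)
    if (!"primaryid" %in% names(parsed)) {
      stop(toupper(tab), ": unparseable layout, no primaryid column; header: ",
           paste(head(names(parsed), 8), collapse = ", "), call. = FALSE)
    }
    meta$malformed[[tab]] <- attr(parsed, "n_malformed")
    out[[tab]] <- parsed
  }
  demo_ids <- unique(out$demo$primaryid)
  for (tab in setdiff(names(out), "demo")) {
    if (nrow(out[[tab]])) {
      meta$orphans[[tab]] <- sum(!out[[tab]]$primaryid %in% demo_ids)
    }
  }
  structure(c(out, list(meta = meta)), class = "faers_tables")
}

#' @export
print.faers_tables <- function(x, ...) {
  cat("<faers_tables>\n")
  for (tab in intersect(FAERS_TABLES, names(x))) {
    cat(sprintf("  %-5s %d rows\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}

#' Deduplicate report versions by the FDA rule
#'
#' A FAERS case (`caseid`) can be represented by several report versions
#' (`primaryid`). Per case the version with the highest `fda_dt` (latest
#' receipt) is retained; ties on `fda_dt` are broken by the largest
#' `primaryid`. Rows with no `caseid` are quarantined, counted, and never
#' kept. The result is independent of input row order and idempotent.
#'
#' @param demo DEMO tibble with `primaryid`, `caseid`, `fda_dt` columns.
#' @return a list of class `faers_dedup`: `keep` (character vector of kept
#'   primaryids), `removed` (tibble `caseid`, `primaryid` of dropped
#'   versions), `quarantined` (tibble of caseid-less rows).
#' @export
dedup_reports <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  demo <- as_tibble(demo)
  no_case <- is.na(demo$caseid) | !nzchar(trimws(as.character(demo$caseid)))
  quarantined <- demo[no_case, c("primaryid", "caseid", "fda_dt")]
  d <- demo[!no_case, ]
  fda <- suppressWarnings(as.numeric(d$fda_dt))
  fda[is.na(fda)] <- -1
  pid <- suppressWarnings(as.numeric(d$primaryid))
  ord <- order(d$caseid, fda, pid)
  d <- d[ord, ]
  keep_row <- !duplicated(d$caseid, fromLast = TRUE)
  list_out <- list(
    keep = as.character(d$primaryid[keep_row]),
    removed = tibble(caseid = as.character(d$caseid[!keep_row]),
                     primaryid = as.character(d$primaryid[!keep_row])),
    quarantined = quarantined
  )
  structure(list_out, class = "faers_dedup")
}

#' Restrict a quarter to deduplicated report versions
#'
#' Applies [dedup_reports()] to DEMO and filters every table to the kept
#' `primaryid`s, attaching the removal ledger as the `"dedup"` attribute.
#'
#' @param tables a `faers_tables` object.
#' @return the filtered `faers_tables`, with attribute `dedup`.
#' @export
dedup_tables <- function(tables) {
  stopifnot(inherits(tables, "faers_tables"))
  led <- dedup_reports(tables$demo)
  out <- tables
  for (tab in intersect(FAERS_TABLES, names(tables))) {
    if (nrow(out[[tab]])) {
      out[[tab]] <- out[[tab]][out[[tab]]$primaryid %in% led$keep, ]
    }
  }
  attr(out, "dedup") <- led
  out
}

#' Drug synonym dictionary
#'
#' Bundles the canonical label of a drug with the lower-cased synonym set
#' (active ingredient, generic and trade names) matched against `drugname`
#' and `prod_ai`. For pembrolizumab the conventional list is
#' `c("pembrolizumab", "keytruda", "mk-3475")`; for nivolumab
#' `c("nivolumab", "opdivo", "opdyta", "bms-936558")`.
#'
#' @param target canonical drug label.
#' @param synonyms character vector of names to match (non-empty).
#' @return object of class `drug_synonym_map`.
#' @export
drug_synonym_map <- function(target, synonyms) {
  synonyms <- unique(normalize_name(synonyms))
  synonyms <- synonyms[!is.na(synonyms)]
  if (length(synonyms) == 0) stop("synonym set must be non-empty", call. = FALSE)
  structure(list(target = target, synonyms = synonyms),
            class = "drug_synonym_map")
}

#' Match raw drug-name strings against a synonym map
#'
#' @param x character vector of raw `drugname` / `prod_ai` values.
#' @param map a [drug_synonym_map()].
#' @param mode `"exact"` (normalized string equals a synonym; default) or
#'   `"substring"` (a synonym occurs anywhere in the normalized string,
#'   e.g. inside combination-product strings).
#' @return logical vector; `NA` input gives `FALSE`.
#' @export
match_drug_name <- function(x, map, mode = c("exact", "substring")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "drug_synonym_map"))
  nx <- normalize_name(x)
  if (mode == "exact") {
    out <- nx %in% map$synonyms
  } else {
    out <- rep(FALSE, length(nx))
    has <- !is.na(nx)
    for (syn in map$synonyms) {
      out[has] <- out[has] | grepl(syn, nx[has], fixed = TRUE)
    }
  }
  out
}

#' Cohort definition: target drug + indication + drug role
#'
#' @param drug a [drug_synonym_map()].
#' @param indication_terms character vector of indication preferred terms
#'   (matched case-insensitively, exact after trimming).
#' @param role drug role code the target entry must carry (default `"PS"`,
#'   primary suspect).
#' @param indication_scope `"drug"` (default): the indication must be linked
#'   to the matching drug entry via `indi_drug_seq = drug_seq`;
#'   `"case"`: any indication row of the report qualifies.
#' @param match_mode passed to [match_drug_name()].
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(drug, indication_terms, role = "PS",
                        indication_scope = c("drug", "case"),
                        match_mode = c("exact", "substring")) {
  stopifnot(inherits(drug, "drug_synonym_map"))
  role <- toupper(role)
  if (!role %in% c("PS", "SS", "C", "I")) {
    stop("role must be one of PS, SS, C, I", call. = FALSE)
  }
  terms <- unique(tolower(trimws(indication_terms)))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0) stop("indication_terms must be non-empty", call. = FALSE)
  structure(list(drug = drug, indication_terms = terms, role = role,
                 indication_scope = match.arg(indication_scope),
                 match_mode = match.arg(match_mode)),
            class = "cohort_spec")
}

# DEMO -> normalized case-level tibble (units converted, dates flagged)
normalize_demo <- function(demo) {
  col <- function(nm) if (nm %in% names(demo)) demo[[nm]] else rep(NA_character_, nrow(demo))
  tibble(
    primaryid = as.character(demo$primaryid),
    caseid = as.character(col("caseid")),
    fda_dt = as.character(col("fda_dt")),
    event_dt = as.character(col("event_dt")),
    event_dt_precision = faers_date_precision(col("event_dt")),
    age_years = age_to_years(col("age"), col("age_cod")),
    sex = normalize_sex(col("sex")),
    weight_kg = weight_to_kg(col("wt"), col("wt_cod")),
    country = toupper(trimws(as.character(col("occr_country")))),
    reporter = toupper(trimws(as.character(col("occp_cod"))))
  )
}

#' Assemble the target-drug / indication cohort
#'
#' A report enters the cohort when it carries at least one drug entry that
#' (i) matches the target synonym set on `drugname` or `prod_ai`, (ii) has
#' the required role code, and (iii) — under drug-level indication scope —
#' is linked (via `indi_drug_seq = drug_seq`) to an indication preferred
#' term in the spec's list. Reports with missing age/sex/weight are
#' retained; they are only dropped per-variable by downstream analyses.
#' The remaining deduplicated reports form the background comparator.
#'
#' @param tables a deduplicated `faers_tables` (see [dedup_tables()]).
#' @param spec a [cohort_spec()].
#' @return object of class `faers_cohort`: tibbles `cases`, `events`
#'   (distinct report-PT pairs), `outcomes`, `therapy` (target-drug therapy
#'   start dates), and a `background` list with `n_reports`, `cases`
#'   (minimal demographics) and `events` for all non-cohort reports.
#' @export
build_cohort <- function(tables, spec) {
  stopifnot(inherits(tables, "faers_tables"), inherits(spec, "cohort_spec"))
  if (is.null(attr(tables, "dedup"))) {
    warning("tables carry no dedup ledger; deduplicating now", call. = FALSE)
    tables <- dedup_tables(tables)
  }
  drug <- tables$drug
  hit <- match_drug_name(drug$drugname, spec$drug, mode = spec$match_mode)
  if ("prod_ai" %in% names(drug)) {
    hit <- hit | match_drug_name(drug$prod_ai, spec$drug, mode = spec$match_mode)
  }
  target_rows <- drug[hit & toupper(trimws(as.character(drug$role_cod))) == spec$role, ]

  indi <- tables$indi
  indi_hit <- indi[tolower(trimws(as.character(indi$indi_pt))) %in%
                     spec$indication_terms, ]
  if (spec$indication_scope == "drug" && "indi_drug_seq" %in% names(indi_hit) &&
      "drug_seq" %in% names(target_rows)) {
    qualified <- dplyr::semi_join(
      target_rows, indi_hit,
      by = c(primaryid = "primaryid", drug_seq = "indi_drug_seq"))
  } else {
    qualified <- target_rows[target_rows$primaryid %in% indi_hit$primaryid, ]
  }
  cohort_ids <- unique(as.character(qualified$primaryid))
  if (length(cohort_ids) == 0) {
    warning("cohort is empty for target '", spec$drug$target, "'", call. = FALSE)
  }

  demo_n <- normalize_demo(tables$demo)
  reac <- tables$reac
  events_all <- dplyr::distinct(
    tibble(primaryid = as.character(reac$primaryid),
           pt = trimws(as.character(reac$pt))))
  events_all <- events_all[!is.na(events_all$pt) & nzchar(events_all$pt), ]

  in_cohort <- demo_n$primaryid %in% cohort_ids
  ther <- tables$ther
  therapy <- dplyr::inner_join(
    qualified[, intersect(c("primaryid", "drug_seq"), names(qualified))],
    tibble(primaryid = as.character(ther$primaryid),
           dsg_drug_seq = as.character(if ("dsg_drug_seq" %in% names(ther))
             ther$dsg_drug_seq else NA_character_),
           start_dt = as.character(if ("start_dt" %in% names(ther))
             ther$start_dt else NA_character_)),
    by = c(primaryid = "primaryid", drug_seq = "dsg_drug_seq"))

  outc <- tables$outc
  outcomes <- tibble(primaryid = as.character(outc$primaryid),
                     outc_cod = toupper(trimws(as.character(
                       if ("outc_cod" %in% names(outc)) outc$outc_cod
                       else rep(NA_character_, nrow(outc))))))
  outcomes <- outcomes[outcomes$primaryid %in% cohort_ids, ]

  structure(list(
    target = spec$drug$target,
    spec = spec,
    cases = demo_n[in_cohort, ],
    events = events_all[events_all$primaryid %in% cohort_ids, ],
    outcomes = outcomes,
    therapy = therapy,
    background = list(
      n_reports = sum(!in_cohort),
      cases = demo_n[!in_cohort, c("primaryid", "age_years", "sex", "weight_kg")],
      events = events_all[!events_all$primaryid %in% cohort_ids, ]
    )
  ), class = "faers_cohort")
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat(sprintf("<faers_cohort> target: %s\n  cohort reports: %d  (distinct PTs: %d)\n  background reports: %d\n",
              x$target, nrow(x$cases), length(unique(x$events$pt)),
              x$background$n_reports))
  invisible(x)
}
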