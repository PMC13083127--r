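# Orchestration: read -> dedup -> cohort -> descriptive -> signals (PT,
# SOC, strata) -> onset -> mortality, with stage logging and delimited
# exports. All outputs are deterministic given inputs + seed.

slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

#' Pipeline configuration
#'
#' @param input either a directory containing one FAERS-dialect quarter or
#'   a [sim_config()] (the quarter is then generated in memory).
#' @param cohorts named list of [cohort_spec()]s; two entries give a
#'   side-by-side drug comparison.
#' @param pt_soc_map PT -> SOC map: a tibble/data.frame with columns `pt`,
#'   `soc`, or a path to a two-column delimited file. `NULL` disables the
#'   SOC stage.
#' @param criteria a [signal_criteria()].
#' @param strata stratification variables for [stratified_signals()].
#' @param analyses which stages to run.
#' @param outdir output directory for the delimited bundle.
#' @param seed integer seed for any randomness (synthetic input).
#' @return validated `pipeline_config` object.
#' @export
pipeline_config <- function(input, cohorts, pt_soc_map = NULL,
                            criteria = signal_criteria(),
                            strata = c("sex", "age_band"),
                            analyses = c("descriptive", "signals", "soc",
                                         "strata", "onset", "mortality"),
                            outdir = tempfile("faersignal-"), seed = 1L) {
  stopifnot(inherits(input, "sim_config") ||
              (is.character(input) && dir.exists(input)))
  if (inherits(cohorts, "cohort_spec")) cohorts <- list(cohorts)
  stopifnot(length(cohorts) >= 1,
            all(vapply(cohorts, inherits, logical(1), "cohort_spec")))
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    names(cohorts) <- vapply(cohorts, function(s) s$drug$target, character(1))
  }
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (is.character(pt_soc_map) && length(pt_soc_map) == 1) {
    pt_soc_map <- readr::read_tsv(pt_soc_map, show_col_types = FALSE)
  }
  if (!is.null(pt_soc_map)) {
    pt_soc_map <- as_tibble(pt_soc_map)
    stopifnot(all(c("pt", "soc") %in% names(pt_soc_map)))
  }
  structure(list(input = input, cohorts = cohorts, pt_soc_map = pt_soc_map,
                 criteria = criteria, strata = strata, analyses = analyses,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_stage <- function(df, outdir, name, manifest) {
  file <- file.path(outdir, paste0(name, ".tsv"))
  readr::write_tsv(df, file)
  c(manifest, file)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, logging every stage's row
#' count, and writes one delimited file per stage output plus `log.tsv`,
#' `dedup_removed.tsv` and `manifest.txt`. When two cohorts are configured
#' a shared-PT ROR comparison table is added. A stage failure aborts with
#' the stage name after writing the manifest of completed outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results (`cohorts`,
#'   `results`, `log`, `outdir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log <- list()
  manifest <- character(0)
  note <- function(stage, count) {
    log[[length(log) + 1]] <<- tibble(stage = stage, count = as.integer(count))
  }
  stage <- "read"
  result <- tryCatch({
    tables <- if (inherits(config$input, "sim_config")) {
      sim_faers(config$input)$tables
    } else {
      read_faers_quarter(config$input)
    }
    note("reports_in", nrow(tables$demo))

    stage <- "dedup"
    tables <- dedup_tables(tables)
    led <- attr(tables, "dedup")
    note("reports_kept", length(led$keep))
    note("reports_removed_dedup", nrow(led$removed))
    note("reports_quarantined", nrow(led$quarantined))
    manifest <- write_stage(led$removed, config$outdir, "dedup_removed",
                            manifest)

    cohorts <- list()
    results <- list()
    for (nm in names(config$cohorts)) {
      tag <- slug(nm)
      stage <- paste0("cohort:", nm)
      cohort <- build_cohort(tables, config$cohorts[[nm]])
      cohorts[[nm]] <- cohort
      note(paste0("cohort_", tag), nrow(cohort$cases))

      if ("descriptive" %in% config$analyses) {
        stage <- paste0("descriptive:", nm)
        desc <- describe_cohort(cohort)
        results[[nm]]$descriptive <- desc
        manifest <- write_stage(desc, config$outdir,
                                paste0("descriptive_", tag), manifest)
      }
      if ("signals" %in% config$analyses) {
        stage <- paste0("signals:", nm)
        sig <- detect_signals(cohort, criteria = config$criteria)
        results[[nm]]$signals <- sig
        note(paste0("positive_pts_", tag), sum(sig$positive))
        manifest <- write_stage(sig, config$outdir,
                                paste0("signals_pt_", tag), manifest)
      }
      if ("soc" %in% config$analyses && !is.null(config$pt_soc_map)) {
        stage <- paste0("soc:", nm)
        soc <- aggregate_soc(cohort, config$pt_soc_map,
                             criteria = config$criteria)
        results[[nm]]$soc <- soc
        manifest <- write_stage(soc, config$outdir,
                                paste0("signals_soc_", tag), manifest)
      }
      if ("strata" %in% config$analyses) {
        for (v in config$strata) {
          stage <- paste0("strata:", nm, ":", v)
          st <- stratified_signals(cohort, v, criteria = config$criteria)
          results[[nm]]$strata[[v]] <- st
          for (lev in names(st)) {
            if (nrow(st[[lev]]) == 0) next
            manifest <- write_stage(
              st[[lev]], config$outdir,
              paste0("signals_", v, "_", slug(lev), "_", tag), manifest)
          }
        }
      }
      onset <- NULL
      if ("onset" %in% config$analyses) {
        stage <- paste0("onset:", nm)
        onset <- compute_tto(cohort)
        note(paste0("onset_records_", tag), nrow(onset))
        results[[nm]]$onset <- onset
        overall <- km_median(onset$tto_days, onset$event) %>%
          mutate(variable = "overall", level = "overall",
                 p_value = NA_real_) %>%
          select("variable", "level", "n", "median_days", "ci_low",
                 "ci_high", "p_value")
        subgroup <- onset_report(onset)
        results[[nm]]$onset_report <- dplyr::bind_rows(overall, subgroup)
        manifest <- write_stage(results[[nm]]$onset_report, config$outdir,
                                paste0("onset_", tag), manifest)
      }
      if ("mortality" %in% config$analyses) {
        stage <- paste0("mortality:", nm)
        mort <- build_mortality_table(cohort, onset)
        mort_rep <- mortality_report(mort)
        results[[nm]]$mortality <- mort_rep
        note(paste0("deaths_", tag), sum(mort$death))
        manifest <- write_stage(mort_rep, config$outdir,
                                paste0("mortality_", tag), manifest)
      }
    }

    if (length(cohorts) >= 2 && "signals" %in% config$analyses) {
      stage <- "comparison"
      cmp <- compare_ror(results)
      manifest <- write_stage(cmp, config$outdir, "comparison_ror", manifest)
    }
    list(cohorts = cohorts, results = results)
  }, error = function(e) {
    readr::write_lines(manifest, file.path(config$outdir, "manifest.txt"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  log_df <- dplyr::bind_rows(log)
  readr::write_tsv(log_df, file.path(config$outdir, "log.tsv"))
  manifest <- c(manifest, file.path(config$outdir, "log.tsv"))
  readr::write_lines(sort(basename(manifest)),
                     file.path(config$outdir, "manifest.txt"))
  invisible(c(result, list(log = log_df, outdir = config$outdir)))
}

# shared-PT ROR side-by-side for a two-drug comparison
compare_ror <- function(results) {
  sigs <- lapply(results, function(r) r$signals)
  nms <- names(sigs)
  out <- NULL
  for (nm in nms) {
    cols <- sigs[[nm]][, c("pt", "a", "ror", "ror_low", "ror_high",
                           "positive")]
    names(cols)[-1] <- paste0(names(cols)[-1], "_", slug(nm))
    out <- if (is.null(out)) cols else
      dplyr::inner_join(out, cols, by = "pt")
  }
  dplyr::arrange(out, .data$pt)
}
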