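# Quarter parsing, the FDA dedup rule, drug-name matching, cohort assembly.

write_table_file <- function(dir, name, header, rows) {
  writeLines(c(paste(header, collapse = "$"),
               vapply(rows, paste, character(1), collapse = "$")),
             file.path(dir, name))
}

tiny_quarter <- function(dir, demo_rows = NULL, trailing = FALSE) {
  demo_rows <- demo_rows %or% list(
    c("101", "1", "20240101", "20200105", "70", "YR", "M", "80", "KG", "US", "MD"),
    c("102", "2", "20240101", "202001", "", "", "F", "154", "LBS", "JP", "HP"))
  hdr <- c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT", "AGE", "AGE_COD",
           "SEX", "WT", "WT_COD", "OCCR_COUNTRY", "OCCP_COD")
  if (trailing) {
    demo_rows <- lapply(demo_rows, function(r) c(r, ""))
    hdr <- c(hdr, "")
  }
  write_table_file(dir, "DEMO24Q1.txt", hdr, demo_rows)
  write_table_file(dir, "DRUG24Q1.txt",
                   c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
                   list(c("101", "1", "PS", "KEYTRUDA", "PEMBROLIZUMAB"),
                        c("102", "1", "C", "pembrolizumab", ""),
                        c("102", "2", "PS", "aspirin", "ASPIRIN")))
  write_table_file(dir, "REAC24Q1.txt", c("primaryid", "pt"),
                   list(c("101", "Hypothyroidism"),
                        c("101", "Rash"),
                        c("102", "Nausea"),
                        c("999", "Orphan event")))
  write_table_file(dir, "OUTC24Q1.txt", c("primaryid", "outc_cod"),
                   list(c("101", "DE")))
  write_table_file(dir, "THER24Q1.txt",
                   c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
                   list(c("101", "1", "20200101", "")))
  write_table_file(dir, "INDI24Q1.txt",
                   c("primaryid", "indi_drug_seq", "indi_pt"),
                   list(c("101", "1", "Oesophageal cancer"),
                        c("102", "2", "Oesophageal cancer")))
  write_table_file(dir, "RPSR24Q1.txt", c("primaryid", "rpsr_cod"),
                   list(c("101", "FGN")))
  dir
}

test_that("quarter parsing preserves rows, flags partial dates, counts orphans", {
  dir <- withr::local_tempdir()
  tabs <- read_faers_quarter(tiny_quarter(dir))
  expect_s3_class(tabs, "faers_tables")
  expect_equal(nrow(tabs$demo), 2)
  expect_equal(names(tabs$demo)[1:3], c("primaryid", "caseid", "fda_dt"))
  expect_equal(faers_date_precision(tabs$demo$event_dt), c("day", "month"))
  # orphaned REAC primaryid is counted, not dropped silently
  expect_equal(tabs$meta$orphans[["reac"]], 1L)
  # unit conversions at the cohort-normalization layer
  demo_n <- faersignal:::normalize_demo(tabs$demo)
  expect_equal(demo_n$age_years, c(70, NA))
  expect_equal(demo_n$weight_kg, c(80, 154 * 0.453592), tolerance = 1e-10)
})

test_that("an extra trailing delimiter per line parses identically", {
  d1 <- tiny_quarter(withr::local_tempdir(), trailing = FALSE)
  d2 <- tiny_quarter(withr::local_tempdir(), trailing = TRUE)
  t1 <- read_faers_quarter(d1)
  t2 <- read_faers_quarter(d2)
  expect_equal(t1$demo, t2$demo)
})

test_that("missing mandatory tables and over-long rows are handled loudly", {
  dir <- withr::local_tempdir()
  tiny_quarter(dir)
  file.remove(file.path(dir, "DRUG24Q1.txt"))
  expect_error(read_faers_quarter(dir), "DRUG")

  dir2 <- withr::local_tempdir()
  tiny_quarter(dir2)
  # a row with more fields than the header is malformed and counted
  cat("103$3$20240101$x$y$z$a$b$c$d$e$EXTRA$EXTRA\n",
      file = file.path(dir2, "DEMO24Q1.txt"), append = TRUE)
  expect_warning(tabs <- read_faers_quarter(dir2), "malformed")
  expect_equal(tabs$meta$malformed[["demo"]], 1L)
  expect_equal(nrow(tabs$demo), 2)
})

test_that("dedup keeps the latest FDA_DT, then the largest PRIMARYID", {
  demo <- tibble::tibble(primaryid = c("1", "2"), caseid = c("7", "7"),
                         fda_dt = c("20240101", "20240401"))
  expect_equal(dedup_reports(demo)$keep, "2")

  demo <- tibble::tibble(primaryid = c("5", "9"), caseid = c("7", "7"),
                         fda_dt = c("20240101", "20240101"))
  expect_equal(dedup_reports(demo)$keep, "9")

  demo <- tibble::tibble(primaryid = c("1", "2", "3"),
                         caseid = c("a", "b", "c"),
                         fda_dt = "20240101")
  expect_setequal(dedup_reports(demo)$keep, c("1", "2", "3"))
})

test_that("caseid-less rows are quarantined and never kept", {
  demo <- tibble::tibble(primaryid = c("1", "2", "3"),
                         caseid = c("7", NA, ""),
                         fda_dt = "20240101")
  led <- dedup_reports(demo)
  expect_equal(led$keep, "1")
  expect_equal(nrow(led$quarantined), 2)
})

test_that("dedup is idempotent and order-independent", {
  set.seed(11)
  for (i in 1:20) {
    demo <- tibble::tibble(
      primaryid = as.character(sample(1000, 40)),
      caseid = as.character(sample(12, 40, replace = TRUE)),
      fda_dt = as.character(sample(20230101:20230120, 40, replace = TRUE)))
    led <- dedup_reports(demo)
    perm <- demo[sample(nrow(demo)), ]
    expect_setequal(dedup_reports(perm)$keep, led$keep)
    again <- dedup_reports(demo[demo$primaryid %in% led$keep, ])
    expect_setequal(again$keep, led$keep)
    expect_equal(nrow(again$removed), 0)
  }
})

test_that("drug-name matching normalizes case, whitespace and punctuation", {
  map <- drug_synonym_map("pembrolizumab",
                          c("pembrolizumab", "keytruda", "mk-3475"))
  expect_true(match_drug_name("KEYTRUDA", map))
  expect_true(match_drug_name("  Mk-3475 ", map))
  expect_false(match_drug_name("nivolumab", map))
  expect_false(match_drug_name(NA_character_, map))
  # combination strings only match in substring mode
  expect_false(match_drug_name("keytruda / cisplatin", map))
  expect_true(match_drug_name("keytruda / cisplatin", map, mode = "substring"))
  expect_error(drug_synonym_map("x", character(0)), "non-empty")
})

test_that("cohort requires PS role and a drug-linked indication", {
  dir <- withr::local_tempdir()
  tabs <- dedup_tables(read_faers_quarter(tiny_quarter(dir)))
  co <- build_cohort(tabs, pembro_spec())
  # 101: PS keytruda + linked EC indication -> in; 102: pembrolizumab is
  # role C and the EC indication sits on drug_seq 2 (aspirin) -> out
  expect_equal(co$cases$primaryid, "101")
  expect_equal(sort(co$events$pt), c("Hypothyroidism", "Rash"))
  expect_equal(co$background$n_reports, 1)
  # case-level scope accepts any indication row, but role C still excludes
  co2 <- build_cohort(tabs, pembro_spec(indication_scope = "case"))
  expect_equal(co2$cases$primaryid, "101")
})

test_that("empty cohort is a warning, not an error", {
  dir <- withr::local_tempdir()
  tabs <- dedup_tables(read_faers_quarter(tiny_quarter(dir)))
  spec <- cohort_spec(drug_synonym_map("nivolumab", "nivolumab"),
                      indication_terms = "Oesophageal cancer")
  expect_warning(co <- build_cohort(tabs, spec), "empty")
  expect_equal(nrow(co$cases), 0)
})

test_that("every cohort case satisfies the predicate under independent re-scan", {
  sim <- sim_faers(small_sim())
  tabs <- dedup_tables(sim$tables)
  co <- build_cohort(tabs, pembro_spec())
  # cohort is a subset of deduplicated reports
  expect_true(all(co$cases$primaryid %in% attr(tabs, "dedup")$keep))
  # brute-force re-scan of the raw tables, independent of build_cohort
  syn <- c("pembrolizumab", "keytruda", "mk-3475")
  drug <- tabs$drug
  ok_drug <- drug[normalize_name(drug$drugname) %in% syn &
                    drug$role_cod == "PS", ]
  indi <- tabs$indi[tolower(tabs$indi$indi_pt) == "oesophageal cancer", ]
  key_drug <- paste(ok_drug$primaryid, ok_drug$drug_seq)
  key_indi <- paste(indi$primaryid, indi$indi_drug_seq)
  expected <- unique(ok_drug$primaryid[key_drug %in% key_indi])
  expect_setequal(co$cases$primaryid, expected)
  # generator ledger agrees: exposed cases are exactly the cohort
  truth <- sim$ledger$cases
  expect_setequal(co$cases$primaryid, truth$primaryid[truth$exposed])
})
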