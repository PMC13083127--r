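# Disproportionality formulas, positivity flags, SOC and stratified tables.

test_that("worked 2x2 arithmetic matches the printed formulas", {
  m <- signal_metrics(10, 90, 100, 9900)
  expect_equal(m$ror, 11.0, tolerance = 1e-12)
  expect_equal(m$ror_low, 5.559, tolerance = 1e-3)
  expect_equal(m$ror_high, 21.765, tolerance = 1e-3)
  expect_equal(m$prr, 10.0, tolerance = 1e-12)
  expect_equal(m$chi2, 74.45, tolerance = 1e-3)
  expect_equal(m$ic, 3.199, tolerance = 1e-3)
  # closed-form posterior moments agree with the scalar re-derivation
  o <- oracle_bcpnn(10, 90, 100, 9900)
  expect_equal(m$e_ic, o$e_ic, tolerance = 1e-12)
  expect_equal(m$v_ic, o$v_ic, tolerance = 1e-12)
  expect_equal(m$ic025, o$ic025, tolerance = 1e-12)
})

test_that("independence and symmetry identities hold", {
  m <- signal_metrics(5, 5, 5, 5)
  expect_equal(m$ror, 1)
  expect_true(m$ror_low < 1 && m$ror_high > 1)
  expect_equal(m$prr, 1)
  expect_equal(m$chi2, 0)
  expect_equal(m$ic, 0)  # a*N = (a+b)(a+c)

  set.seed(42)
  for (i in 1:25) {
    t <- sample(1:200, 4)
    m1 <- signal_metrics(t[1], t[2], t[3], t[4])
    m2 <- signal_metrics(t[2], t[1], t[4], t[3])
    mt <- signal_metrics(t[1], t[3], t[2], t[4])
    expect_equal(m1$ror, 1 / m2$ror, tolerance = 1e-12)
    expect_equal(m1$chi2, mt$chi2, tolerance = 1e-9)
  }
})

test_that("ROR, PRR and IC increase strictly in a with b, c, d fixed", {
  # IC monotonicity needs a below the comparator margins (log2 of the
  # observed/expected ratio turns over once a dominates them)
  b <- 50; c <- 100; d <- 5000
  m <- signal_metrics(1:40, rep(b, 40), rep(c, 40), rep(d, 40))
  expect_true(all(diff(m$ror) > 0))
  expect_true(all(diff(m$prr) > 0))
  expect_true(all(diff(m$ic) > 0))
  expect_true(all(diff(m$e_ic) > 0))
})

test_that("zero cells are flagged by default and smoothed under Haldane", {
  m <- signal_metrics(0, 10, 5, 100)
  expect_false(m$ror_defined)
  expect_true(is.na(m$ror))
  expect_false(m$ic_defined)
  # the prior-regularized moments remain computable
  expect_true(is.finite(m$e_ic) && is.finite(m$ic025))

  h <- signal_metrics(0, 10, 5, 100, zero_cell = "haldane")
  expect_true(h$ror_defined)
  expect_equal(h$ror, (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-12)

  expect_error(signal_metrics(-1, 1, 1, 1), "negative")
  expect_error(signal_metrics(0, 0, 0, 0), "N = 0")
})

test_that("ic025 stays below e_ic on arbitrary valid tables", {
  set.seed(7)
  t <- matrix(sample(0:500, 400, replace = TRUE), ncol = 4)
  t <- t[rowSums(t) > 0, ]
  m <- signal_metrics(t[, 1], t[, 2], t[, 3], t[, 4])
  expect_true(all(m$ic025 < m$e_ic))
  expect_true(all(m$v_ic > 0))
})

test_that("contingency counts agree with the generator ledger", {
  sim <- sim_faers(small_sim(seed = 13, n_cases = 1200))
  co <- build_cohort(dedup_tables(sim$tables), pembro_spec())
  led <- sim$ledger$signals
  for (k in seq_len(nrow(led))) {
    ct <- build_contingency(co, led$pt[k])
    expect_equal(ct$a, led$a[k], info = led$pt[k])
    expect_equal(ct$b, led$b[k], info = led$pt[k])
    expect_equal(ct$c, led$c[k], info = led$pt[k])
    expect_equal(ct$d, led$d[k], info = led$pt[k])
  }
  # a PT present only outside the cohort: a = 0, c > 0
  bg_only <- setdiff(unique(co$background$events$pt), unique(co$events$pt))
  if (length(bg_only)) {
    ct <- build_contingency(co, bg_only[1])
    expect_equal(ct$a, 0)
    expect_gt(ct$c, 0)
  }
  # absent PT is a zero table, not an error
  ct0 <- build_contingency(co, "No such PT anywhere")
  expect_equal(ct0$a + ct0$c, 0)
})

test_that("consensus flag implies every per-algorithm flag; min_a gates all", {
  sim <- sim_faers(small_sim(seed = 19, n_cases = 2000))
  co <- build_cohort(dedup_tables(sim$tables), pembro_spec())
  sig <- detect_signals(co)
  expect_true(all(sig$ror_positive[sig$all_three]))
  expect_true(all(sig$prr_positive[sig$all_three]))
  expect_true(all(sig$bcpnn_positive[sig$all_three]))
  expect_true(all(sig$a >= 3 | !(sig$ror_positive | sig$prr_positive |
                                   sig$bcpnn_positive)))
  # a cohort where every a < 3 yields zero positives
  high_gate <- detect_signals(co, criteria = signal_criteria(min_a = 1e6))
  expect_equal(sum(high_gate$positive), 0)
  expect_equal(attr(sig, "n_tested"), nrow(sig))
})

test_that("SOC roll-up pools reports and reports unmapped PTs", {
  # 10-case fixture by hand: SOC A = {P1, P2}, SOC B = {P3}
  cases <- make_cases(as.character(1:6))
  events <- tibble::tibble(
    primaryid = c("1", "1", "2", "3", "3", "4", "5"),
    pt = c("P1", "P2", "P1", "P3", "P1", "P3", "Unmapped PT"))
  bg_cases <- make_cases(as.character(101:110))
  bg_events <- tibble::tibble(primaryid = c("101", "102", "102", "103"),
                              pt = c("P1", "P2", "P1", "P3"))
  co <- fake_cohort(cases, events, bg_cases, bg_events)
  map <- tibble::tibble(pt = c("P1", "P2", "P3"), soc = c("A", "A", "B"))
  soc <- aggregate_soc(co, map)
  # report 1 lists two SOC-A PTs but counts once
  expect_equal(soc$a[soc$soc == "A"], 3)   # reports 1, 2, 3
  expect_equal(soc$a[soc$soc == "B"], 2)   # reports 3, 4
  expect_equal(soc$c[soc$soc == "A"], 2)   # background 101, 102
  expect_equal(soc$b[soc$soc == "A"], 3)   # 6 cohort reports - 3
  expect_equal(attr(soc, "unmapped_pts"), "Unmapped PT")
  expect_error(aggregate_soc(co, map[0, ]), "non-empty")
})

test_that("stratified detection recovers a stratum-specific planted signal", {
  # signal PT present only among elderly cohort cases
  n_young <- 40; n_old <- 40
  cases <- make_cases(as.character(1:80),
                      age_years = c(rep(40, n_young), rep(75, n_old)))
  old_ids <- as.character((n_young + 1):80)
  events <- dplyr::bind_rows(
    tibble::tibble(primaryid = old_ids[1:25], pt = "Signal PT"),
    tibble::tibble(primaryid = as.character(1:80), pt = "Common PT"))
  bg_cases <- make_cases(as.character(1001:3000),
                         age_years = rep(c(40, 75), 1000))
  bg_events <- dplyr::bind_rows(
    tibble::tibble(primaryid = as.character(1001:1040), pt = "Signal PT"),
    tibble::tibble(primaryid = as.character(1001:3000), pt = "Common PT"))
  co <- fake_cohort(cases, events, bg_cases, bg_events)
  st <- stratified_signals(co, "age_band")
  expect_setequal(names(st), c("<65", ">=65"))
  old_tab <- st[[">=65"]]
  young_tab <- st[["<65"]]
  expect_true(old_tab$positive[old_tab$pt == "Signal PT"])
  expect_false("Signal PT" %in% young_tab$pt[young_tab$positive])
  cmp <- attr(st, "comparison")
  expect_true("Signal PT" %in% cmp$unique[[">=65"]])
  # identical strata give identical positive sets
  cases2 <- make_cases(as.character(1:80), sex = rep(c("M", "F"), 40))
  events2 <- tibble::tibble(primaryid = as.character(1:80), pt = "Common PT")
  co2 <- fake_cohort(cases2, events2, bg_cases, bg_events)
  st2 <- stratified_signals(co2, "sex")
  pos <- lapply(st2, function(t) sort(t$pt[t$positive]))
  expect_equal(pos$M, pos$F)
})
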