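test_that("contingency tables are built by hand-count rules", {
  # 6-case toy store: 2 drugX+event, 1 drugX alone, 1 event alone, 2 neither
  store <- toy_store(1:6,
                     drug = c("drugX", "drugX", "drugX", NA, NA, NA),
                     pt = c("Proteinuria", "Proteinuria", NA, "Proteinuria",
                            NA, NA))
  tab <- build_contingency(store, "drugx", "Proteinuria")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]), c(a = 2, b = 1, c = 1, d = 2))
  # empty target set: a = c = 0
  tab0 <- build_contingency(store, "drugx", character(0))
  expect_equal(tab0$a + tab0$c, 0)
  # absent drug: a = b = 0, flagged
  tabx <- build_contingency(store, "nosuchdrug", "Proteinuria")
  expect_equal(tabx$a + tabx$b, 0)
  expect_true(isTRUE(attr(tabx, "absent")))
})

test_that("ROR, PRR, chi-square and expected count follow their definitions", {
  sym <- contingency_table(10, 10, 10, 10)
  r <- ror_with_ci(sym)
  expect_equal(r$ror, 1)
  expect_true(r$lo < 1 && 1 < r$hi)
  p <- prr_chi2(sym)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)
  e <- expected_count(sym)
  expect_equal(e$expected, 10)
  expect_equal(e$rr, 1)

  hand <- contingency_table(2, 1, 1, 2)
  expect_equal(prr_chi2(hand)$prr, 2)
  expect_equal(prr_chi2(hand)$chi2, 2 / 3)
  expect_equal(expected_count(hand)$expected, 1.5)
  expect_equal(expected_count(hand)$rr, 4 / 3)

  # zero cell: NA without correction, Haldane-Anscombe +0.5 on request
  z <- contingency_table(1, 0, 1, 1)
  expect_true(is.na(ror_with_ci(z)$ror))
  rh <- ror_with_ci(z, correction = "haldane")
  expect_equal(rh$ror, 3)
  expect_true(rh$corrected)
})

test_that("information component and its lower bound behave as defined", {
  sym <- contingency_table(10, 10, 10, 10)   # a = E
  ic <- bcpnn_ic(sym)
  expect_equal(ic$ic, 0)
  expect_lt(ic$ic025, ic$ic)
  # Noren closed-form offset at a = 250
  tab <- contingency_table(250, 1000, 2000, 100000)
  ic2 <- bcpnn_ic(tab)
  expect_equal(ic2$ic - ic2$ic025, 3.3 / sqrt(250) + 2 / 250^1.5,
               tolerance = 1e-12)
  # exact posterior-quantile mode is below the point estimate too
  ic3 <- bcpnn_ic(tab, ic025 = "exact")
  expect_lt(ic3$ic025, ic3$ic)
  # undefined at a = 0
  expect_true(is.na(bcpnn_ic(contingency_table(0, 5, 5, 5))$ic))
})

test_that("scalar and vectorized statistics match a brute-force oracle", {
  set.seed(42)
  n_tab <- 200
  cells <- matrix(sample(1:500, 4 * n_tab, replace = TRUE), ncol = 4)
  counts <- data.table(drug = sprintf("d%03d", seq_len(n_tab)),
                       a = cells[, 1], b = cells[, 2], c = cells[, 3],
                       d = cells[, 4])
  vec <- pvfaers:::compute_signal_stats(counts, classic_mgps_prior())
  for (i in seq_len(n_tab)) {
    o <- oracle_2x2(cells[i, 1], cells[i, 2], cells[i, 3], cells[i, 4])
    r <- ror_with_ci(cells[i, ])
    p <- prr_chi2(cells[i, ])
    e <- expected_count(cells[i, ])
    expect_equal(r$ror, o$ror, tolerance = 1e-12)
    expect_equal(r$lo, o$ror_lo, tolerance = 1e-12)
    expect_equal(p$prr, o$prr, tolerance = 1e-12)
    expect_equal(p$chi2, o$chi2, tolerance = 1e-12)
    expect_equal(e$expected, o$expected, tolerance = 1e-12)
    expect_equal(vec$ror[i], o$ror, tolerance = 1e-12)
    expect_equal(vec$chi2[i], o$chi2, tolerance = 1e-12)
    expect_equal(vec$ic[i], log2(o$rr), tolerance = 1e-12)
  }
})

test_that("EBGM follows the posterior geometric mean and shrinkage rules", {
  # two identical components = single Gamma(2,4) prior; a = 0, E = 0
  single <- gamma_mixture_prior(2, 4, 2, 4, 0.5)
  eb <- ebgm_scores(0, 0, single)
  expect_equal(eb$ebgm, exp(digamma(2)) / 4, tolerance = 1e-10)

  prior <- classic_mgps_prior()
  # monotone increasing in a at fixed E; ebgm05 <= ebgm; shrinkage toward 1
  eb2 <- ebgm_scores(c(5, 10, 20, 40, 80), rep(10, 5), prior)
  expect_true(all(diff(eb2$ebgm) > 0))
  expect_true(all(eb2$ebgm05 <= eb2$ebgm))
  high <- eb2$a / eb2$expected > 1
  expect_true(all(eb2$ebgm[high] <= (eb2$a / eb2$expected)[high]))

  # bisection quantile agrees with the quadrature oracle
  set.seed(7)
  for (i in 1:5) {
    a <- sample(1:400, 1); e <- runif(1, 0.5, 50)
    q <- ebgm05_quadrature(a, e, prior)
    expect_equal(ebgm_scores(a, e, prior)$ebgm05, q, tolerance = 1e-6)
  }
})

test_that("signal flags apply the four-method consensus thresholds", {
  strong <- data.table(a = 700, ror_lo = 30, prr = 39, chi2 = 2e4,
                       ic025 = 5, ebgm05 = 30)
  f <- evaluate_signal(strong)
  expect_true(f$consensus)

  prior <- classic_mgps_prior()
  indep <- pvfaers:::compute_signal_stats(
    data.table(drug = "x", a = 10, b = 10, c = 10, d = 10), prior)
  f0 <- evaluate_signal(indep)
  expect_false(any(unlist(f0[, .(flag_ror, flag_prr, flag_bcpnn, flag_mgps,
                                 consensus)])))

  tiny <- data.table(a = 2, ror_lo = 50, prr = 100, chi2 = 50, ic025 = 2,
                     ebgm05 = 10)
  expect_false(evaluate_signal(tiny)$flag_ror)   # a < 3 gate
  # missing component: flag false, pair not evaluable
  miss <- data.table(a = 10, ror_lo = NA_real_, prr = 3, chi2 = 10,
                     ic025 = 1, ebgm05 = 3)
  fm <- evaluate_signal(miss)
  expect_false(fm$flag_ror)
  expect_false(fm$evaluable)
})

test_that("table reconstruction inverts the ROR/PRR identities", {
  tab <- reconstruct_table(10, 20, 4, 2.5)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 10, b = 10, c = 10, d = 40), tolerance = 1e-9)
  # round trip on random tables
  set.seed(11)
  for (i in 1:50) {
    cells <- sample(5:2000, 4)
    o <- oracle_2x2(cells[1], cells[2], cells[3], cells[4])
    if (abs(o$ror - o$prr) < 1e-6) next
    rec <- reconstruct_table(cells[1], cells[1] + cells[3], o$ror, o$prr)
    expect_equal(rec$b, cells[2], tolerance = 1e-6)
    expect_equal(rec$d, cells[4], tolerance = 1e-6)
  }
  expect_error(reconstruct_table(10, 20, 3, 3), "non-reconstructible")
  expect_error(reconstruct_table(30, 20, 4, 2.5), "event total")
})
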