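test_that("onset days come from therapy start to event date, with exclusions", {
  store <- toy_store(1:5, drug = rep("lenvatinib", 5),
                     pt = rep("Proteinuria", 5),
                     event_dt = c("20200106", "20200106", "202003",
                                  "", "20991231"),
                     start_dt = c("20200101", "20200110", "20200101",
                                  "20200101", "20200101"))
  rec <- compute_onset_days(store, "Proteinuria")
  # case 1: 5 days; case 2: event before start; case 3: imprecise event
  # date; case 4: missing event date; case 5: > 25 years, implausible
  expect_equal(rec$primaryid, "1")
  expect_equal(rec$onset_days, 5)
  expect_equal(rec$drug_class, "anticancer")
  # imprecise dates can be opted in
  rec2 <- compute_onset_days(store, "Proteinuria", include_imprecise = TRUE)
  expect_setequal(rec2$primaryid, c("1", "3"))
})

test_that("multiple therapy episodes use the earliest start before the event", {
  demo <- data.table(primaryid = "1", caseid = "1", caseversion = "1",
                     fda_dt = "20200301", event_dt = "20200210", sex = "M",
                     age = "50", age_cod = "YR", wt = "70", wt_cod = "KG",
                     occr_country = "US")
  drug <- data.table(primaryid = c("1", "1"), caseid = c("1", "1"),
                     drug_seq = c("1", "2"), role_cod = c("PS", "PS"),
                     drugname = c("DRUGA", "DRUGA"))
  reac <- data.table(primaryid = "1", caseid = "1", pt = "Proteinuria")
  ther <- data.table(primaryid = c("1", "1"), caseid = c("1", "1"),
                     dsg_drug_seq = c("1", "2"),
                     start_dt = c("20200201", "20200101"),
                     end_dt = c("", ""))
  store <- build_case_store(list(demo = demo, drug = drug, reac = reac,
                                 ther = ther))
  rec <- compute_onset_days(store, "Proteinuria")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$onset_days, 40)  # from 2020-01-01, the earliest episode
})

test_that("class summaries use the linear-interpolation quartile convention", {
  rec <- data.table(drug_class = c(rep("anti-inflammatory", 4),
                                   rep("anticancer", 5), "digestive"),
                    onset_days = c(5, 5, 5, 5, 1, 2, 3, 4, 5, 10))
  s <- class_tto_summary(rec)
  ai <- s[drug_class == "anti-inflammatory"]
  expect_equal(unlist(ai[, .(mean, q1, q3)]), c(mean = 5, q1 = 5, q3 = 5))
  ac <- s[drug_class == "anticancer"]
  expect_equal(unlist(ac[, .(mean, q1, q3)]), c(mean = 3, q1 = 2, q3 = 4))
  dg <- s[drug_class == "digestive"]
  expect_equal(unlist(dg[, .(n, mean, q1, q3)]),
               c(n = 1, mean = 10, q1 = 10, q3 = 10))
  expect_true(all(s$q1 <= s$q3))
  # scaling all onsets by k scales the quartiles by k
  rec_k <- copy(rec)[, onset_days := onset_days * 3]
  s_k <- class_tto_summary(rec_k)
  expect_equal(s_k$q1, s$q1 * 3)
  expect_equal(s_k$q3, s$q3 * 3)
})

test_that("cumulative incidence is a proper ECDF on the supplied grid", {
  rec <- data.table(drug_class = "anticancer", onset_days = c(5, 10))
  ci <- cumulative_incidence(rec, grid = c(0, 5, 10))
  expect_equal(ci$cum_incidence, c(0, 0.5, 1.0))
  # monotone, order-invariant, reaches 1 at the maximum
  set.seed(23)
  rec2 <- data.table(drug_class = sample(c("x", "y"), 200, replace = TRUE),
                     onset_days = round(rexp(200, 1 / 100)))
  ci2 <- cumulative_incidence(rec2)
  for (cl in c("x", "y")) {
    v <- ci2[drug_class == cl, cum_incidence]
    expect_true(all(diff(v) >= 0))
    expect_equal(v[length(v)], 1)
  }
  ci3 <- cumulative_incidence(rec2[sample(.N)])
  expect_equal(ci3[order(drug_class, day)], ci2[order(drug_class, day)])
})

test_that("synthetic onset medians are recovered from ingested data", {
  cat_ <- data.frame(name = c("druga", "drugb"), share = 0.5, theta = 1,
                     onset_median_days = c(30, 365), onset_sdlog = 0.8)
  cfg <- synthetic_config(n_reports = 8000, drug_catalog = cat_, p0 = 0.5,
                          partial_date_rate = 0, duplicate_rate = 0,
                          seed = 19)
  store <- build_case_store(generate_reports(cfg))
  cmap <- c(druga = "anticancer", drugb = "antiviral")
  rec <- compute_onset_days(store, "Proteinuria", class_map = cmap)
  med <- rec[, stats::median(onset_days), by = drug_class]
  expect_equal(med[drug_class == "anticancer", V1], 30, tolerance = 0.1)
  expect_equal(med[drug_class == "antiviral", V1], 365, tolerance = 0.1)
})
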