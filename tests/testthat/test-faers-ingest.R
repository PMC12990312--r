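test_that("the $-delimited parser honours headers and survives bad rows", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$sex$age",
               "1001$10$M$40",
               "1002$11$F$55",
               "1003$12$M$60"), path)
  dt <- read_faers_table(path)
  expect_equal(nrow(dt), 3L)
  expect_equal(names(dt), c("primaryid", "caseid", "sex", "age"))
  expect_equal(attr(dt, "n_malformed"), 0L)

  # stray delimiter inside a text field: that row is logged, others intact
  writeLines(c("primaryid$caseid$sex$age",
               "1001$10$M$40",
               "1002$11$F$bad$value$55",
               "1003$12$M$60"), path)
  dt <- read_faers_table(path)
  expect_equal(nrow(dt), 2L)
  expect_equal(attr(dt, "n_malformed"), 1L)
  expect_equal(dt$primaryid, c("1001", "1003"))

  # missing mandatory column is a hard error naming the file
  writeLines(c("pid$sex", "1$M"), path)
  expect_error(read_faers_table(path, required = c("primaryid", "caseid")),
               basename(path))
})

test_that("a synthetic quarter round-trips through the file parser", {
  cfg <- synthetic_config(n_reports = 300, duplicate_rate = 0, seed = 5)
  tab <- generate_reports(cfg)
  dir <- withr::local_tempdir()
  write_faers_tables(tab, dir)
  parsed <- parse_quarter(list.files(dir, pattern = "^(DEMO|DRUG|REAC|THER)",
                                     full.names = TRUE))
  expect_equal(nrow(parsed$demo), nrow(tab$demo))
  expect_equal(nrow(parsed$drug), nrow(tab$drug))
  expect_equal(nrow(parsed$reac), nrow(tab$reac))
  expect_equal(nrow(parsed$ther), nrow(tab$ther))
  expect_equal(sum(parsed$log$n_malformed), 0L)
  expect_setequal(parsed$demo$primaryid, tab$demo$primaryid)
})

test_that("deduplication keeps the latest receipt date, ties to max primaryid", {
  demo <- data.table(
    primaryid = c("111", "112", "201", "202", "301"),
    caseid = c("11", "11", "20", "20", "30"),
    fda_dt = c("20200101", "20200301", "20200505", "20200505", "20210101"))
  kept <- deduplicate(demo)
  expect_equal(sort(kept$primaryid), c("112", "202", "301"))
  expect_equal(nrow(kept), length(unique(demo$caseid)))
  expect_equal(attr(kept, "n_removed"), 2L)
  # idempotence
  expect_equal(as.data.frame(deduplicate(kept)[order(caseid)]),
               as.data.frame(kept[order(caseid)]), ignore_attr = TRUE)
})

test_that("deduplication of a duplicated synthetic cohort matches ground truth", {
  cfg <- synthetic_config(n_reports = 1000, duplicate_rate = 0.1, seed = 2)
  tab <- generate_reports(cfg)
  kept <- deduplicate(tab$demo)
  expect_setequal(as.numeric(kept$primaryid),
                  tab$ground_truth$cases$primaryid_latest)
})

test_that("age and weight unit codes convert as defined", {
  demo <- data.table(
    primaryid = as.character(1:7), caseid = as.character(1:7),
    sex = c("M", "F", "", "M", "F", "M", "F"),
    age = c("2", "18", "50", "200", "26", "30", "40"),
    age_cod = c("DEC", "MON", "YR", "YR", "WK", "XX", "YR"),
    wt = c("154", "70000", "70", "70", "70", "70", "900"),
    wt_cod = c("LBS", "GMS", "KG", "KG", "KG", "KG", "KG"),
    occr_country = c("US", "USA", "JP", "", "FR", "DE", "CA"))
  norm <- normalize_demographics(demo)
  expect_equal(norm$age_years[1], 20)
  expect_equal(norm$age_years[2], 1.5)
  expect_true(is.na(norm$age_years[4]))     # out of range
  expect_equal(norm$age_years[5], 0.5)
  expect_true(is.na(norm$age_years[6]))     # unknown unit code
  expect_equal(norm$weight_kg[1], 69.85, tolerance = 1e-3)
  expect_equal(norm$weight_kg[2], 70)
  expect_true(is.na(norm$weight_kg[7]))     # out of range
  expect_equal(norm$sex, c("male", "female", NA, "male", "female", "male",
                           "female"))
  expect_equal(norm$country[1:2], c("United States", "United States"))
  expect_true(is.na(norm$country[4]))
})

test_that("drug names normalize through case folding, suffixes and synonyms", {
  expect_equal(normalize_drug_name("LENVIMA"), "lenvatinib")
  expect_equal(normalize_drug_name("Lenvatinib Mesylate"), "lenvatinib")
  expect_equal(normalize_drug_name("  drugX  "), "drugx")
  expect_equal(normalize_drug_name("Tenofovir Disoproxil Fumarate"),
               "tenofovir disoproxil")
  expect_equal(normalize_drug_name("ZOMETA"), "zoledronic acid")
  expect_equal(normalize_drug_name("ibuprofen  sodium"), "ibuprofen")
})

test_that("partial dates impute to fixed days and are flagged imprecise", {
  p <- parse_faers_date(c("20200115", "202003", "2021", "", "bogus1"))
  expect_equal(p$date[1:3],
               as.Date(c("2020-01-15", "2020-03-15", "2021-07-01")))
  expect_true(all(is.na(p$date[4:5])))
  expect_equal(p$imprecise[1:3], c(FALSE, TRUE, TRUE))
})

test_that("primary-suspect filtering keeps PS mentions and event margins", {
  demo <- data.table(primaryid = c("1", "2"), caseid = c("1", "2"),
                     caseversion = "1", fda_dt = "20200101",
                     event_dt = "20200110", sex = "M", age = "50",
                     age_cod = "YR", wt = "70", wt_cod = "KG",
                     occr_country = "US")
  drug <- data.table(primaryid = c("1", "1", "1", "2"),
                     caseid = c("1", "1", "1", "2"),
                     drug_seq = c("1", "2", "3", "1"),
                     role_cod = c("PS", "C", "C", "C"),
                     drugname = c("DRUGA", "DRUGB", "DRUGC", "DRUGA"))
  reac <- data.table(primaryid = c("1", "2"), caseid = c("1", "2"),
                     pt = c("Proteinuria", "Proteinuria"))
  store <- build_case_store(list(demo = demo, drug = drug, reac = reac))
  ps <- filter_primary_suspect(store)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$drug, "druga")
  # case 2 has no PS drug but still populates the event margin
  tab <- build_contingency(store, "druga", "Proteinuria")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 1, b = 0, c = 1, d = 0))
})

test_that("ingest round-trips a clean synthetic cohort exactly", {
  cfg <- synthetic_config(n_reports = 2000, duplicate_rate = 0,
                          partial_date_rate = 0, seed = 9)
  tab <- generate_reports(cfg)
  store <- build_case_store(tab)
  gt <- tab$ground_truth$cases
  expect_equal(nrow(store$cases), 2000L)
  # sex marginals match the generator's
  expect_equal(sum(store$cases$sex == "male", na.rm = TRUE),
               sum(gt$sex == "M"))
  expect_equal(sum(is.na(store$cases$age_years)), sum(is.na(gt$age_years)))
  # PS drug-event counts match ground truth exactly
  counts <- build_contingency_all(store, target_pts = "Proteinuria")
  gt_counts <- gt[, .(a_true = sum(target_event)), by = drug]
  merged <- merge(counts, gt_counts, by = "drug")
  expect_equal(merged$a, merged$a_true)
})
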