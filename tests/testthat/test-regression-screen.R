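test_that("design matrix coding and complete-case exclusion follow the model", {
  store <- toy_store(1:10,
                     drug = rep("druga", 10),
                     pt = c(rep("Proteinuria", 4), rep(NA, 6)),
                     sex = c("F", rep("M", 9)),
                     age = c("17", "", rep("50", 8)),
                     wt = c("60", rep("70", 9)))
  dm <- build_design_matrix(store, "Proteinuria")
  expect_equal(nrow(dm$data), 9L)          # one missing-age case dropped
  expect_equal(dm$n_excluded, 1L)
  r1 <- dm$data[dm$data$primaryid == "1", ]
  expect_equal(r1$sex_male, 0L)
  expect_equal(as.character(r1$age_class), "<18")   # reference level
  expect_equal(r1$weight_out_of_range, 0L)          # 60 kg is in 50-100
  expect_equal(levels(dm$data$age_class),
               c("<18", "18-40", "41-60", "61-80", ">80"))
  # 110 kg and 45 kg are out of range
  store2 <- toy_store(1:2, drug = c("druga", "druga"), wt = c("110", "45"))
  dm2 <- build_design_matrix(store2, "Proteinuria")
  expect_equal(dm2$data$weight_out_of_range, c(1L, 1L))
})

test_that("the univariate screen applies its three clauses", {
  # planted strong drug and a small-count drug with huge OR
  set.seed(21)
  n <- 4000
  druga <- rbinom(n, 1, 0.1)           # frequent, strong effect
  drugb <- c(rep(1, 50), rep(0, n - 50))  # a = 50 at most: fails count gate
  y <- rbinom(n, 1, plogis(-3 + 2.5 * druga + 3 * drugb))
  store <- toy_store(1:n,
                     drug = ifelse(druga == 1, "druga",
                                   ifelse(drugb == 1, "drugb", NA)),
                     pt = ifelse(y == 1, "Proteinuria", NA))
  dm <- build_design_matrix(store, "Proteinuria")
  scr <- univariate_screen(dm, min_a = 100, p_cut = 0.01)
  expect_true(scr[drug == "druga", retained])
  expect_false(scr[drug == "drugb", retained])
  expect_gt(scr[drug == "drugb", or], 1)   # excluded by the count gate alone

  # closed form equals a glm logistic fit
  g <- glm(y ~ druga, family = binomial())
  expect_equal(scr[drug == "druga", or],
               unname(exp(coef(g)["druga"])), tolerance = 1e-6)
  expect_equal(scr[drug == "druga", p],
               summary(g)$coefficients["druga", 4], tolerance = 1e-6)

  # monotonicity: raising the count gate never grows the retained set
  prev <- scr$drug[scr$retained]
  for (gate in c(150, 300, 600)) {
    cur <- univariate_screen(dm, min_a = gate)$drug
    cur <- cur[univariate_screen(dm, min_a = gate)$retained]
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("LASSO keeps the strong drug, drops the null, and nests by rule", {
  cat_ <- uniform_drug_catalog(10, c(druga = 20), signal_share = 0.1)
  cfg <- synthetic_config(n_reports = 15000, drug_catalog = cat_, p0 = 0.02,
                          demographics = default_demographics(0.05, 0.05,
                                                              0.05),
                          duplicate_rate = 0, seed = 13)
  store <- build_case_store(generate_reports(cfg))
  dm <- build_design_matrix(store, "Proteinuria")
  cand <- c("druga", "drug001", "drug002")
  sel <- lasso_select(dm, cand, seed = 4)
  expect_true("druga" %in% sel$selected)
  expect_false("drug001" %in% sel$selected)
  # at the largest lambda of the path no drug is selected
  expect_equal(sel$path$nonzero_drugs[1], 0)
  # lambda.1se selection nests inside lambda.min on the same folds
  sel_min <- lasso_select(dm, cand, rule = "lambda.min", seed = 4)
  expect_true(all(sel$selected %in% sel_min$selected))
  expect_error(lasso_select(dm, "druga"), "at least two")
})

test_that("the multivariate fit recovers a known log odds ratio", {
  # saturated single-predictor identity: OR equals the 2x2 cross-product
  store <- store_from_counts(2, 1, 1, 2)
  dm <- build_design_matrix(store, "Proteinuria")
  fit <- multivariate_fit(dm, "drugx")
  expect_equal(fit$terms[term == "drugx", or], 4, tolerance = 1e-6)

  # parameter recovery under the full covariate model
  set.seed(31)
  n <- 30000
  x <- rbinom(n, 1, 0.1)
  sexm <- rbinom(n, 1, 0.5)
  wt_out <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(-2.5 + 2.0 * x + 0.3 * sexm - 0.2 * wt_out))
  store2 <- toy_store(1:n,
                      drug = ifelse(x == 1, "druga", "drugz"),
                      pt = ifelse(y == 1, "Proteinuria", NA),
                      sex = ifelse(sexm == 1, "M", "F"),
                      age = sample(as.character(5:90), n, replace = TRUE),
                      wt = ifelse(wt_out == 1, "110", "70"))
  dm2 <- build_design_matrix(store2, "Proteinuria")
  fit2 <- multivariate_fit(dm2, "druga")
  expect_equal(fit2$terms[term == "druga", estimate], 2.0, tolerance = 0.15)
  expect_true(fit2$terms[term == "druga", significant])
})

test_that("AUC equals the pair-ranking oracle and known closed cases", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(c(0.2, 0.3), c(1, 1)), "single class")

  set.seed(17)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    s <- round(runif(n), 2)        # rounded scores force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), auc_pair_oracle(s, y), tolerance = 1e-12)
  }
  # independent library cross-check
  set.seed(18)
  s <- runif(300); y <- rbinom(300, 1, plogis(3 * s - 1.5))
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)

  # ROC points are monotone and end at (1, 1)
  rp <- roc_points(s, y)
  expect_true(all(diff(rp$tpr) >= 0))
  expect_true(all(diff(rp$fpr) >= 0))
  expect_equal(unlist(rp[nrow(rp), .(tpr, fpr)]), c(tpr = 1, fpr = 1))
})
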