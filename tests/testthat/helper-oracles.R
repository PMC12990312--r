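options(pvfaers.quiet = TRUE)
suppressMessages(library(data.table))

# Brute-force arithmetic oracle for the 2x2 statistics, written directly
# from the defining formulas (kept independent of the package internals).
oracle_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  list(
    ror = (a * d) / (b * c),
    ror_lo = exp(log((a * d) / (b * c)) -
                   1.96 * sqrt(1 / a + 1 / b + 1 / c + 1 / d)),
    ror_hi = exp(log((a * d) / (b * c)) +
                   1.96 * sqrt(1 / a + 1 / b + 1 / c + 1 / d)),
    prr = (a / (a + b)) / (c / (c + d)),
    chi2 = n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d)),
    expected = (a + b) * (a + c) / n,
    rr = a / ((a + b) * (a + c) / n))
}

# Quadrature oracle for the 5th posterior percentile of the gamma-mixture
# posterior: numerically integrates the posterior density with integrate()
# and inverts the CDF by bisection on that integral (no pgamma shortcut).
ebgm05_quadrature <- function(a, e, prior, prob = 0.05) {
  l1 <- dnbinom(a, size = prior$alpha1,
                prob = prior$beta1 / (prior$beta1 + e), log = TRUE)
  l2 <- dnbinom(a, size = prior$alpha2,
                prob = prior$beta2 / (prior$beta2 + e), log = TRUE)
  lw1 <- log(prior$w) + l1; lw2 <- log(1 - prior$w) + l2
  m <- max(lw1, lw2)
  q <- exp(lw1 - m) / (exp(lw1 - m) + exp(lw2 - m))
  dens <- function(x) {
    q * dgamma(x, prior$alpha1 + a, rate = prior$beta1 + e) +
      (1 - q) * dgamma(x, prior$alpha2 + a, rate = prior$beta2 + e)
  }
  cdf <- function(x) integrate(dens, 0, x, rel.tol = 1e-10,
                               abs.tol = 0)$value
  hi <- max(qgamma(0.999, prior$alpha1 + a, rate = prior$beta1 + e),
            qgamma(0.999, prior$alpha2 + a, rate = prior$beta2 + e))
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < prob) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * max(hi, 1)) break
  }
  (lo + hi) / 2
}

# Exhaustive pair-counting oracle for the AUC: probability that a random
# positive outranks a random negative, ties counting 1/2.
auc_pair_oracle <- function(scores, outcome) {
  pos <- scores[outcome == 1]
  neg <- scores[outcome == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# The canonical DuMouchel prior (historic fit to the FDA database); used as
# a realistic fixed prior in shrinkage checks.
classic_mgps_prior <- function() {
  gamma_mixture_prior(0.2, 0.1, 2, 4, 1 / 3)
}

# Small in-memory case store built directly from per-case vectors; bypasses
# file parsing so unit tests can target one operation at a time.
toy_store <- function(caseid, drug = NULL, role = "PS", pt = NULL,
                      sex = "M", age = "50", age_cod = "YR",
                      wt = "70", wt_cod = "KG", country = "US",
                      fda_dt = "20200101", event_dt = "20200110",
                      start_dt = "20200101") {
  n <- length(caseid)
  pid <- as.character(caseid)
  demo <- data.table(
    primaryid = pid, caseid = as.character(caseid), caseversion = "1",
    fda_dt = rep_len(fda_dt, n), event_dt = rep_len(event_dt, n),
    sex = rep_len(sex, n), age = rep_len(age, n),
    age_cod = rep_len(age_cod, n), wt = rep_len(wt, n),
    wt_cod = rep_len(wt_cod, n), occr_country = rep_len(country, n))
  has_drug <- !is.na(rep_len(drug %||% NA_character_, n))
  drug_dt <- data.table(
    primaryid = pid[has_drug], caseid = as.character(caseid)[has_drug],
    drug_seq = "1", role_cod = rep_len(role, n)[has_drug],
    drugname = rep_len(drug %||% NA_character_, n)[has_drug])
  has_pt <- !is.na(rep_len(pt %||% NA_character_, n))
  reac <- data.table(
    primaryid = pid[has_pt], caseid = as.character(caseid)[has_pt],
    pt = rep_len(pt %||% NA_character_, n)[has_pt])
  ther <- data.table(
    primaryid = pid[has_drug], caseid = as.character(caseid)[has_drug],
    dsg_drug_seq = "1", start_dt = rep_len(start_dt, n)[has_drug],
    end_dt = "")
  build_case_store(list(demo = demo, drug = drug_dt, reac = reac,
                        ther = ther))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Store realizing exact 2x2 counts (a, b, c, d) for one drug and one PT.
store_from_counts <- function(a, b, c, d, drug = "drugx",
                              pt = "Proteinuria") {
  n <- a + b + c + d
  caseid <- seq_len(n)
  drugs <- c(rep(drug, a + b), rep(NA_character_, c + d))
  pts <- c(rep(pt, a), rep(NA_character_, b), rep(pt, c),
           rep(NA_character_, d))
  toy_store(caseid, drug = drugs, pt = pts)
}

# Frozen study conditions for the planted-signal recovery experiment:
# 50 drugs, three planted rate ratios {5, 10, 40} with shares inversely
# scaled to theta (expected drug-and-event count ~230 each), p0 = 0.02,
# low (5%) per-field missingness.
recovery_config <- function(seed) {
  cat_ <- uniform_drug_catalog(
    50, c(sig05 = 5, sig10 = 10, sig40 = 40),
    signal_share = c(0.0575, 0.0288, 0.0072))
  synthetic_config(
    n_reports = 40000, drug_catalog = cat_, p0 = 0.02,
    demographics = default_demographics(0.05, 0.05, 0.05), seed = seed)
}
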