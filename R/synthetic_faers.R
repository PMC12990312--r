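# Synthetic FAERS-style data with known ground truth.
#
# The generator emulates the statistical structure a spontaneous-report
# analysis assumes: one primary-suspect (PS) drug per case, a target
# preferred term (PT) occurring with probability p0 * theta(drug), an
# independent pool of background PTs, demographics with FAERS unit codes and
# missingness, therapy/event dates with log-normal time-to-onset, and
# injected duplicate case versions that ingest must remove.

#' Default drug catalog for synthetic cohorts
#'
#' 25 generic names: five planted signal drugs (rate ratios 40, 25, 12, 8, 5,
#' echoing the spread seen among real proteinuria signals) and twenty null
#' drugs (theta = 1). Shares are uniform (0.04 each) and sum to 1. Onset
#' medians span the early (days) to late (years) regimes reported for
#' different drug classes.
#'
#' @return A `data.frame` with columns `name`, `share`, `theta`,
#'   `onset_median_days`, `onset_sdlog`.
#' @export
default_drug_catalog <- function() {
  signal <- data.frame(
    name = c("lenvatinib", "voclosporin", "tenofovir disoproxil",
             "atezolizumab", "everolimus"),
    share = 0.04,
    theta = c(40, 25, 12, 8, 5),
    onset_median_days = c(30, 60, 500, 90, 120),
    onset_sdlog = c(1.0, 1.0, 1.2, 1.0, 1.0)
  )
  null_names <- c(
    "metformin", "amlodipine", "atorvastatin", "omeprazole", "levothyroxine",
    "lisinopril", "sertraline", "gabapentin", "furosemide", "warfarin",
    "insulin glargine", "albuterol", "losartan", "clopidogrel", "simvastatin",
    "montelukast", "duloxetine", "pantoprazole", "rosuvastatin", "tramadol"
  )
  null <- data.frame(
    name = null_names, share = 0.04, theta = 1,
    onset_median_days = 60, onset_sdlog = 1.2
  )
  rbind(signal, null)
}

#' Build a uniform drug catalog of null and planted-signal drugs
#'
#' Convenience constructor for calibration studies: `n_drugs` drugs with
#' equal shares except for named planted signals, which receive
#' `signal_share` each and the given rate ratios.
#'
#' @param n_drugs total number of drugs.
#' @param signal_theta named numeric vector of planted rate ratios (may be
#'   empty for an all-null catalog).
#' @param signal_share share of reports assigned to each planted drug
#'   (scalar or one value per planted drug, e.g. inversely scaled to theta
#'   so every planted drug accrues comparable event counts); the remaining
#'   mass is split evenly over null drugs.
#' @param onset_median_days,onset_sdlog log-normal onset parameters applied
#'   to every drug.
#' @return A catalog `data.frame` as in [default_drug_catalog()].
#' @export
uniform_drug_catalog <- function(n_drugs, signal_theta = numeric(),
                                 signal_share = if (length(signal_theta)) 0.1 else NULL,
                                 onset_median_days = 60, onset_sdlog = 1.2) {
  k <- length(signal_theta)
  if (k >= n_drugs) stop_pv("need more drugs than planted signals")
  null_names <- sprintf("drug%03d", seq_len(n_drugs - k))
  if (k == 0) {
    share <- rep(1 / n_drugs, n_drugs)
    name <- null_names
    theta <- rep(1, n_drugs)
  } else {
    if (is.null(names(signal_theta)) || any(names(signal_theta) == "")) {
      names(signal_theta) <- sprintf("signal%02d", seq_len(k))
    }
    signal_share <- rep_len(signal_share, k)
    null_share <- (1 - sum(signal_share)) / (n_drugs - k)
    if (null_share <= 0) stop_pv("signal_share too large for catalog")
    name <- c(names(signal_theta), null_names)
    share <- c(signal_share, rep(null_share, n_drugs - k))
    theta <- c(unname(signal_theta), rep(1, n_drugs - k))
  }
  data.frame(name = name, share = share, theta = theta,
             onset_median_days = onset_median_days, onset_sdlog = onset_sdlog)
}

#' Default background preferred-term pool
#' @return Character vector of 20 MedDRA-style preferred terms.
#' @export
default_background_pts <- function() {
  c("Nausea", "Headache", "Fatigue", "Diarrhoea", "Dizziness", "Rash",
    "Vomiting", "Pyrexia", "Pruritus", "Arthralgia", "Dyspnoea", "Anaemia",
    "Insomnia", "Hypertension", "Constipation", "Cough", "Oedema peripheral",
    "Decreased appetite", "Myalgia", "Abdominal pain")
}

#' Configuration for the synthetic FAERS generator
#'
#' @param n_reports number of unique cases to simulate.
#' @param drug_catalog data.frame with columns `name`, `share` (marginal
#'   probability of being the PS drug; shares must sum to 1), `theta`
#'   (rate ratio for the target PT; 1 = null drug), `onset_median_days`,
#'   `onset_sdlog` (log-normal time-to-onset parameters).
#' @param target_pt the target preferred term.
#' @param background_pts pool of background PTs, each assigned independently.
#' @param background_event_prob per-PT probability of a background PT.
#' @param p0 baseline probability of the target PT; a case whose PS drug has
#'   rate ratio theta carries the target PT with probability `p0 * theta`
#'   (must not exceed 1 for any drug).
#' @param demographics list of demographic distribution settings; see
#'   [default_demographics()].
#' @param concomitant_rate probability that a case lists one concomitant
#'   (role C) drug in addition to its PS drug.
#' @param partial_date_rate fraction of therapy-start/event dates emitted at
#'   reduced precision (YYYYMM or YYYY) to exercise the ingest parser.
#' @param duplicate_rate fraction of cases gaining an extra report version
#'   (must be < 1).
#' @param seed integer RNG seed; the generator is deterministic given the
#'   full configuration.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 10000,
                             drug_catalog = default_drug_catalog(),
                             target_pt = "Proteinuria",
                             background_pts = default_background_pts(),
                             background_event_prob = 0.08,
                             p0 = 0.02,
                             demographics = default_demographics(),
                             concomitant_rate = 0.3,
                             partial_date_rate = 0.05,
                             duplicate_rate = 0.05,
                             seed = 1L) {
  cfg <- list(n_reports = as.integer(n_reports), drug_catalog = drug_catalog,
              target_pt = target_pt, background_pts = background_pts,
              background_event_prob = background_event_prob, p0 = p0,
              demographics = demographics, concomitant_rate = concomitant_rate,
              partial_date_rate = partial_date_rate,
              duplicate_rate = duplicate_rate, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' Default demographic distribution settings
#'
#' Sex/age/weight marginals, FAERS unit-code mixes, country weights and
#' per-field missingness rates, chosen to resemble the composition of a
#' renal-adverse-event case series (mean age in the 60s, US/Japan-dominated
#' reporting, double-digit missingness for sex and weight).
#'
#' @param sex_missing,age_missing,weight_missing per-field missingness rates.
#' @return A list consumed by [synthetic_config()].
#' @export
default_demographics <- function(sex_missing = 0.14, age_missing = 0.05,
                                 weight_missing = 0.15) {
  list(
    sex_probs = c(M = 0.44, F = 0.38, UNK = 0.18),
    sex_missing = sex_missing,
    age_mean = 62, age_sd = 20, age_missing = age_missing,
    age_unit_probs = c(YR = 0.90, DEC = 0.03, MON = 0.04, WK = 0.01, DY = 0.02),
    weight_mean = 75, weight_sd = 18, weight_missing = weight_missing,
    weight_unit_probs = c(KG = 0.85, LBS = 0.13, GMS = 0.02),
    country_probs = c(US = 0.33, JP = 0.17, FR = 0.06, CA = 0.04, DE = 0.04,
                      GB = 0.03, IT = 0.03, ES = 0.02, AU = 0.02, BR = 0.02,
                      CN = 0.24)
  )
}

validate_synthetic_config <- function(cfg) {
  cat <- cfg$drug_catalog
  need <- c("name", "share", "theta", "onset_median_days", "onset_sdlog")
  if (!all(need %in% names(cat))) {
    stop_pv("drug_catalog must have columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(cat$name)) stop_pv("duplicate drug names in catalog")
  if (any(cat$share <= 0) || abs(sum(cat$share) - 1) > 1e-8) {
    stop_pv("drug shares must be positive and sum to 1")
  }
  if (any(cat$theta < 0)) stop_pv("rate ratios must be nonnegative")
  if (any(cat$onset_median_days <= 0) || any(cat$onset_sdlog < 0)) {
    stop_pv("onset distributions need positive median and nonnegative log-SD")
  }
  if (cfg$n_reports < 0) stop_pv("n_reports must be nonnegative")
  if (cfg$p0 <= 0 || cfg$p0 >= 1) stop_pv("p0 must lie in (0,1)")
  if (cfg$p0 * max(cat$theta) > 1) {
    stop_pv("probability overflow: p0 * max(theta) = %.3f exceeds 1",
            cfg$p0 * max(cat$theta))
  }
  if (cfg$background_event_prob <= 0 || cfg$background_event_prob >= 1) {
    stop_pv("background_event_prob must lie in (0,1)")
  }
  if (cfg$duplicate_rate < 0 || cfg$duplicate_rate >= 1) {
    stop_pv("duplicate_rate must lie in [0,1)")
  }
  if (cfg$partial_date_rate < 0 || cfg$partial_date_rate >= 1) {
    stop_pv("partial_date_rate must lie in [0,1)")
  }
  invisible(cfg)
}

# Degrade a YYYYMMDD string to YYYYMM / YYYY for a random subset of rows.
degrade_dates <- function(x, rate) {
  n <- length(x)
  u <- runif(n)
  ym <- u < rate * 0.8
  yo <- !ym & u < rate
  x[ym] <- substr(x[ym], 1, 6)
  x[yo] <- substr(x[yo], 1, 4)
  x
}

#' Generate a synthetic FAERS-style report set
#'
#' Draws `n_reports` unique cases under `config`, then injects duplicate case
#' versions at `config$duplicate_rate`. Output is deterministic given the
#' configuration (including its seed).
#'
#' @param config a [synthetic_config()].
#' @return An object of class `faers_tables`: a list with data.tables `demo`,
#'   `drug`, `reac`, `ther` (character columns, FAERS-style headers), the
#'   `ground_truth` list (per-drug `theta`, `onset_median_days`,
#'   `true_signals`, per-case table `cases` with the latest primaryid, PS
#'   drug, target-event flag and true onset), and the `config`.
#' @export
generate_reports <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_reports
  cat <- config$drug_catalog
  dem <- config$demographics
  if (n == 0L) {
    empty <- function(cols) {
      dt <- data.table::as.data.table(
        setNames(rep(list(character(0)), length(cols)), cols))
      dt
    }
    gt <- list(theta = setNames(cat$theta, cat$name),
               onset_median_days = setNames(cat$onset_median_days, cat$name),
               true_signals = cat$name[cat$theta > 1],
               cases = data.table::data.table(),
               duplicated_caseids = integer(0))
    out <- list(demo = empty(faers_demo_cols()), drug = empty(faers_drug_cols()),
                reac = empty(faers_reac_cols()), ther = empty(faers_ther_cols()),
                ground_truth = gt, config = config)
    class(out) <- "faers_tables"
    return(out)
  }

  out <- with_seed(config$seed, {
    drug_idx <- sample.int(nrow(cat), n, replace = TRUE, prob = cat$share)
    ps_drug <- cat$name[drug_idx]
    theta <- cat$theta[drug_idx]
    target <- runif(n) < pmin(config$p0 * theta, 1)

    k <- length(config$background_pts)
    bg <- matrix(runif(n * k) < config$background_event_prob, n, k)
    # every report must carry at least one reaction PT
    none <- !target & rowSums(bg) == 0L
    if (any(none)) {
      bg[cbind(which(none), sample.int(k, sum(none), replace = TRUE))] <- TRUE
    }

    sex <- sample(c("M", "F", "UNK"), n, TRUE, prob = dem$sex_probs)
    sex[runif(n) < dem$sex_missing] <- ""
    age_years <- pmin(pmax(rnorm(n, dem$age_mean, dem$age_sd), 0.1), 100)
    age_cod <- sample(names(dem$age_unit_probs), n, TRUE, dem$age_unit_probs)
    age_val <- round(age_years * c(YR = 1, DEC = 0.1, MON = 12, WK = 52,
                                   DY = 365.25)[age_cod], 2)
    age_miss <- runif(n) < dem$age_missing
    weight_kg <- pmin(pmax(rnorm(n, dem$weight_mean, dem$weight_sd), 2), 250)
    wt_cod <- sample(names(dem$weight_unit_probs), n, TRUE,
                     dem$weight_unit_probs)
    wt_val <- round(weight_kg * c(KG = 1, LBS = 1 / 0.453592,
                                  GMS = 1000)[wt_cod], 2)
    wt_miss <- runif(n) < dem$weight_missing
    country <- sample(names(dem$country_probs), n, TRUE, dem$country_probs)

    start <- as.Date("2004-01-01") + floor(runif(n, 0, 7305))
    onset_days <- pmax(round(rlnorm(n, log(cat$onset_median_days[drug_idx]),
                                    cat$onset_sdlog[drug_idx])), 0)
    event <- start + onset_days
    fda <- event + 7 + floor(runif(n, 0, 114))

    caseid <- seq_len(n)
    primaryid <- caseid * 100L + 1L

    start_str <- degrade_dates(format_faers_date(start),
                               config$partial_date_rate)
    event_str <- degrade_dates(format_faers_date(event),
                               config$partial_date_rate)

    demo <- data.table::data.table(
      primaryid = as.character(primaryid), caseid = as.character(caseid),
      caseversion = "1", fda_dt = format_faers_date(fda),
      event_dt = event_str, sex = sex,
      age = ifelse(age_miss, "", sprintf("%.2f", age_val)),
      age_cod = ifelse(age_miss, "", age_cod),
      wt = ifelse(wt_miss, "", sprintf("%.2f", wt_val)),
      wt_cod = ifelse(wt_miss, "", wt_cod),
      occr_country = country)

    drug <- data.table::data.table(
      primaryid = as.character(primaryid), caseid = as.character(caseid),
      drug_seq = "1", role_cod = "PS", drugname = toupper(ps_drug))
    has_con <- runif(n) < config$concomitant_rate
    if (any(has_con)) {
      con_drug <- cat$name[sample.int(nrow(cat), sum(has_con), replace = TRUE)]
      drug <- rbind(drug, data.table::data.table(
        primaryid = as.character(primaryid[has_con]),
        caseid = as.character(caseid[has_con]),
        drug_seq = "2", role_cod = "C", drugname = toupper(con_drug)))
    }

    pts <- c(list(ifelse(target, config$target_pt, NA_character_)),
             lapply(seq_len(k), function(j) {
               ifelse(bg[, j], config$background_pts[j], NA_character_)
             }))
    reac <- data.table::rbindlist(lapply(pts, function(p) {
      keep <- !is.na(p)
      data.table::data.table(primaryid = as.character(primaryid[keep]),
                             caseid = as.character(caseid[keep]), pt = p[keep])
    }))
    data.table::setkey(reac, primaryid)

    dur <- 30 + floor(runif(n, 0, 970))
    ther <- data.table::data.table(
      primaryid = as.character(primaryid), caseid = as.character(caseid),
      dsg_drug_seq = "1", start_dt = start_str,
      end_dt = format_faers_date(start + dur))

    gt_cases <- data.table::data.table(
      caseid = caseid, primaryid_latest = primaryid, drug = ps_drug,
      target_event = target, onset_days = as.numeric(onset_days),
      sex = sex, age_years = ifelse(age_miss, NA_real_, age_years),
      weight_kg = ifelse(wt_miss, NA_real_, weight_kg))

    gt <- list(theta = setNames(cat$theta, cat$name),
               onset_median_days = setNames(cat$onset_median_days, cat$name),
               true_signals = cat$name[cat$theta > 1],
               cases = gt_cases, duplicated_caseids = integer(0))
    res <- list(demo = demo, drug = drug, reac = reac, ther = ther,
                ground_truth = gt, config = config)
    class(res) <- "faers_tables"
    res
  })
  if (config$duplicate_rate > 0) {
    out <- inject_duplicates(out, config$duplicate_rate,
                             seed = config$seed + 1L)
  }
  out
}

#' Inject duplicate case versions
#'
#' A random fraction of caseids gains one additional report version with a
#' new primaryid, a receipt date at or after the original's, and (for a
#' subset) an amended weight — the situation FAERS deduplication must
#' resolve. Ground truth is updated so `cases$primaryid_latest` names the
#' report version a correct deduplication keeps.
#'
#' @param tables a `faers_tables` object from [generate_reports()].
#' @param duplicate_rate fraction of caseids duplicated, in \[0,1).
#' @param seed integer RNG seed.
#' @return The modified `faers_tables` object.
#' @export
inject_duplicates <- function(tables, duplicate_rate, seed = 1L) {
  stopifnot(inherits(tables, "faers_tables"))
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    stop_pv("duplicate_rate must lie in [0,1)")
  }
  if (duplicate_rate == 0 || nrow(tables$demo) == 0L) return(tables)
  with_seed(seed, {
    demo <- tables$demo
    orig <- demo[demo$caseversion == "1", ]
    dup_sel <- runif(nrow(orig)) < duplicate_rate
    if (!any(dup_sel)) return(tables)
    dup <- data.table::copy(orig[dup_sel, ])
    old_pid <- dup$primaryid
    dup[, `:=`(
      primaryid = as.character(as.numeric(caseid) * 100 + 2),
      caseversion = "2",
      fda_dt = format_faers_date(as.Date(fda_dt, format = "%Y%m%d") +
                                   sample(0:365, .N, replace = TRUE)))]
    amend <- runif(nrow(dup)) < 0.3
    if (any(amend)) {
      dup[amend, `:=`(wt = sprintf("%.1f", runif(sum(amend), 45, 110)),
                      wt_cod = "KG")]
    }
    pid_map <- setNames(dup$primaryid, old_pid)
    copy_rows <- function(dt) {
      add <- dt[dt$primaryid %in% old_pid, ]
      if (nrow(add) == 0L) return(dt)
      add <- data.table::copy(add)
      add[, primaryid := unname(pid_map[primaryid])]
      rbind(dt, add)
    }
    tables$demo <- rbind(demo, dup)
    tables$drug <- copy_rows(tables$drug)
    tables$reac <- copy_rows(tables$reac)
    tables$ther <- copy_rows(tables$ther)
    dup_cid <- as.integer(dup$caseid)
    gtc <- tables$ground_truth$cases
    gtc[caseid %in% dup_cid,
        primaryid_latest := caseid * 100L + 2L]
    tables$ground_truth$cases <- gtc
    tables$ground_truth$duplicated_caseids <- sort(dup_cid)
    tables
  })
}

faers_demo_cols <- function() c("primaryid", "caseid", "caseversion", "fda_dt",
                                "event_dt", "sex", "age", "age_cod", "wt",
                                "wt_cod", "occr_country")
faers_drug_cols <- function() c("primaryid", "caseid", "drug_seq", "role_cod",
                                "drugname")
faers_reac_cols <- function() c("primaryid", "caseid", "pt")
faers_ther_cols <- function() c("primaryid", "caseid", "dsg_drug_seq",
                                "start_dt", "end_dt")

#' Write synthetic tables as FAERS quarterly ASCII files
#'
#' Splits each table by the quarter of the report's receipt date and writes
#' one "$"-delimited file per table per quarter (`DEMO09Q1.txt`, ...), plus
#' `ground_truth.json` (per-drug parameters) and `ground_truth_cases.csv`.
#'
#' @param tables a `faers_tables` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_faers_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "faers_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  demo <- tables$demo
  d <- as.Date(demo$fda_dt, format = "%Y%m%d")
  qtr <- sprintf("%02dQ%d", as.integer(format(d, "%y")),
                 (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L)
  pid_qtr <- setNames(qtr, demo$primaryid)
  files <- character(0)
  for (tab in c("demo", "drug", "reac", "ther")) {
    dt <- tables[[tab]]
    qq <- pid_qtr[dt$primaryid]
    for (q in sort(unique(qq))) {
      path <- file.path(dir, sprintf("%s%s.txt", toupper(tab), q))
      data.table::fwrite(dt[qq == q, ], path, sep = "$", quote = FALSE)
      files <- c(files, path)
    }
  }
  gt <- tables$ground_truth
  gt_json <- list(theta = as.list(gt$theta),
                  onset_median_days = as.list(gt$onset_median_days),
                  true_signals = gt$true_signals,
                  duplicated_caseids = gt$duplicated_caseids,
                  n_cases = nrow(gt$cases))
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(gt$cases, file.path(dir, "ground_truth_cases.csv"))
  invisible(c(files, file.path(dir, c("ground_truth.json",
                                      "ground_truth_cases.csv"))))
}
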