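# End-to-end pipeline: generate/ingest -> baseline table -> signal detection
# -> regression screen -> time-to-onset, with reproducible artifacts.

#' Baseline characteristics of target-event cases
#'
#' Counts and component ratios (count / total target-event cases, as a
#' percentage with two decimals) over the descriptive bins of a
#' pharmacovigilance baseline table: sex; age <18, 18-64, 65-85, >85;
#' weight (kg) <25, 25-50, 51-75, >76; receipt-year quadrennia 2004-2024;
#' top-5 reporting countries plus Others. The denominator is always the full
#' target-event case count.
#'
#' @param store a `case_store`.
#' @param target_pts target preferred terms.
#' @return data.table with `section`, `level`, `n`, `pct`.
#' @export
summarize_baseline <- function(store, target_pts) {
  stopifnot(inherits(store, "case_store"))
  tgt <- unique(store$events$primaryid[
    tolower(store$events$pt) %in% tolower(target_pts)])
  cases <- store$cases[store$cases$primaryid %in% tgt, ]
  total <- nrow(cases)
  if (total == 0L) stop_pv("no target-event cases to summarize")
  pct <- function(n) round(100 * n / total, 2)
  row <- function(section, level, n) {
    data.table::data.table(section = section, level = level, n = n,
                           pct = pct(n))
  }
  out <- list()

  sex_lvl <- c(male = "Male", female = "Female")
  for (s in names(sex_lvl)) {
    out[[length(out) + 1L]] <- row("Sex", sex_lvl[[s]],
                                   sum(cases$sex == s, na.rm = TRUE))
  }
  out[[length(out) + 1L]] <- row("Sex", "Missing", sum(is.na(cases$sex)))

  age <- cases$age_years
  age_bins <- list("<18" = !is.na(age) & age < 18,
                   "18-64" = !is.na(age) & age >= 18 & age < 65,
                   "65-85" = !is.na(age) & age >= 65 & age <= 85,
                   ">85" = !is.na(age) & age > 85,
                   "Missing" = is.na(age))
  for (b in names(age_bins)) {
    out[[length(out) + 1L]] <- row("Age", b, sum(age_bins[[b]]))
  }

  wt <- cases$weight_kg
  wt_bins <- list("<25" = !is.na(wt) & wt < 25,
                  "25-50" = !is.na(wt) & wt >= 25 & wt <= 50,
                  "51-75" = !is.na(wt) & wt > 50 & wt <= 75,
                  ">76" = !is.na(wt) & wt > 75,
                  "Missing" = is.na(wt))
  for (b in names(wt_bins)) {
    out[[length(out) + 1L]] <- row("Weight (kg)", b, sum(wt_bins[[b]]))
  }

  if ("receipt_date" %in% names(cases)) {
    yr <- as.integer(format(cases$receipt_date, "%Y"))
    yr_bins <- list("2004-2008" = c(2004, 2008), "2009-2012" = c(2009, 2012),
                    "2013-2016" = c(2013, 2016), "2017-2020" = c(2017, 2020),
                    "2021-2024" = c(2021, 2024))
    for (b in names(yr_bins)) {
      out[[length(out) + 1L]] <- row(
        "Reporting year", b,
        sum(!is.na(yr) & yr >= yr_bins[[b]][1] & yr <= yr_bins[[b]][2]))
    }
  }

  cn <- cases$country
  top <- names(sort(table(cn), decreasing = TRUE))
  top <- utils::head(top, 5L)
  for (b in top) {
    out[[length(out) + 1L]] <- row("Country", b, sum(!is.na(cn) & cn == b))
  }
  out[[length(out) + 1L]] <- row("Country", "Others",
                                 sum(is.na(cn) | !(cn %in% top)))

  res <- data.table::rbindlist(out)
  data.table::setattr(res, "total", total)
  res[]
}

#' Pipeline run configuration
#'
#' @param input_mode `"synthetic"` (default) or `"faers_dir"`.
#' @param synthetic a [synthetic_config()] (synthetic mode).
#' @param faers_dir directory of FAERS quarterly ASCII files (faers_dir
#'   mode).
#' @param target_pts target preferred terms.
#' @param screen_min_a,screen_p_cut,screen_or_lo univariate screen
#'   thresholds.
#' @param criteria signal criteria from [signal_criteria()].
#' @param lambda_rule LASSO lambda rule.
#' @param ic025_mode IC025 mode, `"noren"` or `"exact"`.
#' @param signal_min_a minimum drug-event count for a signal-table row.
#' @param seed integer seed for the cross-validation folds.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_mode = c("synthetic", "faers_dir"),
                       synthetic = synthetic_config(),
                       faers_dir = NULL,
                       target_pts = "Proteinuria",
                       screen_min_a = 100, screen_p_cut = 0.01,
                       screen_or_lo = 1,
                       criteria = signal_criteria(),
                       lambda_rule = "lambda.1se",
                       ic025_mode = "noren",
                       signal_min_a = 3,
                       seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "faers_dir" && is.null(faers_dir)) {
    stop_pv("faers_dir mode requires a directory")
  }
  structure(list(input_mode = input_mode, synthetic = synthetic,
                 faers_dir = faers_dir, target_pts = target_pts,
                 screen_min_a = screen_min_a, screen_p_cut = screen_p_cut,
                 screen_or_lo = screen_or_lo, criteria = criteria,
                 lambda_rule = lambda_rule, ic025_mode = ic025_mode,
                 signal_min_a = signal_min_a, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The document maps 1:1 onto [run_config()]; the `synthetic` block maps
#' onto [synthetic_config()], with `drug_catalog` given as a list of
#' records.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn_args <- y$synthetic %||% list()
  if (!is.null(syn_args$drug_catalog)) {
    syn_args$drug_catalog <- data.table::rbindlist(syn_args$drug_catalog)
  }
  if (!is.null(syn_args$demographics)) {
    syn_args$demographics <- utils::modifyList(default_demographics(),
                                               syn_args$demographics)
  }
  syn <- do.call(synthetic_config, syn_args)
  args <- y[setdiff(names(y), "synthetic")]
  args$synthetic <- syn
  if (!is.null(args$criteria)) {
    args$criteria <- do.call(signal_criteria, args$criteria)
  }
  do.call(run_config, args)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

load_faers_dir <- function(dir) {
  files <- list.files(dir, pattern = "^(DEMO|DRUG|REAC|THER)[0-9]{2}Q[1-4]",
                      full.names = TRUE, ignore.case = TRUE)
  if (length(files) == 0L) stop_pv("no FAERS quarterly files in %s", dir)
  parse_quarter(files)
}

#' Run the full pipeline
#'
#' Generates (or ingests) the report tables, then runs baseline
#' summarization, four-method signal detection, the regression screen and
#' the time-to-onset analysis, writing every artifact to `out_dir`:
#' `baseline.csv`, `signals.csv`, `prior.json`, `regression.csv`,
#' `lambda_path.csv`, `roc_points.csv`, `tto_summary.csv`, `tto_ecdf.csv`,
#' `run_summary.json`, `manifest.json` and, in synthetic mode, the generated
#' quarterly files under `faers/` plus `gt_comparison.json`. Identical
#' config and seeds give identical artifacts.
#'
#' @param config a `run_config`.
#' @param out_dir output directory.
#' @param stages subset of stages to run (default all).
#' @return Invisibly, a list with the in-memory results (`store`, `baseline`,
#'   `signals`, `prior`, `screen`, `tto_summary`, `tto_ecdf`, `gt_comparison`).
#' @export
run_all <- function(config, out_dir,
                    stages = c("baseline", "signals", "regress", "tto")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  tables <- NULL
  if (config$input_mode == "synthetic") {
    tables <- generate_reports(config$synthetic)
    write_faers_tables(tables, file.path(out_dir, "faers"))
    parsed <- load_faers_dir(file.path(out_dir, "faers"))
  } else {
    parsed <- load_faers_dir(config$faers_dir)
  }
  store <- build_case_store(parsed)
  pv_log("ingest: %d rows read, %d malformed, %d duplicate versions removed, %d cases",
         sum(parsed$log$n_rows), sum(parsed$log$n_malformed),
         store$log$n_duplicates_removed, nrow(store$cases))
  res <- list(store = store)

  if ("baseline" %in% stages) {
    res$baseline <- summarize_baseline(store, config$target_pts)
    write.csv(res$baseline, file.path(out_dir, "baseline.csv"),
              row.names = FALSE)
  }

  if ("signals" %in% stages || "regress" %in% stages) {
    sig <- signal_table(store, config$target_pts, criteria = config$criteria,
                        ic025 = config$ic025_mode, min_a = config$signal_min_a)
    res$signals <- sig$stats
    res$prior <- sig$prior
    write.csv(sig$stats, file.path(out_dir, "signals.csv"), row.names = FALSE)
    jsonlite::write_json(sig$prior[c("alpha1", "beta1", "alpha2", "beta2",
                                     "w", "loglik")],
                         file.path(out_dir, "prior.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  if ("regress" %in% stages) {
    res$screen <- screen_cascade(store, config$target_pts,
                                 min_a = config$screen_min_a,
                                 p_cut = config$screen_p_cut,
                                 or_lo_min = config$screen_or_lo,
                                 rule = config$lambda_rule,
                                 seed = config$seed)
    if (!is.null(res$screen$fit)) {
      write.csv(res$screen$fit$terms, file.path(out_dir, "regression.csv"),
                row.names = FALSE)
      write.csv(res$screen$roc, file.path(out_dir, "roc_points.csv"),
                row.names = FALSE)
    }
    if (!is.null(res$screen$lasso)) {
      write.csv(res$screen$lasso$path, file.path(out_dir, "lambda_path.csv"),
                row.names = FALSE)
    }
  }

  if ("tto" %in% stages) {
    rec <- compute_onset_days(store, config$target_pts)
    res$tto_summary <- class_tto_summary(rec)
    res$tto_ecdf <- cumulative_incidence(rec)
    write.csv(res$tto_summary, file.path(out_dir, "tto_summary.csv"),
              row.names = FALSE)
    write.csv(res$tto_ecdf, file.path(out_dir, "tto_ecdf.csv"),
              row.names = FALSE)
  }

  if (!is.null(tables) && !is.null(res$signals)) {
    gt <- tables$ground_truth
    flagged <- res$signals$drug[res$signals$consensus]
    res$gt_comparison <- list(
      true_signals = sort(gt$true_signals),
      consensus_flagged = sort(flagged),
      exact_match = setequal(gt$true_signals, flagged),
      multivariate_significant =
        if (!is.null(res$screen$fit))
          sort(res$screen$fit$terms[significant == TRUE, term]) else NULL)
    jsonlite::write_json(res$gt_comparison,
                         file.path(out_dir, "gt_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  summary <- list(
    n_cases = nrow(store$cases),
    n_target_cases = length(unique(store$events$primaryid[
      tolower(store$events$pt) %in% tolower(config$target_pts)])),
    n_consensus_signals = if (!is.null(res$signals))
      sum(res$signals$consensus) else NA,
    n_selected_drugs = length(res$screen$selected %||% character(0)),
    auc = res$screen$auc %||% NA_real_)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "pvfaers",
    version = as.character(utils::packageVersion("pvfaers")),
    r_version = as.character(getRversion()),
    config_hash = config_hash(config),
    seed = config$seed,
    input_mode = config$input_mode,
    stages = stages,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Command-line entry point
#'
#' Drives the pipeline from a shell: `pv <simulate|ingest|signals|regress|
#' tto|all> [--config cfg.yaml] [--out DIR] [--seed N] [--faers-dir DIR]`.
#' A thin Rscript wrapper is installed at `system.file("cli", "pv.R",
#' package = "pvfaers")`.
#'
#' @param args character vector of command-line arguments.
#' @return Invisibly, the [run_all()] result (or the written file list for
#'   `simulate`).
#' @export
pv_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pv <simulate|ingest|signals|regress|tto|all>",
    "[--config cfg.yaml] [--out DIR] [--seed N] [--faers-dir DIR]")
  if (length(args) < 1L) stop_pv(usage)
  cmd <- args[1L]
  opts <- list(out = "pv_out", seed = NULL, config = NULL, faers_dir = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opts) || i == length(args)) stop_pv(usage)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
         else run_config()
  if (!is.null(opts$seed)) {
    cfg$seed <- as.integer(opts$seed)
    cfg$synthetic$seed <- as.integer(opts$seed)
  }
  if (!is.null(opts$faers_dir)) {
    cfg$input_mode <- "faers_dir"
    cfg$faers_dir <- opts$faers_dir
  }
  stages <- switch(cmd,
                   simulate = character(0),
                   ingest = character(0),
                   signals = "signals",
                   regress = "regress",
                   tto = "tto",
                   all = c("baseline", "signals", "regress", "tto"),
                   stop_pv(usage))
  if (cmd == "simulate") {
    tables <- generate_reports(cfg$synthetic)
    files <- write_faers_tables(tables, opts$out)
    pv_log("wrote %d files to %s", length(files), opts$out)
    return(invisible(files))
  }
  res <- run_all(cfg, opts$out, stages = stages)
  invisible(res)
}
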