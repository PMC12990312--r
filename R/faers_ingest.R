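# Ingest of FAERS-style quarterly ASCII tables: parsing, case
# deduplication, demographic/unit normalization, drug-name normalization and
# primary-suspect filtering, ending in a normalized case store.

#' Read one FAERS "$"-delimited ASCII table
#'
#' Columns are taken from the header row (by name, not position). Rows whose
#' field count does not match the header — e.g. a stray delimiter inside a
#' free-text field — are counted and logged as malformed, never fatal.
#'
#' @param path file path.
#' @param required character vector of column names that must be present; a
#'   missing one is a hard error naming the file.
#' @return A data.table of character columns, with attributes `n_malformed`
#'   and `source` recording parse quality.
#' @export
read_faers_table <- function(path, required = character(0)) {
  if (!file.exists(path)) stop_pv("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop_pv("empty file: %s", path)
  header <- strsplit(lines[1L], "$", fixed = TRUE)[[1L]]
  miss <- setdiff(required, header)
  if (length(miss)) {
    stop_pv("file %s lacks mandatory column(s): %s", basename(path),
            paste(miss, collapse = ", "))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "$", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; pad rows one short
  nf <- lengths(parts)
  pad <- nf == length(header) - 1L & endsWith(body, "$")
  parts[pad] <- lapply(parts[pad], function(p) c(p, ""))
  nf[pad] <- nf[pad] + 1L
  ok <- nf == length(header)
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    pv_log("%s: %d malformed row(s) skipped", basename(path), n_bad)
  }
  cols <- data.table::transpose(parts[ok])
  if (is.null(cols)) cols <- rep(list(character(0)), length(header))
  dt <- data.table::setDT(setNames(cols, header))
  data.table::setattr(dt, "n_malformed", n_bad)
  data.table::setattr(dt, "source", path)
  dt[]
}

#' Parse all tables of one or more FAERS quarters
#'
#' @param paths named list or character vector of file paths; names (or file
#'   name prefixes DEMO/DRUG/REAC/THER/INDI/OUTC/RPSR) identify the table
#'   type. Multiple files of one type (several quarters) are stacked.
#' @return A list with one data.table per table type present, plus a `log`
#'   data.table of per-file row and malformed-row counts.
#' @export
parse_quarter <- function(paths) {
  paths <- unlist(paths)
  types <- names(paths)
  if (is.null(types) || any(!nzchar(types))) {
    types <- tolower(sub("^([A-Za-z]+?)[0-9].*$", "\\1", basename(paths)))
  }
  types <- tolower(types)
  known <- c("demo", "drug", "reac", "ther", "indi", "outc", "rpsr")
  if (!all(types %in% known)) {
    stop_pv("unrecognized table type(s): %s",
            paste(setdiff(types, known), collapse = ", "))
  }
  out <- list()
  log <- list()
  for (i in seq_along(paths)) {
    req <- if (types[i] == "demo") c("primaryid", "caseid") else "primaryid"
    dt <- read_faers_table(paths[i], required = req)
    log[[i]] <- data.table::data.table(
      file = basename(paths[i]), table = types[i], n_rows = nrow(dt),
      n_malformed = attr(dt, "n_malformed"))
    out[[types[i]]] <- if (is.null(out[[types[i]]])) dt else
      rbind(out[[types[i]]], dt, fill = TRUE)
  }
  out$log <- data.table::rbindlist(log)
  out
}

#' Deduplicate FAERS cases
#'
#' A FAERS case (caseid) can appear as several report versions (primaryids).
#' Keeps exactly one row per caseid: the latest receipt date (`fda_dt`),
#' ties broken by the largest primaryid — the FDA-documented convention.
#'
#' @param demo data.table with `primaryid`, `caseid`, `fda_dt` columns.
#' @return The kept subset of `demo` (one row per distinct caseid), with
#'   attribute `n_removed`.
#' @export
deduplicate <- function(demo) {
  if (nrow(demo) == 0L) return(demo)
  d <- data.table::copy(demo)
  d[, `.recv` := parse_faers_date(fda_dt)$date]
  d[, `.pid` := as.numeric(primaryid)]
  data.table::setorderv(d, c("caseid", ".recv", ".pid"), c(1L, -1L, -1L),
                        na.last = TRUE)
  kept <- d[, .SD[1L], by = caseid]
  kept[, c(".recv", ".pid") := NULL]
  data.table::setcolorder(kept, names(demo))
  data.table::setattr(kept, "n_removed", nrow(demo) - nrow(kept))
  kept[]
}

#' Normalize FAERS demographic fields
#'
#' Converts age to years from its FAERS unit code (DEC decades, YR years,
#' MON months, WK weeks, DY days, HR hours) and weight to kilograms (KG,
#' LBS, GMS). Implausible values (age outside \[0,150\] years, weight outside
#' (0,700) kg) and unknown unit codes become missing; unknown codes are
#' logged. Sex is mapped to male/female/NA and countries through a small
#' alias table.
#'
#' @param demo data.table with raw `sex`, `age`, `age_cod`, `wt`, `wt_cod`,
#'   `occr_country` columns.
#' @return A data.table with `primaryid`, `caseid`, `sex`, `age_years`,
#'   `weight_kg`, `country` plus receipt/event dates when present.
#' @export
normalize_demographics <- function(demo) {
  age_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                  DY = 1 / 365.25, HR = 1 / 8766)
  wt_factor <- c(KG = 1, LBS = 0.453592, GMS = 1 / 1000)

  sex_raw <- toupper(trimws(demo$sex %||% rep("", nrow(demo))))
  sex <- ifelse(sex_raw == "M", "male",
                ifelse(sex_raw == "F", "female", NA_character_))

  age_raw <- suppressWarnings(as.numeric(demo$age))
  acod <- toupper(trimws(demo$age_cod %||% rep("YR", nrow(demo))))
  acod[acod == ""] <- "YR"
  unk_age <- !is.na(age_raw) & !(acod %in% names(age_factor))
  if (any(unk_age)) {
    pv_log("unknown AGE_COD value(s): %s (set to missing)",
           paste(unique(acod[unk_age]), collapse = ", "))
  }
  age_years <- age_raw * unname(age_factor[acod])
  age_years[unk_age] <- NA_real_
  age_years[!is.na(age_years) & (age_years < 0 | age_years > 150)] <- NA_real_

  wt_raw <- suppressWarnings(as.numeric(demo$wt))
  wcod <- toupper(trimws(demo$wt_cod %||% rep("KG", nrow(demo))))
  wcod[wcod == ""] <- "KG"
  unk_wt <- !is.na(wt_raw) & !(wcod %in% names(wt_factor))
  if (any(unk_wt)) {
    pv_log("unknown WT_COD value(s): %s (set to missing)",
           paste(unique(wcod[unk_wt]), collapse = ", "))
  }
  weight_kg <- wt_raw * unname(wt_factor[wcod])
  weight_kg[unk_wt] <- NA_real_
  weight_kg[!is.na(weight_kg) & (weight_kg <= 0 | weight_kg >= 700)] <- NA_real_

  country <- normalize_country(demo$occr_country %||%
                                 rep(NA_character_, nrow(demo)))

  out <- data.table::data.table(
    primaryid = demo$primaryid, caseid = demo$caseid,
    sex = sex, age_years = age_years, weight_kg = weight_kg,
    country = country)
  if ("fda_dt" %in% names(demo)) {
    rd <- parse_faers_date(demo$fda_dt)
    out[, `:=`(receipt_date = rd$date)]
  }
  if ("event_dt" %in% names(demo)) {
    ed <- parse_faers_date(demo$event_dt)
    out[, `:=`(event_date = ed$date, event_date_imprecise = ed$imprecise)]
  }
  out[]
}

country_aliases <- function() {
  c("US" = "United States", "USA" = "United States",
    "UNITED STATES" = "United States",
    "JP" = "Japan", "JAPAN" = "Japan",
    "FR" = "France", "FRANCE" = "France",
    "CA" = "Canada", "CANADA" = "Canada",
    "DE" = "Germany", "GERMANY" = "Germany",
    "GB" = "United Kingdom", "UK" = "United Kingdom",
    "UNITED KINGDOM" = "United Kingdom",
    "IT" = "Italy", "ES" = "Spain", "AU" = "Australia", "BR" = "Brazil",
    "CN" = "China")
}

normalize_country <- function(x) {
  x <- trimws(x)
  x[is.na(x) | x == ""] <- NA_character_
  key <- toupper(x)
  hit <- key %in% names(country_aliases())
  x[hit] <- unname(country_aliases()[key[hit]])
  x
}

#' Default drug-name synonym map
#'
#' A small packaged brand-to-generic map covering common renal-signal drugs;
#' users extend it with `c(default_synonym_map(), ...)`. Keys and values are
#' lower case.
#' @return Named character vector (verbatim name -> generic name).
#' @export
default_synonym_map <- function() {
  c("lenvima" = "lenvatinib", "lupkynis" = "voclosporin",
    "viread" = "tenofovir disoproxil", "tecentriq" = "atezolizumab",
    "keytruda" = "pembrolizumab", "afinitor" = "everolimus",
    "sutent" = "sunitinib", "eloxatin" = "oxaliplatin",
    "inlyta" = "axitinib", "camptosar" = "irinotecan",
    "taxol" = "paclitaxel", "rituxan" = "rituximab",
    "mabthera" = "rituximab", "prograf" = "tacrolimus",
    "prevacid" = "lansoprazole", "exjade" = "deferasirox",
    "zometa" = "zoledronic acid", "reclast" = "zoledronic acid",
    "atripla" = "efavirenz/emtricitabine/tenofovir disoproxil",
    "advil" = "ibuprofen", "motrin" = "ibuprofen")
}

salt_suffixes <- function() {
  c("mesylate", "mesilate", "hydrochloride", "hcl", "sodium", "potassium",
    "calcium", "disodium", "sulfate", "sulphate", "acetate", "tartrate",
    "citrate", "maleate", "phosphate", "besylate", "tosylate", "succinate",
    "fumarate", "dihydrate", "monohydrate", "hemihydrate", "anhydrous")
}

#' Normalize a verbatim drug name to a generic name
#'
#' Case-folds, trims, collapses whitespace and strips trailing salt/form
#' suffixes, then resolves through the synonym map (applied both before and
#' after suffix stripping). Unmapped names pass through case-folded.
#'
#' @param x character vector of verbatim drug names.
#' @param synonym_map named character vector; see [default_synonym_map()].
#' @return Character vector of normalized generic names.
#' @export
normalize_drug_name <- function(x, synonym_map = default_synonym_map()) {
  v <- tolower(trimws(x))
  v <- gsub("\\s+", " ", v)
  hit <- v %in% names(synonym_map)
  v[hit] <- unname(synonym_map[v[hit]])
  pat <- sprintf("( (%s))+$", paste(salt_suffixes(), collapse = "|"))
  v <- sub(pat, "", v)
  hit <- v %in% names(synonym_map)
  v[hit] <- unname(synonym_map[v[hit]])
  v
}

#' Build a normalized, deduplicated case store
#'
#' The end-to-end ingest step: normalizes demographics and drug names,
#' deduplicates cases, attaches therapy dates to drug mentions and splits
#' drug mentions into primary-suspect (analysis) and other roles.
#'
#' @param tables list with data.tables `demo`, `drug`, `reac` and optionally
#'   `ther` — either from [parse_quarter()] or a `faers_tables` object.
#' @param synonym_map drug-name synonym map.
#' @param dedup logical; deduplicate cases (default TRUE).
#' @return An object of class `case_store`: list with `cases` (one row per
#'   kept report: demographics, receipt/event dates), `events` (primaryid,
#'   pt), `drugs` (primaryid, drug, role, therapy start/end; all roles) and
#'   `log` counters.
#' @export
build_case_store <- function(tables, synonym_map = default_synonym_map(),
                             dedup = TRUE) {
  demo <- data.table::as.data.table(tables$demo)
  drug <- data.table::as.data.table(tables$drug)
  reac <- data.table::as.data.table(tables$reac)
  ther <- if (!is.null(tables$ther)) data.table::as.data.table(tables$ther)
  n_raw <- nrow(demo)
  if (dedup) demo <- deduplicate(demo)
  cases <- normalize_demographics(demo)
  kept <- cases$primaryid

  if (!"drug_seq" %in% names(drug)) drug[, drug_seq := "1"]
  drugs <- drug[drug$primaryid %in% kept,
                .(primaryid, drug_seq, role = toupper(role_cod),
                  drug = normalize_drug_name(drugname, synonym_map))]
  if (!is.null(ther) && nrow(ther)) {
    sd <- parse_faers_date(ther$start_dt)
    ed <- parse_faers_date(ther$end_dt)
    th <- data.table::data.table(
      primaryid = ther$primaryid, drug_seq = ther$dsg_drug_seq,
      therapy_start = sd$date, therapy_start_imprecise = sd$imprecise,
      therapy_end = ed$date)
    drugs <- merge(drugs, th, by = c("primaryid", "drug_seq"),
                   all.x = TRUE, sort = FALSE)
  } else {
    drugs[, `:=`(therapy_start = as.Date(NA),
                 therapy_start_imprecise = NA, therapy_end = as.Date(NA))]
  }

  events <- unique(reac[reac$primaryid %in% kept, .(primaryid, pt)])

  store <- list(cases = cases, events = events, drugs = drugs,
                log = list(n_raw_reports = n_raw, n_cases = nrow(cases),
                           n_duplicates_removed = n_raw - nrow(cases)))
  class(store) <- "case_store"
  store
}

#' @export
print.case_store <- function(x, ...) {
  cat(sprintf(
    "<case_store> %d cases (%d duplicate report versions removed)\n",
    nrow(x$cases), x$log$n_duplicates_removed))
  cat(sprintf("  %d event mentions over %d preferred terms; %d drug mentions (%d PS)\n",
              nrow(x$events), length(unique(x$events$pt)), nrow(x$drugs),
              sum(x$drugs$role == "PS")))
  invisible(x)
}

#' Primary-suspect drug mentions of a case store
#'
#' The analysis drug list: mentions whose role code is PS. Other roles
#' (SS, I, C) remain available in `store$drugs`; cases with no PS drug still
#' count toward event margins.
#'
#' @param store a `case_store`.
#' @return data.table of PS drug mentions.
#' @export
filter_primary_suspect <- function(store) {
  stopifnot(inherits(store, "case_store"))
  store$drugs[store$drugs$role == "PS", ]
}
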