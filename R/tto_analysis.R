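# Time-to-onset (TTO): days from therapy start of the primary-suspect drug
# to the adverse event, summarized per drug class.

#' Packaged drug-to-class map
#'
#' The 21 proteinuria-signal drugs grouped into seven drug systems
#' (anticancer, immunosuppressant, anti-inflammatory, antiviral, orthopedic,
#' digestive, hematologic).
#' @return Named character vector (generic name -> class).
#' @export
drug_class_map <- function() {
  c("lenvatinib" = "anticancer", "rituximab" = "anticancer",
    "voclosporin" = "anticancer", "everolimus" = "anticancer",
    "sunitinib" = "anticancer", "oxaliplatin" = "anticancer",
    "carboplatin" = "anticancer", "axitinib" = "anticancer",
    "irinotecan" = "anticancer", "paclitaxel" = "anticancer",
    "pembrolizumab" = "immunosuppressant", "atezolizumab" = "immunosuppressant",
    "tacrolimus" = "immunosuppressant", "budesonide" = "immunosuppressant",
    "ibuprofen" = "anti-inflammatory", "prednisone" = "anti-inflammatory",
    "tenofovir disoproxil" = "antiviral",
    "efavirenz/emtricitabine/tenofovir disoproxil" = "antiviral",
    "zoledronic acid" = "orthopedic",
    "lansoprazole" = "digestive",
    "deferasirox" = "hematologic")
}

#' Compute per-case time to onset for target-event reports
#'
#' Onset is `event_date - therapy_start` of the primary-suspect drug, in
#' days. When a drug has several therapy episodes, the earliest start at or
#' before the event is used. Records are dropped (and counted) when either
#' date is missing, when onset is negative, or when onset exceeds
#' `max_days` (default 9125, i.e. 25 years, implausible for a single
#' course). Dates imputed from partial precision are excluded unless
#' `include_imprecise = TRUE`.
#'
#' @param store a `case_store`.
#' @param target_pts target preferred terms.
#' @param class_map named vector drug -> class; drugs outside the map get
#'   class NA but are kept.
#' @param include_imprecise keep onsets computed from imputed partial dates.
#' @param max_days plausibility ceiling in days.
#' @return data.table of class `onset_records`: `primaryid`, `drug`,
#'   `drug_class`, `onset_days`, `imprecise_date`; exclusion counts in
#'   attribute `exclusions`.
#' @export
compute_onset_days <- function(store, target_pts,
                               class_map = drug_class_map(),
                               include_imprecise = FALSE, max_days = 9125) {
  stopifnot(inherits(store, "case_store"))
  tgt <- unique(store$events$primaryid[
    tolower(store$events$pt) %in% tolower(target_pts)])
  ps <- filter_primary_suspect(store)
  ps <- ps[ps$primaryid %in% tgt, ]
  ev <- store$cases[, .(primaryid, event_date, event_date_imprecise)]
  x <- merge(ps, ev, by = "primaryid", sort = FALSE)
  # earliest therapy start per (case, drug); if even that postdates the
  # event the onset is negative and excluded below
  x <- x[!is.na(therapy_start) & !is.na(event_date)]
  x <- x[order(primaryid, drug, therapy_start),
         .SD[1L], by = .(primaryid, drug)]
  x[, onset_days := as.numeric(event_date - therapy_start)]
  x[, imprecise_date := event_date_imprecise | therapy_start_imprecise]

  n0 <- nrow(x)
  excl <- c(nonpositive_window = 0L, implausible = 0L, imprecise = 0L)
  bad <- x$onset_days < 0
  excl["nonpositive_window"] <- sum(bad)
  x <- x[!bad]
  bad <- x$onset_days > max_days
  excl["implausible"] <- sum(bad)
  if (any(bad)) pv_log("TTO: %d onset(s) > %d days excluded", sum(bad),
                       max_days)
  x <- x[!bad]
  if (!include_imprecise) {
    excl["imprecise"] <- sum(x$imprecise_date)
    x <- x[imprecise_date == FALSE]
  }
  out <- x[, .(primaryid, drug,
               drug_class = unname(class_map[drug]), onset_days,
               imprecise_date)]
  data.table::setattr(out, "exclusions", excl)
  class(out) <- c("onset_records", class(out))
  out[]
}

#' Per-class time-to-onset summary
#'
#' Arithmetic mean and first/third quartiles of onset days per drug class.
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7). Classes with no records are omitted.
#'
#' @param records an `onset_records` data.table (or any data.table with
#'   `drug_class` and `onset_days`).
#' @param by group column (default `"drug_class"`; use `"drug"` for
#'   per-drug summaries).
#' @return data.table with `n`, `mean`, `q1`, `q3` per group.
#' @export
class_tto_summary <- function(records, by = "drug_class") {
  r <- data.table::as.data.table(records)
  r <- r[!is.na(r[[by]])]
  out <- r[, .(n = .N, mean = mean(onset_days),
               q1 = unname(quantile(onset_days, 0.25, type = 7)),
               q3 = unname(quantile(onset_days, 0.75, type = 7))),
           by = by]
  data.table::setorderv(out, by)
  out[]
}

#' Cumulative-incidence (ECDF) points per drug class
#'
#' The empirical CDF of onset time per class, evaluated on a common day
#' grid — plot-ready data for cumulative incidence curves.
#'
#' @param records an `onset_records` data.table.
#' @param grid numeric day grid; default 200 points from 0 to the maximum
#'   onset.
#' @param by group column (default `"drug_class"`).
#' @return data.table with `drug_class` (or chosen group), `day`,
#'   `cum_incidence` (monotone nondecreasing, reaching 1 at the class
#'   maximum).
#' @export
cumulative_incidence <- function(records, grid = NULL, by = "drug_class") {
  r <- data.table::as.data.table(records)
  r <- r[!is.na(r[[by]])]
  if (nrow(r) == 0L) stop_pv("no onset records")
  if (is.null(grid)) {
    grid <- seq(0, max(r$onset_days), length.out = 200)
  }
  r[, {
    f <- stats::ecdf(onset_days)
    list(day = grid, cum_incidence = f(grid))
  }, by = by]
}
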