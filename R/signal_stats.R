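# Disproportionality statistics on 2x2 contingency tables.
#
# For a drug D and target event Y over N deduplicated reports:
#       a = #(D & Y)   b = #(D & !Y)
#       c = #(!D & Y)  d = #(!D & !Y)
# ROR  = ad/(bc), Wald CI exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))
# PRR  = [a/(a+b)] / [c/(c+d)], with the Pearson chi-square of the table
# E    = (a+b)(a+c)/N, the expected count under independence; RR = a/E
# IC   = log2(a/E); IC025 by the Noren closed-form approximation or an exact
#        gamma posterior quantile
# EBGM = empirical-Bayes geometric mean of the reporting-rate ratio under
#        the two-component gamma (DuMouchel) prior; EBGM05 its 5th posterior
#        percentile.

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d nonnegative counts: `a` drug-and-event, `b` drug-only,
#'   `c` event-only, `d` neither.
#' @return Object of class `contingency_table` (named list, N = a+b+c+d).
#' @export
contingency_table <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop_pv("contingency cells must be nonnegative")
  n <- a + b + c + d
  if (n <= 0) stop_pv("contingency table is empty")
  structure(list(a = a, b = b, c = c, d = d, n = n),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "other drugs"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

#' Build the 2x2 table for one drug and a target PT set
#'
#' `a` counts deduplicated cases where the drug is a primary suspect and any
#' target PT is present. A case with several PS drugs contributes to each
#' drug's table once; cases without any PS drug still populate the event
#' margin (`c`/`d`).
#'
#' @param store a `case_store`.
#' @param drug normalized generic drug name.
#' @param target_pts character vector of target preferred terms (matched
#'   case-insensitively).
#' @return A `contingency_table`; if the drug is absent, `a = b = 0` with
#'   attribute `absent = TRUE`.
#' @export
build_contingency <- function(store, drug, target_pts) {
  stopifnot(inherits(store, "case_store"))
  n <- nrow(store$cases)
  tgt <- unique(store$events$primaryid[
    tolower(store$events$pt) %in% tolower(target_pts)])
  ps <- filter_primary_suspect(store)
  dpid <- unique(ps$primaryid[ps$drug == drug])
  a <- length(intersect(dpid, tgt))
  b <- length(dpid) - a
  c_ <- length(tgt) - a
  d <- n - a - b - c_
  tab <- contingency_table(a, b, c_, d)
  if (length(dpid) == 0L) attr(tab, "absent") <- TRUE
  tab
}

#' Per-drug (or per drug-PT pair) 2x2 counts for a whole case store
#'
#' @param store a `case_store`.
#' @param target_pts target PT set; ignored when `by_pt = TRUE`.
#' @param drugs optional restriction of the drug list (default: every PS
#'   drug observed).
#' @param by_pt if TRUE, build one row per (PS drug, individual PT) pair —
#'   the whole-database layout used to fit the MGPS hyperprior.
#' @return data.table with columns `drug` (and `pt` when `by_pt`), `a`, `b`,
#'   `c`, `d`, `n`, `expected`.
#' @export
build_contingency_all <- function(store, target_pts = NULL, drugs = NULL,
                                  by_pt = FALSE) {
  stopifnot(inherits(store, "case_store"))
  n <- nrow(store$cases)
  ps <- unique(filter_primary_suspect(store)[, .(primaryid, drug)])
  if (is.null(drugs)) drugs <- sort(unique(ps$drug))
  ps <- ps[ps$drug %in% drugs, ]
  drug_margin <- ps[, .(n_drug = .N), by = drug]

  if (by_pt) {
    ev <- unique(store$events[, .(primaryid, pt)])
    pt_margin <- ev[, .(n_event = .N), by = pt]
    hits <- merge(ps, ev, by = "primaryid", allow.cartesian = TRUE)[
      , .(a = .N), by = .(drug, pt)]
    grid <- data.table::CJ(drug = drugs, pt = pt_margin$pt, unique = TRUE)
    out <- merge(grid, hits, by = c("drug", "pt"), all.x = TRUE)
    out <- merge(out, drug_margin, by = "drug", all.x = TRUE)
    out <- merge(out, pt_margin, by = "pt", all.x = TRUE)
    out[is.na(a), a := 0L]
    out[is.na(n_drug), n_drug := 0L]
    out[, `:=`(b = n_drug - a, c = n_event - a)]
    out[, d := n - a - b - c]
    out[, `:=`(n = n, expected = n_drug * n_event / n)]
    out[, c("n_drug", "n_event") := NULL]
    data.table::setcolorder(out, c("drug", "pt", "a", "b", "c", "d", "n",
                                   "expected"))
    return(out[])
  }

  tgt <- unique(store$events$primaryid[
    tolower(store$events$pt) %in% tolower(target_pts)])
  n_event <- length(tgt)
  hits <- ps[ps$primaryid %in% tgt, .(a = .N), by = drug]
  out <- merge(data.table::data.table(drug = drugs), hits, by = "drug",
               all.x = TRUE)
  out <- merge(out, drug_margin, by = "drug", all.x = TRUE)
  out[is.na(a), a := 0L]
  out[is.na(n_drug), n_drug := 0L]
  out[, `:=`(b = n_drug - a, c = n_event - a)]
  out[, d := n - a - b - c]
  out[, `:=`(n = n, expected = n_drug * n_event / n)]
  out[, n_drug := NULL]
  out[]
}

tab_cells <- function(table) {
  if (inherits(table, "contingency_table")) {
    x <- unlist(table[c("a", "b", "c", "d")])
  } else if (is.numeric(table) && length(table) == 4L) {
    x <- setNames(table, c("a", "b", "c", "d"))
  } else {
    stop_pv("expected a contingency_table or a length-4 numeric (a,b,c,d)")
  }
  # double precision: integer cells overflow in n*(ad-bc)^2
  storage.mode(x) <- "double"
  x
}

#' Reporting odds ratio with Wald 95% CI
#'
#' ROR = ad/(bc); CI = exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#' With a zero cell the ROR is undefined; `correction = "haldane"` adds 0.5
#' to every cell (flagged in the result), otherwise NA is returned.
#'
#' @param table a `contingency_table` or numeric (a,b,c,d).
#' @param correction zero-cell handling: "none" (default) or "haldane".
#' @param conf_level confidence level (default 0.95).
#' @return list(ror, lo, hi, corrected).
#' @export
ror_with_ci <- function(table, correction = c("none", "haldane"),
                        conf_level = 0.95) {
  correction <- match.arg(correction)
  x <- tab_cells(table)
  corrected <- FALSE
  if (any(x == 0)) {
    if (correction == "haldane") {
      x <- x + 0.5
      corrected <- TRUE
    } else {
      return(list(ror = NA_real_, lo = NA_real_, hi = NA_real_,
                  corrected = FALSE))
    }
  }
  # the conventional 1.96 multiplier at the default level
  z <- if (conf_level == 0.95) 1.96 else qnorm(1 - (1 - conf_level) / 2)
  ror <- x["a"] * x["d"] / (x["b"] * x["c"])
  se <- sqrt(sum(1 / x))
  list(ror = unname(ror), lo = unname(exp(log(ror) - z * se)),
       hi = unname(exp(log(ror) + z * se)), corrected = corrected)
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' PRR = \[a/(a+b)\] / \[c/(c+d)\]; chi-square is Pearson's statistic of the
#' 2x2 table, N(ad-bc)^2 / \[(a+b)(c+d)(a+c)(b+d)\], without continuity
#' correction by default (`yates = TRUE` applies the Yates correction).
#'
#' @param table a `contingency_table` or numeric (a,b,c,d).
#' @param yates apply Yates continuity correction to the chi-square.
#' @return list(prr, chi2); both NA when the drug margin a+b is zero.
#' @export
prr_chi2 <- function(table, yates = FALSE) {
  x <- tab_cells(table)
  a <- x["a"]; b <- x["b"]; c <- x["c"]; d <- x["d"]
  n <- a + b + c + d
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    return(list(prr = NA_real_, chi2 = NA_real_))
  }
  prr <- (a / (a + b)) / (c / (c + d))
  dev <- abs(a * d - b * c)
  if (yates) dev <- max(dev - n / 2, 0)
  chi2 <- n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(prr = unname(prr), chi2 = unname(chi2))
}

#' Expected count under independence and the observed/expected ratio
#'
#' E = (a+b)(a+c)/N is the count expected if drug and event margins were
#' independent; RR = a/E is the relative reporting rate that both the
#' information component and the MGPS shrink toward.
#'
#' @param table a `contingency_table` or numeric (a,b,c,d).
#' @return list(expected, rr).
#' @export
expected_count <- function(table) {
  x <- tab_cells(table)
  n <- sum(x)
  e <- (x["a"] + x["b"]) * (x["a"] + x["c"]) / n
  list(expected = unname(e), rr = unname(if (e > 0) x["a"] / e else NA_real_))
}

#' BCPNN information component
#'
#' IC = log2(a/E) (the maximum-likelihood information component). The lower
#' 95% credibility bound IC025 is computed by the Noren closed-form
#' approximation IC - 3.3 a^(-1/2) - 2 a^(-3/2) (default), or as the exact
#' 2.5% quantile of the gamma posterior of the rate ratio with a +0.5
#' shrinkage count on observed and expected (`ic025 = "exact"`).
#'
#' @param table a `contingency_table` or numeric (a,b,c,d).
#' @param ic025 "noren" (default) or "exact".
#' @return list(ic, ic025); NA with `a = 0`.
#' @export
bcpnn_ic <- function(table, ic025 = c("noren", "exact")) {
  ic025 <- match.arg(ic025)
  x <- tab_cells(table)
  a <- x["a"]
  e <- expected_count(x)$expected
  if (a == 0 || e <= 0) return(list(ic = NA_real_, ic025 = NA_real_))
  ic <- log2(a / e)
  lo <- if (ic025 == "noren") {
    ic - 3.3 * a^(-0.5) - 2 * a^(-1.5)
  } else {
    log2(qgamma(0.025, shape = a + 0.5, rate = e + 0.5))
  }
  list(ic = unname(ic), ic025 = unname(lo))
}

## ---- MGPS: two-component gamma (DuMouchel) empirical-Bayes shrinkage ----

#' Construct a gamma-mixture prior
#'
#' The MGPS prior on the reporting-rate ratio lambda:
#' `w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2)` (shape/rate).
#'
#' @param alpha1,beta1,alpha2,beta2 positive shape/rate parameters.
#' @param w mixture weight in (0,1).
#' @param loglik optional log-likelihood at the fitted optimum.
#' @return Object of class `gamma_mixture_prior`.
#' @export
gamma_mixture_prior <- function(alpha1, beta1, alpha2, beta2, w,
                                loglik = NA_real_) {
  if (any(c(alpha1, beta1, alpha2, beta2) <= 0) || w <= 0 || w >= 1) {
    stop_pv("invalid gamma mixture prior")
  }
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w, loglik = loglik),
            class = "gamma_mixture_prior")
}

#' @export
print.gamma_mixture_prior <- function(x, ...) {
  cat(sprintf(paste0(
    "<gamma_mixture_prior> w=%.3f  Gamma(%.3g, %.3g) [mean %.3g]  ",
    "Gamma(%.3g, %.3g) [mean %.3g]  loglik=%.2f\n"),
    x$w, x$alpha1, x$beta1, x$alpha1 / x$beta1,
    x$alpha2, x$beta2, x$alpha2 / x$beta2, x$loglik))
  invisible(x)
}

# Marginal log-likelihood of counts a given expecteds E under the mixture
# prior: each component marginal is negative binomial with size alpha and
# success probability beta/(beta+E).
nbmix_loglik <- function(par, a, e) {
  par <- pmin(pmax(par, -25), 25)  # keep exp()/plogis() finite
  alpha1 <- exp(par[1]); beta1 <- exp(par[2])
  alpha2 <- exp(par[3]); beta2 <- exp(par[4])
  w <- stats::plogis(par[5])
  l1 <- suppressWarnings(
    dnbinom(a, size = alpha1, prob = beta1 / (beta1 + e), log = TRUE))
  l2 <- suppressWarnings(
    dnbinom(a, size = alpha2, prob = beta2 / (beta2 + e), log = TRUE))
  if (anyNA(l1) || anyNA(l2)) return(-1e300)
  m <- pmax(l1, l2)
  ll <- sum(m + log(w * exp(l1 - m) + (1 - w) * exp(l2 - m)))
  if (!is.finite(ll)) return(-1e300)
  ll
}

mgps_default_starts <- function() {
  # DuMouchel's classic init first; the others probe distinct basins.
  list(c(0.2, 0.1, 2, 4, 1 / 3),
       c(1, 1, 2, 2, 0.2),
       c(0.5, 0.25, 1, 1, 0.5),
       c(2, 4, 0.2, 0.2, 0.5),
       c(1, 0.5, 4, 2, 0.8))
}

#' Fit the MGPS gamma-mixture hyperprior by marginal maximum likelihood
#'
#' Maximizes the negative-binomial mixture marginal likelihood of the
#' observed counts given their expecteds over the five hyperparameters,
#' using BFGS on log(shape/rate) and logit(weight) from multiple fixed
#' starting points (deterministic).
#'
#' @param a integer vector of observed counts over all drug-event pairs.
#' @param expected numeric vector of expected counts (all > 0).
#' @param starts list of starting values `(alpha1, beta1, alpha2, beta2, w)`;
#'   defaults to five fixed starts including DuMouchel's classic init
#'   (0.2, 0.1, 2, 4, 1/3).
#' @param reltol relative convergence tolerance passed to [stats::optim()].
#' @return A `gamma_mixture_prior` with the achieved log-likelihood.
#' @export
fit_mgps_hyperprior <- function(a, expected, starts = mgps_default_starts(),
                                reltol = 1e-8) {
  if (length(a) != length(expected)) stop_pv("a and expected differ in length")
  keep <- expected > 0 & !is.na(a)
  a <- a[keep]; e <- expected[keep]
  if (length(a) < 2L) stop_pv("need at least two pairs to fit the prior")
  best <- NULL
  diagnostics <- list()
  for (s in starts) {
    par0 <- c(log(s[1:4]), stats::qlogis(s[5]))
    # Nelder-Mead explores the multimodal surface without degenerating onto
    # the equal-components ridge; BFGS then polishes the optimum.
    fit <- tryCatch({
      nm <- optim(par0, nbmix_loglik, a = a, e = e, method = "Nelder-Mead",
                  control = list(fnscale = -1, maxit = 2000, reltol = reltol))
      optim(nm$par, nbmix_loglik, a = a, e = e, method = "BFGS",
            control = list(fnscale = -1, maxit = 500, reltol = reltol))
    }, error = function(err) NULL)
    if (is.null(fit)) next
    diagnostics[[length(diagnostics) + 1L]] <-
      list(start = s, value = fit$value, convergence = fit$convergence)
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  if (is.null(best)) {
    stop_pv("MGPS hyperprior fit failed from every start")
  }
  p <- pmin(pmax(best$par, -25), 25)
  alpha <- exp(p[c(1, 3)]); beta <- exp(p[c(2, 4)])
  w <- stats::plogis(p[5])
  # canonical order: higher-mean component first
  if (alpha[1] / beta[1] < alpha[2] / beta[2]) {
    alpha <- rev(alpha); beta <- rev(beta); w <- 1 - w
  }
  prior <- gamma_mixture_prior(alpha[1], beta[1], alpha[2], beta[2], w,
                               loglik = best$value)
  attr(prior, "diagnostics") <- diagnostics
  prior
}

# Posterior of lambda given (a, E): mixture of Gamma(alpha_k + a, beta_k + E)
# with weights updated by the marginal negative-binomial likelihoods.
posterior_mix <- function(a, e, prior) {
  l1 <- dnbinom(a, size = prior$alpha1,
                prob = prior$beta1 / (prior$beta1 + e), log = TRUE)
  l2 <- dnbinom(a, size = prior$alpha2,
                prob = prior$beta2 / (prior$beta2 + e), log = TRUE)
  lw1 <- log(prior$w) + l1
  lw2 <- log(1 - prior$w) + l2
  m <- pmax(lw1, lw2)
  q <- exp(lw1 - m) / (exp(lw1 - m) + exp(lw2 - m))
  list(q = q,
       shape1 = prior$alpha1 + a, rate1 = prior$beta1 + e,
       shape2 = prior$alpha2 + a, rate2 = prior$beta2 + e)
}

#' EBGM and EBGM05 empirical-Bayes scores
#'
#' EBGM is the geometric mean of the posterior of the reporting-rate ratio,
#' `exp(E[ln lambda | a])`, using `E[ln Gamma(alpha, beta)] = psi(alpha) -
#' ln beta` per mixture component. EBGM05 is the 5th posterior percentile,
#' found by root-finding on the posterior mixture CDF.
#'
#' @param a,expected observed and expected counts (vectorized).
#' @param prior a `gamma_mixture_prior`.
#' @param prob percentile for the lower bound (default 0.05).
#' @return data.table with columns `a`, `expected`, `ebgm`, `ebgm05`.
#' @export
ebgm_scores <- function(a, expected, prior, prob = 0.05) {
  stopifnot(inherits(prior, "gamma_mixture_prior"))
  pm <- posterior_mix(a, expected, prior)
  eln <- pm$q * (digamma(pm$shape1) - log(pm$rate1)) +
    (1 - pm$q) * (digamma(pm$shape2) - log(pm$rate2))
  ebgm <- exp(eln)
  ebgm05 <- vapply(seq_along(a), function(i) {
    mix_cdf <- function(x) {
      pm$q[i] * pgamma(x, pm$shape1[i], rate = pm$rate1[i]) +
        (1 - pm$q[i]) * pgamma(x, pm$shape2[i], rate = pm$rate2[i]) - prob
    }
    q1 <- qgamma(prob, pm$shape1[i], rate = pm$rate1[i])
    q2 <- qgamma(prob, pm$shape2[i], rate = pm$rate2[i])
    lo <- min(q1, q2); hi <- max(q1, q2)
    if (hi - lo < 4 * .Machine$double.eps * hi) return(lo)
    # expand the bracket if floating error leaves both ends on one side
    k <- 0L
    while (mix_cdf(lo) > 0 && k < 60L) { lo <- lo * 0.5; k <- k + 1L }
    k <- 0L
    while (mix_cdf(hi) < 0 && k < 60L) { hi <- hi * 2; k <- k + 1L }
    uniroot(mix_cdf, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
  data.table::data.table(a = a, expected = expected, ebgm = ebgm,
                         ebgm05 = ebgm05)
}

#' Default per-method signal criteria
#'
#' Classical literature thresholds: ROR (a >= 3 and CI lower bound > 1),
#' PRR (PRR >= 2, chi-square >= 4, a >= 3), BCPNN (IC025 > 0), MGPS
#' (EBGM05 > 2). All configurable.
#' @param ror_min_a,ror_lo,prr_min,chi2_min,prr_min_a,ic025_min,ebgm05_min
#'   thresholds.
#' @return list of thresholds used by [evaluate_signal()].
#' @export
signal_criteria <- function(ror_min_a = 3, ror_lo = 1, prr_min = 2,
                            chi2_min = 4, prr_min_a = 3, ic025_min = 0,
                            ebgm05_min = 2) {
  list(ror_min_a = ror_min_a, ror_lo = ror_lo, prr_min = prr_min,
       chi2_min = chi2_min, prr_min_a = prr_min_a, ic025_min = ic025_min,
       ebgm05_min = ebgm05_min)
}

#' Per-method and consensus signal flags
#'
#' A pair is a consensus signal only when all four methods flag it. A
#' missing component statistic makes that method's flag FALSE and is
#' recorded as not evaluable.
#'
#' @param stats data.table (or list) with columns `a`, `ror_lo`, `prr`,
#'   `chi2`, `ic025`, `ebgm05`.
#' @param criteria list from [signal_criteria()].
#' @return data.table of logicals `flag_ror`, `flag_prr`, `flag_bcpnn`,
#'   `flag_mgps`, `consensus`, `evaluable`.
#' @export
evaluate_signal <- function(stats, criteria = signal_criteria()) {
  s <- data.table::as.data.table(stats)
  na_false <- function(x) !is.na(x) & x
  flag_ror <- na_false(s$a >= criteria$ror_min_a & s$ror_lo > criteria$ror_lo)
  flag_prr <- na_false(s$prr >= criteria$prr_min & s$chi2 >= criteria$chi2_min &
                         s$a >= criteria$prr_min_a)
  flag_bcpnn <- na_false(s$ic025 > criteria$ic025_min)
  flag_mgps <- na_false(s$ebgm05 > criteria$ebgm05_min)
  evaluable <- !(is.na(s$ror_lo) | is.na(s$prr) | is.na(s$chi2) |
                   is.na(s$ic025) | is.na(s$ebgm05))
  data.table::data.table(flag_ror = flag_ror, flag_prr = flag_prr,
                         flag_bcpnn = flag_bcpnn, flag_mgps = flag_mgps,
                         consensus = flag_ror & flag_prr & flag_bcpnn &
                           flag_mgps,
                         evaluable = evaluable)
}

#' Full signal table for a case store
#'
#' Builds per-drug 2x2 tables for the target PT set, fits the MGPS
#' hyperprior on the whole drug-by-PT database (unless a prior is supplied),
#' computes all four disproportionality statistics and flags signals.
#'
#' @param store a `case_store`.
#' @param target_pts target preferred terms.
#' @param drugs optional drug restriction.
#' @param prior optional pre-fitted `gamma_mixture_prior`.
#' @param criteria signal criteria, see [signal_criteria()].
#' @param ic025 IC025 mode, "noren" or "exact".
#' @param min_a drop drugs with fewer than `min_a` drug-and-event reports
#'   from the output (default 1 keeps any reported pair).
#' @return list(stats = per-drug data.table shaped like a signal summary
#'   table, prior = the fitted `gamma_mixture_prior`).
#' @export
signal_table <- function(store, target_pts, drugs = NULL, prior = NULL,
                         criteria = signal_criteria(), ic025 = "noren",
                         min_a = 1) {
  counts <- build_contingency_all(store, target_pts = target_pts,
                                  drugs = drugs)
  if (is.null(prior)) {
    pairs <- build_contingency_all(store, by_pt = TRUE)
    prior <- fit_mgps_hyperprior(pairs$a, pairs$expected)
  }
  counts <- counts[a >= min_a]
  stats <- compute_signal_stats(counts, prior, ic025 = ic025)
  flags <- evaluate_signal(stats, criteria)
  list(stats = cbind(stats, flags), prior = prior)
}

# Vectorized statistics over a counts data.table (columns a,b,c,d plus any
# identifier columns, which pass through). Matches the scalar operations
# ror_with_ci / prr_chi2 / expected_count / bcpnn_ic cell for cell.
compute_signal_stats <- function(counts, prior, ic025 = "noren") {
  a <- as.numeric(counts$a); b <- as.numeric(counts$b)
  cc <- as.numeric(counts$c); d <- as.numeric(counts$d)
  n <- a + b + cc + d
  zero <- a == 0 | b == 0 | cc == 0 | d == 0
  ror <- ifelse(zero, NA_real_, a * d / (b * cc))
  se <- ifelse(zero, NA_real_, sqrt(1 / a + 1 / b + 1 / cc + 1 / d))
  margin0 <- (a + b) == 0 | (cc + d) == 0 | (a + cc) == 0 | (b + d) == 0
  prr <- ifelse(margin0, NA_real_, (a / (a + b)) / (cc / (cc + d)))
  chi2 <- ifelse(margin0, NA_real_,
                 n * (a * d - b * cc)^2 /
                   ((a + b) * (cc + d) * (a + cc) * (b + d)))
  e <- (a + b) * (a + cc) / n
  rr <- ifelse(e > 0, a / e, NA_real_)
  ic <- ifelse(a > 0 & e > 0, log2(a / e), NA_real_)
  ic_lo <- if (ic025 == "noren") {
    ic - 3.3 * a^(-0.5) - 2 * a^(-1.5)
  } else {
    ifelse(is.na(ic), NA_real_,
           log2(qgamma(0.025, shape = a + 0.5, rate = e + 0.5)))
  }
  eb <- ebgm_scores(a, pmax(e, .Machine$double.xmin), prior)
  id_cols <- intersect(c("drug", "pt"), names(counts))
  out <- cbind(
    data.table::as.data.table(counts)[, id_cols, with = FALSE],
    data.table::data.table(
      a = counts$a, ror = ror, ror_lo = exp(log(ror) - 1.96 * se),
      ror_hi = exp(log(ror) + 1.96 * se), prr = prr, chi2 = chi2,
      expected = e, rr = rr, ic = ic, ic025 = ic_lo,
      ebgm = eb$ebgm, ebgm05 = eb$ebgm05))
  out[]
}

#' Per-pair signal statistics over the whole drug-by-PT database
#'
#' Computes the four disproportionality statistics and signal flags for
#' every (primary-suspect drug, preferred term) pair in the store — the
#' layout used for database-wide calibration checks.
#'
#' @inheritParams signal_table
#' @return list(stats = per-pair data.table with flags, prior).
#' @export
signal_table_pairs <- function(store, prior = NULL,
                               criteria = signal_criteria(),
                               ic025 = "noren") {
  pairs <- build_contingency_all(store, by_pt = TRUE)
  if (is.null(prior)) prior <- fit_mgps_hyperprior(pairs$a, pairs$expected)
  stats <- compute_signal_stats(pairs, prior, ic025 = ic025)
  flags <- evaluate_signal(stats, criteria)
  list(stats = cbind(stats, flags), prior = prior)
}

#' Reconstruct a 2x2 table from printed summary statistics
#'
#' Given the drug-and-event count `a`, the total number of target-event
#' reports (`a + c`), and the printed ROR and PRR, the remaining cells are
#' identified by the two identities: `b = a (PRR - 1) / (ROR - PRR)` and
#' `d = ROR b c / a`. Used to validate published signal tables without the
#' underlying database.
#'
#' @param a drug-and-event count.
#' @param event_total total target-event reports (a + c).
#' @param ror,prr printed reporting odds ratio and proportional reporting
#'   ratio.
#' @return A `contingency_table` with real-valued `b`, `d`; integer-rounded
#'   cells are in attribute `rounded`.
#' @export
reconstruct_table <- function(a, event_total, ror, prr) {
  if (a >= event_total) stop_pv("a must be below the event total")
  if (abs(ror - prr) < 1e-12) {
    stop_pv("non-reconstructible inputs: ROR equals PRR")
  }
  c_ <- event_total - a
  b <- a * (prr - 1) / (ror - prr)
  d <- ror * b * c_ / a
  if (b <= 0 || d <= 0) stop_pv("non-reconstructible inputs: negative cells")
  rel <- function(x, y) abs(x - y) / max(abs(y), 1)
  r_chk <- a * d / (b * c_)
  p_chk <- (a / (a + b)) / (c_ / (c_ + d))
  if (rel(r_chk, ror) > 1e-9 || rel(p_chk, prr) > 1e-9) {
    stop_pv("reconstruction failed to satisfy the ROR/PRR identities")
  }
  tab <- contingency_table(a, b, c_, d)
  attr(tab, "rounded") <- c(a = a, b = round(b), c = c_, d = round(d))
  tab
}
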