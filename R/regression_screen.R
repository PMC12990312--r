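# Drug-screening cascade: complete-case design matrix, univariate logistic
# screen, LASSO selection with cross-validation, covariate-adjusted
# multivariate logistic regression, and rank-based ROC/AUC.

age_class_levels <- function() c("<18", "18-40", "41-60", "61-80", ">80")

cut_age_class <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 18, 40, 60, 80, Inf),
      labels = age_class_levels(), right = FALSE)
}

#' Build the complete-case design matrix for the regression cascade
#'
#' Outcome is presence of any target PT on the report. Covariates follow the
#' screening model: sex (female = reference), age in five classes (<18 =
#' reference; 18-40, 41-60, 61-80, >80) and body weight dichotomized as
#' 50-100 kg (reference) vs outside that range. Reports missing any of sex,
#' age or weight are excluded (complete-case analysis). Drug indicator
#' columns are ordered alphabetically.
#'
#' @param store a `case_store`.
#' @param target_pts target preferred terms.
#' @param drugs drugs to include as indicators (default: all PS drugs).
#' @return list of class `design_matrix`: `data` (data.table with `outcome`,
#'   one indicator per drug, `sex_male`, `age_class`, `weight_out_of_range`),
#'   `drugs` (indicator column names, backtick-free), `n_excluded`.
#' @export
build_design_matrix <- function(store, target_pts, drugs = NULL) {
  stopifnot(inherits(store, "case_store"))
  cases <- store$cases
  keep <- !is.na(cases$sex) & !is.na(cases$age_years) &
    !is.na(cases$weight_kg)
  n_excluded <- sum(!keep)
  cc <- cases[keep, ]
  if (nrow(cc) == 0L) stop_pv("no complete cases for the design matrix")

  tgt <- unique(store$events$primaryid[
    tolower(store$events$pt) %in% tolower(target_pts)])
  ps <- filter_primary_suspect(store)
  if (is.null(drugs)) drugs <- sort(unique(ps$drug))
  drugs <- sort(drugs)

  dm <- data.table::data.table(
    primaryid = cc$primaryid,
    outcome = as.integer(cc$primaryid %in% tgt),
    sex_male = as.integer(cc$sex == "male"),
    age_class = factor(as.character(cut_age_class(cc$age_years)),
                       levels = age_class_levels()),
    weight_out_of_range = as.integer(cc$weight_kg < 50 | cc$weight_kg > 100))
  for (d in drugs) {
    pid <- unique(ps$primaryid[ps$drug == d])
    dm[, (drug_col(d)) := as.integer(primaryid %in% pid)]
  }
  data.table::setcolorder(dm, c("primaryid", "outcome", drug_col(drugs),
                                "sex_male", "age_class",
                                "weight_out_of_range"))
  structure(list(data = dm, drugs = drugs, n_excluded = n_excluded),
            class = "design_matrix")
}

drug_col <- function(drug) paste0("drug_", gsub("[^a-z0-9]+", "_", drug))

#' Univariate logistic screen of candidate drugs
#'
#' Fits the single-binary-predictor logistic model per drug on the
#' complete-case design matrix. For a binary predictor this model is
#' saturated, so its MLE and Wald statistics are the closed-form 2x2
#' quantities: OR = ad/(bc), SE = sqrt(1/a+1/b+1/c+1/d). A drug is retained
#' when (i) the OR 95% CI lower bound exceeds `or_lo_min`, (ii) its
#' drug-and-event count exceeds `min_a`, and (iii) its Benjamini-Hochberg
#' adjusted p-value is below `p_cut`; the BH family is the set of drugs
#' passing the count gate. Each clause is configurable. Drugs with a zero
#' cell (separation) are flagged non-evaluable and excluded.
#'
#' @param design a `design_matrix`.
#' @param min_a minimum drug-and-event count (default 100).
#' @param p_cut adjusted-p threshold (default 0.01).
#' @param or_lo_min lower-CI threshold (default 1; set to 0 with
#'   `require_or = FALSE`-like behavior).
#' @return data.table per drug: `a`, `or`, `lo`, `hi`, `p`, `p_adj`,
#'   `evaluable`, `retained`.
#' @export
univariate_screen <- function(design, min_a = 100, p_cut = 0.01,
                              or_lo_min = 1) {
  stopifnot(inherits(design, "design_matrix"))
  dm <- design$data
  y <- dm$outcome
  res <- data.table::rbindlist(lapply(design$drugs, function(d) {
    x <- dm[[drug_col(d)]]
    a <- sum(x == 1L & y == 1L); b <- sum(x == 1L & y == 0L)
    c_ <- sum(x == 0L & y == 1L); d_ <- sum(x == 0L & y == 0L)
    if (any(c(a, b, c_, d_) == 0)) {
      return(data.table::data.table(drug = d, a = a, or = NA_real_,
                                    lo = NA_real_, hi = NA_real_,
                                    p = NA_real_, evaluable = FALSE))
    }
    or <- a * d_ / (b * c_)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d_)
    z <- log(or) / se
    data.table::data.table(drug = d, a = a, or = or,
                           lo = exp(log(or) - 1.96 * se),
                           hi = exp(log(or) + 1.96 * se),
                           p = 2 * pnorm(-abs(z)), evaluable = TRUE)
  }))
  if (any(!res$evaluable)) {
    pv_log("univariate screen: %d drug(s) not evaluable (zero cell)",
           sum(!res$evaluable))
  }
  res[, p_adj := NA_real_]
  fam <- res$evaluable & res$a > min_a
  res[fam, p_adj := p.adjust(p, method = "BH")]
  res[, retained := fam & lo > or_lo_min & !is.na(p_adj) & p_adj < p_cut]
  res[]
}

design_model_matrix <- function(design, drugs) {
  dm <- design$data
  x_cov <- stats::model.matrix(~ sex_male + age_class + weight_out_of_range,
                               data = dm)[, -1, drop = FALSE]
  x_drug <- as.matrix(dm[, drug_col(drugs), with = FALSE])
  cbind(x_drug, x_cov)
}

#' LASSO selection of screened drugs
#'
#' L1-penalized logistic regression of the outcome on the retained drug
#' indicators plus the unpenalized demographic covariates, with k-fold
#' cross-validation on binomial deviance. Covariates carry penalty factor 0
#' (adjustment, never selection). Drugs with a nonzero coefficient at the
#' selected lambda are returned.
#'
#' @param design a `design_matrix`.
#' @param drugs character vector of candidate (screened) drugs.
#' @param nfolds folds for cross-validation (default 10).
#' @param rule `"lambda.1se"` (default) or `"lambda.min"`.
#' @param seed integer seed for the fold assignment.
#' @param penalize_covariates penalize covariates too (default FALSE).
#' @return list(selected, lambda, rule, path) where `path` is a data.table
#'   of the cross-validation curve (lambda, mean deviance, nonzero count).
#' @export
lasso_select <- function(design, drugs, nfolds = 10,
                         rule = c("lambda.1se", "lambda.min"), seed = 1L,
                         penalize_covariates = FALSE) {
  rule <- match.arg(rule)
  stopifnot(inherits(design, "design_matrix"))
  if (length(drugs) < 2L) {
    stop_pv("LASSO selection needs at least two candidate drugs")
  }
  x <- design_model_matrix(design, drugs)
  y <- design$data$outcome
  n_drug <- length(drugs)
  pf <- c(rep(1, n_drug),
          rep(if (penalize_covariates) 1 else 0, ncol(x) - n_drug))
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), length(y))))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial",
                          type.measure = "deviance", foldid = foldid,
                          penalty.factor = pf)
  lam <- cv[[rule]]
  beta <- as.matrix(coef(cv, s = lam))[, 1]
  sel_cols <- names(beta)[beta != 0 & names(beta) %in% drug_col(drugs)]
  selected <- drugs[drug_col(drugs) %in% sel_cols]
  if (length(selected) == 0L) {
    warning("LASSO selected no drugs at ", rule, call. = FALSE)
  }
  beta_drugs <- as.matrix(cv$glmnet.fit$beta[drug_col(drugs), ,
                                             drop = FALSE])
  nz_drugs <- colSums(beta_drugs != 0)[match(cv$lambda,
                                             cv$glmnet.fit$lambda)]
  path <- data.table::data.table(lambda = cv$lambda, cvm = cv$cvm,
                                 cvsd = cv$cvsd, nonzero = cv$nzero,
                                 nonzero_drugs = unname(nz_drugs))
  list(selected = selected, lambda = lam, rule = rule, path = path)
}

#' Covariate-adjusted multivariate logistic fit
#'
#' Maximum-likelihood logistic regression of the outcome on the selected
#' drug indicators plus sex, age class and weight category, with Wald odds
#' ratios, 95% CIs and p-values per term. Drug-term p-values additionally
#' get a Benjamini-Hochberg adjustment. Non-convergence or separation
#' (runaway coefficients) is an error naming the offending terms.
#'
#' @param design a `design_matrix`.
#' @param drugs selected drugs entering the model.
#' @param p_cut significance label threshold for drug terms (default 0.01).
#' @return list of class `regression_result`: `terms` (data.table with
#'   `term`, `is_drug`, `estimate`, `or`, `lo`, `hi`, `p`, `p_adj`,
#'   `significant`), `loglik`, `n`, `fitted` (probabilities), `outcome`.
#' @export
multivariate_fit <- function(design, drugs, p_cut = 0.01) {
  stopifnot(inherits(design, "design_matrix"))
  dm <- design$data
  rhs <- c(drug_col(drugs), "sex_male", "age_class", "weight_out_of_range")
  # drop constant columns (e.g. a single age class in a toy store)
  keep <- vapply(rhs, function(cn) {
    v <- dm[[cn]]
    length(unique(v[!is.na(v)])) > 1L
  }, logical(1))
  rhs <- rhs[keep]
  fml <- stats::as.formula(paste("outcome ~",
                                 paste(sprintf("`%s`", rhs), collapse = " + ")))
  fit <- glm(fml, data = dm, family = binomial())
  est <- coef(fit)
  if (!fit$converged || any(abs(est[-1]) > 20, na.rm = TRUE)) {
    bad <- names(est)[-1][abs(est[-1]) > 20]
    stop_pv("multivariate fit unstable (non-convergence/separation): %s",
            paste(if (length(bad)) bad else "see model", collapse = ", "))
  }
  se <- sqrt(diag(vcov(fit)))
  terms <- data.table::data.table(
    term = names(est), estimate = unname(est), se = unname(se))
  terms <- terms[term != "(Intercept)"]
  terms[, `:=`(or = exp(estimate), lo = exp(estimate - 1.96 * se),
               hi = exp(estimate + 1.96 * se),
               p = 2 * pnorm(-abs(estimate / se)))]
  terms[, is_drug := gsub("`", "", term) %in% drug_col(drugs)]
  terms[, term := gsub("`", "", term)]
  terms[, p_adj := NA_real_]
  terms[is_drug == TRUE, p_adj := p.adjust(p, method = "BH")]
  terms[, significant := is_drug & p < p_cut]
  drug_names <- setNames(drugs, drug_col(drugs))
  terms[is_drug == TRUE, term := unname(drug_names[term])]
  structure(list(terms = terms[], loglik = as.numeric(stats::logLik(fit)),
                 n = nrow(dm), fitted = unname(fit$fitted.values),
                 outcome = dm$outcome),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n=%d, logLik=%.2f\n", x$n, x$loglik))
  print(x$terms[, .(term, or = round(or, 3), lo = round(lo, 3),
                    hi = round(hi, 3), p = signif(p, 3), significant)])
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney with tie correction)
#'
#' AUC = (R1 - n1(n1+1)/2) / (n1 n0), where R1 is the rank sum of the
#' positive-class scores under midranks — the probability a random positive
#' outranks a random negative, counting ties as 1/2.
#'
#' @param scores numeric predicted scores/probabilities.
#' @param outcome binary outcomes aligned with `scores`.
#' @return AUC in \[0,1\]; error if only one outcome class is present.
#' @export
roc_auc <- function(scores, outcome) {
  stopifnot(length(scores) == length(outcome))
  y <- as.integer(outcome)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop_pv("AUC undefined: outcome has a single class")
  }
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sensitivity/1-specificity at every distinct score threshold, for plotting.
#'
#' @inheritParams roc_auc
#' @return data.table with `threshold`, `tpr`, `fpr`, ordered from (0,0) to
#'   (1,1).
#' @export
roc_points <- function(scores, outcome) {
  y <- as.integer(outcome)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(ss, fromLast = TRUE)
  data.table::data.table(
    threshold = c(Inf, ss[last]),
    tpr = c(0, tp[last] / sum(y)),
    fpr = c(0, fp[last] / sum(1 - y)))
}

#' Run the whole screening cascade
#'
#' Design matrix, univariate screen, LASSO selection and multivariate fit in
#' sequence, with ROC/AUC of the final model.
#'
#' @param store a `case_store`.
#' @param target_pts target preferred terms.
#' @param min_a,p_cut,or_lo_min univariate screen thresholds.
#' @param nfolds,rule,seed LASSO settings.
#' @return list: `design`, `univariate`, `lasso` (NULL when fewer than two
#'   drugs were retained), `selected`, `fit` (NULL when nothing selected),
#'   `auc`, `roc`.
#' @export
screen_cascade <- function(store, target_pts, min_a = 100, p_cut = 0.01,
                           or_lo_min = 1, nfolds = 10, rule = "lambda.1se",
                           seed = 1L) {
  design <- build_design_matrix(store, target_pts)
  uni <- univariate_screen(design, min_a = min_a, p_cut = p_cut,
                           or_lo_min = or_lo_min)
  retained <- uni$drug[uni$retained]
  lasso <- NULL
  selected <- retained
  if (length(retained) >= 2L) {
    lasso <- lasso_select(design, retained, nfolds = nfolds, rule = rule,
                          seed = seed)
    selected <- lasso$selected
  }
  fit <- NULL; auc <- NA_real_; roc <- NULL
  if (length(selected) > 0L) {
    fit <- multivariate_fit(design, selected, p_cut = p_cut)
    auc <- roc_auc(fit$fitted, fit$outcome)
    roc <- roc_points(fit$fitted, fit$outcome)
  }
  list(design = design, univariate = uni, lasso = lasso, selected = selected,
       fit = fit, auc = auc, roc = roc)
}
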