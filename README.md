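# pvfaers

Pharmacovigilance signal detection and drug screening for spontaneous
adverse-event report databases in the FAERS (FDA Adverse Event Reporting
System) quarterly ASCII layout, built around a drug-related proteinuria
case definition but configurable for any MedDRA preferred-term target.

## Who this is for

Pharmacoepidemiologists and biostatisticians who want a tested, scriptable
version of the standard FAERS workflow: parse the quarterly `$`-delimited
tables (DEMO/DRUG/REAC/THER), deduplicate case versions, restrict to
primary-suspect (PS) drug mentions, and quantify drug–event
disproportionality — plus a synthetic FAERS-like data generator with known
ground truth so the whole pipeline can be validated end to end without
downloading the real database.

## The statistics

For each drug *D* and target event *Y*, the deduplicated database is
collapsed to the 2×2 table *a* = #(D∧Y), *b* = #(D∧¬Y), *c* = #(¬D∧Y),
*d* = #(¬D∧¬Y), with N = a+b+c+d and E = (a+b)(a+c)/N. Four
disproportionality methods are computed with their interval bounds:

- **ROR** = ad/(bc), Wald 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`
- **PRR** = [a/(a+b)]/[c/(c+d)] with the Pearson χ² of the table
- **BCPNN information component** IC = log₂(a/E), with IC025 from the
  Norén closed-form approximation (exact posterior-quantile mode available)
- **MGPS EBGM**: empirical-Bayes geometric mean of the reporting-rate ratio
  λ under the two-component gamma (DuMouchel) prior
  `w·Gamma(α₁,β₁) + (1−w)·Gamma(α₂,β₂)`, whose five hyperparameters are
  fitted by marginal (negative-binomial mixture) maximum likelihood over
  every drug–PT pair; EBGM05 is the 5th posterior percentile.

A pair is a **consensus signal** when all four methods flag it
(a ≥ 3 ∧ ROR CI lower > 1; PRR ≥ 2 ∧ χ² ≥ 4 ∧ a ≥ 3; IC025 > 0;
EBGM05 > 2 — all configurable). A screening cascade then mirrors the
epidemiological workflow: univariate logistic screen (OR CI lower bound
> 1, a > 100, Benjamini–Hochberg adjusted p < 0.01), LASSO selection with
10-fold cross-validation (covariates unpenalized; λ_1se by default), and a
covariate-adjusted multivariate logistic model (sex, five age classes,
50–100 kg weight reference) assessed by rank-based ROC/AUC. Time-to-onset
is summarized per drug class (mean, Q1, Q3, ECDF).

## Worked example

```r
library(pvfaers)

cfg <- synthetic_config(n_reports = 30000, seed = 1)   # 25-drug default catalog
tables <- generate_reports(cfg)                        # FAERS-like tables + ground truth
store <- build_case_store(tables)                      # dedup + normalize
sig <- signal_table(store, "Proteinuria")
print(subset(sig$stats, consensus,
             select = c(drug, a, ror, ror_lo, prr, chi2, ebgm, ebgm05,
                        ic, ic025)), digits = 6)
```

```
                   drug     a      ror   ror_lo      prr     chi2    ebgm  ebgm05      ic   ic025
1:           lenvatinib   950 60.39321 52.12091 13.45182 7689.759 8.91622 8.45041 3.16582 3.05869
2: tenofovir disoproxil   276  3.41364  2.96412  2.84909  325.266 2.63980 2.38862 1.40921 1.21014
3:          voclosporin   604 12.65581 11.21883  6.93214 2593.588 5.54134 5.18026 2.47922 2.34481
```

The consensus set is the three strongest of the five planted signal drugs
(true rate ratios 40, 25 and 12). The two weaker planted drugs (rate
ratios 8 and 5) are *masked*: the default catalog packs five strong
signals into one database, which inflates the expected count E for every
drug and drags their observed/expected ratios below the PRR ≥ 2 and
EBGM05 > 2 thresholds — the same masking that affects disproportionality
statistics on the real database. Note also how shrinkage orders the
columns: the raw ROR of 60 for the top drug collapses to an EBGM of 8.9,
because EBGM measures λ = observed/expected against the whole-database
background rather than drug-vs-drug odds. `screen_cascade(store,
"Proteinuria")` continues into the LASSO/multivariate stage, and
`run_all(run_config(), "out/")` writes the full artifact set (baseline
table, signal CSV, regression forest-plot CSV, λ path, ROC points, TTO
summaries, fitted prior, run manifest).

A thin CLI wraps the same pipeline:

```sh
Rscript inst/cli/pv.R all --out run1 --seed 7
```

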