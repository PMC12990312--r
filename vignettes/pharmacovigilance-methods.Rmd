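---
title: "Disproportionality methods and validation design in pvfaers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods and validation design in pvfaers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvfaers)
```

## The problem

Spontaneous reporting systems such as FAERS collect voluntary reports of
suspected adverse drug reactions. They have no denominator — no exposure
counts, no population at risk — so risk cannot be estimated directly.
Disproportionality analysis instead asks whether a drug–event pair is
reported *more often than expected* given the drug's and the event's overall
reporting frequencies. `pvfaers` implements the standard four-method battery
on top of a reproducible ingest of the FAERS quarterly ASCII layout, a
regression-based drug-screening cascade, time-to-onset profiling, and a
synthetic data generator that makes every stage testable against known
ground truth.

## Ingest rules

FAERS distributes one `$`-delimited ASCII file per table per quarter. The
parser takes column meaning from the header row (never from position),
counts and skips rows whose field count disagrees with the header (a stray
delimiter inside a free-text drug name is the classic cause), and treats a
missing `primaryid`/`caseid` column as a hard error.

Decisions a FAERS analysis must make, and the defaults here:

* **Deduplication.** A case (`caseid`) accumulates report versions
  (`primaryid`s) as follow-ups arrive. We keep, per case, the version with
  the latest receipt date, breaking ties by the largest `primaryid` — the
  FDA-documented convention. Deduplication is idempotent and the kept count
  always equals the number of distinct caseids.
* **Partial dates.** `YYYYMM` imputes day 15, `YYYY` imputes July 1; both
  are flagged imprecise and excluded from time-to-onset by default
  (opt-in via `include_imprecise`).
* **Units.** Age codes DEC/YR/MON/WK/DY/HR convert to years (×10, ×1, ÷12,
  ÷52, ÷365.25, ÷8766); weight KG/LBS/GMS to kilograms (×1, ×0.453592,
  ÷1000). Implausible results (age outside [0, 150] years, weight outside
  (0, 700) kg) and unknown codes become missing, with a logged warning.
* **Drug names.** Verbatim names are case-folded, whitespace-collapsed,
  stripped of trailing salt/form suffixes, and resolved through a packaged
  brand→generic synonym map (user-extensible); unmapped names pass through
  case-folded.
* **Primary suspect.** Only drug mentions with role code PS enter the
  analysis drug list. Cases whose drugs are all non-PS still contribute to
  the event margins: the 2×2 background must cover the whole database.

## The four disproportionality statistics

With $a,b,c,d$ the drug/event 2×2 cells, $N$ their sum and
$E=(a+b)(a+c)/N$:

* **ROR** $= ad/bc$, 95% CI $\exp(\ln\mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$.
  A zero cell makes the ROR undefined; the Haldane–Anscombe +0.5 correction
  is available but off by default (affected pairs are flagged instead).
* **PRR** $= \frac{a/(a+b)}{c/(c+d)}$ with Pearson's $\chi^2$, computed
  *without* Yates continuity correction by default. This choice is
  validated by the reconstruction tests: the recomputed $\chi^2$ on tables
  rebuilt from published two-decimal summaries agrees with the published
  statistic to well within rounding propagation, which the Yates-corrected
  variant does not. Yates remains available as a switch.
* **BCPNN information component** IC $=\log_2(a/E)$ — the
  maximum-likelihood IC without additive smoothing, again the variant that
  reproduces published values on reconstructed tables. The lower 95%
  credibility bound IC025 defaults to the Norén closed-form approximation
  $\mathrm{IC} - 3.3a^{-1/2} - 2a^{-3/2}$; an exact gamma posterior
  quantile mode (`ic025 = "exact"`, shrinkage count +0.5 on observed and
  expected) is also provided. Published FAERS analyses occasionally print
  IC025 values a few hundredths above the Norén approximation, suggesting
  yet another interval convention; rather than guess, both modes are
  exposed and only the IC point estimate is asserted in validation.
* **MGPS / EBGM.** The reporting-rate ratio $\lambda$ gets the DuMouchel
  two-component gamma prior
  $w\,\Gamma(\alpha_1,\beta_1)+(1-w)\,\Gamma(\alpha_2,\beta_2)$. Its five
  hyperparameters are fitted by maximizing the marginal likelihood
  $\sum_i \log[\,w\,\mathrm{NB}(a_i;\alpha_1,\tfrac{\beta_1}{\beta_1+E_i})
  +(1-w)\,\mathrm{NB}(a_i;\alpha_2,\tfrac{\beta_2}{\beta_2+E_i})\,]$ over
  every drug–PT pair in the database. The posterior given $(a,E)$ is again
  a two-gamma mixture; EBGM $=e^{\mathbb{E}[\ln\lambda\,|\,a]}$ uses
  $\mathbb{E}[\ln\Gamma(\alpha,\beta)]=\psi(\alpha)-\ln\beta$, and EBGM05
  is the 5th posterior percentile found by root-bracketing on the mixture
  CDF (cross-checked against numerical quadrature to $10^{-6}$ in tests).

### MGPS numerical choices

The likelihood is maximized on $\log$-shape/rate and logit-weight scales
(positivity and $w\in(0,1)$ by construction) from five fixed starting
points, the first being the classic FAERS init $(0.2, 0.1, 2, 4, 1/3)$.
Plain quasi-Newton search from these starts can collapse onto the
*equal-components ridge* — both components identical, mixture weight
unidentified — which is a stationary set, not the optimum, on databases
where only a handful of pairs depart from $\lambda=1$. Each start therefore
runs Nelder–Mead first (up to 2000 iterations) and polishes with BFGS;
convergence is declared at relative log-likelihood change $<10^{-8}$ and the
best start wins. Components are reported in canonical order (higher prior
mean first). On a simulated database of 50,000 pairs the fit recovers a
known prior's weight within ±0.02 and its shapes/rates within a few percent
(the validation suite asserts the looser ±0.05 / ±20%).

One property worth stating precisely: at large counts EBGM approaches
$(a+\alpha)/(E+\beta)$ for the dominant posterior component, so it
converges to the raw ratio $a/E$ only when the prior's $\beta$ is small
relative to $E$. Realistic database-wide priors have $\beta_1\sim 0.1$ and
satisfy the "shrinkage vanishes" check at the 1% level for $a$ in the
hundreds; a prior with $\beta\approx 0.5$ leaves a visible
$\beta/(\beta+E)$ scale offset (≈2.5% at $E\approx 19$) even at huge $a$.
The validation suite therefore checks hyperprior *recovery* with the
recovered prior and *shrinkage vanishing* with the canonical database
prior.

### Consensus signal

A pair is a signal only when all four methods agree (thresholds
configurable via `signal_criteria()`): $a \ge 3$ and ROR CI lower bound
$> 1$; PRR $\ge 2$, $\chi^2 \ge 4$, $a \ge 3$; IC025 $> 0$; EBGM05 $> 2$.
A missing component statistic makes that method's flag false and marks the
pair not evaluable.

### Validating against published summary tables

Published signal tables print $(a, \mathrm{ROR}, \mathrm{PRR}, \ldots)$ but
not $b$ and $d$. Given the total number of target-event reports, the two
identities invert in closed form: $b = a(\mathrm{PRR}-1)/(\mathrm{ROR}-
\mathrm{PRR})$ and $d = \mathrm{ROR}\,bc/a$ (`reconstruct_table()`, which
refuses ROR = PRR and negative solutions and verifies both identities to
$10^{-9}$ relative). Every derived column — CI bounds, $\chi^2$, IC,
observed/expected — can then be recomputed from the reconstructed table and
compared against print, which is exactly what `scripts/acceptance.R` does.

## The drug-screening cascade

The regression stage mirrors the screening workflow used in
pharmacovigilance case/non-case studies:

1. **Design matrix** — outcome: any target PT on the report; complete-case
   on sex, age and weight ("only reports with complete data"); sex coded
   with female as reference; age in five classes <18 (reference), 18–40,
   41–60, 61–80, >80; weight dichotomized 50–100 kg (reference) vs outside.
2. **Univariate screen** — per drug, the single-binary-predictor logistic
   model, whose MLE is the closed-form 2×2 Wald solution (a unit test
   verifies equality with `glm`). Retention requires *(i)* OR 95% CI lower
   bound > 1, *(ii)* drug-and-event count $a > 100$, *(iii)*
   Benjamini–Hochberg adjusted p < 0.01, the BH family being the drugs
   passing the count gate. The published description of this rule is
   garbled ("a lower limit of the 95% confidence interval for P adjustment
   <0.01"); the reading adopted here is the only one in which both the CI
   bound and the p-adjustment appear, and each clause is independently
   configurable.
3. **LASSO selection** — L1-penalized logistic regression on the retained
   drug indicators with the demographic covariates *unpenalized*
   (adjustment, never selection: penalizing reference covariates distorts
   which drugs survive), 10-fold cross-validated binomial deviance with a
   seeded fold assignment. Which λ the original workflow used is not
   knowable from published output (cross-validation figures typically mark
   both); the default here is the more conservative `lambda.1se`, with
   `lambda.min` a switch.
4. **Multivariate fit** — maximum-likelihood logistic regression of the
   outcome on selected drugs plus covariates; Wald ORs, CIs and p-values;
   drug terms with p < 0.01 labeled significant; non-convergence or
   separation is an error naming the offending terms.
5. **ROC/AUC** — the rank (Mann–Whitney) statistic with midrank tie
   handling, verified against exhaustive pair counting and against an
   independent ROC library.

## Time to onset

Onset is event date minus the earliest therapy start of the
primary-suspect drug, in days. Records with either date missing are
dropped; negative onsets (event before any start) and onsets above 9125
days (25 years — implausible for one treatment course) are excluded and
logged; imputed partial dates are excluded by default. Summaries report
the arithmetic mean and linear-interpolation quartiles
(`stats::quantile` type 7) per drug class — published onset tables cannot
adjudicate a quartile convention without raw data, so the most common
default is used and documented. A constant-onset class correctly collapses
to mean = Q1 = Q3. `cumulative_incidence()` emits per-class ECDF points on
a day grid for plotting.

## The synthetic generator: what it emulates and what it does not

`generate_reports()` draws, per case: one primary-suspect drug from a
catalog of (share, rate ratio θ, log-normal onset) entries; the target PT
with probability $p_0\theta$ (configs with $p_0\max\theta > 1$ are
rejected); ≥1 of 20 background PTs independently at rate 0.08; sex, age
and weight with FAERS unit-code mixes and per-field missingness; receipt,
therapy and event dates (onset log-normal per drug, parameterized by
median and log-SD — positive, right-skewed, two parameters); optional
concomitant (role C) mentions; partial dates at a configurable rate; and
duplicate case versions at `duplicate_rate`, each with a new `primaryid`,
a later-or-equal receipt date and occasionally amended weight. Output is
deterministic given the config, and ground truth records every case's
latest version, PS drug, event status and true onset.

Defaults are chosen to resemble a renal-adverse-event case series at desk
scale: cohorts of 10⁴–10⁵ reports, baseline target probability
$p_0 = 0.02$, mean age in the 60s, US/Japan-dominated country mix,
double-digit missingness for sex and weight. The default 25-drug catalog
plants five signals (θ = 40, 25, 12, 8, 5) on a null background.

What the generator deliberately does **not** emulate — and hence what
passing tests do *not* establish about real data: reporter-country and
stimulated-reporting biases; correlated PTs (real reactions co-occur);
multiple primary suspects per case; indication-driven channeling
(confounding by indication); dose records; and MedDRA hierarchy effects.
One emergent realism worth noting: because disproportionality measures
compare each drug against the whole database, packing several strong
signals into one catalog inflates every expected count and *masks* the
weaker signals — visible already in the default catalog, where the θ = 8
and θ = 5 drugs fall below the PRR/EBGM thresholds.

## Validation study designs and problem sizes

The acceptance-level suite fixes these study conditions (chosen once, from
power analysis, as the package's own validation design):

* **Null calibration** — 10⁵ reports, 200 all-null drugs, $p_0=0.02$:
  consensus flags must fire for <1% of the ~4200 drug–PT pairs, and drug
  terms in multivariate fits on permuted outcomes (100 permutations × 5
  null drugs) must be significant at 0.01 in ≤5% of tests.
* **Planted-signal recovery** — 100 replicates of: 40,000 reports, 50
  drugs, planted θ ∈ {5, 10, 40} at shares {0.0575, 0.0288, 0.0072}
  (inversely scaled to θ so each planted drug expects ≈230 drug-and-event
  reports, clearing the univariate count gate with wide margin while
  keeping background inflation low enough that the θ = 5 drug's
  observed/expected ratio stays near 2.8), 5% per-field missingness. In
  ≥90 replicates the consensus-flagged set and the multivariate-significant
  set must both equal exactly the planted set.
* **MGPS recovery** — 50,000 (a, E) pairs simulated from a known prior
  (0.5, 0.5, 2, 4, w = 0.4), E log-normal around 5.
* **Onset recovery** — 2,000 records per class across four classes with
  medians 5 (constant), 30, 180 and 1000 days.

## Known limitations

* Expected counts are unstratified; age/sex/year-stratified MGPS is out of
  scope, as are drug–drug interaction signals and LRT-based detection.
* The synonym map and drug-class map are deliberately small packaged
  defaults, not a licensed dictionary; real analyses should extend them.
* The cascade assumes one target event definition per run; multi-event
  scans re-run the pipeline per PT set.
* On real FAERS data the absolute AUC of the screening model is dominated
  by unmeasured confounding; the package validates discrimination only on
  synthetic cohorts where the truth is known.
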