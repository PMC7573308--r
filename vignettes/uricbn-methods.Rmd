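---
title: "Methods: phenotyping, odds ratios and Bayesian-network reasoning for hyperuricemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping, odds ratios and Bayesian-network reasoning for hyperuricemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uricbn)
```

`uricbn` implements a complete analysis chain for studying how metabolic
health and obesity jointly relate to hyperuricemia in adult cohorts, with a
particular focus on sex-specific effects: deriving the six metabolic-obesity
phenotypes from raw measurements, estimating sex-stratified prevalences and
sequentially adjusted odds ratios, and learning a discrete Bayesian network
over the discretized cohort for probabilistic reasoning about hyperuricemia
risk.  Because the population-survey microdata this kind of study uses are
access-restricted, the package ships a calibrated synthetic-cohort generator
that reproduces the statistical structure the analysis relies on; every
quantitative claim the test suite makes is a recovery or oracle-equivalence
statement on synthetic data, not a re-analysis of survey data.

## Phenotype derivation

Hyperuricemia is serum uric acid ≥ 420 µmol/L in men and ≥ 360 µmol/L in
women (inclusive).  BMI (kg/m²) is classified with the cut points
recommended for Chinese adults: normal 18.5–23.9, overweight 24.0–27.9,
obese ≥ 28.0; values below 18.5 are labeled `excluded` and dropped from
phenotype-stratified outputs, since the six-phenotype taxonomy starts at
18.5.  All threshold comparisons are made at full floating precision, with
bin edges half-open exactly as documented.

Metabolic health has two interchangeable definitions:

* **ATP-III** (default): four components — elevated blood pressure
  (SBP ≥ 130 or DBP ≥ 85 mmHg, or antihypertensive drugs), elevated
  triglycerides (≥ 1.7 mmol/L or lipid-lowering drugs), elevated fasting
  glucose (≥ 5.6 mmol/L or diabetes medication), and reduced HDL-C
  (< 1.04 mmol/L men, < 1.3 mmol/L women).  The waist criterion is omitted
  because of its collinearity with BMI.  A subject is *unhealthy* at two or
  more abnormal components.  The source literature for this phenotype
  family is ambiguous between "two or more" and "three or more" of the
  four retained items; we default to ≥ 2, the ATP-III metabolic-syndrome
  convention once waist is dropped, and expose
  `phenotype_thresholds(atp3_unhealthy_min = 3)` for the stricter reading.
* **VAI**: the sex-specific Visceral Adiposity Index
  (men \((WC/(39.68+1.88\,BMI))(TG/1.03)(1.31/HDL)\); women
  \((WC/(36.58+1.89\,BMI))(TG/0.81)(1.52/HDL)\)), healthy iff VAI < 1.59
  (strict).

Crossing BMI class with health status yields MHNW, MHOW, MHO, MUNW, MUOW,
MUO.  Abdominal obesity defaults to waist ≥ 90 cm (men) / ≥ 80 cm (women);
these cut-offs vary across guidelines and are config-overridable.
HOMA-IR is insulin (µIU/mL) × glucose (mmol/L) / 22.5.

## Prevalence and odds-ratio estimation

Stratum prevalences use the Wilson score interval by default: it is
asymmetric near the boundary, behaves well at the small stratum sizes an
MHO cell produces, and matches the shape of published prevalence intervals
for this design; Clopper–Pearson is available via `method`.  At the exact
boundaries \(k = 0\) and \(k = n\) the interval endpoints are set to 0 and
1.

Association models are binomial-logit GLMs fitted by IRLS (`glm.fit`),
with the six-way phenotype coded as five indicators against the MHNW
reference.  Model 1 adjusts for age (continuous), sex (total stratum
only), urban residence, smoking and alcohol status; model 2 adds white
blood cell count, total cholesterol, LDL-C, hs-CRP and diabetes.  The
design matrix is rank-checked before fitting, and apparent perfect
separation (diverging coefficients or boundary fitted probabilities) marks
the fit non-converged; `run_association_models()` then reports that
stratum's odds ratios as `NA` with a warning rather than quoting a Wald
interval that does not exist.  Odds-ratio intervals are Wald
(\(\exp(\hat\beta \pm z\,SE)\)) — the standard presentation in
epidemiologic tables and symmetric on the log scale.  Backward stepwise
selection (`stepwise_select()`) uses AIC with the phenotype entering as a
single factor, so the block leaves or stays as a whole; the procedure is
deterministic given the input term order.

## Bayesian-network methodology

The network machinery is written for small discrete problems (≤ ~14 nodes,
2–5 levels) and is deliberately explicit rather than clever:

* **Scoring.** Natural-log BIC, decomposable over nodes:
  \(\mathrm{score}_i=\sum_{j,k} N_{ijk}\ln(N_{ijk}/N_{ij\cdot}) -
  \tfrac{\ln N}{2}\,q_i(r_i-1)\), with \(0\ln 0 = 0\).  Data are collapsed
  to distinct configurations with multiplicities, so one family score costs
  O(#distinct rows); the hot path is compiled (Rcpp).
* **Search.** Tabu search over single-arc additions, deletions and
  reversals, starting from the whitelist-only graph.  The best admissible
  neighbour is accepted even when it worsens the score; the pair just
  modified is tabu for `tabu_tenure` (default 10) iterations unless
  revisiting it would beat the incumbent; search stops after 50
  non-improving iterations (default) or `max_iterations`.  Moves are
  enumerated lexicographically by (from, to, add < delete < reverse), and
  score comparisons use a 1e-9 margin, so score-equivalent moves resolve
  deterministically to the first candidate — bootstrap direction
  frequencies are then stable rather than artifacts of rounding noise.
* **Constraints.** Blacklisted arcs are never added, whitelisted arcs
  never removed or reversed.  `layering_constraints()` encodes the causal
  layering for the cohort network: nothing may leave the outcome
  (hyperuricemia), and the two exposure-layer nodes (metabolic syndrome,
  BMI level) may not point at each other.  The layering language
  "allowed to be directed to" the outcome is read as *permit-only*;
  `force_exposures = TRUE` turns permission into requirement for users who
  prefer forced arcs.
* **Model averaging.** `bootstrap_arc_strengths()` learns one network per
  nonparametric bootstrap resample (default R = 300, resample size m = n;
  on collapsed data a resample is a multinomial reweighting, which is why
  R = 100 × 100 replicates is feasible on a laptop).  An arc's *strength*
  is the fraction of resamples containing it in either direction, its
  *direction* the orientation fraction among those.  `average_network()`
  keeps pairs with strength ≥ threshold (0.5 for the averaged network,
  0.85 for the simplified one), orients by majority (ties to the
  lexicographically smaller source), and — because thresholded majority
  orientations can cycle — drops cycle arcs in increasing strength order
  until acyclic.
* **Parameters and inference.** CPTs are estimated by maximum likelihood
  (`alpha = 0`), with Laplace smoothing available; an unobserved parent
  configuration under MLE gets a uniform row and a warning.
  `exact_query()` enumerates evidence-consistent completions of the joint
  factorization — at ≤ 14 nodes with small cardinalities the free state
  space stays ≤ ~10^6, and enumeration is trivially auditable against a
  materialized joint table (the tests do exactly that, at 1e-12).
  `lw_query()` provides likelihood weighting as an independent stochastic
  cross-check with a reported Monte-Carlo standard error.

For the cohort network, `discretize_cohort()` builds the 14-variable
discrete table: sex; age group (18–39/40–59/60+); BMI level; ATP-III
metabolic-syndrome status; hyperuricemia; diabetes; smoking; alcohol;
urban residence; abdominal obesity; and binary splits of LDL-C
(3.37 mmol/L), total cholesterol (5.2 mmol/L), hs-CRP (3 mg/L) and white
blood cell count (cohort median).  The published network figure shows the
node set but not the coding, so these cut points are package choices,
taken from common clinical conventions and overridable in the config.
Reasoning scenarios that condition on a metabolic-component *count* use
the five-level component node of the reference network below; the
cohort network itself carries metabolic syndrome as a binary node.

## The synthetic-cohort generator

`generator_spec()` encodes the study conditions: 53.6% female; the
published per-sex six-phenotype shares; and per-(phenotype, sex)
hyperuricemia prevalences (the published stratum table).  Sampling is
top-down: sex, then phenotype given sex, then covariates *consistent with
the phenotype label* — BMI inside its class bin, a number of abnormal
ATP-III components compatible with the health label (healthy 0–1,
unhealthy 2–4, with which components chosen by sex-weighted sampling
without replacement), component values truncated at their thresholds
accordingly, and drug flags only among threshold-abnormal subjects.
Re-deriving the phenotype from the raw columns therefore reproduces the
generating label exactly, which the tests verify.

Serum uric acid follows a sex-specific log-normal (σ ≈ 0.30/0.29 on the
log scale, matching the observed coefficient of variation) whose location
is *calibrated by bisection* per stratum so the analytic tail mass above
the sex threshold equals the target cell; the tail is strictly monotone in
the location, so the bisection is guaranteed once a doubling search finds
a bracket.  The remaining covariates use truncated normal / log-normal
laws with sex-conditional parameters loosely matching the published
sample-characteristics table; they are plausibility-level only, since no
recovery target depends on their moments.  Diabetes is drawn conditional
on phenotype with a monotone default.  One master seed is split into
per-field streams so adding a field does not shift unrelated draws;
identical specs give byte-identical tables.

A second outcome mode (`or_model`) draws hyperuricemia directly from a
logistic model on the phenotype label (uric acid then drawn consistently
above/below the sex threshold).  This is the mode used for odds-ratio
recovery experiments, where the estimand is the generating log-odds
coefficient itself.

What the generator does **not** emulate: survey design (clustering,
weights, household structure), realistic covariate correlation beyond the
waist–BMI link, missingness, or measurement error.  Green recovery tests
therefore demonstrate that the estimators recover what the generator
encodes — not that the package would reproduce any particular real-data
table.

## Design of the simulation experiments

Several choices in the test suite are experiment-design decisions worth
stating explicitly:

* **Odds-ratio recovery** uses a women-only, two-arm (MHNW/MHO, 50/50)
  cohort of 200,000 with generating OR 1.95 and baseline prevalence 4%.
  With the study's own MHO share (3.6% of women) the fitted log-OR has
  SE ≈ 0.045, so a ±0.10 check on the OR would be a coin flip at any
  sample size fixed to 200,000; the two-arm allocation brings SE(log OR)
  to ≈ 0.02 and makes the check informative about bias rather than about
  Monte-Carlo luck.  The generator's *defaults* keep the study shares.
* **Reasoning recovery** uses the five-node reference network
  (`reference_reasoning_network()`): sex, BMI group, component count,
  diabetes, hyperuricemia, with the hyperuricemia CPT encoding the
  published risk pattern (0.05 → 0.10/0.14/0.31/0.56 with obesity and
  component count; 0.076 men vs 0.124 women at obese/0 components; 0.606
  at obese/4 components with diabetes).  The auxiliary distributions put
  deliberate mass on the queried strata so each conditional probability is
  re-estimated from ~7,000–11,000 forward samples at n = 100,000 —
  i.e. to 2.5–3 standard errors inside the ±0.01 recovery band.  They are
  test-power choices, not population claims.
* **Structure recovery** uses a six-node binary network with strong CPTs,
  n = 20,000 per replicate, R = 100 bootstrap resamples and 100
  replicates, comparing skeletons by structural Hamming distance.  These
  sizes keep the full suite under a minute on one core while leaving the
  recovery rates far from their thresholds.
* **Interval calibration** checks Wilson coverage at p = 0.085, n = 142
  (the MHO-women cell geometry) over 10,000 replicates, and Wald CI
  coverage of a null odds ratio pooled over the five non-reference
  phenotypes of a balanced null cohort (500 intervals), since the joint
  event "all five CIs cover 1" has nominal probability well below any
  sensible per-interval threshold.

## Numerical and degenerate-input behavior

Probability vectors must sum to 1 within 1e-9 (CPT rows, phenotype
distributions); queries renormalize only over evidence-consistent mass and
refuse zero-probability evidence.  Calibration targets of exactly 0 or 1
are rejected (the log-normal tail cannot attain them).  `tabu_search` on
≤ 56 nodes only (parent sets are bitmasks); parent-state spaces larger
than 5 × 10^7 cells score as −∞ and are never selected.  Bootstrap
strengths have granularity 1/R by construction.  All stochastic entry
points take explicit integer seeds and are byte-reproducible.

## Known limitations

* Exact inference is enumeration — fine at this package's scale, wrong
  tool beyond ~20 nodes; no junction tree or variable elimination.
* No CPDAG/equivalence-class output: score-equivalent orientations are
  resolved by deterministic move order and reported as directed arcs, so a
  single learned arc's direction should be read together with its
  bootstrap direction confidence.
* No constraint-based learners, continuous or hybrid networks, or
  MAP-queries.
* The logistic machinery assumes complete cases and independent
  observations; there is no survey-design variance correction.
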