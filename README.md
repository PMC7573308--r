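# uricbn

Sex-specific metabolic-obesity phenotyping and Bayesian-network analysis of
hyperuricemia.

## What this package is for

Hyperuricemia (serum uric acid ≥ 420 µmol/L in men, ≥ 360 µmol/L in women)
is strongly linked to obesity and to the metabolic syndrome, but *whether a
metabolically healthy obese (MHO) person carries extra risk — and whether
that depends on sex* — is the kind of question that needs the whole
analysis chain: consistent phenotype definitions, stratified prevalence
estimation, sequentially adjusted regression, and a multivariate view of
how the risk factors relate to each other.  `uricbn` packages that chain
for epidemiologists working with adult cohort tables:

* **Phenotyping** — BMI classes at the Chinese-adult cut points
  (18.5/24/28 kg/m²), ATP-III metabolic health (four components, waist
  excluded; unhealthy at ≥ 2 abnormalities), the sex-specific Visceral
  Adiposity Index (healthy iff VAI < 1.59), HOMA-IR, abdominal obesity,
  and the six-way cross MHNW/MHOW/MHO/MUNW/MUOW/MUO.
* **Epidemiological statistics** — Wilson-interval prevalences per
  (phenotype, sex) stratum; sex-group descriptives with t/chi-square
  tests; logistic models of hyperuricemia on phenotype (MHNW reference)
  with two adjustment sets (model 1: age, sex, urban, smoking, alcohol;
  model 2: + white blood cells, total cholesterol, LDL-C, hs-CRP,
  diabetes), for the total cohort and per sex; backward-AIC selection
  with the phenotype as a block.
* **Bayesian networks** — discrete structure learning by Tabu search with
  BIC scoring (`score_i = Σ N_ijk ln(N_ijk/N_ij·) − (ln N)/2 · q_i(r_i−1)`),
  layering constraints (nothing leaves the outcome; the exposure-layer
  nodes may not link to each other), arc-strength estimation over
  bootstrap resamples (default R = 300), consensus networks at the
  0.5/0.85 strength thresholds, maximum-likelihood CPTs, and exact
  conditional-probability reasoning with a likelihood-weighting
  cross-check.
* **Synthetic cohorts** — a seeded generator calibrated to the published
  marginal structure (53.6% female; per-sex phenotype shares;
  per-stratum hyperuricemia prevalences, hit exactly by bisection
  calibration of a log-normal uric-acid law), so estimator behavior can
  be verified by parameter recovery without access-restricted survey
  microdata.

## Worked example

```r
library(uricbn)

spec   <- generator_spec(n_subjects = 20000, seed = 42)  # study-calibrated defaults
cohort <- sample_cohort(spec)
ph     <- phenotype_cohort(cohort)

subset(prevalence_by_phenotype(ph), sex == "female")
#>  phenotype    sex   k    n  p_hat ci_low ci_high level
#>       MHNW female 214 4645 0.0461 0.0404  0.0525  0.95
#>       MHOW female 101 1917 0.0527 0.0436  0.0636  0.95
#>        MHO female  29  401 0.0723 0.0508  0.1019  0.95
#>       MUNW female 298 1566 0.1903 0.1716  0.2105  0.95
#>       MUOW female 328 1396 0.2350 0.2135  0.2579  0.95
#>        MUO female 215  711 0.3024 0.2698  0.3371  0.95
```

The female prevalence gradient runs from ~4.6% in metabolically healthy
normal weight to ~30% in metabolically unhealthy obese, with the MHO cell
(7.2%, CI 5.1–10.2%) sitting well above its healthy normal-weight
reference — the pattern the generator was calibrated to.  The adjusted
odds-ratio table for women (model 2) reads:

```r
subset(run_association_models(ph), stratum == "women" & model == 2)
#>  stratum phenotype model   or ci_low ci_high reference
#>    women      MHNW     2 1.00     NA      NA      TRUE
#>    women      MHOW     2 1.15  0.902    1.47     FALSE
#>    women       MHO     2 1.64  1.094    2.45     FALSE
#>    women      MUNW     2 4.95  4.104    5.97     FALSE
#>    women      MUOW     2 6.55  5.437    7.89     FALSE
#>    women       MUO     2 9.40  7.585   11.64     FALSE
```

so MHO women show a significant association with hyperuricemia (OR 1.64,
CI 1.09–2.45) relative to MHNW women even after full adjustment.  On the
reasoning side, querying the reference five-node network:

```r
bn <- reference_reasoning_network()
exact_query(bn, "hyperuricemia",
            list(bmi_group = "obese", components = "0", sex = "female"))
#> P(hyperuricemia | bmi_group = obese, components = 0, sex = female) by exact:
#>    no   yes
#> 0.876 0.124
```

i.e. an obese but component-free woman carries a 12.4% hyperuricemia
probability under the encoded risk pattern (vs 7.6% for a man — the
sex-specific gap the package exists to quantify).

`run_pipeline(pipeline_config(...))` chains all stages — simulate/read,
phenotype, describe, prevalence, association models, network learning
(bootstrap → averaged 0.5 → simplified 0.85), CPT fit and reasoning —
writing every table, DOT/JSON graph and a seed-recording run log to an
output directory.

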