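# grequiv

Polygenic risk scores, case-control logistic models, and **genetic risk
equivalents** (GRE) for epidemiologic analyses of gene–lifestyle risk
factors, built around the case-control study design used in colorectal
cancer (CRC) research.

## What it does, and for whom

Epidemiologists report excess-weight associations as odds ratios per BMI
category and genetic associations as odds ratios per PRS category — scales
that are hard to communicate jointly. The GRE translates an exposure onto
the genetic scale: the **difference in PRS percentiles whose log-odds
association with disease equals the exposure's**. For a logistic model

    logit P(case | x) = α + β_e·1[exposed] + β_g·g + γ'z

with `g` the PRS percentile (per 10 percentiles by default) and `z` the
adjustment covariates, the GRE of the exposure is the coefficient ratio on
the percentile scale:

    GRE_e = β_e / (β_g · u),      u = model units per percentile (0.1 here)

with delta-method, Fieller, and parametric-bootstrap confidence intervals.
A GRE of 41 for obesity means obesity carries the same increase in disease
odds as a 41-percentile higher PRS.

The package implements the full chain for retrospective case-control data:

* **PRS construction** from a variant scoring table (PGS-Catalog-style TSV)
  and a dosage matrix (TSV or VCF with `DS`/`GT`), with effect-allele
  orientation checks, mid-rank percentile transformation and tertile
  categorization against the control distribution, and decade-lagged BMI
  derivation.
* **Case-control modelling**: minimally/fully adjusted logistic fits
  (`fit_logistic`, `or_table`), multiplicative interaction tests
  (`interaction_test`), PRS-stratified fits (`stratified_fits`), 3×3 joint
  BMI×PRS classification (`joint_classification`), polytomous subtype
  heterogeneity tests (`heterogeneity_test`), VIF diagnostics (`vif`), and
  case-control chi-square descriptives (`chi_square_table`).
* **GRE estimation** (`compute_gre`, `gre_table`, `gre_rescale`).
* **A synthetic cohort generator** (`simulation_config`,
  `simulate_cohort`) that emulates a large CRC case-control study (5053
  cases / 4116 controls, 140-variant PRS) with known generative effect
  sizes, so every stage can be validated against ground truth; and a
  pipeline (`run_pipeline`) that writes all analysis tables plus a
  reproducibility manifest.

## Worked example

Simulate a mid-sized cohort, score it, fit the fully adjusted model, and
express the BMI associations as GREs:

```r
library(grequiv)

cfg <- simulation_config(n_cases = 1200, n_controls = 1000, n_variants = 60,
                         pop_size = 48000, seed = 2024)
sim    <- simulate_cohort(cfg)
cohort <- add_prs(sim$cohort, sim$genotypes, sim$weights)

adj <- c("age", "sex", sapply(cfg$covariate_specs, `[[`, "name"))
fit <- fit_logistic(cohort, "bmi_category", c(adj, "prs_pct10"))
or_table(fit, c("bmi_categoryoverweight", "bmi_categoryobesity", "prs_pct10"))
#>                     term log_or     se   or or_low or_high
#> 1 bmi_categoryoverweight 0.3192 0.1022 1.38   1.13    1.68
#> 2    bmi_categoryobesity 0.4467 0.1339 1.56   1.20    2.03
#> 3              prs_pct10 0.0838 0.0156 1.09   1.05    1.12

compute_gre(fit, "bmi_categoryobesity", "prs_pct10")
#> GRE (delta) for bmi_categoryobesity: 53.3 percentiles (95% CI 16.9 to 89.7)

interaction_test(cohort, "bmi_category", "prs_pct10", adj)$joint
#> chi2 = 1.42 (df 2), p = 0.49
```

Reading: in this simulated cohort obesity carries an adjusted OR of 1.56,
equivalent to having a 53-percentile higher PRS (wide CI at this sample
size); the generative truth is 40.9 under the default effect sizes
(overweight OR 1.31, obesity OR 1.71, PRS OR 1.14 per 10 percentiles), and
there is no BMI×PRS interaction, consistent with the non-significant joint
Wald test. At the full study scale the replicate-mean recovery is exact to
within Monte-Carlo error (see below). `run_pipeline(cfg, out_dir)` writes
the complete set of descriptive, association, interaction, stratified,
joint-classification, and GRE tables as TSVs with a manifest.

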