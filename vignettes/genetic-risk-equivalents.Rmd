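---
title: "Polygenic risk scores, case-control models, and genetic risk equivalents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic risk scores, case-control models, and genetic risk equivalents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Excess body weight and common genetic variation are both established risk
factors for colorectal cancer (CRC), but they are usually reported on scales
that are hard to compare: an odds ratio per BMI category on one hand, an odds
ratio per polygenic-risk-score (PRS) category on the other. The *genetic risk
equivalent* (GRE) puts an exposure's association on the genetic scale: the
GRE of an exposure level is the difference in PRS percentiles whose log-odds
association with disease equals that of the exposure. A GRE of 30 for obesity
means that being obese is associated with the same increase in disease odds
as having a 30-percentile higher PRS. `grequiv` implements the full analytic
chain behind that metric for retrospective case-control data: PRS
construction from dosages, control-referenced percentile and tertile
transformation, adjusted logistic modelling (with interaction, stratified,
joint-classification, and subtype-heterogeneity analyses), and the GRE with
three confidence-interval constructions — together with a synthetic-data
generator whose known effect sizes make every stage testable.

## The model

All association models are unconditional logistic regressions of case status
on exposure indicators and adjustment covariates,

$$\operatorname{logit} P(\text{case} \mid x) = \alpha + \beta_{\text{ow}}\,
\mathbb{1}[\text{overweight}] + \beta_{\text{ob}}\,\mathbb{1}[\text{obesity}]
+ \beta_g \, g + \gamma' z,$$

where $g$ is the PRS percentile (coded per 10 percentiles in the default
analysis) and $z$ the covariate vector. The GRE of an exposure level with
coefficient $\beta_e$ is the coefficient ratio on the percentile scale,

$$\mathrm{GRE}_e = \frac{\beta_e}{\beta_g \cdot u},$$

with $u$ the number of model units per percentile (0.1 for per-10-percentile
coding). Two consequences are worth noting and are enforced by tests:

* **Scale equivariance.** Recoding the PRS term (per 1 vs per 10
  percentiles) together with the matching $u$ changes nothing.
* **Shared-denominator identity.** Within one model all exposure levels
  share $\beta_g$, so $\mathrm{GRE}_a / \mathrm{GRE}_b = \beta_a / \beta_b$
  exactly; one level's GRE is recoverable from another's GRE and the two
  odds ratios.

### Confidence intervals for the ratio

Three methods are implemented; none is claimed to replicate any particular
published computation, and all are labeled in the output.

* **Delta method** (default): $\operatorname{Var}(R) = R^2\,(v_{11}/\beta_1^2
  + v_{22}/\beta_2^2 - 2 v_{12}/(\beta_1 \beta_2))$ with symmetric Wald
  limits. It matches symmetric printed intervals well when the denominator is
  precisely estimated. It is refused when $|\beta_g|/\mathrm{SE} < 0.1$ and a
  warning is issued below 2, because ratio intervals are unreliable with a
  weak denominator.
* **Fieller**: the exact confidence set from the roots of
  $(\beta_1 - g\beta_2)^2 = z^2 (v_{11} - 2 g v_{12} + g^2 v_{22})$; with an
  imprecise denominator the set can be unbounded or exclusive, which is
  flagged rather than truncated.
* **Parametric bootstrap**: percentile interval of the ratio over
  multivariate-normal draws from $(\hat\beta, \hat\Sigma)$.

## PRS construction and percentile conventions

Scores are weighted sums of effect-allele dosages over a scoring panel; unit
weights (the default, a risk-allele count) match the convention of summing
risk alleles over a fixed panel of 140 CRC-associated variants. Dosage
matrices may be TSV or VCF (the `DS` field, with `GT` fallback); columns
counted on the panel's other allele are flipped (`2 - dosage`), and any
other allele configuration is an error — strand-ambiguity resolution beyond
exact/flip matching is out of scope.

Percentiles use the **mid-rank** empirical definition against a reference
group, `100 * (#{ref < x} + 0.5 #{ref = x}) / n`. The definition was an open
choice; mid-ranks were picked because ties are handled symmetrically and the
transform is invariant under any strictly increasing rescaling of the scores,
which propagates to tertiles and to every downstream GRE. The reference group
is the **controls** by default, consistent with defining PRS tertiles among
controls (full-sample referencing is available via `add_prs(reference =
"all")`). Tertile cutpoints are type-1 (inverse-ECDF) quantiles at 1/3 and
2/3 of the reference, which splits controls as evenly as ties permit.

Lagged BMI is derived from the weight reported for the decade roughly ten
years before the index age — reference decade `10 * floor((age - 5) / 10)`,
which reproduces the stated bands (ages 55–64 use weight at 50, ages 65–74
weight at 60) and generalizes them outside the stated range. Categories are
half-open: normal `< 25` (underweight merged, as it is too rare to stand
alone), overweight `[25, 30)`, obesity `>= 30`. A missing required decade
weight flags the record for downstream exclusion instead of guessing.

## The synthetic cohort generator

The generator emulates a large German population-based case-control study of
CRC, and its defaults *are* that study's conditions: 5053 cases, 4116
controls, a 140-variant unit-weight PRS, BMI category prevalences 38.4 /
45.8 / 15.8% (the control distribution), generative odds ratios 1.31
(overweight) and 1.71 (obesity), a PRS effect of OR 1.14 per 10 percentiles,
and ten independent binary/categorical covariates with control-group
marginal prevalences and plausible effect sizes (screening colonoscopy
strongly protective at log-odds −1.2; lifestyle covariates between ±0.05 and
0.45). Where the source material gives no value, a single realistic choice
was made and kept: allele frequencies Uniform(0.1, 0.9), age
truncated-normal (69, 9) on [30, 95], 61% male, BMI values drawn from
truncated normals within each category, and a source population of 200 000
(the smallest round size comfortably above the 20× oversampling floor the
generator enforces).

Mechanically, the generator simulates the full source population (genotypes
Binomial(2, p) in linkage equilibrium, covariates independent), computes each
person's within-population PRS percentile, assigns disease by the logistic
model above with the intercept calibrated by bisection so the expected number
of affected individuals is 1.5 × the requested cases, and then samples cases
and controls without replacement. This population-then-sample scheme was
chosen over direct retrospective sampling because it is transparently
verifiable: a logistic fit on the full population is an oracle for every
case-control fit (outcome-dependent sampling preserves all slopes except the
intercept). Parameterizing the PRS effect directly on the percentile scale
makes the generative GRE available in closed form,
$\beta_e / \beta_{\text{prs,pct}}$, so recovery experiments have an exact
truth (40.9 percentiles for obesity under the defaults).

Optional `subtype_effects` switch the disease model to a three-level
multinomial logit (control / stage I–III / stage IV) with shared PRS and
covariate effects but subtype-specific BMI effects and intercepts
(coordinate bisection calibrates both). Sampling each subtype's cases
against the common controls preserves each equation's slopes, which is what
makes the subtype-heterogeneity test verifiable against ground truth.

One master seed spawns an independent stream per stage (panel, genotypes,
covariates, disease, sampling, tumor labels), so runs are byte-reproducible
and changing one stage's draws does not perturb the others.

What the generator does **not** emulate — and what passing tests therefore do
not establish about real data: linkage disequilibrium and imputation
uncertainty in the genotypes, correlation among covariates (hooks exist but
the default is independence, since no joint distribution is reported),
age/sex frequency matching beyond shared marginal distributions, recall bias
in self-reported weight, and residual confounding.

## Modelling conventions

* Unconditional logistic regression with age/sex adjustment emulates the
  matched design; conditional logistic regression for matched sets is out of
  scope.
* Complete-case handling is per model (the union of fields referenced by
  that model), with the excluded count reported, so
  `n_used + n_excluded = rows`.
* Subtype fits use the full control group against each case subset, so the
  control column is identical across subtypes — which is also why the
  default heterogeneity test is a polytomous (multinomial) regression with a
  Wald equality contrast across subtype equations: it accounts for the
  covariance induced by the shared controls. The naive independent-z variant
  (`heterogeneity_naive`) is provided for comparison and labeled
  approximate.
* Wald tests are used throughout, matching standard epidemiologic reporting.
* Fits are flagged as separated when a non-intercept coefficient diverges
  beyond |15| log-odds; the error names the term rather than returning a
  meaningless estimate.
* Convergence uses a tight IRLS tolerance (1e-10 relative deviance change);
  the 2×2 closed-form oracle is reproduced to 1e-8.
* The PRS enters the fully adjusted model as a continuous percentile (per 10
  percentiles) by default because the GRE denominator needs that scale; a
  raw-score coding is possible by passing any other column name.

## Problem sizes used in validation

The test suite exercises the generator at reduced sizes (400–1500 cases,
populations of 15 000–54 000, 10–25 variants) for unit and property checks,
and at the full study scale for the headline recovery experiment: 200
replicate cohorts of 5053 cases / 4116 controls with the 140-variant panel,
each analyzed by the complete pipeline (PRS from dosages, control-referenced
percentiles, fully adjusted model, delta-method GRE). Monte-Carlo
calibration experiments use 1000 null interaction simulations at n = 4000
and 500 coverage replicates at n = 5000. These sizes give Monte-Carlo
standard errors comfortably below the tolerances being asserted (for the
recovery mean, about 0.4 percentiles).

## Known limitations

* The GRE is interpretable only against the variance explained by the panel
  in use; with a 140-variant panel it quantifies *currently explained*
  genetic risk, not total heritability.
* Delta-method intervals degrade when the PRS coefficient is weak; the
  package warns and, below a signal-to-noise of 0.1, refuses (Fieller
  remains available and flags unbounded sets).
* The simulator's independence assumptions (variants, covariates) make
  standard errors slightly optimistic relative to real genotype data with
  LD.
* Percentile referencing against sampled controls introduces a small
  finite-sample distortion relative to the population percentile scale; at
  the default prevalence (≈4% of the source population affected) the effect
  on recovered GREs is well below the Monte-Carlo noise, as the recovery
  experiment shows.
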