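#' Default covariate specifications for the synthetic cohort
#'
#' Ten lifestyle/medical covariates mirroring the fully adjusted model's
#' covariate set. Marginal prevalences follow the control-group distribution
#' of a large colorectal-cancer case-control study; log-odds effects are
#' plausible epidemiologic magnitudes (protective screening history, modest
#' lifestyle effects). Covariates are generated independently of each other,
#' of BMI, and of the PRS.
#'
#' @return list of covariate specs; each spec is a list with `name`,
#'   `type` (`"binary"`, `"categorical"`, `"continuous"`), distribution
#'   parameters (`prob`, or `levels` + `probs`, or `mean` + `sd`), and `beta`
#'   (scalar for binary/continuous, per-level vector with reference 0 for
#'   categorical).
#' @export
default_covariate_specs <- function() {
  list(
    list(name = "education", type = "categorical",
         levels = c("<9y", "9-10y", ">10y"),
         probs = c(0.552, 0.211, 0.237), beta = c(0, -0.15, -0.30)),
    list(name = "smoking", type = "categorical",
         levels = c("never", "former", "current"),
         probs = c(0.506, 0.383, 0.111), beta = c(0, 0.10, 0.35)),
    list(name = "alcohol_above_limit", type = "binary", prob = 0.227,
         beta = 0.20),
    list(name = "physical_activity", type = "categorical",
         levels = c("q1", "q2", "q3", "q4"),
         probs = c(0.25, 0.25, 0.25, 0.25), beta = c(0, 0.05, 0.08, 0.12)),
    list(name = "meat_intake", type = "categorical",
         levels = c("le1_wk", "multi_wk", "daily", "gt1_day"),
         probs = c(0.117, 0.605, 0.247, 0.031), beta = c(0, 0.20, 0.30, 0.45)),
    list(name = "nsaid_use", type = "binary", prob = 0.380, beta = -0.35),
    list(name = "statin_use", type = "binary", prob = 0.224, beta = -0.25),
    list(name = "diabetes", type = "binary", prob = 0.134, beta = 0.30),
    list(name = "family_history_crc", type = "binary", prob = 0.110,
         beta = 0.30),
    list(name = "colonoscopy_history", type = "binary", prob = 0.603,
         beta = -1.2)
  )
}

#' Configuration for the retrospective case-control simulator
#'
#' The defaults reproduce the target study conditions: 5053 cases and 4116
#' controls, a 140-variant unit-weight PRS, three BMI categories with
#' control-group prevalences 38.4/45.8/15.8%, generative odds ratios 1.31
#' (overweight) and 1.71 (obesity) versus normal weight, a PRS effect of
#' OR 1.14 per 10 percentiles, and ten independent covariates
#' ([default_covariate_specs()]).
#'
#' The disease model is logistic on the linear predictor
#' `baseline + beta_prs_percentile * percentile + BMI-category effect +
#' covariate effects`, where `percentile` is the within-population mid-rank
#' percentile of the risk-allele count. Parameterizing the PRS effect on the
#' percentile scale makes the generative genetic risk equivalent of an
#' exposure available in closed form as `beta_exposure / beta_prs_percentile`.
#'
#' @param n_cases,n_controls numbers of cases and controls to sample.
#' @param n_variants number of PRS variants.
#' @param allele_freqs optional explicit effect-allele frequencies in (0,1);
#'   when `NULL`, frequencies are drawn uniformly from `allele_freq_range`.
#' @param allele_freq_range length-2 range in (0,1) for sampled frequencies.
#' @param beta_prs_percentile log-odds per 1 PRS percentile.
#' @param beta_overweight,beta_obesity log-odds versus normal weight.
#' @param bmi_category_probs probabilities of normal/overweight/obesity,
#'   summing to 1.
#' @param covariate_specs list of covariate specs (see
#'   [default_covariate_specs()]); may be `list()` for none.
#' @param baseline_logit numeric intercept, or `"auto"` (default) to calibrate
#'   by bisection so the expected number of affected individuals equals
#'   `case_margin * n_cases`.
#' @param pop_size size of the source population; must be at least
#'   `20 * (n_cases + n_controls)`.
#' @param seed master seed; all stages derive their own streams from it.
#' @param age_mean,age_sd,age_range age distribution (years, truncated normal).
#' @param p_male probability of male sex.
#' @param beta_age,beta_male log-odds effects of age (per year, centered) and
#'   male sex; zero by default (age/sex emulate matching factors).
#' @param site_probs colon/rectum split among cases.
#' @param stage_probs stage I-III / IV split among cases (ignored when
#'   `subtype_effects` is given).
#' @param subtype_effects optional list enabling subtype-specific BMI effects
#'   via a 3-level multinomial generative model: components `stage13` and
#'   `stage4` (each a named vector `c(overweight=, obesity=)` of log-odds) and
#'   `case_split` (named fractions of cases that are stage I-III / stage IV).
#' @param case_margin calibration margin: expected affected count is
#'   `case_margin * n_cases` (per subtype when `subtype_effects` is set).
#' @param keep_population if `TRUE`, the full source population (phenotypes,
#'   percentile, outcome) is returned for oracle fits; off by default.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_cases = 5053L, n_controls = 4116L,
    n_variants = 140L, allele_freqs = NULL, allele_freq_range = c(0.1, 0.9),
    beta_prs_percentile = log(1.14) / 10,
    beta_overweight = log(1.31), beta_obesity = log(1.71),
    bmi_category_probs = c(normal = 0.384, overweight = 0.458,
                           obesity = 0.158),
    covariate_specs = default_covariate_specs(),
    baseline_logit = "auto", pop_size = 200000L, seed = 1L,
    age_mean = 69, age_sd = 9, age_range = c(30, 95), p_male = 0.61,
    beta_age = 0, beta_male = 0,
    site_probs = c(colon = 0.61, rectum = 0.39),
    stage_probs = c(`I-III` = 0.857, IV = 0.143),
    subtype_effects = NULL, case_margin = 1.5, keep_population = FALSE) {
  stopifnot(n_cases > 0, n_controls > 0, n_variants > 0, pop_size > 0)
  if (pop_size < 20 * (n_cases + n_controls))
    stop("pop_size must be at least 20 * (n_cases + n_controls)",
         call. = FALSE)
  if (!is.null(allele_freqs)) {
    if (length(allele_freqs) != n_variants)
      stop("allele_freqs must have length n_variants", call. = FALSE)
    if (any(allele_freqs <= 0 | allele_freqs >= 1))
      stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  } else if (any(allele_freq_range <= 0) || any(allele_freq_range >= 1) ||
             diff(allele_freq_range) < 0) {
    stop("allele_freq_range must be an increasing range within (0, 1)",
         call. = FALSE)
  }
  if (length(bmi_category_probs) != 3L ||
      abs(sum(bmi_category_probs) - 1) > 1e-9 || any(bmi_category_probs <= 0))
    stop("bmi_category_probs must be 3 positive probabilities summing to 1",
         call. = FALSE)
  if (!identical(baseline_logit, "auto") && !is.numeric(baseline_logit))
    stop("baseline_logit must be numeric or \"auto\"", call. = FALSE)
  if (!is.null(subtype_effects)) {
    need <- c("stage13", "stage4", "case_split")
    if (!all(need %in% names(subtype_effects)))
      stop("subtype_effects needs components stage13, stage4, case_split",
           call. = FALSE)
    if (abs(sum(subtype_effects$case_split) - 1) > 1e-9)
      stop("subtype_effects$case_split must sum to 1", call. = FALSE)
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_variants = as.integer(n_variants), allele_freqs = allele_freqs,
    allele_freq_range = allele_freq_range,
    beta_prs_percentile = beta_prs_percentile,
    beta_overweight = beta_overweight, beta_obesity = beta_obesity,
    bmi_category_probs = bmi_category_probs,
    covariate_specs = covariate_specs, baseline_logit = baseline_logit,
    pop_size = as.integer(pop_size), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    p_male = p_male, beta_age = beta_age, beta_male = beta_male,
    site_probs = site_probs, stage_probs = stage_probs,
    subtype_effects = subtype_effects, case_margin = case_margin,
    keep_population = keep_population), class = "sim_config")
}

#' Simulate hard genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each dosage is an independent Binomial(2, p_j) draw; variants are in
#' linkage equilibrium by construction.
#'
#' @param freqs effect-allele frequencies, all strictly in (0, 1).
#' @param n number of individuals (> 0).
#' @param seed optional seed for reproducibility.
#' @param variant_ids optional column names; defaults to `var0001`, ...
#' @return integer matrix `n x length(freqs)` with values in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(freqs, n, seed = NULL, variant_ids = NULL) {
  if (length(n) != 1L || !is.finite(n) || n <= 0)
    stop("n must be a single positive count", call. = FALSE)
  if (!length(freqs) || any(freqs <= 0 | freqs >= 1))
    stop("all allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  J <- length(freqs)
  G <- matrix(0L, n, J)
  for (j in seq_len(J)) G[, j] <- stats::rbinom(n, 2L, freqs[j])
  colnames(G) <- variant_ids %||% sprintf("var%04d", seq_len(J))
  G
}

## expected affected count as a function of the intercept, solved by bisection
calibrate_intercept <- function(lp, target, lower = -60, upper = 30,
                                max_iter = 200L) {
  f <- function(b) sum(stats::plogis(b + lp)) - target
  if (f(upper) < 0)
    stop("calibration failure: target affected count unreachable", call. = FALSE)
  lo <- lower; hi <- upper
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

## joint calibration of the two subtype intercepts (coordinate bisection);
## expected count of subtype j under the 3-level multinomial logit
calibrate_subtype_intercepts <- function(eta13, eta4, target13, target4) {
  b13 <- b4 <- -10
  exp13 <- function(b) exp(pmin(b + eta13, 30))
  exp4 <- function(b) exp(pmin(b + eta4, 30))
  for (round in 1:8) {
    f13 <- function(b) sum(exp13(b) / (1 + exp13(b) + exp4(b4))) - target13
    b13 <- bisect_root(f13, -60, 30)
    f4 <- function(b) sum(exp4(b) / (1 + exp13(b13) + exp4(b))) - target4
    b4 <- bisect_root(f4, -60, 30)
  }
  c(stage13 = b13, stage4 = b4)
}

bisect_root <- function(f, lo, hi, max_iter = 200L) {
  if (f(hi) < 0)
    stop("calibration failure: target affected count unreachable", call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

draw_covariates <- function(specs, n) {
  out <- list()
  for (sp in specs) {
    out[[sp$name]] <- switch(sp$type,
      binary = stats::rbinom(n, 1L, sp$prob),
      categorical = factor(sample(sp$levels, n, replace = TRUE,
                                  prob = sp$probs), levels = sp$levels),
      continuous = stats::rnorm(n, sp$mean, sp$sd),
      stop("unknown covariate type: ", sp$type, call. = FALSE))
  }
  as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)
}

covariate_linear_predictor <- function(specs, covs) {
  lp <- numeric(nrow(covs))
  for (sp in specs) {
    x <- covs[[sp$name]]
    lp <- lp + switch(sp$type,
      binary = sp$beta * x,
      categorical = sp$beta[match(as.character(x), sp$levels)],
      continuous = sp$beta * (x - sp$mean))
  }
  lp
}

draw_bmi_values <- function(categories) {
  n <- length(categories)
  bmi <- numeric(n)
  i <- categories == "normal"
  bmi[i] <- rtruncnorm(sum(i), 22.8, 1.8, 17, 25)
  i <- categories == "overweight"
  bmi[i] <- rtruncnorm(sum(i), 27.1, 1.4, 25, 30)
  i <- categories == "obesity"
  bmi[i] <- rtruncnorm(sum(i), 32.7, 2.6, 30, 55)
  bmi
}

#' Simulate a retrospective case-control cohort with known effect sizes
#'
#' Generates a source population of `pop_size` individuals (genotypes under
#' Hardy-Weinberg equilibrium, independent covariates, BMI categories),
#' computes the PRS as the weighted risk-allele sum and its within-population
#' mid-rank percentile, assigns disease by the logistic (or, with
#' `subtype_effects`, 3-level multinomial-logit) generative model, and samples
#' `n_cases` affected and `n_controls` unaffected individuals without
#' replacement. Because retrospective sampling preserves exposure odds ratios
#' (intercept aside), every downstream fitted log-OR has the generative value
#' as its ground truth.
#'
#' @param config a [simulation_config()].
#' @return list with components `cohort` (phenotype `data.frame`: one row per
#'   sampled participant with status, age, sex, height, bmi, bmi_category,
#'   covariates, site, stage), `genotypes` (dosage matrix for the sampled
#'   participants, rows named by `participant_id`), `weights` (the unit-weight
#'   scoring table), and, when `config$keep_population` is `TRUE`,
#'   `population` (the full source population with outcome and generative
#'   percentile, for oracle fits). The generative truth (betas, calibrated
#'   intercept, allele frequencies) is attached as attribute `"generative"`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be created by simulation_config()", call. = FALSE)
  s <- spawn_seeds(config$seed, 6L)
  N <- config$pop_size
  J <- config$n_variants

  ## stage 1: scoring panel + genotypes
  set.seed(s[1])
  freqs <- config$allele_freqs %||%
    stats::runif(J, config$allele_freq_range[1], config$allele_freq_range[2])
  pairs <- t(vapply(seq_len(J),
                    function(i) sample(c("A", "C", "G", "T"), 2L),
                    character(2)))
  weights <- variant_weight_table(sprintf("var%04d", seq_len(J)),
                                  pairs[, 1], pairs[, 2], 1)
  G <- simulate_genotypes(freqs, N, seed = s[2],
                          variant_ids = weights$variant_id)
  score <- rowSums(G)
  pct <- percentile_transform(score, score)

  ## stage 2: phenotypes and covariates
  set.seed(s[3])
  age <- rtruncnorm(N, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  sex <- factor(ifelse(stats::runif(N) < config$p_male, "male", "female"),
                levels = c("female", "male"))
  height <- ifelse(sex == "male", stats::rnorm(N, 1.76, 0.07),
                   stats::rnorm(N, 1.64, 0.065))
  height <- pmin(pmax(height, 1.40), 2.10)
  bmi_cat <- factor(sample(c("normal", "overweight", "obesity"), N,
                           replace = TRUE, prob = config$bmi_category_probs),
                    levels = c("normal", "overweight", "obesity"))
  bmi <- draw_bmi_values(bmi_cat)
  covs <- draw_covariates(config$covariate_specs, N)
  if (!nrow(covs) && length(config$covariate_specs) == 0L)
    covs <- data.frame(row.names = seq_len(N))

  lp_common <- config$beta_prs_percentile * pct +
    config$beta_age * (age - config$age_mean) +
    config$beta_male * (sex == "male")
  if (length(config$covariate_specs))
    lp_common <- lp_common +
      covariate_linear_predictor(config$covariate_specs, covs)
  bmi_effect <- c(normal = 0, overweight = config$beta_overweight,
                  obesity = config$beta_obesity)

  ## stage 3: disease assignment
  set.seed(s[4])
  if (is.null(config$subtype_effects)) {
    lp <- lp_common + bmi_effect[as.character(bmi_cat)]
    b0 <- if (identical(config$baseline_logit, "auto"))
      calibrate_intercept(lp, config$case_margin * config$n_cases)
    else config$baseline_logit
    y <- stats::rbinom(N, 1L, stats::plogis(b0 + lp)) == 1L
    subtype <- NULL
  } else {
    se <- config$subtype_effects
    eff13 <- c(normal = 0, se$stage13)
    eff4 <- c(normal = 0, se$stage4)
    eta13 <- lp_common + eff13[as.character(bmi_cat)]
    eta4 <- lp_common + eff4[as.character(bmi_cat)]
    n13 <- round(config$n_cases * se$case_split[["stage13"]])
    n4 <- config$n_cases - n13
    b0 <- calibrate_subtype_intercepts(eta13, eta4,
                                       config$case_margin * n13,
                                       config$case_margin * n4)
    e13 <- exp(pmin(b0[["stage13"]] + eta13, 30))
    e4 <- exp(pmin(b0[["stage4"]] + eta4, 30))
    den <- 1 + e13 + e4
    u <- stats::runif(N)
    subtype <- ifelse(u < e13 / den, "stage13",
                      ifelse(u < (e13 + e4) / den, "stage4", "none"))
    y <- subtype != "none"
  }

  ## stage 4: retrospective sampling
  set.seed(s[5])
  if (is.null(subtype)) {
    aff <- which(y)
    if (length(aff) < config$n_cases)
      stop("insufficient affected individuals in the population pool; ",
           "increase pop_size", call. = FALSE)
    case_idx <- sample(aff, config$n_cases)
  } else {
    p13 <- which(subtype == "stage13"); p4 <- which(subtype == "stage4")
    se <- config$subtype_effects
    n13 <- round(config$n_cases * se$case_split[["stage13"]])
    n4 <- config$n_cases - n13
    if (length(p13) < n13 || length(p4) < n4)
      stop("insufficient affected individuals in a subtype pool; ",
           "increase pop_size", call. = FALSE)
    case_idx <- c(sample(p13, n13), sample(p4, n4))
  }
  unaff <- which(!y)
  if (length(unaff) < config$n_controls)
    stop("insufficient unaffected individuals in the population pool; ",
         "increase pop_size", call. = FALSE)
  ctrl_idx <- sample(unaff, config$n_controls)
  sel <- c(case_idx, ctrl_idx)
  status <- rep(c("case", "control"), c(length(case_idx), length(ctrl_idx)))

  ## stage 5: tumor site/stage labels for cases
  set.seed(s[6])
  n_case <- length(case_idx)
  site <- rep("none", length(sel))
  site[seq_len(n_case)] <- sample(names(config$site_probs), n_case,
                                  replace = TRUE, prob = config$site_probs)
  stage <- rep("none", length(sel))
  if (is.null(subtype)) {
    stage[seq_len(n_case)] <- sample(names(config$stage_probs), n_case,
                                     replace = TRUE,
                                     prob = config$stage_probs)
  } else {
    stage[seq_len(n_case)] <- ifelse(subtype[case_idx] == "stage13",
                                     "I-III", "IV")
  }

  ids <- sprintf("P%06d", seq_along(sel))
  cohort <- data.frame(participant_id = ids, status = status,
                       age = age[sel], sex = sex[sel], height = height[sel],
                       bmi = bmi[sel], bmi_category = bmi_cat[sel],
                       site = site, stage = stage,
                       stringsAsFactors = FALSE)
  if (ncol(covs)) cohort <- cbind(cohort, covs[sel, , drop = FALSE])
  rownames(cohort) <- NULL
  Gs <- G[sel, , drop = FALSE]
  rownames(Gs) <- ids

  out <- list(cohort = cohort, genotypes = Gs, weights = weights)
  if (isTRUE(config$keep_population)) {
    pop <- data.frame(y = y, prs_percentile = pct, bmi_category = bmi_cat,
                      age = age, sex = sex, stringsAsFactors = FALSE)
    if (ncol(covs)) pop <- cbind(pop, covs)
    out$population <- pop
  }
  attr(out, "generative") <- list(
    baseline_logit = b0, beta_prs_percentile = config$beta_prs_percentile,
    beta_overweight = config$beta_overweight,
    beta_obesity = config$beta_obesity, allele_freqs = freqs,
    true_gre_overweight = config$beta_overweight / config$beta_prs_percentile,
    true_gre_obesity = config$beta_obesity / config$beta_prs_percentile)
  out
}
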