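#' Genetic risk equivalent of an exposure
#'
#' The genetic risk equivalent (GRE) of an exposure level is the difference
#' in PRS percentiles whose log-odds association equals the exposure's:
#' `GRE = beta_exposure / (beta_prs * prs_units_per_percentile)`, where
#' `beta_prs` is the fitted PRS coefficient on whatever scale the model coded
#' it and `prs_units_per_percentile` converts that scale to percentiles
#' (0.1 when the model codes the PRS per 10 percentiles, 1 for per-percentile
#' coding). The GRE is always reported on the percentile scale, so recoding
#' the PRS term together with the matching conversion factor leaves the
#' estimate and its confidence limits unchanged.
#'
#' Three confidence-interval constructions are available for the coefficient
#' ratio:
#' \describe{
#'   \item{delta}{first-order Taylor variance
#'     `Var(R) = R^2 (v11/b1^2 + v22/b2^2 - 2 v12/(b1 b2))`, symmetric Wald
#'     limits. Refused when the PRS coefficient is indistinguishable from 0
#'     (`|b2|/se2 < 0.1`); a warning is issued below `|b2|/se2 < 2`.}
#'   \item{fieller}{roots of `(b1 - g b2)^2 = z^2 (v11 - 2 g v12 + g^2 v22)`;
#'     when the denominator is imprecise the confidence set is unbounded or
#'     exclusive and is flagged (`unbounded = TRUE`, infinite limits, the
#'     finite roots kept in attribute `"roots"`).}
#'   \item{bootstrap}{parametric bootstrap: ratio over multivariate-normal
#'     draws from the estimated coefficients and covariance, percentile CI.}
#' }
#'
#' @param fit a `gre_fit` (anything with `coef` and `vcov`).
#' @param exposure_term,prs_term coefficient names of the exposure indicator
#'   and the PRS term.
#' @param prs_units_per_percentile positive conversion factor from the PRS
#'   model coding to percentiles (default 0.1, per-10-percentile coding).
#' @param method `"delta"` (default), `"fieller"`, or `"bootstrap"`.
#' @param level confidence level.
#' @param n_boot bootstrap draws (method `"bootstrap"`).
#' @param boot_seed optional seed for the bootstrap draws.
#' @return object of class `gre_estimate`: list with `gre`, `se` (delta only),
#'   `ci_low`, `ci_high`, `method`, `level`, `exposure_term`, `prs_term`,
#'   `denominator_scale`, `unbounded`, `beta_exposure`, `beta_prs`.
#' @export
compute_gre <- function(fit, exposure_term, prs_term,
                        prs_units_per_percentile = 0.1,
                        method = c("delta", "fieller", "bootstrap"),
                        level = 0.95, n_boot = 10000L, boot_seed = NULL) {
  method <- match.arg(method)
  u <- prs_units_per_percentile
  if (!is.numeric(u) || length(u) != 1L || u <= 0)
    stop("prs_units_per_percentile must be a single positive number",
         call. = FALSE)
  b <- fit$coef
  V <- as.matrix(fit$vcov)
  for (t in c(exposure_term, prs_term))
    if (!t %in% names(b))
      stop("term not found in fit: ", t, call. = FALSE)
  b1 <- b[[exposure_term]]; b2 <- b[[prs_term]]
  v11 <- V[exposure_term, exposure_term]
  v22 <- V[prs_term, prs_term]
  v12 <- V[exposure_term, prs_term]
  z <- stats::qnorm(1 - (1 - level) / 2)
  snr <- abs(b2) / sqrt(v22)
  if (snr < 2)
    warning("PRS coefficient weakly identified (|z| < 2); ratio confidence ",
            "intervals are unreliable", call. = FALSE)
  R <- b1 / (b2 * u)
  se <- NA_real_
  unbounded <- FALSE
  roots <- NULL
  if (method == "delta") {
    if (snr < 0.1)
      stop("PRS denominator indistinguishable from zero; delta method ",
           "refused (consider method = \"fieller\")", call. = FALSE)
    grad <- c(1 / (b2 * u), -b1 / (b2^2 * u))
    Vsub <- matrix(c(v11, v12, v12, v22), 2)
    se <- sqrt(drop(t(grad) %*% Vsub %*% grad))
    ci <- c(R - z * se, R + z * se)
  } else if (method == "fieller") {
    aq <- b2^2 - z^2 * v22
    bq <- b1 * b2 - z^2 * v12
    cq <- b1^2 - z^2 * v11
    disc <- bq^2 - aq * cq
    if (aq > 0 && disc >= 0) {
      r <- sort(c((bq - sqrt(disc)) / aq, (bq + sqrt(disc)) / aq)) / u
      ci <- r
    } else {
      unbounded <- TRUE
      ci <- c(-Inf, Inf)
      if (disc >= 0)  # exclusive set: complement of the finite interval
        roots <- sort(c((bq - sqrt(disc)) / aq, (bq + sqrt(disc)) / aq)) / u
    }
  } else {
    if (!is.null(boot_seed)) set.seed(boot_seed)
    draws <- MASS::mvrnorm(n_boot, c(b1, b2),
                           matrix(c(v11, v12, v12, v22), 2))
    rb <- draws[, 1] / (draws[, 2] * u)
    ci <- unname(stats::quantile(rb, c((1 - level) / 2, 1 - (1 - level) / 2)))
    se <- stats::sd(rb)
  }
  out <- structure(list(gre = unname(R), se = se, ci_low = ci[1],
                        ci_high = ci[2], method = method, level = level,
                        exposure_term = exposure_term, prs_term = prs_term,
                        denominator_scale = u, unbounded = unbounded,
                        beta_exposure = b1, beta_prs = b2),
                   class = "gre_estimate")
  if (!is.null(roots)) attr(out, "roots") <- roots
  out
}

#' @export
print.gre_estimate <- function(x, ...) {
  cat(sprintf("GRE (%s) for %s: %.1f percentiles (%.0f%% CI %.1f to %.1f)%s\n",
              x$method, x$exposure_term, x$gre, 100 * x$level, x$ci_low,
              x$ci_high,
              if (x$unbounded) " [unbounded confidence set]" else ""))
  invisible(x)
}

#' Rescale a GRE to another exposure level sharing the PRS denominator
#'
#' Within one fitted model all exposure levels share the PRS coefficient in
#' the GRE denominator, so GREs are proportional to log odds ratios:
#' `GRE_a = GRE_b * log(OR_a) / log(OR_b)`. This identity lets one level's
#' GRE be recomputed exactly from another level's GRE and the two odds
#' ratios.
#'
#' @param gre_ref GRE of the reference exposure level (percentiles).
#' @param or_target,or_ref odds ratios of the target and reference levels.
#' @return GRE of the target level (percentiles).
#' @export
gre_rescale <- function(gre_ref, or_target, or_ref) {
  if (any(or_target <= 0) || any(or_ref <= 0) || any(or_ref == 1))
    stop("odds ratios must be positive and the reference OR must not be 1",
         call. = FALSE)
  gre_ref * log(or_target) / log(or_ref)
}

#' Genetic risk equivalents by exposure level and outcome
#'
#' Fits the fully adjusted model (exposure categories + PRS term +
#' adjustment covariates) for each requested outcome and reports, per
#' exposure level, case/control counts, the adjusted OR with Wald CI, and
#' the GRE with its CI. Within one outcome all levels share the PRS
#' denominator, so GRE ratios equal log-OR ratios exactly.
#'
#' @inheritParams fit_logistic
#' @param outcomes character vector of outcomes to model.
#' @param exposure_var categorical exposure column (default `bmi_category`).
#' @param prs_term PRS column used as the GRE denominator (default
#'   `prs_pct10`, percentile / 10).
#' @param prs_units_per_percentile conversion of `prs_term` to percentiles.
#' @param ci_method CI method passed to [compute_gre()].
#' @param level confidence level.
#' @return `data.frame` with columns `outcome`, `bmi_level`, `n_cases`,
#'   `n_controls`, `or`, `or_low`, `or_high`, `gre`, `gre_low`, `gre_high`,
#'   `method`; reference rows carry OR 1 / GRE 0 and NA limits.
#' @export
gre_table <- function(cohort, outcomes = c("overall", "colon", "rectum",
                                           "stage13", "stage4"),
                      exposure_var = "bmi_category", prs_term = "prs_pct10",
                      adjustment = character(),
                      prs_units_per_percentile = 0.1, ci_method = "delta",
                      level = 0.95) {
  rows <- list()
  for (oc in outcomes) {
    fit <- fit_logistic(cohort, exposure = exposure_var,
                        adjustment = unique(c(adjustment, prs_term)),
                        outcome = oc)
    cnt <- fit$exposure_counts
    lv <- rownames(cnt)
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = oc, bmi_level = lv[1], n_cases = cnt[1, "case"],
      n_controls = cnt[1, "control"], or = 1, or_low = NA_real_,
      or_high = NA_real_, gre = 0, gre_low = NA_real_, gre_high = NA_real_,
      method = ci_method, stringsAsFactors = FALSE)
    for (l in lv[-1]) {
      term <- paste0(exposure_var, l)
      ot <- or_table(fit, term, level = level)
      g <- compute_gre(fit, term, prs_term,
                       prs_units_per_percentile = prs_units_per_percentile,
                       method = ci_method, level = level)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, bmi_level = l, n_cases = cnt[l, "case"],
        n_controls = cnt[l, "control"], or = ot$or, or_low = ot$or_low,
        or_high = ot$or_high, gre = g$gre, gre_low = g$ci_low,
        gre_high = g$ci_high, method = ci_method, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate simulation experiment recovering generative GREs
#'
#' Repeats the full analysis pipeline on independently seeded synthetic
#' cohorts: simulate a case-control data set, recompute the PRS from the
#' dosage matrix, derive control-referenced percentiles, fit the fully
#' adjusted logistic model (BMI categories + PRS per 10 percentiles +
#' covariates + age + sex), and compute the delta-method GRE for overweight
#' and obesity. Returns per-replicate estimates plus CI-coverage indicators
#' against the generative ratios.
#'
#' @param n_replicates number of replicate cohorts.
#' @param config a [simulation_config()]; its betas define the ground truth.
#' @param seed master seed spawning one stream per replicate.
#' @param ci_method CI method for the per-replicate intervals.
#' @return `data.frame` (class `gre_recovery`) with one row per replicate:
#'   `gre_overweight`, `gre_obesity`, CI limits, and coverage flags; the
#'   generative GREs are attached as attribute `"truth"`.
#' @export
replicate_gre_recovery <- function(n_replicates = 200L,
                                   config = simulation_config(),
                                   seed = 1L, ci_method = "delta") {
  seeds <- spawn_seeds(seed, n_replicates)
  adj <- c("age", "sex",
           vapply(config$covariate_specs, `[[`, "", "name"))
  truth <- c(overweight = config$beta_overweight / config$beta_prs_percentile,
             obesity = config$beta_obesity / config$beta_prs_percentile)
  res <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seeds[i]
    sim <- simulate_cohort(cfg)
    coh <- add_prs(sim$cohort, sim$genotypes, sim$weights)
    rm(sim)
    fit <- fit_logistic(coh, exposure = "bmi_category",
                        adjustment = c(adj, "prs_pct10"))
    gow <- compute_gre(fit, "bmi_categoryoverweight", "prs_pct10",
                       method = ci_method)
    gob <- compute_gre(fit, "bmi_categoryobesity", "prs_pct10",
                       method = ci_method)
    res[[i]] <- data.frame(
      replicate = i, seed = seeds[i],
      gre_overweight = gow$gre, ow_low = gow$ci_low, ow_high = gow$ci_high,
      gre_obesity = gob$gre, ob_low = gob$ci_low, ob_high = gob$ci_high,
      covers_overweight = gow$ci_low <= truth[["overweight"]] &
        truth[["overweight"]] <= gow$ci_high,
      covers_obesity = gob$ci_low <= truth[["obesity"]] &
        truth[["obesity"]] <= gob$ci_high)
    if (i %% 25L == 0L) gc(FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  class(out) <- c("gre_recovery", "data.frame")
  out
}

#' @export
summary.gre_recovery <- function(object, ...) {
  truth <- attr(object, "truth")
  data.frame(
    level = c("overweight", "obesity"),
    true_gre = unname(truth),
    mean_gre = c(mean(object$gre_overweight), mean(object$gre_obesity)),
    sd_gre = c(stats::sd(object$gre_overweight),
               stats::sd(object$gre_obesity)),
    ci_coverage = c(mean(object$covers_overweight),
                    mean(object$covers_obesity)),
    n_replicates = nrow(object), stringsAsFactors = FALSE)
}
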