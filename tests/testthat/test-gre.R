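make_ratio_fit <- function(b1, b2, v11, v22, v12 = 0) {
  fake_fit(c(exposure = b1, prs = b2),
           matrix(c(v11, v12, v12, v22), 2,
                  dimnames = list(c("exposure", "prs"),
                                  c("exposure", "prs"))))
}

test_that("the GRE is the coefficient ratio on the percentile scale", {
  # overweight log-OR over a shared per-percentile PRS coefficient chosen so
  # that the obesity GRE is 40.9: the overweight GRE must come out 20.6
  b_prs_pct10 <- 10 * log(1.71) / 40.9
  f <- make_ratio_fit(log(1.31), b_prs_pct10, 0.003, 1e-4)
  g <- compute_gre(f, "exposure", "prs", prs_units_per_percentile = 0.1)
  expect_equal(round(g$gre, 1), 20.6)
  expect_equal(g$gre, log(1.31) / (log(1.71) / 40.9), tolerance = 1e-12)
  # zero exposure coefficient: GRE 0, CI spans 0
  f0 <- make_ratio_fit(0, 0.13, 0.003, 1e-4)
  g0 <- compute_gre(f0, "exposure", "prs")
  expect_equal(g0$gre, 0)
  expect_true(g0$ci_low < 0 && g0$ci_high > 0)
  expect_error(compute_gre(f0, "nope", "prs"), "not found")
  expect_error(compute_gre(f0, "exposure", "prs",
                           prs_units_per_percentile = -1), "positive")
})

test_that("delta-method SE matches the hand-evaluated formula", {
  f <- make_ratio_fit(1, 0.05, 0.01, 1e-6)
  g <- compute_gre(f, "exposure", "prs", prs_units_per_percentile = 1)
  expect_equal(g$gre, 20)
  # Var(R) = R^2 (v11/b1^2 + v22/b2^2) with v12 = 0
  expect_equal(g$se, 20 * sqrt(0.01 / 1 + 1e-6 / 0.05^2), tolerance = 1e-10)
  expect_equal(g$se, 2.039608, tolerance = 1e-6)
  expect_equal(c(g$ci_low, g$ci_high),
               20 + c(-1, 1) * qnorm(0.975) * g$se, tolerance = 1e-10)
})

test_that("delta SE agrees with a large parametric bootstrap", {
  f <- make_ratio_fit(0.5365, 0.131, 0.0049, 1.5e-5, v12 = 2e-6)
  g <- compute_gre(f, "exposure", "prs")
  gb <- compute_gre(f, "exposure", "prs", method = "bootstrap",
                    n_boot = 2e5, boot_seed = 99)
  expect_equal(g$se, gb$se, tolerance = 0.03)
  expect_equal(g$gre, gb$gre)
})

test_that("Fieller interval matches delta when well conditioned, flags when not", {
  f <- make_ratio_fit(0.5365, 0.131, 0.0049, 1.5e-5)
  gd <- compute_gre(f, "exposure", "prs")
  gf <- compute_gre(f, "exposure", "prs", method = "fieller")
  expect_false(gf$unbounded)
  expect_true(gf$ci_low <= gf$gre && gf$gre <= gf$ci_high)
  expect_equal(gf$ci_low, gd$ci_low, tolerance = 0.08)
  expect_equal(gf$ci_high, gd$ci_high, tolerance = 0.08)
  # denominator indistinguishable from zero: delta refuses, Fieller flags
  f_bad <- make_ratio_fit(0.5, 0.001, 0.0049, 1e-3)
  expect_warning(expect_error(compute_gre(f_bad, "exposure", "prs"),
                              "refused"), "weakly identified")
  expect_warning(gfb <- compute_gre(f_bad, "exposure", "prs",
                                    method = "fieller"),
                 "weakly identified")
  expect_true(gfb$unbounded)
  expect_true(is.infinite(gfb$ci_low) && is.infinite(gfb$ci_high))
})

test_that("GRE is equivariant to the PRS coding scale", {
  # same model coded per 10 percentiles vs per 1 percentile: identical GRE
  f10 <- make_ratio_fit(0.5365, 0.131, 0.0049, 1.5e-5, v12 = 1e-6)
  S <- diag(c(1, 0.1))  # prs coefficient and covariance rescaled
  V1 <- S %*% f10$vcov %*% S
  dimnames(V1) <- dimnames(f10$vcov)
  f1 <- fake_fit(c(exposure = 0.5365, prs = 0.131 * 0.1), V1)
  for (m in c("delta", "fieller")) {
    g10 <- compute_gre(f10, "exposure", "prs", 0.1, method = m)
    g1 <- compute_gre(f1, "exposure", "prs", 1, method = m)
    expect_equal(g10$gre, g1$gre, tolerance = 1e-12)
    expect_equal(g10$ci_low, g1$ci_low, tolerance = 1e-10)
    expect_equal(g10$ci_high, g1$ci_high, tolerance = 1e-10)
  }
  # and on a real fit: recoding the percentile column is a no-op
  set.seed(55)
  d <- quick_cohort(4000, beta_pct = 0.0131, beta_ob = 0.54)
  d$prs_pct <- d$prs_pct10 * 10
  fa <- fit_logistic(d, "bmi_category", "prs_pct10")
  fb <- fit_logistic(d, "bmi_category", "prs_pct")
  ga <- compute_gre(fa, "bmi_categoryobesity", "prs_pct10", 0.1)
  gb <- compute_gre(fb, "bmi_categoryobesity", "prs_pct", 1)
  expect_equal(ga$gre, gb$gre, tolerance = 1e-6)
  expect_equal(ga$se, gb$se, tolerance = 1e-6)
})

test_that("GRE shares the exposure sign and the ratio identity holds exactly", {
  f <- make_ratio_fit(-0.3, 0.131, 0.004, 1.5e-5)
  expect_lt(compute_gre(f, "exposure", "prs")$gre, 0)
  # shared-denominator identity on a fitted multi-level exposure
  set.seed(56)
  d <- quick_cohort(5000, beta_pct = 0.0131, beta_ow = 0.27, beta_ob = 0.54)
  fit <- fit_logistic(d, "bmi_category", "prs_pct10")
  gow <- compute_gre(fit, "bmi_categoryoverweight", "prs_pct10")
  gob <- compute_gre(fit, "bmi_categoryobesity", "prs_pct10")
  expect_equal(gow$gre / gob$gre,
               fit$coef[["bmi_categoryoverweight"]] /
                 fit$coef[["bmi_categoryobesity"]], tolerance = 1e-12)
  ot <- or_table(fit, c("bmi_categoryoverweight", "bmi_categoryobesity"))
  expect_equal(gre_rescale(gob$gre, ot$or[1], ot$or[2]), gow$gre,
               tolerance = 1e-12)
})

test_that("gre_rescale validates its inputs", {
  expect_equal(gre_rescale(40.9, 1.71, 1.71), 40.9)
  expect_error(gre_rescale(40.9, 1.31, 1), "must not be 1")
  expect_error(gre_rescale(40.9, -2, 1.71), "positive")
})

test_that("gre_table reports counts, ORs and GREs per outcome and level", {
  sim <- simulate_cohort(small_config(n_cases = 600, n_controls = 500,
                                      pop_size = 22000,
                                      covariate_specs = list()))
  coh <- add_prs(sim$cohort, sim$genotypes, sim$weights)
  gt <- gre_table(coh, outcomes = c("overall", "colon"),
                  adjustment = c("age", "sex"))
  expect_equal(nrow(gt), 6L)
  expect_equal(gt$bmi_level, rep(c("normal", "overweight", "obesity"), 2))
  ov <- gt[gt$outcome == "overall", ]
  expect_equal(ov$or[1], 1)
  expect_equal(ov$gre[1], 0)
  expect_equal(sum(ov$n_cases), 600)
  expect_equal(sum(ov$n_controls), 500)
  # within one outcome, GRE ratios equal log-OR ratios exactly
  expect_equal(ov$gre[2] / ov$gre[3], log(ov$or[2]) / log(ov$or[3]),
               tolerance = 1e-12)
  # the colon block shares the full control group
  expect_equal(sum(gt$n_controls[gt$outcome == "colon"]), 500)
})
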