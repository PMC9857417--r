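test_that("logistic MLE equals the closed-form 2x2 log cross-product ratio", {
  d <- expand_2x2(10, 20, 30, 40)
  fit <- fit_logistic(d, "x")
  expect_equal(fit$coef[["xunexposed"]], -log(10 * 40 / (20 * 30)),
               tolerance = 1e-8)
  # property: random 2x2 tables, MLE vs closed form to 1e-8
  set.seed(14)
  for (i in 1:25) {
    n <- sample(20:300, 4, replace = TRUE)
    d <- expand_2x2(n[1], n[2], n[3], n[4])
    d$x <- factor(d$x, c("unexposed", "exposed"))
    fit <- fit_logistic(d, "x")
    expect_equal(fit$coef[["xexposed"]],
                 log(n[1] * n[4] / (n[2] * n[3])), tolerance = 1e-8)
    expect_equal(sqrt(fit$vcov["xexposed", "xexposed"]),
                 sqrt(sum(1 / n)), tolerance = 1e-6)
  }
})

test_that("crude obesity OR from descriptive counts is about 1.80", {
  # obesity 1140 cases / 651 controls vs normal weight 1541 / 1580
  d <- expand_2x2(1140, 651, 1541, 1580)
  d$x <- factor(d$x, c("unexposed", "exposed"))
  fit <- fit_logistic(d, "x")
  or <- exp(fit$coef[["xexposed"]])
  expect_equal(or, 1140 * 1580 / (651 * 1541), tolerance = 1e-8)
  expect_equal(round(or, 2), 1.80)
})

test_that("null simulated outcome gives coefficients within 3 SE of zero", {
  set.seed(21)
  d <- quick_cohort(3000)
  fit <- fit_logistic(d, "bmi_category", "prs_pct10")
  ot <- or_table(fit)
  expect_true(all(abs(ot$log_or) < 3 * ot$se))
})

test_that("fit_logistic enforces its contracts", {
  d <- quick_cohort(100)
  expect_error(fit_logistic(d, "bmi_category", "bmi_category"), "disjoint")
  expect_error(fit_logistic(d, "nope"), "not found")
  expect_error(fit_logistic(d[1:8, ], "bmi_category"), "too few")
  # complete-case accounting reconciles with cohort rows
  d2 <- quick_cohort(500)
  d2$prs_pct10[1:40] <- NA
  fit <- fit_logistic(d2, "bmi_category", "prs_pct10")
  expect_equal(fit$n_used + fit$n_excluded, nrow(d2))
  expect_equal(fit$n_excluded, 40)
  # separation is reported as such
  d3 <- data.frame(status = rep(c("case", "control"), each = 30),
                   x = rep(c(1, 0), each = 30))
  expect_error(fit_logistic(d3, "x"), "separation")
})

test_that("or_table exponentiates Wald limits", {
  f <- fake_fit(c(`(Intercept)` = 0, x = 0),
                matrix(c(1, 0, 0, 0.01), 2,
                       dimnames = list(c("(Intercept)", "x"),
                                       c("(Intercept)", "x"))))
  ot <- or_table(f, "x")
  expect_equal(round(c(ot$or, ot$or_low, ot$or_high), 2), c(1, 0.82, 1.22))
  # zero-variance limit collapses the CI onto the point estimate
  f2 <- fake_fit(c(x = log(2)), matrix(1e-20, 1, dimnames = list("x", "x")))
  ot2 <- or_table(f2, "x")
  expect_equal(round(c(ot2$or, ot2$or_low, ot2$or_high), 2), rep(2, 3))
  expect_error(or_table(f, "zz"), "unknown term")
  # CI always brackets the point estimate and widens with the level
  ot90 <- or_table(f, "x", level = 0.90)
  expect_lt(ot$or_low, ot90$or_low)
  expect_gt(ot$or_high, ot90$or_high)
})

test_that("single product term joint Wald chi-square equals z squared", {
  set.seed(33)
  d <- data.frame(status = sample(c("case", "control"), 800, TRUE),
                  a = rbinom(800, 1, 0.4), b = rbinom(800, 1, 0.5))
  it <- interaction_test(d, "a", "b")
  expect_equal(it$joint$chisq, it$per_term$z^2, tolerance = 1e-10)
  expect_equal(it$joint$df, 1L)
  expect_equal(it$per_term$p.value, it$joint$p.value, tolerance = 1e-12)
})

test_that("categorical x categorical interaction gives a joint df test", {
  set.seed(34)
  d <- quick_cohort(2500, beta_pct = 0.013, beta_ow = 0.3, beta_ob = 0.5)
  d$prs_tertile <- factor(sample(c("low", "medium", "high"), nrow(d), TRUE),
                          c("low", "medium", "high"))
  it <- interaction_test(d, "bmi_category", "prs_tertile")
  expect_equal(it$joint$df, 4L)          # 2 x 2 product terms
  expect_equal(nrow(it$per_term), 4L)
  expect_true(it$joint$p.value > 0 && it$joint$p.value <= 1)
})

test_that("stratified fits skip degenerate strata and agree under homogeneity", {
  set.seed(35)
  d <- quick_cohort(6000, beta_ow = 0.4, beta_ob = 0.7)
  d$grp <- factor(sample(c("g1", "g2"), nrow(d), TRUE), c("g1", "g2", "g3"))
  # an empty stratum is skipped with a warning, not an error
  expect_warning(fits <- stratified_fits(d, "grp", "bmi_category"),
                 "skipped")
  expect_named(fits, c("g1", "g2"))
  # no confounding: stratum ORs agree with the pooled OR within 3 MC SE
  pooled <- fit_logistic(d, "bmi_category")
  for (f in fits) {
    se <- sqrt(f$vcov["bmi_categoryobesity", "bmi_categoryobesity"] +
                 pooled$vcov["bmi_categoryobesity", "bmi_categoryobesity"])
    expect_lt(abs(f$coef[["bmi_categoryobesity"]] -
                    pooled$coef[["bmi_categoryobesity"]]), 3 * se)
  }
})

test_that("joint classification is multiplicative when the truth is", {
  set.seed(36)
  n <- 12000
  prs <- factor(sample(c("low", "medium", "high"), n, TRUE),
                c("low", "medium", "high"))
  bmi <- factor(sample(c("normal", "overweight", "obesity"), n, TRUE,
                       prob = c(0.39, 0.45, 0.16)),
                c("normal", "overweight", "obesity"))
  lp <- -0.8 + c(low = 0, medium = 0.4, high = 0.8)[as.character(prs)] +
    c(normal = 0, overweight = 0.3, obesity = log(1.9))[as.character(bmi)]
  d <- data.frame(status = ifelse(rbinom(n, 1, plogis(lp)) == 1,
                                  "case", "control"),
                  prs_tertile = prs, bmi_category = bmi)
  jc <- joint_classification(d)
  tab <- jc$table
  expect_equal(nrow(tab), 9L)
  expect_equal(tab$or[1], 1)
  # (low PRS, obesity) cell recovers the generative obesity OR 1.9
  lo_ob <- tab[tab$prs_level == "low" & tab$bmi_level == "obesity", ]
  se <- or_table(jc$fit, ".celllow:obesity")$se
  expect_lt(abs(log(lo_ob$or) - log(1.9)), 3 * se)
  # multiplicativity: OR(high, obesity) ~ OR(high, normal) * OR(low, obesity)
  hi_ob <- tab[tab$prs_level == "high" & tab$bmi_level == "obesity", ]
  hi_no <- tab[tab$prs_level == "high" & tab$bmi_level == "normal", ]
  expect_lt(abs(log(hi_ob$or) - log(hi_no$or) - log(lo_ob$or)), 0.35)
  # empty cell errors, naming the cell
  d2 <- d[!(d$prs_tertile == "low" & d$bmi_category == "obesity" &
              d$status == "case"), ]
  expect_error(joint_classification(d2), "low:obesity")
})

test_that("null joint classification gives near-unit cell ORs", {
  set.seed(37)
  d <- quick_cohort(8000)
  d$prs_tertile <- factor(sample(c("low", "medium", "high"), nrow(d), TRUE),
                          c("low", "medium", "high"))
  jc <- joint_classification(d)
  ors <- jc$table$or[-1]
  ses <- or_table(jc$fit)$se
  expect_true(all(abs(log(ors)) < 3.5 * ses))
})

test_that("VIF matches the closed form and flags collinearity", {
  set.seed(41)
  # independent covariates: all VIFs near 1
  d <- data.frame(a = rnorm(2000), b = rnorm(2000), c = rnorm(2000))
  expect_true(all(abs(vif(d, c("a", "b", "c")) - 1) < 0.02))
  # exact sample correlation 0.7 -> VIF = 1/(1-0.49)
  x1 <- as.vector(scale(rnorm(500)))
  e <- residuals(lm(rnorm(500) ~ x1))
  x2 <- 0.7 * x1 + sqrt(1 - 0.49) * as.vector(scale(e, center = TRUE))
  d2 <- data.frame(a = x1, b = x2)
  expect_equal(unname(vif(d2, c("a", "b"))), rep(1 / (1 - 0.49), 2),
               tolerance = 1e-6)
  # duplicated column: infinite VIF with a warning
  d3 <- data.frame(a = rnorm(100), b = rnorm(100))
  d3$c <- d3$a
  w <- testthat::capture_warnings(v <- vif(d3, c("a", "b", "c")))
  expect_true(any(grepl("collinearity", w)))
  expect_true(is.infinite(v[["a"]]) && is.infinite(v[["c"]]))
  expect_error(vif(d3, "a"), "at least 2")
})

test_that("chi-square descriptives match the proportion-test identity", {
  # equal case/control distributions: statistic near 0, p near 1
  d <- data.frame(status = rep(c("case", "control"), each = 300),
                  f = rep(rep(c("x", "y", "z"), each = 100), 2))
  cs <- chi_square_table(d, "f")
  expect_equal(cs$statistic, 0, tolerance = 1e-12)
  expect_equal(cs$p.value, 1, tolerance = 1e-12)
  expect_equal(cs$df, 2L)

  # 2x2 chi-square equals z^2 of the two-sample proportion test
  d2 <- expand_2x2(120, 80, 210, 240)
  names(d2)[2] <- "f"
  cs2 <- chi_square_table(d2, "f")
  pt <- prop.test(c(120, 210), c(200, 450), correct = FALSE)
  expect_equal(cs2$statistic, unname(pt$statistic), tolerance = 1e-10)

  # case-control BMI distribution comparison at published counts: p < .001
  d3 <- data.frame(
    status = rep(c("case", "control"), c(5053, 4116)),
    bmi_cat = c(rep(c("normal", "overweight", "obesity"),
                    c(1541, 2372, 1140)),
                rep(c("normal", "overweight", "obesity"),
                    c(1580, 1885, 651))))
  cs3 <- chi_square_table(d3, "bmi_cat")
  expect_lt(cs3$p.value, 0.001)
  # column percentages as printed in descriptive tables
  tb <- cs3$table
  expect_equal(round(tb$case_pct[tb$level == "obesity"], 1), 22.6)
  expect_equal(round(tb$control_pct[tb$level == "obesity"], 1), 15.8)
})
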