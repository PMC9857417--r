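# Shared fixtures: everything is generated in code at test time.

small_config <- function(...) {
  args <- list(n_cases = 400, n_controls = 350, n_variants = 25,
               pop_size = 15000, seed = 42)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# expand a 2x2 exposure-by-status table into per-row case-control records
expand_2x2 <- function(case_exp, ctrl_exp, case_unexp, ctrl_unexp) {
  data.frame(
    status = rep(c("case", "control", "case", "control"),
                 c(case_exp, ctrl_exp, case_unexp, ctrl_unexp)),
    x = rep(c("exposed", "exposed", "unexposed", "unexposed"),
            c(case_exp, ctrl_exp, case_unexp, ctrl_unexp)),
    stringsAsFactors = FALSE)
}

# minimal hand-built fit object (coef + vcov) for closed-form checks
fake_fit <- function(coef, vcov) {
  structure(list(coef = coef, vcov = vcov), class = "gre_fit")
}

# lightweight prospective cohort with percentile-scale PRS effect; used for
# calibration/coverage experiments where the full population simulator would
# be needlessly slow
quick_cohort <- function(n, beta_pct = 0, beta_ow = 0, beta_ob = 0,
                         base = -0.2) {
  pct <- runif(n, 0, 100)
  bmi <- factor(sample(c("normal", "overweight", "obesity"), n, TRUE,
                       prob = c(0.39, 0.45, 0.16)),
                levels = c("normal", "overweight", "obesity"))
  lp <- base + beta_pct * pct +
    c(normal = 0, overweight = beta_ow, obesity = beta_ob)[as.character(bmi)]
  y <- rbinom(n, 1, plogis(lp))
  data.frame(status = ifelse(y == 1, "case", "control"), bmi_category = bmi,
             prs_pct10 = pct / 10, stringsAsFactors = FALSE)
}
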