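## Outcome definitions: each subtype analysis compares one case subset with
## the full control group (the control column is shared across subtypes).
outcome_subset <- function(cohort, outcome) {
  keep <- switch(outcome,
    overall = rep(TRUE, nrow(cohort)),
    colon   = cohort$status == "control" | cohort$site == "colon",
    rectum  = cohort$status == "control" | cohort$site == "rectum",
    stage13 = cohort$status == "control" | cohort$stage == "I-III",
    stage4  = cohort$status == "control" | cohort$stage == "IV",
    stop("unknown outcome: ", outcome, call. = FALSE))
  keep[is.na(keep)] <- FALSE
  cohort[keep, , drop = FALSE]
}

#' Fit a case-control logistic regression model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) of case status on exposure and adjustment
#' terms, with complete-case handling per model: rows missing any referenced
#' field are excluded and counted. Subtype outcomes restrict cases to the
#' subtype (by tumor site or stage) while retaining all controls.
#'
#' @param cohort a cohort `data.frame` with a `status` column
#'   (`"case"`/`"control"`); subtype outcomes additionally need `site`/`stage`
#'   columns.
#' @param exposure character vector of exposure column names.
#' @param adjustment character vector of adjustment column names (disjoint
#'   from `exposure`).
#' @param outcome one of `"overall"`, `"colon"`, `"rectum"`, `"stage13"`,
#'   `"stage4"`.
#' @return object of class `gre_fit`: list with `coef`, `vcov` (inverse
#'   observed information), `n_used`, `n_cases`, `n_controls`, `n_excluded`,
#'   `loglik`, `converged`, `outcome`, `exposure`, `adjustment`, and (when
#'   the first exposure is categorical) `exposure_counts`, the case/control
#'   counts per exposure level among the complete cases.
#' @export
fit_logistic <- function(cohort, exposure, adjustment = character(),
                         outcome = "overall") {
  if (length(intersect(exposure, adjustment)))
    stop("exposure and adjustment term sets must be disjoint", call. = FALSE)
  d <- outcome_subset(cohort, outcome)
  vars <- unique(c(exposure, adjustment))
  miss <- setdiff(vars, names(d))
  if (length(miss))
    stop("field(s) not found in cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cc <- stats::complete.cases(d[vars])
  n_excluded <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  d$.y <- as.integer(d$status == "case")
  mm_cols <- tryCatch(
    ncol(stats::model.matrix(stats::reformulate(vars), data = d)),
    error = function(e) length(vars) + 1L)
  if (nrow(d) < mm_cols + 10L)
    stop("too few complete-case rows for the requested model", call. = FALSE)
  if (length(unique(d$.y)) < 2L)
    stop("outcome is constant after subsetting; cannot fit", call. = FALSE)
  fml <- stats::reformulate(vars, response = ".y")
  ## separation is detected from the coefficients below; muffle glm's
  ## boundary warning so it does not surface twice
  fit <- withCallingHandlers(
    stats::glm(fml, data = d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("logistic fit did not converge", call. = FALSE)
  be <- stats::coef(fit)
  if (anyNA(be))
    stop("aliased (perfectly collinear) term(s): ",
         paste(names(be)[is.na(be)], collapse = ", "), call. = FALSE)
  big <- abs(be) > 15 & names(be) != "(Intercept)"
  if (any(big))
    stop("possible complete or quasi-complete separation; diverging ",
         "coefficient for term(s): ",
         paste(names(be)[big], collapse = ", "), call. = FALSE)
  res <- list(coef = be, vcov = stats::vcov(fit), n_used = nrow(d),
              n_cases = sum(d$.y == 1L), n_controls = sum(d$.y == 0L),
              n_excluded = n_excluded,
              loglik = as.numeric(stats::logLik(fit)),
              converged = TRUE, outcome = outcome, exposure = exposure,
              adjustment = adjustment, xlevels = fit$xlevels)
  ex1 <- d[[exposure[1]]]
  if (is.factor(ex1) || is.character(ex1))
    res$exposure_counts <- table(exposure = ex1,
                                 status = factor(d$status,
                                                 c("case", "control")))
  class(res) <- "gre_fit"
  res
}

#' @export
coef.gre_fit <- function(object, ...) object$coef

#' @export
vcov.gre_fit <- function(object, ...) object$vcov

#' @export
print.gre_fit <- function(x, ...) {
  cat(sprintf("Case-control logistic fit (%s): %d cases / %d controls (%d excluded)\n",
              x$outcome, x$n_cases, x$n_controls, x$n_excluded))
  print(or_table(x))
  invisible(x)
}

#' Odds-ratio table from a logistic fit
#'
#' Exponentiates coefficients and Wald confidence limits
#' `exp(beta +/- z * SE)`. Full precision is retained; rounding (2 decimals)
#' belongs to presentation only.
#'
#' @param fit a `gre_fit` (or any list with `coef` and `vcov`).
#' @param terms coefficient names to report; default all but the intercept.
#' @param level confidence level (default 0.95).
#' @return `data.frame` with columns `term`, `log_or`, `se`, `or`, `or_low`,
#'   `or_high`.
#' @export
or_table <- function(fit, terms = NULL, level = 0.95) {
  terms <- terms %||% setdiff(names(fit$coef), "(Intercept)")
  unknown <- setdiff(terms, names(fit$coef))
  if (length(unknown))
    stop("unknown term(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- unname(fit$coef[terms])
  se <- sqrt(diag(as.matrix(fit$vcov))[terms])
  se <- unname(se)
  data.frame(term = terms, log_or = b, se = se, or = exp(b),
             or_low = exp(b - z * se), or_high = exp(b + z * se),
             stringsAsFactors = FALSE)
}

## joint Wald chi-square for a set of coefficients being all zero
wald_joint <- function(fit, terms) {
  b <- fit$coef[terms]
  V <- as.matrix(fit$vcov)[terms, terms, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  list(chisq = stat, df = length(terms),
       p.value = stats::pchisq(stat, length(terms), lower.tail = FALSE))
}

#' Multiplicative interaction test
#'
#' Appends the cross-product term(s) of `exposure` and `modifier` to the
#' adjusted logistic model and reports a Wald z test per product term plus a
#' joint Wald chi-square over all product terms (for a single product term
#' the joint chi-square equals z squared).
#'
#' @inheritParams fit_logistic
#' @param modifier column name of the putative effect modifier.
#' @return list with `per_term` (`data.frame`: term, estimate, se, z, p),
#'   `joint` (chisq, df, p.value), and `n_used`.
#' @export
interaction_test <- function(cohort, exposure, modifier,
                             adjustment = character(), outcome = "overall") {
  d <- outcome_subset(cohort, outcome)
  vars <- unique(c(exposure, modifier, adjustment))
  cc <- stats::complete.cases(d[vars])
  d <- d[cc, , drop = FALSE]
  d$.y <- as.integer(d$status == "case")
  fml <- stats::reformulate(c(adjustment,
                              paste(exposure, modifier, sep = "*")),
                            response = ".y")
  fit <- stats::glm(fml, data = d, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  if (!fit$converged)
    stop("interaction model did not converge", call. = FALSE)
  be <- stats::coef(fit)
  prod_terms <- grep(":", names(be), fixed = TRUE, value = TRUE)
  if (!length(prod_terms))
    stop("no product terms were generated; check exposure/modifier",
         call. = FALSE)
  if (anyNA(be[prod_terms]) || any(abs(be[prod_terms]) > 15))
    stop("sparse cell(s) induced separation in product term(s): ",
         paste(prod_terms[is.na(be[prod_terms]) |
                            abs(be[prod_terms]) > 15], collapse = ", "),
         call. = FALSE)
  V <- stats::vcov(fit)
  se <- sqrt(diag(V)[prod_terms])
  zst <- be[prod_terms] / se
  per_term <- data.frame(term = prod_terms, estimate = unname(be[prod_terms]),
                         se = unname(se), z = unname(zst),
                         p.value = unname(2 * stats::pnorm(-abs(zst))),
                         stringsAsFactors = FALSE)
  joint <- wald_joint(list(coef = be, vcov = V), prod_terms)
  list(per_term = per_term, joint = joint, n_used = nrow(d))
}

#' Fit the exposure model independently within strata
#'
#' Splits the cohort by a stratum field (PRS tertile, age group, sex, ...)
#' and fits the adjusted exposure model in each stratum. Degenerate strata
#' (too small, no cases, separation) are skipped with a warning.
#'
#' @inheritParams fit_logistic
#' @param stratum column name of the stratification field.
#' @return named list of `gre_fit` objects, one per usable stratum level.
#' @export
stratified_fits <- function(cohort, stratum, exposure,
                            adjustment = character(), outcome = "overall") {
  x <- cohort[[stratum]]
  if (is.null(x)) stop("stratum field not found: ", stratum, call. = FALSE)
  lv <- if (is.factor(x)) levels(x) else sort(unique(x[!is.na(x)]))
  fits <- list()
  for (l in lv) {
    sub <- cohort[which(x == l), , drop = FALSE]
    f <- tryCatch(fit_logistic(sub, exposure, adjustment, outcome),
                  error = function(e) {
                    warning(sprintf("stratum '%s' skipped: %s", l,
                                    conditionMessage(e)), call. = FALSE)
                    NULL
                  })
    if (!is.null(f)) fits[[as.character(l)]] <- f
  }
  fits
}

#' Joint classification of two categorical risk factors
#'
#' Cross-classifies PRS tertile and BMI category into nine cells and fits the
#' fully adjusted model with eight indicator terms against the
#' (low PRS, normal weight) reference cell.
#'
#' @inheritParams fit_logistic
#' @param prs_var,bmi_var column names of the two categorical fields.
#' @return list with `fit` (the `gre_fit`) and `table` (`data.frame` with
#'   `prs_level`, `bmi_level`, counts, and OR columns; the reference cell row
#'   has OR 1 and no CI).
#' @export
joint_classification <- function(cohort, adjustment = character(),
                                 prs_var = "prs_tertile",
                                 bmi_var = "bmi_category",
                                 outcome = "overall") {
  d <- outcome_subset(cohort, outcome)
  p <- d[[prs_var]]; b <- d[[bmi_var]]
  if (is.null(p) || is.null(b))
    stop("both categorical fields must be present", call. = FALSE)
  plv <- if (is.factor(p)) levels(p) else unique(p)
  blv <- if (is.factor(b)) levels(b) else unique(b)
  cells <- as.vector(t(outer(plv, blv, paste, sep = ":")))
  d$.cell <- factor(paste(p, b, sep = ":"), levels = cells)
  tab <- table(cell = d$.cell, status = factor(d$status,
                                               c("case", "control")))
  empty <- rownames(tab)[tab[, "case"] == 0 | tab[, "control"] == 0]
  if (length(empty))
    stop("empty joint cell(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  fit <- fit_logistic(d, exposure = ".cell", adjustment = adjustment,
                      outcome = "overall")
  ot <- or_table(fit, paste0(".cell", cells[-1]))
  out <- data.frame(
    prs_level = rep(plv, each = length(blv)),
    bmi_level = rep(blv, length(plv)),
    n_cases = as.vector(tab[cells, "case"]),
    n_controls = as.vector(tab[cells, "control"]),
    or = c(1, ot$or), or_low = c(NA, ot$or_low),
    or_high = c(NA, ot$or_high), stringsAsFactors = FALSE)
  list(fit = fit, table = out)
}

#' Subtype heterogeneity test
#'
#' Tests whether an exposure's log-OR differs between tumor subtypes that
#' share the same control group. The default method fits a polytomous
#' (multinomial) logistic regression with outcome levels control / subtype_1
#' / subtype_2 and applies a Wald test to the equality of the exposure
#' coefficient(s) across the subtype equations; this respects the covariance
#' induced by the shared controls. See [heterogeneity_naive()] for the
#' approximate independent-Wald variant.
#'
#' @inheritParams fit_logistic
#' @param outcomes character vector (length >= 2) of subtype outcomes, e.g.
#'   `c("stage13", "stage4")` or `c("colon", "rectum")`.
#' @param terms coefficient names to test; default all design columns of the
#'   exposure.
#' @return list with `per_term` (`data.frame`: term, difference of the first
#'   two subtype coefficients, se, z, p), `joint` (chisq, df, p.value over
#'   all equality contrasts), `method`, `n_used`.
#' @export
heterogeneity_test <- function(cohort, exposure, adjustment = character(),
                               outcomes = c("stage13", "stage4"),
                               terms = NULL) {
  if (length(outcomes) < 2L)
    stop("need at least 2 subtype outcomes", call. = FALSE)
  field <- if (all(outcomes %in% c("stage13", "stage4"))) "stage" else "site"
  lab <- c(stage13 = "I-III", stage4 = "IV", colon = "colon",
           rectum = "rectum")[outcomes]
  d <- cohort[cohort$status == "control" |
                cohort[[field]] %in% lab, , drop = FALSE]
  d$.out <- factor(ifelse(d$status == "control", "control",
                          names(lab)[match(d[[field]], lab)]),
                   levels = c("control", outcomes))
  vars <- unique(c(exposure, adjustment))
  d <- d[stats::complete.cases(d[vars]) & !is.na(d$.out), , drop = FALSE]
  fml <- stats::reformulate(vars, response = ".out")
  m <- nnet::multinom(fml, data = d, trace = FALSE, maxit = 500)
  B <- stats::coef(m)                       # outcomes x design columns
  V <- stats::vcov(m)                       # names "outcome:term"
  if (is.null(terms)) {
    dcols <- colnames(B)
    hit <- Reduce(`|`, lapply(exposure, function(e) startsWith(dcols, e)))
    terms <- setdiff(dcols[hit], "(Intercept)")
  }
  if (!length(terms)) stop("no exposure terms to test", call. = FALSE)
  ## equality contrasts: for each term, outcome_k - outcome_1 for k >= 2
  cn <- rownames(V)
  Ls <- list()
  for (t in terms) {
    for (k in 2:length(outcomes)) {
      l <- numeric(length(cn))
      i1 <- match(paste(outcomes[1], t, sep = ":"), cn)
      ik <- match(paste(outcomes[k], t, sep = ":"), cn)
      if (is.na(i1) || is.na(ik))
        stop("term not found in multinomial fit: ", t, call. = FALSE)
      l[i1] <- 1; l[ik] <- -1
      Ls[[length(Ls) + 1L]] <- l
    }
  }
  L <- do.call(rbind, Ls)
  bvec <- as.vector(t(B))
  names(bvec) <- cn
  est <- drop(L %*% bvec)
  Vc <- L %*% V %*% t(L)
  stat <- drop(t(est) %*% solve(Vc, est))
  joint <- list(chisq = stat, df = nrow(L),
                p.value = stats::pchisq(stat, nrow(L), lower.tail = FALSE))
  ## per-term z for the first pair of outcomes
  per <- lapply(terms, function(t) {
    i1 <- paste(outcomes[1], t, sep = ":")
    i2 <- paste(outcomes[2], t, sep = ":")
    dlt <- bvec[[i1]] - bvec[[i2]]
    se <- sqrt(V[i1, i1] + V[i2, i2] - 2 * V[i1, i2])
    z <- dlt / se
    data.frame(term = t, difference = dlt, se = se, z = z,
               p.value = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  list(per_term = do.call(rbind, per), joint = joint,
       method = "polytomous", n_used = nrow(d))
}

#' Approximate heterogeneity z test from two independent fits
#'
#' Naive variant that ignores the covariance induced by shared controls:
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)`. Labeled approximate; prefer
#' [heterogeneity_test()].
#'
#' @param fit1,fit2 `gre_fit` objects for the two subtypes.
#' @param term coefficient name present in both fits.
#' @return `data.frame` with term, difference, se, z, p.value, method.
#' @export
heterogeneity_naive <- function(fit1, fit2, term) {
  b1 <- fit1$coef[[term]]; b2 <- fit2$coef[[term]]
  se <- sqrt(fit1$vcov[term, term] + fit2$vcov[term, term])
  z <- (b1 - b2) / se
  data.frame(term = term, difference = b1 - b2, se = se, z = z,
             p.value = 2 * stats::pnorm(-abs(z)),
             method = "naive-independent", stringsAsFactors = FALSE)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of design column j on all other design columns (factors are
#' expanded to indicator columns first). Perfect collinearity yields `Inf`
#' with a warning.
#'
#' @param data `data.frame` holding the covariates.
#' @param terms character vector (length >= 2) of column names.
#' @return named numeric vector of VIFs, one per design column.
#' @export
vif <- function(data, terms) {
  if (length(terms) < 2L)
    stop("need at least 2 terms for a VIF computation", call. = FALSE)
  d <- data[stats::complete.cases(data[terms]), terms, drop = FALSE]
  mm <- stats::model.matrix(stats::reformulate(terms), data = d)[, -1,
                                                                 drop = FALSE]
  if (ncol(mm) < 2L)
    stop("design has fewer than 2 columns", call. = FALSE)
  out <- numeric(ncol(mm))
  names(out) <- colnames(mm)
  for (j in seq_len(ncol(mm))) {
    x <- mm[, j]
    f <- stats::lm.fit(cbind(1, mm[, -j, drop = FALSE]), x)
    tss <- sum((x - mean(x))^2)
    r2 <- 1 - sum(f$residuals^2) / tss
    if (r2 > 1 - 1e-10) {
      warning("perfect collinearity: infinite VIF for ", colnames(mm)[j],
              call. = FALSE)
      out[j] <- Inf
    } else out[j] <- 1 / (1 - r2)
  }
  out
}

#' Case-control chi-square test with a formatted count table
#'
#' Pearson chi-square (no continuity correction) on the r x 2 table of a
#' categorical field against case/control status, with column percentages.
#' Zero-margin categories are dropped with a warning.
#'
#' @param cohort cohort `data.frame` with `status`.
#' @param field categorical column name.
#' @return list with `table` (`data.frame`: level, case_n, case_pct,
#'   control_n, control_pct), `statistic`, `df`, `p.value`.
#' @export
chi_square_table <- function(cohort, field) {
  x <- cohort[[field]]
  if (is.null(x)) stop("field not found: ", field, call. = FALSE)
  st <- factor(cohort$status, c("case", "control"))
  keep <- !is.na(x) & !is.na(st)
  tab <- table(x[keep], st[keep])
  zero <- rownames(tab)[rowSums(tab) == 0]
  if (length(zero)) {
    warning("dropping zero-margin categor(ies): ",
            paste(zero, collapse = ", "), call. = FALSE)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  }
  if (nrow(tab) < 2L)
    stop("field has fewer than 2 observed categories", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  pct <- sweep(tab, 2, colSums(tab), "/") * 100
  out <- data.frame(level = rownames(tab),
                    case_n = as.vector(tab[, "case"]),
                    case_pct = as.vector(pct[, "case"]),
                    control_n = as.vector(tab[, "control"]),
                    control_pct = as.vector(pct[, "control"]),
                    stringsAsFactors = FALSE)
  list(table = out, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p.value = ct$p.value)
}
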