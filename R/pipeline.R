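#' Read a simulation configuration from a YAML or JSON file
#'
#' Field names mirror the arguments of [simulation_config()]; unknown fields
#' are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [simulation_config()] object.
#' @export
simulation_config_from_file <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(simulation_config, cfg)
}

## adjustment covariate set implied by a config (the fully adjusted model)
adjustment_from_config <- function(config) {
  c("age", "sex", vapply(config$covariate_specs, `[[`, "", "name"))
}

#' Run the full simulate-score-model-report pipeline
#'
#' Executes, in order: cohort simulation, PRS scoring and control-referenced
#' percentile/tertile derivation, case-control descriptive comparisons,
#' minimally and fully adjusted association models for PRS tertiles and BMI
#' categories, multiplicative interaction tests, PRS-tertile-stratified BMI
#' models, joint BMI x PRS classification, and the genetic-risk-equivalent
#' table across outcomes. Writes seven analysis tables plus the input data
#' (cohort, dosages, scoring table, config) and a reproducibility manifest
#' to `out_dir`. Deterministic given the seed; if any stage fails, all files
#' written so far are removed and the error names the stage.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param seed optional master seed overriding `config$seed`.
#' @param ci_method CI method for the GRE table.
#' @return (invisibly) the manifest as a list.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         seed = NULL, ci_method = "delta") {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_tsv(x, p)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  fmt2 <- function(est, lo, hi) ifelse(is.na(lo), sprintf("%.2f", est),
                                       sprintf("%.2f (%.2f-%.2f)", est, lo, hi))
  fmt1 <- function(est, lo, hi) ifelse(is.na(lo), sprintf("%.1f", est),
                                       sprintf("%.1f (%.1f-%.1f)", est, lo, hi))

  sim <- stage("simulate", simulate_cohort(config))
  cohort <- stage("prs", add_prs(sim$cohort, sim$genotypes, sim$weights))
  adj <- adjustment_from_config(config)

  stage("write-data", {
    emit(cohort, "cohort.tsv")
    df <- data.frame(participant_id = rownames(sim$genotypes),
                     sim$genotypes, check.names = FALSE)
    emit(df, "dosages.tsv")
    emit(sim$weights, "weights.tsv")
    cfgp <- file.path(out_dir, "config.json")
    jsonlite::write_json(config[setdiff(names(config), "covariate_specs")],
                         cfgp, auto_unbox = TRUE, digits = NA, null = "null")
    written <- c(written, cfgp)
  })

  t1 <- stage("descriptives", {
    fields <- c("sex", "bmi_category", "prs_tertile",
                vapply(config$covariate_specs, `[[`, "", "name"))
    do.call(rbind, lapply(fields, function(f) {
      cs <- chi_square_table(cohort, f)
      cbind(field = f, cs$table, chisq = cs$statistic, df = cs$df,
            p.value = cs$p.value)
    }))
  })
  emit(t1, "table1_descriptives.tsv")

  t2 <- stage("associations", {
    out <- list()
    for (ex in c("prs_tertile", "bmi_category")) {
      other <- if (ex == "prs_tertile") "bmi_category" else "prs_pct10"
      m1 <- fit_logistic(cohort, ex, c("age", "sex"))
      m2 <- fit_logistic(cohort, ex, unique(c(adj, other)))
      o1 <- or_table(m1, grep(ex, names(m1$coef), value = TRUE,
                              fixed = TRUE))
      o2 <- or_table(m2, o1$term)
      out[[ex]] <- data.frame(
        variable = ex, term = o1$term,
        or_model1 = o1$or, or_model1_low = o1$or_low,
        or_model1_high = o1$or_high,
        or_model2 = o2$or, or_model2_low = o2$or_low,
        or_model2_high = o2$or_high,
        model1_fmt = fmt2(o1$or, o1$or_low, o1$or_high),
        model2_fmt = fmt2(o2$or, o2$or_low, o2$or_high),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  emit(t2, "table2_associations.tsv")

  t_int <- stage("interaction", {
    it_cat <- interaction_test(cohort, "bmi_category", "prs_pct10", adj)
    it_cont <- interaction_test(cohort, "bmi", "prs_pct10", adj)
    data.frame(bmi_coding = c("categorical", "continuous"),
               joint_chisq = c(it_cat$joint$chisq, it_cont$joint$chisq),
               df = c(it_cat$joint$df, it_cont$joint$df),
               p.value = c(it_cat$joint$p.value, it_cont$joint$p.value),
               stringsAsFactors = FALSE)
  })
  emit(t_int, "interaction_tests.tsv")

  t3 <- stage("stratified", {
    fits <- stratified_fits(cohort, "prs_tertile", "bmi_category", adj)
    do.call(rbind, lapply(names(fits), function(l) {
      ot <- or_table(fits[[l]], grep("bmi_category",
                                     names(fits[[l]]$coef), value = TRUE,
                                     fixed = TRUE))
      cbind(prs_tertile = l, ot,
            or_fmt = fmt2(ot$or, ot$or_low, ot$or_high))
    }))
  })
  emit(t3, "table3_stratified.tsv")

  t_joint <- stage("joint", {
    jc <- joint_classification(cohort, adj)
    cbind(jc$table, or_fmt = fmt2(jc$table$or, jc$table$or_low,
                                  jc$table$or_high))
  })
  emit(t_joint, "joint_classification.tsv")

  t4 <- stage("gre", {
    gt <- gre_table(cohort, adjustment = adj, ci_method = ci_method)
    cbind(gt, or_fmt = fmt2(gt$or, gt$or_low, gt$or_high),
          gre_fmt = fmt1(gt$gre, gt$gre_low, gt$gre_high))
  })
  emit(t4, "table4_gre.tsv")

  t_vif <- stage("vif", {
    v <- vif(cohort, unique(c(adj, "bmi_category", "prs_pct10")))
    data.frame(term = names(v), vif = unname(v), stringsAsFactors = FALSE)
  })
  emit(t_vif, "vif.tsv")

  manifest <- stage("manifest", {
    m <- list(
      package = "grequiv",
      version = as.character(utils::packageVersion("grequiv")),
      seed = config$seed,
      config_digest = unname(tools::md5sum(file.path(out_dir,
                                                     "config.json"))),
      n_cases = sum(cohort$status == "case"),
      n_controls = sum(cohort$status == "control"),
      n_variants = config$n_variants,
      files = lapply(sort(written), function(p)
        list(name = basename(p), md5 = unname(tools::md5sum(p)))))
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(m, mp, auto_unbox = TRUE, digits = NA)
    m
  })
  invisible(manifest)
}
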