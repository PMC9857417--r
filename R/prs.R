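#' Variant scoring table
#'
#' A scoring panel in PGS-Catalog style: one row per variant with the effect
#' (risk) allele, the other allele, and a weight. With unit weights the
#' resulting score is the plain risk-allele count.
#'
#' @param variant_id character vector of unique variant identifiers.
#' @param effect_allele,other_allele allele strings; must differ per variant.
#' @param weight numeric weights, finite; defaults to 1 (risk-allele count).
#' @return a `data.frame` with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @export
variant_weight_table <- function(variant_id, effect_allele, other_allele,
                                 weight = 1) {
  variant_id <- as.character(variant_id)
  if (anyDuplicated(variant_id))
    stop("variant_id values must be unique", call. = FALSE)
  effect_allele <- as.character(effect_allele)
  other_allele <- as.character(other_allele)
  if (any(effect_allele == other_allele))
    stop("effect_allele must differ from other_allele", call. = FALSE)
  weight <- rep_len(as.numeric(weight), length(variant_id))
  if (any(!is.finite(weight)))
    stop("weights must be finite", call. = FALSE)
  data.frame(variant_id = variant_id, effect_allele = effect_allele,
             other_allele = other_allele, weight = weight,
             stringsAsFactors = FALSE)
}

#' Compute polygenic risk scores from a dosage matrix
#'
#' Scores each participant as the weighted sum of effect-allele dosages over
#' the scoring panel. Dosages are expected in `[0, 2]` (hard genotypes or
#' imputed dosages). If `dosage_alleles` records which allele the matrix
#' counts, columns keyed to the panel's other allele are flipped
#' (`dosage <- 2 - dosage`); any orientation that is neither an exact match
#' nor a flip is an error.
#'
#' @param dosages numeric matrix, participants x variants, column names are
#'   variant ids, row names are participant ids.
#' @param weights a [variant_weight_table()].
#' @param dosage_alleles optional `data.frame` with columns `variant_id`,
#'   `counted_allele`, `other_allele` describing the matrix orientation (as
#'   returned by [read_dosage_vcf()]); `NULL` means the matrix is already
#'   oriented to the panel's effect alleles.
#' @param mode `"strict"` (default) errors when a scoring variant is absent
#'   from the matrix; `"permissive"` scores on the available variants and
#'   rescales by the missing weight mass, with a warning.
#' @return named numeric vector of scores (names = participant ids).
#' @export
compute_prs <- function(dosages, weights, dosage_alleles = NULL,
                        mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  missing_v <- setdiff(weights$variant_id, colnames(dosages))
  if (length(missing_v) && mode == "strict")
    stop("scoring variant(s) absent from dosage matrix: ",
         paste(utils::head(missing_v, 5), collapse = ", "),
         if (length(missing_v) > 5) ", ...", call. = FALSE)
  present <- weights$variant_id[weights$variant_id %in% colnames(dosages)]
  if (!length(present))
    stop("no scoring variants present in the dosage matrix", call. = FALSE)
  w <- weights[match(present, weights$variant_id), , drop = FALSE]
  X <- dosages[, present, drop = FALSE]
  if (anyNA(X))
    stop("dosage matrix contains missing values (post-imputation contract)",
         call. = FALSE)
  if (min(X) < 0 || max(X) > 2)
    stop("dosages must lie in [0, 2]", call. = FALSE)
  if (!is.null(dosage_alleles)) {
    da <- dosage_alleles[match(present, dosage_alleles$variant_id), ,
                         drop = FALSE]
    if (anyNA(da$variant_id))
      stop("dosage_alleles does not cover all scoring variants", call. = FALSE)
    same <- da$counted_allele == w$effect_allele &
      da$other_allele == w$other_allele
    flip <- da$counted_allele == w$other_allele &
      da$other_allele == w$effect_allele
    bad <- !(same | flip)
    if (any(bad))
      stop("allele mismatch (neither match nor flip) for variant(s): ",
           paste(utils::head(present[bad], 5), collapse = ", "), call. = FALSE)
    if (any(flip)) X[, flip] <- 2 - X[, flip]
  }
  score <- drop(X %*% w$weight)
  if (length(missing_v)) {
    full_mass <- sum(abs(weights$weight))
    avail_mass <- sum(abs(w$weight))
    warning(sprintf(
      "%d scoring variant(s) missing; rescaling scores by total/available weight mass (%.3f/%.3f)",
      length(missing_v), full_mass, avail_mass), call. = FALSE)
    score <- score * full_mass / avail_mass
  }
  names(score) <- rownames(dosages)
  score
}

#' Mid-rank empirical percentile transform against a reference
#'
#' `percentile(x) = 100 * (#\{ref < x\} + 0.5 * #\{ref = x\}) / n_ref`. The
#' mid-rank convention handles ties symmetrically and is invariant under any
#' strictly increasing rescaling applied to both scores and reference.
#'
#' @param scores numeric vector to transform.
#' @param reference nonempty numeric reference distribution (typically the
#'   control-group scores).
#' @return numeric vector of percentiles in `[0, 100]`, nondecreasing in
#'   `scores`.
#' @export
percentile_transform <- function(scores, reference) {
  if (!length(reference)) stop("reference scores must be nonempty", call. = FALSE)
  if (anyNA(reference)) stop("reference scores contain NA", call. = FALSE)
  sref <- sort(reference)
  n_less <- findInterval(scores, sref, left.open = TRUE)
  n_leq <- findInterval(scores, sref)
  100 * (n_less + 0.5 * (n_leq - n_less)) / length(sref)
}

#' Categorize scores into tertiles defined among a reference group
#'
#' Cutpoints are the 1/3 and 2/3 empirical quantiles (type 1, inverse ECDF) of
#' the reference distribution, so reference counts split as evenly as ties
#' permit. Scores at or below the lower cut are `low`, at or below the upper
#' cut `medium`, else `high`; the same cutpoints are applied to cases and
#' controls alike.
#'
#' @param scores numeric vector to categorize.
#' @param reference nonempty, non-degenerate numeric reference scores.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
tertile_categorize <- function(scores, reference) {
  if (!length(reference)) stop("reference scores must be nonempty", call. = FALSE)
  if (length(unique(reference)) < 2L)
    stop("degenerate reference: all reference scores are equal", call. = FALSE)
  cuts <- stats::quantile(reference, c(1, 2) / 3, type = 1, names = FALSE)
  if (cuts[1] == cuts[2])
    stop("degenerate reference: tertile cutpoints coincide", call. = FALSE)
  factor(ifelse(scores <= cuts[1], "low",
                ifelse(scores <= cuts[2], "medium", "high")),
         levels = c("low", "medium", "high"))
}

#' BMI category from numeric BMI
#'
#' Normal weight below 25 (underweight merged in), overweight `[25, 30)`,
#' obesity 30 or greater; boundaries half-open.
#'
#' @param bmi numeric vector of BMI values (kg/m^2).
#' @return factor with levels `normal`, `overweight`, `obesity`.
#' @export
bmi_category <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 25, 30, Inf), right = FALSE,
      labels = c("normal", "overweight", "obesity"))
}

#' Derive lagged BMI from decade-wise weight history
#'
#' Uses the body weight reported for roughly ten years before the index age:
#' the reference decade is `10 * floor((age - 5) / 10)`, so ages 55-64 map to
#' the weight at age 50 and ages 65-74 to the weight at age 60. BMI is
#' weight (kg) divided by squared height (m). If the required decade weight
#' is unavailable the record is flagged missing (to be excluded downstream).
#'
#' @param weights_by_decade named numeric vector of weights in kg, names are
#'   decade ages (`"40"`, `"50"`, ...).
#' @param height height in meters, positive.
#' @param age_at_index age in years at diagnosis or interview.
#' @return list with `bmi`, `category`, `reference_decade`, `missing`.
#' @export
derive_bmi <- function(weights_by_decade, height, age_at_index) {
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
      height <= 0)
    stop("height must be a single positive number (meters)", call. = FALSE)
  if (!length(weights_by_decade))
    stop("at least one decade weight is required", call. = FALSE)
  ref_decade <- 10 * floor((age_at_index - 5) / 10)
  w <- unname(weights_by_decade[as.character(ref_decade)])
  if (is.null(w) || length(w) != 1L || is.na(w)) {
    return(list(bmi = NA_real_, category = factor(NA, levels = c("normal",
      "overweight", "obesity")), reference_decade = ref_decade,
      missing = TRUE))
  }
  bmi <- w / height^2
  list(bmi = bmi, category = bmi_category(bmi), reference_decade = ref_decade,
       missing = FALSE)
}

#' Attach PRS score, percentile, and tertile to a cohort
#'
#' Computes per-participant scores from the dosage matrix and scoring table,
#' then derives percentiles and tertiles against the chosen reference group
#' (controls by default, matching the convention of defining PRS categories
#' among controls). Also adds `prs_pct10` (= percentile / 10), the
#' per-10-percentile coding used by the analysis models.
#'
#' @param cohort a cohort `data.frame` with `participant_id` and `status`
#'   (`"case"`/`"control"`) columns.
#' @param genotypes dosage matrix with participant ids as row names.
#' @param weights a [variant_weight_table()].
#' @param reference `"controls"` (default) or `"all"`: the group whose score
#'   distribution anchors percentiles and tertile cutpoints.
#' @param ... passed to [compute_prs()].
#' @return `cohort` with columns `prs_score`, `prs_percentile`, `prs_tertile`,
#'   `prs_pct10` added.
#' @export
add_prs <- function(cohort, genotypes, weights,
                    reference = c("controls", "all"), ...) {
  reference <- match.arg(reference)
  idx <- match(cohort$participant_id, rownames(genotypes))
  if (anyNA(idx))
    stop("genotype matrix is missing participant(s): ",
         paste(utils::head(cohort$participant_id[is.na(idx)], 5),
               collapse = ", "), call. = FALSE)
  score <- compute_prs(genotypes[idx, , drop = FALSE], weights, ...)
  ref <- if (reference == "controls") score[cohort$status == "control"] else score
  cohort$prs_score <- unname(score)
  cohort$prs_percentile <- percentile_transform(score, ref)
  cohort$prs_tertile <- tertile_categorize(score, ref)
  cohort$prs_pct10 <- cohort$prs_percentile / 10
  cohort
}
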