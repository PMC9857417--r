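#' Read and write variant scoring tables
#'
#' Tab-separated with header columns `variant_id`, `effect_allele`,
#' `other_allele`, `weight` (PGS-Catalog-style).
#'
#' @param path file path.
#' @return [read_weight_table()] returns a validated scoring `data.frame`.
#' @export
read_weight_table <- function(path) {
  x <- read_tsv(path)
  need <- c("variant_id", "effect_allele", "other_allele", "weight")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("scoring table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  variant_weight_table(x$variant_id, x$effect_allele, x$other_allele,
                       x$weight)
}

#' @rdname read_weight_table
#' @param weights a scoring `data.frame` ([variant_weight_table()]).
#' @export
write_weight_table <- function(weights, path) write_tsv(weights, path)

#' Read and write dosage matrices as TSV
#'
#' Rows are participants (first column `participant_id`), remaining columns
#' are variant dosages in `[0, 2]`.
#'
#' @param path file path.
#' @return [read_dosage_tsv()] returns a numeric matrix with participant ids
#'   as row names.
#' @export
read_dosage_tsv <- function(path) {
  x <- read_tsv(path, check.names = FALSE)
  if (names(x)[1] != "participant_id")
    stop("first column of a dosage TSV must be participant_id", call. = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$participant_id
  m
}

#' @rdname read_dosage_tsv
#' @param dosages dosage matrix (participants x variants, row names ids).
#' @export
write_dosage_tsv <- function(dosages, path) {
  df <- data.frame(participant_id = rownames(dosages), dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read dosages from a VCF file
#'
#' Extracts the per-genotype `DS` (dosage) FORMAT field; when absent, hard
#' genotypes (`GT`) are converted to ALT-allele counts 0/1/2. The returned
#' matrix counts the ALT allele; the accompanying allele table lets
#' [compute_prs()] flip columns whose counted allele is the scoring panel's
#' other allele.
#'
#' @param path path to an (uncompressed or bgzipped) VCF.
#' @return list with `dosages` (samples x variants matrix) and `alleles`
#'   (`data.frame`: `variant_id`, `counted_allele` = ALT, `other_allele` =
#'   REF).
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF dosages requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- v@fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(v@fix[, "CHROM"], ":",
                                         v@fix[, "POS"])[is.na(ids) |
                                                           ids == "."]
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  rownames(ds) <- ids
  list(dosages = t(ds),
       alleles = data.frame(variant_id = ids,
                            counted_allele = v@fix[, "ALT"],
                            other_allele = v@fix[, "REF"],
                            stringsAsFactors = FALSE))
}

#' Read and write cohort phenotype tables
#'
#' Tab-separated, one row per participant, `NA` for missing. Reading restores
#' the factor codings used by the analysis models (`bmi_category`,
#' `prs_tertile`, `sex`).
#'
#' @param path file path.
#' @return [read_cohort_tsv()] returns the cohort `data.frame`.
#' @export
read_cohort_tsv <- function(path) {
  x <- read_tsv(path)
  if (!all(c("participant_id", "status") %in% names(x)))
    stop("cohort table needs participant_id and status columns",
         call. = FALSE)
  if ("bmi_category" %in% names(x))
    x$bmi_category <- factor(x$bmi_category,
                             c("normal", "overweight", "obesity"))
  if ("prs_tertile" %in% names(x))
    x$prs_tertile <- factor(x$prs_tertile, c("low", "medium", "high"))
  if ("sex" %in% names(x)) x$sex <- factor(x$sex, c("female", "male"))
  x
}

#' @rdname read_cohort_tsv
#' @param cohort cohort `data.frame`.
#' @export
write_cohort_tsv <- function(cohort, path) write_tsv(cohort, path)
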