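`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spawn reproducible child seeds from one master seed
#'
#' One master seed drives every stage of a run; each stage (genotypes,
#' covariates, disease assignment, sampling, ...) gets its own stream so that
#' changing one stage's draws never perturbs another's. The ambient RNG state
#' is restored on exit.
#'
#' @param master single integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(master, n) {
  if (length(master) != 1L || !is.finite(master))
    stop("`master` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(abs(master) %% (.Machine$integer.max - 1L)))
  sample.int(.Machine$integer.max - 1L, n)
}

## truncated normal via inverse-cdf; lo/hi may be scalar or vectorised
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA", ...)
}
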