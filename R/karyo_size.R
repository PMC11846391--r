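# Genome-size arithmetic: picogram/gigabase conversion, sex differences and
# chromosome-size apportionment under a size-ratio constraint.

#' Convert picograms of DNA to gigabases
#'
#' Two conversion modes: `"unit"` (1 pg = 1 Gb, the rounding convention used
#' when genome sizes are quoted as "4.61 pg, about 4.6 Gb") and
#' `"standard"` (1 pg = 0.978 Gb, the literature constant).
#'
#' @param pg DNA content in picograms (non-negative).
#' @param mode `"unit"` or `"standard"`.
#' @return Gigabases.
#' @export
pg_to_gb <- function(pg, mode = c("unit", "standard")) {
  mode <- match.arg(mode)
  if (any(pg < 0)) stopf("pg must be non-negative")
  pg * if (mode == "unit") 1 else 0.978
}

#' Karyotype model for X apportionment
#'
#' @param n_autosomes Number of autosomes in the haploid set.
#' @param autosome_to_x_ratio Size of one autosome as a fraction of the X.
#' @param haploid_size_gb Haploid genome size in Gb.
#' @return A `karyotype_model` list.
#' @export
karyotype_model <- function(n_autosomes = 11L, autosome_to_x_ratio = 0.1,
                            haploid_size_gb) {
  if (n_autosomes < 0 || autosome_to_x_ratio <= 0 || haploid_size_gb <= 0)
    stopf("invalid karyotype model")
  structure(list(n_autosomes = as.integer(n_autosomes),
                 autosome_to_x_ratio = autosome_to_x_ratio,
                 haploid_size_gb = haploid_size_gb),
            class = "karyotype_model")
}

#' Apportion a haploid genome between the X and the autosomes
#'
#' Under the constraint that every autosome is `autosome_to_x_ratio` times
#' the X, the haploid size decomposes as
#' `X * (1 + n_autosomes * ratio) = haploid_size`, giving
#' `X = haploid / (1 + n * ratio)` and `autosome = ratio * X`.  The
#' conservation identity `n * autosome + X == haploid` holds exactly.
#'
#' @param model A [karyotype_model()] (or its arguments via `...`).
#' @param ... Passed to [karyotype_model()] when `model` is missing.
#' @return Named numeric vector `c(x_gb, autosome_gb)`.
#' @export
apportion_x <- function(model = NULL, ...) {
  if (is.null(model)) model <- karyotype_model(...)
  stopifnot(inherits(model, "karyotype_model"))
  x <- model$haploid_size_gb /
    (1 + model$n_autosomes * model$autosome_to_x_ratio)
  c(x_gb = x, autosome_gb = model$autosome_to_x_ratio * x)
}

#' Female-male genome size difference in megabases
#'
#' @param female_pg,male_pg Diploid genome sizes in picograms.
#' @param mode Conversion mode, see [pg_to_gb()].
#' @return Signed difference in Mb.
#' @export
sex_size_difference <- function(female_pg, male_pg,
                                mode = c("unit", "standard")) {
  if (female_pg < 0 || male_pg < 0) stopf("sizes must be non-negative")
  1000 * (pg_to_gb(female_pg, mode) - pg_to_gb(male_pg, mode))
}
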