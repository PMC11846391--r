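# Within/between-group mean K2P distances per family and conversion of
# divergence to time via T = K / (2r).

#' Dating configuration
#'
#' @param rate_r Substitution rate in changes per site per year.  The
#'   default, 1.11e-8, is the mean satellite turnover rate estimated for
#'   grasshopper satellitomes and assumes one generation per year.
#' @param generations_per_year Documentation-only field recording the
#'   generation-time assumption behind `rate_r`.
#' @return A `dating_config` list.
#' @export
dating_config <- function(rate_r = 1.11e-8, generations_per_year = 1) {
  if (rate_r <= 0) stopf("rate_r must be positive")
  structure(list(rate_r = rate_r,
                 generations_per_year = generations_per_year),
            class = "dating_config")
}

# K2P distance between two sequences.  Equal-length pairs (the common case:
# phase-anchored monomers) are compared positionally, which is the gapless
# global alignment; unequal lengths fall back to a gapped global alignment.
pair_k2p <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    k <- classify_subst(seq_chars(a), seq_chars(b))
  } else {
    st <- align_stats(a, b, type = "global")
    k <- list(sites = st$matches + st$transitions + st$transversions,
              transitions = st$transitions, transversions = st$transversions)
  }
  if (k$sites == 0) return(NA_real_)
  k2p_distance(k$transitions / k$sites, k$transversions / k$sites)
}

#' Mean pairwise K2P distance within or between monomer sets
#'
#' With one set, the mean K2P distance over all unordered pairs within it;
#' with two sets, the plain mean over all cross pairs (no net correction).
#' Saturated pairs are excluded from the mean and counted in the
#' `n_saturated` attribute.
#'
#' @param set_a Character vector of monomer sequences of one family.
#' @param set_b Optional second set for a between-group mean.
#' @return Mean distance (`NA` when undefined: fewer than 2 sequences
#'   within-mode, empty sets, or all pairs saturated), with attributes
#'   `n_pairs` and `n_saturated`.
#' @export
mean_pairwise_distance <- function(set_a, set_b = NULL) {
  set_a <- toupper(set_a)
  undefined <- function() structure(NA_real_, n_pairs = 0L, n_saturated = 0L)
  dists <- if (is.null(set_b)) {
    if (length(set_a) < 2L) return(undefined())
    pr <- utils::combn(length(set_a), 2L)
    vapply(seq_len(ncol(pr)), function(i)
      pair_k2p(set_a[pr[1, i]], set_a[pr[2, i]]), numeric(1))
  } else {
    set_b <- toupper(set_b)
    if (!length(set_a) || !length(set_b)) return(undefined())
    g <- expand.grid(i = seq_along(set_a), j = seq_along(set_b))
    vapply(seq_len(nrow(g)), function(r)
      pair_k2p(set_a[g$i[r]], set_b[g$j[r]]), numeric(1))
  }
  n_sat <- sum(is.na(dists))
  val <- if (all(is.na(dists))) NA_real_ else mean(dists, na.rm = TRUE)
  structure(val, n_pairs = length(dists), n_saturated = n_sat)
}

#' Convert a K2P divergence to a divergence time
#'
#' `T = K / (2 r)`: the distance between two diverging sequence sets splits
#' evenly over the two lineages, each evolving at rate `r` per site per
#' year.
#'
#' @param K K2P divergence (finite, non-negative).  `NA` (the saturation
#'   marker) propagates with a warning.
#' @param cfg A [dating_config()].
#' @return Time in years.
#' @export
divergence_time <- function(K, cfg = dating_config()) {
  stopifnot(inherits(cfg, "dating_config"))
  if (any(is.na(K))) warnf("saturated divergence: time undefined (NA)")
  if (any(K < 0, na.rm = TRUE)) stopf("K must be non-negative")
  K / (2 * cfg$rate_r)
}

#' Render years as millions of years, one decimal
#'
#' @param t_years Time in years.
#' @return Numeric, millions of years rounded to one decimal.
#' @export
format_mya <- function(t_years) round(t_years / 1e6, 1)

#' Per-family divergence report across sexes and sex chromosomes
#'
#' For every family with repeat unit shorter than the read length, extracts
#' phase-anchored monomers from each library and reports mean K2P distances
#' within males, within females, between the sexes, within X, within Y and
#' between X and Y, plus the X-Y divergence time `T = K / (2r)`.  Families
#' absent from a library yield `NA` in the affected columns.
#'
#' @param catalogue Catalogue data frame (`name`, `consensus`, `rul`).
#' @param libs Named list of [sat_library()] objects; names among `male`,
#'   `female`, `X`, `Y`.
#' @param cfg A [dating_config()].
#' @param max_rul Only families with `rul < max_rul` are reported (monomer
#'   extraction needs a full unit inside one read).
#' @param min_monomers Minimum extracted monomers for a within-group mean.
#' @return Data frame with one row per family and the six distance columns,
#'   `k_xy`, `t_xy_years` and `t_xy_mya`.
#' @export
sex_divergence_report <- function(catalogue, libs, cfg = dating_config(),
                                  max_rul = 151L, min_monomers = 2L) {
  stopifnot(is.data.frame(catalogue))
  read_len <- max(vapply(libs, function(l) max(nchar(l$seq), 0L), integer(1)))
  rows <- lapply(seq_len(nrow(catalogue)), function(i) {
    fam <- catalogue[i, ]
    if (fam$rul >= min(max_rul, read_len)) return(NULL)
    mono <- lapply(libs, function(l)
      extract_monomers(l, fam$consensus))
    w_mean <- function(set) {
      if (length(set) < min_monomers) NA_real_
      else as.numeric(mean_pairwise_distance(set))
    }
    b_mean <- function(a, b) {
      if (!length(a) || !length(b)) NA_real_
      else as.numeric(mean_pairwise_distance(a, b))
    }
    k_xy <- b_mean(mono$X, mono$Y)
    t_xy <- if (is.na(k_xy)) NA_real_ else
      suppressWarnings(divergence_time(k_xy, cfg))
    data.frame(family = fam$name %||% as.character(i),
               within_male = w_mean(mono$male),
               within_female = w_mean(mono$female),
               between_mf = b_mean(mono$male, mono$female),
               within_x = w_mean(mono$X),
               within_y = w_mean(mono$Y),
               k_xy = k_xy,
               t_xy_years = t_xy,
               t_xy_mya = if (is.na(t_xy)) NA_real_ else format_mya(t_xy))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(family = character(0), within_male = numeric(0),
                      within_female = numeric(0), between_mf = numeric(0),
                      within_x = numeric(0), within_y = numeric(0),
                      k_xy = numeric(0), t_xy_years = numeric(0),
                      t_xy_mya = numeric(0)))
  do.call(rbind, rows)
}
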