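# Read-level quantification: alignment of library reads to family dimer
# references, Kimura 2-parameter divergence, repeat landscapes and
# male/female/X/Y abundance comparisons.

#' Kimura 2-parameter distance
#'
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, where `P` and `Q` are the
#' proportions of transition and transversion sites over ungapped aligned
#' columns.  The correction accounts for multiple substitutions at one site,
#' so `K >= P + Q` whenever finite.  Saturated inputs (where a log argument
#' is non-positive) return `NA`, the saturation marker.
#'
#' @param P,Q Transition and transversion proportions; vectors recycled to a
#'   common length.  Both must be non-negative with `P + Q <= 1`.
#' @return Numeric vector of distances, `NA` where saturated.
#' @examples
#' k2p_distance(0.1, 0.05)
#' @export
k2p_distance <- function(P, Q) {
  if (any(P < 0 | Q < 0, na.rm = TRUE))
    stopf("P and Q must be non-negative")
  if (any(P + Q > 1 + 1e-12, na.rm = TRUE))
    stopf("P + Q must not exceed 1")
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  ok <- !is.na(a) & a > 0 & b > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- -0.5 * log(a[ok] * sqrt(b[ok]))
  out
}

# Resolve a family argument (catalogue data frame, named character vector or
# single string) into a named consensus vector.
family_consensi <- function(families) {
  if (is.data.frame(families)) {
    stopifnot(all(c("name", "consensus") %in% names(families)))
    return(stats::setNames(families$consensus, families$name))
  }
  if (is.character(families)) {
    if (is.null(names(families)) && length(families) == 1L)
      return(c(family = families))
    stopifnot(!is.null(names(families)))
    return(families)
  }
  stopf("families must be a catalogue data frame or named character vector")
}

# Batch alignment of reads to one family's head-to-tail repeated consensus
# (a dimer, tiled further when the monomer is shorter than the reads, so a
# full read always fits).  Reads are pre-filtered by shared k-mers, then
# aligned on both strands; hits must reach min_identity over alignment
# columns and cover min_cover_read of the read.  type "glocal" aligns the
# whole read within the reference (unbiased per-read divergence, used for
# landscapes); "local" allows read clipping (used for subtraction and
# screening).  Returns a hit table with transition / transversion counts
# and the per-hit K2P divergence from the consensus.
align_hits <- function(reads, consensus, min_identity = 0.7,
                       min_cover_read = 0.5, prefilter_k = 11L,
                       type = c("glocal", "local"), kmer_index = NULL) {
  type <- match.arg(type)
  L <- nchar(consensus)
  reps <- max(2L, ceiling((max(nchar(reads)) + L) / L))
  dimer <- strrep(consensus, reps)
  pf <- kmer_prefilter(reads, paste0(consensus, consensus),
                       k = min(prefilter_k, L), kmer_index = kmer_index,
                       return_strand = TRUE)
  cand <- which(pf$cand)
  empty <- data.frame(read_idx = integer(0), aligned_cols = integer(0),
                      matches = integer(0), transitions = integer(0),
                      transversions = integer(0), gap_cols = integer(0),
                      identity = numeric(0), coverage = numeric(0),
                      read_bases = integer(0), read_start = integer(0),
                      read_end = integer(0), ref_start = integer(0),
                      ref_end = integer(0), strand = character(0),
                      P = numeric(0), Q = numeric(0), k2p = numeric(0),
                      score = numeric(0))
  if (!length(cand)) return(empty)
  # Divergence estimation wants near-gapless alignments of what are tandem
  # substitution variants: permissive gap costs let the aligner absorb
  # substitution clusters into compensating gaps and bias K2P downward, so
  # the glocal path uses stiffer penalties than the hit-screening path.
  st <- if (type == "glocal")
    align_stats(reads[cand], dimer, type = "global-local",
                gap_opening = 4, gap_extension = 1,
                strand = pf$strand[cand])
  else align_stats(reads[cand], dimer, type = "local",
                   strand = pf$strand[cand])
  keep <- st$identity >= min_identity & st$coverage >= min_cover_read
  if (!any(keep)) return(empty)
  st <- st[keep, , drop = FALSE]
  sites <- st$matches + st$transitions + st$transversions
  P <- st$transitions / pmax(sites, 1L)
  Q <- st$transversions / pmax(sites, 1L)
  data.frame(read_idx = cand[st$read_idx],
             aligned_cols = st$aligned_cols, matches = st$matches,
             transitions = st$transitions, transversions = st$transversions,
             gap_cols = st$gap_cols, identity = st$identity,
             coverage = st$coverage,
             read_bases = st$read_end - st$read_start + 1L,
             read_start = st$read_start, read_end = st$read_end,
             ref_start = st$ref_start, ref_end = st$ref_end,
             strand = st$strand, P = P, Q = Q,
             k2p = k2p_distance(P, Q), score = st$score)
}

#' Align one read to a family dimer reference
#'
#' Aligns the read (both strands) against the family consensus concatenated
#' head-to-tail with itself, so reads spanning the junction between two
#' monomer copies align contiguously.  Substitution columns are classified
#' as transitions (A-G, C-T) or transversions, and the hit carries its K2P
#' divergence from the consensus (`NA` when saturated); `P` and `Q` are
#' computed over ungapped columns only.
#'
#' @param read A DNA string (or `sat_library` record sequence).
#' @param family Family consensus string, or a one-row catalogue data frame.
#' @param min_identity Minimum identity (matches / alignment columns).
#' @param min_cover_read Minimum fraction of the read covered by the hit.
#' @return A one-row hit data frame, or `NULL` when no alignment meets the
#'   thresholds.
#' @export
align_to_dimer <- function(read, family, min_identity = 0.7,
                           min_cover_read = 0.5) {
  cons <- family_consensi(family)[1]
  h <- align_hits(toupper(read), cons, min_identity, min_cover_read,
                  prefilter_k = min(11L, nchar(cons)))
  if (!nrow(h)) return(NULL)
  h
}

#' Estimate genomic proportions of satellite families in a library
#'
#' Aligns (a sample of) the library's reads against every family's dimer
#' reference and attributes each read's aligned bases to its best-scoring
#' family (score ties broken by catalogue order, which is abundance rank
#' after naming).  The abundance of a family is the percent of all sampled
#' nucleotides attributed to it, so proportions never double-count and sum
#' to at most 100.
#'
#' @param lib A [sat_library()].
#' @param families Catalogue data frame or named consensus vector.
#' @param sample_pairs Optional number of records to subsample first.
#' @param seed Seed for the subsample.
#' @param min_identity,min_cover_read Hit thresholds (see
#'   [align_to_dimer()]).
#' @param prefilter_k Shared k-mer length of the alignment pre-filter.
#'   Smaller k improves recall of highly diverged copies (a read needs one
#'   intact k-mer to be considered) at the cost of aligning more background
#'   reads; 10-11 suits divergences up to ~30%.
#' @return A list of class `sat_quant`: `abundance` (named percent vector),
#'   `hits` (per-family hit tables with attributed reads only),
#'   `total_bases` (sampled nucleotides) and `label`.
#' @export
quantify_library <- function(lib, families, sample_pairs = NULL, seed = 1L,
                             min_identity = 0.7, min_cover_read = 0.5,
                             prefilter_k = 11L) {
  stopifnot(inherits(lib, "sat_library"))
  cons <- family_consensi(families)
  if (!is.null(sample_pairs) && sample_pairs < length(lib))
    lib <- sample_reads(lib, sample_pairs, seed = seed)
  reads <- unname(reads_of(lib))
  total_bases <- sum(nchar(reads))
  ki <- kmer_codes(reads, prefilter_k)
  hits <- lapply(cons, function(cs) align_hits(reads, cs, min_identity,
                                               min_cover_read,
                                               prefilter_k = prefilter_k,
                                               kmer_index = ki))
  # Best-hit attribution: one family per read.
  if (length(hits) > 1L) {
    all_h <- do.call(rbind, Map(function(h, f) {
      if (nrow(h)) cbind(h, family = f) else NULL
    }, hits, names(hits)))
    if (!is.null(all_h) && nrow(all_h)) {
      fam_rank <- match(all_h$family, names(cons))
      ord <- order(all_h$read_idx, -all_h$score, fam_rank)
      all_h <- all_h[ord, ]
      best <- all_h[!duplicated(all_h$read_idx), ]
      hits <- lapply(names(cons), function(f)
        best[best$family == f, setdiff(names(best), "family"), drop = FALSE])
      names(hits) <- names(cons)
    }
  }
  abundance <- vapply(hits, function(h) 100 * sum(h$read_bases) / total_bases,
                      numeric(1))
  structure(list(abundance = abundance, hits = hits,
                 total_bases = total_bases, label = lib$label),
            class = "sat_quant")
}

#' Genomic proportion of families in a library
#'
#' Convenience wrapper around [quantify_library()] returning only the
#' abundance percentages.
#'
#' @inheritParams quantify_library
#' @return Named numeric vector of percentages.
#' @export
genomic_proportion <- function(lib, families, sample_pairs = NULL, seed = 1L,
                               min_identity = 0.7, min_cover_read = 0.5,
                               prefilter_k = 11L) {
  quantify_library(lib, families, sample_pairs, seed,
                   min_identity, min_cover_read, prefilter_k)$abundance
}

#' Repeat landscape of one family in one library
#'
#' Bins each hit's aligned read bases by its K2P divergence from the
#' consensus (1% bins over 0-50%, saturated hits in an overflow bin) and
#' normalizes by the total sampled nucleotides, so the bin masses sum
#' exactly to the family's abundance estimate.
#'
#' @param quant A `sat_quant` from [quantify_library()], or a hit data frame.
#' @param family Family name (when `quant` is a `sat_quant`).
#' @param total_bases Total sampled nucleotides (required for a raw hit
#'   table).
#' @param library_label Library label for the output table.
#' @param bin_width Bin width in percent divergence.
#' @param max_div Upper edge of the binned range, in percent.
#' @return Data frame: `family`, `library`, `bin_low`, `bin_high` (percent,
#'   the final row is the saturation overflow bin) and `abundance_percent`.
#' @export
repeat_landscape <- function(quant, family = NULL, total_bases = NULL,
                             library_label = NULL, bin_width = 1,
                             max_div = 50) {
  if (inherits(quant, "sat_quant")) {
    stopifnot(!is.null(family))
    hits <- quant$hits[[family]]
    total_bases <- quant$total_bases
    library_label <- library_label %||% quant$label
  } else {
    hits <- quant
    family <- family %||% "family"
    if (is.null(total_bases)) stopf("total_bases required with a hit table")
    library_label <- library_label %||% "library"
  }
  edges <- seq(0, max_div, by = bin_width)
  n_bins <- length(edges) - 1L
  mass <- numeric(n_bins + 1L)  # final element = overflow (saturated / >max)
  if (!is.null(hits) && nrow(hits)) {
    pct <- 100 * hits$k2p
    over <- is.na(pct) | pct >= max_div
    if (any(!over)) {
      bin <- pmin(floor(pct[!over] / bin_width) + 1L, n_bins)
      mass[seq_len(n_bins)] <- as.numeric(
        tapply(hits$read_bases[!over], factor(bin, levels = seq_len(n_bins)),
               sum, default = 0))
    }
    mass[n_bins + 1L] <- sum(hits$read_bases[over])
  }
  data.frame(family = family, library = library_label,
             bin_low = c(edges[-length(edges)], max_div),
             bin_high = c(edges[-1], Inf),
             abundance_percent = 100 * mass / total_bases)
}

#' Locate peaks in a repeat landscape
#'
#' Smooths the binned abundances with a centered moving average and returns
#' the divergence (bin midpoint, percent) of local maxima above a relative
#' abundance floor.  The overflow bin is ignored.
#'
#' @param landscape Output of [repeat_landscape()].
#' @param min_rel Minimum peak height as a fraction of the largest bin.
#' @param smooth Moving-average window (odd integer; 1 disables smoothing).
#' @param min_separation Maxima closer than this (percent divergence) are
#'   merged, keeping the higher one; absorbs bin-level sampling noise on
#'   broad peaks.
#' @return Numeric vector of peak positions in percent divergence.
#' @export
find_landscape_peaks <- function(landscape, min_rel = 0.1, smooth = 5L,
                                 min_separation = 5) {
  x <- landscape$abundance_percent[is.finite(landscape$bin_high)]
  mid <- (landscape$bin_low + landscape$bin_high)[is.finite(landscape$bin_high)] / 2
  n <- length(x)
  if (n < 3L || all(x == 0)) return(numeric(0))
  if (smooth > 1L) {
    half <- smooth %/% 2L
    x <- vapply(seq_len(n), function(i) {
      mean(x[max(1L, i - half):min(n, i + half)])
    }, numeric(1))
  }
  floor_h <- min_rel * max(x)
  peaks <- which(x >= floor_h &
                   x > c(-Inf, x[-n]) &
                   x >= c(x[-1], -Inf))
  if (!length(peaks)) return(numeric(0))
  # Merge nearby maxima, strongest first.
  keep <- integer(0)
  for (p in peaks[order(-x[peaks])]) {
    if (!length(keep) || all(abs(mid[p] - mid[keep]) >= min_separation))
      keep <- c(keep, p)
  }
  # Refine each peak as the local mass centroid: the raw argmax of a skewed,
  # noisy bump is biased toward its light side, the centroid is not.
  refined <- vapply(keep, function(p) {
    w <- max(1L, p - 3L):min(n, p + 3L)
    sum(mid[w] * x[w]) / sum(x[w])
  }, numeric(1))
  sort(refined)
}

#' Compare family abundances across libraries
#'
#' Computes male/female, female/male and X/Y abundance ratios per family and
#' flags sex-biased families.  A zero denominator with a non-zero numerator
#' reports `Inf`.
#'
#' @param abundance A families x libraries numeric matrix or data frame of
#'   abundance percentages; column names must include the requested library
#'   labels.
#' @param male,female,x,y Column names of the four libraries; `x`/`y` may be
#'   `NULL` when microdissected libraries are absent.
#' @param ratio_threshold Ratio above which a family is flagged male- or
#'   female-biased.
#' @return Data frame with one row per family: abundances, `mf_ratio`,
#'   `fm_ratio`, `xy_ratio`, `male_biased`, `female_biased`.
#' @export
compare_libraries <- function(abundance, male = "male", female = "female",
                              x = "X", y = "Y", ratio_threshold = 2) {
  ab <- as.matrix(abundance)
  for (lbl in c(male, female)) {
    if (!lbl %in% colnames(ab)) stopf("missing library column '%s'", lbl)
  }
  ratio <- function(a, b) ifelse(b == 0, ifelse(a == 0, NA_real_, Inf), a / b)
  mf <- ratio(ab[, male], ab[, female])
  fm <- ratio(ab[, female], ab[, male])
  out <- data.frame(family = rownames(ab),
                    male = ab[, male], female = ab[, female],
                    mf_ratio = mf, fm_ratio = fm, row.names = NULL)
  if (!is.null(x) && !is.null(y) && all(c(x, y) %in% colnames(ab))) {
    out$X <- ab[, x]; out$Y <- ab[, y]
    out$xy_ratio <- ratio(ab[, x], ab[, y])
  }
  out$male_biased <- !is.na(mf) & mf > ratio_threshold
  out$female_biased <- !is.na(fm) & fm > ratio_threshold
  out
}
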