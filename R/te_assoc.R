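# Screening of family consensuses against a user-supplied transposable
# element library: local hits, consensus coverage and best similarity.

#' Local alignments of a consensus against a TE library
#'
#' Locally aligns the consensus (both strands) against every entry of the
#' TE library and reports hits above `min_score`, with 1-based inclusive
#' intervals on the consensus.
#'
#' @param consensus Family consensus DNA string.
#' @param te_lib Path to a TE FASTA file or a named character vector.
#' @param min_score Minimum local alignment score (match +1, mismatch -1,
#'   gap open -2, extension -0.5).
#' @return Data frame of hits: `te_id`, `start`, `end` (consensus
#'   coordinates), `identity`, `score`, `strand`.
#' @export
local_hits <- function(consensus, te_lib, min_score = 20) {
  consensus <- toupper(consensus)
  tes <- if (is.character(te_lib) && length(te_lib) == 1L &&
             file.exists(te_lib)) {
    lib <- read_fastx(te_lib, "fasta")
    stats::setNames(lib$seq, lib$id)
  } else {
    stopifnot(is.character(te_lib), length(te_lib) > 0L)
    stats::setNames(toupper(te_lib),
                    names(te_lib) %||% paste0("TE", seq_along(te_lib)))
  }
  rows <- lapply(names(tes), function(id) {
    st <- align_stats(consensus, tes[[id]], type = "local")
    if (!nrow(st) || st$score < min_score) return(NULL)
    data.frame(te_id = id, start = st$read_start, end = st$read_end,
               identity = st$identity, score = st$score, strand = st$strand)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(te_id = character(0), start = integer(0),
                      end = integer(0), identity = numeric(0),
                      score = numeric(0), strand = character(0)))
  do.call(rbind, rows)
}

#' Consensus coverage and best similarity from TE hits
#'
#' Coverage is the percent of consensus positions inside the union of hit
#' intervals; similarity is the best single-hit identity, as a percent.
#'
#' @param hits Hit table from [local_hits()] for one consensus.
#' @param consensus_len Consensus length in bp.
#' @return Named numeric vector `c(coverage_percent, best_similarity_percent)`.
#' @export
coverage_similarity <- function(hits, consensus_len) {
  if (is.null(hits) || !nrow(hits))
    return(c(coverage_percent = 0, best_similarity_percent = 0))
  ir <- IRanges::reduce(IRanges::IRanges(start = hits$start, end = hits$end))
  covered <- sum(IRanges::width(ir))
  c(coverage_percent = 100 * covered / consensus_len,
    best_similarity_percent = 100 * max(hits$identity))
}

#' TE-association report for a family catalogue
#'
#' Screens every family consensus against the TE library and flags families
#' whose coverage or best similarity exceed the reporting thresholds.
#'
#' @param catalogue Catalogue data frame (`name`, `consensus`).
#' @param te_lib Path to TE FASTA or named character vector.
#' @param min_score Passed to [local_hits()].
#' @param flag_coverage,flag_similarity Reporting thresholds in percent.
#' @return Data frame: `family`, `best_te`, `coverage_percent`,
#'   `best_similarity_percent`, `flag_coverage`, `flag_similarity`.
#' @export
te_association <- function(catalogue, te_lib, min_score = 20,
                           flag_coverage = 50, flag_similarity = 60) {
  stopifnot(is.data.frame(catalogue))
  rows <- lapply(seq_len(nrow(catalogue)), function(i) {
    hits <- local_hits(catalogue$consensus[i], te_lib, min_score)
    cs <- coverage_similarity(hits, nchar(catalogue$consensus[i]))
    best <- if (nrow(hits)) hits$te_id[which.max(hits$identity)]
            else NA_character_
    data.frame(family = catalogue$name[i] %||% as.character(i),
               best_te = best,
               coverage_percent = unname(cs[1]),
               best_similarity_percent = unname(cs[2]),
               flag_coverage = unname(cs[1] > flag_coverage),
               flag_similarity = unname(cs[2] > flag_similarity))
  })
  do.call(rbind, rows)
}
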