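# Internal alignment and k-mer machinery shared by discovery, classification,
# quantification and the TE screen.  All gapped alignment is delegated to
# Biostrings::pairwiseAlignment; this file only adds strand handling and
# column bookkeeping (match / transition / transversion / gap counts).

# Scoring: match +1, mismatch -1; first gap position costs 2, each further
# position 0.5 (Biostrings charges opening + extension on the first position).
sat_submat <- function() {
  b <- c(DNA_BASES, "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", ] <- -1; m[, "N"] <- -1
  m
}

# Extract all k-mers of a set of strings.  Returns parallel vectors:
# idx (string index), kmer, and canonical kmer (lexicographic min of the
# k-mer and its reverse complement).
string_kmers <- function(x, k, canonical = TRUE) {
  lens <- nchar(x)
  nk <- pmax(lens - k + 1L, 0L)
  if (sum(nk) == 0L)
    return(list(idx = integer(0), kmer = character(0), canon = character(0)))
  idx <- rep(seq_along(x), nk)
  pos <- sequence(nk)
  kmer <- substring(x[idx], pos, pos + k - 1L)
  out <- list(idx = idx, kmer = kmer)
  if (canonical) {
    xrc <- revcomp(x)
    rc_start <- lens[idx] - (pos + k - 1L) + 1L
    kmer_rc <- substring(xrc[idx], rc_start, rc_start + k - 1L)
    out$canon <- ifelse(kmer <= kmer_rc, kmer, kmer_rc)
  }
  out
}

# Numeric 2-bit encodings of all canonical k-mers of a string set (k <= 26
# keeps 4^k exactly representable in a double).  Windows containing N are
# dropped.  Returns parallel vectors idx (string index) and code (canonical
# = min of forward and reverse-complement encodings).  Roughly an order of
# magnitude faster than materializing k-mer strings.
kmer_codes <- function(x, k) {
  lens <- nchar(x)
  nk <- pmax(lens - k + 1L, 0L)
  if (sum(nk) == 0L) return(list(idx = integer(0), code = numeric(0)))
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L; lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L; lut[utf8ToInt("T") + 1L] <- 3L
  codes <- lut[as.integer(charToRaw(paste(x, collapse = ""))) + 1L]
  offs <- cumsum(c(0L, lens))
  idx <- rep(seq_along(x), nk)
  gstart <- rep(offs[-length(offs)], nk) + sequence(nk)  # global window start
  fwd <- numeric(length(gstart)); rcv <- numeric(length(gstart))
  for (j in seq_len(k)) {
    cj <- codes[gstart + j - 1L]
    fwd <- fwd + cj * 4^(k - j)
    rcv <- rcv + (3 - cj) * 4^(j - 1)
  }
  ok <- !is.na(fwd) & !is.na(rcv)
  list(idx = idx[ok], code = pmin(fwd[ok], rcv[ok]), fwd = fwd[ok],
       rc = rcv[ok])
}

# Logical vector: does each read share at least min_shared canonical k-mers
# (either strand) with the reference sequence?  Used as a cheap pre-filter
# before full alignment.  A precomputed kmer_codes() index for the reads can
# be passed to avoid re-extraction across references.
kmer_prefilter <- function(reads, ref, k = 11L, min_shared = 1L,
                           kmer_index = NULL, return_strand = FALSE) {
  if (length(reads) == 0L) {
    return(if (return_strand)
      list(cand = logical(0), strand = character(0)) else logical(0))
  }
  rk <- kmer_codes(ref, k)
  km <- kmer_index %||% kmer_codes(reads, k)
  hit <- km$code %in% unique(rk$code)
  counts <- tabulate(km$idx[hit], nbins = length(reads))
  cand <- counts >= min_shared
  if (!return_strand) return(cand)
  # Strand vote: forward read k-mers matching the reference's forward
  # encodings argue "+", matches to its reverse-complement encodings "-".
  nf <- tabulate(km$idx[km$fwd %in% unique(rk$fwd)], nbins = length(reads))
  nr <- tabulate(km$idx[km$fwd %in% unique(rk$rc)], nbins = length(reads))
  list(cand = cand, strand = ifelse(nr > nf, "-", "+"))
}

# Align reads against a single reference and return one row per read.  With
# strand = NULL both strands are aligned and the better one kept; a
# per-read strand vector (e.g. from the k-mer strand vote) aligns each read
# once.  type is passed to pairwiseAlignment ("local" for hit finding,
# "global" / "global-local" for identity and divergence work).
align_stats <- function(reads, ref, type = "local",
                        gap_opening = 1.5, gap_extension = 0.5,
                        strand = NULL) {
  n <- length(reads)
  empty <- data.frame(score = numeric(0), strand = character(0),
                      read_start = integer(0), read_end = integer(0),
                      ref_start = integer(0), ref_end = integer(0),
                      aligned_cols = integer(0), matches = integer(0),
                      transitions = integer(0), transversions = integer(0),
                      gap_cols = integer(0), identity = numeric(0),
                      coverage = numeric(0))
  if (n == 0L) return(empty)
  sm <- sat_submat()
  run <- function(x) {
    Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(x),
                                  Biostrings::DNAString(ref),
                                  type = type, substitutionMatrix = sm,
                                  gapOpening = gap_opening,
                                  gapExtension = gap_extension)
  }
  # Whole-set vectorized statistics for one strand's alignments; avoids
  # per-alignment S4 subsetting, which dominates runtime otherwise.
  strand_stats <- function(aln) {
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    ni <- Biostrings::nindel(aln)
    alen <- nm + nmm + Biostrings::insertion(ni)[, "WidthSum"] +
      Biostrings::deletion(ni)[, "WidthSum"]
    mt <- Biostrings::mismatchTable(aln)
    ts <- tv <- integer(length(aln))
    if (nrow(mt)) {
      pch <- as.character(mt$PatternSubstring)
      sch <- as.character(mt$SubjectSubstring)
      base_pair <- pch %in% DNA_BASES & sch %in% DNA_BASES
      is_ts <- base_pair & ((pch %in% PURINES) == (sch %in% PURINES))
      ts <- tabulate(mt$PatternId[is_ts], length(aln))
      tv <- tabulate(mt$PatternId[base_pair & !is_ts], length(aln))
    }
    p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
    list(score = Biostrings::score(aln), alen = alen, nm = nm,
         gap = alen - nm - nmm, ts = ts, tv = tv,
         ps = Biostrings::start(p), pe = Biostrings::end(p),
         ss = Biostrings::start(s), se = Biostrings::end(s))
  }
  if (is.null(strand)) {
    fwd <- strand_stats(run(reads))
    rev <- strand_stats(run(revcomp(reads)))
    use_rev <- rev$score > fwd$score
    pick <- function(field) ifelse(use_rev, rev[[field]], fwd[[field]])
  } else {
    use_rev <- strand == "-"
    fi <- which(!use_rev); ri <- which(use_rev)
    fwd <- if (length(fi)) strand_stats(run(reads[fi])) else NULL
    rev <- if (length(ri)) strand_stats(run(revcomp(reads[ri]))) else NULL
    pick <- function(field) {
      v <- numeric(n)
      if (length(fi)) v[fi] <- fwd[[field]]
      if (length(ri)) v[ri] <- rev[[field]]
      v
    }
  }
  read_len <- nchar(reads)
  ps <- pick("ps"); pe <- pick("pe")
  # Report read coordinates on the original (forward) read.
  rs <- ifelse(use_rev, read_len - pe + 1L, ps)
  re <- ifelse(use_rev, read_len - ps + 1L, pe)
  out <- data.frame(score = pick("score"),
                    strand = ifelse(use_rev, "-", "+"),
                    read_start = as.integer(rs), read_end = as.integer(re),
                    ref_start = as.integer(pick("ss")),
                    ref_end = as.integer(pick("se")),
                    aligned_cols = as.integer(pick("alen")),
                    matches = as.integer(pick("nm")),
                    transitions = as.integer(pick("ts")),
                    transversions = as.integer(pick("tv")),
                    gap_cols = as.integer(pick("gap")),
                    row.names = NULL)
  out$identity <- out$matches / pmax(out$aligned_cols, 1L)
  out$coverage <- (re - rs + 1) / pmax(read_len, 1L)
  out$read_idx <- seq_along(reads)
  out
}
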