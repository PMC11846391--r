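# Sequence data model, FASTA/FASTQ I/O, quality trimming and subsampling.

LIBRARY_ROLES <- c("male_genome", "female_genome", "X_chromosome",
                   "Y_chromosome", "custom")

#' Construct a read library
#'
#' A `sat_library` holds a set of (optionally paired) reads: ids, uppercase
#' DNA sequences and optional per-base Phred qualities stored as Phred+33
#' strings.  Paired libraries carry a second, parallel set of mate sequences;
#' mates always stay synchronized through trimming and subsampling.
#'
#' @param id Character vector of read (pair) identifiers.
#' @param seq Character vector of DNA sequences (R1 for paired data).
#' @param qual Optional Phred+33 quality strings, same lengths as `seq`.
#' @param seq2,qual2 Optional mate sequences/qualities for paired data.
#' @param label Library label used in reports.
#' @param role One of `"male_genome"`, `"female_genome"`, `"X_chromosome"`,
#'   `"Y_chromosome"` or `"custom"`.
#' @param masked Optional logical soft-mask flags (one per record), recording
#'   lowercase (masked) input spans seen during parsing.
#' @return An object of class `sat_library`.
#' @export
sat_library <- function(id, seq, qual = NULL, seq2 = NULL, qual2 = NULL,
                        label = "library", role = "custom", masked = NULL) {
  role <- match.arg(role, LIBRARY_ROLES)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stopf("id and seq lengths differ (%d vs %d)", length(id), length(seq))
  if (!all(is_dna(seq)))
    stopf("sequences contain non-ACGTN characters (first offender: record %d)",
          which(!is_dna(seq))[1])
  check_qual <- function(q, s, what) {
    if (is.null(q)) return(NULL)
    q <- as.character(q)
    if (length(q) != length(s))
      stopf("%s quality count differs from sequence count", what)
    bad <- which(nchar(q) != nchar(s))
    if (length(bad))
      stopf("%s quality/sequence length mismatch at record %d", what, bad[1])
    q
  }
  qual <- check_qual(qual, seq, "R1")
  paired <- !is.null(seq2)
  if (paired) {
    seq2 <- toupper(as.character(seq2))
    if (length(seq2) != length(seq))
      stopf("paired mate streams have unequal record counts (%d vs %d)",
            length(seq), length(seq2))
    if (!all(is_dna(seq2))) stopf("mate sequences contain non-ACGTN characters")
    qual2 <- check_qual(qual2, seq2, "R2")
  } else qual2 <- NULL
  structure(list(label = label, role = role, paired = paired,
                 id = id, seq = seq, qual = qual,
                 seq2 = seq2, qual2 = qual2,
                 masked = masked %||% rep(FALSE, length(id))),
            class = "sat_library")
}

#' @export
print.sat_library <- function(x, ...) {
  cat(sprintf("<sat_library> %s (role: %s): %d %s\n", x$label, x$role,
              length(x$id), if (x$paired) "read pairs" else "reads"))
  invisible(x)
}

#' @export
length.sat_library <- function(x) length(x$id)

# Subset a library by record index, keeping mates together.
subset_library <- function(lib, idx) {
  lib$id <- lib$id[idx]; lib$seq <- lib$seq[idx]
  lib$masked <- lib$masked[idx]
  if (!is.null(lib$qual)) lib$qual <- lib$qual[idx]
  if (lib$paired) {
    lib$seq2 <- lib$seq2[idx]
    if (!is.null(lib$qual2)) lib$qual2 <- lib$qual2[idx]
  }
  lib
}

#' Flatten a library to individual reads
#'
#' Returns all reads of a library as a character vector; for paired libraries
#' both mates are returned, with `/1` and `/2` id suffixes.
#'
#' @param lib A [sat_library()].
#' @return Named character vector of read sequences.
#' @export
reads_of <- function(lib) {
  stopifnot(inherits(lib, "sat_library"))
  if (!lib$paired) return(stats::setNames(lib$seq, lib$id))
  stats::setNames(c(lib$seq, lib$seq2),
                  c(paste0(lib$id, "/1"), paste0(lib$id, "/2")))
}

#' Read sequences from FASTA or FASTQ
#'
#' Parses a (possibly gzipped) FASTA or FASTQ file into a single-end
#' [sat_library()].  Sequences are uppercased on ingestion; records containing
#' lowercase (soft-masked) input are flagged in the `masked` field.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @param label,role Passed to [sat_library()].
#' @return A `sat_library`.
#' @export
read_fastx <- function(path, format = c("auto", "fasta", "fastq"),
                       label = basename(path), role = "custom") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  parsed <- tryCatch({
    if (format == "fastq") {
      x <- Biostrings::readBStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
      list(id = names(x), seq = as.character(x),
           qual = as.character(S4Vectors::mcols(x)$qualities))
    } else {
      x <- Biostrings::readBStringSet(path, format = "fasta")
      list(id = names(x), seq = as.character(x), qual = NULL)
    }
  }, error = function(e) stopf("failed to parse %s as %s: %s",
                               path, format, conditionMessage(e)))
  # First whitespace token is the record id.
  parsed$id <- sub("\\s.*$", "", parsed$id)
  masked <- grepl("[acgtn]", parsed$seq)
  bad <- which(!is_dna(toupper(parsed$seq)))
  if (length(bad))
    stopf("malformed record %d in %s: non-DNA characters", bad[1], path)
  if (!is.null(parsed$qual)) {
    bad <- which(nchar(parsed$qual) != nchar(parsed$seq))
    if (length(bad))
      stopf("format error at record %d in %s: quality length != sequence length",
            bad[1], path)
  }
  sat_library(parsed$id, parsed$seq, qual = parsed$qual,
              label = label, role = role, masked = masked)
}

#' Read a paired-end FASTQ library
#'
#' @param path1,path2 R1 and R2 FASTQ paths.
#' @param label,role Passed to [sat_library()].
#' @return A paired `sat_library`.
#' @export
read_paired_fastq <- function(path1, path2, label = basename(path1),
                              role = "custom") {
  r1 <- read_fastx(path1, "fastq")
  r2 <- read_fastx(path2, "fastq")
  if (length(r1) != length(r2))
    stopf("paired files have unequal record counts (%d vs %d)",
          length(r1), length(r2))
  sat_library(sub("/1$", "", r1$id), r1$seq, r1$qual, r2$seq, r2$qual,
              label = label, role = role)
}

#' Write a library to FASTA or FASTQ
#'
#' Single-end libraries write one file; paired libraries require two paths.
#'
#' @param lib A [sat_library()].
#' @param path Output path (R1 for paired data).
#' @param path2 R2 output path for paired data.
#' @param format `"auto"`, `"fasta"` or `"fastq"`; FASTQ requires qualities.
#' @return Invisibly, the path(s) written.
#' @export
write_fastx <- function(lib, path, path2 = NULL,
                        format = c("auto", "fasta", "fastq")) {
  stopifnot(inherits(lib, "sat_library"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  write_one <- function(id, seq, qual, p) {
    x <- Biostrings::DNAStringSet(seq)
    names(x) <- id
    if (format == "fastq") {
      if (is.null(qual)) stopf("FASTQ output requires qualities")
      Biostrings::writeXStringSet(x, p, format = "fastq",
                                  qualities = Biostrings::BStringSet(qual))
    } else {
      Biostrings::writeXStringSet(x, p, format = "fasta", width = 80L)
    }
    p
  }
  if (lib$paired) {
    if (is.null(path2)) stopf("paired library needs path2")
    out <- c(write_one(paste0(lib$id, "/1"), lib$seq, lib$qual, path),
             write_one(paste0(lib$id, "/2"), lib$seq2, lib$qual2, path2))
  } else {
    out <- write_one(lib$id, lib$seq, lib$qual, path)
  }
  invisible(out)
}

#' Quality-trimming parameters
#'
#' Defaults reproduce the common read-cleaning recipe for 150 bp satellite
#' screening runs: clip leading/trailing bases below Q3, cut at the first
#' 4-base window with mean quality below 20, discard reads shorter than
#' 100 bases and crop survivors to 101 bases.
#'
#' @param leading_q,trailing_q Quality below which leading/trailing bases are
#'   removed.
#' @param window_len,window_q Sliding-window length and mean-quality cutoff.
#' @param min_len Minimum post-trim read length; shorter reads are dropped.
#' @param crop Maximum retained length applied after the length filter.
#' @return A `trim_params` list.
#' @export
trim_params <- function(leading_q = 3, trailing_q = 3, window_len = 4,
                        window_q = 20, min_len = 100, crop = 101) {
  p <- list(leading_q = leading_q, trailing_q = trailing_q,
            window_len = as.integer(window_len), window_q = window_q,
            min_len = as.integer(min_len), crop = as.integer(crop))
  if (any(unlist(p) < 0)) stopf("trim parameters must be >= 0")
  if (p$window_len < 1L) stopf("window_len must be >= 1")
  structure(p, class = "trim_params")
}

# Trim a single read; returns retained length (0 = dropped) applying, in
# order: LEADING, TRAILING, SLIDINGWINDOW (cut before the first failing
# window's start), MINLEN, then CROP.
trim_one <- function(q, p) {
  n <- length(q)
  lo <- 1L
  while (lo <= n && q[lo] < p$leading_q) lo <- lo + 1L
  hi <- n
  while (hi >= lo && q[hi] < p$trailing_q) hi <- hi - 1L
  if (lo > hi) return(c(0L, 0L))
  q <- q[lo:hi]
  n <- length(q)
  if (n >= p$window_len) {
    cs <- cumsum(c(0, q))
    means <- (cs[(p$window_len + 1L):(n + 1L)] - cs[1:(n - p$window_len + 1L)]) /
      p$window_len
    fail <- which(means < p$window_q)
    if (length(fail)) {
      n <- fail[1] - 1L
      if (n == 0L) return(c(0L, 0L))
    }
  }
  if (n < p$min_len) return(c(0L, 0L))
  c(lo, lo + min(n, p$crop) - 1L)
}

#' Quality-trim a read library
#'
#' Applies, per read and in order: removal of leading then trailing bases
#' below the respective quality cutoffs; a 5'-to-3' sliding-window scan that
#' cuts the read at the start of the first window whose mean quality falls
#' below `window_q`; a minimum-length filter; and a final crop.  For paired
#' libraries a pair is dropped whenever either mate is dropped, keeping the
#' two streams synchronized.
#'
#' @param lib A [sat_library()] whose records all carry qualities.
#' @param p A [trim_params()] object.
#' @return The trimmed `sat_library`.
#' @export
quality_trim <- function(lib, p = trim_params()) {
  stopifnot(inherits(lib, "sat_library"), inherits(p, "trim_params"))
  if (is.null(lib$qual)) stopf("quality_trim requires per-base qualities")
  if (lib$paired && is.null(lib$qual2))
    stopf("quality_trim requires qualities on both mates")
  trim_set <- function(seq, qual) {
    bounds <- vapply(qual, function(q) trim_one(qual_to_int(q), p), integer(2))
    keep <- bounds[1, ] > 0L
    list(keep = keep,
         seq = substr(seq, bounds[1, ], bounds[2, ]),
         qual = substr(qual, bounds[1, ], bounds[2, ]))
  }
  t1 <- trim_set(lib$seq, lib$qual)
  if (lib$paired) {
    t2 <- trim_set(lib$seq2, lib$qual2)
    keep <- t1$keep & t2$keep
    out <- lib
    out$seq <- t1$seq[keep]; out$qual <- t1$qual[keep]
    out$seq2 <- t2$seq[keep]; out$qual2 <- t2$qual[keep]
  } else {
    keep <- t1$keep
    out <- lib
    out$seq <- t1$seq[keep]; out$qual <- t1$qual[keep]
  }
  out$id <- lib$id[keep]
  out$masked <- lib$masked[keep]
  out
}

#' Canonical form of a tandem-repeat monomer
#'
#' Two monomers describing the same circular repeat can differ by rotation
#' and/or strand.  The canonical form is the lexicographically smallest string
#' among all rotations of the sequence and all rotations of its reverse
#' complement, making rotations and strand flips of one monomer compare equal.
#'
#' @param seq A non-empty DNA string over `{A,C,G,T}`.
#' @return The canonical monomer string.
#' @examples
#' canonical_monomer("GTTAC") == canonical_monomer("TACGT")
#' @export
canonical_monomer <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stopf("canonical_monomer needs one non-empty string")
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    stopf("canonical_monomer requires an unambiguous A/C/G/T sequence")
  min(c(rotations(seq), rotations(revcomp(seq))))
}

#' Subsample read pairs uniformly without replacement
#'
#' @param lib A [sat_library()].
#' @param n_pairs Number of records (pairs for paired data) to draw.
#' @param seed Integer seed; identical `(n_pairs, seed)` yield identical
#'   samples.
#' @return The subsampled `sat_library`.
#' @export
sample_reads <- function(lib, n_pairs, seed = 1L) {
  stopifnot(inherits(lib, "sat_library"))
  n <- length(lib)
  if (n_pairs > n)
    stopf("requested %d records but library holds %d", n_pairs, n)
  idx <- with_seed(seed, sample.int(n, n_pairs))
  subset_library(lib, sort(idx))
}
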