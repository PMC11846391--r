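# Satellite discovery from unassembled reads: graph-based read clustering,
# tandem consensus inference via the cluster's de Bruijn cycle, read
# subtraction, and the discover-subtract iteration that runs until no new
# satellite candidate emerges.

#' Cluster reads by shared canonical k-mers
#'
#' Builds the read graph in which two reads are joined when they share at
#' least `min_shared` canonical k-mers, and returns its connected components
#' that hold at least `min_cluster_fraction` of the sampled nucleotides,
#' sorted by decreasing size.  Reads from a high-copy tandem family share
#' their monomer k-mers and collapse into one large component, while
#' single-copy background reads form only small chance components.
#'
#' @param reads A [sat_library()] or character vector of read sequences.
#' @param k Odd k-mer size between 11 and 31.
#' @param min_shared Minimum number of distinct shared canonical k-mers.
#' @param min_cluster_fraction Minimum fraction of sampled nucleotides a
#'   component must hold to be reported.
#' @return List of `read_cluster` objects: `read_idx`, `read_ids`,
#'   `n_reads`, `nucleotides`, `sampled_fraction`.
#' @export
cluster_reads <- function(reads, k = 21L, min_shared = 1L,
                          min_cluster_fraction = 5e-4) {
  if (inherits(reads, "sat_library")) reads <- reads_of(reads)
  if (length(reads) == 0L) stopf("no reads to cluster")
  if (k %% 2L == 0L || k < 11L || k > 31L)
    stopf("k must be odd and within [11, 31]")
  if (k > max(nchar(reads)))
    stopf("k = %d exceeds the longest read (%d bp)", k, max(nchar(reads)))
  ids <- names(reads) %||% as.character(seq_along(reads))
  reads <- unname(toupper(reads))
  n <- length(reads)
  km <- kmer_codes(reads, k)
  gid <- match(km$code, unique(km$code))
  key <- (as.numeric(gid) - 1) * (n + 1) + km$idx
  keep_kmer <- !duplicated(key)
  inc <- list(gid = gid[keep_kmer], idx = km$idx[keep_kmer])
  comp <- if (min_shared <= 1L) {
    # Reads sharing a k-mer are transitively linked: join every read of a
    # k-mer group to the group's first read.
    rep_for <- inc$idx[!duplicated(inc$gid)][inc$gid]
    e <- cbind(rep_for, inc$idx)
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    g <- igraph::make_graph(t(e), n = n, directed = FALSE)
    igraph::components(g)$membership
  } else {
    # Exact pairwise shared-k-mer counting; quadratic in group sizes, meant
    # for modest samples.
    by_gid <- split(inc$idx, inc$gid)
    el <- list()
    for (members in by_gid) {
      if (length(members) < 2L) next
      pr <- utils::combn(sort(members), 2L)
      el[[length(el) + 1L]] <- pr
    }
    if (length(el)) {
      pr <- do.call(cbind, el)
      key <- paste(pr[1, ], pr[2, ])
      cnt <- table(key)
      good <- names(cnt)[cnt >= min_shared]
      if (length(good)) {
        e <- do.call(rbind, strsplit(good, " ", fixed = TRUE))
        e <- matrix(as.integer(e), ncol = 2)
        g <- igraph::make_graph(t(e), n = n, directed = FALSE)
        igraph::components(g)$membership
      } else seq_len(n)
    } else seq_len(n)
  }
  total_nt <- sum(nchar(reads))
  nt_by_comp <- tapply(nchar(reads), comp, sum)
  keep <- names(nt_by_comp)[nt_by_comp / total_nt >= min_cluster_fraction]
  keep <- keep[order(-nt_by_comp[keep])]
  lapply(keep, function(cid) {
    idx <- which(comp == as.integer(cid))
    structure(list(read_idx = idx, read_ids = ids[idx],
                   n_reads = length(idx),
                   nucleotides = sum(nchar(reads[idx])),
                   sampled_fraction = sum(nchar(reads[idx])) / total_nt),
              class = "read_cluster")
  })
}

#' @export
print.read_cluster <- function(x, ...) {
  cat(sprintf("<read_cluster> %d reads, %d nt (%.3f%% of sample)\n",
              x$n_reads, x$nucleotides, 100 * x$sampled_fraction))
  invisible(x)
}

# Greedy highest-count walk over the cluster's de Bruijn graph.  Successor
# lookups are fully vectorized: for every distinct k-mer the best successor
# (highest count, ties broken lexicographically, i.e. by base order) is
# precomputed, and the walk follows integer pointers until a node recurs
# (cycle found) or dead-ends (no tandem).
debruijn_cycle <- function(reads, k) {
  both <- c(reads, revcomp(reads))
  kmer <- string_kmers(both, k, canonical = FALSE)$kmer
  if (!length(kmer)) return(NULL)
  u <- unique(kmer)
  cnt <- tabulate(match(kmer, u), nbins = length(u))
  suf <- substr(u, 2L, k)
  cand <- match(paste0(rep(suf, each = 4L), DNA_BASES), u)
  cand <- matrix(cand, nrow = 4L)           # successors of each node, A<C<G<T
  ccnt <- matrix(cnt[cand], nrow = 4L)
  ccnt[is.na(ccnt)] <- -1L
  best_row <- max.col(t(ccnt), ties.method = "first")
  best <- cand[cbind(best_row, seq_along(u))]
  no_succ <- ccnt[cbind(best_row, seq_along(u))] < 0
  best[no_succ] <- NA_integer_
  start <- which.max(cnt)
  pos <- integer(length(u))
  path <- integer(min(length(u) + 1L, 100000L))
  cur <- start; step <- 0L
  repeat {
    step <- step + 1L
    if (step > length(path)) return(NULL)
    if (pos[cur] > 0L) {
      cycle <- path[pos[cur]:(step - 1L)]
      break
    }
    pos[cur] <- step
    path[step] <- cur
    cur <- best[cur]
    if (is.na(cur)) return(NULL)
  }
  cyc_kmers <- u[cycle]
  mass_on <- sum(cnt[match(unique(c(cyc_kmers, revcomp(cyc_kmers))), u)],
                 na.rm = TRUE)
  list(consensus = paste(substr(cyc_kmers, 1L, 1L), collapse = ""),
       rul = length(cycle), tandem_score = min(1, mass_on / sum(cnt)))
}

# Majority-vote polishing of a cycle consensus against cluster reads aligned
# to the tandem-repeated cycle.  Votes are collected per monomer position
# (subject coordinate modulo the repeat length), insertion columns are
# skipped.
polish_consensus <- function(consensus, reads, n_polish = 200L) {
  m <- nchar(consensus)
  if (length(reads) > n_polish)
    reads <- reads[round(seq(1, length(reads), length.out = n_polish))]
  reps <- max(2L, ceiling(max(nchar(reads)) / m) + 1L)
  ref <- strrep(consensus, reps)
  # Align both strands, keep the better per read, and collect votes from
  # covered reference spans plus the mismatch table (vectorized; no
  # per-alignment string extraction).
  sm <- sat_submat()
  run <- function(x) Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(x), Biostrings::DNAString(ref), type = "local",
    substitutionMatrix = sm, gapOpening = 1.5, gapExtension = 0.5)
  gather <- function(aln, chosen) {
    ss <- Biostrings::start(Biostrings::subject(aln))[chosen]
    se <- Biostrings::end(Biostrings::subject(aln))[chosen]
    mt <- Biostrings::mismatchTable(aln)
    mt <- mt[mt$PatternId %in% chosen, , drop = FALSE]
    list(cov_pos = unlist(Map(seq.int, ss, se), use.names = FALSE),
         mm_pos = mt$SubjectStart,
         mm_base = as.character(mt$PatternSubstring))
  }
  aln_f <- run(reads)
  aln_r <- run(revcomp(reads))
  use_rev <- Biostrings::score(aln_r) > Biostrings::score(aln_f)
  gf <- gather(aln_f, which(!use_rev))
  gr <- gather(aln_r, which(use_rev))
  cov_pos <- (c(gf$cov_pos, gr$cov_pos) - 1L) %% m + 1L
  mm_pos <- (c(gf$mm_pos, gr$mm_pos) - 1L) %% m + 1L
  mm_base <- c(gf$mm_base, gr$mm_base)
  base0 <- seq_chars(consensus)
  cov <- tabulate(cov_pos, m)
  mm_tot <- tabulate(mm_pos, m)
  votes <- matrix(0L, nrow = 4L, ncol = m, dimnames = list(DNA_BASES, NULL))
  votes[cbind(match(base0, DNA_BASES), seq_len(m))] <- cov - mm_tot
  ok <- mm_base %in% DNA_BASES
  mm_keys <- (mm_pos[ok] - 1L) * 4L + match(mm_base[ok], DNA_BASES)
  votes <- votes + matrix(tabulate(mm_keys, 4L * m), nrow = 4L)
  polished <- vapply(seq_len(m), function(j) {
    v <- votes[, j]
    if (all(v <= 0L)) return(base0[j])
    DNA_BASES[which.max(v)]
  }, character(1))
  paste(polished, collapse = "")
}

#' Infer a tandem consensus monomer from a read cluster
#'
#' Builds the de Bruijn graph of the cluster's k-mers (both strands), walks
#' greedily from the highest-count k-mer to the highest-count successor
#' until a node recurs, and spells the recurrent portion as the consensus
#' cycle; the repeat unit length (RUL) is the cycle length in nodes.  The
#' consensus is then polished by per-position majority vote of cluster reads
#' aligned to the tandem-repeated cycle and canonicalized (rotation/strand
#' invariant).  `tandem_score` is the fraction of the cluster's k-mer mass
#' lying on the cycle; clusters without a cycle are flagged non-tandem.
#'
#' @param cluster A `read_cluster` from [cluster_reads()] (then `reads` must
#'   be the read set it indexes) or a character vector of cluster reads.
#' @param k K-mer size (as used for clustering).
#' @param reads Full read vector indexed by `cluster$read_idx`.
#' @param n_polish Maximum reads used for polishing.
#' @return A `sat_candidate`: `consensus`, `rul`, `tandem_score`,
#'   `cluster_fraction`, `n_reads`, `tandem` (logical).
#' @export
infer_monomer <- function(cluster, k = 21L, reads = NULL, n_polish = 200L) {
  if (inherits(cluster, "read_cluster")) {
    if (is.null(reads)) stopf("supply the read vector the cluster indexes")
    if (inherits(reads, "sat_library")) reads <- reads_of(reads)
    rs <- unname(toupper(reads[cluster$read_idx]))
    frac <- cluster$sampled_fraction
  } else {
    rs <- unname(toupper(as.character(cluster)))
    frac <- NA_real_
  }
  if (!length(rs)) stopf("empty cluster")
  graph_reads <- if (length(rs) > 500L)
    rs[round(seq(1, length(rs), length.out = 500L))] else rs
  cyc <- debruijn_cycle(graph_reads, k)
  if (is.null(cyc)) {
    return(structure(list(consensus = NA_character_, rul = NA_integer_,
                          tandem_score = 0, cluster_fraction = frac,
                          n_reads = length(rs), tandem = FALSE),
                     class = "sat_candidate"))
  }
  polished <- polish_consensus(cyc$consensus, rs, n_polish)
  structure(list(consensus = canonical_monomer(polished),
                 rul = nchar(polished), tandem_score = cyc$tandem_score,
                 cluster_fraction = frac, n_reads = length(rs),
                 tandem = TRUE),
            class = "sat_candidate")
}

#' @export
print.sat_candidate <- function(x, ...) {
  if (!x$tandem) cat("<sat_candidate> non-tandem cluster\n")
  else cat(sprintf("<sat_candidate> rul = %d, tandem_score = %.2f, reads = %d\n",
                   x$rul, x$tandem_score, x$n_reads))
  invisible(x)
}

# Normalize a candidates argument to a named character vector of consensi.
candidate_consensi <- function(candidates) {
  if (is.character(candidates)) {
    nm <- names(candidates) %||% paste0("cand", seq_along(candidates))
    return(stats::setNames(toupper(candidates), nm))
  }
  if (is.data.frame(candidates)) return(family_consensi(candidates))
  if (inherits(candidates, "sat_candidate")) candidates <- list(candidates)
  cs <- vapply(candidates, function(x) x$consensus, character(1))
  stats::setNames(cs, paste0("cand", seq_along(cs)))
}

#' Remove reads matching satellite candidates
#'
#' Drops every read (pair) with a gapped local alignment to any candidate's
#' head-to-tail dimer at `min_identity` identity or better covering at least
#' `min_cover` of the read.  For paired libraries the pair is dropped when
#' either mate matches.
#'
#' @param lib A [sat_library()].
#' @param candidates `sat_candidate` list, catalogue data frame or character
#'   vector of consensus monomers.
#' @param min_identity Minimum alignment identity.
#' @param min_cover Minimum fraction of the read covered.
#' @return The filtered `sat_library`.
#' @export
subtract_reads <- function(lib, candidates, min_identity = 0.8,
                           min_cover = 0.5) {
  stopifnot(inherits(lib, "sat_library"))
  cons <- candidate_consensi(candidates)
  if (!length(cons)) stopf("no candidates to subtract")
  reads <- unname(reads_of(lib))
  ki <- kmer_codes(reads, 11L)
  hit <- logical(length(reads))
  for (cs in cons) {
    open <- which(!hit)
    sub_ki <- list(idx = match(ki$idx, open), code = ki$code)
    ok <- !is.na(sub_ki$idx)
    sub_ki <- list(idx = sub_ki$idx[ok], code = sub_ki$code[ok])
    h <- align_hits(reads[open], cs, min_identity, min_cover, type = "local",
                    kmer_index = sub_ki)
    if (nrow(h)) hit[open[h$read_idx]] <- TRUE
  }
  n <- length(lib)
  pair_hit <- if (lib$paired) hit[seq_len(n)] | hit[n + seq_len(n)]
              else hit
  subset_library(lib, which(!pair_hit))
}

#' Iterative satellite discovery with read subtraction
#'
#' Repeats sample - cluster - infer - subtract rounds until a round yields
#' no new tandem candidate (or `rounds_max` is reached), mirroring iterative
#' satellite mining: each round removes reads explained by the candidates
#' found so far, letting lower-abundance families surface next.  Candidates
#' are deduplicated across rounds at `dedup_identity` (rotation/strand-aware
#' identity).
#'
#' @param lib A (trimmed) [sat_library()].
#' @param rounds_max Maximum rounds.
#' @param sample_pairs Records sampled per round.
#' @param k,min_shared,min_cluster_fraction Clustering parameters.
#' @param min_tandem_score Minimum tandem score for a cluster consensus to
#'   count as a satellite candidate.  Diverged copies dilute the on-cycle
#'   k-mer mass roughly as `(1 - d)^k` (about 0.34 at 5% divergence with
#'   k = 21), so the default is deliberately permissive; non-tandem
#'   clusters score 0 regardless.
#' @param dedup_identity Identity at which two candidates are the same
#'   family variant.
#' @param subtract_identity,subtract_cover Subtraction thresholds.
#' @param mask Optional consensus set (character vector / catalogue) removed
#'   from the reads before the first round, e.g. a known-repeat database.
#' @param seed Integer seed for per-round sampling.
#' @return List with `candidates` (list of `sat_candidate`) and `log` (one
#'   row per round: clusters inspected, new candidates, reads remaining).
#' @export
iterate_discovery <- function(lib, rounds_max = 8L, sample_pairs = 200000L,
                              k = 21L, min_shared = 1L,
                              min_cluster_fraction = 5e-4,
                              min_tandem_score = 0.1,
                              dedup_identity = 0.95,
                              subtract_identity = 0.8, subtract_cover = 0.5,
                              mask = NULL, seed = 1L) {
  stopifnot(inherits(lib, "sat_library"))
  if (!is.null(mask)) lib <- subtract_reads(lib, mask, subtract_identity,
                                            subtract_cover)
  candidates <- list()
  log <- data.frame(round = integer(0), clusters = integer(0),
                    new_candidates = integer(0), reads_remaining = integer(0))
  for (round in seq_len(rounds_max)) {
    if (length(lib) == 0L) break
    smp <- if (length(lib) > sample_pairs)
      sample_reads(lib, sample_pairs, seed = derive_seed(seed, round))
    else lib
    reads <- unname(reads_of(smp))
    clusters <- tryCatch(cluster_reads(reads, k, min_shared,
                                       min_cluster_fraction),
                         error = function(e) list())
    new_cands <- list()
    for (cl in clusters) {
      cand <- infer_monomer(cl, k = k, reads = reads)
      if (!cand$tandem || cand$tandem_score < min_tandem_score) next
      known <- any(vapply(c(candidates, new_cands), function(x) {
        pairwise_identity(cand$consensus, x$consensus) >= dedup_identity
      }, logical(1)))
      if (!known) new_cands[[length(new_cands) + 1L]] <- cand
    }
    candidates <- c(candidates, new_cands)
    if (length(new_cands))
      lib <- subtract_reads(lib, new_cands, subtract_identity, subtract_cover)
    log <- rbind(log, data.frame(round = round, clusters = length(clusters),
                                 new_candidates = length(new_cands),
                                 reads_remaining = length(lib)))
    if (!length(new_cands)) break
    if (round == rounds_max)
      warnf("rounds_max reached with candidates still emerging; returning partial result")
  }
  list(candidates = candidates, log = log)
}
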