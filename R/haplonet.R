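# Monomer haplotype extraction, singleton filtering and minimum spanning
# tree networks with per-group (sex / chromosome) composition.

#' Extract phase-anchored monomer copies from reads
#'
#' Aligns each read (both strands) to the family's head-to-tail dimer and,
#' for reads whose indel-free alignment spans at least one complete monomer
#' unit starting at consensus coordinate 0, cuts exactly the first such unit
#' and reports it on the consensus strand.  Phase anchoring makes haplotypes
#' from different reads positionally comparable.
#'
#' @param lib A [sat_library()] or character vector of reads.
#' @param family Family consensus string or one-row catalogue data frame.
#' @param min_identity Minimum alignment identity for a read to be used.
#' @return Character vector of monomer sequences (possibly empty).
#' @export
extract_monomers <- function(lib, family, min_identity = 0.7) {
  cons <- unname(family_consensi(family)[1])
  L <- nchar(cons)
  reads <- if (inherits(lib, "sat_library")) unname(reads_of(lib))
           else unname(toupper(lib))
  if (!length(reads)) return(character(0))
  read_len <- max(nchar(reads))
  if (L >= read_len)
    stopf("monomer extraction requires rul (%d) < read length (%d)",
          L, read_len)
  h <- align_hits(reads, cons, min_identity = min_identity,
                  min_cover_read = 0.5)
  if (!nrow(h)) return(character(0))
  h <- h[h$gap_cols == 0L, , drop = FALSE]   # complete, indel-free copies only
  if (!nrow(h)) return(character(0))
  # First complete phase-0 unit: smallest m >= ref_start with
  # (m - 1) %% L == 0 and m + L - 1 <= ref_end (dimer coordinates).
  m <- (ceiling((h$ref_start - 1L) / L)) * L + 1L
  ok <- m + L - 1L <= h$ref_end
  h <- h[ok, , drop = FALSE]; m <- m[ok]
  if (!nrow(h)) return(character(0))
  out <- character(nrow(h))
  for (i in seq_len(nrow(h))) {
    r <- reads[h$read_idx[i]]
    if (h$strand[i] == "-") r <- revcomp(r)
    # Oriented-read coordinate of the alignment start.
    o_start <- if (h$strand[i] == "-")
      nchar(r) - h$read_end[i] + 1L else h$read_start[i]
    off <- m[i] - h$ref_start[i]
    out[i] <- substr(r, o_start + off, o_start + off + L - 1L)
  }
  out[nchar(out) == L]
}

#' Tally haplotypes and remove singletons
#'
#' Exact-sequence tallies per group; haplotypes observed only once in total
#' (likely sequencing errors) are removed.
#'
#' @param monomers Character vector of equal-length monomer sequences.
#' @param groups Group label per monomer (e.g. `"male"` / `"female"`).
#' @return Data frame of class `haplotype_set`: `seq`, one count column per
#'   group, and `total`; empty (with a warning) when everything is unique.
#' @export
filter_singletons <- function(monomers, groups) {
  if (!length(monomers)) stopf("no monomers supplied")
  if (length(unique(nchar(monomers))) != 1L)
    stopf("monomers must share one length (phase-anchored extraction)")
  groups <- rep_len(as.character(groups), length(monomers))
  tab <- table(seq = monomers, group = groups)
  total <- rowSums(tab)
  keep <- total >= 2L
  if (!any(keep)) {
    warnf("all haplotypes are singletons; empty haplotype set")
    keep <- rep(FALSE, length(total))
  }
  out <- data.frame(seq = rownames(tab)[keep], stringsAsFactors = FALSE)
  for (g in colnames(tab)) out[[g]] <- as.integer(tab[keep, g])
  out$total <- as.integer(total[keep])
  rownames(out) <- NULL
  class(out) <- c("haplotype_set", "data.frame")
  out
}

hamming <- function(a, b) sum(seq_chars(a) != seq_chars(b))

# Union-find with path compression (tiny instances).
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i] <- parent[parent[i]]
  i
}

#' Build the minimum spanning tree of a haplotype set
#'
#' Computes all pairwise Hamming distances and extracts an MST with Kruskal's
#' algorithm under a fully deterministic tie-break: lower distance first,
#' then higher summed endpoint counts, then lexicographic endpoint
#' sequences.  Edges of distance 1 (single-base neighbors) are annotated.
#'
#' @param haps A `haplotype_set` from [filter_singletons()], or a character
#'   vector of equal-length haplotype sequences (unit counts assumed).
#' @return A `haplotype_graph`: `nodes` (the haplotype table), `edges`
#'   (`i`, `j`, `distance`, `single_step`), `total_weight`, `is_tree`.
#' @export
build_mst <- function(haps) {
  if (is.character(haps)) {
    haps <- data.frame(seq = haps, total = 1L)
    class(haps) <- c("haplotype_set", "data.frame")
  }
  n <- nrow(haps)
  if (n < 2L) stopf("an MST needs at least 2 haplotypes")
  if (length(unique(nchar(haps$seq))) != 1L)
    stopf("haplotypes must share one length")
  pr <- utils::combn(n, 2L)
  d <- vapply(seq_len(ncol(pr)), function(c)
    hamming(haps$seq[pr[1, c]], haps$seq[pr[2, c]]), numeric(1))
  csum <- haps$total[pr[1, ]] + haps$total[pr[2, ]]
  ekey <- vapply(seq_len(ncol(pr)), function(c) {
    s <- sort(c(haps$seq[pr[1, c]], haps$seq[pr[2, c]]))
    paste(s, collapse = "|")
  }, character(1))
  ord <- order(d, -csum, ekey)
  parent <- seq_len(n)
  edges <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  for (c in ord) {
    a <- uf_find(parent, pr[1, c]); b <- uf_find(parent, pr[2, c])
    if (a != b) {
      parent[a] <- b
      edges <- rbind(edges, data.frame(i = pr[1, c], j = pr[2, c],
                                       distance = d[c]))
      if (nrow(edges) == n - 1L) break
    }
  }
  edges$single_step <- edges$distance == 1
  structure(list(nodes = haps, edges = edges,
                 total_weight = sum(edges$distance),
                 is_tree = nrow(edges) == n - 1L),
            class = "haplotype_graph")
}

#' @export
print.haplotype_graph <- function(x, ...) {
  cat(sprintf("<haplotype_graph> %d haplotypes, MST weight %g\n",
              nrow(x$nodes), x$total_weight))
  invisible(x)
}

#' Exhaustive minimum spanning-tree weight
#'
#' Enumerates every labeled spanning tree (via Prufer sequences, vectorized)
#' and returns the minimum total weight.  Exact but exponential; intended as
#' an independent check of [build_mst()] on small instances.
#'
#' @param dist_matrix Symmetric distance matrix (2-9 nodes).
#' @return Minimum spanning-tree weight over all spanning trees.
#' @export
spanning_tree_min_weight <- function(dist_matrix) {
  n <- nrow(dist_matrix)
  stopifnot(n >= 2L, n <= 9L, ncol(dist_matrix) == n)
  if (n == 2L) return(dist_matrix[1, 2])
  # All Prufer sequences of length n - 2 over labels 1..n.
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  ns <- nrow(seqs)
  deg <- matrix(1L, ns, n)
  for (c in seq_len(n - 2L))
    deg[cbind(seq_len(ns), seqs[, c])] <- deg[cbind(seq_len(ns), seqs[, c])] + 1L
  w <- numeric(ns)
  for (c in seq_len(n - 2L)) {
    leaf <- max.col(deg == 1L, ties.method = "first")
    a <- seqs[, c]
    w <- w + dist_matrix[cbind(leaf, a)]
    deg[cbind(seq_len(ns), leaf)] <- 0L
    deg[cbind(seq_len(ns), a)] <- deg[cbind(seq_len(ns), a)] - 1L
  }
  u <- max.col(deg == 1L, ties.method = "first")
  deg[cbind(seq_len(ns), u)] <- 0L
  v <- max.col(deg == 1L, ties.method = "first")
  w <- w + dist_matrix[cbind(u, v)]
  min(w)
}

#' Shared versus group-exclusive haplotypes
#'
#' @param x A `haplotype_graph` or `haplotype_set`.
#' @return List with `haplotypes` (per-haplotype group counts, `exclusive`
#'   label or `"shared"`) and `summary` (counts of shared and per-group
#'   exclusive haplotypes).
#' @export
shared_haplotype_report <- function(x) {
  haps <- if (inherits(x, "haplotype_graph")) x$nodes else x
  groups <- setdiff(names(haps), c("seq", "total"))
  if (!length(groups)) stopf("haplotype set carries no group counts")
  cnt <- as.matrix(haps[, groups, drop = FALSE])
  nz <- cnt > 0
  excl <- ifelse(rowSums(nz) == 1L, groups[max.col(nz, ties.method = "first")],
                 "shared")
  out <- haps
  out$status <- excl
  summary <- c(table(factor(excl, levels = c("shared", groups))))
  list(haplotypes = out, summary = summary)
}
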