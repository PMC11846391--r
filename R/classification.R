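# Grouping of candidate consensuses into families and superfamilies,
# exclusion screening against multigene-family sequences, and
# abundance-ranked naming.

#' Rotation- and strand-aware identity between two monomers
#'
#' Best global-alignment identity (matches / alignment columns, gap columns
#' counted as non-identity) over all rotations of `a` and of its reverse
#' complement against `b`.  Symmetric, and equal to 1 exactly when the two
#' canonical forms are identical in the indel-free case.
#'
#' @param a,b Non-empty DNA strings.
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!nchar(a) || !nchar(b)) stopf("sequences must be non-empty")
  if (canonical_monomer(a) == canonical_monomer(b)) return(1)
  if (nchar(a) == nchar(b)) {
    # Equal lengths: variants differ by substitutions only, so the best
    # rotation/strand alignment is gapless; identity is the best match
    # fraction over all rotations (symmetric by construction).
    bc <- seq_chars(b)
    best <- 0
    for (r in c(rotations(a), rotations(revcomp(a))))
      best <- max(best, mean(seq_chars(r) == bc))
    return(best)
  }
  # Stiff gap penalties: monomer variants are substitution-dominated, and
  # cheap gaps would let the aligner disguise substitutions as indel pairs.
  one_way <- function(x, y) {
    rots <- c(rotations(x), rotations(revcomp(x)))
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(rots),
                                         Biostrings::DNAString(y),
                                         type = "global",
                                         substitutionMatrix = sat_submat(),
                                         gapOpening = 4, gapExtension = 1)
    max(Biostrings::nmatch(aln) / Biostrings::nchar(aln))
  }
  # Symmetrized: the rotation search is directional, the measure is not.
  max(one_way(a, b), one_way(b, a))
}

# Pairwise identity matrix with a shared-k-mer shortcut: pairs sharing no
# canonical 8-mer cannot approach the family thresholds and are scored 0
# without alignment.
identity_matrix <- function(cons, prefilter_k = 8L) {
  n <- length(cons)
  m <- diag(1, n)
  if (n < 2L) return(m)
  ksets <- lapply(cons, function(s)
    unique(string_kmers(s, min(prefilter_k, nchar(s)))$canon))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      val <- if (length(intersect(ksets[[i]], ksets[[j]])) == 0L) 0
             else pairwise_identity(cons[i], cons[j])
      m[i, j] <- m[j, i] <- val
    }
  }
  m
}

single_linkage <- function(idmat, threshold) {
  adj <- idmat >= threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

#' Group satellite candidates into families and superfamilies
#'
#' Single-linkage clustering on rotation/strand-aware pairwise identity:
#' candidates linked at `variant_threshold` or above are variants of one
#' family (represented by the most abundant member's consensus); families
#' linked at `superfamily_threshold` share a superfamily, and superfamilies
#' with at least two families are labeled `SF-1`, `SF-2`, ... by descending
#' total abundance.  Candidates below the superfamily threshold belong to
#' different superfamilies.
#'
#' @param candidates `sat_candidate` list, catalogue data frame or character
#'   vector of consensus monomers.
#' @param variant_threshold Identity at or above which candidates are
#'   variants of the same family.
#' @param superfamily_threshold Identity at or above which families share a
#'   superfamily.
#' @param abundance Optional per-candidate abundance used for picking family
#'   representatives and ordering superfamilies; defaults to the candidates'
#'   cluster fractions when available.
#' @return A list with `families` (data frame: `family_id`, `consensus`,
#'   `rul`, `at_fraction`, `superfamily`, `n_members`, `abundance`) and
#'   `membership` (candidate index to family_id).
#' @export
group_families <- function(candidates, variant_threshold = 0.95,
                           superfamily_threshold = 0.80, abundance = NULL) {
  cons <- candidate_consensi(candidates)
  cons <- vapply(cons, canonical_monomer, character(1))
  n <- length(cons)
  if (n == 0L)
    return(list(families = data.frame(family_id = integer(0),
                                      consensus = character(0),
                                      rul = integer(0),
                                      at_fraction = numeric(0),
                                      superfamily = character(0),
                                      n_members = integer(0),
                                      abundance = numeric(0)),
                membership = integer(0)))
  if (is.null(abundance)) {
    abundance <- if (is.list(candidates) &&
                     all(vapply(candidates, inherits, logical(1),
                                "sat_candidate"))) {
      vapply(candidates, function(x) x$cluster_fraction %||% NA_real_,
             numeric(1))
    } else rep(NA_real_, n)
  }
  abundance[is.na(abundance)] <- 0
  idmat <- identity_matrix(unname(cons))
  fam_member <- single_linkage(idmat, variant_threshold)
  sf_member <- single_linkage(idmat, superfamily_threshold)
  fam_ids <- sort(unique(fam_member))
  fams <- do.call(rbind, lapply(seq_along(fam_ids), function(fi) {
    members <- which(fam_member == fam_ids[fi])
    rep_i <- members[which.max(abundance[members])]
    data.frame(family_id = fi, consensus = unname(cons[rep_i]),
               rul = nchar(cons[rep_i]),
               at_fraction = mean(seq_chars(cons[rep_i]) %in% c("A", "T")),
               sf_component = sf_member[rep_i],
               n_members = length(members),
               abundance = sum(abundance[members]))
  }))
  # Superfamilies: components holding >= 2 families, SF-N by total abundance.
  sf_sizes <- table(fams$sf_component)
  multi <- names(sf_sizes)[sf_sizes >= 2L]
  sf_tot <- vapply(multi, function(s)
    sum(fams$abundance[fams$sf_component == as.integer(s)]), numeric(1))
  sf_rank <- stats::setNames(rank(-sf_tot, ties.method = "first"), multi)
  fams$superfamily <- ifelse(as.character(fams$sf_component) %in% multi,
                             paste0("SF-", sf_rank[as.character(fams$sf_component)]),
                             NA_character_)
  fams$sf_component <- NULL
  membership <- match(fam_member, fam_ids)
  list(families = fams, membership = membership)
}

#' Screen candidates against an exclusion library
#'
#' Drops candidates resembling entries of an exclusion set (rDNA, histone or
#' other multigene-family sequences): a candidate is removed when its best
#' local alignment to any exclusion sequence reaches `min_identity` identity
#' and covers at least `min_cover` of the candidate.
#'
#' @param candidates `sat_candidate` list, catalogue data frame or character
#'   vector.
#' @param exclusion_lib Path to a FASTA file, or a named character vector of
#'   exclusion sequences.
#' @param min_identity,min_cover Removal thresholds.
#' @return List with `kept` (surviving candidates, same type as the input)
#'   and `removed` (data frame logging each removal and its best hit).
#' @export
screen_exclusions <- function(candidates, exclusion_lib, min_identity = 0.8,
                              min_cover = 0.5) {
  cons <- candidate_consensi(candidates)
  excl <- if (is.character(exclusion_lib) && length(exclusion_lib) == 1L &&
              file.exists(exclusion_lib)) {
    lib <- read_fastx(exclusion_lib, "fasta")
    stats::setNames(lib$seq, lib$id)
  } else {
    stopifnot(is.character(exclusion_lib))
    exclusion_lib
  }
  removed <- data.frame(candidate = character(0), hit = character(0),
                        identity = numeric(0), coverage = numeric(0))
  drop <- logical(length(cons))
  for (i in seq_along(cons)) {
    for (j in seq_along(excl)) {
      st <- align_stats(cons[i], excl[j], type = "local")
      if (nrow(st) && st$identity >= min_identity &&
          st$coverage >= min_cover) {
        drop[i] <- TRUE
        removed <- rbind(removed, data.frame(
          candidate = names(cons)[i] %||% as.character(i),
          hit = names(excl)[j] %||% as.character(j),
          identity = st$identity, coverage = st$coverage))
        break
      }
    }
  }
  kept <- if (is.list(candidates) && !is.data.frame(candidates))
    candidates[!drop]
  else if (is.data.frame(candidates)) candidates[!drop, , drop = FALSE]
  else candidates[!drop]
  list(kept = kept, removed = removed)
}

#' Assign abundance-ranked family names
#'
#' Names families `{prefix}Sat{NN}-{RUL}` with `NN` zero-padded and assigned
#' from 01 by descending abundance in the male genome library; ties are
#' broken by descending repeat-unit length, then by consensus sequence.
#'
#' @param families The `families` data frame from [group_families()].
#' @param male_abundance Numeric vector of male-library abundances, aligned
#'   with the rows of `families` (or named by `family_id`).
#' @param prefix Project prefix prepended to every name.
#' @return The `families` data frame, reordered by rank, with `name` and
#'   `male_abundance` columns.
#' @export
name_families <- function(families, male_abundance, prefix = "") {
  stopifnot(is.data.frame(families))
  if (!is.null(names(male_abundance)))
    male_abundance <- male_abundance[as.character(families$family_id)]
  stopifnot(length(male_abundance) == nrow(families))
  ord <- order(-male_abundance, -families$rul, families$consensus)
  out <- families[ord, , drop = FALSE]
  out$male_abundance <- male_abundance[ord]
  out$name <- sprintf("%sSat%02d-%d", prefix, seq_len(nrow(out)), out$rul)
  rownames(out) <- NULL
  out
}
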