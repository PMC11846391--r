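# Synthetic genomes with planted satellite families and simulated short-read
# libraries (whole-genome male/female plus single-compartment X and Y), with
# exact ground truth for validating the discovery and quantification stack.

#' Specify a satellite family to plant
#'
#' A family is defined by a consensus monomer (given or generated), a set of
#' amplification "pulses" (each pulse places a fraction of copies at a chosen
#' mean divergence from the consensus, emulating bursts of amplification at
#' different ages), per-compartment copy numbers, and optional subfamilies
#' fixed in chosen compartments via diagnostic substitutions.
#'
#' @param name Family name, unique within a genome.
#' @param monomer Consensus monomer string; if `NULL` one is generated from
#'   `length`, `at_fraction` and the genome seed.
#' @param length,at_fraction Monomer length (16-5042 bp) and target A+T
#'   fraction used when `monomer` is `NULL`.
#' @param pulses Data frame with columns `divergence` (mean per-site
#'   divergence of copies from the consensus) and `weight` (fraction of
#'   copies); weights must sum to 1.
#' @param kappa Transition/transversion rate ratio of the mutation process;
#'   a mutated site is a transition with probability `kappa / (kappa + 2)`.
#' @param copies Named integer vector of copy numbers per compartment, e.g.
#'   `c(autosome1 = 100, X = 30, Y = 570)`.
#' @param n_arrays Number of tandem arrays the copies of each compartment are
#'   split into: a single count applied to every compartment, or a named
#'   vector per compartment.
#' @param subfamilies Optional list; each element is a list with fields
#'   `positions` (1-based monomer sites), `bases` (diagnostic bases) and
#'   `compartments` (compartments whose copies carry them, i.e. the
#'   subfamily is fixed there).
#' @return A `family_spec` object.
#' @export
family_spec <- function(name, monomer = NULL, length = NULL,
                        at_fraction = 0.6,
                        pulses = data.frame(divergence = 0.02, weight = 1),
                        kappa = 2, copies = c(autosome1 = 100),
                        n_arrays = 1L, subfamilies = NULL) {
  if (!is.null(monomer)) {
    monomer <- toupper(monomer)
    if (grepl("[^ACGT]", monomer)) stopf("monomer must be over A/C/G/T")
    length <- nchar(monomer)
  }
  if (is.null(length)) stopf("family %s: give monomer or length", name)
  if (length < 16 || length > 5042)
    stopf("family %s: monomer length %d outside the modelled 16-5042 bp range",
          name, length)
  stopifnot(is.data.frame(pulses), all(c("divergence", "weight") %in%
                                         names(pulses)))
  if (abs(sum(pulses$weight) - 1) > 1e-8)
    stopf("family %s: pulse weights must sum to 1", name)
  if (any(pulses$divergence < 0 | pulses$divergence >= 0.75))
    stopf("family %s: pulse divergences must be in [0, 0.75)", name)
  if (is.null(names(copies)) || any(copies < 0))
    stopf("family %s: copies must be a named vector of counts >= 0", name)
  structure(list(name = name, monomer = monomer, length = as.integer(length),
                 at_fraction = at_fraction, pulses = pulses, kappa = kappa,
                 copies = copies, n_arrays = as.integer(n_arrays),
                 subfamilies = subfamilies),
            class = "family_spec")
}

#' Specify a synthetic genome
#'
#' @param compartments Named numeric vector of compartment sizes in bp.
#'   Compartments named `"X"` and `"Y"` are the sex chromosomes; all others
#'   are autosomes.  Sizes are background bp; planted arrays are embedded
#'   within them.
#' @param families List of [family_spec()] objects with unique names.
#' @param seed Default integer seed used by [plant_genome()].
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(compartments, families, seed = 1L) {
  if (is.null(names(compartments)) || any(compartments <= 0))
    stopf("compartments must be a named vector of positive sizes")
  nm <- vapply(families, function(f) f$name, character(1))
  if (anyDuplicated(nm)) stopf("family names must be unique")
  structure(list(compartments = compartments, families = families,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a random consensus monomer
#'
#' Bases are drawn i.i.d. with `P(A) = P(T) = at_fraction/2` and
#' `P(C) = P(G) = (1 - at_fraction)/2`.
#'
#' @param length Monomer length in bp; under `strict = TRUE` it must lie in
#'   the 16-5042 bp range spanned by reported satellite repeat units.
#' @param at_fraction Target A+T fraction, strictly between 0 and 1.
#' @param seed Integer seed; output is deterministic per seed.
#' @param strict Enforce the 16-5042 bp length range.
#' @return A DNA string.
#' @export
make_consensus <- function(length, at_fraction, seed = 1L, strict = TRUE) {
  if (at_fraction <= 0 || at_fraction >= 1)
    stopf("at_fraction must be strictly between 0 and 1")
  if (length < 1) stopf("length must be >= 1")
  if (strict && (length < 16 || length > 5042))
    stopf("length %d outside the 16-5042 bp satellite monomer range", length)
  p <- c(at_fraction / 2, (1 - at_fraction) / 2,
         (1 - at_fraction) / 2, at_fraction / 2)
  with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
                        collapse = ""))
}

#' Mutate copies of a consensus under a transition-biased site model
#'
#' Each site of each copy mutates independently with probability
#' `divergence`; a mutated site becomes a transition with probability
#' `kappa / (kappa + 2)`, otherwise one of the two transversions with equal
#' probability.  Multiple hits within a copy are absent by construction, so
#' realized divergence equals the fraction of mutated sites.
#'
#' @param consensus Consensus monomer string.
#' @param n Number of copies.
#' @param divergence Per-site mutation probability (one value, or one per
#'   copy).
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed.
#' @return Character vector of `n` mutated copies.
#' @export
mutate_copies <- function(consensus, n, divergence, kappa = 2, seed = 1L) {
  L <- nchar(consensus)
  d <- rep_len(divergence, n)
  base <- seq_chars(consensus)
  with_seed(seed, {
    m <- matrix(rep(base, n), nrow = L)
    hit <- which(stats::runif(L * n) < rep(d, each = L))
    if (length(hit)) {
      orig <- m[hit]
      is_ts <- stats::runif(length(hit)) < kappa / (kappa + 2)
      ts_map <- c(A = "G", G = "A", C = "T", T = "C")
      tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))
      new <- character(length(hit))
      new[is_ts] <- ts_map[orig[is_ts]]
      if (any(!is_ts)) {
        tvs <- vapply(orig[!is_ts], function(b) sample(tv_map[[b]], 1),
                      character(1))
        new[!is_ts] <- tvs
      }
      m[hit] <- new
    }
    apply(m, 2, paste, collapse = "")
  })
}

ts_map_global <- c(A = "G", G = "A", C = "T", T = "C")

# Ploidy weights of the standard library designs over compartment names.
ploidy_weights <- function(compartments, design) {
  nm <- names(compartments)
  w <- stats::setNames(numeric(length(nm)), nm)
  auto <- !(nm %in% c("X", "Y"))
  switch(design,
    male = { w[auto] <- 2; w[nm == "X"] <- 1; w[nm == "Y"] <- 1 },
    female = { w[auto] <- 2; w[nm == "X"] <- 2 },
    X = { w[nm == "X"] <- 1 },
    Y = { w[nm == "Y"] <- 1 },
    stopf("unknown library design '%s'", design))
  w
}

#' Plant satellite arrays into a synthetic genome
#'
#' Builds one sequence per compartment: i.i.d. uniform background into which
#' each family's copies are laid head-to-tail in tandem arrays at random
#' non-overlapping positions.  Each copy samples one amplification pulse and
#' is mutated away from the consensus accordingly; subfamily diagnostic
#' substitutions are applied afterwards.  The returned truth table records
#' planted copy numbers, realized divergences and exact abundances.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed (defaults to the spec's seed).
#' @return A list of class `sat_genome` with elements `compartments` (named
#'   character vector of sequences), `truth` (data frame: family,
#'   compartment, n_copies, copy_bp, compartment_bp, abundance_percent, with
#'   per-pulse realized divergence in `attr(truth, "pulses")` and planted
#'   copy sequences in `attr(truth, "copies")`), `consensi` (named vector of
#'   family consensus monomers) and `spec`.
#' @export
plant_genome <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "genome_spec"))
  comp_names <- names(spec$compartments)
  # Resolve consensus monomers.
  consensi <- vapply(seq_along(spec$families), function(i) {
    f <- spec$families[[i]]
    f$monomer %||% make_consensus(f$length, f$at_fraction,
                                  seed = derive_seed(seed, 9000 + i))
  }, character(1))
  names(consensi) <- vapply(spec$families, `[[`, character(1), "name")

  truth <- list(); pulses_out <- list(); copies_out <- list()
  positions_out <- list()
  compartments <- stats::setNames(character(length(comp_names)), comp_names)

  for (cn in comp_names) {
    size <- spec$compartments[[cn]]
    # Families with copies here, and their mutated copy sequences.
    arrays <- list()   # one element per array: concatenated copies
    arr_meta <- list()
    for (fi in seq_along(spec$families)) {
      f <- spec$families[[fi]]
      ncop <- as.integer(f$copies[cn] %||% 0L)
      if (is.na(ncop) || ncop == 0L) next
      L <- nchar(consensi[[f$name]])
      sd1 <- derive_seed(seed, 100 * fi + match(cn, comp_names))
      pulse_idx <- with_seed(sd1, sample.int(nrow(f$pulses), ncop,
                                             replace = TRUE,
                                             prob = f$pulses$weight))
      # Amplification bursts copy contiguously: copies of one pulse form
      # blocks within arrays rather than interleaving, so read-level
      # landscapes show one mode per pulse instead of a smeared mixture.
      pulse_idx <- sort(pulse_idx)
      cp <- mutate_copies(consensi[[f$name]], ncop,
                          f$pulses$divergence[pulse_idx], f$kappa,
                          seed = derive_seed(seed, 100 * fi +
                                               match(cn, comp_names) + 50))
      # Subfamily diagnostic substitutions, applied after pulse mutation.
      if (!is.null(f$subfamilies)) {
        for (sf in f$subfamilies) {
          if (!cn %in% sf$compartments) next
          for (j in seq_along(sf$positions))
            substr(cp, sf$positions[j], sf$positions[j]) <- sf$bases[j]
        }
      }
      raw_div <- 1 - vapply(cp, function(s) {
        mean(seq_chars(s) == seq_chars(consensi[[f$name]]))
      }, numeric(1), USE.NAMES = FALSE)
      for (pi in seq_len(nrow(f$pulses))) {
        sel <- pulse_idx == pi
        if (!any(sel)) next
        pq <- vapply(cp[sel], function(s) {
          k <- classify_subst(seq_chars(s), seq_chars(consensi[[f$name]]))
          c(k$transitions, k$transversions, k$sites)
        }, numeric(3), USE.NAMES = FALSE)
        P <- sum(pq[1, ]) / sum(pq[3, ]); Q <- sum(pq[2, ]) / sum(pq[3, ])
        pulses_out[[length(pulses_out) + 1L]] <- data.frame(
          family = f$name, compartment = cn, pulse = pi,
          target_divergence = f$pulses$divergence[pi],
          n_copies = sum(sel),
          realized_divergence = mean(raw_div[sel]),
          realized_k2p = k2p_distance(P, Q))
      }
      copies_out[[paste(f$name, cn, sep = "|")]] <- unname(cp)
      truth[[length(truth) + 1L]] <- data.frame(
        family = f$name, compartment = cn, n_copies = ncop,
        copy_bp = ncop * L, compartment_bp = size,
        abundance_percent = 100 * ncop * L / size)
      # Split copies into arrays (head-to-tail within each array).
      na_spec <- if (!is.null(names(f$n_arrays))) {
        v <- f$n_arrays[cn]
        if (is.na(v)) 1L else as.integer(v)
      } else as.integer(f$n_arrays)
      na <- max(1L, min(na_spec, ncop))
      grp <- sort(rep_len(seq_len(na), ncop))
      for (g in seq_len(na)) {
        arrays[[length(arrays) + 1L]] <- paste(cp[grp == g], collapse = "")
        arr_meta[[length(arr_meta) + 1L]] <- c(f$name, cn)
      }
    }
    arr_bp <- sum(vapply(arrays, nchar, integer(1)))
    if (arr_bp > size)
      stopf("compartment %s: planted arrays (%d bp) exceed its %d bp; use a larger compartment",
            cn, arr_bp, size)
    bg_bp <- size - arr_bp
    bg <- with_seed(derive_seed(seed, 7 + match(cn, comp_names)),
                    random_dna(1, bg_bp))
    if (length(arrays)) {
      # Uniform non-overlapping placement: split the background at random
      # points and interleave the arrays (in random order) between chunks.
      na <- length(arrays)
      sd2 <- derive_seed(seed, 777 + match(cn, comp_names))
      pieces <- with_seed(sd2, {
        ord <- sample.int(na)
        cuts <- sort(sample.int(bg_bp + 1L, na, replace = TRUE) - 1L)
        list(ord = ord, cuts = cuts)
      })
      bounds <- c(0L, pieces$cuts, bg_bp)
      chunks <- substring(bg, head(bounds, -1) + 1L, bounds[-1])
      out <- character(2L * na + 1L)
      out[seq(1, 2 * na + 1, by = 2)] <- chunks
      out[seq(2, 2 * na, by = 2)] <- unlist(arrays[pieces$ord])
      compartments[[cn]] <- paste(out, collapse = "")
      # Array coordinates in the final compartment.
      lens <- nchar(out)
      starts <- cumsum(c(1L, head(lens, -1)))
      for (g in seq_len(na)) {
        meta <- arr_meta[[pieces$ord[g]]]
        positions_out[[length(positions_out) + 1L]] <- data.frame(
          family = meta[1], compartment = meta[2],
          start = starts[2 * g], end = starts[2 * g] + lens[2 * g] - 1L)
      }
    } else {
      compartments[[cn]] <- bg
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(family = character(0), compartment = character(0),
               n_copies = integer(0), copy_bp = integer(0),
               compartment_bp = numeric(0), abundance_percent = numeric(0))
  attr(truth, "pulses") <- if (length(pulses_out)) do.call(rbind, pulses_out)
    else NULL
  attr(truth, "copies") <- copies_out
  attr(truth, "positions") <- if (length(positions_out))
    do.call(rbind, positions_out) else NULL
  structure(list(compartments = compartments, truth = truth,
                 consensi = consensi, spec = spec, seed = seed),
            class = "sat_genome")
}

#' Expected family abundance in a library design under the ploidy map
#'
#' Computes, from the truth table alone, the exact expected percent of
#' library nucleotides belonging to each family for a given library design
#' (`male` = autosomes x2 + X + Y, `female` = autosomes x2 + X x2,
#' `X`/`Y` = the single microdissected compartment).
#'
#' @param genome A `sat_genome` from [plant_genome()].
#' @param design One of `"male"`, `"female"`, `"X"`, `"Y"`.
#' @return Named numeric vector of expected abundance percentages.
#' @export
truth_abundance <- function(genome, design) {
  stopifnot(inherits(genome, "sat_genome"))
  sizes <- vapply(genome$compartments, nchar, integer(1))
  w <- ploidy_weights(sizes, design)
  tot <- sum(w * sizes)
  tr <- genome$truth
  fams <- unique(tr$family)
  out <- vapply(fams, function(f) {
    rows <- tr[tr$family == f, , drop = FALSE]
    100 * sum(w[rows$compartment] * rows$copy_bp) / tot
  }, numeric(1))
  stats::setNames(out, fams)
}

#' Simulate the four sequencing libraries from a planted genome
#'
#' Draws uniform fragments along the compartments of each library design
#' (whole-genome male and female weighted by the ploidy map; microdissected
#' X and Y from their single compartment), producing 150 bp paired-end reads
#' with a uniform substitution error process and constant quality scores.
#'
#' @param genome A `sat_genome` from [plant_genome()], or a named character
#'   vector of compartment sequences.
#' @param coverage Haploid coverage per library; scalar or a named vector
#'   with entries `male`, `female`, `X`, `Y`.
#' @param read_len Read length in bp.
#' @param paired Generate read pairs (insert of `insert_mean` bp) or
#'   single-end reads.
#' @param insert_mean Fragment length; must be at least `2 * read_len` in
#'   paired mode.
#' @param error_rate Per-base probability of a uniform substitution error.
#' @param const_qual Constant Phred quality assigned to every base.
#' @param seed Integer seed; identical inputs give byte-identical libraries.
#' @param designs Which libraries to simulate.
#' @return Named list of [sat_library()] objects.
#' @export
simulate_reads <- function(genome, coverage = 0.5, read_len = 150L,
                           paired = TRUE, insert_mean = 300L,
                           error_rate = 0.001, const_qual = 40L, seed = 1L,
                           designs = c("male", "female", "X", "Y")) {
  comps <- if (inherits(genome, "sat_genome")) genome$compartments else genome
  if (is.null(names(comps)) || length(comps) == 0L)
    stopf("genome must provide named compartments")
  if (paired && insert_mean < 2 * read_len)
    stopf("insert_mean must be >= 2 * read_len in paired mode")
  sizes <- vapply(comps, nchar, integer(1))
  cov <- if (length(coverage) == 1L)
    stats::setNames(rep(coverage, length(designs)), designs) else coverage
  roles <- c(male = "male_genome", female = "female_genome",
             X = "X_chromosome", Y = "Y_chromosome")
  out <- list()
  for (d in designs) {
    w <- ploidy_weights(sizes, d)
    if (all(w * sizes == 0)) stopf("library design %s selects no compartment", d)
    frag <- if (paired) insert_mean else read_len
    usable <- pmax(sizes - frag + 1L, 0L) * (w > 0)
    if (all(usable == 0))
      stopf("compartments too small for %d bp fragments", frag)
    # Read count targets `coverage` over the union of selected compartments;
    # the ploidy map weights only where fragments are drawn from.
    n_pairs <- round(cov[[d]] * sum(sizes[w > 0]) /
                       (if (paired) 2 * read_len else read_len))
    lib <- with_seed(derive_seed(seed, 31 * match(d, c("male", "female",
                                                       "X", "Y"))), {
      ci <- sample.int(length(comps), n_pairs, replace = TRUE,
                       prob = w * sizes)
      start <- floor(stats::runif(n_pairs) * usable[ci]) + 1L
      fragseq <- substring(comps[ci], start, start + frag - 1L)
      flip <- stats::runif(n_pairs) < 0.5
      fragseq[flip] <- revcomp(fragseq[flip])
      r1 <- substring(fragseq, 1L, read_len)
      if (paired) {
        r2 <- revcomp(substring(fragseq, frag - read_len + 1L, frag))
      } else r2 <- NULL
      add_errors <- function(x) {
        if (error_rate <= 0 || length(x) == 0L) return(x)
        B <- sum(nchar(x))
        n_err <- stats::rbinom(1, B, error_rate)
        if (n_err == 0L) return(x)
        pos <- sort(sample.int(B, n_err))
        offs <- cumsum(c(0L, nchar(x)))
        ridx <- findInterval(pos - 1L, offs, rightmost.closed = FALSE)
        within <- pos - offs[ridx]
        for (j in seq_along(pos)) {
          cur <- substr(x[ridx[j]], within[j], within[j])
          substr(x[ridx[j]], within[j], within[j]) <-
            sample(setdiff(DNA_BASES, cur), 1)
        }
        x
      }
      r1 <- add_errors(r1)
      if (paired) r2 <- add_errors(r2)
      q <- strrep(int_to_qual(const_qual), read_len)
      ids <- sprintf("%s_read%06d", d, seq_len(n_pairs))
      sat_library(ids, r1, qual = rep(q, n_pairs),
                  seq2 = r2,
                  qual2 = if (paired) rep(q, n_pairs) else NULL,
                  label = d, role = roles[[d]])
    })
    out[[d]] <- lib
  }
  out
}

#' Named preset genome scenarios
#'
#' Returns `genome_spec` presets emulating the canonical situations the
#' comparative analysis is designed to detect:
#'
#' * `y_amplified` - one family massively amplified on the Y (male/female
#'   abundance ratio 10 by construction) with a young pulse at 5% and an old
#'   pulse at 25% divergence, giving a two-peaked repeat landscape.
#' * `x_amplified` - one family amplified on the X (female-biased).
#' * `autosomal` - a centromeric-style family on one autosome only.
#' * `subfamilies` - a family with a Y-fixed diagnostic subfamily for
#'   haplotype network tests.
#' * `sex_mix` - the Y-amplified and X-amplified families planted together,
#'   for joint male/female and X/Y comparisons.
#' * `discovery_mix` - five unrelated families (repeat units 16-400 bp,
#'   abundances 0.1-5% of the genome) for discovery-recovery benchmarks.
#'
#' @param prefix Name prefix for planted families.
#' @return Named list of [genome_spec()] objects.
#' @export
standard_scenarios <- function(prefix = "Sim") {
  std <- c(autosome1 = 400000, X = 200000, Y = 200000)
  fam <- function(...) family_spec(...)
  list(
    y_amplified = genome_spec(std, list(
      fam(paste0(prefix, "Y-171"), length = 171, at_fraction = 0.58,
          pulses = data.frame(divergence = c(0.05, 0.25),
                              weight = c(0.5, 0.5)),
          copies = c(X = 30, Y = 570),
          n_arrays = c(X = 1L, Y = 19L))), seed = 101L),
    x_amplified = genome_spec(std, list(
      fam(paste0(prefix, "X-98"), length = 98, at_fraction = 0.62,
          pulses = data.frame(divergence = c(0.04, 0.14),
                              weight = c(0.7, 0.3)),
          copies = c(X = 300, Y = 6), n_arrays = 4L)), seed = 102L),
    autosomal = genome_spec(std, list(
      fam(paste0(prefix, "A-120"), length = 120, at_fraction = 0.55,
          pulses = data.frame(divergence = 0.03, weight = 1),
          copies = c(autosome1 = 250), n_arrays = 2L)), seed = 103L),
    subfamilies = genome_spec(std, list(
      fam(paste0(prefix, "S-64"), length = 64, at_fraction = 0.60,
          pulses = data.frame(divergence = 0.01, weight = 1),
          copies = c(X = 120, Y = 120), n_arrays = 2L,
          subfamilies = list(list(positions = c(10L, 30L, 50L),
                                  bases = c("A", "C", "G"),
                                  compartments = "Y")))), seed = 104L),
    sex_mix = genome_spec(std, list(
      fam(paste0(prefix, "Y-171"), length = 171, at_fraction = 0.58,
          pulses = data.frame(divergence = c(0.05, 0.25),
                              weight = c(0.5, 0.5)),
          copies = c(X = 30, Y = 570),
          n_arrays = c(X = 1L, Y = 19L)),
      fam(paste0(prefix, "X-98"), length = 98, at_fraction = 0.62,
          pulses = data.frame(divergence = c(0.04, 0.14),
                              weight = c(0.7, 0.3)),
          copies = c(X = 300, Y = 6), n_arrays = c(X = 10L, Y = 3L))),
      seed = 106L),
    discovery_mix = genome_spec(c(autosome1 = 4e6), list(
      fam(paste0(prefix, "M-400"), length = 400, at_fraction = 0.46,
          pulses = data.frame(divergence = 0.05, weight = 1),
          copies = c(autosome1 = 500), n_arrays = 4L),
      fam(paste0(prefix, "M-171"), length = 171, at_fraction = 0.55,
          pulses = data.frame(divergence = 0.05, weight = 1),
          copies = c(autosome1 = 468), n_arrays = 4L),
      fam(paste0(prefix, "M-120"), length = 120, at_fraction = 0.60,
          pulses = data.frame(divergence = 0.05, weight = 1),
          copies = c(autosome1 = 333), n_arrays = 4L),
      fam(paste0(prefix, "M-50"), length = 50, at_fraction = 0.68,
          pulses = data.frame(divergence = 0.05, weight = 1),
          copies = c(autosome1 = 400), n_arrays = 2L),
      fam(paste0(prefix, "M-16"), length = 16, at_fraction = 0.75,
          pulses = data.frame(divergence = 0.05, weight = 1),
          copies = c(autosome1 = 250), n_arrays = 1L)), seed = 105L)
  )
}
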