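---
title: "Satellitome discovery and sex-chromosome satDNA analysis: models and methods"
author: "satellitome package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellitome discovery and sex-chromosome satDNA analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satellitome)
```

# The problem

Satellite DNAs (satDNAs) are tandemly repeated, largely heterochromatic
sequences that can make up a substantial fraction of a genome yet are
nearly absent from assemblies. In species with achiasmatic males —
where the X and Y never recombine — individual satDNA families can
amplify independently on each sex chromosome, so comparing their
abundance and divergence between a male genome, a female genome, and
microdissected X and Y chromosome libraries reveals when and where
amplification happened. This package implements that comparative
workflow directly from unassembled short reads (150 bp paired-end in the
motivating design), plus a synthetic-genome simulator that plants
satellite families with known truth so every stage can be validated
quantitatively.

# Pipeline overview

A run proceeds: quality trimming, read subsampling, iterative satellite
discovery with read subtraction, exclusion screening, grouping into
families and superfamilies, abundance-ranked naming, per-library
quantification, Kimura 2-parameter (K2P) repeat landscapes, male/female
and X/Y comparison, divergence dating, minimum-spanning-tree (MST)
haplotype networks, and an optional transposable-element (TE)
association screen. `run_satellitome()` orchestrates the stages;
each is also exported on its own.

# Models and algorithms

## Quality trimming

`quality_trim()` applies, per read and in this order: removal of leading
and trailing bases below quality 3; a 5'-to-3' sliding-window scan (4
bases, mean quality 20) that cuts the read at the start of the first
failing window; a 100-base minimum-length filter; and a crop to 101
bases. The unusual crop-after-minimum order is deliberate — it
reproduces a widely used satellite-screening recipe verbatim, so results
are comparable with studies that used it. Pairs are dropped whenever
either mate is dropped, keeping mate streams synchronized (the recipe
itself is silent on pairing).

## Graph-based clustering and tandem consensus inference

`cluster_reads()` joins two reads when they share at least one canonical
k-mer (k = 21 by default; canonical = the lexicographic minimum of a
k-mer and its reverse complement, encoded as exact 2-bit integers for
speed) and takes connected components. Reads from a high-copy tandem
family share their monomer k-mers and collapse into one large component;
single-copy background reads only connect where they genuinely overlap,
so at the shallow sampling depths used for discovery (well below 1x)
they form small chance components. Components holding at least
`min_cluster_fraction` of sampled nucleotides (default 0.05%) are
examined.

`infer_monomer()` builds the de Bruijn graph of a cluster's k-mers (both
strands), starts from the highest-count k-mer, and follows the
highest-count successor (ties broken lexicographically, which makes the
walk deterministic) until a node recurs; the recurrent portion spells
the consensus cycle and its node count is the repeat unit length (RUL).
A 16 bp monomer is recovered exactly even though k = 21 exceeds it: the
k-mers of a 16-periodic sequence form a 16-node cycle. The consensus is
then polished by per-position majority vote of cluster reads aligned to
the tandem-repeated cycle and canonicalized with `canonical_monomer()`
(rotation- and strand-invariant).

`tandem_score` is the fraction of cluster k-mer mass on the cycle. For
error-free exact tandems it is 1; diverged copies dilute it roughly as
$(1-d)^k$ — about 0.34 at 5% divergence — so the default acceptance
threshold is a permissive 0.1. Clusters with no cycle (background,
dispersed repeats) score 0 and are flagged non-tandem.

Monomers longer than the read length are recoverable through the cycle
walk alone, since no read contains a full unit; polishing then uses
piecewise alignment to the repeated cycle. Accuracy degrades as RUL
grows far beyond the read length, so validation scenarios cap planted
RULs at 400 bp.

## Iterative discovery

`iterate_discovery()` loops sample - cluster - infer - subtract until a
round adds no new candidate. `subtract_reads()` removes read pairs with
a local alignment to any candidate dimer at >= 80% identity covering >=
50% of the read, so each round exposes progressively rarer families.
Candidates are deduplicated across rounds at 95% rotation/strand-aware
identity.

Discovery sampling depth matters: the read-overlap graph of background
sequence percolates when the expected overlap degree
(about `2 * (L - k) / L * coverage`) approaches 1, merging everything
into one component. Sampling below roughly 0.5x background coverage —
as the protocols this emulates do, by drawing a few hundred thousand
reads from multi-gigabase genomes — keeps background subcritical while
satellite families, whose reads cluster by shared monomer k-mers
regardless of genomic position, still form large components.

## Family and superfamily grouping

`pairwise_identity()` scores two monomers as the best global-alignment
identity over all rotations of one sequence and of its reverse
complement against the other. Equal-length monomers are compared
gaplessly over rotations (variants of a family differ by substitutions
under this model); unequal lengths use a gapped global alignment with
deliberately stiff gap penalties, because cheap gaps let an aligner
disguise substitutions as compensating indel pairs and inflate
identity. `group_families()` single-links candidates at >= 95% identity
into families and families at >= 80% into superfamilies; candidate sets
below 80% belong to different superfamilies. The 80% rule is the
community convention for superfamily assignment; the 95% variant level
follows the same protocol family. Superfamilies with at least two
families are labeled SF-1, SF-2, ... by descending abundance.
`name_families()` assigns `Sat{NN}-{RUL}` names by descending
male-library abundance with deterministic tie-breaks (descending RUL,
then consensus sequence).

## Quantification and repeat landscapes

`quantify_library()` aligns reads against each family's consensus
repeated head-to-tail (at least a dimer, tiled further for monomers
shorter than a read) so monomer-junction reads align contiguously. Hits
use a global-local alignment — the entire read placed within the
reference — because local alignment trims high-mismatch read ends and
biases per-read divergence downward. For the same reason the
divergence path uses stiff gap penalties (open 4, extend 1); the
hit-screening paths (subtraction, exclusion and TE screens) keep the
conventional match +1 / mismatch -1 / gap open -2 / extend -0.5
scoring. Substitution columns are classified as transitions (A-G, C-T)
or transversions over ungapped columns, and each hit carries
$K = -\tfrac12 \ln[(1 - 2P - Q)\sqrt{1 - 2Q}]$, the K2P distance, with
saturated hits (non-positive log argument) flagged rather than forced.

Each read is attributed to its best-scoring family only, so family
proportions never double-count and sum to at most 100%.
`repeat_landscape()` bins each hit's read bases by K2P divergence (1%
bins over 0-50% plus a saturation overflow bin); bin masses sum exactly
to the family's abundance estimate. Two tunables matter for old,
highly diverged families: the identity floor (default 0.7) should be
lowered to about 0.6 when divergences near 30% are of interest, and the
pre-filter k-mer length (default 11) to 9-10, since a read must retain
one intact k-mer to be considered at all. Landscape peak positions are
located by `find_landscape_peaks()` as local maxima of lightly smoothed
bins refined to the local mass centroid; the raw argmax of a broad,
noisy bump sits systematically below the true pulse position because
K2P is a convex transform of the per-read mismatch fraction.

## Sex comparisons

`compare_libraries()` forms male/female, female/male and X/Y abundance
ratios and flags families above a ratio threshold. Note an X-linked
family's theoretical female/male ratio under the ploidy map is at most
2 (females carry two X's, males one), so the default threshold of 2 can
never flag pure X-linkage; analyses targeting X-linked families should
use a threshold of about 1.5, as the examples here do.

## Dating

`mean_pairwise_distance()` averages pairwise K2P distances within one
monomer set or across two sets (plain cross-pair mean; no net
correction — a configurable choice, since the tools this mirrors do not
document theirs). Saturated pairs are excluded and counted.
`divergence_time()` converts divergence to time as $T = K/(2r)$ with
$r = 1.11\times10^{-8}$ substitutions per site per year (a satellite
turnover rate estimated in orthopteran satellitome work, assuming one
generation per year); doubling the rate halves the time. Times are
displayed as millions of years to one decimal.

## Haplotype networks

`extract_monomers()` cuts, from each read whose indel-free alignment
spans a complete monomer unit starting at consensus coordinate 0, exactly
that first unit, reported on the consensus strand. Phase anchoring is a
fixed convention (the underlying protocols do not state a cut phase) and
makes haplotypes positionally comparable, so Hamming distance — not edit
distance — is the right metric downstream. `filter_singletons()` removes
haplotypes observed once (likely sequencing errors). `build_mst()` runs
Kruskal's algorithm on all pairwise Hamming distances with a fully
deterministic tie-break (distance, then higher summed endpoint counts,
then lexicographic endpoint sequences); `spanning_tree_min_weight()`
provides an exhaustive Prufer-enumeration check for small instances.
Layout is presentation, topology is the contract.

## TE association and genome-size arithmetic

`te_association()` scores each consensus against a user-supplied TE
FASTA by local alignment on both strands, reporting consensus coverage
(percent of positions inside the union of hit intervals) and best-hit
similarity, with reporting flags at coverage > 50% and similarity > 60%.
A user-supplied library replaces external database searches so runs are
self-contained and reproducible.

`pg_to_gb()` converts picograms to gigabases in two modes: `unit`
(1 pg = 1 Gb, the rounding convention used when genome sizes are quoted
interchangeably in pg and Gb) and `standard` (0.978 Gb/pg).
`apportion_x()` solves the constraint that each of `n` autosomes is a
fixed fraction $\rho$ of the X: $X = G/(1 + n\rho)$, with the
conservation identity exact. With a 2.75 Gb haploid genome, 11
autosomes and $\rho = 0.1$ this gives an X of about 1.3 Gb and
autosomes of about 130 Mb. The default of 11 autosomes follows the
phrasing of the motivating karyotype description even though a
2n = 22 = 20 + XY karyotype implies 10 autosome pairs; both choices
round to the same headline sizes.

# The synthetic-data generator

`plant_genome()` builds i.i.d. uniform background compartments
(autosomes, X, Y) and embeds each family's copies head-to-tail in
arrays at uniform random non-overlapping positions. Each copy samples
an amplification pulse and mutates every site independently with
probability equal to the pulse divergence; a mutated site is a
transition with probability $\kappa/(\kappa+2)$ (default $\kappa = 2$,
i.e. transitions and transversions in equal numbers). The model is
per-site i.i.d. rather than a continuous-time chain: multiple hits are
absent, realized divergence equals the mutated-site fraction, and the
truth table stays exactly interpretable. Planted divergences should
stay below about 0.3; saturation behavior cannot be emulated this way.
Copies of one pulse are laid contiguously within arrays, as
amplification bursts copy contiguously — interleaving pulses would smear
read-level landscapes through reads straddling copies of different
ages.

`simulate_reads()` draws uniform fragments under the ploidy map (male:
autosomes x2 + X + Y; female: autosomes x2 + X x2; microdissected X or
Y: that compartment alone), with fixed insert length, a uniform
substitution error process (no indel errors) and constant base
qualities. Coverage counts over the union of selected compartments.
The truth table records exact per-compartment abundances and per-pulse
realized raw and K2P divergences; `truth_abundance()` maps them through
the ploidy weights to exact expected library abundances.

What the generator does *not* emulate: low-complexity background,
higher-order repeat structure, array interruptions and inversions,
indel sequencing errors, realistic quality profiles, and the
amplification bias of degenerate-oligonucleotide-primed PCR in
microdissected libraries. Passing tests therefore demonstrate correct
recovery of the model's idealized signal, not robustness to every
artifact of real libraries.

## Preset scenarios and validation scale

`standard_scenarios()` fixes the validation conditions:

* `y_amplified` / `sex_mix`: a 171 bp family with 570 Y copies and 30 X
  copies in equal-sized arrays (so array-edge losses cancel in the
  male/female ratio), giving a male/female abundance ratio of exactly 10
  under the ploidy map, with pulses at 5% and 25% divergence in equal
  parts; `sex_mix` adds a 98 bp X-amplified family (300 X, 6 Y copies).
* `autosomal`: a 120 bp centromeric-style family on one autosome.
* `subfamilies`: a 64 bp family with a Y-fixed diagnostic subfamily for
  haplotype-network tests.
* `discovery_mix`: five unrelated families (RULs 400, 171, 120, 50,
  16 bp; A+T 46-75%; abundances 5, 2, 1, 0.5 and 0.1% of a 4 Mb
  genome). The genome size is chosen so the rarest family still yields
  on the order of 20 read pairs at the 0.8x sampling the benchmarks
  use; the rarest family sits in a single array so edge effects stay
  small relative to its size.

Validation runs 20 seeds per scenario; the acceptance script uses 5-10
seeds per scenario so a full reproduction stays within a few minutes.
Recovery is asserted per seed (every family, >= 95% consensus identity
up to rotation and strand); abundance calibration is asserted on the
per-family mean across seeds, because at the 0.1% abundance floor a
single seed's estimate rests on ~20 attributed reads and its +-20% band
would measure Poisson noise rather than estimator bias. The
male/female ratio check (within a factor 1.5 of the designed 10) holds
per seed at the simulated depths; X/Y ordering is required in every
seed.

# Numerical choices and degenerate inputs

* All randomness flows through explicit integer seeds; derived seeds
  stay below $2^{31}$. Identical inputs give byte-identical outputs.
* Greedy-walk ties, Kruskal ties, naming ties: all broken
  deterministically (lexicographic or count-based), so results are
  invariant to input order.
* `k2p_distance()` returns `NA` as the saturation marker; landscape
  code routes saturated hits to the overflow bin, dating code excludes
  and counts them.
* Empty inputs: a repeat-free genome yields an empty candidate list,
  an empty catalogue and valid (empty) reports; singleton-only
  haplotype sets warn and return an empty set; fewer than two sequences
  make within-group distances undefined (`NA`) rather than zero.
* N bases: quality rules treat N through its recorded quality;
  consensus and canonical-form code requires unambiguous A/C/G/T.

# Known limitations

* Consensus accuracy for monomers much longer than the read length
  (multi-kilobase RULs) is limited by cycle-walk coverage; such families
  are detected but their consensus may be locally imprecise.
* Read-level landscape peaks for old pulses sit slightly below the
  copy-level divergence (convex-transform mode shift); the centroid
  refinement in `find_landscape_peaks()` removes most but not all of
  this.
* Abundance estimates lose mass at array edges (reads straddling an
  array boundary fail the identity floor) and gain none from it; for
  families in long arrays the effect is negligible, for a family split
  into many short arrays it can reach several percent of the family's
  abundance.
* The discovery loop assumes satellite families dominate their
  clusters; a family present only as highly diverged copies (> ~25%)
  thins its consensus k-mer path and may be missed at low depth.
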