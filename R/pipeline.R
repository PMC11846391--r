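# End-to-end orchestration: configuration, the full satellitome run, and
# synthetic dataset writing.

CONFIG_FIELDS <- c("prefix", "seed", "trim", "sample_pairs", "k",
                   "min_shared", "min_cluster_fraction", "min_tandem_score",
                   "rounds_max", "dedup_identity", "subtract_identity",
                   "subtract_cover", "variant_threshold",
                   "superfamily_threshold", "exclusion_fasta", "te_fasta",
                   "quant_sample_pairs", "min_identity", "min_cover_read",
                   "ratio_threshold", "rate_r", "mst_families",
                   "mst_min_count", "out_dir")

#' Pipeline configuration
#'
#' Collects every tunable of the satellitome pipeline with its default.
#' Unknown fields are rejected, and every random operation derives its seed
#' from the single `seed` here, making a run fully reproducible.
#'
#' @param ... Named overrides of the defaults (see the field list in the
#'   source; e.g. `seed`, `sample_pairs`, `k`, `rate_r`, `out_dir`).
#' @return A `satellitome_config` list.
#' @export
satellitome_config <- function(...) {
  cfg <- list(prefix = "", seed = 1L, trim = TRUE, sample_pairs = 200000L,
              k = 21L, min_shared = 1L, min_cluster_fraction = 5e-4,
              min_tandem_score = 0.1, rounds_max = 8L,
              dedup_identity = 0.95, subtract_identity = 0.8,
              subtract_cover = 0.5, variant_threshold = 0.95,
              superfamily_threshold = 0.80, exclusion_fasta = NULL,
              te_fasta = NULL, quant_sample_pairs = NULL,
              min_identity = 0.7, min_cover_read = 0.5,
              ratio_threshold = 2, rate_r = 1.11e-8, mst_families = NULL,
              mst_min_count = 2L, out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), CONFIG_FIELDS)
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "satellitome_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the satellitome pipeline end to end
#'
#' Executes trim, subsample, iterative discovery (on the pooled male+female
#' reads), exclusion screening, family/superfamily grouping,
#' abundance-ranked naming, per-library quantification, repeat landscapes,
#' library comparison, the sex-divergence dating report, haplotype MSTs and
#' the TE-association screen, and (when `out_dir` is set) writes every table
#' plus a run manifest.
#'
#' @param libs Named list of [sat_library()] objects; requires `male` and
#'   `female`, uses `X` and `Y` when present.
#' @param cfg A [satellitome_config()].
#' @return A `satellitome_result` list: `catalogue`, `comparison`,
#'   `landscapes`, `dating`, `msts`, `te`, `discovery_log`, `config`.
#' @export
run_satellitome <- function(libs, cfg = satellitome_config()) {
  stopifnot(inherits(cfg, "satellitome_config"))
  for (need in c("male", "female")) {
    if (!need %in% names(libs)) stopf("missing required library '%s'", need)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (cfg$trim && !is.null(libs$male$qual))
    libs <- stage("trim", lapply(libs, quality_trim))

  pool <- stage("pool", {
    n <- min(length(libs$male), length(libs$female), cfg$sample_pairs)
    m <- sample_reads(libs$male, n, seed = derive_seed(cfg$seed, 1))
    f <- sample_reads(libs$female, n, seed = derive_seed(cfg$seed, 2))
    sat_library(c(paste0(m$id, "_M"), paste0(f$id, "_F")),
                c(m$seq, f$seq), qual = c(m$qual, f$qual),
                seq2 = if (m$paired) c(m$seq2, f$seq2) else NULL,
                qual2 = if (m$paired) c(m$qual2, f$qual2) else NULL,
                label = "pooled_mf")
  })
  disc <- stage("discovery", iterate_discovery(
    pool, rounds_max = cfg$rounds_max, sample_pairs = cfg$sample_pairs,
    k = cfg$k, min_shared = cfg$min_shared,
    min_cluster_fraction = cfg$min_cluster_fraction,
    min_tandem_score = cfg$min_tandem_score,
    dedup_identity = cfg$dedup_identity,
    subtract_identity = cfg$subtract_identity,
    subtract_cover = cfg$subtract_cover, seed = derive_seed(cfg$seed, 3)))
  cands <- disc$candidates
  if (!is.null(cfg$exclusion_fasta) && length(cands))
    cands <- stage("screen",
                   screen_exclusions(cands, cfg$exclusion_fasta)$kept)

  empty_catalogue <- data.frame(name = character(0), consensus = character(0),
                                rul = integer(0), at_fraction = numeric(0),
                                family_id = integer(0),
                                superfamily = character(0))
  if (!length(cands)) {
    result <- list(catalogue = empty_catalogue,
                   comparison = NULL, landscapes = NULL,
                   dating = NULL, msts = list(), te = NULL,
                   discovery_log = disc$log, config = cfg)
  } else {
    grp <- stage("group", group_families(cands, cfg$variant_threshold,
                                         cfg$superfamily_threshold))
    fams <- grp$families
    cat0 <- data.frame(name = paste0("fam", fams$family_id),
                       consensus = fams$consensus, rul = fams$rul)
    quants <- stage("quantify", lapply(seq_along(libs), function(i) {
      quantify_library(libs[[i]], cat0,
                       sample_pairs = cfg$quant_sample_pairs,
                       seed = derive_seed(cfg$seed, 10 + i),
                       min_identity = cfg$min_identity,
                       min_cover_read = cfg$min_cover_read)
    }))
    names(quants) <- names(libs)
    abund <- do.call(cbind, lapply(quants, `[[`, "abundance"))
    fams <- stage("name", name_families(fams, abund[, "male"],
                                        prefix = cfg$prefix))
    # Re-key everything by final names.
    key <- match(paste0("fam", fams$family_id), cat0$name)
    catalogue <- data.frame(name = fams$name, consensus = fams$consensus,
                            rul = fams$rul, at_fraction = fams$at_fraction,
                            family_id = fams$family_id,
                            superfamily = fams$superfamily)
    for (lb in names(quants))
      catalogue[[paste0("abundance_", lb)]] <- abund[key, lb]
    ab <- abund[key, , drop = FALSE]
    rownames(ab) <- catalogue$name
    comparison <- stage("compare", compare_libraries(
      ab, ratio_threshold = cfg$ratio_threshold,
      x = if ("X" %in% names(libs)) "X" else NULL,
      y = if ("Y" %in% names(libs)) "Y" else NULL))
    landscapes <- stage("landscape", do.call(rbind, unlist(lapply(
      names(quants), function(lb) {
        lapply(seq_len(nrow(catalogue)), function(i) {
          h <- quants[[lb]]$hits[[paste0("fam", catalogue$family_id[i])]]
          repeat_landscape(h, family = catalogue$name[i],
                           total_bases = quants[[lb]]$total_bases,
                           library_label = lb)
        })
      }), recursive = FALSE)))
    dating <- stage("dating", sex_divergence_report(
      catalogue, libs, dating_config(rate_r = cfg$rate_r)))
    mst_fams <- cfg$mst_families %||%
      utils::head(catalogue$name[catalogue$rul < 151], 3L)
    msts <- stage("mst", {
      out <- list()
      for (fm in mst_fams) {
        row <- catalogue[catalogue$name == fm, ]
        if (!nrow(row)) next
        per_lib <- lapply(names(libs), function(lb)
          extract_monomers(libs[[lb]], row$consensus))
        mono <- unlist(per_lib, use.names = FALSE)
        grps <- rep(names(libs), lengths(per_lib))
        if (length(mono) < 2L) next
        haps <- tryCatch(filter_singletons(mono, grps),
                         warning = function(w) NULL)
        if (is.null(haps) || nrow(haps) < 2L) next
        out[[fm]] <- build_mst(haps)
      }
      out
    })
    te <- if (!is.null(cfg$te_fasta))
      stage("te", te_association(catalogue, cfg$te_fasta)) else NULL
    result <- list(catalogue = catalogue, comparison = comparison,
                   landscapes = landscapes, dating = dating, msts = msts,
                   te = te, discovery_log = disc$log, config = cfg)
  }
  class(result) <- "satellitome_result"
  if (!is.null(cfg$out_dir)) write_result_bundle(result, cfg$out_dir)
  result
}

#' @export
print.satellitome_result <- function(x, ...) {
  cat(sprintf("<satellitome_result> %d families\n", nrow(x$catalogue)))
  invisible(x)
}

# Write every result table plus a manifest echoing parameters and seeds.
write_result_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(result$catalogue, p("catalogue.tsv"))
  if (!is.null(result$comparison))
    write_tsv(result$comparison, p("comparison.tsv"))
  if (!is.null(result$landscapes))
    utils::write.csv(result$landscapes, p("landscapes.csv"),
                     row.names = FALSE, quote = FALSE)
  if (!is.null(result$dating)) write_tsv(result$dating, p("dating.tsv"))
  write_tsv(result$discovery_log, p("discovery_log.tsv"))
  if (!is.null(result$te)) write_tsv(result$te, p("te_association.tsv"))
  for (fm in names(result$msts)) {
    g <- result$msts[[fm]]
    write_tsv(g$edges, p(sprintf("mst_%s_edges.tsv", fm)))
    write_tsv(g$nodes, p(sprintf("mst_%s_nodes.tsv", fm)))
  }
  cfg <- result$config
  manifest <- list(package = "satellitome",
                   version = as.character(utils::packageVersion("satellitome")),
                   config = cfg[!vapply(cfg, is.null, logical(1))],
                   n_families = nrow(result$catalogue))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Simulate and write a synthetic dataset
#'
#' Plants a genome (from a [genome_spec()] or a [standard_scenarios()]
#' preset name), simulates the four libraries, and writes one FASTA per
#' compartment, paired FASTQ per library and the truth table as TSV.
#'
#' @param spec A [genome_spec()] or preset name.
#' @param out_dir Output directory.
#' @param coverage,read_len,error_rate,seed Passed to [simulate_reads()] /
#'   [plant_genome()].
#' @return Invisibly, a list with the `sat_genome`, the libraries and the
#'   output directory.
#' @export
simulate_dataset <- function(spec, out_dir, coverage = 0.5, read_len = 150L,
                             error_rate = 0.001, seed = NULL) {
  if (is.character(spec)) {
    presets <- standard_scenarios()
    if (!spec %in% names(presets))
      stopf("unknown scenario '%s' (available: %s)", spec,
            paste(names(presets), collapse = ", "))
    spec <- presets[[spec]]
  }
  stopifnot(inherits(spec, "genome_spec"))
  seed <- seed %||% spec$seed
  genome <- plant_genome(spec, seed = seed)
  libs <- simulate_reads(genome, coverage = coverage, read_len = read_len,
                         error_rate = error_rate,
                         seed = derive_seed(seed, 5000))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cn in names(genome$compartments)) {
    lib <- sat_library(cn, genome$compartments[[cn]], label = cn)
    write_fastx(lib, file.path(out_dir, paste0(cn, ".fasta")))
  }
  for (lb in names(libs)) {
    write_fastx(libs[[lb]], file.path(out_dir, paste0(lb, "_R1.fastq")),
                file.path(out_dir, paste0(lb, "_R2.fastq")))
  }
  write_tsv(genome$truth, file.path(out_dir, "truth.tsv"))
  pulses <- attr(genome$truth, "pulses")
  if (!is.null(pulses))
    write_tsv(pulses, file.path(out_dir, "truth_pulses.tsv"))
  invisible(list(genome = genome, libs = libs, out_dir = out_dir))
}
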