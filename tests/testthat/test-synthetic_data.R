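test_that("make_consensus respects length bounds and base composition", {
  expect_equal(nchar(make_consensus(16, 0.5, seed = 1)), 16)
  expect_equal(nchar(make_consensus(5042, 0.5, seed = 1)), 5042)
  expect_error(make_consensus(5043, 0.5, seed = 1), "5042")
  expect_error(make_consensus(15, 0.5, seed = 1), "range")
  expect_error(make_consensus(100, 1.2, seed = 1), "between")
  # AT fraction within 3 binomial sigma at length 10,000
  s <- make_consensus(5042, 0.60, seed = 2)
  s2 <- make_consensus(4958, 0.60, seed = 3)
  long <- paste0(s, s2)
  at <- mean(strsplit(long, "")[[1]] %in% c("A", "T"))
  expect_lt(abs(at - 0.60), 3 * sqrt(0.6 * 0.4 / 10000))
  # deterministic per seed
  expect_identical(make_consensus(100, 0.6, seed = 7),
                   make_consensus(100, 0.6, seed = 7))
})

test_that("mutate_copies realizes the requested divergence and transition bias", {
  cons <- make_consensus(100, 0.5, seed = 1)
  expect_identical(mutate_copies(cons, 5, 0, seed = 2), rep(cons, 5))
  cp <- mutate_copies(cons, 1000, 0.05, kappa = 2, seed = 3)
  base <- strsplit(cons, "")[[1]]
  diffs <- vapply(cp, function(x) sum(strsplit(x, "")[[1]] != base),
                  numeric(1))
  n_sites <- 1000 * 100
  expect_lt(abs(sum(diffs) / n_sites - 0.05),
            3 * sqrt(0.05 * 0.95 / n_sites))
  # transition:transversion counts 1:1 at kappa = 2
  pur <- c("A", "G")
  ts <- 0; tv <- 0
  for (x in cp) {
    xc <- strsplit(x, "")[[1]]
    mut <- which(xc != base)
    is_ts <- (xc[mut] %in% pur) == (base[mut] %in% pur)
    ts <- ts + sum(is_ts); tv <- tv + sum(!is_ts)
  }
  n_mut <- ts + tv
  expect_lt(abs(ts / n_mut - 0.5), 3 * sqrt(0.25 / n_mut))
})

test_that("plant_genome records exact abundances and honors compartment design", {
  spec <- genome_spec(c(autosome1 = 30000, X = 20000, Y = 20000), list(
    family_spec("famA", length = 100, copies = c(X = 50, Y = 1),
                pulses = data.frame(divergence = 0, weight = 1))),
    seed = 4)
  g <- plant_genome(spec)
  tr <- g$truth
  expect_equal(tr$abundance_percent,
               100 * tr$copy_bp / tr$compartment_bp)
  ax <- tr$abundance_percent[tr$compartment == "X"]
  ay <- tr$abundance_percent[tr$compartment == "Y"]
  expect_equal(ax / ay, 50)
  # zero divergence: planted copies identical to consensus
  expect_true(all(unlist(attr(tr, "copies")) == g$consensi[["famA"]]))
  # compartment sequences have the declared sizes
  expect_equal(unname(nchar(g$compartments)), c(30000, 20000, 20000))
  # arrays that cannot fit raise a contract error
  big <- genome_spec(c(autosome1 = 1000), list(
    family_spec("famB", length = 100, copies = c(autosome1 = 20))), seed = 1)
  expect_error(plant_genome(big), "larger compartment")
})

test_that("subfamily diagnostic substitutions are fixed in their compartment", {
  spec <- standard_scenarios()$subfamilies
  g <- plant_genome(spec, seed = 10)
  cps <- attr(g$truth, "copies")
  ycopies <- cps[[grep("\\|Y$", names(cps))]]
  xcopies <- cps[[grep("\\|X$", names(cps))]]
  sf <- spec$families[[1]]$subfamilies[[1]]
  for (j in seq_along(sf$positions)) {
    expect_true(all(substr(ycopies, sf$positions[j], sf$positions[j]) ==
                      sf$bases[j]))
  }
  # X copies carry the consensus base at nearly every diagnostic site
  cons_base <- substr(g$consensi[[1]], sf$positions[1], sf$positions[1])
  expect_gt(mean(substr(xcopies, sf$positions[1], sf$positions[1]) ==
                   cons_base), 0.9)
})

test_that("simulate_reads yields the documented pair counts and error rate", {
  spec <- genome_spec(c(autosome1 = 30000), list(
    family_spec("famA", length = 100, copies = c(autosome1 = 10))), seed = 5)
  g <- plant_genome(spec)
  libs <- simulate_reads(g, coverage = 1.0, read_len = 150, paired = TRUE,
                         error_rate = 0, seed = 6, designs = "male")
  # coverage 1.0 on 30,000 bp -> 100 pairs
  expect_equal(length(libs$male), 100)
  # error-free reads are exact substrings of the compartment (either strand)
  comp <- g$compartments[["autosome1"]]
  for (r in libs$male$seq[1:20]) {
    expect_true(grepl(r, comp, fixed = TRUE) ||
                  grepl(revcomp(r), comp, fixed = TRUE))
  }
  # substitution error rate within 3 sigma on a homopolymer source
  mono <- c(autosome1 = strrep("A", 20000))
  lib_e <- simulate_reads(mono, coverage = 8, read_len = 100, paired = FALSE,
                          error_rate = 0.01, seed = 7, designs = "male")$male
  mm <- vapply(lib_e$seq, function(r) {
    ch <- strsplit(r, "")[[1]]
    min(sum(ch != "A"), sum(ch != "T"))
  }, numeric(1))
  n_bases <- sum(nchar(lib_e$seq))
  expect_gt(n_bases, 1e5)
  expect_lt(abs(sum(mm) / n_bases - 0.01), 3 * sqrt(0.01 * 0.99 / n_bases))
})

test_that("identical spec and seed give byte-identical outputs", {
  spec <- standard_scenarios()$autosomal
  g1 <- plant_genome(spec, seed = 9)
  g2 <- plant_genome(spec, seed = 9)
  expect_identical(g1$compartments, g2$compartments)
  l1 <- simulate_reads(g1, coverage = 0.2, seed = 3, designs = "male")
  l2 <- simulate_reads(g2, coverage = 0.2, seed = 3, designs = "male")
  expect_identical(l1$male$seq, l2$male$seq)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastx(l1$male, f1, tempfile(), format = "fastq")
  write_fastx(l2$male, f2, tempfile(), format = "fastq")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("truth_abundance applies the ploidy map", {
  spec <- genome_spec(c(autosome1 = 10000, X = 10000, Y = 10000), list(
    family_spec("famA", length = 100, copies = c(X = 10, Y = 10))), seed = 2)
  g <- plant_genome(spec)
  # male: (10+10)*100 over 2*10000+10000+10000; female: 2*10*100 over 40000
  expect_equal(unname(truth_abundance(g, "male")["famA"]), 100 * 2000 / 40000)
  expect_equal(unname(truth_abundance(g, "female")["famA"]), 100 * 2000 / 40000)
  expect_equal(unname(truth_abundance(g, "Y")["famA"]), 100 * 1000 / 10000)
})
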