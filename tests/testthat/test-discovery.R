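# Small, fully controlled instances for the clustering / consensus-inference
# / subtraction stack; genome-scale recovery lives in the acceptance suite.

make_array_reads <- function(monomer, n_copies, read_len, step,
                             divergence = 0, seed = 1) {
  copies <- mutate_copies(monomer, n_copies, divergence, seed = seed)
  arr <- paste(copies, collapse = "")
  starts <- seq(1, nchar(arr) - read_len, by = step)
  substring(arr, starts, starts + read_len - 1)
}

test_that("reads sharing no k-mer fall into separate singleton components", {
  set.seed(1)
  r1 <- random_read(60)
  r2 <- chartr("ACGT", "CAAC", r1)  # different alphabet usage, no shared 21-mer
  cl <- cluster_reads(c(r1, r2), k = 21, min_cluster_fraction = 0)
  expect_length(cl, 2)
  expect_equal(sort(vapply(cl, function(x) x$n_reads, integer(1))), c(1L, 1L))
  # with a realistic fraction threshold both singletons would be dropped
  cl2 <- cluster_reads(c(r1, r2), k = 21, min_cluster_fraction = 0.6)
  expect_length(cl2, 0)
})

test_that("component structure equals the brute-force all-pairs check", {
  set.seed(2)
  mono <- make_consensus(40, 0.5, seed = 3)
  sat_reads <- make_array_reads(mono, 10, 60, 17)
  bg <- vapply(rep(60, 30), random_read, character(1))
  reads <- sample(c(sat_reads, bg))
  cl <- cluster_reads(reads, k = 21, min_cluster_fraction = 0)
  memb_pkg <- integer(length(reads))
  for (i in seq_along(cl)) memb_pkg[cl[[i]]$read_idx] <- i
  memb_brute <- brute_components(reads, k = 21)
  # same partition: equal label co-membership matrices
  expect_identical(outer(memb_pkg, memb_pkg, "=="),
                   outer(memb_brute, memb_brute, "=="))
})

test_that("a planted satellite collapses into one dominant cluster", {
  set.seed(4)
  mono <- make_consensus(171, 0.55, seed = 5)
  sat_reads <- make_array_reads(mono, 40, 150, 75)  # ~2x array depth
  bg <- vapply(rep(150, 120), random_read, character(1))
  reads <- c(sat_reads, bg)
  is_sat <- c(rep(TRUE, length(sat_reads)), rep(FALSE, length(bg)))
  cl <- cluster_reads(reads, k = 21, min_cluster_fraction = 0.05)
  expect_length(cl, 1)
  expect_gte(mean(which(is_sat) %in% cl[[1]]$read_idx), 0.95)
})

test_that("infer_monomer spells exact tandems with unit repeat length", {
  reads <- substring(strrep("ACGTT", 40), seq(1, 51, by = 5),
                     seq(1, 51, by = 5) + 149)
  cand <- infer_monomer(reads, k = 21)
  expect_true(cand$tandem)
  expect_equal(cand$rul, 5)
  expect_identical(cand$consensus, canonical_monomer("ACGTT"))
  expect_equal(cand$tandem_score, 1)
})

test_that("recovered RUL equals planted RUL for error-free tandems", {
  for (rul in c(16, 50, 120)) {
    mono <- make_consensus(rul, 0.6, seed = rul)
    reads <- make_array_reads(mono, max(4, ceiling(400 / rul)), 150, 60)
    cand <- infer_monomer(reads, k = 21)
    expect_equal(cand$rul, rul)
    expect_identical(cand$consensus, canonical_monomer(mono))
  }
})

test_that("noisy reads still yield a near-exact polished consensus", {
  set.seed(6)
  mono <- make_consensus(120, 0.55, seed = 7)
  copies <- mutate_copies(mono, 30, 0.0, seed = 8)
  arr <- paste(copies, collapse = "")
  starts <- seq(1, nchar(arr) - 150, by = 55)
  reads <- substring(arr, starts, starts + 149)
  # 1% uniform read error
  reads <- vapply(reads, function(r) {
    ch <- strsplit(r, "")[[1]]
    err <- which(runif(length(ch)) < 0.01)
    for (e in err) ch[e] <- sample(setdiff(c("A", "C", "G", "T"), ch[e]), 1)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  cand <- infer_monomer(reads, k = 21)
  expect_true(cand$tandem)
  expect_lte(abs(cand$rul - 120), 1)
  expect_lte(rot_edit_dist(cand$consensus, mono), 2)
})

test_that("clusters of non-repetitive reads are flagged non-tandem", {
  set.seed(9)
  src <- random_read(600)
  reads <- substring(src, seq(1, 450, by = 30), seq(1, 450, by = 30) + 149)
  cand <- infer_monomer(reads, k = 21)
  expect_false(cand$tandem)
  expect_equal(cand$tandem_score, 0)
})

test_that("subtract_reads removes matching reads and keeps the rest", {
  set.seed(10)
  mono <- make_consensus(100, 0.5, seed = 11)
  dimer_sub <- substr(paste0(mono, mono), 30, 170)   # substring of the dimer
  keepers <- vapply(rep(140, 5), random_read, character(1))
  lib <- sat_library(paste0("r", 1:6), c(dimer_sub, keepers))
  out <- subtract_reads(lib, mono)
  expect_identical(out$seq, keepers)
  # mixed pool: removal set matches truth within 2% by count
  sat_reads <- make_array_reads(mono, 30, 120, 40, divergence = 0.02,
                                seed = 12)
  bg <- vapply(rep(120, 200), random_read, character(1))
  lib2 <- sat_library(paste0("m", seq_len(length(sat_reads) + 200)),
                      c(sat_reads, bg))
  out2 <- subtract_reads(lib2, mono)
  removed <- setdiff(lib2$id, out2$id)
  truth_ids <- paste0("m", seq_along(sat_reads))
  expect_lte(abs(length(removed) - length(truth_ids)) / length(truth_ids),
             0.02)
  expect_true(all(removed %in% truth_ids))
})

test_that("iterate_discovery terminates empty on repeat-free genomes", {
  set.seed(13)
  lib <- sat_library(paste0("r", 1:400),
                     vapply(rep(150, 400), random_read, character(1)))
  res <- iterate_discovery(lib, seed = 14)
  expect_length(res$candidates, 0)
  expect_true(all(diff(res$log$reads_remaining) <= 0))
})

test_that("discovery output is invariant to read order", {
  set.seed(15)
  mono <- make_consensus(60, 0.55, seed = 16)
  sat_reads <- make_array_reads(mono, 20, 120, 40)
  bg <- vapply(rep(120, 150), random_read, character(1))
  reads <- c(sat_reads, bg)
  lib_a <- sat_library(paste0("a", seq_along(reads)), reads)
  perm <- sample(length(reads))
  lib_b <- sat_library(paste0("b", seq_along(reads)), reads[perm])
  res_a <- iterate_discovery(lib_a, min_cluster_fraction = 0.02, seed = 17)
  res_b <- iterate_discovery(lib_b, min_cluster_fraction = 0.02, seed = 17)
  cons_a <- sort(vapply(res_a$candidates, `[[`, character(1), "consensus"))
  cons_b <- sort(vapply(res_b$candidates, `[[`, character(1), "consensus"))
  expect_identical(cons_a, cons_b)
  expect_identical(cons_a, canonical_monomer(mono))
})
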