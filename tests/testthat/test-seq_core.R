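test_that("FASTA and FASTQ round trips preserve ids, sequences and qualities", {
  set.seed(42)
  n <- 100
  ids <- sprintf("read%03d", seq_len(n))
  seqs <- vapply(sample(50:150, n, replace = TRUE), random_read, character(1))
  quals <- vapply(nchar(seqs), random_quals, character(1))
  lib <- sat_library(ids, seqs, qual = quals)

  fq <- tempfile(fileext = ".fastq")
  write_fastx(lib, fq)
  back <- read_fastx(fq, "fastq")
  expect_identical(back$id, ids)
  expect_identical(back$seq, seqs)
  expect_identical(back$qual, quals)

  fa <- tempfile(fileext = ".fasta")
  write_fastx(lib, fa, format = "fasta")
  back_fa <- read_fastx(fa, "fasta")
  expect_identical(back_fa$seq, seqs)
  expect_identical(back_fa$id, ids)
})

test_that("parser flags soft-masked records and rejects malformed input", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTacgt", ">b", "ACGTACGT"), fa)
  lib <- read_fastx(fa)
  expect_identical(lib$seq, c("ACGTACGT", "ACGTACGT"))
  expect_identical(lib$masked, c(TRUE, FALSE))

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "III"), bad)
  expect_error(read_fastx(bad, "fastq"))

  expect_error(read_fastx(tempfile(), "fasta"), "not found")
})

test_that("quality_trim applies the five rules in order", {
  p <- trim_params()
  # 150 bp all Q40: nothing trimmed, cropped to 101.
  lib <- sat_library("r1", random_read(150), qual = strrep("I", 150))
  out <- quality_trim(lib, p)
  expect_equal(nchar(out$seq), 101)
  # all Q2: leading rule eats everything.
  lib2 <- sat_library("r2", random_read(150),
                      qual = strrep(rawToChar(as.raw(2 + 33)), 150))
  expect_equal(length(quality_trim(lib2, p)), 0)
  # reads without qualities are rejected.
  expect_error(quality_trim(sat_library("r", "ACGT"), p), "qualities")
})

test_that("quality_trim matches the brute-force five-rule reference", {
  set.seed(7)
  p <- trim_params(leading_q = 5, trailing_q = 6, window_len = 4,
                   window_q = 22, min_len = 40, crop = 90)
  n <- 200
  seqs <- vapply(sample(30:150, n, replace = TRUE), random_read, character(1))
  quals <- vapply(nchar(seqs), random_quals, character(1))
  lib <- sat_library(sprintf("r%03d", seq_len(n)), seqs, qual = quals)
  out <- quality_trim(lib, p)
  expected <- lapply(seq_len(n), function(i) {
    brute_trim(seqs[i], as.integer(charToRaw(quals[i])) - 33L, p)
  })
  keep <- vapply(expected, function(e) nchar(e$seq) > 0, logical(1))
  expect_identical(out$id, lib$id[keep])
  expect_identical(out$seq, vapply(expected[keep], `[[`, character(1), "seq"))
})

test_that("paired trimming drops both mates when either fails", {
  good <- strrep("I", 150)
  bad <- strrep(rawToChar(as.raw(2 + 33)), 150)
  lib <- sat_library(c("p1", "p2"),
                     c(random_read(150), random_read(150)),
                     qual = c(good, good),
                     seq2 = c(random_read(150), random_read(150)),
                     qual2 = c(good, bad))
  out <- quality_trim(lib)
  expect_identical(out$id, "p1")
  expect_equal(nchar(out$seq2), 101)
})

test_that("trimmed read lengths are never above crop nor below min_len", {
  set.seed(11)
  p <- trim_params()
  seqs <- vapply(rep(150, 100), random_read, character(1))
  # mix of noisy and clean quality profiles so both outcomes occur
  quals <- c(vapply(rep(150, 50), random_quals, character(1)),
             rep(strrep("I", 150), 50))
  out <- quality_trim(sat_library(paste0("r", 1:100), seqs, qual = quals), p)
  expect_gt(length(out), 0)
  expect_lt(length(out), 100)
  expect_true(all(nchar(out$seq) >= p$min_len))
  expect_true(all(nchar(out$seq) <= p$crop))
})

test_that("canonical_monomer is invariant under rotation and strand", {
  expect_identical(canonical_monomer("AAA"), "AAA")
  set.seed(3)
  for (i in 1:30) {
    s <- random_read(sample(5:30, 1))
    k <- sample(nchar(s), 1)
    rot <- paste0(substr(s, k, nchar(s)), substr(s, 1, k - 1))
    expect_identical(canonical_monomer(s), canonical_monomer(revcomp(rot)))
  }
  # idempotence
  s <- random_read(25)
  expect_identical(canonical_monomer(canonical_monomer(s)),
                   canonical_monomer(s))
  expect_error(canonical_monomer(""), "non-empty")
  expect_error(canonical_monomer("ACGN"), "unambiguous")
})

test_that("canonical_monomer equals brute-force enumeration of all candidates", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_read(20)
    expect_identical(canonical_monomer(s), brute_canonical(s))
  }
})

test_that("sample_reads is deterministic, complete and uniform", {
  set.seed(8)
  n <- 10
  lib <- sat_library(paste0("r", 1:n), vapply(rep(50, n), random_read,
                                              character(1)))
  full <- sample_reads(lib, n, seed = 1)
  expect_setequal(full$id, lib$id)
  a <- sample_reads(lib, 4, seed = 99)
  b <- sample_reads(lib, 4, seed = 99)
  expect_identical(a$id, b$id)
  expect_error(sample_reads(lib, n + 1), "library holds")

  # uniformity: 10,000 single-read draws, per-read frequency within 3 sigma
  counts <- table(factor(vapply(1:10000, function(s)
    sample_reads(lib, 1, seed = s)$id, character(1)), levels = lib$id))
  expected <- 10000 / n
  sigma <- sqrt(10000 * (1 / n) * (1 - 1 / n))
  expect_true(all(abs(counts - expected) < 3 * sigma))
})
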