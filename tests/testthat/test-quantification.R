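test_that("k2p_distance evaluates the closed form and flags saturation", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0.1, 0.05), -0.5 * log(0.75 * sqrt(0.90)))
  expect_true(is.na(k2p_distance(0.5, 0)))
  expect_true(is.na(k2p_distance(0.2, 0.5)))
  expect_error(k2p_distance(-0.1, 0), "non-negative")
  # correction only inflates: K >= P + Q whenever finite
  set.seed(1)
  P <- runif(200, 0, 0.35); Q <- runif(200, 0, 0.2)
  k <- k2p_distance(P, Q)
  fin <- !is.na(k)
  expect_true(all(k[fin] >= (P + Q)[fin] - 1e-12))
})

test_that("k2p from counted P,Q matches ape's K80 distance on sequence pairs", {
  skip_if_not_installed("ape")
  set.seed(2)
  for (i in 1:25) {
    L <- 300
    a <- strsplit(random_read(L), "")[[1]]
    b <- a
    nts <- sample(0:25, 1); ntv <- sample(0:15, 1)
    sites <- sample(L, nts + ntv)
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    for (s in sites[seq_len(nts)]) b[s] <- ts_map[[b[s]]]
    for (s in sites[nts + seq_len(ntv)])
      b[s] <- setdiff(c("A", "C", "G", "T"),
                      c(b[s], ts_map[[b[s]]]))[sample(2, 1)]
    m <- ape::as.DNAbin(rbind(x = a, y = b))
    ref <- as.numeric(ape::dist.dna(m, model = "K80"))
    ours <- k2p_distance(nts / L, ntv / L)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("align_to_dimer aligns exact and junction-spanning reads in full", {
  cons <- make_consensus(100, 0.5, seed = 3)
  h <- align_to_dimer(cons, cons)
  expect_equal(h$matches, 100)
  expect_equal(h$transitions + h$transversions, 0)
  # read spanning the array junction: last 50 bp + first 100 bp of monomer
  junction <- paste0(substr(cons, 51, 100), cons)
  hj <- align_to_dimer(junction, cons)
  expect_equal(hj$aligned_cols, 150)
  expect_equal(hj$matches, 150)
  # reverse-complement reads hit on the minus strand with equal quality
  hr <- align_to_dimer(revcomp(junction), cons)
  expect_equal(hr$matches, 150)
  expect_identical(hr$strand, "-")
  # absence of a hit returns NULL
  expect_null(align_to_dimer(random_read(150), cons))
})

test_that("per-read divergence recovers the planted pulse level", {
  set.seed(4)
  cons <- make_consensus(150, 0.55, seed = 5)
  copies <- mutate_copies(cons, 60, 0.05, seed = 6)
  arr <- paste(copies, collapse = "")
  reads <- substring(arr, seq(1, nchar(arr) - 150, by = 40),
                     seq(1, nchar(arr) - 150, by = 40) + 149)
  h <- satellitome:::align_hits(reads, cons)
  raw <- mean(h$P + h$Q)
  n_sites <- sum(h$matches + h$transitions + h$transversions)
  expect_lt(abs(raw - 0.05), 3 * sqrt(0.05 * 0.95 / n_sites) + 0.002)
})

test_that("genomic proportions are exclusive and conserve landscape mass", {
  set.seed(7)
  famA <- make_consensus(100, 0.5, seed = 8)
  famB <- make_consensus(80, 0.65, seed = 9)
  bg <- random_read(6000)
  # half of all bases from famA arrays
  comp <- paste0(strrep(famA, 30), bg, strrep(famA, 30))
  genome <- c(autosome1 = comp)
  libs <- simulate_reads(genome, coverage = 6, error_rate = 0, seed = 10,
                         designs = "male")
  q <- quantify_library(libs$male, c(A = famA, B = famB))
  expect_equal(unname(q$abundance["B"]), 0)
  expect_lt(abs(q$abundance["A"] - 50), 7)
  expect_lte(sum(q$abundance), 100)
  # zero-hit library
  q0 <- quantify_library(sat_library("r1", random_read(150)),
                         c(A = famA))
  expect_equal(unname(q0$abundance["A"]), 0)
  # landscape mass conservation, and a pure spike at zero divergence
  ls <- repeat_landscape(q, family = "A")
  expect_equal(sum(ls$abundance_percent), unname(q$abundance["A"]))
  expect_equal(sum(ls$abundance_percent[ls$bin_low == 0]),
               sum(ls$abundance_percent), tolerance = 0.05)
  pk <- find_landscape_peaks(ls)
  expect_lt(min(pk), 2)
})

test_that("compare_libraries derives ratios, infinities and bias flags", {
  ab <- matrix(c(2, 1, 0.4, 2, 0, 0.4,
                 6, 0.1, 0.2, 0.5, 1.5, 0.2), nrow = 3,
               dimnames = list(c("f1", "f2", "f3"),
                               c("male", "female", "X", "Y")))
  cmp <- compare_libraries(ab)
  expect_equal(cmp$mf_ratio[1], 1)
  expect_equal(cmp$mf_ratio[2], Inf)
  expect_equal(cmp$fm_ratio[3], 1)
  expect_equal(cmp$xy_ratio[1], 6 / 0.5)
  expect_true(cmp$male_biased[2])
  expect_false(cmp$female_biased[1])
  expect_error(compare_libraries(ab[, c("male", "X", "Y")]), "female")
})
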