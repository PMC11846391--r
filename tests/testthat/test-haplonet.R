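test_that("extract_monomers cuts the first complete phase-anchored unit", {
  cons <- make_consensus(50, 0.5, seed = 1)
  tiling <- strrep(cons, 4)
  # read covering tiling coords 1-150: yields the coordinate-0 monomer
  r1 <- substr(tiling, 1, 150)
  out1 <- extract_monomers(r1, cons)
  expect_identical(out1, cons)
  # read covering coords 31-150: first complete phase-0 unit is copy 2
  copies <- c(cons,
              mutate_copies(cons, 1, 0.04, seed = 2),
              mutate_copies(cons, 1, 0.04, seed = 3),
              cons)
  arr <- paste(copies, collapse = "")
  r2 <- substr(arr, 31, 180)
  out2 <- extract_monomers(r2, cons)
  expect_identical(out2, copies[2])
  # minus-strand reads report the copy on the consensus strand
  out3 <- extract_monomers(revcomp(r2), cons)
  expect_identical(out3, copies[2])
  # repeat unit not shorter than the read length violates the contract
  expect_error(extract_monomers(r1, strrep("ACGT", 50)), "read length")
})

test_that("phase-anchored extraction reproduces planted copies", {
  set.seed(4)
  cons <- make_consensus(40, 0.6, seed = 5)
  copies <- mutate_copies(cons, 30, 0.03, seed = 6)
  arr <- paste(copies, collapse = "")
  reads <- substring(arr, seq(1, nchar(arr) - 150, by = 20),
                     seq(1, nchar(arr) - 150, by = 20) + 149)
  mono <- extract_monomers(reads, cons)
  expect_gt(length(mono), 0)
  expect_true(all(mono %in% copies))
})

test_that("filter_singletons tallies per group and removes count-1 haplotypes", {
  out <- filter_singletons(c("AAA", "AAA", "AAT"),
                           c("male", "female", "male"))
  expect_equal(nrow(out), 1)
  expect_identical(out$seq, "AAA")
  expect_equal(out$male, 1L)
  expect_equal(out$female, 1L)
  expect_equal(out$total, 2L)
  expect_warning(res <- filter_singletons(c("AAA", "AAT", "ATT"),
                                          rep("male", 3)), "singleton")
  expect_equal(nrow(res), 0)
  expect_error(filter_singletons(c("AA", "AAA"), c("m", "m")), "length")
  # error-prone monomers: every surviving haplotype has count >= 2
  set.seed(7)
  cons <- make_consensus(30, 0.5, seed = 8)
  monos <- sample(mutate_copies(cons, 8, 0.05, seed = 9), 1000,
                  replace = TRUE)
  surv <- filter_singletons(monos, rep("male", 1000))
  expect_true(all(surv$total >= 2))
})

test_that("build_mst recovers exact topologies with deterministic tie-breaks", {
  # two haplotypes: one edge of their Hamming distance
  g2 <- build_mst(c("AAAA", "AATT"))
  expect_equal(nrow(g2$edges), 1)
  expect_equal(g2$edges$distance, 2)
  expect_true(g2$is_tree)
  # star truth: one center, four single-step neighbors
  center <- "AAAAAAAAAA"
  leaves <- vapply(c(1, 4, 7, 10), function(i) {
    x <- strsplit(center, "")[[1]]; x[i] <- "G"; paste(x, collapse = "")
  }, character(1))
  gs <- build_mst(c(center, leaves))
  expect_equal(gs$total_weight, 4)
  expect_true(all(gs$edges$single_step))
  expect_true(all(gs$edges$i == 1 | gs$edges$j == 1))
  expect_error(build_mst("AAAA"), "at least 2")
})

test_that("MST weight equals the exhaustive spanning-tree minimum", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    haps <- unique(vapply(seq_len(n), function(j) random_read(12),
                          character(1)))
    if (length(haps) < 4) next
    g <- build_mst(haps)
    d <- outer(seq_along(haps), seq_along(haps),
               Vectorize(function(a, b) brute_hamming(haps[a], haps[b])))
    expect_equal(g$total_weight, spanning_tree_min_weight(d))
  }
})

test_that("MST total weight is invariant to haplotype input order", {
  set.seed(11)
  haps <- unique(vapply(1:7, function(i) random_read(15), character(1)))
  w1 <- build_mst(haps)$total_weight
  w2 <- build_mst(rev(haps))$total_weight
  w3 <- build_mst(sample(haps))$total_weight
  expect_equal(w1, w2)
  expect_equal(w1, w3)
})

test_that("shared_haplotype_report separates shared and exclusive haplotypes", {
  haps <- data.frame(seq = c("AAAA", "CCCC", "GGGG"),
                     male = c(5L, 0L, 3L), female = c(0L, 4L, 2L),
                     total = c(5L, 4L, 5L))
  class(haps) <- c("haplotype_set", "data.frame")
  rep_ <- shared_haplotype_report(haps)
  expect_identical(rep_$haplotypes$status, c("male", "female", "shared"))
  expect_equal(unname(rep_$summary["shared"]), 1L)
  expect_equal(unname(rep_$summary["male"]), 1L)
})

test_that("a Y-fixed subfamily surfaces as male-exclusive haplotypes", {
  spec <- standard_scenarios()$subfamilies
  g <- plant_genome(spec, seed = 12)
  libs <- simulate_reads(g, coverage = c(X = 2, Y = 2), seed = 13,
                         designs = c("X", "Y"))
  cons <- g$consensi[[1]]
  mono_x <- extract_monomers(libs$X, cons)
  mono_y <- extract_monomers(libs$Y, cons)
  haps <- filter_singletons(c(mono_x, mono_y),
                            c(rep("X", length(mono_x)),
                              rep("Y", length(mono_y))))
  rep_ <- shared_haplotype_report(haps)
  sf <- spec$families[[1]]$subfamilies[[1]]
  has_diag <- substr(rep_$haplotypes$seq, sf$positions[1], sf$positions[1]) ==
    sf$bases[1]
  expect_gt(sum(has_diag), 0)
  expect_true(all(rep_$haplotypes$status[has_diag] == "Y"))
  # and the subfamily split yields at least two haplotype clusters
  expect_gte(nrow(haps), 2)
  expect_true(any(!has_diag))
})
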