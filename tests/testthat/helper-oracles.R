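# Independent reference implementations used as oracles.  These are written
# from the definitions, deliberately sharing no code with the package paths
# they check.

# Five-rule quality trimming, step by step on one read.
brute_trim <- function(seq, qual_ints, p) {
  q <- qual_ints
  s <- strsplit(seq, "")[[1]]
  # LEADING
  while (length(q) > 0 && q[1] < p$leading_q) { q <- q[-1]; s <- s[-1] }
  # TRAILING
  while (length(q) > 0 && q[length(q)] < p$trailing_q) {
    q <- q[-length(q)]; s <- s[-length(s)]
  }
  # SLIDINGWINDOW: cut before the first window of window_len with mean < window_q
  if (length(q) >= p$window_len) {
    for (i in seq_len(length(q) - p$window_len + 1)) {
      if (mean(q[i:(i + p$window_len - 1)]) < p$window_q) {
        q <- q[seq_len(i - 1)]; s <- s[seq_len(i - 1)]
        break
      }
    }
  }
  # MINLEN
  if (length(q) < p$min_len) return(list(seq = "", qual = integer(0)))
  # CROP
  if (length(q) > p$crop) { q <- q[seq_len(p$crop)]; s <- s[seq_len(p$crop)] }
  list(seq = paste(s, collapse = ""), qual = q)
}

brute_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Minimum over the explicit enumeration of all rotations of s and revcomp(s).
brute_canonical <- function(s) {
  n <- nchar(s)
  cands <- character(0)
  for (x in c(s, brute_revcomp(s))) {
    d <- paste0(x, x)
    for (i in seq_len(n)) cands <- c(cands, substr(d, i, i + n - 1))
  }
  min(cands)
}

# All-pairs shared canonical k-mer connected components (transitive closure).
brute_components <- function(reads, k, min_shared = 1) {
  kset <- lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    km <- vapply(seq_len(n - k + 1), function(i) substr(r, i, i + k - 1),
                 character(1))
    rc <- brute_revcomp(r)
    km_rc <- vapply(seq_len(n - k + 1), function(i) substr(rc, i, i + k - 1),
                    character(1))
    unique(mapply(function(x, y) min(c(x, y)), km, rev(km_rc)))
  })
  n <- length(reads)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- length(intersect(kset[[i]], kset[[j]])) >= min_shared
    }
  }
  # Warshall closure
  for (k2 in seq_len(n)) adj <- adj | (adj[, k2] %o% adj[k2, ])
  memb <- integer(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (memb[i] == 0) { cur <- cur + 1; memb[adj[i, ]] <- cur }
  }
  memb
}

# Direct evaluation of the Kimura two-parameter closed form.
brute_k2p <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -(1 / 2) * log(w1 * sqrt(w2))
}

# Hamming distance via explicit character comparison.
brute_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Minimal rotation/strand-aware edit distance between two monomers.
rot_edit_dist <- function(a, b) {
  n <- nchar(a)
  d <- paste0(a, a)
  rots <- vapply(seq_len(n), function(i) substr(d, i, i + n - 1), character(1))
  rc <- brute_revcomp(a)
  drc <- paste0(rc, rc)
  rots <- c(rots, vapply(seq_len(n), function(i) substr(drc, i, i + n - 1),
                         character(1)))
  min(utils::adist(rots, b))
}

# Interval-union coverage by per-base marking.
brute_coverage <- function(starts, ends, len) {
  hitmask <- logical(len)
  for (i in seq_along(starts)) hitmask[starts[i]:ends[i]] <- TRUE
  100 * sum(hitmask) / len
}

# Uniform random quality string of a given length over Phred 0..40.
random_quals <- function(len) {
  paste(vapply(sample(0:40, len, replace = TRUE),
               function(q) rawToChar(as.raw(q + 33)), character(1)),
        collapse = "")
}

random_read <- function(len = 150) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
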