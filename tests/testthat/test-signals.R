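# Window statistics: worked examples, N handling, and property checks
# against the brute-force oracles.

test_that("base counting ignores N and other symbols", {
  expect_equal(count_bases("GCAT"), c(A = 1L, C = 1L, G = 1L, T = 1L))
  expect_equal(count_bases("NNNN"), c(A = 0L, C = 0L, G = 0L, T = 0L))
  expect_equal(count_bases("AAGG"), c(A = 2L, C = 0L, G = 2L, T = 0L))
})

test_that("GC profile, GC skew and entropy match their definitions", {
  expect_equal(gc_profile(count_bases("GGCC")), 1.0)
  expect_equal(gc_profile(count_bases("ATAT")), 0.0)
  expect_equal(gc_profile(count_bases("GCAT")), 0.5)
  expect_true(is.na(gc_profile(count_bases("NNNN"))))

  expect_equal(gc_skew(count_bases("CCCC")), -1.0)
  expect_equal(gc_skew(count_bases("GCGC")), 0.0)
  expect_equal(gc_skew(count_bases("GGGC")), 0.5)
  expect_true(is.na(gc_skew(count_bases("ATAT"))))  # missing, not an error

  expect_equal(entropy(count_bases("ACGT")), 2.0)
  expect_equal(entropy(count_bases("AAAA")), 0.0)
  expect_equal(entropy(count_bases("AACC")), 1.0)
})

test_that("lag pairs enumerate (t, t+k+1) with k intervening bases, skipping N", {
  m <- lag_pairs("ATAT", 0)
  expect_equal(m["A", "T"], 2L)
  expect_equal(m["T", "A"], 1L)
  expect_equal(sum(m), 3L)

  m <- lag_pairs("ACGT", 1)
  expect_equal(m["A", "G"], 1L)
  expect_equal(m["C", "T"], 1L)
  expect_equal(sum(m), 2L)

  m <- lag_pairs("ANAT", 0)
  expect_equal(sum(m), 1L)
  expect_equal(m["A", "T"], 1L)

  expect_error(lag_pairs("AC", 1), "too short")
  expect_error(lag_pairs("NNNN", 0), "no valid pair")
})

test_that("redundancy matches hand-derived values and the iid limit", {
  expect_equal(redundancy("AAAAAA", 0), 0.0)
  expect_equal(redundancy("ATAT", 0), 1.08170, tolerance = 1e-4)
  set.seed(42)
  s <- random_dna(1e5)
  for (k in c(0, 5, 10)) expect_lt(redundancy(s, k), 0.001)
})

test_that("sequence-marginal convention reproduces the composition-entropy reading", {
  # same formula with H from whole-sequence base frequencies; may dip below 0
  set.seed(9)
  for (i in 1:20) {
    s <- random_dna(sample(20:200, 1))
    m <- lag_pairs(s, 0)
    N <- sum(m)
    expected <- 2 * bf_entropy(s) + sum(ifelse(m > 0, m / N * log2(m / N), 0))
    expect_equal(redundancy(s, 0, marginals = "sequence"), expected,
                 tolerance = 1e-12)
  }
})

test_that("redundancy agrees with brute-force enumeration", {
  set.seed(100)
  for (i in 1:30) {
    s <- random_dna(sample(10:500, 1), probs = c(0.35, 0.15, 0.2, 0.3))
    for (k in c(0, 1, 5)) {
      if (nchar(s) < k + 2) next
      expect_equal(redundancy(s, k), bf_redundancy(s, k), tolerance = 1e-12)
    }
  }
})

test_that("redundancy spectrum: degenerate, alternating and iid sequences", {
  sp <- redundancy_spectrum(strrep("A", 100), 5)
  expect_equal(sp$D, rep(0, 6))
  expect_equal(sp$k_plus_2, 2:7)

  # strict alternation saturates dependence at every lag (~1 bit); the
  # adjacent value ties the maximum up to finite-size rounding
  sp <- redundancy_spectrum(strrep("AT", 100), 2)
  expect_true(all(abs(sp$D - 1) < 0.01))
  expect_gte(sp$D[1], max(sp$D) - 1e-4)

  set.seed(7)
  sp <- redundancy_spectrum(random_dna(1e5), 48)
  expect_lt(max(sp$D), 0.001)
})

test_that("mononucleotide shuffling destroys adjacent redundancy", {
  set.seed(5)
  ch <- oriseq:::markov_seq(2000, c(0.3, 0.2, 0.2, 0.3), 0.6)
  expect_gt(redundancy(paste(ch, collapse = ""), 0), 0.1)
  shuffled <- replicate(50, redundancy(paste(sample(ch), collapse = ""), 0))
  expect_lt(mean(shuffled), 0.01)
})

test_that("sliding windows discard trailing partials and handle short regions", {
  r <- intervals("c", 0L, 300L)
  expect_equal(nrow(sliding_windows(r, 300, 300)), 1L)
  w <- sliding_windows(intervals("c", 0L, 600L), 50, 1)
  expect_equal(nrow(w), 551L)
  expect_equal(w$start[1], 0L)
  expect_equal(w$end[551], 600L)
  expect_equal(nrow(sliding_windows(intervals("c", 0L, 40L), 50, 1)), 0L)
})

test_that("vectorised sliding statistics equal the per-window scalar path", {
  set.seed(11)
  s <- paste0(random_dna(400), "NN", random_dna(98))
  w <- 50L
  starts <- seq_len(nchar(s) - w + 1L)
  for (stat in c("gc_profile", "gc_skew", "entropy")) {
    fast <- oriseq:::sliding_stat(s, w, 1L, stat)
    slow <- vapply(starts, function(i) {
      cnt <- count_bases(substr(s, i, i + w - 1L))
      switch(stat, gc_profile = gc_profile(cnt), gc_skew = gc_skew(cnt),
             entropy = entropy(cnt))
    }, numeric(1L))
    expect_equal(fast, slow, tolerance = 1e-12)
  }
  fast <- oriseq:::sliding_redundancy(s, 150L, 1L, k = 0L)
  slow <- vapply(seq_len(nchar(s) - 150L + 1L), function(i) {
    redundancy(substr(s, i, i + 149L), 0)
  }, numeric(1L))
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("signal ranges and strand symmetries hold on random windows", {
  set.seed(21)
  for (i in 1:200) {
    s <- random_dna(sample(10:100, 1), probs = c(0.4, 0.15, 0.15, 0.3))
    cnt <- count_bases(s)
    rc <- count_bases(revcomp(s))
    gp <- gc_profile(cnt)
    sk <- gc_skew(cnt)
    expect_true(gp >= 0 && gp <= 1)
    expect_true(is.na(sk) || (sk >= -1 && sk <= 1))
    h <- entropy(cnt)
    expect_true(h >= 0 && h <= 2)
    expect_equal(gc_profile(rc), gp)
    if (!is.na(sk)) expect_equal(gc_skew(rc), -sk)
    expect_equal(entropy(rc), h)
    d <- redundancy(s, 0)
    expect_gte(d, -1e-9)
    expect_lte(d, 2)
  }
})

test_that("pooled spectrum equals the spectrum of aggregated pair counts", {
  set.seed(31)
  seqs <- replicate(5, random_dna(80))
  sp <- redundancy_spectrum_set(seqs, 3, method = "pooled")
  for (k in 0:3) {
    pooled <- Reduce(`+`, lapply(seqs, bf_lag_pairs, k = k))
    N <- sum(pooled)
    p <- pooled / N
    hj <- -sum(ifelse(p > 0, p * log2(p), 0))
    mix <- (rowSums(p) + colSums(p)) / 2
    hm <- -sum(ifelse(mix > 0, mix * log2(mix), 0))
    expect_equal(sp$D[k + 1], 2 * hm - hj, tolerance = 1e-12)
  }
  spm <- redundancy_spectrum_set(seqs, 3, method = "mean")
  expect_equal(spm$D[1], mean(vapply(seqs, redundancy, numeric(1), k = 0)),
               tolerance = 1e-12)
})
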