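# Independent brute-force oracles: explicit enumeration and direct log-sums,
# sharing no code with the package implementations they check.

random_dna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

bf_counts <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  c(A = sum(ch == "A"), C = sum(ch == "C"),
    G = sum(ch == "G"), T = sum(ch == "T"))
}

bf_gc_profile <- function(seq) {
  n <- bf_counts(seq)
  (n["G"] + n["C"]) / sum(n)
}

bf_gc_skew <- function(seq) {
  n <- bf_counts(seq)
  (n["G"] - n["C"]) / (n["G"] + n["C"])
}

bf_entropy <- function(seq) {
  p <- bf_counts(seq) / sum(bf_counts(seq))
  h <- 0
  for (x in p) if (x > 0) h <- h - x * log2(x)
  h
}

bf_lag_pairs <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- matrix(0L, 4L, 4L, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  for (t in seq_len(length(ch) - k - 1L)) {
    a <- ch[t]
    b <- ch[t + k + 1L]
    if (a %in% rownames(m) && b %in% colnames(m)) {
      m[a, b] <- m[a, b] + 1L
    }
  }
  m
}

# D = 2H(mixture marginal of the pair ensemble) + sum p log2 p, by direct sums
bf_redundancy <- function(seq, k) {
  m <- bf_lag_pairs(seq, k)
  N <- sum(m)
  plogp <- 0
  for (i in 1:4) for (j in 1:4) {
    p <- m[i, j] / N
    if (p > 0) plogp <- plogp + p * log2(p)
  }
  h <- 0
  for (a in 1:4) {
    q <- (sum(m[a, ]) + sum(m[, a])) / (2 * N)
    if (q > 0) h <- h - q * log2(q)
  }
  2 * h + plogp
}

# a small synthetic bundle for cheap end-to-end tests
small_spec <- function(seed = 7L, ...) {
  generator_spec(chrom_lengths = c(chrT = 200000L), n_oris = 40L,
                 seed = seed, ...)
}

# cache the default 1-Mb study-condition bundles across test blocks
.bundle_cache <- new.env(parent = emptyenv())

default_bundle <- function(seed = 7L, null = FALSE) {
  key <- paste0(if (null) "null" else "signal", seed)
  if (is.null(.bundle_cache[[key]])) {
    .bundle_cache[[key]] <- generate_bundle(generator_spec(seed = seed),
                                            null = null)
  }
  .bundle_cache[[key]]
}

# 300-bp sequences centred on each origin midpoint
ori_centred_seqs <- function(bundle, width = 300L) {
  mids <- floor((bundle$oris$start + bundle$oris$end) / 2)
  half <- width %/% 2L
  vapply(seq_len(nrow(bundle$oris)), function(i) {
    substr(bundle$genome[[bundle$oris$chrom[i]]],
           mids[i] - half + 1L, mids[i] - half + width)
  }, character(1L))
}
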