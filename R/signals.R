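# Per-window sequence statistics: GC profile, GC skew, Shannon entropy, and
# k-order information redundancy (a lagged mutual-information statistic), plus
# the sliding-window machinery they run over.
#
# All information measures use log base 2; units are bits. Bases other than
# A/C/G/T (i.e. N) never enter a numerator or denominator.

#' Count A/C/G/T in a DNA string
#'
#' N and any other symbol are ignored, so the total can be smaller than the
#' string length.
#'
#' @param seq Single DNA string.
#' @return Named integer vector `c(A=, C=, G=, T=)`.
#' @export
count_bases <- function(seq) {
  code <- encode_seq(seq)
  n <- tabulate(code[!is.na(code)], nbins = 4L)
  names(n) <- BASES
  n
}

.counts_ok <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) == 4L)
  if (!is.null(names(counts))) counts <- counts[BASES]
  counts
}

#' GC profile of a window
#'
#' Fraction (G + C) / (A + C + G + T); in \[0, 1\]. An all-N window (zero
#' denominator) yields `NA`, which profile aggregation treats as missing.
#'
#' @param counts Base counts as returned by [count_bases()].
#' @return Numeric scalar in \[0, 1\], or `NA`.
#' @export
gc_profile <- function(counts) {
  counts <- .counts_ok(counts)
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  unname((counts[2L] + counts[3L]) / tot)
}

#' GC skew of a window
#'
#' (G − C) / (G + C); in \[−1, 1\]. Windows without any G or C yield `NA`
#' (missing), not an error.
#'
#' @inheritParams gc_profile
#' @return Numeric scalar in \[−1, 1\], or `NA`.
#' @export
gc_skew <- function(counts) {
  counts <- .counts_ok(counts)
  gc <- counts[2L] + counts[3L]
  if (gc == 0) return(NA_real_)
  unname((counts[3L] - counts[2L]) / gc)
}

# -sum p log2 p over the positive entries of a probability vector
.entropy_p <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of base composition
#'
#' H = −Σ_a p_a log2 p_a over a ∈ {A,C,G,T}; maximum 2 bits for DNA.
#'
#' @inheritParams gc_profile
#' @return Entropy in bits, or `NA` for a zero-count window.
#' @export
entropy <- function(counts) {
  counts <- .counts_ok(counts)
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  .entropy_p(counts / tot)
}

#' Counts of base pairs at lag k
#'
#' Counts ordered pairs (base at t, base at t + k + 1): `k` is the number of
#' intervening bases, so `k = 0` counts adjacent pairs. Pairs touching an N
#' are skipped.
#'
#' @param seq Single DNA string.
#' @param k Non-negative integer lag.
#' @return 4x4 integer matrix, rows = first base, cols = second base.
#' @export
lag_pairs <- function(seq, k) {
  stopifnot(k >= 0)
  code <- encode_seq(seq)
  n <- length(code)
  if (n < k + 2L) stop("sequence too short for lag k: no valid pair")
  a <- code[seq_len(n - k - 1L)]
  b <- code[(k + 2L):n]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("sequence too short for lag k: no valid pair")
  m <- matrix(tabulate((a[keep] - 1L) * 4L + b[keep], nbins = 16L),
              nrow = 4L, ncol = 4L, byrow = TRUE,
              dimnames = list(BASES, BASES))
  m
}

#' Information redundancy from a lag-pair count matrix
#'
#' D = 2H + Σ_{ij} p_ij log2 p_ij, where p_ij is the joint distribution of
#' the lag-k pair ensemble. Under the default `marginals = "pair"` convention
#' H is the entropy of the mixture marginal of that ensemble (mean of the
#' first- and second-position marginals), which makes D a mutual-information
#' style quantity, non-negative up to rounding. `marginals = "sequence"` uses
#' the whole-sequence base composition instead (the literal composition-based
#' reading), which can go slightly negative on finite sequences.
#'
#' @param pairs 4x4 count matrix from [lag_pairs()].
#' @param marginals `"pair"` (default) or `"sequence"`.
#' @param seq_counts Base counts of the full sequence; required for
#'   `marginals = "sequence"`.
#' @return Redundancy in bits.
#' @export
redundancy_from_pairs <- function(pairs, marginals = c("pair", "sequence"),
                                  seq_counts = NULL) {
  marginals <- match.arg(marginals)
  N <- sum(pairs)
  stopifnot(N >= 1)
  p <- pairs / N
  h_joint <- .entropy_p(as.vector(p))
  h <- if (marginals == "pair") {
    .entropy_p((rowSums(p) + colSums(p)) / 2)
  } else {
    if (is.null(seq_counts)) stop("seq_counts required for sequence marginals")
    entropy(seq_counts)
  }
  2 * h - h_joint
}

#' k-order information redundancy of a sequence
#'
#' Measures the statistical dependence between bases separated by `k`
#' intervening positions; larger values mean stronger divergence from
#' independence. The subscript convention is `k + 2` (adjacent correlation is
#' D_2).
#'
#' @inheritParams lag_pairs
#' @inheritParams redundancy_from_pairs
#' @return Redundancy D in bits.
#' @export
redundancy <- function(seq, k, marginals = c("pair", "sequence")) {
  marginals <- match.arg(marginals)
  pairs <- lag_pairs(seq, k)
  redundancy_from_pairs(pairs, marginals = marginals,
                        seq_counts = if (marginals == "sequence") count_bases(seq))
}

#' Redundancy spectrum D_{k+2} for k = 0..k_max
#'
#' @inheritParams redundancy
#' @param k_max Largest lag (default 48, i.e. subscripts 2..50).
#' @return Data frame with columns `k`, `k_plus_2`, `D` (bits).
#' @export
redundancy_spectrum <- function(seq, k_max = 48L,
                                marginals = c("pair", "sequence")) {
  marginals <- match.arg(marginals)
  ks <- 0L:k_max
  D <- vapply(ks, function(k) redundancy(seq, k, marginals = marginals),
              numeric(1L))
  data.frame(k = ks, k_plus_2 = ks + 2L, D = D)
}

#' Averaged redundancy spectrum over a set of sequences
#'
#' `method = "pooled"` (default) sums the lag-k pair counts over all
#' sequences before forming probabilities — the consistent estimator, whose
#' small-sample bias shrinks with the pooled pair count. `method = "mean"`
#' averages the per-sequence plug-in spectra, which carries an upward bias of
#' order 1/length per sequence.
#'
#' @param seqs Character vector of DNA strings.
#' @param k_max Largest lag.
#' @param method `"pooled"` or `"mean"`.
#' @return Data frame with columns `k`, `k_plus_2`, `D` (bits).
#' @export
redundancy_spectrum_set <- function(seqs, k_max = 48L,
                                    method = c("pooled", "mean")) {
  method <- match.arg(method)
  stopifnot(length(seqs) >= 1L)
  ks <- 0L:k_max
  if (method == "mean") {
    mat <- vapply(seqs, function(s) redundancy_spectrum(s, k_max)$D,
                  numeric(k_max + 1L))
    return(data.frame(k = ks, k_plus_2 = ks + 2L, D = rowMeans(mat)))
  }
  D <- vapply(ks, function(k) {
    pooled <- Reduce(`+`, lapply(seqs, lag_pairs, k = k))
    redundancy_from_pairs(pooled)
  }, numeric(1L))
  data.frame(k = ks, k_plus_2 = ks + 2L, D = D)
}

#' Sliding windows over a region
#'
#' Windows `[start + m*step, start + m*step + window)`; a trailing partial
#' window is discarded, never padded, so every window has the same width. A
#' window wider than the region yields an empty set (not an error).
#'
#' @param region One-row interval data.frame (chrom, start, end).
#' @param window,step Window width and step in bp, both >= 1.
#' @return Interval data.frame of windows, in genomic order.
#' @export
sliding_windows <- function(region, window, step) {
  stopifnot(window >= 1L, step >= 1L)
  L <- region$end - region$start
  if (window > L) {
    return(intervals(character(0L), integer(0L), integer(0L)))
  }
  m <- floor((L - window) / step)
  starts <- region$start + (0:m) * step
  intervals(rep(region$chrom, m + 1L), starts, starts + window)
}

# ---- vectorised sliding statistics (cumulative-sum based) -------------------

# Per-window A/C/G/T counts for all windows of `window` bp at `step` bp over
# one string. Returns a (windows x 4) matrix; N contributes to no column.
sliding_base_counts <- function(seq, window, step = 1L) {
  code <- encode_seq(seq)
  n <- length(code)
  if (window > n) return(matrix(integer(0L), ncol = 4L,
                                dimnames = list(NULL, BASES)))
  cs <- matrix(0, nrow = n + 1L, ncol = 4L)
  for (b in 1:4) cs[-1L, b] <- cumsum(!is.na(code) & code == b)
  starts <- seq.int(1L, n - window + 1L, by = step)
  out <- cs[starts + window, , drop = FALSE] - cs[starts, , drop = FALSE]
  dimnames(out) <- list(NULL, BASES)
  out
}

# Per-window scalar statistic from sliding_base_counts.
sliding_stat <- function(seq, window, step = 1L,
                         stat = c("gc_profile", "gc_skew", "entropy")) {
  stat <- match.arg(stat)
  m <- sliding_base_counts(seq, window, step)
  if (nrow(m) == 0L) return(numeric(0L))
  tot <- rowSums(m)
  gc <- m[, "G"] + m[, "C"]
  switch(stat,
    gc_profile = ifelse(tot == 0, NA_real_, gc / tot),
    gc_skew = ifelse(gc == 0, NA_real_, (m[, "G"] - m[, "C"]) / gc),
    entropy = {
      p <- m / ifelse(tot == 0, NA_real_, tot)
      lg <- ifelse(p > 0, log2(pmax(p, .Machine$double.xmin)), 0)
      -rowSums(ifelse(p > 0, p * lg, 0))
    })
}

# Per-window redundancy at lag k for all `window`-bp windows at `step` bp.
# Pair at position t spans t..t+k+1 and belongs to windows containing both
# ends. Windows with no valid pair give NA.
sliding_redundancy <- function(seq, window, step = 1L, k = 0L) {
  code <- encode_seq(seq)
  n <- length(code)
  if (window > n || window < k + 2L) return(numeric(0L))
  np <- n - k - 1L
  a <- code[seq_len(np)]
  b <- code[(k + 2L):n]
  pid <- ifelse(!is.na(a) & !is.na(b), (a - 1L) * 4L + b, NA_integer_)
  cs <- matrix(0, nrow = np + 1L, ncol = 16L)
  for (j in 1:16) cs[-1L, j] <- cumsum(!is.na(pid) & pid == j)
  starts <- seq.int(1L, n - window + 1L, by = step)
  # pairs fully inside window [s, s+window): pair starts s .. s+window-k-2
  cnt <- cs[pmin(starts + window - k - 1L, np + 1L), , drop = FALSE] -
    cs[starts, , drop = FALSE]
  N <- rowSums(cnt)
  p <- cnt / ifelse(N == 0, NA_real_, N)
  plog <- ifelse(p > 0, p * log2(pmax(p, .Machine$double.xmin)), 0)
  h_joint <- -rowSums(plog)
  first <- ((1:16 - 1L) %/% 4L) + 1L
  second <- ((1:16 - 1L) %% 4L) + 1L
  M1 <- outer(first, 1:4, `==`) * 1
  M2 <- outer(second, 1:4, `==`) * 1
  mix <- (p %*% M1 + p %*% M2) / 2
  mlog <- ifelse(mix > 0, mix * log2(pmax(mix, .Machine$double.xmin)), 0)
  h_mix <- -rowSums(mlog)
  out <- 2 * h_mix - h_joint
  out[N == 0] <- NA_real_
  out
}
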