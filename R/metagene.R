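# Anchored (metagene) profiles around replication origins and rank-sum
# comparison of region sets.
#
# Anchor point for an interval is its midpoint, floor((start+end)/2); the
# window statistic of each sliding window is assigned to the offset of the
# window centre relative to the anchor, and means are taken across anchors
# per offset.

#' Mean signal profile anchored at a set of intervals
#'
#' For each anchor midpoint, sliding windows are evaluated across
#' `[mid - flank, mid + flank]` and the per-window statistic is assigned to
#' the window-centre offset. Anchors truncated by chromosome ends contribute
#' only to the offsets they cover. GC skew is computed on the plus strand for
#' all anchors (origins carry no orientation).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param anchors Interval data.frame of anchor intervals (e.g. ORIs).
#' @param signal One of `"gc_profile"`, `"gc_skew"`, `"d2"` (adjacent-lag
#'   redundancy) or `"track"` (window mean of `track`).
#' @param flank Half-width of the profiled region in bp.
#' @param window,step Sliding-window width and step in bp.
#' @param track Per-base signal track (required for `signal = "track"`).
#' @param k Lag for `signal = "d2"` (default 0, adjacent).
#' @return Data frame with columns `offset`, `mean`, `count`, `signal`,
#'   offsets strictly increasing, rows restricted to offsets with at least
#'   one contributing anchor.
#' @export
anchored_profile <- function(genome, anchors,
                             signal = c("gc_profile", "gc_skew", "d2", "track"),
                             flank = 300L, window = 50L, step = 1L,
                             track = NULL, k = 0L) {
  signal <- match.arg(signal)
  if (nrow(anchors) == 0L) stop("empty anchor set")
  if (signal == "track" && is.null(track)) stop("track required for signal = 'track'")
  stopifnot(flank >= window)
  half <- floor(window / 2)
  span <- 2L * flank + 1L
  acc_sum <- numeric(span)
  acc_n <- integer(span)
  mids <- interval_midpoint(anchors)
  for (i in seq_len(nrow(anchors))) {
    chrom <- anchors$chrom[i]
    len <- chrom_length(genome, chrom)
    s <- max(0L, mids[i] - flank)
    e <- min(len, mids[i] + flank + 1L)
    if (e - s < window) next
    vals <- if (signal == "track") {
      v <- get_chrom_track(track, chrom)[(s + 1L):e]
      sliding_mean(v, window, step)
    } else if (signal == "d2") {
      sliding_redundancy(subseq0(genome, chrom, s, e), window, step, k = k)
    } else {
      sliding_stat(subseq0(genome, chrom, s, e), window, step, stat = signal)
    }
    starts <- s + (seq_along(vals) - 1L) * step
    idx <- starts + half - mids[i] + flank + 1L
    ok <- idx >= 1L & idx <= span & !is.na(vals)
    idx <- idx[ok]
    acc_sum[idx] <- acc_sum[idx] + vals[ok]
    acc_n[idx] <- acc_n[idx] + 1L
  }
  keep <- acc_n >= 1L
  data.frame(offset = (seq_len(span) - flank - 1L)[keep],
             mean = acc_sum[keep] / acc_n[keep],
             count = acc_n[keep],
             signal = signal)
}

get_chrom_track <- function(track, chrom) {
  if (!chrom %in% names(track)) {
    stop(sprintf("chromosome '%s' not present in track", chrom))
  }
  track[[chrom]]
}

# Sliding mean over a numeric vector, NA-aware: mean of non-missing values in
# each window; NA if a window is entirely missing.
sliding_mean <- function(v, window, step = 1L) {
  n <- length(v)
  if (window > n) return(numeric(0L))
  cs <- c(0, cumsum(ifelse(is.na(v), 0, v)))
  cn <- c(0, cumsum(!is.na(v)))
  starts <- seq.int(1L, n - window + 1L, by = step)
  tot <- cs[starts + window] - cs[starts]
  cnt <- cn[starts + window] - cn[starts]
  ifelse(cnt == 0, NA_real_, tot / cnt)
}

#' Mann–Whitney (Wilcoxon rank-sum) comparison of two value sets
#'
#' Two-sided; exact when both groups are small (min n <= 8) and untied,
#' tie-corrected normal approximation otherwise. Degenerate input (all values
#' identical in both groups) returns p = 1 with a warning.
#'
#' @param values_a,values_b Numeric vectors; `NA`s dropped.
#' @return One-row data.frame: n1, n2, mean_a, mean_b, sd_a, sd_b, U
#'   (statistic for group A), p.
#' @export
compare_regions <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  n1 <- length(a)
  n2 <- length(b)
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical across both groups; p = 1")
    U <- n1 * n2 / 2
    p <- 1.0
  } else {
    use_exact <- min(n1, n2) <= 8L && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = use_exact, correct = TRUE))
    U <- unname(wt$statistic)
    p <- min(1, wt$p.value)
  }
  data.frame(n1 = n1, n2 = n2,
             mean_a = mean(a), mean_b = mean(b),
             sd_a = stats::sd(a), sd_b = stats::sd(b),
             U = U, p = p)
}

#' Non-overlapping background windows tiling the genome
#'
#' @param genome Named character vector of sequences.
#' @param window,step Window width and step (defaults 300/300: the
#'   genome-wide GC background tiling).
#' @return Interval data.frame of windows across all chromosomes.
#' @export
genome_background_windows <- function(genome, window = 300L, step = 300L) {
  out <- lapply(names(genome), function(chrom) {
    sliding_windows(intervals(chrom, 0L, nchar(genome[[chrom]])),
                    window, step)
  })
  do.call(rbind, out)
}

# GC fraction of the `width`-bp window centred on each interval midpoint;
# windows exceeding chromosome bounds are dropped with a warning.
ori_window_gc <- function(genome, oris, width = 300L) {
  mids <- interval_midpoint(oris)
  half <- floor(width / 2)
  vals <- rep(NA_real_, nrow(oris))
  for (i in seq_len(nrow(oris))) {
    len <- chrom_length(genome, oris$chrom[i])
    s <- mids[i] - half
    e <- s + width
    if (s < 0L || e > len) next
    vals[i] <- gc_profile(count_bases(subseq0(genome, oris$chrom[i], s, e)))
  }
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " ORI window(s) exceed chromosome bounds; dropped")
  }
  vals[!is.na(vals)]
}

#' Compare ORI-window GC content with the genome-wide background
#'
#' Group A is the GC fraction of the `ori_window`-bp window centred on each
#' ORI midpoint; group B is the GC fraction of non-overlapping genome-wide
#' windows of the same width.
#'
#' @param genome Named character vector of sequences.
#' @param oris Interval data.frame of origins.
#' @param ori_window Window width in bp (default 300).
#' @return One-row data.frame as [compare_regions()] (group A = ORIs,
#'   group B = background).
#' @export
ori_vs_genome_gc <- function(genome, oris, ori_window = 300L) {
  a <- ori_window_gc(genome, oris, ori_window)
  bg <- genome_background_windows(genome, ori_window, ori_window)
  b <- vapply(seq_len(nrow(bg)), function(i) {
    gc_profile(count_bases(subseq0(genome, bg$chrom[i], bg$start[i], bg$end[i])))
  }, numeric(1L))
  compare_regions(a, b)
}

#' Nucleosome-depletion contrast at origins
#'
#' Compares mean occupancy of the core window `[-core, +core]` around each
#' anchor midpoint against flank windows of the *same width* centred at
#' `±(flank_min + core)` (one per side). Equal window widths make the two
#' groups identically distributed under a stationary track, so the rank-sum
#' p-value is calibrated on null data; a planted depletion drives it to
#' zero. Anchors whose core or flank windows exceed chromosome bounds are
#' dropped.
#'
#' @param track Per-base occupancy track (named list of numeric vectors).
#' @param anchors Interval data.frame of origins.
#' @param core Core half-width in bp (default 75, i.e. a 151-bp window).
#' @param flank_min Inner edge of the flank zone in bp (default 500).
#' @return One-row data.frame as [compare_regions()] (group A = core,
#'   group B = flanks).
#' @export
ndr_contrast <- function(track, anchors, core = 75L, flank_min = 500L) {
  mids <- interval_midpoint(anchors)
  width <- 2L * core + 1L
  core_vals <- numeric(0L)
  flank_vals <- numeric(0L)
  for (i in seq_len(nrow(anchors))) {
    v <- get_chrom_track(track, anchors$chrom[i])
    m <- mids[i]
    lo <- m - flank_min - 2L * core
    hi <- m + flank_min + 2L * core
    if (lo < 0L || hi >= length(v)) next
    core_vals <- c(core_vals,
                   mean(v[(m - core + 1L):(m + core + 1L)], na.rm = TRUE))
    flank_vals <- c(flank_vals,
                    mean(v[(lo + 1L):(lo + width)], na.rm = TRUE),
                    mean(v[(hi - width + 2L):(hi + 1L)], na.rm = TRUE))
  }
  compare_regions(core_vals, flank_vals)
}
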