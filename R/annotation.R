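# Positional genomics of origins: orientation classes of intergenic regions,
# per-ORI location categories, and ORI–TSS distances.

#' Orientation class of an adjacent gene pair
#'
#' A divergent region (left gene on "-", right on "+") holds both flanking
#' promoters; a convergent region ("+", "-") holds both terminators; equal
#' strands give a tandem region (one promoter, one terminator).
#'
#' @param left_strand,right_strand Strand characters, "+" or "-"; vectorised.
#' @return Character vector: "tandem", "divergent" or "convergent".
#' @export
classify_gene_pair <- function(left_strand, right_strand) {
  ok <- left_strand %in% c("+", "-") & right_strand %in% c("+", "-")
  if (!all(ok)) stop("strands must be '+' or '-'")
  ifelse(left_strand == right_strand, "tandem",
         ifelse(left_strand == "-", "divergent", "convergent"))
}

#' Build orientation-classified intergenic regions
#'
#' Genes are sorted per chromosome; clusters of mutually overlapping genes
#' are merged out of consideration (a region is only formed between two
#' consecutive single, non-overlapping genes with a positive gap).
#' Chromosome-terminal gaps are excluded since they have one flanking gene
#' only.
#'
#' @param genes Stranded interval data.frame of genes.
#' @return Data frame with columns chrom, start, end, left_strand,
#'   right_strand, cls.
#' @export
build_intergenic_regions <- function(genes) {
  if (nrow(genes) > 0 && any(genes$strand == "*")) {
    stop("genes must be stranded")
  }
  out <- list()
  for (chrom in unique(genes$chrom)) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(g) < 2L) next
    g <- g[order(g$start, g$end), , drop = FALSE]
    # cluster transitively overlapping genes (abutting genes do not overlap)
    hi <- cummax(g$end)
    cl <- cumsum(!c(FALSE, g$start[-1L] < hi[-nrow(g)]))
    n_per <- tabulate(cl)
    cl_end <- vapply(split(g$end, cl), max, numeric(1L))
    cl_start <- vapply(split(g$start, cl), min, numeric(1L))
    cl_strand <- vapply(split(g$strand, cl), `[[`, character(1L), 1L)
    ncl <- length(n_per)
    if (ncl < 2L) next
    for (i in seq_len(ncl - 1L)) {
      if (n_per[i] > 1L || n_per[i + 1L] > 1L) next   # merged-overlap zone
      s <- cl_end[i]
      e <- cl_start[i + 1L]
      if (e <= s) next                                # zero-length gap
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = as.integer(s), end = as.integer(e),
        left_strand = cl_strand[i], right_strand = cl_strand[i + 1L],
        cls = classify_gene_pair(cl_strand[i], cl_strand[i + 1L]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0L), start = integer(0L),
                      end = integer(0L), left_strand = character(0L),
                      right_strand = character(0L), cls = character(0L),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign each ORI a positional category
#'
#' The ORI midpoint decides membership (a partition: every ORI gets exactly
#' one category). Midpoints inside a gene body are `coding_head` when within
#' the 5'-most `head_tail_fraction` of the gene (strand-aware), `coding_tail`
#' within the 3'-most fraction, else `coding_internal`. Midpoints in an
#' intergenic region take that region's orientation class. Midpoints in
#' excluded zones (terminal gaps, merged-overlap zones) fall back to
#' `coding_internal` with a warning.
#'
#' @param oris Interval data.frame of origins.
#' @param genes Stranded interval data.frame of genes.
#' @param intergenic Output of [build_intergenic_regions()].
#' @param head_tail_fraction Fraction of gene length forming the head/tail
#'   zones (default 0.25).
#' @return Data frame: one row per ORI with columns chrom, start, end,
#'   midpoint, category, hit (gene label or intergenic class, NA for
#'   excluded zones).
#' @export
assign_ori_location <- function(oris, genes, intergenic,
                                head_tail_fraction = 0.25) {
  stopifnot(head_tail_fraction > 0, head_tail_fraction < 0.5)
  mids <- interval_midpoint(oris)
  cats <- character(nrow(oris))
  hits <- rep(NA_character_, nrow(oris))
  n_excluded <- 0L
  for (i in seq_len(nrow(oris))) {
    chrom <- oris$chrom[i]
    if (!chrom %in% genes$chrom) {
      stop(sprintf("chromosome '%s' absent from gene annotation", chrom))
    }
    p <- mids[i]
    g <- genes[genes$chrom == chrom & genes$start <= p & p < genes$end, ,
               drop = FALSE]
    if (nrow(g) > 0L) {
      g <- g[order(g$start), , drop = FALSE][1L, ]
      len <- g$end - g$start
      d5 <- if (g$strand == "+") p - g$start else (g$end - 1L) - p
      cats[i] <- if (d5 < head_tail_fraction * len) "coding_head"
        else if (d5 >= (1 - head_tail_fraction) * len) "coding_tail"
        else "coding_internal"
      hits[i] <- if (is.na(g$label)) sprintf("%s:%d-%d", g$chrom, g$start, g$end) else g$label
      next
    }
    ig <- intergenic[intergenic$chrom == chrom & intergenic$start <= p &
                       p < intergenic$end, , drop = FALSE]
    if (nrow(ig) > 0L) {
      cats[i] <- ig$cls[1L]
      hits[i] <- ig$cls[1L]
    } else {
      cats[i] <- "coding_internal"
      n_excluded <- n_excluded + 1L
    }
  }
  if (n_excluded > 0L) {
    warning(n_excluded,
            " ORI midpoint(s) in excluded zones (terminal gaps or merged",
            " overlaps); categorised coding_internal")
  }
  data.frame(chrom = oris$chrom, start = oris$start, end = oris$end,
             midpoint = mids, category = cats, hit = hits,
             stringsAsFactors = FALSE)
}

#' Distance from each ORI to its nearest TSS
#'
#' Distance is measured from the ORI midpoint to the nearest TSS position on
#' the same chromosome. The summary fraction counts strict `distance <
#' threshold` (a distance of exactly `threshold` is not counted).
#'
#' @param oris Interval data.frame of origins.
#' @param tsses Interval data.frame of TSS positions (1-bp intervals; the
#'   `start` coordinate is the TSS).
#' @param threshold Proximity threshold in bp (default 500).
#' @return List with `distances` (data.frame: chrom, midpoint, distance) and
#'   `fraction` (fraction of ORIs with defined distance < threshold).
#' @export
ori_tss_distances <- function(oris, tsses, threshold = 500L) {
  stopifnot(nrow(oris) >= 1L, nrow(tsses) >= 1L)
  mids <- interval_midpoint(oris)
  d <- rep(NA_real_, nrow(oris))
  for (i in seq_len(nrow(oris))) {
    tp <- tsses$start[tsses$chrom == oris$chrom[i]]
    if (length(tp) == 0L) next
    d[i] <- min(abs(tp - mids[i]))
  }
  if (anyNA(d)) {
    warning(sum(is.na(d)),
            " ORI(s) on chromosomes without TSSs; excluded from summary")
  }
  list(distances = data.frame(chrom = oris$chrom, midpoint = mids,
                              distance = d, stringsAsFactors = FALSE),
       fraction = mean(d[!is.na(d)] < threshold))
}
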