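# Shared low-level helpers: base encoding, reverse complement, interval checks.
# Coordinates everywhere in the package are 0-based half-open (BED convention).

BASES <- c("A", "C", "G", "T")

.base_code <- local({
  x <- rep(NA_integer_, 256L)
  x[utf8ToInt("A")] <- 1L
  x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L
  x[utf8ToInt("T")] <- 4L
  x
})

#' Encode a DNA string as integer base codes
#'
#' A/C/G/T map to 1..4; N and any other character becomes `NA`, which all
#' counting routines treat as "excluded from the denominator".
#'
#' @param seq Single DNA string (uppercase).
#' @return Integer vector, one element per base.
#' @keywords internal
encode_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .base_code[utf8ToInt(seq)]
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A/C/G/T/N (uppercase).
#' @return The reverse-complemented string; N stays N.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
         }, character(1L), USE.NAMES = FALSE))
}

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open. `strand` is "+", "-" or "*" (unstranded).
#'
#' @param chrom Chromosome names.
#' @param start,end Integer coordinates, `0 <= start < end`.
#' @param strand Strand characters; default unstranded.
#' @param label Optional free-text labels.
#' @return A data.frame with columns chrom, start, end, strand, label.
#' @export
intervals <- function(chrom, start, end, strand = "*", label = NA_character_) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L) || any(start >= end)) {
    stop("intervals require 0 <= start < end")
  }
  bad <- !strand %in% c("+", "-", "*")
  if (any(bad)) stop("strand must be one of '+', '-', '*'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = rep_len(as.character(strand), length(chrom)),
             label = rep_len(as.character(label), length(chrom)),
             stringsAsFactors = FALSE)
}

# Midpoint convention used throughout for anchoring ORIs: floor((start+end)/2).
interval_midpoint <- function(x) {
  as.integer(floor((x$start + x$end) / 2))
}

# Fetch one chromosome string, erroring with the offending name.
get_chrom <- function(genome, chrom) {
  if (!chrom %in% names(genome)) {
    stop(sprintf("chromosome '%s' not present in genome", chrom))
  }
  genome[[chrom]]
}

chrom_length <- function(genome, chrom) nchar(get_chrom(genome, chrom))

# substring by 0-based half-open coordinates
subseq0 <- function(genome, chrom, start, end) {
  substr(get_chrom(genome, chrom), start + 1L, end)
}
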