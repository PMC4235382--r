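# Readers and writers for the plain-text genomics formats the pipeline
# touches. One convention everywhere: internal coordinates are 0-based
# half-open (BED native); GFF3's 1-based closed coordinates are converted at
# this boundary and nowhere else.

#' Read a FASTA genome
#'
#' Sequences are uppercased; any character outside A/C/G/T/N is mapped to N
#' with a warning. Duplicate record names and empty files are format errors.
#'
#' @param path FASTA file path.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(ss) == 0L) stop("FASTA file contains no records: ", path)
  # record names: first whitespace-delimited token
  nm <- vapply(strsplit(names(ss), "[ \t]"), `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning(sprintf("%d record(s) contain non-ACGTN characters; mapped to N",
                    sum(bad)))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  if (any(nchar(seqs) < 1L)) stop("FASTA records must have length >= 1")
  names(seqs) <- nm
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, filepath = path, format = "fasta")
  invisible(path)
}

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "#") &
          !startsWith(lines, "track") & !startsWith(lines, "browser")]
}

#' Read a BED3+ file of genomic intervals
#'
#' BED's native 0-based half-open coordinates are kept as-is. Column 4 is
#' parsed as the label and column 6 as strand when present.
#'
#' @param path BED file path.
#' @return Interval data.frame (chrom, start, end, strand, label).
#' @export
read_bed <- function(path) {
  lines <- .read_lines_checked(path)
  if (length(lines) == 0L) {
    return(intervals(character(0L), integer(0L), integer(0L)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED line ", which(nf < 3L)[1L], ": fewer than 3 tab-separated fields")
  }
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start <- as.integer(vapply(fields, `[[`, character(1L), 2L))
  end <- as.integer(vapply(fields, `[[`, character(1L), 3L))
  bad <- is.na(start) | is.na(end) | start >= end | start < 0L
  if (any(bad)) {
    stop("BED line ", which(bad)[1L], ": invalid interval (need 0 <= start < end)")
  }
  label <- vapply(fields, function(f) {
    if (length(f) >= 4L) f[4L] else NA_character_
  }, character(1L))
  strand <- rep("*", length(lines))
  has6 <- nf >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, character(1L), 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  intervals(chrom, start, end, strand, label)
}

#' Write intervals to BED
#'
#' Emits BED6 when any interval is stranded or labelled, else BED3.
#'
#' @param x Interval data.frame.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  plain <- all(x$strand == "*") && all(is.na(x$label))
  lines <- if (plain || nrow(x) == 0L) {
    sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
  } else {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, x$start, x$end,
            ifelse(is.na(x$label), ".", x$label),
            ifelse(x$strand == "*", ".", x$strand))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Keeps rows with feature type `gene`, converting 1-based inclusive GFF
#' coordinates to the internal 0-based half-open convention. Genes must be
#' stranded.
#'
#' @param path GFF3 file path.
#' @return Interval data.frame of genes in input order.
#' @export
read_gff3_genes <- function(path) {
  lines <- .read_lines_checked(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 7L && f[3L] == "gene",
                 logical(1L))
  fields <- fields[keep]
  lineno <- which(keep)
  if (length(fields) == 0L) {
    return(intervals(character(0L), integer(0L), integer(0L)))
  }
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start1 <- as.integer(vapply(fields, `[[`, character(1L), 4L))
  end1 <- as.integer(vapply(fields, `[[`, character(1L), 5L))
  strand <- vapply(fields, `[[`, character(1L), 7L)
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop("GFF3 line ", lineno[bad][1L], ": gene without strand")
  }
  label <- vapply(fields, function(f) {
    if (length(f) >= 9L) sub("^ID=([^;]*).*$", "\\1", f[9L]) else NA_character_
  }, character(1L))
  intervals(chrom, start1 - 1L, end1, strand, label)
}

#' Write gene intervals to GFF3
#'
#' @param genes Interval data.frame (stranded).
#' @param path Output path.
#' @export
write_gff3_genes <- function(genes, path) {
  ids <- ifelse(is.na(genes$label),
                sprintf("gene%04d", seq_len(nrow(genes))), genes$label)
  lines <- c("##gff-version 3",
             sprintf("%s\tosq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end,
                     genes$strand, ids))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a per-base signal track
#'
#' Uncovered bases are `NA` (missing). Overlapping intervals resolve
#' last-writer-wins, with a warning.
#'
#' @param path bedGraph path (4 tab-separated columns).
#' @param genome Named character vector of sequences, defining chromosome
#'   names and lengths.
#' @return Named list of numeric vectors, one per chromosome, one value per
#'   base.
#' @export
read_bedgraph <- function(path, genome) {
  track <- lapply(genome, function(s) rep(NA_real_, nchar(s)))
  lines <- .read_lines_checked(path)
  if (length(lines) == 0L) return(track)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop("bedGraph line ", which(lengths(fields) < 4L)[1L],
         ": fewer than 4 fields")
  }
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start <- as.integer(vapply(fields, `[[`, character(1L), 2L))
  end <- as.integer(vapply(fields, `[[`, character(1L), 3L))
  value <- as.numeric(vapply(fields, `[[`, character(1L), 4L))
  unknown <- !chrom %in% names(genome)
  if (any(unknown)) {
    stop("bedGraph references unknown chromosome: ", chrom[unknown][1L])
  }
  overlapped <- FALSE
  for (i in seq_along(chrom)) {
    len <- nchar(genome[[chrom[i]]])
    if (start[i] < 0L || end[i] > len || start[i] >= end[i]) {
      stop("bedGraph line ", i, ": interval outside chromosome bounds")
    }
    idx <- (start[i] + 1L):end[i]
    if (!overlapped && any(!is.na(track[[chrom[i]]][idx]))) overlapped <- TRUE
    track[[chrom[i]]][idx] <- value[i]
  }
  if (overlapped) {
    warning("overlapping bedGraph intervals: last-writer-wins")
  }
  track
}

#' Write a signal track to bedGraph
#'
#' Runs of equal values are collapsed to one line; missing (`NA`) stretches
#' are omitted.
#'
#' @param track Named list of per-base numeric vectors.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    v <- track[[chrom]]
    if (length(v) == 0L) next
    r <- rle(ifelse(is.na(v), "NA", formatC(v, format = "g", digits = 6L)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != "NA"
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' Write a table as TSV with stable float formatting
#'
#' Floats are rendered at 6 significant digits so that repeated runs are
#' byte-identical.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @export
write_tsv_report <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  fmt <- rows
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) {
      fmt[[j]] <- ifelse(is.na(rows[[j]]), "NA",
                         sprintf("%.6g", rows[[j]]))
    }
  }
  lines <- c(paste(names(fmt), collapse = "\t"),
             if (nrow(fmt) > 0L) do.call(paste,
               c(lapply(fmt, as.character), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
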