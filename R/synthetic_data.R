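# Synthetic genome generator: an iid background genome with planted,
# AT-rich, motif-bearing, nucleosome-depleted origins; a gene annotation
# producing all three intergenic orientation classes; TSSs at gene 5' ends;
# and a phenomenological nucleosome occupancy track (positive sinusoid times
# depletion envelopes at origins and promoters, plus noise).
#
# The generator is the ground-truth oracle for every downstream stage: its
# manifest records each planted property so tests can do parameter recovery.

ACS_CONSENSUS <- "WTTTATRTTTW"   # (T/A)TTTAT(A/G)TTT(T/A), IUPAC

#' Specification of a synthetic origin-bearing genome
#'
#' Defaults describe the study conditions used throughout the package: a
#' 1-Mb chromosome at background GC 0.38 carrying 100 non-overlapping 300-bp
#' origins at GC 0.317, each with one ACS consensus instance planted at its
#' centre on a random strand and a modest first-order (adjacent-copy)
#' correlation; 31% of origins land within 500 bp of a TSS; nucleosome
#' occupancy has a 165-bp period with depth-0.7 depletion at origins and
#' depth-0.5 depletion at promoters.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param background_gc Genome background GC fraction.
#' @param n_oris,ori_length Number and width (bp) of planted origins.
#' @param ori_gc Target GC fraction of a whole origin window (motif
#'   included; non-motif base frequencies are compensated).
#' @param plant_acs Plant one ACS consensus instance per origin?
#' @param ori_copy_prob First-order correlation inside origins: probability
#'   that a base copies its predecessor instead of an independent draw. 0
#'   disables the adjacent-correlation signal.
#' @param gene_length_mean,gene_length_sd,gene_gap_mean Gene-model geometry
#'   in bp (lengths truncated at 300; gaps at 60).
#' @param tss_jitter_sd SD (bp) of TSS placement around the gene 5' end.
#' @param tss_proximity Fraction of origins planted within 500 bp of a TSS.
#' @param nuc_period,nuc_amplitude,nuc_noise_sd Nucleosome sinusoid period
#'   (bp), amplitude, and additive noise SD.
#' @param ndr_depth,ndr_width Depletion depth (fraction of occupancy
#'   removed at the centre) and full width (bp) at origins.
#' @param promoter_ndr_depth,promoter_ndr_width Same for promoters.
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the spec including this seed.
#' @return List of class `ori_generator_spec`.
#' @export
generator_spec <- function(chrom_lengths = c(chrI = 1000000L),
                           background_gc = 0.38,
                           n_oris = 100L, ori_length = 300L, ori_gc = 0.317,
                           plant_acs = TRUE, ori_copy_prob = 0.2,
                           gene_length_mean = 1400, gene_length_sd = 300,
                           gene_gap_mean = 600,
                           tss_jitter_sd = 30, tss_proximity = 0.31,
                           nuc_period = 165, nuc_amplitude = 1,
                           nuc_noise_sd = 0.15,
                           ndr_depth = 0.7, ndr_width = 150,
                           promoter_ndr_depth = 0.5, promoter_ndr_width = 120,
                           seed = 7L) {
  spec <- list(chrom_lengths = chrom_lengths, background_gc = background_gc,
               n_oris = as.integer(n_oris), ori_length = as.integer(ori_length),
               ori_gc = ori_gc, plant_acs = plant_acs,
               ori_copy_prob = ori_copy_prob,
               gene_length_mean = gene_length_mean,
               gene_length_sd = gene_length_sd,
               gene_gap_mean = gene_gap_mean,
               tss_jitter_sd = tss_jitter_sd, tss_proximity = tss_proximity,
               nuc_period = nuc_period, nuc_amplitude = nuc_amplitude,
               nuc_noise_sd = nuc_noise_sd,
               ndr_depth = ndr_depth, ndr_width = ndr_width,
               promoter_ndr_depth = promoter_ndr_depth,
               promoter_ndr_width = promoter_ndr_width,
               seed = as.integer(seed))
  for (f in c("background_gc", "ori_gc", "tss_proximity")) {
    if (spec[[f]] <= 0 || spec[[f]] >= 1) stop(f, " must be in (0, 1)")
  }
  if (any(chrom_lengths <= 0) || ori_length <= 0) stop("lengths must be positive")
  if (n_oris * ori_length >= sum(chrom_lengths) / 2) {
    stop("origins would cover more than half the genome")
  }
  class(spec) <- "ori_generator_spec"
  spec
}

# one ACS instance: degenerate positions drawn uniformly from their sets
sample_acs <- function() {
  paste0(sample(c("T", "A"), 1L), "TTTAT", sample(c("A", "G"), 1L),
         "TTT", sample(c("T", "A"), 1L))
}

# base probabilities at a given GC fraction (strand-symmetric)
base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

# first-order sequence: with prob `copy` repeat the previous base, else an
# independent draw from pi; stationary distribution stays pi
markov_seq <- function(n, pi, copy) {
  draws <- sample(BASES, n, replace = TRUE, prob = pi)
  if (copy <= 0) return(draws)
  copies <- stats::runif(n) < copy
  out <- draws
  for (t in 2:n) if (copies[t]) out[t] <- out[t - 1L]
  out
}

# multiply a gaussian depletion envelope into `env` around `centre`
apply_ndr <- function(env, centre, depth, width) {
  if (depth <= 0) return(env)
  sigma <- width / 2
  lo <- max(1L, as.integer(centre - 3 * sigma))
  hi <- min(length(env), as.integer(centre + 3 * sigma))
  if (lo > hi) return(env)
  x <- lo:hi
  env[x] <- env[x] * (1 - depth * exp(-(x - centre)^2 / (2 * sigma^2)))
  env
}

#' Generate a synthetic origin-bearing genome bundle
#'
#' With `null = TRUE` every origin-specific signal is disabled: origin
#' intervals are still placed (uniformly, without TSS targeting) but their
#' sequence stays background, no motif is planted, there is no
#' adjacent-copy correlation and no origin depletion in the nucleosome
#' track. Promoter depletion is retained, being a property of the genome,
#' not of origins.
#'
#' @param spec A [generator_spec()].
#' @param null Disable all origin-specific signals?
#' @return List of class `ori_bundle`: `genome` (named character vector),
#'   `oris`, `genes`, `tsses` (interval data.frames), `track` (per-base
#'   list), `manifest` (key/value data.frame of planted properties).
#' @export
generate_bundle <- function(spec, null = FALSE) {
  stopifnot(inherits(spec, "ori_generator_spec"))
  set.seed(spec$seed)
  genome <- character(0L)
  oris <- genes <- tsses <- list()
  track <- list()
  margin <- max(1500L, spec$ori_length)
  for (chrom in names(spec$chrom_lengths)) {
    L <- spec$chrom_lengths[[chrom]]
    seqv <- sample(BASES, L, replace = TRUE,
                   prob = base_probs(spec$background_gc))

    # gene model: sequential gap + gene walk, random strands
    g_start <- integer(0L); g_end <- integer(0L); g_strand <- character(0L)
    pos <- max(60L, round(stats::rnorm(1L, spec$gene_gap_mean,
                                       spec$gene_gap_mean / 3)))
    repeat {
      len <- max(300L, round(stats::rnorm(1L, spec$gene_length_mean,
                                          spec$gene_length_sd)))
      if (pos + len > L - 200L) break
      g_start <- c(g_start, pos)
      g_end <- c(g_end, pos + len)
      g_strand <- c(g_strand, sample(c("+", "-"), 1L))
      pos <- pos + len + max(60L, round(stats::rnorm(1L, spec$gene_gap_mean,
                                                     spec$gene_gap_mean / 3)))
    }
    tss_pos <- ifelse(g_strand == "+",
                      g_start + round(stats::rnorm(length(g_start), 0,
                                                   spec$tss_jitter_sd)),
                      g_end - 1L + round(stats::rnorm(length(g_start), 0,
                                                      spec$tss_jitter_sd)))
    tss_pos <- pmin(pmax(tss_pos, 0L), L - 1L)

    # origin placement: a fixed fraction near TSSs, the rest kept clear of
    # every TSS so the realised proximity rate equals the planted one
    n_this <- spec$n_oris  # single-chromosome default; all origins here
    n_prox <- if (null) 0L else round(n_this * spec$tss_proximity)
    mids <- integer(0L)
    tries <- 0L
    sep <- spec$ori_length + 20L
    while (length(mids) < n_this) {
      tries <- tries + 1L
      if (tries > 200L * n_this) stop("infeasible origin placement")
      if (length(mids) < n_prox) {
        m <- tss_pos[sample.int(length(tss_pos), 1L)] +
          sample(-450L:450L, 1L)
      } else {
        m <- sample.int(L - 2L * margin, 1L) + margin
        # signal bundles pin the realised TSS-proximity rate by keeping the
        # remaining origins clear of every TSS; null placement is uniform
        if (!null && min(abs(tss_pos - m)) < 550L) next
      }
      if (m < margin || m > L - margin) next
      if (length(mids) > 0L && min(abs(mids - m)) < sep) next
      mids <- c(mids, m)
    }
    o_start <- mids - spec$ori_length %/% 2L
    o_end <- o_start + spec$ori_length

    if (!null) {
      # compensate the AT-rich motif so the whole window hits ori_gc
      motif_len <- nchar(ACS_CONSENSUS)
      motif_gc_expected <- if (spec$plant_acs) 0.5 else 0
      eff_len <- spec$ori_length - if (spec$plant_acs) motif_len else 0L
      gc_adj <- (spec$ori_length * spec$ori_gc - motif_gc_expected) / eff_len
      for (i in seq_along(mids)) {
        body <- markov_seq(spec$ori_length, base_probs(gc_adj),
                           spec$ori_copy_prob)
        seqv[(o_start[i] + 1L):o_end[i]] <- body
        if (spec$plant_acs) {
          acs <- sample_acs()
          if (sample(c(TRUE, FALSE), 1L)) acs <- revcomp(acs)
          at <- mids[i] - motif_len %/% 2L
          seqv[(at + 1L):(at + motif_len)] <-
            strsplit(acs, "", fixed = TRUE)[[1L]]
        }
      }
    }

    # nucleosome occupancy: positive sinusoid x depletion envelopes + noise
    x <- seq_len(L)
    phase <- stats::runif(1L, 0, spec$nuc_period)
    occ <- spec$nuc_amplitude *
      (1 + sin(2 * pi * (x + phase) / spec$nuc_period)) / 2
    env <- rep(1, L)
    for (tp in tss_pos) {
      env <- apply_ndr(env, tp + 1L, spec$promoter_ndr_depth,
                       spec$promoter_ndr_width)
    }
    if (!null && spec$ndr_depth > 0) {
      for (m in mids) {
        env <- apply_ndr(env, m + 1L, spec$ndr_depth, spec$ndr_width)
      }
    }
    occ <- pmax(occ * env + stats::rnorm(L, 0, spec$nuc_noise_sd), 0)
    occ <- round(occ, 4L)

    genome[chrom] <- paste(seqv, collapse = "")
    oris[[chrom]] <- intervals(rep(chrom, length(mids)), o_start, o_end,
                               label = sprintf("ori%03d", seq_along(mids)))
    genes[[chrom]] <- intervals(rep(chrom, length(g_start)), g_start, g_end,
                                g_strand,
                                sprintf("%s_g%04d", chrom, seq_along(g_start)))
    tsses[[chrom]] <- intervals(rep(chrom, length(tss_pos)), tss_pos,
                                tss_pos + 1L)
    track[[chrom]] <- occ
  }
  oris <- do.call(rbind, oris)
  genes <- do.call(rbind, genes)
  tsses <- do.call(rbind, tsses)
  rownames(oris) <- rownames(genes) <- rownames(tsses) <- NULL

  measured_ori_gc <- mean(ori_window_gc(genome, oris, spec$ori_length))
  bg <- genome_background_windows(genome, 300L, 300L)
  measured_genome_gc <- mean(vapply(seq_len(nrow(bg)), function(i) {
    gc_profile(count_bases(subseq0(genome, bg$chrom[i], bg$start[i], bg$end[i])))
  }, numeric(1L)))
  prox <- ori_tss_distances(oris, tsses, 500L)$fraction
  manifest <- data.frame(
    key = c("null", "seed", "genome_length", "n_oris", "ori_length",
            "ori_gc_target", "background_gc_target", "measured_ori_gc",
            "measured_genome_gc", "plant_acs", "ori_copy_prob",
            "tss_proximity_target", "tss_proximity_realized",
            "n_genes", "ndr_depth", "ndr_width", "promoter_ndr_depth",
            "nuc_period"),
    value = vapply(list(null, spec$seed, sum(spec$chrom_lengths),
                        nrow(oris), spec$ori_length, spec$ori_gc,
                        spec$background_gc, signif(measured_ori_gc, 6L),
                        signif(measured_genome_gc, 6L),
                        !null && spec$plant_acs,
                        if (null) 0 else spec$ori_copy_prob,
                        if (null) NA else spec$tss_proximity,
                        signif(prox, 6L), nrow(genes),
                        if (null) 0 else spec$ndr_depth, spec$ndr_width,
                        spec$promoter_ndr_depth, spec$nuc_period),
                   function(x) as.character(x), character(1L)),
    stringsAsFactors = FALSE)
  structure(list(genome = genome, oris = oris, genes = genes, tsses = tsses,
                 track = track, manifest = manifest, spec = spec,
                 null = null),
            class = "ori_bundle")
}

#' Generate a null bundle (origin signals disabled)
#'
#' @inheritParams generate_bundle
#' @return An `ori_bundle` whose manifest flags `null = TRUE`.
#' @export
generate_null_bundle <- function(spec) {
  generate_bundle(spec, null = TRUE)
}

#' Write a bundle to standard-format files
#'
#' Emits genome.fa, oris.bed, genes.gff3, tss.bed, nucleosome.bedgraph and
#' manifest.tsv into `dir`.
#'
#' @param bundle An `ori_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ori_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(bundle$genome, file.path(dir, "genome.fa"))
  write_bed(bundle$oris, file.path(dir, "oris.bed"))
  write_gff3_genes(bundle$genes, file.path(dir, "genes.gff3"))
  write_bed(bundle$tsses, file.path(dir, "tss.bed"))
  write_bedgraph(bundle$track, file.path(dir, "nucleosome.bedgraph"))
  write_tsv_report(bundle$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Read a bundle back from a directory written by [write_bundle()]
#'
#' @param dir Directory containing the bundle files.
#' @return List with genome, oris, genes, tsses, track, manifest.
#' @export
read_bundle <- function(dir) {
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  list(genome = genome,
       oris = read_bed(file.path(dir, "oris.bed")),
       genes = read_gff3_genes(file.path(dir, "genes.gff3")),
       tsses = read_bed(file.path(dir, "tss.bed")),
       track = read_bedgraph(file.path(dir, "nucleosome.bedgraph"), genome),
       manifest = utils::read.delim(file.path(dir, "manifest.tsv"),
                                    stringsAsFactors = FALSE))
}
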