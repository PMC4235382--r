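# End-to-end orchestration: signals -> metagene -> annotation -> classify,
# writing one TSV per stage plus a plain-text summary whose every number is
# re-derivable from the stage tables. Runs are bit-reproducible given the
# same inputs and seed.

#' Assemble a pipeline run configuration
#'
#' Defaults are the analysis parameters used throughout: 50/1 bp GC windows,
#' 300/300 bp genome background tiling, 150/1 bp adjacent-redundancy
#' windows, redundancy spectrum to subscript 50 (k_max 48), 1000-bp
#' nucleosome flank, 500-bp TSS proximity threshold, 300-bp instances and
#' 10-fold cross-validation.
#'
#' @param genome,oris,genes,tsses Input objects, or file paths (FASTA, BED,
#'   GFF3, BED respectively).
#' @param track Per-base occupancy track, or a bedGraph path; optional
#'   (nucleosome stages are skipped without it).
#' @param out_dir Output directory for stage TSVs and the summary.
#' @param seed Integer seed (fold assignment).
#' @param gc_window,gc_step,background_window,background_step,d2_window,d2_step
#'   Window parameters in bp.
#' @param k_max Largest redundancy lag.
#' @param profile_flank,nuc_flank Metagene half-widths in bp.
#' @param tss_threshold TSS proximity threshold in bp.
#' @param instance_window Classifier instance width in bp.
#' @param folds Cross-validation folds.
#' @param families Feature families to cross-validate.
#' @return List of class `ori_run_config`.
#' @export
run_config <- function(genome, oris, genes, tsses, track = NULL,
                       out_dir, seed = 7L,
                       gc_window = 50L, gc_step = 1L,
                       background_window = 300L, background_step = 300L,
                       d2_window = 150L, d2_step = 1L, k_max = 48L,
                       profile_flank = 300L, nuc_flank = 1000L,
                       tss_threshold = 500L, instance_window = 300L,
                       folds = 10L,
                       families = c("gc_profile", "gc_skew", "d2",
                                    "nucleosome")) {
  structure(as.list(environment()), class = "ori_run_config")
}

.load_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    if (!file.exists(x)) stop("input file not found: ", x)
    reader(x, ...)
  } else {
    x
  }
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full origin-analysis pipeline
#'
#' Executes every stage and writes, under `config$out_dir`:
#' `gc_comparison.tsv` (ORI vs genome-wide GC with the rank-sum test),
#' `profile_gc_profile.tsv`, `profile_gc_skew.tsv`, `profile_d2.tsv` and
#' `profile_nucleosome.tsv` (anchored metagene curves), `d2_spectrum.tsv`,
#' `intergenic_classes.tsv`, `ori_categories.tsv`, `tss_proximity.tsv`,
#' `cv_table.tsv`, and `summary.txt`. Any stage error aborts the run naming
#' the stage.
#'
#' @param config An [run_config()] object.
#' @return Invisibly, a list with all computed stage results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "ori_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- .stage("load_genome", .load_input(config$genome, read_genome_fasta))
  oris <- .stage("load_oris", .load_input(config$oris, read_bed))
  genes <- .stage("load_genes", .load_input(config$genes, read_gff3_genes))
  tsses <- .stage("load_tsses", .load_input(config$tsses, read_bed))
  track <- if (!is.null(config$track)) {
    .stage("load_track", .load_input(config$track, read_bedgraph,
                                     genome = genome))
  }
  out <- function(f) file.path(config$out_dir, f)

  gc_cmp <- .stage("gc_comparison",
                   ori_vs_genome_gc(genome, oris, config$background_window))
  write_tsv_report(gc_cmp, out("gc_comparison.tsv"))

  prof <- list()
  for (sig in c("gc_profile", "gc_skew")) {
    prof[[sig]] <- .stage(paste0("profile_", sig),
      anchored_profile(genome, oris, sig, flank = config$profile_flank,
                       window = config$gc_window, step = config$gc_step))
    write_tsv_report(prof[[sig]], out(sprintf("profile_%s.tsv", sig)))
  }
  prof$d2 <- .stage("profile_d2",
    anchored_profile(genome, oris, "d2", flank = config$profile_flank,
                     window = config$d2_window, step = config$d2_step))
  write_tsv_report(prof$d2, out("profile_d2.tsv"))
  if (!is.null(track)) {
    prof$nucleosome <- .stage("profile_nucleosome",
      anchored_profile(genome, oris, "track", flank = config$nuc_flank,
                       window = 1L, step = 1L, track = track))
    write_tsv_report(prof$nucleosome, out("profile_nucleosome.tsv"))
  }

  spectrum <- .stage("d2_spectrum", {
    mids <- interval_midpoint(oris)
    half <- config$instance_window %/% 2L
    seqs <- character(0L)
    for (i in seq_len(nrow(oris))) {
      s <- mids[i] - half
      e <- s + config$instance_window
      if (s < 0L || e > chrom_length(genome, oris$chrom[i])) next
      seqs <- c(seqs, subseq0(genome, oris$chrom[i], s, e))
    }
    redundancy_spectrum_set(seqs, k_max = config$k_max, method = "pooled")
  })
  write_tsv_report(spectrum, out("d2_spectrum.tsv"))
  spectrum_argmax <- spectrum$k_plus_2[which.max(spectrum$D)]

  intergenic <- .stage("intergenic", build_intergenic_regions(genes))
  class_counts <- as.data.frame(table(
    factor(intergenic$cls, levels = c("tandem", "divergent", "convergent"))),
    stringsAsFactors = FALSE)
  names(class_counts) <- c("class", "count")
  write_tsv_report(class_counts, out("intergenic_classes.tsv"))

  locs <- .stage("ori_categories",
                 assign_ori_location(oris, genes, intergenic))
  cat_levels <- c("convergent", "tandem", "divergent", "coding_head",
                  "coding_tail", "coding_internal")
  cat_tab <- table(factor(locs$category, levels = cat_levels))
  cat_df <- data.frame(category = cat_levels,
                       count = as.integer(cat_tab),
                       fraction = as.numeric(cat_tab) / nrow(locs),
                       stringsAsFactors = FALSE)
  write_tsv_report(cat_df, out("ori_categories.tsv"))

  tssd <- .stage("tss_distances",
                 ori_tss_distances(oris, tsses, config$tss_threshold))
  tss_df <- data.frame(threshold_bp = config$tss_threshold,
                       n_oris = nrow(oris),
                       fraction_within = tssd$fraction)
  write_tsv_report(tss_df, out("tss_proximity.tsv"))

  families <- config$families
  if (is.null(track)) families <- setdiff(families, "nucleosome")
  reports <- lapply(families, function(fam) {
    .stage(paste0("classify_", fam), {
      inst <- build_instance_sets(genome, oris, fam, track = track,
                                  instance_window = config$instance_window)
      cross_validate_svm(inst, folds = config$folds, seed = config$seed)
    })
  })
  cv_tab <- report_table(reports)
  write_tsv_report(cv_tab, out("cv_table.tsv"))

  summary_lines <- c(
    "origin sequence-signature analysis summary",
    sprintf("seed: %d", config$seed),
    sprintf("ORI mean GC %.6g (n=%d) vs genome-wide %.6g (n=%d); U=%.6g p=%.3g",
            gc_cmp$mean_a, gc_cmp$n1, gc_cmp$mean_b, gc_cmp$n2,
            gc_cmp$U, gc_cmp$p),
    sprintf("anchored GC-profile minimum at offset %d bp",
            prof$gc_profile$offset[which.min(prof$gc_profile$mean)]),
    sprintf("redundancy spectrum argmax at subscript k+2 = %d (D = %.6g bits)",
            spectrum_argmax, max(spectrum$D)),
    sprintf("intergenic regions: %s",
            paste(sprintf("%s %d", class_counts$class, class_counts$count),
                  collapse = ", ")),
    sprintf("ORI categories: %s",
            paste(sprintf("%s %.3f", cat_df$category, cat_df$fraction),
                  collapse = ", ")),
    sprintf("fraction of ORIs within %d bp of a TSS: %.6g",
            config$tss_threshold, tssd$fraction),
    "cross-validation (Sn/Sp/Acc):",
    sprintf("  %-12s %.4f %.4f %.4f", cv_tab$family, cv_tab$Sn, cv_tab$Sp,
            cv_tab$Acc))
  writeLines(summary_lines, out("summary.txt"))

  invisible(list(gc_comparison = gc_cmp, profiles = prof,
                 spectrum = spectrum, spectrum_argmax = spectrum_argmax,
                 intergenic = intergenic, class_counts = class_counts,
                 ori_categories = cat_df, ori_locations = locs,
                 tss = tssd, cv_table = cv_tab, reports = reports))
}
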