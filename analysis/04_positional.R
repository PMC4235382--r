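#!/usr/bin/env Rscript
# Positional genomics of origins: nucleosome occupancy metagene across
# ±1000 bp with the core-vs-flank depletion contrast, intergenic orientation
# classes, per-ORI positional categories, and ORI-TSS distances.

suppressPackageStartupMessages(library(oriseq))
dir.create("results", showWarnings = FALSE)

bundle <- generate_bundle(generator_spec(seed = 7L))
null_bundle <- generate_null_bundle(generator_spec(seed = 1007L))

prof <- anchored_profile(bundle$genome, bundle$oris, "track",
                         flank = 1000L, window = 1L, step = 1L,
                         track = bundle$track)
write_tsv_report(prof, "results/profile_nucleosome.tsv")
ndr <- ndr_contrast(bundle$track, bundle$oris)
nndr <- ndr_contrast(null_bundle$track, null_bundle$oris)
write_tsv_report(rbind(cbind(genome = "signal", ndr),
                       cbind(genome = "null", nndr)),
                 "results/ndr_contrast.tsv")
cat(sprintf(
  "Nucleosome occupancy: core [-75,75] mean %.3f vs flank %.3f (p = %.3g);\n",
  ndr$mean_a, ndr$mean_b, ndr$p))
cat(sprintf("null genome p = %.3g - origins sit in depleted regions.\n",
            nndr$p))

ig <- build_intergenic_regions(bundle$genes)
counts <- table(factor(ig$cls, c("tandem", "divergent", "convergent")))
write_tsv_report(data.frame(class = names(counts),
                            count = as.integer(counts)),
                 "results/intergenic_classes.tsv")
cat(sprintf("Intergenic regions: %d tandem, %d divergent, %d convergent.\n",
            counts["tandem"], counts["divergent"], counts["convergent"]))

loc <- suppressWarnings(assign_ori_location(bundle$oris, bundle$genes, ig))
tab <- table(loc$category)
cat_df <- data.frame(category = names(tab), count = as.integer(tab),
                     fraction = as.numeric(tab) / nrow(loc))
write_tsv_report(cat_df, "results/ori_categories.tsv")
cat("ORI categories:",
    paste(sprintf("%s %.0f%%", cat_df$category, 100 * cat_df$fraction),
          collapse = ", "), "\n")

tss <- ori_tss_distances(bundle$oris, bundle$tsses, 500L)
write_tsv_report(data.frame(threshold_bp = 500L, n_oris = nrow(bundle$oris),
                            fraction_within = tss$fraction),
                 "results/tss_proximity.tsv")
cat(sprintf("%.1f%% of origins lie within 500 bp of a TSS.\n",
            100 * tss$fraction))
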