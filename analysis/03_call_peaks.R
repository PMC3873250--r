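#!/usr/bin/env Rscript
# Step 3: peak calling, cross-profile matching and peak-height correlation.
#
# Peaks are local maxima flanked on both sides by valleys (topographic
# prominence >= 5 signal units here, the recovery-study stringency); peaks
# from the two profiles are matched one-to-one within the smoothing
# bandwidth (300 bp) and their heights compared by Pearson correlation.

suppressPackageStartupMessages(library(meiochip))

bandwidth <- 300
dir.create("results/peaks", showWarnings = FALSE, recursive = TRUE)

layout <- read_chrom_sizes("results/simdata/genome.chrom.sizes")
profiles <- lapply(
  c(smc6_a = "results/profiles/smc6_a_subtracted.bedgraph",
    smc6_b = "results/profiles/smc6_b_subtracted.bedgraph"),
  read_bedgraph, layout = layout, resolution = 10)
for (nm in names(profiles)) {
  profiles[[nm]]$bandwidth <- bandwidth
  profiles[[nm]]$sample_name <- nm
}

params <- peak_call_params(min_valley_depth = 5, q_threshold = 0)
peaks <- lapply(profiles, call_peaks, params = params)
for (nm in names(peaks)) {
  write_peak_table(peaks[[nm]], sprintf("results/peaks/%s_peaks.tsv", nm))
  cat(sprintf("%s: %d peaks (median height %.1f)\n", nm, nrow(peaks[[nm]]),
              median(peaks[[nm]]$height)))
}

mt <- match_peaks(peaks$smc6_a, peaks$smc6_b, max_dist = bandwidth)
cat(sprintf("matched %d peak pairs within %d bp (%d + %d unmatched)\n",
            nrow(mt$pairs), bandwidth, length(mt$unmatched_a),
            length(mt$unmatched_b)))

cm <- correlation_matrix(peaks, max_dist = bandwidth)
cat(sprintf("peak-height Pearson correlation smc6_a vs smc6_b: %.3f over %d pairs\n",
            cm$rho["smc6_a", "smc6_b"], cm$n_pairs["smc6_a", "smc6_b"]))

writeLines(c("chrom\tsummit_a\tsummit_b\theight_a\theight_b\tdistance",
             sprintf("%s\t%d\t%d\t%.6g\t%.6g\t%d", mt$pairs$chrom,
                     as.integer(mt$pairs$summit_a),
                     as.integer(mt$pairs$summit_b),
                     mt$pairs$height_a, mt$pairs$height_b,
                     as.integer(mt$pairs$distance))),
           "results/peaks/matches_smc6_a_vs_smc6_b.tsv")
writeLines(c(paste(c("sample", rownames(cm$rho)), collapse = "\t"),
             vapply(rownames(cm$rho), function(i) {
               paste(c(i, sprintf("%.6f", cm$rho[i, ])), collapse = "\t")
             }, "")),
           "results/peaks/correlation_matrix.tsv")
cat("wrote results/peaks/\n")
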