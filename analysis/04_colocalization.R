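#!/usr/bin/env Rscript
# Step 4: DSB hotspot grouping and co-localization significance.
#
# Spo11-oligo 5' ends < 50 bp apart are grouped into hotspots; peak/peak
# overlap is scored with the hypergeometric model (universe = number of
# bandwidth-wide slots in the genome) and peaks-in-hotspots with the
# binomial model (success probability = hotspot bp fraction). Called peaks
# are finally compared against the simulation ground truth.

suppressPackageStartupMessages(library(meiochip))

bandwidth <- 300
dir.create("results/coloc", showWarnings = FALSE, recursive = TRUE)

layout <- read_chrom_sizes("results/simdata/genome.chrom.sizes")
oligos <- read_oligo_table("results/simdata/spo11_oligos.bed", layout)
hotspots <- group_oligo_hotspots(oligos, gap = 50)
write_hotspots(hotspots, "results/coloc/hotspots.bed")
cat(sprintf("grouped %d oligo positions into %d hotspots (%.2f%% of genome)\n",
            nrow(oligos), nrow(hotspots),
            100 * hotspot_bp_fraction(hotspots, layout)))

peaks <- lapply(c(smc6_a = "results/peaks/smc6_a_peaks.tsv",
                  smc6_b = "results/peaks/smc6_b_peaks.tsv"),
                read_peak_table)
for (nm in names(peaks)) {
  attr(peaks[[nm]], "layout") <- layout
  attr(peaks[[nm]], "bandwidth") <- bandwidth
}

p_hot <- hotspot_bp_fraction(hotspots, layout)
tests <- list()
for (nm in names(peaks)) {
  asg <- assign_peaks_to_intervals(peaks[[nm]], hotspots)
  t <- binomial_hotspot_test(asg$n_peaks_in, nrow(peaks[[nm]]), p_hot)
  tests[[paste0("binomial_", nm)]] <- t
  cat(sprintf("%s: %d/%d peaks inside hotspots; binomial log10 p = %.1f\n",
              nm, asg$n_peaks_in, nrow(peaks[[nm]]), t$log10_p))
}

mt <- match_peaks(peaks$smc6_a, peaks$smc6_b, max_dist = bandwidth)
N <- overlap_universe_size(layout, bandwidth)
ht <- hypergeom_overlap_test(nrow(mt$pairs), nrow(peaks$smc6_a),
                             nrow(peaks$smc6_b), N)
tests$hypergeom_smc6_a_vs_smc6_b <- ht
cat(sprintf("peak/peak overlap: k = %d, universe N = %d; hypergeometric log10 p = %.1f\n",
            ht$k, N, ht$log10_p))
write_test_table(tests, "results/coloc/overlap_tests.tsv")

truth <- read_truth_json("results/simdata/truth_a.json")
rep <- peak_truth_report(peaks$smc6_a, truth, tol = bandwidth)
cat(sprintf("truth check (smc6_a): recall %.2f, precision %.2f (%d/%d planted recovered)\n",
            rep$recall, rep$precision, rep$n_recovered, rep$n_true))
jsonlite::write_json(rep, "results/coloc/truth_report.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/coloc/\n")
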