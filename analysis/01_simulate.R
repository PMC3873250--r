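#!/usr/bin/env Rscript
# Step 1: generate the synthetic study dataset.
#
# Two tagged ChIP samples that bind the same occupied subset of DSB
# hotspots (true summit heights drawn as a correlated pair, target Pearson
# 0.8), one untagged control (pure background), and a Spo11-oligo 5'-end
# table around the hotspot centers. Everything is written in the same
# plain-text formats a real experiment would arrive in.

suppressPackageStartupMessages(library(meiochip))

seed <- 42
dir.create("results/simdata", showWarnings = FALSE, recursive = TRUE)

exp <- simulate_experiment(seed, rho = 0.8)

write_chrom_sizes(exp$layout, "results/simdata/genome.chrom.sizes")
write_hits(exp$hits_a, "results/simdata/smc6_a.bed")
write_hits(exp$hits_b, "results/simdata/smc6_b.bed")
write_hits(exp$hits_untagged, "results/simdata/untagged.bed")
write_oligo_table(exp$oligos, "results/simdata/spo11_oligos.bed")
write_truth_json(exp$truth_a, "results/simdata/truth_a.json")
write_truth_json(exp$truth_b, "results/simdata/truth_b.json")

cat(sprintf("genome: %d chromosomes, %s bp\n", nrow(exp$layout),
            format(genome_length(exp$layout), big.mark = ",",
                   scientific = FALSE)))
cat(sprintf("hotspots planted: %d (%d occupied)\n",
            nrow(exp$truth_a$hotspots), length(exp$truth_a$occupied)))
cat(sprintf("reads: tagged_a %d, tagged_b %d, untagged %d\n",
            nrow(exp$hits_a), nrow(exp$hits_b), nrow(exp$hits_untagged)))
cat(sprintf("true background scaling r = %.2f, multi-mapping fraction %.2f\n",
            exp$truth_a$r_true, exp$truth_a$multi_map_fraction))
cat("wrote results/simdata/\n")
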