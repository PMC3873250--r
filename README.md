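# meiochip

ChIP-seq profile analysis at meiotic DSB hotspots in budding yeast.

During meiosis, Spo11 introduces programmed DNA double-strand breaks (DSBs)
at narrow genomic hotspots. Chromatin-association studies of repair and
anti-recombination factors (Smc5/6, Sgs1, and their partners) ask a
quantitative question of ChIP-seq data: do a protein's binding peaks fall
*precisely inside* DSB hotspots more often than chance allows, and do two
proteins' peak intensities agree across the genome? `meiochip` implements
that analysis end to end for compact genomes:

1. **Weighted coverage** — each aligned hit contributes `1/n` to read depth,
   where `n` is the read's number of genome-wide matches (up to a cap of
   5000 hits per read); gaps are explicit zeros.
2. **Smoothing** — Nadaraya–Watson kernel regression of the 1 bp depth,
   sampled every 10 bp. The Gaussian kernel follows the `ksmooth`
   convention: its quartiles sit at ±0.25·*bandwidth* (σ ≈ 0.3706·*b*),
   with bandwidths of 250–500 bp typical.
3. **Normalization** — the NCIS estimator finds the background scaling *r*
   of ChIP to untagged control from low-coverage genomic bins; the
   subtracted profile is `max(0, chip − r·control)`. An optional decile
   normalization (division by the 9th decile of positive bins) puts
   profiles on a common display scale.
4. **Peak calling** — peaks are local maxima flanked on both sides by
   valleys of a minimum depth (topographic prominence), optionally filtered
   at a height quantile *Q* (default 0.7).
5. **Matching & correlation** — peaks from different profiles are matched
   one-to-one within the smoothing bandwidth and their heights compared by
   Pearson correlation.
6. **Co-localization statistics** — Spo11-oligo 5′ ends < 50 bp apart are
   grouped into hotspots; peak/peak overlap significance uses a
   hypergeometric model
   `p = Σ_{i≥k} C(K,i)·C(N−K,n−i)/C(N,n)` over `N = ⌊genome/bandwidth⌋`
   slots, and peaks-in-hotspots uses a binomial model
   `p = Σ_{i≥k} C(n,i)·p^i·(1−p)^{n−i}` with `p` the hotspot base-pair
   fraction. Both are evaluated in log space and stay finite arbitrarily
   deep in the tail.

A seeded synthetic-data generator (`simulate_experiment()` and friends)
produces tagged/untagged read pairs with planted hotspot occupancy, known
background scaling, multi-mapping decoys, and paired peak heights with a
target Pearson correlation, so every stage is testable against ground truth
without sequencing data.

## Worked example

The `analysis/` scripts run the whole study on simulated data:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_build_profiles.R
Rscript analysis/03_call_peaks.R
Rscript analysis/04_colocalization.R
```

Output of the run (seed 42; 2 × 300 kb genome, 40 planted hotspots of
which 30 occupied, true background scaling r = 0.7):

```
smc6_a: NCIS r = 0.7059 (300 background bins of 1000 bp)
smc6_b: NCIS r = 0.7031 (300 background bins of 1000 bp)
smc6_a: 30 peaks (median height 15.6)
matched 30 peak pairs within 300 bp (0 + 0 unmatched)
peak-height Pearson correlation smc6_a vs smc6_b: 0.867 over 30 pairs
grouped 800 oligo positions into 40 hotspots (0.37% of genome)
smc6_a: 28/30 peaks inside hotspots; binomial log10 p = -65.3
peak/peak overlap: k = 30, universe N = 2000; hypergeometric log10 p = -66.5
truth check (smc6_a): recall 1.00, precision 1.00 (30/30 planted recovered)
```

Reading it: NCIS recovers the simulated background fraction to within ~1%;
every occupied hotspot is recovered as a called peak with no false
positives; peaks of the two samples match pairwise and their heights
correlate strongly; and both co-localization models reject the random
placement null at astronomically small p — the behavior expected when a
protein truly localizes to DSB hotspots.

Equivalent single-call interface:

```r
library(meiochip)
cfg <- run_config(samples, chrom_sizes = "genome.chrom.sizes",
                  oligo_table = "spo11_oligos.bed", out_dir = "run")
res <- run_pipeline(cfg)
```

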