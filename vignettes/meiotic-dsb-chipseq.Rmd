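---
title: "Methods: ChIP-seq profiles, peak co-localization and DSB hotspots"
author: "meiochip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ChIP-seq profiles, peak co-localization and DSB hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiochip)
```

# The analysis model

`meiochip` quantifies where a chromatin-associated protein binds relative
to meiotic DSB hotspots, from aligned ChIP-seq hits to co-localization
p-values. The pipeline treats the data generative model as: observed ChIP
coverage = *r* × (control background shape) + localized enrichment at a
subset of genomic sites, where the untagged-strain control measures the
background shape and *r* is an unknown scaling between the two libraries.
Every downstream statistic (peak heights, correlations, overlap counts) is
computed on the background-subtracted profile.

## Multi-mapping weights

Each aligned hit contributes `1/n` to coverage, where `n` is the read's
number of genome-wide matches; reads with more than `max_hits` (default
5000) matches are dropped whole, mirroring the aligner's hit cap. Dropping
rather than truncating keeps per-read mass at exactly 1 for every retained
read — an invariant the tests exercise. Input without a match-count column
(pre-filtered unique alignments) is accepted as weight 1 with a warning.
Hits cover their full aligned interval, both strands pooled, since the
quantity of interest is read depth per position rather than cut sites.

## Kernel smoothing

Smoothing is Nadaraya–Watson regression of the 1 bp depth vector,
evaluated every `resolution` bp (default 10):

$$\hat f(x) = \frac{\sum_p K\!\left(\frac{x-p}{h}\right) d_p}
                  {\sum_p K\!\left(\frac{x-p}{h}\right)},$$

with a Gaussian kernel scaled so its *quartiles* sit at ±0.25 × bandwidth
(σ = 0.25·b / Φ⁻¹(0.75) ≈ 0.3706·b) — the `ksmooth` bandwidth convention,
fixed here so "bandwidth 300 bp" means the same thing across tools.
Numerical choices:

* kernel support truncated at ±4σ (omitted mass < 1e−4 of the kernel);
* the convolution runs through an FFT zero-padded to a 2-3-5-smooth
  length, so cost does not depend on the factorization of the chromosome
  length; agreement with a direct double-loop evaluation is at machine
  precision (~1e−15 relative, tested at 1e−9);
* at chromosome ends the denominator renormalizes over available
  positions — no padding, no edge droop;
* smoothing the 1 bp vector and sampling every 10 bp (rather than
  pre-binning to 10 bp and smoothing bins) keeps the estimate independent
  of bin phase.

Bandwidths used in the analyses: 300 bp for peak calling and matching,
250/500 bp as display scales.

## NCIS background normalization

The background scaling *r* of ChIP to control is estimated from raw
(unsmoothed) 1 kb bins — smoothing first would correlate neighboring bins
and blur the background/signal separation the estimator relies on. Bins
are ordered by total count (ChIP + control); along the cumulative ratio
ΣChIP/Σcontrol over that ordering, low-total bins are background-dominated
and the ratio is flat, rising once signal bins begin to enter. *r* is the
ratio at the first strict increase after at least half of all bins are
included; a relative tolerance of 1e−12 guards the increase test against
floating-point jitter, and an exactly proportional pair (no rise anywhere)
yields the whole-genome ratio. Sorting by the *sum* makes the ratio
conditionally unbiased for pure background (given a bin total *t*, the
ChIP share is Binomial(t, r/(1+r))), which is why the estimator is also
invariant to rescaling both libraries by a common constant.

Subtraction clamps at zero: `max(0, chip − r·control)`. Peaks are defined
on nonnegative signal, and negative residuals carry no biological meaning
in this model.

## Decile normalization

For cross-sample display, a profile can be divided by the value of its
*k*-th decile over positive bins (default the 9th). The quantile uses R's
type-7 (linear interpolation) convention throughout the package. Division
by a robust high quantile is preferred to the maximum because a single
summit would otherwise set the scale. The order *normalize-then-subtract*
versus *subtract-then-normalize* is configurable in the pipeline; the
default applies subtraction first, then the optional decile scaling, so
the decile is computed on the signal actually being displayed.

## Peak calling

"Flanked on both sides by valleys with a minimum depth" is formalized as
topographic prominence: for a local maximum of height *h*, each flanking
valley is the minimum of the signal between the summit and the nearest
strictly higher position (or the chromosome end), and the peak's
prominence is *h* − max(left valley, right valley). A candidate peak must
have prominence ≥ `min_valley_depth`; a shallow saddle between twin maxima
therefore merges them into the higher summit. Plateau summits report the
leftmost grid position; chromosome boundary positions are never summits (a
monotone ramp has no peak). On top of prominence, the *Q* filter retains
candidates whose height reaches the `q_threshold` type-7 quantile of
candidate heights (default Q = 0.7).

The two thresholds serve different purposes. *Q* is a *relative*
stringency: it always keeps the top (1−Q) share of candidates, which is
the right knob when comparing profiles of different depths, but it cannot
bound the false-discovery behavior when candidates are dominated by tiny
background-residual bumps. The recovery analyses in `analysis/` and the
validation suite therefore call peaks with an *absolute* prominence floor
(`min_valley_depth = 5` signal units, roughly 5× the background-residual
scale of the simulated data, i.e. 20% of the mean planted summit height)
and Q = 0. Both are exposed; the defaults (depth 0, Q 0.7) reproduce the
quantile-based stringency used for cross-profile correlation work.

## Matching and correlation

Peak sets from two profiles are matched one-to-one: all same-chromosome
summit pairs within `max_dist` (set to the smoothing bandwidth) are sorted
by distance — ties broken leftmost-first for determinism — and accepted
greedily, each peak used at most once. Greedy nearest-first is O(n log n)
and reproducible; exhaustive enumeration on small sets shows it can
concede a pair of cardinality to the optimal assignment on chained
configurations, a documented property of the contract rather than a bug
(at bandwidth-scale separations between well-spaced peaks the two agree).
Matched heights are compared by Pearson correlation; cells with fewer than
3 pairs are reported as undefined rather than ±1 noise.

## Hotspots and co-localization models

Spo11-oligo 5′ ends closer than 50 bp group into one hotspot
(single-linkage along the chromosome; verified against a union-find
oracle); the interval is `[min, max+1)`, so a lone oligo is a width-1
hotspot, and intervals never overlap by construction. A peak hits a
hotspot iff `start ≤ summit < end` — the summit must sit precisely between
the hotspot borders.

Peak/peak overlap: hypergeometric upper tail with universe
`N = ⌊genome / max_dist⌋`, the number of non-overlapping matching-window
slots. Genome-scale analyses of this kind leave *N* unstated; this choice makes
"overlap" commensurate with the matching tolerance and is exposed as a
parameter and recorded in the output. Peaks-in-hotspots: binomial upper
tail with success probability the hotspot base-pair fraction of the
genome. Both models are evaluated via `phyper`/`pbinom` with `log.p =
TRUE`, so `log10_p` stays finite (no underflow) for counts up to 10⁶ and
p-values far below 1e−300; exact enumeration oracles pin the values to
1e−12 on all small grids.

# The synthetic-data generator

`simulate_experiment()` emulates the assumed data model at desk scale:

| parameter | default | meaning |
|---|---|---|
| `n_chrom`, `chrom_length` | 2 × 300 kb | genome size |
| `n_hotspots`, `min_spacing` | 40, 5 kb | planted hotspot centers |
| `occupancy` | 0.75 | fraction of hotspots truly bound |
| `mean_height`, `height_sdlog` | 25, 0.3 | log-normal summit enrichment (depth units) |
| `background_rate` | 5 | control depth per bp |
| `r_true` | 0.7 | ChIP background scaling |
| `multi_map_fraction`, `decoy_k` | 0.1, 4 | k-fold multi-hits at decoy sites |
| `read_length`, `frag_sd` | 50 bp, 100 bp | read and fragment geometry |

Defaults are chosen once as a scaled-down but structurally faithful
version of a yeast meiotic ChIP experiment: 50 bp single-end reads, a few
×10⁴ reads per sample, hotspot spacing far above the smoothing bandwidth,
summit enrichment ≈ 5× background, ~10% multi-mapping. Signal reads are
drawn with Gaussian fragment spread around the summit, in numbers
calibrated so the expected *raw* depth added at the summit equals the true
height; decoy positions for multi-mapping reads avoid hotspot
neighborhoods so multi-mapping can dilute background but never create a
false peak — isolating the weighting logic under test. Every generator is
a pure function of (parameters, seed); the caller's RNG state is saved and
restored.

Paired peak heights are bivariate log-normal. The latent Gaussian
correlation is calibrated as ρ_z = log(1 + ρ(e^{s²}−1))/s² so that the
*heights themselves* — the quantities the correlation matrix compares —
carry the target Pearson ρ. The spread default `sdlog = 0.3` keeps the
height distribution mild enough that normal-theory (Fisher-z) intervals
for the sample correlation retain near-nominal coverage, a design
requirement of the correlation-recovery study, while still spanning
roughly two-fold height variation.

**What passing does and does not show.** The simulator has uniform
background, Gaussian fragment placement, no chromatin structure, no
mappability or GC bias, no axis-site signal class, and hotspot density far
below the real genome's (~1 per 15 kb here versus ~1 per 1.7 kb in a real
meiotic map). Green tests demonstrate the estimators are correct under
their own model — NCIS recovers *r* within 10%, planted summits are
recovered at ≥95% recall/precision, a known ρ is re-estimated inside its
Fisher-z band — not that real profiles are free of the biases the model
omits.

# Validation study sizes

The suite and `scripts/acceptance.R` use: 2 kb vectors for the
smoothing-oracle comparison; 100 kb genomes × 20 seeds for NCIS recovery
(signal confined to 2% of bins); 2 × 200 kb genomes with 24 hotspots for
the planted-summit and end-to-end runs; n = 1000 pairs × 20 seeds for
correlation recovery; exhaustive enumeration up to N = 12 for the overlap
models. These sizes give each check comfortable statistical resolution
(e.g. the NCIS median-error bound is ~20× the estimator's sampling spread
at this depth) while a full run stays in the minutes range.

# Known limitations

* NCIS assumes background dominates at least half the genome; deeply
  signal-saturated libraries would bias *r* upward.
* The geometric peak definition carries no per-peak error model — that is
  deliberate fidelity to valley-depth calling; a Poisson/NB enrichment
  model is out of scope.
* Greedy matching is not globally optimal (see above); with peaks spaced
  at bandwidth scale the difference is negligible.
* The hypergeometric universe N is a modeling choice, not an estimate;
  conclusions should be checked for robustness across reasonable N.
* Strand-separated profiles, spike-in normalization and mappability
  correction are not implemented.
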