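# DSB hotspot grouping from Spo11-oligo 5' ends and parametric
# co-localization significance models.

#' Group Spo11-oligo 5' ends into DSB hotspots
#'
#' Single-linkage clustering along each chromosome: two consecutive 5'-end
#' positions join the same hotspot iff their distance is strictly less than
#' `gap` bp (default 50). Each hotspot becomes the half-open interval
#' `[min_pos, max_pos + 1)` — a single-oligo hotspot has width 1 — with the
#' member counts summed into its intensity.
#'
#' @param oligos An `OligoTable` (`chrom`, `pos`, `count`).
#' @param gap Grouping distance in bp; positions `< gap` apart cluster.
#' @return A `HotspotSet`: sorted, non-overlapping data.frame with columns
#'   `chrom`, `start`, `end`, `oligo_count`, `n_oligos`.
#' @export
group_oligo_hotspots <- function(oligos, gap = 50) {
  stopifnot(is.data.frame(oligos), gap > 0)
  if (any(oligos$count < 0)) stop("negative oligo count", call. = FALSE)
  per_chrom <- lapply(unique(oligos$chrom), function(ch) {
    o <- oligos[oligos$chrom == ch, , drop = FALSE]
    o <- o[order(o$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(o$pos) >= gap))
    data.frame(
      chrom = ch,
      start = as.numeric(tapply(o$pos, grp, min)),
      end = as.numeric(tapply(o$pos, grp, max)) + 1,
      oligo_count = as.numeric(tapply(o$count, grp, sum)),
      n_oligos = as.integer(tapply(o$count, grp, length)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_chrom)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      oligo_count = numeric(), n_oligos = integer())
  }
  rownames(out) <- NULL
  structure(out, class = c("HotspotSet", "data.frame"), gap = gap)
}

#' Hotspot base-pair fraction of the genome
#'
#' Total hotspot interval length divided by the genome length; the default
#' success probability of [binomial_hotspot_test()].
#'
#' @param hotspots A `HotspotSet`.
#' @param layout A `GenomeLayout`.
#' @return Fraction in (0, 1).
#' @export
hotspot_bp_fraction <- function(hotspots, layout) {
  sum(hotspots$end - hotspots$start) / genome_length(layout)
}

new_overlap_test <- function(model, k, params, log_p) {
  structure(
    c(list(model = model, k = k), params,
      list(p_value = exp(log_p), log10_p = log_p / log(10))),
    class = "OverlapTest"
  )
}

#' @export
print.OverlapTest <- function(x, ...) {
  cat(sprintf("%s overlap test: k = %d, p = %.4g (log10 p = %.2f)\n",
              x$model, x$k, x$p_value, x$log10_p))
  invisible(x)
}

#' Hypergeometric test for peak/peak overlap
#'
#' Upper-tail probability of observing at least `k` overlaps when `n` items
#' are drawn without replacement from a universe of `N` slots of which `K`
#' are marked: `p = sum_{i >= k} C(K,i) C(N-K, n-i) / C(N,n)`, evaluated in
#' log space. For peak overlap between two profiles, `K` and `n` are the two
#' peak counts, `k` the number of matched peaks, and `N` the number of
#' non-overlapping matching-distance-wide slots in the genome (see
#' [overlap_universe_size()]).
#'
#' @param k Observed overlaps.
#' @param K Marked slots (peaks of profile A).
#' @param n Draws (peaks of profile B).
#' @param N Universe size.
#' @return An `OverlapTest` with `p_value` and always-finite `log10_p`.
#' @export
hypergeom_overlap_test <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N) {
    stop("inconsistent hypergeometric parameters", call. = FALSE)
  }
  log_p <- if (k <= 0) 0 else {
    stats::phyper(k - 1, m = K, n = N - K, k = n,
                  lower.tail = FALSE, log.p = TRUE)
  }
  new_overlap_test("hypergeometric", k, list(K = K, n = n, N = N), log_p)
}

#' Universe size for the hypergeometric peak-overlap model
#'
#' The number of non-overlapping `max_dist`-wide slots a peak could occupy:
#' `floor(genome length / max_dist)`. Makes "overlap" commensurate with the
#' peak-matching tolerance (the smoothing bandwidth).
#'
#' @param layout A `GenomeLayout`.
#' @param max_dist Matching distance in bp.
#' @return Integer universe size.
#' @export
overlap_universe_size <- function(layout, max_dist) {
  floor(genome_length(layout) / max_dist)
}

#' Binomial test for peaks falling into hotspot regions
#'
#' Upper-tail probability that at least `k` of `n` peaks land in hotspots
#' when each lands there independently with probability `p_hot`:
#' `p = sum_{i >= k} C(n,i) p_hot^i (1-p_hot)^(n-i)`, in log space.
#' `p_hot` defaults to the hotspot base-pair fraction of the genome.
#'
#' @param k Peaks inside hotspots.
#' @param n Total peaks.
#' @param p_hot Probability a random peak lands in a hotspot, in (0, 1).
#' @return An `OverlapTest` with `p_value` and always-finite `log10_p`.
#' @export
binomial_hotspot_test <- function(k, n, p_hot) {
  if (k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  if (p_hot <= 0 || p_hot >= 1) stop("p_hot must be in (0, 1)", call. = FALSE)
  log_p <- if (k <= 0) 0 else {
    stats::pbinom(k - 1, size = n, prob = p_hot,
                  lower.tail = FALSE, log.p = TRUE)
  }
  new_overlap_test("binomial", k, list(n = n, p_hot = p_hot), log_p)
}

#' qChIP relative enrichment
#'
#' Ratio of a locus qPCR signal to a cold-region reference signal from the
#' same ChIP (e.g. DSB/ADP1 or core/ADP1), correcting for IP-efficiency
#' differences between samples.
#'
#' @param signal Numeric vector of locus signals.
#' @param reference Numeric vector of reference (cold-spot) signals, > 0,
#'   recycled against `signal`.
#' @return `signal / reference`, elementwise.
#' @export
relative_enrichment <- function(signal, reference) {
  if (any(reference <= 0)) stop("reference signal must be > 0", call. = FALSE)
  signal / reference
}

#' Write overlap-test results as TSV
#' @param tests List of `OverlapTest` objects (optionally named).
#' @param path Output path.
#' @export
write_test_table <- function(tests, path) {
  rows <- vapply(seq_along(tests), function(i) {
    t <- tests[[i]]
    label <- if (!is.null(names(tests))) names(tests)[i] else sprintf("test_%d", i)
    par <- if (t$model == "hypergeometric") {
      sprintf("K=%d;n=%d;N=%d", t$K, t$n, t$N)
    } else {
      sprintf("n=%d;p_hot=%s", t$n, fmt_num(t$p_hot))
    }
    sprintf("%s\t%s\t%d\t%s\t%s\t%s", label, t$model, t$k, par,
            fmt_num(t$p_value), fmt_num(t$log10_p))
  }, "")
  writeLines(c("comparison\tmodel\tk\tparameters\tp_value\tlog10_p", rows),
             path)
  invisible(path)
}
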