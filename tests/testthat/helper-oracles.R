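# Independent brute-force oracles used to check the fast implementations.
# Each is written from the definition, not from the code it checks.

# Nadaraya-Watson by direct double loop, Gaussian kernel with quartiles at
# +/- 0.25 * bandwidth, truncated at 4 sigma, renormalized at the ends.
nw_oracle <- function(x, bandwidth, resolution) {
  sigma <- 0.25 * bandwidth / qnorm(0.75)
  W <- ceiling(4 * sigma)
  n <- length(x)
  grid <- seq(0, n - 1, by = resolution)
  vapply(grid, function(g) {
    idx <- max(0, g - W):min(n - 1, g + W)
    w <- dnorm(idx - g, sd = sigma)
    sum(w * x[idx + 1]) / sum(w)
  }, 0)
}

# Per-position accumulation by looping over every hit and every base.
depth_oracle <- function(hits, L, chrom) {
  v <- numeric(L)
  h <- hits[hits$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(h))) {
    for (p in seq(h$start[i], h$end[i] - 1)) v[p + 1] <- v[p + 1] + h$weight[i]
  }
  v
}

# Topographic prominence by direct definition: for each strict local
# maximum, the valley on each side is the minimum between the summit and
# the nearest strictly higher position (or the vector end).
prominence_oracle <- function(v) {
  n <- length(v)
  out <- NULL
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1] == v[i]) j <- j + 1
    if (i > 1 && j < n && v[i - 1] < v[i] && v[j + 1] < v[i]) {
      higher_l <- which(v[seq_len(i - 1)] > v[i])
      lv <- min(v[(if (length(higher_l)) max(higher_l) + 1 else 1):(i - 1)])
      higher_r <- which(v[(j + 1):n] > v[i]) + j
      rv <- min(v[(j + 1):(if (length(higher_r)) min(higher_r) - 1 else n)])
      out <- rbind(out, data.frame(idx = i, height = v[i],
                                   prom = v[i] - max(lv, rv)))
    }
    i <- j + 1
  }
  out
}

# Single-linkage grouping by union-find with the pairwise |pi - pj| < gap
# predicate.
group_oracle <- function(pos, gap) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) < gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  split(pos, roots)
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
hyper_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Binomial upper tail by exhaustive enumeration of all 2^n outcomes.
binom_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  s <- rowSums(outcomes)
  sum(ifelse(s >= k, p^s * (1 - p)^(n - s), 0))
}

# Optimal one-to-one matching by exhaustive enumeration (small sets):
# maximum cardinality, then minimum total distance.
match_oracle <- function(sa, sb, max_dist) {
  na <- length(sa); nb <- length(sb)
  best <- list(card = 0, total = Inf)
  subsets_b <- function(m) if (m == 0) list(integer(0)) else
    unlist(lapply(0:(2^nb - 1), function(mask) {
      s <- which(bitwAnd(mask, 2^(seq_len(nb) - 1)) > 0)
      if (length(s) == m) list(s) else NULL
    }), recursive = FALSE)
  for (m in min(na, nb):0) {
    if (m < best$card) break
    combs_a <- if (m == 0) list(integer(0)) else
      combn(na, m, simplify = FALSE)
    for (ia in combs_a) {
      for (ib in subsets_b(m)) {
        perms <- if (m == 0) list(integer(0)) else perms_of(seq_len(m))
        for (pp in perms) {
          d <- abs(sa[ia] - sb[ib][pp])
          if (all(d <= max_dist)) {
            tot <- sum(d)
            if (m > best$card || (m == best$card && tot < best$total)) {
              best <- list(card = m, total = tot)
            }
          }
        }
      }
    }
    if (best$card == m && m > 0) break
  }
  best
}

perms_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  unlist(lapply(seq_along(x), function(i) {
    lapply(perms_of(x[-i]), function(p) c(x[i], p))
  }), recursive = FALSE)
}

# Small builders -------------------------------------------------------------

toy_profile <- function(v, resolution = 10, bandwidth = 300,
                        name = "toy", state = "control_subtracted") {
  layout <- genome_layout("chrT", length(v) * resolution)
  meiochip:::new_profile(list(chrT = v), layout, resolution, bandwidth,
                         state, name)
}

toy_raw <- function(v, chrom = "chrT") {
  layout <- genome_layout(chrom, length(v))
  meiochip:::new_raw_coverage(stats::setNames(list(as.numeric(v)), chrom),
                              layout)
}

peakset_from_heights <- function(summits, heights, chrom = "chrT",
                                 layout_len = NULL, bandwidth = 300) {
  if (is.null(layout_len)) layout_len <- max(summits) + 1000
  layout <- genome_layout(chrom, layout_len)
  structure(
    data.frame(chrom = chrom, summit = summits, height = heights,
               left_valley = 0, right_valley = 0, prominence = heights,
               passed_q = TRUE, stringsAsFactors = FALSE),
    class = c("PeakSet", "data.frame"),
    resolution = 10, bandwidth = bandwidth, layout = layout,
    sample_name = "synthetic"
  )
}
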