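test_that("oligo grouping follows the <50 bp rule on the worked cases", {
  hs <- group_oligo_hotspots(oligo_table("c1", c(100, 130, 185)), gap = 50)
  # gaps 30 (<50) and 55 (>=50): two hotspots, widths 31 and 1
  expect_equal(nrow(hs), 2L)
  expect_equal(hs$start, c(100, 185))
  expect_equal(hs$end, c(131, 186))
  expect_equal(hs$oligo_count, c(2, 1))

  # chain of positions each 49 bp apart: one hotspot
  chain <- seq(1000, by = 49, length.out = 10)
  hs2 <- group_oligo_hotspots(oligo_table("c1", chain), gap = 50)
  expect_equal(nrow(hs2), 1L)
  expect_equal(hs2$n_oligos, 10L)

  # exactly 50 bp apart: separate
  hs3 <- group_oligo_hotspots(oligo_table("c1", c(0, 50)), gap = 50)
  expect_equal(nrow(hs3), 2L)
})

test_that("grouping equals the union-find oracle on random positions", {
  set.seed(71)
  pos <- sort(sample(0:5000, 200))
  hs <- group_oligo_hotspots(oligo_table("c1", pos, rep(1, 200)), gap = 50)
  clusters <- group_oracle(pos, 50)
  expect_equal(nrow(hs), length(clusters))
  expect_setequal(hs$start, vapply(clusters, min, 0))
  expect_setequal(hs$end, vapply(clusters, max, 0) + 1)
  expect_equal(sum(hs$n_oligos), 200L)
})

test_that("grouping is idempotent and intervals never overlap", {
  set.seed(73)
  for (s in 1:5) {
    pos <- sample(0:3000, 80)
    hs <- group_oligo_hotspots(oligo_table("c1", pos), gap = 50)
    expect_true(all(hs$start[-1] >= hs$end[-nrow(hs)]))
    # regrouping the member extents reproduces the partition
    again <- group_oligo_hotspots(
      oligo_table(hs$chrom, hs$start, hs$oligo_count), gap = 50)
    expect_equal(nrow(again), nrow(hs))
  }
})

test_that("hypergeometric p matches enumeration on all grids with N <= 8", {
  for (N in 2:8) {
    for (n in 1:N) {
      for (K in 0:N) {
        for (k in 0:min(K, n)) {
          p <- hypergeom_overlap_test(k, K, n, N)$p_value
          expect_equal(p, hyper_oracle(k, K, n, N), tolerance = 1e-12,
                       label = sprintf("hyper k=%d K=%d n=%d N=%d", k, K, n, N))
        }
      }
    }
  }
})

test_that("hypergeometric handles the exact corner cases", {
  expect_equal(hypergeom_overlap_test(0, 5, 5, 10)$p_value, 1)
  expect_equal(hypergeom_overlap_test(5, 5, 5, 10)$p_value, 1 / 252,
               tolerance = 1e-12)
  expect_error(hypergeom_overlap_test(6, 5, 5, 10), "inconsistent")
  # non-increasing in k
  ps <- vapply(0:5, function(k) hypergeom_overlap_test(k, 5, 5, 10)$p_value, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("binomial p matches enumeration and the exact small cases", {
  for (n in c(3, 7, 12)) {
    for (p_hot in c(0.1, 0.5, 0.9)) {
      for (k in 0:n) {
        expect_equal(binomial_hotspot_test(k, n, p_hot)$p_value,
                     binom_oracle(k, n, p_hot), tolerance = 1e-12)
      }
    }
  }
  expect_equal(binomial_hotspot_test(0, 10, 0.3)$p_value, 1)
  expect_equal(binomial_hotspot_test(2, 2, 0.5)$p_value, 0.25)
  ps <- vapply(0:10, function(k) binomial_hotspot_test(k, 10, 0.3)$p_value, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(binomial_hotspot_test(3, 10, 1.2), "p_hot")
})

test_that("log-space evaluation stays finite deep in the tail", {
  t1 <- binomial_hotspot_test(5e5, 1e6, 1e-3)
  expect_true(is.finite(t1$log10_p))
  expect_lt(t1$log10_p, -300)  # far below 1e-300
  t2 <- hypergeom_overlap_test(5000, 6000, 6000, 40000)
  expect_true(is.finite(t2$log10_p))
  expect_lt(t2$log10_p, -1000)
})

test_that("relative enrichment is the plain signal/reference ratio", {
  expect_equal(relative_enrichment(0.8, 0.2), 4)
  expect_equal(relative_enrichment(3.7, 3.7), 1)
  set.seed(81)
  s <- runif(20); r <- runif(20, 0.1, 1)
  expect_equal(relative_enrichment(s, r),
               vapply(1:20, function(i) s[i] / r[i], 0))
  expect_error(relative_enrichment(1, 0), "> 0")
})

test_that("hotspot bp fraction and universe size are layout arithmetic", {
  lay <- genome_layout(c("c1", "c2"), c(10000, 5000))
  hs <- structure(
    data.frame(chrom = c("c1", "c2"), start = c(0, 100), end = c(300, 250),
               oligo_count = 1, n_oligos = 1L),
    class = c("HotspotSet", "data.frame"))
  expect_equal(hotspot_bp_fraction(hs, lay), 450 / 15000)
  expect_equal(overlap_universe_size(lay, 300), 50)
})
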