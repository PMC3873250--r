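test_that("layout and hotspot placement is seeded and respects spacing", {
  a <- make_layout_and_hotspots(5)
  b <- make_layout_and_hotspots(5)
  expect_identical(a, b)
  c <- make_layout_and_hotspots(6)
  expect_false(identical(a$hotspots, c$hotspots))

  for (ch in unique(a$hotspots$chrom)) {
    centers <- sort(a$hotspots$center[a$hotspots$chrom == ch])
    if (length(centers) > 1) {
      d <- outer(centers, centers, function(x, y) abs(x - y))
      expect_true(all(d[upper.tri(d)] >= 5000))  # exhaustive pairwise check
    }
  }
  expect_equal(nrow(make_layout_and_hotspots(1, n_hotspots = 0)$hotspots), 0L)
  expect_error(make_layout_and_hotspots(1, chrom_length = 1e4,
                                        n_hotspots = 50, min_spacing = 1000),
               "infeasible")
})

test_that("simulated pairs are seeded, and background depth is calibrated", {
  tr <- synthetic_truth(9, n_chrom = 1, chrom_length = 1e6, n_hotspots = 10,
                        background_rate = 5, multi_map_fraction = 0)
  p1 <- simulate_chip_pair(tr)
  p2 <- simulate_chip_pair(tr)
  expect_identical(p1, p2)

  cov <- accumulate_depth(p1$untagged, tr$layout)
  expect_equal(mean(cov$values[[1]]), 5, tolerance = 0.02)
})

test_that("with no background all tagged mass sits at occupied hotspots", {
  tr <- synthetic_truth(10, background_rate = 1e-9, occupancy = 1,
                        multi_map_fraction = 0)
  pr <- simulate_chip_pair(tr)
  occ <- tr$hotspots[tr$occupied, ]
  near <- vapply(seq_len(nrow(pr$tagged)), function(i) {
    any(occ$chrom == pr$tagged$chrom[i] &
          abs((pr$tagged$start[i] + 25) - occ$center) < 4 * tr$frag_sd + 50)
  }, TRUE)
  expect_true(all(near))
})

test_that("multi-mapping hits conserve per-read weight and avoid hotspots", {
  tr <- synthetic_truth(11, multi_map_fraction = 0.3, decoy_k = 4,
                        occupancy = 0)
  pr <- simulate_chip_pair(tr)
  w <- pr$untagged$weight
  expect_true(all(w %in% c(1, 0.25)))
  # k-fold hits come in groups of k: total weight is an integer read count
  expect_equal(sum(w) %% 1, 0)
  # decoy fraction roughly matches the requested mixture
  expect_equal(sum(w[w < 1]) / sum(w), 0.3, tolerance = 0.05)
})

test_that("paired heights hit the target correlation and are reproducible", {
  hp <- simulate_paired_peak_heights(1000, 0.999, 1)
  expect_gt(cor(hp$a, hp$b), 0.99)
  expect_identical(simulate_paired_peak_heights(500, 0.5, 3),
                   simulate_paired_peak_heights(500, 0.5, 3))
  near0 <- vapply(1:20, function(s) {
    abs(cor(with(simulate_paired_peak_heights(1000, 0, s), cbind(a, b)))[1, 2])
  }, 0)
  expect_true(all(near0 <= 0.1))
})

test_that("oligo tables are seeded and grouping recovers planted hotspots", {
  gh <- make_layout_and_hotspots(12, n_hotspots = 30, min_spacing = 5000)
  o1 <- simulate_oligo_table(gh$hotspots, gh$layout, spread_bp = 20, seed = 2)
  o2 <- simulate_oligo_table(gh$hotspots, gh$layout, spread_bp = 20, seed = 2)
  expect_identical(o1, o2)
  hs <- group_oligo_hotspots(o1, gap = 50)
  expect_equal(nrow(hs), 30L)   # planted-partition recovery

  o0 <- simulate_oligo_table(gh$hotspots, gh$layout, spread_bp = 0, seed = 3)
  expect_setequal(unique(o0$pos), gh$hotspots$center)
  expect_equal(nrow(group_oligo_hotspots(o0, gap = 50)), 30L)
})

test_that("NCIS recovers r_true on fully simulated read pairs", {
  errs <- vapply(1:20, function(s) {
    tr <- synthetic_truth(s, n_hotspots = 12, r_true = 0.7)
    pr <- simulate_chip_pair(tr)
    chip <- accumulate_depth(pr$tagged, tr$layout)
    ctrl <- accumulate_depth(pr$untagged, tr$layout)
    abs(estimate_ncis_factor(chip, ctrl)$r - 0.7) / 0.7
  }, 0)
  expect_lt(median(errs), 0.10)
})

test_that("truth JSON round-trips through write/read", {
  tr <- synthetic_truth(13)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth_json(tr, f)
  back <- read_truth_json(f)
  expect_equal(back$layout, tr$layout)
  expect_equal(back$occupied, tr$occupied)
  expect_equal(back$heights, tr$heights)
  expect_equal(back$r_true, tr$r_true)
})
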