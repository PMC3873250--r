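test_that("simple maxima, ramps and merged twins follow the valley rule", {
  # single bump
  pk <- call_peaks(toy_profile(c(0, 1, 0)), peak_call_params(0.5, 0))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$summit, 10)
  expect_equal(pk$height, 1)

  # strictly monotone ramp: no flanked maximum
  expect_equal(nrow(call_peaks(toy_profile(1:50 / 10), peak_call_params(0, 0))),
               0L)

  # twin maxima with a shallow separating valley merge into the higher one
  v <- c(0, 5, 4, 4.7, 0)
  pk2 <- call_peaks(toy_profile(v), peak_call_params(1, 0))
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$height, 5)
  orc <- prominence_oracle(v)
  expect_equal(orc$prom[orc$height == 4.7], 0.7)   # below the depth cut
})

test_that("candidate prominences equal the exhaustive oracle on random signals", {
  set.seed(21)
  for (rep in 1:5) {
    v <- round(cumsum(rnorm(120)), 2)
    pk <- call_peaks(toy_profile(v), peak_call_params(0, 0))
    orc <- prominence_oracle(v)
    if (is.null(orc)) {
      expect_equal(nrow(pk), 0L)
    } else {
      expect_equal(pk$summit, (orc$idx - 1) * 10)
      expect_equal(pk$height, orc$height)
      expect_equal(pk$prominence, orc$prom)
    }
  }
})

test_that("the Q filter cuts at the linear-interpolation height quantile", {
  # 10 isolated candidates with heights 1..10
  v <- as.numeric(rbind(0, 1:10, 0))
  pk <- call_peaks(toy_profile(v), peak_call_params(0, 0.7))
  # type-7 quantile of 1..10 at 0.7 is 7.3 -> heights 8, 9, 10 survive
  expect_equal(sort(pk$height), c(8, 9, 10))
  all_pk <- call_peaks(toy_profile(v), peak_call_params(0, 0.7),
                       keep_all = TRUE)
  expect_equal(nrow(all_pk), 10L)
  expect_equal(sum(all_pk$passed_q), 3L)
})

test_that("peak calling is shift-invariant and scale-equivariant", {
  set.seed(31)
  v <- pmax(0, cumsum(rnorm(200, sd = 0.5)))
  p0 <- call_peaks(toy_profile(v), peak_call_params(0.4, 0.5))
  p_shift <- call_peaks(toy_profile(v + 11), peak_call_params(0.4, 0.5))
  expect_equal(p_shift$summit, p0$summit)
  expect_equal(p_shift$height, p0$height + 11)
  p_scaled <- call_peaks(toy_profile(3 * v), peak_call_params(3 * 0.4, 0.5))
  expect_equal(p_scaled$summit, p0$summit)
  expect_equal(p_scaled$prominence, 3 * p0$prominence)
})

test_that("plateau summits take the leftmost grid position", {
  v <- c(0, 2, 2, 2, 0)
  pk <- call_peaks(toy_profile(v), peak_call_params(0, 0))
  expect_equal(pk$summit, 10)
})

test_that("matching is one-to-one, bandwidth-bounded and symmetric", {
  a <- peakset_from_heights(c(1000, 5000, 9000), c(5, 7, 9),
                            layout_len = 20000)
  mt <- match_peaks(a, a, 300)
  expect_equal(nrow(mt$pairs), 3L)
  expect_true(all(mt$pairs$distance == 0))

  b <- peakset_from_heights(c(1600), c(4), layout_len = 20000)
  # 600 bp apart with max_dist 500: no pair
  mt2 <- match_peaks(a, b, 500)
  expect_equal(nrow(mt2$pairs), 0L)
  expect_equal(mt2$unmatched_b, 1L)

  set.seed(41)
  sa <- sort(sample(0:10000, 6)); sb <- sort(sample(0:10000, 5))
  A <- peakset_from_heights(sa, runif(6), layout_len = 20000)
  B <- peakset_from_heights(sb, runif(5), layout_len = 20000)
  ab <- match_peaks(A, B, 800)
  ba <- match_peaks(B, A, 800)
  expect_equal(nrow(ab$pairs), nrow(ba$pairs))
  expect_setequal(ab$pairs$distance, ba$pairs$distance)
  expect_lte(nrow(ab$pairs), min(nrow(A), nrow(B)))
  expect_true(all(ab$pairs$distance <= 800))
})

test_that("greedy matching attains the exhaustive optimum on small sets", {
  set.seed(51)
  for (rep in 1:8) {
    sa <- sort(sample(0:3000, sample(2:5, 1)))
    sb <- sort(sample(0:3000, sample(2:5, 1)))
    A <- peakset_from_heights(sa, seq_along(sa), layout_len = 5000)
    B <- peakset_from_heights(sb, seq_along(sb), layout_len = 5000)
    mt <- match_peaks(A, B, 400)
    best <- match_oracle(sa, sb, 400)
    # greedy nearest-first is the contract: it can concede at most one pair
    # of cardinality to the optimal matching on these set sizes (it does on
    # some chained configurations), and every pair respects the bound
    expect_lte(nrow(mt$pairs), best$card)
    expect_gte(nrow(mt$pairs), best$card - 1L)
    expect_true(all(mt$pairs$distance <= 400))
    if (nrow(mt$pairs) == best$card) {
      expect_gte(sum(mt$pairs$distance), best$total - 1e-9)
    }
  }
})

test_that("correlation matrix is symmetric with unit diagonal and exact poles", {
  a <- peakset_from_heights(seq(0, 9900, by = 100), 1:100,
                            layout_len = 20000)
  cm <- correlation_matrix(list(x = a, y = a), 300)
  expect_equal(cm$rho["x", "y"], 1)
  b <- a; b$height <- -b$height + 101
  cm2 <- correlation_matrix(list(x = a, y = b), 300)
  expect_equal(cm2$rho["x", "y"], -1)
  expect_equal(cm2$rho, t(cm2$rho))
  expect_equal(diag(cm2$rho), c(x = 1, y = 1))
  # fewer than 3 matched pairs: undefined
  tiny <- peakset_from_heights(c(0, 100), c(1, 2), layout_len = 20000)
  cm3 <- correlation_matrix(list(x = tiny, y = tiny), 10)
  expect_true(is.na(cm3$rho["x", "y"]) || cm3$n_pairs["x", "y"] >= 3)
  expect_equal(cm3$n_pairs["x", "y"], 2L)
})

test_that("correlated paired heights are recovered by the matrix machinery", {
  n <- 1000
  ci <- tanh(atanh(0.8) + c(-1, 1) * 1.96 / sqrt(n - 3))
  inside <- vapply(1:20, function(s) {
    hp <- simulate_paired_peak_heights(n, 0.8, s)
    pos <- seq(0, by = 1000, length.out = n)
    A <- peakset_from_heights(pos, hp$a, layout_len = 1e6 + 1000)
    B <- peakset_from_heights(pos, hp$b, layout_len = 1e6 + 1000)
    r <- correlation_matrix(list(a = A, b = B), 300)$rho["a", "b"]
    r >= ci[1] && r <= ci[2]
  }, TRUE)
  expect_gte(sum(inside), 18)
})

test_that("summit-in-interval uses half-open containment", {
  hs <- structure(
    data.frame(chrom = "chrT", start = c(100, 300), end = c(200, 320),
               oligo_count = c(5, 2), n_oligos = c(2L, 1L)),
    class = c("HotspotSet", "data.frame"))
  pk <- peakset_from_heights(c(100, 199, 200, 319, 320), rep(1, 5),
                             layout_len = 1000)
  asg <- assign_peaks_to_intervals(pk, hs)
  # start inclusive, end exclusive
  expect_equal(asg$flags, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(asg$n_peaks_in, 3L)
  expect_equal(asg$n_hotspots_hit, 2L)
})

test_that("interval assignment counts match a double loop on random cases", {
  set.seed(61)
  starts <- sort(sample(seq(0, 19000, by = 100), 20))
  hs <- structure(
    data.frame(chrom = "chrT", start = starts, end = starts + 60,
               oligo_count = 1, n_oligos = 1L),
    class = c("HotspotSet", "data.frame"))
  pk <- peakset_from_heights(sample(0:19999, 50), runif(50),
                             layout_len = 20000)
  asg <- assign_peaks_to_intervals(pk, hs)
  flags_bf <- vapply(seq_len(nrow(pk)), function(i) {
    any(hs$start <= pk$summit[i] & pk$summit[i] < hs$end)
  }, TRUE)
  hits_bf <- vapply(seq_len(nrow(hs)), function(j) {
    sum(hs$start[j] <= pk$summit & pk$summit < hs$end[j])
  }, 0)
  expect_equal(asg$flags, flags_bf)
  expect_equal(asg$interval_hits, as.integer(hits_bf))
})
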