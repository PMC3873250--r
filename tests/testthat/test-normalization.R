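make_bg_pair <- function(seed, r_true, L = 100000, rate = 2,
                         signal_bins = 2, signal_rate = 30) {
  # control: Poisson background; chip: r_true-scaled background plus
  # localized signal confined to `signal_bins` kb-bins (2% of the genome
  # at the defaults)
  set.seed(seed)
  ctrl <- rpois(L, rate) + 0
  chip <- rpois(L, r_true * rate) + 0
  centers <- seq(10000, L - 10000, length.out = signal_bins)
  for (c0 in centers) {
    idx <- (c0 - 400):(c0 + 400)
    chip[idx] <- chip[idx] + rpois(length(idx), signal_rate)
  }
  list(chip = toy_raw(chip), ctrl = toy_raw(ctrl))
}

test_that("NCIS recovers the exact ratio for a pure-background pair", {
  set.seed(1)
  ctrl <- rpois(50000, 3) + 0
  chip <- 2 * ctrl
  nf <- estimate_ncis_factor(toy_raw(chip), toy_raw(ctrl), 1000)
  expect_s3_class(nf, "NormFactor")
  expect_equal(nf$r, 2, tolerance = 1e-6)
})

test_that("NCIS recovers r_true within 10% median error on mixtures", {
  errs <- vapply(1:20, function(s) {
    pr <- make_bg_pair(s, r_true = 0.7)
    abs(estimate_ncis_factor(pr$chip, pr$ctrl, 1000)$r - 0.7) / 0.7
  }, 0)
  expect_lt(median(errs), 0.10)
})

test_that("NCIS is invariant to common rescaling and rejects bad input", {
  pr <- make_bg_pair(42, r_true = 1.2)
  r1 <- estimate_ncis_factor(pr$chip, pr$ctrl, 1000)$r
  chip5 <- pr$chip; chip5$values$chrT <- 5 * chip5$values$chrT
  ctrl5 <- pr$ctrl; ctrl5$values$chrT <- 5 * ctrl5$values$chrT
  r2 <- estimate_ncis_factor(chip5, ctrl5, 1000)$r
  expect_equal(r1, r2, tolerance = 1e-12)

  zero <- toy_raw(numeric(100000))
  expect_error(estimate_ncis_factor(pr$chip, zero, 1000), "zero total")
  other <- toy_raw(rep(1, 100000), chrom = "c9")
  expect_error(estimate_ncis_factor(pr$chip, other, 1000), "layout")
})

test_that("control subtraction clamps at zero and matches a direct loop", {
  set.seed(9)
  a <- runif(120, 0, 6); b <- runif(120, 0, 4)
  chip <- toy_profile(a); ctrl <- toy_profile(b)
  out <- subtract_control(chip, ctrl, 1.5)
  expected <- vapply(seq_along(a), function(i) max(0, a[i] - 1.5 * b[i]), 0)
  expect_equal(out$values$chrT, expected)
  expect_true(all(out$values$chrT >= 0))
  expect_true(all(out$values$chrT <= a))
  expect_equal(out$normalization_state, "control_subtracted")

  # chip == r * control -> identically zero
  ctrl2 <- toy_profile(a / 1.5)
  expect_equal(subtract_control(chip, ctrl2, 1.5)$values$chrT,
               numeric(120))
  # single-bin arithmetic: 5 - 1.5 * 2 = 2
  expect_equal(subtract_control(toy_profile(5), toy_profile(2), 1.5)$values$chrT,
               2)
})

test_that("subtraction rejects mismatched resolution or bandwidth", {
  a <- toy_profile(1:10, resolution = 10)
  b <- toy_profile(1:10, resolution = 20)
  expect_error(subtract_control(a, b, 1), "resolution")
  d <- toy_profile(1:10, bandwidth = 500)
  expect_error(subtract_control(a, d, 1), "bandwidth")
  e <- toy_raw(rep(1, 50), chrom = "other")
  f <- smooth_profile(e, 300, 10)
  expect_error(subtract_control(a, f, 1), "layout")
})

test_that("decile normalization is definitional and scale-invariant", {
  set.seed(13)
  v <- c(numeric(20), runif(100, 0.1, 9))
  p <- toy_profile(v)
  out <- decile_normalize(p, 9)
  pos <- out$values$chrT[out$values$chrT > 0]
  expect_equal(quantile(pos, 0.9, type = 7, names = FALSE), 1)
  # sort-based oracle for the divisor: positive bins 1..100, 9th decile
  q <- toy_profile(c(0, 1:100))
  sorted <- sort(1:100)
  d_oracle <- sorted[90] + 0.1 * (sorted[91] - sorted[90])  # type-7 at 0.9
  expect_equal(decile_normalize(q, 9)$values$chrT,
               c(0, 1:100) / d_oracle)
  # scale invariance
  p7 <- toy_profile(7 * v)
  expect_equal(decile_normalize(p7, 9)$values$chrT,
               decile_normalize(p, 9)$values$chrT, tolerance = 1e-12)
  expect_error(decile_normalize(toy_profile(numeric(10))), "positive")
})
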