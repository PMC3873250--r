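# Control-based normalization: NCIS background-fraction estimation,
# scaled control subtraction, and decile rescaling for display.

#' Estimate the ChIP/control background scaling factor (NCIS)
#'
#' Implements the NCIS estimator of the background fraction: the genome is
#' tiled into `bin_size` bins, bins are ordered by increasing total count
#' (ChIP + control), and the cumulative ratio sum(ChIP)/sum(control) is
#' tracked along that ordering. Low-total bins are background-dominated, so
#' the ratio is flat at the background scaling while background bins
#' accumulate and starts to rise once signal bins enter. `r` is the ratio at
#' the first point where it starts increasing after at least half of all
#' bins have been included; if it never rises (a pure-background pair), the
#' ratio over all bins is returned. `r` scales the control to the ChIP
#' background level.
#'
#' Estimation runs on raw (unsmoothed) counts: smoothing correlates
#' neighboring bins and would blur the background/signal ordering.
#'
#' @param chip,control `RawCoverage` objects on the same layout.
#' @param bin_size Bin width in bp (default 1000).
#' @return A `NormFactor`: list with `r` (positive scaling of control to
#'   ChIP background), `bin_size`, and `n_background_bins` (bins counted as
#'   background when the rule fired).
#' @export
estimate_ncis_factor <- function(chip, control, bin_size = 1000) {
  stopifnot(inherits(chip, "RawCoverage"), inherits(control, "RawCoverage"))
  check_same_layout(chip$layout, control$layout)
  chip_b <- bin_coverage(chip, bin_size)
  ctrl_b <- bin_coverage(control, bin_size)
  if (sum(ctrl_b) == 0) stop("control sample has zero total count", call. = FALSE)
  ord <- order(chip_b + ctrl_b, seq_along(chip_b))
  cum_chip <- cumsum(chip_b[ord])
  cum_ctrl <- cumsum(ctrl_b[ord])
  ratio <- ifelse(cum_ctrl > 0, cum_chip / cum_ctrl, NA_real_)
  n <- length(ratio)
  j0 <- max(ceiling(n / 2), 1L)
  j_stop <- n
  for (j in j0:max(j0, n - 1L)) {
    if (j >= n) break
    if (!is.na(ratio[j]) && !is.na(ratio[j + 1]) &&
        ratio[j + 1] > ratio[j] * (1 + 1e-12)) {
      j_stop <- j
      break
    }
  }
  r <- ratio[j_stop]
  if (is.na(r) || r <= 0) {
    stop("NCIS factor undefined: no control counts in the background bins",
         call. = FALSE)
  }
  structure(list(r = r, bin_size = bin_size, n_background_bins = j_stop),
            class = "NormFactor")
}

#' @export
print.NormFactor <- function(x, ...) {
  cat(sprintf("NormFactor: r = %.6g (bin %d bp, %d background bins)\n",
              x$r, x$bin_size, x$n_background_bins))
  invisible(x)
}

#' Subtract the scaled control from a ChIP profile
#'
#' `out = max(0, chip - r * control)` per bin. Negative residuals are
#' clamped to zero: subtracted profiles are treated as signal tracks, and
#' peaks are defined on nonnegative signal.
#'
#' @param chip,control `Profile` objects on the same layout, resolution and
#'   bandwidth.
#' @param factor A `NormFactor` from [estimate_ncis_factor()], or a bare
#'   positive number.
#' @return A `Profile` with `normalization_state = "control_subtracted"`.
#' @export
subtract_control <- function(chip, control, factor) {
  stopifnot(inherits(chip, "Profile"), inherits(control, "Profile"))
  if (chip$resolution != control$resolution) {
    stop("profile resolutions differ", call. = FALSE)
  }
  if (!isTRUE(all.equal(chip$bandwidth, control$bandwidth))) {
    stop("profile bandwidths differ", call. = FALSE)
  }
  check_same_layout(chip$layout, control$layout)
  r <- if (inherits(factor, "NormFactor")) factor$r else as.numeric(factor)
  if (!is.finite(r) || r <= 0) stop("scaling factor must be > 0", call. = FALSE)
  values <- Map(function(a, b) pmax(0, a - r * b), chip$values, control$values)
  out <- new_profile(values, chip$layout, chip$resolution, chip$bandwidth,
                     normalization_state = "control_subtracted",
                     sample_name = chip$sample_name)
  out
}

#' Rescale a profile by one of its deciles
#'
#' Divides the whole profile by the value of its `decile_index`-th decile
#' computed over positive bins only (linear-interpolation quantile), so that
#' decile of the output equals 1. The 9th decile is the default: a robust
#' high quantile that puts profiles from different samples on a comparable
#' display scale without letting a single summit dominate.
#'
#' @param profile A `Profile` with at least one positive bin.
#' @param decile_index Integer 1..9 (default 9).
#' @return The rescaled `Profile`, `normalization_state = "decile_normalized"`.
#' @export
decile_normalize <- function(profile, decile_index = 9) {
  stopifnot(inherits(profile, "Profile"))
  if (!decile_index %in% 1:9) stop("decile_index must be in 1..9", call. = FALSE)
  pos <- unlist(profile$values, use.names = FALSE)
  pos <- pos[pos > 0]
  if (length(pos) == 0L) stop("profile has no positive bins", call. = FALSE)
  d <- stats::quantile(pos, decile_index / 10, type = 7, names = FALSE)
  if (d <= 0) stop("chosen decile is not positive", call. = FALSE)
  values <- lapply(profile$values, function(v) v / d)
  new_profile(values, profile$layout, profile$resolution, profile$bandwidth,
              normalization_state = "decile_normalized",
              sample_name = profile$sample_name)
}
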