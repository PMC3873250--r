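# Weighted coverage accumulation and kernel smoothing.

new_raw_coverage <- function(values, layout) {
  structure(list(values = values, layout = layout), class = "RawCoverage")
}

new_profile <- function(values, layout, resolution, bandwidth,
                        normalization_state, sample_name = NA_character_) {
  structure(
    list(values = values, layout = layout, resolution = resolution,
         bandwidth = bandwidth, normalization_state = normalization_state,
         sample_name = sample_name),
    class = "Profile"
  )
}

#' @export
print.RawCoverage <- function(x, ...) {
  cat("RawCoverage over", nrow(x$layout), "chromosomes; total mass",
      format(sum(vapply(x$values, sum, 0)), digits = 6), "\n")
  invisible(x)
}

#' @export
print.Profile <- function(x, ...) {
  cat(sprintf("Profile '%s': resolution %d bp, bandwidth %s, state %s\n",
              x$sample_name, x$resolution,
              ifelse(is.na(x$bandwidth), "none", paste0(x$bandwidth, " bp")),
              x$normalization_state))
  invisible(x)
}

#' Accumulate weighted read depth at 1 bp resolution
#'
#' Every hit adds its weight to every base it covers; both strands are
#' pooled and uncovered positions are explicit zeros. Position `p`
#' (0-based) of chromosome `ch` ends up holding the sum of weights of all
#' hits whose half-open interval contains `p`.
#'
#' @param hits Weighted-hit data.frame from [read_hits()] (columns `chrom`,
#'   `start`, `end`, `weight`).
#' @param layout `GenomeLayout`.
#' @return A `RawCoverage`: one dense numeric vector per chromosome, with
#'   `values[[ch]][p + 1]` the depth at 0-based position `p`.
#' @export
accumulate_depth <- function(hits, layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  unknown <- setdiff(unique(hits$chrom), layout$chrom)
  if (length(unknown)) {
    stop("hit on unknown chromosome: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  values <- lapply(seq_len(nrow(layout)), function(i) {
    L <- layout$length[i]
    sel <- hits$chrom == layout$chrom[i]
    if (!any(sel)) return(numeric(L))
    s <- hits$start[sel]; e <- hits$end[sel]; w <- hits$weight[sel]
    if (any(s < 0) || any(e > L)) {
      stop("hit beyond chromosome end on ", layout$chrom[i], call. = FALSE)
    }
    # difference-array trick: +w at start, -w after end, then cumsum
    delta <- numeric(L + 1)
    add <- rowsum(c(w, -w), c(s + 1, e + 1))
    delta[as.numeric(rownames(add))] <- add[, 1]
    cumsum(delta)[seq_len(L)]
  })
  names(values) <- layout$chrom
  new_raw_coverage(values, layout)
}

# Gaussian kernel weights under the quartile bandwidth convention:
# quartiles of the kernel sit at +/- 0.25 * bandwidth, i.e.
# sigma = 0.25 * bandwidth / qnorm(0.75); support truncated at 4 sigma
# (mass beyond the cut < 1e-4).
kernel_weights <- function(bandwidth) {
  sigma <- 0.25 * bandwidth / stats::qnorm(0.75)
  W <- ceiling(4 * sigma)
  list(w = stats::dnorm(seq(-W, W), sd = sigma), half = W)
}

# Linear convolution via zero-padded FFT; padding to a 2-3-5-smooth length
# keeps the transform fast for any chromosome length.
conv_open <- function(x, k) {
  n <- length(x); m <- length(k)
  L <- stats::nextn(n + m - 1, c(2L, 3L, 5L))
  fx <- stats::fft(c(x, numeric(L - n)))
  fk <- stats::fft(c(k, numeric(L - m)))
  Re(stats::fft(fx * fk, inverse = TRUE))[seq_len(n + m - 1)] / L
}

nw_smooth_chrom <- function(x, kern, resolution) {
  n <- length(x)
  W <- kern$half
  # numerator and normalizing denominator via FFT convolution; the
  # denominator renormalizes over available positions at chromosome ends
  num <- conv_open(x, kern$w)[(W + 1):(W + n)]
  den <- conv_open(rep(1, n), kern$w)[(W + 1):(W + n)]
  grid <- seq(1, n, by = resolution)   # 0-based positions 0, res, 2*res, ...
  num[grid] / den[grid]
}

#' Smooth raw coverage into a fixed-resolution profile
#'
#' Nadaraya-Watson kernel regression of the 1 bp depth vector, evaluated at
#' every `resolution`-th position. The Gaussian kernel is scaled so its
#' quartiles sit at plus/minus a quarter of `bandwidth` (the `ksmooth`
#' bandwidth convention), and is truncated at 4 standard deviations. Kernel
#' weights renormalize over available positions at chromosome ends.
#'
#' @param raw A `RawCoverage` from [accumulate_depth()].
#' @param bandwidth Smoothing bandwidth in bp (> 0); the source profiles use
#'   250, 300 or 500 bp.
#' @param resolution Output sampling interval in bp (default 10).
#' @param sample_name Optional label carried in the result.
#' @return A `Profile` with `ceiling(L / resolution)` values per chromosome,
#'   value `i` being the estimate at position `(i - 1) * resolution`.
#' @export
smooth_profile <- function(raw, bandwidth, resolution = 10,
                           sample_name = NA_character_) {
  stopifnot(inherits(raw, "RawCoverage"))
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  if (any(vapply(raw$values, length, 1L) == 0L)) {
    stop("empty chromosome", call. = FALSE)
  }
  kern <- kernel_weights(bandwidth)
  values <- lapply(raw$values, nw_smooth_chrom, kern = kern,
                   resolution = resolution)
  new_profile(values, raw$layout, resolution, bandwidth,
              normalization_state = "raw", sample_name = sample_name)
}

#' Bin raw coverage without smoothing
#'
#' Sums the 1 bp depth within consecutive `bin_size` windows (the last bin
#' of a chromosome may be shorter). Used by the NCIS estimator, which works
#' on unsmoothed counts.
#'
#' @param raw A `RawCoverage`.
#' @param bin_size Bin width in bp.
#' @return Numeric vector of per-bin sums, concatenated over chromosomes in
#'   layout order.
#' @export
bin_coverage <- function(raw, bin_size) {
  stopifnot(inherits(raw, "RawCoverage"), bin_size >= 1)
  unlist(lapply(raw$values, function(v) {
    idx <- (seq_along(v) - 1) %/% bin_size
    as.numeric(rowsum(v, idx))
  }), use.names = FALSE)
}
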