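# Valley-flanked peak calling, cross-profile peak matching, and
# peak-height correlation.

#' Peak-calling parameters
#'
#' `min_valley_depth` is the minimum drop required on both sides of a
#' summit, formalized as topographic prominence (the drop to the higher of
#' the two flanking valleys, where a valley extends until the signal first
#' exceeds the summit again). `q_threshold` keeps only candidate peaks whose
#' height reaches that quantile of all candidate heights
#' (linear-interpolation quantile); the stringency knob used for
#' cross-profile comparisons, default Q = 0.7.
#'
#' @param min_valley_depth Required prominence, >= 0 (default 0).
#' @param q_threshold Height-quantile cut in `[0, 1]` (default 0.7; 0
#'   disables the filter).
#' @return A `PeakCallParams` list.
#' @export
peak_call_params <- function(min_valley_depth = 0, q_threshold = 0.7) {
  if (min_valley_depth < 0) stop("min_valley_depth must be >= 0", call. = FALSE)
  if (q_threshold < 0 || q_threshold > 1) {
    stop("q_threshold must be in [0, 1]", call. = FALSE)
  }
  structure(list(min_valley_depth = min_valley_depth,
                 q_threshold = q_threshold),
            class = "PeakCallParams")
}

# Local maxima (plateau-aware) of one numeric vector with flanking-valley
# scans. Returns candidate peaks: summit grid index (leftmost plateau
# position), height, left/right valley depths, prominence. Chromosome
# boundary positions are never summits: a peak must be flanked by a drop on
# both sides within the chromosome.
find_candidate_peaks <- function(v) {
  n <- length(v)
  if (n < 3L) {
    return(data.frame(idx = integer(), height = numeric(),
                      left_valley = numeric(), right_valley = numeric(),
                      prominence = numeric()))
  }
  r <- rle(v)
  k <- length(r$values)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  is_max <- logical(k)
  if (k >= 3L) {
    mid <- 2:(k - 1L)
    is_max[mid] <- r$values[mid] > r$values[mid - 1L] &
      r$values[mid] > r$values[mid + 1L]
  }
  cand <- which(is_max)
  if (!length(cand)) {
    return(data.frame(idx = integer(), height = numeric(),
                      left_valley = numeric(), right_valley = numeric(),
                      prominence = numeric()))
  }
  out <- lapply(cand, function(j) {
    h <- r$values[j]
    # left valley: minimum between the summit and the first strictly higher
    # value to the left (or the chromosome start)
    lv <- Inf
    i <- run_start[j] - 1L
    while (i >= 1L && v[i] <= h) {
      if (v[i] < lv) lv <- v[i]
      i <- i - 1L
    }
    rv <- Inf
    i <- run_end[j] + 1L
    while (i <= n && v[i] <= h) {
      if (v[i] < rv) rv <- v[i]
      i <- i + 1L
    }
    c(idx = run_start[j], height = h, left_valley = lv, right_valley = rv)
  })
  out <- as.data.frame(do.call(rbind, out))
  out$prominence <- out$height - pmax(out$left_valley, out$right_valley)
  out
}

#' Call peaks on a normalized profile
#'
#' Emits local maxima of the binned signal that are flanked on both sides by
#' valleys of at least `min_valley_depth` (topographic prominence), then
#' keeps those whose height reaches the `q_threshold` quantile of candidate
#' heights. Summits are reported on the profile grid in bp; plateau summits
#' take the leftmost grid position of the plateau.
#'
#' @param profile A `Profile`.
#' @param params A [peak_call_params()].
#' @param keep_all If `TRUE`, all prominence-passing candidates are returned
#'   with a `passed_q` flag; otherwise only peaks passing the quantile cut.
#' @return A `PeakSet`: data.frame with columns `chrom`, `summit` (bp),
#'   `height`, `left_valley`, `right_valley`, `prominence`, `passed_q`, and
#'   attributes `resolution`, `bandwidth`, `layout`, `sample_name`.
#' @export
call_peaks <- function(profile, params = peak_call_params(),
                       keep_all = FALSE) {
  stopifnot(inherits(profile, "Profile"), inherits(params, "PeakCallParams"))
  res <- profile$resolution
  per_chrom <- lapply(names(profile$values), function(ch) {
    cand <- find_candidate_peaks(profile$values[[ch]])
    if (nrow(cand)) cand$chrom <- ch
    cand
  })
  cand <- do.call(rbind, per_chrom[vapply(per_chrom, nrow, 1L) > 0])
  if (is.null(cand) || nrow(cand) == 0L) {
    return(empty_peakset(profile))
  }
  cand <- cand[cand$prominence >= params$min_valley_depth & cand$prominence > 0, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(empty_peakset(profile))
  if (params$q_threshold > 0) {
    cut <- stats::quantile(cand$height, params$q_threshold, type = 7,
                           names = FALSE)
    cand$passed_q <- cand$height >= cut
  } else {
    cand$passed_q <- TRUE
  }
  if (!keep_all) cand <- cand[cand$passed_q, , drop = FALSE]
  out <- data.frame(
    chrom = cand$chrom,
    summit = (cand$idx - 1) * res,
    height = cand$height,
    left_valley = cand$left_valley,
    right_valley = cand$right_valley,
    prominence = cand$prominence,
    passed_q = cand$passed_q,
    stringsAsFactors = FALSE
  )
  out <- out[order(match(out$chrom, profile$layout$chrom), out$summit), ]
  rownames(out) <- NULL
  structure(out, class = c("PeakSet", "data.frame"),
            resolution = res, bandwidth = profile$bandwidth,
            layout = profile$layout, sample_name = profile$sample_name)
}

empty_peakset <- function(profile) {
  structure(
    data.frame(chrom = character(), summit = numeric(), height = numeric(),
               left_valley = numeric(), right_valley = numeric(),
               prominence = numeric(), passed_q = logical()),
    class = c("PeakSet", "data.frame"),
    resolution = profile$resolution, bandwidth = profile$bandwidth,
    layout = profile$layout, sample_name = profile$sample_name
  )
}

#' Match peaks one-to-one across two profiles
#'
#' Candidate pairs are peaks on the same chromosome whose summits lie within
#' `max_dist` bp of each other; pairs are sorted by distance (ties broken
#' leftmost-first) and matched greedily nearest-first, each peak used at
#' most once. The conventional `max_dist` is the smoothing bandwidth.
#'
#' @param a,b `PeakSet` objects on the same layout.
#' @param max_dist Maximal summit distance in bp; defaults to the sets'
#'   smoothing bandwidth.
#' @return A `MatchTable`: list with `pairs` (data.frame `chrom`,
#'   `summit_a`, `summit_b`, `height_a`, `height_b`, `distance`),
#'   `unmatched_a`, `unmatched_b` (row indices into `a` and `b`), and
#'   `max_dist`.
#' @export
match_peaks <- function(a, b, max_dist = NULL) {
  stopifnot(inherits(a, "PeakSet"), inherits(b, "PeakSet"))
  la <- attr(a, "layout"); lb <- attr(b, "layout")
  if (!is.null(la) && !is.null(lb)) check_same_layout(la, lb)
  if (is.null(max_dist)) {
    max_dist <- attr(a, "bandwidth")
    if (is.null(max_dist) || is.na(max_dist)) {
      stop("max_dist not given and peak set carries no bandwidth",
           call. = FALSE)
    }
  }
  cand <- NULL
  for (ch in unique(c(a$chrom, b$chrom))) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    if (!length(ia) || !length(ib)) next
    d <- abs(outer(a$summit[ia], b$summit[ib], "-"))
    ok <- which(d <= max_dist, arr.ind = TRUE)
    if (nrow(ok)) {
      cand <- rbind(cand, data.frame(
        i = ia[ok[, 1]], j = ib[ok[, 2]],
        distance = d[ok], stringsAsFactors = FALSE))
    }
  }
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  pairs_idx <- NULL
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$distance, a$summit[cand$i], b$summit[cand$j]), ]
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        pairs_idx <- rbind(pairs_idx, cand[k, ])
      }
    }
  }
  pairs <- if (is.null(pairs_idx)) {
    data.frame(chrom = character(), summit_a = numeric(), summit_b = numeric(),
               height_a = numeric(), height_b = numeric(), distance = numeric())
  } else {
    data.frame(
      chrom = a$chrom[pairs_idx$i],
      summit_a = a$summit[pairs_idx$i], summit_b = b$summit[pairs_idx$j],
      height_a = a$height[pairs_idx$i], height_b = b$height[pairs_idx$j],
      distance = pairs_idx$distance, stringsAsFactors = FALSE
    )
  }
  ord <- order(match(pairs$chrom, unique(c(a$chrom, b$chrom))), pairs$summit_a)
  pairs <- pairs[ord, ]
  rownames(pairs) <- NULL
  structure(
    list(pairs = pairs, unmatched_a = which(!used_a),
         unmatched_b = which(!used_b), max_dist = max_dist),
    class = "MatchTable"
  )
}

#' @export
print.MatchTable <- function(x, ...) {
  cat(sprintf("MatchTable: %d pairs (max_dist %g bp), %d/%d unmatched\n",
              nrow(x$pairs), x$max_dist, length(x$unmatched_a),
              length(x$unmatched_b)))
  invisible(x)
}

#' Pairwise Pearson correlation of matched peak heights
#'
#' For every pair of peak sets, peaks are matched within `max_dist` and the
#' Pearson correlation of the matched heights is computed. Cells with fewer
#' than 3 matched pairs are left `NA` (undefined).
#'
#' @param sets Named list of `PeakSet` objects (>= 2).
#' @param max_dist Maximal matching distance in bp (default: the sets'
#'   bandwidth).
#' @return A `CorrelationMatrix`: list with `rho` (symmetric matrix, unit
#'   diagonal) and `n_pairs` (matched-peak counts per cell).
#' @export
correlation_matrix <- function(sets, max_dist = NULL) {
  stopifnot(is.list(sets), length(sets) >= 2)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("sample", seq_along(sets))
  }
  m <- length(sets)
  rho <- diag(1, m)
  np <- matrix(NA_integer_, m, m)
  dimnames(rho) <- dimnames(np) <- list(names(sets), names(sets))
  diag(np) <- vapply(sets, nrow, 1L)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      mt <- match_peaks(sets[[i]], sets[[j]], max_dist)
      np[i, j] <- np[j, i] <- nrow(mt$pairs)
      rho[i, j] <- rho[j, i] <- if (nrow(mt$pairs) >= 3) {
        stats::cor(mt$pairs$height_a, mt$pairs$height_b)
      } else {
        NA_real_
      }
    }
  }
  structure(list(rho = rho, n_pairs = np), class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat("Pearson correlation of matched peak heights:\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Assign peak summits to intervals
#'
#' A peak hits an interval iff `start <= summit < end` (half-open): the
#' summit must map precisely between the interval borders.
#'
#' @param peaks A `PeakSet`.
#' @param intervals A `HotspotSet` or any data.frame with `chrom`, `start`,
#'   `end`.
#' @return List with `flags` (per-peak logical, inside any interval),
#'   `interval_hits` (per-interval peak counts), `n_peaks_in`,
#'   `n_hotspots_hit`.
#' @export
assign_peaks_to_intervals <- function(peaks, intervals) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (nrow(peaks) == 0L || nrow(intervals) == 0L) {
    return(list(flags = logical(nrow(peaks)),
                interval_hits = integer(nrow(intervals)),
                n_peaks_in = 0L, n_hotspots_hit = 0L))
  }
  pk <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$summit + 1, width = 1))
  iv <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1, end = intervals$end))
  ov <- GenomicRanges::findOverlaps(pk, iv)
  flags <- logical(nrow(peaks))
  flags[S4Vectors::queryHits(ov)] <- TRUE
  interval_hits <- tabulate(S4Vectors::subjectHits(ov), nbins = nrow(intervals))
  list(flags = flags, interval_hits = interval_hits,
       n_peaks_in = sum(flags), n_hotspots_hit = sum(interval_hits > 0))
}
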