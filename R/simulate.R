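# Seeded synthetic-data generator. Emulates the data model the analysis
# assumes: an untagged control that is pure background, a tagged ChIP that
# is scaled background plus localized enrichment at a subset of DSB
# hotspots, multi-mapping reads at decoy sites, and paired profiles whose
# peak heights share a target Pearson correlation. Every generator is a
# pure function of (parameters, seed).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a genome layout with planted hotspot centers
#'
#' Places `n_hotspots` centers uniformly at random, split evenly across
#' `n_chrom` equal-length chromosomes, with all pairwise gaps on a
#' chromosome at least `min_spacing` bp and a margin from the ends.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_length Length of each chromosome in bp (default 3e5).
#' @param n_hotspots Total hotspot centers (default 40).
#' @param min_spacing Minimal center-to-center distance in bp (default 5000).
#' @param margin Keep-out distance from chromosome ends (default 2000).
#' @return List with `layout` (a `GenomeLayout`) and `hotspots` (data.frame
#'   `chrom`, `center`).
#' @export
make_layout_and_hotspots <- function(seed, n_chrom = 2, chrom_length = 3e5,
                                     n_hotspots = 40, min_spacing = 5000,
                                     margin = 2000) {
  layout <- genome_layout(paste0("chr", utils::as.roman(seq_len(n_chrom))),
                          rep(chrom_length, n_chrom))
  per <- diff(round(seq(0, n_hotspots, length.out = n_chrom + 1)))
  if (any(per * min_spacing + 2 * margin > chrom_length)) {
    stop("infeasible packing: hotspots * min_spacing exceeds chromosome length",
         call. = FALSE)
  }
  hot <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_chrom), function(i) {
      n <- per[i]
      if (n == 0L) return(NULL)
      # sorted uniforms stretched by min_spacing: consecutive gaps are
      # >= min_spacing by construction
      span <- chrom_length - 2 * margin - (n - 1) * min_spacing
      u <- sort(stats::runif(n, 0, span))
      data.frame(chrom = layout$chrom[i],
                 center = margin + floor(u) + (seq_len(n) - 1) * min_spacing,
                 stringsAsFactors = FALSE)
    }))
  })
  if (is.null(hot)) {
    hot <- data.frame(chrom = character(), center = numeric())
  }
  rownames(hot) <- NULL
  list(layout = layout, hotspots = hot)
}

#' Ground-truth record for one simulated ChIP/control pair
#'
#' Bundles the parameters and drawn truth of a simulation: which hotspots
#' are occupied by the tagged protein, their true summit enrichment heights,
#' the background depth, the background scaling of ChIP relative to control,
#' and the multi-mapping contamination.
#'
#' @param seed Integer seed (drives hotspot placement, occupancy, heights
#'   and the read draws).
#' @param n_chrom,chrom_length,n_hotspots,min_spacing Passed to
#'   [make_layout_and_hotspots()].
#' @param occupancy Fraction of hotspots truly bound (default 0.75).
#' @param mean_height Mean true enrichment depth at an occupied summit
#'   (default 25); heights are log-normal with `height_sdlog` spread.
#' @param height_sdlog Log-scale sd of true heights (default 0.3).
#' @param background_rate Expected background depth per bp in the control
#'   (default 5).
#' @param r_true Background scaling of ChIP relative to control (default
#'   0.7): the ChIP background depth is `r_true * background_rate`.
#' @param multi_map_fraction Fraction of background reads emitted as k-fold
#'   multi-mapping hits (default 0.1).
#' @param decoy_k Number of genome-wide matches for a multi-mapping read
#'   (default 4).
#' @param read_length Read length in bp (default 50, single-end).
#' @param frag_sd Gaussian spread of fragment centers around an occupied
#'   summit, in bp (default 100).
#' @param heights Optional vector of true heights for the occupied hotspots
#'   (overrides the log-normal draw; used for correlated sample pairs).
#' @return A `SyntheticTruth` list; fields include `layout`, `hotspots`,
#'   `occupied` (indices), `heights`, and all parameters above.
#' @export
synthetic_truth <- function(seed, n_chrom = 2, chrom_length = 3e5,
                            n_hotspots = 40, min_spacing = 5000,
                            occupancy = 0.75, mean_height = 25,
                            height_sdlog = 0.3, background_rate = 5,
                            r_true = 0.7, multi_map_fraction = 0.1,
                            decoy_k = 4, read_length = 50, frag_sd = 100,
                            heights = NULL) {
  stopifnot(r_true > 0, multi_map_fraction >= 0, multi_map_fraction <= 1,
            occupancy >= 0, occupancy <= 1, decoy_k >= 2)
  gh <- make_layout_and_hotspots(seed, n_chrom, chrom_length, n_hotspots,
                                 min_spacing)
  n_occ <- round(occupancy * nrow(gh$hotspots))
  occupied <- with_seed(seed + 101L,
                        sort(sample(nrow(gh$hotspots), n_occ)))
  if (is.null(heights)) {
    heights <- with_seed(seed + 202L, {
      stats::rlnorm(n_occ, meanlog = log(mean_height) - height_sdlog^2 / 2,
                    sdlog = height_sdlog)
    })
  }
  stopifnot(length(heights) == n_occ)
  structure(
    list(seed = seed, layout = gh$layout, hotspots = gh$hotspots,
         occupied = occupied, heights = heights,
         background_rate = background_rate, r_true = r_true,
         multi_map_fraction = multi_map_fraction, decoy_k = decoy_k,
         read_length = read_length, frag_sd = frag_sd),
    class = "SyntheticTruth"
  )
}

# Uniform background read starts over one chromosome, a fraction of them
# re-emitted as k-fold multi-hits with decoys outside hotspot neighborhoods.
sim_background_reads <- function(truth, ch, rate) {
  L <- chrom_length(truth$layout, ch)
  len <- truth$read_length
  n <- stats::rpois(1, rate * L / len)
  if (n == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), weight = numeric()))
  }
  start <- floor(stats::runif(n, 0, L - len))
  mm <- stats::runif(n) < truth$multi_map_fraction
  uniq <- data.frame(chrom = ch, start = start[!mm],
                     end = start[!mm] + len, weight = 1,
                     stringsAsFactors = FALSE)
  if (!any(mm)) return(uniq)
  k <- truth$decoy_k
  centers <- truth$hotspots$center[truth$hotspots$chrom == ch]
  keepout <- 4 * truth$frag_sd
  draw_decoys <- function(m) {
    out <- numeric(0)
    while (length(out) < m) {
      cand <- floor(stats::runif(2 * m, 0, L - len))
      if (length(centers)) {
        near <- vapply(cand, function(p) any(abs(p - centers) < keepout), TRUE)
        cand <- cand[!near]
      }
      out <- c(out, cand)
    }
    out[seq_len(m)]
  }
  n_mm <- sum(mm)
  decoys <- draw_decoys(n_mm * (k - 1))
  multi <- data.frame(
    chrom = ch,
    start = c(start[mm], decoys),
    end = c(start[mm], decoys) + len,
    weight = 1 / k,
    stringsAsFactors = FALSE
  )
  rbind(uniq, multi)
}

#' Simulate a tagged/untagged hit pair from a ground truth
#'
#' The untagged control is uniform Poisson background at `background_rate`.
#' The tagged sample is background at `r_true * background_rate` plus, at
#' every occupied hotspot, uniquely-mapping reads whose fragment centers are
#' Gaussian around the summit with sd `frag_sd`, in numbers calibrated so
#' the expected added depth at the summit equals the true height. A
#' `multi_map_fraction` of background reads is emitted as `decoy_k`-fold
#' multi-hits (weight `1/decoy_k`) whose decoy positions avoid hotspot
#' neighborhoods, so multi-mapping dilutes background but cannot create
#' false peaks.
#'
#' @param truth A [synthetic_truth()].
#' @return List with `tagged` and `untagged` weighted-hit data.frames
#'   (columns `chrom`, `start`, `end`, `weight`).
#' @export
simulate_chip_pair <- function(truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  with_seed(truth$seed + 303L, {
    chroms <- truth$layout$chrom
    untagged <- do.call(rbind, lapply(chroms, function(ch) {
      sim_background_reads(truth, ch, truth$background_rate)
    }))
    tagged_bg <- do.call(rbind, lapply(chroms, function(ch) {
      sim_background_reads(truth, ch, truth$r_true * truth$background_rate)
    }))
    len <- truth$read_length
    # a read covers the summit iff its fragment center is within len/2
    p_cov <- stats::pnorm(len / 2, 0, truth$frag_sd) -
      stats::pnorm(-len / 2, 0, truth$frag_sd)
    signal <- do.call(rbind, lapply(seq_along(truth$occupied), function(i) {
      hs <- truth$hotspots[truth$occupied[i], ]
      L <- chrom_length(truth$layout, hs$chrom)
      n_sig <- stats::rpois(1, truth$heights[i] / p_cov)
      if (n_sig == 0) return(NULL)
      centers <- stats::rnorm(n_sig, hs$center, truth$frag_sd)
      start <- pmin(pmax(round(centers - len / 2), 0), L - len)
      data.frame(chrom = hs$chrom, start = start, end = start + len,
                 weight = 1, stringsAsFactors = FALSE)
    }))
    tagged <- rbind(tagged_bg, signal)
    tagged <- tagged[order(match(tagged$chrom, chroms), tagged$start), ]
    untagged <- untagged[order(match(untagged$chrom, chroms), untagged$start), ]
    rownames(tagged) <- rownames(untagged) <- NULL
    list(tagged = tagged, untagged = untagged)
  })
}

#' Simulate paired peak heights with a target Pearson correlation
#'
#' Draws `n` pairs of log-normal peak heights whose raw-scale Pearson
#' correlation targets `rho`. The latent bivariate-Gaussian correlation is
#' calibrated as `rho_z = log(1 + rho * (exp(s^2) - 1)) / s^2` (with
#' `s = sdlog`), the exact relation between log-scale and raw-scale
#' correlation of a bivariate log-normal, so the heights themselves — the
#' quantities the correlation matrix compares — carry the target
#' correlation.
#'
#' @param n Number of pairs (>= 3).
#' @param rho Target Pearson correlation of the heights, in (-1, 1).
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-scale location and spread (defaults 0 and 0.3;
#'   the mild default keeps the height distribution close enough to
#'   Gaussian that normal-theory intervals for Pearson's r retain near
#'   nominal coverage, a design requirement of the correlation-recovery
#'   validation study, while still spanning roughly two-fold height
#'   variation).
#' @return List with `a`, `b` (height vectors), `rho` (target) and `rho_z`
#'   (latent Gaussian correlation used).
#' @export
simulate_paired_peak_heights <- function(n, rho, seed, meanlog = 0,
                                         sdlog = 0.3) {
  stopifnot(n >= 3, rho > -1, rho < 1)
  s2 <- sdlog^2
  arg <- 1 + rho * (exp(s2) - 1)
  if (arg <= exp(-s2)) {
    stop("target rho is not attainable for a log-normal with this sdlog",
         call. = FALSE)
  }
  rho_z <- log(arg) / s2
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * stats::rnorm(n)
    list(a = exp(meanlog + sdlog * z1), b = exp(meanlog + sdlog * z2),
         rho = rho, rho_z = rho_z)
  })
}

#' Simulate a Spo11-oligo 5'-end table around hotspot centers
#'
#' Each hotspot center receives `oligos_per_hotspot` 5'-end positions,
#' Gaussian-scattered within `spread_bp` (sd), with small positive counts.
#'
#' @param hotspots data.frame with `chrom`, `center` (as from
#'   [make_layout_and_hotspots()]).
#' @param layout A `GenomeLayout` (positions are clamped to bounds).
#' @param oligos_per_hotspot Positions per hotspot (default 20).
#' @param spread_bp Sd of the scatter in bp (default 15; 0 puts every
#'   position at the center).
#' @param seed Integer seed.
#' @return An `OligoTable` sorted by chromosome and position.
#' @export
simulate_oligo_table <- function(hotspots, layout, oligos_per_hotspot = 20,
                                 spread_bp = 15, seed = 1) {
  stopifnot(spread_bp >= 0)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(hotspots)), function(i) {
      ch <- hotspots$chrom[i]
      L <- chrom_length(layout, ch)
      pos <- round(stats::rnorm(oligos_per_hotspot, hotspots$center[i],
                                spread_bp))
      pos <- pmin(pmax(pos, 0), L - 1)
      data.frame(chrom = ch, pos = pos,
                 count = 1 + stats::rpois(oligos_per_hotspot, 2),
                 stringsAsFactors = FALSE)
    })
    o <- do.call(rbind, rows)
    o <- o[order(match(o$chrom, layout$chrom), o$pos), ]
    rownames(o) <- NULL
    oligo_table(o$chrom, o$pos, o$count)
  })
}

#' Simulate a full experiment: two correlated tagged samples + one control
#'
#' Builds one genome and hotspot set, draws two tagged samples that share
#' the occupied hotspots but whose true summit heights are a correlated
#' log-normal pair (target Pearson `rho`), one untagged control, and a
#' Spo11-oligo table around the hotspot centers.
#'
#' @param seed Integer seed.
#' @param rho Target Pearson correlation of the two samples' true heights
#'   (default 0.8).
#' @param ... Passed to [synthetic_truth()].
#' @return List with `truth_a`, `truth_b` (per-sample `SyntheticTruth`),
#'   `hits_a`, `hits_b`, `hits_untagged`, `oligos`, `layout`.
#' @export
simulate_experiment <- function(seed, rho = 0.8, ...) {
  base <- synthetic_truth(seed, ...)
  n_occ <- length(base$occupied)
  mh <- 25
  hp <- simulate_paired_peak_heights(max(n_occ, 3), rho, seed + 404L,
                                     meanlog = log(mh) - 0.3^2 / 2,
                                     sdlog = 0.3)
  truth_a <- synthetic_truth(seed, heights = hp$a[seq_len(n_occ)], ...)
  truth_b <- synthetic_truth(seed, heights = hp$b[seq_len(n_occ)], ...)
  truth_b$seed <- seed + 505L  # independent read noise, same truth frame
  pair_a <- simulate_chip_pair(truth_a)
  pair_b <- simulate_chip_pair(truth_b)
  oligos <- simulate_oligo_table(base$hotspots, base$layout, seed = seed + 606L)
  list(truth_a = truth_a, truth_b = truth_b,
       hits_a = pair_a$tagged, hits_b = pair_b$tagged,
       hits_untagged = pair_a$untagged, oligos = oligos,
       layout = base$layout, target_rho = rho)
}

#' Write / read a simulation ground truth as JSON
#' @param truth A `SyntheticTruth`.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$layout <- as.data.frame(x$layout)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$layout <- genome_layout(x$layout$chrom, x$layout$length)
  x$heights <- as.numeric(x$heights)
  x$occupied <- as.integer(x$occupied)
  structure(x, class = "SyntheticTruth")
}
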