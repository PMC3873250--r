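# End-to-end orchestration: hits -> coverage -> smoothing -> NCIS ->
# subtraction -> (optional decile scaling) -> peaks -> matching ->
# correlation -> hotspot grouping -> co-localization tests.

#' Build a pipeline run configuration
#'
#' @param samples data.frame with columns `name`, `hits` (path), `role`
#'   (`"tagged"` or `"untagged"`), `control` (name of the untagged sample
#'   used as negative control; required for tagged samples).
#' @param chrom_sizes Path to the chrom.sizes file.
#' @param oligo_table Optional path to a Spo11-oligo BED table.
#' @param out_dir Output directory (created if absent).
#' @param bandwidth Smoothing bandwidth in bp (default 300, the
#'   peak-matching setting; 250 and 500 are the display settings).
#' @param resolution Profile resolution in bp (default 10).
#' @param ncis_bin_size NCIS estimation bin in bp (default 1000).
#' @param q_threshold Peak height-quantile cut (default 0.7).
#' @param min_valley_depth Required peak prominence (default 0).
#' @param hotspot_gap Oligo grouping distance in bp (default 50).
#' @param max_hits Multi-mapping cap per read (default 5000).
#' @param decile Optional decile index 1..9; when given, subtracted profiles
#'   are decile-normalized before peak calling.
#' @param truth Optional path to a truth JSON for recall/precision reporting.
#' @param seed Integer recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A validated `RunConfig` list.
#' @export
run_config <- function(samples, chrom_sizes, out_dir, oligo_table = NULL,
                       bandwidth = 300, resolution = 10,
                       ncis_bin_size = 1000, q_threshold = 0.7,
                       min_valley_depth = 0, hotspot_gap = 50,
                       max_hits = 5000, decile = NULL, truth = NULL,
                       seed = 1L) {
  cfg <- structure(
    list(samples = samples, chrom_sizes = chrom_sizes,
         oligo_table = oligo_table, out_dir = out_dir,
         bandwidth = bandwidth, resolution = resolution,
         ncis_bin_size = ncis_bin_size, q_threshold = q_threshold,
         min_valley_depth = min_valley_depth, hotspot_gap = hotspot_gap,
         max_hits = max_hits, decile = decile, truth = truth,
         seed = as.integer(seed)),
    class = "RunConfig"
  )
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  s <- cfg$samples
  need <- c("name", "hits", "role")
  if (!is.data.frame(s) || !all(need %in% names(s))) {
    stop("validation: samples must have columns name, hits, role",
         call. = FALSE)
  }
  if (anyDuplicated(s$name)) stop("validation: duplicate sample name", call. = FALSE)
  if (!all(s$role %in% c("tagged", "untagged"))) {
    stop("validation: role must be tagged or untagged", call. = FALSE)
  }
  tagged <- s[s$role == "tagged", , drop = FALSE]
  if (nrow(tagged) == 0L) stop("validation: no tagged sample", call. = FALSE)
  if (is.null(s$control)) s$control <- NA_character_
  ctrl <- s$control[s$role == "tagged"]
  if (anyNA(ctrl) || !all(ctrl %in% s$name[s$role == "untagged"])) {
    stop("validation: every tagged sample must name an existing untagged control",
         call. = FALSE)
  }
  missing <- s$hits[!file.exists(s$hits)]
  if (length(missing)) {
    stop("validation: missing hits file: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!file.exists(cfg$chrom_sizes)) {
    stop("validation: missing chrom.sizes file", call. = FALSE)
  }
  if (cfg$bandwidth <= 0 || cfg$resolution <= 0) {
    stop("validation: bandwidth and resolution must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

stage <- function(name, sample, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed for sample '%s': %s",
                 name, sample, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' For every tagged sample: weighted hits are accumulated to 1 bp coverage,
#' the NCIS factor against its control is estimated on raw counts, both
#' sample and control are smoothed, the scaled control is subtracted
#' (optionally followed by decile normalization), and peaks are called.
#' Then peaks are matched across all tagged pairs within the bandwidth,
#' peak heights are compared by Pearson correlation, Spo11 oligos (when
#' given) are grouped into hotspots, and hypergeometric (peak/peak) and
#' binomial (peak/hotspot) co-localization tests are computed. All outputs
#' are written as plain text under `out_dir` together with a manifest
#' recording every parameter; re-running the same configuration reproduces
#' every output byte-identically.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `profiles`, `peaks`, `norm_factors`,
#'   `correlation`, `matches`, `hotspots`, `tests`, and (when a truth file
#'   was given) `truth_report`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- read_chrom_sizes(cfg$chrom_sizes)
  s <- cfg$samples
  if (is.null(s$control)) s$control <- NA_character_

  raw <- list()
  for (i in seq_len(nrow(s))) {
    raw[[s$name[i]]] <- stage("coverage", s$name[i], {
      hits <- read_hits(s$hits[i], max_hits = cfg$max_hits, layout = layout)
      accumulate_depth(hits, layout)
    })
  }

  tagged <- s$name[s$role == "tagged"]
  smoothed <- list()
  for (nm in s$name) {
    smoothed[[nm]] <- stage("smoothing", nm, {
      smooth_profile(raw[[nm]], cfg$bandwidth, cfg$resolution,
                     sample_name = nm)
    })
  }

  norm_factors <- list()
  profiles <- list()
  peaks <- list()
  for (nm in tagged) {
    ctrl <- s$control[s$name == nm]
    nf <- stage("ncis", nm, {
      estimate_ncis_factor(raw[[nm]], raw[[ctrl]], cfg$ncis_bin_size)
    })
    norm_factors[[nm]] <- nf
    prof <- stage("subtraction", nm, {
      subtract_control(smoothed[[nm]], smoothed[[ctrl]], nf)
    })
    if (!is.null(cfg$decile)) {
      prof <- stage("decile_normalization", nm,
                    decile_normalize(prof, cfg$decile))
    }
    profiles[[nm]] <- prof
    peaks[[nm]] <- stage("peak_calling", nm, {
      call_peaks(prof, peak_call_params(cfg$min_valley_depth,
                                        cfg$q_threshold))
    })
    write_bedgraph(prof, file.path(cfg$out_dir, paste0(nm, ".bedgraph")))
    write_peak_table(peaks[[nm]],
                     file.path(cfg$out_dir, paste0(nm, "_peaks.tsv")))
    jsonlite::write_json(
      list(sample = nm, control = ctrl, r = nf$r, bin_size = nf$bin_size,
           n_background_bins = nf$n_background_bins),
      file.path(cfg$out_dir, paste0(nm, "_normfactor.json")),
      auto_unbox = TRUE, digits = NA)
  }

  matches <- list()
  tests <- list()
  correlation <- NULL
  if (length(tagged) >= 2) {
    correlation <- correlation_matrix(peaks[tagged], max_dist = cfg$bandwidth)
    write_correlation_tsv(correlation,
                          file.path(cfg$out_dir, "correlation_matrix.tsv"))
    N <- overlap_universe_size(layout, cfg$bandwidth)
    combs <- utils::combn(tagged, 2, simplify = FALSE)
    for (pr in combs) {
      mt <- match_peaks(peaks[[pr[1]]], peaks[[pr[2]]],
                        max_dist = cfg$bandwidth)
      key <- paste(pr, collapse = "_vs_")
      matches[[key]] <- mt
      write_match_tsv(mt, file.path(cfg$out_dir,
                                    paste0("matches_", key, ".tsv")))
      tests[[paste0("hypergeom_", key)]] <- hypergeom_overlap_test(
        k = nrow(mt$pairs), K = nrow(peaks[[pr[1]]]),
        n = nrow(peaks[[pr[2]]]), N = N)
    }
  }

  hotspots <- NULL
  if (!is.null(cfg$oligo_table)) {
    hotspots <- stage("hotspot_grouping", "oligos", {
      group_oligo_hotspots(read_oligo_table(cfg$oligo_table, layout),
                           gap = cfg$hotspot_gap)
    })
    write_hotspots(hotspots, file.path(cfg$out_dir, "hotspots.bed"))
    p_hot <- hotspot_bp_fraction(hotspots, layout)
    for (nm in tagged) {
      asg <- assign_peaks_to_intervals(peaks[[nm]], hotspots)
      tests[[paste0("binomial_", nm, "_in_hotspots")]] <-
        binomial_hotspot_test(asg$n_peaks_in, nrow(peaks[[nm]]), p_hot)
    }
  }
  if (length(tests)) {
    write_test_table(tests, file.path(cfg$out_dir, "overlap_tests.tsv"))
  }

  truth_report <- NULL
  if (!is.null(cfg$truth)) {
    truth <- read_truth_json(cfg$truth)
    truth_report <- lapply(peaks[tagged], peak_truth_report, truth = truth)
    jsonlite::write_json(truth_report,
                         file.path(cfg$out_dir, "truth_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- cfg[setdiff(names(cfg), "samples")]
  manifest$samples <- as.data.frame(s)
  manifest$package_version <- as.character(utils::packageVersion("meiochip"))
  manifest$n_peaks <- vapply(peaks, nrow, 1L)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(layout = layout, profiles = profiles, peaks = peaks,
                 norm_factors = norm_factors, correlation = correlation,
                 matches = matches, hotspots = hotspots, tests = tests,
                 truth_report = truth_report))
}

#' Compare called peaks with a simulation ground truth
#'
#' A planted (occupied) hotspot counts as recovered when a called summit
#' lies within `tol` bp of its center; a called peak is a true positive
#' when it lies within `tol` of any occupied center.
#'
#' @param peaks A `PeakSet`.
#' @param truth A `SyntheticTruth`.
#' @param tol Matching tolerance in bp (default: the peak set's bandwidth).
#' @return List with `recall`, `precision`, `n_true`, `n_called`,
#'   `n_recovered`.
#' @export
peak_truth_report <- function(peaks, truth, tol = NULL) {
  if (is.null(tol)) {
    tol <- attr(peaks, "bandwidth")
    if (is.null(tol) || is.na(tol)) tol <- 300
  }
  occ <- truth$hotspots[truth$occupied, , drop = FALSE]
  if (nrow(occ) == 0L || nrow(peaks) == 0L) {
    return(list(recall = NA_real_, precision = NA_real_,
                n_true = nrow(occ), n_called = nrow(peaks), n_recovered = 0L))
  }
  recovered <- vapply(seq_len(nrow(occ)), function(i) {
    any(peaks$chrom == occ$chrom[i] &
          abs(peaks$summit - occ$center[i]) <= tol)
  }, TRUE)
  true_pos <- vapply(seq_len(nrow(peaks)), function(i) {
    any(occ$chrom == peaks$chrom[i] &
          abs(occ$center - peaks$summit[i]) <= tol)
  }, TRUE)
  list(recall = mean(recovered), precision = mean(true_pos),
       n_true = nrow(occ), n_called = nrow(peaks),
       n_recovered = sum(recovered))
}

write_correlation_tsv <- function(cm, path) {
  nm <- rownames(cm$rho)
  lines <- c(paste(c("sample", nm), collapse = "\t"),
             vapply(seq_along(nm), function(i) {
               paste(c(nm[i], fmt_num(cm$rho[i, ])), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

write_match_tsv <- function(mt, path) {
  p <- mt$pairs
  lines <- c("chrom\tsummit_a\tsummit_b\theight_a\theight_b\tdistance",
             sprintf("%s\t%d\t%d\t%s\t%s\t%d", p$chrom,
                     as.integer(p$summit_a), as.integer(p$summit_b),
                     fmt_num(p$height_a), fmt_num(p$height_b),
                     as.integer(p$distance)))
  writeLines(lines, path)
  invisible(path)
}
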