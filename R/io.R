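# Plain-text readers/writers for the formats the pipeline touches.
# Floats are written with 17 significant digits so write-then-read
# reproduces every stored value exactly (lossless round trips).

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  int <- x == round(x) & abs(x) < 1e15
  out[int] <- sprintf("%d", as.integer(x[int]))
  out
}

#' Read aligned hits with multi-mapping weights
#'
#' Reads a table of aligned hits and attaches the weight `1 / n_matches` to
#' every hit, where `n_matches` is the read's number of genome-wide matches.
#' Reads with more than `max_hits` matches are dropped entirely (the
#' aligner-cap semantics of allowing up to `max_hits` hits per sequence).
#'
#' Two input dialects are supported:
#' \describe{
#'   \item{`"bed"`}{BED-like tab-separated text, 0-based half-open, with the
#'     genome-wide match count in column 4 (`chrom start end n_matches`).
#'     A 3-column file is accepted: every read is then treated as uniquely
#'     mapped (weight 1) with a warning.}
#'   \item{`"sam"`}{SAM/BAM via Rsamtools; the match count is taken from the
#'     `NH` tag, missing tags are treated as unique with a warning.}
#' }
#'
#' @param path Input file.
#' @param max_hits Maximum genome-wide matches per read; reads above the cap
#'   are dropped. Default 5000.
#' @param layout Optional `GenomeLayout`; when given, hits on unknown
#'   chromosomes or beyond chromosome ends raise an error.
#' @param format `"auto"` (by extension), `"bed"` or `"sam"`.
#' @return A data.frame of weighted hits with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `weight` in (0, 1].
#' @export
read_hits <- function(path, max_hits = 5000, layout = NULL,
                      format = c("auto", "bed", "sam")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sam", "bam")) "sam" else "bed"
  }
  if (max_hits < 1) stop("max_hits must be >= 1", call. = FALSE)
  hits <- if (format == "sam") {
    read_hits_sam(path)
  } else {
    read_hits_bed(path)
  }
  hits <- hits[hits$n_matches <= max_hits, , drop = FALSE]
  hits$weight <- 1 / hits$n_matches
  hits$n_matches <- NULL
  if (!is.null(layout)) {
    unknown <- setdiff(unique(hits$chrom), layout$chrom)
    if (length(unknown)) {
      stop("hit on unknown chromosome: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(hits$end > chrom_length(layout, hits$chrom))) {
      stop("hit beyond chromosome end", call. = FALSE)
    }
  }
  rownames(hits) <- NULL
  hits
}

read_hits_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_matches = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 3L)) {
    stop("malformed hit record at line ", which(nf < 3L)[1], call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed hit record at line ", which(is.na(start) | is.na(end))[1],
         call. = FALSE)
  }
  if (any(end <= start)) {
    stop("hit interval end <= start at line ", which(end <= start)[1],
         call. = FALSE)
  }
  if (all(nf >= 4L)) {
    n_matches <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
    if (anyNA(n_matches) || any(n_matches < 1)) {
      stop("malformed match count at line ",
           which(is.na(n_matches) | n_matches < 1)[1], call. = FALSE)
    }
  } else {
    warning("no match-count column; treating all reads as uniquely mapped")
    n_matches <- rep(1, length(chrom))
  }
  data.frame(chrom = chrom, start = start, end = end, n_matches = n_matches,
             stringsAsFactors = FALSE)
}

read_hits_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("the SAM/BAM reader needs the Rsamtools package", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  bam <- if (ext == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "flag"),
    tag = "NH"
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  aligned <- !is.na(res$pos) & !bitwAnd(res$flag, 4L)
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(res$pos))
  nh <- nh[aligned]
  if (anyNA(nh)) {
    warning("reads without NH tag treated as uniquely mapped")
    nh[is.na(nh)] <- 1L
  }
  data.frame(
    chrom = as.character(res$rname)[aligned],
    start = res$pos[aligned] - 1,           # SAM 1-based -> 0-based
    end = res$pos[aligned] - 1 + res$qwidth[aligned],
    n_matches = as.numeric(nh),
    stringsAsFactors = FALSE
  )
}

#' Write weighted hits as a BED-like table
#'
#' Inverse of [read_hits()]: the 4th column stores `round(1/weight)`.
#' @param hits Weighted-hit data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  writeLines(sprintf("%s\t%d\t%d\t%d", hits$chrom, as.integer(hits$start),
                     as.integer(hits$end), as.integer(round(1 / hits$weight))),
             path)
  invisible(path)
}

#' Read/write BED intervals
#'
#' Standard BED (0-based half-open). `read_intervals` returns columns
#' `chrom`, `start`, `end` plus `name` and `score` when present;
#' `write_intervals` writes whichever of those columns exist.
#'
#' @param path File path.
#' @param layout Optional `GenomeLayout` for bounds checking.
#' @return A data.frame of intervals.
#' @export
read_intervals <- function(path, layout = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 3L)) {
    stop("malformed BED record at line ", which(nf < 3L)[1], call. = FALSE)
  }
  out <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.numeric(vapply(parts, `[[`, "", 2L)),
    end = as.numeric(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (any(out$end <= out$start)) {
    stop("interval end <= start at line ", which(out$end <= out$start)[1],
         call. = FALSE)
  }
  if (all(nf >= 4L)) out$name <- vapply(parts, `[[`, "", 4L)
  if (all(nf >= 5L)) out$score <- as.numeric(vapply(parts, `[[`, "", 5L))
  if (!is.null(layout)) check_bounds(out, layout)
  out
}

#' @rdname read_intervals
#' @param intervals Interval data.frame (`chrom`, `start`, `end`, optional
#'   `name`, `score`).
#' @export
write_intervals <- function(intervals, path) {
  cols <- list(intervals$chrom, fmt_num(intervals$start), fmt_num(intervals$end))
  if (!is.null(intervals$name)) cols <- c(cols, list(intervals$name))
  if (!is.null(intervals$score) && !is.null(intervals$name)) {
    cols <- c(cols, list(fmt_num(intervals$score)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

check_bounds <- function(intervals, layout) {
  unknown <- setdiff(unique(intervals$chrom), layout$chrom)
  if (length(unknown)) {
    stop("interval on unknown chromosome: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  over <- intervals$end > chrom_length(layout, intervals$chrom) |
    intervals$start < 0
  if (any(over)) {
    stop("interval out of chromosome bounds (record ", which(over)[1], ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a Spo11-oligo 5'-end table
#'
#' BED-like input; the 5' end is taken as the interval start and the score
#' column (or 1 when absent) as the oligo count.
#'
#' @param path File path.
#' @param layout Optional `GenomeLayout` for bounds checking.
#' @return An `OligoTable` data.frame with columns `chrom`, `pos`, `count`.
#' @export
read_oligo_table <- function(path, layout = NULL) {
  iv <- read_intervals(path, layout)
  count <- if (!is.null(iv$score)) iv$score else rep(1, nrow(iv))
  if (any(count < 0)) stop("negative oligo count", call. = FALSE)
  oligo_table(iv$chrom, iv$start, count)
}

oligo_table <- function(chrom, pos, count = rep(1, length(pos))) {
  structure(
    data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
               count = as.numeric(count), stringsAsFactors = FALSE),
    class = c("OligoTable", "data.frame")
  )
}

#' Write an oligo table as BED (pos, pos+1, name ".", count as score)
#' @param oligos An `OligoTable`.
#' @param path Output path.
#' @export
write_oligo_table <- function(oligos, path) {
  write_intervals(
    data.frame(chrom = oligos$chrom, start = oligos$pos,
               end = oligos$pos + 1, name = ".", score = oligos$count),
    path
  )
}

#' Serialize a profile to bedGraph / read it back
#'
#' One line per bin; bins are half-open `[i*res, min((i+1)*res, L))`.
#' Values survive the round trip exactly (17 significant digits).
#'
#' @param profile A `Profile`.
#' @param path File path.
#' @return `write_bedgraph`: `path`, invisibly. `read_bedgraph`: a `Profile`.
#' @export
write_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "Profile"))
  res <- profile$resolution
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(profile$values)) {
    v <- profile$values[[ch]]
    L <- chrom_length(profile$layout, ch)
    starts <- (seq_along(v) - 1) * res
    ends <- pmin(starts + res, L)
    writeLines(paste(ch, starts, ends, fmt_num(v), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param layout `GenomeLayout` the track lives on.
#' @param resolution Bin width in bp (must match the file's bins).
#' @export
read_bedgraph <- function(path, layout, resolution = 10) {
  iv <- read_intervals(path, layout)
  vals <- lapply(seq_len(nrow(layout)), function(i) {
    ch <- layout$chrom[i]
    n <- ceiling(layout$length[i] / resolution)
    v <- numeric(n)
    sel <- iv$chrom == ch
    if (any(sel)) {
      idx <- iv$start[sel] / resolution + 1
      if (any(idx != round(idx))) {
        stop("bedGraph bins do not sit on the ", resolution, " bp grid",
             call. = FALSE)
      }
      v[idx] <- as.numeric(iv$name[sel])  # 4th column holds the value
    }
    v
  })
  names(vals) <- layout$chrom
  new_profile(lapply(vals, as.numeric), layout, resolution,
              bandwidth = NA_real_, normalization_state = "raw",
              sample_name = basename(path))
}

#' Write a peak table
#'
#' Tab-separated with header `chrom summit height left_valley right_valley
#' passed_q`; coordinates are 0-based profile-grid positions.
#'
#' @param peaks A `PeakSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  passed <- if (!is.null(peaks$passed_q)) peaks$passed_q else rep(TRUE, nrow(peaks))
  lines <- c(
    "chrom\tsummit\theight\tleft_valley\tright_valley\tpassed_q",
    sprintf("%s\t%d\t%s\t%s\t%s\t%d", peaks$chrom, as.integer(peaks$summit),
            fmt_num(peaks$height), fmt_num(peaks$left_valley),
            fmt_num(peaks$right_valley), as.integer(passed))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a peak table written by [write_peak_table()]
#' @param path File path.
#' @return A `PeakSet` data.frame.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$passed_q <- as.logical(df$passed_q)
  df$prominence <- df$height - pmax(df$left_valley, df$right_valley)
  class(df) <- c("PeakSet", "data.frame")
  df
}

#' Write hotspots as BED with the oligo count in the score column
#' @param hotspots A `HotspotSet`.
#' @param path Output path.
#' @export
write_hotspots <- function(hotspots, path) {
  write_intervals(
    data.frame(chrom = hotspots$chrom, start = hotspots$start,
               end = hotspots$end,
               name = sprintf("hotspot_%d", seq_len(nrow(hotspots))),
               score = hotspots$oligo_count),
    path
  )
}
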