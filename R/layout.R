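#' Construct a genome layout
#'
#' A `GenomeLayout` is the ordered set of chromosome names and lengths that
#' fixes the coordinate frame for every profile, peak and hotspot in the
#' pipeline. All internal coordinates are 0-based half-open.
#'
#' @param chrom Character vector of chromosome names (unique, order kept).
#' @param length Integer vector of chromosome lengths in bp (all > 0).
#' @return A `GenomeLayout`: a data.frame with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("chrI", "chrII"), c(230218, 813184))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) == 0L) stop("no chromosomes", call. = FALSE)
  if (base::length(chrom) != base::length(length)) {
    stop("chrom and length must have equal length", call. = FALSE)
  }
  if (anyNA(length) || any(length != round(length))) {
    stop("non-integer chromosome length", call. = FALSE)
  }
  if (any(length <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome name: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("GenomeLayout", "data.frame")
  )
}

#' Read a chrom.sizes file
#'
#' @param path Path to a two-column tab-separated text file (name, length).
#' @return A [genome_layout()] with one entry per line, order preserved.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no chromosomes in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, base::length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed chrom.sizes record at line ", bad[1], call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  len_chr <- vapply(parts, `[[`, "", 2L)
  len <- suppressWarnings(as.numeric(len_chr))
  if (anyNA(len) || any(len != round(len))) {
    stop("non-integer length at line ",
         which(is.na(len) | len != round(len))[1], call. = FALSE)
  }
  genome_layout(chrom, len)
}

#' Write a chrom.sizes file
#' @param layout A `GenomeLayout`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "GenomeLayout"))
  writeLines(sprintf("%s\t%d", layout$chrom, as.integer(layout$length)), path)
  invisible(path)
}

#' Total genome length of a layout
#' @param layout A `GenomeLayout`.
#' @return Total length in bp.
#' @export
genome_length <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  sum(layout$length)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) {
    stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  layout$length[i]
}

check_same_layout <- function(a, b) {
  if (!identical(a$chrom, b$chrom) || !identical(a$length, b$length)) {
    stop("mismatched genome layouts", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", nrow(x), "chromosomes,",
      format(sum(x$length), big.mark = ","), "bp total\n")
  print.data.frame(x, ...)
  invisible(x)
}
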