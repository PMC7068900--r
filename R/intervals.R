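## Genomic intervals are plain data.frames with columns chrom, start, end,
## 0-based half-open. Kept deliberately lightweight: every module does its
## own arithmetic on starts/ends and nothing here depends on an external
## ranges container.

#' Construct a genomic interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors, 0-based half-open; `start < end`.
#' @param ... further equal-length columns to carry along.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (plus `...`).
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(is.na(start)) || any(is.na(end)))
    stop("intervals may not contain NA coordinates")
  if (any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end")
  data.frame(chrom = as.character(chrom), start = start, end = end, ...,
             stringsAsFactors = FALSE)
}

#' Reciprocal overlap of two intervals
#'
#' The merge criterion for structural-variant candidates: the length of the
#' intersection divided by the length of each interval, taking the minimum
#' of the two fractions. Intervals on different chromosomes overlap by 0.
#'
#' @param a,b single-row interval data.frames (or lists) with
#'   `chrom`, `start`, `end`.
#' @return Overlap fraction in \[0, 1\].
#' @examples
#' a <- genomic_intervals("1", 0, 100)
#' reciprocal_overlap(a, genomic_intervals("1", 50, 150))  # 0.5
#' @export
reciprocal_overlap <- function(a, b) {
  if (a$end <= a$start || b$end <= b$start)
    stop("zero-length interval in reciprocal_overlap")
  if (a$chrom != b$chrom) return(0)
  inter <- min(a$end, b$end) - max(a$start, b$start)
  if (inter <= 0) return(0)
  min(inter / (a$end - a$start), inter / (b$end - b$start))
}

## Vectorized intersection length of one interval against a table; 0 when
## chromosomes differ.
interval_intersection <- function(chrom, start, end, tab) {
  len <- pmin(end, tab$end) - pmax(start, tab$start)
  len[tab$chrom != chrom] <- 0
  pmax(len, 0)
}

#' Parse "chrom:start-end" position strings
#'
#' Positions are taken verbatim: published inversion-call tables use
#' `size = end - start`, i.e. the printed coordinates already behave as
#' a half-open interval, so no shift is applied.
#'
#' @param x character vector like `"3:213245322-213670971"`.
#' @return Interval data.frame with a `size` column (`end - start`).
#' @export
parse_position_strings <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed position string(s): ", paste(x[bad], collapse = ", "))
  chrom <- vapply(m, `[[`, "", 2L)
  s <- as.numeric(vapply(m, `[[`, "", 3L))
  e <- as.numeric(vapply(m, `[[`, "", 4L))
  out <- genomic_intervals(chrom, s, e)
  out$size <- out$end - out$start
  out
}

## Tile chromosomes into fixed windows (last window truncated).
tile_windows <- function(chrom_lengths, window) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = window)
    data.frame(chrom = ch, start = starts, end = pmin(starts + window, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
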