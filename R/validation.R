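## merge overlapping/adjacent intervals within chromosomes
merge_intervals <- function(tab) {
  if (!nrow(tab)) return(tab[, c("chrom", "start", "end")])
  tab <- tab[order(tab$chrom, tab$start, tab$end), , drop = FALSE]
  out <- list()
  cur <- tab[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(tab))[-1]) {
    if (tab$chrom[i] == cur$chrom && tab$start[i] <= cur$end) {
      cur$end <- max(cur$end, tab$end[i])
    } else {
      out[[length(out) + 1]] <- cur
      cur <- tab[i, c("chrom", "start", "end")]
    }
  }
  out[[length(out) + 1]] <- cur
  do.call(rbind, out)
}

## fraction of [start,end) on chrom covered by (merged) repeat intervals
repeat_fraction <- function(repeats, chrom, start, end) {
  if (is.null(repeats) || !nrow(repeats)) return(0)
  sum(interval_intersection(chrom, start, end, repeats)) / (end - start)
}

## repeat content of the two junction neighborhoods of a breakpoint pair
flank_repeat_fraction <- function(repeats_merged, chrom, bp1, bp2, flank) {
  (repeat_fraction(repeats_merged, chrom, bp1 - flank, bp1 + flank) +
     repeat_fraction(repeats_merged, chrom, bp2 - flank, bp2 + flank)) / 2
}

#' Generate repeat-matched artificial (uninverted) breakpoints
#'
#' Samples `n` breakpoint pairs from the reference whose junction-flank
#' repeat content matches the candidate set's distribution: each
#' artificial locus draws a target repeat fraction from a candidate
#' (with replacement) and is rejection-sampled until its own flank
#' repeat fraction lies within `tolerance` of the target. Segment
#' lengths are resampled from the candidate segment lengths. These loci
#' carry no inversion, so competitive alignment against them measures
#' the background misassignment level.
#'
#' @param reference named character vector of chromosome sequences.
#' @param repeats repeat annotation interval data.frame (chrom, start,
#'   end), or NULL for a repeat-free genome.
#' @param candidates data.frame of candidate calls with `chrom`,
#'   `start`, `end` (the segment; breakpoints are its ends).
#' @param n number of artificial breakpoint pairs.
#' @param flank junction flank length used for matching (bp).
#' @param tolerance allowed deviation of the repeat fraction from the
#'   target, in fraction points (default 0.10).
#' @param max_attempts rejection-sampling attempts per locus before the
#'   tolerance is doubled (with a warning).
#' @param seed optional integer seed for reproducibility.
#' @return data.frame with `chrom`, `start`, `end`, `repeat_fraction`,
#'   `target_fraction`.
#' @export
generate_artificial_breakpoints <- function(reference, repeats, candidates,
                                            n = 1000, flank = 10000,
                                            tolerance = 0.10,
                                            max_attempts = 200,
                                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), repeat_fraction = numeric(),
                      target_fraction = numeric()))
  rep_m <- if (!is.null(repeats) && nrow(repeats))
    merge_intervals(repeats) else NULL
  chrom_len <- vapply(reference, nchar, 1)
  targets <- vapply(seq_len(nrow(candidates)), function(i)
    flank_repeat_fraction(rep_m, candidates$chrom[i], candidates$start[i],
                          candidates$end[i], flank), 1)
  sizes <- candidates$end - candidates$start
  # only segment sizes that fit somewhere in the reference can be
  # resampled for the null loci
  sizes <- sizes[sizes + 2 * flank < max(chrom_len)]
  if (!length(sizes))
    stop("no candidate segment fits the reference at this flank")
  pick_t <- sample.int(length(targets), n, replace = TRUE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    target <- targets[pick_t[i]]
    tol <- tolerance
    found <- FALSE
    for (attempt in seq_len(2 * max_attempts)) {
      if (attempt == max_attempts + 1) {
        tol <- 2 * tol
        warning(sprintf(
          "relaxing repeat-match tolerance to %.2f for locus %d", tol, i))
      }
      size <- sizes[sample.int(length(sizes), 1)]
      ch <- sample(names(reference), 1)
      lo <- flank; hi <- chrom_len[[ch]] - size - flank
      if (hi <= lo) next
      s <- floor(runif(1, lo, hi))
      fr <- flank_repeat_fraction(rep_m, ch, s, s + size, flank)
      if (abs(fr - target) <= tol) {
        out[[i]] <- data.frame(chrom = ch, start = s, end = s + size,
                               repeat_fraction = fr,
                               target_fraction = target,
                               stringsAsFactors = FALSE)
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("could not match repeat content for artificial locus ", i)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Calibrate the validation null from artificial-breakpoint assignments
#'
#' Summarizes competitive-alignment behavior on loci known to be
#' uninverted: the per-junction coverage distribution (type-7 quartiles
#' and IQR, which anchor the coverage fence used by
#' [validate_inversion()]), the distribution of inverted fractions, and
#' the empirical misassignment rate — the fraction of null junctions
#' that survive the coverage filters and still exceed the
#' inverted-fraction decision threshold.
#'
#' @param null_assignments list of read-assignment data.frames (one per
#'   artificial breakpoint pair, as from [assign_reads()]), or a
#'   precomputed per-junction stats data.frame with columns `coverage`
#'   and `inverted_fraction`.
#' @param min_frac decision threshold on the inverted fraction
#'   (default 0.37).
#' @param min_cov minimum coverage (default 10).
#' @param fence IQR multiplier for the upper coverage fence
#'   (default 2).
#' @param tail apply the coverage fence to the upper tail only
#'   (default) or to both tails.
#' @return A `null_calibration` object: `n_regions`, `coverage`
#'   (vector), `quartiles`, `iqr`, `inverted_fraction` (vector),
#'   `misassignment_rate`, and the thresholds used.
#' @export
calibrate_null <- function(null_assignments, min_frac = 0.37,
                           min_cov = 10, fence = 2.0,
                           tail = c("upper", "both")) {
  tail <- match.arg(tail)
  stats <- if (is.data.frame(null_assignments)) null_assignments
  else do.call(rbind, lapply(null_assignments, breakpoint_stats))
  if (!nrow(stats) || all(stats$coverage == 0))
    stop("null calibration failure: no coverage on artificial breakpoints")
  q <- quantile(stats$coverage, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  hi <- q[3] + fence * iqr
  lo <- if (tail == "both") q[1] - fence * iqr else -Inf
  kept <- stats$coverage >= min_cov & stats$coverage <= hi &
    stats$coverage >= lo
  frac <- stats$inverted_fraction
  miss <- mean(frac[kept] > min_frac, na.rm = TRUE)
  structure(list(n_regions = nrow(stats) / 2,
                 coverage = stats$coverage,
                 quartiles = setNames(q, c("q1", "q2", "q3")),
                 iqr = iqr,
                 inverted_fraction = frac,
                 misassignment_rate = miss,
                 min_frac = min_frac, min_cov = min_cov, fence = fence,
                 tail = tail),
            class = "null_calibration")
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf(paste0("null_calibration: %d regions, coverage Q1/Q2/Q3 = ",
                     "%.1f/%.1f/%.1f, misassignment rate = %.4f\n"),
              x$n_regions, x$quartiles[1], x$quartiles[2], x$quartiles[3],
              x$misassignment_rate))
  invisible(x)
}

#' Decide inversion validity from breakpoint read assignments
#'
#' Applies the long-read decision rule: a junction is discarded when its
#' coverage (ref + inv assigned reads) is below `min_cov` or beyond the
#' null coverage fence (Q3 + `fence` x IQR of the null coverage
#' distribution); a surviving junction passes when its inverted fraction
#' exceeds `min_frac` (strictly). The inversion is valid only when both
#' junctions pass.
#'
#' @param assignments read assignments from [assign_reads()] for one
#'   inversion (both breakpoints).
#' @param null a [calibrate_null()] object.
#' @param min_cov,fence,min_frac decision thresholds (defaults 10, 2.0,
#'   0.37).
#' @param tail coverage fence on the upper tail only (default) or both.
#' @return A `validation_result`: per-breakpoint table (`coverage`,
#'   `inverted_fraction`, `coverage_pass`, `fraction_pass`),
#'   `overall_valid`, `method = "long_read"`, and `reason` when no
#'   coverage was seen.
#' @export
validate_inversion <- function(assignments, null, min_cov = 10,
                               fence = 2.0, min_frac = 0.37,
                               tail = c("upper", "both")) {
  tail <- match.arg(tail)
  st <- breakpoint_stats(assignments)
  hi <- null$quartiles[["q3"]] + fence * null$iqr
  lo <- if (tail == "both") null$quartiles[["q1"]] - fence * null$iqr
  else -Inf
  st$coverage_pass <- st$coverage >= min_cov & st$coverage <= hi &
    st$coverage >= lo
  st$fraction_pass <- !is.na(st$inverted_fraction) &
    st$inverted_fraction > min_frac
  valid <- all(st$coverage_pass & st$fraction_pass)
  structure(list(breakpoints = st,
                 overall_valid = valid,
                 method = "long_read",
                 reason = if (all(st$coverage == 0)) "no coverage" else NA),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("validation_result (%s): %s\n", x$method,
              if (x$overall_valid) "VALID" else "not validated"))
  print(x$breakpoints)
  invisible(x)
}

#' Classify a reassembled supercontig's junction pattern
#'
#' Given ordered alignment segments of one supercontig against the
#' reference, decides whether the supercontig reconstructs an inverted
#' junction: two adjacent segments joining the same-side flanks of the
#' two breakpoints (both upstream, or both downstream) with opposite
#' strands. Segments are pre-filtered to alignment scores above
#' `min_score`; supercontigs of 10 kb or less are not considered.
#'
#' @param segments data.frame of ordered segments with columns `chrom`,
#'   `start`, `end` (target interval), `strand` ("+"/"-"), `score`.
#' @param call inversion call (`chrom`, `start`, `end`).
#' @param flank flank length defining the breakpoint neighborhoods.
#' @param min_score score threshold (default 60, strict).
#' @param contig_length supercontig length in bp (checked against the
#'   10-kb rule when provided).
#' @return list with `supports_bp1`, `supports_bp2`,
#'   `supports_inversion` (either junction reconstructed).
#' @export
classify_supercontig <- function(segments, call, flank = 10000,
                                 min_score = 60, contig_length = NULL) {
  no <- list(supports_bp1 = FALSE, supports_bp2 = FALSE,
             supports_inversion = FALSE)
  if (!is.null(contig_length) && contig_length <= 10000) return(no)
  seg <- segments[segments$score > min_score, , drop = FALSE]
  if (nrow(seg) < 2) return(no)
  s <- call$start; e <- call$end
  regions <- data.frame(
    label = c("bp1_up", "bp1_down", "bp2_up", "bp2_down"),
    start = c(s - flank, s, e - flank, e),
    end = c(s, s + flank, e, e + flank))
  lab <- vapply(seq_len(nrow(seg)), function(i) {
    if (seg$chrom[i] != call$chrom) return(NA_character_)
    ov <- pmax(pmin(seg$end[i], regions$end) -
                 pmax(seg$start[i], regions$start), 0)
    if (all(ov == 0)) return(NA_character_)
    regions$label[which.max(ov)]
  }, "")
  supports <- c(bp1 = FALSE, bp2 = FALSE)
  for (i in seq_len(nrow(seg) - 1)) {
    a <- lab[i]; b <- lab[i + 1]
    if (is.na(a) || is.na(b)) next
    if (seg$strand[i] == seg$strand[i + 1]) next
    pair <- sort(c(a, b))
    if (identical(pair, c("bp1_up", "bp2_up"))) supports[["bp1"]] <- TRUE
    if (identical(pair, c("bp1_down", "bp2_down"))) supports[["bp2"]] <- TRUE
  }
  list(supports_bp1 = supports[["bp1"]], supports_bp2 = supports[["bp2"]],
       supports_inversion = any(supports))
}

#' Assembly-based validation across supercontigs
#'
#' An inversion is assembly-validated when, across all supercontigs,
#' both inverted junctions are reconstructed.
#'
#' @param segment_list list of per-supercontig segment data.frames (see
#'   [classify_supercontig()]); may carry `contig_length` attributes.
#' @param call inversion call.
#' @param ... passed to [classify_supercontig()].
#' @return list with `supports_bp1`, `supports_bp2`, `overall_valid`,
#'   `method = "assembly"`.
#' @export
validate_by_assembly <- function(segment_list, call, ...) {
  res <- lapply(segment_list, function(seg)
    classify_supercontig(seg, call,
                         contig_length = attr(seg, "contig_length"), ...))
  bp1 <- any(vapply(res, `[[`, TRUE, "supports_bp1"))
  bp2 <- any(vapply(res, `[[`, TRUE, "supports_bp2"))
  list(supports_bp1 = bp1, supports_bp2 = bp2,
       overall_valid = bp1 && bp2, method = "assembly")
}
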