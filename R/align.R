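#' Built-in k-mer seed aligner
#'
#' A lightweight competitive aligner for long reads against a handful of
#' junction contigs: exact k-mer seeds, diagonal-band voting, score =
#' seed hits on the best band. Tolerates percent-scale substitution
#' error. External aligners can be plugged in instead through
#' [table_aligner()].
#'
#' @param k seed length (<= 32).
#' @param step query seed stride (larger = faster, less sensitive).
#' @param max_occ contig k-mers occurring more often than this are
#'   treated as repeats and ignored.
#' @param bandwidth diagonal band width in bp.
#' @return An aligner object with an `align(reads, contigs)` method
#'   returning one row per read/contig hit: `read`, `contig` (names),
#'   `score`, `qstart`, `qend`, `tstart`, `tend` (0-based half-open),
#'   `strand`.
#' @export
kmer_aligner <- function(k = 15, step = 3, max_occ = 8, bandwidth = 64) {
  align <- function(reads, contigs) {
    hits <- .kmer_align_cpp(unname(reads), unname(contigs),
                            k = k, step = step, max_occ = max_occ,
                            bandwidth = bandwidth)
    hits$read <- names(reads)[hits$read]
    hits$contig <- names(contigs)[hits$contig]
    hits
  }
  structure(list(align = align, kind = "kmer"), class = "aligner")
}

#' Adapter for precomputed alignment records
#'
#' Wraps a PAF-like table (columns `read`, `contig`, `score`, `qstart`,
#' `qend`, `tstart`, `tend`, `strand`) produced by an external long-read
#' aligner so it can be used wherever the built-in aligner is.
#'
#' @param records data.frame of alignment records.
#' @return An aligner object.
#' @export
table_aligner <- function(records) {
  need <- c("read", "contig", "score", "tstart", "tend", "strand")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  align <- function(reads, contigs) {
    records[records$read %in% names(reads) &
              records$contig %in% names(contigs), , drop = FALSE]
  }
  structure(list(align = align, kind = "table"), class = "aligner")
}

#' Competitively assign long reads to breakpoint junction contigs
#'
#' Reads longer than `min_read_len` are aligned against all pan-genome
#' contigs. Each read goes to the contig with the best score; reads best
#' explained by the masked background are `unassigned`, exact score ties
#' between the reference and inverted contig of the same breakpoint are
#' `ambiguous`, and an assignment only counts as `ref`/`inv` when the
#' alignment extends at least `min_span` bp beyond the junction point on
#' both sides (the dual-span rule).
#'
#' @param reads named character vector of read sequences.
#' @param pangenome a [build_pangenome()] object.
#' @param aligner an aligner object (default [kmer_aligner()]).
#' @param min_read_len reads at or below this length are dropped
#'   (default 5000; "longest reads (> 5 kb)").
#' @param min_span dual-span requirement in bp (default 1000).
#' @return data.frame: `read`, `breakpoint` ("bp1"/"bp2"/NA),
#'   `orientation` ("ref"/"inv"/"ambiguous"/"unassigned"),
#'   `left_span`, `right_span`, `score`.
#' @export
assign_reads <- function(reads, pangenome, aligner = kmer_aligner(),
                         min_read_len = 5000, min_span = 1000) {
  reads <- reads[nchar(reads) > min_read_len]
  if (!length(reads))
    return(data.frame(read = character(), breakpoint = character(),
                      orientation = character(), left_span = numeric(),
                      right_span = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  out <- data.frame(read = names(reads),
                    breakpoint = NA_character_,
                    orientation = "unassigned",
                    left_span = 0, right_span = 0, score = 0,
                    stringsAsFactors = FALSE)
  hits <- tryCatch(aligner$align(reads, pangenome$contigs),
                   error = function(e) {
                     warning("aligner failure: ", conditionMessage(e))
                     NULL
                   })
  if (is.null(hits) || nrow(hits) == 0) return(out)
  jat <- pangenome$junction_at
  for (i in seq_len(nrow(out))) {
    h <- hits[hits$read == out$read[i], , drop = FALSE]
    if (!nrow(h)) next
    best <- max(h$score)
    winners <- h$contig[h$score == best]
    if (all(winners == "background")) next  # stays unassigned
    winners <- setdiff(winners, "background")
    bp <- sub("_(ref|inv)$", "", winners)
    ori <- sub("^bp[12]_", "", winners)
    out$score[i] <- best
    # dual-span rule first: an alignment that does not extend min_span
    # beyond the junction on both sides never gets an orientation
    w <- winners[1]
    hw <- h[h$contig == w & h$score == best, , drop = FALSE][1, ]
    left <- jat[[w]] - hw$tstart
    right <- hw$tend - jat[[w]]
    out$breakpoint[i] <- bp[1]
    out$left_span[i] <- max(left, 0)
    out$right_span[i] <- max(right, 0)
    if (left < min_span || right < min_span) next  # unassigned
    if (length(unique(ori)) > 1) {  # ref/inv tie -> ambiguous
      out$orientation[i] <- "ambiguous"
    } else {
      out$orientation[i] <- ori[1]
    }
  }
  out
}

## per-breakpoint coverage and inverted fraction from read assignments;
## ambiguous reads are excluded from numerator and denominator
breakpoint_stats <- function(assignments) {
  do.call(rbind, lapply(c("bp1", "bp2"), function(bp) {
    a <- assignments[assignments$breakpoint %in% bp, , drop = FALSE]
    n_ref <- sum(a$orientation == "ref")
    n_inv <- sum(a$orientation == "inv")
    data.frame(breakpoint = bp, n_ref = n_ref, n_inv = n_inv,
               coverage = n_ref + n_inv,
               inverted_fraction = if (n_ref + n_inv > 0)
                 n_inv / (n_ref + n_inv) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
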