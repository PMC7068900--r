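#' Reverse complement of a DNA string
#' @param x character scalar (A/C/G/T/N).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## 0-based half-open substring of a chromosome string
seq_slice <- function(chrom_seq, start, end) {
  substr(chrom_seq, start + 1, end)
}

#' Build a pan-genome alignment target for one inversion call
#'
#' For an inversion of segment `[s, e)` with flank length `F`, four
#' junction contigs of length `2F` are constructed:
#' \itemize{
#'   \item `bp1_ref = seq[s-F:s+F]`, `bp2_ref = seq[e-F:e+F]` — the
#'     reference-orientation junctions;
#'   \item `bp1_inv = seq[s-F:s] ++ revcomp(seq[e-F:e])` and
#'     `bp2_inv = revcomp(seq[s:s+F]) ++ seq[e:e+F]` — the junctions an
#'     inverted allele would carry.
#' }
#' Optionally the full chromosome is included as a competing background
#' with both true breakpoint neighborhoods masked to `N`, so reads from
#' elsewhere are not forced onto a junction contig.
#'
#' @param reference named character vector of chromosome sequences.
#' @param call list/row with `chrom`, `start` (s), `end` (e) — 0-based
#'   half-open inversion segment.
#' @param flank flank length F in bp (>= `min_flank`).
#' @param background include the masked chromosome contig?
#' @param min_flank smallest allowed flank (default 1 kb, which keeps
#'   the dual-span rule satisfiable; relax only for toy sequences).
#' @return A `pangenome` object: `contigs` (named character),
#'   `junction_at` (0-based junction offset within each junction contig),
#'   plus the call and flank.
#' @export
build_pangenome <- function(reference, call, flank = 10000,
                            background = TRUE, min_flank = 1000) {
  if (flank < min_flank)
    stop("flank must be at least ", min_flank, " bp")
  chrom_seq <- reference[[call$chrom]]
  if (is.null(chrom_seq)) stop("chromosome not in reference: ", call$chrom)
  len <- nchar(chrom_seq)
  s <- call$start; e <- call$end
  if (e - s < flank)
    warning("inversion shorter than flank; junction flanks overlap")
  fl <- flank; fr <- flank
  if (s - fl < 0 || e + fr > len) {
    warning("flank truncated at chromosome end")
    fl <- min(fl, s)
    fr <- min(fr, len - e)
  }
  # inner flanks keep the full length F; when the inverted segment is
  # shorter than F the inner flanks of the two junctions overlap (warned
  # above), mirroring how short inversions are handled in practice
  fi1 <- min(flank, e)        # left extent of seq[e-F:e]
  fi2 <- min(flank, len - s)  # right extent of seq[s:s+F]
  contigs <- c(
    bp1_ref = paste0(seq_slice(chrom_seq, s - fl, s),
                     seq_slice(chrom_seq, s, s + fi2)),
    bp2_ref = paste0(seq_slice(chrom_seq, e - fi1, e),
                     seq_slice(chrom_seq, e, e + fr)),
    bp1_inv = paste0(seq_slice(chrom_seq, s - fl, s),
                     revcomp(seq_slice(chrom_seq, e - fi1, e))),
    bp2_inv = paste0(revcomp(seq_slice(chrom_seq, s, s + fi2)),
                     seq_slice(chrom_seq, e, e + fr)))
  junction_at <- c(bp1_ref = fl, bp2_ref = fi1, bp1_inv = fl, bp2_inv = fi2)
  bg <- NULL
  if (background) {
    bg <- chrom_seq
    mask <- function(seq, a, b) {
      a <- max(a, 0); b <- min(b, len)
      paste0(substr(seq, 1, a), strrep("N", b - a),
             substr(seq, b + 1, len))
    }
    bg <- mask(bg, s - fl, s + fi2)
    bg <- mask(bg, e - fi1, e + fr)
    contigs <- c(contigs, background = bg)
  }
  structure(list(contigs = contigs, junction_at = junction_at,
                 call = list(chrom = call$chrom, start = s, end = e),
                 flank = flank),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat(sprintf("pangenome for %s:%d-%d (flank %d bp, %d contigs)\n",
              x$call$chrom, x$call$start, x$call$end, x$flank,
              length(x$contigs)))
  invisible(x)
}
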