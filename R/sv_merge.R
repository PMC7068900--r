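#' Read per-sample, per-caller inversion candidates
#'
#' @param path TSV with columns `chrom`, `start`, `end` (0-based
#'   half-open), `sample`, `caller` and optional `quality`.
#' @return data.frame of candidates.
#' @export
read_candidates <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  need <- c("chrom", "start", "end", "sample", "caller")
  if (!all(need %in% names(x)))
    stop("candidate table needs columns: ", paste(need, collapse = ", "))
  if (any(!nzchar(x$caller))) stop("empty caller label")
  genomic_intervals(x$chrom, x$start, x$end, sample = x$sample,
                    caller = x$caller)
}

#' Merge inversion candidates into call loci by reciprocal overlap
#'
#' Candidates from all samples and callers are clustered by single
#' linkage: two candidates are linked when their reciprocal overlap
#' (minimum of the two intersection fractions) reaches `threshold`, and
#' clusters are the connected components of that link graph. Each merged
#' call records its member candidates, the supporting caller and sample
#' sets, the union span, median breakpoints, and a size class
#' (micro = size below `micro_max` bp).
#'
#' @param candidates data.frame from [read_candidates()] (columns
#'   `chrom`, `start`, `end`, `sample`, `caller`).
#' @param threshold reciprocal-overlap fraction required to link two
#'   candidates (default 0.95).
#' @param micro_max size bound for the "micro" class, exclusive
#'   (default 500 kb).
#' @param arm_of optional function(chrom, pos) -> arm letter used in call
#'   ids (default: "q").
#' @return data.frame of calls, ordered by (chrom, start), with columns
#'   `id`, `chrom`, `start`, `end`, `size`, `is_micro`, `n_members`,
#'   `callers`, `samples`, `n_samples`, `bp1`, `bp2` (median member
#'   endpoints), plus a `members` list-column of member row indices.
#' @export
merge_candidates <- function(candidates, threshold = 0.95,
                             micro_max = 5e5, arm_of = NULL) {
  n <- nrow(candidates)
  if (n == 0) return(empty_calls())
  ord <- order(candidates$chrom, candidates$start, candidates$end,
               candidates$sample, candidates$caller)
  cand <- candidates[ord, , drop = FALSE]
  # sweep within chromosome: only candidates whose spans intersect can
  # reach 95% reciprocal overlap, so compare each to the ones that start
  # before it ends
  edges <- matrix(integer(0), ncol = 2)
  for (ch in unique(cand$chrom)) {
    idx <- which(cand$chrom == ch)
    for (a in seq_along(idx)[-1]) {
      i <- idx[a]
      for (b in seq_len(a - 1)) {
        j <- idx[b]
        if (cand$end[j] <= cand$start[i]) next
        ro <- reciprocal_overlap(cand[i, ], cand[j, ])
        if (ro >= threshold) edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_len(n)),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  cluster_of <- comp[as.character(seq_len(n))]

  rows <- lapply(split(seq_len(n), cluster_of), function(m) {
    span_start <- min(cand$start[m]); span_end <- max(cand$end[m])
    data.frame(chrom = cand$chrom[m[1]], start = span_start, end = span_end,
               size = span_end - span_start,
               n_members = length(m),
               callers = paste(sort(unique(cand$caller[m])), collapse = ","),
               samples = paste(sort(unique(cand$sample[m])), collapse = ","),
               n_samples = length(unique(cand$sample[m])),
               bp1 = median(cand$start[m]), bp2 = median(cand$end[m]),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  # report members as row indices into the caller's candidate table
  members <- lapply(split(seq_len(n), cluster_of), function(m) sort(ord[m]))
  o <- order(calls$chrom, calls$start, calls$end)
  calls <- calls[o, , drop = FALSE]
  calls$members <- unname(members[o])
  calls$is_micro <- calls$size < micro_max
  calls$id <- call_ids(calls, arm_of)
  rownames(calls) <- NULL
  calls[, c("id", "chrom", "start", "end", "size", "is_micro", "n_members",
            "callers", "samples", "n_samples", "bp1", "bp2", "members")]
}

empty_calls <- function() {
  data.frame(id = character(), chrom = character(), start = numeric(),
             end = numeric(), size = numeric(), is_micro = logical(),
             n_members = integer(), callers = character(),
             samples = character(), n_samples = integer(),
             bp1 = numeric(), bp2 = numeric())
}

## ids follow the arm-letter convention: <chrom><arm><letter...>, letters
## assigned alphabetically in coordinate order within each chromosome
## ("aa".."az","ba",... after "a".."z" is exhausted per arm).
call_ids <- function(calls, arm_of = NULL) {
  if (is.null(arm_of)) arm_of <- function(chrom, pos) "q"
  arms <- mapply(arm_of, calls$chrom, (calls$start + calls$end) / 2)
  keyv <- paste0(calls$chrom, arms)
  ids <- character(nrow(calls))
  for (key in unique(keyv)) {
    sel <- which(keyv == key)
    ids[sel] <- paste0(key, letter_series(length(sel)))
  }
  ids
}

letter_series <- function(n) {
  single <- letters
  if (n <= 26) return(single[seq_len(n)])
  extra <- as.vector(t(outer(letters, letters, paste0)))
  c(single, extra)[seq_len(n)]
}

#' Summarize merged inversion calls
#'
#' @param calls data.frame from [merge_candidates()] or
#'   [read_inversion_catalogue()].
#' @return list with `n_total`, `n_micro`, `n_large`,
#'   `n_singleton_sample` (calls seen in exactly one sample),
#'   `per_caller` (named vector counting calls supported by each caller),
#'   and `n_concordant` (calls with at least two distinct callers).
#' @export
classify_and_count <- function(calls) {
  caller_sets <- strsplit(calls$callers, ",", fixed = TRUE)
  per_caller <- table(unlist(lapply(caller_sets, unique)))
  list(n_total = nrow(calls),
       n_micro = sum(calls$is_micro),
       n_large = sum(!calls$is_micro),
       n_singleton_sample = if ("n_samples" %in% names(calls))
         sum(calls$n_samples == 1) else NA_integer_,
       per_caller = setNames(as.integer(per_caller), names(per_caller)),
       n_concordant = sum(vapply(caller_sets,
                                 function(x) length(unique(x)) >= 2, TRUE)))
}

#' Read a published-style inversion catalogue table
#'
#' Parses call tables in the layout used for validated inversion
#' catalogues: columns `Inversion` (arm-letter id), `Position`
#' ("chrom:start-end"), `Size`, `Micro` (`*` or empty), `Prog`
#' (supporting caller(s)), `Validation` (Assembly / Long-read align /
#' Both). Sizes are recomputed from the position strings as end - start.
#'
#' @param path TSV path.
#' @return calls data.frame compatible with [classify_and_count()], with
#'   extra columns `size_printed`, `validation`.
#' @export
read_inversion_catalogue <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("Inversion", "Position", "Size", "Micro", "Prog", "Validation")
  if (!all(need %in% names(x)))
    stop("catalogue needs columns: ", paste(need, collapse = ", "))
  iv <- parse_position_strings(x$Position)
  callers <- x$Prog
  callers[callers == "Both"] <- "GROC-SVs,Long Ranger"
  data.frame(id = x$Inversion, chrom = iv$chrom, start = iv$start,
             end = iv$end, size = iv$size,
             is_micro = x$Micro %in% "*",
             callers = callers,
             size_printed = as.numeric(x$Size),
             validation = x$Validation,
             stringsAsFactors = FALSE)
}

#' Write merged calls as a catalogue-style TSV and BED track
#'
#' @param calls data.frame from [merge_candidates()].
#' @param tsv,bed output paths (either may be `NULL` to skip).
#' @return invisibly, the `tsv` path.
#' @export
write_inversion_calls <- function(calls, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    out <- data.frame(Inversion = calls$id,
                      Position = sprintf("%s:%d-%d", calls$chrom,
                                         as.integer(calls$start),
                                         as.integer(calls$end)),
                      Size = calls$size,
                      Micro = ifelse(calls$is_micro, "*", ""),
                      Prog = calls$callers,
                      Samples = calls$samples)
    write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed)) {
    bedt <- data.frame(calls$chrom, as.integer(calls$start),
                       as.integer(calls$end), calls$id)
    write.table(bedt, bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(tsv)
}
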