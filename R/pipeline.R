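#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read sequences from FASTA as a named character vector
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects all stage parameters with their standard defaults: filters
#' (QD > 5, FS < 60, |RankSum| < 8), candidate merging (0.95 reciprocal
#' overlap, 500-kb micro bound), validation (10-kb flanks, reads > 5 kb,
#' 1-kb dual span, coverage >= 10, Q3 + 2xIQR fence, > 37% inverted
#' fraction, 1000 null loci), popgen (1-Mb windows, AIM F_st > 0.8),
#' introgression (5-Mb jackknife blocks, |Z| >= 2, 1-Mb fD windows,
#' Q3 + 1.5xIQR peak fence, 90% of the local maximum over a 200-Mb
#' neighborhood — scale `peak_local_window` with the genome), phylogeny
#' (100 bootstraps).
#'
#' @param sim a [sim_config()] for the simulate stage.
#' @param quartet list(p1, p2, p3, outgroup) of colony names for the
#'   introgression stage.
#' @param ... overrides for any default listed above.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), quartet = NULL, ...) {
  cfg <- list(
    sim = sim,
    quartet = quartet,
    filters = filter_config(),
    merge_threshold = 0.95, micro_max = 5e5,
    flank = 10000, min_read_len = 5000, min_span = 1000,
    n_null = 1000, min_cov = 10, fence = 2.0, min_frac = 0.37,
    coverage = 30,
    window = 1e6, aim_fst_min = 0.8,
    # jackknife blocks and the peak neighborhood scale with the genome:
    # at the toy 1/100 scale the 5-Mb blocks and 200-Mb neighborhood of
    # full-genome analyses become 1 Mb / 2 Mb
    block_size = 1e6, z_min = 2,
    peak_fence = 1.5, peak_local_window = 2e6, peak_local_frac = 0.9,
    n_bootstrap = 100, tree_sites = 2000,
    seed = sim$seed)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Stages run in order — simulate, filter, callsets, merge, validate,
#' popgen, introgression, phylogeny — each writing its artifacts to the
#' run directory; already-present stage outputs are reused (making
#' reruns idempotent and resumable). A machine-readable `summary.json`
#' collects the headline numbers (call counts by class, validation
#' tally, D/Z, fD peak count), and `log.txt` records parameters and
#' seeds.
#'
#' @param config a [pipeline_config()].
#' @param run_dir output directory (created if needed).
#' @param stages subset of stages to run (default all).
#' @return the summary list, invisibly; artifacts under `run_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         run_dir = tempfile("invintro_run_"),
                         stages = c("simulate", "merge", "validate",
                                    "popgen", "introgression",
                                    "phylogeny")) {
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(run_dir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", file = logf,
                               append = TRUE)
  logline("invintro pipeline, seed %d", config$seed)
  summary <- list(seed = config$seed)

  stage <- function(name, fn) {
    if (!name %in% stages) return(NULL)
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logline("stage %s done in %.1fs", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  ds <- stage("simulate", function() {
    ds <- simulate_colony_dataset(config$sim)
    write_fasta(ds$reference$sequences,
                file.path(run_dir, "reference.fasta"))
    write_tsv(ds$reference$repeats, file.path(run_dir, "repeats.bed"))
    write_panel_vcf(ds$panel, file.path(run_dir, "panel.vcf"))
    write_tsv(ds$candidates, file.path(run_dir, "candidates.tsv"))
    write_tsv(ds$spiked$inversions,
              file.path(run_dir, "truth_inversions.tsv"))
    ds
  })
  if (is.null(ds)) stop("the simulate stage is required by later stages")

  calls <- stage("merge", function() {
    calls <- merge_candidates(ds$candidates,
                              threshold = config$merge_threshold,
                              micro_max = config$micro_max)
    write_inversion_calls(calls, file.path(run_dir, "calls.tsv"),
                          file.path(run_dir, "calls.bed"))
    cc <- classify_and_count(calls)
    summary$calls <<- cc[c("n_total", "n_micro", "n_large",
                           "n_singleton_sample", "n_concordant")]
    calls
  })

  stage("validate", function() {
    null_sim <- simulate_null_assignments(
      ds$reference, ds$reference$repeats, calls,
      n = config$n_null, flank = config$flank,
      coverage = config$coverage, error_rate = config$sim$read_error,
      n50 = config$sim$read_n50, seed = config$seed + 10)
    null <- calibrate_null(null_sim$stats, min_frac = config$min_frac,
                           min_cov = config$min_cov,
                           fence = config$fence)
    results <- validate_calls(ds, calls, null, config)
    write_tsv(results, file.path(run_dir, "validation.tsv"))
    summary$validation <<- list(
      n_valid = sum(results$overall_valid),
      null_misassignment_rate = null$misassignment_rate)
    results
  })

  stage("popgen", function() {
    colonies <- setdiff(unique(ds$panel$colony_of), "Mascarensis")
    pis <- vapply(colonies, function(co) {
      w <- window_diversity(ds$panel, co, window = config$window,
                            chrom_lengths = config$sim$chrom_lengths)
      mean(w$value)
    }, 1)
    write_tsv(data.frame(colony = colonies, pi = pis),
              file.path(run_dir, "pi.tsv"))
    summary$popgen <<- list(mean_pi = mean(pis))
  })

  stage("introgression", function() {
    qt <- config$quartet
    if (is.null(qt))
      qt <- list(p1 = c("Thailand_Aaa", "USA_Aaa"), p2 = "Kenya_Aaa",
                 p3 = c("Uganda_Aaf", "Gabon_Aaf", "Kenya_Aaf"),
                 outgroup = "Mascarensis")
    fr <- quartet_freqs(ds$panel, qt$p1, qt$p2, qt$p3, qt$outgroup)
    d <- patterson_d(fr, block_size = config$block_size,
                     z_min = config$z_min)
    track <- martin_fd(fr, window = config$window,
                       chrom_lengths = config$sim$chrom_lengths)
    peaks <- detect_peaks(track, fence = config$peak_fence,
                          local_window = config$peak_local_window,
                          local_frac = config$peak_local_frac)
    write_tsv(track, file.path(run_dir, "fd_track.tsv"))
    write_tsv(peaks, file.path(run_dir, "fd_peaks.tsv"))
    summary$introgression <<- list(d = d$d, z = d$z,
                                   significant = d$significant,
                                   n_peaks = nrow(peaks))
  })

  stage("phylogeny", function() {
    aln <- representative_alignment(ds$panel, seed = config$seed)
    aln <- aln[, colSums(is.na(aln)) == 0, drop = FALSE]
    nsites <- min(ncol(aln), config$tree_sites)
    set.seed(config$seed)
    aln <- snp_alignment(aln[, sample.int(ncol(aln), nsites),
                             drop = FALSE])
    bt <- bootstrap_support(aln, n_reps = config$n_bootstrap,
                            seed = config$seed, n_restarts = 1)
    ape::write.tree(bt$tree, file.path(run_dir, "genome_tree.nwk"))
    summary$phylogeny <<- list(n_taxa = nrow(aln),
                               mean_support = mean(bt$support))
  })

  jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

## long-read validation of merged calls on the synthetic dataset: reads
## are simulated from carrier (or reference, for non-carried loci)
## haplotypes around both breakpoints and competitively assigned
validate_calls <- function(ds, calls, null, config) {
  out <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    pg <- build_pangenome(ds$reference$sequences, call,
                          flank = config$flank, background = FALSE)
    carriers <- ds$spiked$carriers
    truth_id <- truth_id_for(ds$spiked$inversions, call)
    carried <- carriers[!is.na(truth_id) & carriers$id %in% truth_id, ]
    asn <- simulate_call_reads(ds, call, carried, pg, config)
    v <- validate_inversion(asn, null, min_cov = config$min_cov,
                            fence = config$fence,
                            min_frac = config$min_frac)
    data.frame(id = call$id, chrom = call$chrom, start = call$start,
               end = call$end, is_true = !is.na(truth_id),
               overall_valid = v$overall_valid,
               bp1_frac = v$breakpoints$inverted_fraction[1],
               bp2_frac = v$breakpoints$inverted_fraction[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## match a merged call back to a truth inversion by reciprocal overlap
truth_id_for <- function(truth_inv, call, threshold = 0.9) {
  ro <- vapply(seq_len(nrow(truth_inv)), function(j)
    reciprocal_overlap(call, truth_inv[j, ]), 1)
  if (any(ro >= threshold)) truth_inv$id[which.max(ro)] else NA_character_
}

## simulate breakpoint-spanning reads for one call: half the sampled
## haplotypes are carriers when the locus is truly inverted
simulate_call_reads <- function(ds, call, carried, pg, config,
                                read_window = 8000) {
  seqs <- ds$reference$sequences
  chrom_seq <- seqs[[call$chrom]]
  len <- nchar(chrom_seq)
  reads <- character()
  carrier_frac <- if (nrow(carried)) 0.5 else 0
  for (j in c(call$start, call$end)) {
    lo <- max(0, j - read_window); hi <- min(len, j + read_window)
    refpart <- simulate_long_reads(
      seq_slice(chrom_seq, lo, hi),
      coverage = config$coverage * (1 - carrier_frac),
      n50 = config$sim$read_n50, error_rate = config$sim$read_error,
      seed = config$seed + 1000 + round(j %% 997),
      prefix = sprintf("ref_%d", j))
    reads <- c(reads, refpart)
    if (carrier_frac > 0) {
      hapseq <- inverted_region_sequence(chrom_seq, call, lo, hi)
      invpart <- simulate_long_reads(
        hapseq, coverage = config$coverage * carrier_frac,
        n50 = config$sim$read_n50, error_rate = config$sim$read_error,
        seed = config$seed + 2000 + round(j %% 997),
        prefix = sprintf("inv_%d", j))
      reads <- c(reads, invpart)
    }
  }
  assign_reads(reads, pg, min_read_len = config$min_read_len,
               min_span = config$min_span)
}

## the carrier haplotype's local sequence around one junction window:
## reference with the called segment reverse-complemented
inverted_region_sequence <- function(chrom_seq, call, lo, hi) {
  s <- call$start; e <- call$end
  seg <- revcomp(seq_slice(chrom_seq, s, e))
  full <- paste0(seq_slice(chrom_seq, 0, s), seg,
                 seq_slice(chrom_seq, e, nchar(chrom_seq)))
  # junction windows on the inverted haplotype share coordinates with
  # the reference for bp1 (left of s is unchanged) and for bp2 (right
  # of e unchanged), so the same [lo,hi) slice spans the junction
  seq_slice(full, lo, hi)
}
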