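# Shared fixtures: tiny hand-built panels, a cached default synthetic
# dataset, and ground-truth helpers. Everything is built in code at test
# time.

make_panel <- function(a1, a2, colony_of, pos = NULL, chrom = "1",
                       phased = TRUE, role_of = character(), ...) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (is.null(pos)) pos <- seq_len(nrow(a1)) * 10
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                      stringsAsFactors = FALSE, ...)
  genotype_panel(sites, a1, a2, names(colony_of), colony_of, role_of,
                 phased = phased)
}

.fixture_env <- new.env(parent = emptyenv())

## default synthetic dataset, built once per test run
default_dataset <- function(seed = 1) {
  key <- paste0("ds", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_colony_dataset(sim_config(seed = seed))
  .fixture_env[[key]]
}

## intervals of tracts shared by every haplotype of a recipient colony
shared_tract_intervals <- function(ds, recipient = "Kenya_Aaa",
                                   donor = "Kenya_Aaf") {
  tt <- ds$truth$tracts
  tt <- tt[tt$donor == donor &
             ds$panel$colony_of[tt$sample] == recipient, , drop = FALSE]
  nh <- 2 * sum(ds$panel$colony_of == recipient)
  cnt <- table(paste(tt$chrom, tt$start, tt$end))
  keys <- names(cnt)[cnt == nh]
  if (!length(keys)) return(NULL)
  sk <- do.call(rbind, lapply(strsplit(keys, " "), function(x)
    data.frame(chrom = x[1], start = as.numeric(x[2]),
               end = as.numeric(x[3]), stringsAsFactors = FALSE)))
  invintro:::merge_intervals(sk)
}

## the study-layout quartet used on synthetic data: pure Aaa vs the
## hybrid-zone Aaa colony, all Aaf colonies as donor pool
default_quartet_freqs <- function(ds) {
  quartet_freqs(ds$panel, p1 = c("Thailand_Aaa", "USA_Aaa"),
                p2 = "Kenya_Aaa",
                p3 = c("Uganda_Aaf", "Gabon_Aaf", "Kenya_Aaf"),
                outgroup = "Mascarensis")
}

## brute-force single-linkage clustering by reciprocal overlap (oracle)
brute_force_clusters <- function(cand, threshold = 0.95) {
  n <- nrow(cand)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- i == j ||
      reciprocal_overlap(cand[i, ], cand[j, ]) >= threshold
  # transitive closure
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  # canonical labels: smallest member index
  apply(adj, 1, function(r) min(which(r)))
}

## exhaustive minimal parsimony score over all unrooted topologies
brute_force_mp <- function(aln) {
  trees <- phangorn::allTrees(nrow(aln), rooted = FALSE,
                              tip.label = rownames(aln))
  min(vapply(trees, function(tr) fitch_score(tr, aln), 1))
}

## the repeat-matched artificial-breakpoint null experiment at study
## conditions (3 x 5 Mb, 30% repeats, 1000 loci, ~30x reads, 5% error),
## computed once and shared by the calibration and rejection checks
cached_null_experiment <- function() {
  if (is.null(.fixture_env$null_exp)) {
    ds <- default_dataset(1)
    calls <- merge_candidates(
      ds$candidates[, c("chrom", "start", "end", "sample", "caller")])
    null_sim <- simulate_null_assignments(
      ds$reference, ds$reference$repeats, calls, n = 1000,
      flank = 10000, coverage = 30, error_rate = 0.05, n50 = 6789,
      seed = 101)
    .fixture_env$null_exp <- list(
      dataset = ds, calls = calls, stats = null_sim$stats,
      null = calibrate_null(null_sim$stats))
  }
  .fixture_env$null_exp
}
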