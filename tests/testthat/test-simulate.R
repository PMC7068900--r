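small_cfg <- function(seed = 5, ...)
  sim_config(seed = seed, chrom_lengths = c(chr1 = 4e5, chr2 = 4e5),
             n_micro = 1, n_large = 0, micro_size_range = c(3e4, 6e4),
             site_spacing = 400, ...)

test_that("the simulated reference is seeded, sized, and repeat-annotated", {
  cfg <- small_cfg()
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$sequences, r2$sequences)  # byte determinism
  expect_identical(r1$repeats, r2$repeats)
  expect_equal(unname(nchar(r1$sequences)), c(4e5, 4e5))
  # configured 30% repeat density realized within 5 points
  covered <- invintro:::merge_intervals(r1$repeats)
  frac <- sum(covered$end - covered$start) / 8e5
  expect_lt(abs(frac - 0.30), 0.05)
  # density 0 -> empty annotation
  r0 <- simulate_reference(small_cfg(repeat_density = 0))
  expect_equal(nrow(r0$repeats), 0)
})

test_that("panels are seeded and admixture truth matches the config", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  p1 <- simulate_panel(cfg, ref)
  p2 <- simulate_panel(cfg, ref)
  expect_identical(p1$panel$a1, p2$panel$a1)
  expect_identical(p1$truth$tracts, p2$truth$tracts)
  # f = 0 everywhere -> no donor tracts in truth
  cfg0 <- small_cfg(admixture = data.frame(donor = character(),
                                           recipient = character(),
                                           fraction = numeric(),
                                           tract_mean = numeric(),
                                           shared = logical()))
  p0 <- simulate_panel(cfg0, ref)
  expect_equal(nrow(p0$truth$tracts), 0)
  # allele frequencies are proper frequencies in every colony
  for (co in unique(p1$panel$colony_of)) {
    af <- allele_freq(p1$panel, colony_samples(p1$panel, co))$freq
    expect_true(all(af >= 0 & af <= 1, na.rm = TRUE))
  }
})

test_that("spiked inversions hit their carrier frequencies and sequences", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  pan <- simulate_panel(cfg, ref)
  inv <- data.frame(chrom = "chr1", start = 1e5, end = 1.6e5,
                    is_micro = TRUE)
  colonies <- unique(pan$panel$colony_of)
  # frequency 1 in one colony, 0 elsewhere
  attr(inv, "freq") <- list(setNames(as.numeric(colonies == "USA_Aaa"),
                                     colonies))
  cfg$inversions <- inv
  sp <- spike_inversions(cfg, ref, pan$panel)
  usa <- colony_samples(pan$panel, "USA_Aaa")
  expect_setequal(sp$carriers$sample, usa)
  expect_equal(nrow(sp$carriers), 2 * length(usa))  # all haplotypes carry
  # carrier sequence equals manual cut - revcomp - paste
  sid <- usa[1]
  hseq <- haplotype_sequence(ref, pan$panel, sid, 1, "chr1", spiked = sp)
  plain <- haplotype_sequence(ref, pan$panel, sid, 1, "chr1")
  manual <- paste0(substr(plain, 1, 1e5),
                   revcomp(substr(plain, 1e5 + 1, 1.6e5)),
                   substring(plain, 1.6e5 + 1))
  expect_identical(hseq, manual)
  # frequency 0 -> no carriers beyond the guaranteed one
  attr(inv, "freq") <- list(setNames(rep(0, length(colonies)), colonies))
  cfg$inversions <- inv
  sp0 <- spike_inversions(cfg, ref, pan$panel)
  expect_equal(nrow(sp0$carriers), 1)  # every inversion kept in >= 1 hap
})

test_that("long reads match the length, error and strand model", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  seq1 <- substr(ref$sequences[["chr1"]], 1, 2e5)
  # error rate 0: every read is an exact substring or its revcomp
  reads0 <- simulate_long_reads(seq1, coverage = 2, error_rate = 0,
                                seed = 8)
  for (i in seq_len(min(20, length(reads0)))) {
    r <- reads0[i]
    hit <- grepl(r, seq1, fixed = TRUE) ||
      grepl(revcomp(r), seq1, fixed = TRUE)
    expect_true(hit)
  }
  # realized N50 within 15% of the 6789-bp target over >= 500 reads
  big <- simulate_long_reads(seq1, coverage = 20, n50 = 6789,
                             error_rate = 0, seed = 9)
  expect_gte(length(big), 500)
  lens <- sort(nchar(big), decreasing = TRUE)
  n50 <- lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
  expect_lt(abs(n50 - 6789) / 6789, 0.15)
  # determinism
  expect_identical(simulate_long_reads(seq1, coverage = 1, seed = 4),
                   simulate_long_reads(seq1, coverage = 1, seed = 4))
  # coverage 0 -> empty
  expect_length(simulate_long_reads(seq1, coverage = 0), 0)
})

test_that("caller simulation respects sensitivity, jitter and FP settings", {
  cfg <- small_cfg(callers = list(
    LR = list(sens_micro = 1, sens_large = 1, jitter_sd = 0,
              fp_per_sample = 0, fp_size_range = c(1e4, 2e4))))
  ref <- simulate_reference(cfg)
  pan <- simulate_panel(cfg, ref)
  sp <- spike_inversions(cfg, ref, pan$panel)
  cand <- simulate_candidate_calls(cfg, sp, pan$panel, ref)
  # perfect sensitivity, no jitter, no FPs: candidates = carrier truth
  expect_true(all(cand$is_true))
  carriers <- unique(sp$carriers[, c("sample", "id")])
  expect_equal(nrow(cand), nrow(carriers))
  loc <- sp$inversions[match(cand$id, sp$inversions$id), ]
  expect_equal(cand$start, loc$start)
  expect_equal(cand$end, loc$end)
  # zero sensitivity and zero FP rate -> nothing called
  cfg0 <- small_cfg(callers = list(
    LR = list(sens_micro = 0, sens_large = 0, jitter_sd = 0,
              fp_per_sample = 0, fp_size_range = c(1e4, 2e4))))
  sp0 <- spike_inversions(cfg0, ref, pan$panel)
  cand0 <- simulate_candidate_calls(cfg0, sp0, pan$panel, ref)
  expect_equal(NROW(cand0), 0)
})

test_that("jittered candidates still merge with truth at 95% overlap", {
  cfg <- small_cfg(callers = list(
    LR = list(sens_micro = 1, sens_large = 1, jitter_sd = 50,
              fp_per_sample = 0, fp_size_range = c(1e4, 2e4))))
  ref <- simulate_reference(cfg)
  pan <- simulate_panel(cfg, ref)
  sp <- spike_inversions(cfg, ref, pan$panel)   # >= 10-kb inversions
  cand <- simulate_candidate_calls(cfg, sp, pan$panel, ref)
  calls <- merge_candidates(cand[, c("chrom", "start", "end", "sample",
                                     "caller")])
  for (i in seq_len(nrow(sp$inversions))) {
    ro <- vapply(seq_len(nrow(calls)), function(j)
      reciprocal_overlap(calls[j, ], sp$inversions[i, ]), 1)
    expect_gte(max(ro), 0.95)
  }
})

test_that("stronger drift lowers diversity and raises AIM yield", {
  pis <- c(); aims <- c()
  for (fd in c(0.10, 0.25, 0.45)) {
    cfg <- small_cfg(seed = 19, f_div = c(Aaa = fd, Aaf = 0.10))
    ref <- simulate_reference(cfg)
    pan <- simulate_panel(cfg, ref)$panel
    w <- window_diversity(pan, "USA_Aaa", window = 4e5,
                          chrom_lengths = cfg$chrom_lengths)
    pis <- c(pis, mean(w$value))
    cs <- build_callsets(pan)
    a <- select_aims(cs$colony, cs$conserved, c("Thailand_Aaa", "USA_Aaa"),
                     c("Uganda_Aaf", "Gabon_Aaf"))
    aims <- c(aims, nrow(a))
  }
  # AIM count rises monotonically with subspecies drift
  expect_true(all(diff(aims) > 0))
  # diversity in the drifted subspecies falls
  expect_lt(pis[3], pis[1])
})
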