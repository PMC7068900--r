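toy_ref <- c(chr = "GATTACAGATTACAGG")
toy_call <- list(chrom = "chr", start = 4, end = 12)

test_that("pan-genome junction contigs follow the reverse-complement arithmetic", {
  pg <- build_pangenome(toy_ref, toy_call, flank = 4, min_flank = 1)
  expect_equal(pg$contigs[["bp1_ref"]], "GATTACAG")   # seq[0:8]
  expect_equal(pg$contigs[["bp2_ref"]], "ATTACAGG")   # seq[8:16]
  expect_equal(pg$contigs[["bp1_inv"]], "GATTTAAT")
  expect_equal(pg$contigs[["bp2_inv"]], "CTGTCAGG")
  expect_equal(unname(pg$junction_at), c(4, 4, 4, 4))
  # masked background hides both junction neighborhoods
  pgb <- build_pangenome(toy_ref, toy_call, flank = 4, min_flank = 1,
                         background = TRUE)
  expect_equal(pgb$contigs[["background"]], strrep("N", 16))
})

test_that("re-inverting an inverted chromosome recovers the reference junctions", {
  set.seed(5)
  ref <- c(chr = paste(sample(c("A", "C", "G", "T"), 4e4, TRUE),
                       collapse = ""))
  call <- list(chrom = "chr", start = 15000, end = 27000)
  pg_ref <- build_pangenome(ref, call, flank = 3000)
  # chromosome carrying the inversion
  inv_chr <- paste0(substr(ref, 1, call$start),
                    revcomp(substring(ref, call$start + 1, call$end)),
                    substring(ref, call$end + 1, nchar(ref)))
  pg_inv <- build_pangenome(c(chr = inv_chr), call, flank = 3000)
  # the "inverted" junctions of the inverted chromosome are the
  # reference junctions, and vice versa
  expect_equal(pg_inv$contigs[["bp1_inv"]], pg_ref$contigs[["bp1_ref"]])
  expect_equal(pg_inv$contigs[["bp2_inv"]], pg_ref$contigs[["bp2_ref"]])
  expect_equal(pg_inv$contigs[["bp1_ref"]], pg_ref$contigs[["bp1_inv"]])
})

test_that("flanks truncate with a warning at chromosome ends", {
  expect_warning(pg <- build_pangenome(toy_ref,
                                       list(chrom = "chr", start = 2,
                                            end = 12),
                                       flank = 4, min_flank = 1),
                 "truncated|shorter")
  expect_equal(nchar(pg$contigs[["bp1_ref"]]), 2 + 4)
})

test_that("read assignment honors best score, dual span, ties and background", {
  set.seed(21)
  ref <- c(chr = paste(sample(c("A", "C", "G", "T"), 6e4, TRUE),
                       collapse = ""))
  call <- list(chrom = "chr", start = 20000, end = 40000)
  pg <- build_pangenome(ref, call, flank = 5000, background = FALSE)
  # exact 6-kb read centred on the bp1 inverted junction
  j <- pg$junction_at[["bp1_inv"]]
  r_inv <- substr(pg$contigs[["bp1_inv"]], j - 3000 + 1, j + 3000)
  # 6-kb read ending exactly at the junction point (pure left flank)
  r_edge <- unname(substr(ref, call$start - 6000 + 1, call$start))
  asn <- assign_reads(c(centered = unname(r_inv), edge = r_edge), pg)
  expect_equal(asn$orientation[asn$read == "centered"], "inv")
  expect_gte(asn$left_span[asn$read == "centered"], 2900)
  expect_equal(asn$orientation[asn$read == "edge"], "unassigned")

  # a read from far outside the junctions goes to the masked background
  pg_bg <- build_pangenome(ref, call, flank = 5000, background = TRUE)
  r_bg <- substr(ref, 1, 6000)
  asn_bg <- assign_reads(setNames(r_bg, "bg"), pg_bg)
  expect_equal(asn_bg$orientation, "unassigned")

  # equal best scores on ref and inv (e.g. a palindromic flank) tie
  # -> ambiguous; forced here with identical ref/inv contigs
  r_pal <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE),
                 collapse = "")
  pg_tie <- pg
  pg_tie$contigs[["bp1_ref"]] <- r_pal
  pg_tie$contigs[["bp1_inv"]] <- r_pal
  read_tie <- substr(r_pal, 2001, 10000)
  asn_tie <- assign_reads(setNames(read_tie, "tie"), pg_tie)
  expect_equal(asn_tie$orientation, "ambiguous")

  # reads at or below the 5-kb length filter are dropped
  short <- assign_reads(setNames(substr(r_inv, 1, 5000), "short"), pg)
  expect_equal(nrow(short), 0)
})

test_that("artificial breakpoints are repeat-matched, seeded, and sized", {
  set.seed(2)
  ref <- list(sequences = c(chr = paste(sample(c("A", "C", "G", "T"),
                                               2e5, TRUE), collapse = "")))
  reps <- data.frame(chrom = "chr", start = c(5e4, 1.2e5),
                     end = c(6e4, 1.3e5))
  cand <- data.frame(chrom = "chr", start = 8e4, end = 9e4)
  # candidates with repeat-free flanks: all sampled loci must be within
  # 10 points of 0% flank repeat content
  bps <- generate_artificial_breakpoints(ref$sequences, reps, cand,
                                         n = 25, flank = 2000, seed = 4)
  expect_equal(nrow(bps), 25)
  expect_true(all(bps$repeat_fraction <= 0.10 + 1e-9))
  expect_true(all(bps$end - bps$start == 1e4))
  # determinism under seed
  bps2 <- generate_artificial_breakpoints(ref$sequences, reps, cand,
                                          n = 25, flank = 2000, seed = 4)
  expect_identical(bps, bps2)
  # n = 0 -> empty
  expect_equal(nrow(generate_artificial_breakpoints(
    ref$sequences, reps, cand, n = 0, flank = 2000, seed = 1)), 0)
})

test_that("null calibration computes type-7 quartiles and counts exceedances", {
  st <- data.frame(breakpoint = rep(c("bp1", "bp2"), 5),
                   coverage = c(10, 12, 14, 16, 18, 10, 12, 14, 16, 18),
                   inverted_fraction = 0)
  nc <- calibrate_null(st)
  # hand-enumerated type-7 quartiles of {10,12,14,16,18}
  expect_equal(unname(nc$quartiles), c(12, 14, 16))
  expect_equal(nc$iqr, 4)
  expect_equal(nc$misassignment_rate, 0)

  # one of 1000 junctions above the 0.37 threshold -> rate 0.001
  st2 <- data.frame(breakpoint = "bp1", coverage = 20,
                    inverted_fraction = c(0.5, rep(0, 999)))
  expect_equal(calibrate_null(st2)$misassignment_rate, 0.001)

  expect_error(calibrate_null(data.frame(breakpoint = "bp1", coverage = 0,
                                         inverted_fraction = NA)),
               "calibration failure")
})

test_that("validation applies coverage and 37%-fraction rules strictly", {
  # flat null coverage of 100: the fence is Q3 + 2 x IQR = 100
  null <- calibrate_null(data.frame(breakpoint = "bp1",
                                    coverage = rep(100, 30),
                                    inverted_fraction = 0))
  mk_asn <- function(n_inv1, n_ref1, n_inv2, n_ref2) {
    data.frame(read = seq_len(n_inv1 + n_ref1 + n_inv2 + n_ref2),
               breakpoint = c(rep("bp1", n_inv1 + n_ref1),
                              rep("bp2", n_inv2 + n_ref2)),
               orientation = c(rep("inv", n_inv1), rep("ref", n_ref1),
                               rep("inv", n_inv2), rep("ref", n_ref2)),
               left_span = 2000, right_span = 2000, score = 100)
  }
  # 4 inv / 6 ref on both breakpoints: fraction 0.40 > 0.37 -> valid
  v <- validate_inversion(mk_asn(4, 6, 4, 6), null)
  expect_true(v$overall_valid)
  # coverage 9 on one breakpoint -> invalid regardless of the other
  v9 <- validate_inversion(mk_asn(4, 5, 40, 0), null)
  expect_false(v9$overall_valid)
  # fraction exactly 0.37 fails the strict rule
  v37 <- validate_inversion(mk_asn(37, 63, 37, 63), null)
  expect_false(v37$overall_valid)
  # coverage far above the null fence is discarded
  vhi <- validate_inversion(mk_asn(300, 300, 10, 5), null)
  expect_false(vhi$breakpoints$coverage_pass[1])
})

test_that("supercontig junction patterns classify inverted adjacency", {
  call <- list(chrom = "1", start = 1e6, end = 2e6)
  seg <- function(starts, ends, strands, scores = 70)
    data.frame(chrom = "1", start = starts, end = ends, strand = strands,
               score = scores)
  # both-upstream, opposite strands: the bp1 inverted junction
  s1 <- seg(c(0.995e6, 1.995e6), c(1.0e6, 2.0e6), c("+", "-"))
  r1 <- classify_supercontig(s1, call, flank = 1e4, contig_length = 2e4)
  expect_true(r1$supports_bp1)
  expect_true(r1$supports_inversion)
  # colinear reference configuration: no support
  s2 <- seg(c(0.995e6, 1.0e6), c(1.0e6, 1.005e6), c("+", "+"))
  expect_false(classify_supercontig(s2, call, flank = 1e4,
                                    contig_length = 2e4)$supports_inversion)
  # single colinear segment spanning bp1 at score 70: no support
  s3 <- seg(0.99e6, 1.01e6, "+")
  expect_false(classify_supercontig(s3, call, flank = 1e4,
                                    contig_length = 2e4)$supports_inversion)
  # below the score threshold: ignored
  s4 <- seg(c(0.995e6, 1.995e6), c(1.0e6, 2.0e6), c("+", "-"), scores = 60)
  expect_false(classify_supercontig(s4, call, flank = 1e4,
                                    contig_length = 2e4)$supports_inversion)
  # short supercontigs are not considered
  expect_false(classify_supercontig(s1, call, flank = 1e4,
                                    contig_length = 9e3)$supports_inversion)
  # assembly validation needs both junctions across supercontigs
  s_bp2 <- seg(c(1.0e6, 2.0e6), c(1.005e6, 2.005e6), c("+", "-"))
  both <- validate_by_assembly(list(s1, s_bp2), call, flank = 1e4)
  expect_true(both$overall_valid)
  expect_false(validate_by_assembly(list(s1), call,
                                    flank = 1e4)$overall_valid)
})
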