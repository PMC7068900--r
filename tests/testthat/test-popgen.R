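co2 <- setNames(c("A", "A", "B", "B"), paste0("s", 1:4))

test_that("windowed pi matches the closed form and the pairwise oracle", {
  # all homozygous reference -> pi = 0
  p0 <- make_panel(matrix(0L, 5, 2), matrix(0L, 5, 2),
                   setNames(c("A", "A"), c("s1", "s2")))
  expect_equal(window_diversity(p0, "A", window = 1e6,
                                chrom_lengths = c("1" = 1e6))$value, 0)
  # one site with p = 0.5, n = 4 in a 1-Mb window
  p1 <- make_panel(matrix(c(0L, 1L), 1), matrix(c(0L, 1L), 1),
                   setNames(c("A", "A"), c("s1", "s2")), pos = 100)
  expect_equal(window_diversity(p1, "A", window = 1e6,
                                chrom_lengths = c("1" = 1e6))$value,
               2 * 0.25 * (4 / 3) / 1e6)
  # random panel vs brute-force mean pairwise difference over all
  # chromosome pairs (equivalent closed form)
  set.seed(13)
  n <- 40
  haps <- matrix(rbinom(n * 6, 1, runif(n)), n, 6)
  p2 <- make_panel(haps[, c(1, 3, 5)], haps[, c(2, 4, 6)],
                   setNames(rep("A", 3), paste0("s", 1:3)),
                   pos = seq_len(n) * 100)
  w <- window_diversity(p2, "A", window = 1e6,
                        chrom_lengths = c("1" = 1e6))
  pair_diff <- 0
  for (i in 1:5) for (j in (i + 1):6)
    pair_diff <- pair_diff + sum(haps[, i] != haps[, j])
  oracle <- pair_diff / choose(6, 2) / 1e6
  expect_equal(w$value, oracle, tolerance = 1e-12)
})

test_that("pi and F_st are invariant to sample order", {
  set.seed(17)
  n <- 30
  a1 <- matrix(rbinom(4 * n, 1, .4), n); a2 <- matrix(rbinom(4 * n, 1, .4), n)
  p <- make_panel(a1, a2, co2, pos = seq_len(n) * 50)
  perm <- c("s3", "s1", "s4", "s2")
  pp <- subset_panel(p, samples = perm)
  expect_equal(window_diversity(p, "A", chrom_lengths = c("1" = 1e6))$value,
               window_diversity(pp, "A", chrom_lengths = c("1" = 1e6))$value)
  expect_equal(fst_wc(p, c("s1", "s2"), c("s3", "s4"))$value,
               fst_wc(pp, c("s2", "s1"), c("s4", "s3"))$value)
})

test_that("Weir-Cockerham F_st matches fixed-difference and component oracles", {
  p <- make_panel(matrix(c(0, 0, 1, 1), 1), matrix(c(0, 0, 1, 1), 1), co2)
  expect_equal(fst_wc(p, c("s1", "s2"), c("s3", "s4"))$value, 1)
  # identical pools: no positive divergence (WC may be negative)
  pid <- make_panel(matrix(c(0, 1, 0, 1), 1), matrix(c(1, 1, 1, 1), 1), co2)
  expect_lte(fst_wc(pid, c("s1", "s2"), c("s3", "s4"))$value, 0)
  # hand-computed a/b/c components for {0/0,0/1} vs {0/1,1/1}:
  # a = 0.0625, b = 0, c = 0.25 -> F_st = 0.2 (brute-force formula oracle)
  ph <- make_panel(matrix(c(0, 0, 0, 1), 1), matrix(c(0, 1, 1, 1), 1), co2)
  expect_equal(fst_wc(ph, c("s1", "s2"), c("s3", "s4"))$value, 0.2)
  # monomorphic site -> missing, not 0
  pm <- make_panel(matrix(0L, 1, 4), matrix(0L, 1, 4), co2)
  expect_true(is.na(fst_wc(pm, c("s1", "s2"), c("s3", "s4"))$value))
  # windowed value is the ratio of summed components
  p2 <- make_panel(rbind(c(0, 0, 1, 1), c(0, 0, 0, 1)),
                   rbind(c(0, 0, 1, 1), c(0, 1, 1, 1)), co2)
  wv <- fst_wc(p2, c("s1", "s2"), c("s3", "s4"), window = 1e6,
               chrom_lengths = c("1" = 1e6))
  expect_equal(wv$value, (0.5 + 0.0625) / (0.5 + 0.0625 + 0 + 0.25))
})

test_that("ROH detection flags long homozygous stretches", {
  # ~2.2-Mb homozygous stretch flanked by dense het clusters
  pos <- sort(c(seq(1e4, 3e5, by = 2e4), seq(3.2e5, 2.52e6, by = 2e4),
                seq(2.55e6, 2.85e6, by = 2e4)))
  het <- pos < 3.1e5 | pos > 2.53e6
  p <- genotype_panel(data.frame(chrom = "1", pos = pos, ref = "A",
                                 alt = "T"),
                      matrix(0L, length(pos), 1),
                      matrix(ifelse(het, 1L, 0L), length(pos), 1),
                      "s1", setNames("A", "s1"))
  roh <- detect_roh(p, "s1", "1", chrom_length = 3e6)
  expect_equal(nrow(roh), 1)
  expect_lte(roh$start, 3.2e5)
  expect_gte(roh$end, 2.52e6)
  # uniformly heterozygous -> none
  pu <- genotype_panel(data.frame(chrom = "1", pos = seq(0, 2.9e6, 5e4),
                                  ref = "A", alt = "T"),
                       matrix(0L, 59, 1), matrix(1L, 59, 1),
                       "s1", setNames("A", "s1"))
  expect_equal(nrow(detect_roh(pu, "s1", "1", chrom_length = 3e6)), 0)
  # density exactly at the threshold is included (<= rule): 5 hets in
  # exactly 1 Mb
  pos5 <- c(1e5, 3e5, 5e5, 7e5, 9e5)
  pb <- genotype_panel(data.frame(chrom = "1", pos = pos5, ref = "A",
                                  alt = "T"),
                       matrix(0L, 5, 1), matrix(1L, 5, 1),
                       "s1", setNames("A", "s1"))
  roh5 <- detect_roh(pb, "s1", "1", chrom_length = 1e6,
                     min_length = 1e6, max_het_per_mb = 5)
  expect_equal(nrow(roh5), 1)
  expect_equal(roh5$end - roh5$start, 1e6)
})

test_that("ROH masking never increases windowed pi", {
  set.seed(23)
  n <- 200
  a1 <- matrix(rbinom(4 * n, 1, .3), n); a2 <- matrix(rbinom(4 * n, 1, .3), n)
  p <- make_panel(a1, a2, co2, pos = sort(sample.int(3e6, n)))
  w0 <- window_diversity(p, "A", chrom_lengths = c("1" = 3e6))
  mask <- data.frame(chrom = "1", start = 5e5, end = 1.5e6)
  w1 <- window_diversity(p, "A", chrom_lengths = c("1" = 3e6),
                         mask = mask)
  expect_true(all(w1$value <= w0$value + 1e-15))
})

test_that("AIM selection enforces the strict F_st and callability rules", {
  co <- setNames(c("A", "A", "B", "B", "T"), paste0("s", 1:5))
  # site 1: fixed difference; site 2: shared polymorphism
  a1 <- rbind(c(0L, 0L, 1L, 1L, 0L), c(0L, 1L, 0L, 1L, 0L))
  p <- make_panel(a1, a1, co, pos = c(10, 20))
  conserved <- subset_panel(p, sites = 1)   # site 2 absent downstream
  aims <- select_aims(p, conserved, "A", "B")
  expect_equal(aims$pos, 10)
  expect_equal(aims$allele_a, 0L)
  expect_equal(aims$allele_b, 1L)
  # F_st = 0.8 exactly would be excluded; approximate by checking the
  # comparison is strict in code: a fixed difference passes, the shared
  # site does not appear even when callable
  aims2 <- select_aims(p, p, "A", "B")
  expect_equal(nrow(aims2), 1)
  # capped selection warns when fewer are available
  expect_warning(select_aims(p, p, "A", "B", n_max = 5), "available")
})

test_that("AIM ancestry fractions count strictly predominant donor alleles", {
  co <- setNames(c("A", "A", "B", "B", "T", "T"), paste0("s", 1:6))
  n <- 10
  # pools fixed for opposite alleles at all 10 AIMs
  a_pool <- cbind(matrix(0L, n, 2), matrix(1L, n, 2))
  # test colony: donor (B) allele at frequency 0.75 at 4 loci, 0 elsewhere
  t1 <- c(rep(1L, 4), rep(0L, 6)); t2 <- c(rep(1L, 4), rep(0L, 6))
  t1b <- c(rep(1L, 4), rep(0L, 6)); t2b <- c(rep(0L, 4), rep(0L, 6))
  a1 <- cbind(a_pool[, 1:2], a_pool[, 3:4], t1, t1b)
  a2 <- cbind(a_pool[, 1:2], a_pool[, 3:4], t2, t2b)
  p <- make_panel(a1, a2, co, pos = seq_len(n) * 10)
  aims <- select_aims(p, p, "A", "B")
  expect_equal(nrow(aims), n)
  expect_equal(aim_ancestry_fraction(aims, p, "T", donor = "b"), 0.4)
  # a colony fixed for its own subspecies allele scores 0
  expect_equal(aim_ancestry_fraction(aims, p, "A", donor = "b"), 0)
  # frequency exactly 0.5 is not predominant
  t_half1 <- cbind(rep(0L, n), rep(1L, n))
  co3 <- setNames(c("A", "A", "B", "B", "H"), paste0("s", 1:5))
  ph <- make_panel(cbind(a_pool[, 1:2], a_pool[, 3:4], t_half1[, 1]),
                   cbind(a_pool[, 1:2], a_pool[, 3:4], t_half1[, 2]),
                   co3, pos = seq_len(n) * 10)
  aims3 <- select_aims(ph, ph, "A", "B")
  expect_equal(aim_ancestry_fraction(aims3, ph, "H", donor = "b"), 0)
})

test_that("founder-haplotype clustering follows the 1-diff-per-kb rule", {
  hap <- function(id, start, end, pos, alleles)
    list(id = id, start = start, end = end, pos = pos, alleles = alleles)
  pos <- seq(0, 9999, by = 100)
  base <- rep(0L, length(pos))
  # identical 10-kb haplotypes -> one cluster
  h1 <- hap("a", 0, 10000, pos, base)
  h2 <- hap("b", 0, 10000, pos, base)
  expect_equal(unname(cluster_founder_haplotypes(list(h1, h2))),
               c(1L, 1L))
  # 11 mismatches over 10 kb (1.1/kb) -> two clusters
  d11 <- base; d11[1:11] <- 1L
  expect_equal(length(unique(cluster_founder_haplotypes(
    list(h1, hap("c", 0, 10000, pos, d11))))), 2)
  # 10 mismatches over 10 kb (exactly 1.0/kb) -> one cluster
  d10 <- base; d10[1:10] <- 1L
  expect_equal(length(unique(cluster_founder_haplotypes(
    list(h1, hap("d", 0, 10000, pos, d10))))), 1)
  # overlap below 1 kb -> unassigned
  h_far <- hap("e", 9800, 10500, pos[pos >= 9800], base[pos >= 9800])
  cl <- cluster_founder_haplotypes(list(h1, h_far))
  expect_true(is.na(cl[["e"]]))
})
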