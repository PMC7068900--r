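aln4 <- snp_alignment(matrix(c(0, 0, 1, 1,
                               0, 0, 1, 0), 4, 2,
                             dimnames = list(c("A", "B", "C", "D"), NULL)))

test_that("Fitch scores binary characters with missing-as-universal", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  # identical sequences score 0 on any topology
  same <- snp_alignment(matrix(0L, 4, 5,
                               dimnames = list(c("A", "B", "C", "D"),
                                               NULL)))
  expect_equal(fitch_score(tr, same), 0)
  # two sites (0,0,1,1) and (0,0,1,0): total 2 on the matching topology,
  # and 2 is the exhaustive minimum over all three topologies
  expect_equal(fitch_score(tr, aln4), 2)
  expect_equal(brute_force_mp(aln4), 2)
  # adding an invariant site never changes the score
  aln_inv <- snp_alignment(cbind(aln4, c(1L, 1L, 1L, 1L)))
  expect_equal(fitch_score(tr, aln_inv), fitch_score(tr, aln4))
  # missing data forces no change
  aln_na <- aln4; aln_na[4, 2] <- NA
  expect_lte(fitch_score(tr, snp_alignment(aln_na)),
             fitch_score(tr, aln4))
  expect_error(fitch_score(ape::read.tree(text = "((A,B),(C,E));"), aln4),
               "without sequence")
})

test_that("Fitch score is invariant to re-rooting", {
  set.seed(47)
  taxa <- paste0("t", 1:8)
  aln <- snp_alignment(matrix(rbinom(8 * 30, 1, .5), 8, 30,
                              dimnames = list(taxa, NULL)))
  tr <- ape::unroot(ape::rtree(8, tip.label = taxa))
  s0 <- fitch_score(tr, aln)
  for (tip in c("t3", "t7")) {
    rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_score(rr, aln), s0)
  }
})

test_that("Fitch agrees with an independent parsimony implementation", {
  set.seed(53)
  taxa <- paste0("t", 1:7)
  for (rep in 1:3) {
    m <- matrix(rbinom(7 * 25, 1, .4), 7, 25, dimnames = list(taxa, NULL))
    aln <- snp_alignment(m)
    tr <- ape::unroot(ape::rtree(7, tip.label = taxa))
    pd <- phangorn::phyDat(matrix(c("a", "b")[m + 1], 7,
                                  dimnames = dimnames(m)),
                           type = "USER", levels = c("a", "b"))
    expect_equal(fitch_score(tr, aln),
                 phangorn::parsimony(tr, pd, method = "fitch"))
  }
})

test_that("tree search is exhaustive for small trees and seeded above", {
  # clean two-clade signal: the compatible topology is strictly best
  clean <- snp_alignment(matrix(rep(c(0, 0, 1, 1), 6), 4, 6,
                                dimnames = list(c("A", "B", "C", "D"),
                                                NULL)))
  res <- search_mp(clean)
  expect_equal(length(res$trees), 1)
  expect_equal(res$score, 6)
  split <- ape::prop.part(res$trees[[1]])
  expect_true(ape::is.monophyletic(ape::root(res$trees[[1]], "A",
                                             resolve.root = TRUE),
                                   c("C", "D")))
  # constant alignment: all three topologies tie at 0
  const <- snp_alignment(matrix(1L, 4, 3,
                                dimnames = list(c("A", "B", "C", "D"),
                                                NULL)))
  expect_equal(length(search_mp(const)$trees), 3)
  expect_equal(search_mp(const)$score, 0)
  # determinism of the heuristic under a seed
  set.seed(59)
  taxa <- paste0("t", 1:11)
  big <- snp_alignment(matrix(rbinom(11 * 40, 1, .5), 11, 40,
                              dimnames = list(taxa, NULL)))
  r1 <- search_mp(big, seed = 4)
  r2 <- search_mp(big, seed = 4)
  expect_equal(ape::write.tree(r1$consensus), ape::write.tree(r2$consensus))
  expect_equal(r1$score, r2$score)
})

test_that("heuristic search attains the exhaustive optimum on 8 taxa", {
  set.seed(61)
  taxa <- paste0("t", 1:8)
  for (rep in 1:2) {
    aln <- snp_alignment(matrix(rbinom(8 * 30, 1, .4), 8, 30,
                                dimnames = list(taxa, NULL)))
    exact <- search_mp(aln, n_exhaustive = 9)$score
    heur <- search_mp(aln, n_exhaustive = 4, n_restarts = 4,
                      seed = rep)$score
    expect_equal(heur, exact)
  }
})

test_that("bootstrap support is 100% for perfectly congruent signal", {
  clean <- snp_alignment(matrix(rep(c(0, 0, 0, 1, 1, 1), 20), 6, 20,
                               dimnames = list(paste0("t", 1:6), NULL)))
  bt <- bootstrap_support(clean, n_reps = 20, seed = 2)
  expect_true(all(bt$support >= 0 & bt$support <= 100))
  # the split separating t1-t3 from t4-t6 must appear in every replicate
  expect_true(any(bt$support == 100))
})

test_that("regional trees expand the inversion span to the target size", {
  set.seed(67)
  n <- 400
  pos <- sort(sample.int(3e6, n))
  haps <- matrix(rbinom(n * 8, 1, .5), n, 8)
  co <- setNames(rep(c("X", "Y"), each = 2), paste0("s", 1:4))
  p <- make_panel(haps[, c(1, 3, 5, 7)], haps[, c(2, 4, 6, 8)], co,
                  pos = pos, chrom = "c1")
  # 200-kb inversion -> 1-Mb region centred on its midpoint
  res <- regional_tree(p, list(chrom = "c1", start = 1.4e6, end = 1.6e6),
                       chrom_length = 3e6, n_exhaustive = 4,
                       n_restarts = 1, seed = 1)
  expect_equal(res$region$end - res$region$start, 1e6)
  expect_equal((res$region$start + res$region$end) / 2, 1.5e6)
  # 1.2-Mb inversion -> its own span, no shrink
  res2 <- regional_tree(p, list(chrom = "c1", start = 1e6, end = 2.2e6),
                        chrom_length = 3e6, n_exhaustive = 4,
                        n_restarts = 1, seed = 1)
  expect_equal(c(res2$region$start, res2$region$end), c(1e6, 2.2e6))
  # taxa are haplotypes, two per sample
  expect_equal(sort(rownames(res$alignment)),
               sort(c(paste0("s", 1:4, "_", co, "_h1"),
                      paste0("s", 1:4, "_", co, "_h2"))))
})

test_that("clade-nesting classification flags introgressed taxa", {
  group_of <- c(a1 = "Aaa", a2 = "Aaa", a3 = "Aaa",
                f1 = "Aaf", f2 = "Aaf", f3 = "Aaf",
                o1 = "outgroup")
  mono <- ape::read.tree(text = "(((a1,a2),a3),((f1,f2),f3),o1);")
  expect_equal(nrow(classify_clade_introgression(mono, group_of)), 0)
  # one Aaf haplotype grafted inside the Aaa clade
  graft <- ape::read.tree(text = "(((a1,f1),(a2,a3)),(f2,f3),o1);")
  flags <- classify_clade_introgression(graft, group_of)
  expect_true("f1" %in% flags$taxon)
  expect_equal(flags$nested_in[flags$taxon == "f1"], "Aaa")
  expect_error(classify_clade_introgression(mono, group_of[1:6]),
               "no outgroup")
})

test_that("clade-nesting flags agree with an exhaustive clade scan", {
  set.seed(71)
  group_of <- c(x1 = "X", x2 = "X", x3 = "X", y1 = "Y", y2 = "Y",
                y3 = "Y", y4 = "Y", o1 = "outgroup")
  for (rep in 1:10) {
    tr <- ape::rtree(8, tip.label = sample(names(group_of)))
    flags <- classify_clade_introgression(tr, group_of)
    # oracle: root, enumerate all clades, find smallest superset per group
    rt <- ape::root(tr, outgroup = "o1", resolve.root = TRUE)
    parts <- ape::prop.part(rt)
    labs <- attr(parts, "labels")
    oracle <- character(0)
    for (g in c("X", "Y")) {
      gt <- names(group_of)[group_of == g]
      sizes <- vapply(parts, length, 1L)
      ok <- vapply(parts, function(cl) all(gt %in% labs[cl]), TRUE)
      cl <- labs[parts[[which(ok)[which.min(sizes[ok])]]]]
      oracle <- c(oracle, setdiff(cl, c(gt, "o1")))
    }
    expect_setequal(flags$taxon, unique(oracle))
  }
})
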