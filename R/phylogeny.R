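#' Build a binary SNP alignment matrix
#'
#' @param mat integer matrix, taxa x sites, entries 0/1/NA.
#' @return the validated matrix (class `snp_alignment`).
#' @export
snp_alignment <- function(mat) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (is.null(rownames(mat))) stop("alignment needs taxon rownames")
  if (any(!mat %in% c(0L, 1L, NA_integer_)))
    stop("alignment characters must be 0, 1 or NA")
  class(mat) <- c("snp_alignment", class(mat))
  mat
}

## deterministic binary rooting so Fitch sees only bifurcations
.rooted_binary <- function(tree) {
  t2 <- ape::unroot(tree)
  ape::root(t2, outgroup = sort(t2$tip.label)[1], resolve.root = TRUE)
}

#' Fitch parsimony length of a tree on a binary SNP alignment
#'
#' Characters are two-state (biallelic SNPs); missing data is the
#' universal state set \{0,1\} and never forces a change. The score is
#' invariant to rooting; internally the tree is rooted at a fixed tip so
#' every internal node is binary and the Fitch pass is exact.
#'
#' @param tree an `ape` phylo object whose tips appear in the alignment.
#' @param aln matrix from [snp_alignment()] (taxa x sites, 0/1/NA).
#' @param site_weights optional integer weights (bootstrap counts).
#' @return total number of state changes (numeric).
#' @export
fitch_score <- function(tree, aln, site_weights = NULL) {
  miss <- setdiff(tree$tip.label, rownames(aln))
  if (length(miss))
    stop("tree tips without sequence: ", paste(miss, collapse = ", "))
  tr <- ape::reorder.phylo(.rooted_binary(tree), "postorder")
  nt <- length(tr$tip.label)
  ns <- ncol(aln)
  if (is.null(site_weights)) site_weights <- rep(1, ns)
  # state masks: 1 = {0}, 2 = {1}, 3 = {0,1}
  tipm <- aln[tr$tip.label, , drop = FALSE] + 1L
  tipm[is.na(tipm)] <- 3L
  nn <- nt + tr$Nnode
  masks <- matrix(0L, nn, ns)
  masks[seq_len(nt), ] <- tipm
  seen <- logical(nn)
  seen[seq_len(nt)] <- TRUE
  changes <- numeric(ns)
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    if (!seen[p]) {
      masks[p, ] <- masks[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(masks[p, ], masks[ch, ])
      empty <- inter == 0L
      changes <- changes + empty
      masks[p, ] <- ifelse(empty, bitwOr(masks[p, ], masks[ch, ]), inter)
    }
  }
  sum(changes * site_weights)
}

## all unrooted binary topologies (small n), via phangorn
.all_topologies <- function(taxa) {
  phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
}

## insert a new tip into every edge of an unrooted tree; returns list
.insertions <- function(tree, tip) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  tipt <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = tip,
               edge.length = 1, Nnode = 1L)
  class(tipt) <- "phylo"
  lapply(seq_len(nrow(tree$edge)), function(e) {
    tr <- ape::bind.tree(tree, tipt, where = tree$edge[e, 2],
                         position = 0.5)
    tr$edge.length <- NULL
    ape::unroot(tr)
  })
}

#' Maximum-parsimony tree search
#'
#' Exhaustive over all unrooted topologies when the alignment has at
#' most `n_exhaustive` taxa; otherwise stepwise addition (random taxon
#' order per restart) followed by nearest-neighbor-interchange hill
#' climbing. Deterministic under `seed`. All co-optimal topologies found
#' are returned.
#'
#' @param aln matrix from [snp_alignment()] (>= 4 taxa).
#' @param seed integer seed for addition orders.
#' @param n_exhaustive exhaustive-search bound (default 9).
#' @param n_restarts random-addition restarts for the heuristic
#'   (default 3).
#' @param site_weights optional per-site weights.
#' @return list: `trees` (multiPhylo of co-optimal topologies), `score`
#'   (best parsimony length), `consensus` (strict consensus of the
#'   co-optimal trees).
#' @export
search_mp <- function(aln, seed = 1, n_exhaustive = 9, n_restarts = 3,
                      site_weights = NULL) {
  taxa <- rownames(aln)
  if (length(taxa) < 4) stop("tree search needs at least 4 taxa")
  score_of <- function(tr) fitch_score(tr, aln, site_weights)
  if (length(taxa) <= n_exhaustive) {
    trees <- .all_topologies(taxa)
    scores <- vapply(trees, score_of, 1)
    best <- trees[scores == min(scores)]
  } else {
    set.seed(seed)
    best_score <- Inf
    best <- list()
    for (rs in seq_len(n_restarts)) {
      ord <- sample(taxa)
      tr <- ape::unroot(ape::read.tree(
        text = sprintf("(%s,%s,%s);", ord[1], ord[2], ord[3])))
      for (tx in ord[-(1:3)]) {  # stepwise addition at the best edge
        cands <- .insertions(tr, tx)
        sc <- vapply(cands, score_of, 1)
        tr <- cands[[which.min(sc)]]
      }
      # NNI hill climbing
      cur_score <- score_of(tr)
      repeat {
        nbrs <- phangorn::nni(tr)
        sc <- vapply(nbrs, score_of, 1)
        if (min(sc) < cur_score) {
          tr <- nbrs[[which.min(sc)]]
          cur_score <- min(sc)
        } else break
      }
      if (cur_score < best_score - 1e-9) {
        best_score <- cur_score
        best <- list(tr)
      } else if (abs(cur_score - best_score) <= 1e-9 &&
                 !any(vapply(best, function(b)
                   ape::dist.topo(b, tr) == 0, TRUE))) {
        best <- c(best, list(tr))
      }
    }
  }
  class(best) <- "multiPhylo"
  cons <- if (length(best) > 1) ape::consensus(best, p = 1) else best[[1]]
  list(trees = best, score = min(vapply(best, score_of, 1)),
       consensus = cons)
}

#' Bootstrap support for the maximum-parsimony tree
#'
#' Sites are resampled with replacement `n_reps` times; each replicate
#' is re-searched and the support of a branch is the percentage of
#' replicate best trees containing the corresponding bipartition.
#' Supports are attached to the consensus tree's `node.label`.
#'
#' @param aln matrix from [snp_alignment()].
#' @param n_reps bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param n_restarts random-addition restarts per search (default 1;
#'   replicate searches use the same effort).
#' @param ... passed to [search_mp()].
#' @return list: `tree` (consensus with `node.label` support, in
#'   percent), `support` (numeric vector per internal node),
#'   `replicate_trees` (multiPhylo).
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1,
                              n_restarts = 1, ...) {
  base <- search_mp(aln, seed = seed, n_restarts = n_restarts, ...)
  tree <- base$consensus
  ns <- ncol(aln)
  set.seed(seed + 1)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ns, ns, replace = TRUE)
    w <- tabulate(idx, nbins = ns)
    res <- search_mp(aln, seed = seed + r, site_weights = w,
                     n_restarts = n_restarts, ...)
    reps[[r]] <- res$trees[[1]]
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  tree$node.label <- round(support, 1)
  list(tree = tree, support = support, replicate_trees = reps)
}

#' Phased-haplotype alignment for a genomic region
#'
#' Taxa are haplotypes, labeled `<sample>_<colony>_h1/h2`; sites are the
#' panel's SNPs inside the region.
#'
#' @param panel phased `genotype_panel`.
#' @param chrom,start,end region (0-based half-open).
#' @return matrix from [snp_alignment()].
#' @export
haplotype_alignment <- function(panel, chrom, start, end) {
  if (!panel$phased) stop("haplotype alignment requires a phased panel")
  sel <- panel$sites$chrom == chrom & panel$sites$pos >= start &
    panel$sites$pos < end
  lab <- function(h) paste(panel$samples,
                           panel$colony_of[panel$samples], h, sep = "_")
  mat <- rbind(t(panel$a1[sel, , drop = FALSE]),
               t(panel$a2[sel, , drop = FALSE]))
  rownames(mat) <- c(lab("h1"), lab("h2"))
  snp_alignment(mat)
}

#' One-representative-per-sample alignment from unphased genotypes
#'
#' Heterozygous genotypes take the majority allele; exact ties are
#' broken randomly under `seed`. Used for genome-wide trees where phase
#' is unavailable.
#'
#' @param panel a `genotype_panel`.
#' @param seed integer seed for tie-breaking.
#' @return matrix from [snp_alignment()], taxa `<sample>_<colony>`.
#' @export
representative_alignment <- function(panel, seed = 1) {
  set.seed(seed)
  g <- panel$a1 + panel$a2  # dosage 0/1/2
  rep_allele <- matrix(NA_integer_, nrow(g), ncol(g))
  rep_allele[g == 0L] <- 0L
  rep_allele[g == 2L] <- 1L
  ties <- which(g == 1L)
  rep_allele[ties] <- rbinom(length(ties), 1, 0.5)
  mat <- t(rep_allele)
  rownames(mat) <- paste(panel$samples, panel$colony_of[panel$samples],
                         sep = "_")
  snp_alignment(mat)
}

#' Maximum-parsimony tree for the region around an inversion
#'
#' The inversion span is expanded symmetrically to at least
#' `region_size` bp (a span already larger is kept as is), truncated at
#' the chromosome; a phased haplotype alignment over that region is
#' searched with [search_mp()].
#'
#' @param panel phased `genotype_panel`.
#' @param inversion call row (`chrom`, `start`, `end`).
#' @param region_size minimum region length (default 1 Mb).
#' @param chrom_length chromosome length (inferred when NULL).
#' @param ... passed to [search_mp()].
#' @return list as from [search_mp()], plus `region` and `alignment`.
#' @export
regional_tree <- function(panel, inversion, region_size = 1e6,
                          chrom_length = NULL, ...) {
  if (is.null(chrom_length))
    chrom_length <- infer_chrom_lengths(panel)[[inversion$chrom]]
  span <- inversion$end - inversion$start
  if (span >= region_size) {
    start <- inversion$start; end <- inversion$end
  } else {
    mid <- (inversion$start + inversion$end) / 2
    start <- max(0, floor(mid - region_size / 2))
    end <- min(chrom_length, start + region_size)
    start <- max(0, end - region_size)
  }
  aln <- haplotype_alignment(panel, inversion$chrom, start, end)
  aln <- aln[, colSums(!is.na(aln)) > 0, drop = FALSE]
  with_data <- rowSums(!is.na(aln)) > 0
  if (sum(with_data) < 4)
    stop("fewer than 4 haplotypes with data in region")
  res <- search_mp(snp_alignment(aln[with_data, , drop = FALSE]), ...)
  res$region <- data.frame(chrom = inversion$chrom, start = start,
                           end = end)
  res$alignment <- aln
  res
}

#' Flag taxa nested inside a foreign group's clade
#'
#' The tree is rooted on the outgroup; for each focal group the smallest
#' clade containing all of the group's taxa is found, and any non-group,
#' non-outgroup taxon inside that clade is flagged as nested — the
#' operational signature of haplotype introgression into the group.
#'
#' @param tree phylo object.
#' @param group_of named character vector taxon -> group; the group
#'   named `outgroup_label` roots the tree.
#' @param outgroup_label name of the outgroup group (default
#'   "outgroup").
#' @return data.frame: `taxon`, `group`, `nested_in` (the foreign group
#'   whose clade contains it); zero rows when all groups are
#'   monophyletic.
#' @export
classify_clade_introgression <- function(tree, group_of,
                                         outgroup_label = "outgroup") {
  og <- names(group_of)[group_of == outgroup_label]
  og <- intersect(og, tree$tip.label)
  if (!length(og)) stop("no outgroup taxon present; cannot root")
  rt <- tryCatch(ape::root(tree, outgroup = og, resolve.root = TRUE),
                 error = function(e)  # outgroup not monophyletic
                   ape::root(tree, outgroup = og[1], resolve.root = TRUE))
  groups <- setdiff(unique(group_of), outgroup_label)
  flags <- list()
  for (g in groups) {
    gt <- intersect(names(group_of)[group_of == g], rt$tip.label)
    if (length(gt) < 2) next
    mrca <- ape::getMRCA(rt, gt)
    clade <- rt$tip.label[phangorn::Descendants(rt, mrca, "tips")[[1]]]
    nested <- setdiff(clade, c(gt, og))
    for (tx in nested)
      flags[[length(flags) + 1]] <-
        data.frame(taxon = tx, group = unname(group_of[tx]),
                   nested_in = g, stringsAsFactors = FALSE)
  }
  if (!length(flags))
    return(data.frame(taxon = character(), group = character(),
                      nested_in = character()))
  out <- unique(do.call(rbind, flags))
  rownames(out) <- NULL
  out
}
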