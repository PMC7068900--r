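## chromosome lengths inferred from the site table when not supplied
infer_chrom_lengths <- function(panel) {
  tapply(panel$sites$pos + 1, panel$sites$chrom, max)
}

#' Windowed nucleotide diversity and heterozygosity for one colony
#'
#' Per window, pi is the sum over sites of the unbiased per-site
#' heterozygosity `2 p (1-p) n/(n-1)` (n = called chromosomes at the
#' site) divided by the window length; `het` is the count of
#' heterozygous genotypes per called genotype-bp. Windows overlapping a
#' mask (e.g. runs of homozygosity) have masked sites excluded; the
#' denominator stays the window length, so masking can only lower a
#' window's value.
#'
#' @param panel a `genotype_panel`.
#' @param colony colony name (>= 2 samples required for pi).
#' @param window window size in bp (default 1 Mb).
#' @param chrom_lengths named vector; inferred from the site table when
#'   NULL.
#' @param stat "pi" or "het".
#' @param mask optional interval data.frame of regions to exclude.
#' @param denominator "window" (window length, the windowed-tool
#'   convention; default) or "callable" (number of called sites).
#' @return data.frame: `chrom`, `start`, `end`, `stat`, `value`,
#'   `n_sites`.
#' @export
window_diversity <- function(panel, colony, window = 1e6,
                             chrom_lengths = NULL,
                             stat = c("pi", "het"), mask = NULL,
                             denominator = c("window", "callable")) {
  stat <- match.arg(stat)
  denominator <- match.arg(denominator)
  samples <- colony_samples(panel, colony)
  if (stat == "pi" && length(samples) < 2)
    stop("pi needs at least 2 samples (4 chromosomes) in colony ", colony)
  if (is.null(chrom_lengths)) chrom_lengths <- infer_chrom_lengths(panel)
  wins <- tile_windows(as.list(chrom_lengths), window)
  s <- panel$sites
  masked_site <- rep(FALSE, nrow(s))
  if (!is.null(mask) && nrow(mask)) {
    mask <- merge_intervals(mask)
    for (i in seq_len(nrow(mask)))
      masked_site <- masked_site | (s$chrom == mask$chrom[i] &
                                      s$pos >= mask$start[i] &
                                      s$pos < mask$end[i])
  }
  af <- allele_freq(panel, samples)
  a1 <- panel$a1[, samples, drop = FALSE]
  a2 <- panel$a2[, samples, drop = FALSE]
  het_calls <- rowSums(a1 != a2, na.rm = TRUE)
  n_called <- rowSums(!is.na(a1))
  persite <- if (stat == "pi") {
    p <- af$freq; n <- af$n
    ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), 0)
  } else het_calls

  vals <- lapply(seq_len(nrow(wins)), function(i) {
    in_w <- s$chrom == wins$chrom[i] & s$pos >= wins$start[i] &
      s$pos < wins$end[i] & !masked_site
    n_sites <- sum(in_w & af$n > 0)
    denom <- if (stat == "het") max(sum(n_called[in_w]), 1)
    else if (denominator == "window") wins$end[i] - wins$start[i]
    else max(n_sites, 1)
    data.frame(value = sum(persite[in_w], na.rm = TRUE) / denom,
               n_sites = n_sites)
  })
  cbind(wins, stat = stat, do.call(rbind, vals))
}

#' Detect runs of homozygosity in one sample
#'
#' Density-scan reimplementation of ROH detection: maximal intervals of
#' length >= `min_length` whose heterozygous-call density does not
#' exceed `max_het_per_mb` (inclusive). Seed intervals are the gaps
#' between consecutive heterozygous calls; each seed is greedily
#' extended over neighboring heterozygous sites while the density
#' constraint holds, and overlapping results are merged.
#'
#' @param panel a `genotype_panel`.
#' @param sample sample id.
#' @param chrom chromosome name.
#' @param min_length minimum ROH length in bp (default 1 Mb).
#' @param max_het_per_mb allowed heterozygous calls per Mb (default 5).
#' @param chrom_length chromosome length; inferred when NULL.
#' @return interval data.frame of ROH (possibly empty).
#' @export
detect_roh <- function(panel, sample, chrom, min_length = 1e6,
                       max_het_per_mb = 5, chrom_length = NULL) {
  sel <- panel$sites$chrom == chrom & !is.na(panel$a1[, sample])
  pos <- panel$sites$pos[sel]
  het <- panel$a1[sel, sample] != panel$a2[sel, sample]
  if (is.null(chrom_length))
    chrom_length <- max(infer_chrom_lengths(panel)[[chrom]],
                        if (length(pos)) max(pos) + 1 else 1)
  hpos <- pos[het]
  bounds <- c(-1, hpos, chrom_length)  # het positions delimit seed gaps
  dens_ok <- function(a, b, k) k <= max_het_per_mb * (b - a) / 1e6
  out <- list()
  for (g in seq_len(length(bounds) - 1)) {
    a <- bounds[g] + 1; b <- bounds[g + 1]
    if (b - a <= 0) next
    li <- g - 1; ri <- g  # indices into hpos of hets just outside [a,b)
    k <- 0
    repeat {
      grew <- FALSE
      if (li >= 1) {  # absorb the het to the left
        a2 <- if (li >= 2) hpos[li - 1] + 1 else 0
        if (dens_ok(a2, b, k + 1)) {
          a <- a2; k <- k + 1; li <- li - 1; grew <- TRUE
        }
      }
      if (ri <= length(hpos)) {  # absorb the het to the right
        b2 <- if (ri < length(hpos)) hpos[ri + 1] else chrom_length
        if (dens_ok(a, b2, k + 1)) {
          b <- b2; k <- k + 1; ri <- ri + 1; grew <- TRUE
        }
      }
      if (!grew) break
    }
    if (b - a >= min_length)
      out[[length(out) + 1]] <- data.frame(chrom = chrom, start = a,
                                           end = b)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  merge_intervals(do.call(rbind, out))
}

## Weir & Cockerham (1984) per-site variance components for two or more
## populations of diploids; returns a, b, c per site.
wc_components <- function(panel, pops) {
  r <- length(pops)
  stopifnot(r >= 2)
  ns <- nrow(panel$sites)
  n_i <- matrix(sapply(pops, function(ss)
    rowSums(!is.na(panel$a1[, ss, drop = FALSE]))), nrow = ns)
  p_i <- matrix(sapply(pops, function(ss) allele_freq(panel, ss)$freq),
                nrow = ns)
  h_i <- matrix(sapply(pops, function(ss) {
    a1 <- panel$a1[, ss, drop = FALSE]; a2 <- panel$a2[, ss, drop = FALSE]
    n <- rowSums(!is.na(a1))
    ifelse(n > 0, rowSums(a1 != a2, na.rm = TRUE) / n, NA_real_)
  }), nrow = ns)
  nbar <- rowMeans(n_i)
  rn <- r * nbar
  nc <- (rn - rowSums(n_i^2) / rn) / (r - 1)
  pbar <- rowSums(n_i * p_i) / rn
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / rn
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) *
       hbar)
  cc <- hbar / 2
  ok <- rowSums(n_i >= 1) == r & nbar > 1
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  data.frame(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_st between two sample pools
#'
#' Per-site or windowed (ratio-of-sums of the a/(a+b+c) variance
#' components, the convention of windowed F_st tools). Monomorphic
#' windows, where the summed denominator is zero, are reported as `NA`.
#'
#' @param panel a `genotype_panel`.
#' @param pop_a,pop_b character vectors of sample ids (or use
#'   [colony_samples()]).
#' @param window window size in bp, or NULL for per-site values.
#' @param chrom_lengths named vector; inferred when NULL.
#' @return data.frame of window (or site) F_st values with `n_sites`.
#' @export
fst_wc <- function(panel, pop_a, pop_b, window = NULL,
                   chrom_lengths = NULL) {
  comp <- wc_components(panel, list(pop_a, pop_b))
  denom <- comp$a + comp$b + comp$c
  if (is.null(window)) {
    val <- ifelse(!is.na(denom) & denom != 0, comp$a / denom, NA_real_)
    return(data.frame(chrom = panel$sites$chrom, pos = panel$sites$pos,
                      stat = "fst", value = val,
                      n_sites = as.integer(!is.na(denom))))
  }
  if (is.null(chrom_lengths)) chrom_lengths <- infer_chrom_lengths(panel)
  wins <- tile_windows(as.list(chrom_lengths), window)
  s <- panel$sites
  res <- lapply(seq_len(nrow(wins)), function(i) {
    in_w <- s$chrom == wins$chrom[i] & s$pos >= wins$start[i] &
      s$pos < wins$end[i] & !is.na(denom)
    dsum <- sum(denom[in_w])
    data.frame(value = if (sum(in_w) && dsum != 0)
      sum(comp$a[in_w]) / dsum else NA_real_,
      n_sites = sum(in_w))
  })
  cbind(wins, stat = "fst", do.call(rbind, res))
}

#' Select ancestry-informative markers between two subspecies pools
#'
#' Sites with pooled-subspecies Weir-Cockerham F_st strictly above
#' `fst_min`, callable in both the colony and conserved callsets, whose
#' major (diagnostic) alleles differ between the two pools. When `n_max`
#' is set, the top sites by F_st are kept with a deterministic
#' coordinate tie-break.
#'
#' @param colony_callset,conserved_callset `genotype_panel`s.
#' @param pure_a,pure_b character vectors of colony names forming the
#'   two unintrogressed pools.
#' @param fst_min F_st threshold (default 0.8, strict).
#' @param n_max optional cap on the number of AIMs.
#' @return data.frame: `chrom`, `pos`, `fst`, `allele_a`, `allele_b`
#'   (diagnostic allele index per pool).
#' @export
select_aims <- function(colony_callset, conserved_callset, pure_a, pure_b,
                        fst_min = 0.8, n_max = NULL) {
  pa <- colony_samples(colony_callset, pure_a)
  pb <- colony_samples(colony_callset, pure_b)
  fst <- fst_wc(colony_callset, pa, pb)$value
  fa <- allele_freq(colony_callset, pa)$freq
  fb <- allele_freq(colony_callset, pb)$freq
  diag_a <- ifelse(fa > 0.5, 1L, 0L)
  diag_b <- ifelse(fb > 0.5, 1L, 0L)
  in_both <- site_keys(colony_callset) %in% site_keys(conserved_callset)
  keep <- !is.na(fst) & fst > fst_min & in_both &
    !is.na(diag_a) & !is.na(diag_b) & diag_a != diag_b
  aims <- data.frame(chrom = colony_callset$sites$chrom[keep],
                     pos = colony_callset$sites$pos[keep],
                     fst = fst[keep],
                     allele_a = diag_a[keep], allele_b = diag_b[keep],
                     stringsAsFactors = FALSE)
  if (!is.null(n_max)) {
    if (nrow(aims) < n_max)
      warning(sprintf("only %d AIMs available (requested %d)",
                      nrow(aims), n_max))
    ord <- order(-aims$fst, aims$chrom, aims$pos)
    aims <- aims[head(ord, n_max), , drop = FALSE]
    aims <- aims[order(aims$chrom, aims$pos), , drop = FALSE]
  }
  rownames(aims) <- NULL
  aims
}

#' Fraction of AIM loci predominantly showing the donor allele
#'
#' For each AIM, the donor subspecies' diagnostic allele frequency is
#' computed in the test colony; the returned value is the fraction of
#' callable AIM loci where that frequency is strictly above 0.5 (an
#' exact 0.5 does not count as predominant).
#'
#' @param aims AIM table from [select_aims()].
#' @param panel a `genotype_panel` containing the test colony.
#' @param colony colony to score.
#' @param donor `"a"` or `"b"`: which pool of [select_aims()] is the
#'   donor subspecies.
#' @return fraction in \[0, 1\].
#' @export
aim_ancestry_fraction <- function(aims, panel, colony,
                                  donor = c("a", "b")) {
  donor <- match.arg(donor)
  samples <- colony_samples(panel, colony)
  idx <- match(paste(aims$chrom, aims$pos), site_keys(panel))
  ok <- !is.na(idx)
  f_alt <- allele_freq(panel, samples)$freq[idx[ok]]
  donor_allele <- aims[ok, paste0("allele_", donor)]
  f_donor <- ifelse(donor_allele == 1L, f_alt, 1 - f_alt)
  f_donor <- f_donor[!is.na(f_donor)]
  if (!length(f_donor)) stop("no callable AIM loci in colony ", colony)
  mean(f_donor > 0.5)
}

#' Greedy founder-haplotype clustering
#'
#' Phase blocks over a region are compared in order of descending
#' length; a haplotype joins the first existing cluster whose
#' representative (its longest member) differs by at most
#' `max_diff_per_kb` SNP differences per kilobase of overlap, otherwise
#' it founds a new cluster. Haplotypes overlapping a representative by
#' less than `min_overlap` are left unassigned.
#'
#' @param haplotypes list of haplotypes, each a list with `id`, `start`,
#'   `end`, `pos` (site positions), `alleles` (0/1 vector).
#' @param max_diff_per_kb divergence bound (default 1 difference per
#'   kb; strictly more founds a new cluster).
#' @param min_overlap minimum overlap in bp (default 1000).
#' @return integer vector of cluster ids (NA = unassigned), named by
#'   haplotype id; the number of distinct clusters estimates the founder
#'   haplotype count.
#' @export
cluster_founder_haplotypes <- function(haplotypes, max_diff_per_kb = 1.0,
                                       min_overlap = 1000) {
  lens <- vapply(haplotypes, function(h) h$end - h$start, 1)
  ord <- order(-lens)
  cluster <- rep(NA_integer_, length(haplotypes))
  reps <- list()  # cluster representatives (longest member = first)
  for (i in ord) {
    h <- haplotypes[[i]]
    joined <- FALSE
    any_overlap <- FALSE
    for (ci in seq_along(reps)) {
      r <- reps[[ci]]
      lo <- max(h$start, r$start); hi <- min(h$end, r$end)
      if (hi - lo < min_overlap) next
      any_overlap <- TRUE
      shared <- intersect(h$pos[h$pos >= lo & h$pos < hi],
                          r$pos[r$pos >= lo & r$pos < hi])
      nd <- sum(h$alleles[match(shared, h$pos)] !=
                  r$alleles[match(shared, r$pos)])
      if (nd <= max_diff_per_kb * (hi - lo) / 1000) {
        cluster[i] <- ci
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      if (length(reps) && !any_overlap) next  # insufficient overlap
      reps[[length(reps) + 1]] <- h
      cluster[i] <- length(reps)
    }
  }
  names(cluster) <- vapply(haplotypes, function(h) as.character(h$id), "")
  cluster
}
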