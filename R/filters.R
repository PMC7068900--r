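#' Default site-filter thresholds
#'
#' Strict inequalities on GATK-style annotations: quality by depth
#' QD > 5, Fisher strand bias FS < 60, and read-position rank sum
#' |RankSum| < 8 (rank-sum annotations are signed, so the absolute-value
#' reading is the default; set `signed_ranksum = TRUE` for the literal
#' one-sided reading). Only biallelic SNPs are retained.
#'
#' @param qd,fs,ranksum numeric thresholds.
#' @param signed_ranksum if TRUE, test `ranksum < threshold` instead of
#'   `|ranksum| < threshold`.
#' @param missing_annotation `"keep"` or `"drop"`: what to do with sites
#'   lacking an annotation.
#' @param ranksum_field which rank-sum annotation the `ranksum` column
#'   holds (`"ReadPosRankSum"` or `"MQRankSum"`); informational, used by
#'   the VCF reader.
#' @return list of filter settings for [filter_sites()].
#' @export
filter_config <- function(qd = 5, fs = 60, ranksum = 8,
                          signed_ranksum = FALSE,
                          missing_annotation = c("keep", "drop"),
                          ranksum_field = "ReadPosRankSum") {
  list(qd = qd, fs = fs, ranksum = ranksum,
       signed_ranksum = signed_ranksum,
       missing_annotation = match.arg(missing_annotation),
       ranksum_field = ranksum_field)
}

is_snp <- function(ref, alt) {
  nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}

#' Apply site-level quality filters and the biallelic-SNP restriction
#'
#' @param panel a `genotype_panel` (annotation columns `qd`, `fs`,
#'   `ranksum` are consulted when present).
#' @param config a [filter_config()].
#' @return The filtered `genotype_panel`. Idempotent:
#'   `filter_sites(filter_sites(p)) == filter_sites(p)`.
#' @export
filter_sites <- function(panel, config = filter_config()) {
  s <- panel$sites
  n <- nrow(s)
  test <- function(x, pass) {
    if (is.null(x)) x <- rep(NA_real_, n)
    ifelse(is.na(x), config$missing_annotation == "keep", pass(x))
  }
  keep <- test(s$qd, function(x) x > config$qd) &
    test(s$fs, function(x) x < config$fs) &
    test(s$ranksum, function(x) {
      if (config$signed_ranksum) x < config$ranksum
      else abs(x) < config$ranksum
    })
  # biallelic SNP restriction: exactly one alternate allele, both alleles
  # single nucleotides
  keep <- keep & !grepl(",", s$alt, fixed = TRUE) & is_snp(s$ref, s$alt)
  out <- subset_panel(panel, sites = which(keep))
  bad <- !is.na(out$a1) & (out$a1 > 1L | out$a2 > 1L)
  if (any(bad)) {
    i <- which(rowSums(bad) > 0)
    stop(sprintf("genotype allele index > 1 at biallelic site %s:%d",
                 out$sites$chrom[i[1]], out$sites$pos[i[1]] + 1L))
  }
  out
}

#' Build the colony and conserved callsets
#'
#' A site enters the colony callset when it is reliably called in every
#' colony of the focal panel (by default at least one non-missing
#' genotype per colony); the conserved callset additionally requires a
#' call in every outgroup panel at the same chrom/pos. Outgroup samples
#' are appended to the conserved callset so derived-allele polarization
#' can use them directly. The conserved site list is always a subset of
#' the colony site list.
#'
#' @param panel focal colony `genotype_panel`.
#' @param outgroup_panels list of `genotype_panel`s, one per outgroup
#'   species.
#' @param min_called_per_colony minimum non-missing genotypes per colony.
#' @return list with elements `colony` and `conserved` (both
#'   `genotype_panel`s).
#' @export
build_callsets <- function(panel, outgroup_panels = list(),
                           min_called_per_colony = 1L) {
  cpc <- called_per_colony(panel)
  in_colony <- rowSums(cpc >= min_called_per_colony) == ncol(cpc)
  if (!any(in_colony))
    warning("no site is called in every colony; colony callset is empty")
  colony_cs <- subset_panel(panel, sites = which(in_colony))

  keys <- site_keys(colony_cs)
  in_conserved <- rep(TRUE, length(keys))
  for (og in outgroup_panels) {
    og_called <- rowSums(!is.na(og$a1)) >= 1L
    in_conserved <- in_conserved & keys %in% site_keys(og)[og_called]
  }
  conserved <- subset_panel(colony_cs, sites = which(in_conserved))
  # append outgroup genotypes at the conserved sites
  for (og in outgroup_panels) {
    idx <- match(site_keys(conserved), site_keys(og))
    conserved <- genotype_panel(
      conserved$sites,
      cbind(conserved$a1, og$a1[idx, , drop = FALSE]),
      cbind(conserved$a2, og$a2[idx, , drop = FALSE]),
      c(conserved$samples, og$samples),
      c(conserved$colony_of, og$colony_of),
      c(conserved$role_of, og$role_of),
      conserved$phased && og$phased)
  }
  list(colony = colony_cs, conserved = conserved)
}
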