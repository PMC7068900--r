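#' Genotype panel of biallelic SNPs across colony samples
#'
#' The central container: an ordered table of variant sites plus two
#' allele matrices (`a1`, `a2`, sites x samples, entries 0 = reference,
#' 1 = alternate, `NA` = missing) and the sample -> colony -> role
#' metadata used by every downstream module. When `phased = TRUE` the two
#' matrices are haplotype-resolved; otherwise the order of the two
#' alleles within a genotype is arbitrary.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt` and optional annotation columns `qd`, `fs`, `ranksum`.
#' @param a1,a2 integer matrices (sites x samples) of allele indices.
#' @param samples character vector of sample ids (column order of a1/a2).
#' @param colony_of named character vector mapping sample -> colony.
#' @param role_of named character vector mapping colony -> role label
#'   (e.g. subspecies or "outgroup"); optional.
#' @param phased logical; are a1/a2 haplotype-resolved?
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sites, a1, a2, samples, colony_of,
                           role_of = character(), phased = FALSE) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  stopifnot(nrow(a1) == nrow(sites), nrow(a2) == nrow(sites),
            ncol(a1) == length(samples), ncol(a2) == length(samples))
  if (!all(samples %in% names(colony_of)))
    stop("every sample must appear in colony_of")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing genotypes are not supported")
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    a1 <- a1[ord, , drop = FALSE]; a2 <- a2[ord, , drop = FALSE]
  }
  rownames(sites) <- NULL
  colnames(a1) <- colnames(a2) <- samples
  structure(list(sites = sites, a1 = a1, a2 = a2,
                 samples = samples,
                 colony_of = colony_of[samples],
                 role_of = role_of, phased = phased),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d sites x %d samples (%d colonies)%s\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$colony_of)),
              if (x$phased) ", phased" else ""))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) c(nrow(x$sites), length(x$samples))

site_keys <- function(panel) paste(panel$sites$chrom, panel$sites$pos)

#' Subset a panel by site index and/or samples
#'
#' @param panel a `genotype_panel`.
#' @param sites integer or logical index into the site table.
#' @param samples character vector of sample ids to keep.
#' @return A `genotype_panel`.
#' @export
subset_panel <- function(panel, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(panel$sites))
  if (is.null(samples)) samples <- panel$samples
  genotype_panel(panel$sites[sites, , drop = FALSE],
                 panel$a1[sites, samples, drop = FALSE],
                 panel$a2[sites, samples, drop = FALSE],
                 samples, panel$colony_of, panel$role_of, panel$phased)
}

#' Samples belonging to one or more colonies
#' @param panel a `genotype_panel`.
#' @param colonies character vector of colony names.
#' @return character vector of sample ids.
#' @export
colony_samples <- function(panel, colonies) {
  miss <- setdiff(colonies, unique(panel$colony_of))
  if (length(miss)) stop("unknown colony: ", paste(miss, collapse = ", "))
  panel$samples[panel$colony_of %in% colonies]
}

#' Per-site alternate-allele frequency in a set of samples
#'
#' Frequencies are computed over called alleles only; sites with no call
#' in the sample set get `NA`.
#'
#' @param panel a `genotype_panel`.
#' @param samples sample ids (default: all).
#' @return list with `freq` (alt-allele frequency) and `n` (called
#'   chromosomes) per site.
#' @export
allele_freq <- function(panel, samples = panel$samples) {
  a1 <- panel$a1[, samples, drop = FALSE]
  a2 <- panel$a2[, samples, drop = FALSE]
  n <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
  alt <- rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)
  list(freq = ifelse(n > 0, alt / n, NA_real_), n = n)
}

## number of samples with a non-missing genotype per site, per colony
called_per_colony <- function(panel) {
  colonies <- unique(panel$colony_of)
  called <- !is.na(panel$a1)
  sapply(colonies, function(co) {
    rowSums(called[, panel$colony_of == co, drop = FALSE])
  }, simplify = "array") |> matrix(nrow = nrow(panel$sites),
                                   dimnames = list(NULL, colonies))
}

#' Read sample metadata (sample, colony, subspecies/role) from TSV
#'
#' @param path TSV with columns `sample`, `colony`, and optionally
#'   `role` (subspecies label, P1/P2/P3, or "outgroup").
#' @return list with `colony_of` and `role_of` named vectors.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "colony") %in% names(md)))
    stop("metadata must have columns 'sample' and 'colony'")
  colony_of <- setNames(md$colony, md$sample)
  role_of <- character()
  if ("role" %in% names(md)) {
    first <- !duplicated(md$colony)
    role_of <- setNames(md$role[first], md$colony[first])
  }
  list(colony_of = colony_of, role_of = role_of)
}

# ---------------------------------------------------------------------------
# VCF I/O. Reading goes through vcfR; writing is a small deterministic text
# writer so round-trips stay plain text.

#' Write a panel to a VCF 4.2 file
#'
#' Genotypes are emitted as GT (`|`-separated when the panel is phased),
#' QD/FS/ReadPosRankSum annotations as INFO fields when present.
#'
#' @param panel a `genotype_panel`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  s <- panel$sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    paste0("##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,",
           "Description=\"Read position rank-sum\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")), con)
  fmt_num <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g",
                                                      digits = 15))
  info <- rep("", nrow(s))
  for (key in c("qd", "fs", "ranksum")) {
    tag <- c(qd = "QD", fs = "FS", ranksum = "ReadPosRankSum")[[key]]
    if (!is.null(s[[key]])) {
      piece <- ifelse(is.na(s[[key]]), NA,
                      paste0(tag, "=", fmt_num(s[[key]])))
      info <- ifelse(is.na(piece), info,
                     ifelse(info == "", piece, paste(info, piece, sep = ";")))
    }
  }
  info[info == ""] <- "."
  sep <- if (panel$phased) "|" else "/"
  gt <- matrix(paste(panel$a1, panel$a2, sep = sep),
               nrow = nrow(s))
  gt[is.na(panel$a1)] <- paste(".", ".", sep = sep)
  lines <- paste(s$chrom, s$pos + 1L, ".", s$ref, s$alt, ".", ".", info,
                 "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a genotype panel
#'
#' Parsed with vcfR. Multi-allelic sites are retained with their full ALT
#' string and allele codes; [filter_sites()] restricts to biallelic SNPs.
#'
#' @param path VCF path (plain or gzipped).
#' @param colony_of named sample -> colony map; defaults to one colony per
#'   sample named after it.
#' @param role_of optional colony -> role map.
#' @return A `genotype_panel`.
#' @export
read_panel_vcf <- function(path, colony_of = NULL, role_of = character()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  gt <- vcfR::extract.gt(v, element = "GT")
  phased <- any(grepl("|", gt[1, ], fixed = TRUE), na.rm = TRUE)
  split_alleles <- function(k) {
    al <- sub(if (k == 1) "^([^/|]*)[/|].*$" else "^[^/|]*[/|](.*)$", "\\1",
              gt)
    al[al == "." | al == ""] <- NA
    m <- matrix(suppressWarnings(as.integer(al)), nrow = nrow(gt))
    m
  }
  a1 <- split_alleles(1); a2 <- split_alleles(2)
  num_info <- function(tag) {
    x <- vcfR::extract.info(v, element = tag)
    suppressWarnings(as.numeric(x))
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS) - 1,
                      ref = fix$REF, alt = fix$ALT,
                      qd = num_info("QD"), fs = num_info("FS"),
                      ranksum = num_info("ReadPosRankSum"),
                      stringsAsFactors = FALSE)
  if (is.null(colony_of)) colony_of <- setNames(samples, samples)
  genotype_panel(sites, a1, a2, samples, colony_of, role_of, phased)
}
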