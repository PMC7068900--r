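#' Simulation configuration for synthetic colony datasets
#'
#' Defaults describe a toy version of a two-subspecies colony study at
#' roughly 1/100 genomic scale: 3 chromosomes x 5 Mb with ~30% planted
#' repeats, eight colonies (two pure pools per subspecies, a
#' three-colony hybrid zone, and a sister-species outgroup) of 3
#' diploid samples each drawn from small founder pools, subspecies
#' differentiation via Balding-Nichols drift, bidirectional admixture in
#' the hybrid zone, spiked micro and large inversions, Nanopore-like
#' long reads (N50 approximately 6.8 kb), and two caller profiles with
#' differing size preferences and repeat-associated false positives.
#'
#' @param seed master seed; every simulation output is a deterministic
#'   function of it.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param repeat_density target fraction of each chromosome covered by
#'   repeat arrays.
#' @param repeat_motif_length,repeat_families repeat family geometry.
#' @param site_spacing mean distance between SNP sites (bp).
#' @param colonies data.frame(colony, subspecies, n_samples, n_founders).
#' @param f_div named per-subspecies Balding-Nichols drift (differentiation
#'   from the ancestral pool).
#' @param f_colony extra within-subspecies colony-level drift.
#' @param f_outgroup outgroup drift.
#' @param admixture data.frame(donor, recipient, fraction, tract_mean,
#'   shared): donor colony, recipient colony, genome fraction, mean
#'   tract length, and whether tract locations are shared by all
#'   recipient haplotypes (a swept, localized introgression signal — the
#'   kind a windowed fD scan can localize) or drawn independently per
#'   haplotype (diffuse, genome-wide gene flow).
#' @param inversions NULL to auto-place (`n_micro` micro + `n_large`
#'   large at repeat-poor loci), or a data.frame(chrom, start, end) with
#'   an attached list-column `freq` of named colony frequencies.
#' @param n_micro,n_large,micro_size_range,large_size_range auto
#'   placement parameters.
#' @param read_n50,read_sdlog,read_error,read_min_len long-read model.
#' @param callers list of caller profiles (sensitivity by size class,
#'   breakpoint jitter SD, false positives per sample, FP size range).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6,
                                         chr3 = 5e6),
                       repeat_density = 0.30,
                       repeat_motif_length = 400,
                       repeat_families = 6,
                       site_spacing = 300,
                       colonies = NULL,
                       f_div = c(Aaa = 0.35, Aaf = 0.22),
                       f_colony = 0.05,
                       f_outgroup = 0.75,
                       admixture = NULL,
                       inversions = NULL,
                       n_micro = 6, n_large = 2,
                       micro_size_range = c(2e4, 4e5),
                       large_size_range = c(8e5, 1.5e6),
                       read_n50 = 6789, read_sdlog = 0.55,
                       read_error = 0.05, read_min_len = 500,
                       callers = NULL) {
  if (is.null(colonies))
    colonies <- data.frame(
      colony = c("Thailand_Aaa", "USA_Aaa", "Kenya_Aaa", "Kenya_Hyb",
                 "Kenya_Aaf", "Uganda_Aaf", "Gabon_Aaf", "Mascarensis"),
      subspecies = c("Aaa", "Aaa", "Aaa", "Hyb", "Aaf", "Aaf", "Aaf",
                     "outgroup"),
      n_samples = c(3, 3, 3, 3, 3, 3, 3, 2),
      n_founders = c(6, 4, 3, 2, 5, 8, 8, 4),
      stringsAsFactors = FALSE)
  if (is.null(admixture))
    admixture <- data.frame(
      donor = c("Kenya_Aaf", "Kenya_Aaf", "Kenya_Aaf", "Kenya_Aaa"),
      recipient = c("Kenya_Aaa", "Kenya_Aaa", "Kenya_Hyb", "Kenya_Aaf"),
      fraction = c(0.06, 0.05, 0.35, 0.10),
      tract_mean = c(3e5, 8e4, 2e5, 8e4),
      shared = c(TRUE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE)
  if (is.null(callers))
    callers <- list(
      LR = list(sens_micro = 0.9, sens_large = 0.45, jitter_sd = 50,
                fp_per_sample = 2, fp_size_range = c(1e4, 2e5)),
      GSV = list(sens_micro = 0.35, sens_large = 0.85, jitter_sd = 120,
                 fp_per_sample = 1, fp_size_range = c(2e5, 2e6)))
  structure(list(seed = seed, chrom_lengths = chrom_lengths,
                 repeat_density = repeat_density,
                 repeat_motif_length = repeat_motif_length,
                 repeat_families = repeat_families,
                 site_spacing = site_spacing, colonies = colonies,
                 f_div = f_div, f_colony = f_colony,
                 f_outgroup = f_outgroup, admixture = admixture,
                 inversions = inversions, n_micro = n_micro,
                 n_large = n_large,
                 micro_size_range = micro_size_range,
                 large_size_range = large_size_range,
                 read_n50 = read_n50, read_sdlog = read_sdlog,
                 read_error = read_error, read_min_len = read_min_len,
                 callers = callers),
            class = "sim_config")
}

#' Read/write a simulation config as YAML
#' @param path YAML file path.
#' @return a `sim_config` (read) or `path` (write).
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("colonies", "admixture"))
    if (!is.null(y[[nm]])) y[[nm]] <- as.data.frame(y[[nm]])
  for (nm in c("chrom_lengths", "f_div"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  do.call(sim_config, y)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a repeat-bearing reference genome
#'
#' Random background sequence with tandem repeat arrays planted from a
#' small set of mutated family motifs until the configured density is
#' reached; every planted copy is recorded in the annotation.
#'
#' @param config a [sim_config()].
#' @return list: `sequences` (named character), `repeats` (interval
#'   data.frame with `family`).
#' @export
simulate_reference <- function(config) {
  if (config$repeat_density >= 1) stop("repeat density must be < 1")
  set.seed(config$seed)
  motifs <- replicate(config$repeat_families,
                      .rand_dna(config$repeat_motif_length))
  seqs <- list()
  ann <- list()
  for (ch in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[ch]]
    base <- strsplit(.rand_dna(len), "")[[1]]
    target <- config$repeat_density * len
    placed <- 0
    while (placed < target) {
      fam <- sample.int(length(motifs), 1)
      copies <- sample(1:4, 1)
      motif <- strsplit(motifs[fam], "")[[1]]
      # per-array divergence of the motif copy
      nmut <- rpois(1, 0.03 * length(motif))
      if (nmut > 0) {
        at <- sample.int(length(motif), min(nmut, length(motif)))
        motif[at] <- sample(c("A", "C", "G", "T"), length(at),
                            replace = TRUE)
      }
      arr <- rep(motif, copies)
      start <- sample.int(len - length(arr), 1)
      base[start:(start + length(arr) - 1)] <- arr
      ann[[length(ann) + 1]] <-
        data.frame(chrom = ch, start = start - 1,
                   end = start - 1 + length(arr),
                   family = paste0("fam", fam), stringsAsFactors = FALSE)
      placed <- placed + length(arr)
    }
    seqs[[ch]] <- paste(base, collapse = "")
  }
  repeats <- if (length(ann)) do.call(rbind, ann)
  else data.frame(chrom = character(), start = numeric(),
                  end = numeric(), family = character())
  repeats <- repeats[order(repeats$chrom, repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL
  list(sequences = unlist(seqs), repeats = repeats)
}

.balding_nichols <- function(p0, f) {
  shape <- (1 - f) / f
  rbeta(length(p0), p0 * shape, (1 - p0) * shape)
}

#' Simulate a colony genotype panel with drift and introgression
#'
#' Ancestral allele frequencies are drawn per site; each subspecies
#' drifts by Balding-Nichols with its `f_div`, each colony drifts
#' further by `f_colony`, and the outgroup by `f_outgroup`. Founder
#' haplotypes are sampled per colony from the colony frequencies and
#' colony samples resample founders (capturing founder effects), then
#' admixture events copy donor-colony tracts into recipient haplotypes
#' at the configured genome fraction. The reference allele is the
#' ancestral state.
#'
#' @param config a [sim_config()].
#' @param reference from [simulate_reference()].
#' @return list: `panel` (phased `genotype_panel`, all colonies incl.
#'   outgroup), `truth` (ancestral alleles, founder assignment per
#'   haplotype, introgressed tracts with donor labels).
#' @export
simulate_panel <- function(config, reference) {
  set.seed(config$seed + 1)
  col_tab <- config$colonies
  if (any(col_tab$n_founders < 1)) stop("founder count must be >= 1")
  # site map
  sites <- do.call(rbind, lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    n <- round(len / config$site_spacing)
    pos <- sort(sample.int(len, n)) - 1
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  ns <- nrow(sites)
  p0 <- rbeta(ns, 0.6, 0.6)
  # subspecies pools; the hybrid-zone label draws from both parents
  sub_named <- setdiff(unique(col_tab$subspecies), c("outgroup", "Hyb"))
  p_sub <- sapply(sub_named, function(sp)
    .balding_nichols(p0, config$f_div[[sp]]))
  p_out <- .balding_nichols(p0, config$f_outgroup)
  samples <- character(); colony_of <- character()
  a1 <- NULL; a2 <- NULL
  founder_of <- list()
  for (i in seq_len(nrow(col_tab))) {
    co <- col_tab$colony[i]; sp <- col_tab$subspecies[i]
    p_col <- if (sp == "outgroup") p_out
    else if (sp == "Hyb") {
      w <- runif(1, 0.4, 0.6)
      .balding_nichols(w * p_sub[, "Aaa"] + (1 - w) * p_sub[, "Aaf"],
                       config$f_colony)
    } else .balding_nichols(p_sub[, sp], config$f_colony)
    nf <- col_tab$n_founders[i]
    founders <- matrix(rbinom(ns * 2 * nf, 1, p_col), ns, 2 * nf)
    for (s in seq_len(col_tab$n_samples[i])) {
      sid <- sprintf("%s_s%d", co, s)
      pick <- sample.int(2 * nf, 2, replace = TRUE)
      a1 <- cbind(a1, founders[, pick[1]])
      a2 <- cbind(a2, founders[, pick[2]])
      samples <- c(samples, sid)
      colony_of[sid] <- co
      founder_of[[sid]] <- pick
    }
  }
  role_of <- setNames(col_tab$subspecies, col_tab$colony)
  panel <- genotype_panel(sites, a1, a2, samples, colony_of, role_of,
                          phased = TRUE)
  # admixture: copy donor tracts into recipient haplotypes
  tracts <- list()
  adm <- config$admixture
  chrom_lengths <- config$chrom_lengths
  draw_tracts <- function(frac, tract_mean, single = FALSE) {
    out <- list()
    for (ch in names(chrom_lengths)) {
      len <- chrom_lengths[[ch]]
      if (single) {
        # one clean tract per chromosome covering the target fraction —
        # the swept-haplotype geometry a windowed scan localizes
        tlen <- round(frac * len)
        tstart <- sample.int(len - tlen, 1) - 1
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = tstart, end = tstart + tlen,
          stringsAsFactors = FALSE)
        next
      }
      covered <- 0
      guard <- 0
      while (covered < frac * len && guard < 1000) {
        guard <- guard + 1
        tlen <- min(round(stats::rexp(1, 1 / tract_mean)) + 1e4, len)
        tstart <- sample.int(max(len - tlen, 1), 1) - 1
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = tstart, end = tstart + tlen,
          stringsAsFactors = FALSE)
        covered <- covered + tlen
      }
    }
    do.call(rbind, out)
  }
  for (k in seq_len(NROW(adm))) {
    rec_samples <- panel$samples[panel$colony_of == adm$recipient[k]]
    # the donor may pool several colonies ("A+B")
    don_cols <- strsplit(adm$donor[k], "+", fixed = TRUE)[[1]]
    don_samples <- panel$samples[panel$colony_of %in% don_cols]
    if (!length(rec_samples) || !length(don_samples)) next
    shared <- isTRUE(adm$shared[k])
    shared_tr <- if (shared) draw_tracts(adm$fraction[k],
                                         adm$tract_mean[k],
                                         single = TRUE)
    for (sid in rec_samples) for (hap in 1:2) {
      tr <- if (shared) shared_tr
      else draw_tracts(adm$fraction[k], adm$tract_mean[k])
      for (t in seq_len(NROW(tr))) {
        don <- sample(don_samples, 1)
        dhap <- sample(1:2, 1)
        sel <- panel$sites$chrom == tr$chrom[t] &
          panel$sites$pos >= tr$start[t] & panel$sites$pos < tr$end[t]
        src <- if (dhap == 1) panel$a1[sel, don] else panel$a2[sel, don]
        if (hap == 1) panel$a1[sel, sid] <- src
        else panel$a2[sel, sid] <- src
        tracts[[length(tracts) + 1]] <-
          data.frame(sample = sid, hap = hap, chrom = tr$chrom[t],
                     start = tr$start[t], end = tr$end[t],
                     donor = adm$donor[k], stringsAsFactors = FALSE)
      }
    }
  }
  truth <- list(
    ancestral = data.frame(sites, ancestral = 0L),
    founder_of = founder_of,
    tracts = if (length(tracts)) do.call(rbind, tracts)
    else data.frame(sample = character(), hap = integer(),
                    chrom = character(), start = numeric(),
                    end = numeric(), donor = character()))
  list(panel = panel, truth = truth)
}

## choose inversion loci with repeat-poor breakpoint flanks
place_inversions <- function(config, reference, flank = 10000) {
  rep_m <- if (nrow(reference$repeats))
    merge_intervals(reference$repeats) else NULL
  out <- list()
  draw <- function(n, size_range, is_micro) {
    drawn <- 0
    attempts <- 0
    max_repeat <- 0.15  # want clean flanks for spiked truth
    while (drawn < n) {
      attempts <- attempts + 1
      if (attempts %% 2000 == 0) {
        max_repeat <- max_repeat + 0.15
        warning("relaxing flank-repeat bound for inversion placement")
      }
      if (attempts > 10000)
        stop("cannot place ", n, " inversions of ",
             size_range[1], "-", size_range[2],
             " bp on this genome; reduce counts or sizes")
      ch <- sample(names(config$chrom_lengths), 1)
      size <- round(runif(1, size_range[1], size_range[2]))
      len <- config$chrom_lengths[[ch]]
      if (len - size - 2 * flank <= flank) next
      s <- sample(seq(flank, len - size - flank), 1)
      fr <- flank_repeat_fraction(rep_m, ch, s, s + size, flank)
      if (fr > max_repeat) next
      # avoid overlap with already placed inversions
      clash <- any(vapply(out, function(o)
        o$chrom == ch && o$start < s + size + 2 * flank &&
          s < o$end + 2 * flank, TRUE))
      if (clash) next
      out[[length(out) + 1]] <<-
        data.frame(chrom = ch, start = s, end = s + size,
                   is_micro = is_micro, stringsAsFactors = FALSE)
      drawn <- drawn + 1
    }
  }
  draw(config$n_micro, config$micro_size_range, TRUE)
  draw(config$n_large, config$large_size_range, FALSE)
  do.call(rbind, out)
}

#' Spike inversions into the simulated panel
#'
#' Assigns inversion loci (auto-placed at repeat-poor flanks unless
#' given in the config) to carrier haplotypes at per-colony
#' frequencies. Carrier haplotypes have the segment reverse-complemented
#' whenever sequence is realized via [haplotype_sequence()].
#'
#' @param config a [sim_config()].
#' @param reference from [simulate_reference()].
#' @param panel from [simulate_panel()].
#' @return list: `inversions` (loci with ids), `carriers` (data.frame
#'   sample/hap/inversion id).
#' @export
spike_inversions <- function(config, reference, panel) {
  set.seed(config$seed + 2)
  inv <- config$inversions
  if (is.null(inv)) inv <- place_inversions(config, reference)
  inv$id <- sprintf("inv%02d", seq_len(nrow(inv)))
  freqs <- attr(config$inversions, "freq")
  colonies <- unique(panel$colony_of)
  carriers <- list()
  for (i in seq_len(nrow(inv))) {
    fr <- if (!is.null(freqs)) freqs[[i]]
    else {
      # shared polymorphism: segregates in a random subset of colonies
      in_col <- sample(colonies, sample(2:length(colonies), 1))
      setNames(ifelse(colonies %in% in_col, runif(length(colonies),
                                                  0.3, 0.9), 0),
               colonies)
    }
    got_one <- FALSE
    for (sid in panel$samples) {
      f <- fr[[panel$colony_of[[sid]]]]
      if (is.null(f) || is.na(f)) f <- 0
      for (hap in 1:2)
        if (f >= 1 || (f > 0 && rbinom(1, 1, f) == 1)) {
          carriers[[length(carriers) + 1]] <-
            data.frame(sample = sid, hap = hap, id = inv$id[i],
                       stringsAsFactors = FALSE)
          got_one <- TRUE
        }
    }
    if (!got_one) {  # every spiked inversion exists in >= 1 haplotype
      sid <- sample(panel$samples, 1)
      carriers[[length(carriers) + 1]] <-
        data.frame(sample = sid, hap = 1L, id = inv$id[i],
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(carriers))
    carriers <- list(data.frame(sample = character(), hap = integer(),
                                id = character()))
  list(inversions = inv,
       carriers = do.call(rbind, carriers))
}

#' Realize the genomic sequence of one haplotype
#'
#' Applies the haplotype's alternate alleles to the reference (the
#' alternate base is a deterministic transversion of the reference
#' base) and reverse-complements any inversion segments the haplotype
#' carries.
#'
#' @param reference from [simulate_reference()].
#' @param panel phased `genotype_panel`.
#' @param sample,hap haplotype identity (hap 1 or 2).
#' @param chrom chromosome.
#' @param spiked optional result of [spike_inversions()].
#' @return character scalar sequence.
#' @export
haplotype_sequence <- function(reference, panel, sample, hap, chrom,
                               spiked = NULL) {
  seqv <- Biostrings::DNAString(reference$sequences[[chrom]])
  al <- if (hap == 1) panel$a1[, sample] else panel$a2[, sample]
  sel <- which(panel$sites$chrom == chrom & !is.na(al) & al == 1L)
  if (length(sel)) {
    pos <- panel$sites$pos[sel] + 1L
    refb <- strsplit(as.character(seqv[pos]), "")[[1]]
    altb <- chartr("ACGT", "TGCA", refb)  # fixed complement transversion
    seqv <- Biostrings::replaceLetterAt(seqv, pos, altb)
  }
  if (!is.null(spiked)) {
    mine <- spiked$carriers[spiked$carriers$sample == sample &
                              spiked$carriers$hap == hap, "id"]
    for (iid in mine) {
      loc <- spiked$inversions[spiked$inversions$id == iid, ]
      if (loc$chrom != chrom) next
      seg <- Biostrings::subseq(seqv, loc$start + 1, loc$end)
      seqv <- Biostrings::replaceAt(
        seqv, IRanges::IRanges(loc$start + 1, loc$end),
        as.character(Biostrings::reverseComplement(seg)))
    }
  }
  as.character(seqv)
}

#' Simulate long reads from a sequence
#'
#' Read lengths are log-normal with `meanlog` chosen so the theoretical
#' N50 (the median of the length-biased distribution,
#' `exp(meanlog + sdlog^2)`) matches the target; starts are uniform;
#' substitution errors are uniform at `error_rate`; strands are random
#' and recorded in the read names.
#'
#' @param seq character scalar to sample reads from.
#' @param coverage target mean coverage (total read bases / length).
#' @param n50 target read N50 (default 6789).
#' @param sdlog log-normal shape (default 0.55).
#' @param error_rate per-base substitution rate.
#' @param min_len minimum read length.
#' @param seed optional seed.
#' @param prefix read-name prefix.
#' @return named character vector of reads (names
#'   `<prefix>_<i>_<strand>`).
#' @export
simulate_long_reads <- function(seq, coverage = 30, n50 = 6789,
                                sdlog = 0.55, error_rate = 0.05,
                                min_len = 500, seed = NULL,
                                prefix = "read") {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(seq)
  if (coverage <= 0) return(setNames(character(0), character(0)))
  meanlog <- log(n50) - sdlog^2
  mean_len <- exp(meanlog + sdlog^2 / 2)
  n <- max(1, round(coverage * L / mean_len))
  lens <- pmax(round(rlnorm(n, meanlog, sdlog)), min_len)
  lens <- pmin(lens, L)
  starts <- floor(runif(n, 0, L - lens + 1))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  reads <- substring(seq, starts + 1, starts + lens)
  # substitution errors, applied in one pass over the concatenated batch
  if (error_rate > 0) {
    big <- utf8ToInt(paste(reads, collapse = ""))
    nerr <- rbinom(1, length(big), error_rate)
    if (nerr > 0) {
      at <- sample.int(length(big), nerr)
      codes <- utf8ToInt("ACGT")
      shift <- sample(1:3, nerr, replace = TRUE)
      idx <- match(big[at], codes)
      ok <- !is.na(idx)
      big[at[ok]] <- codes[(idx[ok] - 1 + shift[ok]) %% 4 + 1]
    }
    ends <- cumsum(lens)
    reads <- substring(intToUtf8(big), ends - lens + 1, ends)
  }
  flip <- strands == "-"
  if (any(flip))
    reads[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[flip])))
  setNames(reads, sprintf("%s_%d_%s", prefix, seq_along(reads), strands))
}

#' Simulate caller-like inversion candidate tables
#'
#' Each configured caller detects true carrier inversions with a
#' size-class-dependent sensitivity, jitters breakpoints, and adds
#' false-positive candidates preferentially at repeat loci with a
#' caller-specific size profile.
#'
#' @param config a [sim_config()].
#' @param spiked from [spike_inversions()].
#' @param panel from [simulate_panel()].
#' @param reference from [simulate_reference()] (for repeat-located
#'   false positives).
#' @return data.frame of candidates (chrom, start, end, sample,
#'   caller, is_true, inversion id or NA).
#' @export
simulate_candidate_calls <- function(config, spiked, panel, reference) {
  set.seed(config$seed + 3)
  out <- list()
  carriers <- unique(spiked$carriers[, c("sample", "id")])
  reps <- reference$repeats
  for (cl in names(config$callers)) {
    prof <- config$callers[[cl]]
    for (j in seq_len(nrow(carriers))) {
      loc <- spiked$inversions[spiked$inversions$id == carriers$id[j], ]
      sens <- if (loc$is_micro) prof$sens_micro else prof$sens_large
      if (rbinom(1, 1, sens) == 0) next
      jit <- round(stats::rnorm(2, 0, prof$jitter_sd))
      start <- max(0, loc$start + jit[1])
      end <- max(start + 1, loc$end + jit[2])
      out[[length(out) + 1]] <-
        data.frame(chrom = loc$chrom, start = start, end = end,
                   sample = carriers$sample[j], caller = cl,
                   is_true = TRUE, id = loc$id, stringsAsFactors = FALSE)
    }
    # repeat-associated false positives
    if (nrow(reps))
      for (sid in panel$samples) {
        nfp <- rpois(1, prof$fp_per_sample)
        for (f in seq_len(nfp)) {
          rrow <- reps[sample.int(nrow(reps), 1), ]
          len <- config$chrom_lengths[[rrow$chrom]]
          size <- round(runif(1, prof$fp_size_range[1],
                              prof$fp_size_range[2]))
          size <- min(size, len - 2)  # keep FP calls on the chromosome
          start <- max(0, min(rrow$start, len - size - 1))
          out[[length(out) + 1]] <-
            data.frame(chrom = rrow$chrom, start = start,
                       end = start + size, sample = sid, caller = cl,
                       is_true = FALSE, id = NA_character_,
                       stringsAsFactors = FALSE)
        }
      }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), sample = character(),
                      caller = character(), is_true = logical(),
                      id = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$sample, res$caller), ]
  rownames(res) <- NULL
  res
}

#' Simulate the complete synthetic colony dataset
#'
#' Convenience wrapper running reference, panel, inversion spiking and
#' candidate simulation under one seed.
#'
#' @param config a [sim_config()].
#' @return list: `config`, `reference`, `panel`, `truth`, `spiked`,
#'   `candidates`.
#' @export
simulate_colony_dataset <- function(config = sim_config()) {
  reference <- simulate_reference(config)
  pt <- simulate_panel(config, reference)
  spiked <- spike_inversions(config, reference, pt$panel)
  candidates <- simulate_candidate_calls(config, spiked, pt$panel,
                                         reference)
  list(config = config, reference = reference, panel = pt$panel,
       truth = pt$truth, spiked = spiked, candidates = candidates)
}

#' Read assignments for repeat-matched artificial (uninverted) breakpoints
#'
#' The null experiment behind validation calibration: artificial
#' breakpoint pairs are sampled to match candidate repeat content, long
#' reads are simulated from the *uninverted* reference around each
#' junction, competitively assigned against that locus's pan-genome,
#' and the per-junction coverage / inverted-fraction statistics are
#' returned for [calibrate_null()].
#'
#' @param reference from [simulate_reference()] (or any named sequence
#'   set).
#' @param repeats repeat annotation intervals.
#' @param candidates candidate call intervals whose repeat content the
#'   null must match.
#' @param n number of artificial breakpoint pairs (default 1000).
#' @param flank junction flank length (default 10 kb).
#' @param coverage simulated long-read coverage (default 30).
#' @param read_window half-width of the region reads are drawn from
#'   around each junction (default 8 kb).
#' @param n50,sdlog,error_rate,min_len read model (see
#'   [simulate_long_reads()]).
#' @param aligner aligner object (default [kmer_aligner()]).
#' @param seed integer seed.
#' @return list: `breakpoints` (the artificial loci), `stats`
#'   (per-junction data.frame for [calibrate_null()]).
#' @export
simulate_null_assignments <- function(reference, repeats, candidates,
                                      n = 1000, flank = 10000,
                                      coverage = 30, read_window = 8000,
                                      n50 = 6789, sdlog = 0.55,
                                      error_rate = 0.05, min_len = 500,
                                      aligner = kmer_aligner(),
                                      seed = 1) {
  seqs <- if (is.list(reference) && !is.null(reference$sequences))
    reference$sequences else reference
  bps <- generate_artificial_breakpoints(seqs, repeats, candidates,
                                         n = n, flank = flank,
                                         seed = seed)
  stats <- vector("list", n)
  for (i in seq_len(n)) {
    bp <- bps[i, ]
    pg <- build_pangenome(seqs, bp, flank = flank, background = FALSE)
    chrom_seq <- seqs[[bp$chrom]]
    len <- nchar(chrom_seq)
    asn <- lapply(c(bp$start, bp$end), function(j) {
      lo <- max(0, j - read_window); hi <- min(len, j + read_window)
      reads <- simulate_long_reads(seq_slice(chrom_seq, lo, hi),
                                   coverage = coverage, n50 = n50,
                                   sdlog = sdlog,
                                   error_rate = error_rate,
                                   min_len = min_len,
                                   seed = seed + 7 * i + round(j %% 7),
                                   prefix = sprintf("null%d_%d", i, j))
      assign_reads(reads, pg, aligner = aligner)
    })
    stats[[i]] <- breakpoint_stats(do.call(rbind, asn))
  }
  list(breakpoints = bps, stats = do.call(rbind, stats))
}
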