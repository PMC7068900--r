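#' Derived-allele frequencies for a population quartet
#'
#' Computes per-site frequencies for P1, P2, P3 and the outgroup from
#' colony pools, polarized so that "derived" is the allele rare or
#' absent in the outgroup: sites where the outgroup alternate-allele
#' frequency exceeds `max_outgroup_freq` after polarization are
#' excluded, as are sites with an uncalled pool.
#'
#' @param panel a `genotype_panel` (typically the conserved callset with
#'   outgroup samples).
#' @param p1,p2,p3,outgroup colony names (each may be a vector pooling
#'   several colonies).
#' @param max_outgroup_freq tolerated derived-allele frequency in the
#'   outgroup (default 0.1).
#' @return data.frame: `chrom`, `pos`, `p1`, `p2`, `p3`, `po` (derived
#'   frequencies).
#' @export
quartet_freqs <- function(panel, p1, p2, p3, outgroup,
                          max_outgroup_freq = 0.1) {
  f <- lapply(list(p1, p2, p3, outgroup), function(co)
    allele_freq(panel, colony_samples(panel, co))$freq)
  names(f) <- c("p1", "p2", "p3", "po")
  called <- Reduce(`&`, lapply(f, function(x) !is.na(x)))
  # polarize: if the outgroup is mostly ALT, the REF allele is derived
  flip <- !is.na(f$po) & f$po > 0.5
  f <- lapply(f, function(x) ifelse(flip, 1 - x, x))
  keep <- called & f$po <= max_outgroup_freq
  data.frame(chrom = panel$sites$chrom[keep], pos = panel$sites$pos[keep],
             p1 = f$p1[keep], p2 = f$p2[keep], p3 = f$p3[keep],
             po = f$po[keep], stringsAsFactors = FALSE)
}

abba_baba_site <- function(p1, p2, p3, po) {
  list(abba = (1 - p1) * p2 * p3 * (1 - po),
       baba = p1 * (1 - p2) * p3 * (1 - po))
}

#' Patterson's D from quartet allele frequencies
#'
#' The frequency (population-sample) form: per site
#' `ABBA = (1-p1) p2 p3 (1-pO)`, `BABA = p1 (1-p2) p3 (1-pO)`;
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)`. An ABBA excess (D > 0)
#' indicates gene flow between P3 and P2.
#'
#' @param freqs data.frame from [quartet_freqs()] (columns `p1`, `p2`,
#'   `p3`, `po`; `chrom`/`pos` optional but required for jackknifing).
#' @param block_size jackknife block size in bp (contiguous coordinate
#'   slabs; default 5 Mb); set NULL to skip the jackknife.
#' @param z_min significance threshold on |Z| (default 2).
#' @return A `d_result`: `d`, `sum_abba`, `sum_baba`, `n_sites`, and —
#'   when jackknifed — `n_blocks`, `sd`, `z`, `significant`. `d` is `NA`
#'   (undefined) when `sum_abba + sum_baba` is 0, and `z` is `NA` with
#'   `sd_zero = TRUE` when the jackknife SD is 0.
#' @export
patterson_d <- function(freqs, block_size = 5e6, z_min = 2) {
  ab <- abba_baba_site(freqs$p1, freqs$p2, freqs$p3, freqs$po)
  s_abba <- sum(ab$abba); s_baba <- sum(ab$baba)
  tot <- s_abba + s_baba
  d <- if (tot > 0) (s_abba - s_baba) / tot else NA_real_
  res <- list(d = d, sum_abba = s_abba, sum_baba = s_baba,
              n_sites = nrow(freqs), sd = NA_real_, z = NA_real_,
              n_blocks = NA_integer_, significant = NA, sd_zero = FALSE)
  if (!is.null(block_size) && !is.na(d)) {
    jk <- block_jackknife(ab$abba, ab$baba, freqs$chrom, freqs$pos,
                          block_size)
    res$sd <- jk$sd; res$z <- jk$z; res$n_blocks <- jk$n_blocks
    res$sd_zero <- jk$sd_zero
    res$significant <- if (jk$sd_zero) NA else abs(jk$z) >= z_min
  }
  structure(res, class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("Patterson's D = %.4f (ABBA %.2f, BABA %.2f, %d sites)\n",
              x$d, x$sum_abba, x$sum_baba, x$n_sites))
  if (!is.na(x$n_blocks))
    cat(sprintf("  jackknife: %d blocks, SD = %.4f, Z = %.2f%s\n",
                x$n_blocks, x$sd, x$z,
                if (isTRUE(x$significant)) " (significant)" else ""))
  invisible(x)
}

#' Block-jackknife standard deviation and Z for Patterson's D
#'
#' Sites are grouped into contiguous coordinate blocks of `block_size`
#' bp; D is recomputed leaving each block out, and
#' `SD = sqrt((m-1)/m * sum((D_-j - mean(D_-.))^2))` over the m blocks.
#' `Z = D / SD`.
#'
#' @param abba,baba per-site ABBA/BABA values.
#' @param chrom,pos site coordinates.
#' @param block_size block size in bp.
#' @return list: `sd`, `z`, `n_blocks`, `sd_zero`.
#' @export
block_jackknife <- function(abba, baba, chrom, pos, block_size = 5e6) {
  block <- paste(chrom, floor(pos / block_size))
  s_ab <- tapply(abba, block, sum)
  s_ba <- tapply(baba, block, sum)
  nonempty <- (s_ab + s_ba) >= 0  # blocks listed exist by construction
  m <- sum(nonempty)
  if (m < 2) stop("block jackknife needs at least 2 non-empty blocks")
  tot_ab <- sum(s_ab); tot_ba <- sum(s_ba)
  d_minus <- (tot_ab - s_ab - (tot_ba - s_ba)) /
    (tot_ab - s_ab + tot_ba - s_ba)
  sd_jk <- sqrt((m - 1) / m * sum((d_minus - mean(d_minus))^2))
  d <- (tot_ab - tot_ba) / (tot_ab + tot_ba)
  list(sd = sd_jk,
       z = if (sd_jk > 0) d / sd_jk else NA_real_,
       n_blocks = m, sd_zero = sd_jk == 0)
}

#' Martin's fD windowed introgression track
#'
#' Per coordinate window, the ABBA-BABA imbalance
#' `S = sum(ABBA - BABA)` is normalized by its maximal value given local
#' diversity: the same sum with p2 and p3 both replaced at every site by
#' `pD = max(p2, p3)`. Windows whose numerator is not positive are
#' reported as missing (fD is only meaningful where the window-level
#' signal is ABBA-like).
#'
#' @param freqs data.frame from [quartet_freqs()].
#' @param window window size in bp (default 1 Mb).
#' @param chrom_lengths named vector; inferred from sites when NULL.
#' @return data.frame: `chrom`, `start`, `end`, `stat` = "fd", `value`
#'   (NA where undefined), `n_sites`.
#' @export
martin_fd <- function(freqs, window = 1e6, chrom_lengths = NULL) {
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(freqs$pos + 1, freqs$chrom, max)
  wins <- tile_windows(as.list(chrom_lengths), window)
  ab <- abba_baba_site(freqs$p1, freqs$p2, freqs$p3, freqs$po)
  pd <- pmax(freqs$p2, freqs$p3)
  abd <- abba_baba_site(freqs$p1, pd, pd, freqs$po)
  num_site <- ab$abba - ab$baba
  den_site <- abd$abba - abd$baba
  res <- lapply(seq_len(nrow(wins)), function(i) {
    in_w <- freqs$chrom == wins$chrom[i] & freqs$pos >= wins$start[i] &
      freqs$pos < wins$end[i]
    num <- sum(num_site[in_w]); den <- sum(den_site[in_w])
    if (sum(in_w) > 0 && num > 0 && den <= 0)
      stop("fD denominator not positive with positive numerator")
    data.frame(value = if (sum(in_w) > 0 && num > 0) num / den
               else NA_real_,
               n_sites = sum(in_w))
  })
  cbind(wins, stat = "fd", do.call(rbind, res))
}

#' Call peaks of introgression on an fD track
#'
#' A window is peak-eligible when its fD exceeds the Tukey fence
#' `Q3 + fence x IQR` of all non-missing track values AND is at least
#' `local_frac` of the rolling maximum over a centered `local_window`
#' neighborhood (truncated at chromosome ends). Adjacent eligible
#' windows merge into one peak.
#'
#' @param track fD track from [martin_fd()].
#' @param fence IQR multiplier (default 1.5).
#' @param local_window neighborhood span in bp (default 200 Mb; scale
#'   down with the genome).
#' @param local_frac fraction of the local maximum required
#'   (default 0.9).
#' @param anchor fence anchored at `"q3"` (Tukey, default) or
#'   `"median"`.
#' @return data.frame of peaks: `chrom`, `start`, `end`, `max_fd`,
#'   `n_windows`.
#' @export
detect_peaks <- function(track, fence = 1.5, local_window = 2e8,
                         local_frac = 0.9, anchor = c("q3", "median")) {
  anchor <- match.arg(anchor)
  vals <- track$value
  if (all(is.na(vals)))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), max_fd = numeric(),
                      n_windows = integer()))
  if (sum(!is.na(vals)) < 4)
    stop("peak detection needs at least 4 non-missing windows")
  q <- quantile(vals, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7,
                names = FALSE)
  iqr <- q[3] - q[1]
  cut <- (if (anchor == "q3") q[3] else q[2]) + fence * iqr
  mid <- (track$start + track$end) / 2
  local_max <- vapply(seq_len(nrow(track)), function(i) {
    nb <- track$chrom == track$chrom[i] &
      abs(mid - mid[i]) <= local_window / 2
    suppressWarnings(max(vals[nb], na.rm = TRUE))
  }, 1)
  eligible <- !is.na(vals) & vals > cut & vals >= local_frac * local_max
  # merge runs of adjacent eligible windows on the same chromosome
  peaks <- list()
  i <- 1
  while (i <= length(eligible)) {
    if (!eligible[i]) { i <- i + 1; next }
    j <- i
    while (j + 1 <= length(eligible) && eligible[j + 1] &&
           track$chrom[j + 1] == track$chrom[i] &&
           track$start[j + 1] == track$end[j]) j <- j + 1
    peaks[[length(peaks) + 1]] <-
      data.frame(chrom = track$chrom[i], start = track$start[i],
                 end = track$end[j],
                 max_fd = max(vals[i:j], na.rm = TRUE),
                 n_windows = j - i + 1L)
    i <- j + 1
  }
  if (!length(peaks))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), max_fd = numeric(),
                      n_windows = integer()))
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Compare fD inside versus outside inversion loci
#'
#' Track windows are classified by overlap with any inversion interval;
#' the two sets of fD values are compared with a two-sided Mann-Whitney
#' U test.
#'
#' @param track fD track from [martin_fd()].
#' @param inversions interval data.frame of inversion calls.
#' @return list: `mean_in`, `mean_out`, `u` (U statistic for the inside
#'   class), `p` (two-sided), `n_in`, `n_out`.
#' @export
compare_fd_inside_outside <- function(track, inversions) {
  ov <- vapply(seq_len(nrow(track)), function(i)
    sum(interval_intersection(track$chrom[i], track$start[i],
                              track$end[i], inversions)) > 0, TRUE)
  inside <- track$value[ov & !is.na(track$value)]
  outside <- track$value[!ov & !is.na(track$value)]
  if (!length(inside) || !length(outside))
    stop("both window classes must be non-empty for the comparison")
  wt <- wilcox.test(inside, outside, alternative = "two.sided",
                    exact = FALSE, correct = FALSE)
  list(mean_in = mean(inside), mean_out = mean(outside),
       u = unname(wt$statistic), p = wt$p.value,
       n_in = length(inside), n_out = length(outside))
}
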