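#' Site-specific EHH curve around a core marker
#'
#' Haplotypes are partitioned into classes identical over the interval from
#' the core to each flanking marker, extending marker by marker in both
#' directions. The Tang variant normalises identical-pair counts by the
#' core-allele pair counts, `sum_k n_k(n_k-1) / sum_a n_a(n_a-1)`; the
#' Sabeti variant by the total pair count, `sum_k C(n_k,2) / C(n,2)`. Both
#' are defined to equal 1 at the core marker. A haplotype with a missing
#' allele leaves all classes from that marker outward.
#'
#' @param haps a [haplotype_set()] (at least 4 haplotypes).
#' @param core marker index (column of the haplotype matrix).
#' @param variant `"tang"` or `"sabeti"`.
#' @return list (class `ehhs_curve`): `core`, `variant`, `bp` and `ehhs`
#'   (per marker of the core's chromosome).
#' @export
ehhs_curve <- function(haps, core, variant = c("tang", "sabeti")) {
  variant <- match.arg(variant)
  if (nrow(haps$hap) < 4) stop("need at least 4 haplotypes")
  jx <- which(haps$map$chrom == haps$map$chrom[core])
  core_local <- match(core, jx)
  hap <- haps$hap[, jx, drop = FALSE]
  hap[is.na(hap)] <- -1L
  e <- ehhs_curve_cpp(hap, core_local - 1L, match(variant, c("tang", "sabeti")) - 1L)
  structure(list(core = core, core_local = core_local, variant = variant,
                 bp = haps$map$bp[jx], ehhs = e),
            class = "ehhs_curve")
}

#' Integrate an EHHS curve into iES
#'
#' Trapezoidal integral of EHHS over physical position, each side truncated
#' at the first marker where EHHS drops below `cutoff` (that marker is
#' included as the final trapezoid endpoint with its actual value). If a
#' side reaches the chromosome end before dropping below the cutoff and
#' `discard_at_border` is true, the site's iES is undefined (`NA`).
#'
#' @param curve an [ehhs_curve()].
#' @param cutoff EHHS truncation level.
#' @param discard_at_border discard sites whose EHHS never decays within
#'   the chromosome.
#' @return iES in bp-weighted EHHS units, or `NA`.
#' @export
integrate_ies <- function(curve, cutoff = 0.05, discard_at_border = TRUE) {
  bp <- curve$bp; e <- curve$ehhs
  ci <- curve$core_local
  side <- function(idx) {
    prev_e <- 1; prev_p <- bp[ci]; tot <- 0
    for (t in idx) {
      if (is.na(e[t])) return(NA_real_)
      tot <- tot + 0.5 * (prev_e + e[t]) * abs(bp[t] - prev_p)
      prev_e <- e[t]; prev_p <- bp[t]
      if (e[t] < cutoff) return(tot)
    }
    if (discard_at_border) NA_real_ else tot
  }
  m <- length(bp)
  right <- if (ci < m) side((ci + 1):m) else if (discard_at_border) NA_real_ else 0
  left <- if (ci > 1) side((ci - 1):1) else if (discard_at_border) NA_real_ else 0
  if (is.na(left) || is.na(right)) return(NA_real_)
  left + right
}

# iES for every marker, per chromosome, via the compiled kernel
ies_track <- function(haps, variant, cutoff = 0.05, discard_at_border = TRUE) {
  vi <- match(variant, c("tang", "sabeti")) - 1L
  out <- rep(NA_real_, nrow(haps$map))
  for (jx in chrom_index(haps$map)) {
    hap <- haps$hap[, jx, drop = FALSE]
    hap[is.na(hap)] <- -1L
    out[jx] <- ies_all_cpp(hap, haps$map$bp[jx], vi, cutoff, discard_at_border)
  }
  out
}

#' Two-sided Gaussian p-score for a standardised scan statistic
#'
#' `-log10(1 - 2|Phi(z) - 0.5|)`, the minus-log10 two-sided normal
#' p-value used to call outlier SNPs in Rsb / XP-EHH scans.
#'
#' @param z standardised score (vector).
#' @return p-score vector (`>= 0`).
#' @export
score_to_pscore <- function(z) -log10(2 * pnorm(abs(z), lower.tail = FALSE))

#' Cross-population haplotype scan (Rsb / XP-EHH)
#'
#' At every SNP the integrated site-specific EHH (iES) is computed in each
#' population (Tang EHHS variant for Rsb, Sabeti for XP-EHH, overridable)
#' and the raw statistic is `ln(iES_A / iES_B)` over sites defined in both.
#' Standardisation is genome-wide: Rsb is median-centred, XP-EHH is
#' mean-centred, both scaled by the SD. The p-score is the two-sided
#' Gaussian transform `-log10(1 - 2|Phi(score) - 0.5|)`.
#'
#' @param hapsA,hapsB [haplotype_set()] objects on the same marker map.
#' @param statistic `"rsb"` or `"xpehh"`.
#' @param variant EHHS variant override (default per statistic).
#' @param cutoff,discard_at_border iES integration settings
#'   (see [integrate_ies()]).
#' @return data.frame (class `scan_track`): `chrom`, `bp`, `id`, `ies_a`,
#'   `ies_b`, `raw`, `score`, `pscore`; attributes `statistic`, `center`,
#'   `scale`.
#' @export
cross_pop_scan <- function(hapsA, hapsB, statistic = c("rsb", "xpehh"),
                           variant = NULL, cutoff = 0.05,
                           discard_at_border = TRUE) {
  statistic <- match.arg(statistic)
  if (!identical(hapsA$map$id, hapsB$map$id) ||
      !identical(hapsA$map$bp, hapsB$map$bp))
    stop("the two populations must share one marker map")
  variant <- variant %||% if (statistic == "rsb") "tang" else "sabeti"
  ies_a <- ies_track(hapsA, variant, cutoff, discard_at_border)
  ies_b <- ies_track(hapsB, variant, cutoff, discard_at_border)
  ies_a[!is.na(ies_a) & ies_a <= 0] <- NA
  ies_b[!is.na(ies_b) & ies_b <= 0] <- NA
  raw <- log(ies_a / ies_b)
  ok <- !is.na(raw)
  if (sum(ok) < 100)
    warning("only ", sum(ok), " defined sites; standardisation is unstable")
  ctr <- if (statistic == "rsb") median(raw[ok]) else mean(raw[ok])
  scl <- sd(raw[ok])
  if (!is.finite(scl) || scl == 0) scl <- 1  # degenerate: raw constant
  score <- (raw - ctr) / scl
  pscore <- score_to_pscore(score)
  out <- data.frame(chrom = hapsA$map$chrom, bp = hapsA$map$bp,
                    id = hapsA$map$id, ies_a = ies_a, ies_b = ies_b,
                    raw = raw, score = score, pscore = pscore)
  attr(out, "statistic") <- statistic
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  class(out) <- c("scan_track", "data.frame")
  out
}

#' Sliding significance windows over a scan track
#'
#' Windows of `window_bp` tile each chromosome from the first marker
#' position with step `window_bp - overlap_bp`; a window is significant iff
#' it contains at least `min_snps` SNPs with p-score strictly above
#' `threshold`. Terminal windows may be shorter but use the same rule.
#'
#' @param track a `scan_track` from [cross_pop_scan()].
#' @param window_bp window width (bp).
#' @param overlap_bp overlap between adjacent windows (bp).
#' @param min_snps significant-SNP count required.
#' @param threshold p-score threshold (strict).
#' @return data.frame: `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `n_signif`, `significant`.
#' @export
significance_windows <- function(track, window_bp = 250000, overlap_bp = 10000,
                                 min_snps = 3L, threshold = 4.0) {
  if (overlap_bp >= window_bp) stop("overlap must be smaller than the window")
  step <- window_bp - overlap_bp
  out <- list()
  for (ch in unique(track$chrom)) {
    d <- track[track$chrom == ch, , drop = FALSE]
    if (is.unsorted(d$bp)) stop("track must be sorted by position")
    starts <- seq(min(d$bp), max(d$bp), by = step)
    for (s in starts) {
      inw <- d$bp >= s & d$bp <= s + window_bp - 1
      nsig <- sum(inw & !is.na(d$pscore) & d$pscore > threshold)
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = s, end_bp = s + window_bp - 1,
        n_snps = sum(inw), n_signif = nsig,
        significant = nsig >= min_snps)
    }
  }
  do.call(rbind, out)
}

# merge overlapping/adjacent significant windows of one method into regions
# bounded by the first/last significant SNP inside the merged span
method_regions <- function(windows, track, threshold = 4.0) {
  sig <- windows[windows$significant, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer()))
  out <- list()
  for (ch in unique(sig$chrom)) {
    w <- sig[sig$chrom == ch, , drop = FALSE]
    w <- w[order(w$start_bp), , drop = FALSE]
    i <- 1
    while (i <= nrow(w)) {
      s <- w$start_bp[i]; e <- w$end_bp[i]; j <- i
      while (j < nrow(w) && w$start_bp[j + 1] <= e + 1) {
        j <- j + 1; e <- max(e, w$end_bp[j])
      }
      d <- track[track$chrom == ch & track$bp >= s & track$bp <= e &
                   !is.na(track$pscore) & track$pscore > threshold, , drop = FALSE]
      if (nrow(d) > 0)
        out[[length(out) + 1]] <- data.frame(chrom = ch,
                                             start_bp = min(d$bp),
                                             end_bp = max(d$bp),
                                             n_snps = nrow(d))
      i <- j + 1
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer()))
  do.call(rbind, out)
}

#' Consolidate candidate regions across methods
#'
#' Per method, overlapping or adjacent significant windows are merged into
#' regions bounded by the first and last significant SNP inside the merged
#' span; ROH islands enter as regions of their own method. Regions from
#' different methods that overlap by at least 1 bp are reported as one
#' candidate region with the union span and the set of supporting methods.
#'
#' @param windows_rsb,windows_xpehh window data.frames from
#'   [significance_windows()] (either may be `NULL`).
#' @param islands ROH-island data.frame from [roh_islands()] (or `NULL`).
#' @param track_rsb,track_xpehh the corresponding scan tracks.
#' @param threshold p-score threshold used for the windows.
#' @return data.frame (sorted by chrom, start): `chrom`, `start_bp`,
#'   `end_bp`, `methods` (comma-separated), `n_snps`.
#' @export
consolidate_regions <- function(windows_rsb = NULL, windows_xpehh = NULL,
                                islands = NULL, track_rsb = NULL,
                                track_xpehh = NULL, threshold = 4.0) {
  pieces <- list()
  add <- function(d, method) {
    if (is.null(d) || nrow(d) == 0) return()
    d$method <- method
    pieces[[length(pieces) + 1]] <<- d[, c("chrom", "start_bp", "end_bp",
                                           "n_snps", "method")]
  }
  if (!is.null(windows_rsb))
    add(method_regions(windows_rsb, track_rsb, threshold), "Rsb")
  if (!is.null(windows_xpehh))
    add(method_regions(windows_xpehh, track_xpehh, threshold), "XP-EHH")
  if (!is.null(islands) && nrow(islands) > 0)
    add(data.frame(chrom = islands$chrom, start_bp = islands$start_bp,
                   end_bp = islands$end_bp, n_snps = islands$n_snps),
        "ROH-island")
  if (length(pieces) == 0)
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), methods = character(),
                      n_snps = integer()))
  all <- do.call(rbind, pieces)
  out <- list()
  for (ch in unique(all$chrom)) {
    d <- all[all$chrom == ch, , drop = FALSE]
    d <- d[order(d$start_bp, d$end_bp), , drop = FALSE]
    i <- 1
    while (i <= nrow(d)) {
      s <- d$start_bp[i]; e <- d$end_bp[i]; j <- i
      while (j < nrow(d) && d$start_bp[j + 1] <= e) {
        j <- j + 1; e <- max(e, d$end_bp[j])
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = s, end_bp = e,
        methods = paste(sort(unique(d$method[i:j])), collapse = ","),
        n_snps = sum(d$n_snps[i:j]))
      i <- j + 1
    }
  }
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start_bp), , drop = FALSE]
}
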