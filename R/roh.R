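#' Runs-of-homozygosity calling parameters
#'
#' Defaults follow common 50K-array practice: minimum run length 1 Mb,
#' minimum 30 consecutive SNPs, at most one heterozygous and one missing
#' call inside a run, minimum density of one SNP per 100 kb, and a maximum
#' gap of 500 kb between consecutive SNPs.
#'
#' @param min_length_bp minimum span (first to last SNP), bp.
#' @param min_snps minimum marker count in a run.
#' @param max_het maximum heterozygous calls allowed inside a run.
#' @param max_missing maximum missing calls allowed inside a run.
#' @param min_density_bp_per_snp maximum span-per-SNP (bp); a run must have
#'   `span / n_snps` at or below this.
#' @param max_gap_bp maximum adjacent-marker gap inside a run.
#' @return an object of class `roh_params`.
#' @export
roh_params <- function(min_length_bp = 1e6, min_snps = 30L, max_het = 1L,
                       max_missing = 1L, min_density_bp_per_snp = 1e5,
                       max_gap_bp = 5e5) {
  stopifnot(min_length_bp > 0, min_snps > 0, max_het >= 0, max_missing >= 0,
            min_density_bp_per_snp > 0, max_gap_bp > 0)
  structure(list(min_length_bp = min_length_bp, min_snps = as.integer(min_snps),
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing),
                 min_density_bp_per_snp = min_density_bp_per_snp,
                 max_gap_bp = max_gap_bp),
            class = "roh_params")
}

# does [s, e] (marker indices) qualify as a ROH?
roh_ok <- function(het_cum, mis_cum, bp, s, e, par) {
  n <- e - s + 1
  if (n < par$min_snps) return(FALSE)
  span <- bp[e] - bp[s] + 1
  if (span < par$min_length_bp) return(FALSE)
  if (het_cum[e + 1] - het_cum[s] > par$max_het) return(FALSE)
  if (mis_cum[e + 1] - mis_cum[s] > par$max_missing) return(FALSE)
  if (span / n > par$min_density_bp_per_snp) return(FALSE)
  if (n > 1 && max(diff(bp[s:e])) > par$max_gap_bp) return(FALSE)
  TRUE
}

# all maximal qualifying intervals for one individual on one chromosome,
# then the overlap-merge rule (union if the union qualifies, else longest,
# tie -> leftmost)
roh_one <- function(g, bp, par) {
  m <- length(g)
  if (m < par$min_snps) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  het_cum <- c(0L, cumsum(het))
  mis_cum <- c(0L, cumsum(mis))
  gap_ok_right <- c(diff(bp) <= par$max_gap_bp, FALSE)
  # E(s): furthest end satisfying the monotone constraints (het, missing, gap)
  cand <- list()
  e_ptr <- 1L
  for (s in seq_len(m)) {
    if (e_ptr < s) e_ptr <- s
    while (e_ptr < m && gap_ok_right[e_ptr] &&
           het_cum[e_ptr + 2] - het_cum[s] <= par$max_het &&
           mis_cum[e_ptr + 2] - mis_cum[s] <= par$max_missing)
      e_ptr <- e_ptr + 1L
    # largest qualifying end for this start: scan down from E(s)
    for (e in e_ptr:s) {
      if (e - s + 1 < par$min_snps) break
      if (roh_ok(het_cum, mis_cum, bp, s, e, par)) {
        cand[[length(cand) + 1]] <- c(s, e)
        break
      }
    }
  }
  if (length(cand) == 0) return(NULL)
  iv <- unique(do.call(rbind, cand))
  # drop intervals contained in another qualifying interval
  keep <- rep(TRUE, nrow(iv))
  for (i in seq_len(nrow(iv))) for (j in seq_len(nrow(iv)))
    if (i != j && iv[j, 1] <= iv[i, 1] && iv[i, 2] <= iv[j, 2] &&
        !(iv[j, 1] == iv[i, 1] && iv[j, 2] == iv[i, 2]))
      keep[i] <- FALSE
  iv <- iv[keep, , drop = FALSE]
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  # merge overlap-connected clusters
  out <- list()
  i <- 1
  while (i <= nrow(iv)) {
    j <- i
    while (j < nrow(iv) && iv[j + 1, 1] <= max(iv[i:j, 2])) j <- j + 1
    if (j > i) {
      u <- c(min(iv[i:j, 1]), max(iv[i:j, 2]))
      if (roh_ok(het_cum, mis_cum, bp, u[1], u[2], par)) {
        out[[length(out) + 1]] <- u
      } else {
        lens <- bp[iv[i:j, 2]] - bp[iv[i:j, 1]]
        best <- which(lens == max(lens))[1]
        out[[length(out) + 1]] <- iv[i + best - 1, ]
      }
    } else out[[length(out) + 1]] <- iv[i, ]
    i <- j + 1
  }
  do.call(rbind, out)
}

#' Detect runs of homozygosity
#'
#' Per individual and chromosome, returns all maximal marker intervals that
#' satisfy every criterion in `params` (marker count, span, heterozygous
#' and missing allowances, density, adjacent-marker gap); maximal means no
#' qualifying superset interval exists. Overlapping qualifying intervals of
#' one individual are merged into their union when the union itself
#' qualifies, otherwise the longest (tie: leftmost) is kept. Intended for
#' the unpruned post-QC marker set.
#'
#' @param geno a [genotype_matrix()] with the map sorted by (chrom, bp).
#' @param params a [roh_params()].
#' @return data.frame of segments: `indiv`, `pop`, `chrom`, `start_bp`,
#'   `end_bp` (first/last SNP, 1-based inclusive), `n_snps`, `n_het`,
#'   `n_missing`, `length_bp`.
#' @export
detect_roh <- function(geno, params = roh_params()) {
  cidx <- chrom_index(geno$map)
  for (jx in cidx)
    if (is.unsorted(geno$map$bp[jx], strictly = TRUE))
      stop("marker map must be sorted by position within chromosome")
  segs <- list()
  for (ch in names(cidx)) {
    jx <- cidx[[ch]]
    bp <- geno$map$bp[jx]
    for (i in seq_len(nrow(geno$geno))) {
      g <- geno$geno[i, jx]
      iv <- roh_one(g, bp, params)
      if (is.null(iv)) next
      for (r in seq_len(nrow(iv))) {
        s <- iv[r, 1]; e <- iv[r, 2]
        gg <- g[s:e]
        segs[[length(segs) + 1]] <- data.frame(
          indiv = geno$samples$id[i], pop = geno$samples$pop[i], chrom = ch,
          start_bp = bp[s], end_bp = bp[e], n_snps = e - s + 1L,
          n_het = sum(gg == 1L, na.rm = TRUE), n_missing = sum(is.na(gg)),
          length_bp = bp[e] - bp[s] + 1)
      }
    }
  }
  if (length(segs) == 0)
    return(data.frame(indiv = character(), pop = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), length_bp = numeric()))
  out <- do.call(rbind, segs)
  out[order(out$indiv, out$chrom, out$start_bp), , drop = FALSE]
}

#' Genomic inbreeding from ROH (F_ROH) and run summaries
#'
#' Per individual, `F_ROH = L_ROH / L_AUT` where `L_ROH` is the summed
#' segment length and `L_AUT` the autosomal length covered by the array
#' (default 2,452,060,000 bp, the 50K ovine value). Group summaries report
#' the mean run count with both denominators (all individuals, and only
#' individuals carrying at least one run), the mean run length, and counts
#' in the five length classes 1-<5, 5-<10, 10-<15, 15-<20 and >=20 Mb.
#'
#' @param segments segment data.frame from [detect_roh()].
#' @param geno the [genotype_matrix()] the segments came from (supplies the
#'   full individual list, so runless individuals get `F_ROH = 0`).
#' @param l_aut_bp autosomal genome length covered by the array, bp.
#' @return list (class `froh_result`): `per_indiv` data.frame (`indiv`,
#'   `pop`, `n_roh`, `l_roh_bp`, `froh`), `per_group` data.frame
#'   (`mn_roh_all`, `mn_roh_carriers`, `al_roh_bp`, `froh_mean`, class
#'   counts), and `l_aut_bp`.
#' @export
froh <- function(segments, geno, l_aut_bp = 2452060000) {
  if (l_aut_bp <= 0) stop("l_aut_bp must be positive")
  ind <- geno$samples
  l <- tapply(segments$length_bp, factor(segments$indiv, levels = ind$id), sum)
  cnt <- tapply(segments$length_bp, factor(segments$indiv, levels = ind$id), length)
  l[is.na(l)] <- 0; cnt[is.na(cnt)] <- 0
  per_indiv <- data.frame(indiv = ind$id, pop = ind$pop,
                          n_roh = as.integer(cnt), l_roh_bp = as.numeric(l),
                          froh = as.numeric(l) / l_aut_bp)
  cls_breaks <- c(1, 5, 10, 15, 20, Inf) * 1e6
  cls_names <- c("roh_1_5mb", "roh_5_10mb", "roh_10_15mb", "roh_15_20mb", "roh_ge20mb")
  per_group <- do.call(rbind, lapply(split(per_indiv, per_indiv$pop), function(d) {
    seg_g <- segments[segments$pop == d$pop[1], , drop = FALSE]
    cls <- table(cut(seg_g$length_bp, cls_breaks, right = FALSE,
                     labels = cls_names))
    cbind(data.frame(pop = d$pop[1], n = nrow(d),
                     mn_roh_all = mean(d$n_roh),
                     mn_roh_carriers = if (any(d$n_roh > 0))
                       mean(d$n_roh[d$n_roh > 0]) else NA_real_,
                     al_roh_bp = if (nrow(seg_g)) mean(seg_g$length_bp) else NA_real_,
                     froh_mean = mean(d$froh)),
          as.data.frame.matrix(t(as.matrix(cls))))
  }))
  rownames(per_group) <- NULL
  structure(list(per_indiv = per_indiv, per_group = per_group,
                 l_aut_bp = l_aut_bp), class = "froh_result")
}

#' ROH islands from per-SNP run incidence
#'
#' Within a group, the incidence of each SNP is the number of individuals
#' whose ROH covers it divided by the group size. The island threshold is
#' taken at `percentile` of the group's genome-wide incidence distribution
#' and maximal runs of consecutive markers with incidence strictly above
#' the threshold become islands (single-SNP islands allowed).
#'
#' Two threshold methods are provided. `"range"` (default) places the
#' threshold at `percentile` of the way through the observed incidence
#' range, `min + percentile * (max - min)`, so a block of markers tied at
#' the maximum — the signature of a strong shared segment — is always
#' flagged; `"rank"` uses the nearest-rank quantile of the per-SNP
#' incidence values, which is conservative when the top of the
#' distribution is tied (a tied block wider than `1 - percentile` of the
#' genome excludes itself). With a degenerate (constant) incidence
#' distribution both methods return no islands.
#'
#' @param segments segment data.frame from [detect_roh()].
#' @param geno the source [genotype_matrix()].
#' @param group group label (matched against population labels).
#' @param percentile quantile defining the threshold (default 0.999).
#' @param method `"range"` or `"rank"` (see Details).
#' @return data.frame of islands: `group`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `max_incidence`; attributes `threshold` and `incidence`
#'   (per-SNP vector).
#' @export
roh_islands <- function(segments, geno, group, percentile = 0.999,
                        method = c("range", "rank")) {
  method <- match.arg(method)
  ids <- geno$samples$id[geno$samples$pop == group]
  if (length(ids) < 2) stop("group ", group, " has fewer than 2 individuals")
  m <- nrow(geno$map)
  cover <- numeric(m)
  seg_g <- segments[segments$indiv %in% ids, , drop = FALSE]
  for (r in seq_len(nrow(seg_g)))
    cover <- cover + (geno$map$chrom == seg_g$chrom[r] &
                        geno$map$bp >= seg_g$start_bp[r] &
                        geno$map$bp <= seg_g$end_bp[r])
  inc <- cover / length(ids)
  empty <- data.frame(group = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), max_incidence = numeric())
  if (all(inc == 0)) {
    warning("no SNP is covered by any ROH in group ", group)
    out <- empty
    attr(out, "threshold") <- NA_real_
    attr(out, "incidence") <- inc
    return(out)
  }
  if (method == "rank") {
    srt <- sort(inc)
    thr <- srt[max(1L, ceiling(percentile * length(srt)))]
  } else {
    thr <- min(inc) + percentile * (max(inc) - min(inc))
  }
  above <- inc > thr
  out <- empty
  for (jx in chrom_index(geno$map)) {
    a <- above[jx]
    if (!any(a)) next
    r <- rle(a)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      s <- jx[starts[k]]; e <- jx[ends[k]]
      out <- rbind(out, data.frame(group = group, chrom = geno$map$chrom[s],
                                   start_bp = geno$map$bp[s],
                                   end_bp = geno$map$bp[e],
                                   n_snps = ends[k] - starts[k] + 1L,
                                   max_incidence = max(inc[jx][starts[k]:ends[k]])))
    }
  }
  attr(out, "threshold") <- thr
  attr(out, "incidence") <- inc
  out
}
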