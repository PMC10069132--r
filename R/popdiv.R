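#' Observed and expected heterozygosity per population
#'
#' Within each group and marker, observed heterozygosity is the fraction of
#' heterozygous calls among non-missing calls and expected heterozygosity
#' is `2*p*(1-p)` from the within-group allele frequency (the plain PLINK
#' convention; set `unbiased = TRUE` for the `2n/(2n-1)` small-sample
#' correction). Summaries are means and SDs over all markers, polymorphic
#' and monomorphic alike; markers with no calls in a group are skipped.
#'
#' @param geno a [genotype_matrix()].
#' @param groups optional grouping: `NULL` (use population labels) or a
#'   character/factor vector along samples.
#' @param unbiased apply the `2n/(2n-1)` correction to H_E.
#' @return data.frame, one row per group: `pop`, `n`, `ho_mean`, `ho_sd`,
#'   `he_mean`, `he_sd`.
#' @export
heterozygosity <- function(geno, groups = NULL, unbiased = FALSE) {
  grp <- resolve_groups(geno, groups)
  out <- lapply(levels(grp), function(g) {
    X <- geno$geno[grp == g, , drop = FALSE]
    if (nrow(X) < 2) stop("group ", g, " has fewer than 2 individuals")
    nn <- colSums(!is.na(X))
    ok <- nn > 0
    ho <- colSums(X == 1L, na.rm = TRUE)[ok] / nn[ok]
    p <- colSums(X, na.rm = TRUE)[ok] / (2 * nn[ok])
    he <- 2 * p * (1 - p)
    if (unbiased) he <- he * (2 * nn[ok]) / (2 * nn[ok] - 1)
    data.frame(pop = g, n = nrow(X),
               ho_mean = mean(ho), ho_sd = sd(ho),
               he_mean = mean(he), he_sd = sd(he))
  })
  do.call(rbind, out)
}

resolve_groups <- function(geno, groups) {
  if (is.null(groups)) return(factor(geno$samples$pop))
  if (length(groups) != nrow(geno$geno))
    stop("groups must have one entry per sample")
  factor(as.character(groups))
}

# Weir-Cockerham (1984) two-population theta components per locus, from
# per-group non-missing counts (n), allele-1 sums (s) and het counts (h).
# Returns per-locus numerator (a) and denominator (a+b+c) vectors.
wc_components <- function(n1, s1, h1, n2, s2, h2) {
  ok <- n1 > 0 & n2 > 0 & (n1 + n2) > 2
  num <- den <- rep(NA_real_, length(n1))
  n1 <- n1[ok]; n2 <- n2[ok]
  p1 <- s1[ok] / (2 * n1); p2 <- s2[ok] / (2 * n2)
  hh1 <- h1[ok] / n1; hh2 <- h2[ok] / n2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * hh1 + n2 * hh2) / (2 * nbar)
  av <- (nbar / nc) * (s2v - (pbar * (1 - pbar) - s2v / 2 - hbar / 4) / (nbar - 1))
  bv <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2v / 2 -
                                 (2 * nbar - 1) / (4 * nbar) * hbar)
  cv <- hbar / 2
  num[ok] <- av
  den[ok] <- av + bv + cv
  list(num = num, den = den)
}

group_counts <- function(X) {
  list(n = colSums(!is.na(X)),
       s = colSums(X, na.rm = TRUE),
       h = colSums(X == 1L, na.rm = TRUE))
}

# genome-wide ratio-of-sums theta for two dosage matrices
wc_theta <- function(X1, X2) {
  c1 <- group_counts(X1); c2 <- group_counts(X2)
  w <- wc_components(c1$n, c1$s, c1$h, c2$n, c2$s, c2$h)
  sum(w$num, na.rm = TRUE) / sum(w$den, na.rm = TRUE)
}

#' Pairwise F_ST, permutation significance and Reynolds distances
#'
#' For every pair of groups, the Weir-Cockerham (1984) two-population theta
#' is computed per locus and combined as the ratio of sums of its
#' numerator/denominator components over loci. Significance comes from
#' permuting individuals between the pair: the p-value is the fraction of
#' permuted theta values at or above the observed one, with `+1/(n_perm+1)`
#' smoothing. The Reynolds distance is `-ln(1 - theta)` with theta clamped
#' to `[0, 1)`.
#'
#' @param geno a [genotype_matrix()].
#' @param groups optional grouping (see [heterozygosity()]).
#' @param n_perm permutations per pair (0 disables; p-values `NA`).
#' @param seed integer seed for the permutations.
#' @return list of symmetric matrices `fst`, `p_value`, `reynolds`
#'   (class `dist_matrices`).
#' @export
pairwise_fst <- function(geno, groups = NULL, n_perm = 10000, seed = 1L) {
  grp <- resolve_groups(geno, groups)
  gl <- levels(grp)
  if (length(gl) < 2) stop("need at least two groups")
  if (any(table(grp) < 2)) stop("every group needs at least 2 individuals")
  k <- length(gl)
  fst <- p <- rey <- matrix(0, k, k, dimnames = list(gl, gl))
  diag(p) <- NA
  set.seed(op_seed(seed, "pairwise_fst"))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    Xi <- geno$geno[grp == gl[i], , drop = FALSE]
    Xj <- geno$geno[grp == gl[j], , drop = FALSE]
    th <- wc_theta(Xi, Xj)
    fst[i, j] <- fst[j, i] <- th
    thc <- min(max(th, 0), 1 - 1e-12)
    rey[i, j] <- rey[j, i] <- -log(1 - thc)
    if (n_perm > 0) {
      XX <- rbind(Xi, Xj)
      Mn <- !is.na(XX)
      Md <- XX; Md[!Mn] <- 0L
      Mh <- XX == 1L; Mh[!Mn] <- FALSE
      tot <- list(n = colSums(Mn), s = colSums(Md), h = colSums(Mh))
      n1 <- nrow(Xi); ntot <- nrow(XX)
      hits <- 0L
      for (b in seq_len(n_perm)) {
        idx <- sample.int(ntot, n1)
        cn <- colSums(Mn[idx, , drop = FALSE])
        cs <- colSums(Md[idx, , drop = FALSE])
        ch <- colSums(Mh[idx, , drop = FALSE])
        w <- wc_components(cn, cs, ch, tot$n - cn, tot$s - cs, tot$h - ch)
        th_b <- sum(w$num, na.rm = TRUE) / sum(w$den, na.rm = TRUE)
        if (th_b >= th) hits <- hits + 1L
      }
      p[i, j] <- p[j, i] <- (hits + 1) / (n_perm + 1)
    } else p[i, j] <- p[j, i] <- NA_real_
  }
  structure(list(fst = fst, p_value = p, reynolds = rey),
            class = "dist_matrices")
}

#' Classical MDS on identity-by-state distances
#'
#' Pairwise distance between samples is one minus the mean shared-allele
#' fraction over mutually non-missing markers; the embedding is classical
#' (Torgerson) multidimensional scaling of that matrix. The explained
#' proportion of each returned dimension is its eigenvalue over the sum of
#' positive eigenvalues.
#'
#' @param geno a [genotype_matrix()].
#' @param k requested dimensions.
#' @return list (class `mds_result`): `coords` (samples x k'), `explained`
#'   (length k'), `eig` (all eigenvalues), `dist` (the IBS distance matrix).
#'   `k'` can be below `k` if fewer positive eigenvalues exist (warned).
#' @export
ibs_mds <- function(geno, k = 3) {
  n <- nrow(geno$geno)
  if (n < k + 1) stop("need at least k + 1 samples")
  D <- 1 - ibs_matrix(geno$geno)
  fit <- cmdscale(as.dist(D), k = min(k, n - 1), eig = TRUE)
  pos <- fit$eig[fit$eig > 1e-12]
  have <- min(k, length(pos), ncol(fit$points))
  if (have < k) warning("only ", have, " positive-eigenvalue dimensions available")
  coords <- fit$points[, seq_len(have), drop = FALSE]
  rownames(coords) <- geno$samples$id
  structure(list(coords = coords,
                 explained = fit$eig[seq_len(have)] / sum(pos),
                 eig = fit$eig, dist = D),
            class = "mds_result")
}

# Sved's relation: N_e at recombination distance c from adjusted mean r^2
sved_ne <- function(r2_adj, c_bar, alpha = 1) {
  ifelse(!is.na(r2_adj) & r2_adj > 0 & r2_adj < 1 / alpha,
         (1 / (4 * c_bar)) * (1 / r2_adj - alpha), NA_real_)
}

#' LD-based effective population size trajectory
#'
#' For syntenic marker pairs the genetic distance is `c = bp * 1e-8`
#' Morgans (a constant 1 cM/Mb map); pairs are binned by physical distance,
#' and within each bin the mean composite (dosage-correlation) r-squared,
#' corrected for sample size by `-1/n`, gives
#' `N_e = (1/(4*cbar)) * (1/r2_adj - alpha)` at `t = 1/(2*cbar)`
#' generations back. Groups above `max_n` individuals are subsampled
#' (seeded); groups below `min_n` are skipped with a warning, reflecting
#' the instability of r-squared in small samples.
#'
#' @param geno a [genotype_matrix()].
#' @param groups optional grouping (see [heterozygosity()]).
#' @param bins numeric vector of physical-distance break points (bp).
#' @param alpha mutation/phase adjustment in Sved's formula (default 1).
#' @param sample_correction subtract `1/n` from mean r-squared.
#' @param min_n minimum group size analysed (smaller groups skipped).
#' @param max_n subsample size for larger groups.
#' @param seed integer seed for subsampling.
#' @return named list (class `ne_trajectory`), one element per analysed
#'   group: data.frame of bins (`c_bar`, `t`, `n_pairs`, `r2_adj`, `ne`)
#'   with `ne13`/`ne50` attributes (bins with `t` nearest 13 and 50).
#' @export
ld_ne <- function(geno, groups = NULL,
                  bins = seq(0.25e6, 10.25e6, by = 0.5e6),
                  alpha = 1, sample_correction = TRUE,
                  min_n = 20, max_n = 20, seed = 1L) {
  grp <- resolve_groups(geno, groups)
  set.seed(op_seed(seed, "ld_ne"))
  res <- list()
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < min_n) {
      warning("group ", g, " has ", length(idx), " < ", min_n,
              " individuals; skipped")
      next
    }
    if (length(idx) > max_n) idx <- sort(sample(idx, max_n))
    n <- length(idx)
    nb <- length(bins) - 1
    sum_r2 <- sum_c <- cnt <- numeric(nb)
    for (jx in chrom_index(geno$map)) {
      if (length(jx) < 2) next
      X <- geno$geno[idx, jx, drop = FALSE]
      r2 <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))^2
      dmat <- abs(outer(geno$map$bp[jx], geno$map$bp[jx], "-"))
      ut <- upper.tri(r2)
      d <- dmat[ut]; r <- r2[ut]
      keep <- !is.na(r) & d >= bins[1] & d < bins[nb + 1]
      d <- d[keep]; r <- r[keep]
      bi <- findInterval(d, bins)
      sum_r2 <- sum_r2 + vapply(seq_len(nb), function(b) sum(r[bi == b]), 0)
      sum_c <- sum_c + vapply(seq_len(nb), function(b) sum(d[bi == b]), 0) * 1e-8
      cnt <- cnt + tabulate(bi, nb)
    }
    r2_bar <- ifelse(cnt > 0, sum_r2 / cnt, NA)
    c_bar <- ifelse(cnt > 0, sum_c / cnt, NA)
    r2_adj <- r2_bar - if (sample_correction) 1 / n else 0
    ne <- sved_ne(r2_adj, c_bar, alpha)
    t_back <- 1 / (2 * c_bar)
    df <- data.frame(bin_lo = bins[-(nb + 1)], bin_hi = bins[-1],
                     c_bar = c_bar, t = t_back, n_pairs = cnt,
                     r2_adj = r2_adj, ne = ne)
    ok <- !is.na(df$t) & !is.na(df$ne)
    attr(df, "ne13") <- if (any(ok)) df$ne[ok][which.min(abs(df$t[ok] - 13))] else NA
    attr(df, "ne50") <- if (any(ok)) df$ne[ok][which.min(abs(df$t[ok] - 50))] else NA
    res[[g]] <- df
  }
  structure(res, class = "ne_trajectory")
}
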