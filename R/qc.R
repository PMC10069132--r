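#' Quality-control configuration
#'
#' Thresholds for the six-step marker/sample filter and for LD pruning.
#' Defaults follow common SNP-array practice: retain SNPs with call rate
#' strictly above 0.90, samples with missing fraction strictly below 0.05,
#' SNPs with MAF strictly above 0.01, autosomes only, drop one of each
#' sample pair with identity-by-state at or above 0.99, and prune with a
#' 50-SNP window, 5-SNP step and r-squared ceiling 0.5.
#'
#' @param snp_call_rate_min keep SNPs with call rate `>` this.
#' @param indiv_missing_max keep samples with missing fraction `<` this.
#' @param maf_min keep SNPs with MAF `>` this (recomputed after the sample
#'   filter).
#' @param autosomes_only drop markers whose chromosome label is not a
#'   positive integer.
#' @param ibs_duplicate_threshold drop one member of each sample pair whose
#'   IBS is `>=` this (greedy, keep first-seen).
#' @param ld_window_snps,ld_step_snps,ld_r2_max pruning window, step and
#'   r-squared ceiling.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(snp_call_rate_min = 0.90, indiv_missing_max = 0.05,
                      maf_min = 0.01, autosomes_only = TRUE,
                      ibs_duplicate_threshold = 0.99,
                      ld_window_snps = 50L, ld_step_snps = 5L, ld_r2_max = 0.5) {
  stopifnot(snp_call_rate_min >= 0, snp_call_rate_min <= 1,
            indiv_missing_max >= 0, indiv_missing_max <= 1,
            maf_min >= 0, maf_min <= 1, ld_r2_max >= 0, ld_r2_max <= 1,
            ld_window_snps > ld_step_snps, ld_step_snps > 0)
  structure(list(snp_call_rate_min = snp_call_rate_min,
                 indiv_missing_max = indiv_missing_max, maf_min = maf_min,
                 autosomes_only = autosomes_only,
                 ibs_duplicate_threshold = ibs_duplicate_threshold,
                 ld_window_snps = as.integer(ld_window_snps),
                 ld_step_snps = as.integer(ld_step_snps),
                 ld_r2_max = ld_r2_max),
            class = "qc_config")
}

# mean shared-allele fraction between two samples over mutually non-missing
# markers: 1 - |gi - gj| / 2 averaged
ibs_pair <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok)) return(NA_real_)
  mean(1 - abs(gi[ok] - gj[ok]) / 2)
}

# full IBS similarity matrix
ibs_matrix <- function(geno) {
  n <- nrow(geno)
  s <- diag(1, n)
  if (n < 2) return(s)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s[i, j] <- s[j, i] <- ibs_pair(geno[i, ], geno[j, ])
  dimnames(s) <- list(rownames(geno), rownames(geno))
  s
}

subset_geno <- function(g, samples = NULL, markers = NULL) {
  if (!is.null(markers)) {
    g$geno <- g$geno[, markers, drop = FALSE]
    g$map <- g$map[markers, , drop = FALSE]
    class(g$map) <- c("marker_map", "data.frame")
  }
  if (!is.null(samples)) {
    g$geno <- g$geno[samples, , drop = FALSE]
    g$samples <- g$samples[samples, , drop = FALSE]
  }
  g
}

#' Apply the six-step quality-control filter
#'
#' Filters applied in order: (1) SNP call rate strictly above the
#' threshold; (2) SNPs lacking a chromosome or physical position removed;
#' (3) samples with missing-genotype fraction at or above the sample
#' threshold removed; (4) SNPs with minor allele frequency at or below the
#' MAF threshold removed, MAF recomputed after step 3; (5) non-autosomal
#' markers removed; (6) one member of each sample pair with IBS at or above
#' the duplicate threshold removed (greedy: the first-seen sample of each
#' pair is kept). Every removal is recorded in the report.
#'
#' @param geno a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @return list with the filtered `geno` and a `report` data.frame (one
#'   row per step; `removed` is a list-column of removed ids).
#' @export
apply_qc <- function(geno, cfg = qc_config()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (nrow(geno$geno) == 0 || ncol(geno$geno) == 0) stop("empty genotype matrix")
  steps <- list()
  note <- function(what, desc, mb, ma, sb, sa, removed)
    steps[[length(steps) + 1]] <<- data.frame(
      step = length(steps) + 1L, filter = what, description = desc,
      markers_before = mb, markers_after = ma,
      samples_before = sb, samples_after = sa,
      removed = I(list(removed)))
  # (1) SNP call rate > threshold
  cr <- colMeans(!is.na(geno$geno))
  keep <- cr > cfg$snp_call_rate_min
  note("snp_call_rate", sprintf("SNP call rate > %.2f", cfg$snp_call_rate_min),
       ncol(geno$geno), sum(keep), nrow(geno$geno), nrow(geno$geno),
       geno$map$id[!keep])
  geno <- subset_geno(geno, markers = which(keep))
  # (2) chromosome / position present
  keep <- !is.na(geno$map$chrom) & geno$map$chrom != "" & geno$map$chrom != "0" &
    !is.na(geno$map$bp) & geno$map$bp > 0
  note("position_known", "SNP has chromosome and physical position",
       length(keep), sum(keep), nrow(geno$geno), nrow(geno$geno),
       geno$map$id[!keep])
  geno <- subset_geno(geno, markers = which(keep))
  # (3) sample missingness < threshold
  miss <- rowMeans(is.na(geno$geno))
  keep <- miss < cfg$indiv_missing_max
  note("sample_missingness", sprintf("sample missing fraction < %.2f", cfg$indiv_missing_max),
       ncol(geno$geno), ncol(geno$geno), length(keep), sum(keep),
       geno$samples$id[!keep])
  if (sum(keep) == 0) stop("empty after QC: all samples removed")
  geno <- subset_geno(geno, samples = which(keep))
  # (4) MAF > threshold (recomputed on retained samples)
  maf <- marker_freq(geno$geno, fold = TRUE)
  keep <- !is.na(maf) & maf > cfg$maf_min
  note("maf", sprintf("MAF > %.3f", cfg$maf_min),
       length(keep), sum(keep), nrow(geno$geno), nrow(geno$geno),
       geno$map$id[!keep])
  geno <- subset_geno(geno, markers = which(keep))
  # (5) autosomes only
  if (cfg$autosomes_only) {
    keep <- grepl("^[0-9]+$", geno$map$chrom) & as.integer(geno$map$chrom) >= 1
  } else keep <- rep(TRUE, nrow(geno$map))
  note("autosomes", "marker on an autosome",
       length(keep), sum(keep), nrow(geno$geno), nrow(geno$geno),
       geno$map$id[!keep])
  geno <- subset_geno(geno, markers = which(keep))
  # (6) IBS duplicates
  s <- ibs_matrix(geno$geno)
  n <- nrow(s)
  drop <- rep(FALSE, n)
  if (n >= 2) for (i in seq_len(n - 1)) {
    if (drop[i]) next
    for (j in (i + 1):n)
      if (!drop[j] && !is.na(s[i, j]) && s[i, j] >= cfg$ibs_duplicate_threshold)
        drop[j] <- TRUE
  }
  note("ibs_duplicates", sprintf("pairwise IBS < %.2f", cfg$ibs_duplicate_threshold),
       ncol(geno$geno), ncol(geno$geno), n, sum(!drop),
       geno$samples$id[drop])
  if (all(drop)) stop("empty after QC: all samples removed")
  geno <- subset_geno(geno, samples = which(!drop))
  report <- do.call(rbind, steps)
  list(geno = geno, report = report)
}

# r^2 between two dosage vectors over mutually non-missing calls
r2_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  r <- suppressWarnings(cor(x[ok], y[ok]))
  if (is.na(r)) NA_real_ else r^2
}

#' LD-prune a genotype matrix
#'
#' Sliding-window pruning on composite (dosage-correlation) r-squared: in
#' each window of `ld_window_snps` surviving markers, advanced by
#' `ld_step_snps`, while any within-window pair exceeds `ld_r2_max`, the
#' member of the worst pair with the lower call rate is removed (tie: the
#' higher marker index). Passes repeat until no window contains a pair
#' above the ceiling, so the post-condition holds on the final set.
#'
#' @param geno a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @return the pruned [genotype_matrix()].
#' @export
ld_prune <- function(geno, cfg = qc_config()) {
  w <- cfg$ld_window_snps; stp <- cfg$ld_step_snps; rmax <- cfg$ld_r2_max
  cr <- colMeans(!is.na(geno$geno))
  keep <- rep(TRUE, ncol(geno$geno))
  for (jx in chrom_index(geno$map)) {
    repeat {
      removed_any <- FALSE
      alive <- jx[keep[jx]]
      if (length(alive) < 2) break
      starts <- seq(1, length(alive), by = stp)
      for (s in starts) {
        win <- alive[s:min(s + w - 1, length(alive))]
        win <- win[keep[win]]
        if (length(win) < 2) next
        r2m <- suppressWarnings(cor(geno$geno[, win, drop = FALSE],
                                    use = "pairwise.complete.obs"))^2
        r2m[!upper.tri(r2m)] <- NA
        repeat {
          if (all(is.na(r2m)) || max(r2m, na.rm = TRUE) <= rmax) break
          hit <- which(r2m == max(r2m, na.rm = TRUE), arr.ind = TRUE)[1, ]
          worst <- win[c(hit[1], hit[2])]
          victim <- if (cr[worst[1]] < cr[worst[2]]) worst[1] else
            if (cr[worst[2]] < cr[worst[1]]) worst[2] else max(worst)
          keep[victim] <- FALSE
          vi <- match(victim, win)
          r2m[vi, ] <- NA; r2m[, vi] <- NA
          removed_any <- TRUE
        }
      }
      if (!removed_any) break
    }
  }
  subset_geno(geno, markers = which(keep))
}
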