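# Independent brute-force oracles. These recompute the statistics from
# first principles (pair enumeration, exhaustive subinterval scans,
# generic numeric integration) and deliberately share no code with the
# package implementations they check.

# EHHS at marker t for a core, by O(n^2) haplotype-pair comparison
oracle_ehhs <- function(hap, core, t, variant) {
  n <- nrow(hap)
  if (t == core) return(1)
  rng <- min(core, t):max(core, t)
  num <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (all(hap[i, rng] == hap[j, rng])) num <- num + 2L
  if (variant == "tang") {
    den <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (hap[i, core] == hap[j, core]) den <- den + 2L
  } else {
    den <- n * (n - 1)
  }
  if (den == 0) return(NA_real_)
  num / den
}

oracle_ehhs_curve <- function(hap, core, variant) {
  vapply(seq_len(ncol(hap)), function(t) oracle_ehhs(hap, core, t, variant), 0)
}

# exhaustive ROH oracle: enumerate every subinterval, keep qualifying ones,
# drop the contained, then apply the overlap-merge rule
oracle_roh <- function(g, bp, par) {
  m <- length(g)
  qualifies <- function(s, e) {
    n <- e - s + 1
    gg <- g[s:e]
    n >= par$min_snps &&
      (bp[e] - bp[s] + 1) >= par$min_length_bp &&
      sum(gg == 1L, na.rm = TRUE) <= par$max_het &&
      sum(is.na(gg)) <= par$max_missing &&
      (bp[e] - bp[s] + 1) / n <= par$min_density_bp_per_snp &&
      (n == 1 || max(diff(bp[s:e])) <= par$max_gap_bp)
  }
  qual <- list()
  for (s in seq_len(m)) {
    het <- 0L; mis <- 0L; maxgap <- 0
    for (e in s:m) {
      if (e > s) maxgap <- max(maxgap, bp[e] - bp[e - 1])
      if (is.na(g[e])) mis <- mis + 1L else if (g[e] == 1L) het <- het + 1L
      if (het > par$max_het || mis > par$max_missing) break
      n <- e - s + 1
      span <- bp[e] - bp[s] + 1
      if (n >= par$min_snps && span >= par$min_length_bp &&
          span / n <= par$min_density_bp_per_snp && maxgap <= par$max_gap_bp)
        qual[[length(qual) + 1]] <- c(s, e)
    }
  }
  if (length(qual) == 0) return(NULL)
  iv <- unique(do.call(rbind, qual))
  maximal <- vapply(seq_len(nrow(iv)), function(i) {
    !any(vapply(seq_len(nrow(iv)), function(j)
      j != i && iv[j, 1] <= iv[i, 1] && iv[j, 2] >= iv[i, 2] &&
        !(iv[j, 1] == iv[i, 1] && iv[j, 2] == iv[i, 2]), TRUE))
  }, TRUE)
  iv <- iv[maximal, , drop = FALSE]
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out <- NULL
  i <- 1
  while (i <= nrow(iv)) {
    j <- i
    while (j < nrow(iv) && iv[j + 1, 1] <= max(iv[i:j, 2])) j <- j + 1
    if (j > i) {
      u <- c(min(iv[i:j, 1]), max(iv[i:j, 2]))
      if (qualifies(u[1], u[2])) out <- rbind(out, u)
      else {
        lens <- bp[iv[i:j, 2]] - bp[iv[i:j, 1]]
        out <- rbind(out, iv[i + which.max(lens) - 1, ])
      }
    } else out <- rbind(out, iv[i, ])
    i <- j + 1
  }
  unname(out)
}

# truncated-trapezoid iES oracle via pracma::trapz on the clipped curve
oracle_ies <- function(bp, ehhs, core_idx, cutoff, discard_at_border) {
  clip_side <- function(idx) {
    xs <- bp[core_idx]; ys <- 1
    for (t in idx) {
      xs <- c(xs, bp[t]); ys <- c(ys, ehhs[t])
      if (ehhs[t] < cutoff) return(list(x = xs, y = ys, closed = TRUE))
    }
    list(x = xs, y = ys, closed = FALSE)
  }
  m <- length(bp)
  tot <- 0
  for (side in list(if (core_idx < m) (core_idx + 1):m else integer(),
                    if (core_idx > 1) (core_idx - 1):1 else integer())) {
    cl <- clip_side(side)
    if (!cl$closed && discard_at_border) return(NA_real_)
    if (length(cl$x) > 1) tot <- tot + abs(pracma::trapz(cl$x, cl$y))
  }
  tot
}
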