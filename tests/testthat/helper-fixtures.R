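# Fixture builders used across the suite. Everything is generated in code
# under explicit seeds; no data files.

make_map <- function(m, chrom = "1", spacing = 5e4, a1 = "A", a2 = "B") {
  marker_map(chrom, sprintf("m%s_%03d", chrom[1], seq_len(m)),
             seq(spacing, by = spacing, length.out = m), a1, a2)
}

rand_haps <- function(n_hap, m, seed, pop = "p1", p = 0.5) {
  set.seed(seed)
  if (n_hap %% 2L) n_hap <- n_hap + 1L
  hap <- matrix(rbinom(n_hap * m, 1, p), n_hap, m)
  haplotype_set(hap, make_map(m), sprintf("ind%02d", seq_len(n_hap / 2)), pop)
}

rand_geno <- function(n, m, seed, maf = 0.3, miss = 0, pop = "p1", spacing = 5e4) {
  set.seed(seed)
  g <- matrix(rbinom(n * m, 2, maf), n, m)
  if (miss > 0) g[matrix(runif(n * m) < miss, n, m)] <- NA
  genotype_matrix(g, make_map(m, spacing = spacing),
                  sprintf("s%02d", seq_len(n)), pop)
}

# the 10-sample x 6-SNP QC fixture with four planted violations:
# snp1 call rate 0.8, snp2 monomorphic, s01 missing on a surviving SNP,
# s09/s10 duplicated genotypes. Designed for qc_config(snp_call_rate_min
# = 0.85) so the SNP carrying s01's missing call (call rate 0.9) survives
# the marker filter and s01 is caught by the sample filter.
qc_fixture <- function() {
  g <- rbind(
    # snp1 snp2 snp3 snp4 snp5 snp6
    c(   0,   0,  NA,   0,   1,   2),  # s01: missing at snp3 -> removed
    c(  NA,   0,   1,   0,   0,   0),  # s02: missing only at snp1
    c(  NA,   0,   0,   1,   0,   0),  # s03: missing only at snp1
    c(   1,   0,   2,   0,   1,   0),
    c(   2,   0,   0,   2,   0,   0),
    c(   0,   0,   1,   1,   1,   1),
    c(   1,   0,   0,   0,   2,   1),
    c(   2,   0,   1,   2,   2,   2),
    c(   0,   0,   2,   1,   0,   2),  # s09
    c(   0,   0,   2,   1,   0,   2))  # s10 = s09 -> IBS 1, s10 removed
  genotype_matrix(g, make_map(6, spacing = 1e6),
                  sprintf("s%02d", 1:10), "popA")
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
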