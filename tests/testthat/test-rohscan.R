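# genotype_matrix for one individual from a genotype vector + positions
one_ind <- function(g, bp, chrom = "1") {
  map <- marker_map(chrom, sprintf("r%03d", seq_along(g)), bp, "A", "B")
  genotype_matrix(matrix(as.integer(g), 1), map, "i1", "p")
}

test_that("a planted homozygous run is called exactly once", {
  # 35 consecutive homozygous SNPs spanning 1.19 Mb at uniform 35-kb spacing
  bp <- seq(1e6, by = 35e3, length.out = 35)
  segs <- detect_roh(one_ind(rep(0L, 35), bp), roh_params())
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_snps, 35L)
  expect_equal(segs$start_bp, bp[1])
  expect_equal(segs$end_bp, bp[35])
  # with only 29 SNPs the run fails the 30-SNP rule despite its length
  bp29 <- seq(1e6, by = 45e3, length.out = 29)
  expect_identical(nrow(detect_roh(one_ind(rep(0L, 29), bp29), roh_params())), 0L)
})

test_that("the caller matches the exhaustive oracle on structured fixtures", {
  # two hets inside an otherwise qualifying 40-SNP run: the caller must
  # return the oracle's maximal qualifying subintervals
  bp <- seq(1e6, by = 4e4, length.out = 40)
  g <- rep(0L, 40); g[c(15, 28)] <- 1L
  par <- roh_params(min_length_bp = 3e5, min_snps = 8)
  segs <- detect_roh(one_ind(g, bp), par)
  oracle <- oracle_roh(g, bp, par)
  expect_identical(nrow(segs), nrow(oracle))
  expect_equal(segs$start_bp, bp[oracle[, 1]])
  expect_equal(segs$end_bp, bp[oracle[, 2]])
  # at least one of the hets is excluded from every returned segment
  expect_true(all(segs$n_het <= par$max_het))
})

test_that("caller equals the brute-force oracle on random fixtures", {
  set.seed(77)
  for (rep in 1:40) {
    m <- sample(10:50, 1)
    bp <- sort(sample.int(3e6, m))
    par <- roh_params(min_length_bp = sample(c(1e5, 3e5, 6e5), 1),
                      min_snps = sample(3:8, 1),
                      max_het = sample(0:1, 1), max_missing = sample(0:1, 1),
                      min_density_bp_per_snp = sample(c(5e4, 1e5, 2e5), 1),
                      max_gap_bp = sample(c(2e5, 5e5), 1))
    g <- sample(c(0L, 0L, 0L, 2L, 2L, 1L, NA), m, replace = TRUE)
    segs <- detect_roh(one_ind(g, bp), par)
    oracle <- oracle_roh(g, bp, par)
    if (is.null(oracle)) {
      expect_identical(nrow(segs), 0L)
    } else {
      expect_identical(nrow(segs), nrow(oracle))
      expect_equal(segs$start_bp, bp[oracle[, 1]])
      expect_equal(segs$end_bp, bp[oracle[, 2]])
    }
    # every returned segment re-validates against the parameters
    if (nrow(segs) > 0) {
      expect_true(all(segs$n_snps >= par$min_snps))
      expect_true(all(segs$length_bp >= par$min_length_bp))
      expect_true(all(segs$n_het <= par$max_het))
      expect_true(all(segs$n_missing <= par$max_missing))
      expect_true(all(segs$length_bp / segs$n_snps <= par$min_density_bp_per_snp))
    }
  }
})

test_that("unsorted maps are rejected", {
  g <- one_ind(rep(0L, 10), seq(1e6, by = 5e4, length.out = 10))
  g$map$bp[3] <- 9e9  # corrupt order after construction
  expect_error(detect_roh(g), "sorted")
})

test_that("F_ROH arithmetic and group summaries are exact", {
  bp <- seq(1e6, by = 35e3, length.out = 35)
  g <- rep(0L, 35)
  gm <- one_ind(g, bp)
  segs <- detect_roh(gm)
  # paper-scale constant: L_ROH = 245,206,000 with default L_AUT -> 0.1
  fake <- segs; fake$length_bp <- 245206000
  fr <- froh(fake, gm)
  expect_equal(fr$per_indiv$froh, 0.1)
  # individual with no segments has F_ROH 0 and appears in the table
  gm2 <- genotype_matrix(rbind(g, rep(1L, 35)), gm$map, c("i1", "i2"), "p")
  fr2 <- froh(detect_roh(gm2), gm2)
  expect_equal(fr2$per_indiv$froh[fr2$per_indiv$indiv == "i2"], 0)
  expect_identical(fr2$per_group$mn_roh_all, 0.5)
  expect_identical(fr2$per_group$mn_roh_carriers, 1)
  # length classes: the 1.19-Mb segment falls in the 1-<5 Mb class
  expect_identical(fr2$per_group$roh_1_5mb, 1L)
  expect_identical(fr2$per_group$roh_ge20mb, 0L)
  expect_error(froh(segs, gm, l_aut_bp = 0), "positive")
})

test_that("ROH islands recover a shared span and honour degenerate input", {
  # 10 individuals, 6 carrying an identical homozygous run
  m <- 100
  bp <- seq(1e6, by = 5e4, length.out = m)
  map <- marker_map("1", sprintf("r%03d", 1:m), bp, "A", "B")
  set.seed(5)
  g <- matrix(1L, 10, m)  # heterozygous background: no chance ROH
  span <- 40:79           # 39 x 50 kb ~ 1.95 Mb
  for (i in 1:6) g[i, span] <- 0L
  gm <- genotype_matrix(g, map, sprintf("i%02d", 1:10), "p")
  segs <- detect_roh(gm)
  isl <- roh_islands(segs, gm, "p")
  inc <- attr(isl, "incidence")
  expect_equal(max(inc), 0.6)             # 6 of 10 carriers
  expect_identical(nrow(isl), 1L)
  expect_lte(isl$start_bp, bp[span[1]])
  expect_gte(isl$end_bp, bp[span[length(span)]])
  # rank method with a tied top block wider than 0.1% excludes itself
  isl_rank <- roh_islands(segs, gm, "p", method = "rank")
  expect_identical(nrow(isl_rank), 0L)
  # all segments absent -> empty result with warning
  gm_het <- genotype_matrix(matrix(1L, 10, m), map, sprintf("i%02d", 1:10), "p")
  expect_warning(isl0 <- roh_islands(detect_roh(gm_het), gm_het, "p"), "no SNP")
  expect_identical(nrow(isl0), 0L)
  # islands are invariant to individual ordering
  ord <- c(7, 2, 9, 1, 5, 10, 3, 8, 6, 4)
  gm_p <- genotype_matrix(g[ord, ], map, sprintf("i%02d", 1:10)[ord], "p")
  isl_p <- roh_islands(detect_roh(gm_p), gm_p, "p")
  expect_equal(isl_p$start_bp, isl$start_bp)
  expect_equal(isl_p$end_bp, isl$end_bp)
})
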