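test_that("EHHS matches the worked 4-haplotype example in both variants", {
  hap <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 0))
  hs <- haplotype_set(hap, make_map(2), c("i1", "i2"), "p")
  ct <- ehhs_curve(hs, 1, "tang")
  cs <- ehhs_curve(hs, 1, "sabeti")
  expect_equal(ct$ehhs, c(1, 0.5))        # (2*1)/(2*1 + 2*1)
  expect_equal(cs$ehhs, c(1, 1 / 6))      # C(2,2)/C(4,2)
})

test_that("identical haplotypes give EHHS 1 everywhere", {
  hap <- matrix(rep(c(0L, 1L, 1L, 0L, 1L), each = 6), 6, 5)
  hs <- haplotype_set(hap, make_map(5), sprintf("i%d", 1:3), "p")
  for (v in c("tang", "sabeti"))
    expect_true(all(ehhs_curve(hs, 3, v)$ehhs == 1))
})

test_that("EHHS equals the brute-force pair-counting oracle on random fixtures", {
  set.seed(17)
  for (rep in 1:25) {
    n <- 2 * sample(2:8, 1)
    m <- sample(4:20, 1)
    hs <- rand_haps(n, m, seed = 200 + rep, p = runif(1, 0.2, 0.8))
    core <- sample(m, 1)
    for (v in c("tang", "sabeti")) {
      got <- ehhs_curve(hs, core, v)$ehhs
      want <- oracle_ehhs_curve(hs$hap, core, v)
      want[core] <- 1
      expect_equal(got, want, tolerance = 1e-12)
      # monotone non-increasing away from the core
      expect_true(all(diff(got[core:m]) <= 1e-12))
      expect_true(all(diff(got[core:1]) <= 1e-12))
    }
  }
})

test_that("iES integration follows the truncated-trapezoid rule", {
  # one-sided: markers at 0 and 100 kb with EHHS 1 and 0.5 -> integral 75,000
  cu <- structure(list(core = 1, core_local = 1, variant = "tang",
                       bp = c(0, 1e5), ehhs = c(1, 0.5)), class = "ehhs_curve")
  expect_equal(integrate_ies(cu, cutoff = 0.05, discard_at_border = FALSE), 75000)
  # the side never drops below the cutoff: discarded at the border
  expect_true(is.na(integrate_ies(cu, cutoff = 0.05, discard_at_border = TRUE)))
  # truncation: first flanking marker already below cutoff on both sides
  cu2 <- structure(list(core = 2, core_local = 2, variant = "tang",
                        bp = c(0, 1e5, 2e5), ehhs = c(0.01, 1, 0.02)),
                   class = "ehhs_curve")
  expect_equal(integrate_ies(cu2, cutoff = 0.05),
               0.5 * (1 + 0.01) * 1e5 + 0.5 * (1 + 0.02) * 1e5)
})

test_that("iES equals an independent numeric-integration oracle on random curves", {
  set.seed(23)
  for (rep in 1:30) {
    m <- sample(5:40, 1)
    bp <- sort(sample.int(5e6, m))
    core <- sample(m, 1)
    e <- rep(NA_real_, m)
    e[core] <- 1
    if (core > 1) e[(core - 1):1] <- cummin(runif(core - 1))
    if (core < m) e[(core + 1):m] <- cummin(runif(m - core))
    for (db in c(TRUE, FALSE)) {
      cu <- structure(list(core = core, core_local = core, variant = "tang",
                           bp = bp, ehhs = e), class = "ehhs_curve")
      got <- integrate_ies(cu, cutoff = 0.05, discard_at_border = db)
      want <- oracle_ies(bp, e, core, 0.05, db)
      if (is.na(want)) expect_true(is.na(got))
      else expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("the p-transform matches the Gaussian two-sided identity", {
  expect_equal(score_to_pscore(0), 0)
  expect_equal(score_to_pscore(1.959964), -log10(0.05), tolerance = 1e-4)
  expect_equal(score_to_pscore(-1.959964), -log10(0.05), tolerance = 1e-4)
  expect_true(all(score_to_pscore(rnorm(50)) >= 0))
})

test_that("cross-population scans are antisymmetric and null under identity", {
  sim <- simulate_haplotypes(sim_config(n_diploids_per_pop = 15,
    chromosomes = data.frame(name = "1", length_bp = 15e6),
    snp_spacing_bp = 5e4, seed = 31))
  a <- sim$pops[[1]]; b <- sim$pops[[2]]
  # same data in both populations: raw identically 0, all p-scores 0
  tr0 <- suppressWarnings(cross_pop_scan(a, a, "rsb"))
  expect_true(all(tr0$raw[!is.na(tr0$raw)] == 0))
  expect_true(all(tr0$pscore[!is.na(tr0$pscore)] == 0))
  # swapping populations negates raw, keeps p-scores
  for (st in c("rsb", "xpehh")) {
    t_ab <- cross_pop_scan(a, b, st)
    t_ba <- cross_pop_scan(b, a, st)
    expect_equal(t_ab$raw, -t_ba$raw, tolerance = 1e-12)
    expect_equal(t_ab$pscore, t_ba$pscore, tolerance = 1e-9)
  }
})

test_that("windows tile from the first marker with the 250/10 kb geometry", {
  tr <- data.frame(chrom = "1", bp = c(0, 3e5, 5e5, 7.5e5, 1e6),
                   pscore = c(5, 5, 5, 0, 5))
  w <- significance_windows(tr, min_snps = 1)
  expect_identical(nrow(w), 5L)                 # starts 0, 240k, ..., 960k
  expect_equal(w$start_bp, c(0, 2.4e5, 4.8e5, 7.2e5, 9.6e5))
  expect_error(significance_windows(tr, window_bp = 1e4, overlap_bp = 1e4),
               "overlap")
  # >= 3 significant SNPs makes a window significant; 2 do not
  tr2 <- data.frame(chrom = "1", bp = c(1e4, 2e4, 3e4, 4e4),
                    pscore = c(4.5, 4.5, 4.5, 0))
  expect_true(significance_windows(tr2)$significant[1])
  tr3 <- data.frame(chrom = "1", bp = c(1e4, 2e4, 3e4), pscore = c(4.5, 4.5, 4))
  expect_false(any(significance_windows(tr3)$significant))  # strict ">"
  # all p-scores zero: no significant windows
  tr4 <- data.frame(chrom = "1", bp = seq(1e4, 1e6, by = 1e4), pscore = 0)
  expect_false(any(significance_windows(tr4)$significant))
})

test_that("regions merge within and across methods by the overlap rule", {
  trk <- data.frame(chrom = "1", bp = seq(5e4, 6e5, by = 5e4),
                    pscore = c(rep(5, 10), 0, 0))
  w <- significance_windows(trk)
  expect_identical(sum(w$significant), 2L)  # two windows sharing 10 kb
  reg <- popscanr:::method_regions(w, trk)
  expect_identical(nrow(reg), 1L)           # merged through the overlap
  expect_equal(reg$start_bp, 5e4)
  expect_equal(reg$end_bp, 5e5)
  # disjoint methods stay separate with their own support
  trk2 <- data.frame(chrom = "1", bp = seq(2e6, 2.5e6, by = 5e4),
                     pscore = c(5, 5, 5, rep(0, 8)))
  w2 <- significance_windows(trk2)
  out <- consolidate_regions(w, w2, NULL, trk, trk2)
  expect_identical(nrow(out), 2L)
  expect_identical(out$methods, c("Rsb", "XP-EHH"))
  # an island overlapping the Rsb region joins its method set
  isl <- data.frame(group = "p", chrom = "1", start_bp = 2.5e5, end_bp = 4e5,
                    n_snps = 3L, max_incidence = 0.7)
  out2 <- consolidate_regions(w, NULL, isl, trk, NULL)
  expect_identical(nrow(out2), 1L)
  expect_identical(out2$methods, "ROH-island,Rsb")
  expect_equal(out2$end_bp, 5e5)
})
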