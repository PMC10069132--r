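small_cfg <- function(seed = 1, n_dip = 10, ...) {
  sim_config(n_diploids_per_pop = n_dip,
             chromosomes = data.frame(name = "1", length_bp = 10e6),
             snp_spacing_bp = 5e4, seed = seed, ...)
}

test_that("simulation is deterministic under the seed", {
  a <- simulate_haplotypes(small_cfg(7))
  b <- simulate_haplotypes(small_cfg(7))
  expect_identical(a$pops[[1]]$hap, b$pops[[1]]$hap)
  expect_identical(a$pops[[2]]$hap, b$pops[[2]]$hap)
  expect_identical(a$truth$pop_freq, b$truth$pop_freq)
  c <- simulate_haplotypes(small_cfg(8))
  expect_false(identical(a$pops[[1]]$hap, c$pops[[1]]$hap))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(fst_target = 1), "fst_target")
  expect_error(sim_config(ancestral_maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(fst_target = 0, n_founders = 1), "diversity")
  expect_error(sweep_spec(1, "1", 5e6, 1e6, 0), "target_freq")
  expect_error(autozygosity_spec(1, "1", 5e6, 4e6, 0.5), "start_bp")
})

test_that("sample allele frequencies track the drawn population frequencies", {
  sim <- simulate_haplotypes(small_cfg(3))
  for (k in 1:2) {
    p_hat <- colMeans(sim$pops[[k]]$hap)
    p_pop <- sim$truth$pop_freq[, k]
    # binomial-scale agreement: RMS error ~ sqrt(p q (1/nf + 1/2n))
    expect_lt(sqrt(mean((p_hat - p_pop)^2)), 0.12)
    expect_gt(cor(p_hat, p_pop), 0.9)
  }
})

test_that("sweep injection copies the template at the requested frequency", {
  sim <- simulate_haplotypes(small_cfg(5))
  haps <- sim$pops[[1]]
  before <- haps$hap
  sp <- sweep_spec(1, "1", 5e6, 1e6, 0.9)
  res <- suppressWarnings(inject_sweep(haps, sp, seed = 5))
  expect_identical(res$record$n_carriers, round(0.9 * 20))  # 18 of 2n = 20
  win <- haps$map$bp >= 4e6 & haps$map$bp <= 6e6
  # outside the window nothing changes
  expect_identical(res$haps$hap[, !win], before[, !win])
  # carriers share the template's alleles across the window
  tpl <- res$haps$hap[res$record$template_hap, win]
  n_match <- sum(apply(res$haps$hap[, win, drop = FALSE], 1,
                       function(h) all(h == tpl)))
  expect_gte(n_match, 18)
  # target_freq 1 forces identity: EHHS = 1 at every marker in the window
  res1 <- suppressWarnings(inject_sweep(haps, sweep_spec(1, "1", 5e6, 1e6, 1), seed = 5))
  core <- which(win)[ceiling(sum(win) / 2)]
  for (v in c("tang", "sabeti")) {
    cu <- ehhs_curve(res1$haps, core, v)
    expect_true(all(cu$ehhs[win] == 1))
  }
})

test_that("autozygosity injection makes exact homozygous runs, hap1 untouched", {
  sim <- simulate_haplotypes(small_cfg(6))
  haps <- sim$pops[[1]]
  before <- haps$hap
  az <- autozygosity_spec(1, "1", 3e6, 5e6, 0.6)
  res <- inject_autozygosity(haps, az, seed = 6)
  expect_identical(nrow(res$record), 6L)  # 0.6 x 10 individuals
  span <- haps$map$bp >= 3e6 & haps$map$bp <= 5e6
  odd <- seq(1, 19, by = 2)
  # haplotype 1 of every individual is never altered
  expect_identical(res$haps$hap[odd, ], before[odd, ])
  # carriers are homozygous at every marker in the span
  for (ind in res$record$indiv) {
    i <- match(ind, haps$indiv)
    expect_identical(res$haps$hap[2 * i, span], res$haps$hap[2 * i - 1, span])
  }
  # full carrier fraction: every individual homozygous over the span
  res1 <- inject_autozygosity(haps, autozygosity_spec(1, "1", 3e6, 5e6, 1), seed = 6)
  g <- diploidize_and_emit(list(res1$haps), 0, 0, seed = 1)
  expect_true(all(g$geno[, span] != 1L))
})

test_that("diploidization sums haplotype pairs and applies noise at rate", {
  hs <- rand_haps(8, 50, seed = 12)
  g <- diploidize_and_emit(list(hs), 0, 0, seed = 1)
  expect_identical(unname(g$geno),
                   unname(hs$hap[c(1, 3, 5, 7), ] + hs$hap[c(2, 4, 6, 8), ]))
  expect_error(diploidize_and_emit(list(hs), -0.1, 0, seed = 1), "rates")
  # realized missingness close to the nominal rate (10,000 calls)
  hs2 <- rand_haps(40, 500, seed = 13)
  g2 <- diploidize_and_emit(list(hs2), 0.05, 0, seed = 2)
  expect_lt(abs(mean(is.na(g2$geno)) - 0.05), 0.01)
})

test_that("emitted files and the truth set round-trip", {
  az <- autozygosity_spec(1, "1", 3e6, 5e6, 0.5)
  sw <- sweep_spec(2, "1", 7e6, 0.6e6, 0.8)
  cfg <- small_cfg(9, sweep_specs = list(sw), autozygosity_specs = list(az))
  sim <- suppressWarnings(simulate_haplotypes(cfg))
  prefix <- tempfile("sim_")
  g <- diploidize_and_emit(sim$pops, 0, 0, seed = 9, truth = sim$truth,
                           prefix = prefix)
  g2 <- read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_identical(dim(g2$geno), dim(g$geno))
  tr <- read_truth(paste0(prefix, "_truth.tsv"))
  expect_identical(nrow(tr$autozygosity), nrow(sim$truth$autozygosity))
  expect_identical(tr$autozygosity$indiv, sim$truth$autozygosity$indiv)
  expect_equal(tr$autozygosity$start_bp, rep(3e6, 5))
  expect_equal(tr$sweeps$n, round(0.8 * 20))
  hsA <- read_phased(paste0(prefix, "_pop1_phased.tsv"), "tsv",
                     map = g$map, pop = "pop1")
  expect_identical(hsA$hap, sim$pops[[1]]$hap)
})

test_that("swept chromosomes show elevated iES at the core", {
  wins <- sapply(1:8, function(s) {
    cfg <- small_cfg(s, n_dip = 25)
    sim <- simulate_haplotypes(cfg)
    haps <- sim$pops[[1]]
    core_bp <- 5e6
    sp <- sweep_spec(1, "1", core_bp, 1e6, 0.9)
    swept <- suppressWarnings(inject_sweep(haps, sp, seed = s))$haps
    core <- which.min(abs(haps$map$bp - core_bp))
    ies_n <- integrate_ies(ehhs_curve(haps, core, "sabeti"), discard_at_border = FALSE)
    ies_s <- integrate_ies(ehhs_curve(swept, core, "sabeti"), discard_at_border = FALSE)
    ies_s > ies_n
  })
  expect_gte(sum(wins), 7)
})
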