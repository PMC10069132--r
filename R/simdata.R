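#' Simulation configuration for two-population SNP-array data
#'
#' Defines a two-population study design: background differentiation at a
#' target F_ST under the Balding-Nichols model, linkage structure from
#' recombinant founder mosaics, and optional planted selective sweeps and
#' planted autozygous segments with a machine-readable truth set.
#'
#' Defaults emulate a medium-density array design on two moderately
#' diverged groups: 50 diploids per population, one 50-Mb chromosome at one
#' SNP per 50 kb, F_ST 0.05, 200 founder haplotypes per population and a
#' mosaic crossover rate of 2e-6 per bp (mean founder-segment length 500 kb,
#' giving haplotype homozygosity that decays within a few hundred kb as on
#' real livestock arrays).
#'
#' @param n_diploids_per_pop diploid individuals per population.
#' @param chromosomes data.frame with columns `name`, `length_bp`.
#' @param snp_spacing_bp mean inter-marker distance in bp.
#' @param n_founders founder haplotypes per population.
#' @param recomb_rate crossovers per bp per mosaic draw.
#' @param ancestral_maf_range length-2 numeric, bounds of the uniform
#'   ancestral allele-frequency draw (0 < lo < hi < 1).
#' @param fst_target Balding-Nichols differentiation parameter in `[0, 1)`.
#' @param sweep_specs list of [sweep_spec()].
#' @param autozygosity_specs list of [autozygosity_spec()].
#' @param seed integer; fully determines all output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_diploids_per_pop = 50,
                       chromosomes = data.frame(name = "1", length_bp = 50e6),
                       snp_spacing_bp = 50e3,
                       n_founders = 200,
                       recomb_rate = 2e-6,
                       ancestral_maf_range = c(0.1, 0.9),
                       fst_target = 0.05,
                       sweep_specs = list(),
                       autozygosity_specs = list(),
                       seed = 1L) {
  stopifnot(n_diploids_per_pop >= 2, nrow(chromosomes) >= 1,
            all(chromosomes$length_bp > 0), snp_spacing_bp > 0,
            n_founders >= 1, recomb_rate >= 0)
  if (!(fst_target >= 0 && fst_target < 1)) stop("fst_target must be in [0, 1)")
  r <- ancestral_maf_range
  if (!(length(r) == 2 && r[1] > 0 && r[1] < r[2] && r[2] < 1))
    stop("ancestral_maf_range must satisfy 0 < lo < hi < 1")
  if (fst_target == 0 && n_founders < 2)
    stop("fst_target = 0 with fewer than 2 founders gives no diversity source")
  chromosomes$name <- as.character(chromosomes$name)
  structure(list(n_pops = 2L, n_diploids_per_pop = as.integer(n_diploids_per_pop),
                 chromosomes = chromosomes, snp_spacing_bp = snp_spacing_bp,
                 n_founders = as.integer(n_founders), recomb_rate = recomb_rate,
                 ancestral_maf_range = r, fst_target = fst_target,
                 sweep_specs = sweep_specs,
                 autozygosity_specs = autozygosity_specs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted-sweep specification
#'
#' A hard sweep is planted by copying one template haplotype over a window
#' into a chosen fraction of a population's haplotypes, creating a long
#' shared haplotype at high frequency — the signal Rsb/XP-EHH scans detect.
#'
#' @param pop population index (1 or 2).
#' @param chrom chromosome name.
#' @param core_bp sweep core position.
#' @param extent_bp half-width of the swept haplotype in bp.
#' @param target_freq frequency of the sweep haplotype in `(0, 1]`.
#' @export
sweep_spec <- function(pop, chrom, core_bp, extent_bp, target_freq) {
  stopifnot(pop %in% 1:2, extent_bp > 0, target_freq > 0, target_freq <= 1)
  structure(list(pop = as.integer(pop), chrom = as.character(chrom),
                 core_bp = core_bp, extent_bp = extent_bp,
                 target_freq = target_freq), class = "sweep_spec")
}

#' Planted-autozygosity specification
#'
#' Autozygosity is planted by overwriting the second haplotype of selected
#' individuals with their first over a span, creating exact runs of
#' homozygosity for the ROH caller and island procedure to recover.
#'
#' @param pop population index (1 or 2).
#' @param chrom chromosome name.
#' @param start_bp,end_bp span of the autozygous segment.
#' @param carrier_fraction fraction of individuals made autozygous.
#' @export
autozygosity_spec <- function(pop, chrom, start_bp, end_bp, carrier_fraction) {
  stopifnot(pop %in% 1:2, start_bp < end_bp,
            carrier_fraction > 0, carrier_fraction <= 1)
  structure(list(pop = as.integer(pop), chrom = as.character(chrom),
                 start_bp = start_bp, end_bp = end_bp,
                 carrier_fraction = carrier_fraction),
            class = "autozygosity_spec")
}

# one recombinant mosaic haplotype from a founder pool
mosaic_hap <- function(founders, pos, len_bp, rate) {
  nf <- nrow(founders)
  k <- rpois(1, rate * len_bp)
  if (k == 0) return(founders[sample.int(nf, 1), ])
  bk <- sort(runif(k, 0, len_bp))
  seg <- findInterval(pos, bk) + 1L          # segment index per marker
  src <- sample.int(nf, k + 1, replace = TRUE)
  founders[cbind(src[seg], seq_along(pos))]
}

#' Simulate two-population phased haplotypes with known truth
#'
#' For each SNP an ancestral frequency is drawn uniformly in
#' `ancestral_maf_range`; each population's frequency is a Balding-Nichols
#' draw `Beta(p(1-F)/F, (1-p)(1-F)/F)` around it; founder haplotypes are
#' sampled site-wise at the population frequency; each sample haplotype is
#' a recombinant mosaic of founders with Poisson crossovers. Sweeps and
#' autozygous segments from the config are then planted, and all planted
#' truth is recorded.
#'
#' @param config a [sim_config()].
#' @return list with `pops` (list of two [haplotype_set()]) and `truth`
#'   (list: `anc_freq`, `pop_freq`, `sweeps`, `autozygosity` data.frames).
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(op_seed(config$seed, "simulate_haplotypes"))
  maps <- list(); positions <- list()
  for (i in seq_len(nrow(config$chromosomes))) {
    ch <- config$chromosomes$name[i]; L <- config$chromosomes$length_bp[i]
    n_snp <- max(2L, round(L / config$snp_spacing_bp))
    if (n_snp < 2) stop("chromosome ", ch, " shorter than 2 markers")
    pos <- sort(sample.int(L, n_snp))
    positions[[ch]] <- pos
    maps[[ch]] <- data.frame(chrom = ch,
                             id = sprintf("snp_%s_%d", ch, seq_len(n_snp)),
                             bp = pos)
  }
  map_df <- do.call(rbind, maps)
  map <- marker_map(map_df$chrom, map_df$id, map_df$bp, "A", "B")
  m <- nrow(map)
  p_anc <- runif(m, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  F <- config$fst_target
  pop_freq <- matrix(NA_real_, m, 2)
  for (k in 1:2) {
    pop_freq[, k] <- if (F == 0) p_anc else
      rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }
  n <- config$n_diploids_per_pop
  pops <- vector("list", 2)
  for (k in 1:2) {
    founders <- matrix(rbinom(config$n_founders * m, 1, rep(pop_freq[, k],
                                                            each = config$n_founders)),
                       nrow = config$n_founders)
    hap <- matrix(0L, 2 * n, m)
    for (ch in names(positions)) {
      j <- which(map$chrom == ch)
      L <- config$chromosomes$length_bp[config$chromosomes$name == ch]
      for (h in seq_len(2 * n)) {
        hap[h, j] <- mosaic_hap(founders[, j, drop = FALSE], map$bp[j], L,
                                config$recomb_rate)
      }
    }
    pops[[k]] <- haplotype_set(hap, map,
                               sprintf("pop%d_ind%03d", k, seq_len(n)),
                               paste0("pop", k))
  }
  truth <- list(anc_freq = p_anc, pop_freq = pop_freq,
                sweeps = data.frame(), autozygosity = data.frame())
  for (sp in config$sweep_specs) {
    res <- inject_sweep(pops[[sp$pop]], sp, seed = config$seed)
    pops[[sp$pop]] <- res$haps
    truth$sweeps <- rbind(truth$sweeps, res$record)
  }
  for (az in config$autozygosity_specs) {
    res <- inject_autozygosity(pops[[az$pop]], az, seed = config$seed)
    pops[[az$pop]] <- res$haps
    truth$autozygosity <- rbind(truth$autozygosity, res$record)
  }
  list(pops = pops, truth = truth)
}

#' Plant a hard sweep into a haplotype set
#'
#' One existing haplotype is chosen as the sweep template; a
#' `round(target_freq * 2n)` subset of haplotypes has its alleles over
#' `[core_bp - extent_bp, core_bp + extent_bp]` replaced by the template's.
#' Markers outside the window are untouched.
#'
#' @param haps a [haplotype_set()].
#' @param spec a [sweep_spec()].
#' @param seed integer seed (carrier and template choice).
#' @return list with modified `haps` and a one-row `record` data.frame
#'   (realised carrier count and window).
#' @export
inject_sweep <- function(haps, spec, seed = 1L) {
  set.seed(op_seed(seed, paste0("inject_sweep_", spec$chrom, "_", spec$core_bp)))
  lo <- spec$core_bp - spec$extent_bp; hi <- spec$core_bp + spec$extent_bp
  j <- which(haps$map$chrom == spec$chrom & haps$map$bp >= lo & haps$map$bp <= hi)
  if (length(j) == 0) stop("sweep window contains no markers")
  if (length(j) < 30)
    warning("sweep window contains ", length(j),
            " SNPs (< 30); may be undetectable under the window rule")
  nh <- nrow(haps$hap)
  template <- sample.int(nh, 1)
  k <- round(spec$target_freq * nh)
  carriers <- sort(sample.int(nh, k))
  haps$hap[carriers, j] <- matrix(haps$hap[template, j], k, length(j), byrow = TRUE)
  record <- data.frame(pop = haps$pop, chrom = spec$chrom,
                       core_bp = spec$core_bp, extent_bp = spec$extent_bp,
                       target_freq = spec$target_freq,
                       n_carriers = k, template_hap = template)
  list(haps = haps, record = record)
}

#' Plant autozygous segments into a haplotype set
#'
#' For each selected individual (a `carrier_fraction` of the population),
#' the second haplotype's alleles over `[start_bp, end_bp]` are overwritten
#' by the first haplotype's, producing an exact autozygous run. Haplotype 1
#' is never altered.
#'
#' @param haps a [haplotype_set()].
#' @param spec an [autozygosity_spec()].
#' @param seed integer seed (carrier choice).
#' @return list with modified `haps` and a `record` data.frame of planted
#'   intervals (one row per carrier).
#' @export
inject_autozygosity <- function(haps, spec, seed = 1L) {
  set.seed(op_seed(seed, paste0("inject_autozygosity_", spec$chrom, "_", spec$start_bp)))
  j <- which(haps$map$chrom == spec$chrom & haps$map$bp >= spec$start_bp &
               haps$map$bp <= spec$end_bp)
  if (length(j) == 0) stop("autozygosity span contains no markers")
  n <- length(haps$indiv)
  k <- round(spec$carrier_fraction * n)
  carriers <- sort(sample.int(n, k))
  for (i in carriers) haps$hap[2 * i, j] <- haps$hap[2 * i - 1, j]
  record <- data.frame(pop = haps$pop, indiv = haps$indiv[carriers],
                       chrom = spec$chrom, start_bp = spec$start_bp,
                       end_bp = spec$end_bp)
  list(haps = haps, record = record)
}

#' Collapse phased haplotypes to diploid genotypes, with optional files
#'
#' Haplotype pairs `(2i-1, 2i)` become dosage genotypes (allele-1 counts);
#' independent per-call missingness and symmetric allele-flip genotyping
#' error are applied. With `prefix`, writes PED/MAP, a phased haplotype TSV
#' per population, and the truth set as TSV.
#'
#' @param pops list of [haplotype_set()] (one per population).
#' @param missing_rate per-genotype-call missing probability.
#' @param genotyping_error_rate per-allele-call symmetric flip probability.
#' @param seed integer seed.
#' @param truth optional truth list from [simulate_haplotypes()] to emit.
#' @param prefix optional output path prefix.
#' @return a [genotype_matrix()] over all samples.
#' @export
diploidize_and_emit <- function(pops, missing_rate = 0, genotyping_error_rate = 0,
                                seed = 1L, truth = NULL, prefix = NULL) {
  if (missing_rate < 0 || missing_rate > 1 || genotyping_error_rate < 0 ||
      genotyping_error_rate > 1)
    stop("rates must be in [0, 1]")
  set.seed(op_seed(seed, "diploidize_and_emit"))
  map <- pops[[1]]$map
  geno_list <- list(); ids <- character(); popl <- character()
  for (hs in pops) {
    hap <- hs$hap
    if (genotyping_error_rate > 0) {
      flip <- matrix(rbinom(length(hap), 1, genotyping_error_rate),
                     nrow(hap), ncol(hap))
      hap <- abs(hap - flip)
    }
    n <- length(hs$indiv)
    g <- hap[seq(1, 2 * n, 2), , drop = FALSE] + hap[seq(2, 2 * n, 2), , drop = FALSE]
    if (missing_rate > 0)
      g[matrix(rbinom(length(g), 1, missing_rate), n, ncol(g)) == 1L] <- NA_integer_
    geno_list[[length(geno_list) + 1]] <- g
    ids <- c(ids, hs$indiv); popl <- c(popl, rep(hs$pop, n))
  }
  geno <- genotype_matrix(do.call(rbind, geno_list), map, ids, popl)
  if (!is.null(prefix)) {
    write_ped_map(geno, prefix)
    for (hs in pops) write_phased(hs, paste0(prefix, "_", hs$pop, "_phased.tsv"))
    if (!is.null(truth)) write_truth(truth, paste0(prefix, "_truth.tsv"))
  }
  geno
}

#' Write / read the planted-truth set
#'
#' The truth set's interval records (sweeps and autozygous segments) are
#' serialised as a single TSV with a `record` type column; reading it back
#' reproduces the planted intervals exactly.
#'
#' @param truth truth list from [simulate_haplotypes()].
#' @param path TSV path.
#' @return `write_truth` returns `path` invisibly; `read_truth` returns a
#'   list with `sweeps` and `autozygosity` data.frames.
#' @export
write_truth <- function(truth, path) {
  rows <- list()
  if (nrow(truth$sweeps %||% data.frame()) > 0) {
    s <- truth$sweeps
    rows[[1]] <- data.frame(record = "sweep", pop = s$pop, indiv = NA,
                            chrom = s$chrom, start_bp = s$core_bp - s$extent_bp,
                            end_bp = s$core_bp + s$extent_bp,
                            value = s$target_freq, n = s$n_carriers)
  }
  if (nrow(truth$autozygosity %||% data.frame()) > 0) {
    a <- truth$autozygosity
    rows[[2]] <- data.frame(record = "autozygosity", pop = a$pop, indiv = a$indiv,
                            chrom = a$chrom, start_bp = a$start_bp,
                            end_bp = a$end_bp, value = NA, n = NA)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record = character(), pop = character(), indiv = character(),
               chrom = character(), start_bp = numeric(), end_bp = numeric(),
               value = numeric(), n = integer())
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  list(sweeps = d[d$record == "sweep", , drop = FALSE],
       autozygosity = d[d$record == "autozygosity", , drop = FALSE])
}

#' Wright-Fisher forward simulator
#'
#' Discrete-generation random-mating diploid population of constant size
#' `n_diploids` with Poisson recombination at 1 cM/Mb, evolved for
#' `n_generations` from linkage-equilibrium founders. Used to generate
#' genotype data whose true (census = effective) size is known, for
#' calibrating LD-based N_e estimation.
#'
#' @param n_diploids population size (constant).
#' @param n_snp marker count on one chromosome.
#' @param chrom_length_bp chromosome length.
#' @param n_generations generations of random mating.
#' @param seed integer seed.
#' @return a [genotype_matrix()] (population label `"WF"`).
#' @export
sim_wright_fisher <- function(n_diploids = 100, n_snp = 2000,
                              chrom_length_bp = 50e6, n_generations = 200,
                              seed = 1L) {
  set.seed(op_seed(seed, "sim_wright_fisher"))
  pos <- sort(sample.int(chrom_length_bp, n_snp))
  morgans <- chrom_length_bp * 1e-8
  p0 <- runif(n_snp, 0.1, 0.9)
  hap <- matrix(rbinom(2 * n_diploids * n_snp, 1, rep(p0, each = 2 * n_diploids)),
                nrow = 2 * n_diploids)
  gamete <- function(h1, h2) {
    k <- rpois(1, morgans)
    if (k == 0) return(if (runif(1) < 0.5) h1 else h2)
    bk <- sort(runif(k, 0, chrom_length_bp))
    phase <- (findInterval(pos, bk) + (runif(1) < 0.5)) %% 2
    ifelse(phase == 0, h1, h2)
  }
  for (g in seq_len(n_generations)) {
    nxt <- matrix(0L, 2 * n_diploids, n_snp)
    for (i in seq_len(n_diploids)) {
      pa <- sample.int(n_diploids, 2, replace = TRUE)
      nxt[2 * i - 1, ] <- gamete(hap[2 * pa[1] - 1, ], hap[2 * pa[1], ])
      nxt[2 * i, ] <- gamete(hap[2 * pa[2] - 1, ], hap[2 * pa[2], ])
    }
    hap <- nxt
  }
  g <- hap[seq(1, 2 * n_diploids, 2), ] + hap[seq(2, 2 * n_diploids, 2), ]
  map <- marker_map("1", sprintf("wf_snp_%d", seq_len(n_snp)), pos, "A", "B")
  genotype_matrix(g, map, sprintf("wf_ind%03d", seq_len(n_diploids)), "WF")
}
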