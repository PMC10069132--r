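#' Pipeline configuration
#'
#' Bundles all stage settings for the one-command run: either a
#' [sim_config()] (simulation mode) or input file paths (ingest mode),
#' plus QC, ROH and scan settings, the two scan groups, output directory
#' and master seed.
#'
#' @param sim a [sim_config()], or `NULL` to ingest files.
#' @param input list with `ped`, `map`, `phased` (named list of haplotype
#'   TSV per population) when `sim` is `NULL`.
#' @param qc a [qc_config()].
#' @param roh a [roh_params()].
#' @param scan list: `threshold`, `window_bp`, `overlap_bp`, `min_snps`,
#'   `cutoff`, `discard_at_border`.
#' @param scan_groups character of length 2: the two population labels
#'   contrasted by the haplotype scans.
#' @param n_perm F_ST permutations.
#' @param island_percentile ROH-island percentile.
#' @param l_aut_bp denominator for F_ROH.
#' @param missing_rate,genotyping_error_rate simulation emission noise.
#' @param out_dir output directory (created).
#' @param seed master seed; stage seeds derive from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input = NULL,
                            qc = qc_config(), roh = roh_params(),
                            scan = list(), scan_groups = c("pop1", "pop2"),
                            n_perm = 1000, island_percentile = 0.999,
                            l_aut_bp = 2452060000,
                            missing_rate = 0.01, genotyping_error_rate = 0.001,
                            out_dir = tempfile("popscan_run_"), seed = 1L) {
  scan_def <- list(threshold = 4.0, window_bp = 250000, overlap_bp = 10000,
                   min_snps = 3L, cutoff = 0.05, discard_at_border = TRUE)
  scan_def[names(scan)] <- scan
  if (length(scan_groups) != 2) stop("exactly 2 scan groups are required")
  structure(list(sim = sim, input = input, qc = qc, roh = roh,
                 scan = scan_def, scan_groups = scan_groups, n_perm = n_perm,
                 island_percentile = island_percentile, l_aut_bp = l_aut_bp,
                 missing_rate = missing_rate,
                 genotyping_error_rate = genotyping_error_rate,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Declarative counterpart of [pipeline_config()]: top-level keys mirror
#' its arguments; `sim`, `qc`, `roh` sub-maps are passed to their
#' constructors; `sim$chromosomes` is a list of `{name, length_bp}` maps;
#' `sim$sweeps` / `sim$autozygosity` lists are passed to [sweep_spec()] /
#' [autozygosity_spec()].
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    s <- y$sim
    if (!is.null(s$chromosomes))
      s$chromosomes <- do.call(rbind, lapply(s$chromosomes, as.data.frame))
    s$sweep_specs <- lapply(s$sweeps, function(x) do.call(sweep_spec, x))
    s$autozygosity_specs <- lapply(s$autozygosity,
                                   function(x) do.call(autozygosity_spec, x))
    s$sweeps <- NULL; s$autozygosity <- NULL
    sim <- do.call(sim_config, s)
  }
  args <- y[setdiff(names(y), c("sim", "qc", "roh"))]
  args$sim <- sim
  if (!is.null(y$qc)) args$qc <- do.call(qc_config, y$qc)
  if (!is.null(y$roh)) args$roh <- do.call(roh_params, y$roh)
  do.call(pipeline_config, args)
}

log_stage <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))

restrict_haps <- function(haps, map) {
  idx <- match(map$id, haps$map$id)
  if (anyNA(idx)) stop("phased data lacks markers present in the genotype map")
  haplotype_set(haps$hap[, idx, drop = FALSE], map, haps$indiv, haps$pop)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or ingest) -> QC -> LD-pruned branch
#' (heterozygosity, F_ST/Reynolds with permutations, IBS-MDS, LD-based
#' N_e) -> unpruned branch (ROH, F_ROH, ROH islands per scan group) ->
#' phased branch (Rsb and XP-EHH scans with significance windows) ->
#' cross-method candidate-region consolidation. All artifacts are written
#' under `out_dir/{sim,qc,diversity,roh,scan,regions}` and a run report
#' (JSON + text) summarises headline numbers.
#'
#' The pruned set feeds only the diversity/structure branch; ROH and
#' haplotype scans use the unpruned post-QC markers.
#'
#' @param cfg a [pipeline_config()].
#' @return list (class `run_report`): headline results of every stage plus
#'   the paths of all written artifacts.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dirs <- file.path(cfg$out_dir, c("sim", "qc", "diversity", "roh", "scan", "regions"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  keep <- function(p) { artifacts <<- c(artifacts, p); p }

  # --- ingest or simulate -------------------------------------------------
  if (!is.null(cfg$sim)) {
    log_stage("simulate", "2 populations x %d diploids, %d chromosome(s)",
              cfg$sim$n_diploids_per_pop, nrow(cfg$sim$chromosomes))
    cfg$sim$seed <- cfg$seed
    sim <- simulate_haplotypes(cfg$sim)
    pops <- sim$pops; truth <- sim$truth
    prefix <- file.path(cfg$out_dir, "sim", "sim")
    geno <- diploidize_and_emit(pops, cfg$missing_rate,
                                cfg$genotyping_error_rate, seed = cfg$seed,
                                truth = truth, prefix = prefix)
    keep(paste0(prefix, c(".ped", ".map", "_truth.tsv",
                          paste0("_", vapply(pops, `[[`, "", "pop"),
                                 "_phased.tsv"))))
  } else {
    log_stage("ingest", "reading %s / %s", cfg$input$ped, cfg$input$map)
    geno <- read_ped_map(cfg$input$ped, cfg$input$map)
    pops <- lapply(names(cfg$input$phased), function(p)
      read_phased(cfg$input$phased[[p]], "tsv", map = geno$map, pop = p))
    truth <- NULL
  }

  # --- QC -----------------------------------------------------------------
  qcres <- apply_qc(geno, cfg$qc)
  geno_qc <- qcres$geno
  log_stage("qc", "markers %d -> %d, samples %d -> %d",
            ncol(geno$geno), ncol(geno_qc$geno),
            nrow(geno$geno), nrow(geno_qc$geno))
  rep_tab <- qcres$report
  rep_tab$removed <- vapply(rep_tab$removed, function(x) paste(x, collapse = ","), "")
  data.table::fwrite(rep_tab, keep(file.path(cfg$out_dir, "qc", "qc_report.tsv")),
                     sep = "\t")

  # --- diversity branch (LD-pruned) ----------------------------------------
  geno_pruned <- ld_prune(geno_qc, cfg$qc)
  log_stage("prune", "markers %d -> %d", ncol(geno_qc$geno), ncol(geno_pruned$geno))
  het <- heterozygosity(geno_pruned)
  fst <- pairwise_fst(geno_pruned, n_perm = cfg$n_perm, seed = cfg$seed)
  mds <- ibs_mds(geno_pruned, k = 3)
  ne <- ld_ne(geno_pruned, seed = cfg$seed)
  div_tab <- het
  div_tab$ne13 <- vapply(div_tab$pop, function(p)
    if (!is.null(ne[[p]])) attr(ne[[p]], "ne13") else NA_real_, 0)
  div_tab$ne50 <- vapply(div_tab$pop, function(p)
    if (!is.null(ne[[p]])) attr(ne[[p]], "ne50") else NA_real_, 0)
  data.table::fwrite(div_tab, keep(file.path(cfg$out_dir, "diversity", "diversity.tsv")),
                     sep = "\t")
  write.table(fst$fst, keep(file.path(cfg$out_dir, "diversity", "fst.tsv")),
              sep = "\t", quote = FALSE)
  write.table(fst$reynolds, keep(file.path(cfg$out_dir, "diversity", "reynolds.tsv")),
              sep = "\t", quote = FALSE)
  write.table(fst$p_value, keep(file.path(cfg$out_dir, "diversity", "fst_pvalues.tsv")),
              sep = "\t", quote = FALSE)
  data.table::fwrite(data.frame(id = rownames(mds$coords), mds$coords),
                     keep(file.path(cfg$out_dir, "diversity", "mds_coords.tsv")),
                     sep = "\t")

  # --- ROH branch (unpruned post-QC) ---------------------------------------
  segs <- detect_roh(geno_qc, cfg$roh)
  fr <- froh(segs, geno_qc, cfg$l_aut_bp)
  data.table::fwrite(segs, keep(file.path(cfg$out_dir, "roh", "segments.tsv")),
                     sep = "\t")
  data.table::fwrite(fr$per_indiv, keep(file.path(cfg$out_dir, "roh", "froh.tsv")),
                     sep = "\t")
  data.table::fwrite(fr$per_group, keep(file.path(cfg$out_dir, "roh", "froh_groups.tsv")),
                     sep = "\t")
  islands <- do.call(rbind, lapply(cfg$scan_groups, function(g)
    if (g %in% geno_qc$samples$pop)
      roh_islands(segs, geno_qc, g, cfg$island_percentile) else NULL))
  if (!is.null(islands) && nrow(islands) > 0) {
    bed <- data.frame(chrom = islands$chrom,
                      start = format(islands$start_bp - 1, scientific = FALSE, trim = TRUE),
                      end = format(islands$end_bp, scientific = FALSE, trim = TRUE),
                      name = paste0("island_", islands$group))
    write.table(bed, keep(file.path(cfg$out_dir, "roh", "islands.bed")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  log_stage("roh", "%d segments, %s islands", nrow(segs),
            if (is.null(islands)) "0" else nrow(islands))

  # --- haplotype-scan branch (phased, unpruned post-QC markers) -------------
  hapsA <- restrict_haps(pops[[1]], geno_qc$map)
  hapsB <- restrict_haps(pops[[2]], geno_qc$map)
  tr_rsb <- cross_pop_scan(hapsA, hapsB, "rsb", cutoff = cfg$scan$cutoff,
                           discard_at_border = cfg$scan$discard_at_border)
  tr_xp <- cross_pop_scan(hapsA, hapsB, "xpehh", cutoff = cfg$scan$cutoff,
                          discard_at_border = cfg$scan$discard_at_border)
  w_rsb <- significance_windows(tr_rsb, cfg$scan$window_bp, cfg$scan$overlap_bp,
                                cfg$scan$min_snps, cfg$scan$threshold)
  w_xp <- significance_windows(tr_xp, cfg$scan$window_bp, cfg$scan$overlap_bp,
                               cfg$scan$min_snps, cfg$scan$threshold)
  data.table::fwrite(tr_rsb, keep(file.path(cfg$out_dir, "scan", "rsb_track.tsv")), sep = "\t")
  data.table::fwrite(tr_xp, keep(file.path(cfg$out_dir, "scan", "xpehh_track.tsv")), sep = "\t")
  data.table::fwrite(w_rsb, keep(file.path(cfg$out_dir, "scan", "rsb_windows.tsv")), sep = "\t")
  data.table::fwrite(w_xp, keep(file.path(cfg$out_dir, "scan", "xpehh_windows.tsv")), sep = "\t")
  log_stage("scan", "Rsb: %d significant SNPs, %d windows; XP-EHH: %d SNPs, %d windows",
            sum(tr_rsb$pscore > cfg$scan$threshold, na.rm = TRUE), sum(w_rsb$significant),
            sum(tr_xp$pscore > cfg$scan$threshold, na.rm = TRUE), sum(w_xp$significant))

  # --- consolidation --------------------------------------------------------
  regions <- consolidate_regions(w_rsb, w_xp, islands, tr_rsb, tr_xp,
                                 cfg$scan$threshold)
  if (nrow(regions) > 0) {
    bed <- data.frame(chrom = regions$chrom,
                      start = format(regions$start_bp - 1, scientific = FALSE, trim = TRUE),
                      end = format(regions$end_bp, scientific = FALSE, trim = TRUE),
                      name = gsub(",", "+", regions$methods))
    write.table(bed, keep(file.path(cfg$out_dir, "regions", "regions.bed")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  log_stage("regions", "%d consolidated candidate region(s)", nrow(regions))

  report <- list(
    seed = cfg$seed,
    counts = list(markers_in = ncol(geno$geno), markers_qc = ncol(geno_qc$geno),
                  markers_pruned = ncol(geno_pruned$geno),
                  samples_in = nrow(geno$geno), samples_qc = nrow(geno_qc$geno)),
    diversity = div_tab, fst = fst$fst, reynolds = fst$reynolds,
    fst_p = fst$p_value, mds_explained = mds$explained,
    roh = list(n_segments = nrow(segs), froh_mean = mean(fr$per_indiv$froh),
               n_islands = if (is.null(islands)) 0L else nrow(islands)),
    scan = list(rsb_signif_snps = sum(tr_rsb$pscore > cfg$scan$threshold, na.rm = TRUE),
                xpehh_signif_snps = sum(tr_xp$pscore > cfg$scan$threshold, na.rm = TRUE),
                rsb_signif_windows = sum(w_rsb$significant),
                xpehh_signif_windows = sum(w_xp$significant)),
    regions = regions, truth = truth, artifacts = artifacts)
  jsonlite::write_json(report[c("seed", "counts", "roh", "scan")],
                       keep(file.path(cfg$out_dir, "run_report.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(c(sprintf("popscanr run (seed %d)", cfg$seed),
               sprintf("markers: %d -> %d after QC (%d pruned)",
                       ncol(geno$geno), ncol(geno_qc$geno), ncol(geno_pruned$geno)),
               sprintf("ROH segments: %d; mean F_ROH: %.4f", nrow(segs),
                       mean(fr$per_indiv$froh)),
               sprintf("candidate regions: %d", nrow(regions))),
             keep(file.path(cfg$out_dir, "run_report.txt")))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("popscanr run report (seed", x$seed, ")\n")
  cat("  markers:", x$counts$markers_in, "->", x$counts$markers_qc,
      "after QC;", x$counts$markers_pruned, "after pruning\n")
  cat("  samples:", x$counts$samples_in, "->", x$counts$samples_qc, "\n")
  cat("  ROH segments:", x$roh$n_segments, "; islands:", x$roh$n_islands, "\n")
  cat("  significant windows: Rsb", x$scan$rsb_signif_windows,
      "; XP-EHH", x$scan$xpehh_signif_windows, "\n")
  cat("  candidate regions:", nrow(x$regions), "\n")
  invisible(x)
}
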