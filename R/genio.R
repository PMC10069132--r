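#' Read PLINK text PED/MAP genotypes
#'
#' Parses a PLINK text fileset into a [genotype_matrix()]. Biallelic calls
#' are recoded to minor-allele dosage (0/1/2) computed at load time; ties in
#' allele frequency are broken towards the lexicographically smaller allele
#' so the coding is deterministic. `0 0` genotype pairs become missing.
#'
#' @param ped_path path to the `.ped` file (6 leading columns: family id,
#'   sample id, father, mother, sex, phenotype; then two allele columns per
#'   marker). The family id is taken as the population label.
#' @param map_path path to the 4-column `.map` file (chrom, id, cM, bp).
#' @return a [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  map_raw <- data.table::fread(map_path, header = FALSE, colClasses = "character",
                               data.table = FALSE)
  if (ncol(map_raw) != 4) stop("MAP file must have 4 columns")
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  need <- 6L + 2L * m
  bad <- which(vapply(toks, length, 1L) != need)
  if (length(bad))
    stop("ragged PED line ", bad[1], ": expected ", need, " fields, got ",
         length(toks[[bad[1]]]))
  ped <- do.call(rbind, toks)
  n <- nrow(ped)
  fam <- ped[, 1]; sid <- ped[, 2]
  al <- ped[, -(1:6), drop = FALSE]
  a_first <- al[, seq(1, 2 * m, by = 2), drop = FALSE]
  a_second <- al[, seq(2, 2 * m, by = 2), drop = FALSE]
  geno <- matrix(NA_integer_, n, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    x <- c(a_first[, j], a_second[, j])
    obs <- x != "0"
    alleles <- sort(unique(x[obs]))
    if (length(alleles) > 2)
      stop("marker ", map_raw[j, 2], " has more than two alleles: ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0) alleles <- c("0", "0")
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    cnt1 <- sum(x[obs] == alleles[1])
    cnt2 <- sum(x[obs] == alleles[2])
    # minor allele first; tie -> lexicographically smaller (already sorted)
    minor <- if (cnt2 < cnt1) alleles[2] else alleles[1]
    major <- if (cnt2 < cnt1) alleles[1] else alleles[2]
    g <- (a_first[, j] == minor) + (a_second[, j] == minor)
    g[a_first[, j] == "0" | a_second[, j] == "0"] <- NA_integer_
    geno[, j] <- as.integer(g)
    a1[j] <- minor; a2[j] <- major
  }
  map <- marker_map(map_raw[, 1], map_raw[, 2], as.numeric(map_raw[, 4]), a1, a2)
  genotype_matrix(geno, map, sid, fam)
}

#' Write PLINK text PED/MAP genotypes
#'
#' @param geno a [genotype_matrix()] whose map carries allele codes.
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return invisibly, the two file paths.
#' @export
write_ped_map <- function(geno, prefix) {
  if (nrow(geno$geno) == 0 || ncol(geno$geno) == 0)
    stop("refusing to write an empty genotype matrix")
  map <- geno$map
  if (any(is.na(map$a1) | is.na(map$a2)))
    stop("allele codes missing for ", sum(is.na(map$a1) | is.na(map$a2)),
         " markers; cannot write PED")
  m <- nrow(map); n <- nrow(geno$geno)
  pairs <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    g <- geno$geno[, j]
    first <- ifelse(is.na(g), "0", ifelse(g >= 1, map$a1[j], map$a2[j]))
    second <- ifelse(is.na(g), "0", ifelse(g == 2, map$a1[j], map$a2[j]))
    pairs[, 2 * j - 1] <- first
    pairs[, 2 * j] <- second
  }
  ped <- cbind(geno$samples$pop, geno$samples$id, "0", "0", "0", "-9", pairs)
  ped_path <- paste0(prefix, ".ped"); map_path <- paste0(prefix, ".map")
  data.table::fwrite(data.table::as.data.table(ped), ped_path, sep = " ",
                     col.names = FALSE, quote = FALSE)
  data.table::fwrite(data.frame(map$chrom, map$id, 0, format(map$bp, scientific = FALSE, trim = TRUE)),
                     map_path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read phased haplotypes
#'
#' Ingests already-phased binary haplotypes, either as a haplotype-matrix
#' TSV (rows = haplotypes, columns = markers, header line of marker ids,
#' first column = haplotype id of the form `<indiv>_1` / `<indiv>_2`) or as
#' a phased VCF (`GT` with `|` separators; unphased `/` calls are an error).
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param map a [marker_map()] supplying positions for the TSV format
#'   (matched to the header marker ids); ignored for VCF.
#' @param pop population label to attach.
#' @return a [haplotype_set()].
#' @export
read_phased <- function(path, format = c("tsv", "vcf"), map = NULL, pop = "pop1") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    d <- data.table::fread(path, header = TRUE, data.table = FALSE)
    ids <- d[[1]]
    hap <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(hap) <- "integer"
    if (nrow(hap) %% 2L != 0L) stop("odd haplotype count in ", path)
    mids <- colnames(hap)
    if (is.null(map)) stop("a marker map is required for TSV haplotypes")
    idx <- match(mids, map$id)
    if (anyNA(idx)) stop("marker ids in ", path, " not found in map: ",
                         paste(head(mids[is.na(idx)], 3), collapse = ", "))
    map <- map[idx, , drop = FALSE]
    class(map) <- c("marker_map", "data.frame")
    indiv <- sub("_[12]$", "", ids[seq(1, length(ids), by = 2)])
    return(haplotype_set(hap, map, indiv, pop))
  }
  # phased VCF via vcfR
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE))) stop("unphased genotype (\"/\") in ", path)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) stop("non-biallelic site in ", path)
  parts <- strsplit(as.vector(gt), "|", fixed = TRUE)
  if (any(vapply(parts, length, 1L) != 2L)) stop("malformed GT field in ", path)
  h1 <- matrix(as.integer(vapply(parts, `[`, "", 1L)), nrow = nrow(gt))
  h2 <- matrix(as.integer(vapply(parts, `[`, "", 2L)), nrow = nrow(gt))
  n <- ncol(gt); m <- nrow(gt)
  hap <- matrix(NA_integer_, 2 * n, m)
  hap[seq(1, 2 * n, 2), ] <- t(h1)
  hap[seq(2, 2 * n, 2), ] <- t(h2)
  map <- marker_map(vcfR::getCHROM(v), rownames(gt), vcfR::getPOS(v),
                    alt, vcfR::getREF(v))
  haplotype_set(hap, map, colnames(gt), pop)
}

#' Write phased haplotypes as TSV
#'
#' Tab-separated haplotype matrix: header of marker ids, one row per
#' haplotype, first column a haplotype id `<indiv>_1` / `<indiv>_2`.
#'
#' @param haps a [haplotype_set()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_phased <- function(haps, path) {
  ids <- paste0(rep(haps$indiv, each = 2), "_", rep(1:2, length(haps$indiv)))
  d <- data.frame(hap_id = ids, haps$hap, check.names = FALSE)
  colnames(d) <- c("hap_id", haps$map$id)
  data.table::fwrite(d, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# strand complement for orientation checks
comp_allele <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

#' Merge two genotype matrices on shared markers
#'
#' Intersects markers on `(id, chrom, bp)`, concatenates samples and
#' harmonises allele orientation: markers whose allele pair is swapped are
#' dosage-flipped (2 <-> 0); markers matching only after strand
#' complementation are flipped likewise; strand-ambiguous (A/T, C/G) markers
#' with mismatching codes are dropped, as are markers with irreconcilable
#' alleles.
#'
#' @param a,b [genotype_matrix()] objects with allele codes in their maps.
#' @return the merged [genotype_matrix()].
#' @export
merge_on_markers <- function(a, b) {
  key_a <- paste(a$map$id, a$map$chrom, a$map$bp)
  key_b <- paste(b$map$id, b$map$chrom, b$map$bp)
  shared <- intersect(key_a, key_b)
  if (length(shared) == 0) stop("no shared markers between the two datasets")
  if (any(a$samples$id %in% b$samples$id))
    stop("duplicated sample ids across datasets: ",
         paste(head(intersect(a$samples$id, b$samples$id), 3), collapse = ", "))
  ia <- match(shared, key_a); ib <- match(shared, key_b)
  keep <- rep(TRUE, length(shared))
  flip <- rep(FALSE, length(shared))
  for (k in seq_along(shared)) {
    pa <- c(a$map$a1[ia[k]], a$map$a2[ia[k]])
    pb <- c(b$map$a1[ib[k]], b$map$a2[ib[k]])
    ambiguous <- all(sort(pa) %in% c("A", "T")) || all(sort(pa) %in% c("C", "G"))
    if (identical(pa, pb)) next
    if (identical(pa, rev(pb))) {
      if (ambiguous) keep[k] <- FALSE else flip[k] <- TRUE
    } else if (!anyNA(comp_allele(pb)) && identical(pa, unname(comp_allele(pb)))) {
      if (ambiguous) keep[k] <- FALSE
    } else if (!anyNA(comp_allele(pb)) && identical(pa, unname(comp_allele(rev(pb))))) {
      if (ambiguous) keep[k] <- FALSE else flip[k] <- TRUE
    } else keep[k] <- FALSE
  }
  ia <- ia[keep]; ib <- ib[keep]; flip <- flip[keep]
  if (length(ia) == 0) stop("no reconcilable shared markers after harmonisation")
  gb <- b$geno[, ib, drop = FALSE]
  if (any(flip)) gb[, flip] <- 2L - gb[, flip, drop = FALSE]
  # order by the first dataset's map order
  ord <- order(ia)
  ia <- ia[ord]; ib <- ib[ord]
  gb <- gb[, ord, drop = FALSE]
  geno <- rbind(a$geno[, ia, drop = FALSE], gb)
  map <- a$map[ia, , drop = FALSE]
  class(map) <- c("marker_map", "data.frame")
  genotype_matrix(geno, map, c(a$samples$id, b$samples$id),
                  c(a$samples$pop, b$samples$pop))
}
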