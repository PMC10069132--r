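#' Marker map constructor
#'
#' A marker map describes the SNPs of a dataset: chromosome label, marker id,
#' 1-based bp position and the two allele codes (`a1` is the dosage-counted
#' allele, by convention the minor allele when read from PED/MAP).
#'
#' @param chrom character vector of chromosome labels.
#' @param id unique marker ids.
#' @param bp 1-based physical positions, strictly increasing within a
#'   chromosome.
#' @param a1,a2 allele codes (single characters, e.g. "A"/"B" or bases).
#' @return a `data.frame` with class `marker_map`.
#' @export
marker_map <- function(chrom, id, bp, a1 = NA_character_, a2 = NA_character_) {
  map <- data.frame(chrom = as.character(chrom), id = as.character(id),
                    bp = as.numeric(bp), a1 = as.character(a1),
                    a2 = as.character(a2), stringsAsFactors = FALSE)
  if (anyDuplicated(map$id)) stop("marker ids must be unique")
  for (ch in unique(map$chrom)) {
    b <- map$bp[map$chrom == ch]
    if (is.unsorted(b, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Genotype matrix container
#'
#' The hub object of the genotype-based stages: an `n_samples x n_markers`
#' integer matrix of allele dosages (0/1/2, `NA` = missing call) with an
#' attached [marker_map()] and per-sample population labels.
#'
#' @param geno integer matrix, samples in rows, markers in columns; values
#'   in `{0, 1, 2, NA}`. Column order must match the map.
#' @param map a [marker_map()].
#' @param sample_id character vector of unique sample ids.
#' @param pop character vector of population labels (recycled if length 1).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map, sample_id, pop) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (ncol(geno) != nrow(map))
    stop("geno has ", ncol(geno), " markers but map has ", nrow(map))
  if (nrow(geno) != length(sample_id))
    stop("geno has ", nrow(geno), " samples but ", length(sample_id), " ids given")
  if (anyDuplicated(sample_id)) stop("duplicated sample ids")
  pop <- rep_len(as.character(pop), nrow(geno))
  if (any(!is.na(geno) & (geno < 0L | geno > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(is.na(pop) | pop == "")) stop("population labels must be non-empty")
  rownames(geno) <- sample_id
  colnames(geno) <- map$id
  structure(list(geno = geno, map = map,
                 samples = data.frame(id = as.character(sample_id), pop = pop,
                                      stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "samples x", ncol(x$geno), "markers;",
      length(unique(x$samples$pop)), "population(s):",
      paste(unique(x$samples$pop), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Phased haplotype container
#'
#' Binary phased haplotypes for one population: a `2n x m` matrix of alleles
#' in `{0, 1}` (`NA` allowed for missing), rows `2i-1` and `2i` forming
#' individual `i`, with an attached [marker_map()].
#'
#' @param hap integer matrix of alleles, haplotypes in rows.
#' @param map a [marker_map()].
#' @param indiv character vector of individual ids (`nrow(hap)/2` of them).
#' @param pop single population label.
#' @return an object of class `haplotype_set`.
#' @export
haplotype_set <- function(hap, map, indiv, pop) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  if (nrow(hap) %% 2L != 0L) stop("haplotype count must be even (diploids)")
  if (ncol(hap) != nrow(map))
    stop("hap has ", ncol(hap), " markers but map has ", nrow(map))
  if (length(indiv) != nrow(hap) / 2L)
    stop("need one individual id per haplotype pair")
  if (any(!is.na(hap) & hap != 0L & hap != 1L))
    stop("haplotype alleles must be 0/1")
  colnames(hap) <- map$id
  structure(list(hap = hap, map = map, indiv = as.character(indiv),
                 pop = as.character(pop)[1]),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set: population", x$pop, "-", nrow(x$hap), "haplotypes (",
      length(x$indiv), "diploids ) x", ncol(x$hap), "markers\n")
  invisible(x)
}

# split marker indices by chromosome, preserving map order
chrom_index <- function(map) split(seq_len(nrow(map)), map$chrom)[unique(map$chrom)]

# per-marker minor allele frequency from dosage matrix (a1-allele freq,
# folded to <= 0.5 when fold = TRUE)
marker_freq <- function(geno, fold = FALSE) {
  n <- colSums(!is.na(geno))
  p <- colSums(geno, na.rm = TRUE) / (2 * n)
  if (fold) pmin(p, 1 - p) else p
}
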