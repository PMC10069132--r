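test_that("PED/MAP round-trips and uses minor-allele dosage coding", {
  g <- rand_geno(5, 20, seed = 11, miss = 0.1)
  prefix <- tempfile("rt_")
  write_ped_map(g, prefix)
  g2 <- read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_identical(g2$map$id, g$map$id)
  expect_identical(g2$map$bp, g$map$bp)
  expect_identical(g2$samples$id, g$samples$id)
  # dosage is recomputed on the minor allele at load, so columns where the
  # written a1 allele is in fact major come back flipped; compare folded
  same <- g2$geno == g$geno
  flipped <- g2$geno == 2L - g$geno
  expect_true(all(same | flipped, na.rm = TRUE))
  expect_identical(is.na(g2$geno), is.na(g$geno))
  # a second round-trip is exact: coding is now canonical
  prefix2 <- tempfile("rt2_")
  write_ped_map(g2, prefix2)
  g3 <- read_ped_map(paste0(prefix2, ".ped"), paste0(prefix2, ".map"))
  expect_identical(g3$geno, g2$geno)
})

test_that("PED parsing handles missing pairs, rejects bad records", {
  map <- c("1 snpA 0 100", "1 snpB 0 200")
  ped <- c("fam1 s1 0 0 0 -9 A A A G",
           "fam1 s2 0 0 0 -9 0 0 G G",
           "fam1 s3 0 0 0 -9 A A G G")
  g <- read_ped_map(write_lines_tmp(ped, ".ped"), write_lines_tmp(map, ".map"))
  # snpA: A is the only allele -> monomorphic, dosage counts A
  expect_identical(unname(g$geno[, "snpA"]), c(2L, NA, 2L))
  # snpB: A freq 1/6 -> minor, s1 het = 1
  expect_identical(unname(g$geno[, "snpB"]), c(1L, 0L, 0L))
  # triallelic marker errors with its name
  bad <- c("fam1 s1 0 0 0 -9 A A C G", "fam1 s2 0 0 0 -9 A A G T")
  expect_error(read_ped_map(write_lines_tmp(bad, ".ped"),
                            write_lines_tmp(map, ".map")), "snpB")
  # ragged line errors with the line number
  ragged <- c("fam1 s1 0 0 0 -9 A A A G", "fam1 s2 0 0 0 -9 A A")
  expect_error(read_ped_map(write_lines_tmp(ragged, ".ped"),
                            write_lines_tmp(map, ".map")), "line 2")
  # empty matrix refuses to write
  expect_error(write_ped_map(genotype_matrix(matrix(integer(), 0, 2),
                                             make_map(2), character(), character()),
                             tempfile()), "empty")
})

test_that("phased TSV haplotypes round-trip with exact values", {
  hs <- rand_haps(4, 3, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_phased(hs, f)
  hs2 <- read_phased(f, "tsv", map = hs$map, pop = hs$pop)
  expect_identical(hs2$hap, hs$hap)
  expect_identical(hs2$indiv, hs$indiv)
  # hand-written 4 x 3 fixture
  txt <- c("hap_id\tm1_001\tm1_002\tm1_003",
           "a_1\t0\t1\t0", "a_2\t1\t1\t0", "b_1\t0\t0\t1", "b_2\t1\t0\t1")
  hs3 <- read_phased(write_lines_tmp(txt, ".tsv"), "tsv", map = make_map(3))
  expect_identical(unname(hs3$hap),
                   matrix(c(0L,1L,0L,1L, 1L,1L,0L,0L, 0L,0L,1L,1L), 4, 3))
  expect_identical(hs3$indiv, c("a", "b"))
})

test_that("phased VCF is parsed and unphased GT rejected", {
  skip_if_not_installed("vcfR")
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
           "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
           "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|0\t1|0")
  hs <- read_phased(write_lines_tmp(vcf, ".vcf"), "vcf", pop = "p")
  expect_identical(dim(hs$hap), c(4L, 2L))
  expect_identical(unname(hs$hap[, 1]), c(0L, 1L, 1L, 1L))  # s1 then s2
  expect_identical(unname(hs$hap[, 2]), c(0L, 0L, 1L, 0L))
  expect_identical(hs$map$bp, c(100, 200))
  bad <- sub("0\\|1", "0/1", vcf)
  expect_error(read_phased(write_lines_tmp(bad, ".vcf"), "vcf"), "unphased")
})

test_that("merge intersects markers and harmonises allele orientation", {
  # dataset a: 20 markers; dataset b shares 12, with 3 swapped a1/a2
  ga <- rand_geno(4, 20, seed = 21)
  shared <- 5:16
  gb <- rand_geno(3, 20, seed = 22)
  gb$samples$id <- paste0("b_", gb$samples$id)
  gb <- popscanr:::subset_geno(gb, markers = shared)
  swap <- c(2, 5, 9)  # local indices within shared
  gb$map$a1[swap] <- "B"; gb$map$a2[swap] <- "A"
  gb$geno[, swap] <- 2L - gb$geno[, swap]
  mg <- merge_on_markers(ga, gb)
  expect_identical(ncol(mg$geno), 12L)
  expect_identical(nrow(mg$geno), 7L)
  # b's dosages must come back on a's orientation (swaps un-flipped)
  expect_identical(unname(mg$geno[5:7, ]),
                   unname(rand_geno(3, 20, seed = 22)$geno[, shared]))
  # identical marker sets: union of samples, markers unchanged
  gc <- rand_geno(2, 20, seed = 23)
  gc$samples$id <- c("x1", "x2")
  mg2 <- merge_on_markers(ga, gc)
  expect_identical(mg2$map$id, ga$map$id)
  expect_identical(nrow(mg2$geno), 6L)
  # disjoint marker sets error; duplicated sample ids error
  gd <- rand_geno(2, 5, seed = 24)
  gd$map$id <- paste0("other_", gd$map$id)
  expect_error(merge_on_markers(ga, gd), "no shared markers")
  expect_error(merge_on_markers(ga, ga), "duplicated sample ids")
})

test_that("strand-ambiguous mismatching markers are dropped in merge", {
  ga <- rand_geno(3, 6, seed = 31)
  ga$map$a1 <- c("A", "A", "C", "A", "C", "T")
  ga$map$a2 <- c("G", "T", "G", "C", "T", "G")
  gb <- rand_geno(3, 6, seed = 32)
  gb$samples$id <- paste0("b_", gb$samples$id)
  gb$map$a1 <- c("A", "T", "G", "A", "C", "T")
  gb$map$a2 <- c("G", "A", "C", "C", "T", "G")
  # marker 2 is A/T (ambiguous) with swapped codes -> dropped;
  # marker 3 is C/G (ambiguous) with swapped codes -> dropped
  mg <- merge_on_markers(ga, gb)
  expect_identical(mg$map$id, ga$map$id[-c(2, 3)])
})
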