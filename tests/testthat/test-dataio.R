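test_that("genotype TSV writes and reads back identically", {
  gm <- tiny_gm()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, path)
  gm2 <- read_genotypes(path, "tsv")
  expect_equal(unname(gm2$a1), unname(gm$a1))
  expect_equal(unname(gm2$a2), unname(gm$a2))
  expect_equal(gm2$individuals, gm$individuals)
  expect_equal(sum(is.na(gm2$a1)), 0L)
  # canonical round-trip: writing the re-read matrix reproduces the file
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm2, path2)
  expect_identical(readLines(path2), readLines(path))
  # depth sidecar round-trips too
  expect_equal(unname(gm2$depth), unname(gm$depth))
})

test_that("missing token ./. yields a missing call, other calls intact", {
  lines <- c("individual\tm1\tm2", "i1\tA/C\t./.", "i2\tA/A\tG/G")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, path)
  gm <- read_genotypes(path, "tsv")
  expect_true(is.na(gm$a1["i1", "m2"]) && is.na(gm$a2["i1", "m2"]))
  expect_equal(geno_call(gm, "i1", "m1"), c("A", "C"))
  expect_equal(geno_call(gm, "i2", "m2"), c("G", "G"))
})

test_that("unparseable genotype cells become missing with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual\tm1", "i1\tAC", "i2\tA/C"), path)
  expect_warning(gm <- read_genotypes(path, "tsv"), "unparseable")
  expect_true(is.na(gm$a1["i1", "m1"]))
  expect_equal(geno_call(gm, "i2", "m1"), c("A", "C"))
})

test_that("malformed headers and duplicate markers are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tm1", "i1\tA/C"), path)
  expect_error(read_genotypes(path, "tsv"), "line 1")
  writeLines(c("individual\tm1\tm1", "i1\tA/C\tA/C"), path)
  expect_error(read_genotypes(path, "tsv"), "duplicate marker")
})

test_that("minimal VCF parsing fills genotypes and depths, 0-based positions", {
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti1\ti2",
           "sc1\t101\tm1\tA\tC\t.\tPASS\t.\tGT:DP\t0/1:15\t1/1:9",
           "sc2\t501\tm2\tG\tT,TT\t.\tPASS\t.\tGT:DP\t0/2:30\t./.:.")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  gm <- read_genotypes(path, "vcf")
  # hand-parsed expectations
  expect_equal(geno_call(gm, "i1", "m1"), c("A", "C"))
  expect_equal(geno_call(gm, "i2", "m1"), c("C", "C"))
  expect_equal(geno_call(gm, "i1", "m2"), c("G", "TT"))
  expect_true(all(is.na(geno_call(gm, "i2", "m2"))))
  expect_equal(unname(gm$depth["i1", ]), c(15, 30))
  expect_equal(gm$markers$position, c(100L, 500L))
  expect_equal(gm$markers$kind, c("SNP", "SSR"))
})

test_that("pedigrees read correctly regardless of row order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(ped_text_24(), path)
  fams <- read_pedigree(path)
  expect_length(fams, 1)
  f <- fams[["fam1"]]
  expect_equal(nrow(f$offspring), 24)
  expect_equal(sum(f$offspring$sex == "M"), 12)
  writeLines(ped_text_24(order_shuffled = TRUE), path)
  f2 <- read_pedigree(path)[["fam1"]]
  expect_equal(f2$sire_id, f$sire_id)
  expect_setequal(f2$offspring$id, f$offspring$id)
})

test_that("two families may share a sire; invalid families are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tindividual_id\trole\tsex",
               "famA\ts8\tsire\tNA", "famA\td12\tdam\tNA",
               "famA\to1\toffspring\tM",
               "famB\ts8\tsire\tNA", "famB\td13\tdam\tNA",
               "famB\to2\toffspring\tF"), path)
  fams <- read_pedigree(path)
  expect_equal(fams[["famA"]]$sire_id, fams[["famB"]]$sire_id)
  writeLines(c("family_id\tindividual_id\trole\tsex",
               "famC\ts1\tsire\tNA", "famC\td1\tdam\tNA"), path)
  expect_error(read_pedigree(path), "no offspring")
  writeLines(c("family_id\tindividual_id\trole\tsex",
               "famD\ts1\tsire\tNA", "famD\to1\toffspring\tM"), path)
  expect_error(read_pedigree(path), "exactly one sire and one dam")
})

test_that("qc_filter masks shallow homozygotes and drops sparse markers", {
  off <- sprintf("o%02d", 1:24)
  n <- 26
  a <- matrix("A", n, 2); b <- matrix("A", n, 2)
  b[, 2] <- "C"  # marker 2 heterozygous everywhere
  depth <- matrix(30L, n, 2)
  depth[3, 1] <- 9L   # shallow homozygote at marker 1
  depth[3, 2] <- 9L   # shallow heterozygote: must survive
  gm <- geno_matrix(data.frame(id = c("mA", "mB"), scaffold = "s",
                               position = 0:1, kind = "SNP"),
                    c("sire", "dam", off), a, b, depth)
  flt <- qc_filter(gm, off, min_called = 20, min_hom_depth = 10)
  expect_true(is.na(flt$a1["o01", "mA"]))  # o01 is row 3
  expect_equal(geno_call(flt, "o01", "mB"), c("A", "C"))

  # marker called in 19 of 24 offspring is dropped at min_called = 20
  gm2 <- gm
  gm2$a1[3:7, 2] <- NA; gm2$a2[3:7, 2] <- NA
  flt2 <- qc_filter(gm2, off, min_called = 20, min_hom_depth = 0)
  expect_false("mB" %in% flt2$markers$id)
  expect_true("mA" %in% flt2$markers$id)
})

test_that("qc_filter is idempotent, identity at zero thresholds, never unmasks", {
  set.seed(42)
  lay <- two_lg_layout()
  sim <- simulate_family(lay, sd_config_xy("LG5", 2e6, 1), 24, seed = 9)
  noisy <- simulate_depth_noise(sim$geno, mean_depth = 6, seed = 10)
  off <- sim$family$offspring$id
  f1 <- qc_filter(noisy, off, min_called = 20, min_hom_depth = 10)
  f2 <- qc_filter(f1, off, min_called = 20, min_hom_depth = 10)
  expect_identical(f1$a1, f2$a1)
  expect_identical(f1$markers$id, f2$markers$id)
  # identity case
  f0 <- qc_filter(noisy, off, min_called = 0, min_hom_depth = 0)
  expect_identical(f0$a1, noisy$a1)
  # no resurrection: every missing call in the input is missing in output
  common <- intersect(colnames(noisy$a1), colnames(f1$a1))
  expect_true(all(is.na(f1$a1[, common][is.na(noisy$a1[, common])])))
})

test_that("PAF parsing computes identity and honours optional tags", {
  paf <- c(paste(c("sc1", 5000, 0, 5000, "+", "LG5", 1e7, 20000, 25000,
                   4500, 5000, 60), collapse = "\t"),
           paste(c("sc1", 5000, 0, 5000, "+", "LG5", 1e7, 30000, 35000,
                   4990, 5000, 0, "NM:i:10", "s2:i:3"), collapse = "\t"))
  path <- withr::local_tempfile(fileext = ".paf")
  writeLines(paf, path)
  rec <- parse_alignments(path)
  expect_equal(rec$identity[1], 0.90)
  expect_equal(rec$n_suboptimal[1], 0L)       # no tag: defaults to 0
  expect_true(rec$unique[1])                  # mapq 60
  expect_equal(rec$identity[2], 1 - 10 / 5000)
  expect_equal(rec$n_suboptimal[2], 3L)
  expect_false(rec$unique[2])                 # mapq 0

  writeLines(character(), path)
  expect_equal(nrow(parse_alignments(path)), 0L)

  writeLines("sc1\t5000\t0\t5000", path)
  expect_error(parse_alignments(path), "line 1")
})

test_that("alignment records survive a PAF write/parse cycle", {
  lay <- two_lg_layout()
  sp <- make_scaffold_spec(lay, 3, seed = 4, min_len = 60000)
  rec <- simulate_alignments(lay, sp, window = 5000, seed = 5)
  path <- withr::local_tempfile(fileext = ".paf")
  write_alignments(rec, path)
  back <- parse_alignments(path)
  expect_equal(back$scaffold, rec$scaffold)
  expect_equal(back$target_lg, rec$target_lg)
  expect_equal(back$target_pos, rec$target_pos)
  expect_equal(back$window_start, rec$window_start)
  expect_true(all(abs(back$identity - rec$identity) < 1e-3))
})
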