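test_that("assign_sex follows the W-over-Y dominance hierarchy", {
  expect_equal(assign_sex("Y"), "M")
  expect_equal(assign_sex("W"), "F")
  expect_equal(assign_sex(c("Y", "W")), "F")   # W epistatic over Y
  expect_equal(assign_sex(character()), "F")   # default sex (XX female)
  expect_equal(assign_sex(c("Y", "Y")), "M")
})

test_that("a 0-Morgan chromosome transmits an unrecombined parental haplotype", {
  lay <- genome_layout(data.frame(lg = "L", length_bp = 1e6,
                                  length_morgans = 0))
  haps <- list(L = list(h1 = c("a", "a", "a"), h2 = c("b", "b", "b"),
                        pos_morgans = c(0, 0, 0)))
  set.seed(1)
  for (i in 1:20) {
    g <- simulate_gamete(haps, lay)
    expect_true(identical(g$L$alleles, haps$L$h1) ||
                  identical(g$L$alleles, haps$L$h2))
    expect_length(g$L$crossovers, 0)
  }
})

test_that("recombination follows the Haldane map function", {
  # terminal markers on a 1-Morgan chromosome: expected rf = (1 - e^-2)/2
  lay <- genome_layout(data.frame(lg = "L", length_bp = 1e6,
                                  length_morgans = 1))
  haps <- list(L = list(h1 = c("a", "a"), h2 = c("b", "b"),
                        pos_morgans = c(0, 1)))
  set.seed(7)
  rec <- vapply(1:10000, function(i) {
    g <- simulate_gamete(haps, lay)$L$alleles
    g[1] != g[2]
  }, TRUE)
  expect_equal(mean(rec), (1 - exp(-2)) / 2, tolerance = 0.02 / 0.43)
})

test_that("unfused linkage groups assort independently", {
  lay <- genome_layout(data.frame(lg = c("A", "B"),
                                  length_bp = c(1e6, 1e6),
                                  length_morgans = c(0.5, 0.5)))
  haps <- list(A = list(h1 = "a", h2 = "b", pos_morgans = 0),
               B = list(h1 = "a", h2 = "b", pos_morgans = 0))
  set.seed(8)
  draws <- t(vapply(1:5000, function(i) {
    g <- simulate_gamete(haps, lay)
    c(g$A$alleles, g$B$alleles)
  }, c("", "")))
  p <- stats::chisq.test(table(draws[, 1], draws[, 2]))$p.value
  expect_gt(p, 1e-3)
})

test_that("fused chromosomes co-segregate as one linkage unit", {
  # two 0.25-Morgan LGs fused: terminal-to-terminal distance 0.5 Morgans,
  # Haldane rf = (1 - e^-1)/2 ~ 0.316; unfused they would assort at 0.5
  lay <- genome_layout(data.frame(lg = c("A", "B"),
                                  length_bp = c(1e6, 1e6),
                                  length_morgans = c(0.25, 0.25)),
                       fusions = list(c("A", "B")))
  haps <- list(`A-B` = list(h1 = c("a", "a"), h2 = c("b", "b"),
                            pos_morgans = c(0, 0.5)))
  set.seed(9)
  rec <- vapply(1:8000, function(i) {
    g <- simulate_gamete(haps, lay)$`A-B`$alleles
    g[1] != g[2]
  }, TRUE)
  expect_equal(mean(rec), (1 - exp(-1)) / 2, tolerance = 0.05)
})

test_that("simulated sex ratios match the analytic expectation per system", {
  lay <- bench <- genome_layout(
    data.frame(lg = c("LG5", "LG13", "LG16"),
               length_bp = c(38e6, 34e6, 28e6),
               length_morgans = c(0.9, 0.8, 0.7)))
  spec <- marker_spec(snp_per_lg = 1, ssr_per_lg = 0)
  cfg <- list(xy = sd_config_xy("LG5", 2e6, 1),
              zw = sd_config_zw("LG13", 2e6, "LG16", 2e6, 1),
              both = sd_model(data.frame(
                lg = c("LG5", "LG13"), position = c(2e6, 2e6),
                allele = c("Y", "W"), carrier = c("sire", "dam")), 1))
  for (nm in names(cfg)) {
    sim <- simulate_family(lay, cfg[[nm]], 3000, spec,
                           seed = 100 + match(nm, names(cfg)))
    expect_equal(mean(sim$truth$genotypic_sex == "M"),
                 expected_male_fraction(cfg[[nm]]), tolerance = 0.1,
                 label = paste("male fraction for", nm))
  }
  expect_equal(expected_male_fraction(cfg$xy), 0.5)
  expect_equal(expected_male_fraction(cfg$zw), 0.5)
  expect_equal(expected_male_fraction(cfg$both), 0.25)
})

test_that("penetrance controls the sex-reversal fraction", {
  lay <- two_lg_layout()
  sim <- simulate_family(lay, sd_config_xy("LG5", 2e6, 0.88), 5000,
                         marker_spec(snp_per_lg = 1, ssr_per_lg = 0),
                         seed = 77)
  expect_equal(mean(sim$truth$sex_reversed), 0.12, tolerance = 0.015 / 0.12)
  expect_true(all((sim$truth$genotypic_sex != sim$truth$phenotypic_sex) ==
                    sim$truth$sex_reversed))
})

test_that("offspring genotypes are Mendelian-consistent before noise", {
  lay <- two_lg_layout()
  sim <- simulate_family(lay, sd_config_xy("LG5", 2e6, 1), 30, seed = 13)
  mc <- mendelian_consistent(sim$geno, sim$family)
  expect_true(all(mc))
})

test_that("depth noise adds Poisson depths and zero-depth missingness", {
  lay <- two_lg_layout()
  sim <- simulate_family(lay, sd_model(NULL, 1), 50, seed = 21)
  deep <- simulate_depth_noise(sim$geno, mean_depth = 1000, seed = 22)
  expect_equal(sum(is.na(deep$a1)), 0L)

  big <- simulate_family(lay, sd_model(NULL, 1), 1000,
                         marker_spec(snp_per_lg = 10, ssr_per_lg = 0),
                         seed = 23)
  shallow <- simulate_depth_noise(big$geno, mean_depth = 5, seed = 24)
  expect_equal(mean(is.na(shallow$a1)), exp(-5), tolerance = 0.002 / exp(-5))

  again <- simulate_depth_noise(big$geno, mean_depth = 5, seed = 24)
  expect_identical(shallow$a1, again$a1)
  expect_identical(shallow$depth, again$depth)
})

test_that("simulated alignments respect orientation, count, and fusions", {
  lay <- genome_layout(data.frame(lg = c("A", "B"),
                                  length_bp = c(2e6, 2e6),
                                  length_morgans = c(0.5, 0.5)),
                       fusions = list(c("A", "B")))
  # one reversed scaffold on the fused chromosome
  sp <- data.frame(scaffold = c("s1", "s2"), chrom = "A-B",
                   start = c(0, 3e6), end = c(3e6, 4e6),
                   orient = c("+", "-"))
  rec <- simulate_alignments(lay, sp, window = 5000, noise = 0, seed = 31)
  # 1 Mb scaffold at 5 kb windows -> 200 records
  expect_equal(sum(rec$scaffold == "s2"), 200L)
  # reversed orientation: target positions strictly decrease with window index
  r2 <- rec[rec$scaffold == "s2", ]
  r2 <- r2[order(r2$window_start), ]
  expect_true(all(diff(r2$target_pos) < 0))
  # junction-spanning scaffold s1 maps to both reference LGs
  expect_setequal(unique(rec$target_lg[rec$scaffold == "s1"]), c("A", "B"))
  expect_error(simulate_alignments(lay, data.frame(scaffold = "x",
    chrom = "A-B", start = 0, end = 3000, orient = "+"), window = 5000),
    "window larger")
})

test_that("scenario files simulate end-to-end and write readable outputs", {
  sc_path <- system.file("extdata", "scenario_basic.yaml", package = "polysd")
  expect_true(nzchar(sc_path))
  sc <- read_scenario(sc_path)
  expect_s3_class(sc$layout, "genome_layout")
  expect_equal(sc$model$penetrance, 0.88)
  out <- withr::local_tempdir()
  sims <- simulate_scenario(sc, seed = 5, out_dir = out)
  expect_length(sims, nrow(sc$families))
  ped <- read_pedigree(file.path(out, "pedigree.tsv"))
  expect_length(ped, nrow(sc$families))
  g1 <- read_genotypes(file.path(out, paste0(sc$families$name[1], ".geno.tsv")))
  expect_equal(sort(g1$individuals),
               sort(c(sims[[1]]$geno$individuals)))
  truth <- read.delim(file.path(out, "truth.tsv"))
  expect_true(all(c("id", "genotypic_sex", "sex_reversed") %in% names(truth)))
})
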