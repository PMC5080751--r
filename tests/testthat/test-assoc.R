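test_that("fisher_exact_2x2 reproduces hand-enumerated p-values", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  # margins (2,2)/(2,2): 3 tables, tail mass 2 x 1/6
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  # complete 5/5 separation: 2/252 by enumeration over the support
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
  expect_warning(p0 <- fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("fisher_exact_2x2 matches the reference implementation on small tables", {
  # all tables with total <= 12 (the exhaustive <= 30 sweep runs in the
  # acceptance suite); reference = stats::fisher.test
  for (n in 1:12) for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    tb <- matrix(c(a, b, cc, n - a - b - cc), 2)
    expect_equal(fisher_exact_2x2(tb), stats::fisher.test(tb)$p.value,
                 tolerance = 1e-12, label = paste(tb, collapse = ","))
  }
})

test_that("fisher_exact_2x2 is invariant under transposition and row/col swaps", {
  set.seed(3)
  for (i in 1:50) {
    tb <- matrix(rpois(4, 5), 2)
    if (sum(tb) == 0) next
    p <- fisher_exact_2x2(tb)
    expect_equal(fisher_exact_2x2(t(tb)), p)
    expect_equal(fisher_exact_2x2(tb[2:1, 2:1]), p)
  }
})

test_that("allelic tables count two alleles per called individual by sex", {
  gm <- geno_matrix(data.frame(id = "m", scaffold = "s", position = 0L,
                               kind = "SNP"),
                    c("x1", "x2", "x3", "x4"),
                    a1 = matrix(c("A", "A", "a", "a"), 4),
                    a2 = matrix(c("A", "A", "a", "a"), 4))
  off <- data.frame(id = c("x1", "x2", "x3", "x4"),
                    sex = c("M", "M", "F", "F"))
  expect_equal(unname(allelic_table(gm, "m", off)),
               matrix(c(4, 0, 0, 4), 2, byrow = TRUE))

  gm2 <- geno_matrix(data.frame(id = "m", scaffold = "s", position = 0L,
                                kind = "SNP"),
                     c("x1", "x2"), matrix(c("A", "A"), 2),
                     matrix(c("a", "a"), 2))
  off2 <- data.frame(id = c("x1", "x2"), sex = c("M", "F"))
  expect_equal(unname(allelic_table(gm2, "m", off2)),
               matrix(1, 2, 2))

  # missing individuals excluded: column sums are 2 x called
  gm3 <- gm
  gm3$a1[4, 1] <- NA; gm3$a2[4, 1] <- NA
  tb <- allelic_table(gm3, "m", off)
  expect_equal(colSums(tb), c(M = 4, F = 2))

  # multi-allelic markers are skipped with a message
  gm4 <- geno_matrix(data.frame(id = "m", scaffold = "s", position = 0L,
                                kind = "SSR"),
                     c("x1", "x2"), matrix(c("a1", "a2"), 2),
                     matrix(c("a3", "a3"), 2))
  expect_message(res <- allelic_table(gm4, "m", off2), "multi-allelic")
  expect_null(res)
})

test_that("transmission tables deduce parental alleles where unambiguous", {
  cx <- cross_gm(8, 8)
  tb <- transmission_table(cx$gm, cx$family, "mk", "sire")
  expect_equal(unname(tb), matrix(c(8, 0, 0, 8), 2, byrow = TRUE))
  expect_equal(rownames(tb), c("A", "B"))

  # homozygous parent: not informative
  gm_hom <- cx$gm
  gm_hom$a2[1, 1] <- "A"  # sire now A/A
  expect_null(transmission_table(gm_hom, cx$family, "mk", "sire"))

  # dam C/C is informative for no deduction ambiguity but carries no signal
  expect_null(transmission_table(cx$gm, cx$family, "mk", "dam"))

  # double heterozygotes sharing both alleles are confounded -> NI
  gm_ab <- geno_matrix(data.frame(id = "m", scaffold = "s", position = 0L,
                                  kind = "SNP"),
                       c("sire", "dam", sprintf("o%d", 1:6)),
                       a1 = matrix(c("A", "B", rep("A", 6)), ncol = 1),
                       a2 = matrix(c("B", "A", rep("A", 6)), ncol = 1))
  fam <- family_ped("f", "sire", "dam",
                    data.frame(id = sprintf("o%d", 1:6),
                               sex = rep(c("M", "F"), 3)))
  expect_null(transmission_table(gm_ab, fam, "m", "sire"))

  # A/B x A/B offspring: heterozygous offspring ambiguous, excluded
  expect_true(is.na(polysd:::deduce_transmitted(c("A", "B"), c("A", "B"),
                                                c("A", "B"))))
  expect_equal(polysd:::deduce_transmitted(c("A", "B"), c("C", "C"),
                                           c("A", "C")), "A")
})

test_that("assoc_scan composes per-marker exact tests and drops QC failures", {
  lay <- two_lg_layout()
  sim <- simulate_family(lay, sd_config_zw("LG5", 1.9e6, "LG13", 2e6, 1),
                         17, seed = 41)
  res <- assoc_scan(sim$geno, sim$family, mode = "transmission",
                    parent = "dam")
  best <- res[which.min(res$p), ]
  tb <- transmission_table(sim$geno, sim$family, best$marker, "dam")
  expect_equal(best$p, fisher_exact_2x2(tb))

  # markers with fewer than 15 called offspring vanish after QC
  noisy <- simulate_depth_noise(sim$geno, mean_depth = 2, seed = 42)
  flt <- qc_filter(noisy, sim$family$offspring$id, min_called = 15,
                   min_hom_depth = 0)
  res2 <- assoc_scan(flt, sim$family, mode = "allelic")
  called <- n_called(flt, sim$family$offspring$id)
  expect_true(all(called[res2$marker] >= 15))
  expect_true(all(n_called(noisy, sim$family$offspring$id)[
    setdiff(sim$geno$markers$id, flt$markers$id)] < 15))
})

test_that("allelic association is calibrated (conservative) under the null", {
  # sex driven by an untyped locus on LG13; LG5 markers are null
  lay <- two_lg_layout()
  set.seed(43)
  ps <- c()
  for (i in 1:40) {
    sim <- simulate_family(lay, sd_config_none("LG13", 2e6, 1), 24,
                           seed = sample.int(1e8, 1))
    res <- suppressMessages(assoc_scan(sim$geno, sim$family, mode = "allelic"))
    ps <- c(ps, res$p[grepl("^LG5", res$marker)])
  }
  expect_gt(length(ps), 200)
  expect_lte(mean(ps < 0.01), 0.013 + 2 * sqrt(0.01 / length(ps)))
})

test_that("the locus marker attains the minimum p on its linkage group", {
  lay <- two_lg_layout()
  xy <- sd_config_xy("LG5", round(0.05 * 38e6), 1)  # locus at marker LG5_m01
  set.seed(44)
  hits <- 0L; informative <- 0L
  for (i in 1:100) {
    sim <- simulate_family(lay, xy, 24, seed = sample.int(1e8, 1))
    if (is.null(transmission_table(sim$geno, sim$family, "LG5_m01", "sire")))
      next  # locus marker NI in this family: no power statement possible
    informative <- informative + 1L
    res <- assoc_scan(sim$geno, sim$family, mode = "transmission",
                      parent = "sire")
    lg5 <- res[grepl("^LG5", res$marker), ]
    best <- lg5$marker[order(lg5$p, -lg5$n_informative, lg5$marker)][1]
    hits <- hits + (best == "LG5_m01")
  }
  expect_gte(hits / informative, 0.95)
})

test_that("dominant screen flags sex-confined intermediate-frequency alleles", {
  res <- data.frame(
    marker = c("hit_y", "balanced", "rare", "hit_w"),
    p = c(1e-4, 0.5, 0.005, 1e-3),
    minor_freq_m = c(0.25, 0.5, 0.05, 0),
    minor_freq_f = c(0, 0.5, 0.05, 0.30))
  out <- dominant_screen(res)
  expect_equal(out$marker, c("hit_y", "hit_w"))
  expect_equal(out$sd_class, c("Y-like", "W-like"))
  expect_equal(out$carrier_sex, c("M", "F"))
})

test_that("sliding windows score mean -log10 p with exact counts", {
  res <- data.frame(marker = sprintf("m%02d", 1:12), p = 1,
                    neglog10p = 0, scaffold = "s", position = 1:12)
  w <- sliding_window(res, w = 10, step = 1)
  expect_equal(nrow(w), 3L)          # n - w + 1
  expect_equal(w$score, c(0, 0, 0))  # all p = 1

  res$p[1] <- 1e-6; res$neglog10p[1] <- 6
  w2 <- sliding_window(res, w = 10)
  expect_equal(w2$score[1], 0.6)     # one 6 among nine 0s
  # bounded by the window max
  expect_true(all(w2$score <= max(res$neglog10p)))

  w3 <- sliding_window(res, w = 10, stat = "frac_sig")
  expect_equal(w3$score[1], 0.1)

  expect_warning(w0 <- sliding_window(res[1:5, ], w = 10), "fewer than")
  expect_equal(nrow(w0), 0L)
})
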