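#' Analytic male fraction under a sex-determination model
#'
#' Enumerates the transmission of every modelled locus (a heterozygous
#' carrier transmits its allele with probability 1/2, a homozygous carrier
#' always) and composes [assign_sex()] over the resulting genotype
#' distribution, assuming loci segregate independently.  An XY sire alone
#' gives 1/2; an XY sire at one locus with a ZW dam at another gives 1/4,
#' the classic 1:3 male:female epistasis expectation; a W over a fixed
#' male background gives 1/2.
#'
#' @param model an [sd_model()] (penetrance is ignored: this is the
#'   genotypic expectation).
#' @return expected fraction of genotypic males.
#' @export
expected_male_fraction <- function(model) {
  loci <- model$loci
  if (!nrow(loci)) return(0)  # no alleles: default sex is female
  probs <- ifelse(loci$copies == 2L, 1, 0.5)
  pm <- 0
  for (mask in 0:(2^nrow(loci) - 1)) {
    has <- as.logical(bitwAnd(mask, 2^(seq_len(nrow(loci)) - 1)))
    p <- prod(ifelse(has, probs, 1 - probs))
    if (p == 0) next
    if (assign_sex(loci$allele[has]) == "M") pm <- pm + p
  }
  pm
}

# canonical benchmark genome: the LG5+LG14 fusion chromosome, the LG13
# candidate, and LG16 as an untyped background LG; SSR pairs clustered at
# the two candidate loci, emulating a replication-phase marker panel
bench_layout <- function() {
  genome_layout(
    data.frame(lg = c("LG5", "LG14", "LG13", "LG16"),
               length_bp = c(38e6, 25e6, 34e6, 28e6),
               length_morgans = c(0.9, 0.6, 0.8, 0.7)),
    fusions = list(c("LG5", "LG14")),
    marker_positions = data.frame(
      lg = c("LG5", "LG5", "LG13", "LG13"),
      position = c(1.9e6, 3.8e6, 1.7e6, 3.4e6)))
}

bench_models <- function(penetrance) {
  list("LG5-14 XY" = sd_config_xy("LG5", 1.9e6, penetrance),
       "LG13 ZW" = sd_config_zw("LG13", 1.7e6, "LG16", 14e6, penetrance),
       "unknown" = sd_config_none("LG16", 14e6, penetrance))
}

# the three transmission tests of a mapping-summary table: sire probed at
# both candidate regions, dam only where a W is plausible
bench_tests <- function() {
  data.frame(region = c("LG5-14", "LG13", "LG13"),
             parent = c("sire", "sire", "dam"))
}

bench_regions <- function(marker_lg) {
  list("LG5-14" = marker_lg$marker[marker_lg$lg == "LG5"],
       "LG13" = marker_lg$marker[marker_lg$lg == "LG13"])
}

#' Classification parameter-recovery benchmark
#'
#' Simulates families of the three canonical types (XY on the LG5-14
#' fusion, ZW on LG13, and sex driven by an untyped locus) in equal
#' expected proportions, classifies each with [classify_family()] under the
#' mapping-table test design, and scores the family labels against truth.
#'
#' A family counts as correct when [family_system_label()] reproduces the
#' configured system (or `unknown` for the untyped-locus type).  An
#' XY/ZW confusion is scored at the true locus region: the classifier
#' emitted the opposite system there and not the true one (coexisting
#' sire+dam signals, which real crosses do produce, are not confusions).
#'
#' @param n_families number of simulated families.
#' @param penetrance simulated penetrance.
#' @param n_range integer range of offspring counts per family.
#' @param seed integer seed.
#' @return list with `accuracy`, `confusions`, and the truth-by-label
#'   `table`.
#' @export
classification_benchmark <- function(n_families = 200, penetrance = 0.9,
                                     n_range = 16:36, seed = 1) {
  set.seed(seed)
  lay <- bench_layout(); mods <- bench_models(penetrance)
  tst <- bench_tests()
  truth <- pred <- character(n_families); conf <- 0L
  for (i in seq_len(n_families)) {
    tr <- sample(names(mods), 1)
    sim <- simulate_family(lay, mods[[tr]], sample(n_range, 1),
                           seed = sample.int(1e8, 1),
                           family_id = paste0("f", i))
    calls <- classify_family(sim$geno, sim$family,
                             bench_regions(sim$marker_lg), tests = tst)
    truth[i] <- tr
    pred[i] <- family_system_label(calls)
    if (tr != "unknown") {
      trg <- if (tr == "LG5-14 XY") "LG5-14" else "LG13"
      tsy <- if (tr == "LG5-14 XY") "XY" else "ZW"
      sys_here <- calls$system[calls$region == trg]
      if (!(tsy %in% sys_here) && any(c("XY", "ZW") %in% sys_here))
        conf <- conf + 1L
    }
  }
  list(accuracy = mean(truth == pred), confusions = conf,
       table = table(truth = truth, label = pred))
}

#' Penetrance-recovery benchmark
#'
#' Simulates XY families at a known penetrance, classifies them, and
#' averages the per-family penetrance estimates of the recovered XY calls.
#'
#' @param n_families number of simulated families.
#' @param true_penetrance simulated penetrance.
#' @param n_offspring offspring per family.
#' @param seed integer seed.
#' @return list with `mean_estimate`, `n_recovered`, `estimates`.
#' @export
penetrance_benchmark <- function(n_families = 50, true_penetrance = 0.88,
                                 n_offspring = 20, seed = 1) {
  set.seed(seed)
  lay <- bench_layout()
  xy <- sd_config_xy("LG5", 1.9e6, true_penetrance)
  est <- numeric()
  for (i in seq_len(n_families)) {
    sim <- simulate_family(lay, xy, n_offspring, seed = sample.int(1e8, 1),
                           family_id = paste0("f", i))
    calls <- classify_family(sim$geno, sim$family,
                             bench_regions(sim$marker_lg),
                             tests = bench_tests())
    hit <- calls[calls$region == "LG5-14" & calls$system == "XY", ]
    if (nrow(hit)) est <- c(est, hit$penetrance[1])
  }
  list(mean_estimate = mean(est), n_recovered = length(est), estimates = est)
}

#' Chromosome-fusion detection benchmark
#'
#' Simulates replicate two-family cohorts on a genome where two reference
#' LGs are fused into one 50 cM chromosome (with a third, unlinked LG as
#' negative control), runs [lg_pair_linkage()] and [detect_fusions()], and
#' reports sensitivity (fused pair declared at LOD > `lod_threshold`) and
#' the false-positive rate (any unfused pair declared).
#'
#' @param n_reps replicate cohorts.
#' @param n_families,n_offspring cohort composition.
#' @param lod_threshold LOD threshold for [detect_fusions()].
#' @param seed integer seed.
#' @return list with `sensitivity`, `false_positive_rate`, `max_lod_fused`
#'   (per replicate), `max_lod_null` (per replicate).
#' @export
fusion_benchmark <- function(n_reps = 50, n_families = 2, n_offspring = 24,
                             lod_threshold = 4, seed = 1) {
  set.seed(seed)
  lay <- genome_layout(
    data.frame(lg = c("LG8", "LG24", "LG16"),
               length_bp = c(30e6, 25e6, 28e6),
               length_morgans = c(0.25, 0.25, 0.5)),
    fusions = list(c("LG8", "LG24")))
  spec <- marker_spec(snp_per_lg = 0, ssr_per_lg = 4)
  hits <- fps <- logical(n_reps)
  lod_f <- lod_n <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sims <- lapply(seq_len(n_families), function(k)
      simulate_family(lay, sd_model(NULL, 1), n_offspring, spec,
                      seed = sample.int(1e8, 1),
                      family_id = sprintf("r%df%d", r, k),
                      sire_id = sprintf("r%ds%d", r, k),
                      dam_id = sprintf("r%dd%d", r, k)))
    lr <- lg_pair_linkage(lapply(sims, `[[`, "geno"),
                          lapply(sims, `[[`, "family"),
                          sims[[1]]$marker_lg)
    fused <- lr$lg_a %in% c("LG8", "LG24") & lr$lg_b %in% c("LG8", "LG24")
    lod_f[r] <- max(c(lr$lod[fused], 0))
    lod_n[r] <- max(c(lr$lod[!fused], 0))
    fus <- detect_fusions(lr, lod_threshold)
    hits[r] <- nrow(fus) > 0 && any(vapply(strsplit(fus$lgs, ","), function(g)
      setequal(g, c("LG8", "LG24")), TRUE))
    fps[r] <- lod_n[r] > lod_threshold
  }
  list(sensitivity = mean(hits), false_positive_rate = mean(fps),
       max_lod_fused = lod_f, max_lod_null = lod_n)
}

#' Scaffold order/orientation recovery benchmark
#'
#' Random scaffold tilings of a small genome are pushed through
#' [simulate_alignments()] and [anchor_scaffolds()], and each scaffold with
#' at least `min_windows` windows is scored for correct LG, correct
#' orientation, and correct rank order within its LG.  Scaffolds spanning a
#' fusion junction (whose true LG is ambiguous) are excluded from scoring.
#'
#' @param n_reps replicate layouts.
#' @param noise window misassignment fraction passed to
#'   [simulate_alignments()].
#' @param n_per_chrom scaffolds per chromosome.
#' @param window window size, bp.
#' @param min_windows scaffolds with fewer mapped windows are not scored.
#' @param seed integer seed.
#' @return list with `recovery` (fraction of scored scaffolds fully
#'   correct), `n_scored`, and `per_rep` recovery fractions.
#' @export
anchor_benchmark <- function(n_reps = 50, noise = 0, n_per_chrom = 5L,
                             window = 5000L, min_windows = 3L, seed = 1) {
  set.seed(seed)
  lay <- genome_layout(
    data.frame(lg = c("LG1", "LG2", "LG3"),
               length_bp = c(6e6, 5e6, 4e6),
               length_morgans = c(0.6, 0.5, 0.4)))
  chroms <- layout_chromosomes(lay)
  ok <- tot <- 0L; per <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sp <- make_scaffold_spec(lay, n_per_chrom, seed = sample.int(1e8, 1),
                             min_len = 12L * window)
    rec <- simulate_alignments(lay, sp, window, noise = noise,
                               seed = sample.int(1e8, 1))
    am <- anchor_scaffolds(rec, min_windows = min_windows)
    rok <- rtot <- 0L
    for (cid in names(chroms)) {
      d <- chroms[[cid]]
      ss <- sp[sp$chrom == cid, ]
      mid <- (ss$start + ss$end) / 2
      k <- findInterval(mid, d$offset_bp)
      truelg <- d$lg[k]
      spans <- findInterval(ss$start, d$offset_bp) != findInterval(ss$end - 1, d$offset_bp)
      for (g in unique(truelg)) {
        sel <- truelg == g & !spans
        if (!any(sel)) next
        true_order <- ss$scaffold[sel][order(ss$start[sel])]
        got <- am$scaffolds[match(ss$scaffold[sel], am$scaffolds$scaffold), ]
        nw <- vapply(ss$scaffold[sel], function(s)
          sum(rec$scaffold == s), 1L)
        for (j in seq_along(true_order)) {
          s <- ss$scaffold[sel][order(ss$start[sel])][j]
          if (nw[[s]] < min_windows) next
          rtot <- rtot + 1L
          row <- am$scaffolds[am$scaffolds$scaffold == s, ]
          if (!nrow(row) || row$lg != g) next
          peers <- am$scaffolds[am$scaffolds$lg == g &
                                  am$scaffolds$scaffold %in% true_order, ]
          got_order <- peers$scaffold[order(peers$order)]
          orient_true <- ss$orient[ss$scaffold == s]
          if (identical(which(got_order == s), j) &&
              row$orientation == orient_true)
            rok <- rok + 1L
        }
      }
    }
    ok <- ok + rok; tot <- tot + rtot
    per[r] <- if (rtot) rok / rtot else NA_real_
  }
  list(recovery = ok / tot, n_scored = tot, per_rep = per)
}
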