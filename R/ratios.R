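#' Family sex ratio
#'
#' Number of male offspring divided by the total number of offspring.
#'
#' @param males,females non-negative counts, not both zero.
#' @return ratio in `[0, 1]`.
#' @export
sex_ratio <- function(males, females) {
  if (any(males < 0) || any(females < 0)) stop("counts must be non-negative")
  if (any(males + females < 1)) stop("a family must have offspring")
  males / (males + females)
}

#' Chi-square test against a 1:1 sex ratio
#'
#' Pearson goodness-of-fit chi-square with one degree of freedom, expected
#' count (m + f)/2 per sex and no continuity correction.
#'
#' @param males,females pooled offspring counts.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
chisq_1to1 <- function(males, females) {
  if (males + females < 1) stop("need at least one offspring")
  ct <- stats::chisq.test(c(males, females), p = c(0.5, 0.5), correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Welch's unequal-variances t-test
#'
#' Two-sided Welch t-test between two groups of per-family sex ratios (or
#' any numeric summaries), with Welch-Satterthwaite degrees of freedom.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = length(group_a) + length(group_b) - 2,
                  p_value = 1))
    stop("zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = unname(tt$p.value))
}

#' Per-system sex-ratio summary
#'
#' Pools male/female counts by inferred system, tests each pooled count
#' against 1:1, and runs pairwise Welch t-tests on the per-family ratios.
#'
#' @param families data.frame with columns `males`, `females` and `system`
#'   (e.g. [aburtoni_families()] or a [classify_family()] summary).
#' @return list with `pooled` (per-system counts, ratio, chi2, p) and
#'   `pairwise` (Welch tests between systems with >= 2 families).
#' @export
ratio_summary <- function(families) {
  pooled <- do.call(rbind, lapply(split(families, families$system), function(d) {
    ct <- chisq_1to1(sum(d$males), sum(d$females))
    data.frame(system = d$system[1], n_families = nrow(d),
               males = sum(d$males), females = sum(d$females),
               ratio = sex_ratio(sum(d$males), sum(d$females)),
               chi2 = ct$chi2, p_value = ct$p_value)
  }))
  rownames(pooled) <- NULL
  sys <- pooled$system[pooled$n_families >= 2]
  pairs <- if (length(sys) >= 2) utils::combn(sys, 2, simplify = FALSE) else list()
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    ra <- with(families[families$system == pr[1], ], sex_ratio(males, females))
    rb <- with(families[families$system == pr[2], ], sex_ratio(males, females))
    wt <- welch_t(ra, rb)
    data.frame(system_a = pr[1], system_b = pr[2], t = wt$t, df = wt$df,
               p_value = wt$p_value)
  }))
  list(pooled = pooled, pairwise = pairwise)
}

#' Reference crossing families for Astatotilapia burtoni
#'
#' Per-family offspring sex counts, per-parent marker-association p-values
#' (sire alleles probing Y linkage at the LG5-14 and LG13 loci, dam alleles
#' probing W linkage at LG13) and the inferred sex-determination system for
#' the 27 A. burtoni crosses that established polygenic sex determination
#' in the species: 8 LG13-ZW families, 10 LG5-14-XY families, a handful of
#' putative LG13-XY families, and families with no detected association.
#' `NA` marks markers that were not informative (NI) in that family.
#'
#' @return data.frame with columns `family`, `sire`, `dam`, `males`,
#'   `females`, `ratio`, `p_lg514_Y`, `p_lg13_Y`, `p_lg13_W`, `system`.
#' @export
aburtoni_families <- function() {
  d <- utils::read.table(header = TRUE, text = '
family sire dam males females p_lg514_Y p_lg13_Y p_lg13_W system
RAD1   s1   d1   12 12  0.6843 NA     0.0001 "LG13 ZW"
RAD2   s2   d2    9  8  0.0023 0.6199 1      "LG5-14 XY"
F1     s1   d1   10 36  0.1639 NA     0.0012 "LG13 ZW"
F2     s3   d3    8  8  0.0087 NA     0.0001 "LG13 ZW"
F3     s3   d3    9  8  0.3469 NA     0.0152 "LG13 ZW"
F4     s4   d4    6 26  NA     NA     0.0192 "LG13 ZW"
F5     s5   d5    4  6  1      0.5714 0.0048 "LG13 ZW"
F6     s6   d6    4 10  0.2208 1      0.015  "LG13 ZW"
F7     s6   d7   10  9  0.1534 NA     0.009  "LG13 ZW"
F8     s7   d8    2 13  1      0.0128 NA     "LG13 XY"
F9     s7   d9   16 22  0.72   0.0001 0.752  "LG13 XY"
F10    s8   d10  12 14  0.0001 0.2177 1      "LG5-14 XY"
F11    s8   d11  12 10  0.003  0.0092 0.6914 "LG5-14 XY"
F12    s8   d12  15 11  0.0001 0.4283 0.4279 "LG5-14 XY"
F13    s8   d13  12  7  0.0002 0.3261 0.3498 "LG5-14 XY"
F14    s8   d14   4  2  0.0667 0.4    1      "LG5-14 XY"
F15    s9   d15  12 10  0.0015 0.3246 0.1312 "LG5-14 XY"
F16    s9   d16  13  8  0.0237 NA     0.2031 "LG5-14 XY"
F17    s9   d17  15  8  0.0083 0.2213 NA     "LG5-14 XY"
F18    s10  d18  11  5  0.0256 0.5962 1      "LG5-14 XY"
F19    s11  d19   5  4  0.444  0.0079 NA     "LG13 XY + LG5-14 XY"
F20    s12  d20   9 11  1      1      0.1789 "Unknown"
F21    s6   d21  12 26  0.6792 0.2305 NA     "Unknown"
F22    s13  d22   7  9  0.3024 0.1262 0.3147 "Unknown"
F23    s13  d23  14 17  1      1      0.4809 "Unknown"
F24    s13  d24  20 23  0.3652 0.7619 0.0755 "Unknown"
F25    s13  d25  22 20  0.3783 0.0414 1      "Unknown"
')
  d$ratio <- sex_ratio(d$males, d$females)
  d[c("family", "sire", "dam", "males", "females", "ratio",
      "p_lg514_Y", "p_lg13_Y", "p_lg13_W", "system")]
}
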