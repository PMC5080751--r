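#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by hypergeometric enumeration with the minimum-likelihood
#' (point-probability) two-sided rule: with margins fixed, the p-value is
#' the sum of the probabilities of all tables whose point probability does
#' not exceed that of the observed table (within a relative tolerance of
#' 1e-7), the convention used by common genetics association tools.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2, 2))) stop("table must be 2x2")
  if (any(tb < 0)) stop("counts must be non-negative")
  if (sum(tb) == 0) {
    warning("all-zero table; p = 1")
    return(1)
  }
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ]); c1 <- sum(tb[, 1])
  k <- max(0, c1 - r2):min(r1, c1)   # support of cell (1,1)
  d <- stats::dhyper(k, r1, r2, c1)
  d_obs <- stats::dhyper(tb[1, 1], r1, r2, c1)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

# deduce which allele `parent` transmitted to one offspring, given the other
# parent's genotype; NA when not deducible (ambiguous or missing data)
deduce_transmitted <- function(par_g, other_g, off_g) {
  if (anyNA(par_g) || anyNA(off_g)) return(NA_character_)
  cand <- unique(par_g)
  ok <- vapply(cand, function(a) {
    if (!a %in% off_g) return(FALSE)
    b <- if (off_g[1] == a) off_g[2] else off_g[1]
    if (anyNA(other_g)) TRUE else b %in% other_g
  }, TRUE)
  # homozygous offspring: allele could satisfy both "slots"; recheck a/a case
  if (off_g[1] == off_g[2]) ok <- cand == off_g[1] & ok
  cand <- cand[ok]
  if (length(cand) == 1) cand else NA_character_
}

# transmitted alleles of `parent` for all offspring at one marker.
# When both parents are heterozygous for the same two alleles the parental
# origins are fully confounded (only double-homozygote offspring are
# deducible, and for those both parents transmitted the same allele), so
# the marker is treated as uninformative for parent-specific transmission.
transmitted_alleles <- function(gm, family, marker, parent = c("sire", "dam")) {
  parent <- match.arg(parent)
  pid <- if (parent == "sire") family$sire_id else family$dam_id
  oid <- if (parent == "sire") family$dam_id else family$sire_id
  par_g <- geno_call(gm, pid, marker)
  other_g <- geno_call(gm, oid, marker)
  confounded <- !anyNA(par_g) && !anyNA(other_g) &&
    par_g[1] != par_g[2] && setequal(par_g, other_g)
  tr <- if (confounded) rep(NA_character_, nrow(family$offspring))
        else vapply(family$offspring$id, function(o)
          deduce_transmitted(par_g, other_g, geno_call(gm, o, marker)),
          NA_character_)
  data.frame(id = family$offspring$id, sex = family$offspring$sex,
             allele = unname(tr))
}

#' Allele-count-by-sex table for a biallelic marker
#'
#' Counts the two alleles (two per called individual) of all offspring split
#' by phenotypic sex; missing individuals are excluded.  This is the
#' allelic association model of standard case/control genotype tools.
#'
#' @param gm a [geno_matrix()].
#' @param marker marker id (must be biallelic among the counted calls).
#' @param offspring data.frame with columns `id`, `sex`.
#' @return 2x2 integer matrix (alleles x sex `M`,`F`), or `NULL` with a
#'   message when the marker is not biallelic.
#' @export
allelic_table <- function(gm, marker, offspring) {
  a <- c(gm$a1[offspring$id, marker], gm$a2[offspring$id, marker])
  sex <- rep(offspring$sex, 2)
  keep <- !is.na(a)
  alleles <- sort(unique(a[keep]))
  if (length(alleles) > 2) {
    message("marker ", marker, " is multi-allelic; skipped by allelic_table")
    return(NULL)
  }
  if (length(alleles) == 0) return(NULL)
  if (length(alleles) == 1) alleles <- c(alleles, paste0(alleles, "'"))
  tb <- matrix(0L, 2, 2, dimnames = list(alleles, c("M", "F")))
  tt <- table(factor(a[keep], alleles), factor(sex[keep], c("M", "F")))
  tb[rownames(tt), colnames(tt)] <- tt
  tb
}

#' Transmitted-allele-by-sex table for one parent
#'
#' For each offspring whose transmitted allele from the tested parent is
#' unambiguous (parent heterozygous, transmission deducible from the
#' offspring and other-parent genotypes), tallies transmitted allele against
#' offspring sex.  Testing the sire probes Y-type associations; testing the
#' dam probes W-type associations.
#'
#' @param gm a [geno_matrix()].
#' @param family a [family_ped()].
#' @param marker marker id.
#' @param parent `"sire"` or `"dam"`.
#' @param min_informative minimum deducible offspring; below it the marker
#'   is not informative (NI).
#' @return 2x2 integer matrix (parent alleles x sex), or `NULL` when the
#'   marker is not informative for that parent.
#' @export
transmission_table <- function(gm, family, marker, parent = c("sire", "dam"),
                               min_informative = 5L) {
  parent <- match.arg(parent)
  pid <- if (parent == "sire") family$sire_id else family$dam_id
  par_g <- geno_call(gm, pid, marker)
  if (anyNA(par_g) || par_g[1] == par_g[2]) return(NULL)
  tr <- transmitted_alleles(gm, family, marker, parent)
  tr <- tr[!is.na(tr$allele), ]
  if (nrow(tr) < min_informative) return(NULL)
  tb <- table(factor(tr$allele, sort(unique(par_g))),
              factor(tr$sex, c("M", "F")))
  matrix(as.integer(tb), 2, 2, dimnames = dimnames(tb))
}

#' Genome-wide marker-sex association scan
#'
#' Runs one exact test per applicable marker: in `allelic` mode a 2x2
#' allele-by-sex table over offspring ([allelic_table()]); in
#' `transmission` mode a transmitted-allele-by-sex table for the chosen
#' parent ([transmission_table()]).  Markers failing the mode's
#' preconditions (multi-allelic in allelic mode, uninformative in
#' transmission mode) are skipped and counted in the `n_skipped` attribute.
#'
#' @param gm a QC-filtered [geno_matrix()].
#' @param family a [family_ped()].
#' @param mode `"allelic"` or `"transmission"`.
#' @param parent tested parent for transmission mode.
#' @param anchor_map optional [order_orient()] result; when given, results
#'   carry anchored coordinates and are ordered by them.
#' @param min_informative see [transmission_table()].
#' @return data.frame with one row per tested marker: `marker`, `scaffold`,
#'   `position`, `lg`, `anchored_pos`, counts `n11..n22`, `p`, `neglog10p`,
#'   minor-allele frequency per sex and the minor allele label.
#' @export
assoc_scan <- function(gm, family, mode = c("allelic", "transmission"),
                       parent = "sire", anchor_map = NULL,
                       min_informative = 5L) {
  mode <- match.arg(mode)
  off <- family$offspring
  rows <- lapply(gm$markers$id, function(mk) {
    tb <- if (mode == "allelic") allelic_table(gm, mk, off)
          else transmission_table(gm, family, mk, parent, min_informative)
    if (is.null(tb)) return(NULL)
    p <- fisher_exact_2x2(tb)
    colM <- tb[, "M"]; colF <- tb[, "F"]
    fM <- if (sum(colM)) colM / sum(colM) else c(0, 0)
    fF <- if (sum(colF)) colF / sum(colF) else c(0, 0)
    minor <- which.min(rowSums(tb))
    data.frame(marker = mk, n11 = tb[1, 1], n12 = tb[1, 2],
               n21 = tb[2, 1], n22 = tb[2, 2], p = p,
               neglog10p = -log10(p),
               minor_allele = rownames(tb)[minor],
               minor_freq_m = unname(fM[minor]),
               minor_freq_f = unname(fF[minor]),
               n_informative = sum(tb))
  })
  skipped <- sum(vapply(rows, is.null, TRUE))
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame()
  else {
    mi <- match(res$marker, gm$markers$id)
    res <- cbind(res, scaffold = gm$markers$scaffold[mi],
                 position = gm$markers$position[mi])
    res$mode <- mode
    if (!is.null(anchor_map)) {
      lift <- liftover(data.frame(scaffold = res$scaffold,
                                  position = res$position), anchor_map)
      res$lg <- lift$lg
      res$anchored_pos <- lift$anchored_pos
      res <- res[order(res$lg, res$anchored_pos, res$marker), ]
    }
  }
  attr(res, "n_skipped") <- skipped
  res
}

#' Dominant-model screen of association results
#'
#' Keeps markers with a significant sex association whose minor allele sits
#' at intermediate frequency in one sex and is (near-)absent in the other --
#' the footprint of a heterozygous dominant sex-determination allele, whose
#' expected allelic frequency among carriers' alleles is 0.25.  A
#' male-confined allele is Y-like, a female-confined allele W-like.
#'
#' @param results an [assoc_scan()] result (allelic mode).
#' @param p_thresh significance cutoff (default 0.01).
#' @param freq_window inclusive frequency window defining "intermediate".
#' @param absent_eps maximum frequency tolerated in the other sex.
#' @return subset of `results` with an added `sd_class` column
#'   (`"Y-like"`/`"W-like"`) and `carrier_sex`.
#' @export
dominant_screen <- function(results, p_thresh = 0.01,
                            freq_window = c(0.15, 0.60), absent_eps = 0) {
  inwin <- function(x) x >= freq_window[1] & x <= freq_window[2]
  y_like <- inwin(results$minor_freq_m) & results$minor_freq_f <= absent_eps
  w_like <- inwin(results$minor_freq_f) & results$minor_freq_m <= absent_eps
  keep <- results$p < p_thresh & (y_like | w_like)
  out <- results[keep, , drop = FALSE]
  out$sd_class <- ifelse(y_like[keep], "Y-like", "W-like")
  out$carrier_sex <- ifelse(y_like[keep], "M", "F")
  out
}

#' Sliding-window summary of an association scan
#'
#' Windows of `w` consecutive markers advanced by `step`, in the order the
#' results arrive (anchored order when the scan was anchored).  The default
#' score is the mean of -log10 p over the window; `stat = "frac_sig"`
#' scores the fraction of markers with p below `sig_thresh` instead (the
#' density of associated SNPs).
#'
#' @param results an [assoc_scan()] result, already ordered.
#' @param w window size in markers (default 10).
#' @param step step size in markers (default 1).
#' @param stat `"mean"` or `"frac_sig"`.
#' @param sig_thresh significance cutoff for `frac_sig`.
#' @return data.frame with `window`, `start_marker`, `end_marker`,
#'   `scaffold`, `span_start`, `span_end`, `score`; empty (with a warning)
#'   when fewer than `w` results are available.
#' @export
sliding_window <- function(results, w = 10L, step = 1L,
                           stat = c("mean", "frac_sig"), sig_thresh = 0.01) {
  stat <- match.arg(stat)
  n <- nrow(results)
  if (n < w) {
    warning("fewer than w = ", w, " markers; no windows")
    return(data.frame())
  }
  starts <- seq(1L, n - w + 1L, by = step)
  do.call(rbind, lapply(seq_along(starts), function(i) {
    ix <- starts[i]:(starts[i] + w - 1L)
    score <- if (stat == "mean") mean(results$neglog10p[ix])
             else mean(results$p[ix] < sig_thresh)
    data.frame(window = i,
               start_marker = results$marker[ix[1]],
               end_marker = results$marker[ix[w]],
               scaffold = results$scaffold[ix[1]],
               span_start = min(results$position[ix]),
               span_end = max(results$position[ix]),
               score = score)
  }))
}

#' Plot an association scan
#'
#' Manhattan-style plot of -log10 p along anchored (or input) marker order,
#' optionally overlaid with a sliding-window line.
#'
#' @param results an [assoc_scan()] result.
#' @param windows optional [sliding_window()] result.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `results`.
#' @export
plot_assoc <- function(results, windows = NULL, ...) {
  x <- if (!is.null(results$anchored_pos)) results$anchored_pos
       else seq_len(nrow(results))
  graphics::plot(x, results$neglog10p, pch = 16, cex = 0.6,
                 xlab = "anchored position", ylab = "-log10 p", ...)
  if (!is.null(windows) && nrow(windows)) {
    ix <- match(windows$start_marker, results$marker)
    graphics::lines(x[ix], windows$score, col = "red3", lwd = 2)
  }
  invisible(results)
}
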