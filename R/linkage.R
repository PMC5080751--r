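#' Count informative meioses and recombinants between two markers
#'
#' Pseudo-testcross two-point counting: for every offspring whose
#' transmitted allele from `parent` is deducible at both markers, the
#' transmitted-allele pairing is compared with the majority pairing; since
#' parental phase is unknown, the recombinant count is the minimum mismatch
#' count over the two possible phases.
#'
#' @param gm a [geno_matrix()].
#' @param family a [family_ped()].
#' @param marker_a,marker_b marker ids.
#' @param parent `"sire"` or `"dam"`.
#' @return list with `N` (informative meioses) and `R` (recombinants), or
#'   `NULL` when the pair is not informative (parent homozygous/missing at
#'   either marker, or no doubly-deducible offspring).
#' @export
count_recombinants <- function(gm, family, marker_a, marker_b,
                               parent = c("sire", "dam")) {
  parent <- match.arg(parent)
  pid <- if (parent == "sire") family$sire_id else family$dam_id
  ga <- geno_call(gm, pid, marker_a); gb <- geno_call(gm, pid, marker_b)
  if (anyNA(ga) || anyNA(gb) || ga[1] == ga[2] || gb[1] == gb[2])
    return(NULL)
  ta <- transmitted_alleles(gm, family, marker_a, parent)
  tb <- transmitted_alleles(gm, family, marker_b, parent)
  ok <- !is.na(ta$allele) & !is.na(tb$allele)
  if (!any(ok)) return(NULL)
  # phase 1: (ga[1] with gb[1]); mismatches under it are recombinants
  mm <- sum((ta$allele[ok] == ga[1]) != (tb$allele[ok] == gb[1]))
  N <- sum(ok)
  list(N = N, R = min(mm, N - mm))
}

#' Two-point recombination fraction and LOD score
#'
#' Maximum-likelihood recombination fraction `rf = min(R, N - R) / N` and
#' the LOD score `log10 L(rf) / L(0.5)` of the binomial linkage likelihood;
#' the `rf = 0` limit gives `N * log10(2)`.
#'
#' @param N informative meioses (>= 1).
#' @param R recombinants (0 <= R <= N).
#' @return list with `rf` in `[0, 0.5]` and `lod` >= 0.
#' @export
two_point_lod <- function(N, R) {
  if (N < 1) stop("N must be >= 1")
  if (R < 0 || R > N) stop("R must lie in [0, N]")
  Rt <- min(R, N - R)
  rf <- Rt / N
  lod <- if (Rt == 0) N * log10(2)
         else Rt * log10(rf) + (N - Rt) * log10(1 - rf) - N * log10(0.5)
  list(rf = rf, lod = max(0, lod))
}

#' Linkage between reference linkage-group pairs
#'
#' For every pair of reference LGs, takes the maximum two-point LOD over
#' informative cross-LG marker pairs, summing per-family (N, R) counts
#' across families (and both parents) before the LOD computation.  Markers
#' from two LGs that sit on one fused physical chromosome co-segregate, so
#' the fused pair stands out with a high LOD while unlinked pairs stay near
#' zero.
#'
#' @param gm a [geno_matrix()] (or list of them, parallel to `families`).
#' @param families list of [family_ped()] objects.
#' @param marker_lg data.frame `marker`, `lg` assigning each marker to a
#'   reference LG (e.g. from anchoring, or the simulator's truth).
#' @param parents parents whose transmissions are counted.
#' @return data.frame with one row per LG pair carrying at least one
#'   informative marker pair: `lg_a`, `lg_b`, `marker_a`, `marker_b` (the
#'   best pair), `N`, `R`, `rf`, `lod`, `continuous_haplotype` (some family
#'   shows zero recombinants for the best pair).
#' @export
lg_pair_linkage <- function(gm, families, marker_lg,
                            parents = c("sire", "dam")) {
  if (inherits(gm, "geno_matrix")) gm <- rep(list(gm), length(families))
  lgs <- sort(unique(marker_lg$lg))
  if (length(lgs) < 2) return(data.frame())
  out <- list()
  for (i in seq_along(lgs)) for (j in seq_along(lgs)) {
    if (j <= i) next
    ma <- marker_lg$marker[marker_lg$lg == lgs[i]]
    mb <- marker_lg$marker[marker_lg$lg == lgs[j]]
    best <- NULL
    for (a in ma) for (b in mb) {
      N <- 0L; R <- 0L; zero_fam <- FALSE
      for (k in seq_along(families)) {
        for (par in parents) {
          cr <- count_recombinants(gm[[k]], families[[k]], a, b, par)
          if (is.null(cr)) next
          N <- N + cr$N; R <- R + cr$R
          if (cr$R == 0L && cr$N > 0L) zero_fam <- TRUE
        }
      }
      if (N == 0L) next
      tp <- two_point_lod(N, R)
      if (is.null(best) || tp$lod > best$lod)
        best <- data.frame(lg_a = lgs[i], lg_b = lgs[j], marker_a = a,
                           marker_b = b, N = N, R = R, rf = tp$rf,
                           lod = tp$lod, continuous_haplotype = zero_fam)
    }
    if (!is.null(best)) out[[length(out) + 1]] <- best
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Detect chromosome fusions from LG-pair linkage
#'
#' Declares a fusion for every LG pair whose maximum cross-LG LOD exceeds
#' the threshold, and merges transitively linked pairs into one multi-LG
#' group whose name joins the LG numbers (an A-B and B-C signal yields the
#' single group A-B-C).
#'
#' @param results a [lg_pair_linkage()] table.
#' @param lod_threshold minimum LOD to declare linkage (default 4).
#' @return data.frame with `fusion` (joined name), `lgs` (comma-separated
#'   members), `max_lod`, `continuous_haplotype`.
#' @export
detect_fusions <- function(results, lod_threshold = 4) {
  if (!nrow(results)) return(data.frame())
  hits <- results[results$lod > lod_threshold, , drop = FALSE]
  if (!nrow(hits)) return(data.frame())
  # union-find over LGs
  parent <- stats::setNames(unique(c(hits$lg_a, hits$lg_b)),
                            unique(c(hits$lg_a, hits$lg_b)))
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(hits)))
    parent[[find(hits$lg_a[k])]] <- find(hits$lg_b[k])
  roots <- vapply(names(parent), find, "")
  groups <- split(names(parent), roots)
  out <- lapply(groups, function(g) {
    sel <- hits$lg_a %in% g & hits$lg_b %in% g
    g <- sort(g)
    data.frame(fusion = paste0("LG", paste(gsub("^LG", "", g), collapse = "-")),
               lgs = paste(g, collapse = ","),
               max_lod = max(hits$lod[sel]),
               continuous_haplotype = any(hits$continuous_haplotype[sel]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$fusion), , drop = FALSE]
}
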