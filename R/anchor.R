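#' Filter window alignments
#'
#' Keeps windows mapping to a single reference coordinate (`unique`), with
#' fewer than 5 suboptimal hits, and with at least 90 % sequence identity
#' (the 0.90 boundary is inclusive: only windows *below* 90 % are removed).
#'
#' @param records an [alignment_records()] table.
#' @param min_identity minimum identity retained (inclusive).
#' @param max_suboptimal maximum suboptimal-hit count retained (inclusive).
#' @param require_unique drop non-unique mappings.
#' @return filtered [alignment_records()] table.
#' @export
filter_alignments <- function(records, min_identity = 0.90,
                              max_suboptimal = 4L, require_unique = TRUE) {
  keep <- records$identity >= min_identity &
    records$n_suboptimal <= max_suboptimal &
    (!require_unique | records$unique)
  records[keep, , drop = FALSE]
}

#' Assign scaffolds to reference linkage groups by window vote
#'
#' A scaffold is placed on the LG that receives more than `min_vote` of its
#' mapped windows, provided at least `min_windows` windows mapped; anything
#' else is unplaced.  An unplaced scaffold whose windows split
#' substantially between two LGs is flagged as a fusion-junction candidate.
#'
#' @param records filtered [alignment_records()].
#' @param min_vote vote fraction required for placement (exclusive).
#' @param min_windows minimum mapped windows.
#' @param junction_share second-LG share above which an unplaced scaffold
#'   is flagged as a junction candidate.
#' @return data.frame with `scaffold`, `lg` (`NA` if unplaced),
#'   `n_windows`, `vote`, `junction_candidate`.
#' @export
assign_scaffold_lg <- function(records, min_vote = 0.60, min_windows = 3L,
                               junction_share = 0.20) {
  out <- lapply(split(records, records$scaffold), function(d) {
    tab <- sort(table(d$target_lg), decreasing = TRUE)
    share <- as.numeric(tab) / nrow(d)
    placed <- nrow(d) >= min_windows && share[1] > min_vote
    data.frame(scaffold = d$scaffold[1],
               lg = if (placed) names(tab)[1] else NA_character_,
               n_windows = nrow(d), vote = share[1],
               junction_candidate = !placed && nrow(d) >= min_windows &&
                 length(tab) >= 2 && share[2] >= junction_share)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Order and orient placed scaffolds along the reference
#'
#' Scaffolds are ordered within each LG by the median reference position of
#' their windows (ties broken by minimum position, then scaffold id) and
#' oriented by the sign of the Spearman rank correlation between window
#' index and reference position; scaffolds whose orientation cannot be
#' determined (single window or zero correlation) get `"+"` with an
#' ambiguity flag.  Pseudo-chromosome offsets accumulate scaffold lengths
#' plus a fixed inter-scaffold gap; they serve ordering, not physical
#' distance.
#'
#' @param records filtered [alignment_records()] of the placed scaffolds.
#' @param assignment an [assign_scaffold_lg()] table.
#' @param scaffold_lengths optional named lengths (bp); defaults to each
#'   scaffold's maximum window end.
#' @param gap inter-scaffold gap in the pseudo-coordinates (bp).
#' @return object of class `anchor_map`: list with `scaffolds` (data.frame
#'   `scaffold`, `lg`, `order`, `orientation`, `offset`, `length`,
#'   `n_windows`, `vote`, `ambiguous_orient`) and `unplaced` (ids).
#' @export
order_orient <- function(records, assignment, scaffold_lengths = NULL,
                         gap = 1000L) {
  placed <- assignment[!is.na(assignment$lg), , drop = FALSE]
  rec <- records[records$scaffold %in% placed$scaffold, , drop = FALSE]
  # only windows agreeing with the assigned LG inform order/orientation
  rec <- rec[rec$target_lg == placed$lg[match(rec$scaffold, placed$scaffold)], ,
             drop = FALSE]
  per <- lapply(split(rec, rec$scaffold), function(d) {
    d <- d[order(d$window_start), ]
    len <- if (!is.null(scaffold_lengths)) scaffold_lengths[[d$scaffold[1]]]
           else max(d$window_end)
    rho <- if (nrow(d) >= 2 && stats::sd(d$target_pos) > 0)
      stats::cor(d$window_start, d$target_pos, method = "spearman") else 0
    data.frame(scaffold = d$scaffold[1], lg = d$target_lg[1],
               median_pos = stats::median(d$target_pos),
               min_pos = min(d$target_pos),
               orientation = if (rho < 0) "-" else "+",
               ambiguous_orient = rho == 0, length = len)
  })
  per <- do.call(rbind, per)
  per <- per[order(per$lg, per$median_pos, per$min_pos, per$scaffold), ]
  per$order <- stats::ave(seq_len(nrow(per)), per$lg, FUN = seq_along)
  per$offset <- stats::ave(per$length, per$lg,
                           FUN = function(x) cumsum(c(0, utils::head(x, -1))) +
                             gap * (seq_along(x) - 1))
  sc <- merge(per, assignment[c("scaffold", "n_windows", "vote")],
              by = "scaffold")
  sc <- sc[order(sc$lg, sc$order),
           c("scaffold", "lg", "order", "orientation", "offset", "length",
             "n_windows", "vote", "ambiguous_orient")]
  rownames(sc) <- NULL
  structure(list(scaffolds = sc,
                 unplaced = assignment$scaffold[is.na(assignment$lg)],
                 gap = gap),
            class = "anchor_map")
}

#' @export
print.anchor_map <- function(x, ...) {
  cat("anchor_map:", nrow(x$scaffolds), "scaffolds placed on",
      length(unique(x$scaffolds$lg)), "LGs;",
      length(x$unplaced), "unplaced\n")
  invisible(x)
}

#' Build an anchor map from raw alignments
#'
#' Convenience composition: [filter_alignments()], [assign_scaffold_lg()],
#' [order_orient()].
#'
#' @param records an [alignment_records()] table.
#' @inheritParams filter_alignments
#' @inheritParams assign_scaffold_lg
#' @inheritParams order_orient
#' @return an `anchor_map`.
#' @export
anchor_scaffolds <- function(records, min_identity = 0.90,
                             max_suboptimal = 4L, require_unique = TRUE,
                             min_vote = 0.60, min_windows = 3L,
                             scaffold_lengths = NULL, gap = 1000L) {
  flt <- filter_alignments(records, min_identity, max_suboptimal,
                           require_unique)
  asg <- assign_scaffold_lg(flt, min_vote, min_windows)
  order_orient(flt, asg, scaffold_lengths, gap)
}

#' Lift marker coordinates onto pseudo-chromosomes
#'
#' A marker on a `+` scaffold maps to `offset + position`; on a `-`
#' scaffold to `offset + (length - 1 - position)`.  Markers on unplaced or
#' unknown scaffolds get `NA` coordinates.
#'
#' @param markers data.frame with columns `scaffold`, `position`.
#' @param map an `anchor_map` from [order_orient()].
#' @return data.frame `scaffold`, `position`, `lg`, `anchored_pos`.
#' @export
liftover <- function(markers, map) {
  sc <- map$scaffolds
  i <- match(markers$scaffold, sc$scaffold)
  bad <- !is.na(i) & markers$position >= sc$length[i]
  if (any(bad))
    stop("marker position beyond scaffold length: ",
         markers$scaffold[bad][1], ":", markers$position[bad][1])
  pos <- ifelse(sc$orientation[i] == "+",
                sc$offset[i] + markers$position,
                sc$offset[i] + sc$length[i] - 1 - markers$position)
  data.frame(scaffold = markers$scaffold, position = markers$position,
             lg = sc$lg[i], anchored_pos = pos)
}

#' Map pseudo-chromosome coordinates back to scaffold coordinates
#'
#' Inverse of [liftover()] for positions falling inside a placed scaffold.
#'
#' @param lifted data.frame with columns `lg`, `anchored_pos`.
#' @param map an `anchor_map`.
#' @return data.frame `scaffold`, `position`.
#' @export
liftover_inverse <- function(lifted, map) {
  sc <- map$scaffolds
  out <- lapply(seq_len(nrow(lifted)), function(k) {
    cand <- sc[sc$lg == lifted$lg[k] &
                 sc$offset <= lifted$anchored_pos[k] &
                 lifted$anchored_pos[k] < sc$offset + sc$length, , drop = FALSE]
    if (!nrow(cand))
      return(data.frame(scaffold = NA_character_, position = NA_real_))
    rel <- lifted$anchored_pos[k] - cand$offset[1]
    pos <- if (cand$orientation[1] == "+") rel else cand$length[1] - 1 - rel
    data.frame(scaffold = cand$scaffold[1], position = pos)
  })
  do.call(rbind, out)
}

#' Export an anchor map as AGP v2.1
#'
#' Writes the pseudo-chromosome layout (scaffold components separated by
#' fixed gaps) in AGP 2.1 format.
#'
#' @param map an `anchor_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(map, path) {
  lines <- c("##agp-version\t2.1")
  for (lg in unique(map$scaffolds$lg)) {
    d <- map$scaffolds[map$scaffolds$lg == lg, ]
    part <- 0L
    for (k in seq_len(nrow(d))) {
      part <- part + 1L
      lines <- c(lines, sprintf("%s\t%.0f\t%.0f\t%d\tW\t%s\t1\t%.0f\t%s",
                                lg, d$offset[k] + 1, d$offset[k] + d$length[k],
                                part, d$scaffold[k], d$length[k],
                                d$orientation[k]))
      if (k < nrow(d)) {
        part <- part + 1L
        lines <- c(lines, sprintf("%s\t%.0f\t%.0f\t%d\tN\t%d\tscaffold\tyes\talign_genus",
                                  lg, d$offset[k] + d$length[k] + 1,
                                  d$offset[k + 1], part, map$gap))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
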