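#' Parse window alignments from PAF
#'
#' Reads minimap2/bwa-style PAF produced by aligning non-overlapping sequence
#' windows of assembly scaffolds to an anchored reference.  The query name is
#' taken as the scaffold id and query start/end as the window interval;
#' target name/start give the reference linkage group and position.
#'
#' Identity is `NM`-corrected when an `NM:i` tag is present
#' (`1 - NM / block_length`), else the ratio of column 10 (matching bases) to
#' column 11 (alignment block length).  The suboptimal-hit count is taken
#' from an `s2:i` tag when present (count proxy: a recorded secondary score
#' counts as one suboptimal hit per unit reported), defaulting to 0, and the
#' uniqueness flag is mapping quality > 0.  Both conventions are
#' aligner-specific; the columns can be overwritten downstream.
#'
#' @param path PAF file path.
#' @return data.frame of class `alignment_records` with columns `scaffold`,
#'   `window_start`, `window_end`, `target_lg`, `target_pos`, `identity`,
#'   `n_suboptimal`, `unique`.
#' @export
parse_alignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(alignment_records())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 12))
    stop("format error at line ", which(nf < 12)[1],
         ": PAF requires 12 mandatory columns")
  grab <- function(i) vapply(fields, `[[`, "", i)
  tag_int <- function(tag) vapply(fields, function(x) {
    hit <- grep(paste0("^", tag, ":i:"), x, value = TRUE)
    if (length(hit)) as.integer(sub(".*:", "", hit[1])) else NA_integer_
  }, 1L)
  matches <- as.numeric(grab(10))
  blocklen <- as.numeric(grab(11))
  mapq <- as.integer(grab(12))
  nm <- tag_int("NM")
  s2 <- tag_int("s2")
  identity <- ifelse(is.na(nm), matches / blocklen, 1 - nm / blocklen)
  alignment_records(
    scaffold = grab(1),
    window_start = as.integer(grab(3)),
    window_end = as.integer(grab(4)),
    target_lg = grab(6),
    target_pos = as.numeric(grab(8)),
    identity = identity,
    n_suboptimal = ifelse(is.na(s2), 0L, s2),
    unique = mapq > 0L)
}

#' Construct an alignment-record table
#'
#' @param scaffold,window_start,window_end,target_lg,target_pos,identity,n_suboptimal,unique
#'   parallel vectors; see [parse_alignments()].
#' @return data.frame of class `alignment_records`.
#' @export
alignment_records <- function(scaffold = character(), window_start = integer(),
                              window_end = integer(), target_lg = character(),
                              target_pos = numeric(), identity = numeric(),
                              n_suboptimal = integer(), unique = logical()) {
  if (length(window_start) && any(window_end <= window_start))
    stop("window_end must exceed window_start")
  if (length(identity) && any(identity < 0 | identity > 1))
    stop("identity must lie in [0, 1]")
  out <- data.frame(scaffold = as.character(scaffold),
                    window_start = as.integer(window_start),
                    window_end = as.integer(window_end),
                    target_lg = as.character(target_lg),
                    target_pos = as.numeric(target_pos),
                    identity = as.numeric(identity),
                    n_suboptimal = as.integer(n_suboptimal),
                    unique = as.logical(unique))
  class(out) <- c("alignment_records", "data.frame")
  out
}

#' Write alignment records as PAF
#'
#' Counterpart of [parse_alignments()] so simulated alignments can be fed
#' through the same file-based interface as real aligner output.
#'
#' @param records an [alignment_records()] table.
#' @param path output file path.
#' @param window_len nominal window length used for the query-length column.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(records, path, window_len = 5000L) {
  len <- records$window_end - records$window_start
  lines <- sprintf("%s\t%d\t%d\t%d\t+\t%s\t%d\t%.0f\t%.0f\t%.0f\t%d\t%d\ts2:i:%d",
                   records$scaffold, records$window_end, records$window_start,
                   records$window_end, records$target_lg, 1000000000L,
                   records$target_pos, records$target_pos + len,
                   round(records$identity * len), len,
                   ifelse(records$unique, 60L, 0L), records$n_suboptimal)
  writeLines(lines, path)
  invisible(path)
}
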