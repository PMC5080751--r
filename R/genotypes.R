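#' Genotype matrix container
#'
#' A `geno_matrix` stores unphased allele-pair calls for a set of individuals
#' at a set of markers, together with per-call read depth.  Markers may be
#' biallelic SNPs (RAD-style stacks) or multi-allelic SSRs; both live in the
#' same container and downstream operations that require biallelic markers
#' check and skip others.
#'
#' @param markers data.frame with columns `id`, `scaffold`, `position`
#'   (0-based bp), `kind` (`"SNP"` or `"SSR"`).
#' @param individuals character vector of unique individual ids.
#' @param a1,a2 character matrices (individuals x markers) of allele labels;
#'   `NA` means a missing call.  A call is missing in both or neither.
#' @param depth integer matrix of per-call read depth; 0 means unknown
#'   (e.g. SSR genotypes), and such calls are exempt from depth masking.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(markers, individuals, a1, a2, depth = NULL) {
  stopifnot(is.data.frame(markers),
            all(c("id", "scaffold", "position", "kind") %in% names(markers)))
  markers$id <- as.character(markers$id)
  if (anyDuplicated(markers$id))
    stop("duplicate marker id: ", markers$id[duplicated(markers$id)][1])
  if (anyDuplicated(individuals))
    stop("duplicate individual id")
  if (any(markers$position < 0, na.rm = TRUE))
    stop("marker positions must be >= 0")
  n <- length(individuals); m <- nrow(markers)
  a1 <- matrix(as.character(a1), n, m, dimnames = list(individuals, markers$id))
  a2 <- matrix(as.character(a2), n, m, dimnames = list(individuals, markers$id))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) stop("half-missing genotype call (one allele NA)")
  if (is.null(depth)) depth <- matrix(0L, n, m)
  depth <- matrix(as.integer(depth), n, m,
                  dimnames = list(individuals, markers$id))
  depth[is.na(depth)] <- 0L
  structure(list(markers = markers, individuals = as.character(individuals),
                 a1 = a1, a2 = a2, depth = depth),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$individuals), "individuals x",
      nrow(x$markers), "markers (",
      sum(x$markers$kind == "SNP"), "SNP,",
      sum(x$markers$kind == "SSR"), "SSR ),",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(length(x$individuals), nrow(x$markers))

#' Extract one genotype call
#'
#' @param gm a [geno_matrix()].
#' @param ind individual id.
#' @param marker marker id.
#' @return character vector of the two allele labels, or `c(NA, NA)`.
#' @export
geno_call <- function(gm, ind, marker) {
  c(gm$a1[ind, marker], gm$a2[ind, marker])
}

#' Number of individuals with a called genotype per marker
#'
#' @param gm a [geno_matrix()].
#' @param ids individuals to count over (default: all).
#' @return named integer vector over markers.
#' @export
n_called <- function(gm, ids = gm$individuals) {
  colSums(!is.na(gm$a1[ids, , drop = FALSE]))
}

#' Subset a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @param individuals,markers ids to keep (default: all).
#' @return a [geno_matrix()].
#' @export
subset_geno <- function(gm, individuals = gm$individuals,
                        markers = gm$markers$id) {
  keep <- gm$markers$id %in% markers
  geno_matrix(gm$markers[keep, , drop = FALSE], individuals,
              gm$a1[individuals, keep, drop = FALSE],
              gm$a2[individuals, keep, drop = FALSE],
              gm$depth[individuals, keep, drop = FALSE])
}

# observed allele labels per marker, parents first in simulation output
marker_alleles <- function(gm, marker) {
  a <- c(gm$a1[, marker], gm$a2[, marker])
  sort(unique(a[!is.na(a)]))
}

MISSING_TOKEN <- "./."

#' Read a genotype matrix from TSV or minimal VCF
#'
#' The TSV dialect has a header row `individual<TAB>marker1<TAB>...` and cells
#' `A/C` or `./.` for missing.  If a file `<stem>.depth.tsv` sits next to the
#' genotype file it is read as a parallel integer depth matrix.  The VCF path
#' (via the vcfR package) uses CHROM/POS/ID for marker metadata and the GT
#' (and DP, if present) FORMAT fields; coordinates are converted from VCF
#' 1-based to the internal 0-based convention.
#'
#' Unparseable genotype cells become missing; the number of such cells is
#' reported with a warning.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @param marker_map optional data.frame (`marker`, `scaffold`, `position`,
#'   `kind`) giving marker metadata for the TSV path, e.g. from
#'   [read_marker_map()].
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), marker_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") return(read_genotypes_vcf(path))

  lines <- readLines(path)
  if (!length(lines)) stop("format error: empty genotype file")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "individual")
    stop("format error at line 1: expected header 'individual<TAB>marker...'")
  marker_ids <- header[-1]
  if (anyDuplicated(marker_ids))
    stop("duplicate marker id in header: ",
         marker_ids[duplicated(marker_ids)][1])
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(vapply(body, length, 1L) != length(header))
  if (length(bad))
    stop("format error at line ", bad[1] + 1L, ": wrong number of fields")
  inds <- vapply(body, `[[`, "", 1L)
  cells <- t(vapply(body, function(x) x[-1], character(length(marker_ids))))
  if (length(marker_ids) == 1L) cells <- matrix(cells, ncol = 1L)

  parts <- parse_geno_cells(cells)
  depth <- NULL
  dpath <- sub("\\.tsv$", ".depth.tsv", path)
  if (dpath != path && file.exists(dpath)) {
    d <- utils::read.table(dpath, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
    depth <- as.matrix(d)[inds, marker_ids, drop = FALSE]
  }
  markers <- tsv_marker_table(marker_ids, parts$a1, parts$a2, marker_map)
  geno_matrix(markers, inds, parts$a1, parts$a2, depth)
}

# split "A/C" cells into two allele matrices; anything unparseable -> missing
parse_geno_cells <- function(cells) {
  flat <- as.character(cells)
  ok <- grepl("^[^/]+/[^/]+$", flat) & flat != MISSING_TOKEN
  n_bad <- sum(!ok & flat != MISSING_TOKEN & !is.na(flat))
  if (n_bad) warning(n_bad, " unparseable genotype cell(s) set to missing")
  a1 <- a2 <- rep(NA_character_, length(flat))
  sp <- strsplit(flat[ok], "/", fixed = TRUE)
  a1[ok] <- vapply(sp, `[[`, "", 1L)
  a2[ok] <- vapply(sp, `[[`, "", 2L)
  list(a1 = matrix(a1, nrow(cells)), a2 = matrix(a2, nrow(cells)))
}

tsv_marker_table <- function(marker_ids, a1, a2, marker_map) {
  if (!is.null(marker_map)) {
    mm <- marker_map[match(marker_ids, marker_map$marker), ]
    if (anyNA(mm$marker))
      stop("marker(s) absent from marker map: ",
           paste(utils::head(marker_ids[is.na(mm$marker)], 3), collapse = ", "))
    return(data.frame(id = marker_ids, scaffold = as.character(mm$scaffold),
                      position = as.integer(mm$position),
                      kind = as.character(mm$kind)))
  }
  n_all <- vapply(seq_along(marker_ids), function(j) {
    a <- c(a1[, j], a2[, j]); length(unique(a[!is.na(a)]))
  }, 1L)
  data.frame(id = marker_ids, scaffold = NA_character_, position = 0L,
             kind = ifelse(n_all > 2, "SSR", "SNP"))
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required for format = 'vcf'")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) stop("duplicate marker id in VCF")
  alleles <- lapply(seq_along(ids), function(i)
    c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]))
  gt <- vcfR::extract.gt(v, element = "GT")
  inds <- colnames(gt)
  n <- length(inds); m <- length(ids)
  a1 <- a2 <- matrix(NA_character_, n, m)
  for (j in seq_len(m)) {
    g <- gt[j, ]
    sp <- strsplit(g, "[/|]")
    for (i in seq_len(n)) {
      s <- sp[[i]]
      if (length(s) == 2 && !any(is.na(s)) && !any(s == ".")) {
        idx <- as.integer(s) + 1L
        if (all(idx >= 1 & idx <= length(alleles[[j]]))) {
          a1[i, j] <- alleles[[j]][idx[1]]
          a2[i, j] <- alleles[[j]][idx[2]]
        }
      }
    }
  }
  depth <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    depth <- t(dp); depth[is.na(depth)] <- 0
  }
  markers <- data.frame(id = ids, scaffold = fix[, "CHROM"],
                        position = as.integer(fix[, "POS"]) - 1L,
                        kind = ifelse(vapply(alleles, length, 1L) > 2 |
                                        nchar(fix[, "REF"]) > 1, "SSR", "SNP"))
  geno_matrix(markers, inds, a1, a2, depth)
}

#' Write a genotype matrix as canonical TSV
#'
#' Inverse of the TSV path of [read_genotypes()]; a write/read cycle is the
#' identity on calls.  Depth is written to `<stem>.depth.tsv` when any call
#' has depth > 0.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  cells <- matrix(paste0(gm$a1, "/", gm$a2), nrow(gm$a1))
  cells[is.na(gm$a1)] <- MISSING_TOKEN
  lines <- c(paste(c("individual", gm$markers$id), collapse = "\t"),
             vapply(seq_along(gm$individuals), function(i)
               paste(c(gm$individuals[i], cells[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  if (any(gm$depth > 0)) {
    d <- as.data.frame(gm$depth)
    utils::write.table(cbind(individual = gm$individuals, d),
                       sub("\\.tsv$", ".depth.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a marker map
#'
#' @param path TSV with columns `marker`, `scaffold`, `position`, `kind`.
#' @return data.frame with those columns.
#' @export
read_marker_map <- function(path) {
  mm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("marker", "scaffold", "position", "kind")
  if (!all(need %in% names(mm)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  mm
}

#' Depth- and missingness-based genotype QC
#'
#' Applies the two-stage RAD genotype filter: homozygous calls supported by
#' fewer than `min_hom_depth` reads are set to missing (heterozygous calls
#' are never depth-masked, and calls with no recorded depth are exempt), then
#' markers with calls in fewer than `min_called` of the listed offspring are
#' dropped.  The operation is idempotent and never resurrects a missing call.
#'
#' @param gm a [geno_matrix()].
#' @param offspring_ids individuals over which `min_called` is counted.
#' @param min_called minimum number of called offspring to retain a marker.
#' @param min_hom_depth minimum read depth to accept a homozygous call.
#' @return filtered [geno_matrix()].
#' @export
qc_filter <- function(gm, offspring_ids, min_called, min_hom_depth = 10L) {
  if (min_called < 0) stop("min_called must be >= 0")
  if (min_called > length(offspring_ids))
    stop("min_called exceeds number of offspring")
  stopifnot(all(offspring_ids %in% gm$individuals))
  hom <- !is.na(gm$a1) & gm$a1 == gm$a2
  mask <- hom & gm$depth > 0L & gm$depth < min_hom_depth
  gm$a1[mask] <- NA_character_
  gm$a2[mask] <- NA_character_
  called <- colSums(!is.na(gm$a1[offspring_ids, , drop = FALSE]))
  keep <- gm$markers$id[called >= min_called]
  subset_geno(gm, markers = keep)
}
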