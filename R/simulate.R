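#' Genome layout for simulation
#'
#' Describes the reference linkage groups (LGs), which of them are fused into
#' single physical chromosomes in the simulated species, and the genetic
#' length of each LG.  Fused LGs recombine as one unit, so their markers
#' co-segregate -- the signature used downstream for fusion detection.
#'
#' @param linkage_groups data.frame with columns `lg`, `length_bp`,
#'   `length_morgans`.
#' @param fusions list of character vectors, each naming >= 2 LGs joined into
#'   one physical chromosome (in the order they are joined).  An LG may
#'   appear in at most one fusion.
#' @param marker_positions optional data.frame `lg`, `position` (bp) and
#'   optionally `kind` (default `"SSR"`) fixing the marker panel explicitly
#'   (e.g. a cluster of SSRs around a candidate locus); when `NULL`,
#'   [simulate_family()] spaces markers evenly per its [marker_spec()].
#' @return object of class `genome_layout`.
#' @export
genome_layout <- function(linkage_groups, fusions = list(),
                          marker_positions = NULL) {
  stopifnot(is.data.frame(linkage_groups),
            all(c("lg", "length_bp", "length_morgans") %in% names(linkage_groups)))
  if (any(linkage_groups$length_bp <= 0) || any(linkage_groups$length_morgans < 0))
    stop("LG lengths must be positive (genetic length may be 0)")
  fused <- unlist(fusions)
  if (anyDuplicated(fused)) stop("an LG appears in more than one fusion")
  if (!all(fused %in% linkage_groups$lg)) stop("fusion names unknown LG")
  if (!is.null(marker_positions)) {
    stopifnot(all(c("lg", "position") %in% names(marker_positions)))
    if (is.null(marker_positions$kind)) marker_positions$kind <- "SSR"
    len <- linkage_groups$length_bp[match(marker_positions$lg,
                                          linkage_groups$lg)]
    if (anyNA(len) || any(marker_positions$position < 0) ||
        any(marker_positions$position >= len))
      stop("marker positions must lie within their LG")
  }
  structure(list(linkage_groups = linkage_groups, fusions = fusions,
                 marker_positions = marker_positions),
            class = "genome_layout")
}

#' Physical chromosomes of a layout
#'
#' @param layout a [genome_layout()].
#' @return list keyed by chromosome id; each element a data.frame of the
#'   constituent LGs with cumulative `offset_bp` / `offset_morgans`.
#' @export
layout_chromosomes <- function(layout) {
  lgs <- layout$linkage_groups
  groups <- layout$fusions
  solo <- setdiff(lgs$lg, unlist(groups))
  groups <- c(groups, as.list(solo))
  names(groups) <- vapply(groups, paste, "", collapse = "-")
  lapply(groups, function(g) {
    d <- lgs[match(g, lgs$lg), ]
    d$offset_bp <- cumsum(c(0, utils::head(d$length_bp, -1)))
    d$offset_morgans <- cumsum(c(0, utils::head(d$length_morgans, -1)))
    d
  })
}

#' A default mouth-brooder-style simulation layout
#'
#' Five reference linkage groups with one fusion (LG5 + LG14 joined into one
#' physical chromosome), chromosome sizes of around 20-40 Mb and genetic
#' lengths of 0.5-1 Morgan, in the range typical of cichlid chromosomes.
#'
#' @return a [genome_layout()].
#' @export
default_layout <- function() {
  genome_layout(
    data.frame(lg = c("LG5", "LG14", "LG13", "LG8", "LG16"),
               length_bp = c(38e6, 25e6, 34e6, 30e6, 28e6),
               length_morgans = c(0.9, 0.6, 0.8, 0.7, 0.7)),
    fusions = list(c("LG5", "LG14")))
}

#' Multi-locus sex-determination model
#'
#' Each locus carries one dominant sex-determination allele -- `Y`
#' (male-determining) or `W` (female-determining) -- heterozygous in the
#' named carrier parent.  Phenotypic sex follows [assign_sex()] (W epistatic
#' over Y; default sex female) and is flipped with probability
#' `1 - penetrance`.
#'
#' @param loci data.frame with columns `lg`, `position` (bp), `allele`
#'   (`"Y"`/`"W"`), `carrier` (`"sire"`/`"dam"`) and optionally `copies`
#'   (1 = heterozygous, the segregating case; 2 = homozygous, a fixed
#'   background).  A ZW family on the standard ZZ-male convention is a dam
#'   heterozygous for W over a sire homozygous for a background Y, so that
#'   W-free offspring develop male.
#' @param penetrance probability in (0, 1] that phenotypic sex matches
#'   genotypic sex; defaults to 0.88, the mean observed across mapped
#'   families in this system.
#' @return object of class `sd_model`.
#' @export
sd_model <- function(loci, penetrance = 0.88) {
  if (is.null(loci) || !nrow(loci)) {
    loci <- data.frame(lg = character(), position = numeric(),
                       allele = character(), carrier = character(),
                       copies = integer())
  }
  stopifnot(all(c("lg", "position", "allele", "carrier") %in% names(loci)) ||
              !nrow(loci))
  if (is.null(loci$copies)) loci$copies <- rep(1L, nrow(loci))
  if (nrow(loci)) {
    if (!all(loci$allele %in% c("Y", "W"))) stop("allele must be Y or W")
    if (!all(loci$carrier %in% c("sire", "dam"))) stop("carrier must be sire or dam")
    if (!all(loci$copies %in% 1:2)) stop("copies must be 1 or 2")
    if (anyDuplicated(loci[c("lg", "position", "allele")]))
      stop("at most one Y and one W per locus position")
  }
  if (penetrance <= 0 || penetrance > 1) stop("penetrance must be in (0, 1]")
  structure(list(loci = loci, penetrance = penetrance), class = "sd_model")
}

#' Canned sex-determination configurations
#'
#' Convenience constructors for the three family types the classifier is
#' asked to tell apart: an XY family (sire heterozygous for Y), a ZW family
#' (dam heterozygous for W over a homozygous male-determining background in
#' the sire, the ZZ-male convention), and a family whose sex is driven by a
#' locus outside the tested regions (segregating Y on `hidden_lg`).
#'
#' @param lg,position locus of the focal allele.
#' @param penetrance see [sd_model()].
#' @param background_lg,background_pos location of the fixed sire Y
#'   background of a ZW family.
#' @param hidden_lg,hidden_pos location of the untested locus of
#'   `sd_config_none`.
#' @return an [sd_model()].
#' @name sd_configs
NULL

#' @rdname sd_configs
#' @export
sd_config_xy <- function(lg, position, penetrance = 0.88) {
  sd_model(data.frame(lg = lg, position = position, allele = "Y",
                      carrier = "sire", copies = 1L), penetrance)
}

#' @rdname sd_configs
#' @export
sd_config_zw <- function(lg, position, background_lg, background_pos,
                         penetrance = 0.88) {
  sd_model(data.frame(lg = c(lg, background_lg),
                      position = c(position, background_pos),
                      allele = c("W", "Y"), carrier = c("dam", "sire"),
                      copies = c(1L, 2L)), penetrance)
}

#' @rdname sd_configs
#' @export
sd_config_none <- function(hidden_lg, hidden_pos, penetrance = 0.88) {
  sd_model(data.frame(lg = hidden_lg, position = hidden_pos, allele = "Y",
                      carrier = "sire", copies = 1L), penetrance)
}

#' Phenotypic sex implied by carried sex-determination alleles
#'
#' Implements the dominance hierarchy of a polygenic XY/ZW/XYW system:
#' any W allele makes a female (W is epistatic over Y), otherwise any Y makes
#' a male, otherwise the default sex is female (XX-female convention).  With
#' an XY sire at one locus and a ZW dam at another, this yields the expected
#' 1:3 male:female ratio among offspring.
#'
#' @param carried_alleles character vector (multiset) over `{"Y", "W"}`;
#'   other labels are ignored.
#' @return `"M"` or `"F"`.
#' @export
assign_sex <- function(carried_alleles) {
  if (any(carried_alleles == "W")) return("F")
  if (any(carried_alleles == "Y")) return("M")
  "F"
}

# one meiosis for one chromosome: returns list(alleles, crossovers, start)
# loci positions in Morgans along the (possibly fused) chromosome
meiosis_one <- function(h1, h2, pos_m, length_m) {
  k <- stats::rpois(1, length_m)
  start <- sample(0:1, 1)
  if (k == 0L) {
    alle <- if (start == 0L) h1 else h2
    return(list(alleles = alle, crossovers = numeric(), start = start))
  }
  xo <- sort(stats::runif(k, 0, length_m))
  phase <- (start + findInterval(pos_m, xo)) %% 2L
  list(alleles = ifelse(phase == 0L, h1, h2), crossovers = xo, start = start)
}

#' Simulate one gamete from a parent
#'
#' Crossover counts are Poisson in the chromosome's genetic length and
#' crossover positions uniform (Haldane model, no interference).  Fused
#' chromosomes recombine as one unit, so loci on the two constituent LGs
#' co-segregate with recombination fraction set by their combined genetic
#' distance.
#'
#' @param parent_haplotypes list keyed by chromosome id; each element a list
#'   with components `h1`, `h2` (allele vectors) and `pos_morgans` (locus
#'   positions in Morgans along the chromosome).
#' @param layout a [genome_layout()]; supplies genetic lengths per
#'   chromosome (see [layout_chromosomes()]).
#' @param seed optional integer seed.
#' @return list keyed by chromosome id with components `alleles` and
#'   `crossovers` (crossover positions, Morgans).
#' @export
simulate_gamete <- function(parent_haplotypes, layout, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- layout_chromosomes(layout)
  out <- lapply(names(parent_haplotypes), function(cid) {
    hp <- parent_haplotypes[[cid]]
    L <- sum(chroms[[cid]]$length_morgans)
    meiosis_one(hp$h1, hp$h2, hp$pos_morgans, L)
  })
  names(out) <- names(parent_haplotypes)
  out
}

#' Marker panel specification for family simulation
#'
#' @param snp_per_lg,ssr_per_lg markers of each kind per linkage group,
#'   evenly spaced.
#' @param ssr_allele_range integer range of SSR allele counts; founder SSR
#'   alleles are drawn equifrequently from the sampled count.
#' @param snp_beta shape parameters of the Beta distribution from which
#'   founder SNP allele frequencies are drawn.
#' @param markers_per_scaffold markers grouped onto one synthetic scaffold
#'   (sets the `scaffold` metadata used by anchoring/liftover).
#' @return list of class `marker_spec`.
#' @export
marker_spec <- function(snp_per_lg = 8L, ssr_per_lg = 2L,
                        ssr_allele_range = 4:8, snp_beta = c(2, 2),
                        markers_per_scaffold = 3L) {
  structure(list(snp_per_lg = snp_per_lg, ssr_per_lg = ssr_per_lg,
                 ssr_allele_range = ssr_allele_range, snp_beta = snp_beta,
                 markers_per_scaffold = markers_per_scaffold),
            class = "marker_spec")
}

# marker table for a layout: id, lg, scaffold, position(bp), kind
build_marker_table <- function(layout, spec) {
  lgs <- layout$linkage_groups
  if (!is.null(layout$marker_positions)) {
    mp <- layout$marker_positions
    mp <- mp[order(match(mp$lg, lgs$lg), mp$position), ]
    mt <- data.frame(
      id = sprintf("%s_m%02d", mp$lg,
                   stats::ave(seq_len(nrow(mp)), mp$lg, FUN = seq_along)),
      lg = mp$lg, position = mp$position, kind = mp$kind)
    grp <- stats::ave(seq_len(nrow(mt)), mt$lg,
                      FUN = function(ix) (seq_along(ix) - 1) %/%
                        spec$markers_per_scaffold + 1)
    mt$scaffold <- sprintf("sc_%s_%d", mt$lg, grp)
    return(mt)
  }
  rows <- lapply(seq_len(nrow(lgs)), function(i) {
    n <- spec$snp_per_lg + spec$ssr_per_lg
    if (n == 0) return(NULL)
    pos <- round(seq(0.05, 0.95, length.out = n) * lgs$length_bp[i])
    # SSRs interleaved among the SNPs deterministically
    kind <- rep("SNP", n)
    if (spec$ssr_per_lg > 0)
      kind[round(seq(1, n, length.out = spec$ssr_per_lg))] <- "SSR"
    data.frame(id = sprintf("%s_m%02d", lgs$lg[i], seq_len(n)),
               lg = lgs$lg[i], position = pos, kind = kind)
  })
  mt <- do.call(rbind, rows)
  grp <- stats::ave(seq_len(nrow(mt)), mt$lg,
                    FUN = function(ix) (seq_along(ix) - 1) %/% spec$markers_per_scaffold + 1)
  mt$scaffold <- sprintf("sc_%s_%d", mt$lg, grp)
  mt
}

# locus genetic position along its physical chromosome
chrom_positions <- function(chroms, lg, position) {
  cid <- vapply(lg, function(g) {
    names(chroms)[vapply(chroms, function(d) g %in% d$lg, TRUE)][1]
  }, "")
  pos_m <- mapply(function(g, p, ci) {
    d <- chroms[[ci]]; r <- d[d$lg == g, ]
    r$offset_morgans + p / r$length_bp * r$length_morgans
  }, lg, position, cid)
  data.frame(chrom = cid, pos_morgans = as.numeric(pos_m))
}

#' Simulate a full family
#'
#' Builds founder parents, places the sex-determination alleles of
#' `model` heterozygously on one haplotype of the carrier parent, generates
#' each offspring from two independent meioses ([simulate_gamete()]),
#' assigns genotypic sex with [assign_sex()] and flips it with probability
#' `1 - penetrance`, and returns the genotype matrix (parents + offspring),
#' the pedigree, and the ground truth.
#'
#' @param layout a [genome_layout()].
#' @param model an [sd_model()].
#' @param n_offspring number of offspring (families of 10-40 are typical of
#'   the mouth-brooder crosses this emulates).
#' @param spec a [marker_spec()].
#' @param seed integer seed.
#' @param family_id,sire_id,dam_id identifiers.
#' @param founders optional founder allele matrix (markers x 4: sire
#'   haplotypes 1-2, dam haplotypes 3-4) as returned in `$founders` of a
#'   previous call with the same `layout`/`spec`; lets several families
#'   share a parent (e.g. `cbind(a$founders[, 1:2], b$founders[, 3:4])`).
#' @return list with components `geno` ([geno_matrix()], parents first),
#'   `family` ([family_ped()]), `truth` (data.frame with per-offspring
#'   `genotypic_sex`, `phenotypic_sex`, `sex_reversed`, `sd_alleles`),
#'   `marker_lg` (true marker-to-LG map) and `founders`.
#' @export
simulate_family <- function(layout, model, n_offspring, spec = marker_spec(),
                            seed = NULL, family_id = "fam1",
                            sire_id = "sire1", dam_id = "dam1",
                            founders = NULL) {
  if (n_offspring < 1) stop("n_offspring must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (nrow(model$loci) &&
      !all(model$loci$lg %in% layout$linkage_groups$lg))
    stop("sex-determination locus on an LG absent from layout")

  chroms <- layout_chromosomes(layout)
  mt <- build_marker_table(layout, spec)
  gp <- chrom_positions(chroms, mt$lg, mt$position)
  mt$chrom <- gp$chrom; mt$pos_morgans <- gp$pos_morgans

  # hidden sex-determination loci appended as extra positions
  sd <- model$loci
  if (nrow(sd)) {
    sp <- chrom_positions(chroms, sd$lg, sd$position)
    sd$chrom <- sp$chrom; sd$pos_morgans <- sp$pos_morgans
    sd$id <- sprintf("__sd%d", seq_len(nrow(sd)))
  }

  # founder alleles per marker: 4 parental haplotype alleles
  if (is.null(founders)) {
    founder <- lapply(seq_len(nrow(mt)), function(i) {
      if (mt$kind[i] == "SNP") {
        p <- stats::rbeta(1, spec$snp_beta[1], spec$snp_beta[2])
        ifelse(stats::runif(4) < p, "A", "B")
      } else {
        k <- sample(spec$ssr_allele_range, 1)
        sample(sprintf("a%d", seq_len(k)), 4, replace = TRUE)
      }
    })
    fa <- do.call(rbind, founder)  # cols: sire h1, sire h2, dam h1, dam h2
  } else {
    stopifnot(nrow(founders) == nrow(mt), ncol(founders) == 4)
    fa <- founders
  }

  # per-parent, per-chromosome haplotype lists over markers + SD loci
  parent_haps <- function(parent) {
    cols <- if (parent == "sire") 1:2 else 3:4
    lapply(names(chroms), function(cid) {
      on <- mt$chrom == cid
      h1 <- fa[on, cols[1]]; h2 <- fa[on, cols[2]]
      ids <- mt$id[on]; pm <- mt$pos_morgans[on]
      if (nrow(sd)) {
        son <- sd$chrom == cid & sd$carrier == parent
        soth <- sd$chrom == cid & sd$carrier != parent
        if (any(son)) {
          h1 <- c(h1, sd$allele[son])
          h2 <- c(h2, ifelse(sd$copies[son] == 2L, sd$allele[son], "+"))
          ids <- c(ids, sd$id[son]); pm <- c(pm, sd$pos_morgans[son])
        }
        if (any(soth)) {
          h1 <- c(h1, rep("+", sum(soth))); h2 <- c(h2, rep("+", sum(soth)))
          ids <- c(ids, sd$id[soth]); pm <- c(pm, sd$pos_morgans[soth])
        }
      }
      o <- order(pm)
      list(h1 = h1[o], h2 = h2[o], pos_morgans = pm[o], ids = ids[o])
    }) |> stats::setNames(names(chroms))
  }
  sire_h <- parent_haps("sire"); dam_h <- parent_haps("dam")

  off_ids <- sprintf("%s_o%02d", family_id, seq_len(n_offspring))
  inds <- c(sire_id, dam_id, off_ids)
  n <- length(inds); m <- nrow(mt)
  a1 <- a2 <- matrix(NA_character_, n, m)
  a1[1, ] <- fa[, 1]; a2[1, ] <- fa[, 2]
  a1[2, ] <- fa[, 3]; a2[2, ] <- fa[, 4]

  geno_sex <- pheno_sex <- character(n_offspring)
  sd_carried <- character(n_offspring)
  for (k in seq_len(n_offspring)) {
    gs <- simulate_gamete(sire_h, layout)
    gd <- simulate_gamete(dam_h, layout)
    carried <- character()
    for (cid in names(chroms)) {
      ids <- sire_h[[cid]]$ids
      keep <- !startsWith(ids, "__sd")
      j <- match(ids[keep], mt$id)
      a1[2 + k, j] <- gs[[cid]]$alleles[keep]
      a2[2 + k, j] <- gd[[cid]]$alleles[keep]
      carried <- c(carried, gs[[cid]]$alleles[!keep], gd[[cid]]$alleles[!keep])
    }
    carried <- carried[carried %in% c("Y", "W")]
    geno_sex[k] <- assign_sex(carried)
    flip <- stats::runif(1) > model$penetrance
    pheno_sex[k] <- if (flip) setdiff(c("M", "F"), geno_sex[k]) else geno_sex[k]
    sd_carried[k] <- paste(carried, collapse = ",")
  }

  markers <- data.frame(id = mt$id, scaffold = mt$scaffold,
                        position = mt$position, kind = mt$kind)
  gm <- geno_matrix(markers, inds, a1, a2)
  fam <- family_ped(family_id, sire_id, dam_id,
                    data.frame(id = off_ids, sex = pheno_sex))
  truth <- data.frame(id = off_ids, genotypic_sex = geno_sex,
                      phenotypic_sex = pheno_sex,
                      sex_reversed = geno_sex != pheno_sex,
                      sd_alleles = sd_carried)
  list(geno = gm, family = fam, truth = truth,
       marker_lg = data.frame(marker = mt$id, lg = mt$lg),
       founders = fa)
}

#' Overlay ddRAD-style depth noise on a genotype matrix
#'
#' Each call receives an independent Poisson read depth with the given mean;
#' calls landing at depth 0 become missing.  Feeding the result through
#' [qc_filter()] reproduces the depth-driven missingness structure of
#' reduced-representation genotype data.
#'
#' @param gm a [geno_matrix()].
#' @param mean_depth positive mean read depth.
#' @param seed optional integer seed.
#' @return a [geno_matrix()] with `depth` populated and zero-depth calls
#'   missing.
#' @export
simulate_depth_noise <- function(gm, mean_depth, seed = NULL) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(stats::rpois(length(gm$depth), mean_depth), nrow(gm$depth))
  gm$depth <- d
  gm$a1[d == 0L] <- NA_character_
  gm$a2[d == 0L] <- NA_character_
  dimnames(gm$depth) <- dimnames(gm$a1)
  gm
}

#' Random scaffold tiling of the simulated chromosomes
#'
#' Partitions each physical chromosome into scaffolds of random lengths,
#' assigns each a random orientation, and shuffles scaffold names so that no
#' ordering information survives in the ids.  Scaffolds of a fused
#' chromosome cover both constituent LGs, and a scaffold spanning the fusion
#' junction produces windows aligning to two reference LGs.
#'
#' @param layout a [genome_layout()].
#' @param n_per_chrom scaffolds per physical chromosome.
#' @param seed optional integer seed.
#' @param min_len minimum scaffold length, bp.
#' @return data.frame with columns `scaffold`, `chrom`, `start`, `end`,
#'   `orient`, in true chromosome order.
#' @export
make_scaffold_spec <- function(layout, n_per_chrom = 6L, seed = NULL,
                               min_len = 20000L) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- layout_chromosomes(layout)
  rows <- lapply(names(chroms), function(cid) {
    len <- sum(chroms[[cid]]$length_bp)
    repeat {
      cuts <- sort(sample.int(len - 1L, n_per_chrom - 1L))
      bounds <- c(0, cuts, len)
      if (all(diff(bounds) >= min_len)) break
    }
    data.frame(chrom = cid, start = bounds[-length(bounds)],
               end = bounds[-1],
               orient = sample(c("+", "-"), n_per_chrom, replace = TRUE))
  })
  sp <- do.call(rbind, rows)
  sp$scaffold <- sprintf("scaffold_%d", sample.int(nrow(sp)))
  sp[c("scaffold", "chrom", "start", "end", "orient")]
}

#' Simulate window alignments of scaffolds against the reference
#'
#' Partitions each scaffold into non-overlapping fixed-size windows (5 kb by
#' default) and emits one alignment record per window whose target follows
#' the true placement of the scaffold on the reference linkage groups,
#' except that a `noise` fraction of windows is redirected to a uniformly
#' random LG and position.  Identities are drawn uniformly from
#' `identity_range`.
#'
#' @param layout a [genome_layout()].
#' @param scaffold_spec a [make_scaffold_spec()] table.
#' @param window window size in bp (default 5000).
#' @param noise fraction of windows misassigned.
#' @param identity_range range of simulated sequence identities.
#' @param seed optional integer seed.
#' @return an [alignment_records()] table.
#' @export
simulate_alignments <- function(layout, scaffold_spec, window = 5000L,
                                noise = 0, identity_range = c(0.92, 1),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(scaffold_spec$end - scaffold_spec$start < window))
    stop("window larger than shortest scaffold")
  chroms <- layout_chromosomes(layout)
  lgs <- layout$linkage_groups
  rows <- lapply(seq_len(nrow(scaffold_spec)), function(i) {
    s <- scaffold_spec[i, ]
    len <- s$end - s$start
    starts <- seq(0L, len - window, by = window)
    # scaffold coordinate -> chromosome coordinate
    cpos <- if (s$orient == "+") s$start + starts
            else s$end - starts - window
    d <- chroms[[s$chrom]]
    k <- findInterval(cpos, d$offset_bp)
    data.frame(scaffold = s$scaffold, window_start = starts,
               window_end = starts + window,
               target_lg = d$lg[k],
               target_pos = cpos - d$offset_bp[k])
  })
  rec <- do.call(rbind, rows)
  nr <- nrow(rec)
  flip <- stats::runif(nr) < noise
  if (any(flip)) {
    rec$target_lg[flip] <- sample(lgs$lg, sum(flip), replace = TRUE)
    rec$target_pos[flip] <- floor(stats::runif(sum(flip)) *
      lgs$length_bp[match(rec$target_lg[flip], lgs$lg)])
  }
  alignment_records(rec$scaffold, rec$window_start, rec$window_end,
                    rec$target_lg, rec$target_pos,
                    stats::runif(nr, identity_range[1], identity_range[2]),
                    rep(0L, nr), rep(TRUE, nr))
}

#' Read a simulation scenario from YAML/JSON
#'
#' A scenario file describes `linkage_groups`, optional `fusions`, `loci`
#' (sex-determination alleles), `penetrance`, and `families` (name,
#' n_offspring, seed offsets).  See the packaged example under
#' `inst/extdata/scenario_basic.yaml`.
#'
#' @param path YAML (or JSON, a YAML subset) file path.
#' @return list with components `layout` ([genome_layout()]), `model`
#'   ([sd_model()]), and `families` (data.frame).
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  layout <- genome_layout(
    do.call(rbind, lapply(sc$linkage_groups, as.data.frame)),
    lapply(sc$fusions, unlist))
  loci <- if (length(sc$loci))
    do.call(rbind, lapply(sc$loci, as.data.frame)) else NULL
  # YAML 1.1 reads a bare `Y` as boolean truth; map it back
  if (!is.null(loci) && is.logical(loci$allele))
    loci$allele <- ifelse(loci$allele, "Y", "N")
  model <- sd_model(loci, penetrance = sc$penetrance %||% 0.88)
  fams <- do.call(rbind, lapply(sc$families, as.data.frame))
  list(layout = layout, model = model, families = fams)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a scenario and write its files
#'
#' Runs [simulate_family()] for every family of a scenario and writes the
#' genotype TSV, pedigree TSV and a `truth.tsv` to a directory.
#'
#' @param scenario result of [read_scenario()].
#' @param seed global integer seed; per-family sub-seeds are derived from it.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of per-family simulation results.
#' @export
simulate_scenario <- function(scenario, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sims <- lapply(seq_len(nrow(scenario$families)), function(i) {
    f <- scenario$families[i, ]
    simulate_family(scenario$layout, scenario$model, f$n_offspring,
                    seed = (seed + 7919L * i) %% .Machine$integer.max,
                    family_id = f$name,
                    sire_id = paste0(f$name, "_sire"),
                    dam_id = paste0(f$name, "_dam"))
  })
  for (i in seq_along(sims))
    write_genotypes(sims[[i]]$geno,
                    file.path(out_dir, paste0(sims[[i]]$family$family_id, ".geno.tsv")))
  write_pedigree(lapply(sims, `[[`, "family"), file.path(out_dir, "pedigree.tsv"))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sims)
}

#' Check Mendelian consistency of offspring genotypes
#'
#' Every offspring call must be explainable as one sire allele plus one dam
#' allele.  Holds exactly for simulator output before depth noise.
#'
#' @param gm a [geno_matrix()].
#' @param family a [family_ped()].
#' @return logical matrix (offspring x markers); `NA` where any involved
#'   call is missing.
#' @export
mendelian_consistent <- function(gm, family) {
  off <- family$offspring$id
  out <- matrix(NA, length(off), nrow(gm$markers),
                dimnames = list(off, gm$markers$id))
  for (mk in gm$markers$id) {
    s <- geno_call(gm, family$sire_id, mk)
    d <- geno_call(gm, family$dam_id, mk)
    if (anyNA(s) || anyNA(d)) next
    for (o in off) {
      g <- geno_call(gm, o, mk)
      if (anyNA(g)) next
      out[o, mk] <- (g[1] %in% s && g[2] %in% d) ||
                    (g[2] %in% s && g[1] %in% d)
    }
  }
  out
}
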