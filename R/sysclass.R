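#' Classify a family's sex-determination system at candidate loci
#'
#' For each candidate locus region, tests transmission of the sire's alleles
#' (probing a Y) and of the dam's alleles (probing a W) at every region
#' marker with Fisher's exact test, and takes the minimum p per parent (ties
#' broken by more informative offspring, then marker id).  The family is
#' called `XY` at the region when the sire's best p is below `alpha` and the
#' sire's linked allele is carried predominantly by sons; `ZW` when the
#' dam's best p is below `alpha` and her linked allele is carried
#' predominantly by daughters.  Both significant emits two calls (a
#' multi-locus family); neither significant yields `unknown`; no
#' informative marker for either parent yields `NI`.
#'
#' Penetrance is estimated at the best marker as the proportion of
#' informative offspring matching the majority allele-to-sex mapping, and
#' mismatching offspring (putative sex-reversed or recombinant) are listed.
#'
#' @param gm a QC-filtered [geno_matrix()].
#' @param family a [family_ped()].
#' @param regions named list: region name -> character vector of marker ids.
#' @param alpha per-marker significance level (default 0.05).
#' @param min_informative see [transmission_table()].
#' @param tests optional data.frame `region`, `parent` restricting which
#'   parent is probed per region (the mapping-study design tests the sire at
#'   every candidate locus but the dam only where a W is plausible); default
#'   probes both parents everywhere.
#' @return data.frame of class `system_calls`, one row per emitted call:
#'   `family_id`, `region`, `system`, `parent`, `parent_id`, `best_marker`,
#'   `best_p`, `sex_allele` (the sex-linked parental allele),
#'   `n_informative`, `penetrance`, and a list-column `mismatches`.
#' @export
classify_family <- function(gm, family, regions, alpha = 0.05,
                            min_informative = 5L, tests = NULL) {
  stopifnot(length(regions) >= 1, !is.null(names(regions)))
  if (is.null(tests))
    tests <- expand.grid(region = names(regions), parent = c("sire", "dam"),
                         stringsAsFactors = FALSE)
  rows <- list()
  for (rg in names(regions)) {
    mks <- intersect(regions[[rg]], gm$markers$id)
    parents_here <- tests$parent[tests$region == rg]
    per_parent <- lapply(c(sire = "sire", dam = "dam"), function(par) {
      if (!par %in% parents_here) return(NULL)
      best <- NULL
      for (mk in mks) {
        tb <- transmission_table(gm, family, mk, par, min_informative)
        if (is.null(tb)) next
        p <- fisher_exact_2x2(tb)
        cand <- list(marker = mk, p = p, table = tb, n = sum(tb))
        if (is.null(best) || p < best$p ||
            (p == best$p && (cand$n > best$n ||
                             (cand$n == best$n && mk < best$marker))))
          best <- cand
      }
      best
    })
    emitted <- FALSE
    for (par in c("sire", "dam")) {
      b <- per_parent[[par]]
      if (is.null(b) || b$p >= alpha) next
      want_sex <- if (par == "sire") "M" else "F"
      lk <- linked_allele(b$table, want_sex)
      if (is.na(lk$allele)) next  # significant but wrong-direction linkage
      pen <- penetrance_at(gm, family, b$marker, par, min_informative)
      rows[[length(rows) + 1]] <- data.frame(
        family_id = family$family_id, region = rg,
        system = if (par == "sire") "XY" else "ZW",
        parent = par,
        parent_id = if (par == "sire") family$sire_id else family$dam_id,
        best_marker = b$marker, best_p = b$p, sex_allele = lk$allele,
        n_informative = b$n, penetrance = pen$penetrance,
        mismatches = I(list(pen$mismatches)))
      emitted <- TRUE
    }
    if (!emitted) {
      sysname <- if (is.null(per_parent$sire) && is.null(per_parent$dam))
        "NI" else "unknown"
      bst <- per_parent[[which.min(c(
        if (is.null(per_parent$sire)) Inf else per_parent$sire$p,
        if (is.null(per_parent$dam)) Inf else per_parent$dam$p))]]
      rows[[length(rows) + 1]] <- data.frame(
        family_id = family$family_id, region = rg, system = sysname,
        parent = NA_character_, parent_id = NA_character_,
        best_marker = if (is.null(bst)) NA_character_ else bst$marker,
        best_p = if (is.null(bst)) NA_real_ else bst$p,
        sex_allele = NA_character_,
        n_informative = if (is.null(bst)) 0L else bst$n,
        penetrance = NA_real_, mismatches = I(list(character())))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("system_calls", "data.frame")
  out
}

# which parental allele is linked to `want_sex` under the majority mapping;
# NA when the association points the other way (e.g. sire allele linked to
# daughters cannot support an XY call)
linked_allele <- function(tb, want_sex) {
  share <- tb[, want_sex] / pmax(rowSums(tb), 1)
  a <- which.max(share)
  # majority mapping must actually send this allele to want_sex
  if (tb[a, want_sex] <= tb[a, setdiff(c("M", "F"), want_sex)])
    return(list(allele = NA_character_))
  list(allele = rownames(tb)[a])
}

# penetrance and mismatch set at one marker for one parent
penetrance_at <- function(gm, family, marker, parent, min_informative = 5L) {
  tr <- transmitted_alleles(gm, family, marker, parent)
  tr <- tr[!is.na(tr$allele), ]
  if (!nrow(tr)) return(list(penetrance = NA_real_, mismatches = character()))
  alleles <- unique(tr$allele)
  if (length(alleles) == 1) {
    # only one transmitted allele deducible: majority sex defines expectation
    maj <- names(which.max(table(tr$sex)))
    match_ok <- tr$sex == maj
  } else {
    # two candidate allele<->sex pairings; majority (best-fitting) one wins
    fit1 <- (tr$allele == alleles[1] & tr$sex == "M") |
            (tr$allele == alleles[2] & tr$sex == "F")
    match_ok <- if (sum(fit1) >= nrow(tr) - sum(fit1)) fit1 else !fit1
  }
  list(penetrance = mean(match_ok), mismatches = tr$id[!match_ok])
}

#' Penetrance of a system call
#'
#' The proportion of informative offspring showing the expected
#' genotype-phenotype association at the call's best marker, the expectation
#' being the majority allele-to-sex mapping there.  Equals 1 exactly when
#' the call has no mismatching offspring.
#'
#' @param call one row of a [classify_family()] result.
#' @param gm a [geno_matrix()].
#' @param family the matching [family_ped()].
#' @return list with `penetrance` (fraction in `[0,1]`) and `mismatches`
#'   (offspring ids).
#' @export
penetrance <- function(call, gm, family) {
  if (!call$system %in% c("XY", "ZW"))
    stop("penetrance is defined only for XY/ZW calls")
  penetrance_at(gm, family, call$best_marker, call$parent)
}

#' Flag putative sex-reversed offspring
#'
#' Annotates the mismatching offspring of an XY/ZW call with their
#' genotype-implied and phenotypic sexes.  Membership is identical to the
#' mismatch set used by [penetrance()].
#'
#' @param call one row of a [classify_family()] result.
#' @param gm a [geno_matrix()].
#' @param family the matching [family_ped()].
#' @return data.frame with `id`, `genotype_sex`, `phenotype_sex`.
#' @export
flag_sex_reversal <- function(call, gm, family) {
  pen <- penetrance(call, gm, family)
  ids <- pen$mismatches
  sex <- family$offspring$sex[match(ids, family$offspring$id)]
  data.frame(id = ids,
             genotype_sex = vapply(sex, function(s) setdiff(c("M", "F"), s), ""),
             phenotype_sex = sex, row.names = NULL)
}

#' Cross-family consistency of sex-linked parental haplotypes
#'
#' Where several families share a parent and a locus region, the same
#' parental allele should be linked to the determining sex in each (a sire's
#' Y-bearing haplotype makes sons in every family it enters).  Reports, per
#' shared (parent, region, system) combination, whether the sex-linked
#' allele labels agree; groups represented by a single family are marked
#' not comparable.
#'
#' @param calls a [classify_family()]-style data.frame covering >= 1
#'   families (rows with system `XY`/`ZW` are compared).
#' @return data.frame with `parent_id`, `region`, `system`, `n_families`,
#'   `alleles`, `comparable`, `consistent`.
#' @export
shared_haplotype_check <- function(calls) {
  sel <- calls[calls$system %in% c("XY", "ZW"), , drop = FALSE]
  if (!nrow(sel)) return(data.frame())
  key <- paste(sel$parent_id, sel$region, sel$system, sep = "\r")
  out <- lapply(split(sel, key), function(d) {
    data.frame(parent_id = d$parent_id[1], region = d$region[1],
               system = d$system[1], n_families = nrow(d),
               alleles = paste(unique(d$sex_allele), collapse = ","),
               comparable = nrow(d) >= 2,
               consistent = if (nrow(d) >= 2)
                 length(unique(d$sex_allele)) == 1 else NA)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Family-level system label
#'
#' Condenses the per-region calls of one family into the single "System"
#' label of a mapping-summary table: the significant XY/ZW call with the
#' smallest p wins (ties by higher penetrance, more informative offspring,
#' then region name);
#' families with no significant call are labelled `unknown` (or `NI` when
#' no region had an informative marker).
#'
#' @param calls a [classify_family()] result for one family.
#' @return character label, e.g. `"LG5-14 XY"`, `"unknown"`.
#' @export
family_system_label <- function(calls) {
  sig <- calls[calls$system %in% c("XY", "ZW"), , drop = FALSE]
  if (!nrow(sig))
    return(if (all(calls$system == "NI")) "NI" else "unknown")
  o <- order(sig$best_p, -sig$penetrance, -sig$n_informative, sig$region)
  paste(sig$region[o[1]], sig$system[o[1]])
}
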