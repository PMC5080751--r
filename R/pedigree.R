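#' Family (pedigree) objects
#'
#' A `family_ped` describes one cross: a sire, a dam, and offspring with
#' recorded phenotypic (gonadal) sex.
#'
#' @param family_id family identifier.
#' @param sire_id,dam_id parent individual ids (must differ).
#' @param offspring data.frame with columns `id` and `sex` (`"M"`/`"F"`).
#' @return An object of class `family_ped`.
#' @export
family_ped <- function(family_id, sire_id, dam_id, offspring) {
  stopifnot(is.data.frame(offspring), all(c("id", "sex") %in% names(offspring)))
  if (identical(sire_id, dam_id)) stop("sire and dam must differ")
  if (!nrow(offspring)) stop("family ", family_id, " has no offspring")
  if (anyDuplicated(offspring$id)) stop("duplicate offspring id")
  if (any(offspring$id %in% c(sire_id, dam_id)))
    stop("offspring id collides with a parent id")
  if (!all(offspring$sex %in% c("M", "F")))
    stop("offspring sex must be 'M' or 'F'")
  structure(list(family_id = as.character(family_id),
                 sire_id = as.character(sire_id),
                 dam_id = as.character(dam_id),
                 offspring = data.frame(id = as.character(offspring$id),
                                        sex = as.character(offspring$sex))),
            class = "family_ped")
}

#' @export
print.family_ped <- function(x, ...) {
  cat(sprintf("family %s: sire %s x dam %s, %d offspring (%d M / %d F)\n",
              x$family_id, x$sire_id, x$dam_id, nrow(x$offspring),
              sum(x$offspring$sex == "M"), sum(x$offspring$sex == "F")))
  invisible(x)
}

#' Read families from a pedigree TSV
#'
#' Expects columns `family_id`, `individual_id`, `role`
#' (`sire`/`dam`/`offspring`) and `sex` (`M`/`F`/`NA`).  Row order within the
#' file is irrelevant; parental sex entries are ignored (roles define them).
#'
#' @param path file path.
#' @return named list of [family_ped()] objects, keyed by family id.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("family_id", "individual_id", "role", "sex")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  if (!all(ped$role %in% c("sire", "dam", "offspring")))
    stop("role must be sire, dam or offspring")
  fams <- lapply(split(ped, ped$family_id), function(d) {
    sire <- d$individual_id[d$role == "sire"]
    dam <- d$individual_id[d$role == "dam"]
    off <- d[d$role == "offspring", ]
    if (length(sire) != 1 || length(dam) != 1)
      stop("family ", d$family_id[1], " must have exactly one sire and one dam")
    if (!nrow(off)) stop("family ", d$family_id[1], " has no offspring")
    if (anyNA(off$sex)) stop("offspring with missing sex in family ",
                             d$family_id[1])
    family_ped(d$family_id[1], sire, dam,
               data.frame(id = off$individual_id, sex = off$sex))
  })
  fams[unique(as.character(ped$family_id))]
}

#' Write families to a pedigree TSV
#'
#' @param families list of [family_ped()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(families, path) {
  rows <- do.call(rbind, lapply(families, function(f)
    rbind(data.frame(family_id = f$family_id, individual_id = f$sire_id,
                     role = "sire", sex = "NA"),
          data.frame(family_id = f$family_id, individual_id = f$dam_id,
                     role = "dam", sex = "NA"),
          data.frame(family_id = f$family_id, individual_id = f$offspring$id,
                     role = "offspring", sex = f$offspring$sex))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
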