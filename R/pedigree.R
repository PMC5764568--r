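#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per family member and the roles
#' needed for segregation filtering derived on demand: affected sequenced
#' members, obligate carriers (unaffected parents of an affected child) and
#' sequenced unaffected siblings.
#'
#' @param id character vector of member identifiers (must be unique).
#' @param sex integer or character; 1/"M" male, 2/"F" female, 0/NA unknown.
#' @param father_id,mother_id parent identifiers; `NA` or `"0"` for founders.
#'   Parents named here must themselves be listed in `id`.
#' @param affected logical; disease status.
#' @param sequenced logical; whether the member has genotype calls. Defaults
#'   to `TRUE` for everyone; [read_ped()] sets it from the sample set when one
#'   is supplied.
#' @return An object of class `pedigree`: a data frame with columns
#'   `id`, `sex`, `father_id`, `mother_id`, `affected`, `sequenced`.
#' @examples
#' quartet_pedigree()
#' @export
pedigree <- function(id, sex = NA_integer_, father_id = NA_character_,
                     mother_id = NA_character_, affected = FALSE,
                     sequenced = TRUE) {
  n <- length(id)
  norm_parent <- function(p) {
    p <- as.character(p)
    p[p %in% c("0", "", ".")] <- NA_character_
    rep_len(p, n)
  }
  ped <- data.frame(
    id = as.character(id),
    sex = rep_len(as.integer(sub("^M$", "1", sub("^F$", "2", as.character(sex)))), n),
    father_id = norm_parent(father_id),
    mother_id = norm_parent(mother_id),
    affected = rep_len(as.logical(affected), n),
    sequenced = rep_len(as.logical(sequenced), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ped$id) > 0)
    stop("duplicate member ids in pedigree")
  parents <- c(ped$father_id, ped$mother_id)
  missing_par <- setdiff(parents[!is.na(parents)], ped$id)
  if (length(missing_par) > 0)
    stop("parent id(s) not present as members: ", paste(missing_par, collapse = ", "))
  check_pedigree_acyclic(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# topological check: every member must be reachable from founders
check_pedigree_acyclic <- function(ped) {
  done <- is.na(ped$father_id) & is.na(ped$mother_id)
  repeat {
    ready <- !done &
      (is.na(ped$father_id) | ped$father_id %in% ped$id[done]) &
      (is.na(ped$mother_id) | ped$mother_id %in% ped$id[done])
    if (!any(ready)) break
    done <- done | ready
  }
  if (!all(done))
    stop("cyclic parentage involving: ", paste(ped$id[!done], collapse = ", "))
  invisible(TRUE)
}

#' Read a PLINK 6-column PED file
#'
#' Columns: family id, individual id, father id, mother id, sex, phenotype
#' (1 unaffected, 2 affected; 0/-9 unknown, treated as unaffected for
#' filtering). `0` parent ids denote founders.
#'
#' @param path path to a whitespace-delimited PED file.
#' @param sequenced_ids optional character vector of members with genotype
#'   data (typically the VCF sample names). When `NULL` all members are
#'   marked sequenced.
#' @return A [pedigree()].
#' @export
read_ped <- function(path, sequenced_ids = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 6)
    stop("PED file must have 6 columns, found ", ncol(tab), ": ", path)
  ped <- pedigree(
    id = tab[[2]], sex = tab[[5]],
    father_id = tab[[3]], mother_id = tab[[4]],
    affected = tab[[6]] == "2",
    sequenced = if (is.null(sequenced_ids)) TRUE else tab[[2]] %in% sequenced_ids
  )
  attr(ped, "family_id") <- tab[[1]][1]
  ped
}

#' Write a pedigree as a PLINK 6-column PED file
#'
#' @param ped a [pedigree()].
#' @param path output path.
#' @param family_id family identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, family_id = "FAM1") {
  fid <- attr(ped, "family_id")
  if (is.null(fid)) fid <- family_id
  out <- data.frame(
    fid = fid, id = ped$id,
    father = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(is.na(ped$sex), 0L, ped$sex),
    phen = ifelse(ped$affected, 2L, 1L)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pedigree role sets
#'
#' Helpers deriving the member sets the segregation logic needs.
#' `affected_members()` returns affected ids; `obligate_carriers()` the
#' unaffected parents of at least one affected member (expected heterozygous
#' under recessive inheritance); `unaffected_siblings()` the unaffected
#' non-parent members (must not be homozygous for a recessive causal allele).
#'
#' @param ped a [pedigree()].
#' @param sequenced_only restrict to members with genotype data.
#' @return Character vector of member ids.
#' @export
affected_members <- function(ped, sequenced_only = TRUE) {
  keep <- ped$affected & (!sequenced_only | ped$sequenced)
  ped$id[keep]
}

#' @rdname affected_members
#' @export
obligate_carriers <- function(ped, sequenced_only = TRUE) {
  aff <- ped$id[ped$affected]
  parents <- unique(stats::na.omit(c(ped$father_id[ped$id %in% aff],
                                     ped$mother_id[ped$id %in% aff])))
  keep <- ped$id %in% parents & !ped$affected & (!sequenced_only | ped$sequenced)
  ped$id[keep]
}

#' @rdname affected_members
#' @export
unaffected_siblings <- function(ped, sequenced_only = TRUE) {
  carriers <- obligate_carriers(ped, sequenced_only = FALSE)
  all_parents <- unique(stats::na.omit(c(ped$father_id, ped$mother_id)))
  keep <- !ped$affected & !(ped$id %in% all_parents) &
    (!sequenced_only | ped$sequenced)
  ped$id[keep]
}

#' Quartet pedigree matching the studied family design
#'
#' Two affected sisters and their parents; only the mother and the sisters
#' are sequenced by default (the father was unavailable for exome
#' sequencing).
#'
#' @param sequence_father mark the father as sequenced.
#' @return A [pedigree()].
#' @export
quartet_pedigree <- function(sequence_father = FALSE) {
  pedigree(
    id = c("father", "mother", "sister1", "sister2"),
    sex = c(1, 2, 2, 2),
    father_id = c(NA, NA, "father", "father"),
    mother_id = c(NA, NA, "mother", "mother"),
    affected = c(FALSE, FALSE, TRUE, TRUE),
    sequenced = c(sequence_father, TRUE, TRUE, TRUE)
  )
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "members (",
      sum(x$affected), "affected,", sum(x$sequenced), "sequenced )\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
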