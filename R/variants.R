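#' Region and consequence vocabularies
#'
#' `region_classes()` enumerates the genic region classes used throughout the
#' package; `consequence_classes()` the coding-consequence classes.
#'
#' @return Character vector of class names.
#' @export
region_classes <- function() {
  c("upstream", "utr5", "coding_exon", "splice", "deep_intron",
    "utr3", "downstream", "intergenic")
}

#' @rdname region_classes
#' @export
consequence_classes <- function() {
  c("none", "synonymous", "missense", "stop_gain", "stop_loss",
    "frameshift", "inframe_indel", "splice_site")
}

#' Construct a variant set
#'
#' The package's central container: a site table (one row per normalized
#' bi-allelic variant) plus a long genotype-call table (one row per variant
#' per sequenced sample). Multi-allelic records are split upstream, so each
#' site carries exactly one alternate allele.
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `id`
#'   (dbSNP id or `NA`), `ref`, `alt`, `qual`, and the annotation columns
#'   `gene`, `region_class`, `consequence`, `hgvs_c`, `hgvs_p`,
#'   `pathogenic`, `internal_freq`, plus one `maf_<db>` column per
#'   population database (values in \[0,1\], `NA` = not observed). Missing
#'   annotation columns are added as `NA`. A `vid` key column is added if
#'   absent.
#' @param calls data frame with columns `vid`, `sample`, `a1`, `a2`
#'   (allele indices, 0 = reference, `NA` = missing call), `ad_ref`,
#'   `ad_alt`, `dp`, `gq`.
#' @param samples sample names in VCF column order; defaults to the order of
#'   first appearance in `calls`.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(sites, calls, samples = NULL) {
  ann_cols <- c(gene = NA_character_, region_class = NA_character_,
                consequence = NA_character_, hgvs_c = NA_character_,
                hgvs_p = NA_character_, internal_freq = NA_real_)
  for (col in names(ann_cols))
    if (is.null(sites[[col]])) sites[[col]] <- rep(ann_cols[[col]], nrow(sites))
  if (is.null(sites$pathogenic)) sites$pathogenic <- rep(NA, nrow(sites))
  sites$pathogenic <- as.logical(sites$pathogenic)
  if (is.null(sites$id)) sites$id <- rep(NA_character_, nrow(sites))
  if (is.null(sites$vid)) sites$vid <- seq_len(nrow(sites))
  if (anyDuplicated(sites$vid) > 0) stop("duplicate vid in sites")

  if (nrow(sites) > 0) {
    if (any(sites$pos < 1)) stop("variant pos must be >= 1")
    if (any(sites$ref == sites$alt)) stop("ref must differ from alt")
    bad_rc <- !is.na(sites$region_class) &
      !(sites$region_class %in% region_classes())
    if (any(bad_rc))
      stop("unknown region_class: ", paste(unique(sites$region_class[bad_rc]), collapse = ", "))
    bad_cq <- !is.na(sites$consequence) &
      !(sites$consequence %in% consequence_classes())
    if (any(bad_cq))
      stop("unknown consequence: ", paste(unique(sites$consequence[bad_cq]), collapse = ", "))
    freq_cols <- c("internal_freq", grep("^maf_", names(sites), value = TRUE))
    for (col in freq_cols) {
      v <- sites[[col]]
      if (any(!is.na(v) & (v < 0 | v > 1)))
        stop("frequencies in column ", col, " must lie in [0,1]")
    }
  }
  if (nrow(calls) > 0) {
    if (!all(calls$vid %in% sites$vid))
      stop("calls reference unknown vid")
    bad_allele <- (!is.na(calls$a1) & !(calls$a1 %in% 0:1)) |
      (!is.na(calls$a2) & !(calls$a2 %in% 0:1))
    if (any(bad_allele)) stop("allele indices must be 0 or 1 after splitting")
    with_ad <- !is.na(calls$ad_ref) & !is.na(calls$ad_alt) & !is.na(calls$dp)
    if (any(with_ad & calls$dp < pmax(calls$ad_ref, calls$ad_alt)))
      stop("total depth below max allelic depth")
  }
  if (is.null(samples)) samples <- unique(calls$sample)
  structure(list(sites = sites, calls = calls, samples = as.character(samples)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$sites), "sites x", length(x$samples),
      "samples (", paste(x$samples, collapse = ", "), ")\n")
  invisible(x)
}

#' Number of sites in a variant set
#' @param vs a [variant_set()].
#' @return Integer count of sites.
#' @export
n_variants <- function(vs) nrow(vs$sites)

#' Subset a variant set by site
#'
#' @param vs a [variant_set()].
#' @param keep logical vector over sites, or a vector of `vid` keys.
#' @return A `variant_set` containing the selected sites and their calls.
#' @export
subset_variants <- function(vs, keep) {
  vids <- if (is.logical(keep)) vs$sites$vid[keep] else keep
  sites <- vs$sites[vs$sites$vid %in% vids, , drop = FALSE]
  calls <- vs$calls[vs$calls$vid %in% vids, , drop = FALSE]
  rownames(sites) <- NULL
  rownames(calls) <- NULL
  variant_set(sites, calls, samples = vs$samples)
}

# genotype predicates on the calls table
is_het <- function(calls) !is.na(calls$a1) & !is.na(calls$a2) & (calls$a1 + calls$a2 == 1L)
is_hom_alt <- function(calls) !is.na(calls$a1) & !is.na(calls$a2) & calls$a1 == 1L & calls$a2 == 1L
has_alt <- function(calls) (!is.na(calls$a1) & calls$a1 == 1L) | (!is.na(calls$a2) & calls$a2 == 1L)

# vids for which `pred` holds in every sample of `ids` (missing call = FALSE)
vids_where_all <- function(vs, ids, pred) {
  if (length(ids) == 0) return(vs$sites$vid)
  cc <- vs$calls[vs$calls$sample %in% ids, , drop = FALSE]
  ok <- pred(cc)
  n_ok <- tapply(ok, factor(cc$vid, levels = vs$sites$vid), sum, default = 0L)
  vs$sites$vid[n_ok == length(ids)]
}

# vids for which `pred` holds in at least one sample of `ids`
vids_where_any <- function(vs, ids, pred) {
  cc <- vs$calls[vs$calls$sample %in% ids, , drop = FALSE]
  unique(cc$vid[pred(cc)])
}

#' Population-frequency column names of a variant set
#' @param vs a [variant_set()].
#' @return Database names (the `maf_` prefix stripped).
#' @export
population_dbs <- function(vs) {
  sub("^maf_", "", grep("^maf_", names(vs$sites), value = TRUE))
}
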