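#' Filter configuration for the prioritization funnel
#'
#' Defaults mirror standard recessive-disease exome filtering in a
#' consanguineous family: per-sample depth of at least 5 reads, site
#' quality of at least 20, minor allele frequency below 1% in every
#' population database and in the internal cohort, and a high-impact
#' consequence class (truncating, frameshift, canonical splice, or
#' missense flagged pathogenic).
#'
#' @param min_depth minimum per-sample read depth (reads).
#' @param min_site_quality minimum phred-scaled site quality.
#' @param maf_threshold population MAF threshold (variants pass if below
#'   it in every configured database; absent = not observed = pass).
#' @param population_dbs database names, matched to `maf_<db>` columns.
#' @param internal_freq_threshold internal cohort frequency threshold.
#' @param high_impact_classes consequence classes kept by the impact
#'   filter.
#' @param pathogenic_missense also keep missense variants carrying the
#'   pathogenicity flag.
#' @param inheritance inheritance model; only `"recessive_homozygous"` is
#'   implemented (the field is an extension point).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 5, min_site_quality = 20,
                          maf_threshold = 0.01,
                          population_dbs = c("evs", "g1000", "exac"),
                          internal_freq_threshold = 0.01,
                          high_impact_classes = c("stop_gain", "stop_loss",
                                                  "frameshift", "splice_site"),
                          pathogenic_missense = TRUE,
                          inheritance = "recessive_homozygous") {
  stopifnot(min_depth >= 0, min_site_quality >= 0,
            maf_threshold >= 0, maf_threshold <= 1,
            internal_freq_threshold >= 0, internal_freq_threshold <= 1)
  if (!identical(inheritance, "recessive_homozygous"))
    stop("unsupported inheritance model: ", inheritance)
  structure(list(min_depth = min_depth, min_site_quality = min_site_quality,
                 maf_threshold = maf_threshold, population_dbs = population_dbs,
                 internal_freq_threshold = internal_freq_threshold,
                 high_impact_classes = high_impact_classes,
                 pathogenic_missense = pathogenic_missense,
                 inheritance = inheritance),
            class = "filter_config")
}

#' Read a filter configuration from a key=value file
#'
#' Recognized keys are the arguments of [filter_config()]; list-valued
#' keys (`population_dbs`, `high_impact_classes`) take comma-separated
#' values. Unrecognized keys are an error.
#'
#' @param path configuration file.
#' @return A [filter_config()].
#' @export
read_filter_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), character(1)))
  args <- list()
  for (i in seq_along(keys)) {
    args[[keys[i]]] <- switch(keys[i],
      min_depth = , min_site_quality = , maf_threshold = ,
      internal_freq_threshold = as.numeric(vals[i]),
      population_dbs = , high_impact_classes =
        trimws(strsplit(vals[i], ",", fixed = TRUE)[[1]]),
      pathogenic_missense = as.logical(vals[i]),
      inheritance = vals[i],
      stop("unknown configuration key: ", keys[i]))
  }
  do.call(filter_config, args)
}

#' Quality gate: site quality and per-sample depth
#'
#' Keeps variants whose site quality meets the threshold and whose total
#' read depth meets the minimum in every sequenced family member (a
#' missing call or missing depth fails). Runs before the funnel's printed
#' stages, as call sets are normally quality-gated before filtering.
#'
#' @param vs a [variant_set()].
#' @param ped a [pedigree()]; at least one sequenced member required.
#' @param cfg a [filter_config()].
#' @return Filtered `variant_set`.
#' @export
quality_filter <- function(vs, ped, cfg = filter_config()) {
  seq_ids <- intersect(ped$id[ped$sequenced], vs$samples)
  if (length(seq_ids) == 0) stop("no sequenced members with genotype data")
  qual_ok <- !is.na(vs$sites$qual) & vs$sites$qual >= cfg$min_site_quality
  depth_ok_vids <- vids_where_all(vs, seq_ids, function(cc)
    !is.na(cc$dp) & cc$dp >= cfg$min_depth)
  subset_variants(vs, qual_ok & vs$sites$vid %in% depth_ok_vids)
}

#' Shared-in-affecteds filter
#'
#' Keeps variants where every sequenced affected member carries at least
#' one alternate allele. With fewer than two sequenced affecteds the
#' filter warns and passes everything through.
#'
#' @inheritParams quality_filter
#' @return Filtered `variant_set`.
#' @export
shared_in_affecteds <- function(vs, ped) {
  aff <- intersect(affected_members(ped), vs$samples)
  if (length(aff) < 2) {
    warning("fewer than two sequenced affected members; ",
            "shared-in-affecteds filter passes all variants")
    return(vs)
  }
  keep <- vids_where_all(vs, aff, has_alt)
  subset_variants(vs, keep)
}

#' Region filter: coding sequence or splice
#'
#' @param vs a [variant_set()] with region classes set.
#' @return Variants with region class `coding_exon` or `splice`.
#' @export
region_filter <- function(vs) {
  keep <- !is.na(vs$sites$region_class) &
    vs$sites$region_class %in% c("coding_exon", "splice")
  subset_variants(vs, keep)
}

#' Non-synonymous filter
#'
#' Removes synonymous coding variants; splice-site and all other
#' consequence classes are retained.
#'
#' @param vs a [variant_set()] with consequences set.
#' @return Filtered `variant_set`.
#' @export
nonsynonymous_filter <- function(vs) {
  keep <- is.na(vs$sites$consequence) | vs$sites$consequence != "synonymous"
  subset_variants(vs, keep)
}

# the two genotype-pattern components of the recessive segregation rule
hom_in_affecteds_vids <- function(vs, ped) {
  aff <- intersect(affected_members(ped), vs$samples)
  vids_where_all(vs, aff, is_hom_alt)
}

het_in_carriers_vids <- function(vs, ped) {
  carriers <- intersect(obligate_carriers(ped), vs$samples)
  sibs <- intersect(unaffected_siblings(ped), vs$samples)
  keep <- vids_where_all(vs, carriers, is_het)
  if (length(sibs) > 0) {
    bad <- vids_where_any(vs, sibs, is_hom_alt)
    keep <- setdiff(keep, bad)
  }
  keep
}

#' Recessive segregation filter
#'
#' Under the recessive-homozygous model, keeps variants homozygous for the
#' alternate allele in every sequenced affected member and heterozygous in
#' every sequenced obligate carrier (unaffected parent of an affected);
#' sequenced unaffected siblings must not be homozygous for the alternate
#' allele. Unsequenced members impose no constraint.
#'
#' @inheritParams quality_filter
#' @return Filtered `variant_set`.
#' @export
segregation_filter <- function(vs, ped, cfg = filter_config()) {
  if (length(intersect(ped$id[ped$sequenced & !ped$affected], vs$samples)) == 0)
    warning("no sequenced unaffected members; segregation filter ",
            "constrains affecteds only")
  keep <- intersect(hom_in_affecteds_vids(vs, ped),
                    het_in_carriers_vids(vs, ped))
  subset_variants(vs, keep)
}

# population-database predicate; absent annotation counts as rare
maf_pass <- function(sites, dbs, threshold) {
  pass <- rep(TRUE, nrow(sites))
  for (db in dbs) {
    col <- paste0("maf_", db)
    if (is.null(sites[[col]])) next  # database never annotated: all pass
    v <- sites[[col]]
    pass <- pass & (is.na(v) | v < threshold)
  }
  pass
}

#' Population and internal frequency filter
#'
#' Keeps variants rarer than the MAF threshold in every configured
#' population database (a variant absent from a database counts as rare,
#' matching discovery behaviour for novel alleles), then applies the
#' internal-cohort frequency threshold.
#'
#' @param vs a [variant_set()].
#' @param cfg a [filter_config()].
#' @return Filtered `variant_set`.
#' @export
frequency_filter <- function(vs, cfg = filter_config()) {
  keep <- maf_pass(vs$sites, cfg$population_dbs, cfg$maf_threshold)
  intern <- vs$sites$internal_freq
  keep <- keep & (is.na(intern) | intern < cfg$internal_freq_threshold)
  subset_variants(vs, keep)
}

#' High-impact filter
#'
#' Keeps variants whose consequence class is in the configured
#' high-impact set, plus (by default) missense variants flagged
#' pathogenic.
#'
#' @param vs a [variant_set()].
#' @param cfg a [filter_config()].
#' @return Filtered `variant_set`.
#' @export
impact_filter <- function(vs, cfg = filter_config()) {
  cq <- vs$sites$consequence
  keep <- !is.na(cq) & cq %in% cfg$high_impact_classes
  if (isTRUE(cfg$pathogenic_missense))
    keep <- keep | (!is.na(cq) & cq == "missense" & !is.na(vs$sites$pathogenic) &
                      vs$sites$pathogenic)
  subset_variants(vs, keep)
}

#' Run the full prioritization funnel
#'
#' Applies the filter cascade in fixed order — quality gate, shared in
#' affecteds, coding/splice region, non-synonymous, homozygous in
#' affecteds, heterozygous in carriers (with the sibling exclusion),
#' population MAF, internal cohort frequency, high impact — recording the
#' surviving-variant count after each stage. The segregation and
#' frequency filters each contribute two printed stages, giving the
#' familiar eight-row funnel after the quality gate.
#'
#' @inheritParams quality_filter
#' @return A list of class `filter_funnel` with `stages` (data frame
#'   `stage`, `n`), `candidates` (the surviving [variant_set()]), and
#'   `totals` (per-sample counts of variants carrying an alternate
#'   allele, before filtering).
#' @export
run_funnel <- function(vs, ped, cfg = filter_config()) {
  totals <- vapply(vs$samples, function(s) {
    cc <- vs$calls[vs$calls$sample == s, , drop = FALSE]
    sum(has_alt(cc))
  }, integer(1))

  stages <- character(0); counts <- integer(0)
  push <- function(name, v) {
    stages <<- c(stages, name); counts <<- c(counts, n_variants(v)); v
  }
  v <- push("quality_pass", quality_filter(vs, ped, cfg))
  v <- push("shared_in_affecteds", suppressWarnings(shared_in_affecteds(v, ped)))
  v <- push("coding_or_splice", region_filter(v))
  v <- push("non_synonymous", nonsynonymous_filter(v))
  v <- push("hom_alt_in_affecteds",
            subset_variants(v, intersect(v$sites$vid, hom_in_affecteds_vids(v, ped))))
  v <- push("het_in_carriers",
            subset_variants(v, intersect(v$sites$vid, het_in_carriers_vids(v, ped))))
  v <- push("maf_below_threshold",
            subset_variants(v, maf_pass(v$sites, cfg$population_dbs, cfg$maf_threshold)))
  intern <- function(x) is.na(x) | x < cfg$internal_freq_threshold
  v <- push("internal_freq_below_threshold",
            subset_variants(v, intern(v$sites$internal_freq)))
  v <- push("high_impact", impact_filter(v, cfg))

  structure(list(
    stages = data.frame(stage = stages, n = counts, stringsAsFactors = FALSE),
    candidates = v,
    totals = totals),
    class = "filter_funnel")
}

#' @export
print.filter_funnel <- function(x, ...) {
  cat("Variant filter funnel\n")
  if (length(x$totals))
    cat("  called variants per sample:",
        paste(names(x$totals), x$totals, sep = "=", collapse = ", "), "\n")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-30s %d\n", x$stages$stage[i], x$stages$n[i]))
  invisible(x)
}
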