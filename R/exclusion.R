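#' Mean sequencing depth of a gene for one sample
#'
#' The per-exon mean depths are averaged, unweighted, over all exons of
#' the gene.
#'
#' @param cov a coverage table ([read_coverage()]).
#' @param gene gene symbol.
#' @param sample sample id.
#' @return Mean depth in reads; `NA` when the gene/sample has no coverage
#'   records (insufficient evidence).
#' @export
gene_mean_depth <- function(cov, gene, sample) {
  d <- cov$mean_depth[cov$gene == gene & cov$sample == sample]
  if (length(d) == 0) return(NA_real_)
  mean(d)
}

#' Heterozygous-variant presence in affected members
#'
#' TRUE when at least one variant in the gene is called heterozygous in
#' at least one sequenced affected member — which excludes hemizygosity
#' (a heterozygous deletion) over the gene in that individual.
#'
#' @param vs a [variant_set()].
#' @param gene gene symbol.
#' @param ped a [pedigree()].
#' @return Logical.
#' @export
het_presence <- function(vs, gene, ped) {
  g <- subset_variants(vs, !is.na(vs$sites$gene) & vs$sites$gene == gene)
  aff <- intersect(affected_members(ped), vs$samples)
  length(vids_where_any(g, aff, is_het)) > 0
}

#' Mean allelic read ratio over heterozygous calls in affecteds
#'
#' For every heterozygous call with allelic depths in a sequenced
#' affected member, the ratio of alternate to reference reads is taken;
#' ratios are averaged over all such calls pooled across the affecteds.
#' The ratio is directional (alt/ref), so values scatter both below and
#' above 1; a mean near 1 indicates balanced alleles and argues against a
#' deletion. Calls with zero reference reads are skipped with a warning.
#'
#' @inheritParams het_presence
#' @return Mean ratio, or `NA` if no usable heterozygous call exists.
#' @export
mean_allelic_ratio <- function(vs, gene, ped) {
  g <- subset_variants(vs, !is.na(vs$sites$gene) & vs$sites$gene == gene)
  aff <- intersect(affected_members(ped), vs$samples)
  cc <- g$calls[g$calls$sample %in% aff, , drop = FALSE]
  cc <- cc[is_het(cc) & !is.na(cc$ad_ref) & !is.na(cc$ad_alt), , drop = FALSE]
  if (nrow(cc) == 0) return(NA_real_)
  zero_ref <- cc$ad_ref == 0
  if (any(zero_ref)) {
    warning(sum(zero_ref), " heterozygous call(s) with zero reference reads ",
            "skipped in ", gene)
    cc <- cc[!zero_ref, , drop = FALSE]
  }
  if (nrow(cc) == 0) return(NA_real_)
  mean(cc$ad_alt / cc$ad_ref)
}

#' Regional presence of family variants in a gene
#'
#' Presence of called variants across the non-coding genic portions
#' (upstream, 5'UTR, deep intronic, 3'UTR, downstream) argues against a
#' partial deletion of the gene.
#'
#' @param vs a [variant_set()].
#' @param gene gene symbol.
#' @return Named logical vector over the five region classes.
#' @export
regional_presence <- function(vs, gene) {
  classes <- c("upstream", "utr5", "deep_intron", "utr3", "downstream")
  in_gene <- !is.na(vs$sites$gene) & vs$sites$gene == gene
  stats::setNames(
    vapply(classes, function(cl)
      any(in_gene & !is.na(vs$sites$region_class) & vs$sites$region_class == cl),
      logical(1)),
    classes)
}

#' Count correctly segregating, rare, pathogenic variants in a gene
#'
#' Number of variants in the gene that pass the recessive segregation
#' filter, the population/internal frequency filter and the high-impact
#' filter (the funnel's decisive stages restricted to one gene).
#'
#' @inheritParams het_presence
#' @param cfg a [filter_config()].
#' @return Integer count.
#' @export
count_segregating_rare_pathogenic <- function(vs, gene, ped, cfg = filter_config()) {
  g <- subset_variants(vs, !is.na(vs$sites$gene) & vs$sites$gene == gene)
  if (n_variants(g) == 0) return(0L)
  g <- suppressWarnings(segregation_filter(g, ped, cfg))
  g <- frequency_filter(g, cfg)
  g <- impact_filter(g, cfg)
  n_variants(g)
}

# reciprocal overlap of two half-open intervals
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  if (ov == 0) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Segregation filter for copy-number variants
#'
#' A CNV is disease-compatible only if the same event — same state and at
#' least `min_reciprocal` reciprocal overlap — is present in every
#' sequenced affected member and absent from every sequenced unaffected
#' member. All other calls are discarded as unrelated to the phenotype
#' (not shared by the affecteds, or carried by an unaffected member).
#'
#' @param cnvs a CNV table ([read_cnv()]).
#' @param ped a [pedigree()].
#' @param min_reciprocal reciprocal-overlap fraction defining "the same
#'   CNV" across samples.
#' @return The retained rows of `cnvs` (calls in affected members that
#'   segregate with disease).
#' @export
cnv_segregation_filter <- function(cnvs, ped, min_reciprocal = 0.5) {
  aff <- affected_members(ped)
  unaff <- ped$id[ped$sequenced & !ped$affected]
  if (nrow(cnvs) == 0 || length(aff) == 0)
    return(cnvs[integer(0), , drop = FALSE])
  matches_in <- function(row, sample_ids) {
    sub <- cnvs[cnvs$sample %in% sample_ids & cnvs$chrom == row$chrom &
                  cnvs$state == row$state, , drop = FALSE]
    vapply(sample_ids, function(s) {
      ss <- sub[sub$sample == s, , drop = FALSE]
      any(vapply(seq_len(nrow(ss)), function(j)
        reciprocal_overlap(row$start, row$end, ss$start[j], ss$end[j]) >= min_reciprocal,
        logical(1)))
    }, logical(1))
  }
  keep <- vapply(seq_len(nrow(cnvs)), function(i) {
    row <- cnvs[i, ]
    if (!(row$sample %in% aff)) return(FALSE)
    all(matches_in(row, aff)) && !any(matches_in(row, unaff))
  }, logical(1))
  cnvs[keep, , drop = FALSE]
}

#' Summarize coverage depth
#'
#' @param per_base_depths numeric vector of per-base read depths.
#' @param threshold depth threshold for the covered-fraction statistic.
#' @return Named numeric vector: `mean_depth`, and `pct_at_or_above` (100
#'   times the fraction of bases with depth at or above the threshold).
#' @export
coverage_summary <- function(per_base_depths, threshold = 25) {
  if (length(per_base_depths) == 0)
    return(c(mean_depth = NA_real_, pct_at_or_above = NA_real_))
  c(mean_depth = mean(per_base_depths),
    pct_at_or_above = 100 * mean(per_base_depths >= threshold))
}

#' Build the candidate-gene exclusion report
#'
#' One row of evidence per panel gene: mean exon depth per sequenced
#' sample (coverage adequacy), family variant count, heterozygous-variant
#' presence in affecteds (excludes hemizygosity), mean allelic read ratio
#' with an unbiased-band flag, regional variant presence (argues against
#' partial deletions), the count of correctly segregating rare pathogenic
#' variants, and overlap with disease-compatible CNVs.
#'
#' Verdicts: `candidate` when at least one segregating rare pathogenic
#' variant exists; `excluded` when there is none, hemizygosity is ruled
#' out (heterozygous variants present, or no family variants at all),
#' coverage is adequate in every sequenced sample, and no retained CNV
#' overlaps the gene; `insufficient_evidence` otherwise (including genes
#' absent from the coverage table).
#'
#' @param vs a [variant_set()] of family calls.
#' @param cov coverage table.
#' @param cnvs CNV table.
#' @param ped a [pedigree()].
#' @param panel data frame with `gene` and optional `alias`.
#' @param cfg a [filter_config()].
#' @param adequacy_depth minimum mean gene depth (reads) counted as
#'   adequate coverage.
#' @param unbiased_band allelic-ratio interval reported as unbiased.
#' @return Data frame of class `exclusion_report`, one row per panel
#'   gene.
#' @export
build_exclusion_report <- function(vs, cov, cnvs, ped, panel,
                                   cfg = filter_config(),
                                   adequacy_depth = 30,
                                   unbiased_band = c(0.7, 1.4)) {
  seq_ids <- intersect(ped$id[ped$sequenced], vs$samples)
  retained_cnvs <- cnv_segregation_filter(cnvs, ped)
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    g <- panel$gene[i]
    depths <- vapply(seq_ids, function(s) gene_mean_depth(cov, g, s), numeric(1))
    n_fam <- sum(!is.na(vs$sites$gene) & vs$sites$gene == g)
    het <- het_presence(vs, g, ped)
    ratio <- suppressWarnings(mean_allelic_ratio(vs, g, ped))
    reg <- regional_presence(vs, g)
    n_seg <- count_segregating_rare_pathogenic(vs, g, ped, cfg)
    gene_iv <- cov[cov$gene == g, , drop = FALSE]
    cnv_hit <- FALSE
    if (nrow(retained_cnvs) > 0 && nrow(gene_iv) > 0) {
      glo <- min(gene_iv$start); ghi <- max(gene_iv$end)
      gchrom <- gene_iv$chrom[1]
      cnv_hit <- any(retained_cnvs$chrom == gchrom &
                       retained_cnvs$start < ghi & retained_cnvs$end > glo)
    }
    covered <- length(depths) > 0 && !anyNA(depths) && all(depths >= adequacy_depth)
    verdict <-
      if (n_seg >= 1) "candidate"
      else if (length(depths) == 0 || anyNA(depths)) "insufficient_evidence"
      else if ((het || n_fam == 0) && covered && !cnv_hit) "excluded"
      else "insufficient_evidence"
    out <- data.frame(gene = g, alias = panel$alias[i],
                      n_family_variants = n_fam,
                      het_in_any_affected = het,
                      mean_allelic_ratio = ratio,
                      ratio_unbiased = !is.na(ratio) &
                        ratio >= unbiased_band[1] & ratio <= unbiased_band[2],
                      n_segregating_rare_pathogenic = n_seg,
                      cnv_overlap = cnv_hit,
                      verdict = verdict,
                      stringsAsFactors = FALSE)
    for (s in seq_ids) out[[paste0("depth_", s)]] <- depths[[s]]
    for (cl in names(reg)) out[[paste0("present_", cl)]] <- reg[[cl]]
    out
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  class(rep) <- c("exclusion_report", "data.frame")
  rep
}
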