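#' Render the filter funnel as TSV text
#'
#' Two columns, `filter` and `n_variants`, one row per post-quality-gate
#' funnel stage (the familiar eight-row layout), preceded by optional
#' per-sample total rows and the quality-gate row. The text parses back
#' with [parse_funnel_tsv()].
#'
#' @param funnel a `filter_funnel` from [run_funnel()].
#' @param include_totals prepend `total_<sample>` rows with the
#'   per-sample called-variant counts and the quality gate row.
#' @return A single TSV string.
#' @export
render_funnel <- function(funnel, include_totals = TRUE) {
  rows <- funnel$stages
  if (include_totals && length(funnel$totals) > 0) {
    rows <- rbind(
      data.frame(stage = paste0("total_", names(funnel$totals)),
                 n = as.integer(funnel$totals), stringsAsFactors = FALSE),
      rows)
  } else {
    rows <- rows[rows$stage != "quality_pass", , drop = FALSE]
  }
  paste0(paste(c("filter\tn_variants",
                 sprintf("%s\t%d", rows$stage, rows$n)), collapse = "\n"), "\n")
}

#' @rdname render_funnel
#' @param text TSV text produced by `render_funnel`.
#' @return For `parse_funnel_tsv`, a data frame `stage`, `n`.
#' @export
parse_funnel_tsv <- function(text) {
  tab <- utils::read.table(text = text, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab) <- c("stage", "n")
  tab
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

#' Render the gene-exclusion report as TSV text
#'
#' One row per panel gene with the evidence columns of
#' [build_exclusion_report()] (depths, variant counts, heterozygosity,
#' allelic ratio, regional presence flags, segregating-variant count,
#' CNV overlap, verdict). Numbers are formatted at fixed precision;
#' the text parses back with [parse_exclusion_tsv()].
#'
#' @param report an `exclusion_report`.
#' @return A single TSV string.
#' @export
render_exclusion <- function(report) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "n_family_variants" &
    names(df) != "n_segregating_rare_pathogenic"
  for (col in names(df)[num]) df[[col]] <- fmt_num(df[[col]])
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @rdname render_exclusion
#' @param text TSV text produced by `render_exclusion`.
#' @return For `parse_exclusion_tsv`, a data frame.
#' @export
parse_exclusion_tsv <- function(text) {
  utils::read.table(text = text, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Render per-sample sequencing metrics as TSV text
#'
#' @param metrics data frame with columns `sample`, `mean_depth`,
#'   `pct_at_or_above` (see [coverage_summary()]).
#' @return A single TSV string with depth to one decimal and percentage
#'   to one decimal.
#' @export
render_metrics <- function(metrics) {
  lines <- c("sample\tmean_depth\tpct_at_or_above",
             sprintf("%s\t%.1f\t%.1f", metrics$sample, metrics$mean_depth,
                     metrics$pct_at_or_above))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Percent growth of treated relative to untreated cells
#'
#' Growth = 100 x (final treated cell count) / (final untreated cell
#' count). A cytotoxicity summary unrelated to the exome pipeline,
#' included as a reporting utility for the drug-sensitivity assays that
#' typically accompany DNA-repair gene findings.
#'
#' @param treated_count final cell count in the treated culture.
#' @param untreated_count final cell count in the untreated culture;
#'   must be positive.
#' @return Percent growth.
#' @export
compute_growth_inhibition <- function(treated_count, untreated_count) {
  if (any(untreated_count <= 0)) stop("untreated_count must be positive")
  100 * treated_count / untreated_count
}
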