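#' Read a per-exon coverage table
#'
#' BED-like, tab-separated, 0-based half-open intervals:
#' `chrom  start  end  gene  exon_index  mean_depth  sample`.
#'
#' @param path coverage file.
#' @return Data frame of class `coverage_table` with those columns.
#' @export
read_coverage <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("chrom", "start", "end", "gene",
                                         "exon", "mean_depth", "sample"))
  check_intervals(tab, path)
  if (any(tab$mean_depth < 0)) stop("negative mean_depth in ", path)
  class(tab) <- c("coverage_table", "data.frame")
  tab
}

#' @rdname read_coverage
#' @param cov a coverage table.
#' @return For `write_coverage`, `path` invisibly.
#' @export
write_coverage <- function(cov, path) {
  utils::write.table(cov[, c("chrom", "start", "end", "gene", "exon",
                             "mean_depth", "sample")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a copy-number variant call table
#'
#' BED-like, tab-separated, 0-based half-open intervals:
#' `chrom  start  end  sample  state` with state `loss` or `gain`.
#'
#' @param path CNV file.
#' @return Data frame of class `cnv_table`.
#' @export
read_cnv <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("chrom", "start", "end", "sample", "state"))
  check_intervals(tab, path)
  if (!all(tab$state %in% c("loss", "gain")))
    stop("CNV state must be 'loss' or 'gain' in ", path)
  class(tab) <- c("cnv_table", "data.frame")
  tab
}

#' @rdname read_cnv
#' @param cnvs a CNV table.
#' @return For `write_cnv`, `path` invisibly.
#' @export
write_cnv <- function(cnvs, path) {
  utils::write.table(cnvs[, c("chrom", "start", "end", "sample", "state")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_intervals <- function(tab, path) {
  if (nrow(tab) > 0 && any(tab$end <= tab$start))
    stop("interval end <= start at line ",
         which(tab$end <= tab$start)[1], " of ", path)
  invisible(TRUE)
}

#' Read a gene panel file
#'
#' One gene per line: `gene` optionally followed by an alias symbol,
#' tab- or whitespace-separated.
#'
#' @param path panel file.
#' @return Data frame with columns `gene`, `alias` (`NA` when absent).
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(trimws(lines), "[ \t]+")
  data.frame(
    gene = vapply(parts, `[`, character(1), 1),
    alias = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                   character(1)),
    stringsAsFactors = FALSE)
}

#' @rdname read_panel
#' @param panel data frame with `gene` and optional `alias`.
#' @return For `write_panel`, `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  lines <- ifelse(is.na(panel$alias), panel$gene,
                  paste(panel$gene, panel$alias, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
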