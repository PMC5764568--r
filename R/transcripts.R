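#' Construct a transcript model
#'
#' Exon structure plus CDS bounds for one transcript, the substrate for
#' genomic-to-cDNA mapping and coding-consequence calls. Intervals use the
#' package's internal 0-based half-open convention (BED-native); variant
#' positions handed to the mapping functions are 1-based (VCF-native) and
#' converted internally.
#'
#' @param gene gene symbol.
#' @param transcript_id transcript identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column integer matrix of 0-based half-open genomic
#'   intervals, sorted, non-overlapping (genomic order regardless of strand).
#' @param cds_start,cds_end 0-based half-open genomic bounds of the CDS.
#' @param chrom_seq optional chromosome sequence (character); required for
#'   consequence annotation.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene, transcript_id, chrom, strand, exons,
                             cds_start, cds_end, chrom_seq = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  t <- structure(
    list(gene = gene, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         chrom_seq = chrom_seq),
    class = "transcript_model")
  validate_transcript(t, warn = FALSE)
  t
}

#' Validate a transcript model
#'
#' Structural defects (unsorted/overlapping exons, CDS outside exons, CDS
#' length not a multiple of 3) are errors; a CDS that does not begin with
#' ATG or end with a stop codon only raises a warning, since truncated or
#' non-canonical models occur in real annotation.
#'
#' @param t a [transcript_model()].
#' @param warn emit warnings for the soft checks (needs `chrom_seq`).
#' @return `t`, invisibly; errors on structural defects.
#' @export
validate_transcript <- function(t, warn = TRUE) {
  ex <- t$exons
  if (!(t$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (nrow(ex) == 0) stop("transcript has no exons")
  if (any(ex[, 1] >= ex[, 2])) stop("exon end must exceed start")
  if (nrow(ex) > 1) {
    if (is.unsorted(ex[, 1], strictly = TRUE)) stop("exons must be sorted")
    if (any(ex[-1, 1] < ex[-nrow(ex), 2])) stop("exons overlap")
  }
  if (t$cds_start >= t$cds_end) stop("empty CDS")
  if (t$cds_start < min(ex[, 1]) || t$cds_end > max(ex[, 2]))
    stop("CDS outside exon span")
  cds_len <- sum(pmax(0L, pmin(ex[, 2], t$cds_end) - pmax(ex[, 1], t$cds_start)))
  if (cds_len %% 3L != 0L)
    stop("CDS length ", cds_len, " not divisible by 3")
  if (warn && !is.null(t$chrom_seq)) {
    cds <- coding_sequence(t)
    if (substr(cds, 1, 3) != "ATG")
      warning("CDS of ", t$transcript_id, " does not begin with ATG")
    if (!(substr(cds, nchar(cds) - 2, nchar(cds)) %in% c("TAA", "TAG", "TGA")))
      warning("CDS of ", t$transcript_id, " does not end with a stop codon")
  }
  invisible(t)
}

# coding exon pieces: exons clipped to CDS bounds, genomic order
coding_pieces <- function(t) {
  s <- pmax(t$exons[, 1], t$cds_start)
  e <- pmin(t$exons[, 2], t$cds_end)
  keep <- s < e
  cbind(start = s[keep], end = e[keep])
}

#' Spliced, strand-corrected coding sequence of a transcript
#'
#' @param t a [transcript_model()] with `chrom_seq`.
#' @return The CDS as an uppercase character string, 5' to 3' on the coding
#'   strand.
#' @export
coding_sequence <- function(t) {
  if (is.null(t$chrom_seq))
    stop("transcript ", t$transcript_id, " has no chromosome sequence")
  pieces <- coding_pieces(t)
  seqs <- substring(t$chrom_seq, pieces[, 1] + 1L, pieces[, 2])
  cds <- paste(seqs, collapse = "")
  if (t$strand == "-") cds <- revcomp(cds)
  toupper(cds)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read transcript models from BED12 (plus optional FASTA)
#'
#' The BED12 `name` field is parsed as `gene|transcript_id` (plain names are
#' used for both). `thickStart`/`thickEnd` give the CDS; blocks give exons.
#'
#' @param path BED12 file.
#' @param fasta_path optional FASTA of chromosome sequences, read with
#'   [Biostrings::readDNAStringSet()]; needed for consequence annotation.
#' @return List of [transcript_model()] objects.
#' @export
read_transcripts <- function(path, fasta_path = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 12) stop("expected BED12 (12 columns), found ", ncol(tab))
  chrom_seqs <- NULL
  if (!is.null(fasta_path)) {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    chrom_seqs <- stats::setNames(as.character(ss),
                                  sub("\\s.*$", "", names(ss)))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    name <- strsplit(as.character(row[[4]]), "|", fixed = TRUE)[[1]]
    gene <- name[1]
    tx <- if (length(name) > 1) name[2] else name[1]
    n_blocks <- as.integer(row[[10]])
    sizes <- as.integer(strsplit(as.character(row[[11]]), ",")[[1]])
    starts <- as.integer(strsplit(as.character(row[[12]]), ",")[[1]])
    if (length(sizes) != n_blocks || length(starts) != n_blocks)
      stop("BED12 block count mismatch at line ", i)
    ex_start <- as.integer(row[[2]]) + starts
    exons <- cbind(ex_start, ex_start + sizes)
    if (as.integer(row[[3]]) <= as.integer(row[[2]]))
      stop("interval end <= start at line ", i)
    transcript_model(
      gene = gene, transcript_id = tx, chrom = as.character(row[[1]]),
      strand = as.character(row[[6]]), exons = exons,
      cds_start = as.integer(row[[7]]), cds_end = as.integer(row[[8]]),
      chrom_seq = if (!is.null(chrom_seqs)) chrom_seqs[[as.character(row[[1]])]]
    )
  })
}

#' Write transcript models as BED12
#'
#' @param transcripts list of [transcript_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  lines <- vapply(transcripts, function(t) {
    tx_start <- min(t$exons[, 1])
    sizes <- t$exons[, 2] - t$exons[, 1]
    starts <- t$exons[, 1] - tx_start
    paste(t$chrom, tx_start, max(t$exons[, 2]),
          paste0(t$gene, "|", t$transcript_id), 0, t$strand,
          t$cds_start, t$cds_end, 0, nrow(t$exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write chromosome sequences referenced by transcript models as FASTA
#'
#' @param transcripts list of [transcript_model()] carrying `chrom_seq`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  seqs <- list()
  for (t in transcripts)
    if (!is.null(t$chrom_seq) && is.null(seqs[[t$chrom]]))
      seqs[[t$chrom]] <- t$chrom_seq
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
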