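# three-letter amino-acid codes for HGVS p. notation
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

#' Map a genomic position onto a transcript
#'
#' Classifies a 1-based genomic position against a transcript model and,
#' for positions inside the CDS, returns the 1-based cDNA (coding) position.
#' Intronic positions within the splice window (2 bases, the canonical
#' donor/acceptor dinucleotides) of an exon-intron junction are classed
#' `splice`; deeper intronic positions `deep_intron`. Positions beyond the
#' transcript span are `upstream`/`downstream` in transcript orientation.
#' Minus-strand transcripts are handled by coordinate reflection.
#'
#' @param t a [transcript_model()].
#' @param pos 1-based genomic position on `t$chrom`.
#' @param chrom optional chromosome of the query; errors if it differs from
#'   the transcript's.
#' @param splice_window intronic bases from a junction classed as splice.
#' @return List with `region_class` (see [region_classes()]) and `cds_pos`
#'   (1-based coding position, `NA` outside the CDS).
#' @export
genomic_to_cds <- function(t, pos, chrom = NULL, splice_window = 2L) {
  if (!is.null(chrom) && chrom != t$chrom)
    stop("position on ", chrom, " but transcript on ", t$chrom)
  g <- as.integer(pos) - 1L  # 0-based
  ex <- t$exons
  tx_start <- min(ex[, 1]); tx_end <- max(ex[, 2])
  plus <- t$strand == "+"
  if (g < tx_start)
    return(list(region_class = if (plus) "upstream" else "downstream",
                cds_pos = NA_integer_))
  if (g >= tx_end)
    return(list(region_class = if (plus) "downstream" else "upstream",
                cds_pos = NA_integer_))
  in_exon <- which(ex[, 1] <= g & g < ex[, 2])
  if (length(in_exon) == 0) {
    # intronic: distance to flanking exon boundaries
    i <- max(which(ex[, 2] <= g))
    d5 <- g - ex[i, 2] + 1L        # bases past the upstream exon end
    d3 <- ex[i + 1L, 1] - g        # bases before the downstream exon start
    cls <- if (min(d5, d3) <= splice_window) "splice" else "deep_intron"
    return(list(region_class = cls, cds_pos = NA_integer_))
  }
  if (g >= t$cds_start && g < t$cds_end) {
    pieces <- coding_pieces(t)
    j <- which(pieces[, 1] <= g & g < pieces[, 2])
    if (length(j) == 1) {
      if (plus) {
        before <- if (j > 1) sum(pieces[seq_len(j - 1), 2] - pieces[seq_len(j - 1), 1]) else 0L
        cds_pos <- before + (g - pieces[j, 1]) + 1L
      } else {
        after <- if (j < nrow(pieces))
          sum(pieces[seq(j + 1, nrow(pieces)), 2] - pieces[seq(j + 1, nrow(pieces)), 1]) else 0L
        cds_pos <- after + (pieces[j, 2] - 1L - g) + 1L
      }
      return(list(region_class = "coding_exon", cds_pos = as.integer(cds_pos)))
    }
  }
  # exonic but outside the CDS: UTR, side taken in transcript orientation
  five_prime <- if (plus) g < t$cds_start else g >= t$cds_end
  list(region_class = if (five_prime) "utr5" else "utr3",
       cds_pos = NA_integer_)
}

#' Inverse of [genomic_to_cds()] for coding positions
#'
#' @param t a [transcript_model()].
#' @param cds_pos 1-based coding position.
#' @return 1-based genomic position.
#' @export
cds_to_genomic <- function(t, cds_pos) {
  pieces <- coding_pieces(t)
  lens <- pieces[, 2] - pieces[, 1]
  total <- sum(lens)
  if (cds_pos < 1 || cds_pos > total)
    stop("cds_pos ", cds_pos, " outside CDS of length ", total)
  if (t$strand == "-") {
    pieces <- pieces[rev(seq_len(nrow(pieces))), , drop = FALSE]
    lens <- rev(lens)
  }
  cum <- cumsum(lens)
  j <- which(cds_pos <= cum)[1]
  offset <- cds_pos - (if (j > 1) cum[j - 1] else 0L) - 1L  # 0-based in piece
  g <- if (t$strand == "+") pieces[j, 1] + offset else pieces[j, 2] - 1L - offset
  as.integer(g + 1L)  # back to 1-based
}

#' Annotate the coding consequence of one variant against a transcript
#'
#' Sets the region class, consequence, and HGVS c./p. descriptions for a
#' SNV or small indel. Coding SNVs are classified by codon substitution
#' (codon number = ceiling(cds position / 3)); coding indels by length
#' difference modulo 3 (frameshift vs in-frame). A premature stop codon is
#' reported as e.g. `p.Gln1701*`.
#'
#' @param chrom,pos,ref,alt the variant; `pos` 1-based, alleles on the plus
#'   (reference genome) strand.
#' @param t a [transcript_model()] with `chrom_seq`; validated first,
#'   structural failures are errors.
#' @return List with `region_class`, `consequence`, `hgvs_c`, `hgvs_p`,
#'   `gene`.
#' @examples
#' # a CAG -> TAG (Gln -> stop) substitution is reported as stop_gain
#' @export
consequence_call <- function(chrom, pos, ref, alt, t) {
  validate_transcript(t, warn = FALSE)
  if (chrom != t$chrom)
    stop("variant on ", chrom, " but transcript on ", t$chrom)
  out <- list(region_class = NA_character_, consequence = "none",
              hgvs_c = NA_character_, hgvs_p = NA_character_, gene = t$gene)
  loc <- genomic_to_cds(t, pos)
  out$region_class <- loc$region_class
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
  if (loc$region_class == "splice") {
    out$consequence <- "splice_site"
    return(out)
  }
  if (loc$region_class != "coding_exon") return(out)

  if (is_snv) {
    cds <- coding_sequence(t)
    cds_pos <- loc$cds_pos
    # alleles strand-corrected onto the coding strand
    cref <- if (t$strand == "+") toupper(ref) else revcomp(ref)
    calt <- if (t$strand == "+") toupper(alt) else revcomp(alt)
    have <- substr(cds, cds_pos, cds_pos)
    if (have != cref)
      warning("reference allele ", cref, " does not match transcript base ",
              have, " at c.", cds_pos, " of ", t$transcript_id)
    codon_number <- ceiling(cds_pos / 3)
    codon_start <- 3L * (codon_number - 1L) + 1L
    wt_codon <- substr(cds, codon_start, codon_start + 2L)
    within <- cds_pos - codon_start + 1L
    mut_codon <- wt_codon
    substr(mut_codon, within, within) <- calt
    wt_aa <- codon_aa(wt_codon)
    mut_aa <- codon_aa(mut_codon)
    out$consequence <-
      if (wt_aa == mut_aa) "synonymous"
      else if (mut_aa == "*") "stop_gain"
      else if (wt_aa == "*") "stop_loss"
      else "missense"
    out$hgvs_c <- paste0("c.", cds_pos, cref, ">", calt)
    out$hgvs_p <- switch(out$consequence,
      synonymous = paste0("p.", AA3[[wt_aa]], codon_number, "="),
      stop_gain  = paste0("p.", AA3[[wt_aa]], codon_number, "*"),
      stop_loss  = paste0("p.Ter", codon_number, AA3[[mut_aa]]),
      missense   = paste0("p.", AA3[[wt_aa]], codon_number, AA3[[mut_aa]]))
    return(out)
  }

  # coding indel: frame by length difference; simple HGVS on plus strand
  len_diff <- nchar(ref) - nchar(alt)
  out$consequence <- if (len_diff %% 3L != 0L) "frameshift" else "inframe_indel"
  if (t$strand == "+") {
    cds_pos <- loc$cds_pos
    if (len_diff > 0) {
      d1 <- cds_pos + 1L
      d2 <- cds_pos + len_diff
      out$hgvs_c <- if (len_diff == 1L) paste0("c.", d1, "del")
                    else paste0("c.", d1, "_", d2, "del")
    } else if (len_diff < 0) {
      ins <- substr(alt, nchar(ref) + 1L, nchar(alt))
      out$hgvs_c <- paste0("c.", cds_pos, "_", cds_pos + 1L, "ins", ins)
    }
  }
  out
}

#' Annotate all variants in a set against transcript models
#'
#' Each variant is matched to the transcript (at most one per gene) whose
#' extended span (transcript plus `flank` bases either side, classed
#' upstream/downstream) contains it; unmatched variants are classed
#' `intergenic`. Already-annotated sites are left alone unless
#' `overwrite = TRUE`.
#'
#' @param vs a [variant_set()].
#' @param transcripts list of [transcript_model()].
#' @param flank bases beyond the transcript span still attributed to it.
#' @param overwrite re-annotate sites that already carry a region class.
#' @return The annotated `variant_set`.
#' @export
annotate_variants <- function(vs, transcripts, flank = 2000L, overwrite = FALSE) {
  if (n_variants(vs) == 0 || length(transcripts) == 0) return(vs)
  tx_chrom <- vapply(transcripts, function(t) t$chrom, character(1))
  tx_lo <- vapply(transcripts, function(t) min(t$exons[, 1]) - flank, numeric(1))
  tx_hi <- vapply(transcripts, function(t) max(t$exons[, 2]) + flank, numeric(1))
  for (i in seq_len(nrow(vs$sites))) {
    if (!overwrite && !is.na(vs$sites$region_class[i])) next
    hit <- which(tx_chrom == vs$sites$chrom[i] &
                   tx_lo <= vs$sites$pos[i] - 1L & vs$sites$pos[i] - 1L < tx_hi)
    if (length(hit) == 0) {
      vs$sites$region_class[i] <- "intergenic"
      vs$sites$consequence[i] <- "none"
      next
    }
    ann <- consequence_call(vs$sites$chrom[i], vs$sites$pos[i],
                            vs$sites$ref[i], vs$sites$alt[i],
                            transcripts[[hit[1]]])
    vs$sites$region_class[i] <- ann$region_class
    vs$sites$consequence[i] <- ann$consequence
    vs$sites$hgvs_c[i] <- ann$hgvs_c
    vs$sites$hgvs_p[i] <- ann$hgvs_p
    if (is.na(vs$sites$gene[i])) vs$sites$gene[i] <- ann$gene
  }
  vs
}

#' Residues retained by a premature stop codon
#'
#' A stop at residue r truncates the protein after residue r - 1.
#'
#' @param stop_residue 1-based codon index of the premature stop.
#' @return Number of retained residues.
#' @export
truncation_retained_length <- function(stop_residue) {
  stopifnot(stop_residue >= 1)
  stop_residue - 1L
}

#' Residue index of the stop codon in an HGVS p. truncation description
#'
#' @param hgvs_p e.g. `"p.Gln1701*"`.
#' @return Integer residue index, `NA` if not a truncation description.
#' @export
stop_residue_from_hgvs_p <- function(hgvs_p) {
  m <- regmatches(hgvs_p, regexec("^p\\.[A-Za-z]{3}([0-9]+)\\*$", hgvs_p))[[1]]
  if (length(m) < 2) return(NA_integer_)
  as.integer(m[2])
}
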