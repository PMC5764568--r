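# Shared fixtures, built in code.

# single-exon plus-strand transcript whose CDS is the whole exon;
# codon `gln_codon` is CAG so a C>T at its first base creates a stop
single_exon_cag_transcript <- function(n_codons = 1702, gln_codon = 1701,
                                       filler = "GCT") {
  body <- rep(filler, n_codons - 2L)
  body[gln_codon - 1L] <- "CAG"   # body[i] is codon i+1 (codon 1 is ATG)
  cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
  transcript_model(gene = "TOY", transcript_id = "TOY-tx1", chrom = "chrT",
                   strand = "+", exons = cbind(0L, nchar(cds)),
                   cds_start = 0L, cds_end = nchar(cds), chrom_seq = cds)
}

random_chrom <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

# minimal variant-set builder: one row per variant described by a list
# with fields chrom/pos/ref/alt/qual and per-sample genotype strings
# like "0/1" plus optional ad (c(ref, alt)), dp, plus site annotations
build_variant_set <- function(specs, samples) {
  parse_gt <- function(g) {
    if (is.null(g) || is.na(g)) return(c(NA_integer_, NA_integer_))
    as.integer(strsplit(g, "/", fixed = TRUE)[[1]])
  }
  sites <- list(); calls <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    site <- data.frame(
      vid = i,
      chrom = sp$chrom %||% "chr1",
      pos = sp$pos %||% (1000L + i),
      id = sp$id %||% NA_character_,
      ref = sp$ref %||% "A", alt = sp$alt %||% "T",
      qual = sp$qual %||% 100,
      gene = sp$gene %||% NA_character_,
      region_class = sp$region_class %||% NA_character_,
      consequence = sp$consequence %||% NA_character_,
      pathogenic = sp$pathogenic %||% NA,
      internal_freq = sp$internal_freq %||% NA_real_,
      stringsAsFactors = FALSE)
    for (db in names(sp$mafs %||% NULL))
      site[[paste0("maf_", db)]] <- sp$mafs[[db]]
    sites[[i]] <- site
    for (s in samples) {
      a <- parse_gt(sp$gt[[s]])
      ad <- sp$ad[[s]] %||% NULL
      dp <- sp$dp[[s]] %||% (if (!is.null(ad)) sum(ad) else 60L)
      calls[[length(calls) + 1L]] <- data.frame(
        vid = i, sample = s, a1 = a[1], a2 = a[2],
        ad_ref = if (!is.null(ad)) ad[1] else NA_integer_,
        ad_alt = if (!is.null(ad)) ad[2] else NA_integer_,
        dp = dp, gq = 99, stringsAsFactors = FALSE)
    }
  }
  sites <- famfunnel:::fill_missing_cols(sites)
  variant_set(do.call(rbind, sites), do.call(rbind, calls), samples = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force consequence oracle: full translation of wild-type vs mutant CDS
translate_oracle <- function(t, cds_pos, calt) {
  cds <- coding_sequence(t)
  mut <- cds
  substr(mut, cds_pos, cds_pos) <- calt
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x), no.init.codon = TRUE))
  p_wt <- tr(cds); p_mut <- tr(mut)
  if (p_wt == p_mut) return("synonymous")
  i <- which(strsplit(p_wt, "")[[1]] != strsplit(p_mut, "")[[1]])[1]
  wt_aa <- substr(p_wt, i, i); mut_aa <- substr(p_mut, i, i)
  if (mut_aa == "*") "stop_gain" else if (wt_aa == "*") "stop_loss" else "missense"
}

# small simulated dataset reused by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_family(family_sim_config(seed = 42,
                                                  n_background_variants = 600))
    cache
  }
})
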