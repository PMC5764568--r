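#' Fanconi-anaemia pathway gene panel
#'
#' The 27-gene FANC-pathway panel (gene symbol plus customary alias)
#' used as the default candidate-gene list for the exclusion analysis
#' and as the gene pool of the simulator.
#'
#' @return Data frame with columns `gene`, `alias`.
#' @export
fanc_panel <- function() {
  data.frame(
    gene = c("FANCA", "FANCB", "FANCC", "FANCD1", "FANCD2", "FANCE",
             "FANCF", "FANCG", "FANCI", "FANCJ", "FANCL", "FANCM",
             "FANCN", "FANCO", "FANCP", "FANCQ", "FANCR", "FANCS",
             "FANCT", "FANCU", "FANCV", "FAAP100", "FAAP24", "FAAP20",
             "FAAP16", "FAAP10", "FAN1"),
    alias = c(NA, NA, NA, "BRCA2", NA, NA, NA, NA, NA, "BRIP1", NA, NA,
              "PALB2", "RAD51C", "SLX4", "ERCC4", "RAD51", "BRCA1",
              "UBE2T", "XRCC2", "MAD2L2", "C17orf70", "C19orf40",
              "C1orf86", "APITD1", "STRA13", NA),
    stringsAsFactors = FALSE)
}

#' Specification of the implanted causal variant
#'
#' Describes the recessive stop-gain allele the simulator implants:
#' homozygous in both affected sisters, heterozygous in the parents, rare
#' in every population database (default MAF 0.001, emulating a
#' rare truncating allele segregating in an isolated population).
#'
#' @param gene gene carrying the variant (must be in the simulated panel).
#' @param cds_pos 1-based coding position of the substitution; the
#'   simulator arranges the transcript so the substitution creates a
#'   premature stop codon there.
#' @param mafs named numeric vector of database MAFs.
#' @param internal_freq internal cohort frequency.
#' @param genotypes named character vector over family members, values
#'   `hom_ref`, `het`, `hom_alt`; must satisfy the recessive pattern
#'   (homozygous in affecteds, heterozygous in sequenced carriers).
#' @param id variant identifier written to the VCF ID column.
#' @return A list of class `causal_spec`.
#' @export
causal_spec <- function(gene = "FANCM", cds_pos = 5101,
                        mafs = c(evs = 0.001, g1000 = 0.001, exac = 0.001),
                        internal_freq = 0.001,
                        genotypes = c(father = "het", mother = "het",
                                      sister1 = "hom_alt", sister2 = "hom_alt"),
                        id = "rs900000001") {
  stopifnot(cds_pos >= 1, all(genotypes %in% c("hom_ref", "het", "hom_alt")))
  structure(list(gene = gene, cds_pos = as.integer(cds_pos), mafs = mafs,
                 internal_freq = internal_freq, genotypes = genotypes, id = id),
            class = "causal_spec")
}

#' Family exome simulation configuration
#'
#' Defines the study conditions the simulator emulates: a consanguineous
#' quartet (two affected sisters, carrier mother sequenced, father
#' unsequenced), thousands of background exome variants with a
#' rare-skewed allele-frequency spectrum, negative-binomial read depth
#' around 70x, balanced allelic reads at heterozygous sites, and one
#' implanted recessive stop-gain allele.
#'
#' @param seed RNG seed; the whole dataset is deterministic given it.
#' @param n_background_variants number of background variants emitted, i.e.
#'   sites carrying an alternate allele in at least one sequenced member
#'   (a variant caller only reports observed variants); candidate sites
#'   are drawn until this count is reached.
#' @param maf_beta shape parameters of the Beta distribution of true
#'   alternate-allele frequencies.
#' @param consanguinity_f inbreeding coefficient of the children
#'   (probability their two alleles are identical by descent); 0.0625
#'   corresponds to first-cousin parents. Implemented by letting the
#'   parents share an allele identical by descent with probability
#'   `4 * consanguinity_f`, so transmission stays strictly Mendelian.
#' @param depth_mean,depth_dispersion negative-binomial read-depth model
#'   (mean reads; dispersion = NB size).
#' @param het_allele_balance binomial success probability of an alternate
#'   read at a heterozygous site.
#' @param site_quality_shape,site_quality_rate gamma model of phred
#'   site quality.
#' @param region_class_weights categorical distribution of region
#'   classes over background variants (annotations are assigned from it
#'   directly, independent of position).
#' @param coding_consequence_weights consequence distribution within
#'   coding variants.
#' @param pathogenic_missense_rate probability a missense background
#'   variant carries the pathogenicity flag.
#' @param db_chromosomes named integer vector: chromosome counts (2N) of
#'   the emulated population databases; observed MAFs are binomial draws
#'   from the true frequency, and a zero count means "not observed".
#' @param internal_chromosomes chromosome count of the internal cohort.
#' @param panel gene panel data frame (`gene`, `alias`).
#' @param panel_variant_rate probability a background variant falls in a
#'   panel gene rather than an anonymous filler gene.
#' @param include_brother add an unaffected sequenced brother.
#' @param sequence_father mark the father sequenced.
#' @param causal_spec a [causal_spec()], or `NULL` for no implant.
#' @param deletion_spec optional list(`gene`, `carriers`) passed to
#'   [implant_heterozygous_deletion()] after simulation.
#' @param decoy_cnvs emit two CNV calls that violate segregation (one
#'   private to a sister, one shared with the mother), emulating the
#'   disease-unrelated CNVs real exomes show.
#' @return A list of class `family_sim_config`.
#' @export
family_sim_config <- function(seed = 1L,
                              n_background_variants = 5000L,
                              maf_beta = c(0.5, 5),
                              consanguinity_f = 0.0625,
                              depth_mean = 70, depth_dispersion = 8,
                              het_allele_balance = 0.5,
                              site_quality_shape = 6, site_quality_rate = 0.1,
                              region_class_weights = c(
                                coding_exon = 0.50, splice = 0.02,
                                utr5 = 0.05, utr3 = 0.10, deep_intron = 0.20,
                                upstream = 0.06, downstream = 0.06,
                                intergenic = 0.01),
                              coding_consequence_weights = c(
                                synonymous = 0.48, missense = 0.46,
                                stop_gain = 0.02, stop_loss = 0.005,
                                frameshift = 0.02, inframe_indel = 0.015),
                              pathogenic_missense_rate = 0.05,
                              db_chromosomes = c(evs = 13000L, g1000 = 5008L,
                                                 exac = 121412L),
                              internal_chromosomes = 402L,
                              panel = fanc_panel(),
                              panel_variant_rate = 0.02,
                              include_brother = FALSE,
                              sequence_father = FALSE,
                              causal_spec = famfunnel::causal_spec(),
                              deletion_spec = NULL,
                              decoy_cnvs = TRUE) {
  stopifnot(n_background_variants >= 0,
            consanguinity_f >= 0, consanguinity_f <= 0.25,
            het_allele_balance > 0, het_allele_balance < 1,
            all(maf_beta > 0), depth_mean > 0, depth_dispersion > 0)
  if (abs(sum(region_class_weights) - 1) > 1e-6)
    stop("region_class_weights must sum to 1")
  structure(as.list(environment()), class = "family_sim_config")
}

non_stop_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# codon containing the causal position, and the substitution producing a stop
stop_gain_design <- function(within_codon) {
  switch(within_codon,
         `1` = list(codon = "CAG", ref = "C", alt = "T"),  # CAG -> TAG
         `2` = list(codon = "TCG", ref = "C", alt = "A"),  # TCG -> TAG
         `3` = list(codon = "TAC", ref = "C", alt = "A"))  # TAC -> TAA
}

# build one toy transcript on its own chromosome; causal_at (cDNA pos) forces
# a stop-gain-ready codon there
make_toy_transcript <- function(gene, chrom, n_codons, strand,
                                causal_at = NULL) {
  codons <- sample(non_stop_codons(), n_codons - 2L, replace = TRUE)
  cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  if (!is.null(causal_at)) {
    codon_number <- ceiling(causal_at / 3)
    within <- as.character(causal_at - 3L * (codon_number - 1L))
    design <- stop_gain_design(within)
    start <- 3L * (codon_number - 1L) + 1L
    substr(cds, start, start + 2L) <- design$codon
  }
  utr5 <- random_dna(60L)
  utr3 <- random_dna(120L)
  tx_seq <- paste0(utr5, cds, utr3)
  tx_len <- nchar(tx_seq)

  n_exons <- max(2L, round(nchar(cds) / 600))
  cuts <- sort(sample(seq(100L, tx_len - 100L), n_exons - 1L))
  sizes <- diff(c(0L, cuts, tx_len))
  introns <- sample(300:800, n_exons - 1L, replace = TRUE)
  tx_start <- 1000L
  ex_start <- tx_start + c(0L, cumsum(sizes[-n_exons] + introns))
  exons <- cbind(ex_start, ex_start + sizes)

  chrom_len <- max(exons) + 1000L
  chrom_seq <- random_dna(chrom_len)
  # lay transcript sequence into the exons (genomic ascending order)
  genomic_tx <- if (strand == "+") tx_seq else revcomp(tx_seq)
  off <- 0L
  for (i in seq_len(n_exons)) {
    substr(chrom_seq, exons[i, 1] + 1L, exons[i, 2]) <-
      substr(genomic_tx, off + 1L, off + sizes[i])
    off <- off + sizes[i]
  }
  # CDS genomic bounds from transcript offsets of the first/last CDS base
  tx2g <- function(tpos) {  # 1-based transcript pos -> 0-based genomic
    if (strand == "-") tpos <- tx_len - tpos + 1L
    cum <- cumsum(sizes)
    j <- which(tpos <= cum)[1]
    exons[j, 1] + (tpos - (if (j > 1) cum[j - 1] else 0L)) - 1L
  }
  g1 <- tx2g(61L)                       # first CDS base (after 60 nt UTR5)
  g2 <- tx2g(60L + nchar(cds))          # last CDS base
  transcript_model(gene = gene, transcript_id = paste0(gene, "-tx1"),
                   chrom = chrom, strand = strand, exons = exons,
                   cds_start = min(g1, g2), cds_end = max(g1, g2) + 1L,
                   chrom_seq = chrom_seq)
}

#' Simulate a family exome dataset
#'
#' Generates the full input bundle the pipeline consumes — multi-sample
#' variant calls, pedigree, per-exon coverage, transcript models and CNV
#' calls — from a [family_sim_config()]. Founder genotypes follow
#' Hardy-Weinberg at Beta-distributed allele frequencies with parental
#' allele sharing reproducing the configured inbreeding coefficient;
#' children are generated by Mendelian transmission; depths are negative
#' binomial with binomially balanced allelic reads at heterozygous
#' calls. When the configuration carries a [causal_spec()], the causal
#' stop-gain allele is implanted via [implant_causal()]; a
#' `deletion_spec` is applied via [implant_heterozygous_deletion()].
#'
#' @param cfg a [family_sim_config()].
#' @return A list of class `family_sim`: `variants` ([variant_set()]),
#'   `pedigree`, `coverage`, `transcripts`, `cnvs`, `truth` (genotype
#'   dosage matrix of all members, true allele frequencies, causal vid),
#'   and `config`.
#' @export
simulate_family <- function(cfg = family_sim_config()) {
  set.seed(cfg$seed)
  ped_ids <- c("father", "mother", "sister1", "sister2",
               if (cfg$include_brother) "brother")
  ped <- pedigree(
    id = ped_ids,
    sex = c(1, 2, 2, 2, if (cfg$include_brother) 1),
    father_id = c(NA, NA, "father", "father", if (cfg$include_brother) "father"),
    mother_id = c(NA, NA, "mother", "mother", if (cfg$include_brother) "mother"),
    affected = c(FALSE, FALSE, TRUE, TRUE, if (cfg$include_brother) FALSE),
    sequenced = c(cfg$sequence_father, TRUE, TRUE, TRUE,
                  if (cfg$include_brother) TRUE))
  children <- setdiff(ped_ids, c("father", "mother"))
  seq_ids <- ped$id[ped$sequenced]

  # one toy transcript per panel gene, each on its own chromosome
  panel <- cfg$panel
  causal_gene <- if (!is.null(cfg$causal_spec)) cfg$causal_spec$gene else NULL
  transcripts <- lapply(seq_len(nrow(panel)), function(i) {
    g <- panel$gene[i]
    is_causal <- !is.null(causal_gene) && g == causal_gene
    n_codons <- if (is_causal) ceiling(cfg$causal_spec$cds_pos / 3) + 100L else 240L
    make_toy_transcript(
      gene = g, chrom = paste0("chr", i), n_codons = n_codons,
      strand = sample(c("+", "-"), 1),
      causal_at = if (is_causal) cfg$causal_spec$cds_pos)
  })
  names(transcripts) <- panel$gene

  n <- cfg$n_background_variants
  sim <- if (n > 0) simulate_background(cfg, ped, transcripts, n)
         else empty_background(cfg, seq_ids)

  vs <- sim$vs
  truth <- sim$truth

  # per-exon coverage for the panel, per sequenced sample
  sample_factor <- stats::setNames(stats::rnorm(length(seq_ids), 1, 0.05), seq_ids)
  cov_rows <- list()
  for (t in transcripts) {
    for (s in seq_ids) {
      md <- round(pmax(5, stats::rnorm(nrow(t$exons),
                                       cfg$depth_mean * sample_factor[[s]], 8)), 1)
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        chrom = t$chrom, start = t$exons[, 1], end = t$exons[, 2],
        gene = t$gene, exon = seq_len(nrow(t$exons)),
        mean_depth = md, sample = s, stringsAsFactors = FALSE)
    }
  }
  coverage <- do.call(rbind, cov_rows)
  class(coverage) <- c("coverage_table", "data.frame")

  cnvs <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                     sample = character(0), state = character(0),
                     stringsAsFactors = FALSE)
  if (isTRUE(cfg$decoy_cnvs)) {
    decoy_genes <- setdiff(panel$gene, causal_gene)[c(3, 5)]
    span <- function(g) {
      t <- transcripts[[g]]
      list(chrom = t$chrom, start = min(t$exons[, 1]), end = max(t$exons[, 2]))
    }
    s1 <- span(decoy_genes[1]); s2 <- span(decoy_genes[2])
    shared <- intersect(c("mother", "sister1", "sister2"), seq_ids)
    cnvs <- rbind(
      data.frame(chrom = s1$chrom, start = s1$start, end = s1$end,
                 sample = "sister1", state = "loss", stringsAsFactors = FALSE),
      data.frame(chrom = s2$chrom, start = s2$start, end = s2$end,
                 sample = shared, state = "gain", stringsAsFactors = FALSE))
  }
  class(cnvs) <- c("cnv_table", "data.frame")

  out <- structure(list(variants = vs, pedigree = ped, coverage = coverage,
                        transcripts = transcripts, cnvs = cnvs,
                        truth = truth, config = cfg),
                   class = "family_sim")
  if (!is.null(cfg$causal_spec)) {
    out$variants <- implant_causal(out$variants, cfg$causal_spec, ped,
                                   transcripts[[cfg$causal_spec$gene]], cfg)
    out$truth$causal_vid <- out$variants$sites$vid[
      !is.na(out$variants$sites$id) &
        out$variants$sites$id == cfg$causal_spec$id]
  }
  if (!is.null(cfg$deletion_spec))
    out <- implant_heterozygous_deletion(out, cfg$deletion_spec)
  out
}

# Hardy-Weinberg founders with IBD sharing, Mendelian children
draw_genotype_block <- function(cfg, members, n_draw) {
  children <- setdiff(members, c("father", "mother"))
  p <- stats::rbeta(n_draw, cfg$maf_beta[1], cfg$maf_beta[2])
  # parental alleles; with prob 4F the parents share one allele IBD
  shared <- stats::runif(n_draw) < 4 * cfg$consanguinity_f
  draw <- function() as.integer(stats::runif(n_draw) < p)
  fa <- cbind(draw(), draw())
  mo <- cbind(draw(), draw())
  s_allele <- draw()
  fa[shared, 1] <- s_allele[shared]
  mo[shared, 1] <- s_allele[shared]
  alleles <- list(father = fa, mother = mo)
  for (ch in children) {
    pick_f <- sample(1:2, n_draw, replace = TRUE)
    pick_m <- sample(1:2, n_draw, replace = TRUE)
    alleles[[ch]] <- cbind(fa[cbind(seq_len(n_draw), pick_f)],
                           mo[cbind(seq_len(n_draw), pick_m)])
  }
  list(p = p,
       dosage = vapply(members, function(mm) rowSums(alleles[[mm]]),
                       numeric(n_draw)))
}

# draw background sites, genotypes, depths, annotations; exactly n sites
# polymorphic in the sequenced members are emitted (a caller only reports
# observed variants, so n is the called-variant scale of the dataset)
simulate_background <- function(cfg, ped, transcripts, n) {
  seq_ids <- ped$id[ped$sequenced]
  members <- ped$id
  p <- numeric(0)
  dosage <- NULL
  repeat {
    blk <- draw_genotype_block(cfg, members, max(4L * n, 200L))
    called <- rowSums(blk$dosage[, seq_ids, drop = FALSE]) > 0
    p <- c(p, blk$p[called])
    dosage <- rbind(dosage, blk$dosage[called, , drop = FALSE])
    if (nrow(dosage) >= n) break
  }
  idx <- seq_len(n)
  m <- n

  # annotations, independent of position
  rc <- sample(names(cfg$region_class_weights), m, replace = TRUE,
               prob = cfg$region_class_weights)
  cq <- rep("none", m)
  coding <- rc == "coding_exon"
  cq[coding] <- sample(names(cfg$coding_consequence_weights), sum(coding),
                       replace = TRUE, prob = cfg$coding_consequence_weights)
  cq[rc == "splice"] <- "splice_site"
  truncating <- cq %in% c("stop_gain", "stop_loss", "frameshift")
  pathog <- (truncating & stats::runif(m) < 0.9) |
    (cq == "missense" & stats::runif(m) < cfg$pathogenic_missense_rate)

  in_panel <- stats::runif(m) < cfg$panel_variant_rate & rc != "intergenic"
  gene <- paste0("GENE", sprintf("%04d", sample.int(8000L, m, replace = TRUE)))
  gene[in_panel] <- sample(cfg$panel$gene, sum(in_panel), replace = TRUE)
  gene[rc == "intergenic"] <- NA_character_

  # positions: panel variants near their gene; fillers on a background grid
  chrom <- paste0("chr", sample.int(22L, m, replace = TRUE))
  pos <- sample.int(2e8L, m, replace = TRUE) + 1e6L
  for (g in unique(gene[in_panel])) {
    t <- transcripts[[g]]
    sel <- which(in_panel & gene == g)
    chrom[sel] <- t$chrom
    pos[sel] <- sample(seq(max(1L, min(t$exons[, 1]) - 2000L),
                           max(t$exons[, 2]) + 2000L), length(sel))
  }

  # observed database frequencies: binomial draws from the true frequency
  pm <- p[idx]
  db_maf <- lapply(cfg$db_chromosomes, function(N) {
    cnt <- stats::rbinom(m, N, pm)
    ifelse(cnt == 0, NA_real_, cnt / N)
  })
  icnt <- stats::rbinom(m, cfg$internal_chromosomes, pm)
  ifreq <- ifelse(icnt == 0, NA_real_, icnt / cfg$internal_chromosomes)

  ref_alt <- t(vapply(seq_len(m), function(i)
    sample(c("A", "C", "G", "T"), 2), character(2)))
  # small indels for the indel consequence classes
  is_indel <- cq %in% c("frameshift", "inframe_indel")
  ins_len <- ifelse(cq == "frameshift", 1L, 3L)
  alt_col <- ifelse(is_indel,
                    paste0(ref_alt[, 1],
                           strrep(ref_alt[, 2], ins_len)),
                    ref_alt[, 2])

  sites <- data.frame(
    vid = seq_len(m), chrom = chrom, pos = pos, id = NA_character_,
    ref = ref_alt[, 1], alt = alt_col,
    qual = round(stats::rgamma(m, cfg$site_quality_shape, cfg$site_quality_rate), 2),
    gene = gene, region_class = rc, consequence = cq,
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    pathogenic = pathog, internal_freq = ifreq,
    stringsAsFactors = FALSE)
  for (db in names(db_maf)) sites[[paste0("maf_", db)]] <- db_maf[[db]]

  calls <- make_calls(sites$vid, dosage[idx, , drop = FALSE], seq_ids, cfg)

  ord <- order(sites$chrom, sites$pos)
  dos <- dosage[idx, , drop = FALSE][ord, , drop = FALSE]
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  rownames(dos) <- as.character(sites$vid)
  vs <- variant_set(sites, calls, samples = seq_ids)
  list(vs = vs,
       truth = list(dosage = dos, true_maf = stats::setNames(pm[ord], sites$vid),
                    causal_vid = NA_integer_))
}

empty_background <- function(cfg, seq_ids) {
  sites <- data.frame(vid = integer(0), chrom = character(0), pos = integer(0),
                      id = character(0), ref = character(0), alt = character(0),
                      qual = numeric(0), stringsAsFactors = FALSE)
  for (db in names(cfg$db_chromosomes)) sites[[paste0("maf_", db)]] <- numeric(0)
  calls <- data.frame(vid = integer(0), sample = character(0),
                      a1 = integer(0), a2 = integer(0), ad_ref = integer(0),
                      ad_alt = integer(0), dp = integer(0), gq = numeric(0),
                      stringsAsFactors = FALSE)
  list(vs = variant_set(sites, calls, samples = seq_ids),
       truth = list(dosage = NULL, true_maf = numeric(0),
                    causal_vid = NA_integer_))
}

# genotype calls with NB depth, binomial allele balance, deterministic GQ
make_calls <- function(vids, dosage, seq_ids, cfg) {
  rows <- lapply(seq_ids, function(s) {
    n <- length(vids)
    dp <- stats::rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_dispersion)
    dos <- dosage[, s]
    ad_alt <- integer(n)
    het <- dos == 1L
    ad_alt[het] <- stats::rbinom(sum(het), dp[het], cfg$het_allele_balance)
    ad_alt[dos == 2L] <- dp[dos == 2L]
    ad_ref <- dp - ad_alt
    data.frame(vid = vids, sample = s,
               a1 = as.integer(dos >= 1L), a2 = as.integer(dos == 2L),
               ad_ref = ad_ref, ad_alt = ad_alt, dp = dp,
               gq = genotype_quality(dp, ad_alt, dos),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# deterministic genotype quality: grows with depth, shrinks with imbalance
genotype_quality <- function(dp, ad_alt, dosage) {
  balance_penalty <- ifelse(dosage == 1L & dp > 0,
                            pmax(0, 1 - 2 * abs(ad_alt / pmax(dp, 1) - 0.5)), 1)
  pmin(99, round(3 * dp * balance_penalty))
}

#' Implant the causal recessive stop-gain variant
#'
#' Adds one stop-gain substitution at the configured coding position of
#' the causal gene's transcript, genotyped per the causal specification
#' (homozygous alternate in affecteds, heterozygous in sequenced
#' carriers), with the configured database MAFs and the pathogenicity
#' flag set. The specification is validated against the pedigree: a
#' genotype pattern violating recessive segregation is an error.
#'
#' @param vs a [variant_set()].
#' @param spec a [causal_spec()].
#' @param ped a [pedigree()].
#' @param transcript the causal gene's [transcript_model()].
#' @param cfg a [family_sim_config()] (for the depth model of the new
#'   calls).
#' @return The `variant_set` with the causal variant appended (in
#'   coordinate-sorted position).
#' @export
implant_causal <- function(vs, spec, ped, transcript,
                           cfg = family_sim_config()) {
  aff <- affected_members(ped, sequenced_only = FALSE)
  if (!all(spec$genotypes[aff] == "hom_alt"))
    stop("causal specification violates the recessive pattern: ",
         "affected members must be hom_alt")
  carriers <- obligate_carriers(ped)
  if (!all(spec$genotypes[carriers] == "het"))
    stop("causal specification violates the recessive pattern: ",
         "sequenced obligate carriers must be het")

  pos <- cds_to_genomic(transcript, spec$cds_pos)
  g_ref <- toupper(substr(transcript$chrom_seq, pos, pos))
  within <- spec$cds_pos - 3L * (ceiling(spec$cds_pos / 3) - 1L)
  design <- stop_gain_design(as.character(within))
  g_alt <- if (transcript$strand == "+") design$alt else revcomp(design$alt)
  ann <- consequence_call(transcript$chrom, pos, g_ref, g_alt, transcript)
  if (ann$consequence != "stop_gain")
    stop("internal error: implanted variant is not a stop gain")

  seq_ids <- vs$samples
  gts <- spec$genotypes
  gts[setdiff(seq_ids, names(gts))] <- "hom_ref"
  dosage <- stats::setNames(
    c(hom_ref = 0L, het = 1L, hom_alt = 2L)[gts[seq_ids]], seq_ids)
  new_vid <- if (n_variants(vs) > 0) max(vs$sites$vid) + 1L else 1L
  site <- data.frame(
    vid = new_vid, chrom = transcript$chrom, pos = pos, id = spec$id,
    ref = g_ref, alt = g_alt,
    qual = round(100 + stats::rgamma(1, cfg$site_quality_shape,
                                     cfg$site_quality_rate), 2),
    gene = transcript$gene, region_class = ann$region_class,
    consequence = ann$consequence, hgvs_c = ann$hgvs_c, hgvs_p = ann$hgvs_p,
    pathogenic = TRUE, internal_freq = spec$internal_freq,
    stringsAsFactors = FALSE)
  for (db in names(spec$mafs)) site[[paste0("maf_", db)]] <- spec$mafs[[db]]
  for (col in setdiff(names(vs$sites), names(site))) site[[col]] <- NA
  site <- site[, names(vs$sites), drop = FALSE]

  calls <- make_calls(new_vid, matrix(dosage, nrow = 1,
                                      dimnames = list(NULL, seq_ids)),
                      seq_ids, cfg)

  sites <- rbind(vs$sites, site)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  variant_set(sites, rbind(vs$calls, calls), samples = vs$samples)
}

#' Implant a heterozygous deletion over a gene
#'
#' Emulates hemizygosity in the carrier samples: heterozygous calls in
#' the gene lose their reference haplotype (re-emitted homozygous for the
#' remaining alternate allele with collapsed allelic depths), read depth
#' over the gene halves — both at the variant calls and in the per-exon
#' coverage — and a CNV loss call spanning the gene is added per
#' carrier. Downstream, this abolishes heterozygous-variant presence and
#' flips the gene's exclusion verdict.
#'
#' @param sim a `family_sim` (from [simulate_family()]).
#' @param deletion_spec list with `gene` and `carriers` (sample ids).
#' @return The modified `family_sim`.
#' @export
implant_heterozygous_deletion <- function(sim, deletion_spec) {
  g <- deletion_spec$gene
  carriers <- deletion_spec$carriers
  vs <- sim$variants
  in_gene <- vs$sites$vid[!is.na(vs$sites$gene) & vs$sites$gene == g]
  sel <- vs$calls$vid %in% in_gene & vs$calls$sample %in% carriers
  het <- sel & is_het(vs$calls)
  vs$calls$a1[het] <- 1L
  vs$calls$a2[het] <- 1L
  vs$calls$dp[sel] <- pmax(1L, vs$calls$dp[sel] %/% 2L)
  vs$calls$ad_alt[het] <- vs$calls$dp[het]
  vs$calls$ad_ref[het] <- 0L
  hom <- sel & !het
  vs$calls$ad_alt[hom] <- pmin(vs$calls$ad_alt[hom], vs$calls$dp[hom])
  vs$calls$ad_ref[hom] <- vs$calls$dp[hom] - vs$calls$ad_alt[hom]
  vs$calls$gq[sel] <- genotype_quality(
    vs$calls$dp[sel], vs$calls$ad_alt[sel],
    vs$calls$a1[sel] + vs$calls$a2[sel])
  sim$variants <- variant_set(vs$sites, vs$calls, samples = vs$samples)

  crows <- sim$coverage$gene == g & sim$coverage$sample %in% carriers
  sim$coverage$mean_depth[crows] <- sim$coverage$mean_depth[crows] * 0.5

  t <- sim$transcripts[[g]]
  if (!is.null(t)) {
    loss <- data.frame(chrom = t$chrom, start = min(t$exons[, 1]),
                       end = max(t$exons[, 2]), sample = carriers,
                       state = "loss", stringsAsFactors = FALSE)
    sim$cnvs <- rbind(sim$cnvs, loss)
    class(sim$cnvs) <- c("cnv_table", "data.frame")
  }
  sim
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits the exact formats the readers consume: VCF (calls), PED
#' (pedigree), BED-like coverage and CNV tables, BED12 transcripts with
#' a chromosome FASTA, and the gene panel.
#'
#' @param sim a `family_sim`.
#' @param dir output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_family_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "family.vcf"),
    ped = file.path(dir, "family.ped"),
    coverage = file.path(dir, "coverage.bed"),
    cnv = file.path(dir, "cnv.bed"),
    transcripts = file.path(dir, "transcripts.bed12"),
    fasta = file.path(dir, "genome.fa"),
    panel = file.path(dir, "panel.txt"))
  write_vcf(sim$variants, paths$vcf)
  write_ped(sim$pedigree, paths$ped)
  write_coverage(sim$coverage, paths$coverage)
  write_cnv(sim$cnvs, paths$cnv)
  write_transcripts(sim$transcripts, paths$transcripts)
  write_transcript_fasta(sim$transcripts, paths$fasta)
  write_panel(sim$config$panel, paths$panel)
  invisible(paths)
}
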