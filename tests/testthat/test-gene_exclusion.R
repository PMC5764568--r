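trio <- c("mother", "sister1", "sister2")

test_that("gene mean depth is the unweighted mean over the gene's exons", {
  cov <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                    end = c(50, 150, 250), gene = "G1", exon = 1:3,
                    mean_depth = c(80, 90, 100), sample = "s1")
  expect_equal(gene_mean_depth(cov, "G1", "s1"), 90)
  expect_equal(gene_mean_depth(cov[1, ], "G1", "s1"), 80)
  expect_true(is.na(gene_mean_depth(cov, "G2", "s1")))
  # random panel vs direct recomputation
  sim <- small_sim()
  for (g in sample(unique(sim$coverage$gene), 5)) {
    d <- sim$coverage$mean_depth[sim$coverage$gene == g &
                                   sim$coverage$sample == "sister1"]
    expect_equal(gene_mean_depth(sim$coverage, g, "sister1"), mean(d))
  }
})

test_that("heterozygous presence in an affected excludes hemizygosity", {
  ped <- quartet_pedigree()
  vs <- build_variant_set(list(
    list(gene = "G1", gt = list(mother = "0/1", sister1 = "1/1", sister2 = "1/1")),
    list(gene = "G2", gt = list(mother = "0/1", sister1 = "0/1", sister2 = "1/1")),
    list(gene = "G3", gt = list(mother = "0/1", sister1 = "0/0", sister2 = "0/0"))),
    samples = trio)
  expect_false(het_presence(vs, "G1", ped))  # only hom calls in the sisters
  expect_true(het_presence(vs, "G2", ped))   # one 0/1 in one sister suffices
  expect_false(het_presence(vs, "G3", ped))
  # oracle scan on simulated data
  sim <- small_sim()
  genes <- stats::na.omit(unique(sim$variants$sites$gene))
  for (g in sample(genes, min(10, length(genes)))) {
    cc <- sim$variants$calls
    cc <- cc[cc$vid %in% sim$variants$sites$vid[!is.na(sim$variants$sites$gene) &
                                                  sim$variants$sites$gene == g] &
               cc$sample %in% c("sister1", "sister2"), ]
    expect_equal(het_presence(sim$variants, g, sim$pedigree),
                 any(famfunnel:::is_het(cc)), info = g)
  }
})

test_that("mean allelic ratio is the directional alt/ref mean over het calls", {
  ped <- quartet_pedigree()
  vs <- build_variant_set(list(
    list(gene = "G1", gt = list(sister1 = "0/1"), ad = list(sister1 = c(40L, 40L))),
    list(gene = "G2", gt = list(sister1 = "0/1", sister2 = "0/1"),
         ad = list(sister1 = c(30L, 45L), sister2 = c(45L, 30L)))),
    samples = c("sister1", "sister2"))
  expect_equal(mean_allelic_ratio(vs, "G1", ped), 1.0)
  expect_equal(mean_allelic_ratio(vs, "G2", ped), mean(c(45 / 30, 30 / 45)))
  expect_equal(mean_allelic_ratio(vs, "G2", ped), 13 / 12, tolerance = 1e-12)
  expect_true(is.na(mean_allelic_ratio(vs, "nope", ped)))
  # a zero-reference-read call is skipped with a warning
  vz <- build_variant_set(list(
    list(gene = "G", gt = list(sister1 = "0/1"), ad = list(sister1 = c(0L, 50L))),
    list(gene = "G", gt = list(sister1 = "0/1"), ad = list(sister1 = c(25L, 25L)))),
    samples = "sister1")
  expect_warning(r <- mean_allelic_ratio(vz, "G", ped), "zero reference")
  expect_equal(r, 1.0)
})

test_that("the allelic ratio of balanced binomial het calls converges to 1", {
  set.seed(99)
  n <- 200
  dp <- stats::rnbinom(n, mu = 70, size = 8)
  dp <- pmax(dp, 10L)
  alt <- stats::rbinom(n, dp, 0.5)
  specs <- lapply(seq_len(n), function(i)
    list(gene = "G", pos = 1000L + i, gt = list(sister1 = "0/1"),
         ad = list(sister1 = c(dp[i] - alt[i], alt[i]))))
  vs <- build_variant_set(specs, samples = "sister1")
  r <- suppressWarnings(mean_allelic_ratio(vs, "G", quartet_pedigree()))
  expect_gt(r, 0.9)
  expect_lt(r, 1.1)
})

test_that("regional presence flags each genic portion with a family variant", {
  vs <- build_variant_set(list(
    list(gene = "G1", region_class = "utr3", gt = list(s1 = "0/1")),
    list(gene = "G1", region_class = "deep_intron", gt = list(s1 = "0/1")),
    list(gene = "G2", region_class = "coding_exon", gt = list(s1 = "0/1"))),
    samples = "s1")
  flags <- regional_presence(vs, "G1")
  expect_equal(flags, c(upstream = FALSE, utr5 = FALSE, deep_intron = TRUE,
                        utr3 = TRUE, downstream = FALSE))
  expect_true(all(!regional_presence(vs, "G3")))
  expect_true(all(!regional_presence(vs, "G2")))  # coding is not a deletion flag
})

test_that("segregating rare pathogenic counts match the funnel restricted to a gene", {
  sim <- small_sim()
  ped <- sim$pedigree
  cfg <- filter_config()
  causal_gene <- sim$config$causal_spec$gene
  expect_equal(count_segregating_rare_pathogenic(sim$variants, causal_gene,
                                                 ped, cfg), 1L)
  expect_equal(count_segregating_rare_pathogenic(sim$variants, "NOGENE",
                                                 ped, cfg), 0L)
  for (g in sample(unique(stats::na.omit(sim$variants$sites$gene)), 8)) {
    gv <- subset_variants(sim$variants,
                          !is.na(sim$variants$sites$gene) &
                            sim$variants$sites$gene == g)
    ref <- impact_filter(frequency_filter(
      suppressWarnings(segregation_filter(gv, ped, cfg)), cfg), cfg)
    expect_equal(count_segregating_rare_pathogenic(sim$variants, g, ped, cfg),
                 n_variants(ref), info = g)
  }
})

test_that("CNV segregation equals the brute-force presence-pattern oracle", {
  ped <- quartet_pedigree()
  iv <- list(chrom = "chr2", start = 1000L, end = 5000L)
  patterns <- expand.grid(mother = c(FALSE, TRUE), sister1 = c(FALSE, TRUE),
                          sister2 = c(FALSE, TRUE))
  for (i in seq_len(nrow(patterns))) {
    carriers <- trio[unlist(patterns[i, trio])]
    cnvs <- if (length(carriers) > 0)
      data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                 sample = carriers, state = "loss", stringsAsFactors = FALSE)
    else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 sample = character(0), state = character(0))
    kept <- cnv_segregation_filter(cnvs, ped)
    # disease-compatible iff both sisters carry it and the mother does not
    oracle <- patterns$sister1[i] && patterns$sister2[i] && !patterns$mother[i]
    expect_equal(nrow(kept) > 0, oracle, info = paste(carriers, collapse = "+"))
    if (oracle) expect_setequal(kept$sample, c("sister1", "sister2"))
  }
})

test_that("CNV matching respects the reciprocal-overlap threshold", {
  ped <- quartet_pedigree()
  # sister2's call overlaps sister1's by less than half: not the same event
  cnvs <- data.frame(chrom = "chr2", start = c(1000L, 4500L),
                     end = c(5000L, 9000L), sample = c("sister1", "sister2"),
                     state = "loss", stringsAsFactors = FALSE)
  expect_equal(nrow(cnv_segregation_filter(cnvs, ped)), 0)
  # near-identical intervals match
  cnvs$start <- c(1000L, 1100L); cnvs$end <- c(5000L, 5100L)
  expect_equal(nrow(cnv_segregation_filter(cnvs, ped)), 2)
  # same interval but a different state is a different event
  cnvs$state <- c("loss", "gain")
  expect_equal(nrow(cnv_segregation_filter(cnvs, ped)), 0)
})

test_that("coverage summaries report mean depth and threshold coverage", {
  expect_equal(coverage_summary(rep(68, 50), 25),
               c(mean_depth = 68, pct_at_or_above = 100))
  expect_equal(coverage_summary(rep(0, 10), 25),
               c(mean_depth = 0, pct_at_or_above = 0))
  set.seed(17)
  d <- stats::rnbinom(5000, mu = 70, size = 8)
  s <- coverage_summary(d, 25)
  expect_equal(s[["mean_depth"]], mean(d))
  expect_equal(s[["pct_at_or_above"]], 100 * mean(d >= 25))
})

test_that("the exclusion report separates excluded, candidate and uncertain genes", {
  sim <- small_sim()
  rep_tab <- build_exclusion_report(sim$variants, sim$coverage, sim$cnvs,
                                    sim$pedigree, sim$config$panel)
  expect_s3_class(rep_tab, "exclusion_report")
  expect_equal(nrow(rep_tab), 27)
  causal_gene <- sim$config$causal_spec$gene
  crow <- rep_tab[rep_tab$gene == causal_gene, ]
  expect_equal(crow$verdict, "candidate")
  expect_equal(crow$n_segregating_rare_pathogenic, 1L)
  # all other panel genes carry no segregating variant
  expect_true(all(rep_tab$n_segregating_rare_pathogenic[rep_tab$gene != causal_gene] == 0))
  # a well-covered gene without family variants is excluded
  no_var <- rep_tab$n_family_variants == 0 & rep_tab$gene != causal_gene &
    !rep_tab$cnv_overlap
  expect_true(all(rep_tab$verdict[no_var] == "excluded"))
  # a gene absent from the coverage table is insufficient evidence
  panel2 <- rbind(sim$config$panel, data.frame(gene = "GHOST", alias = NA))
  rep2 <- build_exclusion_report(sim$variants, sim$coverage, sim$cnvs,
                                 sim$pedigree, panel2)
  expect_equal(rep2$verdict[rep2$gene == "GHOST"], "insufficient_evidence")
  # the funnel's candidate gene is never excluded
  funnel <- run_funnel(sim$variants, sim$pedigree)
  cand_genes <- stats::na.omit(funnel$candidates$sites$gene)
  expect_false(any(rep_tab$verdict[rep_tab$gene %in% cand_genes] == "excluded"))
})

test_that("an implanted heterozygous deletion changes the gene's evidence", {
  base <- simulate_family(family_sim_config(seed = 77, n_background_variants = 600))
  rep_base <- build_exclusion_report(base$variants, base$coverage, base$cnvs,
                                     base$pedigree, base$config$panel)
  # target: an excluded gene whose exclusion rests on heterozygous variants
  eligible <- rep_base$gene[rep_base$verdict == "excluded" &
                              rep_base$het_in_any_affected &
                              rep_base$n_family_variants > 0]
  expect_gt(length(eligible), 0)
  target <- eligible[1]
  del <- implant_heterozygous_deletion(
    base, list(gene = target, carriers = c("sister1", "sister2")))
  # exon depths halve in carriers
  expect_equal(gene_mean_depth(del$coverage, target, "sister1"),
               gene_mean_depth(base$coverage, target, "sister1") * 0.5)
  expect_equal(gene_mean_depth(del$coverage, target, "mother"),
               gene_mean_depth(base$coverage, target, "mother"))
  # heterozygous presence is abolished while variants remain
  expect_true(het_presence(base$variants, target, base$pedigree))
  expect_false(het_presence(del$variants, target, del$pedigree))
  expect_gt(sum(!is.na(del$variants$sites$gene) &
                  del$variants$sites$gene == target), 0)
  # and the verdict is no longer "excluded"
  rep_del <- build_exclusion_report(del$variants, del$coverage, del$cnvs,
                                    del$pedigree, del$config$panel)
  expect_equal(rep_del$verdict[rep_del$gene == target],
               "insufficient_evidence")
})
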