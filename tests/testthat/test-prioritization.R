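trio_samples <- c("mother", "sister1", "sister2")

test_that("quality gate enforces site quality and per-sample depth thresholds", {
  ped <- quartet_pedigree()
  vs <- build_variant_set(list(
    list(qual = 19.9, gt = list(mother = "0/1", sister1 = "0/1", sister2 = "0/1"),
         dp = list(mother = 50L, sister1 = 50L, sister2 = 50L)),
    list(qual = 20, gt = list(mother = "0/1", sister1 = "0/1", sister2 = "0/1"),
         dp = list(mother = 5L, sister1 = 5L, sister2 = 5L)),
    list(qual = 100, gt = list(mother = "0/1", sister1 = "0/1", sister2 = "0/1"),
         dp = list(mother = 4L, sister1 = 50L, sister2 = 50L))),
    samples = trio_samples)
  kept <- quality_filter(vs, ped)
  expect_equal(kept$sites$vid, 2L)  # edge values 20 and depth 5 retained
  # brute-force predicate scan agrees on simulated data
  sim <- small_sim()
  kept <- quality_filter(sim$variants, sim$pedigree)
  oracle <- vapply(sim$variants$sites$vid, function(v) {
    cc <- sim$variants$calls[sim$variants$calls$vid == v, ]
    s <- sim$variants$sites[sim$variants$sites$vid == v, ]
    s$qual >= 20 && all(!is.na(cc$dp) & cc$dp >= 5)
  }, logical(1))
  expect_setequal(kept$sites$vid, sim$variants$sites$vid[oracle])
  expect_error(quality_filter(vs, pedigree("x", sequenced = FALSE)),
               "no sequenced members")
})

test_that("shared-in-affecteds keeps variants carried by every affected sister", {
  ped <- quartet_pedigree()
  vs <- build_variant_set(list(
    list(gt = list(mother = "0/0", sister1 = "0/1", sister2 = "0/0")),
    list(gt = list(mother = "0/1", sister1 = "1/1", sister2 = "1/1")),
    list(gt = list(mother = "0/0", sister1 = "0/1", sister2 = "1/1"))),
    samples = trio_samples)
  kept <- shared_in_affecteds(vs, ped)
  expect_setequal(kept$sites$vid, c(2L, 3L))
  # set-intersection oracle on simulated data
  sim <- small_sim()
  kept <- shared_in_affecteds(sim$variants, sim$pedigree)
  per_sister <- lapply(c("sister1", "sister2"), function(s) {
    cc <- sim$variants$calls[sim$variants$calls$sample == s, ]
    cc$vid[famfunnel:::has_alt(cc)]
  })
  expect_setequal(kept$sites$vid, Reduce(intersect, per_sister))
  # under two affecteds: warning and pass-through
  solo <- pedigree(c("p", "k"), father_id = c(NA, "p"),
                   affected = c(FALSE, TRUE))
  expect_warning(out <- shared_in_affecteds(vs, solo), "fewer than two")
  expect_equal(n_variants(out), 3)
})

test_that("region and non-synonymous filters act on annotation classes", {
  specs <- lapply(region_classes(), function(rc)
    list(region_class = rc, gt = list(s1 = "0/1")))
  vs <- build_variant_set(specs, samples = "s1")
  kept <- region_filter(vs)
  expect_setequal(kept$sites$region_class, c("coding_exon", "splice"))

  specs <- lapply(consequence_classes(), function(cq)
    list(consequence = cq, region_class = "coding_exon", gt = list(s1 = "0/1")))
  vs <- build_variant_set(specs, samples = "s1")
  kept <- nonsynonymous_filter(vs)
  expect_false("synonymous" %in% kept$sites$consequence)
  expect_true(all(c("stop_gain", "splice_site", "missense") %in%
                    kept$sites$consequence))
})

test_that("segregation filter matches exhaustive trio-genotype enumeration", {
  ped <- quartet_pedigree()
  gts <- c("0/0", "0/1", "1/1")
  combos <- expand.grid(mother = gts, sister1 = gts, sister2 = gts,
                        stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(combos)), function(i)
    list(gt = as.list(combos[i, ])))
  vs <- build_variant_set(specs, samples = trio_samples)
  kept <- suppressWarnings(segregation_filter(vs, ped))
  oracle <- combos$sister1 == "1/1" & combos$sister2 == "1/1" &
    combos$mother == "0/1"
  expect_equal(sum(oracle), 1)  # exactly one of the 27 patterns segregates
  expect_setequal(kept$sites$vid, which(oracle))
  # hom-alt carrier mother is rejected, het mother retained
  expect_true(all(combos$mother[kept$sites$vid] == "0/1"))
})

test_that("unaffected sequenced siblings may not be homozygous alternate", {
  ped <- pedigree(
    id = c("father", "mother", "sister1", "sister2", "brother"),
    sex = c(1, 2, 2, 2, 1),
    father_id = c(NA, NA, "father", "father", "father"),
    mother_id = c(NA, NA, "mother", "mother", "mother"),
    affected = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    sequenced = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  vs <- build_variant_set(list(
    list(gt = list(mother = "0/1", sister1 = "1/1", sister2 = "1/1",
                   brother = "1/1")),
    list(gt = list(mother = "0/1", sister1 = "1/1", sister2 = "1/1",
                   brother = "0/1"))),
    samples = c("mother", "sister1", "sister2", "brother"))
  kept <- segregation_filter(vs, ped)
  expect_equal(kept$sites$vid, 2L)
})

test_that("frequency filter requires rarity in every database plus the cohort", {
  vs <- build_variant_set(list(
    list(mafs = c(db1 = 0.0013, db2 = 0.0089), gt = list(s1 = "0/1")),
    list(mafs = c(db1 = 0.02, db2 = 0.001), gt = list(s1 = "0/1")),
    list(mafs = c(db1 = NA_real_, db2 = NA_real_), gt = list(s1 = "0/1")),
    list(mafs = c(db1 = 0.001, db2 = 0.001), internal_freq = 0.05,
         gt = list(s1 = "0/1"))),
    samples = "s1")
  cfg <- filter_config(population_dbs = c("db1", "db2"))
  kept <- frequency_filter(vs, cfg)
  # 0.0013/0.0089 passes at 1%; 0.02 fails; absent counts as rare;
  # a common internal-cohort allele fails
  expect_setequal(kept$sites$vid, c(1L, 3L))
  # oracle scan over random frequency maps
  set.seed(13)
  specs <- lapply(1:200, function(i) {
    m <- ifelse(runif(2) < 0.3, NA_real_, runif(2, 0, 0.03))
    list(mafs = c(db1 = m[1], db2 = m[2]),
         internal_freq = ifelse(runif(1) < 0.3, NA_real_, runif(1, 0, 0.03)),
         gt = list(s1 = "0/1"))
  })
  vs <- build_variant_set(specs, samples = "s1")
  kept <- frequency_filter(vs, cfg)
  oracle <- vapply(specs, function(sp)
    all(is.na(sp$mafs) | sp$mafs < 0.01) &&
      (is.na(sp$internal_freq) || sp$internal_freq < 0.01), logical(1))
  expect_setequal(kept$sites$vid, which(oracle))
})

test_that("impact filter keeps truncating classes and flagged missense", {
  specs <- list(
    list(consequence = "stop_gain", pathogenic = FALSE, gt = list(s1 = "0/1")),
    list(consequence = "missense", pathogenic = FALSE, gt = list(s1 = "0/1")),
    list(consequence = "missense", pathogenic = TRUE, gt = list(s1 = "0/1")),
    list(consequence = "synonymous", pathogenic = TRUE, gt = list(s1 = "0/1")),
    list(consequence = "frameshift", pathogenic = NA, gt = list(s1 = "0/1")),
    list(consequence = "splice_site", pathogenic = NA, gt = list(s1 = "0/1")))
  vs <- build_variant_set(specs, samples = "s1")
  kept <- impact_filter(vs)
  expect_setequal(kept$sites$vid, c(1L, 3L, 5L, 6L))
  # without the missense extension only the fixed class list remains
  kept <- impact_filter(vs, filter_config(pathogenic_missense = FALSE))
  expect_setequal(kept$sites$vid, c(1L, 5L, 6L))
})

test_that("the funnel is monotone, compositional, and order-robust", {
  sim <- small_sim()
  cfg <- filter_config()
  funnel <- run_funnel(sim$variants, sim$pedigree, cfg)
  # monotone survivor counts
  expect_true(all(diff(funnel$stages$n) <= 0))
  expect_equal(nrow(funnel$stages), 9)
  expect_equal(n_variants(funnel$candidates), tail(funnel$stages$n, 1))
  # compositionality: stage boundaries equal sequential single filters
  v <- quality_filter(sim$variants, sim$pedigree, cfg)
  expect_equal(n_variants(v), funnel$stages$n[1])
  v <- shared_in_affecteds(v, sim$pedigree)
  expect_equal(n_variants(v), funnel$stages$n[2])
  v <- region_filter(v)
  expect_equal(n_variants(v), funnel$stages$n[3])
  v <- nonsynonymous_filter(v)
  expect_equal(n_variants(v), funnel$stages$n[4])
  v <- suppressWarnings(segregation_filter(v, sim$pedigree, cfg))
  expect_equal(n_variants(v), funnel$stages$n[6])
  v <- frequency_filter(v, cfg)
  expect_equal(n_variants(v), funnel$stages$n[8])
  v <- impact_filter(v, cfg)
  expect_equal(n_variants(v), funnel$stages$n[9])
  expect_setequal(v$sites$vid, funnel$candidates$sites$vid)
  # pure site predicates commute: permuted order, same candidates
  set.seed(3)
  filters <- list(
    function(x) region_filter(x),
    function(x) nonsynonymous_filter(x),
    function(x) suppressWarnings(segregation_filter(x, sim$pedigree, cfg)),
    function(x) frequency_filter(x, cfg),
    function(x) impact_filter(x, cfg),
    function(x) shared_in_affecteds(x, sim$pedigree))
  for (perm in 1:4) {
    w <- quality_filter(sim$variants, sim$pedigree, cfg)
    for (f in sample(filters)) w <- f(w)
    expect_setequal(w$sites$vid, funnel$candidates$sites$vid)
  }
})

test_that("an empty call set gives an all-zero funnel", {
  sim <- simulate_family(family_sim_config(seed = 2, n_background_variants = 0,
                                           causal_spec = NULL))
  funnel <- suppressWarnings(run_funnel(sim$variants, sim$pedigree))
  expect_true(all(funnel$stages$n == 0))
})

test_that("the implanted causal variant is recovered across seeded simulations", {
  for (seed in 1:5) {
    sim <- simulate_family(family_sim_config(seed = seed,
                                             n_background_variants = 400))
    funnel <- run_funnel(sim$variants, sim$pedigree)
    expect_true(sim$truth$causal_vid %in% funnel$candidates$sites$vid,
                info = paste("seed", seed))
  }
})

test_that("filter configuration round-trips through a key=value file", {
  tmp <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("min_depth=10", "maf_threshold=0.005",
               "population_dbs=exac,gnomad",
               "high_impact_classes=stop_gain,frameshift",
               "pathogenic_missense=FALSE"), tmp)
  cfg <- read_filter_config(tmp)
  expect_equal(cfg$min_depth, 10)
  expect_equal(cfg$maf_threshold, 0.005)
  expect_equal(cfg$population_dbs, c("exac", "gnomad"))
  expect_equal(cfg$high_impact_classes, c("stop_gain", "frameshift"))
  expect_false(cfg$pathogenic_missense)
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("not_a_key=1", bad)
  expect_error(read_filter_config(bad), "unknown configuration key")
})
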