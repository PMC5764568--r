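#!/usr/bin/env Rscript
# Step 1 -- generate the study dataset: a consanguineous quartet exome
# (two affected sisters and their carrier mother sequenced, father
# unsequenced), 5,000 called background variants, one implanted
# recessive stop-gain allele in FANCM, and two disease-unrelated decoy
# CNVs. Everything downstream reads the files this step writes.
#
#   Rscript analysis/01_simulate.R [--seed <int>]

suppressMessages(library(famfunnel))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

cfg <- family_sim_config(seed = seed, n_background_variants = 5000L)
sim <- simulate_family(cfg)
paths <- write_family_sim(sim, "scratch/simdata")

causal <- sim$variants$sites[sim$variants$sites$vid == sim$truth$causal_vid, ]
cat("Simulated family exome (seed ", seed, ")\n", sep = "")
cat("  variants called:        ", n_variants(sim$variants), "\n")
cat("  sequenced members:      ", paste(sim$variants$samples, collapse = ", "), "\n")
cat("  implanted causal allele:", causal$gene, causal$hgvs_c, causal$hgvs_p, "\n")
cat("  at", paste0(causal$chrom, ":", causal$pos), causal$ref, ">", causal$alt,
    " exac MAF", causal$maf_exac, "\n")
cat("  files written under scratch/simdata/:\n")
for (p in paths) cat("    ", p, "\n")
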