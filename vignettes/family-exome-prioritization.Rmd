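---
title: "Prioritizing recessive variants in a consanguineous family exome"
author: "famfunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing recessive variants in a consanguineous family exome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famfunnel)
```

## The analysis problem

A rare recessive phenotype segregating in a consanguineous family is
mapped by exome sequencing of the available members — here two
affected sisters and their unaffected mother, with the father
unavailable. Under autosomal-recessive inheritance with parental
consanguinity, the causal allele is expected homozygous in both
affected sisters, heterozygous in each parent (obligate carriers), and
rare in the population. The pipeline turns those expectations into an
ordered filter cascade over the multi-sample call set and complements
it with an exclusion analysis that checks, gene by gene over a
candidate panel, whether a causal variant could have been missed.

## The filter funnel

`run_funnel()` applies, in fixed order: a quality gate (site quality
≥ 20, depth ≥ 5 reads in every sequenced member), sharing between the
affected sisters, region class (coding or splice), non-synonymy, the
recessive genotype pattern (split for reporting into
homozygous-in-affecteds and heterozygous-in-carriers, the latter also
rejecting homozygous unaffected siblings), population frequency
(MAF < 1% in every configured database; a variant absent from a
database counts as rare, which is how discovery pipelines treat novel
alleles), internal cohort frequency (< 1%), and predicted impact
(stop gain/loss, frameshift, canonical splice site, or missense
carrying a pathogenicity flag).

Design points worth stating explicitly:

* **"Variant quality" is site QUAL and "depth" per-sample DP.** Caller
  output conventions differ; these are the common semantics of a
  multi-sample VCF, and the genotype-level GQ field is deliberately
  not thresholded.
* **The quality gate is reported as stage 0.** Published funnels
  usually start from an already quality-gated "total"; keeping the
  gate visible makes the cascade self-documenting.
* **Stage order affects intermediate counts only.** Every filter is a
  pure per-site predicate, so the candidate set is order-independent;
  the tests verify this by permuting the cascade.
* **Segregation constraints bind only sequenced members.** An
  unsequenced parent imposes nothing; with no sequenced unaffected
  member the filter warns and constrains the affecteds alone.

Thresholds live in `filter_config()` and can be loaded from a
key=value file (`read_filter_config()`).

## Consequence annotation

`consequence_call()` maps a variant onto a single supplied transcript
model per gene (no multi-isoform collapse): exon intervals are
0-based half-open internally (all interval data in the package use
that convention; variant positions are 1-based, VCF-style, and
converted at the boundary). Positions in the CDS get a 1-based coding
coordinate; codon number is `ceiling(cds_pos / 3)`. Coding SNVs are
classified by codon substitution under the standard nuclear code
(stops TAA/TAG/TGA); coding indels by length difference modulo 3.
Intronic positions within 2 bases of a junction — the canonical
donor/acceptor dinucleotides — are splice; the clinical ±2 convention
is used because region definitions in annotation platforms rarely
state their window. HGVS output covers substitutions
(`c.5101C>T`, `p.Gln1701*`) and simple deletion/insertion forms;
complex delins are out of scope. Minus-strand transcripts are handled
by coordinate reflection, and the test suite checks strand symmetry
and, on hundreds of random transcript/SNV pairs, agreement with a
brute-force oracle that translates the whole mutant CDS.

```{r consequence}
body <- rep("GCT", 1700); body[1700] <- "CAG"
cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
toy <- transcript_model("TOY", "TOY-tx1", "chrT", "+",
                        exons = cbind(0L, nchar(cds)),
                        cds_start = 0L, cds_end = nchar(cds),
                        chrom_seq = cds)
consequence_call("chrT", 5101, "C", "T", toy)[c("consequence", "hgvs_c", "hgvs_p")]
```

## Gene exclusion

`build_exclusion_report()` gathers, per panel gene: mean exon depth
per sample (unweighted over exons; adequacy default 30x — comfortably
below the ~70–90x a well-covered exome shows, so only genuinely
undercovered genes fail it); heterozygous-variant presence in at
least one affected (a heterozygous call is impossible over a deleted
haplotype, so presence rules out hemizygosity); the mean allelic
ratio alt/ref over heterozygous calls pooled across the affecteds
(directional, not folded — real data scatter on both sides of 1; a
`[0.7, 1.4]` band is annotated as unbiased, wide enough to contain
typical binomial scatter at exome depth, and is a flag only, never
part of the verdict); regional variant presence across the
non-coding genic portions (against partial deletions); the count of
variants passing segregation + frequency + impact restricted to the
gene; and overlap with CNVs that survive `cnv_segregation_filter()`
(same state and ≥ 50% reciprocal overlap define "the same CNV" across
samples — a matching rule the CNV literature needs but callers rarely
state). Verdicts: `candidate` if any segregating rare pathogenic
variant; `excluded` if none and hemizygosity is ruled out (het
variants present, or no variants at all), coverage is adequate and no
disease-compatible CNV touches the gene; otherwise
`insufficient_evidence`.

## What the simulator emulates

`simulate_family()` generates the whole input bundle with known
ground truth:

* **Pedigree**: father (unsequenced by default, matching the study
  design where only the mother and sisters had exomes), mother, two
  affected sisters, optionally an unaffected brother.
* **Allele frequencies**: true alternate-allele frequencies are
  Beta(0.5, 5) — a rare-skewed spectrum with mean ≈ 0.09 that yields
  a realistic mix of common and rare sites after conditioning on the
  site being called in the family. `n_background_variants` (default
  5,000) is the number of *called* background sites — the scale of a
  real exome (~40,000 called variants per sample) shrunk an order of
  magnitude so the
  full test suite and the acceptance runs stay in seconds per
  replicate while keeping every count comfortably away from
  small-number artefacts.
* **Consanguinity**: with probability `4F` the two parents share one
  allele identical by descent at a site; children are then produced
  by strictly Mendelian transmission, which gives each child an IBD
  probability of exactly F (default 0.0625, first cousins) while
  keeping every child genotype derivable from its parents — an
  invariant the tests check exhaustively. A naive per-child IBD draw
  would violate it.
* **Depth and balance**: depth ~ NB(mean 70, size 8), matching
  exome-typical mean depth and overdispersion; heterozygous alternate
  reads ~ Binomial(DP, 0.5); genotype quality is a deterministic
  function of depth and balance, since only threshold behaviour
  matters downstream. Site quality ~ Gamma(6, rate 0.1), putting
  ≈ 1.7% of sites under the default QUAL 20 gate.
* **Annotations**: region class, consequence, pathogenicity flag and
  gene assignment are sampled from categorical weights (roughly half
  of variants coding, half of coding non-synonymous), *independently
  of position* — no linkage, no positional realism for background
  sites. Database MAFs are binomial draws from the true frequency at
  each database's chromosome count (EVS/1000G/ExAC-scale), with a
  zero count meaning "not observed"; the internal cohort uses 402
  chromosomes (a ~200-exome in-house collection).
* **The implant**: `implant_causal()` places one stop-gain allele at
  coding position 5101 of the causal gene's transcript (the codon
  there is arranged so the substitution creates a stop), homozygous in
  the sisters, heterozygous in the parents, database MAF 0.001,
  pathogenic-flagged. A specification whose genotypes violate the
  recessive pattern is rejected.
* **Decoy CNVs**: one loss private to sister1 and one gain shared
  with the mother — both correctly discarded by the segregation rule,
  emulating the disease-unrelated CNVs real exomes show.
* **Heterozygous deletions**: `implant_heterozygous_deletion()`
  removes one haplotype over a gene: heterozygous calls are re-emitted
  homozygous for the alternate allele (the retained haplotype is
  taken to be the variant-bearing one, a deterministic simplification)
  with collapsed allelic depths, depth halves at calls and in the
  coverage table, and a CNV loss is added per carrier.

What passing tests on these data do **not** show: performance on real
exomes with linkage disequilibrium, mapping artefacts, batch effects
in databases, multi-nucleotide or complex variants, or X-linked
inheritance (the inheritance model is an extension point and only
`recessive_homozygous` is implemented).

## Numerical and degenerate-input choices

Multi-allelic records are split on ingest into one bi-allelic variant
per alternate allele with allelic depths re-indexed; genotype indices
pointing at a different alternate are recoded as reference-like
("not this alt"). Missing AD with present DP keeps the call but
excludes it from allelic-ratio computations; a heterozygous call with
zero reference reads is skipped with a warning. Missing database
entries pass the frequency filter. An empty call set yields an
all-zero funnel rather than an error. Transcript validation treats
structural defects (unsorted/overlapping exons, CDS length not a
multiple of 3) as errors but a missing ATG/stop as a warning, since
real annotation contains truncated models.

## Problem sizes used in the checks

The acceptance computation uses 20 replicates of 5,000 called
background variants (the modal terminal funnel count over the
replicates is reported); unit and property tests use 150–5,000
variants and 20,000–30,000-site genotype blocks for the statistical
invariants. These sizes were chosen so each check's Monte-Carlo error
is far smaller than the effect it asserts.
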