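Package: famfunnel
Title: Pedigree-Aware Variant Prioritization in Family Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying recessive disease alleles in small
    consanguineous families from whole-exome variant calls. Implements a
    segregation/frequency/impact filter funnel that reduces tens of
    thousands of called variants to a handful of candidates, transcript
    level coding-consequence annotation with HGVS c./p. nomenclature,
    and a candidate-gene exclusion analysis based on exon coverage,
    heterozygosity, allelic read balance, regional variant presence and
    copy-number segregation. A family exome simulator generates VCF,
    PED, coverage and transcript inputs with known ground truth so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    vcfR,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
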