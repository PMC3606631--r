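Package: kirhap
Title: KIR Gene-Content Haplotyping from Multiplex Amplicon Peak Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls presence and copy number of the killer cell
    immunoglobulin-like receptor (KIR) genes from relative peak heights of
    multiplexed amplicon sequencing assays, resolves each diploid genotype
    into phased pairs of gene-content haplotypes against a packaged
    37-haplotype reference catalog, estimates population haplotype and
    motif frequencies by an expectation-maximisation algorithm, computes
    pairwise linkage disequilibrium (D' and r-squared) between KIR genes,
    and localises recombination breakpoints in aligned sequence triplets
    by informative-site chi-square scanning.  A built-in simulator
    generates diploid cohorts, noisy peak observations and recombinant
    alignments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'loci.R'
    'catalog.R'
    'assays.R'
    'genotype.R'
    'resolve.R'
    'popgen.R'
    'breakpoint.R'
    'simulate.R'
    'pipeline.R'
    'io.R'
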