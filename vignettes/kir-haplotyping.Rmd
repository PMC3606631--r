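---
title: "Gene-content haplotyping of the KIR locus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-content haplotyping of the KIR locus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirhap)
```

## The problem

The human KIR locus is a tandem array of highly homologous genes whose
haplotypes vary in gene *content*: which loci are present and in how
many copies. Haplotypes decompose into one centromeric motif (cA01,
cB01, cB02, or the rare cB03) and one telomeric motif (tA01 or tB01),
joined at a recombination hotspot between 3DP1 and 2DL4. On top of the
six major combinations sit recurrent *submotifs*: block deletions
(del3–del10), block duplications (ins3–ins5) and gene hybridisations
(hybd1, and the 2DS2/S3, 2DP1/L1, 2DL1/S1 fusions created by some
deletions). `kirhap` calls diploid gene copy numbers from multiplexed
amplicon peak data, resolves them into phased pairs of catalog
haplotypes, and estimates population haplotype frequencies.

## The reference catalog and its grammar

The packaged catalog holds 37 gene-content haplotypes. Each record
stores a name in `cen|tel[-submotif...]` form, a haploid copy vector
over 15 catalog-level loci (2DS3 and 2DS5 are treated as allele sets of
one merged 2DS35 locus) plus the four hybrid pseudo-loci, and a
population frequency. `load_catalog()` re-derives every copy vector
from the motif gene lists and submotif operations and rejects the table
on any mismatch, so the grammar validates the transcription rather than
trusting it.

Grammar constraints enforced on every haploid vector:

* **Framework**: 3DL3 is present on every haplotype, and every
  haplotype carries a 3DL2 3' end — free-standing or fused into a
  3DL1/L2 hybrid. We phrase the check as `3DL2 + 3DL1/L2 >= 1` because
  the hybd1 haplotype has no free-standing 3DL2, only the fusion gene.
* **2DP1 connection**: the 2DP1-2DL1 block joins 2DL3 or the
  2DL5-2DS35 block, never 2DS2-2DL2 directly.
* **Copy bounds**: 0–2 per haplotype, except the mobile 2DL5-2DS35
  block which can reach 3 copies on one chromosome (both residences
  plus an ins5 duplication).

The per-haplotype frequencies are derived from motif-level summary
percentages: each submotif class's printed frequency is split equally
among its catalogued parent combinations, and the remaining major-motif
mass is allocated under centromere x telomere independence. The
centromeric major percentages count only submotif-free chromosomes
while the telomeric ones also include chromosomes whose centromeric
half carries a cen-only submotif; the derivation honours this
asymmetry, and a construction-time test asserts that the reconstructed
marginals agree with the printed ones to within rounding.

One modelling choice deserves a note: the common form of the
cA01|tB01-del7 haplotype additionally lacks most of 3DL2 (a partial,
intron-level deletion). Because the tool works at gene-content
resolution this is recorded as a boolean attribute of the single del7
record, not as a second record. del8 differs from del7 only in its
breakpoint fine structure and shares its copy vector; the two are
distinct records and their class frequencies are only identifiable as a
sum, which is how they are reported.

## The assay forward model

Fourteen amplicons each co-amplify a family of homologous loci; at each
scored SNP position the dye-terminator peak height of a base is
proportional to the summed copy number of the loci carrying that base,
times an amplicon-specific gain. `expected_peaks()` implements exactly
this linear model. Hybrid genes contribute the parental allele of the
segment the amplicon lies in: the 2DL1/S1 and 2DP1/L1 fusions switch
parent at intron 3, 3DL1/L2 at intron 5/exon 6, 2DS2/S3 at intron 6, so
an exon-3 assay sees 2DL1/S1 as 2DL1 while the exon-4 assays see it as
2DS1. This carriage is a packaged table (`kir_hybrid_carriage.tsv`) and
may be overridden.

The published assay tables print the diagnostic bases; the bases
carried by the other co-amplified genes at each position are not
printed and are a fixed, arbitrary transcription choice in the packaged
table (they only need to differ from the scored base). Positions are
amplicon-local, as printed.

## Copy-number calling

Within one amplicon every height shares one unknown gain, so only
height *ratios* (and presence/absence) are informative. The solver
(`integrate_assays()`) works per sample:

1. **Presence**: a base is present when its height reaches 5% of the
   tallest peak at that position (`detection_floor`; the model offers
   no printed threshold, and 5% sits far below the smallest true
   relative height, 1/8, under the default noise). Every locus carried
   by an absent target is zeroed.
2. **Per-assay enumeration**: for each assay, all integer copy
   configurations of its loci (bounds 0–4; 0–6 for the 2DL5/2DS35
   columns) are scored by the gain-profiled least-squares residual of
   log heights against log predicted copies — the per-assay gain is the
   profiled-out mean log offset, leaving a residual with `n - 1`
   degrees of freedom. Configurations are kept when the residual is
   below `(n + 1) * tolerance^2` and within `2 * tolerance^2` of the
   local best.
3. **Join and anchor**: per-assay solutions are intersected on shared
   loci. Two structural facts close the system: 3DL3 is not
   interrogated by any assay and is fixed at two copies (framework gene
   with no observed deletion), and 3DP1 and 2DL4 — which appear only as
   a joint ratio denominator and are duplicated/deleted as one block by
   every known rearrangement — are carried as a single block count. The
   framework anchor `3DL2 + 3DL1/L2 = 2` pins the telomeric scale.
4. **Known-haplotype screen**: within-amplicon ratios are scale-free,
   so several copy vectors (for example a uniform 1.5x rescaling of a
   homozygote) can fit the ratios equally well. Only vectors
   expressible as the sum of two catalog haplotypes are retained — the
   "match against known haplotype structures" step. If no candidate
   passes, the ratio tolerance is widened (x2, x3.4) and the solve
   repeated; an unscreened best fit is only reported, with a
   discordance note, when widening never helps.
5. **Selection**: among survivors the minimum-residual vector wins;
   exact ties (configurations with identical predicted ratios, which
   arise from genuinely confounded hybrid arrangements) are all
   reported with status `ambiguous`, ordered by the population
   frequency mass of the catalog pairs explaining them.

The default `tolerance` of 0.2 in natural-log space is half the gap
between the 1:1 and 3:2 ratio classes, the tightest adjacent pair in
the published ratio rules; `classify_ratio()` uses it directly as its
unclassifiability cut-off.

A statistical note recorded here because it shaped the design: with
10% multiplicative height noise a *single* peak-height pair has
log-ratio noise of sd 0.14, so isolated nearest-class calls of
3:2-adjacent (and even 2:1-adjacent) classes cross their decision
midpoint in 1–8% of draws. No classifier can call single observations
at 99% accuracy under these conditions. The solver's joint fit over all
scored targets is what achieves >99% per-locus accuracy, and that is
the level at which the noise-robustness tests assert it.

Noiseless identifiability: across all 703 unordered catalog diplotypes
the solver always recovers the true copy vector; 37 diplotypes admit
exactly one additional vector explanation through hybrid-gene carriage
(e.g. an ins5 chromosome plus a del7 chromosome mimics a pair of major
haplotypes in every ratio, because 2DP1/L1 and 2DL1/S1 jointly
impersonate intact 2DP1/2DL1/2DS1 signals). These are reported as
ambiguous calls and resolved probabilistically downstream.

## Diplotype resolution

`enumerate_pairs()` returns exactly the unordered catalog pairs whose
summed copy vectors (2DS35-collapsed) equal the genotype, unioned over
the call's candidate vectors when the call is ambiguous. On the
packaged catalog the 703 diplotypes collapse to 541 distinct genotype
vectors of which 128 are explained by more than one pair (290 of the
703 diplotypes); deletion/duplication complementarity (a del5
chromosome plus an ins3 chromosome sums to two majors) is the dominant
cause. `phase_with_rules()` audits the surviving pairs — placement of
the mobile 2DL5-2DS35 block from its flanking genes, segregation of
mutually exclusive genes onto different haplotypes, strong-LD block
composition — removing violators with an explicit trace, and reports
`unambiguous`/`ambiguous`/`unresolved` without ever breaking a tie
silently: inventing phase would fabricate data.

For genotypes no pair explains, `infer_novel()` subtracts each catalog
haplotype that fits under the genotype and screens the residual
chromosome against the grammar, ranking candidates by submotif-edit
distance to the nearest catalog record (`max_edits` defaults to 2;
deeper searches explode the grammar space). A leave-one-out test
reconstructs every single-submotif catalog record this way.

## Frequency estimation and LD

`em_frequencies()` is a standard EM for multilocus haplotype
frequencies under Hardy-Weinberg: a genotype's likelihood is the sum
over its consistent pairs of `f(h1) f(h2)` (doubled when `h1 != h2`),
the E step allocates each genotype over its pairs posteriorly, the M
step recounts chromosomes. Initialisation is uniform over the catalog;
iteration stops when the log-likelihood gain falls below `tol = 1e-8`
(at most `max_iter = 1000` iterations). The log-likelihood is asserted
non-decreasing on every run — an assertion that caught a genuine
implementation bug (vectorised count updates with duplicated indices)
during development. Haplotypes sharing a copy vector (del7/del8) are
identifiable only as a class; estimates within such a class depend on
the uniform initialisation and only their sum is meaningful.

`motif_summary()` aggregates an estimate into the motif-table layout
(major centromeric rows = submotif-free chromosomes; telomeric rows
additionally count cen-only submotif bearers, whose telomeric half is
intact; one row per single submotif; a combined row for multi-submotif
haplotypes). `submotif_frequency()` sums all haplotypes carrying a
given submotif, including combined ones.

`ld_pairwise()` computes `D' = D/Dmax` and
`r^2 = D^2/(pA qA pB qB)` on gene presence/absence indicators (copy
number is deliberately not used: the design target is the
presence-registering typing the catalog derives from),
frequency-weighted by default or unweighted (`weighted = FALSE`) to
mimic a sequenced-haplotype panel. Monomorphic genes (3DL3) are masked
as undefined. At the motif level 2DL3 and 2DS2 are mutually exclusive
and jointly exhaustive, giving |D'| = r^2 = 1 on the six major
haplotypes; on the full catalog the rare del3/del10 records carry
neither gene, so the full-catalog values sit just below 1. No
multiple-testing correction is applied to LD maps; this is recorded in
the output metadata.

## Breakpoint scanning

`scan_triplet()` detects crossovers in an aligned triplet (query plus
two candidate parents). Informative sites are columns where the
parents differ and the query matches exactly one; at each boundary
between consecutive informative sites a 2x2 chi-square
(left/right flank x supports-A/B, continuity-corrected when any
expected cell is below 5) is tested, Bonferroni-corrected by the number
of boundaries, and maximal non-overlapping significant boundaries are
reported as half-open 0-based column intervals. Defaults: window 20,
alpha 0.001, Bonferroni.

The window unit is *informative sites* per flank by default. At the 5%
parent divergence typical of paralogous KIR gene comparisons, 20
alignment columns contain on average a single informative site and a
chi-square over such flanks has essentially no power; 20 informative
sites per flank (roughly 400 columns at that divergence) is the reading
under which planted crossovers flanked by 20 sites are recovered in
well over 95% of simulations while the familywise false-positive rate
stays at the corrected alpha. The alternative column-based reading is
available as `window_unit = "columns"`. `identity_profile()` provides
the complementary sliding-window percent-identity view used to
pinpoint exchange segments visually.

## The simulator

`sample_cohort()` draws haplotypes i.i.d. at the packaged (or any)
frequencies and pairs them at random. `simulate_peaks()` applies the
forward model, one uniform gain per assay on [0.5, 2] (exercising the
gain-invariance of within-amplicon ratios) and multiplicative
lognormal height noise with `sigma = 0.1` by default — dye-terminator
peak variability is scale-proportional, and 10% is a realistic
inter-peak coefficient of variation for this chemistry.
`simulate_triplet()` builds parents as i.i.d. uniform sequence at a
configured divergence (default 5%, matching inter-paralog divergence
in the regions where crossovers were localised) and a mosaic query
switching parents at the planted breakpoints, with a small
query-private substitution rate (0.005) so that null scans are not
trivially clean. Merged 2DS35 copies are emitted as 2DS3 alleles by
default (`s35_allele`), since the catalog does not distinguish the two.

What the simulator does *not* emulate: allele-level sequence variation
within genes, chromatogram artefacts (primer failure, dye blobs,
mobility shifts), batch effects correlated across assays, and
population structure (no departure from Hardy-Weinberg, no ethnicity
strata). Passing the recovery tests therefore shows the inference is
correct under the stated signal model, not that the wet-lab assay is
robust to artefacts outside it.

## Problem sizes and determinism

The validation suite runs the full 703-diplotype identifiability sweep,
a 10,000-individual frequency-recovery pipeline (about half a minute),
noisy-cohort accuracy at 150–250 individuals, and 700 triplet scans.
All stochastic steps take explicit integer seeds and restore the RNG
state; identical seeds give byte-identical outputs.

## Known limitations

* Absolute copy scale is established by structural knowledge (framework
  anchors and the known-haplotype screen), not by quantitative
  calibration; a genotype built from two genuinely novel chromosomes
  can defeat the screen, surfacing as an unscreened best fit with a
  discordance note.
* The 37 peak-confounded diplotype pairs are intrinsically ambiguous to
  this assay set; resolving them needs segment-specific quantitative
  assays or sequencing.
* 2DS3/2DS5 detail is carried through genotyping but ignored for
  catalog matching, mirroring the catalog's allele-set treatment.
* The breakpoint scanner implements one transparent chi-square method
  with stated parameters, not the portfolio of heuristics found in
  dedicated recombination-detection suites; its calls are intervals
  between informative sites and inherit their spacing as resolution.
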