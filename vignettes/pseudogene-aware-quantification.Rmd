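---
title: "Pseudogene-aware assay design and quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudogene-aware assay design and quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoquant)
```

# The measurement problem

Some genes cannot be quantified by ordinary RT-qPCR because their spliced
mRNA has been retrocopied into the genome several times. Each processed
pseudogene is an intronless, promoter-independent copy of the parent cDNA,
often 85--97% identical to it, and often still transcribed. Any primer pair
placed on exonic sequence — including primers spanning exon--exon junctions,
which pseudogenes retain because they derive from already-spliced mRNA —
amplifies an unknown mixture of parent mRNA and pseudogene RNAs. The
mitochondrial import channel gene *TOMM40*, whose five pseudogene copies
obscure its expression signal in brain tissue, is the motivating case.

`pseudoquant` implements the complete computational workflow for this
situation:

1. **Discovery** (`find_homologous_loci`, `classify_locus`): find every
   cDNA-homologous locus in a genome and classify it as parent, processed
   pseudogene, or diverged paralog.
2. **Discrimination** (`align_to_target`, `find_discriminating_sites`,
   the `design_*` functions): locate target-unique variants and build three
   assay classes — allele-specific primers, splice-junction assays, and
   primary-transcript (intron-targeted) assays.
3. **In-silico PCR** (`find_binding_sites`, `predict_amplification`,
   `cross_amplification_matrix`): predict which assay amplifies which
   template under a 3'-weighted mismatch model, reproducing the observed
   cross-amplification structure.
4. **Quantification** (`delta_ct`, `fold_change`,
   `efficiency_from_dilution`, `dpcr_quantify`, `pool_fraction`,
   `mmp_fold_change`, `compare_groups`): the full ΔΔCT / standard-curve /
   digital-PCR stack, plus mitochondrial phenotype fold changes.
5. **Phylogeny** (`distance_matrix`, `nj_tree`, `bootstrap_support`): the
   paralog family tree with bootstrap support.
6. **Synthetic data** (`generate_locus_set` and friends): seeded generators
   that emulate the full study design with known ground truth.

The central scientific idea is the **primary-transcript surrogate**: parent
pre-mRNA contains introns, pseudogenes do not. An assay with at least one
primer in intronic sequence is therefore structurally incapable of
amplifying pseudogene RNA, and the pre-mRNA level — a roughly constant
fraction of mature mRNA within a tissue type — serves as a specific
surrogate for true parent-gene transcription.

# Homology search

`find_homologous_loci` is a seed-and-extend search:

* **Seeds**: exact k-mers (default `k = 12`), both strands. K-mers occurring
  more than 24 times in the query are dropped as low-complexity.
* **Blocks**: seeds within 16 diagonals and 200 bp of each other collapse
  into colinear blocks; single-seed blocks are discarded as noise (a random
  12-mer match is common at genome scale, two colinear ones are not).
* **Chains**: blocks are chained by dynamic programming, maximizing query
  bases covered minus small gap penalties. Genomic gaps up to 30 kb are
  allowed inside a chain — this is what lets the parent locus chain across
  its introns — while query gaps are capped at 300 bp so flanking noise
  cannot bridge distinct loci. The heaviest chain is extracted and the
  process repeats on the remaining blocks; a short spurious repeat that
  conflicts with a real exon block loses the weight comparison. (An earlier
  greedy nearest-chain heuristic was abandoned after intronic repeats of
  cDNA k-mers were observed to hijack real chains.)
* **Alignment**: each block, and each small inter-block gap, is aligned with
  a banded affine-gap Needleman--Wunsch aligner (Rcpp) under blastn-like
  scoring (+2/−3, gap open −5, extend −2 per base). Hit boundaries are
  refined by ungapped X-drop extension (drop threshold 20), both at chain
  termini and into intron-scale gaps, so mismatch-rich exon margins next to
  introns are still aligned.
* **Identity** is matches over aligned columns with gaps counted as columns
  (megablast-like), except that gap runs of at least `g_intron = 50` bp are
  counted separately as intron-scale gap blocks and excluded from the
  column count — otherwise the parent's own hit would be dominated by its
  introns. Exact parity with NCBI megablast identities is not promised;
  on substitution-dominated copies the aligner reproduces planted
  divergence within ±0.02.

**Classification** follows the two classic pseudogene criteria: a non-parent
locus is a pseudogene iff it is intronless (no genomic-side gap block ≥
50 bp) **or** lacks a full open reading frame (longest ORF < 90% of the
parent CDS). For intron-bearing loci the ORF is judged on the spliced,
query-projected transcript — aligned target segments placed at their query
coordinates, unaligned positions imputed from the cDNA when available —
because the genomic extract of any real gene has its ORF interrupted by
introns. Hits overlapping the parent gene model are the parent; everything
else with introns and an intact frame is a diverged paralog.

Boundary recovery is accurate to a few bases, not exact: when the terminal
base of a planted copy is itself mutated, score-based extension cannot know
the copy extends one base further. Tests therefore check spans to ±10 bp.

# Assay design

Discriminating sites come from a **star alignment**: each paralog is aligned
pairwise to the target and projected onto target coordinates. This keeps
site definitions target-relative and avoids the order-dependence of
progressive multiple alignment. Sites are either *target-unique* (target
differs from every paralog — used for parent-specific primers) or
*paralog-unique* (one paralog differs from target and all other paralogs —
used for pseudogene-specific primers).

Allele-specific primers place a discriminating base at the 3' terminus,
where polymerase extension is most mismatch-sensitive. Enumeration is
exhaustive over position × length (18--25 nt) × strand, filtered by Tm
(57--63 °C, nearest-neighbor with unified duplex parameters, 50 mM Na⁺,
500 nM primer; Wallace rule below 14 nt) and GC content (35--65%), and
ranked by number of 3'-anchored sites, then Tm closeness to 60 °C, then
position. These windows are standard qPCR practice; the source protocol
reports no design constraints, so they are engineering defaults exposed in
`default_design_constraints()`.

Junction assays require the spanning primer to overhang each exon by at
least 4 nt; primary-transcript assays place primers in or across intronic
sequence. Product sizes are constrained to 70--250 bp. Design functions
prefer in-window Tm candidates and fall back to the nearest-Tm candidate
when a window is unsatisfiable on a given template, so design succeeds on
any reasonable sequence; the hard Tm filter remains in the enumeration API.

# The in-silico PCR model

Primer binding is ungapped; a site's score is
\(\prod_{i \in \text{mismatches}} (1 - w_i)\) with positional weights 0.9 at
the 3' terminus, 0.6 at offsets 1--2, 0.3 at offsets 3--4, and 0.1
elsewhere. An assay's combined score on a template is the minimum of its two
primers' best orientation-compatible site scores (3' ends facing, product ≤
2 kb), ties resolved toward the shortest product. Calls: *robust* ≥ 0.5,
*none* < 0.05, *weak* between.

The weights and thresholds are model choices, not measured quantities — the
underlying wet-lab evidence is qualitative gel banding. They are calibrated
structurally: a perfect match scores 1; a single 3'-terminal mismatch scores
0.1, i.e. *weak* — the "leaky" behaviour of allele-specific primers on
near-identical templates — while two anchor mismatches fall below 0.05. Only
call-level patterns are claimed, never band intensities.

The poly-T sizing model is exact arithmetic: amplicon size = 179 bp flank +
tract length; genotype bins S (≤ 198 bp), L (199--208), VL (≥ 209). The
synthetic sizing cohort adds ±1 bp uniform electrophoretic noise, which can
genuinely misclassify alleles of length 19/20 and 29/30; those are flagged
in the truth table.

# Quantification

* **CT calling**: linear interpolation of the first crossing of a fixed
  threshold (default 0.15, in the linear range); curves that never cross are
  censored at the last cycle and excluded from replicate means (with a
  count), never silently imputed.
* **ΔCT** = mean target CT − mean reference CT over replicates (arithmetic
  mean, no outlier rejection); smaller ΔCT means more transcript.
* **Fold change** = \(2^{-\Delta\Delta C_T}\) (Livak). Amplification
  efficiency \(E = 10^{-1/\text{slope}} - 1\) from the dilution-series
  regression is reported for assay QC but deliberately **not** used to
  correct fold changes — matching the uncorrected form used in the protocol
  this package models.
* **Digital PCR**: \(\hat\lambda = -\ln(\text{negatives}/\text{total})\)
  copies per partition, divided by partition volume (default 0.00091 µL for
  a 26,000-partition nanoplate; the plate vendor publishes no volume, so
  this is a documented assumption). The 95% CI is Clopper--Pearson on the
  positive count pushed through the same transform — conservative by
  construction (measured truth coverage 95.0%). A fully positive plate is
  reported as saturated rather than given an infinite point estimate
  silently. Pool fractions are ratios of copies/µL between a target assay
  and a total-pool assay.
* **Group comparison**: two-sided independent-samples t-test, equal-variance
  (student) by default because that is the conventional SPSS setting of the
  protocol being modeled; Welch is available.

# Phylogeny

Distances are p or Jukes--Cantor (`−(3/4)·ln(1 − 4p/3)`) with pairwise gap
deletion (the common MEGA default). Neighbor joining is implemented
directly so the tie rule is guaranteed: among Q-minimizing pairs, the pair
whose clades have the lexicographically smallest representative leaves is
joined — `ape`'s implementation leaves ties unspecified and serves instead
as a cross-check oracle in the tests, along with exact recovery of random
additive matrices. Negative branch lengths are clamped to zero with a
warning. Bootstrap support is column resampling with replacement, NJ per
replicate, and percent of replicates containing each internal bipartition
(counted via `ape::prop.clades`), fully reproducible given a seed.

One caution on interpreting the synthetic family tree: the generator mutates
each copy independently from the parent cDNA, so the true tree is a *star*
centred on the parent. Internal bipartitions of an NJ resolution of a star
are noise-supported; the meaningful structural statement — asserted in the
tests — is that the least-diverged copy is the parent's nearest neighbour by
patristic distance, which is also the copy whose allele-specific primers
cross-react with the parent cDNA.

# What the synthetic generators emulate

`generate_locus_set` defaults reconstruct the motivating system's geometry:
a ten-exon parent (1676-nt cDNA with a real 1020-nt ORF, 12,470-bp genomic
span) and five intronless copies at divergences 4.1--12.7% (the published
identity band), two of them 5'-truncated to 1456/1462 nt, all with a
disrupted reading frame, one planted on the minus strand; plus one
intron-retaining paralog. Realized divergence is exact by construction
(substitutions at a fixed count, no indels by default), which gives the
aligner tests clean truth.

Two generator choices deserve justification:

* **Conserved window** (cDNA 500--860, spanning the exon-4/5 junction
  region): held invariant in all pseudogene copies. This mirrors the
  observed reality that the region targeted by total-pool expression assays
  cross-amplifies *every* pseudogene template — i.e. is well conserved
  across the family — and it is what makes the junction-assay
  cross-amplification demonstration deterministic at any seed.
* **Paralog divergence split** (CDS 15%, UTRs/introns 32%): a functional
  paralog is under purifying selection in its coding exons while its
  non-coding sequence drifts. A uniformly 25--30% diverged copy is both
  biologically unrealistic and unfindable by any exact-seed method (whole
  exons lose all 12-mer seeds), whereas the split model reproduces how such
  paralogs are actually detected: through their conserved coding exons.

The cohort generator plants the study design directly: 47 case vs 20
control samples, triplicate CTs at replicate SD 0.15 cycles, a −1.32-cycle
case effect on ΔCT (≈ 2.5-fold), and six genotype markers with a
group-dependent ε4-carrier frequency. The oxidative-stress generator samples
per-cell-line multipliers uniformly inside the reported ranges (RNA
1.2--1.5×, MtDNA copy number 0.2--0.6×, membrane potential 0.2--0.75×) with
CT noise SD 0.05 cycles and 5% lognormal intensity noise — tight,
cell-line-grade noise levels chosen so that planted effects are recovered
within their bands, as no noise model is published. Normal CT noise and
uniform ±1 bp sizing noise are modeling conventions, not measured error
models.

What passing tests on these fixtures do **not** show: performance on real
genomes with repeat families, segmental duplications, or indel-rich
pseudogenes (the generator's default has no indels; an indel mode exists in
the aligner but not the generator); BLAST-identical identity values;
behaviour of the binding model under degenerate bases or true thermodynamic
extension efficiency.

# Numerical and determinism notes

* All generators are pure functions of (config, seed); they snapshot and
  restore the global RNG state, and repeated calls are byte-identical.
* Alignment band: |length difference| + 32 by default; widened bands only
  change results when indels exceed the band, and the banded score is
  test-verified against full DP.
* Hit merging keeps the higher raw alignment score, ties to the leftmost
  target start. Catalog order: parent first, then descending identity.
* NJ tie rule as above; bootstrap supports are rounded percent.
* Degenerate inputs error early with informative messages: empty FASTA,
  duplicate ids, non-ACGTN characters (with position), N in primers,
  start > end intervals, CTs outside (0, 40], saturated dPCR plates,
  undefined JC69 distances (p ≥ 0.75), all-gap overlaps.

Problem sizes used in the shipped tests: ~14-kb synthetic chromosomes
(full-scale 12.5-kb parent), 2.7-kb pseudogene loci, alignment oracles to
600 bp, in-silico PCR oracles to 2 kb, 200 random trees to 8 taxa, 100-rep
cohort/dPCR/stress simulations. These sizes exercise every code path while
keeping the complete suite under a minute of compute.

# Known limitations

* Repeat masking and repeat-mediated ambiguity are out of scope (the real
  P1 locus is flanked by heavy repeats and was not amplifiable in the wet
  lab; nothing in this package models that).
* The binding model has no indels, degenerate bases, dimer/hairpin
  screening, or polymerase kinetics; probe handling is a placement rule,
  not chemistry.
* Efficiency-corrected (Pfaffl) quantification and multi-reference
  normalization are deliberately absent; the ΔΔCT form is the uncorrected
  Livak estimator.
* Spliced-alignment exon-structure reconstruction is not attempted; intron
  positions in hits are gap blocks, not annotated splice sites.
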