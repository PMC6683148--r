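---
title: "Methods: small RNA discovery and expression profiling in conifer seed tissues"
author: "seedmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA discovery and expression profiling in conifer seed tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Conifer seeds contain three tissues of interest for small-RNA biology:
the zygotic embryo (ZE), the haploid megagametophyte (MG) that feeds
it, and — in clonal propagation programmes — somatic embryos (SE)
raised *in vitro*. Small RNA sequencing of these tissues across
developmental stages yields tens of millions of 18–26-nt reads per
library, from which one wants to annotate conserved miRNA family
isoforms, predict novel miRNAs with their precursor hairpins and
miRNA-star partners, quantify expression across the design, find
differentially expressed miRNAs and their profile groups, and connect
them to putative target transcripts and enriched GO terms.

`seedmir` implements that pipeline end to end, and — because the real
inputs (a multi-gigabase conifer genome, hundreds of millions of reads,
a curated miRNA database) are not reproducible at desk scale — ships a
first-class synthetic-data module that emulates the study design with
full planted ground truth, so every stage is scored against known
answers.

# The synthetic study

`sim_config()` defines the study conditions. The defaults are the
conditions the pipeline is tested under:

* **Design**: sixteen libraries — ZE at five stages (ZE0, ZE3, ZE4B,
  ZE5, ZE7; duplicated except ZE0), MG at three stages (MG0, MG4B,
  MG7; duplicated except MG0), SE at two stages (SE4B, SE7; single
  samples). Stage labels follow the embryo staging system (T0 … T7).
* **Loci**: 12 conserved-homolog MIR hairpins (families drawn from the
  conifer repertoire, e.g. MIR156/159/166/946/947/1311), 8 novel MIR
  hairpins, 6 heterochromatic-siRNA loci emitting 24-nt reads, and 4
  contaminant loci (t/rRNA fragments and low-complexity repeats), all
  planted into a 100-kb random genome, each on a random strand.
* **Hairpin geometry**: a precursor is a perfect inverted repeat —
  lower stem (6 nt), mature (20–22 nt), upper stem extension (4 nt),
  loop (10–14 nt), and the reverse-complement arm. The mature sits at
  the stem base on the 5p or 3p arm; the star is its duplex partner
  under the canonical Dicer rule (2-nt 3′ overhang on each strand),
  i.e. star interval `[P(mature_end)+2, P(mature_start)+2]` under the
  pairing map `P`. Real pre-miRNAs have bulged, imperfect stems; the
  perfect-stem idealization makes the planted truth unambiguous and is
  the main respect in which passing tests understate real-data
  difficulty.
* **Abundances**: per-locus log-normal base intensities (sdlog 1),
  stage programmes (flat, a 6-fold single-stage peak, or a steady
  1.6×/stage increase) and tissue preferences (embryo- or MG-biased,
  20% each, 0.05× in the other tissue). Counts are gamma–Poisson:
  per-library locus intensities are gamma-distributed around their
  means (dispersion 0.15, i.e. CV ≈ 0.39 — typical for biological
  replicates of bulk RNA-seq) and reads are drawn multinomially so that
  each library contains exactly `reads_per_library` (200,000) reads;
  marginally the counts are negative-binomial, and the exact-total
  constraint matches how sequencers deliver fixed yields.
* **Composition**: contaminants take 15% of each library; of the rest,
  the 24-nt siRNA share rises with stage (10% at stage 0 to 35% at
  stage 7), reproducing the observation that 24-nt reads become more
  prominent late in embryogenesis while 21-nt reads dominate
  throughout. Star reads are emitted at 0.25× their mature.
* **Errors**: 0.1% per-base substitution (post-trimming Illumina
  scale), applied after abundance assignment. Qualities are a constant
  placeholder (Q40) and are never used.
* **References**: the mature reference carries, per planted conserved
  family, a homolog at Hamming distance 0, 1 or 2 (round-robin) under
  miRBase-dialect names (`pta-miR156a`), plus decoys at distance ≥ 4;
  the transcriptome plants 2 target sites per planted mature — with
  wobble/mismatch modifications of known expectation score (0 to 4.5)
  — in a dedicated 40% pool of transcripts, leaving the rest site-free;
  the GO map gives every gene a root term, background terms uniformly,
  and one planted term (sulfur-metabolism-flavoured `GO:0006790`) to
  90% of target-pool genes versus 8% elsewhere.

Everything is seeded: the genome, libraries and references derive their
RNG streams from `seed`, `seed + 1` and `seed + 2`, so identical
configurations are byte-identical on disk.

## What the generator does not emulate

No repeat content or multi-mapping families beyond chance k-mer
duplication; no RNA degradation, adapter read-through or quality decay
(reads are born trimmed); no isomiR end-heterogeneity beyond sequencing
error; perfect rather than bulged hairpins; a single chromosome.
Recovery rates on this generator are therefore upper bounds on
real-data performance, which is exactly what makes them usable as
regression oracles: any drop is a pipeline defect, not biology.

# Pipeline stages and their parameters

Defaults carry the study-design thresholds end to end: reads outside
18–26 nt or with total abundance below 5 are removed; mapping is exact
(0 mismatches, both strands, all loci reported); conserved annotation
allows up to 2 mismatches; DE uses p < 0.05 with no multiple-testing
correction; the high-expression shortlist cut-off is 100 CPM; target
selection keeps expectation ≤ 5.

**Collapsing and filtering.** Reads are collapsed to distinct
sequences with per-library counts (U→T internally; N-containing reads
dropped). The abundance threshold is applied to the per-sequence total
across co-processed libraries — the reading that maximizes sensitivity
and matches a pipeline that collapses before filtering — with a
per-library mode available. The low-complexity rule (a filter that sRNA
studies name but rarely define) is: any single nucleotide above 80% of
the read, or a pure dinucleotide repeat; t/rRNA filtering removes exact
substrings of the contaminant reference on either strand.

**Mapping.** A k-mer anchor index (k = 18, the minimum read length)
maps each read by first-k-mer lookup plus full substring verification,
on both strands; reads with no exact locus are flagged unmapped and
excluded from annotation. Multi-mapping reads keep all loci and each
locus is considered independently.

**Conserved annotation.** Ungapped comparison against every reference
mature: Hamming distance at equal length; at length difference ≤ 2 the
shorter slides within the longer and the overhang of the longer counts
as mismatches (the strictest ungapped reading of a two-mismatch
allowance); ties across families record all families, with the
lexicographically smallest as primary and an ambiguity flag.

**Hairpin folding and evaluation.** Candidate precursor windows place
the read near the 5′ or the 3′ end with flanks growing in 25-nt steps
up to 250 nt. Windows are folded by a maximum-weight nested-pairing
dynamic programme (GC = 3, AU = 2, GU = 1, minimum loop 3 nt; compiled
code; traceback prefers pairing and distal partners, favouring long
stems). The backend is pluggable by contract — any function returning a
dot-bracket string can stand in (e.g. a thermodynamic folder) — but the
weighted DP is the default and the one the tests pin down. A candidate
passes when the mature is entirely on one arm, ≥ 75% of its bases are
paired, no unpaired stretch exceeds 4 nt, its partners form a single
stem (monotone, one side, span ≤ mature + 10 nt) and the intervening
loop is ≤ 150 nt. These thresholds follow community plant-miRNA
annotation practice and are configurable; published sRNA pipelines
differ in exactly where they set them. Maximum-weight folding pairs random sequence
aggressively, so an occasional 24-nt siRNA window passes the geometric
criteria — which is why the headline call is *high-confidence* (star
observed among the reads), and why a permissive novel count alongside
a much smaller high-confidence set is expected behaviour.

**Star inference and novel classification.** The star is the duplex
partner shifted for the 2-nt 3′ overhang, with unpaired ends
interpolated from the nearest paired position; it is undeclared when
under half the mature is paired. A call whose inferred star is an
annotated conserved mature is recorded as that miRNA's star; reciprocal
novel calls (each the other's star, within a ±1-nt end tolerance) keep
the more abundant sequence as the mature. Novel identity is the mature
sequence, not the locus; high confidence requires the star (±1-nt end
shifts) among the filtered reads.

**Expression.** CPM is computed against the total filtered reads per
library (so the full table sums to 10^6 per library), then ln(CPM + 1):
the classical transform is ln(CPM), but zero counts occur, and the +1
pseudocount keeps zeros at zero and preserves order. PCA is the
correlation-matrix variant (standardized features via `prcomp`),
zero-variance features dropped, component signs fixed by making the
largest-magnitude loading positive. Replicate consistency uses
average-linkage clustering on 1 − Pearson distances.

**Differential expression.** Per-miRNA one-way fixed-effects ANOVA
across the ZE stages with ≥ 2 replicates, and a pooled-variance t-test
for MG4B vs MG7 (with n = 2 per group, Welch degrees of freedom are
degenerate; pooling is the defensible variant). ZE0 and MG0 have single
replicates and cannot enter a replicated test; treating the earliest
stage as an out-group, their columns are excluded from the test
statistics and used only for profile display. Degenerate
inputs are pinned: all-equal values give p = 1; zero within-group
variance with distinct means gives p = 0. No correction is applied — the uncorrected per-feature test is part
of the procedure this pipeline implements; calibration is instead
verified directly (null rejection rate 0.05 ± 0.01 at 2000 features).

**Profile clustering.** DE miRNA profiles (per-stage replicate means of
ln CPM, z-scored per miRNA) are clustered by k-means with 50 restarts
under a fixed seed; `k = "auto"` maximizes the mean silhouette over
k = 2…8. Because z-profiles live on a fixed scale, a set of
near-identical shapes is flagged as unstructured when the mean pairwise
distance falls below 0.5 (or the silhouette below 0.25) — k-means will
otherwise happily split residual noise.

**Presence and shortlist.** Presence of a miRNA in a tissue/stage
requires detection in every replicate; miRNAs present only in
single-replicate tissues (the SEs) are excluded from the Venn totals.
The shortlist takes replicate-mean CPM ≥ 100 in at least one in-scope
condition (ZE or MG at stages 4B and 7), boundary inclusive.

**Targets and enrichment.** The expectation score is the
psRNAtarget-style additive penalty (match 0, G:U wobble 0.5, mismatch
1, gap 2; doubled at miRNA positions 2–13), following the published
psRNAtarget convention; all constants are configurable. Site scanning
evaluates every window with at most one gap on either duplex strand —
the one-gap limit keeps the search exact and fast at this scale — and
overlapping hits reduce to the best per site. Selection defaults to
E ≤ 5; a narrower literal mode retains 3 ≤ E ≤ 5 — an expectation
window stated as a range admits both readings, so both are provided
and the mode used is recorded in the output. Enrichment is
the upper-tail hypergeometric test per GO term with
Benjamini–Hochberg correction at 0.05, population = all annotated
genes.

# Differential-expression truth under compositionality

The generator's per-locus programme ("flat", "peak", "increasing")
describes absolute activity. CPM is relative: when some loci peak, and
when the 24-nt share grows, every other locus's relative abundance is
compressed, so flat-programme loci are not flat in expected CPM. The
expression truth matrix records the exact expected counts, and
`validate_against_truth()` therefore defines DE truth on expected CPM:
a miRNA is truly DE iff its expected CPM varies ≥ 2-fold across the
tested ZE conditions. With uncorrected per-feature tests at n = 2, the
reported sensitivity is moderate (≈ 0.5–0.85 across seeds) — an honest
property of uncorrected two-replicate testing, not a target.

# Problem sizes and numerical choices

The default synthetic study (16 × 200,000 reads, ~30 loci) runs the
full pipeline in about two minutes on one core; the test suite uses a
smaller mirror of the same design (16 × 8,000 reads) for module tests
and the full default for the end-to-end recovery check. Exhaustive
folding oracles run complete enumerations over two-letter alphabets
(to length 12) plus sampled four-letter sequences (to length 14);
hypergeometric p-values are checked against explicit combinatorial
sums for populations ≤ 25. Ties in k-means are controlled by the fixed
seed and 50 restarts; tie-break in conserved annotation is
lexicographic; the folding traceback is deterministic (pairing beats
unpaired, distal partner first). Contig-edge windows truncate rather
than fail; a star whose overhang would leave the precursor is clipped
to the precursor bounds.

# Known limitations

Maximum-weight folding is not thermodynamic; its structures are only
used for duplex geometry, never for stability claims. The conserved
annotation is ungapped by design. The DE tests apply no
multiple-testing correction, so absolute DE counts are permissive. The GO stage knows nothing of the ontology
graph: terms are independent labels, and no semantic summarization is
attempted. No figures are rendered;
every figure-shaped result is emitted as a table.
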