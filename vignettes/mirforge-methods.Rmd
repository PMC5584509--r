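---
title: "Building a consensus miRNA catalogue: models, thresholds and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a consensus miRNA catalogue: models, thresholds and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirforge)
```

## The problem

Annotating microRNAs in a newly assembled genome is a consensus
problem. No single predictor is adequate: expression-based tools
(miRDeep\*-like) need deep small RNA-seq coverage and miss weakly
expressed genes; homology and covariance-model tools (BLAST-,
Infernal-, GoRAP-like) find conserved genes but produce false calls on
other structured RNAs; grammar-based hairpin finders over-call.
mirforge implements the full computation that turns heterogeneous
per-tool candidate lists plus small RNA-seq alignments into a curated
catalogue: merge, filter, verify by read profile, organise into
genomic clusters and sequence families, predict conserved seed-match
targets with a hypergeometric enrichment test, and compare expressed
miRNA complements across related species as a phylogeny.

Every stage is driven by tabular data (tibbles with
`contig`/`start`/`end`/`strand` in 0-based half-open coordinates) so
results compose with ordinary dplyr pipelines; files move through
standard formats (FASTA, FASTQ, GFF3, BED, Newick, plain gene lists).

## The filter cascade

Candidates ingested from per-tool GFF3 go through a fixed sequence of
rules, each recorded in an audit trail (one rule per removed
candidate):

1. **Gap-free re-anchoring** (`anchor_gap_free()`). A candidate's
   hairpin sequence must be placeable in the genome without
   insertions or deletions (one substitution tolerated by default).
   Candidates with no gap-free placement are dropped; when several
   placements exist the originally reported interval wins if it is
   among them, otherwise the leftmost.
2. **Reliability** (`reliability_filter()`). A candidate is reliable
   if a reference mature matches its hairpin with at most one
   mismatch (homology rescue), or if its predictor score reaches 7
   (inclusive — 7.0 is kept, 6.99 is not). Only the expression-based
   tool is subject to the score rule; conservation-based calls are
   themselves homology evidence and pass.
3. **Overlap de-duplication** (`deduplicate_overlaps()`). Loci on one
   contig whose edge gap is under 100 nt are single-linkage grouped
   regardless of strand (opposite-strand hairpin calls at one
   position are the same physical locus); the best-scoring candidate
   survives, with the union of supporting tools and the union span of
   the group recorded. The union span matters downstream: a
   mature-length call can win on score, but the hairpin extent is the
   union of what all tools saw.
4. **Structure triage** (`extension_triage()`). Loci without a
   reference hit are extended by 50 nt on either side and compared
   against a structured-RNA reference (the comparison engine is
   external; the package consumes its verdicts). A hit to a known
   miRNA structure or no hit at all keeps the locus; a hit to another
   ncRNA class removes it.
5. **Annotation conflicts** (`remove_annotation_conflicts()`). Loci
   overlapping non-miRNA ncRNA genes (any strand) or same-strand
   protein-coding exons are removed; intron-hosted loci are kept,
   since a large share of real miRNA genes are intragenic. The two
   published statements — conflicting candidates were removed, yet
   about half the catalogue is intragenic — are reconciled by exactly
   this class split, and both class lists are configurable.

## Expression verification

The decisive curation step formalises what an annotator sees in a
read browser: a genuine miRNA shows one or two rectangular read
blocks over the mature arms, separated by a loop essentially devoid
of reads, with nothing on the flanks; a degradation product of a
longer transcript shows continuous coverage running past the
precursor. `build_blocks()` reduces collapsed alignments to blocks by
overlap chaining and scores each block's *sharpness* — the fraction
of reads whose 5' end lies within ±2 nt of the modal 5' position.
This replaces a Gaussian-kernel block decomposition deliberately: the
pipeline uses blocks only as a binary shape gate, and the
chaining-plus-sharpness contract is simpler and fully testable.

`classify_profile()` applies, in order: a minimum of 5 total reads
(below: `no_expression`); flank coverage above 10% of the peak
(`rejected_extended`); more than two blocks, or no block with
sharpness ≥ 0.6, or inter-arm coverage above 10% of the smaller
arm's peak (`rejected_diffuse`); otherwise `verified`, with mature
arms annotated from the block intervals (the block nearer the
transcript 5' end is the 5p arm). All thresholds except the absolute
read minimum are fractions, so the verdict is invariant to
sequencing depth. A 5-nt guard band adjacent to the precursor is
excluded from the flank measurement because mature 5' ends naturally
wobble ±2 nt and an edge-positioned arm would otherwise bleed into
its own flank. The published analysis curated profiles manually and
states no numeric thresholds; the defaults here are the package's
formalisation, chosen as the loosest values that cleanly separate
the synthetic positive and negative profile generators, and all are
configurable.

A locus is catalogue-verified if **any** library verifies it (tissue-
restricted expression is common — a miRNA detectable only in brain is
still a miRNA). Unexpressed candidates backed by conservation
evidence stay in the catalogue flagged `putative_unexpressed`;
unexpressed candidates with no such backing, and all profile
rejections, are removed.

## Clusters, families, composition strings

Genomic clusters (`call_clusters()`) chain catalogue entries along a
contig with edge gaps up to 10 kb inclusive, strand-blind, keeping
chains of two or more. Family assignment (`assign_family()`) uses
ungapped sliding identity of the mature against a labelled reference
set: at least 0.9 identity over the shorter sequence plus an exact
seed (nt 2–7); when the two sequences differ in length the seed is
compared at the best alignment offset, since positions 2–7 of a
precursor-length sequence are meaningless. Entries matching no
reference family are clustered into novel families (`NF0001`, …) by
single linkage at the same identity threshold — the reference rule
reused, since no published value exists for it. Cluster composition
strings (`cluster_composition()`) list member families 5'→3' for the
analyst; detecting tandem-repeat patterns in them is deliberately out
of scope.

## Target prediction and enrichment

A target site is the exact reverse complement of the seed (mature
nt 2–7) occurring ungapped at homologous alignment columns in every
required species row of an orthologous 3'-UTR alignment
(`find_seed_sites()`); requiring more species (e.g. adding mouse and
human to the two fish) can only shrink the target list — the
conservative mode. Only the 6-mer site type is implemented by
default; 7mer variants are a configuration extension.

Enrichment of targeted genes in a differentially expressed set uses
the hypergeometric upper tail,

$$p = \sum_{i=r}^{\min(n,R)} \frac{\binom{R}{i}\binom{N-R}{n-i}}{\binom{N}{n}},$$

with \(N\) the gene universe, \(R\) the DE set size, \(n\) the
targeted genes and \(r\) the targeted DE genes, computed in log space
(`hypergeom_pvalue()`) and validated against the exact distribution
function and a big-integer rational oracle to 1e-12 relative error.
P-values are Benjamini–Hochberg adjusted (`bh_adjust()`, the step-up
formula, cross-checked against `p.adjust`) and gated at adjusted
p < 0.05 — the adjusted value is the gate, which is the coherent
reading of describing FDR adjustment and then a 0.05 significance
rule. A per-miRNA mode redefines the universe as all targeted genes
and tests each miRNA's target set.

## Cross-species expression phylogeny

`build_presence_matrix()` calls a miRNA present in a species when any
library reaches the read threshold. Distances are Jaccard on presence
sets, or column mismatch proportions over concatenated mature
sequences (both published descriptions are plausible; both modes are
provided). `bootstrap_tree()` resamples miRNA columns with
replacement, rebuilds an average-linkage dendrogram per replicate,
and reports ordinary bootstrap proportions per clade. Multiscale
(AU) bootstrap support was considered and deliberately not
implemented: the published figure reports generic bootstrap
percentages, and ordinary proportions are sufficient and far easier
to verify.

## The synthetic-data generator

`sim_config()`/`simulate_inputs()` generate every input the pipeline
consumes, with planted ground truth:

* **Genome**: hairpins of 60–120 nt (two 22-nt arms whose sequences
  are reverse complements up to 3 mismatches around a ≥4-nt loop)
  planted on random background, uniformly stranded; decoy loci
  recorded separately. No thermodynamic folding is simulated — the
  pipeline never folds RNA; folding lived inside the external
  predictors. Prescribed clusters are laid out with exact intra-gaps
  on one strand (co-transcription), and cluster members share one
  mature sequence and family, the tandem-duplication situation of
  real miR-430-like clusters; cluster members are always expressed
  for the same reason. Background loci are separated by more than
  the 10-kb cluster distance so the planted cluster architecture is
  the only one present.
* **Tool predictions**: five tools (one expression-based, four
  conservation-based) detect each true locus at sensitivity 0.8 and
  call decoys at rate 0.1, emitting precursor- or mature-length
  intervals per tool; expression-tool scores are drawn at mean 12
  (true) vs 4 (false) so true loci stochastically clear the
  threshold of 7.
* **Reads**: per-arm depth is Poisson with mean 30, read 5' ends
  wobble within ±2 nt, identical reads are collapsed with counts.
  78% of loci are expressed (the published verification rate was
  617/788 ≈ 78%), 5% emit extended (degradation-like) coverage
  across precursor and 50-nt flanks, the rest are silent.
* **UTRs**: 500 genes, 100 DE; a gene carries a planted site with
  probability 0.15, multiplied on the odds scale for DE genes by the
  configured enrichment odds; sites are conserved at identical
  columns in the required species and destroyed elsewhere; occasional
  gap runs are planted away from sites.
* **Species expression**: presence evolves along a planted
  ultrametric 7-taxon tree with loss/gain probabilities
  \(1 - e^{-\text{rate}\cdot l}\) per branch (rates 0.5 and 0.05).
  An earlier uniform-per-branch variant was discarded because it
  gives internal branches no more signal than terminal ones, leaving
  some clades structurally unresolvable at any rate — the
  branch-length model is the standard one and matches the intended
  regime of closely related species sharing most of their miRNAs.

What the generator does **not** emulate: sequencing errors and
quality-score realism, multi-mapping artefacts, genome mis-assembly,
heterogeneous per-tool biases beyond interval length, RNA secondary
structure, and expression covariance across tissues or ages. Passing
the synthetic acceptance suite therefore demonstrates that the
decision rules are implemented correctly and are well calibrated
under the stated noise model — not that the thresholds are optimal
for any particular real library set.

## Numerical and degenerate-input choices

* Quality trimming is hard clipping from both ends (the published
  text does not distinguish hard clipping from sliding windows);
  adapter matching tolerates one mismatch per 10 adapter bases and
  recognises ≥8-nt adapter prefixes at the read 3' end. Trimming
  iterates to a fixed point, which makes it idempotent — a single
  pass is not, because quality clipping can expose a chance terminal
  adapter prefix.
* "Within 100 nt" is read as edge gap < 100; the 10-kb cluster rule
  is edge gap ≤ 10,000 (both boundaries are exercised in tests).
  Midpoint distances were rejected to keep one interval semantics
  everywhere.
* Ties: de-duplication resolves equal scores by the interval emitted
  by most tools, then leftmost start; block mode positions resolve
  count ties to the smallest coordinate; family ties resolve to the
  highest identity then the lexicographically smallest family name.
  All stages are therefore order-stable, and tests permute inputs to
  prove it.
* Degenerate inputs: empty candidate files yield an empty catalogue
  and a zero-count manifest with exit success; a contig too short for
  the requested loci fails with the shortfall in the message; r = 0
  gives p = 1; two empty presence sets are at Jaccard distance 0.
* The hypergeometric sum runs over the feasible range only and is
  log-space stabilised; `lchoose` terms for impossible complements
  are −∞ and drop out naturally.

## Problem sizes

The test and acceptance simulations use 200 planted miRNAs plus 100
decoys on a 4-Mb genome for the end-to-end run, 500-gene UTR sets
with 200 replicates per calibration regime for the enrichment test,
and 50 seeded 7-species matrices of 754 miRNA characters (the size
of the real catalogue, whose full expressed complement feeds the
species comparison) at 1,000 bootstrap replicates for tree recovery.
These sizes give stable pass/fail behaviour for the statistical
checks while each stage remains exhaustively unit-tested at tiny
sizes against hand-computed or brute-force oracles.

## Known limitations

* Scores from different predictors share one `score` column; only the
  expression-tool score has a calibrated threshold. If a
  conservation tool's score scale dominates, its (possibly
  mature-length) interval can win de-duplication — mitigated by
  profiling over the group's union span, but catalogue coordinates
  then reflect the winning call.
* The structure-triage comparison engine is consumed, not
  implemented; triage quality is bounded by the quality of the
  supplied verdict table.
* Family assignment uses ungapped identity; families whose members
  differ by indels in the mature would be split.
* Bootstrap supports are clade proportions on a rooted
  average-linkage dendrogram, not approximately unbiased values; for
  very short internal branches they are conservative.
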