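---
title: "Methods: map-to-pan PAV analysis in panpav"
author: "panpav authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: map-to-pan PAV analysis in panpav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

panpav implements the statistical core of a map-to-pan pangenome
presence/absence-variation (PAV) analysis for clade-structured plant
panels such as wild/landrace/cultivar potato collections spanning
several ploidy levels. The package deliberately starts *after* the
heavy external tools: it consumes alignment-hit records (PAF),
taxonomic hit tables, per-base depth tracks (bedGraph) and gene models
(GFF3), rather than running aligners, assemblers or gene predictors
itself. Everything downstream of those inputs — non-reference sequence
extraction, absence calling, gene-frequency statistics and PAV-based
clustering — is implemented and tested here, and a synthetic-data
generator provides known-truth inputs for every stage.

## Non-reference sequence extraction

Contigs from panel accessions are aligned to a reference; the package
receives the hits and applies four deterministic stages:

1. **Hit filtering.** A hit is kept when its alignment length is at
   least 300 bp *and* its identity at least 90%. Both boundaries are
   inclusive, reading "minimum" thresholds as attainable.
2. **Unaligned-region extraction.** Kept hits are merged per contig
   into a union of covered intervals (0-based, half-open; adjacent
   intervals merge). Every maximal uncovered interval of at least
   500 bp becomes a candidate non-reference segment; a contig with no
   kept hits contributes whole if long enough.
3. **Contamination screening.** Contigs whose taxonomic hits are all
   non-green-plant are removed; mixed contigs are kept when green-plant
   hits cover at least 90% of the query-covered region. Contigs with
   *no* taxonomic hits are kept: the screen removes identified
   contaminants, not unclassified sequence. Organellar screening is the
   same rule with the organelle as the "other" class.
4. **Redundancy removal.** Greedy single-pass clustering in decreasing
   length order: a segment joins the first representative reaching 95%
   identity and 95% coverage, else founds a cluster. The pass is
   deterministic, idempotent on its own output, and leaves no two
   representatives mutually redundant. Multi-tool redundancy cascades
   used in practice do not specify an iteration order; a single
   deterministic longest-first pass is this package's stated choice.

**Identity/coverage definition.** `pairwise_identity()` fits the
shorter sequence globally against its best-matching region of the
longer one (match +1, mismatch −1, linear gap −2), reporting identity
as matches over all alignment columns and coverage as the fraction of
shorter-sequence bases aligned to bases of the longer. A fully global
alignment is unsuitable here: with linear gap costs the length
difference between two sequences is a sunk cost the optimizer can
scatter freely, which lets an unrelated short sequence masquerade as a
near-perfect subsequence of a longer one (we measured ~95% "identity"
for random 500-mers against random 1.4-kb sequences under that
definition). The fitting alignment restores cd-hit-like semantics:
contained duplicates score 100/100, unrelated sequences ~50–60%.

## Absence calling

A gene is called **absent** in an accession when strictly less than
20% of its exonic bases are covered by at least *n* reads, where *n*
adapts to the accession's mean depth: *n* = 2, 4, 6, 8, 10 for mean
depth in [0,10], (10,20], (20,40], (40,80], (80,∞). Two written
ambiguities are resolved as follows:

* "20% of its exon regions" is counted in exonic **bases** (union of
  exon intervals), not whole exons — per-base depth is what a coverage
  track provides, and the base-level reading makes the rule continuous
  in coverage. The whole-exon reading would make calls depend on exon
  annotation granularity.
* The depth bins "41 to 80" and "80+" overlap at 80; we assign mean
  depth exactly 80 to the *n* = 8 bin, reading "80+" as strictly above.

The presence boundary is inclusive at 0.20 (a gene covered on exactly
20% of exonic bases is present), matching the strict "less than"
absence phrasing. `build_pav_matrix()` vectorizes the rule via interval
overlap and is tested for exact agreement with the single-gene path
and with an independent per-base brute-force scan.

## Gene categories, rarefaction and set analyses

Presence frequency is the row mean of the binary matrix. Genes are
**core** when frequency is strictly above 0.97, **cloud** strictly
below 0.03, **shell** otherwise, so the categories partition the gene
set for any thresholds. The strict core boundary follows the ">97%"
results-style reading; both cutoffs are exposed as parameters.

Rarefaction draws random accession orderings (sampling without
replacement, 100 permutations by default, seeded) and tracks the union
(pan) and intersection (core) gene-set sizes as accessions accumulate.
Within every permutation the pan curve is non-decreasing and the core
curve non-increasing by construction; the package asserts this per
permutation, not just on means. For reporting, the plateau is the
smallest k where the mean pan curve gains less than 0.5% over the
preceding 10 accessions.

Clade presence uses an existential rule — a gene is present in a clade
when at least one member carries it — with unique sets and a full Venn
partition whose cells sum to the union. Group core sets use the
within-group frequency with the same strict 0.97 boundary. Group
summaries report mean, depth-weighted mean (down-weighting shallow
accessions, whose calls are noisiest), median and quartiles of gene
counts and of any supplied per-accession annotation column (e.g.
transposable-element counts) — summarization only.

## Selection statistics

For each gene, a 2×2 presence/absence × group table is tested with a
two-sided Fisher exact test (minimum-likelihood convention: the
p-value sums hypergeometric point probabilities not exceeding the
observed one, ties admitted within relative tolerance 1e-12), adjusted
across genes by Benjamini–Hochberg. Fold change is the ratio of the
larger to the smaller presence frequency, +∞ when the smaller is zero
and the larger positive (such genes pass any finite threshold), and 1
when both are zero. A gene is **favorable** at FDR < 0.001, fold > 2
and domesticated frequency above wild; **unfavorable** with the
directions reversed. Favorable genes split further into
landrace-favorable and cultivar-favorable by strict frequency
comparison, with exact ties reported separately rather than assigned.

The implementation computes the exact p-value directly from the
hypergeometric distribution; the test suite verifies it against an
independent binomial-coefficient enumeration for every table with all
margins ≤ 30 and against `stats::fisher.test` on random tables.
Term enrichment is classic per-term Fisher enrichment over a flat
gene→term map with BH adjustment across terms; ontology-graph
propagation and elimination-style algorithms are intentionally out of
scope.

## PAV-based clustering

Distances between accessions are Hamming (proportion of genes with
differing state; default) or Jaccard (shared absence ignored). Hamming
is the default because under clade-structured gene *loss*, shared
absence is informative. Trees are built by neighbor joining with the
standard Q criterion; ties break on the smallest index pair and
negative branch lengths are clamped to zero with the deficit moved to
the sibling edge, so output is deterministic. Support values come from
resampling gene columns with replacement, rebuilding the tree, and
counting how often each internal split of the point tree recurs.

This distance-based tree is a declared substitute for maximum-
likelihood inference on binary characters: the analysis uses the tree
only for clade grouping, NJ is provably consistent on additive
distances (verified on 200 random trees via Robinson–Foulds distance
0), and clade recovery — the property that matters — is asserted
directly. PCA centers gene columns and projects accessions onto
leading eigenvectors (`stats::prcomp`), with component signs fixed by
making the largest-magnitude loading positive.

## The synthetic-data generator

`simulate_study()` generates the package's standard study conditions:

* 3 clades × 20 accessions on a random binary guide tree whose clades
  are monophyletic by construction (clade stems are ordinary branches;
  the gain/loss process acting on them creates clade-level signal);
* 5,000 genes: 2,000 core (present everywhere), 2,500 shell evolving
  by a per-branch Bernoulli gain/loss process (loss 0.08, gain 0.04,
  root presence 0.5), 500 cloud genes placed in at most
  max(1, ⌊3% of accessions⌋) accessions;
* optional ploidy inflation (Poisson-distributed extra presences,
  expectation `ploidy_gene_bonus` per ploidy step) and planted
  selection genes drawn i.i.d. with group-dependent frequencies;
* 30× mean depth; exon coverage in 50-bp constant-depth pieces with
  Poisson(mean depth) depths for present genes; dropout probability
  `noise_fn` = 0.005 and spurious-coverage probability `noise_fp` =
  0.005 for absent genes (a spurious event covers 30% of a gene's
  pieces above the accession's threshold).

The per-branch Bernoulli process was chosen over a continuous-time
Markov chain: the downstream tree is built from PAV distances, not
from a rate model, so branch-length-dependent evolution would add
parameters without adding validation power. Ploidy inflation is
additive in expectation, capturing "polyploids carry more genes"
without modelling homeolog resolution. Coverage is simulated per base,
not per read; read-level artifacts (mapping bias, paired-end
filtering, GC effects) are out of scope, and the spurious-mapping
noise structure is a free parameter of the generator, not an estimate
of any particular dataset. Contig fixtures plant the four truth
classes (reference-derived, novel-insert, redundant pair, contaminant)
with hit records consistent with the planted coordinates; contig
sequence content is random DNA with planted homology, which suffices
for interval and clustering semantics but does not emulate real
repeat structure.

Consequently, passing tests demonstrate that the *rules* are
implemented exactly and that recovery holds under idealized noise;
they do not certify performance on real sequencing data, where error
is structured rather than i.i.d.

## Validation scales and numerical choices

The test suite validates at these scales, chosen to make binomial
bounds tight while keeping the suite quick to run: oracle sweeps of
1,000 random interval fixtures (exact agreement required), an
exhaustive Fisher sweep over all ~164,000 tables with margins ≤ 30
(relative error ≤ 1e-12), 200 random trees for NJ consistency, the
full 3 × 20 × 5,000 study in noise-free (exact recovery, clade
support ≥ 90/100) and noisy form (cell error ≤ 1%, ≥ 95% core
recovery), and 20 replicates of the selection scan (200 planted genes
at 0.9 vs 0.2 among 5,000 nulls; power ≥ 90%, null false-positive
proportion ≤ 0.001). Group labels in the selection fixture are
balanced within clades so that tree-induced presence correlation
carries no group signal — the correct null for size calibration.

Degenerate inputs are defined rather than rejected where a convention
exists: empty depth tracks give all-absent calls; an empty gene-set
union under Jaccard gives distance 0 with a warning; an all-zero
Fisher table is an error; accessions missing from metadata or
coverage are hard errors naming the accession.

## Known limitations

* The dynamic-programming identity oracle is quadratic; for
  chromosome-scale redundancy removal a k-mer prefilter or external
  clusterer would be substituted, with `remove_redundancy()` accepting
  a precomputed comparison function.
* Neighbor joining is O(n³); panels beyond a few hundred accessions
  would need a faster implementation.
* The bootstrap resamples genes, treating them as exchangeable
  columns; linkage between neighboring genes is ignored.
* Fisher tests assume independent accessions; kinship within clades
  makes the test anticonservative when group labels correlate with
  clade structure. Users comparing clade-confounded groups should
  interpret significance cautiously.
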