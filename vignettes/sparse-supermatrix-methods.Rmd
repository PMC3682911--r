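---
title: "Methods: sparse supermatrix assembly, partitioned likelihood and support-aware taxonomy auditing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse supermatrix assembly, partitioned likelihood and support-aware taxonomy auditing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sparsephy` implements the analysis stack used for large-scale,
GenBank-style supermatrix phylogenetics of species-rich clades — the kind of
study that assembles thousands of species sequenced for a handful of
mitochondrial and nuclear loci into one concatenated matrix with extreme
missingness, estimates a partitioned maximum-likelihood tree, attaches
SH-like aLRT branch supports, and audits an existing ranked classification
against the result. The running reference throughout the package is a
12-gene squamate matrix of 4162 terminals and 12896 aligned base pairs with
81% missing cells; its printed per-gene statistics (`squamate_gene_table()`)
are the generator defaults and the bookkeeping checks. This vignette
documents the models, the conventions chosen where published practice is
loose, the numerics, and what the synthetic-data validation does and does
not establish.

## Supermatrix assembly

A supermatrix is built per gene and concatenated
(`concatenate_genes()`); a species absent from a gene receives `?` across
that gene's columns, and records from different genes under the same
binomial are merged into a single composite terminal. Three filtering rules
reproduce standard practice:

* **Longest per species** (`select_longest_per_species()`): within a gene
  pool, the record maximizing non-missing length wins; ties go to the
  earliest record, so the operation is deterministic for a fixed input
  order.
* **Minimum data** (`filter_min_total()`): species whose total non-missing
  length across all genes is strictly below 250 bp are removed. The
  published wording ("sequences totaling less than 250 bp for any species")
  is ambiguous between a per-fragment and a per-species-total rule; the
  total reading is the default because it is consistent with the least
  complete retained terminal (270 bp) in the reference matrix. The
  per-fragment variant is available behind `per_gene = TRUE`.
* **Identical-terminal deduplication** (`deduplicate_identical()`): among
  terminals whose rows agree cell-for-cell — same states where present
  *and* the same missingness footprint — only the case-insensitively first
  label by alphabetical order remains. Requiring the footprint to match is
  the strictest reading of "identical sequences across all genes"; it never
  deletes terminals that any gene could distinguish.

Missing-data semantics are uniform across the package: `?`, `N`, `-` and
any other non-ACGT symbol are fully missing states, contributing a flat
partial likelihood of one. Treating alignment gaps as missing (rather than
as a fifth state) matches the behaviour of the standard supermatrix
toolchain.

## Alignment layer

Coding genes are aligned through translation (`translation_align()`):
each sequence is translated in the frame without internal stop codons
(ties prefer frame 1; a terminal stop stays outside the aligned block;
sequences with stops in every frame are rejected and reported), the amino
acids are aligned progressively, and gaps are expanded 3:1 back onto the
nucleotides, so degapping always recovers the input.

The engine underneath is one profile–profile global aligner with affine
gaps (`profile_merge()`, `pairwise_affine_align()`). The cost convention is
`gap_open + L * gap_extend` for a gap of length `L` (the first gap position
pays both), with protein defaults BLOSUM62 / open 12 / extend 3 and
nucleotide defaults +5/−4 with the same gap scheme (the rRNA scoring is not
published; these mirror common aligner defaults). Published tools do not
document their internal cost convention, so the convention here is pinned
by tests against an exhaustive enumeration oracle on short sequences.
Traceback ties prefer diagonal, then a gap in the second profile, then the
first — determinism matters more than the particular choice. The
progressive guide tree is UPGMA on k-mer distance (k = 6, shortened for
short inputs); any deterministic guide tree is acceptable because the
downstream contracts are property-based (degap round trips, column-only
insertion, singleton equivalence with pairwise alignment).

Two published steps are deliberately not codified: iterative "refine
alignment" passes (internal to the original aligner) and manual by-eye
adjustment. In their place, `trim_ends()` removes leading/trailing columns
below 50% occupancy, and low-occupancy internal columns can be listed for
manual review.

## Partitioned GTR+Γ likelihood

Each partition carries a general time-reversible model with
gamma-distributed among-site rate variation: frequencies π, six
exchangeabilities with GT ≡ 1, and shape α discretized into k = 4
equal-weight categories by category means (the cited tool's default; the
source study never states k). The rate matrix is normalized to one
expected substitution per site at stationarity, so branch lengths are in
substitutions/site. Transition probabilities come from the symmetrized
eigendecomposition (real spectrum for reversible models), and the pruning
kernel (C++) rescales partial likelihoods per node with log accumulation,
which keeps thousands of taxa numerically safe. Pattern compression is
exact: likelihoods are invariant to site and taxon order by construction
and by test.

Partitions share one set of branch lengths with per-partition rate
multipliers constrained to mean one — the standard concatenated behaviour.
When `optimize_model()` renormalizes multipliers it absorbs the scale into
the shared branch lengths, so the renormalization never changes the
likelihood. The default partition scheme is by gene, with coding genes
optionally split by codon position (`write_partition_file()` emits the
`start-end\3` stride syntax); rRNA genes are never split (stems/loops
partitioning is out of scope, as in the reference study).

Numerical choices:

* Branch lengths live in `[1e-8, 10]`. Per-branch optimization uses the
  1-D likelihood profile of each edge (outside partials computed once per
  edge by a C++ kernel, making each Brent evaluation O(patterns) instead
  of a full pruning pass), searching a window `[x/8, 8x]` around the
  current value and widening to the full range only when the optimum
  presses against the window.
* Branch sweeps stop when a full pass gains less than 0.01 log units
  (default), with a warning after 50 sweeps.
* Model optimization is coordinate ascent per partition (empirical base
  frequencies; L-BFGS on log exchangeabilities; Brent on log α in
  [0.02, 100] and on the log rate multiplier), evaluating only the touched
  partition. Data without rate heterogeneity push α to its upper bound,
  which is flagged; single-pattern partitions keep their model, with a
  warning.

## Tree search

Starting trees are seeded random-addition Fitch parsimony
(`stepwise_addition_tree()`): taxa are added in random order, each on the
edge minimizing total parsimony length, ties to the first edge in a
deterministic traversal. The search protocol (`ml_search()`) runs 11 such
starts by default — the reference study's convention — deduplicating
identical starting topologies, optimizes the model once on the first start,
NNI-optimizes each start, and returns the best final likelihood (ties to
the earliest seed), with a final model re-optimization.

`nni_search()` is a hill climb organised in rounds, the round structure
being the one that makes NNI escape shallow local optima in practice. Each
internal edge yields exactly two rearrangements; every candidate is scored
by re-optimizing the five branches incident to the edge (its quartet),
scores are cached per edge and invalidated only in the neighbourhood of an
accepted swap, and candidates are accepted best-first, each verified
against the advancing full-tree likelihood (accepting only gains above
0.01 log units — smaller differences are below the numerical tolerance of
the sweeps). A stalled round triggers one global branch-length refresh
with a cache flush before the climb concludes. SPR moves and bootstrap
resampling are intentionally absent (out
of scope for this stack; the reference analysis likewise relied on
NNI-optimization for its final tree and on SH-like supports instead of
bootstraps).

## SH-like aLRT branch support

For every internal edge, `nni_triplet()` evaluates the current
configuration and its two NNI alternatives, each with local branch
re-optimization, and keeps per-site log-likelihood vectors. `shl_alrt()`
then applies the nonparametric SH-like test with RELL resampling
(B = 1000 by default, the reference implementation's convention): site
weights are drawn multinomially; within each replicate the three totals are
centered by their observed values (the Shimodaira–Hasegawa centering, under
which all three configurations are exchangeable when the branch carries no
signal); the replicate supports the best configuration when the observed
margin `l1 − l2` strictly exceeds the spread (max − min) of the replicate's
centered totals. Support is the percentage of supporting replicates.
Benchmarking the selected margin against the full centered spread is the
conservative reading of the SH correction: it holds supports on zero-length
branches low (mean ≈ 25 in the calibration study) while letting genuinely
supported branches saturate. The published sources state only the null
hypothesis (subtending branch length zero), not the statistic, so the
implementation is pinned by its contract: support lies in [0, 100], is 0
for identical vectors, saturates for overwhelming margins, is monotone in
the number of concordant sites, and is calibrated by simulation (below).
Supports are displayed as integers on the 0–100 scale in Newick node
labels (raw values stay in the per-edge table); 85 is the conventional
strong-support threshold, and summaries use strict `>` by default to match
the usual "nodes with SHL > 85" phrasing while the prose threshold "≥ 85"
remains available.

## Diagnostics and taxonomy audit

`completeness_regression()` is the standard missing-data check: OLS of
terminal branch length on proportional completeness (present bp / total
matrix length — using raw bp instead would not change the correlation),
with Pearson r and its two-sided t-test. `flag_rogues()` is a reproducible
proxy for the qualitative screen used in practice: a terminal is reported
(never removed) when the internal edge above its attachment is weakly
supported (< 50) and its nearest taxonomically labeled neighborhood — the
smallest enclosing clade with ≥ 5 family-labeled tips — is majority a
different family.

`classify_taxon()` operationalizes the informal mono/para/polyphyly
vocabulary on a rooted tree (root on the outgroup first): a taxon is
monophyletic when its tips form one clade; otherwise paraphyletic when the
intruders inside its MRCA form exactly one clade, and polyphyletic when
they are scattered. Taxa with one sampled tip are "trivial" and never
flagged. `conflict_support()` reports the maximum support among edges whose
bipartition splits the taxon while grouping part of it with non-members —
"strongly supported non-monophyly" is operationalized as a conflicting
edge at support ≥ 85 and is labeled as such in reports.

## The synthetic-data generator

The generator exists so that every stage is testable without downloads. It
emulates, and its defaults are calibrated to, the reference matrix:

* **Tree**: Yule, rescaled to a root-to-tip depth of 0.5
  substitutions/site by default — deep-phylogeny scale without saturation.
* **Models**: GTR+Γ with α = 0.5 and mtDNA-like frequencies; mitochondrial
  partitions run at twice the nuclear rate (multipliers renormalized to
  mean one).
* **Occupancy**: gene-wise Bernoulli with the published per-gene coverage
  fractions; a scaffold (8% of taxa by default) always carries the nuclear
  loci, and is carved out of — not added on top of — each gene's nominal
  coverage, so realized per-gene coverage stays at the published fraction.
  An optional mtDNA-only tip set emulates clades represented only by
  mitochondrial data.
* **Fragments**: whole-gene occupancy with the published coverages alone
  yields only ~63% missing cells (1 − Σpᵢ·Lᵢ/ΣLᵢ = 0.634); the real matrix
  reaches 81% because many retained sequences are partial. Retained genes
  therefore keep a contiguous fragment with fraction drawn uniformly from
  0.26–0.66 (scaffold loci stay complete). This was calibrated once against
  the published statistics and then frozen: the default generator realizes
  ≈ 80.5% missing, ≈ 2500 bp and ≈ 3.8 genes per species, against the
  published 81% / 2497 bp / 3.75.
* **Minimum data**: taxa below 250 bp are re-drawn up to 20 times, then
  dropped and logged.
* **Taxonomy**: genera nested in families are assigned to actual clades
  (splitting the largest clade until the requested count exists), so an
  unviolated planted taxonomy is monophyletic by construction; requested
  genus sizes are matched as closely as the tree allows, with a warning on
  mismatch. Violations move named tips across genera to create known
  non-monophyly.

What the generator does *not* emulate: indels and alignment error,
heterotachy, gene-tree/species-tree discordance, contamination and
misidentification, and non-random (phylogenetically clustered) gene
sampling beyond the scaffold and mtDNA-only options. Passing the
validation studies therefore demonstrates correctness of the inference
machinery under the model class it assumes, not robustness to the full
messiness of GenBank data.

## Validation studies and their sizes

Three study functions are shared by the test suite and the acceptance
script; their problem sizes are the package's own desk-scale choices:

* `recovery_study()` — 20 seeds; 8 taxa; the six best-sampled loci (12S,
  16S, cyt-b, ND2, c-mos, RAG-1) at their published coverage fractions,
  3000 bp each (whole-gene occupancy, scaffold fraction 0.25); 11
  parsimony starts. Measured: Robinson–Foulds distance to the true
  topology (target: RF ≤ 2 in ≥ 80% of seeds) and the likelihood margin to
  the optimized truth. With more taxa under the same masks the found tree
  still matches or beats the truth in likelihood, but the data stop
  determining every split — at 10+ taxa the sampled sites genuinely
  support trees a few rearrangements away, so the taxon count here is
  chosen to keep the exercise a test of the machinery rather than of
  finite-sample identifiability. Separately, α is recovered within 10% at 10^5 sites
  and branch lengths within 5% (median) at 5×10^4 sites.
* `shl_calibration_study()` — 10 replicates × 5 internal edges of 8-taxon
  trees; internal branches 10⁻⁸ (null; 1000 sites) vs 0.5 (strong; 5000
  sites). Expected: mean null support < 30; strong support > 95 on ≥ 90%
  of edges.
* `regression_null_study()` — completeness assigned MCAR on 100-tip Yule
  trees; 100 seeds for |r| < 0.2 (≥ 90% of seeds), 500 seeds for the
  slope test's type-I error (≈ 0.05).

## Known limitations

* NNI-only topology search can stall on local optima that SPR would
  escape; multiple parsimony starts mitigate but do not eliminate this.
* The aligner is quadratic in sequence length and intended for desk-scale
  inputs, not genome-length alignments.
* Likelihood ignores ambiguity codes short of full missingness (any
  non-ACGT symbol is treated as missing).
* The rogue screen and the para/polyphyly split are reproducible
  operationalizations of practices that are qualitative in the literature;
  reports label them accordingly.
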