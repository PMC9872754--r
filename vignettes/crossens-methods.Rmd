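---
title: "Methods: cross-species comparison of colonic ENS transcriptomes"
author: "crossens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species comparison of colonic ENS transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossens)
```

`crossens` compares colonic enteric-nervous-system transcriptomes between
pig and human. This vignette is the package's account of the statistical
procedures, the choices that were genuinely open, and what the synthetic
test bed does and does not establish about real data.

## The comparison problem

Two species' RNA-seq experiments are not directly comparable: the gene
universes differ, sequencing depth and library composition differ, and the
interesting question — do the two colons run the same regional expression
*programs*? — lives at the level of functional networks, not individual
genes. The pipeline therefore runs in layers: restrict to trustworthy 1:1
orthologs; normalize within and across species; test distributional
similarity of regional profiles; call regional DEGs; and compare the
enrichment networks those DEGs induce, using linkage coverage rather than
gene-list overlap.

## Ortholog selection

A scored homology table (one row per candidate pair, with homology class,
gene-order-conservation score and whole-genome-alignment score, both on
0–100) is reduced to pairs that are annotated one-to-one and score strictly
above 75 on both metrics. "Above" is read as strict inequality; the
thresholds are arguments. Duplicate rows are removed first; if, after
scoring, a gene still appears in more than one pair, *every* pair touching
it is dropped — strictness over salvage — and the count is reported. The
result is a bijection, which is what makes `map_gene_space()` safe: mapping
a DEG list or an expression matrix across species drops unmapped genes
(with a reported count) and carries values unchanged, and a round trip
restores the mappable subset exactly. Gene identifiers are treated as
opaque strings; no identifier conversion is attempted.

## Normalization

Counts become RPKM (`reads * 1e9 / (total_mapped * length_bp)`), then
`log2(x + 1)`. The pseudocount of 1 is conventional and configurable; note
that it compresses fold-changes of genes expressed below roughly 10 RPKM,
which matters when interpreting effect sizes near the detection floor.

Cross-species scaling follows the median-anchoring idea: choose an anchor
set of stably ranked genes, compute each sample's median expression over
the anchor, and rescale each sample so those medians all equal their grand
mean. The invariant — every sample's anchor median equals the common value
to within 1e-9 relative — is enforced by construction and tested on random
matrices. Because the factor is positive, within-sample rank order is
untouched.

Two points in this step were open:

* **Inner-quartile eligibility.** Requiring a gene to sit inside every
  sample's own [Q1, Q3] becomes vanishingly restrictive as samples accrue
  (with ~66 samples only a percent or two of genes qualify), which is
  inconsistent with anchor sets reported for comparable designs covering
  roughly two-thirds of the ortholog panel. The default therefore deems a
  gene eligible when its cross-sample *mean* expression lies in the
  [Q1, Q3] of gene means (half the genes), leaving the strict every-sample
  rule available as `eligibility = "every_sample"`. A small anchor is not
  just cosmetic: the per-sample anchor median then carries sampling noise
  and bias that propagate multiplicatively into every value of the sample.
* **Scaling space.** Medians are computed and applied in RPKM space, before
  the log transform; the provenance of every matrix records its space.

Rank conservation itself is scored as the variance, across samples, of the
gene's within-sample rank (average ranks for ties, ranks computed over all
genes so that scores are comparable across samples); the requested number
of smallest-variance genes is returned with identifier-order tie-breaking.

Within-species contrasts do not need a cross-species anchor, so the
pipeline runs them on per-species *median-normalized* RPKM (the same
scaling function anchored on all genes). This also removes composition
bias: a strong up-regulated program inflates a sample's total mapped reads
and thus deflates every other gene's RPKM; anchoring on the all-gene median
absorbs that depth artifact, restoring false-discovery control for the
plumbing DE test.

## The plumbing differential-expression test

`simple_de()` is deliberately simple — per-gene Welch t (or Wilcoxon) on
log2 expression with Benjamini–Hochberg adjustment — and is documented as a
stand-in: count-model engines (edgeR, limma-voom) are out of scope, and
externally computed DEG tables are first-class inputs via
`read_deg_list()`. Genes whose mean log2 expression across the tested
samples falls below 1 are not tested (independent filtering): near-zero
counts under `log2(x + 1)` are heavily skewed and inflate the Welch tail,
and removing them both restores type-I control and shrinks the
multiple-testing family. Constant genes under Welch receive p = 1 with a
warning. Directions are A-relative-to-B by sign of the mean difference.

## Distributional similarity

Regional profiles are per-gene means over replicates in scaled space.
Similarity is assessed three ways: two-sample Kolmogorov–Smirnov on the
profiles' ECDFs; a Pearson chi-squared homogeneity test on decile bins of
the pooled sample (the bin count is configurable, reduced automatically
with a warning when the data cannot support it, and no continuity
correction is applied so the statistic matches the textbook 2×k
computation); and Spearman correlation with t-approximation p-values.
The binning choice for the chi-squared comparison is not canonical; the
property suite (size under the null, label invariance), not the exact
binning, carries the contract.

## Enrichment, maps, and linkage coverage

Over-representation is the one-sided hypergeometric upper tail on the
(DEG ∩ term) table against a user-supplied background — the genes detected
in the assay — with BH adjustment across tested terms; terms with no
background genes are skipped with a warning. The test is verified against
exhaustive enumeration of all possible DEG draws for every instance with
background size up to 12.

Term specificity follows the ClueGO-style convention: keep terms at GO
levels 7–15 with at least 1 mapped gene and with mapped genes exceeding
50% of the term's full annotation; then select the smallest level at which
at least 3 terms pass q < 0.05.

The enrichment map links two terms when their member gene sets overlap at
coefficient `|A∩B| / min(|A|,|B|)` ≥ 0.25 (the overlap coefficient, not
Jaccard, per enrichment-map convention) and share at least one gene; the
edge weight is the shared-gene count, called a functional linkage. Two
ambiguities were resolved as follows, both recorded in every report:

* **Linkage accounting.** "Number of functional linkages" can mean edges
  or summed shared genes. Both modes exist; *weight* (summed shared genes)
  is the default because reported linkage magnitudes in this literature
  exceed plausible edge counts for the underlying DEG-list sizes.
* **Edge coverage.** An edge counts as covered by a DEG set when *both*
  endpoint terms contain a DEG of the set — a linkage is a relation between
  two DEG-containing terms. The laxer either-endpoint rule is available
  behind `endpoint_rule = "either"` for sensitivity analysis.

Linkage coverage of a subset is its covered linkage divided by the
reference set's covered linkage; it is 1 for the reference itself, monotone
under subset growth, and errors explicitly when the reference covers
nothing. `cross_species_match()` composes this with the ortholog
projection, so a foreign DEG list can be scored against a native map — the
route by which a few orthologous driver genes can be shown to span an
entire regional network. Term exclusions (e.g. organ-irrelevant
annotations) are a user-supplied list, never hard-coded.

## Pathway-level scores

Per-DEG significances within a pathway are combined with the equal-weight
harmonic mean, `L / Σ(1/p_i)`, chosen over Fisher's method because the DEGs
of one list are dependent events; the asymptotically exact tail
transformation of the harmonic-mean framework is intentionally not included
(the plain statistic is used as a combination score, and its q-values are
BH across pathways within a direction). The up/down enrichment ratio is
defined on the −log10(q) scale (a raw-q mode exists); q = 1 on one side is
flagged infinite, both sides undefined. Gene-gene functional similarity is
the Jaccard index of annotated term sets — a deliberate simplification of
information-content semantic similarity, stated as such. The pro/anti
sharing ratio counts map nodes common to a pathway's term neighborhood
(its terms plus direct neighbors) and each inflammatory signature; node
sharing was chosen over gene sharing as the closer reading of a network
"shared BP" and is the flagged default.

## Single-cell summaries

QC keeps cells with 200–2500 detected genes inclusive and mitochondrial
percentage ≤ 5, then keeps genes expressed in ≥ 3 *retained* cells — the
order matters and is fixed. Markers are one-vs-rest Wilcoxon on
log-normalized counts (counts per 10k, log1p), reported above a natural-log
average fold-change of 0.25 (the base is recorded; only positive markers
are reported). Cell-type DEG lists intersect markers with the bulk DEG
table at p < 0.05, inheriting bulk directions. Ligand-receptor calls are
detection-fraction based: a directed call requires the ligand detected in
more than 10% of source cells and the receptor in more than 10% of target
cells (detection = UMI > 0; the paper states no expression cutoff, so 0.1
is the package's choice, configurable); self-loops are legitimate calls.
The VNS flag marks a call when *either* gene's differential-expression
p-value under stimulation is smaller than without (both per-gene outcomes
are recorded so the stricter both-genes rule is recoverable; a gene missing
from a table compares against p = 1 with a warning).

`cells_required()` answers the design question "how many cells must be
sequenced": the smallest N such that
`P(Binomial(N, fraction) ≥ min_cells)^n_types ≥ confidence`, with exact
binomial tails, independence across types, and N found by incremental
search. Both canonical planning values — 702 cells for 10 types at 2% and
127 for 5 types at 10% (≥6 cells each, 95% confidence) — are reproduced
exactly by this model, which anchors its verification; it warns (without
refusing) when `n_types × fraction > 1`, where independence is only an
approximation.

## The synthetic test bed

The generators emulate the study design rather than any particular
dataset: pig samples over three colonic regions × two plexus layers ×
(6 naive + 3 VNS) replicates, human myenteric samples over three regions ×
4 replicates; one latent log2 expression program shared across species
through a strict 1:1 bijection (with decoy non-1:1 and low-scoring ortholog
records that filtering must remove), perturbed per species by N(0, 0.125)
per gene; planted regional, plexus and VNS programs of |log2FC| = 1.5;
negative-binomial counts (dispersion 0.1, the mean–dispersion
parameterization), uniform library sizes 1–3 million and gene lengths
0.5–5 kb.

Three generator design choices deserve explanation:

* **Planting floor.** Effects are planted only in genes whose *low* side
  keeps ≥ 8 RPKM and ≥ 30 expected reads at the smallest library size. A
  planted effect whose low side sits in shot-noise territory is truth the
  data cannot express; recoverability of planted truth is part of the
  generator's contract.
* **Program size.** The regional program is 300 genes of a 2000-gene
  panel. This is a power-analysis consequence, not a tuning: at effect 1.5,
  dispersion 0.1 and n = 6/6, the per-gene Welch power at a BH threshold of
  ~0.0025 (what a small discovery set induces at 2000 genes) has a
  Monte-Carlo ceiling near 0.85, while the designed recovery scenario for
  the test bed is ≥ 0.9 sensitivity. A sizeable planted program keeps the
  BH threshold in the regime where the designed sensitivity is statistically
  attainable (measured: mean 0.93, FDR ≈ 0.05 across seeds).
* **Gene sets.** GO-like terms are built from disjoint pools except for
  controlled shared blocks, so consecutive terms realize their target
  overlap coefficients exactly; a chain of DEG-enriched terms (overlapping
  windows over the DEG list plus background filler, sharing one specificity
  level) gives the enrichment map real topology; inflammatory signatures
  draw a fraction of their genes from the DEG list so pro/anti sharing is a
  live scenario.

Cells are Poisson-lognormal UMI counts with 20% dropout for five labelled
types (three neuronal, two glial), ten 4-fold marker genes per type, ~2%
baseline mitochondrial content plus small planted blocks of low-complexity
and ~10%-mito cells that QC must remove, and a ligand–receptor table whose
active pair (cholinergic → glia) is detectable at ~50%/40% while inactive
pairs sit near 2%.

What passing these tests shows — and does not. The synthetic data have
exchangeable replicates, a single shared latent program, no batch
structure, no length bias beyond the RPKM model, no ambient RNA or
doublets, and exactly true ortholog annotations. Green tests therefore
establish that the *statistics are computed correctly and behave as
designed under their own assumptions*; they say nothing about annotation
error, batch confounding, or count-model misspecification in real cohorts.
Study-scale headline figures that depend on external cohorts and database
releases are intentionally not targets.

## Problem sizes and determinism

Default problem sizes (2000 genes, 66 bulk samples, 750 cells) complete the
full pipeline in a few seconds on one CPU; the whole test suite runs in
well under a minute. All randomness flows from a single integer seed:
rerunning `run_compare()` with the same configuration writes byte-identical
tables, and each output directory carries a `provenance.yaml` with the
seed, package version, and every threshold actually used.

## Interfaces

The package is a library, not a shell tool: `run_compare()` is the
orchestration entry point (list or YAML configuration, per-stage TSV
outputs), and each stage is an exported function usable on its own. Gene
sets travel as GMT with TSV sidecars for levels, annotation sizes and
categories; counts as TSV; single-cell counts as an MTX triplet; maps
export to GraphML or SIF plus node/edge attribute tables. Multiple-testing
families are fixed and documented: BH is applied within each DEG-list ×
database run (and within each direction for pathway scores).

## Known limitations

The DE stage is a plumbing test, not a count model. Semantic similarity is
set-overlap, not information content. The harmonic-mean combination is used
as a score without the asymptotically exact tail correction, so its
absolute calibration at very small values is approximate. The chi-squared
binning of ECDF comparisons is a convention. The cells-required model
assumes independent types, which overstates certainty when
`n_types × fraction` approaches 1.
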