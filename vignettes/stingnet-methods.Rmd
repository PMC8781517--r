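---
title: "stingnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stingnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stingnet)
```

## The problem

Fish venoms — stingray venoms in particular — are poorly characterised
compared to snake or cone-snail venoms, largely because the venom is
heat-labile, hard to collect in quantity, and dominated by large proteins
rather than the small disulfide-rich peptides classical venomics tooling
expects. Two independent data types are available at reasonable cost: a
venom-gland transcriptome (which toxin-like transcripts are expressed, and
how strongly) and a cell-based high-content screen, HCS (what a crude venom
*does* to cells, summarised as a cytological fingerprint). Neither alone
identifies a mechanism of action. `stingnet` implements the third step:
projecting both data types onto a common functional vocabulary — signalling
pathways and their target systems, as curated in KEGG-style annotation
tables — and building from the *shared* pathways a tripartite network
(entities–pathways–systems) from which symptom-specific subnetworks, such
as a pain cluster, can be read off.

## Annotation filtering and family expression

Similarity-search hits of translated transcripts against a toxin-specific
reference database are filtered with the conventional cascade, all bounds
inclusive:

* identity ≥ 40 %,
* query coverage ≥ 40 %,
* bit score ≥ 30,

then hits on weakly expressed transcripts (TPM < 0.5, strict) are
discarded, and finally only the highest bit-scoring hit per unique
reference accession is kept. Ties on bit score are broken by lower e-value
and then by the lexicographically smallest query id, making the result
independent of row order. The grouping unit for best-hit resolution is the
*subject* accession by default; we expose `scope = "query"` as well because
the per-transcript reading of "best hit" is equally defensible — the
default follows the accession-level phrasing used in the venomics
literature.

Coverage deserves a note: the classic 12-column BLAST tabular format has no
coverage column. The reader accepts either an appended `qcovs` column or a
`qlen` column from which coverage is computed as
`100 * alignment_length / qlen`. Coverage is query-relative by default; the
reference databases involved contain many fragments, which would make
subject-relative coverage erratic.

Toxin-family *relative expression* is the sum of member-hit TPM values
divided by the number of member hits — i.e. the arithmetic mean TPM over
the retained hits of a family. It deliberately is not a sum: it compares
the typical expression of a family's members across families of very
different sizes. Hits whose reference has no family attribution are
reported separately and never aggregated. An optional family → superfamily
map collapses related families before aggregation.

Cross-species comparison uses two statistics: the fraction of families
present in *all* species (intersection over union of family sets, with the
full Venn partition reported) and, per species, the fraction of its
family-annotated hits that fall into those shared families. The
marine-versus-freshwater contrast flags a family as group-differential only
when at least **two** species of a group share the pattern (presence with
complete absence in the other group, or expression strictly above the other
group's maximum / below its minimum in ≥ 2 members). A group with a single
species cannot support a shared pattern, so flagging is disabled for it
with a warning rather than silently producing single-species "patterns".

## Cytological profiles and clustering

Each treatment's fingerprint is built per parameter as

\[ z = \frac{\mathrm{median}(\text{replicate values}) - \bar{x}_{\text{control}}}{s_{\text{control}}} \]

with the sample (n−1) control standard deviation. The median over
replicates is a deliberate robustness choice — a single failed well should
not shift a fingerprint — and the control z-score expresses every parameter
in comparable units (control SDs). Parameters whose control wells are
constant have no scale and are excluded with a warning. An optional QC gate
drops wells with fewer than a configurable number of valid objects before
anything else.

Raw HCS feature sets are large and redundant; the published analyses this
package emulates reduced them stepwise to a compact informative panel. The
exact published reduction procedure is not specified anywhere, so the
package implements a declared three-step stand-in, documented as such:

1. drop (near-)constant parameters (`variance_floor`, default 1e-8);
2. drop parameters never reaching |z| ≥ `z_min` (default 2 control SDs) in
   any treatment — they respond to nothing;
3. greedily drop one of each parameter pair with Spearman |rho| >
   `rho_max` (default 0.95), keeping the higher-variance member (ties keep
   the earlier column).

The endpoint is data-dependent rather than a fixed count; a
`target_count` override exists for emulating a fixed-size panel.

Profile similarity uses the Spearman rank correlation, as distance
`d = 1 − rho` (range 0–2). A `(1 − rho)/2` scale is available for
compatibility with tools that normalise correlation distances to [0, 1];
the 0.7 threshold below is interpreted on the `1 − rho` scale by default.
Clustering is agglomerative with **complete linkage**: the distance between
clusters is the maximum pairwise member distance, so every member of a flat
cluster is within the cophenetic threshold of every other — the natural
reading of "compounds that fell within a distance threshold". The
implementation uses the Lance–Williams maximum update with a fully
deterministic tie-break (among equal-distance candidate pairs, merge the
one with the lexicographically smallest pair of smallest-leaf indices);
the test suite cross-checks it against a naive agglomeration oracle that
recomputes every inter-cluster distance from the original matrix, and
against `stats::hclust` heights on tie-free inputs.

Flat clusters are obtained by cutting the dendrogram at 0.7, and every
reference compound sharing a flat cluster with a venom sample is reported
as co-clustered. A partition cannot represent two venoms with
*partially* overlapping reference sets inside one cluster (the situation
behind "11 of 12 reference compounds overlapped"); for that reading a
pairwise mode is available (`cocluster_mode = "pairwise"`), where a
reference co-clusters with a venom when their direct distance is ≤ 0.7.
The dendrogram cut remains the default because it is what the
clustering-viewer workflow this emulates produces.

Dilution series, where present, are treated as separate leaves (one per
extract–dilution combination); summarising a series to one leaf would
require a potency model that is out of scope.

## Pathway integration

Both entity sets — retained transcript hits (keyed by their best-hit
reference accession, the unit at which functional annotation is possible)
and co-clustered reference compounds — are annotated against an
entity→pathway→system map. Annotation coverage is reported per species and
arithmetically averaged across species, alongside the pooled value. The
**shared core** is the intersection of the transcript-derived and
compound-derived pathway sets; the union is reported alongside (pooled
across species, not per species). Entities are restricted to those touching
at least one shared pathway. The tripartite network then has entity,
pathway and system nodes; entity–pathway edges (`targets`) and
pathway–system edges (`part_of`); every pathway belongs to exactly one
system, enforced at map-reading time. Symptom clusters are induced
subnetworks over user-supplied pathway lists — the curation of which
pathways relate to pain or any other envenomation outcome is a scientific
judgement the package does not automate; it ships example lists only for
its synthetic fixtures.

## The synthetic-data generators

Real inputs for this workflow are multi-gigabyte transcriptomes and
unpublished screening exports, so the package treats synthetic data as a
first-class module. The generators plant ground truth that the pipeline
must recover *exactly*, and write the same file formats the readers
consume.

* `simulate_annotation_dataset()` plants a shared-family core,
  species-exclusive families, an optional group-restricted family, subjects
  without family attribution, fragments and short peptide subjects, plus
  decoy hits that straddle every threshold (identity 39.9, coverage 39.9,
  bit score 29.9, TPM 0.49) and an all-boundary row (40/40/30/0.5) that
  survives filtering but loses best-hit resolution. Margins of ±0.1 around
  each threshold are planted explicitly so tests cannot be flaky. TPM
  values are log-normal (meanlog 1.5, sdlog 0.8, shifted above the floor),
  a standard shape for expression data.
* `simulate_well_data()` builds blocks (venoms plus partner compounds) from
  permutation templates over a fixed value grid. Rejection sampling
  enforces two constructive guarantees: every informative parameter
  receives at least one strong response (so the z-floor cannot drop it),
  and all between-template Spearman correlations satisfy |rho| ≤ 0.25, so
  between-block distances are ≥ 0.75 while within-block distances are
  exactly 0 (replicates are symmetric around their target, making medians
  exact). A small per-well jitter, bounded below half the grid spacing,
  breaks the rank ties that identical block members would otherwise create
  *across parameters* without reordering any sample's own profile — without
  it, the redundancy-reduction step would correctly flag planted
  informative parameters as mutually redundant. Decoy parameters (one
  constant, one duplicated, the rest unresponsive noise) exercise each
  reduction step.
* `simulate_pathway_map()` plants transcript-only, compound-only and shared
  pathway strata, wires every shared pathway to both entity kinds, and
  wires disjoint symptom blocks to exactly the requested member counts.

`simulate_master_fixture()` combines the three into one documented study
sized like a realistic five-species stingray analysis: 19 shared families
in an 80-family union (23.8 % overlap, shared families carrying ~69 % of
hits), ~6 % peptides among non-fragment hits, 31 informative parameters
out of 40, three venom samples (two marine sharing one phenotype block, one
freshwater) with 120 co-clustering references and 10 noise compounds, and a
pathway map with a 216-pathway union, 29 shared pathways over 15 target
systems, 70 core transcripts and 70 core compounds, including a pain block
of 9 pathways / 20 transcripts / 41 compounds and a smaller cardiovascular
block. All generators are pure functions of their arguments and seed
(rejection loops consume the seeded RNG stream), so regeneration is
byte-identical.

What passing these tests shows — and does not show. Recovery of planted
structure demonstrates that the implementation performs each declared
operation correctly and deterministically. It does not validate the
biology: real cytological profiles have correlated noise, batch effects and
dose–response structure; real annotation databases have redundancy and
version drift; real pathway maps are incomplete in structured ways. None of
those are emulated.

## Numerical choices and degenerate inputs

* Thresholds are inclusive (≥), the TPM floor exclusive (<), exactly as
  conventionally printed.
* Percentages live on the 0–100 scale throughout.
* Spearman correlation uses average ranks for ties; a zero-rank-variance
  profile is an error, not a silent NA.
* The complete-linkage tie-break (lexicographic smallest-leaf pair) makes
  trees invariant to input order up to leaf relabelling; heights are
  provably monotone under complete linkage, and the distance values
  produced by the Lance–Williams max update are exact maxima of original
  matrix entries, so tie detection by exact equality is sound.
* An empty filter result, an empty shared core and an empty symptom
  cluster are all valid outputs (with warnings where informative); a
  zero-denominator peptide fraction returns `NA` rather than erroring.
* The pipeline itself draws no random numbers; identical inputs and
  configuration give byte-identical TSV/CSV/JSON outputs and
  canonically-ordered GraphML.

## Problem sizes

The shipped tests and the acceptance script run the master fixture at the
dimensions above (133 clustered samples, ~420 retained hits, 216 pathways)
and the property suites at 200–500 random cases each, with clustering
oracles at n ≤ 8 — sizes chosen so the whole suite completes in well under
a minute on a laptop while still exercising every tie-break and boundary.

## Known limitations

* The stepwise parameter reduction is a declared stand-in for an
  unspecified published procedure; with `target_count` it can emulate a
  fixed panel size but not the original statistics.
* Symptom definitions are inputs, not inferences.
* Best-hit scope, distance scale and co-cluster mode each have two
  defensible readings; all are configurable, and the defaults are
  documented above.
* No live database access: annotation quality is entirely that of the
  supplied map files.
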