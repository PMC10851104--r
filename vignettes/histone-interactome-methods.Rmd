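---
title: "Methods: histone/nucleosome interaction networks in histonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histone/nucleosome interaction networks in histonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histonet)
```

`histonet` implements a pipeline from macromolecular structures of
histone/nucleosome complexes to annotated interaction networks, binding-mode
and hotspot profiles, and interface-mapped cancer mutation analyses. This
vignette documents the model, its assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Interface model

A binding interface is defined purely geometrically: two residues on
different chains are in contact when **any pair of heavy atoms lies within
5 Å**. Three aspects of this definition are deliberate:

* **Inclusive comparison** (`d <= cutoff`). Whether the boundary itself
  counts is a measure-zero question for real coordinates; we fix it
  inclusively so that planted test geometries are unambiguous. The synthetic
  generators never place atoms inside a ±0.1 Å band around the cutoff, so no
  test outcome can hinge on floating-point behavior at the boundary.
* **Heavy atoms only.** Hydrogens (and deuteriums) are excluded; most
  experimental structures do not resolve them, and including them would make
  the contact definition depend on whether a model was protonated. Elements
  are taken from the element column when present and inferred from atom-name
  conventions otherwise.
* **No energetics.** Buried surface area or energy-based interface
  definitions are out of scope; the distance criterion is the model.

Contact detection uses a uniform spatial grid with cell edge equal to the
cutoff, comparing only atoms in adjacent cells. This is an implementation
detail, not a model choice: the test suite asserts exact equality (pair sets
and minimum distances to 1e-6 Å) with a brute-force all-pairs oracle on 50
random structures of 200–2000 atoms, a size chosen to keep the oracle
affordable while exercising multi-cell geometry.

Chains are typed protein/DNA/RNA by residue composition (majority wins for
hybrid chains, with a warning). Protein chains become *histones* by
case-insensitive keyword match of the entity name against a bundled,
user-editable YAML config, with a fallback on global sequence identity ≥ 60%
to a bundled reference sequence per histone type. Identity is computed as
alignment matches divided by the length of the longer sequence, so a short
fragment cannot score as a full-length match. The keyword list approximates
the keyword searches used to retrieve histone entries from structural
databases and is expected to be overridden for unusual naming schemes.

Contacts are classified by the chain roles into HHI, HDI, HPI and DPI.
Partner–partner and DNA–DNA contacts are computed (they are cheap) but
excluded from the four-class networks. RNA chains, which the four-class
model does not cover, are treated as partners and can be filtered by their
molecule class. Modified residues such as ALY or M3L stay in the polymer so
that PTM-site contacts remain detectable; the component → PTM-type map is
config, not code.

## Networks and granularity

The network container is a simple undirected graph: no self-loops, no
multi-edges, canonical edge orientation, and a per-edge **evidence set**
(structure ids, `crosslink`, `highthroughput`). Residue-level nodes are
keyed by molecule identity plus sequence position (structure numbering is
mapped to sequence coordinates through a SIFTS-like table, or an identity
mapping); DNA nucleotides are keyed per chain and residue because sequence
coordinates are not meaningful for synthetic duplexes.

Collapsing granularity replaces each node by its domain or protein parent
and keeps an edge between coarse nodes iff at least one residue-level edge
connects their members (verified exhaustively against that definition on
random networks). One consequence is stated rather than hidden: residue
contacts between the two copies of the same histone variant (e.g. H3–H3′)
collapse onto a single protein node and would become self-loops; the
container forbids self-loops, so they are dropped and counted in an
attribute. At protein granularity DPI edges attach to a single DNA
pseudo-node.

Cross-link and high-throughput evidence enters at protein level only —
those experiments do not resolve residue pairs at the fidelity of a crystal
structure, and the merge keeps their provenance separate in the evidence
sets. The global interactome adds one layer of partner-of-partner edges;
edges touching no existing node are dropped and counted.

## Topology

Maximal cliques are enumerated with the Bron–Kerbosch recursion with
pivoting, checked against exhaustive subset enumeration (all 2^n subsets,
n ≤ 12) and against an independent library implementation. Maximal Clique
Centrality applies the published formula literally:
MCC(v) = Σ (|C|−1)! over maximal cliques C containing v. An isolated node
owns its singleton maximal clique and scores 0! = 1; we do not replicate any
special-casing for edge-free neighborhoods that particular hub-detection
tools may add, because the formula itself is unambiguous. Hub calling
supports both an MCC threshold (default 4) and a fixed top-N, since both
conventions are in use.

The topological coefficient follows the NetworkAnalyzer convention:
T(v) = mean over nodes m ≠ v sharing at least one neighbor with v of
J(v, m) / k(v), with J counting shared neighbors plus 1 if v and m are
adjacent. Nodes with no co-neighbors report 0 with an `undefined` flag
rather than NA, so downstream tabulation never propagates missingness.
Clustering and betweenness are delegated to igraph (with C defined as 0 for
degree < 2); betweenness is normalized by (N−1)(N−2)/2.

`powerlaw_decay_check()` regresses the per-degree mean coefficient on degree
in log–log space and reports the Spearman correlation between degree and the
per-node coefficient **over nodes with a positive coefficient**. The
restriction is a numerical necessity, not a convenience: zero coefficients
have no representation on the log scale on which the decay is defined, and
in preferential-attachment graphs the mass of minimum-degree nodes with
exactly zero clustering would otherwise dominate the rank correlation and
invert its sign. The decay property is asserted across 20 seeded
preferential-attachment graphs (n = 2000, m = 3), matching the scale of a
global interactome while keeping the check under a couple of minutes.

The bundled preferential-attachment generator grows from m unconnected seed
nodes, each new node attaching to m distinct existing nodes proportionally
to degree, giving exactly m(n−m) edges. While any node remains below degree
m, one attachment slot per step is forced onto the most deficient node; this
seed-graph regularization guarantees minimum degree m without changing the
edge count and becomes inactive after the first few steps.

## Binding modes, representatives, hotspots

Representative selection applies, in order: structures with fewer than 7 of
the 8 core-histone chains are subnucleosomal and removed; structures where
more than 20 bp of nucleosomal DNA lack any 5 Å contact with the octamer are
removed (detached DNA invalidates DNA-side binding-mode calls); partners
shorter than 10 residues are removed as peptides; and within each partner,
structures whose interface-residue Jaccard similarity is ≥ 0.8 are treated
as the same binding mode, keeping the highest-resolution mutation-free
member (mutation-free preferred over resolution; ties broken by structure
id; a contested group with missing resolution is an error naming the
structure). The 0.8 Jaccard is a design choice — no published number exists
for "identical binding mode" — selected so that genuinely distinct binding
modes (which in practice share well under half their interface residues)
are never merged; it is exposed as a parameter. Selection is idempotent by
construction and by test.

Binding modes are determined solely by which interface sets are non-empty:
`dna_only` (DPIs without HPIs), `histone_only` (HPIs without DPIs), `both`
(multivalent). Partners with no contacts at all are labeled `none`, warned
about, and excluded from mode fractions.

Histone hotspots are profiled on consensus coordinates: a residue's
consensus position is the alignment column holding its variant's p-th
non-gap character, from a user-supplied alignment (running the aligner is
out of scope). Unique-partner counts are per partner *molecule*, so a
partner engaging through two chains counts once; mean atomic contacts are
averaged over the (structure, partner) pairs that touch a position — not
over all structures — so sparsely-seen positions are not diluted. DNA
hotspots pair strands by reverse-complement indexing (strand II nucleotide
j pairs with base pair L+1−j), tolerate strand-length differences up to 4
nt, and index base pairs relative to the dyad. The dyad is configuration:
inferring it geometrically is out of scope, and absent a value it defaults
to the strand midpoint (ceiling(L/2); 74 for a 147-bp duplex). Superhelic
locations are reported as bp/10 rounded.

## Mutation curation and ΔΔG

The curation filters mirror standard practice for somatic mutation tables:
targeted panels are dropped (their gene selection biases burden and
recurrence), somatic-unmatched calls are dropped (germline contamination),
and only missense calls proceed. The refined set drops samples with tumor
mutation burden strictly above 10 mutations/Mb (hypermutators inflate
passenger counts), drops dbSNP-known variants (likely germline), and keeps
mutations recurring in at least 3 distinct samples — recurrence is keyed on
gene + amino-acid change across cancer types, computed after the preceding
filters. TMB comes from the input column when present and otherwise derives
as per-sample mutation count over a configurable callable territory
(default 38 Mb, a standard exome size). The inequality directions (strict
for TMB, inclusive for recurrence and ΔΔG) are fixed in one place.

Interface mapping is per unique mutation: the (gene product, position) node
either participates in edges of a class or it does not; one mutation may map
to several classes and mutations on all three histone-side classes are
reported separately. Physicochemical profiling uses a fixed five-way
partition: positive {K, R, H}, negative {D, E}, polar uncharged
{S, T, N, Q, C}, nonpolar aliphatic {G, A, V, L, I, M, P}, nonpolar aromatic
{F, W, Y}. Histidine sits with the positives (protonatable; its interface
behavior is charge-like) and cysteine with the polar uncharged class;
alternative conventions exist, which is why the classifier is a single
exported function.

ΔΔG prediction is a plugin contract:
`predictor(structure, chain, position, wt, mut, mode) -> kcal/mol`, positive
= destabilizing. For HHI and HDI requests the partner chains are pruned from
the complex before the call (the quantity of interest is internal nucleosome
stability); for HPI the full complex is passed. Trained predictors are
external tools; the package ships only a deterministic **surrogate** — a
fixed function of charge, hydropathy and volume differences — which is
labeled non-physical, exists so that the pipeline and its tests are
deterministic and self-contained, and must not be used for inference.
Disruptive calls use per-mutation means over distinct structures with
class thresholds 1.0 kcal/mol (HDI) and 1.5 kcal/mol (HHI, HPI) and the
recurrence ≥ 3 gate. Group comparisons use one-way ANOVA with Tukey HSD and
significance flags at 0.05 and 0.005; the test suite calibrates the 0.05
flag under a seeded null (≤ 10% false positives over 100 replicates) and
checks power under a 5-SD shift.

## What the synthetic data does and does not show

The generators exist to plant ground truth, not to imitate physics. Toy
complexes are poly-alanine backbones with one designated contact atom per
residue, laid out on rows 100 Å apart with 14 Å between residues, so the
*only* inter-chain proximities are the planted ones; planted contacts fall
in [cutoff−0.5, cutoff−0.1] and planted non-contacts in
[cutoff+0.1, cutoff+2.0], and each realization is re-verified by an
all-pairs scan before the truth sidecar is written (up to 20 jittered
retries, then an error). Mutation tables plant exact counts per filter
class, recurrence structure, interface placement, and designed-disruptive
substitutions whose surrogate scores clear the thresholds by at least
0.3 kcal/mol.

Passing tests on these fixtures therefore demonstrates that the *rules* are
implemented exactly — the classifiers, filters, counters and selectors
return planted truth — and that the optimized geometry code equals its
brute-force definition. They do not demonstrate anything about real
nucleosome geometry: no superhelical DNA path, no side-chain packing, no
crystallographic noise, no disorder, no real PTM chemistry, and no trained
energetics. Conclusions about real structures inherit the accuracy of the
5 Å heavy-atom definition and, for ΔΔG, of whichever external predictor is
plugged in.

## Problem sizes and determinism

Default test and acceptance sizes — 50 random structures of 200–2000 atoms
for the contact oracle, 100 graphs of n ≤ 12 for the clique oracle, 20
networks for collapse soundness, 20 preferential-attachment graphs at
n = 2000 for the decay property, 100 random tables for filter monotonicity,
100 replicates for Tukey calibration — were chosen as the smallest sizes at
which the corresponding property is meaningfully exercised rather than
trivially true. Every stochastic step is seeded; generators emit
byte-identical files for identical seeds, and the command-line subcommands
write a JSON run log with versions, seed and parameters (timestamps live
only in the log).

## Known limitations

* Model 1 only; alternate locations other than blank/'A' are discarded
  (no occupancy-based tie-break). Ensembles are not analyzed.
* No symmetry expansion or assembly generation: interfaces present only in
  a crystallographic neighbor are invisible.
* Entity metadata recovery from mmCIF is limited to the description/strand
  blocks the bundled writer emits plus standard `_entity` loops; exotic
  header layouts fall back to sequence-identity typing.
* The DNA pseudo-node at protein granularity makes all DPI partners
  one-hop neighbors of "DNA"; interpret protein-level DPI topology
  accordingly.
* Histone copy-pair (H3–H3′) interactions vanish at protein granularity
  (self-loop rule above); analyze them at residue level.
* The surrogate ΔΔG predictor carries no physics whatsoever.
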