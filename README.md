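# histonet

Histone and nucleosome interaction network analysis in R.

Nucleosomes — ~147 bp of DNA wrapped around an octamer of two copies each of
histones H2A, H2B, H3 and H4 — are engaged by chromatin remodelers, PTM
readers/writers/erasers, transcription factors and many other partners.
`histonet` turns macromolecular structures of these complexes into annotated
interaction networks and analyzes them: which residues touch, which partners
bind where and how, which network nodes are hubs, and which cancer-associated
histone mutations fall on binding interfaces and are predicted to disrupt
them.

The package is aimed at structural bioinformaticians and chromatin biologists
who want a reproducible, scriptable version of this analysis for their own
structure collections, mutation tables and interaction evidence.

## What it computes

**Interfaces.** Binding interfaces are residue pairs on different chains with
any pair of heavy atoms within 5 Å (inclusive; configurable). Each contact is
classified into one of four interaction classes:

- HHI — histone–histone,
- HDI — histone–DNA,
- HPI — histone–partner (partner = any non-histone protein in the complex),
- DPI — DNA–partner,

with partner–partner contacts recorded but excluded from the four-class
networks. Contacts at modified residues (ALY, M3L, KCR, …) are flagged with
their PTM type. Chains are typed histone/partner/DNA by entity-name keywords
with a sequence-identity fallback against bundled reference sequences (both
user-overridable).

**Networks.** Residue-level edges from many structures merge into a simple
undirected graph with per-edge evidence sets; the graph collapses to domain
and protein granularity, merges with cross-link and high-throughput
protein-level evidence, and expands by one partner-of-partner layer into a
global interactome. Exports: SIF (Cytoscape), TSV, JSON round-trip.

**Topology.** Per node: degree, local clustering coefficient C, topological
coefficient T (shared-neighbor convention), normalized betweenness, and
Maximal Clique Centrality

MCC(v) = Σ_{C ∈ S(v)} (|C| − 1)!

where S(v) is the set of maximal cliques containing v (Bron–Kerbosch
enumeration with pivoting). Hubs are nodes with MCC ≥ 4 (or a top-N cut).
`powerlaw_decay_check()` quantifies the decay of C or T with degree that
characterizes scale-free interactomes.

**Binding modes and hotspots.** Representative nucleosome complexes are
selected per partner (subnucleosomal structures, complexes with > 20
octamer-detached base pairs and sub-10-residue peptides removed; redundant
structures collapsed at interface Jaccard ≥ 0.8, keeping the
highest-resolution mutation-free member). Partners are labeled `dna_only`,
`histone_only` or `both`; hotspots are profiled per histone consensus
position (via a multiple sequence alignment) and per DNA base pair relative
to the dyad, counting unique partner proteins and mean heavy-atom contacts.

**Mutations.** MAF-like tables are curated into a *combined* set (drop
targeted sequencing and somatic-unmatched records, keep missense) and a
*refined* set (drop samples with tumor mutation burden > 10 mutations/Mb,
drop dbSNP-known variants, keep mutations recurring in ≥ 3 samples), mapped
onto residue-level interfaces, profiled for physicochemical change, and
scored with a pluggable ΔΔG predictor (positive = destabilizing). Mutations
with per-class mean ΔΔG ≥ 1.0 kcal/mol (HDI) or ≥ 1.5 kcal/mol (HHI, HPI)
and recurrence ≥ 3 are called disruptive. A deterministic, clearly labeled
non-physical surrogate predictor ships for testing; external predictors plug
in via a one-function contract.

**Synthetic data.** Seeded generators plant ground truth for every stage:
toy nucleosome complexes with contacts at controlled distances, mutation
tables with planted filter classes and truth sidecars, evidence edge lists
with controlled overlap, and preferential-attachment graphs.

## Worked example

```r
library(histonet)
run_dir <- tempfile("histonet_demo_")

# 1. simulate a nucleosome complex with one planted partner
spec <- toy_complex_spec(seed = 42)
spec <- spec_add_partner(spec, "Chromatin remodeler", length = 20,
  contacts = data.frame(target_chain = c("A", "C", "I"),
                        target_resid  = c(10, 5, 30),
                        contact       = TRUE))
toy <- generate_toy_complex(spec, dir = run_dir)

# 2. parse, classify chains, extract classified interfaces at 5 A
st  <- apply_residue_mapping(parse_structure(toy$pdb_path), "identity")
ann <- classify_chains(st)
ifc <- extract_interfaces(st, ann)
ifc$edges[, c("class", "chain_a", "resid_a", "chain_b", "resid_b",
              "min_dist", "mol_b")]
#>   class chain_a resid_a chain_b resid_b min_dist               mol_b
#> 1   HPI       A      10       P      20    4.879 chromatin_remodeler
#> 2   HPI       C       5       P      19    4.605 chromatin_remodeler
#> 3   DPI       P      18       I      30    4.731                 DNA

# 3. residue-level network, collapsed to protein level
net  <- build_residue_network(ifc$edges)
prot <- collapse_granularity(net, "protein")
prot
#> hinet [protein/structural]: 4 nodes, 3 edges
prot$edges[, c("node_a", "node_b", "interaction_class")]
#>                node_a             node_b interaction_class
#> 1 chromatin_remodeler       histone_h3.1               HPI
#> 2 chromatin_remodeler histone_h2a_type_1               HPI
#> 3 chromatin_remodeler                DNA               DPI

# 4. binding mode of the partner
classify_binding_mode(ifc$edges)
#>   structure_id          partner_id mode
#> 1  toy_complex chromatin_remodeler both
```

The partner was planted within contact range of histone H3 (chain A, residue
10), histone H2A (chain C, residue 5) and nucleosomal DNA (chain I,
nucleotide 30). The extractor recovers exactly those residue pairs with their
minimum heavy-atom distances; the network collapse reduces the three residue
edges to protein-level HPI/DPI edges; and because the partner touches both
histones and DNA it is labeled with the multivalent `both` binding mode.

A command-line front end over the same functions is installed at
`inst/cli/histonet` (subcommands `simulate`, `extract`, `build-network`,
`topology`, `binding-modes`, `mutations`, `report`).

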