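---
title: "Water networks and conserved hydration sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water networks and conserved hydration sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydronet)
```

This vignette explains what `hydronet` computes, which knobs matter,
and where the design was genuinely open — so that results can be
interpreted and, where needed, the defaults overridden deliberately.

## The model

A *water network* is a graph. Nodes are water oxygen atoms (all of
them, bonded or not) plus any protein heavy atoms that participate in a
hydrogen bond; edges are hydrogen bonds. Two criteria define an edge:

* **Distance**: donor–acceptor heavy-atom distance ≤ `distance_cutoff`
  (default **3.8 Å**). This is deliberately a little looser than
  textbook H-bond geometry so that lower-resolution structures, whose
  water positions carry more uncertainty, still yield usable networks.
  The comparison is a closed inequality: a pair at exactly the cutoff
  is accepted.
* **Angle** (only when hydrogen positions exist, e.g. simulation frames
  or neutron structures): at least one D–H···A angle ≥ `angle_cutoff`
  (default **150°**), measured at the hydrogen. When both partners
  carry hydrogens, the bond is accepted if *either* direction passes,
  and the edge is oriented from the passing donor; if both pass, the
  atom with the lower serial is the donor (a deterministic tie-break).
  If neither partner has a resolvable hydrogen — common for protein
  partners in X-ray structures — the pair is judged on distance alone
  rather than silently discarded.

Candidate pairs come from a kd-tree search: for each water oxygen, its
`neighbor_k` (default **10**) nearest members of the candidate pool.
The pool contains water oxygens and protein nitrogen/oxygen heavy atoms
plus the sulfur of Cys/Met; carbon never hydrogen-bonds. Ten neighbours
comfortably exceed the coordination of water in condensed phases, so
whenever the true partner count within the cutoff is below `neighbor_k`
the result provably equals exhaustive all-pairs testing — the test
suite asserts exactly that equality on randomized fixtures.
Protein–protein pairs are never tested: these networks are
water-centric by definition.

Backbone vs side-chain classification is by atom name: `N`, `O` and
`OXT` are backbone; everything else is side-chain.

An optional *active region* restricts the network to a sphere (default
radius 9 Å) around selected atoms or their centre of mass, with a
closed boundary (distance ≤ radius). Waters inside the sphere seed the
network, and partners slightly outside are retained when they bond an
in-region water (a "halo"), so bonds are not artificially severed at
the boundary. Selections are ordinary R expressions over the atom-table
columns (`"name == 'CA' & resno %in% 5:10"`), which keeps the selection
language exactly as expressive as `dplyr::filter()`.

## Graph metrics

For each network the package reports:

* **density** — `2E / N(N−1)` (directed networks use `E / N(N−1)`);
  0 by convention for fewer than two nodes;
* **degree entropy** — Shannon entropy of the empirical node-degree
  distribution, in nats. Any regular graph scores 0; heterogeneous
  degree mixes score higher. Natural log is an arbitrary but fixed
  base choice: another base only rescales the number.
* **characteristic path length** — mean shortest-path edge count over
  distinct vertex pairs, per connected component. `cpl_mean` averages
  per-component values *unweighted* over components with ≥ 2 nodes
  (singletons have no pairs and are excluded, though they still count
  in `n_components`); `cpl_largest` is the value for the component with
  the most nodes, ties broken by edge count and then first occurrence.
  When no component has two nodes the value is `NA`, not 0.
* **clustering coefficients** — the triangle-based local coefficient
  per node, 0 for degree < 2;
* **interaction counts** — water–water and water–protein edges.

Directed networks are projected to undirected graphs for everything
except density. Graph plumbing is delegated to `igraph`; the test suite
verifies every metric against an independent all-pairs BFS / direct
formula implementation on hundreds of random graphs (≤ 30 nodes), to
1e-9.

## Conserved water positions

Comparing waters across structures requires a common frame twice over:

1. **Sequence**: a progressive multiple sequence alignment (pairwise
   and profile–profile Needleman–Wunsch, BLOSUM62, affine gap
   penalties 10/0.5, UPGMA guide tree from pairwise identities) assigns
   every residue a common column index. Gap runs longer than `max_gap`
   (default 20) are disallowed inside the dynamic programme by capping
   the gap-run length carried through the extension state; the cap is
   applied greedily per cell, which is deterministic and exact for the
   short, high-identity sequences this tool is used on. An existing MSA
   in PIR or aligned-FASTA format can be imported instead, and is
   reconciled residue-by-residue against the structures (the first
   discrepant residue is named in the error).
2. **Space**: Kabsch least-squares superposition on the Cα atoms of
   residues sharing an alignment column, onto a reference structure
   (first lexicographically unless configured). Cα-only fitting is a
   choice: it is insensitive to side-chain disorder and needs no atom
   -name reconciliation beyond Cα. Fewer than three shared pairs is an
   error — the rotation would be underdetermined.

Water oxygens pooled over the superposed structures are clustered with
a density-based algorithm:

* **DBSCAN** (default): `eps` 1.0 Å, `min_samples` 5. The 1 Å radius
  matches the match tolerance used by the conservation scores, and 5
  points is a reasonable minimum recurrence for a "site" in sets of
  5–20 structures. Both parameters should scale with the data: for a
  long trajectory of a single protein, raise `min_samples`.
* **OPTICS**: reachability ordering with DBSCAN-equivalent cluster
  extraction at `eps`. The ξ-style hierarchical extraction is not
  implemented; for hydration sites the eps-cut is what the default
  workflow needs, and on well-separated sites the two algorithms agree
  (tested).
* **HDBSCAN**: mutual-reachability single-linkage tree, condensed with
  `min_cluster_size` (default 5), clusters selected by stability
  (excess of mass). When the tree never splits, the root is returned as
  a single cluster rather than calling everything noise.

Noise points are excluded from centroids. Cluster labels are numbered
by first member index, so labelling is deterministic and independent of
any internal ordering. Each centroid is the arithmetic mean of its
member coordinates — the tests verify this against a brute-force mean.

The *summary network* consists of those centroids, connected when
closer than the H-bond `distance_cutoff` (the same rule as ordinary
networks — the natural choice, since summary waters stand in for real
ones). Three conservation quantities follow:

* **per-cluster conservation** — the fraction of source structures (or
  frames) with ≥ 1 water within `match_distance` (default 1 Å) of the
  centroid. Structures that resolved *no* waters still count in the
  denominator.
* **pairwise conservation** — for centroid pairs closer than
  `pair_distance` (default 2 Å), the fraction of sources with waters
  within `match_distance` of *both*.
* **per-structure conservation score** — `(1/N_s) Σ_i a_i / (1 + w_i)`
  with `a_i` the match indicator and `w_i` the number of *additional*
  structure waters inside `local_sphere` (default 6 Å) of summary water
  *i*, the matched water itself excluded (hence the `1 +`). The score
  is 1 exactly when every summary water is matched with an empty local
  sphere; waters farther than `local_sphere` from every summary water
  can never move it. Matching is independent per summary water — one
  structure water may match two nearby summary waters. A bipartite
  (one-to-one) assignment would be the alternative reading; the
  independent rule is simpler, monotone, and the difference only
  appears when summary waters sit within `match_distance` of each
  other, which the clustering discourages by construction.

## Interaction scores and the two-angle map

Per residue (keyed by common alignment column when an alignment is
supplied, by chain/number otherwise): the score is total water–protein
contacts divided by the number of networks, alongside the mean number
of simultaneously bound waters over the networks where the residue
binds at all. The two summaries are deliberately reported together —
"one water always" and "two waters half the time" both score 1.0 but
have mean simultaneity 1.0 vs 2.0. Backbone and side-chain sub-scores
sum exactly to the total. Residues that never bind are absent from the
table (their mean simultaneity is undefined).

Each water–protein contact also gets two angles, measured at the water
oxygen, between the vector to the protein atom and the vectors to two
fixed reference points (defaults (0, 10, 0) and (10, 0, 10) Å in the
common frame; any fixed coordinate such as a conserved Cα works and
co-rotates under superposition). Two angles to two non-collinear
references pin a direction in 3-space up to a reflection, which in
practice separates distinct water positions around a residue on a 2-D
plot. Coincident points (water on top of a reference or of the protein
atom) are a geometry error, not a silent `NaN`.

Occupancy grids (`density_hotspots`, default spacing 0.5 Å) bin pooled
water positions on an axis-aligned grid covering their bounding box;
counts are exact (the tests check total conservation) and export to
OpenDX for visualisation.

## Input handling

PDB reading is delegated to bio3d. First MODEL only for static
structures; trajectory frames come from a multi-model PDB or a
DCD + topology pair, strided, with coordinates copied per frame.
Alternate locations keep the highest-occupancy conformer (first wins
ties) — clustering needs a single position per water, and occupancy is
the least arbitrary selector. Water residues are recognised by name
(`HOH`, `WAT`, `TIP3`, `SPC`, `T3P`, `SOL`; configurable). Residue
identity is the triple (chain, number, insertion code); renumbering
across structures is handled by the alignment, not by the parser.
Hydrogens are never added: protonation is an input property.

## The fixture generator

`fixture_spec()` builds what the validation needs and no more: a short
chain of serine-like pseudo-residues (backbone N/CA/C/O, side-chain
CB/OG) on a gentle helix — enough geometry for Cα superposition and
backbone/side-chain classification — decorated with waters at planted
sites under per-site presence probabilities, Gaussian jitter (default
σ 0.2 Å, a tight crystallographic-water spread), optional rigid-body
displacement per structure, and optional hydrogens placed at 0.96 Å
with a solvable planted D–H···A angle. All randomness flows from one
seed through a counter-based scheme (structure *i*'s draws depend only
on the seed and *i*), so fixtures are reproducible and
order-independent.

What the fixtures deliberately do **not** emulate: physically realistic
water dynamics, force-field energetics, crystallographic noise models,
partial occupancy, or the size of real proteins. Passing tests
therefore demonstrate algorithmic correctness — recovery of planted
geometry, equality with brute-force references, invariances — not that
any particular biological system will show conserved waters.

## Numerical and scale choices

Test problem sizes are chosen to make the checked properties exhaustive
rather than impressive: random structures up to ~200 atoms for H-bond
oracle equality (100 replicates), random graphs up to 30 nodes for
metric equality (200 replicates), 20 structures for planted-site
recovery. These sizes already cover every branch of the algorithms;
the implementations themselves scale to realistic inputs (kd-tree
candidate search, vectorised distance work).

Other fixed conventions: angles are clamped into [−1, 1] before
`acos`; rigid-motion invariance holds to 1e-6 (tested with a random
rotation and translation applied to all structures and references);
identical inputs give identical graphs and byte-identical CSV output
(the run log records all effective parameters but no timestamps).

## Limitations

* π-interactions, halogen bonds and salt bridges are out of scope; the
  graph export lets downstream tools add them.
* No thermodynamic hydration-site analysis (site enthalpy/entropy) and
  no residence-time kinetics: the unit of observation is a structure or
  a frame, never a time-correlated trajectory segment.
* Sequence-guided superposition assumes the family is alignable; for
  very divergent folds an externally computed structural alignment
  should be imported instead.
* The progressive MSA is designed for small sets of closely related
  sequences. It is not a general-purpose aligner.
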