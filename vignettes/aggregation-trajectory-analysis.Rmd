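---
title: "Methods: cluster, structure and order analysis of aggregating peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster, structure and order analysis of aggregating peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggtraj)
```

`aggtraj` quantifies the early, pre-fibrillar stage of peptide
aggregation from all-atom trajectory data. The motivating system is the
pair of N-terminal β-lactoglobulin peptides (residues 1–33 and 1–52 of
the mature chain) that assemble into amyloid fibrils at pH 2 and low
ionic strength: twenty copies in a periodic cubic box of 15–16.5 nm
aggregate spontaneously into clusters that progressively acquire
β-structure, inter-chain hydrogen bonds and orientational order. Each
analysis stage below is an independent function; `run_pipeline()` chains
them, and the numbered scripts under `analysis/` present the full study.

## Cluster identification

Two chains are in contact when *any* inter-chain atom pair is closer
than a cutoff (default **4 Å**, hydrogens included; a heavy-atom-only
mode exists) under the minimum-image convention in an orthorhombic box.
Triclinic boxes are rejected: the target systems are cubic, and
supporting general cells would complicate every distance kernel for no
benefit here. Exact half-box distances are mapped to the `[-L/2, L/2)`
convention so ties resolve deterministically.

Per-frame clusters come from the head-and-list algorithm: all chains
start as single-member clusters; iterating over contacting pairs
`i < j`, two chains in different clusters have their linked lists
spliced (HEAD of the absorbed cluster zeroed, LIST of the tail
redirected, CLUSTER ids and SIZE updated). The partition this yields is
exactly the connected components of the contact graph — the test suite
asserts equality with an independently written union-find and with
`igraph::components()` on hundreds of random graphs, which *is* the
correctness criterion for a single-linkage method.

A bounding-sphere prefilter skips chain pairs whose centroids are too
far apart to matter; the resulting edge set is bit-identical to the
exhaustive double loop (also asserted in tests).

## Cluster statistics and transition networks

The largest and second-largest cluster sizes are reported per frame,
with ties between equal-sized clusters broken by the lowest contained
chain index so that "the largest cluster" is a deterministic object for
downstream per-cluster metrics. A trailing running average smooths the
series; the default window is **10 frames = 1 ns** at the customary
100 ps snapshot spacing. (A 100-frame window would average over 10 ns;
the 1 ns reading is the internally consistent one and the window is a
plain argument.)

Cluster tracking between frames is deliberately simple: for consecutive
frames, every (predecessor, successor) cluster pair sharing at least one
chain generates one `size → size` event. Pairs with identical membership
(nothing happened) are excluded; merges and splits between equal-sized
clusters do count, and a same-size membership exchange is an event. This
rule is symmetric for merges and splits and requires no kinetic model.
Node weights are the summed counts of incident edges (self-loops counted
once), and `top_k_edges()` keeps the 40 most frequent transitions with a
lexicographic tie-break.

## Secondary structure

The assigner is a Kabsch–Sander (DSSP-style) backend, chosen because it
is fully specified by one energy formula and reproducible from
coordinates alone; the statistics built on it (content percentages,
β fractions, propensities) are backend-agnostic, and the assigner is a
single function that can be swapped for an external one in
cross-checks. A backbone N–H···O=C hydrogen bond exists when

E = 27.888 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) < −0.5 kcal/mol,

with distances measured under the minimum image (wrapped frames assign
identically to whole ones — a tested invariant) and a standard 9 Å
Cα–Cα prefilter. Missing amide hydrogens are reconstructed 1.01 Å from
N along the O(i−1)→C(i−1) direction (trans-amide); prolines and chain
starts get none, and pre-existing hydrogens are never overwritten.

The 3-state mapping: two consecutive 4-turns (`HB(i+4 → i)`) label
residues `i..i+3` **H**; parallel or antiparallel bridges — with
partners on any chain, and `|i − j| ≥ 3` within a chain — label both
partners **E**; everything else is **C**, and chains shorter than three
residues are C outright. E overrides H because β content is the
statistic of record for aggregation. Isolated bridges count as E: the
inter-chain sheets of interest begin as single bridges, and excluding
them would censor exactly the onset events. 3₁₀/π helices fold into H.

Per-residue β propensity divides strand events by frames × chains
(e.g. 9000 snapshots × 20 peptides for a 900 ns production run saved
every 100 ps — see `snapshot_accounting()`), which requires all chains
to share one sequence and is enforced.

## Hydrogen bonds and SASA

Geometric hydrogen-bond criteria: hydrogens are first assigned to their
covalent donor (nearest N or O on the same chain within **1.2 Å** — this
cutoff's only chemically sensible role; ties go to the lower atom
index), then a bond requires an N/O acceptor within **3.0 Å** of the
donor and a donor–hydrogen–acceptor angle (vertex at H) of at least
**150°** — the strict-linearity reading of an "angle cutoff". Donors and
acceptors are restricted to N and O, which covers the backbone and all
side chains of the study sequences; sulfur can be added by argument.
Intermolecular means donor and acceptor chains differ; totals always
decompose as inter + intra.

SASA uses the Shrake–Rupley construction: each atom's sphere of radius
r + 1.4 Å is sampled with a deterministic golden-section spiral of 960
points, and the exposed fraction scales the exact sphere area. The
quadrature is exact for an isolated atom, which the tests exploit
(4π(r+p)² to 0.5%). Radii default to the Bondi set (H 1.20, C 1.70,
N 1.55, O 1.52, S 1.80 Å); probe, point count and radii are arguments,
since trajectory sources differ in conventions. Coordinates are
unwrapped per contact-connected cluster before the calculation (periodic
occlusion across images is not modeled), and totals are reported in nm²
with an exact hydrophobic / non-hydrophobic partition. The
classification (hydrophobic A,V,L,I,P,F,M,W; neutral G,S,T,C,Y,N,Q;
hydrophilic D,E,K,R,H) is a reconstruction of the usual three-way
scheme for these peptides and is replaceable; composition-sensitive
percentages should be read with that in mind.

## Orderliness

The molecular direction of a chain is the principal eigenvector of its
Cα gyration tensor, not the end-to-end vector: these peptides are
folded, and end-to-end vectors of folded chains degenerate toward noise
(an `end_to_end` mode exists for sensitivity checks). The nematic order
parameter P2 is the largest eigenvalue of Q = ⟨(3uuᵀ − I)/2⟩ — the
liquid-crystal convention, bounded in [−0.5, 1], invariant under
per-vector sign flips and global rotations (both tested). Perfectly
aligned bundles give exactly 1; fibrils typically exceed 0.8, while
early aggregates live around 0.15–0.65.

The (inter-chain H-bonds, P2) histogram of the largest cluster is
normalized to probability mass; basin cells are local maxima over the
8-neighborhood, with plateau cells all reported (degenerate histograms
collapse to a single bin and are flagged by construction rather than
erroring). "Hydrogen bonds per contact" divides intermolecular bonds
within a cluster by its contact-graph edge count — the chain-pair
reading of "per contact"; a per-atomic-contact reading would need an
atom-contact census the rest of the pipeline never uses.

## Protonation

Formal charges come from a hard threshold — a site is protonated iff
pH < pKa — over a standard table (ASP 3.65, GLU 4.25, HIS 6.0, CYS 8.3,
TYR 10.5, LYS 10.5, ARG 12.5, N-terminus 8.0, C-terminus 3.6). MD
topologies need integer charges, so fractional Henderson–Hasselbalch
occupancies are intentionally not offered; structure-based pKa shifts
are out of scope, and the table is overridable. At pH 2 the packaged
1–33 sequence (two lysines) gets +3 and the 1–52 extension (one more
lysine, one arginine) +5. Net charge is a non-increasing step function
of pH with steps only at table values — a tested property.

The packaged sequences use the mature-chain numbering beginning LEU1;
published residue labels for this system are self-consistent with that
start except for one figure label naming position 1 a glycine, which we
record rather than resolve.

## Synthetic data: what it emulates, what it does not

Every stage is validated against generated inputs with known ground
truth:

- `build_backbone()` builds chains from internal coordinates (N–Cα
  1.458, Cα–C 1.525, C–N 1.329, C–O 1.231 Å, trans ω). φ/ψ = (−57, −47)
  yields a helix with the expected ≈1.5 Å/residue rise; (−139, 135) an
  extended strand.
- `make_sheet()` places ideal strands side by side (target spacing
  4.8 Å) and chooses the register — axial shift, face flip, fine spacing,
  and the sheet-plane orientation of the template strand — by a
  deterministic grid search maximizing inter-strand Kabsch–Sander bonds.
  Parallel sheets use the standard (−119, 113) strand torsions;
  antiparallel strands alternate direction.
- `scripted_aggregation_trajectory()` realizes a prescribed per-frame
  partition geometrically: chains are rigid copies of a template
  (default: the first 8 residues of the 1–33 peptide as a helix) on a
  compact lattice path with ≈3.5 Å nearest-neighbor contacts — safely
  inside the 4 Å criterion, with a small seeded jitter — while cluster
  bounding spheres are packed greedily with >12 Å mutual separation,
  then everything is wrapped into the box. Default conditions are the
  study system: 20 chains, 150 Å cubic box (9.84 mmol/L by n/N_A·V).
  A box too small to separate the scripted clusters is an error, not a
  silent overlap.
- `rod_bundle(n, f, seed)` mixes an aligned fraction f with uniformly
  random directions; measured P2 recovers f (tested at N = 500 over 20
  seeds, within three standard errors).

All generators are seed-deterministic. Deliberate non-goals: the chains
have no internal dynamics (cluster analytics depend only on inter-chain
geometry), no force field acts, and the *stochastic outcomes* of the
real trajectories — which sizes dominate, how much β forms, where P2
settles — are not reproduced, only the machinery that measures them.
Two consequences worth knowing: rigid aligned copies make scripted
clusters trivially ordered (P2 = 1), and the ideal helix template's
N···O distances (≈3.1 Å) sit just above the strict 3.0 Å geometric
donor–acceptor gate, so scripted demos report zero geometric hydrogen
bonds; constructed bonding geometries cover that machinery in the
tests. Passing on synthetic data therefore demonstrates correctness of
the measurements, not realism of the dynamics.

## Numerical choices and problem sizes

Distances are computed in double precision in Å; SASA is converted to
nm² only at the reporting boundary. Eigen-decompositions use base R's
symmetric solver; exact eigenvalue ties in degenerate chains resolve to
the lowest-index axis. The test suite and the demo analyses run on
deliberately small systems — 8-residue template chains, 8–12 frames,
480–960 SASA points — because every assertion is scale-free (exact
partitions, closed forms, conservation laws, oracle equality); larger
systems change runtimes, not the properties being asserted. The
pipeline streams frame by frame and keeps only accumulators, so a
9000-frame production analysis fits comfortably in memory.

## Known limitations

- Orthorhombic boxes only; no trajectory alignment or superposition.
- The pKa rule ignores structural context by design.
- The Kabsch–Sander backend is not STRIDE: absolute helix/strand
  percentages can differ between backends, though the trends and
  fractions built on them are comparable.
- Binary trajectory formats (XTC/DCD) need an external reader feeding
  `aggtraj_trajectory()`.
- The hydrophobicity classification is a documented reconstruction;
  atom-fraction percentages quoted for all-atom topologies will differ
  from backbone-only synthetic systems.
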