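---
title: "Curating antibody-antigen docking benchmarks with abagbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating antibody-antigen docking benchmarks with abagbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abagbench)
```

## The curation problem

A docking benchmark case is a bound antibody–antigen complex together with
experimentally solved unbound structures of its components. Benchmarks of
this kind drive the development of docking and complex-prediction methods,
but they decay: new structures appear continuously, near-duplicate
complexes bias evaluations, and the difficulty mix (how much the partners
deform on binding) determines what a benchmark can actually test.
`abagbench` packages the whole curation procedure: screening
sequence-search hits for unbound partners, preparing coordinate files,
measuring binding-induced conformational change, grading difficulty,
removing redundancy with a graph algorithm, and updating a stored
benchmark incrementally.

This vignette explains the models and conventions behind each stage, the
parameters that matter, and what the synthetic fixtures do and do not
demonstrate.

## Structure model and file handling

Benchmark structure files keep only ATOM coordinate records: heteroatoms,
waters and anisotropic records are dropped at parse time, and only the
first model of a multi-model (NMR) entry is read. Hydrogens are kept in
the atom table but flagged, and every distance-based quantity in the
package ignores them, so deposited structures with and without hydrogens
give identical interfaces.

Conventions the parser commits to, where deposited files are ambiguous:

* **Alternate locations** collapse to the highest-occupancy conformer;
  ties go to the alphabetically first altloc id. A `"first"` policy is
  available for reproducing tools that take the first record.
* **Residue identity** is the triple (chain id, author residue number,
  insertion code), preserved verbatim; the package never renumbers.
* **Nonstandard residues** inside ATOM records (selenomethionine and
  similar) keep their coordinates and map to their standard parent for
  sequence derivation, so alignments see `MSE` as `M`.

Unbound chains are often longer than the bound chain they pair with.
`truncate_unbound()` aligns the two sequences with an end-gap-free global
alignment (Biostrings, BLOSUM62, gap opening 10, extension 0.5) and keeps
only unbound residues in match/mismatch columns — the unbound copy is
trimmed to the bound span, never reordered and never lengthened. The same
alignment machinery produces the residue maps behind every RMSD.

## Unbound-structure screening

A hit from a sequence search of a bound chain against the sequence
database identifies a usable unbound structure when identity exceeds 0.93,
coverage exceeds 0.80 and the E-value is below `1e-5`; all three
inequalities are strict, so boundary values fail. BLAST tabular input
carries identity but not coverage; coverage is computed as the aligned
query span over the bound chain length, which the caller supplies. Cases
are then classed UU/UB/BU/BB by which sides have at least one accepted
candidate; a side with several bound chains (heavy + light) needs every
chain covered independently. Whether the heavy- and light-chain unbound
structures must come from one crystal entry is left to the caller — the
screen treats chains independently, which is the permissive reading.

## Conformational-change metrics

**Interface and contacts.** Interface residues have any non-hydrogen atom
within 10 Å of the partner; contacts are residue pairs within 5 Å. Both
are computed by exact all-pairs distance evaluation in memory-bounded
blocks — a deliberate choice over approximate spatial indexing, so the
computed sets equal a brute-force quadratic scan exactly (the test suite
asserts this identity on randomized fixtures).

**I-RMSD.** The Cα RMSD over interface residues after a least-squares
(Kabsch, SVD-based, reflection-corrected) superposition of the unbound
interface Cα set onto the bound one. Each side has its own value; the
*entire-interface* value used for difficulty grading fits each component
on its own interface set and pools the squared deviations of both sides
into one RMSD. The fitting set behind a published "entire interface"
value is genuinely underdetermined; per-component fitting with pooling is
this package's declared convention, chosen because it never rewards one
side's deformation with the other side's fit.

**f_non-nat.** Each unbound component is placed into the bound frame by
its interface fit; contacts of the superposed pair are recomputed at 5 Å
in bound numbering, and the reported value is the fraction of those model
contacts absent from the native map. The denominator is the model contact
count. A superposed pair with no contacts at all returns 1, flagged with
an attribute, so a completely dissociated interface is maximally
non-native rather than undefined. Superposed-unbound residues with no
bound counterpart keep their own identity and therefore always count as
non-native.

**ΔASA.** Buried surface area is the components' isolated
solvent-accessible areas minus the complex area, all in the bound
conformation, from a Shrake–Rupley calculation: deterministic
golden-spiral point lattices (960 points per atom by default, probe
1.4 Å) on element-radius spheres (C 1.70, N 1.55, O 1.52, S 1.80 Å, …).
This is a numerical SASA with element-level radii; implementations
differing in radii or point sets will disagree by a few percent, which is
why no classification threshold consumes ΔASA. A single isolated atom
recovers the analytic sphere area exactly, and doubling the point density
moves a protein-sized total by well under 1%.

**CDR RMSD.** CDR boundaries arrive as an annotation table (Chothia
numbering produced by any external numbering tool, or by the fixture
generator); the package does not infer numbering from sequence. The
unbound antibody is fitted on framework (non-CDR) Cα atoms only, and each
loop's Cα RMSD is reported without refitting, so the value isolates loop
motion relative to a fixed framework. Loops missing from the unbound
chain are reported `NA` individually. The standard heavy/light framework
blocks masked during antibody-mode docking (heavy 6–22, 39–46, 81–91,
106–end; light 7–20, 38–44, 76–85, 101–end, Chothia numbering) are
exposed as data for masking workflows.

## Difficulty classification

Rigid: I-RMSD < 1.5 Å and f_non-nat < 0.40. Difficult: I-RMSD > 2.2 Å.
Medium: everything else. The inequalities are strict and the regions
partition the quarter-plane, which the tests verify on a dense grid
including the boundary values. Composition tables report two-decimal
percentages under round-half-up — the convention that reproduces printed
benchmark tables; note that half-to-even rounding does not. When a case
has several unbound structures, the first listed pair is the designated
primary and drives classification; alternates are reported alongside.

## Redundancy removal

Two complexes are redundant when (a) every chain type of one matches the
corresponding chain type of the other at identity > 0.60 and
E-value < 1e-30, chain types corresponding by role (heavy, light,
antigen), and (b) the whole-complex Cα RMSD after a single least-squares
superposition over all mapped chains is below 5 Å. Sequence identity
alone is deliberately insufficient: complexes with identical sequences
can bind in different orientations and then both belong in the benchmark.
The RMSD atom selection is Cα — a declared convention, since backbone or
all-atom selections change the value by little but are not interchangeable.

Redundant pairs are edges of an undirected graph over case ids (igraph
container; isolated nodes are preserved). Pruning repeatedly deletes one
node of maximum degree until all degrees are zero. The retained set is an
independent set of the original graph — by construction, not a maximum
one; the greedy heuristic is the method. Ties at the maximum degree break
lexicographically by default so runs are reproducible; a seeded random
tie-break reproduces the randomized variant. Tests compare the pruner
against an independent adjacency-matrix re-implementation on every
labelled graph with up to 5 nodes (1,098 graphs) and seeded samples of 6-
and 7-node graphs — a scale chosen to keep the exhaustive check
affordable while covering every small topology; the greedy loop has no
size-dependent branches, so small-graph exhaustion exercises every code
path.

Updating a stored benchmark compares each incoming case against all
stored cases and other incoming ones under the same criteria. A case
similar to nothing founds a new non-redundant group and is added; cases
similar to something form components that are re-pruned in isolation, so
untouched stored cases are never reconsidered. A failed structure
comparison marks the case unresolved and keeps it out rather than
admitting it silently. On fixtures, incremental updating and rebuilding
from scratch agree up to tie-breaking.

## Synthetic fixtures: what they emulate

`generate_toy_case()` builds helix-like chains (N/CA/C/O/CB atoms, 3.8 Å
Cα spacing) with a fixed, varied, deterministic sequence per chain —
varied because degenerate homopolymer sequences make alignments ambiguous
— and places antibody against antigen at a controlled closest approach
(default 4.5 Å, giving a realistic band of 5 Å contacts inside a broader
10 Å interface). Unbound copies are the bound components under a chosen
perturbation plus an arbitrary rigid motion, which every metric must be
invariant to.

The `rigid_shift` perturbation deserves its note: a literal rigid shift of
a whole unbound component would be absorbed entirely by the interface
superposition and read as zero change. The generator instead displaces
each interface residue by `t_i * u` with the amplitude vector `t` drawn
from the null space of the fit conditions (`sum(t) = 0` and zero
cross-covariance with the centered interface coordinates) and scaled to
RMS magnitude `d`. Under these constraints the optimal superposition is
exactly the identity and the post-fit interface RMSD equals `d` — the
requested conformational change is recovered analytically, not
approximately. With `perturb_side = "both"` the entire-interface value
also equals `d`, which is how fixtures are steered across the 1.5/2.2 Å
difficulty thresholds. `hinge_rotation` and `cdr_displacement` move a
chain segment or the CDR3 loop; a uniform CDR3 translation of `d` yields
a CDR3 RMSD of exactly `d` because the framework fit is unaffected.

`generate_redundant_family()` controls pairwise identity exactly by
mutating disjoint, scattered residue sets (`identity(i,j) = 1 - k_i/n -
k_j/n`) and controls structural divergence with large per-copy hinge
rotations, reproducing both halves of the redundancy criterion, including
the identical-sequence/different-structure case that sequence screening
alone would wrongly merge.

What the fixtures do **not** emulate: real side chains and packing,
loops, waters, crystallographic artifacts, genuinely independent unbound
crystal forms, or realistic E-values (the local comparator substitutes a
vanishing E-value for chain-length alignments and a non-significant one
for fragments). Passing tests therefore demonstrate correctness of the
definitions, conventions and algorithms — not agreement with any
particular deposited complex.

## Numerical choices and problem sizes

* Distance cutoffs are compared with `<=`; the same rule is used by the
  brute-force oracles, so agreement is exact, not tolerance-based.
* Kabsch superposition rejects fewer than 3 points and collinear sets
  (second singular value below 1e-8); rigid-motion removal is verified to
  1e-6 Å.
* Default SASA point count 960 balances a sub-percent discretization
  error against runtime; per-atom areas are exact for isolated atoms.
* Percentages are rounded half-up to two decimals at the reporting
  boundary only; internal arithmetic is double precision.
* Test problem sizes: fixtures of 40–110 residues per chain (≤ 850
  atoms), 100 randomized fixtures for the oracle scans, 10 seeds per
  displacement magnitude for parameter recovery, exhaustive graph
  enumeration to 5 nodes with 1,500-graph samples at 6 and 7. These sizes
  were chosen so the full suite runs in a few minutes while every
  definition is still exercised against an independent oracle.

## Known limitations

* mmCIF input, assembly generation and multi-model NMR handling beyond
  the first model are out of scope; inputs are PDB-format ATOM records.
* The package consumes sequence-search output; it does not run BLAST, and
  E-values in locally computed comparisons are surrogates, suitable for
  fixtures and for screening tables that already carry real E-values.
* ΔASA uses element-level radii; tools with atom-type radii (NACCESS
  lineage) will differ by a few percent systematically.
* The greedy pruner makes no optimality claim; it implements the
  described heuristic, and its output depends on the tie-break rule in
  ways the removal log makes auditable.
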