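---
title: "Binding-site vectors: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site vectors: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitevec)
```

## The descriptor

A binding pocket is encoded by casting rays from a fixed interior
anchor along the vertices of a geodesic sphere. Each ray stops at the
first hard-sphere (van der Waals) atomic surface it meets and records
two numbers: the length at which it stopped and the partial charge of
the atom it stopped on. Because the ray directions are fixed and
indexed, two conformations sharing a reference frame can be compared
index-by-index — the comparison is a per-ray difference, not a surface
registration problem. Rays that traverse the whole casting sphere
without meeting an atom keep the full maximum length (20 Å by default)
and charge zero; they are retained in all sums, so an open channel
contributes systematically long vectors rather than missing data.

The descriptor assumes (i) a meaningful, conserved anchor exists (for
cytochrome P450s, the heme iron), (ii) structures can be rigidly
aligned into a common frame, and (iii) a hard-sphere surface is an
adequate pocket boundary. It deliberately ignores solvent-accessible
surface area, probe rolling and protonation equilibria.

## Geometry of the ray fan

The direction set is a class-I geodesic subdivision: every edge of a
regular icosahedron is split into `f` segments, faces are triangulated,
and vertices are projected radially onto the unit sphere, giving
`10 f² + 2` distinct directions (492 at the default `f = 7`; recursive
bisection could only produce 12, 42, 162, 642, … and can never reach
492). Duplicate vertices generated on shared edges are removed by
rounding coordinates to 1e-8 before hashing; directions are then sorted
by decreasing z and azimuth, which makes the index order a pure
function of `f`.

The icosahedron orientation matters because the hemisphere restriction
counts depend on where lattice vertices fall relative to the equator.
The package fixes the icosahedron in its standard coordinates — the
cyclic permutations of (0, ±1, ±φ), normalised — which places an edge
midpoint on the +z axis. In this orientation the `f = 7` lattice has
exactly 28 vertices on the equator and 232 strictly above it, so the
default inclusion rule, *keep every direction with non-negative dot
product with the plane normal* (the closed upper hemisphere), retains
exactly 260 of 492 directions. We verified that the plausible
alternative orientation — a vertex on each pole — cannot reach 260
under any dot-product threshold (it yields 246 or 281), which is why
the edge-on-z orientation is the package default and not a tunable.
A `strict` rule (drop the equator ring) and an `all` rule are exposed
for users who want an open hemisphere or the full sphere. Restriction
only sets a mask; the full direction list and its indices never change,
so masked descriptors from different structures stay comparable.

## Structures, radii, charges, frames

PDB parsing and writing go through `bio3d`. Van der Waals radii come
from a packaged element table (Bondi-type values; Fe, which Bondi does
not cover, carries a documented conventional 2.0 Å), overridable by a
two-column TSV. Partial charges come from a packaged, intentionally
compact (residue, atom) table in the spirit of united-atom force-field
charge groups — backbone dipoles, charged side-chain termini, heme
iron/pyrrole nitrogens — with a wildcard residue and a zero fallback.
The metric only requires charges to be *consistent* across the compared
structures, not to reproduce any particular force field; users with a
force-field table can load it wholesale in the same format.

The reference frame maps the anchor atom to the origin and the
least-squares plane of the anchor group (the four pyrrole nitrogens
when present, else the heavy atoms of the anchor residue) into the
xy-plane, normal along +z, sign chosen so the structure's centroid — or
a user-supplied "above" selection — sits at positive z. The rotation is
the *minimal* rotation taking the plane normal to +z, which leaves the
in-plane azimuth deterministic without imposing an arbitrary in-plane
reference; applying the frame twice is the identity to 1e-6 Å.
Ensemble frames are aligned to a reference with `superpose()`
(least-squares proper rotation via `bio3d::rot.lsq`, default selection
backbone N/CA/C/O, or any user-supplied stable-residue selection).

## Tracing rules and degenerate cases

For each retained direction the winning atom is the one with the
smallest positive entry distance `b − sqrt(r² − y²)` not exceeding the
maximum length. Three edge rules are deliberate choices:

- atoms whose surface starts at or behind the origin (`entry ≤ 0`) are
  skipped — an atom overlapping the anchor would yield nonphysical
  lengths; groups that surround the anchor (the heme) should instead be
  excluded outright, which `mark_excluded()` does by residue name
  (default HEM/HEC);
- exact ties on the entry distance resolve to the lowest atom index,
  so tracing is deterministic;
- hits beyond the maximum length count as misses (full length, zero
  charge).

Ligand vectors use the same rays but keep the *largest* exit distance
`b + sqrt(r² − y²)` over the ligand atoms — the far side of the ligand
envelope — clamped to the maximum length; rays that miss the ligand get
length 0 and are flagged.

## Metrics

Shape and charge RMSDs are plain per-index root-mean-squares in Å and
e. The combined metric divides length differences by σ_l and charge
differences by σ_q and mixes the two sums with weights
`w_s = 2/(2+d)`, `w_c = 2(1+d)/(2+d)`; the weights average to one for
every `d > −1`, and the domain is restricted to `d > −1` so both stay
positive. `compute_normalizers()` pools *all* vectors of *all*
descriptors in the comparison set and uses the population (divide by n)
standard deviation; the choice of convention is documented because
dataset σ values computed elsewhere may differ in the third decimal,
and both σ are user-settable to reproduce external constants. Pool
means cancel in the difference and are computed for reporting only.

Ensembles are compared by weighting each exemplar pair's RMSD with the
product of the frame fractions the exemplars represent and summing over
all pairs. This is linear in the weights, so splitting an exemplar into
duplicates with split weights provably leaves the value unchanged — a
property the tests exercise.

## Clustering

No affinity-propagation implementation ships with the package's
dependency set, so the Frey–Dueck responsibility/availability updates
are implemented here: damping 0.9, preference defaulting to the median
off-diagonal similarity, at most 1000 iterations with a 50-iteration
stability window, similarities = negated distances, and a seeded
1e-10-scale jitter to break the exact-symmetry degeneracies
(deterministic for a fixed seed; default seed 0). Two conventions are
worth knowing: an input whose off-diagonal distances are all identical
(e.g. exact copies of one frame) short-circuits to a single cluster
with the first item as exemplar, and the median preference — the usual
choice when the cluster count is unknown — tends to split broad
homogeneous blobs; for well-separated but unevenly populated states the
minimum similarity is the standard preference to reach fewer clusters,
and the parameter is exposed everywhere. Published analyses using other
AP implementations will not reproduce exact cluster counts; cluster
counts are data- and hyperparameter-dependent and the package treats
them as such.

The joint second round pools exemplars from several systems, clusters
them on the descriptor metric, and sums each system's first-round
weights per joint cluster; rows of the resulting population table are
normalised by each system's total frame count, so frame counts are
conserved through both rounds (an invariant under test). Similarity
trees are average-linkage (`stats::hclust`) over any of the distance
matrices, exported as Newick through `ape`; ultrametric inputs are
reproduced exactly by the cophenetic distances.

## Ligand-pose criterion

The screening rule — *at most 10% of the ligand vectors may deviate,
by at most 1 Å* — is read conjunctively: every protrusion must be
within the 1 Å slack *and* the protruding fraction within 10%. The
alternative reading (a total deviation budget) is rejected because a
single per-vector tolerance composes better with the per-index
construction; both thresholds are parameters, and acceptance is
provably monotone in each (and in pocket size). The denominator is the
number of ligand-intersecting vectors only, since vectors that miss the
ligand say nothing about the pose. Ligand charges are recorded for
complementarity inspection but do not affect acceptance.

## Synthetic fixtures and what they do (not) show

The generators build pockets whose true geometry is known in closed
form: Fibonacci-lattice shells of identical atoms at radius ρ, for
which the first-surface distance along any covered ray is ρ − r, with a
one-sided excess bounded by the lattice granularity. The generator
reports that bound (computed from the exact hard-sphere hit formula at
the lattice covering angle, with an empirical 1.3 safety factor on the
mean spacing) so tests can set tolerances programmatically rather than
by hand. The shell extends 0.2 rad below the equator so equatorial rays
of a closed-hemisphere scaffold are covered. Two-state ensembles draw
each frame's pocket radius from one of two states and add seeded
coordinate noise; charged-patch cavities put a fixed charge on a
spherical cap, for which the charge RMSD against the neutral cavity is
|q|·√(patch fraction) in closed form. All generators are pure functions
of their arguments including the seed, and restore the caller's RNG
state.

These fixtures validate geometry, metrics and the clustering machinery
exactly, but they are smooth, isotropic and noise-free in ways real
pockets are not: no side-chain texture, no partial occupancy or missing
residues, no correlated backbone motion, no real charge distribution.
Passing tests therefore certify the *implementation*, not the
biological discriminating power of the descriptor on real ensembles.

## Problem sizes and numerical settings

The shipped tests run at deliberately modest sizes chosen to exercise
every code path with comfortable margins: oracle comparisons use 100
random ≤30-atom structures against a 0.001 Å ray-marching oracle on a
frequency-2 hemisphere (agreement required within 0.002 Å, twice the
marching step); cavity recovery uses the full frequency-7/260-vector
scaffold with ~1900 shell atoms; clustering recovery uses 16–40-frame
two-state ensembles on frequency-2/3 scaffolds. Tolerances follow the
quantity: 1e-12 for algebraic identities, 1e-9 for orthonormality and
symmetry, 1e-6 Å for rigid-motion recovery, and generator-reported
granularity for synthetic-cavity geometry.

## Known limitations

- One anchor, one fan: pockets far from the anchor or reachable only
  around a corner are foreshortened or invisible; multi-anchor fans are
  out of scope.
- Index-wise comparison inherits all alignment error; descriptors from
  poorly superposed structures degrade silently.
- Hard-sphere surfaces ignore solvent; a ray can thread a gap narrower
  than a water molecule.
- Affinity-propagation cluster counts are hyperparameter-sensitive;
  only the weighted downstream quantities (population tables,
  ensemble-weighted RMSDs) should be compared across settings.
- The packaged charge table is a documented simplification; absolute
  charge RMSD values depend on the table and should only be compared
  within one charging scheme.
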