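# sitevec

Binding-site vectors: a fixed, indexed fan of rays that turns a
macromolecular binding pocket into a comparable shape + electrostatics
fingerprint.

## The idea

Comparing binding pockets across crystal structures, predicted models or
molecular-dynamics frames is hard because pockets are irregular, buried
cavities with no natural coordinate system. `sitevec` fixes the
coordinate system once: a class-I geodesic sphere (a subdivided
icosahedron projected onto a sphere, 10·f² + 2 vertices at edge
frequency f) defines a set of unit directions, and from an anchor point
inside the pocket one ray is cast per direction. Each ray is truncated
at the first van der Waals atomic surface it meets — with offset *b* of
the atom centre along the ray and perpendicular distance *y*, the hit is
at *c = b − √(r² − y²)* — and labelled with that atom's partial charge.
A conformation thus becomes a pair of fixed-length vectors (lengths
*l_k* in Å, charges *q_k* in e), comparable index-by-index across any
structures aligned to the same reference frame.

For cytochrome P450s, the natural anchor is the heme iron: structures
are placed with the iron at the origin and the heme in the xy-plane, the
default frequency-7 scaffold gives 492 directions, and restriction to
the closed hemisphere above the heme leaves 260 pocket-facing vectors.

Descriptors are compared by per-index RMSD:

- shape: `RMSD_s = sqrt(mean((l_a - l_b)^2))` (Å)
- charge: `RMSD_c = sqrt(mean((q_a - q_b)^2))` (e)
- combined (unitless): lengths and charges normalised by pooled standard
  deviations σ_l, σ_q and mixed with weights `w_s = 2/(2+d)`,
  `w_c = 2(1+d)/(2+d)` so that `(w_s + w_c)/2 = 1`; `d` tunes the
  shape/charge balance.

On top of the metrics sit: affinity-propagation clustering of
conformational ensembles into weighted exemplars, ensemble-weighted
inter-protein RMSD (`sum over exemplar pairs of RMSD_ij · n_i/N ·
n_j/N`), average-linkage similarity trees exported as Newick, a joint
second clustering round with weight propagation into per-system
population tables, and a binary ligand-pose criterion: ligand vectors
(same rays, terminated at the *farthest* ligand-surface point) fit a
pocket when at most 10% of the ligand-intersecting vectors protrude,
none by more than 1 Å.

## Worked example

A synthetic hemispherical pocket of radius 8 Å tiled with 1 Å atoms has
a known first-surface distance of 7 Å along every ray, which the trace
recovers; a 6 Å pocket differs from it by exactly the 2 Å depth change;
and a spherical "ligand" of radius 3 Å centred 3 Å above the anchor fits
the wide pocket but not the narrow one:

```r
library(sitevec)

scaffold <- restrict_hemisphere(build_scaffold(7, 20))
scaffold
#> Binding-site vector scaffold
#>   frequency : 7  (class-I geodesic, 492 directions)
#>   max length: 20 Angstrom
#>   retained  : 260 of 492 directions

pocket <- make_cavity(pocket_radius = 8, atom_radius = 1, shell_density = 4)
desc <- trace_site(pocket, scaffold)
desc
#> Site descriptor 'cavity' (frame 1): 260 vectors, 260 hits
#>   lengths: 7.00 - 7.05 A (max 20.00)

narrow <- trace_site(make_cavity(6, 1, shell_density = 4), scaffold)
rmsd_shape(desc, narrow)
#> [1] 2.000135

lig <- new_structure("ball", element = "C", name = "C1", resname = "LIG",
                     resid = 1, coords = matrix(c(0, 0, 3), 1),
                     radius = 3, charge = 0)
pose_compatible(trace_ligand(lig, scaffold), desc)
#> $accept: TRUE   $n_violations: 0    $n_considered: 232
pose_compatible(trace_ligand(lig, scaffold), narrow)
#> $accept: FALSE  $n_violations: 40   $n_considered: 232  $max_protrusion: 0.96
```

The ligand intersects 232 of the 260 rays; against the narrow pocket 40
of them (17%) protrude, so the pose is rejected by the 10% rule even
though no single protrusion exceeds the 1 Å slack.

Real structures follow the same path: `read_structure()` →
`assign_radii()` → `assign_charges()` → `compute_reference_frame()` /
`apply_frame()` → `trace_site()`; ensembles additionally go through
`cluster_descriptors()` / `summarize_ensemble()` / `ensemble_rmsd()` /
`joint_recluster()` and `build_tree()`. A thin command-line wrapper
(`inst/scripts/sitevec`, subcommands `scaffold`, `frame`, `descriptor`,
`compare`, `cluster`, `recluster`, `tree`, `ligand-fit`) chains the same
functions for shell pipelines.

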