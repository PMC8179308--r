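---
title: "Interfacial structure and hinge-mediated water transport in biphasic slabs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interfacial structure and hinge-mediated water transport in biphasic slabs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slabhinge)
```

## The problem

Water/octanol partitioning is the standard laboratory surrogate for solute
transport across lipid membranes, yet the molecular mechanism by which even
the simplest solute — water itself — crosses the water/octanol phase boundary
is non-trivial. At equilibrium the interface is organised well beyond the
instantaneous water surface: amphiphiles at the surface point their hydroxyl
heads into the water ("Layer-1"), and a second, semi-organised layer of
molecules with heads toward the organic phase ("Layer-2") forms
hydrogen-bonded "bilayer islands". Water moves between these layers by three
distinguishable mechanisms: plain diffusion with no water–octanol hydrogen
bond, reorientation ("stochastic flipping") of a single octanol carrying at
most one water, and a collective *hinge* motion in which an intact
hydrogen-bonded octanol–water cluster swings across the instantaneous
surface, picks water up on one side and deposits it on the other.

`slabhinge` implements the full analysis chain needed to quantify this
picture from slab trajectories, and a reduced one-dimensional Langevin model
of the hinge coordinate. Because no public trajectory exists for this
system, a synthetic-slab generator with planted, labelled structure and
scripted transport events stands in for MD output; every stage is validated
against brute-force oracles and that planted ground truth.

## Geometric conventions

Internal units are Angstrom, ps, kcal/mol, amu, Kelvin (GRO files are
converted from nm on ingest). Boxes are orthorhombic; molecule identity is
positional and constant across frames. All distance criteria use the
minimum-image convention, with components of a displacement mapped to
`[-L/2, L/2)`.

A hydrogen bond is geometric: donor–acceptor O···O distance strictly below
3.5 Å and an H–O···O angle of at most 30°, the same rule for water–water,
water–octanol and octanol–octanol pairs. The angle is evaluated at the donor
oxygen between its covalent O–H vector and the O···O vector; the donor's H is
identified by its role in the topology, never by distance. The distance bound
is exclusive and the angle bound inclusive; the field's customary phrasing
("less than", "0–30°") leaves the angle boundary open, and the choice only
matters on a measure-zero set. Cutoff clusters use the same 3.5 Å O–O
criterion and are connected components of the proximity graph.

Neighbour search uses periodic cell lists with cells at least one cutoff
wide. This is a pure performance device: the test suite asserts bit-identical
results against an all-pairs scan.

## Intrinsic surfaces

**ITIM.** Probe spheres of radius 1.5 Å descend along test lines on a 0.2 Å
xy grid; the first atom each probe touches (centre distance ≤ atomic radius +
probe radius) marks its molecule as truly interfacial. Atomic radii default
to Bondi-type values (O 1.52, H 1.10, C 1.70 Å) since none are stated with
the method; both the radii and the probing direction are configuration. Each
slab side is probed separately.

**Penetrated-water correction.** Waters dissolved in the organic phase would
otherwise be claimed by the probes, so water oxygens are first clustered
with DBSCAN (`eps` 3.5 Å — the HB O···O scale — and `min_samples` 3, both
package choices as the method's parameters are unstated). The largest
cluster, plus any cluster hydrogen-bonded to it, is the aqueous phase; ITIM
runs on that set only. Octanols are truly interfacial iff their hydroxyl is
hydrogen bonded to a truly interfacial water.

**Willard–Chandler surface.** The instantaneous area comes from the
isosurface of a Gaussian coarse-grained density field (coarse-graining
length 2.5 Å, truncated at 4σ, voxel 1.0 Å) at 90% of the bulk water
density, estimated from the central 20% of the aqueous slab. No
marching-cubes implementation exists in the R stack this package targets, so
the isosurface is extracted column-wise as a periodic height field and
triangulated — equivalent for the single-valued, quasi-planar surfaces in
scope, and validated against the planar limit (area → `Lx·Ly` within 2%) and
an analytic surface-integral quadrature for a sinusoidally corrugated slab
(within 3%). Strongly overhanging surfaces are outside this extractor's
domain.

## The five regions and Layer-2

`assign_layers()` partitions every molecule into bulk water, instantaneous
water surface, Layer-1, Layer-2, or bulk octanol:

* surface waters: the corrected truly-interfacial set;
* Layer-1: octanols hydrogen bonded to a surface water;
* Layer-2: the structural definition (second semi-organised layer, heads
  toward the organic phase) is made operational as a second ITIM pass over
  the octanol phase after deleting Layer-1, intersected with the orientation
  sign criterion (end-to-end cosine pointing organic-ward) and a depth bound
  (default 25 Å past the interface, roughly the second density-oscillation
  minimum — about two molecular lengths). The bound is exposed because the
  structural definition gives no bulk-ward limit;
* waters hydrogen bonded to Layer-1/Layer-2 octanols inherit the layer label
  (majority of HB partners, ties to Layer-1);
* everything else is bulk by species, with DBSCAN-penetrated waters counting
  as bulk octanol.

Orientation uses the molecular end-to-end vector from the hydroxyl H to the
terminal chain carbon against the +z normal; interfacial octanols sit near
cos θ ≈ 0.7 (≈45°). In-plane structure is quantified by 2D radial
distribution functions of the layer oxygens (xy-projected minimum-image
distances, normalised per frame by `2πr dr ρ N`, r capped at `min(Lx,Ly)/2`)
and by the two-dimensional excess coordination number
`N_excess(r) = ρ ∫ (g−1) 2πr' dr'` (trapezoidal quadrature); negative values
flag octanol-depleted zones between bilayer islands. Islands themselves are
O–O cutoff clusters within Layer-2 holding at least two octanols. The
surface packing density is the per-frame count over the instantaneous
(Willard–Chandler) area, averaged over frames — per-frame versus pooled
averaging has no fixed convention in the literature; this package averages
per frame.

## Transport events

Region transitions are debounced run-wise: a new region must persist for at
least `persistence` frames (default 1 at 10 ps sampling) and the transition
is stamped at the first frame of the new region. For each water transition
along a transport direction, the hydrogen-bonded carrier cluster containing
the water is inspected over a window of ±1 frame around the crossing, and
the maximal composition (most octanols, then most waters) is recorded, since
cluster membership can fluctuate during migration. Classification follows
the composition: no octanols — diffusion; exactly one octanol that itself
changes layer in the window — stochastic flip; two or more octanols — hinge.
A single attached octanol that does not flip counts as diffusion. Waters
sharing carrier octanols, direction and overlapping windows merge into one
event. Flip statistics for octanols (direction-resolved rates per 10 ps and
the concurrent water-HB load) are collected separately.

Transfer statistics aggregate per direction: event counts, waters moved,
mean carrier composition, mechanism fractions both by events and by waters
(reported against the all-mechanism and the HB-mediated-only denominators,
since the published shares are ambiguous about the denominator), the
per-water stoichiometry (mean octanols per event over mean waters per
event), and three-block standard errors throughout.

Barriers use the Arrhenius relation `E_a = R T ln(A/k)` with
R = 1.98720425864083×10⁻³ kcal/(mol K); negative barriers are flagged, never
clipped. For the effective hinge reaction
`H2O(L1) + ν oct(L1) ⇌ H2O(L2) + ν oct(L2)` the rate constants are the
per-direction water-transfer rates normalised by layer concentrations
(mean molecule counts per frame — the normalisation is recorded in the
output metadata because no standard fixes the units), with ν defaulting to
the measured stoichiometry. The prefactor is the caller's documented choice
between the water–octanol HB-formation rate and the
surface-adsorption-plus-HB rate; two conventions differ in `E_a` by exactly
`R T ln(A₁/A₂)`, which the tests assert as an identity.

## Thermodynamic observables

Interfacial tension uses the planar Kirkwood–Buff pressure-tensor form
`γ = L_z/(2 N_int) · ⟨P_zz − (P_xx+P_yy)/2⟩` with `N_int = 2` interfaces in
the periodic cell and the exact unit chain 1 bar·Å = 10⁻² mN/m; errors are
three-block SEMs. Mole-fraction solubility is `ρ_w/(ρ_w+ρ_oct)` from mean
number densities in the octanol-rich region. Both estimators are in scope;
the published MD values for them (7.83 mN/m, 0.26) require full-scale
equilibrium MD and are not reproduction targets here.

## The Langevin double-well model

The hinge coordinate is reduced to one dimension: two bound states at
z = −0.868 nm (Layer-1) and +0.854 nm (Layer-2) — the mean molecular lengths
of octanol in the two layers — separated by a barrier at z = 0 with
forward/reverse heights 6.00 and 5.60 kcal/mol. The exact fitted functional
forms reported for this model are not publicly available; this package uses the constrained
piecewise quartic `U = E_a(−1 + 2s² − s⁴)` on each side (s the scaled
distance from the minimum to the barrier), continued harmonically with
matched curvature beyond the minima. It satisfies every stated constraint —
minimum positions, barrier location and heights, C¹ smoothness, stationary
endpoints — with no free shape parameters; the well widths it implies are
*not* constrained by anything published, which matters below.

Dynamics: BAOAB discretisation of the Langevin equation at an inner step of
0.01 ps (stable at ω·dt ≈ 0.03 for an 18 amu particle in these wells),
positions sampled every 1 ps for 100 000 samples per replicate, 1000
replicates each started at the left minimum with Maxwell–Boltzmann
velocities, all driven by a counter-derived per-replicate RNG so runs are
bit-reproducible under a fixed seed. Friction has no agreed literature value here;
the default is 1.0 ps⁻¹ and the acceptance analysis documents the value
used. A well-to-well crossing is counted with hysteresis at the *minima*:
the particle, last assigned to one well, must reach the other minimum's z —
so per-replicate |forward − backward| ≤ 1 by construction. The transport
ratio is pooled forward over pooled backward crossings, with a three-block
SEM over replicates.

**Known limitation.** With this potential shape and counting rule the
simulated ratio is ≈1.38–1.42 for every friction in 0.5–5 ps⁻¹ (the crossing
rate peaks near the Kramers turnover at γ ≈ 0.5–1 ps⁻¹), above the published
1.16 ± 0.11. The pooled ratio equals 1 + P(replicate ends in the right
well)/E(backward crossings per replicate); matching 1.16 requires roughly
2.4× our well-to-well rate, i.e. narrower wells or a different (unpublished)
potential shape, or a different crossing-counting rule. Since the shape
constraints stated in the main text pin everything we implement, the
discrepancy is reported rather than tuned away. Occupancies and velocity
statistics, by contrast, agree with basin-integrated Boltzmann weights and
the Maxwell–Boltzmann distribution, which the tests assert.

## The synthetic world

`gen_slab()` states the structural world: an aqueous slab of waters on a
commensurate jittered lattice at liquid-water density (3.1 Å spacing), a
boundary of tunable sinusoidal corrugation, Layer-1 octanols hydrogen bonded
to surface waters at 45° ± 5° mean tilt with the observed 2.80 nm⁻² default
packing, Layer-2 islands built as rings of octanols at 2.8 Å O–O spacing
with heads organic-ward and a linear water loading (`round(0.4 × size)`,
giving 1–3 waters on 4–5-octanol islands), sparse randomly oriented bulk
octanol, and isolated penetrated waters ≥15 Å past the boundary. Octanol is
a 10-site elongated chain (hydroxyl O and H plus eight carbons at 1.5 Å);
conformational flexibility is not modelled.

`gen_event_trajectory()` scripts transport events with ground truth: each
event owns its molecules and an isolated site; hinge carriers rotate rigidly
about a pivot in the Layer-1 plane between the Layer-1 and Layer-2 stations,
flips reorient one octanol in place, diffusing waters traverse without
entering HB range of any octanol. Ground-truth labels switch at the frame
where the moving group crosses the half-height between stations.

What a green test does and does not establish: the generator produces ideal,
noise-free mechanisms — real trajectories have thermal jitter, transient HB
breakage inside carriers, and ambiguous compositions that the maximal-window
rule only approximates. Recovery of planted events validates the
*definitions and bookkeeping*, not classifier robustness to thermal noise;
oracle agreement validates the geometry kernels exactly.

## Numerical choices

* Distance bound exclusive, angle bound inclusive; DBSCAN neighbourhood
  `d ≤ eps` with self-counting `min_samples` (scikit-learn convention).
* Cluster ordering: by smallest member id; label ties for layer waters
  resolve to Layer-1.
* WC bulk density: mean field value between the 40% and 60% z-quantiles of
  the water oxygens; columns locally below the level fall back to their
  densest voxel before scanning outward.
* ECN by trapezoid on the RDF grid, `N_excess(0) = 0` enforced.
* Degenerate inputs error early and name the offending molecule or stage;
  zero-length orientation vectors are skipped with a warning.
* Every stochastic path (generators, Langevin) takes an explicit seed and
  restores the caller's RNG state.
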