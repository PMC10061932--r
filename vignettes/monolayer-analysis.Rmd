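---
title: "Analysing protein-containing surfactant monolayer simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing protein-containing surfactant monolayer simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`psurftools` analyses molecular-dynamics trajectories of lipid
monolayers at the air–water interface — the standard in-silico model of
pulmonary surfactant — with or without embedded hydrophobic proteins
(SP-B, SP-C). This vignette explains the methods behind each stage, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices baked into the implementation.

## The physical setting

A simulated monolayer system is a slab: a water layer in the middle of
the box, one monolayer on each water–vapour interface, chains pointing
outward. Compression is emulated by shrinking the lateral box edge
linearly in time, so the area per lipid (APL) sweeps a range such as
90 → 45 Å² over the run. Under compression the film develops coexisting
phases: liquid-expanded (L~e~, disordered chains) and liquid-condensed
(L~c~, tightly and hexagonally packed chains). Hydrophobic proteins
partition into the L~e~ phase, perturb packing in their vicinity, raise
the surface pressure and slow lipid diffusion.

## Interfacial quantities

Surface tension comes from the pressure-tensor anisotropy,

$$\gamma = 0.1\,\frac{L_z}{n_\mathrm{int}}
  \Bigl(P_{zz} - \tfrac{P_{xx}+P_{yy}}{2}\Bigr),$$

with pressures in bar, $L_z$ in nm and $n_\mathrm{int}=2$ interfaces;
the prefactor converts bar·nm to mN/m. Surface pressure is
$\Pi = \gamma_0 - \gamma$. $\gamma_0$ is a required configuration value,
defaulting to the experimental water–air tensions (69.4 mN/m at 310 K,
71.7 mN/m at 298 K), because the appropriate reference depends on the
water model of the simulation being analysed; it is deliberately not
hard-coded. Negative $\Pi$ values are reported as-is (with a message)
rather than clipped: they are informative about an over-expanded film or
a mis-chosen $\gamma_0$.

Compression runs are out of equilibrium, so `windowed_isotherm()` bins
$\Pi$ and APL into consecutive, non-overlapping, time-based windows
(default 100 ns; half-open on the right) and reports per-window means,
spreads and standard errors; a trailing partial window is kept and
flagged. `isotherm_shift()` interpolates two isotherms linearly in APL
onto the overlap of their ranges, restricted by default to 50–85 Å² —
"across the isotherm" is ill-posed at the collapse and over-expanded
extremes — and averages the pointwise difference. APL never subtracts
protein area: the compression state moves the protein vertically, which
would make any exclusion ambiguous.

## Phase detection

Condensed packing is detected in the monolayer plane with DBSCAN on the
per-chain marker atoms: the 10th carbons of both acyl chains (CHARMM36
names `C210`, `C310`) and the cholesterol `C14`, which sits at the same
depth. The atom labels are a force-field convention and fully
overridable via a YAML role map; the chemistry (10th chain carbon) is
what defines the marker.

`dbscan_pbc()` uses 2D minimum-image Euclidean distances in the
rectangular periodic box, with a cell list for neighbour queries.
Numerical conventions, all mirrored by the brute-force reference used in
the tests:

* `min_pts` counts the query point itself (a core point has at least
  `min_pts − 1` neighbours within `eps`, inclusive distance);
* clusters grow from core points in ascending point-index order, so a
  border point reachable from two clusters goes deterministically to the
  first-reaching (lowest-id) cluster;
* `eps ≥ min(box)/2` is refused — periodic images would be ambiguous.

Defaults are `eps = 0.55` nm, `min_pts = 4`, `min_cluster_size = 10`,
and all three are explicit arguments everywhere. They are chosen so that
a 0.48 nm hexagonal lattice (typical condensed chain spacing) clusters
while a disordered background with separations above 0.55 nm does not;
clusters below `min_cluster_size` do not count as condensed. Distance
profiles around the protein (`lc_fraction_vs_distance()`) use 2D
in-plane distances to protein heavy atoms — phases are defined in the
plane — whereas contact counting (below) is 3D, where transverse protein
positioning matters. Empty distance bins are reported as missing, never
as zero.

## Density maps, thickness and tilt

`density_profile()` aligns each frame and leaflet so the mean phosphorus
z of that leaflet sits at $z' = 0$, with the sign flipped per leaflet so
the acyl-chain (air) side is negative for both. The alignment is
per-leaflet and per-frame, which is exactly what makes "phosphorus stays
at the same depth" true in the averaged map. Mass-weighted histograms
are averaged over leaflets and over the frames of each surface-pressure
regime (the regime of a frame is the window-mean $\Pi$ of the window
containing it). The extent curve records the outermost crossings of 5%
of each species' maximum, linearly interpolated between bin centres, so
extents are resolved below the bin width; monolayer thickness is the
width of the phospholipid extent. Density integrals conserve the total
species mass by construction (validated to 10⁻⁶ relative in the tests).

Chain tilt is the angle between the first→last chain-carbon vector and
the outward leaflet normal (+z upper, −z lower). The protein axis is the
largest-variance principal direction of the centred backbone, sign-fixed
from first to last residue; an angle near 90° means the helix lies in
the monolayer plane. Note that the principal axis of a finite discrete
helix deviates slightly from its geometric axis, so the tests use
backbones with mirrored perpendicular decorations whose covariance
cancels exactly.

## Contacts

A contact is a (protein heavy atom, lipid heavy atom) pair within 0.3 nm
(3D minimum image). Counts are accumulated per protein residue and lipid
type, averaged per frame, then stratified by pressure regime; standard
errors come from replica labels when provided (independent monolayers
are the independent samples). Normalization divides by the number of
heavy atoms of the lipid type in the protein's leaflet — "available
contact partners", correcting for both copy number and molecular size —
with a per-molecule alternative behind the `per` argument. Per-residue
maps are additionally divided by the lipid-type mole fraction so maps
are comparable across compositions. Averaging per frame before pooling
(rather than pooling all frames first) only affects standard errors, not
means; we average per frame because it keeps replica bookkeeping exact.

## Diffusion

Lateral displacements are collected per molecule over non-overlapping
lag windows (default 10 ns) of the unwrapped reference-atom track
(phosphorus for phospholipids, the hydroxyl oxygen for cholesterol,
centre of mass for proteins — configurable, since trajectories do not
dictate which atom represents a lipid). Non-overlapping windows keep
displacements approximately independent, so standard errors need no
autocorrelation correction. Leaflet centre-of-mass drift is subtracted
by default: the two monolayers can drift independently, and the drift
correction removes exactly $1/N$ of the single-molecule variance (the
tests account for this factor). No finite-size periodic-boundary
hydrodynamic correction is applied; relative quantities (ratios across
regimes, slowdown percentages) are unaffected by it.

For free 2D diffusion the displacement magnitude has density
$p(r) = \frac{r}{2Dt}\exp\!\bigl(-\frac{r^2}{4Dt}\bigr)$, whose
maximum-likelihood estimate is $\hat D = \sum r^2/(4tn)$ with standard
error $\hat D/\sqrt n$; a Kolmogorov–Smirnov distance to the fitted
density is attached as a goodness-of-fit diagnostic. RMSD uses the
optimal least-squares rigid superposition computed via the SVD (Kabsch),
with the reflection branch removed; it is implemented in-package because
the available library routine rounds its result more coarsely than the
10⁻⁶ rigid-motion contract the tests impose.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every stage is verified.

`generate_monolayer()` emulates, per leaflet: (i) the 60/20/10/10
DPPC/POPC/POPG/CHOL composition via largest-remainder apportionment;
(ii) a planted condensed fraction `f_lc` of markers on hexagonal patches
of spacing 0.48 nm (patch count shrinks automatically so no patch falls
below 12 markers — smaller islands would not count as condensed);
(iii) a disordered background whose markers keep a strict minimum
separation of 0.55 nm — just above the DBSCAN radius, so the background
can never cluster; (iv) whole lipids assembled around the markers with a
Gaussian z model (phosphorus σ = 0.15 nm about the interface plane,
markers 1.0 nm toward the chain side, terminal carbons 0.55 nm beyond
the markers); and (v) an optional rigid two-layer pseudo-protein disc
(~100 beads, arbitrary residue labels) whose halo demotes lattice
markers to the disordered phase with probability
`halo_lc_suppression`. Ground-truth labels accompany every marker.

Two background-placement regimes are used, both guaranteeing the same
strict separation. Random sequential dart throwing jams near
0.547·4/(π·d²) ≈ 2.3 points/nm² at d = 0.55 nm, while a compressed
monolayer's marker density (two chains per phospholipid) exceeds that
below roughly 82 Å² per lipid when the background dominates. Above 80%
of the jamming density the sampler therefore draws candidates from a
randomly oriented, jittered hexagonal grid at 1.05·d (capacity
≈ 3.5 /nm²) instead of darts. Every candidate passes the identical
distance check; only the attainable density differs. Requests beyond the
grid capacity raise a geometry error — planted fractions must grow under
compression, as they do physically. Consequently planted backgrounds at
high density are locally grid-like rather than ideally random; since
phase detection only tests separations against `eps`, this does not
affect any planted-truth recovery.

What the generator does **not** emulate: real chain conformations and
their thermal disorder, protein structure (the disc is rigid and
featureless), electrostatics, curvature or collapse, and any coupling
between composition and phase preference. Passing the planted-truth
tests therefore demonstrates that the *analysis machinery* is correct —
detection, binning, normalization, estimation — not that any particular
force field or simulation reproduces experiment.

`generate_brownian()` plants 2D Gaussian steps of per-axis variance
2·D·dt with wrapped and unwrapped tracks; `generate_pressure_series()`
plants a surface-tension schedule exactly (before optional Gaussian
noise on each pressure component) and an APL ramp whose box edge is
linear in time; `generate_compression_stack()` builds one configuration
per APL with identical molecule counts and ordering, so the stack shares
a single topology and runs through the pipeline as a trajectory.

## Pipeline

`run_pipeline()` composes the stages over a trajectory plus pressure
series: isotherm, per-frame pressure and regime (single source of truth
for all stratification), phases, protein-distance profiles, density
maps, contacts, diffusion per regime and protein RMSD. Outputs are tidy
tab-separated tables plus a JSON report with parameters, seed, record
counts and a config hash; identical inputs and config reproduce
byte-identical tables. Protein-dependent stages are skipped with a
logged reason for protein-free systems; a stage failure removes partial
outputs and names the stage. A thin command-line wrapper
(`inst/scripts/psurf-pipeline.R`, subcommands `synth` and `run`) exposes
the generator and the pipeline to shell users; the single-stage
operations are the exported functions themselves.

## Problem sizes and test design

The test and acceptance workloads use 400 lipids per leaflet (roughly
760 markers, matching the scale at which phase coexistence is
meaningful), 50 DBSCAN oracle instances of 200 points, Brownian plants
with 5000 displacements, 200-seed bias checks at n = 1000, and
compression stacks of 3–6 frames at 80–150 lipids per leaflet. These
sizes give every stochastic check a comfortable margin (3 standard
errors or better) while the whole suite runs in about a minute.

## Known limitations

* Leaflet assignment for molecules without phosphorus (cholesterol,
  proteins) uses the nearest phosphorus population mean; a protein
  genuinely straddling the interface is still assigned to one leaflet.
* Only orthorhombic boxes are supported; monolayer compression runs use
  square lateral cells.
* Multi-frame GRO is the reference trajectory format; binary formats
  are expected to arrive through an external reader producing the same
  frame structure.
* Contact normalization assumes the SI-level details of published
  normalizations only up to "available partners"; both the heavy-atom
  and per-molecule conventions are exposed.
* The diffusion estimator assumes free 2D diffusion within a lag window;
  anomalous or obstructed diffusion shows up in the KS diagnostic, not
  in a model extension.
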