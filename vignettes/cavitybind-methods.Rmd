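---
title: "Methods behind cavitybind: pose metrics, escape statistics, orientation maps, water exchange and clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind cavitybind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavitybind)
```

# The problem

Buried ligand-binding cavities — the PXR-type nuclear-receptor pocket is
the motivating case — pose three analysis problems that a single RMSD
trace does not answer: *is a simulated pose the same as a crystal pose*
when the protein itself deforms; *how long does a pose survive* across
replicas when many never leave it; and *which way do solvent and ligand
get in* when the only openings are transient gates. This vignette
documents how each statistic in the package is defined, the conventions
and defaults chosen where the underlying methods are conventionally
under-specified, and what the synthetic generator does and does not
establish.

# Coordinate conventions

Coordinates are Angstrom, times nanoseconds, frame indices 0-based (the
convention of mainstream trajectory tools; `times = t0 + frame * dt`).
Residue numbers are never renumbered from the source file and the residue
key is `(chain, residue number, insertion code)`. PDB alternate locations
keep the highest occupancy (tie: altloc A). Hydrogens are recognized by
the element column when present, else by the leading alphabetic character
of the atom name. No periodic-boundary handling is attempted — inputs are
assumed whole — but a validation pass warns on inter-frame atom jumps
above 20 Å, the usual symptom of a broken molecule.

Superposition is the Kabsch least-squares fit with the reflection branch
excluded. Fits with fewer than 3 atoms are errors; near-collinear fit
sets (second singular value < 1e-8 of the first) warn, because the
rotation about the axis is then underdetermined.

Formats: PDB and GRO structures, multi-model PDB and binary (CHARMM-style)
DCD trajectories. XTC is deliberately not supported: its compressed
coordinate codec has no available R implementation, and trajectories are
convertible to DCD with any mainstream tool. Multi-model PDB frames carry
`REMARK TIME_NS=` lines so frame times round-trip through text files.

# dRMSD: superposition-free pose comparison

With ligand heavy atoms $i$ and binding-site heavy atoms $j$,

$$\mathrm{dRMSD} = \sqrt{\frac{\sum_i \sum_j (d_{ij}^x - d_{ij}^m)^2}{N}},$$

where $d^x$ and $d^m$ are ligand-to-site distances in the reference and
model and $N$ is the pair count. Because only internal distances enter,
the metric needs no superposition, is symmetric in the two structures and
is invariant under rigid motion of either — which is exactly what makes
it preferable to a plain ligand RMSD when the protein scaffold deforms
between model and reference.

Conventions chosen here: the site is **frozen on the reference
coordinates** (all protein heavy atoms with minimum distance ≤ 6 Å from
any ligand heavy atom, inclusive boundary); per-frame redefinition would
make values across a trajectory incomparable. Heavy atoms are used on
both sides (the protein-side hydrogen treatment is ambiguous in common
usage; a `heavy_only_site` switch exposes the alternative). Cross-crystal
atom correspondence for `pairwise_site_rmsd()` is by
`(chain, residue number, insertion code, atom name)`; unmatched atoms are
dropped and counted in a message, since reference structures routinely
differ in resolved atoms.

# Escape times and censoring

The per-replica stability statistic is a first-passage time: after a
global Cα fit of every frame to the reference frame, the ligand-heavy-atom
RMSD series is thresholded at 4 Å (inclusive ≥, no persistence window by
default because single-crossing times are the reported convention; a
`persistence` option exists for noisy data). A replica that never reaches
the threshold is right-censored at its total simulated time.

Summary statistics are rank-based with censored replicas ranked above
every observed time — with, say, 11 of 23 replicas censored, the median is
the 12th ordered observed value; if an order statistic lands on a censored
rank it is reported as a lower bound "≥ total time". For even replica
counts the lower-middle order statistic is used, since interpolating
between an observed and a censored value is undefined. Boxplots use the
1.5 × IQR whisker convention. The Cα prefit (rather than a binding-site
fit) is adopted as the stated alignment convention and exposed as
`fit_selection`.

# Orientation collective variables and solid-angle reweighting

Ligand orientation is reduced to the unit vector from the hydroxyl oxygen
to the carbon bridging the two phosphate groups, evaluated after a global
Cα fit so translation is ignored and only rotation inside the cavity is
measured: $\theta = \arccos u_z \in [0°, 180°]$,
$\varphi = \operatorname{atan2}(u_y, u_x) \in (-180°, 180°]$.

Two genuinely open choices had to be fixed:

* **The lab frame.** The polar axes are the axes of the chosen reference
  structure after the Cα fit. The reference is part of the output
  metadata; maps from different runs are comparable only when they share
  it.
* **φ at the poles** is analytically undefined and set to 0 by convention.

Maps are histograms on a regular (θ, φ) grid, default 10° × 10°. Each
bin's count is divided by the sample count and the bin's solid angle
$\Omega = \Delta\varphi\,(\cos\theta_{lo} - \cos\theta_{hi})$, giving a
density per steradian that integrates to exactly 1 and is flat for
uniform directions — the cosine-difference form handles polar bins with
no division by $\sin\theta$. Densities are reported per steradian rather
than per bin so maps with different binning are comparable; no
normalization across panels is imposed, so either a shared or a per-map
colour scale can be reproduced downstream. Crystal poses are projected
onto the same plane by superposing each structure on the common reference
via matched Cα atoms; the great-circle distance between two projected
poses equals the 3-D angle between their O→C vectors.

# Water exchange through labelled channels

"Exchanged" is only well defined with a boundary rule that tolerates
thermal flicker. The package uses radial hysteresis around the per-frame
centroid of the cavity-lining heavy atoms: a water becomes *inside* at
distance ≤ `r_in`, *outside* at ≥ `r_out`, and keeps its state in the dead
band (defaults 6/8 Å for the toy system; real systems must set both).
This is the minimal construct that makes crossings countable; volumetric
occupancy (grid or hull) was rejected as needlessly heavy for a
radially compact cavity. A second guard, the minimum-residence rule,
drops state stretches shorter than `min_residence_frames` (default 5)
before transitions are emitted, scanning the run-length encoding left to
right so a short excursion never changes the confirmed state. Event
counts are therefore monotone non-increasing in the residence threshold.

Each surviving crossing is assigned to the entrance channel whose
gate-residue centroid is nearer at the crossing frame (ties below 0.01 Å
are left unassigned and excluded from fractions); a majority vote over a
window of frames straddling the crossing is available for noisy paths.
Channel fractions are fractions of *events*; the count of unique waters
is reported alongside, since "N waters exchanged" is ambiguous between
the two readings.

# Daura clustering

Conformations are clustered by the GROMOS greedy algorithm: all-pairs
ligand-heavy-atom RMSD after **one global Cα fit per frame** (per-pair
ligand fitting would erase orientation differences — the very signal the
orientation map displays), neighbour test ≤ cutoff (default 2 Å), then
repeatedly extract the frame with the most neighbours together with its
neighbours. The original algorithm is silent on ties; the lowest frame
index wins, making results deterministic. Clusters are ordered by size
(ties: earlier centroid). The matrix is O(n²); above-budget inputs are
strided with the stride logged, which changes populations but not the
location of well-separated modes.

# The synthetic generator: what a green test establishes

The generator produces a stated world, not a tuned one:

* **Toy complex** — a deterministic Fibonacci-lattice shell (default 400
  scaffold pseudo-atoms, 12 Å radius) with two channel cones (default
  half-angle 25°, axes 90° apart, labelled A/B) and gate pseudo-residues
  on each rim; a rigid 5-atom ligand (hydroxyl O, bridge C, two P, ring
  dummy) at the centre.
* **Orientation mixtures** — von Mises–Fisher components sampled by the
  standard inversion method, $w = 1 + \log(u + (1-u)e^{-2\kappa})/\kappa$,
  azimuth uniform, pole rotated onto the mean; κ = 0 reduces exactly to
  the uniform sphere. Defaults in the demo pipeline put the dominant mode
  at (θ = 60°, φ = 150°), a canonical mode location for this kind of map.
* **Escapes** — a scheduled escape translates the ligand 15 Å outward
  along channel B, guaranteeing a permanent ligand RMSD above the 4 Å
  threshold from the scheduled frame on. Escape is modelled as
  translation because the downstream criterion is purely RMSD-based.
* **Waters** — non-interacting tracers moved along channel axes at
  scheduled frames, with optional post-crossing flicker blips (length ≤
  `flicker_max_len`) that the residence rule must absorb. The demo
  schedule routes 63 % of 300 events through channel B, the scenario
  scale for this analysis. Flicker parameters are free test knobs: no
  quantitative flicker statistics exist to estimate them from.

What green tests on this world establish: the *analysis* code recovers
ground truth exactly (escape frames, event counts, channel fractions,
mixture modes, scheduled geometry) and its estimators have the stated
invariances. What they do not establish: behaviour under force-field
physics — correlated protein motion, ligand flexibility, genuinely
diffusive waters, PBC artefacts. The generator emulates the statistical
structure of MD output, not its physics.

# Numerical choices and degenerate inputs

* `within`, site cutoffs and cluster neighbour tests are inclusive (≤);
  the 5.5 Å switch-off frame filter is strict (<), matching
  "smaller than" phrasing.
* Salt-bridge "broken" cutoff defaults to 4.5 Å, a common N–O criterion;
  it is configuration, not a measured constant.
* Empty selections warn and return empty (an empty selection is an
  answer); empty *required* inputs (ligand with no heavy atoms, empty
  cavity lining) are errors.
* Map bin widths must divide 180°/360° so the grid closes exactly;
  normalization is checked to 1e-9 in tests.
* DCD stores the frame interval as a 32-bit float; dt round-trips to
  ~1e-7 relative precision, and trajectory-time consistency is enforced
  at 1e-9 ns on exact-double inputs.

# Known limitations

* XTC trajectories are unsupported (see above).
* The crystal-structure worked example (pairwise site RMSD between the
  SR12813-bound references) needs prepared PDB depositions that an
  offline environment cannot fetch; the corresponding acceptance test
  fails honestly rather than substituting fabricated coordinates.
* Channel assignment presumes two labelled gates; pathways outside both
  cones are still assigned to the nearer gate rather than flagged as a
  third route.
* The all-pairs clustering matrix is dense; very long trajectories must
  be strided.

```{r demo, eval = FALSE}
# end-to-end demonstration, byte-reproducible given the seed
cfg <- pipeline_config(seed = 1)
run_pipeline(cfg, "run1")
```
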