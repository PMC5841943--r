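---
title: "A geometric-mechanical model of puzzle-cell morphogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A geometric-mechanical model of puzzle-cell morphogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(puzzlecell)
```

## The problem

Leaf and cotyledon epidermal cells of many plants grow into interlocking,
jigsaw-puzzle shapes. A compelling functional reading is mechanical: a turgid
cell behaves like a pressurized vessel, and the stress its outer wall carries
scales with the size of the largest open span of the cell. A cell that grows
isodiametrically therefore accumulates wall stress with size, while a cell
that elongates in one direction, or one that covers its area with narrow
lobes, keeps the open span — and the stress — bounded. `puzzlecell`
implements this idea twice over:

* as a **measurement toolkit** for cell contours — lobeyness, circularity,
  hull solidity, the largest empty circle (LEC), growth anisotropy, and a
  thin-wall hoop-stress proxy; and
* as a **generative simulator** in which polygonal cells grow under an
  imposed tissue-scale expansion while stress-triggered, tension-only
  springs spanning each cell locally restrict growth. Puzzle shapes are not
  programmed in; they emerge.

## Shape statistics

**Lobeyness** is the cell perimeter divided by the perimeter of its convex
hull: 1 for any convex shape, rising with contour complexity, and invariant
to translation, rotation and scale. Unlike **circularity**
(perimeter/sqrt(area)), it does not confound elongation with lobing; unlike
the hull **solidity** (hull area / cell area), it is not inflated by bent,
lobe-free worm or boomerang shapes. All three are provided; lobeyness is the
headline statistic.

The **largest empty circle** is computed the way segmentation pipelines
compute it: the contour is resampled to a maximum spacing (default 1/100 of
the bounding-box diagonal), the sample points are Delaunay-triangulated, and
the largest circumscribed circle whose circumcenter falls inside the polygon
is returned. The triangulation is built by Bowyer–Watson insertion with a
deterministic symmetry-breaking jitter of 1e-9 of the contour scale, which
resolves the exact collinearities and cocircularities of regularly sampled
polygons without affecting any measure at the tolerances used. Candidates on
the boundary are discarded: with dense sampling the boundary case carries no
information. The test suite checks the result against an independent
brute-force oracle (the maximum over an interior lattice of the distance to
the contour) to within 2 % on dozens of random star polygons.

Contours extracted from curved surfaces are 3D; `pca_project()` flattens
them onto the plane orthogonal to the direction of minimal variance before
measurement, exactly; an isometry for planar input. The sampling density
used for the LEC is exposed as the `spacing` argument rather than fixed,
since published pipelines do not state it; results are insensitive to it
once spacing is well below the narrowest feature of interest.

**Growth anisotropy** between two tracked contours is the ratio of singular
values of the centred least-squares linear map from the earlier to the later
point set — 1 for isotropic expansion — computed per cell.

The **stress proxy** is the classical thin-wall hoop stress P·r/t with the
LEC radius in place of the cylinder radius. It is a documented closed-form
proxy for ranking cells and tracking trends, not a finite-element result.

## The growth model

A tissue is a shared-node polygonal cell complex: wall segments are linear
springs, every node carries a bending hinge per owning cell, and
**transversal springs** — the proxy for microtubule-guided cellulose
reinforcement that responds to stress — span cell interiors. Transversal
springs are one-sided: they pull when stretched beyond their reference
length and do nothing when slack, as expected of fibres with high tensile
but negligible compressive strength.

Each simulation step has three phases:

1. **Connection placement** (every `reset_period` steps): every wall node of
   every cell seeks the closest node across its own cell such that the chord
   (i) separates the endpoints by at least `s_min` contour nodes, (ii) lies
   within `theta_micro` of the inward wall normal at *both* endpoints,
   (iii) stays entirely inside the cell, and (iv) avoids locally convex wall
   regions. The reference length is `max(distance, min_micro)`: a connection
   only starts to pull once the span it guards exceeds the target
   `min_micro`, the model's stress threshold. Old springs are discarded
   wholesale — the microtubule array is highly dynamic.
2. **Growth**: every node is displaced by the imposed tissue-scale map
   (per-step factors `g_x`, `g_y`, possibly varying across the tissue for
   gradient runs). Stretched wall springs are relaxed — their rest length
   tracks the new geometry but never shrinks — while transversal references
   are deliberately left untouched: reinforcement does not grow.
3. **Equilibration**: interior nodes relax to mechanical equilibrium with
   the tissue outline pinned at its post-growth position, since tissue-scale
   growth is imposed, not negotiated. Unopposed contracting springs would
   otherwise shrink the whole domain.

Lobes emerge through an entirely geometric feedback: once spans exceed
`min_micro`, taut connections pull wall sections inward; an incipient
indentation exposes its tip to many nodes across the cell and so attracts
more connections, while the matching protrusion in the neighbouring cell
becomes convex and — by rule (iv) — loses them. Indentations deepen,
protrusions grow, and each cell's largest open span stays near the target
while its area keeps up with the tissue.

### Energies and the solver

Wall stretching is strain-based, `0.5 k_s (l - l0)^2 / l0`, so subdividing a
wall leaves its mechanics unchanged; bending is a discrete hinge
`0.5 k_b (phi - phi0)^2` on the signed turning angle; transversal springs
store `0.5 k_m max(0, l - ref)^2`. Rest angles are the as-built angles for
template vertices (the initial polygon is not penalized) and straight for
nodes created by wall subdivision, which penalizes emergent sharp features.
At junctions, bending is evaluated independently within each owning cell's
loop. Forces are analytic gradients, verified against central finite
differences to 1e-5 relative error in the test suite.

Equilibration minimizes the total energy over free nodes with L-BFGS using
analytic gradients, restarted until the largest net force on a free node
falls below `solver_tol` or the iteration budget `max_iter` is spent; the
incoming configuration is kept whenever the minimizer cannot improve it, so
energy never increases. On large, heavily loaded tissues late in a run the
force residual can stall above the default tolerance at a level that is a
small fraction of a single spring's force; runs summarize this in their
`$log` and a single end-of-run warning rather than failing, because the
stalled configurations are mechanically indistinguishable at the metric
level.

### Parameters and calibration

The defaults encode the study conditions of the package (micrometre units):
a 36-cell meristematic template (60 x 60 µm, jittered Voronoi tessellation,
2 Lloyd iterations — near-isodiametric convex cells, mean lobeyness below
1.01), per-step growth `g_x = g_y = 1.03` (3 % per step; 45 steps give a
~14-fold area expansion, the order of magnitude over which puzzle shapes
develop), wall subdivision at `max_segment = 2.5` µm, connection target
`min_micro = 10` µm (on the order of the initial cell diameter: lobing
starts once cells outgrow their starting size), cone half-angle
`theta_micro = 0.35` rad, convexity threshold `kappa_convex = 0.5` rad of
total turning over a +/- 2-node arc, and minimum chord separation
`s_min = 5` nodes. The published description of this model family names the
parameters but its numerical table is not available to us, so stiffnesses
(`k_s`, `k_b`, `k_m`) were calibrated once to reproduce the qualitative
regimes the model family is defined by — lobed cells under isotropic growth,
elongated lobe-free cells under anisotropic growth, a spatial shape gradient
under a gradient of anisotropy — and are documented as package defaults, not
as published values.

Two modelling choices deserve emphasis. First, `ref = max(d, min_micro)` at
placement reconciles the "rest length" and "target length" readings of the
connection rule and is the single most consequential choice in the model;
`ref = d` (connections immediately load-bearing) is the natural sensitivity
variant. Second, the convexity test accumulates turning over a fixed node
window rather than averaging it, making eligibility robust to how finely a
wall happens to be discretized: a young convex polygon is everywhere
"convex" under this test, so connections appear only once cells have grown
and their walls flattened — which is also when spans approach the target.

### Scenarios

`run_scenario()` packages the regimes: `isotropic` (defaults), `anisotropic`
(`g_y = 1`), `gradient` (per-step y-growth interpolating linearly from 1 at
the left edge to `g_x` at the right, on a wider 48-cell template — the
displacement map is continuous, so cells shear but never tear),
`no_restriction` (`k_m = 0`: under pure growth every cell remains an affine
image of its template; the control for everything the springs do), and
`spk1`. The spk1 variant models a mutant that cannot form lobes: the
convexity inhibition is removed (connections may attach inside lobes) and,
to account for impaired cytoskeletal remodelling, the walls are grossly
rigidified (stretching and bending), connections are slightly stiffened,
and connection resets are made less frequent. Its cells deform into gently
interdigitating worm-like shapes instead of lobing, ending less lobed than
the wild-type run at a final LEC close to it — shape changes, stress
regulation does not. The wall-rigidity magnitudes matter: with soft walls
the tip-attached connections of this variant fold cells into tightly
serpentine shapes whose perimeter exceeds the wild type's, a regime the
mutant phenotype does not show.

`sweep_parameter()` re-runs the isotropic scenario across a range of one
parameter (growth isotropy, stiffnesses, `min_micro`, `theta_micro`) and
tabulates final lobeyness, aspect ratio and LEC percentiles; lobing varies
continuously along every axis — there is no sharp onset threshold.

## What the synthetic data does and does not emulate

Generated templates emulate a post-mitotic meristematic epidermis: convex,
roughly isodiametric polygonal cells tiling a rectangle with shared walls.
They do not emulate stomatal lineages (no small-cell populations), real wall
thickness variation, curved organ surfaces, or cell division during
expansion — the simulator's topology is fixed. Metrics are therefore
reported for interior cells by default: outline cells are clamped to the
imposed growth and their shapes are boundary artefacts. Passing tests on
synthetic tissues demonstrates the internal consistency of the mechanism and
the measures, not agreement with any particular imaged organ.

## Numerical choices and degenerate inputs

Contours are normalized to counter-clockwise orientation with duplicate
points removed; self-intersecting or zero-area contours are rejected with
errors, not repaired. The problem sizes used by the shipped tests — 36-cell
templates, 45 steps, 50 oracle polygons — were chosen as the smallest at
which the emergent regimes are unambiguous. Determinism is strict: the
random seed enters only through template generation, the loop itself is
deterministic, and identical seed and configuration reproduce metrics files
byte for byte.

## Known limitations

* The stress proxy is a scalar closed form; it ranks cells and tracks
  trends but does not resolve stress concentrations in indentations.
* Tissue outline pinning means outline cells absorb boundary artefacts;
  only interior cells should be measured.
* No cell division, neighbour exchange, or 3D shell mechanics.
* The equilibrium solver is first-order quasi-Newton on a stiff network;
  late-run force residuals can stall above `solver_tol` (reported, see
  above), and very soft bending with very stiff connections can make
  individual runs fail to converge — parameters far outside the documented
  regimes are not supported.
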