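---
title: "White-matter hydraulic permeability from axon-scale microstructure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{White-matter hydraulic permeability from axon-scale microstructure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonperm)
```

## The physical picture

White matter is modelled as a biphasic medium: rigid, parallel myelinated
axons (the solid phase) immersed in the extracellular space (ECS, the fluid
phase). Because axons are long and quasi-circular in cross-section, the
transverse plane reduces to a two-dimensional packing of discs. Interstitial
flow through the ECS at the velocities relevant to convection-enhanced drug
delivery is creeping flow (Reynolds number of order $10^{-3}$), so at the
tissue scale it obeys Darcy's law

$$\tilde{\mathbf v} = -\frac{k}{\mu}\,\nabla p, \qquad
  \tilde{\mathbf v} = \frac{1}{V}\int_{V_f} \mathbf v \, \mathrm dV ,$$

where $\tilde{\mathbf v}$ is the superficial velocity (fluid flux divided by
the *total* volume), $\mu$ the viscosity and $k$ the hydraulic permeability.
`axonperm` estimates $k$ by building random disc packings that honour the
measurable geometric features of white matter, solving the Stokes equations
through the inter-disc space, and homogenising the fields over nested
windows until the estimate is representative.

Three geometric quantities drive the result:

* the **axon diameter distribution (ADD)** of external (myelin-inclusive)
  diameters, modelled as a truncated lognormal;
* the **ECS volume fraction** $\alpha$ (porosity), physiologically
  $\approx 0.15$–$0.30$;
* the **ECS width** $d$, the average fluid "atmosphere" around an axon,

$$d = \frac{V_{\mathrm{axon}}}{S_{\mathrm{axon}}}\,\frac{\alpha}{1-\alpha},
  \qquad \frac{V_{\mathrm{axon}}}{S_{\mathrm{axon}}}
       = \frac{E[r^2]}{2\,E[r]}$$

for unit-length circular cylinders of radii $r$. Physiological ECS widths
are a few tens of nanometres.

## The calibrated ADD

Real diameter histograms from electron microscopy are not redistributable,
so the package ships a synthetic-data generator instead of data.
`calibrated_add()` builds a truncated-lognormal ADD whose volume-to-surface
ratio reproduces a requested ECS width at a reference porosity, by
numerically inverting the atmosphere relation for the lognormal location
parameter at fixed coefficient of variation (default 0.35, a typical value
for axon calibres) and truncation bounds (0.1–1.5 µm). The default
calibration — 35 nm at $\alpha = 0.30$ — gives $V/S \approx 81.7$ nm, a mean
external diameter of 0.291 µm, and widths spanning ≈ 18–35 nm over
$\alpha \in [0.18, 0.30]$, growing quasi-linearly with $\alpha$.

What the generator emulates: the right-skewed calibre distribution, the
physiological porosity range, and nanometre-scale ECS widths. What it does
not emulate: axial undulation and non-circular cross-sections, glial
processes, spatial correlations between neighbouring calibres, and — most
importantly — the *absolute* calibre scale of any particular tract, which
is only pinned here through the ECS-width calibration. Since permeability
scales with the square of the geometric scale at fixed shape, passing tests
demonstrate correct mechanics and correct dimensionless behaviour, not a
tract-specific absolute permeability.

## Geometry generation

**Packing.** `advancing_front_pack()` draws all diameters up-front and
inserts them in draw order (this preserves the target ADD in the packed
phase). The first three discs form a mutually tangent triplet; each later
disc is placed tangent to the two discs of a front edge, on the exterior
side of the propagating front, which is maintained as a closed polygon of
disc centres. When a tangent candidate overlaps the previous or next front
vertex, that vertex is buried and leaves the polygon — without this
cleanup the front develops wedge voids and the packing stays ~0.09 looser
in $\alpha$. Edges on which not even the smallest admissible disc fits are
retired permanently. The domain starts from
$\sum \pi r_i^2 / (1 - 0.22)$ (i.e. sized for a packed ECS fraction of
0.22) and grows by 3% per failed placement pass; in practice the cleaned
front packs densely enough that no growth is needed at study sizes and the
packed $\alpha$ equals 0.22.

Every placement keeps a minimum surface gap `gap_tol` (default $10^{-4}$
µm) between discs so the fluid film between neighbours never has zero
width.

**Void filling.** Packed structures stop at $\alpha \approx 0.22$, short of
the physiological minimum. `fill_voids()` rasterises the ECS (pixel-centre
test, default pixel = smallest radius / 10), thins it to a skeleton
(iterative Zhang–Suen thinning), and reads off the branch points — the
locations farthest from all neighbouring discs. Each pass inserts discs at
the branch points in decreasing-clearance order with radius equal to the
exact clearance minus `gap_tol`, accepting an insertion only if its
diameter lies within the ADD truncation bounds; candidates encroached upon
by a same-pass insertion are shrunk accordingly before the bound check.
Passes repeat until the target $\alpha$ is reached or no admissible branch
point remains; the attainable floor with the default ADD is
$\alpha \approx 0.16$. Batch insertion per skeletonisation pass reaches
the same terminal state as one-at-a-time insertion (the floor is defined by
"no pore admits a minimum-diameter disc") at a fraction of the thinning
cost. Filling preferentially adds small discs; the distortion of the ADD is
quantified by `compare_add()` (maximum CDF gap and relative mean change).

**Shrinking.** Any porosity above the current one is reached exactly by
multiplying every radius by $s = \sqrt{(1-\alpha_{\mathrm{target}})/(1-\alpha)}$
with centres fixed. For the full fill-then-shrink chain to
$\alpha = 0.30$, $s \approx 0.915$ — a diameter decrease below 10%, which
leaves the ADD shape intact (a pure scale factor) and opens every
inter-disc gap, making the fluid region meshable.

## Spatial-randomness verification

Model geometries are only comparable with each other (and with tissue) if
their spatial organisation is consistent. Disc centres are tested against
complete spatial randomness (CSR) with Ripley's function

$$R(t) = \lambda^{-1}\sum_i \sum_{j\neq i}
  w(l_i, l_j)^{-1}\,\frac{I(d_{ij} < t)}{N},\qquad
  L(t) = \sqrt{R(t)/\pi},$$

with the isotropic edge correction: $w$ is the fraction of the circle of
radius $d_{ij}$ centred on point $i$ that lies inside the window (closed
form for rectangles). Under CSR, $R = \pi t^2$ and $L$ is a unit-slope
line through the origin; the through-origin least-squares slope of $L(t)$
up to 25% of the window length classifies a pattern as CSR (slope within
0.05 of 1 by default), clustered (above) or inhibited (below). Packed disc
centres classify as CSR with slopes within a few percent of 1 — tangency
makes them slightly inhibited at contact range, but the large-distance
behaviour that matters for homogenisation is Poisson-like. The estimator is
cross-checked in the test suite against the independent implementation in
the `spatial` package.

## The creeping-flow solver

The geometry is embedded in a straight channel with empty entrance and
exit segments (default one channel height each; the pipeline uses shorter
margins since at $Re \ll 1$ the flow develops within a fraction of the
height). Boundary conditions follow the standard permeametry set-up:
uniform inlet velocity (default 0.0024 m/s, giving $Re \approx 10^{-3}$ on
the mean axon diameter), zero gauge pressure at the outlet, no-slip on the
walls and on every disc.

The Stokes equations are discretised on a marker-and-cell (MAC) staggered
grid of square cells: pressures at cell centres, velocities on faces, discs
rasterised by the cell-centre test with no-slip imposed half a cell inside
the solid via mirror ghosts. Fluid pockets not connected to the inlet are
removed. The discrete saddle-point problem is solved by an
augmented-Lagrangian (grad-div) method: the penalised momentum matrix
$A + \gamma D^{\mathsf T} D$ (penalty $\gamma = 10^7 \mu$) is factorised
once with a sparse supernodal Cholesky decomposition and a few multiplier
updates drive the divergence to machine precision, so mass is conserved
cell by cell and through every cross-section. The scheme is exact for
parabolic profiles up to wall-ghost truncation: the empty-channel
permeability matches $H^2/12$ to 0.14% at 40 cells across, and transverse
permeabilities of square cylinder arrays converge to within ~13% of
Gebart's lubrication formula — comparable to that formula's own accuracy at
moderate porosity.

**Sub-grid throats.** After shrinking, formerly tangent discs are separated
by gaps of 5–30 nm — below any affordable cell size for domains tens of
micrometres wide. In two dimensions an unresolved (rasterised-shut) contact
seals the plane, disconnecting the fluid network entirely, whereas a real
ECS remains connected around contacts (the third dimension provides the
path). The solver therefore keeps a one-cell channel open at every disc
pair whose gap is below twice the cell size. At the production resolution
of 12 nm the carved channels have an effective hydraulic width of
$h\sqrt{3} \approx 21$ nm, close to the true gap scale, so the treatment is
nearly unbiased there; at coarser resolutions it progressively widens the
narrowest throats and biases $k$ upward. This treatment replaces the
"minimum 4 cells across the narrowest gap" refinement rule that a
body-fitted mesher would use: uniform Cartesian refinement to 4 cells
across a 10-nm gap over a 14-µm domain would require ~$10^8$ cells, which
is out of scope for a single-workstation solver, and the grid-sensitivity
protocol below is the instrument that quantifies what the chosen resolution
costs.

**Grid sensitivity.** `grid_sensitivity()` re-solves the domain on
successively finer grids and tracks the average interstitial velocity
magnitude along fixed transversal lines in the porous zone (the superficial
average is fixed by mass conservation and cannot discriminate grids),
declaring convergence when line averages change below 0.5% between levels.
Obstacle flows with resolved gaps converge monotonically; for the
white-matter geometries the line averages are still drifting at the
affordable resolutions because the throat population is progressively
resolved, which is why the production resolution is stated explicitly
(12 nm) rather than claimed converged, and why permeability magnitudes
carry a resolution caveat.

## Homogenisation and the RVE

`window_permeability()` applies the Darcy definitions on a square window:
the superficial velocity is the integral of the streamwise velocity over
the fluid part of the window divided by the *total* window area (windows
cutting through discs thus count the solid as zero velocity, which is
exactly the superficial average), and the driving gradient is the
least-squares slope of the fluid-averaged pressure versus the streamwise
coordinate — the pressure decays linearly through a homogeneous porous
zone, supporting the linear fit.

Near the channel walls the porosity is structurally elevated (discs cannot
cross the wall), so fluid channels along the boundary — the channelling
effect. `channelling_profile()` exposes it as a rise of the
length-averaged streamwise velocity next to each wall;
`channelling_bounds()` locates the local minima nearest the walls on the
smoothed profiles and averages their positions over replicates. Windows are
restricted in two complementary ways, and both are applied: only the first
16 of 20 window sizes are used (the size cap), and any window that would
protrude beyond the measured channelling band is skipped with a warning.
With concentric windows the size cap is the binding constraint in
practice — the largest retained window stays 10% of the height clear of
each wall, inside the measured band.

`rve_sweep()` runs $n$ replicate geometries (default 6) of identical
nominal $\alpha$ and ADD, computes $k$ on concentric windows of edge
$j H/20,\ j = 1..16$, and reports per size the replicate mean
$\bar k = \frac1n \sum k_i$ and the sample standard deviation
$\sigma = \sqrt{\frac{1}{n-1}\sum (k_i - \bar k)^2}$. `select_rve()` takes
the smallest window size at which $\bar k$ has reached its plateau (within
5% of the largest retained window) and the replicate coefficient of
variation is at most 5%. A sweep that never settles returns an explicit
no-RVE result rather than an arbitrary pick. For the default study
configuration the replicate scatter at the largest window is a few percent
of the mean, and the selected RVE sits near 23 mean axon diameters — the
natural homogenisation scale of a disordered packing expressed in its own
correlation length.

## Numerical choices and degenerate inputs

* `gap_tol` $= 10^{-4}$ µm: minimum surface gap at packing and filling
  time; geometries with pinched gaps are rejected by `build_flow_domain()`.
* Truncated-lognormal sampling is inverse-CDF, so bounds are honoured
  exactly; degenerate CV = 0 reduces to a single diameter with
  $V/S = D/4$.
* `tangent_disc_centers()` returns two, one (externally tangent
  construction circles) or zero candidates; coincident parents are an
  error.
* Ripley distances are capped below half the shorter window side (the
  rectangle edge-correction closed form is valid there); patterns need at
  least two points.
* The smallest sweep windows can fall entirely inside a disc; they are
  recorded as unusable (NA) and excluded from the statistics.
* Shrinking to the current porosity is the identity; densifying by
  shrinking is an error, as is filling toward a target above the current
  porosity.
* Pressure in enclosed pockets is undefined; such pockets are excluded
  from the fluid domain before assembly.

## Problem sizes used by the tests and the reproduction script

Unit tests run on 200–300-disc packings and coarse flow grids. The
study-scale suite uses six replicate 2000-disc packings
($\approx 14 \times 14$ µm porous zone), the full pack → fill → shrink
chain to $\alpha = 0.30$, and flow solves at 12 nm cells
($\approx 10^6$ unknowns per geometry, solved in ~15 s each by the
factorise-once augmented-Lagrangian scheme). These sizes are the package's
study configuration; larger domains change the answers only through the
window-size cap.

## Known limitations

* **Two-dimensionality.** Transverse flow through parallel cylinders is a
  2-D idealisation; axial flow, undulation and cross-linking glial
  structure are absent. The contact-gap pathology discussed above is
  intrinsically 2-D.
* **Scale sensitivity.** $k$ scales as the square of the calibre scale at
  fixed dimensionless shape. The ADD here is calibrated to ECS width, so
  dimensionless results (permeability per squared mean diameter, RVE in
  units of mean diameter) are the robust outputs; absolute permeabilities
  inherit the calibration's scale choice and the throat-resolution caveat.
* **Resolution bias.** Unresolved throats are opened at the grid scale;
  $k$ from coarse grids is biased by this smearing. Production figures are
  quoted at the stated 12-nm resolution.
* **Stationary rigid solid.** No poroelastic coupling, osmotic effects or
  axon deformation; the solid is frozen, consistent with quasi-static
  permeametry.
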