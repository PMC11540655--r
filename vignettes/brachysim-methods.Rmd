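---
title: "Simulating needle insertion in prostate brachytherapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating needle insertion in prostate brachytherapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

High-dose-rate brachytherapy of the prostate implants two thin anchor
needles followed by 15–20 catheter-needles through a transperineal template.
As the needles puncture and traverse the gland, the soft tissue displaces by
millimetres — enough to matter against the accuracy targets of dose
delivery. brachysim is a desk-scale simulator of that deformation: a
meshless total-Lagrangian explicit-dynamics (MTLED) solver over a
near-incompressible Neo-Hookean material, a kinematic model of sequential
needle insertion with regional stiffening, and an evaluation layer
(voxelisation, Dice similarity, in-plane displacement statistics) mirroring
the way deformation is quantified on short-axis ultrasound.

This vignette explains the models, the numerical choices behind them, and
what the synthetic phantom does and does not emulate.

## The mechanical model

Tissue occupies a reference configuration $\Omega_0$ (the pre-insertion
anatomy). Displacements $u(X)$ define the deformation gradient
$F = I + \nabla_0 u$ with volume ratio $J = \det F$. The strain energy is
the decoupled (J-split) near-incompressible Neo-Hookean form

$$W(F) = \frac{\mu}{2}\left(J^{-2/3}\,\mathrm{tr}(F^TF) - 3\right)
       + \frac{\kappa}{2}(J-1)^2,$$

with first Piola–Kirchhoff stress $P = \partial W/\partial F$. `W` is zero
exactly at any rotation; the volumetric term penalises volume change with
bulk modulus $\kappa$. Default materials are mid-range elastography values:
prostate $E = 25$ kPa, surrounding tissue $E = 10$ kPa, both at
$\nu = 0.49$ ($\kappa/\mu \approx 50$) and density $1000\ \mathrm{kg/m^3}$.
Published elastography ranges for prostate tissue span roughly 10–60 kPa;
results here are reported as qualitative and the constitutive constants are
config-exposed.

## Meshless discretisation

The domain is a regular node lattice (spacing $h$). Shape functions are
modified moving least squares (MMLS): a quadratic basis
$[1, x, y, z, x^2, y^2, z^2, xy, yz, zx]$, shifted to the evaluation point
and scaled by the support radius, fitted in weighted least squares with a
diagonal penalty $\mu_p = 10^{-6}\,\mathrm{tr}(A)/10$ on the six quadratic
coefficients. The penalty keeps the moment matrix invertible wherever the
support only sustains linear reproduction, while leaving quadratic fields
reproduced to better than $10^{-6}$ where supports are rich. The weight
kernel is regularised-singular, $w(r) = ((r/h)^2 + 10^{-8})^{-1}$, which
makes the approximation interpolating at the nodes to about $10^{-6}$ —
essential, because Dirichlet and prescribed-motion conditions are imposed
directly on nodal parameters. Supports are radius-2$h$ balls, enlarged
locally by factors of 1.25 (at most five times) wherever fewer than 11
nodes are found.

Shape-function gradients are exact derivatives of the full evaluation
(including the trace-dependent penalty), computed by complex-step
differentiation; the test suite cross-checks them against central finite
differences to $10^{-5}$ and against an independently coded dense
normal-equations solve.

### Quadrature

Integration points live in the background lattice cells. Single-point
cell-centre quadrature — the simplest textbook choice — turned out to leave
near-zero-energy modes in the Galerkin stiffness (the well-known rank
deficiency of nodal/low-order quadrature in element-free methods). Those
modes decay so slowly under dynamic relaxation that equilibrium tolerances
below $\sim 10^{-2}$ mm become unreachable. The default is therefore a
degree-2-exact four-point tetrahedral rule per cell (points at the cell
centre $\pm(h/4, h/4, h/4)$ with alternating signs, weight $h^3/4$), which
removes the spurious modes at four times the assembly cost of the
single-point rule; with it the affine patch test is satisfied to machine
precision in the consistent interior and a 20% uniaxial compression matches
the closed-form Neo-Hookean solution to $3\times10^{-4}$. `quadrature = 1`
and `8` remain available.

Quadrature consistency deserves one caveat: Gauss-type background
quadrature in element-free Galerkin methods is integration-inconsistent in
a boundary band about one support radius deep (the quadrature of
$\nabla\phi$ does not exactly balance the missing surface term). The patch
test in the acceptance suite therefore prescribes the affine field over a
band two support radii deep; the interior then reproduces the field to
$\sim10^{-11}$. Prescribing only the outermost node layer leaves an honest
0.5–1% interior deviation at desk resolutions.

### Mass, time step and dynamic relaxation

Nodal masses are row-sum lumped, $m_a = \sum w\,\rho\,\phi_a$ — exact
($\rho h^3$) at interior nodes and exactly mass-conserving. The cardinal
functions of the interpolating MMLS integrate slightly negative at the
block corners (a few percent of $\rho h^3$); such entries are floored at a
tenth of the median mass with the excess removed proportionally elsewhere,
which repairs positivity without touching regular nodes.

The explicit time step follows the CFL-type bound
$\Delta t = s\,h/c_{\max}$, $c = \sqrt{(\kappa + 4\mu/3)/\rho}$, safety
$s = 0.5$. Quasi-static solutions are obtained by damped central-difference
stepping (mass-proportional damping) until the maximum nodal displacement
increment over a 50-step window falls below tolerance. The damping
coefficient is adapted each window to $\alpha = 2\hat\omega$, where
$\hat\omega^2 = \Delta u^T \Delta f / \Delta u^T M \Delta u$ is the
Rayleigh-quotient estimate of the slowest active mode — the standard
dynamic-relaxation tuning, which handles the wide frequency spread between
the soft gland and the 30×-stiffened regions. A fixed damping value can be
supplied instead (the dynamic-accuracy tests use it). During insertion,
stiffened regions also receive selective mass scaling (nodal mass scaled by
the local stiffening factor), which keeps the local wave speed and hence
the stable time step at its unstiffened value; this is legitimate for
quasi-static analyses only, and `stable_timestep()` itself always reports
the physical (unscaled) bound.

## The insertion procedure

Needles are kinematic paths, not deformable bodies. Each needle advances in
$\Delta d = 2$ mm increments. At every increment, material points near the
advancing tip receive a prescribed displacement increment
$w\,\Delta d\,\hat d$ along the insertion direction, where $w$ falls from 1
on the needle surface to 0 at the influence radius $R_{\mathrm{inf}} = 3$
mm (linear decay by default; exponential available). The weight is
evaluated on the *trailing tip segment* of the increment — from one
influence radius behind the previous tip position to the new tip — so
tissue is carried while the tip passes and released once it has moved on.
Driving the full penetrated path instead makes every shaft-adjacent node
ratchet forward on all later increments, which accumulates unbounded axial
drag and, at desk resolution, collapses elements against the stiffened
distal tissue.

The drive is kinematic and overrides the material: stiffened regions near
the tip move with it like all other points. (Driving only soft material
and holding stiff regions in place was tried and abandoned — the
differential prescribed motion shears the narrow gaps between driven and
held tissue until elements invert.) Stiffening instead governs the free
elastic response, which is what keeps placed-catheter regions from being
carried far by later insertions.

After the increment is relaxed, the temporary constraints are released.
Nodes that have entered the needle bore ($r \le$ needle radius) are
captured permanently for the rest of the procedure: the needle occupies the
hole. Their capture position is the post-release equilibrium plus a
retained fraction $\beta$ of the tip-passage drive
(`bore_retention`, default 0.5). The two limits are instructive: $\beta=1$
(full stick) freezes each node at its driven peak, so successive captures
ride on the elastic field of the previous ones and the bore column drags
many millimetres; $\beta=0$ (full slip) lets the tissue slide off the shaft
entirely and almost no residual deformation survives, contradicting the
non-negligible gland deformation observed on post-insertion imaging. The
partial-slip default lies between these limits; it is a config-exposed
modelling parameter, not a fitted constant. A capture is accepted only if
it leaves the configuration with a healthy Jacobian margin
($J \gtrsim 0.1$); otherwise the retention falls back toward full slip —
tissue slips along the shaft rather than being jammed to collapse.

Three robustness nets surround the increments: prescribed targets are
ramped linearly over the first 100 relaxation steps (instantaneous jumps
next to pre-strained stiff regions can invert elements outright); an
increment that still inverts an element is retried at one half down to one
eighth of the advance; and every relaxation validates its final state
against element inversion before it is accepted. Increments relax under a
bounded effort (150 steps by default) and every needle ends with a full
relaxation to the solver tolerance (1e-3 mm), so snapshots are
equilibrated states.

### Stiffening events

After both anchor needles reach depth, surrounding (non-prostate) tissue
distal to the anchors' tip plane is stiffened 30-fold (shear and bulk
moduli alike; density untouched) — the model of the anchors' clinical
purpose, preventing distal displacement of the gland during catheter
insertion. After each catheter reaches depth, a 2-mm-radius sleeve around
its path is likewise stiffened 30-fold. Stiffening composes by maximum —
a point behind the anchors and beside two catheters is 30× stiffer, never
$30^3$ — and is idempotent.

The `anchor_stiffening = FALSE` flag reruns the identical procedure without
the anchor effect, reproducing the anchors-on/anchors-off comparison; the
ordering of catheters is likewise a config (`alternate_lb_rt` starts
left-bottom then right-top alternating inward; `alternate_rb_lb` sweeps
each template row from the right starting at the bottom).

## The synthetic phantom

Patient imaging is replaced by `generate_phantom()`: an ellipsoidal
prostate (default semi-axes 20 × 15 × 15 mm, i.e. a 40-mm gland span)
centred in a softer cuboidal block with a traction-free transperineal face
at the proximal end of the insertion axis and all other faces fixed. The
template is a square 5-mm-pitch grid centred on the prostate silhouette,
with 2 anchors adjacent to the midline and 17 catheters on holes covering
the silhouette; anchors (radius 0.5 mm) stop at two thirds of the gland
extent, catheters (radius 0.75 mm) traverse to 2 mm past the distal
prostate boundary along their own path (the gland is shallower
off-centre). The template centre snaps to the node lattice so that holes
coincide with node columns whenever the pitch is a multiple of the nodal
spacing — on coarse lattices this guarantees that each needle bore actually
contains nodes to capture.

What the phantom does *not* emulate: patient-specific gland shape and
boundary conditions (probe indentation, pelvic anatomy), needle deflection
and insertion-force physics, radial hole-opening around the shaft, and the
image-derived entry trajectories of a real plan (all needles here are
parallel to the insertion axis). Consequently the in-plane deformation of
the phantom arises purely from incompressibility and the interplay of
captured bores and stiffened regions; passing tests demonstrate internal
consistency of the solver and procedure logic at clinically plausible
magnitudes, not patient-level predictive accuracy. Real segmentations can
be substituted through `domain_from_mask()` (NIfTI or MetaImage input).

## Evaluation

`voxelize_region()` reconstructs the deformed prostate surface as the
convex supporting-halfspace envelope of the deformed prostate nodes over a
quasi-uniform direction set (~4000 Fibonacci-sphere directions), expanded
outward by a lattice-sampling correction: along any direction the
outermost node underestimates the support by roughly
$h^{3/2}/\sqrt{2R}$ (the tangency cap of width $\sqrt{2Rt}$ must be wide
enough to contain a lattice point), evaluated with $R$ as the
equivalent-sphere radius. On the default phantom this reproduces the
analytic ellipsoid volume to under 1% at 1-mm voxels. The prostate is
nearly convex, so a convex envelope is an adequate reconstruction at nodal
accuracy; strongly concave shapes would need a different surface method.

`dice()` resamples both masks (nearest neighbour) onto a common cubic grid
aligned with the finer operand — the comparison is exact voxel counting
whenever the operands share a grid — and returns
$D = 2|A\cap B|/(|A|+|B|)$. `inplane_displacement_stats()` projects
prostate-node displacements onto the plane orthogonal to the insertion
axis (the short-axis view of transrectal ultrasound) and reports
mean ± sd and maximum.

## Problem sizes and tolerances

The verification problems run at deliberate desk scale: shape-function
sweeps on 500-node random clouds and a ~2200-node phantom; statics on a
~1400-node bar (uniaxial, in 1 and 10 load increments) and a 2200-node
patch block; full 2-anchor + 17-catheter procedures on a ~2900-node phantom
(5-mm lattice, the coarsest spacing that resolves the gland at three nodes
per semi-axis). Relaxation tolerances are $10^{-6}$–$10^{-7}$ mm for the
statics oracles and $10^{-3}$ mm for procedure runs. Convergence of the
quadrature volume and the voxeliser is checked across two lattice spacings
(5 and 2 mm).

## Known limitations

* Needles are rigid, parallel kinematic paths; insertion forces, needle
  bending and radial hole-opening are not modelled.
* The bore-retention factor summarises shaft–tissue adhesion in a single
  dimensionless number; the true tribology is unknown and the factor is
  deliberately exposed.
* The convex-envelope voxeliser smooths concavities; for the near-convex
  prostate this is a sub-voxel effect, but it would not suit arbitrary
  organs.
* Anisotropy, viscoelasticity and alternative hyperelastic laws
  (Mooney–Rivlin, Ogden) are out of scope.
* The procedure outcome is insertion-history dependent: bore nodes are
  captured at equilibria that depend on which sleeves are already
  stiffened, so the two built-in catheter orderings differ by a mean
  prostate-node displacement of roughly 1.5–2 mm at the 5-mm desk lattice
  (mutual final-shape Dice ≈ 0.93). The effect shrinks with lattice and
  increment refinement but is a real property of the capture model.
* The quadrature is integration-inconsistent in the boundary band (as in
  any Gauss-type EFG); essential boundary conditions are therefore imposed
  over bands, and reported fields are most accurate away from the block
  faces.
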