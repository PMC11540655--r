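# brachysim

Prostate tissue deforms by millimetres while the needles of high-dose-rate
brachytherapy (HDR-BRT) are inserted — two thin *anchor needles* first, to
steady the gland, then 15–20 *catheter-needles* that will carry the
radioactive source. That deformation shifts the target against the
pre-operative plan. brachysim simulates it at desk scale, for researchers
in computational biomechanics and medical physics who want a transparent,
fully scriptable model of the whole multi-needle procedure.

## What is inside

* **Meshless solver** — element-free Galerkin discretisation on a regular
  node cloud with interpolating *modified moving least squares* (MMLS)
  shape functions (quadratic basis, penalised quadratic coefficients,
  regularised-singular weights), total-Lagrangian assembly and damped
  central-difference explicit dynamics driven to quasi-static equilibrium
  by adaptive dynamic relaxation.
* **Constitutive model** — near-incompressible Neo-Hookean energy
  `W = mu/2 (J^{-2/3} tr(F'F) - 3) + kappa/2 (J - 1)^2`, with a
  multiplicative stiffening field: after the anchors are placed the tissue
  behind their tips becomes ~30x stiffer, and each placed catheter leaves a
  ~30x stiffer sleeve around its path.
* **Kinematic insertion** — needles are paths, advanced in 2-mm
  increments; material points near the tip are carried with it (weight
  falling from 1 at the needle surface to 0 at a 3-mm influence radius)
  and released after the tip passes; nodes swallowed by the bore stay
  constrained while the needle is present.
* **Synthetic phantom** — an ellipsoidal prostate (40 x 30 x 30 mm by
  default) in a softer block, with a transperineal template grid, so every
  stage is testable without any imaging data; real binary segmentations
  (NIfTI / MetaImage) can be substituted via `domain_from_mask()`.
* **Evaluation** — deformed-prostate voxelisation on a common cubic grid,
  Dice similarity, in-plane displacement statistics (the short-axis
  ultrasound view), broom-style `tidy()`/`glance()` and `autoplot()`
  methods, VTK export for ParaView.

## A worked example

```r
library(brachysim)

# a coarse phantom: 40 x 30 x 30 mm gland in a 60 mm block, 5 mm lattice
domain <- generate_phantom(phantom_spec(prostate_semi_axes = c(20, 15, 15),
                                        block_dims = c(60, 60, 50),
                                        nodal_spacing = 5))
plan <- generate_needle_plan(domain)   # 2 anchors + 17 catheters
result <- run_procedure(domain, plan)  # a few minutes on one core

glance(result)
inplane_displacement_stats(result$state, domain)
compare_snapshots(result, c("initial", "C17"))
```

On this phantom the run prints (numbers from an actual session):

```
> glance(result)
  n_events n_snapshots all_converged n_failed total_iterations ...
1       19          20 TRUE                 0            91600
> inplane_displacement_stats(result$state, domain)
  mean_mm sd_mm max_mm n_nodes
1   0.652 0.512   2.65     141
> compare_snapshots(result, c("initial", "C17"))
[1] 0.812
```

meaning: all 19 insertion events completed and equilibrated, the prostate
nodes moved on average ~0.7 mm (max ~2.7 mm) within the short-axis plane,
and the gland's final shape overlaps its initial shape with a Dice
coefficient of about 0.81 — non-negligible deformation concentrated around
the needle tracks and the distal gland, on the millimetre scale reported
for real procedures.

`autoplot(result)` plots the per-event displacement progression;
`write_procedure_vtk(result, "out/")` exports the snapshot series for
ParaView. A thin command-line front end lives in `inst/cli/brachysim.R`
(`phantom`, `run`, `ablate-anchors`, `reorder`, `dice` subcommands over
YAML configs).

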