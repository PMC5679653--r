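---
title: "From 4-D image sequences to ventricular hemodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 4-D image sequences to ventricular hemodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hemoflow turns a time-resolved image sequence of a beating embryonic
ventricle into wall-resolved hemodynamic force estimates.  The pipeline has
five stages: (1) a synthetic phantom generator standing in for light-sheet
data, (2) deformable B-spline image registration that extracts the wall
motion, (3) segmentation and meshing of the cavity, (4) an arbitrary
Lagrangian-Eulerian (ALE) finite-element solution of the incompressible
Navier-Stokes equations in the moving cavity, and (5) the mechanobiologic
metrics: wall shear stress (WSS), its area and space-time averages, the
oscillatory shear index (OSI), kinetic energy density, viscous dissipation,
and the contractility indices (stroke volume SV, ejection fraction EF).
This vignette records the models, the tunable parameters and their
defaults, and the numerical decisions, so that every number the package
produces can be traced to an explicit choice.

All internal physics uses CGS units (g, cm, s).  Image voxel spacing is
given in micrometres and converted on load; registration operates in voxel
units.

## The phantom: what it emulates and what it does not

Real light-sheet acquisitions of embryonic zebrafish hearts are stacks of
roughly 512 x 512 x 70 voxels at 0.65 x 0.65 x 2 um with on the order of
100 frames per cardiac cycle.  Such data are not redistributable, so the
package ships a generator whose output has the same *structure*: a bright
myocardial wall (a smooth intensity ramp at least two voxels thick, so
threshold and level-set stages see realistic gradients) around a dark
lumen, pulsing radially as

    R(direction, t) = R0(direction) * (1 + a * sin(2*pi*t/T_c)),

optionally with trabecula-like corrugations `R0 = r0 (1 + b cos(k theta))`.
Because the motion is an analytic radial scaling, the generator knows the
exact displacement field, cavity volume curve `V(t) = V0 * lambda(t)^d`,
and hence EDV, ESV, SV and EF; for amplitude `a`,
`EF = 100 (1 - ((1-a)/(1+a))^d)`, which for the default a = 0.2 in 3-D is
70.37%.  Gaussian intensity noise is optional and seeded; identical specs
and seeds give bit-identical sequences.

Desk-scale defaults are 96 x 96 voxels (2-D) or 64 x 64 x 48 (3-D) at
0.65 um in-plane spacing, 20 frames per cycle, amplitude 0.2, period
0.4 s, wall thickness 3 voxels, noise sigma 0.02.  These sizes were chosen
so a full analysis runs on one desktop core; the grid and frame counts
scale up to the acquisition scale without code changes.

The phantom deliberately does **not** model the optics (no point-spread
function, no attenuation), the slice-by-slice asynchronous acquisition and
its synchronization, myocardial texture, or non-radial (twisting,
shearing) wall motion.  Tests passing on the phantom therefore demonstrate
the correctness of the numerics and the pipeline plumbing under known
ground truth — not robustness to every artefact of real microscopy.  The
corrugated shapes exist precisely because a perfectly circular wall leaves
the tangential component of the motion unobservable (the aperture
problem); on real, textured images the same role is played by intensity
structure.

## Registration and motion tracking

Registration minimizes

    E_obj = E_sim + lambda * E_reg,

where `E_sim` is the mean squared voxelwise difference between the fixed
image and the warped moving image (SSD), and the transform is a free-form
deformation: displacements of a control-point lattice with uniform knot
spacing (default 5 px) interpolated by uniform cubic B-splines, giving a
C2 map that is the identity at zero coefficients.  `E_reg` is half the
squared norm of the displacement-field gradient, evaluated by forward
differences on the voxel grid.  We normalize `E_reg` per voxel, exactly as
`E_sim` is normalized: both terms are then intensity- and size-free
densities, and the trade-off weight lambda = 0.1 is dimensionless and
transfers across image sizes.  (With an unnormalized integral the same
lambda would over-regularize by a factor of the voxel count.)

The optimizer is plain gradient descent with a backtracking line search:
the step halves on an objective increase, is accepted on a decrease, and
grows by 1.2x after acceptance; the first trial step moves the largest
coefficient by 0.4 px.  A level converges when the relative objective
change drops below `tol` (default 1e-8) or after `max_iters` (200)
accepted steps.  The multiresolution schedule downsamples the image by 2
per level and refines the control lattice by 2 per level (exact dyadic
B-spline subdivision), coarse to fine, 4 levels by default; levels whose
image would drop below ~12 px are skipped.

Motion tracking registers successive frame pairs around the cycle starting
from the template (mid-diastolic) frame and morphs the segmented surface
by *evaluating* each pairwise transform at the current vertex positions —
composing maps rather than adding displacement fields, which avoids
resampling error.  Pairs after the first are warm-started from the
previous transform and optimized single-level: adjacent frames differ by a
fraction of the full deformation, and the warm start already carries the
coarse-scale part.  The template frame defaults to the frame whose
quick-segmented volume is nearest (EDV+ESV)/2.  Vertices that drift
marginally outside the lattice support are evaluated with the support
clamped (and counted in a warning) rather than failing; the cycle-closure
error — the mean distance between the template surface and the same
surface morphed through all M registrations — is reported as a tracking
quality diagnostic.

On the default beating-disc phantom the tracked cavity volume stays within
a few percent of the analytic truth over the full cycle, well inside the
10% max / 8% mean budget that the equivalent validation against manual
segmentation established for the imaging workflow this package models.

## Segmentation and geometry

The template frame is thresholded (Otsu on the intensity histogram unless
a threshold is given); the cavity is the largest dark region fully
enclosed by the wall.  The boundary is then refined by a morphological
active contour: voxels in a one-voxel shell switch sides according to
whether their intensity is closer to the inside mean or to the mean of a
narrow outside band, followed by alternating morphological opening and
closing as an unbiased curvature regularization (50 iterations, smoothing
weight 1 by default).  This is a deterministic, dependency-free stand-in
for interactive level-set advection with the same contract: an
edge-conforming refinement of a threshold mask.

Surface extraction is dimension-specific: in 2-D, the 0.5-isocontour of
the mask; in 3-D, voxel-face extraction followed by Taubin (non-shrinking
lambda/mu) smoothing.  Both are then resampled isotropically at a target
edge length (default 3 voxels in the pipeline) as a radius function about
the enclosed centroid — a uniform-angle polygon in 2-D, a subdivided
icosahedron with direction-averaged radii in 3-D.  This replaces
interactive mesh clean-up with a reproducible operation and requires the
cavity to be star-shaped about its centroid, which ventricle-like shapes
are; the mesher verifies the property and fails with a diagnostic
otherwise.

Inlet and outlet orifices are opened at marker points: facets within the
orifice radius (default 30% of the mean centre-to-boundary distance) are
removed, the rim is extruded outward by a collar of twice the mean edge
length, and the opening is capped (a planar fan in 3-D; in 2-D the cap
segment is subdivided so it carries interior nodes — the traction-free
boundary condition needs free test functions on the cap, otherwise the
pressure level is numerically indeterminate).  Caps and collars carry
labels (`inlet_cap`, `inlet_extrusion`, ...) that propagate through
meshing to the boundary conditions and are excluded from the shear
metrics.

The volume mesh shrinks the surface towards the centroid in geometrically
graded shells (ratio set by the edge length, so the element aspect ratio
stays bounded towards the centre), connects consecutive shells by
consistently split prisms (the classical index-based prism-to-3-tets
decomposition, which guarantees conforming diagonals between neighbours),
and joins the innermost shell to the centre by a fan.  The outer shell
*is* the labeled surface: boundary conformity is exact, and remeshing a
deformed cavity preserves the boundary vertices and facets — which also
means per-facet quantities (WSS, OSI) keep their identity across remeshes.

## The flow solver

The fluid is incompressible and Newtonian with density 1.06 g/cm^3 and
viscosity 4 cP (0.04 g/(cm s)); `viscosity_scale = 0.25` reproduces the
reduced-hematocrit variant.  The weak form is the standard ALE Galerkin
form in the moving domain (convective velocity `v - vhat`, with `vhat` the
mesh velocity), discretized with equal-order P1-P1 elements.  Equal-order
pairs are not inf-sup stable, so the residual-based variational multiscale
(VMS) terms are added: SUPG-like convective stabilization, PSPG-like
pressure stabilization, grad-div coupling, and the least-squares term on
the momentum residual, with the element metric tensor
`G_ij = sum_k dxi_k/dx_i dxi_k/dx_j` and

    tau_M = (C_t/dt^2 + (v-vhat).G(v-vhat) + C_I (mu/rho)^2 G:G)^(-1/2)
    tau_C = (tau_M g.g)^(-1)
    tau_B = (tau_M r_M . G tau_M r_M)^(-1/2)

`C_t = 4` and `C_I = 36` are the standard linear-element values.  `tau_B`
divides by the residual norm and is therefore applied only when
`|tau_M r_M|` exceeds 1e-12.  A one-point-per-vertex degree-2 simplex
quadrature (3 points on triangles, 4 on tetrahedra) integrates all terms.

Time integration is the second-order generalized-alpha method for
first-order systems with spectral radius `rho_inf = 0.5`; the nonlinear
step uses modified Newton (the tangent omits the derivatives of the
stabilization scales) to a relative residual of 1e-4, at most 10
iterations.  A verification test evaluates the assembled tangent at a
state where the omitted terms vanish identically (uniform `v = vhat`,
zero momentum residual) and confirms agreement with a finite-difference
Jacobian to 1e-6.

Linear systems can be solved by restarted GMRES (restart 200, tolerance
1e-6) with Jacobi preconditioning, or by a sparse direct factorization
with symmetric diagonal equilibration — necessary because CGS units at
micrometre geometry put momentum and continuity rows ten orders of
magnitude apart.  At desk scale the implicit steps are extremely stiff
(viscous Courant numbers of order 10^3), where a diagonal preconditioner
converges slowly; the cycle driver therefore defaults to the direct
solver, which produces the same solution (the test suite checks GMRES and
the direct path against each other), and GMRES remains the default of
`solver_config()` for the verification problems.

Mesh motion is linear elastostatics with Jacobian-based stiffening: each
element's stiffness is scaled by `(Vbar/V_e)^chi` with chi = 1, so small
elements resist distortion.  The operator is assembled and factorized once
per (re)mesh on the reference configuration and reused every step; the
coupling is quasi-direct — the mesh solve precedes the fluid solve within
the step, lagging it by one nonlinear iteration.  The mesh velocity is
`vhat = (x(t+dt) - x(t))/dt`, the exact time derivative of the linearly
interpolated frame positions; together with prescribing the wall fluid
velocity as the same difference quotient this keeps the wall kinematics
and the ALE convective velocity consistent, and a uniform free stream is
preserved to solver tolerance under arbitrary interior mesh motion.

Boundary conditions switch with the cardiac phase: the volume curve is
piecewise linear in time, so dV/dt is piecewise constant per frame
interval; a positive rate (filling, diastole) gives a traction-free inlet
with backflow stabilization (`beta = 0.3`: the traction gains
`-rho*beta*(v.n)_- v`, a pure sink for re-entering flow) and a closed,
zero-velocity outlet, and a negative rate reverses the two.  An exactly
zero rate is assigned to the upcoming phase.  Remeshing is triggered by a
non-positive element Jacobian, by a scaled-Jacobian quality below 0.05, or
by accumulated boundary travel exceeding one target edge length since the
last remesh — the third trigger exists because a pure radial scaling
leaves the scaled Jacobian unchanged and would otherwise never remesh a
strongly pulsing cavity; nodal fields transfer by element location and
barycentric weights, with nearest-element projection (and a logged count)
for stragglers.

Each output step logs a global mass check: the net boundary flux of the
fluid velocity, `|closed-surface integral of v.n|`, normalized by the
larger of the open-cap flux and the wall-swept flux, must stay below 1e-2.
(The raw difference `integral of (v - vhat).n` equals -dV/dt identically
on a moving domain and is not a useful residual; the implemented check is
the discrete statement that inflow balances wall sweep.)  The run reports
Reynolds number `Re = rho U_p D_i / mu` and Courant number
`CFL = U_p dt / dx` from the peak open-cap mean velocity `U_p` and the
inflow annulus diameter `D_i`.

Simulations run 4 cycles from rest; the first cycle absorbs the start-up
transient and the last 3 are phase-averaged for analysis.

## Metrics

WSS is the tangential viscous traction of the P1 velocity gradient of the
facet's adjacent element: `tau_n = 2 mu (grad^s v) n`,
`tau_w = tau_n - (tau_n.n) n`, so tangency holds exactly by construction.
AAWSS(t) is the instantaneous-area-weighted mean of `|tau_w|` over wall
facets; collars and caps are always excluded.  The space-time average AWSS
is defined here as the T_c-average (trapezoid rule) of AAWSS(t): the
underlying space-time integral leaves open whether the area normalization
is instantaneous or fixed, and the instantaneous choice makes AWSS the
time average of a well-defined instantaneous quantity.  OSI per facet is
`0.5 (1 - |integral tau_w dt| / integral |tau_w| dt)` with the same
trapezoid quadrature in numerator and denominator (an identically zero
history gives 0 by convention); the reported map is computed on the
phase-averaged shear history, with per-cycle values emitted as
diagnostics.  Kinetic energy density and viscous dissipation rate are the
volume averages of `rho |v|^2 / 2` (exact P1 mass-matrix quadrature) and
`mu (grad^s v : grad^s v)` (element-constant gradients).  EDV and ESV are
the volume-curve extremes, `SV = EDV - ESV`, `EF = 100 SV/EDV`.  The
cardiac-work-per-volume estimate converts the literature pressure values
(0.47 and 0.08 mmHg at 5 days post fertilization) to CGS,
`(p_sys - p_dia) * 1333.22 ~ 520 g/(cm s^2)`, and serves as the scale
against which the flow energy densities are compared.

## Problem sizes, tolerances and verification scope

The shipped tests and the default pipeline use desk-scale sizes chosen as
the smallest problems on which each property is cleanly measurable:
registration fixtures at 96 x 96 with a 4 px synthetic warp; Taylor-Green
convergence sweeps on 8/16/32-cell meshes of [0, pi]^2 with the time step
scaled with h (observed velocity L2 orders ~2.0) and a Richardson sweep in
dt on a fixed 24-cell mesh (observed order ~2.0); plane Poiseuille wall
shear on a 12 x 48 channel evaluated away from the do-nothing outlet
(within ~2.3% of 4 mu U / H); and 2- to 4-cycle moving-domain runs of the
beating-disc phantom with 20 frames per cycle and 2 solver steps per frame
interval.  The 3-D path (phantom, segmentation, capped surfaces, tet
meshing, metrics) is exercised on 48^3-scale spheres; full 3-D cycle
simulations use the same dimension-generic code but are outside the
default test budget.

Known limitations: wall motion is prescribed (no fluid-structure
interaction, no wall strains); only pressure gradients are meaningful, not
absolute pressure; the rheology is Newtonian; the mesher requires
star-shaped cavities; and the 2-D desk configuration treats "volume" as
area, so its absolute magnitudes are not physiological — it is the
dimension-generic numerics, not the 2-D magnitudes, that carry over to
3-D.
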