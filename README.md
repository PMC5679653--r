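# hemoflow

Ventricular hemodynamics from 4-D image sequences.

Blood flow and the mechanical forces it exerts on the endocardium —
wall shear stress above all — help regulate the development of the
embryonic heart, in particular the formation of trabeculae.  Measuring
those forces in a beating, hundred-micrometre ventricle is not possible
directly; they must be computed.  hemoflow implements the complete
image-to-forces workflow for developmental cardiac imaging at desk scale:

1. **Wall motion from images.**  The cavity is segmented once, at a
   mid-diastolic template frame; the motion of every other frame is
   recovered by intensity-based non-rigid registration — a cubic B-spline
   free-form deformation `T(x) = x + u(x)` minimizing
   `E_obj = E_sim + λ E_reg`, with `E_sim` the mean squared intensity
   difference (SSD) and `E_reg` the squared norm of the displacement
   gradient, optimized by multiresolution gradient descent
   (λ = 0.1, knot spacing 5 px, tolerance 1e-8, 4 levels).  The template
   surface is morphed through the sequential pairwise transforms.
2. **Moving-domain flow.**  The incompressible Navier–Stokes equations
   are solved in the moving cavity in arbitrary Lagrangian–Eulerian (ALE)
   form with P1-P1 finite elements stabilized by the residual-based
   variational multiscale (VMS) method, generalized-α time integration,
   elastostatic mesh motion with Jacobian-based stiffening, dynamic
   remeshing with barycentric field transfer, backflow stabilization
   (β = 0.3), and valve-mimicking boundary conditions that switch with
   the sign of dV/dt (blood: ρ = 1.06 g/cm³, μ = 4 cP).
3. **Force metrics.**  Wall shear stress
   `τ_w = 2μ(∇ˢv)n − (2μ(∇ˢv)n·n)n`, its area average AAWSS(t) and
   space-time average AWSS, the oscillatory shear index
   `OSI = ½(1 − |∫τ_w dt| / ∫|τ_w| dt) ∈ [0, 0.5]`, volume-averaged
   kinetic energy density and viscous dissipation rate, and the
   contractility indices EDV, ESV, SV = EDV − ESV, EF = 100·SV/EDV.
   Four cycles are simulated and the last three phase-averaged.

Because real light-sheet data are not redistributable, the package
includes a first-class synthetic phantom: a bright-walled, dark-lumen
beating cavity (optionally with trabecula-like corrugations) with known
analytic wall motion, volume curve and ejection fraction, plus
manufactured flow cases (plane Poiseuille, decaying Taylor–Green vortex,
uniform stream) for solver verification.  Every stage is validated
against these ground truths in the test suite.

## Worked example

```r
library(hemoflow)

spec    <- phantom_spec("disc", pulsation_amplitude = 0.2,
                        noise_sigma = 0.02, seed = 1)
phantom <- generate_beating_phantom(spec)

tmpl <- select_template_frame(phantom$seq)
mask <- segment_template(phantom$seq$frames[[tmpl]])
h    <- 3 * min(spec$spacing_um) * 1e-4       # 3-voxel mesh edge, cm
surf <- extract_surface(mask, spec$spacing_um,
                        phantom$seq$orifice_markers, target_edge = h)
mesh <- mesh_interior(surf, target_edge = h)

motion <- track_motion(phantom$seq, surf, tmpl)
series <- run_cycle_simulation(motion, mesh,
                               solver_config(dt = spec$period_s / 40,
                                             n_cycles = 4,
                                             linear_solver = "direct"))
summ <- summarize_hemodynamics(series)
summ
#> hemodynamic_summary
#>   EDV 1.839e-05  ESV 8.55e-06  SV 9.839e-06  EF 53.5%
#>   AWSS 0.2528 g/(cm s^2); mean wall OSI 0.117
#>   peak KE 0.0002629; peak dissipation 66.29; work/volume 520 g/(cm s^2)
#>   Re 0.00173, CFL 2.92, 16 remeshes
```

Reading the numbers: the tracked cavity "volume" (an area in this 2-D
desk configuration, cm²) swings between ESV = 8.55e-06 and
EDV = 1.84e-05, an ejection fraction of 53.5% against the 2-D analytic
value of 55.6% for amplitude 0.2 — the difference is the registration
and segmentation error budget, and the capped surface includes the small
artificial inflow/outflow collars.  AWSS is the space-time averaged wall
shear magnitude over the wall proper (collars and caps excluded); the
mean OSI of 0.117 says the shear direction partially reverses over the
cycle, as it must in a chamber that fills and ejects through neighbouring
orifices.  The work-per-volume figure, 520 g/(cm s²), is the
printed-pressure estimate `(0.47 − 0.08) mmHg × 1333.22` against which
the flow kinetic-energy scale is compared.  `autoplot(summ)` draws the
phase-averaged volume, AAWSS, kinetic-energy and dissipation curves;
`tidy(summ)` and `glance(summ)` return them as tibbles.

The same functions run the 3-D path (`shape_kind = "sphere"`,
`"ellipsoid"`, `"ventricle"`); the beating-sphere phantom at amplitude
0.2 reproduces the analytic EF of 70.4% from per-frame segmentation to
within a tenth of a point.

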