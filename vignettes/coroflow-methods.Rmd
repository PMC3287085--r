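---
title: "Hemodynamics of an idealized stenosed left coronary bifurcation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemodynamics of an idealized stenosed left coronary bifurcation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`coroflow` studies how plaques in the left coronary artery alter local
hemodynamics. It builds an idealized two-dimensional left coronary
bifurcation — a left main stem (LMS) dividing into the left anterior
descending (LAD) and left circumflex (LCx) branches — inserts plaques that
narrow the lumen by a prescribed diameter fraction, solves pulsatile laminar
incompressible Navier–Stokes flow through the lumen under Newtonian and
shear-thinning blood rheology, and reduces the fields to the quantities
cardiovascular CFD studies report: the magnitude of the local pressure
gradient (PSG, in kg m⁻² s⁻² = Pa/m), wall shear stress (WSS, Pa),
cross-sectional velocity profiles at fifteen section planes (A–O), and
recirculation fractions. The standard experiment is a four-arm comparison:
plaque on/off crossed with Newtonian/generalized-power-law blood.

The geometry is synthetic by design. Patient-specific coronary surfaces are
not distributed with this package; the parametric bifurcation stands in for
a segmented CT lumen so that every result is reproducible from code alone.
Consequences of that choice are discussed under *Limitations*.

# Geometry and meshing

## Parametric bifurcation

The lumen is described by branch centerlines and signed wall offsets.
Default dimensions are typical adult left-coronary values: LMS 4.5 mm
diameter × 10 mm, LAD 3.5 mm × 25 mm, LCx 3.0 mm × 25 mm, with an 80°
bifurcation angle split symmetrically about the LMS axis. The two outer
junction corners and the carina (flow divider) apex are smoothed by circular
fillets of radius 1.0 mm, playing the role of the spline smoothing applied
to segmented surfaces to avoid non-physical sharp edges. All three fillets
use one radius; the carina fillet recesses the apex slightly downstream,
which is anatomically reasonable.

Plaques are raised-cosine wall bumps: over an extent $L$ centred at $s_0$
the local width is multiplied by $1 - \delta\,g(s)$ with
$g(s) = \tfrac12(1 + \cos 2\pi (s - s_0)/L)$, so the wall is $C^1$, the
throat diameter is exactly $(1-\delta)D$, and percent diameter stenosis is
$100\,\delta$. The default study uses two symmetric plaques with
$\delta = 0.6$ (60% diameter stenosis) and $L = 4$ mm: one at mid-LMS
($s_0 = 5$ mm) and one in the proximal LAD at $s_0 = 5.5$ mm. The LAD
plaque sits immediately distal to the ostium because the carina fillet
occupies the inner wall out to roughly $s = 3$ mm; a plaque overlapping the
junction smoothing would make the wall offsets ill-defined, so the
constructor rejects it. Eccentric plaques (one-sided bumps) are supported;
the defaults are symmetric.

## Why two dimensions

The solver domain is planar. A patient-scale three-dimensional hexahedral
mesh (order $10^6$ cells) is neither reproducible nor tractable here, and
every mechanism the study examines — stenotic acceleration, post-stenotic
recirculation, elevated PSG and WSS at throats, rheology sensitivity — has
a two-dimensional analogue. The price is quantitative: a 60% diameter
stenosis reduces area by 84% in a circular tube but width by only 60% in a
channel, so velocity amplification and absolute PSG/WSS levels are smaller
than their 3-D counterparts. All acceptance checks are therefore
directional or tied to 2-D closed forms, never to the 3-D patient values.

## Mapped triangulation

No unstructured mesh generator is available as an R dependency, and
determinism was a design goal, so the mesher is a mapped (transfinite)
structured triangulation built by the package: the domain is split along
the lumen midline into an upper half (LMS upper half → LAD) and a lower
half (LMS lower half → LCx). Each half is a curved channel between an
inner curve (midline, then the carina wall) and an outer curve (outer
wall); stations are placed along both curves by arclength with a local
target spacing, cross lines are ruled between them, and each quad is split
into two triangles. The two halves share their midline nodes exactly, so
the merged mesh is conforming, and the construction is fully deterministic
(the `seed` argument is recorded for provenance only).

Default element size is $h = 0.15$ mm with an $h/2$ refinement band across
each plaque extent; cross-stream resolution is set by the largest branch
diameter (24 intervals per half at the default), giving ≈ 14,600 nodes and
28,000 triangles for the default geometry. Boundary edges carry exactly one
of the tags `inlet`, `outlet_lad`, `outlet_lcx`, `wall` (the tag lengths
partition the outline perimeter — a tested invariant). Wall nodes carry a
two-node inward stencil along their cross line, used for second-order
one-sided wall-shear evaluation.

# Blood rheology

Two constitutive models are implemented. The Newtonian model uses the
standard whole-blood constants: viscosity $\mu = 0.0035$ Pa s, density
$\rho = 1060$ kg/m³. The generalized power law evaluates
$\mu(\dot\gamma) = \lambda(\dot\gamma)\,|\dot\gamma|^{\,n(\dot\gamma)-1}$
with

$$\lambda = \mu_\infty + \Delta\mu\,\exp\!\big[-(1 + |\dot\gamma|/a)\,
  e^{-b/|\dot\gamma|}\big],\qquad
  n = n_\infty - \Delta n\,\exp\!\big[-(1 + |\dot\gamma|/c)\,
  e^{-d/|\dot\gamma|}\big],$$

with $\mu_\infty = 0.035$, $n_\infty = 1$, $\Delta\mu = 0.25$,
$\Delta n = 0.45$, $a = 50$, $b = 3$, $c = 50$, $d = 4$. Two conventions
are deliberate and documented:

* **Units.** The constants are interpreted in poise, so the high-shear
  consistency asymptote $\mu_\infty = 0.035$ poise equals the Newtonian
  0.0035 Pa s and the two models agree at the high-shear end (verified to
  0.1% at $\dot\gamma = 1000\ \mathrm{s^{-1}}$). `apparent_viscosity()`
  converts to SI.
* **Grouping.** The inner factors are read as $(1 + |\dot\gamma|/a)$ and
  $\exp(-b/|\dot\gamma|)$ — the standard generalized-power-law form; other
  groupings of the same symbols produce non-physical (non-monotone or
  divergent) viscosity curves.

The fit is valid for $0.1 < \dot\gamma < 1000\ \mathrm{s^{-1}}$ and the
apparent viscosity diverges as $\dot\gamma \to 0$ when $n < 1$, so shear
rates are clamped to that window before evaluation. Shear-thinning
monotonicity over the window is enforced by test on a dense grid.

# Pulsatile inflow

The inlet boundary condition is a Fourier-series waveform: `fit_fourier()`
computes least-squares harmonic coefficients from sampled data over one
period, and the packaged default is an 8-harmonic fit to a synthetic
control-point table (40 points over a 1.0 s cycle). The table is a
stand-in, not measured data: a smooth two-feature coronary-like wave shaped
by three anchors — period 1.0 s, global (peak-systolic) maximum at
t = 0.4 s, and a secondary mid-diastolic feature at t = 0.7 s — with a
positive minimum (≈ 26% of peak; coronary inflow does not fall to zero).
The amplitude is a tuning constant: the fitted wave is rescaled so the
spatial peak of the inlet profile at peak systole is 17 mm/s, placing
model velocities in the display range typical of this literature
(0–30.5 mm/s). Users can substitute a measured waveform via a two-column
CSV (`read_waveform_csv()`).

The spatial profile is fully developed plane-channel (parabolic) flow
scaled so its mean equals the waveform value, zero at the walls
(peak/mean = 1.5). A Womersley-type oscillatory inlet profile was left out
deliberately: at these frequencies and radii the inlet Womersley number is
≈ 2.8 and the parabolic approximation relaxes to the correct oscillatory
profile within a few diameters, upstream of every measurement section.

# Flow solver

Space is discretized with equal-order P1/P1 finite elements and PSPG
pressure stabilization (SUPG is unnecessary: the cell Reynolds number stays
below one at coronary velocities and the default mesh). Time uses implicit
backward Euler with the schedule 80 steps of 0.0125 s per 1.0 s cycle. Two
cycles are run by default and the first is discarded as the start-up
transient; cycle-to-cycle velocity differences at peak systole are below 5%
(tested). Boundary conditions: prescribed velocity at the LMS inlet,
no-slip rigid walls and plaques, and traction-free (zero reference
pressure) LAD/LCx outlets — the well-posed reading of "zero pressure
gradient at the outlets" for a velocity-driven problem. Flow is laminar
(peak Reynolds number ≈ 25 at the throats), walls rigid, plaque rigid.

Within each step, the convective velocity and (for the generalized power
law) the viscosity field are updated by Picard iteration, implemented as
defect corrections: the true nonlinear residual of the discrete system is
evaluated, and corrections are solved with a sparse LU factorization of the
Picard matrix that is reused across iterations and steps and refreshed when
the iteration stops contracting or every 8 steps. Because the *stopping
criterion is the true nonlinear residual*, the lazy factorization affects
only speed, never the converged answer. The step accepts when the
normalized residual falls below $10^{-4}$ (typically after 1–3 inner
iterations; a cap of 100 applies, after which the step warns and records
its residual).

The residual is normalized as in general-purpose CFD codes, with explicit
scales because the reference solver's internal definition is unavailable:
momentum rows (FEM weak residuals, units kg/s² in 2-D) are divided by
$\rho U_{\mathrm{ref}}^2 D_{\mathrm{ref}}$ and continuity rows by
$U_{\mathrm{ref}} D_{\mathrm{ref}}$, with $U_{\mathrm{ref}}$ the waveform's
peak mean velocity and $D_{\mathrm{ref}}$ the inlet width; the reported
residual is the larger of the two. This normalization is exactly invariant
under the dynamic-similarity rescaling $(u, p, \mu, \Delta t) \to
(\alpha u, \alpha^2 p, \alpha\mu, \Delta t/\alpha)$, which is tested to
$10^{-10}$.

Two analytic oracles gate the discretization: steady plane Poiseuille flow
(profile L2 error < 2%, WSS within 5% of $6\mu U/h$) and oscillatory
channel (Womersley) flow at $\alpha \approx 2.8$ (amplitude and phase
within 5% at the default mesh and timestep; measured ≈ 1.2% and 0.02 rad).
Global mass conservation is exact in the discrete sense — summing the
continuity rows telescopes to the boundary flux integral, and the PSPG
contributions cancel — so inflow balances the two outflows to solver
roundoff, far inside the 10⁻³ acceptance band.

# Post-processing

**PSG.** Element P1 pressure gradients are recovered to nodes by
area-weighted averaging of the gradient *vector* (rotation-equivariant,
verified to 10⁻¹⁰) and reported as $|\nabla p|$ in Pa/m. The reported
units match a spatial gradient, and the package treats PSG as one
throughout.

**WSS.** At each wall node the velocity derivative along the inward mesh
stencil is taken from a one-sided quadratic fit through the no-slip zero
and two interior nodes (second order), divided by the stencil-normal
obliquity, and projected on the wall tangent; the active rheology is
evaluated at the resulting wall shear rate. Nodes whose stencil is nearly
tangential to the wall (a handful at the junction saddle) fall back to the
recovered velocity-gradient tensor.

**Sections.** Fifteen planes in three groups of five at 0.5 mm spacing,
laid out the way the flow is read off them: A–E walk up the LMS plaque
(A–B prestenotic, E at the throat), F–J walk down the LAD plaque (F at the
throat, I–J in the postplaque expansion where separation appears), K–O sit
on the proximal LCx starting at the ostium. Section chords are clipped
against the lumen polygon, so ostial planes remain well defined inside the
junction. Profiles are sampled at ≥ 50 points; the integral of the
streamwise component reproduces the branch flux within 1% (tested). The
recirculation fraction of a profile is the fraction of samples with
negative streamwise velocity; the summary reports it both at the two
reporting phases and as its maximum over the stored cycle (with the phase
at which that maximum occurs), because the thin reversal zones at these
Reynolds numbers are strongest during post-systolic deceleration
(t ≈ 0.49–0.55 s), between the two reporting phases.

**Throat amplification.** Continuity fixes the *section-mean* streamwise
velocity ratio between the throat and an unstenosed plane of the same
branch at $1/(1-\delta) = 2.5$ in 2-D. The package reports exactly that
mean-to-mean ratio. The peak-to-mean variant sometimes quoted mixes in a
profile shape factor (1.1–1.5 at these Reynolds numbers) that continuity
does not determine, so it is not used as a check.

**Summary.** `summarize_study()` reduces the four arms at the two
reporting phases (0.4 s, 0.7 s) to min/max velocity per section group
(mm/s, the field's display unit; fields are stored in SI), min/max PSG and
WSS over each plaque region (extent ± one plaque length), recirculation
fractions per section, the LAD:LCx flow split, throat amplification, and
paired comparisons (plaque/no-plaque PSG; GPL/Newtonian WSS). The report
serializes losslessly to JSON and CSV.

# Numerical and design choices, in brief

* Millimetres in geometry and mesh files; metres/SI inside the solver.
* Backward Euler, not Crank–Nicolson: robust at $\Delta t = 0.0125$ s and
  consistent with per-step iterative convergence; the oscillatory-flow
  oracle confirms the first-order damping stays within the 5% band.
* Lumped mass matrix in both the residual and the matrix (consistent
  scheme, cheap diagonal).
* PSPG parameter $\tau_e = \big[(2/\Delta t)^2 + (2|a|/h_e)^2 +
  (4\nu/h_e^2)^2\big]^{-1/2}$ with $h_e = \sqrt{2A_e}$.
* Traction-free outlets impose zero *full* traction, which flattens the
  profile slightly within a diameter of each outlet; all measurement
  sections sit far upstream of the outlets.
* Dirichlet rows are scaled by $\rho\,m_i/\Delta t$ so the system stays
  well-conditioned for sparse LU.
* The default study (4 arms × 2 cycles × 80 steps at $h = 0.15$ mm) was
  sized to run on a single CPU in well under 15 minutes; the validation
  oracles use coarser channels and run in seconds.
* Zero-flow start; the first (discarded) cycle absorbs the impulsive
  start.

# Limitations

* **2-D planar lumen.** Secondary (out-of-plane) flow, helicity and true
  3-D jet impingement are absent; absolute PSG/velocity/WSS levels are not
  comparable to patient-specific 3-D values, only their plaque/no-plaque
  and Newtonian/non-Newtonian contrasts are meaningful.
* **Synthetic geometry and waveform.** Passing tests demonstrates the
  method's correctness on the idealized system, not agreement with any
  patient's anatomy or inflow. Curvature, tapering, side branches and
  motion of the real coronary tree are not modelled.
* **Rigid walls and plaque, laminar flow** — as in the reference study
  design; fluid–structure interaction is out of scope.
* **Rheology comparison is shear-level dependent.** At this study's
  velocity scale the unstenosed wall shear rates are only 5–20 s⁻¹, where
  the generalized power law is genuinely 2–3× more viscous than the
  Newtonian model, so whole-wall WSS medians differ by that factor. The
  familiar "the two models give similar WSS" behaviour emerges only where
  shear is elevated: at the stenotic throats the GPL/Newtonian WSS ratios
  are 1.3–1.7 here, and they approach 1 at physiologic shear rates of
  hundreds of 1/s.
* **Low-Reynolds recirculation.** At the literature's display velocities
  (peak ≈ 17 mm/s at the inlet) the throat Reynolds number is ≈ 25, near
  the threshold where post-stenotic separation first appears; recirculation
  zones are correspondingly thin and phase-dependent.
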