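---
title: "Methods: coupled 0D-LBM hemodynamics for coarctation and bypass grafts"
author: "coaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled 0D-LBM hemodynamics for coarctation and bypass grafts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coaflow is a desk-scale toolkit for assessing the hemodynamics of
coarctation of the aorta (COA) before and after extra-anatomical bypass
grafting. It couples three layers: a Doppler-calibrated lumped-parameter
(0D) model of the left heart and systemic circulation; a lattice-Boltzmann
(LBM) flow kernel for local velocity and wall-shear-stress fields on
programmatically generated vessel geometries; and the statistical machinery
for comparing two velocity fields on a common grid. This vignette documents
the models, the numerical choices, and the design decisions that were
genuinely open.

## The 0D circulation model

The left atrium and left ventricle are time-varying elastance chambers,
`P = E(t) (V - V0)`, with `E(t)` in double-Hill form:

    E(t) = N * [(t/tau1)^m1 / (1 + (t/tau1)^m1)] * [1 / (1 + (t/tau2)^m2)]
           + E_min,        N = (E_max - E_min) / 2

with the standard constants: LV `E_max` 2.1 and `E_min` 0.06 mmHg/mL,
`m1` 1.32, `m2` 27.4, `tau1` 0.269 T, `tau2` 0.452 T; LA `E_max` 0.17,
`m2` 13.1, `tau1` 0.110 T, `tau2` 0.18 T. Two scaling conventions exist in
the literature: some authors renormalize the double-Hill product so the
curve maximum equals `E_max` exactly. coaflow implements the form above
*literally*: with the LV constants the realized peak elastance is about
0.68 mmHg/mL (`N` times the Hill-product maximum of about 0.61, plus
`E_min`). The consequence is physiologically larger chamber volumes at the
same pressures; all pressure and flow targets are reached by calibration
regardless, and the choice is regression-locked by a dense-grid test.

Valves, regurgitant orifices and the coarctation itself are net
pressure-gradient elements built on the energy loss coefficient
`E_L Co = EOA * A / (A - EOA)` (effective orifice area `EOA` opening into a
reference area `A`, which captures downstream pressure recovery):

    PG_net = 2 pi rho / sqrt(E_L Co) * dQ/dt  +  rho / (2 E_L Co^2) * Q^2

evaluated in CGS units and converted at 1 mmHg = 1333.22 dyn/cm2. The
mitral valve uses the inertance form `M_MV / EOA * dQ/dt` with
`M_MV = 0.53 g/cm2`. The convective term is implemented as `Q |Q|` so each
element is odd in the flow direction. A stenosis-free patient
(`EOA = A downstream`) degenerates the element: its energy loss coefficient
is capped at 2000 cm2, which makes both terms hemodynamically inert (well
below 1 mmHg at physiological flows) while keeping the flow ODE
non-singular.

The circuit topology: a rectified-sine pulmonary inflow
`Q_MPV sin(pi t / t_ee)` drives the LA directly; LA to LV through the
mitral element; LV through the aortic valve to the aortic node (compliance
`C_ao`, series resistance `R_ao` = 0.05 mmHg.s/mL); a bifurcation feeds the
upper-body resistance `R_ub`, the descending branch (proximal resistance
`R_pda` = 0.05 in series with the COA element), and — post-intervention — a
bypass-graft branch; all three rejoin at the systemic node (`C_SAC`), then
`R_SA` and `R_SV` = 0.05 to a constant central venous pressure of 4 mmHg.
The pulmonary ladder constants are carried as documented constants but not
dynamically simulated; sensitivity analyses in this model family find their
influence negligible, and the prescribed-inflow source replaces them
functionally. The LA elastance is phase-advanced by a configurable atrial
kick offset (default 0.12 T) so atrial contraction precedes ventricular
systole; the inter-chamber phase is not fixed by the published constants.

The graft is a Hagen-Poiseuille resistance computed from its published
geometry (length about 7-8 cm, diameter 1.5-1.7 cm), about 1.3e-3
mmHg.s/mL. A real anastomosed conduit adds junction losses that a laminar
straight-tube estimate ignores, so in the 0D model the graft branch is an
effective short circuit of the bifurcation; the clinically measured flow
split is restored by the `R_ub` calibration step, which is the quantity the
model is actually conditioned on. Per-branch COA-versus-graft splits are
therefore *not* claimed to be patient-faithful at the 0D level — only the
upper-body versus descending split is.

### Integration

The state vector is (V_LV, V_LA, P_ao, P_sa, Q_av, Q_mv, Q_coa, Q_ar,
Q_mr). Valve conduits are ideal diodes: each inertial flow ODE is active
while its flow is positive or its opening gradient favorable; a zero
crossing from above is localized by step bisection (to 1e-6 s) and the
conduit is clamped shut until the gradient favors reopening. The integrator
is an implicit trapezoidal scheme with full Newton iteration
(finite-difference Jacobian, partial-pivot LU), residual tolerance 1e-6,
initial step 0.1 ms, step growth to 1 ms on success and halving on Newton
failure. The same scheme exists twice: a compiled stepper (the default) and
a pure-R reference implementation; a test integrates both for two cycles
and requires agreement, so the fast path is continuously cross-validated.
A run is declared steady when systolic pressure, diastolic pressure and
forward stroke volume all change by less than 0.1 percent between
consecutive cycles; synthetic patients typically converge in 30-60 cycles,
within the 150-cycle protocol.

## Patient-specific calibration

Calibration proceeds in three sequential steps, iterated to joint
convergence (at most 5 outer passes):

1. `Q_MPV` — scalar root find so the simulated forward LVOT stroke volume
   (per-beat integral of aortic-valve flow) matches the Doppler
   measurement, to 1e-3 relative.
2. `R_SA, C_SAC, C_ao` — matched to the brachial cuff pressures. Two
   constraints cannot identify three parameters, so the step runs in two
   stages: a globalization stage holds the compliance split `C_ao : C_SAC`
   at its prior ratio (1:4 from the standard initial values 0.5 and
   2 mL/mmHg) and solves the well-posed 2x2 problem by nested monotone
   root finds (systolic pressure rises with `R_SA`; diastolic pressure
   rises with total compliance once systole is matched); a polish stage
   then runs bound-constrained Levenberg-Marquardt over all three
   parameters with a weak anchor at the stage-1 point. Convergence demands
   both pressure residuals below 0.5 mmHg. The compliance split itself is
   *not identifiable* from two pressure extrema; recovery experiments are
   therefore meaningful for parameter sets on the prior-ratio manifold,
   and the anchored least squares returns the solution nearest that
   manifold otherwise.
3. `R_ub` — scalar root find so the upper-body branch stroke volume matches
   the Doppler-derived split (post state: forward LVOT-SV minus
   `A_DAO x VTI_DAO`); in the pre state, where no Doppler split exists, the
   branch takes 15 percent of the forward stroke volume by convention.

Physical tolerances (0.5 mmHg on pressures, 1e-3 relative on stroke
volumes) define convergence; the 1e-6 tolerance is the inner ODE residual.
The outer iteration was added because the flow-split step perturbs the
pressure targets; one extra pass is almost always sufficient. During
calibration, simulations run warm-started from the previous steady state
and use a tightened steady tolerance (5e-5), because the least-squares
stage differentiates pressure extrema numerically and cycle-to-cycle drift
must sit well below the finite-difference increment (`epsfcn` 1e-4).

## The synthetic-patient generator

There is no public accession for the clinical records this class of model
is built on, so the generator emulates the published value envelope:
forward LVOT stroke volumes 55-90 mL, systolic pressures 120-160 and
diastolic 50-80 mmHg, heart rates 60-85 /min, LVOT areas 3-4.5 cm2,
ascending aorta 6-9 cm2, descending aorta 3-5 cm2. Severity maps to the
ratio `EOA_coa / A_downstream` as none/mild/moderate/severe =
1.0/0.6/0.4/0.25, which spans the published clinical gradient range (about
4-14 mmHg peak). The descending stroke volume is drawn as 55-70 percent of
the forward volume so the branch split is always realizable. Draws are
deterministic per seed, and a 1000-seed property test asserts every record
satisfies every measurement invariant. What the generator does *not*
emulate: measurement noise and inter-observer variability, regurgitant
lesions (the regurgitant orifice areas default to zero, though the model
elements exist and are switchable), and any correlation structure beyond
the SBP/DBP envelope — so passing calibration tests demonstrates internal
consistency of the pipeline, not fidelity to any real patient.

## The lattice-Boltzmann kernel

D3Q19 (default) and D2Q9 descriptors with single-relaxation-time BGK
collision; multi-relaxation-time variants are out of scope (no moment
basis to reproduce). The Smagorinsky large-eddy closure with
`C_s = 0.1` computes a per-cell effective relaxation time from the norm of
the second-order non-equilibrium moment:

    tau_eff = (tau0 + sqrt(tau0^2 + 2 sqrt(2) Cs^2 |Pi| / (rho cs^4))) / 2

which reduces exactly to BGK at equilibrium or `Cs = 0`; a test verifies
the closure against hand-evaluated scalar arithmetic and that laminar
resolved flow differs from plain BGK by under 1 percent.

Curved walls use the Bouzidi interpolated bounce-back. With `q` the
fraction of the link at which the wall cuts it:

    q < 1/2 :  f_opp(A) = 2q f^c_a(A) + (1 - 2q) f^c_a(E)
    q >= 1/2:  f_opp(A) = f^c_a(A) / (2q) + (2q - 1)/(2q) f^c_opp(A)

(`E` the upstream fluid neighbor, `c` post-collision). Printed versions of
this scheme circulate with sign typos and a duplicated term in the second
branch; the form above is the standard one and is the only one that makes
the two branches agree at `q = 1/2`, where both reduce to plain halfway
bounce-back — asserted bit-level against an independent loop-based
reference. Links whose upstream neighbor is not fluid fall back to plain
bounce-back.

Geometries are built from signed-distance functions sampled at cell
centers: the distance field yields the flags, the per-link `q` (linear
interpolation along the link — exact for planar walls), and outward wall
normals (central-difference gradient of the distance field; the
normal-estimation method is a package choice, as none is fixed by the
scheme). Built-in parametric vessels: straight 2D channel (with fractional
wall offsets), a 45-degree doubly periodic channel array (exercises
off-axis q), straight 3D tube, cosine-constricted channel/tube
(configurable throat ratio = EOA/A), and a constricted tube with a bypass
loop whose proportions follow the published grafts.

The velocity inlet imposes the prescribed axial profile (plug, or
parabolic normalized to the same mean), copies density from the adjacent
bulk node (corner/edge pressure extrapolation), and reconstructs the
off-equilibrium populations from finite-difference velocity gradients
(one-sided second order along the axis, central in-plane) via
`f_neq = -w rho tau / cs2 (c c - cs2 I) : S`. The pressure outlet fixes the
outlet density and copies velocity and off-equilibrium parts from the
neighbor. Pulsatile inflow is wrapped in a sinusoidal smooth startup: a
half-sinusoid ramp to the waveform's initial value, continuous at the
junction. Body-force driving (for periodic benchmarks) adds
`3 w rho (c.g)`.

Wall shear stress follows the non-equilibrium-moment route: strain rate
`eps_ij = -Pi_ij / (2 rho tau cs2)`, deviatoric stress `2 mu eps`, traction
projected onto the wall tangent plane; the tangential magnitude converts to
Pa through the unit map (`dt = (nu_lattice / nu_phys) dx^2`; pressure scale
`rho_phys (dx/dt)^2`). The near-wall sample sits half a cell from the wall,
so in a channel of gap H the sampled stress underestimates the wall value
by about `1/H` relative — which is why the 3-percent analytic check is
specified at 64 cells across the gap. `y_plus()` reports the first-cell
height in friction-velocity units for sublayer checks.

### Benchmark problem sizes

The test and acceptance runs use deliberately small lattices chosen so
each analytic target is met with margin: Poiseuille at 33 cells across the
gap (about 0.1 percent centerline error), Womersley number 4 at 32 cells
(about 0.5 percent amplitude error), wall shear at 64 cells (about
1.8 percent), mesh-refinement acceptance on a throat-ratio-0.45 constricted
channel at 24 versus 36 transverse cells under diffusive scaling (about
1-1.6 percent change in peak velocity and pressure drop, below the
2 percent acceptance line), and a 45-degree channel at sizes 24-54 for the
convergence-order fit. The 2D benchmarks run in seconds; the D3Q19 tube
check uses a radius of 8 cells.

## Velocity-field comparison

Down-sampling to an acquisition-resolution grid is component-wise
trilinear interpolation at the coarse voxel centers, with a coarse voxel
invalidated if any contributing fine voxel is invalid. Smoothing is
penalized least squares in a discrete-cosine basis with the smoothing
parameter chosen by generalized cross-validation (the multidimensional
spline smoother of the Garcia family): missing voxels are imputed
iteratively, preceded by a large-to-small continuation in the smoothing
parameter so imputed values diffuse in from the observations before light
GCV-selected smoothing takes over; the robust mode adds three bisquare
re-weighting passes on studentized residuals. The DCT is applied as an
explicit orthonormal basis matrix per dimension (cached per size) — at the
grid sizes involved this is as fast as an FFT formulation and simpler to
verify.

Agreement statistics operate on velocity magnitude by default (per
component optionally): Bland-Altman bias (mean difference) with
1.96 SD limits of agreement, and Pearson correlation with `R^2 = r^2`.
Because the acquisition-side smoothing of real phase-contrast measurements
has no published kernel, the comparison pipeline applies the same
GCV-selected smoother to the down-sampled field as its imitation; this
proxy is a documented approximation. Phase-error corrections (Maxwell
terms, eddy currents) are out of scope; synthetic fields emulate
post-corrected data, and the Monte-Carlo agreement tests construct
difference fields with known bias and spread (for example N(-0.05, 0.098)
m/s) and require the estimators to recover them within sampling error.

## What the desk-scale suite does and does not show

Patient-scale results — 3D velocity/viscous-stress/turbulence maps on
86-million-cell patient aortas and their agreement with 4D-flow
measurements — require clinical images and cluster compute, and are out of
scope. The package substitutes property-based evidence: analytic flow
benchmarks for the kernel, printed-table arithmetic for the clinical
indices, round-trip parameter recovery for the calibration, and
known-statistics constructions for the comparison machinery. A green suite
means the components are individually faithful and the pipeline is
self-consistent at desk scale; it does not validate the framework against
clinical data.

## Known limitations

- The compliance split `C_ao : C_SAC` is unidentifiable from cuff
  pressures alone (see above); reported compliances are prior-anchored.
- The 0D graft element ignores junction losses, so COA-versus-graft flow
  partition at fixed total descending flow is not clinically faithful.
- The elastance curve is not renormalized to peak at `E_max`; chamber
  volumes run high at matched pressures.
- The LBM inlet reconstruction is first-order in the transverse wall
  gradient at plane edges.
- Robust smoothing assumes sparse outliers; contiguous corrupted regions
  are imputed like missing data, losing genuine small-scale structure.
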