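---
title: "Modeling the venous valve cycle with an immersed finite element method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the venous valve cycle with an immersed finite element method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Venous valves are bileaflet structures that rectify blood flow against
gravity. Their failure modes — fibrosis (stiffened, thickened leaflets) and
atrophy (softened leaflets) — underlie chronic venous insufficiency and
reflux. `venofsi` simulates one valve cycle of a 2D vein segment (wall,
sinus pockets, two leaflets) interacting with pulsatile blood flow, for a
healthy valve and four lesion scenarios (CFV, CAV, IFV, IAV: complete /
incomplete fibrosis / atrophy), and reports the clinically interpreted
quantities: geometric orifice area (GOA), transvalvular flow rate and
venous volumes, wall shear stress on blood (FWSS) and tissue (SWSS),
leaflet rotations, and the mechanical cost ratio SWSS/FWSS.

## Model overview

**Fluid.** Incompressible Navier–Stokes on a fixed, uniform quadrilateral
grid covering a 2.5 × 1.071 cm² box, discretized with equal-order bilinear
(Q1Q1) velocity–pressure elements stabilized by SUPG/PSPG and a grad-div
(LSIC) term. The stabilization parameter is the standard blend
`tau = ((2/dt)^2 + (2|v|/h)^2 + (4 nu/h^2)^2)^(-1/2)` with
`tau_lsic = rho h^2/(4 tau)`. Time stepping is a one-matrix semi-implicit
scheme: Crank–Nicolson Galerkin convection/diffusion with the advection
field extrapolated to the half step, implicit pressure, fully implicit
stabilization, one sparse direct solve per step. We chose this over a
pressure-correction split because equal-order PSPG already stabilizes the
pressure and a monolithic solve is more robust next to an immersed
interface at the modest 2D problem sizes targeted; the manufactured-solution
test in the suite confirms second-order accuracy in time.

Blood is Newtonian with density 1.08 g/cm³ and viscosity 0.036 g/(cm s).
Nodes covered by tissue carry ghost-scaled properties (factor 1e-6).

**Solid.** The vein tissues are hyperelastic in total-Lagrangian Q1
elements under plane strain. Both constitutive families are functions of
the first stretch invariant (the fiber terms drop out in the transverse
plane): a polynomial law `c3 (I1-3) + c5 (I1-3)^2` for wall and sinus and
an exponential law `c0 (exp(c1 (I1-3)^2) - 1)` for the leaflets, plus a
neo-Hookean baseline term `mu_b/2 (I1-3)` that supplies the leaflet's
small-strain modulus (the exponential alone has zero tangent at rest).
Near-incompressibility is enforced by a volumetric penalty
`kappa/2 (J-1)^2` with `kappa = 100 x` the reference shear modulus,
evaluated at the isochoric invariant `I1_bar = tr(B)/J + 1` so the model is
a true hyperelastic potential: the reference state is exactly stress free
and stress power equals the energy rate (both tested). The penalty is
integrated at the element center (selective reduced integration) to avoid
volumetric locking.

Material magnitudes: the characteristic wall pair (2.0, 187.5) kPa is
scaled by a common factor 125 so the wall's small-strain Young modulus is
1.5 MPa, matching its stated initial elastic modulus; the sinus takes a
quarter of the wall stiffness; the healthy leaflet has C0 = 417 kPa,
c1 = 0.06 and `mu_b = 200/3` kPa (small-strain modulus 200 kPa). Without
the wall scaling the raw coefficients give a ~12 kPa modulus and the wall
balloons by half a centimeter under the 4 mmHg head. Fibrotic leaflets
scale C0 and `mu_b` tenfold and are meshed 25% thicker; atrophic leaflets
are softened tenfold.

**Time integration of the solid** is a Newmark scheme in the
generalized-trapezoidal family (`gamma = theta`, `beta = theta^2`), with
Rayleigh damping `C = f_m M + f_k K_t` built on the *current tangent*
stiffness — with the initial stiffness, membrane-scale damping spuriously
freezes finite leaflet rotations. Coefficients: `f_m = 0.05` and
`f_k = 0.01` s. A stiffness-proportional coefficient gives every mode a
relaxation time constant equal to `f_k` regardless of stiffness, so the
often-quoted value 0.272 s would forbid the valve from opening inside its
own 0.15 s opening phase; 0.01 s critically damps modes above ~30 Hz
while the valve-scale response lags by only ~10 ms. Scenario runs use the
dissipative `theta = 0.75`: with the trapezoidal rule, high-frequency
content that the per-step Newton tolerance leaves unresolved accumulates
into node-scale sawtooth during the opening transient. The convergence
tests use `theta = 0.5`.

**Contact.** Leaflet–leaflet and leaflet–sinus interaction uses the 12-6
Lennard-Jones inter-body potential with equilibrium distance
`r0 = 2 u_g0 = 0.036` cm. Panel pairs exchange
`F_i = beta_i beta_j n_j da_i dalpha I(s)` with the closed-form tail
integral `I(s) = eps (r0^12/(10 s^10) - r0^6/(2 s^4))`, repulsive below
`r0 5^(-1/6) ~ 0.765 r0` and weakly adhesive beyond. The repulsion is
saturated below `0.25 r0` (a grazing touch cannot produce unbounded
forces) and the well depth is calibrated so that this saturated ceiling
balances twice the peak transvalvular pressure load on a panel: the
contact can always stop the strongest load, while the adhesive tail stays
at the dyne/cm scale of the reported leaning-contact forces — calibrating
the 0.4 r0 band against the full load instead glues the valve shut and
makes it snap. Panel pairs that are already closer than ~2 r0 in the rest
configuration (the commissure, where leaflet and sinus are anatomically
attached) never interact.

**Coupling.** The Eulerian nodes are classified against the current solid
boundary polygons: covered nodes adjacent to real fluid are ghosts and
receive the solid boundary velocity extrapolated with the
boundary-element velocity gradient (exact for rigid motion); deeper nodes
are inactive and carry no equations but keep their pressure memory so
re-activated cells re-enter continuously. Cells whose center is inside a
solid are excluded from the fluid equations. The fluid loads the solid
with its pressure only (the no-slip condition carries the shear), sampled
a fraction of a cell outside each boundary node along its outward normal,
interpolated bilinearly, smoothed along the boundary with two 1-2-1
passes, and integrated consistently over the boundary edges.

The partitioned loop follows the explicit five-step ordering (solid under
lagged traction and contact; re-classification and mixture update; fluid
with interface Dirichlet values; traction update; contact detection).
Because tissue and blood have near-unity density ratio, several
stabilization layers are applied: a virtual interface added mass
(entrained-fluid inertia, `rho_f x 0.35 cm x` the tributary boundary
length, lumped on wetted nodes), under-relaxation of the traction (0.7),
sub-cycling that keeps the convective CFL near two, and automatic
bisection of any failing step into strongly coupled half steps (Aitken
sub-iterations on the interface force), which then remain active for a
short window. A solid step that cannot meet its Newton tolerance is
rejected rather than silently accepted (accumulated non-converged states
were the main source of spurious "flutter").

## Geometry, meshing, and resolution artifacts

The parametric geometry follows the reference dimensions (wall length
2.5 cm, lumen 0.691 cm, wall 0.04 cm, leaflet depth 0.573 cm and thickness
0.02 cm, tip gap 0.018 cm, sinus 0.922 × 0.05 cm bulge, valve base 0.8 cm
from the distal end). Design choices where the prose is not constructive:

* the sinus bulge is a half-cosine (`sin^2`) of height `h_s` over `d_s`,
  with the wall thickness blended to the sinus thickness by the same
  window;
* the semi-lunar leaflet midline is a quadratic Bezier from the hinge to
  the tip whose control point sits at the radial level `d0/2 - h_v`; the
  midline tip is placed `(u_g0 + t_v)/2` off the axis so that the
  *surface* tips are separated by exactly `u_g0`;
* leaflets are meshed as separate bodies whose base edge is clamped at its
  resting position on the wall (the wall root moves little; a conforming
  merge is impossible at incommensurate spacings);
* blocks use longitudinal spacing equal to the target size and four
  through-thickness layers at the reference size 0.008 cm (scaled with
  `h`, minimum two); this resolves bending and reproduces the reference
  per-part element counts within ±15%.

Resolution presets are the package's problem-size choices: `paper`
(h = 0.008 cm, dt = 0.4 ms; the reference resolution, hours per cycle),
`coarse` (0.02 cm, 1 ms) and `smoke` (0.05 cm, 3.5 ms) for desk-scale
work. Tests and the acceptance script run the valve cycles at the smoke
preset; the healthy valve runs a full cycle, while the lesion comparisons
run to 0.7 of the cycle (the pump pulse ends at 0.55 s, so the compared
volumes, orifice areas and peak velocities are settled by then) and the
never-closing CAV to 0.9.

Two subgrid devices matter at desk scale and vanish with refinement: the
covered-node band of a thin member is dilated to an effective
half-thickness of `1.05 h` (below two grid rows the band is porous to the
bilinear flux and the valve cannot seal), and traction samples falling
into pinched-off cells (the sealed tip gap) take the resolved funnel or
pocket pressure of their side, so the tip region feels the transvalvular
load even when the grid cannot resolve the gap.

## Loading

The cycle alternates the muscular pump and the standing posture. During
the pump window the inlet carries a parabolic pulsatile velocity profile
over the luminal segment (mean amplitude 28.9 cm/s — the reported mean
maximum venous velocity — times the waveform), which bounds the flow rate
at its physiological scale. The waveform is zero during a 0.05 s
relaxation window, then a single `sin^2` pulse of 0.5 s: the pulse must
end well before the cycle does, or flow reversal (critical time ~56% of
the cycle) and closure inside the cycle are impossible; its peak falls at
0.30 s, consistent with a peak transvalvular flow near 0.28 s. After the
pump stops, the hydrostatic column of the standing posture re-establishes
as an adverse normal traction `rho_f g L0` (~1.9 mmHg) on the luminal
segment of the distal outlet, with the inlet left open so reflux can
pass; this drives the low-velocity reverse flow that closes a competent
valve and sustains the reflux of an incompetent one. The total head
`delta_p_max = rho_f g L0 + p_pump = 4 mmHg` is recorded by
`loading_protocol()`; a pure pressure-traction drive is available in the
config but a 4 mmHg head across an open 2D channel exceeds the reported
velocity scales several-fold, so the velocity-driven pump is the default.
The lateral boundaries are clamped in both velocity and pressure.

## What the tests do and do not show

The verification suite covers the parts in isolation: analytic channel
flow and the lid-driven cavity reference tables for the fluid;
finite-difference oracles for the solid stress, tangent and energy
consistency; closed-form and quadrature oracles for the contact integral;
exactness of the interface transfers for rigid motion and linear fields.
The valve-cycle runs at the smoke preset exercise the full pipeline: phase
ordering, opening amplitude, volume bookkeeping and the lesion orderings.
They do not validate against in-vivo data; the 2D plane-strain
idealization, the clamped leaflet roots, and the subgrid devices above are
the main departures from the physical valve, and the smoke-grid leaflet
carries only two elements through its thickness.

## Known limitations

* The explicit/partitioned coupling needs the virtual added mass; it
  adds entrained-fluid inertia to the leaflets and delays their response
  by a few tens of milliseconds at desk scale.
* At the smoke resolution the sealed tip gap unseals only once the
  surface separation exceeds roughly `2 h`, which makes the opening later
  and sharper than at the reference resolution.
* Viscous shear is not transferred to the solid (pressure-only traction),
  as the interface no-slip carries the shear; a config flag could add it
  for sensitivity studies.
* Only symmetric resting geometry is supported; lesions change material
  and thickness maps, not shape.
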