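# venofsi

A 2D fluid–structure interaction simulator for the venous valve cycle,
built on a sharp-interface immersed finite element method.

Venous valves rectify blood flow back to the heart; their lesions —
fibrosis (stiff, thickened leaflets) and atrophy (soft leaflets) — cause
venous incompetence and reflux. `venofsi` models a vein segment (elastic
wall, sinus pockets, bileaflet valve) immersed in a fixed Eulerian grid on
which the incompressible Navier–Stokes equations are solved with
equal-order SUPG/PSPG-stabilized Q1Q1 elements. The tissues are
hyperelastic (polynomial wall/sinus law `c3(I1−3) + c5(I1−3)²`,
exponential leaflet law `c0(exp(c1(I1−3)²) − 1)` with a neo-Hookean
baseline), integrated with a damped Newmark scheme; leaflet–leaflet and
leaflet–sinus contact uses a 12–6 Lennard-Jones adhesive potential
`φ(r) = ε[(r0/r)¹² − 2(r0/r)⁶]`. Velocity passes from solid to fluid
through ghost-node Dirichlet values on the immersed sharp interface;
pressure traction returns by bilinear interpolation.

Post-processing computes the quantities used to characterize valve
function: the geometric orifice area `A_GOA = π (d0 + 2 h's) l_GOA / 4`,
the transvalvular flow rate `Q = π (d0 + 2 h's) ∫ v dy / 4`, forward and
reverse venous volumes and the critical (flow-reversal) time, wall shear
stress on blood (FWSS) and leaflet (SWSS), leaflet rotations, the
mechanical cost SWSS/FWSS, and the four phases of the cycle (opening,
equilibrium, closing, closed). Lesion scenarios CFV/CAV/IFV/IAV scale the
leaflet stiffness ×10 or ÷10 (both or one leaflet) with 25% thickening
for fibrosis.

## Worked example

```r
library(venofsi)

# healthy valve, desk-scale resolution (h = 0.04 cm, dt = 2.5 ms)
cfg <- simulation_config("Normal", preset = "smoke")
rep <- run_scenario(cfg)
print(rep)
rep$phases
```

The desk-scale run above prints, via `print(rep)` and `print(rep$phases)`:

```
valve cycle run: Normal ( smoke )
  peak l_GOA  : 0.800 cm (115.7% of d0)
  peak A_GOA  : 0.536 cm^2
  peak Q      : 12.86 cm^3/s at 0.31 s (peak v 64.9 cm/s)
  volumes     : forward 2.937 cm^3, reverse -0.0452 cm^3
  critical t  : 57% of cycle
  incompetent : FALSE
        phase t_start  t_end
1     opening  0.0500 0.4165
2 equilibrium  0.4165 0.4655
3     closing  0.4655 0.6545
4      closed  0.6545 1.0010
```

`l_GOA` is the tip-to-tip orifice width, `Q` the transvalvular flow rate
through the elliptical orifice, the volumes its time integrals over the
cycle, and the critical time the first forward-to-reverse crossing as a
percentage of the cycle; `incompetent` flags a valve that never reaches
closure. At this resolution the compliant leaflets open flat against the
sinus (peak l_GOA above the lumen diameter, versus ~71% of `d0` at the
reference resolution), while the transport quantities — forward volume,
small negative reverse volume, critical time near 56% of the cycle, and
closure under low reverse velocity — sit close to their reference scales;
the methods vignette discusses this desk-scale artifact. Benchmarks
(`run_benchmark("poiseuille")`, `"cavity"`, `"oscillator"`, ...) verify
each solver against analytic or reference oracles.

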