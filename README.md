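# scrollwave

Scroll waves — the three-dimensional version of spiral waves — that pin
to non-conducting heterogeneities in cardiac tissue sustain dangerous
reentrant arrhythmias. A low-voltage external electric field
redistributes the membrane potential around such an obstacle (the
virtual-electrode effect) and can nucleate waves there ("wave emission
from heterogeneities", WEH). A wave source can displace the reentry
only if it fires *faster* than the pinned scroll rotates, and in 3D an
unpinned filament re-pins as soon as the drive stops, because its
positive tension straightens it back onto the obstacle.

`scrollwave` is a simulation laboratory for this problem, for
researchers in computational cardiac electrophysiology and excitable
media. It implements:

* the two-variable **Barkley medium** on a 3D grid,
  `du/dt = (1/eps) u (1-u) (u - (v+b)/a) + lap(u)`, `dv/dt = u - v`,
  at `a = 0.9, b = 0.08, eps = 0.02` (rigid rotation, positive filament
  tension), integrated by explicit Euler / 7-point central differences
  in compiled code;
* a spherical obstacle embedded by the **phase-field method**, with the
  uniform electric field E(t) entering through the Neumann condition
  `n . grad u = -n . E` on the obstacle surface via the forcing term
  `(1/phi) grad(phi) . E`;
* the three field waveforms: pulsed DC (**PDCEF**), sinusoidal AC
  (**ACEF**) and circularly polarized (**CPEF**, amplitude `E0`
  rotating in the xy-plane);
* the analysis pipeline: probe-based activation frequencies,
  scroll-filament detection as the intersection of the `u = 0.5` and
  `v = a/2 - b` isosurfaces with connected-component classification of
  reentrant (transmural) filaments, detachment/removal classification,
  and `(E0, omega_e)` parameter-region scans.

The headline result it reproduces at reduced scale: all three fields
emit spherical waves from the obstacle in a quiescent medium, but only
the circularly polarized field can emit waves *faster* than the pinned
scroll (its surface forcing extremum `E0 sin(theta)` is
azimuth-independent, unlike `E0 sin(theta)|cos(phi)|` for the linear
fields), and only it sweeps the pinned scroll out of the medium —
after which the medium returns to quiescence when the field stops.

## Worked example

Pin a scroll wave to the obstacle, measure its rotation frequency, and
drive it out with a circularly polarized field (about two minutes at
the reduced 60^3 scale):

```r
library(scrollwave)

params <- model_params(grid = c(60, 60, 60))        # dx 0.25, dt 0.002
domain <- build_phase_field(params, radius = 2.5)   # obstacle R = 2.5

pinned <- pinned_scroll_init(params, domain, relaxation_time = 30)
attr(pinned, "omega_scroll")
#> [1] 1.732284

cpef <- field_spec("CPEF", E0 = 1.8, omega_e = 2.1)
out <- run_removal(cpef, params, domain, pinned, t_limit = 500)
out$success; out$t_removed; out$quiescent_after
#> [1] TRUE
#> [1] 57
#> [1] TRUE
```

The pinned scroll rotates at `omega_scroll ~ 1.73`; the circularly
polarized field at `omega_e = 2.1` entrains spherical waves above that
frequency, overruns the pinned scroll (the last reentrant filament
disappears at `t = 57` here), and once the field is switched off the
remaining waves drain through the boundary and the medium is quiescent.
The same protocol with `field_spec("PDCEF", 2.0, 3.75, 0.1)` leaves the
scroll anchored.

The numbered scripts under `analysis/` run the full set of
computational experiments (surface-forcing table, WEH and
pulse-duration dependence, frequency-response scans of the three
waveforms against `omega_scroll`, the removal time course, and the
`(E0, omega_e)` success region) and write their tables under
`results/`.

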