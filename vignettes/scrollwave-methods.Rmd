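---
title: "Scroll-wave unpinning by electric fields: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scroll-wave unpinning by electric fields: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Rotating scroll waves anchored ("pinned") to non-conducting
heterogeneities — scar tissue, blood vessels — sustain dangerous cardiac
reentry.  A low-voltage external electric field redistributes the
membrane potential around such a heterogeneity (the *virtual electrode*
effect) and can nucleate waves there: wave emission from heterogeneities
(WEH).  A pacing source can displace a reentrant wave only if it runs
*faster* than the reentry, and in three dimensions an unpinned filament
re-pins as soon as the drive stops, because positive filament tension
straightens it back onto the obstacle.  This package implements a
minimal 3D excitable-medium laboratory for the question: which field
waveform — pulsed DC (PDCEF), sinusoidal AC (ACEF), or circularly
polarized (CPEF) — can emit waves faster than the pinned scroll rotates,
and thereby sweep it out of the medium for good.

## Model

The medium is the two-variable Barkley model,

$$\partial_t u = \frac{1}{\varepsilon}\,u(1-u)\Bigl(u - \frac{v+b}{a}\Bigr)
  + \nabla^2 u, \qquad \partial_t v = u - v,$$

with $a = 0.9$, $b = 0.08$, $\varepsilon = 0.02$: the spiral rotates
rigidly and closed filaments have positive tension (the
"collapsing scroll rings" regime).  All quantities are dimensionless
model units; the diffusion coefficient is absorbed into the space unit.

A spherical obstacle of radius $R$ is embedded by the phase-field
method: a smooth indicator
$\varphi(\mathbf r) = \tfrac12\bigl(1+\tanh\frac{|\mathbf r - \mathbf c| - R}{\xi}\bigr)$
replaces the sharp boundary, and the diffusion term becomes

$$\frac{1}{\varphi}\nabla\!\cdot\!(\varphi\nabla u)
  + \frac{1}{\varphi}\,\nabla\varphi\cdot\mathbf E(t),$$

whose sharp-interface limit imposes the Neumann condition
$\mathbf n\cdot\nabla u = -\,\mathbf n\cdot\mathbf E$ on the obstacle
surface (see *Sign convention* below).  The electric field
$\mathbf E(t)$ is spatially uniform: it acts on the medium only through
the obstacle boundary term, which is how a field couples to a
non-conducting inclusion in a monodomain description.

The three waveforms:

| kind  | $\mathbf E(t)$ | surface forcing $\mathbf n \cdot \mathbf E$ | temporal extremum |
|-------|----------------|---------------------------------------------|-------------------|
| PDCEF | $E_0\,\hat x$ during the first $d$ of each period $2\pi/\omega_e$ | $A(t)\sin\theta\cos\phi$ | $E_0\sin\theta\,\lvert\cos\phi\rvert$ |
| ACEF  | $E_0\cos(\omega_e t)\,\hat x$ | $E_0\cos(\omega_e t)\sin\theta\cos\phi$ | $E_0\sin\theta\,\lvert\cos\phi\rvert$ |
| CPEF  | $E_0(\cos\omega_e t, \sin\omega_e t, 0)$ | $E_0\sin\theta\cos(\phi-\omega_e t)$ | $E_0\sin\theta$ |

The CP extremum is independent of azimuth and dominates the linear-field
extremum everywhere on the sphere — the geometric root of its stronger
effect on the boundary membrane potential.

### Sign convention

The forcing term is added with a plus sign, which in steady state gives
$\varphi(\partial_n u + E_n) = \text{const} = 0$, i.e.
$\mathbf n\cdot\nabla u = -\mathbf n\cdot\mathbf E$ with $\mathbf n$ the
outward (into-tissue) normal: the obstacle face the field vector points
*toward* is depolarized, the opposite face hyperpolarized.  The opposite
sign merely mirrors the pattern through the origin and changes nothing
dynamically (for CPEF it reverses the rotation sense of the depolarized
spot).  A regression test pins the realized orientation.

## Numerics

* **Discretization.** Explicit Euler in time; 7-point central-difference
  Laplacian in conservative (flux) form with 2-point face averages of
  $\varphi$; 2-point central differences for $\nabla\varphi$.  The outer
  box is no-flux via mirrored ghost layers, which the flux form realizes
  by dropping the boundary face flux.
* **Steps.** Default $dx = 0.25$ and
  $dt = \min(0.8\,dx^2/6,\ 0.002) = 0.002$: the first bound is the 3D
  diffusion stability limit with a 20 % margin, the second keeps the
  stiff reaction (rate $1/\varepsilon = 50$) accurate.  Halving $dt$
  changes the measured pinned-scroll frequency by well under 1 %.
* **Phase-field floor.** Points with $\varphi < 0.002$ are held at rest
  ($u = v = 0$) and carry no fluxes: faces between an active point and a
  held point are dropped, so the active region conserves its own flux
  budget exactly (without this, the steady boundary flux leaks a few
  percent into the clamped region).  Since the forcing coefficients of
  held points are zeroed, the rest state there is an exact fixed point
  of the update.  Interface dynamics are insensitive to the floor below
  $10^{-2}$.
* **Interface width.** $\xi = 2\,dx$, the smallest width at which the
  tanh profile stays resolved.  $\varphi$ is snapped to exactly 1 beyond
  $R + 5\xi$ (where $1-\varphi < 10^{-4}$), which also lets the stepper
  use a cheap uniform-medium update away from the obstacle.
* **Obstacle radius.** Default $R = 2.5$ ($10\,dx$).  Two constraints
  pick this: the obstacle must sit inside the box with a margin of at
  least one radius (a $R = 5$ sphere cannot, in the 15-unit reduced
  box), and the pinned rotation must stay close to the free scroll
  frequency — pinning to a much larger sphere slows the scroll so much
  that even weak pacing would outrun it, erasing the phenomenon under
  study.  At $R = 2.5$ the pinned scroll rotates at
  $\omega_{scroll} \approx 1.71$, within ~1 % of the free scroll.
* **Grid.** $100^3$ for full runs, $60^3$ (15 space units) for the test
  and acceptance scale.  All analysis in this package is run and
  quoted at the $60^3$ scale.

## Initial states

The generators are deterministic (seed-free); identical configurations
reproduce bitwise-identical states.

* **Quiescent medium**: $u = v = 0$, an exact fixed point.
* **Pinned scroll** (cross-field protocol): excite the half-space
  $x \ge c_x$, block the half-space $y \le c_y$ with $v = 0.6$; the
  single wavefront's free end terminates on the obstacle, curls, and
  pins.  The pattern is z-invariant, so the filament spans the box
  height.  After 30 time units of field-free relaxation (about eight
  rotation periods) the rotation is stationary to within 2 %.  The
  attached filament detected by the isosurface method is a vertical
  line grazing the sphere: its closest tissue sections sit about one
  grid spacing outside the surface.
* **Scroll ring**: excite a hemispherical shell whose rim sits 1.8
  space units (a calibrated curl offset) inside the target radius, and
  refractory-block the interior and the lower half space; the circular
  rim curls outward into a closed filament loop at the target radius.
  The detected loop oscillates with rotation phase by about two grid
  spacings, stays planar (z-spread well under $dx$), and drifts slowly
  along its axis while shrinking under its positive tension — axial
  drift of collapsing rings is real dynamics, so shrinkage is measured
  on the phase-averaged radius.

## Measurements

* **Activation frequency**: upward crossings of $u$ through 0.5 at probe
  points placed $10\,dx$ outside the obstacle surface; the first two
  crossings are discarded as transient and
  $\omega = 2\pi/\overline{\Delta t}$.  Reported wave frequencies are
  the mean over the $+x$ and $+y$ probes.
* **Sound (well-formed) spherical waves**: emission settles through a
  long transient — the first waves leave a broad refractory tail and the
  train can stall or re-lock — so classification uses the second half of
  a 70-time-unit run.  A train is *sound* when every one of six axis
  probes sees the same number of cycles (within one) with
  inter-activation CV below 10 %.  Broken waves fail this visibly: under
  AC drive at $\omega_e \approx 2.0$–$2.25$ the probes along the field
  axis register nearly twice the frequency of the transverse ones.
* **Filament**: intersection cells of the $u = 0.5$ and
  $v = a/2 - b = 0.37$ isosurfaces (the point where wavefront meets
  waveback, i.e. the rotation center), located by a local linear
  solve per straddling cell; cells whose corners dip below
  $\varphi = 0.5$ are excluded so that deep-interface artifacts are
  ignored.
* **Reentrant components**: strongly driven wave trains carry short
  $u$/$v$-isosurface seams that are not rotation filaments (the
  circularly polarized drive alone, in a quiescent medium, lights up a
  few hundred such points riding on its wave surfaces).  Filament
  point sets are therefore clustered into connected components
  (single-linkage, $3\,dx$), and a component counts as a reentrant
  scroll filament only if it reaches a z-wall (within $4\,dx$) or
  spans at least 60 % of the box height — a scroll filament is
  transmural, while the drive's seams are short arcs away from the
  walls (its equatorial section may be hidden inside the obstacle
  interface, which is why wall contact, not total span, is the robust
  signature).
* **Detachment / removal**: the filament is sampled once per time unit.
  Detachment is declared when no reentrant component reaches within
  $2\,dx$ of the obstacle surface (the attached line itself hovers
  near $1\,dx$, so a $1\,dx$ criterion would misfire; the threshold
  is a declared default, not a fitted one).  Removal is declared when
  no reentrant component has any point left inside the
  obstacle-centered success box of half width $2R$; success means
  removal within 500 time units.

## Reduced-scale behavior and known limitations

All quantitative statements in the tests refer to the $60^3$ reduced
scale, and three behaviors differ from the full-scale phenomenology:

* **Pulsed-DC emission dies at high repetition rate.**  At $E_0 = 2.0$,
  $d = 0.1$, sustained emission occurs only for $\omega_e \lesssim 2.2$
  (with subharmonic locking, e.g. 3:1 at $\omega_e = 2$); from
  $\omega_e \approx 2.25$ upward the first wave or two may form but the
  train dies.  The reference behavior instead has sound waves from
  $\omega_e = 2.5$ upward and breaking waves below.  The AC scan *does*
  reproduce that threshold topology here: broken trains at
  $\omega_e = 2.0$–$2.25$, clean 2:1 locking from 2.5 up.  Either way
  the conclusion stands: pulsed-DC wave trains never approach the
  pinned-scroll frequency.
* **The CP entrainment window sits below 2.5.**  The CP field entrains
  spherical waves 1:1 up to $\omega_e \approx 2.3$, so the region with
  $\omega_{wave} > \omega_{scroll}$ is $\omega_e \approx 1.9$–$2.3$ at
  this scale.  The CP frequency scan therefore extends below the
  protocol minimum of 2.5 used for the linear fields; restricting CPEF
  to $\omega_e \ge 2.5$ would land entirely in the subharmonic regime
  and miss the effect the scan exists to measure.
* **Small box; annihilation instead of a slow sweep.**  The $60^3$ box
  is 6 obstacle radii across.  When a circularly polarized field inside
  the entrainment window ($\omega_e \approx 2.0$–$2.2$ at
  $E_0 \gtrsim 1.4$; nothing nucleates against the scroll below
  $\omega_e \approx 1.95$) takes over, the faster waves overrun and
  annihilate the pinned scroll in place after a transient rather than
  sweeping it gradually across the box, so the measured detachment and
  removal times coincide (e.g. both 31 time units at
  $E_0 = 1.8, \omega_e = 2.2$).  After field-off the remaining waves
  drain through the no-flux boundary and the medium returns to
  quiescence, confirming that no reentry survives.  The removal
  demonstration uses $E_0 = 1.8$ (the saturating amplitude) at the
  upper edge of the entrainment window, where takeover is fastest.

The synthetic states emulate idealized, isotropic, homogeneous tissue
with a single spherical obstacle.  Passing tests show the method's
internal consistency at this scale; they do not show that the simplified
kinetics, the monodomain field coupling, or the reduced geometry
quantitatively describe real cardiac tissue.

## Parameter defaults at a glance

| parameter | default | meaning |
|---|---|---|
| $a, b, \varepsilon$ | 0.9, 0.08, 0.02 | kinetics (rigid rotation, positive tension) |
| $dx$, $dt$ | 0.25, 0.002 | grid/time step (stability-bounded) |
| grid | $60^3$ (tests) / $100^3$ | box of 15 / 25 space units |
| $R$, $\xi$ | 2.5, 0.5 | obstacle radius, interface width |
| $\varphi$ floor | 0.002 | held-at-rest threshold |
| $u$ threshold | 0.5 | activation / isosurface level |
| $v$ isovalue | $a/2-b = 0.37$ | filament detection |
| probe offset | $10\,dx$ | outside obstacle surface |
| detach / box / deadline | $2\,dx$ / $2R$ / 500 | removal classification |
| component link / wall tol | $3\,dx$ / $4\,dx$ | reentrant-filament clustering |
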