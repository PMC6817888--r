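---
title: "Methods: coarse-grained lipid DPD under momentum-swap shear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained lipid DPD under momentum-swap shear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdshear)
```

## The model

`dpdshear` simulates double-tailed phospholipids in explicit water with
dissipative particle dynamics (DPD). Every bead represents a small group of
atoms; three species exist: hydrophilic head beads (H), hydrophobic tail
beads (T) and water beads (W). All quantities are in reduced units: lengths
in the cutoff radius $r_c$, energies in $k_BT$, masses $m = 1$ per bead, and
time in $\tau = r_c\sqrt{m/k_BT}$.

A lipid is one linear head of $N_{HB}$ H beads and two linear tails of
$N_{TB}$ T beads each, both tails bonded to the last head bead (the
junction). The standard architecture is $N_{HB} = 3$, $N_{TB} = 4$, eleven
beads per chain. Consecutive beads interact through a harmonic spring

$$\mathbf F_{ij} = k_s\left(1 - \frac{r_{ij}}{r_s}\right)\hat{\mathbf r}_{ij},
\qquad k_s = 100,\; r_s = 0.7\,r_c,$$

and consecutive bonded triples through a harmonic bending term
$U_\theta = k_\theta(\theta - \theta_0)^2$ with $\theta_0 = \pi$ for three
consecutive tail beads and $\theta_0 = 2\pi/3$ for triples at the head--tail
junction. Two modelling choices here were genuinely open:

* **Junction angles.** We attach one $2\pi/3$ angle per tail over
  (H$_{last-1}$, H$_{last}$, T$_1$), and give head-internal triples
  $2\pi/3$ as well, so that every consecutive bonded triple is governed by
  exactly one angle term.
* **Bending constant.** $k_\theta$ has no established printed value for
  this parameterization; we default to $k_\theta = 6$ (reduced), a typical
  semi-flexible choice, and expose it as an argument of `build_lipid()` so
  sensitivity can be checked in one line.

The lipid bead fraction is
$\varphi_P = (N_{HB} + 2N_{TB})/(N_{HB} + 2N_{TB} + N_{WB})$; chain counts
are rounded to nearest and the remainder becomes water, so the realized
fraction is within one chain-equivalent ($11/\rho L^3$) of the request.

## Pair forces and the thermostat

Each pair within $r_c$ feels three forces along the line of centres:

$$\mathbf F_{ij} = a_{ij}\,w(r)\,\hat{\mathbf r}
  \;-\; \gamma\, w^2(r)\,(\hat{\mathbf r}\cdot\mathbf v_{ij})\,\hat{\mathbf r}
  \;+\; \sigma\, w(r)\, \zeta_{ij}\, \Delta t^{-1/2}\,\hat{\mathbf r},$$

with the linear weight $w(r) = 1 - r/r_c$ below the cutoff. The dissipative
and random channels form the DPD thermostat; detailed balance requires the
fluctuation--dissipation relation $\sigma^2 = 2\gamma k_BT$, which
`dpd_forcefield()` enforces at construction ($\sigma = 3 \Rightarrow
\gamma = 4.5$ at $k_BT = 1$).

The repulsion matrix encodes hydrophobicity. The parameterization names only
two levels — 200 between incompatible species and 50 between compatible
ones — without spelling out the full pair matrix; we resolve it as

| | H | T | W |
|---|---|---|---|
| H | 50 | 200 | 50 |
| T | 200 | 50 | 200 |
| W | 50 | 200 | 50 |

i.e. tails repel both water and heads. This choice drives the hydrophobic
segregation that the lipid morphologies require; the full matrix is an
argument, so alternatives are one-line changes.

Noise is generated counter-based: $\zeta_{ij}$ for a pair at a given step is
a Gaussian hash of (stream seed, step, pair), symmetric in $i,j$ by
construction. Two consequences matter in practice: trajectories are exactly
reproducible from `(system, seed)` including across checkpoints, and the
cell-list and brute-force pair paths produce *identical* forces on all three
channels, which the test suite exploits as an oracle.

Degenerate geometry: a pair at exactly zero separation has no direction, so
a reproducible random unit vector is substituted and the event counted (a
warning reports the count); with soft cores this has effectively zero
probability. A bonded angle with a zero-length arm is an error, not a
recoverable state.

Bonded beads also feel the non-bonded DPD forces — no exclusions. The soft
potentials make exclusions unnecessary, and this is the common convention.

Energy bookkeeping uses the antiderivative of each force:
$U^C = \sum (a_{ij} r_c/2)(1 - r/r_c)^2$ for the conservative pairs and
$(k_s r_s/2)(1 - r/r_s)^2$ per bond; total energy is reported per bead.

## Integration

The equations of motion are advanced with the modified velocity Verlet
scheme of the standard DPD literature: positions drift with the current
forces, the new forces are evaluated at $\lambda$-predicted velocities
$\tilde{\mathbf v} = \mathbf v + \lambda\,\Delta t\,\mathbf f$ (which is
what the velocity-dependent dissipative force sees), and velocities are
corrected with the mean of old and new forces. We use $\lambda = 0.65$, the
canonical value, and $\Delta t = 0.01\,\tau$. At these settings the measured
kinetic temperature of a pure water box is within about 1% of the target
($0.992$ at $\Delta t = 0.01$, $1.008$ at $\Delta t = 0.002$; the residual
is the well-known integrator bias of DPD thermostats and shrinks with
$\Delta t$). Kinetic temperature uses $3N - 3$ degrees of freedom, since the
centre-of-mass momentum is conserved (and removed at initialization).

All pair searches go through a cell list (at least three cells per axis,
cell width at least $r_c$; the cell count is capped near $N^{1/3}$ per axis
so tiny cutoffs cannot inflate the grid). Boxes too small for a
decomposition fall back to the $O(N^2)$ loop with a warning.

## Reverse non-equilibrium (momentum-swap) shear

Steady shear is imposed by the Müller-Plathe flip: the box is divided into
$n_{slabs}$ equal z-slabs, and every $W$ steps the bead with the most
negative $v_x$ in the slab at $z = 0$ exchanges its $v_x$ with the bead with
the most positive $v_x$ in the slab at $z = L_z/2$. With equal masses the
exchange conserves total momentum and kinetic energy *exactly* (the test
suite asserts equality, not closeness). The accumulated exchanged momentum
$p_x$ fixes the imposed flux

$$j_z(p_x) = \frac{p_x}{2\,t\,L_x L_y},$$

the factor 2 arising from the two equivalent flux planes of the periodic
box. The fluid responds with a sawtooth $\langle v_x\rangle(z)$ profile;
each monotone branch is fitted by least squares (excluding the two perturbed
swap slabs) and the shear rate is the mean absolute slope
$\dot\gamma = |\partial v_x/\partial z|$.

Design notes:

* The swap slabs sit at $z = 0$ and $z = L_z/2$ — the standard construction
  that produces a two-branch sawtooth over the periodic box. (Placing them
  at $0$ and $L_z$ would designate the same slab twice under periodicity.)
* One bead pair is swapped per event, the canonical flip. $n_{slabs} = 20$
  by default; both are protocol arguments.
* The swap interval maps onto the shear rate only for a given box
  cross-section, because the imposed flux scales as $1/(L_x L_y)$: at the
  full $30^3$ box, $W = 5, 2, 1$ produce $\dot\gamma \approx 0.02, 0.04,
  0.06\,\tau^{-1}$; a $15^3$ box reaches the top of that range already at
  $W = 5$ ($\dot\gamma \approx 0.04$--$0.06$), and $W = 1$ overdrives it to
  $\dot\gamma \approx 0.3$. Scaled-down experiments therefore select $W$ to
  land in the physical $\dot\gamma$ range rather than copying the
  full-scale $W$ values.

The mean flow speed $\langle v_x\rangle(t)$ is computed sign-folded: slab
velocities enter with $+$ in the outer quarter-boxes around the $z = 0$ slab
and $-$ in the inner half, so the two counter-streams add instead of
cancelling. For an ideal sawtooth with extrema $\pm\dot\gamma L_z/4$ this
folded mean equals $\dot\gamma L_z/8$ (direct integration; the test
constructs the profile and checks exactly that value).

## Structural observables

Per chain, after unwrapping the chain across periodic images by walking its
bond graph (the gyration tensor is meaningless on wrapped coordinates), the
squared gyration tensor is

$$R^2_{g\alpha\beta} = \frac{1}{n}\sum_{i=1}^{n}
  (r_{i\alpha} - r_{c\alpha})(r_{i\beta} - r_{c\beta}),$$

with $r_c$ the chain mass centre. Its trace is $R_g^2$; its eigenvalues
$L_1^2 \le L_2^2 \le L_3^2$ (computed by the closed-form symmetric $3\times3$
eigen-solution, vectorized over chains and verified against `eigen()`)
give the shape factor

$$\delta = 1 - 3\,\frac{L_1^2L_2^2 + L_2^2L_3^2 + L_1^2L_3^2}
  {(L_1^2 + L_2^2 + L_3^2)^2} \in [0, 1].$$

$\delta = 0$ for a sphere and $1$ for a rod. Note that an ideal planar disc
($L_1^2 = 0$, $L_2^2 = L_3^2$) evaluates to $\delta = 0.25$ under this
formula, although $\delta \approx 0.5$ is often quoted for "circular"
chain configurations; the implementation follows the formula and we record
the tension here rather than adjusting either.

$\langle R_g\rangle$ averages the per-chain *scalar* $R_g$ (not the square
root of the averaged $R_g^2$), matching the per-chain reading of the
ensemble average; the directional components are reported as chain means of
$\sqrt{R^2_{g\alpha\alpha}}$. Stationary levels are least-squares constants
over the trailing window of the series.

Energy traces are reported per bead; the stable stage is located by a
sliding-window slope test (default $|dE/dt| < 10^{-4}$ per 200 $\tau$
window, both arguments). Aggregate counts come from connected components of
the tail-bead contact graph (union--find over the cell-list pair stream,
cutoff 1 $r_c$).

## Synthetic initial states

All inputs are generated:

* `random_solution()` — chains laid down as random walks of step $r_s$
  (reflected at the walls, then wrapped), water uniform; the disordered
  starting point for self-assembly runs.
* `water_box()` — pure solvent, for thermostat and viscosity
  characterization.
* `porous_cylinder_system()` — an idealized pre-assembled lipid cylinder
  along z whose cross-section carries 3--6 water-filled pores on a regular
  polygon: tails fill the annular matrix, heads coat every lipid--water
  interface, water fills pores and exterior, and the outer radius is set by
  the bead budget so density stays near $\rho$ everywhere. This is a
  *scaled-down stand-in* for the self-assembled porous cylinders that form
  at full scale; it is not a bead-for-bead reproduction, and full-scale
  studies should self-assemble from random states.

What the generator does **not** emulate: polydispersity of real lipids,
electrostatics, solvent structure beyond soft beads, and the slow
self-assembly pathway that produces the full-scale pore patterns
(triangular at $\varphi_P = 0.35$ through hexagonal at $0.50$). Passing
desk-scale tests therefore demonstrates the correctness of forces,
integration, shear imposition and observables — not that a $15\,r_c$ box
reproduces full-scale morphology.

## Problem sizes and validation strategy

The package's own validation ladder, reflected in the test suite and
`scripts/acceptance.R`, uses desk-scale systems chosen so each property is
measurable in minutes on one CPU:

* thermostat fidelity: $L = 10$ water (3000 beads), 20,000 steps, mean
  kinetic temperature $1.00 \pm 0.02$;
* force-path equivalence: cell list vs brute force on dozens of random
  configurations, max deviation $\le 10^{-10}$;
* conservation: momentum drift $\le 10^{-9}$/step without shear; swap
  conservation exact;
* shear response: $L = 10$ water under $W = 5$ and $W = 2$ — per-branch
  sawtooth fits with $R^2 \ge 0.98$, and the viscosity fitted at one swap
  interval predicts the flux measured at the other to within 15%
  (Newtonian consistency of the flux bookkeeping);
* analytic observables: gyration and shape factors on hand-solvable
  geometries to $10^{-12}$;
* scaled-down shear anisotropy: $L = 15$, $\varphi_P = 0.35$
  porous-cylinder start, $W = 5$ ($\dot\gamma$ at the top of the physical
  range), examining the ordering of
  $\langle R_{gxx}\rangle, \langle R_{gyy}\rangle, \langle R_{gzz}\rangle$.

On the last point: at this reduced size the simulated chains elongate
*perpendicular to both the flow and the gradient* (the vorticity direction,
y) — $\langle R_{gyy}\rangle > \langle R_{gxx}\rangle >
\langle R_{gzz}\rangle$ — rather than along the gradient direction z as
reported for the $30^3$ systems. This is the known parallel-vs-perpendicular
lamellar orientation competition: which orientation wins depends on shear
rate and box size, and a $15\,r_c$ box that can hold only a couple of
bilayer repeats along any axis biases the outcome. We report the measured
ordering rather than forcing the full-scale one; the full-scale experiment
below is the definitive check.

Full-scale replication (the $30^3$ box, 81,000 beads,
$2$--$3\times10^5$ steps per state point — hours per run on one CPU) is
launched with the same public API:

```{r full-scale, eval = FALSE}
lip <- build_lipid(3, 4)
sys <- random_solution(0.35, box_edge = 30, lipid = lip, seed = 1) |>
  init_velocities(seed = 2)
ff <- dpd_forcefield()
equil <- dpd_run(sys, ff, n_steps = 200000, seed = 3,
                 sample_every = 500, frame_every = 5000)
shear <- dpd_run(equil$system, ff, n_steps = 300000, seed = 4,
                 sample_every = 500, frame_every = 5000,
                 shear = shear_protocol(swap_every = 5))  # W = 5, 2, 1
energy_trace(shear)                      # plateau level and onset
mean_radius_of_gyration(shear)           # <R_g> and components
mean_flow_velocity(shear)                # saturation of <v_x>
glance(measure_shear_rate(velocity_profile(shear)))
```

## Known limitations

* No electrostatics, many-body DPD or energy-conserving DPD variants; no
  Lees--Edwards or SLLOD shear.
* Morphology classification (vesicle vs lamella vs cylinder) is left to
  inspection and the aggregate-count observable; no automated taxonomy.
* The $W \to \dot\gamma$ calibration is empirical and box-size dependent;
  always measure the realized $\dot\gamma$ from the fitted profile.
* The temperature carried by the DPD thermostat rises a few percent under
  strong driving (viscous heating); reported temperatures accompany every
  run so this is visible.
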