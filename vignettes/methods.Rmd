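---
title: "Models and methods: force spectroscopy of transient ET complexes and rigid-body Brownian dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfsbd)
```

# The scientific problem

Soluble electron carriers such as cytochrome *c*~2~ dock transiently
onto membrane-embedded reaction-centre (RC) complexes.  The docking
proceeds through a loosely bound, electrostatically steered *encounter
complex* before settling into the tightly bound, hydrophobically
stabilised *productive* electron-transfer (ET) complex.  Two
experimental signatures separate the states:

* In single-molecule force spectroscopy (SMFS), the distribution of
  unbinding (rupture) forces is bimodal.  The low-force component is
  attenuated by salt (screened electrostatics) and by unfavourable
  redox pairing, identifying it with the encounter complex; the
  high-force component persists and is assigned to the productive
  complex.
* In Brownian dynamics (BD) simulations of the cytochrome diffusing
  over the receptor's potential field, bound poses cluster at a
  *proximal* site (at the ET cofactors) and a weaker *distal* site near
  the light-harvesting ring.

`smfsbd` implements both computational pipelines end to end, with a
synthetic data generator standing in for the (undeposited) raw AFM
curves, so every stage can be validated blind against known ground
truth.

# Synthetic force-distance curves

## What is emulated

One retract segment per force-distance cycle, sampled uniformly in
tip-sample separation (512 samples over the 25 nm modulation
amplitude):

* white Gaussian baseline noise (SD 8 pN), standing in for the noise
  of high-frequency off-resonance tapping;
* with probability `p_event`, a polymer-tether stretch terminating in
  an instantaneous force drop at the rupture force, which is drawn
  from a two-component Gaussian mixture; the rupture separation
  ("offset") is uniform on 10–20 nm, the tether length plus receptor
  height;
* with probability `p_nonspecific` (0.10), a surface-adhesion spike
  below 5 nm separation with an exponential rise (1 nm decay length)
  and amplitude uniform on 100–400 pN.

The tether stretch follows the worm-like-chain (WLC) interpolation
formula

$$F(x) = \frac{k_BT}{L_p}\left(\frac{1}{4(1-x/L)^2} - \frac14 +
\frac{x}{L}\right)$$

with persistence length $L_p = 0.38$ nm (PEG) and a per-event
effective contour $L$ set so the chain reaches the target rupture
force exactly at the drawn offset — the 9.5 nm PEG contour plus a
protein-height allowance.  The final loaded sample is pinned to the
exact rupture force, so the discretisation of the separation axis does
not bias recovered peak positions downward.

## What is *not* emulated

No tapping waveform or cantilever hydrodynamics, no coloured noise, no
loading-rate spectrum across decades (the instrument operates in a
single narrow loading-rate regime), and no multiple simultaneous
tether attachments.  Passing tests therefore demonstrate that the
analysis pipeline recovers the statistical structure it assumes — not
that it is robust to every instrumental artefact of real AFM data.

## Condition presets

`builtin_presets()` carries one row per measured condition.  Peak
positions and cumulative event probabilities are the published
condition values wherever they are stated numerically (WT 154/332 pN
with 34/32/28/26% over 10–200 mM NaCl; WT ox/ox 173/370 pN at 32%;
N(M188)D 40%→37%, Q(L264)E 39%→36%, D(M184)K 24%→20% on oxidation of
the cytochrome; RC-only 124/247 pN).  Values the study reports only
graphically are documented defaults chosen once to follow the stated
trends: mutant probabilities at intermediate salt interpolate the
WT-relative ordering, the RC-only event probability defaults to 0.30,
mixture weights default to `w_low = 0.40` (0.30 for ox/ox pairs, whose
low-force component is attenuated) and component SDs to 25/30 pN,
consistent with the reported width of the earlier measurements.  The
recovery targets depend on peak positions and total area, not on the
exact weights.

The default retract velocity (7800 nm/s) was chosen so that the
instantaneous loading rate measured just before rupture — the WLC
slope near rupture (~320 pN/nm) times the retract velocity — lands at
the instrument's most probable loading rate of 2.5×10^6 pN/s.

# Rupture detection and deconvolution

The detector estimates the baseline and its noise SD from the outer
20% of the separation range (median/MAD; the far tail is always
force-free), then takes contiguous runs above
`baseline + 5·SD` as candidate events, requiring the force to fall
back below threshold within five samples after the peak (the
unbinding drop).  Event force is peak minus baseline; the loading rate
is the slope of force versus separation over the eight samples before
the peak times the retract velocity.  Events are *specific* iff their
separation lies in the closed window [8, 25] nm — slightly wider than
the nominal 10–20 nm offset to tolerate linker polydispersity.  When a
curve holds several specific events, the curve counts once towards the
cumulative interaction probability and only the final
(largest-separation) event enters the force histogram, matching the
"curves displaying rupture events" counting convention and the
single-complex interpretation.

The histogram is probability-normalised: bin heights sum to the
cumulative interaction probability (percent), so the total area *is*
the probability that an imaged complex shows an unbinding event.  The
default bin width is 20 pN; recovery is insensitive over 10–30 pN.
Deconvolution fits a sum of one or two Gaussians to the bin heights at
bin centres by Levenberg–Marquardt least squares with multistart
initialisation (weighted k-means split of the bin centres, plus four
jittered restarts under a fixed internal seed); components are
reported in increasing-mean order, so "low" is always the encounter
component.  Expectation–maximisation on the raw forces (via `mclust`)
is retained in the test suite as an independent oracle, never as the
implementation.  `select_k()` compares k = 1 vs k = 2 by BIC on the
residual sum of squares, after collapsing degenerate two-component
fits (vanishing amplitude, or means closer than the component width)
to one component; ties go to the simpler model.

# Rigid-body properties and potential grids

Mass, centre of mass and the inertia tensor come directly from the
atomic coordinates.  For hydrodynamics, surface atoms — identified by
a discretised rolling-probe test (probe 1.4 Å on a 1 Å occupancy
grid) — become Stokes beads of radius 2.3 Å (1.2 Å atomic + 1.1 Å
hydration), and the translational diffusion tensor is the Kirkwood
double-sum built from the diagonal Oseen tensor.  This is deliberately
*not* a reimplementation of a full bead-shell hydrodynamics code: BD
needs only a consistent, positive-definite diffusion/friction pair
(`friction = kBT/D`, enforced exactly), and the Kirkwood approximation
is anchored by the exact single-sphere Stokes–Einstein limit and the
closed-form touching-dumbbell values in the tests.  Rotational
diffusion uses the equivalent-sphere radius implied by the mean
translational coefficient; translation–rotation coupling is dropped
(only diagonal components are propagated).

Receptor potentials are precomputed on 1 Å grids covering the
bounding box plus a 30 Å margin:

* **Electrostatics** — Debye–Hückel screened Coulomb with relative
  dielectric 78.5 and the Debye length from the ionic strength.  This
  is the package's own modelling choice (analytic, salinity-aware,
  desk-scale); it is not presented as the original study's scheme,
  which is unstated.  No Poisson–Boltzmann solver, no membrane
  dielectric.
* **Lennard-Jones** — the mobile body's atoms are clustered into three
  categories (H; O,N; C,S), each with `Rmin`/ε averaged over its
  members from the packaged per-element table, and one grid per
  category stores the direct 12-6 sum (Lorentz–Berthelot) of a probe
  atom of that category against every receptor atom, capped at
  +100 kJ/mol so clash regions stay finite.  Direct summation replaces
  thermally sampled implicit-ligand free-energy maps: it preserves the
  1 Å-grid-plus-smoothing structure of the method without requiring
  an MD engine.

All grids pass through a separable 3-D Gaussian filter of width 1 Å
(nearest-value padding).  Energies and forces are evaluated by
trilinear interpolation with the analytic gradient of the trilinear
form; outside the grid a harmonic restoring wall
(10 kJ/mol/Å², on the centre of mass at the grid margin) confines
the mobile body, standing in for the periodic membrane system of the
original setup.

# The BD propagator

States are a centre-of-mass position plus a unit quaternion.  At each
step the per-atom grid gradients are summed into a COM force and a
body-frame torque, and the state advances by the overdamped
(Ermak–McCammon) update per principal body axis,

$$\Delta x = \frac{D}{k_BT}F\,\Delta t + \sqrt{2D\,\Delta t}\,\xi,$$

with the rotational analogue applied as a body-frame rotation vector
composed onto the quaternion (renormalised every step).
Fluctuation–dissipation holds by construction, so the bath temperature
(300 K) needs no thermostat tuning.  The defaults follow the reference
protocol: 100 fs time step, frames recorded every 1 ns.  An inertial
"symplectic" integrator was considered and rejected: at 100 fs with
protein-scale friction the dynamics are deep in the overdamped limit,
and the available physical inputs are friction coefficients, not
inertial trajectories.  The integrator is exact for free diffusion and
first-order in the potential; its known Euler–Maruyama variance bias
of order $\Delta t/2\tau$ (with $\tau = k_BT/(Dk)$ the local
relaxation time) sets how small the step must be relative to the
stiffest feature of the landscape — the tests choose
$\Delta t/\tau \lesssim 0.03$ so equilibrium statistics are recovered
within their 5% tolerances.

`steered_pull()` drags the COM with a harmonic restraint moving at
constant velocity (default 0.05 Å/ns, the reference protocol's value)
and records interaction energy against the COM–site distance.  The
toy pulling mode probes the *shape* of the landscape — positions of
intermediate minima, via `detect_states()` (moving-average smoothing,
local minima with a prominence threshold, sign-convention agnostic) —
and explicitly does not reproduce all-atom steered-MD energies in
kJ/mol.

# Binding analysis

Contacts use the hysteretic criterion: bound when any heavy-atom pair
comes within 7 Å, unbound only once no pair is within 16 Å, which
suppresses flicker at the boundary.  With equal thresholds the rule
reduces to plain thresholding (the off comparison is `>=`, so the
degenerate case is exactly `distance < threshold`).  The 10 Å bound
pose filter is applied as a heavy-atom minimum distance (the
alternative COM-surface reading is not used).

Bound poses are clustered by single linkage on COM positions (cut at
8 Å — the clustering criterion of the original analysis is unstated,
and single linkage with a physical cut needs no preset cluster count).
Clusters are labelled by the nearest annotated receptor site
(`proximal` = ET site, `distal` = peripheral ring point); the
annotations are fixture metadata supplied with the receptor, never
inferred from structure.

Site affinities are estimated from single-molecule occupancy:

$$K_D = \frac{1-p_\mathrm{bound}}{p_\mathrm{bound}}\cdot
\frac{1}{N_A V},$$

with $V$ the simulation volume and bootstrap CIs over replicas.  This
replaces the external per-pose contact-based regression server used in
the original study, which cannot be called or re-derived here; the
occupancy estimator is self-contained and is validated against the
analytic Boltzmann occupancy of a toy well (grid-summed partition
function).  Consequently the package reproduces the *ordering*
property — proximal binds far more tightly than distal — on toy
fixtures, and makes no claim on the absolute µM values, which depend
on all-atom poses and the external regression model.

# Problem sizes and numerical choices

The validation suite runs at desk scale by design: recovery uses 2000
synthetic curves per condition (binomial error ±1.1–2.1% on the
probabilities, ±3–6 pN on fitted peaks), the free-diffusion and
rotational-decay checks use 1000 short replicas, Boltzmann sampling
uses >10^6 steps in a double-well fixture, and the two-site toy
receptor runs 10 replicas of 150 ns.  Degenerate inputs are handled
explicitly: empty force sets, zero-mass bodies, non-positive diffusion
coefficients and empty trajectories raise errors; unknown elements
fall back to the nearest LJ category with a warning; a diverging BD
step (too large a time step for the landscape) raises an error rather
than propagating non-finite positions.

# Known limitations

* The generator's white-noise and instantaneous-rupture idealisations
  mean detector performance on real curves (coloured noise, slow
  detachment cascades) is untested.
* Debye–Hückel electrostatics ignores the low-dielectric protein
  interior and the membrane slab; grid potentials are rigid, so
  induced fit and side-chain rearrangement are absent.
* Hydrodynamic anisotropy is approximate (Kirkwood, no
  translation–rotation coupling) and there are no hydrodynamic
  interactions with the receptor or wall.
* Absolute KD values from occupancy depend on the confinement volume;
  only ratios and orderings between sites in the same box are
  meaningful.
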