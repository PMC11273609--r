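# smfsbd

Single-molecule force spectroscopy (SMFS) analysis and rigid-body
Brownian dynamics (BD) for transient electron-transfer (ET) complexes —
the docking of a small soluble cytochrome (cyt *c*₂) onto a
membrane-embedded reaction-centre (RC / RC-LH1) complex.

ET partners meet through a loosely bound, electrostatically steered
**encounter complex** before forming the tightly bound, hydrophobically
stabilised **productive complex**. The package targets the two
computational signatures of that two-state picture:

1. **Bimodal rupture-force analysis.** AFM force–distance retract
   curves are screened for unbinding events; each event contributes a
   rupture force *F*, a tip–sample separation and an instantaneous
   loading rate. The cumulative interaction probability is
   100 · (curves with a specific event) / (complexes imaged), and the
   probability-normalised force histogram is deconvolved into two
   Gaussian components,

   *h*(*F*) = *A*₁ exp(−(*F*−μ₁)²/2σ₁²) + *A*₂ exp(−(*F*−μ₂)²/2σ₂²),

   with μ₁ < μ₂ — the low-force (encounter) and high-force (productive)
   components, each carrying its own interaction probability
   (Gaussian area on the percent scale).

2. **Rigid-body BD with grid potentials.** The mobile cytochrome is a
   rigid body (mass, inertia, Kirkwood bead-model diffusion tensor,
   Stokes–Einstein friction) propagated by an overdamped Langevin
   scheme (Δx = (D/k_BT)F Δt + √(2DΔt) ξ per principal axis, 100 fs
   steps) over precomputed receptor grids: Debye–Hückel electrostatics
   plus three-category Lennard-Jones maps (H / O,N / C,S) at 1 Å
   spacing, Gaussian-smoothed (σ = 1 Å). Trajectories feed a
   hysteretic contact criterion (bound < 7 Å, unbound > 16 Å,
   heavy atoms), single-linkage pose clustering into proximal/distal
   sites, occupancy-based K_D estimates
   (K_D = (1−p)/p · 1/(N_A·V)), and a steered-pulling mode that maps
   interaction-energy profiles and their intermediate states.

Because the raw AFM data are not deposited, a synthetic curve
generator (`generate_dataset()`, presets in `builtin_presets()`)
emulates the statistical structure of each measured condition —
WT and three interface mutants across four NaCl concentrations, both
redox pairings, and the RC-only construct — so the whole analysis
pipeline is validated by blind parameter recovery.

## Worked example

Generate a synthetic wild-type dataset (10 mM NaCl, oxidised RC /
reduced cytochrome), run detection and deconvolution:

```r
library(smfsbd)

bundle <- generate_dataset(get_preset("WT_10mM_oxred"),
                           n_curves = 2000, seed = 42)
bundle
#> curve_bundle: 2000 curves, condition WT_10mM_oxred
#>   events: 682  nonspecific: 204  complexes imaged: 2000

res <- deconvolve_bundle(bundle)
res$fit
#> mixture_fit: k = 2
#>   component 1: mean 156.2 pN, sd 29.4 pN, amplitude 3.35%
#>   component 2: mean 329.6 pN, sd 29.7 pN, amplitude 5.81%
#>   component probabilities: 12.3% + 21.6% (cumulative 34.3%)

loading_rate_mode(res$events[res$events$final_specific, ])
#> [1] 2492917
```

The fitted peaks (156 / 330 pN), the cumulative interaction
probability (34.3%) and the most probable loading rate (2.5×10⁶ pN/s)
recover the condition parameters of the preset (154 / 332 pN, 34%)
within the sampling error of 2000 curves: the pipeline sees only the
raw synthetic curves, never the generating parameters.

On the BD side:

```r
rec  <- toy_two_well_receptor()      # plate + proximal/distal pockets
body <- toy_probe_body()
cats <- assign_lj_categories(body$atoms)$category_params
grids <- build_grid_set(rec$atoms, cats, spacing = 1)

traj <- run_trajectory(body, grids,
                       bd_params(duration_ns = 100, seed = 1),
                       start = rigid_state(c(0, 0, 12)))
cs <- assign_frame_sites(contact_series(traj, body, rec$atoms),
                         rec$sites)
occupancy_kd(list(cs), simulation_volume_A3 = 1e6)
```

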