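# rbcmem

Structural and mechanical analysis of stacked red blood cell (RBC)
cytoplasmic membranes from X-ray scattering and coarse-grained simulation
output.

Blood banks store red cell concentrate for up to five or six weeks, and the
RBC cytoplasmic membrane changes measurably over that time: lipid domains
reorganise, the bilayer thickens, and the membrane stiffens. `rbcmem`
implements the complete analysis chain used to quantify those changes on
solid-supported multilamellar membrane stacks:

* **Specular analysis** — reflectivity extraction from 2-D intensity maps,
  lamellar peak fitting, the repeat distance `d = 2πn/q_n`, Hermans stack
  orientation `H = (3⟨cos²Φ⟩ − 1)/2`, and relative electron density by
  Fourier synthesis `ρ(z) = (2/d) Σₙ √(Iₙqₙ) νₙ cos(2πnz/d)` with the
  centrosymmetric phase problem solved by a default phase array or
  exhaustive sign enumeration. Head–head distance `d_HH` and water layer
  `d − d_HH` follow.
* **In-plane (wide-angle) analysis** — polynomial background correction,
  three-Gaussian decomposition into protein, liquid-disordered (l_d) and
  liquid-ordered (l_o) peaks, chain spacing `a = 4π/(√3 q)`, area per
  lipid tail `A_T = (√3/2)a²`, Scherrer domain sizes
  `L = 0.94λ/(B(2θ)cosθ)`, and l_d:l_o area fractions.
* **Diffuse scattering (Caillé theory)** — the smectic structure factor
  `S(q_z, q_r) = Σₙ H_z(n) cos(q_z n d) ∫ r dr H_r(r) J₀(q_r r)
  exp(−q_z² δₙ(r)/2)` built on the discrete-smectic height-difference
  correlation function `δₙ(r)`, fitted simultaneously to two in-plane line
  cuts (at 2·q₁ and 2.5·q₁) for the bending modulus κ (kBT) and
  inter-membrane compression modulus B (kBT/Å⁴), with the Caillé parameter
  `η = kBT q₁²/(8π√(Bκ))` and correlation length `ξ = (κ/B)^(1/4)`.
  A brute-force Monte-Carlo scattering oracle validates the analytic
  machinery on small stacks.
* **Fluctuation spectra** — head-bead surfaces gridded per leaflet,
  mid-plane undulation fields, radially averaged spectra, and
  Helfrich–Canham fits `⟨|h(q)|²⟩ = kBT/(κq⁴)` for `q < 0.1 Å⁻¹`.
* **Trajectory maps** — component density maps, deterministic
  threshold-based domain sizing, and out-of-plane mass density profiles.
* **Lipidomics** — summarisation of lipid class/tail/saturation tables and
  mapping of measured species onto a coarse-grained model catalogue by a
  tail-length + saturation error coefficient, with leaflet-asymmetry
  assignment by largest-remainder rounding.

Every input the pipeline consumes can be forward-modelled by the package's
synthetic generators with known ground truth, so the full chain is testable
without access to raw beamline data.

## Worked example

```r
library(rbcmem)

# forward-model a diffraction experiment on a fresh-membrane stack
dm    <- density_model(head_position = 21.5, d = 55.4)
scene <- synth_scene(dm, mosaic_width = 0.5, resolution_width = 0.003,
                     n_orders = 5, counts_scale = 1e6, noise_seed = 13L)
map   <- gen_lamellar_map(scene)

# specular chain: reflectivity -> peaks -> phases -> electron density
peaks <- find_lamellar_peaks(extract_reflectivity(map, 0.05))
ff    <- fit_form_factor(peaks, enumerate = TRUE)
prof  <- fourier_density(peaks, ff$phases)
glance(prof)
#> # A tibble: 1 × 4
#>       d  d_hh water_layer phases
#>   <dbl> <dbl>       <dbl> <chr>
#> 1  55.4  42.8        12.6 -1 -1 1 -1 1
```

The reconstructed lamellar period (55.4 Å), head–head distance (42.8 Å,
i.e. the head positions at ±21.4 Å after five-order truncation) and the
recovered phase array `[-1 -1 1 -1 1]` match the generating model.

```r
# diffuse scattering: two-cut Caillé fit for the bending modulus
stk  <- smectic_stack(kappa = 1.9, B_mod = 1.2e-5, d = 56, n_layers = 100)
cuts <- gen_diffuse_cuts(stk, noise_level = 0.03, seed = 1)
fit  <- fit_diffuse(cuts, caille_model(2.5, 3e-5, 56, r_domain = 2000))
fit
#> <caille_fit> kappa 1.74 +/- 0.078 kBT | B 1.26e-05 kBT/A^4 | eta 0.107 |
#>   xi 19.3 A | converged (at bounds)
```

At 3% multiplicative noise the two-cut fit recovers the generating bending
modulus (1.9 kBT) to within about 10% for this realisation — the lateral
envelope scale is weakly constrained and is flagged when it reaches its
bound — and the median error over seeded replicates is a few percent (see
the recovery tests).

```r
# coarse-grained fluctuation analysis
traj <- gen_height_trajectory(kappa = 3.2, box_side = 340, grid_n = 128,
                              n_frames = 450, seed = 5)
fit_hc(spectrum(traj, grid_n = 128))
#> <hc_fit> kappa = 3.34 +/- 0.09 kBT (q < 0.1 1/A, 5 bins)
```

An end-to-end demonstration over all stages (synthetic map, in-plane
pattern, diffuse cuts, trajectory, lipidomics) is available through
`run_pipeline(pipeline_config())`, or from a shell via `exec/rbcmem all`.

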