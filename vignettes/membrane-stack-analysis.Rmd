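---
title: "Models and methods: membrane-stack scattering and fluctuation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: membrane-stack scattering and fluctuation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcmem)
```

`rbcmem` analyses solid-supported stacks of red-blood-cell cytoplasmic
membranes as studied by X-ray diffraction (structure), X-ray diffuse
scattering (mechanics) and coarse-grained simulation (both). This vignette
is the package's account of the underlying models, the numerical choices,
and what the synthetic-data generators do and do not emulate.

## Conventions and units

All lengths are in ångström and wavevectors in Å⁻¹. Energies are expressed
in units of kBT at the working temperature (default 310.15 K, physiological
37 °C), so the bending modulus κ is a pure number in kBT and the
inter-membrane compression modulus B is in kBT/Å⁴; the in-plane correlation
length ξ = (κ/B)^(1/4) then comes out in Å with no conversion factors.
Angles are degrees at interfaces and radians internally; q-grids ascend;
z = 0 sits at the bilayer centre; histogram bins are half-open [lo, hi).
Seeds are always explicit function arguments — no generator touches global
RNG state without restoring it.

## Specular analysis

A stack of N membranes with period d produces lamellar Bragg peaks at
q_n = 2πn/d. The reflectivity is obtained by integrating the detector map
over a narrow in-plane band |q_par| ≤ w (default w = 0.05 Å⁻¹, exposed as
a parameter since integration-box conventions differ between instruments).
Peaks are fitted as Gaussians over a local linear background; integrated
intensities are the analytic Gaussian areas, which is robust to the fitted
width. Orders are assigned by bootstrapping from the strongest peak and
testing every hypothesis "strongest = order m"; candidates with
|q/q₁ − n| > 0.05 are rejected, and d comes from a least-squares fit of
q_n = n·(2π/d) through the origin, which makes d exactly invariant to
intensity rescaling.

For a centrosymmetric bilayer the form factor F(q_n) = √(I_n q_n) is real
and only its sign ν_n = ±1 is unknown. The relative electron density is
the truncated cosine series ρ(z) = (2/d) Σ √(I_n q_n) ν_n cos(2πnz/d),
affinely normalised to ρ(0) = 0 and ρ(±d/2) = 1 (the absolute electron
scale is not recoverable from relative intensities, and is out of scope).
The head–head distance d_HH is twice the position of the global maximum on
the z > 0 half, refined by a parabola through the three grid points around
the discrete maximum; the z-grid has 512 points per period so that the
sub-grid refinement supports ångström-level readouts. The water layer is
d − d_HH.

Two phase routes are provided. The default phase array is
[−1, −1, 1, −1, 1], the standard head-group assignment for bilayer stacks
in this d-range; beyond five orders it is extended by the sign of
cos(q_n z_ref) with z_ref = 20 Å (the head-group cosine heuristic — for a
density dominated by head maxima near ±z_ref the form factor's sign
follows that cosine). Alternatively all 2^N sign arrays are enumerated
(capped at N = 12) and scored for physical plausibility: the score rewards
a head-band maximum (|z| between 0.25 d and 0.47 d) well above both the
centre density (the CH₃ trough) and the boundary density (inter-membrane
water sits between trough and head densities), and penalises profiles
whose global maximum falls outside the head band. On forward-modelled
two-Gaussian bilayers this score recovers the generating signs for all
five orders, including through Poisson noise.

Stack orientation uses the Hermans function H = (3⟨cos²Φ⟩ − 1)/2 on the
intensity along the arc |q| = q₁. ⟨cos²Φ⟩ is taken with sin Φ solid-angle
weighting, the standard fibre-texture convention, so an isotropic profile
gives exactly H = 0 and a δ-like profile H = 1. By default the moment is
evaluated under a Gaussian fitted to the arc profile (centred at Φ = 0);
a `method = "raw"` path integrates the extracted profile directly for
profiles that are not Gaussian-like, such as the isotropic limit.

## In-plane analysis

The wide-angle region carries three overlapping correlation peaks: a
protein (coiled-coil) peak near 0.7 Å⁻¹ and the hexagonally packed lipid
chain peaks of the l_d (≈1.35 Å⁻¹) and l_o (≈1.73 Å⁻¹) phases. A
polynomial background (degree ≤ 3) is fitted to peak-free anchor windows
and subtracted; the three Gaussians are then fitted simultaneously with a
residual linear term, which absorbs anchor-window leakage and makes the
noise-free decomposition exact. Chain spacing a = 4π/(√3 q) and area per
tail A_T = (√3/2)a² follow from hexagonal (p6) packing; for the protein
peak the hexagonal convention is the default (it reproduces the reported
spacing magnitudes) with the linear 2π/q convention exposed as an option.
Scherrer sizes convert the q-space FWHM (2√(2 ln 2)·σ of the fitted
Gaussian — the 0.94 Scherrer constant assumes FWHM) through the diffraction
angle θ = asin(qλ/4π). No instrumental-broadening deconvolution is applied,
so the sizes are upper limits, and the output carries that caveat. Domain
fractions normalise the l_d and l_o areas over the two lipid components
only, excluding the protein peak.

## Caillé analysis of diffuse scattering

The stack is modelled as a discrete smectic: per-layer bending energy
κ/2 (∇²u_n)² and harmonic inter-layer coupling B/2 (u_{n+1} − u_n)².
The mode spectrum kBT/(κq⁴ + 2B(1 − cos kd)) gives the height-difference
correlation function through an exact Brillouin-zone integral,

δ_n(r) = 2 ∫ q dq/2π · [1 − z(q)^n J₀(qr)] / √(a(a+4B)),   a = κq⁴,

with the lattice Green's function weight z = 2B/(a + 2B + √(a(a+4B)))
evaluated in a cancellation-free form. Two exact limits anchor the
numerics: at r = 0 the integral has the closed form
δ_n(0) = (2η/q₁²)(ψ(n+½) − ψ(½)) (ψ the digamma function) — the discrete
analogue of the Caillé logarithm — and at large lateral separations the
continuum asymptotics
δ_n(r) = (2η/q₁²)(ψ(n+½) − ψ(½) + ln u + E₁(u) + γ), u = r²/(4ξ²n),
(n = 0: (2η/q₁²)(2 ln(r/ξ) + 2γ)) hold to well below 0.1 Å². The
implementation is a hybrid: log-grid quadrature where the Bessel factor is
resolved, closed-form asymptotics beyond u = 6, which keeps the absolute
error of the assembled structure factor at the 10⁻³ level over the fitted
q-range (verified against brute-force adaptive quadrature).

The structure factor is

S(q_z, q_r) = Σ_n H_z(n) cos(q_z n d) ∫ r dr H_r(r) J₀(q_r r) exp(−q_z² δ_n(r)/2).

H_r(r) = exp(−r/r_domain) is the lateral finite-size envelope. For the
layer window H_z the package uses the triangular (Fejér) form 1 − n/N —
the exact pair count of an N-layer stack — rather than a truncated
exponential: a hard truncation of a slowly decaying window acts as a
Dirichlet kernel and can ring S negative between the Bragg peaks, while
the Fejér window keeps S ≥ 0 everywhere. N is not measurable from the data
(several hundred membranes are deposited; the coherent subset is smaller)
and defaults to 100 as a configuration parameter. The radial integral is
evaluated by expanding the smooth factor H_r·exp(−q_z²δ/2) as piecewise
linear in ln r on ~200 knots and precomputing the oscillatory moments
∫ r J₀(q_r r) φ_j(ln r) dr once per fit with Gauss–Legendre sub-panels
sized to the Bessel oscillation; a model evaluation then costs two small
matrix products. The relative accuracy target of the radial quadrature is
10⁻⁴ in the well-conditioned region, degrading to ~10⁻² only in the
pathological rigid limit at large q_r.

The two-cut fit follows the canonical protocol: cuts at q_z = 2·q₁ and
2.5·q₁ fitted simultaneously on log intensity with uniform weights
(counting weights are unavailable for arbitrary inputs), free parameters
log κ, log B, one log amplitude per cut (absolute scale is
instrument-dependent) and optionally log r_domain within a factor 4 of its
initial value — the envelope scale is only weakly identified and an
unbounded search trades it off against κ. The optimizer is bounded
Levenberg–Marquardt (tolerance 10⁻⁸, max 500 iterations); uncertainties
are 95% half-widths (two standard errors) from the Hessian, with an SVD
pseudo-inverse when a direction is flat. Generator and fit share one
canonical quadrature (node placement independent of the model parameters),
so fitting the model to its own noise-free output recovers κ and B to
optimizer tolerance.

Two independent routes validate the machinery. First, a Monte-Carlo
oracle samples layer-displacement fields of a small periodic stack from
the exact Gaussian distribution of the harmonic energy (free-end chain
eigenmodes in the layer index, FFT modes in-plane) and computes the
brute-force scattering sum |Σ ∫ e^{i(q_z(nd+u_n)+q_par·r)}|²/A; the
package's finite-stack expectation assembles the same quantity from pair
correlations via the Gaussian cumulant identity and Fourier transforms.
The two agree within Monte-Carlo error on a 4-layer, 64² instance — the
δ→S mapping, not the shared mode variances, is what this validates.
Second, the one-dimensional (in-plane integrated) line shape built from
the digamma correlations decays as |q_z − q₁|^−(1−η) near the first peak,
the classical Caillé exponent; the package reproduces that slope
numerically over the asymptotic window (measured between the finite-size
cutoff and the inter-peak region, on a stack large enough that the window
is genuinely asymptotic).

## Helfrich–Canham fluctuation analysis

The transform convention is fixed package-wide:
H_q = (Δ²/√A) Σ_r h(r) e^{−iq·r} (Δ the grid spacing, A the box area), so
the tensionless-membrane equipartition reads ⟨|H_q|²⟩ = kBT/(κq⁴) with no
extra area factor; generator and analyser share the convention by
construction.

Head beads define the surfaces; role tags are taken from the trajectory
and never inferred. Scattered beads are gridded by deterministic
nearest-node averaging over the periodic box (exact duplicates therefore
average deterministically) with empty nodes filled by iterative
8-neighbour relaxation — a nearest-neighbour-style fill. No Delaunay
triangulation is used; at the wavelengths that enter the fit (q < 0.1 Å⁻¹,
i.e. modes of index ≲ 6 on a 340 Å box) the gridding transfer function is
indistinguishable from 1, and the residual bead-sampling noise appears as
a white floor far below the q⁻⁴ signal. The mid-plane field is the mean of
the two leaflet grids with the spatial mean removed (the q = 0 mode is
always dropped; thickness fluctuations cancel by construction).

Radial averaging uses annuli of width 2π/L (elliptical in (q_x L_x,
q_y L_y) for non-square boxes). Each annulus is labelled with the
q⁻⁴-unbiased effective magnitude (mean q⁻⁴ over member modes)^(−1/4):
annuli mix modes of different |q|, and labelling them with the bin index
alone biases a steep q⁻⁴ spectrum by ~15% in κ. The fit holds the
exponent at −4 (the Helfrich–Canham form) and estimates only the
intercept, weighted by per-bin mode counts; κ = kBT/exp(intercept). A
free-slope mode reports the fitted exponent as a diagnostic, and fits
requested above q = 0.1 Å⁻¹ are flagged as out of the q⁴ regime —
real spectra bend there as molecular tilt and protrusion modes take over.
The default equilibration discard is 200 ns.

## Trajectory maps

Component density maps are per-frame-normalised 2-D histograms of wrapped
bead positions. Domain sizing replaces the original manual edge-point
measurement with a deterministic procedure — threshold at
median ± k·MAD (k = 1 by default), 8-connected labelling with periodic
seam merging, equivalent-circle diameter from pixel area, components of
fewer than 4 bins discarded — so results are comparable to manual sizing
in magnitude, not in method, and the threshold used is reported.
Out-of-plane profiles are mass-weighted z-histograms divided by slab
volume, in kg/m³ (1 u/Å³ = 1660.54 kg/m³); total mass is conserved to
10⁻⁶ relative by construction, which the tests assert.

## Lipidomics mapping

Measured species (class, two tail lengths, double bonds per tail) map to a
curated catalogue of coarse-grained model lipids by minimising
e = w_len(|Δt₁| + |Δt₂|) + w_sat(|Δdb₁| + |Δdb₂|). The weighting between
tail length and saturation is not dictated by the method; equal weights
are the default and both are exposed. Class must match exactly before
comparison; cross-class fallback is opt-in and flagged. Ties break
lexicographically by model name so the mapping is a pure function of its
inputs. The catalogue ships as a plain CSV of Martini-2.2-style models —
the mapping logic, not the force field, is the subject here — and
cholesterol enters as a configured mole fraction rather than through the
mapper, since its content is set exogenously (30 or 50 mol% in the
membrane models). Leaflet asymmetry is applied per class by
largest-remainder rounding (upper leaflet first on ties), which conserves
totals exactly and keeps every class within one lipid of its target
fraction.

## What the synthetic generators emulate — and what they do not

The generators define the study conditions under which the pipeline is
verified:

* `gen_lamellar_map()` — lamellar peaks at n·2π/d for d ≈ 55–57 Å with
  form-factor intensities I_n = F(q_n)²/q_n from a two-Gaussian bilayer
  density (heads near ±20 Å), Gaussian radial resolution and mosaic
  smearing, Poisson counting noise (`counts_scale` expected counts in the
  brightest pixel).
* `gen_inplane_pattern()` — the 0.70/1.35/1.73 Å⁻¹ triplet with widths
  consistent with the reported Scherrer sizes (FWHM ≈ 5.9/ζ), a low-order
  polynomial background (the actual instrument background is not
  documented; a polynomial is a stand-in), Poisson noise.
* `gen_diffuse_cuts()` — the analytic structure factor at 2·q₁ and 2.5·q₁
  with 3% multiplicative Gaussian noise, the regime of the stored-membrane
  measurements (κ between about 1.9 and 5.3 kBT; B ≈ 1.2×10⁻⁵ kBT/Å⁴,
  which puts η near 0.1 and ξ near 20 Å).
* `gen_height_trajectory()` — Helfrich-distributed height fields
  (Hermitian Gaussian Fourier amplitudes, q = 0 excluded) sampled by
  ~0.022 beads/Å² per leaflet (one head bead per ≈45 Å² lipid, matching
  ≈2,500 lipids per leaflet on a 340 Å box), two leaflets at ± half a
  nominal 40 Å thickness, 0.5 Å vertical jitter, frames every 4 ns from
  200 ns.
* `gen_lipidomics_table()` — a fresh red-cell class profile (PC ≈ 32%,
  PE ≈ 24%, SM ≈ 14%, fatty acids < 1%) and a storage signature (fatty
  acids ≈ 5%, ≈5 percentage points of tail abundance moved to 8–12-carbon
  tails, slightly higher unsaturation).

Passing tests on these inputs demonstrates that the estimators invert
their own forward models at realistic noise and sampling — it does not
demonstrate robustness to what the generators omit: instrument-specific
backgrounds and detector artefacts, resolution-function asymmetry,
mosaic/substrate disorder beyond a Gaussian spread, correlated dynamics in
simulation frames (frames here are independent draws), protein-induced
spectral corrections, or mass-spectrometry identification errors upstream
of the lipid tables.

## Problem sizes used in the verification suite

The recovery studies run at the sizes a careful desk verification would
use: 20 seeded two-cut replicates at 3% noise across κ ∈ {1.9, 4.6, 5.3}
kBT for the Caillé fit; five 450-frame, 128²-grid trajectories for the
Helfrich–Canham fit; a 4-layer, 64², 200-realisation instance for the
Monte-Carlo oracle comparison; 1,000 random species for the mapping
oracle. The larger asymptotic stack (N ≈ 3×10⁴ layer window) appears only
in the Caillé-exponent check, where the power law needs room to develop.

## Known limitations

* The Caillé fit inherits the κ–r_domain degeneracy of envelope-limited
  data; the envelope scale is bounded rather than free, and fits that end
  on a bound are flagged.
* Scherrer sizes are upper limits (no deconvolution), and the domain
  fractions assume the three-peak decomposition is complete.
* The electron-density reconstruction is band-limited by the observed
  orders: d_HH from a five-order series differs from the underlying
  continuous density's head spacing by a truncation shift that the tests
  measure against the truncated-series oracle, not against the continuous
  truth.
* The fluctuation analysis assumes a tensionless, planar, protein-free
  patch; the q⁻⁴ fit window must stay below 0.1 Å⁻¹.
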