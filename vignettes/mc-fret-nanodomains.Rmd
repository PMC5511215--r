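---
title: "Detecting lipid nanodomains by Monte Carlo FRET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lipid nanodomains by Monte Carlo FRET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcfret)
```

## The measurement problem

Sphingomyelin (SM) and cholesterol (Chol) can organize liquid-disordered
phosphatidylcholine bilayers into nanoscopic domains far below the optical
diffraction limit. Förster resonance energy transfer (FRET) between
membrane probes is sensitive to such organization: when donors and
acceptors redistribute between domains and the surrounding bilayer, the
donor fluorescence decay changes in a way that encodes the domain radius
`R_D`, the fractional area coverage `Ar`, and the probes' partition
coefficients `K_D` (the ratio of probe surface concentration inside versus
outside the domains). Because the effect is driven by the domain boundary,
radii between roughly 2 and 50 nm are accessible — exactly the range where
imaging techniques struggle.

Three regimes matter. With equally partitioning probes (`K_D = 1` for both
species) the decay is identical to a homogeneous bilayer: domains are
invisible. When donors enrich in domains and acceptors are excluded, the
species separate and FRET slows the decay less (efficiency drops). When
both species co-enrich, the locally increased acceptor concentration
speeds the donor decay up. The package quantifies this with the relative
FRET efficiency `E_rel = E_hetero / E_homo`.

There is no closed-form decay model for a domain-containing bilayer, so
the forward model is Monte Carlo: simulate bilayer scenes, compute each
donor's total transfer rate, sample transfer times, and build the survival
function `G(t)`. The inverse problem is a chi-squared scan of simulated
decays against the measured one over a grid of `(R_D, Ar, K_D)`.

## Bilayer scenes

`place_domains()` packs non-overlapping disks of radius `R_D` into a
periodic box by random sequential adsorption; when insertion stalls,
small-displacement Metropolis sweeps open gaps, which reaches coverages up
to `Ar = 0.6` (sequential insertion alone jams near 0.547). The domain
number density is `Ar / (pi R_D^2)`. Packing failure raises an explicit
error rather than silently under-filling. Domains are registered across
the two leaflets: one two-dimensional domain pattern, with fluorophores on
two planes separated by `h` (default 4.0 nm, appropriate for
headgroup-labelled probes on opposite leaflets).

`place_probes()` assigns each probe to the domain union with probability
`K_D Ar / (K_D Ar + 1 - Ar)` — the area-weighted consequence of the
partition-coefficient definition — places it uniformly within the union or
its complement, and splits each species evenly between leaflets.

Minimum-image periodic distances are used throughout. A contact clamp
(default 0.5 nm) bounds donor-acceptor approach so the `r^-6` transfer
rate cannot diverge.

## The Monte Carlo decay model

Each donor's total transfer rate sums the pairwise Förster rates over all
acceptors on both leaflets,

    Omega_i = sum_j (1 / tau_bar) * (R0 / r_ij)^6,

with `tau_bar` the amplitude-weighted mean intrinsic donor lifetime and
cross-leaflet distances `sqrt(rho^2 + h^2)`. An excitation event picks a
donor uniformly at random and samples the transfer time by inversion,
`dt = -log(gamma) / Omega_i` with `gamma` uniform on (0, 1]. Each
generated scene is reused for 100 events before a new scene is drawn;
3 × 10^5 events build the default survival histogram. Events beyond the
observation window (100 ns, matching a 10 MHz excitation rate) — including
donors with no acceptor in reach (`Omega = 0`) — are censored into the
tail, never dropped. Donor-donor transfer, acceptor depletion and
re-excitation are outside the model: one excitation per event, acceptors
always available.

`simulate_survival()` offers two estimators of the same quantity. The
`"histogram"` method samples events as above. The `"expectation"` method
returns the exact expectation of that sampling scheme over the same
scenes, `G(t) = <exp(-Omega_i t)>` averaged over donors and
configurations: it carries scene-sampling variance but no event-sampling
variance, which makes it the right choice inside the fitter where
thousands of model decays are compared. The two agree within binomial
error by construction, and the test suite asserts exactly that.

A measured-looking decay is composed as
`F(t) = [sum_m a_m exp(-t / tau_m)] * G(t)`, optionally convolved with an
instrument response, scaled to a photon budget and Poisson-sampled
(`compose_decay()`). FRET efficiencies are computed from
amplitude-normalized decay areas, `E = 1 - integral(F_DA) / integral(F_D)`.

## The analytic homogeneous model

For a homogeneous bilayer the donor survival has the classical planar
form implemented in `bf_survival()`:

    G(t) = exp(-c_A * sum_planes S_h(t)),
    S_h(t) = integral_0^inf [1 - exp(-(t/tau)(R0^2/(rho^2+h^2))^3)] 2 pi rho drho,

with one acceptor plane in the donor leaflet (`h = 0`) and one across the
bilayer (`h = 4 nm`). The in-plane exponent has the closed form
`pi R0^2 Gamma(2/3) (t/tau)^(1/3)`, against which the adaptive quadrature
(relative tolerance 1e-8, substitution `u = rho^2 + h^2`) is verified to
1e-6. This model serves two roles: calibrating the acceptor surface
density `c_A` from a homogeneous reference decay
(`fit_acceptor_density()`, a one-parameter profile fit with a
`delta chi^2 = 1` confidence interval), and cross-validating the Monte
Carlo simulator in the homogeneous limit — two independent routes to the
same curve.

## The inverse problem

`grid_fit()` simulates one decay per node of a grid over `R_D` (2-50 nm),
`Ar` (0-0.6) and a common `K_D` for donor and acceptor (the two are
constrained equal, as their structural similarity suggests), and scores
each node with a reduced chi-squared using Poisson weights
`max(counts, 1)` and an analytic least-squares scale factor, so absolute
intensities never matter. Three numerical choices keep the surface
usable:

* **Common random numbers.** Every node uses the same seed stream and
  shares domain layouts between nodes with equal `(R_D, Ar)`, so Monte
  Carlo noise largely cancels in comparisons between nodes.
* **Matched box sides.** The box side (at least `10 R_D` and 100 nm) is
  adjusted upward by up to 25% so the integer domain count reproduces the
  nominal `Ar`; otherwise the achieved coverage differs from the label by
  up to one domain's area, which distorts node comparisons.
* **Two-stage refinement.** Scene-sampling variance differs between
  nodes (small boxes are noisier) and inflates chi-squared where variance
  is high. The most promising nodes (within 0.3 of the coarse minimum,
  at most 48) are therefore re-simulated at 10× effort before minima are
  extracted.

All local grid minima within `delta chi^2_red = 0.05` of the best are
reported, because the chi-squared landscape genuinely supports
near-degenerate solution pairs — small domains at moderate coverage
versus larger domains at high coverage. `profile_uncertainty()` turns the
same threshold into per-parameter intervals and flags intervals that hit
the grid edge as unbounded.

Homogeneous-compatible data are detected structurally: the best
domain-blind node (`Ar = 0` or `K_D = 1`) is always refined, and when it
ties the global best within `delta` the fit is flagged degenerate — the
honest answer for a bilayer without detectable domains, for which all
domain parameters are then reported unbounded.

### A known, physical limitation

At realistic single-decay conditions (one composition, ~10^6 photons,
acceptor density from a 1:200 labelling), the chi-squared surface has a
flat valley along which increases in `R_D` trade off against increases in
`Ar` with nearly indistinguishable decays. Fits of synthetic ternary-like
data generated at `(R_D = 9 nm, Ar = 0.45, K_D = 20)` typically return a
best node on this valley — sometimes `(8-10, 0.45)`, sometimes
`(12, 0.50)` or beyond — with chi-squared differences of order 0.05-0.2,
and the binary-like scenarios show the same two-minima structure. A
single decay therefore pins down the valley, not always a unique point on
it; resolving `R_D` to ±1 nm in practice requires combining decays from
several compositions or constraining `K_D` independently. The fitter is
deliberately designed to surface this honestly through its
multiple-minima list and profile intervals rather than to hide it behind
a single best-fit number.

## Nanodomain composition accounting

`domain_lipid_counts()` converts fitted `(R_D, Ar)` and the bilayer
composition into per-domain molecule counts under two assumptions: DOPC
distributes equally between domains and the remaining bilayer, while SM
and Chol localize exclusively within the domains. A single-leaflet domain
holds `N_sites = pi R_D^2 / a` lipids at an area per lipid `a`
(default 0.72 nm^2); an equally distributed species contributes
`N_sites x_i` and a confined species `N_sites x_i / Ar`. Parameter sets
in which the confined mole fractions exceed `Ar` would imply local
fractions above one and are flagged inconsistent. The Chol:SM ratio
equals the ratio of their bilayer fractions whenever both are confined —
independent of `Ar` and `a` — which the property tests exploit.

## z-scan FCS diffusion analysis

Fluorescence correlation spectroscopy supports the FRET picture through
probe mobility. The autocorrelation model is free two-dimensional
diffusion, `G(lag) = (1/N) / (1 + lag/tau_diff)`; a triplet term is
omitted by default because the synthetic data do not include one.
Scanning the focus vertically in 20 steps of 150 nm maps the dwell time
onto the diffusion-law parabola

    tau_diff(z) = (w0^2 / 4D) * [1 + (lambda (z - z0) / (pi w0^2 n))^2],

whose fit (`zscan_diffusion_fit()`, Levenberg-Marquardt with starting
values from a quadratic regression) returns the diffusion coefficient
`D`, beam waist `w0` and focus offset `z0` without external waist
calibration. Group differences in `D` across compositions are assessed
with Welch's t-test at the 0.1 significance threshold
(`compare_diffusion()`).

## What the synthetic data emulate — and what they do not

`scenario_presets()` encodes the studied conditions: homogeneous binary
(DOPC/SM 92/8) and ternary (75/25/0) bilayers, binary nanodomain states
`(R_D, Ar) = (8 nm, 0.37)` and `(12 nm, 0.55)` at `K_D = 10`, the ternary
GM1-probe state `(9 nm, 0.45)` at `K_D = 20`, and a PEG-lipid-probe state
`(8 nm, 0.55)` at `K_D = 5`. Fixture generators write donor-only and
donor+acceptor decays (default 10^6 photons from 3 × 10^5 simulated
events) plus a machine-readable truth file, and z-scan series with
Gaussian noise at the fitted-parameter or autocorrelation level.

Defaults that the data do not dictate were fixed once: acceptor density
`c_A ≈ 0.0069 nm^-2` per leaflet from the 1:200 probe-to-lipid loading at
0.72 nm^2 per lipid; an intrinsic donor decay with components
(0.8, 5.5 ns) and (0.2, 2.0 ns), i.e. `tau_bar = 4.8 ns`, typical of
BODIPY-type labels; and `R0 = 6.0 nm`, in the upper range for such dye
pairs, chosen so the ternary nanodomain preset reproduces a relative FRET
efficiency of about 1.12 — the contrast scale these measurements show.

The generator reproduces photon statistics, probe partitioning and domain
geometry. It does not emulate instrument response broadening (convolution
is supported but off by default), detector afterpulsing or pile-up,
probe photophysics beyond a fixed multi-exponential decay, anisotropy or
orientation effects (a fixed isotropic factor is absorbed into `R0`),
domain mobility, or inter-leaflet anti-registration. Passing tests
therefore demonstrate the correctness and internal consistency of the
analysis chain under the stated model, not the validity of that model for
any particular instrument record.

## Problem sizes used by the test suite

The tests scale simulations to what the checks need: survival/oracle
comparisons run at 3 × 10^4 to 3 × 10^5 events; decay fixtures use 10^6
photons; grid-recovery experiments fit 20 replicate synthetic decays on
the full default grid with 10^3 events per coarse node (10^4 after
refinement) and 100 donors per scene; z-scan recovery uses 20-50
replicate series. These sizes are the package's choices for routine
verification; all of them can be increased through the corresponding
function arguments.
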