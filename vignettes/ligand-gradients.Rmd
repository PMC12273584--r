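---
title: "Modelling membrane-proximal ligand concentration gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling membrane-proximal ligand concentration gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligrad)
```

`ligrad` quantifies how the ligand concentration a plasma-membrane receptor
actually experiences can differ from the bulk concentration, and what that
difference does to measured binding parameters. This vignette explains the
models, the assumptions behind them, the tunable parameters, and the
numerical and design choices; it is the package's own account of its
science.

## The physical picture

A hydrophilic growth factor such as EGF is usually assumed to be
"well mixed": the concentration at the receptor equals the concentration in
the dish. Two mechanisms break that assumption near a living cell:

1. **Membrane turnover.** Rapid endocytosis/re-exocytosis cycles
   (kiss-and-run or flicker exocytosis) can act as a net ligand source at
   the membrane, sustaining a steady membrane-proximal concentration peak a
   few micrometres thick.
2. **Locally hindered diffusion.** A spatially stable viscosity gradient
   (e.g. from extracellular matrix) creates a local minimum in the
   diffusion coefficient. At steady state the flux `-d(Dc)/dr` must be
   constant, so a trough in `D` forces a peak in `c` — a membrane-distal
   concentration peak that coincides with the diffusivity minimum.

Both effects enrich ligand where the receptor is, so a titration plotted
against *bulk* concentration reports a distorted (apparently higher)
affinity and (apparently lower) cooperativity.

## FCS evaluation

Concentrations and diffusion coefficients as a function of distance from
the membrane come from fluorescence correlation spectroscopy. The package
fits the normalized autocorrelation with a triplet term and one free 3-D
diffusion component:

$$G(t) = 1 + \frac{1}{N}\,
  \frac{1 - T\,(1 - e^{-t/\tau_{\mathrm{tr}}})}{1 - T}\,
  \left(1 + \frac{t}{\tau_D}\right)^{-1}
  \left(1 + \frac{t}{\kappa^2 \tau_D}\right)^{-1/2}.$$

Parameters and defaults:

| parameter | meaning | unit | default / bound |
|---|---|---|---|
| `N` | mean particles in the confocal volume | — | fitted, > 0 |
| `T` | triplet fraction | — | fitted, bounded to [0, 0.5] |
| `tau_triplet` | triplet correlation time | s | fitted, start 5 µs |
| `tau_D` | diffusion correlation time | s | fitted, start at half-amplitude lag |
| `kappa` | axial/lateral extent of the detection volume | — | 5, **fixed** during sample fits |

`kappa` is held fixed by default because `kappa` and `tau_D` are only weakly
identifiable from a single curve; 5 is a typical value for a confocal FCS
setup and is configurable. The triplet bound of 0.5 is a fitting constraint
that prevents the fast exponential from exchanging with the diffusion
amplitude on noisy curves — it is not a physical statement. The loss is
unweighted least squares; per-point noise magnitudes for a hardware
correlator are instrument-specific and no weighting scheme is assumed.

Unit conversions: the confocal volume is $V_C = \pi^{3/2}\kappa\omega^3$,
the beam radius comes from a reference dye of known diffusion coefficient
(Alexa Fluor 546, 341 µm²/s at 25 °C) through $D = \omega^2/(4\tau_D)$,
and particle counts convert to molarity with 0.6022 particles µm⁻³ nM⁻¹.
When no calibration is supplied, conversions default to
$V_C = 0.16\ \mu m^3$, for which 1 particle/confocal volume ≈ 10 nM.
The intensity-weighted lifetime
$\tau_{\mathrm{eff}} = \sum A_i\tau_i^2 / \sum A_i\tau_i$ supports
molecular-rotor viscometry, where lifetime increases with microviscosity.

## Closed-form steady states

**Fick profile and flux.** Outside a sphere of radius $a$ with constant
$D$, the steady diffusion equation gives $r^2\,dc/dr = K_1$ and

$$c(r) = \frac{a\,(c_m - c_0)}{r} + c_0, \qquad
  J(a) = D\,\frac{c_m - c_0}{a}.$$

The geometry is an idealization — an adherent cell monolayer is not a
sphere in an infinite bath — chosen to keep the model tractable; the cell
radius defaults to $a = 10\ \mu m$. With the measured membrane and bulk
densities (18.75 and 6.25 µm⁻³, i.e. 3 and 1 particles per 0.16-µm³
confocal volume) and $D = 150$ µm²/s, the formula gives 187.5 µm⁻²s⁻¹ at
$a = 10\ \mu m$ and 625 µm⁻²s⁻¹ at a 3-µm length scale. Published
discussions of this flux use the larger figure; since the effective length
scale of the proximal gradient is genuinely ambiguous (the peak decays over
~5 µm, not over the cell radius), `membrane_flux` simply evaluates the
formula for any `a` and both worked values are exercised in the tests,
neither asserted as uniquely correct.

**Fokker–Planck steady state.** With spatially varying diffusivity the
steady state is $\nabla^2(Dc) = 0$, i.e. $r^2\,d(Dc)/dr = K_3$. The
measured dip is described by $D(r) = p_1(r-p_2)^2 + p_3$ (defaults
$p_1 = 0.32$, $p_2 = 23.47\ \mu m$, $p_3 = 91.32\ \mu m^2/s$) — fitted in
original space with $p_3 > 0$, because that is the functional form actually
printed for the measured dependence — and the exact solution is

$$c(r) = \frac{K_4 r - K_3}{D(r)\, r},$$

with $K_3, K_4$ from the 2×2 linear system of two Dirichlet conditions.
The constants are always recomputed from the supplied boundary conditions;
for the boundary values $c(13) = c(35) = 2$ this yields
$K_3 \approx 308.7$, $K_4 \approx 276.5$ and an interior maximum of ≈ 2.88
particles/confocal volume near $r = 23.5\ \mu m$. Reference constants
printed elsewhere for the same problem (291.2, 275.56) differ by 1–6 %,
consistent with unrounded upstream parameters; they are kept as metadata,
never used as an oracle. The tests validate the closed form against an
independent shooting integration of the boundary-value problem at
tolerance 10⁻⁸.

## The reaction–diffusion simulator

Free ligand `L` diffuses; receptors `R` and complexes `LR` are immobile
membrane species:

$$\partial_t L = \frac{D}{r^2}\partial_r(r^2 \partial_r L)
  + k_{\mathrm{off}} LR - k_{\mathrm{on}} L R,\qquad
  \partial_t LR = -\partial_t R = k_{\mathrm{on}} L R - k_{\mathrm{off}} LR.$$

Defaults: $D = 150\ \mu m^2/s$, $k_{on} = 0.0023\ (nM\,s)^{-1}$,
$k_{off} = 0.003\ s^{-1}$ ($K_d \approx 1.3\ nM$), domain
$[10, 100]\ \mu m$, 400 uniform cells.

Numerical choices:

* **Conservative finite volumes.** Fluxes are evaluated at shell faces and
  divergences as $(A_{out}F_{out} - A_{in}F_{in})/V$, so with zero-flux
  boundaries total ligand is conserved to solver tolerance by construction
  (the tests require < 10⁻³ relative drift and observe ~10⁻¹⁵).
* **Stiff implicit integration** via `deSolve::ode(method = "lsodes")`,
  relative tolerance 10⁻⁶, absolute 10⁻⁹ nM. The receptor shell makes the
  system stiff: binding in the first cell relaxes on ~10 ms while
  equilibration of the whole domain takes hundreds of seconds.
* **Receptor localization.** The narrative of the underlying experiments
  adds receptors "to the plasma membrane" while the equations treat them as
  fields; here receptor fields are nonzero only within a membrane shell of
  configurable thickness (default: the first grid cell), with reactions
  applied pointwise. Whether the original computation used one mesh point
  or a finite shell is not documented, so the thickness is exposed as a
  parameter.
* **Instantaneous additions** (scenarios S1 and S3) are initial conditions
  at $t = 0$, not delta-function sources.
* **S4 source** is an inner-boundary influx condition
  $-D\,\partial_r L|_a = -J$ (a flux is the quantity the Fick arithmetic
  produces), with the outer concentration clamped by a Dirichlet condition.

The four scenarios reproduce the qualitative fingerprints that matter:
S1 (receptor introduction) gives a transient *negative* membrane peak and a
spatially uniform equilibrium satisfying detailed balance
$k_{on} L R = k_{off} LR$; S2 (distant bolus) ends homogeneous; S3
(exocytosis pulse of liganded receptor) gives a transient *positive* peak;
S4 (continuous source) a *permanent* positive peak whose steady state
matches the analytic solution
$c(r) = c_0 + (J a^2/D)(1/r - 1/R_{out})$ within 1 %.

Two quantities are not documented in the source material and are package
choices, made once: the S1/S3 receptor surface density, sized by scalar
root-finding on the 0-D conservation law
$L_0 V = L_{eq} V + R_T \frac{L_{eq}}{K_d + L_{eq}} V_{shell}$ so that
equilibrium ligand depletion is 10 % (the documented design figure), and
the S4 influx, defaulting to 625 molecules µm⁻²s⁻¹ — the flux the Fick
budget associates with the observed proximal gradient.

## Binding distortion

If the membrane concentration relates to bulk as
$c_{mem} = A\,c_{bulk}^{\,b}$ (the power-law shape captures enrichment that
fades at high bulk concentration; $b < 1$), then a receptor following the
Hill equation in $c_{mem}$ appears, when plotted against $c_{bulk}$, as an
exact Hill curve with

$$n_{app} = n\,b, \qquad K_{app} = (K_d/A)^{1/b}.$$

This algebraic identity is the module's core correctness oracle: the
fitted apparent parameters must match it to 10⁻⁶ on noiseless data. The
default mapping is *reconstructed* from two observed anchor points
(≈ 3-fold enrichment at 10 nM, none at 100 nM), giving $b = 1 - \log_{10}3
\approx 0.523$ and $A = 9$; for the true parameters (15 nM, $n = 2$) it
produces apparent values ≈ 2.66 nM and ≈ 1.05. The exact mapping
originally used to report apparent values of 3 nM and 1.3 is unpublished,
so those printed numbers are a direction check (higher apparent affinity,
lower apparent cooperativity), not a numeric target. Hill fits are
parameterized in $\log K_d$ for stable optimization, and titration fits of
normalized experimental data may include a free maximal amplitude, because
such data are scaled to the highest-concentration response.

## Synthetic data

The generators produce every input the analyses consume, deterministically
given a seed, and collapse to their noiseless forward models at σ = 0:

* `gen_acf_curves`: the autocorrelation model on 200 quasi-logarithmic lags
  (300 ns – 1 s) plus additive Gaussian noise (default σ = 0.005 on G).
* `gen_radial_profiles`: sampling every 1 µm to 20 µm from the membrane,
  then every 10 µm to 100 µm. The proximal peak is an exponential
  enrichment (amplitude 3× bulk, 5-µm decay length — the reported extent
  and amplitude; the exponential *shape* is a modelling choice, as no
  functional form was measured). The distal peak is never drawn
  independently: it is the Fokker–Planck excess of the diffusivity dip,
  anchored at 2× bulk (the measured particle count) at 3 and 25 µm from
  the membrane, so the concentration–diffusivity anticorrelation is
  structural. Noise is multiplicative lognormal (default σ = 0.05).
* `gen_titration`: Hill saturation at power-mapped (cell-like) or identity
  (GPMV-like; giant plasma-membrane vesicles have no membrane turnover and
  hence no proximal peak) concentrations.
* `gen_decay_histogram`: one multinomial draw over TCSPC bins from a
  multi-exponential decay density, with a companion `fit_decay` for
  recovery studies.

What passing tests on these data do and do not show: they demonstrate that
the estimators recover the parameters of their own generating models under
realistic noise magnitudes, and that the pipeline's formats round-trip.
They cannot validate the biological shape assumptions (exponential
proximal decay, parabolic diffusivity dip, lognormal noise) against real
instrument data, which are not redistributable.

## Problem sizes and tolerances

Unit tests run the simulator on 100–200-cell grids; the end-to-end checks
use the 400-cell default. Equilibria are probed at 3000 s, about seven
times the slowest relaxation time of the coupled system (~40 s for binding
at 10 nM ligand plus diffusion). Grid-convergence tests require reported
equilibria to move by < 0.2 % when the cell count doubles. Noise-recovery
studies use 30–100 seeded replicates. The Fokker–Planck oracle integrates
with `lsoda` at 10⁻¹² tolerances; exact linear-system and arithmetic
identities are asserted at 10⁻¹²–10⁻⁶ as appropriate.

## Known limitations

* Spherical symmetry everywhere; no adherent-monolayer geometry, membrane
  curvature, or 2-D/3-D solvers.
* Receptors neither diffuse nor internalize; no explicit
  endocytosis/recycling compartments — the exocytosis scenarios emulate
  sources, not full trafficking.
* Single-component ACF model only: no anomalous diffusion, membrane
  (2-D) terms, cross-correlation, or instrument-response deconvolution.
* The bulk→membrane mapping is a memoryless power law; ligand depletion
  during a titration is handled by the reaction–diffusion module, not the
  binding module.
* Deterministic continuum description; at femtomolar concentrations
  stochastic kinetics would be required.
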