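---
title: "Quantifying cold-adaptation of enzyme barriers with coldevb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cold-adaptation of enzyme barriers with coldevb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldevb)
```

## The scientific problem

Cold-adapted (psychrophilic) enzymes achieve high catalytic rates near 0
degrees C not by lowering their activation free energy
$\Delta G^\ddagger$ outright — wildtype psychrophilic and mesophilic
orthologs typically differ by only ~1 kcal/mol — but by *repartitioning* it.
The psychrophilic enzyme carries a much lower activation enthalpy
$\Delta H^\ddagger$, paid for by a more negative activation entropy
$\Delta S^\ddagger$. Because the temperature-dependent decay of rates goes as
$e^{-\Delta H^\ddagger/RT}$ while the entropic factor $e^{\Delta S^\ddagger/R}$
is temperature-independent, the low-enthalpy enzyme keeps more of its speed
in the cold. For the salmon (SPE) and porcine (PPE) pancreatic elastases the
computed wildtype partitioning at 22 degrees C is
$(\Delta H^\ddagger, T\Delta S^\ddagger) = (4.6, -13.4)$ and
$(17.2, -2.0)$ kcal/mol respectively, and the shift has been linked to the
mobility of a handful of surface loops: the same loops are 30–40% more
mobile (backbone RMSF) in the psychrophile, and swapping their conserved
residues between the orthologs moves both the activation parameters and the
loop mobilities toward the other enzyme.

Estimating $(\Delta H^\ddagger, \Delta S^\ddagger)$ computationally requires
free-energy profiles of the rate-limiting chemical step at several
temperatures: empirical valence bond (EVB) simulations with free-energy
perturbation / umbrella sampling along the energy-gap coordinate, repeated
over dozens of replicates per temperature, followed by an Arrhenius
decomposition. The original studies spend on the order of microseconds of
all-atom MD on this. `coldevb` implements the complete analysis layer —
EVB energetics, FEP/umbrella estimators, Arrhenius decomposition,
transition-state-theory rates, RMSF/loop-mobility analysis — and replaces
the cluster-scale molecular dynamics with a *surrogate reactive system*
whose activation enthalpy and entropy are known in closed form, so every
estimator in the pipeline can be validated against an exact oracle on a
desktop.

## The two-state EVB model

The reacting system is described by two diabatic states: the reactant
(Michaelis complex) and the tetrahedral intermediate (TI) of the acylation
step. With diabatic energies $\epsilon_1$ and $\epsilon_2$, a constant
gas-phase shift $\Delta\alpha$ added once to state 2
($\epsilon_2' = \epsilon_2 + \Delta\alpha$, see `shifted_state2()`), and a
constant coupling $H_{12}$, the adiabatic ground surface is the lower
eigenvalue of the 2x2 Hamiltonian,

$$E_g = \tfrac12(\epsilon_1+\epsilon_2') -
  \tfrac12\sqrt{(\epsilon_1-\epsilon_2')^2 + 4H_{12}^2},$$

implemented in `adiabatic_ground()`. Defaults are the published elastase
parameters $\Delta\alpha = 195.0$, $H_{12} = 113.0$ kcal/mol. Sampling is
driven from reactants to the TI by the mapping potential
$\epsilon_m = (1-\lambda)\epsilon_1 + \lambda\epsilon_2'$ over 51 evenly
spaced windows (`make_windows()`), and profiles are binned along the
energy-gap reaction coordinate $X = \epsilon_1 - \epsilon_2'$, with the
reactant at negative $X$ (a convention; the sign is arbitrary).

Free energies combine the Zwanzig exponential average between adjacent
windows,

$$\delta G(\lambda_m \to \lambda_{m+1}) =
 -RT\,\ln\big\langle e^{-(\epsilon_{m+1}-\epsilon_m)/RT}\big\rangle_m,$$

(`zwanzig_increment()`, log-sum-exp stabilised; note
$\epsilon_{m+1}-\epsilon_m = -\Delta\lambda\,X$) with the per-bin EVB
umbrella correction

$$\Delta G(X_b) = \Delta G(\lambda_m)
 - RT\,\ln\big\langle \delta_b(X)\, e^{-(E_g-\epsilon_m)/RT}\big\rangle_m,$$

combined over windows by sample-count weighting (`umbrella_profile()`).
`extract_barrier()` reads $\Delta G^\ddagger$ (reactant minimum to the
highest interior maximum) and $\Delta G_{rxn}$ (to the TI minimum) off the
normalised profile.

## The surrogate reactive system

`surrogate_system()` builds a one-dimensional reactive model: two harmonic
diabats (force constant 170 kcal/mol per unit$^2$, minima at $x = \pm 1$,
TI offset +12 kcal/mol before coupling) crossed under the full published
coupling, plus two additional ingredients that act as independent,
analytically known dials:

* **Enthalpic dial — scaffold strain.** A Gaussian energy term (width 0.4)
  centred on the transition state is added *identically to both diabats*.
  Because it is shared, it cancels exactly in the energy gap, in the
  window-to-window perturbation and in the umbrella weight $E_g-\epsilon_m$,
  so none of the estimators see it directly; it simply raises or lowers the
  barrier enthalpy. Physically it stands for strain of the protein scaffold
  at the transition state that both valence states feel alike.
* **Entropic dial — a switchable bath.** Eight harmonic bath modes have
  stiffness $k_i(x)$ that interpolates (Gaussian switch, width 0.25) between
  a reactant value (50 kcal/mol per unit$^2$) and a stiffer transition-state
  value. Integrating the bath out gives the exact free energy
  $$G(x;T) = E_g(x) + \sum_i \tfrac{RT}{2}\,\ln k_i(x) + \text{const},$$
  so the activation entropy is, by the envelope theorem, exactly
  $\Delta S^\ddagger = -\tfrac{R}{2}\sum_i \ln[k_i(x^\ddagger)/k_i(x_R)]$:
  a bath that stiffens at the transition state is the configurational-
  freezing picture of the entropic penalty, the mechanism ascribed to rigid
  mesophilic surface loops — here encoded *directionally*, with no claim
  about the quantitative loop-RMSF-to-entropy mapping, which the source
  analysis does not provide either.

`analytic_activation()` evaluates $G(x;T)$, locates its stationary points by
continuous optimisation and returns exact
$(\Delta G^\ddagger, \Delta H^\ddagger, T\Delta S^\ddagger)$; this is the
oracle for everything downstream. `build_variant()` calibrates the two dials
by a damped 2-D Newton iteration (numeric Jacobian, switching centre relaxed
self-consistently onto the free-energy maximum) until the analytic
parameters match a preset's declared targets to $10^{-4}$ kcal/mol. The 16
presets are the two wildtypes and the 14 surface-loop mutants with their
published $(\Delta H^\ddagger, T\Delta S^\ddagger)$ pairs at 22 degrees C
(`list_presets()`).

Two geometric choices matter for the estimators. The two diabats share one
force constant, which makes $X$ an exactly linear function of $x$: binning
in $X$ is then binning in $x$ and the analytic $G(x;T)$ maps onto the
sampled profile with a constant Jacobian. And the switching width (0.25) is
narrow enough that the bath is genuinely reactant-like in the reactant well
— with a broad switch the Gaussian tail stiffens the reactant bath too, and
the strongly negative psychrophilic $T\Delta S^\ddagger$ becomes
unreachable (the log-ratio saturates); this failure mode is why the width
is fixed rather than exposed as a casual tuning knob.

## Sampling

The paper's observables — free-energy profiles and RMSF — are purely
configurational, so Metropolis Monte Carlo replaces molecular dynamics;
this is the central surrogate substitution, and the per-replicate
randomisation of MD velocities maps onto per-replicate seeds. Each sweep of
the C++ sampler makes one Gaussian trial move in $x$ (bath energy at fixed
bath coordinates enters the acceptance ratio) and then resamples every bath
mode exactly from its Gaussian conditional; both kernels leave the
Boltzmann distribution invariant. The step size is tuned to 30–50%
acceptance during burn-in (first 10% of each window, discarded) and frozen
for production, preserving detailed balance. Windows are sampled in
ascending $\lambda$, each starting from the previous window's final state;
a replicate begins with a stepwise-heating equilibration from 1 K to the
target temperature in the TI state ($\lambda = 1$), mirroring the original
protocol.

The default problem sizes mirror the study protocol where it states one
(5 temperatures 285–305 K; 51 windows; 50 starting replicates, batches of
10 until the Arrhenius $R^2$ exceeds 0.8) and otherwise use desk-scale
values chosen for convergence: $10^4$ production steps per window
(config-exposed; the source does not state its per-window MD length),
thinning stride 10. Every random stream derives from one master seed by a
counter scheme — seed $= 2^{32}\cdot\text{master} + c$ with
$c$ indexing (variant, temperature, replicate, window) in mixed radix —
so any replicate or window can be regenerated in isolation and runs are
bit-reproducible.

## Arrhenius decomposition and rates

The Arrhenius plot in this analysis is $\Delta G^\ddagger/T$ against $1/T$:
since $\Delta G^\ddagger = \Delta H^\ddagger - T\Delta S^\ddagger$ with
constant $\Delta H^\ddagger, \Delta S^\ddagger$, the slope is
$\Delta H^\ddagger$ and the intercept $-\Delta S^\ddagger$
(`arrhenius_fit()`, ordinary least squares by default with
inverse-variance weighting behind a flag; the fitted object satisfies
$\Delta G^\ddagger(T_{ref}) = \Delta H^\ddagger - T_{ref}\Delta S^\ddagger$
identically). Per-replicate barriers are extracted first and then averaged
per temperature — rather than averaging profiles and extracting once —
because the replicate dispersion drives both the convergence rule
(`converge_activation()`) and the percentile bootstrap
(`bootstrap_ci()`, resampling replicates within each temperature and
refitting).

Rates use plain transition-state theory,
$k = (k_B T/h)\,e^{-\Delta G^\ddagger/RT}$ with unit transmission
coefficient and constants $R = 1.987204\times10^{-3}$ kcal/(mol K),
$k_B/h = 2.083661\times10^{10}$ s$^{-1}$K$^{-1}$ (`tst_rate()`).
Temperatures convert as $T = $ degrees C $+\ 273.15$; 295.15 K (not 295 K)
reproduces the published wildtype SPE rate at 22 degrees C exactly, which
fixes the convention. The published rate table's "$\times 100$ s$^{-1}$"
unit is interpreted as printed value $= k(\mathrm{s}^{-1}) \times 100$:
with $\Delta G^\ddagger = 18.0$ kcal/mol, $k = 0.289$ s$^{-1}$, printed
28.9. `rate_table()` and `table_report()` emit both columns, rounded
half-even to one decimal in the published layout, and
`compare_variants()` / `activity_ratios()` implement the mutant-vs-wildtype
arithmetic (rate ratios, percent of wildtype activity,
$\Delta\Delta G^\ddagger = \Delta\Delta H^\ddagger - T\Delta\Delta
S^\ddagger$ bookkeeping).

A note on the published tables: at printed (one-decimal) precision not
every row satisfies $\Delta G^\ddagger = \Delta H^\ddagger - T\Delta
S^\ddagger$ at 295.15 K, and most rate entries cannot be regenerated from
the rounded activation parameters (the originals evidently used unrounded
fit output). Only internally consistent rows (both wildtypes, the SPE
S218L/A221V mutant) are used as exact identity checks; ratio checks use
the printed rates themselves as inputs.

## Backbone mobility

The flexibility module mirrors the mobility protocol: iterative
superposition ("iterpose") — alternate Kabsch superposition of every frame
onto the running average with recomputation of the mean until the average
moves less than $10^{-4}$ Å (`iterative_average()`) — followed by per-atom
RMSF about the superposed mean (`rmsf()`), per-loop averages and percent
change versus a reference variant (`loop_report()`). Protocol mirrors:
backbone means atoms N, CA, C (O excluded; config-exposed); the
superposition mask is the whole-protein backbone, so loop RMSF is measured
in the frame of the stable core rather than self-fitted; replicate
trajectories (four independent runs in the original protocol) are averaged
at the RMSF level before ratios are taken; and a `discard_fraction = 1/6`
flag drops the equilibration sixth of each trajectory (2 ns of 12 ns).
Multi-loop aggregation for the one-bar-per-mutant report is the mean of
per-loop percent changes; the source does not state its aggregation, so
this is a documented package choice.

The synthetic ensembles (`flex_profile()`, `generate_backbone_ensemble()`)
are a bead-chain backbone (3 beads/residue on a coil-like reference) with
independent zero-mean Gaussian displacements per frame — per-coordinate
amplitude $\sigma$ gives per-atom RMSF $\sigma\sqrt3$ — raised by a
multiplier (default 1.35, the midpoint of the reported 30–40% contrast)
inside five synthetic loop regions, plus an optional random rigid-body
transform per frame to exercise the superposition machinery. Frames are
statistically independent: unlike real MD there is no autocorrelation, no
anisotropy, and no coupling between residues, so these ensembles validate
the estimators, not the physics of real trajectories. Trajectories
round-trip through multi-model PDB (via the bio3d reader, 0.001 Å
precision) and plain XYZ frame files.

## Numerical choices and degenerate inputs

* Binning: 100 bins over the pooled $X$ range trimmed to its 0.5–99.5
  percentiles; a window contributes to a bin only with $\ge 10$ raw frames
  (bounds the variance of the log-average). Unsupported bins are masked,
  never interpolated; a support gap between the two minima raises a
  "barrier unresolved" error naming the $\lambda$ region to densify.
* Degenerate multi-maximum profiles take the highest interior maximum
  between the outermost minima.
* Parameter sets whose ground surface is not a double well are rejected
  with a degeneracy error at construction.
* Calibration is numerical root-finding at build time against the analytic
  oracle, never hand-tuned constants; presets are cached per session.
* Zero-acceptance sampling raises a sampler-failure error naming the
  window.

## What the tests do and do not show

The test suite validates every estimator against an independent oracle:
closed-form results (Gaussian Zwanzig limit, equipartition, $\sigma\sqrt3$
RMSF), numerical quadrature (endpoint free energies, exponential
averages), brute-force reimplementations (two-pass RMSF, eigensolve of the
EVB Hamiltonian), an established independent superposition routine
(bio3d), and the analytic surrogate profile (converged umbrella profiles
agree to < 0.15 kcal/mol at $2\times10^5$ samples/window). The end-to-end
acceptance run — 10 replicates of $10^4$ steps/window at the five protocol
temperatures for all 16 presets — recovers each wildtype's declared
$(\Delta H^\ddagger, T\Delta S^\ddagger)$ within its 99% bootstrap CI and
reproduces the direction of every declared mutant shift of at least
2 kcal/mol (about four standard errors at this problem size; smaller
declared shifts, including the -186D insertion that the source itself
reports as the exception with an unchanged $\Delta H^\ddagger$, are below
desk-scale resolution and are not sign-checked). Passing these tests shows
the *analysis machinery* is correct and unbiased at the stated problem
sizes; it does not validate all-atom energetics, force fields, or the
quantitative link between loop RMSF and activation entropy, all of which
live outside the surrogate by design.

## Known limitations

* One reaction coordinate; no multi-state (>2) EVB, no recrossing or
  quantum corrections (transmission coefficient 1, as in the source
  analysis).
* The bath encodes the entropy-flexibility link directionally only.
* Constant $\Delta H^\ddagger, \Delta S^\ddagger$ over 285–305 K (no heat
  capacity term), as the rate extrapolations to 4 and 39 degrees C assume.
* Synthetic backbone ensembles have no kinetics; RMSF convergence rates on
  real correlated trajectories will be slower than on these independent
  frames.

## Configuration and reproduction

`validate_config()` accepts a single YAML file whose defaults are the full
study protocol; `run_pipeline()` executes sampling, convergence, fitting,
bootstrap and report generation (activation and rate tables, Arrhenius
plot, provenance log with the seed table) deterministically from one
master seed. `scripts/acceptance.R` recomputes the package's headline
numbers from scratch; see the README for how to run it.
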