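---
title: "Quantifying CH-pi interactions from host-guest titration data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CH-pi interactions from host-guest titration data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calixchpi)
```

## The measurement strategy

A single CH-π contact is too weak to measure directly in solution. The
strategy implemented here is a *chemical double difference*: bind the same
guest to two receptors that differ only in their aromatic walls, and
attribute the difference in binding free energy to the wall-guest contacts.

The model systems are calix[4]pyrrole receptors binding trimethylamine
*N*-oxide (**2a**) or trimethylphosphine *P*-oxide (**2b**) in
acetonitrile. All receptors clamp the guest's oxygen with the same four
pyrrole NH···O hydrogen bonds; the octamethyl receptor **1a** has no walls,
the "two-wall" receptors (**1b**–**1d**) place two *para*-substituted
phenyl rings next to two guest methyls, and the "four-wall" receptors
(**1e**–**1f**) surround the guest completely. Then

$$\Delta\Delta G = \Delta G(\text{walled}) - \Delta G(\text{reference})$$

isolates the CH-π contribution, and dividing by the number of contacts
(2 or 4, one methyl per wall, as seen in the crystal structures) gives a
per-interaction energy. The assumption behind the subtraction is that the
hydrogen-bonding core, solvation of the polar ends, and guest entropy
penalties cancel between the two complexes; what does not cancel (residual
conformational differences, wall desolvation) is absorbed into the CH-π
estimate, which is why it is an operational, not a spectroscopic, quantity.

The electronic question — are these contacts electrostatic or dispersive? —
is answered by a *pseudo-Hammett* plot: regress the CH-π free energies on
the electrostatic surface potential (ESP) computed at the centre of the
aromatic ring for each *para*-substituent. A slope near zero means the
interaction does not respond to the ring's electrostatics, the signature of
a dispersion-dominated ("typical") CH-π contact between non-acidic C–H
donors and a π face.

## Hydrogen-bond prediction

`predict_hb_free_energy()` implements the descriptor estimate for one
hydrogen bond in a competing solvent,

$$\Delta\Delta G_{HB} = \frac{-(\alpha-\alpha_s)(\beta-\beta_s) + 6}{4.18}
\;\text{kcal·mol}^{-1},$$

with empirical donor strength α, acceptor strength β, and the solvent's
α_s, β_s. The 6 kJ·mol⁻¹ offset and the kJ→kcal factor 4.18 are part of
the published correlation and are fixed. The bundled descriptor table
carries pyrrole (α = 3.0), **2a** (α = 1.2, β = 12.2), **2b** (α = 1.1,
β = 10.7) and acetonitrile (α_s = 1.7, β_s = 5.1); users can supply their
own CSV. The formula holds for one isolated bond — it is used here to rank
the guests' acceptor abilities, not to predict the four-bond complex.

All conversions use ΔG = −RT ln K with R = 1.9872 × 10⁻³ kcal·mol⁻¹·K⁻¹
and T = 298.0 K by default. These constants reproduce each tabulated −ΔG
to 2 decimal places from its tabulated K (whether the original analysis
used 298 or 298.15 K is indistinguishable at that precision; we fix
298.0). ITC experiments run at 293 K keep that temperature on the
experiment object, while free energies are reported at the 298 K analysis
temperature for comparability across methods.

## Binding models and fitting

**Speciation.** For one H + G ⇌ HG equilibrium the complex concentration
is the smaller root of $Kx^2 - K(H_0+G_0+1/K)x + KH_0G_0 = 0$.
`solve_1to1()` evaluates it in the conjugate form
$x = 2H_0G_0/(b+\sqrt{b^2-4H_0G_0})$ (immune to subtractive cancellation
when binding is weak), polishes with two Newton steps to machine
precision, and falls back to bisection on the mass-balance residual in the
rare case the polished root still fails a 10⁻¹⁰ relative equilibrium
residual check.

**NMR (fast exchange).** The observed shift is the population average
$\delta_{obs} = \delta_{free} + f_{bound}(\delta_{bound}-\delta_{free})$
with $f_{bound} = [HG]/H_0$ for host nuclei and $[HG]/G_0$ for guest
nuclei. `fit_nmr_titration()` fits one shared K across all signals by
least squares. Two numerical choices matter:

* the search is over log₁₀K, started from an 8-point log-spaced grid
  spanning 10⁻¹–10⁸ M⁻¹ and refined by golden-section optimisation — K is
  positive and its likelihood surface is far better conditioned on the log
  scale;
* for fixed K the limiting shifts enter linearly, so they are profiled out
  by exact linear solves; the nonlinear search is one-dimensional and
  cannot wander.

Standard errors come from the residual-variance-scaled covariance of the
full parameter set (numeric Jacobian). Signals are weighted equally (ppm
residuals are comparable across ¹H signals). A titration in which no
signal moves above the noise floor (default 10⁻⁴ ppm) is rejected as
K-unidentifiable rather than fitted. Host dilution during guest addition
can be represented explicitly via per-point H₀ values; the generator
supports both constant-host and dilution schedules.

**ITC (Wiseman 1:1 model).** `predict_itc_heats()` uses the perfusion
(overfilled cell) convention: injection $v_i$ scales both running totals
by $1-v_i/V_0$ before adding the new guest, the post-injection complex
concentration comes from the same speciation solver with the host site
concentration $n\,[H]_{tot}$, and

$$q_i = \Delta H\, V_0\,\big(\,[HG]_i - [HG]_{i-1}(1-v_i/V_0)\big).$$

The heats telescope, so a fully saturating run integrates to
$n\,\Delta H\, V_0\, [H]_{tot,0}$ exactly. `fit_itc()` runs
Levenberg–Marquardt (via `minpack.lm`) on (log₁₀K, ΔH), multi-started on
the same log grid, with the first injection excluded by default (the
standard syringe-diffusion convention; configurable) and dilution heats
assumed pre-subtracted. It warns when the Wiseman parameter
c = nK[cell] leaves [1, 1000].

**Stoichiometry: fixed by default.** The fitter supports floating n, but
the default is n = 1 fixed. The reason is identifiability, not
convenience: the four-wall protocol modelled here (25 × 3 μL of a 7×
syringe solution into 1.4 mL of 0.2 mM host) stops at a guest/host molar
ratio of 0.375, well before the equivalence point, and without the
post-equivalence branch the data constrain n and K only jointly. Fixing
the independently known 1:1 stoichiometry (slow-exchange NMR shows one
bound set of signals up to 1 equivalent; the crystal structures are 1:1)
restores a well-posed two-parameter problem. When a thermogram brackets
the equivalence point, `float_n = TRUE` behaves as usual.

**Uncertainties.** Asymptotic covariance errors are the default, matching
the usual "±" reporting style of fitted binding constants.
`bootstrap_uncertainty()` offers residual-resampling percentile intervals
as a cross-check; both are provided because the provenance of published
"±" values is often unstated (fit error vs replicate scatter).

## Decomposition and the pseudo-Hammett regression

`delta_delta_G()` subtracts same-guest, same-temperature fits and combines
σ(ΔG) in quadrature; swapping target and reference flips the sign exactly.
Internally ΔG and ΔΔG are negative for favourable binding; reports print
−ΔG/−ΔΔG so stronger binding reads as a larger positive number, the
conventional tabulation. `per_contact_energy()` divides by the contact
count; the packaged default is the wall count (2 or 4), overridable from
`count_contacts()` on a structure. When a representative four-wall value
is wanted, the mean of the two four-wall magnitudes for **2a** is used
before dividing by 4 — the tabulated constants give
(4.49 + 4.32)/2 ≈ 4.4, hence ≈ 1.1 kcal·mol⁻¹ per contact.

`lfer_regression()` is ordinary least squares of ΔΔG on ESP by default —
the published plot shows no error weighting, and with three points per
guest inverse-variance weighting would let one tight point dominate — with
optional 1/σ² weights. It reports the slope's standard error and the
two-sided t-test against zero (df = n − 2); with exactly two points the
slope is an interpolation and the p-value is NA. Identical ESP values are
a rank-deficiency error, not a silent zero.

One reporting subtlety: recomputing −ΔΔG from the *rounded* tabulated
constants reproduces the tabulated −ΔΔG values only to within a few
hundredths of a kcal·mol⁻¹, because the original differences were
evidently taken before rounding. For the two-wall **2a** complexes the
recomputed and tabulated values agree within 0.03 kcal·mol⁻¹ except for
host **1d**, where the tabulated −ΔG (5.01) and −ΔΔG (2.52) are mutually
inconsistent by 0.04 given the reference value of 2.53; the recomputation
(2.48) is self-consistent and we report it as such.

## Contact geometry

`chpi_parameters()` computes the conventional descriptors of a C–H over
an aromatic ring: d, the H-to-centroid distance (or C-to-centroid in
heavy-atom mode, flagged); Θ, the C–H···centroid angle (180° = linear);
and Φ, the angular displacement of the atom from the ring normal erected
at the centroid, folded into [0°, 90°] so that 0° means "directly above
the ring centre". These angular conventions are stated here explicitly
because figure-label definitions vary between studies; both angles are
computed from the least-squares ring plane (smallest principal component
of the centred ring atoms), whose sign is chosen toward the query atom.
`count_contacts()` counts (methyl, ring) pairs within a cutoff —
default C···centroid ≤ 4.0 Å, the upper edge of the range conventionally
used for methyl CH-π contacts — and orders them by distance. All outputs
are rigid-motion invariant (tested to 10⁻⁹ Å and 10⁻⁷ degrees).
Crystal-structure validation against deposited CIFs is an optional user
path; the package reads XYZ and PDB only and does no symmetry expansion.

## What the synthetic data emulate — and what they do not

`nmr_scenario()` defaults describe the bench protocol for these systems: a
1.6 mM host solution, 14 points from 0 to 12 equivalents (saturation needs
more than 10 equivalents at K ≈ 5 × 10³), an NH signal moving +2 ppm on
binding (guest CH₃ signals move about −0.5 ppm and can be added), and
0.005 ppm Gaussian shift noise — a realistic readout precision for a
400 MHz instrument with sharp signals. `itc_scenario()` defaults describe
the calorimetric protocol: 0.2 mM host in a 1.4 mL cell, 25 × 3 μL
injections at 7× concentration, ΔH = −5 kcal·mol⁻¹, and 0.1 μcal Gaussian
heat noise, a VP-ITC-scale figure. Noise levels are stated as package
defaults because the original reports give none.

The generators draw iid Gaussian noise from a private seeded stream (the
global RNG is never touched), so every dataset is a pure function of
(scenario, seed). They do *not* emulate: baseline drift or phasing errors
in spectra, peak overlap, slow- or intermediate-exchange lineshapes,
heat-of-dilution backgrounds, syringe concentration errors (which bias n
in real ITC), or correlated residuals. Passing recovery tests on these
data therefore demonstrates that the estimators are correct and nearly
unbiased under the stated noise model — not that every systematic error of
a real titration is handled.

Problem sizes used throughout the tests and the acceptance script — 50
replicate NMR fits, 20 replicate ITC fits, 14-point titrations,
25-injection thermograms — mirror the study design above; they complete in
well under a minute and are the package's standard demonstration scale.

## Known limitations

* Strictly 1:1 binding: no 2:1/1:2 models, no cooperative H-bond arrays
  (the descriptor formula explicitly does not extend to them).
* Slow-exchange NMR systems are out of scope by design; they are the
  reason the strong four-wall complexes are handled by ITC.
* The per-contact energy inherits every approximation of the double
  difference (perfect cancellation of the non-wall terms, equal sharing
  across contacts).
* ESP values are consumed as inputs; the package does not compute
  electrostatic potential surfaces.
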