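# calixchpi

Quantification of CH-π interaction free energies in calix[4]pyrrole
host–guest inclusion complexes.

## The problem

Weak CH-π contacts — a non-acidic C–H bond resting on an aromatic π face —
are individually worth well under 1 kcal·mol⁻¹, yet acting in concert they
steer molecular recognition, crystal packing and biomolecular structure.
Measuring one in solution requires a model system in which everything else
is held constant. Aryl-extended calix[4]pyrrole receptors provide exactly
that: trimethylamine *N*-oxide (guest **2a**) or trimethylphosphine
*P*-oxide (guest **2b**) binds in the cone-shaped cavity through four
convergent NH···O hydrogen bonds, and the guest's methyl groups then face
the receptor's two or four *meso*-phenyl "walls". Comparing a walled
receptor with the wall-free octamethyl reference (host **1a**) isolates the
walls' contribution.

This package implements that workflow end to end for chemists analysing
such titration data (and for anyone who wants seeded synthetic data to
exercise the pipeline):

1. **Hydrogen-bond prediction.** Hunter's descriptor estimate of a single
   H-bond free energy in a competing solvent,
   ΔΔG_HB = [−(α − α_s)(β − β_s) + 6]/4.18 kcal·mol⁻¹,
   from empirical donor (α) and acceptor (β) strengths.
2. **Binding constants.** Exact 1:1 speciation ([HG] as the stable root of
   the binding quadratic); fast-exchange NMR titration fitting with one
   shared K across any number of host- and guest-owned signals; Wiseman-type
   1:1 ITC fitting with the perfusion dilution convention. Uncertainties by
   asymptotic covariance or residual bootstrap.
3. **Decomposition.** ΔΔG = ΔG(walled) − ΔG(reference) with errors in
   quadrature, divided by the contact count for a per-interaction energy.
4. **Electrostatic test.** Ordinary least-squares regression of the CH-π
   free energies against the electrostatic surface potential (ESP) at the
   ring centre — a pseudo-Hammett plot whose near-zero slope indicates a
   dispersion-dominated interaction.
5. **Geometry.** Ring centroid/normal, the conventional (d, Φ, Θ) contact
   descriptors and NH···O distances from XYZ or PDB coordinates, with
   cutoff-based contact counting.

All generators (NMR series, ITC thermograms, 3D fixtures) are pure
functions of a scenario and a seed.

## Worked example

```r
library(calixchpi)

# simulate a noisy NH titration of the two-wall OMe host (true K = 5150)
ser <- generate_nmr_titration(nmr_scenario(K_true = 5150, noise_sd = 0.005, seed = 42))
fit <- fit_nmr_titration(ser)
fit
#> 1:1 binding fit (NMR)
#>   K    = 5036 +/- 1.1e+02 M^-1
#>   dG   = -5.048 +/- 0.013 kcal/mol at 298 K
#>   rms residual 0.0048; converged: TRUE

# reference complex with the wall-free octamethyl host (true K = 72.2)
ref <- fit_nmr_titration(generate_nmr_titration(nmr_scenario(K_true = 72.2,
  signals = list(NH = list(owner = "host", delta_free = 7.4, delta_bound = 9.4)),
  noise_sd = 0.005, seed = 43)), host_id = "1a", guest_id = "2a")

fit$host_id <- "1b"; fit$guest_id <- "2a"
delta_delta_G(fit, ref, n_contacts = 2)
#> CH-pi decomposition 2a@1b: ddG = -2.520 +/- 0.021 kcal/mol (2 contacts, -1.260 each)

# does the CH-pi energy track the ring's electrostatic potential? (it does not)
lfer_regression(c(-20.7, -12.9, -2.0), c(2.51, 2.36, 2.52))
#> LFER (ddG vs ESP, OLS, n = 3):
#>   slope = 0.0014 +/- 0.0094 kcal/mol per ESP unit (p = 0.904)
#>   intercept = 2.480 +/- 0.133 kcal/mol
```

The fitted K of 5.0 × 10³ M⁻¹ recovers the simulated truth within its
uncertainty; the decomposition attributes ≈ 2.5 kcal·mol⁻¹ to the two
walls, i.e. ≈ 1.3 kcal·mol⁻¹ per CH-π contact; and the flat LFER slope
(indistinguishable from zero, p = 0.9) says the interaction strength does
not follow the ring's electrostatics.

The whole study — all 12 host × guest systems, fit by the method matched to
their affinity, decomposed and regressed — runs with:

```r
res <- run_full_analysis(list(seed = 1))
res$table      # ESP, K, -dG, -ddG, per-contact energies
res$lfer       # per-guest pseudo-Hammett fits
```

and `reproduce_table1()` rebuilds the free-energy table directly from the
bundled association constants without refitting.

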