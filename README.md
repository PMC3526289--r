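# dimelt

Van't Hoff analysis of melting curves for self-associating nucleic-acid
structures, under a **two-state homodimerization** model, plus
**pH-titration (apparent pKa)** fitting and a seeded synthetic-data
generator.

Dimeric i-motifs, minor-groove-tetrad quadruplexes and related folds form
by the bimolecular association 2 M ⇌ D of two identical strands. Their
thermal stability is usually characterized by CD- or UV-monitored melting:
the raw signal *s(T)* is converted, via linear folded/unfolded baselines,
into the molar fraction of structured strands α(T); the mass balance

    K(T) = α / (2 · Ct · (1 − α)²)        ([D] = α·Ct/2, [M] = (1 − α)·Ct)

gives the equilibrium constant at each temperature; and the van't Hoff
relation

    ln K = ΔS°/R − (ΔH°/R) · 1/T          R = 1.9872 × 10⁻³ kcal mol⁻¹ K⁻¹

is fitted by ordinary least squares to obtain ΔH° and ΔS° with full
error propagation (delta method, slope–intercept covariance included).
The melting temperature follows the strand-fraction convention
α(Tm) = 1/2, i.e. K(Tm)·Ct = 1, giving Tm = ΔH°/(ΔS° + R ln Ct): Tm rises
with strand concentration, the operational signature of a multimolecular
transition, and 1/Tm is linear in ln Ct with slope R/ΔH°
(`fit_tm_vs_concentration()` exploits this as an independent estimate of
ΔH°). Acid-stabilized structures are additionally characterized by
`fit_titration()`, a Hill-sigmoid fit of signal vs pH whose midpoint is
the apparent pKa of the structure. Unimolecular (molecularity-1)
transitions are supported throughout.

The package is aimed at biophysical chemists analysing melting/titration
series of dimeric quadruplexes, i-motifs and similar systems, and ships
reference thermodynamic parameters for three minimal i-motif-forming
sequences (`reference_dimer_params()`) that drive its fixtures and
examples.

## Worked example

```r
library(dimelt)

ref <- reference_dimer_params()           # three characterized sequences
p <- thermo_params(ref$dH[1], TdS298 = ref$TdS298[1])   # cyclic decamer

# simulate a noisy CD melting curve at 50 uM and fit it back
curve <- simulate_melting(p, Ct = 50e-6, noise_sd = 0.15, seed = 7)
fit_melting(curve)
#> Two-state van't Hoff fit
#>   n = 58 points, r^2 = 0.9950814
#>   dH      =   -34.98 +/- 0.33 kcal/mol
#>   T.dS298  =   -27.32 +/- 0.31 kcal/mol
#>   dG298    =    -7.66 +/- 0.02 kcal/mol
#>   Tm      =     41.1 +/- 0.1 C at Ct = 5e-05 M
```

58 transition points (α between 0.15 and 0.85) entered the ln K vs 1/T
regression; at ~1.7% noise the fitted enthalpy sits within a few kcal/mol
of the generating −38.1, the free energy ΔG°₂₉₈ = ΔH° − 298.15·ΔS° is
tightly determined (−7.66 ± 0.02, generating value −7.9), and the fitted
Tm of 41.1 ± 0.1 °C tracks the model value (41.8 °C at 50 µM). A
concentration series recovers the enthalpy exactly on noiseless input:

```r
ser <- data.frame(Ct = c(20e-6, 50e-6, 100e-6))
ser$Tm_C <- sapply(ser$Ct, function(ct) melting_temperature(p, Ct = ct))
fit_tm_vs_concentration(ser)
#> Tm-vs-concentration analysis (1/Tm vs ln Ct)
#>   dH = -38.10 +/- 0.00 kcal/mol (n = 3, r^2 = 1)
#>   T.dS298 = -30.20 kcal/mol

fit_titration(simulate_titration(noise_sd = 0.15, seed = 8))
#> pH-titration fit (Hill sigmoid)
#>   apparent pKa = 5.910 +/- 0.008
#>   Hill coefficient = 2.030 +/- 0.064
#>   plateaus: structured 9.929, unstructured 1.021 (residual sd 0.159)
```

Curves travel as plain CSV with `#`-prefixed metadata
(`read_melting_csv()` / `write_melting_csv()`); `make_fixture_set()`
writes the canonical 12-curve fixture set; the installed `exec/dimelt`
script exposes `simulate`, `fit-melt`, `fit-ph`, `fixtures` and `report`
subcommands. See the vignette (`vignettes/two-state-dimer-melting.Rmd`)
for the model conventions, the iterative occupancy-corrected baseline
refinement, and known limitations.

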