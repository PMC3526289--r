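---
title: "Two-state homodimer melting: model, fitting and error propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state homodimer melting: model, fitting and error propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimelt)
```

## The model

Many non-canonical nucleic-acid structures — dimeric i-motifs, quadruplexes
held by minor-groove tetrads, and similar self-associating folds — form by a
bimolecular association of two identical strands,

$$2\,M \;\rightleftharpoons\; D,$$

with no appreciably populated intermediates. dimelt implements the
thermodynamic analysis of this two-state homodimerization as followed by a
spectroscopic melting experiment (typically CD ellipticity at a fixed
wavelength, recorded while heating slowly enough to stay at equilibrium).

Writing $C_t$ for the total strand concentration (mol/L of strands) and
$\alpha$ for the molar fraction of strands engaged in the dimer
($[D] = \alpha C_t / 2$, $[M] = (1-\alpha) C_t$), the equilibrium constant is

$$K(T) \;=\; \frac{[D]}{[M]^2} \;=\; \frac{\alpha}{2 C_t (1-\alpha)^2},$$

and the integrated van't Hoff relation with temperature-independent
$\Delta H^\circ$, $\Delta S^\circ$ is

$$\ln K(T) \;=\; \frac{\Delta S^\circ}{R} - \frac{\Delta H^\circ}{R}\,\frac{1}{T}.$$

All energies are kcal/mol with $R = 1.9872\times 10^{-3}$ kcal/(mol K).
Solving the mass balance for $\alpha$ at given $q = K C_t$ gives the unique
admissible root of $2q\alpha^2 - (4q+1)\alpha + 2q = 0$; the package
evaluates it in the cancellation-free form
$\alpha = 4q / (4q + 1 + \sqrt{8q+1})$, accurate from $q \to 0$ to
$q \to \infty$ (checked against a bisection solver in the test suite).

Two conventions deserve to be explicit because the literature varies:

* **Tm definition.** $T_m$ is the temperature at which half the *strands*
  are structured, $\alpha(T_m) = 1/2$, which for this symmetric dimer is
  equivalent to $K(T_m)\,C_t = 1$ and yields the closed form
  $T_m = \Delta H^\circ / (\Delta S^\circ + R \ln C_t)$. This convention —
  rather than the $K(T_m) = 4/C_t$ form that arises when $\alpha$ is defined
  at the midpoint of a different progress variable — is the one that
  reproduces the published $(T_m, \Delta H^\circ, T\Delta S^\circ_{298}, C_t)$
  characterizations of the mini i-motif dimers bundled in
  `reference_dimer_params()` to within a quarter of a degree, which is why
  the package fixes it.
* **Reference temperature.** "298" columns are evaluated at 298.15 K; the
  difference from 298 K is far below the rounding of tabulated values.

The concentration dependence of $T_m$ is the operational signature of a
multimolecular transition: $1/T_m$ is linear in $\ln C_t$ with slope
$R/\Delta H^\circ$, so a dilution series both diagnoses molecularity and
provides a second, independent route to $\Delta H^\circ$
(`fit_tm_vs_concentration()`). A unimolecular fold ($\alpha = K/(1+K)$,
molecularity 1, also supported throughout) has a concentration-independent
$T_m = \Delta H^\circ/\Delta S^\circ$; series whose $T_m$ does not move are
flagged as such instead of being forced through the dimer formula.

## From raw curve to parameters

`fit_melting()` runs the pipeline:

1. **Baselines.** The folded and unfolded species each contribute a signal
   that drifts linearly with temperature; `fit_baselines()` fits
   least-squares lines over a low- and a high-temperature window (defaults:
   first and last 15% of the span; user-specifiable in °C). The fitted
   quantities are therefore invariant to any affine transformation
   (gain/offset) of the raw signal — a property the test suite asserts.
2. **Fraction conversion.** $\alpha(T) = (s - u)/(f - u)$ with $f, u$ the
   baseline values at $T$; values outside $[0,1]$ are clipped and flagged,
   pre-clip values retained.
3. **Per-temperature $\ln K$.** The mass balance is inverted at each point
   with $\alpha$ strictly inside an *alpha window*, default $[0.15, 0.85]$.
   $\ln K$ diverges at the plateaus, so plateau points carry no information
   and amplify baseline error; 0.15–0.85 keeps the well-conditioned core of
   the transition.
4. **Van't Hoff regression.** Ordinary (unweighted) least squares of
   $\ln K$ on $1/T$, matching the straight-line fit conventional for this
   analysis; slope and intercept map to $\Delta H^\circ$ and
   $\Delta S^\circ$.
5. **Error propagation.** Coefficient standard errors and their covariance
   map linearly onto $(\Delta H^\circ, \Delta S^\circ)$. Derived quantities
   use the delta method with the full covariance — no independence
   assumption, and `derived_with_errors()` refuses to run without a
   covariance:
   $\sigma^2_{\Delta G} = \sigma^2_{\Delta H} + T^2\sigma^2_{\Delta S}
   - 2T\,\mathrm{cov}$, and $\sigma_{T_m}$ from the gradient of
   $T_m(\Delta H^\circ, \Delta S^\circ)$. A Monte-Carlo sampler of the
   fitted bivariate normal serves as the oracle for these formulas in the
   tests.

### Iterative baseline refinement

A subtlety specific to bimolecular transitions: the folded plateau is never
pure. At any finite concentration $\alpha < 1$ at all temperatures (e.g.
$\alpha \approx 0.98$ at 0 °C for a dimer melting near 28 °C), so a line
fitted directly through the "folded" window is biased by the few percent of
unfolded strands there, and that bias propagates into $\ln K$ and tilts the
van't Hoff slope by up to ~1 kcal/mol. `fit_melting(refine = TRUE)` (the
default) therefore alternates: after each van't Hoff pass, the model
$\alpha(T)$ is used to correct the windowed signals for the occupancy of the
other species — $f$ is refit to $(s - (1-\alpha)u)/\alpha$ over the folded
window and $u$ to $(s - \alpha f)/(1-\alpha)$ over the unfolded window —
and the conversion/regression is repeated until the parameters stabilize
(relative tolerance $10^{-10}$, cap 50 iterations). Each step is still a
linear baseline fit over the user's windows followed by the standard
fraction/van't Hoff analysis; the package deliberately does **not** perform
a one-step nonlinear fit of the raw sigmoid with free baselines. On
noiseless synthetic data the iteration converges to the generating
parameters (the round-trip test requires better than 0.1%); `refine =
FALSE` gives the classical single pass.

`tm_observed()` additionally reports a model-free $T_m$ — the temperature
where the measured $\alpha$ crosses 0.5, by linear interpolation between
the bracketing points — for comparison with the model value.

## pH titrations

Acid-stabilized structures (i-motifs depend on hemi-protonated C:C⁺ pairs)
lose their signal as pH rises. `fit_titration()` fits

$$s(\mathrm{pH}) = s_{\mathrm{high}} + (s_{\mathrm{low}} - s_{\mathrm{high}})
\,\theta, \qquad
\theta = \frac{1}{1 + 10^{\,n_H(\mathrm{pH} - \mathrm{p}K_a^{app})}}$$

by robust nonlinear least squares (Levenberg–Marquardt via minpack.lm). The
midpoint is reported as the **apparent pKa of the structure as a whole** —
the pH of half-denaturation, an aggregate of the underlying cytosine
protonation equilibria, not a microscopic residue pKa. The Hill coefficient
$n_H$ is free by default; the synthetic fixtures use $n_H = 2$ on the
rationale that the minimal dimer contains two hemi-protonated C:C⁺ pairs,
but nothing in the analysis depends on that choice, and `fix_hill` pins it
when data are too sparse to constrain four parameters. Fits whose midpoint
falls outside the sampled pH range are flagged `extrapolated`; flat curves
and coincident plateaus are rejected as "no transition detected".

## The synthetic-data generator

No public numeric datasets exist for the CD curves this analysis was
designed around (they were published as figures only), so
`simulate_melting()` / `simulate_titration()` generate data with exactly
the statistical structure the analysis assumes:
$s(T) = \alpha(T)f(T) + (1-\alpha(T))u(T) + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$ iid, with $\alpha$ from the equilibrium
model, and the Hill sigmoid plus noise for titrations. Defaults, fixed
once:

| parameter | default | rationale |
|---|---|---|
| temperature grid | 0–90 °C, step 0.5 | a 0.5 °C/min scan sampled each minute, annealed from 90 °C |
| folded baseline | $10 - 0.01\,T$ | arbitrary but fixed; figure-level data unavailable |
| unfolded baseline | $1 - 0.002\,T$ | idem; ~9-unit amplitude, gently sloping plateaus |
| noisy-fixture $\sigma$ | 0.15 units (~1.7% amplitude) | realistic CD noise |
| titration grid | pH 4–8, step 0.1 | spans the 5.9 midpoint by ±1.9 |
| titration midpoint / Hill | 5.9 / 2 | reference apparent pKa; two C:C⁺ pairs |

Reproducibility: one global integer seed; element $i$ of a series uses the
sub-seed $(\mathrm{seed} + 7919\,i) \bmod (2^{31}-1)$ (`derive_seed()`), so
any single curve can be regenerated without the rest.
`make_fixture_set()` writes the canonical 12-file fixture set (three
reference melting curves, a 20/50 µM pair, one titration; noiseless and
seeded-noise variants) plus a JSON manifest.

**What passing on synthetic data does and does not show.** The generator
is the exact inverse of the analysis, so round-trip tests verify the
implementation (conventions, algebra, error propagation), not the
two-state assumption itself. Real curves can deviate in ways the generator
does not emulate: populated intermediates or co-existing dimer registers
(which make fitted parameters "apparent"), curved baselines, scan-rate
(kinetic) lag, signal drift correlated in temperature, and pH-dependent
baselines in titrations. Heat-capacity changes ($\Delta C_p \neq 0$),
molecularities above 2 and intermediate-state models are out of scope.

## Numerical choices and limitations

* Tolerances: refinement stops at $10^{-10}$ relative parameter change;
  the $\alpha$ solver is exact closed form with a large-$q$ asymptotic
  branch; Tm solutions outside (0, 500] K are reported as "transition
  outside physical range".
* Degenerate inputs: flat curves ("no resolvable transition"), windows
  with fewer than 4 points, fewer than 5 points in the alpha window
  ("insufficient transition sampling"), all-equal temperatures (singular
  design) and duplicate-only concentration series all fail with specific
  errors; two-point van't Hoff fits interpolate exactly and report their
  SEs as 0 with an `se_undefined` flag.
* Regression SEs are conditional on the estimated baselines and the
  alpha-window membership. At realistic noise (≲3% of amplitude) they are
  well calibrated (the suite checks 3-SE coverage over 100 seeds) and grow
  monotonically with the noise level; far above that regime window
  membership itself becomes noise-driven and the SEs stop tracking — treat
  heavily noisy curves with caution.
* Problem sizes used in the tests — 181-point melting grids, 30-point
  van't Hoff designs, 100-seed calibration loops, $10^5$-draw Monte Carlo
  oracles — keep every statistical check sharp while the whole suite runs
  in seconds.

## Command line

The installed `exec/dimelt` script exposes the pipeline:
`dimelt simulate|fit-melt|fit-ph|fixtures|report` with flags
`--preset`, `--dh`, `--tds298`, `--ct`, `--molecularity`,
`--alpha-window lo,hi`, `--baseline-low lo,hi`, `--baseline-high lo,hi`,
`--noise-sd`, `--fix-hill`, `--seed`, `--out`. Exit codes: 0 success,
2 configuration error (raised before any file is written), 3 data error.
Reports echo the conventional column order
$T_m$, $\Delta G^\circ_{298}$, $\Delta H^\circ$, $T\Delta S^\circ_{298}$,
each with its propagated error.

```{r example}
ref <- reference_dimer_params()
p <- thermo_params(ref$dH[1], TdS298 = ref$TdS298[1])
curve <- simulate_melting(p, Ct = ref$Ct[1])
est <- fit_melting(curve)
est
fit_titration(simulate_titration())
```
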