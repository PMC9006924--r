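---
title: "The pre-formed cavity model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pre-formed cavity model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precav)
```

## The model

Cucurbit[n]uril (CB[n]) macrocycles, and the tailor-made cavities formed by
CB[8] together with a cationic auxiliary probe, bind rigid hydrocarbons and
noble gases in water with a selectivity that spans several orders of
magnitude in affinity. `precav` implements an empirical model for that
selectivity: the host cavity behaves like a cavity in a low-polarity,
low-polarizability solvent whose formation cost has already been paid. If
the solvation free energy of a guest in a mimic solvent is split into a
repulsive cavitation cost and an attractive, dispersion-dominated remainder,

$$\Delta G^{H}_{solv} = \Delta G^{H}_{cav} + \Delta G^{H}_{disp},$$

then the model states that the gas-to-cavity transfer free energy of a
guest is linear in the dispersion term alone:

$$\Delta G_{gas \to cavity} \approx a\,(\Delta G^{H}_{solv} -
\Delta G^{H}_{cav}) + b.$$

A slope $a \approx 1$ means the mimic solvent matches the polarizability of
the cavity walls; the intercept $b$ absorbs host-side constants, chiefly
the free energy of ejecting water from the cavity. Because those constants
differ between hosts, the model predicts *relative* affinities
(selectivity), not absolute ones — except where the cavity is essentially
dry, as for CB[5], where the intercept is close to zero.

`characterize_cavity()` is the fitting function for this model. It takes a
host dataset (`host_data()` / `cb_host()`), a guest table (`cb_guests()`)
and a mimic (`solvent_model()` or `solvent_mixture()`), and returns a
`cavity_fit` with the usual modelling verbs (`print`, `summary`, `coef`,
`predict`, `residuals`, `plot`).

## Hard-sphere cavitation

The cavitation term is computed with a hard-sphere equation of state of the
Boublik–Mansoori–Carnahan–Starling–Leland family, in the Matyushov–Ladanyi
form implemented by `cavitation_energy()`:

$$\beta\Delta G_{cav} = -\ln(1-\eta) + \frac{3\eta}{1-\eta}d +
\left[\frac{3\eta}{1-\eta} + \frac{9}{2}\left(\frac{\eta}{1-\eta}\right)^2
\right]d^2 + \eta Z(\eta)\, d^3,$$

where $d = \sigma_{solute}/\sigma_{solvent}$ is the diameter ratio, $\eta$
the solvent packing fraction and $Z(\eta) = (1+\eta+\eta^2-\eta^3)/
(1-\eta)^3$ the Carnahan–Starling compressibility factor. The form has two
exact limits that the tests pin down: a point solute costs
$-RT\ln(1-\eta)$, and the energy vanishes as $\eta \to 0$; it is strictly
increasing in both $d$ and $\eta$.

Guest diameters come from quantum-chemically computed isodensity volumes
via `effective_diameter()`, $\sigma' = c\,(6V/\pi)^{1/3}$ with $c = 0.922$,
the empirical factor that aligns isodensity diameters with tabulated
hard-sphere diameters. Note that the packaged volumes are stored at their
published precision (one decimal), so recomputed $\sigma'$ values agree
with the published column to one unit in the second decimal, not to half a
unit; the same printed-rounding logic sets the 0.01 kcal/mol comparison
tolerance used throughout the tests for derived energies.

### Calibrated mimic solvents

The solvent hard-sphere parameters are not taken from the density relation
alone; they are calibrated once, with `calibrate_solvent()`, against the
packaged per-guest cavitation energies, and the resulting values are frozen
in the registry `cb_solvents()`:

* **benzene** — $\sigma = 5.16077$ Å with $\eta = 0.48495$ tied to the bulk
  density ($\rho = 0.874$ g/cm³, $M = 78.11$ g/mol). Maximum residual over
  the 21 hydrocarbons: 0.033 kcal/mol.
* **perfluorohexane** — $\sigma = 5.16273$ Å with a *fitted* packing
  fraction $\eta = 0.28396$, decoupled from the density relation (which
  would give 0.21 at this diameter, or $\sigma = 5.92$, $\eta = 0.32$ if
  re-tied). The decoupled two-parameter fit reproduces the packaged column
  to 0.008 kcal/mol and was preferred for that reason; the effective
  packing of a long perfluoroalkane treated as a sphere is genuinely not a
  bulk-density quantity.

`calibrate_solvent()` refuses fits whose worst anchor residual exceeds
0.3 kcal/mol, so a wrong equation-of-state variant cannot calibrate
silently.

## Free-energy bookkeeping

All energies are in kcal/mol, lengths in Å, and the temperature is fixed at
298.15 K ($RT = 0.5925$ kcal/mol); negative transfer energies are
favorable. Relative binding constants map to energies as
$\Delta\Delta G = -RT\ln K_{rel}$ (`relative_binding_free_energy()`), and
aqueous-to-gas conversion adds the difference of aqueous solvation energies
(`gas_to_cavity()`). Moving the gas reference state from 1 atm to 1 mol/L
(about 24.5 atm) contributes $-RT\ln(c^0RT/P^0)$
(`standard_state_correction()`); the exact value at 298.15 K is −1.894,
commonly rounded to −1.90. Solvation energies can alternatively be derived
from a measured solubility and vapor pressure
(`solvation_from_solubility()`); the two published formulations of that
relation are algebraically identical and are asserted equal in the tests.

Mixture dispersion terms are molar-fraction-weighted sums of the
pure-solvent terms (`mixture_dispersive()`); no mixture *cavitation* model
is defined, which is consistent with using the mixture only on the
dispersion axis of the regression. Guests suspected of entering the cavity
as n-mers are handled as standalone guests whose transfer energy is
corrected by the endergonic pre-association free energy
(`preassociation_correction()`).

## The titration estimator

Relative affinities are measured by competitive fast-exchange ¹⁹F NMR: two
hydrocarbons H and H′ in excess compete for the host, the observed reporter
shift is the population-weighted average of the two pure-complex endpoint
shifts, and the bound-complex ratio $(\delta - \delta_{H'})/(\delta_H -
\delta)$ is regressed on the free-solute concentration ratio
$x_H S^0_H / (x_{H'} S^0_{H'})$ (ideal-mixture solubilities,
`mixture_solubility()`). The slope of a free-intercept ordinary
least-squares fit is $K_{rel}$; the intercept is kept free as a
non-ideality diagnostic, with a `through_origin` option that reports both
estimates.

One deliberate estimator choice: the reported `K_rel_se` is **not** the
homoscedastic OLS slope error. The ratio transform maps constant shift
noise into ratio noise whose standard deviation grows as
$(\delta_H - \delta)^{-2}$, i.e. as $(1+r)^2$ in the bound ratio $r$ — a
factor of ~16 in variance across a design spanning $r \in [0.25, 4]$.
Monte-Carlo calibration (500 seeds, 8 points, 0.005 ppm shift noise) shows
that plain OLS errors give 62–85% coverage for a nominal 95% interval,
while the propagated (sandwich) error — per-point variances
$\hat\sigma_\delta^2 (\delta_H-\delta_{H'})^2 (\delta_H-\delta)^{-4}$ with
$\hat\sigma_\delta$ estimated from shift-space residuals on $n-2$ degrees
of freedom — covers at better than 93% (conservatively, near 99%). The
point estimate remains the free-intercept OLS slope; only its error is
heteroscedasticity-aware. The plain OLS error is still reported as
`se_ols`.

Guests that cannot be compared directly are chained through relay guests
(`chain_affinities()`), multiplying K along the unique relay path and
adding relative variances in log space; redundant measurements that close
an inconsistent cycle (mismatch beyond 3 combined sigma) are an error, not
a warning, because a silent reference mismatch would corrupt every
downstream regression. For the same reason host datasets carry their
reference guest explicitly and `characterize_cavity()` shifts both axes to
that reference for relative data — slope and $R^2$ are invariant under the
shift; intercepts are then reference-relative.

## Synthetic data: what it does and does not emulate

`simulate_titration()` inverts the fast-exchange relation exactly and adds
Gaussian noise to the *shifts*, which is where instrument noise lives. Its
default design — frozen before any estimator assessment — places 8 points
with bound fractions of H evenly spaced over [0.2, 0.8] (observed shifts
spanning the central 60% of the endpoint separation), endpoints at −57.94
and −58.52 ppm and solubilities of 1.1×10⁻⁴ / 2.5×10⁻⁴ mol/L, i.e. a
cyclohexane/cycloheptene-like competition; 0.005 ppm noise is
magnitude-consistent with the published affinity uncertainties.
`simulate_host()` draws transfer energies from the linear model with
Gaussian residuals and optional planted outliers.

The generators deliberately do **not** model exchange broadening or
lineshapes, solute-mixture non-ideality (the free intercept exists to
absorb it, but the generator's truth has intercept zero), correlated
residuals across guests, or heavy-tailed errors. Passing the recovery and
coverage suites therefore validates the estimators under their stated
assumptions; it does not certify behavior on real spectra that violate
them.

Problem sizes used by the test suite (chosen once as adequate for the
quantities asserted): 500 seeds for coverage, slope-recovery and
outlier-power Monte-Carlo runs; 8-point titrations; the 9-guest packaged
panel for host simulations.

## Numerical choices

* Mixture-fraction optimization (`optimize_mixture_fraction()`) uses
  bisection (`uniroot`) on the slope–fraction map, tolerance 10⁻⁴ in the
  fraction, after checking that the target slope is bracketed by the two
  pure-solvent slopes; no randomness is involved.
* Solvent calibration minimizes unweighted squared error (anchors are few
  and equally trusted): golden-section search for the one-parameter mode,
  Nelder–Mead with a tight restart for the two-parameter mode.
* Exact or float-level-perfect fits return studentized residuals of zero —
  a perfect line carries no evidence of outlyingness — and two-point fits
  report `NA` standard errors rather than fabricating them.
* Outlier flagging combines an externally studentized residual rule
  (|t| > 2.5) with the curated per-host exclusion lists (guests too large
  for the cavity, or binding as n-mers), whose reasons are carried
  verbatim; curation exists precisely because a "too large to fit" failure
  is a physical regime change the residual rule cannot always detect,
  especially under a forced unity slope where masking inflates the
  residual scale.

## Known limitations

* The model does not predict absolute binding affinities for CB[6]–CB[8]
  systems; the host-specific intercept absorbs the water-ejection term.
* The published benzene-mimic slope for CB[5] (0.60) is not recovered by
  plain OLS on the packaged columns (which gives ≈ 0.67 with or without
  methane); the fitting convention behind that particular published line is
  ambiguous, so the package documents the discrepancy instead of guessing.
  The same applies to the 15-hydrocarbon polarizability correlation for
  CB[7], where direct OLS gives $R^2 \approx 0.88$ against a published
  0.92.
* Cavitation energies depend steeply on the solvent diameter; the packaged
  registry reproduces the published columns to 0.033 (benzene) and 0.008
  (perfluorohexane) kcal/mol, but the last printed digit of any individual
  cell is not guaranteed without the original solvent parameterization.
* Predictions for guests larger than the largest guest in the fit are
  flagged, not refused — but the model's own premise (the guest must fit
  the pre-formed cavity) says such extrapolations can fail precipitously.
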