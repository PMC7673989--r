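---
title: "From titrations and relaxation traces to an allosteric force"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From titrations and relaxation traces to an allosteric force}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allocycle)
```

## The model

The system is a PDZ3 domain with an azobenzene photoswitch cross-linked to
its α3-helix. The switch has two isomers (trans, the dark-adapted state,
and cis, populated by 370 nm illumination), and the protein can be free
(P) or bound to a peptide ligand (PL), giving four states. Two kinds of
measurement determine the enthalpic couplings between them:

* **Titrations.** At fixed initial ligand concentration $L_0$ and varying
  initial protein concentration $P_0$, fluorescence quenching reports the
  fraction of bound ligand. Because $L_0$ (15 µM by default) is comparable
  to the dissociation constant, the dilute-ligand approximation fails and
  the complex concentration must solve the full equilibrium
  $$K_d = \frac{(P_0 - PL)(L_0 - PL)}{PL},$$
  whose physical root the package evaluates in the form
  $PL = 2 P_0 L_0 / (b + \sqrt{b^2 - 4 P_0 L_0})$ with
  $b = P_0 + L_0 + K_d$ (see *Numerical choices*).
* **Relaxation traces.** After the cis state is accumulated, absorbance at
  370 nm (the trans absorption maximum) recovers mono-exponentially with
  the thermal cis→trans time constant $\tau$; $k = 1/\tau$.

Temperature series of the fitted $K_d$ and $\tau$ feed two linear
regressions:

* van't Hoff: $\ln K_a = -\Delta H/(RT) + \Delta S/R$ with
  $K_a = (1\,\mathrm{M})/K_d$. The 1 M standard state is fixed; expressing
  $K_d$ in other units would shift $\Delta S$ by exactly $R\ln(10^6)$
  per factor of $10^6$, which is why the readers normalize units before
  fitting (a tested invariant).
* Arrhenius: $\ln k = \ln A - \Delta H^{\ddagger}/(RT)$. The prefactor's
  uncertainty is reported as the standard error of $\ln A$, because the
  intercept is a long extrapolation to $1/T = 0$ and its sampling
  distribution is log-scale. For context, `eyring_prefactor()` returns the
  transition-state-theory attempt frequency $k_BT/h$.

Both regressions are unweighted ordinary least squares by default: the
experiment they model reports simple straight-line fits, and per-point
uncertainties enter only through the optional `weighted = TRUE`
($1/\mathrm{se}^2$ weights on the log scale). $\Delta H$ is treated as
temperature-independent over the 10–40 °C range (straight-line van't
Hoff); no $\Delta C_p$ term is fitted.

## The four-state cycle

With $\Delta H_{cis}$, $\Delta H_{trans}$ (binding) and
$\Delta H^{\ddagger}_P$, $\Delta H^{\ddagger}_{PL}$ (isomerisation) in
hand, `assemble_cycle()` computes

* $\Delta\Delta H = \Delta H_{cis} - \Delta H_{trans}$ — the extra
  driving force for cis→trans isomerisation when the ligand is bound;
* $\Delta\Delta H^{\ddagger} = \Delta H^{\ddagger}_{PL} - \Delta
  H^{\ddagger}_P$ — the ligand-induced change of the barrier;
* $\Phi = (\Delta H_{cis} + \Delta\Delta H^{\ddagger})/\Delta H_{cis}$ —
  the fraction of the cis-state enthalpy shift that the transition state
  inherits ($\Phi = 1$: fully cis-like barrier; $\Phi = 0$: fully
  trans-like). The underlying result is usually stated in words ("the
  transition state follows the cis-state shift to X %"); this ratio is the
  minimal formalization consistent with that statement, and it is the one
  this package adopts and documents as such.
* the allosteric force $F = \Delta\Delta H/(N_A\,\Delta x)$: the
  enthalpy difference per molecule divided by the distance change
  $\Delta x$ between the switch anchor points. $\Delta x$ is an external
  parameter (≈ 3 Å, estimated from molecular-dynamics work on this
  construct); the package never computes it, only propagates it.

Standard errors propagate to first order assuming the four regressions are
independent, which they are by design: each uses a disjoint set of
measurements. For the pure differences this reduces to root-sum-square.

`build_energy_diagram()` lays the states out as enthalpy offsets relative
to free cis protein ($P_{cis} = 0$, $PL_{cis} = \Delta H_{cis}$,
$TS_P = \Delta H^{\ddagger}_P$,
$TS_{PL} = \Delta H_{cis} + \Delta H^{\ddagger}_{PL}$). The cis→trans
reaction enthalpy itself is not measurable from these data, so trans-side
states appear only when an external `delta_h_iso_p` is supplied; cycle
closure $(PL_{trans}-PL_{cis})-(P_{trans}-P_{cis}) = -\Delta\Delta H$
holds for any value of it.

## The synthetic-data generator

`generate_study()` emulates the measurement campaign the analysis assumes:

* titrations with the exact depletion isotherm, signal linear in fraction
  bound between a free-ligand and a bound-ligand endpoint (the protein's
  own fluorescence contribution is taken as zero, matching the quenching
  readout it emulates), 12 protein concentrations from 0 to 50 µM,
  $L_0 = 15$ µM;
* relaxation traces of 50 points spanning three time constants;
* temperatures 283.15, 294.15, 303.15 and 313.15 K;
* homoscedastic Gaussian noise. No noise magnitudes are published for
  this experiment, so the defaults are chosen once as plausible for the
  instruments involved: SD 0.02 on the normalized titration signal
  (endpoints 1 → 0) and 0.008 AU on absorbance, i.e. 1 % of the default
  0.8 AU relaxation amplitude. Under these defaults the tested
  recovery bounds hold (median $K_d$ error < 10 %, median $\tau$ error
  < 3 % over 200 seeds);
* an optional photostationary purity: with `cis_purity < 1` the cis
  titration signal is the mixture
  $p \cdot s_{cis} + (1-p)\, s_{trans}$. The default is 1 because the
  reference analysis reports uncorrected cis numbers; the mixture mode
  exists for sensitivity studies.

Determinism: every dataset's seed derives from the study seed, so a given
`study_truth` reproduces byte-identical data, and the generator
saves/restores the caller's RNG state.

What the generator does **not** emulate: drift or heteroscedastic
instrument noise, pipetting error in the concentration grids (noise on
$x$, not just $y$), inner-filter effects, partial protein unfolding near
the upper temperature, and photokinetics under illumination. Passing
recovery tests therefore show the estimators are correct and well
conditioned for the assumed error model, not that real data meet that
model.

## Numerical choices

* **Discriminant expansion.** $b^2 - 4P_0L_0$ evaluated directly loses the
  discriminant to rounding when $P_0 \approx L_0 \gg K_d$ (the rounding
  error of $b^2$ can exceed the whole discriminant, costing ~6 digits of
  the root). The package evaluates the algebraically equal, cancellation-free
  sum $(P_0-L_0)^2 + K_d(2(P_0+L_0)+K_d)$, keeping agreement with a
  bisection oracle below $10^{-12}$ relative across
  $K_d \in [10^{-12}, 10^{-2}]$ M, concentrations $\in [10^{-9}, 10^{-3}]$ M.
* **Log-parametrised $K_d$.** `fit_kd()` optimises $\log K_d$: positivity
  needs no box constraint, and a bounded linear-scale fit can stall in the
  $K_d \to 0$ corner where the finite-difference gradient underflows.
  The reported `kd_se` is delta-method transformed back.
* **Plateau handling.** Normalization uses the ligand-alone signal as 0 %
  and the mean of the two highest-concentration points of the stronger
  binder as 100 %. Because a finite titration never quite reaches its
  plateau, the default fit floats a multiplicative saturation scale as a
  nuisance parameter (`plateau = "fit"`); `plateau = "fixed"` trusts the
  references instead. Values outside [0, 1] after normalization are noise
  and are kept, not clipped.
* **Relaxation starting values.** offset₀ = last sample, amplitude₀ =
  first − last, τ₀ from the slope of $\ln|A - \text{offset}_0|$ over the
  first half of the trace; the offset floats by default and can be pinned
  to a known asymptote (`fix_offset`), e.g. the dark-adapted absorbance.
* **Fitting backend.** Both nonlinear fits run Levenberg–Marquardt through
  the residual-function interface (`minpack.lm::nls.lm`); the formula
  interface rebuilds a model object whose gradient QR can be singular in
  nearly degenerate regimes (stoichiometric binding) even when $K_d$
  itself is well determined. Singular curvature degrades to `NA` standard
  errors rather than an error; non-convergence is flagged and warned
  about, never silently returned.
* **Degenerate inputs.** Unidentifiable problems raise errors with the
  reason (single protein concentration, all-zero fractions, constant
  absorbance, amplitude indistinguishable from zero); a trace shorter than
  one fitted time constant only warns. Two-point regressions return exact
  interpolants with `NA` standard errors.
* **Ties.** The $K_d$ starting value is the $P_0$ nearest half-saturation
  (`which.min` takes the first on ties), falling back to the median
  positive $P_0$.

## Interface decisions

* Readers (`read_titration_csv()`, `read_relaxation_csv()`) demand
  explicit unit tags (°C/K, µM/M, h/s) and refuse files without them;
  schema violations name the offending row. Internally everything is SI
  (s, mol/L, K), with the 1 M standard state for $K_a$.
* Reports (`write_report()`) are JSON with sorted keys and
  6-significant-digit floats, so identical inputs give byte-identical
  files.
* The package is a library, not a shell tool: its users drive it from R
  scripts, so the function surface plus `scripts/acceptance.R` replaces a
  subcommand-style command-line interface.
* The fitted Arrhenius prefactors on the packaged series are ≈ 5 × 10¹¹
  (P) and ≈ 1.5 × 10¹⁰ s⁻¹ (PL). Quoted headline values for this system
  are the order-of-magnitude statements 10¹¹ and 10¹⁰ s⁻¹; the package
  reports the fitted values without forcing agreement, and the tests treat
  prefactors as log₁₀ quantities.

## Problem sizes

The tests and the acceptance script run at the scale of the experiment
itself: 4 temperatures × 2 states × 12-point titrations, 4 × 2 × 50-point
traces, Monte-Carlo recovery over 200 seeds, and a ~600-point oracle grid
for the binding solver. The whole suite completes in a few seconds.

## Known limitations

* Enthalpies only: binding entropies are reported, but the cycle is not
  closed in free energy because the isomerisation entropies are not
  measurable from these data.
* Single-site, two-state binding; no competitive or multi-site models.
* Mono-exponential kinetics only; a stretched or bi-exponential decay
  would signal a violated assumption rather than fit better here.
* Standard errors are fit-curvature (asymptotic) estimates; with four
  temperatures they are approximate, and replicate-based errors would be
  preferable when replicates exist.
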