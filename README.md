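# allocycle

Four-state allosteric energetics of a photoswitchable PDZ domain, inferred
from raw titration and relaxation measurements.

## The problem

An azobenzene-derived photoswitch cross-linked to the α3-helix of a PDZ3
domain couples two sites of the protein in both directions: isomerising the
switch (trans ↔ cis) changes the binding affinity of a peptide ligand by
up to two orders of magnitude, and conversely, ligand binding changes the
rate of the thermal cis→trans back-isomerisation. The system has four
states — free (P) or ligand-bound (PL) protein, each with the switch in cis
or trans — and its energetics are fully determined by two binding
equilibria and two isomerisation rate laws measured across temperature.

`allocycle` implements the complete inference chain for this kind of
experiment:

1. **Binding** — exact two-state equilibrium with ligand depletion. The
   complex concentration solves
   K_d = ([P₀]−[PL])([L₀]−[PL])/[PL]; the package uses the
   cancellation-stable root
   [PL] = 2[P₀][L₀]/(b + √(b²−4[P₀][L₀])), b = [P₀]+[L₀]+K_d,
   and fits K_d to normalized fluorescence-quenching titrations by
   Levenberg–Marquardt least squares.
2. **Kinetics** — mono-exponential fits
   A(t) = offset + amplitude·e^(−t/τ) of 370 nm absorbance traces give the
   thermal cis→trans time constant τ per ligation condition, plus a
   photostationary cis-fraction estimate from absorbance ratios.
3. **Thermodynamics** — van't Hoff regression (ln K_a vs 1/T, 1 M standard
   state) gives ΔH and ΔS of binding per switch state; Arrhenius regression
   (ln k vs 1/T) gives the activation enthalpy ΔH‡ and prefactor A per
   ligation condition, compared against the Eyring factor k_BT/h.
4. **Cycle** — the four fits combine into ΔΔH = ΔH_cis − ΔH_trans,
   ΔΔH‡ = ΔH‡_PL − ΔH‡_P, the transition-state cis-likeness
   Φ = (ΔH_cis + ΔΔH‡)/ΔH_cis, and the per-molecule **allosteric force**
   F = ΔΔH/(N_A·Δx) over the switch anchor-distance change Δx ≈ 3 Å, with
   first-order error propagation throughout.

A synthetic-data module generates titrations, relaxation traces and whole
multi-temperature studies with exactly this statistical structure, so every
stage has parameter-recovery tests without external data. The published
temperature series of affinities and time constants ships as a plain-CSV
fixture (`table1()`).

## Worked example

```r
library(allocycle)
reproduce_table1()
```

```
van't Hoff (cis, n = 4): dH = 126.9 +/- 20.3 kJ/mol, dS = 533.9 +/- 68.1 J/(mol K)
van't Hoff (trans, n = 4): dH = -51.2 +/- 1.3 kJ/mol, dS = -70.8 +/- 4.5 J/(mol K)
Arrhenius (P, n = 4): dH_act = 88.8 +/- 2.8 kJ/mol, A = 5.5e+11 1/s (se ln A = 1.1)
Arrhenius (PL, n = 4): dH_act = 79.4 +/- 0.9 kJ/mol, A = 1.5e+10 1/s (se ln A = 0.35)
Four-state allosteric energetics
  dH_cis     =   126.9 +/- 20.3 kJ/mol
  dH_trans   =   -51.2 +/- 1.3 kJ/mol
  dH_act(P)  =    88.8 +/- 2.8 kJ/mol
  dH_act(PL) =    79.4 +/- 0.9 kJ/mol
  ddH        =   178.1 +/- 20.3 kJ/mol
  ddH_act    =    -9.3 +/- 3.0 kJ/mol
  phi        =   0.927 +/- 0.026
  force      = 0.986 nN (dx = 3e-10 m)
  cis binds 118-fold tighter at 40 C; trans 12-fold tighter at 10 C
  Eyring kB*T/h at 303.15 K = 6.32e+12 1/s
```

Reading: binding in the cis state is strongly endothermic (+127 kJ/mol,
entropy-driven) while trans binding is mildly exothermic, so the cis/trans
affinity contrast inverts with temperature (118-fold in favour of cis at
40 °C, 12-fold in favour of trans at 10 °C). Ligand binding lowers the
isomerisation barrier by ≈ 9 kJ/mol, i.e. the transition state inherits
≈ 93 % of the cis-state enthalpy shift, and the ≈ 178 kJ/mol driving-force
difference acting over the 3 Å anchor-distance change corresponds to a
force of ≈ 1 nN per molecule.

The same chain runs on synthetic raw data end to end:

```r
truth <- study_truth(
  130e3, entropy_from_anchor(130e3, 7.0e-6, 294.15),
  -50e3, entropy_from_anchor(-50e3, 3.8e-6, 294.15),
  89e3,  prefactor_from_anchor(89e3, 2.68 * 3600, 294.15),
  79e3,  prefactor_from_anchor(79e3, 2.25 * 3600, 294.15),
  seed = 5L)
res <- analyze_study(generate_study(truth))
res$cycle
```

With the generator's default noise this returns ΔΔH within a few tens of
kJ/mol of the generating 180 kJ/mol; with `noise_sd = 0` in both templates
the recovery is exact to numerical precision (this is a tested invariant).

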