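---
title: "Methods: nitrogen and electron bookkeeping for alkane-anammox consortia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nitrogen and electron bookkeeping for alkane-anammox consortia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkanammox)
```

## The system and its model

The package targets anaerobic bioreactors in which an alkane-oxidizing
bacterium reduces nitrate to nitrite while oxidizing propane or butane, and
anammox bacteria oxidize ammonium with that nitrite, producing dinitrogen
gas and regenerating a small amount of nitrate:

* nitrate reduction: `C3H8 + 10 NO3- -> 3 CO2 + 10 NO2- + 4 H2O`
* anammox: `NH4+ + 1.32 NO2- + 0.066 HCO3- + 0.13 H+ ->
  1.02 N2 + 0.26 NO3- + 2.03 H2O + 0.066 CH2O0.5N0.15`
* denitrification of residual nitrite:
  `3 C3H8 + 20 NO2- + 20 H+ -> 9 CO2 + 10 N2 + 22 H2O`

All analysis rests on three bookkeeping layers over these reactions:
stoichiometric balance checks, rate estimation by linear regression on
batch-cycle concentration profiles, and nitrogen/electron balance closure
with a partition of nitrate reduction between the anammox-coupled route and
denitrification. A 15N isotope-pairing model connects the partition to
measurable 29N2/30N2 isotopologue production.

### Stoichiometric conventions

The two-decimal anammox stoichiometry does not balance nitrogen exactly:
the left side carries 2.32 N, the right side 2.04 + 0.26 + 0.066 x 0.15 =
2.3099 N, a residual of -0.0101. `element_balance()` therefore reports
residuals rather than asserting zero, and the package-wide tolerance for
this reaction is 0.02 per element. Electron counts use mean oxidation
states with O at -II and H at +I: 20 e-/mol propane and 26 e-/mol butane
(full oxidation to CO2), 3 e-/mol N for ammonium to N2, 5 (nitrate to N2),
2 (nitrate to nitrite), 3 (nitrite to N2), 6 (nitrite to ammonium). These
conventions reproduce the reported electron-balance ratios of ~1.13 from
the reported steady-state rates.

Reaction energies are standard transformed values (`delta_g_prime()`),
computed from a bundled formation table (Thauer-style compilation, 298 K,
pH 7 carried by the H+ entry at -39.87 kJ/mol). Formation tables differ
between sources at the percent level, so agreement with published reaction
energies is checked to ±3%, not exactly; with the bundled table the two
propane reactions evaluate to about -1367 and -2385 kJ/mol C3H8. The
biomass pseudo-species CH2O0.5N0.15 carries no formation energy, so the
anammox reaction energy is only computable when the caller supplies one —
a deliberate non-default.

### Rate estimation

Concentration profiles within a feeding cycle are close to linear
(zero-order kinetics while substrates last), so per-cycle rates are
ordinary unweighted least-squares slopes. Cycle boundaries are detected as
upward jumps exceeding `spike_threshold` (default 0.25) times the series
maximum, because re-spikes approximately restore initial concentrations;
flushed product gases (N2) jump downward instead, handled by
`direction = "down"` or, in `cycle_rates()`, by adopting the windows of a
re-spiked reference analyte (nitrate by default). Windows with fewer than
three points are dropped. Gas amounts use the ideal-gas law with
R = 0.08206 L atm / (mol K) and a default temperature of 295 K (room
temperature operation); dissolved alkane is neglected given its low
aqueous solubility. Reported per-reactor rates are magnitudes with an
explicit direction field, matching the field's convention of quoting
consumption and production rates as positive numbers.

### Partition, balances, DNRA diagnostics

`nitrate_partition()` implements
`r(NO3)denit = rNO3 + 0.26 rNH4 - 1.32 rNH4`: every mol of oxidized
ammonium consumes 1.32 mol nitrite and regenerates 0.26 mol nitrate, so
whatever nitrate reduction the measured rates cannot attribute to anammox
coupling is assigned to full denitrification. The reconstruction identity
`r_no3 = r_no3_denit + 1.06 r_nh4` holds to 1e-9 by construction and is
property-tested. When anammox demand exceeds supply the result carries an
infeasibility flag instead of failing.

The nitrogen balance compares nitrate + ammonium consumption against N2-N
production plus net nitrite accumulation; the electron balance compares
donor electrons (alkane, ammonium) against acceptor electrons (nitrate at
5 e-/N). With the literature anammox stoichiometry a perfectly coupled
system closes the electron balance slightly above 1 (the biomass-synthesis
electrons, ~3%), and the idealized 1:1 anammox composition closes it at
exactly 1; the tests assert the exact closure on the idealized composition
and the near-closure on the literature one.

DNRA onset is diagnosed from the conjunction of nitrate depletion (final
nitrate below 0.1 mmol N/L) and nitrite accumulation (maximum above 0.5
mmol N/L). The thresholds sit deliberately below the concentrations at
which switching has been observed (nitrite 0.9-2.4 mmol N/L), and are
overridable. Net ammonium production is tested by a one-sided OLS slope
test (p < 0.05) on the window after the first nitrate-depleted timepoint,
because ammonium is typically consumed before depletion and produced after.

### Isotope pairing

After a 15N-nitrate spike, anammox pairs one nitrite-derived N (atom
fraction `f_no3`, inherited from nitrate) with one ammonium-derived N
(`f_nh4`), while denitrification pairs two nitrite-derived N. With 2.04
N2-N formed per NH4-N:

```
r29 = (f_no3 (1-f_nh4) + (1-f_no3) f_nh4) rNH4 x 2.04
      + f_no3 (1-f_no3) r(NO3)denit
r30 = f_no3 f_nh4 rNH4 x 2.04 + f_no3^2 r(NO3)denit
```

The default `"as_printed"` mode keeps the single-ordering heterolabel
denitrification term `f (1-f)` exactly as the formulas are usually
written; random pairing of two atoms actually yields `2 f (1-f)`, provided
by the `"binomial"` mode. The tests document the relationship (the
literature term is exactly half the Monte-Carlo heterolabel fraction)
without asserting either as "correct"; anammox terms are identical in both
modes because the two atoms come from distinct pools and carry no ordering
ambiguity. Label fractions are treated as constant between spikes: no
isotopic fractionation, and the anammox-regenerated nitrate (0.26 rNH4) is
not fed back into the nitrate pool label. The natural 15N abundance
default is 0.00366.

`invert_denit_share()` subtracts the known anammox terms and solves the
remaining one-parameter linear system for `r(NO3)denit` by equally
weighted least squares over the stacked r29/r30 observations; no variance
weighting is applied because measurement variances are generally not
reported. The share is the estimate divided by the total nitrate reduction
rate, clipped to [0, 1] with a flag. Because the anammox contribution
dominates r29 while r30 is mostly denitrification-derived, the inversion
is exactly identified without noise (the predict-invert identity holds to
1e-9) and is unbiased but noisy per replicate under measurement noise —
hence the median across seeded replicates in the recovery tests.

## The simulator

`simulate_reactor()` is an explicit-Euler integrator (step 0.01 d) over
per-reactor pools NO3, NO2, NH4, N2-N, headspace alkane, and an
assimilated-N ledger, under zero-order kinetics that switch off at
substrate depletion — consistent with the near-linear observed profiles;
Monod kinetics are deliberately not modelled. Each step: nitrate is
reduced at the gross rate `r_no3` while present; a `denit_share` fraction
of the generated nitrite is denitrified (N2 1:1); anammox oxidizes
ammonium at its capacity, capped by the remaining nitrite, consuming 1.32
NO2-N, regenerating 0.26 NO3-N and producing 2.04 N2-N per NH4-N, with the
residual 0.02 N routed to the assimilation ledger so that total nitrogen
is conserved to 1e-9 at every step (the conservation test includes this
pool; the nitrogen-balance closure on noise-free output is therefore
~0.99, not exactly 1). DNRA latches on when nitrate falls below the
depletion threshold while nitrite exceeds the accumulation threshold and
stays active until nitrite is exhausted, converting nitrite to ammonium at
`dnra_yield` (default 1; no published yield exists). Alkane is consumed
according to the electron demand of the nitrogen conversions (2 e-/N for
nitrate to nitrite, 3 for denitrified N, 6 for DNRA N), i.e. fully coupled
by default; a configured `r_alkane` can impose a larger total drawdown.
Cycle boundaries flush the gas pools and re-spike substrates to their
initial concentrations. Observations are sampled on a regular grid with
independent multiplicative Gaussian noise (default 5% relative s.d.; no
autocorrelation, as no empirical error model is available), and every run
is fully determined by its seed.

Scenario presets:

* **A** — no-ammonium batch (0.12 L): nitrate 8.6 mmol N/L, no anammox,
  20% source denitrification, nitrite accumulates, DNRA after depletion.
* **B** — coupled cycles (0.92 L liquid / 0.23 L headspace, 3-day cycles,
  9 days, sampled every 0.2 d): the preset derives its gross nitrate rate
  and source-routed denitrification share from the steady-state measured
  rates (net nitrate 2.34 and ammonium 2.0513 mmol N/L/d) through the
  partition identity, so the noise-free observables reproduce exactly
  those net rates with zero nitrite accumulation.
* **C** — high-alkane batch (0.12 L, 0.75 atm propane): gross nitrate
  reduction 4.7 mmol N/L/d outruns anammox, nitrite accumulates to ~1.8
  mmol N/L, DNRA produces net ammonium after depletion.
* **D** — labelled batch (0.48 L liquid / 0.17 L headspace, 2 days):
  nitrate pool at 20% 15N, ammonium at natural abundance, denitrification
  share 4%, tracking cumulative 29N2/30N2 partial pressures. Sampling
  every 0.05 d emulates frequent automated headspace sampling; the choice
  fixes the information content of one replicate and was made once,
  upfront, as part of the scenario definition.

What the simulator does *not* emulate: substrate-dependent (Monod)
kinetics, biomass growth feedback on rates, isotopic fractionation, label
recycling into the nitrate pool, autocorrelated sensor drift, and gas-
liquid mass-transfer limitation. Passing recovery tests therefore
demonstrate estimator correctness under the stated statistical
assumptions, not robustness to every feature of real reactor data.

## Problem sizes and numerical choices

The test suite and the acceptance script run scenario B (900 Euler steps,
46 samples x 6 analytes) up to a few hundred times and scenario D (200
steps) 50 times; a full run takes seconds on one CPU. Fixed seeds make
every stochastic test reproducible. Balance tolerances default to 0.02
(the printed-coefficient residual scale) and identity checks to 1e-9;
fixture CSV/JSON files are written with 15 significant digits, making
re-runs byte-identical. Ties in cycle segmentation cannot arise because a
strict inequality over a threshold defines breaks; degenerate inputs
(empty series, all-equal values, zero denominators) either return the
documented trivial result or fail with a named error rather than
propagating NaN.

## Known limitations

* The partition and isotope formulas assume all nitrate passes through a
  single nitrite pool with the nitrate label; any direct DNRA from nitrate
  or nitrite-pool labelling dynamics would bias the inversion.
* The electron-balance closure inherits the ~3% biomass-electron blind
  spot of the 20/26/3/5 conventions.
* Reaction energies are standard transformed values only; no correction
  to in-situ concentrations or temperatures is attempted.
* The DNRA switch is a threshold rule with hysteresis, a caricature of
  gene-regulatory dynamics adequate for generating trigger/no-trigger test
  scenarios, not for predicting switching times.
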