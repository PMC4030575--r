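---
title: "The Hsp70 cycle as a non-equilibrium machine: model, solvers and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Hsp70 cycle as a non-equilibrium machine: model, solvers and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsp70cycle)
```

## The model

Hsp70 chaperones (bacterial DnaK) bind substrate proteins while cycling
between an ATP-bound and an ADP-bound conformation. The package models the
canonical four-state cycle

```
      k_on_ATP [S]                    k_on_ADP [S]
  T  <------------>  TS          D  <------------>  DS
      k_off_ATP                       k_off_ADP

  T  <-- k_DT --  D              TS <-- k_DT_S --  DS
  T  -- k_TD -->  D              TS -- k_TD_S -->  DS
```

where `T = Hsp70.ATP`, `D = Hsp70.ADP`, and `TS`, `DS` are the
substrate-bound forms. The ATP-to-ADP conversion lumps two physically
distinct channels: nucleotide *exchange* (rate `k_TD_ex`, `k_TD_ex_S`) and
ATP *hydrolysis* (`k_h`, `k_h_S`), so `k_TD = k_TD_ex + k_h` and
`k_TD_S = k_TD_ex_S + k_h_S`. Exchange shuffles nucleotides with the
chemostatted pool and is thermodynamically neutral; hydrolysis consumes
ATP and is the only detailed-balance-breaking branch. J-domain
co-chaperones (DnaJ) act by raising `k_h_S` only — their binding reactions
are deliberately not modelled explicitly, entering instead as the
*hydrolysis acceleration ratio* `k_h_S / k_h`, the model's central control
parameter. Nucleotide exchange factors are likewise folded into the
effective exchange rates.

### Coarse-graining of exchange

Exchange proceeds through a transient apo state. Eliminating that state at
steady state against fixed `[ATP]` and `[ADP]` gives first-order rates

$$k_{TD}^{ex} = \frac{k_{ATP}^- k_{ADP}^+ [ADP]}{k_{ATP}^+[ATP] + k_{ADP}^+[ADP]},
\qquad
k_{DT} = \frac{k_{ADP}^- k_{ATP}^+ [ATP]}{k_{ATP}^+[ATP] + k_{ADP}^+[ADP]},$$

implemented in `effective_exchange_rates()`. Only the pool *ratio* enters;
the package default mimics the physiological `[ATP]/[ADP] = 10`.

### Thermodynamic closure

Not all six first-order rates are independent: around the hydrolysis-free
loop the accumulated free energy must vanish, which pins the
substrate-bound exchange rate (`closure_k_TD_ex_S()`):

$$k_{TD}^{ex,S} = \frac{k_{TD}^{ex}\,K_D(ATP)\,k_{DT}^S}{K_D(ADP)\,k_{DT}}.$$

`effective_rates()` always derives `k_TD_ex_S` this way, so a
hydrolysis-free parameter set satisfies detailed balance by construction —
`cycle_affinity()`, the log product of forward over backward rates around
the loop, is then zero to machine precision, and becomes positive as soon
as hydrolysis runs. Table-style parameter sets list a single set of
microscopic exchange rates, so the substrate-bound set defaults to the apo
one (`k_DT_S = k_DT`); a distinct `micro_bound` block can be supplied when
evidence warrants it.

When the acceleration ratio is swept, only `k_h_S` (and hence `k_TD_S`)
changes: the closure constrains the *exchange* part of the cycle, which is
nucleotide chemistry and is not touched by hydrolysis stimulation.

### Observables

The effective dissociation constant over the whole cycle is the plug-in
ratio `K_eff = [S]([T]+[D]) / ([TS]+[DS])`. At equilibrium it is the
exchange-weighted average

$$K_{eff}^{eq} = \frac{k_{DT}^S K_D(ATP) + k_{TD}^S K_D(ADP)}{k_{DT}^S + k_{TD}^S},$$

confined to `[K_D(ADP), K_D(ATP)]` — and close to the *weak* end
`K_D(ATP)` at cellular ATP excess. With hydrolysis on, the steady state
still exists and `K_eff` takes a closed rational form in the rates and the
free substrate concentration (`keff_nonequilibrium()`); it can fall orders
of magnitude *below* `K_D(ADP)` — ultra-affinity — down to the kinetic
bound `k_off_ADP / k_on_ATP` (`keff_lower_bound()`): binding through the
fast ATP state, release through the slow ADP state. The energetic price is
the hydrolysis flux `P_diss = k_h[T] + k_h_S[TS]`.

## Numerical choices

* **Steady-state solver.** For fixed free substrate `S` the four state
  concentrations solve a linear system (rank-3 rate matrix, one row
  replaced by chaperone conservation; SVD pseudo-inverse fallback if
  near-singular). `S` itself is pinned by substrate conservation through a
  bracketed root-find on `[max(0, S_tot − Hsp70_tot), S_tot]`, over which
  bound substrate is monotone — the root is unique. The bracket is driven
  essentially to machine precision (default relative tolerance `1e-15`):
  in chaperone excess with strong binding, the conservation residual is
  amplified by the slope of the binding curve, and a looser root would
  visibly break the agreement between the solved state and the closed-form
  `K_eff` evaluated at the solved `S`. Both conservation laws are checked
  to a relative `1e-9` on every return, and negative concentrations are
  treated as internal errors, not warnings.
* **Degenerate inputs.** `S_tot = 0` and `Hsp70_tot = 0` short-circuit to
  exact limits; a zero exchange denominator, zero on-rates, or a
  `k_synth` above its detectability bound (`1e-6` s^-1) are rejected
  eagerly at construction so sweeps fail fast, naming the offending rate.
* **Printed steady-state equations.** Published presentations of the
  non-equilibrium mass balance contain typesetting slips (a stray
  substrate index on an unbinding rate, a dropped operator, a missing
  exchange loss term). The package implements the standard mass-action
  balance for the four-state network and *verifies in its test suite*
  that the printed closed-form `K_eff` emerges from it — the symbolic
  identity was also confirmed independently with a computer-algebra
  system during development. The equilibrium system is solved with the
  total interconversion rates of the hydrolysis-free cycle, since at
  equilibrium no energy is consumed and the substrate-bound branch must
  balance through exchange alone.
* **Sweeps** are log-spaced by default (the phenomenology spans decades),
  61 points per axis, and annotate the physiological acceleration band
  `1e3–1e4` and the equilibrium band `[K_D(ADP), K_D(ATP)]` per grid
  point. Every sweep carries its base parameters, composition and grids
  as attributes, sufficient to reproduce it bit-for-bit.

## The stochastic oracle and the synthetic-data generator

`gillespie_simulate()` runs an exact direct-method simulation of the jump
process in a finite volume (default `1e-16` L, making the standard 40 uM
chaperone pool ~2400 copies; concentrations round to nearest integer
copies). No tau-leaping or other approximation is used: the module exists
to *check* the deterministic solver, and an approximate oracle would
contaminate the tests. Hydrolysis is distinguished from exchange within
the combined ATP-to-ADP channels by thinning with probability
`k_h / k_TD` (`k_h_S / k_TD_S`), so the dissipative flux is measured
without extra reaction channels. Occupancy integrals are accumulated in
contiguous time blocks; `estimate_keff()` resamples blocks (block
bootstrap) for its standard error, and block lengths should exceed the
slowest relaxation (about `1 / (k_DT + k_TD)`, ~50 s at DnaK parameters),
which also sets the burn-in.

`generate_titration()` emulates a noisy equilibrium-binding titration:
bound fraction versus total chaperone on a log grid, with additive
Gaussian noise (default sd 0.02, a typical fluorescence-anisotropy-scale
error) clipped to `[0, 1]`. `fit_keff()` fits the single-site isotherm
`bound = [Hsp70]/(K_eff + [Hsp70])`, which is exact only under chaperone
excess; the generator stores the exact per-point `K_eff` and the
vanishing-substrate closed-form value so recovery can be scored, and the
fitter warns when the excess assumption is violated — out of that regime
the non-equilibrium `K_eff` is genuinely concentration-dependent, which
is itself a signature of broken detailed balance. The confidence interval
is a Student-t interval on `log K_eff` with a residual-bootstrap standard
error; during design this calibrated at ~94% for a nominal 95% on
12-point grids, where plain percentile intervals undercovered (~88%).

What the synthetic data do *not* emulate: titration-point correlations,
heteroscedastic detection noise, pipetting error on the concentration
axis, co-chaperone depletion, or multi-substrate competition. Passing
recovery tests therefore demonstrates the estimator's statistical
soundness on the model's own terms, not robustness to every laboratory
artifact.

## Problem sizes used in the checks

The bundled checks run the solver/formula equivalence on 100 random
positive parameter sets; the stochastic comparison on ~2400 chaperone /
240 substrate copies for 4000 s of simulated time after a 500 s burn-in
(about 2 million events at equilibrium); and the recovery study on 200
independent 12-point titrations with 399 bootstrap refits each. These
sizes give standard errors comfortably below the effects being tested
while keeping a full run in the order of a minute.

## Known limitations

* Co-chaperone binding kinetics are implicit; only `k_h_S` carries JDP
  action, and DnaJ dimerization is not represented.
* `K_eff` reported by sweeps is the self-consistent finite-concentration
  value. In substrate excess at very high acceleration it can sit a few
  percent *below* `K_D(ADP)`: the infinite-substrate limit equals
  `K_D(ADP)` exactly, and the finite-stoichiometry correction approaches
  it from below. Statements that substrate excess confines the constant
  to the equilibrium band are accurate to that few-percent resolution.
* The vanishing-substrate evaluation (`S_free = 0`) of the closed form is
  exposed separately because sweep conventions differ; the package's own
  figures-of-merit use the self-consistent value.
* Rates are temperature-implicit; no Arrhenius scaling is provided.
* The stochastic module chemostats nucleotides exactly (no ATP/ADP
  copy-number fluctuations), mirroring the deterministic treatment.
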