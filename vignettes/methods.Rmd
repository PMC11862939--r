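---
title: "Models and methods behind suprakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind suprakin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suprakin)
```

suprakin analyses container-accelerated bimolecular reactions in three
layers: equilibrium speciation of host–guest mixtures, mass-action kinetics
of the in-cage reaction, and acceleration metrics. This vignette documents
the models, the numerical choices, and what the shipped synthetic data do
and do not establish.

## The speciation model

A `binding_model` consists of components (host cage and guests) with total
concentrations and complexes with overall formation constants
$\beta_s$ (stored as $\log_{10}\beta$). Free concentrations $x_j$ solve the
mass balances
$$T_j = x_j + \sum_s \nu_{sj}\,\beta_s \prod_k x_k^{\nu_{sk}}.$$

Assumptions inherited from the chemistry:

* The acetonitrile solvate of the cage is the *reference free-host state*;
  solvent is never an explicit component, and all constants are defined
  relative to the solvate. Consequently a "1:1 complex" is guest plus
  solvate cage.
* The system is neutral in organic solvent: no protonation equilibria,
  activity coefficients, or ionic strength. Concentrations equal activities.
* The model family is 1 host, at most 2 guest types, at most one host per
  complex — the scope this analysis needs, not a general speciation engine.

**Numerics.** Newton iteration runs on $u_j=\log x_j$, which preserves
positivity with $\beta$ spanning $10^7$–$10^9$. Steps are capped at 5 log
units and halved under a backtracking line search; the initial guess is
$x = T$ (always feasible and within the basin for mM-scale problems). The
converged residual is required to be below $10^{-9}$ relative per component
(typically $10^{-12}$); a nested-bisection fallback covers pathological
$\le 2$-component cases. Components with a total of exactly zero are
eliminated before iteration, so degenerate compositions are legal. The test
suite checks the solver against an independently coded interval-halving
oracle and the closed-form 1:1 quadratic.

**Constants table.** `cage_binding_constants()` transcribes the measured
stepwise constants. Two values exist for the second binding of the ethynyl
guest (1.2 × 10³ in the running text and consistent with the reported
negative cooperativity factor 0.15; 1.3 × 10³ in the table). The default is
the text value; `second_K5 = "table"` selects the other. Model builders use
the *printed* overall constants by default (`use = "printed"`) because those
are the reported quantities; `use = "stepwise"` gives exact products.

One known tension is kept visible rather than patched: with the reported
constants, the 1:2:2 cage/4a/5 mixture also contains ~0.2 mM of the
(5)₂ homocomplex, a species not reported as detected; the NMR detection
threshold is unknown, so the model is left as stated.

## Binding-constant estimation

The estimation mimics the speciation "fine-tuning" workflow: observed
concentration *ratios* of cage species (the robust quantity an integrated
NMR spectrum yields) are compared with simulated ratios. The published
procedure does not state an objective function, so the package makes a
documented choice: weighted least squares on **log** ratios,
$$\chi^2=\sum_i \left(\frac{\log r_i^{sim}-\log r_i^{obs}}{\sigma_i}\right)^2,$$
because integral errors are multiplicative. A coarse grid over
$\log_{10}\beta$ (default step 0.1 within ±3 of a centre) locates the basin
— mirroring manual tuning and making non-identifiability detectable as a
flat grid — and Nelder–Mead (or 1-D golden-section) polishes the optimum.
The default centre is the mass-action heuristic
$(\text{order}-1)\times(-\log_{10}\bar c)$ with $\bar c$ the geometric mean
total; supplying a centre from prior knowledge (constants of related guests)
is both supported and recommended, and is what the shipped recovery studies
do. The heterocomplex protocol fixes the homo constants first and frees only
$\beta_{het}$, exactly as the stepwise experimental protocol dictates.

ITC is *simulation only* (no thermogram fitting — no raw heats are
available): a sequential two-site model solved per injection with perfusion
bookkeeping (displaced volume leaves at pre-injection composition; cell
totals update as $T \leftarrow T(1-\Delta V/V_0)+T_{syr}\Delta V/V_0$). The
heat of an injection is the enthalpy-weighted change in complex content net
of the displaced material, which the package tracks so total heat remains a
state function. The informative output is the isotherm *shape*: two equal
sequential sites inflect at a guest/host molar ratio of 2, one site at 1.

## The kinetic network

`build_cage_network()` assembles the reaction scheme: six reversible binding
steps (two 1:1, two 2:1 homo, and the heteroternary complex reached through
either 1:1 complex) plus the irreversible first-order conversion of the
ternary (Michaelis) complex to the bound product. Key choices:

* **On-rates are not knowable from equilibrium data.** All six steps share a
  reference $k_{on}$ (default $10^7\,\mathrm{M^{-1}s^{-1}}$, a typical
  diffusion-influenced host–guest on-rate) and $k_{off}=k_{on}/K_{step}$.
  Because binding pre-equilibrates much faster than the reaction
  ($k_{intra}\sim10^{-5}\,\mathrm{s^{-1}}$), fitted rate constants must not
  depend on the reference; the suite verifies < 1% variation of the fitted
  $k_{intra}$ across $10^6$–$10^8$.
* The background bulk reaction inside the cage runs is omitted (negligible
  at mM concentrations — the bulk route needs centuries there), and the
  product complex does not dissociate (its binding constant exceeds
  $10^8\,\mathrm{M^{-1}}$); both are fixed modelling switches.
* Runs start from the *equilibrated* binding mixture (`init =
  "equilibrium"`), since complexation is fast on the mixing time scale;
  `init = "unmixed"` exists for the detailed-balance test, whose relaxed
  state must match the equilibrium solver to $10^{-6}$ — the strongest
  structural cross-check between the two halves of the package.

Integration uses `deSolve::lsoda` with an analytic mass-action Jacobian,
rtol $10^{-8}$ and atol $10^{-15}$ M (species span ~10 orders of
magnitude). Host and guest moiety totals are conserved along trajectories to
$10^{-7}$ relative, checked explicitly.

**Estimators.** The initial-rates estimator regresses product concentration
on time over the window where product ≤ 10% of its plateau (minimum three
points; the known (0,0) point at mixing is included by default) and then
fits $v_0 = k_{intra}\,[\mathrm{ternary}]_0$ through the origin. The
full-curve estimator re-simulates the network per candidate and minimises
the SSE over $\log_{10}k_{intra}$ in a bracket, after an 11-point scan that
warns if the objective is not unimodal. The bulk reaction is fitted the same
way with the regioisomer channel ratio held fixed.

Because the measured Michaelis-complex concentrations (0.54, 0.32,
0.10 mM) are an *observable* of the real mixtures rather than a free
input, the package provides `calibrate_ternary_composition()`: it scales a
mixture composition (preserving molar ratios) by a factor found with
`uniroot` until the equilibrium ternary concentration hits the target. The
synthetic initial-rates studies start from compositions calibrated this
way, so the recovery runs at exactly the reported ternary levels.

## Acceleration metrics

$\mathrm{EM}=k_{intra}/k_{bulk}$ (units M);
$\Delta S=-R\ln(\mathrm{EM}/1\,\mathrm{M})$ with
$R=1.9872\,\mathrm{cal\,mol^{-1}K^{-1}}$ and e.u. ≡ cal mol⁻¹ K⁻¹;
$\Delta\Delta G=T|\Delta S|$ at $T=298.15$ K. Reporting rounds EM to two
significant figures and $\Delta S$ to one decimal; internal math is full
precision. `time_to_conversion()` inverts the integrated second-order law in
closed form (both equal and unequal initial concentrations); applied to the
bulk constant at 2 mM reactants it returns ≈283 years to 1 mM product — the
package reports the exact inversion and does not adjust toward any rounder
figure.

## The synthetic-data module

The generators emulate the *derived observables* of the study, not raw
spectra:

* **Titration ratios** — true speciation ratios × lognormal noise. Default
  level 5% (typical integral precision; the study does not state one), with
  every complex observed relative to the free host.
* **Cage time courses** — the network's bound-product trajectory at the NMR
  schedule 0.5, 1, 2, 4, 8, 12, 24, 36, 48 h, × lognormal noise (5%).
* **Bulk time courses** — both regioisomer channels at 25 mM reactants,
  8 HPLC points over 10 days, + additive Gaussian noise (3% of the largest
  signal), clipped at zero.

Every generator takes an explicit seed through `noise_spec()`, runs in a
private RNG stream (the global stream is untouched), and at zero noise
reproduces the forward model bit-for-bit. What passing recovery tests show:
the estimators are unbiased and appropriately tight *under the assumed noise
model and schedule*. What they do not show: robustness to baseline drift,
peak-overlap biases, misassigned integrals, or binding-model
misspecification — none of which the generators emulate.

## Problem sizes and test budget

The shipped tests use deliberately modest sizes: 12 seeded replicates for
the binding-recovery study (grid step 0.2–0.25 within ±1.5–2 log units of
the generating constants), 10 replicates for the initial-rates recovery,
200 replicates only for the cheap law-of-large-numbers check, and single
seeded fits for the full-curve and bulk estimators. These sizes give the
bias/coverage statements comfortable margins while keeping the whole suite
in a few minutes; all tolerances are stated in the tests themselves.

## Known limitations

* Speciation covers the 1-host/≤2-guest family only; no general
  multi-equilibrium engine, no pH or activity corrections.
* ITC thermograms are simulated, never fitted; the experimental average
  binding constant from calorimetry is not recomputable here.
* No catalytic turnover: the product-bound cage is a dead end in the
  network, matching the observed product inhibition.
* The unreactive azide/alkyne pair is representable only as a zero-rate
  scenario; the geometric rationale for its unreactivity is outside the
  scope of a kinetic package.
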