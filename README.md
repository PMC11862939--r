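# suprakin

Quantitative analysis of reaction acceleration inside supramolecular
container hosts ("reactor vessels"): equilibrium speciation of host–guest
mixtures, binding-constant estimation from NMR-style observables, mass-action
kinetics of an in-cage reaction coupled to its binding equilibria, and
acceleration metrics (effective molarity and its thermodynamic equivalents).

The package targets the analysis chain of studies in which a molecular cage
(here, an octa-imine bis-calix[4]pyrrole cage binding pyridine-*N*-oxide
guests at two convergent sites) co-includes an azide and an alkyne and
accelerates their 1,3-dipolar (Huisgen) cycloaddition, but every layer is a
general tool for 1-host / ≤2-guest systems.

## The models

**Speciation.** A binding model lists components *j* with analytical totals
*T<sub>j</sub>* and complexes *s* with overall formation constants
β<sub>s</sub>. The equilibrium free concentrations *x<sub>j</sub>* solve the
mass balances

> *T<sub>j</sub>* = *x<sub>j</sub>* + Σ<sub>s</sub> ν<sub>sj</sub>
> β<sub>s</sub> Π<sub>k</sub> *x<sub>k</sub>*<sup>ν<sub>sk</sub></sup>

solved by damped Newton iteration on log *x* (positivity-preserving for β up
to 10⁹). Derived metrics follow the standard definitions: cooperativity
α = 4 *K*₂/*K*₁ (α = 1 statistical), disproportionation
*K*<sub>dispro</sub> = β<sub>het</sub>²/(β<sub>AA</sub> β<sub>BB</sub>)
(statistical value 4), and path consistency of the two stepwise routes to a
heteroternary complex.

**Kinetics.** The in-cage reaction is modelled as a mass-action network: six
reversible binding steps (on-rates at a common reference, off-rates set by
the stepwise constants) feeding the ternary Michaelis complex, which reacts
irreversibly with first-order constant *k*<sub>intra</sub> to the bound
product. The bulk reference reaction is second order with two parallel
regioisomer channels. Acceleration is quantified as the effective molarity

> EM = *k*<sub>intra</sub>/*k*<sub>bulk</sub>,  ΔS = −*R* ln(EM/1 M),
> ΔΔG = *T*|ΔS|

**Estimation.** Binding constants are estimated by matching simulated
speciation ratios to observed concentration ratios (weighted log-ratio least
squares, grid scan + local refinement); *k*<sub>intra</sub> by initial rates
(v₀ vs ternary concentration through the origin) and by full-curve network
fitting with *k*<sub>intra</sub> the only free parameter; *k*<sub>bulk</sub>
by least squares on the product curve. A seeded synthetic-data module
emulates NMR integrals (5% multiplicative lognormal noise) and HPLC
quantitation (3% additive noise) so every estimator is exercised by
round-trip recovery.

## Worked example

```r
library(suprakin)

# cage 2 mM with 2 equiv each of guests 4a and 5, five-species model
m <- guest_pair_model("4a", "5", c(2e-3, 4e-3, 4e-3))
solve_free_concentrations(m)
#> complexes (mM):
#>     C.4a      C.5  C.4a.4a    C.5.5   C.4a.5
#> 0.020947 0.065308 0.900243 0.220529 0.792218

cooperativity_alpha(cage_stepwise("4a", "4a"))   # 6.2
disproportionation_constant(2.8e8, 6.2e8, 4.0e7) # 3.16

acceleration_result(k_intra = 5.0e-5, k_bulk = 5.6e-8)
#>   EM       8.9e+02 M
#>   delta_S  -13.5 e.u.
#>   delta_G  4.0 kcal/mol at 298.15 K
```

The speciation says the 2 mM host partitions mainly into the (4a)₂ homo
complex (0.90 mM) and the 4a·5 hetero complex (0.79 mM) — the two species an
NMR spectrum of this mixture shows. The EM of ~9 × 10² M means the caged
reaction proceeds as fast as the bulk reaction would at a ~900 M reactant
concentration; expressed entropically the confinement is worth ~13.5 e.u.,
i.e. ~4 kcal mol⁻¹ toward the transition state. For perspective,

```r
time_to_conversion(bulk_reaction_model(5.6e-8, 0, 2e-3, 2e-3), 1e-3)
# 8.93e9 s  ~ 283 years for the bulk reaction to make 1 mM product at 2 mM
```

while the caged reaction finishes in two days.

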