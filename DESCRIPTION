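Package: suprakin
Title: Speciation, Binding and Kinetics of Host-Guest Reactor Cages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying reaction acceleration inside
    supramolecular container hosts. Defines multi-component host-guest
    binding models, solves equilibrium speciation by damped Newton
    iteration on log concentrations, and estimates stepwise binding
    constants from NMR-style concentration-ratio observations. Builds
    mass-action kinetic networks coupling reversible binding equilibria
    to an irreversible in-cage reaction, estimates intracavity rate
    constants by initial rates and by full-curve fitting, models the
    bulk bimolecular reference reaction with parallel regioisomer
    channels, and converts rate-constant ratios into effective
    molarities and their entropy and free-energy equivalents. A seeded
    synthetic-data module emulates NMR and HPLC observables so every
    estimation stage can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
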