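Package: daisyquorum
Title: Deterministic and Stochastic Models of Daisy Quorum Gene Drive
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates daisy quorum drive, a two-stage genetic biocontrol
    design that couples a self-exhausting CRISPR daisy-chain homing drive to
    a two-locus toxin-antidote fitness-valley construct carrying a payload.
    Provides exact multilocus gamete-frequency recursions for arbitrary
    daisy-chain length (diploid selection, germline homing conversion, and
    recombination), equilibrium and separatrix analysis with release-threshold
    bisection, closed-form invasion conditions for the cargo, linear
    stepping-stone metapopulation dynamics with gene swamping, discretized
    reaction-diffusion dynamics on homogeneous or patchy one-dimensional
    landscapes with travelling-wave-speed estimation, and individual-based
    finite-population simulations with demography for population modification
    and suppression scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
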