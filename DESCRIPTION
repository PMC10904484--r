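Package: gamblesim
Title: Two-Stage Economic Model of Gambling Participation and Harm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a two-stage economic model of gambling behaviour in
    which agents maximise current-period decision utility built from
    quadratic psychological and monetary utility components plus a craving
    disutility driven by a geometrically depreciating stock of past
    gambling. Provides closed-form results (myopic optimal amount,
    equilibrium amount and stock, convergence condition, long-run harm
    condition), a per-agent trajectory simulator with income and cap
    constraints, cohort microsimulation over heterogeneous sampled agents,
    intervention transforms (craving reduction, curvature shifts, amount
    caps, deposit limits), and a command-line interface for simulation,
    classification, cohort runs and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
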