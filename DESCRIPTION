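Package: cyclenoise
Title: Noise in Cell-Cycle-Coupled Bursty Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how coupling protein synthesis to the cell
    cycle shapes stochastic fluctuations in protein copy numbers. A stable
    protein is produced in random bursts whose arrival rate depends on the
    current cell-cycle stage; molecules are partitioned between daughters at
    division with tunable error. The package provides exact closed-form
    steady-state mean and noise formulas with an intrinsic-noise
    decomposition into bursty-synthesis and partitioning-error components,
    an independent moment-ODE solver used for cross-validation, an exact
    event-driven single-lineage stochastic simulator (including a two-colour
    mode and an extended promoter/mRNA model), and utilities for comparing
    cell-cycle regulation strategies at a fixed mean expression level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
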