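Package: cfba
Title: Conditional Flux Balance Analysis for Diurnal Phototrophic Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Time-discretized, resource-constrained linear-programming
    framework for cyclic (diurnal) growth of metabolic networks. Every flux
    is capacity-limited by the amount of its catalyzing compound (enzyme,
    ribosome or pigment), which is itself a product of metabolism. The
    cyclic growth factor over a full period is maximized by bisection over
    linear-program feasibility, with flux variability analysis, catalytic
    efficiency calibration from reference flux distributions, light-profile
    scenarios and robustness scans. Ships a three-reaction illustrative
    model and a minimal diurnal model of Synechocystis sp. PCC 6803, and a
    sparse primal-dual interior-point linear-programming solver built on
    'Matrix'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    quadprog
Config/testthat/edition: 3
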