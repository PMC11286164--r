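Package: loopfbm
Title: Series-of-Loops Fibre Bundle Model for Extreme-Extensibility Looped Fibre Meta-Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static, displacement-controlled simulator for bundles of
    parallel fibres in which some fibres store hidden length in series of
    loops that unravel at stochastic critical strains, as in the cribellar
    capture threads of the Southern house spider (Kukulcania hibernalis).
    Implements the classic equal-load-sharing fibre bundle model closed form,
    a hierarchical slack-transmission coupling between looped and straight
    elements, a validated configuration layer with the default 11-element
    Kukulcania thread, parametric sweeps, and analysis utilities for
    force-elongation curves (sawtooth drop detection, peak/break summaries,
    vertical-test geometry and weight-to-force conversion).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
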