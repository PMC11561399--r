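Package: cytoloop
Title: Reactive Flow-Cytometry Feedback Control for Fed-Batch Cultivation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-loop process control driven by at-line flow cytometry of a
    GFP biosensor strain. Reads and writes a defined subset of the FCS 3.1
    listmode format, applies automated debris and quadrant gating (damaged /
    intact GFP-positive / intact GFP-negative), smooths per-sample statistics
    with an exponential moving average, estimates three-point slopes, and runs
    a stepwise feed-pump state machine with a propidium-iodide viability
    safeguard. A phenomenological fed-batch simulator with biosensor
    induction/adaptation dynamics and event-level FCS synthesis closes the
    loop so the whole control chain can be exercised without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), deSolve, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
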