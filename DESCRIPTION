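Package: stcsim
Title: Synaptic Tagging and Capture Dynamics in a Dendritic Compartment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kinetic model of synaptic tagging and capture (STC) in a 10-um
    dendritic compartment: eight coupled nonlinear ordinary differential
    equations describe per-spine calcium-cascade activity, synaptic tag,
    captured plasticity-related protein (PRP), plasticity state and spine
    head volume, together with a shared dendritic PRP synthesis pathway.
    Provides glutamate-uncaging style e-LTP and l-LTP stimulation protocols,
    a stiff piecewise integrator with breakpoints at pulse edges, and the
    simulation experiments that probe the temporal window of late
    associativity and the competitive capture of PRPs by multiple spines,
    including intragroup statistics and enhancement-type classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
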