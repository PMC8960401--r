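Package: meanet
Title: Multi-Well Micro-Electrode Array Network Activity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous network activity recorded on
    multi-well micro-electrode arrays (MEAs) from excitatory/inhibitory
    neuronal co-cultures. Provides Butterworth band-limiting and
    threshold-based spike detection, inter-spike-interval burst detection
    with merge and duration/spike-count filters, coincidence-based network
    burst detection, nine well-level network activity parameters, burst
    shape alignment with per-bin Holm-Sidak comparisons, well quality
    control and exclusion rules, canonical discriminant analysis with
    structure matrix, postsynaptic-current decay-time classification, and a
    synthetic-data generator that plants recoverable excitation/inhibition
    network structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
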