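Package: melodytrf
Title: Melodic Expectation Encoding in Continuous Neural Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis tools for studying how melodic
    expectations (surprise and entropy of note pitch and onset time under a
    variable-order Markov model) are encoded in continuous neural responses
    to music. Includes a synthetic-data generator with known ground truth,
    a PPM-style n-gram expectation model with long- and short-term
    combination and memory-restriction controls, lagged ridge-regression
    temporal response functions with cross-validated prediction and
    backward-elimination lag relevance, note-locked ERP analysis with
    envelope-matched contrasts, and permutation-based statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
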