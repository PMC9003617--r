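Package: dualosc
Title: Coupled Van der Pol Oscillator Model of Discrete-Continuous
    Dual-Task Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates bottom-up attention during a discrete-continuous
    dual task (an auditory reaction-time task performed concurrently with
    visuomotor pursuit tracking) as four coupled, sinusoidally forced Van
    der Pol oscillator units, one per stimulus feature (auditory target
    and non-target, tracking speed and direction change). A time-varying
    on-off gate on the shared coupling drive models fast attentional
    switching between the two tasks. Includes a fixed-step integrator,
    peak-envelope ("push") extraction, threshold-crossing response-time
    and harmonic-RMS readouts, the catalogue of eight experimental
    sequence conditions plus coupling/strength/similarity manipulations,
    a synthetic pursuit-tracking trace generator with hesitation
    detection, and an embedded behavioral reference table for
    model-versus-behavior correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
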