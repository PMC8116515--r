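Package: t2djourney
Title: System Dynamics Simulation of the Type 2 Diabetes Patient Journey
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic stock-and-flow (System Dynamics) simulation of the
    Dutch type 2 diabetes patient journey: normoglycemic individuals become
    (un)diagnosed pre-diabetic and eventually type 2 diabetic, with recovery,
    reversal ("no medicine necessary") and relapse paths. Lifestyle and
    bariatric intervention programmes act as policy levers on recovery and
    onset flows, and population stocks are translated into annual societal
    costs by payer (authorities, insurer, employer, patient organisations,
    programmes). Ships the published scenario presets, a YAML run
    configuration format, a command line interface, and model validation
    utilities: extreme-condition tests, one-at-a-time behaviour sensitivity
    analysis, and behaviour reproduction against national statistics anchors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
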