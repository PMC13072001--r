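Package: sowcal
Title: Indirect Calorimetry Energy Evaluation of Feeds for Gestating Sows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for determining digestible, metabolizable, and net energy
    of feed ingredients for gestating sows from respiration-chamber indirect
    calorimetry and total-collection balance trials. Implements trapezoidal
    integration of chamber gas-exchange traces, total heat production by the
    Brouwer equation, fasting heat production from an overnight fasting
    window, apparent total-tract digestibility and nitrogen balance, the
    retained-energy partition into protein and lipid, difference-method
    ingredient energy values under proportional substitution, Pearson
    correlation screening of chemical composition against energy values, and
    SAS-style stepwise construction of net-energy prediction equations. A
    synthetic-trial generator simulates a complete sow calorimetry experiment
    from known ground truth so every pipeline stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
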