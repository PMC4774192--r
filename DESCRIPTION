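Package: hepatoflux
Title: Kinetic Modelling and Regulatory Analysis of Hepatic Glucose Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A kinetic model of glucose metabolism in rat hepatocytes
    (glycolysis, gluconeogenesis and glycogen turnover) coupled to plasma
    glucose through empirical glucose-hormone transfer functions and
    hormone-dependent reversible enzyme phosphorylation. Provides steady-state
    and diurnal simulation of the hepatic glucose exchange flux, glucose
    set-point analysis, dissection of regulation modes (enzyme abundance,
    phosphorylation, allosteric effectors) via a time-integrated curve
    distance, metabolic control analysis (flux control coefficients,
    pi-elasticities, response coefficients), synthetic generators for every
    external input, and SBML model exchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
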