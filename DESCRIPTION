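Package: sapflux
Title: Sap Flux Processing and Drought-Response Analysis for Dry-Forest Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes thermal dissipation probe (TDP) sap-flow measurements
    into sap flux density, corrects for radial flux variation using heat field
    deformation (HFD) profiles fitted with a Gaussian and integrated as a solid
    of revolution, scales to whole-tree daily water use, and quantifies drought
    responses: vapor pressure deficit and soil-moisture regressions, wet/dry
    contrasts with ANOVA and Tukey letters, a linear mixed model with
    Satterthwaite denominator degrees of freedom, least-squares means and
    marginal/conditional R-squared, and diurnal sap-flux/VPD hysteresis loop
    metrics. Includes a synthetic study generator emulating a tropical
    dry-forest elevation gradient with exported ground truth, so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    Matrix,
    numDeriv,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
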