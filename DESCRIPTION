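Package: pepflux
Title: Pyruvate Kinase Kinetics and Thermodynamics of the PEP Node
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how allosteric regulation of bacterial
    pyruvate kinase shapes the phosphoenolpyruvate (PEP) pool and the
    thermodynamic feasibility of gluconeogenesis. Provides allosteric rate
    laws (Hill-adapted nonessential activation, hyperbolic ATP inhibition),
    conversion of NADH-coupled assay absorbance traces to initial rates, and
    nonlinear least-squares parameter estimation; max-min driving force (MDF)
    pathway thermodynamics by linear programming over bounded metabolite
    concentrations, with cumulative Gibbs-energy profiles, bottleneck
    detection and the flux-force efficacy relation; mass-isotopologue
    unlabeled-fraction analysis for in vivo isotope tracing; metabolomics
    normalization, Z-scoring, standard-addition quantification, carbon-use
    efficiency and growth-rate estimation; and seeded synthetic-data
    generators emulating the statistical structure of plate-reader and LC-MS
    measurements so every analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
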