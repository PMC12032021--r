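Package: maternalsim
Title: Individual-Based Simulation of Maternal and Perinatal Health Services
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A stochastic individual-based model of pregnancy, childbirth and
    the early postnatal period in a low-resource health system, patterned on
    maternity care in Malawi. The package simulates monthly antenatal,
    intrapartum and weekly postnatal/neonatal natural history of common
    obstetric and newborn complications, care seeking from multivariable
    regression models, delivery of screening, preventative and curative
    interventions conditional on consumable availability, clinical competence
    and emergency obstetric care staffing, the three-delays framework with a
    healthcare-worker-time "squeeze" factor, and scenario counterfactuals that
    change the coverage and quality of antenatal, intrapartum and postnatal
    services. Utilities aggregate paired Monte Carlo runs into mortality rates
    (MMR, NMR, SBR), disability-adjusted life years, healthcare-worker time
    accounts and maximum-ability-to-pay economics against a cost-effectiveness
    threshold, and calibrate care-seeking parameters to coverage targets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
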