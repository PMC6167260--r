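Package: cdburden
Title: Modelled Burden of Congenital Disorders and Access to Optimal Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the proportion of a population with access to optimal
    care for congenital disorders from infant mortality (with consanguinity
    and HIV adjustments), applies intervention models (mandatory folic-acid
    flour fortification, anti-D prophylaxis, prenatal diagnosis and
    termination of pregnancy, retrospective and prospective genetic risk
    information) to baseline birth prevalences, and allocates affected
    pregnancies to a conserved envelope of outcomes (termination, stillbirth,
    livebirth; under-5 death, disability, cure) with births-weighted
    aggregation from countries to regions. Includes a deterministic synthetic
    country/condition fixture generator so the full pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
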