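Package: edtsim
Title: Discrete-Event Simulation of a Visual Electrodiagnostic Referral
    Pathway with Hand-Held ERG Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a hospital visual electro-diagnostic testing (EDT)
    referral pathway as a capacity-constrained FIFO waiting list fed by
    Poisson referral streams, with an optional point-of-referral
    electroretinogram (ERG) screening step characterised by sensitivity and
    specificity. Provides a synthetic referral-cohort generator, a
    discrete-event engine with weekly appointment-slot release, a
    deterministic fluid-queue oracle for verification, closed-form screening
    error expectations, a five-experiment scenario driver with a warm-up
    replication protocol, and table-style reporting of waiting times,
    lab-test demand and screening error counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
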