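Package: ap1grn
Title: Compartmental Model and Multivariate Analysis of AT1R-Driven AP-1
    Dimer Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and simulates a two-compartment kinetic model of the
    angiotensin II / AT1R gene regulatory network in brainstem neurons, in
    which the signaling kinases ERK, FRK and JNK drive phosphorylation of
    Elk-1, c-Fos, c-Jun and ATF-2, formation of ppc-Fos:ppc-Jun and
    ppc-Jun:ppc-Jun AP-1 dimers, and transcription of tyrosine hydroxylase.
    Provides Monte-Carlo sequential-constraint parameter screening against
    normalized target time series, time-resolved variance-based global
    sensitivity analysis (first-order and total-effect indices and their
    ratio), template-matching classification of perturbed AP-1 responses,
    and constrained decision-tree analysis of the perturbed parameter
    space, together with a synthetic-data generator for kinase forcing
    profiles and surrogate fitting targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    rpart,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
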