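Package: mevrd
Title: Multievent Robust-Design Capture-Recapture Models for Intermittent
    Breeders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits 3-state (breeder, nonbreeder, dead) multievent
    capture-recapture models with a robust-design observation process:
    weekly breeding-season surveys collapsed into two within-season capture
    periods, combined with auxiliary moult and winter resightings, yield
    eight composite events per animal per year.  Provides encounter-history
    encoding from raw resight records, a forward hidden-Markov likelihood
    conditioned on first capture, maximum-likelihood estimation with
    multiple random starts, Wald intervals, QAIC model selection with
    Akaike weights, overdispersion estimation by parametric bootstrap, and
    a two-level synthetic-data simulator (event-level and raw weekly
    survey records) for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
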