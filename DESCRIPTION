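Package: lifepound
Title: Valuation of Personal Health Data and a Desk-Scale Token Marketplace Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a cost model for personal biomedical records based on
    record type base values, half-life time-value kernels, quality aggregation,
    combination synergies, superlinear group value across users, and a
    pedigree-derived family-relationship multiplier. Includes marginal purchase
    pricing and proportional payment attribution. Around the model it provides
    a desk-scale simulator of a permissioned health-data marketplace: a
    hash-linked block ledger with Merkle inclusion and absence proofs, Shamir
    threshold secret sharing among key keepers, escrow-based data validation
    with timeouts, purchase workflows in a utility token (the LifePound), and a
    fully seeded synthetic generator for users, pedigrees, record streams and
    end-to-end scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    openssl,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
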