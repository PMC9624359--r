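Package: radforage
Title: Radial Foraging Strategy Modelling and Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models animal foraging over a depleting set of food positions
    using k-th nearest-neighbour order statistics ("radial levels").
    Constructs long-term-memory (LMRFT) and short-term-memory (SMRFT)
    optimal foraging paths, compares observed foraging paths against the
    modelled ones with a structural metric on strictly ascending vectors,
    and identifies an agent's foraging radial level by argmin matching.
    Includes seeded generators for synthetic food domains and observed
    paths, bundled worked-example datasets, and a reproduction driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
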