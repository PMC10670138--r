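Package: notescope
Title: Text Mining of Patient Body-Image Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated assessment of body-image perception from short free-text
    patient notes. Provides five-emotion intensity profiling through an
    affective lexicon extended with word-embedding nearest-neighbour
    interpolation, hybrid (dictionary plus classifier) three-class sentiment,
    part-of-speech vocabulary profiling, and latent-semantic-analysis based
    detection of three psychological difficulty areas (body image, acceptance
    of the environment, self-esteem) with a four-way context classifier and
    agreement scoring against expert flags. Includes a seeded synthetic-data
    generator emulating the structure of elicited body-description notes so
    the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
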